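# Shared fixtures and independent oracles. Everything is built in code.

.fix_env <- new.env(parent = emptyenv())

# small molecules exercising rings, branches, heteroatoms, charges
fixture_smiles <- function() {
  c(ethane = "CC", propane = "CCC", butane = "CCCC",
    isobutane = "CC(C)C", isopentane = "CCC(C)C",
    cyclopropane = "C1CC1", cyclohexane = "C1CCCCC1",
    benzene = "c1ccccc1", pyridine = "c1ccncc1",
    toluene = "Cc1ccccc1", phenol = "Oc1ccccc1",
    anisole = "COc1ccccc1", aniline = "Nc1ccccc1",
    thiophene = "c1ccsc1", dmf = "CN(C)C=O",
    acetic = "CC(=O)O", acetonitrile = "CC#N",
    tfm_benzene = "FC(F)(F)c1ccccc1",
    chlorobenzene = "Clc1ccccc1")
}

fixture_graphs <- function() {
  if (is.null(.fix_env$graphs)) {
    smi <- fixture_smiles()
    .fix_env$graphs <- parse_molecules(unname(smi), names(smi))
  }
  .fix_env$graphs
}

# brute-force oracle: all connected m-edge subsets via exhaustive subset
# filtering, independent of the package's compiled enumerator
brute_subgraphs <- function(graph, m) {
  L <- graph$L
  if (m > L) return(list())
  combos <- utils::combn(L, m, simplify = FALSE)
  is_conn <- function(edges) {
    bi <- graph$bonds$i[edges]
    bj <- graph$bonds$j[edges]
    atoms <- unique(c(bi, bj))
    seen <- atoms[1]
    repeat {
      nxt <- unique(c(bj[bi %in% seen], bi[bj %in% seen]))
      new <- setdiff(nxt, seen)
      if (!length(new)) break
      seen <- c(seen, new)
    }
    length(seen) == length(atoms)
  }
  Filter(is_conn, combos)
}

# definition-based classifier used as oracle against the compiled census
brute_classify <- function(graph, edges) {
  bi <- graph$bonds$i[edges]
  bj <- graph$bonds$j[edges]
  atoms <- unique(c(bi, bj))
  if (length(edges) >= length(atoms)) return("Ch")
  deg <- table(factor(c(bi, bj), levels = atoms))
  if (all(deg <= 2)) return("P")
  if (sum(deg >= 3) == 1 && all(deg[deg < 3] == 1)) return("C")
  "PC"
}

# a small simulated study shared by fusion / selection / training tests
small_sim <- function() {
  if (is.null(.fix_env$sim)) {
    spec <- generator_spec(n_molecules = 60L, seed = 421L)
    sim <- simulate_assay_dataset(spec)
    cur <- curate_assays(sim$cases)
    spl <- split_assays(cur)
    desc <- compute_descriptors(sim$molecules)
    full <- dplyr::left_join(spl, desc, by = "molecule_id") |>
      expand_labels(default_condition_registry())
    train <- dplyr::filter(full, partition == "train")
    fus <- fit_fusion(train)
    ftr <- fuse_descriptors(train, fus)
    fte <- fuse_descriptors(dplyr::filter(full, partition == "test"), fus)
    .fix_env$sim <- list(spec = spec, sim = sim, full = full, train = train,
                         fus = fus, ftr = ftr, fte = fte)
  }
  .fix_env$sim
}

small_model <- function() {
  if (is.null(.fix_env$model)) {
    s <- small_sim()
    sel <- suppressWarnings(select_features(s$ftr, s$ftr$ACRC, k = 10))
    cols <- attr(sel, "selected")
    cfg <- ptml_config(restarts = 4L, retained = 2L, maxit = 80L, seed = 99L)
    m <- suppressWarnings(
      ptml_train(s$ftr[c("ACRC", "dt", "ct", "mc", cols)], config = cfg,
                 fusion = s$fus, registry = default_condition_registry()))
    .fix_env$model <- list(model = m, cols = cols, sel = sel)
  }
  .fix_env$model
}
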