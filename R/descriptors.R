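.sg_types <- c("P", "C", "PC", "Ch")

#' Kier-Hall valence delta values
#'
#' `delta_v = Zv - h` for second-period atoms and
#' `delta_v = (Zv - h) / (Z - Zv - 1)` beyond, with the valence-electron
#' count `Zv` adjusted by the formal charge (a cation has one valence
#' electron fewer). Degenerate values (`delta_v <= 0`) raise an error
#' naming the atom.
#'
#' @param graph A `mol_graph`.
#' @return Numeric vector, one value per atom.
#' @export
valence_deltas <- function(graph) {
  at <- graph$atoms
  zv_eff <- at$zv - at$charge
  dv <- ifelse(at$z <= 10,
               zv_eff - at$h,
               (zv_eff - at$h) / (at$z - zv_eff - 1))
  bad <- which(dv <= 0)
  if (length(bad)) {
    rlang::abort(paste0("degenerate valence delta for atom ", bad[1L], " (",
                        at$element[bad[1L]], ") in '", graph$smiles, "'"))
  }
  dv
}

# edge degree in the whole graph: eps(i,j) = delta_i + delta_j - 2
.edge_degrees <- function(graph) {
  d <- graph$atoms$degree
  d[graph$bonds$i] + d[graph$bonds$j] - 2L
}

#' Weighted bond-based spectral moments
#'
#' Builds the `L x L` bond adjacency matrix `E` (off-diagonal 1 where two
#' bonds share an atom, diagonal loaded with the scheme's bond weights) and
#' returns the traces of its powers, `mu_o = tr(E^o)`, for orders 1 to
#' `o_max`. The trace expansion makes each moment a sum over closed walks,
#' i.e. over molecular fragments of up to `o` bonds.
#'
#' @param graph A `mol_graph`.
#' @param scheme Weighting scheme code (see [weight_schemes()]).
#' @param o_max Highest order (default 7).
#' @return Named numeric vector `mu1..mu{o_max}`.
#' @export
spectral_moments <- function(graph, scheme, o_max = 7L) {
  stopifnot(inherits(graph, "mol_graph"))
  w <- bond_weights(graph, scheme)
  L <- graph$L
  E <- matrix(0, L, L)
  if (L > 1L) {
    for (a in seq_len(L - 1L)) {
      for (b in (a + 1L):L) {
        share <- graph$bonds$i[a] == graph$bonds$i[b] ||
          graph$bonds$i[a] == graph$bonds$j[b] ||
          graph$bonds$j[a] == graph$bonds$i[b] ||
          graph$bonds$j[a] == graph$bonds$j[b]
        if (share) E[a, b] <- E[b, a] <- 1
      }
    }
  }
  diag(E) <- w
  out <- numeric(o_max)
  P <- diag(L)
  for (o in seq_len(o_max)) {
    P <- P %*% E
    out[o] <- sum(diag(P))
  }
  stats::setNames(out, paste0("mu", seq_len(o_max)))
}

.census_for <- function(graph, m_max = 6L) {
  dv <- valence_deltas(graph)
  eps <- .edge_degrees(graph)
  ev <- ifelse(eps > 0, 1 / sqrt(eps), 0)
  subgraph_census_cpp(graph$bonds$i - 1L, graph$bonds$j - 1L,
                      nrow(graph$atoms), as.integer(m_max),
                      1 / sqrt(dv), ev)
}

#' Kier-Hall valence connectivity index
#'
#' Sum over connected `m`-edge subgraphs of the given structural type of
#' the product over subgraph atoms of `delta_v^(-1/2)`.
#'
#' @param graph A `mol_graph`.
#' @param sg_type `"P"`, `"C"`, `"PC"` or `"Ch"`.
#' @param m Subgraph order, 1 to 6.
#' @return A single numeric value.
#' @export
valence_connectivity <- function(graph, sg_type, m) {
  sg_type <- match.arg(sg_type, .sg_types)
  stopifnot(m >= 1, m <= 6)
  cen <- .census_for(graph, m_max = as.integer(m))
  cen$atom_sum[cen$type == sg_type & cen$m == m]
}

#' Bond-based connectivity index
#'
#' Sum over connected `m`-edge subgraphs of the given type of the product
#' over subgraph edges of `eps^(-1/2)`, with the edge degree
#' `eps = delta_i + delta_j - 2` taken in the whole graph. Subgraphs
#' containing an `eps = 0` bond (the bond of a two-atom molecule)
#' contribute zero.
#'
#' @inheritParams valence_connectivity
#' @return A single numeric value.
#' @export
bond_connectivity <- function(graph, sg_type, m) {
  sg_type <- match.arg(sg_type, .sg_types)
  stopifnot(m >= 1, m <= 6)
  cen <- .census_for(graph, m_max = as.integer(m))
  cen$edge_sum[cen$type == sg_type & cen$m == m]
}

#' Descriptor identifiers
#'
#' The fixed 194-column grid of graph-theoretical indices: bond-based
#' spectral moments for 7 weighting schemes and orders 1-7, valence and
#' bond connectivity indices for 4 subgraph types and orders 1-6, plus the
#' partially normalized twin of every index (the raw value divided by the
#' bond count `L`, prefixed `N`).
#'
#' @return Character vector of descriptor names, e.g. `"SM(Dip)5"`,
#'   `"NXv(P)6"`, `"Ne(C)4"`.
#' @export
descriptor_ids <- function() {
  schemes <- weight_schemes()$code
  sm <- as.vector(t(outer(schemes, 1:7,
                          function(s, o) paste0("SM(", s, ")", o))))
  xv <- as.vector(t(outer(.sg_types, 1:6,
                          function(t, m) paste0("Xv(", t, ")", m))))
  ee <- as.vector(t(outer(.sg_types, 1:6,
                          function(t, m) paste0("e(", t, ")", m))))
  raw <- c(sm, xv, ee)
  c(raw, paste0("N", raw))
}

#' Full descriptor vector for one molecule
#'
#' @param graph A `mol_graph`.
#' @return Named numeric vector over [descriptor_ids()].
#' @export
descriptor_vector <- function(graph) {
  stopifnot(inherits(graph, "mol_graph"))
  schemes <- weight_schemes()$code
  sm <- unlist(lapply(schemes, function(s) spectral_moments(graph, s)))
  cen <- .census_for(graph, m_max = 6L)
  pick <- function(col) {
    unlist(lapply(.sg_types, function(t) {
      v <- numeric(6)
      for (m in 1:6) {
        hit <- cen$type == t & cen$m == m
        v[m] <- if (any(hit)) cen[[col]][hit] else 0
      }
      v
    }))
  }
  raw <- c(sm, pick("atom_sum"), pick("edge_sum"))
  out <- c(raw, raw / graph$L)
  stats::setNames(out, descriptor_ids())
}

#' Compute descriptors for a table of molecules
#'
#' Takes a data frame with a SMILES column, parses each molecule and
#' returns one row per molecule with the full raw + normalized descriptor
#' grid, ready to be joined back onto assay cases.
#'
#' @param data Data frame with at least the SMILES column.
#' @param smiles_col,id_col Column names (defaults `"smiles"`,
#'   `"molecule_id"`; if the id column is absent the SMILES is used).
#' @param on_error Passed to [parse_molecules()].
#' @return Tibble: `molecule_id`, `molar_mass`, then one column per
#'   descriptor id.
#' @export
compute_descriptors <- function(data, smiles_col = "smiles",
                                id_col = "molecule_id",
                                on_error = c("stop", "drop")) {
  on_error <- match.arg(on_error)
  stopifnot(smiles_col %in% names(data))
  smiles <- data[[smiles_col]]
  ids <- if (id_col %in% names(data)) as.character(data[[id_col]]) else smiles
  dup <- !duplicated(ids)
  graphs <- parse_molecules(smiles[dup], ids[dup], on_error = on_error)
  rows <- purrr::map(graphs, function(g) {
    v <- descriptor_vector(g)
    bind_cols(tibble(molecule_id = g$id, molar_mass = g$molar_mass),
              as_tibble(as.list(v)))
  })
  bind_rows(rows)
}
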