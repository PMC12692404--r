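#' @useDynLib ptmlfbtd, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import dplyr
#' @importFrom rlang .data abort warn inform %||%
#' @importFrom tibble tibble as_tibble
NULL

.ptml_cache <- new.env(parent = emptyenv())

#' Contribution and parameter tables
#'
#' Returns one of the physicochemical contribution tables shipped with the
#' package: `"elements"` (atomic number, valence electrons, standard atomic
#' weight), `"tpsa"` (polar-surface-area fragment contributions),
#' `"crippen"` (atom-typed hydrophobicity/molar-refractivity contributions),
#' `"bond_lengths"`, `"bond_dipoles"` and `"gasteiger"` (orbital
#' electronegativity parameters). Tables are plain CSV resources under
#' `inst/extdata` with provenance comments, so they can be inspected or
#' substituted.
#'
#' @param name Table name.
#' @return A tibble.
#' @export
#' @examples
#' contribution_table("elements")
contribution_table <- function(name = c("elements", "tpsa", "crippen",
                                        "bond_lengths", "bond_dipoles",
                                        "gasteiger")) {
  name <- match.arg(name)
  key <- paste0("tbl_", name)
  if (!is.null(.ptml_cache[[key]])) return(.ptml_cache[[key]])
  file <- c(elements = "elements.csv", tpsa = "tpsa_contributions.csv",
            crippen = "crippen_contributions.csv",
            bond_lengths = "bond_lengths.csv",
            bond_dipoles = "bond_dipoles.csv",
            gasteiger = "gasteiger_params.csv")[[name]]
  path <- system.file("extdata", file, package = "ptmlfbtd", mustWork = TRUE)
  tbl <- readr::read_csv(path, comment = "#", show_col_types = FALSE,
                         progress = FALSE)
  .ptml_cache[[key]] <- tbl
  tbl
}

#' Weighting schemes for bond-based spectral moments
#'
#' The seven physicochemical weighting schemes applied to the diagonal of
#' the bond adjacency matrix: bond standard distance (`Std`), bond dipole
#' moment (`Dip`), hydrophobicity (`Hyd`), polar surface area (`Psa`),
#' molar refractivity (`Mol`), Gasteiger-Marsili charges (`Gas`) and atomic
#' weight (`Ato`). `Std` and `Dip` are looked up per bond; `Hyd`, `Psa`,
#' `Mol` and `Ato` are atomic contributions converted to bond weights by
#' `w(i,j) = p_i/delta_i + p_j/delta_j`; `Gas` uses computed partial
#' charges.
#'
#' @return A tibble with columns `code`, `kind`, `table`, `source`.
#' @export
weight_schemes <- function() {
  tibble(
    code = c("Std", "Dip", "Hyd", "Psa", "Mol", "Gas", "Ato"),
    kind = c("bond-table", "bond-table", "atom-contribution",
             "atom-contribution", "atom-contribution", "computed-charge",
             "atom-contribution"),
    table = c("bond_lengths", "bond_dipoles", "crippen", "tpsa", "crippen",
              "gasteiger", "elements"),
    source = c(
      "Covalent bond-length compilation (Allen 1987; CRC Handbook)",
      "Bond-moment tables (Smyth 1955; Minkin et al. 1970)",
      "Simplified Wildman-Crippen atomic logP contributions",
      "Ertl TPSA fragment contributions (Ertl et al. 2000)",
      "Simplified Wildman-Crippen atomic MR contributions",
      "Gasteiger-Marsili PEOE sigma charges (1980)",
      "IUPAC standard atomic weights"
    )
  )
}

.element_info <- function(symbols) {
  el <- contribution_table("elements")
  idx <- match(symbols, el$element)
  if (anyNA(idx)) {
    abort(paste0("unsupported element(s): ",
                 paste(unique(symbols[is.na(idx)]), collapse = ", ")))
  }
  el[idx, ]
}

# Run OpenBabel once per output format over a batch of SMILES; records are
# re-matched by the index carried in the molecule-name field, so a single
# unparsable record cannot shift the alignment.
.babel_convert <- function(smiles, to) {
  src <- paste0(paste(smiles, paste0("q", seq_along(smiles))), "\n",
                collapse = "")
  out <- suppressWarnings(
    ChemmineOB::convertFormat("SMI", to, source = src,
                              options = data.frame(names = "h", args = ""))
  )
  out
}

# Minimal reader for the TRIPOS MOL2 ATOM/BOND blocks (no installed R
# package parses MOL2); only the fields needed here are extracted.
.parse_mol2 <- function(text) {
  recs <- strsplit(text, "@<TRIPOS>MOLECULE", fixed = TRUE)[[1]]
  recs <- recs[nzchar(trimws(recs))]
  out <- list()
  for (rec in recs) {
    lines <- strsplit(rec, "\n", fixed = TRUE)[[1]]
    name <- trimws(lines[which(nzchar(trimws(lines)))[1]])
    a0 <- grep("@<TRIPOS>ATOM", lines, fixed = TRUE)
    b0 <- grep("@<TRIPOS>BOND", lines, fixed = TRUE)
    if (!length(a0) || !length(b0)) next
    sect_end <- function(start) {
      nxt <- grep("@<TRIPOS>", lines[(start + 1):length(lines)], fixed = TRUE)
      if (length(nxt)) start + nxt[1] - 1 else length(lines)
    }
    atom_lines <- lines[(a0 + 1):sect_end(a0)]
    atom_lines <- atom_lines[nzchar(trimws(atom_lines))]
    atom_lines <- atom_lines[!grepl("@<TRIPOS>", atom_lines, fixed = TRUE)]
    af <- strsplit(trimws(atom_lines), "\\s+")
    bond_lines <- lines[(b0 + 1):sect_end(b0)]
    bond_lines <- bond_lines[nzchar(trimws(bond_lines))]
    bond_lines <- bond_lines[!grepl("@<TRIPOS>", bond_lines, fixed = TRUE)]
    bf <- strsplit(trimws(bond_lines), "\\s+")
    out[[name]] <- list(
      atom_type = vapply(af, `[[`, "", 6L),
      bond = tibble(
        i = vapply(bf, function(x) as.integer(x[2]), 1L),
        j = vapply(bf, function(x) as.integer(x[3]), 1L),
        type = vapply(bf, `[[`, "", 4L)
      )
    )
  }
  out
}

# V2000 charge-code field -> formal charge
.decode_chg <- function(code) {
  c(`0` = 0, `1` = 3, `2` = 2, `3` = 1, `4` = 0, `5` = -1, `6` = -2,
    `7` = -3)[as.character(code)]
}

# bonds that lie on a cycle = non-bridge edges (DFS lowpoint method)
.ring_bonds <- function(n, bi, bj) {
  m <- length(bi)
  if (!m) return(logical(0))
  adj <- vector("list", n)
  for (k in seq_len(m)) {
    adj[[bi[k]]] <- c(adj[[bi[k]]], k)
    adj[[bj[k]]] <- c(adj[[bj[k]]], k)
  }
  disc <- low <- integer(n)
  bridge <- logical(m)
  timer <- 0L
  for (root in seq_len(n)) {
    if (disc[root] > 0L) next
    stack <- list(list(v = root, pe = 0L, ptr = 1L))
    while (length(stack)) {
      fr <- stack[[length(stack)]]
      v <- fr$v
      if (fr$ptr == 1L) {
        timer <- timer + 1L
        disc[v] <- low[v] <- timer
      }
      if (fr$ptr <= length(adj[[v]])) {
        k <- adj[[v]][fr$ptr]
        stack[[length(stack)]]$ptr <- fr$ptr + 1L
        if (k == fr$pe) next
        w <- if (bi[k] == v) bj[k] else bi[k]
        if (disc[w] > 0L) {
          low[v] <- min(low[v], disc[w])
        } else {
          stack[[length(stack) + 1L]] <- list(v = w, pe = k, ptr = 1L)
        }
      } else {
        stack[[length(stack)]] <- NULL
        if (fr$pe > 0L) {
          u <- if (bi[fr$pe] == v) bj[fr$pe] else bi[fr$pe]
          low[u] <- min(low[u], low[v])
          if (low[v] > disc[u]) bridge[fr$pe] <- TRUE
        }
      }
    }
  }
  !bridge
}

.mol2_hyb <- function(type) {
  suffix <- sub("^[^.]+\\.?", "", type)
  dplyr::case_when(
    suffix == "1" ~ "sp",
    suffix %in% c("2", "ar", "am", "pl3", "co2", "cat") ~ "sp2",
    TRUE ~ "sp3"
  )
}

.build_graph <- function(elements, charges, bond_tbl, mol2, smiles, id) {
  hyb <- .mol2_hyb(mol2$atom_type)
  mol2_el <- toupper(sub("\\..*$", "", mol2$atom_type))
  if (!identical(toupper(elements), mol2_el)) {
    abort(paste0("internal atom-order mismatch between conversions for '",
                 smiles, "'"))
  }
  # aromatic bonds: MOL2 'ar' flag restricted to bonds on a cycle (guards
  # against carboxylate/amidine bonds that OpenBabel types as 'ar')
  key <- paste(pmin(bond_tbl$i, bond_tbl$j), pmax(bond_tbl$i, bond_tbl$j))
  m2key <- paste(pmin(mol2$bond$i, mol2$bond$j),
                 pmax(mol2$bond$i, mol2$bond$j))
  ar_flag <- mol2$bond$type[match(key, m2key)] == "ar"
  ar_flag[is.na(ar_flag)] <- FALSE
  on_ring <- .ring_bonds(length(elements), bond_tbl$i, bond_tbl$j)
  aromatic <- ar_flag & on_ring

  heavy <- which(elements != "H")
  hmap <- match(seq_along(elements), heavy)   # old idx -> heavy idx
  is_h <- elements == "H"
  hcount <- integer(length(heavy))
  keep <- !(is_h[bond_tbl$i] | is_h[bond_tbl$j])
  for (k in which(!keep)) {
    hv <- if (is_h[bond_tbl$i[k]]) bond_tbl$j[k] else bond_tbl$i[k]
    if (!is_h[hv]) hcount[hmap[hv]] <- hcount[hmap[hv]] + 1L
  }
  bonds <- tibble(
    i = hmap[bond_tbl$i[keep]],
    j = hmap[bond_tbl$j[keep]],
    order = bond_tbl$order[keep],
    aromatic = aromatic[keep]
  )
  if (nrow(bonds) < 1L) {
    abort(paste0("molecule '", smiles, "' has no heavy-atom bond (L >= 1 required)"))
  }
  degree <- tabulate(c(bonds$i, bonds$j), nbins = length(heavy))
  info <- .element_info(elements[heavy])
  n_h_total <- sum(is_h)
  atoms <- tibble(
    element = elements[heavy],
    z = info$z, zv = info$zv,
    h = hcount,
    charge = as.numeric(charges[heavy]),
    degree = degree,
    aromatic = vapply(seq_along(heavy), function(a)
      any(bonds$aromatic[bonds$i == a | bonds$j == a]), TRUE),
    hyb = hyb[heavy]
  )
  structure(list(
    id = id, smiles = smiles, atoms = atoms, bonds = bonds,
    L = nrow(bonds),
    molar_mass = sum(info$mass) + n_h_total * 1.008
  ), class = "mol_graph")
}

#' Parse SMILES into hydrogen-suppressed molecular graphs
#'
#' Converts SMILES through OpenBabel (via ChemmineOB/ChemmineR) and builds
#' hydrogen-suppressed molecular graphs carrying, per atom, the element,
#' atomic number, valence-electron count, attached-hydrogen count, formal
#' charge, degree and aromaticity, and per bond the kekulized order plus an
#' aromatic flag. The molar mass includes implicit hydrogens.
#' Multi-component SMILES (containing `.`) are rejected, mirroring the
#' curation rule of the modeling workflow.
#'
#' @param smiles Character vector of SMILES strings.
#' @param ids Optional identifiers (defaults to the SMILES themselves).
#' @param on_error `"stop"` (default) or `"drop"`; with `"drop"`,
#'   unparsable records are removed and reported via a warning.
#' @return For `parse_molecules`, a named list of `mol_graph` objects; for
#'   `parse_smiles`, a single `mol_graph`.
#' @export
parse_molecules <- function(smiles, ids = NULL, on_error = c("stop", "drop")) {
  on_error <- match.arg(on_error)
  stopifnot(is.character(smiles), length(smiles) >= 1L)
  if (is.null(ids)) ids <- smiles
  bad <- !nzchar(trimws(smiles)) | is.na(smiles)
  multi <- !bad & grepl(".", smiles, fixed = TRUE)
  fail <- function(which, why) {
    if (on_error == "stop") {
      abort(paste0(why, ": ", paste(utils::head(smiles[which], 3L),
                                    collapse = ", ")))
    }
    which
  }
  drop <- logical(length(smiles))
  if (any(bad))   drop[fail(bad, "empty SMILES")] <- TRUE
  if (any(multi)) drop[fail(multi, "multi-component SMILES rejected")] <- TRUE

  todo <- which(!drop)
  graphs <- stats::setNames(vector("list", length(smiles)), ids)
  if (length(todo)) {
    sdf_txt <- .babel_convert(smiles[todo], "SDF")
    mol2_txt <- .babel_convert(smiles[todo], "MOL2")
    mol2 <- .parse_mol2(mol2_txt)
    sdfset <- NULL
    sdf_names <- character(0)
    if (nzchar(trimws(sdf_txt))) {
      tf <- tempfile(fileext = ".sdf")
      on.exit(unlink(tf), add = TRUE)
      writeLines(sdf_txt, tf)
      sdfset <- tryCatch(suppressWarnings(ChemmineR::read.SDFset(tf)),
                         error = function(e) NULL)
      if (!is.null(sdfset)) {
        sdf_names <- vapply(ChemmineR::SDFset2list(sdfset),
                            function(x) unname(x$header["Molecule_Name"]), "")
      }
    }
    for (pos in seq_along(todo)) {
      i <- todo[pos]
      qn <- paste0("q", pos)
      si <- match(qn, sdf_names)
      if (is.na(si) || is.null(mol2[[qn]])) {
        if (on_error == "stop") {
          abort(paste0("unparsable SMILES: ", smiles[i]))
        }
        drop[i] <- TRUE
        next
      }
      sdf <- sdfset[[si]]
      ab <- ChemmineR::atomblock(sdf)
      bb <- ChemmineR::bondblock(sdf)
      elements <- sub("_.*$", "", rownames(ab))
      charges <- .decode_chg(ab[, "C6"])
      bond_tbl <- tibble(i = as.integer(bb[, "C1"]),
                         j = as.integer(bb[, "C2"]),
                         order = as.integer(bb[, "C3"]))
      g <- tryCatch(
        .build_graph(elements, charges, bond_tbl, mol2[[qn]],
                     smiles[i], ids[i]),
        error = function(e) e
      )
      if (inherits(g, "error")) {
        if (on_error == "stop") stop(g)
        drop[i] <- TRUE
        next
      }
      graphs[[i]] <- g
    }
  }
  if (any(drop)) {
    warn(paste0(sum(drop), " record(s) dropped during SMILES parsing"))
  }
  graphs[!drop]
}

#' @rdname parse_molecules
#' @export
parse_smiles <- function(smiles, ids = NULL) {
  stopifnot(length(smiles) == 1L)
  parse_molecules(smiles, ids, on_error = "stop")[[1L]]
}

#' @export
print.mol_graph <- function(x, ...) {
  cat("<mol_graph> ", x$smiles, "\n", sep = "")
  cat("  atoms: ", nrow(x$atoms), "  bonds (L): ", x$L,
      "  molar mass: ", round(x$molar_mass, 3), " g/mol\n", sep = "")
  invisible(x)
}

#' Gasteiger-Marsili partial charges
#'
#' Iterative partial equalization of orbital electronegativities over the
#' sigma framework: 8 iterations with damping factor `0.5^k`, published
#' electronegativity parameters, hydrogens treated explicitly and their
#' charges folded back into the bearing heavy atom. Charges are seeded with
#' the formal charges, so their sum equals the net molecular charge exactly.
#'
#' @param graph A `mol_graph`.
#' @return Numeric vector, one charge per heavy atom.
#' @export
gasteiger_charges <- function(graph) {
  stopifnot(inherits(graph, "mol_graph"))
  par <- contribution_table("gasteiger")
  at <- graph$atoms
  n_heavy <- nrow(at)
  # extended atom list: heavy atoms then one entry per implicit hydrogen
  el <- c(at$element, rep("H", sum(at$h)))
  hyb <- c(at$hyb, rep("sp3", sum(at$h)))
  owner <- rep(seq_len(n_heavy), at$h)
  bi <- c(graph$bonds$i, owner)
  bj <- c(graph$bonds$j, n_heavy + seq_along(owner))
  idx <- match(paste(el, hyb), paste(par$element, par$hyb))
  fallback <- match(el, par$element)
  idx[is.na(idx)] <- fallback[is.na(idx)]
  if (anyNA(idx)) {
    abort(paste0("no Gasteiger parameters for element: ",
                 paste(unique(el[is.na(idx)]), collapse = ", ")))
  }
  a <- par$a[idx]; b <- par$b[idx]; cc <- par$c[idx]
  chi_plus <- ifelse(el == "H", 20.02, a + b + cc)
  q <- c(at$charge, rep(0, sum(at$h)))
  for (it in seq_len(8L)) {
    damp <- 0.5^it
    chi <- a + b * q + cc * q^2
    dq <- numeric(length(q))
    lo_is_i <- chi[bi] < chi[bj]
    donor <- ifelse(lo_is_i, bi, bj)
    accept <- ifelse(lo_is_i, bj, bi)
    transfer <- abs(chi[bj] - chi[bi]) / chi_plus[donor] * damp
    for (k in seq_along(donor)) {
      dq[donor[k]] <- dq[donor[k]] + transfer[k]
      dq[accept[k]] <- dq[accept[k]] - transfer[k]
    }
    q <- q + dq
  }
  out <- q[seq_len(n_heavy)]
  if (length(owner)) {
    hsum <- tapply(q[-seq_len(n_heavy)], factor(owner, levels = seq_len(n_heavy)), sum)
    hsum[is.na(hsum)] <- 0
    out <- out + as.numeric(hsum)
  }
  unname(out)
}

# per-atom bond-environment profile used by TPSA matching
.atom_profile <- function(graph) {
  at <- graph$atoms
  b <- graph$bonds
  n <- nrow(at)
  ns <- nd <- nt <- na_ <- integer(n)
  for (k in seq_len(nrow(b))) {
    for (v in c(b$i[k], b$j[k])) {
      if (b$aromatic[k]) na_[v] <- na_[v] + 1L
      else if (b$order[k] == 1L) ns[v] <- ns[v] + 1L
      else if (b$order[k] == 2L) nd[v] <- nd[v] + 1L
      else nt[v] <- nt[v] + 1L
    }
  }
  # 3-ring membership: two neighbours of the atom that are themselves bonded
  nb <- lapply(seq_len(n), function(v) c(b$j[b$i == v], b$i[b$j == v]))
  bond_key <- paste(pmin(b$i, b$j), pmax(b$i, b$j))
  in3 <- vapply(seq_len(n), function(v) {
    x <- nb[[v]]
    if (length(x) < 2) return(FALSE)
    pairs <- utils::combn(x, 2)
    any(paste(pmin(pairs[1, ], pairs[2, ]),
              pmax(pairs[1, ], pairs[2, ])) %in% bond_key)
  }, TRUE)
  tibble(nsingle = ns, ndouble = nd, ntriple = nt, naromatic = na_,
         in3ring = as.integer(in3))
}

.tpsa_contribs <- function(graph) {
  at <- graph$atoms
  prof <- .atom_profile(graph)
  tp <- contribution_table("tpsa")
  out <- numeric(nrow(at))
  polar <- at$element %in% c("N", "O", "S", "P")
  # hydrogens folded in: an H on a polar atom is part of the fragment key
  for (v in which(polar)) {
    hit <- which(tp$element == at$element[v] &
                   tp$aromatic == as.integer(at$aromatic[v]) &
                   tp$charge == at$charge[v] &
                   tp$h == at$h[v] &
                   tp$nsingle == prof$nsingle[v] &
                   tp$ndouble == prof$ndouble[v] &
                   tp$ntriple == prof$ntriple[v] &
                   tp$naromatic == prof$naromatic[v] &
                   tp$in3ring == prof$in3ring[v])
    if (!length(hit)) {
      # generic fall-back: ignore the 3-ring flag, then the charge
      hit <- which(tp$element == at$element[v] &
                     tp$aromatic == as.integer(at$aromatic[v]) &
                     tp$charge == at$charge[v] &
                     tp$h == at$h[v] &
                     tp$nsingle == prof$nsingle[v] &
                     tp$ndouble == prof$ndouble[v] &
                     tp$ntriple == prof$ntriple[v] &
                     tp$naromatic == prof$naromatic[v])
    }
    if (!length(hit)) {
      abort(paste0("no polar-surface-area contribution for ",
                   at$element[v], " atom ", v, " in '", graph$smiles, "'"))
    }
    out[v] <- tp$value[hit[1L]]
  }
  out
}

.crippen_type <- function(graph) {
  at <- graph$atoms
  b <- graph$bonds
  n <- nrow(at)
  nb <- lapply(seq_len(n), function(v) c(b$j[b$i == v], b$i[b$j == v]))
  bond_of <- function(v, w) {
    k <- which((b$i == v & b$j == w) | (b$i == w & b$j == v))
    k[1L]
  }
  has_double_to <- function(v, els) {
    any(vapply(nb[[v]], function(w) {
      k <- bond_of(v, w)
      !b$aromatic[k] && b$order[k] == 2L && at$element[w] %in% els
    }, TRUE))
  }
  n_double <- function(v) sum(vapply(nb[[v]], function(w) {
    k <- bond_of(v, w); !b$aromatic[k] && b$order[k] == 2L
  }, TRUE))
  n_triple <- function(v) sum(vapply(nb[[v]], function(w) {
    k <- bond_of(v, w); !b$aromatic[k] && b$order[k] == 3L
  }, TRUE))
  het_nb <- function(v) any(!at$element[nb[[v]]] %in% c("C", "H"))
  vapply(seq_len(n), function(v) {
    e <- at$element[v]
    if (e == "C") {
      if (at$aromatic[v]) {
        if (at$h[v] > 0) return("c_ar_h")
        ext <- nb[[v]][vapply(nb[[v]], function(w)
          !b$aromatic[bond_of(v, w)], TRUE)]
        if (length(ext) && any(!at$element[ext] %in% "C")) return("c_ar_het")
        return("c_ar_sub")
      }
      if (has_double_to(v, c("O", "N", "S"))) return("c_carbonyl")
      if (n_triple(v) > 0 || n_double(v) >= 2) return("c_sp")
      if (n_double(v) > 0) {
        return(if (het_nb(v)) "c_sp2_het" else "c_sp2_plain")
      }
      return(if (het_nb(v)) "c_sp3_het" else "c_sp3_plain")
    }
    if (e == "N") {
      if (at$charge[v] > 0) return("n_charged")
      if (at$aromatic[v]) return("n_aromatic")
      if (n_triple(v) > 0) return("n_nitrile")
      amide <- any(vapply(nb[[v]], function(w) {
        at$element[w] == "C" && has_double_to(w, c("O", "S"))
      }, TRUE))
      if (amide) return("n_amide")
      if (n_double(v) > 0) return("n_sp2")
      if (at$h[v] >= 2) return("n_amine_prim")
      if (at$h[v] == 1) return("n_amine_sec")
      return("n_amine_tert")
    }
    if (e == "O") {
      if (at$charge[v] < 0) return("o_charged")
      if (at$aromatic[v]) return("o_aromatic")
      if (n_double(v) > 0) return("o_carbonyl")
      if (at$h[v] > 0) return("o_hydroxyl")
      return("o_ether")
    }
    if (e == "S") {
      if (at$aromatic[v]) return("s_aromatic")
      if (has_double_to(v, "O") || n_double(v) > 1) return("s_oxidized")
      return("s_thio")
    }
    switch(e,
           P = "p_any", F = "f_any", Cl = "cl_any", Br = "br_any",
           I = "i_any", B = "b_any", Si = "si_any",
           abort(paste0("no hydrophobicity/refractivity type for element ",
                        e, " in '", graph$smiles, "'")))
  }, "")
}

#' Per-atom physicochemical contributions
#'
#' One value per heavy atom under the given weighting scheme: `Ato` standard
#' atomic weight, `Psa` polar-surface-area fragment contribution, `Hyd` and
#' `Mol` atom-typed hydrophobicity / molar refractivity (hydrogen
#' contributions folded into the bearing atom), `Gas` the computed
#' Gasteiger-Marsili charge.
#'
#' @param graph A `mol_graph`.
#' @param scheme Scheme code (`"Ato"`, `"Psa"`, `"Hyd"`, `"Mol"`, `"Gas"`).
#' @return Numeric vector, one value per atom.
#' @export
atomic_contributions <- function(graph, scheme) {
  stopifnot(inherits(graph, "mol_graph"))
  ws <- weight_schemes()
  kind <- ws$kind[match(scheme, ws$code)]
  if (is.na(kind) || kind == "bond-table") {
    abort(paste0("scheme '", scheme, "' does not define atomic contributions"))
  }
  at <- graph$atoms
  switch(scheme,
    Ato = .element_info(at$element)$mass,
    Gas = gasteiger_charges(graph),
    Psa = .tpsa_contribs(graph),
    Hyd = ,
    Mol = {
      cr <- contribution_table("crippen")
      col <- if (scheme == "Hyd") "logp" else "mr"
      types <- .crippen_type(graph)
      idx <- match(types, cr$type)
      hval <- cr[[col]][match(c("h_on_c", "h_on_het"), cr$type)]
      cr[[col]][idx] + at$h * ifelse(at$element == "C", hval[1], hval[2])
    }
  )
}

#' Per-bond weights
#'
#' Bond weights for the diagonal of the bond adjacency matrix. `Std` and
#' `Dip` are direct lookups by (element pair, bond order) with dedicated
#' aromatic entries; atom-derived schemes spread each atomic contribution
#' `p_i` equally over the atom's `delta_i` incident bonds:
#' `w(i,j) = p_i/delta_i + p_j/delta_j`.
#'
#' @param graph A `mol_graph`.
#' @param scheme One of `"Std"`, `"Dip"`, `"Hyd"`, `"Psa"`, `"Mol"`,
#'   `"Gas"`, `"Ato"`.
#' @return Numeric vector, one weight per bond.
#' @export
bond_weights <- function(graph, scheme) {
  stopifnot(inherits(graph, "mol_graph"))
  ws <- weight_schemes()
  kind <- ws$kind[match(scheme, ws$code)]
  if (is.na(kind)) abort(paste0("unknown weighting scheme '", scheme, "'"))
  b <- graph$bonds
  if (kind == "bond-table") {
    tbl <- contribution_table(ws$table[match(scheme, ws$code)])
    e1 <- graph$atoms$element[b$i]
    e2 <- graph$atoms$element[b$j]
    ord <- ifelse(b$aromatic, "ar", as.character(b$order))
    key <- paste(pmin(e1, e2), pmax(e1, e2), ord)
    idx <- match(key, paste(tbl$a, tbl$b, tbl$order))
    if (anyNA(idx)) {
      abort(paste0("no ", scheme, " entry for bond(s): ",
                   paste(unique(key[is.na(idx)]), collapse = "; "),
                   " in '", graph$smiles, "'"))
    }
    return(tbl$value[idx])
  }
  p <- atomic_contributions(graph, scheme)
  d <- graph$atoms$degree
  p[b$i] / d[b$i] + p[b$j] / d[b$j]
}
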