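.default_grammar <- function() {
  list(
    # two-slot ring cores; each slot receives a linker(substituent) fragment
    cores = c("c1cc(%s)ccc1%s", "c1cc(%s)ncc1%s", "c1nc(%s)cnc1%s",
              "c1cc2ccc(%s)cc2cc1%s", "c1csc(%s)c1%s",
              "C1(%s)CCN(%s)CC1", "C1(%s)CCN(C%s)CC1"),
    linkers = c("C%s", "CC%s", "OC%s", "C(=O)N(C)C%s", "N(C)C%s",
                "SC%s", "C(C)(C)%s", "CCOC%s"),
    substituents = c("C", "CC", "C(C)C", "C(C)(C)C", "C(F)(F)F", "OC",
                     "O", "N(C)C", "Cl", "C#N", "c1ccccc1",
                     "c1ccc(F)cc1", "c1ccc(OC)cc1", "c1ccncc1",
                     "N1CCN(C)CC1", "C1CC1")
  )
}

#' Specification for the synthetic assay-data generator
#'
#' Defines desk-scale study conditions emulating a multi-condition
#' anti-proliferative screening dataset: molecules assembled from a
#' fragment grammar (ring cores, linkers, substituents), assayed under the
#' registry conditions, with a planted logistic descriptor-activity
#' relationship `logit P(active) = b0 + sum(beta * z) + gamma(condition)`
#' over standardized planted descriptors. The intercept `b0` is solved so
#' the expected active fraction matches `balance`. GI50 values are drawn
#' log-normally, truncated on the active side of the threshold for active
#' cases and above it otherwise.
#'
#' @param n_molecules Number of molecules (default 400).
#' @param registry Condition registry (default: the seven-condition set).
#' @param grammar List with `cores`, `linkers`, `substituents` SMILES
#'   templates.
#' @param planted Raw descriptor ids carrying the planted signal.
#' @param beta Coefficients on the standardized planted descriptors.
#' @param gamma Named per-condition offsets (recycled to the registry).
#' @param balance Target active fraction (default 0.45).
#' @param threshold_nm Activity threshold (default 1900 nM).
#' @param mass_window Admissible molar-mass window.
#' @param seed Integer seed.
#' @return List of class `generator_spec`.
#' @export
generator_spec <- function(n_molecules = 400L,
                           registry = default_condition_registry(),
                           grammar = .default_grammar(),
                           planted = c("NSM(Psa)1", "SM(Hyd)1", "Xv(P)2"),
                           beta = c(-2.5, 2.0, -1.5),
                           gamma = c(-0.4, 0.3, 0.2, 0.4, 0.1, -0.2, -0.4),
                           balance = 0.45,
                           threshold_nm = 1900,
                           mass_window = c(130, 854),
                           seed = 2026L) {
  stopifnot(length(beta) == length(planted),
            balance > 0, balance < 1, n_molecules >= 2)
  gamma <- rep_len(gamma, nrow(registry))
  names(gamma) <- registry$condition_id
  structure(list(n_molecules = as.integer(n_molecules), registry = registry,
                 grammar = grammar, planted = planted, beta = beta,
                 gamma = gamma, balance = balance,
                 threshold_nm = threshold_nm, mass_window = mass_window,
                 seed = as.integer(seed)),
            class = "generator_spec")
}

#' Generate synthetic molecules from the fragment grammar
#'
#' Core-linker-substituent assembly with rejection of duplicates,
#' unparsable assemblies and molecules outside the molar-mass window;
#' deterministic for a given spec.
#'
#' @param spec A [generator_spec()].
#' @return Tibble: `molecule_id`, `smiles`, `molar_mass`.
#' @export
generate_molecules <- function(spec) {
  stopifnot(inherits(spec, "generator_spec"))
  g <- spec$grammar
  if (!length(g$cores) || !length(g$linkers)) {
    rlang::abort("fragment grammar must contain cores and linkers")
  }
  subs <- if (length(g$substituents)) g$substituents else ""
  set.seed(spec$seed)
  out <- character(0)
  attempts <- 0L
  max_attempts <- spec$n_molecules * 60L
  batch <- max(spec$n_molecules, 50L)
  while (length(out) < spec$n_molecules && attempts < max_attempts) {
    cand <- vapply(seq_len(batch), function(i) {
      frag <- function() sprintf(sample(g$linkers, 1L), sample(subs, 1L))
      sprintf(sample(g$cores, 1L), frag(), frag())
    }, "")
    attempts <- attempts + batch
    cand <- setdiff(unique(cand), out)
    if (!length(cand)) next
    graphs <- suppressWarnings(parse_molecules(cand, on_error = "drop"))
    mass <- vapply(graphs, function(x) x$molar_mass, 1.0)
    ok <- names(mass)[mass >= spec$mass_window[1] &
                        mass <= spec$mass_window[2]]
    out <- c(out, ok)
  }
  if (!length(out)) {
    rlang::abort("fragment grammar yielded no valid assembly")
  }
  if (length(out) < spec$n_molecules) {
    warn(paste0("grammar exhausted: only ", length(out),
                " unique molecules generated"))
  }
  out <- utils::head(out, spec$n_molecules)
  tb <- tibble(molecule_id = sprintf("SYN-%04d", seq_along(out)),
               smiles = out)
  graphs <- parse_molecules(tb$smiles, tb$molecule_id)
  tb$molar_mass <- vapply(graphs, function(x) x$molar_mass, 1.0)
  tb
}

# truncated log-normal draw via inverse-CDF
.rlnorm_trunc <- function(n, meanlog, sdlog, lower = 0, upper = Inf) {
  plo <- stats::plnorm(lower, meanlog, sdlog)
  phi <- stats::plnorm(upper, meanlog, sdlog)
  stats::qlnorm(stats::runif(n, plo, phi), meanlog, sdlog)
}

#' Generate assay cases with a planted descriptor-activity relationship
#'
#' Every molecule is assayed under every registry condition. The activity
#' class is drawn from the planted logistic model; GI50 is then drawn on
#' the matching side of the threshold (log-normal, medians ~350 nM for
#' actives and ~25000 nM for inactives), so the class label and the
#' threshold rule agree by construction.
#'
#' @param molecules Output of [generate_molecules()] (or any tibble with
#'   `molecule_id` and `smiles`).
#' @param spec A [generator_spec()].
#' @return List: `cases` (tibble `molecule_id`, `smiles`, `gi50_nm`,
#'   `condition_id`) and `truth` (planted descriptor ids, `beta`, solved
#'   intercept `beta0`, `gamma`, and the per-case activity probabilities).
#' @export
generate_assays <- function(molecules, spec) {
  stopifnot(inherits(spec, "generator_spec"))
  desc <- compute_descriptors(molecules)
  miss <- setdiff(spec$planted, names(desc))
  if (length(miss)) {
    rlang::abort(paste0("planted descriptor(s) not computed: ",
                        paste(miss, collapse = ", ")))
  }
  Z <- scale(as.matrix(desc[spec$planted]))
  Z[!is.finite(Z)] <- 0
  cases <- tidyr::crossing(molecules[c("molecule_id", "smiles")],
                           condition_id = spec$registry$condition_id) |>
    arrange(.data$molecule_id, .data$condition_id)
  zi <- match(cases$molecule_id, desc$molecule_id)
  lp <- as.vector(Z %*% spec$beta)[zi] + spec$gamma[cases$condition_id]
  beta0 <- stats::uniroot(function(b0) mean(stats::plogis(lp + b0)) -
                            spec$balance,
                          interval = c(-50, 50))$root
  p_active <- stats::plogis(lp + beta0)
  set.seed(spec$seed + 1L)
  active <- stats::rbinom(length(p_active), 1L, p_active) == 1L
  thr <- spec$threshold_nm
  gi50 <- numeric(length(active))
  gi50[active] <- .rlnorm_trunc(sum(active), log(350), 0.9, upper = thr)
  gi50[!active] <- .rlnorm_trunc(sum(!active), log(25000), 0.9, lower = thr)
  cases$gi50_nm <- gi50
  list(
    cases = cases,
    truth = list(planted = spec$planted, beta = spec$beta, beta0 = beta0,
                 gamma = spec$gamma, p_active = p_active,
                 active = active)
  )
}

#' One-call synthetic dataset
#'
#' @param spec A [generator_spec()].
#' @return List: `molecules`, `cases`, `truth`.
#' @export
simulate_assay_dataset <- function(spec = generator_spec()) {
  molecules <- generate_molecules(spec)
  assays <- generate_assays(molecules, spec)
  list(molecules = molecules, cases = assays$cases, truth = assays$truth)
}
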