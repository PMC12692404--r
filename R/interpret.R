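.clip_prob <- function(p) pmin(pmax(p, 1e-12), 1 - 1e-12)

.model_error <- function(model, X, obs) {
  p <- .mlp_forward(model$wts, model$n, X)[, 2L]
  p_obs <- ifelse(obs == 1, p, 1 - p)
  -mean(log(.clip_prob(p_obs)))
}

#' Input sensitivity values
#'
#' For each model input, the column is replaced by its mean over the
#' supplied (training) table and the model's cross-entropy error is
#' recomputed; the sensitivity value is the ratio of the substituted error
#' to the full-model error. `SV = 1` means the input carries no usable
#' information; the larger the SV, the more the model relies on the input.
#'
#' @param model A `ptml_mlp`.
#' @param fused Tibble of training cases with the fused inputs and `ACRC`.
#' @return Tibble of class `ptml_sensitivity`: `term`, `sv`, `rank`
#'   (decreasing SV, ties broken lexicographically).
#' @export
sensitivity_values <- function(model, fused) {
  stopifnot(inherits(model, "ptml_mlp"), "ACRC" %in% names(fused))
  X <- as.matrix(fused[model$feature_ids])
  obs <- fused$ACRC
  err_full <- .model_error(model, X, obs)
  smoothed <- err_full == 0
  if (smoothed) err_full <- err_full + 1e-12
  sv <- vapply(seq_len(ncol(X)), function(j) {
    Xs <- X
    Xs[, j] <- mean(X[, j])
    .model_error(model, Xs, obs) / err_full
  }, 1.0)
  out <- tibble(term = model$feature_ids, sv = sv) |>
    arrange(desc(.data$sv), .data$term) |>
    mutate(rank = dplyr::row_number())
  attr(out, "smoothed") <- smoothed
  class(out) <- c("ptml_sensitivity", class(out))
  out
}

#' Tendency of variation
#'
#' Classifies the direction in which an input should move to favour
#' activity: per input, the mean over correctly classified active cases is
#' compared with the mean over correctly classified inactive cases;
#' `Increase` when the active mean is larger, `Decrease` when smaller,
#' `Indeterminate` when equal within `tol`.
#'
#' @param active_mean,inactive_mean Numeric vectors.
#' @param tol Equality tolerance (default 1e-12).
#' @return Character vector of propensities.
#' @export
classify_tendency <- function(active_mean, inactive_mean, tol = 1e-12) {
  dplyr::case_when(
    is.na(active_mean) | is.na(inactive_mean) ~ NA_character_,
    abs(active_mean - inactive_mean) <= tol ~ "Indeterminate",
    active_mean > inactive_mean ~ "Increase",
    TRUE ~ "Decrease"
  )
}

#' Tendency-of-variation table for a fitted model
#'
#' @param model A `ptml_mlp`.
#' @param fused Training cases with fused inputs and `ACRC`.
#' @return Tibble of class `ptml_tendency`: `term`, `active_mean`,
#'   `inactive_mean`, `propensity`.
#' @export
tendency_table <- function(model, fused) {
  stopifnot(inherits(model, "ptml_mlp"), "ACRC" %in% names(fused))
  X <- as.matrix(fused[model$feature_ids])
  obs <- fused$ACRC
  prob <- .mlp_forward(model$wts, model$n, X)[, 2L]
  correct <- ifelse(prob > 0.5, 1L, -1L) == obs
  ca <- correct & obs == 1
  ci <- correct & obs == -1
  am <- if (any(ca)) colMeans(X[ca, , drop = FALSE]) else rep(NA_real_, ncol(X))
  im <- if (any(ci)) colMeans(X[ci, , drop = FALSE]) else rep(NA_real_, ncol(X))
  out <- tibble(term = model$feature_ids,
                active_mean = unname(am),
                inactive_mean = unname(im),
                propensity = classify_tendency(am, im))
  class(out) <- c("ptml_tendency", class(out))
  out
}

#' Multi-cell activity verdict
#'
#' A molecule shows multi-cell activity when it is predicted active
#' (`ProbAct` above the threshold, strict) in at least `min_active` of the
#' assayed conditions — by default `ceiling(4/7 * n)` conditions, the
#' 4-of-7 rule at seven conditions.
#'
#' @param prob_act Per-condition activity probabilities in `[0, 1]`.
#' @param threshold Activity threshold (default 0.5).
#' @param min_active Minimum number of active conditions (default
#'   `ceiling(4/7 * length(prob_act))`).
#' @return List: `n_active`, `min_active`, `multicell`.
#' @export
multicell_verdict <- function(prob_act, threshold = 0.5, min_active = NULL) {
  stopifnot(length(prob_act) >= 1)
  if (is.null(min_active)) min_active <- ceiling(4 / 7 * length(prob_act))
  n_active <- sum(prob_act > threshold, na.rm = TRUE)
  list(n_active = n_active, min_active = min_active,
       multicell = n_active >= min_active)
}

#' Per-condition predictions and multi-cell report
#'
#' Scores each molecule against every condition of the registry and
#' summarises the 4-of-7-style verdict per molecule.
#'
#' @param model A `ptml_mlp` carrying fusion statistics.
#' @param molecules Tibble with `molecule_id` and `smiles`.
#' @param registry Registry (default: the one stored in the model).
#' @return Tibble of per-condition predictions; the per-molecule summary
#'   (`molecule_id`, `n_active`, `min_active`, `multicell`) is attached as
#'   attribute `"summary"`.
#' @export
multicell_report <- function(model, molecules, registry = NULL) {
  registry <- registry %||% model$registry
  stopifnot(inherits(registry, "condition_registry"))
  cases <- tidyr::crossing(molecules[c("molecule_id", "smiles")],
                           condition_id = registry$condition_id)
  preds <- predict(model, cases, registry = registry)
  summ <- preds |>
    group_by(.data$molecule_id) |>
    summarise(n_active = sum(.data$prob_act > 0.5),
              min_active = ceiling(4 / 7 * dplyr::n()),
              multicell = .data$n_active >= .data$min_active)
  attr(preds, "summary") <- summ
  preds
}

#' Physicochemical properties for druglikeness screening
#'
#' Computes, from SMILES, the molecular weight, Lipinski hydrogen-bond
#' acceptor (N + O) and donor (N-H/O-H) counts, rotatable-bond count
#' (single non-ring bonds between non-terminal heavy atoms, amide C-N
#' excluded), topological polar surface area and the atom-contribution
#' logP (`alogp`) from the shipped tables. `mlogp` is not computed from
#' structure and is returned as `NA`.
#'
#' @param data Tibble with `smiles` (and optionally `molecule_id`).
#' @return Tibble: `molecule_id`, `mw`, `hba`, `hbd`, `rbn`, `psa`,
#'   `alogp`, `mlogp`.
#' @export
molecular_properties <- function(data) {
  stopifnot("smiles" %in% names(data))
  ids <- if ("molecule_id" %in% names(data)) as.character(data$molecule_id)
         else data$smiles
  graphs <- parse_molecules(data$smiles, ids)
  purrr::map_dfr(graphs, function(g) {
    at <- g$atoms
    b <- g$bonds
    ring <- .ring_bonds(nrow(at), b$i, b$j)
    amide_c <- vapply(seq_len(nrow(at)), function(v) {
      at$element[v] == "C" &&
        any((b$i == v & b$order == 2 & !b$aromatic &
               at$element[b$j] == "O") |
              (b$j == v & b$order == 2 & !b$aromatic &
                 at$element[b$i] == "O"))
    }, TRUE)
    rot <- !ring & !b$aromatic & b$order == 1 &
      at$degree[b$i] > 1 & at$degree[b$j] > 1 &
      !((amide_c[b$i] & at$element[b$j] == "N") |
          (amide_c[b$j] & at$element[b$i] == "N"))
    tibble(
      molecule_id = g$id,
      mw = g$molar_mass,
      hba = sum(at$element %in% c("N", "O")),
      hbd = sum(at$element %in% c("N", "O") & at$h > 0),
      rbn = sum(rot),
      psa = sum(.tpsa_contribs(g)),
      alogp = sum(atomic_contributions(g, "Hyd")),
      mlogp = NA_real_
    )
  })
}

#' Druglikeness screening
#'
#' Checks Lipinski's rule of five (`HBA <= 10`, `HBD <= 5`, `MW < 500` Da,
#' `logP <= 5`) and the Veber guidelines (`RBN <= 10`, `PSA < 140` A^2).
#' The logP used for the Lipinski check is `avglogp = (mlogp + alogp)/2`
#' when both estimates are available, otherwise whichever is present.
#' Property columns (`mw`, `hba`, `hbd`, `mlogp`, `alogp`, `rbn`, `psa`)
#' may be supplied directly; rows lacking them are computed from `smiles`.
#'
#' @param data Tibble of property values and/or SMILES.
#' @return Tibble with `avglogp`, the violation list-column `violations`,
#'   `n_lipinski_violations`, `lipinski_ok` and `veber_ok` appended.
#' @export
druglikeness <- function(data) {
  props <- c("mw", "hba", "hbd", "rbn", "psa")
  if (!all(props %in% names(data))) {
    if (!"smiles" %in% names(data)) {
      rlang::abort("supply property columns or a smiles column")
    }
    data <- bind_cols(data["smiles"], molecular_properties(data))
  }
  if (!"mlogp" %in% names(data)) data$mlogp <- NA_real_
  if (!"alogp" %in% names(data)) data$alogp <- NA_real_
  if (!"avglogp" %in% names(data)) {
    data$avglogp <- rowMeans(cbind(data$mlogp, data$alogp), na.rm = TRUE)
  }
  checks <- list(MW = data$mw >= 500, HBA = data$hba > 10,
                 HBD = data$hbd > 5, logP = data$avglogp > 5)
  viol <- purrr::pmap(checks, function(MW, HBA, HBD, logP) {
    v <- c(MW = MW, HBA = HBA, HBD = HBD, logP = logP)
    names(v)[which(v)]
  })
  data |>
    mutate(
      violations = viol,
      n_lipinski_violations = lengths(viol),
      lipinski_ok = .data$n_lipinski_violations == 0L,
      veber_ok = .data$rbn <= 10 & .data$psa < 140
    )
}
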