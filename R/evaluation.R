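#' Confusion counts
#'
#' Counts of active/inactive cases and of those correctly classified, the
#' raw material of the global and local performance metrics.
#'
#' @param predictions,observations Vectors in `{+1, -1}`.
#' @param scope Label for the subset being summarised.
#' @return One-row tibble: `scope`, `n_active`, `cc_active`, `n_inactive`,
#'   `cc_inactive`.
#' @export
confusion_counts <- function(predictions, observations, scope = "all") {
  if (length(predictions) != length(observations)) {
    rlang::abort("predictions and observations differ in length")
  }
  tibble(
    scope = scope,
    n_active = sum(observations == 1),
    cc_active = sum(observations == 1 & predictions == 1),
    n_inactive = sum(observations == -1),
    cc_inactive = sum(observations == -1 & predictions == -1)
  )
}

#' Sensitivity and specificity (percent)
#'
#' `Sn = 100 * CC_active / N_active`, `Sp = 100 * CC_inactive /
#' N_inactive`; a component with zero denominator is returned as `NA`.
#'
#' @param counts A [confusion_counts()] row (or several).
#' @return `counts` with `sn` and `sp` columns appended.
#' @export
sn_sp <- function(counts) {
  counts |>
    mutate(
      sn = ifelse(.data$n_active > 0,
                  100 * .data$cc_active / .data$n_active, NA_real_),
      sp = ifelse(.data$n_inactive > 0,
                  100 * .data$cc_inactive / .data$n_inactive, NA_real_)
    )
}

#' Normalized Matthews correlation coefficient
#'
#' `nMCC = (MCC + 1) / 2`, mapping the Matthews correlation coefficient
#' onto `[0, 1]`; a zero MCC denominator is defined as MCC = 0, hence
#' nMCC = 0.5.
#'
#' @param counts A [confusion_counts()] row (or several).
#' @return Numeric vector of nMCC values.
#' @export
nmcc <- function(counts) {
  tp <- as.numeric(counts$cc_active)
  fn <- as.numeric(counts$n_active) - tp
  tn <- as.numeric(counts$cc_inactive)
  fp <- as.numeric(counts$n_inactive) - tn
  den <- sqrt((tp + fp) * (tp + fn) * (tn + fp) * (tn + fn))
  mcc <- ifelse(den > 0, (tp * tn - fp * fn) / den, 0)
  mcc <- ifelse(counts$n_active + counts$n_inactive == 0, NA_real_, mcc)
  (mcc + 1) / 2
}

#' Local (per-label) performance metrics
#'
#' Sensitivity and specificity restricted to the cases sharing each label
#' of a condition element (doubling-time class, cell line or microsatellite
#' status).
#'
#' @param predictions,observations Vectors in `{+1, -1}`.
#' @param labels Label per case.
#' @param element Name of the element (used in the `scope` column).
#' @return Tibble with one row per label, with counts, `sn`, `sp`.
#' @export
local_metrics <- function(predictions, observations, labels,
                          element = "label") {
  purrr::map_dfr(sort(unique(labels)), function(lb) {
    sel <- labels == lb
    confusion_counts(predictions[sel], observations[sel],
                     scope = paste0(element, ":", lb))
  }) |>
    sn_sp()
}

#' Applicability-domain bounding box
#'
#' Per-descriptor minimum and maximum over the *correctly classified*
#' training cases: the region in which the model's predictions are
#' considered reliable.
#'
#' @param fused Tibble/matrix of the model's fused input columns for the
#'   training cases.
#' @param correct Logical vector: was each training case correctly
#'   classified?
#' @return Object of class `ad_bounds`: tibble `id`, `min`, `max`; the
#'   descriptor count `K` is `nrow()`.
#' @export
ad_bounds <- function(fused, correct) {
  X <- as.matrix(fused)
  stopifnot(nrow(X) == length(correct))
  if (!any(correct)) {
    rlang::abort("applicability domain undefined: no correctly classified case")
  }
  Xc <- X[correct, , drop = FALSE]
  out <- tibble(id = colnames(X),
                min = unname(apply(Xc, 2L, min)),
                max = unname(apply(Xc, 2L, max)))
  class(out) <- c("ad_bounds", class(out))
  out
}

#' Applicability-domain score
#'
#' Per descriptor, the local score `LSAD` is 1 when the case's value lies
#' inside the closed interval `[min, max]` and 0 otherwise; `TSAD` is the
#' sum over the `K` descriptors, and the case is inside the applicability
#' domain iff `TSAD = K`.
#'
#' @param bounds An [ad_bounds()] object.
#' @param fused Tibble/matrix containing at least the bound descriptor
#'   columns, one row per case.
#' @return Tibble with `tsad` and `inside_ad` per case.
#' @export
ad_score <- function(bounds, fused) {
  stopifnot(inherits(bounds, "ad_bounds"))
  miss <- setdiff(bounds$id, colnames(fused))
  if (length(miss)) {
    rlang::abort(paste0("missing fused column(s): ",
                        paste(utils::head(miss, 3), collapse = ", ")))
  }
  X <- as.matrix(fused[, bounds$id, drop = FALSE])
  K <- nrow(bounds)
  inside <- t(t(X) >= bounds$min) & t(t(X) <= bounds$max)
  tsad <- rowSums(inside)
  tibble(tsad = as.integer(tsad), inside_ad = tsad == K)
}
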