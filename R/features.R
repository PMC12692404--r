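.entropy <- function(counts) {
  p <- counts[counts > 0] / sum(counts)
  -sum(p * log2(p))
}

#' Information-theoretic discrimination metrics for one descriptor
#'
#' The descriptor is discretized by equal-width binning over its observed
#' range with the bin count given by Sturges' rule. Three metrics are
#' returned: the differential Shannon entropy
#' `DSE = SE(pooled) - [SE(active) + SE(inactive)]/2` (clamped at zero),
#' the gain ratio `GR = IG / H(X)` and the symmetric uncertainty
#' `SU = 2 IG / (H(X) + H(C))`, where `IG` is the information gain of the
#' class given the binned descriptor. All entropies are in bits.
#'
#' @param values Numeric vector (finite).
#' @param classes Vector in `{+1, -1}` aligned with `values`.
#' @return Tibble with columns `dse`, `gr`, `su`.
#' @export
shannon_metrics <- function(values, classes) {
  stopifnot(length(values) == length(classes), all(is.finite(values)))
  n <- length(values)
  cls <- factor(classes, levels = c(-1, 1))
  if (nlevels(droplevels(cls)) < 2L) {
    warn("single-class input: gain ratio and symmetric uncertainty set to 0")
  }
  k <- max(1L, ceiling(log2(n) + 1))
  rng <- range(values)
  if (rng[1] == rng[2]) {
    bins <- factor(rep(1L, n))
  } else {
    breaks <- seq(rng[1], rng[2], length.out = k + 1L)
    bins <- cut(values, breaks = breaks, include.lowest = TRUE)
  }
  tab_x <- table(bins)
  tab_c <- table(cls)
  tab_xc <- table(bins, cls)
  h_x <- .entropy(tab_x)
  h_c <- .entropy(tab_c)
  # conditional entropy H(C|X)
  h_c_x <- sum(vapply(seq_len(nrow(tab_xc)), function(i) {
    w <- sum(tab_xc[i, ]) / n
    if (w == 0) 0 else w * .entropy(tab_xc[i, ])
  }, 1.0))
  ig <- h_c - h_c_x
  se_act <- .entropy(table(bins[cls == "1"]))
  se_ina <- .entropy(table(bins[cls == "-1"]))
  dse <- max(0, h_x - (se_act + se_ina) / 2)
  tibble(
    dse = dse,
    gr = if (h_x > 0) ig / h_x else 0,
    su = if (h_x + h_c > 0) 2 * ig / (h_x + h_c) else 0
  )
}

#' Rank fused descriptors and remove redundancy
#'
#' Scores every fused descriptor by the geometric mean
#' `GMV = (DSE * GR * SU)^(1/3)` of its information-theoretic metrics,
#' ranks by decreasing GMV (ties broken lexicographically by id), then
#' greedily keeps a descriptor only if its Pearson correlation with every
#' already-kept descriptor lies strictly inside `pcc_window`. The first `k`
#' survivors are selected.
#'
#' @param fused Tibble containing the fused descriptor columns.
#' @param classes Class vector in `{+1, -1}`.
#' @param k Number of descriptors to select (default 20).
#' @param pcc_window Open correlation window (default `c(-0.7, 0.7)`).
#' @param feature_cols Columns to score; defaults to all `D[...]` columns.
#' @return Tibble of scores (`id`, `dse`, `gr`, `su`, `gmv`, `rank`,
#'   `kept`), ordered by rank; selected ids in attribute `"selected"`.
#' @export
select_features <- function(fused, classes, k = 20L,
                            pcc_window = c(-0.7, 0.7),
                            feature_cols = NULL) {
  if (is.null(feature_cols)) {
    feature_cols <- grep("^D\\[", names(fused), value = TRUE)
  }
  stopifnot(k >= 1L, length(feature_cols) >= 1L)
  X <- as.matrix(fused[feature_cols])
  scores <- purrr::map_dfr(feature_cols, function(id) {
    bind_cols(tibble(id = id), shannon_metrics(X[, id], classes))
  })
  scores <- scores |>
    mutate(gmv = (pmax(.data$dse, 0) * pmax(.data$gr, 0) *
                    pmax(.data$su, 0))^(1 / 3)) |>
    arrange(desc(.data$gmv), .data$id) |>
    mutate(rank = dplyr::row_number())
  kept <- character(0)
  flag <- logical(nrow(scores))
  for (i in seq_len(nrow(scores))) {
    if (length(kept) >= k) break
    id <- scores$id[i]
    ok <- TRUE
    for (kid in kept) {
      r <- suppressWarnings(stats::cor(X[, id], X[, kid]))
      if (is.na(r) || r <= pcc_window[1] || r >= pcc_window[2]) {
        ok <- FALSE
        break
      }
    }
    if (ok) {
      kept <- c(kept, id)
      flag[i] <- TRUE
    }
  }
  if (length(kept) < k) {
    warn(paste0("only ", length(kept), " descriptor(s) survived the ",
                "redundancy filter (k = ", k, ")"))
  }
  scores$kept <- flag
  attr(scores, "selected") <- kept
  scores
}
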