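.fusion_elements <- c("dt", "ct", "mc")

#' Fit Box-Jenkins fusion statistics
#'
#' For each descriptor and each label of the three condition elements
#' (`dt`, `ct`, `mc`), computes the moving-average reference
#' `avg[GTI]ej` — the mean over *active* training cases carrying that
#' label — together with the label count `n(ej)`, the a-priori probability
#' `p(ej) = n(ej)/T` (with `T` the total number of training cases), and the
#' per-descriptor dispersion `sdv[GTI]` (population standard deviation over
#' all training cases). Descriptors with zero dispersion are flagged
#' degenerate and excluded.
#'
#' @param train Tibble of training cases with label columns `dt`, `ct`,
#'   `mc`, the class column `ACRC` (+1/-1) and the descriptor columns.
#' @param descriptor_cols Descriptor columns to fuse; defaults to every
#'   column of `train` matching [descriptor_ids()].
#' @return Object of class `fusion_stats`.
#' @export
fit_fusion <- function(train, descriptor_cols = NULL) {
  stopifnot(all(c(.fusion_elements, "ACRC") %in% names(train)))
  if (is.null(descriptor_cols)) {
    descriptor_cols <- intersect(descriptor_ids(), names(train))
  }
  if (!length(descriptor_cols)) rlang::abort("no descriptor columns found")
  if ("partition" %in% names(train) && any(train$partition != "train")) {
    rlang::abort("fit_fusion() must be given training cases only")
  }
  X <- as.matrix(train[descriptor_cols])
  if (!all(is.finite(X))) rlang::abort("non-finite descriptor values")
  T_n <- nrow(train)
  sdv <- apply(X, 2L, function(v) sqrt(mean((v - mean(v))^2)))
  degenerate <- names(sdv)[sdv == 0]
  if (length(degenerate)) {
    inform(paste0(length(degenerate),
                  " degenerate descriptor(s) excluded (zero dispersion)"))
    descriptor_cols <- setdiff(descriptor_cols, degenerate)
    X <- X[, descriptor_cols, drop = FALSE]
    sdv <- sdv[descriptor_cols]
  }
  active <- train$ACRC == 1L
  if (!any(active)) rlang::abort("no active training cases")
  elements <- lapply(stats::setNames(.fusion_elements, .fusion_elements),
                     function(el) {
    labs <- train[[el]][active]
    split_idx <- split(which(active), labs)
    avg <- do.call(rbind, lapply(split_idx, function(ix)
      colMeans(X[ix, , drop = FALSE])))
    list(labels = tibble(label = names(split_idx),
                         n = unname(lengths(split_idx)),
                         p = unname(lengths(split_idx)) / T_n),
         avg = avg)
  })
  structure(list(elements = elements, sdv = sdv, T = T_n,
                 descriptor_cols = descriptor_cols,
                 degenerate = degenerate),
            class = "fusion_stats")
}

#' @export
print.fusion_stats <- function(x, ...) {
  cat("<fusion_stats> T =", x$T, "training cases,",
      length(x$descriptor_cols), "descriptors\n")
  for (el in .fusion_elements) {
    cat("  ", el, ": ", paste(x$elements[[el]]$labels$label, collapse = ", "),
        "\n", sep = "")
  }
  invisible(x)
}

#' Names of the fused perturbation descriptors
#'
#' @param stats A `fusion_stats` object.
#' @return Character vector like `"D[NSM(Dip)5]dt"`.
#' @export
fused_ids <- function(stats) {
  stopifnot(inherits(stats, "fusion_stats"))
  as.vector(vapply(.fusion_elements, function(el)
    paste0("D[", stats$descriptor_cols, "]", el),
    character(length(stats$descriptor_cols))))
}

#' Compute multi-label perturbation descriptors
#'
#' Applies `D[GTI]ej = (GTI - avg[GTI]ej) / (sdv[GTI] * p(ej))` separately
#' for the `dt`, `ct` and `mc` elements, using reference statistics fitted
#' on training data. Cases carrying a label absent from the fitted
#' statistics cannot be scored and raise an error.
#'
#' @param data Tibble with label columns `dt`, `ct`, `mc` and the raw
#'   descriptor columns.
#' @param stats A [fit_fusion()] result.
#' @param keep Columns of `data` to carry through (default: all
#'   non-descriptor columns).
#' @return Tibble with the carried columns plus one fused column per
#'   (descriptor, element).
#' @export
fuse_descriptors <- function(data, stats, keep = NULL) {
  stopifnot(inherits(stats, "fusion_stats"))
  miss <- setdiff(stats$descriptor_cols, names(data))
  if (length(miss)) {
    rlang::abort(paste0("missing descriptor column(s): ",
                        paste(utils::head(miss, 3), collapse = ", ")))
  }
  if (is.null(keep)) keep <- setdiff(names(data), descriptor_ids())
  X <- as.matrix(data[stats$descriptor_cols])
  out <- data[keep]
  for (el in .fusion_elements) {
    info <- stats$elements[[el]]
    idx <- match(data[[el]], info$labels$label)
    if (anyNA(idx)) {
      rlang::abort(paste0("label(s) of element '", el,
                          "' absent from fusion statistics: ",
                          paste(unique(data[[el]][is.na(idx)]),
                                collapse = ", ")))
    }
    D <- (X - info$avg[idx, , drop = FALSE]) /
      rep(stats$sdv, each = nrow(X)) / info$labels$p[idx]
    colnames(D) <- paste0("D[", stats$descriptor_cols, "]", el)
    out <- bind_cols(out, as_tibble(D))
  }
  out
}
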