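#' Network-capacity parameter rho
#'
#' `rho = T / [(I+1)H + (H+1)O]`: the ratio of training cases to free
#' weights of a single-hidden-layer perceptron. Values well above 1
#' indicate the network lacks the capacity to merely memorise the training
#' data; values below ~2 are commonly read as an overfitting risk.
#'
#' @param T_cases Number of training cases.
#' @param I,H,O Input, hidden and output node counts.
#' @return A single numeric value.
#' @export
#' @examples
#' rho(4108, 20, 50, 2)
rho <- function(T_cases, I, H, O) {
  args <- c(T_cases, I, H, O)
  if (any(!is.finite(args)) || any(args < 1)) {
    rlang::abort("all of T, I, H, O must be >= 1")
  }
  T_cases / ((I + 1) * H + (H + 1) * O)
}

#' Training configuration
#'
#' @param h_range Hidden-layer size range sampled over restarts (default
#'   20-60).
#' @param restarts Number of networks trained (desk-scale default 20; set
#'   higher to mirror large-scale protocols).
#' @param retained Number of candidate networks retained and reported.
#' @param decay_candidates Weight-decay values sampled over restarts.
#' @param maxit BFGS iteration cap per network.
#' @param monitor_frac Fraction of the training cases carved out as the
#'   internal monitoring fold used for model selection (the test set is
#'   never touched).
#' @param seed Single integer governing every stochastic stage.
#' @return A list of class `ptml_config`.
#' @export
ptml_config <- function(h_range = c(20L, 60L), restarts = 20L, retained = 6L,
                        decay_candidates = c(1e-4, 1e-3, 1e-2),
                        maxit = 150L, monitor_frac = 0.25, seed = 101L) {
  stopifnot(h_range[1] >= 1, h_range[2] >= h_range[1],
            restarts >= retained, retained >= 1,
            monitor_frac > 0, monitor_frac < 0.5)
  structure(list(h_range = as.integer(h_range), restarts = as.integer(restarts),
                 retained = as.integer(retained),
                 decay_candidates = decay_candidates,
                 maxit = as.integer(maxit), monitor_frac = monitor_frac,
                 seed = as.integer(seed)),
            class = "ptml_config")
}

# forward pass through nnet-layout weights: logistic hidden, softmax output
.mlp_forward <- function(wts, n, X) {
  I <- n[1]; H <- n[2]; O <- n[3]
  W1 <- matrix(wts[seq_len((I + 1) * H)], nrow = I + 1)
  W2 <- matrix(wts[(I + 1) * H + seq_len((H + 1) * O)], nrow = H + 1)
  hid <- 1 / (1 + exp(-(cbind(1, X) %*% W1)))
  z <- cbind(1, hid) %*% W2
  z <- z - apply(z, 1L, max)
  ez <- exp(z)
  ez / rowSums(ez)
}

.composite_score <- function(prob_act, obs, labels_tbl) {
  pred <- ifelse(prob_act > 0.5, 1L, -1L)
  glob <- sn_sp(confusion_counts(pred, obs))
  gm <- mean(c(glob$sn, glob$sp), na.rm = TRUE)
  if (is.null(labels_tbl) || !ncol(labels_tbl)) return(gm)
  loc <- unlist(lapply(names(labels_tbl), function(el) {
    lm <- local_metrics(pred, obs, labels_tbl[[el]], el)
    c(lm$sn, lm$sp)
  }))
  (gm + mean(loc, na.rm = TRUE)) / 2
}

#' Train the PTML multilayer perceptron
#'
#' Trains `restarts` single-hidden-layer networks (logistic hidden units,
#' softmax output, full-batch BFGS optimisation of the cross-entropy via
#' \pkg{nnet}) over sampled hidden-layer sizes and weight decays, scores
#' each on an internal monitoring fold carved from the training cases
#' (global sensitivity/specificity plus the per-label local metrics), and
#' keeps the best. The applicability-domain bounding box is computed from
#' the correctly classified training cases, and the capacity parameter
#' `rho` is stored (a warning is raised when `rho < 2`).
#'
#' @param fused Tibble of training cases containing the fused descriptor
#'   columns, the class column `ACRC` and (optionally) the label columns
#'   `dt`, `ct`, `mc` used for the local-metric part of model selection.
#' @param feature_cols Fused descriptor columns used as inputs (default:
#'   all `D[...]` columns of `fused`).
#' @param config A [ptml_config()].
#' @param fusion Optional [fit_fusion()] statistics stored in the bundle so
#'   the model can predict straight from SMILES.
#' @param registry Optional [condition_registry()] stored alongside.
#' @return Object of class `ptml_mlp`.
#' @export
ptml_train <- function(fused, feature_cols = NULL, config = ptml_config(),
                       fusion = NULL, registry = NULL) {
  stopifnot(inherits(config, "ptml_config"), "ACRC" %in% names(fused))
  if (is.null(feature_cols)) {
    feature_cols <- grep("^D\\[", names(fused), value = TRUE)
  }
  X <- as.matrix(fused[feature_cols])
  if (!all(is.finite(X))) rlang::abort("non-finite model inputs")
  obs <- fused$ACRC
  if (length(unique(obs)) < 2L) {
    rlang::abort("training data contain a single class")
  }
  label_cols <- intersect(c("dt", "ct", "mc"), names(fused))
  labels_tbl <- if (length(label_cols)) fused[label_cols] else NULL

  set.seed(config$seed)
  n <- nrow(X)
  mon <- unlist(lapply(split(seq_len(n), obs), function(ix) {
    sample(ix, max(1L, round(length(ix) * config$monitor_frac)))
  }))
  tr <- setdiff(seq_len(n), mon)
  Y <- cbind(inactive = as.integer(obs == -1), active = as.integer(obs == 1))
  hs <- sample(seq(config$h_range[1], config$h_range[2]),
               config$restarts, replace = TRUE)
  decays <- sample(config$decay_candidates, config$restarts, replace = TRUE)

  fits <- vector("list", config$restarts)
  scores <- numeric(config$restarts)
  for (r in seq_len(config$restarts)) {
    set.seed(config$seed + r)
    fit <- nnet::nnet(x = X[tr, , drop = FALSE], y = Y[tr, ],
                      size = hs[r], decay = decays[r], softmax = TRUE,
                      maxit = config$maxit, trace = FALSE, MaxNWts = 20000L)
    pm <- .mlp_forward(fit$wts, fit$n, X[mon, , drop = FALSE])[, 2L]
    scores[r] <- .composite_score(pm, obs[mon],
                                  if (is.null(labels_tbl)) NULL
                                  else labels_tbl[mon, , drop = FALSE])
    fits[[r]] <- fit
  }
  ord <- order(-scores, hs, seq_along(scores))
  retained <- tibble(restart = ord[seq_len(config$retained)],
                     h = hs[ord[seq_len(config$retained)]],
                     decay = decays[ord[seq_len(config$retained)]],
                     composite = scores[ord[seq_len(config$retained)]])
  best <- fits[[ord[1L]]]

  prob_all <- .mlp_forward(best$wts, best$n, X)[, 2L]
  pred_all <- ifelse(prob_all > 0.5, 1L, -1L)
  correct <- pred_all == obs
  bounds <- ad_bounds(X, correct)
  rho_val <- rho(n, length(feature_cols), best$n[2L], 2L)
  if (rho_val < 2) {
    warn(paste0("rho = ", round(rho_val, 2),
                " < 2: network capacity may allow overfitting"))
  }
  structure(list(
    wts = best$wts, n = best$n, decay = retained$decay[1L],
    feature_ids = feature_cols,
    fusion = fusion, registry = registry, ad = bounds,
    T = n, rho = rho_val, seed = config$seed, config = config,
    retained = retained, monitor_idx = mon,
    versions = list(package = as.character(utils::packageVersion("ptmlfbtd")),
                    r = R.version.string)
  ), class = "ptml_mlp")
}

#' @export
print.ptml_mlp <- function(x, ...) {
  cat("<ptml_mlp> MLP ", x$n[1], "-", x$n[2], "-", x$n[3],
      "  (T = ", x$T, ", rho = ", round(x$rho, 2), ")\n", sep = "")
  invisible(x)
}

#' Predict activity for molecule-condition cases
#'
#' For cases given as `molecule_id` + `smiles` + `condition_id`, the full
#' pipeline is run with the statistics stored in the bundle: descriptors,
#' condition labels, Box-Jenkins fusion, forward pass. If the fused input
#' columns are already present in `cases`, the chemistry is skipped.
#' `ProbAct` is the softmax probability of the active output; the
#' predicted class is active iff `ProbAct > 0.5` (strict). Each case also
#' receives its applicability-domain score.
#'
#' @param object A `ptml_mlp`.
#' @param cases Tibble of cases.
#' @param registry Optional registry overriding the stored one.
#' @param ... Unused.
#' @return Tibble: case keys, `prob_act`, `pacrc`, `tsad`, `inside_ad`.
#' @export
predict.ptml_mlp <- function(object, cases, registry = NULL, ...) {
  if (!all(object$feature_ids %in% names(cases))) {
    if (is.null(object$fusion)) {
      rlang::abort("model bundle lacks fusion statistics; supply fused inputs")
    }
    registry <- registry %||% object$registry
    if (is.null(registry)) {
      rlang::abort("a condition registry is required to score raw cases")
    }
    desc <- compute_descriptors(cases)
    cases <- cases |>
      left_join(desc, by = "molecule_id") |>
      expand_labels(registry) |>
      fuse_descriptors(object$fusion)
  }
  X <- as.matrix(cases[object$feature_ids])
  prob <- .mlp_forward(object$wts, object$n, X)[, 2L]
  keep <- intersect(c("molecule_id", "condition_id", "ACRC", "partition",
                      "dt", "ct", "mc"), names(cases))
  bind_cols(
    cases[keep],
    tibble(prob_act = prob, pacrc = ifelse(prob > 0.5, 1L, -1L)),
    ad_score(object$ad, cases)
  )
}

#' Save / load a model bundle as JSON
#'
#' The bundle is fully self-contained (weights, topology, selected fused
#' descriptor ids, fusion statistics, applicability-domain bounds, seed and
#' versions); a reloaded model reproduces predictions bit-for-bit.
#'
#' @param model A `ptml_mlp`.
#' @param path File path.
#' @return `ptml_load` returns the restored `ptml_mlp`.
#' @export
ptml_save <- function(model, path) {
  stopifnot(inherits(model, "ptml_mlp"))
  writeLines(jsonlite::serializeJSON(model, digits = I(17)), path)
  invisible(path)
}

#' @rdname ptml_save
#' @export
ptml_load <- function(path) {
  model <- jsonlite::unserializeJSON(paste(readLines(path), collapse = "\n"))
  stopifnot(inherits(model, "ptml_mlp"))
  model
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a fitted PTML model
#'
#' One row per model input: the fused descriptor id and its
#' applicability-domain bounds.
#'
#' @param x A `ptml_mlp`.
#' @param ... Unused.
#' @method tidy ptml_mlp
#' @export
tidy.ptml_mlp <- function(x, ...) {
  tibble(term = x$feature_ids,
         index = seq_along(x$feature_ids),
         ad_min = x$ad$min[match(x$feature_ids, x$ad$id)],
         ad_max = x$ad$max[match(x$feature_ids, x$ad$id)])
}

#' Glance at a fitted PTML model
#'
#' @param x A `ptml_mlp`.
#' @param ... Unused.
#' @method glance ptml_mlp
#' @export
glance.ptml_mlp <- function(x, ...) {
  tibble(i = x$n[1], h = x$n[2], o = x$n[3], t = x$T, rho = x$rho,
         decay = x$decay, seed = x$seed,
         restarts = x$config$restarts, retained = x$config$retained,
         composite = x$retained$composite[1L])
}
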