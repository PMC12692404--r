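#' @importFrom ggplot2 autoplot ggplot aes geom_col geom_point geom_segment
#'   coord_flip labs theme_minimal facet_wrap
NULL

#' @export
ggplot2::autoplot

#' Plot input sensitivity values
#'
#' Lollipop chart of the sensitivity values of the model inputs, most
#' influential first.
#'
#' @param object A [sensitivity_values()] result.
#' @param ... Unused.
#' @method autoplot ptml_sensitivity
#' @export
autoplot.ptml_sensitivity <- function(object, ...) {
  df <- as_tibble(object) |>
    mutate(term = stats::reorder(.data$term, .data$sv))
  ggplot(df, aes(x = .data$term, y = .data$sv)) +
    geom_segment(aes(xend = .data$term, y = 1, yend = .data$sv),
                 colour = "grey60") +
    geom_point(size = 2) +
    coord_flip() +
    labs(x = NULL, y = "sensitivity value (error ratio)",
         title = "Input influence in the PTML-MLP model") +
    theme_minimal()
}

#' Plot tendency-of-variation table
#'
#' Dumbbell chart contrasting the active and inactive class means of each
#' model input.
#'
#' @param object A [tendency_table()] result.
#' @param ... Unused.
#' @method autoplot ptml_tendency
#' @export
autoplot.ptml_tendency <- function(object, ...) {
  df <- as_tibble(object) |>
    tidyr::pivot_longer(c("active_mean", "inactive_mean"),
                        names_to = "class", values_to = "mean")
  ggplot(df, aes(x = .data$mean, y = .data$term, colour = .data$class)) +
    geom_point(size = 2) +
    labs(x = "class-conditional mean of the fused input", y = NULL,
         colour = NULL,
         title = "Tendency of variation of the model inputs") +
    theme_minimal()
}

#' Global performance per partition
#'
#' Convenience wrapper computing confusion counts, sensitivity,
#' specificity and normalized MCC per partition from a prediction table.
#'
#' @param predictions Tibble with `pacrc`, `ACRC` and a `partition`
#'   column.
#' @return Tibble of class `ptml_eval`.
#' @export
model_performance <- function(predictions) {
  stopifnot(all(c("pacrc", "ACRC") %in% names(predictions)))
  parts <- if ("partition" %in% names(predictions)) {
    split(predictions, predictions$partition)
  } else list(all = predictions)
  out <- purrr::imap_dfr(parts, function(df, nm) {
    confusion_counts(df$pacrc, df$ACRC, scope = nm)
  }) |>
    sn_sp()
  out$nmcc <- nmcc(out)
  class(out) <- c("ptml_eval", class(out))
  out
}

#' Plot global performance metrics
#'
#' @param object A [model_performance()] result.
#' @param ... Unused.
#' @method autoplot ptml_eval
#' @export
autoplot.ptml_eval <- function(object, ...) {
  df <- as_tibble(object) |>
    tidyr::pivot_longer(c("sn", "sp"), names_to = "metric",
                        values_to = "percent")
  ggplot(df, aes(x = toupper(.data$metric), y = .data$percent,
                 fill = .data$scope)) +
    geom_col(position = "dodge") +
    labs(x = NULL, y = "percent", fill = NULL,
         title = "Classification performance") +
    theme_minimal()
}
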