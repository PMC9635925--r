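#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom tibble as_tibble
#' @export
tibble::as_tibble

#' Plate heatmap
#'
#' Tile map of one plate's raw values or B-scores in physical layout (row A
#' at the top), the standard visual check for positional artifacts before
#' and after normalization.
#'
#' @param scored Long well tibble from [bscore_plates()] or
#'   [as_tibble()] on a [plate_grid()].
#' @param plate Plate id to show (default: first).
#' @param fill Column to map to fill: `"value"` or `"b_score"`.
#' @return A ggplot object.
#' @export
plot_plate <- function(scored, plate = NULL, fill = "value") {
  plate <- plate %||% scored$plate_id[1L]
  d <- scored[scored$plate_id == plate, ]
  if (!nrow(d)) abort(sprintf("No wells for plate '%s'.", plate))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$col, y = .data$row,
                                  fill = .data[[fill]])) +
    ggplot2::geom_tile(colour = "grey80", linewidth = 0.2) +
    ggplot2::scale_y_reverse(breaks = unique(d$row),
                             labels = LETTERS[unique(d$row)]) +
    ggplot2::scale_x_continuous(breaks = unique(d$col)) +
    ggplot2::scale_fill_viridis_c(na.value = "white") +
    ggplot2::labs(title = plate, x = NULL, y = NULL, fill = fill) +
    ggplot2::theme_minimal() +
    ggplot2::theme(panel.grid = ggplot2::element_blank())
}

#' @export
#' @method autoplot screen_hits
#' @rdname call_hits
#' @param object A `screen_hits` tibble.
autoplot.screen_hits <- function(object, ...) {
  b_col <- setdiff(names(object), c("compound_id", "is_hit"))[1L]
  thr <- attr(object, "threshold")
  ggplot2::ggplot(object, ggplot2::aes(x = .data[[b_col]])) +
    ggplot2::geom_histogram(bins = 80, fill = "grey65") +
    ggplot2::geom_vline(xintercept = thr, colour = "firebrick",
                        linetype = "dashed") +
    ggplot2::annotate("text", x = thr, y = Inf, hjust = -0.1, vjust = 1.5,
                      colour = "firebrick",
                      label = sprintf("threshold %.2f", thr)) +
    ggplot2::labs(x = "aggregated B-score", y = "compounds") +
    ggplot2::theme_minimal()
}

#' @export
#' @method autoplot differential_calls
#' @rdname differential_select
#' @param object A `differential_calls` tibble.
#' @param ... Unused.
autoplot.differential_calls <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$b_wt, y = .data$b_mut,
                                       colour = .data$differential_call)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "grey70") +
    ggplot2::geom_abline(slope = 1, intercept = -attr(object, "upper"),
                         linetype = "dashed", colour = "grey50") +
    ggplot2::geom_abline(slope = 1, intercept = -attr(object, "lower"),
                         linetype = "dashed", colour = "grey50") +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::scale_colour_manual(values = c(POSITIVE = "firebrick",
                                            NEGATIVE = "steelblue",
                                            NONE = "grey60")) +
    ggplot2::labs(x = "B-score (WT)", y = "B-score (MUT)",
                  colour = "differential") +
    ggplot2::theme_minimal()
}

#' @export
#' @method autoplot dose_response_fit
#' @rdname fit_dose_response
#' @param object A `dose_response_fit`.
autoplot.dose_response_fit <- function(object, ...) {
  grid <- tibble::tibble(
    x = seq(min(object$data$x) - 0.25, max(object$data$x) + 0.25,
            length.out = 200)
  )
  grid$y <- predict(object, grid$x)
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_line(data = grid, colour = "firebrick") +
    ggplot2::geom_vline(xintercept = object$log_ec50, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::labs(x = "log10 concentration (M)", y = "response") +
    ggplot2::theme_minimal()
}

#' @export
#' @method autoplot cluster_set
#' @rdname cluster_butina
#' @param object A `cluster_set`.
autoplot.cluster_set <- function(object, ...) {
  per <- tidy.cluster_set(object)
  per$cluster <- stats::reorder(factor(per$cluster), -per$n_members)
  ggplot2::ggplot(per, ggplot2::aes(x = .data$cluster, y = .data$n_members,
                                    fill = .data$is_major)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "steelblue",
                                          `FALSE` = "grey70")) +
    ggplot2::labs(x = "cluster (by extraction order)", y = "members",
                  fill = "major") +
    ggplot2::theme_minimal()
}
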