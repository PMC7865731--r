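#' Plot a whole-cell fluorescence trace
#'
#' Normalized fluorescence against time with the stimulation marked at
#' t = 0.
#'
#' @param object A `fluorescence_trace` from [cell_trace()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot fluorescence_trace
#' @export
autoplot.fluorescence_trace <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$time_s, y = .data$f_norm)) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time from stimulation (s)",
                  y = "normalized cell fluorescence") +
    ggplot2::theme_minimal()
}

#' Plot tracked trajectories
#'
#' @param object A `track_table` from [link_tracks()].
#' @param ... Unused.
#' @return A ggplot object (y reversed to match image coordinates).
#' @method autoplot track_table
#' @export
autoplot.track_table <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$col, y = .data$row,
                               group = .data$track_id,
                               colour = factor(.data$track_id))) +
    ggplot2::geom_path(show.legend = FALSE) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "col (px)", y = "row (px)") +
    ggplot2::theme_minimal()
}

#' Plot a displacement histogram
#'
#' @param object A `displacement_histogram`.
#' @param kind Which histogram to show: per-frame `"step"` lengths or
#'   per-track `"track_total"` path lengths.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot displacement_histogram
#' @export
autoplot.displacement_histogram <- function(object, kind = "step", ...) {
  dat <- object[object$kind == kind, , drop = FALSE]
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$bin_left +
                                      (.data$bin_right - .data$bin_left) / 2,
                                    y = .data$count)) +
    ggplot2::geom_col(width = dat$bin_right[1] - dat$bin_left[1],
                      fill = "grey35") +
    ggplot2::labs(x = "displacement (px)", y = "count",
                  title = paste0(kind, " displacements")) +
    ggplot2::theme_minimal()
}

#' Plot per-cell PLA counts
#'
#' @param object A `pla_report` from [count_signals()].
#' @param ... Unused.
#' @return A ggplot object with the signals-per-cell mean marked.
#' @method autoplot pla_report
#' @export
autoplot.pla_report <- function(object, ...) {
  dat <- tidy(object)
  ggplot2::ggplot(dat, ggplot2::aes(x = factor(.data$cell),
                                    y = .data$count)) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::geom_hline(yintercept = object$signals_per_cell,
                        linetype = "dashed", colour = "red") +
    ggplot2::labs(x = "cell", y = "PLA signals") +
    ggplot2::theme_minimal()
}

#' Plot per-site binding scores
#'
#' @param object A `binding_score` from [cell_binding_score()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot binding_score
#' @export
autoplot.binding_score <- function(object, ...) {
  dat <- object$sites
  dat$site <- seq_len(nrow(dat))
  ggplot2::ggplot(dat[dat$score_defined, , drop = FALSE],
                  ggplot2::aes(x = .data$site, y = .data$score)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey60") +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = object$mean_score,
                        linetype = "dashed", colour = "red") +
    ggplot2::labs(x = "site", y = "deltaF / S") +
    ggplot2::theme_minimal()
}
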