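#' Descriptor series
#'
#' A `lox_series` is a tibble with one row per frame and columns `name`
#' (role label), `frame_id`, `value` and `unit` (one of `"angstrom"`,
#' `"degree"`, `"unitless"`).  Every per-trajectory descriptor in the
#' package returns this shape so series can be bound, joined and plotted
#' with ordinary tidyverse verbs.
#'
#' @param name Role label for the series (single string).
#' @param frame_ids Integer frame identifiers.
#' @param values Numeric values, same length as `frame_ids`.
#' @param unit One of `"angstrom"`, `"degree"`, `"unitless"`.
#' @return A tibble of class `lox_series`.
#' @export
lox_series <- function(name, frame_ids, values, unit) {
  unit <- match.arg(unit, c("angstrom", "degree", "unitless"))
  if (length(frame_ids) != length(values)) {
    abort("frame_ids and values must have equal length")
  }
  out <- tibble(name = name, frame_id = as.integer(frame_ids),
                value = as.numeric(values), unit = unit)
  class(out) <- c("lox_series", class(out))
  out
}

#' Mean of a series over a frame window
#'
#' @param series A [lox_series()].
#' @param window Optional integer range `c(first, last)` of frame ids
#'   (inclusive); default uses all frames.
#' @return The mean value over the window.
#' @export
series_window_mean <- function(series, window = NULL) {
  v <- series$value
  if (!is.null(window)) {
    keep <- series$frame_id >= window[1] & series$frame_id <= window[2]
    if (!any(keep)) abort("window contains no frames")
    v <- v[keep]
  }
  mean(v)
}

#' Plot descriptor series against frame index
#'
#' @param object A [lox_series()] (possibly several series bound by row).
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.lox_series <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$frame_id, y = .data$value,
                                       colour = .data$name)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "frame", y = unique(object$unit)[1], colour = NULL) +
    ggplot2::theme_minimal()
}
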