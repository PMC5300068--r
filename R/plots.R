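# ggplot2 presentations of the main result types.

#' @exportS3Method ggplot2::autoplot
autoplot.scattering_curve <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object), ggplot2::aes(x = .data$q,
                                                  y = .data$intensity)) +
    ggplot2::geom_point(size = 0.6) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = expression(Q ~ (nm^-1)), y = "I(Q) (a.u.)") +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.guinier_fit <- function(object, curve, ...) {
  df <- as_tibble(curve)
  df <- df[df$intensity > 0, ]
  df$in_window <- df$q >= object$window[1] & df$q <= object$window[2]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$q^2, y = log(.data$intensity),
                                   color = .data$in_window)) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::geom_abline(intercept = log(object$i0),
                         slope = -object$rg_nm^2 / 3, linetype = 2) +
    ggplot2::scale_color_manual(values = c(`TRUE` = "firebrick",
                                           `FALSE` = "grey60"),
                                guide = "none") +
    ggplot2::labs(x = expression(Q^2 ~ (nm^-2)), y = "ln I(Q)",
                  title = sprintf("Rg = %.2f nm", object$rg_nm)) +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.distance_distribution <- function(object, ...) {
  pk <- attr(object, "peaks_nm")
  p <- ggplot2::ggplot(as_tibble(object), ggplot2::aes(x = .data$r,
                                                       y = .data$p)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "r (nm)", y = "P(r)") +
    ggplot2::theme_minimal()
  if (length(pk) > 0) {
    p <- p + ggplot2::geom_vline(xintercept = pk, linetype = 3,
                                 color = "firebrick")
  }
  p
}

#' R-factor versus Rg scatter of a search
#'
#' The conventional search summary: every accepted trial as a point, the
#' ten best-fit models highlighted, the target Guinier Rg as a vertical
#' line with a +/- 5% band.
#'
#' @param object a `search_result`.
#' @param n_best number of best models to highlight.
#' @param ... unused.
#' @exportS3Method ggplot2::autoplot
autoplot.search_result <- function(object, n_best = 10, ...) {
  tr <- object$trials[object$trials$accepted, ]
  bs <- select_best(object, n_best)
  p <- ggplot2::ggplot(tr, ggplot2::aes(x = .data$rg_nm,
                                        y = .data$r_factor)) +
    ggplot2::geom_point(size = 0.5, color = "grey50") +
    ggplot2::geom_point(data = as_tibble(bs[, c("rg_nm", "r_factor")]),
                        color = "red", size = 1.2) +
    ggplot2::labs(x = "model Rg (nm)", y = "R factor (%)") +
    ggplot2::theme_minimal()
  if (is.finite(object$target_rg_nm)) {
    p <- p +
      ggplot2::geom_vline(xintercept = object$target_rg_nm) +
      ggplot2::geom_vline(xintercept = object$target_rg_nm * c(0.95, 1.05),
                          linetype = 2)
  }
  p
}
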