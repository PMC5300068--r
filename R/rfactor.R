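# Model-versus-experiment agreement.
#
# The goodness-of-fit R factor is the scattering analogue of the
# crystallographic R factor: R = 100 * sum|I_expt - eta * I_calc| /
# sum|I_expt|, with the scale factor eta chosen to minimize R.

#' R factor between an experimental and a calculated curve
#'
#' The calculated curve is interpolated onto the experimental Q grid over
#' the overlapping support; the scale `eta` is optimized on log10(eta) in
#' [-3, 3] (Brent minimization, tolerance 1e-6).
#'
#' @param expt experimental `scattering_curve`.
#' @param calc calculated `scattering_curve`.
#' @param q_range optional length-2 Q range to score.
#' @return object of class `fit_score` with `r_factor` (percent), `eta`,
#'   `q_range`, `n_points`.
#' @export
r_factor <- function(expt, calc, q_range = NULL) {
  lo <- max(min(expt$q), min(calc$q))
  hi <- min(max(expt$q), max(calc$q))
  if (!is.null(q_range)) {
    lo <- max(lo, q_range[1]); hi <- min(hi, q_range[2])
  }
  if (hi <= lo) abort("no overlapping Q support between curves")
  sel <- expt$q >= lo & expt$q <= hi
  qe <- expt$q[sel]
  Ie <- expt$intensity[sel]
  if (all(Ie == 0)) abort("all-zero experimental curve")
  Ic <- approx(calc$q, calc$intensity, xout = qe, rule = 2)$y
  denom <- sum(abs(Ie))
  rfun <- function(logeta) {
    sum(abs(Ie - 10^logeta * Ic)) / denom
  }
  # center the bracket on the least-squares scale so wildly different
  # absolute normalizations still land inside [-3, 3]
  eta0 <- sum(Ie * Ic) / sum(Ic^2)
  shift <- if (is.finite(eta0) && eta0 > 0) log10(eta0) else 0
  opt <- optimize(function(u) rfun(u + shift), interval = c(-3, 3),
                  tol = 1e-6)
  structure(list(r_factor = 100 * opt$objective,
                 eta = 10^(opt$minimum + shift),
                 q_range = c(lo, hi), n_points = length(qe)),
            class = "fit_score")
}

#' @export
print.fit_score <- function(x, ...) {
  cat(sprintf("R factor = %.2f%% (eta = %.4g, Q %.3f-%.3f, %d pts)\n",
              x$r_factor, x$eta, x$q_range[1], x$q_range[2], x$n_points))
  invisible(x)
}

#' Concentration-series consistency check
#'
#' Dilute-solution data should show no trend of I(0)/c or Rg with
#' concentration; a significant trend flags inter-particle interference or
#' self-association.  Fits per-curve Guinier parameters, regresses both
#' I(0)/c and Rg on concentration, and flags slopes that differ from zero
#' at the configured significance.
#'
#' @param curves list of `scattering_curve`s carrying concentration
#'   attributes, or with concentrations supplied separately.
#' @param concentrations optional numeric vector (mg/mL) overriding the
#'   per-curve attributes.
#' @param qrg_limit passed to [guinier_fit()].
#' @param sig_level two-sided significance level for the trend flag.
#' @param rel_tol practical-significance floor: the flag is also raised
#'   when the fitted trend moves a quantity by more than this relative
#'   fraction across the measured concentration range (guards the short
#'   series, where a clear trend can still have few degrees of freedom).
#' @return list of class `concentration_check`: `per_curve` tibble
#'   (`concentration`, `i0`, `i0_per_c`, `rg_nm`), `trends` tibble
#'   (`quantity`, `slope`, `se`, `p_value`, `rel_change`), and logical
#'   `flag`.
#' @export
concentration_series_check <- function(curves, concentrations = NULL,
                                       qrg_limit = 1.3, sig_level = 0.01,
                                       rel_tol = 0.05) {
  if (length(curves) < 2) abort("need at least two concentrations")
  conc <- concentrations %||%
    vapply(curves, function(cv) attr(cv, "concentration_mg_ml") %||% NA_real_,
           numeric(1))
  if (any(is.na(conc))) abort("missing concentration labels")
  fits <- lapply(curves, guinier_fit, qrg_limit = qrg_limit)
  per <- tibble(
    concentration = conc,
    i0 = vapply(fits, function(f) f$i0, numeric(1)),
    rg_nm = vapply(fits, function(f) f$rg_nm, numeric(1))
  )
  per$i0_per_c <- per$i0 / per$concentration
  trend_row <- function(y, nm) {
    if (sd(y) < 1e-9 * max(abs(y), 1e-300)) {
      return(tibble(quantity = nm, slope = 0, se = 0, p_value = 1,
                    rel_change = 0))
    }
    ft <- lm(y ~ conc)
    sm <- suppressWarnings(summary(ft))$coefficients
    tibble(quantity = nm, slope = sm[2, 1], se = sm[2, 2],
           p_value = sm[2, 4],
           rel_change = abs(sm[2, 1]) * diff(range(conc)) / mean(abs(y)))
  }
  trends <- dplyr::bind_rows(trend_row(per$i0_per_c, "i0_per_c"),
                             trend_row(per$rg_nm, "rg_nm"))
  structure(list(per_curve = per, trends = trends,
                 flag = any(trends$p_value < sig_level |
                              trends$rel_change > rel_tol),
                 sig_level = sig_level, rel_tol = rel_tol),
            class = "concentration_check")
}

#' @export
print.concentration_check <- function(x, ...) {
  cat(if (x$flag) "Concentration dependence DETECTED\n"
      else "No concentration dependence detected\n")
  print(x$trends)
  invisible(x)
}
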