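# broom-style accessors for fitted objects.

#' @exportS3Method generics::tidy
tidy.guinier_fit <- function(x, ...) {
  tibble(term = c("rg_nm", "i0"),
         estimate = c(x$rg_nm, x$i0),
         std.error = c(x$rg_se, x$i0_se))
}

#' @exportS3Method generics::glance
glance.guinier_fit <- function(x, ...) {
  tibble(rg_nm = x$rg_nm, rg_se = x$rg_se, i0 = x$i0,
         q_min = x$window[1], q_max = x$window[2],
         qrg_min = x$qrg_range[1], qrg_max = x$qrg_range[2],
         n_points = x$n_points)
}

#' @exportS3Method generics::tidy
tidy.rxs_fit <- function(x, ...) {
  tibble(term = "rxs_nm", estimate = x$rxs_nm, std.error = x$rxs_se)
}

#' @exportS3Method generics::glance
glance.rxs_fit <- function(x, ...) {
  tibble(rxs_nm = x$rxs_nm, rxs_se = x$rxs_se,
         q_min = x$window[1], q_max = x$window[2], n_points = x$n_points)
}

#' @exportS3Method generics::tidy
tidy.fit_score <- function(x, ...) {
  tibble(term = c("r_factor", "eta"), estimate = c(x$r_factor, x$eta))
}

#' @exportS3Method generics::glance
glance.fit_score <- function(x, ...) {
  tibble(r_factor = x$r_factor, eta = x$eta,
         q_min = x$q_range[1], q_max = x$q_range[2], n_points = x$n_points)
}

#' @exportS3Method generics::tidy
tidy.distance_distribution <- function(x, ...) as_tibble(x)

#' @exportS3Method generics::glance
glance.distance_distribution <- function(x, ...) {
  pk <- attr(x, "peaks_nm")
  tibble(L_nm = attr(x, "L_nm"), rg_nm = attr(x, "rg_nm"),
         n_peaks = length(pk),
         peak1_nm = if (length(pk) > 0) pk[1] else NA_real_,
         peak2_nm = if (length(pk) > 1) pk[length(pk)] else NA_real_,
         dmax_nm = attr(x, "dmax_nm"), chisq = attr(x, "chisq"))
}

#' @exportS3Method generics::tidy
tidy.search_result <- function(x, ...) x$trials

#' @exportS3Method generics::glance
glance.search_result <- function(x, ...) {
  acc <- x$trials[x$trials$accepted, ]
  tibble(n_accepted = nrow(acc), n_proposals = nrow(x$trials),
         acceptance_rate = x$meta$acceptance_rate,
         best_r_factor = min(acc$r_factor),
         target_rg_nm = x$target_rg_nm, seed = x$meta$seed)
}

#' @exportS3Method generics::tidy
tidy.hydro_result <- function(x, ...) {
  tibble(term = c("s20w_S", "rh_nm", "frictional_ratio"),
         estimate = c(x$s20w_S, x$rh_nm, x$frictional_ratio))
}

#' @exportS3Method generics::glance
glance.hydro_result <- function(x, ...) {
  tibble(s20w_S = x$s20w_S, rh_nm = x$rh_nm,
         frictional_ratio = x$frictional_ratio, n_beads = x$n_beads,
         bead_radius_nm = x$bead_radius_nm, reduced = x$reduced,
         mass_kDa = x$mass_kDa, vbar_mL_g = x$vbar_mL_g)
}

#' @exportS3Method generics::tidy
tidy.superposition <- function(x, ...) {
  tibble(rmsd_A = x$rmsd_A, n_retained = x$n_retained,
         n_rejected = x$n_rejected)
}

#' @exportS3Method generics::glance
glance.concentration_check <- function(x, ...) {
  tibble(flag = x$flag, sig_level = x$sig_level,
         p_i0_per_c = x$trends$p_value[x$trends$quantity == "i0_per_c"],
         p_rg = x$trends$p_value[x$trends$quantity == "rg_nm"])
}

#' @exportS3Method generics::tidy
tidy.concentration_check <- function(x, ...) x$per_curve

#' @exportS3Method generics::tidy
tidy.recovery_report <- function(x, ...) {
  dplyr::bind_cols(x$geometry, x$fit, x$s20w)
}
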