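# Distance distribution functions P(r).
#
# P(r) is the histogram of all intra-particle pair distances.  It can be
# computed directly from a sphere model, or recovered from a scattering
# curve by a regularized indirect transform.  The maximum length L is read
# from where P(r) returns to zero; peak positions are called after a 3-bin
# moving-average smoothing with a minimum prominence of 2% of the maximum.

new_distance_distribution <- function(r, p, L, rg, peaks, dmax, chisq = NA_real_) {
  out <- tibble::new_tibble(tibble(r = r, p = p),
                            class = "distance_distribution")
  attr(out, "L_nm") <- L
  attr(out, "rg_nm") <- rg
  attr(out, "peaks_nm") <- peaks
  attr(out, "dmax_nm") <- dmax
  attr(out, "chisq") <- chisq
  out
}

# local maxima of a smoothed histogram with a prominence floor
call_peaks <- function(r, p, smooth_bins = 3, prominence = 0.02) {
  if (length(p) < 3) return(numeric(0))
  k <- rep(1 / smooth_bins, smooth_bins)
  ps <- as.vector(stats::filter(p, k, sides = 2))
  ps[is.na(ps)] <- p[is.na(ps)]
  n <- length(ps)
  cand <- which(ps[2:(n - 1)] >= ps[1:(n - 2)] & ps[2:(n - 1)] > ps[3:n]) + 1
  floor_p <- prominence * max(ps)
  cand <- cand[ps[cand] >= floor_p]
  if (length(cand) == 0) return(numeric(0))
  # merge plateaus / immediately adjacent candidates, and require each peak
  # to rise by the prominence floor above the valley separating it from a
  # higher neighbor
  keep <- logical(length(cand))
  for (i in seq_along(cand)) {
    j <- cand[i]
    higher <- cand[ps[cand] > ps[j]]
    if (length(higher) == 0) { keep[i] <- TRUE; next }
    valleys <- vapply(higher, function(h) min(ps[seq(min(h, j), max(h, j))]),
                      numeric(1))
    keep[i] <- all(ps[j] - valleys >= floor_p)
  }
  r[cand[keep]]
}

#' P(r) directly from a sphere model
#'
#' Normalized histogram of all sphere-center pair distances.  Reports the
#' maximum length L (upper edge of the last occupied bin), the real-space
#' radius of gyration from the second moment (`Rg^2 = sum r^2 P / (2 sum
#' P)`), and smoothed-peak positions.
#'
#' @param spheres a `sphere_model` (or any x/y/z table) with >= 2 rows.
#' @param bin_width_nm histogram bin width (nm).
#' @param smooth_bins moving-average window (bins) for peak calling.  Note
#'   that P(r) of a cube-grid sphere model carries lattice ripple; for
#'   peak analysis prefer atom coordinates or [pr_from_curve()].
#' @param prominence minimum peak prominence as a fraction of max P(r).
#' @return a `distance_distribution` tibble (`r`, `p`; area normalized to
#'   1) with attributes `L_nm`, `rg_nm`, `peaks_nm`.
#' @export
pr_from_model <- function(spheres, bin_width_nm = 0.1, smooth_bins = 3,
                          prominence = 0.02) {
  if (nrow(spheres) < 2) abort("need at least two spheres for P(r)")
  d <- as.vector(stats::dist(coords_matrix(spheres)))
  nb <- as.integer(ceiling(max(d) / bin_width_nm)) + 1L
  idx <- pmax(1L, as.integer(ceiling(d / bin_width_nm)))
  counts <- tabulate(idx, nbins = nb)
  r <- (seq_len(nb) - 0.5) * bin_width_nm
  p <- counts / (sum(counts) * bin_width_nm)
  L <- max(which(counts > 0)) * bin_width_nm
  rg <- sqrt(sum(r^2 * p) / (2 * sum(p)))
  new_distance_distribution(r, p, L, rg,
                            call_peaks(r, p, smooth_bins, prominence),
                            dmax = L)
}

#' P(r) from a scattering curve by regularized indirect transform
#'
#' Represents P(r) on `n_points` interior nodes of `[0, dmax]` (P(0) =
#' P(dmax) = 0), and minimizes the weighted misfit to the curve plus
#' `alpha` times a second-derivative smoothness penalty.  Small negative
#' excursions of the solution are clipped to zero before normalization.
#'
#' @param curve a `scattering_curve`; should extend to `Q * dmax` of at
#'   least about pi.
#' @param dmax assumed maximum dimension (nm).
#' @param n_points number of interior P(r) nodes.
#' @param alpha dimensionless regularization weight (default 0.01; larger
#'   values give smoother P(r) and larger chi^2).
#' @param smooth_bins,prominence peak-calling parameters as in
#'   [pr_from_model()].
#' @return a `distance_distribution` with attributes `L_nm`, `rg_nm`,
#'   `peaks_nm`, `chisq`.
#' @export
pr_from_curve <- function(curve, dmax, n_points = 100, alpha = 0.01,
                          smooth_bins = 3, prominence = 0.02) {
  if (dmax <= 0) abort("dmax must be positive")
  if (max(curve$q) * dmax < pi) {
    abort("curve does not extend to Q*dmax >= pi; transform is underdetermined")
  }
  q <- curve$q
  I <- curve$intensity
  w <- if ("sigma" %in% names(curve)) 1 / curve$sigma^2 else rep(1, length(q))
  dr <- dmax / (n_points + 1)
  r <- seq_len(n_points) * dr
  qr <- outer(q, r)
  A <- (sin(qr) / qr) * dr
  D <- diff(diag(n_points), differences = 2)
  AtWA <- crossprod(A, w * A)
  DtD <- crossprod(D)
  lam <- alpha * sum(diag(AtWA)) / sum(diag(DtD))
  H <- AtWA + lam * DtD + 1e-12 * mean(diag(AtWA)) * diag(n_points)
  rhs <- crossprod(A, w * I)
  p <- tryCatch(solve(H, rhs),
                error = function(e) abort("ill-conditioned indirect transform; increase alpha"))
  p <- as.vector(p)
  resid <- I - as.vector(A %*% p)
  chisq <- sum(w * resid^2)
  p[p < 0] <- 0
  area <- sum(p) * dr
  if (area <= 0) abort("degenerate P(r): all-zero solution")
  p <- p / area
  # L: last r at which P exceeds the zero threshold
  thr <- 1e-3 * max(p)
  above <- which(p >= thr)
  L <- if (length(above) > 0) r[max(above)] + dr / 2 else dmax
  rg <- sqrt(sum(r^2 * p) / (2 * sum(p)))
  new_distance_distribution(r, p, L, rg,
                            call_peaks(r, p, smooth_bins, prominence),
                            dmax = dmax, chisq = chisq)
}

#' Write a P(r) curve as 2-column text
#'
#' @param pr a `distance_distribution`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pr <- function(pr, path) {
  writeLines(sprintf("# r(nm) P(r)  L=%.3f Rg=%.3f", attr(pr, "L_nm"),
                     attr(pr, "rg_nm")), path)
  utils::write.table(cbind(pr$r, pr$p), path, append = TRUE,
                     col.names = FALSE, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @export
print.distance_distribution <- function(x, ...) {
  pk <- attr(x, "peaks_nm")
  cat(sprintf("P(r): L = %.2f nm, Rg = %.3f nm, peaks at %s nm\n",
              attr(x, "L_nm"), attr(x, "rg_nm"),
              paste(sprintf("%.2f", pk), collapse = ", ")))
  invisible(x)
}
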