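# Ground-truth toy dimers and synthetic SAXS observations.
#
# The generator builds two-armed antiparallel dimers that mimic the domain
# organization of a MASP homodimer: a rigid core of two CUB1-EGF pairs
# forming the dimer interface, arms of pseudo-atom domain balls connected
# by short explicit-backbone linkers, and a controllable bend angle at the
# EGF-CUB2 hinge.  Every stage of the analysis pipeline can then be tested
# against known ground truth without any experimental download.

#' Specification of a synthetic toy dimer
#'
#' @param arm_domains tibble describing the domains of one arm beyond the
#'   core, in chain order: columns `segment`, `radius_nm` and optionally
#'   `n_atoms` (default scales with volume, clamped to 50..200
#'   pseudo-atoms).
#' @param bend_deg target bend angle theta (degrees, in (0, 180]) between
#'   the two *last* arm domains measured at the core centroid; realized by
#'   rotating each arm at the first (EGF-CUB2) linker.
#' @param core_radii radii of the CUB1 and EGF core domains (nm).
#' @param linker_len residues per flexible linker.
#' @param dy half-offset between the two chains across the interface (nm).
#' @param interface_overlap how deeply the CUB1 and EGF balls of one chain
#'   interpenetrate along x (nm); together with `dy` this sets the buried
#'   surface area of the dimer interface.
#' @param seed integer seed for pseudo-atom sampling.
#' @return list of class `toy_dimer_spec`.
#' @export
toy_dimer_spec <- function(arm_domains = tibble(segment = "CUB2",
                                                radius_nm = 1.5),
                           bend_deg = 180, core_radii = c(CUB1 = 1.4,
                                                          EGF = 0.95),
                           linker_len = 3, dy = 0.8,
                           interface_overlap = 0.2, seed = 1L) {
  arm_domains <- as_tibble(arm_domains)
  if (!"n_atoms" %in% names(arm_domains)) {
    arm_domains$n_atoms <- pmin(200L, pmax(50L, as.integer(
      round(12 * 4 / 3 * pi * arm_domains$radius_nm^3))))
  }
  if (bend_deg <= 0 || bend_deg > 180) abort("bend_deg must lie in (0, 180]")
  if (any(arm_domains$radius_nm <= 0) || any(arm_domains$n_atoms < 1)) {
    abort("arm domain radii and atom counts must be positive")
  }
  structure(list(arm_domains = arm_domains, bend_deg = bend_deg,
                 core_radii = core_radii, linker_len = as.integer(linker_len),
                 dy = dy, interface_overlap = interface_overlap,
                 seed = as.integer(seed)),
            class = "toy_dimer_spec")
}

#' Named toy specifications used throughout the test suite
#'
#' `"masp3d-like"` mimics a CUB1-EGF-CUB2 dimer (length ~13 nm, Rg in the
#' upper-3 nm range); `"fulllength-like"` extends each arm with SCR1, SCR2
#' and SP domains, giving the long two-peak P(r) morphology of a
#' full-length protease dimer.
#'
#' @param name registry key.
#' @param bend_deg bend angle passed through to [toy_dimer_spec()].
#' @param seed seed passed through.
#' @return a `toy_dimer_spec`.
#' @export
toy_registry <- function(name = c("masp3d-like", "fulllength-like"),
                         bend_deg = 180, seed = 1L) {
  name <- match.arg(name)
  arms <- switch(name,
    "masp3d-like" = tibble(segment = "CUB2", radius_nm = 1.5),
    "fulllength-like" = tibble(segment = c("CUB2", "SCR1", "SCR2", "SP"),
                               radius_nm = c(1.5, 0.85, 0.85, 1.45)))
  toy_dimer_spec(arm_domains = arms, bend_deg = bend_deg, seed = seed)
}

# uniform pseudo-atom ball, recentered exactly on `center`
sample_ball <- function(n, radius, center) {
  pts <- matrix(NA_real_, 0, 3)
  while (nrow(pts) < n) {
    cand <- matrix(runif(3 * 2 * n, -radius, radius), ncol = 3)
    cand <- cand[rowSums(cand^2) <= radius^2, , drop = FALSE]
    pts <- rbind(pts, cand)
  }
  pts <- pts[seq_len(n), , drop = FALSE]
  sweep(pts, 2, colMeans(pts) - center, `-`)
}

#' Build a ground-truth toy dimer
#'
#' Constructs the dimer in its straight (180 degree) form, then bends both
#' arms symmetrically at the first linker until the centroid bend angle
#' matches the specification (solved to 0.01 degrees, well inside the 2
#' degree contract).  One pseudo-atom per CUB2 domain is named ASN and
#' serves as a glycan attachment site.
#'
#' @param spec a `toy_dimer_spec`.
#' @return list of class `toy_dimer`: `model` (`structure_model` with mass
#'   and dry-volume attributes), `domains` (`domain_map`), `linkers`
#'   (`linker_set`), `truth` (`geometry_params` of the as-built model) and
#'   `spec`.
#' @export
make_toy_dimer <- function(spec) {
  stopifnot(inherits(spec, "toy_dimer_spec"))
  set.seed(spec$seed)
  dy <- spec$dy
  r_cub1 <- spec$core_radii[["CUB1"]]
  r_egf <- spec$core_radii[["EGF"]]
  x_egf <- 1.0
  ov <- spec$interface_overlap %||% 0.45
  x_cub1 <- x_egf - (r_egf + r_cub1 - ov)   # overlapping => interface
  ball_atoms <- function(r) min(200L, max(50L, as.integer(round(12 * 4 / 3 * pi * r^3))))

  # chain A along +x at y = +dy; residues numbered consecutively
  rows <- list(); segs <- list(); lnks <- list()
  resid <- 0L
  add_ball <- function(name, center, radius, n) {
    pts <- sample_ball(n, radius, center)
    out <- tibble(chain = "A", resid = resid + seq_len(n), insert = "",
                  resname = "ALA", atom = "CA", element = "C",
                  x = pts[, 1], y = pts[, 2], z = pts[, 3],
                  het = FALSE, glycan = FALSE, parent_resid = NA_integer_)
    segs[[length(segs) + 1]] <<- tibble(segment = name, chain = "A",
                                        start = resid + 1L,
                                        end = resid + n, rigid = TRUE)
    resid <<- resid + n
    rows[[length(rows) + 1]] <<- out
    invisible(NULL)
  }
  add_linker <- function(x0) {
    n <- spec$linker_len
    start <- resid + 1L
    for (j in seq_len(n)) {
      base <- x0 + (j - 1) * 0.42
      zig <- if (j %% 2 == 0) 0.06 else -0.06
      rows[[length(rows) + 1]] <<- tibble(
        chain = "A", resid = resid + j, insert = "",
        resname = "GLY", atom = c("N", "CA", "C"), element = c("N", "C", "C"),
        x = base + c(0, 0.145, 0.295), y = dy + c(0, zig, 0),
        z = c(0, 0, 0), het = FALSE, glycan = FALSE,
        parent_resid = NA_integer_)
    }
    lnks[[length(lnks) + 1]] <<- tibble(chain = "A", start = start,
                                        end = resid + n)
    resid <<- resid + n
    x0 + n * 0.42
  }

  add_ball("CUB1", c(x_cub1, dy, 0), r_cub1, ball_atoms(r_cub1))
  add_ball("EGF", c(x_egf, dy, 0), r_egf, ball_atoms(r_egf))
  x <- x_egf + r_egf + 0.10
  for (i in seq_len(nrow(spec$arm_domains))) {
    x <- add_linker(x)
    r <- spec$arm_domains$radius_nm[i]
    add_ball(spec$arm_domains$segment[i], c(x + 0.10 + r, dy, 0), r,
             spec$arm_domains$n_atoms[i])
    x <- x + 0.10 + 2 * r + 0.10
  }
  a <- dplyr::bind_rows(rows)

  # chain B: proper 180-degree rotation about z (antiparallel partner)
  b <- a
  b$chain <- "B"
  b$x <- -b$x
  b$y <- -b$y
  atoms <- dplyr::bind_rows(a, b)

  seg_a <- dplyr::bind_rows(segs)
  seg_b <- seg_a; seg_b$chain <- "B"
  domains <- domain_map(dplyr::bind_rows(seg_a, seg_b))
  lk_a <- dplyr::bind_rows(lnks)
  lk_b <- lk_a; lk_b$chain <- "B"
  linkers <- linker_set(dplyr::bind_rows(lk_a, lk_b), domains)

  # name one surface bead per end domain ASN (glycan attachment site)
  end_seg <- tail(spec$arm_domains$segment, 1)
  for (ch in c("A", "B")) {
    dd <- domains[domains$segment == end_seg & domains$chain == ch, ]
    sel <- which(atoms$chain == ch & atoms$resid >= dd$start &
                   atoms$resid <= dd$end)
    far <- sel[which.max(atoms$x[sel]^2 + atoms$y[sel]^2 + atoms$z[sel]^2)]
    atoms$resname[far] <- "ASN"
  }

  vol <- sum(4 / 3 * pi * c(r_cub1, r_egf, spec$arm_domains$radius_nm)^3) * 2 +
    2 * spec$linker_len * nrow(spec$arm_domains) * 0.11
  mass_kDa <- vol * 602.214 / 0.73 / 1000
  model <- structure_model(atoms, mass_kDa = mass_kDa, dry_volume_nm3 = vol)
  attr(model, "vbar_mL_g") <- 0.73

  if (spec$bend_deg < 180) {
    model <- bend_toy(model, domains, linkers, end_seg, spec$bend_deg)
    if (!clash_check(model, domains, linkers)) {
      abort(paste0("infeasible toy geometry: self-clash at a bend of ",
                   spec$bend_deg, " degrees"))
    }
  }
  truth <- bend_parameters(model, domains, end_domain = end_seg,
                           core_domains = c("CUB1", "EGF"))
  structure(list(model = model, domains = domains, linkers = linkers,
                 truth = truth, spec = spec), class = "toy_dimer")
}

# bend both arms symmetrically at the first linker's mid residue until the
# measured centroid angle hits the target (monotone in the rotation angle)
bend_toy <- function(model, domains, linkers, end_seg, target_deg) {
  lk_a <- linkers[linkers$chain == "A", ][1, ]
  mid_a <- as.integer(floor((lk_a$start + lk_a$end) / 2))
  pivot_of <- function(ch, r) {
    i <- which(model$chain == ch & model$resid == r & model$atom == "CA")
    c(model$x[i], model$y[i], model$z[i])
  }
  apply_bend <- function(m, beta) {
    # both arms swing toward +z (bent inward on the same side, as the
    # best-fit solution ensembles do); theta = 180 - 2*beta up to the
    # small chain offset
    for (ch in c("A", "B")) {
      axis <- c(0, if (ch == "A") -1 else 1, 0)
      piv <- pivot_of(ch, mid_a)
      idx <- which(m$chain == ch & m$resid > mid_a)
      xyz <- rotate_about(cbind(m$x[idx], m$y[idx], m$z[idx]), piv,
                          axis, beta)
      m$x[idx] <- xyz[, 1]; m$y[idx] <- xyz[, 2]; m$z[idx] <- xyz[, 3]
    }
    m
  }
  theta_at <- function(beta) {
    bend_parameters(apply_bend(model, beta), domains, end_domain = end_seg,
                    core_domains = c("CUB1", "EGF"))$theta_deg
  }
  # bracket the root on a coarse grid first: theta falls slower than the
  # rotation angle because the pivot sits at the linker, not at the core
  grid <- seq(0, 178, by = 2)
  th <- vapply(grid, theta_at, numeric(1))
  below <- which(th <= target_deg)
  if (length(below) == 0) {
    abort(paste0("infeasible toy geometry: cannot reach a bend of ",
                 target_deg, " degrees (minimum attainable ",
                 round(min(th), 1), ")"))
  }
  hi <- grid[below[1]]
  lo <- if (below[1] > 1) grid[below[1] - 1] else 0
  root <- stats::uniroot(function(b) theta_at(b) - target_deg,
                         interval = c(lo, hi), tol = 1e-4)
  apply_bend(model, root$root)
}

#' Noise model for synthetic SAXS curves
#'
#' Relative Gaussian noise growing with Q as
#' `rel(Q) = min + (max - min) * ((Q - Qmin)/(Qmax - Qmin))^exponent`,
#' the typical error shape of a dilute-protein synchrotron SAXS curve.
#'
#' @param rel_min relative sigma at the lowest Q.
#' @param rel_max relative sigma at the highest Q.
#' @param exponent growth exponent.
#' @param concentrations concentration labels (mg/mL) of the series.
#' @param replicates replicate curves per concentration.
#' @return list of class `noise_model`.
#' @export
noise_model <- function(rel_min = 0.01, rel_max = 0.20, exponent = 1.5,
                        concentrations = 1.0, replicates = 1L) {
  if (rel_min <= 0 || rel_max <= 0) abort("noise sigmas must be positive")
  structure(list(rel_min = rel_min, rel_max = rel_max, exponent = exponent,
                 concentrations = concentrations,
                 replicates = as.integer(replicates)),
            class = "noise_model")
}

#' Default Q grid for synthetic curves
#'
#' 0.05 to 2 nm^-1, the dilute-solution SAXS range of the analyses the
#' package targets.
#'
#' @param n number of points.
#' @return numeric vector (nm^-1).
#' @export
default_q_grid <- function(n = 120) seq(0.05, 2.0, length.out = n)

#' Simulate noisy SAXS curves of a model
#'
#' Debye curve of the hydrated sphere model, scaled by concentration, with
#' Gaussian noise per the noise law.  Replicates share the mean curve;
#' everything is deterministic under the seed.
#'
#' @param model a `structure_model`.
#' @param noise a `noise_model`; `NULL` gives noise-free curves.
#' @param q_grid Q grid (nm^-1).
#' @param seed integer seed.
#' @param cube_side sphere-model cube side (nm).
#' @param i0_per_c optional per-concentration I(0)/c trend multipliers
#'   (same length as concentrations), for constructing positive controls.
#' @return list of `scattering_curve`s (one per concentration x replicate),
#'   each carrying its concentration attribute.
#' @export
simulate_saxs <- function(model, noise = noise_model(), q_grid = default_q_grid(),
                          seed = 1L, cube_side = 0.55, i0_per_c = NULL) {
  sph <- build_sphere_model(model, cube_side = cube_side, hydrate = TRUE)
  base <- debye_curve(sph, q_grid)
  if (is.null(noise)) {
    return(list(scattering_curve(q_grid, base$intensity,
                                 normalization = "I0",
                                 concentration_mg_ml = 1.0)))
  }
  tq <- (q_grid - min(q_grid)) / (max(q_grid) - min(q_grid))
  rel <- noise$rel_min + (noise$rel_max - noise$rel_min) * tq^noise$exponent
  out <- list()
  k <- 0L
  for (ci in seq_along(noise$concentrations)) {
    cc <- noise$concentrations[ci]
    scale <- cc * (if (is.null(i0_per_c)) 1 else i0_per_c[ci])
    for (rep in seq_len(noise$replicates)) {
      k <- k + 1L
      set.seed(derive_seed(seed, k))
      mu <- base$intensity * scale
      sig <- pmax(mu * rel, 1e-12)
      out[[k]] <- scattering_curve(q_grid, mu + rnorm(length(mu), 0, sig),
                                   sigma = sig,
                                   concentration_mg_ml = cc)
    }
  }
  out
}

#' End-to-end parameter-recovery experiment
#'
#' Simulates a noisy SAXS target from a bent ground-truth dimer, runs the
#' Monte-Carlo search from the straight (180 degree) start, selects the
#' best-fit ensemble and compares recovered bend geometry, R factors and
#' predicted sedimentation coefficients against truth.
#'
#' @param spec a `toy_dimer_spec` (its `bend_deg` is the ground truth).
#' @param noise a `noise_model`.
#' @param n_trials accepted trials for the search.
#' @param seed master seed.
#' @param config passed to [run_search()].
#' @param n_best best-fit ensemble size.
#' @return list of class `recovery_report`: `geometry` (truth vs recovered
#'   theta/d), `fit` (start vs best R factors), `s20w` (truth, start, best
#'   mean), `search` (the `search_result`), `best` (the `best_set`).
#' @export
recovery_experiment <- function(spec, noise = noise_model(), n_trials = 500,
                                seed = 1L, config = list(), n_best = 10) {
  truth <- make_toy_dimer(spec)
  end_seg <- tail(truth$spec$arm_domains$segment, 1)
  target <- simulate_saxs(truth$model, noise, seed = derive_seed(seed, 1))[[1]]

  start_spec <- spec
  start_spec$bend_deg <- 180
  start <- make_toy_dimer(start_spec)

  vdry <- dry_volume(start$model)
  sph_start <- build_sphere_model(start$model, hydrate = TRUE,
                                  target_dry_volume_nm3 = vdry)
  r_start <- r_factor(target, debye_curve(sph_start, target$q))$r_factor

  search <- run_search(start$model, start$linkers, target,
                       n_trials = n_trials, seed = derive_seed(seed, 2),
                       domains = start$domains, config = config)
  best <- select_best(search, n_best)
  geom <- purrr::map_dfr(best$model, function(m) {
    bend_parameters(m, start$domains, end_domain = end_seg,
                    core_domains = c("CUB1", "EGF"))
  })

  s_truth <- predict_s20w(truth$model)$s20w_S
  s_start <- predict_s20w(start$model)$s20w_S
  s_best <- vapply(best$model, function(m) predict_s20w(m)$s20w_S, numeric(1))

  structure(list(
    geometry = tibble(
      theta_true_deg = truth$truth$theta_deg,
      d_true_nm = truth$truth$d_nm,
      theta_recovered_deg = mean(geom$theta_deg),
      theta_recovered_sd = sd(geom$theta_deg),
      d_recovered_nm = mean(geom$d_nm),
      d_recovered_sd = sd(geom$d_nm)),
    fit = tibble(r_factor_start = r_start,
                 r_factor_best = min(best$r_factor),
                 improvement = 1 - min(best$r_factor) / r_start),
    s20w = tibble(s_truth_S = s_truth, s_start_S = s_start,
                  s_best_mean_S = mean(s_best), s_best_sd_S = sd(s_best)),
    search = search, best = best, target = target,
    truth_model = truth, start_model = start
  ), class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat("Recovery experiment\n")
  cat(sprintf("  theta: truth %.1f deg -> recovered %.1f +/- %.1f deg\n",
              x$geometry$theta_true_deg, x$geometry$theta_recovered_deg,
              x$geometry$theta_recovered_sd))
  cat(sprintf("  R factor: start %.2f%% -> best %.2f%%\n",
              x$fit$r_factor_start, x$fit$r_factor_best))
  cat(sprintf("  s20,w: truth %.3f S, start %.3f S, best %.3f S\n",
              x$s20w$s_truth_S, x$s20w$s_start_S, x$s20w$s_best_mean_S))
  invisible(x)
}
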