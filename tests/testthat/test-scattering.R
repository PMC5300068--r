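test_that("a single sphere reproduces the analytic form factor and its first zero", {
  q <- seq(0.1, 6, by = 0.001)
  one <- as_spheres(matrix(0, 1, 3), radius = 1.0)
  cv <- debye_curve(one, q)
  x <- q * 1.0
  expect_equal(cv$intensity, (3 * (sin(x) - x * cos(x)) / x^3)^2,
               tolerance = 1e-12)
  # first zero of the amplitude solves tan x = x; locate it numerically
  x0 <- uniroot(function(x) sin(x) - x * cos(x), c(4, 5), tol = 1e-10)$root
  expect_equal(x0, 4.4934, tolerance = 1e-4)
  expect_equal(cv$q[which.min(cv$intensity[q < 5])], x0, tolerance = 1e-3)
})

test_that("Debye curves are normalized to I(0) = 1 and decay in the Guinier region", {
  set.seed(3)
  xyz <- matrix(rnorm(150, sd = 2), ncol = 3)
  sph <- as_spheres(xyz, radius = 0.3)
  cv <- debye_curve(sph, c(1e-4, seq(0.02, 0.6, by = 0.02)))
  expect_equal(cv$intensity[1], 1, tolerance = 1e-6)
  expect_true(all(diff(cv$intensity[cv$q < 0.3]) < 0))
})

test_that("binned Debye sums match the explicit double sum within 0.1%", {
  set.seed(7)
  xyz <- matrix(runif(150, 0, 6), ncol = 3)
  q <- seq(0.05, 2, by = 0.05)
  sph <- as_spheres(xyz, radius = 0.28)
  binned <- debye_curve(sph, q, bin_width_nm = 0.01)
  direct <- debye_direct(xyz, q, 0.28)
  expect_lt(max(abs(binned$intensity / direct - 1)), 0.001)
  # bin width 0 is the exact sum
  exact <- debye_curve(sph, q, bin_width_nm = 0)
  expect_equal(exact$intensity, direct, tolerance = 1e-10)
})

test_that("Guinier fit is exact on a Gaussian curve and tight on a ball", {
  q <- seq(0.01, 0.5, by = 0.01)
  gf <- guinier_fit(scattering_curve(q, exp(-q^2 * 9 / 3)))
  expect_equal(gf$rg_nm, 3, tolerance = 1e-9)
  expect_equal(gf$i0, 1, tolerance = 1e-9)

  ball <- ball_model(20000, 3, seed = 1)
  sph <- build_sphere_model(ball, cube_side = 0.45, hydrate = FALSE)
  cv <- debye_curve(sph, seq(0.02, 2, by = 0.02))
  # near-Gaussian window: the Guinier approximation for a uniform sphere
  # carries ~2% truncation bias already at Q.Rg = 1.3
  gf <- guinier_fit(cv, qrg_limit = 0.8)
  expect_rel(gf$rg_nm, sqrt(3 / 5) * 3, 0.02)
  expect_true(gf$qrg_range[2] <= 0.8 + 1e-9)
  expect_gte(gf$n_points, 5)
})

test_that("Guinier errors are raised for non-decaying curves and short windows", {
  q <- seq(0.01, 0.5, by = 0.01)
  expect_error(guinier_fit(scattering_curve(q, exp(q^2))), "positive")
  expect_error(guinier_fit(scattering_curve(q[1:3], exp(-q[1:3]^2 * 3))),
               "few points")
})

test_that("replicate Guinier fits summarize in mean +/- sd table style", {
  q <- seq(0.02, 1, by = 0.01)
  mu <- exp(-q^2 * 3.8^2 / 3)
  set.seed(5)
  fits <- lapply(1:8, function(i) {
    guinier_fit(scattering_curve(q, mu * (1 + rnorm(length(q), 0, 0.01))))
  })
  sm <- summarize_guinier(fits)
  expect_equal(sm$mean_rg_nm, 3.8, tolerance = 0.02)
  expect_match(sm$label, "^3\\.[78][0-9] ± 0\\.[0-9][0-9]$")
})

test_that("cross-sectional fit recovers the cylinder radius and vanishes for flat regions", {
  # ideal infinite cylinder: I(Q) = exp(-Q^2 a^2 / 4) / Q  =>  Rxs = a/sqrt(2)
  q <- seq(0.2, 2, by = 0.01)
  a <- 1.2
  cs <- cross_section_fit(scattering_curve(q, exp(-q^2 * a^2 / 4) / q),
                          c(0.3, 1.0))
  expect_rel(cs$rxs_nm, a / sqrt(2), 0.03)
  # flat I*Q: no cross-sectional decay
  flat <- cross_section_fit(scattering_curve(q, 5 / q), c(0.3, 1.0))
  expect_equal(flat$rxs_nm, 0)
  expect_error(cross_section_fit(scattering_curve(q, exp(q^2 / 4) / q),
                                 c(0.3, 1.0)), "positive")
})

test_that("rod-like models obey Rg^2 - Rxs^2 = L^2/12 within 5%", {
  set.seed(2)
  n <- 12000
  cyl <- cbind(runif(n, -0.5, 0.5), runif(n, -0.5, 0.5), runif(n, 0, 12))
  cyl <- cyl[cyl[, 1]^2 + cyl[, 2]^2 <= 0.25, ]
  cv <- debye_curve(as_spheres(cyl), seq(0.02, 3, by = 0.01))
  # rods need a conservative Guinier window and a Q window past 1/L for Rxs
  rg <- guinier_fit(cv, qrg_limit = 0.6)$rg_nm
  rxs <- cross_section_fit(cv, c(1.2, 2.4))$rxs_nm
  expect_rel(rg^2 - rxs^2, 12^2 / 12, 0.05)
})

test_that("P(r) of a ball matches the closed form and its moments return Rg", {
  ball <- ball_model(3000, 3, seed = 4)
  pts <- as_spheres(cbind(ball$x, ball$y, ball$z))
  pr <- pr_from_model(pts, bin_width_nm = 0.15)
  expect_equal(attr(pr, "L_nm"), 6, tolerance = 0.15)
  expect_true(all(pr$p >= 0))
  # closed-form ball distance density, averaged over each bin
  expected <- ball_pr(pr$r, 3)
  expect_lt(max(abs(pr$p - expected)), 0.05 * max(expected))
  # moment identity: Rg from P(r) equals coordinate Rg within 1%
  rg_coord <- sqrt(mean(rowSums(sweep(cbind(ball$x, ball$y, ball$z), 2,
                                      colMeans(cbind(ball$x, ball$y,
                                                     ball$z)))^2)))
  expect_rel(attr(pr, "rg_nm"), rg_coord, 0.01)
})

test_that("a dumbbell gives an intra-ball peak and a separation peak", {
  b1 <- ball_model(500, 1, seed = 5)
  b2 <- ball_model(500, 1, seed = 6, center = c(6, 0, 0))
  xyz <- rbind(cbind(b1$x, b1$y, b1$z), cbind(b2$x, b2$y, b2$z))
  pr <- pr_from_model(as_spheres(xyz), bin_width_nm = 0.2)
  pk <- attr(pr, "peaks_nm")
  expect_gte(length(pk), 2)
  expect_true(any(abs(pk - 6) < 0.5))       # center-center separation
  expect_true(any(pk < 2.5))                # intra-ball distances
})

test_that("indirect transform round-trips a ball curve and is alpha-monotone", {
  ball <- ball_model(20000, 3, seed = 1)
  sph <- build_sphere_model(ball, cube_side = 0.3, hydrate = FALSE)
  cv <- debye_curve(sph, seq(0.05, 2, by = 0.02))
  pr <- pr_from_curve(cv, dmax = 6.5)
  expect_rel(attr(pr, "rg_nm"), sqrt(3 / 5) * 3, 0.02)
  expect_true(all(pr$p >= 0))
  expect_equal(attr(pr, "L_nm"), 6, tolerance = 0.4)
  chis <- vapply(c(1e-3, 1e-2, 1e-1, 1), function(a) {
    attr(pr_from_curve(cv, 6.5, alpha = a), "chisq")
  }, numeric(1))
  expect_true(all(diff(chis) >= 0))
  expect_error(pr_from_curve(cv, dmax = 1), "underdetermined")
})

test_that("model and curve P(r) agree on peak positions for noise-free round trips", {
  b1 <- ball_model(400, 1, seed = 8)
  b2 <- ball_model(400, 1, seed = 9, center = c(5, 0, 0))
  xyz <- rbind(cbind(b1$x, b1$y, b1$z), cbind(b2$x, b2$y, b2$z))
  sph <- as_spheres(xyz)
  cv <- debye_curve(sph, seq(0.05, 3, by = 0.02))
  bw <- 0.25
  pr_m <- pr_from_model(sph, bin_width_nm = bw)
  pr_c <- pr_from_curve(cv, dmax = 7.5, n_points = 29)  # ~0.25 nm nodes
  pk_m <- attr(pr_m, "peaks_nm")
  pk_c <- attr(pr_c, "peaks_nm")
  sep_m <- pk_m[which.min(abs(pk_m - 5))]
  sep_c <- pk_c[which.min(abs(pk_c - 5))]
  expect_lt(abs(sep_m - sep_c), bw + 1e-9)
})

test_that("the R factor is zero under scaling and ranks look-alikes first", {
  ball <- ball_model(2000, 3, seed = 1)
  cv <- debye_curve(as_spheres(cbind(ball$x, ball$y, ball$z), 0.2),
                    seq(0.05, 2, by = 0.02))
  fs <- r_factor(cv, cv)
  expect_equal(fs$r_factor, 0, tolerance = 1e-4)
  expect_equal(fs$eta, 1, tolerance = 1e-4)
  # doubled calculated curve: eta absorbs the scale exactly
  cv2 <- scattering_curve(cv$q, 2 * cv$intensity)
  fs2 <- r_factor(cv, cv2)
  expect_equal(fs2$r_factor, 0, tolerance = 1e-4)
  expect_equal(fs2$eta, 0.5, tolerance = 1e-3)
  # a same-shape ball fits the ball target better than a rod does
  ball_b <- ball_model(2000, 3, seed = 12)
  rod <- cbind(seq(0, 12, length.out = 300), 0, 0)
  r_ball <- r_factor(cv, debye_curve(as_spheres(cbind(ball_b$x, ball_b$y,
                                                      ball_b$z), 0.2),
                                     cv$q))$r_factor
  r_rod <- r_factor(cv, debye_curve(as_spheres(rod, 0.2), cv$q))$r_factor
  expect_lt(r_ball, r_rod)
  expect_error(r_factor(cv, scattering_curve(cv$q + 10, cv$intensity)),
               "overlap")
})

test_that("concentration series flag trips on trends and stays clear on flat series", {
  q <- seq(0.02, 1, by = 0.01)
  mu <- exp(-q^2 * 3.8^2 / 3)
  mk <- function(scale, conc) {
    scattering_curve(q, mu * scale, concentration_mg_ml = conc)
  }
  flat <- concentration_series_check(list(mk(0.25, 0.25), mk(0.7, 0.7),
                                          mk(1.26, 1.26)))
  expect_false(flat$flag)
  expect_true(all(abs(flat$trends$slope) < 1e-9))
  # I(0)/c rising 20% across the series
  rising <- concentration_series_check(list(mk(0.25, 0.25),
                                            mk(0.7 * 1.1, 0.7),
                                            mk(1.26 * 1.2, 1.26)))
  expect_true(rising$flag)
  expect_error(concentration_series_check(list(
    scattering_curve(q, mu), scattering_curve(q, mu))), "concentration")
})

test_that("curve text I/O round-trips, including Angstrom units", {
  q <- seq(0.05, 1, by = 0.05)
  cv <- scattering_curve(q, exp(-q^2), sigma = rep(0.01, length(q)))
  path <- tempfile(fileext = ".dat")
  write_curve(cv, path)
  cv2 <- read_curve(path)
  expect_equal(cv2$q, cv$q, tolerance = 1e-8)
  expect_equal(cv2$intensity, cv$intensity, tolerance = 1e-8)
  expect_equal(cv2$sigma, cv$sigma, tolerance = 1e-8)
  write_curve(cv, path, unit = "A^-1")
  cv3 <- read_curve(path, unit = "A^-1")
  expect_equal(cv3$q, cv$q, tolerance = 1e-8)
})
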