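# small, fast toy used throughout this file
small_toy <- function(bend = 180, seed = 1) {
  make_toy_dimer(toy_dimer_spec(
    arm_domains = tibble::tibble(segment = "CUB2", radius_nm = 1.2,
                                 n_atoms = 60L),
    core_radii = c(CUB1 = 1.2, EGF = 0.9), bend_deg = bend, seed = seed))
}

test_that("an empty linker set leaves the model untouched", {
  toy <- small_toy()
  empty <- linker_set(tibble::tibble(chain = character(), start = integer(),
                                     end = integer()))
  expect_identical(perturb_linkers(toy$model, empty, seed = 1), toy$model)
})

test_that("perturbation is bit-reproducible under a fixed seed and varies across seeds", {
  toy <- small_toy()
  m1 <- perturb_linkers(toy$model, toy$linkers, seed = 99)
  m2 <- perturb_linkers(toy$model, toy$linkers, seed = 99)
  expect_identical(m1$x, m2$x)
  expect_identical(m1$z, m2$z)
  m3 <- perturb_linkers(toy$model, toy$linkers, seed = 100)
  expect_false(identical(m1$x, m3$x))
  # zero-step bounded mode reproduces the input coordinates
  m0 <- perturb_linkers(toy$model, toy$linkers, step = 0, seed = 1,
                        mode = "step")
  expect_equal(m0$x, toy$model$x, tolerance = 1e-12)
})

test_that("every rigid segment survives perturbation as a rigid body", {
  toy <- small_toy()
  for (seed in 1:5) {
    m <- perturb_linkers(toy$model, toy$linkers, seed = seed)
    for (i in seq_len(nrow(toy$domains))) {
      dd <- toy$domains[i, ]
      sel <- toy$model$chain == dd$chain & toy$model$resid >= dd$start &
        toy$model$resid <= dd$end
      P <- cbind(m$x[sel], m$y[sel], m$z[sel])
      Q <- cbind(toy$model$x[sel], toy$model$y[sel], toy$model$z[sel])
      # optimal superposition of the moved segment onto the original
      cp <- colMeans(P); cq <- colMeans(Q)
      H <- crossprod(sweep(P, 2, cp), sweep(Q, 2, cq))
      sv <- svd(H)
      R <- sv$v %*% diag(c(1, 1, sign(det(sv$v %*% t(sv$u))))) %*% t(sv$u)
      dev <- sweep(sweep(P, 2, cp) %*% t(R), 2, cq, `+`) - Q
      expect_lt(sqrt(mean(rowSums(dev^2))), 1e-6)
    }
  }
})

test_that("repeated perturbation of a two-domain toy spans well over 90 degrees of flex", {
  toy <- small_toy()
  cur <- toy$model
  th <- numeric(400)
  for (k in seq_len(400)) {
    cur <- perturb_linkers(cur, toy$linkers, seed = k)
    th[k] <- bend_parameters(cur, toy$domains)$theta_deg
  }
  expect_gt(diff(range(th)), 90)
})

test_that("glycan stubs ride rigidly with their attachment domain", {
  toy <- small_toy()
  asn <- toy$model[toy$model$resname == "ASN", ]
  g <- attach_glycans(toy$model, list(glycan_stub("A", asn$resid[asn$chain == "A"][1],
                                                  n_units = 5)), seed = 2)
  m <- perturb_linkers(g, toy$linkers, seed = 7)
  # distance from each glycan bead to its attachment residue is invariant
  for (who in list(g)) NULL
  anchor0 <- g[g$chain == "A" & g$resid == g$parent_resid[g$glycan][1] &
                 !g$glycan, ]
  anchor1 <- m[m$chain == "A" & m$resid == m$parent_resid[m$glycan][1] &
                 !m$glycan, ]
  d0 <- sqrt((g$x[g$glycan] - anchor0$x[1])^2 +
               (g$y[g$glycan] - anchor0$y[1])^2 +
               (g$z[g$glycan] - anchor0$z[1])^2)
  d1 <- sqrt((m$x[m$glycan] - anchor1$x[1])^2 +
               (m$y[m$glycan] - anchor1$y[1])^2 +
               (m$z[m$glycan] - anchor1$z[1])^2)
  expect_equal(d1, d0, tolerance = 1e-9)
})

test_that("the blocked clash predicate equals the brute-force all-pairs check", {
  toy <- small_toy()
  cur <- toy$model
  n_checked <- 0
  for (k in 1:500) {
    cur <- perturb_linkers(cur, toy$linkers, seed = 1000 + k)
    got <- clash_check(cur, toy$domains, toy$linkers)
    want <- clash_brute(cur, toy$domains, toy$linkers)
    expect_identical(got, want)
    n_checked <- n_checked + 1
    if (!want) cur <- toy$model  # restart the walk after a clash
  }
  expect_equal(n_checked, 500)
})

test_that("trivial clash geometries behave as expected", {
  toy <- small_toy()
  expect_true(clash_check(toy$model, toy$domains, toy$linkers))
  # duplicate one CUB2 on top of the other chain's CUB2
  m <- toy$model
  dd <- toy$domains[toy$domains$segment == "CUB2", ]
  selA <- m$chain == "A" & m$resid >= dd$start[dd$chain == "A"] &
    m$resid <= dd$end[dd$chain == "A"]
  selB <- m$chain == "B" & m$resid >= dd$start[dd$chain == "B"] &
    m$resid <= dd$end[dd$chain == "B"]
  m$x[selB] <- m$x[selA]; m$y[selB] <- m$y[selA]; m$z[selB] <- m$z[selA]
  expect_false(clash_check(m, toy$domains, toy$linkers))
})

test_that("a zero-step one-trial search returns the start structure's own score", {
  toy <- small_toy(bend = 150)
  target <- simulate_saxs(toy$model, noise_model(), seed = 3)[[1]]
  start <- small_toy(bend = 180)
  sr <- run_search(start$model, start$linkers, target, n_trials = 1,
                   seed = 5, domains = start$domains,
                   config = list(mode = "step", step = 0))
  vdry <- dry_volume(start$model)
  own <- r_factor(target, debye_curve(
    build_sphere_model(start$model, target_dry_volume_nm3 = vdry),
    target$q))$r_factor
  expect_equal(sr$trials$r_factor[sr$trials$accepted], own,
               tolerance = 1e-10)
})

test_that("select_best orders by R factor with Rg and trial-index tie-breaks", {
  fake <- structure(list(
    trials = tibble::tibble(trial = 1:4, accepted = TRUE,
                            rg_nm = c(3.0, 3.4, 3.2, 3.9),
                            r_factor = c(5, 2, 2, 7)),
    models = list(list(trial = 1, r = 5, rg = 3.0, model = "m1"),
                  list(trial = 2, r = 2, rg = 3.4, model = "m2"),
                  list(trial = 3, r = 2, rg = 3.2, model = "m3"),
                  list(trial = 4, r = 7, rg = 3.9, model = "m4")),
    target_rg_nm = 3.25,
    meta = list(seed = 1)), class = "search_result")
  bs <- select_best(fake, 3)
  # ties at R = 2 break toward the model whose Rg is nearer the target fit
  expect_equal(bs$trial, c(3, 2, 1))
  expect_warning(select_best(fake, 10), "only 4")
})

test_that("a short search against a bent target improves on the straight start", {
  start <- small_toy(bend = 180)
  truth <- small_toy(bend = 120)
  target <- simulate_saxs(truth$model, noise_model(), seed = 21)[[1]]
  sr <- run_search(start$model, start$linkers, target, n_trials = 250,
                   seed = 8, domains = start$domains,
                   config = list(bend = list(end_domain = "CUB2",
                                             core_domains = c("CUB1", "EGF"))))
  vdry <- dry_volume(start$model)
  r_start <- r_factor(target, debye_curve(
    build_sphere_model(start$model, target_dry_volume_nm3 = vdry),
    target$q))$r_factor
  bs <- select_best(sr, 10)
  expect_lt(min(bs$r_factor), r_start)
  expect_equal(nrow(bs), 10)
  expect_true(all(diff(bs$r_factor) >= 0))
  # recorded bend angles exist for accepted trials
  acc <- sr$trials[sr$trials$accepted, ]
  expect_true(all(is.finite(acc$theta_deg)))

  # restarting from a best-fit model (Search 2) keeps the fit quality
  sr2 <- run_search(bs$model[[1]], start$linkers, target, n_trials = 120,
                    seed = 9, domains = start$domains)
  best2 <- min(select_best(sr2, 10)$r_factor)
  expect_lt(best2, r_start)
  expect_lt(abs(best2 - min(bs$r_factor)), 0.5 * r_start)
})

test_that("searches abort when the acceptance rate collapses", {
  toy <- small_toy()
  # impossible clash cutoff: every proposal is rejected
  target <- simulate_saxs(toy$model, noise_model(), seed = 3)[[1]]
  expect_error(
    run_search(toy$model, toy$linkers, target, n_trials = 5, seed = 1,
               domains = toy$domains,
               config = list(clash_cutoff = 5, floor_window = 100L)),
    "acceptance rate")
})

test_that("rotation at a chain terminus without downstream atoms is rejected", {
  chain <- structure_model(tibble::tibble(
    chain = "A", resid = rep(1:3, each = 3),
    resname = "GLY", atom = rep(c("N", "CA", "C"), 3),
    element = rep(c("N", "C", "C"), 3),
    x = seq(0, 0.8, length.out = 9), y = rep(c(0, 0.05, 0), 3), z = 0))
  m <- chain
  m <- m[!(m$resid == 3 & m$atom == "C"), ]  # drop the terminal C
  lk <- linker_set(tibble::tibble(chain = "A", start = 3, end = 3))
  expect_error(perturb_linkers(structure_model(m), lk, seed = 1),
               "terminus")
})
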