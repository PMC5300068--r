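# Shared fixtures and independent brute-force oracles.
# Oracles here are deliberately written from scratch (plain loops/closed
# forms) so they stay independent of the package implementations they
# check.

# uniform pseudo-atom ball as a structure model
ball_model <- function(n, R, seed = 1, center = c(0, 0, 0)) {
  set.seed(seed)
  pts <- matrix(numeric(0), 0, 3)
  while (nrow(pts) < n) {
    cand <- matrix(runif(3 * 2 * n, -R, R), ncol = 3)
    pts <- rbind(pts, cand[rowSums(cand^2) <= R^2, , drop = FALSE])
  }
  pts <- sweep(pts[seq_len(n), , drop = FALSE], 2, center, `+`)
  structure_model(
    tibble::tibble(chain = "A", resid = seq_len(n), resname = "ALA",
                   atom = "CA", x = pts[, 1], y = pts[, 2], z = pts[, 3]),
    dry_volume_nm3 = 4 / 3 * pi * R^3)
}

# raw x/y/z tibble tagged as a sphere model with a given common radius
as_spheres <- function(xyz, radius = 0) {
  out <- tibble::tibble(x = xyz[, 1], y = xyz[, 2], z = xyz[, 3])
  out <- tibble::new_tibble(out, class = "sphere_model")
  attr(out, "radius_nm") <- radius
  out
}

# Debye double sum, coded directly from the formula (no binning)
debye_direct <- function(xyz, q, radius) {
  n <- nrow(xyz)
  x <- q * radius
  g <- if (radius > 0) (3 * (sin(x) - x * cos(x)) / x^3)^2 else rep(1, length(q))
  s <- numeric(length(q))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      rij <- sqrt(sum((xyz[i, ] - xyz[j, ])^2))
      s <- s + sin(q * rij) / (q * rij)
    }
  }
  g * (1 / n + (2 / n^2) * s)
}

# closed-form pair-distance density of a uniform ball of radius R
ball_pr <- function(r, R) {
  s <- r / R
  p <- 3 * s^2 / R * (1 - 3 * s / 4 + s^3 / 16)
  p[r < 0 | r > 2 * R] <- 0
  p
}

# all-pairs clash predicate over rigid units (independent of the package's
# blocked implementation)
clash_brute <- function(model, domains, linkers, cutoff = 0.25) {
  unit <- rigid_units(model, domains, linkers)
  sel <- which(!is.na(unit) & model$element != "H")
  xyz <- cbind(model$x, model$y, model$z)[sel, , drop = FALSE]
  u <- unit[sel]; ch <- model$chain[sel]; rs <- model$resid[sel]
  n <- length(sel)
  d <- as.matrix(stats::dist(xyz))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (u[i] == u[j]) next
      if (ch[i] == ch[j] && abs(rs[i] - rs[j]) <= 2) next
      if (d[i, j] < cutoff) return(FALSE)
    }
  }
  TRUE
}

# Kirkwood friction coded independently (loop form)
kirkwood_s20w <- function(xyz_nm, a_nm, mass_Da, vbar) {
  eta <- 1.002e-3; rho <- 0.99823; NA_ <- 6.02214076e23
  n <- nrow(xyz_nm)
  a <- a_nm * 1e-9
  f1 <- 6 * pi * eta * a
  S <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    rij <- sqrt(sum((xyz_nm[i, ] - xyz_nm[j, ])^2)) * 1e-9
    S <- S + 1 / max(rij, a)
  }
  f <- n * f1 / (1 + (f1 / (6 * pi * eta * n)) * S)
  (mass_Da / 1000) * (1 - vbar * rho) / (NA_ * f) / 1e-13
}

# PDB ATOM/HETATM line with correct fixed columns
pdb_line <- function(serial, name, alt, resn, chain, resno, x, y, z,
                     occ = 1, rec = "ATOM", elem = substr(name, 1, 1)) {
  sprintf("%-6s%5d %-4s%1s%-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          rec, serial, name, alt, resn, chain, resno, x, y, z, occ, 0, elem)
}

# three-residue two-chain PDB text (coordinates in Angstrom)
tiny_pdb <- function(path) {
  lines <- c(
    pdb_line(1, "N", " ", "GLY", "A", 1, 0.0, 0.0, 0.0),
    pdb_line(2, "CA", " ", "GLY", "A", 1, 1.45, 0.0, 0.0, elem = "C"),
    pdb_line(3, "C", " ", "GLY", "A", 1, 2.0, 1.4, 0.0),
    pdb_line(4, "N", " ", "ALA", "A", 2, 3.3, 1.5, 0.1),
    pdb_line(5, "CA", " ", "ALA", "A", 2, 4.2, 2.6, 0.2, elem = "C"),
    pdb_line(6, "CB", " ", "ALA", "A", 2, 4.1, 3.6, 1.3),
    pdb_line(7, "CA", " ", "SER", "B", 1, 8.0, 0.0, 3.0, elem = "C"),
    "TER",
    pdb_line(8, "CA", " ", "CA", "B", 90, 10.0, 2.0, 3.0, rec = "HETATM",
             elem = "CA"),
    "END")
  writeLines(lines, path)
  path
}

expect_rel <- function(actual, expected, tol) {
  expect_lt(abs(actual / expected - 1), tol)
}
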