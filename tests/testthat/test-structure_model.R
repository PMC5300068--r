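test_that("PDB reading partitions chains, keeps hetero ions and converts to nm", {
  path <- tiny_pdb(tempfile(fileext = ".pdb"))
  m <- read_structure(path)
  prot <- m[!m$het, ]
  expect_equal(sort(unique(prot$chain)), c("A", "B"))
  nres <- nrow(dplyr::distinct(tibble::as_tibble(prot)[, c("chain", "resid")]))
  expect_equal(nres, 3)
  expect_equal(m$x[m$atom == "CA" & m$chain == "A" & m$resid == 1], 0.145)
  ca_ion <- m[m$het, ]
  expect_equal(nrow(ca_ion), 1)
  expect_equal(ca_ion$element, "CA")
})

test_that("write/read round trip preserves atoms, order and coordinates", {
  path <- tiny_pdb(tempfile(fileext = ".pdb"))
  m <- read_structure(path)
  out <- tempfile(fileext = ".pdb")
  write_structure(m, out)
  m2 <- read_structure(out)
  expect_equal(nrow(m2), nrow(m))
  expect_equal(m2$atom, m$atom)
  expect_equal(m2$resid, m$resid)
  # coordinates identical to 1e-4 nm (PDB stores 3 decimals in Angstrom)
  expect_lt(max(abs(m2$x - m$x), abs(m2$y - m$y), abs(m2$z - m$z)), 1e-4)
})

test_that("altloc resolution keeps the highest-occupancy conformer", {
  path <- tempfile(fileext = ".pdb")
  writeLines(c(
    pdb_line(1, "CA", "A", "GLY", "A", 1, 0, 0, 0, occ = 0.4, elem = "C"),
    pdb_line(2, "CA", "B", "GLY", "A", 1, 5, 0, 0, occ = 0.6, elem = "C"),
    pdb_line(3, "CA", " ", "GLY", "A", 2, 9, 0, 0, elem = "C"),
    "END"), path)
  m <- read_structure(path)
  expect_equal(nrow(m), 2)
  expect_equal(m$x[m$resid == 1], 0.5)  # conformer B, in nm
})

test_that("degenerate PDB input is rejected with a parse error", {
  path <- tempfile(fileext = ".pdb")
  writeLines(c(
    pdb_line(1, "CA", " ", "GLY", "A", 1, 0, 0, 0, elem = "C"),
    pdb_line(2, "CA", " ", "GLY", "A", 1, 1, 0, 0, elem = "C"),
    "END"), path)
  expect_error(read_structure(path), "duplicate atom")
  expect_error(read_structure(tempfile()), "cannot read")
  empty <- tempfile(fileext = ".pdb")
  writeLines("END", empty)
  expect_error(read_structure(empty), ".")
})

test_that("domain maps refuse overlapping segments and linkers inside rigid ranges", {
  expect_error(domain_map(tibble::tibble(
    segment = c("D1", "D2"), chain = "A", start = c(1, 40), end = c(50, 80))),
    "overlapping")
  dm <- domain_map(tibble::tibble(segment = c("D1", "D2"), chain = "A",
                                  start = c(1, 60), end = c(50, 80)))
  expect_error(linker_set(tibble::tibble(chain = "A", start = 45, end = 55), dm),
               "overlaps rigid")
  expect_s3_class(linker_set(tibble::tibble(chain = "A", start = 51,
                                            end = 59), dm), "linker_set")
})

test_that("glycan attachment conserves volume/mass bookkeeping and leaves protein atoms alone", {
  toy <- make_toy_dimer(toy_registry("masp3d-like"))
  expect_identical(attach_glycans(toy$model, list()), toy$model)

  asn <- toy$model[toy$model$resname == "ASN" & toy$model$chain == "A", ]
  stub <- glycan_stub("A", asn$resid[1], n_units = 11)
  g <- attach_glycans(toy$model, list(stub), seed = 5)
  expect_equal(nrow(g), nrow(toy$model) + 11)
  expect_equal(sum(g$glycan), 11)
  expect_equal(attr(g, "dry_volume_nm3"),
               attr(toy$model, "dry_volume_nm3") + 11 * stub$unit_volume_nm3)
  expect_equal(attr(g, "mass_kDa"),
               attr(toy$model, "mass_kDa") + 11 * stub$unit_mass_Da / 1000)
  # pre-existing coordinates untouched
  expect_identical(g$x[seq_len(nrow(toy$model))], toy$model$x)
  # clash-free against the protein surface
  prot <- g[!g$glycan, ]
  gl <- g[g$glycan, ]
  dmin <- min(as.matrix(stats::dist(rbind(cbind(gl$x, gl$y, gl$z),
                                          cbind(prot$x, prot$y, prot$z))))[
    seq_len(nrow(gl)), nrow(gl) + seq_len(nrow(prot))])
  expect_gt(dmin, 0.25)
  # deterministic under seed
  g2 <- attach_glycans(toy$model, list(stub), seed = 5)
  expect_identical(g$x, g2$x)
  expect_error(attach_glycans(toy$model, list(glycan_stub("A", 999999L))),
               "missing")
})

test_that("sphere model of an ideal ball reproduces sqrt(3/5) R within 2%", {
  ball <- ball_model(20000, 3, seed = 1)
  sph <- build_sphere_model(ball, cube_side = 0.3, hydrate = FALSE)
  expect_rel(sphere_model_rg(sph), sqrt(3 / 5) * 3, 0.02)
})

test_that("sphere-model volume bookkeeping is conserved on every build", {
  for (nm in c("masp3d-like", "fulllength-like")) {
    toy <- make_toy_dimer(toy_registry(nm))
    vdry <- attr(toy$model, "dry_volume_nm3")
    mass <- attr(toy$model, "mass_kDa") * 1000
    dry <- build_sphere_model(toy$model, hydrate = FALSE)
    r <- attr(dry, "radius_nm")
    expect_rel(nrow(dry) * 4 / 3 * pi * r^3, vdry, 1e-6)

    wet <- build_sphere_model(toy$model, hydrate = TRUE)
    rw <- attr(wet, "radius_nm")
    target_wet <- vdry + 0.3 * mass / 602.214
    expect_rel(nrow(wet) * 4 / 3 * pi * rw^3, target_wet, 1e-6)
    expect_equal(attr(wet, "hydrated_volume_nm3"), target_wet)
    expect_gte(nrow(wet), nrow(dry))
    expect_equal(sum(!wet$hydration), nrow(dry))
  }
})

test_that("grid binning matches an independent brute-force cube count", {
  set.seed(42)
  coil <- structure_model(tibble::tibble(
    chain = "A", resid = 1:100, resname = "ALA", atom = "CA",
    x = cumsum(rnorm(100, 0, 0.3)), y = cumsum(rnorm(100, 0, 0.3)),
    z = cumsum(rnorm(100, 0, 0.3))))
  cube <- 0.55
  xyz <- cbind(coil$x, coil$y, coil$z)
  org <- apply(xyz, 2, min) - cube / 2
  key <- apply(floor(sweep(xyz, 2, org) / cube), 1, paste, collapse = "/")
  n_expected <- length(unique(key))
  sph <- build_sphere_model(coil, cube_side = cube, atom_cutoff = 1,
                            hydrate = FALSE,
                            target_dry_volume_nm3 = n_expected * cube^3)
  expect_equal(nrow(sph), n_expected)
})

test_that("coarse-graining preserves the radius of gyration within 3%", {
  # coarse-bead toy at the default grid scale
  toy <- make_toy_dimer(toy_registry("masp3d-like"))
  rg_atoms <- sqrt(mean(rowSums(
    sweep(cbind(toy$model$x, toy$model$y, toy$model$z), 2,
          colMeans(cbind(toy$model$x, toy$model$y, toy$model$z)))^2)))
  # the one-bead-per-residue toys sit below atomic density, so the grid
  # spreads their mass slightly; agreement is correspondingly looser
  for (cube in c(0.55, 0.6)) {
    sph <- build_sphere_model(toy$model, cube_side = cube, hydrate = FALSE)
    expect_rel(sphere_model_rg(sph), rg_atoms, 0.06)
  }
  # at protein heavy-atom density (~87 atoms/nm^3) the 3% contract holds
  # across the whole admissible grid range
  ball <- ball_model(9800, 3, seed = 2)
  for (cube in c(0.3, 0.45, 0.55, 0.6)) {
    sph <- build_sphere_model(ball, cube_side = cube, hydrate = FALSE)
    expect_rel(sphere_model_rg(sph), sqrt(3 / 5) * 3, 0.03)
  }
})

test_that("adding glycans to the model improves the fit against a glycosylated target", {
  toy <- make_toy_dimer(toy_registry("masp3d-like"))
  asn <- toy$model[toy$model$resname == "ASN", ]
  stubs <- lapply(seq_len(nrow(asn)), function(i) {
    glycan_stub(asn$chain[i], asn$resid[i], n_units = 11)
  })
  glyco <- attach_glycans(toy$model, stubs, seed = 3)
  target <- simulate_saxs(glyco, noise_model(), seed = 9)[[1]]
  vg <- dry_volume(glyco)
  vp <- dry_volume(toy$model)
  r_glyco <- r_factor(target, debye_curve(
    build_sphere_model(glyco, target_dry_volume_nm3 = vg), target$q))$r_factor
  r_bare <- r_factor(target, debye_curve(
    build_sphere_model(toy$model, target_dry_volume_nm3 = vp), target$q))$r_factor
  expect_lt(r_glyco, r_bare)
})
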