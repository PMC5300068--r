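# Cube-grid sphere models.
#
# Scattering is computed not from atoms but from a coarse-grained set of
# equal spheres on a cubic grid: every grid cube holding at least
# `atom_cutoff` atoms contributes one sphere at its center.  The cutoff is
# auto-tuned so that the total sphere volume reproduces the
# composition-derived dry volume, and the common sphere radius is then
# rescaled so the match is exact (the integer grid quantizes volume in
# steps of one cube).  Hydration appends spheres on empty cubes touching
# the filled surface until the volume accounts for 0.3 g bound water per g
# of glycoprotein.

#' Composition-derived dry volume of a model
#'
#' Sums consensus residue volumes over the protein chains plus declared
#' glycan volume.  Falls back to the model's `dry_volume_nm3` attribute
#' (synthetic models carry one), then to a mean heavy-atom volume for
#' models with non-standard residues.
#'
#' @param model a `structure_model`.
#' @return dry volume in nm^3.
#' @export
dry_volume <- function(model) {
  v <- attr(model, "dry_volume_nm3")
  if (!is.null(v)) return(v)
  seqs <- chain_sequences(model)
  res <- unlist(seqs, use.names = FALSE)
  known <- res %in% .AA_TABLE$resname
  gly <- attr(model, "glycan_volume_nm3") %||%
    (sum(model$glycan) * .SUGAR_TABLE$volume_nm3[1])
  if (mean(known) > 0.9) {
    vres <- sum(.AA_TABLE$volume_nm3[match(res[known], .AA_TABLE$resname)])
    # unknown residues contribute a mean residue volume
    return(vres + sum(!known) * mean(.AA_TABLE$volume_nm3) + gly)
  }
  nheavy <- sum(!model$glycan & model$element != "H")
  nheavy * .HEAVY_ATOM_VOLUME + gly
}

# best-estimate molecular mass (Da) for hydration bookkeeping
model_mass_Da <- function(model, target_dry = NULL) {
  m <- attr(model, "mass_kDa")
  if (!is.null(m)) return(m * 1000)
  seqs <- chain_sequences(model)
  res <- unlist(seqs, use.names = FALSE)
  known <- res %in% .AA_TABLE$resname
  gly <- attr(model, "glycan_mass_Da") %||% (sum(model$glycan) * .SUGAR_TABLE$mass[1])
  if (mean(known) > 0.9) {
    return(sum(.AA_TABLE$mass[match(res[known], .AA_TABLE$resname)]) +
             sum(!known) * mean(.AA_TABLE$mass) +
             18.02 * length(seqs) + gly)
  }
  # fall back through the dry volume and a conventional 0.73 mL/g
  v <- target_dry %||% dry_volume(model)
  v * 602.214 / 0.73
}

#' Coarse-grain a structure into a cube-grid sphere model
#'
#' @param model a `structure_model` (any coordinate set; hydrogens are
#'   ignored).
#' @param cube_side grid cube side in nm (must lie in (0.2, 1.2)).
#' @param atom_cutoff minimum atoms per cube for a sphere, or `NULL` to
#'   auto-tune over 1..8 by minimizing the dry-volume error (ties to the
#'   smaller cutoff).
#' @param hydrate logical; if `TRUE`, append hydration spheres for 0.3 g/g
#'   bound water.
#' @param target_dry_volume_nm3 override for the composition dry volume.
#' @return a tibble of class `sphere_model` with columns `x`, `y`, `z`,
#'   `hydration`, and attributes `radius_nm`, `cube_side_nm`,
#'   `atom_cutoff`, `dry_volume_nm3`, `hydrated_volume_nm3`, `hydrated`.
#' @export
build_sphere_model <- function(model, cube_side = 0.55, atom_cutoff = NULL,
                               hydrate = TRUE, target_dry_volume_nm3 = NULL) {
  if (cube_side <= 0.2 || cube_side >= 1.2) {
    abort("cube_side must lie in (0.2, 1.2) nm")
  }
  model <- structure_model(model)
  heavy <- model[model$element != "H", ]
  xyz <- coords_matrix(heavy)
  target <- target_dry_volume_nm3 %||% dry_volume(model)
  vcube <- cube_side^3

  org <- apply(xyz, 2, min) - cube_side / 2
  ix <- floor(sweep(xyz, 2, org) / cube_side)
  dims <- apply(ix, 2, max) + 1L
  lin <- ix[, 1] + dims[1] * (ix[, 2] + dims[2] * ix[, 3])
  counts <- table(lin)
  occ_keys <- as.numeric(names(counts))
  occ_n <- as.integer(counts)

  cutoffs <- if (is.null(atom_cutoff)) 1:8 else as.integer(atom_cutoff)
  vols <- vapply(cutoffs, function(cc) sum(occ_n >= cc) * vcube, numeric(1))
  err <- abs(vols - target)
  best <- cutoffs[which.min(err)]
  vbest <- vols[which.min(err)]
  if (vbest <= 0 || abs(vbest - target) / target > 0.30) {
    abort(paste0("cannot match dry volume ", signif(target, 4),
                 " nm^3 on this grid; best achieved ", signif(vbest, 4),
                 " nm^3 at cutoff ", best))
  }
  keep <- occ_keys[occ_n >= best]
  centers <- key_to_center(keep, dims, org, cube_side)
  n_dry <- nrow(centers)

  n_wet <- 0L
  if (hydrate) {
    mass <- model_mass_Da(model, target)
    vwater <- .HYDRATION_G_PER_G * mass / 602.214  # water density 1.0 g/mL
    n_wet <- max(0L, as.integer(round(vwater / vcube)))
    if (n_wet > 0) {
      wet_cells <- hydration_shell(keep, dims, n_wet)
      wc <- cbind(org[1] + (wet_cells[, 1] + 0.5) * cube_side,
                  org[2] + (wet_cells[, 2] + 0.5) * cube_side,
                  org[3] + (wet_cells[, 3] + 0.5) * cube_side)
      centers <- rbind(centers, wc)
    }
  }
  total_target <- target + if (hydrate) n_wet * vcube else 0
  # hydration bookkeeping: hydrated volume = dry volume + bound-water volume
  if (hydrate) total_target <- target + .HYDRATION_G_PER_G *
      model_mass_Da(model, target) / 602.214
  radius <- (total_target / nrow(centers) * 3 / (4 * pi))^(1 / 3)

  out <- tibble::new_tibble(
    tibble(x = centers[, 1], y = centers[, 2], z = centers[, 3],
           hydration = c(rep(FALSE, n_dry), rep(TRUE, nrow(centers) - n_dry))),
    class = "sphere_model")
  attr(out, "radius_nm") <- radius
  attr(out, "cube_side_nm") <- cube_side
  attr(out, "atom_cutoff") <- best
  attr(out, "dry_volume_nm3") <- target
  attr(out, "hydrated_volume_nm3") <- if (hydrate) total_target else NA_real_
  attr(out, "hydrated") <- hydrate
  attr(out, "mass_Da") <- model_mass_Da(model, target)
  out
}

key_to_center <- function(keys, dims, org, cube_side) {
  kx <- keys %% dims[1]
  ky <- (keys %/% dims[1]) %% dims[2]
  kz <- keys %/% (dims[1] * dims[2])
  cbind(org[1] + (kx + 0.5) * cube_side,
        org[2] + (ky + 0.5) * cube_side,
        org[3] + (kz + 0.5) * cube_side)
}

# grow shells of empty face-adjacent cubes around the filled set, in
# deterministic cube-index order, until n cubes have been collected;
# returns integer cube coordinates (possibly outside the original grid
# footprint, since the shell grows outward)
hydration_shell <- function(filled, dims, n) {
  kx <- filled %% dims[1]
  ky <- (filled %/% dims[1]) %% dims[2]
  kz <- filled %/% (dims[1] * dims[2])
  # pad generously so shell growth can never wrap around an edge
  pad <- max(3L, as.integer(ceiling(n^(1 / 3))) + 1L)
  pd <- dims + 2L * pad
  enc <- function(x, y, z) (x + pad) + pd[1] * ((y + pad) + pd[2] * (z + pad))
  off <- c(-1, 1, -pd[1], pd[1], -pd[1] * pd[2], pd[1] * pd[2])
  have <- enc(kx, ky, kz)
  picked <- numeric(0)
  while (length(picked) < n) {
    nb <- unique(sort(as.vector(outer(have, off, `+`))))
    nb <- setdiff(nb, have)
    nb <- nb[nb >= 0 & nb < prod(pd)]
    if (length(nb) == 0) break
    take <- head(nb, n - length(picked))
    picked <- c(picked, take)
    have <- c(have, take)
  }
  cbind(picked %% pd[1] - pad,
        (picked %/% pd[1]) %% pd[2] - pad,
        picked %/% (pd[1] * pd[2]) - pad)
}

#' Radius of gyration of a sphere model (centers, equal weights)
#'
#' @param spheres a `sphere_model` (or any table with x/y/z columns).
#' @param dry_only drop hydration spheres first.
#' @return Rg in nm.
#' @export
sphere_model_rg <- function(spheres, dry_only = FALSE) {
  if (dry_only && "hydration" %in% names(spheres)) {
    spheres <- spheres[!spheres$hydration, ]
  }
  points_rg(coords_matrix(spheres))
}

#' @export
print.sphere_model <- function(x, ...) {
  cat("<sphere_model> ", nrow(x), " spheres (", sum(!x$hydration), " dry), ",
      "radius ", signif(attr(x, "radius_nm"), 4), " nm, cube ",
      attr(x, "cube_side_nm"), " nm\n", sep = "")
  NextMethod()
}
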