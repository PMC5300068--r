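# Simplified extended N-glycan stubs.
#
# Crystal structures of glycoproteins rarely resolve their N-glycans, yet
# the sugars contribute several kDa of scattering mass.  The package models
# each oligosaccharide as a linear chain of sugar-unit pseudo-atoms placed
# along the outward normal of the attachment asparagine, i.e. an "extended
# conformation" stub that adds the right mass and volume at roughly the
# right place without any all-atom sugar chemistry.

#' Declare an N-glycan stub
#'
#' @param chain chain id of the attachment residue.
#' @param resid residue number of the attachment asparagine.
#' @param n_units number of sugar units in the extended chain.
#' @param unit_volume_nm3 dry volume per sugar unit (nm^3).
#' @param unit_mass_Da mass per sugar unit (Da).
#' @param spacing_nm rise per sugar unit along the chain (nm).
#' @return a list of class `glycan_stub`.
#' @export
glycan_stub <- function(chain, resid, n_units = 11,
                        unit_volume_nm3 = .SUGAR_TABLE$volume_nm3[1],
                        unit_mass_Da = .SUGAR_TABLE$mass[1],
                        spacing_nm = 0.5) {
  if (n_units < 1) abort("glycan stub needs at least one sugar unit")
  if (unit_volume_nm3 <= 0 || unit_mass_Da <= 0 || spacing_nm <= 0) {
    abort("glycan stub geometry parameters must be positive")
  }
  structure(list(chain = chain, resid = as.integer(resid),
                 n_units = as.integer(n_units),
                 unit_volume_nm3 = unit_volume_nm3,
                 unit_mass_Da = unit_mass_Da,
                 spacing_nm = spacing_nm),
            class = "glycan_stub")
}

#' Attach extended glycan stubs to a structure model
#'
#' Appends one pseudo-atom per sugar unit along the outward normal from each
#' attachment site (direction from the protein centroid through the residue
#' centroid).  Placements that clash with the protein are retried with
#' random tilts of the chain direction (at most 100, seeded).  Pre-existing
#' atom coordinates are never modified; mass and dry-volume attributes are
#' incremented by the glycan contribution.
#'
#' @param model a `structure_model`.
#' @param stubs list of [glycan_stub()] objects (empty list returns the
#'   model unchanged).
#' @param seed integer seed for the tilt retries.
#' @param clash_nm clearance between a sugar bead center and any protein
#'   atom surface (nm).
#' @return the model with glycan pseudo-atoms appended (`glycan = TRUE`,
#'   `parent_resid` = attachment residue).
#' @export
attach_glycans <- function(model, stubs, seed = 1L, clash_nm = 0.25) {
  model <- structure_model(model)
  if (length(stubs) == 0) return(model)
  if (inherits(stubs, "glycan_stub")) stubs <- list(stubs)
  prot <- model[!model$glycan, ]
  pxyz <- coords_matrix(prot)
  pr <- unname(.VDW_RADII[prot$element])
  pr[is.na(pr)] <- .VDW_DEFAULT
  ctr <- colMeans(pxyz)
  added <- list()
  extra_mass <- 0
  extra_vol <- 0
  for (si in seq_along(stubs)) {
    st <- stubs[[si]]
    sel <- model$chain == st$chain & model$resid == st$resid & !model$glycan
    if (!any(sel)) {
      abort(paste0("glycan attachment residue missing: ", st$chain, ":", st$resid))
    }
    if (!any(model$resname[sel] == "ASN")) {
      warn(paste0("glycan attached to non-Asn residue ", st$chain, ":",
                  st$resid, " (", model$resname[sel][1], ")"))
    }
    anchor <- colMeans(coords_matrix(model[sel, , drop = FALSE]))
    dir0 <- anchor - ctr
    if (sqrt(sum(dir0^2)) < 1e-9) dir0 <- c(0, 0, 1)
    dir0 <- dir0 / sqrt(sum(dir0^2))
    set.seed(derive_seed(seed, si))
    placed <- NULL
    for (try in 0:100) {
      dirn <- dir0
      if (try > 0) {
        # random tilt: rotate the outward normal about a random
        # perpendicular axis by up to 60 degrees
        rnd <- rnorm(3)
        perp <- rnd - sum(rnd * dir0) * dir0
        if (sqrt(sum(perp^2)) < 1e-9) next
        dirn <- as.vector(rotation_matrix(perp, runif(1, 5, 60)) %*% dir0)
      }
      beads <- anchor + outer(0.3 + st$spacing_nm * seq_len(st$n_units), dirn)
      # clearance against every protein atom surface
      ok <- TRUE
      for (b in seq_len(nrow(beads))) {
        d <- sqrt(colSums((t(pxyz) - beads[b, ])^2))
        if (any(d < pr + clash_nm)) { ok <- FALSE; break }
      }
      if (ok) { placed <- beads; break }
    }
    if (is.null(placed)) {
      abort(paste0("no clash-free glycan placement at ", st$chain, ":",
                   st$resid, " after 100 tilt retries"))
    }
    base <- max(model$resid[model$chain == st$chain], na.rm = TRUE) +
      1000L * si
    added[[si]] <- tibble(
      chain = st$chain,
      resid = base + seq_len(st$n_units),
      insert = "",
      resname = "HEX",
      atom = "C1",
      element = "C",
      x = placed[, 1], y = placed[, 2], z = placed[, 3],
      het = FALSE, glycan = TRUE,
      parent_resid = st$resid
    )
    extra_mass <- extra_mass + st$n_units * st$unit_mass_Da
    extra_vol <- extra_vol + st$n_units * st$unit_volume_nm3
  }
  out <- dplyr::bind_rows(as_tibble(model), dplyr::bind_rows(added))
  res <- structure_model(out)
  m0 <- attr(model, "mass_kDa")
  v0 <- attr(model, "dry_volume_nm3")
  if (!is.null(m0)) attr(res, "mass_kDa") <- m0 + extra_mass / 1000
  if (!is.null(v0)) attr(res, "dry_volume_nm3") <- v0 + extra_vol
  attr(res, "glycan_mass_Da") <- (attr(model, "glycan_mass_Da") %||% 0) + extra_mass
  attr(res, "glycan_volume_nm3") <- (attr(model, "glycan_volume_nm3") %||% 0) + extra_vol
  res
}
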