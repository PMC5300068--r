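# Bead-model hydrodynamics: sedimentation-coefficient prediction.
#
# One bead per heavy atom, radius 0.284 nm (the inflated "hydrated atomic
# element" radius), Kirkwood double-sum estimate of the translational
# friction, and s20,w = M (1 - vbar*rho) / (N_A * f) with water at 20 C.

#' Sequence/composition-derived mass and partial specific volume
#'
#' @param sequences per-chain sequences: a character vector of one-letter
#'   strings, or a list of three-letter-code vectors (as produced from a
#'   structure model).
#' @param glycans optional list of [glycan_stub()]s adding sugar mass and
#'   volume.
#' @return object of class `composition_properties`: `mass_kDa`,
#'   `vbar_mL_g`, `dry_volume_nm3`, `n_chains`.
#' @export
composition_properties <- function(sequences, glycans = list()) {
  if (length(sequences) == 0) abort("no sequences supplied")
  to3 <- function(s) {
    s <- toupper(s)
    if (all(nchar(s) == 3) && all(s %in% .AA_TABLE$resname)) return(s)
    if (length(s) == 1) {
      cc <- strsplit(s, "")[[1]]
      i <- match(cc, .AA_TABLE$code1)
      if (any(is.na(i))) {
        abort(paste0("unknown residue code: ",
                     paste(unique(cc[is.na(i)]), collapse = ", ")))
      }
      return(.AA_TABLE$resname[i])
    }
    if (any(!s %in% .AA_TABLE$resname)) {
      abort(paste0("unknown residue code: ",
                   paste(setdiff(unique(s), .AA_TABLE$resname),
                         collapse = ", ")))
    }
    s
  }
  chains <- lapply(sequences, to3)
  i <- match(unlist(chains), .AA_TABLE$resname)
  mass_prot <- sum(.AA_TABLE$mass[i]) + 18.02 * length(chains)
  vol_prot <- sum(.AA_TABLE$volume_nm3[i])
  vbar_prot <- sum(.AA_TABLE$vbar[i] * .AA_TABLE$mass[i]) / sum(.AA_TABLE$mass[i])
  mass_gly <- 0; vol_gly <- 0; vbar_gly_num <- 0
  if (inherits(glycans, "glycan_stub")) glycans <- list(glycans)
  for (g in glycans) {
    gm <- g$n_units * g$unit_mass_Da
    mass_gly <- mass_gly + gm
    vol_gly <- vol_gly + g$n_units * g$unit_volume_nm3
    # sugar vbar from its own mass/volume ratio
    vbar_gly_num <- vbar_gly_num + gm *
      (g$unit_volume_nm3 * 602.214 / g$unit_mass_Da)
  }
  mass <- mass_prot + mass_gly
  vbar <- (vbar_prot * mass_prot + vbar_gly_num) / mass
  if (vbar <= 0.5 || vbar >= 0.9) {
    abort(sprintf("implausible partial specific volume %.3f mL/g", vbar))
  }
  structure(list(mass_kDa = mass / 1000, vbar_mL_g = vbar,
                 dry_volume_nm3 = vol_prot + vol_gly,
                 n_chains = length(chains)),
            class = "composition_properties")
}

#' One-bead-per-heavy-atom hydrodynamic model
#'
#' @param model a `structure_model`.
#' @param bead_radius_nm common bead radius (default 0.284 nm, which
#'   absorbs the hydration shell).
#' @param max_beads models with more beads are grid-merged down to at most
#'   this many, with a volume-preserving common radius; the reduction is
#'   flagged in the output.
#' @return tibble of class `bead_model` (`x`, `y`, `z`) with attributes
#'   `radius_nm`, `reduced`.
#' @export
bead_model_from_atoms <- function(model, bead_radius_nm = .HYDRO_BEAD_RADIUS,
                                  max_beads = 5000L,
                                  reduce_above = 20000L) {
  if (bead_radius_nm <= 0) abort("bead radius must be positive")
  heavy <- model[model$element != "H", ]
  if (nrow(heavy) == 0) abort("empty model: no heavy atoms")
  xyz <- coords_matrix(heavy)
  reduced <- FALSE
  wt <- NULL
  intra <- 0
  n_true <- nrow(xyz)
  if (nrow(xyz) > reduce_above) {
    # grid-merge into weighted cluster beads: the Kirkwood double sum is
    # later evaluated with cluster weights, and the exact intra-cluster
    # inverse-distance sum is carried along, so only the (second-order)
    # centroid approximation of inter-cluster terms remains
    side <- 2 * bead_radius_nm
    repeat {
      cell <- floor(sweep(xyz, 2, apply(xyz, 2, min)) / side)
      key <- paste(cell[, 1], cell[, 2], cell[, 3])
      if (length(unique(key)) <= max_beads) break
      side <- side * 1.3
    }
    agg <- rowsum(xyz, key)
    cnt <- as.vector(table(key)[rownames(agg)])
    groups <- split(seq_len(nrow(xyz)), key)
    a <- bead_radius_nm
    for (g in groups) {
      if (length(g) < 2) next
      d <- as.vector(stats::dist(xyz[g, , drop = FALSE]))
      intra <- intra + 2 * sum(1 / pmax(d, a))
    }
    xyz <- unname(agg / cnt)
    wt <- cnt
    reduced <- TRUE
  }
  out <- tibble::new_tibble(tibble(x = xyz[, 1], y = xyz[, 2], z = xyz[, 3]),
                            class = "bead_model")
  if (!is.null(wt)) out$weight <- wt
  attr(out, "radius_nm") <- bead_radius_nm
  attr(out, "reduced") <- reduced
  attr(out, "n_true") <- n_true
  attr(out, "intra_inv_sum_nm") <- intra
  out
}

#' Predict the sedimentation coefficient of a bead model
#'
#' Kirkwood approximation to the translational friction of `n` identical
#' beads of radius `a`:
#' `f = n f1 / (1 + (f1 / (6 pi eta n)) * sum_{i != j} 1 / r_ij)` with
#' `f1 = 6 pi eta a`.  Overlapping pairs (`r_ij < a`) are clamped to `a`.
#' Then `s20,w = M (1 - vbar rho) / (N_A f)` with water at 20 C
#' (eta = 1.002 mPa s, rho = 0.99823 g/mL).
#'
#' @param beads a `bead_model` (or x/y/z table with a `radius_nm`
#'   attribute).
#' @param props a `composition_properties`, or a list with `mass_kDa` and
#'   `vbar_mL_g`.
#' @return object of class `hydro_result`: `s20w_S`, `rh_nm`,
#'   `frictional_ratio`, `n_beads`, `reduced`, plus the solvent parameters
#'   used.
#' @export
sedimentation_coefficient <- function(beads, props) {
  n <- nrow(beads)
  if (n < 1) abort("empty bead model")
  a_nm <- attr(beads, "radius_nm") %||% .HYDRO_BEAD_RADIUS
  eta <- .WATER_VISCOSITY_20C
  rho <- .WATER_DENSITY_20C
  M <- props$mass_kDa * 1000
  vbar <- props$vbar_mL_g
  if (is.null(M) || M <= 0) abort("composition properties lack a positive mass")
  a <- a_nm * 1e-9
  f1 <- 6 * pi * eta * a
  w <- beads[["weight"]] %||% rep(1, n)
  n_eff <- attr(beads, "n_true") %||% sum(w)
  if (n == 1 && n_eff == 1) {
    f <- f1
  } else {
    xyz <- coords_matrix(beads)
    d <- as.vector(stats::dist(xyz)) * 1e-9
    if (any(d < 1e-15)) {
      pr <- which(as.matrix(stats::dist(xyz)) < 1e-6 &
                    upper.tri(matrix(0, n, n)), arr.ind = TRUE)[1, ]
      abort(paste0("coincident beads ", pr[1], " and ", pr[2]))
    }
    if (is.null(beads[["weight"]])) {
      d[d < a] <- a
      S <- 2 * sum(1 / d)        # ordered-pair sum
    } else {
      # weighted inter-cluster sum plus the exact intra-cluster part
      Dinv <- 1 / pmax(as.matrix(stats::dist(xyz)) * 1e-9, a)
      diag(Dinv) <- 0
      S <- as.numeric(t(w) %*% Dinv %*% w) +
        (attr(beads, "intra_inv_sum_nm") %||% 0) * 1e9
    }
    f <- n_eff * f1 / (1 + (f1 / (6 * pi * eta * n_eff)) * S)
  }
  rh <- f / (6 * pi * eta)
  # equal-volume anhydrous sphere radius from M and vbar
  v_mL <- M * vbar / .AVOGADRO
  r0 <- (3 * v_mL * 1e-6 / (4 * pi))^(1 / 3)   # meters
  s <- M * (1 - vbar * rho) / (.AVOGADRO * f) / 1000  # vbar mL/g * rho g/mL; M g/mol
  # units: M[g/mol] -> kg/mol via /1000; f in SI; s in seconds
  structure(list(s20w_S = s / 1e-13, rh_nm = rh * 1e9,
                 frictional_ratio = rh / r0,
                 n_beads = n, bead_radius_nm = a_nm,
                 reduced = attr(beads, "reduced") %||% FALSE,
                 eta_Pa_s = eta, rho_g_mL = rho,
                 mass_kDa = M / 1000, vbar_mL_g = vbar),
            class = "hydro_result")
}

#' Predict s20,w straight from a structure model
#'
#' Convenience wrapper: bead model from heavy atoms, composition from the
#' model's attributes or sequences, then [sedimentation_coefficient()].
#'
#' @param model a `structure_model`.
#' @param props optional `composition_properties`; derived from the model
#'   when omitted.
#' @param ... passed to [bead_model_from_atoms()].
#' @return a `hydro_result`.
#' @export
predict_s20w <- function(model, props = NULL, ...) {
  if (is.null(props)) {
    m <- attr(model, "mass_kDa")
    if (!is.null(m)) {
      props <- list(mass_kDa = m, vbar_mL_g = attr(model, "vbar_mL_g") %||% 0.73)
    } else {
      props <- composition_properties(chain_sequences(model))
    }
  }
  sedimentation_coefficient(bead_model_from_atoms(model, ...), props)
}

#' @export
print.hydro_result <- function(x, ...) {
  cat(sprintf("s20,w = %.3f S (Rh = %.3f nm, f/f0 = %.3f, %d beads%s)\n",
              x$s20w_S, x$rh_nm, x$frictional_ratio, x$n_beads,
              if (x$reduced) ", reduced" else ""))
  invisible(x)
}

#' @export
print.composition_properties <- function(x, ...) {
  cat(sprintf("mass = %.2f kDa, vbar = %.3f mL/g, dry volume = %.1f nm^3 (%d chains)\n",
              x$mass_kDa, x$vbar_mL_g, x$dry_volume_nm3, x$n_chains))
  invisible(x)
}
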