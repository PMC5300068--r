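# Monte-Carlo conformational sampling at declared flexible linkers.
#
# Trial structures are generated by redrawing backbone dihedrals of linker
# residues and rotating everything downstream of the varied bond; rigid
# segments therefore move as rigid bodies and their internal geometry is
# preserved exactly.  The search is a generate-and-filter scan: sterically
# clashing proposals are discarded at creation (no Metropolis criterion),
# every surviving conformation is scored against the target curve with the
# R factor, and the lowest-R ensemble is retained.

#' Rigid-unit assignment for clash checking
#'
#' Groups rigid domain segments into rigid units: consecutive segments of a
#' chain merge unless a declared linker lies between them, and the
#' N-terminal (root) units of all chains merge into one core unit, since
#' the dimer interface itself is rigid.  Linker residues get unit `NA`;
#' glycan pseudo-atoms inherit the unit of their attachment residue.
#'
#' @param model a `structure_model`.
#' @param domains a `domain_map`.
#' @param linkers a `linker_set`.
#' @return integer vector of unit ids per atom (`NA` for linker atoms).
#' @export
rigid_units <- function(model, domains, linkers) {
  seg <- as_tibble(domains)
  seg <- seg[seg$rigid, ]
  unit <- rep(NA_integer_, nrow(seg))
  next_id <- 1L
  for (ch in unique(seg$chain)) {
    idx <- which(seg$chain == ch)
    idx <- idx[order(seg$start[idx])]
    unit[idx[1]] <- next_id
    if (length(idx) > 1) {
      for (i in 2:length(idx)) {
        gap <- c(seg$end[idx[i - 1]] + 1, seg$start[idx[i]] - 1)
        lk <- linkers[linkers$chain == ch, , drop = FALSE]
        between <- gap[2] >= gap[1] &&
          any(lk$start <= gap[2] & lk$end >= gap[1])
        if (between) {
          next_id <- next_id + 1L
          unit[idx[i]] <- next_id
        } else {
          unit[idx[i]] <- unit[idx[i - 1]]
        }
      }
    }
    next_id <- next_id + 1L
  }
  # merge the root (first) unit of every chain into one core unit
  roots <- vapply(unique(seg$chain), function(ch) {
    idx <- which(seg$chain == ch)
    unit[idx[order(seg$start[idx])][1]]
  }, integer(1))
  unit[unit %in% roots] <- roots[1]

  res_unit <- rep(NA_integer_, nrow(model))
  for (i in seq_len(nrow(seg))) {
    sel <- model$chain == seg$chain[i] & !model$glycan &
      model$resid >= seg$start[i] & model$resid <= seg$end[i]
    res_unit[sel] <- unit[i]
  }
  gly <- which(model$glycan)
  if (length(gly) > 0) {
    for (i in gly) {
      sel <- model$chain == model$chain[i] & !model$glycan &
        model$resid == model$parent_resid[i]
      u <- res_unit[sel]
      res_unit[i] <- if (length(u) > 0) u[1] else NA_integer_
    }
  }
  res_unit
}

#' Perturb flexible-linker backbone dihedrals
#'
#' For each chain listed in the linker set, one linker residue is chosen
#' uniformly and its phi/psi dihedrals are redrawn (chains are sampled
#' independently; no 2-fold symmetry is imposed).  The default `"flat"`
#' mode resamples from a flat distribution on (-180, 180]; `"step"` mode
#' adds a bounded uniform step of at most `step` degrees.  All atoms
#' downstream of the varied bond rotate rigidly; glycan stubs ride with
#' their attachment residue.
#'
#' @param model a `structure_model`.
#' @param linkers a `linker_set` (empty set returns the model unchanged).
#' @param step maximum dihedral step in degrees (used by `"step"` mode;
#'   `step = 0` reproduces the input).
#' @param seed integer seed; identical inputs and seed give bit-identical
#'   output.
#' @param mode `"flat"` (full resample) or `"step"` (bounded step).
#' @return the perturbed model, with an attribute `varied`: a tibble of
#'   (chain, resid, angle, delta_deg).
#' @export
perturb_linkers <- function(model, linkers, step = 180, seed = 1L,
                            mode = c("flat", "step")) {
  mode <- match.arg(mode)
  if (step < 0 || step > 180) abort("step must lie in [0, 180] degrees")
  if (nrow(linkers) == 0) return(model)
  set.seed(seed)
  varied <- list()
  for (ch in sort(unique(linkers$chain))) {
    lk <- linkers[linkers$chain == ch, , drop = FALSE]
    cand <- sort(unique(unlist(lapply(seq_len(nrow(lk)),
                                      function(i) lk$start[i]:lk$end[i]))))
    has_ca <- vapply(cand, function(r) {
      any(model$chain == ch & model$resid == r & model$atom == "CA" &
            !model$glycan)
    }, logical(1))
    cand <- cand[has_ca]
    if (length(cand) == 0) next
    r <- cand[sample.int(length(cand), 1)]
    for (ang in c("phi", "psi")) {
      delta <- switch(mode,
                      flat = runif(1, -180, 180),
                      step = runif(1, -step, step))
      model <- rotate_dihedral(model, ch, r, ang, delta)
      varied[[length(varied) + 1]] <-
        tibble(chain = ch, resid = r, angle = ang, delta_deg = delta)
    }
  }
  attr(model, "varied") <- dplyr::bind_rows(varied)
  model
}

# rotate everything downstream of residue r's phi or psi bond by delta
rotate_dihedral <- function(model, ch, r, angle, delta) {
  in_res <- model$chain == ch & model$resid == r & !model$glycan
  ca <- which(in_res & model$atom == "CA")
  if (length(ca) == 0) abort(paste0("residue ", ch, ":", r, " has no CA atom"))
  if (angle == "phi") {
    nn <- which(in_res & model$atom == "N")
    if (length(nn) == 0) return(model)  # chain start without N: skip phi
    a1 <- c(model$x[nn[1]], model$y[nn[1]], model$z[nn[1]])
    a2 <- c(model$x[ca[1]], model$y[ca[1]], model$z[ca[1]])
    moving <- (model$chain == ch & !model$glycan &
                 ((model$resid == r & !model$atom %in% c("N", "CA", "H")) |
                    model$resid > r)) |
      (model$chain == ch & model$glycan & model$parent_resid >= r)
  } else {
    cc <- which(in_res & model$atom == "C")
    if (length(cc) == 0) {
      abort(paste0("linker residue ", ch, ":", r,
                   " has no downstream atoms to rotate (chain terminus)"))
    }
    a1 <- c(model$x[ca[1]], model$y[ca[1]], model$z[ca[1]])
    a2 <- c(model$x[cc[1]], model$y[cc[1]], model$z[cc[1]])
    moving <- (model$chain == ch & !model$glycan &
                 ((model$resid == r & model$atom == "O") | model$resid > r)) |
      (model$chain == ch & model$glycan & model$parent_resid > r)
  }
  idx <- which(moving)
  if (length(idx) == 0) return(model)
  xyz <- rotate_about(cbind(model$x[idx], model$y[idx], model$z[idx]),
                      a1, a2 - a1, delta)
  model$x[idx] <- xyz[, 1]
  model$y[idx] <- xyz[, 2]
  model$z[idx] <- xyz[, 3]
  model
}

#' Steric clash predicate
#'
#' `TRUE` iff no heavy-atom pair belonging to two *different* rigid units
#' (including glycan beads, which inherit their attachment unit) lies
#' closer than `cutoff`.  Pairs within two residues of each other on the
#' same chain are exempt (bonded and near-bonded neighbours across a
#' linker).  Uses a cell-list neighbor grid; equivalent to the all-pairs
#' check.
#'
#' @param model a `structure_model`.
#' @param domains a `domain_map`.
#' @param linkers a `linker_set`.
#' @param cutoff clash distance in nm.
#' @return logical: `TRUE` when clash-free.
#' @export
clash_check <- function(model, domains, linkers, cutoff = 0.25) {
  if (cutoff <= 0) abort("cutoff must be positive")
  unit <- rigid_units(model, domains, linkers)
  sel <- which(!is.na(unit) & model$element != "H")
  if (length(sel) < 2) return(TRUE)
  xyz <- coords_matrix(model)[sel, , drop = FALSE]
  u <- unit[sel]
  ch <- model$chain[sel]
  rs <- model$resid[sel]
  ids <- sort(unique(u))
  parts <- lapply(ids, function(k) which(u == k))
  ctrs <- lapply(parts, function(p) colMeans(xyz[p, , drop = FALSE]))
  rads <- vapply(seq_along(parts), function(i) {
    sqrt(max(rowSums(sweep(xyz[parts[[i]], , drop = FALSE], 2,
                           ctrs[[i]])^2)))
  }, numeric(1))
  c2 <- cutoff^2
  for (i in seq_along(ids)) {
    for (j in seq_len(i - 1)) {
      # bounding-sphere prefilter, then exact blocked distances
      if (sqrt(sum((ctrs[[i]] - ctrs[[j]])^2)) >
            rads[i] + rads[j] + cutoff) next
      pi_ <- parts[[i]]; pj <- parts[[j]]
      A <- xyz[pi_, , drop = FALSE]; B <- xyz[pj, , drop = FALSE]
      d2 <- outer(rowSums(A^2), rowSums(B^2), `+`) - 2 * tcrossprod(A, B)
      hit <- which(d2 < c2, arr.ind = TRUE)
      if (nrow(hit) > 0) {
        ia <- pi_[hit[, 1]]; ib <- pj[hit[, 2]]
        exempt <- ch[ia] == ch[ib] & abs(rs[ia] - rs[ib]) <= 2
        if (any(!exempt)) return(FALSE)
      }
    }
  }
  TRUE
}

#' Monte-Carlo conformational search against a target curve
#'
#' Runs the generate-and-filter scan: perturb the linkers, discard steric
#' clashes, coarse-grain the survivor into a hydrated sphere model, compute
#' its Debye curve on the target's Q grid, and score it with the R factor.
#' Proposals walk from the previous accepted conformation, so restarting
#' from a previous best-fit model ("Search 2") is simply a different
#' `start`.  Each proposal draws its randomness from a seed derived from
#' `(seed, proposal index)`, so any trial is reproducible in isolation.
#'
#' @param start starting `structure_model` (e.g. the crystal structure, or
#'   a previous best-fit model).
#' @param linkers a `linker_set`.
#' @param target target `scattering_curve`.
#' @param n_trials number of accepted (clash-free, scored) trials to
#'   accumulate.
#' @param seed master seed.
#' @param domains `domain_map` used for clash checking.
#' @param config list of knobs: `cube_side` (nm, default 0.55), `hydrate`
#'   (TRUE), `clash_cutoff` (nm, 0.25), `mode` ("flat"), `step` (180),
#'   `q_range` (NULL = full overlap), `n_keep` (stored models, 16),
#'   `floor` (minimum acceptance rate over a 5000-proposal window, 0.02),
#'   and optionally `bend` (list with `end_domain` and `core_domains`):
#'   when set, the bend angle of every accepted trial is recorded in the
#'   trial table as `theta_deg`.
#' @return object of class `search_result`: `trials` tibble (`trial`,
#'   `accepted`, `rg_nm`, `r_factor`), stored best `models`, `target_rg_nm`
#'   (Guinier Rg of the target), and `meta` (seed, counts, config).
#' @export
run_search <- function(start, linkers, target, n_trials = 500, seed = 1L,
                       domains = NULL, config = list()) {
  if (n_trials < 1) abort("n_trials must be >= 1")
  cfg <- utils::modifyList(list(cube_side = 0.55, hydrate = TRUE,
                                clash_cutoff = 0.25, mode = "flat",
                                step = 180, q_range = NULL, n_keep = 16L,
                                floor = 0.02, floor_window = 5000L,
                                bend = NULL), config)
  if (is.null(domains)) abort("run_search needs a domain_map for clash checking")
  target_fit <- tryCatch(guinier_fit(target), error = function(e) NULL)
  target_rg <- if (is.null(target_fit)) NA_real_ else target_fit$rg_nm
  vdry <- dry_volume(start)

  score_model <- function(m) {
    sph <- build_sphere_model(m, cube_side = cfg$cube_side,
                              hydrate = cfg$hydrate,
                              target_dry_volume_nm3 = vdry)
    fs <- r_factor(target, debye_curve(sph, target$q), q_range = cfg$q_range)
    list(rg = sphere_model_rg(sph), r = fs$r_factor, eta = fs$eta)
  }

  current <- start
  rows <- list()
  best <- list()   # each: list(trial, r, rg, model)
  accepted <- 0L
  k <- 0L
  acc_log <- logical(0)
  while (accepted < n_trials) {
    k <- k + 1L
    prop <- perturb_linkers(current, linkers, step = cfg$step,
                            seed = derive_seed(seed, k), mode = cfg$mode)
    ok <- clash_check(prop, domains, linkers, cutoff = cfg$clash_cutoff)
    acc_log <- c(acc_log, ok)
    if (!ok) {
      rows[[k]] <- tibble(trial = k, accepted = FALSE,
                          rg_nm = NA_real_, r_factor = NA_real_,
                          theta_deg = if (is.null(cfg$bend)) NULL else NA_real_)
      if (length(acc_log) >= cfg$floor_window &&
          mean(tail(acc_log, cfg$floor_window)) < cfg$floor) {
        abort(paste0("acceptance rate below ", cfg$floor, " over the last ",
                     cfg$floor_window, " proposals (", accepted,
                     " accepted of ", k, "); check linker declarations and ",
                     "clash cutoff"))
      }
      next
    }
    sc <- score_model(prop)
    accepted <- accepted + 1L
    th <- if (is.null(cfg$bend)) NULL else {
      bend_parameters(prop, domains, end_domain = cfg$bend$end_domain,
                      core_domains = cfg$bend$core_domains)$theta_deg
    }
    rows[[k]] <- tibble(trial = k, accepted = TRUE,
                        rg_nm = sc$rg, r_factor = sc$r, theta_deg = th)
    best[[length(best) + 1]] <- list(trial = k, r = sc$r, rg = sc$rg,
                                     model = prop)
    if (length(best) > cfg$n_keep) {
      rs <- vapply(best, function(b) b$r, numeric(1))
      best <- best[order(rs)][seq_len(cfg$n_keep)]
    }
    current <- prop
  }
  structure(list(
    trials = dplyr::bind_rows(rows),
    models = best,
    target_rg_nm = target_rg,
    meta = list(seed = seed, n_trials = n_trials, n_proposals = k,
                acceptance_rate = accepted / k, start_label =
                  attr(start, "label") %||% "start", config = cfg)
  ), class = "search_result")
}

#' Select the best-fit ensemble from a search
#'
#' Returns the `n` accepted trials with the lowest R factors; ties are
#' broken by smaller |Rg(model) - Rg(target fit)|, then by trial index.
#'
#' @param result a `search_result`.
#' @param n ensemble size (default 10, the conventional best-fit set).
#' @return tibble of class `best_set` with columns `trial`, `r_factor`,
#'   `rg_nm` and a list-column `model`.
#' @export
select_best <- function(result, n = 10) {
  stopifnot(inherits(result, "search_result"))
  bb <- result$models
  if (length(bb) == 0) abort("search produced no accepted trials")
  n_acc <- sum(result$trials$accepted)
  if (n > n_acc) {
    warn(paste0("requested ", n, " models but only ", n_acc,
                " trials were accepted; returning all stored models"))
  }
  r <- vapply(bb, function(b) b$r, numeric(1))
  rg <- vapply(bb, function(b) b$rg, numeric(1))
  tr <- vapply(bb, function(b) b$trial, numeric(1))
  dv <- abs(rg - (result$target_rg_nm %||% NA_real_))
  dv[is.na(dv)] <- 0
  ord <- order(r, dv, tr)
  ord <- ord[seq_len(min(n, length(ord)))]
  out <- tibble(trial = tr[ord], r_factor = r[ord], rg_nm = rg[ord],
                model = lapply(bb[ord], function(b) b$model))
  tibble::new_tibble(out, class = "best_set")
}

#' Persist a search result
#'
#' Writes the trial table as TSV, the best `n` models as PDB files, and a
#' run-metadata text block (seed, counts, config).
#'
#' @param result a `search_result`.
#' @param dir output directory (created if needed).
#' @param n number of best models to write.
#' @return `dir`, invisibly.
#' @export
write_search_result <- function(result, dir, n = 10) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(result$trials, file.path(dir, "trials.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  bs <- select_best(result, n)
  for (i in seq_len(nrow(bs))) {
    write_structure(bs$model[[i]],
                    file.path(dir, sprintf("best_%02d.pdb", i)))
  }
  meta <- result$meta
  writeLines(c(
    paste0("seed\t", meta$seed),
    paste0("n_trials\t", meta$n_trials),
    paste0("n_proposals\t", meta$n_proposals),
    paste0("acceptance_rate\t", signif(meta$acceptance_rate, 4)),
    paste0("start\t", meta$start_label),
    paste0("config\t", paste(names(meta$config),
                             vapply(meta$config, function(x)
                               paste(format(x), collapse = ","), ""),
                             sep = "=", collapse = "; "))
  ), file.path(dir, "run_metadata.txt"))
  invisible(dir)
}

#' @export
print.search_result <- function(x, ...) {
  acc <- sum(x$trials$accepted)
  cat(sprintf("<search_result> %d accepted / %d proposals; best R = %.2f%%; target Rg = %.3f nm\n",
              acc, nrow(x$trials), min(x$trials$r_factor, na.rm = TRUE),
              x$target_rg_nm))
  invisible(x)
}
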