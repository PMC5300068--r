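# Coordinate models, domain annotation and flexible-linker declarations.
#
# A structure model is a tibble with one row per atom.  Coordinates are in
# nm throughout the package; PDB files (in Angstrom) are converted on read
# and write.  Glycan pseudo-atoms added by attach_glycans() carry a
# `glycan` flag plus the residue number of their attachment site so that
# they ride rigidly with it during conformational sampling.

.MODEL_COLS <- c("chain", "resid", "insert", "resname", "atom", "element",
                 "x", "y", "z", "het", "glycan", "parent_resid")

#' Build a structure model from an atom table
#'
#' Validates and classes a data frame of atom records as a structure model.
#' Missing bookkeeping columns (`insert`, `element`, `het`, `glycan`,
#' `parent_resid`) are filled with defaults.
#'
#' @param atoms data frame with at least columns `chain`, `resid`,
#'   `resname`, `atom`, `x`, `y`, `z` (coordinates in nm).
#' @param mass_kDa optional molecular mass carried as an attribute (kDa).
#' @param dry_volume_nm3 optional composition dry volume attribute (nm^3).
#' @return a tibble of class `structure_model`.
#' @export
structure_model <- function(atoms, mass_kDa = NULL, dry_volume_nm3 = NULL) {
  atoms <- as_tibble(atoms)
  need <- c("chain", "resid", "resname", "atom", "x", "y", "z")
  miss <- setdiff(need, names(atoms))
  if (length(miss) > 0) {
    abort(paste0("atom table lacks column(s): ", paste(miss, collapse = ", ")))
  }
  if (nrow(atoms) == 0) abort("structure model contains zero atoms")
  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z))) {
    abort("non-finite coordinates in structure model")
  }
  if (!"insert" %in% names(atoms)) atoms$insert <- ""
  if (!"element" %in% names(atoms)) {
    atoms$element <- guess_element(atoms$atom)
  }
  if (!"het" %in% names(atoms)) atoms$het <- FALSE
  if (!"glycan" %in% names(atoms)) atoms$glycan <- FALSE
  if (!"parent_resid" %in% names(atoms)) atoms$parent_resid <- NA_integer_
  atoms$resid <- as.integer(atoms$resid)
  atoms <- atoms[, union(.MODEL_COLS, names(atoms))]
  out <- tibble::new_tibble(atoms, class = "structure_model")
  attr(out, "unit") <- "nm"
  if (!is.null(mass_kDa)) attr(out, "mass_kDa") <- mass_kDa
  if (!is.null(dry_volume_nm3)) attr(out, "dry_volume_nm3") <- dry_volume_nm3
  out
}

guess_element <- function(atom_names) {
  nm <- gsub("[0-9' ]", "", toupper(atom_names))
  el <- substr(nm, 1, 1)
  two <- substr(nm, 1, 2)
  el[two %in% c("CA", "FE", "ZN", "MG", "SE", "CL", "NA")] <-
    two[two %in% c("CA", "FE", "ZN", "MG", "SE", "CL", "NA")]
  # CA as an *atom name* is a carbon (the alpha carbon); calcium ions come
  # in as HETATM residues named CA, handled by the PDB reader directly
  el[nm == "CA"] <- "C"
  el
}

#' Read a coordinate file in PDB format
#'
#' Parses ATOM/HETATM records (via bio3d), converts coordinates to nm,
#' resolves alternate locations by keeping the highest-occupancy conformer,
#' and retains hetero atoms such as bound Ca2+ ions with `het = TRUE`.
#' Insertion codes are kept verbatim.
#'
#' @param path path to a PDB-format file.
#' @return a `structure_model` tibble (coordinates in nm).
#' @export
read_structure <- function(path) {
  if (!file.exists(path)) abort(paste0("cannot read file: ", path))
  pdb <- tryCatch(bio3d::read.pdb(path, rm.alt = FALSE, verbose = FALSE),
                  error = function(e) abort(paste0("PDB parse error in '",
                                                   path, "': ",
                                                   conditionMessage(e))))
  at <- pdb$atom
  if (is.null(at) || nrow(at) == 0) abort(paste0("zero atoms in ", path))
  occ <- at$o
  occ[is.na(occ)] <- 1.0
  at$o <- occ
  alt <- at$alt
  alt[is.na(alt)] <- ""
  at$alt <- alt
  # altloc resolution: within each atom identity keep the highest occupancy
  # (ties: first conformer in file order)
  key <- paste(at$chain, at$resno, at$insert, at$resid, at$elety, sep = "|")
  ord <- order(key, -occ, seq_len(nrow(at)))
  at <- at[ord, ]
  key <- key[ord]
  keep <- !duplicated(key)
  # duplicates with the same alt code are genuine duplicate records
  bad <- duplicated(paste(key, at$alt, sep = "|"))
  if (any(bad)) {
    i <- which(bad)[1]
    abort(paste0("duplicate atom record in ", path, ": chain ",
                 at$chain[i], " residue ", at$resno[i], " atom ",
                 at$elety[i]))
  }
  at <- at[keep, ]
  at <- at[order(match(at$chain, unique(at$chain)), at$resno, at$eleno), ]
  ins <- at$insert
  ins[is.na(ins)] <- ""
  el <- at$elesy
  if (is.null(el)) el <- rep(NA_character_, nrow(at))
  el[is.na(el) | el == ""] <- guess_element(at$elety[is.na(el) | el == ""])
  ch <- at$chain
  ch[is.na(ch)] <- " "
  structure_model(tibble(
    chain = ch,
    resid = as.integer(at$resno),
    insert = ins,
    resname = at$resid,
    atom = at$elety,
    element = toupper(el),
    x = at$x * .NM_PER_ANGSTROM,
    y = at$y * .NM_PER_ANGSTROM,
    z = at$z * .NM_PER_ANGSTROM,
    het = at$type == "HETATM",
    glycan = FALSE,
    parent_resid = NA_integer_
  ))
}

#' Write a structure model to a PDB-format file
#'
#' Coordinates are converted from nm back to Angstrom.  Glycan pseudo-atoms
#' are written as HETATM records.
#'
#' @param model a `structure_model`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(model, path) {
  model <- structure_model(model)
  xyz <- as.vector(t(coords_matrix(model))) / .NM_PER_ANGSTROM
  type <- ifelse(model$het | model$glycan, "HETATM", "ATOM")
  ch <- model$chain
  ch[ch == " " | is.na(ch)] <- ""
  bio3d::write.pdb(file = path, xyz = xyz, type = type,
                   resno = model$resid, resid = model$resname,
                   chain = ch, elety = model$atom,
                   insert = model$insert,
                   elesy = model$element,
                   o = rep(1, nrow(model)), b = rep(0, nrow(model)))
  invisible(path)
}

#' Declare named rigid/flexible domain segments
#'
#' A domain map lists named segments (e.g. CUB1, EGF, CUB2, SCR1, SCR2, SP)
#' as chain + inclusive residue ranges with a per-segment rigid flag.
#' Segments within a chain must not overlap.
#'
#' @param segments data frame with columns `segment`, `chain`, `start`,
#'   `end` and optionally `rigid` (default TRUE).
#' @return tibble of class `domain_map`.
#' @export
domain_map <- function(segments) {
  seg <- as_tibble(segments)
  need <- c("segment", "chain", "start", "end")
  miss <- setdiff(need, names(seg))
  if (length(miss) > 0) abort(paste0("domain map lacks: ", paste(miss, collapse = ", ")))
  if (!"rigid" %in% names(seg)) seg$rigid <- TRUE
  if (any(seg$end < seg$start)) abort("domain segment with end < start")
  for (ch in unique(seg$chain)) {
    s <- seg[seg$chain == ch, ]
    s <- s[order(s$start), ]
    if (nrow(s) > 1 && any(s$start[-1] <= s$end[-nrow(s)])) {
      abort(paste0("overlapping segments in chain ", ch))
    }
  }
  tibble::new_tibble(seg, class = "domain_map")
}

#' Declare flexible linker residue ranges
#'
#' Linkers are chain + inclusive residue ranges free to vary during
#' conformational sampling; they must not fall inside any rigid segment.
#'
#' @param linkers data frame with columns `chain`, `start`, `end`.
#' @param domains optional `domain_map` checked for exclusivity.
#' @return tibble of class `linker_set`.
#' @export
linker_set <- function(linkers, domains = NULL) {
  lk <- as_tibble(linkers)
  need <- c("chain", "start", "end")
  miss <- setdiff(need, names(lk))
  if (length(miss) > 0) abort(paste0("linker set lacks: ", paste(miss, collapse = ", ")))
  if (any(lk$end < lk$start)) abort("empty linker range (end < start)")
  if (!is.null(domains)) {
    for (i in seq_len(nrow(lk))) {
      d <- domains[domains$chain == lk$chain[i] & domains$rigid, , drop = FALSE]
      clash <- d$start <= lk$end[i] & d$end >= lk$start[i]
      if (any(clash)) {
        abort(paste0("linker ", lk$chain[i], ":", lk$start[i], "-", lk$end[i],
                     " overlaps rigid segment ", d$segment[which(clash)[1]]))
      }
    }
  }
  tibble::new_tibble(lk, class = "linker_set")
}

# residue-level sequence (three-letter codes) per chain, protein atoms only
chain_sequences <- function(model) {
  m <- model[!model$het & !model$glycan, ]
  res <- dplyr::distinct(as_tibble(m)[, c("chain", "resid", "insert", "resname")])
  split(res$resname, res$chain)
}

#' @export
print.structure_model <- function(x, ...) {
  nres <- nrow(dplyr::distinct(as_tibble(x)[!x$het & !x$glycan,
                                            c("chain", "resid", "insert")]))
  cat("<structure_model> ", nrow(x), " atoms, ", nres,
      " residues, chains: ", paste(unique(x$chain), collapse = " "),
      " (nm)\n", sep = "")
  NextMethod()
}
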