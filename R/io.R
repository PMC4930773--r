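#' Read a structure or multi-model ensemble from a PDB or mmCIF file
#'
#' ATOM/HETATM records are read with author residue numbering preserved.
#' Files ending in `.cif` are read as mmCIF (read only; output is always
#' PDB).  Multi-model files (MODEL/ENDMDL) are returned as an
#' [new_ensemble()] `Ensemble` when `model_policy = "all"`; under
#' `model_policy = "first"` only the first model is kept.  Waters are flagged
#' from the residue-name set `{HOH, WAT, TIP3, TIP, SOL}`.  When several
#' alternate locations are present the highest-occupancy altloc is kept, ties
#' broken by altloc letter order.
#'
#' @param path path to a PDB (`.pdb`) or mmCIF (`.cif`) file.
#' @param model_policy `"first"` (default) or `"all"`.
#' @param verbose emit progress/fallback messages.
#' @return a `Structure`, or an `Ensemble` for multi-model input under
#'   `model_policy = "all"`.
#' @export
read_structure <- function(path, model_policy = c("first", "all"), verbose = FALSE) {
  model_policy <- match.arg(model_policy)
  if (!file.exists(path)) stop("file not found: ", path)
  multi <- model_policy == "all"
  if (grepl("\\.cif(\\.gz)?$", path, ignore.case = TRUE)) {
    # muffle bio3d's blanket beta notice and its missing-SSE-records notice;
    # neither concerns the atom records consumed here
    pdb <- withCallingHandlers(
      bio3d::read.cif(path, multi = multi, rm.alt = FALSE, verbose = FALSE),
      warning = function(w) {
        if (grepl("beta version|helix/sheet", conditionMessage(w))) {
          invokeRestart("muffleWarning")
        }
      }
    )
  } else {
    validate_pdb_lines(path)
    pdb <- bio3d::read.pdb(path, multi = multi, rm.alt = FALSE, verbose = FALSE)
  }

  at <- pdb$atom
  blank_el <- is.null(at$elesy) || all(is.na(at$elesy)) || all(trimws(at$elesy) == "")
  if (blank_el && verbose) message("element column absent; inferring elements from atom names")
  atoms <- data.frame(
    eleno = at$eleno,
    name = trimws(at$elety),
    altloc = ifelse(is.na(at$alt), "", at$alt),
    resname = trimws(at$resid),
    chain = ifelse(is.na(at$chain), "", at$chain),
    resno = at$resno,
    insert = ifelse(is.na(at$insert), "", at$insert),
    x = at$x, y = at$y, z = at$z,
    occ = ifelse(is.na(at$o), 1, at$o),
    b = ifelse(is.na(at$b), 0, at$b),
    element = if (blank_el) "" else trimws(at$elesy),
    stringsAsFactors = FALSE
  )
  atoms <- resolve_altlocs(atoms, verbose = verbose)

  s <- new_structure(atoms, model_id = 1L, metadata = list(source = path))
  if (!multi) {
    return(s)
  }
  nframes <- nrow(pdb$xyz)
  if (is.null(nframes) || nframes <= 1) {
    return(new_ensemble(list(s)))
  }
  # bio3d returns all models as rows of the xyz matrix over one shared topology
  sel_idx <- atoms_kept_index(at, atoms)
  frames <- lapply(seq_len(nframes), function(i) {
    xyz <- matrix(pdb$xyz[i, ], ncol = 3, byrow = TRUE)[sel_idx, , drop = FALSE]
    f <- set_coords(s, xyz)
    f$model_id <- as.integer(i)
    f
  })
  new_ensemble(frames)
}

# map the retained (post-altloc) eleno back to row positions of the raw table
atoms_kept_index <- function(raw, kept) {
  match(kept$eleno, raw$eleno)
}

resolve_altlocs <- function(atoms, verbose = FALSE) {
  has_alt <- atoms$altloc != ""
  if (!any(has_alt)) {
    return(atoms)
  }
  key <- paste(atoms$chain, atoms$resno, atoms$insert, atoms$name, sep = "|")
  ord <- order(key, -atoms$occ, atoms$altloc)
  keep <- !duplicated(key[ord])
  kept <- atoms[ord, ][keep, ]
  kept <- kept[order(kept$eleno), ]
  n_drop <- nrow(atoms) - nrow(kept)
  if (n_drop > 0 && verbose) {
    message("dropped ", n_drop, " alternate-location records (kept highest occupancy)")
  }
  rownames(kept) <- NULL
  kept
}

# minimal structural sanity check so malformed coordinate records fail with the
# offending line number rather than propagating NA coordinates
validate_pdb_lines <- function(path) {
  lines <- readLines(path, warn = FALSE)
  rec <- grepl("^(ATOM  |HETATM)", lines)
  idx <- which(rec)
  for (i in idx) {
    ln <- lines[i]
    if (nchar(ln) < 54) {
      stop("unparseable coordinate record at line ", i, ": record too short")
    }
    xyz <- suppressWarnings(as.numeric(c(
      substr(ln, 31, 38), substr(ln, 39, 46), substr(ln, 47, 54)
    )))
    if (any(is.na(xyz))) {
      stop("unparseable coordinate record at line ", i, ": non-numeric coordinates")
    }
  }
  invisible(TRUE)
}

#' Write a Structure or Ensemble to a PDB file
#'
#' Ensembles are written as multi-model PDB (MODEL/ENDMDL blocks).
#' Coordinates are written at PDB precision (3 decimals).
#'
#' @param x `Structure` or `Ensemble`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(x, path) {
  if (inherits(x, "Structure")) {
    frames <- list(x)
  } else if (inherits(x, "Ensemble")) {
    frames <- x$frames
  } else {
    stop("x must be a Structure or Ensemble")
  }
  a <- frames[[1]]$atoms
  xyz <- do.call(rbind, lapply(frames, function(f) as.vector(t(coords(f)))))
  bio3d::write.pdb(
    file = path,
    xyz = xyz,
    type = ifelse(a$resname %in% STANDARD_AA, "ATOM", "HETATM"),
    resno = a$resno,
    resid = a$resname,
    eleno = a$eleno,
    elety = a$name,
    chain = ifelse(a$chain == "", " ", a$chain),
    insert = ifelse(a$insert == "", "", a$insert),
    o = a$occ,
    b = a$b,
    elesy = a$element
  )
  invisible(path)
}
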