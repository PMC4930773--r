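#' @keywords internal
"_PACKAGE"

# Residue names treated as water throughout the package.
WATER_RESNAMES <- c("HOH", "WAT", "TIP3", "TIP", "SOL")

# Backbone atom names for amino-acid residues (everything else is side chain).
BACKBONE_ATOMS <- c("N", "CA", "C", "O", "OXT", "H", "HA", "H1", "H2", "H3")

STANDARD_AA <- c(
  "ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS", "ILE",
  "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP", "TYR", "VAL"
)

#' Construct a Structure
#'
#' A `Structure` is one coordinate model: a flat atom table plus metadata.
#' Coordinates are in angstroms with author residue numbering preserved, the
#' same conventions used by crystallographic PDB entries.  Residues are
#' identified by the triple (chain, residue number, insertion code).
#'
#' @param atoms data frame with columns `eleno`, `name`, `altloc`, `resname`,
#'   `chain`, `resno`, `insert`, `x`, `y`, `z`, `occ`, `b`, `element`.
#'   Missing optional columns are filled with defaults.
#' @param model_id integer model identifier (1 for single-model files).
#' @param metadata named list of header fields.
#' @return object of class `Structure`.
#' @export
new_structure <- function(atoms, model_id = 1L, metadata = list()) {
  stopifnot(is.data.frame(atoms), nrow(atoms) >= 1)
  need <- c("name", "resname", "chain", "resno", "x", "y", "z")
  miss <- setdiff(need, names(atoms))
  if (length(miss) > 0) {
    stop("atom table is missing required columns: ", paste(miss, collapse = ", "))
  }
  n <- nrow(atoms)
  if (is.null(atoms$eleno)) atoms$eleno <- seq_len(n)
  if (is.null(atoms$altloc)) atoms$altloc <- ""
  if (is.null(atoms$insert)) atoms$insert <- ""
  atoms$insert[is.na(atoms$insert)] <- ""
  atoms$altloc[is.na(atoms$altloc)] <- ""
  if (is.null(atoms$occ)) atoms$occ <- 1
  if (is.null(atoms$b)) atoms$b <- 0
  if (is.null(atoms$element) || all(is.na(atoms$element)) || all(atoms$element == "")) {
    atoms$element <- infer_element(atoms$name, atoms$resname)
  } else {
    blank <- is.na(atoms$element) | atoms$element == ""
    if (any(blank)) {
      atoms$element[blank] <- infer_element(atoms$name[blank], atoms$resname[blank])
    }
  }
  if (is.null(atoms$vdw)) atoms$vdw <- NA_real_
  coords <- as.matrix(atoms[, c("x", "y", "z")])
  if (!all(is.finite(coords))) stop("non-finite atom coordinates")
  atoms$is_water <- atoms$resname %in% WATER_RESNAMES
  atoms$is_sidechain <- !(atoms$name %in% BACKBONE_ATOMS) & !atoms$is_water
  rownames(atoms) <- NULL
  structure(
    list(atoms = atoms, model_id = as.integer(model_id), metadata = metadata),
    class = "Structure"
  )
}

#' Construct an Ensemble of frames sharing one topology
#'
#' Frames stand in for trajectory snapshots; all analyses that consume an
#' `Ensemble` (loop-gap series, RMSF, water penetration) iterate over frames.
#' Topology identity (atom names, residue keys, ordering) across frames is a
#' hard error, not a warning, because every downstream per-frame comparison
#' assumes positional correspondence.
#'
#' @param frames list of `Structure` objects.
#' @param frame_times optional numeric vector (ns), strictly increasing.
#' @return object of class `Ensemble`.
#' @export
new_ensemble <- function(frames, frame_times = NULL) {
  stopifnot(is.list(frames), length(frames) >= 1)
  lapply(frames, function(f) stopifnot(inherits(f, "Structure")))
  sig <- topology_signature(frames[[1]])
  for (i in seq_along(frames)[-1]) {
    if (!identical(topology_signature(frames[[i]]), sig)) {
      stop("frame ", i, " does not share the topology of frame 1")
    }
  }
  if (!is.null(frame_times)) {
    stopifnot(length(frame_times) == length(frames))
    if (any(diff(frame_times) <= 0)) stop("frame_times must be strictly increasing")
  }
  structure(list(frames = frames, frame_times = frame_times), class = "Ensemble")
}

topology_signature <- function(s) {
  a <- s$atoms
  paste(a$chain, a$resno, a$insert, a$resname, a$name, sep = "|")
}

#' Residue table of a Structure
#'
#' @param s Structure.
#' @param protein_only drop waters and other non-amino-acid residues.
#' @return data frame with one row per residue: `chain`, `resno`, `insert`,
#'   `resname`, in file order.
#' @export
residue_table <- function(s, protein_only = FALSE) {
  a <- s$atoms
  if (protein_only) a <- a[a$resname %in% STANDARD_AA, , drop = FALSE]
  key <- paste(a$chain, a$resno, a$insert, sep = "|")
  keep <- !duplicated(key)
  out <- a[keep, c("chain", "resno", "insert", "resname")]
  rownames(out) <- NULL
  out
}

residue_key_string <- function(chain, resno, insert = "") {
  insert[is.na(insert)] <- ""
  paste0(chain, ":", resno, ifelse(insert == "", "", paste0(":", insert)))
}

#' Look up a C-alpha coordinate
#'
#' @param s Structure.
#' @param chain chain identifier.
#' @param resno author residue number.
#' @param insert insertion code (default none).
#' @return numeric length-3 coordinate (angstroms).
#' @export
ca_xyz <- function(s, chain, resno, insert = "") {
  a <- s$atoms
  hit <- a$chain == chain & a$resno == resno & a$insert == insert & a$name == "CA"
  if (!any(hit)) {
    stop("no CA atom for residue ", residue_key_string(chain, resno, insert))
  }
  as.numeric(a[which(hit)[1], c("x", "y", "z")])
}

#' Coordinate matrix of a Structure
#' @param s Structure.
#' @return n x 3 numeric matrix.
#' @export
coords <- function(s) {
  as.matrix(s$atoms[, c("x", "y", "z")])
}

set_coords <- function(s, xyz) {
  stopifnot(nrow(xyz) == nrow(s$atoms))
  s$atoms$x <- xyz[, 1]
  s$atoms$y <- xyz[, 2]
  s$atoms$z <- xyz[, 3]
  s
}

#' Apply a rigid motion to a Structure
#' @param s Structure.
#' @param rotation 3x3 rotation matrix.
#' @param translation length-3 vector (angstroms).
#' @return transformed Structure.
#' @export
transform_structure <- function(s, rotation = diag(3), translation = c(0, 0, 0)) {
  xyz <- coords(s) %*% t(rotation)
  xyz <- sweep(xyz, 2, translation, "+")
  set_coords(s, xyz)
}

# Element inference from PDB atom names (columns 13-16 conventions):
# two-character elements only for common hetero cases; amino-acid names start
# with the element letter.
infer_element <- function(name, resname) {
  nm <- toupper(trimws(name))
  el <- substr(nm, 1, 1)
  two <- substr(nm, 1, 2)
  el[two %in% c("FE", "ZN", "MG", "MN", "CU", "NA", "CL", "BR", "SE")] <-
    two[two %in% c("FE", "ZN", "MG", "MN", "CU", "NA", "CL", "BR", "SE")]
  # numerals lead in some hydrogen names (e.g. 1HB)
  dig <- grepl("^[0-9]", nm)
  el[dig] <- substr(sub("^[0-9]+", "", nm[dig]), 1, 1)
  el
}

#' @export
print.Structure <- function(x, ...) {
  rt <- residue_table(x)
  cat("Structure (model ", x$model_id, "): ",
    nrow(x$atoms), " atoms, ", nrow(rt), " residues, chains: ",
    paste(unique(x$atoms$chain), collapse = " "), "\n",
    sep = ""
  )
  invisible(x)
}

#' @export
print.Ensemble <- function(x, ...) {
  cat("Ensemble: ", length(x$frames), " frames of ",
    nrow(x$frames[[1]]$atoms), " atoms\n",
    sep = ""
  )
  invisible(x)
}
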