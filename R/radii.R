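# cache for data tables shipped under inst/extdata
.loopgate_cache <- new.env(parent = emptyenv())

read_extdata <- function(fname) {
  key <- paste0("extdata:", fname)
  if (!is.null(.loopgate_cache[[key]])) {
    return(.loopgate_cache[[key]])
  }
  path <- system.file("extdata", fname, package = "loopgate")
  if (path == "") {
    # during development the package may be loaded from source
    path <- file.path("inst", "extdata", fname)
  }
  # na.strings = "": the element symbol "NA" (sodium) must stay a string
  tab <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = "")
  .loopgate_cache[[key]] <- tab
  tab
}

#' Tabulated van der Waals radii
#'
#' @param radius_set `"bondi"` or `"chothia"`.
#' @return data frame with columns `element` and `radius` (angstroms); the
#'   `"*"` row is the default for unknown elements.
#' @export
vdw_radius_table <- function(radius_set = c("bondi", "chothia")) {
  radius_set <- match.arg(radius_set)
  tab <- read_extdata("vdw_radii.csv")
  tab[tab$set == radius_set, c("element", "radius")]
}

#' Assign van der Waals radii to every atom
#'
#' Radii drive the Shrake-Rupley surface calculation.  Elements missing from
#' the chosen table receive the table's default radius with a warning.
#'
#' @param s Structure.
#' @param radius_set `"bondi"` (default) or `"chothia"`.
#' @return Structure with the `vdw` column filled.
#' @export
assign_radii <- function(s, radius_set = c("bondi", "chothia")) {
  radius_set <- match.arg(radius_set)
  tab <- vdw_radius_table(radius_set)
  el <- toupper(s$atoms$element)
  idx <- match(el, tab$element)
  default <- tab$radius[tab$element == "*"]
  unknown <- is.na(idx)
  if (any(unknown)) {
    warning(
      "unknown element(s) ", paste(unique(el[unknown]), collapse = ", "),
      "; using default radius ", default, " Å"
    )
  }
  r <- tab$radius[idx]
  r[unknown] <- default
  s$atoms$vdw <- r
  s
}

#' Hydrophobicity scale used for SAP scoring
#'
#' The Black-Mould side-chain hydrophobicity values, shifted so that glycine
#' scores exactly zero (the convention of the spatial-aggregation-propensity
#' method: hydrophilic residues are negative, hydrophobic positive).
#'
#' @param scale scale name; only `"black_mould"` ships with the package.
#' @return named numeric vector keyed by three-letter residue code.
#' @export
hydrophobicity_scale <- function(scale = "black_mould") {
  if (!identical(scale, "black_mould")) {
    stop("unknown hydrophobicity scale: ", scale)
  }
  tab <- read_extdata("hydrophobicity_black_mould.csv")
  stats::setNames(tab$value, tab$resname)
}
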