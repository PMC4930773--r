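#' Select atoms with a small text grammar
#'
#' Clauses are joined by the conjunctions `and`, `of`, or `within` and all
#' must hold.  Supported clauses:
#' \itemize{
#'   \item `chain A` (comma lists allowed: `chain A,B`)
#'   \item `resi 199-203`, `resi 82`, `resi 82,108,173`
#'   \item `name CA`, `name OD1,OD2`
#'   \item `resn SER,TYR`
#'   \item `elem O`
#'   \item bare words `sidechain`, `backbone`, `water`, `protein`,
#'     `structure` (or `all`, matching everything)
#' }
#' Any clause may be negated with a leading `not`.  The result is returned in
#' file order; an empty selection is legal.
#'
#' @param s Structure.
#' @param spec selection expression, e.g. `"chain A and resi 199-203 and name CA"`.
#' @return data frame of selected atom rows with an `idx` attribute giving the
#'   row indices into `s$atoms`.
#' @export
select_atoms <- function(s, spec) {
  a <- s$atoms
  keep <- rep(TRUE, nrow(a))
  clauses <- strsplit(spec, "\\s+(and|of|within)\\s+")[[1]]
  pos <- 1L
  for (cl in clauses) {
    cl_trim <- trimws(cl)
    m <- clause_mask(a, cl_trim, pos)
    keep <- keep & m
    pos <- pos + nchar(cl) + 1L
  }
  out <- a[keep, , drop = FALSE]
  attr(out, "idx") <- which(keep)
  out
}

clause_mask <- function(a, cl, pos) {
  if (cl == "") stop("empty selection clause at position ", pos)
  negate <- FALSE
  if (grepl("^not\\s+", cl)) {
    negate <- TRUE
    cl <- trimws(sub("^not\\s+", "", cl))
  }
  toks <- strsplit(cl, "\\s+")[[1]]
  kw <- tolower(toks[1])
  arg <- if (length(toks) > 1) paste(toks[-1], collapse = "") else ""
  m <- switch(kw,
    chain = a$chain %in% strsplit(arg, ",")[[1]],
    resi = a$resno %in% parse_resi_arg(arg, pos),
    name = a$name %in% strsplit(toupper(arg), ",")[[1]],
    resn = a$resname %in% strsplit(toupper(arg), ",")[[1]],
    elem = toupper(a$element) %in% strsplit(toupper(arg), ",")[[1]],
    sidechain = a$is_sidechain,
    backbone = !a$is_sidechain & !a$is_water,
    water = a$is_water,
    protein = a$resname %in% STANDARD_AA,
    structure = rep(TRUE, nrow(a)),
    all = rep(TRUE, nrow(a)),
    stop("malformed selection clause '", cl, "' at position ", pos)
  )
  if (kw %in% c("sidechain", "backbone", "water", "protein", "structure", "all") &&
    length(toks) > 1) {
    stop("clause '", kw, "' takes no argument (at position ", pos, ")")
  }
  if (negate) !m else m
}

parse_resi_arg <- function(arg, pos) {
  parts <- strsplit(arg, ",")[[1]]
  out <- integer(0)
  for (p in parts) {
    if (grepl("^-?[0-9]+--?[0-9]+$", p) || grepl("^[0-9]+-[0-9]+$", p)) {
      ab <- as.integer(strsplit(p, "(?<=[0-9])-", perl = TRUE)[[1]])
      out <- c(out, seq(ab[1], ab[2]))
    } else if (grepl("^-?[0-9]+$", p)) {
      out <- c(out, as.integer(p))
    } else {
      stop("malformed residue range '", p, "' at position ", pos)
    }
  }
  out
}

# parse "A:82" / "A:82:B" residue-key strings
parse_reskey <- function(key) {
  parts <- strsplit(key, ":")[[1]]
  if (length(parts) < 2) stop("malformed residue key '", key, "' (expected chain:resno)")
  list(
    chain = parts[1],
    resno = as.integer(parts[2]),
    insert = if (length(parts) >= 3) parts[3] else ""
  )
}

residue_atom_rows <- function(s, key) {
  k <- if (is.character(key)) parse_reskey(key) else key
  which(s$atoms$chain == k$chain & s$atoms$resno == k$resno & s$atoms$insert == k$insert)
}
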