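# Idealized-geometry construction: NeRF atom placement, side-chain internal
# coordinate templates, and an extended-peptide builder.  These serve in-silico
# mutagenesis, the fully-exposed SASA reference tripeptides, and the synthetic
# fixture generators.  Geometry is idealized (standard bond lengths/angles,
# common rotamers), not energy-minimized.

unit3 <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < 1e-12) stop("zero-length vector in geometry construction")
  v / n
}

cross3 <- function(a, b) {
  c(
    a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1]
  )
}

# place atom d given positions a-b-c, bond length |cd|, angle b-c-d (deg) and
# dihedral a-b-c-d (deg): the natural-extension-reference-frame construction
place_atom <- function(a, b, c, dist, angle, dihedral) {
  ang <- angle * pi / 180
  dih <- dihedral * pi / 180
  bc <- unit3(c - b)
  n <- unit3(cross3(b - a, bc))
  m <- cross3(n, bc)
  d2 <- c(
    -dist * cos(ang),
    dist * sin(ang) * cos(dih),
    dist * sin(ang) * sin(dih)
  )
  c + d2[1] * bc + d2[2] * m + d2[3] * n
}

vec_angle <- function(a, b, c) {
  u <- unit3(a - b)
  v <- unit3(c - b)
  acos(max(-1, min(1, sum(u * v)))) * 180 / pi
}

# Side-chain templates: each atom placed by NeRF from three previously placed
# atoms (backbone N/CA/C or earlier side-chain atoms).  Chi defaults are the
# most common rotamer; angles/lengths are standard values.
SIDECHAIN_ZMAT <- list(
  ALA = list(),
  SER = list(list("OG", "CB", "CA", "N", 1.41, 110.8, 64)),
  CYS = list(list("SG", "CB", "CA", "N", 1.81, 114.4, -65)),
  THR = list(
    list("OG1", "CB", "CA", "N", 1.43, 109.6, 60),
    list("CG2", "CB", "CA", "N", 1.52, 110.5, -60)
  ),
  VAL = list(
    list("CG1", "CB", "CA", "N", 1.52, 110.5, 175),
    list("CG2", "CB", "CA", "N", 1.52, 110.5, 55)
  ),
  LEU = list(
    list("CG", "CB", "CA", "N", 1.53, 116.3, -65),
    list("CD1", "CG", "CB", "CA", 1.52, 110.7, 175),
    list("CD2", "CG", "CB", "CA", 1.52, 110.7, 55)
  ),
  ILE = list(
    list("CG1", "CB", "CA", "N", 1.53, 110.4, -65),
    list("CG2", "CB", "CA", "N", 1.52, 110.5, 170),
    list("CD1", "CG1", "CB", "CA", 1.51, 113.8, 170)
  ),
  PRO = list(
    list("CG", "CB", "CA", "N", 1.50, 104.0, 30),
    list("CD", "CG", "CB", "CA", 1.51, 105.0, -35)
  ),
  PHE = list(
    list("CG", "CB", "CA", "N", 1.50, 113.8, -65),
    list("CD1", "CG", "CB", "CA", 1.39, 120.8, 90),
    list("CD2", "CG", "CB", "CA", 1.39, 120.8, -90),
    list("CE1", "CD1", "CG", "CB", 1.39, 120.0, 180),
    list("CE2", "CD2", "CG", "CB", 1.39, 120.0, 180),
    list("CZ", "CE1", "CD1", "CG", 1.39, 120.0, 0)
  ),
  TYR = list(
    list("CG", "CB", "CA", "N", 1.50, 113.8, -65),
    list("CD1", "CG", "CB", "CA", 1.39, 120.8, 90),
    list("CD2", "CG", "CB", "CA", 1.39, 120.8, -90),
    list("CE1", "CD1", "CG", "CB", 1.39, 120.0, 180),
    list("CE2", "CD2", "CG", "CB", 1.39, 120.0, 180),
    list("CZ", "CE1", "CD1", "CG", 1.39, 120.0, 0),
    list("OH", "CZ", "CE1", "CD1", 1.38, 120.0, 180)
  ),
  TRP = list(
    list("CG", "CB", "CA", "N", 1.50, 113.6, -65),
    list("CD1", "CG", "CB", "CA", 1.37, 127.0, 90),
    list("CD2", "CG", "CB", "CA", 1.43, 126.6, -90),
    list("NE1", "CD1", "CG", "CB", 1.38, 110.0, 180),
    list("CE2", "CD2", "CG", "CB", 1.41, 107.0, 180),
    list("CE3", "CD2", "CG", "CB", 1.40, 133.9, 0),
    list("CZ2", "CE2", "CD2", "CG", 1.40, 122.4, 180),
    list("CZ3", "CE3", "CD2", "CG", 1.39, 118.6, 180),
    list("CH2", "CZ2", "CE2", "CD2", 1.37, 117.5, 0)
  ),
  ASP = list(
    list("CG", "CB", "CA", "N", 1.52, 113.0, -65),
    list("OD1", "CG", "CB", "CA", 1.25, 118.5, -15),
    list("OD2", "CG", "CB", "CA", 1.25, 118.5, 165)
  ),
  ASN = list(
    list("CG", "CB", "CA", "N", 1.52, 113.0, -65),
    list("OD1", "CG", "CB", "CA", 1.23, 120.8, -60),
    list("ND2", "CG", "CB", "CA", 1.32, 116.4, 120)
  ),
  GLU = list(
    list("CG", "CB", "CA", "N", 1.52, 114.0, -65),
    list("CD", "CG", "CB", "CA", 1.52, 114.0, 180),
    list("OE1", "CD", "CG", "CB", 1.25, 118.5, -15),
    list("OE2", "CD", "CG", "CB", 1.25, 118.5, 165)
  ),
  GLN = list(
    list("CG", "CB", "CA", "N", 1.52, 114.0, -65),
    list("CD", "CG", "CB", "CA", 1.52, 114.0, 180),
    list("OE1", "CD", "CG", "CB", 1.23, 120.8, -60),
    list("NE2", "CD", "CG", "CB", 1.32, 116.4, 120)
  ),
  MET = list(
    list("CG", "CB", "CA", "N", 1.52, 114.0, -65),
    list("SD", "CG", "CB", "CA", 1.80, 112.7, 180),
    list("CE", "SD", "CG", "CB", 1.79, 100.9, 180)
  ),
  LYS = list(
    list("CG", "CB", "CA", "N", 1.52, 114.0, -65),
    list("CD", "CG", "CB", "CA", 1.52, 111.3, 180),
    list("CE", "CD", "CG", "CB", 1.52, 111.3, 180),
    list("NZ", "CE", "CD", "CG", 1.49, 111.9, 180)
  ),
  ARG = list(
    list("CG", "CB", "CA", "N", 1.52, 114.0, -65),
    list("CD", "CG", "CB", "CA", 1.52, 111.3, 180),
    list("NE", "CD", "CG", "CB", 1.46, 112.0, 180),
    list("CZ", "NE", "CD", "CG", 1.33, 124.2, 180),
    list("NH1", "CZ", "NE", "CD", 1.33, 120.0, 0),
    list("NH2", "CZ", "NE", "CD", 1.33, 120.0, 180)
  ),
  HIS = list(
    list("CG", "CB", "CA", "N", 1.49, 113.8, -65),
    list("ND1", "CG", "CB", "CA", 1.38, 122.7, -75),
    list("CD2", "CG", "CB", "CA", 1.35, 131.0, 105),
    list("CE1", "ND1", "CG", "CB", 1.32, 109.0, 180),
    list("NE2", "CD2", "CG", "CB", 1.35, 107.0, 180)
  ),
  GLY = list()
)

# CB from backbone N/CA/C: ideal tetrahedral branch off the backbone plane
place_cb <- function(n, ca, c, dist = 1.53) {
  u <- unit3(n - ca)
  v <- unit3(c - ca)
  m <- unit3(-(u + v))
  nrm <- unit3(cross3(v, u)) # choice fixes L-configuration
  gamma <- vec_angle(n, ca, c) * pi / 180
  # want angle(N-CA-CB) = angle(C-CA-CB) = 110.5 deg
  alpha <- cos(110.5 * pi / 180) / (-cos(gamma / 2))
  alpha <- max(-1, min(1, alpha))
  beta <- sqrt(max(0, 1 - alpha^2))
  ca + dist * (alpha * m + beta * nrm)
}

# build the full idealized side chain (including CB) off an existing backbone;
# returns a named list of coordinates, possibly with per-atom chi overrides
build_sidechain <- function(resname, n, ca, c, chi_overrides = NULL) {
  if (!resname %in% names(SIDECHAIN_ZMAT)) {
    stop("no side-chain template for residue type ", resname)
  }
  pos <- list(N = n, CA = ca, C = c)
  out <- list()
  if (resname != "GLY") {
    cb <- place_cb(n, ca, c)
    pos$CB <- cb
    out$CB <- cb
  }
  for (row in SIDECHAIN_ZMAT[[resname]]) {
    nm <- row[[1]]
    dih <- row[[7]]
    if (!is.null(chi_overrides) && !is.null(chi_overrides[[nm]])) {
      dih <- chi_overrides[[nm]]
    }
    p <- place_atom(
      pos[[row[[4]]]], pos[[row[[3]]]], pos[[row[[2]]]],
      row[[5]], row[[6]], dih
    )
    pos[[nm]] <- p
    out[[nm]] <- p
  }
  out
}

# Extended-backbone peptide builder (phi = psi = 180, trans peptide bonds).
# Returns an atom data frame suitable for new_structure().
build_peptide <- function(resnames, resnos = seq_along(resnames), chain = "A",
                          origin = c(0, 0, 0), reverse = FALSE,
                          chi_overrides = NULL) {
  stopifnot(length(resnames) == length(resnos))
  rows <- list()
  # seed the first residue backbone in the xy-plane
  n1 <- origin
  ca1 <- origin + c(1.46, 0, 0)
  c1 <- ca1 + 1.52 * c(cos(69 * pi / 180), sin(69 * pi / 180), 0)
  prev <- list(N = n1, CA = ca1, C = c1)
  for (i in seq_along(resnames)) {
    if (i > 1) {
      n <- place_atom(prev$N, prev$CA, prev$C, 1.33, 116.2, 180) # psi
      ca <- place_atom(prev$CA, prev$C, n, 1.46, 121.7, 180) # omega
      c <- place_atom(prev$C, n, ca, 1.52, 111.0, 180) # phi
    } else {
      n <- prev$N
      ca <- prev$CA
      c <- prev$C
    }
    o <- place_atom(n, ca, c, 1.23, 120.5, 0)
    res <- resnames[i]
    atoms <- list(N = n, CA = ca, C = c, O = o)
    sc <- build_sidechain(res, n, ca, c, chi_overrides = chi_overrides)
    atoms <- c(atoms, sc)
    for (nm in names(atoms)) {
      rows[[length(rows) + 1]] <- data.frame(
        name = nm, resname = res, chain = chain, resno = resnos[i],
        x = atoms[[nm]][1], y = atoms[[nm]][2], z = atoms[[nm]][3],
        stringsAsFactors = FALSE
      )
    }
    prev <- list(N = n, CA = ca, C = c)
  }
  df <- do.call(rbind, rows)
  if (reverse) df$x <- -df$x
  df$x <- df$x + 0 # keep numeric
  df
}

#' Extended Gly-X-Gly tripeptide
#'
#' Builds the extended tripeptide used for the fully-exposed SASA reference
#' (see [max_sasa_reference()]).
#'
#' @param center_resname three-letter code of the central residue.
#' @param resnos residue numbers (length 3).
#' @param chain chain identifier.
#' @return a Structure with three residues in an extended conformation.
#' @export
build_tripeptide <- function(center_resname, resnos = 1:3, chain = "A") {
  atoms <- build_peptide(c("GLY", center_resname, "GLY"), resnos = resnos, chain = chain)
  new_structure(atoms)
}
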