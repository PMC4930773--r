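# Shrake-Rupley solvent accessible surface area and spatial aggregation
# propensity (SAP).  Sphere points come from a deterministic Fibonacci
# lattice, so areas are bit-reproducible with no random seed.

fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

# Rotation that re-seeds the test-point directions in a frame derived from the
# structure itself (principal axes, signs fixed by third central moments).
# The frame transforms covariantly under rigid motion -- if the coordinates
# are rotated by R the frame rotates by R too -- so per-atom point geometry,
# and hence SASA, is invariant under rigid motion up to round-off rather than
# up to lattice discretization.
canonical_frame <- function(xyz) {
  n <- nrow(xyz)
  if (n < 3) {
    return(diag(3))
  }
  ctr <- colMeans(xyz)
  x0 <- sweep(xyz, 2, ctr)
  ev <- eigen(crossprod(x0) / n, symmetric = TRUE)
  v <- ev$vectors
  scl <- sqrt(mean(x0^2)) + 1e-12
  for (k in 1:3) {
    pr <- x0 %*% v[, k]
    m3 <- sum(pr^3)
    if (abs(m3) > 1e-8 * n * scl^3) {
      sgn <- sign(m3)
    } else {
      nz <- pr[abs(pr) > 1e-8 * scl]
      sgn <- if (length(nz) > 0) sign(nz[1]) else 1
    }
    v[, k] <- v[, k] * sgn
  }
  if (det(v) < 0) v[, 3] <- -v[, 3]
  v
}

#' Solvent accessible surface area (Shrake-Rupley)
#'
#' For every atom, the fraction of quasi-uniform test points on the sphere of
#' radius `vdw + probe_radius` that fall inside no neighbouring expanded
#' sphere, times the analytic sphere area.  Waters are excluded (neither
#' scored nor occluding) unless `include_waters = TRUE`; hydrogens are used as
#' occluders when present.
#'
#' @param s Structure with radii assigned (see [assign_radii()]).
#' @param probe_radius probe sphere radius in angstroms (default 1.4, water).
#' @param n_points test points per atom (default 960; at least 92).
#' @param include_waters score and occlude with water atoms.
#' @param frame optional 3x3 rotation for the test-point directions.  By
#'   default a canonical frame is derived from the scored coordinates; pass a
#'   shared frame when areas from separate calls must cancel exactly (see
#'   [delta_saa()]).
#' @return object of class `SasaResult`: list with `atom_table`
#'   (chain/resno/insert/resname/name/area), `residue_table` (summed per
#'   residue), `probe_radius`, `n_points`.
#' @export
sasa <- function(s, probe_radius = 1.4, n_points = 960, include_waters = FALSE,
                 frame = NULL) {
  stopifnot(n_points >= 92, probe_radius >= 0)
  a <- s$atoms
  keep <- if (include_waters) rep(TRUE, nrow(a)) else !a$is_water
  a <- a[keep, , drop = FALSE]
  if (any(is.na(a$vdw))) stop("configuration error: atoms without vdW radii; call assign_radii() first")
  xyz <- as.matrix(a[, c("x", "y", "z")])
  r_exp <- a$vdw + probe_radius
  if (is.null(frame)) frame <- canonical_frame(xyz)
  pts <- fibonacci_sphere(n_points) %*% t(frame)
  n <- nrow(a)
  area <- numeric(n)
  max_reach <- max(r_exp)
  for (i in seq_len(n)) {
    di <- sqrt(colSums((t(xyz) - xyz[i, ])^2))
    nb <- which(di < r_exp[i] + r_exp & di > 1e-9)
    sp <- pts * r_exp[i]
    sp <- sweep(sp, 2, xyz[i, ], "+")
    acc <- rep(TRUE, n_points)
    for (j in nb) {
      dd <- (sp[, 1] - xyz[j, 1])^2 + (sp[, 2] - xyz[j, 2])^2 + (sp[, 3] - xyz[j, 3])^2
      acc <- acc & dd > r_exp[j]^2
      if (!any(acc)) break
    }
    area[i] <- mean(acc) * 4 * pi * r_exp[i]^2
  }
  atom_table <- data.frame(
    chain = a$chain, resno = a$resno, insert = a$insert,
    resname = a$resname, name = a$name, is_sidechain = a$is_sidechain,
    area = area, stringsAsFactors = FALSE
  )
  key <- paste(a$chain, a$resno, a$insert, sep = "|")
  agg <- tapply(area, key, sum)
  first <- !duplicated(key)
  residue_table <- data.frame(
    chain = a$chain[first], resno = a$resno[first], insert = a$insert[first],
    resname = a$resname[first],
    area = as.numeric(agg[match(key[first], names(agg))])
  )
  rownames(residue_table) <- NULL
  structure(
    list(
      atom_table = atom_table, residue_table = residue_table,
      probe_radius = probe_radius, n_points = n_points
    ),
    class = "SasaResult"
  )
}

#' Total solvent accessible surface area
#'
#' @param sr a `SasaResult` from [sasa()].
#' @return total area in square angstroms.
#' @export
total_sasa <- function(sr) sum(sr$atom_table$area)

subset_structure <- function(s, rows) {
  if (length(rows) == 0) stop("selection error: empty atom subset")
  out <- s
  out$atoms <- s$atoms[rows, , drop = FALSE]
  rownames(out$atoms) <- NULL
  out
}

#' Dimer versus monomer solvent accessible area
#'
#' Computes the total SASA of the assembled dimer and of each chain taken in
#' isolation; the buried interface area is
#' `saa(chain A) + saa(chain B) - saa(dimer)`.
#'
#' @param dimer two-chain Structure with radii assigned.
#' @param chain_a,chain_b chain identifiers.
#' @param ... passed to [sasa()].
#' @return list with `saa_dimer`, `saa_monomers` (sum of the two isolated
#'   chains) and `buried` (all in square angstroms).
#' @export
delta_saa <- function(dimer, chain_a, chain_b, ...) {
  a_rows <- which(dimer$atoms$chain == chain_a & !dimer$atoms$is_water)
  b_rows <- which(dimer$atoms$chain == chain_b & !dimer$atoms$is_water)
  if (length(a_rows) == 0) stop("selection error: chain ", chain_a, " absent")
  if (length(b_rows) == 0) stop("selection error: chain ", chain_b, " absent")
  # one shared point frame (from the assembled dimer) so that the monomer and
  # dimer discretizations cancel exactly when the chains do not touch
  ab <- c(a_rows, b_rows)
  fr <- canonical_frame(as.matrix(dimer$atoms[ab, c("x", "y", "z")]))
  sd_ <- total_sasa(sasa(subset_structure(dimer, ab), frame = fr, ...))
  sa <- total_sasa(sasa(subset_structure(dimer, a_rows), frame = fr, ...))
  sb <- total_sasa(sasa(subset_structure(dimer, b_rows), frame = fr, ...))
  list(saa_dimer = sd_, saa_monomers = sa + sb, buried = sa + sb - sd_)
}

#' Fully-exposed reference SASA per residue type
#'
#' Side-chain atom SASA (plus C-alpha for glycine, which stands in for its
#' absent side chain) of the central residue in an extended Gly-X-Gly
#' tripeptide, computed by this package's own surface engine so that SAP
#' exposure ratios are self-consistent with the radii and point set in use.
#' The table shipped in `extdata` was produced with the default parameters;
#' `recompute = TRUE` rebuilds it from scratch.
#'
#' @param probe_radius,n_points as in [sasa()].
#' @param recompute rebuild instead of using the shipped table.
#' @return data frame `resname`, `name`, `area` (square angstroms).
#' @export
max_sasa_reference <- function(probe_radius = 1.4, n_points = 960, recompute = FALSE) {
  default_call <- probe_radius == 1.4 && n_points == 960
  if (!recompute && default_call) {
    return(read_extdata("max_sasa_gxg.csv"))
  }
  key <- sprintf("maxsasa:%g:%d", probe_radius, n_points)
  if (!is.null(.loopgate_cache[[key]])) {
    return(.loopgate_cache[[key]])
  }
  rows <- list()
  for (res in STANDARD_AA) {
    tri <- assign_radii(build_tripeptide(res), "bondi")
    sr <- sasa(tri, probe_radius = probe_radius, n_points = n_points)
    at <- sr$atom_table
    central <- at$resno == 2
    sel <- central & (at$is_sidechain | (res == "GLY" & at$name == "CA"))
    rows[[res]] <- data.frame(
      resname = res, name = at$name[sel], area = at$area[sel],
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  .loopgate_cache[[key]] <- out
  out
}

#' Spatial aggregation propensity (SAP)
#'
#' For each atom i, SAP(i) sums, over all side-chain atoms j within
#' `radius_R` of i (glycine's C-alpha standing in for its side chain), the
#' relative solvent exposure of j (its SASA divided by the fully-exposed
#' reference SASA of the same atom in an extended Gly-X-Gly tripeptide)
#' weighted by the side-chain hydrophobicity of j's residue.  Positive SAP
#' marks exposed hydrophobic patches; hydrophilic residues can score negative.
#' The per-residue score is the mean over the residue's side-chain atoms.
#'
#' @param s Structure with radii assigned.
#' @param sasa_res `SasaResult` computed on `s` (same atoms, same engine).
#' @param radius_R neighbourhood radius in angstroms (default 10; 5 is the
#'   common alternative for finer patches).
#' @param scale hydrophobicity scale name (see [hydrophobicity_scale()]).
#' @return object of class `SapResult`: list with `atom_table` (per-atom
#'   `sap`), `residue_table` (per-residue `sap`), `radius_R`, `scale_name`.
#' @export
sap <- function(s, sasa_res = NULL, radius_R = 10, scale = "black_mould") {
  if (is.null(sasa_res)) sasa_res <- sasa(s)
  hydro <- hydrophobicity_scale(scale)
  at <- sasa_res$atom_table
  bad <- setdiff(unique(at$resname), names(hydro))
  if (length(bad) > 0) {
    stop("configuration error: hydrophobicity scale lacks residue type(s) ", paste(bad, collapse = ", "))
  }
  ref <- max_sasa_reference(sasa_res$probe_radius, sasa_res$n_points)
  a <- s$atoms[!s$atoms$is_water, , drop = FALSE]
  if (nrow(a) != nrow(at)) stop("sasa result does not match structure atom set")
  xyz <- as.matrix(a[, c("x", "y", "z")])

  contrib_mask <- at$is_sidechain | (at$resname == "GLY" & at$name == "CA")
  jdx <- which(contrib_mask)
  ref_area <- ref$area[match(
    paste(at$resname[jdx], at$name[jdx]),
    paste(ref$resname, ref$name)
  )]
  missing_ref <- is.na(ref_area)
  if (any(missing_ref)) {
    stop(
      "configuration error: no fully-exposed reference for atom(s) ",
      paste(unique(paste(at$resname[jdx][missing_ref], at$name[jdx][missing_ref])), collapse = ", ")
    )
  }
  w <- (at$area[jdx] / ref_area) * hydro[at$resname[jdx]]
  xyz_j <- xyz[jdx, , drop = FALSE]

  n <- nrow(a)
  sap_atom <- numeric(n)
  r2 <- radius_R^2
  for (i in seq_len(n)) {
    d2 <- (xyz_j[, 1] - xyz[i, 1])^2 + (xyz_j[, 2] - xyz[i, 2])^2 + (xyz_j[, 3] - xyz[i, 3])^2
    sap_atom[i] <- sum(w[d2 <= r2])
  }
  atom_table <- data.frame(
    chain = at$chain, resno = at$resno, insert = at$insert,
    resname = at$resname, name = at$name, sap = sap_atom,
    stringsAsFactors = FALSE
  )
  key <- paste(at$chain, at$resno, at$insert, sep = "|")
  res_mask <- contrib_mask
  agg <- tapply(sap_atom[res_mask], key[res_mask], mean)
  first <- !duplicated(key)
  residue_table <- data.frame(
    chain = at$chain[first], resno = at$resno[first], insert = at$insert[first],
    resname = at$resname[first],
    sap = as.numeric(agg[match(key[first], names(agg))])
  )
  rownames(residue_table) <- NULL
  structure(
    list(
      atom_table = atom_table, residue_table = residue_table,
      radius_R = radius_R, scale_name = scale
    ),
    class = "SapResult"
  )
}

#' Residues gaining positive SAP in a mutant
#'
#' Selection rule for extra exposed aggregation-prone residues: residues whose
#' mutant per-residue SAP is positive and larger than in the wild type, ranked
#' by the SAP increase in descending order.
#'
#' @param wt,mut `SapResult` objects over the same residue topology.
#' @return data frame `chain`, `resno`, `insert`, `resname`, `sap_wt`,
#'   `sap_mut`, `delta`, ranked by `delta` descending.
#' @export
delta_sap_selection <- function(wt, mut) {
  kw <- paste(wt$residue_table$chain, wt$residue_table$resno, wt$residue_table$insert, sep = "|")
  km <- paste(mut$residue_table$chain, mut$residue_table$resno, mut$residue_table$insert, sep = "|")
  if (length(kw) != length(km) || !all(kw == km)) {
    stop("comparison error: residue topologies differ between the two SAP results")
  }
  out <- wt$residue_table[, c("chain", "resno", "insert", "resname")]
  out$sap_wt <- wt$residue_table$sap
  out$sap_mut <- mut$residue_table$sap
  out$delta <- out$sap_mut - out$sap_wt
  out <- out[!is.na(out$sap_mut) & out$sap_mut > 0 & out$delta > 0, , drop = FALSE]
  out <- out[order(-out$delta), ]
  rownames(out) <- NULL
  out
}
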