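#' Optimal rigid-body superposition (Kabsch algorithm)
#'
#' Least-squares optimal proper rotation and translation mapping `mobile` onto
#' `reference`, via singular value decomposition of the cross-covariance
#' matrix with the determinant sign correction that excludes reflections.
#'
#' @param reference n x 3 coordinate matrix (angstroms).
#' @param mobile n x 3 coordinate matrix, paired row-by-row with `reference`.
#' @return object of class `SuperpositionResult`: list with `rotation` (3 x 3,
#'   det = +1), `translation` (length 3), `rmsd` (post-fit, angstroms) and
#'   `atom_count`.  The fitted mobile coordinates are
#'   `mobile %*% t(rotation) + translation` (rows).
#' @export
kabsch_superpose <- function(reference, mobile) {
  reference <- as.matrix(reference)
  mobile <- as.matrix(mobile)
  if (nrow(reference) != nrow(mobile)) {
    stop("pairing error: reference has ", nrow(reference), " atoms, mobile ", nrow(mobile))
  }
  n <- nrow(reference)
  if (n < 3) stop("need at least 3 paired atoms for superposition")
  cr <- colMeans(reference)
  cm <- colMeans(mobile)
  P <- sweep(mobile, 2, cm)
  Q <- sweep(reference, 2, cr)
  if (svd(P)$d[2] < 1e-8 || svd(Q)$d[2] < 1e-8) {
    stop("conditioning error: degenerate (collinear) point set")
  }
  H <- t(P) %*% Q
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  fitted <- P %*% t(R)
  rmsd <- sqrt(mean(rowSums((fitted - Q)^2)))
  structure(
    list(
      rotation = R,
      translation = as.numeric(cr - R %*% cm),
      rmsd = rmsd,
      atom_count = n
    ),
    class = "SuperpositionResult"
  )
}

apply_superposition <- function(xyz, fit) {
  sweep(as.matrix(xyz) %*% t(fit$rotation), 2, fit$translation, "+")
}

# paired atom row indices (ref, mob) matched by chain/resno/insert/atom-name
matched_atom_rows <- function(reference, mobile, scope = c("CA", "backbone", "heavy")) {
  scope <- match.arg(scope)
  pick <- function(a) {
    keep <- !a$is_water & !toupper(a$element) %in% "H"
    if (scope == "CA") keep <- keep & a$name == "CA"
    if (scope == "backbone") keep <- keep & a$name %in% c("N", "CA", "C", "O")
    keep
  }
  ra <- reference$atoms
  ma <- mobile$atoms
  rk <- paste(ra$chain, ra$resno, ra$insert, ra$name, sep = "|")
  mk <- paste(ma$chain, ma$resno, ma$insert, ma$name, sep = "|")
  ri <- which(pick(ra))
  common <- intersect(rk[ri], mk[pick(ma)])
  ri <- ri[rk[ri] %in% common]
  mi <- match(rk[ri], mk)
  list(ref = ri, mob = mi)
}

#' Per-residue RMSD between two structures
#'
#' The mobile structure is first globally superposed onto the reference using
#' the fit selection (default: all shared C-alpha atoms), then an RMSD is
#' evaluated per shared residue over the scope atoms.  Residues are shared when
#' chain, residue number and insertion code coincide; atoms are paired by name,
#' so a point mutant still yields a value at the mutated position from the
#' atoms the two residue types have in common.
#'
#' @param reference,mobile `Structure` objects.
#' @param atom_scope `"CA"` (default), `"backbone"` or `"heavy"`.
#' @param fit_selection selection expression (see [select_atoms()]) defining
#'   the superposition atoms on the reference; `NULL` fits on all shared CA.
#' @return object of class `PerResidueRMSD`: data frame with columns `chain`,
#'   `resno`, `insert`, `resname`, `rmsd` plus attributes `scope` and `fit`.
#' @export
per_residue_rmsd <- function(reference, mobile, atom_scope = c("CA", "backbone", "heavy"),
                             fit_selection = NULL) {
  atom_scope <- match.arg(atom_scope)
  fit_pairs <- matched_atom_rows(reference, mobile, "CA")
  if (!is.null(fit_selection)) {
    sel <- attr(select_atoms(reference, fit_selection), "idx")
    keep <- fit_pairs$ref %in% sel
    fit_pairs <- list(ref = fit_pairs$ref[keep], mob = fit_pairs$mob[keep])
  }
  if (length(fit_pairs$ref) < 3) stop("alignment error: fewer than 3 shared fit atoms")
  fit <- kabsch_superpose(
    coords(reference)[fit_pairs$ref, , drop = FALSE],
    coords(mobile)[fit_pairs$mob, , drop = FALSE]
  )
  mob_xyz <- apply_superposition(coords(mobile), fit)
  ref_xyz <- coords(reference)

  pairs <- matched_atom_rows(reference, mobile, atom_scope)
  if (length(pairs$ref) == 0) stop("alignment error: no shared residues in scope")
  ra <- reference$atoms[pairs$ref, ]
  key <- paste(ra$chain, ra$resno, ra$insert, sep = "|")
  d2 <- rowSums((ref_xyz[pairs$ref, , drop = FALSE] - mob_xyz[pairs$mob, , drop = FALSE])^2)
  agg <- tapply(d2, key, mean)
  first <- !duplicated(key)
  out <- data.frame(
    chain = ra$chain[first], resno = ra$resno[first], insert = ra$insert[first],
    resname = ra$resname[first],
    rmsd = sqrt(as.numeric(agg[match(key[first], names(agg))]))
  )
  out <- out[order(out$chain, out$resno, out$insert), ]
  rownames(out) <- NULL
  attr(out, "scope") <- atom_scope
  attr(out, "fit_rmsd") <- fit$rmsd
  class(out) <- c("PerResidueRMSD", "data.frame")
  out
}

#' Select perturbed residue regions from a per-residue RMSD profile
#'
#' Implements a fixed-threshold rule: maximal runs of consecutive residue
#' numbers (within a chain) whose RMSD exceeds `threshold`, kept when at least
#' `min_run` residues long.  This is a descriptive selection, not a statistical
#' test; no multiplicity correction applies.
#'
#' @param prr `PerResidueRMSD` (or a data frame with `chain`, `resno`, `rmsd`).
#' @param threshold RMSD threshold in angstroms (default 2, the conventional
#'   significance cut for structural divergence between relaxed structures).
#' @param min_run minimum run length (default 3, suppressing single-residue
#'   noise).
#' @return data frame of regions: `chain`, `start`, `end`, `length`,
#'   `max_rmsd`; zero rows when nothing exceeds the threshold.
#' @export
select_perturbed_regions <- function(prr, threshold = 2, min_run = 3) {
  stopifnot(threshold > 0, min_run >= 1)
  out <- data.frame(
    chain = character(0), start = integer(0), end = integer(0),
    length = integer(0), max_rmsd = numeric(0)
  )
  for (ch in unique(prr$chain)) {
    sub <- prr[prr$chain == ch, ]
    sub <- sub[order(sub$resno), ]
    hot <- sub$resno[sub$rmsd > threshold]
    if (length(hot) == 0) next
    brk <- c(0, which(diff(hot) != 1), length(hot))
    for (k in seq_len(length(brk) - 1)) {
      run <- hot[(brk[k] + 1):brk[k + 1]]
      if (length(run) >= min_run) {
        out <- rbind(out, data.frame(
          chain = ch, start = min(run), end = max(run), length = length(run),
          max_rmsd = max(sub$rmsd[sub$resno %in% run])
        ))
      }
    }
  }
  rownames(out) <- NULL
  out
}

#' Inter-loop gate distance series
#'
#' Euclidean C-alpha to C-alpha distance, per frame, for one residue pair in
#' the N-terminal domain and its structural equivalent in the C-terminal
#' domain.  Distances are internal coordinates, so no superposition is applied
#' or needed.
#'
#' @param x `Ensemble` or single `Structure`.
#' @param pair_ntd,pair_ctd character vectors of two residue keys
#'   (`"chain:resno"`), e.g. `c("A:82", "A:108")` and `c("A:173", "A:200")`.
#' @return object of class `LoopGapSeries`: list with per-frame `distances_ntd`
#'   and `distances_ctd` and their arithmetic `mean_ntd`, `mean_ctd`
#'   (angstroms).
#' @export
loop_gap <- function(x, pair_ntd = c("A:82", "A:108"), pair_ctd = c("A:173", "A:200")) {
  frames <- if (inherits(x, "Ensemble")) x$frames else list(x)
  dist_pair <- function(f, pair) {
    k1 <- parse_reskey(pair[1])
    k2 <- parse_reskey(pair[2])
    p1 <- ca_xyz(f, k1$chain, k1$resno, k1$insert)
    p2 <- ca_xyz(f, k2$chain, k2$resno, k2$insert)
    sqrt(sum((p1 - p2)^2))
  }
  d_ntd <- vapply(frames, dist_pair, numeric(1), pair = pair_ntd)
  d_ctd <- vapply(frames, dist_pair, numeric(1), pair = pair_ctd)
  structure(
    list(
      pair_ntd = pair_ntd, pair_ctd = pair_ctd,
      distances_ntd = d_ntd, distances_ctd = d_ctd,
      mean_ntd = mean(d_ntd), mean_ctd = mean(d_ctd)
    ),
    class = "LoopGapSeries"
  )
}

#' @export
print.LoopGapSeries <- function(x, ...) {
  cat(
    "Gate-loop Ca-Ca distances over", length(x$distances_ntd), "frame(s)\n",
    " NTD pair", paste(x$pair_ntd, collapse = "-"), ": mean",
    sprintf("%.2f", x$mean_ntd), "Å\n",
    " CTD pair", paste(x$pair_ctd, collapse = "-"), ": mean",
    sprintf("%.2f", x$mean_ctd), "Å\n"
  )
  invisible(x)
}

#' Per-residue root-mean-square fluctuation over an ensemble
#'
#' Each frame is superposed onto the first frame on the fit selection (default
#' all shared CA), then the RMSF of each atom about its ensemble-mean position
#' is computed and averaged over the scope atoms of each residue.
#'
#' @param ensemble `Ensemble` with at least 2 frames.
#' @param atom_scope `"CA"` (default), `"backbone"` or `"heavy"`.
#' @param fit_selection optional selection expression for the fit atoms.
#' @return data frame `chain`, `resno`, `insert`, `resname`, `rmsf` (angstroms).
#' @export
rmsf <- function(ensemble, atom_scope = c("CA", "backbone", "heavy"), fit_selection = NULL) {
  atom_scope <- match.arg(atom_scope)
  if (!inherits(ensemble, "Ensemble") || length(ensemble$frames) < 2) {
    stop("insufficient frames: RMSF needs an Ensemble with >= 2 frames")
  }
  ref <- ensemble$frames[[1]]
  fit_idx <- which(ref$atoms$name == "CA" & !ref$atoms$is_water)
  if (!is.null(fit_selection)) {
    fit_idx <- intersect(fit_idx, attr(select_atoms(ref, fit_selection), "idx"))
  }
  if (length(fit_idx) < 3) stop("fewer than 3 fit atoms")
  ref_xyz <- coords(ref)
  fitted <- lapply(ensemble$frames, function(f) {
    xyz <- coords(f)
    fit <- kabsch_superpose(ref_xyz[fit_idx, , drop = FALSE], xyz[fit_idx, , drop = FALSE])
    apply_superposition(xyz, fit)
  })
  arr <- simplify2array(fitted) # natoms x 3 x nframes
  mean_xyz <- apply(arr, c(1, 2), mean)
  dev2 <- sapply(seq_along(fitted), function(i) rowSums((arr[, , i] - mean_xyz)^2))
  atom_rmsf <- sqrt(rowMeans(dev2))

  a <- ref$atoms
  keep <- !a$is_water & toupper(a$element) != "H"
  if (atom_scope == "CA") keep <- keep & a$name == "CA"
  if (atom_scope == "backbone") keep <- keep & a$name %in% c("N", "CA", "C", "O")
  key <- paste(a$chain, a$resno, a$insert, sep = "|")
  agg <- tapply(atom_rmsf[keep], key[keep], mean)
  kidx <- which(keep)
  firstk <- kidx[!duplicated(key[kidx])]
  out <- data.frame(
    chain = a$chain[firstk], resno = a$resno[firstk], insert = a$insert[firstk],
    resname = a$resname[firstk],
    rmsf = as.numeric(agg[match(key[firstk], names(agg))])
  )
  out <- out[order(out$chain, out$resno, out$insert), ]
  rownames(out) <- NULL
  out
}
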