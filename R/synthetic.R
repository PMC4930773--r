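# Seed-deterministic synthetic fixtures.  The structures use real amino-acid
# atom naming (so selection, SASA typing, H-bond typing run unmodified) with
# idealized geometry; they emulate the layout of a two-domain beta-crystallin
# subunit -- each domain's hydrophobic core shielded by a pair of interacting
# "gate" loops -- without pretending to be physically plausible proteins.

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)) {
    get(".Random.seed", envir = .GlobalEnv)
  } else {
    NULL
  }
  on.exit({
    if (!is.null(old)) {
      assign(".Random.seed", old, envir = .GlobalEnv)
    } else if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)) {
      rm(".Random.seed", envir = .GlobalEnv)
    }
  })
  set.seed(seed)
  force(expr)
}

rot_about_axis <- function(axis, angle) {
  u <- unit3(axis)
  c_ <- cos(angle)
  s_ <- sin(angle)
  ux <- u[1]
  uy <- u[2]
  uz <- u[3]
  matrix(c(
    c_ + ux^2 * (1 - c_), ux * uy * (1 - c_) - uz * s_, ux * uz * (1 - c_) + uy * s_,
    uy * ux * (1 - c_) + uz * s_, c_ + uy^2 * (1 - c_), uy * uz * (1 - c_) - ux * s_,
    uz * ux * (1 - c_) - uy * s_, uz * uy * (1 - c_) + ux * s_, c_ + uz^2 * (1 - c_)
  ), 3, 3, byrow = TRUE)
}

# rotation taking unit vector u onto unit vector v
rot_between <- function(u, v) {
  u <- unit3(u)
  v <- unit3(v)
  d <- max(-1, min(1, sum(u * v)))
  if (d > 1 - 1e-12) {
    return(diag(3))
  }
  if (d < -1 + 1e-12) {
    p <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    ax <- unit3(cross3(u, p))
    return(rot_about_axis(ax, pi))
  }
  rot_about_axis(cross3(u, v), acos(d))
}

atom_xyz <- function(df, resno, name) {
  r <- df[df$resno == resno & df$name == name, ]
  if (nrow(r) == 0) stop("atom ", name, " of residue ", resno, " not found in fragment")
  as.numeric(r[1, c("x", "y", "z")])
}

translate_df <- function(df, v) {
  df$x <- df$x + v[1]
  df$y <- df$y + v[2]
  df$z <- df$z + v[3]
  df
}

transform_df <- function(df, rot = diag(3), trans = c(0, 0, 0), center = c(0, 0, 0)) {
  xyz <- as.matrix(df[, c("x", "y", "z")])
  xyz <- sweep(sweep(xyz, 2, center) %*% t(rot), 2, center + trans, "+")
  df$x <- xyz[, 1]
  df$y <- xyz[, 2]
  df$z <- xyz[, 3]
  df
}

# rotate a residue's side chain rigidly about its CA so that the tip atom ends
# up exactly `target_dist` from `target`; the rotated tip stays in the plane
# spanned by the CA->target direction and a deterministic perpendicular
aim_sidechain_df <- function(df, resno, tip_atom, target, target_dist) {
  ca <- atom_xyz(df, resno, "CA")
  tip <- atom_xyz(df, resno, tip_atom)
  L <- sqrt(sum((tip - ca)^2))
  D <- sqrt(sum((target - ca)^2))
  if (target_dist < abs(D - L) - 1e-9 || target_dist > D + L + 1e-9) {
    stop(
      "construction error: cannot aim ", tip_atom, " of residue ", resno,
      " (|CA-target| = ", round(D, 2), ", side-chain reach = ", round(L, 2), ")"
    )
  }
  cth <- (D^2 + L^2 - target_dist^2) / (2 * D * L)
  cth <- max(-1, min(1, cth))
  th <- acos(cth)
  base <- unit3(target - ca)
  p <- cross3(base, c(0, 0, 1))
  if (sqrt(sum(p^2)) < 1e-6) p <- cross3(base, c(1, 0, 0))
  p <- unit3(p)
  new_dir <- base * cos(th) + cross3(p, base) * sin(th)
  R <- rot_between(tip - ca, new_dir * L)
  sc <- df$resno == resno & !(df$name %in% c("N", "CA", "C", "O", "OXT"))
  xyz <- as.matrix(df[sc, c("x", "y", "z")])
  xyz <- sweep(sweep(xyz, 2, ca) %*% t(R), 2, ca, "+")
  df[sc, c("x", "y", "z")] <- xyz
  df
}

# anchor-centered loop sequence: Ala/Gly alternation with a named residue in
# the middle
loop_sequence <- function(anchor_resname, anchor_resno, n) {
  if (n %% 2 == 0) n <- n + 1
  half <- (n - 1) / 2
  resnos <- (anchor_resno - half):(anchor_resno + half)
  resnames <- rep(c("ALA", "GLY"), length.out = n)
  resnames[half + 1] <- anchor_resname
  list(resnames = resnames, resnos = resnos)
}

#' Synthetic two-domain gate-loop structure
#'
#' Builds a toy beta-crystallin-like subunit (chain A) in which each of two
#' "domains" carries a pair of interacting loops whose designated C-alpha
#' separation equals `gap` exactly: residues N82/N108 in the N-terminal
#' domain and S173/G200 in the C-terminal domain.  The C-terminal cluster
#' additionally plants the serine tether of the last beta-strand: S228 forms
#' two backbone hydrogen bonds with Y196 and side-chain contacts with Y198
#' and Y201, the network a Ser-to-Pro substitution at 228 dismantles.  A
#' short hydrophobic segment (L185-V189) sits between the C-terminal loops as
#' the plantable core for water-penetration fixtures, and the interface
#' residues D169/D170 and R231/R233 are present for dimer fixtures.
#'
#' Construction is fully deterministic; `seed` is accepted for interface
#' uniformity but unused.
#'
#' @param gap planted C-alpha gate distance in angstroms (> 2); scalar or
#'   length 2 (NTD, CTD).
#' @param n_residues_per_loop residues per N-terminal-domain loop (odd,
#'   default 7).
#' @param seed unused; the builder is deterministic.
#' @return list with `structure` (a `Structure`) and `manifest` (planted
#'   ground truth).
#' @export
make_gate_structure <- function(gap = 6.2, n_residues_per_loop = 7, seed = NULL) {
  if (any(gap <= 2)) stop("construction error: gap must exceed 2 Å")
  if (length(gap) == 1) gap <- c(gap, gap)
  gap_ntd <- gap[1]
  gap_ctd <- gap[2]
  if (n_residues_per_loop < 3) stop("construction error: loops need at least 3 residues")

  # --- C-terminal cluster ------------------------------------------------
  # strand with Y196/Y198 and loop start P199
  a1 <- build_peptide(c("ALA", "TYR", "GLY", "TYR", "PRO"), resnos = 195:199)
  # last beta-strand with S228 and the interface arginines R231/R233
  bst <- build_peptide(
    c("ALA", "GLY", "SER", "ALA", "GLY", "ARG", "ALA", "ARG"),
    resnos = 226:233
  )
  o196 <- atom_xyz(a1, 196, "O")
  n196 <- atom_xyz(a1, 196, "N")

  # antiparallel pairing: run the 226-233 strand opposite to 195-199 so the
  # reciprocal backbone bonds N228->O196 and N196->O228 are both reachable
  bst <- transform_df(bst, rot_about_axis(c(0, 0, 1), pi),
    center = colMeans(as.matrix(bst[, c("x", "y", "z")]))
  )
  # translate the strand so S228's amide N sits 2.9 A from the Y196 carbonyl
  # O, approaching from below and slightly behind so the donor angle clears 90
  u <- unit3(c(-0.45, 0, -1))
  bst <- translate_df(bst, (o196 + 2.9 * u) - atom_xyz(bst, 228, "N"))
  # keep the strand's side chains pointing up toward the 196-199 strand
  if (atom_xyz(bst, 228, "CB")[3] < atom_xyz(bst, 228, "CA")[3]) {
    ca228 <- atom_xyz(bst, 228, "CA")
    bst <- transform_df(bst, rot_about_axis(c(1, 0, 0), pi), center = ca228)
    bst <- translate_df(bst, (o196 + 2.9 * u) - atom_xyz(bst, 228, "N"))
  }
  # re-aim the S228 carbonyl toward the Y196 amide for the second backbone bond
  c228 <- atom_xyz(bst, 228, "C")
  bst[bst$resno == 228 & bst$name == "O", c("x", "y", "z")] <-
    as.list(c228 + 1.23 * unit3(n196 - c228))
  o228 <- atom_xyz(bst, 228, "O")

  # S228 OG aimed at Y198's hydroxyl: first swing the Y198 ring toward CB228,
  # then drop OG on the CB->OH segment at the standard 1.41 A bond length
  cb228 <- atom_xyz(bst, 228, "CB")
  a1 <- aim_sidechain_df(a1, 198, "OH", cb228, 1.41 + 2.85)
  oh198 <- atom_xyz(a1, 198, "OH")
  bst[bst$resno == 228 & bst$name == "OG", c("x", "y", "z")] <-
    as.list(cb228 + 1.41 * unit3(oh198 - cb228))

  # returning strand of the hairpin, carrying G200 and Y201; positioned so
  # Y201's hydroxyl can donate to the S228 carbonyl from above
  a2 <- build_peptide(c("GLY", "TYR", "ARG", "GLY", "ALA"), resnos = 200:204)
  target_ca201 <- o228 + c(-2.0, 5.5, 6.2)
  a2 <- translate_df(a2, target_ca201 - atom_xyz(a2, 201, "CA"))
  a2 <- aim_sidechain_df(a2, 201, "OH", o228, 2.85)

  # gate loop with D169/D170, P172 and the S173 anchor
  l1 <- build_peptide(
    c("GLY", "ASP", "ASP", "ALA", "PRO", "SER", "VAL", "VAL", "VAL", "ALA", "GLY"),
    resnos = 168:178
  )
  l1 <- translate_df(l1, (atom_xyz(a2, 200, "CA") + c(0, 0, gap_ctd)) - atom_xyz(l1, 173, "CA"))

  # buried hydrophobic segment between the two C-terminal loops
  core <- build_peptide(c("LEU", "VAL", "PHE", "LEU", "VAL"), resnos = 185:189)
  core_target <- (atom_xyz(a2, 200, "CA") + atom_xyz(l1, 173, "CA")) / 2 + c(0, -4.5, 0)
  core <- translate_df(core, core_target - atom_xyz(core, 187, "CA"))

  # --- N-terminal domain: two plain loops around N82 and N108 ------------
  ntd1 <- do.call(
    build_peptide,
    c(loop_sequence("ASN", 82, n_residues_per_loop), list(origin = c(0, -40, 0)))
  )
  ntd2 <- do.call(
    build_peptide,
    c(loop_sequence("ASN", 108, n_residues_per_loop), list(origin = c(0, -40, 0)))
  )
  ntd2 <- translate_df(ntd2, (atom_xyz(ntd1, 82, "CA") + c(0, 0, gap_ntd)) - atom_xyz(ntd2, 108, "CA"))

  atoms <- rbind(ntd1, ntd2, l1, core, a1, a2, bst)
  s <- new_structure(atoms)
  manifest <- list(
    kind = "gate",
    ground_truth = list(
      gap_ntd = gap_ntd, gap_ctd = gap_ctd,
      pair_ntd = c("A:82", "A:108"), pair_ctd = c("A:173", "A:200"),
      tether_focus = "A:228",
      tether_partners = c("A:196", "A:198", "A:201"),
      core_residues = paste0("A:", 185:189),
      interface_acidic = c("A:169", "A:170"),
      interface_basic = c("A:231", "A:233")
    )
  )
  list(structure = s, manifest = manifest)
}

#' Synthetic gate-loop dimer
#'
#' Two copies of [make_gate_structure()] arranged with an approximate two-fold
#' axis so that the acidic pair D169/D170 of each chain faces the basic pair
#' R231/R233 of the other, then snapped so the closest cross-chain
#' carboxylate-O/guanidinium-N contact is 3.0 angstroms; `separation` then
#' pulls chain B away along the interface axis.
#'
#' @param gap planted gate distance, as in [make_gate_structure()].
#' @param separation extra rigid translation of chain B away from the
#'   interface, angstroms (default 0).
#' @param ... passed to [make_gate_structure()].
#' @return list with `structure` (two-chain `Structure`) and `manifest`.
#' @export
make_gate_dimer <- function(gap = 6.2, separation = 0, ...) {
  mono <- make_gate_structure(gap = gap, ...)
  a <- mono$structure$atoms

  centroid_of <- function(df, resnos, names_want) {
    sel <- df$resno %in% resnos & df$name %in% names_want
    colMeans(as.matrix(df[sel, c("x", "y", "z")]))
  }
  dc <- centroid_of(a, c(169, 170), c("OD1", "OD2"))
  rc <- centroid_of(a, c(231, 233), c("NH1", "NH2", "NE"))

  b <- a
  m <- (dc + rc) / 2
  b <- transform_df(b, rot_about_axis(c(0, 0, 1), pi), center = c(m[1], m[2], 0))
  rc_b <- centroid_of(b, c(231, 233), c("NH1", "NH2", "NE"))
  b <- translate_df(b, c(0, 0, dc[3] - rc_b[3]))

  # snap: slide chain B along the interface axis until the closest cross-chain
  # acidic-O / basic-N contact is exactly 3.0 A (root search keeps every other
  # pair clash-free)
  ao <- as.matrix(a[a$resno %in% c(169, 170) & a$name %in% c("OD1", "OD2"), c("x", "y", "z")])
  bn <- as.matrix(b[b$resno %in% c(231, 233) & b$name %in% c("NH1", "NH2", "NE"), c("x", "y", "z")])
  dmat <- outer(seq_len(nrow(ao)), seq_len(nrow(bn)), Vectorize(function(i, j) {
    sqrt(sum((ao[i, ] - bn[j, ])^2))
  }))
  hit <- which(dmat == min(dmat), arr.ind = TRUE)[1, ]
  gapv <- ao[hit[1], ] - bn[hit[2], ]
  u_axis <- unit3(gapv)
  min_contact <- function(t) {
    bn_t <- sweep(bn, 2, gapv - t * u_axis, "+")
    min(outer(seq_len(nrow(ao)), seq_len(nrow(bn_t)), Vectorize(function(i, j) {
      sqrt(sum((ao[i, ] - bn_t[j, ])^2))
    })))
  }
  t_snap <- stats::uniroot(function(t) min_contact(t) - 3.0,
    lower = 3.0, upper = 40, tol = 1e-10
  )$root
  b <- translate_df(b, gapv - t_snap * u_axis)

  axis <- unit3(centroid_of(b, unique(b$resno), unique(b$name)) -
    centroid_of(a, unique(a$resno), unique(a$name)))
  if (separation != 0) b <- translate_df(b, separation * axis)
  b$chain <- "B"
  atoms <- rbind(a, b)
  atoms$eleno <- seq_len(nrow(atoms))
  s <- new_structure(atoms)
  manifest <- mono$manifest
  manifest$kind <- "gate_dimer"
  manifest$ground_truth$interface_quartet <- list(
    acidic = c("A:169", "A:170", "B:169", "B:170"),
    basic = c("A:231", "A:233", "B:231", "B:233")
  )
  manifest$ground_truth$separation <- separation
  list(structure = s, manifest = manifest)
}

#' Synthetic coordinate ensemble with planted mobile regions
#'
#' Frames are the base structure plus per-atom isotropic Gaussian noise
#' (`sigma_background`); residues in `hot_regions` receive larger noise
#' (`sigma_hot`) and a coherent displacement ramping linearly from zero to at
#' least `displacement` at the final frame, so the final frame carries the
#' planted large-displacement regions that the fixed-threshold RMSD rule is
#' expected to recover.
#'
#' With exactly two hot regions the displacements are antiparallel along the
#' axis joining the region centroids and scaled so the net translation and
#' torque of the planted field vanish (the regions move apart, as gate loops
#' opening); the global superposition of the analysis then cannot absorb the
#' planted signal or smear it onto unperturbed residues.  With any other
#' number of regions each direction is seed-random.
#'
#' @param base `Structure`.
#' @param n_frames number of frames (default 20).
#' @param sigma_background background positional noise per coordinate,
#'   angstroms (default 0.15).
#' @param hot_regions list of `list(chain =, resno =)` regions (default none).
#' @param sigma_hot per-coordinate noise inside hot regions (default 0.5).
#' @param displacement coherent displacement of hot regions at the final
#'   frame, angstroms (default 4, chosen so the planted regions exceed a 2
#'   angstrom per-residue RMSD from base in the final frame with margin even
#'   after the global superposition partially absorbs the shift).
#' @param seed RNG seed (restores the caller's RNG state).
#' @return list with `ensemble` and `manifest` (records the hot residue set).
#' @export
make_ensemble <- function(base, n_frames = 20, sigma_background = 0.15,
                          hot_regions = NULL, sigma_hot = 0.5,
                          displacement = 4.0, seed = 1) {
  stopifnot(inherits(base, "Structure"), nrow(base$atoms) > 0)
  if (!is.null(hot_regions) && sigma_hot < sigma_background) {
    stop("sigma_hot must be at least sigma_background")
  }
  xyz0 <- coords(base)
  n <- nrow(xyz0)
  hot_mask <- rep(FALSE, n)
  if (!is.null(hot_regions)) {
    for (reg in hot_regions) {
      hot_mask <- hot_mask | (base$atoms$chain == reg$chain & base$atoms$resno %in% reg$resno)
    }
  }
  region_sel <- lapply(hot_regions, function(reg) {
    base$atoms$chain == reg$chain & base$atoms$resno %in% reg$resno
  })
  frames <- with_seed(seed, {
    mags <- rep(displacement, length(hot_regions))
    if (length(hot_regions) == 2) {
      c1 <- colMeans(xyz0[region_sel[[1]], , drop = FALSE])
      c2 <- colMeans(xyz0[region_sel[[2]], , drop = FALSE])
      e <- unit3(c1 - c2)
      dirs <- list(e, -e)
      # antiparallel magnitudes balancing the net planted translation; both
      # regions still move at least `displacement`
      n1 <- sum(region_sel[[1]])
      n2 <- sum(region_sel[[2]])
      f <- displacement * max(n1, n2)
      mags <- c(f / n1, f / n2)
    } else {
      dirs <- lapply(seq_along(hot_regions), function(i) unit3(stats::rnorm(3)))
    }
    lapply(seq_len(n_frames), function(fi) {
      sig <- ifelse(hot_mask, sigma_hot, sigma_background)
      xyz <- xyz0 + matrix(stats::rnorm(3 * n, sd = rep(sig, 3)), n, 3)
      if (!is.null(hot_regions) && displacement > 0) {
        for (ri in seq_along(hot_regions)) {
          xyz[region_sel[[ri]], ] <- sweep(
            xyz[region_sel[[ri]], , drop = FALSE], 2,
            (mags[ri] * fi / n_frames) * dirs[[ri]], "+"
          )
        }
      }
      f <- set_coords(base, xyz)
      f$model_id <- as.integer(fi)
      f
    })
  })
  hot_keys <- unlist(lapply(hot_regions, function(reg) paste0(reg$chain, ":", reg$resno)))
  list(
    ensemble = new_ensemble(frames),
    manifest = list(
      kind = "ensemble", seed = seed,
      ground_truth = list(
        hot_residues = hot_keys, sigma_background = sigma_background,
        sigma_hot = sigma_hot, displacement = displacement, n_frames = n_frames
      )
    )
  )
}

#' Plant water molecules inside and outside a hydrophobic core
#'
#' Adds water oxygens (chain W) to a structure: `n_inside` within `cutoff` of
#' the side-chain heavy atoms of the core residues, `n_outside` beyond twice
#' the cutoff from all of them.  Placement rejects positions closer than 2.4
#' angstroms to any heavy atom (clash floor) and fails after 1000 attempts per
#' water.
#'
#' @param base `Structure`.
#' @param core_residues character vector of residue keys.
#' @param n_inside,n_outside planted counts.
#' @param cutoff penetration cutoff, angstroms (default 4).
#' @param seed RNG seed.
#' @return list with `structure` and `manifest` recording both counts.
#' @export
make_hydrated_core <- function(base, core_residues, n_inside = 3, n_outside = 10,
                               cutoff = 4.0, seed = 1) {
  if (length(core_residues) == 0) stop("core residue set must be defined")
  a <- base$atoms
  core_rows <- integer(0)
  for (key in core_residues) {
    rows <- residue_atom_rows(base, key)
    core_rows <- c(core_rows, rows[a$is_sidechain[rows] | (a$resname[rows] == "GLY" & a$name[rows] == "CA")])
  }
  if (length(core_rows) == 0) stop("core residues have no side-chain atoms")
  heavy <- which(toupper(a$element) != "H")
  xyz <- coords(base)
  core_xyz <- xyz[core_rows, , drop = FALSE]
  heavy_xyz <- xyz[heavy, , drop = FALSE]

  min_dist <- function(p, m) sqrt(min(rowSums(sweep(m, 2, p)^2)))
  waters <- with_seed(seed, {
    out <- list()
    place <- function(inside) {
      for (attempt in 1:1000) {
        if (inside) {
          anchor <- core_xyz[sample(nrow(core_xyz), 1), ]
          dir <- unit3(stats::rnorm(3))
          p <- anchor + stats::runif(1, 2.5, cutoff - 0.1) * dir
          ok <- min_dist(p, heavy_xyz) >= 2.4 && min_dist(p, core_xyz) <= cutoff
        } else {
          ctr <- colMeans(heavy_xyz)
          rad <- max(sqrt(rowSums(sweep(heavy_xyz, 2, ctr)^2))) + 2 * cutoff + 6
          p <- ctr + rad * unit3(stats::rnorm(3))
          ok <- min_dist(p, core_xyz) > 2 * cutoff && min_dist(p, heavy_xyz) >= 2.4
        }
        if (ok) {
          # waters must not crowd each other either
          if (length(out) > 0) {
            wm <- do.call(rbind, out)
            if (min_dist(p, wm) < 2.4) next
          }
          return(p)
        }
      }
      stop("placement error: could not place water after 1000 attempts")
    }
    for (i in seq_len(n_inside)) out[[length(out) + 1]] <- place(TRUE)
    for (i in seq_len(n_outside)) out[[length(out) + 1]] <- place(FALSE)
    out
  })
  if (length(waters) > 0) {
    wdf <- do.call(rbind, lapply(seq_along(waters), function(i) {
      data.frame(
        name = "O", resname = "HOH", chain = "W", resno = i,
        x = waters[[i]][1], y = waters[[i]][2], z = waters[[i]][3],
        stringsAsFactors = FALSE
      )
    }))
    atoms <- rbind(a[, c("name", "resname", "chain", "resno", "x", "y", "z")], wdf)
  } else {
    atoms <- a[, c("name", "resname", "chain", "resno", "x", "y", "z")]
  }
  s <- new_structure(atoms)
  list(
    structure = s,
    manifest = list(
      kind = "hydrated", seed = seed,
      ground_truth = list(
        n_inside = n_inside, n_outside = n_outside,
        cutoff = cutoff, core_residues = core_residues
      )
    )
  )
}

#' Synthetic spectra, titration curves and turbidity traces
#'
#' Emulates the package's spectroscopy inputs: tryptophan emission spectra as
#' Gaussian bands (a native/red-shifted pair for emission-maximum recovery),
#' a three-state denaturant titration with planted transition midpoints, and
#' first-order aggregation turbidity traces with a lag (one noiseless, one
#' noisy).  All planted parameters are recorded in the manifest.
#'
#' @param params named list overriding the defaults: `emax_native` (332 nm),
#'   `emax_red_shift` (8 nm), `bandwidth` (20 nm), `wavelengths` (300-400),
#'   `conc` (0.1-6 mol/L by 0.1), `midpoints` (1.3, 2.2 mol/L),
#'   `widths` (0.12, 0.18 mol/L), `state_signals` (N 1, I 0.55, U 0.05),
#'   `titration_noise` (0.004), `plateau` (1), `rate_k` (0.05 /s),
#'   `lag` (30 s), `baseline` (0.02), `dt` (2 s), `t_end` (3000 s),
#'   `trace_noise` (0.02 of plateau).
#' @param seed RNG seed for the noise.
#' @param dir optional directory: writes two-column CSV files plus a JSON
#'   manifest.
#' @return list with `spectra` (native, shifted), `titration`
#'   (`TitrationCurve`), `trace_noiseless`, `trace_noisy` (data frames
#'   `time`, `a400`) and `manifest`.
#' @export
make_spectra_and_traces <- function(params = list(), seed = 1, dir = NULL) {
  p <- utils::modifyList(list(
    emax_native = 332, emax_red_shift = 8, bandwidth = 20,
    wavelengths = 300:400,
    conc = seq(0.1, 6, by = 0.1), midpoints = c(1.3, 2.2), widths = c(0.12, 0.18),
    state_signals = c(N = 1, I = 0.55, U = 0.05), titration_noise = 0.004,
    plateau = 1.0, rate_k = 0.05, lag = 30, baseline = 0.02,
    dt = 2, t_end = 3000, trace_noise = 0.02
  ), params)
  if (p$bandwidth <= 0 || p$plateau <= 0 || p$rate_k <= 0 || p$lag < 0) {
    stop("validation error: non-physical generator parameters")
  }
  if (length(p$midpoints) != 2 || diff(p$midpoints) <= 0) {
    stop("validation error: midpoints must be two increasing concentrations")
  }
  gauss_spec <- function(center, label) {
    new_spectrum(p$wavelengths, exp(-(p$wavelengths - center)^2 / (2 * p$bandwidth^2)),
      excitation = 295, label = label
    )
  }
  out <- with_seed(seed, {
    spectra <- list(
      native = gauss_spec(p$emax_native, "native"),
      shifted = gauss_spec(p$emax_native + p$emax_red_shift, "red-shifted")
    )
    f_u <- stats::plogis((p$conc - p$midpoints[2]) / p$widths[2])
    f_n <- 1 - stats::plogis((p$conc - p$midpoints[1]) / p$widths[1])
    f_i <- pmax(0, 1 - f_n - f_u)
    sig <- p$state_signals["N"] * f_n + p$state_signals["I"] * f_i + p$state_signals["U"] * f_u
    sig <- as.numeric(sig) + stats::rnorm(length(sig), sd = p$titration_noise)
    titration <- assemble_transition(p$conc, sig, signal_name = "signal")

    t <- seq(0, p$t_end, by = p$dt)
    y0 <- ifelse(t < p$lag, p$baseline,
      p$baseline + p$plateau * (1 - exp(-p$rate_k * (t - p$lag)))
    )
    trace_noiseless <- data.frame(time = t, a400 = y0)
    trace_noisy <- data.frame(
      time = t,
      a400 = y0 + stats::rnorm(length(t), sd = p$trace_noise * p$plateau)
    )
    list(
      spectra = spectra, titration = titration,
      trace_noiseless = trace_noiseless, trace_noisy = trace_noisy
    )
  })
  out$manifest <- list(kind = "spectra", seed = seed, ground_truth = p)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    for (nm in names(out$spectra)) {
      sp <- out$spectra[[nm]]
      utils::write.csv(
        data.frame(wavelength = sp$wavelengths, intensity = sp$intensities),
        file.path(dir, paste0("spectrum_", nm, ".csv")),
        row.names = FALSE
      )
    }
    utils::write.csv(
      data.frame(conc_M = out$titration$conc, signal = out$titration$signal),
      file.path(dir, "titration.csv"),
      row.names = FALSE
    )
    utils::write.csv(
      data.frame(time_s = out$trace_noisy$time, A400 = out$trace_noisy$a400),
      file.path(dir, "turbidity.csv"),
      row.names = FALSE
    )
    jsonlite::write_json(out$manifest, file.path(dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  }
  out
}
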