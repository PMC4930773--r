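# Geometric hydrogen-bond and salt-bridge detection, interface electrostatic
# proxy, and water-penetration counting.

# donor atoms with their covalent antecedent (used for the hydrogen-less
# angle criterion).  Backbone N is a donor for every residue type except
# proline, whose ring nitrogen carries no amide hydrogen -- the structural
# consequence of a Ser-to-Pro substitution.
SIDECHAIN_DONORS <- list(
  SER = list(c("OG", "CB")),
  THR = list(c("OG1", "CB")),
  TYR = list(c("OH", "CZ")),
  CYS = list(c("SG", "CB")),
  ASN = list(c("ND2", "CG")),
  GLN = list(c("NE2", "CD")),
  LYS = list(c("NZ", "CE")),
  ARG = list(c("NE", "CD"), c("NH1", "CZ"), c("NH2", "CZ")),
  HIS = list(c("ND1", "CG"), c("NE2", "CE1")),
  TRP = list(c("NE1", "CD1"))
)

SIDECHAIN_ACCEPTORS <- list(
  ASP = c("OD1", "OD2"),
  GLU = c("OE1", "OE2"),
  ASN = c("OD1"),
  GLN = c("OE1"),
  SER = c("OG"),
  THR = c("OG1"),
  TYR = c("OH"),
  HIS = c("ND1", "NE2"),
  MET = c("SD")
)

donor_table <- function(a) {
  rows <- list()
  std <- a$resname %in% STANDARD_AA
  bbN <- which(std & a$name == "N" & a$resname != "PRO")
  if (length(bbN) > 0) rows[["bbN"]] <- data.frame(idx = bbN, antecedent = "CA")
  for (res in names(SIDECHAIN_DONORS)) {
    for (pair in SIDECHAIN_DONORS[[res]]) {
      hit <- which(a$resname == res & a$name == pair[1])
      if (length(hit) > 0) {
        rows[[paste(res, pair[1])]] <- data.frame(idx = hit, antecedent = pair[2])
      }
    }
  }
  wat <- which(a$is_water & toupper(a$element) == "O")
  if (length(wat) > 0) rows[["wat"]] <- data.frame(idx = wat, antecedent = NA_character_)
  do.call(rbind, rows)
}

acceptor_index <- function(a) {
  std <- a$resname %in% STANDARD_AA
  acc <- which(std & a$name %in% c("O", "OXT"))
  for (res in names(SIDECHAIN_ACCEPTORS)) {
    acc <- c(acc, which(a$resname == res & a$name %in% SIDECHAIN_ACCEPTORS[[res]]))
  }
  acc <- c(acc, which(a$is_water & toupper(a$element) == "O"))
  sort(unique(acc))
}

#' Detect hydrogen bonds geometrically
#'
#' Donor/acceptor typing is table driven (backbone N of every residue except
#' proline, plus the usual side-chain donors; backbone carbonyl O plus the
#' usual side-chain acceptors; water O both donates and accepts).  A bond is
#' reported when the donor-acceptor heavy-atom distance is at most `d_cutoff`
#' and the angle criterion holds: with an explicit hydrogen bonded to the
#' donor, the D-H...A angle must be at least `angle_cutoff`; without hydrogens
#' (the default situation for crystal structures and stripped trajectory
#' frames), the antecedent-donor-acceptor angle must be at least 90 degrees.
#' Pairs within one residue, and backbone-backbone pairs of sequence-adjacent
#' residues (covalently constrained), are excluded.
#'
#' @param s Structure.
#' @param d_cutoff donor-acceptor heavy-atom distance cutoff, angstroms
#'   (default 3.5).
#' @param angle_cutoff D-H...A angle cutoff in degrees when hydrogens are
#'   present (default 120).
#' @return data frame with one row per bond: donor/acceptor residue keys and
#'   atom names, `distance`, `angle`, and `category` (backbone-backbone,
#'   backbone-sidechain or sidechain-sidechain).
#' @export
detect_hbonds <- function(s, d_cutoff = 3.5, angle_cutoff = 120) {
  a <- s$atoms
  unknown <- unique(a$resname[!(a$resname %in% STANDARD_AA) & !a$is_water])
  if (length(unknown) > 0) {
    warning("unknown residue type(s) skipped in H-bond typing: ", paste(unknown, collapse = ", "))
  }
  don <- donor_table(a)
  acc <- acceptor_index(a)
  empty <- data.frame(
    donor_chain = character(0), donor_resno = integer(0), donor_insert = character(0),
    donor_resname = character(0), donor_atom = character(0),
    acceptor_chain = character(0), acceptor_resno = integer(0), acceptor_insert = character(0),
    acceptor_resname = character(0), acceptor_atom = character(0),
    distance = numeric(0), angle = numeric(0), category = character(0),
    stringsAsFactors = FALSE
  )
  if (is.null(don) || nrow(don) == 0 || length(acc) == 0) {
    return(empty)
  }
  xyz <- coords(s)
  hydros <- which(toupper(a$element) == "H")
  out <- list()
  for (k in seq_len(nrow(don))) {
    i <- don$idx[k]
    d2 <- (xyz[acc, 1] - xyz[i, 1])^2 + (xyz[acc, 2] - xyz[i, 2])^2 + (xyz[acc, 3] - xyz[i, 3])^2
    near <- acc[d2 <= d_cutoff^2 & d2 > 1e-9]
    for (j in near) {
      if (a$chain[j] == a$chain[i] && a$resno[j] == a$resno[i] && a$insert[j] == a$insert[i]) next
      same_chain_adjacent <- a$chain[j] == a$chain[i] && abs(a$resno[j] - a$resno[i]) == 1
      d_bb <- !a$is_sidechain[i] && !a$is_water[i]
      a_bb <- !a$is_sidechain[j] && !a$is_water[j]
      if (same_chain_adjacent && d_bb && a_bb) next
      # angle criterion
      ang <- NA_real_
      ok <- FALSE
      dh <- hydros[a$chain[hydros] == a$chain[i] & a$resno[hydros] == a$resno[i]]
      if (length(dh) > 0) {
        dd <- sqrt(rowSums((xyz[dh, , drop = FALSE] -
          matrix(xyz[i, ], length(dh), 3, byrow = TRUE))^2))
        dh <- dh[dd < 1.25]
      }
      if (length(dh) > 0) {
        angs <- vapply(dh, function(h) vec_angle(xyz[i, ], xyz[h, ], xyz[j, ]), numeric(1))
        ang <- max(angs)
        ok <- ang >= angle_cutoff
      } else if (is.na(don$antecedent[k])) {
        ok <- TRUE # water donor without hydrogens: distance criterion only
      } else {
        ante <- which(a$chain == a$chain[i] & a$resno == a$resno[i] &
          a$insert == a$insert[i] & a$name == don$antecedent[k])
        if (length(ante) == 1) {
          ang <- vec_angle(xyz[ante, ], xyz[i, ], xyz[j, ])
          ok <- ang >= 90
        }
      }
      if (!ok) next
      category <- if (d_bb && a_bb) {
        "backbone-backbone"
      } else if (!d_bb && !a_bb) {
        "sidechain-sidechain"
      } else {
        "backbone-sidechain"
      }
      out[[length(out) + 1]] <- data.frame(
        donor_chain = a$chain[i], donor_resno = a$resno[i], donor_insert = a$insert[i],
        donor_resname = a$resname[i], donor_atom = a$name[i],
        acceptor_chain = a$chain[j], acceptor_resno = a$resno[j], acceptor_insert = a$insert[j],
        acceptor_resname = a$resname[j], acceptor_atom = a$name[j],
        distance = sqrt(sum((xyz[i, ] - xyz[j, ])^2)), angle = ang,
        category = category, stringsAsFactors = FALSE
      )
    }
  }
  if (length(out) == 0) {
    return(empty)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Hydrogen-bond network of one residue with named partners
#'
#' Filters [detect_hbonds()] output to bonds where one end lies in the focus
#' residue and the other in one of the partner residues, e.g. the tether
#' network of a serine against three tyrosines.
#'
#' @param s Structure.
#' @param focus residue key string (`"A:228"`).
#' @param partners character vector of residue keys.
#' @param ... passed to [detect_hbonds()].
#' @return data frame in the format of [detect_hbonds()].
#' @export
hbond_network <- function(s, focus, partners, ...) {
  fk <- parse_reskey(focus)
  if (length(residue_atom_rows(s, fk)) == 0) stop("focus residue ", focus, " not found")
  pks <- lapply(partners, parse_reskey)
  for (i in seq_along(pks)) {
    if (length(residue_atom_rows(s, pks[[i]])) == 0) {
      stop("partner residue ", partners[i], " not found")
    }
  }
  hb <- detect_hbonds(s, ...)
  if (length(partners) == 0 || nrow(hb) == 0) {
    return(hb[0, ])
  }
  keyd <- paste(hb$donor_chain, hb$donor_resno, hb$donor_insert, sep = "|")
  keya <- paste(hb$acceptor_chain, hb$acceptor_resno, hb$acceptor_insert, sep = "|")
  kf <- paste(fk$chain, fk$resno, fk$insert, sep = "|")
  kp <- vapply(pks, function(k) paste(k$chain, k$resno, k$insert, sep = "|"), character(1))
  keep <- (keyd == kf & keya %in% kp) | (keya == kf & keyd %in% kp)
  out <- hb[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# formal charge groups for the electrostatic proxy: side-chain centers of
# Asp/Glu (-1) and Arg/Lys (+1) plus chain termini
charge_groups <- function(s, chain) {
  a <- s$atoms
  rows <- which(a$chain == chain & a$resname %in% STANDARD_AA)
  if (length(rows) == 0) stop("selection error: chain ", chain, " absent")
  sub <- a[rows, ]
  xyz <- as.matrix(sub[, c("x", "y", "z")])
  groups <- list()
  add <- function(q, center, label) {
    groups[[length(groups) + 1]] <<- list(q = q, center = center, label = label)
  }
  key <- paste(sub$resno, sub$insert)
  for (k in unique(key)) {
    idx <- which(key == k)
    res <- sub$resname[idx[1]]
    nm <- sub$name[idx]
    ctr_of <- function(names_want) {
      sel <- idx[nm %in% names_want]
      if (length(sel) == 0) {
        return(NULL)
      }
      colMeans(xyz[sel, , drop = FALSE])
    }
    if (res == "ASP") {
      c0 <- ctr_of(c("OD1", "OD2"))
      if (!is.null(c0)) add(-1, c0, paste0(chain, ":", k, ":ASP"))
    } else if (res == "GLU") {
      c0 <- ctr_of(c("OE1", "OE2"))
      if (!is.null(c0)) add(-1, c0, paste0(chain, ":", k, ":GLU"))
    } else if (res == "ARG") {
      c0 <- ctr_of(c("NH1", "NH2", "NE"))
      if (!is.null(c0)) add(+1, c0, paste0(chain, ":", k, ":ARG"))
    } else if (res == "LYS") {
      c0 <- ctr_of("NZ")
      if (!is.null(c0)) add(+1, c0, paste0(chain, ":", k, ":LYS"))
    }
  }
  # termini: first residue amine, last residue carboxylate
  first_res <- which(key == key[1])
  last_res <- which(key == key[length(key)])
  nterm <- first_res[sub$name[first_res] == "N"]
  if (length(nterm) == 1) add(+1, xyz[nterm, ], paste0(chain, ":Nterm"))
  cterm <- last_res[sub$name[last_res] %in% c("O", "OXT")]
  if (length(cterm) > 0) add(-1, colMeans(xyz[cterm, , drop = FALSE]), paste0(chain, ":Cterm"))
  groups
}

ACIDIC_ATOMS <- list(ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"))
BASIC_ATOMS <- list(ARG = c("NH1", "NH2", "NE"), LYS = "NZ", HIS = c("ND1", "NE2"))

#' Subunit-interface contact analysis
#'
#' Reports cross-chain salt bridges (acidic carboxylate O versus basic N pairs
#' within `acidic_basic_cutoff`), a screened-Coulomb electrostatic proxy, and
#' the number of cross-chain hydrogen bonds.  The proxy places formal charges
#' of plus/minus 1 on Asp/Glu carboxylates, Arg/Lys side chains and the chain
#' termini and sums 332 q_i q_j / (eps(r) r) in kcal/mol with the
#' distance-dependent dielectric eps(r) = 4r over cross-chain pairs within 12
#' angstroms (negative = attractive).  It is a qualitative ranking device for
#' comparing variants, not a force-field energy.
#'
#' @param dimer two-chain Structure.
#' @param chain_a,chain_b chain identifiers.
#' @param acidic_basic_cutoff salt-bridge N/O distance cutoff (default 4).
#' @param proxy_cutoff charge-pair distance cutoff for the proxy (default 12).
#' @param ... passed to [detect_hbonds()].
#' @return object of class `InterfaceReport`: list with `salt_bridges` (data
#'   frame), `electrostatic_proxy` (kcal/mol) and `hbond_count`.
#' @export
interface_analysis <- function(dimer, chain_a, chain_b, acidic_basic_cutoff = 4.0,
                               proxy_cutoff = 12.0, ...) {
  a <- dimer$atoms
  if (!any(a$chain == chain_a)) stop("selection error: chain ", chain_a, " absent")
  if (!any(a$chain == chain_b)) stop("selection error: chain ", chain_b, " absent")
  xyz <- coords(dimer)

  side_atoms <- function(chain, table) {
    idx <- integer(0)
    for (res in names(table)) {
      idx <- c(idx, which(a$chain == chain & a$resname == res & a$name %in% table[[res]]))
    }
    idx
  }
  bridges <- list()
  for (dir in list(c(chain_a, chain_b), c(chain_b, chain_a))) {
    ai <- side_atoms(dir[1], ACIDIC_ATOMS)
    bi <- side_atoms(dir[2], BASIC_ATOMS)
    if (length(ai) == 0 || length(bi) == 0) next
    for (i in ai) {
      d <- sqrt(rowSums((xyz[bi, , drop = FALSE] -
        matrix(xyz[i, ], length(bi), 3, byrow = TRUE))^2))
      for (h in which(d <= acidic_basic_cutoff)) {
        j <- bi[h]
        bridges[[length(bridges) + 1]] <- data.frame(
          acidic = residue_key_string(a$chain[i], a$resno[i], a$insert[i]),
          acidic_resname = a$resname[i],
          basic = residue_key_string(a$chain[j], a$resno[j], a$insert[j]),
          basic_resname = a$resname[j],
          distance = d[h], stringsAsFactors = FALSE
        )
      }
    }
  }
  sb <- if (length(bridges) > 0) do.call(rbind, bridges) else
    data.frame(acidic = character(0), acidic_resname = character(0),
               basic = character(0), basic_resname = character(0), distance = numeric(0))
  if (nrow(sb) > 0) {
    # keep the minimum N/O distance per residue pair
    pk <- paste(sb$acidic, sb$basic)
    sb <- sb[order(pk, sb$distance), ]
    sb <- sb[!duplicated(paste(sb$acidic, sb$basic)), ]
    rownames(sb) <- NULL
  }

  ga <- charge_groups(dimer, chain_a)
  gb <- charge_groups(dimer, chain_b)
  proxy <- 0
  for (p in ga) {
    for (q in gb) {
      r <- sqrt(sum((p$center - q$center)^2))
      if (r > 0 && r <= proxy_cutoff) {
        proxy <- proxy + 332 * p$q * q$q / (4 * r * r)
      }
    }
  }

  hb <- detect_hbonds(dimer, ...)
  cross <- nrow(hb[hb$donor_chain != hb$acceptor_chain &
    hb$donor_chain %in% c(chain_a, chain_b) &
    hb$acceptor_chain %in% c(chain_a, chain_b), , drop = FALSE])

  structure(
    list(salt_bridges = sb, electrostatic_proxy = proxy, hbond_count = cross),
    class = "InterfaceReport"
  )
}

#' Count waters penetrating a hydrophobic core
#'
#' Per frame, the number of water oxygens within `cutoff` of any side-chain
#' heavy atom of the core residues (C-alpha stands in for glycine).
#'
#' @param x `Ensemble` or `Structure`.
#' @param core_residues character vector of residue keys (`"A:186"`).
#' @param cutoff distance cutoff in angstroms (default 4).
#' @return object of class `WaterPenetration`: list with `per_frame_counts`,
#'   `mean`, `core_residues`, `cutoff`.
#' @export
water_penetration <- function(x, core_residues, cutoff = 4.0) {
  if (length(core_residues) == 0) stop("configuration error: empty core residue set")
  frames <- if (inherits(x, "Ensemble")) x$frames else list(x)
  counts <- vapply(frames, function(f) {
    a <- f$atoms
    core_rows <- integer(0)
    for (key in core_residues) {
      rows <- residue_atom_rows(f, key)
      rr <- rows[a$is_sidechain[rows] | (a$resname[rows] == "GLY" & a$name[rows] == "CA")]
      core_rows <- c(core_rows, rr)
    }
    core_rows <- core_rows[toupper(a$element[core_rows]) != "H"]
    if (length(core_rows) == 0) {
      return(0L)
    }
    wat <- which(a$is_water & toupper(a$element) == "O")
    if (length(wat) == 0) {
      warning("no waters present in frame; count is 0")
      return(0L)
    }
    xyz <- coords(f)
    cnt <- 0L
    for (wi in wat) {
      d2 <- (xyz[core_rows, 1] - xyz[wi, 1])^2 + (xyz[core_rows, 2] - xyz[wi, 2])^2 +
        (xyz[core_rows, 3] - xyz[wi, 3])^2
      if (any(d2 <= cutoff^2)) cnt <- cnt + 1L
    }
    cnt
  }, integer(1))
  structure(
    list(
      core_residues = core_residues, cutoff = cutoff,
      per_frame_counts = counts, mean = mean(counts)
    ),
    class = "WaterPenetration"
  )
}

#' Hydrophobic-core residue set from relative side-chain burial
#'
#' Residues whose side-chain SASA, relative to the fully-exposed Gly-X-Gly
#' reference of their residue type, is below `rel_cutoff` (default 10
#' percent).  Used as the default core definition when no explicit list is
#' configured.
#'
#' @param s Structure with radii assigned.
#' @param chain restrict to one chain (default all).
#' @param rel_cutoff relative-exposure threshold (default 0.10).
#' @param ... passed to [sasa()].
#' @return character vector of residue keys.
#' @export
hydrophobic_core_residues <- function(s, chain = NULL, rel_cutoff = 0.10, ...) {
  sr <- sasa(s, ...)
  at <- sr$atom_table
  ref <- max_sasa_reference(sr$probe_radius, sr$n_points)
  ref_sum <- tapply(ref$area, ref$resname, sum)
  sel <- at$is_sidechain | (at$resname == "GLY" & at$name == "CA")
  if (!is.null(chain)) sel <- sel & at$chain == chain
  sel <- sel & at$resname %in% names(ref_sum)
  key <- paste(at$chain[sel], at$resno[sel], at$insert[sel], sep = "|")
  sc_area <- tapply(at$area[sel], key, sum)
  resname <- tapply(at$resname[sel], key, function(v) v[1])
  rel <- as.numeric(sc_area) / as.numeric(ref_sum[as.character(resname)])
  keys <- names(sc_area)[rel < rel_cutoff]
  vapply(strsplit(keys, "\\|"), function(p) {
    residue_key_string(p[1], as.integer(p[2]), if (length(p) > 2) p[3] else "")
  }, character(1))
}
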