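# Shared fixtures and independent oracles for the test suite.

# ---- PDB text fixtures --------------------------------------------------

pdb_atom_line <- function(serial, name, resname, chain, resno, x, y, z,
                          altloc = " ", occ = 1.00, record = "ATOM  ",
                          element = NULL) {
  if (is.null(element)) element <- substr(gsub("[0-9]", "", name), 1, 1)
  namefield <- if (nchar(name) < 4) sprintf(" %-3s", name) else name
  sprintf(
    "%s%5d %s%s%-3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    record, serial, namefield, altloc, resname, chain, resno,
    x, y, z, occ, 0.0, element
  )
}

write_pdb_fixture <- function(lines, path = tempfile(fileext = ".pdb")) {
  writeLines(c(lines, "END"), path)
  path
}

gly_3atom_pdb <- function() {
  write_pdb_fixture(c(
    pdb_atom_line(1, "N", "GLY", "A", 1, 0, 0, 0),
    pdb_atom_line(2, "CA", "GLY", "A", 1, 1.46, 0, 0),
    pdb_atom_line(3, "C", "GLY", "A", 1, 2.0, 1.4, 0)
  ))
}

# ---- memoized synthetic fixtures ---------------------------------------

.fixture_cache <- new.env(parent = emptyenv())

gate62 <- function() {
  if (is.null(.fixture_cache$gate62)) .fixture_cache$gate62 <- make_gate_structure(6.2)
  .fixture_cache$gate62
}

gate93 <- function() {
  if (is.null(.fixture_cache$gate93)) .fixture_cache$gate93 <- make_gate_structure(9.3)
  .fixture_cache$gate93
}

hot_regions_default <- function() {
  list(
    list(chain = "A", resno = 199:203),
    list(chain = "A", resno = 172:176)
  )
}

planted_hot_resnos <- function() sort(c(199:203, 172:176))

region_resnos <- function(regions) {
  if (nrow(regions) == 0) {
    return(integer(0))
  }
  sort(unlist(mapply(seq, regions$start, regions$end, SIMPLIFY = FALSE)))
}

# ---- independent oracles ------------------------------------------------

# analytic accessible area of two identical spheres of expanded radius re at
# center distance d (each loses one spherical cap of height re - d/2)
two_sphere_area_oracle <- function(re, d) {
  h <- re - d / 2
  2 * (4 * pi * re^2 - 2 * pi * re * h)
}

# brute-force SAP: plain double loop over atoms, no vectorization shared with
# the implementation
sap_oracle <- function(s, sasa_res, radius_R, scale = "black_mould") {
  hydro <- hydrophobicity_scale(scale)
  at <- sasa_res$atom_table
  ref <- max_sasa_reference(sasa_res$probe_radius, sasa_res$n_points)
  a <- s$atoms[!s$atoms$is_water, , drop = FALSE]
  n <- nrow(a)
  out <- numeric(n)
  for (i in seq_len(n)) {
    acc <- 0
    for (j in seq_len(n)) {
      contributes <- at$is_sidechain[j] || (at$resname[j] == "GLY" && at$name[j] == "CA")
      if (!contributes) next
      d <- sqrt((a$x[i] - a$x[j])^2 + (a$y[i] - a$y[j])^2 + (a$z[i] - a$z[j])^2)
      if (d > radius_R) next
      refa <- ref$area[ref$resname == at$resname[j] & ref$name == at$name[j]]
      acc <- acc + (at$area[j] / refa) * hydro[[at$resname[j]]]
    }
    out[i] <- acc
  }
  out
}

# brute-force Kabsch: coarse Euler-angle grid plus Nelder-Mead refinement,
# translation handled analytically by centering
kabsch_oracle_rmsd <- function(ref, mob) {
  rc <- colMeans(ref)
  mc <- colMeans(mob)
  A <- sweep(ref, 2, rc)
  B <- sweep(mob, 2, mc)
  rot <- function(ang) {
    cx <- cos(ang[1]); sx <- sin(ang[1])
    cy <- cos(ang[2]); sy <- sin(ang[2])
    cz <- cos(ang[3]); sz <- sin(ang[3])
    Rx <- matrix(c(1, 0, 0, 0, cx, -sx, 0, sx, cx), 3, 3, byrow = TRUE)
    Ry <- matrix(c(cy, 0, sy, 0, 1, 0, -sy, 0, cy), 3, 3, byrow = TRUE)
    Rz <- matrix(c(cz, -sz, 0, sz, cz, 0, 0, 0, 1), 3, 3, byrow = TRUE)
    Rz %*% Ry %*% Rx
  }
  obj <- function(ang) sqrt(mean(rowSums((B %*% t(rot(ang)) - A)^2)))
  grid <- seq(0, 2 * pi, length.out = 13)[-13]
  best <- c(0, 0, 0)
  best_v <- obj(best)
  for (ax in grid) {
    for (ay in grid) {
      for (az in grid) {
        v <- obj(c(ax, ay, az))
        if (v < best_v) {
          best_v <- v
          best <- c(ax, ay, az)
        }
      }
    }
  }
  opt <- stats::optim(best, obj, method = "Nelder-Mead",
    control = list(reltol = 1e-14, maxit = 5000)
  )
  opt$value
}

random_rotation <- function(seed) {
  set.seed(seed)
  q <- rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), 3, 3, byrow = TRUE)
}
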