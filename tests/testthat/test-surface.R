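# surface_analysis: SASA, delta-SAA, SAP

single_atom_structure <- function(r = 1.7) {
  s <- new_structure(data.frame(
    name = "CA", resname = "GLY", chain = "A", resno = 1,
    x = 0, y = 0, z = 0, element = "C"
  ))
  s$atoms$vdw <- r
  s
}

test_that("isolated sphere matches the analytic area within 0.5% at 960 points", {
  sr <- sasa(single_atom_structure(1.7), probe_radius = 1.4, n_points = 960)
  analytic <- 4 * pi * 3.1^2
  expect_lt(abs(total_sasa(sr) - analytic) / analytic, 0.005)
  expect_equal(analytic, 120.76, tolerance = 1e-3)
})

test_that("a fully caged atom has zero accessible area", {
  # central atom surrounded by an octahedron plus cube corners of overlapping
  # large spheres
  dirs <- rbind(
    diag(3), -diag(3),
    as.matrix(expand.grid(c(-1, 1), c(-1, 1), c(-1, 1))) / sqrt(3)
  )
  atoms <- data.frame(
    name = "CA", resname = "GLY", chain = "A", resno = seq_len(nrow(dirs) + 1),
    x = c(0, dirs[, 1] * 2), y = c(0, dirs[, 2] * 2), z = c(0, dirs[, 3] * 2),
    element = "C"
  )
  s <- new_structure(atoms)
  s$atoms$vdw <- 1.7
  sr <- sasa(s, n_points = 960)
  expect_equal(sr$atom_table$area[1], 0)
})

test_that("two overlapping spheres match the spherical-cap closed form within 2%", {
  d <- 3.0
  atoms <- data.frame(
    name = "CA", resname = "GLY", chain = "A", resno = 1:2,
    x = c(0, d), y = 0, z = 0, element = "C"
  )
  s <- new_structure(atoms)
  s$atoms$vdw <- 1.7
  sr <- sasa(s, probe_radius = 1.4, n_points = 960)
  oracle <- two_sphere_area_oracle(3.1, d)
  expect_lt(abs(total_sasa(sr) - oracle) / oracle, 0.02)
})

test_that("SASA converges within 1% between 960 and 3840 points", {
  s <- assign_radii(loopgate:::build_tripeptide("PHE"), "bondi")
  a1 <- total_sasa(sasa(s, n_points = 960))
  a2 <- total_sasa(sasa(s, n_points = 3840))
  expect_lt(abs(a1 - a2) / a2, 0.01)
})

test_that("total SASA is invariant under rigid motion", {
  s <- assign_radii(gate62()$structure, "bondi")
  a1 <- total_sasa(sasa(s))
  moved <- transform_structure(s, random_rotation(5), c(20, -3, 7))
  a2 <- total_sasa(sasa(moved))
  expect_equal(a2, a1, tolerance = 1e-6)
})

test_that("sasa validates its inputs", {
  s <- gate62()$structure # no radii assigned
  expect_error(sasa(s), "radii|configuration")
  expect_error(sasa(assign_radii(s), n_points = 50), "92")
})

test_that("per-residue SASA sums member atoms", {
  s <- assign_radii(loopgate:::build_tripeptide("SER"), "bondi")
  sr <- sasa(s)
  at <- sr$atom_table
  expect_equal(
    sr$residue_table$area,
    as.numeric(tapply(at$area, at$resno, sum)[as.character(sr$residue_table$resno)])
  )
})

test_that("buried interface area behaves like an interface", {
  dimer <- assign_radii(make_gate_dimer(6.2)$structure, "bondi")
  d0 <- delta_saa(dimer, "A", "B")
  expect_gt(d0$buried, 50)
  expect_equal(d0$buried, d0$saa_monomers - d0$saa_dimer, tolerance = 1e-9)

  # translating the chains apart monotonically removes the buried area
  seps <- c(5, 15, 40)
  buried <- vapply(seps, function(sp) {
    delta_saa(assign_radii(make_gate_dimer(6.2, separation = sp)$structure), "A", "B")$buried
  }, numeric(1))
  expect_true(all(diff(c(d0$buried, buried)) <= 1e-6))
  expect_equal(buried[3], 0, tolerance = 1e-6)

  expect_error(delta_saa(dimer, "A", "Q"), "chain Q")
})

test_that("SAP equals the brute-force double-loop oracle exactly", {
  s <- assign_radii(gate62()$structure, "bondi")
  expect_lte(nrow(s$atoms), 500)
  sr <- sasa(s)
  sp <- sap(s, sr, radius_R = 10)
  oracle <- sap_oracle(s, sr, radius_R = 10)
  expect_equal(sp$atom_table$sap, oracle, tolerance = 1e-12)
})

test_that("a single fully exposed residue scores exactly its scale value", {
  # central Ala of an extended Gly-Ala-Gly tripeptide: the fully-exposed
  # reference comes from this same construction, so the exposure ratio of its
  # only side-chain atom (CB) is exactly 1
  s <- assign_radii(loopgate:::build_tripeptide("ALA"), "bondi")
  sp <- sap(s, sasa(s), radius_R = 3)
  hydro <- hydrophobicity_scale("black_mould")
  cb <- sp$atom_table$resno == 2 & sp$atom_table$name == "CB"
  expect_equal(sp$atom_table$sap[cb], unname(hydro["ALA"]), tolerance = 1e-9)
  expect_equal(
    sp$residue_table$sap[sp$residue_table$resno == 2],
    unname(hydro["ALA"]),
    tolerance = 1e-9
  )
})

test_that("a fully buried side chain contributes nothing to neighbours", {
  s <- assign_radii(gate62()$structure, "bondi")
  sr <- sasa(s)
  at <- sr$atom_table
  buried <- which(at$is_sidechain & at$area == 0)
  skip_if(length(buried) == 0, "fixture has no fully buried side-chain atom")
  # removing a zero-area contributor does not change any SAP value
  sp <- sap(s, sr, radius_R = 10)
  at2 <- at
  at2$area[buried[1]] <- 0 # already zero; oracle with and without the atom
  oracle <- sap_oracle(s, sr, radius_R = 10)
  expect_equal(sp$atom_table$sap, oracle, tolerance = 1e-12)
})

test_that("sap validates scale coverage and topology matching", {
  s <- assign_radii(gate62()$structure, "bondi")
  sr <- sasa(s)
  s_bad <- s
  s_bad$atoms$resname[s_bad$atoms$resno == 226] <- "XYZ"
  sr_bad <- sasa(s_bad)
  expect_error(sap(s_bad, sr_bad), "XYZ")
})

test_that("the shipped fully-exposed reference equals a fresh recomputation", {
  shipped <- max_sasa_reference(1.4, 960)
  fresh <- max_sasa_reference(1.4, 960, recompute = TRUE)
  expect_equal(shipped$area, fresh$area, tolerance = 1e-6)
  expect_identical(shipped$resname, fresh$resname)
  expect_identical(shipped$name, fresh$name)
})

test_that("delta-SAP selection implements the positive-and-increased rule", {
  s <- assign_radii(gate62()$structure, "bondi")
  sp <- sap(s, sasa(s))
  expect_equal(nrow(delta_sap_selection(sp, sp)), 0) # wt = mut -> empty

  g93 <- assign_radii(gate93()$structure, "bondi")
  sp93 <- sap(g93, sasa(g93))
  sel <- delta_sap_selection(sp, sp93)
  if (nrow(sel) > 1) expect_true(all(diff(sel$delta) <= 0)) # ranked descending
  expect_true(all(sel$sap_mut > 0 & sel$delta > 0))

  sp_bad <- sp93
  sp_bad$residue_table <- sp_bad$residue_table[-1, ]
  expect_error(delta_sap_selection(sp, sp_bad), "topolog")
})

test_that("residues gaining exposure in the mutant are selected and top-ranked", {
  # planted fixture: open the CTD gate (gap 9.3) and verify the 199-203 loop
  # region ranks at the top of the delta-SAP selection
  wt <- assign_radii(gate62()$structure, "bondi")
  mut <- assign_radii(gate93()$structure, "bondi")
  sel <- delta_sap_selection(sap(wt, sasa(wt)), sap(mut, sasa(mut)))
  skip_if(nrow(sel) == 0, "no residue gained positive SAP on this fixture")
  expect_true(any(sel$resno %in% c(172:176, 199:203)))
})
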