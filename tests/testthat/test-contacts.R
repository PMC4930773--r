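# contacts: H-bonds, named networks, interface analysis, water penetration

two_residue_no <- function(d) {
  # backbone N of an alanine facing a glycine carbonyl O at distance d along
  # the N -> O axis, antecedent CA behind the donor (linear approach)
  atoms <- rbind(
    data.frame(name = c("N", "CA", "C", "O"), resname = "ALA", chain = "A", resno = 10,
      x = c(0, -1.46, -2.0, -2.6), y = c(0, 0, 1.2, 2.2), z = 0),
    data.frame(name = c("N", "CA", "C", "O"), resname = "GLY", chain = "B", resno = 50,
      x = c(d + 3, d + 2, d + 1.23, d), y = 0, z = 0)
  )
  new_structure(atoms)
}

test_that("an ideal linear N...O pair at 2.9 A gives one H-bond", {
  hb <- detect_hbonds(two_residue_no(2.9))
  expect_equal(nrow(hb), 1)
  expect_equal(hb$donor_atom, "N")
  expect_equal(hb$acceptor_atom, "O")
  expect_equal(hb$distance, 2.9, tolerance = 1e-9)
  expect_equal(hb$category, "backbone-backbone")
})

test_that("N...O at 4.5 A is rejected by the distance cutoff", {
  expect_equal(nrow(detect_hbonds(two_residue_no(4.5))), 0)
})

test_that("proline backbone N is never a donor", {
  s <- two_residue_no(2.9)
  s$atoms$resname[s$atoms$resno == 10] <- "PRO"
  hb <- detect_hbonds(s)
  expect_false(any(hb$donor_atom == "N" & hb$donor_resno == 10))
})

test_that("detect_hbonds is invariant under global rigid motion", {
  s <- gate62()$structure
  hb1 <- detect_hbonds(s)
  hb2 <- detect_hbonds(transform_structure(s, random_rotation(9), c(-8, 14, 3)))
  expect_equal(nrow(hb2), nrow(hb1))
  expect_equal(sort(hb2$distance), sort(hb1$distance), tolerance = 1e-9)
})

test_that("unknown residue types produce a typing warning and are skipped", {
  s <- two_residue_no(2.9)
  s$atoms$resname[s$atoms$resno == 50] <- "LIG"
  expect_warning(hb <- detect_hbonds(s), "LIG|unknown")
  expect_equal(nrow(hb), 0)
})

test_that("the serine tether network is recovered on the gate fixture", {
  s <- gate62()$structure
  net <- hbond_network(s, "A:228", c("A:196", "A:198", "A:201"))
  expect_gt(nrow(net), 0)
  bb <- net[net$category == "backbone-backbone", ]
  pair196 <- (bb$donor_resno == 228 & bb$acceptor_resno == 196) |
    (bb$donor_resno == 196 & bb$acceptor_resno == 228)
  expect_equal(sum(pair196), 2) # two backbone bonds with Y196
  partners <- unique(c(net$donor_resno, net$acceptor_resno))
  expect_true(all(c(196, 198, 201) %in% partners))
})

test_that("after S->P the serine donor bonds disappear from the network", {
  m <- mutate_residue(gate62()$structure, "A:228:SER>PRO")
  net <- hbond_network(m, "A:228", c("A:196", "A:198", "A:201"))
  expect_false(any(net$donor_resno == 228 & net$donor_atom %in% c("N", "OG")))
  expect_false(any(c(net$donor_atom, net$acceptor_atom) == "OG"))
})

test_that("hbond_network validates focus and partners and allows empty lists", {
  s <- gate62()$structure
  expect_error(hbond_network(s, "A:9999", "A:196"), "A:9999")
  expect_error(hbond_network(s, "A:228", c("A:196", "A:8888")), "A:8888")
  expect_equal(nrow(hbond_network(s, "A:228", character(0))), 0)
})

test_that("interface analysis finds the planted acidic/basic quartet pairs", {
  dimer <- make_gate_dimer(6.2)$structure
  rep <- interface_analysis(dimer, "A", "B")
  sb <- rep$salt_bridges
  expect_gt(nrow(sb), 0)
  expect_true(all(sub(":.*", "", sb$acidic) != sub(":.*", "", sb$basic)))
  expect_true(all(sub(".*:", "", sb$acidic) %in% c("169", "170")))
  expect_true(all(sub(".*:", "", sb$basic) %in% c("231", "233")))
  expect_true(all(sb$distance <= 4.0))
  expect_lt(rep$electrostatic_proxy, 0) # attractive
})

test_that("chains separated by 50 A have no bridges and ~zero proxy", {
  far <- make_gate_dimer(6.2, separation = 50)$structure
  rep <- interface_analysis(far, "A", "B")
  expect_equal(nrow(rep$salt_bridges), 0)
  expect_equal(rep$electrostatic_proxy, 0)
  expect_error(interface_analysis(far, "A", "Q"), "chain Q")
})

test_that("a single +1/-1 pair at 3.32 A gives -7.53 kcal/mol", {
  # one arginine guanidinium against one aspartate carboxylate, centers at
  # 3.32 A, built directly from charge groups
  atoms <- rbind(
    data.frame(name = c("N", "CA", "C", "O", "CB", "CG", "OD1", "OD2"),
      resname = "ASP", chain = "A", resno = 1,
      x = c(-8, -7, -6.5, -6, -6.8, -5.9, 0, 0),
      y = c(3, 3, 4, 5, 1.8, 0.9, 0.8, -0.8), z = 0),
    data.frame(name = c("N", "CA", "C", "O", "CB", "CG", "CD", "NE", "CZ", "NH1", "NH2"),
      resname = "ARG", chain = "B", resno = 2,
      x = c(12, 11, 10.5, 10, 10.8, 9.9, 8.9, 3.32, 8, 3.32, 3.32),
      y = c(3, 3, 4, 5, 1.8, 0.9, 1.5, 0, 3, 0.8, -0.8), z = 0)
  )
  s <- new_structure(atoms)
  ga <- loopgate:::charge_groups(s, "A")
  gb <- loopgate:::charge_groups(s, "B")
  # isolate the side-chain groups (drop the terminal charges) via their labels
  side_a <- Filter(function(g) grepl(":ASP$", g$label), ga)
  side_b <- Filter(function(g) grepl(":ARG$", g$label), gb)
  expect_length(side_a, 1)
  expect_length(side_b, 1)
  r <- sqrt(sum((side_a[[1]]$center - side_b[[1]]$center)^2))
  proxy <- 332 * side_a[[1]]$q * side_b[[1]]$q / (4 * r * r)
  expect_equal(r, 3.32, tolerance = 1e-6)
  expect_equal(proxy, -7.53, tolerance = 0.01)
})

test_that("the proxy tail decays monotonically to zero with separation", {
  # near contact the proxy is not monotone: cross-chain like-charge
  # repulsions partially cancel the salt-bridge attraction and fade faster
  # than it as the chains part.  The far-field tail, once every cross-chain
  # group pair is receding, must decay monotonically in magnitude and vanish
  # beyond the interaction cutoff.
  seps <- c(8, 12, 16, 24, 32)
  prox <- vapply(seps, function(sp) {
    interface_analysis(make_gate_dimer(6.2, separation = sp)$structure, "A", "B")$electrostatic_proxy
  }, numeric(1))
  expect_true(all(diff(abs(prox)) <= 1e-9))
  expect_equal(prox[length(prox)], 0)
  expect_lt(interface_analysis(make_gate_dimer(6.2)$structure, "A", "B")$electrostatic_proxy, 0)
})

test_that("every reported salt bridge is within the distance cutoff", {
  rep <- interface_analysis(make_gate_dimer(6.2)$structure, "A", "B", acidic_basic_cutoff = 4)
  expect_true(all(rep$salt_bridges$distance <= 4))
})

test_that("water penetration counts planted waters exactly", {
  g <- gate62()
  core <- g$manifest$ground_truth$core_residues
  h <- make_hydrated_core(g$structure, core, n_inside = 3, n_outside = 10, seed = 2)
  wp <- water_penetration(h$structure, core, cutoff = 4)
  expect_equal(wp$mean, 3)
  expect_equal(wp$per_frame_counts, 3L)

  h0 <- make_hydrated_core(g$structure, core, n_inside = 0, n_outside = 5, seed = 2)
  expect_equal(water_penetration(h0$structure, core, cutoff = 4)$mean, 0)
})

test_that("water penetration warns when no waters are present and checks the core", {
  s <- gate62()$structure
  expect_warning(wp <- water_penetration(s, "A:185"), "water")
  expect_equal(wp$mean, 0)
  expect_error(water_penetration(s, character(0)), "core")
})

test_that("water penetration counts are monotone in the cutoff", {
  g <- gate62()
  core <- g$manifest$ground_truth$core_residues
  h <- make_hydrated_core(g$structure, core, n_inside = 3, n_outside = 10, seed = 6)
  counts <- vapply(c(2.5, 3, 4, 6, 9, 20), function(cu) {
    water_penetration(h$structure, core, cutoff = cu)$mean
  }, numeric(1))
  expect_true(all(diff(counts) >= 0))
})

test_that("water penetration counts are stable under rigid motion", {
  g <- gate62()
  core <- g$manifest$ground_truth$core_residues
  h <- make_hydrated_core(g$structure, core, seed = 8)
  moved <- transform_structure(h$structure, random_rotation(3), c(4, 4, -9))
  expect_equal(
    water_penetration(moved, core, cutoff = 4)$mean,
    water_penetration(h$structure, core, cutoff = 4)$mean
  )
})

test_that("hydrophobic core auto-detection returns residue keys", {
  s <- assign_radii(gate62()$structure, "bondi")
  hc <- hydrophobic_core_residues(s)
  expect_type(hc, "character")
  expect_true(all(grepl("^[A-Za-z0-9]+:", hc)))
  # a permissive cutoff yields a superset of the strict one
  hc_loose <- hydrophobic_core_residues(s, rel_cutoff = 0.5)
  expect_true(all(hc %in% hc_loose))
})
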