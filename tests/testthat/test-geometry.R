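# geometry_core: superposition, RMSD/RMSF, regions, loop gap

test_that("identical point sets superpose with rmsd 0 and identity rotation", {
  set.seed(1)
  pts <- matrix(rnorm(30), 10, 3)
  fit <- kabsch_superpose(pts, pts)
  expect_lt(fit$rmsd, 1e-12)
  expect_equal(fit$rotation, diag(3), tolerance = 1e-10)
  expect_equal(det(fit$rotation), 1, tolerance = 1e-12)
})

test_that("rigid motion is removed exactly (rmsd < 1e-8)", {
  set.seed(2)
  pts <- matrix(rnorm(45), 15, 3)
  Rz <- matrix(c(0, -1, 0, 1, 0, 0, 0, 0, 1), 3, 3, byrow = TRUE) # 90 deg about z
  mob <- pts %*% t(Rz) + matrix(c(5, -3, 2), 15, 3, byrow = TRUE)
  fit <- kabsch_superpose(pts, mob)
  expect_lt(fit$rmsd, 1e-8)
})

test_that("kabsch rmsd is invariant under rigid motion of both sets", {
  set.seed(3)
  ref <- matrix(rnorm(24), 8, 3)
  mob <- ref + matrix(rnorm(24, sd = 0.3), 8, 3)
  base <- kabsch_superpose(ref, mob)$rmsd
  R <- random_rotation(11)
  t <- c(3, -7, 1)
  moved <- kabsch_superpose(
    ref %*% t(R) + matrix(t, 8, 3, byrow = TRUE),
    mob %*% t(R) + matrix(t, 8, 3, byrow = TRUE)
  )$rmsd
  expect_equal(moved, base, tolerance = 1e-10)
})

test_that("balanced 4-point displacement case equals the closed form 1.0 A", {
  # square of points with displacements perpendicular to its plane summing to
  # zero net translation and torque: the optimal fit is the identity and
  # rmsd = sqrt(sum d^2 / N) = sqrt(4 * 1 / 4) = 1.0 exactly
  ref <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0))
  mob <- ref + rbind(c(0, 0, 1), c(0, 0, 1), c(0, 0, -1), c(0, 0, -1))
  fit <- kabsch_superpose(ref, mob)
  expect_equal(fit$rmsd, 1.0, tolerance = 1e-10)
  expect_equal(kabsch_oracle_rmsd(ref, mob), 1.0, tolerance = 1e-6)
})

test_that("single displaced atom case matches the brute-force rotation oracle", {
  # the spec's literal reading (one atom displaced 2 A among 4) is not 1.0 A
  # under an optimal fit; assert instead that the implementation equals an
  # independent brute-force minimization over rotations
  ref <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0))
  mob <- ref
  mob[1, 3] <- 2
  fit <- kabsch_superpose(ref, mob)
  expect_equal(fit$rmsd, kabsch_oracle_rmsd(ref, mob), tolerance = 1e-6)
  expect_lte(fit$rmsd, sqrt(sum((mob - ref)^2) / 4) + 1e-12)
})

test_that("kabsch rejects count mismatch and degenerate geometry", {
  expect_error(kabsch_superpose(matrix(0, 4, 3), matrix(0, 5, 3)), "pairing")
  line <- cbind(1:5, 0, 0)
  expect_error(kabsch_superpose(line, line + 1), "conditioning|degenerate")
  expect_error(kabsch_superpose(matrix(0, 2, 3), matrix(0, 2, 3)), "3")
})

test_that("per-residue RMSD is zero for identical structures", {
  s <- gate62()$structure
  prr <- per_residue_rmsd(s, s)
  expect_true(all(prr$rmsd < 1e-12))
  expect_equal(nrow(prr), nrow(residue_table(s)))
})

test_that("planted displaced residues exceed 2 A, the rest stay below 0.5 A", {
  g <- gate62()
  e <- make_ensemble(g$structure,
    hot_regions = hot_regions_default(),
    sigma_background = 0, sigma_hot = 0, seed = 4
  )
  prr <- per_residue_rmsd(g$structure, e$ensemble$frames[[20]])
  hot <- prr$resno %in% planted_hot_resnos()
  expect_true(all(prr$rmsd[hot] > 2))
  expect_true(all(prr$rmsd[!hot] < 0.5))
})

test_that("select_perturbed_regions returns the planted ranges and is monotone", {
  g <- gate62()
  e <- make_ensemble(g$structure, hot_regions = hot_regions_default(), seed = 5)
  prr <- per_residue_rmsd(g$structure, e$ensemble$frames[[20]])
  reg <- select_perturbed_regions(prr, threshold = 2, min_run = 3)
  expect_equal(region_resnos(reg), planted_hot_resnos())

  # monotone non-increasing in threshold (set inclusion)
  reg_hi <- select_perturbed_regions(prr, threshold = 3.5, min_run = 3)
  expect_true(all(region_resnos(reg_hi) %in% region_resnos(reg)))

  # threshold above max -> empty
  reg_top <- select_perturbed_regions(prr, threshold = max(prr$rmsd) + 1)
  expect_equal(nrow(reg_top), 0)

  # all-zero input -> empty
  prr0 <- per_residue_rmsd(g$structure, g$structure)
  expect_equal(nrow(select_perturbed_regions(prr0, threshold = 2)), 0)
})

test_that("loop_gap returns planted separations exactly and averages frames", {
  expect_equal(loop_gap(gate62()$structure)$mean_ntd, 6.2, tolerance = 1e-12)
  expect_equal(loop_gap(gate62()$structure)$mean_ctd, 6.2, tolerance = 1e-12)
  expect_equal(loop_gap(gate93()$structure)$mean_ctd, 9.3, tolerance = 1e-12)

  s <- gate62()$structure
  e <- new_ensemble(list(s, s))
  lg <- loop_gap(e)
  expect_equal(lg$distances_ntd, c(6.2, 6.2), tolerance = 1e-12)
  expect_equal(lg$mean_ntd, 6.2, tolerance = 1e-12)
})

test_that("loop_gap is superposition independent and validates lookups", {
  s <- gate62()$structure
  moved <- transform_structure(s, random_rotation(7), c(11, -4, 9))
  expect_equal(loop_gap(moved)$mean_ctd, loop_gap(s)$mean_ctd, tolerance = 1e-9)
  expect_error(loop_gap(s, pair_ntd = c("A:82", "A:9999")), "A:9999")
})

test_that("rmsf is zero on identical frames and errors on a single frame", {
  s <- gate62()$structure
  e <- new_ensemble(list(s, s, s))
  rf <- rmsf(e)
  expect_true(all(rf$rmsf < 1e-12))
  expect_error(rmsf(new_ensemble(list(s))), "frames")
})

test_that("isotropic noise on one residue gives RMSF sigma*sqrt(3) within 5%", {
  base <- loopgate:::build_peptide(rep("ALA", 9), resnos = 1:9)
  s <- new_structure(base)
  sigma <- 0.3
  target <- s$atoms$resno == 5
  set.seed(42)
  frames <- lapply(1:2000, function(i) {
    xyz <- loopgate:::coords(s)
    xyz[target, ] <- xyz[target, ] + matrix(rnorm(sum(target) * 3, sd = sigma), sum(target), 3)
    loopgate:::set_coords(s, xyz)
  })
  rf <- rmsf(new_ensemble(frames), fit_selection = "resi 1-4")
  expect_equal(rf$rmsf[rf$resno == 5], sigma * sqrt(3), tolerance = 0.05)
  expect_lt(max(rf$rmsf[rf$resno != 5]), 0.02)
})

test_that("planted hot residues rank top by RMSF", {
  g <- gate62()
  e <- make_ensemble(g$structure, hot_regions = hot_regions_default(), seed = 1)
  rf <- rmsf(e$ensemble)
  top10 <- rf$resno[order(-rf$rmsf)][1:10]
  expect_setequal(top10, planted_hot_resnos())
})
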