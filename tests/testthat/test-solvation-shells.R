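test_that("shell assignment partitions waters exhaustively", {
  fr <- make_solvated_ion_fixture("Na", c(2.3, 2.4, 5.0), seed = 2)
  asg <- assign_shells(fr, c(Na = 3.2))
  expect_length(asg$members[[1L]], 2L)
  expect_length(asg$fw, 1L)
  expect_setequal(c(asg$fss, asg$fw), which(fr$species == "O"))

  # zero radii: everything is free water
  asg0 <- assign_shells(fr, c(Na = 0))
  expect_length(asg0$fss, 0L)
  expect_length(asg0$fw, 3L)

  # an O midway between two ions is claimed by both, deduplicated in FW
  fr2 <- simulation_frame(c("Na", "Na", "O"),
                          rbind(c(8, 10, 10), c(12, 10, 10), c(10, 10, 10)),
                          20)
  asg2 <- assign_shells(fr2, c(Na = 2.5))
  expect_equal(asg2$n_claims, 2L)
  expect_length(asg2$fss, 1L)
  expect_length(asg2$fw, 0L)

  # translation invariance
  fr3 <- simulation_frame(fr$species,
                          sweep(fr$positions, 2L, c(7.3, -2.1, 11.9), "+"),
                          fr$cell)
  asg3 <- assign_shells(fr3, c(Na = 3.2))
  expect_identical(asg3$members, asg$members)
})

test_that("shell radii come from the first minimum of the O-ion RDF", {
  fr <- make_solvated_ion_fixture("Na", c(2.3, 2.4, 5.0), seed = 2)
  traj <- trajectory(list(fr))
  radii <- determine_shell_radii(traj, "Na", dr = 0.05)
  expect_gt(radii[["Na"]], 2.4)
  expect_lt(radii[["Na"]], 5.0)

  # cation shell is tighter than anion shell in the toy electrolyte
  spec <- toy_electrolyte_system(n_water = 240L, n_pairs = 8L)
  sol <- sample_toy_electrolyte(spec, n_steps = 600L, n_frames = 32L,
                                seed = 11)
  radii2 <- determine_shell_radii(sol, c("Na", "Cl"))
  expect_lt(radii2[["Na"]], radii2[["Cl"]])
  expect_gt(radii2[["Na"]], 2.42)   # beyond the Na-O contact distance

  # structureless g(r): no shell radius exists
  gas <- make_ideal_gas(2000, 20, n_frames = 40, seed = 3)
  gas <- trajectory(lapply(gas$frames, function(f)
    simulation_frame(c(rep("Na", 200), rep("O", 1800)), f$positions,
                     f$cell)))
  expect_error(determine_shell_radii(gas, "Na"), "not found")
})

test_that("FSS occupancy fractions hit their analytic limits", {
  fr <- make_solvated_ion_fixture("Na", c(2.3, 2.4, 5.0), seed = 2)
  traj <- trajectory(list(fr))
  expect_equal(fss_fraction(traj, radii = c(Na = 0))$overall, 0)
  expect_equal(fss_fraction(traj, radii = c(Na = 10))$overall, 1)
  expect_equal(fss_fraction(traj, radii = c(Na = 3.2))$overall, 2 / 3)

  # monotone non-decreasing in the shell radius
  f <- vapply(seq(0.5, 9.5, by = 0.5), function(r)
    fss_fraction(traj, radii = c(Na = r))$overall, 0)
  expect_true(all(diff(f) >= 0))
})

test_that("FSS pair distribution resolves octahedral shell distances", {
  d <- 2.5
  centre <- c(10, 10, 10)
  shell <- rbind(c(d, 0, 0), c(-d, 0, 0), c(0, d, 0), c(0, -d, 0),
                 c(0, 0, d), c(0, 0, -d))
  fr <- simulation_frame(c("Na", rep("O", 6)),
                         rbind(centre, sweep(shell, 2L, centre, "+")), 20)
  pd <- fss_pair_distribution(trajectory(list(fr)), "Na", c(Na = 3), dr = 0.02)
  nz <- pd$r[pd$p > 0]
  expect_length(nz, 2L)
  expect_lt(abs(nz[1] - d * sqrt(2)), 0.02)
  expect_equal(nz[2], 2 * d)
  expect_equal(pd$p[pd$p > 0] * pd$dr, c(12, 3) / 15, tolerance = 1e-12)

  lone <- make_solvated_ion_fixture("Na", 2.0, seed = 5)
  expect_error(fss_pair_distribution(trajectory(list(lone)), "Na",
                                     c(Na = 3)), "two or more")
})

test_that("FSS, FW and cross pair contributions sum exactly to g_OO", {
  spec <- toy_electrolyte_system(n_water = 120L, n_pairs = 4L)
  sol <- sample_toy_electrolyte(spec, n_steps = 120L, n_frames = 6L,
                                seed = 13)
  part <- rdf_partition(sol, c(Na = 3.5, Cl = 4.3), dr = 0.05)
  total <- part$fss$g + part$fw$g + part$cross$g
  expect_equal(total, part$full$g, tolerance = 1e-12)

  # limits: radii beyond the largest possible minimum-image distance make
  # the FSS piece the whole RDF; zero radii kill it
  rbig <- sqrt(3) * min(sol$frames[[1]]$cell) / 2 + 0.1
  big <- rdf_partition(sol, c(Na = rbig, Cl = rbig), dr = 0.05)
  expect_equal(big$fss$g, big$full$g, tolerance = 1e-12)
  zero <- rdf_partition(sol, c(Na = 0, Cl = 0), dr = 0.05)
  expect_equal(zero$fss$g, rep(0, length(zero$fss$g)))
  expect_equal(fss_rdf_contribution(sol, c(Na = rbig, Cl = rbig),
                                    dr = 0.05)$g,
               big$full$g, tolerance = 1e-12)
})
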