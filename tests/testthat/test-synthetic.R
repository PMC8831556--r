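test_that("ideal-gas generator is uniform, reproducible and validated", {
  traj <- make_ideal_gas(1000, 20, n_frames = 10, seed = 1)
  rdf <- compute_rdf(traj, c("O", "O"), dr = 0.02)
  # per-bin bound from the expected ordered-pair count; pairs sharing an
  # atom inflate the Poisson variance by the factor (1 + 2 N s)
  s <- 4 * pi * rdf$r^2 * rdf$dr / 8000
  expected <- 10 * 1000 * 999 * s
  z <- abs(rdf$g - 1) * sqrt(expected / (1 + 2 * 1000 * s))
  keep <- rdf$r > 1          # skip near-empty small-r bins
  expect_gt(mean(z[keep] <= 3), 0.985)
  expect_lt(max(z[keep]), 5.5)

  expect_identical(make_ideal_gas(50, 10, 3, seed = 9),
                   make_ideal_gas(50, 10, 3, seed = 9))
  expect_error(make_ideal_gas(1, 10), "at least 2")
})

test_that("diamond lattice reproduces tetrahedral-network geometry", {
  nn <- 2.76
  fr <- make_diamond_lattice(nn, 3L)
  expect_length(fr$species, 8 * 27)

  # neighbour-shell distances by explicit enumeration around one site
  d <- sort(vapply(2:216, function(j) brute_min_image(fr, 1L, j), 0))
  expect_equal(d[1:4], rep(nn, 4), tolerance = 1e-9)
  expect_equal(d[5:16], rep(sqrt(8 / 3) * nn, 12), tolerance = 1e-9)

  # 8-atom cell: every site exactly 4-coordinated under PBC
  f1 <- make_diamond_lattice(nn, 1L)
  for (i in 1:8) {
    di <- vapply(setdiff(1:8, i), function(j) brute_min_image(f1, i, j), 0)
    expect_equal(sum(di < nn * 1.01), 4L)
  }

  # tetrahedral bond angle at a vertex
  ang <- brute_triplet_angles(f1, nn * 1.1, centres = 1L)
  expect_equal(ang, rep(acos(-1 / 3) * 180 / pi, 6), tolerance = 1e-9)

  expect_error(make_diamond_lattice(-1), "positive")
  expect_error(make_diamond_lattice(2.76, 0L), "at least 1")
})

test_that("hydrogen decoration satisfies donor geometry on networks", {
  fr <- make_diamond_lattice(2.76, 2L)
  dec <- decorate_hydrogens(fr, oh_length = 1.0, hoh_angle = 104.5, seed = 3)
  n_o <- sum(dec$species == "O")
  expect_equal(sum(dec$species == "H"), 2L * n_o)
  expect_identical(dec, decorate_hydrogens(fr, 1.0, 104.5, seed = 3))

  # every O-H points within 15 degrees of some O-O bond direction
  o_idx <- which(dec$species == "O")
  h_idx <- which(dec$species == "H")
  for (h in h_idx) {
    don <- o_idx[which.min(vapply(o_idx, function(o)
      brute_min_image(dec, h, o), 0))]
    oh <- dec$positions[h, ] - dec$positions[don, ]
    devs <- vapply(setdiff(o_idx, don), function(o) {
      d <- dec$positions[o, ] - dec$positions[don, ]
      d <- d - dec$cell * round(d / dec$cell)
      if (sqrt(sum(d^2)) > 2.76 * 1.1) return(180)
      acos(max(-1, min(1, sum(oh * d) / sqrt(sum(oh^2) * sum(d^2))))) *
        180 / pi
    }, 0)
    expect_lt(min(devs), 15)
  }

  mixed <- simulation_frame(c("O", "Na"), rbind(c(0, 0, 0), c(3, 0, 0)), 10)
  expect_error(decorate_hydrogens(mixed), "only O")
})

test_that("soft-sphere Monte Carlo sampler honours its contract", {
  spec <- toy_electrolyte_system(n_water = 100L, n_pairs = 4L)

  # zero steps: frames equal the initial lattice placement
  t0 <- sample_toy_electrolyte(spec, n_steps = 0L, n_frames = 3L, seed = 5)
  expect_identical(t0$frames[[1L]]$positions, t0$frames[[3L]]$positions)

  t1 <- sample_toy_electrolyte(spec, n_steps = 60L, n_frames = 4L, seed = 6)
  t2 <- sample_toy_electrolyte(spec, n_steps = 60L, n_frames = 4L, seed = 6)
  expect_identical(t1$frames, t2$frames)
  expect_gt(t1$metadata$acceptance_rate, 0.1)
  expect_lt(t1$metadata$acceptance_rate, 0.95)

  # density above the packing bound is refused
  expect_error(toy_model_spec(species = "O", count = 500L,
                              sigma = c(O = 2.8), cell = 10),
               "packing")
})

test_that("toy solvent shows a contact peak near its sphere diameter", {
  spec <- toy_electrolyte_system(n_water = 216L, n_pairs = 0L)
  traj <- sample_toy_electrolyte(spec, n_steps = 300L, n_frames = 10L,
                                 seed = 17)
  rdf <- compute_rdf(traj, c("O", "O"), dr = 0.05)
  pk <- find_peaks(rdf, k = 1, min_prominence = 0.3)
  expect_gt(pk, 2.8 * 0.95)
  expect_lt(pk, 2.8 * 1.25)
  # Faber-Ziman limit: S -> 1 at large Q
  sq <- rdf_to_structure_factor(rdf, rho = 216 / prod(traj$frames[[1]]$cell))
  expect_lt(abs(sq$S[length(sq$S)] - 1), 0.05)
})

test_that("solvated-ion fixtures place waters at the requested radii", {
  fr <- make_solvated_ion_fixture("Na", c(2.3, 2.4, 5.0), seed = 2)
  d <- vapply(2:4, function(j) brute_min_image(fr, 1L, j), 0)
  expect_equal(sort(d), c(2.3, 2.4, 5.0), tolerance = 1e-9)
  asg <- assign_shells(fr, c(Na = 3.2))
  expect_length(asg$members[[1L]], 2L)
  expect_length(asg$fw, 1L)

  only_ion <- make_solvated_ion_fixture("Cl", numeric(0))
  expect_identical(only_ion$species, "Cl")

  six <- make_solvated_ion_fixture("Na", rep(2.0, 6), seed = 4)
  expect_length(assign_shells(six, c(Na = 2.5))$members[[1L]], 6L)

  expect_error(make_solvated_ion_fixture("Na", c(2, 40), cell = 20),
               "half the cell")
})
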