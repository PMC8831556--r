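test_that("RDF normalisation matches the closed-form single-pair value", {
  # one ordered A-B pair at exactly 5 A in a 100 A cube
  fr <- simulation_frame(c("O", "Na"), rbind(c(0, 0, 0), c(5, 0, 0)), 100)
  traj <- trajectory(list(fr))
  rdf <- compute_rdf(traj, c("O", "Na"), r_max = 10, dr = 0.1)
  k <- which(rdf$g > 0)
  expect_length(k, 1L)
  expect_equal(rdf$r[k], 5.0)
  expect_equal(rdf$g[k], 100^3 / (4 * pi * 5^2 * 0.1), tolerance = 1e-9)
})

test_that("g_ab equals g_ba bin-by-bin and matches the naive histogram", {
  spec <- toy_electrolyte_system(n_water = 60L, n_pairs = 3L)
  traj <- sample_toy_electrolyte(spec, n_steps = 40L, n_frames = 3L, seed = 8)
  g1 <- compute_rdf(traj, c("O", "Na"), dr = 0.1)
  g2 <- compute_rdf(traj, c("Na", "O"), dr = 0.1)
  expect_equal(g1$g, g2$g, tolerance = 1e-12)

  # all-pairs naive counts vs the cell histogram, like species
  gas <- make_ideal_gas(40, 8, n_frames = 2, seed = 3)
  rdf <- compute_rdf(gas, c("O", "O"), dr = 0.05)
  counts <- naive_rdf_counts(gas, r_max = 4, dr = 0.05)
  rho <- 39 / 512
  g_ref <- counts / 2 / (40 * 4 * pi * rdf$r^2 * 0.05 * rho)
  expect_equal(rdf$g, g_ref, tolerance = 1e-12)
})

test_that("structure-factor transform has exact ideal limits", {
  r <- seq(0.02, 10, by = 0.02)
  flat <- structure(list(pair = c("O", "O"), r = r, g = rep(1, length(r)),
                         dr = 0.02, rho = 0.03, n_frames = 1,
                         subset_tag = "all"), class = "rdf")
  sq <- rdf_to_structure_factor(flat, rho = 0.033)
  expect_equal(sq$S, rep(1, length(sq$Q)), tolerance = 1e-12)

  # single atom: no pairs, S identically 1
  one <- trajectory(list(simulation_frame("O", matrix(5, 1, 3), 10)))
  sd1 <- debye_structure_factor(one, c("O", "O"))
  expect_equal(sd1$S, rep(1, length(sd1$Q)), tolerance = 1e-12)

  expect_error(rdf_to_structure_factor(flat, rho = -1), "positive")
})

test_that("Fourier and Debye routes agree on an ideal gas above the finite-size cutoff", {
  gas <- make_ideal_gas(200, 14, n_frames = 4, seed = 21)
  Q <- seq(0.3, 12, by = 0.1)
  sft <- rdf_to_structure_factor(compute_rdf(gas, c("O", "O"), dr = 0.02),
                                 rho = 200 / 14^3, Q = Q)
  sdb <- debye_structure_factor(gas, c("O", "O"), Q = Q)
  sel <- Q >= 3 * 2 * pi / 14
  expect_lt(max(abs(sft$S - sdb$S)[sel]), 0.05)
  expect_lt(max(abs(sdb$S - 1)[sel]), 0.05)
})

test_that("Lorch window leaves the first-peak position unchanged", {
  spec <- toy_electrolyte_system(n_water = 216L, n_pairs = 0L)
  traj <- sample_toy_electrolyte(spec, n_steps = 300L, n_frames = 8L,
                                 seed = 31)
  rdf <- compute_rdf(traj, c("O", "O"), dr = 0.02)
  rho <- 216 / prod(traj$frames[[1]]$cell)
  s0 <- rdf_to_structure_factor(rdf, rho, window = "none")
  s1 <- rdf_to_structure_factor(rdf, rho, window = "lorch")
  p0 <- find_peaks(curve(s0$Q, s0$S), 1, min_prominence = 0.05)
  p1 <- find_peaks(curve(s1$Q, s1$S), 1, min_prominence = 0.05)
  expect_lt(abs(p0 - p1), 0.05 + 1e-9)
})

test_that("composite weights follow the Faber-Ziman formula and sum to 1", {
  w <- composite_weights(c(A = 0.5, B = 0.5), c(A = 2, B = 2))
  expect_equal(w$weights$w, c(0.25, 0.5, 0.25))

  set.seed(13)
  for (k in 1:20) {
    conc <- runif(3); conc <- conc / sum(conc)
    names(conc) <- c("O", "Na", "Cl")
    b <- stats::setNames(runif(3, 1, 10), names(conc))
    expect_equal(sum(composite_weights(conc, b)$weights$w), 1,
                 tolerance = 1e-9)
  }
  expect_error(composite_weights(c(A = 0.7, B = 0.7), c(A = 1, B = 1)),
               "sum to 1")
})

test_that("composite structure factor reduces correctly", {
  Q <- seq(0.5, 5, by = 0.1)
  mk <- function(S) structure(list(label = "x", Q = Q, S = S,
                                   method = "FT-of-g"),
                              class = "structure_factor")
  # single species: composite equals the partial
  w1 <- composite_weights(c(O = 1), c(O = 5.8))
  p <- mk(1 + sin(Q))
  expect_equal(composite_structure_factor(list("O-O" = p), w1)$S, p$S)

  # all partials flat at 1: composite is 1 by weight normalisation
  w2 <- composite_weights(c(O = 0.6, Na = 0.4), c(O = 5.8, Na = 3.6))
  flat <- list("O-O" = mk(rep(1, length(Q))),
               "O-Na" = mk(rep(1, length(Q))),
               "Na-Na" = mk(rep(1, length(Q))))
  expect_equal(composite_structure_factor(flat, w2)$S, rep(1, length(Q)),
               tolerance = 1e-12)

  bad <- flat
  bad[["Na-Na"]]$Q <- Q + 0.01
  expect_error(composite_structure_factor(bad, w2), "common Q grid")
  expect_error(composite_structure_factor(flat[1:2], w2), "missing partial")
})

test_that("minimum and peak finders match dense-grid oracles", {
  gfun <- function(r) 1 + exp(-(r - 3)^2 / 0.1) + 0.5 * exp(-(r - 5)^2 / 0.2)
  r <- seq(0.02, 8, by = 0.02)
  found <- find_first_minimum(curve(r, gfun(r)))
  dense <- seq(3, 5, by = 1e-4)
  oracle <- dense[which.min(gfun(dense))]
  expect_lt(abs(found - oracle), 0.02 + 1e-9)

  # monotone curve has no first minimum
  expect_error(find_first_minimum(curve(r, exp(-r))), "not found")

  # single Gaussian bump: peak centre within one bin
  bump <- curve(r, 0.3 * exp(-(r - 3)^2 / 0.05))
  expect_lt(abs(find_peaks(bump, 1) - 3), 0.02 + 1e-9)

  # structureless noise: either no peak clears the threshold, or whatever
  # does is flagged with a prominence far below real liquid structure
  gas <- make_ideal_gas(1000, 20, n_frames = 10, seed = 19)
  flatg <- compute_rdf(gas, c("O", "O"), dr = 0.02)
  sel <- flatg$r >= 1
  noise_pk <- tryCatch(
    find_peaks(curve(flatg$r[sel], flatg$g[sel]), 1, min_prominence = 0.1),
    error = function(e) e)
  if (inherits(noise_pk, "error")) {
    expect_match(conditionMessage(noise_pk), "not found")
  } else {
    expect_lt(attr(noise_pk, "prominence"), 0.2)
  }
})

test_that("diamond-lattice RDF peaks sit on the analytic shell distances", {
  traj <- trajectory(list(make_diamond_lattice(2.76, 3L)))
  rdf <- compute_rdf(traj, c("O", "O"), dr = 0.02)
  pks <- find_peaks(rdf, k = 2)
  expect_equal(pks[1], 2.76, tolerance = 0.021)
  expect_equal(pks[2], sqrt(8 / 3) * 2.76, tolerance = 0.021)
})
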