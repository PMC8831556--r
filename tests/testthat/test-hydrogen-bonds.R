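two_waters <- function(dev_deg, d_oo = 2.8, cell = 50) {
  # donor at the origin with one H pointing dev_deg away from the O-O axis
  o1 <- c(20, 20, 20)
  o2 <- o1 + c(d_oo, 0, 0)
  a <- dev_deg * pi / 180
  w1 <- place_water(o1, c(cos(a), sin(a), 0), c(0, 0, 1))
  w2 <- place_water(o2, c(0, 0, 1), c(1, 0, 0))   # acceptor H point away
  waters_frame(list(w1, w2), cell = cell)
}

test_that("geometric criteria decide water-water and water-anion bonds", {
  net <- detect_hbonds(two_waters(5))
  expect_equal(nrow(net$edges), 1L)
  expect_equal(net$edges$donor, 1L)
  expect_equal(net$edges$acceptor, 4L)
  expect_equal(net$edges$type, "OO")

  expect_equal(nrow(detect_hbonds(two_waters(60))$edges), 0L)
  # beyond the O-O distance cutoff no bond forms even when aligned
  expect_equal(nrow(detect_hbonds(two_waters(5, d_oo = 3.8))$edges), 0L)

  # proton aimed at an anion 2.2 A away
  o1 <- c(20, 20, 20)
  w1 <- place_water(o1, c(1, 0, 0), c(0, 1, 0))
  fr <- waters_frame(list(w1), ions = list(
    list(species = "Cl", pos = o1 + c(3.2, 0, 0))))
  net2 <- detect_hbonds(fr, anions = "Cl")
  expect_equal(net2$edges$type, "OX")
  expect_equal(net2$edges$acceptor, 4L)

  # an H with no oxygen within the covalent cutoff is an error
  orphan <- simulation_frame(c("O", "H"), rbind(c(5, 5, 5), c(9, 5, 5)), 20)
  expect_error(detect_hbonds(orphan), "covalent")
})

test_that("edge counts are monotone under tightening and rigid-motion invariant", {
  fr <- decorate_hydrogens(make_diamond_lattice(2.9, 2L), 1.0, 104.5,
                           seed = 31)
  loose <- hbond_criteria(r_oo = 3.5, theta_max = 30)
  n_loose <- nrow(detect_hbonds(fr, loose)$edges)
  expect_gt(n_loose, 0L)
  for (crit in list(hbond_criteria(r_oo = 3.0, theta_max = 30),
                    hbond_criteria(r_oo = 3.5, theta_max = 15),
                    hbond_criteria(r_oo = 3.0, theta_max = 15)))
    expect_lte(nrow(detect_hbonds(fr, crit)$edges), n_loose)

  # rigid rotation of a cluster preserves the edge list
  set.seed(41)
  blocks <- lapply(1:5, function(k)
    place_water(c(22, 22, 22) + 2.8 * (k - 3) * c(1, 0.2, 0) / sqrt(1.04),
                stats::rnorm(3), stats::rnorm(3)))
  fr2 <- waters_frame(blocks, cell = 60)
  th <- 0.9
  Rz <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  cen <- c(30, 30, 30)
  rot <- simulation_frame(fr2$species,
                          sweep(sweep(fr2$positions, 2L, cen) %*% t(Rz),
                                2L, cen, "+"), fr2$cell)
  e1 <- detect_hbonds(fr2)$edges
  e2 <- detect_hbonds(rot)$edges
  expect_identical(e1[c("donor", "h", "acceptor")],
                   e2[c("donor", "h", "acceptor")])
})

test_that("anion-shell nonbonded fractions are exact on constructed shells", {
  cl <- c(20, 20, 20)
  mk_shell <- function(n_toward, n_away) {
    dirs <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0))
    blocks <- list()
    for (k in seq_len(n_toward + n_away)) {
      o <- cl + 3.0 * dirs[k, ]
      if (k <= n_toward)
        blocks[[k]] <- place_water(o, -dirs[k, ], c(0, 0, 1))   # H at 2 A
      else
        blocks[[k]] <- place_water(o, c(0, 0, 1), dirs[k, ])    # H away
    }
    trajectory(list(waters_frame(blocks, cell = 40, ions = list(
      list(species = "Cl", pos = cl)))))
  }
  crit <- hbond_criteria(r_hx = 2.5)
  expect_equal(fss_anion_nonbonded_fraction(mk_shell(4, 0), "Cl",
                                            c(Cl = 3.5), crit), 0)
  expect_equal(fss_anion_nonbonded_fraction(mk_shell(3, 1), "Cl",
                                            c(Cl = 3.5), crit), 0.25)
  expect_error(fss_anion_nonbonded_fraction(mk_shell(4, 0), "Cl",
                                            c(Cl = 0.5), crit),
               "no waters")
})

test_that("hydrogen-bond chains require a bonded shell pair plus a third water", {
  # W1 -> W2 -> W3 collinear chain, all inside the Cl shell
  o <- lapply(0:2, function(k) c(10 + 2.8 * k, 10, 10))
  w <- list(place_water(o[[1]], c(1, 0, 0), c(0, 1, 0)),
            place_water(o[[2]], c(1, 0, 0), c(0, 1, 0)),
            place_water(o[[3]], c(0, 1, 0), c(1, 0, 0)))
  all_in <- trajectory(list(waters_frame(w, cell = 30, ions = list(
    list(species = "Cl", pos = c(12.8, 12.3, 10))))))
  expect_equal(fss_chain_fraction(all_in, "Cl", c(Cl = 3.7)), 1.0)

  # a bonded pair with no third water is not a chain
  pair_only <- trajectory(list(waters_frame(w[1:2], cell = 30, ions = list(
    list(species = "Cl", pos = c(11.4, 12.3, 10))))))
  expect_equal(fss_chain_fraction(pair_only, "Cl", c(Cl = 3.5)), 0.0)

  # mutually non-bonded shell waters: no chains
  far <- list(place_water(c(10, 10, 10), c(0, 0, 1), c(1, 0, 0)),
              place_water(c(14.5, 10, 10), c(0, 0, 1), c(1, 0, 0)))
  none <- trajectory(list(waters_frame(far, cell = 30, ions = list(
    list(species = "Cl", pos = c(12.25, 11, 10))))))
  expect_equal(fss_chain_fraction(none, "Cl", c(Cl = 3.5)), 0.0)

  # third water outside the shell counts under "any", not under "fss"
  out <- trajectory(list(waters_frame(w, cell = 30, ions = list(
    list(species = "Cl", pos = c(11.4, 12.1, 10))))))
  expect_equal(fss_chain_fraction(out, "Cl", c(Cl = 3.0),
                                  third_water_scope = "any"), 1.0)
  expect_equal(fss_chain_fraction(out, "Cl", c(Cl = 3.0),
                                  third_water_scope = "fss"), 0.0)
})

test_that("graph-based chain detection matches the brute-force detector", {
  crit <- hbond_criteria()
  for (seed in 1:10) {
    set.seed(seed)
    blocks <- lapply(1:10, function(k)
      place_water(runif(3, 9, 17), stats::rnorm(3), stats::rnorm(3)))
    fr <- waters_frame(blocks, cell = 26, ions = list(
      list(species = "Cl", pos = c(13, 13, 13))))
    traj <- trajectory(list(fr))
    got <- tryCatch(fss_chain_fraction(traj, "Cl", c(Cl = 6), crit),
                    error = function(e) NA_real_)
    ref <- tryCatch(brute_chain_fraction(fr, "Cl", c(Cl = 6), crit),
                    error = function(e) NA_real_)
    expect_equal(got, ref)
  }
})
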