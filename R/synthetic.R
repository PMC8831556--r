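#' Ideal-gas (uniform random) trajectory
#'
#' The null model for every pair statistic: independent uniform positions,
#' for which g(r) = 1 and S(Q) = 1 up to sampling noise.
#'
#' @param n number of atoms (>= 2), all labelled `"O"`.
#' @param cell cubic cell edge (angstroms) or three edge lengths.
#' @param n_frames number of independent frames.
#' @param seed integer RNG seed (optional; the current RNG state is used when
#'   omitted).
#' @return A [trajectory()].
#' @export
make_ideal_gas <- function(n, cell, n_frames = 1L, seed = NULL) {
  if (n < 2L) stop("`n` must be at least 2")
  if (length(cell) == 1L) cell <- rep(cell, 3L)
  if (!is.null(seed)) set.seed(seed)
  frames <- lapply(seq_len(n_frames), function(k) {
    pos <- cbind(runif(n, 0, cell[1]), runif(n, 0, cell[2]),
                 runif(n, 0, cell[3]))
    simulation_frame(rep("O", n), pos, cell, k)
  })
  trajectory(frames, metadata = list(generator = "ideal_gas", n = n,
                                     seed = seed))
}

#' Diamond-cubic oxygen network
#'
#' A perfect tetrahedral network: every site has exactly four nearest
#' neighbours at `nn_distance`, bond angles of arccos(-1/3) = 109.47 degrees,
#' and a second-neighbour distance of sqrt(8/3) * `nn_distance`.  This is the
#' analytic stand-in for the tetrahedral hydrogen-bond network of water,
#' whose signatures are the ~4.5 A second O-O distance and the ~109.5 degree
#' O-O-O angle.
#'
#' @param nn_distance nearest-neighbour distance in angstroms.
#' @param replicas number of conventional cubic cells per axis (>= 1).
#' @return A [simulation_frame()] with `8 * replicas^3` oxygen atoms.
#' @export
make_diamond_lattice <- function(nn_distance, replicas = 1L) {
  if (nn_distance <= 0) stop("`nn_distance` must be positive")
  replicas <- as.integer(replicas)
  if (replicas < 1L) stop("`replicas` must be at least 1")
  a <- 4 * nn_distance / sqrt(3)         # conventional lattice constant
  fcc <- rbind(c(0, 0, 0), c(0, .5, .5), c(.5, 0, .5), c(.5, .5, 0))
  basis <- rbind(fcc, sweep(fcc, 2L, c(.25, .25, .25), "+"))
  shifts <- as.matrix(expand.grid(0:(replicas - 1L), 0:(replicas - 1L),
                                  0:(replicas - 1L)))
  pos <- do.call(rbind, lapply(seq_len(nrow(shifts)), function(s)
    sweep(basis, 2L, shifts[s, ], "+")))
  simulation_frame(rep("O", nrow(pos)), pos * a, rep(a * replicas, 3L))
}

#' Decorate oxygen sites with two hydrogens each
#'
#' Adds two H per O at the stated internal geometry.  When the frame is a
#' connected network (every O has at least two neighbours within 1.25x the
#' minimum O-O distance) the first O-H points exactly along an O-O bond and
#' the second lies in the plane of two bonds at `hoh_angle` from the first,
#' so donor geometric hydrogen-bond criteria are satisfiable by
#' construction.  Otherwise molecules are randomly oriented.
#'
#' @param frame a [simulation_frame()] containing only `"O"` atoms.
#' @param oh_length O-H bond length in angstroms.
#' @param hoh_angle internal H-O-H angle in degrees, in (0, 180).
#' @param seed integer RNG seed (optional).
#' @return A [simulation_frame()] with the original O atoms followed by 2 H
#'   per O.
#' @export
decorate_hydrogens <- function(frame, oh_length = 1.0, hoh_angle = 104.5,
                               seed = NULL) {
  if (!all(frame$species == "O"))
    stop("validation error: frame must contain only O atoms")
  if (oh_length <= 0) stop("`oh_length` must be positive")
  if (hoh_angle <= 0 || hoh_angle >= 180)
    stop("`hoh_angle` must lie in (0, 180)")
  if (!is.null(seed)) set.seed(seed)
  pos <- frame$positions
  n <- nrow(pos)
  ang <- hoh_angle * pi / 180

  # neighbour lists within 1.25x the minimum O-O distance
  nbrs <- network_neighbours(pos, frame$cell)
  networked <- n > 1L && all(vapply(nbrs, length, 0L) >= 2L)

  hpos <- matrix(0, 2L * n, 3L)
  for (i in seq_len(n)) {
    if (networked) {
      pick <- sort(sample(nbrs[[i]], 2L))
      d1 <- min_image_disp(pos[i, ], pos[pick[1L], , drop = FALSE],
                           frame$cell)[1L, ]
      d2 <- min_image_disp(pos[i, ], pos[pick[2L], , drop = FALSE],
                           frame$cell)[1L, ]
      u1 <- d1 / sqrt(sum(d1^2))
      # component of the second bond direction orthogonal to the first
      w <- d2 - sum(d2 * u1) * u1
      w <- w / sqrt(sum(w^2))
      u2 <- cos(ang) * u1 + sin(ang) * w
    } else {
      u1 <- random_unit_vector()
      w <- random_unit_vector()
      w <- w - sum(w * u1) * u1
      w <- w / sqrt(sum(w^2))
      u2 <- cos(ang) * u1 + sin(ang) * w
    }
    hpos[2L * i - 1L, ] <- pos[i, ] + oh_length * u1
    hpos[2L * i, ] <- pos[i, ] + oh_length * u2
  }
  simulation_frame(c(frame$species, rep("H", 2L * n)), rbind(pos, hpos),
                   frame$cell, frame$frame_index)
}

network_neighbours <- function(pos, cell) {
  n <- nrow(pos)
  if (n < 2L) return(rep(list(integer(0)), n))
  dmin <- Inf
  dm <- vector("list", n)
  for (i in seq_len(n)) {
    d <- min_image_disp(pos[i, ], pos, cell)
    r <- sqrt(rowSums(d^2))
    r[i] <- Inf
    dm[[i]] <- r
    dmin <- min(dmin, min(r))
  }
  lapply(dm, function(r) which(r <= 1.25 * dmin))
}

random_unit_vector <- function() {
  v <- rnorm(3L)
  v / sqrt(sum(v^2))
}

#' Specify a soft-sphere toy electrolyte
#'
#' Defines the species, per-species soft-sphere diameters and counts, the
#' cell and the reduced temperature of the Monte Carlo model used by
#' [sample_toy_electrolyte()].  The default diameters mimic a NaCl-like salt:
#' the cation sphere (2.04 A, twice the 1.02 A ionic radius) is markedly
#' smaller than the anion sphere (3.62 A, twice 1.81 A), with a 2.8 A
#' water-oxygen sphere in between.
#'
#' @param species character vector of species labels.
#' @param count integer atom count per species.
#' @param sigma soft-sphere diameter per species in angstroms (additive
#'   Lorentz combination `sigma_ij = (sigma_i + sigma_j)/2`).
#' @param cell cubic cell edge in angstroms.
#' @param tstar dimensionless temperature of the Metropolis acceptance rule.
#' @return An object of class `toy_model_spec`.
#' @export
toy_model_spec <- function(species = c("O", "Na", "Cl"),
                           count = c(240L, 0L, 0L),
                           sigma = c(O = 2.8, Na = 2.04, Cl = 3.62),
                           cell = 19.61, tstar = 1.0) {
  if (length(count) != length(species))
    stop("`count` must match `species`")
  if (any(count < 0)) stop("counts must be non-negative")
  if (sum(count) < 1L) stop("at least one atom is required")
  sigma <- sigma[species]
  if (anyNA(sigma)) stop("`sigma` must name every species")
  if (length(cell) == 1L) cell <- rep(cell, 3L)
  vol <- prod(cell)
  eta <- sum(count * pi / 6 * sigma^3) / vol   # sphere packing fraction
  if (eta >= 0.60)
    stop("validation error: packing fraction ", signif(eta, 3),
         " exceeds the 0.60 close-packing bound for this model")
  counts <- as.integer(count); names(counts) <- species
  structure(list(species = species, count = counts, sigma = sigma,
                 cell = cell, tstar = tstar, packing_fraction = eta),
            class = "toy_model_spec")
}

#' Standard toy electrolyte study system
#'
#' The reference conditions used throughout the package's validation: a
#' liquid-like one-sphere-per-molecule solvent (packing fraction 0.366,
#' which for the 2.8 A solvent sphere corresponds to a water-like oxygen
#' density of ~0.032 per cubic angstrom) with an optional NaCl-like salt at
#' a given mole ratio.  The cell edge is computed so that the soft-sphere
#' packing fraction is the same with and without salt: since dissolving
#' salt at constant volume would compress the solvent, holding the packing
#' fraction fixed is the constant-pressure proxy that mirrors solutions
#' prepared at 1 bar.
#'
#' @param n_water number of solvent spheres.
#' @param n_pairs number of cation-anion pairs (0 for pure solvent); 8
#'   pairs per 240 waters is a 1:30 salt:water mole ratio, inside the
#'   1:83-1:10 span typical of concentrated-electrolyte studies.
#' @param packing_fraction target soft-sphere packing fraction.
#' @param sigma per-species diameters (angstroms).
#' @param tstar reduced temperature.
#' @return A [toy_model_spec()].
#' @export
toy_electrolyte_system <- function(n_water = 240L, n_pairs = 8L,
                                   packing_fraction = 0.366,
                                   sigma = c(O = 2.8, Na = 2.04, Cl = 3.62),
                                   tstar = 1.0) {
  count <- c(O = as.integer(n_water), Na = as.integer(n_pairs),
             Cl = as.integer(n_pairs))
  vol <- sum(count * pi / 6 * sigma[names(count)]^3) / packing_fraction
  keep <- count > 0L
  toy_model_spec(species = names(count)[keep], count = count[keep],
                 sigma = sigma, cell = vol^(1 / 3), tstar = tstar)
}

#' Sample a toy electrolyte by soft-sphere Monte Carlo
#'
#' Metropolis single-particle-move Monte Carlo of purely repulsive soft
#' spheres (pair energy `(sigma_ij/r)^12`).  The model emulates salt-water
#' mixtures in which a small cation and a large anion perturb the packing of
#' a one-sphere-per-molecule solvent; it carries no electrostatics because
#' every analysis in this package consumes coordinates only.  The first half
#' of the sweeps is discarded as equilibration and `n_frames` frames are
#' sampled evenly from the remainder.  The acceptance rate and per-frame
#' energies are stored in the trajectory metadata.
#'
#' @param spec a [toy_model_spec()].
#' @param n_steps number of MC sweeps (each sweep attempts one move per
#'   atom).  With `n_steps = 0` the returned frames all equal the initial
#'   lattice placement.
#' @param n_frames number of frames to record.
#' @param seed integer RNG seed (optional).
#' @param max_disp maximum trial displacement per axis in angstroms.
#' @return A [trajectory()].
#' @export
sample_toy_electrolyte <- function(spec, n_steps = 400L, n_frames = 10L,
                                   seed = NULL, max_disp = 0.35) {
  if (!inherits(spec, "toy_model_spec")) stop("`spec` must be a toy_model_spec")
  if (n_steps < 0L) stop("`n_steps` must be non-negative")
  if (!is.null(seed)) set.seed(seed)
  n <- sum(spec$count)
  species <- rep(spec$species, spec$count)
  sig <- rep(spec$sigma, spec$count)
  # initial placement: simple cubic lattice, species assigned in shuffled order
  m <- ceiling(n^(1 / 3))
  grid <- as.matrix(expand.grid(seq_len(m), seq_len(m), seq_len(m))) - 0.5
  pos0 <- sweep(grid[seq_len(n), , drop = FALSE], 2L, spec$cell / m, "*")
  ord <- sample.int(n)
  species <- species[ord]; sig <- sig[ord]

  if (n_steps == 0L) {
    frames <- lapply(seq_len(n_frames), function(k)
      simulation_frame(species, pos0, spec$cell, k))
    return(trajectory(frames, metadata = list(generator = "toy_electrolyte",
                                              spec = spec, seed = seed,
                                              acceptance_rate = NA_real_)))
  }
  keep <- max(1L, floor(n_steps / 2) + 1L)
  record_at <- unique(as.integer(round(seq(keep, n_steps,
                                           length.out = n_frames))))
  r_cut <- min(min(spec$cell) / 2, 3 * max(spec$sigma))
  res <- cpp_mc_soft_sphere(pos0, sig, spec$cell, spec$tstar, max_disp,
                            as.integer(n_steps), record_at, r_cut)
  frames <- lapply(seq_along(res$frames), function(k)
    simulation_frame(species, res$frames[[k]], spec$cell, k))
  # if n_frames exceeded distinct sweeps, pad by repeating the last frame
  while (length(frames) < n_frames)
    frames[[length(frames) + 1L]] <- frames[[length(frames)]]
  trajectory(frames, metadata = list(
    generator = "toy_electrolyte", spec = spec, seed = seed,
    n_steps = n_steps, acceptance_rate = res$acceptance_rate,
    energies = res$energies, record_at = record_at))
}

#' Deterministic solvated-ion fixture
#'
#' One ion at the cell centre with oxygen atoms placed at exactly the stated
#' radial distances in random, mutually non-overlapping directions.  Used to
#' test solvation-shell assignment with known occupancies.
#'
#' @param ion_species label for the central ion.
#' @param shell_distances numeric vector of radial O-ion distances in
#'   angstroms (possibly empty), each below half the cell edge.
#' @param seed integer RNG seed (optional).
#' @param cell cubic cell edge in angstroms.
#' @param min_oo minimum allowed O-O separation in angstroms.
#' @return A [simulation_frame()] with the ion first, then the O atoms.
#' @export
make_solvated_ion_fixture <- function(ion_species, shell_distances,
                                      seed = NULL, cell = 20, min_oo = 1.5) {
  if (length(cell) == 1L) cell <- rep(cell, 3L)
  if (length(shell_distances) &&
      (any(shell_distances <= 0) || any(shell_distances >= min(cell) / 2)))
    stop("shell distances must be positive and below half the cell edge")
  if (!is.null(seed)) set.seed(seed)
  centre <- cell / 2
  placed <- matrix(numeric(0), 0L, 3L)
  for (d in shell_distances) {
    ok <- FALSE
    for (try in seq_len(1000L)) {
      cand <- centre + d * random_unit_vector()
      if (!nrow(placed) ||
          all(sqrt(rowSums(min_image_disp(cand, placed, cell)^2)) >= min_oo)) {
        placed <- rbind(placed, cand)
        ok <- TRUE
        break
      }
    }
    if (!ok)
      stop("generation error: could not place an O at distance ", d,
           " without overlap after 1000 tries")
  }
  simulation_frame(c(ion_species, rep("O", nrow(placed))),
                   rbind(centre, placed), cell)
}
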