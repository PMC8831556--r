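#' Spherical cavity region
#'
#' The excluded region of a frame: one sphere per excluded ion, centred on
#' the ion and with the radius of its first solvation shell.  The retained
#' region (box minus spheres, under minimum-image wrapping) is where a
#' subset of waters lives after solvation shells are carved out.
#'
#' @param centers numeric matrix (n x 3) of sphere centres in angstroms
#'   (may have zero rows).
#' @param radii numeric vector of positive sphere radii, one per centre.
#' @param cell orthorhombic cell edge lengths.
#' @return An object of class `cavity_region`.
#' @export
cavity_region <- function(centers, radii, cell) {
  centers <- as.matrix(centers)
  if (!nrow(centers)) centers <- matrix(numeric(0), 0L, 3L)
  if (ncol(centers) != 3L) stop("`centers` must have three columns")
  if (length(radii) != nrow(centers))
    stop("`radii` must have one entry per centre")
  if (length(radii) && any(radii <= 0)) stop("cavity radii must be positive")
  if (length(cell) == 1L) cell <- rep(cell, 3L)
  # wrap centres into the cell
  if (nrow(centers))
    centers <- centers - sweep(floor(sweep(centers, 2L, cell, "/")),
                               2L, cell, "*")
  structure(list(centers = centers, radii = as.numeric(radii),
                 cell = as.numeric(cell)), class = "cavity_region")
}

#' Excluded-volume normalisation curve
#'
#' Monte-Carlo estimate of the pair-distance density of uniformly random
#' points confined to the retained region (box minus cavity spheres,
#' minimum-image), expressed as the ratio to the free-box ideal-gas density:
#' `F(r) = P(point at distance r in a random direction is retained | start
#' point retained)`.  Dividing a subset pair histogram by F(r) makes it
#' comparable to the RDF of a homogeneous liquid.  With an empty cavity set
#' the analytic shortcut returns exactly 1 at every r.
#'
#' @param cavity a [cavity_region()].
#' @param r bin centres (angstroms) matching the target RDF.
#' @param n_samples number of Monte-Carlo start points (>= 1e4).
#' @param seed integer RNG seed (optional).
#' @return list with `ratio` (F at each r), `retained_fraction`, and
#'   `analytic` (TRUE when the no-cavity shortcut was taken).
#' @export
random_point_normalization <- function(cavity, r, n_samples = 2e5,
                                       seed = NULL) {
  if (!inherits(cavity, "cavity_region"))
    stop("`cavity` must be a cavity_region")
  if (!nrow(cavity$centers))
    return(list(ratio = rep(1, length(r)), retained_fraction = 1,
                analytic = TRUE))
  if (n_samples < 1e4) stop("`n_samples` must be at least 1e4")
  if (!is.null(seed)) set.seed(seed)
  res <- cpp_cavity_norm(cavity$centers, cavity$radii, cavity$cell, r,
                         as.integer(n_samples))
  if (res$retained_fraction < 0.01)
    stop("degenerate region: retained volume fraction ",
         signif(res$retained_fraction, 3), " is below 1%")
  list(ratio = res$ratio, retained_fraction = res$retained_fraction,
       analytic = FALSE)
}

#' Excluded-volume-corrected subset RDF
#'
#' O-O radial distribution function of a subset of waters occupying a
#' cavity-riddled region, renormalised so it is comparable to the RDF of a
#' homogeneous liquid: each frame's subset pair histogram is divided by the
#' ideal-pair expectation at the subset density in the *retained* volume and
#' by the [random_point_normalization()] curve of the frame's cavities, then
#' frames are averaged.  For a structureless subset in an arbitrary cavity
#' geometry the corrected g is 1 at all r, which is the correction's
#' defining property; with no cavities it reduces exactly to the standard
#' RDF.
#'
#' The correction loses meaning when the cavities swallow most of the box
#' (as happens at extreme salt fractions), so the computation refuses to
#' proceed when the mean retained volume fraction falls below
#' `retained_min`; the refusal reports the computed fraction.
#'
#' @param traj a [trajectory()].
#' @param subset list (one per frame) of O atom indices in the subset.
#' @param cavities list (one per frame) of [cavity_region()] objects.
#' @param dr bin width in angstroms.
#' @param r_max histogram range; default half the minimum cell edge.
#' @param n_samples Monte-Carlo start points per frame for the
#'   normalisation curve.
#' @param seed integer RNG seed (optional).
#' @param retained_min minimum admissible mean retained volume fraction.
#' @return An `rdf` with extra fields `retained_fraction` (mean over
#'   frames) and `g_uncorrected` (the same histogram normalised with the
#'   retained-region density but without the cavity-geometry factor F(r);
#'   it sinks below 1 at large r when cavities are present, which is
#'   exactly what the correction repairs).
#' @export
corrected_subset_rdf <- function(traj, subset, cavities, dr = 0.02,
                                 r_max = NULL, n_samples = 2e5, seed = NULL,
                                 retained_min = 0.30) {
  cell <- traj$frames[[1L]]$cell
  vol <- prod(cell)
  if (is.null(r_max)) r_max <- min(cell) / 2
  nf <- length(traj$frames)
  if (length(subset) != nf || length(cavities) != nf)
    stop("`subset` and `cavities` must have one element per frame")
  for (k in seq_len(nf))
    if (!length(subset[[k]]))
      stop("empty subset in frame ", k)
  if (!is.null(seed)) set.seed(seed)
  nbins <- as.integer(floor(r_max / dr + 0.5))
  r <- dr * seq_len(nbins)

  norms <- lapply(cavities, random_point_normalization, r = r,
                  n_samples = n_samples)
  fracs <- vapply(norms, `[[`, 0, "retained_fraction")
  if (mean(fracs) < retained_min)
    stop("excluded-volume correction refused: mean retained volume ",
         "fraction ", signif(mean(fracs), 3), " is below the ",
         retained_min, " threshold (cavities dominate the box)")

  g_sum <- numeric(nbins)
  gu_sum <- numeric(nbins)
  for (k in seq_len(nf)) {
    fr <- traj$frames[[k]]
    sub <- subset[[k]]
    h <- 2 * as.numeric(cpp_pair_hist(fr$positions[sub, , drop = FALSE],
                                      fr$positions[sub, , drop = FALSE],
                                      fr$cell, r_max, dr, TRUE))
    n <- length(sub)
    v_ret <- vol * fracs[k]
    ideal_ret <- n * 4 * pi * r^2 * dr * (n - 1) / v_ret
    Fr <- norms[[k]]$ratio
    g_sum <- g_sum + ifelse(Fr > 0, h / (ideal_ret * Fr),
                            ifelse(h == 0, 0, NA_real_))
    gu_sum <- gu_sum + h / ideal_ret
  }
  new_rdf(c("O", "O"), r, g_sum / nf, dr, NA_real_, nf, "corrected-subset",
          extra = list(retained_fraction = mean(fracs),
                       g_uncorrected = gu_sum / nf,
                       n_samples = n_samples))
}
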