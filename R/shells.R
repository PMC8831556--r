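#' First-solvation-shell radii from O-ion RDFs
#'
#' For each ion species the shell radius is the first minimum of the O-ion
#' radial distribution function, the standard geometric definition of an
#' ionic first solvation shell (FSS).  Radii are computed once from the
#' whole trajectory, not per frame, for stability.
#'
#' Because the O-ion histograms of a small system are far noisier than the
#' O-O one (few ions per frame), the curve is smoothed with a short moving
#' average and a larger prominence threshold is applied before the minimum
#' is located; shallow first minima of weakly structured shells would
#' otherwise be lost to bin noise.
#'
#' @param traj a [trajectory()].
#' @param ion_species character vector of ion labels present in `traj`.
#' @param dr RDF bin width in angstroms (coarser than the O-O default, for
#'   counting statistics).
#' @param r_max RDF range; default half the minimum cell edge.
#' @param smooth_bins width (bins) of the moving average applied to the
#'   O-ion g(r) before minimum finding.
#' @param min_prominence prominence threshold passed to
#'   [find_first_minimum()].
#' @param r_min bins below this radius (angstroms) are ignored: no ion-water
#'   contact occurs there, and in sparse histograms the near-empty small-r
#'   bins carry the largest relative noise.
#' @return named numeric vector of shell radii (angstroms) with the source
#'   RDFs attached as attribute `rdfs`.
#' @export
determine_shell_radii <- function(traj, ion_species, dr = 0.05,
                                  r_max = NULL, smooth_bins = 5L,
                                  min_prominence = 0.1, r_min = 1.5) {
  radii <- numeric(0)
  rdfs <- list()
  for (sp in ion_species) {
    if (is.null(traj$composition[[sp]]))
      stop("validation error: ion species '", sp, "' not present")
    rdf <- compute_rdf(traj, c("O", sp), r_max = r_max, dr = dr)
    ys <- if (smooth_bins > 1L)
      as.numeric(stats::filter(rdf$g, rep(1 / smooth_bins, smooth_bins),
                               sides = 2L))
    else rdf$g
    ok <- !is.na(ys) & rdf$r >= r_min
    r <- tryCatch(
      find_first_minimum(list(x = rdf$r[ok], y = ys[ok]),
                         min_prominence = min_prominence),
      error = function(e)
        stop("shell radius for '", sp, "' not found: ", conditionMessage(e)))
    radii[sp] <- r
    rdfs[[sp]] <- rdf
  }
  attr(radii, "rdfs") <- rdfs
  radii
}

#' Assign waters to ionic first solvation shells
#'
#' An O atom belongs to the FSS of ion i when its minimum-image distance to
#' that ion is at most the shell radius of the ion's species.  Overlapping
#' claims are allowed (an O may sit in several shells); the free-water (FW)
#' set is the O atoms claimed by no ion, so FW and the union of FSSs always
#' partition the O atoms exhaustively.
#'
#' @param frame a [simulation_frame()].
#' @param radii named numeric vector of shell radii per ion species
#'   (angstroms), e.g. from [determine_shell_radii()].
#' @return An object of class `shell_assignment`: `ions` (data.frame of
#'   atom index and species), `members` (list of O index vectors per ion),
#'   `n_claims` (per-O claim count), `fss` (O indices claimed at least
#'   once), `fw` (unclaimed O indices), `radii`.
#' @export
assign_shells <- function(frame, radii) {
  if (any(radii < 0)) stop("shell radii must be non-negative")
  o_idx <- species_indices(frame, "O")
  ion_idx <- which(frame$species %in% names(radii))
  members <- vector("list", length(ion_idx))
  claims <- integer(length(o_idx))
  opos <- frame$positions[o_idx, , drop = FALSE]
  for (k in seq_along(ion_idx)) {
    i <- ion_idx[k]
    rad <- radii[[frame$species[i]]]
    if (rad <= 0 || !length(o_idx)) { members[[k]] <- integer(0); next }
    d2 <- rowSums(min_image_disp(frame$positions[i, ], opos, frame$cell)^2)
    inside <- which(d2 <= rad^2)
    members[[k]] <- o_idx[inside]
    claims[inside] <- claims[inside] + 1L
  }
  structure(list(
    ions = data.frame(index = ion_idx, species = frame$species[ion_idx],
                      stringsAsFactors = FALSE),
    members = members,
    n_claims = claims,
    fss = o_idx[claims > 0L],
    fw = o_idx[claims == 0L],
    radii = radii), class = "shell_assignment")
}

#' Shell assignments for every frame of a trajectory
#' @inheritParams assign_shells
#' @param traj a [trajectory()].
#' @return list of [assign_shells()] results, one per frame.
#' @export
assign_shells_trajectory <- function(traj, radii) {
  lapply(traj$frames, assign_shells, radii = radii)
}

#' Fraction of waters inside first solvation shells
#'
#' Time-averaged fraction of O atoms claimed by at least one ion (overall,
#' counting multiply-claimed O once) and by each ion species separately.
#'
#' @param traj a [trajectory()].
#' @param assignments per-frame assignments from
#'   [assign_shells_trajectory()]; computed from `radii` when omitted.
#' @param radii shell radii (used when `assignments` is missing).
#' @return list with `overall` and named `per_species` fractions.
#' @export
fss_fraction <- function(traj, assignments = NULL, radii = NULL) {
  if (is.null(assignments)) {
    if (is.null(radii)) stop("supply `assignments` or `radii`")
    assignments <- assign_shells_trajectory(traj, radii)
  }
  n_o <- traj$composition[["O"]]
  species <- unique(assignments[[1L]]$ions$species)
  tot_in <- 0
  per <- stats::setNames(numeric(length(species)), species)
  for (asg in assignments) {
    tot_in <- tot_in + length(asg$fss)
    for (sp in species) {
      mem <- unique(unlist(asg$members[asg$ions$species == sp]))
      per[sp] <- per[sp] + length(mem)
    }
  }
  nf <- length(assignments)
  list(overall = tot_in / (n_o * nf), per_species = per / (n_o * nf))
}

#' O-O distance distribution inside one species' solvation shells
#'
#' Normalised histogram of minimum-image O-O distances over unordered pairs
#' whose members lie in the same ion's FSS, pooled over ions and frames
#' (pair-weighted averaging: every qualifying pair counts once, so shells
#' with more waters contribute more pairs).  Integrates to 1.
#'
#' @param traj a [trajectory()].
#' @param ion_species single ion label.
#' @param radii shell radii per ion species.
#' @param dr bin width in angstroms.
#' @param r_max histogram range; default half the minimum cell edge.
#' @return list with `r`, `p` (density per angstrom), `dr`, `n_pairs`,
#'   `ion_species`.
#' @export
fss_pair_distribution <- function(traj, ion_species, radii, dr = 0.02,
                                  r_max = NULL) {
  cell <- traj$frames[[1L]]$cell
  if (is.null(r_max)) r_max <- min(cell) / 2
  nbins <- as.integer(floor(r_max / dr + 0.5))
  counts <- numeric(nbins)
  for (fr in traj$frames) {
    asg <- assign_shells(fr, radii)
    sel <- which(asg$ions$species == ion_species)
    for (k in sel) {
      mem <- asg$members[[k]]
      if (length(mem) < 2L) next
      counts <- counts + cpp_pair_hist(fr$positions[mem, , drop = FALSE],
                                       fr$positions[mem, , drop = FALSE],
                                       fr$cell, r_max, dr, TRUE)
    }
  }
  total <- sum(counts)
  if (total == 0)
    stop("empty result: no FSS of '", ion_species,
         "' contains two or more waters")
  list(r = dr * seq_len(nbins), p = counts / (total * dr), dr = dr,
       n_pairs = total, ion_species = ion_species)
}

# Per-frame FSS / FW index lists from assignments.
fss_fw_index_lists <- function(assignments) {
  list(fss = lapply(assignments, `[[`, "fss"),
       fw = lapply(assignments, `[[`, "fw"))
}

# O-O RDF contribution of a class of pairs, normalised with the same global
# denominator as the full g_OO so contributions are literally additive.
subset_rdf_contribution <- function(traj, idx_a, idx_b, r_max, dr,
                                    within, subset_tag) {
  cell <- traj$frames[[1L]]$cell
  counts <- subset_pair_counts(traj, idx_a, idx_b, r_max, dr, within)
  n_o <- traj$composition[["O"]]
  rho <- (n_o - 1L) / prod(cell)
  r <- dr * seq_len(length(counts))
  g <- counts / length(traj$frames) / (n_o * 4 * pi * r^2 * dr * rho)
  new_rdf(c("O", "O"), r, g, dr, rho, length(traj$frames), subset_tag)
}

#' Contribution of solvation-shell pairs to the full g_OO
#'
#' The O-O RDF restricted to pairs whose members are both inside at least
#' one FSS, normalised with the same global denominator as the full g_OO(r)
#' so that FSS-pair, FW-pair and cross-pair contributions sum bin-exactly
#' to the full curve (see [rdf_partition()]).
#'
#' @param traj a [trajectory()].
#' @param radii shell radii per ion species.
#' @param dr bin width in angstroms.
#' @param r_max histogram range; default half the minimum cell edge.
#' @return An `rdf` with `subset_tag = "FSS"`.
#' @export
fss_rdf_contribution <- function(traj, radii, dr = 0.02, r_max = NULL) {
  rdf_partition(traj, radii, dr = dr, r_max = r_max)$fss
}

#' Partition of g_OO into FSS, FW and cross contributions
#'
#' Splits every O-O pair by shell membership of its two members: both in an
#' FSS, both free water, or one of each.  All three pieces share the global
#' g_OO denominator, so `fss$g + fw$g + cross$g` equals the full `g_OO`
#' bin-by-bin for every frame.
#'
#' @inheritParams fss_rdf_contribution
#' @return list of `rdf` objects `fss`, `fw`, `cross`, `full`.
#' @export
rdf_partition <- function(traj, radii, dr = 0.02, r_max = NULL) {
  cell <- traj$frames[[1L]]$cell
  if (is.null(r_max)) r_max <- min(cell) / 2
  assignments <- assign_shells_trajectory(traj, radii)
  idx <- fss_fw_index_lists(assignments)
  list(
    fss = subset_rdf_contribution(traj, idx$fss, NULL, r_max, dr, TRUE, "FSS"),
    fw = subset_rdf_contribution(traj, idx$fw, NULL, r_max, dr, TRUE, "FW-pairs"),
    cross = subset_rdf_contribution(traj, idx$fss, idx$fw, r_max, dr, FALSE,
                                    "FSS-FW-cross"),
    full = compute_rdf(traj, c("O", "O"), r_max = r_max, dr = dr))
}
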