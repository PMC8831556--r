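#' Subset-resolved "virtual diffraction" structure factor
#'
#' Computes the O-O structure factor restricted to a chosen population of
#' waters, the computational analogue of a diffraction experiment that
#' could see only part of the liquid.  For the non-trivial subsets the
#' pipeline is: shell radii from the first minima of the O-ion RDFs, shell
#' assignment, cavity construction over the excluded ions,
#' excluded-volume-corrected subset RDF, then Fourier transform to S(Q).
#'
#' Subsets: `"all"` (plain S_OO(Q)); `"FW"` (free waters only, all ionic
#' shells carved out); `"FW+FSS:<species>"` (free waters plus the shells of
#' one ion species, the other species' shells carved out).  On an ion-free
#' trajectory `"FW"` is identical to `"all"`.
#'
#' @param traj a [trajectory()].
#' @param subset one of `"all"`, `"FW"`, `"FW+FSS:<species>"`.
#' @param ion_species ion labels; defaults to every species other than O
#'   and H.
#' @param radii optional precomputed shell radii (named, angstroms); found
#'   with [determine_shell_radii()] when omitted.
#' @param Q momentum-transfer grid.
#' @param dr RDF bin width in angstroms.
#' @param r_max RDF range; default half the minimum cell edge.
#' @param window `"none"` or `"lorch"` for the Fourier transform.
#' @param n_samples Monte-Carlo points per frame for the excluded-volume
#'   normalisation.
#' @param seed integer RNG seed for the normalisation (optional).
#' @param retained_min minimum admissible retained volume fraction; below
#'   it the correction (and hence the subset S(Q)) is refused with a
#'   diagnostic naming the computed fraction.
#' @return A `structure_factor` with metadata fields `subset_tag`, `radii`,
#'   `retained_fraction` and the underlying `rdf`.
#' @export
virtual_sq <- function(traj, subset = "all", ion_species = NULL,
                       radii = NULL, Q = default_q_grid(), dr = 0.02,
                       r_max = NULL, window = "none", n_samples = 2e5,
                       seed = NULL, retained_min = 0.30) {
  if (is.null(ion_species))
    ion_species <- setdiff(names(traj$composition), c("O", "H"))
  cell <- traj$frames[[1L]]$cell
  vol <- prod(cell)
  n_o <- traj$composition[["O"]]

  plain <- function(tag) {
    rdf <- compute_rdf(traj, c("O", "O"), r_max = r_max, dr = dr)
    sq <- rdf_to_structure_factor(rdf, rho = n_o / vol, Q = Q,
                                  window = window)
    sq$subset_tag <- tag
    sq$rdf <- rdf
    sq$retained_fraction <- 1
    sq
  }
  if (subset == "all") return(plain("all"))
  if (!length(ion_species)) {
    if (subset == "FW") return(plain("FW"))
    stop("subset '", subset, "' needs ions, but the trajectory has none")
  }
  if (is.null(radii)) radii <- determine_shell_radii(traj, ion_species, dr = dr)
  keep_species <- character(0)
  if (grepl("^FW\\+FSS", subset)) {
    keep_species <- gsub("^FW\\+FSS[:(]([^)]*)\\)?$", "\\1", subset)
    if (!keep_species %in% ion_species)
      stop("unknown ion species in subset '", subset, "'")
  } else if (subset != "FW") {
    stop("unknown subset '", subset,
         "' (use 'all', 'FW' or 'FW+FSS:<species>')")
  }
  assignments <- assign_shells_trajectory(traj, radii)
  waters <- vector("list", length(assignments))
  cavities <- vector("list", length(assignments))
  for (k in seq_along(assignments)) {
    asg <- assignments[[k]]
    keep_ions <- asg$ions$species %in% keep_species
    w <- asg$fw
    if (any(keep_ions))
      w <- sort(unique(c(w, unlist(asg$members[keep_ions]))))
    waters[[k]] <- w
    excl <- which(!keep_ions)
    cavities[[k]] <- cavity_region(
      traj$frames[[k]]$positions[asg$ions$index[excl], , drop = FALSE],
      radii[asg$ions$species[excl]], cell)
  }
  crdf <- corrected_subset_rdf(traj, waters, cavities, dr = dr,
                               r_max = r_max, n_samples = n_samples,
                               seed = seed, retained_min = retained_min)
  rho_sub <- mean(vapply(waters, length, 0L)) /
    (vol * crdf$retained_fraction)
  sq <- rdf_to_structure_factor(crdf, rho = rho_sub, Q = Q, window = window)
  sq$subset_tag <- subset
  sq$radii <- radii
  sq$retained_fraction <- crdf$retained_fraction
  sq$rdf <- crdf
  sq
}
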