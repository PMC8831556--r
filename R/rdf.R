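#' Partial radial distribution function
#'
#' Frame-averaged histogram of minimum-image alpha-beta distances, each bin
#' divided by the ideal-gas expectation `n_alpha * 4 pi r^2 dr * rho_beta`.
#' For a like pair (alpha == beta) the self term is excluded and
#' `rho_beta = (N_beta - 1) / V`, so an ideal gas gives g = 1 without bias.
#' Bins are centred on multiples of `dr` (the first bin centre is `dr`), so a
#' distance that is an exact multiple of the resolution is reported at that
#' value.
#'
#' @param traj a [trajectory()].
#' @param pair character vector of two species labels, e.g. `c("O", "O")`.
#' @param r_max histogram range in angstroms; defaults to half the minimum
#'   cell edge (the largest range for which minimum-image distances sample
#'   full spherical shells).
#' @param dr bin width in angstroms.
#' @return An object of class `rdf` with fields `pair`, `r` (bin centres),
#'   `g`, `dr`, `rho` (normalising beta density), `n_frames`, `subset_tag`.
#' @export
compute_rdf <- function(traj, pair, r_max = NULL, dr = 0.02) {
  if (!inherits(traj, "trajectory")) stop("`traj` must be a trajectory")
  if (length(pair) != 2L) stop("`pair` must name two species")
  cell <- traj$frames[[1L]]$cell
  half <- min(cell) / 2
  if (is.null(r_max)) r_max <- half
  if (r_max > half + 1e-9)
    stop("validation error: r_max (", r_max,
         ") exceeds half the minimum cell edge (", half, ")")
  missing <- setdiff(unique(pair), names(traj$composition))
  if (length(missing))
    stop("validation error: species not present in trajectory: ",
         paste(missing, collapse = ", "))
  same <- pair[1L] == pair[2L]
  nbins <- as.integer(floor(r_max / dr + 0.5))
  counts <- numeric(nbins)
  for (fr in traj$frames) {
    ia <- species_indices(fr, pair[1L])
    ib <- species_indices(fr, pair[2L])
    h <- cpp_pair_hist(fr$positions[ia, , drop = FALSE],
                       fr$positions[ib, , drop = FALSE],
                       fr$cell, r_max, dr, same)
    counts <- counts + if (same) 2 * h else h   # ordered pairs
  }
  na <- traj$composition[[pair[1L]]]
  nb <- traj$composition[[pair[2L]]]
  vol <- prod(cell)
  rho_b <- (nb - as.integer(same)) / vol
  r <- dr * seq_len(nbins)
  g <- counts / length(traj$frames) / (na * 4 * pi * r^2 * dr * rho_b)
  new_rdf(pair, r, g, dr, rho_b, length(traj$frames), "all")
}

new_rdf <- function(pair, r, g, dr, rho, n_frames, subset_tag,
                    extra = list()) {
  structure(c(list(pair = pair, r = r, g = g, dr = dr, rho = rho,
                   n_frames = n_frames, subset_tag = subset_tag), extra),
            class = "rdf")
}

#' @export
print.rdf <- function(x, ...) {
  cat(sprintf("rdf %s-%s [%s]: %d bins, dr = %g A, r in [%g, %g] A\n",
              x$pair[1L], x$pair[2L], x$subset_tag, length(x$r), x$dr,
              x$r[1L], x$r[length(x$r)]))
  invisible(x)
}

#' @export
as.data.frame.rdf <- function(x, ...) data.frame(r = x$r, g = x$g)

# Ordered-pair distance histogram restricted to per-frame index subsets.
# idx_a / idx_b: lists (one per frame) of atom indices; when `within` is
# TRUE both lists are identical and unordered pairs are doubled, otherwise
# the subsets are assumed disjoint and each unordered cross pair counts
# twice as ordered.  Returns the summed ordered counts.
subset_pair_counts <- function(traj, idx_a, idx_b, r_max, dr,
                               within = TRUE) {
  nbins <- as.integer(floor(r_max / dr + 0.5))
  counts <- numeric(nbins)
  for (k in seq_along(traj$frames)) {
    fr <- traj$frames[[k]]
    a <- idx_a[[k]]
    b <- if (within) a else idx_b[[k]]
    if (length(a) < 1L || length(b) < 1L) next
    h <- cpp_pair_hist(fr$positions[a, , drop = FALSE],
                       fr$positions[b, , drop = FALSE],
                       fr$cell, r_max, dr, within)
    counts <- counts + 2 * h
  }
  counts
}
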