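#' O-O-O angular distribution function
#'
#' For every central O in the chosen subset, every unordered pair of its O
#' neighbours within `cutoff` contributes the angle it subtends at the
#' centre.  The histogram is normalised to unit integral over (0, 180]
#' degrees (plain angle bins, no sin-theta Jacobian; post-multiply if a
#' solid-angle density is wanted).  Bin centres sit on multiples of
#' `dtheta`.
#'
#' In a tetrahedral network the distribution peaks at
#' arccos(-1/3) = 109.47 degrees; perturbed solvation-shell environments
#' shift or split that feature.
#'
#' @param traj a [trajectory()].
#' @param cutoff neighbour cutoff in angstroms; conventionally the first
#'   minimum of the relevant g_OO(r).
#' @param subset `NULL` for all O atoms, or a list (one element per frame)
#'   of O atom indices defining the subset (e.g. free waters or the waters
#'   of an ion's solvation shells).
#' @param dtheta bin width in degrees.
#' @param neighbour_scope `"subset"` (default): the two neighbours must also
#'   belong to the subset; `"all"`: only the central atom is restricted.
#' @param subset_tag label stored with the result.
#' @return An object of class `adf` with fields `theta`, `p` (density per
#'   degree), `dtheta`, `cutoff`, `subset_tag`, `neighbour_scope`,
#'   `n_triplets`.
#' @export
compute_adf <- function(traj, cutoff, subset = NULL, dtheta = 0.5,
                        neighbour_scope = c("subset", "all"),
                        subset_tag = if (is.null(subset)) "all" else "subset") {
  neighbour_scope <- match.arg(neighbour_scope)
  if (!inherits(traj, "trajectory")) stop("`traj` must be a trajectory")
  if (cutoff <= 0) stop("`cutoff` must be positive")
  nbins <- as.integer(floor(180 / dtheta + 0.5))
  counts <- numeric(nbins)
  for (k in seq_along(traj$frames)) {
    fr <- traj$frames[[k]]
    o_all <- species_indices(fr, "O")
    sel <- if (is.null(subset)) o_all else subset[[k]]
    if (!length(sel)) next
    if (neighbour_scope == "subset" || is.null(subset)) {
      pool <- fr$positions[sel, , drop = FALSE]
      centres <- seq_along(sel)
    } else {
      pool <- fr$positions[o_all, , drop = FALSE]
      centres <- match(sel, o_all)
    }
    counts <- counts + cpp_angle_hist(pool, fr$cell, as.integer(centres),
                                      cutoff, dtheta, nbins)
  }
  total <- sum(counts)
  if (total == 0)
    stop("empty result: no O-O-O triplets found for subset '", subset_tag,
         "' at cutoff ", cutoff, " A")
  structure(list(theta = dtheta * seq_len(nbins), p = counts / (total * dtheta),
                 dtheta = dtheta, cutoff = cutoff, subset_tag = subset_tag,
                 neighbour_scope = neighbour_scope, n_triplets = total),
            class = "adf")
}

#' @export
print.adf <- function(x, ...) {
  cat(sprintf("adf [%s]: %d triplets, cutoff %g A, dtheta %g deg (neighbours: %s)\n",
              x$subset_tag, x$n_triplets, x$cutoff, x$dtheta,
              x$neighbour_scope))
  invisible(x)
}

#' @export
as.data.frame.adf <- function(x, ...) data.frame(theta = x$theta, p = x$p)
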