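#' Geometric hydrogen-bond criteria
#'
#' The field-standard donor-acceptor geometry: a water-water bond requires
#' donor-acceptor oxygen separation at most `r_oo` and an
#' H-O(donor)...O(acceptor) angle at most `theta_max`; a water-anion bond
#' requires the proton within `r_hx` of the anion under the same angular
#' condition.  Every reported statistic echoes the criteria it was computed
#' with.
#'
#' @param r_oo maximum donor-acceptor O-O distance, angstroms.
#' @param theta_max maximum H-O(donor)...acceptor angle, degrees.
#' @param r_hx maximum H...anion distance, angstroms; conventionally the
#'   first minimum of the H-anion RDF of the system under study.
#' @param covalent_cutoff radius for assigning each H to its nearest O,
#'   angstroms.
#' @return list of class `hbond_criteria`.
#' @export
hbond_criteria <- function(r_oo = 3.5, theta_max = 30, r_hx = 3.0,
                           covalent_cutoff = 1.2) {
  stopifnot(r_oo > 0, theta_max > 0, r_hx > 0, covalent_cutoff > 0)
  structure(list(r_oo = r_oo, theta_max = theta_max, r_hx = r_hx,
                 covalent_cutoff = covalent_cutoff),
            class = "hbond_criteria")
}

#' Detect hydrogen bonds in one frame
#'
#' Each H is first assigned to its nearest O within the covalent cutoff
#' (an H with no such O is an error).  Each H then donates at most one
#' bond: among all acceptor candidates (other waters' O, and anion atoms)
#' satisfying the geometric criteria, the one with the smallest
#' H-O(donor)...acceptor angle is kept, so a donor O contributes at most
#' two donated bonds (one per proton).
#'
#' @param frame a [simulation_frame()] containing O and H (and optionally
#'   ions).
#' @param criteria an [hbond_criteria()] object.
#' @param anions character vector of anion species labels to consider as
#'   acceptors.
#' @return An object of class `hbond_network`: a data.frame `edges` with
#'   columns `donor` (O index), `h` (H index), `acceptor` (O or anion
#'   index), `type` (`"OO"` or `"OX"`), plus the `criteria` used.
#' @export
detect_hbonds <- function(frame, criteria = hbond_criteria(),
                          anions = character(0)) {
  o_idx <- species_indices(frame, "O")
  h_idx <- species_indices(frame, "H")
  x_idx <- which(frame$species %in% anions)
  pos <- frame$positions
  cell <- frame$cell

  # H -> parent O ownership
  parent <- integer(length(h_idx))
  for (k in seq_along(h_idx)) {
    d <- sqrt(rowSums(min_image_disp(pos[h_idx[k], ],
                                     pos[o_idx, , drop = FALSE], cell)^2))
    j <- which.min(d)
    if (d[j] > criteria$covalent_cutoff)
      stop("validation error: H atom ", h_idx[k], " has no O within the ",
           criteria$covalent_cutoff, " A covalent cutoff")
    parent[k] <- o_idx[j]
  }

  edges <- list()
  for (k in seq_along(h_idx)) {
    h <- h_idx[k]
    don <- parent[k]
    oh <- min_image_disp(pos[don, ], pos[h, , drop = FALSE], cell)[1L, ]
    best <- NULL
    consider <- function(acc, type, dist_ok) {
      da <- min_image_disp(pos[don, ], pos[acc, , drop = FALSE], cell)[1L, ]
      ra <- sqrt(sum(da^2))
      if (!dist_ok(ra, acc)) return(NULL)
      cosang <- sum(oh * da) / (sqrt(sum(oh^2)) * ra)
      ang <- acos(pmin(1, pmax(-1, cosang))) * 180 / pi
      if (ang > criteria$theta_max) return(NULL)
      list(acceptor = acc, type = type, angle = ang)
    }
    for (acc in setdiff(o_idx, don)) {
      cand <- consider(acc, "OO",
                       function(ra, acc) ra <= criteria$r_oo)
      if (!is.null(cand) && (is.null(best) || cand$angle < best$angle))
        best <- cand
    }
    for (acc in x_idx) {
      hx <- sqrt(sum(min_image_disp(pos[h, ],
                                    pos[acc, , drop = FALSE], cell)^2))
      if (hx > criteria$r_hx) next
      cand <- consider(acc, "OX", function(ra, acc) TRUE)
      if (!is.null(cand) && (is.null(best) || cand$angle < best$angle))
        best <- cand
    }
    if (!is.null(best))
      edges[[length(edges) + 1L]] <-
        data.frame(donor = don, h = h, acceptor = best$acceptor,
                   type = best$type, angle = best$angle)
  }
  edges <- if (length(edges)) do.call(rbind, edges) else
    data.frame(donor = integer(0), h = integer(0), acceptor = integer(0),
               type = character(0), angle = numeric(0))
  structure(list(edges = edges, criteria = criteria, anions = anions),
            class = "hbond_network")
}

#' @export
print.hbond_network <- function(x, ...) {
  cat("hbond_network:", nrow(x$edges), "edges (",
      sum(x$edges$type == "OO"), "water-water,",
      sum(x$edges$type == "OX"), "water-anion )\n")
  invisible(x)
}

# Undirected water-water adjacency (list of bonded O index pairs) from a
# network.
ww_bond_pairs <- function(net) {
  e <- net$edges[net$edges$type == "OO", , drop = FALSE]
  if (!nrow(e)) return(matrix(integer(0), 0L, 2L))
  unique(cbind(pmin(e$donor, e$acceptor), pmax(e$donor, e$acceptor)))
}

#' Fraction of shell waters not hydrogen-bonded to their anion
#'
#' Time-averaged fraction of waters in the anion's first solvation shell
#' that donate no hydrogen bond to the ion whose shell they occupy.  Waters
#' are pooled over ions and frames.
#'
#' @param traj a [trajectory()] with decorated waters (H present).
#' @param anion anion species label.
#' @param radii shell radii per ion species (must include `anion`).
#' @param criteria an [hbond_criteria()].
#' @return fraction in `[0, 1]`.
#' @export
fss_anion_nonbonded_fraction <- function(traj, anion, radii,
                                         criteria = hbond_criteria()) {
  if (is.na(radii[anion])) stop("`radii` must include the anion species")
  n_fss <- 0L
  n_nonbonded <- 0L
  for (fr in traj$frames) {
    asg <- assign_shells(fr, radii)
    net <- detect_hbonds(fr, criteria, anions = anion)
    ox <- net$edges[net$edges$type == "OX", , drop = FALSE]
    sel <- which(asg$ions$species == anion)
    for (k in sel) {
      ion <- asg$ions$index[k]
      mem <- asg$members[[k]]
      if (!length(mem)) next
      bonded <- unique(ox$donor[ox$acceptor == ion])
      n_fss <- n_fss + length(mem)
      n_nonbonded <- n_nonbonded + sum(!(mem %in% bonded))
    }
  }
  if (n_fss == 0L)
    stop("empty result: no waters found in the FSS of '", anion, "'")
  n_nonbonded / n_fss
}

#' Fraction of shell waters in hydrogen-bond chains
#'
#' A shell water is "in a chain" when it is hydrogen-bonded (either
#' direction) to another water of the same ion's shell and at least one
#' member of that bonded pair is additionally bonded to a third, distinct
#' water molecule.  Chains signal partial recovery of the water network
#' inside a solvation shell; flexible anion shells show them, rigid cation
#' shells barely do.
#'
#' @inheritParams fss_anion_nonbonded_fraction
#' @param ion ion species label whose shells are examined.
#' @param third_water_scope `"any"` (default): the third water may sit in
#'   any shell or in the free water; `"fss"`: it must belong to the same
#'   ion's shell.
#' @return time-averaged fraction of the ion's shell waters in chains.
#' @export
fss_chain_fraction <- function(traj, ion, radii,
                               criteria = hbond_criteria(),
                               third_water_scope = c("any", "fss")) {
  third_water_scope <- match.arg(third_water_scope)
  if (is.na(radii[ion])) stop("`radii` must include the ion species")
  n_fss <- 0L
  n_chain <- 0L
  for (fr in traj$frames) {
    asg <- assign_shells(fr, radii)
    net <- detect_hbonds(fr, criteria,
                         anions = setdiff(names(radii), c("O", "H")))
    bp <- ww_bond_pairs(net)
    nbrs <- function(o) unique(c(bp[bp[, 1L] == o, 2L], bp[bp[, 2L] == o, 1L]))
    sel <- which(asg$ions$species == ion)
    for (k in sel) {
      mem <- asg$members[[k]]
      if (!length(mem)) next
      n_fss <- n_fss + length(mem)
      for (o in mem) {
        partners <- intersect(nbrs(o), setdiff(mem, o))
        in_chain <- FALSE
        for (p in partners) {
          third <- setdiff(unique(c(nbrs(o), nbrs(p))), c(o, p))
          if (third_water_scope == "fss") third <- intersect(third, mem)
          if (length(third)) { in_chain <- TRUE; break }
        }
        if (in_chain) n_chain <- n_chain + 1L
      }
    }
  }
  if (n_fss == 0L)
    stop("empty result: no waters found in the FSS of '", ion, "'")
  n_chain / n_fss
}
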