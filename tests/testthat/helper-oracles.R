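# Independent brute-force oracles and hand-built fixtures.  Everything here
# is deliberately naive (image enumeration, triple loops) so it can vouch
# for the optimised implementations.

# Minimum-image distance by explicit enumeration of all 27 periodic images
# (after wrapping both atoms into the primary cell, so arbitrary unwrapped
# coordinates are handled).
brute_min_image <- function(frame, i, j) {
  wrap <- function(p) p - frame$cell * floor(p / frame$cell)
  shifts <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  d <- sweep(shifts, 2L, frame$cell, "*")
  img <- sweep(d, 2L, wrap(frame$positions[j, ]), "+")
  min(sqrt(rowSums(sweep(img, 2L, wrap(frame$positions[i, ]))^2)))
}

# All-pairs minimum-image distances of one frame (rows i < j).
brute_pair_distances <- function(frame, idx = seq_along(frame$species)) {
  n <- length(idx)
  out <- numeric(0)
  for (a in seq_len(n - 1L))
    for (b in (a + 1L):n)
      out <- c(out, brute_min_image(frame, idx[a], idx[b]))
  out
}

# Naive RDF: histogram brute-force distances with centre-aligned bins and
# the same ordered-pair normalisation as compute_rdf.
naive_rdf_counts <- function(traj, r_max, dr) {
  nbins <- as.integer(floor(r_max / dr + 0.5))
  counts <- numeric(nbins)
  for (fr in traj$frames) {
    for (d in brute_pair_distances(fr)) {
      k <- as.integer(floor(d / dr + 0.5))
      if (k >= 1L && k <= nbins) counts[k] <- counts[k] + 2
    }
  }
  counts
}

# All triplet angles (degrees) at every centre within cutoff, by triple loop.
brute_triplet_angles <- function(frame, cutoff, centres = NULL) {
  o <- which(frame$species == "O")
  if (is.null(centres)) centres <- o
  angles <- numeric(0)
  for (c0 in centres) {
    nb <- list()
    for (j in o) {
      if (j == c0) next
      d <- frame$positions[j, ] - frame$positions[c0, ]
      d <- d - frame$cell * round(d / frame$cell)
      if (sqrt(sum(d^2)) <= cutoff) nb[[length(nb) + 1L]] <- d
    }
    if (length(nb) < 2L) next
    for (u in seq_len(length(nb) - 1L))
      for (v in (u + 1L):length(nb)) {
        cosang <- sum(nb[[u]] * nb[[v]]) /
          sqrt(sum(nb[[u]]^2) * sum(nb[[v]]^2))
        angles <- c(angles, acos(max(-1, min(1, cosang))) * 180 / pi)
      }
  }
  angles
}

# A water molecule: O at `o`, first H at unit direction u1, second in the
# (u1, u2) plane at `angle` degrees from u1.
place_water <- function(o, u1, u2, oh = 1.0, angle = 104.5) {
  u1 <- u1 / sqrt(sum(u1^2))
  w <- u2 - sum(u2 * u1) * u1
  w <- w / sqrt(sum(w^2))
  a <- angle * pi / 180
  rbind(o, o + oh * u1, o + oh * (cos(a) * u1 + sin(a) * w))
}

# Frame with waters (each a 3-row block O,H,H) plus optional extra ions.
waters_frame <- function(blocks, cell = 50, ions = NULL) {
  pos <- do.call(rbind, blocks)
  species <- rep(c("O", "H", "H"), length(blocks))
  if (!is.null(ions)) {
    pos <- rbind(pos, do.call(rbind, lapply(ions, `[[`, "pos")))
    species <- c(species, vapply(ions, `[[`, "", "species"))
  }
  simulation_frame(species, pos, cell)
}

# Independent chain detector: triple loop over FSS waters of one ion.
brute_chain_fraction <- function(frame, ion_label, radii, criteria,
                                 scope = "any") {
  asg <- assign_shells(frame, radii)
  net <- detect_hbonds(frame, criteria,
                       anions = setdiff(names(radii), c("O", "H")))
  e <- net$edges[net$edges$type == "OO", , drop = FALSE]
  bonded <- function(a, b)
    any((e$donor == a & e$acceptor == b) | (e$donor == b & e$acceptor == a))
  n_fss <- 0L
  n_chain <- 0L
  for (k in which(asg$ions$species == ion_label)) {
    mem <- asg$members[[k]]
    n_fss <- n_fss + length(mem)
    all_o <- which(frame$species == "O")
    for (o in mem) {
      hit <- FALSE
      for (p in setdiff(mem, o)) {
        if (!bonded(o, p)) next
        pool <- setdiff(all_o, c(o, p))
        if (scope == "fss") pool <- intersect(pool, mem)
        for (w3 in pool)
          if (bonded(o, w3) || bonded(p, w3)) { hit <- TRUE; break }
        if (hit) break
      }
      if (hit) n_chain <- n_chain + 1L
    }
  }
  if (n_fss == 0L) stop("no FSS waters")
  n_chain / n_fss
}

# Curve object accepted by the peak finders.
curve <- function(x, y) list(x = x, y = y)
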