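#' Default momentum-transfer grid
#'
#' 0.3 to 15 inverse angstroms in steps of 0.05, the span over which liquid
#' structure factors are usually compared with neutron data.
#' @return numeric vector of Q values.
#' @export
default_q_grid <- function() seq(0.3, 15, by = 0.05)

new_structure_factor <- function(label, Q, S, method, extra = list()) {
  structure(c(list(label = label, Q = Q, S = S, method = method), extra),
            class = "structure_factor")
}

#' @export
print.structure_factor <- function(x, ...) {
  cat(sprintf("structure_factor %s (%s): %d Q points in [%g, %g] 1/A\n",
              x$label, x$method, length(x$Q), min(x$Q), max(x$Q)))
  invisible(x)
}

#' @export
as.data.frame.structure_factor <- function(x, ...) data.frame(Q = x$Q, S = x$S)

#' Fourier transform a g(r) into a structure factor
#'
#' Evaluates, by midpoint quadrature on the RDF bins,
#' `S(Q) = 1 + 4 pi rho Int r^2 (g(r) - 1) sin(Qr)/(Qr) W(r) dr`
#' with `W` either unity or the Lorch window
#' `sin(pi r / r_max) / (pi r / r_max)`, which damps truncation ripple at
#' the cost of slight peak broadening.  With the Faber-Ziman convention used
#' throughout, S tends to 1 at large Q.
#'
#' @param rdf an `rdf` object from [compute_rdf()] (or a corrected subset
#'   variant) whose g has decayed to ~1 by `r_max`.
#' @param rho number density used in the transform, in atoms per cubic
#'   angstrom.  The conventional choice here is the total number density of
#'   the scattering species set; pass a per-pair density to switch
#'   normalisation.
#' @param Q momentum-transfer grid in inverse angstroms, strictly positive.
#' @param window `"none"` or `"lorch"`.
#' @return A `structure_factor` (method `"FT-of-g"`).
#' @export
rdf_to_structure_factor <- function(rdf, rho, Q = default_q_grid(),
                                    window = c("none", "lorch")) {
  window <- match.arg(window)
  if (!inherits(rdf, "rdf")) stop("`rdf` must be an rdf object")
  if (!is.numeric(rho) || rho <= 0)
    stop("validation error: `rho` must be positive")
  if (any(Q <= 0) || is.unsorted(Q, strictly = TRUE))
    stop("`Q` must be strictly increasing and positive")
  r <- rdf$r
  r_max <- r[length(r)] + rdf$dr / 2
  W <- if (window == "lorch") {
    x <- pi * r / r_max
    sin(x) / x
  } else rep(1, length(r))
  integrand <- r^2 * (rdf$g - 1) * W * rdf$dr
  S <- vapply(Q, function(q)
    1 + 4 * pi * rho * sum(integrand * sin(q * r) / (q * r)), 0)
  lbl <- paste0(rdf$pair[1L], "-", rdf$pair[2L],
                if (rdf$subset_tag != "all") paste0("-", rdf$subset_tag) else "")
  new_structure_factor(lbl, Q, S, "FT-of-g",
                       list(convention = "Faber-Ziman", rho = rho,
                            window = window, subset_tag = rdf$subset_tag))
}

#' Direct (Debye) partial structure factor
#'
#' Independent reciprocal-space route, used as an oracle for the
#' Fourier-transform path: the frame-averaged double sum
#' `S(Q) = delta_ab + (1/sqrt(Na Nb)) sum_{i,j} sin(Q r_ij)/(Q r_ij)`
#' over minimum-image pairs with `r_ij <= r_cut`, minus the analytic
#' uniform-background term of the spherical cutoff,
#' `4 pi rho_ab (sin(Q r_cut) - Q r_cut cos(Q r_cut)) / Q^3`.  Without that
#' subtraction the sharp sampling-volume boundary of a periodic box
#' contaminates S at small and moderate Q; with it, the estimator is exact
#' for an ideal gas at every Q.  Cost is O(N^2) per frame, so this is meant
#' for small systems (<= ~2000 atoms).
#'
#' @param traj a [trajectory()].
#' @param pair two species labels.
#' @param Q momentum-transfer grid in inverse angstroms.
#' @param r_cut pair-distance cutoff; defaults to half the minimum cell edge.
#' @return A `structure_factor` (method `"Debye"`).
#' @export
debye_structure_factor <- function(traj, pair, Q = default_q_grid(),
                                   r_cut = NULL) {
  if (!inherits(traj, "trajectory")) stop("`traj` must be a trajectory")
  if (length(pair) != 2L) stop("`pair` must name two species")
  cell <- traj$frames[[1L]]$cell
  if (is.null(r_cut)) r_cut <- min(cell) / 2
  same <- pair[1L] == pair[2L]
  na <- traj$composition[[pair[1L]]]
  nb <- traj$composition[[pair[2L]]]
  if (is.null(na) || is.null(nb))
    stop("validation error: species not present in trajectory")
  acc <- numeric(length(Q))
  for (fr in traj$frames) {
    ia <- species_indices(fr, pair[1L])
    ib <- species_indices(fr, pair[2L])
    s <- cpp_debye_sum(fr$positions[ia, , drop = FALSE],
                       fr$positions[ib, , drop = FALSE],
                       fr$cell, Q, r_cut, same)
    acc <- acc + if (same) 2 * s else s
  }
  acc <- acc / length(traj$frames) / sqrt(na * nb)
  vol <- prod(cell)
  rho_ab <- if (same) (na - 1) / vol else sqrt(na * nb) / vol
  bg <- 4 * pi * rho_ab * (sin(Q * r_cut) - Q * r_cut * cos(Q * r_cut)) / Q^3
  S <- as.numeric(same) + acc - bg
  new_structure_factor(paste0(pair[1L], "-", pair[2L]), Q, S, "Debye",
                       list(convention = "Faber-Ziman", r_cut = r_cut))
}

#' Neutron-weighting coefficients for a composite structure factor
#'
#' Faber-Ziman weights
#' `w_ab = (2 - delta_ab) c_a c_b b_a b_b / (sum_g c_g b_g)^2`
#' from mole fractions and coherent scattering lengths; the weights of all
#' unordered pairs sum to 1.  Scattering lengths are user-supplied (they
#' depend on isotopic composition), not hard-coded.
#'
#' @param concentration named numeric vector of mole fractions (must sum
#'   to 1).
#' @param b named numeric vector of coherent scattering lengths (fm), same
#'   names.
#' @return An object of class `composite_weights` with a `weights`
#'   data.frame (`alpha`, `beta`, `w`) over unordered pairs.
#' @export
composite_weights <- function(concentration, b) {
  sp <- names(concentration)
  if (is.null(sp) || !setequal(sp, names(b)))
    stop("`concentration` and `b` must be named over the same species")
  if (abs(sum(concentration) - 1) > 1e-8)
    stop("validation error: concentrations must sum to 1")
  b <- b[sp]
  denom <- sum(concentration * b)^2
  pairs <- which(upper.tri(diag(length(sp)), diag = TRUE), arr.ind = TRUE)
  w <- vapply(seq_len(nrow(pairs)), function(k) {
    a <- pairs[k, 1L]; bb <- pairs[k, 2L]
    (2 - as.numeric(a == bb)) * concentration[a] * concentration[bb] *
      b[a] * b[bb] / denom
  }, 0)
  out <- data.frame(alpha = sp[pairs[, 1L]], beta = sp[pairs[, 2L]], w = w,
                    stringsAsFactors = FALSE)
  stopifnot(abs(sum(out$w) - 1) < 1e-9)
  structure(list(species = sp, concentration = concentration, b = b,
                 weights = out),
            class = "composite_weights")
}

#' Neutron-weighted composite structure factor
#'
#' The weighted sum `S_XX(Q) = sum_ab w_ab S_ab(Q)` over partials, the
#' quantity a neutron diffraction experiment measures for a multi-component
#' liquid.
#'
#' @param partials named list of `structure_factor` objects on a common Q
#'   grid; names are `"alpha-beta"` pair labels (order-insensitive).
#' @param weights a [composite_weights()] object covering every pair.
#' @return A `structure_factor` labelled `"XX-composite"`.
#' @export
composite_structure_factor <- function(partials, weights) {
  if (!inherits(weights, "composite_weights"))
    stop("`weights` must come from composite_weights()")
  if (!length(partials)) stop("no partials supplied")
  Q <- partials[[1L]]$Q
  for (p in partials)
    if (!isTRUE(all.equal(p$Q, Q)))
      stop("validation error: partials are not on a common Q grid")
  lookup <- function(a, b) {
    key1 <- paste0(a, "-", b); key2 <- paste0(b, "-", a)
    p <- partials[[key1]]
    if (is.null(p)) p <- partials[[key2]]
    if (is.null(p))
      stop("validation error: missing partial for pair ", key1)
    p
  }
  S <- numeric(length(Q))
  wtab <- weights$weights
  for (k in seq_len(nrow(wtab)))
    S <- S + wtab$w[k] * lookup(wtab$alpha[k], wtab$beta[k])$S
  new_structure_factor("XX-composite", Q, S, partials[[1L]]$method,
                       list(convention = "Faber-Ziman",
                            weights = wtab))
}
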