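# Peak and minimum location on binned curves.
#
# All finders smooth with a centred 3-bin moving average first and require a
# minimum prominence, so that shell radii derived from first minima are
# stable run-to-run against histogram noise.  A flat-topped (plateau) local
# maximum is reported at its midpoint.

smooth3 <- function(y) {
  n <- length(y)
  if (n < 3L) return(y)
  s <- as.numeric(stats::filter(y, rep(1 / 3, 3L), sides = 2L))
  s[1L] <- mean(y[1:2])
  s[n] <- mean(y[(n - 1L):n])
  s
}

# Local maxima (plateau-aware) with prominences.  Returns a data.frame with
# columns idx (plateau midpoint), height, prominence.
local_maxima <- function(y) {
  n <- length(y)
  out <- data.frame(idx = integer(0), height = numeric(0),
                    prominence = numeric(0))
  if (n < 3L) return(out)
  # collapse runs of equal values
  run_end <- c(which(diff(y) != 0), n)
  run_start <- c(1L, head(run_end, -1L) + 1L)
  for (k in seq_along(run_start)) {
    s <- run_start[k]; e <- run_end[k]
    if (s == 1L || e == n) next                       # boundary plateau
    if (y[s - 1L] < y[s] && y[e + 1L] < y[e]) {
      mid <- s + (e - s) %/% 2L
      # prominence: lowest point between the peak and the nearest higher
      # point (or the boundary) on each side; prominence = height - the
      # higher of the two side minima.
      left_min <- y[s]
      i <- s - 1L
      while (i >= 1L && y[i] <= y[s]) { left_min <- min(left_min, y[i]); i <- i - 1L }
      if (i < 1L) left_min <- min(y[1:s])
      right_min <- y[e]
      i <- e + 1L
      while (i <= n && y[i] <= y[e]) { right_min <- min(right_min, y[i]); i <- i + 1L }
      if (i > n) right_min <- min(y[e:n])
      out <- rbind(out, data.frame(idx = mid, height = y[mid],
                                   prominence = y[mid] - max(left_min, right_min)))
    }
  }
  out
}

curve_xy <- function(obj) {
  if (inherits(obj, "rdf")) list(x = obj$r, y = obj$g)
  else if (inherits(obj, "adf")) list(x = obj$theta, y = obj$p)
  else if (is.list(obj) && !is.null(obj$x) && !is.null(obj$y)) obj
  else stop("expected an rdf, adf, or list(x, y)")
}

#' Locate the first minimum of a g(r)
#'
#' The position of the lowest bin between the first and the second local
#' maximum of the 3-bin-smoothed curve (ties broken toward smaller r).  When
#' only one maximum clears the prominence threshold, the deepest bin after it
#' that is followed by a rise of at least the threshold is used.  This is the
#' convention that defines ionic first-solvation-shell radii (the first
#' minimum of the O-ion RDF).
#'
#' @param rdf an `rdf` object (or any `list(x, y)` curve).
#' @param min_prominence minimum peak prominence, in g units, for a local
#'   maximum to count as structure.
#' @return the position of the minimum, in the x units of the curve.
#' @export
find_first_minimum <- function(rdf, min_prominence = 0.02) {
  cv <- curve_xy(rdf)
  ys <- smooth3(cv$y)
  pk <- local_maxima(ys)
  pk <- pk[pk$prominence >= min_prominence, , drop = FALSE]
  if (!nrow(pk))
    stop("not found: no interior maximum with prominence >= ",
         min_prominence, " (monotone or structureless curve)")
  pk <- pk[order(pk$idx), , drop = FALSE]
  if (nrow(pk) >= 2L) {
    lo <- pk$idx[1L]; hi <- pk$idx[2L]
    seg <- ys[lo:hi]
    return(cv$x[lo + which.min(seg) - 1L])
  }
  # single peak: deepest bin after it that is followed by a rise
  lo <- pk$idx[1L]
  seg <- ys[lo:length(ys)]
  m <- lo + which.min(seg) - 1L
  if (m < length(ys) && max(ys[m:length(ys)]) >= ys[m] + min_prominence)
    return(cv$x[m])
  stop("not found: no minimum followed by a rise after the first peak")
}

#' Locate the k most prominent peaks of a g(r)
#'
#' Positions of the k highest local maxima of the 3-bin-smoothed curve that
#' clear the prominence threshold, sorted by position.
#'
#' @inheritParams find_first_minimum
#' @param k number of peaks requested.
#' @return numeric vector of k positions (ascending), with attributes
#'   `height` and `prominence`.
#' @export
find_peaks <- function(rdf, k = 1L, min_prominence = 0.02) {
  if (k < 1L) stop("`k` must be at least 1")
  cv <- curve_xy(rdf)
  ys <- smooth3(cv$y)
  pk <- local_maxima(ys)
  pk <- pk[pk$prominence >= min_prominence, , drop = FALSE]
  if (nrow(pk) < k)
    stop("not found: requested ", k, " peak(s) but only ", nrow(pk),
         " local maxima clear prominence ", min_prominence)
  pk <- pk[order(-pk$height, pk$idx), , drop = FALSE][seq_len(k), , drop = FALSE]
  pk <- pk[order(pk$idx), , drop = FALSE]
  structure(cv$x[pk$idx], height = pk$height, prominence = pk$prominence)
}

#' Locate peaks of an angular distribution
#'
#' As [find_peaks()] on the (theta, p) grid.  The default prominence
#' threshold is relative (2% of the maximum density) because ADF densities
#' integrate to 1 and their absolute scale varies with width.
#'
#' @param adf an `adf` object from [compute_adf()].
#' @param k number of peaks requested.
#' @param min_prominence minimum prominence in density-per-degree units;
#'   default `0.02 * max(p)`.
#' @return numeric vector of k angles in degrees (ascending).
#' @export
find_adf_peaks <- function(adf, k = 1L, min_prominence = NULL) {
  cv <- curve_xy(adf)
  if (is.null(min_prominence)) min_prominence <- 0.02 * max(cv$y)
  find_peaks(cv, k = k, min_prominence = min_prominence)
}
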