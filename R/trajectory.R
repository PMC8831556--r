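#' Construct a single periodic configuration
#'
#' A `simulation_frame` holds one species-labelled periodic configuration:
#' atom labels, Cartesian coordinates in angstroms and the three edge lengths
#' of an orthorhombic cell.  Coordinates are stored as given (unwrapped);
#' periodic wrapping is applied on demand inside distance computations.
#'
#' @param species character vector of atom labels (e.g. `"O"`, `"H"`, `"Na"`).
#' @param positions numeric matrix with one row per atom and columns x, y, z
#'   (angstroms).
#' @param cell numeric vector of three strictly positive orthorhombic edge
#'   lengths (angstroms); a single number is recycled to a cubic cell.
#' @param frame_index ordinal position of the frame in its trajectory.
#' @return An object of class `simulation_frame`.
#' @export
simulation_frame <- function(species, positions, cell, frame_index = 1L) {
  positions <- as.matrix(positions)
  if (length(cell) == 1L) cell <- rep(cell, 3L)
  cell <- as.numeric(cell)
  if (ncol(positions) != 3L)
    stop("`positions` must have three columns (x, y, z)")
  if (length(species) != nrow(positions))
    stop("`species` length (", length(species), ") does not match the number of atoms (",
         nrow(positions), ")")
  if (!all(is.finite(positions)))
    stop("all coordinates must be finite")
  if (length(cell) != 3L || !all(is.finite(cell)) || any(cell <= 0))
    stop("`cell` must be three strictly positive edge lengths")
  structure(
    list(species = as.character(species), positions = unname(positions),
         cell = cell, frame_index = as.integer(frame_index)),
    class = "simulation_frame")
}

#' Construct a trajectory from a list of frames
#'
#' @param frames list of [simulation_frame()] objects with identical
#'   composition (same species counts in every frame).
#' @param metadata optional named list recording provenance (generator,
#'   seed, model parameters).
#' @return An object of class `trajectory`: the frames plus a composition
#'   summary (atom count per species).
#' @export
trajectory <- function(frames, metadata = list()) {
  if (length(frames) == 0L)
    stop("a trajectory must contain at least one frame")
  comp0 <- species_counts(frames[[1L]]$species)
  for (k in seq_along(frames)) {
    fr <- frames[[k]]
    if (!inherits(fr, "simulation_frame"))
      stop("frame ", k, " is not a simulation_frame")
    if (!identical(species_counts(fr$species), comp0))
      stop("inconsistent composition: frame ", k,
           " differs from frame 1")
    frames[[k]]$frame_index <- k
  }
  structure(list(frames = frames, composition = comp0, metadata = metadata),
            class = "trajectory")
}

species_counts <- function(species) {
  tab <- table(species)
  out <- as.integer(tab)
  names(out) <- names(tab)
  out[order(names(out))]
}

#' @export
length.trajectory <- function(x) length(x$frames)

#' @export
print.trajectory <- function(x, ...) {
  comp <- paste(sprintf("%s:%d", names(x$composition), x$composition),
                collapse = ", ")
  cat("trajectory:", length(x$frames), "frame(s), composition {", comp, "}\n")
  cat("cell:", paste(format(x$frames[[1L]]$cell), collapse = " x "), "A\n")
  invisible(x)
}

#' @export
print.simulation_frame <- function(x, ...) {
  cat("simulation_frame:", length(x$species), "atoms, cell",
      paste(format(x$cell), collapse = " x "), "A\n")
  invisible(x)
}

#' Indices of atoms of given species in a frame
#' @param frame a [simulation_frame()].
#' @param species character vector of labels to select.
#' @return integer vector of atom indices.
#' @export
species_indices <- function(frame, species) {
  which(frame$species %in% species)
}

#' Minimum-image distance between two atoms
#'
#' Euclidean distance between atoms `i` and `j` measured to the nearest
#' periodic image under the orthorhombic cell of the frame.
#'
#' @param frame a [simulation_frame()].
#' @param i,j distinct 1-based atom indices.
#' @return distance in angstroms.
#' @export
minimum_image_distance <- function(frame, i, j) {
  n <- nrow(frame$positions)
  if (i < 1L || i > n || j < 1L || j > n)
    stop("atom index out of range")
  if (i == j)
    stop("`i` and `j` must be distinct atoms")
  d <- frame$positions[i, ] - frame$positions[j, ]
  d <- d - frame$cell * round(d / frame$cell)
  sqrt(sum(d * d))
}

# Minimum-image displacement vectors from one reference row to many rows.
min_image_disp <- function(from, to, cell) {
  d <- sweep(to, 2L, from, "-")
  d - sweep(round(sweep(d, 2L, cell, "/")), 2L, cell, "*")
}
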