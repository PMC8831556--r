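#' Read an extended-XYZ trajectory
#'
#' Parses the single dialect this package writes: per frame an atom-count
#' line, a comment line carrying `Lattice="ax 0 0 0 by 0 0 0 cz"` and
#' `Properties=species:S:1:pos:R:3`, then one `species x y z` record per
#' atom.  Only orthorhombic lattices (zero off-diagonal components) are
#' supported; all lengths are angstroms.
#'
#' @param path path to an extended-XYZ file.
#' @return A [trajectory()].
#' @export
read_extxyz <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  frames <- list()
  ln <- 1L
  while (ln <= length(lines)) {
    if (!nzchar(trimws(lines[ln]))) { ln <- ln + 1L; next }
    n <- suppressWarnings(as.integer(trimws(lines[ln])))
    if (is.na(n) || n < 1L)
      stop("parse error at line ", ln, ": expected an atom count, got '",
           lines[ln], "'")
    if (ln + 1L > length(lines))
      stop("parse error at line ", ln + 1L, ": missing comment line")
    cell <- parse_lattice(lines[ln + 1L], ln + 1L)
    if (ln + 1L + n > length(lines))
      stop("parse error at line ", length(lines),
           ": truncated frame (expected ", n, " atom records)")
    rec <- lines[(ln + 2L):(ln + 1L + n)]
    toks <- strsplit(trimws(rec), "[[:space:]]+")
    bad <- which(vapply(toks, length, 0L) < 4L)
    if (length(bad))
      stop("parse error at line ", ln + 1L + bad[1L],
           ": expected 'species x y z'")
    species <- vapply(toks, `[[`, "", 1L)
    xyz <- vapply(toks, function(t) {
      v <- suppressWarnings(as.numeric(t[2:4]))
      v
    }, numeric(3))
    if (anyNA(xyz)) {
      bad <- which(apply(is.na(xyz), 2L, any))[1L]
      stop("parse error at line ", ln + 1L + bad,
           ": non-numeric coordinate")
    }
    frames[[length(frames) + 1L]] <-
      simulation_frame(species, t(xyz), cell, length(frames) + 1L)
    ln <- ln + 2L + n
  }
  if (!length(frames)) stop("no frames found in ", path)
  tryCatch(trajectory(frames, metadata = list(source = path)),
           error = function(e)
             stop("validation error reading ", path, ": ",
                  conditionMessage(e)))
}

parse_lattice <- function(comment, lineno) {
  m <- regmatches(comment, regexpr('Lattice="[^"]*"', comment))
  if (!length(m))
    stop("parse error at line ", lineno, ": no Lattice=\"...\" field")
  vals <- suppressWarnings(as.numeric(strsplit(
    sub('^Lattice="', "", sub('"$', "", m)), "[[:space:]]+")[[1L]]))
  vals <- vals[!is.na(vals)]
  if (length(vals) != 9L)
    stop("parse error at line ", lineno, ": Lattice must hold 9 numbers")
  L <- matrix(vals, 3L, 3L, byrow = TRUE)
  off <- L; diag(off) <- 0
  if (any(abs(off) > 1e-10))
    stop("unsupported geometry at line ", lineno,
         ": only orthorhombic (diagonal) lattices are supported")
  if (any(diag(L) <= 0))
    stop("parse error at line ", lineno, ": cell edges must be positive")
  diag(L)
}

#' Write a trajectory as extended-XYZ
#'
#' @param traj a [trajectory()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_extxyz <- function(traj, path) {
  if (!inherits(traj, "trajectory")) stop("`traj` must be a trajectory")
  out <- character(0)
  for (fr in traj$frames) {
    cl <- fr$cell
    comment <- sprintf(
      'Lattice="%.10g 0 0 0 %.10g 0 0 0 %.10g" Properties=species:S:1:pos:R:3',
      cl[1], cl[2], cl[3])
    body <- sprintf("%s %.8f %.8f %.8f", fr$species,
                    fr$positions[, 1], fr$positions[, 2], fr$positions[, 3])
    out <- c(out, as.character(length(fr$species)), comment, body)
  }
  ok <- tryCatch({ writeLines(out, path); TRUE },
                 error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop("cannot write to ", path)
  invisible(path)
}
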