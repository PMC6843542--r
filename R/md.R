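# Trajectory metrics on plain-text frames: mean energy, unaligned RMSD,
# minimum inter-group distances.

#' Trajectory frame series
#'
#' Ordered coordinate frames with a constant atom count and optional
#' per-atom group labels (e.g. `"peptide"`, `"POPC"`, `"POPG"`).
#'
#' @param times numeric vector of frame times (ps), strictly increasing.
#' @param coords list of N x 3 numeric matrices (Angstrom), one per frame.
#' @param groups optional character vector of length N labelling each atom.
#' @return object of class `frame_series`.
#' @export
frame_series <- function(times, coords, groups = NULL) {
  if (length(times) != length(coords)) stop("times and coords lengths differ")
  if (any(diff(times) <= 0)) stop("frame times must be strictly increasing")
  coords <- lapply(coords, function(m) {
    m <- as.matrix(m)
    if (ncol(m) != 3) stop("each frame must be an N x 3 matrix")
    storage.mode(m) <- "double"
    m
  })
  n <- nrow(coords[[1]])
  if (any(vapply(coords, nrow, 1L) != n)) stop("atom count varies across frames")
  if (!is.null(groups) && length(groups) != n)
    stop("groups must label every atom")
  structure(list(times = times, coords = coords, groups = groups),
            class = "frame_series")
}

#' @export
print.frame_series <- function(x, ...) {
  cat(sprintf("<frame_series> %d frames, %d atoms", length(x$times),
              nrow(x$coords[[1]])))
  if (!is.null(x$groups))
    cat(", groups:", paste(unique(x$groups), collapse = ", "))
  cat("\n")
  invisible(x)
}

#' Read a multi-frame XYZ trajectory
#'
#' Standard XYZ text format: atom count line, comment line (a `time = <t>`
#' token, if present, sets the frame time; otherwise frames are numbered
#' 0, 1, ...), then one `element x y z` line per atom. The element column
#' becomes the group label.
#'
#' @param path file path.
#' @return a [frame_series()].
#' @export
read_xyz <- function(path) {
  lines <- readLines(path, warn = FALSE)
  i <- 1L; frames <- list(); times <- numeric(0); groups <- NULL; f <- 0L
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    n <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(n)) stop("line ", i, ": expected an atom count")
    comment <- lines[i + 1L]
    tm <- regmatches(comment, regexpr("time\\s*=\\s*[-0-9.eE+]+", comment))
    t_val <- if (length(tm)) as.numeric(sub("time\\s*=\\s*", "", tm)) else f
    rows <- lines[(i + 2L):(i + 1L + n)]
    parts <- strsplit(trimws(rows), "[[:space:]]+")
    lab <- vapply(parts, `[[`, "", 1L)
    m <- t(vapply(parts, function(p) as.numeric(p[2:4]), numeric(3)))
    if (any(is.na(m))) stop("non-numeric coordinate in frame ", f + 1L)
    if (is.null(groups)) groups <- lab
    frames[[f + 1L]] <- m
    times <- c(times, t_val)
    f <- f + 1L
    i <- i + 2L + n
  }
  frame_series(times, frames, groups)
}

#' Mean of an energy series
#'
#' Arithmetic mean \eqn{\bar{E} = \frac{1}{N}\sum_i E_i} of an energy log.
#'
#' @param series numeric vector of energies, or an [xy_series()] of
#'   (time, energy) pairs.
#' @return numeric scalar.
#' @export
mean_energy <- function(series) {
  e <- if (inherits(series, "xy_series")) series$y else as.numeric(series)
  if (!length(e)) stop("empty energy series")
  mean(e)
}

.group_index <- function(fs, group) {
  if (is.null(group)) return(seq_len(nrow(fs$coords[[1]])))
  if (is.numeric(group)) return(as.integer(group))
  if (is.null(fs$groups)) stop("frame series carries no group labels")
  idx <- which(fs$groups %in% group)
  if (!length(idx)) stop("unknown group label: ", paste(group, collapse = ", "))
  idx
}

#' Root-mean-square deviation between two frames
#'
#' \deqn{RMSD = \sqrt{\sum_i \|r_i(t_1) - r_i(t_2)\|^2 / N}}
#' computed directly on the coordinates, with no superposition or mass
#' weighting. For a least-squares superposed variant see [kabsch_rmsd()].
#'
#' @param a,b N x 3 coordinate matrices (Angstrom).
#' @param idx optional atom index subset applied to both frames.
#' @return RMSD in Angstrom.
#' @export
frame_rmsd <- function(a, b, idx = NULL) {
  a <- as.matrix(a); b <- as.matrix(b)
  if (!is.null(idx)) { a <- a[idx, , drop = FALSE]; b <- b[idx, , drop = FALSE] }
  if (!identical(dim(a), dim(b))) stop("frames differ in atom count")
  sqrt(sum((a - b)^2) / nrow(a))
}

#' RMSD of every frame against a reference
#'
#' @param fs a [frame_series()].
#' @param reference frame index used as reference (default the first frame).
#' @param group optional group label(s) or atom indices to restrict to.
#' @return an [xy_series()] of (time, RMSD); the reference frame maps to 0.
#' @export
rmsd_series <- function(fs, reference = 1L, group = NULL) {
  stopifnot(inherits(fs, "frame_series"))
  idx <- .group_index(fs, group)
  ref <- fs$coords[[reference]][idx, , drop = FALSE]
  r <- vapply(fs$coords, function(m)
    frame_rmsd(m[idx, , drop = FALSE], ref), numeric(1))
  xy_series(fs$times, r, list(kind = "rmsd",
                              group = if (is.null(group)) "all" else paste(group, collapse = "+")))
}

#' Minimum inter-group distance per frame
#'
#' The smallest Euclidean distance between any atom of `groupA` and any
#' atom of `groupB`, per frame.
#'
#' @param fs a [frame_series()].
#' @param groupA,groupB group labels or atom index vectors (non-empty).
#' @return an [xy_series()] of (time, minimum distance in Angstrom).
#' @export
min_distance_series <- function(fs, groupA, groupB) {
  stopifnot(inherits(fs, "frame_series"))
  ia <- .group_index(fs, groupA); ib <- .group_index(fs, groupB)
  if (!length(ia) || !length(ib)) stop("empty atom group")
  d <- vapply(fs$coords, function(m) {
    a <- m[ia, , drop = FALSE]; b <- m[ib, , drop = FALSE]
    # squared distances via the expansion |a-b|^2 = |a|^2 + |b|^2 - 2 a.b
    d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
    sqrt(max(min(d2), 0))
  }, numeric(1))
  xy_series(fs$times, d, list(kind = "min_distance"))
}

#' Superposed (Kabsch) RMSD between two frames
#'
#' Removes the optimal rigid rotation and translation before computing the
#' deviation. This is *not* the deviation used by the trajectory metrics
#' above, which compare raw coordinates; it is provided for users who want
#' internal-conformation differences only.
#'
#' @inheritParams frame_rmsd
#' @return RMSD in Angstrom after least-squares superposition.
#' @export
kabsch_rmsd <- function(a, b, idx = NULL) {
  a <- as.matrix(a); b <- as.matrix(b)
  if (!is.null(idx)) { a <- a[idx, , drop = FALSE]; b <- b[idx, , drop = FALSE] }
  if (!identical(dim(a), dim(b))) stop("frames differ in atom count")
  ac <- scale(a, scale = FALSE); bc <- scale(b, scale = FALSE)
  s <- svd(crossprod(bc, ac))
  d <- sign(det(s$v %*% t(s$u)))
  rot <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  frame_rmsd(ac %*% rot, bc)
}
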