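#' x-y data series (spectrum or thermogram)
#'
#' The shared container for one instrument trace: a strictly monotone
#' x grid (wavenumber in cm^-1 or temperature in degrees C) with one value
#' per grid point (absorbance or heat flow). Descending input is stored
#' ascending with the reversal recorded in `meta$reversed`. Units are
#' carried as metadata and never converted silently.
#'
#' @param x numeric grid, strictly monotone (either direction).
#' @param y numeric values, same length as `x`.
#' @param meta named list of free-form metadata (sample id, units,
#'   peptide:lipid ratio, ...).
#' @return an object of class `xy_series`: a list with elements `x`
#'   (ascending), `y` and `meta`.
#' @export
xy_series <- function(x, y, meta = list()) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) stop("x and y lengths differ")
  if (length(x) < 1) stop("empty series")
  if (!all(is.finite(x)) || !all(is.finite(y))) stop("non-finite values in series")
  dx <- diff(x)
  if (all(dx > 0)) {
    # ascending, keep
  } else if (all(dx < 0)) {
    x <- rev(x); y <- rev(y)
    meta$reversed <- TRUE
  } else {
    stop("x grid is not strictly monotone")
  }
  structure(list(x = x, y = y, meta = meta), class = "xy_series")
}

#' @export
print.xy_series <- function(x, ...) {
  cat(sprintf("<xy_series> %d points, x in [%g, %g]\n",
              length(x$x), min(x$x), max(x$x)))
  if (length(x$meta)) {
    flat <- vapply(x$meta, function(v) paste(format(v), collapse = " "), "")
    cat("  meta:", paste(names(flat), flat, sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
length.xy_series <- function(x) length(x$x)

#' Read an x-y table from delimited text or JCAMP-DX
#'
#' Reads two-or-more-column delimited text (comma, tab or whitespace,
#' autodetected) or a minimal JCAMP-DX file in the `(X++(Y..Y))` XYDATA
#' dialect. Comment lines starting with `#`, `;` or `//` are skipped.
#' The first two numeric columns become x and y.
#'
#' @param path file path.
#' @param kind `"spectrum"` (x in cm^-1) or `"thermogram"` (x in degrees C);
#'   recorded in the metadata.
#' @return an [xy_series()], stored with ascending x.
#' @export
read_xy <- function(path, kind = c("spectrum", "thermogram")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  if (any(grepl("^##XYDATA", lines))) {
    ser <- read_jcamp_lines(lines)
  } else {
    ser <- read_delim_lines(lines)
  }
  ser$meta$kind <- kind
  ser$meta$source <- path
  ser
}

read_delim_lines <- function(lines) {
  keep <- !grepl("^\\s*($|#|;|//)", lines)
  lineno <- which(keep)
  lines <- lines[keep]
  if (!length(lines)) stop("no data rows")
  delim <- if (any(grepl(",", lines))) "," else if (any(grepl("\t", lines))) "\t" else "[[:space:]]+"
  xs <- numeric(length(lines)); ys <- numeric(length(lines))
  for (i in seq_along(lines)) {
    parts <- strsplit(trimws(lines[i]), delim)[[1]]
    parts <- parts[nzchar(parts)]
    if (length(parts) < 2)
      stop("line ", lineno[i], ": expected at least 2 columns")
    vals <- suppressWarnings(as.numeric(parts[1:2]))
    if (any(is.na(vals)))
      stop("line ", lineno[i], ": non-numeric value in x/y columns")
    xs[i] <- vals[1]; ys[i] <- vals[2]
  }
  xy_series(xs, ys)
}

# Minimal JCAMP-DX: fixed-form (X++(Y..Y)) with XFACTOR/YFACTOR applied.
read_jcamp_lines <- function(lines) {
  getnum <- function(key, default = NA_real_) {
    hit <- grep(paste0("^##", key, "="), lines, value = TRUE)
    if (!length(hit)) return(default)
    as.numeric(sub(paste0("^##", key, "=\\s*"), "", hit[1]))
  }
  xf <- getnum("XFACTOR", 1); yf <- getnum("YFACTOR", 1)
  start <- grep("^##XYDATA", lines)[1]
  stopline <- grep("^##END", lines)
  stopline <- if (length(stopline)) min(stopline[stopline > start]) else length(lines) + 1L
  body <- lines[seq(start + 1L, stopline - 1L)]
  body <- body[nzchar(trimws(body))]
  xs <- numeric(0); ys <- numeric(0)
  # infer the per-point x step from NPOINTS/FIRSTX/LASTX when present
  np <- getnum("NPOINTS"); fx <- getnum("FIRSTX"); lx <- getnum("LASTX")
  dx <- if (is.finite(np) && np > 1) (lx - fx) / (np - 1) else NA_real_
  for (ln in body) {
    vals <- suppressWarnings(as.numeric(strsplit(trimws(ln), "[[:space:]]+")[[1]]))
    if (any(is.na(vals)) || length(vals) < 2) stop("unparseable JCAMP data line: ", ln)
    x0 <- vals[1] * xf
    yv <- vals[-1] * yf
    step <- if (is.finite(dx)) dx * xf else 1
    xs <- c(xs, x0 + step * (seq_along(yv) - 1))
    ys <- c(ys, yv)
  }
  xy_series(xs, ys)
}

#' Write an x-y series as a two-column CSV
#'
#' @param ser an [xy_series()].
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_xy <- function(ser, path) {
  stopifnot(inherits(ser, "xy_series"))
  utils::write.table(data.frame(x = ser$x, y = ser$y), path,
                     sep = ",", row.names = FALSE, col.names = FALSE)
  invisible(path)
}
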