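# internal numeric helpers

#' @importFrom pracma trapz
trapz_range <- function(x, y, lo, hi) {
  keep <- x >= lo & x <= hi
  if (sum(keep) < 2) stop("fewer than 2 points in [", lo, ", ", hi, "]")
  pracma::trapz(x[keep], y[keep])
}

# Centered moving average. Even windows use the standard half-weight
# (2 x k) filter so the output stays on the input grid; edges are padded
# by replicating the end values.
moving_average <- function(y, k) {
  if (k <= 1) return(y)
  taps <- if (k %% 2 == 0) c(0.5, rep(1, k - 1), 0.5) / k else rep(1 / k, k)
  h <- (length(taps) - 1) / 2
  ypad <- c(rep(y[1], h), y, rep(y[length(y)], h))
  out <- stats::filter(ypad, taps, sides = 2)
  as.numeric(out[(h + 1):(h + length(y))])
}

# Round percentages to integers that sum to the rounded total (largest
# remainder / Hamilton method). Ties go to the larger value, then lower index.
largest_remainder_round <- function(p, total = 100L) {
  if (any(p < 0)) stop("negative percentage")
  fl <- floor(p)
  rem <- p - fl
  short <- total - sum(fl)
  if (short > 0) {
    ord <- order(-rem, -p, seq_along(p))
    fl[ord[seq_len(short)]] <- fl[ord[seq_len(short)]] + 1
  }
  as.integer(fl)
}

# Prominences of local maxima of v (scipy definition). Returns a data.frame
# with the index of each interior local maximum and its prominence.
peak_prominences <- function(v) {
  n <- length(v)
  idx <- which(diff(sign(diff(v))) < 0) + 1L
  idx <- idx[v[idx] > v[idx - 1L]]          # strict rise on the left
  if (!length(idx)) {
    return(data.frame(index = integer(), prominence = numeric()))
  }
  prom <- vapply(idx, function(i) {
    lmin <- v[i]; j <- i
    while (j > 1L && v[j - 1L] <= v[i]) { j <- j - 1L; lmin <- min(lmin, v[j]) }
    left <- if (j == 1L && v[j] <= v[i]) min(lmin, v[1L]) else lmin
    rmin <- v[i]; j <- i
    while (j < n && v[j + 1L] <= v[i]) { j <- j + 1L; rmin <- min(rmin, v[j]) }
    right <- if (j == n && v[j] <= v[i]) min(rmin, v[n]) else rmin
    v[i] - max(left, right)
  }, numeric(1))
  data.frame(index = idx, prominence = prom)
}

# Sub-grid peak position by quadratic interpolation through the vertex
# and its two neighbours.
refine_peak <- function(x, y, i) {
  if (i <= 1L || i >= length(x)) return(x[i])
  y1 <- y[i - 1L]; y2 <- y[i]; y3 <- y[i + 1L]
  denom <- y1 - 2 * y2 + y3
  if (denom == 0) return(x[i])
  d <- 0.5 * (y1 - y3) / denom
  d <- max(min(d, 1), -1)
  x[i] + d * (x[i] - x[i - 1L])
}
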