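# Independent brute-force oracles, kept deliberately naive so they share
# no code path with the implementation they check.

oracle_moment <- function(seq, delta = 100, scale = pepmem::fauchere_pliska) {
  res <- strsplit(toupper(seq), "")[[1]]
  acc <- 0 + 0i
  for (n in seq_along(res)) {
    acc <- acc + scale[[res[n]]] * exp(1i * (n - 1) * delta * pi / 180)
  }
  Mod(acc) / length(res)
}

oracle_rmsd <- function(a, b) {
  s <- 0
  for (i in seq_len(nrow(a))) {
    for (j in 1:3) s <- s + (a[i, j] - b[i, j])^2
  }
  sqrt(s / nrow(a))
}

oracle_min_dist <- function(a, b) {
  best <- Inf
  for (i in seq_len(nrow(a))) {
    for (j in seq_len(nrow(b))) {
      d <- sqrt(sum((a[i, ] - b[j, ])^2))
      if (d < best) best <- d
    }
  }
  best
}

# analytic second derivative of a sum of Gaussians A*exp(-(x-c)^2/(2s^2))
oracle_gauss_d2 <- function(x, A, c, s) {
  out <- numeric(length(x))
  for (k in seq_along(A)) {
    u <- (x - c[k]) / s[k]^2
    out <- out + A[k] * exp(-(x - c[k])^2 / (2 * s[k]^2)) * (u^2 * s[k]^2 - 1) / s[k]^2
  }
  out
}

gaussian_spectrum <- function(centers, areas, sigmas, grid = seq(1300, 1800, 1),
                              slope = 0, intercept = 0) {
  y <- intercept + slope * (grid - 1300)
  for (k in seq_along(centers)) {
    y <- y + areas[k] * stats::dnorm(grid, centers[k], sigmas[k])
  }
  pepmem::xy_series(grid, y)
}
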