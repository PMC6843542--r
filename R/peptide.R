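# Sequence-level descriptors: charge, hydrophobicity, hydrophobic moment,
# helical wheel projection.

#' Fauchere-Pliska hydrophobicity scale
#'
#' Side-chain octanol/water transfer free energies (kcal/mol) from
#' Fauchere & Pliska (1983), Eur. J. Med. Chem. 18, 369-375; the scale
#' used by the HeliQuest server for hydrophobicity and hydrophobic-moment
#' calculations.
#'
#' @format named numeric vector over the 20 canonical one-letter codes.
#' @export
fauchere_pliska <- c(
  A = 0.31, R = -1.01, N = -0.60, D = -0.77, C = 1.54,
  Q = -0.22, E = -0.64, G = 0.00, H = 0.13, I = 1.80,
  L = 1.70, K = -0.99, M = 1.23, F = 1.79, P = 0.72,
  S = -0.04, T = 0.26, W = 2.25, Y = 0.96, V = 1.22)

.residue_class <- c(
  A = "hydrophobic", C = "hydrophobic", F = "hydrophobic", I = "hydrophobic",
  L = "hydrophobic", M = "hydrophobic", V = "hydrophobic", W = "hydrophobic",
  Y = "hydrophobic",
  K = "positive", R = "positive",
  D = "negative", E = "negative",
  S = "polar", T = "polar", N = "polar", Q = "polar", H = "polar",
  G = "other", P = "other")

validate_sequence <- function(seq) {
  if (!is.character(seq) || length(seq) != 1 || nchar(seq) < 1)
    stop("sequence must be a single non-empty string")
  seq <- toupper(seq)
  res <- strsplit(seq, "")[[1]]
  bad <- which(!res %in% names(fauchere_pliska))
  if (length(bad))
    stop("invalid residue '", res[bad[1]], "' at position ", bad[1])
  res
}

#' Net side-chain charge at pH 7
#'
#' +1 per Lys/Arg, -1 per Asp/Glu; His is treated as uncharged (side-chain
#' pKa ~6) and the free termini cancel (+1 N-terminus, -1 C-terminus).
#'
#' @param seq one-letter peptide sequence.
#' @return integer net charge.
#' @examples
#' net_charge("GLKEIFKAGLGSLVKGIAAHVAS")  # 2
#' net_charge("GLKRIFKSGLGKLVKGISAHVAS")  # 5
#' @export
net_charge <- function(seq) {
  res <- validate_sequence(seq)
  sum(res %in% c("K", "R")) - sum(res %in% c("D", "E"))
}

#' Mean residue hydrophobicity
#'
#' Arithmetic mean of per-residue scale values (default
#' [fauchere_pliska]).
#'
#' @param seq one-letter peptide sequence.
#' @param scale named numeric vector over residue letters.
#' @return numeric scalar.
#' @export
mean_hydrophobicity <- function(seq, scale = fauchere_pliska) {
  res <- validate_sequence(seq)
  mean(scale[res])
}

#' Eisenberg hydrophobic moment
#'
#' \deqn{\mu_H = \frac{1}{N}\left|\sum_{n=0}^{N-1} H_n e^{i n \delta}\right|}
#' with residues placed `delta` degrees apart around an ideal helix
#' (100 degrees per residue). Normalization by N (the mean moment, matching
#' HeliQuest) is the default; `normalize = FALSE` returns the raw vector sum.
#'
#' @param seq one-letter peptide sequence.
#' @param delta angular step per residue, degrees.
#' @param scale hydrophobicity scale.
#' @param normalize divide by the number of residues.
#' @return numeric scalar, >= 0.
#' @export
hydrophobic_moment <- function(seq, delta = 100, scale = fauchere_pliska,
                               normalize = TRUE) {
  res <- validate_sequence(seq)
  h <- scale[res]
  n <- seq_along(h) - 1
  ang <- n * delta * pi / 180
  mu <- sqrt(sum(h * cos(ang))^2 + sum(h * sin(ang))^2)
  if (normalize) mu / length(h) else mu
}

#' Helical wheel projection
#'
#' Places the first `window` residues on an ideal alpha-helical wheel,
#' residue n (zero-based) at `(n x 100) mod 360` degrees, and classifies
#' each residue (hydrophobic; K/R positive; D/E negative; S/T/N/Q/H polar;
#' G/P other).
#'
#' @param seq one-letter peptide sequence of length >= `window`.
#' @param window number of residues projected (default 18, the span of an
#'   N-terminal amphipathic segment).
#' @return object of class `wheel_projection`: a data.frame with columns
#'   `index` (zero-based), `letter`, `angle` (degrees), `radius`, `class`.
#' @export
wheel_projection <- function(seq, window = 18) {
  res <- validate_sequence(seq)
  if (window > length(res)) stop("window longer than the sequence")
  res <- res[seq_len(window)]
  n <- seq_len(window) - 1
  out <- data.frame(index = n, letter = res, angle = (n * 100) %% 360,
                    radius = 1, class = unname(.residue_class[res]),
                    stringsAsFactors = FALSE)
  class(out) <- c("wheel_projection", class(out))
  out
}

#' @export
plot.wheel_projection <- function(x, ...) {
  pal <- c(hydrophobic = "gold", positive = "steelblue", negative = "firebrick",
           polar = "orchid", other = "grey60")
  th <- x$angle * pi / 180
  graphics::plot(sin(th), cos(th), asp = 1, axes = FALSE, xlab = "", ylab = "",
                 pch = 21, cex = 4, bg = pal[x$class], ...)
  graphics::text(sin(th), cos(th), x$letter, font = 2)
  invisible(x)
}

#' Positions at which two sequences differ
#'
#' @param a,b equal-length one-letter sequences.
#' @return zero-based integer positions of mismatches.
#' @export
seq_diff_positions <- function(a, b) {
  ra <- validate_sequence(a); rb <- validate_sequence(b)
  if (length(ra) != length(rb)) stop("sequences differ in length")
  which(ra != rb) - 1L
}
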