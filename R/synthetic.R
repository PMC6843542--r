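# Seeded generators for FTIR spectra, DSC thermograms and toy trajectories
# with known ground truth, plus presets encoding every tabulated
# peptide / membrane condition so the pipelines are validated by
# parameter recovery.

#' Recipe for a synthetic amide I' spectrum
#'
#' @param bands data.frame with columns `center, sigma, gamma, area`
#'   (cm^-1 / absorbance x cm^-1) covering amide I', amide II, side-chain
#'   and (optionally) lipid C=O components.
#' @param baseline `c(intercept, slope)`: linear absorbance baseline,
#'   slope per cm^-1 relative to 1300 cm^-1.
#' @param noise_frac additive Gaussian noise sd as a fraction of the
#'   maximum band signal (0.01 corresponds to SNR 100).
#' @param grid `c(start, stop, step)` in cm^-1; must cover 1300-1800.
#' @param lipid `"none"`, `"PC"` or `"PC_PG"`; stored in the metadata and
#'   used when computing the truth fractions.
#' @param seed default random seed for the noise.
#' @return object of class `spectrum_recipe`.
#' @export
spectrum_recipe <- function(bands, baseline = c(0.02, 0), noise_frac = 0.01,
                            grid = c(1300, 1800, 1), lipid = "none", seed = 1L) {
  stopifnot(is.data.frame(bands),
            all(c("center", "sigma", "gamma", "area") %in% names(bands)))
  if (any(bands$area <= 0)) stop("band areas must be > 0")
  if (length(grid) != 3 || grid[3] <= 0 || grid[1] >= grid[2])
    stop("grid must be c(start, stop, step) with step > 0")
  if (grid[1] > 1300 || grid[2] < 1800)
    stop("grid must cover 1300-1800 cm^-1")
  structure(list(bands = bands, baseline = baseline, noise_frac = noise_frac,
                 grid = grid, lipid = lipid, seed = as.integer(seed)),
            class = "spectrum_recipe")
}

#' Recipe for a synthetic DSC thermogram
#'
#' @param transitions data.frame with columns `T` (peak temperature,
#'   degrees C), `dH` (J/g), `fwhm` (degrees C) and optionally `shape`
#'   (`"gaussian"` or `"asym"`).
#' @param baseline `c(intercept, slope)` in mW and mW per degree C.
#' @param noise_frac noise sd as a fraction of the tallest transition peak.
#' @param mass_g lipid mass (g).
#' @param rate_c_min heating rate (degrees C/min).
#' @param grid `c(start, stop, step)` in degrees C.
#' @param ratio peptide:lipid molar ratio label.
#' @param seed default random seed.
#' @return object of class `thermogram_recipe`.
#' @export
thermogram_recipe <- function(transitions, baseline = c(0.05, 0.002),
                              noise_frac = 0.01, mass_g = 0.002,
                              rate_c_min = 1, grid = c(8, 40, 0.02),
                              ratio = NA_character_, seed = 1L) {
  stopifnot(is.data.frame(transitions),
            all(c("T", "dH", "fwhm") %in% names(transitions)))
  if (any(transitions$dH < 0)) stop("transition dH must be >= 0")
  if (any(transitions$fwhm <= 0)) stop("transition widths must be > 0")
  if (length(grid) != 3 || grid[3] <= 0 || grid[1] >= grid[2])
    stop("grid must be c(start, stop, step) with step > 0")
  if (any(transitions$T <= grid[1] | transitions$T >= grid[2]))
    stop("transitions outside the temperature grid")
  if (is.null(transitions$shape)) transitions$shape <- "gaussian"
  structure(list(transitions = transitions, baseline = baseline,
                 noise_frac = noise_frac, mass_g = mass_g,
                 rate_c_min = rate_c_min, grid = grid, ratio = ratio,
                 seed = as.integer(seed)),
            class = "thermogram_recipe")
}

#' Generate a synthetic amide I' spectrum with known truth
#'
#' Sums unit-area Voigt components scaled by the recipe areas, adds the
#' linear baseline and seeded Gaussian noise. The truth record carries the
#' exact component table plus the structure fractions and C=O ratio the
#' analysis pipeline is expected to recover.
#'
#' @param recipe a [spectrum_recipe()], or a FTIR preset name from
#'   [list_presets()].
#' @param seed overrides the recipe seed when given.
#' @return list with `spectrum` (an [xy_series()]) and `truth` (list with
#'   `bands`, `fractions`, `co_ratio`).
#' @export
make_spectrum <- function(recipe, seed = NULL) {
  if (is.character(recipe)) recipe <- get_preset(recipe)$recipe
  stopifnot(inherits(recipe, "spectrum_recipe"))
  if (is.null(seed)) seed <- recipe$seed
  g <- recipe$grid
  x <- seq(g[1], g[2], by = g[3])
  b <- recipe$bands
  # components are renormalized on the finite grid so each band's on-grid
  # integral equals its requested area exactly (Lorentzian wings otherwise
  # lose ~1% beyond the grid edges)
  sig <- numeric(length(x))
  for (k in seq_len(nrow(b))) {
    comp <- voigt_profile(x, b$center[k], b$sigma[k], b$gamma[k])
    sig <- sig + b$area[k] * comp / pracma::trapz(x, comp)
  }
  y <- sig + recipe$baseline[1] + recipe$baseline[2] * (x - 1300)
  if (recipe$noise_frac > 0) {
    y <- y + withr::with_seed(seed,
      stats::rnorm(length(x), sd = recipe$noise_frac * max(sig)))
  }
  spec <- xy_series(x, y, list(kind = "spectrum", lipid = recipe$lipid,
                               synthetic = TRUE, seed = seed))
  list(spectrum = spec, truth = .spectrum_truth(recipe))
}

.spectrum_truth <- function(recipe) {
  b <- recipe$bands
  lipid_free <- identical(recipe$lipid, "none")
  cls <- vapply(b$center, function(cc)
    tryCatch(assign_band(cc, b$center, lipid_free), error = function(e) "outside"),
    "")
  amide <- cls %in% .amide_classes
  total <- sum(b$area[amide])
  pct <- 100 * tapply(b$area[amide], cls[amide], sum) / total
  rounded <- largest_remainder_round(as.numeric(pct))
  names(rounded) <- names(pct)
  co <- sum(b$area[cls == "lipid_CO"])
  list(bands = cbind(b, class = cls),
       fractions = rounded[order(-rounded)],
       co_ratio = if (co > 0) 100 * co / (co + total) else NA_real_)
}

# split-Gaussian density (unit area) used for the "asym" transition shape
.split_gauss <- function(x, center, sl, sr) {
  h <- 2 / (sqrt(2 * pi) * (sl + sr))
  ifelse(x < center, h * exp(-(x - center)^2 / (2 * sl^2)),
         h * exp(-(x - center)^2 / (2 * sr^2)))
}

#' Generate a synthetic DSC thermogram with known truth
#'
#' Each transition contributes an endothermic peak whose baseline-free
#' excess-heat integral per gram equals its `dH`; a drifting linear
#' baseline and seeded Gaussian noise (scaled to the tallest peak) are
#' added on top.
#'
#' @param recipe a [thermogram_recipe()], or a DSC preset name from
#'   [list_presets()].
#' @param seed overrides the recipe seed when given.
#' @return list with `thermogram` (a [thermogram()]) and `truth` (the
#'   transition table: `T`, `dH`, `fwhm`, `role`).
#' @export
make_thermogram <- function(recipe, seed = NULL) {
  if (is.character(recipe)) recipe <- get_preset(recipe)$recipe
  stopifnot(inherits(recipe, "thermogram_recipe"))
  if (is.null(seed)) seed <- recipe$seed
  g <- recipe$grid
  x <- seq(g[1], g[2], by = g[3])
  tr <- recipe$transitions
  rate_c_s <- recipe$rate_c_min / 60
  y <- numeric(length(x))
  heights <- numeric(nrow(tr))
  for (k in seq_len(nrow(tr))) {
    # peak area in mW*degC reproducing dH J/g after /rate /mass /1000
    area <- tr$dH[k] * recipe$mass_g * 1000 * rate_c_s
    s <- tr$fwhm[k] / (2 * sqrt(2 * log(2)))
    shape <- if (identical(tr$shape[k], "asym"))
      .split_gauss(x, tr$T[k], 1.4 * s, 0.7 * s)
    else stats::dnorm(x, tr$T[k], s)
    y <- y + area * shape
    heights[k] <- area * max(shape)
  }
  y <- y + recipe$baseline[1] + recipe$baseline[2] * (x - g[1])
  if (recipe$noise_frac > 0 && any(heights > 0)) {
    y <- y + withr::with_seed(seed,
      stats::rnorm(length(x), sd = recipe$noise_frac * max(heights)))
  }
  truth <- tr
  truth$role <- ifelse(seq_len(nrow(tr)) == which.max(tr$dH / tr$fwhm), "main",
                       ifelse(tr$T < tr$T[which.max(tr$dH / tr$fwhm)], "pre", "minor"))
  tg <- thermogram(x, y, mass_g = recipe$mass_g,
                   rate_c_min = recipe$rate_c_min, ratio = recipe$ratio,
                   meta = list(kind = "thermogram", synthetic = TRUE, seed = seed))
  list(thermogram = tg, truth = truth)
}

# ---- presets ---------------------------------------------------------------

.ftir_band <- function(center, area, sigma = 7, gamma = 3)
  data.frame(center = center, sigma = sigma, gamma = gamma, area = area)

# amide I' component areas sum to 1; side-chain / amide II extras are shared.
.ftir_aux <- rbind(
  .ftir_band(1540, 0.080, sigma = 8),   # residual amide II
  .ftir_band(1575, 0.015, sigma = 5, gamma = 2),  # His side chain
  .ftir_band(1527, 0.020, sigma = 5, gamma = 2))  # Lys side chain

.co_area <- function(ratio_pct) ratio_pct / (100 - ratio_pct)

.ftir_recipes <- function() {
  co_band <- function(pct) .ftir_band(1730, .co_area(pct), sigma = 8, gamma = 4)
  list(
    pep2_free = spectrum_recipe(
      rbind(.ftir_band(1691, 0.20), .ftir_band(1666, 0.34),
            .ftir_band(1622, 0.46), .ftir_aux),
      lipid = "none"),
    pep2_pc = spectrum_recipe(
      rbind(.ftir_band(1684, 0.36), .ftir_band(1653, 0.64),
            co_band(22), .ftir_aux),
      lipid = "PC"),
    pep2_pcpg = spectrum_recipe(
      rbind(.ftir_band(1681, 0.49), .ftir_band(1653, 0.51),
            co_band(29), .ftir_aux),
      lipid = "PC_PG"),
    pep5_free = spectrum_recipe(
      rbind(.ftir_band(1680, 0.26), .ftir_band(1647, 0.48),
            .ftir_band(1618, 0.26), .ftir_aux),
      lipid = "none"),
    pep5_pc = spectrum_recipe(
      rbind(.ftir_band(1684, 0.28), .ftir_band(1653, 0.72),
            co_band(14), .ftir_aux),
      lipid = "PC"),
    pep5_pcpg = spectrum_recipe(
      rbind(.ftir_band(1681, 0.81), .ftir_band(1646, 0.19),
            co_band(16), .ftir_aux),
      lipid = "PC_PG"))
}

# main-transition FWHM broadens with peptide load, emulating the
# near-disappearance of the transition at the highest ratio.
.dsc_fwhm <- c("0:1" = 0.8, "1:100" = 1.5, "1:50" = 2.0, "1:25" = 3.0)

.dsc_row <- function(ratio, Tm, dH, pre_T = NA) {
  tr <- data.frame(T = Tm, dH = dH, fwhm = unname(.dsc_fwhm[ratio]))
  if (!is.na(pre_T))
    tr <- rbind(data.frame(T = pre_T, dH = 0.2, fwhm = 1.8), tr)
  thermogram_recipe(tr, ratio = ratio)
}

.dsc_recipes <- function() {
  list(
    dmpc_control       = .dsc_row("0:1", 22.9, 1.47, pre_T = 12.9),
    dmpc_pep2_1to100   = .dsc_row("1:100", 21.2, 0.63),
    dmpc_pep2_1to50    = .dsc_row("1:50", 21.5, 0.62),
    dmpc_pep2_1to25    = .dsc_row("1:25", 21.2, 0.62),
    dmpc_pep5_1to100   = .dsc_row("1:100", 22.7, 0.80),
    dmpc_pep5_1to50    = .dsc_row("1:50", 22.2, 0.63),
    dmpc_pep5_1to25    = .dsc_row("1:25", 20.5, 0.18),
    dmpcg_control      = .dsc_row("0:1", 22.9, 1.60, pre_T = 12.0),
    dmpcg_pep2_1to100  = .dsc_row("1:100", 22.9, 0.54),
    dmpcg_pep2_1to50   = .dsc_row("1:50", 22.8, 0.38),
    dmpcg_pep2_1to25   = .dsc_row("1:25", 21.3, 0.30),
    dmpcg_pep5_1to100  = .dsc_row("1:100", 22.9, 0.64),
    dmpcg_pep5_1to50   = .dsc_row("1:50", 23.0, 0.45),
    dmpcg_pep5_1to25   = .dsc_row("1:25", 22.6, 0.44))
}

.preset_notes <- c(
  pep2_free = "peptide +2 in buffer: beta-sheet 66% (1691+1622), turns 34% (1666)",
  pep2_pc = "peptide +2 + POPC: alpha 64% (1653), beta/turns 36% (1684), C=O ratio 22%",
  pep2_pcpg = "peptide +2 + POPC/POPG: alpha 51% (1653), beta/turns 49% (1681), C=O ratio 29%",
  pep5_free = "peptide +5 in buffer: unordered 48% (1647), aggregation 52% (1680+1618)",
  pep5_pc = "peptide +5 + POPC: alpha 72% (1653), beta/turns 28% (1684), C=O ratio 14%",
  pep5_pcpg = "peptide +5 + POPC/POPG: beta/turns 81% (1681), unordered 19% (1646), C=O ratio 16%",
  dmpc_control = "DMPC MLVs alone: pre-transition 12.9 C, Tm 22.9 C, dH 1.47 J/g",
  dmpc_pep2_1to100 = "DMPC + peptide +2 (1:100): Tm 21.2 C, dH 0.63 J/g",
  dmpc_pep2_1to50 = "DMPC + peptide +2 (1:50): Tm 21.5 C, dH 0.62 J/g",
  dmpc_pep2_1to25 = "DMPC + peptide +2 (1:25): Tm 21.2 C, dH 0.62 J/g",
  dmpc_pep5_1to100 = "DMPC + peptide +5 (1:100): Tm 22.7 C, dH 0.80 J/g",
  dmpc_pep5_1to50 = "DMPC + peptide +5 (1:50): Tm 22.2 C, dH 0.63 J/g",
  dmpc_pep5_1to25 = "DMPC + peptide +5 (1:25): Tm 20.5 C, dH 0.18 J/g (transition nearly abolished)",
  dmpcg_control = "DMPC/DMPG (3:1) MLVs alone: pre-transition 12 C, Tm 22.9 C, dH 1.6 J/g",
  dmpcg_pep2_1to100 = "DMPC/DMPG + peptide +2 (1:100): Tm 22.9 C, dH 0.54 J/g",
  dmpcg_pep2_1to50 = "DMPC/DMPG + peptide +2 (1:50): Tm 22.8 C, dH 0.38 J/g",
  dmpcg_pep2_1to25 = "DMPC/DMPG + peptide +2 (1:25): Tm 21.3 C, dH 0.30 J/g",
  dmpcg_pep5_1to100 = "DMPC/DMPG + peptide +5 (1:100): Tm 22.9 C, dH 0.64 J/g",
  dmpcg_pep5_1to50 = "DMPC/DMPG + peptide +5 (1:50): Tm 23.0 C, dH 0.45 J/g",
  dmpcg_pep5_1to25 = "DMPC/DMPG + peptide +5 (1:25): Tm 22.6 C, dH 0.44 J/g")

#' Catalogue of synthetic presets
#'
#' One FTIR preset per tabulated secondary-structure condition (6) and one
#' DSC preset per tabulated thermogram condition (14), each carrying the
#' ground truth the analysis pipeline is expected to recover.
#'
#' @return data.frame with columns `name`, `kind` (`"ftir"`/`"dsc"`) and
#'   `note` (the encoded condition and truth values). Pass a `name` to
#'   [get_preset()], [make_spectrum()] or [make_thermogram()].
#' @export
list_presets <- function() {
  f <- names(.ftir_recipes()); d <- names(.dsc_recipes())
  data.frame(name = c(f, d),
             kind = c(rep("ftir", length(f)), rep("dsc", length(d))),
             note = unname(.preset_notes[c(f, d)]),
             stringsAsFactors = FALSE)
}

#' Fetch one preset
#'
#' @param name a preset name from [list_presets()].
#' @return list with `name`, `kind`, `note`, `recipe` and `truth` (the
#'   quantities a perfect analysis would recover).
#' @export
get_preset <- function(name) {
  fr <- .ftir_recipes(); dr <- .dsc_recipes()
  if (name %in% names(fr)) {
    r <- fr[[name]]
    list(name = name, kind = "ftir", note = unname(.preset_notes[name]),
         recipe = r, truth = .spectrum_truth(r))
  } else if (name %in% names(dr)) {
    r <- dr[[name]]
    tr <- r$transitions
    main <- which.max(tr$dH / tr$fwhm)
    list(name = name, kind = "dsc", note = unname(.preset_notes[name]),
         recipe = r,
         truth = list(Tm = tr$T[main], dH = tr$dH[main],
                      pre_transition_T = if (nrow(tr) > 1) tr$T[-main][1] else NA_real_))
  } else stop("unknown preset: ", name)
}

#' Synthetic random-walk trajectory
#'
#' Seeded toy trajectory for exercising the trajectory metrics: atoms start
#' on a cubic lattice and take independent Gaussian steps each frame.
#'
#' @param n_atoms atoms per frame.
#' @param n_frames number of frames.
#' @param step_sd per-coordinate step standard deviation (Angstrom).
#' @param groups optional atom group labels (length `n_atoms`).
#' @param seed random seed.
#' @return a [frame_series()].
#' @export
make_trajectory <- function(n_atoms = 20, n_frames = 10, step_sd = 0.5,
                            groups = NULL, seed = 1L) {
  side <- ceiling(n_atoms^(1 / 3))
  lat <- as.matrix(expand.grid(x = seq_len(side), y = seq_len(side),
                               z = seq_len(side)))[seq_len(n_atoms), , drop = FALSE] * 3
  dimnames(lat) <- NULL
  withr::with_seed(seed, {
    frames <- vector("list", n_frames)
    cur <- lat
    for (f in seq_len(n_frames)) {
      frames[[f]] <- cur
      cur <- cur + matrix(stats::rnorm(3 * n_atoms, sd = step_sd), n_atoms, 3)
    }
    frame_series(seq_len(n_frames) - 1, frames, groups)
  })
}
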