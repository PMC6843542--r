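make_gauss_tg <- function(area = 0.05, center = 25, sigma = 1, slope = 0,
                          intercept = 0, noise = 0, grid = seq(8, 40, 0.02),
                          mass_g = 0.002, rate = 1, seed = 1) {
  y <- area * dnorm(grid, center, sigma) + intercept + slope * (grid - 8)
  if (noise > 0) y <- y + withr::with_seed(seed, rnorm(length(grid), sd = noise))
  thermogram(grid, y, mass_g = mass_g, rate_c_min = rate, ratio = "0:1")
}

test_that("baseline correction recovers the analytic peak area on a slope", {
  tg <- make_gauss_tg(area = 0.05, slope = 0.01, intercept = 0.2)
  corr <- correct_baseline(tg)
  got <- pracma::trapz(corr$x, corr$y)
  expect_equal(got, 0.05, tolerance = 0.02 * 0.05)

  # flat zero trace is unchanged
  flat <- thermogram(seq(8, 40, 0.02), rep(0, 1601), 0.002, 1)
  out <- correct_baseline(flat)
  expect_equal(out$y, flat$y, tolerance = 1e-12)

  # a peak occupying nearly the whole scan leaves no stable baseline
  wide <- make_gauss_tg(area = 1, center = 24, sigma = 8)
  expect_error(correct_baseline(wide, exclusion_zones = list(c(9, 39))),
               "explicit")
})

test_that("transitions are detected, labelled and measured on the control preset", {
  pr <- make_thermogram("dmpc_control", seed = 1)
  corr <- correct_baseline(pr$thermogram)
  tr <- detect_transitions(corr)
  expect_identical(tr$role, c("pre", "main"))
  expect_lt(abs(tr$peak_T[tr$role == "pre"] - 12.9), 0.3)
  expect_lt(abs(tr$peak_T[tr$role == "main"] - 22.9), 0.2)
  # main is always the most prominent peak
  expect_equal(max(tr$prominence), tr$prominence[tr$role == "main"])
})

test_that("featureless noise yields no transitions; prominence ratio labels pre vs main", {
  noise <- thermogram(seq(8, 40, 0.02),
                      withr::with_seed(3, rnorm(1601, sd = 1e-4)),
                      0.002, 1)
  corr <- correct_baseline(noise)
  expect_identical(nrow(detect_transitions(corr)), 0L)

  grid <- seq(8, 40, 0.02)
  y <- 0.01 * dnorm(grid, 15, 0.5) + 0.1 * dnorm(grid, 25, 0.5)
  two <- thermogram(grid, y, 0.002, 1)
  two$meta$baseline_corrected <- TRUE
  tr <- detect_transitions(two)
  expect_equal(tr$peak_T[tr$role == "pre"], 15, tolerance = 0.05)
  expect_equal(tr$peak_T[tr$role == "main"], 25, tolerance = 0.05)
})

test_that("transition enthalpy integrates to the known value and scales with mass", {
  # area chosen so that dH = 1.47 J/g at 2 mg and 1 C/min
  area <- 1.47 * 0.002 * 1000 / 60
  tg <- make_gauss_tg(area = area, center = 22.9, sigma = 0.4)
  tg$meta$baseline_corrected <- TRUE
  dH <- transition_enthalpy(tg, 22.9)
  expect_equal(dH, 1.47, tolerance = 0.02 * 1.47)

  # zero-amplitude peak integrates to zero
  flat <- thermogram(seq(8, 40, 0.02), rep(0, 1601), 0.002, 1)
  flat$meta$baseline_corrected <- TRUE
  expect_equal(transition_enthalpy(flat, 22.9), 0)

  # doubling the mass halves dH exactly
  tg2 <- tg; tg2$meta$mass_g <- 0.004
  expect_equal(transition_enthalpy(tg2, 22.9), dH / 2)

  expect_error(transition_enthalpy(tg, 22.9, integration_limits = c(5, 50)),
               "outside")
})

test_that("enthalpy is invariant to an added linear baseline (within 2%)", {
  pr <- make_thermogram("dmpc_control", seed = 5)
  base <- pr$thermogram
  tilted <- base
  tilted$y <- tilted$y + 0.3 - 0.01 * tilted$x
  d1 <- transition_enthalpy(correct_baseline(base), 22.9)
  d2 <- transition_enthalpy(correct_baseline(tilted), 22.9)
  expect_equal(d2, d1, tolerance = 0.02 * d1)
})

test_that("titration table is ratio-ordered with deltas against the control", {
  names <- c("dmpc_pep5_1to25", "dmpc_control", "dmpc_pep5_1to100",
             "dmpc_pep5_1to50")                      # shuffled on purpose
  tgs <- lapply(names, function(n) make_thermogram(n, seed = 11)$thermogram)
  tab <- titration_report(tgs)
  expect_identical(tab$ratio, c("0:1", "1:100", "1:50", "1:25"))
  # enthalpy falls monotonically with peptide load in this series
  expect_true(all(diff(tab$dH) <= 0))
  expect_equal(tab$dTm[1], 0)
  expect_equal(tab$ddH[1], 0)

  solo <- titration_report(list(make_thermogram("dmpc_control", seed = 2)$thermogram))
  expect_identical(nrow(solo), 1L)

  expect_warning(
    nc <- titration_report(list(make_thermogram("dmpc_pep2_1to50", seed = 2)$thermogram)),
    "control")
  expect_false("dTm" %in% names(nc))
})
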