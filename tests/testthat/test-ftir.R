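test_that("preprocess removes a linear baseline and normalizes the area", {
  spec <- gaussian_spectrum(1650, areas = 2.0, sigmas = 8,
                            slope = 1e-4, intercept = 0.05)
  out <- preprocess(spec)
  area <- pracma::trapz(out$x[out$x >= 1600 & out$x <= 1700],
                        out$y[out$x >= 1600 & out$x <= 1700])
  expect_equal(area, 1, tolerance = 0.005)

  expect_error(preprocess(xy_series(seq(1300, 1800, 1), rep(0, 501))),
               "normalization")

  # an already baseline-free unit-area spectrum passes through almost intact
  flat <- gaussian_spectrum(1650, 1.0, 8)
  out2 <- preprocess(flat)
  mid <- flat$x > 1320 & flat$x < 1780
  expect_equal(out2$y[mid], flat$y[mid], tolerance = 5e-3)
})

test_that("Savitzky-Golay second derivative matches analytic oracles", {
  x <- seq(1300, 1800, 1)
  # straight line: second derivative vanishes
  line <- xy_series(x, 0.2 + 3e-4 * x)
  d2 <- second_derivative(line)
  expect_lt(max(abs(d2$y)), 1e-9)

  # single Gaussian: global minimum at the center
  g1 <- gaussian_spectrum(1650, 1, 8)
  d2 <- second_derivative(g1)
  expect_lt(abs(d2$x[which.min(d2$y)] - 1650), 1)
  # and the filter output tracks the analytic second derivative
  # (a 15-point cubic window over sigma = 8 leaves a few-percent wing error)
  ref <- oracle_gauss_d2(d2$x, 1, 1650, 8)
  expect_equal(d2$y, ref, tolerance = 0.05 * max(abs(ref)))

  # two Gaussians: two minima, each near a center
  g2 <- gaussian_spectrum(c(1653, 1684), c(0.6, 0.4), c(8, 8))
  d2 <- second_derivative(g2)
  centers <- locate_bands(d2)
  expect_length(centers, 2)
  expect_lt(abs(centers[1] - 1684), 1.5)
  expect_lt(abs(centers[2] - 1653), 1.5)

  expect_error(second_derivative(xy_series(1:8, rnorm(8))), "fewer points")
  expect_error(second_derivative(g1, window_points = 14), "odd")
})

test_that("locate_bands finds the lipid-free +2-type triplet and handles edge cases", {
  ms <- make_spectrum(spectrum_recipe(
    data.frame(center = c(1691, 1666, 1622), sigma = 7, gamma = 3,
               area = c(0.20, 0.34, 0.46)), noise_frac = 0))
  centers <- locate_bands(second_derivative(ms$spectrum))
  expect_length(centers, 3)
  expect_lt(abs(centers[1] - 1691), 2)
  expect_lt(abs(centers[2] - 1666), 2)
  expect_lt(abs(centers[3] - 1622), 2)
  # descending order is part of the contract
  expect_true(all(diff(centers) < 0))

  flat <- xy_series(seq(1300, 1800, 1), rep(0, 501))
  expect_length(locate_bands(second_derivative(flat)), 0)

  one <- gaussian_spectrum(1650, 1, 8)
  expect_length(locate_bands(second_derivative(one)), 1)
})

test_that("two-stage Voigt fit recovers noiseless band parameters", {
  x <- seq(1300, 1800, 1)
  truth <- data.frame(center = c(1653, 1684), sigma = c(7, 7),
                      gamma = c(3, 3), area = c(0.6, 0.4))
  y <- truth$area[1] * voigt_profile(x, 1653, 7, 3) +
       truth$area[2] * voigt_profile(x, 1684, 7, 3)
  spec <- xy_series(x, y)
  fit <- fit_amide_region(spec, init_centers = c(1653, 1684))
  got <- fit$bands[order(fit$bands$center), ]
  expect_equal(got$area, c(0.6, 0.4), tolerance = 0.01)
  expect_equal(got$center, c(1653, 1684), tolerance = 0.1)
  expect_lt(fit$chi2, 1e-8)

  # single-band spectrum with exact init: essentially zero residual
  y1 <- 0.5 * voigt_profile(x, 1650, 6, 2)
  f1 <- fit_amide_region(xy_series(x, y1), 1650)
  expect_lt(f1$chi2, 1e-12)
})

test_that("fit recovers centers of a noisy lipid-bound five-component fixture", {
  ms <- make_spectrum("pep5_pc", seed = 42)
  pp <- preprocess(ms$spectrum)
  centers <- locate_bands(second_derivative(pp))
  fit <- fit_amide_region(pp, centers)
  truth_centers <- c(1730, 1684, 1653)
  for (tc in truth_centers) {
    expect_lt(min(abs(fit$bands$center - tc)), 2,
              label = paste("recovered center near", tc))
  }
})

test_that("band assignment follows the wavenumber catalogue and the aggregation pair rule", {
  expect_equal(assign_band(1653, c(1730, 1684, 1653), lipid_free = FALSE),
               "alpha_helix")
  # simultaneous 1680 + 1618 without lipid: intermolecular aggregation
  expect_equal(assign_band(1680, c(1680, 1647, 1618), lipid_free = TRUE),
               "aggregation")
  expect_equal(assign_band(1618, c(1680, 1647, 1618), lipid_free = TRUE),
               "aggregation")
  # 1684 with no low-frequency partner: beta-sheet or turns
  expect_equal(assign_band(1684, c(1684, 1653), lipid_free = FALSE),
               "beta_sheet_or_turns")
  # the same high band in a lipid-bound cohort is never aggregation
  expect_equal(assign_band(1680, c(1680, 1646, 1618), lipid_free = FALSE),
               "beta_sheet_or_turns")
  expect_equal(assign_band(1691, 1691), "beta_sheet")
  expect_equal(assign_band(1622, 1622), "beta_sheet")
  expect_equal(assign_band(1666, 1666), "turns")
  expect_equal(assign_band(1647, 1647), "unordered")
  expect_equal(assign_band(1730, 1730), "lipid_CO")
  expect_equal(assign_band(1540, 1540), "amide_II")
  expect_equal(assign_band(1575, 1575), "side_chain_his")
  expect_equal(assign_band(1527, 1527), "side_chain_lys")
  expect_error(assign_band(1600, 1600), "nearest")
  expect_error(assign_band(1400, 1400), "range")
})

test_that("structure summaries aggregate areas, round to 100 and report the C=O ratio", {
  # two equal bands, one alpha one beta
  b <- data.frame(center = c(1653, 1622), sigma = 7, gamma = 3,
                  area = c(0.5, 0.5))
  rep <- summarize_structure(b, c("alpha_helix", "beta_sheet"))
  expect_equal(unname(rep$fractions[c("alpha_helix", "beta_sheet")]), c(50L, 50L))

  # split beta-sheet pair summed before rounding
  b <- data.frame(center = c(1691, 1666, 1622), sigma = 7, gamma = 3,
                  area = c(0.20, 0.34, 0.46))
  rep <- summarize_structure(b, c("beta_sheet", "turns", "beta_sheet"))
  expect_equal(unname(rep$fractions["beta_sheet"]), 66L)
  expect_equal(unname(rep$fractions["turns"]), 34L)

  # lipid carbonyl excluded from the amide total, reported as a ratio
  b <- data.frame(center = c(1730, 1653), sigma = 7, gamma = 3,
                  area = c(0.22, 0.78))
  rep <- summarize_structure(b, c("lipid_CO", "alpha_helix"))
  expect_equal(rep$co_ratio, 22)
  expect_equal(unname(rep$fractions["alpha_helix"]), 100L)

  expect_error(summarize_structure(
    data.frame(center = 1730, sigma = 7, gamma = 3, area = 1), "lipid_CO"),
    "zero amide")
})

test_that("rounded fractions always total 100 (largest remainder)", {
  for (seed in 1:10) {
    set.seed(seed)
    n <- sample(2:5, 1)
    areas <- runif(n, 0.05, 1)
    b <- data.frame(center = seq(1650, by = -9, length.out = n),
                    sigma = 7, gamma = 3, area = areas)
    cls <- sample(c("alpha_helix", "turns", "unordered", "beta_sheet",
                    "beta_sheet_or_turns"), n)
    rep <- summarize_structure(b, cls)
    expect_identical(sum(rep$fractions), 100L)
  }
})

test_that("fitted component areas conserve the window area on noiseless input", {
  ms <- make_spectrum(spectrum_recipe(
    data.frame(center = c(1684, 1653), sigma = 7, gamma = 3,
               area = c(0.36, 0.64)), noise_frac = 0))
  pp <- preprocess(ms$spectrum)
  fit <- fit_amide_region(pp, locate_bands(second_derivative(pp)))
  win_area <- pracma::trapz(fit$fitted$x, pp$y[pp$x >= min(fit$fitted$x) &
                                               pp$x <= max(fit$fitted$x)])
  expect_equal(sum(fit$bands$area), win_area, tolerance = 0.02 * win_area)
})

test_that("increasing the generated lipid C=O area strictly increases the recovered ratio", {
  ratios <- vapply(c(0.1, 0.2, 0.35), function(co_area) {
    bands <- rbind(
      data.frame(center = 1653, sigma = 7, gamma = 3, area = 0.7),
      data.frame(center = 1684, sigma = 7, gamma = 3, area = 0.3),
      data.frame(center = 1730, sigma = 8, gamma = 4, area = co_area))
    ms <- make_spectrum(spectrum_recipe(bands, lipid = "PC", noise_frac = 0))
    analyze_spectrum(ms$spectrum)$co_ratio
  }, numeric(1))
  expect_true(all(diff(ratios) > 0))
})

test_that("analyze_spectrum recovers tabulated compositions end to end", {
  # lipid-free +5-type: unordered + aggregation near 50/50
  ms <- make_spectrum("pep5_free", seed = 7)
  rep <- analyze_spectrum(ms$spectrum)
  expect_lt(abs(rep$fractions[["unordered"]] - 48), 5)
  expect_lt(abs(rep$fractions[["aggregation"]] - 52), 5)

  # pure single-Gaussian alpha-helix spectrum: 100% helix
  spec <- gaussian_spectrum(1653, 1, 7)
  rep <- analyze_spectrum(spec)
  expect_identical(unname(rep$fractions["alpha_helix"]), 100L)
})
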