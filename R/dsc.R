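# DSC thermogram analysis: baseline correction, transition detection,
# enthalpy integration, titration tables.

#' DSC thermogram
#'
#' An [xy_series()] of heat flow (mW, endotherm-positive) versus temperature
#' (degrees C) carrying the sample mass and heating rate needed for
#' enthalpy integration. Traces recorded endotherm-down can be flipped with
#' `endotherm = "down"`.
#'
#' @param x temperature grid (degrees C), ascending.
#' @param y heat flow (mW).
#' @param mass_g sample (lipid) mass in grams, > 0.
#' @param rate_c_min heating rate in degrees C per minute, > 0.
#' @param ratio peptide:lipid molar ratio label, e.g. `"0:1"`, `"1:100"`.
#' @param endotherm `"up"` if endothermic peaks point up in `y`.
#' @param meta extra metadata.
#' @return an object of classes `thermogram`, `xy_series`.
#' @export
thermogram <- function(x, y, mass_g, rate_c_min, ratio = NA_character_,
                       endotherm = c("up", "down"), meta = list()) {
  endotherm <- match.arg(endotherm)
  if (!is.finite(mass_g) || mass_g <= 0) stop("mass_g must be > 0")
  if (!is.finite(rate_c_min) || rate_c_min <= 0) stop("rate_c_min must be > 0")
  if (endotherm == "down") y <- -y
  meta$mass_g <- mass_g
  meta$rate_c_min <- rate_c_min
  meta$ratio <- ratio
  ser <- xy_series(x, y, meta)
  class(ser) <- c("thermogram", class(ser))
  ser
}

#' Baseline correction of a thermogram
#'
#' Fits a baseline to the transition-free segments of the scan and
#' subtracts it. Segments are auto-detected by iterative outlier rejection
#' (points more than 2.5 robust standard deviations above the current
#' baseline are treated as peak and dropped, repeated to convergence), or
#' supplied explicitly as exclusion zones. At least 20% of the scan must
#' remain as baseline.
#'
#' @param tg a [thermogram()].
#' @param exclusion_zones `NULL` for auto-detection, or a list of
#'   `c(lo, hi)` temperature intervals to exclude from the baseline fit.
#' @param model `"linear"` (default) or `"spline"` (smoothing spline).
#' @param max_iter iteration cap for the auto-detection.
#' @return the corrected [thermogram()], `meta$baseline_model` set.
#' @export
correct_baseline <- function(tg, exclusion_zones = NULL,
                             model = c("linear", "spline"), max_iter = 30) {
  stopifnot(inherits(tg, "thermogram"))
  model <- match.arg(model)
  x <- tg$x; y <- tg$y; n <- length(x)
  if (is.null(exclusion_zones)) {
    keep <- rep(TRUE, n)
    for (it in seq_len(max_iter)) {
      fit <- stats::lm.fit(cbind(1, x[keep]), y[keep])
      base <- fit$coefficients[1] + fit$coefficients[2] * x
      r <- y - base
      s <- stats::mad(r[keep])
      if (s == 0) s <- stats::sd(r[keep])
      if (!is.finite(s) || s == 0) break
      keep_new <- r < 2.5 * s
      if (identical(keep_new, keep)) break
      keep <- keep_new
      if (mean(keep) < 0.2) break
    }
  } else {
    keep <- rep(TRUE, n)
    for (z in exclusion_zones) keep[x >= min(z) & x <= max(z)] <- FALSE
  }
  if (mean(keep) < 0.2)
    stop("no stable baseline segments (less than 20% of the scan); ",
         "supply explicit exclusion_zones")
  base <- if (model == "linear") {
    fit <- stats::lm.fit(cbind(1, x[keep]), y[keep])
    fit$coefficients[1] + fit$coefficients[2] * x
  } else {
    sp <- stats::smooth.spline(x[keep], y[keep], df = 4)
    stats::predict(sp, x)$y
  }
  out <- tg
  out$y <- y - base
  out$meta$baseline_model <- model
  out$meta$baseline_corrected <- TRUE
  out
}

# light Savitzky-Golay smoothing used only for peak *detection*
.smooth_for_detection <- function(y, n_target) {
  n <- max(5L, 2L * (n_target %/% 2L) + 1L)
  if (length(y) <= n) return(y)
  signal::sgolayfilt(y, p = 2, n = n)
}

#' Detect endothermic transitions
#'
#' Finds local maxima of the baseline-corrected heat flow. A peak is kept
#' when its prominence exceeds both `min_prominence_frac` times the largest
#' prominence and an absolute noise floor (4x the robust noise level of the
#' trace), so a featureless noise scan yields an empty list ("transition
#' abolished"). The most prominent peak is labelled `main`; the most
#' prominent smaller peak at lower temperature, if any, is labelled `pre`.
#' Peak temperatures are refined by local quadratic interpolation.
#'
#' @param tg baseline-corrected [thermogram()] (see [correct_baseline()]).
#' @param min_prominence_frac relative prominence threshold.
#' @return data.frame with columns `peak_T`, `prominence`, `half_width`
#'   (full width at half prominence, degrees C) and `role`
#'   (`"main"`/`"pre"`/`"minor"`), ascending in temperature; zero rows when
#'   nothing is detected.
#' @export
detect_transitions <- function(tg, min_prominence_frac = 0.02) {
  stopifnot(inherits(tg, "thermogram"))
  if (!isTRUE(tg$meta$baseline_corrected))
    warning("thermogram does not appear to be baseline-corrected")
  x <- tg$x
  ys <- .smooth_for_detection(tg$y, round(length(x) / 100))
  noise <- stats::mad(diff(tg$y)) / sqrt(2)
  pk <- peak_prominences(ys)
  empty <- data.frame(peak_T = numeric(), prominence = numeric(),
                      half_width = numeric(), role = character())
  if (!nrow(pk)) return(empty)
  thr <- max(min_prominence_frac * max(pk$prominence), 4 * noise)
  pk <- pk[pk$prominence >= thr, , drop = FALSE]
  if (!nrow(pk)) return(empty)
  half_width <- vapply(seq_len(nrow(pk)), function(j) {
    i <- pk$index[j]; h <- ys[i] - pk$prominence[j] / 2
    l <- i; while (l > 1 && ys[l] > h) l <- l - 1
    r <- i; while (r < length(ys) && ys[r] > h) r <- r + 1
    x[r] - x[l]
  }, numeric(1))
  peak_T <- vapply(pk$index, function(i) refine_peak(x, ys, i), numeric(1))
  out <- data.frame(peak_T = peak_T, prominence = pk$prominence,
                    half_width = half_width, role = "minor",
                    stringsAsFactors = FALSE)
  main <- which.max(out$prominence)
  out$role[main] <- "main"
  lower <- which(out$peak_T < out$peak_T[main] & out$role == "minor")
  if (length(lower)) out$role[lower[which.max(out$prominence[lower])]] <- "pre"
  out[order(out$peak_T), , drop = FALSE]
}

#' Transition enthalpy by peak integration
#'
#' Integrates the baseline-corrected excess heat flow over the peak and
#' converts to J per gram of lipid:
#' \deqn{\Delta H = \frac{1}{1000\, m}\int \frac{P(T)}{\beta}\, dT}
#' with heat flow \eqn{P} in mW, heating rate \eqn{\beta} in degrees C/s and
#' mass \eqn{m} in g. Automatic integration limits extend from the peak to
#' where the (lightly smoothed) signal falls below 1% of the peak height.
#'
#' @param tg baseline-corrected [thermogram()] with mass and rate metadata.
#' @param peak_T peak temperature (degrees C), e.g. from
#'   [detect_transitions()].
#' @param integration_limits `NULL` for automatic limits or `c(lo, hi)`
#'   in degrees C.
#' @param height_frac fraction of peak height defining the automatic limits.
#' @return enthalpy in J/g (non-negative).
#' @export
transition_enthalpy <- function(tg, peak_T, integration_limits = NULL,
                                height_frac = 0.01) {
  stopifnot(inherits(tg, "thermogram"))
  m <- tg$meta$mass_g; rate <- tg$meta$rate_c_min
  if (is.null(m) || is.null(rate)) stop("mass and heating rate metadata required")
  x <- tg$x; y <- tg$y
  if (is.null(integration_limits)) {
    ys <- .smooth_for_detection(y, round(length(x) / 100))
    i0 <- which.min(abs(x - peak_T))
    h <- ys[i0]
    if (h <= 0) return(0)
    cut <- height_frac * h
    l <- i0; while (l > 1 && ys[l] > cut) l <- l - 1
    r <- i0; while (r < length(x) && ys[r] > cut) r <- r + 1
    integration_limits <- c(x[l], x[r])
  } else {
    if (min(integration_limits) < min(x) || max(integration_limits) > max(x))
      stop("integration limits outside the scan range")
  }
  area <- trapz_range(x, y, min(integration_limits), max(integration_limits))
  # mW * degC / (degC/s) / g / 1000 = J/g
  max(area / (rate / 60) / m / 1000, 0)
}

#' Titration table across peptide:lipid ratios
#'
#' Runs the full DSC pipeline (baseline correction, transition detection,
#' enthalpy integration) on each scan and tabulates one row per scan,
#' ordered by increasing peptide fraction. When a `0:1` control is present,
#' `dTm` and `ddH` columns give changes relative to it.
#'
#' @param tgs list of [thermogram()] objects, each carrying a `ratio`.
#' @return data.frame with columns `ratio, pre_transition_T, Tm, dH,
#'   half_width` and, when a control exists, `dTm, ddH`.
#' @export
titration_report <- function(tgs) {
  stopifnot(length(tgs) >= 1)
  parse_ratio <- function(r) {
    if (is.na(r)) return(NA_real_)
    p <- as.numeric(strsplit(r, ":")[[1]])
    if (length(p) != 2 || p[2] == 0) return(NA_real_)
    p[1] / p[2]
  }
  rows <- lapply(tgs, function(tg) {
    corr <- correct_baseline(tg)
    tr <- detect_transitions(corr)
    main <- tr[tr$role == "main", , drop = FALSE]
    pre <- tr[tr$role == "pre", , drop = FALSE]
    if (nrow(main)) {
      data.frame(ratio = as.character(tg$meta$ratio),
                 pre_transition_T = if (nrow(pre)) pre$peak_T else NA_real_,
                 Tm = main$peak_T,
                 dH = transition_enthalpy(corr, main$peak_T),
                 half_width = main$half_width, stringsAsFactors = FALSE)
    } else {
      data.frame(ratio = as.character(tg$meta$ratio),
                 pre_transition_T = NA_real_, Tm = NA_real_, dH = 0,
                 half_width = NA_real_, stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  out <- out[order(vapply(out$ratio, parse_ratio, numeric(1))), , drop = FALSE]
  rownames(out) <- NULL
  ctrl <- which(out$ratio == "0:1")
  if (length(ctrl) == 1) {
    out$dTm <- out$Tm - out$Tm[ctrl]
    out$ddH <- out$dH - out$dH[ctrl]
  } else {
    warning("no 0:1 control scan; relative columns omitted")
  }
  out
}
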