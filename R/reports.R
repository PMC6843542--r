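#' Secondary-structure report
#'
#' Result of a full amide I' decomposition: integer percentage of amide I'
#' component area per structure class (summing to 100), the lipid-carbonyl
#' area ratio, the reduced chi-squared of the fit and the fitted band table.
#'
#' @param fractions named numeric vector of integer percentages over
#'   structure classes; must sum to 100 +/- 0.5.
#' @param co_ratio lipid C=O band area as percent of (C=O + amide I') area,
#'   in `[0, 100]`; `NA` when no lipid was present.
#' @param chi2 reduced chi-squared of the final fit (optional).
#' @param bands data.frame of fitted bands with columns
#'   `center, sigma, gamma, area, class` (optional).
#' @return object of class `structure_report`.
#' @export
structure_report <- function(fractions, co_ratio = NA_real_, chi2 = NA_real_,
                             bands = NULL) {
  fractions <- unlist(fractions)
  if (is.null(names(fractions)) || any(!nzchar(names(fractions))))
    stop("fractions must be named by structure class")
  if (any(fractions < 0)) stop("negative fraction")
  if (abs(sum(fractions) - 100) > 0.5)
    stop("amide I' fractions must sum to 100 +/- 0.5, got ", sum(fractions))
  if (!is.na(co_ratio) && (co_ratio < 0 || co_ratio > 100))
    stop("co_ratio must lie in [0, 100]")
  structure(list(fractions = fractions, co_ratio = co_ratio,
                 chi2 = chi2, bands = bands),
            class = "structure_report")
}

#' @export
print.structure_report <- function(x, ...) {
  cat("<structure_report>\n")
  for (nm in names(x$fractions))
    cat(sprintf("  %-22s %3d %%\n", nm, as.integer(round(x$fractions[[nm]]))))
  if (!is.na(x$co_ratio))
    cat(sprintf("  C=O / total area       %.1f %%\n", x$co_ratio))
  if (!is.na(x$chi2)) cat(sprintf("  reduced chi2           %.3g\n", x$chi2))
  invisible(x)
}

#' Phase-transition report
#'
#' One DSC scan summarised: optional pre-transition temperature, main
#' transition temperature Tm (peak maximum), transition enthalpy in J/g of
#' lipid, and the width of the main peak at half height.
#'
#' @param Tm main-transition peak temperature (degrees C).
#' @param dH transition enthalpy (J/g), >= 0.
#' @param pre_transition_T pre-transition peak temperature (degrees C) or `NA`.
#' @param peak_width_at_half_height width of the main peak (degrees C) or `NA`.
#' @param baseline_model descriptor of the baseline removed (e.g. "linear").
#' @return object of class `transition_report`.
#' @export
transition_report <- function(Tm, dH, pre_transition_T = NA_real_,
                              peak_width_at_half_height = NA_real_,
                              baseline_model = "linear") {
  if (!is.finite(Tm)) stop("Tm must be finite")
  if (!is.finite(dH) || dH < 0) stop("dH must be >= 0")
  if (!is.na(pre_transition_T) && pre_transition_T >= Tm)
    stop("pre-transition temperature must be below Tm")
  structure(list(pre_transition_T = pre_transition_T, Tm = Tm, dH = dH,
                 peak_width_at_half_height = peak_width_at_half_height,
                 baseline_model = baseline_model),
            class = "transition_report")
}

#' @export
print.transition_report <- function(x, ...) {
  cat("<transition_report>\n")
  if (!is.na(x$pre_transition_T))
    cat(sprintf("  pre-transition  %.2f C\n", x$pre_transition_T))
  cat(sprintf("  Tm              %.2f C\n", x$Tm))
  cat(sprintf("  dH              %.3f J/g\n", x$dH))
  invisible(x)
}

#' Write a report to JSON / read it back
#'
#' Round-trips are exact for integers and within 1e-9 for floating point
#' (values are written at full precision).
#'
#' @param report a [structure_report()] or [transition_report()].
#' @param path output path (JSON).
#' @return `write_report` invisibly returns `path`; `read_report` returns
#'   the reconstructed, re-validated report object.
#' @export
write_report <- function(report, path) {
  if (inherits(report, "structure_report")) {
    payload <- list(type = "structure_report",
                    fractions = as.list(report$fractions),
                    co_ratio = report$co_ratio, chi2 = report$chi2,
                    bands = report$bands)
  } else if (inherits(report, "transition_report")) {
    payload <- c(list(type = "transition_report"), unclass(report))
  } else stop("not a report object")
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       na = "null", dataframe = "columns")
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  to_na <- function(v) if (is.null(v)) NA_real_ else as.numeric(v)
  if (identical(p$type, "structure_report")) {
    bands <- if (!is.null(p$bands) && length(p$bands)) as.data.frame(p$bands) else NULL
    structure_report(unlist(p$fractions), to_na(p$co_ratio), to_na(p$chi2), bands)
  } else if (identical(p$type, "transition_report")) {
    transition_report(to_na(p$Tm), to_na(p$dH), to_na(p$pre_transition_T),
                      to_na(p$peak_width_at_half_height),
                      if (is.null(p$baseline_model)) "linear" else p$baseline_model)
  } else stop("unknown report type in ", path)
}
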