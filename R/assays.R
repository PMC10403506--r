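# Spectroscopic assay calculations: standard curves, loading efficiency
# for a hydrophobic dye, and release efficiency for a self-quenching
# hydrophilic dye.

#' Fit a linear standard curve
#'
#' Ordinary least-squares line through concentration/response pairs; the
#' dynamic range is the span of fitted responses, and later predictions
#' outside it are flagged rather than refused.
#'
#' @param concentrations Non-negative concentrations (µM or mM), at least 3,
#'   not all equal.
#' @param responses Instrument responses (absorbance or fluorescence, AU).
#' @return Object of class `standard_curve`: `slope`, `intercept`,
#'   `r_squared`, `dynamic_range` (`c(min, max)` fitted response), `data`.
#' @export
fit_standard_curve <- function(concentrations, responses) {
  if (length(concentrations) < 3 ||
      length(concentrations) != length(responses)) {
    stop("invalid input: need at least 3 concentration/response pairs",
         call. = FALSE)
  }
  if (any(concentrations < 0)) {
    stop("invalid input: concentrations must be non-negative", call. = FALSE)
  }
  if (stats::sd(concentrations) == 0) {
    stop("invalid input: degenerate concentrations", call. = FALSE)
  }
  fit <- stats::lm(responses ~ concentrations)
  cf <- stats::coef(fit)
  if (cf[["concentrations"]] <= 0) {
    warning("standard-curve slope is not positive")
  }
  structure(list(slope = cf[["concentrations"]],
                 intercept = cf[["(Intercept)"]],
                 r_squared = .r_squared(fit, responses),
                 dynamic_range = range(stats::fitted(fit)),
                 data = data.frame(concentration = concentrations,
                                   response = responses)),
            class = "standard_curve")
}

#' @export
print.standard_curve <- function(x, ...) {
  cat(sprintf(
    "<standard_curve> response = %.4g + %.4g * conc (R^2 = %.5f)\n",
    x$intercept, x$slope, x$r_squared))
  cat(sprintf("  dynamic range: [%.4g, %.4g] AU\n",
              x$dynamic_range[1], x$dynamic_range[2]))
  invisible(x)
}

#' Invert a standard curve
#'
#' Maps responses back to concentrations as
#' `(response - intercept) / slope`. Responses outside the curve's dynamic
#' range (e.g. a sample whose signal falls below the fitted span) are still
#' converted but flagged out of range.
#'
#' @param curve A [fit_standard_curve()] result.
#' @param response Response value(s) (AU).
#' @return Data frame with `response`, `concentration`, `out_of_range`.
#' @export
concentration_from_response <- function(curve, response) {
  stopifnot(inherits(curve, "standard_curve"))
  if (!is.finite(curve$slope) || curve$slope == 0) {
    stop("invalid curve: zero slope", call. = FALSE)
  }
  data.frame(
    response = response,
    concentration = (response - curve$intercept) / curve$slope,
    out_of_range = response < curve$dynamic_range[1] |
      response > curve$dynamic_range[2])
}

#' Loading efficiency of a hydrophobic cargo
#'
#' With `C0` the total dye put through the device and `Cf` the unencapsulated
#' dye recovered in the pellet, the fraction retained by the particles is
#' `100 * (C0 - Cf) / C0` percent. A pellet concentration exceeding the
#' input (`Cf > C0`) is physically impossible and is clamped to 0% with a
#' warning and a `clamped` attribute.
#'
#' @param C0 Initial total dye concentration (> 0).
#' @param Cf_unencapsulated Unencapsulated (pellet-derived) concentration,
#'   same units, non-negative.
#' @return Percentage in \[0, 100\] with attribute `clamped`.
#' @export
#' @examples
#' loading_efficiency(10, 5)  # 50
loading_efficiency <- function(C0, Cf_unencapsulated) {
  if (!.is_scalar_num(C0) || C0 <= 0) stop("C0 must be positive", call. = FALSE)
  if (!.is_scalar_num(Cf_unencapsulated) || Cf_unencapsulated < 0) {
    stop("Cf must be non-negative", call. = FALSE)
  }
  eff <- 100 * (C0 - Cf_unencapsulated) / C0
  clamped <- FALSE
  if (eff < 0) {
    warning("Cf exceeds C0; loading efficiency clamped to 0%")
    eff <- 0
    clamped <- TRUE
  }
  structure(eff, clamped = clamped)
}

#' Construct a dye-release time course
#'
#' @param times Times (minutes), strictly increasing.
#' @param fluorescence Fluorescence readings (AU), same length.
#' @param F0 Initial fluorescence; defaults to the first reading.
#' @param F_triton Post-surfactant full-release fluorescence; defaults to
#'   the final reading. A value at or below `F0` is flagged with a warning
#'   (release efficiency is then undefined).
#' @return Object of class `release_trace`.
#' @export
release_trace <- function(times, fluorescence, F0 = NULL, F_triton = NULL) {
  if (length(times) != length(fluorescence) || length(times) < 2) {
    stop("invalid input: need matching times and fluorescence", call. = FALSE)
  }
  if (any(diff(times) <= 0)) {
    stop("invalid input: times must be strictly increasing", call. = FALSE)
  }
  if (is.null(F0)) F0 <- fluorescence[1]
  if (is.null(F_triton)) F_triton <- fluorescence[length(fluorescence)]
  if (F_triton <= F0) {
    warning("F_triton does not exceed F0; release efficiency undefined")
  }
  structure(list(times = as.numeric(times),
                 fluorescence = as.numeric(fluorescence),
                 F0 = F0, F_triton = F_triton),
            class = "release_trace")
}

#' Release efficiency at a time point
#'
#' For a self-quenching dye the fluorescence before surfactant lysis tracks
#' released (diluted) dye; comparing against the post-surfactant plateau
#' gives `100 * (F(t) - F0) / (F_triton - F0)` percent, with `F(t)` linearly
#' interpolated between samples. The result is clamped to \[0, 100\].
#'
#' @param trace A [release_trace()].
#' @param t Time(s) in minutes within the sampled range.
#' @return Percentage(s) in \[0, 100\].
#' @export
release_efficiency <- function(trace, t) {
  stopifnot(inherits(trace, "release_trace"))
  if (trace$F_triton <= trace$F0) {
    stop("undefined release: F_triton must exceed F0", call. = FALSE)
  }
  Ft <- stats::approx(trace$times, trace$fluorescence, xout = t,
                      rule = 2)$y
  pmin(pmax(100 * (Ft - trace$F0) / (trace$F_triton - trace$F0), 0), 100)
}
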