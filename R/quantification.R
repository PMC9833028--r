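# Calibration, QC and standard-curve quantification.
#
# The camera's intensity response is not linear in OD, so each chip unit
# carries a calibration curve mapping inverse blue intensity to OD, built
# from droplets of known OD. Readings below the negative-control threshold
# are excluded, calibrated ODs are regressed linearly on concentration,
# and the limit of detection follows the ICH-style 3.3 * sigma / slope
# rule.

#' Fit a per-unit calibration curve
#'
#' Isotonic regression of OD on inverse blue intensity followed by
#' piecewise-linear interpolation through the regressed knots: monotone by
#' construction and assumption-light. If the raw pairs deviate from
#' monotonicity by more than `tol`, a warning reports how much the
#' isotonic step had to adjust them.
#'
#' @param inv_b Inverse blue intensities (>= 3 distinct values).
#' @param od Matching optical densities.
#' @param unit Chip unit id the curve belongs to.
#' @param tol Tolerated non-monotonicity (max |adjustment| in OD) before
#'   warning.
#' @return An object of class `calibration_curve` with the knots and the
#'   valid `inv_b` range.
#' @export
fit_calibration <- function(inv_b, od, unit = 1, tol = 1e-8) {
  stopifnot(length(inv_b) == length(od))
  if (length(inv_b) < 3) {
    stop("need at least 3 (inv_b, OD) pairs to fit a calibration curve")
  }
  if (anyDuplicated(inv_b)) stop("inv_b values must be distinct")
  ord <- order(inv_b)
  x <- inv_b[ord]; y <- od[ord]
  iso <- stats::isoreg(x, y)
  adj <- max(abs(iso$yf - y))
  if (adj > tol) {
    warning(sprintf(
      "calibration pairs for unit %s are non-monotone; isotonic step moved OD by up to %.4g",
      unit, adj))
  }
  structure(list(unit = unit,
                 knots = data.frame(inv_b = x, od = iso$yf),
                 range = range(x)),
            class = "calibration_curve")
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf("<calibration_curve> unit %s: %d knots, inv_b in [%g, %g], OD in [%g, %g]\n",
              x$unit, nrow(x$knots), x$range[1], x$range[2],
              min(x$knots$od), max(x$knots$od)))
  invisible(x)
}

#' Convert inverse blue intensity to OD
#'
#' Piecewise-linear interpolation through the calibration knots. Inputs
#' outside the fitted range are clamped to the end knots (with a warning):
#' the curve never extrapolates beyond its evidence.
#'
#' @param curve A [fit_calibration()] result.
#' @param inv_b Inverse blue intensities (vectorized).
#' @return Optical densities.
#' @export
apply_calibration <- function(curve, inv_b) {
  stopifnot(inherits(curve, "calibration_curve"))
  out_of_range <- inv_b < curve$range[1] | inv_b > curve$range[2]
  if (any(out_of_range)) {
    warning(sum(out_of_range),
            " inv_b value(s) outside the calibrated range; clamped")
  }
  stats::approx(curve$knots$inv_b, curve$knots$od, xout = inv_b,
                rule = 2, ties = "ordered")$y
}

#' QC exclusion rule
#'
#' Readings with inverse blue intensity strictly below the threshold are
#' indistinguishable from the negative control and are excluded.
#'
#' @param inv_b_threshold Threshold on the 0-255 inverse-blue scale
#'   (default 140).
#' @return An object of class `qc_rule`.
#' @export
qc_rule <- function(inv_b_threshold = 140) {
  stopifnot(inv_b_threshold >= 0, inv_b_threshold <= 255)
  structure(list(inv_b_threshold = inv_b_threshold), class = "qc_rule")
}

#' Partition readings by the QC rule
#'
#' A reading is excluded iff `inv_b < threshold` (strict). Row order is
#' preserved within both partitions.
#'
#' @param readings Data frame with an `inv_b` column.
#' @param rule A [qc_rule()].
#' @return A list with data frames `kept` and `excluded`.
#' @export
qc_filter <- function(readings, rule = qc_rule()) {
  stopifnot(inherits(rule, "qc_rule"))
  if (nrow(readings) == 0) {
    return(list(kept = readings, excluded = readings))
  }
  drop <- readings$inv_b < rule$inv_b_threshold
  list(kept = readings[!drop, , drop = FALSE],
       excluded = readings[drop, , drop = FALSE])
}

#' Fit a linear standard curve
#'
#' Ordinary least squares of OD on concentration:
#' `OD = slope * conc + intercept`, with the residual standard deviation
#' on n - 2 degrees of freedom.
#'
#' @param concentrations Analyte concentrations (>= 2 distinct).
#' @param ods Matching optical densities.
#' @return An object of class `standard_curve` with `slope`, `intercept`,
#'   `residual_sd`, `r_squared`, `slope_se`, `conc_range`, `n`.
#' @export
fit_standard_curve <- function(concentrations, ods) {
  stopifnot(length(concentrations) == length(ods))
  if (length(unique(concentrations)) < 2) {
    stop("need at least 2 distinct concentrations")
  }
  fit <- stats::lm(ods ~ concentrations)
  # summary.lm warns on exactly collinear (perfect) fits; those are fine
  sm <- suppressWarnings(summary(fit))
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 residual_sd = sm$sigma,
                 r_squared = sm$r.squared,
                 slope_se = sm$coefficients[2, 2],
                 conc_range = range(concentrations),
                 n = length(ods)),
            class = "standard_curve")
}

#' @export
print.standard_curve <- function(x, ...) {
  cat(sprintf(
    "<standard_curve> OD = %.4g * conc + %.4g (R^2 = %.4f, sd = %.4g, n = %d)\n",
    x$slope, x$intercept, x$r_squared, x$residual_sd, x$n))
  invisible(x)
}

#' Limit of detection from a standard curve
#'
#' `LOD = 3.3 * sd(blank ODs) / slope` (ICH-style signal-to-slope rule,
#' tagged `"3.3sigma_slope"`).
#'
#' @param curve A [fit_standard_curve()] result with positive slope.
#' @param blank_ods ODs of >= 2 blank (zero-analyte) replicates.
#' @return An object of class `lod_estimate` with `lod`, `method`,
#'   `blank_mean`, `blank_sd`, `slope`.
#' @export
compute_lod <- function(curve, blank_ods) {
  stopifnot(inherits(curve, "standard_curve"))
  if (!(curve$slope > 0)) {
    stop("standard curve slope must be > 0 to compute an LOD")
  }
  if (length(blank_ods) < 2) stop("need at least 2 blank replicates")
  bsd <- stats::sd(blank_ods)
  structure(list(lod = 3.3 * bsd / curve$slope,
                 method = "3.3sigma_slope",
                 blank_mean = mean(blank_ods), blank_sd = bsd,
                 slope = curve$slope),
            class = "lod_estimate")
}

#' @export
print.lod_estimate <- function(x, ...) {
  cat(sprintf("<lod_estimate> LOD = %.4g (%s; blank sd %.4g, slope %.4g)\n",
              x$lod, x$method, x$blank_sd, x$slope))
  invisible(x)
}

# -- end-to-end image pipeline ---------------------------------------------

# single-well mini layout used to render individual droplets cheaply
single_well_layout <- function() {
  w <- microwell(1, c(10, 10), 7, 50, observation_window = TRUE)
  w2 <- microwell(2, c(10, 3), 4, 10)
  ch <- microchannel(c(1, 2), 1.3)
  chip_layout(list(chip_unit(1, list(w, w2),
                             list(ch),
                             stats::setNames(c(1L, 2L), c("1", "2")),
                             origin = c(0, 0), size = c(20, 20))),
              footprint = c(20, 20))
}

#' Render a droplet of known OD and read back its inverse blue intensity
#'
#' Convenience wrapper around [render_chip()] and [droplet_reading()] on a
#' single-well layout; the workhorse of calibration construction and
#' pipeline tests.
#'
#' @param od Optical densities (vectorized).
#' @param volume_ul Droplet volume in uL.
#' @param illumination Passed to [render_chip()].
#' @param seed Base RNG seed; element i uses `seed + i`.
#' @return Numeric vector of inverse blue intensities.
#' @export
rendered_inv_b <- function(od, volume_ul = 50, illumination = list(),
                           seed = 1) {
  layout <- single_well_layout()
  vapply(seq_along(od), function(i) {
    dr <- data.frame(unit = 1, well = 1, od = od[i],
                     volume_ul = volume_ul)
    fr <- render_chip(dr, layout, illumination, seed = seed + i,
                      px_per_mm = 2)
    droplet_reading(fr, fr$rois[[1]])$inv_b
  }, numeric(1))
}

#' Build a calibration curve from rendered droplets of known OD
#'
#' Emulates the bench procedure of imaging developed droplets of known
#' optical densities: renders each knot OD noise-free, reads its inverse
#' blue intensity and fits the monotone calibration.
#'
#' @param od_knots Known ODs (>= 3, strictly increasing recommended).
#' @param unit Chip unit id recorded on the curve.
#' @param illumination Renderer settings (noise is forced off for knots).
#' @return A [fit_calibration()] result.
#' @export
calibration_from_renders <- function(od_knots = seq(0, 2, by = 0.1),
                                     unit = 1, illumination = list()) {
  il <- utils::modifyList(illumination, list(noise_sd = 0))
  inv_b <- rendered_inv_b(od_knots, illumination = il)
  fit_calibration(inv_b, od_knots, unit = unit)
}

#' Quantify a synthetic standard-curve dataset through the image pipeline
#'
#' The full simulate -> render -> read -> calibrate -> fit -> LOD chain:
#' each replicate droplet is rendered at its noisy OD, read back as
#' inverse blue intensity, converted to OD through the calibration curve,
#' optionally QC-filtered, and the calibrated ODs are regressed on
#' concentration to yield the standard curve and LOD.
#'
#' @param dataset A [generate_standard_curve_dataset()] result.
#' @param calibration A [fit_calibration()] curve (one is built from
#'   renders when NULL).
#' @param illumination Renderer settings for the replicate droplets.
#' @param qc A [qc_rule()], or NULL to skip QC filtering.
#' @param seed Base seed for render sensor noise.
#' @return A list with `readings` (per-droplet data frame), `curve`
#'   ([fit_standard_curve()]), `lod` ([compute_lod()]), `calibration` and
#'   `excluded`.
#' @export
quantify_dataset <- function(dataset, calibration = NULL,
                             illumination = list(), qc = NULL, seed = 1) {
  if (is.null(calibration)) {
    max_od <- max(dataset$od_noisy) * 1.1
    calibration <- calibration_from_renders(
      seq(0, max(max_od, 0.5), length.out = 21),
      illumination = illumination)
  }
  inv_b <- rendered_inv_b(dataset$od_noisy, illumination = illumination,
                          seed = seed)
  readings <- data.frame(concentration = dataset$concentration,
                         replicate = dataset$replicate,
                         unit = dataset$unit,
                         inv_b = inv_b,
                         od = apply_calibration(calibration, inv_b))
  excluded <- readings[0, , drop = FALSE]
  if (!is.null(qc)) {
    parts <- qc_filter(readings, qc)
    readings <- parts$kept
    excluded <- parts$excluded
  }
  curve <- fit_standard_curve(readings$concentration, readings$od)
  blanks <- readings$od[readings$concentration == 0]
  lod <- if (length(blanks) >= 2 && curve$slope > 0) {
    compute_lod(curve, blanks)
  } else {
    NULL
  }
  list(readings = readings, curve = curve, lod = lod,
       calibration = calibration, excluded = excluded)
}
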