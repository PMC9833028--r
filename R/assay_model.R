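# Synthetic bead-based sandwich-ELISA signal model.
#
# Stand-in data generator for the capture-antibody / analyte /
# enzyme-labelled detection antibody sandwich formed on magnetic beads:
# equilibrium Langmuir binding, linear chromogen development, Gaussian
# replicate noise. Everything downstream (rendering, calibration, standard
# curves, LOD) is exercised against data from this module, so recovery of
# its generating parameters is the pipeline's testable ground truth.

#' Assay signal-model parameters
#'
#' @param k_half Half-saturation analyte concentration (same units as the
#'   analyte concentrations fed to [simulate_binding()]).
#' @param capacity Maximum bound amount per bead population (arbitrary
#'   mass units).
#' @param dev_rate OD produced per bound-enzyme amount per minute of
#'   development.
#' @param dev_time Development time, minutes.
#' @param noise_sd Gaussian OD standard deviation per replicate.
#' @param blank_od_mean Mean OD of a blank (zero-analyte) droplet.
#' @return A list of class `assay_params`.
#' @export
assay_params <- function(k_half = 10, capacity = 1, dev_rate = 0.4,
                         dev_time = 5, noise_sd = 0.02,
                         blank_od_mean = 0.05) {
  stopifnot(k_half > 0, capacity >= 0, dev_rate >= 0, dev_time >= 0,
            noise_sd >= 0, blank_od_mean >= 0)
  structure(list(k_half = k_half, capacity = capacity, dev_rate = dev_rate,
                 dev_time = dev_time, noise_sd = noise_sd,
                 blank_od_mean = blank_od_mean),
            class = "assay_params")
}

#' Equilibrium binding on the bead surface
#'
#' Langmuir isotherm: `bound = capacity * conc / (conc + k_half)`.
#' Monotone and saturating; half the capacity is bound at `conc = k_half`.
#'
#' @param conc Analyte concentration (>= 0, vectorized).
#' @param params [assay_params()].
#' @return Bound amount (same length as `conc`).
#' @export
simulate_binding <- function(conc, params = assay_params()) {
  if (any(conc < 0)) stop("concentration must be >= 0")
  params$capacity * conc / (conc + params$k_half)
}

#' Chromogen development
#'
#' `OD = blank_od_mean + dev_rate * dev_time * bound * retention`:
#' linear in the bound-enzyme amount, scaled by the fraction of beads that
#' survived the transfers into the development droplet.
#'
#' @param bound Bound amount from [simulate_binding()].
#' @param retention Bead retention fraction in [0, 1].
#' @param params [assay_params()].
#' @return Optical density (unitless).
#' @export
simulate_development <- function(bound, retention = 1,
                                 params = assay_params()) {
  if (any(bound < 0) || any(retention < 0)) stop("inputs must be >= 0")
  params$blank_od_mean +
    params$dev_rate * params$dev_time * bound * retention
}

#' Small-signal slope of the synthetic assay
#'
#' The OD-per-concentration slope of the model in its linear regime
#' (`conc << k_half`): `dev_rate * dev_time * capacity * retention /
#' k_half`. This is the ground truth a fitted standard curve should
#' recover on low-concentration data.
#'
#' @param params [assay_params()].
#' @param retention Bead retention fraction.
#' @return Slope in OD per concentration unit.
#' @export
assay_linear_slope <- function(params = assay_params(), retention = 1) {
  params$dev_rate * params$dev_time * params$capacity * retention /
    params$k_half
}

#' Generate a synthetic standard-curve dataset
#'
#' One row per (concentration, replicate): the noiseless model OD and a
#' noisy replicate OD (`true + N(0, noise_sd)`). Blank rows at
#' concentration 0 are always included. Replicates are assigned
#' round-robin to chip units 1-4. Reproducible for a given seed.
#'
#' @param concentrations Numeric vector of analyte concentrations (>= 2
#'   distinct values; 0 is appended if absent).
#' @param replicates Replicates per concentration (>= 1).
#' @param params [assay_params()].
#' @param seed Integer RNG seed.
#' @param retention Bead retention fraction applied to every droplet.
#' @return A data frame of class `standard_curve_dataset` with columns
#'   `concentration`, `replicate`, `unit`, `od_true`, `od_noisy`.
#' @export
generate_standard_curve_dataset <- function(concentrations, replicates = 3,
                                            params = assay_params(),
                                            seed = 1, retention = 1) {
  concentrations <- sort(unique(as.numeric(concentrations)))
  if (!(0 %in% concentrations)) concentrations <- c(0, concentrations)
  if (length(concentrations) < 2) {
    stop("need at least 2 distinct concentrations")
  }
  if (replicates < 1) stop("replicates must be >= 1")
  set.seed(seed)
  grid <- expand.grid(replicate = seq_len(replicates),
                      concentration = concentrations)
  grid <- grid[, c("concentration", "replicate")]
  grid$unit <- ((grid$replicate - 1L) %% 4L) + 1L
  grid$od_true <- simulate_development(
    simulate_binding(grid$concentration, params), retention, params)
  grid$od_noisy <- grid$od_true +
    stats::rnorm(nrow(grid), 0, params$noise_sd)
  grid$od_noisy <- pmax(grid$od_noisy, 0)
  class(grid) <- c("standard_curve_dataset", "data.frame")
  grid
}

#' Generate a synthetic mixing image sequence
#'
#' Frames of a merging-droplet ROI whose blue-channel mixing index decays
#' exponentially from `m_i` to `m_f` with time constant `tau` (dye
#' spreading through the droplet by stirring or diffusion): each frame's
#' ROI pixels are drawn as `round(mean_b + sd_t * z)` clipped to [0, 255],
#' with `sd_t = m_f + (m_i - m_f) exp(-t/tau)`. The first two returned
#' frames are the unmixed and fully-mixed references.
#'
#' @param tau Decay time constant, s (> 0).
#' @param times Numeric vector of frame times, s.
#' @param geometry List: `width_px`, `height_px`, ROI `radius_px`,
#'   background `bg`, droplet mean blue `mean_b`, reference indices
#'   `m_i`, `m_f`.
#' @param seed Integer RNG seed.
#' @return A list with `frames` (list of [image_frame()] at `times`),
#'   `mi_frame`, `mf_frame` (reference frames), `roi` ([circle_roi()]) and
#'   `truth` (generating parameters).
#' @export
generate_mixing_image_sequence <- function(tau, times = seq(0, 600, by = 50),
                                           geometry = list(), seed = 1) {
  if (!(tau > 0)) stop("tau must be > 0")
  g <- utils::modifyList(
    list(width_px = 64, height_px = 64, radius_px = 24, bg = 235,
         mean_b = 128, m_i = 40, m_f = 6),
    geometry)
  set.seed(seed)
  roi <- circle_roi(g$width_px / 2, g$height_px / 2, g$radius_px)
  make_frame <- function(sd_t, t) {
    px <- array(g$bg, dim = c(g$height_px, g$width_px, 3))
    idx <- roi_pixel_indices(roi, g$height_px, g$width_px)
    n <- length(idx)
    blue <- matrix(g$bg, g$height_px, g$width_px)
    blue[idx] <- pmin(255, pmax(0, round(g$mean_b +
                                           sd_t * stats::rnorm(n))))
    px[, , 1] <- g$bg
    px[, , 2] <- g$bg
    px[, , 3] <- blue
    image_frame(px, time_s = t)
  }
  frames <- lapply(times, function(t) {
    make_frame(g$m_f + (g$m_i - g$m_f) * exp(-t / tau), t)
  })
  list(frames = frames,
       mi_frame = make_frame(g$m_i, NA_real_),
       mf_frame = make_frame(g$m_f, NA_real_),
       roi = roi,
       truth = list(tau = tau, m_i = g$m_i, m_f = g$m_f,
                    mean_b = g$mean_b, times = times, seed = seed))
}
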