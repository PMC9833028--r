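# Mixing index and homogeneity kinetics.
#
# The mixing index M of a droplet image ROI is the population standard
# deviation of its blue-channel pixel intensities; homogeneity H rescales
# the current index M_c between an unmixed reference M_i (pure water
# droplet) and a fully-mixed reference M_f (vortexed dye droplet):
#     H = 1 - (M_c - M_f) / (M_i - M_f).
# Active mixing (magnet-driven stirring cycles) and passive diffusion both
# relax the residual 1 - H exponentially; the two default constants are
# calibrated so that 3 active cycles (~54 s) and ~700 s of passive
# diffusion each reach H = 0.95 from a fully unmixed start.

#' Default mixing kinetics parameters
#'
#' `rho` is the residual factor per active mixing cycle: `1 - H` is
#' multiplied by `rho` each cycle. The default `0.05^(1/3)` makes three
#' cycles reach H = 0.95. `tau` is the passive (diffusion-only) relaxation
#' time constant in seconds; the default `700 / log(20)` reaches H = 0.95
#' at 700 s. `cycle_s` is the wall-clock duration of one active cycle
#' (54 s / 3 cycles).
#'
#' @param rho Per-cycle residual factor, in (0, 1).
#' @param tau Passive relaxation time constant, s (> 0).
#' @param cycle_s Seconds per active mixing cycle.
#' @return A list of class `mixing_params`.
#' @export
mixing_params <- function(rho = 0.05^(1 / 3), tau = 700 / log(20),
                          cycle_s = 18) {
  if (!(rho > 0 && rho < 1)) stop("rho must be in (0, 1)")
  if (!(tau > 0)) stop("tau must be > 0")
  if (!(cycle_s > 0)) stop("cycle_s must be > 0")
  structure(list(rho = rho, tau = tau, cycle_s = cycle_s),
            class = "mixing_params")
}

#' Mixing index of a pixel sample
#'
#' Population standard deviation (divisor N, not N - 1) of blue-channel
#' pixel intensities within a droplet ROI.
#'
#' @param intensities Numeric vector of pixel intensities (0-255), N >= 1.
#' @return The mixing index M >= 0.
#' @export
mixing_index <- function(intensities) {
  x <- as.numeric(intensities)
  n <- length(x)
  if (n < 1L) stop("mixing_index needs at least one pixel")
  if (anyNA(x)) stop("intensities contain NA")
  sqrt(sum((x - mean(x))^2) / n)
}

#' Homogeneity from mixing indices
#'
#' `H = 1 - (M_c - M_f) / (M_i - M_f)`, clamped to [0, 1]. `M_i` and `M_f`
#' are the unmixed and fully-mixed reference indices; camera noise can push
#' `M_c` slightly outside the reference interval, hence the clamp.
#'
#' @param m_c Current mixing index.
#' @param m_i Initial (unmixed) reference index.
#' @param m_f Final (fully mixed) reference index; must differ from `m_i`.
#' @return Homogeneity H in [0, 1].
#' @export
homogeneity <- function(m_c, m_i, m_f) {
  if (m_i == m_f) {
    stop("degenerate references: M_i must differ from M_f")
  }
  h <- 1 - (m_c - m_f) / (m_i - m_f)
  pmin(1, pmax(0, h))
}

#' Advance homogeneity under active mixing
#'
#' Each cycle multiplies the unmixed residual `1 - H` by `params$rho`.
#'
#' @param h Homogeneity in [0, 1].
#' @param cycles Number of cycles (>= 0, need not be integer).
#' @param params [mixing_params()].
#' @return Updated homogeneity.
#' @export
advance_active <- function(h, cycles, params = mixing_params()) {
  stopifnot(h >= 0, h <= 1, cycles >= 0)
  1 - (1 - h) * params$rho^cycles
}

#' Advance homogeneity under passive diffusion
#'
#' The residual decays as `exp(-dt / params$tau)`.
#'
#' @param h Homogeneity in [0, 1].
#' @param dt Elapsed time, s (>= 0).
#' @param params [mixing_params()].
#' @return Updated homogeneity.
#' @export
advance_passive <- function(h, dt, params = mixing_params()) {
  stopifnot(h >= 0, h <= 1, dt >= 0)
  1 - (1 - h) * exp(-dt / params$tau)
}

#' Time (or cycles) to reach a target homogeneity
#'
#' Inverts the relaxation dynamics starting from H = 0. For active mixing
#' the answer is reported in whole cycles (ceiling, with a 1e-9 relative
#' guard against floating-point overshoot) and converted to seconds at
#' `params$cycle_s` per cycle; for passive mixing it is continuous time.
#'
#' @param target Target homogeneity H*, in [0, 1).
#' @param mode `"active"` or `"passive"`.
#' @param params [mixing_params()].
#' @return A list with `mode`, `seconds`, and for active mode `cycles`.
#' @export
time_to_homogeneity <- function(target, mode = c("active", "passive"),
                                params = mixing_params()) {
  mode <- match.arg(mode)
  if (!(target >= 0 && target < 1)) {
    stop("target homogeneity must be in [0, 1); H = 1 is unreachable")
  }
  if (target == 0) {
    return(if (mode == "active") {
      list(mode = mode, cycles = 0L, seconds = 0)
    } else {
      list(mode = mode, seconds = 0)
    })
  }
  if (mode == "active") {
    raw <- log(1 - target) / log(params$rho)
    cycles <- as.integer(ceiling(raw * (1 - 1e-9)))
    list(mode = mode, cycles = cycles,
         seconds = cycles * params$cycle_s)
  } else {
    list(mode = mode, seconds = -params$tau * log(1 - target))
  }
}

#' Fit a passive relaxation time constant to a mixing curve
#'
#' Given observed mixing indices over time, fits
#' `M(t) = M_f + (M_i - M_f) * exp(-t / tau)` by nonlinear least squares,
#' started from a log-linear regression on the early decay.
#'
#' @param time_s Numeric vector of frame times.
#' @param m_c Observed mixing indices at those times.
#' @return A list with `tau`, `m_i`, `m_f` (fitted values).
#' @export
fit_mixing_tau <- function(time_s, m_c) {
  stopifnot(length(time_s) == length(m_c), length(time_s) >= 4)
  mf0 <- min(m_c)
  mi0 <- max(m_c)
  amp <- pmax(m_c - mf0, (mi0 - mf0) * 1e-3)
  tau0 <- -1 / stats::coef(stats::lm(log(amp) ~ time_s))[["time_s"]]
  if (!is.finite(tau0) || tau0 <= 0) tau0 <- diff(range(time_s)) / 3
  fit <- stats::nls(
    m_c ~ mf + (mi - mf) * exp(-time_s / tau),
    start = list(mf = mf0, mi = mi0, tau = tau0),
    control = stats::nls.control(maxiter = 200, warnOnly = TRUE)
  )
  co <- stats::coef(fit)
  list(tau = unname(co["tau"]), m_i = unname(co["mi"]),
       m_f = unname(co["mf"]))
}
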