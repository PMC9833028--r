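# Shared fixtures, built in code at test time.

fixture_layout <- function() builtin_elisa_layout()
fixture_protocol <- function() builtin_elisa_protocol()

# independent oracle: population standard deviation by explicit two-pass loop
oracle_pop_sd <- function(x) {
  n <- length(x)
  m <- 0
  for (v in x) m <- m + v / n
  ss <- 0
  for (v in x) ss <- ss + (v - m)^2
  sqrt(ss / n)
}

# independent oracle: spherical-cap footprint via numerical slice
# integration of the cap volume, inverted with uniroot
oracle_cap_diameter <- function(volume_ul, contact_angle_deg) {
  th <- contact_angle_deg * pi / 180
  cap_volume <- function(r) {
    # sphere of radius r truncated at height h = r (1 - cos th)
    h <- r * (1 - cos(th))
    f <- function(z) pi * (r^2 - (r - z)^2)   # slice area at depth z from top
    stats::integrate(f, 0, h, rel.tol = 1e-10)$value
  }
  if (volume_ul == 0) return(0)
  r <- stats::uniroot(function(r) cap_volume(r) - volume_ul,
                      c(1e-6, 100), tol = 1e-12)$root
  if (contact_angle_deg >= 90) 2 * r else 2 * r * sin(th)
}

# least-squares slope of the generator's noiseless ODs over a design grid:
# the recoverable ground truth for standard-curve fits on Langmuir data
design_slope <- function(concentrations, params, retention = 1) {
  od <- simulate_development(simulate_binding(concentrations, params),
                             retention, params)
  unname(stats::coef(stats::lm(od ~ concentrations))[2])
}

# minimal two-well protocol with no extraction transitions: droplet passes
# through the wide 8-9 channel (small droplet), beads ride along
no_extraction_protocol <- function() {
  mdm_protocol(
    "pass-only",
    list(hold_command(magnet_position("B", 9), 20),
         move_command(magnet_position("B", 9), magnet_position("B", 8))),
    metadata = list(manifest = data.frame(
      well = 9, species = "sample", volume_ul = 10))
  )
}
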