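---
title: "Models and methods behind mdmsim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind mdmsim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mdmsim)
```

`mdmsim` is a digital twin of a magnetic digital microfluidic (MDM)
immunodiagnostic chip. On such a platform, discrete droplets sit in
recessed microwells on a superhydrophobic surface and are manipulated by
dragging a cluster of magnetic microbeads with external magnets. This
vignette explains the models the package implements, the constants they
are calibrated to, and the limits of what the synthetic data can show.

## The chip and the motion grid

The built-in chip (`builtin_elisa_layout()`) is a 60 x 60 mm plate with
four identical units run in parallel (a sample in triplicate plus a
negative control). Each unit has nine microwells in a chain joined by
eight microchannels: wells 1-7 are 6 mm / 30 uL, well 8 is 7 mm / 50 uL
and is the uncoated observation window used for imaging, and well 9 is
4 mm / 10 uL for the stop solution.

Magnet motion is discretized on two axes:

* **Keypoints 1-9**, the planar stations coinciding with well centers.
* **Layers T/N/M/B** (top, neutral, mezzanine, bottom), the vertical
  stations. At T and B the field is strong enough to collect the beads
  into a cluster at the droplet ceiling or the well floor; at M the beads
  are only partially attracted and can stir the droplet; at N the magnet
  has no effect on droplets.

A protocol is a sequence of commands over this grid: moves written
`"T1 to N5"`, plus `MIX`, `HOLD` and `INCUBATE` keyword forms. The
validator enforces the motion rules the grid implies: free planar travel
only in the neutral layer, bottom-layer traversals only along a
microchannel, vertical hops anywhere. Moves that change both layer and
keypoint are decomposed as the vertical hop first, then lateral travel in
the destination layer.

The two field strengths of the physical magnets (53 mT at the top layer,
551 mT at the bottom) are treated as documented constants; `mdmsim` does
not compute magnetostatics.

## Droplet geometry and the pass/extract rule

A droplet on the superhydrophobic coating is modelled as a spherical cap
with contact angle 150 degrees. The cap volume is
$V = \frac{\pi R^3}{3}(1-\cos\theta)^2(2+\cos\theta)$, and the footprint
reported by `droplet_footprint_diameter()` is the equatorial width $2R$
(for $\theta \ge 90^\circ$). This reproduces the platform's published
approximations: 10 uL is about 2.7 mm wide, 30 uL about 3.9 mm.

Whether a bead-dragged droplet passes a microchannel is decided by the
ratio of channel width to droplet footprint:
`PASS_DROPLET` iff $w / d \ge r_\mathrm{pass}$, with default
$r_\mathrm{pass} = 0.35$. The two documented operating points — a 1.3 mm
channel passing a ~2.5 mm droplet, and a 0.6 mm channel holding back a
~3.7 mm droplet — are reproduced by any threshold in roughly
(0.24, 0.52); 0.35 sits centrally between them. The same rule makes the
8-9 channel (1.3 mm) direction-sensitive in practice: the large
development droplet (~4.6 mm) cannot follow the beads into well 9, but
the small stop droplet (~2.7 mm) rides back through it, which is exactly
the asymmetry the workflow needs.

## Bead retention

Each extraction (a bottom traversal where the droplet is held back)
thins the bead population binomially: survivors are
$\mathrm{Binomial}(n, p_\mathrm{retain})$ with one draw per unit per
extraction, all from a single seeded generator. The built-in workflow has
exactly eight extraction transfers (wells 1 through 9), and the default
$p_\mathrm{retain} = 0.78^{1/8} \approx 0.9694$ is calibrated so the
expected overall retention matches the platform's reported ~78% at
1 mm/s. This is a calibrated constant, not a prediction, and it is
user-overridable in `engine_params()`.

Extraction also drags a fixed carry-over volume (default 0.5 uL, the
platform itself does not quantify it) with the cluster, with
proportional amounts of every dissolved species. Because carry-over is
moved rather than destroyed, total liquid volume is conserved exactly,
and the event log records every transfer so both the volume and the bead
ledgers can be audited (`total_volume()`, `retention_summary()`; the
conservation tests do exactly this audit over 100 seeded runs).

## Mixing index and homogeneity

The mixing index of a droplet image ROI is the population standard
deviation of its blue-channel pixels,
$M = \sqrt{\frac{1}{N}\sum_b (I_b - \bar I)^2}$ (divisor $N$, not
$N-1$). Homogeneity rescales the current index between an unmixed
reference $M_i$ (pure water droplet) and a fully mixed reference $M_f$
(vortexed dye droplet):

$$H = 1 - \frac{M_c - M_f}{M_i - M_f},$$

clamped to [0, 1] because camera noise can push $M_c$ slightly outside
the reference interval. $H$ is invariant under affine rescaling of all
three indices, so it does not depend on exposure or gain.

Both mixing modes relax the residual $1-H$ exponentially, which is the
dynamics any exponentially relaxing $M_c$ induces through the equation
above. Two published anchors fix the two default constants:

* **Active** (magnet stirring): $H$ exceeds 0.95 after 3 cycles
  (~54 s), so the per-cycle residual factor is
  $\rho = 0.05^{1/3} \approx 0.368$ and one cycle is budgeted 18 s
  (54 s / 3). The platform's timing does not say whether the 54 s
  includes travel overhead; the 18 s/cycle figure assumes it does.
* **Passive** (diffusion only): $H$ reaches 0.95 at ~700 s, so
  $\tau = 700 / \ln 20 \approx 233.7$ s.

`time_to_homogeneity()` inverts these; active answers are reported in
whole cycles (ceiling, with a 1e-9 relative guard so an exact boundary
like 3.0 cycles is not rounded up by floating-point noise).

## The built-in ELISA workflow

`builtin_elisa_protocol()` encodes the bead-based sandwich assay: sample
plus capture beads incubate ~15 min in well 1 with 50 embedded mixing
cycles; a 20 s bottom hold clusters the beads; the cluster is extracted
through narrow channels across washes in wells 2-3 (1 min, 3 cycles
each); detection antibody binds in well 4 (~15 min, 50 cycles); three
more washes (wells 5-7); chromogen development in well 8; extraction to
the stop droplet in well 9; and a wide-channel return that merges the
stop droplet back into well 8 for reading.

Choices the published description leaves open, fixed here once:

* **Development time** in well 8 is never stated; the default is 300 s,
  which puts the estimated end-to-end duration (2640 s ≈ 44 min) in line
  with the stated ~45 min turnaround.
* **Clustering holds**: only the first 20 s bottom hold is printed; the
  protocol applies the same 20 s hold before every transfer by analogy,
  since the engine requires a clustered population (bottom hold >= 1 s)
  before any traversal.
* **TMB load**: the platform's description gives both 40 uL and 50 uL
  for well 8 in different places; the default is 50 uL (matching the
  well's stated capacity) and it is an argument, not a constant. With
  50 uL the final merged droplet (~60 uL) nominally exceeds the well's
  capacity; the engine logs this as an `overflow_warning` event rather
  than failing, which is also a useful regression probe.
* **Embedded mixing** during an incubation does not add wall time — it
  happens within the stated incubation window. An incubation applies its
  embedded active cycles and then passive relaxation over its duration.
* **Merging** always resets homogeneity to 0 (the mixing experiments
  start from a dye droplet freshly merged into water) and sums volumes
  and species amounts; a droplet moved into an occupied well always
  merges, never bounces.

## Synthetic assay, renderer and quantification

The signal model is deliberately simple: equilibrium Langmuir binding
$b = \mathrm{capacity}\cdot c/(c + K_{1/2})$ (incubations are long and
no kinetic constants are available), linear development
$\mathrm{OD} = \mathrm{blank} + k_\mathrm{dev}\, t_\mathrm{dev}\, b\,
r$ where $r$ is bead retention, and homoscedastic Gaussian replicate
noise on OD. Defaults: $K_{1/2} = 10$ concentration units, capacity 1,
0.4 OD per bound amount per minute over 5 min, noise sd 0.02 OD, blank
OD 0.05 — numbers chosen to give a realistic ELISA dynamic range
(saturating OD ~2) and replicate scatter of a few percent.

The renderer maps OD to blue-channel intensity in Beer-Lambert fashion,
$B = L\cdot 10^{-g\,\mathrm{OD}}$ with illumination level $L = 235$ and
gain $g = 1$, so the useful OD range 0-2.4 stays inside 8-bit range. The
real camera response is unknown; this stand-in is exactly the
nonlinearity the calibration module is there to correct. Calibration is
isotonic regression of OD on inverse blue intensity ($255 - \bar B$)
followed by piecewise-linear interpolation — monotone by construction
and assumption-light, since the platform does not state its calibration
functional form (a quadratic would fit its plotted curve equally well).
Out-of-range inputs clamp to the end knots rather than extrapolate.

Readings below the negative-control threshold are excluded by a strict
`inv_b < 140` rule, read literally from the platform's QC description.
How that 140 was derived (fixed constant vs. per-run statistic) is not
stated; it is a plain parameter of `qc_rule()`. Note the threshold is
meaningful for the platform's camera; on the synthetic renderer a blank
droplet reads `inv_b` ≈ 20, so the pipeline functions default to no QC
unless a rule is passed.

Standard curves are ordinary least squares of calibrated OD on
concentration, and the limit of detection is the ICH-style
$\mathrm{LOD} = 3.3\,\sigma_\mathrm{blank}/\mathrm{slope}$ (the
platform cites a linear-regression LOD method without printing the
formula; the method tag `"3.3sigma_slope"` is recorded so a 3-sigma
variant can be compared).

### What recovery tests can and cannot show

The platform's own detection limits (0.091 ug/mL, 1.611 ng/mL,
235.561 ng/mL for its three targets) depend on instrument data shown
only in its figures and are not reproducible from a desk. The package's
headline property is instead *parameter recovery*: simulate a dataset
with known constants, push it through render → read → calibrate → fit →
LOD, and compare with ground truth. Because the binding model is
Langmuir, the recoverable truth for a standard-curve fit is the
least-squares slope of the *noiseless* generator output over the same
concentration grid (on 0-2 with $K_{1/2}=10$ that design slope is
~0.167 OD per unit, about 17% below the small-signal slope
`assay_linear_slope()` returns). The acceptance suite checks, over 100
seeded datasets, that per-seed 95% confidence intervals cover that truth
at the nominal rate, that the mean fitted slope is within 2% of it, and
that the mean pipeline LOD is within 10% of
$3.3\,\sigma_\mathrm{noise}/\mathrm{slope}$; the mixing-sequence time
constant is recovered within 5%.

What the generator does *not* emulate: droplet segmentation (ROIs are
given, as on the platform), non-uniform illumination, exposure and
white-balance variation, heteroscedastic replicate noise, bead adhesion
artifacts, and reagent chemistry. Passing tests therefore validate the
computational pipeline, not photometric realism.

## Problem sizes and numerical notes

The shipped tests and the acceptance script use sizes chosen to keep the
statistics sharp at desk scale: 1000 seeded runs of the full workflow
with 10,000 beads per unit for the retention average (3-standard-error
check against $p_\mathrm{retain}^8$), 100 runs for the conservation
audit, 100 seeded datasets with 6 concentrations x 8 replicates for the
recovery suite, mixing sequences of 16 frames of 64 x 64 px with a
~1790-pixel ROI. Renders for calibration and replicates use a 40 x 40 mm
single-well scene at 2 px/mm; sensor noise of 1 intensity step is left
on in recovery tests because it dithers the 8-bit quantization that
would otherwise floor small OD differences.

Degenerate inputs are defined errors, not silent results: empty pixel
sets, equal reference indices ($M_i = M_f$), fewer than 3 calibration
pairs, non-distinct concentrations, non-positive slopes for LOD, and
bottom traversals without a prior clustering hold all raise with named
messages, while layout/protocol *validators* return violation lists as
data so a caller can report them all at once.

## Known limitations

* The engine is event-discrete: no continuum fluid dynamics, droplet
  pinning, splitting, or magnetic force fields; per-extraction loss is a
  single calibrated probability, not a function of speed, bead load or
  channel geometry (the 1 mm/s speed enters only travel time).
* One bead population per unit; partial cluster splitting is not
  modelled.
* The renderer is photometric plumbing, not a camera model (no gamma,
  no color constancy, 8-bit only).
* Retention calibration and the mixing constants are tied to the
  published operating point; at other speeds or bead loads they are
  extrapolations the user must re-calibrate.
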