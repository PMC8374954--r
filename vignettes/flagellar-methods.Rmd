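---
title: "Models and methods behind flagellar"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind flagellar}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flagellar)
```

`flagellar` turns time series of planar sperm-flagellum centerlines into a
small set of physically interpretable quantities: shape modes, beat
frequency, a representative beat cycle, amplitude envelopes, hydrodynamic
power dissipation, a projected free-swimming velocity, and a Procrustes
measure for comparing beat patterns between groups. This vignette explains
the models, the numerical choices, and what the synthetic-data tests do and
do not demonstrate.

## The data model

The raw input is a head-tethered cell's centerline, sampled on a common
uniform arc-length grid: frame times $\tau_1 < \dots < \tau_N$ (nominally
400 frames/s), arc coordinates $s_1 = 0, \dots, s_M = L$ (default $M = 100$
points over $L = 110\,\mu m$, the length of a mouse sperm flagellum), and
$N \times M$ position matrices in micrometres. $s = 0$ is the head/neck
junction and the head point is expected to stay put to within a tether
tolerance (2 um by default; violations warn rather than fail, because
loosely tethered cells are an analyst's judgement call).

Raw tracked polylines with unequal point counts are accepted too:
`read_centerlines()` fits cubic splines against chord length, measures the
spline's arc length on a 10-fold refined grid, and interpolates positions
onto the uniform grid. A `smooth.spline` smoothing stage (`spar`) is
available for noisy tracking; the default interpolates without smoothing so
that the resampler never silently alters clean data.

## Tangent angles and shape modes

The shape of each frame is encoded as the tangent angle
$\psi(s, \tau)$ — the angle of the local tangent against the horizontal lab
axis. Derivatives use second-order three-point stencils in both $s$ and
$\tau$ (one-sided at boundaries, with per-step weights so mildly non-uniform
frame intervals are handled exactly). $\psi$ is unwrapped along arc length
within each frame; across frames the branch is anchored on the mean over
the proximal 10% of arc points. Anchoring on a single head point turned out
to be fragile — one noisy tangent estimate near $\pm\pi$ can shift an
entire frame by $2\pi$ and corrupt the decomposition — while the proximal
mean averages tracking noise down by an order of magnitude.

Proper orthogonal decomposition writes the beat as

$$\psi(s_m, \tau_n) = \psi_0(s_m) + \sum_k B_k(\tau_n)\,\psi_k(s_m),$$

with $\psi_0$ the time average, modes $\psi_k$ the right singular vectors
of the deviation matrix $X = \psi - \psi_0$ (identically, eigenvectors of
the covariance $X^T X$), and coefficients $B = X \Psi^T$. The field is
demeaned over time only; per-arc-point variance is *not* normalized, so
modes retain their radian units. SVD signs are arbitrary, so each mode's
largest-magnitude entry is made positive — a deterministic rule that makes
coefficients comparable across cells and reruns bitwise-reproducible. Full
decompositions are computed; reporting defaults to four modes, and the
first two typically dominate for planar beats. Near-degenerate singular
value pairs make the $B_1$–$B_2$ plane rotationally ambiguous; comparisons
should then lean on the reconstructed cycles rather than raw coefficients.

## Beat frequency, cycles, and the representative beat

The primary oscillation frequency (POF) is the dominant peak of the $B_1$
periodogram: de-mean, Hann-window, FFT, take the largest magnitude-squared
peak in (0.5 Hz, Nyquist), and refine it by a quadratic fit to the
log-power of the three surrounding bins. The Hann window is what makes the
three-bin parabola trustworthy on short records (an interpolated peak is
good to ~0.01 Hz at 2.5 s where the raw bin is 0.4 Hz wide); interpolation
is suppressed when the neighbouring bins sit at rounding-noise level, as
happens when a noise-free tone lands exactly on a bin. The $B_2$ spectrum
is computed as a consistency check, warning if its peak is more than one
bin away.

Cycles are segmented in the $(B_1, B_2)$ plane: the phase
$\theta = \mathrm{atan2}(B_2/\sigma_{B_2},\, B_1/\sigma_{B_1})$ is
unwrapped, its net rotation sense detected (and flipped if clockwise), and
cycle boundaries placed at the upward crossings of successive multiples of
$2\pi$, linearly interpolated to fractional frames. At least three complete
cycles are required; purely one-dimensional oscillations ($B_2$ constant)
are a degenerate-phase error rather than a silent wrong answer.

The representative beat cycle is built in a body frame — head point at the
origin, the mean shape's proximal tangent rotated onto $+x$ — so that it is
invariant to where and how the cell happened to lie in the field of view.
Each cycle's frames are mapped to $[0, 1)$ by linear phase, positions are
interpolated onto a $P = 64$-point phase grid (any $P \ge 8$ works;
doubling $P$ moves the amplitude profile by well under 1%), and mean and SD
are taken per (phase, arc) point. The amplitude envelope is half the
peak-to-peak excursion of the body-frame lateral coordinate, normalized by
$L$; averaging happens first, normalization second. Regional summaries use
trapezoidal integrals with interpolated endpoints over the mouse partition
mid-piece [0, 24) um, principal piece [24, 104) um, end piece [104, 110] um,
so the three regional power integrals sum to the whole-cell rate exactly
(to rounding).

## Resistive-force-theory dissipation

Near a wall, a slender filament's local drag is anisotropic:

$$\zeta_t = \frac{2\pi\mu}{\ln(2h/a(s))}, \qquad
  \zeta_n = \frac{4\pi\mu}{\ln(2h/a(s))},$$

with a linearly tapered radius $a(s) = (a_h - a_t)(L - s)/L + a_t$
($a_h = 0.57$ um at the head end, $a_t = 0.18$ um at the tip) and the wall
distance fixed at $h = a_h$ along the whole tail — a deliberate
approximation for a head-tethered cell beating parallel to the slide,
implemented as such with the parameter exposed. The force per unit length
is $f = \zeta_t u_t \hat t + \zeta_n u_n \hat n$, and the dissipation
density $p = f \cdot u = \zeta_t u_t^2 + \zeta_n u_n^2 \ge 0$. Time
averages and the whole-cell rate $E = \int_0^L \bar p\, ds$ use trapezoidal
quadrature; micrometre/second units are converted to SI only inside this
module, and $E$ is reported in watts with a femtowatt accessor. One-sided
first/last-frame velocities are included in the time average by default
(`trim_boundary_frames` drops them). The default medium is water-like,
$\mu = 10^{-3}$ Pa s (1 cP).

## The projected free swimmer

If the tether were cut and the beat unchanged, zero net force at low
Reynolds number fixes the translation velocity:
$U(\tau) = -\left(\int \hat\zeta\, ds\right)^{-1} \int \hat\zeta \cdot u\, ds$
with the friction tensor $\hat\zeta = \zeta_t \hat t \hat t + \zeta_n \hat
n \hat n$. Only force balance is imposed — torque balance and body rotation
are deliberately neglected, so the trajectory is a first-order projection,
not a swimming simulation. The trajectory is the cumulative trapezoidal
integral of $U$, and VSL is the net displacement per beat cycle divided by
the period, averaged over all complete cycles (the first-cycle value is
kept alongside; the multi-cycle mean is less noisy, and both are exported).
The residual of the force balance is checked every frame and stays at
machine precision; reciprocal (standing-wave) beats drift less than
$10^{-3}$ um per cycle, a numerical statement of the scallop theorem.

## Procrustes comparison

Two representative beat patterns on the same grids are compared point by
point in the shared body frame. The default `rms` variant,
$d = \sqrt{\tfrac{1}{PM}\sum_{i,j} (\Delta x_{ij}^2 + \Delta y_{ij}^2)}$
in micrometres, matches the verbal definition of a root-mean-squared
waveform deviation; a plain `sum` variant (the same deviations summed, not
averaged) is kept behind a flag because both conventions circulate. No
rotation or scale superimposition is applied — the body frame already fixes
pose, and removing size differences would erase exactly the amplitude
differences the measure is meant to see. The only free alignment is the
phase origin of the second pattern, chosen by exhaustive circular shift
over the $P$ grid points. Group tables report within-group and
between-group pairwise means ± SD; statistical testing is intentionally
left to external tools.

## The synthetic generator and what the tests show

`generate_traveling_wave()` builds
$\psi(s,\tau) = \psi_0(s) + \varepsilon(s)\sin(2\pi f \tau - 2\pi s/\lambda + \varphi_0)$
and reconstructs positions with the head pinned at the origin (tethered
head, free proximal angle). Defaults emulate the study geometry this
package is aimed at: $f = 7$ Hz, $\lambda = L = 110$ um, 400 fps, 1000
frames, and a linear envelope ramping from 0.1 rad at the clamp to 1.0 rad
at the tip, which produces a ~15 um tip excursion — a realistic planar
mouse-sperm beat. Tracking noise is i.i.d. Gaussian on positions, seeded;
temporally correlated noise is not modelled. `generate_standing_wave()`
provides a reciprocal control, and `generate_group()` jitters frequency and
envelope scale multiplicatively (5% SD by default) across 25 cells from 6
round-robin mouse IDs.

With these defaults the pipeline recovers the generator frequency to
±0.1 Hz (the test sweep covers 3–9 Hz with 20 noisy replicates each), the
leading two modes carry over 99% of the variance of a clean single-component
beat, and four modes carry ≥ 98% when a second wave component plus
tracking noise worth 2% of the tangent-angle variance is added (that noise
level corresponds to ~0.09 um position noise — sub-pixel at typical
dark-field resolution — and is calibrated at run time rather than
hard-coded, because position noise amplifies by roughly the inverse arc
spacing when differentiated into angles). Whole-cell dissipation for the
defaults is ~116 fW, inside the 10–1000 fW decade expected for sperm in a
1 cP medium.

Two honest caveats. First, the synthetic beat is a clean constant-speed
traveling wave, which is a far more efficient propeller than a real mouse
waveform: the projected VSL of the defaults is ~75 um/s, an order of
magnitude above values measured on real sperm with this projection. VSL
magnitudes on synthetic data therefore validate contracts (scaling with
amplitude squared, rotation invariance, scallop-theorem nulls), not
physiological numbers. Second, passing on this generator demonstrates
correctness of the computations, not robustness to everything real
tracking produces (out-of-plane excursions, self-crossing hyperactivated
beats and correlated tracking errors are all out of scope; z-coordinates
are rejected outright rather than dropped).

## Numerical choices and degenerate inputs, in one place

* Quadrature: trapezoidal everywhere (time averages, arc integrals,
  trajectory integration); subinterval integrals interpolate their
  endpoints so partitions are exact.
* Derivatives: second-order three-point stencils, one-sided at boundaries,
  per-step weights for non-uniform time steps.
* Problem sizes in the shipped tests are scaled for a laptop-class single
  core: 1000-frame default records, cohorts of 25 cells per group in the
  end-to-end check, 10 cells per group in the acceptance script.
* Ties and signs: mode signs fixed by the largest-entry rule; Procrustes
  phase-shift ties resolve to the smallest shift; cycle boundaries at
  exactly a crossing choose the earlier frame interval.
* Degenerate inputs fail loudly with typed conditions: coincident
  centerline points (undefined tangent), constant coefficient series (no
  oscillation), $B_2 \equiv 0$ (degenerate phase), fewer than three cycles,
  singular friction tensors (impossible for $\zeta_n \ne \zeta_t > 0$ and
  finite length, but asserted), wall distance inside the filament radius.
* The zero-variance case (a static shape) decomposes cleanly: all
  coefficients zero, variance fractions reported as zero rather than NaN.

## Worked example

```{r example, eval = FALSE}
library(flagellar)

series <- generate_traveling_wave(wave_spec(noise_sigma = 0.1, seed = 1))
res <- analyze_cell(series)
glance(res)

autoplot(res$beat_cycle)   # representative cycle, colored by phase
autoplot(res$power)        # time-averaged dissipation density along the tail
plot_b_space(res$decomposition)

wt <- generate_group(wave_spec(noise_sigma = 0.1), n_cells = 10,
                     group = "wt", seed = 11)
ko <- generate_group(wave_spec(frequency = 4.1, amplitude = c(0.05, 0.5),
                               noise_sigma = 0.1),
                     n_cells = 10, group = "ko", seed = 12)
tabs <- compare_groups(analyze_cells(dplyr::bind_rows(wt, ko)))
tabs$kinematics
tabs$procrustes
```
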