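---
title: "Simulating and analysing corral-confined membrane diffusion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and analysing corral-confined membrane diffusion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The scientific problem

Membrane receptors such as the lymphatic hyaluronan receptor LYVE-1 do not
diffuse freely in the plasma membrane: the submembranous actin cytoskeleton
forms corrals that transiently confine them, and transient binding to
less-mobile structures ("trapping") slows them further. Spot-variation
fluorescence correlation spectroscopy (STED-FCS) discriminates these modes
by measuring the apparent diffusion coefficient `D` at several observation
spot diameters `d`: free diffusion gives a flat `D(d)`, trapping depresses
`D` at small spots, and hop diffusion across a meshwork depresses `D` at
large spots (equivalently, `D` rises as the spot shrinks below the mesh
size).

`corralfcs` implements the full computational chain needed to study this
quantitatively on synthetic data: a Monte-Carlo simulator of
trapped/hopping diffusion in a Voronoi confinement mesh, fluorescence
readout through Gaussian observation spots, autocorrelation analysis with
bleaching correction, fitting of the two-dimensional FCS diffusion model,
the spot-size-dependent diffusion law and its classification, two-component
FRAP recovery fitting, and watershed-based counting of ligand-coated beads.

## The Monte-Carlo model

Molecules perform Brownian motion in a circular arena (default diameter
3,000 nm). Each time step `dt` (default 0.001 ms):

1. A free molecule becomes trapped with probability `p_trap` (default
   5e-5 per step); a trapped molecule is released with the same
   probability, so the equilibrium trapped fraction is 1/2. Trapped
   molecules keep diffusing with `D_trap` = 1e-10 um^2/s — practically
   immobile.
2. The molecule takes a Gaussian step with per-axis variance `2 D dt`,
   `D` being `D_free` (default 0.4 um^2/s) or `D_trap`.
3. A step whose endpoint falls outside the arena re-enters antipodally
   (the exit point is mapped through the centre). This preserves the
   density of molecules on a circular domain, which a rectangular torus
   cannot.
4. If the endpoint lies in a different Voronoi compartment than the
   start, the move is accepted with probability `p_hop`; otherwise the
   molecule stays exactly where it was (no reflection). `p_hop = 1` means
   unrestricted passage; smaller values make the corral fences
   progressively harder to cross. The wrap is applied before the
   compartment test, so a (rare) re-entry event is treated as a boundary
   encounter as well.

The confinement mesh is the Voronoi tessellation of a homogeneous Poisson
point process clipped to the arena. A stated "average seed distance" `s`
is interpreted as the mean nearest-neighbour distance of the process,
which fixes the intensity via `mean NN distance = 0.5 / sqrt(lambda)`,
i.e. `lambda = (0.5 / s)^2`. At the default `s` = 50 nm this yields a mesh
size — defined throughout as the square root of the mean compartment
area — of about 100 nm, within the tolerance of the ~110-nm corral scale
the simulation is meant to emulate. The tessellation itself comes from
`deldir`; tiles crossing the arena boundary are clipped to a 128-gon
approximation of the circle (area error 4e-4, negligible against the
0.1% tiling check used in the tests). Compartment membership during the
simulation is resolved by exact nearest-seed lookup through a spatial
grid index, which is equivalent to Voronoi containment; ties break to the
lowest seed index.

A note on `p_hop` and the step size: the number of boundary encounters
per unit time scales as `1/sqrt(dt)`, so the *effective* fence
permeability at a given `p_hop` depends on `dt` (coarser steps mean
fewer crossing attempts and hence stronger confinement at the same
`p_hop`). Comparisons across `p_hop` values are therefore always made at
a fixed `dt`; the test conditions use the scaled-down `dt` = 0.002 ms
throughout.

## Fluorescence readout and correlation

The intensity seen by an observation spot of full width at half maximum
`d` centred at `c` is `sum_j B exp(-4 ln2 |r_j - c|^2 / d^2)` with
brightness `B` counts per molecule per sample (default 1, Poisson shot
noise optional). In the standard FCS convention the effective focal area
of this profile is `pi d^2 / (2 ln2)`, so the fitted occupancy `N` equals
the molecular density times that area; `effective_spot_area()` exposes
this for tests.

Correlation uses the estimator `G(tau) = <dF(t) dF(t+tau)> / <F>^2`. The
`direct` estimator evaluates every multiple of the sampling interval and
serves as the reference; the production `multitau` estimator implements
the standard multiple-tau scheme (16 points per octave by default,
pairwise binning per level, the same global-mean normalisation per level)
and agrees with the direct estimator to well under 1% on shared lags.
Lags are reported on the sampling-interval grid; no interpolation is
performed.

Bleaching correction for measured (or carpet) traces crops the first
5 s (configurable 5–10 s) and then rescales the trace against a local
baseline built from consecutive 16-s intervals:
`F'(t) = F(t) <F> / baseline(t)`, where the baseline interpolates the
geometric interval means in log space. Geometric means and log-space
interpolation make the baseline exact for exponential photobleaching
(the correction leaves no residual trend), and the multiplicative form
preserves the relative fluctuation amplitude that the `1/N` amplitude
estimate depends on; a subtractive correction would not. Traces that
touch zero fall back to arithmetic interval means.

## Model fitting

The one-component two-dimensional diffusion model
`G(tau) = (1/N) / (1 + tau/tau_D) + offset` is fitted by
Levenberg–Marquardt least squares (`minpack.lm`), with `N` and `tau_D`
bounded positive, the offset free, and starting values taken from the
curve itself (amplitude from the first in-range lag, `tau_D` from the
half-amplitude lag, offset from the tail). Weights are uniform by
default; per-lag weights can be supplied when repetitions are available.
The default fit range of 0.5–4,000 ms matches scanning-FCS practice; the
simulation analyses use a range matched to their much finer sampling
(0.1–200 ms), since a 0.5-ms floor would discard most of the decay of a
1-ms transit through a 50-nm spot. The optional two-pass mode
(`refine = TRUE`) refits over a window scaled to the first-pass decay
(`tau_D/30` to `30 tau_D`), which balances the weight given to the
amplitude plateau and to the noise tail when one nominal range spans
spot sizes whose transit times differ by a factor of 25.

Transit-time populations are summarised by a log-normal fitted in three
representations — density on Freedman–Diaconis bins of the
log-transformed samples, the empirical cumulative distribution, and a
Gaussian on the log samples — with the consensus median taken as the
geometric mean of the three per-form medians `exp(mu)`. The three forms
are near-redundant for clean samples (which is the point: the agreement
flag is lowered when any pair of medians differs by more than 20%).

Two conversions from transit time to diffusion coefficient coexist
deliberately:

* `transit_to_D_spot()`: `D = d^2 / (8 ln2 tau_D)` from the spot
  geometry, with 1 nm^2/ms = 1e-3 um^2/s.
* `transit_to_D_calibrated()`: `D = D_ref tau_ref / tau_D` from a
  reference pair measured on the same instrument. Published confocal
  sFCS pairs (e.g. 50 ms at 0.14 um^2/s) are inconsistent with the
  geometric relation at a nominal 250-nm spot, which indicates an
  instrument-calibrated effective focus; the calibrated form reproduces
  such measured pairs and is therefore kept separate rather than forced
  through the geometric formula.

## Spot-variation analysis

`calibrate_spot()` converts depletion-power series on a supported lipid
bilayer into spot diameters via `d = FWHM_conf sqrt(tau_STED/tau_conf)`
(replicates averaged first; entries with `tau_STED > tau_conf` flagged as
unphysical but retained). `diffusion_law()` converts per-spot fits into
`D(d)` with mean, sd and n per spot, and `classify_mode()` labels the law
by the ratio `rho = D(d_min)/D(d_max)` with a default tolerance of 0.2:
free within the band, trapped below, hop above, and ambiguous when the
propagated standard errors of the endpoints straddle a decision
threshold. The ratio of the extreme spot sizes is used instead of a
fitted slope because typical laws have only 4–5 points and the extreme
ratio matches how such plots are read.

## FRAP

The recovery model is
`F(t) = A1 (1 - exp(-(t - t0)/tau1)) + A2 (1 - exp(-(t - t0)/tau2))`,
fitted to post-bleach frames with components relabeled so `tau1 < tau2`.
Fitting goes through `minpack.lm::nls.lm` with a small multi-start (three
starting geometries for the time constants), because a single start can
converge to a degenerate optimum in which one component collapses onto
its bound; the best sum of squares wins. Preprocessing subtracts the
background, optionally divides by a no-bleach acquisition control (which
removes multiplicative acquisition decay exactly), normalizes to the
prebleach mean and puts `t = 0` at the first post-bleach frame. Times are
carried in whatever unit the input uses: published component recovery
times for this protocol are quoted in ms while the protocol samples at
1 frame/s, an inconsistency the package does not try to resolve — the
synthetic untreated-condition curves use the printed numerals
(amplitude split 52/48, time constants 2.5 and 17.5) interpreted in
seconds on the protocol's 100-s, 1-frame/s grid, and only the
dimensionless fractions are compared against published values.
`frap_tau_to_D()` provides the simple-diffusion scale estimate
`D = r^2/(4 tau)` only; no reaction–diffusion model is attempted.

## Bead counting

The bead-binding quantification is threshold → Gaussian filter →
regional maxima → marker-based watershed → count. The implementation
thresholds with Otsu's method (fixed values supported), takes the
distance transform of the binary mask, smooths *the distance transform*
(smoothing the binary image directly and re-thresholding would be
ill-defined, and this keeps the maxima stable while preserving the
binary-then-smooth order), finds regional maxima with a minimum
separation (default 5 px, the expected bead radius), and grows
marker-based watershed regions restricted to the mask (`EBImage`
distance map, Otsu and propagation). Objects below a minimum area
(default `0.25 pi r^2`) are discarded. Because Otsu always splits a
histogram, a guard rejects segmentations whose foreground does not stand
at least three background standard deviations above the background mean —
otherwise a blank noisy field would yield hundreds of false beads. The
guard, like the rest of the pipeline, is invariant to affine intensity
rescaling and to image rotation.

## What the synthetic data do and do not emulate

The generator reproduces the statistical structure the analysis relies
on: Poisson point seeding of corrals, Gaussian steps with two-state
trapping kinetics, fence-crossing statistics, Gaussian-spot readout with
optional shot noise, model-exact FCS and FRAP curves with controlled
noise, and bead fields with known ground truth. It deliberately omits
dye photophysics (blinking, bleaching within the simulation),
out-of-plane (3-D) diffusion, membrane topography, detector afterpulsing
and dead time, and any spatial heterogeneity of brightness. Passing
tests therefore demonstrate that the analysis chain recovers known
inputs under idealised optics and photophysics — not that it is robust
to every artefact of real recordings (bleaching correction is exercised
against synthetic exponential decay only).

## Numerical choices and problem sizes

* The propagation core is compiled (Rcpp) and uses R's RNG, so every run
  is bit-reproducible from `set.seed()`/`rng_seed`. When `p_hop = 1` and
  no per-step states are requested, the compartment lookup is skipped
  entirely (nothing can be rejected), which roughly quadruples speed.
* Unwrapped coordinates (displacement sums without wrap jumps) are
  recorded alongside wrapped positions so mean-square displacements are
  free of boundary artefacts; they can be disabled to halve memory on
  long intensity-only runs.
* The test and acceptance runs use the scaled-down study conditions:
  50 molecules, 2–6 s of trajectory at `dt` = 0.001–0.002 ms (200
  molecules for the trapping classification, where trapped-event
  statistics dominate), ten repetitions for the free-diffusion recovery
  check, and five observation positions per realization. Reading out
  several well-separated positions per run mirrors the experimental
  practice of measuring several regions per cell and stabilises the
  correlation estimates at no extra simulation cost. Correlation curves
  are averaged over repetitions and positions before fitting, the
  standard way to fit repeated FCS measurements.
* Finite traces bias the mean-subtracted correlation estimator downward
  by roughly `(2/T) integral(G)`; the free offset absorbs most of it,
  and the remaining tilt shrinks with trace length, which is why the
  recovery checks use 4–6-s traces rather than the 2-s minimum.
* Histogram binning for the log-normal density form uses
  Freedman–Diaconis on the log scale; degenerate samples (zero log-sd)
  short-circuit to the exact answer.

## Known limitations

* The correlators are plain R; traces beyond ~10^7 samples are better
  served by chunked or compiled correlators.
* The single-component FCS model is the only one offered (no anomalous
  exponents, two-component or triplet terms), matching the analysis it
  reproduces.
* `classify_mode()` is a two-point rule by design; with many spot sizes
  a fitted diffusion-law slope would use more of the data.
* The sFCS carpet path assumes a common sampling interval per pixel and
  does not model scanner dwell-time effects.

## A minimal end-to-end run

```{r example}
library(corralfcs)

cfg <- sim_config("test", spot_fwhms = c(250, 100), n_repetitions = 4,
                  duration = 4, p_trap = 0, p_hop = 1,
                  sampling_interval = 0.05, rng_seed = 1)
res <- run_pipeline(cfg, centers = spot_grid(5), fit_range = c(0.1, 200),
                    average = TRUE, refine = TRUE)
res$law
autoplot(res$law)
```
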