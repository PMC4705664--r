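---
title: "Models and methods behind rampfold"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind rampfold}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rampfold)
```

## The experiment being modelled

A single DNA molecule carrying a folded region of interest — here the
twelve G-tracts of the hTERT promoter, which can fold two stacked
G-quadruplexes — is held between two dsDNA handles (2028 and 2690 bp) in a
dual-trap optical-tweezers instrument and ramped at 5.5 pN/s at 23 °C.
Each time a folded element unravels, the tether lengthens abruptly: the
rupture force reports mechanical stability, and the released contour
length ΔL reports the size of the element. By attaching handles around
sub-segments (native mechanical segmentation), the 5′ quadruplex (NMS1-4),
the 3′ quadruplex block (NMS5-12) or the whole region (hTERT1-12) can be
interrogated separately. The package implements the full analysis chain
for such data, plus a generator of synthetic data sets with known ground
truth.

## Polymer elasticity and the ΔL ↔ nucleotide map

Tether mechanics use the Marko–Siggia worm-like chain. The ssDNA released
by unfolding is treated as inextensible (persistence length 0.8 nm,
contour 0.45 nm/nt); the dsDNA handles as extensible (P = 50 nm,
K = 1200 pN, rise 0.338 nm/bp). These are standard optical-tweezers
values and all are overridable. Root finding is by safeguarded Newton /
bracketed `uniroot` on the monotone force law, and the stretching free
energy ∫F dx is evaluated by adaptive quadrature; dense spline profiles
of φ(F) and ∫φ dF are cached per persistence length for the hot paths.

The map between ΔL and nucleotide count is an empirical straight line
fitted by least squares to nine published (nt, ΔL) pairs, giving
slope `r round(calibrate_conversion()$slope, 4)` nm/nt and intercept
`r round(calibrate_conversion()$intercept, 4)` nm. The intercept absorbs
the end-to-end width of the folded structure. The printed pairs are not
exactly collinear (residuals up to 0.65 nm), so the line is a calibration
with ~1-nt accuracy, not an exact law; leave-one-out fits still reproduce
the published identities (68 nt ↔ 25 nm, 2.5 nm → 7 nt). Users with their
own calibration can supply any (slope, intercept), e.g. the common
literature convention ΔL = 0.45·N − x_fold.

## The synthetic-data generator

Each foldable element (quadruplex, hairpin/triplex intermediate, or the
inter-quadruplex stacking contact) is a *species* with Bell–Evans rupture
kinetics k(F) = k₀ e^{F·Δx‡/kT}; under a linear ramp the rupture-force
density has the closed form used for exact inverse-CDF sampling. A
*scenario* adds the instrument parameters (5.5 pN/s, 200 Hz, 0.2 pN
Gaussian force noise, 65 pN overstretching plateau) and a set of
*refolding configurations*: each pulling cycle samples which species
re-formed during the preceding relaxation, expressing the refolding
heterogeneity seen between cycles. Stages within a configuration rupture
in hierarchy order, implemented as a hazard restart at the previous
stage's last rupture force, so an inner structure can never unfold before
its shield. A dependent species can merge with its prerequisite into a
single cooperative event with probability `coop_prob`.

Two generator choices deserve emphasis:

* **Thermodynamic consistency.** Given a species' folding free energy ΔG,
  its released contour ΔL and its Δx‡, the zero-force rate k₀ is solved
  from E[e^{−W(F)/kT}] = e^{−ΔG/kT}, where W(F) = ΔL·∫₀^F φ_ss and the
  expectation runs over the Bell–Evans density. This makes the Jarzynski
  estimator asymptotically unbiased on simulated works by construction,
  so free-energy recovery tests have a well-defined truth.
* **Work spread and transition-state placement.** The Jarzynski average
  is dominated by rare low-work events; when the work spread σ_W greatly
  exceeds kT the estimator needs exponentially many pulls. For the
  species whose free energies the analysis is meant to recover (the
  18-nt quadruplex and the 21-nt cooperative unit) the transition state
  is placed late (Δx‡ = 7.0 and 8.5 nm, comparable to the released
  extension), giving σ_W ≈ 1 kT and convergent estimates at a few
  hundred pulls — the near-equilibrium regime in which this kind of
  analysis is actually informative. Structural species not used for
  energetics keep earlier barriers (Δx‡ 0.9–4 nm) chosen so every modal
  rupture force falls in the experimentally observed 10–45 pN window.
  None of these kinetic parameters are measured values.

The built-in twins encode the observed phenomenology: NMS1-4 mixes
stack-plus-quadruplex cycles (22.5%, always cooperative — a consistent
2 kcal/mol contact that releases only ~0.9 nm ruptures near 29 pN, well
above the near-equilibrium quadruplex's own range, so when the stack is
present the pair unfolds as one step), quadruplex-only cycles (52.5%,
the stack failed to re-form) and a 14-nt triplex configuration (25%),
which yields a 30% cooperative fraction among full-fold cycles. NMS5-12
uses four configurations reproducing the 15/26/32/42/47-nt species and a
31% single-step fraction. hTERT1-12 realises the published 65/24/11
pathway split as configuration probabilities, with two mechanical
conformers of the 5′ quadruplex so that each branch's rupture ordering is
kinetically consistent. The stacking contact carries 2.0 kcal/mol in all
constructs (3, 5 or 7 nt released depending on the handle placement);
the 3′ quadruplex gains 6 kcal/mol of hairpin-loop stabilisation. A
cooperative composite releases the conversion of the summed nucleotide
count (one folded unit, one end-correction), not the sum of the two
conversions.

What the generator does *not* emulate: bead/trap hydrodynamics and force
calibration, drift, extension-side measurement noise (noise enters
through the recorded force), force-dependent refolding during relax, and
atomistic structure of the intermediates. Passing recovery tests on the
twin therefore validates the analysis logic and its statistical
behaviour, not instrument-specific artefact handling.

## Rupture detection and ΔL estimation

Jumps are found on the sample-to-sample extension increments after
removing an 11-sample running-median baseline; increments above five
median absolute deviations (with a 0.3 nm absolute floor, which guards
the noise-free limit) are events. The published work does not specify a
detection algorithm, so these thresholds are this package's own choices,
all configurable. Each jump is quantified by linear fits of extension and
force against sample index on both flanks — the ramp is linear in time,
and regressing extension on the *noisy* force over a narrow window would
put noise on the predictor side and destabilise the fit. ΔL = Δx/φ_ss(F)
with first-order error propagation; events closer than 0.5 pN are merged
(ringing protection); detection stops at 55 pN to stay clear of the
overstretching plateau, whose presence within 65 ± 5 pN (near-zero
slope over ≥ 15 nm) is the single-tether fingerprint. Each event carries
an event-level standard error (the deconvolution kernel scale) and the
per-sample plateau noise, which matches the scatter of the ΔL–force
representation (x_baseline(F) − x(F))/φ_ss(F).

## Population deconvolution (PoDNano)

Each bootstrap resample draws events with replacement and accumulates
per-event Gaussian kernels on a 0.02 nm grid; local maxima above 5% of
the density maximum are recorded, and the positions pooled over all
resamples (5000 by default) are clustered at the basins of their own
density. Populations detected in fewer than half the resamples are
discarded. Three numerical choices matter and were set as follows:

* *Kernel width* = 0.5 × the event's standard error: the measured values
  already contain the scatter the error quantifies, so the kernel only
  smooths them into a density; 0.5·se matches a Silverman-scale bandwidth
  at these sample sizes. An optional jitter layer re-perturbs each drawn
  value by its full error (at some resolution cost).
* *Mode clustering by density basins*, not fixed-cutoff single linkage:
  resamples that happen to merge two populations leave bridge modes
  midway between them, and single linkage chains genuinely distinct
  populations through those bridges.
* *A credibility floor on separations*: candidate populations closer than
  2.8 × the median standard error are merged. Splitting artefacts of a
  single population appear at 1.5–2.7 error units at appreciable rates,
  while the method's real resolving power sits near three error units —
  the resolution scan bottoms out around 0.4–0.5 nm at a 0.15 nm error,
  consistent with the sub-0.5 nm resolution reported for the approach.

Final centers are refined as the mean ΔL of the events assigned to each
population (a far less noisy location estimate than a raw density mode);
probabilities are assignment shares, and centers convert to nucleotide
counts through the calibration.

## Pathway reconstruction

Following the published procedure, only molecules showing the full-fold
summed ΔL (25 nm for hTERT1-12, 18 nm for NMS5-12; ±2 nm here) enter the
analysis, and for hTERT1-12 a molecule must also show a trace that
unfolds completely during the ramp. Population histograms keep all cycles
of a selected molecule; pathway statistics use its full-fold cycles.
Events bin to the nearest population center (4 nm bins, per the published
three-standard-deviation rule; midpoint ties to the smaller center) and
rank by order of occurrence, which disambiguates near-identical ΔL
values. Each cycle's initial state is its own summed ΔL — accommodating
incomplete refolding — and every event moves to a smaller folded core, so
the aggregated transition graph is acyclic with strictly decreasing
nucleotide labels; outgoing percentages normalise to 100 per state.
Cycles with unclassifiable events, and molecules broken prematurely, are
excluded and reported. Because the published statistics alternate between
per-trace and per-molecule phrasing, cooperative fractions are reported
both ways (per-trace is primary). The cooperative signature uses a 1 nm
tolerance, tighter than trace selection, so a single-step event one
population below the full fold is not miscounted.

## Energetics

The unfolding work of an event is W = F·Δx − ΔG_stretch(ΔL, 0→F) in
kcal/mol, and ΔG = −kT ln⟨e^{−W/kT}⟩ with a log-sum-exp guard and a
seeded 2000-resample bootstrap for the standard error. Only first-rank
(first-rupture) events enter free-energy estimates: later ruptures do not
start from equilibrium at zero force, so the Jarzynski protocol is
ill-defined for them, and their force distributions are censored by the
hierarchy. The estimator obeys Jensen's inequality on every input and its
finite-sample bias is positive and shrinks with the number of pulls (both
property-tested). The stacking free energy is the state-function
difference ΔG(quadruplex+stack population) − ΔG(quadruplex population);
on the NMS1-4 twin at ~200/470 events per population this recovers the
generating 2.0 kcal/mol with ≈ 0.16 kcal/mol spread, independent of the
loading rate (5.5 vs 11 pN/s).

## Problem sizes and determinism

The shipped tests run the twins at desk scale: 100–500 cycles for
detection and pathway recovery, 900 cycles (×20 replicates) for the
energetics recovery, 10⁵ draws for distributional checks, and
1000–5000 resamples per deconvolution. All randomness flows from
user-supplied seeds (the resampling core uses R's RNG, so `set.seed()`
governs it too); identical configurations reproduce files byte for byte.

## Known limitations

The ΔL↔nt line inherits the ~1-nt inconsistency of its calibration
pairs. Detection assumes instantaneous ruptures and clean single-tether
traces; closely spaced ruptures (≲ 0.5 pN apart) merge, which the twins
show costs ~2% recall. The deconvolution's resolution claim is tied to
the assumed error scale and degrades proportionally for noisier events.
Bell–Evans kinetics (a single sharp barrier, force-independent Δx‡) is
the simplest adequate rupture model; Dudko–Hummer–Szabo kinetics, Crooks
two-sided analysis and hidden-Markov assignment on constant-force data
are out of scope. The kinetic parameter defaults are plausible choices
tuned only to the published force window, not measured quantities.
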