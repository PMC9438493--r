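---
title: "Direct phasing of high-solvent-content crystals by iterative projection"
author: "dmphase"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Direct phasing of high-solvent-content crystals by iterative projection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dmphase)
```

## The problem

A diffraction experiment measures only the magnitudes $|F_\mathbf{h}|$ of
the structure factors; the phases needed to reconstruct the electron
density are lost. For protein crystals with very high solvent content
(solvent volume fraction $f_s \gtrsim 0.70$) the density carries enough
redundancy for the amplitudes alone to determine the structure: if the
solvent region is featureless and occupies more than half the cell, the
degrees of freedom of the density are more than halved, and the phase
problem has (generically) a unique solution even when the molecular
envelope itself is unknown. `dmphase` implements a practical, unsupervised
procedure that exploits this: iterative projection phase retrieval with
solvent-flatness and histogram constraints, variance-based envelope
determination, gradual resolution extension, and consensus clustering of
independently seeded runs.

## Constraint sets and projections

The density over one unit cell, sampled on an $N$-point grid, is a vector
$\mathbf{x} \in \mathbb{R}^N$. Two constraint sets are used:

* **Real space ($A$):** given a binary molecular envelope, the solvent
  region has a one-point (flat) distribution and the protein region has a
  generic protein density histogram. The projection $P_A$ sets the solvent
  to its mean (solvent flattening) and applies rank-preserving histogram
  specification in the protein region, followed by a mean shift to the
  reference mean (`projectReal()`). Rank-preserving transport onto a fixed
  set of target quantiles is the least-squares monotone map, so $P_A$ is
  the projection onto the constraint set for a fixed envelope.
* **Fourier space ($B$):** the calculated amplitudes must match the
  measured ones. $P_B$ (`projectFourier()`) Fourier-transforms the
  density, replaces each observed amplitude by the apodized, least-squares
  scaled measurement while keeping the calculated phase (the closest map
  with the required amplitudes), and transforms back. A single overall
  scale factor is refit at every projection; per-shell scaling was
  considered and deferred as the simplest choice consistent with the
  procedure's needs.

Reflections below the 25 Å low-resolution cutoff, the $F_{000}$ term and
all unmeasured amplitudes are *missing*: they evolve freely except for a
Wilson-statistics guard (`wilsonGuard()`) that resets any amplitude whose
upper-tail probability under the class-appropriate Wilson distribution
(Rayleigh for acentric, half-normal for centric reflections, mean square
$\epsilon\Sigma$ from shell statistics) falls below $5\times10^{-6}$. The
comparison is implemented on the amplitude axis (reset iff
$F > F_{\text{thr}}$ with $F_{\text{thr}}$ the threshold amplitude), which
is numerically robust and exactly equivalent to the strict probability
inequality. The map mean is therefore algorithm-determined: no offset
convention is imposed. Grid frequencies inside the resolution sphere that
never appear in the reflection table are guarded with $\epsilon = 1$
(general position), since their exact symmetry factors are not tabulated;
measured reflections always use their exact $\epsilon$.

## The update rules

Error Reduction (`erStep()`) is plain alternating projection,
$\mathbf{x} \mapsto P_A P_B \mathbf{x}$: it converges locally but
stagnates at non-solutions of non-convex problems, so it is used only for
final polishing. The Difference Map (`dmStep()`) is

$$\mathbf{x}_{n+1} = \mathbf{x}_n + \beta\,[P_A f_B(\mathbf{x}_n) -
P_B f_A(\mathbf{x}_n)], \qquad
f_{A,B}(\mathbf{x}) = (1+\gamma_{A,B}) P_{A,B}\mathbf{x} -
\gamma_{A,B}\mathbf{x},$$

with $-1 < \beta < 1$, $\beta \neq 0$. The relaxation constants default to
the standard recommended choice $\gamma_A = -1/\beta$,
$\gamma_B = +1/\beta$; they are exposed in `dmParameters()` because the
update rule is sometimes used with other choices. With these defaults,
negating $\beta$ reproduces the $+\beta$ dynamics with the projections
applied in the opposite order (covered by a test). The two solution
estimates $\mathbf{x}_A = P_A f_B(\mathbf{x})$ and
$\mathbf{x}_B = P_B f_A(\mathbf{x})$ satisfy their respective constraints
exactly; their root-mean-square difference $\delta_{DM}$ (`deltaDM()`) is
the convergence indicator — zero iff a point in the intersection has been
found. One ER cycle is defined here as $P_A(P_B(x))$, i.e. Fourier
projection first, ending in real space, which keeps the estimate
conventions of the two algorithms consistent; the order is configurable.

## Envelope determination

The molecular envelope is unknown a priori and is re-determined at every
iteration from the Fourier-constraint estimate $\mathbf{x}_B$: the
density's local variance is computed with a triweight kernel
$T(r) = (1-(r/r_0)^2)^3$ (radius $r_0$ in Å) via the one-pass identity
$K\!*\!\rho^2 - (K\!*\!\rho)^2$ with a unit-sum periodic kernel (FFT
convolution), and the highest-variance fraction $1-f_s$ of grid points is
marked protein (`localVarianceMap()`, `envelopeFromVariance()`).
Protein interiors fluctuate; flat solvent does not — so local variance
separates the regions more reliably than the local mean. Ties at the
threshold break deterministically by (value, linear grid index), and for
symmetric maps whole orbits are kept together so the mask respects the
space-group symmetry.

## Apodization and resolution extension

Amplitudes are weighted by a Gaussian $w(s) = e^{-s^2/2\sigma^2}$ in the
scattering-vector magnitude $s = 1/d$; a Gaussian taper avoids the ringing
of a hard cutoff. Widths are reported both as $\sigma$ (Å$^{-1}$) and as
the 1/100-height half width $3.03\sigma$ or its resolution. During phase
determination $\sigma$ increases over 30 steps such that the area under
$w$ (integrated to the data limit $s_{\max}$) grows by equal increments,
ending unapodized; intermediate $\sigma$ values are found by monotone
root-finding to relative tolerance $10^{-6}$ (`apodizationSchedule()`).
Reference histograms are recomputed at each step with the same apodization
applied.

## The benchmarked protocol

`defaultEnvelopeConfig()`: 50 runs × (1475 DM + 25 ER) iterations;
$\beta$ alternating 0.72/0.78 each iteration; fixed $\sigma = 0.091$
Å$^{-1}$ (1/100 height at 3.6 Å); 25 Å low-resolution cutoff; $r_0$
shrinking linearly 10.8 → 8.0 Å over the first 1000 iterations (the
linear form is this package's choice; only the endpoints and window are
prescribed); grids at 2/5 of the 3.6 Å effective resolution.

`defaultPhaseConfig(d)`: 20 runs × 8100 iterations; 7200 DM iterations
under the 30-step schedule from $\sigma_0 = 0.16$ Å$^{-1}$ with $\beta$
alternating 0.675/0.800 every 60 iterations; then four repeats of (100 DM
at $\beta = +0.75$, 100 DM at $\beta = -0.55$, 25 ER) with no apodization;
the starting envelope held fixed for 10 iterations; $r_0 = 8.0$ Å
throughout; grids at $2d/5$. `scaleStageConfig()` shrinks these budgets
proportionally while leaving every constant untouched — the scaled
profiles used in the tests are 10 envelope runs × 300 iterations and 5
phase runs × 1200 iterations (30 schedule steps of 32 iterations, then
scaled final blocks), sizes chosen so a complete synthetic experiment runs
comfortably on one CPU.

The amplitude scale is refit at every projection (per iteration, not per
apodization step): the simplest convention, and the one that keeps $P_B$
idempotent.

## Registration, clustering and consensus

Randomly initiated runs pick their crystallographic origin — and, in the
43 achiral space groups relevant to protein work, possibly the hand —
arbitrarily. Before comparison, solutions are brought to a common origin
over the group's permitted shifts (`bestRegistration()`): FFT
cross-correlation scores all grid translations at once and the maximiser
is restricted to the allowed set; the inversion alternative is searched
when the group permits it. Envelopes are compared with the Matthews
correlation of the two masks, and clustered on
$d = \sqrt{1-\mathrm{CC}^2}$ with DB-SCAN (minPoints = 10% of the run
count, $\varepsilon$ = the 4th percentile of the pairwise distances —
a data-driven choice because absolute correlations vary widely between
data sets). Phase sets are compared by the mean absolute phase difference
after registration, clustered at $\varepsilon = 40°$ (50° fallback),
minPoints = 2.

For phase sets along *continuous*-origin directions (P1, polar axes) the
on-grid search is polished by continuous optimisation of the weighted
phase-agreement score: two independently converged runs in P1 sit at a
sub-grid relative origin, and an on-grid-only comparison would inflate the
distance by an amount comparable to the clustering threshold. Envelope
registration stays on-grid — binary masks cannot be meaningfully shifted
by sub-grid amounts.

Consensus envelopes take the per-voxel majority (ties → protein,
documented for determinism), then a connectivity edit erases protein
islands and fills solvent voids smaller than 1% of the protein voxel
count (threshold configurable; no specific value is prescribed by the
underlying procedure). Consensus phases are per-reflection circular means;
cluster consistency is summarised by the sample circular variance
$1 - \bar R$. A reflection with zero resultant (e.g. an antipodal pair)
has no mean direction and is flagged undefined rather than invented.
DB-SCAN border points are assigned to the first cluster that reaches them,
with clusters grown in input order — deterministic across platforms.

## The two-stage pipeline and its success rule

`runTwoStage()` first coalesces envelopes at low effective resolution,
clusters them, builds ranked consensus candidates (ranking by conformity
with the target volume fraction, then protein-region connectivity), and
then starts full-resolution phase determination from the best candidate
(continuing down the ranking if needed). Success is declared iff a cluster
of at least two mutually consistent final phase sets exists — across
benchmarks, such clusters always correspond to the true solution, whereas
conventional agreement metrics routinely fail to indicate success. Runs
are fully independent tasks with per-run seeds derived deterministically
from the master seed, so results are identical for any worker count.

## The synthetic toy crystals

`generateToyCrystal()` builds pseudo-atom structures (isotropic
Gaussians, single B factor) at residue-level coarse graining: one bead
per ~135 cubic Angstrom of protein volume, placed with a bond-scale
minimum separation so they fill a single compact molecular ball out to
its surface, with bead weights modulated by ~10 Angstrom blobs that stand
in for secondary-structure contrast. Both ingredients matter and were
chosen by measurement: a sparser cluster leaves the envelope's outer
shell empty (only ~1.5% of the protein signal in the 0.80-0.85 fraction
shell), which makes the density insensitive to solvent-fraction
over-estimation; a heavy-atom-density uniform fill instead suppresses the
8-25 Angstrom density fluctuations (hard-sphere-liquid behaviour) that
envelope determination feeds on. The residue-level filled ball sits
between the two and reproduces the method's qualitative behaviour on both
axes. The generator
computes exact structure factors to the stated resolution, and emulates
the statistical structure the method relies on: Wilson-distributed
intensities with an overall B-factor falloff, a generic smooth protein
histogram, and featureless solvent. Amplitude noise is multiplicative
(2% default) with sigmas emitted consistently. The *true envelope* is the
fraction-matching molecular footprint of the pseudo-atom cluster (grid
points nearest to any atom under the minimum-image metric): the envelope
concept refers to the protein *region*, and a raw density threshold at
high solvent fractions would select only the sharp peaks on the atoms
rather than the molecular volume (measured on these toys, the raw
threshold mask correlates at only ~0.2 with the footprint while the
variance-filter envelope of the true band-passed map reaches ~0.65).
Reference
histograms for the real-space projection come from an independently
generated reference toy at the estimated B factor and matched resolution
and apodization, replacing any dependence on deposited reference
structures.

What the toys do *not* emulate: atomic form factors and chemistry, bulk
solvent scattering (solvent is strictly flat), anisotropy, measurement
error models beyond multiplicative noise, and realistic crystal packing.
Passing end-to-end tests on toys therefore demonstrates the correctness
and the qualitative behaviour of the machinery (envelope coalescence,
clustering as the success diagnostic, sensitivity to solvent-fraction
overestimation) — not real-data success rates.

## Numerical choices and degenerate inputs

* Population (not sample) variance throughout: grid points are the whole
  population of a region.
* Histogram matching preserves the *post*-mapping (reference) variance by
  default — the mean is shifted, the quantile-mapped spread kept; a
  `preserve = "pre"` option rescales to the pre-mapping variance instead,
  for users who read the convention the other way.
* Degenerate cells, constant variance maps, empty solvent regions,
  single-class masks, zero-resultant consensus phases, non-finite
  densities mid-run: all are errors or flagged results, never silent.
* Equal-count resolution shells (20 by default, at least 50 reflections
  each when possible) stabilise the Wilson statistics on small synthetic
  data sets.
* FFT grids use only factors 2, 3, 5 and honour the symmetry operators'
  translation denominators; axes mixed by a rotation share a count.

## Problem sizes used in the tests

The deterministic suites run on 8³–16³ grids and toy cells of 20–24 Å.
The end-to-end checks use the generator defaults (40 Å P1 cube, 95
residue-level pseudo-atoms, solvent fraction 0.80, 3 Å data, 2% noise;
~4900 unique reflections; 30³ envelope-stage and 36³ phase-stage grids)
with the scaled protocol above, plus a matched fraction-0.60 control and
mis-specification conditions (assumed 0.75 and 0.90, i.e. 0.05 under and
0.10 over) at a slightly smaller run budget (6 envelope runs, 4 phase
runs). These sizes are the
package's standard demonstration profile.

## Known limitations

* Non-crystallographic symmetry constraints are not implemented (the
  interface leaves other real-space projections possible).
* Hand determination in achiral groups is reported, not decided: both
  hands may emerge as separate clusters, and choosing between them needs
  external information.
* The built-in space-group table covers P1, P21, P212121, I222 and
  P61/P65; other groups enter via an operator file, with origin shifts
  derived from the operators.
* Sub-grid origin refinement is applied to phase sets only; envelope
  consensus in continuous-origin groups can blur by up to half a grid
  spacing.
* Intensities-to-amplitudes conversion, scaling/merging, twinning and
  anomalous data are out of scope: input is a reduced amplitude list.
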