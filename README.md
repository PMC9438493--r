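# dmphase

Ab initio (direct) phasing of X-ray diffraction data from protein
crystals with high solvent content, in R.

## The problem and who this is for

A diffraction experiment measures only Fourier *amplitudes*; the phases
required to compute an electron-density map are lost. When the solvent
volume fraction of a crystal exceeds about 0.70, the solvent-flatness
constraint (plus the generic shape of protein density histograms) is
strong enough that the amplitudes alone determine the structure — if an
algorithm with global, rather than local, convergence is used to find it.
`dmphase` is for structural biologists and methods developers who want a
complete, self-contained implementation of such a procedure: iterative
projection phase retrieval with the Difference Map, automatic molecular
envelope determination, resolution extension by Gaussian apodization, and
consensus clustering of independently seeded runs as the success
diagnostic.

## The method in brief

Density is a vector **x** of grid samples over one unit cell. Two
constraint sets are enforced by projections: the real-space set *A*
(solvent flat at its mean; protein region histogram-matched to a
reference distribution) and the Fourier-space set *B* (calculated
amplitudes equal the measured ones, after Gaussian apodization
w(s) = exp(−s²/2σ²) and least-squares scaling; missing amplitudes are
guarded by Wilson statistics at a 5×10⁻⁶ tail threshold). The Difference
Map iteration

    x ← x + β [ P_A(f_B(x)) − P_B(f_A(x)) ],   f_i(x) = (1+γ_i) P_i(x) − γ_i x,
    γ_A = −1/β,  γ_B = +1/β

searches globally; its two solution estimates satisfy *A* and *B*
respectively and coincide exactly at a solution (their RMS difference
δ_DM is the convergence measure). Error Reduction (plain alternating
projection) polishes at the end. The molecular envelope is re-derived
every iteration by thresholding the triweight-filtered local variance of
the current estimate. A two-stage protocol — envelope determination from
50 random starts at low effective resolution, then phase determination
from a consensus envelope with gradual resolution extension — is run with
per-run seeds; DB-SCAN clustering of the resulting envelopes and phase
sets identifies consistent (i.e. correct) solutions, and the emergence of
two or more mutually consistent phase sets (mean absolute phase
difference below 40–50°) *is* the success criterion.

## Worked example

Everything below runs from scratch in a few minutes on one CPU; no
external data are needed — the package generates a synthetic crystal with
known answers.

```r
library(dmphase)

# a 40 A P1 toy crystal: 95 pseudo-atoms, 80% solvent, 3 A data, 2% noise
toy <- generateToyCrystal(seed = 3)
toy
#> ToyCrystal: 95 pseudo-atoms in P1, solvent fraction 0.800, 4921 unique reflections

# two-stage phasing, scaled down from the benchmark protocol
envCfg <- scaleStageConfig(defaultEnvelopeConfig(), runs = 10, iterations = 300)
phCfg  <- scaleStageConfig(defaultPhaseConfig(3),   runs = 5,  iterations = 1200)
res <- runTwoStage(toy@refl, solventFraction = 0.80, envCfg, phCfg,
                   seed = 42, truth = list(phases = toy@phases,
                                           envelope = toy@envelope))
res
#> Two-stage phasing pipeline (seed 42, solvent fraction 0.80)
#>   success: YES (phase clustering at eps = 40 deg)
#> ClusterSet: 1 cluster(s) of sizes 5; 0 noise of 5 (minPoints=2, eps=40)
#>   consensus circular variance: 0.039
#>   consensus vs truth: 28.4 deg
```

Reading the output: all five phase-determination runs landed in one
cluster (five mutually consistent phase sets — the success diagnostic),
their consensus phases differ from the ground truth by 28° on a weighted
mean absolute basis after origin registration, and the very low circular
variance (0.04) says the cluster members agree closely with each other.
The best consensus envelope correlates with the true molecular envelope
at `max(res$envelopeTruthCC)` ≈ 0.49 on the coarse envelope-stage grid —
enough of an approximation to bias the phase runs into the right basin.

A command-line wrapper with `simulate`, `envelope`, `phase`, `cluster`
and `run` verbs is installed at `inst/scripts/dmphase-tool.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("scripts/dmphase-tool.R", package="dmphase"))')" \
    simulate --solvent 0.8 --seed 3 --out toy/
```

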