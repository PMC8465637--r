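---
title: "Models and methods: cooperative ParA dimer assembly on partition promoters"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: cooperative ParA dimer assembly on partition promoters}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(parpromoter)
```

## The scientific question

Type Ia partition systems of low-copy-number plasmids encode an ATPase
(ParA) that represses its own operon by binding the promoter region
through an N-terminal winged helix-turn-helix (wHTH). For the F plasmid,
the promoter carries four copies of the hexamer 5'-CTTTGC; quantitative
surface plasmon resonance puts six ParA monomers — three dimers — on that
fragment at saturation. The geometry that reconciles those numbers is an
*overlapping inverted-repeat* (IR) architecture: one perfect IR whose
half-sites sit 28 bp apart (centers 34 bp, about three helical turns, so
nearly on one face of the duplex), a degenerate IR overlapping it, and a
singleton half-site. Each dimer reads one IR through its two wHTH motifs;
binding is cooperative, DNA must bend ~3°/bp for the dimer span to reach
both half-sites, and the wHTH region is highly flexible.

This package rebuilds that analysis chain as testable code, replacing
every wet-lab input with a seeded synthetic generator that carries the
statistical structure the downstream estimator assumes. Passing tests
demonstrate that each estimator recovers the truth *of its generator*
under realistic noise — they are evidence about the methods, not new
evidence about the biology.

## Synthetic data: what is emulated, and what is not

* **Promoter sequences** — i.i.d. background nucleotides with
  P(A) = P(T) = `at_fraction/2` (default 0.73, the AT-richness of the
  natural promoter over 100 bp), with motif elements embedded at exact
  coordinates. The background is *screened*: it is resampled
  (deterministically, from seed-derived substreams) until rescanning the
  built sequence finds no spurious exact-consensus window and no IR pair
  beyond the embedded ones. An unscreened AT-rich background of this
  length produces a spurious exact hexamer with probability ≈3% and about
  eight ≤2-mismatch windows, which would make motif counts depend on
  background luck rather than architecture. Not emulated: dinucleotide
  structure, A-tract bending (bending lives only in the geometry module),
  real flanking sequence.
* **SPR sensorgrams** — exact 1:1 Langmuir phase solutions plus i.i.d.
  Gaussian noise (default 5 RU, ~0.5% of the saturating response). The
  true saturating response follows the mass-proportionality relation
  `Rmax = dimers · 2 · (MW_A / MW_L) · R_L` with a 660 Da/bp duplex mass
  convention and a 44 kDa monomer; stoichiometry results are
  self-consistent under any monomer mass because generator and estimator
  share it. Not emulated: mass-transport limitation, bulk refractive
  index jumps, baseline drift.
* **Titrations** — fraction bound from the Hill or ligand-depletion
  forward model plus Gaussian noise (default 0.03 fraction-bound units),
  clipped to [0, 1]. The cooperative scenario uses a Hill coefficient of
  3; no measured value exists (the source data show only a "sharp
  slope"), so this is an explicit assumption of the scenario, not a
  recovered quantity. Kinetic truths (ka = 1e5 /M/s, kd = 1e-2 /s, KD =
  100 nM) are likewise scenario choices consistent with the ~100 nM
  equilibrium affinity; no kinetic rate constants were ever reported.
* **Melt curves** — two-state van't Hoff unfolding (default ΔH 300
  kJ/mol) with linear folded/unfolded baselines; the 330 nm channel is
  flat and the 350 nm channel carries the ratio. Channel noise is
  multiplicative Gaussian (scenario default 0.005 when enabled; the
  printed-condition scenarios are noiseless). Not emulated: aggregation
  scattering, multi-domain transitions, heating-rate lag — the analysis
  grid (0.1 °C) is deliberately decoupled from the instrument's heating
  rate.
* **Trajectories** — a fixed non-collinear helical CA trace plus
  per-residue isotropic Gaussian displacements (core σ 0.5 Å, loop σ 2 Å
  over the loop interval), optionally with a linear drift carrying a
  marker residue a prescribed distance (30 Å by default, emulating the
  wing-tip excursion) between first and last frames. Not emulated: any
  actual dynamics — no force field, no temporal correlation, no
  covariance between residues.

All generators take explicit integer seeds and derive per-purpose
substreams keyed by a stage label, so equal scenario + seed is
bit-reproducible and adding a stage never reshuffles another stage's
noise.

## Estimators and numerical choices

**Motif scanning** compares every window on both strands to the consensus
by Hamming distance (minus-strand windows after reverse complement);
coordinates are 0-based, half-open, on the plus strand. IR pairing takes
every (plus, downstream minus) couple with spacer in [26, 29] (the range
observed across F/P1/P7-type promoters; configurable), at most 2
mismatches across the pair and at least one perfect half-site — the
tolerance that admits the natural degenerate pair (tcTTGC two mismatches,
partner perfect). Center distance is spacer + motif length, avoiding
half-integer centers. The left-margin flag uses a 40-bp threshold,
a heuristic derived from the ~85-bp minimal binding fragment minus the IR
footprint. Information content is `2 + Σ p log2 p` per column with
0·log 0 = 0 and no small-sample correction by default (motif sets as
small as 3 are analysed); the `e_n` correction is available by flag.

**Kinetic fitting** uses closed-form Langmuir phase solutions (exact, no
ODE tolerance) inside a Levenberg–Marquardt least-squares fit on
log-parameters, started from a fixed 3×3×3 log-spaced grid in fixed order
— deterministic by construction. The default "local" mode fits each
concentration separately and aggregates by the median, mirroring
per-curve local analysis; a global shared-parameter mode is available.
Stoichiometry is the pure arithmetic `S = Rmax / ((MW_A / MW_L) · R_L)`.

**Isotherm fitting** bounds the Hill fit at h ∈ [0.5, 6] and kd ∈ (0,
10·max P]; `kd_app` is the EC50 of the cooperative curve (an apparent
KD), not a microscopic constant. When the KD approaches the probe
concentration the free-protein approximation fails, so the
depletion model fits the physical root of the binding quadratic with the
probe concentration known from the experiment design.

**Geometry** reduces curved-DNA modelling to a planar circular arc:
contour L = Δbp · 0.34 nm, arc angle θ = Δbp · bend, chord
2(L/θ)sin(θ/2). Curvature uses the N-steps-for-N-bp convention (3° × 40
= 120°); a strict N−1 convention is available by flag. A per-bp polyline
construction serves as an independent cross-check (agreement < 0.01 nm).
Helical face offset folds (Δbp mod 10.5)/10.5·360° into [0, 180°] with a
90° same-face threshold — deliberately generous, since "same face" is a
qualitative notion at 3.24 turns.

**Flexibility** superposes frames by the Kabsch algorithm with the
proper-rotation (det +1) constraint; degenerate (collinear) inputs are
rejected. Fluctuations are measured against an iterated mean structure
(two passes), the standard reference for a B-factor analogy, while RMSD
series use the first frame to mirror "distance from the starting
structure"; `B = (8π²/3)·⟨Δr²⟩` per residue after mass-weighted
averaging (identical to the plain mean for CA-only input). Flexible
regions are residues with `B > median + 3·MAD`, merged across gaps ≤ 2
residues, discarding intervals under 3 residues. A mean + 2·SD threshold
— the textbook rule — fails outright when the flexible region spans a
large fraction of the chain (≈40% here): the loop inflates both mean and
SD until the threshold exceeds the loop itself. The robust median/MAD
baseline stays anchored to the rigid core; the minimum width rejects
isolated noise outliers.

**Tm extraction** computes the 350/330 ratio pointwise, differentiates it
with a quadratic Savitzky–Golay filter over a 5 °C window, and refines
the largest interior |derivative| extremum with an iterated local
quadratic vertex fit (half-width 2.5 °C). Two numerical facts drive those
choices:

1. *Window width.* The derivative peak of a two-state transition with
   ΔH = 300 kJ/mol has FWHM ≈ 6 °C. A window much narrower than that
   (e.g. 1.5 °C) leaves the differentiated noise correlated on the same
   scale as the peak's curvature, and the pointwise argmax then hops more
   than a degree at channel noise as low as 0.2%. With the 5 °C window
   and vertex refinement, recovery is within ~0.2 °C at 0.2% noise and
   ~0.5 °C at 0.5% noise.
2. *Intrinsic skew.* The derivative of the unfolded fraction carries a
   1/T² factor, so its maximum sits below the thermodynamic midpoint by
   ≈ 4R²T³/ΔH² — about 0.85 °C at ΔH = 100 kJ/mol, 0.09 °C at 300, and
   negligible beyond. The extractor reports the derivative extremum
   (the method as practised), not a bias-corrected midpoint; the test
   suite asserts the skew law explicitly.

A curve is declared transition-free when its smoothed ratio deviates from
the best straight line by less than the point-noise level (estimated from
the raw-minus-smoothed residual), which cleanly separates flat or purely
linear curves — noisy or not — from genuine transitions. The ratio
orientation (350/330 vs 330/350) only flips the extremum sign; using
|derivative| makes the two conventions agree to ~1% of Tm.

## Problem sizes

The test suite and acceptance script run: a 138-bp synthetic promoter;
8-concentration sensorgrams at 1 s sampling (481 points each);
16-point titrations; 401-point melt grids; trajectories of 120–150
residues × 400–2000 frames; 200 random sequences against the brute-force
scanner oracle and 50 random coordinate pairs against a
quaternion-parameterised superposition oracle. These sizes make every
Monte-Carlo tolerance in the suite comfortable (e.g. ⟨Δr²⟩ = 3σ² to
within 5% needs ≈ 2000 frames) while keeping the full run in tens of
seconds.

## Known limitations

* The generators share their forward models with the fitters (by
  design): recovery tests validate implementation and identifiability,
  not model adequacy on real instruments.
* The depletion quadratic loses precision below ~1e-9 nM probe
  (catastrophic cancellation); the non-depleting limit is exact there
  anyway.
* The planar-arc model concentrates all bending in one plane; real
  A-tract curvature is phased with the helical screw and sequence
  dependent.
* The B-factor analogy assumes harmonic, isotropic, uncorrelated
  fluctuations — exactly what the generator produces, and exactly what
  real trajectories violate.
* `fit_kinetics` in local mode needs curves that approach saturation for
  Rmax to be identifiable per curve; the median across a dose series is
  robust to the weakly-informative low-concentration fits.
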