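---
title: "Models and methods behind hypernuc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind hypernuc}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models implemented in `hypernuc`, the
assumptions behind them, the parameters that matter and their defaults, the
numerical conventions, and what the synthetic generators do and do not
emulate. It is the design record of the package: every choice that was
genuinely open is stated here with its rationale.

## The chromatin model

Archaeal hypernucleosomes are stacks of histone units on DNA. The
generator (`chromatin_spec()`, `assemble_chromatin()`) reduces this to
three ingredients:

* **Footprint unit** (bp): the DNA protected per histone unit — 30 bp for a
  canonical dimer, 60 bp for a tetramer-forming variant. Particle lengths
  are exact multiples of the unit.
* **Geometric stacking**: after laying one unit a particle extends by a
  further unit with probability `stacking_p`, giving
  `P(k units) = stacking_p^(k-1) (1 - stacking_p)` and mean stack
  `1/(1 - stacking_p)`. This is the simplest one-parameter model of
  cooperative extension; stacking in vivo is known only qualitatively, so
  nothing finer is warranted.
* **Nucleosome-free regions**: a hard exclusion zone of `nfr_halfwidth` bp
  (default 100) around each TSS, extended downstream by
  `round(coupling × rank × halfwidth)` where `rank` is the TSS's expression
  percentile. Promoter-proximal depletion scaling with transcription is
  reported only as a contrast between high- and low-expression gene
  quintiles, without a functional form; a linear rank coupling is the
  least-committed monotone choice.

Placement draws particles one at a time, chooses a free gap with
probability proportional to the number of admissible start positions, and
stops at the target `occupancy_fraction` (achieved within ±5% whenever
geometrically feasible; an unreachable target is an explicit error naming
the constraint).

### Digestion

`digest_chromatin()` models limited MNase digestion: cut positions are a
Poisson process (`cut_rate` per bp) over the *cuttable bonds* of linker
DNA. For a linker occupying `[ls, le)` the cuttable backbone positions are
`ls..le` inclusive — both particle-flanking bonds are exposed — so in the
complete-digestion limit fragments converge exactly to the protected
particle spans. Emitted fragments are the segments between consecutive
cuts; consequently no cut ever falls inside a particle and every particle
lies wholly within one fragment, while partial linker remnants stay
attached at moderate digestion, shifting the fragment ladder slightly above
exact footprint multiples — exactly the behaviour seen on digestion gels.
Fragment ends are then perturbed by Gaussian trimming noise
(`boundary_jitter_sd`, applied to both ends and truncated so start < end)
and fragments below `min_fragment` are discarded. The in vivo default
`min_fragment = 100` mirrors the depletion of short duplexes by library
clean-up; the in vitro presets use 30 bp, the resolution floor of the gel
assay they emulate.

The preset digestion level (`cut_rate = 0.8`/bp, jitter 1 bp) was fixed
once so that the emulated gels reproduce the observed band positions:
canonical-dimer bands near 60/90/120 bp and variant-tetramer bands in the
60–70 and 120–130 bp ranges (the observed ~70/~130 species carry residual
linker ends). This digestion strength also keeps the size-spectrum peaks
narrow, which matters for the period estimator below.

One 10-kb template yields only ~100 fragments per digestion pass, so
`subsample_n` pools independent passes of the same particle map —
digestion of many template copies — before uniform subsampling.

The Poisson-on-linker cutting model is a stand-in for unknown MNase
kinetics, not a claim about the enzyme; it has the right qualitative
behaviour (protection conservation, linker chew-back with digestion
strength) and nothing downstream depends on more.

## MNase-seq statistics

* **Size spectrum**: fragment lengths histogrammed in 1-bp bins over
  1..600 bp, optionally after seeded uniform subsampling so libraries of
  different depth share a y axis.
* **Ladder period**: the lag in 10–100 bp maximising the mean-removed
  autocorrelation of the spectrum. Periodicity in the source assays is
  read off visually; autocorrelation was chosen because it scores every
  candidate spacing on the same footing and breaks ties deterministically
  (first maximum). A flat spectrum signals an explicit
  `hypernuc_flat_spectrum` error rather than returning 0.
* **Size classes**: a fragment joins every class whose ±10% window
  (inclusive bounds) contains its length. For nominal sizes 30 bp apart
  from 300 bp upwards adjacent windows overlap, so membership is per class,
  never a partition.
* **Mid-point tracks**: midpoint of a half-open fragment is
  `floor((start + end)/2)` — a documented convention for even lengths —
  binned at 10 bp and smoothed with a 3-bin moving average whose windows
  shrink at the track ends (mean of the available bins), so no signal is
  invented beyond the boundaries.
* **Particle positions**: summits (local maxima, plateaus collapsed to
  their leftmost bin) whose value reaches the top 1% of track values; ties
  between distinct summits are kept, sorted by coordinate.
* **TSS-anchored maps**: per-TSS windows are summed with minus-strand
  windows coordinate-reversed (strand handling is unstated in the assays;
  reversal puts "downstream" on a common side), normalised by the mean
  over all window bins, and the deproteinised-DNA control is subtracted.
  Normalising chromatin and control *separately before* subtracting makes
  the self-subtraction identity exact (a track anchored against itself is
  identically zero), which is the property the tests pin down; the other
  order would not have it.
* **60-bp-multiple bias**: per 120-bp bin,
  `log2(cov60 + pc) − log2(cov30odd + pc)` with `pc = 0.5`, where coverage
  is *per-base coverage averaged over the bin* and a fragment counts at
  every bin it overlaps. Whether the source analysis counted fragments by
  midpoint or by base overlap is unstated; base overlap was chosen as the
  more common convention, and the difference matters for interdecile
  values on real data, so it is stated here prominently. Writing the
  statistic as a difference of logarithms makes the group-swap
  antisymmetry exact in floating point. Bins with zero coverage in both
  groups get value 0 by pseudocount symmetry and are flagged undefined.
* **Quantiles**: everywhere (interdecile range, summit thresholds) the
  linear-interpolation convention between order statistics (R type 7) is
  used and tested against the closed-form formula.

## The TPM model and step estimator

A tethered bead explores a disc bounded by its tether. The generator
draws per-frame radial excursions from a Rayleigh distribution truncated
at the tether extension `L`, isotropic in angle, plus Gaussian
localization noise (default 2 nm) and an optional anchor random walk.

The Rayleigh **scale is set equal to `L`**. With the hard cutoff this
places the 97.5% radial quantile at ≈0.983 L, so the analysis-side
estimator — the 2.5% most distant positions per bead, pooled over the 25
beads closest to each fitted population RMS, fitted with a skew-normal —
reads the tether length nearly unbiasedly, and differences between
population peaks estimate the true extension steps. A much smaller scale
(e.g. `L/2.5`) would put the extreme quantile near 0.93 L and bias every
peak, and hence the step, low by ~7%; since generator and analyser share
the geometry convention, the scale was fixed at `L` so that the
extreme-position estimator estimates the quantity it is defined to
estimate.

Other conventions: the anchor is the trajectory centroid (optionally after
centred-moving-average drift correction); the "triangular" end-to-end
calculation is `e = sqrt(r² + z_offset²)` with `z_offset` defaulting to 0
(whether the original calculation folds bead radius or tether height into
the triangle is unstated, so the offset is exposed rather than guessed);
mixture fitting is a univariate unequal-variance Gaussian mixture with K
chosen by BIC over 1..5 (deterministic hierarchical initialisation, via
mclust); the skew-normal fit is a direct maximum-likelihood optimisation
(BFGS on location/log-scale/shape, moment-based start values) with the
peak located numerically on the fitted density to 10⁻⁴ nm; pairwise
difference spectra are restricted to adjacent populations by default
(`all_pairs = TRUE` is available), each fitted by the Gaussian MLE (sample
mean and SD of the pooled |eᵢ − eⱼ|).

## Bridging titrations

Recovery is `100 × sample_cpm / reference_cpm`. The titration curve is
fitted as a Hill function
`recovery(c) = plateau · cⁿ / (cⁿ + mⁿ)` by nonlinear least squares
(Levenberg–Marquardt) — the assay itself reports only a half-maximal
point, so the functional form is a labelled modelling choice, and `m` is
flagged when it falls outside the sampled concentration range. Confidence
intervals come from a seeded bootstrap over data points (default 1000
resamples), appropriate for assays run in small numbers of replicates.
The generator adds Poisson counting noise around the expected cpm with a
reference level of ~8000 cpm, the scale of the scintillation counts being
emulated.

## Structure geometry

Atomic models are parsed with bio3d (PDB and mmCIF); the first model of
multi-model files is used, alternate locations resolve to the
highest-occupancy conformer, waters are dropped by default, and a missing
Cα is an explicit error naming chain and residue. The
disulfide-compatibility window (3.5–7.5 Å, bounds inclusive) is applied to
Cα–Cα distances, matching how engineered-cysteine feasibility is assessed
against predicted geometry. Salt bridges use the standard 4.0 Å cutoff
between formal-charge heavy atoms (Lys NZ; Arg NH1/NH2/NE vs Asp OD1/OD2;
Glu OE1/OE2), grouped per residue pair with intra- and inter-chain
contacts flagged separately. Within-dimer versus cross-dimer questions are
served by `cross_chain_pair_scan()`, which enumerates all ordered chain
pairs rather than presuming a dimer grouping.

The synthetic fixture writer emits minimal fixed-width PDB ATOM records
(3-decimal coordinates) and is intended only for constructed test
geometries, labelled as such.

## Reproducibility machinery

All randomness flows through explicit integer seeds. `run_pipeline()`
fans one run seed out to per-stage child seeds by a documented affine map
(`derive_seed()`), records a manifest (package version, configuration,
seed, stage seeds, input checksums, outputs, completed stages), and a
fixed seed reproduces every artifact byte-identically — bedGraph output is
written at full double precision (`%.17g`) precisely so that round trips
and reruns are lossless.

## Problem sizes used in the test and benchmark suites

The packaged suites run entirely on synthetic data at the following
scales, chosen to match the emulated assays while keeping a full run in
the minutes range: 10-kb genomes with 20,000 fragments and 25-seed sweeps
for the ladder-period studies; 3 × 50 beads × 2000 frames for the TPM
three-state preset (about 200 beads per condition, the scale of a TPM flow
cell); 11-point titrations at 8000 reference cpm; and structure fixtures
of 2–4 chains. The mixture-recovery study uses 50 replicates of 150 beads;
the Kolmogorov–Smirnov check of the excursion law uses 10⁵ samples.

## What the generators do not emulate — and what passing means

The chromatin generator produces interval statistics only: no sequence, no
MNase sequence bias, no base-composition effects, no chromatin remodelling
dynamics. Its NFR model is a hard exclusion, not an occupancy gradient.
The TPM generator draws i.i.d. frames — no temporal autocorrelation from
bead diffusion, no blinking/tracking artefacts — and its excursion law is
a convenient truncated Rayleigh, not a polymer model (no worm-like-chain
mechanics). The titration generator assumes ideal Hill behaviour plus
counting noise only. Passing tests therefore demonstrate that the
*analysis* pipeline recovers the parameters of data with the assumed
statistical structure at the stated sizes; they do not validate the
generators as models of real chromatin, real bead dynamics, or enzyme
kinetics, and real-data idiosyncrasies (sequence bias, drift, aggregation)
can degrade estimates in ways these suites cannot detect.

Analyses that inherently need external data — deposited sequencing
libraries, deposited crystal structures — are supported through the same
interfaces (`load_fragments()` for BED/BAM, `load_structure()` for
PDB/mmCIF) but are not part of the self-contained suites.
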