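# hypernuc

Quantitative analysis of archaeal histone-based chromatin, built around
tetramer-forming histone variants.

Archaeal histones are dimers that stack on DNA into *hypernucleosomes*,
each dimer wrapping ~30 bp, so that limited micrococcal nuclease (MNase)
digestion yields a fragment ladder in 30-bp increments. Some variant
histones instead homotetramerise through a C-terminal tetramerization
module, protect ~60 bp of DNA per particle, compact DNA in discrete ~20-nm
steps, and can bridge two DNA duplexes. `hypernuc` implements the analyses
needed to characterise this behaviour quantitatively — from MNase-seq
fragment statistics through single-molecule tethered-particle-motion (TPM)
step analysis and DNA-bridging titrations to distance geometry on atomic
models — together with seeded synthetic-data generators that emulate each
assay so the whole pipeline is testable without external data.

## What it computes

**MNase chromatin analysis.** Fragment-size spectra in 1-bp bins
(`size_spectrum()`), ladder periodicity as the lag maximising the
mean-removed autocorrelation of the spectrum (`estimate_period()`),
particle size classes at ±10% length windows (`classify_particles()`),
smoothed mid-point frequency tracks and top-percentile summit calling
(`midpoint_track()`, `call_particle_positions()`), TSS-anchored,
control-subtracted occupancy matrices (`anchored_map()`), and the local
bias towards tetramer-sized protection (`ratio_60mer()`):

    value(bin) = log2( cov(120±5, 180±5) + pc ) − log2( cov(90±5, 150±5, 210±5) + pc )

computed over 120-bp bins from per-base fragment coverage, summarised by
its interdecile range (`interdecile()`) and between-sample Pearson
correlation (`track_correlation()`).

**TPM step analysis.** Per-bead RMS displacement about the anchor
(`compute_rms()`), Gaussian-mixture deconvolution of bead populations with
BIC-selected K (`fit_populations()`), selection of the 25 beads closest to
each fitted population mean (`select_beads()`), the 2.5% most distant
positions per bead (`extreme_positions()`), end-to-end transformation
e = sqrt(r² + z²) (`end_to_end()`), maximum-likelihood skew-normal fits
whose mode is the population peak (`fit_end_to_end()`), and the
adjacent-population pairwise difference spectrum whose fitted Gaussian
means give the compaction step (`pairwise_peaks()`, `tpm_pipeline()`).

**DNA bridging.** Recovery % = 100 · sample_cpm / reference_cpm
(`recovery()`) and the half-maximal protein concentration from a Hill-curve
fit with bootstrap confidence intervals (`fit_midpoint()`).

**Structure geometry.** PDB/mmCIF loading (`load_structure()`), inter-chain
Cα distances and chain-pair scans (`ca_distance()`,
`cross_chain_pair_scan()`), the 3.5–7.5 Å disulfide-compatibility window
(`disulfide_compatible()`), and salt-bridge detection between charged
side-chain atoms at a 4 Å cutoff (`find_salt_bridges()`).

**Synthetic generators.** `assemble_chromatin()` / `digest_chromatin()`
(geometric stacking of 30- or 60-bp footprint units, Poisson linker
cutting, NFR exclusion around TSSs scaled by expression rank),
`simulate_tpm()` (truncated-Rayleigh bead excursions in discrete compaction
populations), `simulate_titration()` (Hill curve with Poisson counting
noise), and `write_fixture_structure()` (minimal synthetic PDB fixtures).

## Worked example

```r
library(hypernuc)

## 10-kb genome chromatinised with the tetramer-forming variant preset,
## digested to 20,000 fragments
preset    <- chromatin_preset("variant-tetramer", subsample_n = 20000)
particles <- assemble_chromatin(preset$chromatin, seed = 1)
frags     <- digest_chromatin(particles, preset$chromatin$genome_length,
                              preset$digestion, seed = 2)
estimate_period(size_spectrum(frags, max_size = 600), 10, 100)
#> $period
#> [1] 60
#> $score
#> [1] 0.4361031
```

The estimated ladder period of 60 bp (autocorrelation score 0.44) is the
signature of tetramer-sized protection; the canonical-dimer preset returns
30 bp on the same analysis.

```r
## three-state TPM compaction: populations at 150/132/112 nm tether length
traj <- simulate_tpm(tpm_preset_three_state(), seed = 3)
res  <- tpm_pipeline(traj)
res$model
#> <population_model> K = 3 (BIC -650.1)
#>   label   mean_nm     sd_nm    weight
#> 1     I 101.67309 0.8613934 0.3333333
#> 2    II  89.32813 0.5940340 0.3333333
#> 3   III  75.82027 0.4574540 0.3333333
round(vapply(res$samples, `[[`, numeric(1), "peak"), 1)
#> [1] 148.4 130.6 111.1
round(res$step_nm, 2)
#> [1] 18.88
```

The mixture finds the three RMS populations, the extreme-position
skew-normal peaks recover the three tether lengths to within ~1.5 nm, and
the mean adjacent step of ~19 nm reports the ~60-bp DNA increment wrapped
per binding event.

```r
## bridging titration: half-maximal recovery concentration
ser <- simulate_titration(titration_spec(), seed = 4)
fit_midpoint(ser, n_boot = 200, seed = 5)
#> <midpoint_fit> midpoint 2.52 uM, Hill n 3.72, plateau 80.8%
```

A reproducible multi-stage run with a manifest:

```r
run_pipeline(list(pipeline = list(
  list(stage = "simulate_chromatin", preset = "canonical-dimer"),
  list(stage = "spectrum"),
  list(stage = "ratio60"),
  list(stage = "report"))), outdir = "out", seed = 7)
```

A thin command-line front-end over the same functions is installed at
`inst/cli/hypernuc.R` (`Rscript hypernuc.R simulate chromatin --seed 7 ...`).

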