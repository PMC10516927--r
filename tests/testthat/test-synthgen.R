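test_that("assembled particles are unit multiples, non-overlapping, NFR-free", {
  spec <- chromatin_spec(genome_length = 20000L, n_tss = 5L,
                         footprint_unit = 60L, stacking_p = 0.5,
                         occupancy_fraction = 0.6, nfr_halfwidth = 80L)
  p <- assemble_chromatin(spec, seed = 11)
  expect_true(all((p$end - p$start) %% 60L == 0))
  expect_true(all((p$end - p$start) / 60L == p$units))
  expect_true(all(utils::head(p$end, -1) <= utils::tail(p$start, -1)))
  tss <- attr(p, "tss")
  for (i in seq_len(nrow(tss))) {
    zs <- tss$position[i] - 80L; ze <- tss$position[i] + 80L
    expect_true(all(p$end <= zs | p$start > ze))
  }
  cov <- sum(p$end - p$start) / spec$genome_length
  expect_lt(abs(cov - 0.6), 0.05)
})

test_that("zero occupancy and degenerate stacking behave as limits", {
  s0 <- chromatin_spec(occupancy_fraction = 0)
  expect_identical(nrow(assemble_chromatin(s0, 1)), 0L)
  s1 <- chromatin_spec(footprint_unit = 30L, stacking_p = 0,
                       occupancy_fraction = 0.4)
  p <- assemble_chromatin(s1, 2)
  expect_true(all(p$end - p$start == 30L))
})

test_that("mean particle length matches the geometric-stacking oracle", {
  spec <- chromatin_spec(genome_length = 200000L, n_tss = 2L,
                         footprint_unit = 60L, stacking_p = 0.5,
                         occupancy_fraction = 0.3, nfr_halfwidth = 50L)
  p <- assemble_chromatin(spec, seed = 7)
  set.seed(99)
  oracle <- mean(60 * (1 + rgeom(1e4, prob = 0.5)))  # ~ 120 bp
  expect_lt(abs(mean(p$end - p$start) - oracle), 8)
  expect_lt(abs(oracle - 120), 3)
})

test_that("infeasible occupancy raises an error naming the constraint", {
  spec <- chromatin_spec(genome_length = 1000L, n_tss = 4L,
                         occupancy_fraction = 0.95, nfr_halfwidth = 200L)
  expect_error(assemble_chromatin(spec, 1), "infeasible occupancy")
})

test_that("assembly and digestion are bit-identical under a fixed seed", {
  pr <- chromatin_preset("canonical-dimer", subsample_n = 500L)
  p1 <- assemble_chromatin(pr$chromatin, 42)
  p2 <- assemble_chromatin(pr$chromatin, 42)
  expect_identical(p1, p2)
  f1 <- digest_chromatin(p1, 10000L, pr$digestion, 43)
  f2 <- digest_chromatin(p2, 10000L, pr$digestion, 43)
  expect_identical(as.data.frame(f1), as.data.frame(f2))
})

test_that("digestion limits: no cuts and complete linker digestion", {
  p <- data.frame(start = 100L, end = 130L, units = 1L)
  no_cut <- digestion_spec(cut_rate = 0, boundary_jitter_sd = 0,
                           min_fragment = 0L)
  f <- digest_chromatin(p, 1000L, no_cut, 1)
  expect_identical(nrow(f), 1L)
  expect_identical(c(f$start, f$end), c(0L, 1000L))

  full <- digestion_spec(cut_rate = 50, boundary_jitter_sd = 0,
                         min_fragment = 0L)
  f2 <- digest_chromatin(p, 1000L, full, 2)
  big <- f2[f2$end - f2$start >= 30, ]
  expect_identical(nrow(big), 1L)
  expect_identical(c(big$start, big$end), c(100L, 130L))
})

test_that("digestion conserves protection for tandem particles", {
  ## 6 particles of 30 bp with 10-bp linkers
  starts <- 10L + (0:5) * 40L
  p <- data.frame(start = starts, end = starts + 30L, units = 1L)
  spec <- digestion_spec(cut_rate = 0.1, boundary_jitter_sd = 0,
                         min_fragment = 0L)
  for (s in 1:20) {
    f <- digest_chromatin(p, 260L, spec, s)
    ## fragments tile the template
    f <- f[order(f$start), ]
    expect_identical(f$start[1], 0L)
    expect_identical(f$end[nrow(f)], 260L)
    expect_true(all(utils::tail(f$start, -1) == utils::head(f$end, -1)))
    ## no fragment boundary falls strictly inside a particle
    inner <- setdiff(c(f$start, f$end), c(0L, 260L))
    for (b in inner) expect_false(any(b > p$start & b < p$end))
    ## each particle lies wholly within one fragment
    for (i in seq_len(nrow(p))) {
      expect_true(any(f$start <= p$start[i] & f$end >= p$end[i]))
    }
    ## protected fragments carry whole particles plus at most flanking linker
    lens <- f$end - f$start
    with_part <- vapply(seq_len(nrow(f)), function(k) {
      sum(p$start >= f$start[k] & p$end <= f$end[k])
    }, numeric(1))
    expect_true(all(lens[with_part > 0] >= 30 * with_part[with_part > 0]))
  }
})

test_that("TPM excursions respect the tether-length truncation bound", {
  spec <- tpm_population_spec(data.frame(end_to_end_nm = 120, n_beads = 3),
                              frames_per_bead = 500L,
                              localization_noise_sd = 0, anchor_drift_sd = 0)
  traj <- simulate_tpm(spec, 5)
  r <- sqrt(traj$x_nm^2 + traj$y_nm^2)
  expect_true(all(r <= 120))
})

test_that("TPM radial distances follow the documented truncated Rayleigh", {
  spec <- tpm_population_spec(data.frame(end_to_end_nm = 150, n_beads = 50),
                              frames_per_bead = 2000L,
                              localization_noise_sd = 0, anchor_drift_sd = 0)
  traj <- simulate_tpm(spec, 8)
  r <- sort(sqrt(traj$x_nm^2 + traj$y_nm^2))
  emp <- seq_along(r) / length(r)
  theo <- oracle_ptrunc_rayleigh(r, scale = 150, cutoff = 150)
  expect_lt(max(abs(emp - theo)), 0.02)  # KS distance at 1e5 samples
})

test_that("extreme-position estimates track the tether lengths", {
  spec <- tpm_preset_three_state()
  traj <- simulate_tpm(spec, 21)
  for (pop in 1:3) {
    L <- spec$populations$end_to_end_nm[pop]
    sub <- traj[traj$truth_label == pop, ]
    est <- vapply(split(sub, sub$bead_id), function(b) {
      mean(end_to_end(extreme_positions(b, 0.025)))
    }, numeric(1))
    expect_lt(abs(mean(est) - L), 3)
  }
})

test_that("titration follows the Hill curve", {
  ## near-noiseless regime: large reference counts
  spec <- titration_spec(midpoint_um = 2.5, hill_n = 4,
                         max_recovery_pct = 80,
                         concentrations_um = c(0, 1, 2, 2.5, 3, 5),
                         reference_cpm = 1e7)
  ser <- simulate_titration(spec, 3)
  hand <- c(0,
            80 * 1^4 / (1^4 + 2.5^4),
            80 * 2^4 / (2^4 + 2.5^4),
            40,
            80 * 3^4 / (3^4 + 2.5^4),
            80 * 5^4 / (5^4 + 2.5^4))
  expect_equal(ser$recovery_pct, hand, tolerance = 5e-3)
  expect_identical(ser$sample_cpm[1], 0L)  # zero concentration, zero signal
})

test_that("fixture structures round-trip through the PDB path", {
  g <- data.frame(chain = c("A", "B"), resno = 1L, resid = "GLY",
                  elety = "CA", x = 0, y = 0, z = c(0, 11.1))
  f <- withr::local_tempfile(fileext = ".pdb")
  write_fixture_structure(g, f)
  m <- load_structure(f)
  expect_equal(ca_distance(m, list("A", 1), list("B", 1))$distance, 11.1,
               tolerance = 1e-9)

  expect_error(write_fixture_structure(g[0, ], f), "nonempty")
  bad <- g; bad$chain <- c("AB", "B")
  expect_error(write_fixture_structure(bad, f), "chain")

  helix <- helix_ca_trace(10)
  fh <- withr::local_tempfile(fileext = ".pdb")
  write_fixture_structure(helix, fh)
  mh <- load_structure(fh)
  d <- vapply(1:9, function(i) {
    ca_distance(mh, list("A", i), list("A", i + 1))$distance
  }, numeric(1))
  expect_true(all(abs(d - 3.8) <= 0.001))
})
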