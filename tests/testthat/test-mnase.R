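test_that("BED fragments pass through and BAM pairs match the BED route", {
  bed <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr1\t100\t130\tf1\t30\t.",
               "chr1\t200\t250\tf2\t50\t.",
               "chr1\t300\t420\tf3\t120\t."), bed)
  fs <- load_fragments(bed, elements = c(chr1 = 10000L))
  expect_identical(fs$start, c(100L, 200L, 300L))
  expect_identical(fs$end, c(130L, 250L, 420L))

  ## same three pairs through a BAM constructed from SAM text
  sam <- withr::local_tempfile(fileext = ".sam")
  rec <- function(id, pos, tlen) {
    c(sprintf("%s\t99\tchr1\t%d\t60\t25M\t=\t%d\t%d\t*\t*",
              id, pos, pos + tlen - 25, tlen),
      sprintf("%s\t147\tchr1\t%d\t60\t25M\t=\t%d\t%d\t*\t*",
              id, pos + tlen - 25, pos, -tlen))
  }
  writeLines(c("@HD\tVN:1.6\tSO:coordinate", "@SQ\tSN:chr1\tLN:10000",
               rec("r1", 101, 30), rec("r2", 201, 50), rec("r3", 301, 120)),
             sam)
  bam <- Rsamtools::asBam(sam, withr::local_tempfile(),
                          overwrite = TRUE, indexDestination = TRUE)
  fb <- load_fragments(bam)
  expect_identical(fb$element, fs$element)
  expect_identical(fb$start, fs$start)
  expect_identical(fb$end, fs$end)

  empty <- withr::local_tempfile(fileext = ".bed")
  file.create(empty)
  expect_warning(fe <- load_fragments(empty, elements = c(chr1 = 100L)),
                 "empty")
  expect_identical(nrow(fe), 0L)

  writeLines("chrX\t0\t50\tf\t50\t.", bed)
  expect_warning(load_fragments(bed, elements = c(chr1 = 100L)),
                 "undeclared")
})

test_that("size spectrum counts, subsampling and mass fractions", {
  f90 <- frags_with_lengths(rep(90L, 20))
  sp <- size_spectrum(f90, max_size = 200L)
  expect_identical(unname(sp$counts[90]), 20L)
  expect_identical(sum(sp$counts), 20L)

  frg <- frags_with_lengths(c(rep(60L, 5000), rep(90L, 3000), rep(120L, 2000)))
  full <- size_spectrum(frg, max_size = 300L)
  same <- size_spectrum(frg, max_size = 300L, subsample_n = 10000L, seed = 1)
  expect_identical(full$counts, same$counts)
  expect_equal(unname(full$counts[c(60, 90, 120)]) / full$total,
               c(0.5, 0.3, 0.2))
  expect_error(size_spectrum(frg, subsample_n = 1e6), "exceeds")
})

test_that("period estimation matches the brute-force autocorrelation oracle", {
  ladder30 <- frags_with_lengths(rep(c(60L, 90L, 120L, 150L), each = 50))
  sp <- size_spectrum(ladder30, max_size = 300L)
  est <- estimate_period(sp, 10, 100)
  lags <- 10:100
  oracle <- lags[which.max(oracle_autocorr(sp$counts, lags))]
  expect_identical(est$period, oracle)
  expect_identical(est$period, 30L)

  ladder60 <- frags_with_lengths(rep(c(70L, 130L), each = 100))
  sp60 <- size_spectrum(ladder60, max_size = 300L)
  expect_identical(estimate_period(sp60)$period, 60L)

  flat <- frags_with_lengths(1:300)
  spf <- size_spectrum(flat, max_size = 300L)
  expect_error(estimate_period(spf), class = "hypernuc_flat_spectrum")
})

test_that("particle size-class windows are inclusive, per-class memberships", {
  frg <- frags_with_lengths(c(100L, 110L, 121L, 150L, 166L))
  cls <- classify_particles(frg, c(110L, 150L))
  expect_identical(sort(fragment_lengths(cls[["110"]]$members)),
                   c(100L, 110L, 121L))
  expect_identical(fragment_lengths(cls[["150"]]$members), 150L)

  ## adjacent 30-bp-spaced nominals >= 300 bp have overlapping windows
  frg2 <- frags_with_lengths(310L)
  cls2 <- classify_particles(frg2, c(300L, 330L))
  expect_identical(nrow(cls2[["300"]]$members), 1L)
  expect_identical(nrow(cls2[["330"]]$members), 1L)
})

test_that("mid-point tracks bin and smooth as declared", {
  fs <- fragment_set(data.frame(element = "e1", start = 100L, end = 130L),
                     elements = c(e1 = 300L))
  raw <- midpoint_track(fs, bin_size = 10L, smooth = FALSE)
  expect_identical(which(raw$values > 0), 12L)  # midpoint 115 -> [110,120)

  ## raw [0,3,0] smooths to centre 1.0 with shrinking edge windows
  fs3 <- fragment_set(data.frame(element = "e1",
                                 start = c(10L, 10L, 10L),
                                 end = c(16L, 16L, 16L)),
                      elements = c(e1 = 30L))
  sm <- midpoint_track(fs3, bin_size = 10L)
  expect_equal(sm$values, c(1.5, 1.0, 1.5))

  ## smoothing is the same as direct convolution on interior bins
  set.seed(4)
  st <- sample.int(960, 100) - 1L
  fsr <- fragment_set(data.frame(element = "e1", start = st, end = st + 30L),
                      elements = c(e1 = 1000L))
  raw2 <- midpoint_track(fsr, bin_size = 10L, smooth = FALSE)$values
  sm2 <- midpoint_track(fsr, bin_size = 10L)$values
  conv <- stats::filter(raw2, rep(1 / 3, 3), sides = 2)
  inner <- 2:(length(raw2) - 1)
  expect_equal(sm2[inner], as.numeric(conv[inner]))
  expect_equal(sum(sm2[inner]), sum(as.numeric(conv[inner])))
})

test_that("particle positions are the top-percentile summits", {
  mk_track <- function(values, bin_size = 10L) {
    structure(list(element = "e1", bin_size = bin_size, values = values,
                   smoothing = "3-bin moving average", normalized = FALSE),
              class = "midpoint_track")
  }
  spike <- mk_track(c(rep(0.1, 5), 5, rep(0.1, 4)))
  expect_identical(call_particle_positions(spike), 50L)

  twin <- mk_track(c(0.1, 4, 0.1, 0.2, 4, 0.1))
  expect_identical(call_particle_positions(twin, percentile = 40), c(10L, 40L))

  expect_warning(p <- call_particle_positions(mk_track(rep(1, 20))),
                 "constant")
  expect_identical(p, integer(0))

  ## 12 planted peaks in a 1000-bin track, verified by exhaustive scan
  set.seed(9)
  v <- runif(1000, 0, 1)
  at <- round(seq(40, 990, length.out = 12))
  v[at] <- 10 + runif(12)
  tr <- mk_track(v)
  got <- call_particle_positions(tr, percentile = 1.2)
  thr <- quantile(v, 1 - 0.012, names = FALSE)
  oracle <- integer(0)
  for (i in seq_along(v)) {
    l <- if (i > 1) v[i - 1] else -Inf
    r <- if (i < length(v)) v[i + 1] else -Inf
    if (v[i] >= l && v[i] >= r && v[i] >= thr && v[i] != l) {
      oracle <- c(oracle, (i - 1L) * 10L)
    }
  }
  expect_identical(got, oracle)
  expect_identical(got, as.integer(at - 1L) * 10L)
})

test_that("anchored maps normalise, reverse minus strands and subtract", {
  mk_track <- function(values) {
    structure(list(element = "e1", bin_size = 10L, values = values,
                   smoothing = "3-bin moving average", normalized = FALSE),
              class = "midpoint_track")
  }
  tss <- data.frame(element = "e1", position = c(300L, 600L),
                    strand = c("+", "-"), expression = c(1, 2))
  set.seed(2)
  chrom <- mk_track(runif(100, 1, 5))
  ## self-subtraction is identically zero
  m0 <- anchored_map(list(`150` = chrom), list(`150` = chrom), tss,
                     flank = 100L)
  expect_true(all(m0 == 0))

  ## uniform chromatin with zero control is identically one
  uni <- mk_track(rep(3, 100))
  zero <- mk_track(rep(0, 100))
  m1 <- anchored_map(list(`150` = uni), list(`150` = zero), tss, flank = 100L)
  expect_true(all(m1 == 1))
  expect_identical(dim(m1), c(1L, 21L))

  ## planted depletion downstream of each TSS shows up below upstream signal
  depl <- rep(4, 100)
  depl[31:40] <- 0.2   # downstream of + TSS at bin 31
  depl[51:60] <- 0.2   # downstream of - TSS at bin 61 (reversed window)
  md <- anchored_map(list(`150` = mk_track(depl)), list(`150` = zero),
                     tss, flank = 100L)
  cols <- as.integer(colnames(md))
  expect_lt(mean(md[, cols > 0]), mean(md[, cols < 0]))

  ## TSS whose window leaves the element are skipped and counted
  tss2 <- rbind(tss, data.frame(element = "e1", position = 30L,
                                strand = "+", expression = 1))
  m2 <- anchored_map(list(`150` = uni), list(`150` = zero), tss2,
                     flank = 100L)
  expect_identical(attr(m2, "skipped"), 1L)  # one TSS window out of bounds
})
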