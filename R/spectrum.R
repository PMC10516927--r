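#' Fragment insert-size spectrum
#'
#' Histogram of fragment lengths in 1-bp bins over a declared size range,
#' optionally after seeded uniform subsampling without replacement (used to
#' place libraries of different depth on a common y axis).
#'
#' @param frags a [fragment_set()].
#' @param max_size upper end of the size range (bins run 1..`max_size`).
#' @param subsample_n fragments to retain, or `NULL` for all; must not exceed
#'   the total.
#' @param seed seed for the subsample.
#' @return object of class `size_spectrum`: list with `counts` (named integer
#'   vector, one bin per bp), `total`, and `subsample_n`.
#' @export
size_spectrum <- function(frags, max_size = 600L, subsample_n = NULL,
                          seed = 1L) {
  len <- fragment_lengths(frags)
  if (!is.null(subsample_n)) {
    .assert(subsample_n <= length(len),
            "subsample_n (%d) exceeds fragment count (%d)",
            subsample_n, length(len))
    set.seed(as.integer(seed))
    len <- len[sample.int(length(len), subsample_n)]
  }
  len <- len[len >= 1 & len <= max_size]
  counts <- tabulate(len, nbins = max_size)
  names(counts) <- seq_len(max_size)
  structure(list(counts = counts, total = sum(counts),
                 subsample_n = subsample_n),
            class = "size_spectrum")
}

#' @export
print.size_spectrum <- function(x, ...) {
  cat(sprintf("<size_spectrum> %d fragments over %d 1-bp bins\n",
              x$total, length(x$counts)))
  invisible(x)
}

#' Estimate the ladder period of a size spectrum
#'
#' Finds the dominant spacing of the fragment-size ladder as the lag
#' maximising the mean-removed autocorrelation of the 1-bp spectrum within
#' `[min_period, max_period]`.  A 30-bp period is the signature of chromatin
#' built from single histone-dimer units; a 60-bp period indicates
#' tetramer-sized protection.
#'
#' @param spec a [size_spectrum()]; must cover at least `3 * max_period` bins.
#' @param min_period,max_period search window in bp.
#' @return list with `period` (bp) and `score` (normalised autocorrelation at
#'   that lag).  A flat spectrum has no period: an error of class
#'   `hypernuc_flat_spectrum` is signalled rather than returning 0.
#' @export
estimate_period <- function(spec, min_period = 10L, max_period = 100L) {
  stopifnot(inherits(spec, "size_spectrum"))
  x <- as.numeric(spec$counts)
  .assert(length(x) >= 3 * max_period,
          "spectrum covers %d bins; need >= 3 * max_period = %d",
          length(x), 3 * max_period)
  x <- x - mean(x)
  denom <- sum(x^2)
  if (denom == 0) {
    stop(structure(class = c("hypernuc_flat_spectrum", "error", "condition"),
                   list(message = "flat spectrum: ladder period undefined",
                        call = sys.call(-1))))
  }
  lags <- seq.int(min_period, max_period)
  ac <- vapply(lags, function(l) {
    n <- length(x) - l
    sum(x[seq_len(n)] * x[seq_len(n) + l]) / denom
  }, numeric(1))
  best <- which.max(ac)
  list(period = lags[best], score = ac[best])
}
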