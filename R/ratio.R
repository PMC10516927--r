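#' Log2 coverage bias of 60-bp multiples versus odd 30-bp multiples
#'
#' For each 120-bp genomic bin, compares mean per-base coverage from
#' fragments whose length is a 60-bp multiple (`120 +/- 5` or `180 +/- 5` bp,
#' i.e. tetramer-sized protection) against coverage from odd 30-bp multiples
#' (`90`, `150`, `210 +/- 5` bp, dimer-stack sizes incompatible with pure
#' tetramer protection):
#' `value = log2((cov60 + pc) / (cov30odd + pc))`.
#' A fragment contributes base coverage to every bin it overlaps.  Bins with
#' zero coverage in both groups get value 0 by pseudocount symmetry and are
#' flagged as undefined.
#'
#' @param frags a [fragment_set()].
#' @param element element to tile (default: first declared element).
#' @param bin_size bin width in bp (default 120).
#' @param pseudocount added to both mean coverages (default 0.5).
#' @param sixty_sizes,odd_sizes nominal lengths of the two fragment groups.
#' @param size_halfwidth half-width in bp of each size window (default 5).
#' @return object of class `ratio_track`: list with `element`, `bin_size`,
#'   `values` (log2 ratio per bin), `defined` (logical; `FALSE` where both
#'   coverages were zero), `pseudocount`.
#' @export
ratio_60mer <- function(frags, element = NULL, bin_size = 120L,
                        pseudocount = 0.5,
                        sixty_sizes = c(120L, 180L),
                        odd_sizes = c(90L, 150L, 210L),
                        size_halfwidth = 5L) {
  .assert(pseudocount > 0, "pseudocount must be > 0")
  elements <- attr(frags, "elements")
  if (is.null(element)) element <- names(elements)[1]
  .assert(element %in% names(elements), "undeclared element: %s", element)
  elen <- elements[[element]]
  sub <- frags[frags$element == element, , drop = FALSE]
  len <- sub$end - sub$start
  in_group <- function(sizes) {
    sel <- rep(FALSE, length(len))
    for (s in sizes) sel <- sel | (abs(len - s) <= size_halfwidth)
    sel
  }
  cov60 <- .binned_mean_coverage(sub[in_group(sixty_sizes), ], elen, bin_size)
  cov30 <- .binned_mean_coverage(sub[in_group(odd_sizes), ], elen, bin_size)
  defined <- !(cov60 == 0 & cov30 == 0)
  ## difference of logs so that swapping the groups negates bin-wise exactly
  values <- log2(cov60 + pseudocount) - log2(cov30 + pseudocount)
  structure(list(element = element, bin_size = as.integer(bin_size),
                 values = values, defined = defined,
                 pseudocount = pseudocount),
            class = "ratio_track")
}

## mean per-base coverage of each bin tiling [0, elen)
.binned_mean_coverage <- function(records, elen, bin_size) {
  nbin <- ceiling(elen / bin_size)
  bs <- (seq_len(nbin) - 1L) * bin_size + 1L
  be <- pmin(seq_len(nbin) * bin_size, elen)
  if (!nrow(records)) return(numeric(nbin))
  cov <- IRanges::coverage(
    IRanges::IRanges(start = records$start + 1L, end = records$end),
    width = elen)
  v <- IRanges::Views(cov, start = bs, end = be)
  IRanges::viewMeans(v)
}

#' Interdecile range of a ratio track
#'
#' 90th minus 10th percentile of the defined bin values, using the linear
#' interpolation quantile convention (R type 7).  A tight interdecile range
#' indicates the absence of genomic regions with a strong bias towards
#' 60-bp-multiple protection.
#'
#' @param track a [ratio_60mer()] track (or any list with `values` and
#'   `defined`).
#' @return the interdecile range (dimensionless, log2 units).
#' @export
interdecile <- function(track) {
  v <- track$values[track$defined]
  .assert(length(v) >= 10, "need >= 10 defined bins, got %d", length(v))
  q <- quantile(v, c(0.1, 0.9), names = FALSE, type = 7)
  q[2] - q[1]
}

#' Pearson correlation between two ratio tracks
#'
#' Standard product-moment correlation over bins defined in both tracks; used
#' to compare biological samples digested with different MNase concentrations.
#'
#' @param a,b [ratio_60mer()] tracks on the same element and binning.
#' @return Pearson's rho.
#' @export
track_correlation <- function(a, b) {
  .assert(identical(a$element, b$element) &&
          identical(a$bin_size, b$bin_size) &&
          length(a$values) == length(b$values),
          "tracks must share element and binning")
  keep <- a$defined & b$defined
  .assert(sum(keep) >= 3, "need >= 3 shared defined bins, got %d", sum(keep))
  cor(a$values[keep], b$values[keep])
}
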