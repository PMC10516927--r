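#' Write a binned track as bedGraph
#'
#' One interval per bin (0-based half-open), values written at full double
#' precision so that bin-aligned tracks round-trip losslessly through
#' [read_bedgraph()].  Negative values (e.g. after background subtraction)
#' are preserved.
#'
#' @param track a [midpoint_track()] or [ratio_60mer()] track.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path) {
  elen_hint <- length(track$values) * track$bin_size
  start <- (seq_along(track$values) - 1L) * track$bin_size
  end <- pmin(start + track$bin_size, elen_hint)
  lines <- sprintf("%s\t%d\t%d\t%.17g", track$element, start, end,
                   track$values)
  writeLines(lines, path)
  invisible(path)
}

#' Read a bedGraph file back into a binned track
#'
#' Intervals must be non-overlapping and tile a regular bin grid on a single
#' element; overlapping intervals are an error.
#'
#' @param path bedGraph file.
#' @return list of class `bin_track` with `element`, `bin_size`, `values`.
#' @export
read_bedgraph <- function(path) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  .assert(length(gr) > 0, "empty bedGraph: %s", path)
  gr <- sort(gr)
  starts <- GenomicRanges::start(gr) - 1L
  ends <- GenomicRanges::end(gr)
  if (any(utils::head(ends, -1) > utils::tail(starts, -1) &
          as.character(utils::head(GenomicRanges::seqnames(gr), -1)) ==
            as.character(utils::tail(GenomicRanges::seqnames(gr), -1)))) {
    stop("overlapping intervals in bedGraph: ", path, call. = FALSE)
  }
  element <- as.character(GenomicRanges::seqnames(gr))[1]
  .assert(all(as.character(GenomicRanges::seqnames(gr)) == element),
          "multi-element bedGraph not supported: %s", path)
  widths <- ends - starts
  bin_size <- as.integer(widths[1])
  structure(list(element = element, bin_size = bin_size,
                 values = as.numeric(GenomicRanges::score(gr))),
            class = "bin_track")
}
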