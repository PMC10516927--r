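#' Fragment set container
#'
#' A set of MNase-protected genomic fragments: 0-based half-open intervals on
#' named DNA elements (chromosome / plasmid), plus the declared element-length
#' table they must fall on.
#'
#' @param records data.frame with columns `element`, `start`, `end`
#'   (0-based half-open).
#' @param elements named integer vector of element lengths (bp).  Records on
#'   undeclared elements are rejected with their count reported.
#' @param provenance free-text label recording where the fragments came from.
#' @return data.frame of class `fragment_set` with attributes `elements` and
#'   `provenance`.
#' @export
fragment_set <- function(records, elements, provenance = "unknown") {
  .assert(all(c("element", "start", "end") %in% names(records)),
          "records need columns element, start, end")
  records$start <- as.integer(records$start)
  records$end <- as.integer(records$end)
  .assert(all(records$start < records$end) || nrow(records) == 0,
          "all records must satisfy start < end")
  .assert(!is.null(names(elements)) && all(elements > 0),
          "elements must be a named vector of positive lengths")
  bad <- !(records$element %in% names(elements))
  if (any(bad)) {
    warning(sprintf("rejected %d record(s) on undeclared elements", sum(bad)))
    records <- records[!bad, , drop = FALSE]
  }
  rownames(records) <- NULL
  structure(records[, c("element", "start", "end")],
            class = c("fragment_set", "data.frame"),
            elements = setNames(as.integer(elements), names(elements)),
            provenance = provenance)
}

#' @export
print.fragment_set <- function(x, ...) {
  cat(sprintf("<fragment_set> %d fragments on %d element(s) [%s]\n",
              nrow(x), length(attr(x, "elements")), attr(x, "provenance")))
  if (nrow(x)) print(utils::head(as.data.frame(x), 5))
  invisible(x)
}

fragment_lengths <- function(frags) frags$end - frags$start

#' Load fragments from BED or BAM
#'
#' BED records (0-based half-open) pass through unchanged.  For BAM, properly
#' paired first-mate alignments are converted to
#' `(leftmost start, leftmost start + template length)`; pairs with
#' non-positive template length are skipped with a warning count, and mates
#' below `min_mapq` are dropped.
#'
#' @param path BED (`.bed`) or coordinate-sorted BAM (`.bam`) file.
#' @param elements named vector of declared element lengths; for BAM, defaults
#'   to the BAM header sequence lengths.
#' @param min_mapq minimum mapping quality (BAM only).
#' @return a [fragment_set()].
#' @export
load_fragments <- function(path, elements = NULL, min_mapq = 0L) {
  .assert(file.exists(path), "file not found: %s", path)
  ext <- tolower(tools::file_ext(path))
  if (ext == "bam") {
    .load_fragments_bam(path, elements, min_mapq)
  } else {
    .load_fragments_bed(path, elements)
  }
}

.load_fragments_bed <- function(path, elements) {
  if (file.size(path) == 0) {
    warning("empty fragment file: ", path)
    return(fragment_set(data.frame(element = character(), start = integer(),
                                   end = integer()),
                        elements = elements %||% c(none = 1L),
                        provenance = path))
  }
  gr <- rtracklayer::import(path, format = "BED")
  rec <- data.frame(element = as.character(GenomicRanges::seqnames(gr)),
                    start = GenomicRanges::start(gr) - 1L,
                    end = GenomicRanges::end(gr),
                    stringsAsFactors = FALSE)
  if (is.null(elements)) {
    elements <- tapply(rec$end, rec$element, max)
    elements <- setNames(as.integer(elements), names(elements))
  }
  fragment_set(rec, elements, provenance = path)
}

.load_fragments_bam <- function(path, elements, min_mapq) {
  hdr <- Rsamtools::scanBamHeader(path)[[1]]$targets
  if (is.null(elements)) elements <- hdr
  flag <- Rsamtools::scanBamFlag(isProperPair = TRUE, isFirstMateRead = TRUE,
                                 isUnmappedQuery = FALSE)
  param <- Rsamtools::ScanBamParam(
    flag = flag, what = c("rname", "pos", "isize", "mapq"))
  b <- Rsamtools::scanBam(path, param = param)[[1]]
  keep <- !is.na(b$pos) & !is.na(b$isize)
  if (min_mapq > 0) keep <- keep & !is.na(b$mapq) & b$mapq >= min_mapq
  rname <- as.character(b$rname)[keep]
  pos <- b$pos[keep]; isize <- b$isize[keep]
  neg <- isize <= 0
  if (any(neg)) warning(sprintf("skipped %d pair(s) with non-positive template length",
                                sum(neg)))
  rname <- rname[!neg]; pos <- pos[!neg]; isize <- isize[!neg]
  fragment_set(data.frame(element = rname, start = pos - 1L,
                          end = pos - 1L + isize, stringsAsFactors = FALSE),
               elements = elements, provenance = path)
}

#' Write fragments as 6-column BED
#'
#' Columns: element, start, end, name, score = fragment length, strand ".".
#'
#' @param frags a [fragment_set()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fragments_bed <- function(frags, path) {
  df <- data.frame(frags$element, frags$start, frags$end,
                   sprintf("f%d", seq_len(nrow(frags))),
                   frags$end - frags$start, ".")
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read / write a TSS table
#'
#' Tab-separated with header columns `element`, `position` (0-based),
#' `strand` (`+`/`-`), `expression`.
#'
#' @param tss data.frame with those columns.
#' @param path file path.
#' @return `read_tss_table()` returns the data.frame; `write_tss_table()`
#'   returns `path` invisibly.
#' @export
write_tss_table <- function(tss, path) {
  utils::write.table(tss[, c("element", "position", "strand", "expression")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tss_table
#' @export
read_tss_table <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  .assert(all(c("element", "position", "strand", "expression") %in% names(df)),
          "TSS table needs columns element, position, strand, expression")
  df
}
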