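#' TSS-anchored occupancy matrix
#'
#' Aggregates mid-point frequency tracks into a matrix of normalised,
#' background-subtracted occupancy around transcription start sites: rows are
#' particle size classes, columns are positions relative to the TSS.  For
#' each size class the per-TSS windows are summed (minus-strand windows
#' coordinate-reversed so that downstream is always to the right), the summed
#' window is divided by its mean over all window bins, the same is done for
#' the deproteinised-DNA control, and the control is subtracted to ameliorate
#' MNase cleavage bias.  Values may therefore be negative.
#'
#' @param class_tracks named list (one entry per size class) of
#'   [midpoint_track()] objects, or of named lists of tracks keyed by element
#'   when the TSS table spans several elements.
#' @param control_tracks control tracks with the same structure and binning
#'   (deproteinised genomic DNA).
#' @param tss TSS table: columns `element`, `position` (0-based), `strand`,
#'   `expression`.
#' @param flank window half-width in bp either side of the TSS.
#' @return numeric matrix (size classes x relative positions) with attribute
#'   `"skipped"`: the number of TSS whose window exceeded element bounds.
#' @export
anchored_map <- function(class_tracks, control_tracks, tss, flank = 500L) {
  .assert(length(class_tracks) >= 1, "need at least one size class")
  .assert(identical(names(class_tracks), names(control_tracks)),
          "chromatin and control size classes must match")
  skipped <- 0L
  rows <- lapply(names(class_tracks), function(cls) {
    chrom <- .anchor_sum(class_tracks[[cls]], tss, flank)
    ctrl <- .anchor_sum(control_tracks[[cls]], tss, flank)
    .assert(length(chrom$vec) == length(ctrl$vec),
            "chromatin and control binning differ for class %s", cls)
    skipped <<- skipped + chrom$skipped
    .norm_unit_mean(chrom$vec) - .norm_unit_mean(ctrl$vec)
  })
  m <- do.call(rbind, rows)
  tr1 <- .first_track(class_tracks[[1]])
  w <- flank %/% tr1$bin_size
  dimnames(m) <- list(names(class_tracks),
                      as.character(seq.int(-w, w) * tr1$bin_size))
  attr(m, "skipped") <- skipped
  m
}

.first_track <- function(x) if (inherits(x, "midpoint_track")) x else x[[1]]

.norm_unit_mean <- function(v) {
  m <- mean(v)
  if (m == 0) return(v * 0)
  v / m
}

.anchor_sum <- function(tracks, tss, flank) {
  single <- inherits(tracks, "midpoint_track")
  bin_size <- .first_track(tracks)$bin_size
  w <- flank %/% bin_size
  acc <- numeric(2L * w + 1L)
  skipped <- 0L
  for (i in seq_len(nrow(tss))) {
    tr <- if (single) tracks else tracks[[tss$element[i]]]
    if (is.null(tr)) { skipped <- skipped + 1L; next }
    centre <- tss$position[i] %/% bin_size + 1L
    idx <- seq.int(centre - w, centre + w)
    if (idx[1] < 1 || idx[length(idx)] > length(tr$values)) {
      skipped <- skipped + 1L
      next
    }
    win <- tr$values[idx]
    if (tss$strand[i] == "-") win <- rev(win)
    acc <- acc + win
  }
  list(vec = acc, skipped = skipped)
}
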