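#' Sort fragments into chromatin particle size classes
#'
#' A fragment of length `L` joins every class whose window
#' `[nominal * (1 - tolerance), nominal * (1 + tolerance)]` (inclusive)
#' contains `L`.  Windows of neighbouring nominal sizes may overlap, so
#' membership is per class, not a partition: one fragment can appear in two
#' classes.
#'
#' @param frags a [fragment_set()].
#' @param nominal_sizes positive, sorted nominal particle sizes in bp.
#' @param tolerance_fraction half-width of the window as a fraction of the
#'   nominal size (default 0.10).
#' @return named list of `particle_class` objects, one per nominal size; each
#'   carries `nominal`, `tolerance_fraction`, and `members`
#'   (a [fragment_set()]).
#' @export
classify_particles <- function(frags, nominal_sizes,
                               tolerance_fraction = 0.10) {
  .assert(all(nominal_sizes > 0) && !is.unsorted(nominal_sizes),
          "nominal_sizes must be positive and sorted")
  len <- fragment_lengths(frags)
  out <- lapply(nominal_sizes, function(nom) {
    lo <- nom * (1 - tolerance_fraction)
    hi <- nom * (1 + tolerance_fraction)
    idx <- which(len >= lo & len <= hi)
    structure(list(nominal = nom, tolerance_fraction = tolerance_fraction,
                   members = fragment_set(as.data.frame(frags)[idx, , drop = FALSE],
                                          elements = attr(frags, "elements"),
                                          provenance = attr(frags, "provenance"))),
              class = "particle_class")
  })
  names(out) <- as.character(nominal_sizes)
  out
}

#' Mid-point frequency track
#'
#' Per-bin frequency of fragment mid-points for one element.  The mid-point
#' of a 0-based half-open fragment is `floor((start + end) / 2)`.  Smoothing
#' is a 3-bin moving average with a shrinking window at the track ends (mean
#' over the available bins).
#'
#' @param frags a [fragment_set()] or `particle_class` (its members are used).
#' @param element element name (must be declared in the fragment set).
#' @param bin_size bin width in bp (default 10).
#' @param smooth apply the 3-bin moving average (default `TRUE`).
#' @return object of class `midpoint_track`: list with `element`, `bin_size`,
#'   `values` (one per bin tiling the element), `smoothing`, `normalized`.
#' @export
midpoint_track <- function(frags, element = NULL, bin_size = 10L,
                           smooth = TRUE) {
  if (inherits(frags, "particle_class")) frags <- frags$members
  .assert(bin_size >= 1, "bin_size must be >= 1")
  elements <- attr(frags, "elements")
  if (is.null(element)) element <- names(elements)[1]
  .assert(element %in% names(elements), "undeclared element: %s", element)
  elen <- elements[[element]]
  nbin <- ceiling(elen / bin_size)
  sub <- frags[frags$element == element, , drop = FALSE]
  mid <- (sub$start + sub$end) %/% 2L
  bin <- mid %/% bin_size + 1L
  bin <- bin[bin >= 1 & bin <= nbin]
  values <- tabulate(bin, nbins = nbin)
  smoothing <- "none"
  if (smooth) {
    values <- smooth3(values)
    smoothing <- "3-bin moving average"
  }
  structure(list(element = element, bin_size = as.integer(bin_size),
                 values = values, smoothing = smoothing, normalized = FALSE),
            class = "midpoint_track")
}

## 3-bin moving average with shrinking windows at the ends
smooth3 <- function(v) {
  n <- length(v)
  if (n <= 2) return(as.numeric(v))
  out <- (v + c(v[-1], 0) + c(0, v[-n])) / 3
  out[1] <- mean(v[1:2])
  out[n] <- mean(v[(n - 1):n])
  out
}

#' Call particle positions from a mid-point track
#'
#' Particle positions are the summits of peaks in the smoothed mid-point
#' frequency track whose value reaches the top `percentile` percent of all
#' track values.  A summit is a local maximum (`>=` both neighbours); runs of
#' equal values yield their leftmost bin.  Two distinct equal-valued maxima
#' are both returned, sorted by coordinate.
#'
#' @param track a smoothed [midpoint_track()].
#' @param percentile top percentage of track values to keep (default 1, the
#'   top 1%).
#' @return integer vector of summit bin start coordinates (bp, 0-based).  A
#'   constant track yields an empty vector with a warning.
#' @export
call_particle_positions <- function(track, percentile = 1) {
  stopifnot(inherits(track, "midpoint_track"))
  .assert(track$smoothing != "none", "track must be smoothed before calling")
  v <- track$values
  n <- length(v)
  if (n == 0 || max(v) == min(v)) {
    warning("constant track: no particle positions called")
    return(integer(0))
  }
  thr <- quantile(v, 1 - percentile / 100, names = FALSE)
  left <- c(-Inf, v[-n])
  right <- c(v[-1], -Inf)
  is_max <- v >= left & v >= right & v >= thr
  ## collapse plateaus to their leftmost bin
  plateau <- v == left
  is_max[plateau] <- FALSE
  sort((which(is_max) - 1L) * track$bin_size)
}
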