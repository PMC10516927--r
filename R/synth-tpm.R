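#' TPM population specification
#'
#' Parameters of the synthetic tethered-particle-motion model.  Each bead
#' belongs to one compaction population with tether extension
#' `end_to_end_nm`; its per-frame radial excursion from the anchor follows a
#' Rayleigh distribution truncated at the tether extension (the bead cannot
#' move further than the tether allows), isotropic in angle, with additive
#' Gaussian localization noise.  The Rayleigh scale equals the tether
#' extension, which concentrates the most distant excursions near the
#' truncation point so that the extreme-position estimator downstream reads
#' the tether length nearly unbiasedly.  The anchor optionally random-walks
#' to model stage drift.
#'
#' @param populations data.frame with columns `end_to_end_nm` (> 0) and
#'   `n_beads`; an optional `weight` column must sum to 1 (default:
#'   proportional to `n_beads`).
#' @param frames_per_bead frames recorded per bead (>= 100).
#' @param localization_noise_sd nm of isotropic localization noise per frame.
#' @param anchor_drift_sd nm per frame of anchor random-walk drift.
#' @return an object of class `tpm_population_spec`.
#' @export
tpm_population_spec <- function(populations, frames_per_bead = 2000L,
                                localization_noise_sd = 2,
                                anchor_drift_sd = 0) {
  .assert(all(populations$end_to_end_nm > 0), "end_to_end_nm must be > 0")
  .assert(frames_per_bead >= 100, "frames_per_bead must be >= 100")
  .assert(localization_noise_sd >= 0 && anchor_drift_sd >= 0,
          "noise parameters must be >= 0")
  if (is.null(populations$weight)) {
    populations$weight <- populations$n_beads / sum(populations$n_beads)
  }
  .assert(abs(sum(populations$weight) - 1) < 1e-8, "weights must sum to 1")
  structure(list(populations = populations,
                 frames_per_bead = as.integer(frames_per_bead),
                 localization_noise_sd = localization_noise_sd,
                 anchor_drift_sd = anchor_drift_sd),
            class = "tpm_population_spec")
}

#' Three-state compaction preset
#'
#' Bead populations at tether extensions 150, 132 and 112 nm (successive
#' compaction states ~20 nm apart, matching tetramer-sized DNA wrapping
#' steps), 50 beads each, 2000 frames per bead.
#'
#' @param n_beads beads per population.
#' @param frames_per_bead frames per bead.
#' @return a [tpm_population_spec()].
#' @export
tpm_preset_three_state <- function(n_beads = 50L, frames_per_bead = 2000L) {
  tpm_population_spec(
    data.frame(end_to_end_nm = c(150, 132, 112),
               n_beads = rep(as.integer(n_beads), 3)),
    frames_per_bead = frames_per_bead)
}

## truncated Rayleigh sampler / quantile (scale sigma, hard cutoff)
rtrunc_rayleigh <- function(n, scale, cutoff) {
  cap <- 1 - exp(-cutoff^2 / (2 * scale^2))
  u <- runif(n) * cap
  scale * sqrt(-2 * log(1 - u))
}

qtrunc_rayleigh <- function(p, scale, cutoff) {
  cap <- 1 - exp(-cutoff^2 / (2 * scale^2))
  scale * sqrt(-2 * log(1 - p * cap))
}

#' Simulate tethered-particle-motion trajectories
#'
#' @param spec a [tpm_population_spec()].
#' @param seed integer seed.
#' @return data.frame of class `tpm_trajectories` with columns `bead_id`,
#'   `frame`, `x_nm`, `y_nm`, `truth_label` (the ground-truth population
#'   index, 1 = least compacted).
#' @export
simulate_tpm <- function(spec, seed) {
  stopifnot(inherits(spec, "tpm_population_spec"))
  set.seed(as.integer(seed))
  pops <- spec$populations
  nf <- spec$frames_per_bead
  out <- vector("list", sum(pops$n_beads))
  bead <- 0L
  for (p in seq_len(nrow(pops))) {
    L <- pops$end_to_end_nm[p]
    for (i in seq_len(pops$n_beads[p])) {
      bead <- bead + 1L
      r <- rtrunc_rayleigh(nf, scale = L, cutoff = L)
      th <- runif(nf, 0, 2 * pi)
      ax <- ay <- rep(0, nf)
      if (spec$anchor_drift_sd > 0) {
        ax <- cumsum(rnorm(nf, 0, spec$anchor_drift_sd))
        ay <- cumsum(rnorm(nf, 0, spec$anchor_drift_sd))
      }
      x <- ax + r * cos(th)
      y <- ay + r * sin(th)
      if (spec$localization_noise_sd > 0) {
        x <- x + rnorm(nf, 0, spec$localization_noise_sd)
        y <- y + rnorm(nf, 0, spec$localization_noise_sd)
      }
      out[[bead]] <- data.frame(bead_id = bead, frame = seq_len(nf),
                                x_nm = x, y_nm = y, truth_label = p)
    }
  }
  structure(do.call(rbind, out),
            class = c("tpm_trajectories", "data.frame"), spec = spec)
}

#' Read / write TPM trajectories
#'
#' Tab-separated with header `bead_id`, `frame`, `x_nm`, `y_nm`,
#' `truth_label` (label column optional on read).
#'
#' @param traj trajectory data.frame.
#' @param path file path.
#' @return `read_trajectories()` returns the data.frame; the writer returns
#'   `path` invisibly.
#' @export
write_trajectories <- function(traj, path) {
  utils::write.table(as.data.frame(traj), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_trajectories
#' @export
read_trajectories <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  .assert(all(c("bead_id", "frame", "x_nm", "y_nm") %in% names(df)),
          "trajectory file needs columns bead_id, frame, x_nm, y_nm")
  df
}
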