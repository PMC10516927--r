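#' Root-mean-square bead displacement
#'
#' `rms = sqrt(mean((x - xbar)^2 + (y - ybar)^2))` about the anchor (the
#' trajectory centroid).  With `drift_window`, a centred moving average of
#' the positions is subtracted per frame before the RMS is taken, removing
#' slow stage drift.
#'
#' @param traj data.frame with columns `x_nm`, `y_nm` (one bead).
#' @param drift_window moving-average window in frames, or `NULL`.
#' @return list of class `rms_measurement`: `bead_id` (if present), `rms`,
#'   `anchor` (x, y), `n_frames`.
#' @export
compute_rms <- function(traj, drift_window = NULL) {
  x <- traj$x_nm; y <- traj$y_nm
  n <- length(x)
  .assert(n >= 2 && all(is.finite(x)) && all(is.finite(y)),
          "trajectory must have >= 2 finite positions")
  anchor <- c(x = mean(x), y = mean(y))
  if (!is.null(drift_window)) {
    .assert(drift_window <= n, "drift_window (%d) > n_frames (%d)",
            drift_window, n)
    dx <- x - .runmean(x, drift_window)
    dy <- y - .runmean(y, drift_window)
  } else {
    dx <- x - anchor["x"]; dy <- y - anchor["y"]
  }
  structure(list(bead_id = traj$bead_id[1] %||% NA,
                 rms = sqrt(mean(dx^2 + dy^2)),
                 anchor = anchor, n_frames = n),
            class = "rms_measurement")
}

## centred moving average, shrinking windows at the ends
.runmean <- function(v, w) {
  n <- length(v)
  half <- (w - 1L) %/% 2L
  cs <- cumsum(c(0, v))
  lo <- pmax(1L, seq_len(n) - half)
  hi <- pmin(n, seq_len(n) + half)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Deconvolve bead RMS values into compaction populations
#'
#' Fits a K-component univariate Gaussian mixture (unequal variances) to
#' per-bead RMS values; `K = "auto"` selects K in 1..`max_K` by the Bayesian
#' information criterion.  Beads are hard-assigned to their
#' maximum-responsibility component.  Populations are labelled with roman
#' numerals I, II, ... in order of decreasing mean RMS (least compacted
#' first).
#'
#' @param rms_values numeric vector of per-bead RMS (nm); >= 10 beads.
#' @param K component count, or `"auto"`.
#' @param max_K largest K considered under `"auto"`.
#' @return list of class `population_model`: `K`, `means`, `sds`, `weights`
#'   (each named by population label, means descending), `assignment`
#'   (per-bead label), `bic`.
#' @export
fit_populations <- function(rms_values, K = "auto", max_K = 5L) {
  .assert(length(rms_values) >= 10, "need >= 10 beads, got %d",
          length(rms_values))
  G <- if (identical(K, "auto")) seq_len(max_K) else as.integer(K)
  fit <- mclust::Mclust(rms_values, G = G, modelNames = "V", verbose = FALSE)
  if (is.null(fit)) {
    fit <- mclust::Mclust(rms_values, G = G, modelNames = "E",
                          verbose = FALSE)
  }
  .assert(!is.null(fit), "mixture fit did not converge")
  means <- fit$parameters$mean
  sds <- sqrt(fit$parameters$variance$sigmasq)
  if (length(sds) == 1) sds <- rep(sds, length(means))
  wts <- fit$parameters$pro
  ord <- order(means, decreasing = TRUE)
  labels <- as.character(utils::as.roman(seq_along(ord)))
  relabel <- setNames(labels, as.character(ord))
  structure(list(K = length(means),
                 means = setNames(means[ord], labels),
                 sds = setNames(sds[ord], labels),
                 weights = setNames(wts[ord], labels),
                 assignment = unname(relabel[as.character(fit$classification)]),
                 bic = unname(fit$bic)),
            class = "population_model")
}

#' @export
print.population_model <- function(x, ...) {
  cat(sprintf("<population_model> K = %d (BIC %.1f)\n", x$K, x$bic))
  print(data.frame(label = names(x$means), mean_nm = unname(x$means),
                   sd_nm = unname(x$sds), weight = unname(x$weights)))
  invisible(x)
}

#' Select the beads closest to a population's fitted RMS
#'
#' Among beads hard-assigned to the population, returns the `n` with the
#' smallest `|rms - population mean|`; ties are broken by bead id.
#'
#' @param model a [fit_populations()] model.
#' @param rms_values per-bead RMS values, in the same order used for the fit.
#' @param population population label (e.g. `"II"`).
#' @param n beads to select (default 25).
#' @param bead_ids bead identifiers (default: positional indices).
#' @return vector of selected bead ids.  Fewer than `n` assigned beads are
#'   all returned with a warning.
#' @export
select_beads <- function(model, rms_values, population, n = 25L,
                         bead_ids = seq_along(rms_values)) {
  .assert(population %in% names(model$means),
          "no population labelled %s", population)
  idx <- which(model$assignment == population)
  if (length(idx) < n) {
    warning(sprintf("population %s has %d beads (< n = %d); returning all",
                    population, length(idx), n))
    n <- length(idx)
  }
  d <- abs(rms_values[idx] - model$means[[population]])
  ord <- order(d, bead_ids[idx])
  bead_ids[idx][ord][seq_len(n)]
}

#' Most distant bead positions
#'
#' Returns the `ceil(fraction * n_frames)` positions with the largest radial
#' distance from the trajectory centre (the anchor); ties are broken by frame
#' index.
#'
#' @param traj data.frame with columns `x_nm`, `y_nm` (one bead).
#' @param fraction fraction of frames to keep, in (0, 0.5); default 0.025.
#' @return data.frame `frame`, `x_nm`, `y_nm`, `r_nm` with attribute
#'   `"anchor"`.
#' @export
extreme_positions <- function(traj, fraction = 0.025) {
  .assert(fraction > 0 && fraction < 0.5, "fraction must be in (0, 0.5)")
  anchor <- c(x = mean(traj$x_nm), y = mean(traj$y_nm))
  r <- sqrt((traj$x_nm - anchor["x"])^2 + (traj$y_nm - anchor["y"])^2)
  k <- ceiling(fraction * nrow(traj))
  ord <- order(-r, seq_len(nrow(traj)))[seq_len(k)]
  out <- data.frame(frame = traj$frame[ord] %||% ord,
                    x_nm = traj$x_nm[ord], y_nm = traj$y_nm[ord],
                    r_nm = r[ord])
  attr(out, "anchor") <- anchor
  out
}

#' End-to-end distances from extreme positions
#'
#' Right-triangle combination of the in-plane excursion with a configurable
#' vertical offset: `e = sqrt(r^2 + z_offset^2)` where `r` is the in-plane
#' distance from the anchor.  `z_offset` models out-of-plane geometry (bead
#' radius / tether height) and defaults to 0 (pure in-plane).
#'
#' @param points data.frame from [extreme_positions()] (or any with `x_nm`,
#'   `y_nm`).
#' @param anchor length-2 numeric (x, y); default: the points' stored anchor.
#' @param z_offset vertical offset in nm.
#' @return numeric vector of end-to-end distances (nm).
#' @export
end_to_end <- function(points, anchor = attr(points, "anchor"),
                       z_offset = 0) {
  .assert(nrow(points) > 0, "points must be nonempty")
  .assert(length(anchor) == 2, "anchor must be (x, y)")
  r <- sqrt((points$x_nm - anchor[[1]])^2 + (points$y_nm - anchor[[2]])^2)
  sqrt(r^2 + z_offset^2)
}

#' Skew-normal fit of an end-to-end distance sample
#'
#' Maximum-likelihood fit of the skew-normal density
#' `f(x) = (2/omega) phi(z) Phi(alpha z)`, `z = (x - xi)/omega`, with the
#' reported peak being the numerically located mode of the fitted density.
#' Initial values come from the method of moments on the sample skewness.
#'
#' @param distances numeric vector, >= 30 points, positive variance.
#' @param label optional population label carried through.
#' @return list of class `end_to_end_sample`: `label`, `distances`,
#'   `location` (xi), `scale` (omega), `shape` (alpha), `peak` (mode, nm),
#'   `converged`.
#' @export
fit_end_to_end <- function(distances, label = NA_character_) {
  .assert(length(distances) >= 30, "need >= 30 points, got %d",
          length(distances))
  .assert(sd(distances) > 0, "degenerate (zero-variance) input")
  m <- mean(distances); s <- sd(distances)
  g1 <- mean((distances - m)^3) / s^3
  a <- min(abs(g1), 0.99)^(2 / 3)
  delta <- sign(g1) * sqrt(pi / 2 * a / (a + ((4 - pi) / 2)^(2 / 3)))
  delta <- max(min(delta, 0.995), -0.995)
  alpha0 <- delta / sqrt(1 - delta^2)
  omega0 <- s / sqrt(max(1 - 2 * delta^2 / pi, 0.05))
  xi0 <- m - omega0 * delta * sqrt(2 / pi)
  nll <- function(p) {
    xi <- p[1]; omega <- exp(p[2]); alpha <- p[3]
    z <- (distances - xi) / omega
    -sum(log(2) - log(omega) + dnorm(z, log = TRUE) +
           pnorm(alpha * z, log.p = TRUE))
  }
  fit <- optim(c(xi0, log(omega0), alpha0), nll, method = "BFGS",
               control = list(maxit = 500))
  xi <- fit$par[1]; omega <- exp(fit$par[2]); alpha <- fit$par[3]
  dens <- function(x) {
    z <- (x - xi) / omega
    2 / omega * dnorm(z) * pnorm(alpha * z)
  }
  opt <- optimize(dens, interval = c(xi - 4 * omega, xi + 4 * omega),
                  maximum = TRUE, tol = 1e-4)
  structure(list(label = label, distances = distances, location = xi,
                 scale = omega, shape = alpha, peak = opt$maximum,
                 converged = fit$convergence == 0),
            class = "end_to_end_sample")
}

#' Pairwise step spectrum between adjacent populations
#'
#' For each adjacent pair of populations (in the given order, least compacted
#' first), pools all absolute cross differences `|e_i - e_j|` between their
#' end-to-end points and fits a Gaussian (maximum likelihood: sample mean and
#' standard deviation).  The average of the fitted means is the compaction
#' step size.
#'
#' @param samples list of >= 2 [fit_end_to_end()] samples, ordered by
#'   decreasing peak.
#' @param all_pairs also include non-adjacent pairs (default `FALSE`).
#' @return list of class `pairwise_distribution`: `pairs` (data.frame with
#'   `from`, `to`, `mean_nm`, `sd_nm`, `n`), `step_nm` (mean of the
#'   adjacent-pair fitted means).
#' @export
pairwise_peaks <- function(samples, all_pairs = FALSE) {
  .assert(length(samples) >= 2, "need >= 2 populations")
  idx <- if (all_pairs) {
    which(upper.tri(diag(length(samples))), arr.ind = TRUE)
  } else {
    cbind(seq_len(length(samples) - 1L), seq_len(length(samples) - 1L) + 1L)
  }
  rows <- lapply(seq_len(nrow(idx)), function(k) {
    i <- idx[k, 1]; j <- idx[k, 2]
    d <- abs(outer(samples[[i]]$distances, samples[[j]]$distances, "-"))
    data.frame(from = samples[[i]]$label, to = samples[[j]]$label,
               mean_nm = mean(d), sd_nm = sd(as.vector(d)),
               n = length(d), adjacent = (j == i + 1L))
  })
  pairs <- do.call(rbind, rows)
  structure(list(pairs = pairs,
                 step_nm = mean(pairs$mean_nm[pairs$adjacent])),
            class = "pairwise_distribution")
}

#' Full TPM analysis pipeline
#'
#' RMS per bead, mixture deconvolution, per-population selection of the
#' beads closest to the fitted RMS, extraction of the most distant positions,
#' end-to-end transformation, skew-normal fits, and the adjacent pairwise
#' step spectrum.
#'
#' @param traj long trajectory data.frame (`bead_id`, `frame`, `x_nm`,
#'   `y_nm`).
#' @param K mixture components or `"auto"`.
#' @param select_n beads per population used for end-to-end estimation.
#' @param extreme_fraction fraction of most distant positions per bead.
#' @param z_offset vertical offset for [end_to_end()].
#' @param drift_window optional drift-correction window for [compute_rms()].
#' @return list of class `tpm_result`: `rms` (data.frame bead_id, rms),
#'   `model`, `samples` (per-population [fit_end_to_end()] results, least
#'   compacted first), `pairwise`, `step_nm`.
#' @export
tpm_pipeline <- function(traj, K = "auto", select_n = 25L,
                         extreme_fraction = 0.025, z_offset = 0,
                         drift_window = NULL) {
  beads <- split(traj, traj$bead_id)
  rms_df <- data.frame(
    bead_id = as.integer(names(beads)),
    rms = vapply(beads, function(b) compute_rms(b, drift_window)$rms,
                 numeric(1)))
  rms_df <- rms_df[order(rms_df$bead_id), ]
  model <- fit_populations(rms_df$rms, K = K)
  samples <- lapply(names(model$means), function(lab) {
    sel <- select_beads(model, rms_df$rms, lab, n = select_n,
                        bead_ids = rms_df$bead_id)
    e <- unlist(lapply(sel, function(id) {
      b <- beads[[as.character(id)]]
      pts <- extreme_positions(b, extreme_fraction)
      end_to_end(pts, z_offset = z_offset)
    }))
    fit_end_to_end(e, label = lab)
  })
  pw <- pairwise_peaks(samples)
  structure(list(rms = rms_df, model = model, samples = samples,
                 pairwise = pw, step_nm = pw$step_nm),
            class = "tpm_result")
}
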