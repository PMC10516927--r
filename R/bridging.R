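#' Titration specification for the DNA-bridging assay
#'
#' Hill-type recovery curve with Poisson counting noise:
#' `expected recovery(c) = max_recovery_pct * c^n / (c^n + midpoint^n)`;
#' observed counts are Poisson around the expected cpm and recovery is
#' computed against the reference counts.
#'
#' @param midpoint_um protein concentration (µM monomer) at half-maximal
#'   recovery.
#' @param hill_n cooperativity exponent (> 0).
#' @param max_recovery_pct plateau recovery, in (0, 100].
#' @param concentrations_um concentrations sampled.
#' @param reference_cpm expected counts of the reference sample (the full
#'   amount of labelled DNA; ~8000 cpm in the assay being emulated).
#' @return an object of class `titration_spec`.
#' @export
titration_spec <- function(midpoint_um = 2.5, hill_n = 4,
                           max_recovery_pct = 80,
                           concentrations_um = c(0, 0.5, 1, 1.5, 2, 2.5,
                                                 3, 4, 5, 7.5, 10),
                           reference_cpm = 8000) {
  .assert(midpoint_um > 0, "midpoint_um must be > 0")
  .assert(hill_n > 0, "hill_n must be > 0")
  .assert(max_recovery_pct > 0 && max_recovery_pct <= 100,
          "max_recovery_pct must be in (0, 100]")
  .assert(all(concentrations_um >= 0), "concentrations must be >= 0")
  .assert(reference_cpm > 0, "reference_cpm must be > 0")
  structure(list(midpoint_um = midpoint_um, hill_n = hill_n,
                 max_recovery_pct = max_recovery_pct,
                 concentrations_um = concentrations_um,
                 reference_cpm = reference_cpm),
            class = "titration_spec")
}

## noiseless Hill curve (percent recovery)
hill_recovery <- function(c_um, midpoint_um, hill_n, max_recovery_pct) {
  ifelse(c_um == 0, 0,
         max_recovery_pct * c_um^hill_n /
           (c_um^hill_n + midpoint_um^hill_n))
}

#' Simulate a bridging titration series
#'
#' @param spec a [titration_spec()].
#' @param seed integer seed.
#' @param replicate replicate identifier carried through.
#' @return data.frame of class `titration_series`: `concentration_um`,
#'   `sample_cpm` (Poisson), `reference_cpm` (Poisson), `recovery_pct`.
#' @export
simulate_titration <- function(spec, seed, replicate = 1L) {
  stopifnot(inherits(spec, "titration_spec"))
  set.seed(as.integer(seed))
  exp_rec <- hill_recovery(spec$concentrations_um, spec$midpoint_um,
                           spec$hill_n, spec$max_recovery_pct)
  ref <- rpois(length(exp_rec), spec$reference_cpm)
  ref <- pmax(ref, 1L)
  cpm <- rpois(length(exp_rec), exp_rec / 100 * spec$reference_cpm)
  structure(data.frame(replicate = replicate,
                       concentration_um = spec$concentrations_um,
                       sample_cpm = cpm, reference_cpm = ref,
                       recovery_pct = recovery(cpm, ref)),
            class = c("titration_series", "data.frame"), spec = spec)
}

#' DNA recovery percentage
#'
#' `100 * sample_cpm / reference_cpm`, the fraction of labelled DNA
#' co-captured on the bead-immobilised DNA.  Scale-invariant: multiplying
#' both counts by the same factor leaves recovery unchanged.
#'
#' @param sample_cpm counts of the pulled-down sample.
#' @param reference_cpm counts of the reference (> 0).
#' @return recovery in percent.
#' @export
recovery <- function(sample_cpm, reference_cpm) {
  .assert(all(reference_cpm > 0), "reference_cpm must be > 0")
  100 * sample_cpm / reference_cpm
}

#' Fit the titration midpoint
#'
#' Nonlinear least squares of
#' `recovery(c) = plateau * c^n / (c^n + m^n)` (a Hill curve, a modelling
#' choice: the assay itself reports only the half-maximal point), with
#' seeded bootstrap confidence intervals over data points.
#'
#' @param series data.frame with columns `concentration_um`, `recovery_pct`
#'   (rows from several replicates may be pooled); >= 4 distinct
#'   concentrations spanning the midpoint.
#' @param n_boot bootstrap resamples for the CIs (default 1000).
#' @param seed bootstrap seed.
#' @return list of class `midpoint_fit`: `midpoint_um`, `hill_n`,
#'   `plateau_pct`, `ci` (2.5/97.5% bootstrap quantiles per parameter),
#'   `flagged` (`TRUE` when the fit failed, the data carry no signal, or the
#'   midpoint falls outside the sampled range), `model` (the `nls` object or
#'   `NULL`), `note`.
#' @export
fit_midpoint <- function(series, n_boot = 1000L, seed = 1L) {
  conc <- series$concentration_um
  rec <- series$recovery_pct
  .assert(length(unique(conc)) >= 4, "need >= 4 distinct concentrations")
  flagged_out <- function(note) {
    structure(list(midpoint_um = NA_real_, hill_n = NA_real_,
                   plateau_pct = NA_real_, ci = NULL, flagged = TRUE,
                   model = NULL, note = note),
              class = "midpoint_fit")
  }
  if (max(rec) <= 0 || sd(rec) == 0) {
    return(flagged_out("no recovery signal: midpoint undefined"))
  }
  fit1 <- function(conc, rec) {
    plateau0 <- max(rec)
    m0 <- conc[which.min(abs(rec - plateau0 / 2))]
    if (m0 <= 0) m0 <- stats::median(conc[conc > 0])
    tryCatch(
      minpack.lm::nlsLM(
        rec ~ plateau * conc^n / (conc^n + m^n),
        start = list(plateau = plateau0, m = m0, n = 2),
        lower = c(plateau = 1e-6, m = 1e-6, n = 0.1),
        upper = c(plateau = 200, m = max(conc) * 100, n = 50),
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
  }
  fit <- fit1(conc, rec)
  if (is.null(fit)) return(flagged_out("nonlinear fit did not converge"))
  p <- coef(fit)
  flagged <- p[["m"]] < min(conc[conc > 0]) || p[["m"]] > max(conc)
  ci <- NULL
  if (n_boot > 0) {
    set.seed(as.integer(seed))
    boot <- matrix(NA_real_, n_boot, 3,
                   dimnames = list(NULL, c("plateau", "m", "n")))
    for (b in seq_len(n_boot)) {
      i <- sample.int(length(conc), replace = TRUE)
      f <- fit1(conc[i], rec[i])
      if (!is.null(f)) boot[b, ] <- coef(f)
    }
    boot <- boot[complete.cases(boot), , drop = FALSE]
    if (nrow(boot) >= 100) {
      ci <- apply(boot, 2, quantile, probs = c(0.025, 0.975))
    }
  }
  structure(list(midpoint_um = unname(p["m"]), hill_n = unname(p["n"]),
                 plateau_pct = unname(p["plateau"]), ci = ci,
                 flagged = flagged, model = fit,
                 note = if (flagged) "midpoint outside sampled range" else ""),
            class = "midpoint_fit")
}

#' @export
print.midpoint_fit <- function(x, ...) {
  if (x$flagged && is.na(x$midpoint_um)) {
    cat("<midpoint_fit> flagged:", x$note, "\n")
  } else {
    cat(sprintf("<midpoint_fit> midpoint %.3g uM, Hill n %.2f, plateau %.1f%%%s\n",
                x$midpoint_um, x$hill_n, x$plateau_pct,
                if (x$flagged) paste0(" [", x$note, "]") else ""))
  }
  invisible(x)
}
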