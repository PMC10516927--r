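#' Derive a stage seed from the run seed
#'
#' One global run seed is fanned out deterministically to per-stage child
#' seeds (`(seed * 1009 + 9973 * stage_index) mod (2^31 - 1)`), so any stage
#' can be re-run in isolation with the seed recorded in the manifest.
#'
#' @param seed global run seed.
#' @param stage_index 1-based stage position.
#' @return integer child seed.
#' @export
derive_seed <- function(seed, stage_index) {
  as.integer((as.double(seed) * 1009 + 9973 * stage_index) %% (2^31 - 1))
}

#' Run a configured analysis pipeline
#'
#' Executes the stages declared in a YAML (or list) configuration in order,
#' writing each stage's artifacts and a run manifest to `outdir`.  The
#' manifest (`manifest.json`) records the package version, configuration,
#' run seed, per-stage derived seeds, md5 checksums of file inputs, the list
#' of completed stages and the output files, so any run is reproducible from
#' its manifest alone.  On a stage failure the manifest still records the
#' stages completed so far before the error is re-signalled.
#'
#' Supported stages: `simulate_chromatin` (fields `preset`, `subsample_n`),
#' `spectrum` (`max_size`), `classify` (`nominal_sizes`, `bin_size`),
#' `ratio60` (`bin_size`, `pseudocount`), `simulate_tpm` (`n_beads`,
#' `frames_per_bead`), `tpm` (`select_n`, `extreme_fraction`, `z_offset`),
#' `simulate_titration`, `bridge`, `report`.
#'
#' @param config path to a YAML file or an equivalent list with a `pipeline`
#'   element (list of stages, each with a `stage` name and parameters).
#' @param outdir output directory (created if needed).
#' @param seed global run seed.
#' @param quiet suppress per-stage messages to stderr.
#' @return (invisibly) the manifest list.
#' @export
run_pipeline <- function(config, outdir, seed = 1L, quiet = FALSE) {
  config_path <- NULL
  if (is.character(config)) {
    .assert(file.exists(config), "config not found: %s", config)
    config_path <- config
    config <- yaml::read_yaml(config)
  }
  .assert(is.list(config$pipeline) && length(config$pipeline) >= 1,
          "config must declare a non-empty 'pipeline' list")
  for (st in config$pipeline) {
    .assert(is.character(st$stage %||% NULL),
            "every pipeline entry needs a 'stage' name")
  }
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message("[hypernuc] ", sprintf(...))

  manifest <- list(
    package = "hypernuc",
    version = as.character(utils::packageVersion("hypernuc")),
    seed = as.integer(seed),
    config = config,
    config_md5 = if (!is.null(config_path))
      unname(tools::md5sum(config_path)) else NA,
    input_checksums = list(), stages = list(), outputs = character())

  state <- new.env(parent = emptyenv())
  add_out <- function(path) {
    manifest$outputs <<- c(manifest$outputs, path)
    path
  }
  write_manifest <- function() {
    jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, null = "null",
                         na = "null")
  }

  run_stage <- function(st, i) {
    s <- derive_seed(seed, i)
    nm <- st$stage
    say("stage %d: %s (seed %d)", i, nm, s)
    switch(nm,
      simulate_chromatin = {
        preset <- chromatin_preset(st$preset %||% "canonical-dimer",
                                   subsample_n = st$subsample_n %||% 20000L)
        particles <- assemble_chromatin(preset$chromatin, seed = s)
        frags <- digest_chromatin(particles, preset$chromatin$genome_length,
                                  preset$digestion, seed = s + 1L)
        state$frags <- frags
        write_fragments_bed(frags, add_out(file.path(outdir, "fragments.bed")))
        write_tss_table(attr(particles, "tss"),
                        add_out(file.path(outdir, "tss.tsv")))
      },
      spectrum = {
        .assert(!is.null(state$frags), "spectrum: no fragments simulated/loaded")
        sp <- size_spectrum(state$frags, max_size = st$max_size %||% 600L)
        state$spectrum <- sp
        utils::write.table(
          data.frame(size = as.integer(names(sp$counts)), count = sp$counts),
          add_out(file.path(outdir, "spectrum.tsv")),
          sep = "\t", quote = FALSE, row.names = FALSE)
      },
      classify = {
        .assert(!is.null(state$frags), "classify: no fragments available")
        sizes <- st$nominal_sizes %||% c(60L, 90L, 120L, 150L)
        cls <- classify_particles(state$frags, sizes)
        state$classes <- cls
        for (nmc in names(cls)) {
          tr <- midpoint_track(cls[[nmc]], bin_size = st$bin_size %||% 10L)
          write_bedgraph(tr, add_out(file.path(
            outdir, sprintf("midpoints_%sbp.bedgraph", nmc))))
        }
      },
      ratio60 = {
        .assert(!is.null(state$frags), "ratio60: no fragments available")
        rt <- ratio_60mer(state$frags, bin_size = st$bin_size %||% 120L,
                          pseudocount = st$pseudocount %||% 0.5)
        state$ratio <- rt
        write_bedgraph(rt, add_out(file.path(outdir, "ratio60.bedgraph")))
      },
      simulate_tpm = {
        spec <- tpm_preset_three_state(
          n_beads = st$n_beads %||% 50L,
          frames_per_bead = st$frames_per_bead %||% 2000L)
        state$traj <- simulate_tpm(spec, seed = s)
        write_trajectories(state$traj,
                           add_out(file.path(outdir, "trajectories.tsv")))
      },
      tpm = {
        .assert(!is.null(state$traj), "tpm: no trajectories available")
        res <- tpm_pipeline(state$traj,
                            select_n = st$select_n %||% 25L,
                            extreme_fraction = st$extreme_fraction %||% 0.025,
                            z_offset = st$z_offset %||% 0)
        state$tpm <- res
        jsonlite::write_json(
          list(populations = list(means_nm = res$model$means,
                                  weights = res$model$weights),
               peaks_nm = vapply(res$samples, `[[`, numeric(1), "peak"),
               step_nm = res$step_nm),
          add_out(file.path(outdir, "tpm.json")),
          auto_unbox = TRUE, digits = NA, pretty = TRUE)
      },
      simulate_titration = {
        spec <- do.call(titration_spec, st[setdiff(names(st), "stage")])
        state$titration <- simulate_titration(spec, seed = s)
        utils::write.table(as.data.frame(state$titration),
                           add_out(file.path(outdir, "titration.tsv")),
                           sep = "\t", quote = FALSE, row.names = FALSE)
      },
      bridge = {
        .assert(!is.null(state$titration), "bridge: no titration available")
        fit <- fit_midpoint(state$titration, seed = s)
        state$bridge <- fit
        jsonlite::write_json(
          list(midpoint_um = fit$midpoint_um, hill_n = fit$hill_n,
               plateau_pct = fit$plateau_pct, flagged = fit$flagged),
          add_out(file.path(outdir, "bridge.json")),
          auto_unbox = TRUE, digits = NA, pretty = TRUE)
      },
      report = {
        rep <- list()
        if (!is.null(state$spectrum)) {
          per <- tryCatch(estimate_period(state$spectrum),
                          error = function(e) list(period = NA, score = NA))
          rep$period_bp <- per$period
          rep$period_score <- per$score
        }
        if (!is.null(state$ratio)) {
          rep$interdecile <- interdecile(state$ratio)
        }
        if (!is.null(state$tpm)) rep$tpm_step_nm <- state$tpm$step_nm
        if (!is.null(state$bridge)) rep$midpoint_um <- state$bridge$midpoint_um
        jsonlite::write_json(rep, add_out(file.path(outdir, "summary.json")),
                             auto_unbox = TRUE, digits = NA, pretty = TRUE)
      },
      stop(sprintf("unknown stage '%s'", nm), call. = FALSE))
    manifest$stages[[length(manifest$stages) + 1L]] <<-
      list(index = i, stage = nm, seed = s, status = "completed")
  }

  ## checksum any file inputs named in the config
  for (st in config$pipeline) {
    for (f in c(st$input %||% NULL, st$path %||% NULL)) {
      if (is.character(f) && file.exists(f)) {
        manifest$input_checksums[[f]] <- unname(tools::md5sum(f))
      }
    }
  }

  for (i in seq_along(config$pipeline)) {
    res <- tryCatch(run_stage(config$pipeline[[i]], i),
                    error = function(e) e)
    if (inherits(res, "error")) {
      manifest$stages[[length(manifest$stages) + 1L]] <-
        list(index = i, stage = config$pipeline[[i]]$stage,
             status = "failed", error = conditionMessage(res))
      write_manifest()
      stop(res)
    }
  }
  write_manifest()
  invisible(manifest)
}
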