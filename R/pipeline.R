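# End-to-end orchestration: staged runs with provenance, and named
# fixture generation.

pipeline_stages <- c("simulate", "detect", "link", "coloc", "stoich",
                     "steps", "dol", "lifetime", "events")

stage_rank <- stats::setNames(seq_along(pipeline_stages), pipeline_stages)

#' Run a staged analysis pipeline
#'
#' Executes the configured stages in order (simulation before detection
#' before linking before analysis), carrying intermediate results between
#' stages, and returns a machine-readable run report with per-stage record
#' counts, fit results and provenance (package version, config hash,
#' seed).
#'
#' Supported stages and their parameter blocks:
#' * `simulate`: `scenario` (`"loading"`), `n_foci`, plus any
#'   [scenario_loading()] argument — builds a movie-free focus set, or
#'   `movie = TRUE` to render a small movie;
#' * `detect`: `min_snr`, `window` — detect foci on each movie frame;
#' * `link`: `max_step`, `max_gap`;
#' * `stoich`: `k`, `mode`, `scaled_sds` — copy numbers plus mixture fit.
#'
#' @param config List with `seed`, `stages` (character vector in order) and
#'   one parameter block per stage name.
#' @param out_json Optional path for the JSON run report.
#' @return The run report (list), invisibly the same as written.
#' @export
run_pipeline <- function(config, out_json = NULL) {
  if (is.null(config$stages) || !length(config$stages))
    stopf("config must name at least one stage")
  unknown <- setdiff(config$stages, pipeline_stages)
  if (length(unknown))
    stopf("unknown stage name: %s", paste(unknown, collapse = ", "))
  if (any(diff(stage_rank[config$stages]) <= 0))
    stopf("stages out of order: expected the order %s",
          paste(pipeline_stages, collapse = " > "))
  seed <- config$seed %||% 1L
  cfg_json <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA,
                               force = TRUE)
  report <- list(
    tool = "replitrace",
    version = as.character(utils::packageVersion("replitrace")),
    config_hash = fnv1a_hash(as.character(cfg_json)),
    seed = seed,
    stages = list())
  state <- new.env(parent = emptyenv())
  for (stage in config$stages) {
    params <- config[[stage]] %||% list()
    res <- tryCatch(
      run_stage(stage, params, state, seed),
      error = function(e)
        stopf("stage '%s' failed: %s", stage, conditionMessage(e)))
    report$stages[[stage]] <- res
  }
  if (!is.null(out_json))
    jsonlite::write_json(report, out_json, auto_unbox = TRUE, digits = NA,
                         null = "null", pretty = TRUE)
  invisible(report)
}

run_stage <- function(stage, params, state, seed) {
  switch(stage,
    simulate = {
      scen <- params$scenario %||% "loading"
      if (scen != "loading")
        stopf("only the 'loading' scenario is wired into run_pipeline")
      args <- params[setdiff(names(params), c("scenario", "movie"))]
      sc <- do.call(scenario_loading, c(list(seed = seed), args))
      state$scenario <- sc
      if (isTRUE(params$movie)) {
        cfgargs <- list(seed = seed, field_shape = c(48L, 48L),
                        n_frames = 3L, dye_model = "binomial")
        cfg <- do.call(sim_config, cfgargs)
        n <- min(length(sc$n_hexamers), 12L)
        truths <- lapply(seq_len(n), function(i)
          emitter_truth(emitter_id = i,
                        x = 6 + ((i - 1) %% 4) * 11,
                        y = 6 + ((i - 1) %/% 4) * 15,
                        n_hexamers = sc$n_hexamers[i],
                        dye_counts = rep(0L, sc$n_hexamers[i])))
        for (i in seq_len(n)) {
          d <- sc$dye_counts[i]
          truths[[i]]$dye_counts <- as.integer(
            c(d, rep(0, sc$n_hexamers[i] - 1)))
        }
        state$movie <- simulate_movie(cfg, truths, seed = seed)
      }
      list(n_trajectories = length(sc$trajectories),
           n_visible_foci = length(sc$n_hexamers))
    },
    detect = {
      if (is.null(state$movie)) stopf("no movie; add a simulate stage with movie = TRUE")
      foci <- lapply(seq_len(dim(state$movie$frames)[1]), function(k)
        detect_foci(state$movie$frames[k, , ],
                    min_snr = params$min_snr %||% 5,
                    window = params$window %||% 7L))
      state$foci <- foci
      list(n_foci = sum(vapply(foci, nrow, integer(1))))
    },
    link = {
      if (is.null(state$foci)) stopf("no foci; run detect first")
      state$tracks <- link_trajectories(state$foci,
                                        max_step = params$max_step %||% 3,
                                        max_gap = params$max_gap %||% 1L)
      list(n_tracks = length(state$tracks))
    },
    stoich = {
      sc <- state$scenario
      if (is.null(sc)) stopf("no simulated foci; run simulate first")
      est <- vapply(sc$trajectories, function(tr)
        estimate_stoichiometry(tr, sc$calib)$copies, numeric(1))
      k <- params$k %||% 3L
      fit <- fit_stoichiometry_mixture(
        est, k = k, mode = params$mode %||% "constrained",
        scaled_sds = params$scaled_sds %||% TRUE, seed = seed)
      state$copies <- est
      list(n_foci = length(est),
           mixture = list(k = fit$k, means = fit$means, sds = fit$sds,
                          weights = fit$weights,
                          log_likelihood = fit$log_likelihood))
    },
    stopf("stage '%s' is not wired into run_pipeline", stage)
  )
}

#' Generate a named fixture directory
#'
#' Writes a self-contained directory for one of the named scenarios —
#' trajectories as CSV, ground truth and an expected-property manifest as
#' JSON — for use as a regression fixture or worked example.
#'
#' * `"loading"`: stoichiometry populations at 1/2/3 helicases;
#' * `"chase"`: bleach-only control vs chase arm trajectories;
#' * `"frap"`: one noisy FRAP recovery curve;
#' * `"association"`: two binding-rate groups (full replisome vs helicase
#'   alone).
#'
#' @param name Scenario name.
#' @param seed Seed.
#' @param dir Output directory (created).
#' @param n Optional trajectory-count override to keep fixtures small.
#' @return `dir`, invisibly.
#' @export
generate_fixtures <- function(name = c("loading", "chase", "frap",
                                       "association"),
                              seed = 1L, dir, n = NULL) {
  name <- match.arg(name)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_trajs <- function(trajs, prefix) {
    for (i in seq_along(trajs))
      write_trajectory_csv(trajs[[i]],
                           file.path(dir, sprintf("%s_%03d.csv", prefix, i)))
  }
  manifest <- switch(name,
    loading = {
      sc <- scenario_loading(seed, n_foci = n %||% 120L)
      write_trajs(sc$trajectories, "focus")
      jsonlite::write_json(
        list(n_hexamers = sc$n_hexamers, dye_counts = sc$dye_counts),
        file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
      list(scenario = "loading", seed = seed,
           expected = list(populations = c(1, 2, 3),
                           weights_decreasing = TRUE,
                           calibration = unclass(sc$calib)))
    },
    chase = {
      sc <- scenario_chase(seed, n_chase = n %||% 10L,
                           n_control = n %||% 10L, duration_min = 5)
      write_trajs(sc$chase, "chase")
      write_trajs(sc$control, "control")
      list(scenario = "chase", seed = seed,
           expected = list(tau_bleach_min = sc$tau_bleach_min,
                           exchange_rate = sc$exchange_rate,
                           lifetimes_indistinguishable =
                             sc$exchange_rate == 0))
    },
    frap = {
      sc <- scenario_frap(seed)
      write_trajectory_csv(
        intensity_trajectory(sc$times, sc$values),
        file.path(dir, "frap_curve.csv"))
      list(scenario = "frap", seed = seed, expected = sc$truth)
    },
    association = {
      hi <- scenario_association(seed, event_rate = 0.84,
                                 mean_dwell = 30.7,
                                 n_traj = n %||% 20L, duration_s = 600)
      lo <- scenario_association(seed + 1L, event_rate = 0.13,
                                 mean_dwell = 55,
                                 n_traj = n %||% 20L, duration_s = 600)
      write_trajs(hi$trajectories, "replisome")
      write_trajs(lo$trajectories, "helicase_only")
      list(scenario = "association", seed = seed,
           expected = list(rate_replisome = 0.84, rate_helicase_only = 0.13,
                           calibration = unclass(hi$calib)))
    })
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
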