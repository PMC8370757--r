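# Orchestration: simulate -> track -> connect -> fuse -> summarise, plus
# rheology and crowding blocks, from one configuration list, with a
# machine-readable JSON report. The numbered scripts under analysis/ are
# thin drivers over these functions.

#' Validate a pipeline configuration
#'
#' The configuration is a plain list (writable as YAML or JSON, see
#' [read_pipeline_config()]) with fields:
#' \describe{
#'   \item{mode}{"simulate", "analyze" or "full".}
#'   \item{seed}{integer; drives every stochastic stage.}
#'   \item{control}{name of the control condition (exactly one).}
#'   \item{conditions}{named list; each entry may carry a `gelation` block
#'     (`arrest_times_h`, optional `sim` overrides for
#'     [simulation_config()]) and/or a `fusion` block (`n_replicates`,
#'     `schedule` with per-event `cluster_a`, `cluster_b`, `onset_min`,
#'     `duration_min`, optional `sim` overrides).}
#'   \item{inputs}{analyze mode only: named list mapping conditions to
#'     vectors of trajectory CSV paths.}
#'   \item{rheology}{optional list of trace parameter sets
#'     (`condition`, `lag`, `rate_gp`, `plateau_gp`, ...).}
#'   \item{crowding}{optional: `specs` (list of [crowder_spec()] argument
#'     lists), `reaction_volume_ul`, `nominal_um`.}
#' }
#'
#' @param config configuration list.
#' @return the validated configuration, invisibly.
#' @export
validate_pipeline_config <- function(config) {
  stopifnot(is.list(config))
  mode <- config$mode %||% "full"
  if (!mode %in% c("simulate", "analyze", "full"))
    stop("mode must be simulate, analyze or full", call. = FALSE)
  if (is.null(config$seed)) stop("config needs a seed", call. = FALSE)
  has_cond <- !is.null(config$conditions) || !is.null(config$inputs)
  if (has_cond) {
    cond_names <- names(config$conditions %||% config$inputs)
    if (is.null(config$control) || !(config$control %in% cond_names))
      stop("exactly one existing condition must be designated control",
           call. = FALSE)
  }
  if (mode == "analyze") {
    if (is.null(config$inputs)) stop("analyze mode needs inputs",
                                     call. = FALSE)
    missing <- unlist(config$inputs)[!file.exists(unlist(config$inputs))]
    if (length(missing))
      stop("input paths do not exist: ", paste(missing, collapse = ", "),
           call. = FALSE)
  }
  invisible(config)
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("pipeline stage '%s' failed: %s", name,
                 conditionMessage(e)), call. = FALSE))
}

analyze_gelation_series <- function(series, pars) {
  prof <- compute_speed_profile(series)
  est <- estimate_gelation_time(
    prof,
    threshold_frac = pars$threshold_frac %||% 0.1,
    persistence_h = pars$persistence_h %||% 0.5,
    noise_floor = pars$noise_floor %||% 0.05)
  list(profile = prof, estimate = est)
}

analyze_fusion_series <- function(series, pars) {
  tc <- cluster_timecourse(
    series,
    window = pars$window %||% 5L,
    neighbour_radius = pars$neighbour_radius %||% 150,
    cos_threshold = pars$cos_threshold %||% 0.5,
    min_speed = pars$min_speed %||% 0.1)
  lin <- track_lineages(tc, overlap_threshold = pars$overlap_threshold %||% 0.3)
  detect_fusion_events(lin, persistence = pars$persistence %||% 5L)
}

#' Run the full quantification pipeline
#'
#' Executes the configured stages in order (simulation where configured,
#' tracking and gelation timing, connectivity and fusion quantitation,
#' cross-replicate heterogeneity, rheology features, crowding arithmetic)
#' and assembles the report. A fixed seed yields an identical report;
#' a failing stage aborts with the stage named.
#'
#' @param config see [validate_pipeline_config()].
#' @param out_dir optional directory; when given, trajectory tables and the
#'   JSON report are written there (partial outputs are kept, with a
#'   `FAILED` marker file, if a stage aborts).
#' @return a `pipeline_report` list (see [generate_report()]).
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  validate_pipeline_config(config)
  mode <- config$mode %||% "full"
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  on_fail_marker <- function() {
    if (!is.null(out_dir))
      writeLines("pipeline aborted; outputs are partial",
                 file.path(out_dir, "FAILED"))
  }
  report <- list(seed = config$seed, mode = mode)
  ok <- FALSE
  on.exit(if (!ok) on_fail_marker())

  gel_pars <- config$gelation %||% list()
  fus_pars <- config$fusion_params %||% list()

  # gather per-condition replicate series (simulated or read from disk)
  cond_series <- list(); cond_fusion_series <- list()
  if (mode %in% c("simulate", "full") && !is.null(config$conditions)) {
    run_stage("simulate", {
      ci <- 0L
      for (cn in names(config$conditions)) {
        ci <- ci + 1L
        cc <- config$conditions[[cn]]
        if (!is.null(cc$gelation)) {
          at <- cc$gelation$arrest_times_h
          cond_series[[cn]] <- lapply(seq_along(at), function(i) {
            args <- utils::modifyList(
              list(seed = config$seed + 1000L * ci + i,
                   gelation_time = at[[i]]),
              cc$gelation$sim %||% list())
            args$gelation_time <- at[[i]]
            args$seed <- config$seed + 1000L * ci + i
            sim <- simulate_particle_field(
              do.call(simulation_config, args),
              replicate_id = sprintf("%s_rep%d", cn, i))
            if (!is.null(out_dir) && mode == "simulate")
              write_trajectories(sim$series, file.path(
                out_dir, sprintf("traj_%s_rep%d.csv", cn, i)))
            sim$series
          })
        }
        if (!is.null(cc$fusion)) {
          nr <- cc$fusion$n_replicates %||% 1L
          sched <- cc$fusion$schedule
          if (!is.null(sched)) sched <- as.data.frame(sched)
          cond_fusion_series[[cn]] <- lapply(seq_len(nr), function(i) {
            args <- utils::modifyList(
              list(duration = 1, frame_interval = 0.2, n_clusters = 4,
                   gelation_time = Inf),
              cc$fusion$sim %||% list())
            args$seed <- config$seed + 5000L * ci + i
            args$fusion_schedule <- sched
            sim <- simulate_particle_field(
              do.call(simulation_config, args),
              replicate_id = sprintf("%s_fus%d", cn, i))
            sim$series
          })
        }
      }
      invisible(NULL)
    })
  }
  if (mode == "analyze") {
    run_stage("load-inputs", {
      for (cn in names(config$inputs))
        cond_series[[cn]] <- lapply(config$inputs[[cn]], read_trajectories)
      invisible(NULL)
    })
  }

  if (length(cond_series)) {
    report$gelation <- run_stage("gelation-timing", {
      lapply(cond_series, function(reps) {
        res <- lapply(reps, analyze_gelation_series, pars = gel_pars)
        times <- vapply(res, function(r)
          r$estimate$gelation_time_h, numeric(1))
        list(replicate_times_h = times,
             mean_h = mean(times), sd_h = if (length(times) > 1) sd(times)
                                          else NA_real_,
             gelled = vapply(res, function(r) r$estimate$gelled, logical(1)))
      })
    })
    report$heterogeneity <- run_stage("heterogeneity", {
      lapply(cond_series, function(reps) {
        if (length(reps) < 2L) return(NULL)
        profs <- lapply(reps, function(s) {
          p <- compute_speed_profile(s)$profile
          data.frame(time = p$time_h, value = p$mean_speed_um_min)
        })
        grid <- profs[[1]]$time
        m <- align_replicates(profs, grid)
        m[is.na(m)] <- 0
        hp <- cov_profile(m)
        list(max_cov = hp$max_cov, time_span_above = hp$time_span_above)
      })
    })
  }
  if (length(cond_fusion_series)) {
    report$fusion <- run_stage("fusion", {
      ev <- list()
      for (cn in names(cond_fusion_series)) {
        for (i in seq_along(cond_fusion_series[[cn]])) {
          e <- analyze_fusion_series(cond_fusion_series[[cn]][[i]], fus_pars)
          if (nrow(e)) {
            e$condition <- cn; e$replicate <- i
            ev[[length(ev) + 1L]] <- e
          }
        }
      }
      if (!length(ev)) return(list(n_events = 0L))
      events <- do.call(rbind, ev)
      summ <- summarize_fusion(events, config$control)
      list(n_events = nrow(events),
           conditions = summ$conditions, folds = summ$folds)
    })
  }
  if (!is.null(config$rheology)) {
    report$rheology <- run_stage("rheology", {
      lapply(config$rheology, function(p) {
        tr <- simulate_rheology_trace(
          lag = p$lag, rate_gp = p$rate_gp, plateau_gp = p$plateau_gp,
          rate_gpp = p$rate_gpp %||% (0.3 * p$rate_gp),
          noise_sd = p$noise_sd %||% 0,
          dt = p$dt %||% 0.1, duration = p$duration %||% 24,
          seed = config$seed)
        f <- extract_gelation_features(tr)
        list(condition = p$condition %||% "trace",
             lag_h = f$lag_h, rate_gp_pa_h = f$rate_gp_pa_h,
             plateau_gp_pa = f$plateau_gp_pa, regime = f$regime)
      })
    })
  }
  if (!is.null(config$crowding)) {
    report$crowding <- run_stage("crowding", {
      specs <- lapply(config$crowding$specs, function(s)
        do.call(crowder_spec, s))
      res <- crowding_analysis(
        specs,
        reaction_volume_ul = config$crowding$reaction_volume_ul %||% 345,
        nominal_um = config$crowding$nominal_um %||% 4)
      as.data.frame(res)
    })
  }
  class(report) <- "pipeline_report"
  if (!is.null(out_dir)) generate_report(report, file.path(out_dir,
                                                           "report.json"))
  ok <- TRUE
  report
}

#' Serialise a pipeline report to JSON (plus a human-readable summary)
#'
#' The JSON is written with stable field order and full precision, so a
#' fixed-seed run is byte-identical; re-reading it reproduces the in-memory
#' structure.
#'
#' @param report a `pipeline_report` from [run_pipeline()].
#' @param path optional JSON output path.
#' @return the JSON string, invisibly.
#' @export
generate_report <- function(report, path = NULL) {
  if (!length(report)) stop("empty report", call. = FALSE)
  js <- jsonlite::toJSON(unclass(report), auto_unbox = TRUE, digits = NA,
                         dataframe = "rows", na = "null", pretty = TRUE)
  if (!is.null(path)) writeLines(js, path)
  invisible(as.character(js))
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("<pipeline_report>\n")
  if (!is.null(x$gelation)) {
    for (cn in names(x$gelation)) {
      g <- x$gelation[[cn]]
      cat(sprintf("  gelation %-10s mean %.2f h (sd %.2f), n = %d\n",
                  cn, g$mean_h, g$sd_h, length(g$replicate_times_h)))
    }
  }
  if (!is.null(x$fusion$folds) && nrow(as.data.frame(x$fusion$folds))) {
    f <- as.data.frame(x$fusion$folds)
    for (i in seq_len(nrow(f)))
      cat(sprintf("  fusion  %-10s onset x%.1f (%s), completion x%.1f (%s)\n",
                  f$condition[i], f$onset_fold[i], f$onset_direction[i],
                  f$completion_fold[i], f$completion_direction[i]))
  }
  if (!is.null(x$crowding)) {
    cr <- as.data.frame(x$crowding)
    for (i in seq_len(nrow(cr)))
      cat(sprintf("  crowding %-10s %.3g molecules, %.0f ul, %.1f uM\n",
                  cr$name[i], cr$molecule_count[i], cr$occupied_ul[i],
                  cr$effective_um[i]))
  }
  invisible(x)
}
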