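# End-to-end orchestration: respirometry -> synchrony -> kinematics -> join
# -> inference, with a reproducible run manifest.

#' Join per-fish, per-trial and SMR tables into the tidy analysis dataset
#'
#' Inner-joins the per-fish breath counts with the SMR table (on fish and
#' temperature) and stamps the per-trial covariates. Rows dropped by either
#' join are counted and reported; duplicate keys raise an error.
#'
#' @param per_fish Data frame `trial_id`, `fish_id`, `group`, `temp`, `o2`,
#'   `abf`.
#' @param per_trial Data frame `trial_id`, ..., `abf_group`, `cd`, `speed`,
#'   `cohesion`.
#' @param smr_table Data frame `fish_id`, `temp`, `mass`, `smr`.
#' @return List with `per_fish` (tidy individual-level table including
#'   `mass` and `smr`), `per_trial` (unchanged), and `n_dropped`.
#' @export
join_tables <- function(per_fish, per_trial, smr_table) {
  key_fish <- paste(per_fish$trial_id, per_fish$fish_id)
  if (anyDuplicated(key_fish))
    stop("duplicate per-fish keys: ",
         paste(utils::head(key_fish[duplicated(key_fish)], 5), collapse = "; "))
  if (anyDuplicated(per_trial$trial_id))
    stop("duplicate trial ids: ",
         paste(utils::head(per_trial$trial_id[duplicated(per_trial$trial_id)], 5),
               collapse = "; "))
  key_smr <- paste(smr_table$fish_id, smr_table$temp)
  if (anyDuplicated(key_smr))
    stop("duplicate SMR keys: ",
         paste(utils::head(key_smr[duplicated(key_smr)], 5), collapse = "; "))
  joined <- merge(per_fish, smr_table[, c("fish_id", "temp", "mass", "smr")],
                  by = c("fish_id", "temp"), sort = FALSE)
  n_dropped <- nrow(per_fish) - nrow(joined)
  if (n_dropped > 0)
    warning(sprintf("%d per-fish row(s) dropped in the SMR join", n_dropped))
  list(per_fish = joined, per_trial = per_trial, n_dropped = n_dropped)
}

#' Assemble a pipeline run configuration
#'
#' @param events,roster,trajectories,traces Paths to the input CSVs (any may
#'   be `NULL`; stages without inputs are skipped with notice). `traces` is
#'   a long-format trace CSV; `blanks` a CSV
#'   `channel,pre_slope,post_slope,trial_start,trial_end`; `chambers` a CSV
#'   `channel,fish_id,group,temp,chamber_volume_ml,tubing_volume_ml,mass_g`.
#' @param blanks,chambers Paths for the respirometry stage.
#' @param out_dir Output directory.
#' @param trial_duration Behavioural trial duration, s.
#' @param bin_width CD bin width, s.
#' @param px_per_cm,frame_rate Video calibration and frame rate.
#' @param plan A [cycle_plan()].
#' @param models Battery models to fit (subset of [battery_spec()] names).
#' @param select Backward-eliminate each model by LRT.
#' @param seed Integer seed recorded in the manifest.
#' @return An object of class `run_config`.
#' @export
run_config <- function(events = NULL, roster = NULL, trajectories = NULL,
                       traces = NULL, blanks = NULL, chambers = NULL,
                       out_dir = "airbreath_out", trial_duration = 720,
                       bin_width = 5, px_per_cm = 1, frame_rate = 25,
                       plan = cycle_plan(),
                       models = c("smr", "group_abf", "cd", "indiv_abf",
                                  "activity", "cohesion"),
                       select = TRUE, seed = 1) {
  structure(
    list(events = events, roster = roster, trajectories = trajectories,
         traces = traces, blanks = blanks, chambers = chambers,
         out_dir = out_dir, trial_duration = trial_duration,
         bin_width = bin_width, px_per_cm = px_per_cm,
         frame_rate = frame_rate, plan = plan, models = models,
         select = select, seed = seed),
    class = "run_config"
  )
}

#' Load a pipeline run configuration from YAML
#'
#' @param path YAML file whose keys mirror the arguments of [run_config()]
#'   (the `plan` key takes the [cycle_plan()] fields).
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$plan)) y$plan <- do.call(cycle_plan, y$plan)
  do.call(run_config, y)
}

# respirometry stage: traces + blanks + chambers -> per-fish SMR table
.stage_respirometry <- function(config) {
  traces <- read_o2_traces(config$traces)
  blanks <- .read_csv(config$blanks)
  chambers <- .read_csv(config$chambers)
  rows <- lapply(names(traces), function(ch) {
    meta <- chambers[chambers$channel == ch, , drop = FALSE]
    if (nrow(meta) != 1)
      stop("chamber metadata missing or duplicated for channel ", ch)
    bl <- blanks[blanks$channel == ch, , drop = FALSE]
    bg <- if (nrow(bl) == 1)
      background_model(bl$pre_slope, bl$post_slope, bl$trial_start,
                       bl$trial_end) else NULL
    cfg <- chamber_config(meta$chamber_volume_ml, meta$tubing_volume_ml,
                          fish_mass = meta$mass_g, channel_id = ch)
    series <- trace_to_mo2(traces[[ch]], config$plan, cfg, background = bg)
    est <- estimate_smr(series)
    data.frame(fish_id = meta$fish_id, group = meta$group, temp = meta$temp,
               mass = meta$mass_g, smr = est$smr, n_cycles = est$n_cycles,
               mean_bg_pct = est$mean_background_fraction,
               method = est$method, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# residual diagnostic plot for one fitted model
.diagnostic_plot <- function(fit, path) {
  grDevices::png(path, width = 900, height = 450)
  on.exit(grDevices::dev.off())
  graphics::par(mfrow = c(1, 2))
  r <- stats::residuals(fit$object)
  f <- stats::fitted(fit$object)
  graphics::plot(f, r, xlab = "Fitted", ylab = "Residual",
                 main = "Residuals vs fitted")
  graphics::abline(h = 0, lty = 2)
  stats::qqnorm(r); stats::qqline(r)
}

#' Run the full analysis pipeline
#'
#' Executes the stages respirometry, synchrony, kinematics, join, inference
#' and report in order, skipping (with an explicit notice) any stage whose
#' inputs are absent from the configuration. Per-stage CSVs, model
#' summaries, residual diagnostic plots and a machine-readable YAML manifest
#' (inputs, parameters, package version, seed, stage status) are written to
#' `config$out_dir`. A stage failure halts the run; partial outputs are
#' retained alongside a `FAILED` marker file naming the stage.
#'
#' @param config A [run_config()].
#' @return List with `smr_table`, `synchrony`, `kinematics`, `dataset`,
#'   `models` (per-model fit, R-squared, selection trace) and `manifest`.
#' @export
run_all <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  stages <- c("respirometry", "synchrony", "kinematics", "join",
              "inference", "report")
  status <- stats::setNames(rep("pending", length(stages)), stages)
  result <- list()
  fail <- function(stage, err) {
    writeLines(c(sprintf("stage: %s", stage), conditionMessage(err)),
               file.path(config$out_dir, "FAILED"))
    stop(sprintf("pipeline halted at stage '%s': %s", stage,
                 conditionMessage(err)), call. = FALSE)
  }

  # respirometry
  if (!is.null(config$traces)) {
    result$smr_table <- tryCatch(.stage_respirometry(config),
                                 error = function(e) fail("respirometry", e))
    write_table_csv(result$smr_table, file.path(config$out_dir, "smr.csv"))
    status["respirometry"] <- "done"
  } else {
    message("no trace input: respirometry stage skipped")
    status["respirometry"] <- "skipped"
  }

  # synchrony
  if (!is.null(config$events)) {
    events <- read_breath_events(config$events)
    roster <- if (!is.null(config$roster)) .read_csv(config$roster) else NULL
    result$synchrony <- tryCatch(
      synchrony_summary(events, roster = roster,
                        duration = config$trial_duration,
                        width = config$bin_width),
      error = function(e) fail("synchrony", e))
    write_table_csv(result$synchrony$per_trial,
                    file.path(config$out_dir, "synchrony_per_trial.csv"))
    write_table_csv(result$synchrony$per_fish,
                    file.path(config$out_dir, "abf_per_fish.csv"))
    status["synchrony"] <- "done"
  } else {
    message("no event input: synchrony stage skipped")
    status["synchrony"] <- "skipped"
  }

  # kinematics
  if (!is.null(config$trajectories)) {
    traj <- read_trajectories(config$trajectories,
                              px_per_cm = if (config$px_per_cm != 1)
                                config$px_per_cm else NULL)
    arena <- arena_config(frame_rate = config$frame_rate)
    result$kinematics <- tryCatch(kinematics_summary(traj, arena),
                                  error = function(e) fail("kinematics", e))
    write_table_csv(result$kinematics,
                    file.path(config$out_dir, "kinematics.csv"))
    status["kinematics"] <- "done"
  } else {
    message("no trajectory input: kinematics stage skipped (activity and cohesion models will be skipped)")
    status["kinematics"] <- "skipped"
  }

  # join: assemble tidy tables from whatever stages ran
  dataset <- NULL
  if (!is.null(result$synchrony)) {
    per_trial <- result$synchrony$per_trial
    per_fish <- result$synchrony$per_fish
    # design columns from the event table
    ev <- read_breath_events(config$events)
    meta_cols <- intersect(c("group", "temp", "o2"), names(ev))
    if (length(meta_cols) > 0) {
      meta <- unique(ev[, c("trial_id", meta_cols), drop = FALSE])
      per_trial <- merge(per_trial[, setdiff(names(per_trial), meta_cols)],
                         meta, by = "trial_id", sort = FALSE)
      per_fish <- merge(per_fish, meta, by = "trial_id", sort = FALSE)
    }
    if (!is.null(result$kinematics))
      per_trial <- merge(per_trial,
                         result$kinematics[, c("trial_id", "mean_speed_cm_s",
                                               "cohesion_cm")],
                         by = "trial_id", sort = FALSE)
    names(per_trial)[names(per_trial) == "mean_speed_cm_s"] <- "speed"
    names(per_trial)[names(per_trial) == "cohesion_cm"] <- "cohesion"
    if (!is.null(result$smr_table)) {
      dataset <- tryCatch(join_tables(per_fish, per_trial, result$smr_table),
                          error = function(e) fail("join", e))
    } else {
      dataset <- list(per_fish = per_fish, per_trial = per_trial,
                      n_dropped = 0L)
    }
    result$dataset <- dataset
    write_table_csv(dataset$per_fish,
                    file.path(config$out_dir, "dataset_per_fish.csv"))
    write_table_csv(dataset$per_trial,
                    file.path(config$out_dir, "dataset_per_trial.csv"))
    status["join"] <- "done"
  } else {
    status["join"] <- "skipped"
  }

  # inference
  if (!is.null(dataset)) {
    have_kin <- !is.null(result$kinematics) &&
      all(c("speed", "cohesion") %in% names(dataset$per_trial))
    have_smr <- !is.null(result$smr_table)
    runnable <- Filter(function(m) switch(
      m,
      smr = have_smr,
      indiv_abf = have_smr,
      activity = have_kin,
      cohesion = have_kin,
      group_abf = TRUE, cd = TRUE), config$models)
    skipped <- setdiff(config$models, runnable)
    if (length(skipped) > 0)
      message("models skipped for missing inputs: ",
              paste(skipped, collapse = ", "))
    # design variables are categorical throughout the model battery
    for (col in intersect(c("temp", "o2", "group", "fish_id"),
                          names(dataset$per_fish)))
      dataset$per_fish[[col]] <- factor(dataset$per_fish[[col]])
    for (col in intersect(c("temp", "o2", "group"),
                          names(dataset$per_trial)))
      dataset$per_trial[[col]] <- factor(dataset$per_trial[[col]])
    result$models <- tryCatch({
      fits <- lapply(runnable, function(m) {
        dat <- if (m == "smr") {
          # one row per fish x temperature (SMR is measured once per temp)
          unique(dataset$per_fish[, c("fish_id", "group", "temp", "mass",
                                      "smr")])
        } else if (m == "indiv_abf") dataset$per_fish else {
          d <- dataset$per_trial
          d[!is.na(d$cd) | m != "cd", , drop = FALSE]
        }
        if (m %in% c("group_abf", "cd") && !have_kin) {
          # reduced structure without the behavioural covariates
          spec <- battery_spec(m)
          f <- stats::update(spec$formula, . ~ . - speed - cohesion)
          fit <- if (spec$family == "gaussian") fit_lmm(f, dat) else
            fit_nb_glmm(f, dat)
          list(fit = fit, r2 = nakagawa_r2(fit), trace = NULL)
        } else {
          fit_battery_model(m, dat, select = config$select)
        }
      })
      names(fits) <- runnable
      fits
    }, error = function(e) fail("inference", e))
    for (m in names(result$models)) {
      write_table_csv(summary_table(result$models[[m]]$fit),
                      file.path(config$out_dir, sprintf("model_%s.csv", m)))
      if (!is.null(result$models[[m]]$trace))
        write_table_csv(result$models[[m]]$trace,
                        file.path(config$out_dir,
                                  sprintf("model_%s_selection.csv", m)))
      .diagnostic_plot(result$models[[m]]$fit,
                       file.path(config$out_dir,
                                 sprintf("model_%s_residuals.png", m)))
    }
    status["inference"] <- "done"
  } else {
    status["inference"] <- "skipped"
  }

  # report: manifest
  manifest <- list(
    package = "airbreath",
    version = as.character(utils::packageVersion("airbreath")),
    seed = config$seed,
    inputs = Filter(Negate(is.null),
                    config[c("events", "roster", "trajectories", "traces",
                             "blanks", "chambers")]),
    parameters = list(trial_duration = config$trial_duration,
                      bin_width = config$bin_width,
                      px_per_cm = config$px_per_cm,
                      frame_rate = config$frame_rate,
                      plan = unclass(config$plan),
                      models = config$models, select = config$select),
    stages = as.list(status))
  status["report"] <- "done"
  manifest$stages <- as.list(status)
  yaml::write_yaml(manifest, file.path(config$out_dir, "manifest.yaml"))
  result$manifest <- manifest
  invisible(result)
}
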