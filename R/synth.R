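# Seed-deterministic synthetic-data generators for all four input streams:
# respirometry O2 traces, air-breath event tables, 2-D trajectories, and the
# full factorial study dataset. Every generator stores its ground truth so
# downstream estimators can be validated against known values.

# run expr with a local, seeded RNG; the caller's RNG state is untouched
.with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Factorial study design
#'
#' The default design: 6 groups of 7 fish, each group observed at two
#' acclimation temperatures (25 and 30 deg C) and filmed for 12 min at each
#' of three oxygen saturations (100, 60, 20% air saturation), with one 16-h
#' overnight respirometry run per fish per temperature.
#'
#' @param n_groups Number of social groups.
#' @param group_size Fish per group.
#' @param temperatures Acclimation temperatures, deg C.
#' @param o2_levels Oxygen saturations of the behavioural trials, percent.
#' @param trial_duration Behavioural trial length, s.
#' @param respirometry_duration Respirometry run length, s.
#' @param frame_rate Video frame rate for trajectories, frames s^-1.
#' @param traj_frames Frames simulated per trial in the tidy (non-raw) study
#'   generator; raw mode uses `trial_duration * frame_rate`.
#' @return An object of class `study_design`.
#' @export
study_design <- function(n_groups = 6, group_size = 7,
                         temperatures = c(25, 30),
                         o2_levels = c(100, 60, 20),
                         trial_duration = 720,
                         respirometry_duration = 16 * 3600,
                         frame_rate = 25,
                         traj_frames = 1500) {
  stopifnot(n_groups >= 1, group_size >= 2, length(temperatures) >= 1,
            length(o2_levels) >= 1, trial_duration > 0)
  structure(
    list(n_groups = n_groups, group_size = group_size,
         temperatures = temperatures, o2_levels = o2_levels,
         trial_duration = trial_duration,
         respirometry_duration = respirometry_duration,
         frame_rate = frame_rate, traj_frames = traj_frames),
    class = "study_design"
  )
}

#' Simulation effect sizes
#'
#' Ground-truth parameters of the synthetic study. Defaults qualitatively
#' mirror the directional pattern expected for a facultative air breather:
#' air breathing highest in severe hypoxia (20% saturation), more group
#' breaths and higher SMR after warm acclimation, weak individual-level
#' temperature effect. They are synthetic defaults, not estimates from any
#' real dataset.
#'
#' @param smr_baseline SMR of a 1 g fish at the cooler temperature,
#'   mg O2 h^-1.
#' @param mass_exponent Allometric scaling exponent of SMR on mass.
#' @param temp_factor Multiplicative SMR effect of warm vs cool acclimation.
#' @param smr_sdlog Log-normal noise sd of individual SMR around the
#'   allometric expectation.
#' @param breath_rate_base Baseline air-breath rate, events min^-1 fish^-1,
#'   at the reference oxygen level and cool temperature.
#' @param o2_rate_multipliers Named multipliers of the breath rate per
#'   oxygen level (names are the saturation percentages).
#' @param temp_rate_multiplier Multiplier of the breath rate at the warmer
#'   temperature.
#' @param synchrony_participation Probability `p` in `[0, 1]` that a fish
#'   joins a group surfacing trigger; `p = 0` gives independent (Poisson)
#'   breathing, `p = 1` fully trigger-driven breathing.
#' @param trigger_jitter Within-bout spread of joined breaths, s.
#' @param cohesion_attraction Attraction rate `kappa` (frame^-1) toward the
#'   group centroid in the trajectory model (each frame a fish closes a
#'   fraction `1 - exp(-kappa)` of its distance to the centroid); larger
#'   values give tighter (more cohesive) groups.
#' @param speed_scale Step length of the trajectory model, cm frame^-1.
#' @param heading_sd Angular noise sd (radians frame^-1) of the persistent
#'   random walk.
#' @param o2_noise_sd Gaussian measurement noise of the O2 probe,
#'   mg O2 L^-1.
#' @param background_pre,background_post Blank (bacterial) O2 slopes before
#'   and after a respirometry run, mg O2 L^-1 h^-1.
#' @return An object of class `effect_config`.
#' @export
effect_config <- function(smr_baseline = 0.20,
                          mass_exponent = 0.9,
                          temp_factor = 1.4,
                          smr_sdlog = 0.15,
                          breath_rate_base = 0.5,
                          o2_rate_multipliers = c("100" = 1, "60" = 1.01, "20" = 1.46),
                          temp_rate_multiplier = 1.2,
                          synchrony_participation = 0.1,
                          trigger_jitter = 2,
                          cohesion_attraction = 0.005,
                          speed_scale = 0.12,
                          heading_sd = 0.4,
                          o2_noise_sd = 0.02,
                          background_pre = -0.25,
                          background_post = -0.60) {
  p <- synchrony_participation
  if (p < 0 || p > 1) stop("`synchrony_participation` must be in [0, 1]")
  if (any(c(smr_baseline, breath_rate_base, o2_rate_multipliers,
            temp_rate_multiplier, cohesion_attraction, speed_scale) < 0))
    stop("rates and scales must be >= 0")
  structure(
    list(smr_baseline = smr_baseline, mass_exponent = mass_exponent,
         temp_factor = temp_factor, smr_sdlog = smr_sdlog,
         breath_rate_base = breath_rate_base,
         o2_rate_multipliers = o2_rate_multipliers,
         temp_rate_multiplier = temp_rate_multiplier,
         synchrony_participation = p, trigger_jitter = trigger_jitter,
         cohesion_attraction = cohesion_attraction,
         speed_scale = speed_scale, heading_sd = heading_sd,
         o2_noise_sd = o2_noise_sd,
         background_pre = background_pre, background_post = background_post),
    class = "effect_config"
  )
}

#' Simulate an intermittent-flow respirometry O2 trace
#'
#' Generates a dissolved-oxygen trace with the flush/closed structure of an
#' intermittent-flow system. During each closed phase O2 declines linearly
#' at `uptake / V_eff + |background(t)|` (mg O2 L^-1 h^-1); during flushes
#' it relaxes exponentially back toward saturation with a time constant
#' chosen so a full flush reaches >= 99% of saturation. Gaussian measurement
#' noise is added on top. The generating uptake profile is stored as
#' attribute `truth`.
#'
#' @param chamber A [chamber_config()].
#' @param plan A [cycle_plan()].
#' @param uptake Per-cycle true whole-animal uptake, mg O2 h^-1 (length =
#'   number of cycles).
#' @param background A [background_model()] or `NULL` (no background).
#' @param noise_sd Measurement noise sd, mg O2 L^-1.
#' @param seed Integer seed; identical seeds give identical traces.
#' @param saturation Dissolved O2 at full saturation, mg O2 L^-1.
#' @return An [o2_trace()] with attribute `truth` (list: `uptake`,
#'   `background`, `saturation`).
#' @export
simulate_o2_trace <- function(chamber, plan, uptake, background = NULL,
                              noise_sd = 0, seed = 1, saturation = 8.26) {
  n_cycles <- length(uptake)
  if (n_cycles < 1) stop("`uptake` must give at least one cycle")
  v <- effective_volume_l(chamber)
  tau <- plan$flush_duration / log(100)  # >= 99% recovery within one flush
  times <- seq(0, n_cycles * plan$period, by = plan$sampling_interval)
  o2 <- numeric(length(times))
  o2_now <- saturation
  for (i in seq_along(times)) {
    t <- times[i]
    if (i > 1) {
      dt <- times[i] - times[i - 1]
      t_prev <- times[i - 1]
      cyc <- min(floor(t_prev / plan$period), n_cycles - 1)
      in_flush <- (t_prev - cyc * plan$period) < plan$flush_duration
      if (in_flush) {
        o2_now <- saturation - (saturation - o2_now) * exp(-dt / tau)
      } else {
        bg <- if (is.null(background)) 0 else
          abs(background_at(background, min(max(times[i - 1],
                                                background$trial_start),
                                            background$trial_end)))
        rate <- (uptake[cyc + 1] / v + bg) / 3600  # mg/L/s
        o2_now <- o2_now - rate * dt
      }
      if (o2_now <= 0)
        stop("hypoxic chamber, shorten closed phase: simulated O2 reached zero")
    }
    o2[i] <- o2_now
  }
  if (noise_sd > 0)
    o2 <- .with_seed(seed, pmax(o2 + stats::rnorm(length(o2), 0, noise_sd), 0))
  out <- o2_trace(times, o2, channel_id = chamber$channel_id)
  attr(out, "truth") <- list(uptake = uptake, background = background,
                             saturation = saturation)
  out
}

#' Simulate air-breath events for one trial
#'
#' Superposition of independent and trigger-driven breathing. Each fish
#' breathes independently as a homogeneous Poisson process at rate
#' `rate * (1 - p)`; group triggers arrive as a Poisson process at rate
#' `rate` and each fish joins each trigger independently with probability
#' `p`, breathing within a short jitter window after the trigger. The
#' expected per-fish rate is therefore `rate` for every `p` — synchrony
#' (`p`) can be varied at a fixed overall breathing rate.
#'
#' @param n_fish Number of fish in the group.
#' @param duration Trial duration, s.
#' @param rate Per-fish total breath rate, events min^-1.
#' @param p Trigger participation probability in `[0, 1]`.
#' @param jitter Bout spread, s (joined breaths fall within
#'   `[trigger, trigger + jitter]`).
#' @param seed Integer seed.
#' @param trial_id Trial identifier stamped on the rows.
#' @param fish_ids Fish identifiers (default `f1..fN`).
#' @return Data frame `trial_id`, `fish_id`, `time_s`, sorted by time, with
#'   attribute `truth` (list: `rate`, `p`).
#' @export
simulate_breath_events <- function(n_fish, duration, rate, p = 0, jitter = 2,
                                   seed = 1, trial_id = "trial1",
                                   fish_ids = paste0("f", seq_len(n_fish))) {
  if (!is.finite(rate) || rate < 0) stop("`rate` must be finite and >= 0")
  if (p < 0 || p > 1) stop("`p` must be in [0, 1]")
  dur_min <- duration / 60
  .with_seed(seed, {
    times <- numeric(0); ids <- character(0)
    # independent component
    for (j in seq_len(n_fish)) {
      n <- stats::rpois(1, rate * (1 - p) * dur_min)
      if (n > 0) {
        times <- c(times, stats::runif(n, 0, duration))
        ids <- c(ids, rep(fish_ids[j], n))
      }
    }
    # common-trigger component
    if (p > 0) {
      n_trig <- stats::rpois(1, rate * dur_min)
      trig <- stats::runif(n_trig, 0, duration)
      for (tt in trig) {
        join <- stats::runif(n_fish) < p
        if (any(join)) {
          bt <- pmin(tt + stats::runif(sum(join), 0, jitter), duration)
          times <- c(times, bt)
          ids <- c(ids, fish_ids[join])
        }
      }
    }
    ord <- order(times)
    out <- data.frame(trial_id = rep(trial_id, length(times)),
                      fish_id = ids[ord], time_s = times[ord],
                      stringsAsFactors = FALSE)
    attr(out, "truth") <- list(rate = rate, p = p)
    out
  })
}

#' Simulate 2-D group trajectories in a circular arena
#'
#' Persistent random walk with social attraction: each frame, a fish steps
#' `speed_scale` cm along its heading (heading turning by Gaussian noise)
#' and additionally relaxes a fraction `1 - exp(-kappa)` of its distance
#' toward the current group centroid; positions are reflected at the arena
#' wall. The relaxation form keeps the dynamics stable for any `kappa >= 0`
#' and makes group spread strictly decreasing in `kappa`.
#'
#' @param n_fish Number of fish.
#' @param n_frames Number of frames.
#' @param speed_scale Step length, cm frame^-1.
#' @param kappa Centroid attraction rate, frame^-1 (>= 0; 0 = no social
#'   attraction).
#' @param heading_sd Angular noise sd, radians frame^-1 (0 = straight-line
#'   headings).
#' @param arena An [arena_config()] (supplies the radius).
#' @param seed Integer seed.
#' @return Data frame `frame`, `fish_id`, `x`, `y` (cm, arena-centred), with
#'   attribute `truth` (list: `speed_scale`, `kappa`).
#' @export
simulate_trajectories <- function(n_fish, n_frames, speed_scale, kappa = 0,
                                  heading_sd = 0.4, arena = arena_config(),
                                  seed = 1) {
  if (kappa < 0) stop("`kappa` must be >= 0")
  if (speed_scale <= 0) stop("`speed_scale` must be > 0")
  R <- arena$radius
  .with_seed(seed, {
    # start positions uniform in the disc (rejection-free polar sampling)
    r0 <- R * sqrt(stats::runif(n_fish))
    a0 <- stats::runif(n_fish, 0, 2 * pi)
    x <- r0 * cos(a0); y <- r0 * sin(a0)
    theta <- stats::runif(n_fish, 0, 2 * pi)
    X <- matrix(NA_real_, n_frames, n_fish)
    Y <- matrix(NA_real_, n_frames, n_fish)
    X[1, ] <- x; Y[1, ] <- y
    for (f in 2:n_frames) {
      if (heading_sd > 0)
        theta <- theta + stats::rnorm(n_fish, 0, heading_sd)
      dx <- speed_scale * cos(theta)
      dy <- speed_scale * sin(theta)
      if (kappa > 0) {
        frac <- 1 - exp(-kappa)
        cx <- mean(x); cy <- mean(y)
        dx <- dx + frac * (cx - x)
        dy <- dy + frac * (cy - y)
      }
      x <- x + dx; y <- y + dy
      # radial reflection at the wall
      r <- sqrt(x^2 + y^2)
      out <- r > R
      if (any(out)) {
        x[out] <- x[out] * (2 * R - r[out]) / r[out]
        y[out] <- y[out] * (2 * R - r[out]) / r[out]
        theta[out] <- theta[out] + pi
      }
      X[f, ] <- x; Y[f, ] <- y
    }
    out <- data.frame(
      frame = rep(seq_len(n_frames), n_fish),
      fish_id = rep(paste0("f", seq_len(n_fish)), each = n_frames),
      x = as.vector(X), y = as.vector(Y), stringsAsFactors = FALSE)
    attr(out, "truth") <- list(speed_scale = speed_scale, kappa = kappa)
    out
  })
}

#' Simulate the full factorial study
#'
#' Draws fish masses log-normally, assigns each fish a true SMR from the
#' allometric model `smr_baseline * mass^mass_exponent * temp_factor^(warm)`
#' with log-normal noise, then simulates every behavioural trial of the
#' factorial design: air-breath events (through the common-trigger model,
#' with oxygen-level and temperature rate multipliers) and group
#' trajectories. Per-trial CD, ABF, speed and cohesion are computed with the
#' package's own analysis functions, so the tidy dataset is exactly what the
#' analysis pipeline would produce. With `raw = TRUE` the raw streams
#' (respirometry O2 traces, event tables, trajectories) are returned as
#' well, for end-to-end pipeline runs.
#'
#' @param design A [study_design()].
#' @param effects An [effect_config()].
#' @param seed Integer seed; identical seeds give identical datasets.
#' @param raw Also generate and return the raw input streams.
#' @param behaviour Simulate the behavioural trials (default `TRUE`); with
#'   `FALSE` only masses and the SMR table are generated, which is much
#'   faster for replication studies of the metabolic-rate models alone.
#' @param chamber,plan Respirometry configuration used when `raw = TRUE`
#'   (fish volume is taken from each fish's simulated mass).
#' @return List with `per_fish` (fish x temperature x oxygen rows: fish_id,
#'   group, mass, temp, smr, o2, abf), `per_trial` (trial rows: trial_id,
#'   group, temp, o2, abf_group, cd, clustered, n_events, speed, cohesion),
#'   `truth` (all generating parameters and per-fish true SMR), and — when
#'   `raw = TRUE` — `events`, `roster`, `trajectories`, `traces`, `blanks`.
#' @export
simulate_study <- function(design = study_design(), effects = effect_config(),
                           seed = 1, raw = FALSE, behaviour = TRUE,
                           chamber = NULL, plan = cycle_plan()) {
  d <- design; e <- effects
  fish <- expand.grid(fish = seq_len(d$group_size), group = seq_len(d$n_groups))
  fish$fish_id <- sprintf("g%d_f%d", fish$group, fish$fish)
  fish$group <- sprintf("g%d", fish$group)
  n_fish <- nrow(fish)

  masses <- .with_seed(seed, stats::rlnorm(n_fish, log(1.65), 0.12))
  fish$mass <- masses

  # true SMR per fish x temperature
  smr_tab <- do.call(rbind, lapply(seq_along(d$temperatures), function(ti) {
    tmp <- d$temperatures[ti]
    warm <- as.integer(ti > 1)
    mu <- e$smr_baseline * fish$mass^e$mass_exponent * e$temp_factor^warm
    noise <- .with_seed(seed + 1000L + ti,
                        stats::rlnorm(n_fish, 0, e$smr_sdlog))
    data.frame(fish_id = fish$fish_id, group = fish$group, mass = fish$mass,
               temp = tmp, smr_true = mu, smr = mu * noise,
               stringsAsFactors = FALSE)
  }))
  smr_tab$temp <- factor(smr_tab$temp, levels = d$temperatures)

  if (!behaviour) {
    return(list(per_fish = NULL, per_trial = NULL, smr_table = smr_tab,
                truth = list(design = d, effects = e, seed = seed,
                             smr_true = smr_tab[, c("fish_id", "temp",
                                                    "smr_true")])))
  }

  trials <- expand.grid(group = sprintf("g%d", seq_len(d$n_groups)),
                        temp = d$temperatures, o2 = d$o2_levels,
                        stringsAsFactors = FALSE)
  trials$trial_id <- sprintf("%s_t%g_o%g", trials$group, trials$temp, trials$o2)

  arena <- arena_config(frame_rate = d$frame_rate)
  n_frames <- if (raw) round(d$trial_duration * d$frame_rate) else d$traj_frames

  events_list <- traj_list <- vector("list", nrow(trials))
  per_trial <- vector("list", nrow(trials))
  per_fish <- vector("list", nrow(trials))
  for (i in seq_len(nrow(trials))) {
    tr <- trials[i, ]
    warm <- tr$temp != d$temperatures[1]
    rate <- e$breath_rate_base *
      e$o2_rate_multipliers[[as.character(tr$o2)]] *
      (if (warm) e$temp_rate_multiplier else 1)
    ids <- fish$fish_id[fish$group == tr$group]
    ev <- simulate_breath_events(
      n_fish = d$group_size, duration = d$trial_duration, rate = rate,
      p = e$synchrony_participation, jitter = e$trigger_jitter,
      seed = seed + 2000L + i, trial_id = tr$trial_id, fish_ids = ids)
    traj <- simulate_trajectories(
      n_fish = d$group_size, n_frames = n_frames,
      speed_scale = e$speed_scale, kappa = e$cohesion_attraction,
      heading_sd = e$heading_sd, arena = arena, seed = seed + 3000L + i)
    traj$trial_id <- tr$trial_id
    traj$fish_id <- ids[match(traj$fish_id, paste0("f", seq_len(d$group_size)))]

    cd <- clustered <- NA
    if (nrow(ev) > 0) {
      disp <- coefficient_of_dispersion(bin_events(ev, d$trial_duration))
      cd <- disp$cd; clustered <- disp$clustered
    }
    sp <- mean_speed(traj, arena)
    co <- cohesion(traj)
    per_trial[[i]] <- data.frame(
      trial_id = tr$trial_id, group = tr$group, temp = tr$temp, o2 = tr$o2,
      abf_group = abf_group(ev), cd = cd, clustered = clustered,
      n_events = nrow(ev), speed = sp$mean_speed, cohesion = co$cohesion,
      stringsAsFactors = FALSE)
    abf <- abf_individual(ev, roster = ids)
    per_fish[[i]] <- data.frame(
      trial_id = tr$trial_id, fish_id = names(abf), group = tr$group,
      temp = tr$temp, o2 = tr$o2, abf = unname(abf), stringsAsFactors = FALSE)
    events_list[[i]] <- ev
    traj_list[[i]] <- traj
  }
  per_trial <- do.call(rbind, per_trial)
  per_fish <- do.call(rbind, per_fish)
  per_fish <- merge(per_fish,
                    smr_tab[, c("fish_id", "temp", "mass", "smr")],
                    by.x = c("fish_id", "temp"), by.y = c("fish_id", "temp"),
                    sort = FALSE)
  for (col in c("temp", "o2")) {
    per_trial[[col]] <- factor(per_trial[[col]],
                               levels = if (col == "temp") d$temperatures else d$o2_levels)
    per_fish[[col]] <- factor(per_fish[[col]],
                              levels = if (col == "temp") d$temperatures else d$o2_levels)
  }

  out <- list(
    per_fish = per_fish[order(per_fish$trial_id, per_fish$fish_id), ],
    per_trial = per_trial,
    smr_table = smr_tab,
    truth = list(design = d, effects = e, seed = seed,
                 smr_true = smr_tab[, c("fish_id", "temp", "smr_true")]))
  rownames(out$per_fish) <- NULL

  if (raw) {
    roster <- unique(per_fish[, c("trial_id", "fish_id")])
    events <- do.call(rbind, events_list)
    trajectories <- do.call(rbind, traj_list)
    n_cycles <- floor(d$respirometry_duration / plan$period)
    traces <- list(); blanks <- list()
    for (r in seq_len(nrow(smr_tab))) {
      ch <- if (is.null(chamber))
        chamber_config(75, 5, fish_mass = smr_tab$mass[r],
                       channel_id = smr_tab$fish_id[r])
      else chamber
      bg <- background_model(e$background_pre, e$background_post,
                             0, n_cycles * plan$period)
      # baseline uptake plus sporadic activity bursts above it
      bursts <- .with_seed(seed + 4000L + r, {
        b <- stats::rexp(n_cycles, 1) * 0.6 *
          (stats::runif(n_cycles) < 0.35)
        b
      })
      uptake <- smr_tab$smr[r] * (1 + bursts)
      key <- sprintf("%s_t%g", smr_tab$fish_id[r], as.numeric(as.character(smr_tab$temp[r])))
      traces[[key]] <- simulate_o2_trace(
        ch, plan, uptake, background = bg, noise_sd = e$o2_noise_sd,
        seed = seed + 5000L + r)
      blanks[[key]] <- bg
    }
    out$events <- events
    out$roster <- roster
    out$trajectories <- trajectories
    out$traces <- traces
    out$blanks <- blanks
  }
  out
}
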