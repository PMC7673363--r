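# Intermittent-flow respirometry: from raw O2 traces to per-cycle oxygen
# uptake and a standard metabolic rate (SMR) estimate per fish.

#' Respirometry chamber configuration
#'
#' Describes one respirometry channel: the glass chamber, its associated
#' tubing, and the fish inside. The effective water volume used to convert an
#' oxygen-decline slope into a whole-animal uptake rate is
#' `chamber_volume + tubing_volume - fish_volume`.
#'
#' @param chamber_volume Chamber volume in mL (> 0).
#' @param tubing_volume Volume of the recirculation tubing in mL (>= 0).
#' @param fish_mass Wet mass of the fish in g.
#' @param fish_volume Volume of the fish in mL. If `NULL`, derived from mass
#'   assuming tissue density 1 g mL^-1 (standard respirometry practice).
#' @param channel_id Identifier of the respirometry channel.
#'
#' @return An object of class `chamber_config`.
#' @examples
#' chamber_config(75, 5, fish_mass = 1.65, channel_id = "ch1")
#' @export
chamber_config <- function(chamber_volume, tubing_volume = 0, fish_mass = NA_real_,
                           fish_volume = NULL, channel_id = "ch1") {
  if (!is.numeric(chamber_volume) || chamber_volume <= 0)
    stop("`chamber_volume` must be a positive number (mL)")
  if (tubing_volume < 0) stop("`tubing_volume` must be >= 0")
  if (is.null(fish_volume)) {
    fish_volume <- if (is.na(fish_mass)) 0 else fish_mass  # density 1 g/mL
  }
  if (fish_volume < 0) stop("`fish_volume` must be >= 0")
  if (fish_volume >= chamber_volume + tubing_volume)
    stop("`fish_volume` must be smaller than chamber + tubing volume")
  structure(
    list(chamber_volume = chamber_volume, tubing_volume = tubing_volume,
         fish_mass = fish_mass, fish_volume = fish_volume,
         channel_id = channel_id),
    class = "chamber_config"
  )
}

#' Effective water volume of a respirometry channel
#'
#' @param chamber A [chamber_config()] object.
#' @return Effective volume in litres.
#' @export
effective_volume_l <- function(chamber) {
  v <- chamber$chamber_volume + chamber$tubing_volume - chamber$fish_volume
  if (v <= 0) stop("non-positive effective volume")
  v / 1000
}

#' Intermittent-flow cycle plan
#'
#' Timing of the flush/closed respirometry cycle. Defaults follow a common
#' protocol for small fish: chambers flushed with oxygenated water for 2 min
#' every 8 min, oxygen logged every 2 s, the first minute after closure
#' discarded, and a 16 h overnight run.
#'
#' @param flush_duration Flush (re-oxygenation) phase length, s.
#' @param closed_duration Sealed measurement phase length, s.
#' @param discard_initial Seconds discarded at the start of each closed phase
#'   (mixing transient), must be < `closed_duration`.
#' @param sampling_interval Sampling interval of the oxygen probe, s.
#' @param total_duration Nominal total trial duration, s.
#'
#' @return An object of class `cycle_plan`; `$period` is the full cycle
#'   length `flush_duration + closed_duration`.
#' @export
cycle_plan <- function(flush_duration = 120, closed_duration = 360,
                       discard_initial = 60, sampling_interval = 2,
                       total_duration = 16 * 3600) {
  if (flush_duration < 0 || closed_duration <= 0)
    stop("phase durations must be positive")
  if (discard_initial >= closed_duration)
    stop("`discard_initial` must be shorter than the closed phase")
  if (sampling_interval <= 0) stop("`sampling_interval` must be > 0")
  structure(
    list(flush_duration = flush_duration, closed_duration = closed_duration,
         discard_initial = discard_initial,
         sampling_interval = sampling_interval,
         total_duration = total_duration,
         period = flush_duration + closed_duration),
    class = "cycle_plan"
  )
}

#' Dissolved-oxygen trace for one respirometry channel
#'
#' @param timestamps Time in seconds, strictly increasing.
#' @param o2 Dissolved oxygen, mg O2 L^-1, non-negative.
#' @param temperature Water temperature in deg C (scalar or per-sample).
#' @param channel_id Channel identifier.
#'
#' @return An object of class `o2_trace` (a data frame with columns
#'   `time_s`, `o2_mg_l`, `temp_c` and attribute `channel_id`).
#' @export
o2_trace <- function(timestamps, o2, temperature = NA_real_, channel_id = "ch1") {
  if (length(timestamps) != length(o2))
    stop("`timestamps` and `o2` must have equal length")
  if (any(diff(timestamps) <= 0))
    stop("timestamps must be strictly increasing")
  if (any(o2 < 0)) stop("negative O2 concentrations in trace")
  out <- data.frame(time_s = as.numeric(timestamps), o2_mg_l = as.numeric(o2),
                    temp_c = rep_len(as.numeric(temperature), length(o2)))
  attr(out, "channel_id") <- channel_id
  class(out) <- c("o2_trace", "data.frame")
  out
}

#' Segment an O2 trace into closed-phase measurement windows
#'
#' Splits a trace into flush/closed cycles and returns, for each complete
#' cycle, the measurement window: the closed phase minus the initial discard
#' period. Trailing partial cycles are dropped, never extrapolated.
#'
#' @param trace An [o2_trace()].
#' @param plan A [cycle_plan()].
#'
#' @return A list of windows; each is a list with `cycle_index` (1-based),
#'   `start`, `end` (absolute seconds), and `data` (the trace rows whose
#'   timestamps fall in `[start, end]`).
#' @export
segment_cycles <- function(trace, plan) {
  stopifnot(inherits(plan, "cycle_plan"))
  if (any(diff(trace$time_s) <= 0)) stop("timestamps must be strictly increasing")
  t0 <- trace$time_s[1]
  duration <- trace$time_s[nrow(trace)] - t0
  n_cycles <- floor((duration + plan$sampling_interval / 2) / plan$period)
  if (n_cycles < 1) stop("trace too short: shorter than one full cycle")
  windows <- vector("list", n_cycles)
  for (k in seq_len(n_cycles)) {
    cyc_start <- t0 + (k - 1) * plan$period
    w_start <- cyc_start + plan$flush_duration + plan$discard_initial
    w_end <- cyc_start + plan$period
    rows <- trace$time_s >= w_start & trace$time_s <= w_end
    windows[[k]] <- list(cycle_index = k, start = w_start, end = w_end,
                         data = trace[rows, , drop = FALSE])
  }
  windows
}

#' Fit an oxygen-decline slope over one closed-phase window
#'
#' Ordinary least-squares regression of oxygen concentration on time over the
#' retained samples of a measurement window. The slope is reported per hour
#' (negative when oxygen declines). For a zero-variance (constant) O2 signal
#' r-squared is defined as 0.
#'
#' @param window A window as returned by [segment_cycles()], or an
#'   [o2_trace()] / data frame with columns `time_s` and `o2_mg_l`.
#'
#' @return An object of class `slope_estimate`: list with `cycle_index`,
#'   `slope` (mg O2 L^-1 h^-1), `intercept` (mg O2 L^-1 at window start),
#'   `r_squared`, `midpoint_time` (s), `n`.
#' @examples
#' w <- data.frame(time_s = 0:299, o2_mg_l = 8 - 0.001 * (0:299))
#' fit_slope(w)$slope  # -3.6 mg O2 / L / h
#' @export
fit_slope <- function(window) {
  cycle_index <- NA_integer_
  dat <- window
  if (is.list(window) && !is.data.frame(window) && !is.null(window$data)) {
    cycle_index <- window$cycle_index
    dat <- window$data
  }
  if (nrow(dat) < 3) stop("fewer than 3 retained samples in window")
  t <- dat$time_s
  y <- dat$o2_mg_l
  if (stats::var(t) == 0) stop("constant time values in window")
  fit <- stats::lm(y ~ t)
  slope_s <- unname(stats::coef(fit)[2])
  sst <- sum((y - mean(y))^2)
  r2 <- if (sst == 0) 0 else 1 - sum(stats::residuals(fit)^2) / sst
  structure(
    list(cycle_index = cycle_index,
         slope = slope_s * 3600,
         intercept = unname(stats::coef(fit)[1] + slope_s * t[1]),
         r_squared = r2,
         midpoint_time = mean(range(t)),
         n = length(t)),
    class = "slope_estimate"
  )
}

#' Linear bacterial background model
#'
#' Background (microbial) oxygen uptake in the empty system, measured as
#' blank slopes before and after the animal trial and assumed to change
#' linearly in between. If only one blank exists, the background is treated
#' as constant at that value, with a warning.
#'
#' @param pre_slope Blank O2 slope before the trial, mg O2 L^-1 h^-1
#'   (typically <= 0), or `NA`.
#' @param post_slope Blank O2 slope after the trial, or `NA`.
#' @param trial_start,trial_end Trial time span, s.
#'
#' @return An object of class `background_model`.
#' @export
background_model <- function(pre_slope, post_slope, trial_start, trial_end) {
  if (trial_end <= trial_start) stop("`trial_end` must exceed `trial_start`")
  if (is.na(pre_slope) && is.na(post_slope))
    stop("at least one blank slope is required")
  if (is.na(pre_slope) || is.na(post_slope)) {
    warning("only one blank measurement supplied; background treated as constant")
    val <- if (is.na(pre_slope)) post_slope else pre_slope
    pre_slope <- post_slope <- val
  }
  structure(
    list(pre_slope = pre_slope, post_slope = post_slope,
         trial_start = trial_start, trial_end = trial_end),
    class = "background_model"
  )
}

#' Evaluate the background O2 slope at a time point
#'
#' Linear interpolation between the pre- and post-trial blank slopes. No
#' extrapolation outside the trial span.
#'
#' @param model A [background_model()].
#' @param t Time in seconds, within `[trial_start, trial_end]`.
#' @return Background slope at `t`, mg O2 L^-1 h^-1 (vectorised over `t`).
#' @export
background_at <- function(model, t) {
  stopifnot(inherits(model, "background_model"))
  if (any(t < model$trial_start | t > model$trial_end))
    stop("time outside the trial span; background is not extrapolated")
  frac <- (t - model$trial_start) / (model$trial_end - model$trial_start)
  model$pre_slope + frac * (model$post_slope - model$pre_slope)
}

#' Convert a fitted slope to whole-animal oxygen uptake
#'
#' Subtracts the background slope from the measured slope and multiplies by
#' the effective water volume (chamber + tubing - fish, converted mL to L):
#' `MO2 = (|slope| - |background|) * V_eff`. A background larger than the
#' measured slope yields a negative uptake; such values are retained and
#' flagged (not clamped) so the downstream quantile estimator sees the raw
#' distribution.
#'
#' @param slope A `slope_estimate` (or a bare numeric slope, mg O2 L^-1 h^-1).
#' @param bg Background slope at the window midpoint, mg O2 L^-1 h^-1.
#' @param chamber A [chamber_config()].
#'
#' @return List with `mo2` (mg O2 h^-1), `background_share`
#'   (`|bg| / |slope|`, `NA` when the fish slope is 0), and `flagged`
#'   (`TRUE` when the corrected uptake is negative).
#' @examples
#' ch <- chamber_config(75, 5, fish_volume = 1.65)
#' compute_mo2(-1.2, bg = -0.2, chamber = ch)$mo2  # 0.07835
#' @export
compute_mo2 <- function(slope, bg, chamber) {
  s <- if (inherits(slope, "slope_estimate")) slope$slope else slope
  v <- effective_volume_l(chamber)
  net <- abs(s) - abs(bg)
  mo2 <- net * v
  list(mo2 = mo2,
       background_share = if (abs(s) > 0) abs(bg) / abs(s) else NA_real_,
       flagged = mo2 < 0)
}

#' Per-cycle oxygen-uptake series for one fish
#'
#' Bundles background-corrected per-cycle uptake values with their background
#' shares; the input to [estimate_smr()].
#'
#' @param mo2 Numeric vector of per-cycle uptake values, mg O2 h^-1.
#' @param background_share Per-cycle `|background| / |slope|` fractions.
#' @param channel_id,fish_id Identifiers.
#' @return An object of class `mo2_series`.
#' @export
mo2_series <- function(mo2, background_share = rep(NA_real_, length(mo2)),
                       channel_id = "ch1", fish_id = NA_character_) {
  if (length(background_share) != length(mo2))
    stop("`background_share` must match `mo2` in length")
  structure(
    list(mo2 = as.numeric(mo2), background_share = as.numeric(background_share),
         channel_id = channel_id, fish_id = fish_id),
    class = "mo2_series"
  )
}

#' Process a full O2 trace into an MO2 series
#'
#' Convenience wrapper: segments the trace, fits a slope per closed phase,
#' evaluates the background at each window midpoint, and converts to uptake.
#'
#' @param trace An [o2_trace()].
#' @param plan A [cycle_plan()].
#' @param chamber A [chamber_config()].
#' @param background A [background_model()], or `NULL` for no correction.
#' @param r2_min Optional minimum r-squared for a cycle to be retained
#'   (default `NULL`: no filtering by fit quality).
#'
#' @return An `mo2_series` with one value per accepted cycle; attribute
#'   `slopes` keeps the per-cycle `slope_estimate`s.
#' @export
trace_to_mo2 <- function(trace, plan, chamber, background = NULL, r2_min = NULL) {
  wins <- segment_cycles(trace, plan)
  slopes <- lapply(wins, fit_slope)
  if (!is.null(r2_min)) {
    keep <- vapply(slopes, function(s) s$r_squared >= r2_min, logical(1))
    slopes <- slopes[keep]
  }
  if (length(slopes) == 0) stop("no cycles retained")
  bg <- if (is.null(background)) rep(0, length(slopes)) else
    vapply(slopes, function(s) background_at(background, s$midpoint_time), numeric(1))
  res <- mapply(function(s, b) compute_mo2(s, b, chamber), slopes, bg,
                SIMPLIFY = FALSE)
  n_flag <- sum(vapply(res, `[[`, logical(1), "flagged"))
  if (n_flag > 0)
    message(sprintf("%d cycle(s) with background exceeding the fish slope (negative uptake retained)", n_flag))
  out <- mo2_series(vapply(res, `[[`, numeric(1), "mo2"),
                    vapply(res, `[[`, numeric(1), "background_share"),
                    channel_id = attr(trace, "channel_id"))
  attr(out, "slopes") <- slopes
  out
}

#' Estimate standard metabolic rate from an MO2 series
#'
#' SMR is estimated as the lowest 20th percentile of the per-cycle uptake
#' values over the trial. Two readings of that definition are supported:
#' `"quantile"` (default) takes the 0.2-quantile by sorted-order linear
#' interpolation (plotting position `(k-1)/(n-1)`, i.e. [stats::quantile()]
#' type 7); `"mean_lowest"` averages the lowest 20% of values. The quantile
#' probability itself is adjustable via `p`.
#'
#' @param series An [mo2_series()] (or bare numeric vector of uptake values).
#' @param method `"quantile"` or `"mean_lowest"`.
#' @param p Quantile probability / lowest fraction, default 0.2.
#' @param min_cycles Minimum number of cycles required (default 5).
#'
#' @return An object of class `smr_estimate`: list with `smr` (mg O2 h^-1),
#'   `method` (descriptor recorded in output), `n_cycles`, and
#'   `mean_background_fraction` (mean per-cycle background share, percent;
#'   `NA` when shares are unknown).
#' @examples
#' x <- c(0.08, 0.09, 0.10, 0.11, 0.12, 0.14, 0.15, 0.18, 0.20, 0.25, 0.30)
#' estimate_smr(mo2_series(x))$smr  # 0.10
#' @export
estimate_smr <- function(series, method = c("quantile", "mean_lowest"),
                         p = 0.2, min_cycles = 5) {
  method <- match.arg(method)
  x <- if (inherits(series, "mo2_series")) series$mo2 else as.numeric(series)
  shares <- if (inherits(series, "mo2_series")) series$background_share else
    rep(NA_real_, length(x))
  n <- length(x)
  if (n < min_cycles)
    stop(sprintf("too few cycles: %d supplied, minimum is %d", n, min_cycles))
  smr <- if (method == "quantile") {
    unname(stats::quantile(x, probs = p, type = 7))
  } else {
    xs <- sort(x)
    mean(xs[seq_len(max(1L, floor(n * p)))])
  }
  structure(
    list(smr = smr,
         method = sprintf("%s_p%.2g", method, p),
         n_cycles = n,
         mean_background_fraction = if (all(is.na(shares))) NA_real_ else
           100 * mean(shares, na.rm = TRUE)),
    class = "smr_estimate"
  )
}

#' Convert percent air saturation to oxygen concentration
#'
#' @param sat Percent air saturation (>= 0).
#' @param solubility Dissolved O2 at 100% air saturation for the prevailing
#'   temperature and salinity, mg O2 L^-1.
#' @return Concentration in mg O2 L^-1.
#' @examples
#' convert_saturation(60, solubility = 8.26)  # 4.956
#' @export
convert_saturation <- function(sat, solubility) {
  if (any(sat < 0)) stop("`sat` must be >= 0")
  if (any(solubility <= 0)) stop("`solubility` must be > 0")
  sat / 100 * solubility
}

#' @export
print.smr_estimate <- function(x, ...) {
  cat(sprintf("SMR estimate: %.4g mg O2/h (%s, %d cycles", x$smr, x$method,
              x$n_cycles))
  if (!is.na(x$mean_background_fraction))
    cat(sprintf(", mean background %.1f%%", x$mean_background_fraction))
  cat(")\n")
  invisible(x)
}
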