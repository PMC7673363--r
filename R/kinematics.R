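# Group activity (mean speed) and social cohesion (mean pairwise distance)
# from 2-D trajectories of tracked fish.

#' Behavioural arena configuration
#'
#' @param area Arena floor area, cm^2 (default 3117, a circular tank of
#'   radius ~31.5 cm).
#' @param px_per_cm Pixel-to-cm calibration scale of the video.
#' @param frame_rate Video frame rate, frames s^-1.
#' @return An object of class `arena_config` with derived `radius` (cm).
#' @export
arena_config <- function(area = 3117, px_per_cm = 1, frame_rate = 25) {
  if (area <= 0 || px_per_cm <= 0 || frame_rate <= 0)
    stop("`area`, `px_per_cm` and `frame_rate` must all be > 0")
  structure(
    list(area = area, radius = sqrt(area / pi), px_per_cm = px_per_cm,
         frame_rate = frame_rate),
    class = "arena_config"
  )
}

#' Convert pixel trajectories to cm
#'
#' Divides `x` and `y` by the calibration scale. Missing positions (tracking
#' dropouts, `NA`) pass through unchanged.
#'
#' @param traj Data frame with columns `frame`, `fish_id`, `x`, `y`
#'   (pixels).
#' @param px_per_cm Calibration scale, pixels per cm (> 0).
#' @return The same data frame with `x`, `y` in cm.
#' @export
calibrate <- function(traj, px_per_cm) {
  if (!is.numeric(px_per_cm) || px_per_cm <= 0)
    stop("`px_per_cm` must be a positive number")
  traj$x <- traj$x / px_per_cm
  traj$y <- traj$y / px_per_cm
  traj
}

# long (frame, fish_id, x, y) -> list of x and y matrices [frame, fish]
.traj_matrices <- function(traj) {
  frames <- sort(unique(traj$frame))
  fish <- sort(unique(as.character(traj$fish_id)))
  fi <- match(traj$frame, frames)
  fj <- match(as.character(traj$fish_id), fish)
  x <- matrix(NA_real_, length(frames), length(fish),
              dimnames = list(NULL, fish))
  y <- x
  x[cbind(fi, fj)] <- traj$x
  y[cbind(fi, fj)] <- traj$y
  list(x = x, y = y, frames = frames, fish = fish)
}

#' Group activity: mean swimming speed
#'
#' Per fish, speed is the mean over consecutive valid frame pairs of
#' displacement times frame rate (cm s^-1); the group value is the
#' unweighted mean over fish, which is robust to unequal numbers of valid
#' frames per fish. Frame pairs containing a missing position are skipped
#' (never interpolated); a fish with no valid frame pair is excluded with a
#' warning. Pooling all displacement steps across fish before averaging is
#' available as a switch.
#'
#' @param traj Data frame `frame`, `fish_id`, `x`, `y` in cm.
#' @param arena An [arena_config()] (supplies the frame rate).
#' @param pooled If `TRUE`, average displacement steps pooled across fish
#'   instead of averaging per-fish means.
#' @return An object of class `activity_result`: list with `mean_speed`
#'   (cm s^-1), `per_fish_speeds` (named), `frames_used`.
#' @export
mean_speed <- function(traj, arena, pooled = FALSE) {
  m <- .traj_matrices(traj)
  if (length(m$frames) < 2) stop("need at least 2 frames to measure speed")
  dx <- diff(m$x); dy <- diff(m$y)
  step <- sqrt(dx^2 + dy^2) * arena$frame_rate  # cm/s per consecutive pair
  valid <- !is.na(step)
  n_valid <- colSums(valid)
  if (all(n_valid == 0)) stop("no fish has a valid consecutive frame pair")
  if (any(n_valid == 0))
    warning(sprintf("fish excluded from speed (no valid frame pair): %s",
                    paste(m$fish[n_valid == 0], collapse = ", ")))
  per_fish <- colMeans(step, na.rm = TRUE)[n_valid > 0]
  group <- if (pooled) mean(step[valid]) else mean(per_fish)
  structure(
    list(mean_speed = group, per_fish_speeds = per_fish,
         frames_used = length(m$frames)),
    class = "activity_result"
  )
}

# mean pairwise Euclidean distance among valid points in one frame
.frame_mean_pairdist <- function(xs, ys) {
  ok <- !is.na(xs) & !is.na(ys)
  if (sum(ok) < 2) return(NA_real_)
  mean(stats::dist(cbind(xs[ok], ys[ok])))
}

#' Group cohesion: mean pairwise inter-individual distance
#'
#' Per frame, the mean Euclidean distance over all unordered pairs of fish
#' with both positions valid; the trial value is the mean over frames.
#' Smaller values indicate individuals closer together, i.e. a more cohesive
#' group. Frames with fewer than 2 valid positions are skipped.
#'
#' @param traj Data frame `frame`, `fish_id`, `x`, `y` in cm.
#' @return An object of class `cohesion_result`: list with `cohesion` (cm),
#'   `n_pairs` (pairs per complete frame), `frames_used`.
#' @export
cohesion <- function(traj) {
  m <- .traj_matrices(traj)
  n_fish <- length(m$fish)
  per_frame <- vapply(seq_along(m$frames),
                      function(i) .frame_mean_pairdist(m$x[i, ], m$y[i, ]),
                      numeric(1))
  used <- !is.na(per_frame)
  if (!any(used)) stop("no frame has 2 or more valid positions")
  structure(
    list(cohesion = mean(per_frame[used]),
         n_pairs = n_fish * (n_fish - 1) / 2,
         frames_used = sum(used)),
    class = "cohesion_result"
  )
}

#' Smooth trajectories with a centred moving average
#'
#' Optional pre-processing: raw tracking jitter inflates speed estimates; a
#' short moving-average window suppresses it. Off by default throughout the
#' pipeline; its use is logged.
#'
#' @param traj Data frame `frame`, `fish_id`, `x`, `y`.
#' @param window Odd window length in frames (>= 3).
#' @return The smoothed data frame.
#' @export
smooth_trajectory <- function(traj, window = 5) {
  if (window < 3 || window %% 2 == 0) stop("`window` must be odd and >= 3")
  sm <- function(v) as.numeric(stats::filter(v, rep(1 / window, window),
                                             sides = 2))
  out <- traj[order(as.character(traj$fish_id), traj$frame), ]
  for (id in unique(out$fish_id)) {
    sel <- out$fish_id == id
    xs <- sm(out$x[sel]); ys <- sm(out$y[sel])
    # keep original values at the edges where the window is incomplete
    out$x[sel] <- ifelse(is.na(xs), out$x[sel], xs)
    out$y[sel] <- ifelse(is.na(ys), out$y[sel], ys)
  }
  out
}

#' Per-trial kinematics summary
#'
#' @param traj Data frame `frame`, `fish_id`, `x`, `y` (cm), optionally with
#'   a `trial_id` column to split on.
#' @param arena An [arena_config()].
#' @return Data frame `trial_id`, `mean_speed_cm_s`, `cohesion_cm`,
#'   `frames_used`.
#' @export
kinematics_summary <- function(traj, arena) {
  split_ids <- if ("trial_id" %in% names(traj))
    as.character(traj$trial_id) else rep("trial1", nrow(traj))
  do.call(rbind, lapply(unique(split_ids), function(tid) {
    tr <- traj[split_ids == tid, , drop = FALSE]
    sp <- mean_speed(tr, arena)
    co <- cohesion(tr)
    data.frame(trial_id = tid, mean_speed_cm_s = sp$mean_speed,
               cohesion_cm = co$cohesion, frames_used = co$frames_used,
               stringsAsFactors = FALSE)
  }))
}
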