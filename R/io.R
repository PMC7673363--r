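# CSV readers and writers for the pipeline's tabular interfaces. All files
# are plain CSV with documented headers; comment lines starting '#' (probe
# export dialects) are skipped on read.

.read_csv <- function(path) {
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Read oxygen traces from a long-format CSV
#'
#' Expected header: `time_s,channel,o2_mg_l,temp_c`. Alternatively the
#' oxygen column may be `o2_sat_pct` (percent air saturation), in which case
#' `solubility` (mg O2 L^-1 at 100% saturation) must be supplied and the
#' values are converted with [convert_saturation()].
#'
#' @param path CSV file path.
#' @param solubility Solubility for saturation-unit traces, mg O2 L^-1.
#' @return Named list of [o2_trace()] objects, one per channel.
#' @export
read_o2_traces <- function(path, solubility = NULL) {
  df <- .read_csv(path)
  if (!"o2_mg_l" %in% names(df)) {
    if (!"o2_sat_pct" %in% names(df))
      stop("trace CSV needs an `o2_mg_l` or `o2_sat_pct` column")
    if (is.null(solubility))
      stop("`solubility` is required to convert `o2_sat_pct` traces")
    df$o2_mg_l <- convert_saturation(df$o2_sat_pct, solubility)
  }
  temp <- if ("temp_c" %in% names(df)) df$temp_c else NA_real_
  chans <- unique(as.character(df$channel))
  stats::setNames(lapply(chans, function(ch) {
    sel <- df$channel == ch
    o2_trace(df$time_s[sel], df$o2_mg_l[sel],
             temperature = if (length(temp) > 1) temp[sel] else temp,
             channel_id = ch)
  }), chans)
}

#' Read an air-breath event table
#'
#' Expected columns: `trial_id`, `fish_id`, `time_s`; optional design
#' columns (`group`, `temp_c`, `o2_pct`) are carried through.
#'
#' @param path CSV file path.
#' @return Data frame of events.
#' @export
read_breath_events <- function(path) {
  df <- .read_csv(path)
  need <- c("trial_id", "fish_id", "time_s")
  if (!all(need %in% names(df)))
    stop("event CSV must have columns: ", paste(need, collapse = ", "))
  df
}

#' Read a trajectory table
#'
#' Expected columns: `frame`, `fish_id`, `x`, `y` (optional `trial_id`).
#' Empty fields become `NA` (tracking dropouts).
#'
#' @param path CSV file path.
#' @param px_per_cm If supplied, positions are assumed to be pixels and are
#'   calibrated to cm with [calibrate()].
#' @return Data frame of positions in cm.
#' @export
read_trajectories <- function(path, px_per_cm = NULL) {
  df <- .read_csv(path)
  need <- c("frame", "fish_id", "x", "y")
  if (!all(need %in% names(df)))
    stop("trajectory CSV must have columns: ", paste(need, collapse = ", "))
  if (!is.null(px_per_cm)) df <- calibrate(df, px_per_cm)
  df
}

#' Write a data frame as CSV
#'
#' @param x Data frame.
#' @param path Output path (directories created as needed).
#' @return `path`, invisibly.
#' @export
write_table_csv <- function(x, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(x, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
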