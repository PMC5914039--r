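ACTIVITY_LEVELS <- c("sleep", "sedentary", "standing", "walking", "running",
                     "other_mvpa_context", "nonwear")

#' Classifier thresholds
#'
#' Default thresholds of the transparent decision-tree activity-type
#' classifier. Posture is the inclination change from the subject's standing
#' reference orientation (device vertical along gravity when upright);
#' cadence bands are in Hz; intensities in mg.
#'
#' @param posture_deg inclination above which posture is taken as
#'   sitting/lying (default 30).
#' @param standing_ref_deg inclination of the standing reference (default 0).
#' @param sedentary_mg intensity below which a window is motionless
#'   (default 30).
#' @param walk_band cadence band for walking, Hz (default 1.4--2.5).
#' @param walk_periodicity minimum autocorrelation peak for gait
#'   (default 0.3).
#' @param walk_mg walking intensity range, mg (default 50--400).
#' @param run_cadence_hz running cadence floor, Hz (default 2.5).
#' @param run_mg running intensity floor, mg (default 400).
#' @param cutpoint_mg MVPA cut-point, mg (default 70, inclusive).
#' @param min_wear_frac minimum worn fraction for a window to be classified
#'   rather than passed through as non-wear (default 0.5).
#' @return A named list of class `classifier_rules`.
#' @export
classifier_rules <- function(posture_deg = 30, standing_ref_deg = 0,
                             sedentary_mg = 30,
                             walk_band = c(1.4, 2.5), walk_periodicity = 0.3,
                             walk_mg = c(50, 400),
                             run_cadence_hz = 2.5, run_mg = 400,
                             cutpoint_mg = 70, min_wear_frac = 0.5) {
  structure(list(posture_deg = posture_deg, standing_ref_deg = standing_ref_deg,
                 sedentary_mg = sedentary_mg, walk_band = walk_band,
                 walk_periodicity = walk_periodicity, walk_mg = walk_mg,
                 run_cadence_hz = run_cadence_hz, run_mg = run_mg,
                 cutpoint_mg = cutpoint_mg, min_wear_frac = min_wear_frac),
            class = "classifier_rules")
}

#' Flag MVPA epochs by ENMO cut-point
#'
#' An epoch is moderate-to-vigorous physical activity iff it is worn and its
#' ENMO is at or above the cut-point (70 mg by default, inclusive). Non-wear
#' and gap epochs never carry the flag.
#'
#' @param epochs an [epoch_series()].
#' @param cutpoint_mg cut-point in mg (> 0).
#' @return Data frame with `epoch_start` and logical `mvpa`.
#' @export
flag_mvpa <- function(epochs, cutpoint_mg = 70) {
  if (!is_scalar_number(cutpoint_mg) || cutpoint_mg <= 0)
    stop_config("cutpoint_mg must be > 0")
  mvpa <- epochs$wear & !epochs$gap & !is.na(epochs$enmo_mg) &
    epochs$enmo_mg >= cutpoint_mg
  data.frame(epoch_start = epochs$epoch_start, mvpa = mvpa)
}

#' Read a sleep diary CSV
#'
#' Expects `subject_id,date,bed_time,wake_time,nap_minutes`. Bed and wake
#' times are ISO-8601 timestamps (empty when only a nightly duration was
#' recorded).
#' @param path CSV path.
#' @return Data frame of diary days.
#' @export
read_sleep_diary <- function(path) {
  if (!file.exists(path)) stop_validation("diary file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df$date <- as.Date(df$date)
  for (cl in c("bed_time", "wake_time"))
    df[[cl]] <- as.POSIXct(df[[cl]], tz = "UTC",
                           tryFormats = c("%Y-%m-%dT%H:%M:%S",
                                          "%Y-%m-%d %H:%M:%S"))
  df
}

# Sleep intervals (bed/wake + naps) for one subject, sorted and checked for
# overlap.
diary_intervals <- function(diary) {
  di <- diary[!is.na(diary$bed_time) & !is.na(diary$wake_time), , drop = FALSE]
  if (nrow(di) == 0L)
    return(data.frame(start = as.POSIXct(character(), tz = "UTC"),
                      end = as.POSIXct(character(), tz = "UTC")))
  iv <- data.frame(start = di$bed_time, end = di$wake_time)
  iv <- iv[order(iv$start), , drop = FALSE]
  if (any(iv$end <= iv$start))
    stop_validation("diary interval with wake_time <= bed_time")
  if (nrow(iv) > 1L && any(iv$start[-1] < iv$end[-nrow(iv)]))
    stop_validation("overlapping diary sleep intervals")
  iv
}

in_intervals <- function(times, iv) {
  if (nrow(iv) == 0L) return(rep(FALSE, length(times)))
  i <- findInterval(as.numeric(times), as.numeric(iv$start))
  i > 0L & as.numeric(times) < as.numeric(iv$end)[pmax(i, 1L)]
}

#' Decision-tree activity-type classification
#'
#' Assigns each epoch exactly one label from sleep, sedentary, standing,
#' walking, running, other_mvpa_context or nonwear. Non-wear passes through;
#' diary sleep intervals override everything else worn; motionless windows
#' split into sedentary vs standing by posture; periodic windows in the
#' walking cadence band with walking-range intensity are walking; running
#' needs either a periodic cadence above the running floor or intensity
#' above the running intensity floor; remaining MVPA-intensity windows are
#' other_mvpa_context; any residue falls back on posture. Window labels are
#' broadcast to their 1 s epochs; the per-epoch MVPA flag is independent of
#' the label (see [flag_mvpa()]).
#'
#' @param features output of [extract_features()].
#' @param epochs the matching [epoch_series()].
#' @param diary optional diary data frame for this subject (see
#'   [read_sleep_diary()]); only rows with bed/wake timestamps contribute
#'   intervals.
#' @param rules a [classifier_rules()] list.
#' @return A data frame of class `label_series` with `epoch_start`,
#'   `label` (factor) and `mvpa` (logical).
#' @export
classify_types <- function(features, epochs, diary = NULL,
                           rules = classifier_rules()) {
  window_s <- attr(features, "window_s") %||% 5
  n_w <- nrow(features)

  # worn fraction per window
  widx <- floor(as.numeric(epochs$epoch_start - features$window_start[1],
                           units = "secs") / window_s) + 1L
  ok <- widx >= 1L & widx <= n_w
  wear_n <- tabulate(widx[ok][epochs$wear[ok]], n_w)
  tot_n <- tabulate(widx[ok], n_w)
  wear_frac <- ifelse(tot_n > 0, wear_n / tot_n, 0)

  iv <- if (is.null(diary)) diary_intervals(data.frame(bed_time = NA, wake_time = NA)[0, ])
        else diary_intervals(diary)
  asleep <- in_intervals(features$window_start, iv)

  inten <- features$mean_enmo
  tilt <- abs(features$inclination_deg - rules$standing_ref_deg)
  tilted <- tilt > rules$posture_deg
  f <- features$dominant_freq_hz
  per <- features$periodicity
  walking <- !is.na(f) & per > rules$walk_periodicity &
    f >= rules$walk_band[1] & f <= rules$walk_band[2] &
    inten >= rules$walk_mg[1] & inten <= rules$walk_mg[2]
  running <- (!is.na(f) & f > rules$run_cadence_hz &
                per > rules$walk_periodicity) |
    (!is.na(inten) & inten > rules$run_mg)
  low <- !is.na(inten) & inten < rules$sedentary_mg
  mvpa_w <- !is.na(inten) & inten >= rules$cutpoint_mg

  lab <- rep(NA_character_, n_w)
  posture_lab <- ifelse(tilted, "sedentary", "standing")
  lab[is.na(lab) & low] <- posture_lab[is.na(lab) & low]
  lab[is.na(lab) & walking] <- "walking"
  lab[is.na(lab) & running] <- "running"
  lab[is.na(lab) & mvpa_w] <- "other_mvpa_context"
  lab[is.na(lab)] <- posture_lab[is.na(lab)]
  lab[asleep] <- "sleep"
  lab[wear_frac < rules$min_wear_frac | !features$complete] <- "nonwear"

  ep_lab <- lab[pmin(pmax(widx, 1L), n_w)]
  ep_lab[!epochs$wear | epochs$gap] <- "nonwear"
  mv <- flag_mvpa(epochs, rules$cutpoint_mg)$mvpa
  mv[ep_lab == "nonwear"] <- FALSE

  out <- data.frame(
    epoch_start = epochs$epoch_start,
    label = factor(ep_lab, levels = ACTIVITY_LEVELS),
    mvpa = mv)
  attr(out, "subject_id") <- epochs$subject_id[1]
  class(out) <- c("label_series", "data.frame")
  out
}

#' Daily minutes of sedentary time, walking and MVPA
#'
#' Aggregates a per-epoch label series into analysis days. Days run from
#' `day_start_hour` to the same hour next day (default 09:00--09:00,
#' matching a protocol that starts recorders at 09:00). Sedentary minutes
#' count epochs labelled sedentary (diary sleep is already a separate
#' label); walking minutes count walking labels; MVPA minutes count the
#' per-epoch MVPA flag; wear minutes count non-nonwear epochs. When a diary
#' recorded only a nightly duration (no intervals, so no sleep labels),
#' pass it via `subtract_sleep_min` to remove it from sedentary time,
#' floored at zero.
#'
#' @param labels a `label_series` from [classify_types()].
#' @param day_start_hour hour of day (0--23) at which analysis days begin.
#' @param subtract_sleep_min optional numeric: sleep minutes per day to
#'   subtract from sedentary time (recycled across days).
#' @param subject_id overrides the subject id carried on `labels`.
#' @return Data frame: `subject_id`, `date`, `instrument`, `sedentary_min`,
#'   `walking_min`, `mvpa_min`, `wear_min`.
#' @export
summarize_day <- function(labels, day_start_hour = 9,
                          subtract_sleep_min = NULL, subject_id = NULL) {
  subject_id <- subject_id %||% attr(labels, "subject_id") %||% "unknown"
  t <- labels$epoch_start
  day0 <- as.POSIXct(trunc(t[1], "days")) + day_start_hour * 3600
  if (t[1] < day0) day0 <- day0 - 86400
  day_id <- floor(as.numeric(t - day0, units = "secs") / 86400)
  days <- sort(unique(day_id))
  mins <- function(flag) {
    v <- group_sum(as.numeric(flag), day_id - days[1] + 1L,
                   max(day_id) - days[1] + 1L)[days - days[1] + 1L]
    v / 60
  }
  out <- data.frame(
    subject_id = subject_id,
    date = as.Date(day0 + days * 86400, tz = "UTC"),
    instrument = "accelerometer",
    sedentary_min = mins(labels$label == "sedentary"),
    walking_min = mins(labels$label == "walking"),
    mvpa_min = mins(labels$mvpa),
    wear_min = mins(labels$label != "nonwear"))
  if (!is.null(subtract_sleep_min))
    out$sedentary_min <- pmax(out$sedentary_min -
                                rep_len(subtract_sleep_min, nrow(out)), 0)
  out
}
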