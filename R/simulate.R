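# Mean of the positive part of the unit gait waveform
# sin + 0.5 sin(2.) + 0.25 sin(3.), used to scale amplitude to a target
# mean ENMO. Computed once on a fine grid (no randomness involved).
gait_pos_mean <- local({
  th <- seq(0, 2 * pi, length.out = 20001L)[-20001L]
  mean(pmax(sin(th) + 0.5 * sin(2 * th) + 0.25 * sin(3 * th), 0))
})

# Accelerometer-side daily-minute targets per grouping scheme and category:
# subject-level means and between-subject SDs for sedentary, walking and
# MVPA minutes/day.
acc_truth_tables <- function() {
  mk <- function(cats, mean, sd)
    data.frame(category = rep(cats, each = 3),
               measure = rep(c("sedentary", "walking", "mvpa"), length(cats)),
               mean = mean, sd = sd)
  list(
    bmi = mk(c("normal", "overweight", "obese"),
             c(597, 42, 103, 704, 77, 100, 823, 77, 44),
             c(67, 27, 19, 73, 21, 21, 94, 19, 27)),
    bia = mk(c("average", "high", "obese"),
             c(521, 83, 121, 638, 61, 82, 798, 37, 24),
             c(86, 25, 25, 98, 28, 28, 102, 29, 29)),
    whr = mk(c("normal", "overweight", "obese"),
             c(560, 123, 158, 644, 71, 92, 845, 50, 65),
             c(60, 17, 17, 72, 21, 21, 97, 28, 28)))
}

# Reporting-bias model per scheme/category/measure: mean questionnaire-minus-
# accelerometer shift and the subject-level SD of the paired difference
# (back-derived from limits-of-agreement widths as width / (2 * 1.96)).
bias_tables <- function() {
  mk <- function(cats, bias, width)
    data.frame(category = rep(cats, each = 3),
               measure = rep(c("sedentary", "walking", "mvpa"), length(cats)),
               bias = bias, diff_sd = width / (2 * 1.96))
  list(
    bmi = mk(c("normal", "overweight", "obese"),
             c(-121, 14, 22, -159, 18, 21, -195, 19, 26),
             c(262, 114, 89, 372, 106, 106, 399, 90, 115)),
    bia = mk(c("average", "high", "obese"),
             c(-99, 19, 12, -106, 17, 29, -142, 6, 24),
             c(368, 105, 106, 439, 126, 126, 492, 141, 141)),
    whr = mk(c("normal", "overweight", "obese"),
             c(-103, 7, 11, -43, 7, 9, -133, 5, 17),
             c(297, 85, 85, 328, 94, 94, 348, 100, 99)))
}

#' Per-activity-type signal parameters
#'
#' Posture inclination (degrees from the device vertical), white-noise SD
#' per axis (mg), and for gait/ambulatory types the cadence range (Hz) and
#' target mean ENMO (mg). Walking defaults to 60 mg -- below the 70 mg MVPA
#' cut-point, consistent with cohorts whose accelerometer MVPA minutes are
#' fewer than their walking minutes -- while generic moderate activity
#' (`other_mvpa_context`) is aperiodic at 150 mg and running is periodic at
#' 500 mg.
#' @return Named list of per-type parameter lists.
#' @export
signal_params <- function() {
  list(
    sleep = list(incl_deg = 80, noise_sd_mg = 25),
    sedentary = list(incl_deg = 65, noise_sd_mg = 35),
    standing = list(incl_deg = 0, noise_sd_mg = 35),
    walking = list(incl_deg = 0, noise_sd_mg = 10,
                   cadence_hz = c(1.5, 2.1), target_mg = 55, osc_mg = 35),
    running = list(incl_deg = 0, noise_sd_mg = 15,
                   cadence_hz = c(2.6, 3.2), target_mg = 500),
    other_mvpa_context = list(incl_deg = 0, noise_sd_mg = 10, target_mg = 150),
    nonwear = list(incl_deg = 0, noise_sd_mg = 0))
}

#' Simulation configuration
#'
#' Assembles the generator configuration with study-protocol defaults: 117
#' subjects recorded for 3 days from 09:00 at 60 Hz, category allocations
#' 37/37/43 (BMI), 43/33/41 (BIA) and 43/32/42 (WHR) scaled to the cohort
#' size, activity minutes coupled to adiposity category, and a reporting-
#' bias model whose defaults reproduce the questionnaire-minus-accelerometer
#' differences per scheme in expectation.
#'
#' @param ... overrides of the defaults listed below.
#' @return List of class `sim_config` with elements `n_subjects` (117),
#'   `days` (3), `seed` (1), `start` (first 09:00), `sample_rate` (60),
#'   `scheme` ("bmi"), `resolution` ("daily", "epoch" or "raw"),
#'   `allocation`, `activity_truth`, `bias`, `bias_override`,
#'   `report_noise_mult`, `signal`, `sleep_minutes` (450), `running_min`
#'   (0), `moderate_frac` (0.7), `nonwear` (list: `n_subjects`, `minutes`,
#'   `day`).
#' @export
sim_config <- function(...) {
  defaults <- list(
    n_subjects = 117,
    days = 3,
    seed = 1,
    start = as.POSIXct("2017-03-06 09:00:00", tz = "UTC"),
    sample_rate = 60,
    scheme = "bmi",
    resolution = "daily",
    allocation = list(bmi = c(normal = 37, overweight = 37, obese = 43),
                      bia = c(average = 43, high = 33, obese = 41),
                      whr = c(normal = 43, overweight = 32, obese = 42)),
    activity_truth = acc_truth_tables(),
    bias = bias_tables(),
    bias_override = NULL,       # named list measure -> constant bias
    report_noise_mult = 1,      # scales the diff SDs (0 = noiseless reports)
    signal = signal_params(),
    sleep_minutes = 450,
    running_min = 0,
    moderate_frac = 0.7,
    nonwear = list(n_subjects = 0, minutes = 150, day = 2))
  ov <- list(...)
  bad <- setdiff(names(ov), names(defaults))
  if (length(bad)) stop_config("unknown option(s): ", paste(bad, collapse = ", "))
  # tables and per-type parameter lists are replaced per scheme/type, not
  # merged field-by-field
  special <- intersect(names(ov), c("activity_truth", "bias", "allocation",
                                    "signal"))
  cfg <- utils::modifyList(defaults, ov[setdiff(names(ov), special)])
  for (k in special)
    for (nm in names(ov[[k]])) cfg[[k]][[nm]] <- ov[[k]][[nm]]
  if (!cfg$resolution %in% c("daily", "epoch", "raw"))
    stop_config("resolution must be daily, epoch or raw")
  if (!cfg$scheme %in% names(cfg$allocation))
    stop_config("unknown scheme: ", cfg$scheme)
  if (cfg$n_subjects < 1) stop_config("n_subjects must be >= 1")
  structure(cfg, class = "sim_config")
}

scale_alloc <- function(alloc, n) {
  p <- alloc / sum(alloc)
  k <- floor(p * n)
  short <- n - sum(k)
  if (short > 0) {
    add <- order(p * n - k, decreasing = TRUE)[seq_len(short)]
    k[add] <- k[add] + 1L
  }
  if (sum(k) != n) stop_config("infeasible allocation")
  k
}

split_chunks <- function(total, size) {
  if (total <= 0) return(integer(0))
  k <- ceiling(total / size)
  base <- total %/% k
  out <- rep(base, k)
  extra <- total - base * k
  if (extra > 0) out[seq_len(extra)] <- out[seq_len(extra)] + 1L
  out
}

# One day's activity blocks (whole minutes summing to 1440): bouts of
# walking/MVPA/running interleaved with sedentary and standing chunks over
# the waking period, sleep as the final block before the next 09:00.
make_day_blocks <- function(sedentary, walking, mvpa, running, sleep_target) {
  active <- sedentary + walking + mvpa + running
  if (active > 1440) {
    sedentary <- max(0, 1440 - walking - mvpa - running)
    active <- sedentary + walking + mvpa + running
    if (active > 1440) {
      sc <- 1440 / active
      walking <- floor(walking * sc); mvpa <- floor(mvpa * sc)
      running <- floor(running * sc)
      sedentary <- 1440 - walking - mvpa - running
      active <- 1440
    }
  }
  sleep <- min(sleep_target, 1440 - active)
  standing <- 1440 - sleep - active
  pieces <- list(
    sedentary = split_chunks(sedentary, 120),
    standing = split_chunks(standing, 120),
    walking = split_chunks(walking, 30),
    other_mvpa_context = split_chunks(mvpa, 30),
    running = split_chunks(running, 15))
  cycle <- c("sedentary", "standing", "walking", "sedentary", "standing",
             "other_mvpa_context", "running")
  type <- character(0); dur <- integer(0)
  ptr <- stats::setNames(rep(1L, length(pieces)), names(pieces))
  while (any(vapply(names(pieces),
                    function(tp) ptr[tp] <= length(pieces[[tp]]), TRUE))) {
    for (tp in cycle) {
      if (ptr[tp] <= length(pieces[[tp]])) {
        type <- c(type, tp); dur <- c(dur, pieces[[tp]][ptr[tp]])
        ptr[tp] <- ptr[tp] + 1L
      }
    }
  }
  if (sleep > 0) { type <- c(type, "sleep"); dur <- c(dur, sleep) }
  data.frame(type = type, dur_min = dur)
}

carve_nonwear <- function(blocks, minutes) {
  rem <- minutes
  for (i in seq_len(nrow(blocks))) {
    if (rem <= 0) break
    if (blocks$type[i] == "sleep") next
    take <- min(rem, blocks$dur_min[i])
    blocks$dur_min[i] <- blocks$dur_min[i] - take
    rem <- rem - take
  }
  rbind(data.frame(type = "nonwear", dur_min = minutes - rem),
        blocks[blocks$dur_min > 0, ])
}

block_minutes <- function(blocks) {
  tp <- c("sleep", "sedentary", "standing", "walking", "other_mvpa_context",
          "running", "nonwear")
  vapply(tp, function(t) sum(blocks$dur_min[blocks$type == t]), 0)
}

#' Synthesise a raw 60 Hz tri-axial signal from an activity schedule
#'
#' Per block, the gravity vector sits at the type's inclination with white
#' noise on every axis. Gait types add a cadence-locked waveform (fundamental
#' plus 2nd and 3rd harmonics at amplitude ratio 1 : 0.5 : 0.25) along the
#' device vertical: walking as a sustained dynamic offset of `target_mg`
#' plus an oscillation of `osc_mg` (the magnitude never drops below 1 g, so
#' the mean ENMO equals the target exactly and per-second means are steady),
#' running as a rectified oscillation scaled so the mean ENMO hits the
#' target. Generic moderate activity adds aperiodic vertical noise scaled to
#' its target; device-flat/non-wear blocks are exactly constant gravity.
#'
#' @param blocks data frame with `type` and `dur_min` (whole minutes).
#' @param params [signal_params()] list.
#' @param start_time `POSIXct` start of the block sequence.
#' @param subject_id trace identifier.
#' @param cadence named list of cadences (Hz) for `walking` and `running`;
#'   defaults to the midpoints of the configured ranges.
#' @param sample_rate samples/second (default 60).
#' @param seed optional RNG seed for reproducible traces.
#' @return A [raw_trace()].
#' @export
generate_signal <- function(blocks, params = signal_params(),
                            start_time = as.POSIXct("2017-03-06 09:00:00",
                                                    tz = "UTC"),
                            subject_id = "sim", cadence = NULL,
                            sample_rate = 60, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  bad <- setdiff(blocks$type, names(params))
  if (length(bad)) stop_validation("unknown activity type: ",
                                   paste(bad, collapse = ", "))
  fs <- sample_rate
  N <- sum(blocks$dur_min) * 60 * fs
  x <- numeric(N); y <- numeric(N); z <- numeric(N)
  off <- 0L
  for (i in seq_len(nrow(blocks))) {
    tp <- blocks$type[i]
    p <- params[[tp]]
    n <- blocks$dur_min[i] * 60L * fs
    if (n == 0L) next
    sl <- off + seq_len(n)
    if (tp == "nonwear") {           # device flat on a surface
      x[sl] <- 0; y[sl] <- 0; z[sl] <- 1
    } else {
      th <- p$incl_deg * pi / 180
      sdg <- p$noise_sd_mg / 1000
      zb <- cos(th) + stats::rnorm(n, 0, sdg)
      x[sl] <- sin(th) + stats::rnorm(n, 0, sdg)
      y[sl] <- stats::rnorm(n, 0, sdg)
      if (tp %in% c("walking", "running")) {
        f <- (cadence[[tp]] %||% mean(p$cadence_hz))
        tloc <- (seq_len(n) - 1) / fs
        wav <- sin(2 * pi * f * tloc) + 0.5 * sin(4 * pi * f * tloc) +
          0.25 * sin(6 * pi * f * tloc)
        if (tp == "walking") {
          # sustained dynamic offset plus cadence-locked oscillation: the
          # oscillation never drives the magnitude below 1 g, so the mean
          # ENMO equals target_mg exactly and per-second means stay steady
          zb <- zb + p$target_mg / 1000 + (p$osc_mg / 1000) * wav
        } else {
          # rectified oscillation scaled so mean ENMO hits the target
          zb <- zb + ((p$target_mg / 1000) / gait_pos_mean) * wav
        }
      } else if (tp == "other_mvpa_context") {
        # E[max(N(0, s), 0)] = s / sqrt(2*pi), so scale to the target ENMO
        zb <- zb + stats::rnorm(n, 0, (p$target_mg / 1000) * sqrt(2 * pi))
      }
      z[sl] <- zb
    }
    off <- off + n
  }
  raw_trace(subject_id, start_time, fs, time = (seq_len(N) - 1) / fs,
            x = x, y = y, z = z)
}

#' Biased daily questionnaire reports from ground truth
#'
#' Reported minutes are true minutes plus a category-specific mean shift
#' plus Gaussian day-level noise, floored at 0 and capped at 1440; the MVPA
#' report is split into moderate and vigorous items. Default shifts and
#' noise SDs reproduce, in expectation, the questionnaire-minus-
#' accelerometer group differences of the configured bias table for the
#' scheme in use.
#'
#' @param truth data frame with `subject_id`, `date`, `sedentary_min`,
#'   `walking_min`, `mvpa_min` (true daily values).
#' @param category per-row adiposity category under `config$scheme`.
#' @param config a [sim_config()].
#' @param seed optional RNG seed.
#' @return A questionnaire-day data frame (see [read_questionnaire_csv()]).
#' @export
generate_questionnaire <- function(truth, category, config = sim_config(),
                                   seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  bt <- config$bias[[config$scheme]]
  n <- nrow(truth)
  rep1 <- function(measure, true_val) {
    key <- match(paste(as.character(category), measure),
                 paste(bt$category, bt$measure))
    bias <- ifelse(is.na(key), 0, bt$bias[key])
    sdd <- ifelse(is.na(key), 0, bt$diff_sd[key]) * sqrt(config$days) *
      config$report_noise_mult
    if (!is.null(config$bias_override)) {
      ov <- config$bias_override[[measure]]
      if (!is.null(ov)) bias <- rep_len(ov, n)
    }
    clamp(round(true_val + bias + stats::rnorm(n, 0, sdd)), 0, 1440)
  }
  mvpa_rep <- rep1("mvpa", truth$mvpa_min)
  moderate <- round(config$moderate_frac * mvpa_rep)
  data.frame(
    subject_id = truth$subject_id,
    date = truth$date,
    moderate_min = moderate,
    vigorous_min = mvpa_rep - moderate,
    walking_min = rep1("walking", truth$walking_min),
    sitting_min = rep1("sedentary", truth$sedentary_min))
}

#' Generate a complete synthetic study cohort
#'
#' Draws anthropometrics targeted at the configured category allocation
#' (rejection sampling on the scheme under test), couples scheduled daily
#' sedentary/walking/MVPA minutes to the adiposity category, builds whole-
#' minute activity schedules with diary-recorded sleep, injects optional
#' non-wear, and produces biased questionnaire reports. Depending on
#' `config$resolution`, accelerometer data are available as on-demand raw
#' 60 Hz traces (`trace_for(subject, day)`), on-demand epoch series
#' (`epochs_for(subject)`) or schedule-level daily summaries (`daily_acc`).
#' One seed fixes every stream.
#'
#' @param config a [sim_config()].
#' @return List of class `sim_cohort`: `config`, `anthropometrics`,
#'   `profiles`, `truth` (per subject-day scheduled minutes), `blocks`,
#'   `diaries`, `questionnaires`, `daily_acc`, `category` (assigned category
#'   under the scheme), `cadence`, `trace_for`, `epochs_for`,
#'   `truth_labels_for`.
#' @export
generate_cohort <- function(config = sim_config()) {
  set.seed(config$seed)
  n <- config$n_subjects
  scheme <- config$scheme
  ids <- sprintf("S%04d", seq_len(n))
  alloc <- scale_alloc(config$allocation[[scheme]], n)
  category <- sample(rep(names(alloc), alloc))
  sex <- sample(c("M", "F"), n, TRUE, prob = c(0.51, 0.49))
  age <- round(clamp(stats::rnorm(n, 44, 9.2), 24, 60))
  # anthropometrics are drawn pre-rounded to measurement precision so the
  # emitted CSV reproduces the targeted categories exactly
  height <- round(stats::rnorm(n, 177, 5), 1)
  h2 <- (height / 100)^2

  # Redraw entries of `cur` (by index, so covariate alignment is kept)
  # until `ok` holds; after 200 rounds fall back to direct band sampling.
  reject <- function(cur, redraw, ok, fallback) {
    bad <- !ok(cur)
    for (it in seq_len(200)) {
      if (!any(bad)) break
      cur[bad] <- redraw(which(bad))
      bad <- !ok(cur)
    }
    if (any(bad)) cur[bad] <- fallback(which(bad))
    cur
  }

  # BMI: weight drawn around the cohort mean; targeted when scheme == "bmi"
  weight <- round(stats::rnorm(n, 94, 8), 1)
  if (scheme == "bmi") {
    bands <- list(normal = c(20, 24.8), overweight = c(25.1, 29.8),
                  obese = c(30.1, 40))
    for (catg in names(bands)) {
      sel <- which(category == catg)
      if (!length(sel)) next
      weight[sel] <- reject(
        weight[sel],
        redraw = function(idx) round(stats::rnorm(length(idx), 94, 8), 1),
        ok = function(w) as.character(categorize_bmi(w / h2[sel])) == catg,
        fallback = function(idx)
          round(stats::runif(length(idx), bands[[catg]][1], bands[[catg]][2]) *
                  h2[sel][idx], 1))
    }
  }
  bmi <- weight / h2

  # Percent body fat: height/weight/age/sex relation plus noise; targeted
  # when scheme == "bia"
  bf_base <- 1.2 * bmi + 0.23 * age - 10.8 * (sex == "M") - 5.4
  bodyfat <- round(clamp(bf_base + stats::rnorm(n, 0, 3), 6, 55), 1)
  if (scheme == "bia") {
    bands_f <- list(average = c(22, 25.9), high = c(26, 36), obese = c(36.1, 50))
    bands_m <- list(average = c(14, 20.9), high = c(21, 25), obese = c(25.1, 45))
    for (catg in c("average", "high", "obese")) {
      sel <- which(category == catg)
      if (!length(sel)) next
      bodyfat[sel] <- reject(
        bodyfat[sel],
        redraw = function(idx) round(clamp(bf_base[sel][idx] +
                                             stats::rnorm(length(idx), 0, 6),
                                           6, 55), 1),
        ok = function(v) as.character(suppressWarnings(
          categorize_bia(v, sex[sel]))) == catg,
        fallback = function(idx) vapply(idx, function(j) {
          bd <- if (sex[sel][j] == "F") bands_f[[catg]] else bands_m[[catg]]
          round(stats::runif(1, bd[1], bd[2]), 1)
        }, 0))
    }
  }

  # Waist-to-hip ratio: waist drawn around a sex baseline shifted with BMI,
  # rejected on the rounded circumferences; targeted when scheme == "whr"
  hip <- round(stats::rnorm(n, 104, 6), 1)
  draw_waist <- function(idx, spread = 0.04)
    round(clamp(ifelse(sex[idx] == "M", 0.95, 0.84) +
                  0.010 * (bmi[idx] - 30) +
                  stats::rnorm(length(idx), 0, spread), 0.6, 1.3) * hip[idx], 1)
  waist <- draw_waist(seq_len(n))
  if (scheme == "whr") {
    bands_f <- list(normal = c(0.70, 0.79), overweight = c(0.802, 0.845),
                    obese = c(0.855, 1.05))
    bands_m <- list(normal = c(0.80, 0.893), overweight = c(0.902, 0.995),
                    obese = c(1.005, 1.15))
    for (catg in c("normal", "overweight", "obese")) {
      sel <- which(category == catg)
      if (!length(sel)) next
      waist[sel] <- reject(
        waist[sel],
        redraw = function(idx) draw_waist(sel[idx], spread = 0.06),
        ok = function(w) as.character(
          categorize_whr(w, hip[sel], sex[sel])$category) == catg,
        fallback = function(idx) vapply(idx, function(j) {
          bd <- if (sex[sel][j] == "F") bands_f[[catg]] else bands_m[[catg]]
          round(stats::runif(1, bd[1], bd[2]) * hip[sel][j], 1)
        }, 0))
    }
  }
  whr <- waist / hip

  anthro <- data.frame(
    subject_id = ids, sex = sex, age = age,
    height_cm = height, weight_kg = weight,
    bodyfat_pct = bodyfat, waist_cm = waist, hip_cm = hip)
  profiles <- adiposity_profile(anthro)

  # Scheduled activity minutes per subject (constant across days; the
  # between-day variation in this design lives in the questionnaire noise).
  tt <- config$activity_truth[[scheme]]
  draw_measure <- function(measure) {
    key <- match(paste(category, measure), paste(tt$category, tt$measure))
    round(pmax(stats::rnorm(n, tt$mean[key], tt$sd[key]), 0))
  }
  sed <- draw_measure("sedentary")
  walk <- draw_measure("walking")
  mvpa <- draw_measure("mvpa")
  run <- rep(config$running_min, n)
  cadence <- list(walking = stats::runif(n, config$signal$walking$cadence_hz[1],
                                         config$signal$walking$cadence_hz[2]),
                  running = stats::runif(n, config$signal$running$cadence_hz[1],
                                         config$signal$running$cadence_hz[2]))

  nw_k <- min(config$nonwear$n_subjects, n)
  nw_subjects <- if (nw_k > 0) sort(sample.int(n, nw_k)) else integer(0)
  nw_day <- min(config$nonwear$day, config$days)

  blocks <- vector("list", n)
  truth_rows <- vector("list", n)
  day_starts <- config$start + (seq_len(config$days) - 1) * 86400
  for (i in seq_len(n)) {
    base <- make_day_blocks(sed[i], walk[i], mvpa[i], run[i],
                            config$sleep_minutes)
    days_i <- vector("list", config$days)
    for (d in seq_len(config$days)) {
      b <- base
      if (i %in% nw_subjects && d == nw_day)
        b <- carve_nonwear(b, config$nonwear$minutes)
      days_i[[d]] <- b
    }
    blocks[[i]] <- days_i
    bm <- t(vapply(days_i, block_minutes, numeric(7)))
    truth_rows[[i]] <- data.frame(
      subject_id = ids[i], day = seq_len(config$days),
      date = as.Date(day_starts, tz = "UTC"),
      sleep_min = bm[, "sleep"], sedentary_min = bm[, "sedentary"],
      standing_min = bm[, "standing"], walking_min = bm[, "walking"],
      mvpa_min = bm[, "other_mvpa_context"], running_min = bm[, "running"],
      nonwear_min = bm[, "nonwear"])
  }
  truth <- do.call(rbind, truth_rows)

  # Sleep diaries: bed time at the start of the scheduled sleep block, wake
  # at the next 09:00.
  diaries <- data.frame(
    subject_id = truth$subject_id, date = truth$date,
    bed_time = rep(day_starts, n) + (1440 - truth$sleep_min) * 60,
    wake_time = rep(day_starts, n) + 86400,
    nap_minutes = 0)
  diaries$bed_time[truth$sleep_min == 0] <- NA
  diaries$wake_time[truth$sleep_min == 0] <- NA

  truth_measures <- data.frame(
    subject_id = truth$subject_id, date = truth$date,
    sedentary_min = truth$sedentary_min,
    walking_min = truth$walking_min,
    mvpa_min = truth$mvpa_min + truth$running_min)
  questionnaires <- generate_questionnaire(
    truth_measures, category[match(truth$subject_id, ids)], config)

  daily_acc <- data.frame(
    subject_id = truth$subject_id, date = truth$date,
    instrument = "accelerometer",
    sedentary_min = truth$sedentary_min,
    walking_min = truth$walking_min,
    mvpa_min = truth$mvpa_min + truth$running_min,
    wear_min = 1440 - truth$nonwear_min)

  sub_seeds <- matrix(sample.int(.Machine$integer.max - 1L, n * config$days),
                      nrow = n)

  cohort <- list(
    config = config, anthropometrics = anthro, profiles = profiles,
    truth = truth, blocks = blocks, diaries = diaries,
    questionnaires = questionnaires, daily_acc = daily_acc,
    category = stats::setNames(category, ids),
    cadence = cadence, sub_seeds = sub_seeds)

  cohort$trace_for <- function(subject, day) {
    i <- if (is.character(subject)) match(subject, ids) else subject
    generate_signal(blocks[[i]][[day]], config$signal,
                    start_time = day_starts[day], subject_id = ids[i],
                    cadence = list(walking = cadence$walking[i],
                                   running = cadence$running[i]),
                    sample_rate = config$sample_rate,
                    seed = sub_seeds[i, day])
  }
  cohort$epochs_for <- function(subject) {
    i <- if (is.character(subject)) match(subject, ids) else subject
    sim_epochs(blocks[[i]], config, ids[i], day_starts, sub_seeds[i, ])
  }
  cohort$truth_labels_for <- function(subject) {
    i <- if (is.character(subject)) match(subject, ids) else subject
    lab <- unlist(lapply(blocks[[i]], function(b) rep(b$type, b$dur_min * 60)))
    data.frame(
      epoch_start = config$start + seq_len(length(lab)) - 1,
      label = factor(lab, levels = ACTIVITY_LEVELS))
  }
  class(cohort) <- "sim_cohort"
  cohort
}

# Epoch-resolution realisation of a subject's schedule: per-epoch ENMO and
# per-axis summary moments consistent with the raw-signal model, without
# synthesising 60 Hz samples.
sim_epochs <- function(day_blocks, config, subject_id, day_starts, seeds) {
  sp <- config$signal
  eps <- vector("list", length(day_blocks))
  for (d in seq_along(day_blocks)) {
    set.seed(seeds[d])
    b <- day_blocks[[d]]
    n_ep <- sum(b$dur_min) * 60L
    enmo <- numeric(n_ep); sdx <- numeric(n_ep)
    mx <- numeric(n_ep); mz <- numeric(n_ep)
    off <- 0L
    for (i in seq_len(nrow(b))) {
      tp <- b$type[i]; p <- sp[[tp]]
      k <- b$dur_min[i] * 60L
      sl <- off + seq_len(k)
      mean_mg <- switch(tp,
        walking = p$target_mg, running = p$target_mg,
        other_mvpa_context = p$target_mg,
        nonwear = 0,
        p$noise_sd_mg / sqrt(2 * pi))  # rectified-noise mean
      sd_ep <- if (tp == "nonwear") 0.05 else pmax(1, 0.05 * mean_mg)
      axis_sd <- switch(tp,
        walking = 120, running = 600, other_mvpa_context = 380,
        nonwear = 0.2, p$noise_sd_mg)
      enmo[sl] <- pmax(stats::rnorm(k, mean_mg, sd_ep), 0)
      sdx[sl] <- pmax(axis_sd * stats::runif(k, 0.95, 1.05), 0.01)
      th <- p$incl_deg * pi / 180
      mx[sl] <- sin(th); mz[sl] <- cos(th)
      if (tp == "nonwear") { mx[sl] <- 0; mz[sl] <- 1 }
      off <- off + k
    }
    eps[[d]] <- data.frame(start = day_starts[d] + seq_len(n_ep) - 1,
                           enmo = enmo, sdx = sdx, mx = mx, mz = mz)
  }
  all <- do.call(rbind, eps)
  epoch_series(subject_id, all$start, all$enmo,
               mean_x = all$mx, mean_y = 0, mean_z = all$mz,
               sd_x_mg = all$sdx, sd_y_mg = all$sdx, sd_z_mg = all$sdx,
               sample_rate = config$sample_rate, epoch_s = 1)
}

#' Write a simulated cohort as the pipeline's CSV input families
#'
#' Emits `questionnaires.csv`, `diaries.csv`, `anthropometrics.csv`,
#' `truth_schedule.csv` and optionally per-epoch `truth_labels_<id>.csv`
#' files (only sensible for small cohorts).
#'
#' @param cohort a `sim_cohort`.
#' @param dir output directory (created if needed).
#' @param include_labels write per-epoch truth labels (default `FALSE`).
#' @return `dir`, invisibly.
#' @export
write_cohort_csv <- function(cohort, dir, include_labels = FALSE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(df, name) {
    df2 <- df
    for (cl in names(df2))
      if (inherits(df2[[cl]], "POSIXct"))
        df2[[cl]] <- format(df2[[cl]], "%Y-%m-%dT%H:%M:%S")
    utils::write.csv(df2, file.path(dir, name), row.names = FALSE, quote = FALSE)
  }
  w(cohort$questionnaires, "questionnaires.csv")
  w(cohort$diaries, "diaries.csv")
  w(cohort$anthropometrics, "anthropometrics.csv")
  w(cohort$truth, "truth_schedule.csv")
  if (include_labels)
    for (id in cohort$anthropometrics$subject_id)
      w(cohort$truth_labels_for(id), paste0("truth_labels_", id, ".csv"))
  invisible(dir)
}
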