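#' Per-second ENMO epoch series
#'
#' Constructs the epoch container used throughout the pipeline. Normally
#' produced by [compute_enmo()]; the explicit constructor exists so the
#' synthetic-cohort generator can emit epoch-resolution data without a 60 Hz
#' signal. ENMO values are in milligravity (mg, 1000 mg = 1 g); per-axis
#' means are in g (they encode orientation) and per-axis standard deviations
#' in mg (they drive non-wear detection).
#'
#' @param subject_id identifier.
#' @param epoch_start `POSIXct` vector, a gapless 1 s grid.
#' @param enmo_mg per-epoch mean ENMO (mg); `NA` inside gaps.
#' @param mean_x,mean_y,mean_z per-epoch mean axis acceleration (g).
#' @param sd_x_mg,sd_y_mg,sd_z_mg per-epoch per-axis sample SD (mg).
#' @param gap logical, epoch overlaps a recorded timestamp gap.
#' @param wear logical wear flag (updated by [detect_nonwear()]).
#' @param sample_rate samples per second underlying each epoch.
#' @param epoch_s epoch length in seconds.
#' @return A data frame of class `epoch_series`.
#' @export
epoch_series <- function(subject_id, epoch_start, enmo_mg,
                         mean_x = NA_real_, mean_y = NA_real_, mean_z = NA_real_,
                         sd_x_mg = NA_real_, sd_y_mg = NA_real_, sd_z_mg = NA_real_,
                         gap = FALSE, wear = !gap,
                         sample_rate = 60, epoch_s = 1) {
  n <- length(epoch_start)
  if (n == 0L) stop_validation("empty epoch series")
  if (any(!is.na(enmo_mg) & enmo_mg < 0))
    stop_validation("ENMO must be non-negative")
  out <- data.frame(
    subject_id = as.character(subject_id),
    epoch_start = as.POSIXct(epoch_start, tz = "UTC"),
    enmo_mg = enmo_mg,
    mean_x = mean_x, mean_y = mean_y, mean_z = mean_z,
    sd_x_mg = sd_x_mg, sd_y_mg = sd_y_mg, sd_z_mg = sd_z_mg,
    gap = rep_len(gap, n), wear = rep_len(wear, n))
  attr(out, "sample_rate") <- sample_rate
  attr(out, "epoch_s") <- epoch_s
  class(out) <- c("epoch_series", "data.frame")
  out
}

group_sum <- function(v, idx, n_groups) {
  out <- numeric(n_groups)
  rs <- rowsum(v, idx, reorder = FALSE)
  out[as.integer(rownames(rs))] <- rs[, 1]
  out
}

#' Compute per-second ENMO epochs from a raw trace
#'
#' ENMO (Euclidean Norm Minus One) is computed per sample as
#' `max(sqrt(x^2 + y^2 + z^2) - 1, 0)` in g, then averaged over each 1 s
#' epoch and expressed in mg. Per-axis epoch means (g) and SDs (mg) are
#' retained for posture and non-wear handling. Epochs overlapping recorded
#' gaps are flagged and their wear flag cleared; a partially filled trailing
#' second is dropped so the epoch grid stays exact.
#'
#' @param trace a [raw_trace()].
#' @param epoch_s epoch length in seconds (default 1).
#' @return An [epoch_series()].
#' @export
compute_enmo <- function(trace, epoch_s = 1) {
  if (!inherits(trace, "raw_trace")) stop_validation("not a raw_trace")
  d <- trace$data
  if (nrow(d) == 0L) stop_validation("empty trace")
  fs <- trace$sample_rate
  t0 <- d$time[1]
  span <- d$time[nrow(d)] + 1 / fs - t0
  n_epochs <- floor(span / epoch_s + 1e-9)
  if (n_epochs < 1L) stop_validation("trace shorter than one epoch")

  m <- round(fs * epoch_s)
  n <- nrow(d)
  # Fast path: gapless regular grid -> reshape into samples x epochs
  if (nrow(trace$gaps) == 0L &&
      n == round((d$time[n] - t0) * fs) + 1L && n >= m) {
    E <- n %/% m
    use <- seq_len(E * m)
    enmo <- pmax(sqrt(d$x[use]^2 + d$y[use]^2 + d$z[use]^2) - 1, 0)
    cm <- function(v) .colMeans(v, m, E)
    csd <- function(v, mu) {
      va <- (.colMeans(v * v, m, E) - mu^2) * m / (m - 1)
      sqrt(pmax(va, 0))
    }
    mx <- cm(d$x[use]); my <- cm(d$y[use]); mz <- cm(d$z[use])
    return(epoch_series(
      trace$subject_id,
      epoch_start = trace$start_time + t0 + (seq_len(E) - 1) * epoch_s,
      enmo_mg = cm(enmo) * 1000,
      mean_x = mx, mean_y = my, mean_z = mz,
      sd_x_mg = csd(d$x[use], mx) * 1000,
      sd_y_mg = csd(d$y[use], my) * 1000,
      sd_z_mg = csd(d$z[use], mz) * 1000,
      gap = FALSE, wear = TRUE, sample_rate = fs, epoch_s = epoch_s))
  }

  idx <- floor((d$time - t0) / epoch_s + 1e-9) + 1L
  keep <- idx <= n_epochs
  idx <- idx[keep]

  enmo <- pmax(sqrt(d$x[keep]^2 + d$y[keep]^2 + d$z[keep]^2) - 1, 0)
  cnt <- tabulate(idx, n_epochs)
  smean <- function(v) {
    s <- group_sum(v, idx, n_epochs)
    ifelse(cnt > 0, s / cnt, NA_real_)
  }
  ssd <- function(v, m) {
    sq <- group_sum(v^2, idx, n_epochs)
    va <- ifelse(cnt > 1, (sq - cnt * m^2) / (cnt - 1), NA_real_)
    sqrt(pmax(va, 0))
  }
  mx <- smean(d$x[keep]); my <- smean(d$y[keep]); mz <- smean(d$z[keep])
  expected <- round(fs * epoch_s)
  gap <- cnt < expected
  epoch_series(
    trace$subject_id,
    epoch_start = trace$start_time + t0 + (seq_len(n_epochs) - 1) * epoch_s,
    enmo_mg = smean(enmo) * 1000,
    mean_x = mx, mean_y = my, mean_z = mz,
    sd_x_mg = ssd(d$x[keep], mx) * 1000,
    sd_y_mg = ssd(d$y[keep], my) * 1000,
    sd_z_mg = ssd(d$z[keep], mz) * 1000,
    gap = gap, wear = !gap, sample_rate = fs, epoch_s = epoch_s)
}

#' Flag non-wear epochs by the stationary-window rule
#'
#' A window of at least `window_minutes` in which the standard deviation of
#' every axis stays below `sd_threshold_mg` is taken as device-off time
#' (prolonged motionless constant orientation); all epochs inside any such
#' window have their wear flag cleared. Windowed SDs are pooled exactly from
#' the per-epoch axis means and SDs, so the result equals the raw-sample SD.
#' Windows containing gap epochs never qualify (gaps are already missing).
#'
#' @param epochs an [epoch_series()].
#' @param window_minutes minimum stationary window length (default 60).
#' @param sd_threshold_mg per-axis SD threshold in mg (default 13).
#' @return The epoch series with updated `wear` flags.
#' @export
detect_nonwear <- function(epochs, window_minutes = 60, sd_threshold_mg = 13) {
  if (!is_scalar_number(window_minutes) || window_minutes <= 0)
    stop_config("window_minutes must be > 0")
  if (!is_scalar_number(sd_threshold_mg) || sd_threshold_mg <= 0)
    stop_config("sd_threshold_mg must be > 0")
  epoch_s <- attr(epochs, "epoch_s") %||% 1
  fs <- attr(epochs, "sample_rate") %||% 60
  m <- round(fs * epoch_s)                     # samples per epoch
  W <- round(window_minutes * 60 / epoch_s)    # epochs per window
  E <- nrow(epochs)
  if (E < W) return(epochs)

  ok <- !epochs$gap
  roll <- function(v) {
    cs <- c(0, cumsum(ifelse(ok, v, 0)))
    cs[(W + 1):(E + 1)] - cs[1:(E - W + 1)]
  }
  n_ok <- {
    cs <- c(0, cumsum(as.numeric(ok)))
    cs[(W + 1):(E + 1)] - cs[1:(E - W + 1)]
  }
  full <- n_ok == W
  below <- full
  for (ax in c("x", "y", "z")) {
    mu <- epochs[[paste0("mean_", ax)]] * 1000          # mg
    s  <- epochs[[paste0("sd_", ax, "_mg")]]
    ss <- (m - 1) * s^2 + m * mu^2                      # per-epoch sum of squares
    sum_ss <- roll(ss)
    sum_mu <- roll(m * mu)
    N <- W * m
    v <- (sum_ss - sum_mu^2 / N) / (N - 1)
    below <- below & sqrt(pmax(v, 0)) < sd_threshold_mg
  }
  starts <- which(below)
  if (length(starts)) {
    paint <- integer(E + 1L)
    paint[starts] <- paint[starts] + 1L
    ends <- starts + W
    tb <- tabulate(ends, E + 1L)
    paint <- paint - tb
    covered <- cumsum(paint[1:E]) > 0L
    epochs$wear <- epochs$wear & !covered
  }
  epochs
}

#' Recording completeness and inclusion decision
#'
#' Missing time is the sum of gap and non-wear minutes over the recording.
#' Subjects with strictly more than `threshold_minutes` missing (default
#' 120, i.e. more than 2 h over the collection period) are excluded.
#'
#' @param epochs an [epoch_series()] after [detect_nonwear()].
#' @param threshold_minutes exclusion threshold (default 120).
#' @return A list of class `completeness_report` with `subject_id`,
#'   `missing_minutes` and `included`.
#' @export
assess_completeness <- function(epochs, threshold_minutes = 120) {
  epoch_s <- attr(epochs, "epoch_s") %||% 1
  missing_minutes <- sum(epochs$gap | !epochs$wear) * epoch_s / 60
  structure(
    list(subject_id = epochs$subject_id[1],
         missing_minutes = missing_minutes,
         threshold_minutes = threshold_minutes,
         included = missing_minutes <= threshold_minutes),
    class = "completeness_report")
}

#' @export
print.completeness_report <- function(x, ...) {
  cat(sprintf("<completeness> subject %s: %.1f missing min -> %s\n",
              x$subject_id, x$missing_minutes,
              if (x$included) "included" else "excluded"))
  invisible(x)
}

#' Write an epoch series to CSV
#'
#' Emits `subject_id,epoch_start,enmo_mg,wear`.
#' @param epochs an [epoch_series()].
#' @param path output path.
#' @export
write_epochs_csv <- function(epochs, path) {
  utils::write.csv(
    data.frame(subject_id = epochs$subject_id,
               epoch_start = format(epochs$epoch_start, "%Y-%m-%dT%H:%M:%S"),
               enmo_mg = epochs$enmo_mg,
               wear = epochs$wear),
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
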