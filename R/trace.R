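#' Raw tri-axial acceleration trace
#'
#' Container for a continuous recording of tri-axial acceleration in gravity
#' (g) units at a nominal sample rate (60 Hz for the devices this pipeline
#' targets). Timestamp gaps found at read time are carried along as explicit
#' gap intervals and are never interpolated.
#'
#' @param subject_id character scalar identifying the wearer.
#' @param start_time `POSIXct` time of the first sample.
#' @param sample_rate samples per second (must be > 0).
#' @param time numeric vector of sample times in seconds since `start_time`,
#'   strictly increasing.
#' @param x,y,z numeric vectors of axis accelerations in g.
#' @param gaps optional data frame with columns `start`, `end` (seconds since
#'   `start_time`) describing intervals with no samples.
#' @return An object of class `raw_trace`.
#' @export
raw_trace <- function(subject_id, start_time, sample_rate, time, x, y, z,
                      gaps = NULL) {
  if (!is_scalar_number(sample_rate) || sample_rate <= 0)
    stop_validation("sample_rate must be a positive number")
  n <- length(time)
  if (n == 0L) stop_validation("empty trace")
  if (length(x) != n || length(y) != n || length(z) != n)
    stop_validation("time, x, y, z must have equal length")
  if (!all(is.finite(x)) || !all(is.finite(y)) || !all(is.finite(z)))
    stop_validation("all acceleration components must be finite")
  if (n > 1L && any(diff(time) <= 0))
    stop_validation("non-monotone timestamps")
  if (is.null(gaps)) gaps <- data.frame(start = numeric(0), end = numeric(0))
  structure(
    list(subject_id = as.character(subject_id),
         start_time = as.POSIXct(start_time, tz = "UTC"),
         sample_rate = sample_rate,
         data = data.frame(time = time, x = x, y = y, z = z),
         gaps = gaps),
    class = "raw_trace")
}

#' @export
print.raw_trace <- function(x, ...) {
  dur <- x$data$time[nrow(x$data)] - x$data$time[1] + 1 / x$sample_rate
  cat(sprintf("<raw_trace> subject %s: %d samples @ %g Hz (%.1f min)\n",
              x$subject_id, nrow(x$data), x$sample_rate, dur / 60))
  if (nrow(x$gaps))
    cat(sprintf("  %d recorded gap(s), %.1f s total\n", nrow(x$gaps),
                sum(x$gaps$end - x$gaps$start)))
  invisible(x)
}

# Locate timestamp gaps: any jump exceeding 1.5 nominal sample intervals.
find_gaps <- function(time, sample_rate) {
  dt <- 1 / sample_rate
  jumps <- which(diff(time) > 1.5 * dt)
  data.frame(start = time[jumps] + dt, end = time[jumps + 1L])
}

#' Read a raw acceleration CSV
#'
#' Reads `time,x,y,z` CSV files with either ISO-8601 timestamps or
#' elapsed-seconds in the time column (auto-detected), plus a minimal
#' ActiGraph-style RAW export dialect whose metadata header block declares the
#' sample rate and start time, followed by three axis columns. Accelerations
#' are in g. Timestamp gaps are recorded on the returned trace, not filled.
#'
#' @param path CSV file path.
#' @param subject_id identifier for the trace; defaults to the file base name.
#' @param dialect `"auto"`, `"plain"` or `"actigraph"`.
#' @param expected_rate if non-`NULL`, error unless the inferred sample rate
#'   matches (the pipeline is defined for 60 Hz input and does not resample).
#' @return A [raw_trace()].
#' @export
read_raw_csv <- function(path, subject_id = NULL,
                         dialect = c("auto", "plain", "actigraph"),
                         expected_rate = 60) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop_validation("file not found: ", path)
  if (is.null(subject_id))
    subject_id <- sub("\\.[Cc][Ss][Vv]$", "", basename(path))
  head1 <- readLines(path, n = 1L)
  if (dialect == "auto")
    dialect <- if (grepl("^-|ActiGraph", head1)) "actigraph" else "plain"

  if (dialect == "actigraph") {
    hdr <- readLines(path, n = 12L)
    body_at <- grep("^-+$|^-{3,}", hdr)
    body_at <- if (length(body_at) >= 2) body_at[2] else 10L
    rate_ln <- grep("Hz", hdr, value = TRUE)
    rate <- as.numeric(sub(".*[^0-9]([0-9]+) *Hz.*", "\\1", rate_ln[1]))
    st_ln <- grep("Start Time", hdr, value = TRUE)
    sd_ln <- grep("Start Date", hdr, value = TRUE)
    st <- sub(".*Start Time[ ,]*", "", st_ln[1])
    sd <- sub(".*Start Date[ ,]*", "", sd_ln[1])
    start_time <- as.POSIXct(paste(sd, st), tz = "UTC",
                             tryFormats = c("%d/%m/%Y %H:%M:%S",
                                            "%Y-%m-%d %H:%M:%S"))
    df <- utils::read.csv(path, skip = body_at, header = TRUE)
    if (ncol(df) < 3) stop_validation("ActiGraph dialect needs 3 axis columns")
    n <- nrow(df)
    return(raw_trace(subject_id, start_time, rate,
                     time = (seq_len(n) - 1) / rate,
                     x = df[[1]], y = df[[2]], z = df[[3]]))
  }

  df <- utils::read.csv(path, header = TRUE, stringsAsFactors = FALSE,
                        colClasses = "character")
  need <- c("time", "x", "y", "z")
  if (!all(need %in% names(df)))
    stop_validation("header must declare columns time,x,y,z")
  num <- function(col, name) {
    v <- suppressWarnings(as.numeric(col))
    bad <- which(is.na(v) & !is.na(col) & nzchar(col))
    if (length(bad))
      stop("parse error: malformed ", name, " value at line ", bad[1] + 1L,
           " of ", path, call. = FALSE)
    if (anyNA(v))
      stop("parse error: missing ", name, " value at line ",
           which(is.na(v))[1] + 1L, " of ", path, call. = FALSE)
    v
  }
  tm_raw <- df$time
  tm_num <- suppressWarnings(as.numeric(tm_raw))
  if (anyNA(tm_num)) { # ISO-8601 timestamps
    tt <- as.POSIXct(tm_raw, tz = "UTC",
                     tryFormats = c("%Y-%m-%dT%H:%M:%OS", "%Y-%m-%d %H:%M:%OS"))
    if (anyNA(tt))
      stop("parse error: malformed time value at line ",
           which(is.na(tt))[1] + 1L, " of ", path, call. = FALSE)
    start_time <- tt[1]
    time <- as.numeric(tt) - as.numeric(tt[1])
  } else {
    start_time <- as.POSIXct("1970-01-01", tz = "UTC")
    time <- tm_num
    if (time[1] != 0) { start_time <- start_time + time[1]; time <- time - time[1] }
  }
  if (length(time) > 1L && any(diff(time) <= 0))
    stop_validation("non-monotone time column in ", path)
  x <- num(df$x, "x"); y <- num(df$y, "y"); z <- num(df$z, "z")
  rate <- if (length(time) > 1L) 1 / stats::median(diff(time)) else expected_rate %||% 60
  rate <- round(rate, 6)
  if (!is.null(expected_rate)) {
    if (abs(rate - expected_rate) > 0.5)
      stop_validation(sprintf(
        "sample rate %.3g Hz differs from expected %g Hz; this pipeline does not resample",
        rate, expected_rate))
    rate <- expected_rate      # snap timestamp-precision jitter to nominal
  }
  raw_trace(subject_id, start_time, rate, time, x, y, z,
            gaps = find_gaps(time, rate))
}

#' Write a raw trace to CSV
#'
#' Writes the `time,x,y,z` dialect read by [read_raw_csv()].
#'
#' @param trace a [raw_trace()].
#' @param path output path.
#' @param time_format `"elapsed"` (seconds) or `"iso"` (ISO-8601 timestamps).
#' @export
write_raw_csv <- function(trace, path, time_format = c("elapsed", "iso")) {
  time_format <- match.arg(time_format)
  tm <- if (time_format == "iso")
    format(trace$start_time + trace$data$time, "%Y-%m-%dT%H:%M:%OS4")
  else trace$data$time
  utils::write.csv(
    data.frame(time = tm, x = trace$data$x, y = trace$data$y, z = trace$data$z),
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
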