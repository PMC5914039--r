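#' Signature features for activity-type classification
#'
#' Computes, per fixed-length window of the raw signal, the features the
#' type classifier consumes: mean ENMO intensity (mg), posture inclination
#' (degrees between the low-pass gravity vector and the device vertical
#' axis, here +z), the dominant movement frequency (Hz, spectral peak of
#' the detrended vector magnitude over a configured band) and periodicity
#' (normalised autocorrelation at the dominant lag, clamped to [0, 1]).
#'
#' The gravity vector is the per-window mean of each axis: at the default
#' 5 s window this boxcar acts as a ~0.1 Hz low-pass, far below any gait
#' cadence, and has no filter transient. Windows overlapping recorded gaps
#' get `NA` features and `complete = FALSE`.
#'
#' @param trace a [raw_trace()].
#' @param window_s window length in whole seconds (default 5).
#' @param freq_band numeric length-2, spectral search band in Hz.
#' @return A data frame with columns `window_start`, `mean_enmo`,
#'   `inclination_deg`, `dominant_freq_hz`, `periodicity`, `complete`.
#' @export
extract_features <- function(trace, window_s = 5, freq_band = c(0.5, 5)) {
  if (!inherits(trace, "raw_trace")) stop_validation("not a raw_trace")
  if (!is_scalar_number(window_s) || window_s <= 0 ||
      abs(window_s - round(window_s)) > 1e-9)
    stop_config("window_s must be a positive whole number of seconds")
  fs <- trace$sample_rate
  L <- round(window_s * fs)
  if (L < 2) stop("window shorter than 2 samples", call. = FALSE)

  d <- trace$data
  t0 <- d$time[1]
  n <- nrow(d)
  if (nrow(trace$gaps) == 0L && n == round((d$time[n] - t0) * fs) + 1L) {
    n_w <- n %/% L                     # gapless regular grid: direct reshape
    if (n_w < 1L) stop_validation("trace shorter than one window")
    use <- seq_len(n_w * L)
    X <- matrix(d$x[use], L); Y <- matrix(d$y[use], L); Z <- matrix(d$z[use], L)
  } else {
    pos <- round((d$time - t0) * fs) + 1L
    n_grid <- max(pos)
    n_w <- floor(n_grid / L)
    if (n_w < 1L) stop_validation("trace shorter than one window")
    used <- pos <= n_w * L
    fill <- function(v) {
      out <- rep(NA_real_, n_w * L)
      out[pos[used]] <- v[used]
      matrix(out, nrow = L)
    }
    X <- fill(d$x); Y <- fill(d$y); Z <- fill(d$z)
  }
  complete <- colSums(is.na(X)) == 0L

  gx <- colMeans(X); gy <- colMeans(Y); gz <- colMeans(Z)
  gmag <- sqrt(gx^2 + gy^2 + gz^2)
  inclination <- acos(clamp(gz / gmag, -1, 1)) * 180 / pi

  VM <- sqrt(X^2 + Y^2 + Z^2)
  mean_enmo <- colMeans(pmax(VM - 1, 0)) * 1000

  D <- VM - rep(colMeans(VM), each = L)
  D[is.na(D)] <- 0
  Fp <- stats::mvfft(D)
  S <- Re(Fp)^2 + Im(Fp)^2

  half <- floor(L / 2)
  freqs <- seq_len(half) * fs / L
  kband <- which(freqs >= freq_band[1] & freqs <= freq_band[2])
  kpk <- kband[max.col(t(S[kband + 1L, , drop = FALSE]), ties.method = "first")]
  dominant <- kpk * fs / L

  power <- colSums(D^2)                     # autocorrelation at lag 0
  still <- power < 1e-12 | !complete
  dominant[still] <- 0
  lag <- as.integer(ifelse(dominant > 0, pmin(round(fs / dominant), L - 1L), 1L))
  # autocorrelation only at each window's dominant lag (few distinct lags,
  # since dominant frequencies are quantised to the FFT grid)
  periodicity <- numeric(n_w)
  for (L0 in unique(lag[!still])) {
    cols <- which(lag == L0 & !still)
    num <- .colSums(D[seq_len(L - L0), cols, drop = FALSE] *
                      D[(L0 + 1):L, cols, drop = FALSE], L - L0, length(cols))
    periodicity[cols] <- clamp(num / pmax(power[cols], 1e-12), 0, 1)
  }

  out <- data.frame(
    window_start = trace$start_time + t0 + (seq_len(n_w) - 1) * window_s,
    mean_enmo = ifelse(complete, mean_enmo, NA_real_),
    inclination_deg = ifelse(complete, inclination, NA_real_),
    dominant_freq_hz = ifelse(complete, dominant, NA_real_),
    periodicity = ifelse(complete, periodicity, NA_real_),
    complete = complete)
  attr(out, "window_s") <- window_s
  out
}
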