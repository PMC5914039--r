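# Shared fixtures and independent oracles, all built in code.

T0 <- as.POSIXct("2017-03-06 09:00:00", tz = "UTC")

# Constant-orientation trace of n samples at fs Hz.
const_trace <- function(x, y, z, n = 180, fs = 60, id = "t") {
  raw_trace(id, T0, fs, time = (seq_len(n) - 1) / fs,
            x = rep_len(x, n), y = rep_len(y, n), z = rep_len(z, n))
}

trace_from_xyz <- function(x, y, z, fs = 60, id = "t") {
  raw_trace(id, T0, fs, time = (seq_along(x) - 1) / fs, x = x, y = y, z = z)
}

# Hand-built epoch series with given per-epoch ENMO and axis SDs.
simple_epochs <- function(enmo, sd_mg = 50, wear = TRUE, gap = FALSE,
                          id = "e") {
  n <- length(enmo)
  epoch_series(id, T0 + seq_len(n) - 1, enmo,
               mean_x = 0, mean_y = 0, mean_z = 1,
               sd_x_mg = rep_len(sd_mg, n), sd_y_mg = rep_len(sd_mg, n),
               sd_z_mg = rep_len(sd_mg, n),
               gap = gap, wear = wear)
}

# Independent Spearman oracle: exhaustive-loop mid-ranks, then Pearson by
# explicit sums (no calls into the code path under test).
midrank_loop <- function(v) {
  n <- length(v)
  r <- numeric(n)
  for (i in seq_len(n)) {
    less <- 0; equal <- 0
    for (j in seq_len(n)) {
      if (v[j] < v[i]) less <- less + 1
      if (v[j] == v[i]) equal <- equal + 1
    }
    r[i] <- less + (equal + 1) / 2
  }
  r
}

spearman_bruteforce <- function(x, y) {
  rx <- midrank_loop(x); ry <- midrank_loop(y)
  n <- length(x)
  mx <- sum(rx) / n; my <- sum(ry) / n
  num <- 0; dx <- 0; dy <- 0
  for (i in seq_len(n)) {
    num <- num + (rx[i] - mx) * (ry[i] - my)
    dx <- dx + (rx[i] - mx)^2
    dy <- dy + (ry[i] - my)^2
  }
  num / sqrt(dx * dy)
}

# Sample with exact mean (and optionally exact sample SD).
exact_sample <- function(n, mean, sd = NULL, seed_vec = NULL) {
  x <- seed_vec %||% stats::rnorm(n)
  if (!is.null(sd)) x <- (x - base::mean(x)) / stats::sd(x) * sd
  x - base::mean(x) + mean
}

# A label series covering whole hours of given labels.
labels_of <- function(types, hours, mvpa = NULL, id = "l") {
  lab <- rep(types, hours * 3600)
  n <- length(lab)
  out <- data.frame(
    epoch_start = T0 + seq_len(n) - 1,
    label = factor(lab, levels = activagree:::ACTIVITY_LEVELS),
    mvpa = mvpa %||% rep(FALSE, n))
  attr(out, "subject_id") <- id
  class(out) <- c("label_series", "data.frame")
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
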