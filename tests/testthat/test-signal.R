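test_that("raw CSV read-back is the identity and round-trips", {
  p <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("time,x,y,z",
               "0,0,0,1",
               sprintf("%.10f,0,0,1", 1 / 60),
               sprintf("%.10f,0,0,1", 2 / 60)), p)
  tr <- read_raw_csv(p, subject_id = "s1")
  expect_s3_class(tr, "raw_trace")
  expect_equal(nrow(tr$data), 3)
  expect_equal(tr$sample_rate, 60, tolerance = 1e-6)
  expect_equal(tr$data$z, c(1, 1, 1))
  expect_equal(nrow(tr$gaps), 0)

  n <- 300
  tr2 <- trace_from_xyz(rnorm(n, 0, 0.05), rnorm(n, 0, 0.05),
                        1 + rnorm(n, 0, 0.05))
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_raw_csv(tr2, p2)
  tr3 <- read_raw_csv(p2, subject_id = tr2$subject_id)
  expect_equal(tr3$data$x, tr2$data$x, tolerance = 1e-9)
  expect_equal(tr3$data$z, tr2$data$z, tolerance = 1e-9)
  expect_equal(tr3$data$time, tr2$data$time, tolerance = 1e-9)

  # ISO-8601 time column is auto-detected
  p4 <- withr::local_tempfile(fileext = ".csv")
  write_raw_csv(const_trace(0, 0, 1, n = 120), p4, time_format = "iso")
  tr4 <- read_raw_csv(p4)
  expect_equal(nrow(tr4$data), 120)
  expect_equal(tr4$sample_rate, 60, tolerance = 1e-6)
})

test_that("the ActiGraph RAW export dialect is read via its header block", {
  p <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "------------ Data File Created By ActiGraph GT3X+ ActiLife ------------",
    "Serial Number: NEO1D000000", "Start Time 09:00:00",
    "Start Date 06/03/2017", "Epoch Period (hh:mm:ss) 00:00:00",
    "Download Time 10:00:00", "Download Date 09/03/2017",
    "Current Memory Address: 0", "Mode = 12, Sample Rate = 60 Hz",
    "--------------------------------------------------",
    "Accelerometer X,Accelerometer Y,Accelerometer Z",
    rep("0.1,0,1", 120)), p)
  tr <- read_raw_csv(p, subject_id = "ag1")
  expect_equal(tr$sample_rate, 60)
  expect_equal(nrow(tr$data), 120)
  expect_equal(tr$data$x[1], 0.1)
  expect_equal(format(tr$start_time, "%Y-%m-%d %H:%M:%S"),
               "2017-03-06 09:00:00")
})

test_that("timestamp jumps are recorded as gaps, never interpolated", {
  dt <- 1 / 60
  t1 <- (0:59) * dt
  t2 <- max(t1) + dt + 5 + (0:59) * dt   # 5 s hole in the grid
  p <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(data.frame(time = c(t1, t2), x = 0, y = 0, z = 1), p,
                   row.names = FALSE)
  tr <- read_raw_csv(p)
  expect_equal(nrow(tr$data), 120)        # no rows invented
  expect_equal(nrow(tr$gaps), 1)
  expect_equal(tr$gaps$end - tr$gaps$start, 5, tolerance = 1e-6)

  ep <- compute_enmo(tr)
  expect_true(any(ep$gap))
  expect_true(all(!ep$wear[ep$gap]))
  # the hole counts toward missing time
  expect_gte(assess_completeness(ep)$missing_minutes, 4 / 60)
})

test_that("malformed and non-monotone inputs fail loudly with location", {
  p <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("time,x,y,z", "0,0,0,1", "0.016,zap,0,1"), p)
  expect_error(read_raw_csv(p), "line 3")
  p2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("time,x,y,z", "0,0,0,1", "0.2,0,0,1", "0.1,0,0,1"), p2)
  expect_error(read_raw_csv(p2), "non-monotone")
  p3 <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(data.frame(time = (0:99) / 30, x = 0, y = 0, z = 1), p3,
                   row.names = FALSE)
  expect_error(read_raw_csv(p3), "does not resample")
})

test_that("ENMO closed forms: static orientations", {
  expect_equal(compute_enmo(const_trace(0, 0, 1))$enmo_mg, rep(0, 3))
  expect_equal(compute_enmo(const_trace(0, 0, 1.2))$enmo_mg, rep(200, 3),
               tolerance = 1e-9)
  # any static orientation with |v| <= 1 g gives zero
  expect_equal(compute_enmo(const_trace(0.6, 0, 0.8))$enmo_mg, rep(0, 3),
               tolerance = 1e-12)
  expect_equal(compute_enmo(const_trace(0.3, 0.3, 0.5))$enmo_mg,
               rep(0, 3), tolerance = 1e-12)
})

test_that("ENMO of a sinusoidal trace matches the sample-grid oracle", {
  fs <- 60
  t <- (0:(10 * fs - 1)) / fs
  tr <- trace_from_xyz(rep(0, length(t)), rep(0, length(t)),
                       1 + 0.1 * sin(2 * pi * t))
  ep <- compute_enmo(tr)
  # oracle: per-second mean of max(0.1 sin, 0) on the same grid, by loop
  oracle <- vapply(0:9, function(s) {
    idx <- which(t >= s & t < s + 1)
    acc <- 0
    for (i in idx) acc <- acc + max(0.1 * sin(2 * pi * t[i]), 0)
    acc / length(idx) * 1000
  }, 0)
  expect_equal(ep$enmo_mg, oracle, tolerance = 1e-9)
  expect_equal(ep$enmo_mg, rep(1000 * 0.1 / pi, 10), tolerance = 0.1)
})

test_that("ENMO is rotation invariant and linear below truncation", {
  set.seed(11)
  n <- 600
  x <- rnorm(n, 0, 0.2); y <- rnorm(n, 0, 0.2); z <- 1 + rnorm(n, 0, 0.2)
  base <- compute_enmo(trace_from_xyz(x, y, z))
  for (k in 1:5) {
    Q <- qr.Q(qr(matrix(rnorm(9), 3)))
    if (det(Q) < 0) Q[, 1] <- -Q[, 1]
    R <- Q %*% rbind(x, y, z)
    rot <- compute_enmo(trace_from_xyz(R[1, ], R[2, ], R[3, ]))
    expect_equal(rot$enmo_mg, base$enmo_mg, tolerance = 1e-9)
  }
  # doubling a strictly positive dynamic component doubles the epoch value
  t <- (seq_len(n) - 1) / 60
  d <- 0.05 * (1.2 + sin(2 * pi * 1.3 * t))   # always > 0: no truncation
  e1 <- compute_enmo(trace_from_xyz(rep(0, n), rep(0, n), 1 + d))
  e2 <- compute_enmo(trace_from_xyz(rep(0, n), rep(0, n), 1 + 2 * d))
  expect_equal(e2$enmo_mg, 2 * e1$enmo_mg, tolerance = 1e-9)
})

test_that("epoch means equal a brute-force per-second mean", {
  set.seed(5)
  n <- 20 * 60 + 30                       # partial trailing second
  x <- rnorm(n, 0, 0.3); y <- rnorm(n, 0, 0.3); z <- 1 + rnorm(n, 0, 0.3)
  tr <- trace_from_xyz(x, y, z)
  ep <- compute_enmo(tr)
  expect_equal(nrow(ep), 20)              # partial epoch dropped
  for (s in c(1, 7, 20)) {
    idx <- ((s - 1) * 60 + 1):(s * 60)
    acc <- 0
    for (i in idx) acc <- acc + max(sqrt(x[i]^2 + y[i]^2 + z[i]^2) - 1, 0)
    expect_equal(ep$enmo_mg[s], acc / 60 * 1000, tolerance = 1e-9)
  }
})

test_that("stationary-window non-wear detection obeys window length", {
  # 90 min of exactly constant orientation: zero variance, all flagged
  still <- simple_epochs(rep(0, 90 * 60), sd_mg = 0)
  out <- detect_nonwear(still)
  expect_true(all(!out$wear))

  # 30 min constant block inside an active day is below the window length
  active <- simple_epochs(rep(30, 180 * 60), sd_mg = 50)
  mid <- 60 * 60 + seq_len(30 * 60)
  active$sd_x_mg[mid] <- active$sd_y_mg[mid] <- active$sd_z_mg[mid] <- 0.1
  out2 <- detect_nonwear(active)
  expect_true(all(out2$wear))

  # a 75 min quiet block is flagged, its active surroundings are not
  active$sd_x_mg <- active$sd_y_mg <- active$sd_z_mg <- rep(50, 180 * 60)
  quiet <- 30 * 60 + seq_len(75 * 60)
  active$sd_x_mg[quiet] <- active$sd_y_mg[quiet] <- active$sd_z_mg[quiet] <- 0.1
  active$enmo_mg[quiet] <- 0
  out3 <- detect_nonwear(active)
  flagged <- which(!out3$wear)
  # the quiet block is fully covered; the pooled-SD window rule may bleed a
  # few minutes into the active margins, bounded by the SD ratio
  expect_lte(min(flagged), min(quiet))
  expect_gte(max(flagged), max(quiet))
  expect_lte(min(quiet) - min(flagged), 5 * 60)
  expect_lte(max(flagged) - max(quiet), 5 * 60)

  expect_error(detect_nonwear(still, window_minutes = 0), "config")
  expect_error(detect_nonwear(still, window_minutes = -5), "config")
})

test_that("completeness threshold is strictly greater-than 120 minutes", {
  full <- simple_epochs(rep(10, 3 * 1440 * 60), sd_mg = 40)
  expect_true(assess_completeness(full)$included)
  expect_equal(assess_completeness(full)$missing_minutes, 0)

  at_threshold <- full
  at_threshold$wear[seq_len(120 * 60)] <- FALSE
  expect_true(assess_completeness(at_threshold)$included)   # exactly 2 h stays

  over <- full
  over$wear[seq_len(121 * 60)] <- FALSE
  cp <- assess_completeness(over)
  expect_false(cp$included)
  expect_equal(cp$missing_minutes, 121)
})
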