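test_that("one seed fixes every generated stream", {
  cfg <- sim_config(n_subjects = 6, days = 2, seed = 99)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$anthropometrics, b$anthropometrics)
  expect_identical(a$questionnaires, b$questionnaires)
  expect_identical(a$truth, b$truth)

  cfgr <- sim_config(n_subjects = 2, days = 1, seed = 99, resolution = "raw")
  ca <- generate_cohort(cfgr)
  cb <- generate_cohort(cfgr)
  t1 <- ca$trace_for(1, 1)
  t2 <- cb$trace_for(1, 1)
  expect_identical(t1$data, t2$data)
  expect_identical(ca$epochs_for(2)$enmo_mg, cb$epochs_for(2)$enmo_mg)
})

test_that("schedules fill each day and match emitted truth labels", {
  cfg <- sim_config(n_subjects = 5, days = 3, seed = 17,
                    nonwear = list(n_subjects = 1, minutes = 150, day = 2))
  co <- generate_cohort(cfg)
  per_day <- with(co$truth, sleep_min + sedentary_min + standing_min +
                    walking_min + mvpa_min + running_min + nonwear_min)
  expect_true(all(per_day == 1440))

  lab <- co$truth_labels_for(3)
  counts <- table(lab$label) / 60
  tr3 <- co$truth[co$truth$subject_id == "S0003", ]
  expect_equal(unname(counts["sedentary"]), sum(tr3$sedentary_min))
  expect_equal(unname(counts["walking"]), sum(tr3$walking_min))
  expect_equal(unname(counts["sleep"]), sum(tr3$sleep_min))

  # exactly one subject carries the injected non-wear, on day 2
  nw <- co$truth[co$truth$nonwear_min > 0, ]
  expect_equal(nrow(nw), 1)
  expect_equal(nw$day, 2)
  expect_equal(nw$nonwear_min, 150)
})

test_that("questionnaire bias model is controllable and exact at zero noise", {
  cfg <- sim_config(n_subjects = 30, days = 3, seed = 5,
                    bias_override = list(sedentary = 0, walking = 0, mvpa = 0),
                    report_noise_mult = 0)
  co <- generate_cohort(cfg)
  sc <- score_ipaq_daily(co$questionnaires)
  truth <- co$truth
  expect_equal(sc$sedentary_min, truth$sedentary_min)
  expect_equal(sc$walking_min, truth$walking_min)
  expect_equal(sc$mvpa_min, truth$mvpa_min + truth$running_min)

  # constant -50 bias propagates exactly through the full stats module
  # (truth minutes kept well above 50 so the report floor never binds)
  big <- data.frame(category = rep(c("normal", "overweight", "obese"), each = 3),
                    measure = rep(c("sedentary", "walking", "mvpa"), 3),
                    mean = rep(c(600, 200, 150), 3), sd = rep(c(50, 20, 20), 3))
  cfg2 <- sim_config(n_subjects = 30, days = 3, seed = 5,
                     activity_truth = list(bmi = big),
                     bias_override = list(sedentary = -50, walking = -50,
                                          mvpa = -50),
                     report_noise_mult = 0)
  co2 <- generate_cohort(cfg2)
  summ <- rbind(co2$daily_acc, score_ipaq_daily(co2$questionnaires))
  tab <- stratified_agreement(summ, co2$profiles, "bmi")
  expect_equal(tab$mean_diff, rep(-50, nrow(tab)), tolerance = 1e-9)
  expect_equal(tab$loa_low, rep(-50, nrow(tab)), tolerance = 1e-9)
})

test_that("generated signals realise their schedule", {
  # all-day flat-on-surface schedule: ENMO is zero everywhere
  flat <- generate_signal(data.frame(type = "nonwear", dur_min = 30), seed = 1)
  expect_true(all(compute_enmo(flat)$enmo_mg < 1e-9))

  # 10 min of walking hits the target intensity within 10%
  blocks <- data.frame(type = "walking", dur_min = 10)
  tr <- generate_signal(blocks, seed = 2)
  target <- signal_params()$walking$target_mg
  expect_equal(mean(compute_enmo(tr)$enmo_mg), target,
               tolerance = 0.1 * target)

  expect_error(generate_signal(data.frame(type = "flying", dur_min = 5)),
               "unknown activity type")
})

test_that("cohort allocation follows the study proportions", {
  co <- generate_cohort(sim_config(n_subjects = 117, seed = 2))
  expect_equal(unname(table(co$category)[c("normal", "overweight", "obese")]),
               c(37, 37, 43), ignore_attr = TRUE)
  # assigned categories agree with the derived adiposity profiles
  expect_equal(as.character(co$profiles$category_bmi),
               unname(co$category[co$profiles$subject_id]))
  # scaled allocation still sums to n
  co2 <- generate_cohort(sim_config(n_subjects = 40, seed = 2, scheme = "whr"))
  expect_equal(length(co2$category), 40)
  expect_equal(as.character(co2$profiles$category_whr),
               unname(co2$category[co2$profiles$subject_id]))
})

test_that("accelerometer couples to adiposity more strongly than self-report", {
  # the generator couples true activity to category while the questionnaire
  # adds bias and noise, so the objective instrument must correlate more
  # strongly with the ordinal category for every measure
  co <- generate_cohort(sim_config(n_subjects = 800, seed = 13))
  summ <- rbind(co$daily_acc,
                suppressWarnings(score_ipaq_daily(co$questionnaires)))
  assoc <- adiposity_association_table(summ, co$profiles, schemes = "bmi")
  expect_true(all(abs(assoc$rho_accelerometer) > abs(assoc$rho_questionnaire)))
})

test_that("cohort CSV families round-trip through the package readers", {
  co <- generate_cohort(sim_config(n_subjects = 4, days = 2, seed = 31))
  dir <- withr::local_tempdir()
  write_cohort_csv(co, dir)
  q <- read_questionnaire_csv(file.path(dir, "questionnaires.csv"))
  expect_equal(nrow(q), 8)
  d <- read_sleep_diary(file.path(dir, "diaries.csv"))
  expect_equal(nrow(d), 8)
  a <- read_anthropometrics(file.path(dir, "anthropometrics.csv"))
  pr <- adiposity_profile(a)
  expect_equal(as.character(pr$category_bmi),
               as.character(co$profiles$category_bmi))
})
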