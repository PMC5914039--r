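test_that("Spearman correlation matches hand-derived examples", {
  x <- c(3, 1, 4, 1.5, 9)
  expect_equal(spearman_rho(x, x), 1)
  expect_equal(spearman_rho(x, -x), -1)
  # d^2 = (1,1,1,1,0): 1 - 6*4/(5*24) = 0.8 by the rank-difference formula
  expect_equal(spearman_rho(1:5, c(2, 1, 4, 3, 5)), 0.8)
  expect_error(spearman_rho(rep(1, 5), 1:5), "constant")
  expect_error(spearman_rho(1:4, 1:5), "length")
})

test_that("Spearman agrees with exhaustive-loop mid-ranks (with ties)", {
  set.seed(101)
  for (r in 1:60) {
    n <- sample(5:25, 1)
    x <- sample(1:8, n, replace = TRUE) + rnorm(n, 0, 0.01 * (r %% 2))
    y <- sample(1:8, n, replace = TRUE)
    if (sd(x) == 0 || sd(y) == 0) next
    expect_equal(spearman_rho(x, y), spearman_bruteforce(x, y),
                 tolerance = 1e-12)
  }
})

test_that("Fisher-z intervals match the closed form and collapse at level 0", {
  ci <- fisher_ci(0, 403)
  expect_equal(unname(ci), c(-tanh(1.959964 / 20), tanh(1.959964 / 20)),
               tolerance = 1e-6)
  expect_equal(unname(ci[1]), -unname(ci[2]))          # symmetric about 0
  expect_equal(round(unname(ci), 3), c(-0.098, 0.098))

  ci2 <- fisher_ci(0.5, 28)
  expect_equal(unname(ci2), c(tanh(atanh(0.5) - qnorm(0.975) / 5),
                              tanh(atanh(0.5) + qnorm(0.975) / 5)),
               tolerance = 1e-12)
  expect_equal(round(unname(ci2), 3), c(0.156, 0.736))

  expect_equal(unname(fisher_ci(0.37, 50, level = 0)), c(0.37, 0.37),
               tolerance = 1e-12)
  expect_error(fisher_ci(0.5, 3), ">= 4")
  expect_error(fisher_ci(1, 30), "strictly")
})

test_that("limits of agreement satisfy their algebraic identities", {
  expect_equal(limits_of_agreement(c(5, 7, 9), c(5, 7, 9))[
    c("mean_diff", "loa_low", "loa_high")],
    list(mean_diff = 0, loa_low = 0, loa_high = 0))

  # any paired set with instrument means 628 and 823 gives -195 exactly
  set.seed(2)
  q <- exact_sample(43, 628, 83)
  a <- exact_sample(43, 823, 94)
  expect_equal(limits_of_agreement(q, a)$mean_diff, -195, tolerance = 1e-9)

  d <- limits_of_agreement(q, a)
  expect_equal(d$mean_diff, mean(q) - mean(a), tolerance = 1e-12)
  expect_equal(d$loa_high - d$loa_low, 2 * 1.96 * sd(q - a),
               tolerance = 1e-12)
  expect_error(limits_of_agreement(1, 2), "2 pairs")
})

test_that("Monte-Carlo pairs recover injected bias and limits", {
  set.seed(33)
  n <- 1e4
  a <- rnorm(n, 600, 80)
  q <- a - 100 + rnorm(n, 0, 50)
  fit <- limits_of_agreement(q, a)
  expect_equal(fit$mean_diff, -100, tolerance = 2)
  expect_equal(fit$loa_low, -198, tolerance = 3)
  expect_equal(fit$loa_high, -2, tolerance = 3)
})

test_that("paired t statistic matches the closed form", {
  set.seed(4)
  d <- exact_sample(25, 5, 5)
  tt <- paired_t(d, rep(0, 25))
  expect_equal(tt$t_stat, 5, tolerance = 1e-9)
  expect_equal(tt$df, 24)
  expect_equal(tt$p_value, 2 * pt(-5, 24), tolerance = 1e-12)

  alt <- rep(c(1, -1), 10)
  t0 <- paired_t(alt, rep(0, 20))
  expect_equal(t0$t_stat, 0, tolerance = 1e-12)
  expect_equal(t0$p_value, 1, tolerance = 1e-12)

  expect_error(paired_t(c(3, 3, 3), c(1, 1, 1)), "degenerate")
})

test_that("the agreement estimator exposes the usual S3 surface", {
  set.seed(6)
  a <- rnorm(40, 700, 70)
  q <- a - 150 + rnorm(40, 0, 60)
  fit <- agreement(q, a, measure = "sedentary")
  expect_s3_class(fit, "pa_agreement")
  expect_true(fit$ci_low <= fit$rho && fit$rho <= fit$ci_high)
  expect_true(fit$loa_low <= fit$mean_diff && fit$mean_diff <= fit$loa_high)
  expect_lte(abs(fit$rho), 1)
  co <- coef(fit)
  expect_equal(unname(co["mean_diff"]), mean(q - a))
  ci <- confint(fit)
  expect_equal(dim(ci), c(2, 2))
  expect_output(print(fit), "Spearman")
  expect_output(summary(fit), "Mean difference")
  pdf(NULL); on.exit(dev.off())
  expect_silent(plot(fit))

  # degenerate strata fall back to NA rather than erroring
  tiny <- agreement(c(1, 1, 1), c(2, 2, 2))
  expect_true(is.na(tiny$rho))
  expect_true(is.na(tiny$p_value))
})

test_that("stratified tables reduce to the pooled analysis for one stratum", {
  set.seed(12)
  n <- 24
  ids <- sprintf("P%02d", 1:n)
  acc <- data.frame(subject_id = rep(ids, 2), date = rep(1:2, each = n),
                    instrument = "accelerometer",
                    sedentary_min = rnorm(2 * n, 600, 50),
                    walking_min = rnorm(2 * n, 80, 10),
                    mvpa_min = rnorm(2 * n, 90, 15), wear_min = 1440)
  qst <- acc
  qst$instrument <- "questionnaire"
  qst$sedentary_min <- qst$sedentary_min - 120 + rnorm(2 * n, 0, 30)
  summ <- rbind(acc, qst)
  profiles <- data.frame(
    subject_id = ids,
    category_bmi = factor(rep("obese", n),
                          levels = c("normal", "overweight", "obese"),
                          ordered = TRUE))
  tab <- stratified_agreement(summ, profiles, "bmi")
  sed <- tab[tab$measure == "sedentary", ]
  expect_equal(sed$mean_diff[sed$stratum == "all"],
               sed$mean_diff[sed$stratum == "obese"])
  expect_equal(sed$rho[sed$stratum == "all"], sed$rho[sed$stratum == "obese"])

  # a stratum with n < 4 is emitted with an unavailable CI
  profiles$category_bmi[1:3] <- "normal"
  tab2 <- stratified_agreement(summ, profiles, "bmi")
  small <- tab2[tab2$stratum == "normal" & tab2$measure == "sedentary", ]
  expect_equal(small$n, 3)
  expect_true(is.na(small$ci_low))
  expect_false(is.na(small$mean_diff))

  # unknown subjects are a validation error
  profiles2 <- profiles[-1, ]
  expect_error(stratified_agreement(summ, profiles2, "bmi"), "category")
})

test_that("ordinal adiposity association has the expected behaviour", {
  cats <- factor(rep(c("normal", "overweight", "obese"), each = 20),
                 levels = c("normal", "overweight", "obese"), ordered = TRUE)
  rising <- as.integer(cats) * 100 + seq_along(cats)
  expect_gt(adiposity_association(rising, cats), 0.8)
  expect_error(adiposity_association(rnorm(10), rep(1L, 10)), "single-category")

  set.seed(9)
  null_rho <- adiposity_association(rnorm(2000),
                                    sample(1:3, 2000, replace = TRUE))
  expect_lt(abs(null_rho), 0.06)
})
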