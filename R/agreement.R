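#' Spearman rank correlation
#'
#' Pearson correlation of mid-ranks (ties receive average ranks).
#'
#' @param x,y numeric vectors of equal length (>= 2), neither constant.
#' @return The correlation coefficient.
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y)) stop_validation("x and y must have equal length")
  if (length(x) < 2L) stop_validation("need at least 2 pairs")
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stop_validation("non-finite values")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("undefined correlation: constant vector", call. = FALSE)
  stats::cor(x, y, method = "spearman")
}

#' Fisher-z confidence interval for a correlation
#'
#' `tanh(atanh(rho) +/- z_crit / sqrt(n - 3))`.
#'
#' @param rho correlation in (-1, 1).
#' @param n number of pairs (>= 4).
#' @param level confidence level (default 0.95).
#' @return Numeric length-2 `(ci_low, ci_high)`.
#' @export
fisher_ci <- function(rho, n, level = 0.95) {
  if (!is_scalar_number(n) || n < 4) stop_validation("n must be >= 4")
  if (!is_scalar_number(rho) || abs(rho) >= 1)
    stop_validation("rho must lie strictly inside (-1, 1)")
  if (!is_scalar_number(level) || level < 0 || level >= 1)
    stop_validation("level must lie in [0, 1)")
  z <- atanh(rho)
  hw <- stats::qnorm(1 - (1 - level) / 2) / sqrt(n - 3)
  c(ci_low = tanh(z - hw), ci_high = tanh(z + hw))
}

#' Bland-Altman limits of agreement
#'
#' Differences are questionnaire minus accelerometer; the limits are the
#' mean difference plus/minus 1.96 times the sample SD (n - 1 denominator)
#' of the differences.
#'
#' @param questionnaire,accelerometer paired vectors (n >= 2).
#' @param k multiplier for the SD (default 1.96).
#' @return List: `mean_diff`, `sd_diff`, `loa_low`, `loa_high`, `n`.
#' @export
limits_of_agreement <- function(questionnaire, accelerometer, k = 1.96) {
  if (length(questionnaire) != length(accelerometer))
    stop_validation("pairs incomplete: unequal lengths")
  n <- length(questionnaire)
  if (n < 2L) stop_validation("need at least 2 pairs")
  d <- questionnaire - accelerometer
  m <- mean(d); s <- stats::sd(d)
  list(mean_diff = m, sd_diff = s, loa_low = m - k * s, loa_high = m + k * s,
       n = n)
}

#' Paired t-test of the two instruments
#'
#' Two-sided test of mean(questionnaire - accelerometer) = 0 with n - 1
#' degrees of freedom.
#'
#' @param questionnaire,accelerometer paired vectors (n >= 2) whose
#'   differences are not all identical.
#' @return List: `t_stat`, `df`, `p_value`.
#' @export
paired_t <- function(questionnaire, accelerometer) {
  if (length(questionnaire) != length(accelerometer))
    stop_validation("pairs incomplete: unequal lengths")
  if (length(questionnaire) < 2L) stop_validation("need at least 2 pairs")
  if (stats::sd(questionnaire - accelerometer) == 0)
    stop("degenerate case: zero variance of differences", call. = FALSE)
  tt <- stats::t.test(questionnaire, accelerometer, paired = TRUE)
  list(t_stat = unname(tt$statistic), df = unname(tt$parameter),
       p_value = tt$p.value)
}

#' Fit the method-agreement estimator for one set of pairs
#'
#' The core comparison between the two instruments for one measure in one
#' stratum: Spearman's rho with a Fisher-z confidence interval, the mean
#' questionnaire-minus-accelerometer difference with Bland-Altman limits of
#' agreement, and a paired t-test. Components that are undefined for the
#' data at hand (rho on a constant vector, a CI with n < 4, a t-test with
#' zero difference variance) are returned as `NA` rather than erroring, so
#' small strata can still be tabulated.
#'
#' @param questionnaire,accelerometer paired per-subject values (min/day).
#' @param conf_level confidence level for the rho CI (default 0.95).
#' @param stratum,measure optional labels carried into print output.
#' @return An object of class `pa_agreement`.
#' @seealso [stratified_agreement()] for the tabled, stratified analysis.
#' @export
agreement <- function(questionnaire, accelerometer, conf_level = 0.95,
                      stratum = "all", measure = NULL) {
  n <- length(questionnaire)
  loa <- if (n >= 2) limits_of_agreement(questionnaire, accelerometer)
  else list(mean_diff = mean(questionnaire - accelerometer),
            sd_diff = NA_real_, loa_low = NA_real_, loa_high = NA_real_,
            n = n)
  rho <- tryCatch(spearman_rho(questionnaire, accelerometer),
                  error = function(e) NA_real_)
  ci <- if (!is.na(rho) && abs(rho) < 1 && n >= 4)
    fisher_ci(rho, n, conf_level) else c(ci_low = NA_real_, ci_high = NA_real_)
  tt <- tryCatch(paired_t(questionnaire, accelerometer),
                 error = function(e) list(t_stat = NA_real_, df = n - 1,
                                          p_value = NA_real_))
  structure(
    list(n = n, rho = rho, ci_low = unname(ci[1]), ci_high = unname(ci[2]),
         conf_level = conf_level,
         mean_diff = loa$mean_diff, sd_diff = loa$sd_diff,
         loa_low = loa$loa_low, loa_high = loa$loa_high,
         t_stat = tt$t_stat, df = tt$df, p_value = tt$p_value,
         stratum = stratum, measure = measure,
         data = data.frame(questionnaire = questionnaire,
                           accelerometer = accelerometer)),
    class = "pa_agreement")
}

#' @export
print.pa_agreement <- function(x, digits = 2, ...) {
  hdr <- paste0("Method agreement",
                if (!is.null(x$measure)) paste0(": ", x$measure),
                if (!identical(x$stratum, "all")) paste0(" [", x$stratum, "]"))
  cat(hdr, sprintf("(n = %d)\n", x$n))
  cat(sprintf("  Spearman rho %.2f (%.0f%% CI %.2f, %.2f)\n",
              x$rho, 100 * x$conf_level, x$ci_low, x$ci_high))
  cat(sprintf("  Mean difference %.*f min/day (LoA %.*f to %.*f)\n",
              digits, x$mean_diff, digits, x$loa_low, digits, x$loa_high))
  cat(sprintf("  Paired t = %.2f, df = %d, p = %.3g\n",
              x$t_stat, as.integer(x$df), x$p_value))
  invisible(x)
}

#' @export
summary.pa_agreement <- function(object, ...) {
  print(object, digits = 3)
  invisible(object)
}

#' @export
coef.pa_agreement <- function(object, ...) {
  c(rho = object$rho, mean_diff = object$mean_diff, sd_diff = object$sd_diff,
    loa_low = object$loa_low, loa_high = object$loa_high,
    t_stat = object$t_stat, p_value = object$p_value, n = object$n)
}

#' @export
confint.pa_agreement <- function(object, parm, level = NULL, ...) {
  lv <- level %||% object$conf_level
  ci <- if (!is.na(object$rho) && abs(object$rho) < 1 && object$n >= 4)
    fisher_ci(object$rho, object$n, lv) else c(NA_real_, NA_real_)
  out <- rbind(rho = ci,
               mean_diff = c(object$loa_low, object$loa_high))
  colnames(out) <- c("lower", "upper")
  out
}

#' Bland-Altman plot of a fitted agreement object
#'
#' Pairwise means against questionnaire-minus-accelerometer differences,
#' with the mean difference and the limits of agreement drawn as horizontal
#' lines.
#' @param x a `pa_agreement` object.
#' @param ... passed to [graphics::plot()].
#' @export
plot.pa_agreement <- function(x, ...) {
  d <- x$data
  avg <- (d$questionnaire + d$accelerometer) / 2
  diff <- d$questionnaire - d$accelerometer
  graphics::plot(avg, diff,
                 xlab = "Mean of instruments (min/day)",
                 ylab = "Questionnaire - accelerometer (min/day)",
                 main = paste0("Bland-Altman",
                               if (!is.null(x$measure)) paste0(": ", x$measure)),
                 ...)
  graphics::abline(h = x$mean_diff, lty = 1)
  graphics::abline(h = c(x$loa_low, x$loa_high), lty = 2)
  invisible(x)
}

# Subject-level aggregation: mean over recorded days per instrument.
subject_means <- function(summaries, measure) {
  col <- paste0(measure, "_min")
  agg <- stats::aggregate(summaries[[col]],
                          by = list(subject_id = summaries$subject_id,
                                    instrument = summaries$instrument),
                          FUN = mean)
  q <- agg[agg$instrument == "questionnaire", c("subject_id", "x")]
  a <- agg[agg$instrument == "accelerometer", c("subject_id", "x")]
  m <- merge(q, a, by = "subject_id", suffixes = c("_q", "_a"))
  m[order(m$subject_id), , drop = FALSE]
}

#' Stratified instrument-agreement table
#'
#' Runs the [agreement()] estimator for each activity measure in each
#' stratum of the chosen adiposity (or other grouping) scheme, plus an
#' all-participants row. The unit of analysis is the subject: each
#' instrument is summarised as the mean over that subject's recorded days
#' (day-level pooling is available via `unit = "day"`). Strata with fewer
#' than 4 subjects are still emitted, with the CI marked unavailable.
#'
#' @param summaries long daily-summary data frame containing both
#'   instruments (columns `subject_id`, `date`, `instrument`,
#'   `sedentary_min`, `walking_min`, `mvpa_min`).
#' @param profiles output of [adiposity_profile()], or any data frame with
#'   `subject_id` and a `category_<scheme>` column.
#' @param scheme `"bmi"`, `"bia"` or `"whr"`.
#' @param measures which measures to tabulate.
#' @param conf_level confidence level for rho CIs.
#' @param unit `"subject"` (default) or `"day"`.
#' @return Data frame of class `comparison_table`, one row per stratum per
#'   measure.
#' @export
stratified_agreement <- function(summaries, profiles,
                                 scheme = c("bmi", "bia", "whr"),
                                 measures = c("sedentary", "walking", "mvpa"),
                                 conf_level = 0.95,
                                 unit = c("subject", "day")) {
  scheme <- match.arg(scheme)
  unit <- match.arg(unit)
  cat_col <- paste0("category_", scheme)
  if (!cat_col %in% names(profiles))
    stop_validation("profiles lack column ", cat_col)
  rows <- list()
  for (measure in measures) {
    pairs <- if (unit == "subject") subject_means(summaries, measure) else {
      col <- paste0(measure, "_min")
      q <- summaries[summaries$instrument == "questionnaire",
                     c("subject_id", "date", col)]
      a <- summaries[summaries$instrument == "accelerometer",
                     c("subject_id", "date", col)]
      m <- merge(q, a, by = c("subject_id", "date"), suffixes = c("_q", "_a"))
      names(m)[3:4] <- c("x_q", "x_a")
      m
    }
    cat <- profiles[[cat_col]][match(pairs$subject_id, profiles$subject_id)]
    if (anyNA(cat))
      stop_validation("subject(s) without a ", scheme, " category: ",
                      paste(utils::head(pairs$subject_id[is.na(cat)], 3),
                            collapse = ", "))
    strata <- c("all", levels(droplevels(cat)))
    for (st in strata) {
      sel <- if (st == "all") rep(TRUE, nrow(pairs)) else cat == st
      fit <- agreement(pairs$x_q[sel], pairs$x_a[sel], conf_level,
                       stratum = st, measure = measure)
      rows[[length(rows) + 1L]] <- data.frame(
        scheme = scheme, stratum = st, measure = measure, n = fit$n,
        rho = fit$rho, ci_low = fit$ci_low, ci_high = fit$ci_high,
        mean_diff = fit$mean_diff, sd_diff = fit$sd_diff,
        loa_low = fit$loa_low, loa_high = fit$loa_high,
        t_stat = fit$t_stat, p_value = fit$p_value)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("comparison_table", "data.frame")
  out
}

#' @export
print.comparison_table <- function(x, ...) {
  y <- as.data.frame(x)
  rnd <- c(rho = 2, ci_low = 2, ci_high = 2, mean_diff = 0, loa_low = 0,
           loa_high = 0, sd_diff = 1, t_stat = 2)
  for (cl in names(rnd))
    if (cl %in% names(y) && is.numeric(y[[cl]]))
      y[[cl]] <- round(y[[cl]], rnd[[cl]])
  if ("p_value" %in% names(y) && is.numeric(y$p_value))
    y$p_value <- signif(y$p_value, 3)
  print.data.frame(y, row.names = FALSE)
  invisible(x)
}

#' Spearman association of a measure with ordinal adiposity category
#'
#' Correlates a continuous activity measure against the 1/2/3 ordinal
#' category (mid-ranks for the heavy category ties).
#'
#' @param values per-subject measure values.
#' @param categories ordered factor or integer codes 1--3.
#' @return Spearman's rho.
#' @export
adiposity_association <- function(values, categories) {
  code <- if (is.factor(categories)) as.integer(categories) else
    as.integer(categories)
  if (length(unique(code)) < 2L)
    stop("undefined correlation: single-category cohort", call. = FALSE)
  spearman_rho(values, code)
}

#' Activity-versus-adiposity association table
#'
#' For each scheme and measure, the Spearman correlation of each
#' instrument's subject-level measure with the ordinal adiposity category
#' (the layout of a questionnaire-vs-accelerometer association table).
#'
#' @param summaries long daily-summary data frame with both instruments.
#' @param profiles output of [adiposity_profile()].
#' @param schemes schemes to include.
#' @param measures measures to include.
#' @return Data frame: `scheme`, `measure`, `rho_questionnaire`, `rho_accelerometer`.
#' @export
adiposity_association_table <- function(summaries, profiles,
                                        schemes = c("bmi", "bia", "whr"),
                                        measures = c("sedentary", "walking",
                                                     "mvpa")) {
  rows <- list()
  for (scheme in schemes) {
    cat_col <- paste0("category_", scheme)
    for (measure in measures) {
      pairs <- subject_means(summaries, measure)
      cat <- profiles[[cat_col]][match(pairs$subject_id, profiles$subject_id)]
      rows[[length(rows) + 1L]] <- data.frame(
        scheme = scheme, measure = measure,
        rho_questionnaire = adiposity_association(pairs$x_q, cat),
        rho_accelerometer = adiposity_association(pairs$x_a, cat))
    }
  }
  do.call(rbind, rows)
}
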