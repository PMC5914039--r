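#' BMI category
#'
#' Normal weight below 25 kg/m2, overweight in [25, 30), obese at or above
#' 30: the printed bands (<=24.9 / 25--29.9 / >=30) read as half-open
#' intervals so every continuous BMI maps to exactly one category.
#'
#' @param bmi body mass index, kg/m2 (> 0).
#' @return Ordered factor `normal < overweight < obese`.
#' @export
categorize_bmi <- function(bmi) {
  if (any(!is.finite(bmi)) || any(bmi <= 0))
    stop_validation("bmi must be positive and finite")
  cut(bmi, c(-Inf, 25, 30, Inf), labels = c("normal", "overweight", "obese"),
      right = FALSE, ordered_result = TRUE)
}

norm_sex <- function(sex) {
  s <- toupper(substr(as.character(sex), 1, 1))
  if (any(!s %in% c("M", "F")))
    stop_validation("unknown sex code: ",
                    paste(unique(sex[!s %in% c("M", "F")]), collapse = ", "))
  s
}

#' Bioimpedance percent-body-fat category
#'
#' Sex-specific bands with the printed gaps closed half-open at the upper
#' boundary: women average < 26, high [26, 36], obese > 36; men average
#' < 21, high [21, 25], obese > 25. Values below the printed "average"
#' floor (22 for women, 14 for men) are classed average and flagged in the
#' `below_floor` attribute (the study population excluded underweight
#' adults, so such values signal a data-quality issue rather than a band).
#'
#' @param bodyfat_pct percent body fat, in (0, 100).
#' @param sex "M"/"F" (or male/female, any case).
#' @return Ordered factor `average < high < obese` with attribute
#'   `below_floor`.
#' @export
categorize_bia <- function(bodyfat_pct, sex) {
  if (any(!is.finite(bodyfat_pct)) || any(bodyfat_pct <= 0) ||
      any(bodyfat_pct >= 100))
    stop_validation("bodyfat_pct must lie in (0, 100)")
  s <- norm_sex(sex)
  hi_lo <- ifelse(s == "F", 26, 21)  # start of "high"
  ob_lo <- ifelse(s == "F", 36, 25)  # "obese" is strictly above this
  floor_lo <- ifelse(s == "F", 22, 14)
  cat <- ifelse(bodyfat_pct > ob_lo, "obese",
                ifelse(bodyfat_pct >= hi_lo, "high", "average"))
  below <- bodyfat_pct < floor_lo
  if (any(below))
    warning(sum(below), " body-fat value(s) below the printed average floor; ",
            "classed average and flagged", call. = FALSE)
  out <- factor(cat, levels = c("average", "high", "obese"), ordered = TRUE)
  attr(out, "below_floor") <- below
  out
}

#' Waist-to-hip ratio and category
#'
#' WHR = waist / hip. Sex-specific bands, printed gaps closed half-open:
#' women normal < 0.80, overweight [0.80, 0.85), obese >= 0.85; men normal
#' < 0.90, overweight [0.90, 1.00), obese >= 1.00.
#'
#' @param waist,hip circumferences in cm (> 0).
#' @param sex "M"/"F".
#' @return Data frame with `whr` and ordered factor `category`.
#' @export
categorize_whr <- function(waist, hip, sex) {
  if (any(!is.finite(hip)) || any(hip <= 0))
    stop_validation("hip must be positive")
  if (any(!is.finite(waist)) || any(waist <= 0))
    stop_validation("waist must be positive")
  s <- norm_sex(sex)
  whr <- waist / hip
  ov <- ifelse(s == "F", 0.80, 0.90)
  ob <- ifelse(s == "F", 0.85, 1.00)
  cat <- ifelse(whr >= ob, "obese", ifelse(whr >= ov, "overweight", "normal"))
  data.frame(whr = whr,
             category = factor(cat, levels = c("normal", "overweight", "obese"),
                               ordered = TRUE))
}

#' Read anthropometrics CSV
#'
#' Expects `subject_id,sex,age,height_cm,weight_kg,bodyfat_pct,waist_cm,hip_cm`.
#' @param path CSV path.
#' @return Data frame.
#' @export
read_anthropometrics <- function(path) {
  if (!file.exists(path)) stop_validation("anthropometrics file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "sex", "age", "height_cm", "weight_kg",
            "bodyfat_pct", "waist_cm", "hip_cm")
  if (!all(need %in% names(df)))
    stop_validation("anthropometrics CSV must have columns ",
                    paste(need, collapse = ","))
  df
}

#' Adiposity profile: BMI, WHR and all three categorisations
#'
#' Adds `bmi` (weight / height^2), `whr` (waist / hip) and the ordinal
#' categories under the BMI, bioimpedance and waist-to-hip schemes.
#'
#' @param df anthropometrics data frame (see [read_anthropometrics()]).
#' @return The input with columns `bmi`, `whr`, `category_bmi`,
#'   `category_bia`, `category_whr` appended.
#' @export
adiposity_profile <- function(df) {
  h <- df$height_cm / 100
  if (any(!is.finite(h)) || any(h <= 0)) stop_validation("height must be positive")
  df$bmi <- df$weight_kg / h^2
  w <- categorize_whr(df$waist_cm, df$hip_cm, df$sex)
  df$whr <- w$whr
  df$category_bmi <- categorize_bmi(df$bmi)
  df$category_bia <- suppressWarnings(categorize_bia(df$bodyfat_pct, df$sex))
  attr(df$category_bia, "below_floor") <- NULL
  df$category_whr <- w$category
  df
}
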