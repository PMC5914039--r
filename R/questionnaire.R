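#' Read daily questionnaire records
#'
#' Expects `subject_id,date,moderate_min,vigorous_min,walking_min,sitting_min`:
#' one row per subject-day of end-of-day recall (IPAQ short form items asked
#' about "today").
#' @param path CSV path.
#' @return Data frame of questionnaire days.
#' @export
read_questionnaire_csv <- function(path) {
  if (!file.exists(path)) stop_validation("questionnaire file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "date", "moderate_min", "vigorous_min",
            "walking_min", "sitting_min")
  if (!all(need %in% names(df)))
    stop_validation("questionnaire CSV must have columns ",
                    paste(need, collapse = ","))
  df$date <- as.Date(df$date)
  df
}

#' Score daily IPAQ-S records
#'
#' MVPA minutes are the sum of the moderate and vigorous items (reported
#' minutes, no MET weighting); walking passes through; the sitting item
#' becomes sedentary minutes. Items must lie in [0, 1440]; days whose items
#' total more than 1440 minutes are retained with a warning rather than
#' truncated.
#'
#' @param days data frame of questionnaire days (see
#'   [read_questionnaire_csv()]).
#' @return Daily summary rows with `instrument = "questionnaire"`.
#' @export
score_ipaq_daily <- function(days) {
  items <- c("moderate_min", "vigorous_min", "walking_min", "sitting_min")
  for (it in items) {
    v <- days[[it]]
    if (any(!is.finite(v)) || any(v < 0))
      stop_validation("negative or missing ", it)
    if (any(v > 1440))
      stop_validation(it, " exceeds 1440 minutes/day")
  }
  tot <- rowSums(days[items])
  if (any(tot > 1440))
    warning(sum(tot > 1440),
            " day(s) report more than 1440 total minutes; retained unmodified",
            call. = FALSE)
  data.frame(
    subject_id = days$subject_id,
    date = days$date,
    instrument = "questionnaire",
    sedentary_min = days$sitting_min,
    walking_min = days$walking_min,
    mvpa_min = days$moderate_min + days$vigorous_min,
    wear_min = NA_real_)
}
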