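#' Rank-based inverse normal transformation
#'
#' Maps values to normal quantiles of their (Blom-offset) fractional
#' ranks: `qnorm((rank - c) / (n - 2c + 1))` with offset `c = 3/8` by
#' default. Ties receive the average rank; missing values are propagated.
#' The transform is invariant to any strictly monotone transformation of
#' the input.
#'
#' @param values numeric vector with at least 2 distinct non-missing values.
#' @param offset rank offset constant `c` (Blom's 3/8 by default).
#' @return numeric vector of the same length, approximately standard
#'   normal, with `NA` where the input was missing.
#' @export
rint <- function(values, offset = 3 / 8) {
  ok <- !is.na(values)
  x <- values[ok]
  if (length(x) < 2L) stop("need at least 2 non-missing values")
  if (length(unique(x)) < 2L)
    stop("all values identical; rank transform undefined")
  n <- length(x)
  out <- rep(NA_real_, length(values))
  out[ok] <- qnorm((rank(x, ties.method = "average") - offset) /
                     (n - 2 * offset + 1))
  out
}

.diet_map <- c("almost every day" = 7, "3-4 days per week" = 3.5,
               "1-2 days per week" = 1.5, "rarely" = 0)

# activity: total minutes per week; parenthesized halved values apply to
# gymnastics, whose sessions are counted at 15 rather than 30 minutes.
.activity_map <- c(">=30 min/day" = 210, "<30 min/day" = 140,
                   "3-4 times a week >=30 min" = 105,
                   "3-4 times a week <30 min" = 70,
                   "1-2 times a week >=30 min" = 45,
                   "1-2 times a week <30 min" = 30,
                   "rarely" = 0)

.normalize_label <- function(x) {
  x <- tolower(trimws(x))
  x <- gsub("–|—", "-", x)          # en/em dash -> hyphen
  x <- gsub("≥|>=", ">=", x)             # unicode >=
  x <- gsub("times per week", "times a week", x, fixed = TRUE)
  x <- gsub("three to four", "3-4", x, fixed = TRUE)
  x <- gsub("one to two", "1-2", x, fixed = TRUE)
  x <- gsub("\\s+times\\s+a\\s+week\\s+for\\s+", " times a week ", x)
  x <- gsub("min day-1|min/day|min per day", "min/day", x)
  gsub("\\s+", " ", x)
}

#' Encode dietary-frequency questionnaire responses
#'
#' Four-point consumption-frequency categories are mapped to days per
#' week: almost every day = 7, 3-4 days per week = 3.5, 1-2 days per week
#' = 1.5, rarely = 0. Labels are matched case-insensitively after
#' whitespace/dash normalization; `NA` is propagated.
#'
#' @param category character vector of responses.
#' @return numeric vector of weekly frequencies.
#' @export
encode_diet <- function(category) {
  key <- .normalize_label(category)
  out <- unname(.diet_map[key])
  bad <- is.na(out) & !is.na(category)
  if (any(bad))
    stop("unknown diet category: ", paste(unique(category[bad]), collapse = ", "),
         "; valid: ", paste(names(.diet_map), collapse = "; "))
  out
}

#' Encode physical-activity questionnaire responses
#'
#' Seven-point frequency/duration categories are converted to total
#' minutes of activity per week: 210 / 140 / 105 / 70 / 45 / 30 / 0. For
#' gymnastics the session duration threshold is 15 rather than 30
#' minutes, giving exactly half the value in each category (105 / 70 /
#' 52.5 / 35 / 22.5 / 15 / 0).
#'
#' @param category character vector of responses (see `names(gpdscan:::.activity_map)`).
#' @param gymnastics logical; use the halved gymnastics scale.
#' @return numeric vector, minutes per week.
#' @export
encode_activity <- function(category, gymnastics = FALSE) {
  key <- .normalize_label(category)
  if (gymnastics) key <- gsub("15", "30", key, fixed = TRUE) # 15-min scale labels
  out <- unname(.activity_map[key])
  bad <- is.na(out) & !is.na(category)
  if (any(bad))
    stop("unknown activity category: ",
         paste(unique(category[bad]), collapse = ", "),
         "; valid: ", paste(names(.activity_map), collapse = "; "))
  if (gymnastics) out / 2 else out
}
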