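# Daily activity-level labeling.
#
# A day is scored on a five-point scale from its step count and its
# MET-equivalent weekly activity minutes, W = (2*VPA + MPA) * 7, where one
# vigorous minute counts as two moderate-equivalent minutes.  Each level has
# two sufficient conditions: a minutes band (requiring at least 5000 steps)
# and a step-count band.  A day receives the highest level granted by any
# satisfied condition.

#' Names of the five daily activity levels
#'
#' Level 0 is sedentary, 4 is highly active; the integer level doubles as the
#' day's score.
#' @return Character vector of length 5, named by score "0".."4".
#' @export
activity_level_names <- function() {
  c(`0` = "Sedentary", `1` = "Low Active", `2` = "Active",
    `3` = "Medium Active", `4` = "Highly Active")
}

#' Weekly MET-equivalent activity minutes
#'
#' @param mpa,vpa Daily moderate / vigorous activity minutes.
#' @return `(2 * vpa + mpa) * 7`, the week-equivalent moderate-intensity
#'   minutes implied by one day's activity.
#' @export
weekly_equivalent_minutes <- function(mpa, vpa) {
  assert_nonneg(mpa, "mpa"); assert_nonneg(vpa, "vpa")
  (2 * vpa + mpa) * 7
}

#' Classify one or more days into activity levels 0-4
#'
#' Evaluates the five level rules and returns the highest satisfied level.
#' The minutes-based conditions all require at least 5000 steps, so a day
#' under 5000 steps is always sedentary (level 0) regardless of recorded
#' activity minutes; conversely a day may qualify on minutes for a higher
#' level than its step count alone grants, and then the minutes level wins.
#'
#' @param steps Daily step count (vectorised).
#' @param lpa,mpa,vpa Daily light / moderate / vigorous activity minutes.
#' @return Integer vector of levels in 0..4 (the level is also the score).
#' @examples
#' classify_day(4500, 300, 0, 0)   # 0: under 5000 steps
#' classify_day(8000, 0, 0, 0)     # 2: step band 7500-9999
#' classify_day(5000, 0, 60, 0)    # 4: 60 moderate minutes/day
#' @export
classify_day <- function(steps, lpa = 0, mpa = 0, vpa = 0) {
  n <- max(length(steps), length(lpa), length(mpa), length(vpa))
  steps <- rep_len(steps, n); lpa <- rep_len(lpa, n)
  mpa <- rep_len(mpa, n); vpa <- rep_len(vpa, n)
  assert_nonneg(steps, "steps"); assert_nonneg(lpa, "lpa")
  assert_nonneg(mpa, "mpa"); assert_nonneg(vpa, "vpa")
  w <- weekly_equivalent_minutes(mpa, vpa)
  lvl <- integer(n)                                   # steps < 5000 => 0
  hit1 <- (steps > 4999 & w >= 90 & w < 210) | (steps > 4999 & steps < 7500)
  hit2 <- (steps > 4999 & w >= 210 & w < 300) | (steps > 7499 & steps < 10000)
  hit3 <- (steps > 4999 & w >= 300 & w < 360) | (steps > 9999 & steps < 12500)
  hit4 <- (steps > 4999 & w >= 360) | (steps > 12499)
  lvl[hit1] <- 1L; lvl[hit2] <- 2L; lvl[hit3] <- 3L; lvl[hit4] <- 4L
  lvl
}

#' Label a data set of daily activity records
#'
#' Adds `activity_level`, `activity_level_name`, `score` and
#' `weekly_equivalent_min` columns and reports the class histogram.
#'
#' @param days Data frame with columns `steps`, `lpa_min`, `mpa_min`,
#'   `vpa_min` (as produced by [gen_daily_records()] or
#'   [aggregate_minutes_to_days()]).
#' @return The input data frame with label columns appended; the class
#'   histogram is attached as attribute `"class_histogram"`.
#' @export
label_dataset <- function(days) {
  stopifnot(is.data.frame(days), nrow(days) >= 1)
  need <- c("steps", "lpa_min", "mpa_min", "vpa_min")
  miss <- setdiff(need, names(days))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  lvl <- classify_day(days$steps, days$lpa_min, days$mpa_min, days$vpa_min)
  days$activity_level <- lvl
  days$activity_level_name <- unname(activity_level_names()[as.character(lvl)])
  days$score <- lvl
  days$weekly_equivalent_min <- weekly_equivalent_minutes(days$mpa_min, days$vpa_min)
  attr(days, "class_histogram") <- table(factor(lvl, levels = 0:4))
  days
}
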