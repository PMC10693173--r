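# Synthetic wearable-activity data generation.
#
# No real sensor data ships with the package: personas generate daily step
# series with weekday/weekend structure, linear trend and noise, and
# minute-resolution sensor records in which every minute's posture/intensity
# seconds sum exactly to the 60-second budget.

# Waking window within which non-sedentary minutes may occur; nights are
# recorded as sedentary (the sensor counts sleep in sedentary time).
.WAKE_START <- 6L   # 06:00
.WAKE_END   <- 23L  # up to 22:59

# Per-level bands for t = 2*VPA + MPA (minutes/day), chosen so that
# (2*VPA + MPA) * 7 lands inside the level's weekly-minutes rule band.
.T_BANDS <- list(`0` = c(0L, 12L), `1` = c(13L, 29L), `2` = c(30L, 42L),
                 `3` = c(43L, 51L), `4` = c(52L, 80L))

# Per-level daily step ranges matching the step-count rule bands.
.STEP_BANDS <- list(`0` = c(1200, 4999), `1` = c(5000, 7499),
                    `2` = c(7500, 9999), `3` = c(10000, 12499),
                    `4` = c(12500, 16500))

#' Construct a synthetic activity persona
#'
#' A persona fixes the generative conditions for one simulated participant:
#' a target activity level, the mean and spread of daily steps, a weekend
#' multiplier on the step mean, a linear trend, and the per-waking-minute
#' intensity mix.
#'
#' @param persona_class Target daily activity level, integer 0-4.
#' @param mean_daily_steps Mean steps per day (>= 0).
#' @param step_sd Standard deviation of daily steps.
#' @param weekend_multiplier Multiplicative factor applied to the step mean on
#'   Saturdays and Sundays (> 0).
#' @param trend_per_day Additive linear trend in steps/day/day.
#' @param minute_intensity_mix Named probability vector over
#'   `c("sedentary", "lpa", "mpa", "vpa", "weight_bearing", "standing")`
#'   for each waking minute; must sum to 1.
#' @return An object of class `activity_profile`.
#' @export
activity_profile <- function(persona_class,
                             mean_daily_steps,
                             step_sd = 0,
                             weekend_multiplier = 1,
                             trend_per_day = 0,
                             minute_intensity_mix = NULL) {
  stopifnot(persona_class %in% 0:4, mean_daily_steps >= 0, step_sd >= 0,
            weekend_multiplier > 0)
  cats <- c("sedentary", "lpa", "mpa", "vpa", "weight_bearing", "standing")
  if (is.null(minute_intensity_mix)) {
    minute_intensity_mix <- c(sedentary = 0.70, lpa = 0.18, mpa = 0.05,
                              vpa = 0.01, weight_bearing = 0.03, standing = 0.03)
  }
  if (!all(names(minute_intensity_mix) %in% cats))
    stop("minute_intensity_mix names must be among: ", paste(cats, collapse = ", "))
  mix <- stats::setNames(numeric(length(cats)), cats)
  mix[names(minute_intensity_mix)] <- minute_intensity_mix
  if (abs(sum(mix) - 1) > 1e-8) stop("minute_intensity_mix must sum to 1")
  if (any(mix < 0)) stop("minute_intensity_mix entries must be non-negative")
  structure(list(persona_class = as.integer(persona_class),
                 mean_daily_steps = mean_daily_steps,
                 step_sd = step_sd,
                 weekend_multiplier = weekend_multiplier,
                 trend_per_day = trend_per_day,
                 minute_intensity_mix = mix),
            class = "activity_profile")
}

#' @export
print.activity_profile <- function(x, ...) {
  cat("<activity_profile> target level", x$persona_class,
      sprintf("(%s)\n", activity_level_names()[as.character(x$persona_class)]))
  cat("  steps/day:", x$mean_daily_steps, "+/-", x$step_sd,
      " weekend x", x$weekend_multiplier, " trend", x$trend_per_day, "/day\n")
  cat("  minute mix:", paste(sprintf("%s=%.2f", names(x$minute_intensity_mix),
                                     x$minute_intensity_mix), collapse = " "), "\n")
  invisible(x)
}

#' Default personas, one per activity level
#'
#' Step means sit mid-band for each level and activity-minute draws stay in
#' the matching weekly-minutes band, so each persona's days labels
#' predominantly as its own class.
#'
#' @return Named list of five [activity_profile()] objects, `"0"` to `"4"`.
#' @export
default_personas <- function() {
  mk <- function(cls, mu, sd, mix) activity_profile(cls, mu, sd,
                                                    weekend_multiplier = 1.2,
                                                    minute_intensity_mix = mix)
  list(
    `0` = mk(0, 3500, 700, c(sedentary = 0.86, lpa = 0.08, mpa = 0.006, vpa = 0,
                             weight_bearing = 0.027, standing = 0.027)),
    `1` = mk(1, 6200, 600, c(sedentary = 0.76, lpa = 0.15, mpa = 0.02, vpa = 0.002,
                             weight_bearing = 0.034, standing = 0.034)),
    `2` = mk(2, 8700, 600, c(sedentary = 0.70, lpa = 0.18, mpa = 0.033, vpa = 0.002,
                             weight_bearing = 0.04, standing = 0.045)),
    `3` = mk(3, 11200, 600, c(sedentary = 0.65, lpa = 0.21, mpa = 0.044, vpa = 0.002,
                              weight_bearing = 0.045, standing = 0.049)),
    `4` = mk(4, 14200, 800, c(sedentary = 0.58, lpa = 0.25, mpa = 0.055, vpa = 0.01,
                              weight_bearing = 0.05, standing = 0.055)))
}

# Draw per-day target steps honouring weekend multiplier and trend.
.daily_step_targets <- function(profile, dates) {
  weekend <- format(dates, "%u") %in% c("6", "7")
  mu <- profile$mean_daily_steps +
    profile$trend_per_day * (seq_along(dates) - 1)
  mu[weekend] <- mu[weekend] * profile$weekend_multiplier
  mu
}

#' Generate minute-resolution sensor records
#'
#' Produces `days * 1440` records with columns `timestamp`, `ima`,
#' `sedentary_s`, `weight_bearing_s`, `standing_s`, `lpa_s`, `mpa_s`,
#' `vpa_s`, `steps`.  Every record's six seconds fields sum to exactly 60.
#' Each waking minute (06:00-22:59) is assigned one dominant intensity drawn
#' from the persona's mix; its activity-intensity count `ima` is drawn
#' uniformly inside the band of that intensity (0-400 light, 401-800
#' moderate, >= 801 vigorous) and is 0 for sedentary, weight-bearing and
#' standing minutes.  Night minutes are sedentary with zero steps.
#'
#' @param profile An [activity_profile()].
#' @param days Number of days (>= 1).
#' @param seed RNG seed; identical arguments give identical output.
#' @param start_date First calendar date (default a Monday).
#' @return Data frame of minute records, `days * 1440` rows.
#' @export
gen_minute_records <- function(profile, days, seed = 1L,
                               start_date = as.Date("2023-01-02")) {
  stopifnot(inherits(profile, "activity_profile"))
  if (!is.numeric(days) || days < 1) stop("`days` must be >= 1")
  days <- as.integer(days)
  local_seed(seed, {
    dates <- start_date + seq_len(days) - 1
    targets <- .daily_step_targets(profile, dates)
    cats <- names(profile$minute_intensity_mix)
    out <- vector("list", days)
    wake <- 60L * .WAKE_START + seq_len(60L * (.WAKE_END - .WAKE_START)) - 1L
    for (d in seq_len(days)) {
      minute_cat <- rep("sedentary", 1440L)
      minute_cat[wake + 1L] <- sample(cats, length(wake), replace = TRUE,
                                      prob = profile$minute_intensity_mix)
      active <- minute_cat %in% c("lpa", "mpa", "vpa")
      n_active <- sum(active)
      steps <- integer(1440L)
      if (n_active > 0 && targets[d] > 0) {
        rate <- targets[d] / n_active
        draw <- stats::rnorm(n_active, rate, 0.2 * rate)
        steps[active] <- as.integer(round(pmax(0, draw)))
      }
      ima <- integer(1440L)
      ima[minute_cat == "lpa"] <- sample(0:400, sum(minute_cat == "lpa"), TRUE)
      ima[minute_cat == "mpa"] <- sample(401:800, sum(minute_cat == "mpa"), TRUE)
      ima[minute_cat == "vpa"] <- sample(801:1200, sum(minute_cat == "vpa"), TRUE)
      sec <- matrix(0L, nrow = 1440L, ncol = 6,
                    dimnames = list(NULL, c("sedentary_s", "weight_bearing_s",
                                            "standing_s", "lpa_s", "mpa_s", "vpa_s")))
      col_of <- c(sedentary = 1L, weight_bearing = 2L, standing = 3L,
                  lpa = 4L, mpa = 5L, vpa = 6L)
      sec[cbind(seq_len(1440L), col_of[minute_cat])] <- 60L
      out[[d]] <- data.frame(
        timestamp = format(as.POSIXct(dates[d], tz = "UTC") +
                             60 * (0:1439), "%Y-%m-%dT%H:%M:%S"),
        ima = ima, sec, steps = steps, stringsAsFactors = FALSE)
    }
    do.call(rbind, out)
  })
}

# Draw daily MPA/VPA minutes whose MET-equivalent total stays inside the
# persona class's weekly band; VPA is a small share of the total.
.draw_activity_minutes <- function(persona_class, n) {
  band <- .T_BANDS[[as.character(persona_class)]]
  t <- sample(band[1]:band[2], n, replace = TRUE)
  vpa <- vapply(t, function(ti) sample(0:(ti %/% 6), 1L), integer(1))
  mpa <- t - 2L * vpa
  list(mpa = mpa, vpa = vpa, t = t)
}

#' Generate daily activity summaries
#'
#' Daily steps are drawn as `Normal(mean, sd)` (rounded, floored at 0) with
#' the weekend multiplier applied on Saturdays/Sundays and the linear trend
#' added; LPA/MPA/VPA minutes are drawn inside the persona class's
#' weekly-minutes band so the generated day labels as the persona's class.
#'
#' @inheritParams gen_minute_records
#' @return Data frame with columns `date`, `steps`, `sedentary_min`,
#'   `lpa_min`, `mpa_min`, `vpa_min`.
#' @export
gen_daily_records <- function(profile, days, seed = 1L,
                              start_date = as.Date("2023-01-02")) {
  stopifnot(inherits(profile, "activity_profile"))
  if (!is.numeric(days) || days < 1) stop("`days` must be >= 1")
  days <- as.integer(days)
  local_seed(seed, {
    dates <- start_date + seq_len(days) - 1
    mu <- .daily_step_targets(profile, dates)
    steps <- round(pmax(0, stats::rnorm(days, mu, profile$step_sd)))
    act <- .draw_activity_minutes(profile$persona_class, days)
    lpa <- sample(60:240, days, replace = TRUE)
    data.frame(date = dates, steps = steps,
               sedentary_min = 1440L - lpa - act$mpa - act$vpa,
               lpa_min = lpa, mpa_min = act$mpa, vpa_min = act$vpa)
  })
}

#' Mark a fraction of a series as missing
#'
#' Replaces `floor(rate * n)` positions with `NA`; positions are sampled
#' without replacement and are reproducible under `seed`.  Values are marked
#' missing rather than dropped so that fill strategies can be exercised.
#'
#' @param series Numeric vector.
#' @param rate Fraction of positions to blank, in `[0, 1)`.
#' @param seed RNG seed.
#' @return `series` with `NA` at the selected positions.
#' @export
inject_missing <- function(series, rate, seed = 1L) {
  if (!is.numeric(rate) || length(rate) != 1 || rate < 0 || rate >= 1)
    stop("`rate` must be in [0, 1)")
  n_gap <- floor(rate * length(series))
  if (n_gap == 0) return(series)
  local_seed(seed, {
    series[sample(seq_along(series), n_gap)] <- NA
    series
  })
}

#' Generate a class-imbalanced labeled feature table
#'
#' Per-class counts are apportioned from `class_weights` by largest
#' remainder; each row's features (`sedentary`, `lpa`, `mpa`, `vpa`,
#' `steps`) are drawn inside its class's step and weekly-minutes bands, so
#' every row is a fixed point of [classify_day()].
#'
#' @param class_weights Named fractions over levels "0".."4" summing to 1.
#' @param n Total rows (>= number of classes with positive weight).
#' @param seed RNG seed.
#' @return Data frame with feature columns and an integer `label` column.
#' @export
make_imbalanced_dataset <- function(class_weights, n, seed = 1L) {
  if (any(class_weights < 0)) stop("class weights must be non-negative")
  if (abs(sum(class_weights) - 1) > 1e-8) stop("class weights must sum to 1")
  if (is.null(names(class_weights))) names(class_weights) <- as.character(seq_along(class_weights) - 1)
  if (n < sum(class_weights > 0)) stop("`n` smaller than the number of classes")
  counts <- largest_remainder(class_weights, n)
  local_seed(seed, {
    rows <- lapply(seq_along(counts), function(i) {
      ni <- counts[i]
      if (ni == 0) return(NULL)
      cls <- names(class_weights)[i]
      sb <- .STEP_BANDS[[cls]]
      steps <- sample(sb[1]:sb[2], ni, replace = TRUE)
      act <- .draw_activity_minutes(as.integer(cls), ni)
      lpa <- sample(60:240, ni, replace = TRUE)
      data.frame(sedentary = 1440L - lpa - act$mpa - act$vpa,
                 lpa = lpa, mpa = act$mpa, vpa = act$vpa,
                 steps = steps, label = as.integer(cls))
    })
    out <- do.call(rbind, rows)
    out[sample(nrow(out)), , drop = FALSE]
  })
}
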