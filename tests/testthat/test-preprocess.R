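# Aggregation, intensity banding, gap filling, and feature selection.

test_that("daily aggregation matches an independent re-sum of the minutes", {
  p <- default_personas()[["2"]]
  m <- gen_minute_records(p, 3, seed = 6)
  d <- aggregate_minutes_to_days(m)
  expect_equal(nrow(d), 3L)
  expect_false(any(d$partial))
  # brute-force oracle: re-accumulate over the raw table per date
  date <- substr(m$timestamp, 1, 10)
  expect_equal(d$steps, as.integer(tapply(m$steps, date, sum)), ignore_attr = TRUE)
  expect_equal(d$lpa_min, as.numeric(tapply(m$lpa_s, date, sum) / 60),
               ignore_attr = TRUE)
  expect_equal(d$sedentary_min, as.numeric(tapply(m$sedentary_s, date, sum) / 60),
               ignore_attr = TRUE)
})

test_that("hand-built minute blocks aggregate to the expected minutes", {
  m <- data.frame(
    timestamp = format(as.POSIXct("2023-03-01", tz = "UTC") + 60 * (0:1439),
                       "%Y-%m-%dT%H:%M:%S"),
    ima = 0L, sedentary_s = 60L, weight_bearing_s = 0L, standing_s = 0L,
    lpa_s = 0L, mpa_s = 0L, vpa_s = 0L, steps = 2L)
  m$lpa_s[1:30] <- 60L; m$sedentary_s[1:30] <- 0L
  d <- aggregate_minutes_to_days(m)
  expect_equal(d$steps, 2880L)
  expect_equal(d$lpa_min, 30)
  expect_equal(d$sedentary_min, 1410)
  m2 <- rbind(m, m[1, ])
  expect_error(aggregate_minutes_to_days(m2), "duplicate")
})

test_that("intensity bands partition the nonnegative counts exactly", {
  expect_equal(ima_to_activity_type(c(0, 400, 401, 800, 801, 5000)),
               c("LPA", "LPA", "MPA", "MPA", "VPA", "VPA"))
  expect_error(ima_to_activity_type(-1), ">= 0")
  # every value falls in exactly one band
  grid <- 0:2000
  bands <- ima_to_activity_type(grid)
  expect_true(all(bands %in% c("LPA", "MPA", "VPA")))
  expect_equal(sum(bands == "LPA"), 401L)
  expect_equal(sum(bands == "MPA"), 400L)
})

test_that("gap filling is forward-then-backward and idempotent", {
  expect_equal(fill_missing(c(5, NA, NA, 8)), c(5, 5, 5, 8))
  expect_equal(fill_missing(c(NA, 3, 4)), c(3, 3, 4))
  x <- c(1, 2, 3)
  expect_equal(fill_missing(x), x)
  y <- c(NA, 1, NA, NA, 2, NA)
  expect_equal(fill_missing(fill_missing(y)), fill_missing(y))
  expect_error(fill_missing(c(NA, NA)), "all-missing")
})

test_that("duplicated columns are pruned at the correlation threshold", {
  set.seed(1)
  df <- data.frame(a = rnorm(100))
  df$b <- df$a
  df$c <- rnorm(100)
  rep <- select_features(df, threshold = 0.72)
  expect_length(rep$retained, 2)
  expect_equal(nrow(rep$dropped), 1L)
  expect_equal(abs(rep$dropped$r), 1, tolerance = 1e-12)
  expect_true("c" %in% rep$retained)
})

test_that("independent features survive the 0.72 threshold", {
  set.seed(7)
  df <- as.data.frame(matrix(runif(500 * 4), ncol = 4))
  rep <- select_features(df, threshold = 0.72)
  expect_equal(sort(rep$retained), sort(names(df)))
  expect_equal(nrow(rep$dropped), 0L)
})

test_that("feature-set intersection yields the common feature space", {
  set.seed(3)
  fs1 <- data.frame(sedentary = rnorm(50), LPA = rnorm(50), MPA = rnorm(50),
                    VPA = rnorm(50), steps = rnorm(50), calorie = rnorm(50))
  rep <- select_features(fs1, threshold = 0.72,
                         other_set = c("sedentary", "LPA", "MPA", "VPA",
                                       "steps", "ima"))
  expect_setequal(rep$retained, c("sedentary", "LPA", "MPA", "VPA", "steps"))
})

test_that("constant features are reported with undefined correlations", {
  df <- data.frame(a = rnorm(30), b = rep(1, 30))
  rep <- select_features(df)
  expect_identical(rep$constant, "b")
  expect_true("b" %in% rep$retained)
  expect_true(is.na(rep$normality_p[["b"]]))
})

test_that("selection is stable under column permutation", {
  set.seed(9)
  df <- data.frame(x = rnorm(80))
  df$y <- df$x + rnorm(80, 0, 0.01)
  df$z <- rnorm(80)
  r1 <- select_features(df)
  r2 <- select_features(df[, c("z", "y", "x")])
  expect_setequal(r1$retained, r2$retained)
})
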