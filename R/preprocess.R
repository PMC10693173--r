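# Minute-to-day aggregation, IMA banding, gap filling, and correlation-based
# feature selection.

#' Aggregate minute records into daily activity summaries
#'
#' Steps are summed per calendar date; each seconds column is converted to
#' minutes (`sum(seconds) / 60`).  Days with fewer than 1440 minute records
#' are aggregated but flagged `partial`; downstream stages exclude flagged
#' days by default.
#'
#' @param records Minute records as produced by [gen_minute_records()]
#'   (columns `timestamp`, seconds fields, `steps`).
#' @return Data frame with `date`, `steps`, `sedentary_min`,
#'   `weight_bearing_min`, `standing_min`, `lpa_min`, `mpa_min`, `vpa_min`,
#'   `n_minutes`, `partial`.
#' @export
aggregate_minutes_to_days <- function(records) {
  stopifnot(is.data.frame(records))
  if (anyDuplicated(records$timestamp))
    stop("duplicate timestamps in minute records")
  ts <- records$timestamp
  ord <- order(ts)
  records <- records[ord, , drop = FALSE]
  date <- as.Date(substr(records$timestamp, 1, 10))
  agg <- function(x) tapply(x, date, sum)
  out <- data.frame(
    date = as.Date(names(agg(records$steps))),
    steps = as.integer(agg(records$steps)),
    sedentary_min = as.numeric(agg(records$sedentary_s)) / 60,
    weight_bearing_min = as.numeric(agg(records$weight_bearing_s)) / 60,
    standing_min = as.numeric(agg(records$standing_s)) / 60,
    lpa_min = as.numeric(agg(records$lpa_s)) / 60,
    mpa_min = as.numeric(agg(records$mpa_s)) / 60,
    vpa_min = as.numeric(agg(records$vpa_s)) / 60,
    n_minutes = as.integer(table(date)),
    row.names = NULL)
  out$partial <- out$n_minutes < 1440L
  out
}

#' Band a minute's activity-intensity count into an activity type
#'
#' @param ima Non-negative activity-intensity count(s).
#' @return Character vector: `"LPA"` for 0-400, `"MPA"` for 401-800,
#'   `"VPA"` for 801 and above.
#' @examples
#' ima_to_activity_type(c(400, 401, 801))
#' @export
ima_to_activity_type <- function(ima) {
  if (any(!is.finite(ima)) || any(ima < 0)) stop("`ima` must be >= 0")
  ifelse(ima <= 400, "LPA", ifelse(ima <= 800, "MPA", "VPA"))
}

#' Fill gaps in an ordered series
#'
#' Forward fill first, then backward fill for any leading gap; idempotent and
#' preserves all observed values.
#'
#' @param series Numeric vector possibly containing `NA`.
#' @return The series with no missing values.
#' @export
fill_missing <- function(series) {
  if (all(is.na(series))) stop("cannot fill an all-missing series")
  zoo::na.locf(zoo::na.locf(series, na.rm = FALSE), fromLast = TRUE)
}

#' Correlation-based feature selection
#'
#' Computes the pairwise Spearman correlation matrix and drops one member of
#' every pair with `|r| >= threshold`: within a violating pair the feature
#' with the larger mean absolute correlation to all other features is
#' dropped, ties broken alphabetically.  Constant features have undefined
#' correlations; they are reported and retained.  If `other_set` is given
#' the retained set is intersected with it (the common feature space of two
#' data sources).  Shapiro-Wilk normality p-values are reported per feature
#' (they motivate the rank correlation but never gate the selection).
#'
#' @param table Data frame of numeric features, at least 3 rows.
#' @param threshold Absolute Spearman r at or above which a pair is pruned
#'   (default 0.72).
#' @param other_set Optional character vector of feature names to intersect
#'   the retained set with.
#' @return An object of class `feature_selection_report`: list with
#'   `correlation_matrix`, `dropped` (feature, partner, r), `retained`,
#'   `normality_p`, `constant`.
#' @export
select_features <- function(table, threshold = 0.72, other_set = NULL) {
  stopifnot(is.data.frame(table), nrow(table) >= 3)
  num <- vapply(table, is.numeric, logical(1))
  if (!all(num)) stop("all features must be numeric")
  feats <- names(table)
  constant <- feats[vapply(table, function(x) length(unique(x[!is.na(x)])) <= 1, logical(1))]
  cm <- suppressWarnings(stats::cor(table, method = "spearman",
                                    use = "pairwise.complete.obs"))
  normality_p <- vapply(table, function(x) {
    x <- x[!is.na(x)]
    if (length(unique(x)) <= 1 || length(x) < 3) return(NA_real_)
    if (length(x) > 5000) x <- x[seq(1, length(x), length.out = 5000)]
    stats::shapiro.test(x)$p.value
  }, numeric(1))
  retained <- feats
  dropped <- data.frame(feature = character(), partner = character(),
                        r = numeric(), stringsAsFactors = FALSE)
  repeat {
    sub <- cm[setdiff(retained, constant), setdiff(retained, constant), drop = FALSE]
    diag(sub) <- 0
    if (!length(sub) || max(abs(sub), na.rm = TRUE) < threshold) break
    viol <- which(abs(sub) >= threshold, arr.ind = TRUE)
    cand <- unique(rownames(sub)[viol[, 1]])
    # mean absolute correlation to all other retained features
    mac <- vapply(cand, function(f) {
      r <- abs(sub[f, setdiff(colnames(sub), f)])
      if (!length(r)) 0 else mean(r, na.rm = TRUE)
    }, numeric(1))
    worst <- cand[order(-mac, cand)][1]
    prow <- viol[rownames(sub)[viol[, 1]] == worst, , drop = FALSE][1, ]
    dropped <- rbind(dropped, data.frame(
      feature = worst, partner = colnames(sub)[prow[2]],
      r = unname(sub[prow[1], prow[2]]), stringsAsFactors = FALSE))
    retained <- setdiff(retained, worst)
  }
  if (!is.null(other_set)) retained <- intersect(retained, other_set)
  structure(list(correlation_matrix = cm,
                 dropped = dropped,
                 retained = retained,
                 normality_p = normality_p,
                 constant = constant,
                 threshold = threshold),
            class = "feature_selection_report")
}

#' @export
print.feature_selection_report <- function(x, ...) {
  cat("<feature_selection_report> threshold |r| >=", x$threshold, "\n")
  cat("  retained:", paste(x$retained, collapse = ", "), "\n")
  if (nrow(x$dropped))
    cat("  dropped :", paste(sprintf("%s (r=%.2f with %s)", x$dropped$feature,
                                     x$dropped$r, x$dropped$partner),
                             collapse = "; "), "\n")
  if (length(x$constant))
    cat("  constant (correlations undefined):",
        paste(x$constant, collapse = ", "), "\n")
  invisible(x)
}
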