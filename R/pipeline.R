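# End-to-end orchestration: simulate -> preprocess -> label -> (balance) ->
# forecast -> classify -> recommend -> export RDF -> query, with a seeded
# config and a content-hashed run manifest.

#' Build a pipeline run configuration
#'
#' Every stochastic stage receives an explicit seed derived from the master
#' seed; the config round-trips losslessly through YAML/JSON.
#'
#' @param seed Master RNG seed.
#' @param persona_class Persona level 0-4 used by the simulator.
#' @param days Number of simulated days (>= 21).
#' @param participant Pseudonymous participant id.
#' @param balance Run ADASYN balancing on the labeled table (default TRUE).
#' @param lag,window Base and residual AR orders for forecasting.
#' @param c Interval coverage constant (default 1.28, 80% nominal).
#' @param horizon Forecast horizon in days (default 7).
#' @param k ADASYN neighbour count.
#' @param target_score Weekly goal score (default 21).
#' @param model Classifier for the incremental weekly protocol.
#' @param override_week_levels Optional 7 predicted levels replacing the
#'   classifier's last-week output (used to replay a reference worked
#'   example).
#' @return List of class `run_config`.
#' @export
run_config <- function(seed = 1L, persona_class = 1L, days = 120L,
                       participant = "P-1", balance = TRUE, lag = 14L,
                       window = 5L, c = 1.28, horizon = 7L, k = 5L,
                       target_score = 21L, model = "gradient_boosting",
                       override_week_levels = NULL) {
  if (days < 21) stop("need at least 21 simulated days")
  structure(list(seed = as.integer(seed), persona_class = as.integer(persona_class),
                 days = as.integer(days), participant = participant,
                 balance = isTRUE(balance), lag = as.integer(lag),
                 window = as.integer(window), c = c, horizon = as.integer(horizon),
                 k = as.integer(k), target_score = as.integer(target_score),
                 model = model, override_week_levels = override_week_levels),
            class = "run_config")
}

#' Run the full eCoaching pipeline
#'
#' Executes the stages in order, writes every artifact under `out_dir`, and
#' returns a manifest listing each artifact with its MD5 content hash;
#' re-running with the same config reproduces all hashes.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory (created if needed).
#' @return The manifest (list), invisibly written as `manifest.json`.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  art <- list()
  put <- function(name, writer) {
    path <- file.path(out_dir, name)
    writer(path)
    art[[name]] <<- unname(tools::md5sum(path))
    path
  }
  # 1. simulate
  profile <- default_personas()[[as.character(config$persona_class)]]
  daily <- gen_daily_records(profile, config$days, seed = config$seed)
  put("daily.csv", function(p) utils::write.csv(daily, p, row.names = FALSE))
  # 2. preprocess: gap-fill steps, feature-selection report
  daily$steps <- fill_missing(daily$steps)
  fs <- select_features(daily[, c("sedentary_min", "lpa_min", "mpa_min",
                                  "vpa_min", "steps")])
  put("feature_selection.json", function(p) jsonlite::write_json(
    list(retained = fs$retained, dropped = fs$dropped), p, auto_unbox = TRUE))
  # 3. label
  labeled <- label_dataset(daily)
  put("labeled.csv", function(p) utils::write.csv(labeled, p, row.names = FALSE))
  # 4. balance (report only; classification below uses the raw history,
  # mirroring the per-participant incremental protocol)
  if (config$balance) {
    feats <- labeled[, c("sedentary_min", "lpa_min", "mpa_min", "vpa_min", "steps")]
    if (length(unique(labeled$activity_level)) > 1) {
      bal <- adasyn_resample(feats, labeled$activity_level, k = config$k,
                             seed = config$seed + 1L)
      put("balanced.csv", function(p) utils::write.csv(
        data.frame(bal$features, label = bal$labels, synthetic = bal$synthetic),
        p, row.names = FALSE))
    }
  }
  # 5. forecast next week's steps with residual-error correction
  fc <- rem_walk_forward(labeled$steps, lag = config$lag, window = config$window)
  sigma_h <- fc$metrics_corrected$rsd
  last_fc <- utils::tail(fc$corrected_forecast, config$horizon)
  intervals <- interval_forecast_table(last_fc, sigma_h = sigma_h, c = config$c)
  put("forecast.csv", function(p) utils::write.csv(intervals, p, row.names = FALSE))
  put("forecast_metrics.json", function(p) jsonlite::write_json(
    list(base = fc$metrics_base, corrected = fc$metrics_corrected,
         sigma_h = sigma_h), p, auto_unbox = TRUE, digits = NA))
  # 6. incremental weekly classification
  weekly <- incremental_weekly_predict(
    labeled, classifier_config(config$model, seed = config$seed + 2L))
  if (!is.null(config$override_week_levels)) {
    weekly$predicted_levels <- as.integer(config$override_week_levels)
    weekly$predicted_scores <- weekly$predicted_levels
    weekly$agreement <- sum(weekly$predicted_levels == weekly$actual_levels)
    weekly$score_difference <- sum(weekly$actual_scores) - sum(weekly$predicted_scores)
  }
  # 7. weekly report + recommendation
  pref <- preference(target_score = config$target_score)
  report <- build_weekly_report(weekly$predicted_levels, pref,
                                forecast = intervals$point)
  rec <- render_recommendation(report)
  put("weekly_report.json", function(p) jsonlite::write_json(
    list(daily_levels = report$daily_levels, achieved = report$achieved,
         goal = report$goal, difference = report$difference,
         fired_variables = report$fired_variables,
         weekly_messages = report$weekly_messages,
         formal = rec$formal, informal = rec$informal, emoji = rec$emoji),
    p, auto_unbox = TRUE))
  # 8. export RDF
  graph <- build_graph(
    participants = config$participant,
    preferences = stats::setNames(list(pref), config$participant),
    labeled_days = data.frame(participant = config$participant,
                              date = utils::tail(labeled$date, 7),
                              level = report$daily_levels),
    forecasts = data.frame(participant = config$participant,
                           day = intervals$day, point = intervals$point,
                           lower = intervals$lower, upper = intervals$upper),
    recommendations = data.frame(participant = config$participant,
                                 message_id = report$weekly_messages,
                                 date = as.character(max(labeled$date))))
  put("graph.ttl", function(p) write_graph(graph, p))
  # 9. query back the delivered messages
  qr <- run_query(graph, sprintf(
    "SELECT ?msg WHERE { sc:%s sc:hasReceivedRecommendation ?r . ?r sc:messageId ?msg . } ORDER BY ?msg",
    config$participant))
  manifest <- list(
    config = unclass(config),
    artifacts = art,
    metrics = list(
      achieved = report$achieved, goal = report$goal,
      difference = report$difference,
      weekly_messages = report$weekly_messages,
      queried_messages = sub('^"(.*)"$', "\\1", sort(qr$msg)),
      agreement = weekly$agreement,
      score_difference = weekly$score_difference,
      rmse_base = fc$metrics_base$rmse,
      rmse_corrected = fc$metrics_corrected$rmse))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
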