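# Shared fixtures and independent oracles, built in code.

# Brute-force evaluator of the activity-level rules: evaluates every
# level's disjunction literally and independently of classify_day, returning
# the maximum satisfied level.
brute_force_level <- function(steps, lpa, mpa, vpa) {
  w <- (vpa * 2 + mpa) * 7
  sat <- c(
    ((steps < 5000) && (w < 90) && (lpa >= 0)) || (steps < 5000),
    ((steps > 4999) && (w >= 90) && (w < 210)) || (steps > 4999 && steps < 7500),
    ((steps > 4999) && (w >= 210) && (w < 300)) || (steps > 7499 && steps < 10000),
    ((steps > 4999) && (w >= 300) && (w < 360)) || (steps > 9999 && steps < 12500),
    ((steps > 4999) && (w >= 360)) || (steps > 12499))
  max(c(0L, which(sat) - 1L))
}

# Brute-force binary confusion-matrix metrics straight from the textbook
# formulas (per-class one-vs-rest), on the 0-100 scale.
brute_force_binary <- function(tp, fp, fn, tn) {
  list(accuracy = 100 * (tp + tn) / (tp + fp + fn + tn),
       precision = 100 * tp / (tp + fp),
       recall = 100 * tp / (tp + fn),
       specificity = 100 * tn / (tn + fp),
       f1 = 100 * (2 * (tp / (tp + fp)) * (tp / (tp + fn))) /
         ((tp / (tp + fp)) + (tp / (tp + fn))),
       mcc = 100 * (tp * tn - fp * fn) /
         sqrt((tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)))
}

# A small deterministic labeled data set whose features encode the label
# noise-free (for classifier sanity checks).
noise_free_days <- function(n, levels_seq = NULL, seed = 42) {
  stepcoach:::local_seed(seed, {
    lv <- levels_seq %||% sample(0:4, n, replace = TRUE)
    step_mid <- c(3000, 6200, 8700, 11200, 14000)[lv + 1]
    t_mid <- c(6, 21, 36, 47, 60)[lv + 1]
    data.frame(sedentary = 1200 - t_mid, lpa = 100, mpa = t_mid, vpa = 0,
               steps = step_mid, activity_level = lv)
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

table18_levels <- c(1L, 1L, 3L, 2L, 1L, 1L, 1L)
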