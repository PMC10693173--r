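# Rule evaluation, mutual-exclusivity verification, weekly scoring, and
# message rendering.

toy_rules <- function(rules, daily_ids) {
  vars <- data.frame(id = unique(c(daily_ids, unlist(lapply(rules, function(r)
    c(r$consequent, r$else_consequent))))),
    description = "", daily = FALSE, stringsAsFactors = FALSE)
  vars$daily <- vars$id %in% daily_ids
  guard <- list(id = "G", antecedent = "TRUE", consequent = "guard",
                rule_class = "satisfiability")
  rule_set(c(rules, list(guard)), vars)
}

test_that("rules fire along the decision tree with a trace", {
  rs <- toy_rules(list(list(id = "r1", antecedent = "A", consequent = "M1"),
                       list(id = "r2", antecedent = "NOT A", consequent = "M2")),
                  daily_ids = c("M1", "M2"))
  ev <- evaluate_ruleset(list(A = TRUE), rs)
  expect_equal(ev$fired, "M1")
  expect_true(ev$guard_ok)
  expect_equal(ev$trace$value[ev$trace$rule == "r1"], TRUE)
  ev2 <- evaluate_ruleset(list(A = FALSE), rs)
  expect_equal(ev2$fired, "M2")
  expect_error(evaluate_ruleset(list(), rs), "unassigned variable.*A")
})

test_that("the expression grammar covers NOT/AND/OR/IMPLIES/EQUIV", {
  rs <- toy_rules(list(list(id = "r", antecedent = "(A IMPLIES B) EQUIV (NOT A OR B)",
                            consequent = "M")), daily_ids = character())
  for (a in c(TRUE, FALSE)) for (b in c(TRUE, FALSE))
    expect_equal(evaluate_ruleset(list(A = a, B = b), rs)$fired, "M")
  expect_error(stepcoach:::parse_expr("A AND"), "unexpected end")
  expect_error(rule_set(list(list(id = "x", antecedent = "A ++ B",
                                  consequent = "M",
                                  rule_class = "satisfiability")),
                        data.frame(id = "A", description = "", daily = FALSE)),
               "bad characters")
})

test_that("mutually exclusive daily triggers pass, independent ones fail", {
  ok <- toy_rules(list(list(id = "r1", antecedent = "A", consequent = "M1"),
                       list(id = "r2", antecedent = "NOT A", consequent = "M2")),
                  daily_ids = c("M1", "M2"))
  v <- verify_exclusivity(ok)
  expect_true(v$satisfiable)
  expect_null(v$witness)
  bad <- toy_rules(list(list(id = "r1", antecedent = "A", consequent = "M1"),
                        list(id = "r2", antecedent = "B", consequent = "M2")),
                   daily_ids = c("M1", "M2"))
  v2 <- verify_exclusivity(bad)
  expect_false(v2$satisfiable)
  expect_true(all(v2$witness[c("A", "B")]))
})

test_that("the shipped rule set never fires two once-a-day messages", {
  v <- verify_exclusivity(default_ruleset())
  expect_true(v$satisfiable)
  expect_equal(v$n_assignments, 2^9)
  # replay: every guard-passing assignment fires at most one daily message
  rs <- default_ruleset()
  daily <- rs$variables$id[rs$variables$daily]
  vars <- c("A-2", "A-3", "A-4", "A-5", "A-6", "A-8", "A-9", "A-13", "A-17")
  for (mask in 0:(2^9 - 1)) {
    bits <- as.logical(bitwAnd(bitwShiftR(mask, 0:8), 1L))
    ev <- evaluate_ruleset(setNames(as.list(bits), vars), rs)
    if (ev$guard_ok) expect_lte(length(intersect(ev$fired, daily)), 1)
  }
})

test_that("daily evaluation of an all-false assignment hits the default leaf", {
  rs <- default_ruleset()
  facts <- setNames(as.list(rep(FALSE, 9)),
                    c("A-2", "A-3", "A-4", "A-5", "A-6", "A-8", "A-9",
                      "A-13", "A-17"))
  ev <- evaluate_ruleset(facts, rs, scope = "daily")
  expect_equal(ev$fired, "A-15")
})

test_that("the weekly report reproduces the worked week", {
  rep <- build_weekly_report(table18_levels, preference(target_score = 21),
                             forecast = rep(6000, 7))
  expect_equal(rep$achieved, 10)
  expect_equal(rep$goal, 21)
  expect_equal(rep$difference, 11)
  expect_equal(rep$weekly_messages, c("A-17", "A-13"))
  expect_equal(rep$fired_variables[[1]], c("A-2", "A-6", "A-8", "A-10", "A-15"))
  expect_equal(rep$fired_variables[[3]], c("A-4", "A-6", "A-9", "A-11", "A-14"))
  expect_equal(rep$fired_variables[[4]], c("A-3", "A-6", "A-8", "A-10", "A-15"))
  expect_equal(rep$emoji, "☹")
})

test_that("weekly scoring is order-invariant and complementary to the goal", {
  set.seed(61)
  for (i in 1:10) {
    wk <- sample(0:4, 7, replace = TRUE)
    r1 <- build_weekly_report(wk)
    r2 <- build_weekly_report(sample(wk))
    expect_equal(r1$achieved, sum(wk))            # independent re-sum
    expect_equal(r1$achieved, r2$achieved)
    expect_equal(r1$difference + r1$achieved, r1$goal)
    expect_true(r1$achieved >= 0 && r1$achieved <= 28)
  }
  # goal met: single congratulatory weekly outcome with the happy face
  all3 <- build_weekly_report(rep(3, 7))
  expect_equal(all3$achieved, 21)
  expect_equal(all3$difference, 0)
  expect_equal(all3$weekly_messages, "A-16")
  expect_equal(all3$emoji, "\U0001F60A")
  expect_error(build_weekly_report(rep(3, 6)), "7 days")
})

test_that("rendering fills templates strictly and carries the emoji", {
  rep <- build_weekly_report(table18_levels, preference(), rep(6000, 7))
  out <- render_recommendation(rep)
  expect_match(out$formal, "11 points behind")
  expect_match(out$informal, "☹")
  expect_setequal(out$message_ids, c("A-17", "A-13"))
  # unknown message id
  kb <- default_message_kb(); kb[["A-13"]] <- NULL
  expect_error(render_recommendation(rep, kb), "missing from the knowledge base")
  # unresolved placeholder is an error, not silent omission
  kb2 <- default_message_kb()
  kb2[["A-17"]]$formal <- "Deficit {deficit}, unknown {nope}"
  expect_error(render_recommendation(rep, kb2), "unresolved placeholder")
})

test_that("rule sets and preferences round-trip through YAML", {
  rs <- default_ruleset()
  path <- tempfile(fileext = ".yaml")
  doc <- list(
    variables = lapply(seq_len(nrow(rs$variables)), function(i)
      as.list(rs$variables[i, ])),
    rules = lapply(rs$rules, function(r)
      r[intersect(names(r), c("id", "antecedent", "consequent",
                              "else_consequent", "rule_class", "scope"))]))
  yaml::write_yaml(doc, path)
  rs2 <- ruleset_load(path)
  expect_equal(length(rs2$rules), length(rs$rules))
  expect_true(verify_exclusivity(rs2)$satisfiable)
  ppath <- tempfile(fileext = ".yaml")
  yaml::write_yaml(list(target_score = 28, nature_of_goal = "personalized"), ppath)
  pref <- preference_load(ppath)
  expect_equal(pref$target_score, 28L)
})
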