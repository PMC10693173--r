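# Rule-based personalized recommendation layer: a propositional knowledge
# base (variables, IF -> THEN rules, message templates), rule evaluation
# over a binary decision tree, an exhaustive mutual-exclusivity verifier
# for "once a day" messages, weekly goal scoring, and message rendering.

## ---- propositional expression parser ------------------------------------

# Tokens: identifiers (letters, digits, '_' and '-', e.g. A-17), the
# operators NOT/AND/OR/IMPLIES/EQUIV, parentheses, and the literals
# TRUE/FALSE.  Precedence (loosest first): EQUIV, IMPLIES, OR, AND, NOT.
.tokenize_expr <- function(text) {
  pat <- "\\(|\\)|[A-Za-z][A-Za-z0-9_-]*"
  m <- gregexpr(pat, text)[[1]]
  if (m[1] == -1) stop("empty antecedent expression")
  toks <- regmatches(text, gregexpr(pat, text))[[1]]
  rest <- gsub(pat, "", text)
  if (grepl("[^[:space:]]", rest))
    stop("bad characters in expression: ", text)
  toks
}

parse_expr <- function(text) {
  toks <- .tokenize_expr(text)
  pos <- 1L
  peek <- function() if (pos <= length(toks)) toks[pos] else NA_character_
  take <- function() { t <- peek(); pos <<- pos + 1L; t }
  expect <- function(t) if (!identical(take(), t))
    stop("expected '", t, "' in expression: ", text)
  p_primary <- function() {
    t <- take()
    if (is.na(t)) stop("unexpected end of expression: ", text)
    if (t == "(") { e <- p_equiv(); expect(")"); return(e) }
    if (t == "NOT") return(list(op = "not", x = p_primary()))
    if (toupper(t) %in% c("TRUE", "FALSE"))
      return(list(op = "const", value = toupper(t) == "TRUE"))
    if (t %in% c("AND", "OR", "IMPLIES", "EQUIV", ")"))
      stop("misplaced '", t, "' in expression: ", text)
    list(op = "var", name = t)
  }
  p_and <- function() {
    e <- p_primary()
    while (identical(peek(), "AND")) { take(); e <- list(op = "and", x = e, y = p_primary()) }
    e
  }
  p_or <- function() {
    e <- p_and()
    while (identical(peek(), "OR")) { take(); e <- list(op = "or", x = e, y = p_and()) }
    e
  }
  p_implies <- function() {
    e <- p_or()
    if (identical(peek(), "IMPLIES")) { take(); e <- list(op = "implies", x = e, y = p_implies()) }
    e
  }
  p_equiv <- function() {
    e <- p_implies()
    while (identical(peek(), "EQUIV")) { take(); e <- list(op = "equiv", x = e, y = p_implies()) }
    e
  }
  out <- p_equiv()
  if (!is.na(peek())) stop("trailing tokens in expression: ", text)
  out
}

eval_expr <- function(ast, facts) {
  switch(ast$op,
    const = ast$value,
    var = {
      if (!ast$name %in% names(facts))
        stop("unassigned variable in antecedent: ", ast$name)
      isTRUE(facts[[ast$name]])
    },
    not = !eval_expr(ast$x, facts),
    and = eval_expr(ast$x, facts) && eval_expr(ast$y, facts),
    or = eval_expr(ast$x, facts) || eval_expr(ast$y, facts),
    implies = !eval_expr(ast$x, facts) || eval_expr(ast$y, facts),
    equiv = eval_expr(ast$x, facts) == eval_expr(ast$y, facts),
    stop("unknown operator: ", ast$op))
}

expr_vars <- function(ast) {
  switch(ast$op,
    const = character(0),
    var = ast$name,
    not = expr_vars(ast$x),
    unique(c(expr_vars(ast$x), expr_vars(ast$y))))
}

## ---- rule sets and message KB -------------------------------------------

#' Construct a rule set
#'
#' @param rules List of rules; each rule is a list with `id`, `antecedent`
#'   (expression string over propositional variables using
#'   NOT/AND/OR/IMPLIES/EQUIV), `consequent` (message id fired when the
#'   antecedent is true), optional `else_consequent` (fired on the false
#'   edge of the decision node), `rule_class` (`"activity_level"` or
#'   `"satisfiability"`), and optional `scope` (`"daily"` or `"weekly"`).
#' @param variables Data frame with columns `id`, `description`, `daily`
#'   (logical: is the variable's message a "once a day" message).
#' @return Object of class `rule_set`.  Exactly one satisfiability guard
#'   rule is required: when its antecedent is false the whole rule set
#'   evaluates to false and no message fires.
#' @export
rule_set <- function(rules, variables) {
  stopifnot(is.list(rules), is.data.frame(variables),
            all(c("id", "description", "daily") %in% names(variables)))
  if (anyDuplicated(variables$id)) stop("variable ids must be unique")
  cls <- vapply(rules, function(r) r$rule_class %||% "activity_level", character(1))
  if (sum(cls == "satisfiability") != 1)
    stop("a rule set must contain exactly one satisfiability guard rule")
  rules <- lapply(rules, function(r) {
    r$ast <- parse_expr(r$antecedent)
    r$rule_class <- r$rule_class %||% "activity_level"
    r$scope <- r$scope %||% "weekly"
    r
  })
  structure(list(rules = rules, variables = variables), class = "rule_set")
}

#' @export
print.rule_set <- function(x, ...) {
  n_act <- sum(vapply(x$rules, function(r) r$rule_class, character(1)) == "activity_level")
  cat("<rule_set>", n_act, "activity-level rules + 1 satisfiability guard;",
      nrow(x$variables), "variables\n")
  invisible(x)
}

#' Load a rule set from YAML
#'
#' The file must contain a `variables` list (`id`, `description`, `daily`)
#' and a `rules` list (`id`, `antecedent`, `consequent`, optional
#' `else_consequent`, `rule_class`, `scope`).
#'
#' @param path YAML file path.
#' @return A [rule_set()].
#' @export
ruleset_load <- function(path) {
  doc <- yaml::read_yaml(path)
  vars <- do.call(rbind, lapply(doc$variables, function(v)
    data.frame(id = v$id, description = v$description %||% "",
               daily = isTRUE(v$daily), stringsAsFactors = FALSE)))
  rule_set(doc$rules, vars)
}

#' The package's default rule set
#'
#' Fourteen propositional variables (`A-2` .. `A-17`) drive seven
#' activity-level rules and one satisfiability guard.  Per day: `A-2`/`A-3`/
#' `A-4`/`A-5` mark a low-active/active/medium-active/highly-active day,
#' `A-6` a non-sedentary day, `A-8`/`A-9` a daily score below / at-or-above
#' the medium-active target, and `A-10`/`A-11` the matching
#' needs-improvement / on-pace flags.  The two "once a day" messages are
#' `A-15` (increase activity) and `A-14` (keep it up).  Weekly, `A-17`
#' (goal missed; its false edge fires `A-16`, goal achieved) and `A-13`
#' (next-week step forecast below goal pace) select the weekly messages.
#' The guard asserts the mutual exclusivity of the daily triggers:
#' `NOT (A-8 AND A-9) AND NOT (A-9 AND NOT A-6)`.
#'
#' @return A [rule_set()].
#' @export
default_ruleset <- function() {
  variables <- data.frame(
    id = c("A-2", "A-3", "A-4", "A-5", "A-6", "A-8", "A-9", "A-10", "A-11",
           "A-13", "A-14", "A-15", "A-16", "A-17"),
    description = c(
      "low-active day", "active day", "medium-active day",
      "highly-active day", "non-sedentary day (step threshold met)",
      "daily score below the medium-active target",
      "daily score at or above the medium-active target",
      "daily pace needs improvement", "daily pace on target",
      "next-week step forecast below the weekly goal pace",
      "once a day: keep up the good work",
      "once a day: move more today",
      "weekly goal achieved", "weekly goal missed"),
    daily = c(rep(FALSE, 9), FALSE, TRUE, TRUE, FALSE, FALSE),
    stringsAsFactors = FALSE)
  rules <- list(
    list(id = "R-1", antecedent = "NOT A-6", consequent = "A-15",
         scope = "daily"),
    list(id = "R-2", antecedent = "A-2 AND A-8", consequent = "A-15",
         scope = "daily"),
    list(id = "R-3", antecedent = "A-3 AND A-8", consequent = "A-15",
         scope = "daily"),
    list(id = "R-4", antecedent = "A-4 AND A-9", consequent = "A-14",
         scope = "daily"),
    list(id = "R-5", antecedent = "A-5 AND A-9", consequent = "A-14",
         scope = "daily"),
    list(id = "R-6", antecedent = "A-17", consequent = "A-17",
         else_consequent = "A-16", scope = "weekly"),
    list(id = "R-7", antecedent = "A-13", consequent = "A-13",
         scope = "weekly"),
    list(id = "R-8", rule_class = "satisfiability", scope = "guard",
         antecedent = "NOT (A-8 AND A-9) AND NOT (A-9 AND NOT A-6)",
         consequent = "guard"))
  rule_set(rules, variables)
}

#' Evaluate a rule set over a truth assignment
#'
#' Rules are walked as a binary decision tree: each internal node tests one
#' antecedent, its True edge fires the consequent, its False edge fires the
#' `else_consequent` when one is defined.  The satisfiability guard is
#' evaluated first: when false, the entire rule set is false and nothing
#' fires.
#'
#' @param facts Named logical list/vector assigning every variable used in
#'   the evaluated antecedents; an unassigned variable is an error naming it.
#' @param rules A [rule_set()].
#' @param scope `"all"`, `"daily"` or `"weekly"` -- which rules to walk.
#' @return List with `fired` (message ids in rule order), `guard_ok`, and
#'   `trace` (data frame: rule id, antecedent, value, fired message).
#' @export
evaluate_ruleset <- function(facts, rules, scope = c("all", "daily", "weekly")) {
  scope <- match.arg(scope)
  stopifnot(inherits(rules, "rule_set"))
  facts <- as.list(facts)
  guard <- Filter(function(r) r$rule_class == "satisfiability", rules$rules)[[1]]
  guard_ok <- eval_expr(guard$ast, facts)
  trace <- data.frame(rule = guard$id, antecedent = guard$antecedent,
                      value = guard_ok, fired = NA_character_,
                      stringsAsFactors = FALSE)
  fired <- character(0)
  if (guard_ok) {
    for (r in rules$rules) {
      if (r$rule_class == "satisfiability") next
      if (scope != "all" && r$scope != scope) next
      v <- eval_expr(r$ast, facts)
      hit <- if (v) r$consequent else r$else_consequent %||% NA_character_
      if (!is.na(hit)) fired <- c(fired, hit)
      trace <- rbind(trace, data.frame(rule = r$id, antecedent = r$antecedent,
                                       value = v, fired = hit,
                                       stringsAsFactors = FALSE))
    }
  }
  list(fired = unique(fired), guard_ok = guard_ok, trace = trace)
}

#' Verify that two "once a day" messages can never fire together
#'
#' Exhaustively enumerates all `2^|V|` assignments of the variables used in
#' the rule antecedents (refusing beyond 24 variables).  Assignments that
#' falsify the satisfiability guard disable the whole rule set and fire
#' nothing; among guard-passing assignments, any one firing two or more
#' distinct daily messages is a counterexample and is returned as a witness.
#'
#' @param rules A [rule_set()].
#' @return List with `satisfiable` (`TRUE` when exclusivity holds),
#'   `witness` (a named logical assignment, or `NULL`), and `n_assignments`.
#' @export
verify_exclusivity <- function(rules) {
  stopifnot(inherits(rules, "rule_set"))
  vars <- sort(unique(unlist(lapply(rules$rules, function(r) expr_vars(r$ast)))))
  if (length(vars) > 24)
    stop("more than 24 variables; exhaustive enumeration refused ",
         "(use sampled checking, which is incomplete)")
  daily_msgs <- rules$variables$id[rules$variables$daily]
  n <- length(vars)
  for (mask in 0:(2^n - 1)) {
    bits <- as.logical(bitwAnd(bitwShiftR(mask, 0:(n - 1)), 1L))
    facts <- stats::setNames(as.list(bits), vars)
    ev <- evaluate_ruleset(facts, rules, scope = "all")
    if (!ev$guard_ok) next
    if (length(intersect(ev$fired, daily_msgs)) >= 2)
      return(list(satisfiable = FALSE,
                  witness = stats::setNames(bits, vars),
                  n_assignments = 2^n))
  }
  list(satisfiable = TRUE, witness = NULL, n_assignments = 2^n)
}

## ---- preferences, weekly report, rendering ------------------------------

#' Personal recommendation preferences
#'
#' Defaults follow the generic weekly goal for adults: stay medium active
#' (score 3) every day of the week, i.e. a target score of 21.
#'
#' @param goal_setting Scoring period (default `"weekly"`).
#' @param nature_of_goal `"generic_WHO"` or `"personalized"`.
#' @param frequency Delivery cadence.
#' @param target_goal Free-text goal description.
#' @param target_score Integer weekly goal score (>= 0; 21 = medium active
#'   all week).
#' @param mode Delivery channel.
#' @param delivery_time Clock time of delivery.
#' @return Object of class `preference`.
#' @export
preference <- function(goal_setting = "weekly",
                       nature_of_goal = c("generic_WHO", "personalized"),
                       frequency = "weekly",
                       target_goal = "Stay medium active for the entire week",
                       target_score = 21L,
                       mode = "push_notification",
                       delivery_time = "08:00") {
  nature_of_goal <- match.arg(nature_of_goal)
  if (target_score < 0) stop("target_score must be >= 0")
  structure(list(goal_setting = goal_setting, nature_of_goal = nature_of_goal,
                 frequency = frequency, target_goal = target_goal,
                 target_score = as.integer(target_score), mode = mode,
                 delivery_time = delivery_time), class = "preference")
}

#' Load preferences from a YAML or JSON file
#'
#' @param path File path (`.yaml`/`.yml` or `.json`).
#' @return A [preference()].
#' @export
preference_load <- function(path) {
  doc <- if (grepl("\\.json$", path)) jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  do.call(preference, doc)
}

# Truth assignment for one day's activity level.
.day_facts <- function(level) {
  list(`A-2` = level == 1, `A-3` = level == 2, `A-4` = level == 3,
       `A-5` = level == 4, `A-6` = level >= 1,
       `A-8` = level < 3, `A-9` = level >= 3,
       `A-10` = level < 3, `A-11` = level >= 3,
       `A-13` = FALSE, `A-17` = FALSE)
}

# Weekly score implied by a 7-day step forecast: each forecast day is
# levelled on steps alone.
.forecast_weekly_score <- function(points) sum(classify_day(pmax(0, points)))

#' Build the weekly goal report
#'
#' Sums the seven daily scores, compares against the preference's target
#' score, assigns each day's propositional variables and "once a day"
#' message via the daily rules, sets the weekly variables (`A-17` = goal
#' missed; `A-13` = the step forecast for the coming week, levelled on
#' steps alone, sums below the goal), and fires the weekly rules.  The
#' emoji follows the weekly outcome: `difference <= 0` gives the happy
#' face, a deficit up to `ceiling(goal / 3)` the neutral face, and a larger
#' deficit the sad face.
#'
#' @param week Seven predicted daily levels: an integer vector in 0..4 or a
#'   labeled data frame with an `activity_level` column.
#' @param pref A [preference()].
#' @param forecast Optional numeric vector of next-week daily step point
#'   forecasts (or a data frame with a `point` column).
#' @param rules A [rule_set()] (default [default_ruleset()]).
#' @return Object of class `weekly_report`: `daily_levels`, `daily_scores`,
#'   `achieved`, `goal`, `difference`, `fired_variables` (per day),
#'   `daily_messages`, `weekly_messages`, `emoji`.
#' @export
build_weekly_report <- function(week, pref = preference(), forecast = NULL,
                                rules = default_ruleset()) {
  levels <- if (is.data.frame(week)) week$activity_level else week
  levels <- as.integer(levels)
  if (length(levels) != 7) stop("a weekly report needs exactly 7 days")
  if (any(levels < 0 | levels > 4)) stop("levels must be in 0..4")
  achieved <- sum(levels)
  goal <- pref$target_score
  difference <- goal - achieved
  daily_msgs <- character(7); fired_vars <- vector("list", 7)
  for (d in 1:7) {
    facts <- .day_facts(levels[d])
    ev <- evaluate_ruleset(facts, rules, scope = "daily")
    daily_msgs[d] <- if (length(ev$fired)) ev$fired[1] else NA_character_
    truth <- names(facts)[vapply(facts, isTRUE, logical(1))]
    fired_vars[[d]] <- c(truth, ev$fired)
  }
  fc_points <- if (is.data.frame(forecast)) forecast$point else forecast
  weekly_facts <- list(`A-17` = achieved < goal,
                       `A-13` = !is.null(fc_points) &&
                         .forecast_weekly_score(fc_points) < goal,
                       `A-6` = TRUE, `A-8` = FALSE, `A-9` = FALSE)
  evw <- evaluate_ruleset(weekly_facts, rules, scope = "weekly")
  emoji <- if (difference <= 0) "\U0001F60A"
  else if (difference <= ceiling(goal / 3)) "\U0001F610" else "☹"
  structure(list(daily_levels = levels, daily_scores = levels,
                 achieved = achieved, goal = goal, difference = difference,
                 fired_variables = fired_vars, daily_messages = daily_msgs,
                 weekly_messages = evw$fired, emoji = emoji,
                 preference = pref), class = "weekly_report")
}

#' @export
print.weekly_report <- function(x, ...) {
  nm <- activity_level_names()
  cat("<weekly_report>\n")
  for (d in 1:7)
    cat(sprintf("  Day-%d: %-13s score %d   [%s]\n", d,
                nm[as.character(x$daily_levels[d])], x$daily_scores[d],
                paste(x$fired_variables[[d]], collapse = ", ")))
  cat(sprintf("  achieved %d / goal %d (difference %d)  weekly: %s %s\n",
              x$achieved, x$goal, x$difference,
              paste(x$weekly_messages, collapse = ", "), x$emoji))
  invisible(x)
}

#' The default recommendation message knowledge base
#'
#' Formal and informal templates per message id, with `{placeholders}`
#' resolved at render time (`deficit`, `goal`, `achieved`, `emoji`).
#'
#' @return Named list of message entries (`formal`, `informal`).
#' @export
default_message_kb <- function() {
  list(
    `A-13` = list(
      formal = "Your step forecast for the coming week is below your goal pace. Plan extra activity next week.",
      informal = "Aim a little higher next week! {emoji}"),
    `A-14` = list(
      formal = "You reached the daily activity target today. Keep it up.",
      informal = "Great job today! {emoji}"),
    `A-15` = list(
      formal = "You are below the daily activity target today. Try to move more.",
      informal = "Time to move a little more! {emoji}"),
    `A-16` = list(
      formal = "Congratulations! You reached your weekly goal of {goal} points with {achieved} points.",
      informal = "Well done! {emoji}"),
    `A-17` = list(
      formal = "You are {deficit} points behind to reach your weekly goal. Work hard on the following week.",
      informal = "Improve your performance to meet the goal! {emoji}"))
}

#' Load a message knowledge base from YAML
#'
#' @param path YAML file mapping message ids to `formal`/`informal` texts.
#' @return Named list usable by [render_recommendation()].
#' @export
message_kb_load <- function(path) yaml::read_yaml(path)

# Strict template substitution: every placeholder must resolve and none may
# remain.
.render_template <- function(template, values) {
  out <- template
  for (k in names(values))
    out <- gsub(paste0("{", k, "}"), as.character(values[[k]]), out, fixed = TRUE)
  left <- regmatches(out, gregexpr("\\{[A-Za-z_]+\\}", out))[[1]]
  if (length(left))
    stop("unresolved placeholder(s) in message template: ",
         paste(left, collapse = ", "))
  out
}

#' Render the weekly recommendation texts
#'
#' The weekly outcome message (`A-16` or `A-17`) provides the single formal
#' and informal weekly message; any further fired weekly messages (e.g. the
#' forecast advisory `A-13`) are appended to the `messages` table.
#'
#' @param report A [build_weekly_report()] result.
#' @param kb Message knowledge base (default [default_message_kb()]).
#' @return List with `formal`, `informal`, `emoji`, `message_ids`, and a
#'   `messages` data frame (id, formal, informal).
#' @export
render_recommendation <- function(report, kb = default_message_kb()) {
  stopifnot(inherits(report, "weekly_report"))
  ids <- report$weekly_messages
  missing <- setdiff(ids, names(kb))
  if (length(missing))
    stop("message id(s) missing from the knowledge base: ",
         paste(missing, collapse = ", "))
  vals <- list(deficit = max(report$difference, 0), goal = report$goal,
               achieved = report$achieved, emoji = report$emoji)
  outcome <- intersect(c("A-17", "A-16"), ids)[1]
  if (is.na(outcome)) stop("no weekly outcome message fired")
  msgs <- do.call(rbind, lapply(ids, function(id) data.frame(
    id = id,
    formal = .render_template(kb[[id]]$formal, vals),
    informal = .render_template(kb[[id]]$informal, vals),
    stringsAsFactors = FALSE)))
  list(formal = msgs$formal[msgs$id == outcome],
       informal = msgs$informal[msgs$id == outcome],
       emoji = report$emoji, message_ids = ids, messages = msgs)
}
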