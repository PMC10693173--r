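# RDF knowledge graph: participants, preferences, daily activity levels,
# step predictions and recommendations as triples, with closed-world
# constraint validation against the property schema, Turtle persistence,
# and a SPARQL engine supporting SELECT / ASK / CONSTRUCT basic graph
# patterns with ORDER BY and DISTINCT.
#
# No RDF triple-store package is available in this R stack, so the store,
# the Turtle reader/writer (covering the subset the package emits) and the
# query engine are implemented here.  Terms are kept in prefixed (CURIE)
# form internally and expanded against the prefix map for matching.

.PREFIXES <- c(
  sc = "http://stepcoach.org/ns#",
  rdf = "http://www.w3.org/1999/02/22-rdf-syntax-ns#",
  rdfs = "http://www.w3.org/2000/01/rdf-schema#",
  owl = "http://www.w3.org/2002/07/owl#",
  xsd = "http://www.w3.org/2001/XMLSchema#")

.expand_term <- function(term, prefixes = .PREFIXES) {
  vapply(term, function(t) {
    if (grepl("^<.*>$", t)) return(substr(t, 2, nchar(t) - 1))
    m <- regmatches(t, regexec("^([A-Za-z][A-Za-z0-9_]*):(.*)$", t))[[1]]
    if (length(m) == 3 && m[2] %in% names(prefixes))
      return(paste0(prefixes[[m[2]]], m[3]))
    t
  }, character(1), USE.NAMES = FALSE)
}

#' Create an (optionally pre-populated) RDF graph
#'
#' Triples are stored as a data frame with `subject`, `predicate`, `object`
#' and a `literal` flag; IRIs use prefixed names against the built-in
#' prefix map (`sc:`, `rdf:`, `rdfs:`, `owl:`, `xsd:`).
#'
#' @param triples Optional data frame with columns `subject`, `predicate`,
#'   `object`, `literal`.
#' @return Object of class `rdf_graph`.
#' @export
rdf_graph <- function(triples = NULL) {
  if (is.null(triples))
    triples <- data.frame(subject = character(), predicate = character(),
                          object = character(), literal = logical(),
                          stringsAsFactors = FALSE)
  stopifnot(all(c("subject", "predicate", "object", "literal") %in% names(triples)))
  triples <- unique(triples[, c("subject", "predicate", "object", "literal")])
  rownames(triples) <- NULL
  structure(list(triples = triples, prefixes = .PREFIXES), class = "rdf_graph")
}

#' @export
print.rdf_graph <- function(x, ...) {
  cat("<rdf_graph>", nrow(x$triples), "triples,",
      length(unique(x$triples$subject)), "subjects\n")
  invisible(x)
}

#' Number of triples in a graph
#' @param graph An `rdf_graph`.
#' @return Integer count.
#' @export
graph_size <- function(graph) nrow(graph$triples)

.add <- function(df, s, p, o, literal = FALSE) {
  rbind(df, data.frame(subject = s, predicate = p, object = o,
                       literal = literal, stringsAsFactors = FALSE))
}

#' The ontology class tree and property schema
#'
#' Classes hang directly under `owl:Thing` (a connected, acyclic, directed
#' tree); properties carry domain, range and a restriction kind among
#' Some (existential), Only (universal), Min, Exact and Max cardinality.
#'
#' @return `schema_graph()`: an `rdf_graph` of class/property declarations.
#' @export
schema_graph <- function() {
  classes <- c("Participant", "HealthRecord", "PersonalData", "Preferences",
               "Recommendation", "ParticipantStatus", "ActivityData",
               "ActivityDataValue", "TemporalEntity", "ActivityDevice",
               "MeasurementCapability", "SensorOutput", "Property",
               "Stimulus", "Observation", "FeatureOfInterest", "Sensor",
               "Questionnaire", "StepPrediction", "ActivityLevelDaily")
  df <- rdf_graph()$triples
  for (cl in classes) {
    df <- .add(df, paste0("sc:", cl), "rdf:type", "owl:Class")
    df <- .add(df, paste0("sc:", cl), "rdfs:subClassOf", "owl:Thing")
  }
  spec <- property_specs()
  for (i in seq_len(nrow(spec))) {
    p <- paste0("sc:", spec$property[i])
    df <- .add(df, p, "rdf:type", "owl:ObjectProperty")
    df <- .add(df, p, "rdfs:domain", paste0("sc:", spec$domain[i]))
    df <- .add(df, p, "rdfs:range", paste0("sc:", spec$range[i]))
  }
  rdf_graph(df)
}

#' Object-property schema: domain, range, restriction kind, cardinality
#'
#' @return Data frame with columns `property`, `domain`, `range`,
#'   `restriction` (Some/Only/Min/Exact/Max), `cardinality` (`NA` unless a
#'   cardinality restriction).
#' @export
property_specs <- function() {
  s <- function(p, d, r, k = "Some", n = NA_integer_)
    data.frame(property = p, domain = d, range = r, restriction = k,
               cardinality = n, stringsAsFactors = FALSE)
  rbind(
    s("hasHealthRecord", "Participant", "HealthRecord"),
    s("hasPersonalData", "Participant", "PersonalData"),
    s("hasPreferences", "Participant", "Preferences"),
    s("hasReceivedRecommendation", "Participant", "Recommendation"),
    s("hasStatus", "Participant", "ParticipantStatus"),
    s("hasBeenCollectedBy", "ActivityData", "ActivityDataValue"),
    s("hasTimeStamp", "ActivityDataValue", "TemporalEntity"),
    s("hasTimeStamp", "Questionnaire", "TemporalEntity"),
    s("hasTimeStamp", "Recommendation", "TemporalEntity"),
    s("hasTimeStamp", "HealthRecord", "TemporalEntity"),
    s("hasMeasurementCapability", "ActivityDevice", "MeasurementCapability", "Only"),
    s("hasOutput", "ActivityDevice", "SensorOutput"),
    s("observes", "ActivityDevice", "Property", "Only"),
    s("detects", "ActivityDevice", "Stimulus", "Only"),
    s("featureOfInterest", "Observation", "FeatureOfInterest", "Only"),
    s("observationResult", "Observation", "SensorOutput", "Only"),
    s("observedBy", "Observation", "Sensor", "Only"),
    s("isPropertyOf", "Property", "FeatureOfInterest"),
    s("hasProperty", "FeatureOfInterest", "Property"),
    s("hasIntervalDay", "Participant", "StepPrediction"),
    s("hasActivityLevel", "Participant", "ActivityLevelDaily"))
}

#' Build the knowledge graph from pipeline outputs
#'
#' Mints stable IRIs under the `sc:` namespace from pseudonymous
#' participant ids, types every instance, and links predictions via
#' `hasIntervalDay`, daily levels via `hasActivityLevel`, preferences via
#' `hasPreferences` and recommendations via `hasReceivedRecommendation`
#' (each recommendation carrying a `hasTimeStamp` edge to a
#' `TemporalEntity`).  Stub `HealthRecord` / `PersonalData` /
#' `ParticipantStatus` nodes are minted so the existential schema
#' constraints hold for every participant.
#'
#' @param participants Character vector of participant ids (e.g. `"P-1"`).
#' @param preferences Optional named list of [preference()] per participant.
#' @param labeled_days Optional data frame with `participant`, `date`,
#'   `level` columns.
#' @param forecasts Optional data frame with `participant`, `day`, `point`,
#'   `lower`, `upper` columns.
#' @param recommendations Optional data frame with `participant`,
#'   `message_id` (and optionally `date`) columns; referencing an unknown
#'   participant is a build error.
#' @return An `rdf_graph` containing the schema plus instance triples.
#' @export
build_graph <- function(participants, preferences = NULL, labeled_days = NULL,
                        forecasts = NULL, recommendations = NULL) {
  participants <- as.character(participants)
  df <- schema_graph()$triples
  iri <- function(...) paste0("sc:", gsub("[^A-Za-z0-9_.-]", "_", paste0(...)))
  for (p in participants) {
    pi <- iri(p)
    df <- .add(df, pi, "rdf:type", "sc:Participant")
    for (stub in c("HealthRecord", "PersonalData", "ParticipantStatus")) {
      ni <- iri(p, "_", stub)
      df <- .add(df, ni, "rdf:type", paste0("sc:", stub))
      prop <- c(HealthRecord = "sc:hasHealthRecord",
                PersonalData = "sc:hasPersonalData",
                ParticipantStatus = "sc:hasStatus")[[stub]]
      df <- .add(df, pi, prop, ni)
      if (stub == "HealthRecord") {       # records carry a temporal entity
        ti <- paste0(ni, "_ts")
        df <- .add(df, ni, "sc:hasTimeStamp", ti)
        df <- .add(df, ti, "rdf:type", "sc:TemporalEntity")
      }
    }
    pref_i <- iri(p, "_Preferences")
    df <- .add(df, pref_i, "rdf:type", "sc:Preferences")
    df <- .add(df, pi, "sc:hasPreferences", pref_i)
    pref <- preferences[[p]]
    if (!is.null(pref)) {
      df <- .add(df, pref_i, "sc:targetScore", as.character(pref$target_score), TRUE)
      df <- .add(df, pref_i, "sc:goalSetting", pref$goal_setting, TRUE)
    }
  }
  known <- function(p) {
    bad <- setdiff(unique(as.character(p)), participants)
    if (length(bad)) stop("dangling reference to unknown participant(s): ",
                          paste(bad, collapse = ", "))
  }
  if (!is.null(labeled_days) && nrow(labeled_days)) {
    known(labeled_days$participant)
    for (i in seq_len(nrow(labeled_days))) {
      r <- labeled_days[i, ]
      ni <- iri(r$participant, "_level_", r$date)
      df <- .add(df, ni, "rdf:type", "sc:ActivityLevelDaily")
      df <- .add(df, iri(r$participant), "sc:hasActivityLevel", ni)
      df <- .add(df, ni, "sc:levelValue", as.character(r$level), TRUE)
      df <- .add(df, ni, "sc:onDate", as.character(r$date), TRUE)
    }
  }
  if (!is.null(forecasts) && nrow(forecasts)) {
    known(forecasts$participant)
    for (i in seq_len(nrow(forecasts))) {
      r <- forecasts[i, ]
      ni <- iri(r$participant, "_prediction_day", r$day)
      df <- .add(df, ni, "rdf:type", "sc:StepPrediction")
      df <- .add(df, iri(r$participant), "sc:hasIntervalDay", ni)
      df <- .add(df, ni, "sc:pointForecast", as.character(r$point), TRUE)
      if (!is.null(r$lower)) df <- .add(df, ni, "sc:lowerBound", as.character(r$lower), TRUE)
      if (!is.null(r$upper)) df <- .add(df, ni, "sc:upperBound", as.character(r$upper), TRUE)
    }
  }
  if (!is.null(recommendations) && nrow(recommendations)) {
    known(recommendations$participant)
    for (i in seq_len(nrow(recommendations))) {
      r <- recommendations[i, ]
      ni <- iri(r$participant, "_rec_", r$message_id)
      ti <- paste0(ni, "_ts")
      df <- .add(df, ni, "rdf:type", "sc:Recommendation")
      df <- .add(df, iri(r$participant), "sc:hasReceivedRecommendation", ni)
      df <- .add(df, ni, "sc:messageId", as.character(r$message_id), TRUE)
      df <- .add(df, ni, "sc:hasTimeStamp", ti)
      df <- .add(df, ti, "rdf:type", "sc:TemporalEntity")
      if (!is.null(r$date))
        df <- .add(df, ti, "sc:value", as.character(r$date), TRUE)
    }
  }
  g <- rdf_graph(df)
  .check_class_tree(g)
  g
}

# The class hierarchy must stay a connected acyclic tree rooted at
# owl:Thing; a cycle is a hard error on load/build.
.check_class_tree <- function(graph) {
  sub <- graph$triples[graph$triples$predicate == "rdfs:subClassOf", , drop = FALSE]
  if (!nrow(sub)) return(invisible(TRUE))
  parent <- stats::setNames(sub$object, sub$subject)
  for (start in names(parent)) {
    seen <- character(0); node <- start
    while (node %in% names(parent)) {
      if (node %in% seen) stop("cycle in the class hierarchy at ", node)
      seen <- c(seen, node)
      node <- parent[[node]]
    }
    if (node != "owl:Thing") stop("class hierarchy not rooted at owl:Thing: ", start)
  }
  invisible(TRUE)
}

.instances_of <- function(graph, class) {
  t <- graph$triples
  t$subject[t$predicate == "rdf:type" & t$object == class]
}

#' Validate a graph against the property schema (closed world)
#'
#' For each `Some` spec every instance of the domain class must have at
#' least one edge of the property; for each `Only` spec every such edge's
#' object must be typed with the range class; `Min`/`Exact`/`Max` compare
#' the per-instance edge count with the stated cardinality.  Validation is
#' closed-world over the materialized triples (the graph validates its own
#' exports; no open-world inference).
#'
#' @param graph An `rdf_graph`.
#' @param specs Property specs (default [property_specs()]).
#' @return Data frame of violations (`instance`, `property`, `rule`,
#'   `detail`); zero rows when compliant.
#' @export
validate_graph <- function(graph, specs = property_specs()) {
  stopifnot(inherits(graph, "rdf_graph"), nrow(specs) > 0)
  known <- sub("^sc:", "", .instances_of(graph, "owl:Class"))
  bad_cls <- setdiff(unique(c(specs$domain, specs$range)), known)
  if (length(known) && length(bad_cls))
    stop("unknown class in spec: ", paste(bad_cls, collapse = ", "))
  t <- graph$triples
  out <- data.frame(instance = character(), property = character(),
                    rule = character(), detail = character(),
                    stringsAsFactors = FALSE)
  viol <- function(i, p, r, d) out <<- rbind(out, data.frame(
    instance = i, property = p, rule = r, detail = d, stringsAsFactors = FALSE))
  for (i in seq_len(nrow(specs))) {
    sp <- specs[i, ]
    prop <- paste0("sc:", sp$property)
    dom <- paste0("sc:", sp$domain); rng <- paste0("sc:", sp$range)
    inst <- .instances_of(graph, dom)
    edges <- t[t$predicate == prop & t$subject %in% inst, , drop = FALSE]
    cnt <- table(factor(edges$subject, levels = inst))
    if (sp$restriction == "Some") {
      for (s in inst[cnt == 0])
        viol(s, sp$property, "Some",
             sprintf("instance of %s lacks a %s edge", sp$domain, sp$property))
    } else if (sp$restriction == "Only") {
      for (j in seq_len(nrow(edges))) {
        o <- edges$object[j]
        typed <- t$object[t$predicate == "rdf:type" & t$subject == o]
        if (edges$literal[j] || !(rng %in% typed))
          viol(edges$subject[j], sp$property, "Only",
               sprintf("object %s is not of range class %s", o, sp$range))
      }
    } else {
      lim <- sp$cardinality
      cmp <- switch(sp$restriction,
                    Min = function(k) k >= lim,
                    Max = function(k) k <= lim,
                    Exact = function(k) k == lim,
                    stop("unknown restriction: ", sp$restriction))
      for (s in inst[!vapply(as.integer(cnt), cmp, logical(1))])
        viol(s, sp$property, sp$restriction,
             sprintf("cardinality %d violates %s %d", cnt[[s]],
                     sp$restriction, lim))
    }
  }
  out
}

## ---- Turtle serialization ------------------------------------------------

.ttl_escape <- function(x) gsub('"', '\\\\"', gsub("\\\\", "\\\\\\\\", x))
.ttl_unescape <- function(x) gsub('\\\\"', '"', gsub("\\\\\\\\", "\\\\", x))

#' Write a graph as Turtle
#'
#' @param graph An `rdf_graph`.
#' @param path Output file path (`.ttl`).
#' @return `path`, invisibly.
#' @export
write_graph <- function(graph, path) {
  stopifnot(inherits(graph, "rdf_graph"))
  lines <- sprintf("@prefix %s: <%s> .", names(graph$prefixes), graph$prefixes)
  t <- graph$triples[order(graph$triples$subject, graph$triples$predicate,
                           graph$triples$object), , drop = FALSE]
  for (s in unique(t$subject)) {
    rows <- t[t$subject == s, , drop = FALSE]
    obj <- ifelse(rows$literal, sprintf('"%s"', .ttl_escape(rows$object)),
                  rows$object)
    body <- paste(sprintf("  %s %s", rows$predicate, obj), collapse = " ;\n")
    lines <- c(lines, "", paste0(s, "\n", body, " ."))
  }
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read a Turtle file written by [write_graph()]
#'
#' Supports the emitted subset: `@prefix` declarations, prefixed names,
#' `<iri>` terms, quoted literals with escapes, `;` predicate lists and the
#' `a` keyword.
#'
#' @param path Turtle file path.
#' @return An `rdf_graph`.
#' @export
read_graph <- function(path) {
  text <- paste(readLines(path, warn = FALSE, encoding = "UTF-8"), collapse = "\n")
  toks <- .ttl_tokens(text)
  prefixes <- character(0)
  df <- rdf_graph()$triples
  i <- 1L
  subject <- NULL; predicate <- NULL
  while (i <= nrow(toks)) {
    tk <- toks$value[i]; ty <- toks$type[i]
    if (ty == "at_prefix") {
      pfx <- sub(":$", "", toks$value[i + 1])
      iri <- sub("^<(.*)>$", "\\1", toks$value[i + 2])
      if (toks$value[i + 3] != ".") stop("malformed @prefix at token ", i)
      prefixes[pfx] <- iri
      i <- i + 4L
      subject <- NULL
      next
    }
    if (is.null(subject)) { subject <- tk; i <- i + 1L; next }
    if (is.null(predicate)) {
      predicate <- if (tk == "a") "rdf:type" else tk
      i <- i + 1L; next
    }
    if (ty %in% c("term", "literal", "kw")) {
      df <- .add(df, subject, predicate,
                 if (ty == "literal") .ttl_unescape(sub('^"(.*)"$', "\\1", tk)) else tk,
                 literal = ty == "literal")
      i <- i + 1L
      # after an object: ';' continues subject, ',' continues predicate,
      # '.' closes the statement
      nxt <- if (i <= nrow(toks)) toks$value[i] else "."
      if (nxt == ";") { predicate <- NULL; i <- i + 1L }
      else if (nxt == ",") { i <- i + 1L }
      else if (nxt == ".") { subject <- NULL; predicate <- NULL; i <- i + 1L }
      else stop("unexpected token '", nxt, "' after object")
      next
    }
    stop("unexpected token '", tk, "' (", ty, ") at position ", i)
  }
  g <- rdf_graph(df)
  if (length(prefixes)) g$prefixes <- utils::modifyList(as.list(.PREFIXES), as.list(prefixes))
  g$prefixes <- unlist(g$prefixes)
  g
}

.ttl_tokens <- function(text) {
  pat <- paste0(
    '@prefix|',
    '"(?:[^"\\\\]|\\\\.)*"|',       # quoted literal with escapes
    "<[^>]*>|",
    "[A-Za-z][A-Za-z0-9_.-]*:[A-Za-z0-9_.-]*|",  # curie
    "[A-Za-z][A-Za-z0-9_-]*:?|",    # bare name / prefix intro / 'a'
    "[;,.]")
  m <- gregexpr(pat, text, perl = TRUE)[[1]]
  vals <- regmatches(text, list(m))[[1]]
  type <- vapply(vals, function(v) {
    if (v == "@prefix") "at_prefix"
    else if (grepl('^"', v)) "literal"
    else if (v %in% c(";", ",", ".")) "punct"
    else if (v == "a") "kw"
    else "term"
  }, character(1), USE.NAMES = FALSE)
  data.frame(value = vals, type = type, stringsAsFactors = FALSE)
}

## ---- SPARQL subset -------------------------------------------------------

#' Run a SPARQL query over a graph
#'
#' Supports `SELECT [DISTINCT] ?v ... | *`, `ASK` and `CONSTRUCT` forms
#' with basic graph patterns (triple patterns over variables, prefixed
#' names, `<iri>`s, quoted literals and the `a` keyword), `PREFIX`
#' declarations, and `ORDER BY [DESC(...)]` for deterministic ordering.
#'
#' @param graph An `rdf_graph`.
#' @param query Query string.
#' @return `SELECT`: data frame of bindings (one column per variable);
#'   `ASK`: logical; `CONSTRUCT`: an `rdf_graph`.
#' @export
run_query <- function(graph, query) {
  stopifnot(inherits(graph, "rdf_graph"))
  q <- .parse_sparql(query)
  prefixes <- c(q$prefixes, graph$prefixes)
  prefixes <- prefixes[!duplicated(names(prefixes))]
  bind <- .match_bgp(graph, q$where, prefixes)
  if (q$form == "ASK") return(nrow(bind) > 0)
  if (q$form == "CONSTRUCT") {
    df <- rdf_graph()$triples
    for (i in seq_len(nrow(bind)))
      for (pt in q$template) {
        term <- function(x) if (startsWith(x, "?")) bind[i, substring(x, 2)] else x
        df <- .add(df, term(pt[1]), term(pt[2]), term(pt[3]))
      }
    return(rdf_graph(df))
  }
  vars <- if (identical(q$select, "*")) names(bind) else sub("^\\?", "", q$select)
  missing_v <- setdiff(vars, names(bind))
  if (length(missing_v))
    stop("SPARQL error: selected variable(s) not bound: ",
         paste(missing_v, collapse = ", "))
  out <- bind[, vars, drop = FALSE]
  if (q$distinct) out <- unique(out)
  if (length(q$order_by)) {
    keys <- lapply(q$order_by, function(o) {
      v <- out[[sub("^\\?", "", o$var)]]
      if (o$desc) -xtfrm(v) else xtfrm(v)
    })
    out <- out[do.call(order, keys), , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

.sparql_error <- function(msg, near, text) {
  pos <- if (!is.na(near)) regexpr(near, text, fixed = TRUE)[1] else NA
  stop("SPARQL syntax error", if (!is.na(pos) && pos > 0)
    paste0(" near position ", pos, " ('", near, "')"), ": ", msg, call. = FALSE)
}

.parse_sparql <- function(query) {
  text <- query
  # strip comment lines (no '#' inside our IRIs appears at line starts only)
  lines <- strsplit(text, "\n")[[1]]
  lines <- lines[!grepl("^\\s*#", lines)]
  text <- paste(lines, collapse = "\n")
  prefixes <- character(0)
  pm <- gregexpr("PREFIX\\s+([A-Za-z][A-Za-z0-9_]*)\\s*:\\s*<([^>]*)>",
                 text, perl = TRUE, ignore.case = TRUE)[[1]]
  if (pm[1] != -1) {
    for (mm in regmatches(text, list(pm))[[1]]) {
      parts <- regmatches(mm, regexec(
        "PREFIX\\s+([A-Za-z][A-Za-z0-9_]*)\\s*:\\s*<([^>]*)>", mm,
        ignore.case = TRUE))[[1]]
      prefixes[parts[2]] <- parts[3]
    }
    text <- gsub("PREFIX\\s+[A-Za-z][A-Za-z0-9_]*\\s*:\\s*<[^>]*>", "", text,
                 ignore.case = TRUE)
  }
  form_m <- regexec("^\\s*(SELECT|ASK|CONSTRUCT)\\b", text, ignore.case = TRUE)[[1]]
  if (form_m[1] == -1) .sparql_error("query must start with SELECT, ASK or CONSTRUCT",
                                     substr(trimws(text), 1, 12), query)
  form <- toupper(regmatches(text, list(form_m))[[1]][2])
  blocks <- regmatches(text, gregexpr("\\{[^{}]*\\}", text))[[1]]
  if (form == "ASK") {
    if (length(blocks) < 1) .sparql_error("ASK needs a pattern block", "{", query)
    return(list(form = "ASK", prefixes = prefixes,
                where = .parse_patterns(blocks[1], query)))
  }
  if (form == "CONSTRUCT") {
    if (length(blocks) < 2) .sparql_error("CONSTRUCT needs template and WHERE blocks", "{", query)
    return(list(form = "CONSTRUCT", prefixes = prefixes,
                template = .parse_patterns(blocks[1], query),
                where = .parse_patterns(blocks[2], query)))
  }
  head <- sub("\\{.*", "", text)
  distinct <- grepl("\\bDISTINCT\\b", head, ignore.case = TRUE)
  head_vars <- regmatches(head, gregexpr("\\?[A-Za-z][A-Za-z0-9_]*", head))[[1]]
  select <- if (grepl("SELECT\\s+(DISTINCT\\s+)?\\*", head, ignore.case = TRUE)) "*"
  else if (length(head_vars)) head_vars
  else .sparql_error("SELECT needs variables or *", trimws(head), query)
  if (length(blocks) < 1) .sparql_error("missing WHERE block", "{", query)
  tail_txt <- sub(".*\\}", "", text)
  order_by <- list()
  om <- regmatches(tail_txt, gregexpr(
    "(DESC\\s*\\(\\s*)?\\?[A-Za-z][A-Za-z0-9_]*\\s*\\)?", tail_txt))[[1]]
  if (grepl("ORDER\\s+BY", tail_txt, ignore.case = TRUE) && length(om)) {
    order_by <- lapply(om, function(o) list(
      var = regmatches(o, regexpr("\\?[A-Za-z][A-Za-z0-9_]*", o)),
      desc = grepl("DESC", o, ignore.case = TRUE)))
  }
  list(form = "SELECT", prefixes = prefixes, select = select,
       distinct = distinct, where = .parse_patterns(blocks[1], query),
       order_by = order_by)
}

.parse_patterns <- function(block, query) {
  inner <- sub("^\\{", "", sub("\\}$", "", block))
  pat <- paste0('\\?[A-Za-z][A-Za-z0-9_]*|',
                '"(?:[^"\\\\]|\\\\.)*"|<[^>]*>|',
                "[A-Za-z][A-Za-z0-9_.-]*:[A-Za-z0-9_.-]*|\\ba\\b|\\.")
  toks <- regmatches(inner, gregexpr(pat, inner, perl = TRUE))[[1]]
  rest <- gsub(pat, "", inner, perl = TRUE)
  if (grepl("[^[:space:];]", rest))
    .sparql_error("unrecognised tokens in pattern block",
                  trimws(gsub("[[:space:]]+", " ", rest)), query)
  groups <- split(toks, cumsum(toks == ".") - (toks == "."))
  pats <- list()
  for (g in groups) {
    g <- g[g != "."]
    if (!length(g)) next
    if (length(g) != 3)
      .sparql_error("each triple pattern needs subject, predicate, object",
                    paste(g, collapse = " "), query)
    if (g[2] == "a") g[2] <- "rdf:type"
    pats[[length(pats) + 1]] <- g
  }
  if (!length(pats)) .sparql_error("empty pattern block", block, query)
  pats
}

.match_bgp <- function(graph, patterns, prefixes) {
  t <- graph$triples
  exp_s <- .expand_term(t$subject, prefixes)
  exp_p <- .expand_term(t$predicate, prefixes)
  exp_o <- ifelse(t$literal, paste0('"', t$object, '"'),
                  .expand_term(t$object, prefixes))
  bind <- data.frame(row.names = 1)[, 0, drop = FALSE]   # one empty binding
  first <- TRUE
  for (pt in patterns) {
    cols <- list(exp_s, exp_p, exp_o)
    keep <- rep(TRUE, nrow(t))
    var_at <- integer(0)
    for (k in 1:3) {
      term <- pt[k]
      if (startsWith(term, "?")) { var_at <- c(var_at, k); next }
      val <- if (startsWith(term, '"')) term else .expand_term(term, prefixes)
      keep <- keep & cols[[k]] == val
    }
    cand <- data.frame(row.names = NULL)
    for (k in var_at) {
      v <- substring(pt[k], 2)
      col <- cols[[k]][keep]
      if (ncol(cand) == 0 && !nrow(cand)) cand <- data.frame(tmp = col, stringsAsFactors = FALSE)[, 0, drop = FALSE]
      cand[[v]] <- col
    }
    if (!length(var_at)) {
      if (!any(keep)) return(bind[0, , drop = FALSE])
      next
    }
    cand <- unique(cand)
    shared <- intersect(names(bind), names(cand))
    bind <- if (first && !ncol(bind)) cand
    else if (length(shared)) merge(bind, cand, by = shared, stringsAsFactors = FALSE)
    else merge(bind, cand, by = NULL)
    first <- FALSE
    if (!nrow(bind)) return(bind)
  }
  bind
}
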