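# Knowledge graph: construction, closed-world validation, Turtle
# round-trip, and SPARQL querying.

week_graph <- function() {
  build_graph(
    participants = "P-1",
    preferences = list(`P-1` = preference()),
    labeled_days = data.frame(participant = "P-1",
                              date = as.Date("2023-03-06") + 0:6,
                              level = table18_levels),
    forecasts = data.frame(participant = "P-1", day = 1:7,
                           point = c(7369, 8879, 8202, 7557, 10199, 9819, 7426),
                           lower = 1, upper = 2),
    recommendations = data.frame(participant = "P-1",
                                 message_id = c("A-17", "A-13"),
                                 date = "2023-03-12"))
}

test_that("graph construction links each entity kind once per input row", {
  g <- week_graph()
  t <- g$triples
  expect_equal(sum(t$predicate == "sc:hasReceivedRecommendation"), 2L)
  expect_equal(sum(t$predicate == "sc:hasActivityLevel"), 7L)
  expect_equal(sum(t$predicate == "sc:hasIntervalDay"), 7L)
  expect_equal(sum(t$predicate == "rdf:type" & t$object == "sc:Participant"), 1L)
  # empty input: schema triples only
  empty <- build_graph(character(0))
  expect_equal(graph_size(empty), graph_size(schema_graph()))
  expect_error(build_graph("P-1", recommendations = data.frame(
    participant = "P-9", message_id = "A-17")), "dangling")
})

test_that("closed-world validation flags Some and Only violations exactly", {
  g <- week_graph()
  expect_equal(nrow(validate_graph(g)), 0L)
  # a participant with no status edge: one Some violation
  t <- g$triples
  g2 <- rdf_graph(t[t$predicate != "sc:hasStatus", ])
  v <- validate_graph(g2)
  expect_equal(nrow(v), 1L)
  expect_equal(v$rule, "Some")
  expect_equal(v$property, "hasStatus")
  # an observing device pointing outside the range class: Only violation
  t3 <- stepcoach:::.add(g$triples, "sc:dev1", "rdf:type", "sc:ActivityDevice")
  t3 <- stepcoach:::.add(t3, "sc:out1", "rdf:type", "sc:SensorOutput")
  t3 <- stepcoach:::.add(t3, "sc:dev1", "sc:hasOutput", "sc:out1")
  t3 <- stepcoach:::.add(t3, "sc:notAProperty", "rdf:type", "sc:Stimulus")
  t3 <- stepcoach:::.add(t3, "sc:dev1", "sc:observes", "sc:notAProperty")
  v3 <- validate_graph(rdf_graph(t3))
  expect_equal(nrow(v3), 1L)
  expect_equal(v3$rule, "Only")
  expect_equal(v3$property, "observes")
  expect_error(validate_graph(g, data.frame(property = "p", domain = "Nope",
                                            range = "Participant",
                                            restriction = "Some",
                                            cardinality = NA)), "unknown class")
})

test_that("the class hierarchy must stay an acyclic tree", {
  t <- schema_graph()$triples
  t <- stepcoach:::.add(t, "owl:Thing", "rdfs:subClassOf", "sc:Participant")
  expect_error(stepcoach:::.check_class_tree(rdf_graph(t)), "cycle")
})

test_that("a graph survives a Turtle round-trip isomorphically", {
  g <- week_graph()
  path <- tempfile(fileext = ".ttl")
  write_graph(g, path)
  g2 <- read_graph(path)
  canon <- function(gr) {
    t <- gr$triples[do.call(order, gr$triples), ]
    rownames(t) <- NULL
    t
  }
  expect_equal(canon(g2), canon(g))
  # queries are stable across the round-trip
  q <- "SELECT ?m WHERE { ?r sc:messageId ?m . } ORDER BY ?m"
  expect_equal(run_query(g2, q), run_query(g, q))
})

test_that("SELECT, ASK and CONSTRUCT queries answer over the graph", {
  g <- build_graph(c("P-1", "P-2", "P-3"))
  res <- run_query(g, "SELECT ?p WHERE { ?p a sc:Participant . }")
  expect_equal(nrow(res), 3L)
  expect_true(run_query(g, "ASK { sc:P-2 a sc:Participant . }"))
  expect_false(run_query(g, "ASK { sc:P-9 a sc:Participant . }"))
  con <- run_query(g, paste(
    "CONSTRUCT { ?p a sc:Person . } WHERE { ?p a sc:Participant . }"))
  expect_s3_class(con, "rdf_graph")
  expect_equal(graph_size(con), 3L)
  expect_error(run_query(g, "NONSENSE ?x"), "SPARQL syntax error")
})

test_that("the delivered messages for the worked week are queryable", {
  g <- week_graph()
  res <- run_query(g, paste(
    "SELECT ?msg WHERE { sc:P-1 sc:hasReceivedRecommendation ?r .",
    "?r sc:messageId ?msg . } ORDER BY ?msg"))
  expect_equal(res$msg, c('"A-13"', '"A-17"'))
  # join across three patterns with an explicit PREFIX
  res2 <- run_query(g, paste(
    "PREFIX sc: <http://stepcoach.org/ns#>",
    "SELECT DISTINCT ?p ?msg WHERE { ?p a sc:Participant .",
    "?p sc:hasReceivedRecommendation ?r . ?r sc:messageId ?msg . }",
    "ORDER BY DESC(?msg)"))
  expect_equal(res2$msg, c('"A-17"', '"A-13"'))
  expect_true(all(grepl("P-1", res2$p)))
})
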