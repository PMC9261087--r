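edge_map <- function(g) {
  e <- g$edges[order(g$edges$from, g$edges$to), , drop = FALSE]
  rownames(e) <- NULL
  e
}

test_that("structural graphs reproduce the printed worked-example chain", {
  g <- build_structural(content_lemmas(cookie_response()))
  expect_identical(
    edge_map(g),
    data.frame(from = c("cookie", "grab", "kid"),
               to = c("jar", "cookie", "grab"),
               weight = c(1L, 1L, 1L), stringsAsFactors = FALSE))
  expect_length(g$nodes, 4L)
  # the two-utterance sequence contains the chain i -> see -> chair
  g2 <- build_structural(content_lemmas(two_frame_response()))
  expect_true(all(c("i\rsee", "see\rchair") %in%
                    paste0(g2$edges$from, "\r", g2$edges$to)))
})

test_that("structural edge weights count ordered adjacencies, skipping self-loops", {
  expect_identical(nrow(build_structural("a")$edges), 0L)
  expect_length(build_structural("a")$nodes, 1L)
  g <- build_structural(c("a", "b", "a", "b"))
  expect_identical(edge_map(g),
                   data.frame(from = c("a", "b"), to = c("b", "a"),
                              weight = c(2L, 1L), stringsAsFactors = FALSE))
  # identical consecutive lemmas are skipped, not self-looped
  g <- build_structural(c("a", "a", "b"))
  expect_identical(edge_map(g),
                   data.frame(from = "a", to = "b", weight = 1L,
                              stringsAsFactors = FALSE))
  expect_length(build_structural(character())$nodes, 0L)
})

test_that("total structural weight equals the count of non-loop adjacent pairs", {
  set.seed(7)
  for (i in 1:25) {
    lem <- sample(letters[1:4], sample(0:40, 1), replace = TRUE)
    g <- build_structural(lem)
    n <- length(lem)
    expected <- if (n >= 2) sum(lem[-n] != lem[-1]) else 0L
    expect_identical(sum(g$edges$weight), as.integer(expected))
  }
})

test_that("semantic graphs combine predication and action edges per frame", {
  g <- build_semantic(list(cookie_utterance()))
  expect_identical(
    edge_map(g),
    data.frame(from = c("grab", "grab", "kid"),
               to = c("cookie jar", "kid", "cookie jar"),
               weight = c(1L, 1L, 1L), stringsAsFactors = FALSE))
  g <- build_semantic(list(chair_utterance()))
  expect_identical(
    edge_map(g),
    data.frame(from = c("i", "see", "see"),
               to = c("chair", "chair", "i"),
               weight = c(1L, 1L, 1L), stringsAsFactors = FALSE))
  # actor-only frame: single predication edge, no action edge
  tok <- speech_tokens(c("I", "sleep"), c("i", "sleep"), c("PRON", "VERB"))
  u <- speech_utterance(0L, tok,
                        list(srl_frame(c(1L, 2L), "sleep",
                                       list(A0 = c(0L, 1L)))))
  g <- build_semantic(list(u))
  expect_identical(edge_map(g),
                   data.frame(from = "sleep", to = "i", weight = 1L,
                              stringsAsFactors = FALSE))
  # A2 as second undergoer: A0->A2 but never A1->A2
  tok <- speech_tokens(c("kid", "gives", "jar", "to", "dog"),
                       c("kid", "give", "jar", "to", "dog"),
                       c("NOUN", "VERB", "NOUN", "ADP", "NOUN"))
  u <- speech_utterance(0L, tok, list(
    srl_frame(c(1L, 2L), "give",
              list(A0 = c(0L, 1L), A1 = c(2L, 3L), A2 = c(3L, 5L)))))
  keys <- with(build_semantic(list(u))$edges, paste(from, to, sep = ">"))
  expect_setequal(keys, c("give>kid", "give>jar", "give>dog",
                          "kid>jar", "kid>dog"))
})

test_that("repeated relations accumulate weight; frames without arguments contribute only the predicate node", {
  two <- list(cookie_utterance(), local({
    u <- cookie_utterance(); u$utterance_id <- 1L; u
  }))
  g <- build_semantic(two)
  expect_true(all(g$edges$weight == 2L))
  bare <- speech_utterance(0L, speech_tokens("runs", "run", "VERB"),
                           list(srl_frame(c(0L, 1L), "run")))
  g <- build_semantic(list(bare))
  expect_identical(g$nodes, "run")
  expect_identical(nrow(g$edges), 0L)
  # zero frames anywhere -> empty graph
  g <- build_semantic(list(speech_utterance(0L, speech_tokens("hi", "hi", "INTJ"))))
  expect_length(g$nodes, 0L)
})

test_that("semantic weights are invariant to utterance order and additive over utterances", {
  utts <- two_frame_utterances()
  g_fwd <- build_semantic(utts)
  g_rev <- build_semantic(rev(utts))
  expect_identical(edge_map(g_fwd), edge_map(g_rev))
  # whole-scope build equals union-with-weight-summation of per-utterance builds
  per <- lapply(utts, function(u) build_semantic(list(u)))
  pooled <- do.call(rbind, lapply(per, `[[`, "edges"))
  pooled <- aggregate(weight ~ from + to, pooled, sum)
  pooled <- pooled[order(pooled$from, pooled$to), c("from", "to", "weight")]
  rownames(pooled) <- NULL
  pooled$weight <- as.integer(pooled$weight)
  expect_identical(edge_map(g_fwd), pooled)
})

test_that("self-identity relations are skipped in semantic graphs", {
  tok <- speech_tokens(c("kid", "sees", "kid"), c("kid", "see", "kid"),
                       c("NOUN", "VERB", "NOUN"))
  u <- speech_utterance(0L, tok, list(
    srl_frame(c(1L, 2L), "see", list(A0 = c(0L, 1L), A1 = c(2L, 3L)))))
  g <- build_semantic(list(u))  # kid -> kid action edge must be skipped
  keys <- with(g$edges, paste(from, to, sep = ">"))
  expect_setequal(keys, c("see>kid"))
  expect_identical(g$edges$weight, 2L)  # two predication instances
})

test_that("speech_graph enforces the simple-digraph invariants", {
  expect_error(speech_graph(data.frame(from = "a", to = "a", weight = 1),
                            "a", "structural"), "self-loops")
  expect_error(speech_graph(data.frame(from = c("a", "a"), to = c("b", "b"),
                                       weight = c(1, 1)),
                            c("a", "b"), "structural"), "parallel")
  expect_error(speech_graph(data.frame(from = "a", to = "b", weight = 0),
                            c("a", "b"), "structural"), "weights")
})

test_that("graph export round-trips exactly in both formats", {
  fig1 <- build_semantic(two_frame_utterances(),
                         provenance = list(participant = "p1"))
  expect_length(fig1$nodes, 6L)
  expect_identical(nrow(fig1$edges), 6L)
  for (fmt in c("graphml", "tsv")) {
    path <- withr::local_tempfile(fileext = paste0(".", fmt))
    export_graph(fig1, path, fmt)
    back <- import_graph(path, fmt)
    expect_setequal(back$nodes, fig1$nodes)
    expect_identical(edge_map(back), edge_map(fig1))
    expect_identical(back$graph_type, "semantic")
  }
  # empty graph round-trips
  empty <- build_structural(character())
  path <- withr::local_tempfile(fileext = ".tsv")
  export_graph(empty, path, "tsv")
  expect_length(import_graph(path, "tsv")$nodes, 0L)
  # property: seeded random graphs round-trip (including isolated nodes)
  set.seed(11)
  for (i in 1:10) {
    g <- random_speech_graph()
    fmt <- if (i %% 2) "graphml" else "tsv"
    path <- withr::local_tempfile(fileext = paste0(".", fmt))
    export_graph(g, path, fmt)
    back <- import_graph(path, fmt)
    expect_setequal(back$nodes, g$nodes)
    expect_identical(edge_map(back), edge_map(g))
  }
})
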