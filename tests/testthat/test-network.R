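test_that("co-occurrence units drop stopwords, exclusions, and numerals", {
  cfg <- network_config(stopwords = "the", extra_exclusions = "things")
  corpus <- corpus_table("n1", "a1",
                         "the voices came. the voices stayed", "FPA")
  units <- network_tokens(corpus, cfg)
  expect_equal(units, list(c("voices", "came"), c("voices", "stayed")))

  corpus2 <- corpus_table("n2", "a2", "things happened in 1994 again", "FPA")
  units2 <- network_tokens(corpus2, network_config(
    stopwords = c("in"), extra_exclusions = c("things", "one", "will", "much")))
  expect_false("things" %in% unlist(units2))
  expect_false("1994" %in% unlist(units2))

  expect_warning(
    u0 <- network_tokens(corpus[0, ], cfg),
    "empty"
  )
  expect_length(u0, 0)
})

test_that("window mode slides within narratives only", {
  cfg <- network_config(cooccurrence_unit = "window", window_size = 2,
                        stopwords = character(0), extra_exclusions = character(0))
  corpus <- corpus_table("n1", "a1", "alpha beta gamma", "FPA")
  units <- network_tokens(corpus, cfg)
  expect_equal(units, list(c("alpha", "beta"), c("beta", "gamma")))
})

test_that("word frequencies aggregate additively over units", {
  expect_equal(word_frequencies(list(c("a", "b"), "a")),
               c(a = 2L, b = 1L))
  expect_length(word_frequencies(list()), 0)
})

test_that("graph construction uses per-unit set semantics and accumulates weights", {
  cfg <- network_config(stopwords = character(0),
                        extra_exclusions = character(0))
  g1 <- build_cooccurrence_graph(list(c("a", "b", "c")), cfg)
  expect_equal(nrow(g1$edges), 3L)
  expect_true(all(g1$edges$weight == 1L))

  g2 <- build_cooccurrence_graph(list(c("a", "b"), c("a", "b")), cfg)
  expect_equal(g2$edges$weight, 2L)

  # a repeated word contributes one co-occurrence per pair per unit
  g3 <- build_cooccurrence_graph(list(c("a", "a", "b")), cfg)
  expect_equal(g3$edges$weight, 1L)
  expect_equal(g3$nodes$frequency[g3$nodes$word == "a"], 2L)
})

test_that("graph construction is invariant to narrative order", {
  cfg <- network_config(stopwords = character(0), extra_exclusions = character(0))
  u <- list(c("a", "b"), c("b", "c"), c("a", "c", "d"))
  ga <- build_cooccurrence_graph(u, cfg)
  gb <- build_cooccurrence_graph(rev(u), cfg)
  expect_equal(ga$edges, gb$edges)
  expect_equal(ga$nodes, gb$nodes)
})

test_that("betweenness matches closed forms on path and star graphs", {
  path <- make_word_graph(c("a", "b", "c"), data.frame(
    word1 = c("a", "b"), word2 = c("b", "c"), weight = 1L, highlighted = NA))
  b <- betweenness_centrality(path)
  expect_equal(unname(b[c("a", "b", "c")]), c(0, 1, 0))

  star <- make_word_graph(c("x", paste0("l", 1:4)), data.frame(
    word1 = "x", word2 = paste0("l", 1:4), weight = 1L, highlighted = NA))
  bs <- betweenness_centrality(star)
  expect_equal(unname(bs["x"]), 6)  # all C(4,2) leaf pairs
  expect_true(all(bs[paste0("l", 1:4)] == 0))
})

test_that("betweenness agrees exactly with exhaustive path enumeration", {
  set.seed(202)
  for (i in 1:40) {
    g <- random_word_graph(sample(2:8, 1))
    got <- betweenness_centrality(g)
    want <- bf_betweenness(g$nodes$word, g$edges)
    expect_equal(got[g$nodes$word], want[g$nodes$word], tolerance = 1e-9)
  }
})

test_that("betweenness total credit is conserved under relabeling", {
  set.seed(7)
  g <- random_word_graph(7)
  b1 <- betweenness_centrality(g)
  relab <- g
  new <- setNames(paste0("z", rev(seq_len(7))), g$nodes$word)
  relab$nodes$word <- unname(new[g$nodes$word])
  relab$edges$word1 <- unname(new[g$edges$word1])
  relab$edges$word2 <- unname(new[g$edges$word2])
  b2 <- betweenness_centrality(relab)
  expect_equal(sum(b1), sum(b2), tolerance = 1e-9)
})

test_that("bridge ranking orders by betweenness then frequency then name", {
  path <- make_word_graph(c("a", "m", "z"), data.frame(
    word1 = c("a", "m"), word2 = c("m", "z"), weight = 1L, highlighted = NA))
  path$nodes$betweenness <- betweenness_centrality(path)[path$nodes$word]
  expect_equal(bridge_ranking(path)[1], "m")

  # complete graph: all betweenness 0, falls back to frequency order
  k3 <- make_word_graph(c("a", "b", "c"), data.frame(
    word1 = c("a", "a", "b"), word2 = c("b", "c", "c"),
    weight = 1L, highlighted = NA), freq = c(1L, 5L, 3L))
  k3$nodes$betweenness <- betweenness_centrality(k3)[k3$nodes$word]
  expect_equal(bridge_ranking(k3), c("b", "c", "a"))
})

test_that("edge highlighting keeps the heaviest quantile with ties included", {
  cfg <- network_config(stopwords = character(0), extra_exclusions = character(0))
  g <- make_word_graph(paste0("w", 1:11), data.frame(
    word1 = rep("w1", 10), word2 = paste0("w", 2:11),
    weight = 1:10, highlighted = NA))
  s <- style_edges(g, network_config(highlight_quantile = 0.4))
  expect_equal(sum(s$edges$highlighted), 4L)
  expect_true(all(s$edges$weight[s$edges$highlighted] >= 7))

  g$edges$weight <- rep(3L, 10)
  s2 <- style_edges(g, network_config(highlight_quantile = 0.4))
  expect_true(all(s2$edges$highlighted))

  s3 <- style_edges(g, network_config(highlight_quantile = 1))
  expect_true(all(s3$edges$highlighted))
})

test_that("graph exports round-trip through GraphML and TSV", {
  cfg <- network_config(stopwords = character(0), extra_exclusions = character(0))
  g <- build_cooccurrence_graph(list(c("a", "b", "c"), c("b", "c")), cfg,
                                subset = "demo")
  gml <- withr::local_tempfile(fileext = ".graphml")
  export_graph(g, gml, "graphml")
  back <- import_graph(gml, subset = "demo")
  expect_equal(back$nodes, g$nodes)
  expect_equal(back$edges, g$edges)

  ntsv <- withr::local_tempfile(fileext = ".tsv")
  export_graph(g, ntsv, "node_tsv")
  nd <- read.delim(ntsv)
  expect_equal(nd$word, g$nodes$word)
  expect_equal(nd$betweenness, g$nodes$betweenness)

  # empty graph exports a valid document
  g0 <- build_cooccurrence_graph(list(), cfg)
  gml0 <- withr::local_tempfile(fileext = ".graphml")
  export_graph(g0, gml0, "graphml")
  back0 <- import_graph(gml0)
  expect_equal(nrow(back0$nodes), 0L)
  expect_equal(nrow(back0$edges), 0L)
})

test_that("adding a direct inter-cluster edge reduces the bridge's betweenness", {
  # two triangles joined through m
  words <- c("a1", "a2", "a3", "b1", "b2", "b3", "m")
  e <- data.frame(
    word1 = c("a1", "a1", "a2", "b1", "b1", "b2", "a1", "b1"),
    word2 = c("a2", "a3", "a3", "b2", "b3", "b3", "m", "m"),
    weight = 1L, highlighted = NA)
  g <- make_word_graph(words, e)
  b_before <- betweenness_centrality(g)["m"]
  e2 <- rbind(e, data.frame(word1 = "a2", word2 = "b2", weight = 1L,
                            highlighted = NA))
  b_after <- betweenness_centrality(make_word_graph(words, e2))["m"]
  expect_lt(b_after, b_before)
})
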