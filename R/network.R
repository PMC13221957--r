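#' Word network configuration
#'
#' @param top_k Number of most frequent words flagged for display
#'   (default 20).
#' @param highlight_quantile Fraction of heaviest edges highlighted
#'   (default 0.40, i.e. the top 40 percent).
#' @param cooccurrence_unit `"sentence"` (default) or `"window"`. Sentences
#'   keep long essays from collapsing into near-complete graphs; windows are
#'   an alternative for unpunctuated text.
#' @param window_size Sliding window length in tokens when
#'   `cooccurrence_unit = "window"` (default 10).
#' @param stopwords Character vector of stopwords; default the pinned list
#'   shipped with the package ([default_stopwords()]).
#' @param extra_exclusions Additional non-meaningful words dropped before
#'   counting; seeded with `c("things", "one", "will", "much")`.
#' @param distance_mode `"unweighted"` (default: every edge has length 1 for
#'   shortest paths) or `"inverse_weight"` (edge length `1/weight`, so
#'   frequent co-occurrence means proximity).
#' @return A list of class `network_config`.
#' @export
network_config <- function(top_k = 20L,
                           highlight_quantile = 0.40,
                           cooccurrence_unit = c("sentence", "window"),
                           window_size = 10L,
                           stopwords = default_stopwords(),
                           extra_exclusions = c("things", "one", "will", "much"),
                           distance_mode = c("unweighted", "inverse_weight")) {
  stopifnot(top_k >= 1L, highlight_quantile > 0, highlight_quantile <= 1,
            window_size >= 1L)
  structure(
    list(
      top_k = as.integer(top_k),
      highlight_quantile = highlight_quantile,
      cooccurrence_unit = match.arg(cooccurrence_unit),
      window_size = as.integer(window_size),
      stopwords = tolower(stopwords),
      extra_exclusions = tolower(extra_exclusions),
      distance_mode = match.arg(distance_mode)
    ),
    class = "network_config"
  )
}

#' Pinned English stopword list
#'
#' Loads the fixed, versioned stopword list shipped with the package
#' (`inst/extdata/stopwords_en.txt`). Pinning the list (rather than pulling
#' one from another library at run time) keeps network results reproducible.
#'
#' @return Character vector of lowercase stopwords.
#' @export
default_stopwords <- function() {
  path <- system.file("extdata", "stopwords_en.txt", package = "lexnet")
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- trimws(lines)
  lines[nzchar(lines) & !startsWith(lines, "#")]
}

#' Co-occurrence units for a corpus subset
#'
#' Tokenizes each narrative, drops stopwords, configured exclusions, and
#' purely numeric tokens, and emits one token set per co-occurrence unit
#' (sentence or sliding window). Units never cross narrative boundaries.
#'
#' @param corpus A [corpus_table()] subset.
#' @param config A [network_config()].
#' @return List of character vectors (tokens per unit, with within-unit
#'   duplicates retained; pairing uses set semantics later).
#' @export
network_tokens <- function(corpus, config = network_config()) {
  stopifnot(inherits(corpus, "corpus_table"), inherits(config, "network_config"))
  if (nrow(corpus) == 0L) {
    warning("empty corpus subset: no co-occurrence units")
    return(list())
  }
  drop <- c(config$stopwords, config$extra_exclusions)
  units <- list()
  for (i in seq_len(nrow(corpus))) {
    st <- tokenize(corpus$text[i], narrative_id = corpus$narrative_id[i])
    keep <- !(st$tokens %in% drop) & !grepl("^[0-9]+$", st$tokens)
    toks <- st$tokens[keep]
    sent <- st$sentence_index[keep]
    if (!length(toks)) next
    if (config$cooccurrence_unit == "sentence") {
      units <- c(units, unname(split(toks, sent)))
    } else {
      w <- config$window_size
      if (length(toks) <= w) {
        units <- c(units, list(toks))
      } else {
        starts <- seq_len(length(toks) - w + 1L)
        units <- c(units, lapply(starts, function(s) toks[s:(s + w - 1L)]))
      }
    }
  }
  units
}

#' Aggregate word frequencies over units
#'
#' @param units List of token vectors ([network_tokens()]).
#' @return Named integer vector of occurrence counts (decreasing, ties
#'   alphabetical).
#' @export
word_frequencies <- function(units) {
  toks <- unlist(units, use.names = FALSE)
  if (!length(toks)) return(stats::setNames(integer(0), character(0)))
  tab <- table(toks)
  cnt <- as.integer(tab)
  nm <- names(tab)
  ord <- order(-cnt, nm)
  stats::setNames(cnt[ord], nm[ord])
}

#' Build a word co-occurrence graph
#'
#' Within each unit every unordered pair of distinct words co-occurs once
#' (set semantics: repeating a word inside a unit does not inflate its
#' pairs); an edge's weight is the number of units in which the pair
#' co-occurs. Nodes are all retained words; the `displayed` flag marks the
#' `top_k` most frequent (ties broken alphabetically).
#'
#' @param units List of token vectors ([network_tokens()]).
#' @param config A [network_config()].
#' @param subset Label recorded on the graph.
#' @return An object of class `word_graph`: list with data frames `nodes`
#'   (`word`, `frequency`, `betweenness`, `displayed`) and `edges`
#'   (`word1 < word2`, `weight`, `highlighted`), plus `subset` and `config`.
#' @export
build_cooccurrence_graph <- function(units, config = network_config(),
                                     subset = "") {
  freq <- word_frequencies(units)
  words <- names(freq)
  pair_keys <- unlist(lapply(units, function(u) {
    u <- sort(unique(u))
    if (length(u) < 2L) return(character(0))
    n <- length(u)
    i <- rep.int(seq_len(n - 1L), (n - 1L):1L)
    j <- unlist(lapply(seq_len(n - 1L), function(a) (a + 1L):n))
    paste(u[i], u[j], sep = "\x1f")
  }), use.names = FALSE)
  if (length(pair_keys)) {
    tab <- table(pair_keys)
    parts <- strsplit(names(tab), "\x1f", fixed = TRUE)
    edges <- data.frame(
      word1 = vapply(parts, `[`, character(1), 1L),
      word2 = vapply(parts, `[`, character(1), 2L),
      weight = as.integer(tab),
      highlighted = NA,
      stringsAsFactors = FALSE
    )
    ord <- order(edges$word1, edges$word2)
    edges <- edges[ord, , drop = FALSE]
    rownames(edges) <- NULL
  } else {
    edges <- data.frame(word1 = character(0), word2 = character(0),
                        weight = integer(0), highlighted = logical(0),
                        stringsAsFactors = FALSE)
  }
  displayed <- rep(FALSE, length(words))
  displayed[seq_len(min(config$top_k, length(words)))] <- TRUE  # freq-ordered
  nodes <- data.frame(
    word = words,
    frequency = as.integer(freq),
    betweenness = rep(NA_real_, length(words)),
    displayed = displayed,
    stringsAsFactors = FALSE
  )
  g <- structure(
    list(nodes = nodes, edges = edges, subset = subset, config = config),
    class = "word_graph"
  )
  g$nodes$betweenness <- betweenness_centrality(g, config)[nodes$word]
  g <- style_edges(g, config)
  g
}

#' Betweenness centrality of every node
#'
#' Standard undirected, unnormalized betweenness: for each node `v`, the sum
#' over unordered pairs `{s, t}` (both distinct from `v`) of the fraction of
#' shortest s-t paths passing through `v`. Computed on the full graph, never
#' just the displayed nodes, so display pruning cannot distort centrality.
#' With `distance_mode = "unweighted"` every edge has length 1; with
#' `"inverse_weight"` the length is `1/weight`.
#'
#' @param graph A `word_graph`.
#' @param config A [network_config()]; defaults to the graph's own.
#' @return Named numeric vector of betweenness values (one per node).
#' @export
betweenness_centrality <- function(graph, config = graph$config) {
  stopifnot(inherits(graph, "word_graph"))
  words <- graph$nodes$word
  if (!length(words)) return(stats::setNames(numeric(0), character(0)))
  ig <- igraph::graph_from_data_frame(
    graph$edges[, c("word1", "word2", "weight")],
    directed = FALSE,
    vertices = data.frame(name = words, stringsAsFactors = FALSE)
  )
  w <- if (config$distance_mode == "inverse_weight") {
    1 / igraph::E(ig)$weight
  } else {
    rep(1, igraph::ecount(ig))
  }
  b <- igraph::betweenness(ig, directed = FALSE, weights = w, normalized = FALSE)
  stats::setNames(as.numeric(b), igraph::V(ig)$name)[words]
}

#' Rank displayed words as bridges
#'
#' Displayed nodes sorted by betweenness descending, ties broken by
#' frequency descending, then alphabetically. The first element is the most
#' central "bridge" word of the subset.
#'
#' @param graph A `word_graph` with betweenness computed.
#' @return Character vector of displayed words in bridge order.
#' @export
bridge_ranking <- function(graph) {
  stopifnot(inherits(graph, "word_graph"))
  nd <- graph$nodes[graph$nodes$displayed, , drop = FALSE]
  if (!nrow(nd)) return(character(0))
  nd$word[order(-nd$betweenness, -nd$frequency, nd$word)]
}

#' Highlight the heaviest edges
#'
#' Marks as highlighted every edge whose weight is at least the
#' `ceiling(highlight_quantile * n_edges)`-th largest weight; ties at the
#' threshold are included and all edges are retained.
#'
#' @param graph A `word_graph`.
#' @param config A [network_config()]; defaults to the graph's own.
#' @return The graph with `edges$highlighted` filled in.
#' @export
style_edges <- function(graph, config = graph$config) {
  stopifnot(inherits(graph, "word_graph"))
  m <- nrow(graph$edges)
  if (m == 0L) return(graph)
  k <- ceiling(config$highlight_quantile * m)
  thr <- sort(graph$edges$weight, decreasing = TRUE)[k]
  graph$edges$highlighted <- graph$edges$weight >= thr
  graph
}

#' @export
print.word_graph <- function(x, ...) {
  cat("<word_graph>", if (nzchar(x$subset)) paste0("[", x$subset, "] "),
      nrow(x$nodes), "nodes,", nrow(x$edges), "edges;",
      sum(x$nodes$displayed), "displayed,",
      sum(x$edges$highlighted %in% TRUE), "highlighted edges\n")
  top <- utils::head(bridge_ranking(x), 5L)
  if (length(top)) cat("  top bridges:", paste(top, collapse = ", "), "\n")
  invisible(x)
}

#' Export a word graph
#'
#' `graphml` writes a single GraphML file with node attributes `frequency`,
#' `betweenness`, `displayed` and edge attributes `weight`, `highlighted`
#' (logicals encoded 0/1). `node_tsv` / `edge_tsv` write the corresponding
#' tables. [import_graph()] round-trips a GraphML export back to an
#' identical `word_graph` (modulo the config, which is not serialized).
#'
#' @param graph A `word_graph`.
#' @param path Output file path.
#' @param format One of `"graphml"`, `"node_tsv"`, `"edge_tsv"`.
#' @return `path`, invisibly.
#' @export
export_graph <- function(graph, path, format = c("graphml", "node_tsv", "edge_tsv")) {
  format <- match.arg(format)
  stopifnot(inherits(graph, "word_graph"))
  if (format == "node_tsv") {
    utils::write.table(graph$nodes, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, fileEncoding = "UTF-8")
  } else if (format == "edge_tsv") {
    utils::write.table(graph$edges, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, fileEncoding = "UTF-8")
  } else {
    vertices <- data.frame(
      name = graph$nodes$word,
      frequency = graph$nodes$frequency,
      betweenness = graph$nodes$betweenness,
      displayed = as.integer(graph$nodes$displayed),
      stringsAsFactors = FALSE
    )
    ig <- igraph::graph_from_data_frame(
      data.frame(
        from = graph$edges$word1, to = graph$edges$word2,
        weight = graph$edges$weight,
        highlighted = as.integer(graph$edges$highlighted),
        stringsAsFactors = FALSE
      ),
      directed = FALSE, vertices = vertices
    )
    igraph::write_graph(ig, path, format = "graphml")
  }
  invisible(path)
}

#' @rdname export_graph
#' @param subset Label for the re-imported graph.
#' @param config Config attached to the re-imported graph.
#' @export
import_graph <- function(path, subset = "", config = network_config()) {
  ig <- igraph::read_graph(path, format = "graphml")
  nodes <- data.frame(
    word = igraph::V(ig)$name,
    frequency = as.integer(igraph::V(ig)$frequency),
    betweenness = as.numeric(igraph::V(ig)$betweenness),
    displayed = as.logical(as.integer(igraph::V(ig)$displayed)),
    stringsAsFactors = FALSE
  )
  el <- igraph::as_data_frame(ig, what = "edges")
  if (nrow(el)) {
    w1 <- pmin(el$from, el$to)
    w2 <- pmax(el$from, el$to)
    edges <- data.frame(
      word1 = w1, word2 = w2,
      weight = as.integer(el$weight),
      highlighted = as.logical(as.integer(el$highlighted)),
      stringsAsFactors = FALSE
    )
    edges <- edges[order(edges$word1, edges$word2), , drop = FALSE]
    rownames(edges) <- NULL
  } else {
    edges <- data.frame(word1 = character(0), word2 = character(0),
                        weight = integer(0), highlighted = logical(0),
                        stringsAsFactors = FALSE)
  }
  structure(
    list(nodes = nodes, edges = edges, subset = subset, config = config),
    class = "word_graph"
  )
}

#' Plot a word graph
#'
#' Static rendering convenience: displayed nodes only, node size
#' proportional to betweenness, grayscale edges with highlighted edges drawn
#' darker and heavier.
#'
#' @param x A `word_graph`.
#' @param ... Passed to [igraph::plot.igraph()].
#' @export
plot.word_graph <- function(x, ...) {
  nd <- x$nodes[x$nodes$displayed, , drop = FALSE]
  keep <- x$edges$word1 %in% nd$word & x$edges$word2 %in% nd$word
  ed <- x$edges[keep, , drop = FALSE]
  ig <- igraph::graph_from_data_frame(
    ed[, c("word1", "word2", "weight", "highlighted")],
    directed = FALSE,
    vertices = data.frame(name = nd$word, stringsAsFactors = FALSE)
  )
  b <- nd$betweenness
  size <- 8 + if (max(b) > 0) 22 * b / max(b) else 0
  ecol <- ifelse(igraph::E(ig)$highlighted %in% c(TRUE, 1),
                 grDevices::gray(0.2, alpha = 0.9),
                 grDevices::gray(0.6, alpha = 0.25))
  igraph::plot.igraph(
    ig,
    vertex.size = size,
    vertex.label = nd$word,
    vertex.color = "white",
    edge.color = ecol,
    edge.width = 0.5 + 2 * igraph::E(ig)$weight / max(c(igraph::E(ig)$weight, 1)),
    ...
  )
  invisible(x)
}
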