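# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths (and igraph) so agreement is a real check.

# --- exhaustive shortest-path betweenness -----------------------------------
# Enumerates every shortest path between every unordered node pair by
# breadth-first distances plus recursive backward path expansion. Only viable
# for small graphs, which is the point.
bf_betweenness <- function(words, edges) {
  n <- length(words)
  adj <- lapply(words, function(w) {
    c(edges$word2[edges$word1 == w], edges$word1[edges$word2 == w])
  })
  names(adj) <- words
  bet <- stats::setNames(numeric(n), words)
  if (n < 3L) return(bet)
  bfs_dist <- function(s) {
    d <- stats::setNames(rep(Inf, n), words)
    d[s] <- 0
    frontier <- s
    while (length(frontier)) {
      nxt <- character(0)
      for (u in frontier) {
        for (v in adj[[u]]) {
          if (is.infinite(d[v])) {
            d[v] <- d[u] + 1
            nxt <- c(nxt, v)
          }
        }
      }
      frontier <- unique(nxt)
    }
    d
  }
  all_paths <- function(s, t, d) {
    # all shortest s->t paths, built backward from t
    expand <- function(node) {
      if (node == s) return(list(s))
      preds <- adj[[node]][d[adj[[node]]] == d[node] - 1]
      out <- list()
      for (p in preds) {
        for (pp in expand(p)) out <- c(out, list(c(pp, node)))
      }
      out
    }
    expand(t)
  }
  for (i in seq_len(n - 1)) {
    d <- bfs_dist(words[i])
    for (j in (i + 1):n) {
      t <- words[j]
      if (is.infinite(d[t])) next
      paths <- all_paths(words[i], t, d)
      sigma <- length(paths)
      inner <- unlist(lapply(paths, function(p) p[-c(1, length(p))]))
      if (length(inner)) {
        cnt <- table(inner)
        bet[names(cnt)] <- bet[names(cnt)] + as.numeric(cnt) / sigma
      }
    }
  }
  bet
}

# random small graph as a word_graph-shaped fixture (no unit construction)
random_word_graph <- function(n_nodes, p_edge = 0.4) {
  words <- paste0("w", seq_len(n_nodes))
  pairs <- t(utils::combn(words, 2))
  keep <- stats::runif(nrow(pairs)) < p_edge
  edges <- data.frame(
    word1 = pairs[keep, 1], word2 = pairs[keep, 2],
    weight = sample.int(5L, sum(keep), replace = TRUE),
    highlighted = rep(NA, sum(keep)), stringsAsFactors = FALSE
  )
  make_word_graph(words, edges)
}

make_word_graph <- function(words, edges, freq = NULL) {
  structure(
    list(
      nodes = data.frame(
        word = words,
        frequency = if (is.null(freq)) rep.int(1L, length(words)) else freq,
        betweenness = NA_real_,
        displayed = TRUE,
        stringsAsFactors = FALSE
      ),
      edges = edges,
      subset = "fixture",
      config = network_config()
    ),
    class = "word_graph"
  )
}

# --- reference Benjamini-Hochberg step-up -----------------------------------
bh_reference <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  adj <- ps * m / seq_len(m)
  # enforce monotone non-decreasing from the largest rank down
  if (m >= 2) {
    for (i in (m - 1):1) adj[i] <- min(adj[i], adj[i + 1])
  }
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# --- definitional Krippendorff alpha (nominal) ------------------------------
# Straight from the definition: observed vs expected disagreement over all
# pairable value pairs, without building the package's coincidence matrix.
alpha_reference <- function(m) {
  vals <- as.vector(m)
  do_num <- 0; do_den <- 0
  pooled <- c()
  for (u in seq_len(nrow(m))) {
    v <- m[u, ]; v <- v[!is.na(v)]
    mu <- length(v)
    if (mu < 2) next
    pooled <- c(pooled, v)
    pairs <- utils::combn(mu, 2)
    # ordered pairable pairs: each unordered disagreement counts twice
    dis <- 2 * sum(v[pairs[1, ]] != v[pairs[2, ]])
    do_num <- do_num + dis / (mu - 1)
    do_den <- do_den + mu
  }
  Do <- do_num / do_den
  n <- length(pooled)
  tab <- table(pooled)
  De <- (n^2 - sum(tab^2)) / (n * (n - 1))
  1 - Do / De
}

# --- tiny corpus fixtures ----------------------------------------------------
write_corpus_fixture <- function(dir, texts, meta_extra = NULL, sep = ",") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  n <- length(texts)
  files <- sprintf("n%02d.txt", seq_len(n))
  for (i in seq_len(n)) {
    writeLines(texts[[i]], file.path(dir, files[i]), useBytes = TRUE)
  }
  meta <- data.frame(
    narrative_id = sprintf("N%02d", seq_len(n)),
    author_id = sprintf("A%02d", seq_len(n)),
    file = files,
    account_type = rep("FPA", n),
    stringsAsFactors = FALSE
  )
  if (!is.null(meta_extra)) for (nm in names(meta_extra)) meta[[nm]] <- meta_extra[[nm]]
  ext <- if (sep == ",") "metadata.csv" else "metadata.tsv"
  mp <- file.path(dir, ext)
  utils::write.table(meta, mp, sep = sep, row.names = FALSE, quote = TRUE)
  mp
}

# small two-category lexicon used by feature tests
tiny_lexicon <- function() {
  lexicon(list(
    pos_tone = c("good", "happy", "fine"),
    neg_tone = c("bad", "sad"),
    negate = c("not", "no", "never", "don't"),
    social = c("friend*")
  ), name = "tiny")
}
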