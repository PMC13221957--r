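#' Default per-token category emission rates
#'
#' One row per group, one column per emission category. The three named
#' groups mirror the study design (first-person accounts with and without
#' coded interpersonal difficulties, and third-person accounts); their tone,
#' social, and pronoun rates equal the published group means divided by 100,
#' so a generated corpus reproduces the study's feature structure in
#' expectation. Groups not named here fall back to the `FPA_noID` row, which
#' makes arbitrary group labels usable for simulation experiments.
#'
#' @return Numeric matrix, groups x categories.
#' @export
default_category_rates <- function() {
  cats <- c("pos_tone", "neg_tone", "social",
            "pron_i", "pron_we", "pron_you", "pron_shehe", "pron_they",
            "ipron", "article", "prep", "auxverb", "conj", "adverb",
            "negate", "exclusive")
  m <- rbind(
    FPA_ID   = c(0.0242, 0.0253, 0.0836, 0.0922, 0.0037, 0.0032, 0.0084,
                 0.0074, 0.055, 0.06, 0.11, 0.08, 0.05, 0.04, 0.012, 0.008),
    FPA_noID = c(0.0282, 0.0217, 0.0840, 0.0802, 0.0035, 0.0044, 0.0065,
                 0.0076, 0.051, 0.06, 0.11, 0.08, 0.05, 0.04, 0.012, 0.008),
    TPA      = c(0.0259, 0.0236, 0.1463, 0.0430, 0.0114, 0.0026, 0.0445,
                 0.0072, 0.042, 0.06, 0.11, 0.08, 0.05, 0.04, 0.012, 0.008)
  )
  colnames(m) <- cats
  m
}

#' Default narrative length distributions (log-normal, tokens)
#'
#' Parameters chosen so the mean and dispersion of generated token counts
#' match the published word-count means and SDs per group (interpersonal
#' difficulties narratives are about twice as long as those without).
#'
#' @return Named list of `c(meanlog, sdlog)` per group.
#' @export
default_length_distribution <- function() {
  list(
    FPA_ID   = c(meanlog = 7.90, sdlog = 0.906),
    FPA_noID = c(meanlog = 7.47, sdlog = 0.538),
    TPA      = c(meanlog = 7.73, sdlog = 0.562)
  )
}

#' Specification for a synthetic narrative corpus
#'
#' The generator emits per-token category draws with group-specific rates
#' over the word lists of a lexicon, inserts negations before emotion
#' tokens, assembles sentences of 8-15 tokens, and draws narrative lengths
#' from log-normal distributions. Defaults reproduce the study design: group
#' sizes 56 (FPA with interpersonal difficulties), 77 (FPA without), 44
#' (TPA), study-scale lengths, and published group mean rates.
#'
#' @param n_per_group Named integer vector of narratives per group.
#' @param length_distribution Either a single `c(meanlog, sdlog)` used for
#'   all groups or a named list per group ([default_length_distribution()]).
#' @param category_rates Groups x categories matrix of per-token emission
#'   probabilities ([default_category_rates()]); rows for groups missing
#'   from the matrix fall back to the `FPA_noID` row.
#' @param rate_jitter_cv Between-narrative heterogeneity: each narrative's
#'   rate for category k is `rate_k * (1 + cv * Z)` truncated at 0.
#' @param negation_rate Probability that an emitted emotion token is
#'   immediately preceded by an inserted negation ("not"). Default 0.002,
#'   matching the rarity of negated emotions in published essays.
#' @param planted_effects List of planted standardized group differences,
#'   each `list(variable =, groups = c(g1, g2), d =)`: the two groups' base
#'   rates for `variable` are moved apart so the expected Cohen's d of the
#'   category percentage equals `d` (positive d means g1 higher).
#' @param bridge_plan Cluster plan for [generate_bridge_corpus()]: list with
#'   `cluster_a`, `cluster_b` (word vectors), `bridge` (a word in neither
#'   cluster), `leak` (probability a sentence mixes both clusters),
#'   `n_sentences`, `bridge_rate` (probability a sentence carries the
#'   bridge word).
#' @param rater_plan List with `n_raters`, `accuracy` (in `[0.5, 1]`),
#'   `base_rate` for [generate_rater_codes()].
#' @param seed Integer master seed; per-narrative substreams are derived by
#'   counter so a narrative's text does not depend on how many narratives
#'   are generated.
#' @param lexicon Lexicon whose literal word lists supply the emission
#'   vocabulary (default [base_lexicon()]).
#' @return A list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_per_group = c(FPA_ID = 56, FPA_noID = 77, TPA = 44),
                           length_distribution = default_length_distribution(),
                           category_rates = default_category_rates(),
                           rate_jitter_cv = 0.2,
                           negation_rate = 0.002,
                           planted_effects = list(),
                           bridge_plan = default_bridge_plan(),
                           rater_plan = list(n_raters = 3, accuracy = 0.9,
                                             base_rate = 56 / 133),
                           seed = 1L,
                           lexicon = base_lexicon()) {
  if (is.null(names(n_per_group)) || any(!nzchar(names(n_per_group)))) {
    stop("n_per_group must be a named vector of group sizes")
  }
  if (negation_rate < 0 || negation_rate > 1) stop("negation_rate must be in [0, 1]")
  if (!is.null(bridge_plan)) {
    if (bridge_plan$leak >= 1) stop("bridge leak probability must be < 1")
    if (bridge_plan$bridge %in% c(bridge_plan$cluster_a, bridge_plan$cluster_b)) {
      stop("bridge word must belong to neither cluster")
    }
  }
  rates <- resolve_rates(names(n_per_group), category_rates)
  bad <- rowSums(rates) > 1
  if (any(bad)) {
    stop("infeasible category rates (sum > 1) for group: ",
         paste(rownames(rates)[bad], collapse = ", "))
  }
  structure(
    list(
      n_per_group = n_per_group,
      length_distribution = length_distribution,
      category_rates = rates,
      rate_jitter_cv = rate_jitter_cv,
      negation_rate = negation_rate,
      planted_effects = planted_effects,
      bridge_plan = bridge_plan,
      rater_plan = rater_plan,
      seed = as.integer(seed),
      lexicon = lexicon
    ),
    class = "synthetic_spec"
  )
}

#' @export
print.synthetic_spec <- function(x, ...) {
  cat("<synthetic_spec>", sum(x$n_per_group), "narratives in",
      length(x$n_per_group), "groups (",
      paste(names(x$n_per_group), x$n_per_group, sep = "=", collapse = ", "),
      "), seed", x$seed, "\n")
  if (length(x$planted_effects)) {
    for (pe in x$planted_effects) {
      cat("  planted:", pe$variable, "d =", pe$d, "between",
          paste(pe$groups, collapse = " vs "), "\n")
    }
  }
  invisible(x)
}

#' Default planted-bridge plan
#'
#' Two eight-word topic clusters (treatment/hospital and social life) joined
#' only by the bridge word "voices", mirroring the kind of semantic-bridge
#' structure a betweenness ranking is meant to recover.
#'
#' @param leak Probability a sentence mixes both clusters (default 0).
#' @param n_sentences Number of sentences (default 200).
#' @param bridge_rate Probability a sentence carries the bridge word
#'   (default 0.3).
#' @return A bridge plan list.
#' @export
default_bridge_plan <- function(leak = 0, n_sentences = 200L, bridge_rate = 0.3) {
  list(
    cluster_a = c("hospital", "medication", "treatment", "nurse",
                  "ward", "therapy", "clinic", "recovery"),
    cluster_b = c("friends", "family", "school", "work",
                  "neighbors", "church", "community", "marriage"),
    bridge = "voices",
    leak = leak,
    n_sentences = as.integer(n_sentences),
    bridge_rate = bridge_rate
  )
}

resolve_rates <- function(groups, category_rates) {
  fallback <- if ("FPA_noID" %in% rownames(category_rates)) {
    category_rates["FPA_noID", ]
  } else {
    category_rates[1, ]
  }
  out <- t(vapply(groups, function(g) {
    if (g %in% rownames(category_rates)) category_rates[g, ] else fallback
  }, numeric(ncol(category_rates))))
  colnames(out) <- colnames(category_rates)
  rownames(out) <- groups
  out
}

resolve_lengths <- function(groups, length_distribution) {
  if (is.numeric(length_distribution)) {
    ld <- lapply(groups, function(g) length_distribution)
  } else {
    fallback <- length_distribution[["FPA_noID"]] %||% length_distribution[[1]]
    ld <- lapply(groups, function(g) length_distribution[[g]] %||% fallback)
  }
  names(ld) <- groups
  ld
}

# literal (non-wildcard) word lists per emission category; the categories
# used for emission must be pairwise disjoint so rates stay controllable.
emission_lists <- function(lex, cats) {
  lists <- lapply(cats, function(k) {
    pats <- lex$categories[[k]]
    if (is.null(pats)) stop("lexicon lacks emission category: ", k)
    pats[!endsWith(pats, "*")]
  })
  names(lists) <- cats
  all <- unlist(lists, use.names = FALSE)
  if (anyDuplicated(all)) {
    stop("emission categories overlap: ",
         paste(unique(all[duplicated(all)]), collapse = ", "))
  }
  lists
}

#' Closed filler vocabulary
#'
#' 500 pronounceable pseudo-words built deterministically from syllables and
#' guaranteed to match no lexicon category, no stopword, and no numeral, so
#' filler tokens never leak into category percentages.
#'
#' @param lex Lexicon to stay disjoint from.
#' @param n Number of filler words (default 500).
#' @return Character vector of filler words.
#' @export
filler_vocabulary <- function(lex = base_lexicon(), n = 500L) {
  key <- paste(lex$name, lex$version, n, sep = "|")
  cached <- get0(key, envir = .lexnet_cache, ifnotfound = NULL)
  if (!is.null(cached)) return(cached)
  cons <- c("b", "d", "f", "g", "k", "l", "m", "n", "p", "r", "s", "t", "v", "z")
  vow <- c("a", "e", "i", "o", "u")
  syl <- as.vector(outer(cons, vow, paste0))
  words <- as.vector(outer(outer(syl, syl, paste0), syl[1:3], paste0))
  stop_set <- default_stopwords()
  hits <- category_hits(words, lex)
  any_hit <- Reduce(`|`, hits)
  w <- words[!any_hit & !(words %in% stop_set)]
  if (length(w) < n) stop("filler vocabulary exhausted")
  w <- w[seq_len(n)]
  assign(key, w, envir = .lexnet_cache)
  w
}

.lexnet_cache <- new.env(parent = emptyenv())

# counter-derived substream seed, kept below 2^31
derive_seed <- function(seed, counter) {
  as.integer((as.double(seed %% 65011) * 33013 + counter * 7919) %% 2147483629)
}

#' Generate a synthetic corpus with known ground truth
#'
#' Per narrative: token count drawn from the group's log-normal length
#' distribution (floored at 16), tokens emitted by jittered group category
#' rates over the lexicon word lists with filler for the remainder,
#' negations inserted before emotion tokens at `negation_rate` (inside the
#' same sentence), and sentences of 8-15 tokens. Deterministic for a fixed
#' spec seed; each narrative uses a counter-derived substream so corpora are
#' stable under changes to the number of narratives.
#'
#' @param spec A [synthetic_spec()].
#' @return List with `corpus` (a [corpus_table()] with an extra `group`
#'   column) and `truth` (data frame of per-narrative group, token count,
#'   realized per-category emission rates).
#' @export
generate_corpus <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  groups <- names(spec$n_per_group)
  rates <- apply_planted_effects(spec)
  cats <- colnames(rates)
  emis <- emission_lists(spec$lexicon, cats)
  filler <- filler_vocabulary(spec$lexicon)
  lds <- resolve_lengths(groups, spec$length_distribution)
  tone_cats <- intersect(c("pos_tone", "neg_tone"), cats)
  counter <- 0L
  recs <- list()
  truth <- list()
  for (g in groups) {
    for (j in seq_len(spec$n_per_group[[g]])) {
      counter <- counter + 1L
      nar <- generate_narrative(
        rates = rates[g, ], emis = emis, filler = filler,
        ld = lds[[g]], cv = spec$rate_jitter_cv,
        negation_rate = spec$negation_rate, tone_cats = tone_cats,
        seed = derive_seed(spec$seed, counter)
      )
      id <- sprintf("%s_%03d", g, j)
      recs[[counter]] <- list(
        narrative_id = id, group = g, text = nar$text,
        account_type = if (startsWith(g, "TPA")) "TPA" else "FPA",
        idc = if (g == "FPA_ID") TRUE else if (g == "FPA_noID") FALSE else NA
      )
      truth[[counter]] <- c(list(narrative_id = id, group = g,
                                 n_tokens = nar$n_tokens),
                            as.list(nar$realized_rates))
    }
  }
  corpus <- corpus_table(
    narrative_id = vapply(recs, `[[`, character(1), "narrative_id"),
    author_id = vapply(recs, `[[`, character(1), "narrative_id"),
    text = vapply(recs, `[[`, character(1), "text"),
    account_type = vapply(recs, `[[`, character(1), "account_type"),
    interpersonal_difficulties = vapply(recs, `[[`, logical(1), "idc"),
    provenance = sprintf("synthetic corpus, seed %d", spec$seed)
  )
  corpus$group <- vapply(recs, `[[`, character(1), "group")
  truth_df <- do.call(rbind, lapply(truth, function(r) {
    as.data.frame(r, stringsAsFactors = FALSE)
  }))
  list(corpus = corpus, truth = truth_df)
}

# move the two named groups' base rates apart so the expected standardized
# difference of the measured category percentage equals d
apply_planted_effects <- function(spec) {
  rates <- spec$category_rates
  if (!length(spec$planted_effects)) return(rates)
  lds <- resolve_lengths(rownames(rates), spec$length_distribution)
  for (pe in spec$planted_effects) {
    v <- pe$variable
    g <- pe$groups
    if (!v %in% colnames(rates)) stop("unknown planted variable: ", v)
    if (!all(g %in% rownames(rates))) stop("unknown planted group")
    r0 <- mean(rates[g, v])
    einv <- mean(vapply(g, function(gg) {
      p <- lds[[gg]]
      exp(-p[["meanlog"]] + p[["sdlog"]]^2 / 2)
    }, numeric(1)))
    sd_pct <- 100 * sqrt((spec$rate_jitter_cv * r0)^2 + r0 * (1 - r0) * einv)
    delta_rate <- pe$d * sd_pct / 100
    rates[g[1], v] <- r0 + delta_rate / 2
    rates[g[2], v] <- r0 - delta_rate / 2
    if (any(rates[g, v] < 0)) stop("planted effect drives a rate below 0")
  }
  rates
}

generate_narrative <- function(rates, emis, filler, ld, cv, negation_rate,
                               tone_cats, seed) {
  old <- local_seed(seed)
  on.exit(restore_seed(old))
  L <- max(16L, as.integer(round(stats::rlnorm(1, ld[["meanlog"]], ld[["sdlog"]]))))
  K <- length(rates)
  r <- rates * pmax(0, 1 + cv * stats::rnorm(K))
  s <- sum(r)
  if (s > 0.95) r <- r * 0.95 / s
  cat_idx <- sample.int(K + 1L, L, replace = TRUE, prob = c(r, 1 - sum(r)))
  words <- character(L)
  for (k in seq_len(K)) {
    ix <- which(cat_idx == k)
    if (length(ix)) words[ix] <- sample(emis[[k]], length(ix), replace = TRUE)
  }
  ixf <- which(cat_idx == K + 1L)
  if (length(ixf)) words[ixf] <- sample(filler, length(ixf), replace = TRUE)
  # sentence assignment: lengths 8-15 tokens
  lens <- sample(8:15, ceiling(L / 8), replace = TRUE)
  sent <- rep.int(seq_along(lens), lens)[seq_len(L)]
  # negation insertion before emotion tokens, same sentence
  tone_ids <- match(tone_cats, names(rates))
  emo <- which(cat_idx %in% tone_ids)
  ins <- if (length(emo)) emo[stats::runif(length(emo)) < negation_rate] else integer(0)
  flag <- logical(L)
  flag[ins] <- TRUE
  shift <- cumsum(flag)
  out_n <- L + sum(flag)
  out_words <- character(out_n)
  out_sent <- integer(out_n)
  tgt <- seq_len(L) + shift
  out_words[tgt] <- words
  out_sent[tgt] <- sent
  if (length(ins)) {
    nt <- tgt[ins] - 1L
    out_words[nt] <- "not"
    out_sent[nt] <- sent[ins]
  }
  text <- paste(
    vapply(split(out_words, out_sent),
           function(w) paste0(paste(w, collapse = " "), "."),
           character(1)),
    collapse = " "
  )
  realized <- tabulate(cat_idx, nbins = K) / L
  names(realized) <- names(rates)
  list(text = text, n_tokens = out_n, realized_rates = realized)
}

#' Generate a corpus with a planted semantic bridge
#'
#' Each sentence draws its words from cluster A or cluster B (choosing by a
#' fair coin), never both except with probability `leak`; the bridge word is
#' added to sentences of both clusters at rate `bridge_rate`. With zero leak
#' every shortest path between the clusters passes through the bridge word,
#' so it must attain the highest betweenness centrality.
#'
#' @param spec A [synthetic_spec()] whose `bridge_plan` is set
#'   ([default_bridge_plan()]).
#' @return A [corpus_table()] with one narrative containing all sentences.
#' @export
generate_bridge_corpus <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  bp <- spec$bridge_plan
  if (is.null(bp)) stop("spec has no bridge_plan")
  if (bp$leak >= 1) stop("bridge leak probability must be < 1")
  old <- local_seed(derive_seed(spec$seed, 999983L))
  on.exit(restore_seed(old))
  sentences <- character(bp$n_sentences)
  for (i in seq_len(bp$n_sentences)) {
    mixed <- stats::runif(1) < bp$leak
    if (mixed) {
      pool_a <- sample(bp$cluster_a, min(3L, length(bp$cluster_a)))
      pool_b <- sample(bp$cluster_b, min(3L, length(bp$cluster_b)))
      w <- c(pool_a, pool_b)
    } else {
      cl <- if (stats::runif(1) < 0.5) bp$cluster_a else bp$cluster_b
      w <- sample(cl, min(sample(4:6, 1), length(cl)))
    }
    if (stats::runif(1) < bp$bridge_rate) w <- c(w, bp$bridge)
    sentences[i] <- paste0(paste(sample(w), collapse = " "), ".")
  }
  corpus_table(
    narrative_id = "bridge_001",
    author_id = "bridge_001",
    text = paste(sentences, collapse = " "),
    account_type = "FPA",
    provenance = sprintf("synthetic bridge corpus, leak %.2f, seed %d",
                         bp$leak, spec$seed)
  )
}

#' Generate multi-rater binary codings with controlled accuracy
#'
#' Each rater independently reports the true label with probability
#' `accuracy` and the flipped label otherwise. `accuracy = 1` gives perfect
#' agreement (alpha 1); `accuracy = 0.5` gives chance-level coding
#' (alpha near 0).
#'
#' @param true_labels Logical (or 0/1) vector of true item labels.
#' @param n_raters Number of raters (>= 2).
#' @param accuracy Per-rater accuracy in `[0.5, 1]`.
#' @param seed Integer seed.
#' @return A [rater_coding_table()] (items x raters, integer 0/1 codes).
#' @export
generate_rater_codes <- function(true_labels, n_raters = 3L, accuracy = 0.9,
                                 seed = 1L) {
  if (accuracy < 0.5 || accuracy > 1) stop("accuracy must be in [0.5, 1]")
  if (n_raters < 2L) stop("at least 2 raters required")
  truth <- as.integer(as.logical(true_labels))
  old <- local_seed(seed)
  on.exit(restore_seed(old))
  n <- length(truth)
  m <- matrix(NA_integer_, n, n_raters,
              dimnames = list(sprintf("item_%04d", seq_len(n)),
                              sprintf("rater_%d", seq_len(n_raters))))
  for (r in seq_len(n_raters)) {
    keep <- stats::runif(n) < accuracy
    m[, r] <- ifelse(keep, truth, 1L - truth)
  }
  rater_coding_table(m)
}
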