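#' Percentage of tokens matching a lexicon category
#'
#' Computes `100 * matching / total` where matches are counted per token
#' occurrence (a repeated word counts each time) and a token may count toward
#' several categories.
#'
#' @param stream A [tokenize()] result.
#' @param lex A [lexicon()].
#' @param category Category name; must exist in `lex` (a missing category is
#'   an error, an existing category with no matching tokens gives 0).
#' @return Percentage in `[0, 100]`.
#' @export
category_percent <- function(stream, lex, category) {
  stopifnot(inherits(stream, "token_stream"), inherits(lex, "lexicon"))
  if (!category %in% names(lex$categories)) {
    stop("unknown lexicon category: ", category)
  }
  n <- length(stream$tokens)
  if (n == 0L) {
    stop("undefined feature: empty token stream",
         if (!is.na(stream$narrative_id)) paste0(" [", stream$narrative_id, "]"))
  }
  hits <- category_hits(stream$tokens, lex)[[category]]
  100 * sum(hits) / n
}

#' Locate negated emotion tokens
#'
#' An emotion token (positive or negative tone) counts as negated when a
#' negation token occurs within `window` tokens before it inside the same
#' sentence, mirroring constructions like "not good". Each negated emotion
#' occurrence is reported once.
#'
#' @param stream A [tokenize()] result.
#' @param lex A [lexicon()] with categories `pos_tone`, `neg_tone`, and
#'   `negate`.
#' @param window Number of preceding tokens scanned for a negation (default 3).
#' @return A data frame with columns `position` (1-based token index),
#'   `category` (`"pos_tone"` or `"neg_tone"`; a token in both tone
#'   categories yields two rows).
#' @export
find_negated_emotions <- function(stream, lex, window = 3L) {
  stopifnot(inherits(stream, "token_stream"), inherits(lex, "lexicon"))
  need <- c("pos_tone", "neg_tone", "negate")
  miss <- setdiff(need, names(lex$categories))
  if (length(miss)) stop("lexicon lacks categories: ", paste(miss, collapse = ", "))
  hits <- category_hits(stream$tokens, lex)
  neg_pos <- which(hits$negate)
  out_pos <- integer(0)
  out_cat <- character(0)
  for (cat in c("pos_tone", "neg_tone")) {
    emo <- which(hits[[cat]])
    if (!length(emo) || !length(neg_pos)) next
    for (p in emo) {
      lo <- max(1L, p - as.integer(window))
      prior <- neg_pos[neg_pos >= lo & neg_pos < p]
      prior <- prior[stream$sentence_index[prior] == stream$sentence_index[p]]
      if (length(prior)) {
        out_pos <- c(out_pos, p)
        out_cat <- c(out_cat, cat)
      }
    }
  }
  data.frame(position = out_pos, category = out_cat, stringsAsFactors = FALSE)
}

#' Negation-adjusted emotional tone
#'
#' Positive and negative tone percentages after removing negated emotion
#' occurrences from the numerator; the denominator stays the total token
#' count. "Not good" therefore contributes to neither tone, rather than being
#' scored as positive.
#'
#' @inheritParams find_negated_emotions
#' @return A list with `pos_tone`, `neg_tone` (percentages) and
#'   `negation_case_count` (number of distinct negated emotion occurrences).
#' @export
adjusted_tone <- function(stream, lex, window = 3L) {
  n <- length(stream$tokens)
  if (n == 0L) stop("undefined feature: empty token stream")
  hits <- category_hits(stream$tokens, lex)
  neg <- find_negated_emotions(stream, lex, window)
  drop_pos <- neg$position[neg$category == "pos_tone"]
  drop_neg <- neg$position[neg$category == "neg_tone"]
  pos_n <- sum(hits$pos_tone) - length(unique(drop_pos))
  neg_n <- sum(hits$neg_tone) - length(unique(drop_neg))
  list(
    pos_tone = 100 * pos_n / n,
    neg_tone = 100 * neg_n / n,
    negation_case_count = length(unique(neg$position))
  )
}

# Built-in closed-class pronoun lists used by pronoun_percents(); identical to
# the pron_* categories of the packaged lexicon.
pronoun_classes <- function() {
  list(
    I = c("i", "me", "my", "mine", "myself"),
    we = c("we", "us", "our", "ours", "ourselves"),
    you = c("you", "your", "yours", "yourself", "yourselves"),
    she_he = c("she", "her", "hers", "herself", "he", "him", "his", "himself"),
    they = c("they", "them", "their", "theirs", "themselves")
  )
}

#' Specific pronoun class percentages
#'
#' Percentage of tokens in each of the five pronoun classes (I, we, you,
#' she/he, they), using built-in closed word lists.
#'
#' @param stream A [tokenize()] result.
#' @return Named numeric vector with elements `I`, `we`, `you`, `she_he`,
#'   `they`.
#' @export
pronoun_percents <- function(stream) {
  stopifnot(inherits(stream, "token_stream"))
  n <- length(stream$tokens)
  if (n == 0L) stop("undefined feature: empty token stream")
  vapply(
    pronoun_classes(),
    function(w) 100 * sum(stream$tokens %in% w) / n,
    numeric(1)
  )
}

#' Default coefficients of the surrogate summary scores
#'
#' The Analytic, Clout, and Authenticity scores of commercial text-analysis
#' software are proprietary regression composites. This package ships open,
#' documented linear surrogates over category percentages, clamped to
#' `[0, 100]`:
#'
#' * `analytic = 30 + article + prep - ppron - ipron - auxverb - conj -
#'   adverb - negate` (a categorical-versus-dynamic function-word index);
#' * `clout = 45 + 6*we + 6*you - 4*I - 2*negate` (rises with
#'   other-oriented pronouns, falls with self-reference and negation);
#' * `authentic = 40 + 5*I + 2*exclusive - 4*she_he` (rises with
#'   self-reference and exclusive words, falls with third-person narration).
#'
#' Any output carrying these scores is labeled
#' `"surrogate, not proprietary LIWC"`. Coefficients are configuration: pass
#' a modified copy of this list to [summary_scores()] or
#' [compute_features()].
#'
#' @return A list with components `analytic`, `clout`, `authentic`, each a
#'   named vector of coefficients plus an `(Intercept)` term, and `label`.
#' @export
summary_coefficients <- function() {
  list(
    analytic = c(`(Intercept)` = 30, article = 1, prep = 1, ppron = -1,
                 ipron = -1, auxverb = -1, conj = -1, adverb = -1, negate = -1),
    clout = c(`(Intercept)` = 45, pron_we = 6, pron_you = 6, pron_i = -4,
              negate = -2),
    authentic = c(`(Intercept)` = 40, pron_i = 5, exclusive = 2,
                  pron_shehe = -4),
    label = "surrogate, not proprietary LIWC"
  )
}

#' Surrogate summary scores from category percentages
#'
#' @param percents Named numeric vector of category percentages (as produced
#'   by [compute_features()]; must cover every category named in the
#'   coefficient vectors).
#' @param coefficients Coefficient configuration, see
#'   [summary_coefficients()].
#' @return Named numeric vector `analytic`, `clout`, `authentic`, each
#'   clamped to `[0, 100]`.
#' @export
summary_scores <- function(percents, coefficients = summary_coefficients()) {
  score_one <- function(beta) {
    vars <- setdiff(names(beta), "(Intercept)")
    miss <- setdiff(vars, names(percents))
    if (length(miss)) {
      stop("summary score configuration error: missing categories ",
           paste(miss, collapse = ", "))
    }
    val <- beta[["(Intercept)"]] + sum(beta[vars] * percents[vars])
    min(100, max(0, val))
  }
  c(
    analytic = score_one(coefficients$analytic),
    clout = score_one(coefficients$clout),
    authentic = score_one(coefficients$authentic)
  )
}

#' Per-narrative linguistic feature table
#'
#' Tokenizes every narrative and computes the full feature vector: word
#' count, all lexicon category percentages (with `pos_tone` and `neg_tone`
#' negation-adjusted; the raw tone percentages are kept as
#' `pos_tone_unadjusted` / `neg_tone_unadjusted`), the five specific pronoun
#' percentages (`pron_I`, `pron_we`, `pron_you`, `pron_she_he`,
#' `pron_they`), the three surrogate summary scores, and the negated-emotion
#' occurrence count.
#'
#' Narratives that tokenize to zero tokens are skipped with a warning.
#' Narratives shorter than `min_tokens` are flagged in the `short` column but
#' retained.
#'
#' @param corpus A [corpus_table()].
#' @param lex A [lexicon()], default [base_lexicon()].
#' @param window Negation window passed to [adjusted_tone()].
#' @param coefficients Summary-score configuration
#'   ([summary_coefficients()]).
#' @param min_tokens Length floor below which a narrative is flagged (not
#'   dropped); default 25.
#' @return A data frame, one row per (retained) narrative, with attribute
#'   `summary_score_label` recording the surrogate labeling.
#' @export
compute_features <- function(corpus, lex = base_lexicon(), window = 3L,
                             coefficients = summary_coefficients(),
                             min_tokens = 25L) {
  stopifnot(inherits(corpus, "corpus_table"))
  cats <- names(lex$categories)
  rows <- vector("list", nrow(corpus))
  kept <- logical(nrow(corpus))
  for (i in seq_len(nrow(corpus))) {
    st <- tokenize(corpus$text[i], narrative_id = corpus$narrative_id[i])
    n <- length(st$tokens)
    if (n == 0L) {
      warning("skipping narrative with no tokens: ", corpus$narrative_id[i])
      next
    }
    hits <- category_hits(st$tokens, lex)
    pct <- vapply(hits, function(h) 100 * sum(h) / n, numeric(1))
    tone <- adjusted_tone(st, lex, window)
    pct_adj <- pct
    pct_adj[["pos_tone"]] <- tone$pos_tone
    pct_adj[["neg_tone"]] <- tone$neg_tone
    pron <- pronoun_percents(st)
    ss <- summary_scores(pct_adj, coefficients)
    rows[[i]] <- c(
      list(
        narrative_id = corpus$narrative_id[i],
        word_count = n
      ),
      as.list(pct_adj),
      list(
        pos_tone_unadjusted = pct[["pos_tone"]],
        neg_tone_unadjusted = pct[["neg_tone"]],
        pron_I = unname(pron["I"]),
        pron_we = unname(pron["we"]),
        pron_you = unname(pron["you"]),
        pron_she_he = unname(pron["she_he"]),
        pron_they = unname(pron["they"]),
        analytic = unname(ss["analytic"]),
        clout = unname(ss["clout"]),
        authentic = unname(ss["authentic"]),
        negation_case_count = tone$negation_case_count,
        short = n < min_tokens
      )
    )
    kept[i] <- TRUE
  }
  out <- do.call(rbind, lapply(rows[kept], function(r) {
    as.data.frame(r, stringsAsFactors = FALSE, check.names = FALSE)
  }))
  if (is.null(out)) {
    stop("no narrative produced any tokens; cannot compute features")
  }
  rownames(out) <- NULL
  attr(out, "summary_score_label") <- coefficients$label
  attr(out, "lexicon") <- paste0(lex$name, " v", lex$version)
  out
}

#' Write a feature table to CSV
#'
#' Percentages are written at full precision; a `#`-prefixed comment line
#' records the lexicon and the surrogate labeling of the summary scores.
#'
#' @param features Result of [compute_features()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_features_csv <- function(features, path) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(sprintf(
    "# lexnet features; lexicon=%s; summary scores: %s",
    attr(features, "lexicon") %||% "unknown",
    attr(features, "summary_score_label") %||% "surrogate, not proprietary LIWC"
  ), con)
  utils::write.csv(features, con, row.names = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
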