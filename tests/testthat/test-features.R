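test_that("category_percent counts per-occurrence matches over total tokens", {
  lex <- tiny_lexicon()
  expect_equal(category_percent(tokenize("i am sad"), lex, "neg_tone"),
               100 / 3)
  # wildcard category
  expect_equal(category_percent(tokenize("my friends are good friends"),
                                lex, "social"), 40)
  expect_error(category_percent(tokenize(""), lex, "pos_tone"), "empty")
})

test_that("I-word share of the quoted interpersonal sentence matches a hand count", {
  # "I want friends, but I don't know how to make them." tokenizes to 11
  # tokens of which 2 are "i": 2/11 = 18.1818...%
  st <- tokenize("I want friends, but I don’t know how to make them.")
  expect_length(st$tokens, 11)
  expect_equal(category_percent(st, base_lexicon(), "pron_i"),
               100 * 2 / 11, tolerance = 1e-12)
})

test_that("negated emotions are detected within the window and sentence", {
  lex <- tiny_lexicon()
  hits <- find_negated_emotions(tokenize("not good"), lex)
  expect_equal(hits$position, 2L)
  expect_equal(hits$category, "pos_tone")

  # scope: only the emotion following the negation is flagged
  hits2 <- find_negated_emotions(tokenize("good, not bad"), lex, window = 3)
  expect_equal(hits2$category, "neg_tone")
  expect_equal(hits2$position, 3L)

  # sentence boundary blocks negation scope
  hits3 <- find_negated_emotions(tokenize("not. good"), lex)
  expect_equal(nrow(hits3), 0L)

  # window limit: negation 4 tokens back is out of scope at window 3
  hits4 <- find_negated_emotions(tokenize("not one two three good"), lex, window = 3)
  expect_equal(nrow(hits4), 0L)
  hits5 <- find_negated_emotions(tokenize("not one two good"), lex, window = 3)
  expect_equal(nrow(hits5), 1L)
})

test_that("adjusted tone excludes negated occurrences from the numerator only", {
  lex <- tiny_lexicon()
  t1 <- adjusted_tone(tokenize("i am not good"), lex)
  expect_equal(t1$pos_tone, 0)
  expect_equal(t1$negation_case_count, 1L)

  t2 <- adjusted_tone(tokenize("i am good"), lex)
  expect_equal(t2$pos_tone, 100 / 3)
  expect_equal(t2$negation_case_count, 0L)

  # all emotion tokens negated -> both tones exactly 0
  t3 <- adjusted_tone(tokenize("not good and not bad and not sad"), lex)
  expect_equal(t3$pos_tone, 0)
  expect_equal(t3$neg_tone, 0)

  # adjusted <= unadjusted always, equality iff no negated case touches it
  st <- tokenize("good things but not good days and sad nights")
  adj <- adjusted_tone(st, lex)
  expect_lt(adj$pos_tone, category_percent(st, lex, "pos_tone"))
  expect_equal(adj$neg_tone, category_percent(st, lex, "neg_tone"))
})

test_that("pronoun class percentages match hand tallies", {
  expect_equal(unname(pronoun_percents(tokenize("she helped him"))["she_he"]),
               100 * 2 / 3)
  expect_equal(unname(pronoun_percents(tokenize("i i i"))["I"]), 100)
  # 20-token mixed fixture: 3 I-class, 1 we, 1 you, 1 she_he, 2 they
  st <- tokenize(
    "i saw her and we talked. you and they came to me today. my house was near theirs okay then."
  )
  expect_length(st$tokens, 20)
  pp <- pronoun_percents(st)
  expect_equal(unname(pp), c(15, 5, 5, 5, 10))
})

test_that("surrogate summary scores follow their documented formulas", {
  zeros <- stats::setNames(
    rep(0, 12),
    c("article", "prep", "ppron", "ipron", "auxverb", "conj", "adverb",
      "negate", "pron_i", "pron_we", "pron_you", "pron_shehe")
  )
  zeros["exclusive"] <- 0
  s0 <- summary_scores(zeros)
  expect_equal(unname(s0["analytic"]), 30)

  p2 <- zeros
  p2["article"] <- 10; p2["prep"] <- 10
  expect_equal(unname(summary_scores(p2)["analytic"]), 50)

  # monotonicity: more I-words lowers clout, raises authenticity
  lo <- zeros; lo["pron_i"] <- 2
  hi <- zeros; hi["pron_i"] <- 8
  expect_lt(summary_scores(hi)["clout"], summary_scores(lo)["clout"])
  expect_gt(summary_scores(hi)["authentic"], summary_scores(lo)["authentic"])

  expect_error(summary_scores(zeros[1:3]), "missing categories")
})

test_that("feature percentages are invariant to text repetition; word count doubles", {
  lex <- base_lexicon()
  corpus1 <- corpus_table("n1", "a1", "I was sad but my friends helped me. Not bad now.", "FPA")
  txt2 <- paste(corpus1$text, corpus1$text, sep = " ")
  corpus2 <- corpus_table("n1", "a1", txt2, "FPA")
  f1 <- compute_features(corpus1, lex)
  f2 <- compute_features(corpus2, lex)
  expect_equal(f2$word_count, 2L * f1$word_count)
  pct_cols <- c(names(lex$categories), "pron_I", "pron_we", "analytic",
                "clout", "authentic")
  for (cl in pct_cols) expect_equal(f2[[cl]], f1[[cl]], tolerance = 1e-12)
  expect_equal(f2$negation_case_count, 2L * f1$negation_case_count)
})

test_that("disjoint category percentages sum to at most 100", {
  lex <- base_lexicon()
  spec <- synthetic_spec(n_per_group = c(A = 4),
                         length_distribution = c(meanlog = log(120), sdlog = 0.4),
                         seed = 11)
  gen <- generate_corpus(spec)
  f <- compute_features(gen$corpus, lex)
  disjoint <- c("pos_tone", "neg_tone", "social", "article", "prep",
                "auxverb", "conj", "adverb", "exclusive",
                "pron_i", "pron_we", "pron_you", "pron_shehe", "pron_they",
                "ipron")
  expect_true(all(rowSums(f[, disjoint]) <= 100))
})

test_that("category percent ignores sentence segmentation but adjusted tone does not", {
  lex <- tiny_lexicon()
  one <- tokenize("we were not good friends today")
  two <- tokenize("we were not. good friends today")
  expect_equal(category_percent(one, lex, "pos_tone"),
               category_percent(two, lex, "pos_tone"))
  expect_lt(adjusted_tone(one, lex)$pos_tone, adjusted_tone(two, lex)$pos_tone)
})
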