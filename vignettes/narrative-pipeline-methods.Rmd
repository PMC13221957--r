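---
title: "Methods: linguistic features, group inference, and word networks for illness narratives"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: linguistic features, group inference, and word networks for illness narratives}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lexnet)
```

lexnet implements a complete quantitative workflow for comparing groups of
illness narratives: per-narrative dictionary features, variance-gated group
comparisons with false-discovery-rate control, inter-rater reliability for
the human codes that define the groups, and word co-occurrence networks
whose betweenness ranking surfaces "bridge" themes. This vignette explains
the models and procedures, the tunable parameters and their defaults, what
the synthetic generator does and does not emulate, and the numerical and
design choices made where the method description left room.

## Corpus model

A corpus is a table of narratives, each with an author, an account type
(first-person, FPA, or third-person, TPA), and an optional human-coded
binary flag for interpersonal-difficulties content. Two preprocessing
conventions matter downstream:

* **Author merging.** Prolific authors publish many essays; analysis is at
  the author level, so `merge_by_author()` concatenates an author's texts
  in ascending publication order (ties broken by narrative id — the order
  an author's works were combined in is rarely documented, so a
  deterministic convention is required) separated by a blank line, which
  preserves sentence boundaries for the co-occurrence units. The merged
  interpersonal-difficulties code is the OR of the components: a coded
  mention anywhere marks the author.
* **Normalization.** Text is Unicode-NFC normalized at load; typographic
  apostrophes and quotes map to ASCII; line endings become `\n`. Published
  essays mix typographic and plain punctuation, and the tokenizer should
  not distinguish "don’t" from "don't".

`split_groups()` produces the four analysis subsets — FPA, TPA, FPA with
the interpersonal-difficulties code (FPA_ID), FPA without (FPA_noID).
Coded FPAs partition exactly into the latter two; uncoded FPAs stay out of
the ID split with a warning rather than being silently assigned.

## Feature extraction

A token is a maximal run of letters/digits/apostrophes; hyphens split;
sentences end at `.`, `!`, `?` followed by whitespace. Category scores are
percentages of total tokens, counted with multiplicity, and one token may
feed several categories (pronoun words count toward their specific class,
the personal-pronoun class, and total pronouns).

**Negation-adjusted tone.** Dictionary tone scoring inverts valence on
constructions like "not good". An emotion token is treated as negated when
a negation token occurs within `window` tokens before it in the same
sentence; negated occurrences are removed from the tone numerator while
the denominator (total tokens) is unchanged. Defaults: window = 3 tokens —
the common convention for surface negation scope, configurable — and a
negation list of `not, no, never, none, cannot, nothing` plus the n't
contractions. Exclusion is at the token level (not sentence or narrative
level): it is the minimal intervention that removes the artifact while
leaving the rest of the sentence scored.

**Summary scores.** Commercial text-analysis suites report Analytic,
Clout, and Authenticity as proprietary regression composites; their exact
weights are unpublished. lexnet ships open linear surrogates
(`summary_coefficients()`):

* analytic = 30 + articles + prepositions − personal pronouns − impersonal
  pronouns − auxiliary verbs − conjunctions − adverbs − negations,
* clout = 45 + 6·we + 6·you − 4·I − 2·negations,
* authentic = 40 + 5·I + 2·exclusives − 4·she/he,

each clamped to [0, 100]. The analytic form is the familiar
categorical-versus-dynamic function-word index; clout rises with
other-oriented pronouns and falls with self-reference; authenticity rises
with self-reference and exclusive words and falls with third-person
narration. The coefficient vectors are configuration, and every output
carrying these scores is labeled `"surrogate, not proprietary LIWC"`:
numbers from these surrogates must not be conflated with the commercial
scores, even though they move in the same directions for the contrasts the
package targets.

**The packaged lexicon** (`base_lexicon()`) is a small open dictionary
authored for this package — 18 categories, ~300 patterns — covering tone,
social words, negations, pronoun classes, and the function-word categories
the surrogates need. The engine accepts any dictionary in the
percent-delimited format or as a two-column TSV; serious applications
should supply a full-scale lexicon. Stem wildcards are prefix matches
without longest-match precedence; all matches count.

## Group inference

Per variable, `two_sample_t()` runs classic Levene (absolute deviations
from group means — the median-centered Brown–Forsythe variant is an
option) and switches to Welch's t with Satterthwaite df when Levene's p
falls below the gate (default .05), otherwise Student's pooled t. Cohen's
d uses the n−1-weighted pooled SD, signed like t. Welch df are fractional
and reported as computed.

Multiplicity control is Benjamini–Hochberg step-up within declared
families. The family partition is a genuine design choice: the package
defaults to one family per reported table block — the seven
summary/basic variables, and the five pronoun classes — applied separately
per contrast, mirroring how such tables are printed and read. The
partition is configurable per call.

For contrasts where the groups differ grossly in narrative length, the
battery is complemented by `ancova_group_effect()` (linear model
`y ~ group + covariate`; with one covariate and two groups, sequential and
partial tests coincide) and `partial_correlation()` (residual-on-residual
Pearson r, p from the t transform with n−3 df). Both the plain t tests and
the covaried variants are reported rather than choosing between them.

`krippendorff_alpha()` implements nominal-level alpha from the coincidence
matrix over all pairable values within items, with missing codes allowed.
The confidence interval is a percentile bootstrap over items (default 1000
reps, seeded): the method descriptions this package follows do not state a
CI construction, and the item-resampling percentile bootstrap is the
standard reproducible choice.

## Word networks

Per subset, narratives are tokenized, stopwords and configured
non-meaningful words (seeded with "things", "one", "will", "much") and
pure numerals are dropped, and tokens are grouped into co-occurrence
units. The default unit is the sentence: whole-narrative units on
multi-thousand-word essays would connect almost every word to every other,
destroying the bridge structure betweenness is meant to measure. A sliding
window (default width 10, never crossing narratives) is available for
weakly punctuated text.

Within a unit, every unordered pair of distinct words co-occurs once (set
semantics — robust to repetition inside long sentences); an edge's weight
is the number of units containing the pair. Betweenness centrality is the
standard undirected, unnormalized form — for node v, the sum over node
pairs of the fraction of shortest paths through v — computed on the *full*
graph with unweighted edges by default (`inverse_weight` distances are an
option; published figure pipelines rarely state whether display weights
entered the distances, so the simplest convention is the default). The
top-20-by-frequency display set only affects which nodes are flagged for
plotting and ranking; centrality always sees the whole graph. Bridge
ranking sorts displayed nodes by betweenness, then frequency, then
alphabetically. Edge highlighting marks the top 40% of edges by weight,
ties at the threshold included. The stopword list is pinned inside the
package (a ~150-word standard English list): swapping stopword lists
between runs silently changes every network, so reproducibility requires
shipping one.

Surface forms are used throughout (no lemmatization), and frequency
ranking happens after exclusion-list pruning.

## The synthetic generator

`synthetic_spec()` defines corpora with known ground truth. Defaults are
the study design the package replicates structurally: 56 + 77 FPAs (with /
without the interpersonal-difficulties code) and 44 TPAs; log-normal
narrative lengths with parameters matched to the published group means and
SDs of word count (ID narratives about twice as long); per-token category
emission rates equal to the published group mean percentages divided by
100 (tone, social, pronoun classes), with function-word rates set to
typical English values; multiplicative between-narrative rate jitter with
CV 0.2; and a negation-insertion rate of 0.002 per emotion token,
matching the rarity of negated emotions in published essays. Sentences are
8–15 tokens. Filler probability mass goes to a closed list of 500
pseudo-words verified disjoint from every lexicon category, so category
percentages are exactly controllable.

Planted effects move two groups' base rates apart so the expected
standardized difference of the measured percentage equals the requested d;
the conversion accounts for both jitter variance and binomial sampling at
the length distribution in use (via E[1/L] of the log-normal). Rater codes
are generated by independent raters reporting the true label with a given
accuracy. Bridge corpora draw each sentence's words from one of two
clusters (mixing only with the leak probability) and attach the bridge
word to sentences of both clusters, which guarantees — at zero leak — that
every inter-cluster shortest path passes through the bridge.

Randomness uses one master seed with per-narrative substreams derived by
counter, so narrative k's text is invariant to how many narratives are
generated — corpora are stable fixtures under design changes.

**What the generator does not emulate.** Grammar, discourse, and topic
structure (token order within a sentence is exchangeable); realistic
between-narrative heterogeneity beyond a single jitter CV (real essays
vary far more, so synthetic effect sizes for a given mean difference are
larger than real ones — group separations in the worked examples are
sharper than any real corpus would show); correlated rater errors;
vocabulary growth with length. Passing tests therefore demonstrate the
pipeline's statistical correctness and calibration — type-I control,
effect recovery, bridge detection — not that any particular real-world
effect exists.

## Numerical choices and degenerate inputs

* Empty token streams are an error for every percentage (the caller skips
  the narrative, with a warning in `compute_features()`).
* Narratives under 25 tokens are flagged (`short`) but retained: no length
  floor is imposed silently.
* Levene on two identical-spread samples returns W = 0, p = 1; all-equal
  values in both groups are a degeneracy error. Zero variance in both
  groups with equal means is an undefined-t error.
* `partial_correlation()` treats residual variance below a relative
  `sqrt(eps)` tolerance as zero — perfect collinearity with the control —
  rather than reporting numerically meaningless correlations of rounding
  noise.
* BH adjustment validates p ∈ [0, 1] and otherwise delegates to the stock
  step-up implementation; ties and single-member families behave as the
  step-up rule dictates (unchanged values).
* Bridge ranking ties (e.g. all-zero betweenness on a complete graph) fall
  back to frequency, then lexicographic order, so rankings are total and
  deterministic.
* Edge highlighting uses the k-th largest weight (k = ⌈quantile · m⌉) as
  an inclusive threshold, so ties at the cut are all highlighted and a
  quantile of 1 highlights everything.
* GraphML round-trips encode logical attributes as 0/1 integers and decode
  them on import, avoiding boolean-serialization differences.

## Problem sizes used in the test suite

Simulation-based checks run on corpora of 60 narratives per group with
~100-token narratives (400 replicates for null calibration, 100 for
effect recovery), 200 random graphs of at most 8 nodes for the exhaustive
betweenness oracle, 100 bridge corpora of 200 sentences, and one
full-scale study-shaped corpus (177 narratives at study lengths) for the
end-to-end structural replica. These sizes make the suite's statistical
assertions stable under the fixed seeds while keeping a full run
affordable on a laptop; the calibration properties they verify do not
depend on narrative length.

## Known limitations

* The surrogate summary scores share only direction and rough scale with
  their proprietary namesakes; absolute values are not comparable across
  implementations.
* Prefix wildcards occasionally overmatch (a stem like `pain*` also
  matches "paint"); a production lexicon should prefer explicit inflection
  lists where this matters.
* Negation scope is a fixed token window; syntactic negation ("nothing
  about this was good") is out of scope.
* Betweenness on very dense graphs (whole-narrative units) is close to
  uniform; use sentence units or windows.
* The interpersonal-difficulties code is ingested as a human label; the
  package deliberately does not attempt to detect it from text.
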