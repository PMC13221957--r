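#' Normalize narrative text
#'
#' Applies Unicode NFC normalization, maps typographic (curly) apostrophes and
#' quotation marks to their ASCII equivalents, and converts Windows/old-Mac
#' line endings to `"\n"`. Published essays mix typographic and plain
#' punctuation; normalizing once at load time keeps the tokenizer simple.
#'
#' @param x Character vector of raw text.
#' @return Character vector of normalized text.
#' @export
normalize_text <- function(x) {
  x <- stringi::stri_trans_nfc(x)
  x <- gsub("\r\n", "\n", x, fixed = TRUE)
  x <- gsub("\r", "\n", x, fixed = TRUE)
  # U+2018/U+2019 -> ', U+201C/U+201D -> "
  x <- chartr("‘’“”", "''\"\"", x)
  x
}

#' Tokenize text into lowercase word tokens with sentence indices
#'
#' A token is a maximal run of letters, digits, and internal apostrophes;
#' hyphens split tokens ("self-esteem" yields two tokens). Sentence boundaries
#' are placed at `.`, `!`, or `?` followed by whitespace (or end of text).
#' Tokens are lowercased. Contractions keep their apostrophe ("don't" is one
#' token).
#'
#' @param text A single character string (normalized or raw; typographic
#'   apostrophes are mapped to ASCII before splitting).
#' @param narrative_id Optional identifier carried along with the stream.
#' @return An object of class `token_stream`: a list with `tokens` (character
#'   vector of lowercase tokens), `sentence_index` (0-based integer vector,
#'   non-decreasing, same length as `tokens`), and `narrative_id`.
#' @examples
#' ts <- tokenize("Self-esteem fell. Badly!")
#' ts$tokens
#' ts$sentence_index
#' @export
tokenize <- function(text, narrative_id = NA_character_) {
  stopifnot(is.character(text), length(text) == 1L)
  if (is.na(text) || !nzchar(trimws(text))) {
    return(token_stream(character(0), integer(0), narrative_id))
  }
  text <- tolower(normalize_text(text))
  # sentence split: terminator run followed by whitespace (or end)
  sentences <- strsplit(text, "[.!?]+(\\s+|$)", perl = TRUE)[[1]]
  sentences <- sentences[nzchar(trimws(sentences))]
  toks <- lapply(sentences, function(s) {
    m <- gregexpr("[a-z0-9]+(?:'[a-z0-9]+)*", s, perl = TRUE)[[1]]
    if (m[1] == -1L) character(0) else regmatches(s, list(m))[[1]]
  })
  n <- lengths(toks)
  keep <- n > 0L
  toks <- toks[keep]
  n <- n[keep]
  token_stream(
    tokens = unlist(toks, use.names = FALSE),
    sentence_index = rep.int(seq_along(toks) - 1L, n),
    narrative_id = narrative_id
  )
}

token_stream <- function(tokens, sentence_index, narrative_id = NA_character_) {
  structure(
    list(
      tokens = as.character(tokens),
      sentence_index = as.integer(sentence_index),
      narrative_id = narrative_id
    ),
    class = "token_stream"
  )
}

#' @export
print.token_stream <- function(x, ...) {
  cat(
    "<token_stream>", length(x$tokens), "tokens,",
    if (length(x$sentence_index)) max(x$sentence_index) + 1L else 0L,
    "sentences"
  )
  if (!is.na(x$narrative_id)) cat(" [", x$narrative_id, "]", sep = "")
  cat("\n")
  invisible(x)
}

#' @export
length.token_stream <- function(x) length(x$tokens)
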