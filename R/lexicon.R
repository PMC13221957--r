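#' Construct a category lexicon
#'
#' A lexicon maps category names to sets of patterns. A pattern is either a
#' literal lowercase word or a stem ending in `*`, which matches any token
#' having the stem as a prefix (so `friend*` matches "friend", "friends",
#' "friendship"). A word may belong to several categories; all memberships
#' count when scoring.
#'
#' @param categories Named list of character vectors of patterns.
#' @param name,version Metadata strings recorded on the object.
#' @return An object of class `lexicon`.
#' @export
lexicon <- function(categories, name = "custom", version = "0") {
  stopifnot(is.list(categories), length(categories) > 0L)
  if (is.null(names(categories)) || anyNA(names(categories)) ||
      any(!nzchar(names(categories)))) {
    stop("every category must be named")
  }
  if (anyDuplicated(names(categories))) {
    stop("category names must be unique")
  }
  categories <- lapply(categories, function(p) {
    p <- tolower(as.character(p))
    if (any(!nzchar(p))) stop("empty pattern in lexicon")
    if (any(grepl("\\*.", p))) stop("'*' allowed only as final character of a pattern")
    unique(p)
  })
  obj <- structure(
    list(categories = categories, name = name, version = version),
    class = "lexicon"
  )
  obj$index <- build_lexicon_index(categories)
  obj
}

# Precomputed matcher: hashed environment for single-token lookup, literal
# word vectors per category for vectorized scoring, and wildcard stems.
build_lexicon_index <- function(categories) {
  lit <- new.env(parent = emptyenv(), hash = TRUE)
  lit_by_cat <- vector("list", length(categories))
  stems <- character(0)
  stem_cat <- integer(0)
  for (k in seq_along(categories)) {
    pats <- categories[[k]]
    wild <- endsWith(pats, "*")
    lit_by_cat[[k]] <- pats[!wild]
    for (w in pats[!wild]) {
      assign(w, c(get0(w, envir = lit, ifnotfound = integer(0)), k), envir = lit)
    }
    s <- sub("\\*$", "", pats[wild])
    stems <- c(stems, s)
    stem_cat <- c(stem_cat, rep.int(k, length(s)))
  }
  list(literal = lit, lit_by_cat = lit_by_cat, stems = stems, stem_cat = stem_cat)
}

#' @export
print.lexicon <- function(x, ...) {
  cat("<lexicon>", x$name, "v", x$version, "-",
      length(x$categories), "categories,",
      sum(lengths(x$categories)), "patterns\n")
  invisible(x)
}

#' Load a lexicon from disk
#'
#' Two formats are accepted. The percent-sign-delimited dictionary dialect
#' has a header block between two lines containing only `%`, each header line
#' being `index<TAB>category`, followed by word lines
#' `pattern<TAB>index[<TAB>index...]`. Alternatively, a plain two-column
#' TSV (`pattern<TAB>category`, header optional) is read when the file has no
#' `%` header.
#'
#' @param path Path to a `.dic` or `.tsv` lexicon file.
#' @param name Optional name recorded on the lexicon (defaults to file name).
#' @return A [lexicon()].
#' @export
load_lexicon <- function(path, name = NULL) {
  if (!file.exists(path)) stop("lexicon file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- normalize_text(lines)
  if (is.null(name)) name <- basename(path)
  pct <- which(trimws(lines) == "%")
  if (length(pct) >= 2L) {
    parse_dic(lines, pct, name)
  } else {
    parse_lexicon_tsv(lines, name)
  }
}

parse_dic <- function(lines, pct, name) {
  hdr <- lines[(pct[1] + 1L):(pct[2] - 1L)]
  hdr <- hdr[nzchar(trimws(hdr))]
  cat_ids <- integer(0)
  cat_names <- character(0)
  for (i in seq_along(hdr)) {
    f <- strsplit(trimws(hdr[i]), "\t+|\\s{2,}")[[1]]
    if (length(f) < 2L || is.na(suppressWarnings(as.integer(f[1])))) {
      stop("malformed lexicon header at line ", pct[1] + i, ": ", hdr[i])
    }
    cat_ids <- c(cat_ids, as.integer(f[1]))
    cat_names <- c(cat_names, f[2])
  }
  if (anyDuplicated(cat_ids)) stop("duplicate category index in lexicon header")
  cats <- stats::setNames(vector("list", length(cat_ids)), cat_names)
  body <- lines[-seq_len(pct[2])]
  for (i in seq_along(body)) {
    ln <- trimws(body[i])
    if (!nzchar(ln) || startsWith(ln, "#")) next
    f <- strsplit(ln, "\t+|\\s+")[[1]]
    if (length(f) < 2L) stop("malformed word line ", pct[2] + i, ": ", ln)
    ids <- suppressWarnings(as.integer(f[-1]))
    if (anyNA(ids) || !all(ids %in% cat_ids)) {
      stop("unknown category index at line ", pct[2] + i, ": ", ln)
    }
    for (id in ids) {
      k <- match(id, cat_ids)
      cats[[k]] <- c(cats[[k]], tolower(f[1]))
    }
  }
  empty <- lengths(cats) == 0L
  if (any(empty)) {
    stop("empty category in lexicon: ", paste(cat_names[empty], collapse = ", "))
  }
  lexicon(cats, name = name)
}

parse_lexicon_tsv <- function(lines, name) {
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty lexicon file")
  f1 <- strsplit(lines[1], "\t")[[1]]
  if (length(f1) >= 2L && tolower(f1[1]) %in% c("pattern", "word") ) {
    lines <- lines[-1]
  }
  cats <- list()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t")[[1]]
    if (length(f) < 2L) stop("malformed lexicon line ", i, ": ", lines[i])
    cats[[f[2]]] <- c(cats[[f[2]]], tolower(f[1]))
  }
  lexicon(cats, name = name)
}

#' Categories matched by a single token
#'
#' Returns every category whose literal patterns equal the token or whose
#' stem patterns (`friend*`) are a prefix of the token. All matches count;
#' there is no longest-match precedence.
#'
#' @param token A lowercase word token.
#' @param lex A [lexicon()].
#' @return Character vector of category names (possibly empty).
#' @export
match_categories <- function(token, lex) {
  stopifnot(inherits(lex, "lexicon"), length(token) == 1L)
  idx <- lex$index
  ks <- get0(token, envir = idx$literal, ifnotfound = integer(0))
  if (length(idx$stems)) {
    hit <- startsWith(token, idx$stems)
    ks <- c(ks, idx$stem_cat[hit])
  }
  names(lex$categories)[sort(unique(ks))]
}

# Vectorized category membership: list(category -> logical vector over the
# token vector). Hash-based %in% per category keeps this linear in corpus
# size even for millions of tokens.
category_hits <- function(tokens, lex) {
  idx <- lex$index
  ncat <- length(lex$categories)
  hits <- vector("list", ncat)
  for (k in seq_len(ncat)) {
    h <- tokens %in% idx$lit_by_cat[[k]]
    ws <- idx$stems[idx$stem_cat == k]
    for (s in ws) h <- h | startsWith(tokens, s)
    hits[[k]] <- h
  }
  names(hits) <- names(lex$categories)
  hits
}

#' Built-in lexicon shipped with the package
#'
#' Loads the packaged open category lexicon (`inst/extdata/lexnet_base.dic`).
#' Its word lists were authored for this package and cover the categories the
#' feature engine needs: emotional tone (positive/negative), social words,
#' negations, personal/impersonal/total pronouns, the five specific pronoun
#' classes, and the function-word categories consumed by the surrogate summary
#' scores (articles, prepositions, auxiliary verbs, conjunctions, adverbs,
#' exclusives). It is an open surrogate, not the proprietary LIWC dictionary.
#'
#' @return A [lexicon()].
#' @export
base_lexicon <- function() {
  cached <- get0("base_lexicon", envir = .lexicon_cache, ifnotfound = NULL)
  if (!is.null(cached)) return(cached)
  lex <- load_lexicon(
    system.file("extdata", "lexnet_base.dic", package = "lexnet"),
    name = "lexnet_base"
  )
  assign("base_lexicon", lex, envir = .lexicon_cache)
  lex
}

.lexicon_cache <- new.env(parent = emptyenv())
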