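#' Construct a corpus table
#'
#' A corpus table is a data frame with one row per narrative and columns
#' `narrative_id`, `author_id`, `text`, `account_type` (`"FPA"` first-person
#' or `"TPA"` third-person), `interpersonal_difficulties` (logical, may be
#' `NA`), and `publication_order` (non-negative integer, unique within
#' author).
#'
#' @param narrative_id,author_id Character vectors.
#' @param text Character vector of narrative text (non-empty after
#'   whitespace stripping).
#' @param account_type Character vector, each `"FPA"` or `"TPA"`.
#' @param interpersonal_difficulties Logical vector (default all `NA`):
#'   human-coded flag for narratives whose text mentions interpersonal
#'   difficulties.
#' @param publication_order Integer vector; defaults to within-author rank in
#'   input order.
#' @param provenance Free-text source note.
#' @return A data frame of class `corpus_table`.
#' @export
corpus_table <- function(narrative_id, author_id, text, account_type,
                         interpersonal_difficulties = NA,
                         publication_order = NULL,
                         provenance = "") {
  n <- length(narrative_id)
  narrative_id <- as.character(narrative_id)
  author_id <- as.character(author_id)
  text <- as.character(text)
  account_type <- as.character(account_type)
  id <- rep_len(as.logical(interpersonal_difficulties), n)
  if (is.null(publication_order)) {
    publication_order <- stats::ave(seq_len(n), author_id, FUN = seq_along)
  }
  publication_order <- as.integer(publication_order)
  if (anyDuplicated(narrative_id)) {
    stop("duplicate narrative_id: ",
         paste(unique(narrative_id[duplicated(narrative_id)]), collapse = ", "))
  }
  bad <- !account_type %in% c("FPA", "TPA")
  if (any(bad)) {
    stop("unknown account_type token: ",
         paste(unique(account_type[bad]), collapse = ", "))
  }
  if (any(!nzchar(trimws(text)))) {
    stop("empty text for narrative: ",
         paste(narrative_id[!nzchar(trimws(text))], collapse = ", "))
  }
  if (any(publication_order < 0L, na.rm = TRUE)) {
    stop("publication_order must be non-negative")
  }
  dup <- stats::ave(publication_order, author_id,
                    FUN = function(x) duplicated(x))
  if (any(dup == 1)) {
    stop("publication_order not unique within author: ",
         paste(author_id[dup == 1], collapse = ", "))
  }
  out <- data.frame(
    narrative_id = narrative_id,
    author_id = author_id,
    text = text,
    account_type = account_type,
    interpersonal_difficulties = id,
    publication_order = publication_order,
    stringsAsFactors = FALSE
  )
  class(out) <- c("corpus_table", "data.frame")
  attr(out, "provenance") <- provenance
  out
}

#' @export
print.corpus_table <- function(x, ...) {
  cat("<corpus_table> ", nrow(x), " narratives, ",
      length(unique(x$author_id)), " authors (",
      sum(x$account_type == "FPA"), " FPA / ",
      sum(x$account_type == "TPA"), " TPA)\n", sep = "")
  prov <- attr(x, "provenance")
  if (!is.null(prov) && nzchar(prov)) cat("  provenance: ", prov, "\n", sep = "")
  invisible(x)
}

#' Load a corpus from a metadata table and a directory of text files
#'
#' The metadata table (CSV by default; TSV accepted, chosen by file
#' extension) must have a header with columns `narrative_id`, `author_id`,
#' `file`, `account_type`, and optionally `interpersonal_difficulties`
#' (logical or 0/1) and `publication_order`. Each `file` is read as UTF-8
#' from `text_dir`, line endings are normalized to `"\n"`, and text is
#' Unicode-NFC normalized with typographic apostrophes mapped to ASCII.
#'
#' @param metadata_path Path to the metadata CSV/TSV.
#' @param text_dir Directory containing the referenced `.txt` files.
#' @return A [corpus_table()]; row order follows the metadata.
#' @export
load_corpus <- function(metadata_path, text_dir) {
  if (!file.exists(metadata_path)) stop("metadata file not found: ", metadata_path)
  sep <- if (grepl("\\.tsv$", metadata_path, ignore.case = TRUE)) "\t" else ","
  meta <- utils::read.table(metadata_path, header = TRUE, sep = sep,
                            quote = "\"", stringsAsFactors = FALSE,
                            fileEncoding = "UTF-8", comment.char = "")
  need <- c("narrative_id", "author_id", "file", "account_type")
  miss <- setdiff(need, names(meta))
  if (length(miss)) stop("metadata lacks columns: ", paste(miss, collapse = ", "))
  texts <- character(nrow(meta))
  for (i in seq_len(nrow(meta))) {
    fp <- file.path(text_dir, meta$file[i])
    if (!file.exists(fp)) {
      stop("missing text file for narrative '", meta$narrative_id[i], "': ", fp)
    }
    raw <- readChar(fp, file.size(fp), useBytes = TRUE)
    Encoding(raw) <- "UTF-8"
    texts[i] <- normalize_text(raw)
  }
  idc <- if ("interpersonal_difficulties" %in% names(meta)) {
    v <- meta$interpersonal_difficulties
    if (is.character(v)) v <- tolower(trimws(v)) %in% c("true", "1", "yes")
    as.logical(v)
  } else NA
  po <- if ("publication_order" %in% names(meta)) meta$publication_order else NULL
  corpus_table(
    narrative_id = meta$narrative_id,
    author_id = meta$author_id,
    text = texts,
    account_type = meta$account_type,
    interpersonal_difficulties = idc,
    publication_order = po,
    provenance = paste0("loaded from ", metadata_path)
  )
}

#' Merge narratives written by the same author
#'
#' Prolific authors contribute many narratives; for author-level analysis
#' their texts are combined into one record per author. Component texts are
#' concatenated in ascending `publication_order` (ties broken by
#' `narrative_id`), joined by a blank line so sentence boundaries survive.
#' The merged interpersonal-difficulties code is the logical OR of the
#' components: a mention anywhere marks the author. `account_type` must be
#' homogeneous within an author.
#'
#' The operation is idempotent: merging an already-merged corpus returns it
#' unchanged.
#'
#' @param corpus A [corpus_table()].
#' @return A [corpus_table()] with one record per author; `narrative_id`
#'   equals `author_id`.
#' @export
merge_by_author <- function(corpus) {
  stopifnot(inherits(corpus, "corpus_table"))
  split_idx <- split(seq_len(nrow(corpus)), corpus$author_id)
  recs <- lapply(split_idx, function(ix) {
    at <- unique(corpus$account_type[ix])
    if (length(at) > 1L) {
      stop("conflicting account_type within author ",
           corpus$author_id[ix[1]], ": ", paste(at, collapse = ", "))
    }
    ord <- ix[order(corpus$publication_order[ix], corpus$narrative_id[ix])]
    idc <- corpus$interpersonal_difficulties[ix]
    list(
      author_id = corpus$author_id[ix[1]],
      text = paste(corpus$text[ord], collapse = "\n\n"),
      account_type = at,
      interpersonal_difficulties =
        if (all(is.na(idc))) NA else isTRUE(any(idc, na.rm = TRUE))
    )
  })
  # preserve first-appearance order of authors
  first <- vapply(split_idx, `[`, integer(1), 1L)
  recs <- recs[order(first)]
  out <- corpus_table(
    narrative_id = vapply(recs, `[[`, character(1), "author_id"),
    author_id = vapply(recs, `[[`, character(1), "author_id"),
    text = vapply(recs, `[[`, character(1), "text"),
    account_type = vapply(recs, `[[`, character(1), "account_type"),
    interpersonal_difficulties =
      vapply(recs, `[[`, logical(1), "interpersonal_difficulties"),
    publication_order = rep.int(1L, length(recs)),
    provenance = attr(corpus, "provenance") %||% ""
  )
  attr(out, "merged") <- TRUE
  out
}

#' Split a merged corpus into analysis groups
#'
#' Returns the four subsets analysed throughout: all first-person accounts
#' (`FPA`), third-person accounts (`TPA`), and first-person accounts with
#' (`FPA_ID`) and without (`FPA_noID`) the coded interpersonal-difficulties
#' flag. `FPA` is the disjoint union of `FPA_ID` and `FPA_noID` over coded
#' records; FPA records with a missing code stay in `FPA` but in neither ID
#' subset (a warning lists them). An ID code on a TPA record is ignored for
#' the ID split.
#'
#' @param corpus A (merged) [corpus_table()].
#' @return Named list of four [corpus_table()] objects:
#'   `FPA`, `TPA`, `FPA_ID`, `FPA_noID`.
#' @export
split_groups <- function(corpus) {
  stopifnot(inherits(corpus, "corpus_table"))
  fpa <- corpus[corpus$account_type == "FPA", , drop = FALSE]
  tpa <- corpus[corpus$account_type == "TPA", , drop = FALSE]
  uncoded <- is.na(fpa$interpersonal_difficulties)
  if (any(uncoded)) {
    warning("FPA narratives without an interpersonal-difficulties code are ",
            "excluded from the ID split: ",
            paste(fpa$narrative_id[uncoded], collapse = ", "))
  }
  sub <- function(df) {
    class(df) <- c("corpus_table", "data.frame")
    df
  }
  list(
    FPA = sub(fpa),
    TPA = sub(tpa),
    FPA_ID = sub(fpa[!uncoded & fpa$interpersonal_difficulties, , drop = FALSE]),
    FPA_noID = sub(fpa[!uncoded & !fpa$interpersonal_difficulties, , drop = FALSE])
  )
}

#' Write / read a corpus snapshot as TSV
#'
#' Serializes a corpus to a single TSV with newlines in `text` escaped as
#' `\n` (and literal backslashes as `\\`), so the snapshot is a plain text
#' file with one line per narrative. `read_corpus_tsv()` inverts the
#' escaping exactly.
#'
#' @param corpus A [corpus_table()].
#' @param path Output/input file path.
#' @return `write_corpus_tsv()`: `path` invisibly; `read_corpus_tsv()`: a
#'   [corpus_table()].
#' @export
write_corpus_tsv <- function(corpus, path) {
  stopifnot(inherits(corpus, "corpus_table"))
  esc <- corpus$text
  esc <- gsub("\\", "\\\\", esc, fixed = TRUE)
  esc <- gsub("\n", "\\n", esc, fixed = TRUE)
  esc <- gsub("\t", "\\t", esc, fixed = TRUE)
  df <- data.frame(
    narrative_id = corpus$narrative_id,
    author_id = corpus$author_id,
    account_type = corpus$account_type,
    interpersonal_difficulties = corpus$interpersonal_difficulties,
    publication_order = corpus$publication_order,
    text = esc,
    stringsAsFactors = FALSE
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_corpus_tsv
#' @export
read_corpus_tsv <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                          stringsAsFactors = FALSE, fileEncoding = "UTF-8",
                          comment.char = "")
  unesc <- function(s) {
    # protect literal backslash pairs before expanding \n and \t
    s <- gsub("\\\\", "\x01", s, fixed = TRUE)
    s <- gsub("\\n", "\n", s, fixed = TRUE)
    s <- gsub("\\t", "\t", s, fixed = TRUE)
    gsub("\x01", "\\", s, fixed = TRUE)
  }
  txt <- unesc(df$text)
  corpus_table(
    narrative_id = df$narrative_id,
    author_id = df$author_id,
    text = txt,
    account_type = df$account_type,
    interpersonal_difficulties = df$interpersonal_difficulties,
    publication_order = df$publication_order,
    provenance = paste0("snapshot ", path)
  )
}
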