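#' Configuration for a full pipeline run
#'
#' @param metadata_path,text_dir Corpus location ([load_corpus()]); either
#'   these or `corpus` must be given.
#' @param corpus A pre-loaded [corpus_table()] (alternative to the paths).
#' @param lexicon_path Optional path to a lexicon file; default the packaged
#'   lexicon.
#' @param negation_window Negation scope in tokens (default 3).
#' @param families Benjamini-Hochberg families ([default_families()]).
#' @param levene_gate Levene p-value gate for Welch switching (default 0.05).
#' @param network A [network_config()].
#' @param output_dir Directory for all outputs (created if needed).
#' @param seed Integer seed recorded in the manifest.
#' @param merge_authors Merge narratives by author before analysis
#'   (default TRUE).
#' @param log_level `"info"` or `"warning"`.
#' @return A list of class `run_config`.
#' @export
run_config <- function(metadata_path = NULL, text_dir = NULL, corpus = NULL,
                       lexicon_path = NULL, negation_window = 3L,
                       families = default_families(), levene_gate = 0.05,
                       network = network_config(), output_dir,
                       seed = 1L, merge_authors = TRUE,
                       log_level = c("info", "warning")) {
  if (is.null(corpus) && (is.null(metadata_path) || is.null(text_dir))) {
    stop("provide either a corpus or metadata_path + text_dir")
  }
  structure(
    list(
      metadata_path = metadata_path, text_dir = text_dir, corpus = corpus,
      lexicon_path = lexicon_path, negation_window = as.integer(negation_window),
      families = families, levene_gate = levene_gate, network = network,
      output_dir = output_dir, seed = as.integer(seed),
      merge_authors = merge_authors, log_level = match.arg(log_level)
    ),
    class = "run_config"
  )
}

pipeline_log <- function(config, level, ...) {
  if (config$log_level == "warning" && level == "info") return(invisible())
  message(sprintf("[%s] %s", level, paste0(...)))
}

#' Run the full study-replica pipeline
#'
#' Stages: load (or accept) the corpus, merge authors, split groups, compute
#' per-narrative features, run the two comparison batteries (FPA vs TPA and,
#' within FPAs, interpersonal difficulties vs none -- each with the t-test
#' battery plus the word-count-covaried variant), and build, rank, and
#' export the four group word networks. Writes a JSON manifest listing every
#' output file with an MD5 content hash, the echoed configuration, and
#' package/R versions; reruns with the same inputs and seed produce
#' identical hashes.
#'
#' A contrast whose groups have fewer than 2 narratives each is skipped with
#' a logged warning; remaining stages still run.
#'
#' @param config A [run_config()].
#' @return The manifest, invisibly (also written to
#'   `output_dir/manifest.json`).
#' @export
run_full_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  outputs <- character(0)
  t0 <- Sys.time()

  corpus <- if (!is.null(config$corpus)) config$corpus else {
    load_corpus(config$metadata_path, config$text_dir)
  }
  pipeline_log(config, "info", "loaded ", nrow(corpus), " narratives")
  if (config$merge_authors) {
    corpus <- merge_by_author(corpus)
    pipeline_log(config, "info", "merged to ", nrow(corpus), " author records")
  }
  groups <- split_groups(corpus)
  sizes <- vapply(groups, nrow, integer(1))
  pipeline_log(config, "info", "group sizes: ",
               paste(names(sizes), sizes, sep = "=", collapse = ", "))

  lex <- if (is.null(config$lexicon_path)) base_lexicon() else {
    load_lexicon(config$lexicon_path)
  }
  feats <- compute_features(corpus, lex, window = config$negation_window)
  n_short <- sum(feats$short)
  if (n_short > 0) {
    pipeline_log(config, "warning", n_short,
                 " narratives under 25 tokens (flagged, retained)")
  }
  fp <- file.path(config$output_dir, "features.csv")
  write_features_csv(feats, fp)
  outputs <- c(outputs, fp)

  key <- match(feats$narrative_id, corpus$narrative_id)
  feats$account_type <- corpus$account_type[key]
  feats$interpersonal_difficulties <- corpus$interpersonal_difficulties[key]

  contrasts <- list(
    fpa_vs_tpa = list(
      sel = rep(TRUE, nrow(feats)),
      grouping = factor(feats$account_type, levels = c("FPA", "TPA"))
    ),
    fpa_id_vs_noid = list(
      sel = feats$account_type == "FPA" & !is.na(feats$interpersonal_difficulties),
      grouping = factor(ifelse(feats$interpersonal_difficulties, "FPA_ID", "FPA_noID"),
                        levels = c("FPA_ID", "FPA_noID"))
    )
  )
  for (cn in names(contrasts)) {
    ct <- contrasts[[cn]]
    f <- feats[ct$sel, , drop = FALSE]
    gr <- droplevels(ct$grouping[ct$sel])
    if (nlevels(gr) < 2L || min(table(gr)) < 2L) {
      pipeline_log(config, "warning", "skipping contrast ", cn,
                   ": a group has fewer than 2 narratives")
      next
    }
    bat <- run_comparison_battery(f, gr, config$families, config$levene_gate)
    bp <- file.path(config$output_dir, paste0("comparison_", cn, ".csv"))
    write_battery_csv(bat, bp)
    outputs <- c(outputs, bp)
    # covariate-adjusted variant: word count as covariate
    anc <- do.call(rbind, lapply(unlist(config$families, use.names = FALSE),
      function(v) {
        ancova_group_effect(f[[v]], gr, f$word_count, variable = v,
                            covariate_name = "word_count")
      }))
    ap <- file.path(config$output_dir, paste0("ancova_", cn, ".csv"))
    utils::write.csv(anc, ap, row.names = FALSE)
    outputs <- c(outputs, ap)
    pipeline_log(config, "info", "contrast ", cn, " complete")
  }

  for (gn in names(groups)) {
    sub <- groups[[gn]]
    if (nrow(sub) == 0L) {
      pipeline_log(config, "warning", "skipping empty network group ", gn)
      next
    }
    units <- network_tokens(sub, config$network)
    g <- build_cooccurrence_graph(units, config$network, subset = gn)
    gp <- file.path(config$output_dir, paste0("network_", gn, ".graphml"))
    np <- file.path(config$output_dir, paste0("network_", gn, "_nodes.tsv"))
    ep <- file.path(config$output_dir, paste0("network_", gn, "_edges.tsv"))
    rp <- file.path(config$output_dir, paste0("network_", gn, "_bridges.txt"))
    export_graph(g, gp, "graphml")
    export_graph(g, np, "node_tsv")
    export_graph(g, ep, "edge_tsv")
    writeLines(bridge_ranking(g), rp)
    outputs <- c(outputs, gp, np, ep, rp)
    pipeline_log(config, "info", "network ", gn, ": ", nrow(g$nodes),
                 " nodes, ", nrow(g$edges), " edges")
  }

  manifest <- list(
    created = format(t0, "%Y-%m-%dT%H:%M:%S"),
    seed = config$seed,
    group_sizes = as.list(sizes),
    n_comparison_tables = sum(grepl("comparison_", basename(outputs))),
    n_network_bundles = sum(grepl("\\.graphml$", outputs)),
    outputs = lapply(outputs, function(p) {
      list(file = basename(p), md5 = unname(tools::md5sum(p)))
    }),
    config = list(
      negation_window = config$negation_window,
      levene_gate = config$levene_gate,
      families = config$families,
      network = config$network[setdiff(names(config$network), "stopwords")],
      n_stopwords = length(config$network$stopwords),
      merge_authors = config$merge_authors
    ),
    summary_scores = "surrogate, not proprietary LIWC",
    versions = list(
      lexnet = as.character(utils::packageVersion("lexnet")),
      igraph = as.character(utils::packageVersion("igraph")),
      R = paste(R.version$major, R.version$minor, sep = ".")
    )
  )
  jsonlite::write_json(manifest, file.path(config$output_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  pipeline_log(config, "info", "pipeline complete in ",
               sprintf("%.1f", as.numeric(difftime(Sys.time(), t0, units = "secs"))),
               " s")
  invisible(manifest)
}
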