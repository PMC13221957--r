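#' Construct a rater coding table
#'
#' Items (narratives) in rows, raters in columns, nominal codes in cells;
#' `NA` marks a missing coding. At least 2 raters and at least 2 items with
#' 2 or more non-missing codes are required for reliability computation.
#'
#' @param codes A matrix or data frame, items x raters.
#' @param item_ids,rater_ids Optional dimension names.
#' @return A matrix of class `rater_coding_table`.
#' @export
rater_coding_table <- function(codes, item_ids = NULL, rater_ids = NULL) {
  m <- as.matrix(codes)
  if (ncol(m) < 2L) stop("at least 2 raters required")
  if (!is.null(item_ids)) rownames(m) <- item_ids
  if (!is.null(rater_ids)) colnames(m) <- rater_ids
  class(m) <- c("rater_coding_table", class(m))
  m
}

# alpha for one items-x-raters matrix of nominal codes, via the coincidence
# matrix over all pairable values within items.
alpha_nominal <- function(m) {
  vals <- sort(unique(as.vector(m[!is.na(m)])))
  k <- length(vals)
  if (k < 2L) return(1)  # a single observed category: no possible disagreement
  o <- matrix(0, k, k, dimnames = list(vals, vals))
  n_pairable <- 0
  for (u in seq_len(nrow(m))) {
    v <- m[u, ]
    v <- v[!is.na(v)]
    mu <- length(v)
    if (mu < 2L) next
    n_pairable <- n_pairable + mu
    idx <- match(v, vals)
    tab <- tabulate(idx, nbins = k)
    # ordered pairs within the unit, weighted 1/(mu - 1)
    pair <- outer(tab, tab) - diag(tab)
    o <- o + pair / (mu - 1)
  }
  if (n_pairable == 0) stop("insufficient data: fewer than 2 pairable items")
  nc <- rowSums(o)
  n <- sum(nc)
  do_ <- sum(o) - sum(diag(o))
  de <- (n^2 - sum(nc^2)) / (n - 1)
  if (de == 0) return(1)
  1 - do_ / de
}

#' Krippendorff's alpha for nominal codes with bootstrap CI
#'
#' Chance-corrected inter-rater agreement `alpha = 1 - Do/De` computed from
#' the coincidence matrix over all pairable values within items. The
#' confidence interval is a percentile bootstrap over items: item rows are
#' resampled with replacement and alpha recomputed.
#'
#' @param codes A [rater_coding_table()] or items x raters matrix.
#' @param level Measurement level; only `"nominal"` is implemented.
#' @param bootstrap_reps Number of bootstrap resamples (default 1000; 0
#'   skips the CI).
#' @param seed Integer seed for the bootstrap.
#' @param conf Confidence level (default 0.95).
#' @return An object of class `reliability_result`: list with `alpha`,
#'   `ci_low`, `ci_high`, `n_items`, `n_raters`, `bootstrap_reps`, `seed`.
#' @export
krippendorff_alpha <- function(codes, level = "nominal",
                               bootstrap_reps = 1000L, seed = 1L,
                               conf = 0.95) {
  level <- match.arg(level, "nominal")
  m <- as.matrix(unclass(codes))
  if (ncol(m) < 2L) stop("at least 2 raters required")
  usable <- rowSums(!is.na(m)) >= 2L
  if (sum(usable) < 2L) stop("insufficient data: fewer than 2 pairable items")
  alpha <- alpha_nominal(m)
  ci <- c(NA_real_, NA_real_)
  if (bootstrap_reps > 0L) {
    stats <- numeric(bootstrap_reps)
    old <- local_seed(seed)
    on.exit(restore_seed(old))
    for (b in seq_len(bootstrap_reps)) {
      mb <- m[sample.int(nrow(m), nrow(m), replace = TRUE), , drop = FALSE]
      stats[b] <- tryCatch(alpha_nominal(mb), error = function(e) NA_real_)
    }
    qs <- stats::quantile(stats, c((1 - conf) / 2, 1 - (1 - conf) / 2),
                          na.rm = TRUE, names = FALSE)
    ci <- c(min(qs[1], alpha), max(qs[2], alpha))
  }
  structure(
    list(
      alpha = alpha, ci_low = ci[1], ci_high = ci[2],
      n_items = nrow(m), n_raters = ncol(m),
      bootstrap_reps = as.integer(bootstrap_reps), seed = as.integer(seed),
      conf = conf
    ),
    class = "reliability_result"
  )
}

#' @export
print.reliability_result <- function(x, ...) {
  cat(sprintf("Krippendorff's alpha = %.3f", x$alpha))
  if (!is.na(x$ci_low)) {
    cat(sprintf(" (%d%% CI %.3f-%.3f, %d bootstrap reps)",
                round(100 * x$conf), x$ci_low, x$ci_high, x$bootstrap_reps))
  }
  cat(sprintf("\n%d items, %d raters\n", x$n_items, x$n_raters))
  invisible(x)
}

# Scoped RNG helpers: set a seed without clobbering the caller's stream.
local_seed <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  set.seed(seed)
  old
}

restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  invisible(NULL)
}
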