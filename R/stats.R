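#' Levene's test for homogeneity of variances (two samples)
#'
#' Classic Levene statistic: a one-way ANOVA on absolute deviations from the
#' group means. `center = "median"` gives the Brown-Forsythe variant.
#'
#' @param x,y Numeric samples, each of size >= 2.
#' @param center `"mean"` (classic Levene, default) or `"median"`
#'   (Brown-Forsythe).
#' @return List with `W` (the F statistic on the deviations) and `p`.
#' @export
levene_test <- function(x, y, center = c("mean", "median")) {
  center <- match.arg(center)
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) < 2L || length(y) < 2L) stop("each sample needs >= 2 values")
  cfun <- if (center == "mean") mean else stats::median
  zx <- abs(x - cfun(x))
  zy <- abs(y - cfun(y))
  if (all(zx == 0) && all(zy == 0)) {
    stop("degenerate variance: all values identical within both groups")
  }
  n1 <- length(zx); n2 <- length(zy); n <- n1 + n2
  zbar <- mean(c(zx, zy))
  ssb <- n1 * (mean(zx) - zbar)^2 + n2 * (mean(zy) - zbar)^2
  ssw <- sum((zx - mean(zx))^2) + sum((zy - mean(zy))^2)
  if (ssw == 0) {
    # deviations constant within groups: infinite separation unless equal
    W <- if (ssb == 0) 0 else Inf
  } else {
    W <- (ssb / 1) / (ssw / (n - 2))
  }
  p <- if (is.infinite(W)) 0 else stats::pf(W, 1, n - 2, lower.tail = FALSE)
  list(W = W, p = p)
}

#' Cohen's d (pooled standard deviation)
#'
#' `(mean(x) - mean(y)) / s_pooled` with the usual n-1 weighted pooled SD.
#' The sign matches the t statistic computed on the same group order.
#'
#' @param x,y Numeric samples, each of size >= 2.
#' @return The standardized mean difference.
#' @export
cohens_d <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) < 2L || length(y) < 2L) stop("each sample needs >= 2 values")
  n1 <- length(x); n2 <- length(y)
  sp2 <- ((n1 - 1) * stats::var(x) + (n2 - 1) * stats::var(y)) / (n1 + n2 - 2)
  if (sp2 == 0) stop("undefined effect size: pooled SD is zero")
  (mean(x) - mean(y)) / sqrt(sp2)
}

#' Variance-gated two-sample t test
#'
#' Runs Levene's test first; when its p-value falls below `gate` (the
#' homogeneity assumption is violated) Welch's t test with Satterthwaite
#' degrees of freedom is used, otherwise Student's pooled-variance test.
#'
#' @param x,y Numeric samples (group 1 and group 2), each of size >= 2.
#' @param gate Levene p-value threshold switching to Welch (default 0.05).
#' @param variable,groups Optional labels carried into the result.
#' @param levene_center Passed to [levene_test()].
#' @return A one-row data frame of class `comparison_result`: `variable`,
#'   `group1`, `group2`, `n1`, `n2`, `mean1`, `sd1`, `mean2`, `sd2`,
#'   `levene_W`, `levene_p`, `test_kind` (`"student"` or `"welch"`), `t`,
#'   `df`, `p_raw`, `cohen_d`, and `p_adj` (NA until a family adjustment is
#'   applied).
#' @export
two_sample_t <- function(x, y, gate = 0.05, variable = NA_character_,
                         groups = c("group1", "group2"),
                         levene_center = "mean") {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) < 2L || length(y) < 2L) stop("each sample needs >= 2 values")
  if (stats::var(x) == 0 && stats::var(y) == 0 && mean(x) == mean(y)) {
    stop("undefined t: zero variance in both groups with equal means")
  }
  lev <- tryCatch(
    levene_test(x, y, center = levene_center),
    error = function(e) list(W = 0, p = 1)  # identical spreads: homogeneous
  )
  kind <- if (lev$p < gate) "welch" else "student"
  tt <- stats::t.test(x, y, var.equal = (kind == "student"))
  d <- tryCatch(cohens_d(x, y), error = function(e) NA_real_)
  out <- data.frame(
    variable = variable,
    group1 = groups[1], group2 = groups[2],
    n1 = length(x), n2 = length(y),
    mean1 = mean(x), sd1 = stats::sd(x),
    mean2 = mean(y), sd2 = stats::sd(y),
    levene_W = lev$W, levene_p = lev$p,
    test_kind = kind,
    t = unname(tt$statistic),
    df = unname(tt$parameter),
    p_raw = tt$p.value,
    p_adj = NA_real_,
    cohen_d = d,
    stringsAsFactors = FALSE
  )
  class(out) <- c("comparison_result", "data.frame")
  out
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Adjusted p-values of the step-up false discovery rate procedure: sort
#' ascending, take `p_(i) * m / i`, enforce monotonicity from the largest
#' rank down, cap at 1, and return in input order. Delegates to
#' [stats::p.adjust()] after validation.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @param family Optional family label (recorded as an attribute).
#' @return Adjusted p-values in input order.
#' @export
bh_adjust <- function(p, family = NULL) {
  p <- as.numeric(p)
  if (anyNA(p) || any(p < 0 | p > 1)) {
    stop("p-values must lie in [0, 1] with no missing values")
  }
  out <- stats::p.adjust(p, method = "BH")
  if (!is.null(family)) attr(out, "family") <- family
  out
}

#' Covariate-adjusted group effect (one-way ANCOVA)
#'
#' Fits `y ~ group + covariate` by least squares and reports the group and
#' covariate effects given each other (with a single covariate and two
#' groups, sequential and partial tests coincide).
#'
#' @param y Numeric outcome.
#' @param group Two-level factor (or coercible).
#' @param covariate Numeric covariate; must vary.
#' @param variable,covariate_name Labels carried into the result.
#' @return A one-row data frame of class `ancova_result`: group effect
#'   estimate, t, p; covariate estimate, t, p.
#' @export
ancova_group_effect <- function(y, group, covariate,
                                variable = NA_character_,
                                covariate_name = "covariate") {
  group <- droplevels(as.factor(group))
  if (nlevels(group) != 2L) stop("group must have exactly 2 represented levels")
  if (stats::var(as.numeric(covariate)) == 0) {
    stop("rank deficiency: covariate is constant")
  }
  fit <- stats::lm(y ~ group + covariate)
  cf <- summary(fit)$coefficients
  out <- data.frame(
    variable = variable,
    covariate = covariate_name,
    group_effect = cf[2, "Estimate"],
    group_effect_stat = cf[2, "t value"],
    group_effect_p = cf[2, "Pr(>|t|)"],
    covariate_stat = cf[3, "t value"],
    covariate_p = cf[3, "Pr(>|t|)"],
    stringsAsFactors = FALSE
  )
  class(out) <- c("ancova_result", "data.frame")
  out
}

#' Partial correlation controlling for one variable
#'
#' Pearson correlation of the residuals of `x` and `y` after each is
#' regressed on `control`; the p-value uses the t transform with `n - 3`
#' degrees of freedom.
#'
#' @param x,y,control Numeric vectors of common length >= 4.
#' @param labels Optional character vector of length 3 naming x, y, control.
#' @return A one-row data frame of class `partial_correlation_result` with
#'   `r_partial`, `p`, `n`.
#' @export
partial_correlation <- function(x, y, control,
                                labels = c("x", "y", "control")) {
  n <- length(x)
  if (n < 4L || length(y) != n || length(control) != n) {
    stop("x, y, control must share length >= 4")
  }
  rx <- stats::residuals(stats::lm(x ~ control))
  ry <- stats::residuals(stats::lm(y ~ control))
  # relative tolerance: residuals that are numerically zero (perfect
  # collinearity with the control) leave the correlation undefined
  tol <- .Machine$double.eps^0.5
  if (stats::var(rx) <= tol * max(stats::var(x), tol) ||
      stats::var(ry) <= tol * max(stats::var(y), tol)) {
    stop("undefined correlation: zero residual variance")
  }
  r <- stats::cor(rx, ry)
  df <- n - 3
  p <- if (abs(r) >= 1) 0 else {
    tval <- r * sqrt(df / (1 - r^2))
    2 * stats::pt(-abs(tval), df)
  }
  out <- data.frame(
    x = labels[1], y = labels[2], control = labels[3],
    r_partial = r, p = p, n = n, stringsAsFactors = FALSE
  )
  class(out) <- c("partial_correlation_result", "data.frame")
  out
}

#' Default variable families for the comparison battery
#'
#' Multiplicity is controlled within declared families, one per printed
#' table block: the summary + basic variable block and the specific-pronoun
#' block.
#'
#' @return Named list of character vectors of feature-column names.
#' @export
default_families <- function() {
  list(
    summary_basic = c("authentic", "clout", "analytic", "pos_tone",
                      "neg_tone", "social", "total_pronouns"),
    pronouns = c("pron_I", "pron_we", "pron_you", "pron_she_he", "pron_they")
  )
}

#' Run the between-group comparison battery
#'
#' For each variable in each family: variance-gated t test
#' ([two_sample_t()]) plus Cohen's d, with Benjamini-Hochberg adjustment
#' applied separately within each family.
#'
#' @param features Feature data frame ([compute_features()]); must contain
#'   every family variable.
#' @param grouping Vector (length `nrow(features)`) with exactly two
#'   represented levels; the first level in factor order is group 1.
#' @param families Named list of variable vectors; default
#'   [default_families()].
#' @param gate Levene gate passed to [two_sample_t()].
#' @return A data frame of class `comparison_battery`, one row per
#'   (family, variable), with `p_adj` filled in.
#' @export
run_comparison_battery <- function(features, grouping,
                                   families = default_families(),
                                   gate = 0.05) {
  grouping <- droplevels(as.factor(grouping))
  if (nlevels(grouping) != 2L) {
    stop("grouping must have exactly 2 represented levels")
  }
  lv <- levels(grouping)
  if (min(table(grouping)) < 2L) {
    stop("insufficient group: fewer than 2 narratives in ", lv[which.min(table(grouping))])
  }
  res <- list()
  for (fam in names(families)) {
    vars <- families[[fam]]
    miss <- setdiff(vars, names(features))
    if (length(miss)) {
      stop("features table lacks variables: ", paste(miss, collapse = ", "))
    }
    rows <- lapply(vars, function(v) {
      r <- two_sample_t(features[[v]][grouping == lv[1]],
                        features[[v]][grouping == lv[2]],
                        gate = gate, variable = v, groups = lv)
      r$family <- fam
      r
    })
    fam_df <- do.call(rbind, rows)
    fam_df$p_adj <- as.numeric(bh_adjust(fam_df$p_raw))
    res[[fam]] <- fam_df
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  class(out) <- c("comparison_battery", "data.frame")
  out
}

#' @export
print.comparison_battery <- function(x, digits = 2, ...) {
  cat("<comparison_battery> ", x$group1[1], " vs ", x$group2[1],
      " (n = ", x$n1[1], "/", x$n2[1], ")\n", sep = "")
  df <- data.frame(
    family = x$family,
    variable = x$variable,
    m1 = round(x$mean1, digits), sd1 = round(x$sd1, digits),
    m2 = round(x$mean2, digits), sd2 = round(x$sd2, digits),
    test = x$test_kind,
    t = round(x$t, digits), df = round(x$df, digits),
    p_adj = signif(x$p_adj, 2), d = round(x$cohen_d, digits)
  )
  print(df, row.names = FALSE)
  invisible(x)
}

#' Write a comparison battery to CSV
#'
#' Fixed, documented column order: family, variable, group1, group2, n1, n2,
#' mean1, sd1, mean2, sd2, levene_W, levene_p, test_kind, t, df, p_raw,
#' p_adj, cohen_d.
#'
#' @param battery A `comparison_battery`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_battery_csv <- function(battery, path) {
  cols <- c("family", "variable", "group1", "group2", "n1", "n2",
            "mean1", "sd1", "mean2", "sd2", "levene_W", "levene_p",
            "test_kind", "t", "df", "p_raw", "p_adj", "cohen_d")
  utils::write.csv(battery[, cols], path, row.names = FALSE)
  invisible(path)
}
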