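#' Pearson chi-square test of a contingency table
#'
#' Classic Pearson chi-square without continuity correction:
#' `sum((O - E)^2 / E)` on `(r-1)(c-1)` degrees of freedom.  No automatic
#' Fisher fallback is applied even with sparse cells — baseline tables in
#' small clinical cohorts are conventionally reported with the plain
#' chi-square — but an expected count below 5 raises a warning, and
#' `fisher = TRUE` switches to Fisher's exact test for sensitivity checks.
#'
#' @param counts Matrix (at least 2x2) of non-negative counts.
#' @param fisher Use [stats::fisher.test()] instead.
#' @return List with `statistic`, `df`, `p` (for Fisher, `statistic` and
#'   `df` are `NA`), and `expected` counts.
#' @export
pearson_chi2 <- function(counts, fisher = FALSE) {
  counts <- as.matrix(counts)
  if (nrow(counts) < 2L || ncol(counts) < 2L) {
    stop("contingency table must be at least 2x2", call. = FALSE)
  }
  if (anyNA(counts) || any(counts < 0)) {
    stop("counts must be non-negative without missing values", call. = FALSE)
  }
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0)) {
    stop("every row and column marginal must be positive", call. = FALSE)
  }
  if (fisher) {
    ht <- stats::fisher.test(counts)
    return(list(statistic = NA_real_, df = NA_integer_, p = ht$p.value,
                expected = outer(rowSums(counts), colSums(counts)) /
                  sum(counts)))
  }
  ht <- suppressWarnings(stats::chisq.test(counts, correct = FALSE))
  if (any(ht$expected < 5)) {
    warning("some expected cell counts are below 5; ",
            "chi-square approximation may be poor", call. = FALSE)
  }
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value, expected = ht$expected)
}

#' Mann-Whitney U test
#'
#' Two-sided rank-sum comparison of two samples.  The exact permutation
#' distribution is enumerated when `n1 * n2 <= exact_limit` and the data
#' are tie-free; otherwise the tie-corrected normal approximation with
#' continuity correction is used.  Ties are handled by midranks.
#'
#' @param x,y Numeric samples, each non-empty.
#' @param exact_limit Product `n1 * n2` up to which the exact distribution
#'   is used (default 400).
#' @return List with `U` (number of (x, y) pairs with x > y, counting ties
#'   as 1/2), `p`, and `exact` (logical, which path was taken).
#' @export
mann_whitney_u <- function(x, y, exact_limit = 400) {
  if (!length(x) || !length(y)) {
    stop("both samples must be non-empty", call. = FALSE)
  }
  ties <- anyDuplicated(c(x, y)) > 0L
  exact <- !ties && length(x) * length(y) <= exact_limit
  ht <- stats::wilcox.test(x, y, exact = exact, correct = TRUE)
  list(U = unname(ht$statistic), p = ht$p.value, exact = exact)
}

#' Two-group numeric summary with a comparison p-value
#'
#' Per-group mean and sample (n-1) standard deviation — the clinical
#' reporting convention "mean +/- SD" — together with a two-sided p-value.
#' The default comparison is the Mann-Whitney U test (the nonparametric
#' convention for baseline tables); Welch's t is also computed, and both
#' p-values are returned so reports can show either.
#'
#' @param x,y Numeric samples with at least 2 values each.
#' @param test Which p-value populates `$p`: `"mann-whitney"` (default) or
#'   `"welch"`.
#' @return List: `mean_x`, `sd_x`, `n_x`, `mean_y`, `sd_y`, `n_y`, `p`,
#'   `p_mann_whitney`, `p_welch`, `test`.
#' @export
two_sample_mean_summary <- function(x, y, test = c("mann-whitney", "welch")) {
  test <- match.arg(test)
  if (length(x) < 2L || length(y) < 2L) {
    stop("each group needs at least 2 observations", call. = FALSE)
  }
  p_mw <- mann_whitney_u(x, y)$p
  p_w <- if (stats::sd(x) == 0 && stats::sd(y) == 0) {
    if (mean(x) == mean(y)) 1 else 0
  } else {
    stats::t.test(x, y)$p.value
  }
  list(mean_x = mean(x), sd_x = stats::sd(x), n_x = length(x),
       mean_y = mean(y), sd_y = stats::sd(y), n_y = length(y),
       p = if (test == "mann-whitney") p_mw else p_w,
       p_mann_whitney = p_mw, p_welch = p_w, test = test)
}

#' Baseline characteristics table by group
#'
#' Builds a baseline comparison in the layout of a clinical "Table 2":
#' numeric characteristics summarized as median (range) and compared by
#' Mann-Whitney; categorical ones as per-group counts compared by Pearson
#' chi-square.  Rows with a missing value of a characteristic are dropped
#' listwise for that characteristic only, with a message giving the count.
#'
#' @param data Data frame (e.g. a [cohort()]).
#' @param group Factor (or column name in `data`) with 2+ levels.
#' @param numeric_vars,categorical_vars Character vectors of column names.
#' @return Data frame with columns `characteristic`, one summary column per
#'   group level, `p`, `test`.
#' @export
baseline_table <- function(data, group, numeric_vars = character(),
                           categorical_vars = character()) {
  if (is.character(group) && length(group) == 1L) group <- data[[group]]
  group <- factor(group)
  lev <- levels(group)
  out <- list()
  for (v in numeric_vars) {
    x <- data[[v]]
    ok <- !is.na(x) & !is.na(group)
    if (any(!ok)) message(sum(!ok), " record(s) dropped for '", v, "'")
    sp <- split(x[ok], group[ok])
    p <- if (all(lengths(sp) > 0) && length(sp) == 2L) {
      mann_whitney_u(sp[[1L]], sp[[2L]])$p
    } else {
      stats::kruskal.test(x[ok], group[ok])$p.value
    }
    row <- data.frame(characteristic = v, t(vapply(sp, function(s) {
      sprintf("%.1f (%.1f-%.1f)", stats::median(s), min(s), max(s))
    }, character(1))), p = p, test = "mann-whitney",
    check.names = FALSE)
    names(row)[2:(1 + length(lev))] <- lev
    out[[length(out) + 1L]] <- row
  }
  for (v in categorical_vars) {
    x <- factor(data[[v]])
    ok <- !is.na(x) & !is.na(group)
    if (any(!ok)) message(sum(!ok), " record(s) dropped for '", v, "'")
    tab <- table(x[ok], group[ok])
    p <- tryCatch(pearson_chi2(tab)$p, error = function(e) NA_real_)
    row <- data.frame(characteristic = v, t(vapply(lev, function(l) {
      paste(sprintf("%s:%d", rownames(tab), tab[, l]), collapse = " ")
    }, character(1))), p = p, test = "pearson-chi2", check.names = FALSE)
    names(row)[2:(1 + length(lev))] <- lev
    out[[length(out) + 1L]] <- row
  }
  do.call(rbind, out)
}
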