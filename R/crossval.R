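#' Random equal-size split of a cohort
#'
#' Uniformly random partition of the cohort rows into subsets A and B of
#' (as close as possible) equal size.  With odd n, subset A receives the
#' extra patient — an arbitrary but fixed convention so that a given
#' (cohort order, seed) pair always reproduces the same partition.
#'
#' @param x A [cohort()] or an integer cohort size.
#' @param seed Integer seed; required, so the split is always reproducible.
#' @return List with integer row indices `A` and `B` (each sorted) and the
#'   seed as an attribute.
#' @export
split_cohort <- function(x, seed) {
  n <- if (is.numeric(x) && length(x) == 1L) as.integer(x) else nrow(x)
  if (is.na(n) || n < 4L) {
    stop("cohort must contain at least 4 patients to split", call. = FALSE)
  }
  perm <- with_seed(seed, sample.int(n))
  nA <- as.integer(ceiling(n / 2))
  structure(list(A = sort(perm[seq_len(nA)]), B = sort(perm[-seq_len(nA)])),
            seed = seed)
}

#' Two-fold cross-validated cut-point significance test
#'
#' An honest significance test for a data-derived cut-point, following the
#' two-fold cross-validation idea of Faraggi and Simon.  The cohort is
#' randomly split into subsets A and B of equal size.  Within each subset
#' the cut-point scan ([scan_cutpoints()]) finds the cutoff with minimal
#' two-sided log-rank p.  Subset B patients are then labelled
#' above/below using subset A's cutoff, and subset A patients using subset
#' B's cutoff — so no patient's label ever depends on a cutoff estimated
#' from data containing that patient.  Finally a log-rank test of
#' above vs below, stratified by subset, yields the reported chi-square and
#' p-value.  Unlike the naive minimum p over the full-data scan, this p is
#' approximately calibrated under the null.
#'
#' A single random split is used, as in the classical procedure; see
#' [cv_sensitivity()] for a multi-split view across seeds (an extension
#' beyond the classical single-split test).
#'
#' @param x A [cohort()].
#' @param marker Name of the marker column (default `"dplt"`).
#' @param endpoint `"pfs"` or `"os"`; selects `<endpoint>_time` /
#'   `<endpoint>_event`.
#' @param min_group_frac Passed to the within-subset scans.
#' @param seed Integer seed for the split; required and recorded in the
#'   result.
#' @return A `crossval_result`: `seed`, per-patient `split` (A/B) and
#'   `pooled` (above/below) labels, `cutoff_A`, `cutoff_B`, stratified
#'   log-rank `chi2`, `df` and `p`.
#' @export
cv_cutpoint_test <- function(x, marker = "dplt",
                             endpoint = c("pfs", "os"),
                             min_group_frac = 0.10, seed) {
  stopifnot(inherits(x, "cohort"))
  endpoint <- match.arg(endpoint)
  time <- x[[paste0(endpoint, "_time")]]
  event <- x[[paste0(endpoint, "_event")]]
  mk <- x[[marker]]
  if (is.null(mk)) stop("no column '", marker, "' in cohort", call. = FALSE)
  sp <- split_cohort(x, seed)
  n <- nrow(x)

  scan_subset <- function(rows, label) {
    tryCatch(
      scan_cutpoints(survival_sample(time[rows], event[rows]), mk[rows],
                     min_group_frac = min_group_frac, marker_name = marker),
      error = function(e) {
        stop(sprintf(
          "cut-point scan failed in subset %s (seed %s): %s",
          label, format(seed), conditionMessage(e)), call. = FALSE)
      })
  }
  cutoff_A <- optimal_cutpoint(scan_subset(sp$A, "A"))
  cutoff_B <- optimal_cutpoint(scan_subset(sp$B, "B"))

  # honest assignment: each patient classified by the *other* fold's cutoff
  above <- logical(n)
  above[sp$B] <- mk[sp$B] > cutoff_A
  above[sp$A] <- mk[sp$A] > cutoff_B
  split_lab <- factor(rep("B", n), levels = c("A", "B"))
  split_lab[sp$A] <- "A"

  res <- suppressMessages(stratified_logrank(survival_sample(
    time, event,
    group = factor(ifelse(above, "above", "below"),
                   levels = c("below", "above")),
    stratum = split_lab)))

  structure(list(seed = seed,
                 split = split_lab,
                 pooled = factor(ifelse(above, "above", "below"),
                                 levels = c("below", "above")),
                 cutoff_A = cutoff_A, cutoff_B = cutoff_B,
                 chi2 = res$chi2, df = res$df, p = res$p,
                 endpoint = endpoint, marker = marker),
            class = "crossval_result")
}

#' @export
print.crossval_result <- function(x, ...) {
  cat(sprintf(
    "<crossval_result> %s on %s (seed %s)\n", x$marker, toupper(x$endpoint),
    format(x$seed)))
  cat(sprintf("  cutoff A = %g, cutoff B = %g\n", x$cutoff_A, x$cutoff_B))
  cat(sprintf("  stratified log-rank chi2 = %.4f (df %d), p = %.4g\n",
              x$chi2, x$df, x$p))
  invisible(x)
}

#' Multi-split sensitivity of the cross-validated test
#'
#' Repeats [cv_cutpoint_test()] over several seeds and tabulates the
#' fold-specific cutoffs and p-values.  This is an exploratory extension of
#' the classical single-split procedure: the classical test reports one
#' split, and this table shows how much the answer moves with the split.
#'
#' @inheritParams cv_cutpoint_test
#' @param seeds Integer vector of split seeds.
#' @return Data frame with one row per seed: `seed`, `cutoff_A`,
#'   `cutoff_B`, `chi2`, `p`.
#' @export
cv_sensitivity <- function(x, seeds, marker = "dplt",
                           endpoint = c("pfs", "os"),
                           min_group_frac = 0.10) {
  endpoint <- match.arg(endpoint)
  rows <- lapply(seeds, function(s) {
    r <- cv_cutpoint_test(x, marker = marker, endpoint = endpoint,
                          min_group_frac = min_group_frac, seed = s)
    data.frame(seed = s, cutoff_A = r$cutoff_A, cutoff_B = r$cutoff_B,
               chi2 = r$chi2, p = r$p)
  })
  do.call(rbind, rows)
}

#' Export a cross-validation result as tables
#'
#' @param x A `crossval_result`.
#' @param ... Unused.
#' @return Data frame with one row per patient (`split`, `pooled`) plus the
#'   summary carried in attributes `cutoff_A`, `cutoff_B`, `chi2`, `p`,
#'   `seed`.
#' @export
as.data.frame.crossval_result <- function(x, ...) {
  structure(data.frame(split = x$split, pooled = x$pooled),
            cutoff_A = x$cutoff_A, cutoff_B = x$cutoff_B,
            chi2 = x$chi2, p = x$p, seed = x$seed)
}
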