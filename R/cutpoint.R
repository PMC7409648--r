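#' Admissible candidate cut-points
#'
#' Enumerates the distinct observed marker values whose strict-greater
#' dichotomization leaves both groups with at least
#' `max(1, ceiling(min_group_frac * n))` members.  The global maximum is
#' never a candidate (its high group is empty).  Candidates are observed
#' values rather than midpoints, keeping cut-points interpretable in the
#' marker's original units.
#'
#' @param values Numeric marker vector with at least 2 distinct values.
#' @param min_group_frac Minimum fraction of the cohort required in each
#'   group, in `[0, 0.5)`.  Default 0.10: permissive enough to admit
#'   clinically lopsided splits (roughly 20/80) while excluding degenerate
#'   tails.
#' @return Ascending numeric vector of admissible cut-points.
#' @export
candidate_cutpoints <- function(values, min_group_frac = 0.10) {
  if (!is.numeric(values) || anyNA(values)) {
    stop("'values' must be numeric without missing values", call. = FALSE)
  }
  if (!is.numeric(min_group_frac) || length(min_group_frac) != 1L ||
      min_group_frac < 0 || min_group_frac >= 0.5) {
    stop("'min_group_frac' must lie in [0, 0.5)", call. = FALSE)
  }
  n <- length(values)
  v <- sort(unique(values))
  if (length(v) < 2L) {
    stop("marker is constant: no admissible cut-point exists", call. = FALSE)
  }
  gmin <- max(1L, ceiling(min_group_frac * n))
  n_low <- cumsum(tabulate(match(sort(values), v), length(v)))
  n_high <- n - n_low
  ok <- n_low >= gmin & n_high >= gmin
  if (!any(ok)) {
    stop("no admissible candidate cut-point; lower 'min_group_frac'",
         call. = FALSE)
  }
  v[ok]
}

#' Scan candidate cut-points by maximal log-rank chi-square
#'
#' The core of the cut-point search: for every admissible candidate the
#' marker is dichotomized (high = strictly greater), the two-group log-rank
#' test is run, and the chi-square, p-value, direction of association and
#' group sizes are recorded.  The optimum is the candidate with maximal
#' chi-square (equivalently minimal p at 1 df); ties break to the smallest
#' candidate value.  Direction is `"direct"` when the high-marker group has
#' fewer observed events than expected (higher marker, better outcome),
#' `"indirect"` when more, `"none"` when observed equals expected (including
#' candidates with no events at all, which score chi-square 0).
#'
#' Because every entry is a full log-rank test on a data-derived split, the
#' minimal p across the profile is *not* an honest p-value; see
#' [cv_cutpoint_test()] for the cross-validated test that corrects it.
#'
#' @param sample A [survival_sample()] (group labels, if any, are ignored).
#' @param marker Numeric marker vector aligned with `sample`.
#' @param min_group_frac Passed to [candidate_cutpoints()].
#' @param marker_name Label stored in the profile.
#' @return A `cutpoint_profile`: data frame with columns `candidate`,
#'   `chi2`, `p`, `direction`, `n_high`, `n_low`, and attributes `optimal`
#'   (row index of the selected candidate), `marker_name`, `n`.
#' @export
scan_cutpoints <- function(sample, marker, min_group_frac = 0.10,
                           marker_name = "marker") {
  stopifnot(inherits(sample, "survival_sample"))
  n <- length(sample$time)
  if (length(marker) != n) {
    stop("'marker' length differs from the survival sample", call. = FALSE)
  }
  cand <- candidate_cutpoints(marker, min_group_frac)
  k <- length(cand)
  chi2 <- p <- numeric(k)
  n_high <- n_low <- integer(k)
  dir <- character(k)
  for (i in seq_len(k)) {
    hi <- marker > cand[i]
    gint <- 1L + hi                     # 1 = low, 2 = high
    res <- .logrank_engine(sample$time, sample$event, gint, 2L)
    chi2[i] <- res$chi2
    p[i] <- stats::pchisq(res$chi2, 1L, lower.tail = FALSE)
    n_high[i] <- sum(hi)
    n_low[i] <- n - n_high[i]
    d_high <- res$u[2L]                 # O_high - E_high
    dir[i] <- if (d_high < 0) "direct" else if (d_high > 0) "indirect"
              else "none"
  }
  opt <- which(chi2 == max(chi2))[1L]   # candidates ascending: smallest tie
  structure(data.frame(candidate = cand, chi2 = chi2, p = p,
                       direction = dir, n_high = n_high, n_low = n_low),
            optimal = opt, marker_name = marker_name, n = n,
            min_group_frac = min_group_frac,
            class = c("cutpoint_profile", "data.frame"))
}

#' Optimal cut-point of a scan profile
#'
#' @param profile A `cutpoint_profile` from [scan_cutpoints()].
#' @return The marker value attaining the maximal log-rank chi-square
#'   (smallest value under ties).
#' @export
optimal_cutpoint <- function(profile) {
  stopifnot(inherits(profile, "cutpoint_profile"))
  profile$candidate[attr(profile, "optimal")]
}

#' @export
print.cutpoint_profile <- function(x, ...) {
  opt <- attr(x, "optimal")
  cat(sprintf(
    "<cutpoint_profile> %s: %d candidates over n = %d\n",
    attr(x, "marker_name"), nrow(x), attr(x, "n")))
  cat(sprintf(
    "  optimum: %s > %g (chi2 = %.3f, p = %.4g, %d high / %d low, %s)\n",
    attr(x, "marker_name"), x$candidate[opt], x$chi2[opt], x$p[opt],
    x$n_high[opt], x$n_low[opt], x$direction[opt]))
  invisible(x)
}

#' Marker histogram as a table
#'
#' Tabular counterpart of the scan's companion marker-distribution plot:
#' bin edges and counts, exportable as delimited text.
#'
#' @param values Numeric marker vector.
#' @param breaks Passed to [graphics::hist()] (computed, never plotted).
#' @return Data frame with `bin_lower`, `bin_upper`, `count`.
#' @export
marker_histogram <- function(values, breaks = "Sturges") {
  h <- graphics::hist(values, breaks = breaks, plot = FALSE)
  data.frame(bin_lower = utils::head(h$breaks, -1L),
             bin_upper = h$breaks[-1L],
             count = h$counts)
}
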