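#' Bundle survival follow-up vectors
#'
#' Packs parallel vectors of follow-up time (months), event indicator
#' (1 = event, 0 = censored) and optional group / stratum labels into a
#' validated `survival_sample`, the unit consumed by [km_estimate()],
#' [logrank_test()], [stratified_logrank()] and [scan_cutpoints()].
#'
#' @param time Follow-up durations, months, >= 0.
#' @param event 0/1 event indicators.
#' @param group Optional group labels (factor or coercible).
#' @param stratum Optional stratum labels.
#' @return A `survival_sample` list.
#' @export
survival_sample <- function(time, event, group = NULL, stratum = NULL) {
  check_nonneg(time, "time")
  check_event(event, "event")
  n <- length(time)
  if (n == 0L) stop("survival sample must contain at least one record",
                    call. = FALSE)
  if (length(event) != n) stop("'time' and 'event' lengths differ",
                               call. = FALSE)
  if (!is.null(group) && length(group) != n) {
    stop("'group' length differs from 'time'", call. = FALSE)
  }
  if (!is.null(stratum) && length(stratum) != n) {
    stop("'stratum' length differs from 'time'", call. = FALSE)
  }
  as_factor <- function(x) if (is.factor(x)) x else factor(x)
  structure(list(time = as.numeric(time), event = as.integer(event),
                 group = if (!is.null(group)) as_factor(group),
                 stratum = if (!is.null(stratum)) as_factor(stratum)),
            class = "survival_sample")
}

#' Kaplan-Meier product-limit estimate
#'
#' Standard product-limit estimator for a single group.  Ties at one time
#' are handled by a single simultaneous factor; records censored at an
#' event time remain in the risk set for that time (censoring is taken to
#' occur after events at equal times).  An all-censored sample yields a
#' curve that is identically 1 with no event times.
#'
#' @param time Follow-up times, or a [survival_sample()] (single group).
#' @param event 0/1 event indicators (ignored when `time` is a sample).
#' @return A `km_curve` with fields `event_times` (ascending distinct times
#'   with at least one event), `survival` (step values S(t)), `at_risk`,
#'   `n_events`, `n` and `max_time` (largest observed time, either status).
#' @export
km_estimate <- function(time, event = NULL) {
  if (inherits(time, "survival_sample")) {
    event <- time$event
    time <- time$time
  }
  check_nonneg(time, "time")
  check_event(event, "event")
  ord <- order(time)
  t <- time[ord]
  d <- event[ord]
  tt <- unique(t)                       # ascending
  m <- length(tt)
  idx <- match(t, tt)
  n_at <- rev(cumsum(rev(tabulate(idx, m))))
  n_ev <- tabulate(idx[d == 1L], m)
  surv <- cumprod(1 - n_ev / n_at)
  keep <- n_ev > 0L
  structure(list(event_times = tt[keep],
                 survival = surv[keep],
                 at_risk = n_at[keep],
                 n_events = n_ev[keep],
                 n = length(t),
                 max_time = if (length(t)) max(t) else NA_real_),
            class = "km_curve")
}

#' @export
print.km_curve <- function(x, ...) {
  cat(sprintf("<km_curve> n = %d, %d event time(s)\n",
              x$n, length(x$event_times)))
  if (length(x$event_times)) {
    utils::head(data.frame(time = x$event_times, at_risk = x$at_risk,
                           events = x$n_events, survival = x$survival),
                10L) |> print()
  }
  invisible(x)
}

#' Export a Kaplan-Meier curve as a table
#'
#' @param x A `km_curve`.
#' @param ... Unused.
#' @return Data frame with columns `time`, `survival`, `at_risk`,
#'   `n_events`, suitable for [utils::write.csv()] and external plotting.
#' @export
as.data.frame.km_curve <- function(x, ...) {
  data.frame(time = x$event_times, survival = x$survival,
             at_risk = x$at_risk, n_events = x$n_events)
}

#' Survival rate at a fixed horizon
#'
#' Reads the step function S(t) at `horizon` months: the value at the
#' largest event time not exceeding the horizon, or 1 before the first
#' event.  When the horizon lies beyond the largest observed follow-up the
#' last value is carried forward and flagged via the `beyond_follow_up`
#' attribute.
#'
#' @param curve A `km_curve`.
#' @param horizon Months, >= 0.
#' @return Survival proportion with attribute `beyond_follow_up` (logical).
#' @export
survival_rate_at <- function(curve, horizon) {
  stopifnot(inherits(curve, "km_curve"))
  if (!is.numeric(horizon) || length(horizon) != 1L || is.na(horizon) ||
      horizon < 0) {
    stop("'horizon' must be a single number >= 0", call. = FALSE)
  }
  i <- findInterval(horizon, curve$event_times)
  s <- if (i == 0L) 1 else curve$survival[i]
  structure(s, beyond_follow_up = is.finite(curve$max_time) &&
              horizon > curve$max_time)
}

# Core log-rank accumulator.  For each stratum, tabulates risk sets at the
# distinct event times and accumulates per-group observed counts, expected
# counts and the hypergeometric (co)variance.  Both the unstratified and
# the stratified tests run through this single routine (the unstratified
# test is the constant-stratum case), so their agreement is structural.
# gint: integer group codes 1..K; stratum: integer codes (any).
.logrank_engine <- function(time, event, gint, K, stratum = NULL) {
  n <- length(time)
  obs <- numeric(K)
  expd <- numeric(K)
  V <- matrix(0, K, K)
  chunks <- if (is.null(stratum)) list(seq_len(n)) else
    split(seq_len(n), stratum)
  for (rows in chunks) {
    if (!length(rows)) next
    t <- time[rows]; d <- event[rows]; g <- gint[rows]
    o <- order(t)
    t <- t[o]; d <- d[o]; g <- g[o]
    tt <- unique(t)
    m <- length(tt)
    idx <- match(t, tt)
    ev_all <- tabulate(idx[d == 1L], m)
    keep <- ev_all > 0L
    if (!any(keep)) next
    n_at <- rev(cumsum(rev(tabulate(idx, m))))
    nj <- n_at[keep]
    dj <- ev_all[keep]
    # hypergeometric variance weight; zero when the risk set is a singleton
    w <- ifelse(nj > 1L, dj * (nj - dj) / (nj - 1), 0)
    p <- matrix(0, sum(keep), K)
    for (k in seq_len(K)) {
      cnt_k <- tabulate(idx[g == k], m)
      ev_k <- tabulate(idx[d == 1L & g == k], m)
      nk <- rev(cumsum(rev(cnt_k)))[keep]
      obs[k] <- obs[k] + sum(ev_k[keep])
      p[, k] <- nk / nj
      expd[k] <- expd[k] + sum(dj * p[, k])
    }
    for (k in seq_len(K)) {
      for (l in k:K) {
        v <- sum(w * p[, k] * ((k == l) - p[, l]))
        V[k, l] <- V[k, l] + v
        if (l > k) V[l, k] <- V[l, k] + v
      }
    }
  }
  u <- obs - expd
  if (K == 2L) {
    chi2 <- if (V[1L, 1L] > 0) u[1L]^2 / V[1L, 1L] else 0
  } else {
    Vs <- V[-K, -K, drop = FALSE]
    us <- u[-K]
    chi2 <- tryCatch(drop(crossprod(us, solve(Vs, us))), error = function(e) {
      # rank-deficient variance (e.g. empty risk overlaps): pseudo-inverse
      s <- svd(Vs)
      pos <- s$d > max(s$d) * 1e-12
      drop(crossprod(us, s$v[, pos, drop = FALSE] %*%
                       ((t(s$u[, pos, drop = FALSE]) %*% us) / s$d[pos])))
    })
    if (!is.finite(chi2) || chi2 < 0) chi2 <- 0
  }
  list(chi2 = chi2, obs = obs, expd = expd, V = V, u = u)
}

.logrank_build <- function(sample, stratum, warn = TRUE) {
  stopifnot(inherits(sample, "survival_sample"))
  g <- sample$group
  if (is.null(g)) stop("sample has no group labels", call. = FALSE)
  if (!is.factor(g)) g <- factor(g)
  K <- nlevels(g)
  if (K < 2L) stop("log-rank test needs at least 2 groups", call. = FALSE)
  if (any(tabulate(as.integer(g), K) == 0L)) {
    stop("every group must contain at least one record", call. = FALSE)
  }
  res <- .logrank_engine(sample$time, sample$event, as.integer(g), K,
                         stratum = stratum)
  if (sum(sample$event) == 0L && warn) {
    warning("no events in sample; chi-square is 0 and p = 1", call. = FALSE)
  }
  df <- K - 1L
  structure(list(chi2 = res$chi2, df = df,
                 p = stats::pchisq(res$chi2, df, lower.tail = FALSE),
                 observed = stats::setNames(res$obs, levels(g)),
                 expected = stats::setNames(res$expd, levels(g)),
                 o_minus_e = stats::setNames(res$u, levels(g)),
                 var = res$V,
                 stratified = !is.null(stratum)),
            class = "logrank_result")
}

#' Log-rank test
#'
#' Two-sided log-rank test comparing the survival of the groups in
#' `sample`.  For two groups the statistic is `(O1 - E1)^2 / V` with the
#' hypergeometric variance summed over distinct event times; for K groups
#' the usual (K-1)-df quadratic form.  The p-value is the upper tail of the
#' chi-square reference distribution with `df = K - 1` — the conventional
#' reading of a "two-sided log-rank p".  Censored records tied with an
#' event time stay in that time's risk set.
#'
#' @param sample A [survival_sample()] with group labels; every group
#'   non-empty, and at least one event overall (zero events yields
#'   chi-square 0 and p = 1 with a warning).
#' @return A `logrank_result`: `chi2`, `df`, `p`, per-group `observed` and
#'   `expected` counts, `o_minus_e`, and the variance matrix `var`.
#' @seealso [stratified_logrank()]
#' @export
logrank_test <- function(sample) {
  .logrank_build(sample, stratum = NULL)
}

#' Stratified log-rank test
#'
#' Log-rank test with observed-minus-expected and variance contributions
#' accumulated within each stratum and summed across strata before the
#' quadratic form.  With a single stratum this reduces exactly (same code
#' path) to [logrank_test()].  A stratum containing only one group
#' contributes zero to both numerator and variance; this is reported via a
#' message, not an error.
#'
#' @param sample A [survival_sample()] with both group and stratum labels.
#' @return A `logrank_result` (see [logrank_test()]).
#' @export
stratified_logrank <- function(sample) {
  if (is.null(sample$stratum)) {
    stop("sample has no stratum labels", call. = FALSE)
  }
  g <- factor(sample$group)
  one_group <- vapply(split(as.integer(g), sample$stratum),
                      function(gg) length(unique(gg)) == 1L, logical(1))
  if (any(one_group)) {
    message(sum(one_group),
            " stratum(s) contain a single group and contribute nothing")
  }
  .logrank_build(sample, stratum = sample$stratum)
}

#' @export
print.logrank_result <- function(x, ...) {
  cat(sprintf("<%slog-rank> chi2 = %.4f on %d df, p = %.4g\n",
              if (x$stratified) "stratified " else "", x$chi2, x$df, x$p))
  print(data.frame(observed = x$observed, expected = x$expected))
  invisible(x)
}
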