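# Independent oracles, deliberately written in naive loop style so they
# share no code (and no vectorization tricks) with the package internals.

# Product-limit estimator by direct risk-set counting.
oracle_km <- function(time, event) {
  ts <- sort(unique(time[event == 1]))
  s <- 1
  surv <- numeric(length(ts))
  for (j in seq_along(ts)) {
    n_at <- sum(time >= ts[j])
    d <- sum(time == ts[j] & event == 1)
    s <- s * (1 - d / n_at)
    surv[j] <- s
  }
  list(times = ts, surv = surv)
}

# Two-group log-rank by explicit O/E/V tabulation over event times.
# g: logical, TRUE marks membership of the group whose O/E is tracked.
oracle_logrank2 <- function(time, event, g) {
  O <- E <- V <- 0
  for (t in sort(unique(time[event == 1]))) {
    at <- time >= t
    n <- sum(at)
    n1 <- sum(at & g)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & g)
    O <- O + d1
    E <- E + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  list(chi2 = if (V > 0) (O - E)^2 / V else 0, O = O, E = E, V = V)
}

# Exact permutation p of the two-group log-rank chi-square: enumerate all
# reassignments preserving the group sizes.
oracle_perm_p <- function(time, event, g) {
  n <- length(time)
  k <- sum(g)
  obs <- oracle_logrank2(time, event, g)$chi2
  combs <- utils::combn(n, k)
  stat <- apply(combs, 2L, function(idx) {
    gg <- rep(FALSE, n)
    gg[idx] <- TRUE
    oracle_logrank2(time, event, gg)$chi2
  })
  mean(stat >= obs - 1e-9)
}

# Efron partial log-likelihood for a single covariate, by direct summation.
oracle_cox_loglik <- function(beta, time, event, x) {
  eta <- beta * x
  w <- exp(eta)
  ll <- 0
  for (t in sort(unique(time[event == 1]))) {
    D <- which(time == t & event == 1)
    R <- which(time >= t)
    d <- length(D)
    swR <- sum(w[R])
    swD <- sum(w[D])
    ll <- ll + sum(eta[D])
    for (l in seq_len(d) - 1L) ll <- ll - log(swR - (l / d) * swD)
  }
  ll
}

# Brute-force maximizer of the single-covariate partial likelihood.
oracle_cox_mle <- function(time, event, x, interval = c(-8, 8)) {
  stats::optimize(function(b) oracle_cox_loglik(b, time, event, x),
                  interval = interval, maximum = TRUE,
                  tol = 1e-10)$maximum
}

# Small random censored sample for property loops.
random_sample <- function(n, cens_p = 0.3, tie_prob = 0) {
  tm <- if (tie_prob > 0) sample(1:5, n, replace = TRUE) else
    round(stats::rexp(n, 0.1), 6)
  list(time = tm, event = stats::rbinom(n, 1, 1 - cens_p))
}

# Tiny deterministic cohort table used across construction tests.
toy_cohort_df <- function(n = 8) {
  data.frame(
    patient_id = paste0("p", seq_len(n)),
    plt_pre = seq(10, by = 5, length.out = n),
    plt_peak = seq(200, by = 50, length.out = n),
    pfs_time = seq_len(n) * 2,
    pfs_event = rep(c(1L, 0L), length.out = n),
    os_time = seq_len(n) * 2 + 1,
    os_event = rep(c(1L, 0L), length.out = n),
    age = seq(20, by = 3, length.out = n),
    sex = rep(c("male", "female"), length.out = n),
    stringsAsFactors = FALSE)
}
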