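test_that("Kaplan-Meier matches hand tabulation, including tie handling", {
  # no censoring: survival steps through 2/3, 1/3, 0
  km <- km_estimate(c(5, 10, 15), c(1, 1, 1))
  expect_equal(km$event_times, c(5, 10, 15))
  expect_equal(km$survival, c(2 / 3, 1 / 3, 0))
  expect_equal(km$at_risk, c(3L, 2L, 1L))

  # all censored: S identically 1, no event times
  km0 <- km_estimate(c(5, 10), c(0, 0))
  expect_length(km0$event_times, 0)

  # censored record tied with the event at t = 4 stays in that risk set
  km2 <- km_estimate(c(2, 4, 4, 6), c(1, 1, 0, 1))
  expect_equal(km2$event_times, c(2, 4, 6))
  expect_equal(km2$survival, c(0.75, 0.5, 0))
  orc <- oracle_km(c(2, 4, 4, 6), c(1, 1, 0, 1))
  expect_equal(km2$survival, orc$surv)
})

test_that("Kaplan-Meier agrees with survival::survfit on censored samples", {
  set.seed(11)
  for (rep in 1:50) {
    n <- sample(3:40, 1)
    s <- random_sample(n, cens_p = 0.4, tie_prob = if (rep %% 2) 0.5 else 0)
    if (sum(s$event) == 0) next
    km <- km_estimate(s$time, s$event)
    sf <- survival::survfit(survival::Surv(s$time, s$event) ~ 1)
    at_event <- sf$n.event > 0
    expect_equal(km$event_times, sf$time[at_event])
    expect_equal(km$survival, sf$surv[at_event], tolerance = 1e-12)
    expect_equal(km$at_risk, sf$n.risk[at_event])
    # invariants: S non-increasing in [0, 1], risk sets strictly decreasing
    expect_true(all(diff(km$survival) <= 0))
    expect_true(all(km$survival >= 0 & km$survival <= 1))
    expect_true(all(diff(km$at_risk) < 0))
  }
})

test_that("survival_rate_at reads the step function and flags overreach", {
  km <- km_estimate(c(5, 10, 15), c(1, 1, 1))
  expect_equal(as.numeric(survival_rate_at(km, 0)), 1)
  expect_equal(as.numeric(survival_rate_at(km, 12)), 1 / 3)
  expect_equal(as.numeric(survival_rate_at(km, 10)), 1 / 3)
  expect_false(attr(survival_rate_at(km, 12), "beyond_follow_up"))
  r <- survival_rate_at(km, 99)
  expect_equal(as.numeric(r), 0)
  expect_true(attr(r, "beyond_follow_up"))
  expect_error(survival_rate_at(km, -1), "horizon")
})

test_that("log-rank matches the frozen hand-tabulated example", {
  # A: times 1,2; B: times 3,4; all events.  O_A = 2, E_A = 5/6,
  # V = 17/36, chi2 = 49/17 (hand tabulation over the 4 event times).
  s <- survival_sample(c(1, 2, 3, 4), c(1, 1, 1, 1),
                       group = c("A", "A", "B", "B"))
  r <- logrank_test(s)
  expect_equal(r$chi2, 49 / 17, tolerance = 1e-12)
  expect_equal(unname(r$observed["A"]), 2)
  expect_equal(unname(r$expected["A"]), 5 / 6, tolerance = 1e-12)
  expect_equal(r$df, 1L)
  expect_equal(sum(r$observed), sum(r$expected), tolerance = 1e-10)
  orc <- oracle_logrank2(s$time, s$event, s$group == "A")
  expect_equal(r$chi2, orc$chi2, tolerance = 1e-12)
})

test_that("log-rank degenerate and error contracts hold", {
  # identical (time, event) multisets in both groups: perfect symmetry
  s <- survival_sample(c(1, 2, 3, 1, 2, 3), c(1, 0, 1, 1, 0, 1),
                       group = rep(c("A", "B"), each = 3))
  r <- logrank_test(s)
  expect_equal(r$chi2, 0)
  expect_equal(r$p, 1)

  # zero events: chi2 = 0, p = 1, with a warning
  s0 <- survival_sample(c(1, 2, 3, 4), c(0, 0, 0, 0),
                        group = c("A", "A", "B", "B"))
  expect_warning(r0 <- logrank_test(s0), "no events")
  expect_equal(r0$chi2, 0)
  expect_equal(r0$p, 1)

  # an empty group level is an error
  g <- factor(c("A", "A", "B", "B"), levels = c("A", "B", "C"))
  expect_error(logrank_test(survival_sample(1:4, c(1, 1, 1, 1), group = g)),
               "at least one record")
  expect_error(logrank_test(survival_sample(1:4, c(1, 1, 1, 1))), "group")
})

test_that("log-rank agrees with survival::survdiff, also for 3 groups", {
  set.seed(23)
  # 67-patient synthetic cohort at a fixed prespecified cutoff
  co <- generate_cohort(cohort_config(seed = 17))
  g <- dichotomize(co$dplt, 300)
  r <- logrank_test(survival_sample(co$pfs_time, co$pfs_event, group = g))
  sd2 <- survival::survdiff(survival::Surv(pfs_time, pfs_event) ~ g,
                            data = data.frame(pfs_time = co$pfs_time,
                                              pfs_event = co$pfs_event,
                                              g = g))
  expect_equal(r$chi2, unname(sd2$chisq), tolerance = 1e-8)
  expect_equal(unname(r$observed), unname(sd2$obs), tolerance = 1e-10)
  expect_equal(unname(r$expected), unname(sd2$exp), tolerance = 1e-10)

  for (rep in 1:20) {
    n <- sample(10:50, 1)
    s <- random_sample(n, tie_prob = if (rep %% 2) 0.5 else 0)
    grp <- sample(c("x", "y", "z"), n, replace = TRUE)
    if (length(unique(grp)) < 3 || sum(s$event) == 0) next
    r3 <- logrank_test(survival_sample(s$time, s$event, group = grp))
    sd3 <- survival::survdiff(survival::Surv(tt, ee) ~ gg,
                              data = data.frame(tt = s$time, ee = s$event,
                                                gg = grp))
    expect_equal(r3$chi2, unname(sd3$chisq), tolerance = 1e-8)
    expect_equal(r3$df, 2L)
  }
})

test_that("log-rank is invariant under monotone time transformation", {
  set.seed(31)
  s <- random_sample(30, cens_p = 0.3)
  grp <- rep(c("A", "B"), 15)
  r1 <- logrank_test(survival_sample(s$time, s$event, group = grp))
  for (f in list(function(t) t^2, function(t) log1p(t), function(t) 3 * t)) {
    r2 <- logrank_test(survival_sample(f(s$time), s$event, group = grp))
    expect_equal(r2$chi2, r1$chi2, tolerance = 1e-12)
  }
})

test_that("stratified log-rank reduces, cancels and sums correctly", {
  set.seed(47)
  # one stratum: identical to the unstratified test, bit for bit
  for (rep in 1:20) {
    s <- random_sample(sample(6:30, 1), tie_prob = 0.5)
    grp <- sample(c("A", "B"), length(s$time), replace = TRUE)
    if (length(unique(grp)) < 2 || sum(s$event) == 0) next
    un <- logrank_test(survival_sample(s$time, s$event, group = grp))
    st <- stratified_logrank(survival_sample(
      s$time, s$event, group = grp,
      stratum = rep("all", length(s$time))))
    expect_identical(st$chi2, un$chi2)
    expect_identical(st$p, un$p)
  }

  # two internally symmetric strata: O = E within each stratum
  tm <- c(1, 2, 3, 1, 2, 3, 4, 5, 4, 5)
  ev <- rep(1, 10)
  grp <- c("A", "A", "A", "B", "B", "B", "A", "A", "B", "B")
  str <- c(rep(1, 6), rep(2, 4))
  r <- stratified_logrank(survival_sample(tm, ev, group = grp,
                                          stratum = str))
  expect_equal(r$chi2, 0)

  # opposite effects of equal magnitude cancel in the summed O - E
  tm2 <- c(1, 2, 9, 10, 9, 10, 1, 2)
  ev2 <- rep(1, 8)
  grp2 <- rep(c("A", "A", "B", "B"), 2)
  str2 <- rep(c("s1", "s2"), each = 4)
  per_stratum <- lapply(split(seq_along(tm2), str2), function(i) {
    oracle_logrank2(tm2[i], ev2[i], grp2[i] == "A")
  })
  u_sum <- sum(vapply(per_stratum, function(o) o$O - o$E, 0))
  v_sum <- sum(vapply(per_stratum, function(o) o$V, 0))
  rs <- stratified_logrank(survival_sample(tm2, ev2, group = grp2,
                                           stratum = str2))
  expect_equal(rs$chi2, u_sum^2 / v_sum, tolerance = 1e-12)
  expect_equal(rs$chi2, 0, tolerance = 1e-12)  # exact cancellation here
  expect_gt(per_stratum[[1]]$chi2, 1)          # despite large per-stratum chi2

  # agreement with survival::survdiff + strata on random data
  for (rep in 1:10) {
    n <- 40
    s <- random_sample(n, tie_prob = 0.5)
    grp <- sample(c("A", "B"), n, replace = TRUE)
    str <- sample(c("u", "v", "w"), n, replace = TRUE)
    if (length(unique(grp)) < 2 || sum(s$event) == 0) next
    r1 <- suppressMessages(stratified_logrank(
      survival_sample(s$time, s$event, group = grp, stratum = str)))
    sdo <- survival::survdiff(
      survival::Surv(tt, ee) ~ gg + survival::strata(ss),
      data = data.frame(tt = s$time, ee = s$event, gg = grp, ss = str))
    expect_equal(r1$chi2, unname(sdo$chisq), tolerance = 1e-8)
  }

  # a stratum holding a single group contributes nothing, with a message
  tm3 <- c(1, 2, 3, 4, 5, 6)
  grp3 <- c("A", "B", "A", "B", "A", "A")
  str3 <- c(1, 1, 1, 1, 2, 2)
  expect_message(
    r3 <- stratified_logrank(survival_sample(tm3, rep(1, 6), group = grp3,
                                             stratum = str3)),
    "single group")
  r3_only <- logrank_test(survival_sample(tm3[1:4], rep(1, 4),
                                          group = grp3[1:4]))
  expect_equal(r3$chi2, r3_only$chi2, tolerance = 1e-12)
})
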