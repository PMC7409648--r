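test_that("design encoding expands references and collapses courses", {
  df <- data.frame(
    age = c(30, 40, 50),
    risk_group = c("favorable", "intermediate", "adverse"),
    courses_to_cr = c(1L, 2L, 3L),
    sex = c("female", "male", "female"),
    consolidation = c("HDAraC", "AML-87", "AML-201"),
    dplt_group = factor(c("high", "low", "high"), c("high", "low")))
  enc <- encode_design(df, default_covariate_spec())
  x <- enc$x
  expect_equal(colnames(x),
               c("age", "sex=male", "risk_group=intermediate",
                 "risk_group=adverse", "courses_to_cr=more than 1",
                 "consolidation=AML-87", "consolidation=AML-201",
                 "dplt_group=low"))
  # 3-level risk with reference favorable: two indicator columns
  expect_equal(unname(x[, "risk_group=intermediate"]), c(0, 1, 0))
  expect_equal(unname(x[, "risk_group=adverse"]), c(0, 0, 1))
  # courses 1, 2, 3 collapse to a single "more than 1" indicator
  expect_equal(unname(x[, "courses_to_cr=more than 1"]), c(0, 1, 1))
  # the all-reference patient has an all-zero categorical row
  expect_true(all(x[1, -1] == 0))

  df_bad <- df
  df_bad$risk_group[2] <- "unknown-risk"
  expect_error(encode_design(df_bad, default_covariate_spec()),
               "unknown-risk")

  df_na <- df
  df_na$age[3] <- NA
  expect_message(enc2 <- encode_design(df_na, default_covariate_spec()),
                 "1 record")
  expect_equal(enc2$n_dropped, 1)
  expect_equal(enc2$rows, c(1L, 2L))
})

test_that("a null binary covariate gives hazard ratio near 1", {
  set.seed(51)
  n <- 200
  x <- matrix(rbinom(n, 1, 0.5), ncol = 1,
              dimnames = list(NULL, "grp"))
  time <- rexp(n, 0.1)
  event <- rbinom(n, 1, 0.7)
  f <- fit_cox(x, time, event)
  expect_lt(abs(f$coefficients$estimate), 0.3)
  expect_true(f$coefficients$ci_lower < 1 && f$coefficients$ci_upper > 1)
  expect_true(f$converged)
})

test_that("estimates match brute-force partial-likelihood maximization", {
  set.seed(52)
  # untied small sample
  n <- 25
  x <- rbinom(n, 1, 0.4)
  time <- round(rexp(n, 0.1) * exp(-0.8 * x), 6)
  event <- rbinom(n, 1, 0.8)
  f <- suppressWarnings(fit_cox(matrix(x, ncol = 1), time, event))
  bhat <- oracle_cox_mle(time, event, x)
  expect_lt(abs(f$coefficients$estimate - bhat), 1e-6)
  # fitted partial likelihood improves on the null
  expect_gte(f$loglik[2], f$loglik[1])
  expect_equal(f$loglik[2],
               oracle_cox_loglik(f$coefficients$estimate, time, event, x),
               tolerance = 1e-8)

  # tied sample: Efron handling in fit and oracle alike
  time_t <- sample(1:6, n, replace = TRUE)
  f_t <- suppressWarnings(fit_cox(matrix(x, ncol = 1), time_t, event))
  expect_lt(abs(f_t$coefficients$estimate - oracle_cox_mle(time_t, event, x)),
            1e-6)
})

test_that("confidence intervals and reference flips behave exactly", {
  set.seed(53)
  n <- 80
  x <- rbinom(n, 1, 0.5)
  time <- rexp(n, 0.1 * exp(0.7 * x))
  event <- rep(1L, n)
  f1 <- fit_cox(matrix(x, ncol = 1), time, event)
  f2 <- fit_cox(matrix(1 - x, ncol = 1), time, event)
  # flipping the reference of a binary covariate negates the estimate
  expect_equal(f1$coefficients$estimate, -f2$coefficients$estimate,
               tolerance = 1e-8)
  cf <- f1$coefficients
  expect_equal(cf$hr, exp(cf$estimate))
  expect_equal(cf$ci_lower, exp(cf$estimate - 1.96 * cf$se))
  expect_equal(cf$ci_upper, exp(cf$estimate + 1.96 * cf$se))
  expect_true(cf$ci_lower < cf$hr && cf$hr < cf$ci_upper)
})

test_that("degenerate designs raise typed failures", {
  set.seed(54)
  n <- 40
  x1 <- rbinom(n, 1, 0.5)
  time <- rexp(n, 0.1)
  event <- rbinom(n, 1, 0.8)
  expect_error(fit_cox(cbind(a = x1, b = x1), time, event),
               "rank deficient")
  expect_error(fit_cox(cbind(a = x1, b = rep(1, n)), time, event),
               "rank deficient")
  expect_error(fit_cox(matrix(x1, ncol = 1), time, rep(0L, n)),
               "no events")
  few_events <- c(rep(1L, 6), rep(0L, n - 6))
  expect_warning(fit_cox(matrix(x1, ncol = 1), time, few_events),
                 "events per coefficient")
})

test_that("univariate sweep reports one row per coefficient plus the
           multivariate block", {
  co <- generate_cohort(cohort_config(n = 150, seed = 55))
  xd <- as.data.frame(co)
  xd$dplt_group <- dichotomize(co$dplt, optimal_cutpoint(
    scan_cutpoints(survival_sample(co$pfs_time, co$pfs_event), co$dplt)))
  rep_pfs <- suppressWarnings(suppressMessages(
    univariate_sweep(xd, default_covariate_spec(), "pfs")))
  expect_equal(nrow(rep_pfs), 8)   # 6 covariates -> 8 coefficients
  expect_true(all(c("uni_hr", "uni_p", "multi_hr", "multi_p") %in%
                    names(rep_pfs)))
  expect_true(all(is.finite(rep_pfs$multi_hr)))

  # a pure-noise covariate keeps a CI covering 1; a strong covariate's
  # multivariate estimate stays consistent with its univariate one
  set.seed(56)
  xd$noise <- rnorm(nrow(xd))
  spec2 <- list(covariate_spec("dplt_group", "categorical",
                               reference = "high"),
                covariate_spec("noise", "continuous"))
  r2 <- suppressWarnings(univariate_sweep(xd, spec2, "pfs"))
  noise_row <- r2[r2$term == "noise", ]
  expect_true(noise_row$uni_ci_lower < 1 && noise_row$uni_ci_upper > 1)
  strong <- r2[r2$term == "dplt_group=low", ]
  expect_lt(abs(log(strong$multi_hr) - log(strong$uni_hr)), 0.5)
})

test_that("score test at zero equals the log-rank chi-square", {
  set.seed(57)
  for (i in 1:5) {
    n <- 60
    x <- rbinom(n, 1, 0.5)
    time <- runif(n, 0, 100)          # continuous: no ties
    event <- rbinom(n, 1, 0.6)
    if (sum(event) == 0 || length(unique(x)) < 2) next
    f <- fit_cox(matrix(x, ncol = 1), time, event)
    lr <- logrank_test(survival_sample(time, event, group = x))
    expect_equal(unname(f$score), lr$chi2, tolerance = 1e-6)
  }
})
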