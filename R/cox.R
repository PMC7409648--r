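#' Describe one model covariate
#'
#' One entry of the covariate specification consumed by [encode_design()]:
#' continuous covariates pass through unchanged; categorical ones expand to
#' indicator columns against a stated reference level.  An optional
#' `transform` is applied to the raw column first (used e.g. to collapse an
#' induction-course count to the binary "1" vs "more than 1").
#'
#' @param name Column name in the data.
#' @param kind `"continuous"` or `"categorical"`.
#' @param reference Reference level (categorical only).
#' @param levels Optional explicit non-reference level order.
#' @param transform Optional function applied to the raw column.
#' @return A `covariate_spec` list.
#' @export
covariate_spec <- function(name, kind = c("continuous", "categorical"),
                           reference = NULL, levels = NULL,
                           transform = NULL) {
  kind <- match.arg(kind)
  if (kind == "categorical" && is.null(reference)) {
    stop("categorical covariate '", name, "' needs a reference level",
         call. = FALSE)
  }
  structure(list(name = name, kind = kind, reference = reference,
                 levels = levels, transform = transform),
            class = "covariate_spec")
}

#' Default clinical covariate specification
#'
#' The six-covariate encoding used in the package's worked analyses of
#' remission cohorts: age as a numeric variate; sex with reference female;
#' cytogenetic/molecular risk with reference favorable; induction courses
#' to remission collapsed to "1" (reference) vs "more than 1";
#' consolidation regimen with reference HDAraC; and the dichotomized
#' recovery-marker group with reference high (so the reported hazard ratio
#' is low vs high).
#'
#' @return List of [covariate_spec()] entries.
#' @export
default_covariate_spec <- function() {
  list(
    covariate_spec("age", "continuous"),
    covariate_spec("sex", "categorical", reference = "female"),
    covariate_spec("risk_group", "categorical", reference = "favorable",
                   levels = c("intermediate", "adverse")),
    covariate_spec("courses_to_cr", "categorical", reference = "1",
                   transform = function(x) {
                     factor(ifelse(x > 1, "more than 1", "1"),
                            levels = c("1", "more than 1"))
                   }),
    covariate_spec("consolidation", "categorical", reference = "HDAraC",
                   levels = c("AML-87", "AML-201")),
    covariate_spec("dplt_group", "categorical", reference = "high")
  )
}

#' Encode a design matrix from a covariate specification
#'
#' Continuous covariates pass through; categorical covariates become
#' indicator columns for each non-reference level (named `name=level`).
#' Rows with any missing covariate are removed listwise, with a message
#' giving the count.  A data level absent from the specification is an
#' error naming the level.
#'
#' @param data Data frame (e.g. a [cohort()] with a `dplt_group` column).
#' @param spec List of [covariate_spec()] entries.
#' @return List: `x` (numeric design matrix), `rows` (indices of the rows
#'   kept), `n_dropped`.
#' @export
encode_design <- function(data, spec) {
  cols <- list()
  for (cv in spec) {
    v <- data[[cv$name]]
    if (is.null(v)) stop("no column '", cv$name, "' in data", call. = FALSE)
    if (!is.null(cv$transform)) v <- cv$transform(v)
    if (cv$kind == "continuous") {
      cols[[cv$name]] <- as.numeric(v)
    } else {
      f <- factor(v)
      seen <- levels(droplevels(f[!is.na(f)]))
      allowed <- c(cv$reference, cv$levels %||% setdiff(seen, cv$reference))
      unseen <- setdiff(seen, allowed)
      if (length(unseen)) {
        stop("level '", unseen[1L], "' of '", cv$name,
             "' is not in the covariate specification", call. = FALSE)
      }
      for (l in setdiff(allowed, cv$reference)) {
        cols[[paste0(cv$name, "=", l)]] <-
          ifelse(is.na(f), NA_real_, as.numeric(f == l))
      }
    }
  }
  x <- do.call(cbind, cols)
  keep <- stats::complete.cases(x)
  if (any(!keep)) {
    message(sum(!keep), " record(s) with missing covariates dropped")
  }
  list(x = x[keep, , drop = FALSE], rows = which(keep),
       n_dropped = sum(!keep))
}

#' Fit a Cox proportional-hazards model
#'
#' Maximizes the Cox partial likelihood (Efron tie handling by default,
#' Breslow available for cross-checks) by Newton-type iteration, with
#' convergence declared at a relative log-likelihood change below 1e-9
#' within 100 iterations.  Standard errors come from the inverse observed
#' information; per-coefficient 95% confidence intervals use
#' `exp(estimate +/- 1.96 * se)` and p-values are two-sided Wald.  The fit
#' is unpenalized; when the events-per-coefficient ratio falls below 10 a
#' warning is emitted (and the fit still returned), mirroring how small
#' clinical cohorts are analysed in practice.
#'
#' @param x Numeric design matrix (see [encode_design()]); no constant or
#'   collinear columns (rank deficiency is an error).
#' @param time,event Survival outcome aligned with the rows of `x`.
#' @param ties `"efron"` (default) or `"breslow"`.
#' @return A `cox_fit`: `coefficients` data frame (`term`, `estimate`,
#'   `se`, `hr`, `ci_lower`, `ci_upper`, `p`), `n`, `n_events`, `loglik`
#'   (null and fitted log partial likelihood), `score` (score chi-square at
#'   beta = 0), `converged`, `iter`.
#' @export
fit_cox <- function(x, time, event, ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  x <- as.matrix(x)
  if (is.null(colnames(x))) {
    colnames(x) <- paste0("x", seq_len(ncol(x)))
  }
  check_nonneg(time, "time")
  check_event(event, "event")
  if (nrow(x) != length(time)) {
    stop("design matrix and survival vectors have different lengths",
         call. = FALSE)
  }
  nev <- sum(event)
  if (nev == 0L) stop("no events: Cox model is not estimable", call. = FALSE)
  if (qr(cbind(1, x))$rank < ncol(x) + 1L) {
    stop("design matrix is rank deficient (constant or collinear columns)",
         call. = FALSE)
  }
  if (nev < ncol(x)) {
    stop("fewer events than coefficients", call. = FALSE)
  }
  if (nev / ncol(x) < 10) {
    warning(sprintf(
      "only %.1f events per coefficient (< 10); estimates may be unstable",
      nev / ncol(x)), call. = FALSE)
  }

  df <- as.data.frame(x)
  names(df) <- paste0("V", seq_len(ncol(x)))   # syntactic; report real names
  df$.time <- time
  df$.event <- event
  fml <- stats::as.formula(paste(
    "survival::Surv(.time, .event) ~", paste(names(df)[seq_len(ncol(x))],
                                             collapse = " + ")))
  converged <- TRUE
  fit <- withCallingHandlers(
    survival::coxph(fml, data = df, ties = ties,
                    control = survival::coxph.control(eps = 1e-9,
                                                      iter.max = 100)),
    warning = function(w) {
      if (grepl("Ran out of iterations|did not converge",
                conditionMessage(w))) {
        converged <<- FALSE
        invokeRestart("muffleWarning")
      }
    })
  beta <- stats::coef(fit)
  if (anyNA(beta)) {
    stop("Cox fit dropped coefficient(s); design is rank deficient",
         call. = FALSE)
  }
  se <- sqrt(diag(fit$var))
  coefs <- data.frame(term = colnames(x),
                      estimate = unname(beta),
                      se = unname(se),
                      hr = unname(exp(beta)),
                      ci_lower = unname(exp(beta - 1.96 * se)),
                      ci_upper = unname(exp(beta + 1.96 * se)),
                      p = unname(2 * stats::pnorm(-abs(beta / se))))
  structure(list(coefficients = coefs, n = nrow(x), n_events = nev,
                 loglik = fit$loglik, score = fit$score,
                 converged = converged, iter = fit$iter, ties = ties),
            class = "cox_fit")
}

#' @export
print.cox_fit <- function(x, ...) {
  cat(sprintf("<cox_fit> n = %d, events = %d, ties = %s%s\n",
              x$n, x$n_events, x$ties,
              if (!x$converged) " [NOT CONVERGED]" else ""))
  cf <- x$coefficients
  print(data.frame(term = cf$term, HR = round(cf$hr, 3),
                   `95% CI` = sprintf("%.3f-%.3f", cf$ci_lower, cf$ci_upper),
                   p = signif(cf$p, 3), check.names = FALSE))
  invisible(x)
}

#' Univariate sweep plus multivariate fit
#'
#' For each covariate in `spec`, fits a Cox model with that covariate
#' alone, then fits the joint multivariate model with all of them — the
#' shape of a clinical risk-factor table, reported for one endpoint at a
#' time.  Per-covariate failures are recorded inline (`error` column)
#' without aborting the sweep.
#'
#' @param data Data frame with covariates and `<endpoint>_time` /
#'   `<endpoint>_event` columns.
#' @param spec List of [covariate_spec()] entries.
#' @param endpoint `"pfs"` or `"os"`.
#' @return A `cox_report` data frame: one row per coefficient with
#'   univariate and multivariate estimate, HR, CI bounds and p, plus an
#'   attribute `fits` holding the underlying `cox_fit` objects.
#' @export
univariate_sweep <- function(data, spec = default_covariate_spec(),
                             endpoint = c("pfs", "os")) {
  endpoint <- match.arg(endpoint)
  time <- data[[paste0(endpoint, "_time")]]
  event <- data[[paste0(endpoint, "_event")]]

  fit_for <- function(sp) {
    enc <- suppressMessages(encode_design(data, sp))
    suppressWarnings(fit_cox(enc$x, time[enc$rows], event[enc$rows]))
  }
  uni <- lapply(spec, function(cv) {
    tryCatch(fit_for(list(cv)), error = function(e) conditionMessage(e))
  })
  multi <- tryCatch(fit_for(spec), error = function(e) conditionMessage(e))

  rows <- list()
  for (i in seq_along(spec)) {
    f <- uni[[i]]
    if (is.character(f)) {
      rows[[i]] <- data.frame(term = spec[[i]]$name, uni_hr = NA_real_,
                              uni_ci_lower = NA_real_,
                              uni_ci_upper = NA_real_, uni_p = NA_real_,
                              error = f)
    } else {
      cf <- f$coefficients
      rows[[i]] <- data.frame(term = cf$term, uni_hr = cf$hr,
                              uni_ci_lower = cf$ci_lower,
                              uni_ci_upper = cf$ci_upper, uni_p = cf$p,
                              error = NA_character_)
    }
  }
  out <- do.call(rbind, rows)
  out$multi_hr <- out$multi_ci_lower <- out$multi_ci_upper <-
    out$multi_p <- NA_real_
  if (!is.character(multi)) {
    cf <- multi$coefficients
    m <- match(cf$term, out$term)
    out$multi_hr[m] <- cf$hr
    out$multi_ci_lower[m] <- cf$ci_lower
    out$multi_ci_upper[m] <- cf$ci_upper
    out$multi_p[m] <- cf$p
  }
  structure(out, endpoint = endpoint,
            fits = list(univariate = uni, multivariate = multi),
            class = c("cox_report", "data.frame"))
}
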