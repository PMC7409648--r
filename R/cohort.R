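#' Platelet-recovery marker
#'
#' Computes the platelet-recovery degree: the difference between the
#' post-remission peak platelet count and the pre-treatment platelet count,
#' `plt_peak - plt_pre`, both in units of 10^9/L.  The marker may be
#' negative when a patient's peak never exceeds the pre-treatment count;
#' negative values are representable even though typical remission cohorts
#' show large positive recoveries.
#'
#' @param plt_pre Peripheral platelet count on the day before initial
#'   treatment (10^9/L), finite and non-negative.
#' @param plt_peak Peak platelet count after marrow recovery following the
#'   remission-inducing course (10^9/L), finite and non-negative.
#' @return Numeric vector `plt_peak - plt_pre` (10^9/L).
#' @examples
#' compute_dplt(100, 312)  # 212
#' @export
compute_dplt <- function(plt_pre, plt_peak) {
  check_nonneg(plt_pre, "plt_pre")
  check_nonneg(plt_peak, "plt_peak")
  if (length(plt_pre) != length(plt_peak)) {
    stop("'plt_pre' and 'plt_peak' must have the same length", call. = FALSE)
  }
  plt_peak - plt_pre
}

#' Morphological complete-remission check
#'
#' Tests the standard morphological CR definition: marrow blasts below 5%,
#' no extramedullary disease, neutrophil recovery above 1 x 10^9/L and
#' platelet recovery above 100 x 10^9/L.  All comparisons are strict.
#'
#' @param marrow_blast_pct Bone-marrow blast percentage.
#' @param extramedullary_disease Logical; presence of extramedullary disease.
#' @param neutrophils Absolute neutrophil count (10^9/L).
#' @param platelets Peripheral platelet count (10^9/L).
#' @return Logical vector, `TRUE` where all four criteria hold.
#' @export
meets_morphologic_cr <- function(marrow_blast_pct, extramedullary_disease,
                                 neutrophils, platelets) {
  check_nonneg(marrow_blast_pct, "marrow_blast_pct")
  check_nonneg(neutrophils, "neutrophils")
  check_nonneg(platelets, "platelets")
  if (!is.logical(extramedullary_disease) || anyNA(extramedullary_disease)) {
    stop("'extramedullary_disease' must be logical without missing values",
         call. = FALSE)
  }
  marrow_blast_pct < 5 & !extramedullary_disease &
    neutrophils > 1 & platelets > 100
}

#' Dichotomize a continuous marker at a cut-point
#'
#' Splits marker values into `"high"` and `"low"` groups.  By default
#' "high" means strictly greater than the cut-point, so a cut-point chosen
#' from the observed values leaves its defining patient in the low group
#' (the convention of the maximally-selected-statistic literature).
#'
#' @param values Numeric marker vector, non-empty.
#' @param cutoff Finite cut-point on the marker scale.
#' @param strict If `TRUE` (default) high means `> cutoff`; if `FALSE`,
#'   `>= cutoff`.
#' @return Factor with levels `c("low", "high")`, same length as `values`.
#' @export
dichotomize <- function(values, cutoff, strict = TRUE) {
  if (length(values) == 0L) stop("'values' is empty", call. = FALSE)
  if (!is.numeric(values) || anyNA(values)) {
    stop("'values' must be numeric without missing values", call. = FALSE)
  }
  if (!is.numeric(cutoff) || length(cutoff) != 1L || !is.finite(cutoff)) {
    stop("'cutoff' must be a single finite number", call. = FALSE)
  }
  hi <- if (strict) values > cutoff else values >= cutoff
  factor(ifelse(hi, "high", "low"), levels = c("low", "high"))
}

# Columns every cohort table must carry; dplt is derived on construction.
.cohort_required <- c("patient_id", "plt_pre", "plt_peak",
                      "pfs_time", "pfs_event", "os_time", "os_event")

#' Construct a validated patient cohort
#'
#' Wraps a patient-level data frame as a `cohort`: one row per patient with
#' platelet counts (10^9/L), two (time, event) survival pairs in months
#' (progression-free and overall survival), and optional baseline covariates
#' (`age`, `sex`, `risk_group`, `courses_to_cr`, `consolidation`, `wbc`,
#' `hemoglobin`, `marrow_blast_pct`).  The recovery marker `dplt` is always
#' recomputed as `plt_peak - plt_pre`; a supplied `dplt` column that
#' disagrees triggers a warning and is overwritten.  Row order is preserved
#' and significant: random splits are reproducible only for a fixed order.
#'
#' `os_time >= pfs_time` is not enforced (observational tables sometimes
#' violate it through rounding); violations raise a warning, not an error.
#'
#' @param data Data frame with at least the columns `patient_id`, `plt_pre`,
#'   `plt_peak`, `pfs_time`, `pfs_event`, `os_time`, `os_event`.
#' @param provenance Free-text source tag stored as an attribute.
#' @return A `cohort` object (data frame subclass) with a `dplt` column.
#' @export
cohort <- function(data, provenance = "unspecified") {
  data <- as.data.frame(data, stringsAsFactors = FALSE)
  missing_cols <- setdiff(.cohort_required, names(data))
  if (length(missing_cols)) {
    stop("cohort is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (nrow(data) == 0L) stop("cohort has no rows", call. = FALSE)
  if (anyDuplicated(data$patient_id)) {
    stop("'patient_id' values must be unique", call. = FALSE)
  }
  check_nonneg(data$plt_pre, "plt_pre")
  check_nonneg(data$plt_peak, "plt_peak")
  check_nonneg(data$pfs_time, "pfs_time")
  check_nonneg(data$os_time, "os_time")
  check_event(data$pfs_event, "pfs_event")
  check_event(data$os_event, "os_event")

  dplt <- data$plt_peak - data$plt_pre
  if (!is.null(data$dplt) &&
      any(abs(data$dplt - dplt) > 1e-8, na.rm = TRUE)) {
    warning("supplied 'dplt' column disagrees with plt_peak - plt_pre; ",
            "recomputed", call. = FALSE)
  }
  data$dplt <- dplt

  n_bad <- sum(data$os_time < data$pfs_time)
  if (n_bad > 0L) {
    warning(sprintf("%d record(s) have os_time < pfs_time", n_bad),
            call. = FALSE)
  }
  structure(data,
            provenance = as.character(provenance),
            class = c("cohort", "data.frame"))
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("<cohort> %d patients (source: %s)\n",
              nrow(x), attr(x, "provenance")))
  cat(sprintf("  dplt: median %.1f, range %.1f-%.1f (10^9/L)\n",
              stats::median(x$dplt), min(x$dplt), max(x$dplt)))
  cat(sprintf("  events: %d/%d PFS, %d/%d OS\n",
              sum(x$pfs_event), nrow(x), sum(x$os_event), nrow(x)))
  invisible(x)
}

#' Read a cohort from delimited text
#'
#' Reads a comma-separated file with a header row into a validated
#' [cohort()].  Platelet units are fixed at 10^9/L and times at months;
#' column names follow the documented schema (see [cohort()]).
#'
#' @param path Path to a CSV file.
#' @param provenance Source tag; defaults to the file path.
#' @return A `cohort`.
#' @export
read_cohort <- function(path, provenance = path) {
  data <- utils::read.csv(path, stringsAsFactors = FALSE)
  cohort(data, provenance = provenance)
}

#' Write a cohort to delimited text
#'
#' @param x A `cohort`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(x, path) {
  stopifnot(inherits(x, "cohort"))
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}
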