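#' Paired complete cases for two methods
#'
#' Builds the paired sample on which all agreement analyses run: the
#' intersection of cases with a non-missing volume under both methods
#' (complete-case analysis). Where a method has several readings per case,
#' the first reading (lowest `reader_id`) is used, matching the study's use
#' of the first ABC/2 measurement for between-method comparisons.
#'
#' @param records long-format measurement data frame.
#' @param method1,method2 method names; by convention `method2` is the
#'   reference, so positive differences mean `method1` overestimates.
#' @return A list of class `paired_sample` with `case_ids`, `m1`, `m2`,
#'   `method1`, `method2`, ordered by `case_id`.
#' @export
paired_complete_cases <- function(records, method1, method2) {
  first_reading <- function(meth) {
    sub <- records[records$method == meth & !records$missed &
                     !is.na(records$volume_mL), , drop = FALSE]
    if (!nrow(sub)) return(sub)
    sub <- sub[order(sub$case_id, sub$reader_id), , drop = FALSE]
    sub[!duplicated(sub$case_id), , drop = FALSE]
  }
  for (meth in c(method1, method2)) {
    if (!any(records$method == meth)) {
      stop(sprintf("method '%s' not present in the measurement table", meth))
    }
  }
  r1 <- first_reading(method1)
  r2 <- first_reading(method2)
  ids <- sort(intersect(r1$case_id, r2$case_id))
  if (length(ids) < 2L) {
    stop(sprintf("fewer than 2 complete pairs for %s vs %s", method1, method2))
  }
  structure(list(case_ids = ids,
                 m1 = r1$volume_mL[match(ids, r1$case_id)],
                 m2 = r2$volume_mL[match(ids, r2$case_id)],
                 method1 = method1, method2 = method2),
            class = "paired_sample")
}

#' Paired differences and pairwise means
#'
#' @param paired a [paired_complete_cases()] sample.
#' @param mode `"absolute"` for `m1 - m2` (mL) or `"percent"` for
#'   `100 * (m1 - m2) / ((m1 + m2)/2)`.
#' @return A list with `d` (differences) and `means` (pairwise means, the
#'   Bland-Altman X axis).
#' @export
differences <- function(paired, mode = c("absolute", "percent")) {
  mode <- match.arg(mode)
  if (!inherits(paired, "paired_sample")) stop("expected a `paired_sample`")
  means <- (paired$m1 + paired$m2) / 2
  d <- if (mode == "absolute") {
    paired$m1 - paired$m2
  } else {
    if (any(means == 0)) {
      stop("percent differences undefined: a pair has zero mean volume")
    }
    100 * (paired$m1 - paired$m2) / means
  }
  list(d = d, means = means)
}

#' Bland-Altman limits of agreement
#'
#' Mean difference, SD of differences (n-1 denominator), and the limits of
#' agreement `mean +/- 1.96 * SD`.
#'
#' @param diffs numeric vector of paired differences (length >= 2).
#' @return A list with `mean_diff`, `sd_diff`, `loa_low`, `loa_high`.
#' @examples
#' bland_altman_limits(c(1, 2, 3))  # mean 2, SD 1, LoA 0.04 / 3.96
#' @export
bland_altman_limits <- function(diffs) {
  if (length(diffs) < 2L) stop("need at least 2 differences")
  m <- mean(diffs)
  s <- stats::sd(diffs)
  list(mean_diff = m, sd_diff = s,
       loa_low = m - 1.96 * s, loa_high = m + 1.96 * s)
}

#' Kendall's tau heteroscedasticity screen
#'
#' Tie-corrected Kendall's tau (tau-b) between the absolute differences and
#' the pairwise means: a positive association indicates that disagreement
#' grows with volume (heteroscedasticity), the trigger for the
#' log-transformed analysis.
#'
#' @param diffs paired differences.
#' @param means pairwise means.
#' @return tau in \[-1, 1\].
#' @export
kendall_tau_het <- function(diffs, means) {
  if (length(diffs) != length(means)) stop("`diffs` and `means` must be aligned")
  if (length(diffs) < 3L) stop("need at least 3 pairs")
  a <- abs(diffs)
  if (stats::sd(a) == 0 || stats::sd(means) == 0) {
    stop("Kendall's tau undefined: all-tied input")
  }
  stats::cor(a, means, method = "kendall")
}

#' Back-transform a log-scale limit of agreement
#'
#' A limit `l` on the scale of differences of logs corresponds to a
#' measurement ratio `r = exp(l)`, and the original-scale limit at pairwise
#' mean `X` is `slope * X` with `slope = 2 (e^l - 1) / (e^l + 1)`
#' (equivalently `2 tanh(l/2)`): the mean-dependent limits drawn on the
#' conventional Bland-Altman plot after a log analysis.
#'
#' @param log_limit finite log-scale limit.
#' @return the slope multiplying the pairwise mean.
#' @examples
#' back_transform_loa(log(3))  # exactly 1
#' @export
back_transform_loa <- function(log_limit) {
  if (any(!is.finite(log_limit))) stop("`log_limit` must be finite")
  2 * (exp(log_limit) - 1) / (exp(log_limit) + 1)
}

#' Heteroscedasticity-adaptive Bland-Altman analysis
#'
#' The study's agreement procedure for one method pair: compute the raw
#' Bland-Altman limits; screen for heteroscedasticity with Kendall's tau
#' between absolute differences and means; if `tau > tau_threshold`,
#' recompute tau on differences of logs, and if the log transform reduced
#' tau, report the log-scale limits together with their back-transformed,
#' mean-dependent form `slope * X` (see [back_transform_loa()]).
#'
#' The log branch applies to absolute-mode analyses; in percent mode the
#' differences are already scale-free, so only the raw limits and the tau
#' diagnostic are reported.
#'
#' @param paired a [paired_complete_cases()] sample.
#' @param mode `"absolute"` or `"percent"` differences.
#' @param tau_threshold heteroscedasticity trigger (default 0.1).
#' @return A list of class `bland_altman_result`: `n`, `mode`, `mean_diff`,
#'   `sd_diff`, `loa_low`, `loa_high`, `tau_raw`, `heteroscedastic`, and
#'   (when entered) `log_branch` with `tau_log`, `mean_log_diff`,
#'   `sd_log_diff`, `loa_log_low/high`, `ratio_low/high`, `slope_low/high`.
#' @export
adaptive_log_loa <- function(paired, mode = c("absolute", "percent"),
                             tau_threshold = 0.1) {
  mode <- match.arg(mode)
  dd <- differences(paired, mode)
  ba <- bland_altman_limits(dd$d)
  # degenerate inputs (e.g. an error-free method pair with all differences
  # equal) carry no evidence of heteroscedasticity: tau is taken as 0
  tau_raw <- if (stats::sd(abs(dd$d)) == 0 || stats::sd(dd$means) == 0) {
    0
  } else {
    kendall_tau_het(dd$d, dd$means)
  }
  het <- tau_raw > tau_threshold
  log_branch <- NULL
  if (het && mode == "absolute") {
    bad <- paired$m1 <= 0 | paired$m2 <= 0
    if (any(bad)) {
      stop(sprintf("log transform impossible: nonpositive volume for case %s",
                   paired$case_ids[which(bad)[1]]))
    }
    dlog <- log(paired$m1) - log(paired$m2)
    tau_log <- kendall_tau_het(dlog, dd$means)
    if (tau_log < tau_raw) {
      bal <- bland_altman_limits(dlog)
      log_branch <- list(
        tau_log = tau_log,
        mean_log_diff = bal$mean_diff,
        sd_log_diff = bal$sd_diff,
        loa_log_low = bal$loa_low,
        loa_log_high = bal$loa_high,
        ratio_low = exp(bal$loa_low),
        ratio_high = exp(bal$loa_high),
        slope_low = back_transform_loa(bal$loa_low),
        slope_high = back_transform_loa(bal$loa_high))
    }
  }
  structure(list(n = length(dd$d), mode = mode,
                 mean_diff = ba$mean_diff, sd_diff = ba$sd_diff,
                 loa_low = ba$loa_low, loa_high = ba$loa_high,
                 tau_raw = tau_raw, heteroscedastic = het,
                 log_branch = log_branch),
            class = "bland_altman_result")
}

#' @export
print.bland_altman_result <- function(x, ...) {
  unit <- if (x$mode == "percent") "%" else " mL"
  cat(sprintf("<bland_altman_result> n=%d, mean diff %.2f%s (LoA %.2f to %.2f), tau=%.3f%s\n",
              x$n, x$mean_diff, unit, x$loa_low, x$loa_high, x$tau_raw,
              if (x$heteroscedastic) " [heteroscedastic]" else ""))
  if (!is.null(x$log_branch)) {
    cat(sprintf("  log branch: tau_log=%.3f, mean-dependent LoA %.2fX to %.2fX\n",
                x$log_branch$tau_log, x$log_branch$slope_low,
                x$log_branch$slope_high))
  }
  invisible(x)
}

#' Paired t-test on differences
#'
#' `t = mean(d) / (sd(d)/sqrt(n))` with a two-sided p-value on n-1 degrees
#' of freedom.
#'
#' @param diffs numeric vector of paired differences.
#' @return A list of class `test_result`: `statistic`, `p_value`, `df`,
#'   `test`.
#' @export
paired_t_test <- function(diffs) {
  n <- length(diffs)
  if (n < 2L) stop("need at least 2 differences")
  s <- stats::sd(diffs)
  if (s == 0) stop("paired t-test undefined: zero variance")
  t_stat <- mean(diffs) / (s / sqrt(n))
  structure(list(statistic = t_stat,
                 p_value = 2 * stats::pt(-abs(t_stat), df = n - 1),
                 df = n - 1L, test = "paired_t"),
            class = "test_result")
}

#' Shapiro-Wilk normality test
#'
#' Thin wrapper over the standard Royston algorithm, used to check the
#' normality of paired differences before interpreting the t-test.
#'
#' @param x numeric vector, 3 <= n <= 5000.
#' @return A list of class `test_result` with the W statistic and p-value.
#' @export
shapiro_wilk <- function(x) {
  n <- length(x)
  if (n < 3L || n > 5000L) stop("Shapiro-Wilk requires 3 <= n <= 5000")
  sw <- stats::shapiro.test(x)
  structure(list(statistic = unname(sw$statistic),
                 p_value = sw$p.value, test = "shapiro_wilk"),
            class = "test_result")
}

#' Subgroup agreement analyses
#'
#' Runs [adaptive_log_loa()] within each stratum of a clinical stratifier:
#' presence of IVH, haematoma location, or reference volume below/above
#' 40 mL. A stratum with fewer than 3 complete pairs is reported as
#' not estimable rather than failing.
#'
#' @param records long-format measurement data frame.
#' @param truth cohort ground-truth table (needs `case_id`, `ivh_present`,
#'   `location`).
#' @param stratifier one of `"ivh"`, `"location"`, `"volume_40"`.
#' @param method1,method2 the method pair, as in [paired_complete_cases()].
#' @param mode difference mode passed to [adaptive_log_loa()].
#' @param reference_method method whose volumes define the `volume_40`
#'   split.
#' @return A named list of `bland_altman_result` objects (or the string
#'   `"not estimable"`), one per stratum.
#' @export
subgroup_agreement <- function(records, truth,
                               stratifier = c("ivh", "location", "volume_40"),
                               method1, method2,
                               mode = "absolute",
                               reference_method = "reference_voxel") {
  stratifier <- match.arg(stratifier)
  strata <- switch(stratifier,
    ivh = split(truth$case_id, ifelse(truth$ivh_present, "ivh", "no_ivh")),
    location = split(truth$case_id, truth$location),
    volume_40 = {
      ref <- records[records$method == reference_method &
                       !is.na(records$volume_mL), , drop = FALSE]
      ref <- ref[match(truth$case_id, ref$case_id), ]
      split(truth$case_id,
            ifelse(ref$volume_mL < 40, "lt_40_mL", "ge_40_mL"))
    })
  lapply(strata, function(ids) {
    sub <- records[records$case_id %in% ids, , drop = FALSE]
    res <- tryCatch(
      paired_complete_cases(sub, method1, method2),
      error = function(e) NULL)
    if (is.null(res) || length(res$case_ids) < 3L) {
      return("not estimable")
    }
    adaptive_log_loa(res, mode = mode)
  })
}

#' Clinical acceptability of percent limits of agreement
#'
#' The study's 10% rule: a method pair is clinically acceptable if both
#' percent limits of agreement lie within `[-limit_pct, +limit_pct]`
#' (boundary inclusive: "10% or less").
#'
#' @param result a percent-mode `bland_altman_result`.
#' @param limit_pct acceptability bound in percent (default 10).
#' @return `TRUE` or `FALSE`.
#' @export
acceptance_check <- function(result, limit_pct = 10) {
  if (!inherits(result, "bland_altman_result")) {
    stop("expected a `bland_altman_result`")
  }
  if (result$mode != "percent") {
    stop("the acceptability rule is defined on percent-mode limits")
  }
  result$loa_low >= -limit_pct && result$loa_high <= limit_pct
}
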