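#' One-way random-effects intraclass correlation
#'
#' Single-measurement ICC from the one-way analysis-of-variance
#' decomposition, the form appropriate for inter-observer designs in which
#' different reader subsets rate different cases (unbalanced). With
#' between-case mean square `MSB`, within-case mean square `MSW` and the
#' unbalanced-design average group size
#' \deqn{\bar k = (N - \sum_i k_i^2 / N) / (n - 1),}
#' the estimate is
#' \deqn{ICC = (MSB - MSW) / (MSB + (\bar k - 1) MSW).}
#' Cases with a single reading contribute to the between-case sum of
#' squares only.
#'
#' @param ratings data frame with columns `case_id`, `reader_id`,
#'   `volume_mL` (column `volume` also accepted).
#' @return A list of class `icc_result`: `icc`, `ms_between`, `ms_within`,
#'   `n_subjects`, `k_bar`.
#' @export
icc_oneway <- function(ratings) {
  vcol <- if ("volume_mL" %in% names(ratings)) "volume_mL" else "volume"
  if (!all(c("case_id", "reader_id", vcol) %in% names(ratings))) {
    stop("`ratings` needs columns case_id, reader_id and volume_mL (or volume)")
  }
  y <- ratings[[vcol]]
  keep <- !is.na(y)
  y <- y[keep]
  g <- as.character(ratings$case_id)[keep]
  k_i <- table(g)
  n <- length(k_i)
  N <- length(y)
  if (n < 2L) stop("need at least 2 cases")
  if (!any(k_i >= 2L)) stop("ICC undefined: no case has 2 or more readings")
  grand <- mean(y)
  means <- tapply(y, g, mean)
  ssb <- sum(as.numeric(k_i) * (means - grand)^2)
  ssw <- sum((y - means[g])^2)
  df_b <- n - 1L
  df_w <- N - n
  if (df_w < 1L) stop("ICC undefined: no within-case degrees of freedom")
  msb <- ssb / df_b
  msw <- ssw / df_w
  k_bar <- (N - sum(as.numeric(k_i)^2) / N) / (n - 1)
  structure(list(icc = (msb - msw) / (msb + (k_bar - 1) * msw),
                 ms_between = msb, ms_within = msw,
                 n_subjects = n, k_bar = k_bar),
            class = "icc_result")
}

#' @export
print.icc_result <- function(x, ...) {
  cat(sprintf("<icc_result> ICC = %.3f (one-way random effects, %d subjects, mean %.2f readings)\n",
              x$icc, x$n_subjects, x$k_bar))
  invisible(x)
}
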