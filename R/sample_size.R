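#' Sample-size configuration for a limits-of-agreement study
#'
#' Design parameters for planning a Bland-Altman method-comparison study:
#' the expected mean difference and SD of differences between the methods,
#' and the clinically acceptable bound `delta` that both limits of
#' agreement must stay within (with confidence `1 - alpha`).
#'
#' @param mu_d expected mean difference (mL).
#' @param sd_d expected SD of differences (mL), positive.
#' @param delta clinically acceptable bound (mL), positive.
#' @param alpha two-sided confidence level for the LoA bounds.
#' @param target_power required power.
#' @return A list of class `sample_size_config`.
#' @examples
#' # a 5 mL (SD 2) difference taken as the acceptable upper limit, with a
#' # 10 mL clinical bound:
#' sample_size_config(mu_d = 5, sd_d = 2, delta = 10)
#' @export
sample_size_config <- function(mu_d = 0, sd_d = 2, delta = 5,
                               alpha = 0.05, target_power = 0.8) {
  if (sd_d <= 0) stop("`sd_d` must be positive")
  if (delta <= 0) stop("`delta` must be positive")
  if (alpha <= 0 || alpha >= 1) stop("`alpha` must be in (0, 1)")
  if (target_power <= 0 || target_power >= 1) {
    stop("`target_power` must be in (0, 1)")
  }
  structure(list(mu_d = mu_d, sd_d = sd_d, delta = delta,
                 alpha = alpha, target_power = target_power),
            class = "sample_size_config")
}

# standard approximate SE multiplier of an estimated LoA: sd * sqrt(1/n +
# 1.96^2 / (2(n-1)))
loa_se_factor <- function(n) sqrt(1 / n + 1.96^2 / (2 * (n - 1)))

#' Power of a limits-of-agreement study
#'
#' Probability that both two-sided `(1 - alpha)` confidence bounds of the
#' estimated limits of agreement fall inside `(-delta, delta)`, under
#' normally distributed differences `N(mu_d, sd_d^2)`. The sample mean and
#' SD are independent, so the power is computed exactly (to quadrature
#' accuracy) by integrating the normal probability of the admissible range
#' of the sample mean over the sampling distribution of the sample SD
#' (scaled chi). The LoA confidence bounds use the standard approximate
#' standard error `sd * sqrt(1/n + 1.96^2 / (2(n-1)))` with a Student-t
#' quantile.
#'
#' @param n number of paired differences (>= 2).
#' @param config a [sample_size_config()].
#' @return Power in \[0, 1\].
#' @export
loa_power <- function(n, config) {
  if (!inherits(config, "sample_size_config")) {
    stop("expected a `sample_size_config`")
  }
  n <- as.integer(n)
  if (n < 2L) stop("`n` must be >= 2")
  mu <- config$mu_d
  sigma <- config$sd_d
  delta <- config$delta
  tq <- stats::qt(1 - config$alpha / 2, df = n - 1)
  half <- 1.96 + tq * loa_se_factor(n)  # sample-SD multiplier of both bounds
  # given sample SD s: need |dbar| < delta - half * s
  se_mean <- sigma / sqrt(n)
  integrand <- function(s) {
    room <- delta - half * s
    p <- ifelse(room <= 0, 0,
                stats::pnorm((room - mu) / se_mean) -
                  stats::pnorm((-room - mu) / se_mean))
    # density of s = sigma * sqrt(chisq_{n-1}/(n-1))
    dens <- stats::dchisq((n - 1) * s^2 / sigma^2, df = n - 1) *
      2 * (n - 1) * s / sigma^2
    p * dens
  }
  upper <- delta / half
  if (upper <= 0) return(0)
  stats::integrate(integrand, 0, upper, rel.tol = 1e-8)$value
}

#' Monte-Carlo power of a limits-of-agreement study
#'
#' Independent simulation oracle for [loa_power()]: draws `reps` samples of
#' `n` normal differences, forms the LoA confidence bounds with the same
#' rule, and reports the fraction of samples in which both bounds lie
#' inside `(-delta, delta)`.
#'
#' @param n number of paired differences.
#' @param config a [sample_size_config()].
#' @param reps number of Monte-Carlo replicates (>= 1000).
#' @param seed integer seed.
#' @return Estimated power; standard error about
#'   `sqrt(p (1 - p) / reps)`.
#' @export
power_by_simulation <- function(n, config, reps = 20000L, seed = 1L) {
  if (!inherits(config, "sample_size_config")) {
    stop("expected a `sample_size_config`")
  }
  if (reps < 1000L) stop("`reps` must be at least 1000")
  n <- as.integer(n)
  if (n < 2L) stop("`n` must be >= 2")
  tq <- stats::qt(1 - config$alpha / 2, df = n - 1)
  fac <- loa_se_factor(n)
  with_seed(seed, {
    x <- matrix(stats::rnorm(n * reps, config$mu_d, config$sd_d), nrow = n)
    db <- colMeans(x)
    s <- sqrt((colSums(x^2) - n * db^2) / (n - 1))
    hi <- db + 1.96 * s + tq * fac * s
    lo <- db - 1.96 * s - tq * fac * s
    mean(hi < config$delta & lo > -config$delta)
  })
}

#' Minimum sample size for a limits-of-agreement study
#'
#' Smallest `n` with `loa_power(n) >= target_power`, found by bracketed
#' doubling and bisection. A configuration whose true limits of agreement
#' `|mu_d| + 1.96 sd_d` already reach `delta` can never attain the target
#' power (the power tends to 0 as n grows); it is reported as infeasible
#' rather than as a huge n.
#'
#' @param config a [sample_size_config()].
#' @param n_max search cap.
#' @return A list of class `sample_size_result`: `n` (integer, or `NA` if
#'   infeasible), `achieved_power`, `feasible`, and the config.
#' @export
loa_sample_size <- function(config, n_max = 1e6L) {
  if (!inherits(config, "sample_size_config")) {
    stop("expected a `sample_size_config`")
  }
  feasible <- abs(config$mu_d) + 1.96 * config$sd_d < config$delta
  if (!feasible) {
    return(structure(list(n = NA_integer_, achieved_power = 0,
                          feasible = FALSE, config = config),
                     class = "sample_size_result"))
  }
  lo <- 2L
  hi <- 2L
  p_hi <- loa_power(hi, config)
  while (p_hi < config$target_power && hi < n_max) {
    lo <- hi
    hi <- min(as.integer(hi * 2L), as.integer(n_max))
    p_hi <- loa_power(hi, config)
  }
  if (p_hi < config$target_power) {
    return(structure(list(n = NA_integer_, achieved_power = p_hi,
                          feasible = FALSE, config = config),
                     class = "sample_size_result"))
  }
  while (hi - lo > 1L) {
    mid <- as.integer((lo + hi) %/% 2L)
    if (loa_power(mid, config) >= config$target_power) hi <- mid else lo <- mid
  }
  structure(list(n = hi, achieved_power = loa_power(hi, config),
                 feasible = TRUE, config = config),
            class = "sample_size_result")
}

#' @export
print.sample_size_result <- function(x, ...) {
  if (!x$feasible) {
    cat("<sample_size_result> infeasible: the true limits of agreement reach the clinical bound\n")
  } else {
    cat(sprintf("<sample_size_result> n = %d (achieved power %.3f, target %.2f)\n",
                x$n, x$achieved_power, x$config$target_power))
  }
  invisible(x)
}
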