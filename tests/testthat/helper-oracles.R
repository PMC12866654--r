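# Independent oracles and small fixture builders shared across tests.
# Everything here is deliberately written with explicit sums/loops, sharing
# no code with the package implementation it checks.

# Kendall tau-b by explicit pair counting (O(n^2) loops)
tau_b_brute <- function(a, b) {
  n <- length(a)
  concordant <- discordant <- 0
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      s <- sign(a[i] - a[j]) * sign(b[i] - b[j])
      if (s > 0) concordant <- concordant + 1
      if (s < 0) discordant <- discordant + 1
    }
  }
  n0 <- n * (n - 1) / 2
  tie_pairs <- function(x) {
    t <- table(x)
    sum(t * (t - 1) / 2)
  }
  (concordant - discordant) /
    sqrt((n0 - tie_pairs(a)) * (n0 - tie_pairs(b)))
}

# Full brute-force recomputation of the heteroscedasticity-adaptive
# Bland-Altman analysis with explicit sums
brute_force_adaptive_loa <- function(m1, m2, tau_threshold = 0.1) {
  n <- length(m1)
  d <- m1 - m2
  X <- (m1 + m2) / 2
  mean_d <- sum(d) / n
  sd_d <- sqrt(sum((d - mean_d)^2) / (n - 1))
  out <- list(mean_diff = mean_d, sd_diff = sd_d,
              loa_low = mean_d - 1.96 * sd_d,
              loa_high = mean_d + 1.96 * sd_d)
  out$tau_raw <- tau_b_brute(abs(d), X)
  out$heteroscedastic <- out$tau_raw > tau_threshold
  if (out$heteroscedastic) {
    dl <- log(m1) - log(m2)
    tau_log <- tau_b_brute(abs(dl), X)
    if (tau_log < out$tau_raw) {
      ml <- sum(dl) / n
      sl <- sqrt(sum((dl - ml)^2) / (n - 1))
      lo <- ml - 1.96 * sl
      hi <- ml + 1.96 * sl
      out$log_branch <- list(
        tau_log = tau_log, mean_log_diff = ml, sd_log_diff = sl,
        loa_log_low = lo, loa_log_high = hi,
        ratio_low = exp(lo), ratio_high = exp(hi),
        slope_low = 2 * (exp(lo) - 1) / (exp(lo) + 1),
        slope_high = 2 * (exp(hi) - 1) / (exp(hi) + 1))
    }
  }
  out
}

# build a paired_sample directly (bypassing the record-table plumbing)
make_paired <- function(m1, m2, ids = NULL) {
  structure(list(
    case_ids = if (is.null(ids)) sprintf("c%04d", seq_along(m1)) else ids,
    m1 = m1, m2 = m2, method1 = "method1", method2 = "method2"),
    class = "paired_sample")
}

# long measurement table for two methods from paired vectors, with optional
# missingness in method1
make_records <- function(m1, m2, missing1 = logical(length(m1)),
                         methods = c("auto_sim", "reference_voxel")) {
  ids <- sprintf("c%04d", seq_along(m1))
  rbind(
    data.frame(case_id = ids, method = methods[1], reader_id = NA_character_,
               volume_mL = ifelse(missing1, NA_real_, m1),
               missed = missing1, partial = FALSE, ivh_included = FALSE,
               distractor_included = FALSE, stringsAsFactors = FALSE),
    data.frame(case_id = ids, method = methods[2], reader_id = NA_character_,
               volume_mL = m2, missed = FALSE, partial = FALSE,
               ivh_included = FALSE, distractor_included = FALSE,
               stringsAsFactors = FALSE))
}

# one-way ANOVA ICC via stats::aov, as an independent cross-check
icc_oneway_aov <- function(ratings) {
  fit <- stats::aov(volume_mL ~ factor(case_id), data = ratings)
  ms <- summary(fit)[[1]][["Mean Sq"]]
  msb <- ms[1]
  msw <- ms[2]
  k <- table(ratings$case_id)
  N <- sum(k)
  n <- length(k)
  kbar <- (N - sum(k^2) / N) / (n - 1)
  (msb - msw) / (msb + (kbar - 1) * msw)
}

# small, quick default phantom for volumetry tests
test_sphere <- function(r_mm = 10, spacing = 1, pad = 4L) {
  shp <- rep(2L * as.integer(ceiling(r_mm / spacing)) + 2L * pad, 3L)
  shp <- shp + shp %% 2L
  make_ellipsoid_mask(rep(r_mm, 3), rep(spacing, 3), shp)
}
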