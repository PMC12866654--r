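test_that("paired_complete_cases keeps exactly the jointly measured cases", {
  set.seed(1)
  m1 <- rlnorm(300, 3, 1)
  m2 <- rlnorm(300, 3, 1)
  missing1 <- rep(c(TRUE, FALSE), c(50, 250))
  recs <- make_records(m1, m2, missing1)
  paired <- paired_complete_cases(recs, "auto_sim", "reference_voxel")
  expect_equal(length(paired$case_ids), 250L)
  expect_identical(paired$case_ids, sort(paired$case_ids))

  full <- paired_complete_cases(make_records(m1, m2), "auto_sim",
                                "reference_voxel")
  expect_equal(length(full$case_ids), 300L)

  expect_error(paired_complete_cases(recs, "abc2", "reference_voxel"),
               "not present")
  # disjoint non-missing sets
  recs2 <- make_records(m1[1:4], m2[1:4], c(TRUE, TRUE, FALSE, FALSE))
  recs2$volume_mL[recs2$method == "reference_voxel" &
                    recs2$case_id %in% c("c0003", "c0004")] <- NA
  expect_error(paired_complete_cases(recs2, "auto_sim", "reference_voxel"),
               "fewer than 2")

  # several readings per case: the first reader's value is used
  recs3 <- rbind(
    measurement_record("a", "abc2", 10, reader_id = "reader_1"),
    measurement_record("a", "abc2", 99, reader_id = "reader_2"),
    measurement_record("b", "abc2", 20, reader_id = "reader_1"),
    measurement_record("a", "reference_voxel", 11),
    measurement_record("b", "reference_voxel", 21))
  p3 <- paired_complete_cases(recs3, "abc2", "reference_voxel")
  expect_equal(p3$m1, c(10, 20))
})

test_that("differences support both modes with the pairwise-mean denominator", {
  p <- make_paired(12, 10)
  expect_equal(differences(p, "absolute")$d, 2)
  expect_equal(differences(p, "percent")$d, 100 * 2 / 11, tolerance = 1e-12)
  expect_equal(differences(p, "percent")$means, 11)

  same <- make_paired(c(3, 7), c(3, 7))
  expect_equal(differences(same, "absolute")$d, c(0, 0))
  expect_equal(differences(same, "percent")$d, c(0, 0))

  # antisymmetry
  a <- make_paired(c(5, 9, 2), c(4, 10, 2.5))
  b <- make_paired(c(4, 10, 2.5), c(5, 9, 2))
  expect_equal(differences(a, "absolute")$d, -differences(b, "absolute")$d)
  expect_equal(differences(a, "percent")$d, -differences(b, "percent")$d)

  expect_error(differences(make_paired(c(1, 0), c(1, 0)), "percent"),
               "zero mean")
})

test_that("bland_altman_limits evaluates the textbook formula", {
  ba <- bland_altman_limits(c(1, 2, 3))
  expect_equal(ba$mean_diff, 2)
  expect_equal(ba$sd_diff, 1)
  expect_equal(ba$loa_low, 2 - 1.96)
  expect_equal(ba$loa_high, 2 + 1.96)

  flat <- bland_altman_limits(c(2, 2, 2, 2))
  expect_equal(flat$sd_diff, 0)
  expect_equal(flat$loa_low, 2)
  expect_equal(flat$loa_high, 2)
  expect_error(bland_altman_limits(1), "at least 2")
})

test_that("limits of agreement cover ~95% of Gaussian differences", {
  set.seed(101)
  d <- rnorm(10000, 5, 10)
  ba <- bland_altman_limits(d)
  inside <- mean(d >= ba$loa_low & d <= ba$loa_high)
  expect_gte(inside, 0.94)
  expect_lte(inside, 0.96)
})

test_that("kendall_tau_het matches its definition and null behaviour", {
  X <- seq(10, 100, length.out = 50)
  expect_equal(kendall_tau_het(0.1 * X, X), 1)
  # sign of the differences is irrelevant (absolute value first)
  d <- 0.1 * X
  expect_equal(kendall_tau_het(-d, X), kendall_tau_het(d, X))
  expect_error(kendall_tau_het(rep(1, 10), rep(2, 10)), "tied")

  # null: independent differences rarely exceed the 0.1 trigger
  set.seed(7)
  hits <- replicate(200, {
    X <- runif(300, 10, 100)
    d <- rnorm(300)
    abs(kendall_tau_het(d, X)) <= 0.1
  })
  expect_gte(mean(hits), 0.9)

  # agrees with explicit pair counting
  set.seed(8)
  a <- rnorm(40)
  b <- rnorm(40) + 0.5 * a
  expect_equal(kendall_tau_het(a, b), tau_b_brute(abs(a), b),
               tolerance = 1e-12)
})

test_that("back_transform_loa is exact and inverts algebraically", {
  expect_equal(back_transform_loa(0), 0)
  expect_equal(back_transform_loa(log(3)), 1.0)
  # round trip slope -> ratio -> slope for a grid including the printed form
  for (r in c(0.1, 0.5, 1, 2, 4.714285714285714)) {
    slope <- back_transform_loa(log(r))
    r_back <- (2 + slope) / (2 - slope)
    expect_equal(r_back, r, tolerance = 1e-9)
    expect_equal(back_transform_loa(log(r_back)), slope, tolerance = 1e-9)
  }
  # a slope of 1.30 corresponds to ratio 4.714...
  expect_equal(back_transform_loa(log(33 / 7)), 1.30, tolerance = 1e-9)
  expect_error(back_transform_loa(Inf), "finite")
})

test_that("adaptive_log_loa triggers the log branch only under heteroscedasticity", {
  set.seed(21)
  additive <- replicate(100, {
    m1 <- runif(300, 10, 100)
    m2 <- m1 + rnorm(300, 0, 2)
    res <- adaptive_log_loa(make_paired(m1, m2))
    res$heteroscedastic
  })
  expect_lte(mean(additive), 0.1)

  multiplicative <- replicate(100, {
    m2 <- runif(300, 10, 100)
    m1 <- m2 * exp(rnorm(300, 0, 0.4))
    res <- adaptive_log_loa(make_paired(m1, m2))
    res$heteroscedastic && !is.null(res$log_branch) &&
      res$log_branch$tau_log < res$tau_raw
  })
  expect_gte(mean(multiplicative), 0.9)

  # log branch errors on nonpositive volumes, naming the case
  bad <- make_paired(c(0, 2, 30, 40, 60, 80) + 0.0, c(1, 1, 3, 4, 6, 8))
  expect_error(adaptive_log_loa(bad), "case")

  # degenerate identical methods: no heteroscedasticity flag, no crash
  same <- make_paired(c(3, 7, 9), c(3, 7, 9))
  res0 <- adaptive_log_loa(same)
  expect_false(res0$heteroscedastic)
  expect_equal(res0$tau_raw, 0)
})

test_that("adaptive_log_loa matches an independent brute-force recomputation", {
  set.seed(33)
  for (k in 1:50) {
    n <- sample(5:25, 1)
    m2 <- runif(n, 5, 80)
    m1 <- m2 * exp(rnorm(n, 0, runif(1, 0.05, 0.5)))
    res <- adaptive_log_loa(make_paired(m1, m2))
    ref <- brute_force_adaptive_loa(m1, m2)
    expect_equal(res$mean_diff, ref$mean_diff, tolerance = 1e-10)
    expect_equal(res$sd_diff, ref$sd_diff, tolerance = 1e-10)
    expect_equal(res$loa_low, ref$loa_low, tolerance = 1e-10)
    expect_equal(res$loa_high, ref$loa_high, tolerance = 1e-10)
    expect_equal(res$tau_raw, ref$tau_raw, tolerance = 1e-10)
    expect_identical(res$heteroscedastic, ref$heteroscedastic)
    expect_identical(is.null(res$log_branch), is.null(ref$log_branch))
    if (!is.null(res$log_branch)) {
      for (f in names(ref$log_branch)) {
        expect_equal(res$log_branch[[f]], ref$log_branch[[f]],
                     tolerance = 1e-10)
      }
      # structural invariants of the result type
      expect_equal(res$log_branch$ratio_low, exp(res$log_branch$loa_log_low))
      expect_lt(res$log_branch$slope_low, res$log_branch$slope_high)
    }
    # LoA arithmetic identity holds exactly
    expect_identical(res$loa_low, res$mean_diff - 1.96 * res$sd_diff)
    expect_identical(res$loa_high, res$mean_diff + 1.96 * res$sd_diff)
  }
})

test_that("back-transformed slopes match empirical percentiles of differences", {
  # multiplicative pairs with the ratio independent of the pairwise mean --
  # the exact model under which the back-transformed limits are defined
  set.seed(55)
  n <- 100000
  X0 <- runif(n, 10, 100)
  R <- exp(rnorm(n, 0, 0.4))
  m2 <- 2 * X0 / (1 + R)
  m1 <- m2 * R
  dl <- log(m1) - log(m2)
  bal <- bland_altman_limits(dl)
  slope_low <- back_transform_loa(bal$loa_low)
  slope_high <- back_transform_loa(bal$loa_high)
  d <- m1 - m2
  X <- (m1 + m2) / 2
  # central bins of the mean: empirical 2.5/97.5 percentiles vs slope * X
  brk <- quantile(X, seq(0.2, 0.8, by = 0.1))
  for (b in 1:(length(brk) - 1)) {
    sel <- X >= brk[b] & X < brk[b + 1]
    xc <- mean(X[sel])
    emp <- quantile(d[sel], c(0.025, 0.975), names = FALSE)
    expect_lt(abs(emp[1] - slope_low * xc) / abs(slope_low * xc), 0.1)
    expect_lt(abs(emp[2] - slope_high * xc) / abs(slope_high * xc), 0.1)
  }
})

test_that("icc_oneway matches aov and recovers known designs", {
  # perfect agreement with between-case spread
  perfect <- data.frame(case_id = rep(1:10, each = 2),
                        reader_id = rep(c("a", "b"), 10),
                        volume_mL = rep(seq(5, 50, by = 5), each = 2))
  expect_equal(icc_oneway(perfect)$icc, 1)

  # reader noise only: ICC near zero on average (a single n = 200 draw has
  # sampling SD ~ 0.07)
  set.seed(13)
  null_icc <- replicate(20, {
    icc_oneway(data.frame(case_id = rep(1:200, each = 2),
                          reader_id = rep(c("a", "b"), 200),
                          volume_mL = rnorm(400, 20, 3)))$icc
  })
  expect_lte(mean(null_icc), 0.1)

  # unbalanced design agrees with the aov-based computation
  set.seed(14)
  k <- sample(1:4, 60, replace = TRUE)
  k[1:2] <- 2  # guarantee within-case df
  ub <- do.call(rbind, lapply(seq_along(k), function(i) {
    data.frame(case_id = i, reader_id = paste0("r", seq_len(k[i])),
               volume_mL = rnorm(k[i], mean = rnorm(1, 30, 10), sd = 2))
  }))
  expect_equal(icc_oneway(ub)$icc, icc_oneway_aov(ub), tolerance = 1e-10)

  # parameter recovery at the study's printed inter-observer agreement
  set.seed(15)
  est <- replicate(500, {
    subj <- rnorm(30, 0, sqrt(0.97))
    y <- rep(subj, each = 2) + rnorm(60, 0, sqrt(0.03))
    icc_oneway(data.frame(case_id = rep(1:30, each = 2),
                          reader_id = rep(c("a", "b"), 30),
                          volume_mL = y))$icc
  })
  expect_lt(abs(mean(est) - 0.97), 0.02)

  expect_error(icc_oneway(data.frame(case_id = 1:5, reader_id = "a",
                                     volume_mL = 1:5)),
               "2 or more readings")
})

test_that("paired_t_test evaluates the closed form", {
  tt <- paired_t_test(c(1, 2, 3))
  expect_equal(tt$statistic, 2 / (1 / sqrt(3)), tolerance = 1e-10)
  expect_equal(tt$p_value, 2 * pt(-abs(tt$statistic), 2), tolerance = 1e-12)
  expect_equal(tt$p_value, 0.0742, tolerance = 1e-3)

  sym <- paired_t_test(c(-1, 1))
  expect_equal(sym$statistic, 0)
  expect_equal(sym$p_value, 1)

  # scale invariance
  a <- paired_t_test(c(0.5, 1.2, -0.3, 2))
  b <- paired_t_test(10 * c(0.5, 1.2, -0.3, 2))
  expect_equal(a$statistic, b$statistic)
  expect_equal(a$p_value, b$p_value)

  expect_error(paired_t_test(c(2, 2, 2)), "zero variance")
})

test_that("shapiro_wilk keeps its type-I error and detects lognormal data", {
  set.seed(91)
  rejections <- mean(replicate(1000, shapiro_wilk(rnorm(300))$p_value < 0.05))
  expect_gte(rejections, 0.03)
  expect_lte(rejections, 0.07)

  power <- mean(replicate(100, shapiro_wilk(rlnorm(300, 0, 1))$p_value < 0.05))
  expect_gte(power, 0.95)

  # W is invariant to affine transforms
  x <- rnorm(50)
  expect_equal(shapiro_wilk(x)$statistic, shapiro_wilk(3 * x - 7)$statistic,
               tolerance = 1e-12)
  expect_error(shapiro_wilk(rnorm(2)), "3 <= n")
})

test_that("subgroup_agreement stratifies, partitions and degrades gracefully", {
  set.seed(41)
  n <- 120
  truth <- data.frame(case_id = sprintf("c%04d", 1:n),
                      ivh_present = rep(c(TRUE, FALSE), n / 2),
                      location = sample(c("lobar", "basal_ganglia_thalamus"),
                                        n, replace = TRUE),
                      stringsAsFactors = FALSE)
  m2 <- rlnorm(n, log(26), 1)
  m1 <- m2 * exp(rnorm(n, 0, 0.2)) + ifelse(truth$ivh_present, 8, 0)
  recs <- make_records(m1, m2)

  by_ivh <- subgroup_agreement(recs, truth, "ivh", "auto_sim",
                               "reference_voxel")
  expect_named(by_ivh, c("ivh", "no_ivh"))
  expect_equal(by_ivh$ivh$n + by_ivh$no_ivh$n, n)  # strata partition cases
  # IVH inclusion shows up as a larger mean difference in the IVH stratum
  expect_gt(by_ivh$ivh$mean_diff, by_ivh$no_ivh$mean_diff)

  by_vol <- subgroup_agreement(recs, truth, "volume_40", "auto_sim",
                               "reference_voxel")
  expect_setequal(names(by_vol), c("lt_40_mL", "ge_40_mL"))

  # degenerate stratum: no IVH cases at all -> single estimable stratum
  truth0 <- truth
  truth0$ivh_present <- FALSE
  one <- subgroup_agreement(recs, truth0, "ivh", "auto_sim",
                            "reference_voxel")
  expect_named(one, "no_ivh")
  expect_s3_class(one$no_ivh, "bland_altman_result")

  # a tiny stratum is reported as not estimable, not an error
  truth2 <- truth
  truth2$ivh_present <- c(TRUE, TRUE, rep(FALSE, n - 2))
  small <- subgroup_agreement(recs, truth2, "ivh", "auto_sim",
                              "reference_voxel")
  expect_identical(small$ivh, "not estimable")
})

test_that("the 10% acceptability rule is boundary-inclusive on percent limits", {
  fake_pct <- function(lo, hi) {
    structure(list(n = 100L, mode = "percent", mean_diff = (lo + hi) / 2,
                   sd_diff = (hi - lo) / (2 * 1.96), loa_low = lo,
                   loa_high = hi, tau_raw = 0, heteroscedastic = FALSE,
                   log_branch = NULL),
              class = "bland_altman_result")
  }
  # the study's own failed check: percent LoA (-66.7, 121.2)
  expect_false(acceptance_check(fake_pct(-66.7, 121.2)))
  expect_true(acceptance_check(fake_pct(-9, 9)))
  expect_true(acceptance_check(fake_pct(-10, 10)))  # "10% or less"
  expect_false(acceptance_check(fake_pct(-10.01, 9)))
  abs_res <- fake_pct(-5, 5)
  abs_res$mode <- "absolute"
  expect_error(acceptance_check(abs_res), "percent")
})
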