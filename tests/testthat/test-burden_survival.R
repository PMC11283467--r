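test_that("quantile dichotomization uses the strict-exceedance rule", {
  v <- stats::setNames(1:10, sprintf("S%02d", 1:10))
  d <- dichotomize_quantile(v, 0.6)
  expect_equal(d$threshold, 6)
  expect_setequal(names(d$groups)[d$groups == "high"],
                  sprintf("S%02d", 7:10))
  # group sizes match brute-force counting on random values
  set.seed(401)
  for (rep in 1:30) {
    n <- sample(5:200, 1)
    x <- stats::setNames(rnorm(n), sprintf("S%03d", seq_len(n)))
    q <- sample(seq(0.1, 0.9, 0.1), 1)
    d <- dichotomize_quantile(x, q)
    expect_equal(sum(d$groups == "high"), sum(x > d$threshold))
    expect_gte(sum(sort(x) <= d$threshold), q * n - 1e-6)
    # threshold is the smallest value satisfying the quantile condition
    below <- sort(x)[sort(x) < d$threshold]
    if (length(below) > 0) {
      expect_lt(sum(x <= max(below)), q * n + 1e-6)
    }
  }
  # identical values: everything low, with a warning
  tied <- stats::setNames(rep(4, 5), sprintf("S%d", 1:5))
  expect_warning(d <- dichotomize_quantile(tied, 0.6), "identical")
  expect_true(all(d$groups == "low"))
})

test_that("KM with no censoring is the empirical survivor function", {
  k <- km_estimate(c(10, 20, 70, 80), c(TRUE, TRUE, TRUE, TRUE))
  expect_equal(survival_at(k, 60)$rate, 0.5)
  set.seed(402)
  for (rep in 1:20) {
    n <- sample(5:60, 1)
    t <- round(rexp(n, 0.02), 1)
    k <- km_estimate(t, rep(TRUE, n))
    for (tt in sample(t, 3)) {
      expect_equal(survival_at(k, tt)$rate, mean(t > tt))
    }
  }
  # all censored: survival identically 1 with zero variance
  k0 <- km_estimate(c(5, 10, 15), c(FALSE, FALSE, FALSE))
  expect_equal(length(k0$time), 0)
  expect_equal(survival_at(k0, 100)$rate, 1)
})

test_that("KM curve and Greenwood variance match the survival package", {
  skip_if_not_installed("survival")
  set.seed(403)
  for (rep in 1:20) {
    n <- sample(10:80, 1)
    t <- round(rexp(n, 0.03), 2)
    e <- runif(n) < 0.7
    if (!any(e)) e[1] <- TRUE
    k <- km_estimate(t, e)
    fit <- survival::survfit(survival::Surv(t, e) ~ 1)
    at_events <- fit$n.event > 0
    expect_equal(k$time, fit$time[at_events])
    expect_equal(k$survival, fit$surv[at_events], tolerance = 1e-12)
    expect_equal(k$n_risk, fit$n.risk[at_events])
    # survfit std.err is the SE of log S; Greenwood var = S^2 * se_log^2
    # (survfit reports NaN once S reaches 0; we define the variance as 0 there)
    want <- (fit$surv[at_events] * fit$std.err[at_events])^2
    finite <- is.finite(want)
    expect_equal(k$greenwood_var[finite], want[finite], tolerance = 1e-10)
    expect_equal(k$greenwood_var[!finite],
                 rep(0, sum(!finite)))
  }
})

test_that("cloglog confidence interval matches the closed form and survfit", {
  skip_if_not_installed("survival")
  set.seed(404)
  t <- round(rexp(60, 0.02), 2)
  e <- runif(60) < 0.65
  k <- km_estimate(t, e)
  fit <- survival::survfit(survival::Surv(t, e) ~ 1, conf.type = "log-log")
  t0 <- sort(t[e])[20]
  got <- survival_at(k, t0)
  i <- max(which(fit$time <= t0))
  expect_equal(got$rate, fit$surv[i], tolerance = 1e-12)
  expect_equal(got$ci_low, fit$lower[i], tolerance = 1e-8)
  expect_equal(got$ci_high, fit$upper[i], tolerance = 1e-8)
  # degenerate cases
  expect_equal(survival_at(k, min(k$time) - 1),
               list(rate = 1, ci_low = 1, ci_high = 1, t = min(k$time) - 1))
  k0 <- km_estimate(c(1, 2), c(FALSE, FALSE))
  s0 <- survival_at(k0, 5)
  expect_equal(s0$ci_low, s0$rate)
  expect_equal(s0$ci_high, s0$rate)
})

test_that("log-rank reproduces the hand-computed 2-vs-2 worked example", {
  # groups {1,2} and {3,4}, all events: O1 = 2, E1 = 1/2 + 1/3,
  # V = 1/4 + 2/9, chi-square = (7/6)^2 / (17/36) = 49/17
  lr <- logrank_test(c(1, 2, 3, 4), rep(TRUE, 4), c("a", "a", "b", "b"))
  expect_equal(lr$statistic, 49 / 17, tolerance = 1e-12)
  expect_equal(lr$observed, 2)
  expect_equal(lr$expected, 5 / 6, tolerance = 1e-12)
  expect_equal(lr$p, pchisq(49 / 17, 1, lower.tail = FALSE))
})

test_that("log-rank is symmetric, label-exchange invariant and censoring-stable", {
  t <- c(3, 6, 9, 12, 15)
  # both groups contain the same dataset: statistic 0, p 1
  lr <- logrank_test(c(t, t), rep(TRUE, 10), rep(c("a", "b"), each = 5))
  expect_equal(lr$statistic, 0, tolerance = 1e-12)
  expect_equal(lr$p, 1)
  # swapping labels leaves the chi-square unchanged
  set.seed(405)
  tt <- rexp(30, 0.05); ee <- runif(30) < 0.8
  gg <- rep(c("a", "b"), 15)
  lr1 <- logrank_test(tt, ee, gg)
  lr2 <- logrank_test(tt, ee, ifelse(gg == "a", "b", "a"))
  expect_equal(lr1$statistic, lr2$statistic, tolerance = 1e-12)
  # a subject censored before the first event enters no risk set
  lr3 <- logrank_test(c(tt, min(tt[ee]) / 2), c(ee, FALSE), c(gg, "a"))
  expect_equal(lr3$statistic, lr1$statistic, tolerance = 1e-12)
  # no events at all: statistic 0, p 1
  lr0 <- logrank_test(c(1, 2), c(FALSE, FALSE), c("a", "b"))
  expect_equal(lr0$p, 1)
})

test_that("log-rank chi-square agrees with survdiff and a permutation null", {
  skip_if_not_installed("survival")
  set.seed(406)
  for (rep in 1:15) {
    n <- sample(16:60, 1)
    t <- round(rexp(n, 0.04), 2)
    e <- runif(n) < 0.75
    g <- sample(c("a", "b"), n, TRUE)
    if (length(unique(g)) < 2) g[1:2] <- c("a", "b")
    lr <- logrank_test(t, e, g)
    sd <- survival::survdiff(survival::Surv(t, e) ~ g)
    expect_equal(lr$statistic, sd$chisq, tolerance = 1e-8)
  }
  # permutation oracle: moderate effect, n = 60, B = 4000
  set.seed(407)
  t <- c(rexp(30, 0.02), rexp(30, 0.04))
  e <- runif(60) < 0.8
  g <- rep(c("a", "b"), each = 30)
  p_chisq <- logrank_test(t, e, g)$p
  p_perm <- perm_logrank_p(t, e, g, B = 4000)
  mc_se <- sqrt(p_perm * (1 - p_perm) / 4000)
  expect_lt(abs(p_chisq - p_perm), 0.02 + 3 * mc_se)
})

test_that("rank comparisons match exact enumeration and are label-symmetric", {
  v <- stats::setNames(c(1, 2, 3, 4, 5, 6), sprintf("S%d", 1:6))
  lab <- stats::setNames(rep(c("a", "b"), each = 3), names(v))
  got <- suppressWarnings(compare_groups(v, lab, "wilcoxon"))
  # exact two-sided p over all C(6,3) = 20 assignments of the labels
  combos <- combn(6, 3)
  rank_sums <- apply(combos, 2, function(idx) sum(rank(v)[idx]))
  obs <- sum(rank(v)[lab == "a"])
  mu <- mean(rank_sums)
  p_exact <- mean(abs(rank_sums - mu) >= abs(obs - mu) - 1e-12)
  expect_equal(got$p, p_exact)
  # label swap leaves p unchanged
  swapped <- stats::setNames(ifelse(lab == "a", "b", "a"), names(lab))
  expect_equal(suppressWarnings(compare_groups(v, swapped, "wilcoxon"))$p, got$p)
  # kruskal on 2 groups is a valid fallback; 3 groups works
  v3 <- stats::setNames(rnorm(30), sprintf("S%02d", 1:30))
  l3 <- stats::setNames(rep(c("a", "b", "c"), 10), names(v3))
  expect_true(compare_groups(v3, l3, "kruskal")$p >= 0)
  expect_error(compare_groups(v3, l3, "wilcoxon"), "two groups")
})

test_that("kruskal-wallis holds its nominal type-I error under the null", {
  set.seed(408)
  reps <- 2000
  rej <- 0L
  ids <- sprintf("S%02d", 1:30)
  labs <- stats::setNames(rep(c("a", "b", "c"), each = 10), ids)
  for (r in seq_len(reps)) {
    v <- stats::setNames(rnorm(30), ids)
    if (compare_groups(v, labs, "kruskal")$p < 0.05) rej <- rej + 1L
  }
  expect_gt(rej / reps, 0.03)
  expect_lt(rej / reps, 0.07)
})

test_that("BH adjustment equals the definitional min-over-k oracle", {
  expect_equal(fdr_adjust(0.03), 0.03)
  expect_equal(fdr_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  set.seed(409)
  for (rep in 1:30) {
    p <- runif(sample(1:40, 1))
    adj <- fdr_adjust(p)
    expect_equal(adj, bh_oracle(p), tolerance = 1e-12)
    expect_true(all(adj >= p - 1e-12))
    expect_true(all(adj <= 1))
    # adjusted p-values are non-decreasing in the rank of the raw p
    expect_true(all(diff(adj[order(p)]) >= -1e-12))
  }
})

test_that("cutoff scan is deterministic and honours untestable cells", {
  set.seed(410)
  n <- 120
  ids <- sprintf("S%03d", seq_len(n))
  burden <- stats::setNames(rnbinom(n, mu = 8, size = 2.5), ids)
  clin <- tibble::tibble(
    sample_id = ids,
    subtype = sample(c("HR+HER2-", "TNBC"), n, TRUE),
    efs_months = round(rexp(n, 0.01), 2),
    efs_event = runif(n) < 0.7
  )
  s1 <- scan_cutoffs(burden, clin)
  s2 <- scan_cutoffs(burden, clin)
  expect_identical(s1$results, s2$results)
  expect_identical(s1$selected_quantile, s2$selected_quantile)
  # single subgroup, single quantile: that quantile is selected trivially
  s3 <- scan_cutoffs(burden, clin, subgroups = list(all = ids), grid = 0.4)
  expect_equal(s3$selected_quantile, 0.4)
  # a subgroup whose members all sit at the minimum burden has an empty high
  # arm once the threshold reaches the maximum: cell marked untestable
  burden2 <- burden
  low_ids <- ids[1:20]
  burden2[low_ids] <- 0
  burden2[setdiff(ids, low_ids)] <- 100
  s4 <- scan_cutoffs(burden2, clin,
                     subgroups = list(all = ids, stuck = low_ids))
  stuck <- s4$results[s4$results$subgroup == "stuck", ]
  expect_true(all(!stuck$testable))
  expect_true(all(is.na(stuck$p)))
  cov_vals <- s4$coverage
  expect_true(all(cov_vals <= 1))
})

test_that("high-burden arms show worse 5-year EFS under a planted hazard ratio", {
  cfg_base <- cohort_config(seed = 1)
  worse <- 0L
  n_seeds <- 100
  for (s in seq_len(n_seeds)) {
    cfg <- cohort_config(seed = 5000 + s)
    groups <- stats::setNames(
      rep(c("high", "low"), c(120, 180)), sprintf("S%03d", 1:300))
    surv <- generate_survival(groups, cfg)
    hi <- surv$sample_id %in% names(groups)[groups == "high"]
    k_hi <- km_estimate(surv$efs_months[hi], surv$efs_event[hi])
    k_lo <- km_estimate(surv$efs_months[!hi], surv$efs_event[!hi])
    if (survival_at(k_hi, 60)$rate < survival_at(k_lo, 60)$rate) {
      worse <- worse + 1L
    }
  }
  expect_gte(worse / n_seeds, 0.95)
})
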