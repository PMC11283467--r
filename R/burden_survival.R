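# Burden dichotomization, Kaplan-Meier estimation with Greenwood variance,
# the two-group log-rank test, quantile cutoff scanning across subgroups,
# rank-based group comparisons and FDR adjustment.
#
# The product-limit estimator and the log-rank statistic are implemented
# here; rank tests and Benjamini-Hochberg adjustment are delegated to base R
# (stats::wilcox.test, stats::kruskal.test, stats::p.adjust).

#' Dichotomize a per-sample quantity at an empirical quantile
#'
#' The threshold is the smallest observed value `v` such that at least
#' `q * n` of the values are `<= v` (type-1 empirical quantile). Samples with
#' values strictly above the threshold ("exceeding" it) are labelled
#' `"high"`; ties at the threshold go to `"low"`, so the high group is a
#' strict minority for continuous data.
#'
#' @param values Named numeric vector, sample id -> value (>= 2 samples).
#' @param q Quantile in (0, 1); default 0.6.
#' @return A list with `groups` (named character vector, `"high"`/`"low"`),
#'   `threshold` and `q`.
#' @export
dichotomize_quantile <- function(values, q = 0.6) {
  values <- as_named(values, "values")
  stopifnot(length(values) >= 2, q > 0, q < 1, !anyNA(values))
  n <- length(values)
  k <- as.integer(ceiling(q * n - 1e-9))
  threshold <- sort(values, method = "radix")[k]
  groups <- ifelse(values > threshold, "high", "low")
  names(groups) <- names(values)
  if (all(groups == "low") && length(unique(values)) == 1) {
    warning("all values identical: every sample assigned to the low group")
  }
  list(groups = groups, threshold = unname(threshold), q = q)
}

#' Kaplan-Meier survival curve
#'
#' Product-limit estimator over distinct event times, with subjects censored
#' at an event time remaining at risk for that time's factor (the standard
#' convention), and Greenwood's variance accumulated along the curve.
#'
#' @param times Non-negative follow-up times (months).
#' @param events Logical (or 0/1) event indicators; `FALSE` = censored.
#' @return An object of class `km_curve`: list with `time` (distinct event
#'   times, ascending), `n_risk`, `n_event`, `survival`, `greenwood_var`,
#'   and `n` (sample size). S(0) = 1 is implicit.
#' @export
km_estimate <- function(times, events) {
  events <- as.logical(events)
  stopifnot(length(times) == length(events), length(times) > 0,
            all(times >= 0), !anyNA(times), !anyNA(events))
  ev_times <- sort(unique(times[events]))
  n_risk <- vapply(ev_times, function(t) sum(times >= t), 0L)
  n_event <- vapply(ev_times, function(t) sum(times == t & events), 0L)
  surv <- cumprod(1 - n_event / n_risk)
  gw_terms <- ifelse(n_risk > n_event,
                     n_event / (n_risk * (n_risk - n_event)), NA_real_)
  gw <- surv^2 * cumsum(ifelse(is.na(gw_terms), 0, gw_terms))
  gw[surv == 0] <- 0
  structure(list(time = ev_times, n_risk = as.integer(n_risk),
                 n_event = as.integer(n_event), survival = surv,
                 greenwood_var = gw, n = length(times)),
            class = "km_curve")
}

#' @export
print.km_curve <- function(x, ...) {
  cat(sprintf("<km_curve: n = %d, %d events at %d distinct times%s>\n",
              x$n, sum(x$n_event), length(x$time),
              if (length(x$time) > 0)
                sprintf(", final S = %.3f", x$survival[length(x$survival)])
              else ""))
  invisible(x)
}

#' Survival probability at a time point with confidence interval
#'
#' Evaluates the step function at the last event time `<= t` (1 with a
#' degenerate interval if `t` precedes the first event). The confidence
#' interval uses the complementary log-log transform with Greenwood's
#' variance and is clipped to `[0, 1]`; a zero-variance curve yields a
#' degenerate interval at the point estimate.
#'
#' @param curve A `km_curve` from [km_estimate()].
#' @param t Time point (e.g. 60 months for the 5-year rate).
#' @param conf_level Confidence level (default 0.95).
#' @return A list with `rate`, `ci_low`, `ci_high`, `t`.
#' @export
survival_at <- function(curve, t, conf_level = 0.95) {
  stopifnot(inherits(curve, "km_curve"), t >= 0)
  idx <- which(curve$time <= t)
  if (length(idx) == 0) {
    return(list(rate = 1, ci_low = 1, ci_high = 1, t = t))
  }
  i <- max(idx)
  s <- curve$survival[i]
  v <- curve$greenwood_var[i]
  if (v <= 0 || s <= 0 || s >= 1) {
    lo <- hi <- s
  } else {
    z <- stats::qnorm(1 - (1 - conf_level) / 2)
    se_theta <- sqrt(v) / abs(s * log(s))
    lo <- s^exp(z * se_theta)
    hi <- s^exp(-z * se_theta)
  }
  list(rate = s, ci_low = max(0, min(1, lo)), ci_high = max(0, min(1, hi)),
       t = t)
}

#' Two-group log-rank test
#'
#' Observed-minus-expected statistic with hypergeometric variance summed over
#' distinct event times; two-sided p-value from the chi-square distribution
#' with 1 degree of freedom, no continuity correction. With no events at all
#' (or zero variance) the statistic is 0 and p = 1.
#'
#' @param times Follow-up times.
#' @param events Logical event indicators.
#' @param group Two-level group labels (factor/character), each level
#'   non-empty.
#' @return A list with `statistic`, `df` (1), `p`, `observed` and `expected`
#'   (events in the first group).
#' @export
logrank_test <- function(times, events, group) {
  events <- as.logical(events)
  group <- as.factor(group)
  stopifnot(length(times) == length(events), length(times) == length(group),
            nlevels(droplevels(group)) == 2)
  group <- droplevels(group)
  g1 <- group == levels(group)[1]
  ev_times <- sort(unique(times[events]))
  o1 <- e1 <- v <- 0
  for (t in ev_times) {
    at_risk <- times >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & g1)
    d <- sum(times == t & events)
    d1 <- sum(times == t & events & g1)
    o1 <- o1 + d1
    e1 <- e1 + d * n1 / n
    if (n > 1) {
      v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
    }
  }
  if (v <= 0) {
    return(list(statistic = 0, df = 1L, p = 1, observed = o1, expected = e1))
  }
  stat <- (o1 - e1)^2 / v
  list(statistic = stat, df = 1L,
       p = stats::pchisq(stat, df = 1, lower.tail = FALSE),
       observed = o1, expected = e1)
}

#' Scan burden cutoff quantiles across subgroups
#'
#' For every quantile on the grid, the burden of the full analyzed cohort is
#' dichotomized at that quantile (one global threshold, as in stratified
#' Kaplan-Meier panels that share a cutoff), then an event-free-survival
#' log-rank test is run within every subgroup. A subgroup whose high or low
#' arm is empty at a quantile is untestable there and excluded from coverage.
#' Coverage is the number of subgroups significant at `alpha`; following the
#' convention that significance is judged on FDR-adjusted p-values, the
#' default adjusts p-values per quantile across subgroups
#' (`p_adjust = "BH"`). The selected quantile maximizes coverage; ties break
#' by the smaller raw all-patients p, then by the smaller quantile.
#'
#' @param burden Named numeric vector, sample id -> fusion burden.
#' @param clinical Data frame with columns `sample_id`, `subtype`,
#'   optionally `intrinsic`, `efs_months`, `efs_event`.
#' @param subgroups Optional named list of sample-id vectors. Default: all
#'   patients, one subgroup per IHC subtype present, and one per intrinsic
#'   subtype with at least `min_subgroup` samples.
#' @param grid Quantile grid (default 0.1..0.9 by 0.1).
#' @param alpha Significance level for coverage (default 0.05).
#' @param p_adjust `"BH"` (default) or `"none"`: whether coverage counts
#'   FDR-adjusted or raw p-values.
#' @param min_subgroup Minimum size for default intrinsic-subtype subgroups
#'   (default 10; small panels such as a handful of normal-like samples are
#'   not informative).
#' @return An object of class `cutoff_scan`: list with `results` (tibble:
#'   `quantile`, `subgroup`, `n_high`, `n_low`, `p`, `p_adj`, `testable`),
#'   `coverage` (named by quantile), `selected_quantile`,
#'   `selected_threshold`, `alpha`, `p_adjust`.
#' @export
scan_cutoffs <- function(burden, clinical, subgroups = NULL,
                         grid = seq(0.1, 0.9, by = 0.1), alpha = 0.05,
                         p_adjust = c("BH", "none"), min_subgroup = 10L) {
  p_adjust <- match.arg(p_adjust)
  burden <- as_named(burden, "burden")
  stopifnot(all(c("sample_id", "subtype", "efs_months", "efs_event") %in%
                  names(clinical)))
  clinical <- clinical[clinical$sample_id %in% names(burden), , drop = FALSE]
  stopifnot(nrow(clinical) >= 2)
  ids <- clinical$sample_id
  if (is.null(subgroups)) {
    subgroups <- c(list(all = ids),
                   split(ids, clinical$subtype))
    if ("intrinsic" %in% names(clinical)) {
      intr <- split(ids, clinical$intrinsic)
      intr <- intr[vapply(intr, length, 0L) >= min_subgroup]
      subgroups <- c(subgroups, intr)
    }
    subgroups <- subgroups[vapply(subgroups, length, 0L) > 0]
  }
  times <- stats::setNames(clinical$efs_months, ids)
  events <- stats::setNames(as.logical(clinical$efs_event), ids)

  rows <- list()
  thresholds <- stats::setNames(numeric(length(grid)), format(grid))
  for (qi in seq_along(grid)) {
    q <- grid[qi]
    dq <- dichotomize_quantile(burden[ids], q)
    thresholds[qi] <- dq$threshold
    for (sg in names(subgroups)) {
      sub <- intersect(subgroups[[sg]], ids)
      g <- dq$groups[sub]
      n_high <- sum(g == "high"); n_low <- sum(g == "low")
      testable <- n_high > 0 && n_low > 0
      p <- if (testable) logrank_test(times[sub], events[sub], g)$p else NA_real_
      rows[[length(rows) + 1]] <- tibble::tibble(
        quantile = q, subgroup = sg, n_high = n_high, n_low = n_low,
        p = p, testable = testable)
    }
  }
  res <- dplyr::bind_rows(rows)
  res <- res |>
    dplyr::group_by(.data$quantile) |>
    dplyr::mutate(p_adj = if (p_adjust == "BH") fdr_adjust(.data$p) else .data$p) |>
    dplyr::ungroup()
  cov <- res |>
    dplyr::group_by(.data$quantile) |>
    dplyr::summarise(coverage = sum(.data$p_adj < alpha, na.rm = TRUE),
                     .groups = "drop")
  coverage <- stats::setNames(cov$coverage, format(cov$quantile))
  # selection: max coverage, then smallest raw all-patients p, then smaller q
  p_all <- res$p[res$subgroup == "all"]
  p_all <- stats::setNames(p_all, format(res$quantile[res$subgroup == "all"]))
  p_all[is.na(p_all)] <- Inf
  ord <- order(-cov$coverage, p_all[format(cov$quantile)], cov$quantile)
  selected <- cov$quantile[ord[1]]
  structure(list(results = res, coverage = coverage,
                 selected_quantile = selected,
                 selected_threshold = unname(thresholds[format(selected)]),
                 thresholds = thresholds,
                 alpha = alpha, p_adjust = p_adjust,
                 subgroups = lapply(subgroups, length)),
            class = "cutoff_scan")
}

#' @export
print.cutoff_scan <- function(x, ...) {
  cat(sprintf("<cutoff_scan: selected quantile %.1f (threshold %g), coverage %d of %d subgroups at alpha %.2f [%s p-values]>\n",
              x$selected_quantile, x$selected_threshold,
              x$coverage[format(x$selected_quantile)], length(x$subgroups),
              x$alpha, if (x$p_adjust == "BH") "BH-adjusted" else "raw"))
  invisible(x)
}

#' Rank-based comparison of a quantity between groups
#'
#' Wilcoxon rank-sum test for two groups or Kruskal-Wallis for two or more,
#' delegated to [stats::wilcox.test()] / [stats::kruskal.test()] (average
#' ranks for ties; the Wilcoxon test is exact for small untied samples and
#' uses the normal approximation otherwise).
#'
#' @param values Named numeric vector, sample id -> value.
#' @param labels Named vector, sample id -> group label.
#' @param test `"wilcoxon"` (exactly 2 groups) or `"kruskal"` (>= 2).
#' @return A list with `statistic`, `p`, `test`, `n`.
#' @export
compare_groups <- function(values, labels, test = c("wilcoxon", "kruskal")) {
  test <- match.arg(test)
  values <- as_named(values, "values")
  labels <- as_named(labels, "labels")
  common <- intersect(names(values), names(labels))
  v <- unname(values[common])
  f <- droplevels(as.factor(unname(labels[common])))
  if (any(table(f) == 0) || nlevels(f) < 2) {
    stop("compare_groups requires at least two non-empty groups")
  }
  if (test == "wilcoxon") {
    if (nlevels(f) != 2) stop("wilcoxon test requires exactly two groups")
    ht <- stats::wilcox.test(v ~ f)
  } else {
    ht <- stats::kruskal.test(v, f)
  }
  list(statistic = unname(ht$statistic), p = unname(ht$p.value),
       test = test, n = length(v))
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up false-discovery-rate adjustment with monotonicity enforcement
#' (delegates to [stats::p.adjust()] with `method = "BH"`); `NA` entries are
#' passed through.
#'
#' @param pvalues Numeric vector of raw p-values in `[0, 1]`.
#' @return Adjusted p-values, elementwise `>=` the raw values and `<= 1`.
#' @export
fdr_adjust <- function(pvalues) {
  stopifnot(all(pvalues >= 0 & pvalues <= 1, na.rm = TRUE))
  stats::p.adjust(pvalues, method = "BH")
}
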