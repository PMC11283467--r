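# Fixture builders and independent brute-force oracles used across tests.
# The oracles are written as plain loops over rows so they share no code
# path with the vectorized package implementation they check.

# Random normalized fusion-call table.
rand_calls <- function(n, n_samples = 3, genes = sprintf("G%02d", 1:15),
                       p_flag = 0.15, callers = c("A", "B", "C")) {
  g5 <- sample(genes, n, replace = TRUE)
  g3 <- sample(genes, n, replace = TRUE)
  clash <- g5 == g3
  g3[clash] <- genes[(match(g5[clash], genes) %% length(genes)) + 1L]
  split <- rpois(n, 4)
  disc <- rpois(n, 3)
  tibble::tibble(
    sample_id = sample(sprintf("S%02d", seq_len(n_samples)), n, replace = TRUE),
    caller = sample(callers, n, replace = TRUE),
    gene5 = g5,
    chrom5 = sample(CHROMOSOMES, n, replace = TRUE),
    pos5 = sample.int(100000000L, n, replace = TRUE),
    strand5 = sample(c("+", "-", "."), n, replace = TRUE, prob = c(.45, .45, .1)),
    gene3 = g3,
    chrom3 = sample(CHROMOSOMES, n, replace = TRUE),
    pos3 = sample.int(100000000L, n, replace = TRUE),
    strand3 = sample(c("+", "-", "."), n, replace = TRUE, prob = c(.45, .45, .1)),
    split_reads = split,
    discordant_pairs = disc,
    total_support = split + disc,
    read_through = runif(n) < p_flag
  )
}

# Row-by-row predicate scan + explicit pair/caller-set enumeration; the
# independent reference for the filter cascade and consensus merge.
oracle_cascade_keys <- function(calls, cfg, blacklists = list()) {
  keep <- logical(nrow(calls))
  for (i in seq_len(nrow(calls))) {
    r <- as.list(calls[i, ])
    ok <- TRUE
    if (r$total_support < cfg$min_total_support) ok <- FALSE
    if (r$split_reads < cfg$min_split_reads) ok <- FALSE
    if (cfg$drop_flagged_read_through && r$read_through) ok <- FALSE
    gap <- r$pos3 - r$pos5
    if (r$chrom5 == r$chrom3 && r$strand5 == r$strand3 &&
        r$strand5 %in% c("+", "-") && gap > 0 &&
        gap <= cfg$read_through_max_gap) ok <- FALSE
    for (b in blacklists) {
      if (any(b$pairs$gene5 == r$gene5 & b$pairs$gene3 == r$gene3)) ok <- FALSE
      if (r$gene5 %in% b$single_genes || r$gene3 %in% b$single_genes) ok <- FALSE
    }
    keep[i] <- ok
  }
  kept <- calls[keep, , drop = FALSE]
  out <- character()
  for (s in unique(kept$sample_id)) {
    sub <- kept[kept$sample_id == s, , drop = FALSE]
    pk <- paste(sub$gene5, sub$gene3, sep = "|")
    for (p in unique(pk)) {
      if (length(unique(sub$caller[pk == p])) >= cfg$min_callers) {
        out <- c(out, paste(s, p, sep = "|"))
      }
    }
  }
  sort(out)
}

consensus_keys <- function(cons) {
  sort(paste(cons$sample_id, cons$gene5, cons$gene3, sep = "|"))
}

# Random cohort catalog for tabulation properties.
rand_catalog <- function(n) {
  chrom5 <- sample(CHROMOSOMES, n, replace = TRUE)
  intra <- runif(n) < 0.5
  chrom3 <- ifelse(intra, chrom5, sample(CHROMOSOMES, n, replace = TRUE))
  tibble::tibble(
    gene5 = sprintf("U%04d", seq_len(n)), gene3 = sprintf("V%04d", seq_len(n)),
    chrom5 = chrom5, chrom3 = chrom3,
    n_samples = 1L + rpois(n, 0.7),
    known = runif(n) < 0.3,
    sources = "", recurrent = NA
  ) |>
    dplyr::mutate(recurrent = n_samples >= 2)
}

# Definitional Benjamini-Hochberg: adj(i) = min over k with p_(k) >= p_(i)
# of m * p_(k) / k, computed with explicit loops.
bh_oracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj_sorted <- numeric(m)
  for (i in seq_len(m)) {
    vals <- numeric(0)
    for (k in i:m) vals <- c(vals, m * p[ord[k]] / k)
    adj_sorted[i] <- min(1, min(vals))
  }
  out <- numeric(m)
  out[ord] <- adj_sorted
  out
}

# Permutation reference for the log-rank p-value.
perm_logrank_p <- function(times, events, group, B) {
  obs <- logrank_test(times, events, group)$statistic
  hits <- 0L
  for (b in seq_len(B)) {
    stat <- logrank_test(times, events, sample(group))$statistic
    if (stat >= obs - 1e-12) hits <- hits + 1L
  }
  hits / B
}

# Linear-interpolation quantile computed from first principles
# (h = (n - 1) p + 1 on the sorted sample).
interp_quantile <- function(x, p) {
  s <- sort(unname(x))
  h <- (length(s) - 1) * p + 1
  lo <- floor(h)
  hi <- ceiling(h)
  s[lo] + (h - lo) * (s[hi] - s[lo])
}
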