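# Seeded generator of a complete synthetic study bundle: per-caller fusion
# files in the three dialects, clinical table with event-free survival and
# WES-style covariates, a TPM-like expression matrix with an immune gene
# set, blacklist / known-fusion lists, and a machine-readable truth file.
#
# The generator plants every effect the pipeline is meant to recover:
# subtype-dependent negative-binomial fusion burden, caller-specific
# sensitivity, three artifact classes (read-through, blacklist hit,
# low-support), a burden-dependent proportional-hazards effect on EFS, and a
# downward immune-signature shift in high-burden samples. Blacklist genes
# are drawn from a reserved part of the gene universe that never hosts true
# fusions, and non-low-support true calls always satisfy the default support
# thresholds, so with sensitivity 1 and artifact rates 0 the pipeline
# recovers the planted burden exactly.

#' Synthetic cohort configuration
#'
#' Defaults describe an early-breast-cancer-like cohort: 300 samples with
#' IHC subtype mix 22.6/14.1/12.1/51.2% (HR+HER2-/HR+HER2+/HR-HER2+/TNBC),
#' per-subtype negative-binomial burden means 7/10/10/9 events, caller
#' sensitivities 0.90/0.85/0.75 (dialects A/B/C), a baseline exponential EFS
#' hazard of -log(0.8)/60 per month (5-year EFS 80% in the low-burden arm),
#' hazard ratio 3 for the high-burden arm, 20% independent uniform
#' censoring, and an immune signature shifted down by 1 log unit in
#' high-burden samples.
#'
#' @param n_samples Cohort size.
#' @param subtype_proportions Named proportions over the four IHC subtypes
#'   (must sum to 1).
#' @param burden_mean Named per-subtype negative-binomial means of the true
#'   fusion burden.
#' @param burden_dispersion Negative-binomial size (dispersion) parameter.
#' @param caller_sensitivity Named per-caller detection probabilities in
#'   `[0, 1]` for callers `A`, `B`, `C`.
#' @param artifact_rates Named expected per-sample counts of the artifact
#'   classes `read_through`, `blacklist`, `low_support`.
#' @param p_low_support_true Fraction of true fusions whose read support
#'   falls below the default support filter in every caller.
#' @param support_split_mean,support_split_size Negative-binomial model of
#'   split-read counts for well-supported calls (a floor guarantees
#'   `split >= 1` and `total >= 3`).
#' @param support_discordant_mean,support_discordant_size Same for
#'   discordant-pair counts.
#' @param survival_rate Baseline exponential event hazard per month.
#' @param hazard_ratio_high Hazard ratio of the high-burden arm.
#' @param censoring_fraction Expected fraction of censored samples.
#' @param burden_quantile Quantile used to split truth burden into
#'   high/low survival arms (default 0.6).
#' @param n_fusion_genes Size of the synthetic gene universe (the last 40
#'   genes are reserved for artifacts and blacklists).
#' @param n_recurrent_pool Size of the shared pool of pairs that recur
#'   across samples.
#' @param p_recurrent Probability a true fusion is drawn from the recurrent
#'   pool rather than invented privately.
#' @param n_genes,n_immune_genes Expression-matrix dimensions: background
#'   genes plus the immune set.
#' @param immune_shift Downward log-scale shift of in-set expression in
#'   high-burden samples.
#' @param seed Integer seed; every derived random stream flows from it.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(
    n_samples = 300L,
    subtype_proportions = c("HR+HER2-" = 0.226, "HR+HER2+" = 0.141,
                            "HR-HER2+" = 0.121, "TNBC" = 0.512),
    burden_mean = c("HR+HER2-" = 7, "HR+HER2+" = 10,
                    "HR-HER2+" = 10, "TNBC" = 9),
    burden_dispersion = 2.5,
    caller_sensitivity = c(A = 0.90, B = 0.85, C = 0.75),
    artifact_rates = c(read_through = 2, blacklist = 1.5, low_support = 2),
    p_low_support_true = 0.05,
    support_split_mean = 7, support_split_size = 2,
    support_discordant_mean = 4, support_discordant_size = 1.5,
    survival_rate = -log(0.8) / 60,
    hazard_ratio_high = 3,
    censoring_fraction = 0.2,
    burden_quantile = 0.6,
    n_fusion_genes = 400L,
    n_recurrent_pool = 30L,
    p_recurrent = 0.3,
    n_genes = 1000L,
    n_immune_genes = 50L,
    immune_shift = 1,
    seed = 1L) {
  stopifnot(
    n_samples >= 2,
    abs(sum(subtype_proportions) - 1) < 1e-8,
    identical(sort(names(subtype_proportions)), sort(names(burden_mean))),
    all(burden_mean >= 0), burden_dispersion > 0,
    identical(sort(names(caller_sensitivity)), c("A", "B", "C")),
    all(caller_sensitivity >= 0 & caller_sensitivity <= 1),
    identical(sort(names(artifact_rates)),
              sort(c("read_through", "blacklist", "low_support"))),
    all(artifact_rates >= 0),
    p_low_support_true >= 0, p_low_support_true <= 1,
    survival_rate > 0, hazard_ratio_high > 0,
    censoring_fraction >= 0, censoring_fraction < 1,
    burden_quantile > 0, burden_quantile < 1,
    n_fusion_genes >= 100, n_genes >= 10,
    n_immune_genes >= 2, n_immune_genes < n_genes,
    seed == as.integer(seed)
  )
  structure(as.list(environment()), class = "cohort_config")
}

#' @export
print.cohort_config <- function(x, ...) {
  cat(sprintf("<cohort_config: n = %d, HR(high burden) = %g, censoring %.0f%%, seed %d>\n",
              x$n_samples, x$hazard_ratio_high,
              100 * x$censoring_fraction, x$seed))
  invisible(x)
}

# Number of universe genes reserved for artifact/blacklist use only.
.n_reserved <- 40L

# Synthetic gene universe: symbols with chromosome, strand and position.
# Chromosome placement is skewed (extra weight on chr17, chr1, chr11, chr8)
# so that per-chromosome tabulations are non-uniform, echoing real fusion
# landscapes where chromosome 17 dominates.
generate_gene_universe <- function(n_genes) {
  w <- stats::setNames(rep(1, length(CHROMOSOMES)), CHROMOSOMES)
  w["chr17"] <- 3; w["chr1"] <- 2.5; w["chr11"] <- 2; w["chr8"] <- 1.5
  w["chrY"] <- 0.1
  tibble::tibble(
    gene = sprintf("FG%04d", seq_len(n_genes)),
    chrom = sample(CHROMOSOMES, n_genes, replace = TRUE, prob = w / sum(w)),
    strand = sample(c("+", "-"), n_genes, replace = TRUE),
    pos = sample.int(200000000L, n_genes, replace = TRUE)
  )
}

# Draw a true gene pair that can never look like a read-through (different
# chromosome, different strand, or far apart). `chrom`, `strand`, `pos` are
# named lookup vectors over the universe.
draw_true_pair <- function(genes, pool5, pool3, p_recurrent, taken,
                           chrom, strand, pos) {
  repeat {
    if (length(pool5) > 0 && stats::runif(1) < p_recurrent) {
      i <- sample.int(length(pool5), 1)
      g5 <- pool5[i]; g3 <- pool3[i]
    } else {
      idx <- sample.int(length(genes), 2)
      g5 <- genes[idx[1]]; g3 <- genes[idx[2]]
    }
    if (pair_key(g5, g3) %in% taken) next
    rt_like <- chrom[[g5]] == chrom[[g3]] && strand[[g5]] == strand[[g3]] &&
      (pos[[g3]] - pos[[g5]]) > 0 && (pos[[g3]] - pos[[g5]]) <= 60000
    if (!rt_like) return(c(g5, g3))
  }
}

# Well-supported read counts: split >= 1 and split + discordant >= 3.
draw_support <- function(n, config) {
  split <- 1L + stats::rnbinom(n, mu = config$support_split_mean - 1,
                               size = config$support_split_size)
  disc <- stats::rnbinom(n, mu = config$support_discordant_mean,
                         size = config$support_discordant_size)
  disc <- pmax(disc, pmax(0L, 3L - split))
  list(split = as.integer(split), disc = as.integer(disc))
}

#' Generate event-free survival under a planted burden effect
#'
#' Event times are exponential with hazard
#' `survival_rate * hazard_ratio_high^(group == "high")`; censoring times are
#' uniform on `(0, u)` with `u` solved numerically so the expected censoring
#' fraction matches the configuration. Observed time is the minimum, the
#' event indicator marks events observed before censoring.
#'
#' @param groups Named character vector, sample id -> `"high"`/`"low"`.
#' @param config A [cohort_config()] (uses its survival fields and seed).
#' @return A tibble: `sample_id`, `efs_months`, `efs_event`.
#' @export
generate_survival <- function(groups, config = cohort_config()) {
  groups <- as_named(groups, "groups")
  stopifnot(all(groups %in% c("high", "low")))
  run_seeded(derive_seed(config$seed, "survival"), {
    n <- length(groups)
    lambda <- config$survival_rate *
      ifelse(groups == "high", config$hazard_ratio_high, 1)
    t_event <- stats::rexp(n, rate = lambda)
    if (config$censoring_fraction <= 0) {
      efs <- t_event
      event <- rep(TRUE, n)
    } else {
      cens_prob <- function(u) mean((1 - exp(-lambda * u)) / (lambda * u))
      u <- stats::uniroot(function(u) cens_prob(u) - config$censoring_fraction,
                          lower = 1e-6, upper = 1e9, tol = 1e-8)$root
      t_cens <- stats::runif(n, 0, u)
      efs <- pmin(t_event, t_cens)
      event <- t_event <= t_cens
    }
    tibble::tibble(sample_id = names(groups),
                   efs_months = round(efs, 3),
                   efs_event = event)
  })
}

#' Generate an expression matrix with a planted immune-signature shift
#'
#' Log-normal TPM-like baseline (per-gene log-mean drawn once, log-sd 0.6);
#' in high-burden samples the immune-set genes are shifted down by
#' `immune_shift` log units.
#'
#' @inheritParams generate_survival
#' @return A list with `expr` (gene x sample matrix) and `gene_set`
#'   (character vector of immune-set symbols).
#' @export
generate_expression <- function(groups, config = cohort_config()) {
  groups <- as_named(groups, "groups")
  run_seeded(derive_seed(config$seed, "expression"), {
    n_bg <- config$n_genes - config$n_immune_genes
    genes <- c(sprintf("IMMG%04d", seq_len(config$n_immune_genes)),
               sprintf("BGRD%04d", seq_len(n_bg)))
    meanlog <- stats::rnorm(config$n_genes, mean = 1.5, sd = 1)
    n <- length(groups)
    expr <- matrix(stats::rlnorm(config$n_genes * n,
                                 meanlog = rep(meanlog, times = n),
                                 sdlog = 0.6),
                   nrow = config$n_genes, ncol = n,
                   dimnames = list(genes, names(groups)))
    high <- groups == "high"
    if (any(high) && config$immune_shift != 0) {
      expr[seq_len(config$n_immune_genes), high] <-
        expr[seq_len(config$n_immune_genes), high] * exp(-config$immune_shift)
    }
    list(expr = expr, gene_set = genes[seq_len(config$n_immune_genes)])
  })
}

# Conditional intrinsic-subtype probabilities given IHC subtype.
.intrinsic_probs <- rbind(
  "HR+HER2-" = c(LumA = 0.55, LumB = 0.30, HER2E = 0.03, Basal = 0.02, Normal = 0.10),
  "HR+HER2+" = c(LumA = 0.10, LumB = 0.40, HER2E = 0.40, Basal = 0.05, Normal = 0.05),
  "HR-HER2+" = c(LumA = 0.02, LumB = 0.05, HER2E = 0.75, Basal = 0.15, Normal = 0.03),
  "TNBC"     = c(LumA = 0.02, LumB = 0.02, HER2E = 0.07, Basal = 0.85, Normal = 0.04)
)

#' Generate a full synthetic study bundle
#'
#' Draws the whole cohort (gene universe, clinical table, true fusions,
#' caller calls with artifacts, survival, covariates, expression) from
#' `config$seed`. Identical configurations produce byte-identical bundles.
#' If `dir` is given, writes: `clinical.csv`, `expression.tsv`,
#' `immune_gene_set.txt`, `known_fusions.tsv`, `blacklist_pairs.tsv`,
#' `blacklist_genes.tsv`, `truth.json`, and per-sample caller files
#' `calls/<sample>.<caller>.tsv` in the three dialects.
#'
#' @param config A [cohort_config()].
#' @param dir Optional output directory for the file bundle.
#' @return A list with `config`, `clinical` (tibble incl. survival and
#'   covariates), `calls` (normalized fusion-call tibble over all callers),
#'   `truth` (list: per-sample true pairs, burden, group, artifact counts,
#'   survival parameters), `expression`, `gene_set`, `known_db`,
#'   `blacklists`, `universe`, and `dir`.
#' @export
generate_cohort <- function(config = cohort_config(), dir = NULL) {
  stopifnot(inherits(config, "cohort_config"))
  bundle <- run_seeded(derive_seed(config$seed, "cohort"), {
    universe <- generate_gene_universe(config$n_fusion_genes)
    n_true_genes <- config$n_fusion_genes - .n_reserved
    true_universe <- universe[seq_len(n_true_genes), ]
    reserved <- universe$gene[(n_true_genes + 1):config$n_fusion_genes]

    # shared recurrent pool and annotation lists
    pool_idx <- matrix(sample.int(n_true_genes, 2 * config$n_recurrent_pool,
                                  replace = TRUE),
                       ncol = 2)
    pool_idx <- pool_idx[pool_idx[, 1] != pool_idx[, 2], , drop = FALSE]
    pool <- tibble::tibble(gene5 = true_universe$gene[pool_idx[, 1]],
                           gene3 = true_universe$gene[pool_idx[, 2]])
    pool <- pool[!duplicated(pair_key(pool$gene5, pool$gene3)), ]
    n_known_pool <- min(20L, nrow(pool))
    known_extra_idx <- matrix(sample.int(n_true_genes, 40, replace = TRUE),
                              ncol = 2)
    known_pairs <- rbind(
      pool[sample.int(nrow(pool), n_known_pool), ],
      tibble::tibble(gene5 = true_universe$gene[known_extra_idx[, 1]],
                     gene3 = true_universe$gene[known_extra_idx[, 2]])
    )
    known_pairs <- known_pairs[known_pairs$gene5 != known_pairs$gene3, ]
    known_db <- gene_pair_list("synthetic_known_db", pairs = known_pairs)

    bl_idx <- matrix(sample(reserved, 30, replace = TRUE), ncol = 2)
    bl_pairs <- tibble::tibble(gene5 = bl_idx[, 1], gene3 = bl_idx[, 2])
    bl_pairs <- bl_pairs[bl_pairs$gene5 != bl_pairs$gene3, ]
    bl_genes <- sample(reserved, 5)
    blacklists <- list(
      gene_pair_list("synthetic_blacklist_pairs", pairs = bl_pairs),
      gene_pair_list("synthetic_blacklist_genes", single_genes = bl_genes)
    )

    # clinical frame
    sample_ids <- sprintf("SMP%04d", seq_len(config$n_samples))
    subtypes <- names(config$subtype_proportions)
    subtype <- sample(subtypes, config$n_samples, replace = TRUE,
                      prob = config$subtype_proportions)
    intrinsic <- vapply(subtype, function(s) {
      sample(colnames(.intrinsic_probs), 1, prob = .intrinsic_probs[s, ])
    }, "")

    burden_true <- stats::rnbinom(config$n_samples,
                                  mu = config$burden_mean[subtype],
                                  size = config$burden_dispersion)
    names(burden_true) <- sample_ids

    # per-sample true pairs
    uni_pos <- stats::setNames(universe$pos, universe$gene)
    uni_chrom <- stats::setNames(universe$chrom, universe$gene)
    uni_strand <- stats::setNames(universe$strand, universe$gene)
    true_pairs <- vector("list", config$n_samples)
    names(true_pairs) <- sample_ids
    for (i in seq_len(config$n_samples)) {
      taken <- character()
      g5s <- g3s <- character(burden_true[i])
      for (k in seq_len(burden_true[i])) {
        p <- draw_true_pair(true_universe$gene, pool$gene5, pool$gene3,
                            config$p_recurrent, taken,
                            uni_chrom, uni_strand, uni_pos)
        taken <- c(taken, pair_key(p[1], p[2]))
        g5s[k] <- p[1]; g3s[k] <- p[2]
      }
      true_pairs[[i]] <- tibble::tibble(gene5 = g5s, gene3 = g3s)
    }

    dq <- dichotomize_quantile(
      stats::setNames(as.numeric(burden_true), sample_ids),
      config$burden_quantile)
    groups <- dq$groups

    # covariates: mildly burden-associated WES-style scores
    high <- groups == "high"
    hrd <- round(stats::rlnorm(config$n_samples,
                               meanlog = log(20) + 0.35 * high, sdlog = 0.5), 2)
    tmb <- round(stats::rlnorm(config$n_samples,
                               meanlog = log(60) + 0.30 * high, sdlog = 0.6), 2)
    cnv <- round(stats::rlnorm(config$n_samples,
                               meanlog = log(0.25) + 0.30 * high, sdlog = 0.5), 4)

    # caller calls: accumulate plain column vectors, build one tibble at the end
    callers <- c("A", "B", "C")
    sens <- config$caller_sensitivity[callers]
    acc <- new.env(parent = emptyenv())
    acc$rows <- vector("list", 4096)
    acc$n <- 0L
    push <- function(sid, caller, g5, g3, split, disc, rt,
                     chrom5, pos5, strand5, chrom3, pos3, strand3) {
      acc$n <- acc$n + 1L
      if (acc$n > length(acc$rows)) length(acc$rows) <- 2L * length(acc$rows)
      acc$rows[[acc$n]] <- list(sid, caller, g5, chrom5, as.integer(pos5),
                                strand5, g3, chrom3, as.integer(pos3),
                                strand3, as.integer(split), as.integer(disc),
                                rt)
    }
    art_counts <- matrix(0L, nrow = config$n_samples, ncol = 3,
                         dimnames = list(sample_ids,
                                         c("read_through", "blacklist",
                                           "low_support")))
    bl_pair_keys <- pair_key(bl_pairs$gene5, bl_pairs$gene3)
    for (i in seq_len(config$n_samples)) {
      sid <- sample_ids[i]
      tp <- true_pairs[[i]]
      n_tp <- nrow(tp)
      low_support <- if (n_tp > 0)
        stats::runif(n_tp) < config$p_low_support_true else logical()

      for (cl in callers) {
        # true calls seen by this caller
        if (n_tp > 0) {
          seen <- stats::runif(n_tp) < sens[cl]
          if (any(seen)) {
            ns <- sum(seen)
            sup <- draw_support(ns, config)
            if (any(low_support[seen])) {
              ls <- low_support[seen]
              sup$split[ls] <- stats::rbinom(sum(ls), 1, 0.5)
              sup$disc[ls] <- sample(0:1, sum(ls), replace = TRUE)
            }
            g5 <- tp$gene5[seen]; g3 <- tp$gene3[seen]
            push(rep(sid, ns), rep(cl, ns), g5, g3, sup$split, sup$disc,
                 rep(FALSE, ns),
                 unname(uni_chrom[g5]),
                 unname(uni_pos[g5]) + sample.int(1000L, ns, replace = TRUE),
                 unname(uni_strand[g5]),
                 unname(uni_chrom[g3]),
                 unname(uni_pos[g3]) + sample.int(1000L, ns, replace = TRUE),
                 unname(uni_strand[g3]))
          }
        }
      }

      # read-through artifacts (shared across callers, per-caller detection)
      n_rt <- stats::rpois(1, config$artifact_rates[["read_through"]])
      art_counts[i, "read_through"] <- n_rt
      for (k in seq_len(n_rt)) {
        g <- sample(reserved, 2)
        chrom <- sample(CHROMOSOMES[1:22], 1)
        strand <- sample(c("+", "-"), 1)
        pos5 <- sample.int(150000000L, 1) + 1000000L
        pos3 <- pos5 + sample(1000:45000, 1)
        flagged <- stats::runif(1) < 0.7
        for (cl in callers) {
          if (stats::runif(1) < sens[cl]) {
            sup <- draw_support(1, config)
            push(sid, cl, g[1], g[2], sup$split, sup$disc, flagged,
                 chrom, pos5, strand, chrom, pos3, strand)
          }
        }
      }

      # blacklist-hit artifacts
      n_bl <- stats::rpois(1, config$artifact_rates[["blacklist"]])
      art_counts[i, "blacklist"] <- n_bl
      for (k in seq_len(n_bl)) {
        if (nrow(bl_pairs) > 0 && stats::runif(1) < 0.7) {
          j <- sample.int(nrow(bl_pairs), 1)
          g5 <- bl_pairs$gene5[j]; g3 <- bl_pairs$gene3[j]
        } else {
          g5 <- sample(bl_genes, 1); g3 <- sample(reserved, 1)
        }
        chroms <- sample(CHROMOSOMES[1:22], 2)
        for (cl in callers) {
          if (stats::runif(1) < sens[cl]) {
            sup <- draw_support(1, config)
            push(sid, cl, g5, g3, sup$split, sup$disc, FALSE,
                 chroms[1], sample.int(200000000L, 1), sample(c("+", "-"), 1),
                 chroms[2], sample.int(200000000L, 1), sample(c("+", "-"), 1))
          }
        }
      }

      # low-support artifacts
      n_ls <- stats::rpois(1, config$artifact_rates[["low_support"]])
      art_counts[i, "low_support"] <- n_ls
      for (k in seq_len(n_ls)) {
        repeat {
          g <- sample(reserved, 2)
          if (!pair_key(g[1], g[2]) %in% bl_pair_keys &&
              !any(g %in% bl_genes)) break
        }
        chroms <- sample(CHROMOSOMES[1:22], 2)
        split <- stats::rbinom(1, 1, 0.5)
        disc <- sample(0:1, 1)
        for (cl in callers) {
          if (stats::runif(1) < sens[cl]) {
            push(sid, cl, g[1], g[2], split, disc, FALSE,
                 chroms[1], sample.int(200000000L, 1), sample(c("+", "-"), 1),
                 chroms[2], sample.int(200000000L, 1), sample(c("+", "-"), 1))
          }
        }
      }
    }
    chunks <- acc$rows[seq_len(acc$n)]
    col <- function(j) unlist(lapply(chunks, `[[`, j), use.names = FALSE)
    calls <- tibble::tibble(
      sample_id = col(1), caller = col(2),
      gene5 = col(3), chrom5 = col(4), pos5 = col(5), strand5 = col(6),
      gene3 = col(7), chrom3 = col(8), pos3 = col(9), strand3 = col(10),
      split_reads = col(11), discordant_pairs = col(12),
      read_through = col(13)
    )
    calls$total_support <- calls$split_reads + calls$discordant_pairs
    calls <- calls[, c("sample_id", "caller", "gene5", "chrom5", "pos5",
                       "strand5", "gene3", "chrom3", "pos3", "strand3",
                       "split_reads", "discordant_pairs", "total_support",
                       "read_through")]
    validate_fusion_calls(calls)

    list(universe = universe, pool = pool, known_db = known_db,
         blacklists = blacklists, sample_ids = sample_ids,
         subtype = subtype, intrinsic = intrinsic,
         burden_true = burden_true, true_pairs = true_pairs,
         groups = groups, threshold = dq$threshold,
         hrd = hrd, tmb = tmb, cnv = cnv,
         calls = calls, art_counts = art_counts)
  })

  surv <- generate_survival(bundle$groups, config)
  expr <- generate_expression(bundle$groups, config)

  clinical <- tibble::tibble(
    sample_id = bundle$sample_ids,
    subtype = bundle$subtype,
    intrinsic = bundle$intrinsic,
    efs_months = surv$efs_months[match(bundle$sample_ids, surv$sample_id)],
    efs_event = surv$efs_event[match(bundle$sample_ids, surv$sample_id)],
    hrd = bundle$hrd, tmb = bundle$tmb, cnv_burden = bundle$cnv
  )

  truth <- list(
    seed = config$seed,
    burden = as.list(bundle$burden_true),
    group = as.list(bundle$groups),
    burden_threshold = bundle$threshold,
    true_pairs = lapply(bundle$true_pairs,
                        function(p) paste(p$gene5, p$gene3, sep = "--")),
    artifact_counts = lapply(seq_along(bundle$sample_ids), function(i)
      as.list(bundle$art_counts[i, ])),
    survival = list(rate = config$survival_rate,
                    hazard_ratio_high = config$hazard_ratio_high,
                    censoring_fraction = config$censoring_fraction)
  )
  names(truth$artifact_counts) <- bundle$sample_ids

  out <- list(config = config, clinical = clinical, calls = bundle$calls,
              truth = truth, expression = expr$expr, gene_set = expr$gene_set,
              known_db = bundle$known_db, blacklists = bundle$blacklists,
              universe = bundle$universe, dir = dir)

  if (!is.null(dir)) write_cohort_bundle(out, dir)
  out
}

# Write the bundle files; called by generate_cohort(dir = ...).
write_cohort_bundle <- function(bundle, dir) {
  dir.create(file.path(dir, "calls"), recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(bundle$clinical, file.path(dir, "clinical.csv"),
                   progress = FALSE)
  expr_df <- tibble::as_tibble(round(bundle$expression, 4), rownames = "gene")
  readr::write_tsv(expr_df, file.path(dir, "expression.tsv"), progress = FALSE)
  writeLines(bundle$gene_set, file.path(dir, "immune_gene_set.txt"))
  readr::write_tsv(bundle$known_db$pairs, file.path(dir, "known_fusions.tsv"),
                   col_names = FALSE, progress = FALSE)
  readr::write_tsv(bundle$blacklists[[1]]$pairs,
                   file.path(dir, "blacklist_pairs.tsv"),
                   col_names = FALSE, progress = FALSE)
  writeLines(bundle$blacklists[[2]]$single_genes,
             file.path(dir, "blacklist_genes.tsv"))
  jsonlite::write_json(bundle$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = 10, pretty = TRUE)
  for (sid in unique(bundle$clinical$sample_id)) {
    for (cl in c("A", "B", "C")) {
      sub <- bundle$calls[bundle$calls$sample_id == sid &
                            bundle$calls$caller == cl, , drop = FALSE]
      write_dialect_file(sub, cl,
                         file.path(dir, "calls",
                                   sprintf("%s.%s.tsv", sid, cl)))
    }
  }
  invisible(dir)
}

#' Read a written cohort bundle's caller files back into one call table
#'
#' Re-imports every `calls/<sample>.<caller>.tsv` file of a bundle directory
#' through [read_caller_table()].
#'
#' @param dir Bundle directory written by [generate_cohort()].
#' @return A normalized fusion-call tibble over all samples and callers.
#' @export
read_cohort_calls <- function(dir) {
  files <- list.files(file.path(dir, "calls"), pattern = "\\.tsv$",
                      full.names = TRUE)
  parts <- lapply(files, function(f) {
    base <- sub("\\.tsv$", "", basename(f))
    caller <- sub("^.*\\.", "", base)
    sid <- sub("\\.[ABC]$", "", base)
    read_caller_table(f, caller, sid)
  })
  dplyr::bind_rows(parts)
}
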