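mk_call <- function(split = 3, disc = 0, chrom5 = "chr1", chrom3 = "chr2",
                    strand5 = "+", strand3 = "+", pos5 = 1000L, pos3 = 2000L,
                    rt = FALSE, g5 = "AAA", g3 = "BBB", sample = "S01",
                    caller = "A") {
  tibble::tibble(sample_id = sample, caller = caller,
                 gene5 = g5, chrom5 = chrom5, pos5 = pos5, strand5 = strand5,
                 gene3 = g3, chrom3 = chrom3, pos3 = pos3, strand3 = strand3,
                 split_reads = as.integer(split),
                 discordant_pairs = as.integer(disc),
                 total_support = as.integer(split + disc),
                 read_through = rt)
}

test_that("support filter removes split-less and weakly supported calls", {
  cfg <- filter_config()
  expect_equal(nrow(filter_support(mk_call(split = 0, disc = 5), cfg)), 0)
  expect_equal(nrow(filter_support(mk_call(split = 3, disc = 0), cfg)), 1)
  expect_equal(nrow(filter_support(mk_call(split = 1, disc = 1), cfg)), 0)
  # brute-force predicate scan on random calls
  set.seed(201)
  calls <- rand_calls(200)
  got <- filter_support(calls, cfg)
  want <- calls[sapply(seq_len(nrow(calls)), function(i)
    calls$total_support[i] >= 3 && calls$split_reads[i] >= 1), ]
  expect_equal(as.data.frame(got), as.data.frame(want))
})

test_that("read-through filter removes flagged and within-gap same-strand calls", {
  cfg <- filter_config()
  expect_equal(nrow(filter_read_through(mk_call(rt = TRUE), cfg)), 0)
  expect_equal(nrow(filter_read_through(mk_call(chrom5 = "chr1", chrom3 = "chr2"), cfg)), 1)
  # planted truth table: 100 calls, 12 known read-throughs
  set.seed(202)
  calls <- rand_calls(100, p_flag = 0)
  # force every call interchromosomal first, then plant the artifacts
  calls$chrom3 <- CHROMOSOMES[match(calls$chrom5, CHROMOSOMES) %% 24 + 1]
  idx <- sample(100, 12)
  flagged <- idx[1:5]
  nearby <- idx[6:12]
  calls$read_through[flagged] <- TRUE
  calls$chrom3[nearby] <- calls$chrom5[nearby]
  calls$strand5[nearby] <- "+"
  calls$strand3[nearby] <- "+"
  calls$pos3[nearby] <- calls$pos5[nearby] + sample(1:50000, 7)
  got <- filter_read_through(calls, cfg)
  expect_equal(nrow(got), 88)
  expect_true(all(!got$read_through))
  expect_equal(as.data.frame(got), as.data.frame(calls[-sort(idx), ]))
})

test_that("blacklist filter matches ordered pairs and single genes", {
  bl <- list(gene_pair_list("b1", pairs = tibble::tibble(gene5 = "AAA", gene3 = "BBB")),
             gene_pair_list("b2", single_genes = "ZZZ"))
  expect_equal(nrow(filter_blacklist(mk_call(), bl)), 0)
  # reversed order is a different pair
  expect_equal(nrow(filter_blacklist(mk_call(g5 = "BBB", g3 = "AAA"), bl)), 1)
  expect_equal(nrow(filter_blacklist(mk_call(g3 = "ZZZ"), bl)), 0)
  # empty blacklist set is the identity
  set.seed(203)
  calls <- rand_calls(50)
  expect_equal(as.data.frame(filter_blacklist(calls, list())),
               as.data.frame(calls))
  # set-membership oracle on random lists
  lists <- list(
    gene_pair_list("r1", pairs = tibble::tibble(
      gene5 = sample(sprintf("G%02d", 1:15), 8, TRUE),
      gene3 = sample(sprintf("G%02d", 1:15), 8, TRUE))),
    gene_pair_list("r2", single_genes = sample(sprintf("G%02d", 1:15), 2))
  )
  got <- filter_blacklist(calls, lists)
  keep <- sapply(seq_len(nrow(calls)), function(i) {
    r <- calls[i, ]
    !any(lists[[1]]$pairs$gene5 == r$gene5 & lists[[1]]$pairs$gene3 == r$gene3) &&
      !(r$gene5 %in% lists[[2]]$single_genes) &&
      !(r$gene3 %in% lists[[2]]$single_genes)
  })
  expect_equal(as.data.frame(got), as.data.frame(calls[keep, ]))
})

test_that("consensus keeps pairs seen by enough callers with max support", {
  cfg <- filter_config()
  two <- dplyr::bind_rows(mk_call(split = 5, disc = 2, caller = "A"),
                          mk_call(split = 3, disc = 6, caller = "B"))
  got <- consensus_merge(two, cfg)
  expect_equal(nrow(got), 1)
  expect_equal(got$callers, "A,B")
  expect_equal(got$split_reads, 5)
  expect_equal(got$total_support, 9)
  expect_false(got$intrachromosomal)
  # single-caller pair is dropped
  expect_equal(nrow(consensus_merge(mk_call(caller = "C"), cfg)), 0)
  # duplicate (sample, caller, pair) rows collapse to one
  dup <- dplyr::bind_rows(mk_call(split = 2, caller = "A", pos5 = 10L),
                          mk_call(split = 9, caller = "A", pos5 = 99L),
                          mk_call(split = 4, caller = "B"))
  gd <- consensus_merge(dup, cfg)
  expect_equal(nrow(gd), 1)
  expect_equal(gd$split_reads, 9)
})

test_that("the per-call filters are order-independent pure predicates", {
  set.seed(204)
  cfg <- filter_config()
  bl <- list(gene_pair_list("b", pairs = tibble::tibble(
    gene5 = sprintf("G%02d", 1:3), gene3 = sprintf("G%02d", 4:6))))
  filters <- list(
    function(x) filter_support(x, cfg),
    function(x) filter_read_through(x, cfg),
    function(x) filter_blacklist(x, bl)
  )
  orders <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1),
                 c(3, 1, 2), c(3, 2, 1))
  for (rep in 1:100) {
    calls <- rand_calls(25)
    results <- lapply(orders, function(o) {
      out <- calls
      for (f in filters[o]) out <- f(out)
      out[order(out$sample_id, out$caller, out$gene5, out$gene3, out$pos5), ]
    })
    for (k in 2:6) {
      expect_equal(as.data.frame(results[[k]]), as.data.frame(results[[1]]))
    }
  }
})

test_that("cascade with no thresholds and one caller is the identity on events", {
  set.seed(205)
  cfg <- filter_config(min_total_support = 0, min_split_reads = 0,
                       min_callers = 1, read_through_max_gap = 0,
                       drop_flagged_read_through = FALSE)
  calls <- rand_calls(80)
  cons <- filter_cascade(calls, cfg, list())
  want <- unique(paste(calls$sample_id, calls$gene5, calls$gene3, sep = "|"))
  expect_setequal(consensus_keys(cons), want)
})

test_that("cascade plus consensus equals the brute-force enumeration", {
  set.seed(206)
  cfg <- filter_config()
  bl <- list(gene_pair_list("b", pairs = tibble::tibble(
    gene5 = sprintf("G%02d", c(2, 7)), gene3 = sprintf("G%02d", c(9, 1)))),
    gene_pair_list("g", single_genes = "G05"))
  for (rep in 1:50) {
    calls <- rand_calls(sample(10:60, 1), n_samples = sample(1:5, 1))
    cons <- filter_cascade(calls, cfg, bl)
    expect_identical(consensus_keys(cons), oracle_cascade_keys(calls, cfg, bl))
  }
})

test_that("burden counts distinct ordered pairs and fills absent samples with zero", {
  calls <- dplyr::bind_rows(
    mk_call(g5 = "X", g3 = "Y", caller = "A"),
    mk_call(g5 = "X", g3 = "Y", caller = "B"),
    mk_call(g5 = "Y", g3 = "X", caller = "A"),
    mk_call(g5 = "Y", g3 = "X", caller = "C")
  )
  cons <- consensus_merge(calls, filter_config())
  burden <- per_sample_burden(cons, samples = c("S01", "S99"))
  expect_equal(unname(burden["S01"]), 2)  # X-Y and Y-X are distinct events
  expect_equal(unname(burden["S99"]), 0)
  expect_equal(sum(burden), nrow(cons))  # burden map sums to total events
})
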