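# Per-call filter cascade and two-of-three caller consensus.
#
# The cascade mirrors common practice for RNA-seq fusion curation: drop calls
# with weak read support (total < 3 or no split reads), drop read-through
# transcripts, drop blacklisted gene pairs/genes, then keep only gene pairs
# predicted by at least two of the three callers within a sample. The three
# per-call filters are pure row predicates and commute; consensus must come
# last.

#' Filter configuration
#'
#' @param min_total_support Minimum `split_reads + discordant_pairs` for a
#'   call to survive (default 3, i.e. calls with fewer than three supporting
#'   reads are removed).
#' @param min_split_reads Minimum junction-spanning reads (default 1: calls
#'   without any split reads are removed).
#' @param min_callers Number of distinct callers that must predict a gene
#'   pair within a sample (default 2 of 3).
#' @param read_through_max_gap Fallback read-through heuristic: unflagged
#'   same-chromosome, same-strand calls whose 3' breakpoint lies within this
#'   many bp downstream of the 5' breakpoint are treated as read-throughs
#'   (default 50 kb; 0 disables the heuristic).
#' @param drop_flagged_read_through Drop calls the caller itself flagged as
#'   read-through (default `TRUE`).
#' @return An object of class `filter_config`.
#' @export
filter_config <- function(min_total_support = 3L, min_split_reads = 1L,
                          min_callers = 2L, read_through_max_gap = 50000L,
                          drop_flagged_read_through = TRUE) {
  stopifnot(min_total_support >= 0, min_split_reads >= 0,
            min_callers >= 1, min_callers <= 3,
            read_through_max_gap >= 0,
            is.logical(drop_flagged_read_through))
  structure(list(min_total_support = as.integer(min_total_support),
                 min_split_reads = as.integer(min_split_reads),
                 min_callers = as.integer(min_callers),
                 read_through_max_gap = as.integer(read_through_max_gap),
                 drop_flagged_read_through = drop_flagged_read_through),
            class = "filter_config")
}

#' @export
print.filter_config <- function(x, ...) {
  cat(sprintf(paste0("<filter_config: total support >= %d, split reads >= %d, ",
                     "callers >= %d, read-through gap <= %d bp, drop flagged: %s>\n"),
              x$min_total_support, x$min_split_reads, x$min_callers,
              x$read_through_max_gap, x$drop_flagged_read_through))
  invisible(x)
}

#' Remove weakly supported calls
#'
#' Keeps exactly the calls with `total_support >= min_total_support` and
#' `split_reads >= min_split_reads`.
#'
#' @param calls Normalized fusion-call tibble.
#' @param cfg A [filter_config()].
#' @return The surviving calls.
#' @export
filter_support <- function(calls, cfg = filter_config()) {
  validate_fusion_calls(calls)
  calls[calls$total_support >= cfg$min_total_support &
          calls$split_reads >= cfg$min_split_reads, , drop = FALSE]
}

#' Remove read-through artifacts
#'
#' Drops calls flagged as read-through by their caller (when
#' `drop_flagged_read_through` is set) and, as a fallback for callers that do
#' not flag them, unflagged calls that look like transcription read-through:
#' same chromosome, same known strand, with
#' `0 < pos3 - pos5 <= read_through_max_gap`.
#'
#' @inheritParams filter_support
#' @return The surviving calls.
#' @export
filter_read_through <- function(calls, cfg = filter_config()) {
  validate_fusion_calls(calls)
  flagged <- if (cfg$drop_flagged_read_through) calls$read_through else FALSE
  gap <- calls$pos3 - calls$pos5
  heuristic <- calls$chrom5 == calls$chrom3 &
    calls$strand5 == calls$strand3 & calls$strand5 %in% c("+", "-") &
    gap > 0 & gap <= cfg$read_through_max_gap
  calls[!(flagged | heuristic), , drop = FALSE]
}

#' Remove blacklisted fusions
#'
#' Drops calls whose ordered `(gene5, gene3)` pair appears in any list's
#' pairs, or either of whose genes appears in any list's single-gene set
#' (healthy-tissue and homology "red herring" lists).
#'
#' @param calls Normalized fusion-call tibble.
#' @param blacklists A `gene_pair_list` or list of them.
#' @return The surviving calls.
#' @export
filter_blacklist <- function(calls, blacklists) {
  validate_fusion_calls(calls)
  if (inherits(blacklists, "gene_pair_list")) blacklists <- list(blacklists)
  bad_pairs <- unlist(lapply(blacklists,
                             function(b) pair_key(b$pairs$gene5, b$pairs$gene3)))
  bad_genes <- unlist(lapply(blacklists, function(b) b$single_genes))
  hit <- pair_key(calls$gene5, calls$gene3) %in% bad_pairs |
    calls$gene5 %in% bad_genes | calls$gene3 %in% bad_genes
  calls[!hit, , drop = FALSE]
}

#' Merge calls across callers into consensus fusions
#'
#' Within each sample, calls are grouped by ordered `(gene5, gene3)` pair;
#' breakpoint coordinates are deliberately ignored because callers disagree
#' on exact junctions. Groups predicted by at least `min_callers` distinct
#' callers become one consensus fusion whose read support is the per-field
#' maximum across callers (max, not sum, so reads seen by several callers
#' are not double-counted). Duplicate `(sample, caller, pair)` rows (isoform
#' breakpoints) collapse to the per-caller maximum first.
#'
#' @inheritParams filter_support
#' @return A tibble of consensus fusions with columns `sample_id`, `gene5`,
#'   `gene3`, `chrom5`, `chrom3`, `callers` (comma-joined sorted caller set),
#'   `n_callers`, `split_reads`, `total_support`, `intrachromosomal`.
#' @export
consensus_merge <- function(calls, cfg = filter_config()) {
  validate_fusion_calls(calls)
  out <- calls |>
    dplyr::group_by(.data$sample_id, .data$gene5, .data$gene3) |>
    dplyr::summarise(
      chrom5 = .data$chrom5[1],
      chrom3 = .data$chrom3[1],
      callers = paste(sort(unique(.data$caller)), collapse = ","),
      n_callers = dplyr::n_distinct(.data$caller),
      split_reads = max(.data$split_reads),
      total_support = max(.data$total_support),
      .groups = "drop"
    ) |>
    dplyr::filter(.data$n_callers >= cfg$min_callers) |>
    dplyr::mutate(intrachromosomal = .data$chrom5 == .data$chrom3) |>
    dplyr::arrange(.data$sample_id, .data$gene5, .data$gene3)
  out
}

#' Run the full filter cascade
#'
#' Convenience wrapper applying support, read-through and blacklist filters
#' followed by caller consensus, in that order.
#'
#' @inheritParams filter_support
#' @param blacklists A list of `gene_pair_list` objects (possibly empty).
#' @return Consensus fusions (see [consensus_merge()]).
#' @export
filter_cascade <- function(calls, cfg = filter_config(), blacklists = list()) {
  calls |>
    filter_support(cfg) |>
    filter_read_through(cfg) |>
    filter_blacklist(blacklists) |>
    consensus_merge(cfg)
}

#' Per-sample fusion burden
#'
#' Fusion burden is the number of distinct ordered `(gene5, gene3)` events
#' per sample after filtering and consensus. Samples listed in `samples` but
#' carrying no surviving fusion are reported with burden 0.
#'
#' @param fusions Consensus fusion tibble from [consensus_merge()].
#' @param samples Optional character vector of all cohort sample ids.
#' @return A named integer vector, sample id -> burden.
#' @export
per_sample_burden <- function(fusions, samples = NULL) {
  key <- pair_key(fusions$gene5, fusions$gene3)
  uniq <- !duplicated(paste(fusions$sample_id, key, sep = "\r"))
  counts <- table(fusions$sample_id[uniq])
  if (is.null(samples)) samples <- sort(names(counts))
  burden <- stats::setNames(integer(length(samples)), samples)
  present <- intersect(names(counts), samples)
  burden[present] <- as.integer(counts[present])
  burden
}
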