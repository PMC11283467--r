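# Cohort-level fusion catalog: known/unknown annotation, private/recurrent
# classification, the 2x2 classification table, and the per-chromosome
# inter/intra distribution in which each fusion is counted twice (once for
# the 5' gene's chromosome, once for the 3' gene's).

#' Build the cohort fusion catalog
#'
#' Deduplicates consensus fusions to unique ordered `(gene5, gene3)` pairs,
#' counts the distinct samples carrying each pair, annotates pairs found in
#' any known-fusion database list (exact ordered-pair symbol match; no alias
#' resolution), and classifies pairs as recurrent when carried by at least
#' `recurrent_min` samples.
#'
#' @param fusions Consensus fusion tibble (see [consensus_merge()]).
#' @param known_dbs List of `gene_pair_list` objects of known fusions
#'   (e.g. Mitelman/COSMIC/ChimerDB-style pair lists); may be empty.
#' @param recurrent_min Minimum carrying-sample count for "recurrent"
#'   (default 2).
#' @return A tibble with one row per unique pair: `gene5`, `gene3`, `chrom5`,
#'   `chrom3`, `n_samples`, `known`, `sources` (comma-joined DB tags),
#'   `recurrent`.
#' @export
build_catalog <- function(fusions, known_dbs = list(), recurrent_min = 2L) {
  if (inherits(known_dbs, "gene_pair_list")) known_dbs <- list(known_dbs)
  cat <- fusions |>
    dplyr::group_by(.data$gene5, .data$gene3) |>
    dplyr::summarise(
      chrom5 = .data$chrom5[1],
      chrom3 = .data$chrom3[1],
      n_samples = dplyr::n_distinct(.data$sample_id),
      .groups = "drop"
    )
  keys <- pair_key(cat$gene5, cat$gene3)
  sources <- rep("", length(keys))
  for (db in known_dbs) {
    hit <- keys %in% pair_key(db$pairs$gene5, db$pairs$gene3)
    sources[hit] <- ifelse(nzchar(sources[hit]),
                           paste(sources[hit], db$name, sep = ","), db$name)
  }
  cat$known <- nzchar(sources)
  cat$sources <- sources
  cat$recurrent <- cat$n_samples >= recurrent_min
  dplyr::arrange(cat, .data$gene5, .data$gene3)
}

#' Private/recurrent x unknown/known classification table
#'
#' Cross-tabulates the unique fusions of a catalog by occurrence (private =
#' one carrying sample, recurrent = several) and annotation (unknown/known),
#' with percentages of the grand total rounded half-up to one decimal, plus
#' row and column margins.
#'
#' @param catalog Catalog tibble from [build_catalog()].
#' @return An object of class `classification_table`: list with `counts` and
#'   `percentages` (2x2 matrices, rows `private`/`recurrent`, columns
#'   `unknown`/`known`), `row_totals`, `col_totals`, `row_pct`, `col_pct`,
#'   and `total`.
#' @export
classification_table <- function(catalog) {
  occurrence <- factor(ifelse(catalog$recurrent, "recurrent", "private"),
                       levels = c("private", "recurrent"))
  annotation <- factor(ifelse(catalog$known, "known", "unknown"),
                       levels = c("unknown", "known"))
  counts <- table(occurrence, annotation)
  counts <- matrix(as.integer(counts), nrow = 2,
                   dimnames = list(occurrence = c("private", "recurrent"),
                                   annotation = c("unknown", "known")))
  total <- sum(counts)
  pct <- if (total > 0) round_half_up(100 * counts / total, 1) else counts * 0
  structure(list(
    counts = counts,
    percentages = pct,
    row_totals = rowSums(counts),
    col_totals = colSums(counts),
    row_pct = if (total > 0) round_half_up(100 * rowSums(counts) / total, 1) else c(private = 0, recurrent = 0),
    col_pct = if (total > 0) round_half_up(100 * colSums(counts) / total, 1) else c(unknown = 0, known = 0),
    total = total
  ), class = "classification_table")
}

#' @export
print.classification_table <- function(x, ...) {
  fmt <- function(n, p) sprintf("%d (%.1f%%)", n, p)
  cat("Unique fusions by occurrence and annotation\n")
  cat(sprintf("%-10s %-16s %-16s %-16s\n", "", "Unknown", "Known", "Sum"))
  for (r in rownames(x$counts)) {
    cat(sprintf("%-10s %-16s %-16s %-16s\n", r,
                fmt(x$counts[r, "unknown"], x$percentages[r, "unknown"]),
                fmt(x$counts[r, "known"], x$percentages[r, "known"]),
                fmt(x$row_totals[r], x$row_pct[r])))
  }
  cat(sprintf("%-10s %-16s %-16s %-16s\n", "Sum",
              fmt(x$col_totals["unknown"], x$col_pct["unknown"]),
              fmt(x$col_totals["known"], x$col_pct["known"]),
              fmt(x$total, if (x$total > 0) 100.0 else 0)))
  invisible(x)
}

#' Per-chromosome inter/intra-chromosomal fusion counts
#'
#' Tabulates fusions per chromosome with the double-counting convention:
#' every fusion contributes two chromosome-level counts, one for the 5' gene
#' (gene1) and one for the 3' gene (gene2). An intrachromosomal fusion adds
#' 2 to its chromosome's intra count; an interchromosomal fusion adds 1 to
#' each partner chromosome's inter count. `intra_pct` is the percentage of
#' that chromosome's counts that are intrachromosomal (half-up, 1 decimal;
#' `NA` for chromosomes with no counts).
#'
#' @param catalog Catalog tibble from [build_catalog()].
#' @param scope `"all"` fusions or `"known"` fusions only.
#' @param multiplicity `"unique"` counts each catalog entry once;
#'   `"per_sample"` counts each entry once per carrying sample.
#' @return A tibble with one row per canonical chromosome: `chrom`,
#'   `inter_count`, `intra_count`, `intra_pct`.
#' @export
chromosome_table <- function(catalog, scope = c("all", "known"),
                             multiplicity = c("unique", "per_sample")) {
  scope <- match.arg(scope)
  multiplicity <- match.arg(multiplicity)
  if (scope == "known") catalog <- catalog[catalog$known, , drop = FALSE]
  w <- if (multiplicity == "per_sample") catalog$n_samples else rep(1L, nrow(catalog))
  inter <- stats::setNames(integer(length(CHROMOSOMES)), CHROMOSOMES)
  intra <- inter
  is_intra <- catalog$chrom5 == catalog$chrom3
  for (i in seq_len(nrow(catalog))) {
    if (is_intra[i]) {
      intra[catalog$chrom5[i]] <- intra[catalog$chrom5[i]] + 2L * w[i]
    } else {
      inter[catalog$chrom5[i]] <- inter[catalog$chrom5[i]] + w[i]
      inter[catalog$chrom3[i]] <- inter[catalog$chrom3[i]] + w[i]
    }
  }
  denom <- inter + intra
  tibble::tibble(
    chrom = CHROMOSOMES,
    inter_count = as.integer(unname(inter)),
    intra_count = as.integer(unname(intra)),
    intra_pct = unname(ifelse(denom > 0,
                              round_half_up(100 * intra / denom, 1),
                              NA_real_))
  )
}

#' Burden summaries by group
#'
#' Median and interquartile range (25th/75th percentiles, linear-interpolation
#' quantile rule) of per-sample fusion burden within groups; groups with no
#' samples are omitted.
#'
#' @param burden Named numeric vector, sample id -> burden.
#' @param labels Named character vector, sample id -> group label.
#' @return A tibble: `group`, `n`, `median`, `q25`, `q75`.
#' @export
burden_by_group <- function(burden, labels) {
  burden <- as_named(burden, "burden")
  labels <- as_named(labels, "labels")
  common <- intersect(names(burden), names(labels))
  groups <- split(unname(burden[common]), unname(labels[common]))
  tibble::tibble(
    group = names(groups),
    n = vapply(groups, length, 0L, USE.NAMES = FALSE),
    median = vapply(groups, stats::median, 0, USE.NAMES = FALSE),
    q25 = vapply(groups, function(v) unname(stats::quantile(v, 0.25, type = 7)),
                 0, USE.NAMES = FALSE),
    q75 = vapply(groups, function(v) unname(stats::quantile(v, 0.75, type = 7)),
                 0, USE.NAMES = FALSE)
  )
}
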