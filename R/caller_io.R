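# Import of fusion-caller output tables (three TSV dialects) and the
# normalized fusion-table format used by the rest of the pipeline.
#
# Dialect column maps are fixed here; each models the tab-separated layout of
# one common caller family:
#   A - Arriba-like:      gene1 gene2 breakpoint1 breakpoint2 split_reads
#                         discordant_mates type
#   B - STAR-Fusion-like: FusionName LeftGene RightGene LeftBreakpoint
#                         RightBreakpoint JunctionReadCount SpanningFragCount
#                         annots                  (genes as "SYMBOL^ENSG...")
#   C - STAR-SEQR-like:   LEFT_SYMBOL RIGHT_SYMBOL LEFT_BRKPT RIGHT_BRKPT
#                         JXN_READS SPAN_READS FUSION_CLASS
# Breakpoints are "chrom:pos:strand", 1-based, hg38 contig names with or
# without the "chr" prefix.

.dialects <- list(
  A = list(
    header = c("gene1", "gene2", "breakpoint1", "breakpoint2",
               "split_reads", "discordant_mates", "type"),
    gene5 = "gene1", gene3 = "gene2",
    bp5 = "breakpoint1", bp3 = "breakpoint2",
    split = "split_reads", disc = "discordant_mates",
    flag = "type", flag_pattern = "read[-_ ]?through", flag_ignore_case = TRUE
  ),
  B = list(
    header = c("FusionName", "LeftGene", "RightGene", "LeftBreakpoint",
               "RightBreakpoint", "JunctionReadCount", "SpanningFragCount",
               "annots"),
    gene5 = "LeftGene", gene3 = "RightGene",
    bp5 = "LeftBreakpoint", bp3 = "RightBreakpoint",
    split = "JunctionReadCount", disc = "SpanningFragCount",
    flag = "annots", flag_pattern = "READ-?THRU|READ-?THROUGH",
    flag_ignore_case = FALSE
  ),
  C = list(
    header = c("LEFT_SYMBOL", "RIGHT_SYMBOL", "LEFT_BRKPT", "RIGHT_BRKPT",
               "JXN_READS", "SPAN_READS", "FUSION_CLASS"),
    gene5 = "LEFT_SYMBOL", gene3 = "RIGHT_SYMBOL",
    bp5 = "LEFT_BRKPT", bp3 = "RIGHT_BRKPT",
    split = "JXN_READS", disc = "SPAN_READS",
    flag = "FUSION_CLASS", flag_pattern = "READ_?THROUGH",
    flag_ignore_case = FALSE
  )
)

# Column order of the normalized fusion table.
.fusion_cols <- c("sample_id", "caller", "gene5", "chrom5", "pos5", "strand5",
                  "gene3", "chrom3", "pos3", "strand3",
                  "split_reads", "discordant_pairs", "read_through")

# Canonicalize a caller gene field: strip whitespace and "^ENSG..." suffixes;
# multi-symbol fields ("A,B") resolve to the first listed symbol.
canon_gene <- function(x) {
  x <- trimws(x)
  x <- sub("\\^.*$", "", x)
  x <- sub("[,;].*$", "", x)
  x <- trimws(x)
  x[is.na(x)] <- ""
  x
}

# Normalize a chromosome name to "chr"-prefixed form; returns NA for
# non-canonical contigs (chrM, alt/decoy, ...).
norm_chrom <- function(x) {
  x <- trimws(x)
  x <- as.character(ifelse(grepl("^chr", x, ignore.case = TRUE),
                           sub("^chr", "chr", x, ignore.case = TRUE),
                           paste0("chr", x)))
  as.character(ifelse(x %in% CHROMOSOMES, x, NA_character_))
}

# Split "chrom:pos:strand" breakpoints into a list of vectors.
parse_breakpoint <- function(x) {
  parts <- strsplit(x, ":", fixed = TRUE)
  chrom <- vapply(parts, function(p) if (length(p) >= 1) p[[1]] else NA_character_, "")
  pos <- vapply(parts, function(p) if (length(p) >= 2) p[[2]] else NA_character_, "")
  strand <- vapply(parts, function(p) if (length(p) >= 3) p[[3]] else ".", "")
  strand[!strand %in% c("+", "-")] <- "."
  list(chrom = norm_chrom(chrom),
       pos = suppressWarnings(as.integer(pos)),
       strand = strand)
}

# Validate a normalized fusion-call tibble; returns it invisibly.
validate_fusion_calls <- function(calls) {
  need <- c(.fusion_cols, "total_support")
  missing <- setdiff(need, names(calls))
  if (length(missing) > 0) {
    stop("fusion call table lacks columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(calls) > 0) {
    stopifnot(
      all(calls$total_support == calls$split_reads + calls$discordant_pairs),
      all(calls$chrom5 %in% CHROMOSOMES), all(calls$chrom3 %in% CHROMOSOMES),
      all(calls$pos5 >= 1), all(calls$pos3 >= 1),
      all(nzchar(calls$gene5)), all(nzchar(calls$gene3)),
      all(calls$split_reads >= 0), all(calls$discordant_pairs >= 0),
      is.logical(calls$read_through)
    )
  }
  invisible(calls)
}

#' Read one fusion caller's output table
#'
#' Parses one of the three supported caller TSV dialects into the normalized
#' fusion-call table. Gene symbols are canonicalized (whitespace stripped,
#' `SYMBOL^ENSG...` identifiers reduced to the symbol, multi-symbol fields
#' like `"A,B"` resolved to the first symbol), breakpoints are split into
#' `chr`-prefixed chromosome, 1-based position and strand, and the caller's
#' read-through/artifact annotation is mapped to a logical flag.
#'
#' Rows whose gene pair cannot be parsed, whose numeric support fields are
#' malformed, or whose breakpoints fall on non-canonical contigs are skipped;
#' their counts are attached as attributes `n_skipped_gene`,
#' `n_skipped_numeric` and `n_skipped_contig` and summarized in a message.
#'
#' @param path Path to the caller's TSV output.
#' @param dialect One of `"A"` (Arriba-like), `"B"` (STAR-Fusion-like),
#'   `"C"` (STAR-SEQR-like).
#' @param sample_id Sample identifier recorded on every parsed call.
#' @return A tibble with columns `sample_id`, `caller`, `gene5`, `chrom5`,
#'   `pos5`, `strand5`, `gene3`, `chrom3`, `pos3`, `strand3`, `split_reads`,
#'   `discordant_pairs`, `total_support`, `read_through`; one row per
#'   successfully parsed caller record.
#' @seealso [write_fusion_table()], [read_fusion_table()]
#' @export
read_caller_table <- function(path, dialect = c("A", "B", "C"), sample_id) {
  dialect <- match.arg(dialect)
  spec <- .dialects[[dialect]]
  stopifnot(is.character(sample_id), length(sample_id) == 1, nzchar(sample_id))
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         show_col_types = FALSE, progress = FALSE,
                         na = character())
  if (!identical(names(raw), spec$header)) {
    stop(sprintf("header of '%s' does not match dialect %s (expected: %s)",
                 path, dialect, paste(spec$header, collapse = ", ")),
         call. = FALSE)
  }
  n_rows <- nrow(raw)
  gene5 <- canon_gene(raw[[spec$gene5]])
  gene3 <- canon_gene(raw[[spec$gene3]])
  bp5 <- parse_breakpoint(raw[[spec$bp5]])
  bp3 <- parse_breakpoint(raw[[spec$bp3]])
  split_reads <- suppressWarnings(as.integer(raw[[spec$split]]))
  discordant <- suppressWarnings(as.integer(raw[[spec$disc]]))
  read_through <- grepl(spec$flag_pattern, raw[[spec$flag]],
                        ignore.case = isTRUE(spec$flag_ignore_case))

  bad_gene <- !nzchar(gene5) | !nzchar(gene3)
  bad_num <- is.na(split_reads) | is.na(discordant) |
    split_reads < 0 | discordant < 0 |
    is.na(bp5$pos) | is.na(bp3$pos) | bp5$pos < 1 | bp3$pos < 1
  bad_contig <- is.na(bp5$chrom) | is.na(bp3$chrom)
  keep <- !(bad_gene | bad_num | bad_contig)

  out <- tibble::tibble(
    sample_id = rep(sample_id, sum(keep)),
    caller = dialect,
    gene5 = gene5[keep], chrom5 = bp5$chrom[keep], pos5 = bp5$pos[keep],
    strand5 = bp5$strand[keep],
    gene3 = gene3[keep], chrom3 = bp3$chrom[keep], pos3 = bp3$pos[keep],
    strand3 = bp3$strand[keep],
    split_reads = split_reads[keep], discordant_pairs = discordant[keep],
    total_support = split_reads[keep] + discordant[keep],
    read_through = read_through[keep]
  )
  attr(out, "n_skipped_gene") <- sum(bad_gene)
  attr(out, "n_skipped_numeric") <- sum(bad_num & !bad_gene)
  attr(out, "n_skipped_contig") <- sum(bad_contig & !bad_gene & !bad_num)
  attr(out, "n_rows") <- n_rows
  n_skipped <- n_rows - nrow(out)
  if (n_skipped > 0) {
    message(sprintf("read_caller_table: skipped %d of %d rows in '%s' (%d bad gene pair, %d bad numeric/position, %d non-canonical contig)",
                    n_skipped, n_rows, path,
                    attr(out, "n_skipped_gene"),
                    attr(out, "n_skipped_numeric"),
                    attr(out, "n_skipped_contig")))
  }
  validate_fusion_calls(out)
  out
}

#' Write the normalized fusion table
#'
#' Writes calls as a tab-separated table in the fixed normalized column order
#' with a deterministic row order (`sample_id`, `gene5`, `gene3`, `pos5`,
#' `pos3`, `caller`), so identical call sets always produce identical bytes.
#'
#' @param calls Normalized fusion-call tibble (see [read_caller_table()]).
#' @param path Output path.
#' @export
write_fusion_table <- function(calls, path) {
  validate_fusion_calls(calls)
  ord <- order(calls$sample_id, calls$gene5, calls$gene3,
               calls$pos5, calls$pos3, calls$caller, method = "radix")
  out <- calls[ord, .fusion_cols]
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Read a normalized fusion table
#'
#' Inverse of [write_fusion_table()]; recomputes `total_support` from the
#' stored split and discordant counts and re-validates all invariants.
#'
#' @param path Path to a normalized fusion table TSV.
#' @return A normalized fusion-call tibble.
#' @export
read_fusion_table <- function(path) {
  out <- readr::read_tsv(
    path,
    col_types = readr::cols(
      sample_id = readr::col_character(), caller = readr::col_character(),
      gene5 = readr::col_character(), chrom5 = readr::col_character(),
      pos5 = readr::col_integer(), strand5 = readr::col_character(),
      gene3 = readr::col_character(), chrom3 = readr::col_character(),
      pos3 = readr::col_integer(), strand3 = readr::col_character(),
      split_reads = readr::col_integer(),
      discordant_pairs = readr::col_integer(),
      read_through = readr::col_logical()
    ),
    show_col_types = FALSE, progress = FALSE
  )
  out$total_support <- out$split_reads + out$discordant_pairs
  out <- out[, c(.fusion_cols[1:12], "total_support", "read_through")]
  validate_fusion_calls(out)
  out
}

#' Load a blacklist or known-fusion gene-pair list
#'
#' Reads a headerless TSV with either two symbol columns (ordered 5'-3' gene
#' pairs) or one symbol column (single genes whose every fusion is banned,
#' e.g. homology or normal-tissue gene lists). Entries are deduplicated.
#'
#' @param path Path to the headerless TSV.
#' @param mode `"pairs"` (two columns) or `"genes"` (one column).
#' @param name Source tag (defaults to the file name without extension).
#' @return An object of class `gene_pair_list`: a list with `name`, `pairs`
#'   (tibble with `gene5`, `gene3`) and `single_genes` (character vector).
#' @export
load_gene_pair_list <- function(path, mode = c("pairs", "genes"), name = NULL) {
  mode <- match.arg(mode)
  if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))
  raw <- utils::read.table(path, sep = "\t", header = FALSE,
                           colClasses = "character", quote = "",
                           blank.lines.skip = TRUE)
  expected <- if (mode == "pairs") 2L else 1L
  if (ncol(raw) != expected) {
    stop(sprintf("'%s': expected %d column(s) for mode '%s', found %d",
                 path, expected, mode, ncol(raw)), call. = FALSE)
  }
  if (mode == "pairs") {
    g5 <- canon_gene(raw[[1]]); g3 <- canon_gene(raw[[2]])
    ok <- nzchar(g5) & nzchar(g3)
    keep <- !duplicated(pair_key(g5[ok], g3[ok]))
    gene_pair_list(name,
                   pairs = tibble::tibble(gene5 = g5[ok][keep],
                                          gene3 = g3[ok][keep]))
  } else {
    g <- canon_gene(raw[[1]])
    gene_pair_list(name, single_genes = unique(g[nzchar(g)]))
  }
}

#' Construct a gene-pair list in code
#'
#' @param name Source tag.
#' @param pairs Tibble/data frame with columns `gene5`, `gene3` (ordered
#'   pairs), or `NULL`.
#' @param single_genes Character vector of banned single genes, or `NULL`.
#' @return A `gene_pair_list`.
#' @export
gene_pair_list <- function(name, pairs = NULL, single_genes = NULL) {
  if (is.null(pairs)) {
    pairs <- tibble::tibble(gene5 = character(), gene3 = character())
  }
  pairs <- tibble::as_tibble(pairs[, c("gene5", "gene3")])
  pairs <- pairs[!duplicated(pair_key(pairs$gene5, pairs$gene3)), ]
  if (is.null(single_genes)) single_genes <- character()
  stopifnot(all(nzchar(pairs$gene5)), all(nzchar(pairs$gene3)),
            all(nzchar(single_genes)))
  structure(list(name = name, pairs = pairs,
                 single_genes = unique(single_genes)),
            class = "gene_pair_list")
}

#' @export
print.gene_pair_list <- function(x, ...) {
  cat(sprintf("<gene_pair_list '%s': %d pairs, %d single genes>\n",
              x$name, nrow(x$pairs), length(x$single_genes)))
  invisible(x)
}

#' Write caller output in a given dialect
#'
#' Renders normalized calls in one caller dialect's file layout (the inverse
#' of [read_caller_table()]); used by the synthetic-cohort generator and by
#' round-trip tests. All calls must come from a single sample.
#'
#' @param calls Normalized fusion-call tibble for one sample.
#' @param dialect `"A"`, `"B"` or `"C"`.
#' @param path Output path.
#' @export
write_dialect_file <- function(calls, dialect = c("A", "B", "C"), path) {
  dialect <- match.arg(dialect)
  validate_fusion_calls(calls)
  bp5 <- paste(calls$chrom5, calls$pos5, calls$strand5, sep = ":")
  bp3 <- paste(calls$chrom3, calls$pos3, calls$strand3, sep = ":")
  inter <- calls$chrom5 != calls$chrom3
  out <- switch(dialect,
    A = tibble::tibble(
      gene1 = calls$gene5, gene2 = calls$gene3,
      breakpoint1 = bp5, breakpoint2 = bp3,
      split_reads = calls$split_reads,
      discordant_mates = calls$discordant_pairs,
      type = ifelse(calls$read_through, "deletion/read-through",
                    ifelse(inter, "translocation", "deletion"))
    ),
    B = tibble::tibble(
      FusionName = paste0(calls$gene5, "--", calls$gene3),
      LeftGene = paste0(calls$gene5, "^ENSG00000000000"),
      RightGene = paste0(calls$gene3, "^ENSG00000000000"),
      LeftBreakpoint = bp5, RightBreakpoint = bp3,
      JunctionReadCount = calls$split_reads,
      SpanningFragCount = calls$discordant_pairs,
      annots = ifelse(calls$read_through, "[\"READTHRU\"]",
                      ifelse(inter, "[\"INTERCHROMOSOMAL\"]",
                             "[\"INTRACHROMOSOMAL\"]"))
    ),
    C = tibble::tibble(
      LEFT_SYMBOL = calls$gene5, RIGHT_SYMBOL = calls$gene3,
      LEFT_BRKPT = bp5, RIGHT_BRKPT = bp3,
      JXN_READS = calls$split_reads, SPAN_READS = calls$discordant_pairs,
      FUSION_CLASS = ifelse(calls$read_through, "READ_THROUGH",
                            ifelse(inter, "TRANSLOCATION", "DUPLICATION"))
    )
  )
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}
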