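# Shared helpers: chromosome set, rounding convention, seeded evaluation.

#' Canonical chromosome names
#'
#' The 24 canonical human chromosome names (`chr1`..`chr22`, `chrX`, `chrY`).
#' Calls on any other contig are dropped during import.
#'
#' @export
CHROMOSOMES <- paste0("chr", c(1:22, "X", "Y"))

# Half-up decimal rounding, matching how percentages are printed in cohort
# tables (base round() is half-even).
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Internal key for an ordered 5'-3' gene pair; "\r" cannot occur in a
# canonicalized symbol.
pair_key <- function(gene5, gene3) paste(gene5, gene3, sep = "\r")

# Deterministic sub-seed for a named component, kept below 2^31 - 1.
derive_seed <- function(seed, tag) {
  codes <- utf8ToInt(tag)
  h <- sum(codes * seq_along(codes))
  as.integer((as.numeric(seed) %% 65536 * 7919 + h * 131) %% 2147483647)
}

# Evaluate `expr` under `set.seed(seed)` and restore the caller's RNG state,
# so generators never leak global RNG state.
run_seeded <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  force(expr)
}

# Coerce a map given as a named vector (or 1-col data frame) to a named vector.
as_named <- function(x, what = "values") {
  if (is.null(names(x)) || anyNA(names(x)) || any(names(x) == "")) {
    stop(sprintf("`%s` must be a named vector (names = sample ids)", what),
         call. = FALSE)
  }
  x
}
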