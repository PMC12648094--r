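# Rank providers: pluggable sources of peptide-HLA percentile ranks.
# A provider is a function(peptides, alleles) -> numeric %Rank in (0, 100],
# vectorized over parallel peptide/allele vectors. External prediction
# engines are consumed through the table provider; the surrogate providers
# exist so the whole pipeline runs (deterministically) without them.

# Deterministic string hash: Horner scheme base 131 modulo the Mersenne
# prime 2^31 - 1, folded with the seed. Pure double arithmetic, every
# intermediate < 2^53, hence platform-independent.
surrogate_hash <- function(keys, seed) {
  m <- 2147483647
  vapply(keys, function(k) {
    h <- (abs(seed) %% m)
    for (code in utf8ToInt(k)) h <- (h * 131 + code) %% m
    h
  }, numeric(1), USE.NAMES = FALSE)
}

#' Rank provider: deterministic seeded surrogate
#'
#' Maps each (peptide, allele) pair to a pseudo-uniform percentile rank in
#' (0, 100] via a seeded keyed hash. The same seed gives byte-identical
#' ranks across runs and platforms. Used to exercise the pipeline when no
#' external binding predictions are available; the ranks carry no biology.
#'
#' @param seed integer seed folded into the hash.
#' @return a function `(peptides, alleles) -> numeric` of class
#'   `rank_provider`.
#' @export
rank_provider_surrogate <- function(seed = 0L) {
  force(seed)
  structure(function(peptides, alleles) {
    keys <- paste(peptides, alleles, sep = "|")
    (surrogate_hash(keys, seed) + 1) / 2147483648 * 100
  }, class = c("rank_provider", "function"))
}

#' Rank provider: lookup from a precomputed prediction table
#'
#' Serves ranks from a table of external predictor output (e.g. NetMHCpan
#' or PRIME percentile ranks) with columns `peptide`, `allele`, `rank_pct`.
#' A query absent from the table is an error naming the peptide and allele.
#'
#' @param table a data.frame with columns `peptide`, `allele`, `rank_pct`,
#'   or a file path readable by [read_rank_table()].
#' @return a `rank_provider` function.
#' @export
rank_provider_table <- function(table) {
  if (is.character(table)) table <- read_rank_table(table)
  stopifnot(all(c("peptide", "allele", "rank_pct") %in% names(table)))
  lookup <- setNames(as.numeric(table$rank_pct),
                     paste(table$peptide, table$allele, sep = "|"))
  structure(function(peptides, alleles) {
    keys <- paste(peptides, alleles, sep = "|")
    hit <- match(keys, names(lookup))
    if (anyNA(hit)) {
      i <- which(is.na(hit))[1]
      stop("no rank for peptide ", peptides[i], " on allele ", alleles[i],
           call. = FALSE)
    }
    unname(lookup[hit])
  }, class = c("rank_provider", "function"))
}

#' Rank provider: surrogate with planted strong binders
#'
#' Wraps another provider and forces designated "true" epitope peptides to
#' a fixed strong rank (default 0.1, i.e. below the 0.5 selection
#' threshold), on every allele. Used by the synthetic-cohort generator to
#' plant recoverable ground truth.
#'
#' @param base a `rank_provider` to wrap (default a seeded surrogate).
#' @param planted character vector of mutant peptide sequences to force.
#' @param forced_rank_pct rank assigned to planted peptides, default 0.1.
#' @return a `rank_provider` function.
#' @export
rank_provider_planted <- function(base = rank_provider_surrogate(),
                                  planted = character(),
                                  forced_rank_pct = 0.1) {
  force(base); force(planted); force(forced_rank_pct)
  structure(function(peptides, alleles) {
    r <- base(peptides, alleles)
    r[peptides %in% planted] <- forced_rank_pct
    r
  }, class = c("rank_provider", "function"))
}

#' Read a peptide-HLA rank table
#'
#' @param path comma- or tab-delimited table with columns `peptide`,
#'   `allele`, `rank_pct`.
#' @return a data.frame.
#' @export
read_rank_table <- function(path) {
  df <- read_dialect_table(path, required = c("peptide", "allele", "rank_pct"))
  df$rank_pct <- as.numeric(df$rank_pct)
  if (any(!is.finite(df$rank_pct)) || any(df$rank_pct <= 0) ||
      any(df$rank_pct > 100)) {
    stop("rank_pct must lie in (0, 100]", call. = FALSE)
  }
  df
}
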