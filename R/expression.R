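#' Convert raw gene counts to TPM
#'
#' Transcripts-per-million normalization: each gene's count is divided by
#' its length in kilobases, and the resulting rates are scaled to sum to
#' one million. Fractional counts are allowed (multi-mapping reads reported
#' as fractions). An all-zero count vector yields an all-zero table.
#'
#' @param counts named non-negative numeric vector of per-gene read counts.
#' @param lengths_bp named positive numeric vector of gene (transcript)
#'   lengths in base pairs; every counted gene must have a length.
#' @return named numeric vector of TPM values summing to 1e6 (or all zero).
#' @examples
#' counts_to_tpm(c(g1 = 10, g2 = 10), c(g1 = 1000, g2 = 2000))
#' @export
counts_to_tpm <- function(counts, lengths_bp) {
  if (is.null(names(counts)) || is.null(names(lengths_bp))) {
    stop("counts and lengths_bp must be named by gene_id", call. = FALSE)
  }
  missing <- setdiff(names(counts), names(lengths_bp))
  if (length(missing) > 0L) {
    stop("no length for gene(s): ", paste(head(missing, 5), collapse = ", "),
         call. = FALSE)
  }
  len <- lengths_bp[names(counts)]
  if (any(!is.finite(len)) || any(len <= 0)) {
    stop("gene lengths must be positive", call. = FALSE)
  }
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  rate <- counts / (len / 1000)
  total <- sum(rate)
  if (total == 0) return(setNames(numeric(length(counts)), names(counts)))
  setNames(as.numeric(rate / total * 1e6), names(counts))
}

#' Read a gene expression table
#'
#' Accepts either a precomputed TPM table (columns `gene_id`, `tpm`) or a
#' raw count table (columns `gene_id`, `count`, `length_bp`) which is
#' normalized with [counts_to_tpm()].
#'
#' @param path path to a comma- or tab-delimited table.
#' @return named numeric vector of TPM values.
#' @export
read_expression <- function(path) {
  df <- read_dialect_table(path, required = "gene_id")
  if ("tpm" %in% names(df)) {
    tpm <- setNames(as.numeric(df$tpm), as.character(df$gene_id))
    if (any(tpm < 0)) stop("negative TPM in ", path, call. = FALSE)
    return(tpm)
  }
  if (all(c("count", "length_bp") %in% names(df))) {
    return(counts_to_tpm(setNames(as.numeric(df$count), df$gene_id),
                         setNames(as.numeric(df$length_bp), df$gene_id)))
  }
  stop("expression table needs either a 'tpm' column or 'count' + 'length_bp'",
       call. = FALSE)
}
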