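#' HLA class I genotype
#'
#' @param alleles character vector (1-6) of class I allele names at 4-digit
#'   resolution, e.g. `"HLA-A*02:01"`. Locus must be A, B or C.
#' @return an object of class `hla_genotype`.
#' @export
hla_genotype <- function(alleles) {
  alleles <- unique(as.character(alleles))
  if (length(alleles) < 1L || length(alleles) > 6L) {
    stop("an HLA class I genotype has 1-6 alleles", call. = FALSE)
  }
  ok <- grepl("^HLA-[ABC]\\*[0-9]{2,3}:[0-9]{2,3}$", alleles)
  if (!all(ok)) {
    stop("invalid HLA class I allele name(s): ",
         paste(alleles[!ok], collapse = ", "), call. = FALSE)
  }
  structure(list(alleles = alleles), class = "hla_genotype")
}

#' Candidate selection configuration
#'
#' Two selection modes mirror the two screening designs the pipeline
#' supports: `threshold` keeps peptides with predicted binding
#' `%Rank < rank_threshold_pct` AND source-gene expression
#' `TPM > tpm_threshold` (both strict); `top_n` ranks all peptides by %Rank
#' and keeps the `n_top` best unique mutant sequences (best allele per
#' peptide), ignoring TPM unless `tpm_threshold` is explicitly supplied
#' (screens without tumor RNA-seq have no expression filter).
#'
#' @param mode `"threshold"` or `"top_n"`.
#' @param rank_threshold_pct strict upper bound on %Rank, default 0.5.
#' @param tpm_threshold strict lower bound on TPM, default 1.0 in threshold
#'   mode; `NA` in top_n mode disables the expression filter.
#' @param n_top number of unique peptides kept in top_n mode, default 150.
#' @return an object of class `selection_config`.
#' @export
selection_config <- function(mode = c("threshold", "top_n"),
                             rank_threshold_pct = 0.5,
                             tpm_threshold = if (match.arg(mode) == "threshold") 1.0 else NA_real_,
                             n_top = 150L) {
  mode <- match.arg(mode)
  stopifnot_scalar_number(rank_threshold_pct, "rank_threshold_pct", positive = TRUE)
  n_top <- as.integer(n_top)
  if (n_top < 1L) stop("n_top must be >= 1", call. = FALSE)
  if (!is.na(tpm_threshold)) {
    stopifnot_scalar_number(tpm_threshold, "tpm_threshold", positive = TRUE)
  }
  structure(list(mode = mode, rank_threshold_pct = rank_threshold_pct,
                 tpm_threshold = tpm_threshold, n_top = n_top),
            class = "selection_config")
}

#' Score peptide candidates against a patient's HLA alleles
#'
#' Takes the Cartesian product of unique mutant peptides and the patient's
#' alleles, queries the rank provider for each pair, and annotates each
#' scored candidate with its source gene's TPM (0 if the gene is absent
#' from the expression table, so it is later filtered out). When the same
#' mutant sequence arises from several variants, one representative row
#' (first in input order) carries it into scoring. Output order is
#' deterministic: mutant peptide, then allele.
#'
#' @param pairs peptide-pair data.frame from [peptide_candidates()].
#' @param hla an [hla_genotype()].
#' @param provider a `rank_provider` function.
#' @param expr named TPM vector (see [read_expression()]); may be `NULL`
#'   when no expression data exist (TPM recorded as `NA`).
#' @return a data.frame with columns of `pairs` plus `allele`, `rank_pct`,
#'   `tpm`.
#' @export
score_candidates <- function(pairs, hla, provider, expr = NULL) {
  stopifnot(is.data.frame(pairs), inherits(hla, "hla_genotype"),
            is.function(provider))
  uniq <- pairs[!duplicated(pairs$mut_peptide), , drop = FALSE]
  uniq <- uniq[order(uniq$mut_peptide), , drop = FALSE]
  if (nrow(uniq) == 0L) {
    out <- cbind(uniq, allele = character(), rank_pct = numeric(),
                 tpm = numeric())
    return(out)
  }
  alleles <- sort(hla$alleles)
  grid <- expand.grid(i = seq_len(nrow(uniq)), allele = alleles,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid <- grid[order(grid$i, grid$allele), , drop = FALSE]
  out <- uniq[grid$i, , drop = FALSE]
  out$allele <- grid$allele
  out$rank_pct <- provider(out$mut_peptide, out$allele)
  if (any(!is.finite(out$rank_pct))) {
    bad <- which(!is.finite(out$rank_pct))[1]
    stop("rank provider failed for peptide ", out$mut_peptide[bad],
         " on allele ", out$allele[bad], call. = FALSE)
  }
  out$tpm <- if (is.null(expr)) {
    NA_real_
  } else {
    unname(ifelse(out$gene_id %in% names(expr), expr[out$gene_id], 0))
  }
  rownames(out) <- NULL
  out
}

#' Select candidate peptides for synthesis
#'
#' Applies the configured selection mode to scored candidates (see
#' [selection_config()] for the two modes). Output is sorted by `rank_pct`
#' ascending; ties in top_n mode break by mutant peptide then allele so the
#' selected list is reproducible.
#'
#' @param scored data.frame from [score_candidates()].
#' @param config a [selection_config()].
#' @return the selected subset, with a `selected_mode` column appended.
#' @export
select_candidates <- function(scored, config = selection_config()) {
  stopifnot(is.data.frame(scored), inherits(config, "selection_config"))
  ord <- order(scored$rank_pct, scored$mut_peptide, scored$allele)
  scored <- scored[ord, , drop = FALSE]
  if (config$mode == "threshold") {
    tpm <- scored$tpm
    keep <- scored$rank_pct < config$rank_threshold_pct &
      !is.na(tpm) & tpm > config$tpm_threshold
    out <- scored[keep, , drop = FALSE]
  } else {
    keep <- rep(TRUE, nrow(scored))
    if (!is.na(config$tpm_threshold)) {
      keep <- !is.na(scored$tpm) & scored$tpm > config$tpm_threshold
    }
    pool <- scored[keep, , drop = FALSE]
    # best allele per unique mutant sequence, then first n_top sequences
    pool <- pool[!duplicated(pool$mut_peptide), , drop = FALSE]
    out <- pool[seq_len(min(config$n_top, nrow(pool))), , drop = FALSE]
  }
  if (nrow(out) > 0L) out$selected_mode <- config$mode
  else out$selected_mode <- character(0)
  rownames(out) <- NULL
  out
}
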