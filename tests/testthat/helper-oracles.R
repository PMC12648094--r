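# Independent oracles used across tests. These deliberately avoid the code
# paths of the package implementations they check.

# Fisher two-sided p by direct enumeration of all tables with the observed
# margins, probabilities from exact choose() products (exact in doubles for
# N <= 40).
oracle_fisher <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c; n <- r1 + r2
  support <- max(0, c1 - r2):min(r1, c1)
  probs <- choose(r1, support) * choose(r2, c1 - support) / choose(n, c1)
  p_obs <- probs[support == a]
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

# same, but in log space so margins up to a few hundred are safe
oracle_fisher_log <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c; n <- r1 + r2
  support <- max(0, c1 - r2):min(r1, c1)
  lp <- lchoose(r1, support) + lchoose(r2, c1 - support) - lchoose(n, c1)
  probs <- exp(lp - max(lp))
  p_obs <- probs[support == a]
  sum(probs[probs <= p_obs * (1 + 1e-7)]) / sum(probs)
}

# Wilcoxon signed-rank two-sided exact p by brute force over all 2^n sign
# assignments of the observed absolute-difference ranks (doubling rule).
oracle_signed_rank <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) return(1)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), n)))
  v_all <- apply(signs, 1, function(s) sum(r[s]))
  min(1, 2 * min(mean(v_all <= v_obs), mean(v_all >= v_obs)))
}

# all substrings of the mutant window that contain the mutated position,
# paired with the wild-type substring at the same offset
oracle_substrings <- function(wt, mut, idx0, lengths) {
  out <- list()
  for (k in sort(lengths)) {
    for (o in 0:(nchar(wt) - k)) {
      if (o <= idx0 && idx0 <= o + k - 1) {
        out[[length(out) + 1]] <- data.frame(
          length = k, offset_in_window = o,
          mut_peptide = substr(mut, o + 1, o + k),
          wt_peptide = substr(wt, o + 1, o + k), stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, out)
}

# random protein sequence
random_protein <- function(n) {
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], n, TRUE),
        collapse = "")
}

# build a variant data.frame the way read_variants() would return it
make_variants <- function(protein_id, protein_pos, aa_ref, aa_alt,
                          callers, variant_class = "missense",
                          gene_id = paste0("G_", protein_id)) {
  df <- data.frame(gene_id = gene_id, protein_id = protein_id,
                   protein_pos = protein_pos, aa_ref = aa_ref,
                   aa_alt = aa_alt, variant_class = variant_class,
                   stringsAsFactors = FALSE)
  df$callers <- I(callers)
  df$n_callers <- lengths(callers)
  df
}

# minimal in-memory ELISPOT plate table (same columns as
# read_elispot_plates() returns)
make_plates <- function(rows) {
  df <- do.call(rbind, lapply(rows, function(r) {
    data.frame(experiment_id = r$experiment_id,
               sample_source = r$sample_source %||% "TIL",
               condition_id = r$condition_id, kind = r$kind,
               members = paste(r$members %||% character(), collapse = ";"),
               stringsAsFactors = FALSE)
  }))
  df$spot_counts <- I(lapply(rows, function(r) as.integer(r$spots)))
  df
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# clonotype_table built directly from a count matrix (clonotype x sample)
make_ct <- function(counts, n_cells, timepoints = NULL) {
  samples <- data.frame(sample_id = colnames(counts), patient = "PX",
                        compartment = colnames(counts),
                        timepoint = timepoints %||%
                          rep("pre_bcg", ncol(counts)),
                        n_cells = as.integer(n_cells),
                        stringsAsFactors = FALSE)
  meta <- data.frame(clonotype_key = rownames(counts),
                     trb_key = rownames(counts),
                     tra_key = NA_character_, ambiguous_trb = FALSE,
                     stringsAsFactors = FALSE)
  structure(list(clonotypes = meta, counts = counts,
                 detected = counts >= 2L, samples = samples),
            class = "clonotype_table")
}
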