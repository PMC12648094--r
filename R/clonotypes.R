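#' Read single-cell TCR rearrangements (AIRR-style subset)
#'
#' @param path tab- or comma-delimited table with columns `cell_id`,
#'   `sample_id`, `locus` (`TRA`/`TRB`), `v_call`, `j_call`, `junction_aa`.
#' @return a data.frame.
#' @export
read_rearrangements <- function(path) {
  req <- c("cell_id", "sample_id", "locus", "v_call", "j_call", "junction_aa")
  df <- read_dialect_table(path, required = req)[req]
  if (!all(df$locus %in% c("TRA", "TRB"))) {
    stop("locus must be TRA or TRB", call. = FALSE)
  }
  if (any(!nzchar(df$junction_aa))) {
    stop("empty junction_aa in ", path, call. = FALSE)
  }
  df
}

#' Read a sample sheet
#'
#' @param path table with columns `sample_id`, `patient`, `compartment`
#'   (`tumor`, `adjacent_bladder`, `post_bcg_bladder`, `blood`), `timepoint`
#'   (`pre_bcg`/`post_bcg`), `n_cells` (QC-passing sorted cells).
#' @return a data.frame.
#' @export
read_samples <- function(path) {
  req <- c("sample_id", "patient", "compartment", "timepoint", "n_cells")
  df <- read_dialect_table(path, required = req)[req]
  df$n_cells <- as.integer(df$n_cells)
  if (any(df$n_cells < 1L)) stop("n_cells must be >= 1", call. = FALSE)
  df
}

# canonical clonotype keys: V and J at gene (not allele) resolution plus the
# CDR3 amino-acid junction; bulk DNA repertoires and single-cell calls
# disagree at allele level, so allele suffixes (*01 etc.) are stripped
gene_level <- function(x) sub("\\*.*$", "", x)

trb_key_of <- function(v, j, junction) {
  paste(gene_level(v), gene_level(j), junction, sep = "_")
}

#' Build a clonotype table from single-cell rearrangements
#'
#' Cells are grouped into clonotypes keyed on the TRB triple (V gene, J
#' gene, CDR3 junction) plus the TRA triple when present. Cells with a TRB
#' but no TRA merge into the paired clonotype sharing that TRB triple when
#' exactly one such pairing exists; if several TRA pairings share the TRB,
#' the TRB-only cells stay a separate (ambiguous) clonotype. Cells with two
#' distinct TRBs are dropped with a warning (suspected doublets); cells
#' with only a TRA are excluded (unjoinable to bulk TRB data). A clonotype
#' counts as detected in a sample when seen in at least two cells there.
#'
#' @param rearrangements data.frame from [read_rearrangements()].
#' @param samples data.frame from [read_samples()].
#' @return an object of class `clonotype_table`: list with `clonotypes`
#'   (data.frame: `clonotype_key`, `trb_key`, `tra_key`, `ambiguous_trb`),
#'   `counts` (clonotype x sample integer matrix), `detected` (logical
#'   matrix, counts >= 2) and `samples`.
#' @export
build_clonotype_table <- function(rearrangements, samples) {
  stopifnot(all(rearrangements$sample_id %in% samples$sample_id))
  cells <- split(rearrangements, rearrangements$cell_id)
  recs <- list()
  dropped <- 0L
  for (cell in cells) {
    trb <- cell[cell$locus == "TRB", , drop = FALSE]
    tra <- cell[cell$locus == "TRA", , drop = FALSE]
    trb_keys <- unique(trb_key_of(trb$v_call, trb$j_call, trb$junction_aa))
    if (length(trb_keys) > 1L) { dropped <- dropped + 1L; next }
    if (length(trb_keys) == 0L) next           # TRA-only cell: excluded
    tra_key <- if (nrow(tra) > 0L) {
      k <- sort(unique(trb_key_of(tra$v_call, tra$j_call, tra$junction_aa)))
      k[1]                                     # <=1 productive TRA retained
    } else NA_character_
    recs[[length(recs) + 1L]] <- data.frame(
      cell_id = cell$cell_id[1], sample_id = cell$sample_id[1],
      trb_key = trb_keys, tra_key = tra_key, stringsAsFactors = FALSE)
  }
  if (dropped > 0L) {
    warning(dropped, " cell(s) with two distinct TRB chains dropped ",
            "(suspected doublets)", call. = FALSE)
  }
  cells_df <- do.call(rbind, recs)
  if (is.null(cells_df)) stop("no cells with a TRB chain", call. = FALSE)
  # resolve TRB-only cells against paired clonotypes with the same TRB
  key <- character(nrow(cells_df))
  ambiguous <- logical(nrow(cells_df))
  for (tk in unique(cells_df$trb_key)) {
    i <- which(cells_df$trb_key == tk)
    tra_present <- unique(cells_df$tra_key[i][!is.na(cells_df$tra_key[i])])
    for (j in i) {
      if (!is.na(cells_df$tra_key[j])) {
        key[j] <- paste(tk, cells_df$tra_key[j], sep = "+")
      } else if (length(tra_present) == 1L) {
        key[j] <- paste(tk, tra_present, sep = "+")   # merge into the pair
      } else {
        key[j] <- tk
        ambiguous[j] <- length(tra_present) > 1L
      }
    }
  }
  cells_df$clonotype_key <- key
  cells_df$ambiguous <- ambiguous
  keys <- sort(unique(key))
  counts <- matrix(0L, nrow = length(keys), ncol = nrow(samples),
                   dimnames = list(keys, samples$sample_id))
  tab <- table(cells_df$clonotype_key, cells_df$sample_id)
  counts[rownames(tab), colnames(tab)] <- as.integer(tab)
  over <- counts > matrix(samples$n_cells, nrow = length(keys),
                          ncol = nrow(samples), byrow = TRUE)
  if (any(over)) {
    stop("clonotype cell count exceeds sample n_cells", call. = FALSE)
  }
  meta <- data.frame(
    clonotype_key = keys,
    trb_key = vapply(strsplit(keys, "+", fixed = TRUE), `[`, character(1), 1),
    tra_key = vapply(strsplit(keys, "+", fixed = TRUE),
                     function(x) if (length(x) > 1) x[2] else NA_character_,
                     character(1)),
    stringsAsFactors = FALSE)
  meta$ambiguous_trb <- keys %in% cells_df$clonotype_key[cells_df$ambiguous]
  structure(list(clonotypes = meta, counts = counts,
                 detected = counts >= 2L, samples = samples),
            class = "clonotype_table")
}

#' @export
print.clonotype_table <- function(x, ...) {
  cat("clonotype_table:", nrow(x$clonotypes), "clonotypes across",
      nrow(x$samples), "sample(s);", sum(x$counts), "cells\n")
  invisible(x)
}

#' Per-sample clonotype frequencies
#'
#' Frequency is the cell count of the clonotype divided by the sample's
#' QC-passing cell number; 0 when absent. The per-sample detection floor
#' (1 / n_cells, the smallest observable non-zero frequency) is returned as
#' an attribute.
#'
#' @param ct a `clonotype_table`.
#' @param sample_id sample to evaluate.
#' @return named numeric vector of frequencies with attribute
#'   `detection_floor`.
#' @export
clonotype_frequencies <- function(ct, sample_id) {
  stopifnot(inherits(ct, "clonotype_table"),
            sample_id %in% ct$samples$sample_id)
  n <- ct$samples$n_cells[ct$samples$sample_id == sample_id]
  structure(as.numeric(ct$counts[, sample_id]) / n,
            names = rownames(ct$counts), detection_floor = 1 / n)
}

#' Compare a clonotype's frequency between two timepoints
#'
#' Two-sided Fisher exact test (minimum-likelihood convention, see
#' [fisher_exact_2x2()]) on the 2x2 table of (cells in clonotype, other
#' cells) x (pre, post). The fold change is `freq_pre / freq_post`; when
#' the clonotype is absent post-treatment the post frequency is floored at
#' the detection floor `1 / n_post` (policy `"detection_floor"`), so the
#' reported fold change is a lower bound (`fold_is_bound = TRUE`).
#'
#' @param ct a `clonotype_table`.
#' @param clonotype_key clonotype to test.
#' @param pre_sample,post_sample sample ids of the pre- and post-treatment
#'   samples.
#' @param alpha significance level, default 0.05 (nominal, uncorrected).
#' @param floor_policy `"detection_floor"` (default) or `"na"` (fold change
#'   `NA` when the post count is 0).
#' @return a one-row data.frame: `clonotype_key`, counts and depths,
#'   `freq_pre`, `freq_post`, `fold_change`, `fold_is_bound`, `p_value`,
#'   `significant`; `NULL` when the clonotype is absent from both samples.
#' @export
compare_timepoints <- function(ct, clonotype_key, pre_sample, post_sample,
                               alpha = 0.05,
                               floor_policy = c("detection_floor", "na")) {
  floor_policy <- match.arg(floor_policy)
  stopifnot(inherits(ct, "clonotype_table"))
  s <- ct$samples
  pre_n <- s$n_cells[s$sample_id == pre_sample]
  post_n <- s$n_cells[s$sample_id == post_sample]
  if (length(pre_n) != 1L || length(post_n) != 1L) {
    stop("unknown sample id", call. = FALSE)
  }
  k_pre <- ct$counts[clonotype_key, pre_sample]
  k_post <- ct$counts[clonotype_key, post_sample]
  if (k_pre == 0L && k_post == 0L) return(NULL)   # comparison undefined
  p <- fisher_exact_2x2(k_pre, pre_n - k_pre, k_post, post_n - k_post)
  f_pre <- k_pre / pre_n
  f_post <- k_post / post_n
  bound <- k_post == 0L
  fold <- if (!bound) {
    f_pre / f_post
  } else if (floor_policy == "detection_floor") {
    f_pre / (1 / post_n)
  } else NA_real_
  data.frame(clonotype_key = clonotype_key,
             count_pre = k_pre, n_pre = pre_n,
             count_post = k_post, n_post = post_n,
             freq_pre = f_pre, freq_post = f_post,
             fold_change = fold, fold_is_bound = bound,
             p_value = p, significant = p < alpha,
             stringsAsFactors = FALSE)
}

#' Screen for tumor-enriched clonotypes
#'
#' Returns the clonotypes detected in the tumor sample (at least two cells)
#' whose tumor frequency strictly exceeds their frequency in every
#' reference sample (e.g. adjacent tissue and blood), ranked by tumor
#' frequency descending with ties broken by clonotype key.
#'
#' @param ct a `clonotype_table`.
#' @param tumor_sample tumor sample id.
#' @param reference_samples character vector of reference sample ids
#'   (length >= 1).
#' @return a data.frame: `clonotype_key`, `tumor_count`, `tumor_freq`,
#'   `max_reference_freq`.
#' @export
enrichment_screen <- function(ct, tumor_sample, reference_samples) {
  stopifnot(inherits(ct, "clonotype_table"), length(reference_samples) >= 1L)
  ft <- clonotype_frequencies(ct, tumor_sample)
  ref <- vapply(reference_samples, function(s) clonotype_frequencies(ct, s),
                numeric(nrow(ct$clonotypes)))
  ref_max <- apply(matrix(ref, nrow = nrow(ct$clonotypes)), 1, max)
  keep <- ct$detected[, tumor_sample] & ft > ref_max
  out <- data.frame(clonotype_key = rownames(ct$counts)[keep],
                    tumor_count = ct$counts[keep, tumor_sample],
                    tumor_freq = ft[keep],
                    max_reference_freq = ref_max[keep],
                    stringsAsFactors = FALSE)
  out <- out[order(-out$tumor_freq, out$clonotype_key), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Match clonotypes to a bulk blood TRB repertoire
#'
#' Exact join on the TRB key (gene-level V/J plus junction). Clonotypes
#' absent from the bulk table are recorded as not detected with the bulk
#' detection floor; distinct clonotypes sharing one TRB key both map to the
#' same bulk frequency and are flagged ambiguous.
#'
#' @param ct a `clonotype_table`.
#' @param bulk data.frame with columns `v_call`, `j_call`, `junction_aa`,
#'   `frequency`.
#' @param detection_floor frequency reported for unmatched clonotypes;
#'   defaults to the smallest frequency present in `bulk`.
#' @return a data.frame: `clonotype_key`, `trb_key`, `bulk_frequency`,
#'   `detected_in_bulk`, `ambiguous_match`.
#' @export
match_bulk_trb <- function(ct, bulk, detection_floor = NULL) {
  stopifnot(inherits(ct, "clonotype_table"),
            all(c("v_call", "j_call", "junction_aa", "frequency") %in%
                  names(bulk)))
  bulk_key <- trb_key_of(bulk$v_call, bulk$j_call, bulk$junction_aa)
  if (is.null(detection_floor)) {
    detection_floor <- if (nrow(bulk) > 0) min(bulk$frequency) else NA_real_
  }
  meta <- ct$clonotypes
  hit <- match(meta$trb_key, bulk_key)
  shared <- meta$trb_key %in% meta$trb_key[duplicated(meta$trb_key)]
  data.frame(clonotype_key = meta$clonotype_key,
             trb_key = meta$trb_key,
             bulk_frequency = ifelse(is.na(hit), detection_floor,
                                     bulk$frequency[hit]),
             detected_in_bulk = !is.na(hit),
             ambiguous_match = shared & !is.na(hit),
             stringsAsFactors = FALSE)
}
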