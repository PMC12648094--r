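#' Deterministic single-patient repertoire fixture
#'
#' Builds, by construction rather than by sampling, a repertoire with the
#' shape of the best-characterized patient in the study this package is
#' modeled on: 48 clonotypes over 222 tumor cells carrying a TCR, single-cell
#' depths of 266 (pre-treatment tumor), 158 (pre-treatment adjacent bladder)
#' and 48 (post-treatment bladder), 6 planted tumor-enriched clonotypes
#' (each with at least 2 tumor cells, absent from the adjacent tissue, and
#' dropped at least 10-fold post-treatment), and every non-planted
#' tumor-detected clonotype at least as frequent in the adjacent tissue as
#' in the tumor, so an enrichment screen recovers exactly the planted set.
#'
#' Only the V/J/CDR3 labels are drawn from a fixed-seed RNG; all cell
#' counts are deterministic, so the guarantees above hold by construction.
#'
#' @param out_dir optional directory; when supplied, `rearrangements.tsv`,
#'   `samples.tsv` and `bulk_trb.tsv` are written there.
#' @return a list with `rearrangements`, `samples`, `bulk_trb`,
#'   `planted_enriched` (the 6 clonotype keys) and `tumor_cells` (222).
#' @export
uc1_like_fixture <- function(out_dir = NULL) {
  old <- .Random.seed_exists()
  on.exit(restore_rng(old), add = TRUE)
  set.seed(20200207L)

  n_cl <- 48L
  trb_v <- sample(TRBV_POOL, n_cl, TRUE)
  trb_j <- sample(TRBJ_POOL, n_cl, TRUE)
  trb_cdr3 <- random_junction(n_cl)
  tra_v <- sample(TRAV_POOL, n_cl, TRUE)
  tra_j <- sample(TRAJ_POOL, n_cl, TRUE)
  tra_cdr3 <- random_junction(n_cl, len = 12L)
  keys <- paste(trb_key_of(trb_v, trb_j, trb_cdr3),
                trb_key_of(tra_v, tra_j, tra_cdr3), sep = "+")

  # tumor: 222 cells in 48 clonotypes; the 6 planted ones are the largest
  planted_counts <- c(30L, 25L, 20L, 16L, 12L, 10L)        # 113 cells
  rest <- rep(1L, 42L)
  extra <- 222L - sum(planted_counts) - sum(rest)          # 67 to spread
  rest <- rest + as.integer(extra %/% 42L)
  topup <- extra %% 42L
  if (topup > 0L) rest[seq_len(topup)] <- rest[seq_len(topup)] + 1L
  tumor_counts <- c(planted_counts, rest)
  stopifnot(sum(tumor_counts) == 222L)

  # adjacent bladder: planted absent; every other clonotype gets its tumor
  # count, so its adjacent frequency (x/158) exceeds its tumor frequency
  # (x/266) and it cannot be called enriched
  adj_counts <- c(rep(0L, 6L), rest)                       # 109 <= 158 cells
  # post-treatment bladder (48 cells): planted absent (frequency below the
  # 1/48 detection floor, i.e. a >10-fold drop from >=10/266); a handful of
  # non-planted clonotypes reappear
  post_counts <- integer(n_cl)
  post_counts[7:14] <- 3L                                  # 24 <= 48 cells

  samples <- data.frame(
    sample_id = c("UC1_tumor", "UC1_adjacent", "UC1_postbcg"),
    patient = "UC1",
    compartment = c("tumor", "adjacent_bladder", "post_bcg_bladder"),
    timepoint = c("pre_bcg", "pre_bcg", "post_bcg"),
    n_cells = c(266L, 158L, 48L),
    stringsAsFactors = FALSE)

  counts <- cbind(UC1_tumor = tumor_counts, UC1_adjacent = adj_counts,
                  UC1_postbcg = post_counts)
  rearr <- list()
  cell_no <- 0L
  for (s in seq_len(nrow(samples))) {
    sid <- samples$sample_id[s]
    for (ci in which(counts[, s] > 0L)) {
      for (cell in seq_len(counts[ci, s])) {
        cell_no <- cell_no + 1L
        cid <- sprintf("UC1_c%04d", cell_no)
        rearr[[length(rearr) + 1L]] <- data.frame(
          cell_id = cid, sample_id = sid, locus = "TRB",
          v_call = paste0(trb_v[ci], "*01"),
          j_call = paste0(trb_j[ci], "*01"),
          junction_aa = trb_cdr3[ci], stringsAsFactors = FALSE)
        rearr[[length(rearr) + 1L]] <- data.frame(
          cell_id = cid, sample_id = sid, locus = "TRA",
          v_call = paste0(tra_v[ci], "*01"),
          j_call = paste0(tra_j[ci], "*01"),
          junction_aa = tra_cdr3[ci], stringsAsFactors = FALSE)
      }
    }
  }
  rearr <- do.call(rbind, rearr)

  # bulk blood TRB: planted clonotypes rare (1e-5), background higher
  bulk <- data.frame(
    v_call = trb_v, j_call = trb_j, junction_aa = trb_cdr3,
    frequency = c(rep(1e-5, 6L), rep(1e-3, n_cl - 6L)),
    stringsAsFactors = FALSE)

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.table(rearr, file.path(out_dir, "rearrangements.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(samples, file.path(out_dir, "samples.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(bulk, file.path(out_dir, "bulk_trb.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  list(rearrangements = rearr, samples = samples, bulk_trb = bulk,
       planted_enriched = keys[1:6], tumor_cells = 222L)
}
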