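# Synthetic cohort generator: a stand-in for controlled-access patient data
# with planted, machine-readable ground truth at every stage.

AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

HLA_POOL <- list(
  A = c("HLA-A*01:01", "HLA-A*02:01", "HLA-A*03:01", "HLA-A*24:02"),
  B = c("HLA-B*07:02", "HLA-B*08:01", "HLA-B*35:01", "HLA-B*44:02"),
  C = c("HLA-C*04:01", "HLA-C*05:01", "HLA-C*07:01", "HLA-C*07:02"))

TRBV_POOL <- sprintf("TRBV%d", c(2, 4, 5, 6, 7, 9, 11, 12, 19, 20, 27, 28))
TRBJ_POOL <- sprintf("TRBJ%d-%d", rep(1:2, c(6, 7)), c(1:6, 1:7))
TRAV_POOL <- sprintf("TRAV%d", c(1, 3, 8, 12, 13, 17, 21, 26, 29, 38))
TRAJ_POOL <- sprintf("TRAJ%d", c(6, 9, 15, 23, 28, 33, 42, 49))

#' Configuration for the synthetic cohort generator
#'
#' Defaults emulate the data shapes of a small single-center bladder-cancer
#' study: a per-tumor missense burden drawn from the published range 20-567
#' scaled down 1/10 for desk-scale runs, imperfect three-caller detection,
#' log-normal TPM expression, uniform surrogate binding ranks with planted
#' strong binders, Poisson ELISPOT backgrounds (3 replicate wells, 2
#' independent experiments) with planted responders at 3x the background
#' mean, and a 48-clonotype repertoire sampled at the published single-cell
#' depths (266 tumor / 158 adjacent / 48 post-treatment cells) with planted
#' tumor enrichment and planted 10-fold post-treatment drops.
#'
#' @param seed integer root seed; per-patient streams are derived from it
#'   with a documented counter scheme, so patient k is reproducible on its
#'   own.
#' @param n_patients number of patients, default 4.
#' @param proteome,variants,expression,epitopes,elispot,repertoire named
#'   lists overriding individual defaults (partial lists are merged).
#' @return an object of class `cohort_config`.
#' @export
cohort_config <- function(seed = 1L, n_patients = 4L,
                          proteome = list(), variants = list(),
                          expression = list(), epitopes = list(),
                          elispot = list(), repertoire = list()) {
  merge_defaults <- function(defaults, user) {
    stopifnot(all(names(user) %in% names(defaults)))
    defaults[names(user)] <- user
    defaults
  }
  cfg <- list(
    seed = as.integer(seed),
    n_patients = as.integer(n_patients),
    proteome = merge_defaults(list(n_genes = 60L, mean_length_aa = 300L),
                              proteome),
    variants = merge_defaults(list(
      mutations_range = c(2L, 57L),
      caller_sensitivities = c(mutect2 = 0.9, strelka2 = 0.85,
                               varscan2 = 0.8),
      caller_fpr = 0.05), variants),
    expression = merge_defaults(list(log_tpm_mean = 1, log_tpm_sd = 1.5),
                                expression),
    epitopes = merge_defaults(list(n_true_per_patient = 3L,
                                   forced_rank_pct = 0.1), epitopes),
    elispot = merge_defaults(list(neg_mean = 10, effect_multiplier = 3,
                                  n_replicates = 3L, n_experiments = 2L,
                                  overdispersion = 0, pool_size = 15L),
                             elispot),
    repertoire = merge_defaults(list(
      n_clonotypes = 48L, dirichlet_alpha = 0.5,
      depths = c(tumor = 266L, adjacent_bladder = 158L,
                 post_bcg_bladder = 48L),
      n_planted_enriched = 6L, planted_fold_drop = 10), repertoire))
  probs <- c(cfg$variants$caller_sensitivities, cfg$variants$caller_fpr)
  if (any(probs < 0 | probs > 1)) {
    stop("caller sensitivities and FPR must lie in [0, 1]", call. = FALSE)
  }
  if (any(cfg$repertoire$depths < 1)) stop("depths must be >= 1",
                                           call. = FALSE)
  if (cfg$repertoire$n_planted_enriched > cfg$repertoire$n_clonotypes) {
    stop("more planted clonotypes than clonotypes", call. = FALSE)
  }
  structure(cfg, class = "cohort_config")
}

draw_spots <- function(n, mean, overdispersion) {
  if (overdispersion > 0) {
    stats::rnbinom(n, mu = mean, size = 1 / overdispersion)
  } else {
    stats::rpois(n, mean)
  }
}

rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  if (sum(g) == 0) g <- rep(1, length(alpha))
  g / sum(g)
}

random_junction <- function(n, len = 13L) {
  vapply(seq_len(n), function(i) {
    paste0("CASS", paste(sample(AA20, len - 5L, TRUE), collapse = ""), "F")
  }, character(1))
}

#' Generate a synthetic patient cohort with planted ground truth
#'
#' Writes, per patient, a protein FASTA, a multi-caller somatic variant
#' table, a TPM expression table, an HLA genotype, a surrogate peptide-HLA
#' rank table with planted strong binders, ELISPOT plate CSVs with planted
#' responder pools/peptides, single-cell TCR rearrangement and sample
#' tables with planted tumor-enriched and post-treatment-dropped
#' clonotypes, and a bulk blood TRB table -- plus a cohort-level
#' `ground_truth.json`. Every file round-trips through the package's own
#' readers. A fixed seed yields byte-identical bundles.
#'
#' @param config a [cohort_config()].
#' @param out_dir output directory (created if needed).
#' @return invisibly, a list with `dir`, `patients` and `truth` (the ground
#'   truth also serialized as JSON).
#' @export
generate_cohort <- function(config = cohort_config(), out_dir) {
  stopifnot(inherits(config, "cohort_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  truth <- list()
  patients <- sprintf("P%02d", seq_len(config$n_patients))
  for (p in seq_len(config$n_patients)) {
    truth[[patients[p]]] <-
      generate_patient(config, child_seed(config$seed, p),
                       patients[p], file.path(out_dir, patients[p]))
  }
  jsonlite::write_json(truth, file.path(out_dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(dir = out_dir, patients = patients, truth = truth))
}

generate_patient <- function(config, seed, patient_id, pdir) {
  dir.create(pdir, showWarnings = FALSE, recursive = TRUE)
  set.seed(seed)
  pc <- config$proteome

  ## proteome ---------------------------------------------------------------
  n_genes <- pc$n_genes
  lens <- pmax(40L, stats::rpois(n_genes, pc$mean_length_aa))
  gene_ids <- sprintf("GENE%04d", seq_len(n_genes))
  prot_ids <- sprintf("PROT%04d", seq_len(n_genes))
  seqs <- vapply(lens, function(L) paste(sample(AA20, L, TRUE), collapse = ""),
                 character(1))
  names(seqs) <- prot_ids
  Biostrings::writeXStringSet(Biostrings::AAStringSet(seqs),
                              file.path(pdir, "proteome.fasta"), width = 60L)

  ## somatic variants with imperfect multi-caller detection -----------------
  vc <- config$variants
  callers <- names(vc$caller_sensitivities)
  rng <- vc$mutations_range
  n_mut <- sample(seq(rng[1], rng[2]), 1L)
  gi <- sample(n_genes, n_mut, replace = n_mut > n_genes)
  pos <- vapply(gi, function(i) sample(lens[i], 1L), integer(1))
  aa_ref <- substr(seqs[gi], pos, pos)
  aa_alt <- vapply(aa_ref, function(a) sample(setdiff(AA20, a), 1L),
                   character(1), USE.NAMES = FALSE)
  support <- vapply(callers, function(cl) {
    stats::rbinom(n_mut, 1L, vc$caller_sensitivities[[cl]]) == 1L
  }, logical(n_mut))
  support <- matrix(support, nrow = n_mut,
                    dimnames = list(NULL, callers))
  detected <- rowSums(support) > 0L
  rows <- data.frame(
    gene_id = gene_ids[gi], protein_id = prot_ids[gi], protein_pos = pos,
    aa_ref = unname(aa_ref), aa_alt = aa_alt,
    callers = apply(support, 1, function(s) paste(callers[s], collapse = ";")),
    variant_class = "missense", stringsAsFactors = FALSE)[detected, ]
  # caller-private false positives plus a couple of non-missense calls
  fp_rows <- list()
  for (cl in callers) {
    n_fp <- stats::rpois(1L, vc$caller_fpr * n_mut)
    if (n_fp == 0L) next
    fgi <- sample(n_genes, n_fp, replace = TRUE)
    fpos <- vapply(fgi, function(i) sample(lens[i], 1L), integer(1))
    fref <- substr(seqs[fgi], fpos, fpos)
    falt <- vapply(fref, function(a) sample(setdiff(AA20, a), 1L),
                   character(1), USE.NAMES = FALSE)
    fp_rows[[cl]] <- data.frame(
      gene_id = gene_ids[fgi], protein_id = prot_ids[fgi], protein_pos = fpos,
      aa_ref = unname(fref), aa_alt = falt, callers = cl,
      variant_class = "missense", stringsAsFactors = FALSE)
  }
  other <- data.frame(
    gene_id = gene_ids[1:2], protein_id = prot_ids[1:2],
    protein_pos = c(1L, 2L), aa_ref = substr(seqs[1:2], c(1, 2), c(1, 2)),
    aa_alt = substr(seqs[1:2], c(1, 2), c(1, 2)),
    callers = paste(callers, collapse = ";"),
    variant_class = "other", stringsAsFactors = FALSE)
  var_tab <- do.call(rbind, c(list(rows), fp_rows, list(other)))
  utils::write.table(var_tab, file.path(pdir, "variants.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  ## expression -------------------------------------------------------------
  ec <- config$expression
  tpm <- stats::rlnorm(n_genes, ec$log_tpm_mean, ec$log_tpm_sd)
  utils::write.table(data.frame(gene_id = gene_ids, tpm = tpm),
                     file.path(pdir, "expression.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  tpm_vec <- stats::setNames(tpm, gene_ids)

  ## HLA genotype -----------------------------------------------------------
  alleles <- c(sample(HLA_POOL$A, 2L), sample(HLA_POOL$B, 2L),
               sample(HLA_POOL$C, 2L))
  writeLines(alleles, file.path(pdir, "hla.txt"))
  hla <- hla_genotype(alleles)

  ## candidate scoring with planted strong binders --------------------------
  cons_cfg <- consensus_config(caller_universe = callers)
  variants <- read_variants(file.path(pdir, "variants.tsv"), cons_cfg)
  cons <- consensus_filter(variants, cons_cfg)
  pairs <- peptide_candidates(cons, seqs)
  epc <- config$epitopes
  eligible <- which(cons$gene_id %in% names(tpm_vec)[tpm_vec > 1])
  chosen <- head(eligible, epc$n_true_per_patient)
  planted <- vapply(chosen, function(i) {
    sub <- pairs[pairs$protein_id == cons$protein_id[i] &
                   pairs$protein_pos == cons$protein_pos[i] &
                   pairs$length == 9L, , drop = FALSE]
    sub$mut_peptide[ceiling(nrow(sub) / 2)]
  }, character(1))
  provider <- rank_provider_planted(rank_provider_surrogate(seed), planted,
                                    epc$forced_rank_pct)
  scored <- score_candidates(pairs, hla, provider, tpm_vec)
  utils::write.table(
    data.frame(peptide = scored$mut_peptide, allele = scored$allele,
               rank_pct = scored$rank_pct),
    file.path(pdir, "ranks.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  selected <- select_candidates(scored, selection_config("threshold"))

  ## ELISPOT plates with planted responders ---------------------------------
  el <- config$elispot
  pools <- suppressWarnings(assign_pools(unique(selected$mut_peptide),
                                         el$pool_size, seed = seed))
  responder_pools <- names(pools)[vapply(pools, function(m)
    any(m %in% planted), logical(1))]
  plate <- list()
  add_row <- function(eid, cid, kind, members, mean_spots) {
    plate[[length(plate) + 1L]] <<- data.frame(
      experiment_id = eid, sample_source = "TIL", condition_id = cid,
      kind = kind, members = paste(members, collapse = ";"),
      t(stats::setNames(draw_spots(el$n_replicates, mean_spots,
                                   el$overdispersion),
                        sprintf("well_%d", seq_len(el$n_replicates)))),
      stringsAsFactors = FALSE)
  }
  for (e in seq_len(el$n_experiments)) {
    eid <- sprintf("E%d", e)
    add_row(eid, "neg_ctrl", "negative_control", character(), el$neg_mean)
    add_row(eid, "pos_ctrl", "positive_control", character(),
            el$neg_mean * 20)
    for (pid in names(pools)) {
      hot <- pid %in% responder_pools
      add_row(eid, pid, "pool", pools[[pid]],
              el$neg_mean * if (hot) el$effect_multiplier else 1)
    }
    for (pid in responder_pools) {
      for (m in pools[[pid]]) {
        add_row(eid, m, "single_peptide", m,
                el$neg_mean * if (m %in% planted) el$effect_multiplier else 1)
      }
    }
  }
  plate <- do.call(rbind, plate)
  utils::write.csv(plate, file.path(pdir, "elispot_plates.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.table(
    data.frame(pool_id = names(pools),
               members = vapply(pools, paste, character(1), collapse = ";")),
    file.path(pdir, "pools.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)

  ## single-cell TCR repertoire with planted enrichment and drops -----------
  rp <- config$repertoire
  if (!identical(names(rp$depths),
                 c("tumor", "adjacent_bladder", "post_bcg_bladder"))) {
    stop("repertoire depths must be named tumor, adjacent_bladder, ",
         "post_bcg_bladder", call. = FALSE)
  }
  n_cl <- rp$n_clonotypes
  trb_v <- sample(TRBV_POOL, n_cl, TRUE); trb_j <- sample(TRBJ_POOL, n_cl, TRUE)
  trb_cdr3 <- random_junction(n_cl)
  tra_v <- sample(TRAV_POOL, n_cl, TRUE); tra_j <- sample(TRAJ_POOL, n_cl, TRUE)
  tra_cdr3 <- random_junction(n_cl, len = 12L)
  k <- rp$n_planted_enriched
  f_enr <- 0.12 * 0.8^(seq_len(k) - 1)
  base <- rdirichlet1(rep(rp$dirichlet_alpha, n_cl - k))
  freq_tumor <- c(f_enr, (1 - sum(f_enr)) * base)
  freq_adj <- c(rep(0, k), rdirichlet1(rep(rp$dirichlet_alpha, n_cl - k)))
  f_post_enr <- f_enr / rp$planted_fold_drop
  freq_post <- c(f_post_enr, (1 - sum(f_post_enr)) * base)
  depths <- rp$depths
  sample_ids <- paste(patient_id, names(depths), sep = "_")
  timepoints <- ifelse(grepl("post", names(depths)), "post_bcg", "pre_bcg")
  samples <- data.frame(sample_id = sample_ids, patient = patient_id,
                        compartment = names(depths), timepoint = timepoints,
                        n_cells = as.integer(depths),
                        stringsAsFactors = FALSE)
  freqs <- list(freq_tumor, freq_adj, freq_post)
  rearr <- list()
  for (s in seq_along(sample_ids)) {
    cnt <- as.integer(stats::rmultinom(1, depths[s], freqs[[s]]))
    for (ci in which(cnt > 0L)) {
      for (cell in seq_len(cnt[ci])) {
        cell_id <- sprintf("%s_c%04d", sample_ids[s],
                           length(rearr) %/% 2L + 1L)
        rearr[[length(rearr) + 1L]] <- data.frame(
          cell_id = cell_id, sample_id = sample_ids[s], locus = "TRB",
          v_call = paste0(trb_v[ci], "*01"), j_call = paste0(trb_j[ci], "*01"),
          junction_aa = trb_cdr3[ci], stringsAsFactors = FALSE)
        rearr[[length(rearr) + 1L]] <- data.frame(
          cell_id = cell_id, sample_id = sample_ids[s], locus = "TRA",
          v_call = paste0(tra_v[ci], "*01"), j_call = paste0(tra_j[ci], "*01"),
          junction_aa = tra_cdr3[ci], stringsAsFactors = FALSE)
      }
    }
  }
  rearr <- do.call(rbind, rearr)
  utils::write.table(rearr, file.path(pdir, "rearrangements.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(samples, file.path(pdir, "samples.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  # bulk blood TRB repertoire: planted clonotypes diluted 50-fold in blood
  bulk_freq <- c(f_enr / 50, (1 - sum(f_enr / 50)) *
                   rdirichlet1(rep(rp$dirichlet_alpha, n_cl - k)))
  utils::write.table(
    data.frame(v_call = trb_v, j_call = trb_j, junction_aa = trb_cdr3,
               frequency = bulk_freq),
    file.path(pdir, "bulk_trb.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)

  keys <- paste(trb_key_of(trb_v, trb_j, trb_cdr3),
                trb_key_of(tra_v, tra_j, tra_cdr3), sep = "+")
  list(
    seed = seed,
    n_true_variants = n_mut,
    true_variant_keys = as.list(paste(prot_ids[gi], pos, aa_alt, sep = "|")),
    true_epitopes = as.list(planted),
    responder_pools = as.list(responder_pools),
    enriched_clonotypes = as.list(keys[seq_len(k)]),
    dropped_clonotypes = as.list(keys[seq_len(k)]))
}
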