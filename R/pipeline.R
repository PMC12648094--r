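#' Run configuration for the end-to-end pipeline
#'
#' @param input_dir cohort directory: one subdirectory per patient
#'   containing `variants.tsv`, `proteome.fasta`, `expression.tsv`,
#'   `hla.txt`, `ranks.tsv` and optionally `elispot_plates.csv` +
#'   `pools.tsv` and `rearrangements.tsv` + `samples.tsv` (+
#'   `bulk_trb.tsv`), i.e. the layout written by [generate_cohort()].
#' @param out_dir directory for per-stage outputs and `summary.json`.
#' @param caller_universe,min_callers consensus rule (see
#'   [consensus_config()]).
#' @param selection a [selection_config()].
#' @param alpha significance level for clonotype frequency tests.
#' @param sd_floor ELISPOT negative-control SD floor.
#' @param seed integer seed (reserved for stages with randomized order).
#' @return an object of class `run_config`.
#' @export
run_config <- function(input_dir, out_dir,
                       caller_universe = c("mutect2", "strelka2", "varscan2"),
                       min_callers = 2L,
                       selection = selection_config("threshold"),
                       alpha = 0.05, sd_floor = 0, seed = 1L) {
  if (!dir.exists(input_dir)) stop("input_dir not found: ", input_dir,
                                   call. = FALSE)
  structure(list(input_dir = input_dir, out_dir = out_dir,
                 consensus = consensus_config(caller_universe, min_callers),
                 selection = selection, alpha = alpha, sd_floor = sd_floor,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Load a run configuration from a YAML file
#'
#' Recognized keys: `input_dir`, `out_dir`, `caller_universe`,
#' `min_callers`, `selection` (`mode`, `rank_threshold_pct`,
#' `tpm_threshold`, `n_top`), `alpha`, `sd_floor`, `seed`.
#'
#' @param path YAML file.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  sel <- do.call(selection_config, y$selection %||% list())
  run_config(input_dir = y$input_dir, out_dir = y$out_dir,
             caller_universe = y$caller_universe %||%
               c("mutect2", "strelka2", "varscan2"),
             min_callers = y$min_callers %||% 2L,
             selection = sel, alpha = y$alpha %||% 0.05,
             sd_floor = y$sd_floor %||% 0, seed = y$seed %||% 1L)
}

#' Run the screening pipeline end to end
#'
#' For every patient subdirectory of `input_dir`: consensus-filters the
#' variant table, enumerates mutant/wild-type peptide pairs, scores them
#' against the patient's HLA alleles with the precomputed rank table,
#' applies candidate selection, then (when the respective inputs exist)
#' calls ELISPOT responses and deconvolutes confirmed pools, and tracks
#' clonotype frequencies across timepoints. Per-stage TSVs are written
#' under `out_dir/<patient>/`, record counts are logged to stderr so
#' filter attrition is auditable, and a cohort `summary.json` is written.
#' A patient is flagged `response_detected` when at least one antigen
#' (pool or single peptide) is confirmed in at least two experiments.
#' Re-running with identical inputs and seed reproduces identical outputs.
#'
#' @param config a [run_config()] (or path to a YAML file for
#'   [read_run_config()]).
#' @param quiet suppress progress logging.
#' @return invisibly, the summary list.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  log_msg <- function(...) if (!quiet) message("[neoscreen] ", ...)
  patients <- sort(list.dirs(config$input_dir, recursive = FALSE,
                             full.names = FALSE))
  if (length(patients) == 0L) stop("no patient subdirectories in ",
                                   config$input_dir, call. = FALSE)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  summary <- list(schema_version = "1.0", patients = list())
  for (pt in patients) {
    pin <- file.path(config$input_dir, pt)
    pout <- file.path(config$out_dir, pt)
    dir.create(pout, showWarnings = FALSE, recursive = TRUE)
    psum <- list(patient = pt)

    ## candidates ----------------------------------------------------------
    variants <- read_variants(file.path(pin, "variants.tsv"),
                              config$consensus)
    cons <- consensus_filter(variants, config$consensus)
    log_msg(pt, ": variants ", nrow(variants), " -> consensus ", nrow(cons))
    proteome <- read_proteome(file.path(pin, "proteome.fasta"))
    pairs <- peptide_candidates(cons, proteome)
    hla <- hla_genotype(readLines(file.path(pin, "hla.txt")))
    provider <- rank_provider_table(file.path(pin, "ranks.tsv"))
    expr_path <- file.path(pin, "expression.tsv")
    expr <- if (file.exists(expr_path)) read_expression(expr_path) else NULL
    scored <- score_candidates(pairs, hla, provider, expr)
    selected <- select_candidates(scored, config$selection)
    log_msg(pt, ": peptide pairs ", nrow(pairs), " -> scored ",
            nrow(scored), " -> selected ", nrow(selected))
    utils::write.table(selected, file.path(pout, "candidates.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    psum$n_variants <- nrow(variants)
    psum$n_consensus <- nrow(cons)
    psum$n_peptide_pairs <- nrow(pairs)
    psum$n_selected <- nrow(selected)

    ## ELISPOT screening ----------------------------------------------------
    plate_path <- file.path(pin, "elispot_plates.csv")
    if (file.exists(plate_path)) {
      plates <- read_elispot_plates(plate_path)
      calls <- screen_antigens(plates, sd_floor = config$sd_floor)
      kinds <- vapply(calls, function(x) x$kind, character(1))
      pools_path <- file.path(pin, "pools.tsv")
      pools <- if (file.exists(pools_path)) {
        pt_tab <- read_dialect_table(pools_path, c("pool_id", "members"))
        stats::setNames(strsplit(pt_tab$members, ";", fixed = TRUE),
                        pt_tab$pool_id)
      } else {
        lapply(calls[kinds == "pool"], function(x) x$members)
      }
      report <- suppressWarnings(
        deconvolute(calls[kinds == "pool"], calls[kinds == "single_peptide"],
                    pools))
      call_tab <- do.call(rbind, lapply(calls, function(x) data.frame(
        antigen_id = x$antigen_id, kind = x$kind,
        n_positive = x$n_positive, confirmed = x$confirmed,
        status = x$status, stringsAsFactors = FALSE)))
      utils::write.table(call_tab, file.path(pout, "response_calls.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      utils::write.table(report$attributions,
                         file.path(pout, "deconvolution.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      psum$n_antigens_tested <- length(calls)
      psum$n_confirmed <- sum(call_tab$confirmed)
      psum$confirmed_peptides <- report$attributions$peptide
      psum$unresolved_pools <- report$unresolved_pools
      psum$response_detected <- any(call_tab$confirmed)
      log_msg(pt, ": ", length(calls), " antigens tested, ",
              sum(call_tab$confirmed), " confirmed")
    } else {
      log_msg(pt, ": no ELISPOT inputs; screening stages skipped")
    }

    ## clonotype tracking ---------------------------------------------------
    rearr_path <- file.path(pin, "rearrangements.tsv")
    if (file.exists(rearr_path)) {
      rearr <- read_rearrangements(rearr_path)
      samples <- read_samples(file.path(pin, "samples.tsv"))
      ct <- build_clonotype_table(rearr, samples)
      pre <- samples$sample_id[samples$compartment == "tumor" &
                                 samples$timepoint == "pre_bcg"]
      post <- samples$sample_id[samples$timepoint == "post_bcg"]
      comp <- NULL
      if (length(pre) == 1L && length(post) >= 1L) {
        keys <- rownames(ct$counts)[ct$detected[, pre] |
                                      ct$detected[, post[1]]]
        comp <- do.call(rbind, lapply(keys, function(k)
          compare_timepoints(ct, k, pre, post[1], alpha = config$alpha)))
        utils::write.table(comp, file.path(pout, "clonotype_comparison.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        refs <- samples$sample_id[samples$sample_id != pre &
                                    samples$timepoint == "pre_bcg"]
        if (length(refs) >= 1L) {
          enr <- enrichment_screen(ct, pre, refs)
          utils::write.table(enr, file.path(pout, "enriched_clonotypes.tsv"),
                             sep = "\t", quote = FALSE, row.names = FALSE)
          psum$n_enriched <- nrow(enr)
        }
      }
      psum$n_clonotypes <- nrow(ct$clonotypes)
      psum$n_significant_shifts <- if (is.null(comp)) 0L else
        sum(comp$significant)
      log_msg(pt, ": ", nrow(ct$clonotypes), " clonotypes, ",
              psum$n_significant_shifts, " significant frequency shifts")
    }
    summary$patients[[pt]] <- psum
  }
  summary$n_patients <- length(patients)
  summary$n_response_detected <- sum(vapply(
    summary$patients, function(x) isTRUE(x$response_detected), logical(1)))
  jsonlite::write_json(summary, file.path(config$out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(summary)
}
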