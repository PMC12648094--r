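# Operating-characteristic simulations for the screening rules. These are
# part of the package surface so the same machinery that analyses data can
# also report its own false-positive and recovery rates.

#' False-positive rate of the ELISPOT caller under the null
#'
#' Simulates screens in which every antigen is unstimulated background:
#' negative-control and antigen wells are drawn from the same Poisson (or
#' negative-binomial) law. Reports the per-antigen single-experiment
#' positive rate alongside the rate of antigens confirmed in >= 2
#' independent experiments, quantifying how much the confirmation
#' requirement suppresses false positives.
#'
#' @param n_screens number of simulated screens, default 200.
#' @param n_antigens antigens per screen, default 100.
#' @param neg_mean background mean spot count, default 10.
#' @param n_replicates replicate wells per condition, default 3.
#' @param n_experiments independent experiments per screen, default 2.
#' @param overdispersion negative-binomial overdispersion (0 = Poisson).
#' @param sd_floor negative-control SD floor for [call_experiment()].
#' @param seed integer seed.
#' @return a list with `single_rate`, `confirmed_rate`, `n_single_calls`,
#'   `n_antigen_calls`.
#' @export
elispot_null_fpr <- function(n_screens = 200L, n_antigens = 100L,
                             neg_mean = 10, n_replicates = 3L,
                             n_experiments = 2L, overdispersion = 0,
                             sd_floor = 0, seed = 1L) {
  set.seed(as.integer(seed))
  single_pos <- 0L; confirmed <- 0L
  for (s in seq_len(n_screens)) {
    pos_per_antigen <- integer(n_antigens)
    for (e in seq_len(n_experiments)) {
      neg <- draw_spots(n_replicates, neg_mean, overdispersion)
      for (a in seq_len(n_antigens)) {
        stim <- draw_spots(n_replicates, neg_mean, overdispersion)
        if (call_experiment(stim, neg, sd_floor = sd_floor)$positive) {
          pos_per_antigen[a] <- pos_per_antigen[a] + 1L
          single_pos <- single_pos + 1L
        }
      }
    }
    confirmed <- confirmed + sum(pos_per_antigen >= 2L)
  }
  list(single_rate = single_pos / (n_screens * n_antigens * n_experiments),
       confirmed_rate = confirmed / (n_screens * n_antigens),
       n_single_calls = n_screens * n_antigens * n_experiments,
       n_antigen_calls = n_screens * n_antigens)
}

#' Recovery rate of planted responders through call and deconvolution
#'
#' Simulates screens each containing one responder peptide inside a pool:
#' the pool and the responder's single-peptide wells draw from the effect
#' mean, all other conditions from background. Each screen is processed
#' with the package's own calling chain ([screen_antigens()] then
#' [deconvolute()]); a screen counts as recovered when the planted peptide
#' is attributed to its confirmed pool, which requires both the pool and
#' the single peptide to be positive in at least two experiments.
#'
#' @inheritParams elispot_null_fpr
#' @param pool_size peptides per pool, default 15.
#' @param effect_mean stimulated-well mean; default
#'   `neg_mean + 6 * sqrt(neg_mean)`, i.e. six background standard
#'   deviations above background.
#' @return a list with `recovery_rate`, `pool_confirm_rate`, `n_screens`.
#' @export
elispot_recovery <- function(n_screens = 200L, pool_size = 15L,
                             neg_mean = 10,
                             effect_mean = neg_mean + 6 * sqrt(neg_mean),
                             n_replicates = 3L, n_experiments = 2L,
                             overdispersion = 0, sd_floor = 0, seed = 1L) {
  set.seed(as.integer(seed))
  members <- sprintf("pep%02d", seq_len(pool_size))
  planted <- members[1]
  pools <- list(pool_01 = members)
  recovered <- 0L; pool_confirmed <- 0L
  for (s in seq_len(n_screens)) {
    rows <- list()
    add <- function(eid, cid, kind, mem, mean_spots) {
      rows[[length(rows) + 1L]] <<- data.frame(
        experiment_id = eid, sample_source = "TIL", condition_id = cid,
        kind = kind, members = paste(mem, collapse = ";"),
        stringsAsFactors = FALSE)
      attr(rows[[length(rows)]], "spots") <<-
        draw_spots(n_replicates, mean_spots, overdispersion)
    }
    for (e in seq_len(n_experiments)) {
      eid <- sprintf("E%d", e)
      add(eid, "neg", "negative_control", character(), neg_mean)
      add(eid, "pool_01", "pool", members, effect_mean)
      for (m in members) {
        add(eid, m, "single_peptide", m,
            if (m == planted) effect_mean else neg_mean)
      }
    }
    plates <- do.call(rbind, rows)
    plates$spot_counts <- I(lapply(rows, attr, "spots"))
    calls <- screen_antigens(plates, sd_floor = sd_floor)
    kinds <- vapply(calls, function(x) x$kind, character(1))
    rep <- deconvolute(calls[kinds == "pool"],
                       calls[kinds == "single_peptide"], pools)
    if (calls$pool_01$confirmed) pool_confirmed <- pool_confirmed + 1L
    if (planted %in% rep$attributions$peptide) recovered <- recovered + 1L
  }
  list(recovery_rate = recovered / n_screens,
       pool_confirm_rate = pool_confirmed / n_screens,
       n_screens = n_screens)
}

#' Power to flag planted clonotype frequency drops
#'
#' For clonotypes planted at pre-treatment frequencies `freqs_pre` that
#' drop `fold_drop`-fold post-treatment, computes (a) the exact predicted
#' power of the two-sided Fisher test at level `alpha` -- summing binomial
#' sampling probabilities of all (pre, post) count pairs whose test
#' rejects -- and (b) the empirical flag rate over `n_sims` simulated
#' repertoires with multinomial cell sampling at the given depths, analysed
#' with [compare_timepoints()].
#'
#' @param freqs_pre numeric vector of planted pre-treatment frequencies.
#' @param fold_drop fold decrease post-treatment, default 10.
#' @param depths named vector `c(pre = ..., post = ...)` of cells sampled
#'   per timepoint.
#' @param n_sims simulated repertoires, default 200.
#' @param alpha significance level, default 0.05.
#' @param seed integer seed for the empirical half.
#' @return a list with `predicted` (per-clonotype exact powers),
#'   `predicted_mean`, `empirical` (overall flag rate), `n_sims`.
#' @export
clonotype_drop_power <- function(freqs_pre, fold_drop = 10,
                                 depths = c(pre = 266L, post = 48L),
                                 n_sims = 200L, alpha = 0.05, seed = 1L) {
  stopifnot(all(freqs_pre > 0), sum(freqs_pre) < 1)
  n_pre <- as.integer(depths[["pre"]]); n_post <- as.integer(depths[["post"]])
  freqs_post <- freqs_pre / fold_drop

  predicted <- vapply(seq_along(freqs_pre), function(i) {
    f1 <- freqs_pre[i]; f2 <- freqs_post[i]
    xs <- max(0, stats::qbinom(1e-12, n_pre, f1)):
      stats::qbinom(1 - 1e-12, n_pre, f1)
    ys <- 0:stats::qbinom(1 - 1e-12, n_post, f2)
    px <- stats::dbinom(xs, n_pre, f1)
    py <- stats::dbinom(ys, n_post, f2)
    pow <- 0
    for (xi in seq_along(xs)) {
      for (yi in seq_along(ys)) {
        x <- xs[xi]; y <- ys[yi]
        if (x == 0 && y == 0) next   # undefined comparison, skipped
        p <- fisher_exact_2x2(x, n_pre - x, y, n_post - y)
        if (p < alpha) pow <- pow + px[xi] * py[yi]
      }
    }
    pow
  }, numeric(1))

  set.seed(as.integer(seed))
  k <- length(freqs_pre)
  flags <- 0L; tested <- 0L
  for (s in seq_len(n_sims)) {
    cnt_pre <- as.integer(stats::rmultinom(
      1, n_pre, c(freqs_pre, 1 - sum(freqs_pre))))[seq_len(k)]
    cnt_post <- as.integer(stats::rmultinom(
      1, n_post, c(freqs_post, 1 - sum(freqs_post))))[seq_len(k)]
    counts <- cbind(pre = cnt_pre, post = cnt_post)
    rownames(counts) <- sprintf("planted%02d", seq_len(k))
    ct <- structure(list(
      clonotypes = data.frame(clonotype_key = rownames(counts),
                              trb_key = rownames(counts),
                              tra_key = NA_character_,
                              ambiguous_trb = FALSE,
                              stringsAsFactors = FALSE),
      counts = counts, detected = counts >= 2L,
      samples = data.frame(sample_id = c("pre", "post"), patient = "sim",
                           compartment = c("tumor", "post_bcg_bladder"),
                           timepoint = c("pre_bcg", "post_bcg"),
                           n_cells = c(n_pre, n_post),
                           stringsAsFactors = FALSE)),
      class = "clonotype_table")
    for (key in rownames(counts)) {
      r <- compare_timepoints(ct, key, "pre", "post", alpha = alpha)
      if (is.null(r)) next
      tested <- tested + 1L
      if (r$significant) flags <- flags + 1L
    }
  }
  # clonotypes unseen at both timepoints yield no test; they count as
  # unflagged so the empirical rate is comparable to the prediction
  list(predicted = predicted, predicted_mean = mean(predicted),
       empirical = flags / (n_sims * k), n_sims = n_sims)
}
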