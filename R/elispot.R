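#' Read ELISPOT plate data
#'
#' Expects a CSV with columns `experiment_id`, `sample_source`,
#' `condition_id`, `kind` (one of `negative_control`, `pool`,
#' `single_peptide`, `positive_control`), `members` (semicolon-separated
#' peptide ids, empty for controls) and one or more replicate well columns
#' named `well_1`, `well_2`, ... Wells left blank (NA) are treated as not
#' plated, so conditions may have different replicate numbers.
#'
#' @param path path to the plate CSV.
#' @return a data.frame with a list-column `spot_counts`; class
#'   `elispot_plates`.
#' @export
read_elispot_plates <- function(path) {
  req <- c("experiment_id", "sample_source", "condition_id", "kind", "members")
  df <- read_dialect_table(path, required = req)
  wells <- grep("^well", names(df), value = TRUE)
  if (length(wells) == 0L) stop("no replicate well columns in ", path,
                                call. = FALSE)
  counts <- lapply(seq_len(nrow(df)), function(i) {
    x <- suppressWarnings(as.numeric(df[i, wells]))
    x <- x[!is.na(x)]
    if (any(x < 0) || any(x != round(x))) {
      stop("spot counts must be non-negative integers (row ", i, " of ",
           path, ")", call. = FALSE)
    }
    as.integer(x)
  })
  out <- df[req]
  out$members <- as.character(out$members)
  out$spot_counts <- I(counts)
  validate_plates(out)
}

validate_plates <- function(plates) {
  kinds <- c("negative_control", "pool", "single_peptide", "positive_control")
  if (!all(plates$kind %in% kinds)) {
    stop("unknown condition kind: ",
         paste(setdiff(plates$kind, kinds), collapse = ", "), call. = FALSE)
  }
  for (e in unique(plates$experiment_id)) {
    sub <- plates[plates$experiment_id == e, ]
    neg <- sub[sub$kind == "negative_control", ]
    if (nrow(neg) != 1L) {
      stop("experiment ", e, " must have exactly one negative control",
           call. = FALSE)
    }
    if (length(neg$spot_counts[[1]]) < 2L) {
      stop("experiment ", e,
           ": negative control needs >= 2 replicate wells (SD undefined)",
           call. = FALSE)
    }
  }
  class(plates) <- c("elispot_plates", "data.frame")
  plates
}

#' Group candidate peptides into screening pools
#'
#' Deterministically chunks the peptide list (optionally after a seeded
#' shuffle) into pools of `pool_size`; a trailing remainder pool with fewer
#' than 2 members is merged into the previous pool. Screening practice uses
#' pools of 10 to 20 peptides; sizes outside those bounds trigger a
#' warning, not an error.
#'
#' @param peptides character vector of peptide ids.
#' @param pool_size target pool size, default 15.
#' @param seed optional integer; when supplied the peptide order is
#'   shuffled reproducibly before chunking.
#' @return a named list `pool_id -> character vector of members`.
#' @export
assign_pools <- function(peptides, pool_size = 15L, seed = NULL) {
  peptides <- as.character(peptides)
  if (length(peptides) == 0L) return(structure(list(), names = character()))
  if (anyDuplicated(peptides)) stop("duplicate peptide ids", call. = FALSE)
  pool_size <- as.integer(pool_size)
  if (pool_size < 1L) stop("pool_size must be >= 1", call. = FALSE)
  if (pool_size < 10L || pool_size > 20L) {
    warning("pool_size ", pool_size, " outside the usual 10-20 range",
            call. = FALSE)
  }
  if (!is.null(seed)) {
    peptides <- local({
      old <- .Random.seed_exists()
      on.exit(restore_rng(old), add = TRUE)
      set.seed(as.integer(seed))
      sample(peptides)
    })
  }
  idx <- ceiling(seq_along(peptides) / pool_size)
  pools <- split(peptides, idx)
  np <- length(pools)
  if (np > 1L && length(pools[[np]]) < 2L) {
    pools[[np - 1L]] <- c(pools[[np - 1L]], pools[[np]])
    pools[[np]] <- NULL
    np <- np - 1L
  }
  if (np == 1L && length(pools[[1]]) < 2L) {
    warning("single pool with fewer than 2 peptides", call. = FALSE)
  }
  names(pools) <- sprintf("pool_%02d", seq_len(np))
  pools
}

.Random.seed_exists <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Call one stimulated condition against its negative control
#'
#' A condition is positive within an experiment when the mean spot count of
#' its replicate wells strictly exceeds the negative-control mean by more
#' than three negative-control standard deviations (sample SD, n-1
#' denominator): `mean(stim) > mean(neg) + 3 * max(sd(neg), sd_floor)`.
#'
#' @param stim_counts integer vector of replicate spot counts for the
#'   stimulated condition (length >= 1).
#' @param neg_counts integer vector of negative-control replicate counts
#'   (length >= 2, otherwise the SD is undefined and an error is raised).
#' @param sd_floor lower bound applied to the negative-control SD, default
#'   0 (no floor); guards against all-identical negative wells.
#' @return a list with `stim_mean`, `neg_mean`, `neg_sd`, `threshold`,
#'   `positive`.
#' @export
call_experiment <- function(stim_counts, neg_counts, sd_floor = 0) {
  if (length(stim_counts) < 1L) stop("no stimulated wells", call. = FALSE)
  if (length(neg_counts) < 2L) {
    stop("negative control needs >= 2 replicate wells (SD undefined)",
         call. = FALSE)
  }
  neg_sd <- max(sample_sd(neg_counts), sd_floor)
  thr <- mean(neg_counts) + 3 * neg_sd
  list(stim_mean = mean(stim_counts), neg_mean = mean(neg_counts),
       neg_sd = sample_sd(neg_counts), threshold = thr,
       positive = mean(stim_counts) > thr)
}

#' Call one antigen across independent experiments
#'
#' Applies [call_experiment()] in every experiment where the antigen was
#' tested; experiments lacking the antigen are skipped (not counted as
#' negative). The call is `confirmed` when at least two independent
#' experiments are positive.
#'
#' @param antigen_id condition id of the pool or single peptide.
#' @param plates an `elispot_plates` data.frame covering one or more
#'   experiments (see [read_elispot_plates()]).
#' @param sd_floor passed to [call_experiment()].
#' @return an object of class `response_call`: list with `antigen_id`,
#'   `kind`, `members`, `per_experiment` (data.frame), `n_positive`,
#'   `confirmed`, `status` (`"positive"` or `"negative"`;
#'   `"unresolved_pool"` is assigned by [deconvolute()]).
#' @export
call_antigen <- function(antigen_id, plates, sd_floor = 0) {
  rows <- which(plates$condition_id == antigen_id &
                  plates$kind %in% c("pool", "single_peptide"))
  if (length(rows) == 0L) {
    stop("antigen ", antigen_id, " not tested in any experiment",
         call. = FALSE)
  }
  per <- lapply(rows, function(i) {
    e <- plates$experiment_id[i]
    neg <- plates[plates$experiment_id == e &
                    plates$kind == "negative_control", ]
    r <- call_experiment(plates$spot_counts[[i]], neg$spot_counts[[1]],
                         sd_floor = sd_floor)
    data.frame(experiment_id = e, stim_mean = r$stim_mean,
               neg_mean = r$neg_mean, neg_sd = r$neg_sd,
               positive = r$positive, stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, per)
  n_pos <- sum(per$positive)
  confirmed <- n_pos >= 2L
  structure(list(
    antigen_id = antigen_id,
    kind = plates$kind[rows[1]],
    members = strsplit(plates$members[rows[1]], ";", fixed = TRUE)[[1]],
    per_experiment = per,
    n_positive = n_pos,
    confirmed = confirmed,
    status = if (confirmed) "positive" else "negative"
  ), class = "response_call")
}

#' Call every pool and single-peptide condition in a plate set
#'
#' @inheritParams call_antigen
#' @return a named list of `response_call` objects.
#' @export
screen_antigens <- function(plates, sd_floor = 0) {
  ids <- unique(plates$condition_id[plates$kind %in%
                                      c("pool", "single_peptide")])
  calls <- lapply(ids, call_antigen, plates = plates, sd_floor = sd_floor)
  names(calls) <- ids
  calls
}

#' Deconvolute confirmed peptide pools to single peptides
#'
#' For each confirmed-positive pool, attributes its reactivity to member
#' peptides with confirmed single-peptide calls. A confirmed pool whose
#' members were all tested singly and all called negative is reported as
#' `unresolved_pool` (recognition of the pool that could not be resolved);
#' untested members are listed as pending. Single calls for peptides that
#' belong to no pool are reported separately with a warning.
#'
#' @param pool_calls list of `response_call`s for pool conditions.
#' @param single_calls list of `response_call`s for single peptides; names
#'   (or `antigen_id`s) are peptide ids.
#' @param pools named list `pool_id -> members` (see [assign_pools()]).
#' @return a list with `attributions` (data.frame pool_id/peptide),
#'   `unresolved_pools`, `pending` (data.frame pool_id/peptide),
#'   `orphan_singles`, and `pool_status` (named character).
#' @export
deconvolute <- function(pool_calls, single_calls, pools) {
  single_ids <- vapply(single_calls, function(x) x$antigen_id, character(1))
  single_confirmed <- vapply(single_calls, function(x) x$confirmed, logical(1))
  names(single_confirmed) <- single_ids
  orphans <- setdiff(single_ids, unlist(pools))
  if (length(orphans) > 0L) {
    warning("single-peptide call(s) for peptide(s) absent from any pool: ",
            paste(orphans, collapse = ", "), call. = FALSE)
  }
  attributions <- list(); pending <- list()
  unresolved <- character(); status <- character()
  for (pc in pool_calls) {
    pid <- pc$antigen_id
    if (!pc$confirmed) { status[pid] <- "negative"; next }
    members <- pools[[pid]] %||% pc$members
    tested <- intersect(members, single_ids)
    hits <- tested[single_confirmed[tested]]
    untested <- setdiff(members, tested)
    if (length(hits) > 0L) {
      attributions[[pid]] <- data.frame(pool_id = pid, peptide = hits,
                                        stringsAsFactors = FALSE)
      status[pid] <- "positive"
    } else if (length(untested) == 0L) {
      unresolved <- c(unresolved, pid)
      status[pid] <- "unresolved_pool"
    } else {
      status[pid] <- "positive"   # confirmed pool, deconvolution incomplete
    }
    if (length(untested) > 0L) {
      pending[[pid]] <- data.frame(pool_id = pid, peptide = untested,
                                   stringsAsFactors = FALSE)
    }
  }
  empty <- data.frame(pool_id = character(), peptide = character(),
                      stringsAsFactors = FALSE)
  list(
    attributions = if (length(attributions)) do.call(rbind, c(attributions, list(make.row.names = FALSE))) else empty,
    unresolved_pools = unresolved,
    pending = if (length(pending)) do.call(rbind, c(pending, list(make.row.names = FALSE))) else empty,
    orphan_singles = orphans,
    pool_status = status
  )
}

#' Compare recognition of mutant vs wild-type peptide
#'
#' Paired two-sided Wilcoxon signed-rank test on matched mutant/wild-type
#' spot measurements (same effectors, same assay), exact for up to 25
#' non-zero pairs. Direction is the sign of the median paired difference.
#'
#' @param mut_counts,wt_counts paired numeric vectors.
#' @return a list with `statistic` (V), `p_value` and `direction`
#'   (`"mutant_higher"`, `"wt_higher"` or `"none"`).
#' @export
compare_mut_wt <- function(mut_counts, wt_counts) {
  r <- wilcoxon_signed_rank(mut_counts, wt_counts)
  dir <- switch(r$direction, x_higher = "mutant_higher",
                y_higher = "wt_higher", "none")
  list(statistic = r$V, p_value = r$p_value, direction = dir)
}
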