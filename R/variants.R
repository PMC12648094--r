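#' Consensus configuration for multi-caller variant selection
#'
#' @param caller_universe character vector of caller identifiers that may
#'   appear in the input; defaults to the three callers commonly run on
#'   tumor/normal exomes.
#' @param min_callers minimum number of supporting callers for a variant to
#'   be retained (the "at least 2 of 3" rule generalized to k of n).
#' @return an object of class `consensus_config`.
#' @export
consensus_config <- function(caller_universe = c("mutect2", "strelka2", "varscan2"),
                             min_callers = 2L) {
  caller_universe <- as.character(caller_universe)
  min_callers <- as.integer(min_callers)
  if (length(caller_universe) < 1L || anyDuplicated(caller_universe)) {
    stop("caller_universe must be a non-empty set of unique identifiers",
         call. = FALSE)
  }
  if (min_callers < 1L || min_callers > length(caller_universe)) {
    stop("min_callers must satisfy 1 <= min_callers <= |caller_universe|",
         call. = FALSE)
  }
  structure(list(caller_universe = caller_universe,
                 min_callers = min_callers),
            class = "consensus_config")
}

#' Read a protein-level somatic variant table
#'
#' Parses a variant table (comma or tab delimited, dialect auto-detected
#' from the header) with columns `gene_id`, `protein_id`, `protein_pos`,
#' `aa_ref`, `aa_alt`, `callers` (semicolon-separated caller identifiers)
#' and `variant_class`. Duplicate rows describing the same amino-acid change
#' (`protein_id`, `protein_pos`, `aa_alt`) are merged by unioning their
#' caller support.
#'
#' @param path path to the variant table.
#' @param config a [consensus_config()]; caller identifiers outside its
#'   universe are a validation error.
#' @return a data.frame of variants with a list-column `callers`.
#' @export
read_variants <- function(path, config = consensus_config()) {
  req <- c("gene_id", "protein_id", "protein_pos", "aa_ref", "aa_alt",
           "callers", "variant_class")
  df <- read_dialect_table(path, required = req)
  if (nrow(df) == 0L) {
    return(variant_frame(df[req][0, ], list()))
  }
  pos <- suppressWarnings(as.integer(df$protein_pos))
  bad <- which(is.na(pos) | pos < 1L | !nzchar(df$aa_ref) | !nzchar(df$aa_alt))
  if (length(bad) > 0L) {
    stop("malformed variant row at line ", bad[1] + 1L, " of ", path,
         call. = FALSE)
  }
  callers <- strsplit(as.character(df$callers), ";", fixed = TRUE)
  callers <- lapply(callers, function(x) unique(x[nzchar(x)]))
  unknown <- setdiff(unique(unlist(callers)), config$caller_universe)
  if (length(unknown) > 0L) {
    stop("unknown caller identifier(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  if (any(lengths(callers) == 0L)) {
    stop("malformed variant row at line ",
         which(lengths(callers) == 0L)[1] + 1L, " of ", path,
         ": empty caller support", call. = FALSE)
  }
  miss <- df$variant_class == "missense" & df$aa_ref == df$aa_alt
  if (any(miss)) {
    stop("missense variant with aa_ref == aa_alt at line ",
         which(miss)[1] + 1L, " of ", path, call. = FALSE)
  }
  out <- data.frame(gene_id = as.character(df$gene_id),
                    protein_id = as.character(df$protein_id),
                    protein_pos = pos,
                    aa_ref = toupper(df$aa_ref),
                    aa_alt = toupper(df$aa_alt),
                    variant_class = as.character(df$variant_class),
                    stringsAsFactors = FALSE)
  key <- paste(out$protein_id, out$protein_pos, out$aa_alt, sep = "|")
  if (anyDuplicated(key)) {
    first <- !duplicated(key)
    merged <- tapply(callers, key, function(x) unique(unlist(x)),
                     simplify = FALSE)
    callers <- unname(merged[key[first]])
    out <- out[first, , drop = FALSE]
    rownames(out) <- NULL
  }
  variant_frame(out, callers)
}

variant_frame <- function(df, callers) {
  df$callers <- I(unname(callers))
  df$n_callers <- lengths(df$callers)
  class(df) <- c("neoscreen_variants", "data.frame")
  df
}

#' Filter variants by missense class and caller consensus
#'
#' Retains exactly the missense variants supported by at least
#' `config$min_callers` callers, preserving input order. Idempotent; the
#' output is always a subset of the input.
#'
#' @param variants a variant data.frame from [read_variants()] (or built in
#'   code with the same columns, `callers` as a list-column).
#' @param config a [consensus_config()].
#' @return the retained subset of `variants`.
#' @export
consensus_filter <- function(variants, config = consensus_config()) {
  stopifnot(is.data.frame(variants))
  keep <- variants$variant_class == "missense" &
    lengths(variants$callers) >= config$min_callers
  out <- variants[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
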