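#' Read a reference proteome FASTA
#'
#' One record per protein; the first whitespace-delimited token of each
#' FASTA header is taken as the `protein_id`.
#'
#' @param path path to an (uncompressed or gzipped) amino-acid FASTA file.
#' @return a named [Biostrings::AAStringSet].
#' @export
read_proteome <- function(path) {
  aa <- Biostrings::readAAStringSet(path)
  names(aa) <- sub("\\s.*$", "", names(aa))
  if (anyDuplicated(names(aa))) {
    stop("duplicate protein_id in proteome FASTA", call. = FALSE)
  }
  aa
}

#' Build the 25-residue sequence window around a missense variant
#'
#' The window spans positions `protein_pos - 12` to `protein_pos + 12` of
#' the reference protein, clipped at the termini (truncation is flagged, the
#' variant is kept). The mutant window carries `aa_alt` substituted at the
#' variant position; all other residues are identical to wild type.
#'
#' @param variant a single-row variant data.frame (see [read_variants()])
#'   or a list with fields `protein_id`, `protein_pos`, `aa_ref`, `aa_alt`.
#' @param proteome a named `AAStringSet` from [read_proteome()], or a named
#'   character vector of protein sequences.
#' @param flank number of residues on each side of the variant (12 gives
#'   the 25-mer window).
#' @return an object of class `sequence_window`: a list with `wt_window`,
#'   `mut_window`, `mut_index_in_window` (0-based), `left_truncated`,
#'   `right_truncated`, `window_start` (1-based protein coordinate) and the
#'   originating `variant` fields.
#' @export
build_window <- function(variant, proteome, flank = 12L) {
  v <- as.list(variant)
  pid <- as.character(v$protein_id)
  pos <- as.integer(v$protein_pos)
  seqs <- if (is.character(proteome)) proteome else as.character(proteome)
  if (!pid %in% names(seqs)) {
    stop("protein ", pid, " not found in proteome", call. = FALSE)
  }
  prot <- seqs[[pid]]
  len <- nchar(prot)
  if (pos < 1L || pos > len) {
    stop("position ", pos, " outside protein ", pid, " (length ", len, ")",
         call. = FALSE)
  }
  ref_res <- substr(prot, pos, pos)
  if (!identical(ref_res, as.character(v$aa_ref))) {
    stop("reference mismatch for ", pid, " position ", pos, ": proteome has ",
         ref_res, ", variant expects ", v$aa_ref,
         " (stale annotation?)", call. = FALSE)
  }
  start <- max(1L, pos - flank)
  end <- min(len, pos + flank)
  wt <- substr(prot, start, end)
  idx0 <- pos - start                      # 0-based index of the variant
  mut <- wt
  substr(mut, idx0 + 1L, idx0 + 1L) <- as.character(v$aa_alt)
  structure(list(
    wt_window = wt,
    mut_window = mut,
    mut_index_in_window = idx0,
    left_truncated = start > pos - flank,
    right_truncated = end < pos + flank,
    window_start = start,
    variant = v[c("gene_id", "protein_id", "protein_pos", "aa_ref", "aa_alt")]
  ), class = "sequence_window")
}

#' Enumerate mutant/wild-type peptide pairs covering the mutated residue
#'
#' Emits every substring of each requested length that lies within the
#' window and contains the mutated residue, paired with the wild-type
#' substring at the same offset. For an untruncated 25-mer window this is
#' exactly `k` peptides per length `k <= 13`, i.e. 38 pairs for lengths
#' 8-11. Peptides containing non-standard residues (anything outside the 20
#' canonical amino acids) are dropped with a warning, since binding
#' predictors cannot score them. Order is deterministic: length ascending,
#' then offset ascending.
#'
#' @param window a `sequence_window` from [build_window()].
#' @param lengths integer vector of peptide lengths, default `8:11`.
#' @return a data.frame with columns `gene_id`, `protein_id`, `protein_pos`,
#'   `aa_ref`, `aa_alt`, `length`, `offset_in_window` (0-based),
#'   `mut_peptide`, `wt_peptide`.
#' @export
enumerate_peptides <- function(window, lengths = 8:11) {
  stopifnot(inherits(window, "sequence_window"))
  lengths <- sort(unique(as.integer(lengths)))
  wlen <- nchar(window$wt_window)
  idx <- window$mut_index_in_window       # 0-based
  rows <- list()
  for (k in lengths) {
    if (k > wlen) next
    # 0-based offsets o with o <= idx <= o + k - 1, window-bounded
    lo <- max(0L, idx - k + 1L)
    hi <- min(wlen - k, idx)
    if (hi < lo) next
    for (o in lo:hi) {
      rows[[length(rows) + 1L]] <- data.frame(
        length = k,
        offset_in_window = o,
        mut_peptide = substr(window$mut_window, o + 1L, o + k),
        wt_peptide = substr(window$wt_window, o + 1L, o + k),
        stringsAsFactors = FALSE
      )
    }
  }
  out <- if (length(rows) == 0L) {
    data.frame(length = integer(), offset_in_window = integer(),
               mut_peptide = character(), wt_peptide = character(),
               stringsAsFactors = FALSE)
  } else {
    do.call(rbind, rows)
  }
  nonstd <- grepl("[^ACDEFGHIKLMNPQRSTVWY]", out$mut_peptide) |
    grepl("[^ACDEFGHIKLMNPQRSTVWY]", out$wt_peptide)
  if (any(nonstd)) {
    warning(sum(nonstd), " peptide(s) with non-standard residues dropped",
            call. = FALSE)
    out <- out[!nonstd, , drop = FALSE]
  }
  v <- window$variant
  cbind(data.frame(gene_id = v$gene_id %||% NA_character_,
                   protein_id = v$protein_id,
                   protein_pos = v$protein_pos,
                   aa_ref = v$aa_ref, aa_alt = v$aa_alt,
                   stringsAsFactors = FALSE)[rep(1L, nrow(out)), , drop = FALSE],
        out, row.names = NULL)
}

#' Enumerate peptide pairs for a whole variant table
#'
#' Convenience wrapper: builds the window for every variant and concatenates
#' the per-variant peptide pairs. Duplicate mutant sequences arising from
#' different variants are kept (deduplication happens at scoring).
#'
#' @inheritParams build_window
#' @param variants a variant data.frame (normally the output of
#'   [consensus_filter()]).
#' @param lengths peptide lengths, default `8:11`.
#' @return a data.frame as in [enumerate_peptides()].
#' @export
peptide_candidates <- function(variants, proteome, lengths = 8:11,
                               flank = 12L) {
  parts <- lapply(seq_len(nrow(variants)), function(i) {
    w <- build_window(variants[i, , drop = FALSE], proteome, flank = flank)
    enumerate_peptides(w, lengths = lengths)
  })
  if (length(parts) == 0L) {
    return(enumerate_peptides(structure(list(wt_window = "", mut_window = "",
                                             mut_index_in_window = 0L,
                                             variant = list()),
                                        class = "sequence_window"),
                              lengths))
  }
  do.call(rbind, parts)
}
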