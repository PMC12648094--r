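# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

# Read a delimited table whose dialect (comma or tab) is auto-detected from
# the header line. Used for variant, expression and rank tables.
read_dialect_table <- function(path, required = character()) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  header <- readLines(path, n = 1L)
  if (length(header) == 0L) stop("empty file: ", path, call. = FALSE)
  sep <- if (grepl("\t", header)) "\t" else ","
  df <- utils::read.delim(path, sep = sep, header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          blank.lines.skip = TRUE)
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L) {
    stop("file ", path, " lacks required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  df
}

# Deterministic child-seed derivation: a single root seed fans out to
# per-patient / per-stage streams via a counter scheme (Lehmer step modulo
# the Mersenne prime 2^31 - 1), so each patient is independently
# reproducible. All intermediates stay below 2^53, exact in doubles.
child_seed <- function(seed, counter) {
  stopifnot(is.numeric(seed), is.numeric(counter))
  m <- 2147483647
  s <- (abs(seed) %% m) + 1
  s <- (s * 48271) %% m
  s <- (s + (abs(counter) %% m) * 69621) %% m
  as.integer(s)
}

# sample standard deviation (n-1 denominator); NA for n < 2
sample_sd <- function(x) {
  if (length(x) < 2L) return(NA_real_)
  stats::sd(x)
}

stopifnot_scalar_number <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    stop(name, " must be a single number", call. = FALSE)
  }
  if (positive && x <= 0) stop(name, " must be > 0", call. = FALSE)
  invisible(x)
}
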