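# Internal helpers: logging, base coding, reverse complement, misc.

.mr_env <- new.env(parent = emptyenv())
.mr_env$log_level <- "info"

.LOG_LEVELS <- c(debug = 1L, info = 2L, warn = 3L, quiet = 4L)

#' Set the package log level
#'
#' @param level one of `"debug"`, `"info"`, `"warn"`, `"quiet"`.
#' @return the previous level, invisibly.
#' @export
set_log_level <- function(level = c("info", "debug", "warn", "quiet")) {
  level <- match.arg(level)
  old <- .mr_env$log_level
  .mr_env$log_level <- level
  invisible(old)
}

mr_log <- function(level, fmt, ...) {
  if (.LOG_LEVELS[[level]] >= .LOG_LEVELS[[.mr_env$log_level]]) {
    message(sprintf("[%s] %s", level, sprintf(fmt, ...)))
  }
  invisible(NULL)
}

#' @noRd
mr_stop <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# Nucleotide coding used throughout: A=1, C=2, G=3, T=4, N/other = NA.
BASES <- c("A", "C", "G", "T")
COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

# integer complement: A<->T (1<->4), C<->G (2<->3)
comp_code <- function(code) 5L - code

#' @noRd
dna_to_code <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  v <- match(strsplit(toupper(x), "", fixed = TRUE)[[1]], BASES)
  v
}

#' @noRd
code_to_dna <- function(code) {
  s <- BASES[code]
  s[is.na(s)] <- "N"
  paste0(s, collapse = "")
}

#' Reverse complement of a DNA string (N preserved)
#' @noRd
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# Deterministic sub-seed derivation; keeps results below 2^31.
derive_seed <- function(seed, offset) {
  (as.integer(seed) %% 1000000000L) + as.integer(offset)
}

# Fixed-format number printing so pipeline outputs are byte-stable.
fmt_num <- function(x, digits = 6L) {
  out <- vapply(x, function(v) {
    if (is.na(v)) "NA" else sprintf(paste0("%.", digits, "g"), v)
  }, character(1))
  out
}

# write a data.frame as TSV with deterministic formatting
write_tsv <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1))
  for (j in which(num)) df[[j]] <- fmt_num(df[[j]])
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE)
  invisible(path)
}

input_digest <- function(path) {
  unname(tools::md5sum(path.expand(path)))
}
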