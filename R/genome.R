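# Genome container and FASTA I/O.

#' Genome object
#'
#' A genome is a set of named contigs (nucleotide strings over A,C,G,T,N)
#' plus the genome-wide background distribution of the four bases, computed
#' from A/C/G/T counts only (N excluded).  Non-ACGT IUPAC characters are
#' coerced to N.
#'
#' @param contigs named character vector or list of nucleotide strings.
#' @return an object of class `mr_genome` with elements `contigs` (named
#'   character vector) and `background` (named length-4 probability vector).
#' @examples
#' g <- genome_from_strings(c(chr = "ACGTACGT"))
#' g$background
#' @export
genome_from_strings <- function(contigs) {
  contigs <- vapply(contigs, as.character, character(1))
  if (is.null(names(contigs)) || any(!nzchar(names(contigs))))
    mr_stop("all contigs must be named")
  if (anyDuplicated(names(contigs)))
    mr_stop("duplicate contig id: %s",
            names(contigs)[duplicated(names(contigs))][1])
  contigs <- toupper(contigs)
  if (any(nchar(contigs) == 0L)) mr_stop("empty contig in genome")
  # IUPAC-only guard, then collapse ambiguity codes to N
  bad <- grepl("[^ACGTRYSWKMBDHVNU]", contigs)
  if (any(bad)) mr_stop("non-IUPAC characters in contig %s",
                        names(contigs)[bad][1])
  contigs <- gsub("[^ACGT]", "N", contigs)
  counts <- setNames(numeric(4), BASES)
  for (s in contigs) {
    tab <- table(factor(strsplit(s, "", fixed = TRUE)[[1]], levels = BASES))
    counts <- counts + as.numeric(tab)
  }
  if (sum(counts) == 0) mr_stop("genome contains no A/C/G/T bases")
  structure(list(contigs = contigs, background = counts / sum(counts)),
            class = "mr_genome")
}

#' Read a genome from a FASTA file
#'
#' Computes the genome-wide background nucleotide distribution from A/C/G/T
#' counts (N and ambiguity codes excluded).  Contig order is preserved.
#'
#' @param path FASTA file (one or more contigs).
#' @return an `mr_genome` object; see [genome_from_strings()].
#' @export
read_genome <- function(path) {
  if (!file.exists(path)) mr_stop("genome file not found: %s", path)
  ss <- tryCatch(Biostrings::readDNAStringSet(path),
                 error = function(e) mr_stop("not a valid FASTA file: %s (%s)",
                                             path, conditionMessage(e)))
  if (length(ss) == 0L) mr_stop("empty FASTA file: %s", path)
  # drop description after first whitespace, as scanners conventionally do
  ids <- sub("\\s.*$", "", names(ss))
  if (anyDuplicated(ids)) mr_stop("duplicate contig id in %s", path)
  genome_from_strings(setNames(as.character(ss), ids))
}

#' Write a genome (or any named set of sequences) to FASTA
#'
#' @param x an `mr_genome`, or a named character vector of sequences.
#' @param path output file.
#' @param width line width for wrapping.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path, width = 70L) {
  seqs <- if (inherits(x, "mr_genome")) x$contigs else x
  if (is.null(names(seqs))) mr_stop("sequences must be named")
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' @export
print.mr_genome <- function(x, ...) {
  cat(sprintf("mr_genome: %d contig(s), %s bp total\n",
              length(x$contigs),
              format(sum(nchar(x$contigs)), big.mark = ",")))
  cat("background:",
      paste(sprintf("%s=%.4f", BASES, x$background), collapse = " "), "\n")
  invisible(x)
}
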