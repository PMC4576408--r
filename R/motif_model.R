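# MotifModel: PWM with two-block core annotation and symmetry type,
# plus MEME-minimal-format I/O.

#' Construct a motif model
#'
#' A motif model is a position weight matrix (PWM) `theta` over A,C,G,T with
#' an annotation of its two conserved core blocks and their intrinsic
#' symmetry type.  Rows of `theta` are positions and must sum to 1; all
#' entries must be strictly positive (apply pseudocounts upstream).
#'
#' @param theta w-by-4 numeric matrix (columns A,C,G,T), rows summing to 1.
#' @param block1,block2 half-open position intervals `c(from, to)` within
#'   `[0, w)`, equal length, `block1` entirely before `block2`; `NULL` if
#'   not annotated.
#' @param symmetry one of `"palindromic"`, `"direct_repeat"`,
#'   `"inverted_repeat"`, `"none"`.
#' @param alpha pseudocount used when the PWM was estimated (metadata).
#' @param name motif name used in MEME output.
#' @return object of class `mr_motif` with elements `width`, `theta`,
#'   `block1`, `block2`, `symmetry`, `alpha`, `name`, `consensus`.
#' @export
motif_model <- function(theta, block1 = NULL, block2 = NULL,
                        symmetry = "none", alpha = 0.5, name = "motif") {
  theta <- as.matrix(theta)
  if (ncol(theta) != 4L) mr_stop("theta must have 4 columns (A,C,G,T)")
  w <- nrow(theta)
  if (any(theta <= 0)) mr_stop("theta entries must be strictly positive")
  if (any(abs(rowSums(theta) - 1) > 1e-9))
    mr_stop("theta rows must sum to 1 (max deviation %.2e)",
            max(abs(rowSums(theta) - 1)))
  colnames(theta) <- BASES
  rownames(theta) <- NULL
  if (!is.null(block1)) {
    check_blocks(w, block1, block2)
  }
  if (!symmetry %in% c("palindromic", "direct_repeat", "inverted_repeat",
                       "none"))
    mr_stop("unknown symmetry type: %s", symmetry)
  structure(list(width = w, theta = theta,
                 block1 = block1, block2 = block2, symmetry = symmetry,
                 alpha = alpha, name = name,
                 consensus = pwm_consensus(theta)),
            class = "mr_motif")
}

check_blocks <- function(w, block1, block2) {
  if (is.null(block1) || is.null(block2) ||
      length(block1) != 2L || length(block2) != 2L)
    mr_stop("block1 and block2 must both be c(from, to) intervals")
  c1 <- block1[2] - block1[1]
  c2 <- block2[2] - block2[1]
  if (c1 != c2) mr_stop("blocks must have equal length (got %d, %d)", c1, c2)
  if (c1 < 3L) mr_stop("block length must be >= 3")
  if (block1[1] < 0L || block2[2] > w || block1[2] > block2[1])
    mr_stop("blocks must be disjoint, ordered and within [0, w)")
  invisible(TRUE)
}

#' Consensus string of a PWM (ties resolved alphabetically)
#' @param theta w-by-4 PWM.
#' @return length-w character string.
#' @export
pwm_consensus <- function(theta) {
  paste0(BASES[apply(theta, 1, which.max)], collapse = "")
}

#' Information content of a PWM in bits
#'
#' Per-column `2 + sum(p * log2(p))`, summed over columns (uniform
#' background convention).
#'
#' @param theta w-by-4 PWM (or an `mr_motif`).
#' @param per_column return the per-column vector instead of the total.
#' @return total information content in bits, or per-column vector.
#' @export
pwm_information <- function(theta, per_column = FALSE) {
  if (inherits(theta, "mr_motif")) theta <- theta$theta
  ic <- 2 + rowSums(theta * log2(theta))
  if (per_column) ic else sum(ic)
}

#' @export
print.mr_motif <- function(x, ...) {
  cat(sprintf("mr_motif '%s': width %d, symmetry %s\n", x$name, x$width,
              x$symmetry))
  cat("consensus:", x$consensus, "\n")
  if (!is.null(x$block1))
    cat(sprintf("blocks: [%d,%d) and [%d,%d)\n", x$block1[1], x$block1[2],
                x$block2[1], x$block2[2]))
  cat(sprintf("information: %.2f bits\n", pwm_information(x$theta)))
  invisible(x)
}

#' Write a motif in MEME minimal format
#'
#' Standard MEME minimal motif format; the two-block annotation and
#' symmetry type are recorded as comment lines so that a round trip through
#' [read_motif()] preserves them, while remaining parseable by standard
#' motif tools.
#'
#' @param motif an `mr_motif`.
#' @param path output file.
#' @param background background probabilities written to the header
#'   (default uniform).
#' @param nsites number of sites reported in the header.
#' @return `path`, invisibly.
#' @export
write_motif <- function(motif, path, background = rep(0.25, 4),
                        nsites = 20L) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("MEME version 4", "",
               "ALPHABET= ACGT", "",
               "strands: + -", "",
               "Background letter frequencies",
               paste(sprintf("%s %.6f", BASES, background), collapse = " "),
               ""), con)
  writeLines(sprintf("MOTIF %s", motif$name), con)
  if (!is.null(motif$block1))
    writeLines(sprintf("# blocks %d %d %d %d", motif$block1[1],
                       motif$block1[2], motif$block2[1], motif$block2[2]),
               con)
  writeLines(sprintf("# symmetry %s", motif$symmetry), con)
  writeLines(sprintf(
    "letter-probability matrix: alphlen= 4 w= %d nsites= %d E= 0",
    motif$width, as.integer(nsites)), con)
  writeLines(apply(motif$theta, 1,
                   function(p) paste(sprintf("%.6f", p), collapse = " ")),
             con)
  writeLines("", con)
  invisible(path)
}

#' Read a motif from a MEME minimal format file
#'
#' Reads the first motif in the file.  Comment lines written by
#' [write_motif()] restore block spans and symmetry; zero probabilities are
#' floored at 1e-6 and rows renormalized so the result is a valid
#' `mr_motif`.
#'
#' @param path MEME minimal format file.
#' @return an `mr_motif`.
#' @export
read_motif <- function(path) {
  if (!file.exists(path)) mr_stop("motif file not found: %s", path)
  lines <- readLines(path)
  mi <- grep("^MOTIF\\s+", lines)
  if (length(mi) == 0L) mr_stop("no MOTIF record in %s", path)
  name <- strsplit(trimws(sub("^MOTIF", "", lines[mi[1]])), "\\s+")[[1]][1]
  hi <- grep("^letter-probability matrix:", lines)
  hi <- hi[hi > mi[1]][1]
  if (is.na(hi)) mr_stop("no letter-probability matrix in %s", path)
  wm <- regmatches(lines[hi], regexec("w=\\s*([0-9]+)", lines[hi]))[[1]]
  if (length(wm) != 2L) mr_stop("missing w= in matrix header of %s", path)
  w <- as.integer(wm[2])
  rows <- lines[(hi + 1):(hi + w)]
  theta <- do.call(rbind, lapply(strsplit(trimws(rows), "\\s+"), as.numeric))
  if (any(is.na(theta)) || ncol(theta) != 4L)
    mr_stop("malformed probability rows in %s", path)
  theta <- pmax(theta, 1e-6)
  theta <- theta / rowSums(theta)
  block1 <- block2 <- NULL
  symmetry <- "none"
  cmt <- lines[seq(mi[1], hi)]
  bl <- grep("^# blocks ", cmt, value = TRUE)
  if (length(bl) == 1L) {
    v <- as.integer(strsplit(trimws(sub("^# blocks", "", bl)), "\\s+")[[1]])
    block1 <- v[1:2]; block2 <- v[3:4]
  }
  sy <- grep("^# symmetry ", cmt, value = TRUE)
  if (length(sy) == 1L) symmetry <- trimws(sub("^# symmetry", "", sy))
  motif_model(theta, block1 = block1, block2 = block2, symmetry = symmetry,
              name = name)
}
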