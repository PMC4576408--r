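# Labeled numeric matrices (genes x conditions) as TSV.

#' Read a genes-by-conditions matrix from TSV
#'
#' First column holds gene ids, header row holds condition ids.  Cells equal
#' to `na_token` are read as missing (never as zero); any other non-numeric
#' cell is a format error.  Duplicate gene ids are rejected.
#'
#' @param path TSV file.
#' @param na_token string representing missing values (default `"NA"`).
#' @param transpose set `TRUE` if the file is conditions-by-genes.
#' @return numeric matrix with gene rownames and condition colnames.
#' @export
read_matrix <- function(path, na_token = "NA", transpose = FALSE) {
  if (!file.exists(path)) mr_stop("matrix file not found: %s", path)
  df <- read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                   stringsAsFactors = FALSE, colClasses = "character",
                   comment.char = "")
  if (ncol(df) < 2L) mr_stop("matrix file needs id column + data: %s", path)
  ids <- df[[1]]
  if (anyDuplicated(ids))
    mr_stop("duplicate gene id in %s: %s", path, ids[duplicated(ids)][1])
  body <- as.matrix(df[, -1, drop = FALSE])
  body[body == na_token] <- NA_character_
  suppressWarnings(num <- matrix(as.numeric(body), nrow = nrow(body)))
  bad <- !is.na(body) & is.na(num)
  if (any(bad)) {
    i <- which(bad, arr.ind = TRUE)[1, ]
    mr_stop("non-numeric cell in %s (gene %s, column %s): '%s'",
            path, ids[i[1]], colnames(body)[i[2]], body[i[1], i[2]])
  }
  dimnames(num) <- list(ids, colnames(body))
  if (transpose) num <- t(num)
  num
}

#' Write a labeled matrix as TSV
#'
#' Inverse of [read_matrix()]: first column `gene_id`, header = condition
#' ids, missing values written as `na_token`.
#'
#' @param mat numeric matrix with dimnames.
#' @param path output file.
#' @param na_token token used for missing values.
#' @param digits significant digits to print.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(mat, path, na_token = "NA", digits = 8L) {
  if (is.null(rownames(mat)) || is.null(colnames(mat)))
    mr_stop("matrix must have row and column names")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("gene_id", colnames(mat)), collapse = "\t"), con)
  body <- matrix(fmt_num(mat, digits), nrow = nrow(mat))
  body[body == "NA"] <- na_token
  writeLines(paste(rownames(mat), apply(body, 1, paste, collapse = "\t"),
                   sep = "\t"), con)
  invisible(path)
}
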