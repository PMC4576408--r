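# Gene annotations and operon tables.
#
# Internal coordinate convention everywhere: 0-based half-open [start, end).
# GFF3 I/O converts from/to 1-based inclusive; BED is already half-open.

#' Build a gene annotation table
#'
#' @param gene_id character vector of unique gene ids.
#' @param contig contig id per gene.
#' @param start,end 0-based half-open coordinates.
#' @param strand `"+"` or `"-"`.
#' @return a `data.frame` of class `mr_annotations` with columns
#'   `gene_id`, `contig`, `start`, `end`, `strand`, sorted by contig and
#'   start.
#' @export
annotations <- function(gene_id, contig, start, end, strand) {
  df <- data.frame(gene_id = as.character(gene_id),
                   contig = as.character(contig),
                   start = as.integer(start), end = as.integer(end),
                   strand = as.character(strand),
                   stringsAsFactors = FALSE)
  if (anyDuplicated(df$gene_id))
    mr_stop("duplicate gene id: %s", df$gene_id[duplicated(df$gene_id)][1])
  if (any(df$start < 0L) || any(df$start >= df$end))
    mr_stop("invalid coordinates: require 0 <= start < end")
  if (!all(df$strand %in% c("+", "-")))
    mr_stop("strand must be '+' or '-'")
  df <- df[order(df$contig, df$start, df$gene_id), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("mr_annotations", "data.frame")
  df
}

#' Read gene annotations from GFF3 or BED6
#'
#' GFF3 coordinates (1-based inclusive) are converted to the internal
#' 0-based half-open convention; BED6 is used as is.  For GFF3 the gene id
#' is taken from the `ID`, `locus_tag` or `Name` attribute (first present).
#'
#' @param path annotation file; format chosen by extension (`.gff`, `.gff3`
#'   vs `.bed`) unless `format` is given.
#' @param format `"gff3"`, `"bed"` or `NULL` (auto).
#' @param feature GFF3 feature types to keep (default `"gene"`; use `NULL`
#'   for all rows).
#' @return an `mr_annotations` data.frame.
#' @export
read_annotations <- function(path, format = NULL, feature = "gene") {
  if (!file.exists(path)) mr_stop("annotation file not found: %s", path)
  if (is.null(format)) {
    format <- if (grepl("\\.bed$", path, ignore.case = TRUE)) "bed" else "gff3"
  }
  if (format == "bed") {
    df <- read.table(path, sep = "\t", header = FALSE,
                     stringsAsFactors = FALSE, comment.char = "#")
    if (ncol(df) < 6L) mr_stop("BED6 requires 6 columns: %s", path)
    return(annotations(df[[4]], df[[1]], df[[2]], df[[3]], df[[6]]))
  }
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  if (length(lines) == 0L) mr_stop("no records in GFF3 file: %s", path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) < 9L)) mr_stop("malformed GFF3 line in %s", path)
  m <- do.call(rbind, parts)
  keep <- if (is.null(feature)) rep(TRUE, nrow(m)) else m[, 3] %in% feature
  if (!any(keep)) mr_stop("no '%s' features in %s",
                          paste(feature, collapse = ","), path)
  m <- m[keep, , drop = FALSE]
  attr_id <- function(a) {
    for (key in c("ID", "locus_tag", "Name")) {
      hit <- regmatches(a, regexec(paste0("(?:^|;)", key, "=([^;]+)"), a))[[1]]
      if (length(hit) == 2L) return(hit[2])
    }
    NA_character_
  }
  ids <- vapply(m[, 9], attr_id, character(1), USE.NAMES = FALSE)
  if (anyNA(ids)) mr_stop("GFF3 record without ID/locus_tag/Name in %s", path)
  annotations(ids, m[, 1], as.integer(m[, 4]) - 1L, as.integer(m[, 5]),
              m[, 7])
}

#' Write gene annotations as GFF3
#'
#' @param ann an `mr_annotations` data.frame.
#' @param path output file.
#' @param source value of the GFF3 source column.
#' @param feature value of the GFF3 type column.
#' @return `path`, invisibly.
#' @export
write_annotations_gff3 <- function(ann, path, source = "motifregulon",
                                   feature = "gene") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  writeLines(sprintf("%s\t%s\t%s\t%d\t%d\t.\t%s\t.\tID=%s",
                     ann$contig, source, feature,
                     ann$start + 1L, ann$end, ann$strand, ann$gene_id), con)
  invisible(path)
}

#' Read an operon table
#'
#' TSV with two columns: gene id, operon id (header optional, detected from
#' a first line whose second field is `operon` or `operon_id`).  Gene order
#' within an operon follows file order and is interpreted as genomic order
#' in operon orientation (head gene first).
#'
#' @param path TSV file.
#' @return an object of class `mr_operons`: list with `gene2operon`
#'   (named character vector) and `operons` (named list of ordered gene-id
#'   vectors).
#' @export
read_operons <- function(path) {
  df <- read.table(path, sep = "\t", header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) mr_stop("operon table needs 2 columns: %s", path)
  if (tolower(df[1, 2]) %in% c("operon", "operon_id")) df <- df[-1, ]
  operon_table(df[[1]], df[[2]])
}

#' Build an operon table from vectors
#'
#' @param gene_id gene ids (a gene may appear in at most one operon).
#' @param operon_id operon id per gene; members are ordered as given,
#'   head gene first.
#' @return an `mr_operons` object; see [read_operons()].
#' @export
operon_table <- function(gene_id, operon_id) {
  gene_id <- as.character(gene_id)
  operon_id <- as.character(operon_id)
  if (anyDuplicated(gene_id))
    mr_stop("gene %s is in more than one operon",
            gene_id[duplicated(gene_id)][1])
  ops <- split(gene_id, operon_id)
  # preserve within-operon order of appearance
  ops <- lapply(ops, function(g) gene_id[gene_id %in% g])
  structure(list(gene2operon = setNames(operon_id, gene_id), operons = ops),
            class = "mr_operons")
}

#' Write an operon table as TSV
#' @param ops an `mr_operons` object.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_operons <- function(ops, path) {
  df <- data.frame(gene_id = names(ops$gene2operon),
                   operon_id = unname(ops$gene2operon))
  write_tsv(df, path)
}

# check operon members share contig and strand; warn+drop missing genes
validate_operons <- function(ops, ann) {
  for (oid in names(ops$operons)) {
    genes <- ops$operons[[oid]]
    miss <- setdiff(genes, ann$gene_id)
    if (length(miss) > 0L) {
      mr_log("warn", "operon %s: member(s) %s missing from annotations",
             oid, paste(miss, collapse = ","))
      genes <- setdiff(genes, miss)
      ops$operons[[oid]] <- genes
    }
    if (length(genes) == 0L) next
    idx <- match(genes, ann$gene_id)
    if (length(unique(ann$contig[idx])) > 1L ||
        length(unique(ann$strand[idx])) > 1L)
      mr_stop("operon %s members do not share contig and strand", oid)
  }
  ops
}
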