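# Regulon assembly: pair accepted sites with downstream genes
# bidirectionally, extend through operons, evaluate against a reference.

#' Pair binding sites with candidate target genes
#'
#' For every site two searches are performed: (i) along the site's 5'-3'
#' direction on the positive strand, pairing the nearest downstream `+`
#' gene whose translation start lies within `max_upstream` of the site;
#' (ii) along the complementary site's 5'-3' direction on the negative
#' strand, pairing the nearest `-` gene likewise.  A site may thus pair
#' with two divergently transcribed genes.  A site falling inside an ORF is
#' paired to that gene with `intragenic = TRUE` when `allow_intragenic`.
#' Sites pairing no gene are returned in the `unassigned` attribute.
#'
#' Offsets follow the upstream convention: site start minus translation
#' start in gene orientation, negative when the site lies upstream.
#'
#' @param sites an `mr_sites` data.frame ([scan_genome()] output).
#' @param ann `mr_annotations`.
#' @param max_upstream maximum pairing distance in bp (default 300,
#'   mirroring the discovery window).
#' @param allow_intragenic pair sites inside ORFs (default TRUE).
#' @param strand_restricted only search downstream on the strand the site
#'   was called on (default FALSE = bidirectional).
#' @return data.frame of class `mr_regulon_entries`: columns `gene_id`,
#'   `site_index` (row of `sites`), `contig`, `site_start`, `site_strand`,
#'   `sequence`, `score`, `p_value`, `offset`, `intragenic`, `via_operon`;
#'   canonically sorted, with unassigned site indices in attribute
#'   `unassigned`.
#' @export
assign_sites_to_genes <- function(sites, ann, max_upstream = 300L,
                                  allow_intragenic = TRUE,
                                  strand_restricted = FALSE) {
  entries <- list()
  unassigned <- integer(0)
  w_all <- nchar(sites$sequence)
  for (i in seq_len(nrow(sites))) {
    s0 <- sites$start[i]
    w <- w_all[i]
    s1 <- s0 + w
    contig_ann <- ann[ann$contig == sites$contig[i], , drop = FALSE]
    found <- list()
    strands <- if (strand_restricted) sites$strand[i] else c("+", "-")
    for (strand in strands) {
      cand <- contig_ann[contig_ann$strand == strand, , drop = FALSE]
      if (nrow(cand) == 0L) next
      if (strand == "+") {
        ok <- cand$start >= s1
        off <- s0 - cand$start
        dist <- cand$start - s1
      } else {
        ok <- cand$end <= s0
        off <- cand$end - s1
        dist <- s0 - cand$end
      }
      ok <- ok & (-off <= max_upstream)
      if (!any(ok)) next
      j <- which(ok)[which.min(dist[ok])]
      found[[length(found) + 1L]] <-
        list(gene = cand$gene_id[j], offset = off[j], intragenic = FALSE)
    }
    if (allow_intragenic) {
      inside <- contig_ann$start < s1 & contig_ann$end > s0
      for (j in which(inside)) {
        off <- if (contig_ann$strand[j] == "+") s0 - contig_ann$start[j]
               else contig_ann$end[j] - s1
        found[[length(found) + 1L]] <-
          list(gene = contig_ann$gene_id[j], offset = off,
               intragenic = TRUE)
      }
    }
    if (length(found) == 0L) {
      unassigned <- c(unassigned, i)
      next
    }
    for (f in found) {
      entries[[length(entries) + 1L]] <- data.frame(
        gene_id = f$gene, site_index = i, contig = sites$contig[i],
        site_start = s0, site_strand = sites$strand[i],
        sequence = sites$sequence[i], score = sites$score[i],
        p_value = sites$p_value[i], offset = as.integer(f$offset),
        intragenic = f$intragenic, via_operon = FALSE,
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(entries) > 0L) do.call(rbind, entries) else
    empty_entries()
  out <- canonical_entries(out)
  attr(out, "unassigned") <- unassigned
  out
}

empty_entries <- function() {
  data.frame(gene_id = character(0), site_index = integer(0),
             contig = character(0), site_start = integer(0),
             site_strand = character(0), sequence = character(0),
             score = numeric(0), p_value = numeric(0),
             offset = integer(0), intragenic = logical(0),
             via_operon = logical(0), stringsAsFactors = FALSE)
}

canonical_entries <- function(df) {
  df <- df[!duplicated(df[, c("gene_id", "site_index")]), , drop = FALSE]
  df <- df[order(df$contig, df$site_start, df$gene_id), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("mr_regulon_entries", "data.frame")
  df
}

#' Extend paired genes through predicted operons
#'
#' For each paired gene that heads (or belongs to) a predicted operon, all
#' genes downstream of it within the operon are appended as entries with
#' `via_operon = TRUE`, sharing the head's site — co-transcribed genes are
#' regulated through the operon promoter.
#'
#' @param entries an `mr_regulon_entries` data.frame.
#' @param operons an `mr_operons` table, or `NULL` to disable (output =
#'   input).
#' @param ann optional annotations used to validate operon membership
#'   (members missing from `ann` are skipped with a warning).
#' @return extended `mr_regulon_entries`.
#' @export
extend_operons <- function(entries, operons, ann = NULL) {
  if (is.null(operons)) return(entries)
  if (!is.null(ann)) operons <- validate_operons(operons, ann)
  extra <- list()
  for (i in seq_len(nrow(entries))) {
    g <- entries$gene_id[i]
    oid <- operons$gene2operon[g]
    if (is.na(oid)) next
    members <- operons$operons[[oid]]
    pos <- match(g, members)
    if (is.na(pos) || pos == length(members)) next
    for (m in members[(pos + 1L):length(members)]) {
      row <- entries[i, , drop = FALSE]
      row$gene_id <- m
      row$via_operon <- TRUE
      row$offset <- NA_integer_   # inherited site; offset undefined
      extra[[length(extra) + 1L]] <- row
    }
  }
  out <- rbind(entries, if (length(extra) > 0L) do.call(rbind, extra))
  canonical_entries(out)
}

#' Assemble a regulon object
#'
#' @param tf TF gene id.
#' @param entries an `mr_regulon_entries` data.frame.
#' @return object of class `mr_regulon`: list with `tf`, `entries`,
#'   `genes` (distinct gene ids), `n_sites` (distinct sites).
#' @export
regulon <- function(tf, entries) {
  structure(list(tf = tf, entries = entries,
                 genes = sort(unique(entries$gene_id)),
                 n_sites = length(unique(entries$site_index))),
            class = "mr_regulon")
}

#' @export
print.mr_regulon <- function(x, ...) {
  cat(sprintf("mr_regulon of %s: %d genes via %d sites (%d intragenic, %d via operon)\n",
              x$tf, length(x$genes), x$n_sites,
              sum(x$entries$intragenic), sum(x$entries$via_operon)))
  invisible(x)
}

#' Write a regulon table as TSV
#' @param reg an `mr_regulon` (or entries data.frame).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_regulon <- function(reg, path) {
  df <- if (inherits(reg, "mr_regulon")) reg$entries else reg
  write_tsv(df, path)
}

#' Evaluate a predicted regulon against a reference gene set
#'
#' Counts over gene ids: `TPR = TP / (TP + FN)`,
#' `FPR = FP / (FP + TN)`.
#'
#' @param predicted character vector of predicted regulon gene ids.
#' @param reference character vector of reference regulon gene ids.
#' @param universe all annotated gene ids (`reference` must be a subset).
#' @return list with `TP`, `FP`, `FN`, `TN`, `TPR`, `FPR` (`TPR` is `NA`
#'   with empty reference).
#' @export
evaluate_regulon <- function(predicted, reference, universe) {
  predicted <- unique(predicted)
  reference <- unique(reference)
  universe <- unique(universe)
  if (!all(reference %in% universe))
    mr_stop("reference genes missing from universe: %s",
            paste(head(setdiff(reference, universe), 3), collapse = ","))
  predicted <- intersect(predicted, universe)
  tp <- length(intersect(predicted, reference))
  fp <- length(setdiff(predicted, reference))
  fn <- length(setdiff(reference, predicted))
  tn <- length(universe) - tp - fp - fn
  tpr <- if (length(reference) == 0L) NA_real_ else tp / (tp + fn)
  if (length(reference) == 0L)
    mr_log("warn", "empty reference set: TPR undefined")
  fpr <- if (fp + tn == 0L) NA_real_ else fp / (fp + tn)
  list(TP = tp, FP = fp, FN = fn, TN = tn, TPR = tpr, FPR = fpr)
}

#' ROC curve over score thresholds
#'
#' Re-runs scan + assembly at every threshold of a descending grid and
#' evaluates the predicted gene set against the reference.  TPR is
#' non-decreasing as the threshold is lowered.
#'
#' @param motif an `mr_motif`.
#' @param genome an `mr_genome`.
#' @param ann `mr_annotations`.
#' @param reference reference regulon gene ids.
#' @param thresholds descending numeric vector of score thresholds (bits).
#' @param p_threshold p-value threshold passed to [scan_genome()].
#' @param operons optional `mr_operons` for extension.
#' @param ... further arguments to [assign_sites_to_genes()].
#' @return data.frame with columns `s_threshold`, `n_sites`, `TP`, `FP`,
#'   `TPR`, `FPR`.
#' @export
roc_curve <- function(motif, genome, ann, reference, thresholds,
                      p_threshold = 0.001, operons = NULL, ...) {
  if (is.unsorted(rev(thresholds)))
    mr_stop("thresholds must be in descending order")
  universe <- ann$gene_id
  rows <- lapply(thresholds, function(s) {
    sites <- scan_genome(genome, motif, p_threshold = p_threshold,
                         s_threshold = s)
    entries <- assign_sites_to_genes(sites, ann, ...)
    entries <- extend_operons(entries, operons, ann)
    ev <- evaluate_regulon(unique(entries$gene_id), reference, universe)
    data.frame(s_threshold = s, n_sites = nrow(sites), TP = ev$TP,
               FP = ev$FP, TPR = ev$TPR, FPR = ev$FPR)
  })
  do.call(rbind, rows)
}
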