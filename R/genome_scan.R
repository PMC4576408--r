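# PWM genome scanning: log-likelihood-ratio scores, exact p-values via the
# score-distribution dynamic program, thresholded site lists.

#' Log-likelihood-ratio score of a k-mer under a motif
#'
#' `sum_j log2(theta[j, kmer_j] / background[kmer_j])` in bits.  A k-mer
#' containing N is unscorable and returns `NA`.
#'
#' @param motif an `mr_motif` (or w-by-4 PWM).
#' @param background length-4 background probabilities (A,C,G,T).
#' @param kmer character string of length w.
#' @return score in bits, or `NA` for unscorable k-mers.
#' @export
llr_score <- function(motif, background, kmer) {
  theta <- if (inherits(motif, "mr_motif")) motif$theta else motif
  w <- nrow(theta)
  if (nchar(kmer) != w) mr_stop("kmer length %d != motif width %d",
                                nchar(kmer), w)
  code <- dna_to_code(kmer)
  if (anyNA(code)) return(NA_real_)
  sum(log2(theta[cbind(seq_len(w), code)]) - log2(background[code]))
}

#' Exact distribution of LLR scores under the background model
#'
#' Column-wise convolution of the per-position score contributions over a
#' discretized score grid, weighted by the background distribution — the
#' standard exact dynamic program for PWM score p-values.  The returned
#' object maps any score to `P(S >= score)` for a random background k-mer.
#'
#' @param motif an `mr_motif` or w-by-4 PWM.
#' @param background length-4 background probabilities.
#' @param eps discretization step in bits; default `score range / 10000`.
#'   Smaller values give finer (towards exact) p-values at linear cost.
#' @return object of class `mr_score_dist`: list with `eps`, `grid`
#'   (integer score indices), `mass` (probability per index, sums to 1),
#'   `tail` (upper-tail probability per index), `w`, `min_score`,
#'   `max_score`.
#' @export
score_distribution <- function(motif, background, eps = NULL) {
  theta <- if (inherits(motif, "mr_motif")) motif$theta else motif
  background <- background / sum(background)
  w <- nrow(theta)
  contrib <- log2(theta) - matrix(log2(background), w, 4, byrow = TRUE)
  min_score <- sum(apply(contrib, 1, min))
  max_score <- sum(apply(contrib, 1, max))
  if (is.null(eps)) {
    rng <- max(max_score - min_score, 1e-6)
    eps <- rng / 10000
  }
  if (eps <= 0) mr_stop("eps must be > 0")
  idx <- round(contrib / eps)      # per-position integer score indices
  # sparse convolution over integer indices (named by index value)
  cur_idx <- 0
  cur_mass <- 1
  for (j in seq_len(w)) {
    new_idx <- outer(cur_idx, idx[j, ], "+")
    new_mass <- outer(cur_mass, background, "*")
    agg <- rowsum(as.vector(new_mass), group = as.vector(new_idx))
    cur_idx <- as.numeric(rownames(agg))
    cur_mass <- as.vector(agg)
  }
  ord <- order(cur_idx)
  grid <- cur_idx[ord]
  mass <- cur_mass[ord]
  tail <- rev(cumsum(rev(mass)))
  structure(list(eps = eps, grid = grid, mass = mass, tail = tail, w = w,
                 min_score = min_score, max_score = max_score),
            class = "mr_score_dist")
}

#' P-value of a score under a score distribution
#'
#' `P(S >= score)` for a background k-mer.  A tolerance of `w/2` grid
#' steps absorbs the rounding drift between a directly computed score and
#' its discretized counterpart, so that the p-value of the minimum
#' achievable score is exactly 1 and p-values are monotone non-increasing
#' in the score.
#'
#' @param dist an `mr_score_dist`.
#' @param score numeric vector of scores in bits.
#' @return numeric vector of p-values in `[0, 1]`.
#' @export
score_pvalue <- function(dist, score) {
  q <- round(score / dist$eps) - dist$w / 2
  # first grid index >= q  ->  tail mass at that index
  pos <- findInterval(q - 0.5, dist$grid) + 1L
  out <- numeric(length(score))
  inside <- pos <= length(dist$grid)
  out[inside] <- dist$tail[pos[inside]]
  out[!inside] <- 0
  out
}

#' Scan a genome for motif occurrences
#'
#' Scores every position of every contig on both strands with
#' [llr_score()], computes p-values from [score_distribution()], and keeps
#' sites with `p <= p_threshold` and `score >= s_threshold`.  A reverse-
#' complement pair of hits at the same locus (common for palindromic
#' motifs) is collapsed to the higher-scoring strand (ties kept as `+`).
#' Windows containing N are skipped.  Background entries below `bg_floor`
#' are floored and the background renormalized (with a warning).
#'
#' @param genome an `mr_genome`.
#' @param motif an `mr_motif`.
#' @param p_threshold p-value threshold (default 0.001).
#' @param s_threshold raw score threshold in bits; `NULL` uses
#'   [choose_score_threshold()]'s default (60% of the maximum achievable
#'   score).
#' @param max_sites optional cap: keep only the top-scoring sites.
#' @param eps score-distribution discretization step (default automatic).
#' @param bg_floor background probability floor (default 1e-3).
#' @return data.frame of class `mr_sites`: columns `contig`, `start`
#'   (0-based), `strand`, `sequence` (site in motif orientation), `score`
#'   (bits), `p_value`; sorted by contig then start.  The score
#'   distribution is attached as attribute `score_dist`.
#' @export
scan_genome <- function(genome, motif, p_threshold = 0.001,
                        s_threshold = NULL, max_sites = NULL, eps = NULL,
                        bg_floor = 1e-3) {
  w <- motif$width
  if (w > min(nchar(genome$contigs)))
    mr_stop("motif width %d exceeds shortest contig", w)
  bg <- genome$background
  if (any(bg < bg_floor)) {
    mr_log("warn", "background entries below %g floored and renormalized",
           bg_floor)
    bg <- pmax(bg, bg_floor)
    bg <- bg / sum(bg)
  }
  if (is.null(s_threshold))
    s_threshold <- choose_score_threshold(motif, background = bg)
  dist <- score_distribution(motif, bg, eps)
  theta_flat <- as.numeric(t(motif$theta))
  hits <- list()
  for (contig in names(genome$contigs)) {
    codes <- seq_to_codes(genome$contigs[[contig]])
    n_skipped <- sum(codes == 0L)
    if (n_skipped > 0L)
      mr_log("debug", "contig %s: %d N bases; overlapping windows skipped",
             contig, n_skipped)
    fwd <- scan_scores_cpp(codes, theta_flat, bg, w, FALSE)
    rev <- scan_scores_cpp(codes, theta_flat, bg, w, TRUE)
    # collapse strand pairs at the same locus: keep higher score, tie -> +
    use_rev <- !is.na(rev) & (is.na(fwd) | rev > fwd)
    score <- ifelse(use_rev, rev, fwd)
    strand <- ifelse(use_rev, "-", "+")
    ok <- !is.na(score) & score >= s_threshold
    if (!any(ok)) next
    pv <- score_pvalue(dist, score[ok])
    keep <- pv <= p_threshold
    if (!any(keep)) next
    starts <- which(ok)[keep] - 1L
    sq <- substring(genome$contigs[[contig]], starts + 1L, starts + w)
    isrev <- strand[ok][keep] == "-"
    sq[isrev] <- vapply(sq[isrev], revcomp, character(1), USE.NAMES = FALSE)
    hits[[contig]] <- data.frame(
      contig = contig, start = starts, strand = strand[ok][keep],
      sequence = sq, score = score[ok][keep], p_value = pv[keep],
      stringsAsFactors = FALSE)
  }
  out <- if (length(hits) > 0L) do.call(rbind, hits) else
    data.frame(contig = character(0), start = integer(0),
               strand = character(0), sequence = character(0),
               score = numeric(0), p_value = numeric(0))
  out <- out[order(out$contig, out$start), , drop = FALSE]
  if (!is.null(max_sites) && nrow(out) > max_sites) {
    keep <- order(-out$score)[seq_len(max_sites)]
    out <- out[sort(keep), , drop = FALSE]
  }
  rownames(out) <- NULL
  attr(out, "score_dist") <- dist
  attr(out, "s_threshold") <- s_threshold
  class(out) <- c("mr_sites", "data.frame")
  out
}

#' Choose a raw score threshold for scanning
#'
#' With reference site sequences, returns the largest threshold that still
#' recovers at least `recover` (default 90%) of them, i.e. the appropriate
#' order statistic of their scores.  Without references, the default is
#' 60% of the maximum achievable score.  Unscorable (N-containing)
#' reference sites are excluded with a warning.
#'
#' @param motif an `mr_motif`.
#' @param reference_sites optional character vector of known site
#'   sequences (length w).
#' @param background background probabilities (used for scoring).
#' @param recover fraction of reference sites to recover (default 0.9).
#' @param default_frac fraction of the maximum achievable score used
#'   without references (default 0.6).
#' @return score threshold in bits.
#' @export
choose_score_threshold <- function(motif, reference_sites = NULL,
                                   background = rep(0.25, 4),
                                   recover = 0.9, default_frac = 0.6) {
  theta <- motif$theta
  contrib <- log2(theta) - matrix(log2(background / sum(background)),
                                  nrow(theta), 4, byrow = TRUE)
  if (is.null(reference_sites) || length(reference_sites) == 0L)
    return(default_frac * sum(apply(contrib, 1, max)))
  scores <- vapply(reference_sites, function(s)
    llr_score(motif, background, s), numeric(1), USE.NAMES = FALSE)
  if (anyNA(scores)) {
    mr_log("warn", "%d unscorable reference site(s) excluded",
           sum(is.na(scores)))
    scores <- scores[!is.na(scores)]
  }
  if (length(scores) == 0L)
    return(default_frac * sum(apply(contrib, 1, max)))
  sorted <- sort(scores, decreasing = TRUE)
  sorted[max(1L, ceiling(recover * length(sorted)))]
}

#' Write predicted sites as BED6
#'
#' 0-based half-open coordinates; the score column carries the LLR score in
#' bits, and the p-value is appended as a seventh column.
#'
#' @param sites an `mr_sites` data.frame from [scan_genome()].
#' @param path output file.
#' @param name feature name (default the motif id `"site"`).
#' @return `path`, invisibly.
#' @export
write_sites_bed <- function(sites, path, name = "site") {
  df <- data.frame(sites$contig, sites$start,
                   sites$start + nchar(sites$sequence),
                   paste0(name, "_", seq_len(nrow(sites))),
                   fmt_num(sites$score, 4L), sites$strand,
                   fmt_num(sites$p_value, 4L))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}
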