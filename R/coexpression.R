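# TF-seeded co-regulated gene set estimation: correlation profiles,
# linear-coherency biclustering with optional fitness veto, operon-head
# filtering, feeding order and upstream extraction.

#' Correlation profile of all genes against the TF gene
#'
#' Pearson correlation of every gene's expression with the TF's, computed
#' pairwise over shared non-missing entries of the selected conditions.
#' Genes sharing fewer than `min_obs` observations with the TF, or with
#' zero variance over the shared entries, get `NA` (flagged, excluded from
#' any selection downstream).
#'
#' @param expr genes-by-conditions numeric matrix (missing allowed).
#' @param tf TF gene id (must be a rowname of `expr`).
#' @param conditions condition ids to use (default: all columns).
#' @param min_obs minimum shared non-missing observations (default 10).
#' @return named numeric vector of correlations (NA where undefined).
#' @export
correlation_profile <- function(expr, tf, conditions = NULL,
                                min_obs = 10L) {
  if (!tf %in% rownames(expr)) mr_stop("TF gene '%s' not in matrix", tf)
  cols <- if (is.null(conditions)) seq_len(ncol(expr)) else
    which(colnames(expr) %in% conditions)
  x <- expr[tf, cols]
  sub <- expr[, cols, drop = FALSE]
  r <- suppressWarnings(
    as.vector(cor(t(sub), x, use = "pairwise.complete.obs")))
  names(r) <- rownames(expr)
  nshared <- as.vector((!is.na(sub)) %*% as.numeric(!is.na(x)))
  r[nshared < min_obs] <- NA_real_
  r[!is.finite(r)] <- NA_real_
  r[tf] <- 1
  r
}

#' Estimate the TF-seeded bicluster
#'
#' Alternating optimization for a gene set and condition set that exhibit
#' linear coherency with the TF gene: the model is
#' `x_g = a_g * x_tf + b_g + noise` on the selected conditions.
#'
#' Gene step: keep genes whose |correlation with the TF| over the current
#' conditions is at least `r_init`; when fewer than `min_genes` pass, the
#' top `min_genes` genes by |correlation| are kept instead (seeding rule —
#' correlations over the full condition set are diluted by the incoherent
#' conditions).  Condition step: fit each member gene's least-squares line
#' against the TF, compute per-condition mean squared standardized
#' residuals, and drop conditions above the `q` quantile, never going below
#' `min_cond_frac` of all conditions.  Iterate to a fixed point (at most
#' `max_iter` rounds).
#'
#' When a fitness matrix is supplied, genes whose |fitness correlation with
#' the TF| falls below `r_fit_min` are vetoed from the final set (the TF is
#' exempt; genes without fitness data are kept).
#'
#' @param expr genes-by-conditions expression matrix.
#' @param tf TF gene id.
#' @param fitness optional genes-by-conditions fitness matrix.
#' @param r_init gene admission threshold on |correlation| (default 0.7).
#' @param q residual quantile above which conditions are dropped (0.9).
#' @param min_cond_frac minimum fraction of conditions retained (0.5).
#' @param max_iter maximum alternation rounds (20).
#' @param min_genes seeding floor for the gene step (5).
#' @param r_fit_min fitness veto threshold (0.5).
#' @param min_obs minimum shared observations for any correlation (10).
#' @return object of class `mr_bicluster`: list with `tf`, `genes`,
#'   `conditions`, `score` (mean |gene-TF correlation| over the selected
#'   conditions), `correlations` (signed, per member gene), `fits`
#'   (data.frame gene/slope/intercept/resid_sd), `iterations`,
#'   `converged`, `vetoed` (genes removed by the fitness veto).
#' @export
estimate_bicluster <- function(expr, tf, fitness = NULL,
                               r_init = 0.7, q = 0.9, min_cond_frac = 0.5,
                               max_iter = 20L, min_genes = 5L,
                               r_fit_min = 0.5, min_obs = 10L) {
  if (!tf %in% rownames(expr)) mr_stop("TF gene '%s' not in matrix", tf)
  all_conds <- colnames(expr)
  min_conds <- max(min_obs, ceiling(min_cond_frac * length(all_conds)))
  conds <- all_conds
  genes <- rownames(expr)
  prev <- NULL
  iterations <- 0L
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    iterations <- it
    ## gene step
    r <- correlation_profile(expr, tf, conds, min_obs = min_obs)
    keep <- names(r)[!is.na(r) & abs(r) >= r_init]
    if (length(setdiff(keep, tf)) < min_genes) {
      ord <- order(-abs(r))
      keep <- union(tf, head(names(r)[ord][!is.na(r[ord])], min_genes + 1L))
    }
    genes <- union(tf, keep)
    ## condition step
    fits <- fit_gene_lines(expr, tf, genes, conds)
    resid <- condition_residuals(expr, tf, genes, conds, fits)
    thr <- quantile(resid, q, na.rm = TRUE, names = FALSE)
    drop <- names(resid)[resid > thr]
    new_conds <- setdiff(conds, drop)
    if (length(new_conds) < min_conds) {
      ord <- order(resid)           # keep the best min_conds conditions
      new_conds <- names(resid)[ord][seq_len(min(min_conds, length(resid)))]
      new_conds <- conds[conds %in% new_conds]  # keep original order
    }
    state <- list(genes = sort(genes), conds = new_conds)
    if (identical(state, prev)) { converged <- TRUE; break }
    prev <- state
    conds <- new_conds
  }
  if (length(conds) < min_conds) {
    mr_log("warn", "fewer than %d conditions survived; using all conditions",
           min_conds)
    conds <- all_conds
  }
  r <- correlation_profile(expr, tf, conds, min_obs = min_obs)
  genes <- sort(genes)
  vetoed <- character(0)
  if (!is.null(fitness)) {
    vetoed <- fitness_veto(fitness, tf, setdiff(genes, tf), r_fit_min,
                           min_obs)
    genes <- setdiff(genes, vetoed)
  }
  fits <- fit_gene_lines(expr, tf, genes, conds)
  structure(list(tf = tf, genes = genes, conditions = conds,
                 score = mean(abs(r[genes]), na.rm = TRUE),
                 correlations = r[genes], fits = fits,
                 iterations = iterations, converged = converged,
                 vetoed = vetoed),
            class = "mr_bicluster")
}

# least-squares line x_g = a*x_tf + b per gene over given conditions
fit_gene_lines <- function(expr, tf, genes, conds) {
  x <- expr[tf, conds]
  out <- data.frame(gene = genes, slope = NA_real_, intercept = NA_real_,
                    resid_sd = NA_real_, stringsAsFactors = FALSE)
  for (i in seq_along(genes)) {
    y <- expr[genes[i], conds]
    ok <- !is.na(x) & !is.na(y)
    if (sum(ok) < 3L || stats::var(x[ok]) == 0) next
    a <- stats::cov(x[ok], y[ok]) / stats::var(x[ok])
    b <- mean(y[ok]) - a * mean(x[ok])
    res <- y[ok] - a * x[ok] - b
    out$slope[i] <- a
    out$intercept[i] <- b
    out$resid_sd[i] <- max(stats::sd(res), 1e-8)
  }
  out
}

# per-condition mean squared standardized residual over member genes
condition_residuals <- function(expr, tf, genes, conds, fits) {
  x <- expr[tf, conds]
  genes <- fits$gene[!is.na(fits$slope)]
  if (length(genes) == 0L)
    return(setNames(rep(0, length(conds)), conds))
  fits <- fits[match(genes, fits$gene), ]
  pred <- outer(fits$slope, x) + fits$intercept
  res2 <- ((expr[genes, conds, drop = FALSE] - pred) / fits$resid_sd)^2
  out <- colMeans(res2, na.rm = TRUE)
  out[is.nan(out)] <- 0
  setNames(out, conds)
}

fitness_veto <- function(fitness, tf, genes, r_fit_min, min_obs) {
  if (!tf %in% rownames(fitness)) {
    mr_log("warn", "TF '%s' absent from fitness matrix; veto disabled", tf)
    return(character(0))
  }
  have <- intersect(genes, rownames(fitness))
  if (length(have) == 0L) return(character(0))
  r <- correlation_profile(fitness, tf, min_obs = min_obs)
  vet <- have[!is.na(r[have]) & abs(r[have]) < r_fit_min]
  if (length(vet) > 0L)
    mr_log("info", "fitness veto removed %d gene(s): %s", length(vet),
           paste(vet, collapse = ","))
  vet
}

#' @export
print.mr_bicluster <- function(x, ...) {
  cat(sprintf(
    "mr_bicluster: tf=%s, %d genes x %d conditions, score %.3f (%s)\n",
    x$tf, length(x$genes), length(x$conditions), x$score,
    if (x$converged) sprintf("converged in %d iter", x$iterations)
    else "max_iter reached"))
  invisible(x)
}

#' Keep only operon-head genes
#'
#' Groups the given genes into maximal runs of genomically adjacent
#' same-strand genes (no other annotated gene in between, intergenic gap at
#' most `max_gap`) whose consecutive pairwise expression correlations are
#' at least `r_adj` — i.e. putative operons.  From each run only the head
#' gene (5'-most in gene orientation) is retained; isolated genes pass
#' through unchanged.  Operon-interior genes rarely carry their own binding
#' site, so their upstream windows would only dilute motif discovery.
#'
#' @param genes character vector of gene ids (subset of annotations).
#' @param ann `mr_annotations` for the whole genome.
#' @param expr expression matrix containing the genes.
#' @param tf TF gene id (unused in grouping, kept for interface symmetry).
#' @param r_adj adjacency co-expression threshold in (0,1) (default 0.8).
#' @param max_gap maximum intergenic gap in bp for adjacency (default 200).
#' @param min_obs minimum shared observations for a correlation.
#' @return character vector: the retained head/isolated genes, in
#'   annotation order.
#' @export
filter_operon_heads <- function(genes, ann, expr, tf = NULL, r_adj = 0.8,
                                max_gap = 200L, min_obs = 10L) {
  if (!(r_adj > 0 && r_adj < 1)) mr_stop("r_adj must be in (0,1)")
  missing_ann <- setdiff(genes, ann$gene_id)
  if (length(missing_ann) > 0L)
    mr_stop("unannotated gene(s): %s", paste(missing_ann, collapse = ","))
  idx <- match(genes, ann$gene_id)
  ord <- order(ann$contig[idx], ann$start[idx])
  genes <- genes[ord]
  idx <- idx[ord]
  n <- length(genes)
  if (n == 0L) return(character(0))
  # linked[i]: gene i+1 continues gene i's run
  linked <- logical(max(n - 1L, 0L))
  for (i in seq_len(n - 1L)) {
    a <- idx[i]; b <- idx[i + 1L]
    if (ann$contig[a] != ann$contig[b]) next
    if (ann$strand[a] != ann$strand[b]) next
    if (b != a + 1L) next                    # another annotated gene between
    if (ann$start[b] - ann$end[a] > max_gap) next
    ra <- pair_correlation(expr, genes[i], genes[i + 1L], min_obs)
    if (is.na(ra) || ra < r_adj) next
    linked[i] <- TRUE
  }
  run_id <- cumsum(c(1L, !linked))
  keep <- logical(n)
  for (rid in unique(run_id)) {
    members <- which(run_id == rid)
    if (length(members) == 1L) { keep[members] <- TRUE; next }
    strand <- ann$strand[idx[members[1]]]
    head_i <- if (strand == "+") members[1] else members[length(members)]
    keep[head_i] <- TRUE
  }
  genes[keep]
}

pair_correlation <- function(expr, g1, g2, min_obs = 10L) {
  if (!all(c(g1, g2) %in% rownames(expr))) return(NA_real_)
  x <- expr[g1, ]; y <- expr[g2, ]
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < min_obs) return(NA_real_)
  suppressWarnings(r <- cor(x[ok], y[ok]))
  if (!is.finite(r)) NA_real_ else r
}

#' Order genes for motif discovery
#'
#' Sorts genes by descending |correlation with the TF| (ties by gene id),
#' with the TF's own gene first — sequences most likely to contain a site
#' are fed to the sampler first.  With `scramble = TRUE` a seeded random
#' permutation is returned instead (useful for re-runs when co-expression
#' is not determinative).
#'
#' @param genes character vector of gene ids.
#' @param expr expression matrix.
#' @param tf TF gene id.
#' @param scramble return a seeded random permutation instead.
#' @param seed RNG seed for `scramble`.
#' @return ordered character vector of gene ids.
#' @export
feeding_order <- function(genes, expr, tf, scramble = FALSE, seed = 1L) {
  missing <- setdiff(genes, rownames(expr))
  if (length(missing) > 0L)
    mr_stop("gene(s) not in expression matrix: %s",
            paste(missing, collapse = ","))
  if (scramble) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old))
    set.seed(derive_seed(seed, 0L))
    return(sample(genes))
  }
  r <- correlation_profile(expr, tf)[genes]
  r[is.na(r)] <- 0
  ord <- order(-abs(r), genes)
  out <- genes[ord]
  if (tf %in% out) out <- c(tf, setdiff(out, tf))
  out
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Extract upstream sequences of genes
#'
#' For each gene, the `length` bases 5' of its translation start in gene
#' orientation: for a `+` strand gene the slice `[start-length, start)`,
#' for a `-` strand gene the reverse complement of `[end, end+length)`.
#' Windows are truncated at contig edges; genes whose window is empty are
#' skipped with a warning.
#'
#' @param genes ordered character vector of gene ids.
#' @param genome an `mr_genome`.
#' @param ann `mr_annotations`.
#' @param length upstream window size in bp (default 300).
#' @return named character vector of upstream sequences (names = gene ids),
#'   in the order of `genes`.
#' @export
extract_upstreams <- function(genes, genome, ann, length = 300L) {
  idx <- match(genes, ann$gene_id)
  if (anyNA(idx))
    mr_stop("unannotated gene(s): %s",
            paste(genes[is.na(idx)], collapse = ","))
  out <- character(0)
  for (k in seq_along(genes)) {
    i <- idx[k]
    contig <- genome$contigs[[ann$contig[i]]]
    if (is.null(contig)) mr_stop("contig %s not in genome", ann$contig[i])
    L <- nchar(contig)
    if (ann$strand[i] == "+") {
      from <- max(0L, ann$start[i] - length)
      to <- ann$start[i]
      if (to <= from) {
        mr_log("warn", "gene %s at contig start: empty upstream, skipped",
               genes[k])
        next
      }
      s <- substr(contig, from + 1L, to)
    } else {
      from <- ann$end[i]
      to <- min(L, ann$end[i] + length)
      if (to <= from) {
        mr_log("warn", "gene %s at contig end: empty upstream, skipped",
               genes[k])
        next
      }
      s <- revcomp(substr(contig, from + 1L, to))
    }
    if (nchar(s) < length)
      mr_log("warn", "gene %s upstream truncated to %d bp", genes[k],
             nchar(s))
    out[genes[k]] <- s
  }
  out
}
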