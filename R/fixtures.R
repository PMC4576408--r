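# Seeded generators for synthetic test data: planted PWMs, toy genomes
# with planted binding sites, expression matrices with planted linear-
# coherency biclusters, operon structures, and fitness matrices.  Every
# generator is a pure function of (parameters, seed), and each bundle
# carries its ground truth.

with_seed <- function(seed, expr) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  expr
}

#' Generate a random PWM with exact core-block symmetry
#'
#' Core blocks are the motif halves: `block1 = [0, c)`,
#' `block2 = [w - c, w)` with `c = floor(w/2)`.  A random core consensus is
#' drawn; each core column gives probability `conservation` to its
#' consensus base and splits the rest evenly.  Block2 is the exact
#' transform of block1 under the requested symmetry, so
#' [block_dissimilarity()] is 0 for that type by construction.  The middle
#' column of odd-width motifs is mildly informative.  Consensus draws are
#' rejected until the three symmetry transforms are mutually separated by
#' at least 0.5 bits, keeping the planted symmetry identifiable.
#'
#' @param width motif width.
#' @param symmetry `"palindromic"`, `"direct_repeat"`, `"inverted_repeat"`
#'   or `"none"` (independent random block2).
#' @param conservation dominant-base probability in core columns,
#'   in (0.25, 1).
#' @param seed integer seed.
#' @return an `mr_motif` with blocks and symmetry annotated.
#' @export
make_pwm <- function(width, symmetry = "palindromic", conservation = 0.85,
                     seed = 1L) {
  if (!(conservation > 0.25 && conservation <= 1))
    mr_stop("conservation must be in (0.25, 1]")
  cons <- min(conservation, 1 - 3e-4)   # keep entries strictly positive
  w <- as.integer(width)
  cc <- w %/% 2L
  with_seed(derive_seed(seed, 104729L), {
    repeat {
      cons1 <- sample.int(4L, cc, replace = TRUE)
      block1 <- column_probs(cons1, cons)
      block2 <- switch(symmetry,
        palindromic = column_probs(rev(comp_code(cons1)), cons),
        direct_repeat = column_probs(cons1, cons),
        inverted_repeat = column_probs(rev(cons1), cons),
        none = column_probs(sample.int(4L, cc, replace = TRUE), cons))
      theta <- matrix(0.25, w, 4)
      theta[1:cc, ] <- block1
      theta[(w - cc + 1L):w, ] <- block2
      if (w %% 2L == 1L) {
        mid <- sample.int(4L, 1L)
        theta[cc + 1L, ] <- column_probs(mid, 0.4)
      }
      # identifiability: the three transforms must disagree on block1/2
      b1 <- c(0L, cc); b2 <- c(w - cc, w)
      D <- vapply(SYMMETRY_TYPES, function(s)
        block_dissimilarity(theta, b1, b2, s), numeric(1))
      sep_ok <- symmetry == "none" ||
        all(D[setdiff(SYMMETRY_TYPES, symmetry)] > D[symmetry] + 0.5)
      if (sep_ok) {
        return(motif_model(theta, b1, b2, symmetry,
                           name = paste0("planted_", symmetry)))
      }
    }
  })
}

column_probs <- function(cons_codes, conservation) {
  m <- matrix((1 - conservation) / 3, length(cons_codes), 4)
  m[cbind(seq_along(cons_codes), cons_codes)] <- conservation
  m
}

#' Sample site sequences from a PWM at a given per-position identity
#'
#' Each position emits the consensus base with probability `identity` and
#' otherwise a uniform non-consensus base; `identity = NULL` samples from
#' the PWM probabilities themselves.
#'
#' @param motif an `mr_motif`.
#' @param n number of sites.
#' @param identity per-position consensus identity, or `NULL`.
#' @param seed integer seed.
#' @return character vector of site sequences.
#' @export
sample_sites <- function(motif, n, identity = NULL, seed = 1L) {
  theta <- motif$theta
  w <- motif$width
  cons <- dna_to_code(motif$consensus)
  with_seed(derive_seed(seed, 15485863L %% 1000000L), {
    vapply(seq_len(n), function(i) {
      bases <- vapply(seq_len(w), function(j) {
        if (is.null(identity)) {
          sample.int(4L, 1L, prob = theta[j, ])
        } else if (runif(1) <= identity) {
          cons[j]
        } else {
          sample(setdiff(1:4, cons[j]), 1L)
        }
      }, integer(1))
      code_to_dna(bases)
    }, character(1))
  })
}

#' Generate background sequences with planted motif instances
#'
#' Each sequence is i.i.d. background; with probability `presence` one
#' site (drawn by [sample_sites()] at the given identity) is planted at a
#' uniform offset on the forward strand.  The returned truth records
#' presence and offsets, giving a self-contained benchmark for motif
#' discovery.
#'
#' @param motif planted `mr_motif`.
#' @param n number of sequences.
#' @param len sequence length (default 300).
#' @param identity per-position consensus identity (or `NULL` to sample
#'   from the PWM).
#' @param presence probability a sequence contains a site (default 0.9).
#' @param background base probabilities of the background.
#' @param seed integer seed.
#' @return list with `sequences` (named character vector) and `truth`
#'   (data.frame `seq_id`, `present`, `offset`, `site`).
#' @export
make_planted_sequences <- function(motif, n, len = 300L, identity = 0.85,
                                   presence = 0.9,
                                   background = rep(0.25, 4), seed = 1L) {
  w <- motif$width
  if (len < w) mr_stop("sequence length %d below motif width %d", len, w)
  sites <- sample_sites(motif, n, identity = identity,
                        seed = derive_seed(seed, 271L))
  with_seed(derive_seed(seed, 979687L), {
    present <- runif(n) <= presence
    offsets <- rep(NA_integer_, n)
    seqs <- vapply(seq_len(n), function(i) {
      s <- code_to_dna(sample.int(4L, len, replace = TRUE,
                                  prob = background))
      if (!present[i]) return(s)
      o <- sample.int(len - w + 1L, 1L) - 1L
      offsets[i] <<- o
      paste0(substr(s, 1, o), sites[i], substr(s, o + w + 1L, len))
    }, character(1))
    names(seqs) <- sprintf("seq%03d", seq_len(n))
    list(sequences = seqs,
         truth = data.frame(seq_id = names(seqs), present = present,
                            offset = offsets,
                            site = ifelse(present, sites, NA_character_),
                            stringsAsFactors = FALSE))
  })
}

#' Generate a toy genome with planted binding sites
#'
#' Builds an i.i.d. background contig, places `n_genes` genes (300 bp ORFs)
#' along it and plants one motif site in the 300-bp upstream window (in
#' gene orientation) of each designated regulon gene.  Non-operon genes
#' alternate strands and are spaced >= 400 bp apart so upstream windows
#' never overlap ORFs; genes named in `operons` are placed consecutively
#' on a shared strand with 50-bp intergenic gaps, so adjacency-based
#' operon detection has true positives.
#'
#' @param n_genes number of genes.
#' @param site_genes character vector (subset of gene ids `g01`, `g02`,
#'   ...) receiving a planted site.
#' @param motif planted `mr_motif` (see [make_pwm()]).
#' @param identity per-site consensus identity in (0, 1]; 1 plants exact
#'   consensus sites.
#' @param operons named list: operon id -> vector of member gene ids
#'   (consecutive placement, head first); `NULL` for none.
#' @param background genome background probabilities.
#' @param upstream_length upstream window size (default 300).
#' @param gene_length ORF length (default 300).
#' @param spacing intergenic spacing for non-operon genes (default 420).
#' @param contig_length total contig length; `NULL` sizes automatically,
#'   and a length too small for the layout is an error.
#' @param seed integer seed.
#' @return list with `genome` (`mr_genome`), `annotations`
#'   (`mr_annotations`), `operons` (`mr_operons` or NULL) and `truth`
#'   (list: `motif`, `consensus`, `symmetry`, `sites` data.frame with
#'   `gene_id`, `contig`, `start`, `strand`, `sequence`, `offset`;
#'   `site_genes`; `params`).
#' @export
make_genome <- function(n_genes, site_genes, motif, identity = 0.9,
                        operons = NULL, background = rep(0.25, 4),
                        upstream_length = 300L, gene_length = 300L,
                        spacing = 420L, contig_length = NULL, seed = 1L) {
  gene_ids <- sprintf("g%02d", seq_len(n_genes))
  bad <- setdiff(site_genes, gene_ids)
  if (length(bad) > 0L) mr_stop("unknown site gene(s): %s",
                                paste(bad, collapse = ","))
  in_operon <- unlist(operons, use.names = FALSE)
  if (anyDuplicated(in_operon))
    mr_stop("gene in more than one operon")
  # layout: walk along the contig, alternating strand for singletons
  starts <- integer(n_genes); ends <- integer(n_genes)
  strands <- character(n_genes)
  pos <- spacing
  flip <- TRUE
  i <- 1L
  placed <- character(0)
  while (i <= n_genes) {
    gid <- gene_ids[i]
    if (gid %in% placed) { i <- i + 1L; next }
    run <- gid
    for (op in operons) if (gid == op[1]) run <- op
    strand <- if (flip) "+" else "-"
    flip <- !flip
    run_in_order <- if (strand == "+") run else rev(run)
    for (g in run_in_order) {
      k <- match(g, gene_ids)
      starts[k] <- pos
      ends[k] <- pos + gene_length
      strands[k] <- strand
      placed <- c(placed, g)
      pos <- pos + gene_length + 50L
    }
    pos <- pos - 50L + spacing
    i <- i + 1L
  }
  total <- pos + upstream_length
  if (is.null(contig_length)) contig_length <- total
  if (contig_length < total)
    mr_stop("contig_length %d too small for layout (need %d)",
            contig_length, total)

  with_seed(derive_seed(seed, 32452843L %% 1000000L), {
    contig <- code_to_dna(sample.int(4L, contig_length, replace = TRUE,
                                     prob = background))
    site_seqs <- sample_sites(motif, length(site_genes),
                              identity = if (identity >= 1) NULL else
                                identity,
                              seed = derive_seed(seed, 7L))
    if (identity >= 1)
      site_seqs <- rep(motif$consensus, length(site_genes))
    w <- motif$width
    truth_rows <- list()
    for (k in seq_along(site_genes)) {
      g <- site_genes[k]
      gi <- match(g, gene_ids)
      # uniform placement within the upstream window, in gene orientation
      offset <- -(sample.int(upstream_length - w, 1L) + w - 1L)
      if (strands[gi] == "+") {
        s0 <- starts[gi] + offset
        planted <- site_seqs[k]
      } else {
        s0 <- ends[gi] - offset - w
        planted <- revcomp(site_seqs[k])
      }
      substr(contig, s0 + 1L, s0 + w) <- planted
      truth_rows[[k]] <- data.frame(
        gene_id = g, contig = "chr", start = s0, strand = strands[gi],
        sequence = site_seqs[k], offset = offset,
        stringsAsFactors = FALSE)
    }
    genome <- genome_from_strings(c(chr = contig))
    ann <- annotations(gene_ids, "chr", starts, ends, strands)
    ops <- if (is.null(operons)) NULL else
      operon_table(unlist(operons, use.names = FALSE),
                   rep(names(operons), lengths(operons)))
    list(genome = genome, annotations = ann, operons = ops,
         truth = list(motif = motif, consensus = motif$consensus,
                      symmetry = motif$symmetry,
                      sites = do.call(rbind, truth_rows),
                      site_genes = site_genes,
                      params = list(n_genes = n_genes, identity = identity,
                                    upstream_length = upstream_length,
                                    seed = seed)))
  })
}

#' Generate an expression matrix with a planted linear-coherency bicluster
#'
#' The TF profile is standard normal over all conditions.  Bicluster genes
#' follow `a_g * x_tf + b_g + sigma * noise` on the bicluster conditions
#' and independent standard normal noise elsewhere; all other cells are
#' independent standard normal.  Genes listed in `operon_runs` copy their
#' run head's finished profile plus `run_sd` noise, emulating
#' co-transcription (for adjacency-filter tests).
#'
#' @param n_genes,n_conditions matrix dimensions.
#' @param bicluster_genes gene ids in the planted bicluster (must include
#'   `tf`).
#' @param bicluster_conditions condition ids (subset of `c001`, ...) or a
#'   count (the first k conditions).
#' @param tf TF gene id (default the first bicluster gene).
#' @param sigma residual noise sd within the bicluster (default 0.3).
#' @param slope_range magnitude range of the slopes `a_g` (sign random).
#' @param operon_runs named list: run head gene id -> member gene ids that
#'   copy its profile.
#' @param run_sd noise sd for operon-run copies (default 0.1).
#' @param gene_ids optional explicit gene ids (default `g01`...).
#' @param seed integer seed.
#' @return list with `expr` (matrix), `truth` (list: `tf`, `genes`,
#'   `conditions`, `slopes`, `intercepts`, `sigma`, `operon_runs`,
#'   `seed`).
#' @export
make_expression <- function(n_genes, n_conditions, bicluster_genes,
                            bicluster_conditions, tf = bicluster_genes[1],
                            sigma = 0.3, slope_range = c(0.8, 1.5),
                            operon_runs = NULL, run_sd = 0.1,
                            gene_ids = NULL, seed = 1L) {
  if (is.null(gene_ids))
    gene_ids <- sprintf("g%0*d", max(2L, nchar(n_genes)), seq_len(n_genes))
  cond_ids <- sprintf("c%03d", seq_len(n_conditions))
  if (is.numeric(bicluster_conditions) && length(bicluster_conditions) == 1L)
    bicluster_conditions <- cond_ids[seq_len(bicluster_conditions)]
  if (!tf %in% bicluster_genes)
    mr_stop("tf must be a member of the planted bicluster")
  if (!all(bicluster_genes %in% gene_ids))
    mr_stop("bicluster gene(s) outside the gene universe")
  with_seed(derive_seed(seed, 49979687L %% 1000000L), {
    expr <- matrix(rnorm(n_genes * n_conditions), n_genes, n_conditions,
                   dimnames = list(gene_ids, cond_ids))
    x <- rnorm(n_conditions)
    expr[tf, ] <- x
    others <- setdiff(bicluster_genes, tf)
    slopes <- setNames(runif(length(others), slope_range[1],
                             slope_range[2]) *
                         sample(c(-1, 1), length(others), replace = TRUE),
                       others)
    intercepts <- setNames(runif(length(others), -1, 1), others)
    bc <- match(bicluster_conditions, cond_ids)
    for (g in others) {
      expr[g, bc] <- slopes[g] * x[bc] + intercepts[g] +
        sigma * rnorm(length(bc))
    }
    if (!is.null(operon_runs)) {
      for (h in names(operon_runs)) {
        for (m in operon_runs[[h]]) {
          expr[m, ] <- expr[h, ] + run_sd * rnorm(n_conditions)
        }
      }
    }
    list(expr = expr,
         truth = list(tf = tf, genes = sort(bicluster_genes),
                      conditions = bicluster_conditions, slopes = slopes,
                      intercepts = intercepts, sigma = sigma,
                      operon_runs = operon_runs, seed = seed))
  })
}

#' Generate a knockout-fitness matrix with a coherent gene subset
#'
#' Coherent genes share a latent per-condition response vector plus noise;
#' all other genes are independent standard normal.  Condition ids (`f001`,
#' ...) are disjoint from expression condition ids by construction.
#'
#' @param genes gene ids.
#' @param n_conditions number of fitness conditions.
#' @param coherent character vector of coherent gene ids (subset of
#'   `genes`).
#' @param sigma noise sd around the latent response (default 0.1).
#' @param seed integer seed.
#' @return list with `fitness` (matrix) and `truth` (list: `coherent`,
#'   `sigma`, `seed`).
#' @export
make_fitness <- function(genes, n_conditions, coherent = character(0),
                         sigma = 0.1, seed = 1L) {
  bad <- setdiff(coherent, genes)
  if (length(bad) > 0L) mr_stop("coherent gene(s) not in genes: %s",
                                paste(bad, collapse = ","))
  cond_ids <- sprintf("f%03d", seq_len(n_conditions))
  with_seed(derive_seed(seed, 86028157L %% 1000000L), {
    fit <- matrix(rnorm(length(genes) * n_conditions), length(genes),
                  n_conditions, dimnames = list(genes, cond_ids))
    if (length(coherent) > 0L) {
      z <- rnorm(n_conditions)
      for (g in coherent) fit[g, ] <- z + sigma * rnorm(n_conditions)
    }
    list(fitness = fit, truth = list(coherent = coherent, sigma = sigma,
                                     seed = seed))
  })
}

#' Generate the default end-to-end fixture bundle
#'
#' A desk-scale emulation of a bacterial regulon study: 50 genes on one
#' contig, a TF (`g01`) with an 18-bp palindromic motif, planted sites
#' upstream of 12 genes (8 singletons including the autoregulated TF and 4
#' three-gene operon heads), a 200-condition expression matrix whose
#' 120-condition bicluster holds the 12 site genes (operon members copy
#' their head), and a 30-condition fitness matrix coherent for the regulon
#' genes.  The truth regulon is the 12 site genes plus the 8 operon-member
#' genes.
#'
#' @param seed integer seed (default 7).
#' @param n_genes number of genes (default 50).
#' @param motif_width planted motif width (default 18).
#' @param conservation core conservation of the planted PWM (default 0.9).
#' @param identity per-site consensus identity (default 0.9).
#' @param sigma expression noise within the bicluster (default 0.3).
#' @param n_conditions expression conditions (default 200).
#' @param n_bicluster_conditions coherent conditions (default 120).
#' @param n_fitness_conditions fitness conditions (default 30).
#' @return list with `genome`, `annotations`, `operons`, `expr`,
#'   `fitness`, `tf`, and `truth` (planted motif, sites, regulon genes,
#'   bicluster, operon map, all generator parameters).
#' @export
make_fixture_bundle <- function(seed = 7L, n_genes = 50L,
                                motif_width = 18L, conservation = 0.9,
                                identity = 0.9, sigma = 0.3,
                                n_conditions = 200L,
                                n_bicluster_conditions = 120L,
                                n_fitness_conditions = 30L) {
  tf <- "g01"
  singletons <- sprintf("g%02d", 1:8)
  heads <- sprintf("g%02d", c(10, 20, 30, 40))
  operons <- list(op1 = sprintf("g%02d", 10:12),
                  op2 = sprintf("g%02d", 20:22),
                  op3 = sprintf("g%02d", 30:32),
                  op4 = sprintf("g%02d", 40:42))
  site_genes <- c(singletons, heads)
  members <- setdiff(unlist(operons), heads)
  motif <- make_pwm(motif_width, "palindromic", conservation,
                    seed = derive_seed(seed, 3L))
  gen <- make_genome(n_genes, site_genes, motif, identity = identity,
                     operons = operons, seed = derive_seed(seed, 11L))
  run_list <- setNames(lapply(operons, function(x) x[-1]),
                       vapply(operons, `[`, character(1), 1))
  ex <- make_expression(n_genes, n_conditions, site_genes,
                        n_bicluster_conditions, tf = tf, sigma = sigma,
                        operon_runs = run_list,
                        gene_ids = sprintf("g%02d", seq_len(n_genes)),
                        seed = derive_seed(seed, 13L))
  regulon_genes <- sort(c(site_genes, members))
  fit <- make_fitness(sprintf("g%02d", seq_len(n_genes)),
                      n_fitness_conditions, coherent = regulon_genes,
                      seed = derive_seed(seed, 17L))
  list(genome = gen$genome, annotations = gen$annotations,
       operons = gen$operons, expr = ex$expr, fitness = fit$fitness,
       tf = tf,
       truth = list(motif = motif, consensus = motif$consensus,
                    symmetry = motif$symmetry, sites = gen$truth$sites,
                    site_genes = site_genes, regulon_genes = regulon_genes,
                    bicluster = ex$truth, fitness = fit$truth,
                    operons = operons, seed = seed,
                    params = list(n_genes = n_genes,
                                  motif_width = motif_width,
                                  conservation = conservation,
                                  identity = identity, sigma = sigma)))
}

#' Write a fixture bundle to disk
#'
#' Emits FASTA (genome), GFF3 (annotations), TSV (expression, fitness,
#' operons), MEME (planted motif) and a JSON truth file, i.e. exactly the
#' input formats the pipeline readers consume.
#'
#' @param bundle a bundle from [make_fixture_bundle()].
#' @param dir output directory (created if needed).
#' @return named character vector of written paths, invisibly.
#' @export
write_fixture_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(genome = file.path(dir, "genome.fa"),
             annotations = file.path(dir, "genes.gff3"),
             expression = file.path(dir, "expression.tsv"),
             fitness = file.path(dir, "fitness.tsv"),
             operons = file.path(dir, "operons.tsv"),
             motif = file.path(dir, "planted_motif.meme"),
             truth = file.path(dir, "truth.json"))
  write_fasta(bundle$genome, paths["genome"])
  write_annotations_gff3(bundle$annotations, paths["annotations"])
  write_matrix(bundle$expr, paths["expression"])
  write_matrix(bundle$fitness, paths["fitness"])
  write_operons(bundle$operons, paths["operons"])
  write_motif(bundle$truth$motif, paths["motif"])
  truth <- bundle$truth
  truth$motif <- list(theta = unname(truth$motif$theta),
                      block1 = truth$motif$block1,
                      block2 = truth$motif$block2,
                      symmetry = truth$motif$symmetry)
  jsonlite::write_json(truth, paths["truth"], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(paths)
}
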