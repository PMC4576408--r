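# Configuration and the end-to-end pipeline:
# bicluster -> operon-head filter -> feeding order -> upstream extraction
# -> motif discovery -> genome scan -> regulon assembly -> evaluation.

#' Default pipeline configuration
#'
#' Returns the full set of tunable parameters with their defaults; any
#' subset can be overridden by a YAML config file ([read_config()]) or by
#' the caller.
#'
#' @return named list of parameters.
#' @export
default_config <- function() {
  list(
    genome = NULL, annotations = NULL, expression = NULL, fitness = NULL,
    operons = NULL, tf = NULL, out_dir = NULL, seed = 1L,
    na_token = "NA", transpose = FALSE,
    # coexpression
    r_init = 0.7, residual_quantile = 0.9, min_cond_frac = 0.5,
    max_iter = 20L, min_genes = 5L, r_fit_min = 0.5, min_obs = 10L,
    r_adj = 0.8, max_gap = 200L, upstream_length = 300L,
    min_sequences = 4L, scramble = FALSE,
    # motif discovery
    w_min = 12L, w_max = 24L, n_particles = 1000L, alpha = 0.5,
    presence = 0.8, lambda_sym = 1.0, prior_motif = NULL, prior_m = 10,
    none_threshold = 1.0, resample_frac = 0.5,
    # scan + assembly
    p_threshold = 0.001, s_threshold = NULL, max_sites = NULL,
    bg_floor = 1e-3, max_upstream = 300L, allow_intragenic = TRUE,
    extend_operons = TRUE, strand_restricted = FALSE,
    log_level = "info")
}

#' Read a pipeline configuration from YAML
#'
#' Keys mirror [default_config()]; unknown keys are an error so typos do
#' not silently fall back to defaults.
#'
#' @param path YAML file.
#' @param overrides named list applied on top of the file (e.g. parsed CLI
#'   flags; these win).
#' @return full configuration list.
#' @export
read_config <- function(path = NULL, overrides = list()) {
  cfg <- default_config()
  if (!is.null(path)) {
    file_cfg <- yaml::read_yaml(path)
    unknown <- setdiff(names(file_cfg), names(cfg))
    if (length(unknown) > 0L)
      mr_stop("unknown config key(s): %s", paste(unknown, collapse = ","))
    cfg <- modifyList(cfg, file_cfg)
  }
  overrides <- overrides[!vapply(overrides, is.null, logical(1))]
  unknown <- setdiff(names(overrides), names(cfg))
  if (length(unknown) > 0L)
    mr_stop("unknown config key(s): %s", paste(unknown, collapse = ","))
  modifyList(cfg, overrides)
}

#' Run the full regulon-inference pipeline
#'
#' Chains all stages from raw input files (or in-memory objects) to the
#' predicted regulon.  All randomness derives from `config$seed`; a fixed
#' seed gives bit-identical outputs.  When `config$out_dir` is set, every
#' intermediate artifact is written there (gene set TSV, upstream FASTA,
#' motif MEME, width-score TSV, site TSV/BED, regulon TSV, JSON report).
#'
#' @param config a configuration list (see [default_config()] /
#'   [read_config()]).  `genome`, `annotations`, `expression` may be file
#'   paths or ready objects; `tf` is required.
#' @return list of class `mr_pipeline`: `bicluster`, `head_genes`,
#'   `feeding_order`, `upstreams`, `discovery`, `motif`, `sites`,
#'   `regulon`, `config`, `report`.
#' @export
run_pipeline <- function(config) {
  cfg <- modifyList(default_config(), config)
  if (is.null(cfg$tf)) mr_stop("config must name the TF gene id ('tf')")
  if (is.null(cfg$genome) || is.null(cfg$annotations) ||
      is.null(cfg$expression))
    mr_stop("config must name genome, annotations and expression inputs")
  old_level <- set_log_level(cfg$log_level)
  on.exit(set_log_level(old_level))

  digests <- list()
  load_input <- function(x, reader, what) {
    if (is.character(x) && length(x) == 1L) {
      mr_log("info", "reading %s from %s (md5 %s)", what, x,
             digests[[what]] <<- input_digest(x))
      reader(x)
    } else x
  }
  genome <- load_input(cfg$genome, read_genome, "genome")
  ann <- load_input(cfg$annotations, read_annotations, "annotations")
  expr <- load_input(cfg$expression,
                     function(p) read_matrix(p, cfg$na_token,
                                             cfg$transpose),
                     "expression")
  fitness <- if (is.null(cfg$fitness)) NULL else
    load_input(cfg$fitness, function(p) read_matrix(p, cfg$na_token),
               "fitness")
  operons <- if (is.null(cfg$operons)) NULL else
    load_input(cfg$operons, read_operons, "operons")
  prior_theta <- if (is.null(cfg$prior_motif)) NULL else
    load_input(cfg$prior_motif, read_motif, "prior_motif")

  if (!cfg$tf %in% rownames(expr))
    mr_stop("TF gene '%s' absent from the expression matrix", cfg$tf)

  mr_log("info", "stage 1: bicluster estimation (r_init=%.2f, q=%.2f)",
         cfg$r_init, cfg$residual_quantile)
  bic <- estimate_bicluster(expr, cfg$tf, fitness = fitness,
                            r_init = cfg$r_init,
                            q = cfg$residual_quantile,
                            min_cond_frac = cfg$min_cond_frac,
                            max_iter = cfg$max_iter,
                            min_genes = cfg$min_genes,
                            r_fit_min = cfg$r_fit_min,
                            min_obs = cfg$min_obs)

  mr_log("info", "stage 2: operon-head filter (r_adj=%.2f, gap<=%d)",
         cfg$r_adj, cfg$max_gap)
  heads <- filter_operon_heads(intersect(bic$genes, ann$gene_id), ann,
                               expr, cfg$tf, r_adj = cfg$r_adj,
                               max_gap = cfg$max_gap,
                               min_obs = cfg$min_obs)

  order_genes <- feeding_order(heads, expr, cfg$tf,
                               scramble = isTRUE(cfg$scramble),
                               seed = cfg$seed)
  upstreams <- extract_upstreams(order_genes, genome, ann,
                                 length = cfg$upstream_length)
  if (length(upstreams) < cfg$min_sequences)
    mr_stop(paste0("high-confidence set too small: %d upstream sequences",
                   " (minimum %d); relax r_init or supply more data"),
            length(upstreams), cfg$min_sequences)

  mr_log("info", "stage 3: motif discovery on %d sequences (w %d..%d)",
         length(upstreams), cfg$w_min, cfg$w_max)
  disc <- discover_motif(upstreams, w_range = cfg$w_min:cfg$w_max,
                         n_particles = cfg$n_particles,
                         seed = derive_seed(cfg$seed, 23L),
                         alpha = cfg$alpha, presence = cfg$presence,
                         lambda_sym = cfg$lambda_sym,
                         background = genome$background,
                         prior_theta = prior_theta,
                         prior_m = cfg$prior_m,
                         none_threshold = cfg$none_threshold,
                         resample_frac = cfg$resample_frac)
  if (disc$status != "ok")
    mr_stop("motif discovery failed: %s", disc$status)

  mr_log("info", "stage 4: genome scan (p<=%g)", cfg$p_threshold)
  sites <- scan_genome(genome, disc$motif, p_threshold = cfg$p_threshold,
                       s_threshold = cfg$s_threshold,
                       max_sites = cfg$max_sites, bg_floor = cfg$bg_floor)

  mr_log("info", "stage 5: regulon assembly (%d sites)", nrow(sites))
  entries <- assign_sites_to_genes(sites, ann,
                                   max_upstream = cfg$max_upstream,
                                   allow_intragenic = cfg$allow_intragenic,
                                   strand_restricted =
                                     cfg$strand_restricted)
  if (isTRUE(cfg$extend_operons) && !is.null(operons))
    entries <- extend_operons(entries, operons, ann)
  reg <- regulon(cfg$tf, entries)

  report <- list(
    tf = cfg$tf, seed = cfg$seed,
    n_bicluster_genes = length(bic$genes),
    n_bicluster_conditions = length(bic$conditions),
    bicluster_score = bic$score,
    n_head_genes = length(heads),
    motif_width = disc$motif$width,
    motif_consensus = disc$motif$consensus,
    motif_symmetry = disc$motif$symmetry,
    motif_information_bits = pwm_information(disc$motif$theta),
    s_threshold = attr(sites, "s_threshold"),
    n_sites = nrow(sites),
    n_regulon_genes = length(reg$genes),
    n_intragenic = sum(entries$intragenic),
    n_via_operon = sum(entries$via_operon),
    input_digests = digests)

  out <- structure(list(bicluster = bic, head_genes = heads,
                        feeding_order = order_genes,
                        upstreams = upstreams, discovery = disc,
                        motif = disc$motif, sites = sites, regulon = reg,
                        config = cfg, report = report),
                   class = "mr_pipeline")
  if (!is.null(cfg$out_dir)) write_pipeline_outputs(out, cfg$out_dir)
  out
}

write_pipeline_outputs <- function(res, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  bic <- res$bicluster
  gene_status <- data.frame(
    gene_id = names(bic$correlations),
    correlation = unname(bic$correlations),
    head = names(bic$correlations) %in% res$head_genes,
    vetoed = names(bic$correlations) %in% bic$vetoed,
    stringsAsFactors = FALSE)
  write_tsv(gene_status, file.path(dir, "bicluster_genes.tsv"))
  writeLines(bic$conditions, file.path(dir, "bicluster_conditions.txt"))
  write_fasta(res$upstreams, file.path(dir, "upstreams.fa"))
  write_motif(res$motif, file.path(dir, "motif.meme"))
  write_tsv(res$discovery$width_scores, file.path(dir, "width_scores.tsv"))
  write_tsv(res$discovery$sites, file.path(dir, "site_calls.tsv"))
  sites_df <- as.data.frame(res$sites)
  write_tsv(sites_df, file.path(dir, "sites.tsv"))
  write_sites_bed(res$sites, file.path(dir, "sites.bed"))
  write_regulon(res$regulon, file.path(dir, "regulon.tsv"))
  rep <- res$report
  jsonlite::write_json(rep, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = 10, pretty = TRUE)
  invisible(dir)
}

#' @export
print.mr_pipeline <- function(x, ...) {
  r <- x$report
  cat(sprintf(
    paste0("mr_pipeline: tf=%s\n",
           "  bicluster: %d genes x %d conditions (score %.3f)\n",
           "  heads fed to discovery: %d\n",
           "  motif: width %d, %s, symmetry %s\n",
           "  sites: %d (threshold %.2f bits, p<=%g)\n",
           "  regulon: %d genes\n"),
    r$tf, r$n_bicluster_genes, r$n_bicluster_conditions,
    r$bicluster_score, r$n_head_genes, r$motif_width, r$motif_consensus,
    r$motif_symmetry, r$n_sites, r$s_threshold, x$config$p_threshold,
    r$n_regulon_genes))
  invisible(x)
}
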