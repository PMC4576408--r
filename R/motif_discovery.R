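# Two-block SMC motif discovery: a population of weighted particles, each
# holding per-sequence site placements and the aligned base counts, is
# updated one upstream sequence at a time.  Candidate placements are scored
# by a Dirichlet-multinomial predictive against the genome background, a
# presence prior, and a symmetry prior favouring PWMs whose half-site
# blocks are mutually palindromic / repeated.  The motif width is selected
# by penalized marginal likelihood across independent SMC families.

#' Symmetrized cross-entropy dissimilarity between two PWM blocks
#'
#' `D = (1/c) * sum_j [KL(p_j || q_j) + KL(q_j || p_j)] / 2` in bits, where
#' `p_j` is the j-th column of `block1` and `q_j` the j-th column of
#' `block2` transformed per symmetry type: `palindromic` reverse-complements
#' block2, `direct_repeat` leaves it unchanged, `inverted_repeat` reverses
#' the column order without complementing.  `D` is 0 iff the transformed
#' blocks are identical, so minimizing it maximizes the intrinsic symmetry
#' conformation of the motif cores.
#'
#' @param theta w-by-4 PWM (strictly positive entries) or an `mr_motif`.
#' @param block1,block2 half-open intervals `c(from, to)`, equal length.
#' @param symmetry `"palindromic"`, `"direct_repeat"` or
#'   `"inverted_repeat"`.
#' @return nonnegative dissimilarity in bits.
#' @export
block_dissimilarity <- function(theta, block1, block2,
                                symmetry = c("palindromic", "direct_repeat",
                                             "inverted_repeat")) {
  if (inherits(theta, "mr_motif")) theta <- theta$theta
  symmetry <- match.arg(symmetry)
  check_blocks(nrow(theta), block1, block2)
  if (any(theta <= 0))
    mr_stop("theta has zero entries; apply pseudocounts first")
  p <- theta[(block1[1] + 1L):block1[2], , drop = FALSE]
  q <- theta[(block2[1] + 1L):block2[2], , drop = FALSE]
  q <- transform_block(q, symmetry)
  d <- 0.5 * rowSums((p - q) * (log2(p) - log2(q)))
  mean(d)
}

transform_block <- function(q, symmetry) {
  switch(symmetry,
         palindromic = q[rev(seq_len(nrow(q))), c(4, 3, 2, 1), drop = FALSE],
         direct_repeat = q,
         inverted_repeat = q[rev(seq_len(nrow(q))), , drop = FALSE])
}

SYMMETRY_TYPES <- c("palindromic", "direct_repeat", "inverted_repeat")

#' Select the intrinsic symmetry type of a motif's core blocks
#'
#' Evaluates [block_dissimilarity()] for the three symmetry types and
#' returns the minimizer; if even the minimum exceeds `none_threshold` the
#' motif is classified as having no intrinsic symmetry.  Ties are broken in
#' the fixed order palindromic > direct_repeat > inverted_repeat.
#'
#' @param theta w-by-4 PWM or `mr_motif`.
#' @param block1,block2 core block intervals.
#' @param none_threshold dissimilarity (bits) above which `"none"` is
#'   returned (default 1.0).
#' @return list with `symmetry`, `D_min`, and `D` (named vector over the
#'   three types).
#' @export
select_symmetry <- function(theta, block1, block2, none_threshold = 1.0) {
  D <- vapply(SYMMETRY_TYPES, function(s)
    block_dissimilarity(theta, block1, block2, s), numeric(1))
  k <- which.min(D)   # which.min takes the first minimum: fixed tie order
  sym <- if (D[k] > none_threshold) "none" else SYMMETRY_TYPES[k]
  list(symmetry = sym, D_min = unname(D[k]), D = D)
}

#' Locate the two conserved core blocks of a PWM
#'
#' Exhaustively scores all disjoint ordered equal-length block pairs with
#' block length `c` in `[c_min, c_max]` by
#' `total information content of both blocks - lambda * D_min`, where
#' `D_min` is the minimum [block_dissimilarity()] over the three symmetry
#' types.  Ties prefer smaller `c`, then the leftmost pair.
#'
#' @param theta w-by-4 PWM or `mr_motif`.
#' @param c_min,c_max block length bounds (defaults 3 and `floor(w/2)`).
#' @param lambda weight of the dissimilarity term (default 1.0).
#' @return list with `block1`, `block2`, `score`, `c`.
#' @export
find_blocks <- function(theta, c_min = 3L, c_max = NULL, lambda = 1.0) {
  if (inherits(theta, "mr_motif")) theta <- theta$theta
  w <- nrow(theta)
  if (is.null(c_max)) c_max <- w %/% 2L
  c_max <- min(c_max, w %/% 2L)
  if (w < 2L * c_min) mr_stop("width %d too small for block length %d", w,
                              c_min)
  ic <- 2 + rowSums(theta * log2(theta))
  best <- NULL
  for (cc in seq(c_min, c_max)) {
    for (b1 in 0:(w - 2L * cc)) {
      for (b2 in (b1 + cc):(w - cc)) {
        blk1 <- c(b1, b1 + cc)
        blk2 <- c(b2, b2 + cc)
        icsum <- sum(ic[(b1 + 1L):(b1 + cc)]) + sum(ic[(b2 + 1L):(b2 + cc)])
        dmin <- min(vapply(SYMMETRY_TYPES, function(s)
          block_dissimilarity(theta, blk1, blk2, s), numeric(1)))
        sc <- icsum - lambda * dmin
        if (is.null(best) || sc > best$score + 1e-12) {
          best <- list(block1 = blk1, block2 = blk2, score = sc, c = cc)
        }
      }
    }
  }
  best
}

## ---------------------------------------------------------------------
## SMC machinery

seq_to_codes <- function(s) {
  v <- dna_to_code(s)
  v[is.na(v)] <- 0L      # N -> 0, excluded from placements in C++
  v
}

#' Initialize an SMC particle population
#'
#' Particles start with no placements and zero aligned counts (or, when a
#' prior PWM is supplied, with pseudo-counts `m * prior_theta` per column,
#' i.e. a prior sample size of `m` sites).  Weights are uniform.
#'
#' @param w motif width.
#' @param n_particles population size (>= 100 recommended).
#' @param prior_theta optional w-by-4 prior PWM.
#' @param prior_m prior strength (pseudo-sites) when `prior_theta` given.
#' @param seed integer seed; all randomness in subsequent steps derives
#'   from it.
#' @param alpha per-base Dirichlet pseudocount (default 0.5).
#' @param presence prior probability that a sequence contains a site
#'   (default 0.8).
#' @param lambda_sym weight of the symmetry prior; 0 disables it.
#' @param background genome background probabilities (A,C,G,T).
#' @return object of class `mr_particles`.
#' @export
smc_init <- function(w, n_particles, prior_theta = NULL, prior_m = 10,
                     seed = 1L, alpha = 0.5, presence = 0.8,
                     lambda_sym = 1.0, background = rep(0.25, 4)) {
  w <- as.integer(w)
  n <- as.integer(n_particles)
  counts0 <- numeric(4L * w)
  if (!is.null(prior_theta)) {
    if (inherits(prior_theta, "mr_motif")) prior_theta <- prior_theta$theta
    if (nrow(prior_theta) != w) mr_stop("prior PWM width != w")
    counts0 <- as.numeric(t(prior_theta) * prior_m)  # layout: (j,b) -> j*4+b
  }
  structure(list(
    w = w, n_particles = n,
    counts = matrix(rep(counts0, each = n), nrow = n),
    weights = rep(1 / n, n),
    placements = matrix(integer(0), nrow = n, ncol = 0),
    alpha = alpha, presence = presence, lambda_sym = lambda_sym,
    background = as.numeric(background / sum(background)),
    seed = as.integer(seed), step = 0L,
    log_ml = 0, ess_trace = numeric(0)),
    class = "mr_particles")
}

#' Advance the SMC by one sequence
#'
#' For each particle, all candidate placements — absent, or `(offset,
#' strand)` over both strands — are weighted by presence prior, the
#' Dirichlet-multinomial predictive probability of the aligned window
#' relative to background, and the symmetry prior
#' `exp(-lambda_sym * D_min)` evaluated on the tentatively updated
#' posterior-mean PWM (core blocks = motif halves).  One placement is
#' sampled per particle, weights are multiplied by the candidate
#' normalizer, and systematic resampling is triggered when the effective
#' sample size drops below `resample_frac * n_particles`.
#'
#' @param particles an `mr_particles` state.
#' @param sequence character DNA string (a sequence shorter than `w`
#'   forces an absent placement).
#' @param resample_frac ESS fraction triggering resampling (default 0.5).
#' @return the updated `mr_particles`.
#' @export
smc_step <- function(particles, sequence, resample_frac = 0.5) {
  p <- particles
  codes <- seq_to_codes(sequence)
  res <- smc_step_cpp(p$counts, p$weights, p$placements,
                      as.integer(codes), p$w, p$alpha, p$presence,
                      p$lambda_sym, p$background,
                      derive_seed(p$seed, 7919L * (p$step + 1L)),
                      resample_frac)
  p$counts <- res$counts
  p$weights <- as.numeric(res$weights)
  p$placements <- res$placements
  p$step <- p$step + 1L
  p$log_ml <- p$log_ml + res$log_z
  p$ess_trace <- c(p$ess_trace, res$ess)
  p
}

#' Effective sample size of the particle population
#' @param particles an `mr_particles`.
#' @return `1 / sum(weights^2)`.
#' @export
smc_ess <- function(particles) 1 / sum(particles$weights^2)

# run a full SMC family over an ordered set of sequences
smc_run <- function(sequences, w, n_particles, prior_theta = NULL,
                    prior_m = 10, seed = 1L, alpha = 0.5, presence = 0.8,
                    lambda_sym = 1.0, background = rep(0.25, 4),
                    resample_frac = 0.5) {
  st <- smc_init(w, n_particles, prior_theta, prior_m, seed, alpha,
                 presence, lambda_sym, background)
  for (s in sequences) st <- smc_step(st, s, resample_frac)
  st
}

# posterior-mean PWM of one particle (row p of the counts matrix)
particle_theta <- function(particles, p = which.max(particles$weights)[1]) {
  w <- particles$w
  cm <- matrix(particles$counts[p, ], nrow = w, ncol = 4, byrow = TRUE)
  th <- (cm + particles$alpha) / (rowSums(cm) + 4 * particles$alpha)
  colnames(th) <- BASES
  th
}

# number of non-absent placements of one particle
particle_n_sites <- function(particles,
                             p = which.max(particles$weights)[1]) {
  if (ncol(particles$placements) == 0L) return(0L)
  sum(particles$placements[p, ] >= 0L)
}

decode_placement <- function(code) {
  if (code < 0L) return(NULL)
  list(offset = code %/% 2L, strand = if (code %% 2L == 0L) "+" else "-")
}

#' Score candidate motif widths and select one
#'
#' Runs one independent SMC family per candidate width (seeds derived as
#' `seed + w`).  The per-width score is the log marginal-likelihood
#' estimate (accumulated log normalizing constants) minus a BIC-style
#' penalty `(3w/2) * log(n_sites)` with `n_sites` the non-absent placement
#' count of the maximum-weight particle.  The argmax width is selected,
#' ties preferring the smaller width.
#'
#' @param sequences ordered character vector of upstream sequences.
#' @param w_range candidate widths (subset of 8..30; default 12:24).
#' @param n_particles particles per family.
#' @param seed base seed.
#' @param ... further arguments passed to the SMC
#'   (`alpha`, `presence`, `lambda_sym`, `background`, `prior_theta`,
#'   `prior_m`, `resample_frac`).
#' @return list with `w` (selected), `table` (data.frame of per-width
#'   scores), and `best` (the selected width's `mr_particles` state).
#' @export
estimate_width <- function(sequences, w_range = 12:24, n_particles = 1000L,
                           seed = 1L, ...) {
  if (length(w_range) == 0L) mr_stop("empty width range")
  if (any(w_range < 8L | w_range > 30L))
    mr_stop("w_range must lie within [8, 30]")
  w_range <- sort(unique(as.integer(w_range)))
  rows <- vector("list", length(w_range))
  best <- NULL; best_score <- -Inf; best_w <- NA_integer_
  for (i in seq_along(w_range)) {
    w <- w_range[i]
    st <- smc_run(sequences, w, n_particles,
                  seed = derive_seed(seed, w), ...)
    n_sites <- particle_n_sites(st)
    penalty <- (3 * w / 2) * log(max(1L, n_sites))
    score <- st$log_ml - penalty
    rows[[i]] <- data.frame(w = w, log_ml = st$log_ml, n_sites = n_sites,
                            penalty = penalty, score = score)
    if (score > best_score + 1e-12) {  # strict: ties keep smaller w
      best <- st; best_score <- score; best_w <- w
    }
  }
  list(w = best_w, table = do.call(rbind, rows), best = best)
}

#' Discover a motif in a set of upstream sequences
#'
#' Full two-block SMC motif discovery: width selection by
#' [estimate_width()], then the maximum-weight particle of the selected
#' width provides the site placements; the final PWM is its posterior mean;
#' core blocks come from [find_blocks()] and the symmetry type from
#' [select_symmetry()].  Per-sequence posterior site probabilities are the
#' total particle weight agreeing with the reported placement.
#'
#' @param sequences named, ordered character vector of upstream sequences
#'   (>= 4), most informative first (see [feeding_order()]).
#' @param w_range candidate motif widths (default 12:24).
#' @param n_particles particle population size (default 1000).
#' @param seed integer seed; results are fully reproducible given it.
#' @param alpha Dirichlet pseudocount per base (default 0.5).
#' @param presence prior probability a sequence carries a site (0.8).
#' @param lambda_sym symmetry prior weight (1.0; 0 = symmetry-agnostic).
#' @param background genome background base probabilities.
#' @param prior_theta optional prior PWM (its width fixes `w_range`).
#' @param prior_m prior strength in pseudo-sites (default 10).
#' @param none_threshold symmetry `"none"` threshold in bits.
#' @param resample_frac ESS fraction triggering resampling.
#' @return object of class `mr_discovery`: list with `status`
#'   (`"ok"`/`"no motif found"`), `motif` (an `mr_motif`, NULL on
#'   failure), `sites` (data.frame `seq_id`, `offset`, `strand`,
#'   `posterior`; absent sequences have NA offset), `width_scores`,
#'   `ess_trace`, `symmetry` (full [select_symmetry()] result).
#' @export
discover_motif <- function(sequences, w_range = 12:24, n_particles = 1000L,
                           seed = 1L, alpha = 0.5, presence = 0.8,
                           lambda_sym = 1.0, background = rep(0.25, 4),
                           prior_theta = NULL, prior_m = 10,
                           none_threshold = 1.0, resample_frac = 0.5) {
  if (length(sequences) < 4L)
    mr_stop("need at least 4 sequences for motif discovery (got %d)",
            length(sequences))
  if (is.null(names(sequences)))
    names(sequences) <- sprintf("seq%03d", seq_along(sequences))
  if (!is.null(prior_theta)) {
    if (inherits(prior_theta, "mr_motif")) prior_theta <- prior_theta$theta
    w_range <- nrow(prior_theta)
  }
  ew <- estimate_width(sequences, w_range, n_particles, seed,
                       alpha = alpha, presence = presence,
                       lambda_sym = lambda_sym, background = background,
                       prior_theta = prior_theta, prior_m = prior_m,
                       resample_frac = resample_frac)
  st <- ew$best
  pbest <- which.max(st$weights)[1]
  placements <- st$placements[pbest, ]
  # null model: every sequence without a site.  If the best penalized
  # width score does not beat it, nothing credible was found.
  null_score <- length(sequences) * log(1 - min(presence, 1 - 1e-12))
  best_score <- max(ew$table$score)
  if (all(placements < 0L) || best_score <= null_score) {
    return(structure(list(status = "no motif found", motif = NULL,
                          sites = NULL, width_scores = ew$table,
                          ess_trace = st$ess_trace, symmetry = NULL),
                     class = "mr_discovery"))
  }
  theta <- particle_theta(st, pbest)
  blocks <- find_blocks(theta)
  sym <- select_symmetry(theta, blocks$block1, blocks$block2,
                         none_threshold)
  motif <- motif_model(theta, blocks$block1, blocks$block2, sym$symmetry,
                       alpha = st$alpha)
  sites <- data.frame(seq_id = names(sequences),
                      offset = NA_integer_, strand = NA_character_,
                      posterior = 0, stringsAsFactors = FALSE)
  for (t in seq_along(sequences)) {
    code <- placements[t]
    post <- sum(st$weights[st$placements[, t] == code])
    sites$posterior[t] <- min(max(post, 0), 1)
    if (code >= 0L) {
      pl <- decode_placement(code)
      sites$offset[t] <- pl$offset
      sites$strand[t] <- pl$strand
    }
  }
  structure(list(status = "ok", motif = motif, sites = sites,
                 width_scores = ew$table, ess_trace = st$ess_trace,
                 symmetry = sym),
            class = "mr_discovery")
}

#' @export
print.mr_discovery <- function(x, ...) {
  cat("mr_discovery:", x$status, "\n")
  if (x$status == "ok") {
    cat(sprintf("  width %d, consensus %s, symmetry %s (D=%.3f bits)\n",
                x$motif$width, x$motif$consensus, x$motif$symmetry,
                x$symmetry$D_min))
    cat(sprintf("  %d/%d sequences with a called site\n",
                sum(!is.na(x$sites$offset)), nrow(x$sites)))
  }
  invisible(x)
}

#' Alignment distance between two consensus strings
#'
#' Minimum Hamming mismatches of the shorter string against every offset of
#' the longer, on both strands, plus the width difference.  Used to compare
#' a recovered consensus against a planted one when the selected width may
#' differ by a position or two.
#'
#' @param a,b consensus strings.
#' @return integer distance.
#' @export
consensus_distance <- function(a, b) {
  if (nchar(a) > nchar(b)) { tmp <- a; a <- b; b <- tmp }
  av <- strsplit(a, "")[[1]]
  best <- Inf
  for (cand in c(b, revcomp(b))) {
    bv <- strsplit(cand, "")[[1]]
    for (off in 0:(length(bv) - length(av))) {
      mism <- sum(av != bv[(off + 1):(off + length(av))])
      best <- min(best, mism)
    }
  }
  as.integer(best + (nchar(b) - nchar(a)))
}
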