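# Independent oracles and small shared helpers for the test suite.

set_log_level("warn")

jaccard <- function(a, b) length(intersect(a, b)) / length(union(a, b))

# all 4^w k-mers as an integer matrix (rows = kmers, codes 1..4)
all_kmers <- function(w) {
  as.matrix(expand.grid(rep(list(1:4), w)))
}

# brute-force LLR score p-values: enumerate every k-mer under background
brute_force_pvalues <- function(theta, background, query_scores) {
  w <- nrow(theta)
  km <- all_kmers(w)
  scores <- apply(km, 1, function(k)
    sum(log2(theta[cbind(seq_len(w), k)]) - log2(background[k])))
  probs <- apply(km, 1, function(k) prod(background[k]))
  vapply(query_scores, function(s) sum(probs[scores >= s - 1e-9]),
         numeric(1))
}

brute_force_scores <- function(theta, background) {
  w <- nrow(theta)
  km <- all_kmers(w)
  apply(km, 1, function(k)
    sum(log2(theta[cbind(seq_len(w), k)]) - log2(background[k])))
}

# exact joint posterior over per-sequence placements for the SMC target
# (lambda_sym = 0), by exhaustive enumeration: collapsed Polya (Dirichlet-
# multinomial) likelihood of the aligned windows over background, times
# the placement prior.  Returns a data.frame over the full placement grid.
exact_placement_posterior <- function(seqs, w, alpha, presence,
                                      background) {
  codes <- lapply(seqs, function(s) {
    v <- match(strsplit(toupper(s), "")[[1]], c("A", "C", "G", "T"))
    v[is.na(v)] <- 0L
    v
  })
  K <- nchar(seqs[1]) - w + 1
  window_codes <- function(code, pl) {
    if (pl < 0L) return(NULL)
    o <- pl %/% 2L
    win <- code[(o + 1L):(o + w)]
    if (pl %% 2L == 1L) win <- rev(5L - win)
    win
  }
  prior <- function(pl) if (pl < 0L) 1 - presence else presence / (2 * K)
  joint_weight <- function(pls) {
    kms <- Filter(Negate(is.null),
                  lapply(seq_along(pls), function(i)
                    window_codes(codes[[i]], pls[i])))
    lw <- sum(log(vapply(pls, prior, numeric(1))))
    if (length(kms) > 0) {
      cnt <- matrix(0, w, 4)
      for (km in kms)
        for (j in seq_len(w)) cnt[j, km[j]] <- cnt[j, km[j]] + 1
      lw <- lw + sum(lgamma(alpha + cnt) - lgamma(alpha)) +
        w * (lgamma(4 * alpha) - lgamma(4 * alpha + length(kms)))
      for (km in kms) lw <- lw - sum(log(background[km]))
    }
    lw
  }
  pls <- -1:(2 * K - 1)
  grid <- expand.grid(rep(list(pls), length(seqs)))
  names(grid) <- paste0("z", seq_along(seqs))
  lw <- apply(grid, 1, joint_weight)
  grid$prob <- exp(lw - max(lw))
  grid$prob <- grid$prob / sum(grid$prob)
  grid
}

# re-estimate a PWM from sampled site sequences (frequency + pseudocount)
estimate_pwm_from_sites <- function(sites, w, pseudo = 0.5) {
  cnt <- matrix(pseudo, w, 4)
  for (s in sites) {
    v <- match(strsplit(s, "")[[1]], c("A", "C", "G", "T"))
    for (j in seq_len(w)) cnt[j, v[j]] <- cnt[j, v[j]] + 1
  }
  cnt / rowSums(cnt)
}

# random strictly-positive PWM (not symmetry-structured)
random_theta <- function(w, seed) {
  set.seed(seed)
  th <- matrix(rexp(4 * w) + 0.05, w, 4)
  th / rowSums(th)
}

write_temp_fasta <- function(seqs, dir = tempdir()) {
  path <- tempfile("seqs", fileext = ".fa", tmpdir = dir)
  write_fasta(seqs, path)
  path
}
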