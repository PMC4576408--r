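# LLR scoring, exact score-distribution p-values, genome scanning and
# threshold selection.

test_that("llr_score matches hand arithmetic and strand convention", {
  # theta = background -> every kmer scores 0
  bg <- c(0.3, 0.2, 0.2, 0.3)
  th <- matrix(bg, 6, 4, byrow = TRUE)
  expect_equal(llr_score(th, bg, "ACGTGT"), 0)
  # w=1 hand value
  th1 <- matrix(c(0.7, 0.1, 0.1, 0.1), 1)
  expect_equal(llr_score(th1, rep(0.25, 4), "A"), log2(0.7 / 0.25),
               tolerance = 1e-9)
  expect_equal(round(llr_score(th1, rep(0.25, 4), "A"), 4), 1.4854)
  # N is unscorable
  expect_true(is.na(llr_score(th, bg, "ACGNGT")))
  expect_error(llr_score(th, bg, "ACGT"), "length")
})

test_that("score_distribution matches brute-force enumeration (w=5)", {
  th <- random_theta(5, seed = 31)
  bg <- c(0.35, 0.15, 0.15, 0.35)
  d <- score_distribution(th, bg, eps = 1e-9)
  scores <- brute_force_scores(th, bg)
  expect_lt(max(abs(score_pvalue(d, scores) -
                      brute_force_pvalues(th, bg, scores))), 1e-6)
  expect_equal(sum(d$mass), 1, tolerance = 1e-9)
  # minimum achievable score has p-value exactly 1
  expect_equal(score_pvalue(d, min(scores)), 1)
  # beyond-maximum boundary: mass of the single best word, or zero
  pmax_beyond <- score_pvalue(d, max(scores) + 1)
  expect_true(pmax_beyond == 0 ||
                abs(pmax_beyond -
                      brute_force_pvalues(th, bg, max(scores))) < 1e-9)
  # monotone non-increasing in score
  qs <- sort(scores)
  expect_true(all(diff(score_pvalue(d, qs)) <= 1e-12))
})

test_that("default-eps p-values stay close to brute force", {
  th <- random_theta(6, seed = 7)
  bg <- rep(0.25, 4)
  d <- score_distribution(th, bg)      # default lattice
  scores <- brute_force_scores(th, bg)
  qs <- quantile(scores, c(0.5, 0.9, 0.99), names = FALSE)
  expect_lt(max(abs(score_pvalue(d, qs) -
                      brute_force_pvalues(th, bg, qs))), 5e-3)
})

scan_fixture <- function(identity = 1, seed = 41, width = 14) {
  motif <- make_pwm(width, "palindromic", 0.9, seed = seed)
  make_genome(30, sprintf("g%02d", c(2, 5, 8, 11, 14, 17, 20, 23, 26, 28,
                                     15, 3)),
              motif, identity = identity, seed = seed)
}

test_that("scan recovers all consensus-exact planted sites", {
  fx <- scan_fixture()
  motif <- fx$truth$motif
  # consensus is genuinely significant at p <= 0.001 (DP, spot-checked by
  # Monte Carlo below)
  d <- score_distribution(motif$theta, fx$genome$background)
  cons_score <- llr_score(motif, fx$genome$background, motif$consensus)
  expect_lt(score_pvalue(d, cons_score), 0.001)
  set.seed(1)
  rnd <- replicate(20000, paste0(
    sample(c("A", "C", "G", "T"), motif$width, TRUE), collapse = ""))
  mc <- mean(vapply(rnd, function(k)
    llr_score(motif, fx$genome$background, k), numeric(1)) >= cons_score)
  expect_lt(mc, 0.002)

  sites <- scan_genome(fx$genome, motif, p_threshold = 0.001)
  expect_true(all(fx$truth$sites$start %in% sites$start))
  # palindromic planted sites are reported once, not per strand
  expect_equal(anyDuplicated(sites$start), 0L)
  # site sequences equal the genome slice in reported orientation
  for (i in seq_len(nrow(sites))) {
    slice <- substr(fx$genome$contigs[[sites$contig[i]]],
                    sites$start[i] + 1,
                    sites$start[i] + nchar(sites$sequence[i]))
    expected <- if (sites$strand[i] == "+") slice else
      as.character(Biostrings::reverseComplement(Biostrings::DNAString(slice)))
    expect_equal(sites$sequence[i], expected)
  }
})

test_that("thresholds filter anti-monotonically", {
  fx <- scan_fixture()
  motif <- fx$truth$motif
  s0 <- scan_genome(fx$genome, motif, p_threshold = 0.001)
  s_strict <- scan_genome(fx$genome, motif, p_threshold = 1e-6)
  expect_lte(nrow(s_strict), nrow(s0))
  expect_true(all(s_strict$start %in% s0$start))
  s_hi <- scan_genome(fx$genome, motif, p_threshold = 0.001,
                      s_threshold = attr(s0, "s_threshold") + 5)
  expect_lte(nrow(s_hi), nrow(s0))
  expect_equal(nrow(scan_genome(fx$genome, motif, p_threshold = 0)), 0L)
})

test_that("reverse-complemented genome gives the mirror site list", {
  motif <- make_pwm(12, "none", 0.9, seed = 55)   # asymmetric: no ties
  fx <- make_genome(12, sprintf("g%02d", c(2, 5, 8)), motif,
                    identity = 1, seed = 56)
  fwd <- scan_genome(fx$genome, motif, p_threshold = 0.001)
  L <- nchar(fx$genome$contigs[["chr"]])
  rc <- genome_from_strings(c(
    chr = as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(fx$genome$contigs[["chr"]])))))
  rc$background <- fx$genome$background   # hold the null model fixed
  rev <- scan_genome(rc, motif, p_threshold = 0.001)
  expect_equal(nrow(rev), nrow(fwd))
  expect_setequal(L - fwd$start - motif$width, rev$start)
  m <- match(L - fwd$start - motif$width, rev$start)
  expect_true(all(rev$strand[m] != fwd$strand))
  expect_equal(rev$score[m], fwd$score)
})

test_that("score threshold selection honours reference recovery", {
  motif <- make_pwm(14, "palindromic", 0.9, seed = 61)
  refs <- sample_sites(motif, 40, identity = 0.85, seed = 62)
  thr <- choose_score_threshold(motif, refs, rep(0.25, 4))
  scores <- vapply(refs, function(s) llr_score(motif, rep(0.25, 4), s),
                   numeric(1))
  expect_gte(mean(scores >= thr), 0.9)
  # largest such threshold: one grid notch higher loses the guarantee
  expect_lt(mean(scores >= thr + 1e-6), 0.9)
  # stated default without references: 60% of the maximum score
  contrib <- log2(motif$theta) - log2(0.25)
  expect_equal(choose_score_threshold(motif, background = rep(0.25, 4)),
               0.6 * sum(apply(contrib, 1, max)))
  # unscorable reference sites are dropped with a warning
  refs2 <- c(refs, paste0("N", substr(refs[1], 2, 14)))
  expect_message(thr2 <- choose_score_threshold(motif, refs2, rep(0.25, 4)),
                 "unscorable")
  expect_equal(thr2, thr)
})

test_that("BED output is 0-based half-open with score and p-value", {
  fx <- scan_fixture()
  sites <- scan_genome(fx$genome, fx$truth$motif, p_threshold = 0.001)
  p <- tempfile(fileext = ".bed")
  write_sites_bed(sites, p)
  bed <- read.table(p, sep = "\t")
  expect_equal(bed[[2]], sites$start)
  expect_equal(bed[[3]], sites$start + fx$truth$motif$width)
  expect_true(all(bed[[7]] <= 0.001))
})
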