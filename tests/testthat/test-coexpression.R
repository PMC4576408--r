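# Co-regulated gene set estimation: correlation profiles, biclustering,
# operon-head filtering, feeding order, upstream extraction.

make_toy_expr <- function() {
  x <- c(1, 2, 3, 4, 5)
  rbind(tf = x,
        affine = 2 * x + 1,
        anti = c(5, 4, 3, 2, 1),
        flat = rep(2, 5))
}

test_that("correlation_profile matches hand-computed correlations", {
  expr <- make_toy_expr()
  r <- correlation_profile(expr, "tf", min_obs = 3L)
  expect_equal(unname(r["tf"]), 1)
  expect_equal(unname(r["affine"]), 1)
  expect_equal(unname(r["anti"]), -1)       # hand: perfectly reversed
  expect_true(is.na(r["flat"]))             # zero variance -> flagged
})

test_that("correlations are pairwise over shared observations", {
  expr <- make_toy_expr()
  expr["affine", 2] <- NA
  r <- correlation_profile(expr, "tf", min_obs = 3L)
  expect_equal(unname(r["affine"]), 1)      # affine on remaining 4 points
  # below min_obs -> undefined
  expr["affine", 1:3] <- NA
  r2 <- correlation_profile(expr, "tf", min_obs = 3L)
  expect_true(is.na(r2["affine"]))
  expect_error(correlation_profile(expr, "nope"), "not in matrix")
})

test_that("bicluster recovers a planted affine gene/condition set", {
  ex <- make_expression(400, 200, sprintf("g%03d", 1:12), 120,
                        sigma = 0.2, seed = 21)
  bic <- estimate_bicluster(ex$expr, ex$truth$tf)
  expect_true(all(ex$truth$genes %in% bic$genes))
  expect_gte(jaccard(bic$genes, ex$truth$genes), 0.8)
  expect_gte(jaccard(bic$conditions, ex$truth$conditions), 0.7)
  expect_true(bic$score >= 0 && bic$score <= 1)
  expect_true(ex$truth$tf %in% bic$genes)
})

test_that("bicluster gene set is monotone in r_init", {
  ex <- make_expression(300, 150, sprintf("g%03d", 1:10), 90,
                        sigma = 0.3, seed = 5)
  sets <- lapply(c(0.6, 0.75, 0.9), function(r)
    estimate_bicluster(ex$expr, ex$truth$tf, r_init = r)$genes)
  expect_true(all(sets[[2]] %in% sets[[1]]))
  expect_true(all(sets[[3]] %in% sets[[2]]))
})

test_that("fitness veto removes anti-coherent genes only", {
  ex <- make_expression(300, 150, sprintf("g%03d", 1:10), 90,
                        sigma = 0.2, seed = 8)
  genes <- rownames(ex$expr)
  # g005 coherent in expression but incoherent in fitness
  fit <- make_fitness(genes, 30, coherent = setdiff(ex$truth$genes, "g005"),
                      seed = 8)
  bic0 <- estimate_bicluster(ex$expr, ex$truth$tf)
  bic1 <- estimate_bicluster(ex$expr, ex$truth$tf, fitness = fit$fitness)
  expect_true("g005" %in% bic0$genes)
  expect_false("g005" %in% bic1$genes)
  expect_true("g005" %in% bic1$vetoed)
  expect_true(all(setdiff(ex$truth$genes, "g005") %in% bic1$genes))
})

# three-operon toy genome: runs of co-expressed adjacent same-strand genes
operon_toy <- function(run_corr = 0.95, seed = 2) {
  ann <- annotations(
    sprintf("g%02d", 1:8), "chr",
    start = c(100, 450, 800, 2000, 2350, 4000, 4350, 6000),
    end = c(400, 750, 1100, 2300, 2650, 4300, 4650, 6300),
    strand = c("+", "+", "+", "-", "-", "+", "+", "-"))
  set.seed(seed)
  x <- rnorm(60)
  expr <- matrix(rnorm(8 * 60), 8, 60,
                 dimnames = list(sprintf("g%02d", 1:8),
                                 sprintf("c%02d", 1:60)))
  expr["g01", ] <- x
  noise <- sqrt(1 / run_corr^2 - 1)
  for (g in c("g02", "g03")) expr[g, ] <- x + noise * rnorm(60)
  y <- rnorm(60)
  expr["g04", ] <- y
  expr["g05", ] <- y + noise * rnorm(60)
  z <- rnorm(60)
  expr["g06", ] <- z
  expr["g07", ] <- z + noise * rnorm(60)
  list(ann = ann, expr = expr)
}

test_that("operon-head filter retains exactly the head genes", {
  toy <- operon_toy()
  got <- filter_operon_heads(sprintf("g%02d", 1:8), toy$ann, toy$expr,
                             "g01", r_adj = 0.8)
  # + runs keep 5'-most = lowest start; the - run (g04,g05) keeps g05
  expect_setequal(got, c("g01", "g05", "g06", "g08"))
  # idempotent
  expect_setequal(filter_operon_heads(got, toy$ann, toy$expr, "g01"), got)
  # output always a subset of input
  sub <- filter_operon_heads(c("g02", "g03"), toy$ann, toy$expr, "g01")
  expect_true(all(sub %in% c("g02", "g03")))
})

test_that("uncorrelated or distant adjacent genes are not merged", {
  toy <- operon_toy()
  # break co-expression of g02/g03: both become their own run heads
  toy$expr["g03", ] <- rnorm(60)
  got <- filter_operon_heads(c("g01", "g02", "g03"), toy$ann, toy$expr,
                             "g01", r_adj = 0.8)
  expect_true("g03" %in% got)
  # isolated gene passes through
  expect_equal(filter_operon_heads("g08", toy$ann, toy$expr, "g01"), "g08")
  # gap rule: same toy but with a 1kb gap between g06 and g07
  toy2 <- operon_toy()
  got2 <- filter_operon_heads(c("g06", "g07"), toy2$ann, toy2$expr, "g01",
                              max_gap = 10L)
  expect_setequal(got2, c("g06", "g07"))
  expect_error(filter_operon_heads("gXX", toy$ann, toy$expr, "g01"),
               "unannotated")
})

test_that("feeding order sorts by |correlation| with deterministic ties", {
  set.seed(3)
  x <- rnorm(50)
  expr <- rbind(tf = x,
                strong = 0.99 * x + 0.01 * rnorm(50),
                weak = 0.3 * x + rnorm(50),
                dupA = c(x[1:25], rnorm(25)),
                dupB = c(x[1:25], rnorm(25)))
  expr["dupB", ] <- expr["dupA", ]          # exactly tied correlations
  ord <- feeding_order(c("weak", "dupB", "strong", "dupA"), expr, "tf")
  expect_equal(ord[1], "strong")
  expect_lt(which(ord == "dupA"), which(ord == "dupB"))  # lexicographic
  # tf first when present
  expect_equal(feeding_order(c("weak", "tf"), expr, "tf")[1], "tf")
  # scrambled mode is a seeded, reproducible permutation
  s1 <- feeding_order(rownames(expr), expr, "tf", scramble = TRUE, seed = 4)
  s2 <- feeding_order(rownames(expr), expr, "tf", scramble = TRUE, seed = 4)
  expect_identical(s1, s2)
  expect_setequal(s1, rownames(expr))
})

test_that("upstream extraction follows gene orientation", {
  contig <- "AACTCCGGTGGCACGTAATT"   # 20 bp toy
  g <- genome_from_strings(c(chr = contig))
  ann <- annotations(c("plus", "minus"), "chr", c(8L, 2L), c(12L, 8L),
                     c("+", "-"))
  up <- extract_upstreams(c("plus", "minus"), g, ann, length = 4L)
  expect_equal(unname(up["plus"]), substr(contig, 5, 8))   # "CCGG"
  # minus gene [2,8): upstream = revcomp of [8,12) = revcomp("TGGC")
  expect_equal(unname(up["minus"]), "GCCA")

  # truncation at contig edge, and skipping of empty windows
  ann2 <- annotations(c("short", "atstart"), "chr", c(2L, 0L), c(6L, 4L),
                      c("+", "+"))
  expect_message(up2 <- extract_upstreams("short", g, ann2, length = 10L),
                 "truncated")
  expect_equal(nchar(up2[["short"]]), 2L)
  expect_message(up3 <- extract_upstreams("atstart", g, ann2, length = 10L),
                 "skipped")
  expect_length(up3, 0L)
})

test_that("+ strand gene at 300 gets bases [0,300) as upstream", {
  set.seed(1)
  contig <- paste0(sample(c("A", "C", "G", "T"), 700, TRUE), collapse = "")
  g <- genome_from_strings(c(chr = contig))
  ann <- annotations("gA", "chr", 300L, 600L, "+")
  up <- extract_upstreams("gA", g, ann, length = 300L)
  expect_equal(unname(up["gA"]), substr(contig, 1, 300))
})
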