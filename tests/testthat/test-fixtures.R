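# Synthetic-data generators: determinism, planted structure, truth files.

test_that("make_pwm plants exact symmetry and is seed-deterministic", {
  for (sym in c("palindromic", "direct_repeat", "inverted_repeat")) {
    m <- make_pwm(16, sym, 0.85, seed = 3)
    expect_equal(block_dissimilarity(m, m$block1, m$block2, sym), 0)
    expect_equal(m$symmetry, sym)
  }
  expect_identical(make_pwm(16, "palindromic", 0.85, seed = 3),
                   make_pwm(16, "palindromic", 0.85, seed = 3))
  # conservation 1 gives deterministic consensus columns
  m1 <- make_pwm(12, "direct_repeat", 1, seed = 4)
  core <- c(1:6, 7:12)
  expect_true(all(apply(m1$theta[core, ], 1, max) > 0.99))
  expect_error(make_pwm(10, "palindromic", 0.2), "conservation")
})

test_that("sampled sites follow the identity parameter", {
  m <- make_pwm(14, "palindromic", 0.9, seed = 5)
  exact <- sample_sites(m, 5, identity = 1, seed = 5)
  expect_true(all(exact == m$consensus))
  noisy <- sample_sites(m, 200, identity = 0.8, seed = 5)
  mism <- vapply(noisy, function(s)
    sum(strsplit(s, "")[[1]] != strsplit(m$consensus, "")[[1]]),
    numeric(1))
  expect_equal(mean(mism) / 14, 0.2, tolerance = 0.05)
  expect_identical(noisy, sample_sites(m, 200, identity = 0.8, seed = 5))
})

test_that("make_genome plants sites at the recorded loci", {
  m <- make_pwm(16, "palindromic", 0.9, seed = 11)
  fx <- make_genome(25, sprintf("g%02d", c(3, 7, 12, 18, 22)), m,
                    identity = 1, seed = 11)
  expect_equal(nrow(fx$truth$sites), 5L)
  for (i in seq_len(nrow(fx$truth$sites))) {
    tr <- fx$truth$sites[i, ]
    slice <- substr(fx$genome$contigs[[tr$contig]], tr$start + 1,
                    tr$start + 16)
    expected <- if (tr$strand == "+") tr$sequence else
      as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(tr$sequence)))
    expect_equal(slice, expected)
    expect_equal(tr$sequence, m$consensus)   # identity 1 -> consensus
    # the planted offset is inside the upstream window
    expect_true(tr$offset <= -16 && tr$offset >= -300)
  }
  # scanning with the planted PWM recovers every consensus-exact site
  sites <- scan_genome(fx$genome, m, p_threshold = 0.001)
  expect_true(all(fx$truth$sites$start %in% sites$start))
  expect_identical(fx$genome$contigs,
                   make_genome(25, sprintf("g%02d", c(3, 7, 12, 18, 22)),
                               m, identity = 1, seed = 11)$genome$contigs)
  expect_error(make_genome(25, "g03", m, contig_length = 100L, seed = 1),
               "too small")
})

test_that("operon genes are adjacent and same-strand in the layout", {
  m <- make_pwm(14, "palindromic", 0.9, seed = 2)
  ops <- list(op1 = c("g05", "g06", "g07"))
  fx <- make_genome(10, "g05", m, operons = ops, seed = 2)
  ann <- fx$annotations
  idx <- match(c("g05", "g06", "g07"), ann$gene_id)
  expect_equal(length(unique(ann$strand[idx])), 1L)
  ord <- idx[order(ann$start[idx])]
  gaps <- ann$start[ord][-1] - ann$end[ord][-3]
  expect_true(all(gaps <= 200L))
  # head gene is 5'-most in gene orientation
  strand <- ann$strand[idx[1]]
  head_start <- ann$start[match("g05", ann$gene_id)]
  expect_equal(head_start,
               if (strand == "+") min(ann$start[idx]) else
                 max(ann$start[idx]))
})

test_that("expression generator plants linear coherency", {
  ex0 <- make_expression(50, 80, sprintf("g%02d", 1:6), 50, sigma = 0,
                         seed = 31)
  r <- correlation_profile(ex0$expr[, ex0$truth$conditions], "g01")
  expect_equal(unname(abs(r[ex0$truth$genes])), rep(1, 6),
               tolerance = 1e-12)
  # noise genes stay uncorrelated with the TF over all conditions
  ex1 <- make_expression(1100, 200, c("g0001", "g0002"), 120, seed = 32)
  rn <- correlation_profile(ex1$expr, "g0001")
  noise <- setdiff(rownames(ex1$expr), ex1$truth$genes)
  expect_gte(mean(abs(rn[noise]) < 0.3), 0.99)
  expect_identical(ex1$expr,
                   make_expression(1100, 200, c("g0001", "g0002"), 120,
                                   seed = 32)$expr)
  # operon runs copy the head profile
  ex2 <- make_expression(20, 60, sprintf("g%02d", 1:4), 40,
                         operon_runs = list(g02 = c("g09", "g10")),
                         seed = 33)
  expect_gt(cor(ex2$expr["g02", ], ex2$expr["g09", ]), 0.98)
  expect_error(make_expression(20, 60, c("gx", "g02"), 40, tf = "g02"),
               "universe")
})

test_that("fitness generator plants a coherent subset", {
  genes <- sprintf("g%02d", 1:20)
  fit <- make_fitness(genes, 30, coherent = genes[1:6], sigma = 0.1,
                      seed = 41)
  r <- correlation_profile(fit$fitness, "g01")
  expect_true(all(r[genes[2:6]] >= 0.8))
  expect_true(mean(abs(r[genes[7:20]])) < 0.5)
  # empty coherent subset: all independent
  fit0 <- make_fitness(genes, 30, seed = 41)
  r0 <- correlation_profile(fit0$fitness, "g01")
  expect_true(all(abs(r0[genes[2:20]]) < 0.9))
  expect_identical(fit$fitness,
                   make_fitness(genes, 30, coherent = genes[1:6],
                                sigma = 0.1, seed = 41)$fitness)
})

test_that("the default bundle is small, consistent and written faithfully", {
  b <- make_fixture_bundle(seed = 7)
  expect_equal(length(b$truth$site_genes), 12L)
  expect_equal(length(b$truth$regulon_genes), 20L)
  expect_true(all(b$truth$site_genes %in% b$annotations$gene_id))
  expect_equal(dim(b$expr), c(50L, 200L))
  # planted sites really are in the genome
  for (i in seq_len(nrow(b$truth$sites))) {
    tr <- b$truth$sites[i, ]
    slice <- substr(b$genome$contigs[[tr$contig]], tr$start + 1,
                    tr$start + b$truth$motif$width)
    expected <- if (tr$strand == "+") tr$sequence else
      as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(tr$sequence)))
    expect_equal(slice, expected)
  }
  dir <- tempfile("bundle")
  paths <- write_fixture_bundle(b, dir)
  expect_true(all(file.exists(paths)))
  expect_lt(sum(file.size(paths)), 5e6)
  # the written files round-trip through the package readers
  g <- read_genome(paths["genome"])
  expect_equal(g$contigs, b$genome$contigs)
  ann <- read_annotations(paths["annotations"])
  expect_equal(as.data.frame(ann), as.data.frame(b$annotations))
  expect_equal(read_matrix(paths["expression"]), b$expr,
               tolerance = 1e-6)
  ops <- read_operons(paths["operons"])
  expect_equal(ops$operons[order(names(ops$operons))],
               b$operons$operons[order(names(b$operons$operons))])
  truth <- jsonlite::read_json(paths["truth"])
  expect_equal(truth$consensus, b$truth$consensus)
})
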