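# SMC motif discovery: particle mechanics, width selection, discovery.

test_that("smc_init builds a uniform population with optional prior", {
  st <- smc_init(10, 500, seed = 1)
  expect_equal(st$n_particles, 500L)
  expect_equal(st$weights, rep(1 / 500, 500))
  expect_equal(sum(st$counts), 0)
  expect_equal(ncol(st$placements), 0L)

  prior <- make_pwm(10, "palindromic", 0.8, seed = 2)
  stp <- smc_init(10, 100, prior_theta = prior, prior_m = 10, seed = 1)
  cm <- matrix(stp$counts[1, ], 10, 4, byrow = TRUE)
  expect_equal(rowSums(cm), rep(10, 10))   # prior strength per column
  expect_equal(cm / rowSums(cm), unname(prior$theta), tolerance = 1e-12)
})

test_that("smc_step conserves weights and restores ESS on resampling", {
  set.seed(4)
  seqs <- vapply(1:6, function(i)
    paste0(sample(c("A", "C", "G", "T"), 60, TRUE), collapse = ""),
    character(1))
  st <- smc_init(8, 200, seed = 3)
  for (s in seqs) {
    st <- smc_step(st, s)
    expect_equal(sum(st$weights), 1, tolerance = 1e-12)
  }
  expect_equal(ncol(st$placements), 6L)
  # force a resampling event and check ESS resets to n
  st2 <- smc_init(8, 200, seed = 3, presence = 0.99)
  motif <- make_pwm(8, "direct_repeat", 0.95, seed = 9)
  planted <- vapply(1:8, function(i) {
    bg <- paste0(sample(c("A", "C", "G", "T"), 60, TRUE), collapse = "")
    paste0(substr(bg, 1, 20), motif$consensus, substr(bg, 29, 60))
  }, character(1))
  resampled_once <- FALSE
  for (s in planted) {
    before <- st2
    st2 <- smc_step(st2, s)
    if (smc_ess(st2) == st2$n_particles &&
        ncol(st2$placements) > 0) resampled_once <- TRUE
  }
  expect_true(resampled_once)
  expect_equal(sum(st2$weights), 1, tolerance = 1e-12)
})

test_that("sequences shorter than w force an absent placement", {
  st <- smc_init(10, 50, seed = 2)
  st <- smc_step(st, "ACGTA")
  expect_true(all(st$placements[, 1] == -1L))
})

test_that("identical seeds give identical SMC runs", {
  set.seed(11)
  seqs <- vapply(1:5, function(i)
    paste0(sample(c("A", "C", "G", "T"), 80, TRUE), collapse = ""),
    character(1))
  a <- motifregulon:::smc_run(seqs, 10, 200, seed = 42)
  b <- motifregulon:::smc_run(seqs, 10, 200, seed = 42)
  expect_identical(a$placements, b$placements)
  expect_identical(a$weights, b$weights)
  expect_identical(a$log_ml, b$log_ml)
  c <- motifregulon:::smc_run(seqs, 10, 200, seed = 43)
  expect_false(identical(a$placements, c$placements))
})

test_that("zero presence prior yields no motif", {
  m <- make_pwm(12, "palindromic", 0.9, seed = 5)
  fix <- make_planted_sequences(m, 8, len = 100, identity = 1,
                                presence = 1, seed = 5)
  d <- discover_motif(fix$sequences, w_range = 12L, n_particles = 200,
                      seed = 1, presence = 0)
  expect_equal(d$status, "no motif found")
  expect_null(d$motif)
})

test_that("the SMC placement posterior matches exhaustive enumeration", {
  # scaled-down version of the oracle check (full scale in acceptance)
  seqs <- c("ACGTACGTACGT", "TTGACGTACGCA")
  bg <- c(0.3, 0.2, 0.2, 0.3)
  exact <- exact_placement_posterior(seqs, 8, 0.5, 0.8, bg)
  st <- motifregulon:::smc_run(seqs, 8, 10000, seed = 11, alpha = 0.5,
                               presence = 0.8, lambda_sym = 0,
                               background = bg)
  emp <- numeric(nrow(exact))
  key <- match(paste(st$placements[, 1], st$placements[, 2]),
               paste(exact$z1, exact$z2))
  for (i in seq_along(key)) emp[key[i]] <- emp[key[i]] + st$weights[i]
  expect_lt(0.5 * sum(abs(emp - exact$prob)), 0.1)
})

test_that("width selection brackets the planted width", {
  m <- make_pwm(16, "palindromic", 0.9, seed = 6)
  fix <- make_planted_sequences(m, 12, len = 200, identity = 0.9,
                                presence = 1, seed = 6)
  ew <- estimate_width(fix$sequences, w_range = 14:18, n_particles = 400,
                       seed = 6)
  expect_equal(nrow(ew$table), 5L)
  expect_true(ew$w %in% 15:17)
  # single-width range is forced
  ew1 <- estimate_width(fix$sequences, w_range = 16L, n_particles = 100,
                        seed = 1)
  expect_equal(ew1$w, 16L)
  expect_error(estimate_width(fix$sequences, integer(0)), "empty")
  expect_error(estimate_width(fix$sequences, 4:6), "within")
})

test_that("discovery recovers a planted motif and its placements", {
  m <- make_pwm(16, "palindromic", 0.85, seed = 13)
  fix <- make_planted_sequences(m, 15, len = 250, identity = 0.9,
                                presence = 1, seed = 13)
  d <- discover_motif(fix$sequences, w_range = 15:17, n_particles = 500,
                      seed = 13)
  expect_equal(d$status, "ok")
  expect_lte(consensus_distance(d$motif$consensus, m$consensus), 2L)
  expect_equal(d$motif$symmetry, "palindromic")
  hit <- !is.na(d$sites$offset) &
    abs(d$sites$offset - fix$truth$offset) <= 4
  expect_gte(sum(hit, na.rm = TRUE) / sum(fix$truth$present), 0.8)
  expect_true(all(d$sites$posterior >= 0 & d$sites$posterior <= 1))
  expect_error(discover_motif(fix$sequences[1:3]), "at least 4")
})

test_that("uniform background sequences yield no credible motif", {
  set.seed(9)
  seqs <- vapply(1:10, function(i)
    paste0(sample(c("A", "C", "G", "T"), 200, TRUE), collapse = ""),
    character(1))
  d <- discover_motif(seqs, w_range = c(12L, 16L), n_particles = 300,
                      seed = 9)
  expect_true(d$status == "no motif found" ||
                pwm_information(d$motif$theta) < 4)
})

test_that("a matched prior PWM does not hurt site recall", {
  m <- make_pwm(14, "palindromic", 0.8, seed = 17)
  fix <- make_planted_sequences(m, 12, len = 200, identity = 0.8,
                                presence = 0.9, seed = 17)
  recall <- function(d) {
    hit <- !is.na(d$sites$offset) &
      abs(d$sites$offset - fix$truth$offset) <= 4
    sum(hit, na.rm = TRUE) / sum(fix$truth$present)
  }
  d0 <- discover_motif(fix$sequences, w_range = 14L, n_particles = 400,
                       seed = 17)
  d1 <- discover_motif(fix$sequences, n_particles = 400, seed = 17,
                       prior_theta = m, prior_m = 20)
  expect_gte(recall(d1), recall(d0))
})
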