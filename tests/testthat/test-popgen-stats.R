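test_that("pairwise differences: identity, self-heterozygosity, hand-walk", {
  # identical fully homozygous genomes -> 0 differences
  d <- cbind(a = c(0L, 2L, 2L, 0L), b = c(0L, 2L, 2L, 0L))
  g <- toy_geno(d, frag_len = 10000)
  expect_equal(pairwise_diff_per_kbp(g, "a", "b", seed = 1)$diff_per_kbp, 0)

  # self-comparison counts heterozygous genotypes per callable kbp
  d2 <- cbind(a = rep(1L, 100), b = rep(0L, 100))
  g2 <- genotype_matrix(data.frame(frag = 1L, pos = seq_len(100) * 500L),
                        d2, frag_lengths = 100000)
  expect_equal(pairwise_diff_per_kbp(g2, "a", "a")$diff_per_kbp, 1.0)

  # 10-site toy against the documented allele-sampling stream
  set.seed(77)
  d3 <- cbind(a = sample(0:2, 10, TRUE), b = sample(0:2, 10, TRUE))
  g3 <- toy_geno(d3, frag_len = 50000)
  seed <- 3
  alle <- matrix(0L, 10, 2)
  for (j in 1:2) {
    col <- d3[, j]
    a <- as.integer(col == 2)
    het <- which(col == 1)
    if (length(het)) {
      set.seed(seed + j)
      a[het] <- as.integer(runif(length(het)) < 0.5)
    }
    alle[, j] <- a
  }
  expected <- sum(alle[, 1] != alle[, 2]) / 50
  expect_equal(pairwise_diff_per_kbp(g3, "a", "b", seed = seed)$diff_per_kbp,
               expected)
  expect_error(pairwise_diff_per_kbp(
    genotype_matrix(data.frame(frag = integer(0), pos = integer(0)),
                    matrix(integer(0), 0, 1, dimnames = list(NULL, "a")),
                    frag_lengths = 1000,
                    mask = data.frame(frag = 1L, start = 0, end = 0)),
    "a", "a"), "callable")
})

test_that("ROH caller finds maximal depleted runs and applies both rules", {
  mask2 <- data.frame(frag = 1L, start = 0, end = 2e6)
  none <- data.frame(frag = integer(0), pos = integer(0))
  r <- call_roh(none, mask2)
  expect_identical(nrow(r), 1L)
  expect_equal(r$tier, 1.5e6)
  expect_equal(r$length, 2e6)

  # 60%-callable candidate is rejected by the 67% rule
  mask60 <- data.frame(frag = 1L, start = c(0, 7e5), end = c(3e5, 1e6))
  expect_identical(nrow(call_roh(none, mask60)), 0L)

  # one heterozygous site splits the run (strict 10% threshold)
  het1 <- data.frame(frag = 1L, pos = 1000500L)
  r2 <- call_roh(het1, mask2)
  expect_identical(nrow(r2), 2L)
  expect_true(all(r2$tier == 0.5e6))

  # mask-representation invariance: splitting intervals changes nothing
  mask_split <- data.frame(frag = 1L, start = c(0, 5e5, 11e5),
                           end = c(5e5, 11e5, 2e6))
  expect_equal(call_roh(het1, mask_split), r2)

  # unsorted het positions are rejected
  expect_error(call_roh(data.frame(frag = 1L, pos = c(200L, 100L)), mask2),
               "sorted")
})

test_that("D-statistic matches the hand tally and longhand jackknife", {
  patterns <- rbind(
    c(0, 1, 1), c(0, 1, 1), c(0, 1, 1), c(1, 0, 1),    # block 1: 3 ABBA 1 BABA
    c(0, 1, 1), c(1, 0, 1), c(1, 0, 1), c(0, 0, 1),    # block 2: 1 ABBA 2 BABA
    c(0, 1, 1), c(0, 1, 1), c(1, 1, 1), c(0, 0, 1))    # block 3: 2 ABBA 0 BABA
  g <- quartet_geno(patterns, frag = rep(1:3, each = 4))
  d <- d_statistic(g, "W", "X", "Y", "Chimp", block_size = 1000)
  expect_identical(d$abba, 6L)
  expect_identical(d$baba, 3L)
  expect_equal(d$D, 1 / 3)
  expect_equal(d$se, 0.3518658, tolerance = 1e-6)
  expect_equal(d$Z, 0.9473309, tolerance = 1e-6)
  expect_identical(d$n_blocks, 3L)
})

test_that("D-statistic limits and antisymmetry", {
  # equal ABBA and BABA -> D = 0
  pat <- rbind(c(0, 1, 1), c(1, 0, 1), c(0, 1, 1), c(1, 0, 1),
               c(0, 1, 1), c(1, 0, 1))
  g <- quartet_geno(pat, frag = rep(1:3, each = 2))
  expect_equal(d_statistic(g, "W", "X", "Y", block_size = 1000)$D, 0)

  # all ABBA -> D = 1
  g1 <- quartet_geno(rbind(c(0, 1, 1), c(0, 1, 1), c(0, 1, 1), c(0, 1, 1)),
                     frag = c(1, 1, 2, 2))
  expect_equal(d_statistic(g1, "W", "X", "Y", block_size = 1000)$D, 1)

  # swapping W and X flips the sign under the same keyed allele sampling
  set.seed(12)
  dh <- matrix(sample(0:2, 90, TRUE), 30, 3,
               dimnames = list(NULL, c("W", "X", "Y")))
  gh <- toy_geno(dh, frag = rep(1:3, each = 10))
  a <- d_statistic(gh, "W", "X", "Y", block_size = 1000, seed = 4)
  b <- d_statistic(gh, "X", "W", "Y", block_size = 1000, seed = 4)
  expect_equal(a$D, -b$D)
  expect_equal(a$se, b$se)
  expect_true(abs(a$D) <= 1)
  expect_equal(sign(a$Z), sign(a$D))

  # zero informative sites errors
  g0 <- quartet_geno(rbind(c(1, 1, 1), c(0, 0, 1)), frag = c(1, 2))
  expect_error(d_statistic(g0, "W", "X", "Y", block_size = 1000),
               "zero informative")
})

test_that("f4-ratio degenerate forms: reference substitution and duplicates", {
  set.seed(20)
  p <- make_admixed_panel(0.4, fragment_set(300, 10000))
  # X replaced by the denominator reference -> ratio exactly 1
  r1 <- f4_ratio(p$geno, c("Src_1", "Sister", "Src_2", "Ref"),
                 c("Src_1", "Sister", "Src_2", "Ref"), block_size = 5e5)
  expect_equal(r1$ratio, 1)
  # duplicated population in the numerator -> f4 = 0 -> ratio 0
  r0 <- f4_ratio(p$geno, c("Src_1", "Sister", "Ref", "Ref"),
                 c("Src_1", "Sister", "Src_2", "Ref"), block_size = 5e5)
  expect_equal(r0$ratio, 0)
  # zero denominator errors with the quartet named
  expect_error(f4_ratio(p$geno, c("Src_1", "Sister", "Target", "Ref"),
                        c("Src_1", "Sister", "Ref", "Ref")),
               "denominator")
})

test_that("f4-ratio recovers a planted admixture proportion of 0.3", {
  set.seed(30)
  fr <- fragment_set(2000, 20000)
  est <- vapply(seq_len(20), function(r) {
    p <- make_admixed_panel(0.3, fr)
    f4_ratio(p$geno, c("Src_1", "Sister", "Target", "Ref"),
             c("Src_1", "Sister", "Src_2", "Ref"))$ratio
  }, numeric(1))
  expect_gt(mean(est), 0.25)
  expect_lt(mean(est), 0.35)
})

test_that("weighted block jackknife reduces to the unweighted formula for
           equal blocks", {
  theta <- 0.5
  tm <- c(0.4, 0.55, 0.6, 0.45)
  m <- rep(10, 4)
  jk <- ghostabc:::weighted_block_jackknife(theta, tm, m)
  g <- 4
  ps <- g * theta - (g - 1) * tm  # pseudovalues
  expect_equal(jk$est, mean(ps))
  expect_equal(jk$se, sqrt(var(ps) / g))
})
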