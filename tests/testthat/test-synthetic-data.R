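test_that("planted ROH segments are recovered within one window", {
  fix <- make_roh_genome(length_bp = 10e6,
                         planted = data.frame(start = 4e6, end = 6e6),
                         background_rate = 1, seed = 101)
  r <- call_roh(fix$het, fix$mask)
  big <- r[r$tier == 1.5e6, ]
  expect_identical(nrow(big), 1L)
  expect_lt(abs(big$start - 4e6), 2000)
  expect_lt(abs(big$end - 6e6), 2000)
})

test_that("background heterozygosity alone produces no long ROH", {
  # with 1 het/kbp, a run of >= 500 empty consecutive kbp windows has
  # probability ~ exp(-1)^500 per start; none are expected in 10 Mbp
  hits <- vapply(1:20, function(s) {
    fix <- make_roh_genome(length_bp = 10e6, background_rate = 1, seed = s)
    nrow(call_roh(fix$het, fix$mask))
  }, numeric(1))
  expect_true(mean(hits == 0) >= 0.95)
})

test_that("ROH fixtures honour masks, overlap checks and determinism", {
  expect_error(make_roh_genome(planted = data.frame(start = c(0, 5e5),
                                                    end = c(6e5, 9e5))),
               "overlap")
  # an empty mask (gap covering everything) yields no hets and no calls
  fix <- make_roh_genome(length_bp = 1e6,
                         gaps = data.frame(start = 0, end = 1e6), seed = 1)
  expect_identical(nrow(fix$het), 0L)
  expect_identical(nrow(call_roh(fix$het, fix$mask)), 0L)
  f1 <- make_roh_genome(length_bp = 2e6, seed = 7)
  f2 <- make_roh_genome(length_bp = 2e6, seed = 7)
  expect_identical(f1$het, f2$het)
})

test_that("roh fixture writes consistent VCF, BED and manifest", {
  dir <- tempfile()
  fix <- make_roh_genome(length_bp = 1e6,
                         planted = data.frame(start = 2e5, end = 5e5),
                         gaps = data.frame(start = 8e5, end = 9e5),
                         seed = 5, dir = dir)
  expect_true(all(file.exists(fix$paths)))
  gm <- read_vcf(fix$paths["vcf"], frag_lengths = 1e6)
  expect_equal(gm$sites$pos, fix$het$pos)
  mask <- read_bed_mask(fix$paths["bed"])
  expect_equal(attr(mask, "callable_length"), 9e5)
})

test_that("a panel with no admixture gives a null D-statistic", {
  set.seed(55)
  fr <- fragment_set(400, 20000)
  z <- vapply(1:50, function(r) {
    p <- make_admixed_panel(0, fr)
    d_statistic(p$geno, "Ref", "Target", "Src_1", "Chimp",
                block_size = 1e6)$Z
  }, numeric(1))
  expect_gte(mean(abs(z) < 3), 0.9)
})

test_that("admixed panels are reproducible and carry their truth", {
  fr <- fragment_set(30, 10000)
  p1 <- make_admixed_panel(0.2, fr, seed = 9)
  p2 <- make_admixed_panel(0.2, fr, seed = 9)
  expect_identical(p1$geno$geno, p2$geno$geno)
  expect_equal(p1$manifest$alpha, 0.2)
})

test_that("jSFS banks are balanced, disjoint and model-separable", {
  fr <- fragment_set(30, 10000)
  set.seed(3)
  noise <- noise_panel_jsfs(fr, seed = 4)
  bank <- make_jsfs_bank(models = c("A", "B"), n_train = 10, n_ref = 10,
                         n_pseudo = 5, fragments = fr, noise = noise,
                         seed = 11)
  expect_identical(nrow(bank$train$X), 20L)
  expect_equal(as.vector(table(bank$train$labels)), c(10, 10))
  expect_identical(nrow(bank$reference$X), 20L)
  expect_identical(dim(bank$pseudo$A), c(5L, ncol(bank$train$X)))
  # partitions are disjoint by provenance id
  expect_identical(anyDuplicated(bank$provenance$id), 0L)
  expect_setequal(unique(bank$provenance$partition),
                  c("train", "reference", "pseudo"))
  # rows are normalized spectra
  expect_true(all(abs(rowSums(bank$train$X) - 1) < 1e-9))
})

test_that("model B at maximal ghost pulses separates from model A in
           expectation", {
  fr <- desk_fragments()
  n <- 360
  pA <- prior_midpoint("A")
  pB <- prior_midpoint("B")
  shared <- intersect(names(pA), names(pB))
  pB[shared] <- pA[shared]
  pB[c("IntrogressionXf_Kho", "IntrogressionXf_Mbuti",
       "IntrogressionXf_WestAfrica")] <- 0.1  # prior maximum
  mean_jsfs <- function(model_id, params, seed0) {
    X <- vapply(seq_len(n), function(i) {
      g <- simulate_fragments(build_model(model_id, params), fr,
                              seed = seed0 + i)
      flatten_jsfs(normalize_jsfs(compute_jsfs(g)))
    }, numeric(3^7))
    rowMeans(X)
  }
  mA1 <- mean_jsfs("A", pA, 1000)
  mA2 <- mean_jsfs("A", pA, 2000)
  mB <- mean_jsfs("B", pB, 3000)
  noise_floor <- sum(abs(mA1 - mA2))
  expect_gt(sum(abs(mB - (mA1 + mA2) / 2)), 3 * noise_floor)
  # nesting: model B with its ghost pulses at zero collapses onto model A
  pB0 <- pB
  pB0[c("IntrogressionXf_Kho", "IntrogressionXf_Mbuti",
        "IntrogressionXf_WestAfrica")] <- 0
  mB0 <- mean_jsfs("B", pB0, 4000)
  expect_lt(sum(abs(mB0 - (mA1 + mA2) / 2)), 1.5 * noise_floor)
})
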