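test_that("jSFS equals a brute-force per-site tally on a toy table", {
  d <- rbind(c(0, 1, 2), c(1, 1, 0), c(2, 2, 2), c(0, 0, 1), c(1, 0, 0))
  colnames(d) <- c("a", "b", "c")
  g <- toy_geno(d)
  j <- compute_jsfs(g, axis_order = c("a", "b", "c"))
  # independent oracle: loop over sites, increment one cell each
  oracle <- array(0, dim = c(3, 3, 3))
  skipped <- 0
  for (i in seq_len(nrow(d))) {
    if (all(d[i, ] == 0) || all(d[i, ] == 2)) { skipped <- skipped + 1; next }
    idx <- d[i, ] + 1
    oracle[idx[1], idx[2], idx[3]] <- oracle[idx[1], idx[2], idx[3]] + 1
  }
  expect_equal(j$counts, oracle)
  expect_identical(j$n_sites, 4)          # all-derived corner excluded
  expect_identical(j$n_skipped, 1L)
  expect_equal(sum(j$counts), j$n_sites)  # conservation
})

test_that("empty input gives an all-zero spectrum", {
  g <- toy_geno(matrix(integer(0), 0, 2, dimnames = list(NULL, c("a", "b"))))
  j <- compute_jsfs(g, axis_order = c("a", "b"))
  expect_true(all(j$counts == 0))
  expect_identical(j$n_sites, 0)
  expect_error(normalize_jsfs(j), "empty")
})

test_that("axis permutation permutes the tensor identically", {
  set.seed(2)
  d <- matrix(sample(0:2, 60, replace = TRUE), 20, 3,
              dimnames = list(NULL, c("a", "b", "c")))
  g <- toy_geno(d)
  j1 <- compute_jsfs(g, axis_order = c("a", "b", "c"))
  j2 <- compute_jsfs(g, axis_order = c("c", "a", "b"))
  expect_equal(aperm(j1$counts, c(3, 1, 2)), j2$counts)
})

test_that("tallying halves separately and summing equals one tally", {
  set.seed(3)
  d <- matrix(sample(0:2, 120, replace = TRUE), 40, 3,
              dimnames = list(NULL, c("a", "b", "c")))
  g_all <- toy_geno(d)
  g1 <- toy_geno(d[1:20, ]); g2 <- toy_geno(d[21:40, ])
  expect_equal(compute_jsfs(g_all, c("a", "b", "c"))$counts,
               compute_jsfs(g1, c("a", "b", "c"))$counts +
                 compute_jsfs(g2, c("a", "b", "c"))$counts)
})

test_that("normalization sums to one and is idempotent", {
  set.seed(4)
  d <- matrix(sample(0:2, 90, replace = TRUE), 30, 3,
              dimnames = list(NULL, c("a", "b", "c")))
  j <- compute_jsfs(toy_geno(d), c("a", "b", "c"))
  n1 <- normalize_jsfs(j)
  expect_equal(sum(n1$counts), 1, tolerance = 1e-12)
  expect_equal(normalize_jsfs(n1), n1)
})

test_that("noise injection draws from the documented mixture", {
  # two-cell arithmetic oracle: 0.7*(0.8,0.2) + 0.3*(0.2,0.8) = (0.62,0.38)
  set.seed(5)
  n <- 1e6
  counts <- ghostabc:::mix_resample(c(0.8, 0.2), c(0.2, 0.8), 0.3, n)
  expect_equal(sum(counts), n)  # mass conserved exactly
  se <- sqrt(0.62 * 0.38 / n)
  expect_lt(abs(counts[1] / n - 0.62), 3 * se)

  # lambda limits on full spectra
  set.seed(6)
  d1 <- matrix(sample(0:2, 3000, replace = TRUE, prob = c(3, 2, 1)), 1000, 3,
               dimnames = list(NULL, c("a", "b", "c")))
  d2 <- matrix(sample(0:2, 3000, replace = TRUE, prob = c(1, 2, 3)), 1000, 3,
               dimnames = list(NULL, c("a", "b", "c")))
  js <- compute_jsfs(toy_geno(d1), c("a", "b", "c"))
  jn <- compute_jsfs(toy_geno(d2), c("a", "b", "c"))
  out0 <- inject_noise(js, jn, lambda = 0, n_resample = 2e5, seed = 1)
  p_sim <- js$counts / sum(js$counts)
  expect_lt(max(abs(out0$counts / 2e5 - p_sim)), 0.01)
  out1 <- inject_noise(js, jn, lambda = 1, n_resample = 2e5, seed = 1)
  p_noise <- jn$counts / sum(jn$counts)
  expect_lt(max(abs(out1$counts / 2e5 - p_noise)), 0.01)
  expect_equal(out1$n_sites, 2e5)
  # seeded reproducibility and axis checks
  expect_equal(inject_noise(js, jn, 0.4, 1000, seed = 9),
               inject_noise(js, jn, 0.4, 1000, seed = 9))
  jn_bad <- jn; jn_bad$axes <- c("x", "y", "z")
  expect_error(inject_noise(js, jn_bad), "axis mismatch")
})

test_that("jSFS TSV round-trips counts and axis order", {
  set.seed(7)
  d <- matrix(sample(0:2, 90, replace = TRUE), 30, 3,
              dimnames = list(NULL, c("a", "b", "c")))
  j <- compute_jsfs(toy_geno(d), c("a", "b", "c"))
  path <- tempfile(fileext = ".tsv")
  write_jsfs_tsv(j, path)
  j2 <- read_jsfs_tsv(path)
  expect_equal(j2$counts, j$counts)
  expect_identical(j2$axes, j$axes)
})
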