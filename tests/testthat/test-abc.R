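test_that("rejection matches a brute-force distance sort on a toy table", {
  ref <- rbind(c(0, 0), c(1, 0), c(0, 2), c(3, 3), c(0.5, 0.5))
  obs <- c(0, 0)
  d_oracle <- sqrt(rowSums(sweep(ref, 2, obs)^2))  # 0, 1, 2, 4.243, 0.707
  vals <- letters[1:5]
  # nearest-neighbour limit
  r1 <- abc_reject(obs, ref, vals, q = 1e-9)
  expect_identical(r1$accepted, "a")
  # three nearest
  r3 <- abc_reject(obs, ref, vals, q = 3 / 5)
  expect_setequal(r3$accepted, vals[order(d_oracle)][1:3])
  # epsilon mode with no acceptance suggests quantile mode
  expect_error(abc_reject(c(100, 100), ref, vals, epsilon = 1e-6),
               "quantile")
  # epsilon = Inf accepts everything: posterior equals the prior proportions
  rall <- abc_reject(obs, ref, c("A", "A", "B", "B", "B"), epsilon = Inf)
  post <- model_posterior(rall$accepted, models = c("A", "B"))
  expect_equal(unname(post), c(2 / 5, 3 / 5))
})

test_that("boundary ties are all included", {
  ref <- matrix(c(0, 1, 1, 1, 5), ncol = 1)
  r <- abc_reject(0, ref, 1:5, q = 2 / 5)  # threshold lands on a triple tie
  expect_identical(sort(r$accepted), c(1L, 2L, 3L, 4L))
})

test_that("with epsilon = Inf the parameter posterior recovers the prior", {
  set.seed(1)
  prior_draws <- runif(4000, 2, 7)
  ss <- matrix(rnorm(4000), ncol = 1)
  acc <- abc_reject(0, ss, prior_draws, epsilon = Inf)
  expect_identical(length(acc$accepted), 4000L)
  expect_gt(stats::ks.test((acc$accepted - 2) / 5, "punif")$p.value, 0.01)
})

test_that("shrinking the acceptance quantile shrinks the mean distance", {
  set.seed(2)
  ref <- matrix(rnorm(2000 * 3), ncol = 3)
  obs <- c(0, 0, 0)
  mean_d <- vapply(c(0.5, 0.1, 0.02, 0.005), function(q) {
    mean(abc_reject(obs, ref, seq_len(2000), q = q)$distances)
  }, numeric(1))
  expect_true(all(diff(mean_d) < 0))
})

test_that("model posterior is the accepted fraction per model", {
  expect_equal(unname(model_posterior(rep(ghost_model_ids(), 5))),
               rep(1 / 6, 6))
  expect_equal(unname(model_posterior(rep("B", 10)))[2], 1)
  acc <- rep(c("A", "B", "C"), c(17, 2, 1))
  expect_equal(unname(model_posterior(acc)),
               c(0.85, 0.10, 0.05, 0, 0, 0))
  expect_equal(sum(model_posterior(acc)), 1)
})

test_that("parameter posterior summary matches order-statistics oracle", {
  p <- parameter_posterior(c(5, 5, 5))
  expect_equal(p$mean, 5)
  expect_equal(c(p$q2.5, p$q97.5), c(5, 5))

  x <- as.numeric(1:1000)
  p2 <- parameter_posterior(x)
  expect_equal(p2$mean, 500.5)
  # independent sort-and-interpolate computation (type-7 order statistics)
  manual_q <- function(p) {
    h <- (length(x) - 1) * p + 1
    lo <- floor(h)
    sort(x)[lo] + (h - lo) * (sort(x)[lo + 1] - sort(x)[lo])
  }
  expect_equal(p2$q2.5, manual_q(0.025))
  expect_equal(p2$q97.5, manual_q(0.975))
  expect_identical(names(p2), c("parameter", "mean", "q2.5", "q97.5",
                                "n_accepted"))
  expect_true(p2$q2.5 <= p2$mean && p2$mean <= p2$q97.5)
  expect_warning(parameter_posterior(42), "degenerate")
})

test_that("posterior mean lies inside the hull of accepted values", {
  set.seed(3)
  ref <- matrix(rnorm(500), ncol = 1)
  vals <- rgamma(500, 2)
  acc <- abc_reject(0.2, ref, vals, q = 0.05)
  p <- parameter_posterior(acc$accepted)
  expect_gte(p$mean, min(acc$accepted))
  expect_lte(p$mean, max(acc$accepted))
})

test_that("Bayes factors: symmetry, reciprocity and the published contrast", {
  post <- setNames(c(0.002, 0.85, 0.01, 0.078, 0.03, 0.03), ghost_model_ids())
  bf <- bayes_factor(post / sum(post))
  expect_equal(bf["B", "D"], 0.85 / 0.078, tolerance = 1e-9)
  expect_equal(unname(bf["B", "D"]), 10.897, tolerance = 1e-3)
  expect_true(all(abs(bf * t(bf) - 1) < 1e-9))
  equal <- bayes_factor(setNames(rep(1 / 6, 6), ghost_model_ids()))
  expect_true(all(abs(equal - 1) < 1e-12))
  zero <- bayes_factor(c(Am = 1, Bm = 0))
  expect_true(is.infinite(zero["Am", "Bm"]))
  expect_true(nrow(attr(zero, "infinite")) >= 1)
})
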