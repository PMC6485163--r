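test_that("classifier separates linearly separable synthetic classes", {
  set.seed(1)
  n <- 600; d <- 50
  mu <- matrix(rnorm(2 * d, sd = 1), 2, d)
  X <- mu[rep(1:2, each = n / 2), ] + matrix(rnorm(n * d, sd = 0.3), n, d)
  labs <- rep(c("A", "B"), each = n / 2)
  idx <- sample(n, 500)
  ens <- train_classifier(X[idx, ], labs[idx], n_networks = 3, seed = 2)
  p <- predict_ss(ens, X[-idx, ])
  acc <- mean(colnames(p)[apply(p, 1, which.max)] == labs[-idx])
  expect_gte(acc, 0.95)
})

test_that("classifier is at chance on randomly permuted labels", {
  set.seed(3)
  n <- 600; d <- 100
  X <- matrix(rnorm(n * d), n, d)
  labs <- sample(rep(LETTERS[1:6], each = n / 6))  # labels carry no signal
  idx <- seq_len(480)
  ens <- train_classifier(X[idx, ], labs[idx], n_networks = 3, seed = 4)
  p <- predict_ss(ens, X[-idx, ])
  acc <- mean(colnames(p)[apply(p, 1, which.max)] == labs[-idx])
  n_held <- n - length(idx)
  se <- sqrt((1 / 6) * (5 / 6) / n_held)
  expect_lt(abs(acc - 1 / 6), 3 * se)
})

test_that("ensemble prediction is the arithmetic mean of member outputs", {
  set.seed(5)
  X <- matrix(rnorm(200 * 20), 200, 20)
  labs <- rep(c("A", "B", "C", "D"), each = 50)
  ens <- train_classifier(X, labs, n_networks = 4, seed = 6,
                          arch = list(max_epochs = 5L))
  p_ens <- predict_ss(ens, X[1:10, ])
  p_manual <- Reduce(`+`, lapply(1:4, function(i) {
    predict_ss(ens, X[1:10, ], network = i)
  })) / 4
  expect_equal(p_ens, p_manual)
  # probabilities sum to one for many random inputs
  p_many <- predict_ss(ens, matrix(rnorm(1000 * 20), 1000, 20))
  expect_true(all(abs(rowSums(p_many) - 1) < 1e-9))
  expect_error(predict_ss(ens, matrix(0, 2, 7)), "dimension")
})

test_that("training is reproducible under a fixed seed", {
  set.seed(7)
  X <- matrix(rnorm(300 * 30), 300, 30)
  labs <- rep(c("A", "B"), each = 150)
  e1 <- train_classifier(X, labs, n_networks = 2, seed = 11,
                         arch = list(max_epochs = 8L))
  e2 <- train_classifier(X, labs, n_networks = 2, seed = 11,
                         arch = list(max_epochs = 8L))
  expect_equal(predict_ss(e1, X), predict_ss(e2, X))
})

test_that("regressor fits constant and realizable targets", {
  set.seed(8)
  X <- matrix(rnorm(500 * 20, sd = 0.5), 500, 20)
  # constant target
  r0 <- train_parameter_regressors(X, rep(0, 500), n_networks = 2, seed = 9,
                                   arch = list(max_epochs = 30L))
  expect_lt(mean(abs(predict_ss(r0, X))), 0.1)
  # linear function of one input cell, held-out R^2 >= 0.99
  set.seed(10)
  n <- 1200; d <- 10
  X2 <- matrix(rnorm(n * d, sd = 0.5), n, d)
  y <- 3 * X2[, 5] + 1
  re <- train_parameter_regressors(
    X2[1:1000, ], y[1:1000], n_networks = 1, seed = 3,
    arch = list(max_epochs = 500L, patience = 60L, lr = 3e-3))
  ph <- as.vector(predict_ss(re, X2[1001:1200, ]))
  r2 <- 1 - sum((ph - y[1001:1200])^2) / sum((y[1001:1200] -
                                                mean(y[1001:1200]))^2)
  expect_gte(r2, 0.99)
})

test_that("ensemble averaging does not hurt held-out log-loss (Jensen)", {
  set.seed(12)
  n <- 400; d <- 40
  mu <- matrix(rnorm(3 * d, sd = 0.6), 3, d)
  X <- mu[rep(1:3, length.out = n), ] + matrix(rnorm(n * d, sd = 0.8), n, d)
  labs <- rep(c("A", "B", "C"), length.out = n)
  idx <- seq_len(320)
  ens <- train_classifier(X[idx, ], labs[idx], n_networks = 4, seed = 13,
                          arch = list(max_epochs = 15L))
  Yh <- outer(labs[-idx], ens$classes, "==") * 1
  ll <- function(P) -mean(rowSums(Yh * log(P + 1e-12)))
  ens_loss <- ll(predict_ss(ens, X[-idx, ]))
  member_losses <- vapply(1:4, function(i) {
    ll(predict_ss(ens, X[-idx, ], network = i))
  }, numeric(1))
  expect_lte(ens_loss, mean(member_losses) + 1e-9)
})

test_that("Spearman-based selection picks the faithful network", {
  set.seed(14)
  X <- matrix(rnorm(200 * 10), 200, 10)
  truth <- seq_len(200)
  ens <- train_parameter_regressors(X, rnorm(200), n_networks = 3, seed = 15,
                                    arch = list(max_epochs = 3L))
  # selection rule on stub predictions: one member tracks the truth exactly
  preds <- list(rnorm(200), truth, rnorm(200))
  rho <- vapply(preds, function(p) cor(p, truth, method = "spearman"),
                numeric(1))
  expect_identical(which.max(rho), 2L)

  # hand-computed Spearman on a 10-point list matches stats::cor
  x <- c(3, 1, 4, 1.5, 9, 2.6, 5.3, 5.8, 9.7, 0.1)
  y <- c(2, 0.5, 5, 1, 8, 3, 6, 5.5, 10, 0)
  rx <- rank(x); ry <- rank(y)
  hand <- sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  expect_equal(cor(x, y, method = "spearman"), hand)

  # tie at rho = 1 resolves to the lowest index, and constant networks error
  expect_identical(which.max(c(1, 1, 0.2)), 1L)
  expect_error(select_network_by_spearman(ens, X, rep(1, 200)), "distinct")
})

test_that("selection over real ensemble members returns a valid index", {
  set.seed(16)
  X <- matrix(rnorm(300 * 15, sd = 1), 300, 15)
  y <- X[, 3] * 2 + rnorm(300, sd = 0.2)
  ens <- train_parameter_regressors(X[1:250, ], y[1:250], n_networks = 3,
                                    seed = 17, arch = list(max_epochs = 60L))
  best <- select_network_by_spearman(ens, X[251:300, ], y[251:300])
  rho <- attr(best, "rho")
  expect_true(best %in% 1:3)
  expect_identical(as.integer(best), as.integer(which.max(rho)))
})
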