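## Self-consistency validation: confusion matrix and factor-2 ----------------

#' Model-choice confusion matrix from precomputed summary statistics
#'
#' Low-level assembly of the confusion matrix: for pseudo-observed datasets
#' generated under each model, runs rejection ABC against the reference
#' table and records either the mean posterior probability assigned to each
#' model (`mode = "mean_posterior"`, the default) or the frequency with
#' which each model attains the maximum posterior
#' (`mode = "assignment"`).
#'
#' @param pseudo_ss Named list (one entry per generating model) of
#'   matrices of SS-DL vectors, one row per pseudo-observed dataset.
#' @param ref_ss Reference-table SS-DL matrix.
#' @param ref_labels Generating model of each reference row.
#' @param q Acceptance quantile for [abc_reject()].
#' @param mode `"mean_posterior"` or `"assignment"`.
#' @param models Model set (defaults to the six models).
#' @return Square matrix: rows = generating model, columns = mean posterior
#'   probability (or assignment frequency) per model; rows sum to one.
#' @export
confusion_from_ss <- function(pseudo_ss, ref_ss, ref_labels, q = 0.005,
                              mode = c("mean_posterior", "assignment"),
                              models = names(pseudo_ss)) {
  mode <- match.arg(mode)
  cm <- matrix(0, length(models), length(models),
               dimnames = list(true = models, predicted = models))
  for (mi in seq_along(models)) {
    ss <- pseudo_ss[[models[mi]]]
    post <- matrix(0, nrow(ss), length(models))
    for (r in seq_len(nrow(ss))) {
      acc <- abc_reject(ss[r, ], ref_ss, ref_labels, q = q)
      post[r, ] <- model_posterior(acc$accepted, models)
    }
    if (mode == "mean_posterior") {
      cm[mi, ] <- colMeans(post)
    } else {
      win <- apply(post, 1, which.max)
      cm[mi, ] <- tabulate(win, length(models)) / nrow(ss)
    }
  }
  cm
}

#' Factor-2 statistic for parameter recovery
#'
#' Fraction of replicates whose estimate lies within 50\%--200\% of the
#' true value, boundaries inclusive. Signs are handled by requiring
#' `0.5 * |truth| <= estimate * sign(truth) <= 2 * |truth|`; pairs with
#' `truth == 0` are excluded from the fraction and counted separately
#' (the statistic is undefined at zero).
#'
#' @param truth Numeric vector of true parameter values.
#' @param estimate Numeric vector of estimates (posterior means), same
#'   length.
#' @return List with `fraction`, `n_used`, `n_excluded`, `within`
#'   (logical per used pair).
#' @export
factor2 <- function(truth, estimate) {
  if (length(truth) != length(estimate)) {
    stop("truth and estimate must have equal length")
  }
  zero <- truth == 0
  t_ <- truth[!zero]; e <- estimate[!zero]
  within <- (e * sign(t_) >= 0.5 * abs(t_)) & (e * sign(t_) <= 2 * abs(t_))
  list(fraction = if (length(within)) mean(within) else NA_real_,
       n_used = length(within), n_excluded = sum(zero), within = within)
}
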