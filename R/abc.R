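## Rejection ABC on SS-DL summary statistics ---------------------------------

#' Rejection step of ABC
#'
#' Accepts the reference-table rows whose SS-DL summary statistics are
#' closest (Euclidean distance) to the observed summary. Two tolerance
#' modes: `epsilon` (absolute distance threshold) or `quantile` (accept the
#' `ceiling(q * N)` nearest rows). Distance ties at the acceptance boundary
#' are all included.
#'
#' @param ss_obs Numeric vector: observed SS-DL.
#' @param ss_ref Matrix, reference simulations x SS-DL dimensions.
#' @param values Labels (model choice) or numeric parameter values, one per
#'   reference row.
#' @param epsilon Absolute distance threshold; use `Inf` to accept all.
#' @param q Acceptance quantile in (0, 1]; used when `epsilon` is `NULL`.
#' @return List with `accepted` (subset of `values`), `distances`
#'   (accepted distances), and `threshold`.
#' @export
abc_reject <- function(ss_obs, ss_ref, values, epsilon = NULL, q = 0.005) {
  ss_ref <- as.matrix(ss_ref)
  if (!nrow(ss_ref)) stop("empty reference table")
  if (length(values) != nrow(ss_ref)) {
    stop("values must match reference rows")
  }
  if (length(ss_obs) != ncol(ss_ref)) {
    stop("SS-DL dimension mismatch: observed ", length(ss_obs),
         ", reference ", ncol(ss_ref))
  }
  d <- sqrt(colSums((t(ss_ref) - as.numeric(ss_obs))^2))
  if (!is.null(epsilon)) {
    keep <- d <= epsilon
    if (!any(keep)) {
      stop("no reference simulation within epsilon = ", epsilon,
           "; consider quantile mode (q)")
    }
    thr <- epsilon
  } else {
    if (q <= 0 || q > 1) stop("q must be in (0, 1]")
    k <- ceiling(q * length(d))
    thr <- sort(d, partial = k)[k]
    keep <- d <= thr  # boundary ties all included
  }
  list(accepted = values[keep], distances = d[keep], threshold = thr)
}

#' Posterior model probabilities from accepted labels
#'
#' @param accepted Character/factor labels of accepted reference rows.
#' @param models The model set (defaults to the six models).
#' @return Named numeric vector of probabilities summing to one.
#' @export
model_posterior <- function(accepted, models = ghost_model_ids()) {
  if (!length(accepted)) stop("no accepted simulations")
  tab <- table(factor(as.character(accepted), levels = models))
  as.vector(tab) / length(accepted) -> p
  setNames(p, models)
}

#' Posterior summary of an accepted parameter sample
#'
#' Mean and equal-tailed 95\% credible interval (2.5\% and 97.5\% empirical
#' percentiles, linear interpolation between order statistics, i.e.
#' `quantile(type = 7)`), mirroring the published posterior-summary table
#' layout (parameter, mean, 2.50\%, 97.50\%).
#'
#' @param accepted Numeric vector of accepted parameter values.
#' @param parameter Parameter name (metadata).
#' @return `data.frame` with columns `parameter`, `mean`, `q2.5`, `q97.5`,
#'   `n_accepted`.
#' @export
parameter_posterior <- function(accepted, parameter = "parameter") {
  if (!length(accepted)) stop("no accepted simulations")
  if (length(accepted) == 1) {
    warning("single accepted value; degenerate credible interval")
  }
  qs <- quantile(accepted, c(0.025, 0.975), names = FALSE, type = 7)
  data.frame(parameter = parameter, mean = mean(accepted),
             q2.5 = qs[1], q97.5 = qs[2], n_accepted = length(accepted),
             stringsAsFactors = FALSE)
}

#' Pairwise Bayes factors between models
#'
#' `factor(i, j) = [P(i)/P(j)] * [prior(j)/prior(i)]`. With equal priors
#' this is the posterior-odds ratio. Zero denominators give `Inf` and are
#' flagged in the `infinite` attribute.
#'
#' @param posterior Named numeric vector of posterior model probabilities.
#' @param prior Prior model probabilities (default equal).
#' @return Square matrix of Bayes factors with attribute `infinite`.
#' @export
bayes_factor <- function(posterior,
                         prior = rep(1 / length(posterior),
                                     length(posterior))) {
  k <- length(posterior)
  if (abs(sum(posterior) - 1) > 1e-6) posterior <- posterior / sum(posterior)
  bf <- outer(seq_len(k), seq_len(k), function(i, j) {
    (posterior[i] / posterior[j]) * (prior[j] / prior[i])
  })
  dimnames(bf) <- list(names(posterior), names(posterior))
  attr(bf, "infinite") <- which(is.infinite(bf), arr.ind = TRUE)
  bf
}
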