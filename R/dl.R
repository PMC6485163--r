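## Deep-learning summary statistics ------------------------------------------

# Per-cell standardization statistics from a training matrix. Cells with
# zero variance get unit scale so they map to a constant.
standardizer <- function(X) {
  ctr <- colMeans(X)
  scl <- apply(X, 2, sd)
  scl[!is.finite(scl) | scl < 1e-12] <- 1
  list(center = ctr, scale = scl)
}

apply_standardizer <- function(std, X) {
  sweep(sweep(X, 2, std$center, "-"), 2, std$scale, "/")
}

default_arch <- function() {
  list(hidden = c(64L, 32L, 16L, 8L), lr = 1e-3, batch = 64L,
       max_epochs = 40L, patience = 6L, val_frac = 0.1)
}

#' Train the ensemble of model-classification networks
#'
#' Trains `n_networks` independently initialized feed-forward networks
#' (four ReLU hidden layers, softmax head) that map a flattened normalized
#' jSFS to the probability of each demographic model. The averaged
#' prediction of the ensemble is the summary statistic (SS-DL) used inside
#' ABC.
#'
#' @param X Numeric matrix, simulations x jSFS cells (normalized spectra).
#' @param labels Factor or character vector of generating models, one per
#'   row; classes must be balanced in the study design.
#' @param n_networks Ensemble size (default 10).
#' @param arch List of hyperparameters (`hidden`, `lr`, `batch`,
#'   `max_epochs`, `patience`, `val_frac`); see `default_arch` values in
#'   the methods vignette.
#' @param seed Optional seed; training is reproducible given the seed.
#' @return An object of class `ssdl_ensemble`.
#' @export
train_classifier <- function(X, labels, n_networks = 10,
                             arch = default_arch(), seed = NULL) {
  X <- as.matrix(X)
  if (ncol(X) == 0) stop("degenerate input: zero-dimensional spectra")
  classes <- sort(unique(as.character(labels)))
  if (length(classes) < 2) stop("need at least two classes")
  Y <- outer(as.character(labels), classes, "==") * 1
  std <- standardizer(X)
  Xs <- apply_standardizer(std, X)
  a <- utils::modifyList(default_arch(), arch)
  with_seed(seed, {
    nets <- lapply(seq_len(n_networks), function(i) {
      mlp_train_cpp(Xs, Y, as.integer(a$hidden), 0L, a$lr,
                    as.integer(a$batch), as.integer(a$max_epochs),
                    as.integer(a$patience), a$val_frac)
    })
    structure(list(task = "classify", nets = nets, std = std,
                   classes = classes, arch = a, input_dim = ncol(X)),
              class = "ssdl_ensemble")
  })
}

#' Train the ensemble of parameter-regression networks
#'
#' As [train_classifier()] but with a scalar target (one model parameter)
#' and a linear head; the target is standardized internally and
#' predictions are returned on the natural scale.
#'
#' @inheritParams train_classifier
#' @param target Numeric vector of true parameter values, one per row.
#' @param param_name Name of the regressed parameter (metadata).
#' @return An object of class `ssdl_ensemble`.
#' @export
train_parameter_regressors <- function(X, target, param_name = "parameter",
                                       n_networks = 10, arch = default_arch(),
                                       seed = NULL) {
  X <- as.matrix(X)
  if (ncol(X) == 0) stop("degenerate input: zero-dimensional spectra")
  std <- standardizer(X)
  Xs <- apply_standardizer(std, X)
  t_ctr <- mean(target)
  t_scl <- sd(target)
  if (!is.finite(t_scl) || t_scl < 1e-12) t_scl <- 1
  Y <- matrix((target - t_ctr) / t_scl, ncol = 1)
  a <- utils::modifyList(default_arch(), arch)
  with_seed(seed, {
    nets <- lapply(seq_len(n_networks), function(i) {
      mlp_train_cpp(Xs, Y, as.integer(a$hidden), 1L, a$lr,
                    as.integer(a$batch), as.integer(a$max_epochs),
                    as.integer(a$patience), a$val_frac)
    })
    structure(list(task = "regress", nets = nets, std = std,
                   param_name = param_name, target_center = t_ctr,
                   target_scale = t_scl, arch = a, input_dim = ncol(X)),
              class = "ssdl_ensemble")
  })
}

#' @export
print.ssdl_ensemble <- function(x, ...) {
  cat("ssdl_ensemble (", x$task, "): ", length(x$nets), " networks, input ",
      x$input_dim, " cells",
      if (x$task == "classify") paste0(", classes ",
                                       paste(x$classes, collapse = ",")),
      if (x$task == "regress") paste0(", parameter ", x$param_name),
      "\n", sep = "")
  invisible(x)
}

#' Predict the SS-DL summary statistic
#'
#' For classification, the arithmetic mean of the member networks'
#' probability vectors (rows sum to one); for regression, the mean scalar
#' prediction on the natural scale. `network` restricts the prediction to a
#' single ensemble member (used after Spearman-based selection).
#'
#' @param ens An `ssdl_ensemble`.
#' @param X Matrix (or vector) of flattened normalized spectra.
#' @param network Optional single member index.
#' @return Matrix, rows = inputs: model probabilities (classification) or
#'   one column of parameter predictions (regression).
#' @export
predict_ss <- function(ens, X, network = NULL) {
  if (is.null(dim(X))) X <- matrix(X, nrow = 1)
  X <- as.matrix(X)
  if (ncol(X) != ens$input_dim) {
    stop("input dimension ", ncol(X), " does not match training dimension ",
         ens$input_dim)
  }
  Xs <- apply_standardizer(ens$std, X)
  task <- if (ens$task == "classify") 0L else 1L
  idx <- if (is.null(network)) seq_along(ens$nets) else network
  preds <- lapply(ens$nets[idx], function(nw) mlp_predict_cpp(nw, Xs, task))
  out <- Reduce(`+`, preds) / length(preds)
  if (ens$task == "regress") {
    out <- out * ens$target_scale + ens$target_center
    colnames(out) <- ens$param_name %||% "prediction"
  } else {
    colnames(out) <- ens$classes
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Select the best regression network by Spearman correlation
#'
#' Computes, for each ensemble member, the Spearman rank correlation
#' between its predictions on a validation set and the true parameter
#' values, and returns the index of the member with the highest
#' correlation. Ties are broken by the lowest index.
#'
#' @param ens A regression `ssdl_ensemble`.
#' @param X_val Validation spectra (matrix).
#' @param truth True parameter values for the validation rows.
#' @return Integer index of the selected network, with the per-network
#'   correlations attached as attribute `"rho"`.
#' @export
select_network_by_spearman <- function(ens, X_val, truth) {
  if (ens$task != "regress") stop("network selection applies to regressors")
  if (length(unique(truth)) < 2) {
    stop("validation truth must contain at least two distinct values")
  }
  rho <- vapply(seq_along(ens$nets), function(i) {
    p <- as.vector(predict_ss(ens, X_val, network = i))
    if (sd(p) < 1e-300 || !is.finite(sd(p))) NA_real_
    else cor(p, truth, method = "spearman")
  }, numeric(1))
  if (all(is.na(rho))) {
    stop("all networks produce constant predictions; correlation undefined")
  }
  best <- which.max(rho)  # NA ranks last; ties -> lowest index
  attr(best, "rho") <- rho
  best
}
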