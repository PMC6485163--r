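## End-to-end ABC-DL studies: presets, banks, confusion matrix, factor-2 -----

#' Study presets
#'
#' Concrete problem sizes for a full study. `desk_study()` is the
#' laptop-scale configuration used by the test-suite and the analysis
#' scripts: 300 fragments of 20 kbp, 500 training and 500 reference
#' simulations per model, 20 pseudo-observed datasets per model, 2,000
#' training / 2,000 reference simulations and 100 replicates for parameter
#' recovery, acceptance quantile 0.02. `paper_study()` mirrors the
#' published protocol (11,642 fragments totalling 393.5 Mbp; 15,000
#' training and 150,000 reference simulations per model; 100
#' pseudo-observed datasets per model; 20,000 simulations per parameter;
#' 1,000 recovery replicates).
#'
#' @return List of study settings.
#' @export
desk_study <- function() {
  list(name = "desk",
       fragments = desk_fragments(),
       n_train = 500L, n_ref = 500L, n_pseudo = 20L,
       par_n_train = 2000L, par_n_ref = 2000L, par_n_rep = 100L,
       q = 0.02, lambda = 0.5, n_networks = 10L,
       arch = default_arch())
}

#' @rdname desk_study
#' @export
paper_study <- function() {
  list(name = "paper",
       fragments = paper_fragments(),
       n_train = 15000L, n_ref = 150000L, n_pseudo = 100L,
       par_n_train = 20000L, par_n_ref = 150000L, par_n_rep = 1000L,
       q = 0.005, lambda = 0.5, n_networks = 10L,
       arch = utils::modifyList(default_arch(), list(max_epochs = 100L)))
}

#' Synthetic noise-panel spectrum
#'
#' The published protocol injects noise from the observed jSFS of a
#' designated noise panel of real genomes. With no real genomes in scope,
#' the noise panel is emulated by a single simulation of model B at the
#' prior midpoint, under the study's fragment preset.
#'
#' @param fragments A [fragment_set()].
#' @param seed Seed for the noise-panel simulation.
#' @return A `joint_sfs` of counts.
#' @export
noise_panel_jsfs <- function(fragments = desk_fragments(), seed = 1) {
  model <- build_model("B", prior_midpoint("B"))
  compute_jsfs(simulate_fragments(model, fragments, seed = seed))
}

# simulate one noise-injected, normalized, flattened jSFS under a model
sim_one_jsfs <- function(model_id, params, fragments, noise, lambda) {
  model <- build_model(model_id, params)
  geno <- simulate_fragments(model, fragments)
  js <- compute_jsfs(geno)
  if (js$n_sites == 0) stop("simulation produced no segregating sites")
  if (!is.null(noise)) js <- inject_noise(js, noise, lambda = lambda)
  flatten_jsfs(normalize_jsfs(js))
}

#' Simulate a labelled jSFS bank
#'
#' Draws parameters from the priors, simulates the fragmented genomes,
#' tallies and noise-injects the jSFS, and returns flattened normalized
#' spectra with full provenance.
#'
#' @param model_id One of `"A"`..`"F"`.
#' @param n Number of simulations.
#' @param fragments A [fragment_set()].
#' @param noise Noise-panel `joint_sfs` (or `NULL` to skip injection).
#' @param lambda Noise mixture weight.
#' @param seed Seed.
#' @param partition Provenance tag (e.g. `"train"`).
#' @return List with `X` (n x cells matrix), `params` (n x p matrix),
#'   `model_id`, `provenance` (`data.frame` of ids and seeds).
#' @export
simulate_jsfs_bank <- function(model_id, n, fragments = desk_fragments(),
                               noise = NULL, lambda = 0.5, seed = 1,
                               partition = "train") {
  params <- with_seed(child_seed(seed, 0), draw_parameters(model_id, n = n))
  if (n == 1) params <- matrix(params, nrow = 1,
                               dimnames = list(NULL, names(params)))
  seeds <- vapply(seq_len(n), function(i) child_seed(seed, i), integer(1))
  X <- NULL
  for (i in seq_len(n)) {
    v <- with_seed(seeds[i],
                   sim_one_jsfs(model_id, params[i, ], fragments, noise,
                                lambda))
    if (is.null(X)) X <- matrix(NA_real_, n, length(v))
    X[i, ] <- v
  }
  list(X = X, params = params, model_id = model_id,
       provenance = data.frame(
         id = sprintf("%s:%s:%d", model_id, partition, seq_len(n)),
         model = model_id, partition = partition, index = seq_len(n),
         seed = seeds, stringsAsFactors = FALSE))
}

#' Build train/reference/pseudo-observed jSFS banks for a model set
#'
#' The three partitions are disjoint by construction (independent draws
#' and seeds; provenance ids identify every simulation).
#'
#' @param models Character vector of model ids.
#' @param n_train,n_ref,n_pseudo Simulations per model and partition.
#' @param fragments A [fragment_set()].
#' @param noise Noise-panel `joint_sfs`.
#' @param lambda Noise mixture weight.
#' @param seed Master seed.
#' @return List with `train` (`X`, `labels`), `reference` (`X`, `labels`),
#'   `pseudo` (named list of matrices per model), and `provenance`.
#' @export
make_jsfs_bank <- function(models = ghost_model_ids(), n_train = 10,
                           n_ref = 10, n_pseudo = 0,
                           fragments = desk_fragments(), noise = NULL,
                           lambda = 0.5, seed = 1) {
  parts <- list()
  prov <- list()
  pull <- function(part, n, off) {
    xs <- list(); labs <- character(0)
    for (mi in seq_along(models)) {
      b <- simulate_jsfs_bank(models[mi], n, fragments, noise, lambda,
                              seed = child_seed(seed, off + mi * 131),
                              partition = part)
      xs[[mi]] <- b$X
      labs <- c(labs, rep(models[mi], n))
      prov[[length(prov) + 1]] <<- b$provenance
    }
    list(X = do.call(rbind, xs), labels = labs)
  }
  with_seed(seed, {
    if (n_train > 0) parts$train <- pull("train", n_train, 1000)
    if (n_ref > 0) parts$reference <- pull("reference", n_ref, 2000)
    if (n_pseudo > 0) {
      ps <- pull("pseudo", n_pseudo, 3000)
      parts$pseudo <- split.data.frame(ps$X, ps$labels)[models]
    }
  })
  parts$provenance <- do.call(rbind, prov)
  parts
}

#' Run the model-choice study and its confusion matrix
#'
#' The full ABC-DL self-consistency loop for model choice: simulate
#' noise-injected training/reference/pseudo-observed banks under all six
#' models, train the classifier ensemble, compute SS-DL summaries, run
#' rejection ABC for every pseudo-observed dataset, and assemble the
#' confusion matrix of mean posterior probabilities.
#'
#' @param preset Study preset (see [desk_study()]).
#' @param seed Master seed.
#' @param models Model set.
#' @return List with `confusion` (matrix), `ensemble`, `ss_ref`,
#'   `ref_labels`, and the `preset` used.
#' @export
run_model_choice_study <- function(preset = desk_study(), seed = 1,
                                   models = ghost_model_ids()) {
  noise <- noise_panel_jsfs(preset$fragments, seed = child_seed(seed, 7))
  bank <- make_jsfs_bank(models, preset$n_train, preset$n_ref,
                         preset$n_pseudo, preset$fragments, noise,
                         preset$lambda, seed = child_seed(seed, 11))
  ens <- train_classifier(bank$train$X, bank$train$labels,
                          n_networks = preset$n_networks,
                          arch = preset$arch, seed = child_seed(seed, 13))
  ss_ref <- predict_ss(ens, bank$reference$X)
  pseudo_ss <- lapply(bank$pseudo, function(X) predict_ss(ens, X))
  cm <- confusion_from_ss(pseudo_ss, ss_ref, bank$reference$labels,
                          q = preset$q, models = models)
  list(confusion = cm, ensemble = ens, ss_ref = ss_ref,
       ref_labels = bank$reference$labels, preset = preset, seed = seed)
}

#' Run the factor-2 parameter-recovery study
#'
#' For one free parameter of a model: train the 10-network regression
#' ensemble on prior draws, select the best network by Spearman
#' correlation on the reference simulations, then for each recovery
#' replicate (a fresh prior draw treated as observed data) run rejection
#' ABC on the selected network's SS-DL and record the posterior mean.
#' The factor-2 statistic summarizes how often the posterior mean falls
#' within 50\%--200\% of the truth.
#'
#' @param parameter Parameter name (default `"tAMH-XAf"`).
#' @param model_id Generating model (default `"B"`).
#' @param preset Study preset.
#' @param seed Master seed.
#' @return List with `report` (the [factor2()] output), `truth`,
#'   `posterior_mean` vectors, the selected network index, and the preset.
#' @export
run_parameter_recovery_study <- function(parameter = "tAMH-XAf",
                                         model_id = "B",
                                         preset = desk_study(), seed = 1) {
  if (!parameter %in% enumerate_parameters(model_id)) {
    stop("unknown parameter for model ", model_id, ": ", parameter)
  }
  noise <- noise_panel_jsfs(preset$fragments, seed = child_seed(seed, 7))
  train <- simulate_jsfs_bank(model_id, preset$par_n_train,
                              preset$fragments, noise, preset$lambda,
                              seed = child_seed(seed, 21),
                              partition = "train")
  ens <- train_parameter_regressors(train$X, train$params[, parameter],
                                    param_name = parameter,
                                    n_networks = preset$n_networks,
                                    arch = preset$arch,
                                    seed = child_seed(seed, 23))
  ref <- simulate_jsfs_bank(model_id, preset$par_n_ref, preset$fragments,
                            noise, preset$lambda,
                            seed = child_seed(seed, 25),
                            partition = "reference")
  best <- select_network_by_spearman(ens, ref$X, ref$params[, parameter])
  ss_ref <- predict_ss(ens, ref$X, network = best)

  rep_bank <- simulate_jsfs_bank(model_id, preset$par_n_rep,
                                 preset$fragments, noise, preset$lambda,
                                 seed = child_seed(seed, 27),
                                 partition = "pseudo")
  ss_rep <- predict_ss(ens, rep_bank$X, network = best)
  post_mean <- vapply(seq_len(nrow(ss_rep)), function(r) {
    acc <- abc_reject(ss_rep[r, ], ss_ref, ref$params[, parameter],
                      q = preset$q)
    mean(acc$accepted)
  }, numeric(1))
  truth <- rep_bank$params[, parameter]
  list(report = factor2(truth, post_mean), truth = truth,
       posterior_mean = post_mean, selected_network = as.integer(best),
       spearman_rho = attr(best, "rho"), preset = preset, seed = seed,
       parameter = parameter, model_id = model_id)
}
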