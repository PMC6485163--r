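## Fragment sets -------------------------------------------------------------

#' Define the fragmented callable genome to simulate
#'
#' Fragments are simulated as independent coalescent replicates (no linkage
#' between fragments, and each fragment treated as a single non-recombining
#' locus; see the methods vignette for the rationale).
#'
#' @param n_fragments Number of fragments.
#' @param lengths Fragment lengths in bp; a scalar is recycled.
#' @param mutation_rate Per bp per generation (default 1.25e-8).
#' @param recombination_rate Per bp per generation; retained as metadata
#'   (fragments are unlinked and internally non-recombining).
#' @return An object of class `fragment_set`.
#' @export
fragment_set <- function(n_fragments, lengths, mutation_rate = 1.25e-8,
                         recombination_rate = 1e-8) {
  lengths <- rep_len(as.numeric(lengths), n_fragments)
  if (any(lengths <= 0)) stop("fragment lengths must be > 0")
  if (mutation_rate < 0) stop("mutation_rate must be >= 0")
  structure(list(n_fragments = as.integer(n_fragments), lengths = lengths,
                 mutation_rate = mutation_rate,
                 recombination_rate = recombination_rate),
            class = "fragment_set")
}

#' Desk-scale fragment preset: 300 fragments of 20 kbp
#' @inheritParams fragment_set
#' @export
desk_fragments <- function(mutation_rate = 1.25e-8) {
  fragment_set(300L, 20000, mutation_rate)
}

#' Study-scale fragment preset: 11,642 fragments totalling 393.5 Mbp
#'
#' Equal fragment lengths up to 1 bp rounding so that the total callable
#' length is exactly 393.5 Mbp.
#' @inheritParams fragment_set
#' @export
paper_fragments <- function(mutation_rate = 1.25e-8) {
  n <- 11642L
  total <- 393.5e6
  base <- floor(total / n)
  rem <- total - base * n
  lengths <- rep(base, n)
  if (rem > 0) lengths[seq_len(rem)] <- base + 1
  fragment_set(n, lengths, mutation_rate)
}

## Genotype matrices ---------------------------------------------------------

#' Construct a genotype matrix object
#'
#' Container for polarized diploid genotypes over a fragmented genome:
#' a site table (fragment id, 0-based position), a sites x samples matrix of
#' derived-allele dosages in \{0,1,2\}, per-fragment lengths and a callable
#' mask (0-based half-open intervals per fragment).
#'
#' @param sites `data.frame` with integer columns `frag` (1-based fragment
#'   id) and `pos` (0-based position within the fragment).
#' @param geno Integer matrix, sites x samples, dosages 0/1/2; column names
#'   are sample labels.
#' @param frag_lengths Numeric vector of fragment lengths (bp).
#' @param mask Callable mask, `data.frame(frag, start, end)` 0-based
#'   half-open; defaults to fully callable fragments.
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(sites, geno, frag_lengths, mask = NULL) {
  stopifnot(nrow(sites) == nrow(geno))
  if (is.null(colnames(geno))) stop("geno must have sample column names")
  if (any(geno < 0 | geno > 2)) stop("dosages must be in {0,1,2}")
  if (nrow(sites) &&
      any(sites$pos < 0 | sites$pos >= frag_lengths[sites$frag])) {
    stop("site outside its fragment")
  }
  if (is.null(mask)) {
    mask <- data.frame(frag = seq_along(frag_lengths), start = 0,
                       end = frag_lengths)
  }
  structure(list(sites = sites, geno = geno,
                 samples = colnames(geno),
                 frag_lengths = frag_lengths, mask = mask),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", nrow(x$sites), "sites x", ncol(x$geno),
      "samples over", length(x$frag_lengths), "fragments (",
      format(sum(x$frag_lengths) / 1e6, digits = 4), "Mbp )\n")
  invisible(x)
}

## Simulation ----------------------------------------------------------------

#' Simulate fragmented genomes under a demographic model
#'
#' Runs the structured-coalescent engine for every fragment independently
#' and returns polarized diploid genotypes for all sampled individuals.
#' Individuals are ordered by the canonical panel order
#' ([panel_populations()]) and labelled by population (suffixed `_1`,
#' `_2`, ... when a population contributes several diploids).
#'
#' @param model A `ghost_model` from [build_model()], or any object with
#'   the same structure.
#' @param fragments A [fragment_set()].
#' @param seed Optional integer seed (the caller's RNG state is restored on
#'   exit); with `seed = NULL` the current RNG stream is used.
#' @return A [genotype_matrix()] with a fully callable mask.
#' @export
simulate_fragments <- function(model, fragments, seed = NULL) {
  with_seed(seed, simulate_fragments_impl(model, fragments))
}

simulate_fragments_impl <- function(model, fragments) {
  pops <- model$populations
  sampled <- pops[pops$n_diploid > 0, ]
  if (!nrow(sampled)) stop("configuration error: model samples no population")
  ord <- order(match(sampled$name, panel_populations(), nomatch = 999L))
  sampled <- sampled[ord, ]

  gen <- function(kya) kya * 1000 / model$generation_time
  popidx <- setNames(seq_len(nrow(pops)) - 1L, pops$name)

  sample_pop <- integer(0)
  sample_time <- numeric(0)
  labels <- character(0)
  for (i in seq_len(nrow(sampled))) {
    k <- sampled$n_diploid[i]
    sample_pop <- c(sample_pop, rep(popidx[[sampled$name[i]]], k))
    sample_time <- c(sample_time, rep(gen(sampled$sample_time_kya[i]), k))
    labels <- c(labels, if (k == 1) sampled$name[i] else
                paste0(sampled$name[i], "_", seq_len(k)))
  }

  ev <- model$events
  ev <- ev[order(ev$time_kya, ev$kind != "pulse_introgression"), ]
  ev_kind <- ifelse(ev$kind == "split", 0L, 1L)
  # splits move the child's lineages into the parent; pulses (viewed
  # backward in time) move each recipient lineage to the introgressing
  # source with probability equal to the pulse proportion
  ev_from_pop <- ifelse(ev_kind == 0L, ev$source, ev$dest)
  ev_to_pop <- ifelse(ev_kind == 0L, ev$dest, ev$source)
  mig <- model$migrations
  if (is.null(mig)) mig <- data.frame(from = character(0), to = character(0),
                                      rate = numeric(0))

  res <- sim_fragments_cpp(
    pop_ne = pops$Ne,
    sample_pop = as.integer(sample_pop),
    sample_time = sample_time,
    ev_time = gen(ev$time_kya),
    ev_kind = as.integer(ev_kind),
    ev_from = as.integer(popidx[ev_from_pop]),
    ev_to = as.integer(popidx[ev_to_pop]),
    ev_prop = ifelse(is.na(ev$magnitude), 0, ev$magnitude),
    mig_from = as.integer(popidx[mig$from]),
    mig_to = as.integer(popidx[mig$to]),
    mig_rate = mig$rate,
    frag_len = fragments$lengths,
    mu = fragments$mutation_rate)

  o <- order(res$frag, res$pos)
  geno <- res$geno[o, , drop = FALSE]
  colnames(geno) <- labels
  genotype_matrix(
    sites = data.frame(frag = res$frag[o], pos = res$pos[o]),
    geno = geno, frag_lengths = fragments$lengths)
}

#' Calibration check: recover a planted admixture pulse
#'
#' Simulates a four-population scenario with a single admixture pulse of
#' proportion `alpha` from a diverged source into a target population and
#' estimates the pulse size with the f4-ratio
#' `f4(Src1, Sister; Target, Ref) / f4(Src1, Sister; Src2, Ref)`, where
#' `Src1`/`Src2` are two diploid genomes from the source population.
#'
#' @param alpha Planted admixture proportion in `[0, 1]`.
#' @param fragments A [fragment_set()].
#' @param block_size Jackknife block size in bp.
#' @return List with the f4-ratio estimate (`alpha_hat`), its jackknife SE,
#'   and the planted truth.
#' @export
plant_pulse_check <- function(alpha, fragments = fragment_set(500, 20000),
                              block_size = 1e6) {
  panel <- make_admixed_panel(alpha, fragments = fragments)
  fr <- f4_ratio(panel$geno,
                 num = c("Src_1", "Sister", "Target", "Ref"),
                 den = c("Src_1", "Sister", "Src_2", "Ref"),
                 block_size = block_size)
  list(alpha_hat = fr$ratio, se = fr$se, alpha_true = alpha)
}
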