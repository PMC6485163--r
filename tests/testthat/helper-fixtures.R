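# Shared fixtures, all generated in code.

# single panmictic population, one diploid sample
single_pop_model <- function(Ne = 5000) {
  structure(list(
    model_id = "single",
    populations = data.frame(name = "P", Ne = Ne, sample_time_kya = 0,
                             n_diploid = 1L, stringsAsFactors = FALSE),
    events = data.frame(kind = character(0), time_kya = numeric(0),
                        source = character(0), dest = character(0),
                        magnitude = numeric(0), time_gen = numeric(0)),
    migrations = NULL, generation_time = 29), class = "ghost_model")
}

# two populations splitting at `split_kya`, one diploid sample each
two_pop_model <- function(split_kya, Ne = 5000) {
  m <- structure(list(
    model_id = "two_pop",
    populations = data.frame(name = c("P1", "P2", "ANC"), Ne = Ne,
                             sample_time_kya = 0,
                             n_diploid = c(1L, 1L, 0L),
                             stringsAsFactors = FALSE),
    events = data.frame(kind = c("split", "split"),
                        time_kya = c(split_kya, split_kya),
                        source = c("P1", "P2"), dest = c("ANC", "ANC"),
                        magnitude = c(NA_real_, NA_real_),
                        stringsAsFactors = FALSE),
    migrations = NULL, generation_time = 29), class = "ghost_model")
  m$events$time_gen <- m$events$time_kya * 1000 / 29
  m
}

# genotype matrix from explicit dosage rows (one fragment per `frag`)
toy_geno <- function(dosages, frag = NULL, pos = NULL, frag_len = NULL) {
  g <- as.matrix(dosages)
  n <- nrow(g)
  if (is.null(frag)) frag <- rep(1L, n)
  if (is.null(pos)) pos <- ave(seq_len(n), frag, FUN = seq_along) * 10
  nfrag <- max(1L, if (n) max(frag) else 1L)
  if (is.null(frag_len)) frag_len <- max(1000L, if (n) max(pos) + 10 else 0)
  genotype_matrix(sites = data.frame(frag = as.integer(frag),
                                     pos = as.integer(pos)),
                  geno = g,
                  frag_lengths = rep(frag_len, nfrag))
}

# quartet toy: per-site sampled-allele patterns (w, x, y) with ancestral
# outgroup; homozygous dosages make allele sampling deterministic
quartet_geno <- function(patterns, frag, frag_len = 1000) {
  g <- 2L * as.matrix(patterns)
  colnames(g) <- c("W", "X", "Y")
  toy_geno(g, frag = frag, frag_len = frag_len)
}
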