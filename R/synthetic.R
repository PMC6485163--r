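## Synthetic fixtures: planted-ROH genomes and planted-admixture panels ------

#' Generate a genome with planted runs of homozygosity
#'
#' Heterozygous sites are placed by a Poisson process at `background_rate`
#' per kbp on the callable genome, thinned to `inside_rate` per kbp inside
#' the planted segments (default 0: fully depleted). The callable mask is
#' the full contig minus `gaps`. The planted truth is recorded in a
#' manifest so callers can verify recovery.
#'
#' @param length_bp Contig length.
#' @param planted `data.frame(start, end)` of planted ROH (0-based
#'   half-open, non-overlapping).
#' @param background_rate Heterozygosity per kbp outside segments
#'   (default 1, the expected heterozygosity assumed by the ROH caller).
#' @param inside_rate Heterozygosity per kbp inside planted segments.
#' @param gaps Optional `data.frame(start, end)` of non-callable intervals.
#' @param seed Optional seed.
#' @param dir Optional directory; when given, a VCF (`roh.vcf`), BED mask
#'   (`roh.bed`) and manifest TSV are written there.
#' @return List with `geno` (a [genotype_matrix()] for sample `"S"`),
#'   `het` (site table), `mask`, `manifest`, and file `paths` (when `dir`
#'   is given).
#' @export
make_roh_genome <- function(length_bp = 10e6,
                            planted = data.frame(start = numeric(0),
                                                 end = numeric(0)),
                            background_rate = 1, inside_rate = 0,
                            gaps = NULL, seed = NULL, dir = NULL) {
  if (nrow(planted) > 1) {
    p <- planted[order(planted$start), ]
    if (any(p$start[-1] < p$end[-nrow(p)])) {
      stop("planted segments overlap")
    }
  }
  mask <- data.frame(frag = 1L, start = 0, end = length_bp)
  if (!is.null(gaps) && nrow(gaps)) {
    keep_s <- numeric(0); keep_e <- numeric(0)
    cur <- 0
    g <- gaps[order(gaps$start), ]
    for (i in seq_len(nrow(g))) {
      if (g$start[i] > cur) { keep_s <- c(keep_s, cur)
                              keep_e <- c(keep_e, g$start[i]) }
      cur <- max(cur, g$end[i])
    }
    if (cur < length_bp) { keep_s <- c(keep_s, cur)
                           keep_e <- c(keep_e, length_bp) }
    mask <- data.frame(frag = rep(1L, length(keep_s)), start = keep_s,
                       end = keep_e)
  }

  pos <- with_seed(seed, {
    n <- rpois(1, length_bp * background_rate / 1000)
    cand <- sort(floor(runif(n) * length_bp))
    callable <- rep(FALSE, length(cand))
    for (i in seq_len(nrow(mask))) {
      callable <- callable | (cand >= mask$start[i] & cand < mask$end[i])
    }
    cand <- cand[callable]
    if (nrow(planted)) {
      inside <- rep(FALSE, length(cand))
      for (i in seq_len(nrow(planted))) {
        inside <- inside | (cand >= planted$start[i] & cand < planted$end[i])
      }
      thin <- runif(length(cand)) < inside_rate / background_rate
      cand <- cand[!inside | thin]
    }
    cand
  })

  sites <- data.frame(frag = rep(1L, length(pos)), pos = pos)
  geno <- genotype_matrix(
    sites = sites,
    geno = matrix(1L, nrow = length(pos), ncol = 1,
                  dimnames = list(NULL, "S")),
    frag_lengths = length_bp, mask = mask)
  manifest <- list(kind = "roh_genome", length_bp = length_bp,
                   planted = planted, background_rate = background_rate,
                   inside_rate = inside_rate, seed = seed)
  paths <- NULL
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    vcf <- file.path(dir, "roh.vcf"); bed <- file.path(dir, "roh.bed")
    man <- file.path(dir, "roh_manifest.tsv")
    write_vcf(geno, vcf, bed)
    write.table(
      data.frame(key = c("length_bp", "background_rate", "inside_rate",
                         "planted"),
                 value = c(length_bp, background_rate, inside_rate,
                           paste(sprintf("%d-%d", as.integer(planted$start),
                                         as.integer(planted$end)),
                                 collapse = ","))),
      man, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- c(vcf = vcf, bed = bed, manifest = man)
  }
  list(geno = geno, het = sites, mask = mask, manifest = manifest,
       paths = paths)
}

#' Simulate a panel with one planted admixture pulse
#'
#' A five-genome fixture driving the D-statistic and f4-ratio tests: a
#' source population `Src` (two diploid genomes), its sister population
#' `Sister`, an admixed target `Target`, and an unadmixed reference `Ref`.
#' `Target` receives a single pulse of proportion `alpha` from `Src` at
#' `pulse_kya`. The planted truth is returned in the manifest; the
#' expectation of `f4(Src_1, Sister; Target, Ref) / f4(Src_1, Sister;
#' Src_2, Ref)` equals `alpha`.
#'
#' @param alpha Pulse proportion in `[0, 1]`.
#' @param fragments A [fragment_set()].
#' @param split_target_ref Split time of `Target` and `Ref` (kya).
#' @param split_src_sister Split time of `Src` and `Sister` (kya).
#' @param split_deep Split of the two clades (kya).
#' @param pulse_kya Pulse time (kya).
#' @param Ne Diploid size used for every branch.
#' @param seed Optional seed.
#' @return List with `geno` (a [genotype_matrix()]) and `manifest`.
#' @export
make_admixed_panel <- function(alpha, fragments = fragment_set(500, 20000),
                               split_target_ref = 60, split_src_sister = 60,
                               split_deep = 120, pulse_kya = 1, Ne = 3000,
                               seed = NULL) {
  if (alpha < 0 || alpha > 1) stop("alpha must be in [0,1]")
  pops <- c("Src", "Sister", "Target", "Ref", "ANC_SRC", "ANC_TGT", "ROOT")
  model <- structure(list(
    model_id = "admixture_fixture",
    populations = data.frame(
      name = pops, Ne = Ne, sample_time_kya = 0,
      n_diploid = c(2L, 1L, 1L, 1L, 0L, 0L, 0L), stringsAsFactors = FALSE),
    events = data.frame(
      kind = c("pulse_introgression", "split", "split", "split", "split",
               "split", "split"),
      time_kya = c(pulse_kya, split_src_sister, split_src_sister,
                   split_target_ref, split_target_ref, split_deep,
                   split_deep),
      source = c("Src", "Src", "Sister", "Target", "Ref", "ANC_SRC",
                 "ANC_TGT"),
      dest = c("Target", "ANC_SRC", "ANC_SRC", "ANC_TGT", "ANC_TGT",
               "ROOT", "ROOT"),
      magnitude = c(alpha, NA, NA, NA, NA, NA, NA),
      stringsAsFactors = FALSE),
    migrations = NULL,
    generation_time = 29), class = "ghost_model")
  model$events$time_gen <- model$events$time_kya * 1000 / 29
  geno <- simulate_fragments(model, fragments, seed = seed)
  list(geno = geno,
       manifest = list(kind = "admixed_panel", alpha = alpha,
                       pulse_kya = pulse_kya,
                       splits = c(target_ref = split_target_ref,
                                  src_sister = split_src_sister,
                                  deep = split_deep),
                       Ne = Ne, seed = seed))
}
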