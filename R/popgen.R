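## Descriptive statistics: diversity, ROH, D-statistic, f4-ratio -------------

#' Sample one allele per individual per site
#'
#' Haploidizes a diploid dosage matrix: dosage 0 gives allele 0, dosage 2
#' gives allele 1, and heterozygous sites draw one allele at random. The
#' random stream is documented and keyed per sample so results do not
#' depend on the order in which samples are later used: for the j-th sample
#' column, the stream is seeded with `seed + j` and one `runif()` draw is
#' consumed per heterozygous site, in site order (allele 1 when the draw is
#' < 0.5).
#'
#' @param geno A [genotype_matrix()].
#' @param seed Integer seed.
#' @return Integer matrix sites x samples of alleles in \{0, 1\}.
#' @export
sample_alleles <- function(geno, seed = 1) {
  g <- geno$geno
  out <- matrix(0L, nrow(g), ncol(g), dimnames = dimnames(g))
  for (j in seq_len(ncol(g))) {
    col <- g[, j]
    a <- as.integer(col == 2)
    het <- which(col == 1L)
    if (length(het)) {
      u <- with_seed(seed + j, runif(length(het)))
      a[het] <- as.integer(u < 0.5)
    }
    out[, j] <- a
  }
  out
}

# allele track for a quartet member: a sample column or the all-ancestral
# pseudo-outgroup ("Chimp" / "ancestral")
allele_track <- function(haplo, geno, name) {
  if (name %in% c("Chimp", "ancestral", "Ancestral")) {
    return(rep(0L, nrow(haplo)))
  }
  if (!name %in% colnames(haplo)) stop("missing sample: ", name)
  haplo[, name]
}

#' Pairwise genotype differences per kbp of callable genome
#'
#' For two distinct individuals, one of the two alleles is sampled at
#' random in each locus (seeded, see [sample_alleles()]) and the number of
#' mismatching sampled alleles is divided by the callable length in kbp.
#' The self-comparison compares the individual's two chromosomes, i.e.
#' counts heterozygous genotypes per callable kbp (heterozygosity).
#'
#' @param geno A [genotype_matrix()].
#' @param s1,s2 Sample labels (equal labels give heterozygosity).
#' @param seed Seed for allele sampling.
#' @return List with `diff_per_kbp`, `n_callable_kbp`, `pair`, `seed`.
#' @export
pairwise_diff_per_kbp <- function(geno, s1, s2, seed = 1) {
  callable <- sum(geno$mask$end - geno$mask$start)
  if (callable <= 0) stop("empty callable overlap")
  kbp <- callable / 1000
  if (!all(c(s1, s2) %in% geno$samples)) {
    stop("missing sample(s): ",
         paste(setdiff(c(s1, s2), geno$samples), collapse = ", "))
  }
  if (identical(s1, s2)) {
    nd <- sum(geno$geno[, s1] == 1L)
  } else {
    h <- sample_alleles(geno, seed)
    nd <- sum(h[, s1] != h[, s2])
  }
  list(diff_per_kbp = nd / kbp, n_callable_kbp = kbp,
       pair = c(s1, s2), seed = seed)
}

## ROH -----------------------------------------------------------------------

# merge 0-based half-open intervals of one contig
merge_intervals <- function(start, end) {
  o <- order(start)
  start <- start[o]; end <- end[o]
  ms <- start[1]; me <- end[1]
  out_s <- numeric(0); out_e <- numeric(0)
  for (i in seq_along(start)[-1]) {
    if (start[i] <= me) me <- max(me, end[i])
    else { out_s <- c(out_s, ms); out_e <- c(out_e, me)
           ms <- start[i]; me <- end[i] }
  }
  cbind(start = c(out_s, ms), end = c(out_e, me))
}

#' Call runs of homozygosity
#'
#' Implements the three-tier ROH rule: the callable genome of each contig
#' is cut into consecutive windows of exactly 1 kbp of callable sequence
#' (mask gaps are compressed; a trailing partial window is dropped). A
#' window is low-heterozygosity iff its heterozygous-genotype count is
#' strictly below 10\% of the expected heterozygosity (1 het per callable
#' kbp, i.e. < 0.1). Maximal runs of consecutive low-het windows are
#' reported as ROH if their physical span exceeds the smallest tier
#' threshold and at least 67\% of the span is callable; each segment is
#' labelled with the largest tier (0.5, 1, 1.5 Mbp) its span exceeds.
#'
#' @param het `data.frame` with columns `frag` and `pos` (0-based) of the
#'   sample's heterozygous sites, sorted by position within each contig.
#' @param mask Callable mask `data.frame(frag, start, end)`, 0-based
#'   half-open.
#' @param tiers Span thresholds in bp (default 0.5, 1, 1.5 Mbp).
#' @param min_callable_frac Minimum callable fraction of the span
#'   (default 0.67).
#' @return `data.frame` with columns `frag`, `start`, `end`, `length`,
#'   `callable_frac`, `tier` (threshold in bp of the largest tier met).
#' @export
call_roh <- function(het, mask, tiers = c(0.5e6, 1e6, 1.5e6),
                     min_callable_frac = 0.67) {
  res <- list()
  for (f in unique(mask$frag)) {
    m <- merge_intervals(mask$start[mask$frag == f],
                         mask$end[mask$frag == f])
    pos <- het$pos[het$frag == f]
    if (length(pos) && any(diff(pos) < 0)) {
      stop("heterozygous positions must be sorted within contig ", f)
    }
    cum <- c(0, cumsum(m[, "end"] - m[, "start"]))
    n_bins <- floor(cum[length(cum)] / 1000)
    if (n_bins == 0) next

    # physical coordinate of callable offset c (0-based)
    phys <- function(cc) {
      i <- findInterval(cc, cum, rightmost.closed = FALSE)
      i[i > nrow(m)] <- nrow(m)
      m[i, "start"] + (cc - cum[i])
    }
    bin_start <- phys(1000 * (seq_len(n_bins) - 1))
    bin_end <- phys(1000 * seq_len(n_bins) - 1) + 1  # pos after last bp

    counts <- integer(n_bins)
    if (length(pos)) {
      iv <- findInterval(pos, m[, "start"])
      inside <- iv >= 1 & pos < m[cbind(pmax(iv, 1), 2)]
      off <- cum[iv[inside]] + (pos[inside] - m[iv[inside], "start"])
      b <- floor(off / 1000) + 1
      b <- b[b <= n_bins]
      if (length(b)) {
        tb <- table(b)
        counts[as.integer(names(tb))] <- as.integer(tb)
      }
    }

    low <- counts < 0.1  # strict: below 10% of 1 het per callable kbp
    r <- rle(low)
    ends_idx <- cumsum(r$lengths)
    starts_idx <- ends_idx - r$lengths + 1
    for (k in which(r$values)) {
      i0 <- starts_idx[k]; i1 <- ends_idx[k]
      span_start <- bin_start[i0]; span_end <- bin_end[i1]
      span <- span_end - span_start
      frac <- (1000 * (i1 - i0 + 1)) / span
      met <- tiers[span > tiers]
      if (length(met) && frac >= min_callable_frac) {
        res[[length(res) + 1]] <- data.frame(
          frag = f, start = span_start, end = span_end, length = span,
          callable_frac = frac, tier = max(met))
      }
    }
  }
  if (!length(res)) {
    return(data.frame(frag = integer(0), start = numeric(0),
                      end = numeric(0), length = numeric(0),
                      callable_frac = numeric(0), tier = numeric(0)))
  }
  do.call(rbind, res)
}

## Block jackknife -----------------------------------------------------------

# Weighted delete-one-block jackknife (delete-m_j) for an estimator theta.
# theta_full: estimate on all data; theta_minus: leave-one-block-out
# estimates; m: per-block weights (e.g. informative sites); n = sum(m).
weighted_block_jackknife <- function(theta_full, theta_minus, m) {
  keep <- m > 0
  theta_minus <- theta_minus[keep]; m <- m[keep]
  g <- length(m)
  if (g < 2) stop("need at least two non-empty blocks")
  n <- sum(m)
  h <- n / m
  theta_j <- g * theta_full - sum((1 - m / n) * theta_minus)
  tau <- h * theta_full - (h - 1) * theta_minus
  var_j <- mean((tau - theta_j)^2 / (h - 1))
  list(est = theta_j, se = sqrt(var_j), n_blocks = g)
}

# assign each fragment to a contiguous genomic block of ~block_size bp
fragment_blocks <- function(frag_lengths, block_size) {
  cum_start <- cumsum(c(0, frag_lengths))[seq_along(frag_lengths)]
  pmin(floor(cum_start / block_size) + 1,
       max(1, ceiling(sum(frag_lengths) / block_size)))
}

## D-statistic ---------------------------------------------------------------

#' ABBA-BABA D-statistic with weighted block jackknife
#'
#' Computes the four-taxon D-statistic from one sampled allele per
#' individual per site (seeded; see [sample_alleles()]). With sampled
#' alleles `w, x, y, o`, a site is ABBA when `w == o`, `x == y`, `w != x`,
#' and BABA when `x == o`, `w == y`, `w != x`;
#' `D = (ABBA - BABA) / (ABBA + BABA)`. The standard error comes from a
#' weighted block jackknife over contiguous genomic blocks (default 5 Mbp),
#' weighted by the informative-site count per block; `Z = D / SE`.
#'
#' @param geno A [genotype_matrix()].
#' @param w,x,y,o Sample labels; `o` may be `"Chimp"`/`"ancestral"` for the
#'   all-ancestral outgroup.
#' @param block_size Jackknife block size in bp.
#' @param seed Seed for allele sampling.
#' @return List with `quartet`, `abba`, `baba`, `D`, `se`, `Z`, `n_blocks`.
#' @export
d_statistic <- function(geno, w, x, y, o = "Chimp", block_size = 5e6,
                        seed = 1) {
  h <- sample_alleles(geno, seed)
  aw <- allele_track(h, geno, w); ax <- allele_track(h, geno, x)
  ay <- allele_track(h, geno, y); ao <- allele_track(h, geno, o)

  abba <- (aw == ao) & (ax == ay) & (aw != ax)
  baba <- (ax == ao) & (aw == ay) & (aw != ax)
  n_abba <- sum(abba); n_baba <- sum(baba)
  tot <- n_abba + n_baba
  if (tot == 0) stop("zero informative sites for quartet (",
                     paste(c(w, x, y, o), collapse = ", "), ")")

  blocks <- fragment_blocks(geno$frag_lengths, block_size)
  site_block <- blocks[geno$sites$frag]
  ab_j <- vapply(split(abba, site_block), sum, numeric(1))
  ba_j <- vapply(split(baba, site_block), sum, numeric(1))
  m <- ab_j + ba_j

  D <- (n_abba - n_baba) / tot
  theta_minus <- ((n_abba - ab_j) - (n_baba - ba_j)) /
    pmax((n_abba - ab_j) + (n_baba - ba_j), 1)
  jk <- weighted_block_jackknife(D, theta_minus, m)
  list(quartet = c(W = w, X = x, Y = y, O = o),
       abba = n_abba, baba = n_baba, D = D, se = jk$se,
       Z = D / jk$se, n_blocks = jk$n_blocks)
}

## f4 and f4-ratio -----------------------------------------------------------

# per-site f4 products and per-block sums for a quartet
f4_sums <- function(h, geno, quartet, site_block) {
  a <- allele_track(h, geno, quartet[1]); b <- allele_track(h, geno, quartet[2])
  c_ <- allele_track(h, geno, quartet[3]); d <- allele_track(h, geno, quartet[4])
  prod <- (a - b) * (c_ - d)
  list(total = sum(prod),
       by_block = vapply(split(prod, site_block), sum, numeric(1)))
}

#' f4 statistic
#'
#' Mean per-site product `(a - b)(c - d)` of sampled alleles for the
#' quartet `(A, B; C, D)`, with a weighted block jackknife SE (weights =
#' sites per block).
#'
#' @param geno A [genotype_matrix()].
#' @param quartet Character vector of four sample labels.
#' @inheritParams d_statistic
#' @return List with `f4`, `se`, `Z`, `n_blocks`.
#' @export
f4_statistic <- function(geno, quartet, block_size = 5e6, seed = 1) {
  h <- sample_alleles(geno, seed)
  blocks <- fragment_blocks(geno$frag_lengths, block_size)
  site_block <- blocks[geno$sites$frag]
  s <- f4_sums(h, geno, quartet, site_block)
  n_sites <- nrow(geno$sites)
  m <- vapply(split(rep(1, n_sites), site_block), sum, numeric(1))
  f4 <- s$total / n_sites
  theta_minus <- (s$total - s$by_block) / (n_sites - m)
  jk <- weighted_block_jackknife(f4, theta_minus, m)
  list(f4 = f4, se = jk$se, Z = f4 / jk$se, n_blocks = jk$n_blocks)
}

#' f4-ratio admixture-proportion estimate
#'
#' Ratio of two f4 statistics, `alpha = f4(num) / f4(den)`, with a
#' weighted block jackknife SE computed on the ratio of delete-one-block
#' estimates. The three published ratio forms are available as presets via
#' [f4_ratio_presets()].
#'
#' @param geno A [genotype_matrix()].
#' @param num,den Quartets (length-4 character vectors) for the numerator
#'   and denominator f4.
#' @inheritParams d_statistic
#' @param min_den_z Error if the denominator's |Z| falls below this
#'   threshold (default 3): the ratio is undefined for a null denominator.
#' @return List with `ratio`, `se`, `num_f4`, `den_f4`, `n_blocks`.
#' @export
f4_ratio <- function(geno, num, den, block_size = 5e6, seed = 1,
                     min_den_z = 0) {
  h <- sample_alleles(geno, seed)
  blocks <- fragment_blocks(geno$frag_lengths, block_size)
  site_block <- blocks[geno$sites$frag]
  sn <- f4_sums(h, geno, num, site_block)
  sd_ <- f4_sums(h, geno, den, site_block)
  n_sites <- nrow(geno$sites)
  if (abs(sd_$total) < .Machine$double.eps * n_sites) {
    stop("denominator f4 is zero for quartet (",
         paste(den, collapse = ", "), ")")
  }
  if (min_den_z > 0) {
    dz <- f4_statistic(geno, den, block_size, seed)
    if (abs(dz$Z) < min_den_z) {
      stop("denominator f4 not significantly nonzero (|Z| = ",
           format(abs(dz$Z), digits = 3), ") for quartet (",
           paste(den, collapse = ", "), ")")
    }
  }
  alpha <- sn$total / sd_$total
  m <- vapply(split(rep(1, n_sites), site_block), sum, numeric(1))
  minus <- (sn$total - sn$by_block) / (sd_$total - sd_$by_block)
  jk <- weighted_block_jackknife(alpha, minus, m)
  list(ratio = alpha, se = jk$se, num_f4 = sn$total / n_sites,
       den_f4 = sd_$total / n_sites, n_blocks = jk$n_blocks,
       num = num, den = den)
}

#' Published f4-ratio quartet forms
#'
#' The three ratio constructions used in the study, expressed with panel
#' labels: Eurasian ancestry in hunter-gatherers
#' (`f4(Han, Yoruba; X, Chimp) / f4(Han, Yoruba; French, Chimp)`),
#' Eurasian ancestry in other African groups
#' (`f4(Sardinian, Han; X, Yoruba) / f4(Sardinian, Han; French, Yoruba)`),
#' and Neanderthal ancestry
#' (`f4(Denisova, Chimp; X, Yoruba) / f4(Denisova, Chimp; Neanderthal,
#' Yoruba)`). Substitute concrete sample labels for the placeholders.
#'
#' @return Named list of `list(num, den)` templates with placeholder `"X"`.
#' @export
f4_ratio_presets <- function() {
  list(
    eurasian_in_huntergatherer = list(
      num = c("Han", "Yoruba", "X", "Chimp"),
      den = c("Han", "Yoruba", "French", "Chimp")),
    eurasian_in_african = list(
      num = c("Sardinian", "Han", "X", "Yoruba"),
      den = c("Sardinian", "Han", "French", "Yoruba")),
    neanderthal_in_african = list(
      num = c("Denisova", "Chimp", "X", "Yoruba"),
      den = c("Denisova", "Chimp", "Neanderthal", "Yoruba"))
  )
}
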