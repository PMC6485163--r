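## Joint site frequency spectrum ---------------------------------------------

#' Compute the multidimensional unfolded joint SFS
#'
#' Tallies every polymorphic, polarized site of a [genotype_matrix()] into a
#' k-dimensional tensor with one axis of length 3 (derived-allele dosage
#' 0/1/2) per diploid sample. The two monomorphic corner cells (all samples
#' dosage 0, or all dosage 2) are excluded from the tally: they carry no
#' polymorphism information and, on real data, are dominated by callable
#' genome length.
#'
#' @param geno A [genotype_matrix()].
#' @param axis_order Sample labels defining the axis order; defaults to the
#'   canonical panel order intersected with the available samples.
#' @return An object of class `joint_sfs`: list with `counts` (array),
#'   `n_sites`, `normalized`, `axes`, and `n_skipped` (corner-cell sites).
#' @export
compute_jsfs <- function(geno, axis_order = NULL) {
  if (is.null(axis_order)) {
    axis_order <- intersect(panel_populations(), geno$samples)
    if (!length(axis_order)) axis_order <- geno$samples
  }
  missing <- setdiff(axis_order, geno$samples)
  if (length(missing)) {
    stop("missing sample(s): ", paste(missing, collapse = ", "))
  }
  k <- length(axis_order)
  g <- geno$geno[, axis_order, drop = FALSE]
  counts <- array(0, dim = rep(3L, k))
  n_skipped <- 0L
  if (nrow(g)) {
    code <- as.vector(g %*% 3^(seq_len(k) - 1))  # axis 1 fastest
    corner <- code == 0L | code == 3^k - 1L
    n_skipped <- sum(corner)
    code <- code[!corner]
    tab <- tabulate(code + 1L, nbins = 3^k)
    counts <- array(as.numeric(tab), dim = rep(3L, k))
  }
  structure(list(counts = counts, n_sites = as.numeric(sum(counts)),
                 normalized = FALSE, axes = axis_order,
                 n_skipped = n_skipped),
            class = "joint_sfs")
}

#' @export
print.joint_sfs <- function(x, ...) {
  cat("joint_sfs over (", paste(x$axes, collapse = ", "), "): ",
      x$n_sites, " sites", if (x$normalized) " (normalized)", "\n", sep = "")
  invisible(x)
}

#' Normalize a joint SFS to proportions
#'
#' Entries sum to one over the included cells; idempotent.
#' @param jsfs A `joint_sfs`.
#' @return A normalized `joint_sfs`.
#' @export
normalize_jsfs <- function(jsfs) {
  if (jsfs$normalized) return(jsfs)
  if (jsfs$n_sites <= 0) stop("cannot normalize an empty spectrum")
  jsfs$counts <- jsfs$counts / sum(jsfs$counts)
  jsfs$normalized <- TRUE
  jsfs
}

#' Flatten a joint SFS into a numeric vector
#' @param jsfs A `joint_sfs`.
#' @export
flatten_jsfs <- function(jsfs) as.vector(jsfs$counts)

# Mixture-resampling core: draw a multinomial sample of size n from the
# blend (1-lambda) p_sim + lambda p_noise of two count/probability vectors.
mix_resample <- function(sim_counts, noise_counts, lambda, n) {
  if (length(sim_counts) != length(noise_counts)) {
    stop("axis mismatch between simulated and noise spectra")
  }
  if (lambda < 0 || lambda > 1) stop("lambda must be in [0,1]")
  p_sim <- sim_counts / sum(sim_counts)
  p_noise <- noise_counts / sum(noise_counts)
  p <- (1 - lambda) * p_sim + lambda * p_noise
  as.vector(rmultinom(1, size = n, prob = p))
}

#' Inject observed-spectrum noise into a simulated joint SFS
#'
#' Implements noise injection as multinomial resampling from the mixture
#' `(1 - lambda) * p_sim + lambda * p_noise` of the two normalized spectra.
#' The result has exactly `n_resample` sites. This mixture-resampling
#' scheme is this package's documented interpretation of jSFS noise
#' injection (the mechanism is configurable through `lambda` and
#' `n_resample`).
#'
#' @param sim Simulated `joint_sfs`.
#' @param noise_source Noise `joint_sfs` (same axes).
#' @param lambda Mixture weight of the noise spectrum in `[0, 1]`
#'   (default 0.5).
#' @param n_resample Total sites in the output (default: `sim$n_sites`).
#' @param seed Optional seed.
#' @return A `joint_sfs` of counts with `n_sites = n_resample`.
#' @export
inject_noise <- function(sim, noise_source, lambda = 0.5,
                         n_resample = sim$n_sites, seed = NULL) {
  if (!identical(sim$axes, noise_source$axes)) {
    stop("axis mismatch between simulated and noise spectra")
  }
  counts <- with_seed(seed, mix_resample(as.vector(sim$counts),
                                         as.vector(noise_source$counts),
                                         lambda, n_resample))
  out <- sim
  out$counts <- array(as.numeric(counts), dim = dim(sim$counts))
  out$n_sites <- as.numeric(sum(counts))
  out$normalized <- FALSE
  out
}

#' Write / read a joint SFS as a flat TSV table
#'
#' One row per non-zero cell: the dosage index of every axis plus the
#' count. The axis order is recorded in a header comment line.
#'
#' @param jsfs A `joint_sfs`.
#' @param path File path.
#' @export
write_jsfs_tsv <- function(jsfs, path) {
  k <- length(jsfs$axes)
  nz <- which(jsfs$counts != 0)
  idx <- arrayInd(nz, dim(jsfs$counts)) - 1L
  colnames(idx) <- jsfs$axes
  df <- cbind(as.data.frame(idx), count = jsfs$counts[nz])
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# axes: ", paste(jsfs$axes, collapse = ",")), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_jsfs_tsv
#' @export
read_jsfs_tsv <- function(path) {
  header <- readLines(path, n = 1)
  axes <- strsplit(sub("^# axes: ", "", header), ",")[[1]]
  df <- read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                   check.names = FALSE)
  k <- length(axes)
  counts <- array(0, dim = rep(3L, k))
  idx <- as.matrix(df[, axes, drop = FALSE]) + 1L
  counts[idx] <- df$count
  structure(list(counts = counts, n_sites = sum(counts),
                 normalized = !all(counts == floor(counts)) ||
                   abs(sum(counts) - 1) < 1e-9,
                 axes = axes, n_skipped = 0L),
            class = "joint_sfs")
}
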