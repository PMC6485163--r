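## VCF / BED interfaces ------------------------------------------------------
##
## Coordinate conventions, stated once and enforced by tests: internal
## coordinates are 0-based half-open; VCF is 1-based at the boundary; BED is
## native 0-based half-open. Fragments map to pseudo-contigs "frag<N>".

frag_contig <- function(frag) paste0("frag", frag)
contig_frag <- function(contig) as.integer(sub("^frag", "", contig))

#' Write a genotype matrix as VCF (plus BED callable mask)
#'
#' One pseudo-contig per fragment, 1-based positions, ancestral allele in
#' `INFO/AA` (always the REF allele: simulated sites are polarized). Plain
#' uncompressed text.
#'
#' @param geno A [genotype_matrix()].
#' @param vcf_path Output VCF path.
#' @param bed_path Optional BED path for the callable mask.
#' @return `vcf_path`, invisibly.
#' @export
write_vcf <- function(geno, vcf_path, bed_path = NULL) {
  con <- file(vcf_path, "w")
  on.exit(close(con))
  writeLines("##fileformat=VCFv4.2", con)
  writeLines(sprintf("##contig=<ID=%s,length=%d>",
                     frag_contig(seq_along(geno$frag_lengths)),
                     as.integer(geno$frag_lengths)), con)
  writeLines("##INFO=<ID=AA,Number=1,Type=String,Description=\"Ancestral allele\">", con)
  writeLines("##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">", con)
  writeLines(paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", geno$samples), collapse = "\t"), con)
  if (nrow(geno$sites)) {
    gt <- matrix(c("0/0", "0/1", "1/1")[geno$geno + 1L],
                 nrow = nrow(geno$geno))
    lines <- paste(frag_contig(geno$sites$frag), geno$sites$pos + 1L, ".",
                   "A", "T", ".", "PASS", "AA=A", "GT",
                   apply(gt, 1, paste, collapse = "\t"), sep = "\t")
    writeLines(lines, con)
  }
  if (!is.null(bed_path)) write_bed_mask(geno$mask, bed_path)
  invisible(vcf_path)
}

#' Read a VCF into a genotype matrix
#'
#' Positions are converted from 1-based VCF to the 0-based internal
#' convention. Sites outside the callable mask and multi-allelic records
#' are dropped, with counts reported in the `log` attribute. Genotypes are
#' polarized by `INFO/AA` when present (records whose AA matches neither
#' allele are dropped and counted); without an AA field the REF allele is
#' taken as ancestral.
#'
#' @param path VCF path (uncompressed or gzipped; parsed with the vcfR
#'   package).
#' @param samples Sample names to load (default: all).
#' @param mask Optional callable mask `data.frame(frag, start, end)`; also
#'   accepted as a BED file path.
#' @param frag_lengths Optional named fragment lengths; inferred from
#'   `##contig` headers when absent.
#' @return A [genotype_matrix()] with attribute `log` (dropped-site
#'   counts).
#' @export
read_vcf <- function(path, samples = NULL, mask = NULL,
                     frag_lengths = NULL) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop("the vcfR package is required to read VCF files")
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v, getINFO = TRUE)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  meta <- v@meta
  if (is.null(frag_lengths)) {
    cl <- regmatches(meta, regexec("##contig=<ID=([^,>]+),length=([0-9]+)",
                                   meta))
    cl <- cl[vapply(cl, length, integer(1)) == 3]
    if (length(cl)) {
      ids <- vapply(cl, `[`, "", 2)
      lens <- as.numeric(vapply(cl, `[`, "", 3))
      frag_lengths <- lens[order(contig_frag(ids))]
    } else stop("fragment lengths not given and no ##contig headers found")
  }
  gt <- vcfR::extract.gt(v)
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = 1,
                                     dimnames = list(NULL, names(gt)))
  if (is.null(samples)) samples <- colnames(gt)
  missing <- setdiff(samples, colnames(gt))
  if (length(missing)) {
    stop("missing sample(s) in VCF: ", paste(missing, collapse = ", "))
  }
  gt <- gt[, samples, drop = FALSE]

  frag <- contig_frag(fix[, "CHROM"])
  pos <- as.integer(fix[, "POS"]) - 1L  # VCF 1-based -> internal 0-based
  alt <- fix[, "ALT"]
  ref <- fix[, "REF"]

  multi <- grepl(",", alt)
  n_multi <- sum(multi)

  info <- fix[, "INFO"]
  aa <- rep(NA_character_, length(info))
  has_aa <- grepl("(^|;)AA=", info)
  aa[has_aa] <- sub(".*(^|;)AA=([^;]+).*", "\\2", info[has_aa])

  dose <- matrix(NA_integer_, nrow(gt), ncol(gt),
                 dimnames = list(NULL, samples))
  for (j in seq_len(ncol(gt))) {
    g <- gt[, j]
    d <- rep(NA_integer_, length(g))
    d[g %in% c("0/0", "0|0")] <- 0L
    d[g %in% c("0/1", "1/0", "0|1", "1|0")] <- 1L
    d[g %in% c("1/1", "1|1")] <- 2L
    dose[, j] <- d
  }
  bad_gt <- apply(dose, 1, function(r) any(is.na(r)))

  # polarization: flip dosages where the ALT allele is ancestral
  unpol <- rep(FALSE, length(aa))
  flip <- rep(FALSE, length(aa))
  idx_aa <- which(has_aa & !multi)
  flip[idx_aa] <- aa[idx_aa] == alt[idx_aa]
  unpol[idx_aa] <- aa[idx_aa] != ref[idx_aa] & aa[idx_aa] != alt[idx_aa]

  if (is.character(mask) && length(mask) == 1) mask <- read_bed_mask(mask)
  masked <- rep(FALSE, length(pos))
  if (!is.null(mask)) {
    for (i in seq_along(pos)) {
      mm <- mask[mask$frag == frag[i], , drop = FALSE]
      masked[i] <- !any(pos[i] >= mm$start & pos[i] < mm$end)
    }
  }

  keep <- !multi & !unpol & !masked & !bad_gt
  dose <- dose[keep, , drop = FALSE]
  dose[flip[keep], ] <- 2L - dose[flip[keep], ]

  gm <- genotype_matrix(
    sites = data.frame(frag = frag[keep], pos = pos[keep]),
    geno = dose, frag_lengths = frag_lengths, mask = mask)
  attr(gm, "log") <- list(n_multiallelic = n_multi, n_masked = sum(masked),
                          n_unpolarized = sum(unpol),
                          n_bad_genotype = sum(bad_gt & !multi))
  gm
}

#' Read a BED callable mask
#'
#' BED is 0-based half-open. Overlapping intervals are merged per contig
#' and the total callable length is attached as attribute
#' `callable_length`.
#'
#' @param path BED file path (contig, start, end; tab-separated).
#' @return `data.frame(frag, start, end)`.
#' @export
read_bed_mask <- function(path) {
  if (file.size(path) == 0) {
    out <- data.frame(frag = integer(0), start = numeric(0), end = numeric(0))
    attr(out, "callable_length") <- 0
    return(out)
  }
  bed <- read.table(path, header = FALSE, sep = "\t",
                    col.names = c("contig", "start", "end"),
                    colClasses = c("character", "numeric", "numeric"))
  if (any(bed$end <= bed$start)) stop("BED interval with end <= start")
  frag <- contig_frag(bed$contig)
  out <- do.call(rbind, lapply(sort(unique(frag)), function(f) {
    m <- merge_intervals(bed$start[frag == f], bed$end[frag == f])
    data.frame(frag = f, start = m[, "start"], end = m[, "end"])
  }))
  rownames(out) <- NULL
  attr(out, "callable_length") <- sum(out$end - out$start)
  out
}

#' @rdname read_bed_mask
#' @param mask `data.frame(frag, start, end)`.
#' @param path Output path.
#' @export
write_bed_mask <- function(mask, path) {
  df <- data.frame(contig = frag_contig(mask$frag),
                   start = format(mask$start, scientific = FALSE, trim = TRUE),
                   end = format(mask$end, scientific = FALSE, trim = TRUE))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}
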