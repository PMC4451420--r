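#' Call-rate quality control
#'
#' Drops low-call-rate samples first, then low-call-rate SNPs computed on
#' the remaining samples — the order matters and is fixed. A sample or
#' SNP is kept when its call rate is greater than or equal to the
#' threshold.
#'
#' @param ds a [genotype_dataset()].
#' @param sample_min minimum per-sample call rate in (0, 1], default 0.95.
#' @param snp_min minimum per-SNP call rate in (0, 1], default 0.95.
#' @return a filtered `genotype_dataset`; the input is not modified.
#' @export
filter_call_rate <- function(ds, sample_min = 0.95, snp_min = 0.95) {
  stopifnot(inherits(ds, "genotype_dataset"),
            sample_min > 0, sample_min <= 1,
            snp_min > 0, snp_min <= 1)
  sample_cr <- rowMeans(!is.na(ds$calls))
  keep_s <- ds$samples[sample_cr >= sample_min]
  if (!length(keep_s))
    stop("all samples filtered at call rate >= ", sample_min)
  g <- ds$calls[keep_s, , drop = FALSE]
  snp_cr <- colMeans(!is.na(g))
  keep_v <- which(snp_cr >= snp_min)
  if (!length(keep_v))
    stop("all SNPs filtered at call rate >= ", snp_min)
  subset_genotypes(ds, samples = keep_s, variants = keep_v)
}

#' Per-variant minor allele frequency
#'
#' MAF = min(p, 1 - p) over non-missing calls of the given samples.
#' Variants with all calls missing get `NA`, not 0.
#'
#' @param ds a [genotype_dataset()].
#' @param subset sample ids to use (default all).
#' @return numeric vector of MAF per variant.
#' @export
minor_allele_freq <- function(ds, subset = NULL) {
  p <- allele_freqs(ds, subset)
  pmin(p, 1 - p)
}

#' Squared genotype correlation between variant columns
#'
#' Composite (unphased) r^2 from the Pearson correlation of 0/1/2
#' genotype codes, pairwise-complete over missing data. Used by LD
#' pruning, which runs before phasing.
#'
#' @param g genotype matrix (samples x variants).
#' @return symmetric matrix of r^2 values; `NA` where a variant is
#'   monomorphic among the complete pairs.
#' @keywords internal
genotype_r2 <- function(g) {
  suppressWarnings(stats::cor(g, use = "pairwise.complete.obs"))^2
}

#' Sliding-window LD pruning
#'
#' Removes variants with MAF below `maf_min`, then slides a window of
#' `window_snps` variants advancing `step_snps` at a time along each
#' chromosome; within a window, for every pair with genotype r^2 above
#' `r2_max` the later-positioned variant is removed (the earlier one is
#' kept). Deterministic given the input order.
#'
#' @param ds a [genotype_dataset()].
#' @param window_snps window size in SNPs, default 50.
#' @param step_snps step size in SNPs, default 10.
#' @param r2_max maximum tolerated r^2, default 0.1.
#' @param maf_min minimum MAF, default 0.01.
#' @return the pruned `genotype_dataset`.
#' @export
ld_prune <- function(ds, window_snps = 50, step_snps = 10,
                     r2_max = 0.1, maf_min = 0.01) {
  stopifnot(inherits(ds, "genotype_dataset"),
            window_snps > step_snps, step_snps > 0)
  maf <- minor_allele_freq(ds)
  keep <- !is.na(maf) & maf >= maf_min
  idx <- which(keep)
  if (!length(idx)) stop("all variants filtered at MAF >= ", maf_min)
  chrom <- ds$variants$chrom[idx]
  alive <- rep(TRUE, length(idx))
  for (ch in unique(chrom)) {
    pos_in_idx <- which(chrom == ch)
    nn <- length(pos_in_idx)
    starts <- unique(c(seq(1L, max(nn - 1L, 1L), by = step_snps)))
    for (s in starts) {
      w <- pos_in_idx[s:min(s + window_snps - 1L, nn)]
      w <- w[alive[w]]
      if (length(w) < 2L) next
      r2 <- genotype_r2(ds$calls[, idx[w], drop = FALSE])
      for (a in seq_len(length(w) - 1L)) {
        if (!alive[w[a]]) next
        for (b in seq((a + 1L), length(w))) {
          if (!alive[w[b]]) next
          if (!is.na(r2[a, b]) && r2[a, b] > r2_max) alive[w[b]] <- FALSE
        }
      }
    }
  }
  subset_genotypes(ds, variants = idx[alive])
}
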