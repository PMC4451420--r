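#' Construct a genotype dataset
#'
#' The central container of the pipeline: diploid genotypes for a set of
#' samples at a set of mapped SNPs, together with a population label per
#' sample. Genotypes are coded as counts of the alternate allele
#' (0, 1, 2) with `NA` for missing calls; the alternate allele is the
#' second allele listed in the variant map, following the PLINK
#' convention.
#'
#' @param calls integer matrix, samples in rows, variants in columns;
#'   entries in `{0, 1, 2, NA}`.
#' @param variants data frame with columns `id`, `chrom`, `pos_bp`,
#'   `allele_ref`, `allele_alt`; one row per column of `calls`.
#'   Must be sorted by `(chrom, pos_bp)`; `genotype_dataset()` sorts and
#'   permutes `calls` accordingly if it is not.
#' @param samples character vector of sample ids, one per row of `calls`.
#' @param populations named character vector mapping every sample id to a
#'   population label.
#' @return an object of class `genotype_dataset` with fields `calls`,
#'   `variants`, `samples`, `populations`.
#' @examples
#' ds <- genotype_dataset(
#'   calls = rbind(c(0L, 1L), c(2L, NA)),
#'   variants = data.frame(id = c("s1", "s2"), chrom = "1",
#'                         pos_bp = c(100L, 200L),
#'                         allele_ref = "A", allele_alt = "B"),
#'   samples = c("ind1", "ind2"),
#'   populations = c(ind1 = "popA", ind2 = "popA"))
#' ds
#' @export
genotype_dataset <- function(calls, variants, samples, populations) {
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  variants <- validate_variants(variants)
  if (nrow(variants) != ncol(calls))
    stop("variants rows (", nrow(variants), ") != calls columns (",
         ncol(calls), ")")
  if (length(samples) != nrow(calls))
    stop("samples length (", length(samples), ") != calls rows (",
         nrow(calls), ")")
  if (anyDuplicated(samples))
    stop("duplicated sample ids")
  miss <- setdiff(samples, names(populations))
  if (length(miss))
    stop("samples missing a population label: ",
         paste(utils::head(miss, 5), collapse = ", "))
  bad <- calls[!is.na(calls) & !(calls %in% 0:2)]
  if (length(bad))
    stop("genotype codes outside {0,1,2,NA}: ", paste(unique(bad), collapse = ", "))
  ord <- order_variants(variants)
  if (!identical(ord, seq_len(nrow(variants)))) {
    variants <- variants[ord, , drop = FALSE]
    rownames(variants) <- NULL
    calls <- calls[, ord, drop = FALSE]
  }
  dimnames(calls) <- list(samples, variants$id)
  structure(list(calls = calls,
                 variants = variants,
                 samples = as.character(samples),
                 populations = populations[samples]),
            class = "genotype_dataset")
}

validate_variants <- function(variants) {
  variants <- as.data.frame(variants, stringsAsFactors = FALSE)
  need <- c("id", "chrom", "pos_bp", "allele_ref", "allele_alt")
  miss <- setdiff(need, names(variants))
  if (length(miss))
    stop("variant table lacks columns: ", paste(miss, collapse = ", "))
  variants$id <- as.character(variants$id)
  variants$chrom <- as.character(variants$chrom)
  variants$pos_bp <- as.integer(variants$pos_bp)
  if (any(variants$pos_bp < 1L))
    stop("variant positions must be >= 1")
  if (any(variants$allele_ref == variants$allele_alt))
    stop("reference and alternate allele identical for variant ",
         variants$id[which(variants$allele_ref == variants$allele_alt)[1]])
  key <- paste(variants$chrom, variants$pos_bp)
  if (anyDuplicated(key))
    stop("duplicated (chrom, pos) at ", key[anyDuplicated(key)])
  variants
}

order_variants <- function(variants) order(variants$chrom, variants$pos_bp)

#' @export
print.genotype_dataset <- function(x, ...) {
  cat("genotype_dataset:", length(x$samples), "samples x",
      nrow(x$variants), "variants\n")
  cat("  chromosomes:", paste(unique(x$variants$chrom), collapse = ", "), "\n")
  tab <- table(x$populations)
  cat("  populations:",
      paste(sprintf("%s (%d)", names(tab), tab), collapse = ", "), "\n")
  miss <- mean(is.na(x$calls))
  cat(sprintf("  missing calls: %.2f%%\n", 100 * miss))
  invisible(x)
}

#' Subset a genotype dataset
#'
#' @param ds a `genotype_dataset`.
#' @param samples optional character vector of sample ids to keep.
#' @param variants optional logical/integer index over variants to keep.
#' @return a new `genotype_dataset`; the input is not modified.
#' @export
subset_genotypes <- function(ds, samples = NULL, variants = NULL) {
  stopifnot(inherits(ds, "genotype_dataset"))
  keep_s <- if (is.null(samples)) ds$samples else {
    unknown <- setdiff(samples, ds$samples)
    if (length(unknown)) stop("unknown sample ids: ",
                              paste(utils::head(unknown, 5), collapse = ", "))
    samples
  }
  keep_v <- if (is.null(variants)) seq_len(nrow(ds$variants)) else variants
  genotype_dataset(ds$calls[keep_s, keep_v, drop = FALSE],
                   ds$variants[keep_v, , drop = FALSE],
                   keep_s, ds$populations)
}

#' Sample ids belonging to a population
#' @param ds a `genotype_dataset`.
#' @param population population label.
#' @return character vector of sample ids.
#' @export
population_samples <- function(ds, population) {
  stopifnot(inherits(ds, "genotype_dataset"))
  ids <- ds$samples[ds$populations == population]
  if (!length(ids)) stop("no samples in population '", population, "'")
  ids
}

#' Per-variant alternate-allele frequencies
#'
#' Frequencies of the alternate allele computed over non-missing calls of
#' the given samples. Variants with no non-missing call get `NA`.
#'
#' @param ds a `genotype_dataset`.
#' @param subset sample ids to use (default all samples).
#' @return numeric vector, one frequency per variant.
#' @export
allele_freqs <- function(ds, subset = NULL) {
  stopifnot(inherits(ds, "genotype_dataset"))
  if (is.null(subset)) subset <- ds$samples
  unknown <- setdiff(subset, ds$samples)
  if (length(unknown)) stop("unknown sample ids: ",
                            paste(utils::head(unknown, 5), collapse = ", "))
  g <- ds$calls[subset, , drop = FALSE]
  n_called <- colSums(!is.na(g))
  alt <- colSums(g, na.rm = TRUE)
  ifelse(n_called > 0, alt / (2 * n_called), NA_real_)
}

#' Construct a phased haplotype set
#'
#' Phased 0/1 alleles with haplotypes in rows (rows `2i - 1` and `2i` are
#' the two chromosome copies of sample `i`) and variants in columns.
#' Haplotype sets carry no missing data.
#'
#' @param haplotypes integer matrix of 0/1 alleles, one haplotype per row;
#'   row count must be even.
#' @param variants variant map as in [genotype_dataset()].
#' @param samples optional sample ids (length `nrow(haplotypes) / 2`).
#' @return an object of class `haplotype_set`.
#' @export
haplotype_set <- function(haplotypes, variants, samples = NULL) {
  haplotypes <- as.matrix(haplotypes)
  storage.mode(haplotypes) <- "integer"
  if (nrow(haplotypes) %% 2L != 0L)
    stop("haplotype row count must be even (two copies per sample)")
  if (anyNA(haplotypes) || !all(haplotypes %in% 0:1))
    stop("haplotype alleles must be 0/1 with no missing values")
  variants <- validate_variants(variants)
  ord <- order_variants(variants)
  if (!identical(ord, seq_len(nrow(variants)))) {
    variants <- variants[ord, , drop = FALSE]
    rownames(variants) <- NULL
    haplotypes <- haplotypes[, ord, drop = FALSE]
  }
  if (nrow(variants) != ncol(haplotypes))
    stop("variants rows != haplotype columns")
  if (is.null(samples))
    samples <- paste0("sample", seq_len(nrow(haplotypes) / 2L))
  structure(list(haplotypes = haplotypes, variants = variants,
                 samples = as.character(samples)),
            class = "haplotype_set")
}

#' @export
print.haplotype_set <- function(x, ...) {
  cat("haplotype_set:", nrow(x$haplotypes), "haplotypes x",
      nrow(x$variants), "variants;",
      length(unique(x$variants$chrom)), "chromosome(s)\n")
  invisible(x)
}

#' Collapse phased haplotypes to diploid genotypes
#'
#' @param hapset a `haplotype_set`.
#' @param population label assigned to every sample.
#' @return a `genotype_dataset` with no missing calls.
#' @export
haplotypes_to_genotypes <- function(hapset, population = "pop1") {
  stopifnot(inherits(hapset, "haplotype_set"))
  h <- hapset$haplotypes
  n <- nrow(h) / 2L
  calls <- h[seq(1L, 2L * n, by = 2L), , drop = FALSE] +
    h[seq(2L, 2L * n, by = 2L), , drop = FALSE]
  pops <- stats::setNames(rep(population, n), hapset$samples)
  genotype_dataset(calls, hapset$variants, hapset$samples, pops)
}
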