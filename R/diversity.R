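#' Observed heterozygosity of a population
#'
#' Mean over variants of the fraction of heterozygous calls among
#' non-missing calls; variants with no non-missing call in the
#' population are excluded from the mean.
#'
#' @param ds a [genotype_dataset()].
#' @param population population label.
#' @return observed heterozygosity in `[0, 1]`.
#' @export
observed_het <- function(ds, population) {
  g <- ds$calls[population_samples(ds, population), , drop = FALSE]
  n_called <- colSums(!is.na(g))
  het <- colSums(g == 1L, na.rm = TRUE)
  keep <- n_called > 0
  if (!any(keep)) stop("no called variants in population '", population, "'")
  mean(het[keep] / n_called[keep])
}

#' Nei's unbiased expected heterozygosity of a population
#'
#' Per variant with `k` allele copies called and alternate frequency
#' `p`, the small-sample-corrected gene diversity
#' `(k / (k - 1)) * (1 - p^2 - (1 - p)^2)` (Nei 1978); the population
#' value is the mean over variants. Variants with fewer than two called
#' diploids are excluded; monomorphic variants contribute 0 and are
#' retained, since an array panel is fixed across populations.
#'
#' @inheritParams observed_het
#' @return unbiased expected heterozygosity in `[0, 1]`.
#' @export
expected_het_unbiased <- function(ds, population) {
  g <- ds$calls[population_samples(ds, population), , drop = FALSE]
  n_called <- colSums(!is.na(g))
  keep <- n_called >= 2L
  if (!any(keep)) stop("no variant with >= 2 calls in '", population, "'")
  k <- 2 * n_called[keep]
  p <- colSums(g[, keep, drop = FALSE], na.rm = TRUE) / k
  he <- (k / (k - 1)) * (1 - p^2 - (1 - p)^2)
  mean(he)
}

#' Inbreeding coefficient from heterozygosities
#'
#' `F_IS = 1 - Ho / He`; `NA` when `He` is zero.
#'
#' @param ho observed heterozygosity.
#' @param he expected heterozygosity.
#' @return the inbreeding coefficient, or `NA` if undefined.
#' @export
fis <- function(ho, he) {
  ifelse(he > 0, 1 - ho / he, NA_real_)
}

#' Welch's unequal-variance t-test
#'
#' Two-sided Welch t-test with Welch-Satterthwaite degrees of freedom,
#' as used for group comparisons of per-breed statistics.
#'
#' @param group_a,group_b numeric vectors (each >= 2 values with nonzero
#'   variance).
#' @return list with `t`, `df`, `p`.
#' @export
welch_test <- function(group_a, group_b) {
  stopifnot(length(group_a) >= 2, length(group_b) >= 2)
  if (stats::var(group_a) == 0 && stats::var(group_b) == 0)
    stop("both groups have zero variance")
  fit <- stats::t.test(group_a, group_b, var.equal = FALSE)
  list(t = unname(fit$statistic), df = unname(fit$parameter),
       p = fit$p.value)
}

#' Per-population diversity summary
#'
#' One row per population, in the input's population order: sample
#' size, observed heterozygosity, unbiased expected heterozygosity, and
#' F_IS computed from the multilocus means (`1 - mean(Ho) / mean(He)`).
#'
#' @param ds a [genotype_dataset()].
#' @param min_n drop populations with fewer diploids than this
#'   (default 1 keeps everything; group comparisons are commonly
#'   rechecked at `min_n = 20`).
#' @return data frame with columns `population`, `n`, `ho`, `he`, `fis`,
#'   and `fis_panel` — the same coefficient computed against the mean
#'   He across the reported populations, since published per-breed F
#'   values are sometimes quoted against a panel-wide He.
#' @export
diversity_table <- function(ds, min_n = 1) {
  stopifnot(inherits(ds, "genotype_dataset"))
  pops <- unique(unname(ds$populations))
  rows <- lapply(pops, function(pp) {
    n <- sum(ds$populations == pp)
    if (n < min_n) return(NULL)
    ho <- observed_het(ds, pp)
    he <- expected_het_unbiased(ds, pp)
    data.frame(population = pp, n = n, ho = ho, he = he,
               fis = fis(ho, he), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) return(NULL)
  out$fis_panel <- fis(out$ho, mean(out$he))
  rownames(out) <- NULL
  out
}
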