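#' Hill-Robertson r-squared between two variants from phased haplotypes
#'
#' With haplotype frequency `p_AB` and allele frequencies `p_A`, `p_B`,
#' `D = p_AB - p_A p_B` and
#' `r^2 = D^2 / (p_A (1 - p_A) p_B (1 - p_B))`. `NA` when either
#' variant is monomorphic in the haplotype sample.
#'
#' @param hapset a [haplotype_set()].
#' @param i,j variant indices (columns).
#' @return r-squared in `[0, 1]`, or `NA` if undefined.
#' @export
haplotype_r2 <- function(hapset, i, j) {
  a <- hapset$haplotypes[, i]
  b <- hapset$haplotypes[, j]
  pa <- mean(a)
  pb <- mean(b)
  if (pa %in% c(0, 1) || pb %in% c(0, 1)) return(NA_real_)
  d <- mean(a * b) - pa * pb
  d^2 / (pa * (1 - pa) * pb * (1 - pb))
}

#' Collect pairwise LD estimates by physical distance
#'
#' All within-chromosome variant pairs separated by `min_bp` to `max_bp`
#' (inclusive) whose minor allele frequencies are both at least
#' `maf_min`; monomorphic loci never enter (haplotype sets carry no
#' missing data — loci with missing data must be excluded upstream).
#'
#' @param hapset a [haplotype_set()] (may span several chromosomes).
#' @param min_bp minimum pair distance, default 5000.
#' @param max_bp maximum pair distance, default 1e6.
#' @param maf_min minimum within-sample MAF, default 0.05.
#' @return data frame with columns `dist_bp`, `r2`.
#' @export
collect_ld_pairs <- function(hapset, min_bp = 5000, max_bp = 1e6,
                             maf_min = 0.05) {
  stopifnot(inherits(hapset, "haplotype_set"))
  p <- colMeans(hapset$haplotypes)
  maf <- pmin(p, 1 - p)
  out_d <- list()
  out_r <- list()
  for (ch in unique(hapset$variants$chrom)) {
    idx <- which(hapset$variants$chrom == ch & maf >= maf_min)
    if (length(idx) < 2L) next
    pos <- hapset$variants$pos_bp[idx]
    h <- hapset$haplotypes[, idx, drop = FALSE]
    pj <- p[idx]
    denom <- pj * (1 - pj)
    n_hap <- nrow(h)
    for (a in seq_len(length(idx) - 1L)) {
      b <- which(pos - pos[a] >= min_bp & pos - pos[a] <= max_bp)
      b <- b[b > a]
      if (!length(b)) next
      pab <- as.vector(crossprod(h[, a], h[, b, drop = FALSE])) / n_hap
      d <- pab - pj[a] * pj[b]
      out_d[[length(out_d) + 1L]] <- pos[b] - pos[a]
      out_r[[length(out_r) + 1L]] <- d^2 / (denom[a] * denom[b])
    }
  }
  data.frame(dist_bp = as.integer(unlist(out_d)),
             r2 = as.numeric(unlist(out_r)))
}

#' Equal-count distance bins of LD pairs
#'
#' Orders pairs by distance (stable) and slices them into `n_bins`
#' contiguous bins whose sizes differ by at most one, the direct
#' analogue of binning at empirical distance quantiles. Each bin
#' reports the arithmetic means of member distances and r-squared
#' values. If every pair sits at a single distance the result is one
#' degenerate bin flagged by the `degenerate` attribute.
#'
#' @param pairs data frame from [collect_ld_pairs()].
#' @param n_bins number of bins, default 30.
#' @return data frame with columns `mean_dist_bp`, `mean_r2`, `n_pairs`,
#'   sorted by distance.
#' @export
bin_equal_count <- function(pairs, n_bins = 30) {
  n <- nrow(pairs)
  if (length(unique(pairs$dist_bp)) == 1L) {
    out <- data.frame(mean_dist_bp = mean(pairs$dist_bp),
                      mean_r2 = mean(pairs$r2), n_pairs = n)
    attr(out, "degenerate") <- TRUE
    warning("all LD pairs at a single distance; returning one bin")
    return(out)
  }
  if (n < n_bins)
    stop("fewer pairs (", n, ") than bins (", n_bins, ")")
  ord <- order(pairs$dist_bp)   # stable
  sizes <- rep(n %/% n_bins, n_bins)
  extra <- n %% n_bins
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  stop_at <- cumsum(sizes)
  start_at <- c(1L, utils::head(stop_at, -1L) + 1L)
  out <- do.call(rbind, lapply(seq_len(n_bins), function(b) {
    members <- ord[start_at[b]:stop_at[b]]
    data.frame(mean_dist_bp = mean(pairs$dist_bp[members]),
               mean_r2 = mean(pairs$r2[members]),
               n_pairs = length(members))
  }))
  attr(out, "degenerate") <- FALSE
  out
}

#' Sved's LD-based effective population size estimator
#'
#' `N_t = (1 / (4 f(c))) * (1 / r^2 - 1)`, interpreted as the effective
#' size `t = 1 / (2 c)` generations ago. The default mapping is
#' `f(c) = c`; the `sved_paper` mapping uses
#' `f(c) = c (1 - c/2) / (1 - 2c)^2`, which agrees with the linear form
#' to under 0.5\% for small `c`.
#'
#' @param mean_r2 mean r-squared of a bin, in (0, 1].
#' @param c recombination fraction in Morgans, > 0.
#' @param mapping `"linear"` or `"sved_paper"`.
#' @return the Ne estimate (`Inf` when `mean_r2` is 0).
#' @export
sved_ne <- function(mean_r2, c, mapping = c("linear", "sved_paper")) {
  mapping <- match.arg(mapping)
  stopifnot(all(c > 0), all(mean_r2 >= 0), all(mean_r2 <= 1))
  fc <- switch(mapping,
               linear = c,
               sved_paper = c * (1 - c / 2) / (1 - 2 * c)^2)
  ifelse(mean_r2 == 0, Inf, (1 / (4 * fc)) * (1 / mean_r2 - 1))
}

#' Generations ago probed by a recombination fraction
#'
#' Under the LD-based estimator, the mean r-squared at recombination
#' fraction `c` reflects the effective size about `t = 1 / (2 c)`
#' generations ago.
#'
#' @param c recombination fraction in Morgans.
#' @return generations before present.
#' @export
sved_time <- function(c) {
  stopifnot(all(c > 0))
  1 / (2 * c)
}

#' Convert generations to years
#'
#' @param generations generations before present.
#' @param generation_years years per generation (default 4, the
#'   conventional cattle generation interval).
#' @return years before present.
#' @export
generations_to_years <- function(generations, generation_years = 4) {
  generations * generation_years
}

#' Effective-population-size trajectory from phased haplotypes
#'
#' Pools LD pairs across chromosomes, bins them into equal-count
#' distance bins, converts each bin's mean distance to a recombination
#' fraction with the linear genetic map (`c = dist_bp * morgans_per_bp`,
#' default 1 cM/Mb), applies [sved_ne()] per bin and dates each bin at
#' `t = 1/(2c)` generations ago. The trajectory summary is the harmonic
#' mean of the per-bin estimates.
#'
#' @param hapset a [haplotype_set()] for one population.
#' @param population label stored in the output.
#' @param n_bins distance bins, default 30.
#' @param min_bp,max_bp,maf_min pair collection limits, see
#'   [collect_ld_pairs()].
#' @param morgans_per_bp map scale, default 1e-8.
#' @param mapping `f(c)` mapping for [sved_ne()].
#' @param r2_adjust subtract the 1/(haplotype count) sampling term from
#'   each bin's mean r-squared before inversion (off by default).
#' @return object of class `ne_trajectory`: list with `population`,
#'   `bins` (data frame sorted by `t_generations`, most recent first:
#'   `mean_dist_bp`, `mean_r2`, `n_pairs`, `c`, `t_generations`, `ne`)
#'   and `harmonic_mean_ne`.
#' @export
ne_trajectory <- function(hapset, population = "pop1", n_bins = 30,
                          min_bp = 5000, max_bp = 1e6, maf_min = 0.05,
                          morgans_per_bp = 1e-8,
                          mapping = c("linear", "sved_paper"),
                          r2_adjust = FALSE) {
  mapping <- match.arg(mapping)
  pairs <- collect_ld_pairs(hapset, min_bp = min_bp, max_bp = max_bp,
                            maf_min = maf_min)
  if (nrow(pairs) < n_bins)
    stop("only ", nrow(pairs), " LD pairs for ", n_bins, " bins")
  bins <- bin_equal_count(pairs, n_bins)
  r2 <- bins$mean_r2
  if (r2_adjust) r2 <- pmax(r2 - 1 / nrow(hapset$haplotypes), 1e-12)
  bins$c <- bins$mean_dist_bp * morgans_per_bp
  bins$t_generations <- sved_time(bins$c)
  bins$ne <- sved_ne(r2, bins$c, mapping)
  bins <- bins[order(bins$t_generations), , drop = FALSE]
  rownames(bins) <- NULL
  pos <- is.finite(bins$ne) & bins$ne > 0
  hm <- sum(pos) / sum(1 / bins$ne[pos])
  structure(list(population = population, bins = bins,
                 harmonic_mean_ne = hm),
            class = "ne_trajectory")
}

#' @export
print.ne_trajectory <- function(x, ...) {
  cat("ne_trajectory for", x$population, "-", nrow(x$bins), "bins,",
      sprintf("t in [%.0f, %.0f] generations, harmonic-mean Ne %.1f\n",
              min(x$bins$t_generations), max(x$bins$t_generations),
              x$harmonic_mean_ne))
  invisible(x)
}
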