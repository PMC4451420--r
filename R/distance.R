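#' Reynolds' genetic distance between two allele-frequency vectors
#'
#' The least-squares coancestry distance of Reynolds, Weir & Cockerham
#' (1983) for biallelic loci:
#' `theta = sum_v sum_alleles (p - q)^2 / (2 * sum_v (1 - sum_alleles p q))`,
#' suited to short, drift-dominated divergence. Loci where one frequency
#' is missing are dropped; loci fixed identically in both populations
#' contribute zero to both sums. `NA` when every locus is fixed
#' identically (zero denominator).
#'
#' @param freqs_a,freqs_b alternate-allele frequencies on the same
#'   variant list, values in `[0, 1]`.
#' @return a non-negative distance, or `NA` if undefined.
#' @export
reynolds_distance <- function(freqs_a, freqs_b) {
  if (length(freqs_a) != length(freqs_b))
    stop("frequency vectors differ in length")
  ok <- !is.na(freqs_a) & !is.na(freqs_b)
  p <- freqs_a[ok]
  q <- freqs_b[ok]
  if (any(p < 0 | p > 1 | q < 0 | q > 1))
    stop("frequencies outside [0, 1]")
  num <- sum((p - q)^2 + ((1 - p) - (1 - q))^2)
  den <- 2 * sum(1 - (p * q + (1 - p) * (1 - q)))
  if (den == 0) return(NA_real_)
  num / den
}

#' Reynolds distance matrix among populations
#'
#' @param ds a [genotype_dataset()].
#' @param populations populations to include (default all, in input
#'   order).
#' @param variants optional variant index (used by the bootstrap).
#' @return symmetric matrix with zero diagonal, labelled by population.
#' @export
reynolds_matrix <- function(ds, populations = NULL, variants = NULL) {
  stopifnot(inherits(ds, "genotype_dataset"))
  if (is.null(populations)) populations <- unique(unname(ds$populations))
  freqs <- sapply(populations, function(pp)
    allele_freqs(ds, population_samples(ds, pp)))
  if (!is.null(variants)) freqs <- freqs[variants, , drop = FALSE]
  k <- length(populations)
  m <- matrix(0, k, k, dimnames = list(populations, populations))
  for (i in seq_len(k - 1)) for (j in seq((i + 1), k)) {
    m[i, j] <- m[j, i] <- reynolds_distance(freqs[, i], freqs[, j])
  }
  m
}

#' Neighbor-joining dendrogram from a distance matrix
#'
#' Saitou-Nei neighbor joining (via \pkg{ape}) on a symmetric distance
#' matrix. Negative branch lengths, an artifact of NJ on noisy
#' distances, are clamped to zero by default for display.
#'
#' @param d symmetric matrix or `dist` with >= 3 labels.
#' @param clamp_negative clamp negative branch lengths to 0
#'   (default `TRUE`); set `FALSE` for raw NJ output.
#' @return an [ape::phylo] tree.
#' @export
nj_tree <- function(d, clamp_negative = TRUE) {
  m <- as.matrix(d)
  if (nrow(m) < 3) stop("need >= 3 labels")
  if (max(abs(m - t(m))) > 1e-8) stop("distance matrix is not symmetric")
  if (anyNA(m)) stop("distance matrix contains NA")
  tr <- ape::nj(stats::as.dist(m))
  if (clamp_negative) tr$edge.length <- pmax(tr$edge.length, 0)
  tr
}

#' Neighbor-joining tree with bootstrap support
#'
#' Resamples variants with replacement, recomputes the Reynolds matrix
#' and NJ tree per replicate, and scores each internal edge of the full
#' tree by the fraction of replicate trees containing the same
#' bipartition (branch lengths and rooting ignored). Deterministic given
#' the seed.
#'
#' @param ds a [genotype_dataset()].
#' @param replicates bootstrap replicates, default 100.
#' @param seed RNG seed.
#' @param populations populations to include (default all).
#' @return an [ape::phylo] tree whose `node.label` holds support
#'   fractions (root label empty).
#' @export
bootstrap_support <- function(ds, replicates = 100, seed = 1L,
                              populations = NULL) {
  stopifnot(replicates >= 1)
  main <- nj_tree(reynolds_matrix(ds, populations))
  set.seed(seed)
  n_var <- nrow(ds$variants)
  boots <- vector("list", replicates)
  for (r in seq_len(replicates)) {
    idx <- sample.int(n_var, n_var, replace = TRUE)
    boots[[r]] <- nj_tree(reynolds_matrix(ds, populations, variants = idx))
  }
  counts <- ape::prop.clades(main, boots, rooted = FALSE)
  counts[is.na(counts)] <- 0
  main$node.label <- c("", format(counts[-1] / replicates,
                                  trim = TRUE, digits = 3))
  attr(main, "support") <- counts / replicates
  main
}

#' Bootstrap support of a given split
#'
#' @param tree a tree returned by [bootstrap_support()].
#' @param side character vector of labels forming one side of the split.
#' @return the support fraction, or `NA` if the tree lacks that split.
#' @export
split_support <- function(tree, side) {
  sup <- attr(tree, "support")
  if (is.null(sup)) stop("tree carries no support attribute")
  tips <- tree$tip.label
  parts <- ape::prop.part(tree)
  side <- sort(side)
  for (i in seq_along(parts)) {
    s1 <- sort(tips[parts[[i]]])
    s2 <- sort(setdiff(tips, s1))
    if (identical(s1, side) || identical(s2, side)) return(unname(sup[i]))
  }
  NA_real_
}

#' Unrooted bipartitions of a tree
#'
#' The set of non-trivial splits of the leaf set implied by internal
#' edges, each split given as the lexicographically smaller side.
#' Useful for comparing topologies irrespective of rooting and label
#' order.
#'
#' @param tree an [ape::phylo].
#' @return list of character vectors (sorted leaf labels).
#' @export
tree_bipartitions <- function(tree) {
  tips <- tree$tip.label
  parts <- ape::prop.part(tree)
  out <- list()
  for (p in parts) {
    side <- sort(tips[p])
    other <- sort(setdiff(tips, side))
    if (length(side) < 2 || length(other) < 2) next
    key <- if (paste(side, collapse = "|") < paste(other, collapse = "|"))
      side else other
    out[[paste(key, collapse = "|")]] <- key
  }
  unname(out[unique(names(out))])
}
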