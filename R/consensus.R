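#' Bundle replicated XP-EHH comparisons
#'
#' A comparison set holds the standardized, flagged XP-EHH records of
#' several pairwise population comparisons that were oriented the same
#' way (population A of every comparison drawn from the same side of
#' the design), plus the consensus threshold `m`.
#'
#' @param name label, e.g. `"taurine-vs-indicine"`.
#' @param comparisons named list of flagged record frames from
#'   [flag_outliers()]; all must share the variant map.
#' @param m minimum number of same-sign extreme comparisons for a
#'   consensus call, default `length(comparisons) - 1` capped below at 1.
#' @param require_all_tested require a SNP to be tested in every
#'   comparison rather than in at least `m` (default `FALSE`).
#' @return object of class `comparison_set`.
#' @export
comparison_set <- function(name, comparisons,
                           m = max(1L, length(comparisons) - 1L),
                           require_all_tested = FALSE) {
  k <- length(comparisons)
  if (k < 1) stop("need at least one comparison")
  if (m > k) stop("m (", m, ") exceeds the number of comparisons (", k, ")")
  map <- comparisons[[1]][c("id", "chrom", "pos_bp")]
  for (cc in comparisons[-1]) {
    if (!identical(cc[c("id", "chrom", "pos_bp")], map))
      stop("comparisons do not share a variant map")
  }
  for (cc in comparisons) {
    if (is.null(cc$outlier))
      stop("comparisons must be standardized and flagged")
  }
  structure(list(name = name, comparisons = comparisons, m = as.integer(m),
                 require_all_tested = isTRUE(require_all_tested)),
            class = "comparison_set")
}

#' Replicated-comparison consensus calls
#'
#' A SNP is called under selection when it is tested in at least `m`
#' comparisons (all of them under `require_all_tested`), is an extreme
#' outlier with the same sign in at least `m` comparisons, and — under
#' the default conservative rule — is never an extreme of the opposite
#' sign. `allow_conflict = TRUE` drops the last clause.
#'
#' @param cs a [comparison_set()].
#' @param allow_conflict permit opposite-sign extremes among the other
#'   comparisons (default `FALSE`).
#' @return data frame with one row per called SNP: `id`, `chrom`,
#'   `pos_bp`, `direction` (`"pop_a_side"`/`"pop_b_side"`), `support`,
#'   `n_tested`, `conflicting`.
#' @export
consensus <- function(cs, allow_conflict = FALSE) {
  stopifnot(inherits(cs, "comparison_set"))
  k <- length(cs$comparisons)
  tested <- do.call(cbind, lapply(cs$comparisons, `[[`, "tested"))
  high <- do.call(cbind, lapply(cs$comparisons,
                                function(cc) cc$outlier == "high"))
  low <- do.call(cbind, lapply(cs$comparisons,
                               function(cc) cc$outlier == "low"))
  n_tested <- rowSums(tested)
  n_high <- rowSums(high)
  n_low <- rowSums(low)
  enough <- if (cs$require_all_tested) n_tested == k else n_tested >= cs$m
  call_high <- enough & n_high >= cs$m & (allow_conflict | n_low == 0L)
  call_low <- enough & n_low >= cs$m & (allow_conflict | n_high == 0L)
  sel <- which(call_high | call_low)
  map <- cs$comparisons[[1]]
  out <- data.frame(
    id = map$id[sel], chrom = map$chrom[sel], pos_bp = map$pos_bp[sel],
    direction = ifelse(call_high[sel], "pop_a_side", "pop_b_side"),
    support = ifelse(call_high[sel], n_high[sel], n_low[sel]),
    n_tested = n_tested[sel],
    conflicting = (n_high[sel] > 0L & n_low[sel] > 0L),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Null rate of consensus calls under independent flags
#'
#' Monte-Carlo estimate of the per-SNP probability of a consensus call
#' when, in each of `K` independent comparisons, a SNP is flagged high
#' with probability `q`, low with probability `q`, and unflagged
#' otherwise — the calibration expectation for sweep-free data.
#'
#' @param K number of comparisons.
#' @param m consensus threshold.
#' @param q per-tail flag probability, in (0, 0.5).
#' @param replicates simulated SNPs, default 1e5.
#' @param seed RNG seed.
#' @param allow_conflict as in [consensus()].
#' @return estimated per-SNP call probability.
#' @export
null_consensus_rate <- function(K, m, q, replicates = 1e5, seed = 1L,
                                allow_conflict = FALSE) {
  stopifnot(q > 0, q < 0.5, m <= K)
  set.seed(seed)
  flags <- matrix(sample(c(-1L, 0L, 1L), K * replicates, replace = TRUE,
                         prob = c(q, 1 - 2 * q, q)),
                  replicates, K)
  n_high <- rowSums(flags == 1L)
  n_low <- rowSums(flags == -1L)
  call <- (n_high >= m & (allow_conflict | n_low == 0L)) |
    (n_low >= m & (allow_conflict | n_high == 0L))
  mean(call)
}

#' Link consensus SNPs to nearby gene features
#'
#' Links every gene whose interval intersects the window
#' `[pos - window_bp, pos + window_bp]` around a called SNP; the
#' reported distance is 0 for a SNP inside the gene, otherwise the bp
#' gap to the nearer gene edge.
#'
#' @param calls data frame from [consensus()] (needs `id`, `chrom`,
#'   `pos_bp`; a `direction` column is carried through if present).
#' @param features gene features from [read_features()].
#' @param window_bp linkage window, default 50000.
#' @return data frame with columns `id`, `chrom`, `pos_bp`,
#'   (`direction`,) `gene`, `biotype`, `distance_bp`.
#' @export
link_genes <- function(calls, features, window_bp = 50000) {
  out <- list()
  for (ch in unique(calls$chrom)) {
    sn <- calls[calls$chrom == ch, , drop = FALSE]
    ft <- features[features$chrom == ch, , drop = FALSE]
    if (!nrow(ft) || !nrow(sn)) next
    hits <- IRanges::findOverlaps(
      IRanges::IRanges(sn$pos_bp - window_bp, sn$pos_bp + window_bp),
      IRanges::IRanges(ft$start_bp, ft$end_bp))
    if (!length(hits)) next
    i <- S4Vectors::queryHits(hits)
    j <- S4Vectors::subjectHits(hits)
    dist <- pmax(0L, pmax(ft$start_bp[j] - sn$pos_bp[i],
                          sn$pos_bp[i] - ft$end_bp[j]))
    block <- data.frame(id = sn$id[i], chrom = ch, pos_bp = sn$pos_bp[i],
                        gene = ft$id[j], biotype = ft$biotype[j],
                        distance_bp = dist, stringsAsFactors = FALSE)
    if (!is.null(sn$direction)) block$direction <- sn$direction[i]
    out[[length(out) + 1L]] <- block
  }
  if (!length(out))
    return(data.frame(id = character(), chrom = character(),
                      pos_bp = integer(), gene = character(),
                      biotype = character(), distance_bp = integer(),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Tally gene biotypes among linked genes
#'
#' Counts distinct genes per biotype — a gene linked by several SNPs
#' counts once — optionally split by the consensus call direction.
#'
#' @param links data frame from [link_genes()].
#' @return data frame with columns `direction` (if present in `links`),
#'   `biotype`, `n_genes`.
#' @export
tally_biotypes <- function(links) {
  biotypes <- c(KNOWN_BIOTYPES, "other")
  if (!nrow(links)) {
    return(data.frame(biotype = biotypes,
                      n_genes = 0L, stringsAsFactors = FALSE))
  }
  if (!is.null(links$direction)) {
    out <- do.call(rbind, lapply(unique(links$direction), function(d) {
      sub <- links[links$direction == d, , drop = FALSE]
      data.frame(direction = d, biotype = biotypes,
                 n_genes = vapply(biotypes, function(b)
                   length(unique(sub$gene[sub$biotype == b])), 0L),
                 stringsAsFactors = FALSE)
    }))
  } else {
    out <- data.frame(biotype = biotypes,
                      n_genes = vapply(biotypes, function(b)
                        length(unique(links$gene[links$biotype == b])), 0L),
                      stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}
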