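# group-splitting EHH machinery: haplotypes sharing an allele string
# from the core to the current extension share a group id.
step_groups <- function(g, allele) {
  key <- g * 2L + allele
  match(key, key[!duplicated(key)])
}

ehh_from_groups <- function(g, n_hap) {
  cnt <- tabulate(g)
  sum(cnt * (cnt - 1)) / (n_hap * (n_hap - 1))
}

#' Extended haplotype homozygosity curve from a core SNP
#'
#' Whole-sample EHH: at extension `x`, haplotypes are grouped by their
#' allele string from the core to `x`, and
#' `EHH(x) = sum_g C(n_g, 2) / C(N, 2)`. The curve starts at the core
#' with EHH 1 and is truncated once EHH drops below `cutoff` (that
#' point is kept), at a gap to the next SNP larger than `max_gap_bp`
#' (the far SNP is not kept), or at the chromosome end.
#'
#' @param hapset a [haplotype_set()] (phased, missing-free).
#' @param core variant index of the core SNP.
#' @param direction `"left"` or `"right"` along the chromosome.
#' @param cutoff EHH truncation level, default 0.05.
#' @param max_gap_bp maximum tolerated inter-SNP gap, default 400000.
#' @return data frame with columns `pos_bp`, `ehh` (first row is the
#'   core with EHH 1); EHH is non-increasing away from the core.
#' @export
ehh <- function(hapset, core, direction = c("right", "left"),
                cutoff = 0.05, max_gap_bp = 400000) {
  direction <- match.arg(direction)
  stopifnot(inherits(hapset, "haplotype_set"))
  h <- hapset$haplotypes
  n_hap <- nrow(h)
  if (n_hap < 2) stop("need at least 2 haplotypes")
  chrom <- hapset$variants$chrom
  pos <- hapset$variants$pos_bp
  step <- if (direction == "right") 1L else -1L
  g <- step_groups(rep(1L, n_hap), h[, core])
  out_pos <- pos[core]
  out_ehh <- 1
  val <- 1   # curve value at the core itself
  x <- core
  repeat {
    if (val < cutoff) break
    nx <- x + step
    if (nx < 1L || nx > ncol(h)) break
    if (chrom[nx] != chrom[core]) break
    if (abs(pos[nx] - pos[x]) > max_gap_bp) break
    g <- step_groups(g, h[, nx])
    val <- ehh_from_groups(g, n_hap)
    out_pos <- c(out_pos, pos[nx])
    out_ehh <- c(out_ehh, val)
    x <- nx
    if (val < cutoff) break
    if (val == 0) break
  }
  data.frame(pos_bp = out_pos, ehh = out_ehh)
}

#' Integrated haplotype homozygosity
#'
#' Trapezoidal integral of the EHH curves over physical distance (bp),
#' left plus right of the shared core.
#'
#' @param curve_left,curve_right EHH curves from [ehh()] sharing the
#'   same core (either may be `NULL`).
#' @return iHH in bp-homozygosity units.
#' @export
ihh <- function(curve_left, curve_right) {
  trap <- function(curve) {
    if (is.null(curve) || nrow(curve) < 2) return(0)
    d <- abs(diff(curve$pos_bp))
    sum(d * (utils::head(curve$ehh, -1) + utils::tail(curve$ehh, -1)) / 2)
  }
  trap(curve_left) + trap(curve_right)
}

# iHH for every variant of one chromosome block, without materialising
# curves: walks outward from each core accumulating the trapezoids.
ihh_scan_chrom <- function(h, pos, cutoff, max_gap_bp) {
  n_hap <- nrow(h)
  m <- ncol(h)
  out <- numeric(m)
  for (core in seq_len(m)) {
    total <- 0
    for (step in c(1L, -1L)) {
      g <- step_groups(rep(1L, n_hap), h[, core])
      val <- 1
      x <- core
      while (val >= cutoff && val > 0) {
        nx <- x + step
        if (nx < 1L || nx > m) break
        gap <- abs(pos[nx] - pos[x])
        if (gap > max_gap_bp) break
        g <- step_groups(g, h[, nx])
        nval <- ehh_from_groups(g, n_hap)
        total <- total + gap * (val + nval) / 2
        val <- nval
        x <- nx
      }
    }
    out[core] <- total
  }
  out
}

#' Per-variant integrated haplotype homozygosity
#'
#' @param hapset a [haplotype_set()].
#' @inheritParams ehh
#' @return numeric vector of iHH values, one per variant.
#' @export
ihh_scan <- function(hapset, cutoff = 0.05, max_gap_bp = 400000) {
  stopifnot(inherits(hapset, "haplotype_set"))
  out <- numeric(nrow(hapset$variants))
  for (ch in unique(hapset$variants$chrom)) {
    idx <- which(hapset$variants$chrom == ch)
    out[idx] <- ihh_scan_chrom(hapset$haplotypes[, idx, drop = FALSE],
                               hapset$variants$pos_bp[idx],
                               cutoff, max_gap_bp)
  }
  out
}

#' Cross-population extended haplotype homozygosity scan
#'
#' For every SNP shared by the two phased populations, computes
#' `raw = ln(iHH_A / iHH_B)`. A SNP is `tested` when its MAF reaches
#' `maf_min` in both populations and both iHH values are positive;
#' untested SNPs keep `NA` scores. Positive scores mean longer
#' haplotype homozygosity (a sweep signal) in population A.
#'
#' @param hapset_a,hapset_b [haplotype_set()]s sharing the variant map.
#' @param maf_min per-population MAF threshold, default 0.05.
#' @param max_gap_bp maximum inter-SNP gap, default 400000.
#' @param cutoff EHH truncation level, default 0.05.
#' @return data frame with columns `id`, `chrom`, `pos_bp`, `ihh_a`,
#'   `ihh_b`, `raw`, `tested`.
#' @export
xpehh <- function(hapset_a, hapset_b, maf_min = 0.05,
                  max_gap_bp = 400000, cutoff = 0.05) {
  va <- hapset_a$variants
  vb <- hapset_b$variants
  if (!identical(va[c("id", "chrom", "pos_bp")],
                 vb[c("id", "chrom", "pos_bp")]))
    stop("variant maps of the two populations differ")
  pa <- colMeans(hapset_a$haplotypes)
  pb <- colMeans(hapset_b$haplotypes)
  maf_ok <- pmin(pa, 1 - pa) >= maf_min & pmin(pb, 1 - pb) >= maf_min
  ihh_a <- ihh_scan(hapset_a, cutoff, max_gap_bp)
  ihh_b <- ihh_scan(hapset_b, cutoff, max_gap_bp)
  tested <- maf_ok & ihh_a > 0 & ihh_b > 0
  raw <- ifelse(tested, log(ihh_a / ihh_b), NA_real_)
  data.frame(id = va$id, chrom = va$chrom, pos_bp = va$pos_bp,
             ihh_a = ihh_a, ihh_b = ihh_b, raw = raw, tested = tested,
             stringsAsFactors = FALSE)
}

#' Standardize XP-EHH scores within chromosomes
#'
#' Adds `z = (raw - mean) / sd` computed over the tested records of
#' each chromosome separately (sample standard deviation).
#'
#' @param records data frame from [xpehh()].
#' @return the records with a `z` column (`NA` for untested records).
#' @export
standardize_by_chrom <- function(records) {
  records$z <- NA_real_
  for (ch in unique(records$chrom)) {
    sel <- records$chrom == ch & records$tested
    if (sum(sel) < 2)
      stop("chromosome ", ch, " has fewer than 2 tested records")
    s <- stats::sd(records$raw[sel])
    if (s == 0) stop("zero XP-EHH variance on chromosome ", ch)
    records$z[sel] <- (records$raw[sel] - mean(records$raw[sel])) / s
  }
  records
}

#' Flag outlier XP-EHH scores by distribution quantiles
#'
#' Thresholds are the `q_low` and `q_high` quantiles (linear
#' interpolation) of the standardized scores over all tested records —
#' genome-wide by default, per chromosome behind `per_chrom`.
#' Comparison is inclusive: `z <= low` is `"low"`, `z >= high` is
#' `"high"`. When the two thresholds coincide (degenerate score
#' distribution) nothing is flagged.
#'
#' @param records standardized records from [standardize_by_chrom()].
#' @param q_low,q_high tail quantiles, defaults 0.05 and 0.95.
#' @param per_chrom take quantiles per chromosome instead of
#'   genome-wide (default `FALSE`).
#' @return the records with an `outlier` column in
#'   `{"low", "none", "high"}` (`"none"` for untested records).
#' @export
flag_outliers <- function(records, q_low = 0.05, q_high = 0.95,
                          per_chrom = FALSE) {
  if (is.null(records$z)) stop("records are not standardized")
  records$outlier <- "none"
  flag_block <- function(sel) {
    zz <- records$z[sel]
    thr <- stats::quantile(zz, c(q_low, q_high), names = FALSE, type = 7)
    if (thr[1] == thr[2]) return()
    records$outlier[sel][zz <= thr[1]] <<- "low"
    records$outlier[sel][zz >= thr[2]] <<- "high"
  }
  if (per_chrom) {
    for (ch in unique(records$chrom)) flag_block(records$chrom == ch &
                                                   records$tested)
  } else {
    flag_block(records$tested)
  }
  records
}
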