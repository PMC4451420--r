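make_records <- function(outliers, tested = NULL, n = length(outliers)) {
  # one comparison's records over n SNPs
  if (is.null(tested)) tested <- outliers != "untested"
  data.frame(id = paste0("s", seq_len(n)), chrom = "1",
             pos_bp = seq_len(n) * 1000,
             ihh_a = 1, ihh_b = 1, raw = 0, tested = tested,
             z = 0, outlier = ifelse(outliers == "untested", "none", outliers),
             stringsAsFactors = FALSE)
}

make_cs <- function(flag_rows, m, ...) {
  # flag_rows: list of per-comparison flag vectors over the same SNPs
  comps <- lapply(flag_rows, make_records)
  comparison_set("test", comps, m = m, ...)
}

test_that("the 3-of-4 rule calls supported SNPs and rejects conflicts", {
  # one SNP per scenario, four comparisons
  flags <- list(c("high", "high", "none"),
                c("high", "high", "none"),
                c("high", "low", "none"),
                c("untested", "high", "none"))
  cs <- make_cs(flags, m = 3)
  calls <- consensus(cs)
  # SNP1: high, high, high, untested -> called toward population A
  expect_identical(calls$id, "s1")
  expect_identical(calls$direction, "pop_a_side")
  expect_identical(calls$support, 3)
  expect_identical(calls$n_tested, 3)
  # SNP2: high, high, low, high would reach m but conflicts
  permissive <- consensus(make_cs(list(
    c("high"), c("high"), c("low"), c("high")), m = 3), allow_conflict = TRUE)
  expect_identical(permissive$id, "s1")
  expect_true(permissive$conflicting)
  # SNP3: nothing flagged -> no call
  expect_identical(nrow(consensus(make_cs(list(
    c("none"), c("none"), c("none"), c("none")), m = 3))), 0L)
})

test_that("low-tail consensus is directional and m is validated", {
  cs <- make_cs(list(c("low"), c("low"), c("low")), m = 3)
  calls <- consensus(cs)
  expect_identical(calls$direction, "pop_b_side")
  expect_error(make_cs(list(c("none"), c("none")), m = 3), "m \\(3\\)")
  # require_all_tested blocks the untested-supported call
  strict <- make_cs(list(c("high"), c("high"), c("high"), c("untested")),
                    m = 3, require_all_tested = TRUE)
  expect_identical(nrow(consensus(strict)), 0L)
})

test_that("null consensus rate matches closed forms", {
  # K=3, m=3: 2 q^3
  est3 <- null_consensus_rate(3, 3, 0.05, replicates = 4e5, seed = 2)
  p3 <- 2 * 0.05^3
  se3 <- sqrt(p3 * (1 - p3) / 4e5)
  expect_lt(abs(est3 - p3), 3 * se3)
  # K=4, m=3 with the no-conflict rule:
  # 2 * (C(4,3) q^3 (1-2q) + q^4)
  est4 <- null_consensus_rate(4, 3, 0.05, replicates = 4e5, seed = 3)
  p4 <- 2 * (choose(4, 3) * 0.05^3 * 0.9 + 0.05^4)
  se4 <- sqrt(p4 * (1 - p4) / 4e5)
  expect_lt(abs(est4 - p4), 3 * se4)
  # enumeration oracle over all 3^4 flag configurations
  grid <- expand.grid(rep(list(c(-1, 0, 1)), 4))
  pr <- apply(grid, 1, function(f)
    prod(ifelse(f == 0, 0.9, 0.05)))
  call <- apply(grid, 1, function(f)
    (sum(f == 1) >= 3 && sum(f == -1) == 0) ||
      (sum(f == -1) >= 3 && sum(f == 1) == 0))
  expect_equal(sum(pr[call]), p4)
  expect_error(null_consensus_rate(3, 3, 0), "q > 0")
})

test_that("gene linkage follows the 50 kb window geometry", {
  feats <- data.frame(id = c("gA", "gB", "gC"), chrom = "1",
                      start_bp = c(140000L, 151000L, 90000L),
                      end_bp = c(160000L, 160000L, 110000L),
                      biotype = c("protein_coding", "miRNA", "snoRNA"),
                      stringsAsFactors = FALSE)
  calls <- data.frame(id = "s1", chrom = "1", pos_bp = 100000L,
                      direction = "pop_a_side", stringsAsFactors = FALSE)
  links <- link_genes(calls, feats)
  # gA at 40 kb linked; gB at 51 kb not; gC contains the SNP
  expect_setequal(links$gene, c("gA", "gC"))
  expect_identical(links$distance_bp[links$gene == "gA"], 40000L)
  expect_identical(links$distance_bp[links$gene == "gC"], 0L)
})

test_that("gene linkage agrees with a brute-force interval scan", {
  set.seed(43)
  feats <- data.frame(id = paste0("g", 1:40),
                      chrom = sample(c("1", "2"), 40, TRUE),
                      start_bp = sample(1:9e5, 40),
                      biotype = "other", stringsAsFactors = FALSE)
  feats$end_bp <- feats$start_bp + sample(1000:50000, 40)
  feats <- feats[order(feats$chrom, feats$start_bp), ]
  calls <- data.frame(id = paste0("s", 1:25),
                      chrom = sample(c("1", "2"), 25, TRUE),
                      pos_bp = sample(1:1e6, 25), stringsAsFactors = FALSE)
  links <- link_genes(calls, feats, window_bp = 50000)
  brute <- list()
  for (i in seq_len(nrow(calls))) for (j in seq_len(nrow(feats))) {
    if (calls$chrom[i] != feats$chrom[j]) next
    gap <- max(0, feats$start_bp[j] - calls$pos_bp[i],
               calls$pos_bp[i] - feats$end_bp[j])
    if (gap <= 50000)
      brute[[length(brute) + 1L]] <-
        c(calls$id[i], feats$id[j], gap)
  }
  brute <- do.call(rbind, brute)
  got <- links[order(links$id, links$gene), c("id", "gene", "distance_bp")]
  want <- brute[order(brute[, 1], brute[, 2]), , drop = FALSE]
  expect_identical(nrow(got), nrow(want))
  expect_identical(got$gene, unname(want[, 2]))
  expect_identical(got$distance_bp, as.integer(want[, 3]))
})

test_that("biotype tallies count distinct genes once", {
  links <- data.frame(id = c("s1", "s2", "s3"), chrom = "1",
                      pos_bp = 1:3, gene = c("gA", "gA", "gB"),
                      biotype = c("protein_coding", "protein_coding", "miRNA"),
                      distance_bp = 0L, stringsAsFactors = FALSE)
  tal <- tally_biotypes(links)
  expect_identical(tal$n_genes[tal$biotype == "protein_coding"], 1L)
  expect_identical(tal$n_genes[tal$biotype == "miRNA"], 1L)
  expect_identical(sum(tally_biotypes(links[0, ])$n_genes), 0L)
  links2 <- rbind(links,
                  data.frame(id = "s4", chrom = "1", pos_bp = 4L,
                             gene = "gC", biotype = "protein_coding",
                             distance_bp = 10L))
  tal2 <- tally_biotypes(links2)
  expect_identical(tal2$n_genes[tal2$biotype == "protein_coding"], 2L)
  # split by direction when the links carry one
  links3 <- links
  links3$direction <- c("pop_a_side", "pop_a_side", "pop_b_side")
  tal3 <- tally_biotypes(links3)
  expect_identical(
    tal3$n_genes[tal3$direction == "pop_a_side" &
                   tal3$biotype == "protein_coding"], 1L)
  expect_identical(
    tal3$n_genes[tal3$direction == "pop_b_side" &
                   tal3$biotype == "miRNA"], 1L)
})
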