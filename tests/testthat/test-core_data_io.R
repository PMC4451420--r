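test_that("PED/MAP reading codes genotypes as alt-allele counts", {
  dir <- withr::local_tempdir()
  fx <- write_ped_fixture(
    dir,
    ped_lines = c("fam1 ind1 0 0 1 0 A A A C G G",
                  "fam1 ind2 0 0 2 0 A C C C 0 0"),
    map_lines = c("1 snp1 0 100", "1 snp2 0 200", "1 snp3 0 300"),
    pop_lines = c("ind1 popA", "ind2 popB"))
  ds <- read_genotypes(fx$ped, fx$map, fx$pop)
  # ref = first allele observed in the PED, alt = second
  expect_identical(dim(ds$calls), c(2L, 3L))
  expect_identical(unname(ds$calls[, "snp1"]), c(0L, 1L))
  expect_identical(unname(ds$calls[, "snp2"]), c(1L, 2L))
  # "0 0" is a missing call, not homozygous anything
  expect_identical(unname(ds$calls[, "snp3"]), c(0L, NA_integer_))
  expect_identical(unname(ds$populations), c("popA", "popB"))
})

test_that("unsorted MAP positions are sorted with calls permuted", {
  dir <- withr::local_tempdir()
  fx <- write_ped_fixture(
    dir,
    ped_lines = c("f i1 0 0 1 0 A A C C G G",
                  "f i2 0 0 1 0 A T C A G T"),
    map_lines = c("1 s_c 0 300", "1 s_a 0 100", "2 s_b 0 50"),
    pop_lines = c("i1 p", "i2 p"))
  ds <- read_genotypes(fx$ped, fx$map, fx$pop)
  expect_identical(ds$variants$id, c("s_a", "s_c", "s_b"))
  # independent check: sort the fixture by (chrom, pos) by hand
  expect_identical(ds$variants$pos_bp, c(100L, 300L, 50L))
  # s_a alleles were (C C) and (C A): alt allele is A
  expect_identical(unname(ds$calls[, "s_a"]), c(0L, 1L))
})

test_that("reader errors name the offending line and missing samples", {
  dir <- withr::local_tempdir()
  fx <- write_ped_fixture(
    dir,
    ped_lines = c("f i1 0 0 1 0 A A"),
    map_lines = c("1 snp1 0 100", "1 snp2 0 200"),
    pop_lines = c("i1 p"))
  expect_error(read_genotypes(fx$ped, fx$map, fx$pop), "PED line 1")
  fx2 <- write_ped_fixture(
    dir,
    ped_lines = c("f stranger 0 0 1 0 A A"),
    map_lines = c("1 snp1 0 100"),
    pop_lines = c("i1 p"))
  expect_error(read_genotypes(fx2$ped, fx2$map, fx2$pop), "stranger")
})

test_that("call-rate filter drops samples first, then SNPs, and is idempotent", {
  # 10 samples x 2 SNPs; ind1 misses one of two SNPs (50% < 95%)
  calls <- matrix(1L, 10, 2)
  calls[1, 1] <- NA
  ds <- make_ds(calls)
  kept <- filter_call_rate(ds)
  expect_identical(kept$samples, paste0("ind", 2:10))
  # snp1 is complete again once ind1 left: no SNP drops
  expect_identical(nrow(kept$variants), 2L)
  # identity on clean data and idempotence
  clean <- make_ds(matrix(2L, 4, 3))
  expect_identical(filter_call_rate(clean)$calls, clean$calls)
  expect_identical(filter_call_rate(kept)$calls, kept$calls)
})

test_that("sample-before-SNP filter order changes the outcome on purpose", {
  # ind1 has call rate 2/10; snp1 is missing only in ind1.
  # Sample-first: ind1 leaves, snp1 becomes complete and survives.
  # SNP-first would have removed snp1 (9/10 = 90% < 95%).
  calls <- matrix(1L, 10, 10)
  calls[1, 1:8] <- NA
  ds <- make_ds(calls)
  kept <- filter_call_rate(ds)
  expect_false("ind1" %in% kept$samples)
  expect_true("snp1" %in% kept$variants$id)
  expect_identical(nrow(kept$variants), 10L)
  # a SNP missing in 1 of 10 remaining samples is below 95% and leaves
  # (20 SNPs keep that sample's own call rate at 19/20 = 95%)
  calls2 <- matrix(1L, 10, 20)
  calls2[2, 2] <- NA
  kept2 <- filter_call_rate(make_ds(calls2))
  expect_identical(length(kept2$samples), 10L)
  expect_identical(kept2$variants$id, paste0("snp", (1:20)[-2]))
})

test_that("all-filtered datasets raise explicit errors", {
  calls <- matrix(NA_integer_, 3, 2)
  calls[, 1] <- 1L   # samples keep 50% call rate
  expect_error(filter_call_rate(make_ds(calls), sample_min = 0.9),
               "all samples")
  calls3 <- matrix(c(1L, NA, 1L, NA, 1L, NA), 3, 2)
  expect_error(filter_call_rate(make_ds(calls3), sample_min = 0.4,
                                snp_min = 0.9), "all SNPs")
})

test_that("minor allele frequency counts alleles over non-missing calls", {
  ds <- make_ds(rbind(c(0L, 0L, NA), c(1L, 0L, NA), c(2L, 0L, NA),
                      c(2L, 0L, NA)))
  maf <- minor_allele_freq(ds)
  # calls {0,1,2,2}: p_alt = 5/8, MAF = 3/8
  expect_equal(unname(maf[1]), 0.375)
  expect_equal(unname(maf[2]), 0)       # monomorphic
  expect_true(is.na(maf[3]))            # all-missing: undefined, not 0
  expect_error(allele_freqs(ds, "nobody"), "unknown sample")
})

test_that("LD pruning keeps the earlier variant of a correlated pair", {
  set.seed(1)
  g1 <- sample(0:2, 40, replace = TRUE)
  g_indep <- sample(0:2, 40, replace = TRUE)
  calls <- cbind(g1, g1, g_indep)  # duplicate pair + independent SNP
  ds <- make_ds(calls)
  pruned <- ld_prune(ds, window_snps = 3, step_snps = 1)
  expect_identical(pruned$variants$id, c("snp1", "snp3"))
  # identity when all r2 are below the threshold
  set.seed(2)
  calls2 <- matrix(sample(0:2, 200, replace = TRUE), 50, 4)
  ds2 <- make_ds(calls2)
  stopifnot(all(genotype_r2(calls2)[upper.tri(diag(4))] < 0.1))
  expect_identical(ld_prune(ds2, window_snps = 4, step_snps = 1)$variants$id,
                   ds2$variants$id)
})

test_that("LD pruning matches an exhaustive pairwise oracle", {
  # 5 SNPs with one correlated triple; oracle prunes the whole set
  # with the same keep-the-earlier rule, no windows
  set.seed(3)
  base <- sample(0:2, 60, replace = TRUE)
  noise <- function() ifelse(runif(60) < 0.08, sample(0:2, 60, TRUE), base)
  calls <- cbind(base, noise(), sample(0:2, 60, TRUE), noise(),
                 sample(0:2, 60, TRUE))
  ds <- make_ds(calls)
  oracle <- function(g, r2_max) {
    alive <- rep(TRUE, ncol(g))
    r2 <- genotype_r2(g)
    for (a in 1:(ncol(g) - 1)) {
      if (!alive[a]) next
      for (b in (a + 1):ncol(g)) {
        if (alive[b] && !is.na(r2[a, b]) && r2[a, b] > r2_max)
          alive[b] <- FALSE
      }
    }
    alive
  }
  keep <- oracle(calls, 0.1)
  pruned <- ld_prune(ds, window_snps = 5, step_snps = 1, maf_min = 0)
  expect_identical(pruned$variants$id, ds$variants$id[keep])
})

test_that("feature readers honor BED and GFF3 coordinate conventions", {
  dir <- withr::local_tempdir()
  bed <- file.path(dir, "x.bed")
  writeLines(c("chr1\t999\t2000\tgeneA", "chr1\t0\t10\tgeneB\tmiRNA"), bed)
  fb <- read_features(bed, "bed")
  expect_identical(fb$start_bp, c(1L, 1000L))
  expect_identical(fb$end_bp[fb$id == "geneA"], 2000L)
  expect_identical(fb$biotype, c("miRNA", "other"))

  gff <- file.path(dir, "x.gff3")
  writeLines(paste("chr2", "src", "gene", "500", "900", ".", "+", ".",
                   "ID=geneC;biotype=miRNA", sep = "\t"), gff)
  fg <- read_features(gff, "gff3")
  expect_identical(fg$start_bp, 500L)
  expect_identical(fg$biotype, "miRNA")

  empty <- file.path(dir, "empty.bed")
  writeLines(character(), empty)
  expect_identical(nrow(read_features(empty, "bed")), 0L)
  bad <- file.path(dir, "bad.bed")
  writeLines(c("chr1\t1\t100\tok", "chr1\tx"), bad)
  expect_error(read_features(bad, "bed"), "line 2")
})

test_that("haplotype files round-trip bit-exactly", {
  hs <- make_haps(rbind(c(0L, 1L, 1L), c(1L, 0L, 1L),
                        c(0L, 0L, 0L), c(1L, 1L, 0L)))
  path <- withr::local_tempfile(fileext = ".haps")
  write_haplotypes(hs, path)
  back <- read_haplotypes(path)
  expect_identical(back$haplotypes, unname(hs$haplotypes))
  expect_identical(back$variants$pos_bp, hs$variants$pos_bp)
  # write(read(x)) is also stable
  path2 <- withr::local_tempfile(fileext = ".haps")
  write_haplotypes(back, path2)
  expect_identical(readLines(path), readLines(path2))

  bad <- withr::local_tempfile(fileext = ".haps")
  writeLines(c("1 s1 100 A B 0 2 1 0"), bad)
  expect_error(read_haplotypes(bad), "not in \\{0,1\\}")
  odd <- withr::local_tempfile(fileext = ".haps")
  writeLines(c("1 s1 100 A B 0 1 1"), odd)
  expect_error(read_haplotypes(odd), "even")
})

test_that("simulator output survives a haplotype round-trip", {
  sim <- two_pop_sim(seed = 3, n_variants = 60, horizon = 30, split = 15,
                     ne = 30, n_sample = 10)
  hs <- sim$haplotypes$A
  path <- withr::local_tempfile(fileext = ".haps")
  write_haplotypes(hs, path)
  back <- read_haplotypes(path)
  expect_identical(back$haplotypes, unname(hs$haplotypes))
})
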