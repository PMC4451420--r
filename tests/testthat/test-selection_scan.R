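test_that("EHH handles uniform, split and exhausted haplotype groups", {
  # all haplotypes identical: EHH stays 1
  hs <- make_haps(matrix(1L, 6, 4))
  cr <- ehh(hs, 1, "right")
  expect_equal(cr$ehh, rep(1, 4))
  # 4 haplotypes splitting into two equal groups: (1+1)/C(4,2)
  hs2 <- make_haps(rbind(c(0L, 0L), c(0L, 0L), c(0L, 1L), c(0L, 1L)))
  cr2 <- ehh(hs2, 1, "right")
  expect_equal(cr2$ehh, c(1, 1 / 3))
  # all distinct at the extension: EHH hits 0
  hs3 <- make_haps(cbind(c(0L, 0L, 1L, 1L), c(0L, 1L, 0L, 1L)))
  expect_equal(ehh(hs3, 1, "right")$ehh, c(1, 0))
  expect_error(ehh(make_haps(matrix(0L, 1, 2))), "even")
})

test_that("EHH is non-increasing and matches the brute-force oracle", {
  set.seed(23)
  for (rep in 1:150) {
    n <- 2L * sample(1:5, 1)
    m <- sample(3:12, 1)
    h <- matrix(rbinom(n * m, 1, runif(1, 0.2, 0.8)), n, m)
    hs <- make_haps(h, pos = sort(sample(1:1e5, m)))
    core <- sample(m, 1)
    for (dir in c("left", "right")) {
      cv <- ehh(hs, core, dir, cutoff = 0, max_gap_bp = 1e9)
      expect_true(all(diff(cv$ehh) <= 1e-12))
      for (k in seq_len(nrow(cv))[-1]) {
        x <- which(hs$variants$pos_bp == cv$pos_bp[k])
        expect_equal(cv$ehh[k], brute_ehh(h, core, x))
      }
    }
  }
})

test_that("EHH truncates at the cutoff and at large gaps", {
  # groups collapse at the first flank: curve keeps that point, stops
  h <- cbind(rep(0L, 4), c(0L, 1L, 0L, 1L), rep(0L, 4))
  hs <- make_haps(h, pos = c(1000, 2000, 3000))
  cr <- ehh(hs, 1, "right", cutoff = 0.5)
  expect_identical(nrow(cr), 2L)
  expect_equal(cr$ehh[2], 1 / 3)
  # a > max_gap_bp gap truncates before the far SNP
  hs2 <- make_haps(matrix(0L, 4, 3), pos = c(1000, 2000, 500000))
  cr2 <- ehh(hs2, 1, "right", max_gap_bp = 400000)
  expect_equal(cr2$pos_bp, c(1000, 2000))
})

test_that("iHH is the trapezoidal area of both curve sides", {
  # EHH 1 over [core, core+10000], then a drop to zero at +12000
  left <- NULL
  right <- data.frame(pos_bp = c(0, 5000, 10000, 12000),
                      ehh = c(1, 1, 1, 0))
  expect_equal(ihh(left, right), 10000 + 2000 * 0.5)
  # doubling distances doubles the integral
  right2 <- right
  right2$pos_bp <- right2$pos_bp * 2
  expect_equal(ihh(left, right2), 2 * ihh(left, right))
  # minimal support: only the boundary trapezoids on both sides
  h <- cbind(c(0L, 1L, 0L, 1L), rep(0L, 4), c(0L, 1L, 1L, 0L))
  hs <- make_haps(h, pos = c(1000, 2000, 4000))
  cl <- ehh(hs, 2, "left")
  cr <- ehh(hs, 2, "right")
  expect_equal(ihh(cl, cr),
               1000 * (1 + cl$ehh[2]) / 2 + 2000 * (1 + cr$ehh[2]) / 2)
  # the full scan agrees with the curve-based computation
  expect_equal(ihh_scan(hs)[2], ihh(cl, cr))
})

test_that("scan-based iHH equals curve-based iHH on random data", {
  set.seed(29)
  h <- matrix(rbinom(20 * 30, 1, 0.5), 20, 30)
  hs <- make_haps(h, pos = sort(sample(1:3e5, 30)))
  scan <- ihh_scan(hs)
  for (core in c(1, 7, 15, 30)) {
    expect_equal(scan[core],
                 ihh(ehh(hs, core, "left"), ehh(hs, core, "right")))
  }
})

test_that("XP-EHH is zero against itself and antisymmetric", {
  sim <- two_pop_sim(seed = 31, n_variants = 120, horizon = 60, split = 30,
                     ne = 40, n_sample = 15)
  ha <- sim$haplotypes$A
  hb <- sim$haplotypes$B
  self <- xpehh(ha, ha)
  expect_true(all(self$raw[self$tested] == 0))
  ab <- xpehh(ha, hb)
  ba <- xpehh(hb, ha)
  expect_equal(ab$raw[ab$tested], -ba$raw[ba$tested])
  expect_identical(ab$tested, ba$tested)
  # mismatched maps are rejected
  hc <- hb
  hc$variants$pos_bp[1] <- hc$variants$pos_bp[1] + 1L
  expect_error(xpehh(ha, hc), "variant maps")
})

test_that("per-chromosome standardization has unit moments and shift invariance", {
  rec <- data.frame(id = paste0("s", 1:6), chrom = rep(c("1", "2"), each = 3),
                    pos_bp = rep(c(1e3, 2e3, 3e3), 2),
                    ihh_a = 1, ihh_b = 1,
                    raw = c(0.1, 0.3, 0.5, -1, 0, 2), tested = TRUE)
  z <- standardize_by_chrom(rec)
  for (ch in c("1", "2")) {
    expect_equal(mean(z$z[z$chrom == ch]), 0)
    expect_equal(sd(z$z[z$chrom == ch]), 1)
  }
  # two-record chromosome: z = +/- 1/sqrt(2) with sample sd
  rec2 <- rec[1:2, ]
  rec2$raw <- c(0.1, 0.3)
  expect_equal(standardize_by_chrom(rec2)$z, c(-1, 1) / sqrt(2))
  # adding a constant per chromosome leaves z unchanged
  rec3 <- rec
  rec3$raw[rec3$chrom == "1"] <- rec3$raw[rec3$chrom == "1"] + 5
  expect_equal(standardize_by_chrom(rec3)$z, z$z)
  rec4 <- rec
  rec4$tested[1:2] <- FALSE
  expect_error(standardize_by_chrom(rec4), "chromosome 1")
})

test_that("quantile outlier flags take 5 high and 5 low of 100 distinct scores", {
  set.seed(37)
  zval <- sample(seq(-3, 3, length.out = 100))
  rec <- data.frame(id = paste0("s", 1:100), chrom = "1",
                    pos_bp = seq_len(100) * 1000,
                    ihh_a = 1, ihh_b = 1, raw = zval, tested = TRUE)
  rec$z <- zval
  fl <- flag_outliers(rec)
  expect_identical(sum(fl$outlier == "low"), 5L)
  expect_identical(sum(fl$outlier == "high"), 5L)
  # sort-based oracle: the flagged ones are exactly the extreme five
  srt <- sort(zval)
  expect_setequal(fl$z[fl$outlier == "low"], srt[1:5])
  expect_setequal(fl$z[fl$outlier == "high"], srt[96:100])
  # permutation invariance
  perm <- sample(100)
  fl2 <- flag_outliers(rec[perm, ])
  expect_identical(fl2$outlier[order(perm)], fl$outlier)
  # all-equal scores: thresholds coincide, nothing is flagged
  rec$z <- rep(1, 100)
  expect_true(all(flag_outliers(rec)$outlier == "none"))
})
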