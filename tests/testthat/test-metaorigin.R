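test_that("bin matrix has 20 bins at the standard flank/bin sizes", {
  tr <- make_track(list(chr1 = rep(0.7, 9000))) # 450 kb
  os <- origin_set(data.frame(chrom = "chr1", center = 225e3))
  m <- bin_matrix(tr, os, flank = 1e5, bin = 1e4)
  expect_equal(dim(m), c(1L, 20L))
  expect_equal(attr(m, "bin_offsets"), seq(-1e5, 9e4, by = 1e4))
  # constant track: every in-bounds entry equals the constant
  expect_true(all(abs(m - 0.7) < 1e-12))
})

test_that("bins extending past chromosome ends are missing, not zero", {
  tr <- make_track(list(chr1 = rep(1, 6000))) # 300 kb
  os <- origin_set(data.frame(chrom = "chr1", center = 50e3))
  m <- bin_matrix(tr, os)
  off <- attr(m, "bin_offsets")
  expect_true(all(is.na(m[1, off + 50e3 < 0])))
  expect_true(all(!is.na(m[1, off + 50e3 >= 0])))
  expect_error(bin_matrix(tr, origin_set(data.frame(chrom = "chrX", center = 1e4))),
               "chrX")
})

test_that("bin matrix entries match a brute-force midpoint-mean oracle", {
  set.seed(3)
  tr <- make_track(list(cA = rnorm(5000), cB = rnorm(4200)))
  os <- origin_set(data.frame(chrom = c("cA", "cA", "cB"),
                              center = c(110e3, 140e3, 101e3)))
  m <- bin_matrix(tr, os, flank = 1e5, bin = 1e4)
  for (o in 1:3) {
    ch <- os$chrom[o]
    mid <- anchor_midpoints(tr, ch)
    v <- tr$values[[ch]]
    L <- tr$lengths[[ch]]
    for (j in 1:20) {
      lo <- os$center[o] - 1e5 + (j - 1) * 1e4
      hi <- lo + 1e4
      if (lo < 0 || hi > L) {
        expect_true(is.na(m[o, j]))
      } else {
        expect_equal(m[o, j], mean(v[mid >= lo & mid < hi]), tolerance = 1e-12)
      }
    }
  }
})

test_that("mean profile is the missing-aware column mean", {
  tr <- make_track(list(c1 = rnorm(8000)))
  os1 <- origin_set(data.frame(chrom = "c1", center = 200e3))
  m <- bin_matrix(tr, os1)
  p <- mean_profile(m)
  expect_equal(p$mean, as.numeric(m[1, ]))
  expect_equal(p$n, rep(1L, 20))
  # symmetry: rows r and 2 - r average to 1
  os2 <- origin_set(data.frame(chrom = c("c1", "c1"), center = c(200e3, 200e3)))
  m2 <- bin_matrix(tr, os2)
  fake <- with_values(m2, rbind(m[1, ], 2 - m[1, ]))
  expect_equal(mean_profile(fake)$mean, rep(1, 20))
})

test_that("ratio profiles use the linear enrichment domain", {
  tr <- make_track(list(c1 = rnorm(8000)))
  os <- origin_set(data.frame(chrom = "c1", center = 200e3))
  m <- bin_matrix(tr, os)
  expect_equal(ratio_profile(m, m)$ratio, rep(1, 20))
  m2 <- with_values(m, unclass(m) + 1) # +1 in log2 doubles linear enrichment
  expect_equal(ratio_profile(m2, m)$ratio, rep(2, 20), tolerance = 1e-12)
  # linear-domain input: num = 2 * den gives exactly 2
  lin_den <- with_values(m, abs(unclass(m)) + 0.5)
  lin_num <- with_values(m, 2 * unclass(lin_den))
  expect_equal(ratio_profile(lin_num, lin_den, log2_input = FALSE)$ratio,
               rep(2, 20))
  # nonpositive linear denominators are flagged missing
  lin_den[1, 3] <- 0
  expect_true(is.na(ratio_profile(lin_num, lin_den, log2_input = FALSE)$ratio[3]))
})

test_that("ratio profile averages per-origin ratios (mean of ratios)", {
  set.seed(12)
  tr1 <- make_track(list(c1 = rnorm(12000)))
  tr2 <- make_track(list(c1 = rnorm(12000)))
  os <- origin_set(data.frame(chrom = "c1", center = c(150e3, 320e3, 480e3)))
  num <- bin_matrix(tr1, os)
  den <- bin_matrix(tr2, os)
  rp <- ratio_profile(num, den)
  oracle <- colMeans(2^unclass(num) / 2^unclass(den))
  expect_equal(rp$ratio, as.numeric(oracle), tolerance = 1e-12)
})

test_that("per-bin Wilcoxon matches sign-assignment enumeration on small n", {
  # n = 5 all-positive differences: exact two-sided p = 2/2^5
  d <- c(0.3, 1.2, 0.5, 0.9, 2.0)
  expect_equal(cohesinmeta:::signed_rank_p(d), 0.0625)
  expect_equal(oracle_signed_rank_p(d), 0.0625)
  set.seed(8)
  for (i in 1:20) {
    d <- round(rnorm(sample(4:9, 1)), 2)
    d <- d[d != 0]
    if (length(d) < 2 || any(duplicated(abs(d)))) next
    expect_equal(cohesinmeta:::signed_rank_p(d), oracle_signed_rank_p(d),
                 tolerance = 1e-12)
  }
})

test_that("bin_wilcoxon handles degenerate and structured inputs", {
  set.seed(9)
  vals <- rnorm(8000)
  tr <- make_track(list(c1 = vals))
  os <- origin_set(data.frame(chrom = "c1", center = c(150e3, 250e3)))
  m <- bin_matrix(tr, os)
  # identical matrices: all differences zero -> missing p
  res <- bin_wilcoxon(m, m)
  expect_true(all(is.na(res$p)))
  # constant +1 shift with 30 origins: strongly significant, direction +1
  os30 <- origin_set(data.frame(chrom = "c1",
                                center = seq(110e3, 290e3, length.out = 30)))
  m30 <- bin_matrix(tr, os30)
  shifted <- with_values(m30, unclass(m30) + 1)
  res30 <- bin_wilcoxon(m30, shifted)
  expect_true(all(res30$p < 1e-5))
  expect_true(all(res30$direction == 1))
  expect_equal(res30$minus_log10_p, -log10(res30$p))
  # BH option adds a monotone q column
  resq <- bin_wilcoxon(m30, shifted, adjust = "BH")
  expect_true(all(resq$q >= resq$p - 1e-15))
})

test_that("origin files are read from TSV and BED, preserving record count", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("chrom\tcenter", "chr2L\t1000000", "chr2L\t2000000", "chr3R\t1500000"),
             path)
  os <- read_origins(path)
  expect_s3_class(os, "origin_set")
  expect_equal(nrow(os), 3L)
  expect_equal(os$center, c(1e6, 2e6, 1.5e6))
  bed <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr2L\t900\t1100\tori1\t0\t.", "chr3R\t0\t200\tori2\t0\t."), bed)
  osb <- read_origins(bed)
  expect_equal(osb$center, c(1000, 100))
})
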