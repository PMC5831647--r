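test_that("element sets enforce the fixed element width", {
  df <- data.frame(chrom = "c1", start = c(0, 600), end = c(500, 1100),
                   class = c("promoter", "enhancer"))
  es <- element_set(df)
  expect_equal(nrow(es), 2L)
  bad <- df
  bad$end[1] <- 400
  expect_error(element_set(bad), "exactly 500 bp")
})

test_that("element means equal the brute-force midpoint oracle", {
  set.seed(4)
  tr <- make_track(list(c1 = rnorm(400), c2 = rnorm(300)))
  starts <- c(sample(0:(400 * 50 + 200 - 500), 30), sample(0:(300 * 50 + 200 - 500), 20))
  es <- element_set(data.frame(
    chrom = rep(c("c1", "c2"), c(30, 20)), start = starts, end = starts + 500,
    class = sample(c("promoter", "enhancer", "PRE"), 50, replace = TRUE)
  ))
  ee <- element_enrichment(tr, es)
  for (i in seq_len(nrow(es))) {
    mid <- anchor_midpoints(tr, es$chrom[i])
    inside <- mid >= es$start[i] & mid < es$end[i]
    expect_equal(ee$value[i], mean(tr$values[[es$chrom[i]]][inside]))
  }
  # constant track: every element value is the constant
  trc <- make_track(list(c1 = rep(2.5, 400), c2 = rep(2.5, 300)))
  expect_true(all(element_enrichment(trc, es)$value == 2.5))
  expect_error(element_enrichment(tr, element_set(
    data.frame(chrom = "c9", start = 0, end = 500, class = "PRE"))), "c9")
})

test_that("elements overlapping no anchor are missing", {
  # chromosome shorter than the window has no anchors at all
  tr <- enrichment_track(list(tiny = numeric(0), c1 = rnorm(100)),
                         250, 50, c(tiny = 240, c1 = 100 * 50 + 200))
  es <- element_set(data.frame(chrom = "tiny", start = 0, end = 500, class = "PRE"))
  expect_true(is.na(element_enrichment(tr, es)$value))
})

test_that("element ratios are linear-domain with class medians", {
  set.seed(14)
  tr1 <- make_track(list(c1 = rnorm(500)))
  tr2 <- make_track(list(c1 = rnorm(500)))
  starts <- seq(0, 24000, by = 1000)
  es <- element_set(data.frame(chrom = "c1", start = starts, end = starts + 500,
                               class = rep(c("promoter", "enhancer"), length.out = 25)))
  a <- element_enrichment(tr1, es)
  b <- element_enrichment(tr2, es)
  same <- element_ratio(a, a)
  expect_true(all(same$ratios$ratio == 1))
  expect_true(all(same$medians$median == 1))
  b2 <- b
  b2$value <- a$value + 1 # denominator = 2x numerator in linear domain
  expect_equal(element_ratio(a, b2)$ratios$ratio, rep(0.5, 25))
  # medians equal the sort-based per-class oracle
  er <- element_ratio(a, b)
  for (k in unique(es$class)) {
    expect_equal(er$medians$median[er$medians$class == k],
                 median(er$ratios$ratio[er$ratios$class == k]))
  }
})

test_that("random control elements respect bounds, count, and exclusions", {
  lens <- c(c1 = 100e3, c2 = 60e3)
  expect_equal(nrow(sample_random_elements(lens, n = 0)), 0L)
  es <- sample_random_elements(lens, n = 1000, seed = 3)
  expect_equal(nrow(es), 1000L)
  expect_true(all(es$end - es$start == 500))
  expect_true(all(es$start >= 0 & es$end <= lens[es$chrom]))
  expect_equal(es, sample_random_elements(lens, n = 1000, seed = 3))
  # exclusion honored, verified by brute-force interval scan
  excl <- data.frame(chrom = "c1", start = seq(0, 90e3, by = 10e3),
                     end = seq(0, 90e3, by = 10e3) + 5000)
  es2 <- sample_random_elements(lens, n = 500, exclude = excl, seed = 5)
  hits <- mapply(function(ch, s, e) {
    any(excl$chrom == ch & excl$start < e & excl$end > s)
  }, es2$chrom, es2$start, es2$end)
  expect_false(any(hits))
  # impossible placement errors out
  all_of_it <- data.frame(chrom = c("c1", "c2"), start = 0, end = c(100e3, 60e3))
  expect_error(sample_random_elements(lens, n = 10, exclude = all_of_it, seed = 1),
               "could not place")
})

test_that("per-class depletion tests detect planted shifts with direction", {
  set.seed(6)
  tr <- make_track(list(c1 = rnorm(3000)))
  starts <- seq(0, 99000, by = 1000)
  es <- element_set(data.frame(chrom = "c1", start = starts, end = starts + 500,
                               class = rep(c("promoter", "enhancer"), 50)))
  mock <- element_enrichment(tr, es)
  dep <- mock
  dep$value <- dep$value + ifelse(es$class == "promoter", 1, 0) +
    rnorm(100, 0, 0.01)
  res <- class_depletion_test(mock, dep)
  pro <- res[res$class == "promoter", ]
  expect_lt(pro$p, 1e-9)
  expect_equal(pro$direction, 1)
  expect_gt(pro$median_diff, 0.9)
  # identical values: zero differences dropped, p missing
  same <- class_depletion_test(mock, mock)
  expect_true(all(is.na(same$p)))
})

test_that("constant promoter shift of +1 on 100 elements is overwhelmingly significant", {
  set.seed(44)
  tr <- make_track(list(c1 = rnorm(3000)))
  starts <- seq(0, 99000, by = 1000)
  es <- element_set(data.frame(chrom = "c1", start = starts, end = starts + 500,
                               class = "promoter"))
  mock <- element_enrichment(tr, es)
  dep <- mock
  dep$value <- dep$value + 1
  res <- class_depletion_test(mock, dep)
  expect_lt(res$p, 1e-15)
  expect_equal(res$direction, 1)
})
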