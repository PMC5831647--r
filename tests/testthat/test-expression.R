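make_expr <- function(values, condition) {
  rownames(values) <- sprintf("g%03d", seq_len(nrow(values)))
  expression_matrix(values, condition)
}

test_that("contrast is zero when depleted equals mock and BH keeps q >= p", {
  set.seed(1)
  base <- matrix(rlnorm(200 * 3, log(50), 1), 200, 3)
  expr <- make_expr(cbind(base, base), c(rep("mock", 3), rep("iPds5", 3)))
  ct <- contrast(expr, "iPds5")
  expect_true(all(ct$log2fc == 0))
  expect_true(all(ct$q >= ct$p - 1e-15, na.rm = TRUE))
  expect_error(contrast(expr, "iWapl"), "not found")
  one_rep <- make_expr(cbind(base, base[, 1, drop = FALSE]),
                       c(rep("mock", 3), "iPds5"))
  expect_error(contrast(one_rep, "iPds5"), "2 replicates")
})

test_that("per-gene Welch test matches t.test and BH matches p.adjust", {
  set.seed(2)
  m <- matrix(rlnorm(50 * 9, log(30), 0.8), 50, 9)
  cond <- c(rep("mock", 6), rep("dep", 3))
  expr <- make_expr(m, cond)
  ct <- contrast(expr, "dep")
  lg <- log2(m + 1)
  for (i in c(1, 7, 23, 50)) {
    ref <- t.test(lg[i, cond == "dep"], lg[i, cond == "mock"])$p.value
    expect_equal(ct$p[i], ref, tolerance = 1e-12)
  }
  expect_equal(ct$q, p.adjust(ct$p, "BH"))
})

test_that("estimated fold-changes recover the planted truth (r >= 0.9)", {
  model <- expression_model(n_genes = 5000)
  sim <- simulate_expression(model, seed = 10)
  ct <- contrast(sim$expr, "iPds5")
  r <- cor(ct$log2fc, sim$truth[, "iPds5"])
  expect_gt(r, 0.9)
})

test_that("contrast correlation behaves on identity, nulls, and planted correlation", {
  sim <- simulate_expression(expression_model(n_genes = 5000), seed = 21)
  c1 <- contrast(sim$expr, "iPds5")
  c2 <- contrast(sim$expr, "iBrca2")
  expect_equal(correlate_contrasts(c1, c1), 1)
  # independent effects: correlation near zero
  sim0 <- simulate_expression(expression_model(n_genes = 5000, effect_cor = 0),
                              seed = 22)
  r0 <- correlate_contrasts(contrast(sim0$expr, "iPds5"),
                            contrast(sim0$expr, "iBrca2"))
  expect_lt(abs(r0), 0.08)
  # planted correlation 0.6 recovered within 0.1 despite estimation noise
  r6 <- correlate_contrasts(c1, c2)
  expect_lt(abs(r6 - 0.6), 0.1)
})

test_that("Fisher overlaps match hypergeometric enumeration on random tables", {
  set.seed(3)
  for (i in 1:200) {
    tab <- matrix(sample(0:30, 4, replace = TRUE), 2)
    if (sum(tab) == 0) next
    expect_equal(fisher.test(tab)$p.value, oracle_fisher_p(tab), tolerance = 1e-9)
  }
  expect_equal(fisher.test(matrix(1, 2, 2))$p.value, 1)
})

test_that("overlap analysis partitions genes and flags self-overlap", {
  sim <- simulate_expression(expression_model(n_genes = 2000), seed = 30)
  c1 <- contrast(sim$expr, "iPds5")
  c2 <- contrast(sim$expr, "iBrca2")
  ov <- overlap_analysis(c1, c2)
  expect_equal(ov$universe_size, 2000L)
  with(ov$overlaps, {
    expect_true(all(n_both <= pmin(n_a, n_b)))
    expect_true(all(n_discordant <= n_a))
  })
  self <- overlap_analysis(c1, c1)
  expect_equal(self$overlaps$n_both, self$overlaps$n_a)
  expect_true(all(self$overlaps$fisher_p_greater[self$overlaps$n_a > 0] < 1e-10))
  # empty significant sets: overlap 0, Fisher p = 1
  c_none <- c1
  c_none$p <- rep(1, nrow(c_none))
  ov0 <- overlap_analysis(c_none, c2)
  expect_equal(ov0$overlaps$n_both, c(0L, 0L))
  expect_equal(ov0$overlaps$fisher_p_two_sided, c(1, 1))
})

test_that("wing-disc active-gene rule is the union over the control median", {
  set.seed(4)
  G <- 101
  cm <- matrix(rlnorm(G * 2), G, 2)
  mm <- matrix(rlnorm(G * 2), G, 2)
  rownames(cm) <- rownames(mm) <- sprintf("g%03d", 1:G)
  got <- active_genes(cm, mm)
  med <- median(rowMeans(cm))
  want <- rownames(cm)[rowMeans(cm) >= med | rowMeans(mm) >= med]
  expect_equal(got, want)
  # mutant == control reduces to genes at/above the control median
  same <- active_genes(cm, cm)
  expect_equal(same, rownames(cm)[rowMeans(cm) >= med])
  expect_equal(length(same), ceiling(G / 2))
  # a gene high only in the mutant is included via the union clause
  mm2 <- cm
  low <- setdiff(rownames(cm), same)[1]
  mm2[low, ] <- max(cm) * 2
  expect_true(low %in% active_genes(cm, mm2))
  expect_error(active_genes(cm[0, , drop = FALSE], mm), "empty")
})

test_that("expression matrices round-trip through TSV", {
  sim <- simulate_expression(expression_model(n_genes = 40), seed = 5)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_expression_tsv(sim$expr, path)
  back <- read_expression_tsv(path)
  expect_equal(back$values, sim$expr$values, tolerance = 1e-6)
  expect_equal(back$condition, sim$expr$condition)
})
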