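test_that("genome simulation is deterministic and respects bounds", {
  spec <- genome_spec(c(chr1 = 2e6), n_origins = 1, seed = 7)
  a1 <- simulate_genome(spec)
  a2 <- simulate_genome(spec)
  expect_identical(a1$origins, a2$origins)
  expect_identical(a1$genes, a2$genes)
  expect_identical(a1$elements, a2$elements)
  # empty origin set is a valid bundle
  a0 <- simulate_genome(genome_spec(c(chr1 = 1e6), n_origins = 0, seed = 1))
  expect_equal(nrow(a0$origins), 0L)
  # two chromosomes, 10 origins: every coordinate within bounds, by scan
  ann <- simulate_genome(genome_spec(c(c1 = 3e6, c2 = 2e6), n_origins = 10, seed = 2))
  expect_equal(nrow(ann$origins), 10L)
  for (i in seq_len(nrow(ann$origins))) {
    L <- ann$chrom_lengths[[ann$origins$chrom[i]]]
    expect_true(ann$origins$center[i] >= 2e5 && ann$origins$center[i] <= L - 2e5)
  }
  expect_true(all(ann$elements$start >= 0))
  expect_true(all(ann$elements$end <= ann$chrom_lengths[ann$elements$chrom]))
  expect_true(all(ann$elements$end - ann$elements$start == 500))
  expect_error(genome_spec(c(c1 = 1e6), origin_positions = list(c1 = 999e3)),
               "bounds")
  expect_error(genome_spec(c(c1 = 500)), ">= 1 kb")
})

test_that("annotation BED files are written with activity and class fields", {
  ann <- small_annotation()
  dir <- withr::local_tempdir()
  paths <- write_annotation_bed(ann, dir)
  genes <- read.table(file.path(dir, "genes.bed"), sep = "\t")
  expect_equal(nrow(genes), nrow(ann$genes))
  expect_equal(genes$V5, as.integer(ann$genes$active))
  els <- read.table(file.path(dir, "elements.bed"), sep = "\t")
  expect_setequal(unique(els$V4), unique(ann$elements$class))
})

test_that("simulated coverage is integer, non-negative, at the requested depth", {
  ann <- small_annotation()
  m <- occupancy_model("Rad21", depth = 10, dispersion = 0)
  pair <- simulate_chip_pair(ann, m, seed = 3, input_depth = 20)
  for (v in pair$chip$coverage) {
    expect_true(all(v >= 0))
    expect_true(all(v == floor(v)))
  }
  nb <- sum(as.numeric(ann$chrom_lengths))
  expect_lt(abs(pair$chip$total / (10 * nb) - 1), 0.05)
  expect_lt(abs(pair$input$total / (20 * nb) - 1), 0.05)
  # determinism for a fixed seed
  pair2 <- simulate_chip_pair(ann, m, seed = 3, input_depth = 20)
  expect_identical(pair$chip$coverage, pair2$chip$coverage)
  expect_identical(pair$input$coverage, pair2$input$coverage)
})

test_that("active-gene gating keeps inactive genes at scaled baseline depth", {
  ann <- small_annotation(seed = 11, n_chrom = 2, chrom_length = 1e6, n_origins = 3)
  m <- occupancy_model("Rad21", depth = 30, dispersion = 0)
  pair <- simulate_chip_pair(ann, m, seed = 5)
  rel <- expected_occupancy(ann, m)
  inact <- ann$genes[!ann$genes$active, ]
  obs <- exp_depth <- 0
  for (i in seq_len(nrow(inact))) {
    idx <- (inact$start[i] + 1):inact$end[i]
    obs <- obs + sum(pair$chip$coverage[[inact$chrom[i]]][idx])
    exp_depth <- exp_depth + sum(30 * rel[[inact$chrom[i]]][idx])
  }
  expect_lt(abs(obs / exp_depth - 1), 0.1)
  # expected occupancy over inactive genes is the flat scaled baseline
  inact_rel <- unlist(lapply(seq_len(nrow(inact)), function(i) {
    rel[[inact$chrom[i]]][(inact$start[i] + 1):inact$end[i]]
  }))
  expect_lt(diff(range(inact_rel)), 1e-12)
})

test_that("zero amplitude gives a null model with enrichment about zero", {
  ann <- small_annotation(seed = 12)
  m <- occupancy_model("flat", amplitude = 0, depth = 30, dispersion = 0)
  pair <- simulate_chip_pair(ann, m, seed = 6, input_depth = 30)
  e <- compute_enrichment(pair$chip, pair$input)
  expect_lt(abs(mean(unlist(e$values))), 0.02)
  expect_lt(sd(unlist(e$values)), 0.5)
})

test_that("planted decay scale is recovered from the noise-free track within 5%", {
  lens <- c(c1 = 3e6)
  ann <- simulate_genome(genome_spec(lens, origin_positions = list(c1 = 1.5e6),
                                     seed = 3))
  m <- occupancy_model("Rad21", baseline = 0.5, amplitude = 4, decay_bp = 25000,
                       gate_active = FALSE)
  e <- expected_enrichment_track(ann, m)
  mid <- anchor_midpoints(e, "c1")
  d <- abs(mid - 1.5e6)
  keep <- d < 2e5
  lin <- 2^e$values$c1[keep]
  fit <- nls(y ~ a + b * exp(-x / s), data.frame(y = lin, x = d[keep]),
             start = list(a = min(lin), b = max(lin) - min(lin), s = 2e4))
  expect_lt(abs(coef(fit)[["s"]] / 25000 - 1), 0.05)
})

test_that("calibrated dispersion lands replicate correlation in the reported band", {
  ann <- small_annotation(seed = 13, n_chrom = 3, chrom_length = 1e6, n_origins = 5)
  m <- occupancy_model("Rad21")
  cal <- calibrate_dispersion(ann, m, seed = 4)
  m$dispersion <- cal$dispersion
  p1 <- simulate_chip_pair(ann, m, seed = 41)
  p2 <- simulate_chip_pair(ann, m, seed = 42)
  r <- replicate_correlation(compute_enrichment(p1$chip, p1$input),
                             compute_enrichment(p2$chip, p2$input))
  expect_gt(r, 0.65)
  expect_lt(r, 0.9)
})

test_that("expression generator hits its correlation, noise, and degenerate contracts", {
  model <- expression_model(n_genes = 5000, effect_cor = 0.6)
  sim <- simulate_expression(model, seed = 31)
  # same seed reproduces byte-identical output
  sim2 <- simulate_expression(model, seed = 31)
  expect_identical(sim$expr$values, sim2$expr$values)
  # planted effect correlation within 0.05 of target
  r <- cor(sim$truth[, 1], sim$truth[, 2])
  expect_lt(abs(r - 0.6), 0.05)
  # replicate correlation of log expression above 0.95
  lg <- log2(sim$expr$values + 1)
  mocks <- which(sim$expr$condition == "mock")
  expect_gt(cor(lg[, mocks[1]], lg[, mocks[2]]), 0.95)
  # zero effect SD: truth is exactly zero
  sim0 <- simulate_expression(expression_model(n_genes = 100, effect_sd = 0),
                              seed = 1)
  expect_true(all(sim0$truth == 0))
  expect_error(expression_model(n_reps = 1), "2 replicates")
  expect_error(expression_model(effect_cor = 1.5), "effect_cor")
})

test_that("fiber generator honors stall factor, positivity, and empty tables", {
  m <- fiber_model(n = 500, stall_factor = 1)
  t1 <- simulate_fibers(m, seed = 51)
  expect_true(all(t1$idu_length_um > 0 & t1$cldu_length_um > 0))
  expect_lt(abs(median(t1$cldu_length_um / t1$idu_length_um) - 1), 0.05)
  m5 <- fiber_model(n = 500, stall_factor = 0.5)
  t5 <- simulate_fibers(m5, treated = TRUE, seed = 52)
  expect_lt(abs(median(t5$cldu_length_um / t5$idu_length_um) - 0.5), 0.05)
  # untreated rows ignore the stall factor
  t5u <- simulate_fibers(m5, treated = FALSE, seed = 52)
  expect_lt(abs(median(t5u$cldu_length_um / t5u$idu_length_um) - 1), 0.05)
  empty <- simulate_fibers(fiber_model(n = 0), seed = 1)
  expect_equal(nrow(empty), 0L)
  expect_identical(simulate_fibers(m, seed = 7), simulate_fibers(m, seed = 7))
  expect_error(fiber_model(stall_factor = 1.5), "stall_factor")
})
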