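#' Configuration for an end-to-end synthetic depletion run
#'
#' Bundles the synthetic genome spec, occupancy/expression/fiber models and
#' all analysis parameters. Analysis defaults are the standard parameters of
#' the method: 250/50 bp windows, 95th percentile over >= 300 bp for region
#' calling, +/-100 kb meta-origin window in 10 kb bins, alpha 0.05.
#'
#' @param seed Master integer seed; all stage seeds derive from it.
#' @param n_chrom,chrom_length,n_origins Synthetic genome shape (defaults:
#'   5 chromosomes of 1.2 Mb with 20 origins).
#' @param window,step,pseudocount Enrichment parameters.
#' @param percentile,min_len Region-calling parameters.
#' @param flank,bin Meta-origin parameters.
#' @param alpha Significance threshold for overlap gene sets.
#' @param chip_depth,input_depth Sequencing depths (x coverage).
#' @param dispersion Replicate noise dispersion for the ChIP simulations.
#' @param n_random_elements Random 500 bp control elements to sample.
#' @param write_tracks Also write enrichment bedGraph files (slower)?
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L, n_chrom = 5L, chrom_length = 1.2e6,
                            n_origins = 20L, window = 250L, step = 50L,
                            pseudocount = 1, percentile = 95, min_len = 300L,
                            flank = 1e5, bin = 1e4, alpha = 0.05,
                            chip_depth = 10, input_depth = 45,
                            dispersion = 0.25, n_random_elements = 300L,
                            write_tracks = FALSE) {
  cfg <- structure(
    list(seed = as.integer(seed), n_chrom = as.integer(n_chrom),
         chrom_length = chrom_length, n_origins = as.integer(n_origins),
         window = as.integer(window), step = as.integer(step),
         pseudocount = pseudocount, percentile = percentile,
         min_len = as.integer(min_len), flank = flank, bin = bin,
         alpha = alpha, chip_depth = chip_depth, input_depth = input_depth,
         dispersion = dispersion,
         n_random_elements = as.integer(n_random_elements),
         write_tracks = isTRUE(write_tracks)),
    class = "pipeline_config"
  )
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  pos <- c("n_chrom", "chrom_length", "n_origins", "window", "step", "flank",
           "bin", "min_len", "chip_depth", "input_depth")
  for (f in pos) {
    if (!is.numeric(cfg[[f]]) || length(cfg[[f]]) != 1L || is.na(cfg[[f]]) ||
        cfg[[f]] <= 0) {
      stopf("config field `%s` must be a single positive number", f)
    }
  }
  if (cfg$percentile <= 0 || cfg$percentile > 100) {
    stop("config field `percentile` must be in (0, 100]")
  }
  if (cfg$alpha <= 0 || cfg$alpha > 1) stop("config field `alpha` must be in (0, 1]")
  if (cfg$window < cfg$step) stop("config: `window` must be >= `step`")
  if (cfg$dispersion < 0) stop("config field `dispersion` must be >= 0")
  if (cfg$pseudocount < 0) stop("config field `pseudocount` must be >= 0")
  if (cfg$n_random_elements < 0) stop("config field `n_random_elements` must be >= 0")
  invisible(cfg)
}

#' Read a pipeline configuration from JSON or YAML
#'
#' Fields missing from the file take the [pipeline_config()] defaults;
#' unknown fields are an error. Validation happens before any computation.
#'
#' @param path Path to a `.json`, `.yaml` or `.yml` file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  known <- names(formals(pipeline_config))
  bad <- setdiff(names(raw), known)
  if (length(bad)) stopf("unknown config field(s): %s", paste(bad, collapse = ", "))
  do.call(pipeline_config, raw)
}

#' Run the full synthetic depletion experiment
#'
#' One command reproduces a complete analysis on synthetic data with ground
#' truth: simulate a genome, mock and Pds5-depletion-style ChIP/input pairs
#' for the cohesin ring (Rad21) and SA subunits, compute enrichment, call
#' and intersect binding regions, run the meta-origin profile / ratio /
#' Wilcoxon analyses, quantify element enrichment with per-class depletion
#' tests, contrast synthetic depletion expression with Fisher overlaps, and
#' compare fiber tract statistics. All tables are written as TSV/BED under
#' `out_dir` together with a parameter log; outputs are deterministic for a
#' fixed config.
#'
#' @param config A [pipeline_config()] (or path handled by
#'   [read_pipeline_config()]).
#' @param out_dir Output directory (created; partial outputs of a failed
#'   run are retained).
#' @return Invisibly, a list with all in-memory stage results.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  validate_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "pipeline.log")
  log_line <- function(...) {
    msg <- paste0(format(Sys.time(), "%H:%M:%S"), " ", ...)
    cat(msg, "\n", file = log_path, append = TRUE, sep = "")
    message(msg)
  }
  stage <- function(name, expr) {
    log_line("stage ", name, " started")
    tryCatch(expr, error = function(e) {
      stopf("pipeline stage `%s` failed: %s", name, conditionMessage(e))
    })
  }
  cat("", file = log_path)
  log_line("config: ", jsonlite::toJSON(unclass(config), auto_unbox = TRUE))
  res <- list(config = config)

  res$annotation <- stage("simulate-genome", {
    lens <- stats::setNames(rep(config$chrom_length, config$n_chrom),
                            paste0("chr", seq_len(config$n_chrom)))
    ann <- simulate_genome(genome_spec(lens, n_origins = config$n_origins,
                                       seed = derive_seed(config$seed, 1L)))
    write_annotation_bed(ann, out_dir)
    ann
  })
  ann <- res$annotation
  origins <- origin_set(ann$origins)

  # Factor models: the ring subunit and SA; Pds5-loss-style condition
  # extends domains (decay x2, flank x1.5) and drains SA from origin centers.
  models <- list(
    Rad21 = occupancy_model("Rad21", dispersion = config$dispersion,
                            depth = config$chip_depth),
    SA = occupancy_model("SA", dispersion = config$dispersion,
                         depth = config$chip_depth)
  )
  conds <- list(
    mock = list(Rad21 = condition_modifiers("mock"),
                SA = condition_modifiers("mock")),
    iPds5 = list(
      Rad21 = condition_modifiers("iPds5", decay_mult = 2, flank_amp_mult = 1.5),
      SA = condition_modifiers("iPds5", decay_mult = 2, flank_amp_mult = 1.5,
                               origin_amp_mult = 0.5)
    )
  )
  res$enrichment <- stage("enrich", {
    out <- list()
    k <- 10L
    for (cond in names(conds)) {
      for (fac in names(models)) {
        k <- k + 1L
        pair <- simulate_chip_pair(ann, models[[fac]], conds[[cond]][[fac]],
                                   input_depth = config$input_depth,
                                   seed = derive_seed(config$seed, k))
        tr <- compute_enrichment(pair$chip, pair$input, config$window,
                                 config$step, config$pseudocount)
        tr$samples <- paste(fac, cond, sep = "_")
        if (config$write_tracks) {
          write_enrichment_bedgraph(
            tr, file.path(out_dir, paste0("enrichment_", fac, "_", cond, ".bedGraph")))
        }
        out[[paste(fac, cond, sep = "_")]] <- tr
      }
    }
    out
  })
  enr <- res$enrichment

  res$regions <- stage("call-regions", {
    ra <- call_regions(enr$Rad21_mock, config$percentile, config$min_len)
    rb <- call_regions(enr$SA_mock, config$percentile, config$min_len)
    write_regions_bed(ra, file.path(out_dir, "regions_Rad21_mock.bed"))
    write_regions_bed(rb, file.path(out_dir, "regions_SA_mock.bed"))
    rep <- intersect_region_sets(ra, rb)
    utils::write.table(
      data.frame(n_a = rep$n_a, n_b = rep$n_b, n_overlap = rep$n_overlap,
                 fraction_pct = rep$fraction_pct),
      file.path(out_dir, "region_overlap.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
    list(Rad21 = ra, SA = rb, overlap = rep)
  })

  res$metaorigin <- stage("metaorigin", {
    bm <- lapply(enr, bin_matrix, origins = origins, flank = config$flank,
                 bin = config$bin)
    prof <- mean_profile(bm$Rad21_mock)
    wt <- bin_wilcoxon(bm$Rad21_mock, bm$Rad21_iPds5)
    rat_mock <- ratio_profile(bm$SA_mock, bm$Rad21_mock)
    rat_dep <- ratio_profile(bm$SA_iPds5, bm$Rad21_iPds5)
    write_profile_tsv(prof, file.path(out_dir, "metaorigin_profile_Rad21_mock.tsv"))
    write_profile_tsv(wt, file.path(out_dir, "metaorigin_wilcoxon_Rad21.tsv"))
    write_profile_tsv(rat_mock, file.path(out_dir, "metaorigin_ratio_SA_Rad21_mock.tsv"))
    write_profile_tsv(rat_dep, file.path(out_dir, "metaorigin_ratio_SA_Rad21_iPds5.tsv"))
    list(bin_matrices = bm, profile = prof, wilcoxon = wt,
         ratio_mock = rat_mock, ratio_iPds5 = rat_dep)
  })

  res$elements <- stage("elements", {
    els <- element_set(ann$elements)
    rnd <- sample_random_elements(ann, n = config$n_random_elements,
                                  seed = derive_seed(config$seed, 30L))
    all_els <- element_set(rbind(as.data.frame(els)[, -1L],
                                 as.data.frame(rnd)[, -1L]))
    em <- element_enrichment(enr$Rad21_mock, all_els)
    ed <- element_enrichment(enr$Rad21_iPds5, all_els)
    test <- class_depletion_test(em, ed)
    rat <- element_ratio(element_enrichment(enr$SA_mock, all_els), em)
    utils::write.table(test, file.path(out_dir, "element_depletion_test.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(rat$medians, file.path(out_dir, "element_ratio_medians.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    list(enrichment_mock = em, enrichment_iPds5 = ed, depletion_test = test,
         ratio = rat)
  })

  res$expression <- stage("expression", {
    sim <- simulate_expression(expression_model(),
                               seed = derive_seed(config$seed, 40L))
    write_expression_tsv(sim$expr, file.path(out_dir, "expression.tsv"))
    c1 <- contrast(sim$expr, "iPds5")
    c2 <- contrast(sim$expr, "iBrca2")
    write_contrast_tsv(c1, file.path(out_dir, "contrast_iPds5.tsv"))
    write_contrast_tsv(c2, file.path(out_dir, "contrast_iBrca2.tsv"))
    r <- correlate_contrasts(c1, c2)
    ov <- overlap_analysis(c1, c2, alpha = config$alpha)
    utils::write.table(
      cbind(data.frame(universe = ov$universe_size), ov$overlaps),
      file.path(out_dir, "expression_overlap.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
    list(sim = sim, iPds5 = c1, iBrca2 = c2, fc_correlation = r, overlap = ov)
  })

  res$fibers <- stage("fibers", {
    f_mock <- simulate_fibers(fiber_model(), treated = FALSE,
                              seed = derive_seed(config$seed, 50L), group = "mock")
    f_hu <- simulate_fibers(fiber_model(stall_factor = 0.5), treated = TRUE,
                            seed = derive_seed(config$seed, 51L), group = "mock_HU")
    tbl <- rbind(f_mock, f_hu)
    write_fibers_csv(tbl, file.path(out_dir, "fibers.csv"))
    cmp <- compare_groups(tbl, "mock", "mock_HU", quantity = "ratio")
    utils::write.table(
      data.frame(group_a = "mock", group_b = "mock_HU", quantity = cmp$quantity,
                 median_a = cmp$median_a, median_b = cmp$median_b, p = cmp$p),
      file.path(out_dir, "fiber_comparison.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
    list(table = tbl, comparison = cmp)
  })

  log_line("pipeline finished")
  invisible(res)
}
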