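#' Expression effect model for synthetic depletion RNA-seq
#'
#' Each depletion's true per-gene log2 fold-change vector is drawn from a
#' shared latent effect plus independent noise, giving a target pairwise
#' correlation between depletions; only a fraction of genes (the same set
#' across depletions) is affected at all. Observed replicate values are the
#' baseline expression (log-normal "mean normalized nucleotide coverage per
#' gene") times 2^effect, times log-normal replicate noise.
#'
#' @param n_genes Number of genes.
#' @param depletions Character vector of depletion condition labels.
#' @param effect_cor Target pairwise correlation of the true effect vectors,
#'   in \[-1, 1\].
#' @param effect_sd SD of the true log2 fold-change among affected genes.
#' @param affected_fraction Fraction of genes with any true effect.
#' @param rep_noise_sd Replicate noise SD on the log2 scale.
#' @param n_reps Replicates per depletion (>= 2).
#' @param n_mock Mock control replicates (>= 2).
#' @param baseline_meanlog,baseline_sdlog Log-normal parameters of baseline
#'   coverage per gene.
#' @return An object of class `expression_model`.
#' @export
expression_model <- function(n_genes = 5000L, depletions = c("iPds5", "iBrca2"),
                             effect_cor = 0.6, effect_sd = 0.9,
                             affected_fraction = 0.4, rep_noise_sd = 0.25,
                             n_reps = 3L, n_mock = 6L,
                             baseline_meanlog = log(50), baseline_sdlog = 1) {
  if (effect_cor < -1 || effect_cor > 1) stop("`effect_cor` must be in [-1, 1]")
  if (n_reps < 2L || n_mock < 2L) {
    stop("at least 2 replicates per condition are required (contrast untestable otherwise)")
  }
  if (effect_sd < 0 || rep_noise_sd < 0 || affected_fraction < 0 ||
      affected_fraction > 1) {
    stop("effect_sd/rep_noise_sd must be >= 0 and affected_fraction in [0, 1]")
  }
  structure(
    list(n_genes = as.integer(n_genes), depletions = depletions,
         effect_cor = effect_cor, effect_sd = effect_sd,
         affected_fraction = affected_fraction, rep_noise_sd = rep_noise_sd,
         n_reps = as.integer(n_reps), n_mock = as.integer(n_mock),
         baseline_meanlog = baseline_meanlog, baseline_sdlog = baseline_sdlog),
    class = "expression_model"
  )
}

#' Simulate an expression matrix with known depletion effects
#'
#' @param model An [expression_model()].
#' @param seed Integer seed.
#' @return List with `expr` (an [expression_matrix()]: genes x samples mean
#'   normalized nucleotide coverage, mock columns first) and `truth`
#'   (genes x depletions matrix of true log2 fold-changes).
#' @export
simulate_expression <- function(model, seed = 1L) {
  stopifnot(inherits(model, "expression_model"))
  with_seed(seed, {
    G <- model$n_genes
    K <- length(model$depletions)
    genes <- sprintf("gene%05d", seq_len(G))
    mu <- stats::rlnorm(G, model$baseline_meanlog, model$baseline_sdlog)
    affected <- stats::runif(G) < model$affected_fraction
    z <- stats::rnorm(G)
    rho <- model$effect_cor
    b <- sqrt(1 - abs(rho))
    truth <- vapply(seq_len(K), function(k) {
      # negative target correlation: flip the shared component on even-index
      # depletions (exact for two depletions, the usual paired contrast)
      a <- sqrt(abs(rho)) * (if (rho < 0 && k %% 2L == 0L) -1 else 1)
      model$effect_sd * as.numeric(affected) * (a * z + b * stats::rnorm(G))
    }, numeric(G))
    colnames(truth) <- model$depletions
    rownames(truth) <- genes
    cols <- list()
    cond <- character(0)
    for (r in seq_len(model$n_mock)) {
      cols[[length(cols) + 1L]] <- mu * 2^stats::rnorm(G, 0, model$rep_noise_sd)
      cond <- c(cond, "mock")
    }
    for (k in seq_len(K)) {
      for (r in seq_len(model$n_reps)) {
        cols[[length(cols) + 1L]] <-
          mu * 2^(truth[, k] + stats::rnorm(G, 0, model$rep_noise_sd))
        cond <- c(cond, model$depletions[k])
      }
    }
    values <- do.call(cbind, cols)
    rownames(values) <- genes
    colnames(values) <- make.unique(cond, sep = "_r")
    list(expr = expression_matrix(values, cond), truth = truth)
  })
}
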