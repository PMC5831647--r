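#' Expression matrix with sample condition labels
#'
#' Genes x samples matrix of mean normalized nucleotide coverage per gene,
#' with one condition label per sample column.
#'
#' @param values Numeric matrix (genes x samples, non-negative) with gene
#'   rownames.
#' @param condition Character vector of condition labels, one per column.
#' @return An object of class `expression_matrix`.
#' @export
expression_matrix <- function(values, condition) {
  values <- as.matrix(values)
  if (is.null(rownames(values))) stop("`values` needs gene rownames")
  if (length(condition) != ncol(values)) {
    stop("`condition` must have one label per sample column")
  }
  if (any(values < 0, na.rm = TRUE)) stop("expression values must be non-negative")
  structure(list(values = values, condition = as.character(condition)),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat("expression_matrix:", nrow(x$values), "genes x", ncol(x$values),
      "samples (", paste(unique(x$condition), collapse = ", "), ")\n")
  invisible(x)
}

#' Read / write an expression matrix as TSV
#'
#' The TSV has a header row (`gene`, then sample IDs); condition labels are
#' taken from sample IDs by stripping a trailing replicate suffix
#' (`_r<k>`), or supplied explicitly.
#'
#' @param path File path.
#' @param condition Optional explicit condition labels per sample column.
#' @return For `read_expression_tsv`, an [expression_matrix()].
#' @export
read_expression_tsv <- function(path, condition = NULL) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df[[1L]]
  condition <- condition %||% sub("_r[0-9]+$", "", colnames(m))
  expression_matrix(m, condition)
}

#' @rdname read_expression_tsv
#' @param expr An [expression_matrix()].
#' @export
write_expression_tsv <- function(expr, path) {
  stopifnot(inherits(expr, "expression_matrix"))
  df <- data.frame(gene = rownames(expr$values), expr$values,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Depletion-versus-mock expression contrast
#'
#' Per gene: `log2FC = log2((mean(depleted) + pc) / (mean(mock) + pc))`, a
#' Welch two-sample t-test on `log2(coverage + pc)` between the two
#' replicate groups, and Benjamini-Hochberg q values across all tested
#' genes. Genes with zero variance in both groups and equal means are
#' untestable and get a missing p.
#'
#' @param expr An [expression_matrix()].
#' @param depleted Condition label of the depletion samples.
#' @param mock Condition label of the control samples (default `"mock"`).
#' @param pseudocount Added to coverage before logs and ratios (default 1).
#' @return data.frame of class `depletion_contrast` with columns `gene`,
#'   `log2fc`, `p`, `q`; the contrast labels are kept in attributes.
#' @export
contrast <- function(expr, depleted, mock = "mock", pseudocount = 1) {
  stopifnot(inherits(expr, "expression_matrix"))
  for (lab in c(depleted, mock)) {
    if (!lab %in% expr$condition) stopf("condition label not found: %s", lab)
  }
  xd <- expr$values[, expr$condition == depleted, drop = FALSE]
  xm <- expr$values[, expr$condition == mock, drop = FALSE]
  if (ncol(xd) < 2L || ncol(xm) < 2L) {
    stop("need at least 2 replicates per condition")
  }
  log2fc <- log2((rowMeans(xd) + pseudocount) / (rowMeans(xm) + pseudocount))
  p <- welch_t_rows(log2(xd + pseudocount), log2(xm + pseudocount))
  data.frame(gene = rownames(expr$values), log2fc = log2fc,
             p = p, q = stats::p.adjust(p, method = "BH"),
             row.names = NULL) -> out
  structure(out, depleted = depleted, mock = mock,
            class = c("depletion_contrast", "data.frame"))
}

# Vectorized Welch t-test p values over matrix rows.
welch_t_rows <- function(a, b) {
  na <- ncol(a); nb <- ncol(b)
  ma <- rowMeans(a); mb <- rowMeans(b)
  va <- rowSums((a - ma)^2) / (na - 1L)
  vb <- rowSums((b - mb)^2) / (nb - 1L)
  se2 <- va / na + vb / nb
  t <- (ma - mb) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1L) + (vb / nb)^2 / (nb - 1L))
  p <- 2 * stats::pt(-abs(t), df)
  p[se2 == 0] <- NA_real_
  p
}

#' Pearson correlation of log2 fold-changes between two contrasts
#'
#' @param a,b [contrast()] results over a shared gene universe.
#' @return Pearson r over the shared genes.
#' @export
correlate_contrasts <- function(a, b) {
  shared <- intersect(a$gene, b$gene)
  if (length(shared) < 3L) stop("fewer than 3 shared genes")
  x <- a$log2fc[match(shared, a$gene)]
  y <- b$log2fc[match(shared, b$gene)]
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("correlation undefined: a contrast has zero fold-change variance")
  }
  stats::cor(x, y)
}

#' Thresholded gene-set overlap between two contrasts
#'
#' Genes of the shared universe are partitioned by significance at `alpha`
#' (on p by default; q gives the stricter FDR sets) and direction of change
#' in each contrast. For the increase/increase and decrease/decrease
#' overlaps a 2x2 Fisher's exact test against the shared universe is
#' reported (two-sided and one-sided enrichment). Empty significant sets
#' give overlap 0 with Fisher p = 1.
#'
#' @param a,b [contrast()] results.
#' @param alpha Significance threshold (default 0.05).
#' @param use `"p"` (default; larger gene groups) or `"q"`.
#' @return An object of class `overlap_table`: list with `universe_size`,
#'   `counts` (per-contrast up/down counts), and `overlaps` (data.frame
#'   with concordant and discordant counts and Fisher p values).
#' @export
overlap_analysis <- function(a, b, alpha = 0.05, use = c("p", "q")) {
  use <- match.arg(use)
  shared <- intersect(a$gene, b$gene)
  if (length(shared) == 0L) stop("no shared genes")
  ia <- match(shared, a$gene); ib <- match(shared, b$gene)
  sig_a <- !is.na(a[[use]][ia]) & a[[use]][ia] <= alpha
  sig_b <- !is.na(b[[use]][ib]) & b[[use]][ib] <= alpha
  up_a <- sig_a & a$log2fc[ia] > 0; dn_a <- sig_a & a$log2fc[ia] < 0
  up_b <- sig_b & b$log2fc[ib] > 0; dn_b <- sig_b & b$log2fc[ib] < 0
  fisher2x2 <- function(x, y) {
    tab <- matrix(c(sum(x & y), sum(x & !y), sum(!x & y), sum(!x & !y)), 2L)
    list(two_sided = stats::fisher.test(tab, alternative = "two.sided")$p.value,
         greater = stats::fisher.test(tab, alternative = "greater")$p.value)
  }
  f_up <- fisher2x2(up_a, up_b)
  f_dn <- fisher2x2(dn_a, dn_b)
  overlaps <- data.frame(
    direction = c("increase", "decrease"),
    n_a = c(sum(up_a), sum(dn_a)),
    n_b = c(sum(up_b), sum(dn_b)),
    n_both = c(sum(up_a & up_b), sum(dn_a & dn_b)),
    n_discordant = c(sum(up_a & dn_b), sum(dn_a & up_b)),
    fisher_p_two_sided = c(f_up$two_sided, f_dn$two_sided),
    fisher_p_greater = c(f_up$greater, f_dn$greater)
  )
  structure(list(universe_size = length(shared), alpha = alpha, use = use,
                 overlaps = overlaps),
            class = "overlap_table")
}

#' @export
print.overlap_table <- function(x, ...) {
  cat("overlap_table: universe", x$universe_size, "genes,",
      x$use, "<=", x$alpha, "\n")
  print(x$overlaps)
  invisible(x)
}

#' Wing-disc active-gene rule
#'
#' Active genes are the union of genes expressed at or above the median
#' level in control samples and genes expressed at or above the *control*
#' median in mutant samples.
#'
#' @param control,mutant [expression_matrix()]s (or plain matrices with gene
#'   rownames) over the same genes.
#' @return Character vector of active gene names.
#' @export
active_genes <- function(control, mutant) {
  get_values <- function(x) if (inherits(x, "expression_matrix")) x$values else as.matrix(x)
  cm <- get_values(control); mm <- get_values(mutant)
  if (nrow(cm) == 0L || nrow(mm) == 0L) stop("empty expression matrix")
  if (!identical(rownames(cm), rownames(mm))) {
    shared <- intersect(rownames(cm), rownames(mm))
    if (length(shared) == 0L) stop("no shared genes")
    cm <- cm[shared, , drop = FALSE]; mm <- mm[shared, , drop = FALSE]
  }
  c_mean <- rowMeans(cm); m_mean <- rowMeans(mm)
  med <- stats::median(c_mean)
  rownames(cm)[c_mean >= med | m_mean >= med]
}

#' Write a contrast table as TSV
#'
#' @param x A [contrast()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_contrast_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
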