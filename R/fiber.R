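#' Per-fiber label ratios and group medians
#'
#' The ratio of the second-label (CldU) to the connected first-label (IdU)
#' tract length per fiber reports fork progression after the label switch;
#' a stalled fork shortens the second tract and pushes the ratio below 1.
#' Rows with non-positive lengths are rejected with a warning giving their
#' count.
#'
#' @param t Fiber table: data.frame with `idu_length_um`, `cldu_length_um`
#'   and `group` columns (see [simulate_fibers()] / [read_fibers_csv()]).
#' @return List with `ratios` (the retained rows plus a `ratio` column),
#'   `medians` (data.frame group / n / median ratio) and `n_rejected`.
#' @export
tract_ratios <- function(t) {
  if (nrow(t) == 0L) stop("fiber table is empty")
  bad <- !(t$idu_length_um > 0 & t$cldu_length_um > 0)
  if (any(bad)) {
    warning(sum(bad), " row(s) with non-positive tract length rejected")
    t <- t[!bad, , drop = FALSE]
  }
  t$ratio <- t$cldu_length_um / t$idu_length_um
  grp <- sort(unique(t$group))
  medians <- data.frame(
    group = grp,
    n = vapply(grp, function(g) sum(t$group == g), integer(1L)),
    median = vapply(grp, function(g) stats::median(t$ratio[t$group == g]),
                    numeric(1L)),
    row.names = NULL
  )
  list(ratios = t, medians = medians, n_rejected = sum(bad))
}

#' Compare a tract quantity between two fiber groups
#'
#' Two-sided Wilcoxon rank-sum (Mann-Whitney) test of the chosen quantity
#' between two groups of fibers (unpaired: groups are different cells).
#' The exact distribution is used when both groups have at most `exact_max`
#' fibers and no ties; otherwise the normal approximation with tie and
#' continuity correction. Degenerate all-tied data gives p = 1 with a
#' warning.
#'
#' @param t Fiber table.
#' @param group_a,group_b Group labels to compare.
#' @param quantity `"first_length"` (IdU tract length) or `"ratio"`
#'   (CldU/IdU).
#' @param exact_max Largest per-group n for the exact test (default 20).
#' @return List with `p`, `median_a`, `median_b`, `n_a`, `n_b`, `quantity`.
#' @export
compare_groups <- function(t, group_a, group_b,
                           quantity = c("first_length", "ratio"),
                           exact_max = 20L) {
  quantity <- match.arg(quantity)
  tr <- tract_ratios(t)$ratios
  pick <- function(g) {
    r <- tr[tr$group == g, , drop = FALSE]
    if (nrow(r) < 2L) stopf("group %s has fewer than 2 fibers", g)
    if (quantity == "first_length") r$idu_length_um else r$ratio
  }
  x <- pick(group_a); y <- pick(group_b)
  if (length(unique(c(x, y))) == 1L) {
    warning("all values tied between groups; p = 1")
    p <- 1
  } else {
    exact <- length(x) <= exact_max && length(y) <= exact_max &&
      !any(duplicated(c(x, y)))
    p <- suppressWarnings(
      stats::wilcox.test(x, y, alternative = "two.sided", exact = exact,
                         correct = TRUE)$p.value
    )
  }
  list(p = p, median_a = stats::median(x), median_b = stats::median(y),
       n_a = length(x), n_b = length(y), quantity = quantity)
}

#' Read / write fiber tables as CSV
#'
#' Columns: `fiber_id`, `idu_length_um`, `cldu_length_um`, `group`,
#' `hu_treated`.
#'
#' @param path File path.
#' @return For `read_fibers_csv`, the fiber data.frame.
#' @export
read_fibers_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("idu_length_um", "cldu_length_um", "group")
  if (!all(need %in% names(df))) {
    stopf("fiber CSV must contain columns: %s", paste(need, collapse = ", "))
  }
  df
}

#' @rdname read_fibers_csv
#' @param t Fiber data.frame.
#' @export
write_fibers_csv <- function(t, path) {
  utils::write.csv(t, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
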