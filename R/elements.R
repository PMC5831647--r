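#' Set of 500 bp regulatory elements
#'
#' @param df data.frame with columns `chrom`, `start`, `end` (0-based
#'   half-open) and `class` (e.g. promoter / enhancer / PRE / random).
#' @param element_length Required element width in bp (default 500).
#' @return A data.frame of class `element_set` with an `element_id` column.
#' @export
element_set <- function(df, element_length = 500L) {
  need <- c("chrom", "start", "end", "class")
  if (!all(need %in% names(df))) {
    stop("element set needs chrom/start/end/class columns")
  }
  if (nrow(df) && any(df$end - df$start != element_length)) {
    stopf("all elements must be exactly %d bp", as.integer(element_length))
  }
  out <- data.frame(element_id = sprintf("e%05d", seq_len(nrow(df))),
                    chrom = as.character(df$chrom), start = df$start,
                    end = df$end, class = as.character(df$class))
  structure(out, element_length = as.integer(element_length),
            class = c("element_set", "data.frame"))
}

#' Read elements from BED (class in the name field)
#'
#' @param path BED file path (>= 4 columns).
#' @param element_length Required element width in bp.
#' @return An [element_set()].
#' @export
read_elements_bed <- function(path, element_length = 500L) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 4L) stop("element BED needs at least 4 columns (class in name field)")
  element_set(data.frame(chrom = df[[1L]], start = df[[2L]], end = df[[3L]],
                         class = df[[4L]]),
              element_length = element_length)
}

#' Mean enrichment per 500 bp element
#'
#' For each element, the mean of the anchor values whose window midpoint
#' lies within the element. Elements overlapping no anchor get a missing
#' value.
#'
#' @param track An [enrichment_track()].
#' @param elements An [element_set()].
#' @return data.frame of class `element_enrichment` carrying the element
#'   columns plus `value`.
#' @export
element_enrichment <- function(track, elements) {
  stopifnot(inherits(track, "enrichment_track"))
  bad <- setdiff(unique(elements$chrom), names(track$values))
  if (length(bad)) stopf("element(s) on chromosome(s) absent from track: %s",
                         paste(bad, collapse = ","))
  eps <- 1e-6
  vals <- rep(NA_real_, nrow(elements))
  for (ch in unique(elements$chrom)) {
    idx <- which(elements$chrom == ch)
    m <- anchor_midpoints(track, ch)
    v <- track$values[[ch]]
    if (length(m) == 0L) next
    for (i in idx) {
      k <- findInterval(c(elements$start[i] - eps, elements$end[i] - eps), m)
      if (k[2L] > k[1L]) vals[i] <- mean(v[(k[1L] + 1L):k[2L]])
    }
  }
  out <- cbind(as.data.frame(elements), data.frame(value = vals))
  structure(out, class = c("element_enrichment", "data.frame"))
}

check_same_elements <- function(a, b) {
  if (nrow(a) != nrow(b) || !identical(a$chrom, b$chrom) ||
      !identical(a$start, b$start) || !identical(a$class, b$class)) {
    stop("element enrichments are over different element sets")
  }
  invisible(TRUE)
}

#' Per-element factor ratio with class medians
#'
#' The per-element ratio of two factors' mean enrichment, taken in the
#' linear enrichment domain, with the median ratio per element class (the
#' distribution summary conventionally marked on violin plots).
#'
#' @param a,b [element_enrichment()]s over the same element set
#'   (numerator and denominator).
#' @param log2_input Are the enrichment values log2 (default) or linear?
#' @return List with `ratios` (element data.frame plus `ratio`) and
#'   `medians` (data.frame class / n / median).
#' @export
element_ratio <- function(a, b, log2_input = TRUE) {
  check_same_elements(a, b)
  num <- if (log2_input) 2^a$value else a$value
  den <- if (log2_input) 2^b$value else b$value
  den[!is.na(den) & den <= 0] <- NA_real_
  ratios <- a
  ratios$value <- NULL
  ratios$ratio <- num / den
  list(ratios = ratios, medians = class_medians(ratios, "ratio"))
}

class_medians <- function(df, col) {
  cls <- sort(unique(df$class))
  data.frame(
    class = cls,
    n = vapply(cls, function(k) sum(df$class == k & !is.na(df[[col]])), integer(1L)),
    median = vapply(cls, function(k) {
      stats::median(df[[col]][df$class == k], na.rm = TRUE)
    }, numeric(1L)),
    row.names = NULL
  )
}

#' Sample random 500 bp control elements
#'
#' Uniform placement over the included chromosomes (probability proportional
#' to placeable length), optionally rejecting candidates overlapping an
#' exclusion set; placement fails with an error after bounded retries.
#' Deterministic per seed.
#'
#' @param chrom_lengths Named vector of chromosome lengths, or a
#'   `genome_annotation`.
#' @param n Number of elements (default 6892, the full-scale negative
#'   control count).
#' @param length Element width in bp (default 500).
#' @param chromosomes Optional include-list.
#' @param exclude Optional data.frame of intervals (chrom/start/end) that
#'   elements must not overlap. Nothing is excluded by default.
#' @param seed Integer seed.
#' @return An [element_set()] with class `"random"`.
#' @export
sample_random_elements <- function(chrom_lengths, n = 6892L, length = 500L,
                                   chromosomes = NULL, exclude = NULL,
                                   seed = 1L) {
  if (inherits(chrom_lengths, "genome_annotation")) {
    chrom_lengths <- chrom_lengths$chrom_lengths
  }
  if (!is.null(chromosomes)) chrom_lengths <- chrom_lengths[chromosomes]
  if (length(chrom_lengths) == 0L) stop("no chromosomes to place elements on")
  with_seed(seed, {
    pos <- sample_positions(chrom_lengths, n, length, avoid = exclude)
    pos$class <- rep("random", nrow(pos))
    element_set(pos, element_length = length)
  })
}

#' Per-class paired depletion test on element enrichments
#'
#' For each element class, the paired Wilcoxon signed-rank test on
#' `depleted - mock` across elements, with the median values and the
#' direction of the median shift. Zero differences are dropped before
#' ranking; classes with fewer than two usable pairs get a missing p.
#'
#' @param mock,depleted [element_enrichment()]s over the same element set.
#' @param exact_max Largest effective n for the exact null distribution.
#' @return data.frame with one row per class: `class`, `n_pairs`,
#'   `median_mock`, `median_depleted`, `median_diff`, `direction`, `p`.
#' @export
class_depletion_test <- function(mock, depleted, exact_max = 25L) {
  check_same_elements(mock, depleted)
  cls <- sort(unique(mock$class))
  out <- lapply(cls, function(k) {
    i <- mock$class == k
    d <- depleted$value[i] - mock$value[i]
    keep <- !is.na(d)
    med_m <- stats::median(mock$value[i], na.rm = TRUE)
    med_d <- stats::median(depleted$value[i], na.rm = TRUE)
    dd <- d[keep & d != 0]
    p <- if (length(dd) >= 2L) signed_rank_p(dd, exact_max) else NA_real_
    data.frame(class = k, n_pairs = length(dd), median_mock = med_m,
               median_depleted = med_d, median_diff = med_d - med_m,
               direction = if (sum(keep)) sign(stats::median(d[keep])) else NA_real_,
               p = p)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
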