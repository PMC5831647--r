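#' Set of replication-origin centers
#'
#' @param df data.frame with columns `chrom` and `center` (bp).
#' @param label Label for the set.
#' @return An object of class `origin_set` (a data.frame).
#' @export
origin_set <- function(df, label = "origins") {
  if (!all(c("chrom", "center") %in% names(df))) {
    stop("origin set needs `chrom` and `center` columns")
  }
  if (anyNA(df$center) || !is.numeric(df$center)) stop("origin centers must be numeric")
  out <- data.frame(chrom = as.character(df$chrom), center = as.numeric(df$center))
  structure(out, label = label, class = c("origin_set", "data.frame"))
}

#' Read origin positions from BED or two-column TSV
#'
#' Accepts a BED file (>= 3 columns; the interval midpoint becomes the
#' center) or a two-column `chrom<TAB>center` table. A single header line
#' whose second field is non-numeric is skipped.
#'
#' @param path File path.
#' @param label Label for the set.
#' @return An [origin_set()].
#' @export
read_origins <- function(path, label = basename(path)) {
  first <- utils::read.table(path, sep = "\t", header = FALSE, nrows = 1L,
                             stringsAsFactors = FALSE, comment.char = "#")
  has_header <- is.na(suppressWarnings(as.numeric(first[[2L]])))
  df <- utils::read.table(path, sep = "\t", header = has_header,
                          stringsAsFactors = FALSE, comment.char = "#")
  center <- if (ncol(df) >= 3L && is.numeric(df[[3L]])) {
    floor((as.numeric(df[[2L]]) + as.numeric(df[[3L]])) / 2)
  } else {
    as.numeric(df[[2L]])
  }
  origin_set(data.frame(chrom = df[[1L]], center = center), label = label)
}

#' Per-origin, per-bin mean enrichment matrix
#'
#' The coordinate system of all meta-origin statistics: for each origin,
#' enrichment anchors are assigned to non-overlapping `bin` bp bins from
#' `-flank` to `+flank` around the origin center by their window midpoint
#' (half-open bin edges), and averaged per bin. Bins extending past a
#' chromosome end are missing (`NA`), never zero.
#'
#' @param track An [enrichment_track()].
#' @param origins An [origin_set()] (non-empty).
#' @param flank Half-width of the meta-origin window in bp (default 100 kb).
#' @param bin Bin width in bp (default 10 kb); `2 * flank / bin` must be an
#'   integer.
#' @return Matrix (origins x bins) of class `origin_bin_matrix` with
#'   attributes `bin_offsets` (bin start offsets from the center), `flank`,
#'   `bin` and `origins`.
#' @export
bin_matrix <- function(track, origins, flank = 1e5, bin = 1e4) {
  stopifnot(inherits(track, "enrichment_track"))
  if (nrow(origins) == 0L) stop("origin set is empty")
  n_bins <- 2 * flank / bin
  if (abs(n_bins - round(n_bins)) > 1e-9) stop("2*flank must be a multiple of bin")
  n_bins <- as.integer(round(n_bins))
  bad <- setdiff(unique(origins$chrom), names(track$values))
  if (length(bad)) stopf("origin(s) on chromosome(s) absent from track: %s",
                         paste(bad, collapse = ","))
  mids <- lapply(names(track$values), function(ch) anchor_midpoints(track, ch))
  names(mids) <- names(track$values)
  M <- matrix(NA_real_, nrow = nrow(origins), ncol = n_bins)
  eps <- 1e-6
  for (o in seq_len(nrow(origins))) {
    ch <- origins$chrom[o]
    m <- mids[[ch]]
    v <- track$values[[ch]]
    L <- track$lengths[[ch]]
    ctr <- origins$center[o]
    for (j in seq_len(n_bins)) {
      lo <- ctr - flank + (j - 1L) * bin
      hi <- lo + bin
      if (lo < 0 || hi > L) next # out-of-bounds bin stays NA
      k <- findInterval(c(lo - eps, hi - eps), m)
      if (k[2L] > k[1L]) M[o, j] <- mean(v[(k[1L] + 1L):k[2L]])
    }
  }
  structure(M, bin_offsets = -flank + (seq_len(n_bins) - 1L) * bin,
            flank = flank, bin = bin, origins = origins,
            class = c("origin_bin_matrix", "matrix"))
}

bin_offset_frame <- function(m) {
  off <- attr(m, "bin_offsets")
  data.frame(bin_start = off, bin_end = off + attr(m, "bin"))
}

check_same_bins <- function(a, b) {
  if (!all(dim(a) == dim(b)) ||
      !isTRUE(all.equal(attr(a, "bin_offsets"), attr(b, "bin_offsets")))) {
    stop("bin matrices have different origins or bin layout")
  }
  invisible(TRUE)
}

#' Missing-aware mean meta-origin profile
#'
#' Column means of an [bin_matrix()] result, ignoring missing entries, with
#' the per-bin number of contributing origins.
#'
#' @param m An `origin_bin_matrix`.
#' @return data.frame with `bin_start`, `bin_end` (offsets from the origin
#'   center), `mean` (NA when no origin contributes) and `n`.
#' @export
mean_profile <- function(m) {
  stopifnot(inherits(m, "origin_bin_matrix"))
  if (nrow(m) < 1L) stop("need at least one origin")
  n <- colSums(!is.na(m))
  mu <- ifelse(n > 0L, colMeans(m, na.rm = TRUE), NA_real_)
  cbind(bin_offset_frame(m), data.frame(mean = mu, n = n))
}

#' Per-bin factor-ratio profile (e.g. SA to Rad21)
#'
#' For every origin and bin the ratio of the two factors' mean enrichment is
#' taken in the linear enrichment domain, then averaged across origins per
#' bin -- the stoichiometry proxy used to compare a cohesin subunit to the
#' core ring. Matrices built from log2 tracks (the [bin_matrix()] default)
#' are converted with `2^x` first; pass `log2_input = FALSE` for matrices
#' already holding linear enrichment. Bins with a non-positive denominator
#' are flagged missing.
#'
#' @param num,den `origin_bin_matrix` objects sharing origins and bins
#'   (numerator and denominator factors).
#' @param log2_input Are the matrix entries log2 enrichment values?
#' @return data.frame with `bin_start`, `bin_end`, `ratio` (per-bin mean of
#'   per-origin ratios) and `n` contributing origins.
#' @export
ratio_profile <- function(num, den, log2_input = TRUE) {
  stopifnot(inherits(num, "origin_bin_matrix"), inherits(den, "origin_bin_matrix"))
  check_same_bins(num, den)
  a <- if (log2_input) 2^unclass(num) else unclass(num)
  b <- if (log2_input) 2^unclass(den) else unclass(den)
  b[!is.na(b) & b <= 0] <- NA_real_
  r <- a / b
  n <- colSums(!is.na(r))
  mu <- ifelse(n > 0L, colMeans(r, na.rm = TRUE), NA_real_)
  cbind(bin_offset_frame(num), data.frame(ratio = mu, n = n))
}

#' Per-bin paired Wilcoxon signed-rank test between conditions
#'
#' For each meta-origin bin, tests the paired differences
#' `depleted(origin, bin) - mock(origin, bin)` across origins with the
#' two-sided Wilcoxon signed-rank test. Zero differences are dropped before
#' ranking (Wilcoxon's original rule); ties share average ranks. The exact
#' null distribution is used when the effective n is at most `exact_max`,
#' otherwise the normal approximation with continuity correction. Bins with
#' fewer than two usable pairs get a missing p value. No multiple-testing
#' correction is applied by default (profiles are conventionally displayed
#' as raw -log10 p); request `adjust = "BH"` for decision rules.
#'
#' @param mock,depleted `origin_bin_matrix` objects sharing origins/bins.
#' @param exact_max Largest effective n for which the exact distribution is
#'   used (default 25).
#' @param adjust `"none"` (default) or `"BH"`.
#' @return data.frame with `bin_start`, `bin_end`, `n_pairs`, `p`,
#'   `minus_log10_p`, `direction` (sign of the median difference) and,
#'   when requested, `q`.
#' @export
bin_wilcoxon <- function(mock, depleted, exact_max = 25L,
                         adjust = c("none", "BH")) {
  stopifnot(inherits(mock, "origin_bin_matrix"), inherits(depleted, "origin_bin_matrix"))
  adjust <- match.arg(adjust)
  check_same_bins(mock, depleted)
  res <- lapply(seq_len(ncol(mock)), function(j) {
    d <- depleted[, j] - mock[, j]
    d <- d[!is.na(d)]
    dir <- if (length(d)) sign(stats::median(d)) else NA_real_
    d <- d[d != 0]
    n <- length(d)
    if (n < 2L) {
      return(data.frame(n_pairs = n, p = NA_real_, direction = dir))
    }
    p <- signed_rank_p(d, exact_max)
    data.frame(n_pairs = n, p = p, direction = dir)
  })
  out <- cbind(bin_offset_frame(mock), do.call(rbind, res))
  out$minus_log10_p <- -log10(out$p)
  if (adjust == "BH") out$q <- stats::p.adjust(out$p, method = "BH")
  out[, c("bin_start", "bin_end", "n_pairs", "p", "minus_log10_p",
          "direction", if (adjust == "BH") "q")]
}

# Two-sided signed-rank p for nonzero differences d.
signed_rank_p <- function(d, exact_max = 25L) {
  n <- length(d)
  exact <- n <= exact_max && !any(duplicated(abs(d)))
  suppressWarnings(
    stats::wilcox.test(d, mu = 0, alternative = "two.sided",
                       exact = exact, correct = TRUE)$p.value
  )
}

#' Write a meta-origin profile or test table as TSV
#'
#' @param profile data.frame from [mean_profile()], [ratio_profile()] or
#'   [bin_wilcoxon()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_profile_tsv <- function(profile, path) {
  utils::write.table(profile, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
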