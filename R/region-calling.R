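#' Call binding regions by percentile threshold and minimum length
#'
#' The threshold is the given percentile (linear interpolation between order
#' statistics, i.e. `quantile(type = 7)`) of all anchor values on the
#' included chromosomes jointly. Maximal runs of consecutive anchors with
#' value at or above the threshold ("or greater": ties included) are
#' expanded to their full window extents; extents that touch or overlap are
#' merged, and merged intervals shorter than `min_len` bp are discarded.
#' The include-list operationalizes "euchromatic" chromosomes: pass the
#' major chromosome arms and leave heterochromatic scaffolds out.
#'
#' @param track An [enrichment_track()].
#' @param percentile Percentile threshold in (0, 100\] (default 95).
#' @param min_len Minimum region length in bp (default 300).
#' @param chromosomes Chromosomes to include (default: all in the track).
#' @return A data.frame of class `binding_regions` with columns `chrom`,
#'   `start`, `end` (0-based half-open) and `mean_enrichment` (mean of
#'   anchor values whose window midpoint lies in the region), sorted and
#'   non-overlapping, with the threshold in `attr(, "threshold")`.
#' @export
call_regions <- function(track, percentile = 95, min_len = 300L,
                         chromosomes = NULL) {
  stopifnot(inherits(track, "enrichment_track"))
  if (percentile <= 0 || percentile > 100) stop("`percentile` must be in (0, 100]")
  chromosomes <- chromosomes %||% names(track$values)
  if (length(chromosomes) == 0L) stop("empty chromosome include-list")
  missing <- setdiff(chromosomes, names(track$values))
  if (length(missing)) stopf("chromosome(s) not in track: %s",
                             paste(missing, collapse = ","))
  all_vals <- unlist(track$values[chromosomes], use.names = FALSE)
  if (length(all_vals) == 0L) stop("track has no anchors on the included chromosomes")
  thr <- stats::quantile(all_vals, percentile / 100, type = 7, names = FALSE)
  out <- lapply(chromosomes, function(ch) {
    v <- track$values[[ch]]
    ok <- v >= thr
    if (!any(ok)) return(NULL)
    r <- rle(ok)
    hi <- cumsum(r$lengths)
    lo <- hi - r$lengths + 1L
    keep <- r$values
    ir <- IRanges::IRanges(start = (lo[keep] - 1L) * track$step + 1L,
                           end = (hi[keep] - 1L) * track$step + track$window)
    ir <- IRanges::reduce(ir)
    ir <- ir[IRanges::width(ir) >= min_len]
    if (length(ir) == 0L) return(NULL)
    m <- anchor_midpoints(track, ch)
    means <- vapply(seq_along(ir), function(i) {
      inside <- m >= (IRanges::start(ir)[i] - 1L) & m < IRanges::end(ir)[i]
      mean(v[inside])
    }, numeric(1L))
    data.frame(chrom = ch, start = IRanges::start(ir) - 1L,
               end = IRanges::end(ir), mean_enrichment = means)
  })
  df <- do.call(rbind, out) %||%
    data.frame(chrom = character(), start = integer(), end = integer(),
               mean_enrichment = numeric())
  rownames(df) <- NULL
  structure(df, threshold = thr, class = c("binding_regions", "data.frame"))
}

validate_region_set <- function(df, what = "region set") {
  need <- c("chrom", "start", "end")
  if (!all(need %in% names(df))) stopf("%s must have chrom/start/end columns", what)
  for (ch in unique(df$chrom)) {
    r <- df[df$chrom == ch, , drop = FALSE]
    if (is.unsorted(r$start)) stopf("%s is not sorted on %s", what, ch)
    if (nrow(r) > 1L && any(r$start[-1L] < r$end[-nrow(r)])) {
      stopf("%s has overlapping regions on %s", what, ch)
    }
  }
  invisible(TRUE)
}

#' Overlap statistics between two binding-region sets
#'
#' An A region counts as overlapping when it shares at least 1 bp with any
#' B region (half-open interval semantics, as with bedtools intersect).
#'
#' @param a,b Region data.frames (e.g. from [call_regions()]), each sorted
#'   and non-overlapping within itself.
#' @return An [overlap_report()].
#' @export
intersect_region_sets <- function(a, b) {
  validate_region_set(a, "set A")
  validate_region_set(b, "set B")
  n_hit <- if (nrow(a) == 0L || nrow(b) == 0L) 0L else {
    gra <- GenomicRanges::GRanges(a$chrom, IRanges::IRanges(a$start + 1L, a$end))
    grb <- GenomicRanges::GRanges(b$chrom, IRanges::IRanges(b$start + 1L, b$end))
    # disjoint chromosome name sets are a valid zero-overlap case
    suppressWarnings(sum(GenomicRanges::countOverlaps(gra, grb) > 0L))
  }
  overlap_report(nrow(a), nrow(b), n_hit)
}

#' Overlap report between two region sets
#'
#' @param n_a,n_b Region counts in sets A and B.
#' @param n_overlap Number of A regions overlapping at least one B region.
#' @return An object of class `overlap_report` with the counts, the exact
#'   `fraction` (`n_overlap / n_a`) and `fraction_pct` rounded to the
#'   nearest percent.
#' @examples
#' overlap_report(6452, 6430, 3600)$fraction_pct # 56
#' @export
overlap_report <- function(n_a, n_b, n_overlap) {
  if (n_overlap > n_a) stop("overlap count exceeds the size of set A")
  if (any(c(n_a, n_b, n_overlap) < 0)) stop("counts must be non-negative")
  fraction <- if (n_a == 0L) NA_real_ else n_overlap / n_a
  structure(list(n_a = as.integer(n_a), n_b = as.integer(n_b),
                 n_overlap = as.integer(n_overlap), fraction = fraction,
                 fraction_pct = if (is.na(fraction)) NA_real_ else round(100 * fraction)),
            class = "overlap_report")
}

#' @export
print.overlap_report <- function(x, ...) {
  cat(sprintf("overlap_report: |A| = %d, |B| = %d, %d A regions overlap B (%s%%)\n",
              x$n_a, x$n_b, x$n_overlap,
              ifelse(is.na(x$fraction_pct), "NA", x$fraction_pct)))
  invisible(x)
}

#' Read / write binding regions as BED
#'
#' Regions are stored as BED with the mean enrichment in the score column.
#'
#' @param path File path.
#' @return For `read_regions_bed`, a `binding_regions` data.frame.
#' @export
read_regions_bed <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 3L) stop("BED file needs at least 3 columns: ", path)
  score <- if (ncol(df) >= 5L) suppressWarnings(as.numeric(df[[5L]])) else NA_real_
  out <- data.frame(chrom = df[[1L]], start = df[[2L]], end = df[[3L]],
                    mean_enrichment = score)
  structure(out, class = c("binding_regions", "data.frame"))
}

#' @rdname read_regions_bed
#' @param regions A `binding_regions` data.frame.
#' @export
write_regions_bed <- function(regions, path) {
  bed <- data.frame(chrom = regions$chrom, start = regions$start,
                    end = regions$end, name = "region",
                    score = regions$mean_enrichment, strand = ".")
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
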