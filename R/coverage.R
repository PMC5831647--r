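#' Per-base coverage track
#'
#' A coverage track stores one non-negative read-depth value per base for
#' each chromosome, plus the total mapped depth. ChIP and input samples are
#' each one track. Values are usually integer read-extended depths from
#' [simulate_chip_pair()] or [read_bedgraph()], but non-integer expected
#' depths (e.g. from a noise-free occupancy model) are allowed.
#'
#' @param coverage Named list of numeric vectors, one per chromosome; each
#'   vector holds the depth at bases `1..L` of that chromosome.
#' @return An object of class `coverage_track` with fields `coverage`
#'   (named list of numeric vectors), `lengths` (named integer vector of
#'   chromosome lengths) and `total` (sum of all per-base depth).
#' @examples
#' ct <- coverage_track(list(chr1 = rep(2, 1000)))
#' ct$lengths
#' @export
coverage_track <- function(coverage) {
  if (!is.list(coverage) || length(coverage) == 0L || is.null(names(coverage)) ||
      any(!nzchar(names(coverage)))) {
    stop("`coverage` must be a non-empty named list of numeric vectors")
  }
  for (v in coverage) {
    if (!is.numeric(v)) stop("coverage vectors must be numeric")
    if (anyNA(v) || any(v < 0)) stop("coverage values must be non-negative and non-missing")
  }
  structure(
    list(
      coverage = coverage,
      lengths = vapply(coverage, length, integer(1L)),
      total = sum(vapply(coverage, sum, numeric(1L)))
    ),
    class = "coverage_track"
  )
}

#' @export
print.coverage_track <- function(x, ...) {
  cat("coverage_track:", length(x$coverage), "chromosome(s),",
      format(sum(as.double(x$lengths)), big.mark = ","), "bp, mean depth",
      signif(x$total / sum(as.double(x$lengths)), 4), "\n")
  invisible(x)
}

# Internal constructor for trusted (simulator-generated) coverage lists.
new_coverage_track <- function(coverage) {
  structure(
    list(coverage = coverage,
         lengths = vapply(coverage, length, integer(1L)),
         total = sum(vapply(coverage, sum, numeric(1L)))),
    class = "coverage_track"
  )
}

#' Read a coverage track from a bedGraph file
#'
#' Imports a 4-column bedGraph (0-based half-open intervals with a depth
#' score) and expands it to per-base coverage. Bases not covered by any
#' interval get depth 0.
#'
#' @param path Path to a bedGraph file.
#' @param lengths Optional named vector of chromosome lengths; defaults to
#'   the largest end coordinate seen per chromosome.
#' @return A [coverage_track()].
#' @export
read_bedgraph <- function(path, lengths = NULL) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  if (length(gr) == 0L) stop("bedGraph file is empty: ", path)
  cov <- GenomicRanges::coverage(gr, weight = "score")
  out <- lapply(names(cov), function(ch) as.numeric(cov[[ch]]))
  names(out) <- names(cov)
  if (!is.null(lengths)) {
    for (ch in names(out)) {
      L <- lengths[[ch]]
      if (is.null(L)) stop("no length supplied for chromosome ", ch)
      if (length(out[[ch]]) > L) stop("bedGraph extends past supplied length on ", ch)
      out[[ch]] <- c(out[[ch]], numeric(L - length(out[[ch]])))
    }
  }
  coverage_track(out)
}

#' Write a coverage track as bedGraph
#'
#' Run-length encodes the per-base depth and writes 0-based half-open
#' intervals. Zero-depth runs are written too, so the file round-trips.
#'
#' @param track A [coverage_track()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path) {
  stopifnot(inherits(track, "coverage_track"))
  grl <- lapply(names(track$coverage), function(ch) {
    r <- rle(track$coverage[[ch]])
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    GenomicRanges::GRanges(ch, IRanges::IRanges(starts, ends), score = r$values)
  })
  gr <- suppressWarnings(do.call(c, grl)) # per-chromosome seqlevels differ
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}
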