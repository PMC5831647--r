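#' Sliding-window log2 enrichment track
#'
#' Holds log2(ChIP/input) values anchored on a regular grid: one value per
#' `step` bp, each computed from a `window` bp sliding window. Anchors are
#' indexed by window start; anchor `i` (1-based) covers the 0-based
#' half-open interval `[(i-1)*step, (i-1)*step + window)`. Trailing bases
#' that do not fit a full window carry no anchor.
#'
#' @param values Named list of numeric vectors of per-anchor log2 enrichment.
#' @param window Window width in bp.
#' @param step Anchor spacing in bp.
#' @param lengths Named vector of chromosome lengths in bp.
#' @param samples Character vector of sample identifiers (provenance).
#' @param n_replicates Number of biological replicates averaged in.
#' @return An object of class `enrichment_track`.
#' @export
enrichment_track <- function(values, window, step, lengths,
                             samples = character(), n_replicates = 1L) {
  stopifnot(is.list(values), !is.null(names(values)))
  lengths <- lengths[names(values)]
  for (ch in names(values)) {
    expect <- n_anchors(lengths[[ch]], window, step)
    if (length(values[[ch]]) != expect) {
      stopf("chromosome %s: %d anchors supplied, %d expected for length %d",
            ch, length(values[[ch]]), expect, lengths[[ch]])
    }
  }
  structure(
    list(values = lapply(values, as.numeric), window = as.integer(window),
         step = as.integer(step), lengths = lengths,
         samples = samples, n_replicates = as.integer(n_replicates)),
    class = "enrichment_track"
  )
}

#' @export
print.enrichment_track <- function(x, ...) {
  cat("enrichment_track:", length(x$values), "chromosome(s),",
      format(sum(vapply(x$values, length, integer(1L))), big.mark = ","),
      "anchors (window", x$window, "bp / step", x$step, "bp),",
      x$n_replicates, "replicate(s)\n")
  invisible(x)
}

#' Number of full sliding windows on a chromosome
#'
#' @param L Chromosome length in bp.
#' @param window Window width in bp.
#' @param step Step between anchors in bp.
#' @return `floor((L - window)/step) + 1`, or 0 when `L < window`.
#' @export
n_anchors <- function(L, window, step) {
  ifelse(L < window, 0L, (as.integer(L) - as.integer(window)) %/% as.integer(step) + 1L)
}

#' Anchor window midpoints for one chromosome of an enrichment track
#'
#' Midpoints are used for bin and element membership throughout the package.
#'
#' @param track An [enrichment_track()].
#' @param chrom Chromosome name.
#' @return Numeric vector of window midpoints in bp (0-based coordinates).
#' @export
anchor_midpoints <- function(track, chrom) {
  n <- length(track$values[[chrom]])
  if (n == 0L) return(numeric(0L))
  (seq_len(n) - 1L) * track$step + track$window / 2
}

# Sum of `v` over windows [k*step+1, k*step+window]; rolling-sum kernel,
# accumulated in double so deep integer coverage cannot overflow.
window_sums <- function(v, window, step) {
  .window_sums(v, as.integer(window), as.integer(step))
}

#' Compute input-normalized sliding-window enrichment
#'
#' For each anchor the value is
#' `log2((chip_window_sum * s + pseudocount) / (input_window_sum + pseudocount))`
#' where `s = total_input_depth / total_chip_depth` scales the ChIP sample to
#' the sequencing depth of the input. The pseudocount (default one count per
#' window) keeps every value finite. 250 bp windows every 50 bp reduce
#' counting noise and put all samples on a common anchor grid for direct
#' comparison.
#'
#' @param chip,input [coverage_track()]s sharing chromosome names and lengths.
#' @param window Window width in bp (default 250).
#' @param step Anchor spacing in bp (default 50).
#' @param pseudocount Added to both window sums (default 1).
#' @return An [enrichment_track()].
#' @export
compute_enrichment <- function(chip, input, window = 250L, step = 50L,
                               pseudocount = 1) {
  stopifnot(inherits(chip, "coverage_track"), inherits(input, "coverage_track"))
  if (window < step) stop("`window` must be >= `step`")
  check_same_chromosomes(chip$coverage, input$coverage, "chip and input")
  if (!all(chip$lengths[names(input$lengths)] == input$lengths)) {
    stop("chip and input chromosome lengths differ")
  }
  if (input$total <= 0) stop("input track has zero total depth")
  if (chip$total <= 0) stop("chip track has zero total depth")
  s <- input$total / chip$total
  vals <- lapply(names(chip$coverage), function(ch) {
    wc <- window_sums(chip$coverage[[ch]], window, step)
    wi <- window_sums(input$coverage[[ch]], window, step)
    log2((wc * s + pseudocount) / (wi + pseudocount))
  })
  names(vals) <- names(chip$coverage)
  enrichment_track(vals, window, step, chip$lengths)
}

#' Average replicate enrichment tracks
#'
#' Anchor-wise arithmetic mean of replicate tracks sharing one anchor grid.
#' Averaged tracks are the unit of all downstream analyses.
#'
#' @param tracks List of [enrichment_track()]s with identical grids.
#' @return An [enrichment_track()] whose `n_replicates` records the total
#'   replicate count.
#' @export
average_replicates <- function(tracks) {
  if (!is.list(tracks) || length(tracks) == 0L) stop("need at least one track")
  ref <- tracks[[1L]]
  for (t in tracks[-1L]) check_same_grid(ref, t)
  vals <- lapply(names(ref$values), function(ch) {
    Reduce(`+`, lapply(tracks, function(t) t$values[[ch]])) / length(tracks)
  })
  names(vals) <- names(ref$values)
  enrichment_track(vals, ref$window, ref$step, ref$lengths,
                   samples = unique(unlist(lapply(tracks, `[[`, "samples"))),
                   n_replicates = sum(vapply(tracks, `[[`, integer(1L), "n_replicates")))
}

check_same_grid <- function(a, b) {
  stopifnot(inherits(a, "enrichment_track"), inherits(b, "enrichment_track"))
  if (a$window != b$window || a$step != b$step) {
    stop("enrichment tracks use different window/step grids")
  }
  check_same_chromosomes(a$values, b$values, "enrichment tracks")
  if (!all(vapply(names(a$values), function(ch) {
    length(a$values[[ch]]) == length(b$values[[ch]])
  }, logical(1L)))) {
    stop("enrichment tracks have different anchor counts")
  }
  invisible(TRUE)
}

#' Pearson correlation between two enrichment tracks
#'
#' Genome-wide by default; a restricted-region variant (for example a single
#' gene neighbourhood) is selected with `chrom`/`start`/`end`, keeping
#' anchors whose window midpoint falls in `[start, end)`.
#'
#' @param a,b [enrichment_track()]s on identical grids.
#' @param chrom,start,end Optional region restriction (0-based half-open).
#' @return Pearson correlation coefficient.
#' @export
replicate_correlation <- function(a, b, chrom = NULL, start = NULL, end = NULL) {
  check_same_grid(a, b)
  if (is.null(chrom)) {
    x <- unlist(a$values, use.names = FALSE)
    y <- unlist(b$values, use.names = FALSE)
  } else {
    if (!chrom %in% names(a$values)) stop("unknown chromosome: ", chrom)
    m <- anchor_midpoints(a, chrom)
    keep <- m >= (start %||% 0) & m < (end %||% Inf)
    x <- a$values[[chrom]][keep]
    y <- b$values[[chrom]][keep]
  }
  if (length(x) < 2L) stop("fewer than two anchors selected")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("correlation undefined: a track has zero variance over the selected anchors")
  }
  stats::cor(x, y)
}

#' Per-anchor fold-change between two enrichment tracks
#'
#' Anchor-wise difference of log2 enrichments, i.e. the log2 fold-change of
#' enrichment every `step` bp, used to visualise depletion effects along
#' chromosomes.
#'
#' @param cond,ref [enrichment_track()]s on identical grids
#'   (condition and reference/mock).
#' @return An [enrichment_track()] holding `cond - ref` at each anchor.
#' @export
fold_change_track <- function(cond, ref) {
  check_same_grid(cond, ref)
  vals <- lapply(names(cond$values), function(ch) cond$values[[ch]] - ref$values[[ch]])
  names(vals) <- names(cond$values)
  enrichment_track(vals, cond$window, cond$step, cond$lengths,
                   samples = c(cond$samples, ref$samples))
}

#' Write an enrichment track as bedGraph
#'
#' Each anchor is written as a `step`-wide interval starting at the window
#' start, matching the "one value every 50 bp" representation.
#'
#' @param track An [enrichment_track()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_enrichment_bedgraph <- function(track, path) {
  stopifnot(inherits(track, "enrichment_track"))
  grl <- lapply(names(track$values), function(ch) {
    v <- track$values[[ch]]
    if (length(v) == 0L) return(GenomicRanges::GRanges())
    starts <- (seq_along(v) - 1L) * track$step
    GenomicRanges::GRanges(ch, IRanges::IRanges(starts + 1L, starts + track$step),
                           score = v)
  })
  gr <- suppressWarnings(do.call(c, grl)) # per-chromosome seqlevels differ
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}
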