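#' Specification of a synthetic genome
#'
#' Defines chromosome lengths, how many early replication origins to place
#' (or their exact positions), and the densities of genes and 500 bp
#' regulatory elements. Origins are kept at least `edge_margin` bp from
#' chromosome ends so that a full +/-100 kb meta-origin window fits; set
#' `edge_margin = 0` only to exercise edge handling.
#'
#' @param chrom_lengths Named integer vector of chromosome lengths (bp),
#'   each >= 1000.
#' @param n_origins Total number of origins to place (ignored when
#'   `origin_positions` is given).
#' @param origin_positions Optional named list of numeric vectors of origin
#'   centers per chromosome.
#' @param seed Integer seed; the spec is deterministic given this seed.
#' @param edge_margin Minimum distance of an origin from a chromosome end
#'   (default 200 kb).
#' @param gene_meanlog,gene_sdlog Log-normal parameters of gene length (bp).
#' @param intergenic_mean Mean intergenic gap length (bp, exponential).
#' @param active_fraction Probability that a gene is transcriptionally active.
#' @param enhancers_per_mb,pres_per_mb Densities of extragenic enhancer and
#'   PRE elements (all elements are exactly 500 bp).
#' @return An object of class `genome_spec`.
#' @export
genome_spec <- function(chrom_lengths, n_origins = 0L, origin_positions = NULL,
                        seed = 1L, edge_margin = 2e5,
                        gene_meanlog = log(6000), gene_sdlog = 0.6,
                        intergenic_mean = 2000, active_fraction = 0.5,
                        enhancers_per_mb = 4.4, pres_per_mb = 1.6) {
  if (is.null(names(chrom_lengths)) || any(!nzchar(names(chrom_lengths)))) {
    stop("`chrom_lengths` must be named")
  }
  if (any(chrom_lengths < 1000)) stop("chromosome lengths must be >= 1 kb")
  if (!is.null(origin_positions)) {
    bad <- setdiff(names(origin_positions), names(chrom_lengths))
    if (length(bad)) stopf("origin positions on unknown chromosome(s): %s",
                           paste(bad, collapse = ","))
    for (ch in names(origin_positions)) {
      p <- origin_positions[[ch]]
      if (any(p < edge_margin | p > chrom_lengths[[ch]] - edge_margin)) {
        stopf("origin outside allowed bounds on %s (edge margin %d bp)",
              ch, as.integer(edge_margin))
      }
    }
    n_origins <- sum(lengths(origin_positions))
  }
  structure(
    list(chrom_lengths = chrom_lengths, n_origins = as.integer(n_origins),
         origin_positions = origin_positions, seed = as.integer(seed),
         edge_margin = edge_margin, gene_meanlog = gene_meanlog,
         gene_sdlog = gene_sdlog, intergenic_mean = intergenic_mean,
         active_fraction = active_fraction,
         enhancers_per_mb = enhancers_per_mb, pres_per_mb = pres_per_mb),
    class = "genome_spec"
  )
}

#' Simulate a genome annotation bundle
#'
#' Places origins, genes with an active/inactive flag, and 500 bp regulatory
#' elements (promoters at active gene starts, extragenic enhancers, PREs) on
#' the chromosomes of a [genome_spec()]. Deterministic for a fixed spec seed.
#'
#' @param spec A [genome_spec()].
#' @return An object of class `genome_annotation`: a list with
#'   `chrom_lengths`, `origins` (data.frame chrom/center), `genes`
#'   (data.frame chrom/start/end/active, 0-based half-open) and `elements`
#'   (data.frame chrom/start/end/class).
#' @export
simulate_genome <- function(spec) {
  stopifnot(inherits(spec, "genome_spec"))
  with_seed(spec$seed, {
    lens <- spec$chrom_lengths
    origins <- simulate_origins(spec)
    genes <- do.call(rbind, lapply(names(lens), function(ch) {
      simulate_genes_chrom(ch, lens[[ch]], spec)
    }))
    elements <- simulate_elements(genes, lens, spec)
    ann <- structure(
      list(chrom_lengths = lens, origins = origins, genes = genes,
           elements = elements),
      cache = new.env(parent = emptyenv()),
      class = "genome_annotation"
    )
    validate_annotation(ann, spec$edge_margin)
    ann
  })
}

simulate_origins <- function(spec) {
  lens <- spec$chrom_lengths
  if (!is.null(spec$origin_positions)) {
    pos <- spec$origin_positions
    df <- do.call(rbind, lapply(names(pos), function(ch) {
      if (length(pos[[ch]]) == 0L) return(NULL)
      data.frame(chrom = ch, center = sort(as.numeric(pos[[ch]])))
    }))
    return(df %||% data.frame(chrom = character(), center = numeric()))
  }
  n <- spec$n_origins
  if (n == 0L) return(data.frame(chrom = character(), center = numeric()))
  usable <- pmax(as.numeric(lens) - 2 * spec$edge_margin, 0)
  if (all(usable <= 0)) stop("no chromosome long enough for the edge margin")
  alloc <- distribute_counts(n, usable)
  out <- lapply(seq_along(lens), function(i) {
    k <- alloc[i]
    if (k == 0L) return(NULL)
    ch <- names(lens)[i]
    lo <- spec$edge_margin
    hi <- lens[[i]] - spec$edge_margin
    # evenly spaced with +/-10% spacing jitter: realistic spread, no clumps
    centers <- lo + (seq_len(k) - 0.5) / k * (hi - lo)
    jitter <- (hi - lo) / k * 0.1 * stats::runif(k, -1, 1)
    data.frame(chrom = ch, center = round(pmin(pmax(centers + jitter, lo), hi)))
  })
  df <- do.call(rbind, out)
  df[order(df$chrom, df$center), , drop = FALSE]
}

# Largest-remainder allocation of n items proportional to weights.
distribute_counts <- function(n, w) {
  w <- pmax(w, 0)
  exact <- n * w / sum(w)
  base <- floor(exact)
  rem <- n - sum(base)
  if (rem > 0) {
    idx <- order(exact - base, decreasing = TRUE)[seq_len(rem)]
    base[idx] <- base[idx] + 1
  }
  as.integer(base)
}

simulate_genes_chrom <- function(ch, L, spec) {
  starts <- integer(0); ends <- integer(0)
  pos <- 0
  repeat {
    gap <- round(stats::rexp(1L, 1 / spec$intergenic_mean))
    len <- round(stats::rlnorm(1L, spec$gene_meanlog, spec$gene_sdlog))
    len <- min(max(len, 500), 50000)
    if (pos + gap + len > L) break
    starts <- c(starts, pos + gap)
    ends <- c(ends, pos + gap + len)
    pos <- pos + gap + len
  }
  if (length(starts) == 0L) {
    return(data.frame(chrom = character(), start = numeric(), end = numeric(),
                      active = logical()))
  }
  data.frame(chrom = ch, start = starts, end = ends,
             active = stats::runif(length(starts)) < spec$active_fraction)
}

simulate_elements <- function(genes, lens, spec) {
  elen <- 500
  parts <- list()
  act <- genes[genes$active & (genes$start + elen) <= lens[genes$chrom], , drop = FALSE]
  if (nrow(act)) {
    parts$promoter <- data.frame(chrom = act$chrom, start = act$start,
                                 end = act$start + elen, class = "promoter")
  }
  for (cls in c("enhancer", "PRE")) {
    dens <- if (cls == "enhancer") spec$enhancers_per_mb else spec$pres_per_mb
    n <- round(dens * sum(as.numeric(lens)) / 1e6)
    if (n == 0L) next
    pos <- sample_positions(lens, n, elen,
                            avoid = if (cls == "enhancer") genes else NULL)
    if (nrow(pos)) {
      pos$class <- cls
      parts[[cls]] <- pos
    }
  }
  df <- do.call(rbind, parts)
  if (is.null(df)) {
    df <- data.frame(chrom = character(), start = numeric(), end = numeric(),
                     class = character())
  }
  rownames(df) <- NULL
  df[order(df$chrom, df$start), , drop = FALSE]
}

# Uniformly sample n intervals of width `len`, optionally avoiding `avoid`
# (data.frame chrom/start/end). Bounded retries; used for enhancers/PREs and
# by sample_random_elements().
sample_positions <- function(lens, n, len, avoid = NULL, max_tries = 200L) {
  if (n == 0L) {
    return(data.frame(chrom = character(), start = numeric(), end = numeric()))
  }
  ok_lens <- lens[lens >= len]
  if (length(ok_lens) == 0L) stop("no chromosome long enough for the elements")
  avoid_gr <- NULL
  if (!is.null(avoid) && nrow(avoid)) {
    avoid_gr <- GenomicRanges::GRanges(avoid$chrom,
                                       IRanges::IRanges(avoid$start + 1L, avoid$end))
  }
  got <- list(); n_got <- 0L; tries <- 0L
  while (n_got < n && tries < max_tries) {
    tries <- tries + 1L
    m <- n - n_got
    ch <- sample(names(ok_lens), m, replace = TRUE,
                 prob = as.numeric(ok_lens) - len + 1)
    start <- floor(stats::runif(m) * (as.numeric(ok_lens[ch]) - len + 1))
    cand <- data.frame(chrom = ch, start = start, end = start + len)
    if (!is.null(avoid_gr)) {
      gr <- GenomicRanges::GRanges(cand$chrom,
                                   IRanges::IRanges(cand$start + 1L, cand$end))
      hits <- suppressWarnings(GenomicRanges::countOverlaps(gr, avoid_gr))
      cand <- cand[hits == 0L, , drop = FALSE]
    }
    if (nrow(cand)) {
      got[[length(got) + 1L]] <- cand
      n_got <- n_got + nrow(cand)
    }
  }
  if (n_got < n) {
    stopf("could not place %d element(s) after %d tries (exclusion too dense?)",
          n, max_tries)
  }
  out <- do.call(rbind, got)[seq_len(n), , drop = FALSE]
  rownames(out) <- NULL
  out
}

validate_annotation <- function(ann, edge_margin = 0) {
  lens <- ann$chrom_lengths
  with_df <- function(df, what) {
    if (nrow(df) == 0L) return(invisible(TRUE))
    bad <- setdiff(unique(df$chrom), names(lens))
    if (length(bad)) stopf("%s on unknown chromosome(s): %s", what,
                           paste(bad, collapse = ","))
    if (any(df$start < 0) || any(df$end > lens[df$chrom])) {
      stopf("%s outside chromosome bounds", what)
    }
    invisible(TRUE)
  }
  with_df(ann$genes, "gene")
  with_df(ann$elements, "element")
  if (nrow(ann$elements) && any(ann$elements$end - ann$elements$start != 500)) {
    stop("elements must be exactly 500 bp")
  }
  if (nrow(ann$origins)) {
    bad <- setdiff(unique(ann$origins$chrom), names(lens))
    if (length(bad)) stopf("origin on unknown chromosome(s): %s",
                           paste(bad, collapse = ","))
    if (any(ann$origins$center < edge_margin) ||
        any(ann$origins$center > lens[ann$origins$chrom] - edge_margin)) {
      stop("origin closer than the edge margin to a chromosome end")
    }
  }
  invisible(TRUE)
}

#' @export
print.genome_annotation <- function(x, ...) {
  cat("genome_annotation:", length(x$chrom_lengths), "chromosome(s),",
      format(sum(as.numeric(x$chrom_lengths)), big.mark = ","), "bp,",
      nrow(x$origins), "origin(s),", nrow(x$genes), "gene(s)",
      sprintf("(%d active),", sum(x$genes$active)),
      nrow(x$elements), "element(s)\n")
  invisible(x)
}

#' Write a genome annotation bundle as BED files
#'
#' Writes `origins.bed` (1 bp intervals at origin centers), `genes.bed`
#' (BED6; score column 1/0 flags active/inactive) and `elements.bed`
#' (BED6; element class in the name field).
#'
#' @param ann A `genome_annotation` from [simulate_genome()].
#' @param dir Output directory (created if needed).
#' @return Character vector of the three file paths, invisibly.
#' @export
write_annotation_bed <- function(ann, dir) {
  stopifnot(inherits(ann, "genome_annotation"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, c("origins.bed", "genes.bed", "elements.bed"))
  ob <- data.frame(chrom = ann$origins$chrom, start = ann$origins$center,
                   end = ann$origins$center + 1, name = "origin", score = 0,
                   strand = ".")
  gb <- data.frame(chrom = ann$genes$chrom, start = ann$genes$start,
                   end = ann$genes$end, name = "gene",
                   score = as.integer(ann$genes$active), strand = ".")
  eb <- data.frame(chrom = ann$elements$chrom, start = ann$elements$start,
                   end = ann$elements$end, name = ann$elements$class,
                   score = 0, strand = ".")
  for (i in seq_along(paths)) {
    utils::write.table(list(ob, gb, eb)[[i]], paths[i], sep = "\t",
                       quote = FALSE, row.names = FALSE, col.names = FALSE)
  }
  invisible(paths)
}
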