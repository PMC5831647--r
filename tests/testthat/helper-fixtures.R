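# Small fixtures shared across the suite; everything is generated in code.

# A tiny deterministic enrichment track from explicit values.
make_track <- function(values, window = 250L, step = 50L) {
  lengths <- vapply(values, function(v) length(v) * step + (window - step), integer(1L))
  enrichment_track(values, window, step, lengths)
}

# Random enrichment track on `n_anchor` anchors per chromosome.
random_track <- function(n_anchors = c(chrA = 40L, chrB = 25L), seed = 1L,
                         window = 250L, step = 50L) {
  set.seed(seed)
  make_track(lapply(n_anchors, function(n) rnorm(n)), window, step)
}

# Small genome annotation used by simulator-dependent tests.
small_annotation <- function(seed = 7L, n_chrom = 2L, chrom_length = 6e5,
                             n_origins = 2L) {
  lens <- stats::setNames(rep(chrom_length, n_chrom), paste0("chr", seq_len(n_chrom)))
  simulate_genome(genome_spec(lens, n_origins = n_origins, seed = seed))
}

# Brute-force sliding-window sum oracle (naive O(L * W)).
oracle_window_sums <- function(v, window, step) {
  L <- length(v)
  if (L < window) return(numeric(0))
  n <- (L - window) %/% step + 1
  vapply(seq_len(n), function(i) {
    a <- (i - 1) * step
    sum(v[(a + 1):(a + window)])
  }, numeric(1))
}

# Brute-force region caller: threshold every anchor, merge runs to window
# extents, merge overlapping extents, drop short regions.
oracle_call_regions <- function(track, percentile, min_len, chromosomes = NULL) {
  chromosomes <- chromosomes %||% names(track$values)
  all_vals <- unlist(track$values[chromosomes], use.names = FALSE)
  thr <- stats::quantile(all_vals, percentile / 100, type = 7, names = FALSE)
  out <- list()
  for (ch in chromosomes) {
    v <- track$values[[ch]]
    ok <- which(v >= thr)
    if (!length(ok)) next
    # split into runs of consecutive anchors
    runs <- split(ok, cumsum(c(1, diff(ok) != 1)))
    iv <- lapply(runs, function(r) {
      c((min(r) - 1) * track$step, (max(r) - 1) * track$step + track$window)
    })
    # merge overlapping/touching intervals
    iv <- iv[order(vapply(iv, `[`, numeric(1), 1))]
    merged <- list(iv[[1]])
    for (x in iv[-1]) {
      last <- merged[[length(merged)]]
      if (x[1] <= last[2]) {
        merged[[length(merged)]] <- c(last[1], max(last[2], x[2]))
      } else {
        merged[[length(merged) + 1]] <- x
      }
    }
    for (x in merged) {
      if (x[2] - x[1] >= min_len) {
        out[[length(out) + 1]] <- data.frame(chrom = ch, start = x[1], end = x[2])
      }
    }
  }
  if (!length(out)) {
    return(data.frame(chrom = character(), start = numeric(), end = numeric()))
  }
  do.call(rbind, out)
}

# Exact two-sided signed-rank p by enumerating all sign assignments.
oracle_signed_rank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- expand.grid(rep(list(c(0, 1)), n))
  vs <- as.matrix(signs) %*% r
  e_v <- n * (n + 1) / 4
  p <- mean(abs(vs - e_v) >= abs(v_obs - e_v) - 1e-9)
  p
}

# Two-sided Fisher exact p by hypergeometric enumeration over all tables
# with the observed margins.
oracle_fisher_p <- function(tab) {
  m <- sum(tab[1, ]); n <- sum(tab[2, ]); k <- sum(tab[, 1])
  support <- max(0, k - n):min(k, m)
  probs <- stats::dhyper(support, m, n, k)
  p_obs <- stats::dhyper(tab[1, 1], m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Copy an origin_bin_matrix, replacing its values but keeping bin metadata.
with_values <- function(m, vals) {
  out <- m
  out[] <- vals
  out
}

# Study-scale conditions for the planted meta-origin depletion experiments:
# 78 origins spaced 210 kb on six chromosomes plus origin-free territory so
# that origin domains cover a realistic minority of the genome.
study_annotation <- function(seed = 3L) {
  lens <- c(stats::setNames(rep(400e3 + 12 * 210e3, 6), paste0("chrO", 1:6)),
            stats::setNames(rep(16.5e6, 4), paste0("chrF", 1:4)))
  pos <- lapply(stats::setNames(paste0("chrO", 1:6), paste0("chrO", 1:6)),
                function(ch) 200e3 + (0:12) * 210e3)
  simulate_genome(genome_spec(lens, origin_positions = pos, seed = seed))
}

# Replicate-averaged track emulation: three >=10X replicates averaged.
study_model <- function(factor_name) {
  occupancy_model(factor_name, amplitude = 2, depth = 30, dispersion = 0.05)
}

# One seeded mock-vs-depleted comparison with a shared 45X input, returning
# the per-bin BH-adjusted Wilcoxon table.
study_depletion_run <- function(ann, model, cond, os, seed) {
  pm <- simulate_chip_pair(ann, model, seed = seed)
  pd <- simulate_chip_pair(ann, model, cond, seed = seed + 50000,
                           make_input = FALSE)
  em <- compute_enrichment(pm$chip, pm$input)
  ed <- compute_enrichment(pd$chip, pm$input)
  bin_wilcoxon(bin_matrix(em, os), bin_matrix(ed, os), adjust = "BH")
}
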