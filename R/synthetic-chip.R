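#' Factor occupancy model for synthetic ChIP-seq
#'
#' Parametrizes the qualitative occupancy structure seen for cohesin and its
#' regulators: occupancy is maximal at early replication origins and decays
#' exponentially with distance, and (when gating is on) is restricted to
#' active genes -- inactive genes and intergenic DNA carry baseline signal
#' only. Within active genes the expected relative occupancy at position `x`
#' is
#' `baseline + amplitude * mu(d) * exp(-d(x) / (decay_bp * decay_mult))`
#' where `d(x)` is the distance to the nearest origin on the chromosome and
#' `mu(d)` interpolates between the condition's origin-center and flanking
#' amplitude multipliers,
#' `mu(d) = origin_amp_mult + (flank_amp_mult - origin_amp_mult) * (1 - exp(-d / (decay_bp / 2)))`.
#' Multipliers come from a [condition_modifiers()] object (all 1 for the
#' mock condition, so `mu(d) = 1` everywhere). Depletion effects are thus
#' anchored to the origin-centered occupancy domains: chromatin far from
#' any origin carries baseline occupancy in every condition, as observed
#' for genes beyond the reach of origin-proximal cohesin domains.
#'
#' @param factor_name Factor label (e.g. `"Rad21"`, `"SA"`).
#' @param baseline Baseline relative occupancy (> 0).
#' @param amplitude Origin-peak amplitude added at origin centers (> 0).
#' @param decay_bp Exponential decay length scale in bp (> 0).
#' @param gate_active Restrict occupancy above baseline to active genes?
#' @param dispersion Gamma dispersion (variance of a mean-1 multiplicative
#'   noise field applied in 1 kb blocks, independently per replicate);
#'   0 gives pure Poisson counting noise. Calibrate with
#'   [calibrate_dispersion()].
#' @param depth Target mean sequencing depth of the ChIP sample (x coverage).
#' @param frag_len Fragment length in bp: each simulated read start is
#'   extended by this much (default 300, a typical sonication size).
#' @return An object of class `occupancy_model`.
#' @export
occupancy_model <- function(factor_name = "factor", baseline = 0.5,
                            amplitude = 8, decay_bp = 25000,
                            gate_active = TRUE, dispersion = 0.05,
                            depth = 20, frag_len = 300L) {
  if (baseline <= 0 || amplitude < 0 || decay_bp <= 0 || depth <= 0 ||
      frag_len <= 0 || dispersion < 0) {
    stop("baseline/decay_bp/depth/frag_len must be positive; amplitude and dispersion non-negative")
  }
  structure(
    list(factor_name = factor_name, baseline = baseline, amplitude = amplitude,
         decay_bp = decay_bp, gate_active = isTRUE(gate_active),
         dispersion = dispersion, depth = depth, frag_len = as.integer(frag_len)),
    class = "occupancy_model"
  )
}

#' Per-condition modifiers of an occupancy model
#'
#' Depletion conditions act on the origin-anchored occupancy component
#' multiplicatively: `decay_mult` stretches the decay length scale (domain
#' extension, as with Pds5 or Wapl loss), `origin_amp_mult` scales the
#' component at origin centers (e.g. SA loss at origins with Pds5
#' depletion, SA gain with Brca2 depletion), and `flank_amp_mult` scales it
#' in the origin-flanking regions, with a smooth transition between the two
#' (see [occupancy_model()]). The mock condition is all ones.
#'
#' @param label Condition label (e.g. `"mock"`, `"iPds5"`).
#' @param decay_mult,origin_amp_mult,flank_amp_mult Positive multipliers.
#' @return An object of class `condition_modifiers`.
#' @export
condition_modifiers <- function(label = "mock", decay_mult = 1,
                                origin_amp_mult = 1, flank_amp_mult = 1) {
  if (decay_mult <= 0 || origin_amp_mult < 0 || flank_amp_mult <= 0) {
    stop("modifiers must be positive (origin_amp_mult may be 0)")
  }
  structure(list(label = label, decay_mult = decay_mult,
                 origin_amp_mult = origin_amp_mult,
                 flank_amp_mult = flank_amp_mult),
            class = "condition_modifiers")
}

# Distance from every base of a chromosome to the nearest origin center.
# Piecewise between consecutive origin midpoints, so each base is touched once.
distance_to_origins <- function(L, centers) {
  if (length(centers) == 0L) return(rep(Inf, L))
  centers <- sort(centers)
  cuts <- c(0, ceiling((centers[-length(centers)] + centers[-1L]) / 2), L)
  d <- numeric(L)
  for (i in seq_along(centers)) {
    lo <- cuts[i] + 1L
    hi <- cuts[i + 1L]
    if (lo > hi) next
    d[lo:hi] <- abs(seq.int(lo, hi) - 0.5 - centers[i])
  }
  d
}

# Logical active-gene mask for one chromosome.
active_mask <- function(L, genes_chrom) {
  m <- logical(L)
  act <- genes_chrom[genes_chrom$active, , drop = FALSE]
  for (i in seq_len(nrow(act))) {
    m[(act$start[i] + 1L):act$end[i]] <- TRUE
  }
  m
}

# Unnormalized expected occupancy per base for each chromosome.
occupancy_lambda <- function(ann, model, condition) {
  condition <- condition %||% condition_modifiers()
  lens <- ann$chrom_lengths
  cache <- annotation_cache(ann)
  out <- lapply(names(lens), function(ch) {
    L <- lens[[ch]]
    if (!any(ann$origins$chrom == ch)) {
      # no origin on this chromosome: occupancy is baseline everywhere,
      # kept as a scalar so long chromosomes cost nothing here
      return(model$baseline)
    }
    dk <- paste0("dist_", ch)
    if (is.null(cache[[dk]])) {
      cache[[dk]] <- distance_to_origins(L, ann$origins$center[ann$origins$chrom == ch])
    }
    d <- cache[[dk]]
    mu <- condition$origin_amp_mult +
      (condition$flank_amp_mult - condition$origin_amp_mult) *
      (1 - exp(-d / (model$decay_bp / 2)))
    lam <- model$baseline +
      model$amplitude * mu * exp(-d / (model$decay_bp * condition$decay_mult))
    if (model$gate_active) {
      mk <- paste0("mask_", ch)
      if (is.null(cache[[mk]])) {
        cache[[mk]] <- active_mask(L, ann$genes[ann$genes$chrom == ch, , drop = FALSE])
      }
      lam[!cache[[mk]]] <- model$baseline
    }
    lam
  })
  names(out) <- names(lens)
  out
}

# Per-annotation memo of distance vectors and active-gene masks; environments
# are reference objects, so repeated simulations on one annotation reuse them.
annotation_cache <- function(ann) {
  env <- attr(ann, "cache")
  if (is.null(env)) env <- new.env(parent = emptyenv())
  env
}

# Normalized (genome mean 1) relative occupancy; chromosomes without any
# origin come back as length-1 scalars (constant baseline), and the result
# is memoized per annotation/model/condition so repeated simulations on one
# genome skip the per-base exponentials.
occupancy_rate <- function(ann, model, condition) {
  condition <- condition %||% condition_modifiers()
  cache <- annotation_cache(ann)
  key <- paste("rate", model$factor_name, model$baseline, model$amplitude,
               model$decay_bp, model$gate_active, condition$decay_mult,
               condition$origin_amp_mult, condition$flank_amp_mult, sep = "|")
  if (!is.null(cache[[key]])) return(cache[[key]])
  lam <- occupancy_lambda(ann, model, condition)
  lens <- ann$chrom_lengths
  tot <- sum(vapply(names(lam), function(ch) {
    if (length(lam[[ch]]) == 1L) lam[[ch]] * as.numeric(lens[[ch]]) else sum(lam[[ch]])
  }, numeric(1L)))
  mean_lam <- tot / sum(as.numeric(lens))
  out <- lapply(lam, function(v) v / mean_lam)
  cache[[key]] <- out
  out
}

#' Expected relative occupancy of a factor model
#'
#' Returns the noise-free per-base occupancy implied by an
#' [occupancy_model()] under a condition, normalized to genome-wide mean 1.
#' This is the planted truth that [simulate_chip_pair()] adds noise to.
#'
#' @param ann A `genome_annotation`.
#' @param model An [occupancy_model()].
#' @param condition A [condition_modifiers()] (default mock).
#' @return Named list of per-chromosome numeric vectors with mean 1.
#' @export
expected_occupancy <- function(ann, model, condition = NULL) {
  rate <- occupancy_rate(ann, model, condition)
  lens <- ann$chrom_lengths
  out <- lapply(names(rate), function(ch) {
    v <- rate[[ch]]
    if (length(v) == 1L) rep(v, lens[[ch]]) else v
  })
  names(out) <- names(rate)
  out
}

#' Noise-free enrichment track implied by an occupancy model
#'
#' Builds the log2 enrichment track that the sliding-window machinery would
#' recover at infinite sequencing depth: the ChIP coverage is the expected
#' relative occupancy, the input is uniform, and no pseudocount is applied.
#' Useful as the planted truth for recovery tests and for computing planted
#' ratio profiles.
#'
#' @inheritParams expected_occupancy
#' @param window,step Sliding-window parameters (defaults 250/50).
#' @return An [enrichment_track()].
#' @export
expected_enrichment_track <- function(ann, model, condition = NULL,
                                      window = 250L, step = 50L) {
  rel <- expected_occupancy(ann, model, condition)
  chip <- coverage_track(rel)
  input <- coverage_track(lapply(ann$chrom_lengths, function(L) rep(1, L)))
  compute_enrichment(chip, input, window = window, step = step, pseudocount = 0)
}

#' Simulate a matched ChIP / input coverage pair
#'
#' Simulates fragment read starts as Poisson counts proportional to the
#' model occupancy (times a per-replicate gamma block-noise field when
#' `dispersion > 0`), extends each start by `frag_len` bp and accumulates
#' integer per-base depth. The input sample is occupancy-independent Poisson
#' noise around a uniform expected depth, emulating deeply sequenced input
#' chromatin.
#'
#' @param ann A `genome_annotation` from [simulate_genome()].
#' @param model An [occupancy_model()].
#' @param condition A [condition_modifiers()]; default mock (all ones).
#' @param input_depth Mean depth of the input track (default 45).
#' @param seed Integer seed; one seed fully determines both tracks.
#' @param make_input Set to `FALSE` to skip the input simulation (e.g. when
#'   several ChIP samples are normalized to one shared deep input).
#' @return List with elements `chip` and `input`, both [coverage_track()]s
#'   (`input` is `NULL` when `make_input = FALSE`).
#' @export
simulate_chip_pair <- function(ann, model, condition = NULL,
                               input_depth = 45, seed = 1L,
                               make_input = TRUE) {
  stopifnot(inherits(ann, "genome_annotation"), inherits(model, "occupancy_model"))
  if (input_depth <= 0) stop("`input_depth` must be positive")
  with_seed(seed, {
    rel <- occupancy_rate(ann, model, condition)
    lens <- ann$chrom_lengths
    block <- 1000L
    chip <- lapply(names(rel), function(ch) {
      L <- lens[[ch]]
      mult <- if (model$dispersion > 0) {
        nb <- ceiling(L / block)
        stats::rgamma(nb, shape = 1 / model$dispersion, rate = 1 / model$dispersion)
      } else {
        numeric(0)
      }
      .simulate_coverage(rel[[ch]], L, mult, block,
                         model$depth / model$frag_len, model$frag_len)
    })
    names(chip) <- names(rel)
    input <- if (isTRUE(make_input)) {
      new_coverage_track(lapply(lens, function(L) {
        .simulate_coverage(1, L, numeric(0), block,
                           input_depth / model$frag_len, model$frag_len)
      }))
    }
    list(chip = new_coverage_track(chip), input = input)
  })
}

# Mean-1 gamma multiplicative noise, piecewise constant in `block` bp blocks.
noise_field <- function(L, dispersion, block = 1000L) {
  nb <- ceiling(L / block)
  g <- stats::rgamma(nb, shape = 1 / dispersion, rate = 1 / dispersion)
  rep(g, each = block)[seq_len(L)]
}

# Per-base depth from per-base read-start counts extended by frag_len.
extend_starts <- function(k, frag_len) {
  .cov_from_starts(k, as.integer(frag_len))
}

#' Calibrate replicate noise dispersion to a correlation band
#'
#' The replicate-agreement band is an observed property of the experiments
#' being emulated, not a generative parameter, so the generator searches the
#' gamma block-noise dispersion that lands the genome-wide Pearson
#' correlation of two simulated replicate enrichment tracks at the middle of
#' the requested band. Correlation decreases monotonically in dispersion;
#' the search evaluates an increasing grid and linearly interpolates between
#' the bracketing values.
#'
#' @param ann A `genome_annotation`.
#' @param model An [occupancy_model()]; its `dispersion` field is ignored.
#' @param condition Optional [condition_modifiers()].
#' @param band Target correlation band (default `c(0.65, 0.9)`).
#' @param input_depth Input depth used for the trial simulations.
#' @param seed Integer seed for the trial simulations.
#' @param grid Increasing dispersions to probe.
#' @return List with `dispersion` (calibrated value) and `r` (correlation
#'   measured at it).
#' @export
calibrate_dispersion <- function(ann, model, condition = NULL,
                                 band = c(0.65, 0.9), input_depth = 45,
                                 seed = 1L,
                                 grid = c(0, 0.02, 0.05, 0.1, 0.2, 0.4, 0.8, 1.6)) {
  stopifnot(length(band) == 2L, band[1] < band[2])
  target <- mean(band)
  eval_r <- function(disp, s) {
    m <- model
    m$dispersion <- disp
    p1 <- simulate_chip_pair(ann, m, condition, input_depth, seed = derive_seed(s, 1L))
    p2 <- simulate_chip_pair(ann, m, condition, input_depth, seed = derive_seed(s, 2L))
    e1 <- compute_enrichment(p1$chip, p1$input)
    e2 <- compute_enrichment(p2$chip, p2$input)
    replicate_correlation(e1, e2)
  }
  rs <- numeric(0)
  for (i in seq_along(grid)) {
    rs[i] <- eval_r(grid[i], derive_seed(seed, i))
    if (rs[i] < target) break
  }
  k <- length(rs)
  if (rs[1] < target) {
    # even noiseless replicates sit below the target: nothing to add
    return(list(dispersion = grid[1], r = rs[1]))
  }
  if (rs[k] >= target) {
    return(list(dispersion = grid[k], r = rs[k]))
  }
  # interpolate between grid[k-1] (r above target) and grid[k] (below)
  w <- (rs[k - 1] - target) / (rs[k - 1] - rs[k])
  disp <- grid[k - 1] + w * (grid[k] - grid[k - 1])
  list(dispersion = disp, r = eval_r(disp, derive_seed(seed, 1000L)))
}
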