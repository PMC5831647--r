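#' Model of dual-label DNA fiber tract lengths
#'
#' Fibers carry two sequentially incorporated thymidine-analog labels (IdU
#' then CldU); only CldU tracts continuous with an IdU tract are measured,
#' so every simulated row has both lengths. First-label lengths are
#' log-normal; the connected second-label tract is the first length times
#' log-normal noise, and under fork-stalling treatment (e.g. hydroxyurea)
#' additionally times a stall factor in (0, 1].
#'
#' @param median_um Median first-label tract length in microns.
#' @param sdlog Log-scale SD of tract length.
#' @param ratio_sdlog Log-scale SD of the second/first length ratio.
#' @param stall_factor Multiplier applied to the second-label tract under
#'   treatment, in (0, 1].
#' @param n Number of fibers to simulate.
#' @return An object of class `fiber_model`.
#' @export
fiber_model <- function(median_um = 9, sdlog = 0.45, ratio_sdlog = 0.25,
                        stall_factor = 1, n = 200L) {
  if (median_um <= 0 || sdlog < 0 || ratio_sdlog < 0) {
    stop("`median_um` must be positive and SDs non-negative")
  }
  if (stall_factor <= 0 || stall_factor > 1) {
    stop("`stall_factor` must be in (0, 1]")
  }
  if (n < 0) stop("`n` must be non-negative")
  structure(list(median_um = median_um, sdlog = sdlog,
                 ratio_sdlog = ratio_sdlog, stall_factor = stall_factor,
                 n = as.integer(n)),
            class = "fiber_model")
}

#' Simulate a dual-label fiber table
#'
#' @param model A [fiber_model()].
#' @param treated Apply the stall factor to the second-label tract?
#' @param seed Integer seed.
#' @param group Group label for the rows; defaults to `"treated"` /
#'   `"untreated"`.
#' @return A data.frame with columns `fiber_id`, `idu_length_um`,
#'   `cldu_length_um`, `group`, `hu_treated`. All lengths are strictly
#'   positive; `n = 0` yields an empty table.
#' @export
simulate_fibers <- function(model, treated = FALSE, seed = 1L, group = NULL) {
  stopifnot(inherits(model, "fiber_model"))
  group <- group %||% if (treated) "treated" else "untreated"
  with_seed(seed, {
    n <- model$n
    idu <- stats::rlnorm(n, log(model$median_um), model$sdlog)
    stall <- if (treated) model$stall_factor else 1
    cldu <- idu * stall * exp(stats::rnorm(n, 0, model$ratio_sdlog))
    data.frame(
      fiber_id = if (n) sprintf("%s_f%04d", group, seq_len(n)) else character(0),
      idu_length_um = idu, cldu_length_um = cldu,
      group = rep(group, n), hu_treated = rep(isTRUE(treated), n)
    )
  })
}
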