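#' Evaluate an expression under a temporary RNG seed
#'
#' All stochastic operations in the package route their randomness through
#' this helper so that a single explicit integer seed per call fully
#' determines the output and the caller's RNG state is left untouched.
#'
#' @param seed Integer seed, or `NULL` to use (and advance) the current RNG
#'   state.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (is.null(seed)) {
    return(force(code))
  }
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single integer", call. = FALSE)
  }
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1L) # initialise RNG state so it can be saved
  }
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# Derive a stage-specific seed from a base seed; stays below 2^31 - 1.
derive_seed <- function(seed, k) {
  as.integer((as.double(seed) * 7919 + 104729 * as.double(k)) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# Validate a named list of per-chromosome vectors against expected names.
check_same_chromosomes <- function(a, b, what = "tracks") {
  if (!identical(sort(names(a)), sort(names(b)))) {
    stopf("%s cover different chromosomes (%s vs %s)", what,
          paste(names(a), collapse = ","), paste(names(b), collapse = ","))
  }
  invisible(TRUE)
}
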