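# run code under a temporary RNG seed, restoring the caller's RNG state
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE))
    get(".Random.seed", envir = .GlobalEnv) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = .GlobalEnv)
    else suppressWarnings(rm(".Random.seed", envir = .GlobalEnv))
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

#' Monotonic clock
#'
#' Reading of a monotonic (wall-clock-independent) timer in nanoseconds, used
#' for the benchmark timestampers and for accounting real processing time
#' into vessel busy windows.
#'
#' @return a double: nanoseconds since an arbitrary fixed origin.
#' @export
monotonic_clock_ns <- function() monotonic_ns()
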