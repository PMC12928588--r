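#' @useDynLib fleetkit, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Cooperative event scheduler on a virtual nanosecond clock.
#
# The framework's runtime is simulated in-process: every timed activity
# (source polling, inbox processing, user tasks) is an event at a virtual
# instant. Events execute atomically; "parallelism" between vessels is
# expressed through independent per-vessel busy windows on the shared virtual
# clock. This keeps every run deterministic while preserving the queueing
# semantics (a busy consumer delays only its own inbox, never a producer).

Scheduler <- R6::R6Class("Scheduler",
  public = list(
    now = 0,          # virtual ns
    initialize = function() {
      private$times <- numeric(0)
      private$seqs <- numeric(0)
      private$fns <- list()
    },

    # Schedule fn at absolute virtual time `at` (ns). Ties run in
    # scheduling order.
    schedule = function(at, fn) {
      stopifnot(is.function(fn), is.numeric(at), at >= 0)
      private$counter <- private$counter + 1
      private$times <- c(private$times, at)
      private$seqs <- c(private$seqs, private$counter)
      private$fns[[length(private$fns) + 1L]] <- fn
      invisible(private$counter)
    },

    n_pending = function() length(private$fns),

    # Run every event due at or before t_end; clock ends at t_end.
    run_until = function(t_end) {
      repeat {
        if (length(private$fns) == 0L) break
        due <- private$times <= t_end
        if (!any(due)) break
        cand <- which(due)
        i <- cand[order(private$times[cand], private$seqs[cand])][1L]
        fn <- private$fns[[i]]
        self$now <- max(self$now, private$times[i])
        private$times <- private$times[-i]
        private$seqs <- private$seqs[-i]
        private$fns[[i]] <- NULL
        fn()
      }
      self$now <- max(self$now, t_end)
      invisible(self$now)
    },

    # Advance by `sec` virtual seconds.
    run_for = function(sec) self$run_until(self$now + sec * 1e9),

    # Drain all pending events regardless of time (bounded by n events
    # currently known plus what they spawn, up to `max_events`).
    drain = function(max_events = 1e6) {
      n <- 0
      while (length(private$fns) > 0L && n < max_events) {
        self$run_until(min(private$times))
        n <- n + 1
      }
      invisible(n)
    },

    clear = function() {
      private$times <- numeric(0)
      private$seqs <- numeric(0)
      private$fns <- list()
      invisible(NULL)
    }
  ),
  private = list(times = NULL, seqs = NULL, fns = NULL, counter = 0)
)
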