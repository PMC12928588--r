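# The vessel: a fault-isolating wrapper around one component.
#
# A vessel holds the component's build/teardown logic (builder, optional
# initializer and invalidator), a pair of independent flags (state
# offline/loading/online vs. user-controlled activity), a bounded FIFO inbox
# of incoming messages, and the data operations attached to it. All component
# code runs behind guarded calls: no error raised inside a builder,
# initializer, invalidator, action or data operation ever escapes the
# framework; each produces exactly one log record and, where appropriate, an
# invalidation.

VESSEL_STATES <- c("offline", "loading", "online")
INVALIDATION_CAUSES <- c("none", "local_failure", "user", "cascade", "shutdown")

Vessel <- R6::R6Class("Vessel",
  public = list(
    name = NULL,
    queue_capacity = NULL,
    strategy = NULL,          # "queued" or "direct"
    source_rate = NULL,       # Hz or NULL (manual sourcing only)
    capture_logs = FALSE,
    state = "offline",
    is_active = TRUE,
    component = NULL,
    inbox = NULL,             # list of fleet_message
    dropped = 0,              # messages dropped on overflow
    invalidation_cause = "none",
    last_error = NULL,
    n_built = 0,
    n_invalidated = 0,
    busy_until = 0,           # virtual ns; end of current processing window
    processing_cost_ns = 0,   # extra virtual cost per processed message
    proc_pending = FALSE,     # one queued-processing slot in the scheduler
    poll_token = 0L,          # invalidates stale pollers when the rate changes
    operations = NULL,

    initialize = function(fleet, name, builder, initializer = NULL,
                          invalidator = NULL, depends_on = list(),
                          queue_capacity = 64,
                          strategy = c("queued", "direct"),
                          source_rate = NULL, capture_logs = FALSE) {
      stopifnot(is.character(name), nzchar(name), is.function(builder))
      strategy <- match.arg(strategy)
      if (!is.numeric(queue_capacity) || queue_capacity < 1)
        stop("queue_capacity must be >= 1", call. = FALSE)
      if (!is.null(source_rate) && source_rate <= 0)
        stop("source_rate must be positive (or NULL)", call. = FALSE)
      dep_names <- vapply(depends_on, function(d) d$name, character(1))
      if (anyDuplicated(dep_names))
        stop("duplicate dependencies for vessel '", name, "'", call. = FALSE)
      if (name %in% dep_names)
        stop("vessel '", name, "' cannot depend on itself", call. = FALSE)
      self$name <- name
      self$queue_capacity <- as.integer(queue_capacity)
      self$strategy <- strategy
      self$source_rate <- source_rate
      self$capture_logs <- isTRUE(capture_logs)
      self$inbox <- list()
      self$operations <- list()
      private$fleet <- fleet
      private$builder <- builder
      private$initializer <- initializer
      private$invalidator <- invalidator
      private$deps <- depends_on
    },

    fleet_ref = function() private$fleet,

    dependencies = function() private$deps,
    dependency_names = function() {
      vapply(private$deps, function(d) d$name, character(1))
    },

    is_online = function() identical(self$state, "online"),

    # Construct (and initialize) the component; offline -> loading -> online.
    # Returns a reload report; never raises for component-level failures.
    reload = function() {
      dep_states <- vapply(private$deps, function(d) d$is_online(), logical(1))
      if (!all(dep_states)) {
        off <- self$dependency_names()[!dep_states]
        err <- simpleError(sprintf(
          "dependencies not online: %s", paste(off, collapse = ", ")))
        return(private$reload_report(FALSE, err))
      }
      if (self$is_online()) {
        # user-invoked reset: tear down locally, then rebuild
        self$invalidate("user", propagate = FALSE)
      }
      private$set_state("loading")
      dep_comps <- lapply(private$deps, function(d) d$component)
      built <- private$guard("builder", private$builder, dep_comps)
      if (!built$ok || is.null(built$value)) {
        if (built$ok) {
          # a builder yielding nothing (no device matched) is a build failure
          err <- simpleError("builder returned no component")
          self$last_error <- new_error_record(self$name, "builder", err,
                                              private$fleet$now())
          private$fleet$log(self$name, paste0("builder returned no component"),
                            "error")
        }
        private$set_state("offline")
        self$invalidation_cause <- "local_failure"
        return(private$reload_report(FALSE, self$last_error))
      }
      self$component <- built$value
      self$n_built <- self$n_built + 1
      if (!is.null(private$initializer)) {
        init <- private$guard("initializer", private$initializer,
                              c(dep_comps, list(self$component)))
        if (!init$ok) {
          # the component exists: tear it down before going offline
          private$run_invalidator()
          self$component <- NULL
          self$n_invalidated <- self$n_invalidated + 1
          private$set_state("offline")
          self$invalidation_cause <- "local_failure"
          return(private$reload_report(FALSE, self$last_error))
        }
      }
      self$invalidation_cause <- "none"
      private$set_state("online")
      if (length(self$inbox) > 0) private$fleet$request_processing(self)
      private$reload_report(TRUE, NULL)
    },

    # Tear the component down; idempotent when there is nothing to tear down.
    # `propagate` controls whether the downstream-invalidation signal is
    # emitted to the link graph (a user reset inside reload() keeps it local).
    invalidate = function(cause = "user", propagate = TRUE) {
      cause <- match.arg(cause, INVALIDATION_CAUSES)
      if (!self$is_online()) return(invisible(character(0)))
      private$run_invalidator()
      self$component <- NULL
      self$n_invalidated <- self$n_invalidated + 1
      private$set_state("offline")
      self$invalidation_cause <- cause
      out <- self$name
      if (propagate) {
        desc <- private$fleet$invalidate_descendants(self)
        out <- c(out, desc)
      }
      invisible(out)
    },

    # Guarded application of arbitrary user code to the component.
    execute_call = function(action) {
      stopifnot(is.function(action))
      if (!self$is_online()) {
        return(new_call_result(FALSE, error = simpleError(
          sprintf("vessel '%s' is not available (state: %s)",
                  self$name, self$state))))
      }
      res <- private$guard("action", action, list(self$component))
      if (!res$ok) {
        self$invalidate("local_failure")
        return(new_call_result(FALSE, error = self$last_error))
      }
      new_call_result(TRUE, value = res$value)
    },

    set_active = function(flag) {
      flag <- isTRUE(flag)
      if (!identical(flag, self$is_active)) {
        self$is_active <- flag
        private$fleet$log(self$name,
                          if (flag) "activated" else "deactivated", "debug")
        if (flag && length(self$inbox) > 0 && self$is_online())
          private$fleet$request_processing(self)
      }
      invisible(self)
    },

    add_operation = function(op) {
      self$operations[[length(self$operations) + 1L]] <- op
      private$fleet$mark_data_graph_stale()
      invisible(op)
    },

    # Invoke every SOURCE operation; each value becomes a dispatched message.
    # The has_more loop is capped at queue_capacity invocations per call so a
    # greedy source cannot starve the scheduler.
    generate_data = function() {
      if (!self$is_online() || !self$is_active) return(invisible(0L))
      emitted <- 0L
      for (op in self$operations) {
        if (!identical(op$kind, "source")) next
        for (i in seq_len(self$queue_capacity)) {
          res <- private$guard("source", op$body, list(self$component))
          if (!res$ok) {
            self$invalidate("local_failure")
            return(invisible(emitted))
          }
          out <- res$value
          if (!is.null(out) && !is.null(out$value)) {
            private$fleet$emit(self, op, out$value)
            emitted <- emitted + 1L
          }
          if (is.null(out) || !isTRUE(out$has_more)) break
        }
      }
      invisible(emitted)
    },

    # Append to the inbox unless full; overflow drops the newest message.
    enqueue = function(message) {
      if (length(self$inbox) >= self$queue_capacity) {
        self$dropped <- self$dropped + 1
        private$fleet$log(self$name, sprintf(
          "inbox full (capacity %d): dropped message #%d",
          self$queue_capacity, message$metadata$message_id), "warning")
        return(invisible(FALSE))
      }
      self$inbox[[length(self$inbox) + 1L]] <- message
      private$fleet$request_processing(self)
      invisible(TRUE)
    },

    # Pop the oldest message and feed it to every matching transformer/sink.
    # Returns the processed message, or NULL if nothing was processed.
    process_inbox_step = function() {
      if (!self$is_online() || length(self$inbox) == 0) return(invisible(NULL))
      msg <- self$inbox[[1L]]
      self$inbox <- self$inbox[-1L]
      self$process_message(msg)
      invisible(msg)
    },

    # Run all compatible non-source operations over one message (used both by
    # the queued path and by direct dispatch).
    process_message = function(message) {
      meta <- message$metadata
      for (op in self$operations) {
        if (identical(op$kind, "source")) next
        if (!private$fleet$types_compatible(meta$payload_type, op$input_type))
          next
        if (!is.null(op$source_filter) &&
            !(meta$original_source %in% op$source_filter)) next
        res <- private$guard(op$kind, op$body,
                             list(self$component, message$payload, meta))
        if (!res$ok) {
          self$invalidate("local_failure")
          return(invisible(NULL))
        }
        if (identical(op$kind, "transformer") && !is.null(res$value)) {
          private$fleet$emit(self, op, res$value, parent_meta = meta)
        }
      }
      invisible(NULL)
    },

    queue_occupancy = function() length(self$inbox) / self$queue_capacity,

    print = function(...) {
      cat(sprintf("<vessel '%s' %s%s  inbox %d/%d  ops %d  deps [%s]>\n",
                  self$name, self$state,
                  if (self$is_active) " active" else " inactive",
                  length(self$inbox), self$queue_capacity,
                  length(self$operations),
                  paste(self$dependency_names(), collapse = ", ")))
      invisible(self)
    }
  ),

  private = list(
    fleet = NULL,
    builder = NULL,
    initializer = NULL,
    invalidator = NULL,
    deps = NULL,

    set_state = function(new) {
      old <- self$state
      if (identical(old, new)) return(invisible(NULL))
      self$state <- new
      # transitions log at info; the failure itself (if any) already produced
      # exactly one error-level record in guard()
      private$fleet$log(self$name, sprintf("state: %s -> %s", old, new),
                        "info")
      invisible(NULL)
    },

    # Run user code; capture stdout into the log when requested; convert any
    # error into a failed result with a structured record + one log line.
    guard = function(phase, fn, args) {
      res <- tryCatch({
        if (self$capture_logs) {
          out <- utils::capture.output(value <- do.call(fn, args))
          for (line in out) private$fleet$log(self$name, line, "info")
        } else {
          value <- do.call(fn, args)
        }
        list(ok = TRUE, value = value)
      }, error = function(e) list(ok = FALSE, condition = e))
      if (!res$ok) {
        self$last_error <- new_error_record(self$name, phase, res$condition,
                                            private$fleet$now())
        private$fleet$log(self$name, sprintf(
          "error in %s: %s", phase, conditionMessage(res$condition)), "error")
      }
      res
    },

    run_invalidator = function() {
      if (is.null(private$invalidator)) return(invisible(NULL))
      dep_comps <- lapply(private$deps, function(d) d$component)
      private$guard("invalidator", private$invalidator,
                    c(dep_comps, list(self$component)))
      invisible(NULL)
    },

    reload_report = function(ok, error) {
      structure(list(vessel = self$name, ok = ok, error = error),
                class = "fleet_reload_report")
    }
  )
)

#' @export
print.fleet_reload_report <- function(x, ...) {
  cat(sprintf("<reload '%s': %s%s>\n", x$vessel,
              if (x$ok) "ok" else "FAILED",
              if (x$ok) "" else paste0(" - ", x$error$message)))
  invisible(x)
}
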