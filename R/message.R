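# Messages and their provenance metadata.

new_message_metadata <- function(payload_type, sender, original_source,
                                 source_rate, message_id, timestamp) {
  structure(
    list(
      payload_type = payload_type,
      sender = sender,
      original_source = original_source,
      source_rate = source_rate,   # Hz or NULL
      message_id = message_id,     # fleet-global, strictly increasing
      timestamp = timestamp        # virtual monotonic ns
    ),
    class = "fleet_message_metadata"
  )
}

new_message <- function(payload, metadata) {
  structure(list(payload = payload, metadata = metadata),
            class = "fleet_message")
}

#' @export
print.fleet_message <- function(x, ...) {
  m <- x$metadata
  cat(sprintf("<message #%d %s  %s -> (from %s)%s>\n",
              m$message_id, m$payload_type, m$sender, m$original_source,
              if (is.null(m$source_rate)) "" else
                sprintf(" @%g Hz", m$source_rate)))
  invisible(x)
}

# Structured error record attached to vessels and log entries.
new_error_record <- function(vessel, phase, condition, timestamp) {
  structure(
    list(vessel = vessel, phase = phase,
         message = conditionMessage(condition), timestamp = timestamp),
    class = "fleet_error_record"
  )
}

# Guarded-call result: either a value or an error record.
new_call_result <- function(ok, value = NULL, error = NULL) {
  structure(list(ok = ok, value = value, error = error),
            class = "fleet_call_result")
}

#' Did a guarded call succeed?
#'
#' Framework calls into component code ([execute_call()], command invocation)
#' never raise; they return a call-result object. `call_succeeded()` tests it,
#' `call_value()` extracts the value (or `NULL` on failure).
#'
#' @param result a call result as returned by [execute_call()].
#' @return `call_succeeded`: logical scalar. `call_value`: the returned value.
#' @export
call_succeeded <- function(result) {
  stopifnot(inherits(result, "fleet_call_result"))
  isTRUE(result$ok)
}

#' @rdname call_succeeded
#' @export
call_value <- function(result) {
  stopifnot(inherits(result, "fleet_call_result"))
  result$value
}

#' @export
print.fleet_call_result <- function(x, ...) {
  if (x$ok) {
    cat("<call ok>\n")
  } else {
    cat(sprintf("<call failed: %s>\n",
                if (is.character(x$error)) x$error else x$error$message))
  }
  invisible(x)
}
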