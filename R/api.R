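#' Create a fleet
#'
#' A fleet is the unit an application launches: a registry of vessels plus the
#' dependency (link) graph, the data graph, a services pool, a logger and a
#' shared virtual clock. Build one, [freight()] components into it, attach
#' data operations, then [launch()].
#'
#' @param name fleet name (used in logs and graph exports).
#' @param settings_path optional path to an XML settings file (see
#'   [read_settings()]); a missing file simply yields empty settings.
#' @param log_path optional path of a log file; records are always also kept
#'   in memory.
#' @return a `Fleet` object.
#' @examples
#' fl <- fleet("demo")
#' v <- freight(fl, "Counter", builder = function() new.env())
#' launch(fl)
#' status_snapshot(fl)
#' shutdown(fl)
#' @export
fleet <- function(name = "fleet", settings_path = NULL, log_path = NULL) {
  Fleet$new(name = name, settings_path = settings_path, log_path = log_path)
}

#' Wrap a component into a vessel
#'
#' "Freighting" registers a new vessel with a fleet. The vessel starts
#' offline (no component is built yet) and active. The builder constructs the
#' component; it receives the dependency components positionally, in
#' declaration order. The optional initializer/invalidator receive the
#' dependency components followed by the component itself. A builder that
#' returns `NULL` (e.g. no matching device found) is treated as a build
#' failure: the vessel must never claim to be online around an absent
#' component.
#'
#' @param fleet a [fleet()].
#' @param name unique vessel name.
#' @param builder `function(dep1, dep2, ...)` returning the component.
#' @param initializer optional `function(dep1, ..., component)`, run right
#'   after a successful build. If it fails, the invalidator is run on the
#'   partially built component and the vessel stays offline.
#' @param invalidator optional `function(dep1, ..., component)`, run when the
#'   component is torn down. Errors are caught and logged.
#' @param depends_on vessels (or their names) this vessel depends on
#'   hierarchically; these form the link-graph edges.
#' @param queue_capacity inbox capacity in messages (default 64).
#' @param strategy `"queued"` (default; messages buffered in the inbox) or
#'   `"direct"` (processed synchronously in the sender's flow).
#' @param source_rate optional polling rate in Hz for this vessel's sources.
#' @param capture_logs if `TRUE`, standard output produced by component code
#'   is rerouted to the fleet logger, attributed to this vessel.
#' @return the new `Vessel`.
#' @export
freight <- function(fleet, name, builder, initializer = NULL,
                    invalidator = NULL, depends_on = list(),
                    queue_capacity = 64, strategy = c("queued", "direct"),
                    source_rate = NULL, capture_logs = FALSE) {
  fleet$freight(name, builder, initializer, invalidator, depends_on,
                queue_capacity, strategy, source_rate, capture_logs)
}

#' Vessel lifecycle
#'
#' `reload()` builds and initializes the component and switches the vessel
#' online (offline -> loading -> online); on an already-online vessel it first
#' tears the component down (a user reset), so the component identity
#' changes. `invalidate()` tears the component down, marks the vessel offline
#' with the given cause, and emits the downstream-invalidation signal through
#' the link graph. `execute_call()` runs arbitrary user code against the
#' component behind the framework's guard: errors are returned (never
#' re-raised) and invalidate the vessel. `set_active()` toggles the vessel's
#' participation in the data graph without touching its state.
#'
#' @param vessel a `Vessel`.
#' @param cause one of `"user"`, `"local_failure"`, `"cascade"`, `"shutdown"`.
#' @param action `function(component)`.
#' @param flag logical.
#' @return `reload`: a reload report (fields `ok`, `error`). `invalidate`:
#'   names of vessels taken offline, invisibly. `execute_call`: a call result
#'   (see [call_succeeded()]). `set_active`: the vessel, invisibly.
#' @export
reload <- function(vessel) vessel$reload()

#' @rdname reload
#' @export
invalidate <- function(vessel, cause = "user") vessel$invalidate(cause)

#' @rdname reload
#' @export
execute_call <- function(vessel, action) vessel$execute_call(action)

#' @rdname reload
#' @export
set_active <- function(vessel, flag) vessel$set_active(flag)

#' Attach data operations to a vessel
#'
#' Data operations come in three kinds. A *source* generates new data: its
#' body is `function(component)` and must return `list(value =, has_more =)`
#' (a `NULL` value emits nothing; `has_more = TRUE` re-invokes the body, up to
#' `queue_capacity` times per polling call). A *transformer* modifies data:
#' `function(component, value, metadata)` returning the new value or `NULL`
#' to emit nothing. A *sink* consumes data: `function(component, value,
#' metadata)`. Messages route automatically to every operation whose declared
#' input type is compatible with the produced type (exact match or a widening
#' registered with [register_widening()]); `source_filter` restricts an
#' operation to messages whose original source is in the given set.
#'
#' @param vessel a `Vessel`.
#' @param body the operation body (signatures above).
#' @param output_type,input_type type identifiers (strings).
#' @param source_filter optional character vector of accepted original-source
#'   vessel names.
#' @return the attached operation, invisibly.
#' @export
add_source <- function(vessel, body, output_type) {
  vessel$add_operation(new_data_operation(vessel, "source", body,
                                          output_type = output_type))
}

#' @rdname add_source
#' @export
add_transformer <- function(vessel, body, input_type, output_type,
                            source_filter = NULL) {
  vessel$add_operation(new_data_operation(vessel, "transformer", body,
                                          input_type = input_type,
                                          output_type = output_type,
                                          source_filter = source_filter))
}

#' @rdname add_source
#' @export
add_sink <- function(vessel, body, input_type, source_filter = NULL) {
  vessel$add_operation(new_data_operation(vessel, "sink", body,
                                          input_type = input_type,
                                          source_filter = source_filter))
}

#' Message generation and inbox control
#'
#' `generate_data()` invokes the vessel's sources once (respecting the
#' `has_more` drain loop) and dispatches any produced messages; it is what the
#' periodic poller calls. `process_inbox_step()` pops the oldest queued
#' message and feeds it to every matching transformer/sink on the vessel.
#' `queue_occupancy()` reports inbox fill as a fraction in `[0, 1]`.
#' `set_source_rate()` sets the polling frequency (Hz; `NULL` means sources
#' fire only on manual `generate_data()` calls).
#'
#' @param vessel a `Vessel`.
#' @param fleet the owning [fleet()].
#' @param hz polling frequency in Hz (> 0) or `NULL`.
#' @return `generate_data`: number of messages emitted, invisibly.
#'   `process_inbox_step`: the processed message or `NULL`, invisibly.
#' @export
generate_data <- function(vessel) vessel$generate_data()

#' @rdname generate_data
#' @export
process_inbox_step <- function(vessel) vessel$process_inbox_step()

#' @rdname generate_data
#' @export
queue_occupancy <- function(vessel) vessel$queue_occupancy()

#' @rdname generate_data
#' @export
set_source_rate <- function(fleet, vessel, hz) fleet$set_source_rate(vessel, hz)

#' Declare a type widening
#'
#' Routing uses exact type-identifier matches by default; a registered
#' widening additionally lets consumers of `to` accept messages of type
#' `from`.
#'
#' @param fleet a [fleet()].
#' @param from,to type identifiers.
#' @export
register_widening <- function(fleet, from, to) {
  fleet$register_widening(from, to)
}

#' Launch and stop a fleet
#'
#' `launch()` loads settings, builds and validates both graphs (a dependency
#' cycle aborts the launch), starts every vessel in topological rank order
#' (skipping vessels whose dependencies failed), and starts the source
#' pollers. Individual vessel failures do not abort the launch. `shutdown()`
#' stops the pollers and invalidates vessels in descending rank order
#' (dependents before their dependencies); it is idempotent.
#'
#' @param fleet a [fleet()].
#' @param settings_path optional settings file to load before starting.
#' @return `launch`: the per-vessel start report (columns `vessel`, `ok`,
#'   `skipped`), invisibly.
#' @export
launch <- function(fleet, settings_path = NULL) fleet$launch(settings_path)

#' @rdname launch
#' @export
shutdown <- function(fleet) fleet$shutdown()

#' Advance the fleet's clock
#'
#' The runtime is event-driven on a virtual nanosecond clock: pollers,
#' message deliveries and inbox processing are events. `run_for()` advances
#' the clock by `sec` seconds, executing everything that falls due;
#' `run_until_idle()` drains all pending events regardless of their time.
#'
#' @param fleet a [fleet()].
#' @param sec virtual seconds to advance.
#' @param max_events safety bound for `run_until_idle`.
#' @return the virtual clock reading (ns), invisibly.
#' @export
run_for <- function(fleet, sec) fleet$run_for(sec)

#' @rdname run_for
#' @export
run_until_idle <- function(fleet, max_events = 1e6) {
  fleet$run_until_idle(max_events)
}

#' Link-graph queries and failure handling
#'
#' `link_ranks()` returns the longest-path depth of every vessel in the
#' dependency DAG (roots have rank 0); startup proceeds rank by rank,
#' alphabetical within a rank. `start_in_order()` (re)starts every vessel in
#' that order. `cascade_invalidate()` invalidates a vessel and all of its
#' link-graph descendants (data-graph-only neighbours are untouched) and
#' returns the invalidated set. `restore_segment()` reloads a repaired vessel
#' and revives exactly its cascade casualties, leaving user-stopped vessels
#' down.
#'
#' @param fleet a [fleet()].
#' @param vessel a `Vessel` or vessel name.
#' @param cause recorded invalidation cause for the origin.
#' @return `link_ranks`: named integer vector. `cascade_invalidate` /
#'   `restore_segment`: character vector of affected vessel names.
#' @export
link_ranks <- function(fleet) fleet$link_ranks()

#' @rdname link_ranks
#' @export
start_in_order <- function(fleet) fleet$start_in_order()

#' @rdname link_ranks
#' @export
cascade_invalidate <- function(fleet, vessel, cause = "local_failure") {
  fleet$cascade_invalidate(vessel, cause)
}

#' @rdname link_ranks
#' @export
restore_segment <- function(fleet, vessel) fleet$restore_segment(vessel)

#' Textual status and graph export
#'
#' `status_snapshot()` gives a consistent point-in-time table of every
#' vessel's state, activity flag, inbox occupancy and dropped-message count.
#' `fleet_to_dot()` renders both graphs as DOT text (solid link edges, dashed
#' data edges).
#'
#' @param fleet a [fleet()].
#' @return `status_snapshot`: a data frame. `fleet_to_dot`: a string.
#' @export
status_snapshot <- function(fleet) fleet$status_snapshot()

#' @rdname status_snapshot
#' @export
fleet_to_dot <- function(fleet) fleet$to_dot()

#' Fleet-scoped services
#'
#' A service is a lazily constructed singleton kept in the fleet's services
#' pool: the first `get_service()` call constructs it, later calls return the
#' same instance, so state persists across callers. Access is serialized (one
#' caller at a time); `with_service()` runs `fn(instance)` inside the access
#' guard. A failing constructor propagates its error and caches nothing, so a
#' later call retries.
#'
#' @param fleet a [fleet()].
#' @param name service identifier.
#' @param constructor zero-argument function building the instance.
#' @param fn `function(instance)` to run under the access guard.
#' @export
get_service <- function(fleet, name, constructor = NULL) {
  fleet$get_service(name, constructor)
}

#' @rdname get_service
#' @export
with_service <- function(fleet, name, fn, constructor = NULL) {
  fleet$with_service(name, fn, constructor)
}

#' Text-command registry
#'
#' Vessels can expose arbitrary code under text commands. Invocation routes
#' through the guarded-call machinery: a failing action invalidates the
#' owning vessel and returns an error result, never raising in the caller.
#'
#' @param fleet a [fleet()].
#' @param vessel owning `Vessel` (or name).
#' @param name command name, unique per fleet.
#' @param action `function(component, ...)`.
#' @param ... arguments forwarded to the action.
#' @return `invoke_command`: a call result (see [call_succeeded()]).
#' @export
register_command <- function(fleet, vessel, name, action) {
  fleet$register_command(vessel, name, action)
}

#' @rdname register_command
#' @export
invoke_command <- function(fleet, name, ...) fleet$invoke_command(name, ...)

# internal: operation constructor shared by the add_* wrappers
new_data_operation <- function(vessel, kind, body, input_type = NULL,
                               output_type = NULL, source_filter = NULL) {
  stopifnot(is.function(body))
  fl <- vessel$fleet_ref()
  structure(
    list(id = fl$next_op_id(), kind = kind, owner = vessel$name, body = body,
         input_type = input_type, output_type = output_type,
         source_filter = source_filter),
    class = "fleet_data_operation"
  )
}
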