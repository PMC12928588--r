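# The fleet: all vessels, both graphs, and the shared runtime.

Fleet <- R6::R6Class("Fleet",
  public = list(
    name = NULL,
    scheduler = NULL,
    logger = NULL,
    settings = NULL,        # settings document or NULL
    running = FALSE,
    user_data_path = NULL,

    initialize = function(name = "fleet", settings_path = NULL,
                          log_path = NULL) {
      self$name <- name
      self$scheduler <- Scheduler$new()
      self$logger <- Logger$new(path = log_path)
      private$vessels <- list()
      private$widenings <- list()
      private$services <- new.env(parent = emptyenv())
      private$service_locks <- new.env(parent = emptyenv())
      private$commands <- new.env(parent = emptyenv())
      if (!is.null(settings_path)) self$load_settings(settings_path)
      self$user_data_path <- self$setting_or("UserDataPath", tempfile("fleet_"))
      self$log("fleet", sprintf("fleet '%s' created", name), "notice")
    },

    now = function() self$scheduler$now,

    log = function(origin, text, level = "info") {
      self$logger$log(origin, text, level, wall = Sys.time())
      invisible(NULL)
    },

    load_settings = function(path) {
      self$settings <- read_settings(path)
      invisible(self$settings)
    },

    setting_or = function(name, default, path = character(0)) {
      v <- fetch_setting(self$settings, path, name)
      if (is.null(v)) default else v
    },

    ## -- vessel registry --------------------------------------------------

    # Wrap a component into a new vessel ("freighting").
    freight = function(name, builder, initializer = NULL, invalidator = NULL,
                       depends_on = list(), queue_capacity = 64,
                       strategy = c("queued", "direct"), source_rate = NULL,
                       capture_logs = FALSE) {
      if (name %in% names(private$vessels))
        stop("a vessel named '", name, "' is already registered",
             call. = FALSE)
      if (inherits(depends_on, "Vessel")) depends_on <- list(depends_on)
      depends_on <- lapply(depends_on, function(d) {
        if (is.character(d)) self$vessel(d) else d
      })
      v <- Vessel$new(self, name, builder, initializer, invalidator,
                      depends_on, queue_capacity, strategy, source_rate,
                      capture_logs)
      private$vessels[[name]] <- v
      private$link_stale <- TRUE
      private$data_stale <- TRUE
      self$log(name, "freighted (offline, active)", "debug")
      v
    },

    vessel = function(name) {
      v <- private$vessels[[name]]
      if (is.null(v)) stop("no vessel named '", name, "'", call. = FALSE)
      v
    },

    vessel_names = function() names(private$vessels),
    all_vessels = function() private$vessels,

    ## -- link graph -------------------------------------------------------

    # Dependency DAG ranks: longest-path depth from the roots.
    link_ranks = function() {
      private$ensure_link_graph()
      private$ranks
    },

    link_edges = function() {
      private$ensure_link_graph()
      private$edges
    },

    # Reload every vessel rank by rank (alphabetical within a rank); a vessel
    # whose dependency is not online is skipped and marked as a cascade
    # casualty.
    start_in_order = function() {
      private$ensure_link_graph()
      order <- private$startup_order()
      if (length(order) == 0)
        return(data.frame(vessel = character(0), ok = logical(0),
                          skipped = logical(0)))
      rows <- lapply(order, function(nm) {
        v <- self$vessel(nm)
        deps_ok <- all(vapply(v$dependencies(), function(d) d$is_online(),
                              logical(1)))
        if (!deps_ok) {
          v$invalidation_cause <- "cascade"
          self$log(nm, "start skipped: dependency offline", "warning")
          return(data.frame(vessel = nm, ok = FALSE, skipped = TRUE,
                            stringsAsFactors = FALSE))
        }
        rep <- v$reload()
        data.frame(vessel = nm, ok = rep$ok, skipped = FALSE,
                   stringsAsFactors = FALSE)
      })
      do.call(rbind, c(rows, list(make.row.names = FALSE)))
    },

    # Invalidate origin and every link-graph descendant (ascending rank).
    # Returns the names actually taken offline (origin included).
    cascade_invalidate = function(vessel, cause = "local_failure") {
      if (is.character(vessel)) vessel <- self$vessel(vessel)
      out <- vessel$invalidate(cause, propagate = TRUE)
      unique(c(vessel$name, out))
    },

    # Called by Vessel$invalidate when the downstream signal propagates.
    invalidate_descendants = function(origin) {
      private$ensure_link_graph()
      desc <- private$descendants(origin$name)
      if (length(desc) == 0) return(character(0))
      desc <- desc[order(private$ranks[desc], desc)]
      hit <- character(0)
      for (nm in desc) {
        v <- self$vessel(nm)
        if (v$is_online()) {
          v$invalidate("cascade", propagate = FALSE)
          hit <- c(hit, nm)
        }
      }
      hit
    },

    # Reload a repaired vessel, then revive its cascade casualties (and only
    # those) in ascending rank order. User-stopped vessels stay down.
    restore_segment = function(vessel) {
      if (is.character(vessel)) vessel <- self$vessel(vessel)
      private$ensure_link_graph()
      deps_ok <- all(vapply(vessel$dependencies(), function(d) d$is_online(),
                            logical(1)))
      if (!deps_ok)
        stop("cannot restore '", vessel$name,
             "': its dependencies are not online", call. = FALSE)
      restored <- character(0)
      rep <- vessel$reload()
      if (!rep$ok) return(invisible(restored))
      restored <- vessel$name
      desc <- private$descendants(vessel$name)
      desc <- desc[order(private$ranks[desc], desc)]
      for (nm in desc) {
        v <- self$vessel(nm)
        if (!v$is_online() && identical(v$invalidation_cause, "cascade")) {
          ok <- all(vapply(v$dependencies(), function(d) d$is_online(),
                           logical(1)))
          if (ok && v$reload()$ok) restored <- c(restored, nm)
        }
      }
      invisible(restored)
    },

    ## -- data graph -------------------------------------------------------

    register_widening = function(from, to) {
      private$widenings[[from]] <- unique(c(private$widenings[[from]], to))
      private$data_stale <- TRUE
      invisible(NULL)
    },

    types_compatible = function(produced, consumed) {
      if (is.null(produced) || is.null(consumed)) return(FALSE)
      identical(produced, consumed) || consumed %in% private$widenings[[produced]]
    },

    mark_data_graph_stale = function() {
      private$data_stale <- TRUE
      invisible(NULL)
    },

    next_op_id = function() {
      private$op_counter <- private$op_counter + 1L
      private$op_counter
    },

    # Type-compatible producer -> consumer routes (a multidigraph: one route
    # per operation pair; parallel routes between two vessels are fine).
    data_routes = function() {
      if (private$data_stale) private$build_data_graph()
      private$routes
    },

    ## -- messaging --------------------------------------------------------

    # Stamp a payload with metadata and multicast it.
    emit = function(vessel, op, payload, parent_meta = NULL) {
      meta <- new_message_metadata(
        payload_type = op$output_type,
        sender = vessel$name,
        original_source = if (is.null(parent_meta)) vessel$name
                          else parent_meta$original_source,
        source_rate = if (is.null(parent_meta)) vessel$source_rate
                      else parent_meta$source_rate,
        message_id = private$next_message_id(),
        timestamp = self$now())
      msg <- new_message(payload, meta)
      self$dispatch(msg, op)
      invisible(msg)
    },

    # Deliver a message along every route leaving `producing_op`. Returns the
    # number of vessels it reached.
    dispatch = function(message, producing_op) {
      routes <- self$data_routes()
      mine <- routes[vapply(routes, function(r) r$from == producing_op$id,
                            logical(1))]
      if (length(mine) == 0) return(invisible(0L))
      # group consumer operations by owning vessel, in attachment order
      owners <- unique(vapply(mine, function(r) r$to_owner, character(1)))
      delivered <- 0L
      for (nm in owners) {
        v <- self$vessel(nm)
        if (!v$is_online() || !v$is_active) next
        ops <- mine[vapply(mine, function(r) r$to_owner == nm, logical(1))]
        # at least one route's operation must pass the source filter
        passes <- vapply(ops, function(r) {
          f <- r$to_filter
          is.null(f) || message$metadata$original_source %in% f
        }, logical(1))
        if (!any(passes)) next
        if (identical(v$strategy, "direct")) {
          v$process_message(message)
          delivered <- delivered + 1L
        } else if (isTRUE(v$enqueue(message))) {
          delivered <- delivered + 1L
        }
      }
      invisible(delivered)
    },

    # One queued-processing slot per vessel: schedules an inbox step at the
    # end of the vessel's current busy window. Real elapsed time of the step
    # (plus any configured virtual cost) extends the window, so a slow
    # consumer back-pressures only itself.
    request_processing = function(vessel) {
      if (vessel$proc_pending) return(invisible(NULL))
      vessel$proc_pending <- TRUE
      at <- max(self$scheduler$now, vessel$busy_until)
      self$scheduler$schedule(at, function() {
        vessel$proc_pending <- FALSE
        if (!vessel$is_online() || !vessel$is_active ||
            length(vessel$inbox) == 0) return(invisible(NULL))
        t0 <- monotonic_ns()
        vessel$process_inbox_step()
        elapsed <- monotonic_ns() - t0
        start <- max(self$scheduler$now, vessel$busy_until)
        vessel$busy_until <- start + elapsed + vessel$processing_cost_ns
        if (length(vessel$inbox) > 0) self$request_processing(vessel)
        invisible(NULL)
      })
      invisible(NULL)
    },

    set_source_rate = function(vessel, hz) {
      if (is.character(vessel)) vessel <- self$vessel(vessel)
      if (!is.null(hz) && (!is.numeric(hz) || hz <= 0))
        stop("source rate must be a positive frequency in Hz (or NULL)",
             call. = FALSE)
      vessel$source_rate <- hz
      vessel$poll_token <- vessel$poll_token + 1L
      if (self$running && !is.null(hz)) private$start_polling(vessel)
      invisible(NULL)
    },

    ## -- lifecycle --------------------------------------------------------

    # Settings -> graphs -> ordered start -> pollers.
    launch = function(settings_path = NULL) {
      if (!is.null(settings_path)) self$load_settings(settings_path)
      private$ensure_link_graph()   # cycle here aborts the launch
      private$build_data_graph()
      report <- self$start_in_order()
      self$running <- TRUE
      for (v in private$vessels) {
        if (!is.null(v$source_rate)) private$start_polling(v)
      }
      self$log("fleet", "launch complete", "notice")
      invisible(report)
    },

    run_for = function(sec) {
      self$scheduler$run_for(sec)
      invisible(self$now())
    },

    # Drain in-flight work (queued processing, pending deliveries). Pollers
    # are paused for the drain -- otherwise a periodic source would reschedule
    # itself forever -- and restarted afterwards.
    run_until_idle = function(max_events = 1e6) {
      was <- self$running
      self$running <- FALSE
      self$scheduler$drain(max_events)
      self$running <- was
      if (was) {
        for (v in private$vessels) {
          if (!is.null(v$source_rate)) {
            v$poll_token <- v$poll_token + 1L
            private$start_polling(v)
          }
        }
      }
      invisible(self$now())
    },

    # Stop pollers, then invalidate dependents before their dependencies.
    shutdown = function() {
      if (!self$running &&
          !any(vapply(private$vessels, function(v) v$is_online(), logical(1))))
        return(invisible(NULL))
      self$running <- FALSE
      private$ensure_link_graph()
      nms <- names(private$vessels)
      if (length(nms) > 0) {
        nms <- nms[order(-private$ranks[nms], nms)]
        for (nm in nms) {
          v <- self$vessel(nm)
          if (v$is_online()) v$invalidate("shutdown", propagate = FALSE)
        }
      }
      self$logger$flush()
      self$log("fleet", "shutdown complete", "notice")
      invisible(NULL)
    },

    status_snapshot = function() {
      rows <- lapply(private$vessels, function(v) {
        data.frame(vessel = v$name, state = v$state, active = v$is_active,
                   occupancy_pct = 100 * v$queue_occupancy(),
                   queued = length(v$inbox), dropped = v$dropped,
                   stringsAsFactors = FALSE)
      })
      out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
      if (is.null(out))
        out <- data.frame(vessel = character(0), state = character(0),
                          active = logical(0), occupancy_pct = numeric(0),
                          queued = integer(0), dropped = numeric(0))
      out
    },

    # DOT text with the two edge classes: solid link edges, dashed data edges.
    to_dot = function() {
      private$ensure_link_graph()
      routes <- self$data_routes()
      lines <- c(sprintf("digraph \"%s\" {", self$name),
                 "  node [shape=box];")
      for (nm in names(private$vessels))
        lines <- c(lines, sprintf("  \"%s\";", nm))
      for (e in private$edges)
        lines <- c(lines, sprintf("  \"%s\" -> \"%s\" [color=blue];",
                                  e[1], e[2]))
      seen <- character(0)
      for (r in routes) {
        key <- paste(r$from_owner, r$to_owner, sep = "\r")
        if (key %in% seen) next
        seen <- c(seen, key)
        lines <- c(lines, sprintf(
          "  \"%s\" -> \"%s\" [style=dashed, color=purple];",
          r$from_owner, r$to_owner))
      }
      paste(c(lines, "}"), collapse = "\n")
    },

    ## -- services / commands ---------------------------------------------

    # Lazily constructed fleet-scoped singleton, reused on every later call.
    get_service = function(name, constructor = NULL) {
      if (exists(name, envir = private$services, inherits = FALSE))
        return(get(name, envir = private$services))
      if (is.null(constructor))
        stop("service '", name, "' has not been constructed yet and no ",
             "constructor was given", call. = FALSE)
      inst <- constructor()   # a failure propagates; nothing is cached
      assign(name, inst, envir = private$services)
      self$log("services", sprintf("service '%s' constructed", name), "debug")
      inst
    },

    # Serialized access: one caller at a time per service. The cooperative
    # runtime executes critical sections atomically; the guard additionally
    # rejects re-entrant acquisition from within a section.
    with_service = function(name, fn, constructor = NULL) {
      inst <- self$get_service(name, constructor)
      if (isTRUE(private$service_locks[[name]]))
        stop("service '", name, "' is busy (re-entrant access)", call. = FALSE)
      private$service_locks[[name]] <- TRUE
      on.exit(private$service_locks[[name]] <- FALSE, add = TRUE)
      fn(inst)
    },

    register_command = function(vessel, name, action) {
      if (is.character(vessel)) vessel <- self$vessel(vessel)
      if (exists(name, envir = private$commands, inherits = FALSE))
        stop("command '", name, "' is already registered", call. = FALSE)
      assign(name, list(vessel = vessel, action = action),
             envir = private$commands)
      invisible(NULL)
    },

    invoke_command = function(name, ...) {
      if (!exists(name, envir = private$commands, inherits = FALSE))
        return(new_call_result(FALSE, error = simpleError(
          sprintf("unknown command '%s'", name))))
      cmd <- get(name, envir = private$commands)
      args <- list(...)
      cmd$vessel$execute_call(function(comp) do.call(cmd$action,
                                                     c(list(comp), args)))
    },

    print = function(...) {
      snap <- self$status_snapshot()
      cat(sprintf("<fleet '%s': %d vessels, %s>\n", self$name, nrow(snap),
                  if (self$running) "running" else "stopped"))
      if (nrow(snap) > 0) print(snap)
      invisible(self)
    }
  ),

  private = list(
    vessels = NULL,
    widenings = NULL,
    services = NULL,
    service_locks = NULL,
    commands = NULL,
    routes = list(),
    edges = list(),
    ranks = integer(0),
    graph = NULL,           # igraph of the link layer
    link_stale = TRUE,
    data_stale = TRUE,
    msg_counter = -1,
    op_counter = 0L,

    next_message_id = function() {
      private$msg_counter <- private$msg_counter + 1
      private$msg_counter
    },

    # Build/validate the dependency DAG and assign longest-path ranks.
    ensure_link_graph = function() {
      if (!private$link_stale) return(invisible(NULL))
      nms <- names(private$vessels)
      edges <- list()
      for (v in private$vessels) {
        for (d in v$dependency_names()) edges <- c(edges, list(c(d, v$name)))
      }
      g <- igraph::make_empty_graph(directed = TRUE)
      g <- igraph::add_vertices(g, length(nms), name = nms)
      if (length(edges) > 0)
        g <- igraph::add_edges(g, unlist(lapply(edges, function(e)
          c(which(nms == e[1]), which(nms == e[2])))))
      if (length(nms) > 0 && !igraph::is_dag(g)) {
        in_cycle <- nms[vapply(seq_along(nms), function(i) {
          reach <- igraph::subcomponent(g, i, mode = "out")
          any(vapply(igraph::neighbors(g, i, mode = "in"),
                     function(j) j %in% reach, logical(1)))
        }, logical(1))]
        stop("dependency cycle detected involving: ",
             paste(in_cycle, collapse = ", "), call. = FALSE)
      }
      ranks <- integer(length(nms))
      names(ranks) <- nms
      if (length(nms) > 0) {
        topo <- nms[as.integer(igraph::topo_sort(g, mode = "out"))]
        for (nm in topo) {
          deps <- self$vessel(nm)$dependency_names()
          ranks[nm] <- if (length(deps) == 0) 0L else
            max(ranks[deps]) + 1L
        }
      }
      private$graph <- g
      private$edges <- edges
      private$ranks <- ranks
      private$link_stale <- FALSE
      invisible(NULL)
    },

    startup_order = function() {
      nms <- names(private$vessels)
      if (length(nms) == 0) return(character(0))
      nms[order(private$ranks[nms], nms)]
    },

    descendants = function(name) {
      nms <- names(private$vessels)
      i <- which(nms == name)
      reach <- nms[as.integer(igraph::subcomponent(private$graph, i,
                                                   mode = "out"))]
      setdiff(reach, name)
    },

    build_data_graph = function() {
      routes <- list()
      for (v in private$vessels) {
        for (op in v$operations) {
          if (is.null(op$output_type)) next
          for (w in private$vessels) {
            for (cons in w$operations) {
              if (identical(cons$kind, "source")) next
              if (identical(cons$id, op$id)) next  # no self-route
              if (!self$types_compatible(op$output_type, cons$input_type))
                next
              routes <- c(routes, list(list(
                from = op$id, from_owner = v$name,
                to = cons$id, to_owner = w$name,
                to_filter = cons$source_filter)))
            }
          }
        }
      }
      private$routes <- routes
      private$data_stale <- FALSE
      invisible(NULL)
    },

    start_polling = function(vessel) {
      token <- vessel$poll_token
      period <- 1e9 / vessel$source_rate
      tick <- NULL
      tick <- function() {
        if (!self$running || vessel$poll_token != token ||
            is.null(vessel$source_rate)) return(invisible(NULL))
        vessel$generate_data()
        self$scheduler$schedule(self$scheduler$now + period, tick)
        invisible(NULL)
      }
      self$scheduler$schedule(self$scheduler$now + period, tick)
      invisible(NULL)
    }
  )
)
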