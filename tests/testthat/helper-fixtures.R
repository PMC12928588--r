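# Shared fixtures: an eight-vessel reference fleet, counting components,
# random DAG generators and a hand-written reachability oracle (kept
# independent of the package's graph machinery).

# Reference fleet: link edges A->B, B->C, B->D, F->G, G->H; E isolated.
# One data-only edge H -> E. Builders/invalidators count invocations and
# record call order in `trace`.
make_ref_fleet <- function(failing = character(0)) {
  fl <- fleet("ref")
  trace <- new.env(parent = emptyenv())
  trace$order <- character(0)
  trace$built <- integer(0)
  trace$torn <- integer(0)
  mk <- function(name, deps = list()) {
    force(name)
    freight(fl, name, depends_on = deps,
      builder = function(...) {
        trace$order <- c(trace$order, name)
        trace$built[name] <- (if (is.na(trace$built[name])) 0L
                              else trace$built[name]) + 1L
        if (name %in% failing) stop("injected failure in ", name)
        list(tag = name)
      },
      invalidator = function(..., comp) {
        trace$torn[name] <- (if (is.na(trace$torn[name])) 0L
                             else trace$torn[name]) + 1L
      })
  }
  A <- mk("A"); B <- mk("B", list(A)); C <- mk("C", list(B))
  D <- mk("D", list(B)); E <- mk("E"); F <- mk("F")
  G <- mk("G", list(F)); H <- mk("H", list(G))
  # data edge H -> E
  add_source(H, output_type = "hdata", body = function(comp)
    list(value = "payload", has_more = FALSE))
  trace$e_seen <- 0L
  add_sink(E, input_type = "hdata", body = function(comp, v, m)
    trace$e_seen <- trace$e_seen + 1L)
  list(fleet = fl, trace = trace)
}

# random DAG over n vessels: edge i -> j allowed only for i < j in a random
# labelling, so acyclicity holds by construction
make_random_dag_fleet <- function(n, p = 0.3) {
  nms <- sprintf("V%02d", sample(n))
  edges <- list()
  fl <- fleet("rand")
  trace <- new.env(parent = emptyenv())
  trace$order <- character(0)
  vessels <- list()
  for (i in seq_len(n)) {
    deps <- list()
    if (i > 1) {
      pick <- which(stats::runif(i - 1) < p)
      deps <- vessels[pick]
      for (j in pick) edges <- c(edges, list(c(nms[j], nms[i])))
    }
    nm <- nms[i]
    vessels[[i]] <- freight(fl, nm, depends_on = deps,
      builder = local({
        nm0 <- nm
        function(...) {
          trace$order <- c(trace$order, nm0)
          list(tag = nm0)
        }
      }))
  }
  list(fleet = fl, edges = edges, names = nms, trace = trace)
}

# independent oracle: breadth-first reachability over an explicit edge list
bfs_descendants <- function(edges, origin) {
  adj <- list()
  for (e in edges) adj[[e[1]]] <- c(adj[[e[1]]], e[2])
  seen <- character(0)
  frontier <- origin
  while (length(frontier) > 0) {
    nxt <- unique(unlist(lapply(frontier, function(v) adj[[v]])))
    nxt <- setdiff(nxt, c(seen, origin))
    seen <- c(seen, nxt)
    frontier <- nxt
  }
  sort(seen)
}

# simple chain fleet: source vessel -> optional transformer vessels -> sink
# vessel; the sink records (payload, sender, original_source, message_id)
make_chain_fleet <- function(n_hops = 0) {
  fl <- fleet("chain")
  src <- freight(fl, "Src", builder = function() new.env())
  queue <- new.env(parent = emptyenv())
  queue$pending <- list()
  add_source(src, output_type = "t0", body = function(comp) {
    if (length(queue$pending) == 0)
      return(list(value = NULL, has_more = FALSE))
    v <- queue$pending[[1]]
    queue$pending <- queue$pending[-1]
    list(value = v, has_more = length(queue$pending) > 0)
  })
  prev_type <- "t0"
  for (k in seq_len(n_hops)) {
    hop <- freight(fl, sprintf("Hop%d", k), builder = function() list())
    out_type <- sprintf("t%d", k)
    add_transformer(hop, input_type = prev_type, output_type = out_type,
                    body = function(comp, v, m) v)
    prev_type <- out_type
  }
  sink <- freight(fl, "Sink", builder = function() new.env())
  seen <- new.env(parent = emptyenv())
  seen$rows <- list()
  add_sink(sink, input_type = prev_type, body = function(comp, v, m) {
    seen$rows[[length(seen$rows) + 1L]] <-
      list(payload = v, sender = m$sender,
           original_source = m$original_source, id = m$message_id)
  })
  list(fleet = fl, queue = queue, seen = seen)
}

seen_df <- function(seen) {
  rows <- seen$rows
  data.frame(
    payload = vapply(rows, function(r) as.numeric(r$payload), numeric(1)),
    sender = vapply(rows, `[[`, "", "sender"),
    original_source = vapply(rows, `[[`, "", "original_source"),
    id = vapply(rows, function(r) as.numeric(r$id), numeric(1)))
}
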