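# Typed messaging: routing, metadata, FIFO queues, overflow, isolation.

test_that("routes follow type compatibility exactly (producer x consumer)", {
  fl <- fleet("t")
  types_out <- c("T", "T", "T", "U")
  for (i in seq_along(types_out)) {
    v <- freight(fl, sprintf("P%d", i), builder = function() list())
    add_source(v, output_type = types_out[i], body = function(comp)
      list(value = 1, has_more = FALSE))
  }
  types_in <- c("T", "T", "V")
  for (i in seq_along(types_in)) {
    v <- freight(fl, sprintf("C%d", i), builder = function() list())
    add_sink(v, input_type = types_in[i], body = function(comp, v, m) NULL)
  }
  routes <- fl$data_routes()
  # brute-force expectation: 3 producers of T x 2 consumers of T
  expect_equal(length(routes), sum(outer(types_out, types_in, `==`)))

  # a widening opens the U -> V route
  register_widening(fl, "U", "V")
  expect_equal(length(fl$data_routes()),
               sum(outer(types_out, types_in, `==`)) + 1)
})

test_that("multiple sinks on one vessel and unmatched sinks are permitted", {
  fl <- fleet("t")
  s <- freight(fl, "S", builder = function() list())
  add_source(s, output_type = "frame", body = function(comp)
    list(value = 0, has_more = FALSE))
  d <- freight(fl, "D", builder = function() new.env())
  n1 <- 0; n2 <- 0
  add_sink(d, input_type = "frame", body = function(comp, v, m) n1 <<- n1 + 1)
  add_sink(d, input_type = "frame", body = function(comp, v, m) n2 <<- n2 + 1)
  orphan <- freight(fl, "O", builder = function() list())
  add_sink(orphan, input_type = "nobody_makes_this",
           body = function(comp, v, m) NULL)
  launch(fl)
  routes <- fl$data_routes()
  expect_equal(sum(vapply(routes, function(r) r$to_owner == "O", logical(1))),
               0)
  generate_data(s)
  run_until_idle(fl)
  # one enqueued message, processed by both sinks
  expect_equal(c(n1, n2), c(1, 1))
})

test_that("source drain loop emits consecutive ids and respects the cap", {
  ch <- make_chain_fleet(0)
  launch(ch$fleet)
  ch$queue$pending <- as.list(1:5)
  expect_equal(generate_data(ch$fleet$vessel("Src")), 5L)
  run_until_idle(ch$fleet)
  df <- seen_df(ch$seen)
  expect_equal(df$payload, 1:5)
  expect_equal(diff(df$id), rep(1, 4))          # consecutive fleet-global ids

  # drain cap: more pending values than queue_capacity emits at most capacity
  cap <- ch$fleet$vessel("Src")$queue_capacity
  ch$queue$pending <- as.list(seq_len(cap + 10))
  expect_equal(generate_data(ch$fleet$vessel("Src")), cap)
})

test_that("metadata: original_source survives a 3-hop chain, sender updates per hop", {
  ch <- make_chain_fleet(3)
  launch(ch$fleet)
  ch$queue$pending <- list(7)
  generate_data(ch$fleet$vessel("Src"))
  run_until_idle(ch$fleet)
  df <- seen_df(ch$seen)
  expect_equal(nrow(df), 1)
  expect_identical(df$original_source, "Src")
  expect_identical(df$sender, "Hop3")
})

test_that("FIFO: messages process in emission order per consumer", {
  ch <- make_chain_fleet(0)
  launch(ch$fleet)
  set.seed(11)
  all_vals <- numeric(0)
  for (burst in 1:10) {
    vals <- sample(1000, sample(1:8, 1))
    all_vals <- c(all_vals, vals)
    ch$queue$pending <- as.list(vals)
    generate_data(ch$fleet$vessel("Src"))
    if (burst %% 3 == 0) run_until_idle(ch$fleet)
  }
  run_until_idle(ch$fleet)
  df <- seen_df(ch$seen)
  expect_equal(order(df$id), seq_len(nrow(df)))   # processed in id order
  expect_equal(df$payload, all_vals)              # ... which is emission order
})

test_that("source filtering excludes foreign original sources", {
  fl <- fleet("t")
  mk_cam <- function(nm) {
    v <- freight(fl, nm, builder = function() list())
    add_source(v, output_type = "frame", body = function(comp)
      list(value = nm, has_more = FALSE))
    v
  }
  a <- mk_cam("CameraA"); b <- mk_cam("CameraB")
  snk <- freight(fl, "Saver", builder = function() list())
  got <- character(0)
  add_sink(snk, input_type = "frame", source_filter = "CameraA",
           body = function(comp, v, m) got <<- c(got, m$original_source))
  launch(fl)
  generate_data(a); generate_data(b)
  run_until_idle(fl)
  expect_identical(got, "CameraA")
})

test_that("a full inbox drops the newest message and reports occupancy", {
  fl <- fleet("t")
  src <- freight(fl, "Src", builder = function() list())
  add_source(src, output_type = "x", body = function(comp)
    list(value = 1, has_more = FALSE))
  slow <- freight(fl, "Slow", builder = function() list(), queue_capacity = 4)
  add_sink(slow, input_type = "x", body = function(comp, v, m) NULL)
  launch(fl)
  slow$processing_cost_ns <- 1e12      # effectively stalled
  expect_equal(queue_occupancy(slow), 0)
  for (i in 1:4) generate_data(src)
  expect_equal(queue_occupancy(slow), 1)
  expect_equal(slow$dropped, 0)
  generate_data(src)                   # fifth: dropped, queue stays at 4
  expect_equal(length(slow$inbox), 4)
  expect_equal(slow$dropped, 1)
  expect_true(any(grepl("inbox full", log_records(fl, "warning")$text)))
})

test_that("periodic polling emits at the requested rate; inactive vessels stay silent", {
  fl <- fleet("t")
  src <- freight(fl, "Src", builder = function() list())
  add_source(src, output_type = "x", body = function(comp)
    list(value = 1, has_more = FALSE))
  n <- 0
  snk <- freight(fl, "Snk", builder = function() list())
  add_sink(snk, input_type = "x", body = function(comp, v, m) n <<- n + 1)
  launch(fl)
  set_source_rate(fl, src, 100)
  run_for(fl, 1)
  run_until_idle(fl)
  expect_equal(n, 100, tolerance = 0.2)
  expect_error(set_source_rate(fl, src, -5), "positive")

  n <- 0
  set_active(src, FALSE)
  run_for(fl, 0.5)
  expect_equal(n, 0)
})

test_that("producer isolation: a stalled consumer never slows the source", {
  fl <- fleet("t")
  src <- freight(fl, "Src", builder = function() new.env())
  src_emitted <- 0
  add_source(src, output_type = "x", body = function(comp) {
    src_emitted <<- src_emitted + 1
    list(value = src_emitted, has_more = FALSE)
  })
  stalled <- freight(fl, "Stalled", builder = function() list(),
                     queue_capacity = 8)
  add_sink(stalled, input_type = "x", body = function(comp, v, m) NULL)
  launch(fl)
  stalled$processing_cost_ns <- 1e9     # 1 s per message >> 20 ms period
  set_source_rate(fl, src, 50)
  run_for(fl, 2)
  expect_equal(src_emitted, 100, tolerance = 0.2)
  expect_equal(queue_occupancy(stalled), 1)
  expect_gt(stalled$dropped, 0)
})

test_that("direct dispatch delivers the same payload sequence as queued", {
  run_mode <- function(strategy) {
    fl <- fleet("t")
    src <- freight(fl, "Src", builder = function() list())
    add_source(src, output_type = "x", body = local({
      i <- 0
      function(comp) {
        i <<- i + 1
        if (i <= 20) list(value = i, has_more = TRUE)
        else list(value = NULL, has_more = FALSE)
      }
    }))
    got <- numeric(0)
    snk <- freight(fl, "Snk", builder = function() list(), strategy = strategy)
    add_sink(snk, input_type = "x", body = function(comp, v, m)
      got <<- c(got, v))
    launch(fl)
    generate_data(src)
    run_until_idle(fl)
    got
  }
  expect_identical(run_mode("direct"), run_mode("queued"))
})

test_that("conservation: emitted = processed + queued + dropped at quiescence", {
  fl <- fleet("t")
  src <- freight(fl, "Src", builder = function() list())
  add_source(src, output_type = "x", body = function(comp)
    list(value = 1, has_more = FALSE))
  processed <- 0
  snk <- freight(fl, "Snk", builder = function() list(), queue_capacity = 16)
  add_sink(snk, input_type = "x", body = function(comp, v, m)
    processed <<- processed + 1)
  launch(fl)
  snk$processing_cost_ns <- 5e7      # 50 ms per message: backlog builds
  emitted <- 0
  for (i in 1:40) emitted <- emitted + generate_data(src)
  # quiesce without advancing past the backlog: freeze processing cost
  expect_equal(emitted, processed + length(snk$inbox) + snk$dropped)
  snk$processing_cost_ns <- 0
  run_until_idle(fl)
  expect_equal(emitted, processed + snk$dropped)
})

test_that("messages queued at invalidation survive for the restore", {
  fl <- fleet("t")
  src <- freight(fl, "Src", builder = function() list())
  add_source(src, output_type = "x", body = function(comp)
    list(value = 1, has_more = FALSE))
  n <- 0
  snk <- freight(fl, "Snk", builder = function() list())
  add_sink(snk, input_type = "x", body = function(comp, v, m) n <<- n + 1)
  launch(fl)
  snk$processing_cost_ns <- 1e12
  for (i in 1:5) generate_data(src)
  cascade_invalidate(fl, "Snk", "local_failure")
  expect_equal(length(snk$inbox), 5)   # retained: no experimental data wasted
  snk$processing_cost_ns <- 0
  restore_segment(fl, "Snk")
  run_until_idle(fl)
  expect_equal(n, 5)
})
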