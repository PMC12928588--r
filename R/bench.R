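# Framework-overhead benchmark: a six-stage fleet (rate-limited request
# source, timestamper, tunable test operator, second timestamper, time
# difference calculator, text writer) plus the no-intercept regression that
# turns paired timings into an overhead estimate.

#' Calibrated CPU-bound test operator
#'
#' A pure, deterministic floating-point multiply-add load: difficulty `d`
#' performs `d * iters_per_difficulty` operations, so compute time grows
#' linearly (and strictly) with difficulty, and the same difficulty always
#' yields the same arithmetic result. `calibrate_test_operator()` measures
#' the machine once and sizes `iters_per_difficulty` so difficulty 1 lands
#' near `target_ms`.
#'
#' @param iters_per_difficulty multiply-add operations per difficulty unit.
#' @param target_ms desired compute time at difficulty 1 (milliseconds).
#' @return a `test_operator`: call it as `op$run(difficulty)`.
#' @export
make_test_operator <- function(iters_per_difficulty) {
  chunk <- seq_len(1000) * 1e-6
  run <- function(difficulty) {
    stopifnot(difficulty >= 1)
    reps <- ceiling(difficulty * iters_per_difficulty / 1000)
    acc <- 0
    for (r in seq_len(reps)) acc <- acc + sum(chunk * 1.000001 + 1e-9)
    acc
  }
  structure(list(run = run, iters_per_difficulty = iters_per_difficulty),
            class = "test_operator")
}

#' @rdname make_test_operator
#' @export
calibrate_test_operator <- function(target_ms = 2) {
  probe <- make_test_operator(1e5)
  probe$run(1)   # warmup
  t0 <- monotonic_ns()
  probe$run(1)
  per_1e5_ms <- (monotonic_ns() - t0) / 1e6
  ipd <- max(1000, round(1e5 * target_ms / per_1e5_ms))
  make_test_operator(ipd)
}

#' Reference timings of the test operator
#'
#' Direct invocation outside any fleet; per difficulty, `warmup` runs are
#' discarded and `samples` runs are timed with the monotonic clock.
#'
#' @param operator a [make_test_operator()].
#' @param difficulties integer difficulty levels.
#' @param samples timed runs per difficulty (> 0).
#' @param warmup discarded runs per difficulty.
#' @return list with `timings` (`difficulty`, `sample`, `t_ns`) and
#'   `summary` (`difficulty`, `mean_ns`, `sd_ns`).
#' @export
run_reference <- function(operator, difficulties = 1:10, samples = 20,
                          warmup = 2) {
  stopifnot(inherits(operator, "test_operator"))
  if (samples <= 0) stop("samples must be positive", call. = FALSE)
  rows <- list()
  for (d in difficulties) {
    for (i in seq_len(warmup)) operator$run(d)
    for (i in seq_len(samples)) {
      t0 <- monotonic_ns()
      operator$run(d)
      rows[[length(rows) + 1L]] <- c(d, i, monotonic_ns() - t0)
    }
  }
  timings <- as.data.frame(do.call(rbind, rows))
  names(timings) <- c("difficulty", "sample", "t_ns")
  summary <- stats::aggregate(t_ns ~ difficulty, timings, function(v)
    c(mean = mean(v), sd = stats::sd(v)))
  summary <- data.frame(difficulty = summary$difficulty,
                        mean_ns = summary$t_ns[, "mean"],
                        sd_ns = summary$t_ns[, "sd"])
  list(timings = timings, summary = summary)
}

#' Assemble the benchmark fleet
#'
#' Six vessels in sequence: `RequestSource` emits difficulty requests at a
#' fixed rate; `PreStamper` stamps the monotonic clock; `TestOperator` runs
#' the load; `PostStamper` stamps again; `DiffCalc` computes the
#' difference; `RecordWriter` collects the records (and optionally appends
#' them to a CSV). The two timestampers are separate vessels so the measured
#' path crosses real framework dispatch.
#'
#' @param operator a [make_test_operator()].
#' @param rate_hz request rate (Hz).
#' @param csv_path optional CSV to append records to
#'   (`difficulty,sample,t_pre_ns,t_post_ns,delta_ns`).
#' @return the assembled, launched fleet.
#' @export
build_bench_fleet <- function(operator, rate_hz = 50, csv_path = NULL) {
  fl <- fleet("bench")
  src <- freight(fl, "RequestSource", builder = function() {
    e <- new.env(parent = emptyenv())
    e$difficulty <- 1L
    e$remaining <- 0L
    e
  }, source_rate = rate_hz)
  add_source(src, output_type = "bench_request", body = function(comp) {
    if (comp$remaining <= 0) return(list(value = NULL, has_more = FALSE))
    comp$remaining <- comp$remaining - 1L
    list(value = comp$difficulty, has_more = FALSE)
  })

  pre <- freight(fl, "PreStamper", builder = function() list())
  add_transformer(pre, input_type = "bench_request", output_type = "stamped",
                  body = function(comp, difficulty, meta)
                    list(difficulty = difficulty, t_pre = monotonic_ns()))

  opv <- freight(fl, "TestOperator", builder = function() operator)
  add_transformer(opv, input_type = "stamped", output_type = "computed",
                  body = function(op, req, meta) {
                    req$result <- op$run(req$difficulty)
                    req
                  })

  post <- freight(fl, "PostStamper", builder = function() list())
  add_transformer(post, input_type = "computed", output_type = "timed",
                  body = function(comp, req, meta) {
                    req$t_post <- monotonic_ns()
                    req
                  })

  diffc <- freight(fl, "DiffCalc", builder = function() list())
  add_transformer(diffc, input_type = "timed", output_type = "timing_record",
                  body = function(comp, req, meta) {
                    req$delta <- req$t_post - req$t_pre
                    req
                  })

  wr <- freight(fl, "RecordWriter", builder = function() {
    e <- new.env(parent = emptyenv())
    e$records <- list()
    e$csv_path <- csv_path
    if (!is.null(csv_path) && !file.exists(csv_path))
      writeLines("difficulty,sample,t_pre_ns,t_post_ns,delta_ns", csv_path)
    e
  })
  add_sink(wr, input_type = "timing_record", body = function(comp, rec, meta) {
    comp$records[[length(comp$records) + 1L]] <- rec
    if (!is.null(comp$csv_path))
      cat(sprintf("%d,%d,%.0f,%.0f,%.0f\n", rec$difficulty,
                  length(comp$records), rec$t_pre, rec$t_post, rec$delta),
          file = comp$csv_path, append = TRUE)
  })

  launch(fl)
  fl
}

#' Run the benchmark through the framework
#'
#' For each difficulty, `samples` requests are issued at `rate_hz` and timed
#' across the dispatch chain. Overload (the inbox of the operator vessel
#' accumulating because per-item compute time exceeds the request period) is
#' detected from the queue-occupancy trace and flagged, not raised.
#'
#' @param operator a [make_test_operator()].
#' @param difficulties difficulty levels to run.
#' @param rate_hz request rate (Hz).
#' @param samples requests per difficulty.
#' @param csv_path optional record CSV (see [build_bench_fleet()]).
#' @return list with `records` (`difficulty`, `t_pre_ns`, `t_post_ns`,
#'   `delta_ns`), `summary` (per-difficulty mean/sd and `overload` flag) and
#'   `occupancy` (per-difficulty occupancy traces of the operator vessel).
#' @export
run_framework <- function(operator, difficulties = 1:10, rate_hz = 50,
                          samples = 20, csv_path = NULL) {
  fl <- build_bench_fleet(operator, rate_hz = rate_hz, csv_path = csv_path)
  on.exit(shutdown(fl), add = TRUE)
  src <- fl$vessel("RequestSource")
  opv <- fl$vessel("TestOperator")
  wr <- fl$vessel("RecordWriter")
  period <- 1 / rate_hz
  sum_rows <- list()
  occ <- list()
  for (d in difficulties) {
    n_before <- length(wr$component$records)
    src$component$difficulty <- as.integer(d)
    src$component$remaining <- as.integer(samples)
    # sample the operator-vessel occupancy once per period during the window
    trace <- numeric(samples)
    for (i in seq_len(samples)) {
      fl$scheduler$schedule(fl$now() + i * period * 1e9,
                            local({ i0 <- i; function()
                              trace[i0] <<- opv$queue_occupancy() }))
    }
    run_for(fl, samples * period + period)
    run_until_idle(fl)
    occ[[as.character(d)]] <- trace
    recs <- wr$component$records
    recs <- if (length(recs) > n_before)
      recs[seq(n_before + 1L, length(recs))] else list()
    deltas <- vapply(recs, `[[`, numeric(1), "delta")
    sum_rows[[length(sum_rows) + 1L]] <- data.frame(
      difficulty = d, n = length(deltas), mean_ns = mean(deltas),
      sd_ns = stats::sd(deltas),
      overload = opv$dropped > 0 || max(trace) > 0.5 ||
        utils::tail(trace, 1) > trace[1] + 2 / opv$queue_capacity)
  }
  all_recs <- wr$component$records
  records <- data.frame(
    difficulty = vapply(all_recs, `[[`, numeric(1), "difficulty"),
    t_pre_ns = vapply(all_recs, `[[`, numeric(1), "t_pre"),
    t_post_ns = vapply(all_recs, `[[`, numeric(1), "t_post"),
    delta_ns = vapply(all_recs, `[[`, numeric(1), "delta"))
  list(records = records, summary = do.call(rbind, sum_rows),
       occupancy = occ)
}

#' No-intercept regression slope
#'
#' Closed-form least-squares slope of `y = a x` through the origin:
#' `a = sum(x*y) / sum(x^2)`.
#'
#' @param x,y numeric vectors of equal length.
#' @return the slope `a`.
#' @export
no_intercept_slope <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) > 0)
  sxx <- sum(x * x)
  if (sxx == 0) stop("degenerate fit: all reference times are zero",
                     call. = FALSE)
  sum(x * y) / sxx
}

#' Estimate the framework overhead
#'
#' Pairs every framework timing with the mean reference time of its
#' difficulty and fits `T_framework = a * T_ref` with no intercept; the
#' overhead fraction is `a - 1` (the extra time the framework adds relative
#' to the bare operation).
#'
#' @param framework a [run_framework()] result (or a data frame with
#'   `difficulty` and `delta_ns`).
#' @param reference a [run_reference()] result (or its `summary` data frame).
#' @return an `overhead_estimate`: `slope`, `overhead`, `per_difficulty`.
#' @export
estimate_overhead <- function(framework, reference) {
  fw <- if (is.data.frame(framework)) framework else framework$records
  ref <- if (is.data.frame(reference)) reference else reference$summary
  stopifnot(all(c("difficulty", "delta_ns") %in% names(fw)),
            all(c("difficulty", "mean_ns") %in% names(ref)))
  m <- match(fw$difficulty, ref$difficulty)
  if (anyNA(m))
    stop("framework run contains difficulties without reference timings",
         call. = FALSE)
  x <- ref$mean_ns[m]
  y <- fw$delta_ns
  a <- no_intercept_slope(x, y)
  per <- stats::aggregate(delta_ns ~ difficulty, fw, function(v)
    c(mean = mean(v), sd = stats::sd(v), n = length(v)))
  per <- data.frame(difficulty = per$difficulty,
                    fw_mean_ns = per$delta_ns[, "mean"],
                    fw_sd_ns = per$delta_ns[, "sd"],
                    n = per$delta_ns[, "n"])
  per$ref_mean_ns <- ref$mean_ns[match(per$difficulty, ref$difficulty)]
  structure(list(slope = a, overhead = a - 1, per_difficulty = per),
            class = "overhead_estimate")
}

#' @export
print.overhead_estimate <- function(x, ...) {
  cat(sprintf("Framework overhead estimate\n  slope (y = ax): %.4f\n  overhead: %.1f%%\n",
              x$slope, 100 * x$overhead))
  print(x$per_difficulty, row.names = FALSE)
  invisible(x)
}
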