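# Vessel state machine: construction, reload, invalidation, guarded calls.

test_that("freighting registers an offline, active vessel and validates the spec", {
  fl <- fleet("t")
  v <- freight(fl, "Cam", builder = function() list())
  expect_identical(v$state, "offline")
  expect_true(v$is_active)
  expect_null(v$component)
  expect_identical(v$queue_capacity, 64L)
  expect_identical(v$strategy, "queued")

  expect_error(freight(fl, "Cam", builder = function() list()),
               "already registered")
  expect_error(
    freight(fl, "Selfish", builder = function() list(),
            depends_on = list(v, v)),
    "duplicate")
  # a vessel naming itself as a dependency is impossible to express by
  # object (it does not exist yet); the name-based path must also refuse
  prov <- freight(fl, "Prov", builder = function() list())
  expect_error(
    Vessel <- fl$freight("Loop", function() list(),
                         depends_on = list(fl$vessel("Loop"))),
    "no vessel named")
  expect_error(freight(fl, "Tiny", builder = function() list(),
                       queue_capacity = 0), "queue_capacity")
})

test_that("reload builds, initializes, and recovers from component errors", {
  fl <- fleet("t")
  calls <- new.env(); calls$b <- 0; calls$i <- 0; calls$inv <- 0
  prov <- freight(fl, "Provider", builder = function() list(serial = "SN1"))
  cam <- freight(fl, "Camera", depends_on = list(prov),
    builder = function(p) {
      calls$b <- calls$b + 1
      stopifnot(identical(p$serial, "SN1"))  # dependency handle, in order
      e <- new.env(); e$running <- FALSE; e
    },
    initializer = function(p, comp) { calls$i <- calls$i + 1
                                      comp$running <- TRUE },
    invalidator = function(p, comp) { calls$inv <- calls$inv + 1
                                      comp$running <- FALSE })

  # dependency offline: precondition error, no state change, builder unrun
  rep <- reload(cam)
  expect_false(rep$ok)
  expect_match(rep$error$message, "not online")
  expect_identical(cam$state, "offline")
  expect_equal(calls$b, 0)

  expect_true(reload(prov)$ok)
  expect_true(reload(cam)$ok)
  expect_identical(cam$state, "online")
  expect_true(cam$component$running)
  expect_equal(c(calls$b, calls$i, calls$inv), c(1, 1, 0))

  # reload of an online vessel: teardown then rebuild, identity changes
  first <- cam$component
  expect_true(reload(cam)$ok)
  expect_equal(c(calls$b, calls$inv), c(2, 1))
  expect_false(identical(cam$component, first))
})

test_that("builder failure and empty build leave the vessel offline with one log record", {
  fl <- fleet("t")
  boom <- freight(fl, "Boom", builder = function() stop("no device"))
  rep <- reload(boom)
  expect_false(rep$ok)
  expect_identical(boom$state, "offline")
  logs <- log_records(fl, "error")
  expect_equal(sum(logs$origin == "Boom" & grepl("no device", logs$text)), 1)

  # a builder returning nothing (FirstOrDefault-style miss) must not go online
  ghost <- freight(fl, "Ghost", builder = function() NULL)
  expect_false(reload(ghost)$ok)
  expect_identical(ghost$state, "offline")
})

test_that("initializer failure tears down the partially built component", {
  fl <- fleet("t")
  calls <- new.env(); calls$inv <- 0
  v <- freight(fl, "Half", builder = function() list(x = 1),
               initializer = function(comp) stop("init boom"),
               invalidator = function(comp) calls$inv <- calls$inv + 1)
  expect_false(reload(v)$ok)
  expect_identical(v$state, "offline")
  expect_equal(calls$inv, 1)
  expect_null(v$component)
  expect_equal(v$n_built, v$n_invalidated)
})

test_that("invalidate is idempotent and survives a raising invalidator", {
  fl <- fleet("t")
  calls <- new.env(); calls$inv <- 0
  v <- freight(fl, "Cam", builder = function() new.env(),
               invalidator = function(comp) {
                 calls$inv <- calls$inv + 1
                 stop("stop failed")
               })
  reload(v)
  invalidate(v, "user")
  expect_identical(v$state, "offline")
  expect_identical(v$invalidation_cause, "user")
  expect_equal(calls$inv, 1)
  logs <- log_records(fl, "error")
  expect_true(any(grepl("stop failed", logs$text)))

  invalidate(v, "user")          # offline: no-op
  expect_equal(calls$inv, 1)
})

test_that("execute_call guards component access", {
  fl <- fleet("t")
  v <- freight(fl, "Cam", builder = function() list(val = 42))
  reload(v)
  res <- execute_call(v, function(comp) comp$val)
  expect_true(call_succeeded(res))
  expect_equal(call_value(res), 42)

  # raising action: error result AND the vessel goes offline
  res <- execute_call(v, function(comp) stop("hardware fault"))
  expect_false(call_succeeded(res))
  expect_identical(v$state, "offline")
  expect_identical(v$invalidation_cause, "local_failure")

  # offline vessel: "not available" error, action never invoked
  spy <- new.env(); spy$n <- 0
  res <- execute_call(v, function(comp) spy$n <- spy$n + 1)
  expect_false(call_succeeded(res))
  expect_match(res$error$message, "not available")
  expect_equal(spy$n, 0)
  expect_identical(v$state, "offline")
})

test_that("activity toggling gates data flow without touching vessel state", {
  fl <- fleet("t")
  src <- freight(fl, "Src", builder = function() new.env())
  snk <- freight(fl, "Snk", builder = function() new.env())
  add_source(src, output_type = "x", body = function(comp)
    list(value = 1, has_more = FALSE))
  got <- 0
  add_sink(snk, input_type = "x", body = function(comp, v, m) got <<- got + 1)
  launch(fl)

  set_active(snk, FALSE)
  generate_data(src)
  run_until_idle(fl)
  expect_equal(got, 0)
  expect_identical(snk$state, "online")     # the two flags are independent

  set_active(snk, TRUE)
  generate_data(src)
  run_until_idle(fl)
  expect_equal(got, 1)

  # inactive source: polling and manual generation emit nothing
  set_active(src, FALSE)
  expect_equal(generate_data(src), 0L)
})

test_that("lifecycle counts stay conserved under random fail/restore scripts", {
  set.seed(42)
  for (rep in 1:5) {
    rf <- make_ref_fleet()
    fl <- rf$fleet
    launch(fl)
    nms <- fl$vessel_names()
    for (step in 1:20) {
      nm <- sample(nms, 1)
      op <- sample(c("kill", "restore", "reload", "call"), 1)
      expect_no_error(switch(op,
        kill = cascade_invalidate(fl, nm, "local_failure"),
        restore = {
          v <- fl$vessel(nm)
          deps_ok <- all(vapply(v$dependencies(),
                                function(d) d$is_online(), logical(1)))
          if (deps_ok) restore_segment(fl, nm)
        },
        reload = {
          v <- fl$vessel(nm)
          deps_ok <- all(vapply(v$dependencies(),
                                function(d) d$is_online(), logical(1)))
          if (deps_ok) reload(v)
        },
        call = execute_call(fl$vessel(nm), function(comp) comp$tag)))
      # quiescent-point conservation for every vessel
      for (vn in nms) {
        v <- fl$vessel(vn)
        expect_equal(v$n_built, v$n_invalidated + as.integer(v$is_online()),
                     info = sprintf("vessel %s after %s(%s)", vn, op, nm))
      }
      # order safety: nobody online above an offline dependency
      for (vn in nms) {
        v <- fl$vessel(vn)
        if (v$is_online())
          expect_true(all(vapply(v$dependencies(),
                                 function(d) d$is_online(), logical(1))))
      }
    }
    shutdown(fl)
    for (vn in nms)
      expect_equal(fl$vessel(vn)$n_built, fl$vessel(vn)$n_invalidated)
  }
})
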