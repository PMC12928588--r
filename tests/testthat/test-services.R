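# Services pool, settings, logger, metadata collection, command registry.

test_that("services are lazily constructed singletons with persistent state", {
  fl <- fleet("t")
  built <- 0
  ctor <- function() {
    built <<- built + 1
    e <- new.env(); e$count <- 0; e
  }
  a <- get_service(fl, "counter", ctor)
  b <- get_service(fl, "counter", ctor)
  expect_identical(a, b)
  expect_equal(built, 1)

  # state persists across callers (two vessels sharing one counter)
  with_service(fl, "counter", function(s) s$count <- s$count + 1)
  with_service(fl, "counter", function(s) s$count <- s$count + 1)
  expect_equal(a$count, 2)

  # scheduler-interleaved first requests still construct exactly once
  fl2 <- fleet("t2")
  built2 <- 0
  for (i in 1:100) {
    fl2$scheduler$schedule(0, function()
      get_service(fl2, "shared", function() {
        built2 <<- built2 + 1
        new.env()
      }))
  }
  run_until_idle(fl2)
  expect_equal(built2, 1)
})

test_that("a failing constructor caches nothing; the next attempt retries", {
  fl <- fleet("t")
  attempts <- 0
  flaky <- function() {
    attempts <<- attempts + 1
    if (attempts == 1) stop("transient init failure")
    list(ok = TRUE)
  }
  expect_error(get_service(fl, "flaky", flaky), "transient")
  inst <- get_service(fl, "flaky", flaky)
  expect_true(inst$ok)
  expect_equal(attempts, 2)
  expect_identical(get_service(fl, "flaky"), inst)
})

test_that("service access is serialized: a non-reentrant probe sees no interleaving", {
  fl <- fleet("t")
  probe_ctor <- function() {
    e <- new.env(); e$active <- 0; e$violations <- 0; e
  }
  enter <- function(s) {
    if (s$active > 0) s$violations <- s$violations + 1
    s$active <- s$active + 1
    s$active <- s$active - 1
  }
  for (i in 1:50) with_service(fl, "probe", enter, probe_ctor)
  expect_equal(get_service(fl, "probe")$violations, 0)
  # re-entrant acquisition from inside a critical section is refused
  expect_error(
    with_service(fl, "probe", function(s)
      with_service(fl, "probe", identity)),
    "busy")
})

test_that("settings lookups resolve nested paths and miss gracefully", {
  xml <- tempfile(fileext = ".xml")
  writeLines(c("<SARDINE>",
               '  <CameraSettings CameraSN="SN_Test"/>',
               '  <Application>',
               '    <Loader BorderBrush="DarkRed"/>',
               "  </Application>",
               "</SARDINE>"), xml)
  doc <- read_settings(xml)
  expect_identical(fetch_setting(doc, "CameraSettings", "CameraSN"),
                   "SN_Test")
  expect_identical(fetch_setting(doc, c("Application", "Loader"),
                                 "BorderBrush"), "DarkRed")
  expect_null(fetch_setting(doc, "NoSuchNode", "X"))
  expect_null(fetch_setting(doc, "CameraSettings", "NoSuchAttr"))

  # missing file: empty document, all lookups absent
  expect_null(read_settings(tempfile()))
  expect_null(fetch_setting(NULL, "CameraSettings", "CameraSN"))

  # malformed XML errors at load time
  bad <- tempfile(fileext = ".xml")
  writeLines("<SARDINE><open>", bad)
  expect_error(read_settings(bad))

  # a fleet resolves its UserDataPath from the settings root
  xml2 <- tempfile(fileext = ".xml")
  writeLines(sprintf('<SARDINE UserDataPath="%s" Name="Demo"/>',
                     tempdir()), xml2)
  fl <- fleet("t", settings_path = xml2)
  expect_identical(fl$user_data_path, tempdir())
  expect_identical(fetch_setting(fl, character(0), "Name"), "Demo")
})

test_that("the logger orders its eight levels and records state changes", {
  expect_length(LOG_LEVELS, 8)
  fl <- fleet("t")
  v <- freight(fl, "Cam", builder = function() list())
  reload(v)
  invalidate(v, "user")
  logs <- log_records(fl)
  transitions <- logs[grepl("^state:", logs$text) & logs$origin == "Cam", ]
  # offline->loading, loading->online, online->offline: one record each
  expect_equal(nrow(transitions), 3)

  fleet_log(fl, "Cam", "custom message", "notice")
  expect_true(any(log_records(fl, "notice")$text == "custom message"))
  expect_error(fleet_log(fl, "Cam", "bad", "loud"))

  # failure path: exactly one error-or-higher record naming the vessel
  boom <- freight(fl, "Boom", builder = function() stop("dead device"))
  reload(boom)
  errs <- log_records(fl, "error")
  expect_equal(sum(errs$origin == "Boom"), 1)
})

test_that("stdout from component code is captured when requested", {
  fl <- fleet("t")
  chatty <- freight(fl, "Chatty", capture_logs = TRUE,
                    builder = function() {
                      cat("device firmware 1.2\n")
                      list()
                    })
  reload(chatty)
  expect_true(any(log_records(fl)$origin == "Chatty" &
                  grepl("firmware", log_records(fl)$text)))

  quiet <- freight(fl, "Quiet", capture_logs = FALSE,
                   builder = function() {
                     cat("should go to the console, not the log\n")
                     list()
                   })
  out <- utils::capture.output(reload(quiet))
  expect_false(any(grepl("console", log_records(fl)$text)))
  expect_true(any(grepl("console", out)))
})

test_that("log files get one tab-separated line per record", {
  path <- tempfile("log_", fileext = ".log")
  fl <- fleet("t", log_path = path)
  fleet_log(fl, "x", "hello", "info")
  fl$logger$flush()
  lines <- readLines(path)
  expect_true(any(grepl("\tINFO\tx\thello$", lines)))
})

test_that("metadata collection snapshots online vessels and flags the rest", {
  fl <- fleet("t")
  cam <- freight(fl, "ImagingCamera", builder = function() {
    e <- new.env(); e$FrameRate <- 100; e$SerialNumber <- "SN1"; e
  })
  down <- freight(fl, "Down", builder = function() list())
  reload(cam)

  rep <- collect_metadata(fl, list(
    ImagingCamera = c("FrameRate", "NoSuchParam"),
    Down = "Whatever"))
  expect_equal(rep$vessels$ImagingCamera$parameters$FrameRate, 100)
  expect_true(is.na(rep$vessels$ImagingCamera$parameters$NoSuchParam))
  expect_false(rep$vessels$Down$available)

  # snapshots do not track later component changes
  cam$component$FrameRate <- 250
  expect_equal(rep$vessels$ImagingCamera$parameters$FrameRate, 100)

  # empty spec: empty report with a timestamp
  empty <- collect_metadata(fl, list())
  expect_length(empty$vessels, 0)
  expect_s3_class(empty$timestamp, "POSIXct")

  f <- tempfile()
  write_metadata_report(rep, f)
  txt <- readLines(f)
  expect_true(any(grepl("FrameRate = 100", txt)))
  expect_true(any(grepl("Down: unavailable", txt)))
})

test_that("text commands route through the guarded-call machinery", {
  fl <- fleet("t")
  cam <- freight(fl, "Cam", builder = function() {
    e <- new.env(); e$running <- FALSE; e
  })
  reload(cam)
  register_command(fl, cam, "camera.start",
                   function(comp) { comp$running <- TRUE; "started" })
  register_command(fl, cam, "camera.fail", function(comp) stop("jammed"))
  expect_error(register_command(fl, cam, "camera.start", identity),
               "already registered")

  res <- invoke_command(fl, "camera.start")
  expect_true(call_succeeded(res))
  expect_identical(call_value(res), "started")
  expect_true(cam$component$running)

  expect_false(call_succeeded(invoke_command(fl, "no.such.command")))

  res <- invoke_command(fl, "camera.fail")
  expect_false(call_succeeded(res))
  expect_identical(cam$state, "offline")   # failure invalidates the owner
})
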