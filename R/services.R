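# Support services: logging, XML settings, metadata collection.

#' Ordered log levels
#'
#' The logger distinguishes eight levels of importance, totally ordered from
#' `trace` (lowest) to `fatal` (highest). Vessel state changes are logged
#' automatically: transitions to offline caused by failures produce exactly
#' one record at `error` or above naming the vessel.
#'
#' @export
LOG_LEVELS <- c("trace", "debug", "info", "notice",
                "warning", "error", "critical", "fatal")

Logger <- R6::R6Class("Logger",
  public = list(
    path = NULL,
    initialize = function(path = NULL) {
      self$path <- path
      private$rows <- list()
      if (!is.null(path)) {
        dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
        private$con <- file(path, open = "a")
      }
    },
    log = function(origin, text, level = "info", wall = Sys.time()) {
      level <- match.arg(level, LOG_LEVELS)
      rec <- list(timestamp = wall, level = level, origin = origin,
                  text = text)
      private$rows[[length(private$rows) + 1L]] <- rec
      if (!is.null(private$con)) {
        writeLines(paste(format(wall, "%Y-%m-%dT%H:%M:%OS6"),
                         toupper(level), origin, text, sep = "\t"),
                   private$con)
      }
      invisible(NULL)
    },
    records = function(min_level = "trace") {
      lv <- match(min_level, LOG_LEVELS)
      rows <- Filter(function(r) match(r$level, LOG_LEVELS) >= lv,
                     private$rows)
      if (length(rows) == 0)
        return(data.frame(timestamp = as.POSIXct(character(0)),
                          level = character(0), origin = character(0),
                          text = character(0)))
      data.frame(
        timestamp = do.call(c, lapply(rows, `[[`, "timestamp")),
        level = vapply(rows, `[[`, "", "level"),
        origin = vapply(rows, `[[`, "", "origin"),
        text = vapply(rows, `[[`, "", "text"),
        stringsAsFactors = FALSE)
    },
    flush = function() {
      if (!is.null(private$con)) flush(private$con)
      invisible(NULL)
    }
  ),
  private = list(
    rows = NULL, con = NULL,
    finalize = function() {
      if (!is.null(private$con)) try(close(private$con), silent = TRUE)
    }
  )
)

#' Fleet log access
#'
#' `fleet_log()` appends a custom record; `log_records()` returns all records
#' at or above a level as a data frame (`timestamp`, `level`, `origin`,
#' `text`). When a log file path was given at fleet creation, each record is
#' also written as one tab-separated line.
#'
#' @param fleet a [fleet()].
#' @param origin vessel/service name the record is attributed to.
#' @param text message text.
#' @param level one of [LOG_LEVELS].
#' @param min_level lowest level to include.
#' @export
fleet_log <- function(fleet, origin, text, level = "info") {
  fleet$log(origin, text, level)
}

#' @rdname fleet_log
#' @export
log_records <- function(fleet, min_level = "trace") {
  fleet$logger$records(min_level)
}

## -- settings ------------------------------------------------------------

#' Read an XML settings document
#'
#' Settings live in a small XML dialect: nested elements name a path, values
#' are attributes, e.g. `<SARDINE><CameraSettings CameraSN="SN_Test"/></SARDINE>`.
#' A path written `Application -> Loader -> BorderBrush` addresses the
#' `BorderBrush` attribute of the `Loader` element nested in `Application`.
#' A missing file yields an empty document on which every lookup returns
#' `NULL`; unknown settings are preserved and fetchable. The document is
#' read-only after load.
#'
#' @param path file path.
#' @return a settings document (or `NULL` for the empty document).
#' @export
read_settings <- function(path) {
  if (!file.exists(path)) return(NULL)
  doc <- xml2::read_xml(path)   # malformed XML errors with file position
  structure(list(doc = doc, path = path), class = "fleet_settings")
}

#' Fetch one setting
#'
#' @param settings a document from [read_settings()], a [fleet()] (its loaded
#'   settings are used), or `NULL`.
#' @param path character vector of nested element names below the root: the
#'   first element names a child of the root, and so on. `character(0)`
#'   addresses an attribute of the root element itself.
#' @param name attribute name holding the value.
#' @return the attribute value as a string, or `NULL` if any step is absent.
#'   Never raises on missing keys.
#' @examples
#' f <- tempfile(fileext = ".xml")
#' writeLines('<SARDINE><CameraSettings CameraSN="SN_Test"/></SARDINE>', f)
#' fetch_setting(read_settings(f), "CameraSettings", "CameraSN")
#' @export
fetch_setting <- function(settings, path, name) {
  if (inherits(settings, "Fleet")) settings <- settings$settings
  if (is.null(settings)) return(NULL)
  node <- settings$doc
  for (p in path) {
    kids <- xml2::xml_children(node)
    hit <- which(xml2::xml_name(kids) == p)
    if (length(hit) == 0) return(NULL)
    node <- kids[[hit[1]]]
  }
  v <- xml2::xml_attr(node, name)
  if (is.na(v)) NULL else v
}

## -- metadata collection -------------------------------------------------

#' Collect a metadata report from vessels
#'
#' Snapshots the requested readable parameters of each named vessel's
#' component (list, environment or R6 components are indexed with `[[`).
#' Offline vessels are reported as unavailable; unknown parameters are
#' recorded as missing, never fatal. Values are copies: later component
#' changes do not mutate the report.
#'
#' @param fleet a [fleet()].
#' @param spec named list: vessel name -> character vector of parameter
#'   names.
#' @return a `fleet_metadata_report`: named list of per-vessel snapshots plus
#'   an emission timestamp.
#' @export
collect_metadata <- function(fleet, spec) {
  out <- list()
  for (nm in names(spec)) {
    v <- fleet$vessel(nm)
    if (!v$is_online()) {
      out[[nm]] <- list(available = FALSE, parameters = list())
      next
    }
    params <- list()
    for (p in spec[[nm]]) {
      res <- v$execute_call(function(comp) {
        val <- tryCatch(comp[[p]], error = function(e) NULL)
        if (is.null(val)) NA else val
      })
      params[[p]] <- if (call_succeeded(res)) call_value(res) else NA
    }
    out[[nm]] <- list(available = TRUE, parameters = params)
  }
  structure(list(vessels = out, timestamp = Sys.time()),
            class = "fleet_metadata_report")
}

#' Write a metadata report as human-readable text
#'
#' @param report a report from [collect_metadata()].
#' @param path output file.
#' @export
write_metadata_report <- function(report, path) {
  stopifnot(inherits(report, "fleet_metadata_report"))
  lines <- c(sprintf("# metadata snapshot %s",
                     format(report$timestamp, "%Y-%m-%dT%H:%M:%S")))
  for (nm in names(report$vessels)) {
    entry <- report$vessels[[nm]]
    if (!entry$available) {
      lines <- c(lines, sprintf("%s: unavailable", nm))
      next
    }
    lines <- c(lines, sprintf("%s:", nm))
    for (p in names(entry$parameters)) {
      lines <- c(lines, sprintf("  %s = %s", p,
                                paste(format(entry$parameters[[p]]),
                                      collapse = ", ")))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' @export
print.fleet_metadata_report <- function(x, ...) {
  cat(sprintf("<metadata report, %d vessels, %s>\n", length(x$vessels),
              format(x$timestamp, "%H:%M:%S")))
  invisible(x)
}
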