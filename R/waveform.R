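# Waveform synthesis, pattern blocks, sequencing, and virtual channels.
#
# Hardware-control outputs are built bottom-up: per-channel waveform
# synthesizers produce aligned sample tracks, tracks plus software
# instructions form pattern blocks, and a sequencer concatenates scheduled
# blocks into the full device arrays with an absolute-time instruction
# timeline. Sample indices are 0-based; block event ranges are half-open
# [0, length). Digital tracks are stored as 0/1 samples for uniformity.

#' Waveform specifications
#'
#' Constructors for the supported shapes. `wf_constant(value)` holds a level;
#' `wf_sine` synthesizes `offset + amplitude * sin(2*pi*frequency*i/rate +
#' phase)` at sample `i`; `wf_square` is high (`offset + amplitude`) for the
#' first `duty` fraction of each period and low (`offset`) for the rest;
#' `wf_ramp` sweeps linearly from `from` towards `to` across the duration
#' (endpoint excluded, so repeated blocks chain seamlessly); `wf_samples`
#' plays back an explicit sample vector.
#'
#' @param value constant level (volts, or 0/1 for digital).
#' @param amplitude,offset,frequency,phase,duty usual oscillator parameters;
#'   `frequency` in Hz, `phase` in radians, `duty` in (0, 1].
#' @param from,to ramp endpoints.
#' @param samples numeric vector of explicit samples.
#' @return a `waveform_spec`.
#' @export
wf_constant <- function(value) new_wf("constant", value = value)

#' @rdname wf_constant
#' @export
wf_sine <- function(amplitude, frequency, offset = 0, phase = 0) {
  new_wf("sine", amplitude = amplitude, frequency = frequency,
         offset = offset, phase = phase)
}

#' @rdname wf_constant
#' @export
wf_square <- function(amplitude, frequency, duty = 0.5, offset = 0,
                      phase = 0) {
  stopifnot(duty > 0, duty <= 1)
  new_wf("square", amplitude = amplitude, frequency = frequency, duty = duty,
         offset = offset, phase = phase)
}

#' @rdname wf_constant
#' @export
wf_ramp <- function(from, to) new_wf("ramp", from = from, to = to)

#' @rdname wf_constant
#' @export
wf_samples <- function(samples) new_wf("samples", samples = samples)

new_wf <- function(shape, ...) {
  structure(c(list(shape = shape), list(...)), class = "waveform_spec")
}

#' @export
print.waveform_spec <- function(x, ...) {
  cat(sprintf("<waveform %s>\n", x$shape))
  invisible(x)
}

#' Synthesize a waveform to samples
#'
#' Deterministically renders `round(sample_rate * duration)` samples (at
#' least 1) of a [wf_constant()]-family specification.
#'
#' @param spec a `waveform_spec`.
#' @param sample_rate sampling rate in Hz (> 0).
#' @param duration duration in seconds (> 0).
#' @return numeric vector of samples.
#' @examples
#' synthesize(wf_sine(1, 100), sample_rate = 1000, duration = 0.01)
#' @export
synthesize <- function(spec, sample_rate, duration) {
  stopifnot(inherits(spec, "waveform_spec"))
  if (!is.numeric(sample_rate) || sample_rate <= 0)
    stop("sample_rate must be positive", call. = FALSE)
  if (!is.numeric(duration) || duration <= 0)
    stop("duration must be positive", call. = FALSE)
  n <- round(sample_rate * duration)
  if (n < 1) stop("duration too short: zero samples", call. = FALSE)
  i <- seq_len(n) - 1
  switch(spec$shape,
    constant = rep(spec$value, n),
    sine = spec$offset +
      spec$amplitude * sin(2 * pi * spec$frequency * i / sample_rate +
                           spec$phase),
    square = {
      pos <- (spec$frequency * i / sample_rate +
              spec$phase / (2 * pi)) %% 1
      spec$offset + spec$amplitude * as.numeric(pos < spec$duty)
    },
    ramp = spec$from + (spec$to - spec$from) * i / n,
    samples = {
      if (length(spec$samples) != n)
        stop(sprintf("explicit samples length %d != %d required",
                     length(spec$samples), n), call. = FALSE)
      as.numeric(spec$samples)
    },
    stop("unknown waveform shape '", spec$shape, "'", call. = FALSE)
  )
}

#' Build a pattern block
#'
#' Aligns one synthesized track per physical channel with a list of virtual
#' events (software instructions scheduled at sample positions within the
#' block). All tracks must share one length; event indices are 0-based and
#' must lie in `[0, length)`.
#'
#' @param sample_rate sampling rate in Hz shared by all tracks.
#' @param tracks named list: channel name -> `waveform_spec` or numeric
#'   sample vector.
#' @param duration seconds; required when any track is a spec.
#' @param virtual_events optional data frame with columns `index` (0-based
#'   sample position) and `instruction` (identifier).
#' @return a `pattern_block` with fields `sample_rate`, `length`, `tracks`,
#'   `virtual_events`.
#' @export
pattern_block <- function(sample_rate, tracks, duration = NULL,
                          virtual_events = NULL) {
  stopifnot(is.list(tracks), length(tracks) > 0, !is.null(names(tracks)))
  arrs <- lapply(tracks, function(tr) {
    if (inherits(tr, "waveform_spec")) {
      if (is.null(duration))
        stop("duration is required to synthesize waveform tracks",
             call. = FALSE)
      synthesize(tr, sample_rate, duration)
    } else {
      as.numeric(tr)
    }
  })
  lens <- vapply(arrs, length, integer(1))
  if (length(unique(lens)) != 1)
    stop("track lengths differ: ",
         paste(sprintf("%s=%d", names(lens), lens), collapse = ", "),
         call. = FALSE)
  len <- lens[[1]]
  if (is.null(virtual_events))
    virtual_events <- data.frame(index = integer(0),
                                 instruction = character(0))
  stopifnot(all(c("index", "instruction") %in% names(virtual_events)))
  if (nrow(virtual_events) > 0 &&
      (any(virtual_events$index < 0) || any(virtual_events$index >= len)))
    stop("virtual event index out of range [0, ", len, ")", call. = FALSE)
  structure(list(sample_rate = sample_rate, length = len, tracks = arrs,
                 virtual_events = virtual_events),
            class = "pattern_block")
}

#' @export
print.pattern_block <- function(x, ...) {
  cat(sprintf("<pattern block: %d samples @ %g Hz, channels [%s], %d events>\n",
              x$length, x$sample_rate, paste(names(x$tracks), collapse = ", "),
              nrow(x$virtual_events)))
  invisible(x)
}

#' Sequence pattern blocks into full device output
#'
#' Concatenates scheduled blocks (each repeated `repeats` times) into one
#' array per channel, offsetting every virtual event by its cumulative sample
#' position per repetition. All blocks must share the sample rate and channel
#' set.
#'
#' @param schedule list of `list(block =, repeats =)` entries (a bare
#'   `pattern_block` means one repeat).
#' @return a `sequenced_output`: per-channel arrays, `total_length`,
#'   `sample_rate` and the absolute-index `virtual_timeline`.
#' @export
sequence_blocks <- function(schedule) {
  schedule <- lapply(schedule, function(s) {
    if (inherits(s, "pattern_block")) list(block = s, repeats = 1L) else s
  })
  if (length(schedule) == 0) {
    return(structure(list(channels = list(), total_length = 0L,
                          sample_rate = NA_real_,
                          virtual_timeline = data.frame(
                            index = numeric(0), instruction = character(0))),
                     class = "sequenced_output"))
  }
  blocks <- lapply(schedule, `[[`, "block")
  reps <- vapply(schedule, function(s) as.integer(s$repeats), integer(1))
  stopifnot(all(vapply(blocks, inherits, logical(1), "pattern_block")),
            all(reps >= 0))
  rates <- unique(vapply(blocks, `[[`, numeric(1), "sample_rate"))
  if (length(rates) != 1)
    stop("blocks have heterogeneous sample rates: ",
         paste(rates, collapse = ", "), call. = FALSE)
  ch_sets <- lapply(blocks, function(b) sort(names(b$tracks)))
  if (length(unique(vapply(ch_sets, paste, "", collapse = ","))) != 1)
    stop("blocks have heterogeneous channel sets", call. = FALSE)
  channels <- names(blocks[[1]]$tracks)
  arrays <- stats::setNames(vector("list", length(channels)), channels)
  for (ch in channels) {
    parts <- mapply(function(b, r) rep(b$tracks[[ch]], times = r),
                    blocks, reps, SIMPLIFY = FALSE)
    arrays[[ch]] <- unlist(parts, use.names = FALSE)
    if (is.null(arrays[[ch]])) arrays[[ch]] <- numeric(0)
  }
  timeline <- list()
  offset <- 0
  for (k in seq_along(blocks)) {
    b <- blocks[[k]]
    for (r in seq_len(reps[k])) {
      if (nrow(b$virtual_events) > 0) {
        timeline[[length(timeline) + 1L]] <- data.frame(
          index = b$virtual_events$index + offset,
          instruction = b$virtual_events$instruction,
          stringsAsFactors = FALSE)
      }
      offset <- offset + b$length
    }
  }
  timeline <- if (length(timeline) > 0) do.call(rbind, timeline) else
    data.frame(index = numeric(0), instruction = character(0))
  timeline <- timeline[order(timeline$index), , drop = FALSE]
  rownames(timeline) <- NULL
  structure(list(channels = arrays, total_length = offset,
                 sample_rate = rates, virtual_timeline = timeline),
            class = "sequenced_output")
}

#' @export
print.sequenced_output <- function(x, ...) {
  cat(sprintf("<sequenced output: %d samples @ %g Hz, channels [%s], %d virtual events>\n",
              x$total_length, x$sample_rate,
              paste(names(x$channels), collapse = ", "),
              nrow(x$virtual_timeline)))
  invisible(x)
}

#' Fire the virtual-channel timeline on a simulated sample clock
#'
#' Walks the sequenced output's virtual timeline in absolute-index order and
#' invokes the handler registered for each instruction exactly once. All
#' instructions must have handlers before the run starts. A handler error is
#' caught and recorded; remaining events still fire.
#'
#' @param sequenced a [sequence_blocks()] result.
#' @param handlers named list: instruction identifier -> `function(index)`.
#' @return data frame `index`, `instruction`, `fired_order`, `error`.
#' @export
run_virtual <- function(sequenced, handlers) {
  stopifnot(inherits(sequenced, "sequenced_output"))
  tl <- sequenced$virtual_timeline
  missing <- setdiff(unique(tl$instruction), names(handlers))
  if (length(missing) > 0)
    stop("no handler for instruction(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  n <- nrow(tl)
  errs <- character(n)
  for (k in seq_len(n)) {
    errs[k] <- tryCatch({
      handlers[[tl$instruction[k]]](tl$index[k])
      NA_character_
    }, error = function(e) conditionMessage(e))
  }
  data.frame(index = tl$index, instruction = tl$instruction,
             fired_order = seq_len(n), error = errs,
             stringsAsFactors = FALSE)
}

#' Export sequenced output as CSV
#'
#' One column per channel, one row per sample, for external inspection.
#'
#' @param sequenced a [sequence_blocks()] result.
#' @param path output file.
#' @export
write_sequenced_csv <- function(sequenced, path) {
  stopifnot(inherits(sequenced, "sequenced_output"))
  df <- as.data.frame(sequenced$channels)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
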