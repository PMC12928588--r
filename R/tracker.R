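# Synthetic larva movie rendering and online tail tracking.
#
# The demonstration fleet tracks the tail of a head-fixed larva in a
# synthetic grayscale movie with known ground truth. Tail segment k
# (0-based) at frame t points at
#   theta_k(t) = base_angle + A * sin(2*pi*f*t/frame_rate + k*phase_lag),
# so every segment oscillates with amplitude A and a travelling phase along
# the tail. The tracker never sees the ground truth; it estimates the
# segment angles from pixels by sequential arc search, the classical scheme
# for larval zebrafish posture tracking.

#' Describe a synthetic larva scene
#'
#' Bundles geometry, oscillation, noise and reproducibility parameters for
#' [render_frame()]. Pixels are 8-bit grayscale, row-major, origin top-left;
#' x grows rightwards, y downwards; angles are measured in radians from the
#' +x axis towards +y.
#'
#' @param width,height frame size in pixels.
#' @param head head position `c(x, y)` in pixels (the tail grows from here).
#' @param n_segments number of tail segments.
#' @param segment_length segment length in pixels.
#' @param base_angle resting tail orientation (radians).
#' @param amplitude oscillation amplitude A (radians).
#' @param frequency tail-beat frequency in Hz.
#' @param frame_rate movie frame rate in Hz.
#' @param phase_lag phase advance per segment (radians); gives the travelling
#'   wave along the tail.
#' @param noise_sd per-pixel Gaussian noise (8-bit counts).
#' @param intensity peak body brightness (8-bit counts).
#' @param body_sigma Gaussian cross-section of the body (pixels).
#' @param seed base seed; frame `t` uses `seed + t`, so any frame renders
#'   identically in isolation.
#' @return a `larva_scene` parameter list.
#' @export
larva_scene <- function(width = 120, height = 120, head = c(30, 60),
                        n_segments = 7, segment_length = 10,
                        base_angle = 0, amplitude = 0.35, frequency = 2,
                        frame_rate = 100, phase_lag = 0.4, noise_sd = 4,
                        intensity = 200, body_sigma = 1.5, seed = 1) {
  structure(as.list(environment()), class = "larva_scene")
}

#' Ground-truth segment angles
#'
#' Closed-form tail segment angles of a [larva_scene()] at frame `t`.
#'
#' @param scene a [larva_scene()].
#' @param t 0-based frame index.
#' @return numeric vector of `n_segments` angles (radians).
#' @export
truth_angles <- function(scene, t) {
  k <- seq_len(scene$n_segments) - 1
  scene$base_angle + scene$amplitude *
    sin(2 * pi * scene$frequency * t / scene$frame_rate + k * scene$phase_lag)
}

# Tail polyline: (n_segments + 1) x 2 matrix of points, head first.
tail_points <- function(scene, angles) {
  pts <- matrix(0, nrow = scene$n_segments + 1, ncol = 2)
  pts[1, ] <- scene$head
  for (k in seq_len(scene$n_segments)) {
    pts[k + 1, ] <- pts[k, ] + scene$segment_length *
      c(cos(angles[k]), sin(angles[k]))
  }
  pts
}

#' Render one synthetic movie frame
#'
#' Deterministic given the scene and frame index: a static textured
#' background, a bright larva (head blob plus tail drawn as connected
#' segments following the closed-form angles), and per-frame sensor noise.
#' The true angles and the body mask are recorded on the frame for
#' ground-truth evaluation; the tracking pipeline does not use them.
#'
#' @param scene a [larva_scene()].
#' @param t 0-based frame index.
#' @return a `synthetic_frame`: `width`, `height`, `pixels` (numeric matrix
#'   `height x width`, 0-255), `frame_index`, `truth_angles`, `mask`.
#' @export
render_frame <- function(scene, t) {
  stopifnot(inherits(scene, "larva_scene"), t >= 0)
  ang <- truth_angles(scene, t)
  pts <- tail_points(scene, ang)
  pad <- 3 * scene$body_sigma
  if (any(pts[, 1] < 1 + pad) || any(pts[, 1] > scene$width - pad) ||
      any(pts[, 2] < 1 + pad) || any(pts[, 2] > scene$height - pad))
    stop("larva out of frame bounds", call. = FALSE)

  h <- scene$height; w <- scene$width
  bg <- with_seed(scene$seed + 10^6, {
    matrix(stats::runif(h * w, 12, 28), nrow = h, ncol = w)
  })
  body <- matrix(0, nrow = h, ncol = w)

  # sample the skeleton densely; stamp a Gaussian blob at each sample
  step <- 0.5
  skel <- list(scene$head)
  for (k in seq_len(scene$n_segments)) {
    nstep <- max(2, ceiling(scene$segment_length / step))
    fr <- seq(0, 1, length.out = nstep)[-1]
    seg <- cbind(pts[k, 1] + fr * (pts[k + 1, 1] - pts[k, 1]),
                 pts[k, 2] + fr * (pts[k + 1, 2] - pts[k, 2]))
    skel <- c(skel, split(seg, row(seg)[, 1]))
  }
  sig <- scene$body_sigma
  win <- ceiling(3 * sig)
  for (p in skel) {
    xs <- max(1, floor(p[1]) - win):min(w, ceiling(p[1]) + win)
    ys <- max(1, floor(p[2]) - win):min(h, ceiling(p[2]) + win)
    dx2 <- (xs - p[1])^2
    dy2 <- (ys - p[2])^2
    blob <- scene$intensity * exp(-(outer(dy2, dx2, `+`)) / (2 * sig^2))
    body[ys, xs] <- pmax(body[ys, xs], blob)
  }
  # head blob, wider than the tail
  hx <- scene$head[1]; hy <- scene$head[2]
  hw <- ceiling(3 * 2 * sig)
  xs <- max(1, floor(hx) - hw):min(w, ceiling(hx) + hw)
  ys <- max(1, floor(hy) - hw):min(h, ceiling(hy) + hw)
  blob <- scene$intensity *
    exp(-outer((ys - hy)^2, (xs - hx)^2, `+`) / (2 * (2 * sig)^2))
  body[ys, xs] <- pmax(body[ys, xs], blob)

  pix <- bg + body
  if (scene$noise_sd > 0) {
    pix <- pix + with_seed(scene$seed + t, {
      matrix(stats::rnorm(h * w, 0, scene$noise_sd), nrow = h, ncol = w)
    })
  }
  pix <- pmin(pmax(pix, 0), 255)
  structure(list(width = w, height = h, pixels = pix, frame_index = t,
                 truth_angles = ang, mask = body > 1),
            class = "synthetic_frame")
}

#' @export
print.synthetic_frame <- function(x, ...) {
  cat(sprintf("<synthetic frame #%d %dx%d>\n", x$frame_index, x$width,
              x$height))
  invisible(x)
}

#' Freeze a background model
#'
#' Per-pixel median over the first K frames: with the tail sweeping back and
#' forth, the median converges on the static background.
#'
#' @param frames list of `synthetic_frame`s (or pixel matrices) with uniform
#'   geometry.
#' @return a `background_model` with the reference image and the absorbed
#'   frame count; immutable after this call.
#' @export
freeze_background <- function(frames) {
  stopifnot(length(frames) >= 1)
  mats <- lapply(frames, function(f) if (is.matrix(f)) f else f$pixels)
  dims <- unique(lapply(mats, dim))
  if (length(dims) != 1)
    stop("frames have mismatching geometry", call. = FALSE)
  arr <- array(unlist(mats), dim = c(dims[[1]], length(mats)))
  ref <- apply(arr, c(1, 2), stats::median)
  structure(list(reference = ref, frames_absorbed = length(mats)),
            class = "background_model")
}

#' Background subtraction
#'
#' Pixelwise `|frame - model|`, zeroed below the threshold; geometry is
#' preserved.
#'
#' @param model a [freeze_background()] result.
#' @param frame a `synthetic_frame` or pixel matrix.
#' @param threshold minimum absolute difference kept (8-bit counts).
#' @return a `foreground_frame`: `pixels` and `frame_index`.
#' @export
subtract_background <- function(model, frame, threshold = 10) {
  stopifnot(inherits(model, "background_model"))
  pix <- if (is.matrix(frame)) frame else frame$pixels
  if (!identical(dim(pix), dim(model$reference)))
    stop("frame geometry does not match the background model", call. = FALSE)
  fg <- abs(pix - model$reference)
  fg[fg < threshold] <- 0
  structure(list(pixels = fg,
                 frame_index = if (is.matrix(frame)) NA_integer_ else
                   frame$frame_index),
            class = "foreground_frame")
}

#' Tail-tracking configuration
#'
#' @param head tracking start point `c(x, y)` (must lie inside the frame).
#' @param segment_length segment length in pixels.
#' @param n_segments number of segments to fit.
#' @param initial_angle heading prior for the first segment (radians).
#' @param half_angle arc search half-angle around the current heading
#'   (radians).
#' @param arc_samples candidate directions per arc.
#' @param intensity_floor minimum summed arc intensity to accept a segment;
#'   below it the fit is declared failed.
#' @return a `tail_track_config`.
#' @export
tail_track_config <- function(head, segment_length = 10, n_segments = 7,
                              initial_angle = 0, half_angle = 0.7,
                              arc_samples = 31, intensity_floor = 5) {
  structure(as.list(environment()), class = "tail_track_config")
}

# bilinear intensity lookup; out-of-bounds reads as 0
sample_intensity <- function(pix, x, y) {
  h <- nrow(pix); w <- ncol(pix)
  out <- numeric(length(x))
  x0 <- floor(x); y0 <- floor(y)
  ok <- x0 >= 1 & x0 < w & y0 >= 1 & y0 < h
  if (any(ok)) {
    fx <- x[ok] - x0[ok]; fy <- y[ok] - y0[ok]
    i00 <- pix[cbind(y0[ok], x0[ok])]
    i01 <- pix[cbind(y0[ok], x0[ok] + 1)]
    i10 <- pix[cbind(y0[ok] + 1, x0[ok])]
    i11 <- pix[cbind(y0[ok] + 1, x0[ok] + 1)]
    out[ok] <- i00 * (1 - fx) * (1 - fy) + i01 * fx * (1 - fy) +
      i10 * (1 - fx) * fy + i11 * fx * fy
  }
  out
}

#' Track a tail by sequential arc search
#'
#' From the head point and the heading prior, candidate directions are
#' sampled over an arc; the intensity-weighted mean direction (sampled at the
#' half and full segment radius) becomes the segment angle and the search
#' repeats from the new endpoint. The fit fails (never raises) when the
#' summed arc intensity drops below the configured floor.
#'
#' @param foreground a [subtract_background()] result (or pixel matrix).
#' @param config a [tail_track_config()].
#' @return a `tail_track_result`: `frame_index`, `segment_points`
#'   (`(n_segments + 1) x 2`), `segment_angles`, `success`.
#' @export
track_tail <- function(foreground, config) {
  stopifnot(inherits(config, "tail_track_config"))
  pix <- if (is.matrix(foreground)) foreground else foreground$pixels
  fidx <- if (is.matrix(foreground)) NA_integer_ else foreground$frame_index
  h <- nrow(pix); w <- ncol(pix)
  if (config$head[1] < 1 || config$head[1] > w ||
      config$head[2] < 1 || config$head[2] > h)
    stop("tracking head point lies outside the frame", call. = FALSE)

  pos <- config$head
  heading <- config$initial_angle
  n <- config$n_segments
  pts <- matrix(NA_real_, nrow = n + 1, ncol = 2)
  pts[1, ] <- pos
  angles <- rep(NA_real_, n)
  for (k in seq_len(n)) {
    cand <- heading + seq(-config$half_angle, config$half_angle,
                          length.out = config$arc_samples)
    wgt <- sample_intensity(pix, pos[1] + config$segment_length * cos(cand),
                            pos[2] + config$segment_length * sin(cand)) +
      sample_intensity(pix, pos[1] + 0.5 * config$segment_length * cos(cand),
                       pos[2] + 0.5 * config$segment_length * sin(cand))
    if (sum(wgt) < config$intensity_floor) {
      return(structure(list(frame_index = fidx, segment_points = pts,
                            segment_angles = angles, success = FALSE),
                       class = "tail_track_result"))
    }
    ang <- sum(wgt * cand) / sum(wgt)
    pos <- pos + config$segment_length * c(cos(ang), sin(ang))
    pts[k + 1, ] <- pos
    angles[k] <- ang
    heading <- ang
  }
  structure(list(frame_index = fidx, segment_points = pts,
                 segment_angles = angles, success = TRUE),
            class = "tail_track_result")
}

#' @export
print.tail_track_result <- function(x, ...) {
  cat(sprintf("<tail track frame #%s: %s>\n", x$frame_index,
              if (x$success)
                paste(round(x$segment_angles, 3), collapse = " ")
              else "FAILED"))
  invisible(x)
}

## -- record writers -------------------------------------------------------

#' Tracking record and raw-frame writers
#'
#' The text format is one line per frame: `frame_index<TAB>angle_1..angle_N`
#' (angles in radians, tab-separated). The binary format concatenates frames,
#' each preceded by a fixed 16-byte header: 4-byte magic `"FKBF"`, then
#' `width`, `height`, `frame_index` as little-endian int32; pixel data
#' follows as `width * height` unsigned bytes, row-major.
#'
#' @param con a connection open in the appropriate append mode.
#' @param result a `tail_track_result`.
#' @param frame a `synthetic_frame`.
#' @param path file path (for the readers).
#' @export
write_text_record <- function(con, result) {
  writeLines(paste(c(result$frame_index,
                     sprintf("%.6f", result$segment_angles)),
                   collapse = "\t"), con)
  invisible(NULL)
}

#' @rdname write_text_record
#' @export
write_binary_frame <- function(con, frame) {
  writeChar("FKBF", con, nchars = 4, eos = NULL)
  writeBin(as.integer(c(frame$width, frame$height, frame$frame_index)), con,
           size = 4, endian = "little")
  # row-major: transpose the column-major R matrix
  writeBin(as.raw(round(t(frame$pixels))), con)
  invisible(NULL)
}

#' @rdname write_text_record
#' @export
read_text_records <- function(path) {
  if (!file.exists(path) || file.size(path) == 0)
    return(data.frame(frame_index = integer(0)))
  df <- utils::read.table(path, sep = "\t", header = FALSE)
  names(df) <- c("frame_index",
                 paste0("angle_", seq_len(ncol(df) - 1)))
  df
}

#' @rdname write_text_record
#' @export
read_binary_frames <- function(path) {
  con <- file(path, open = "rb")
  on.exit(close(con))
  frames <- list()
  repeat {
    magic <- readChar(con, 4, useBytes = TRUE)
    if (length(magic) == 0 || !nzchar(magic)) break
    if (!identical(magic, "FKBF")) stop("bad frame magic", call. = FALSE)
    hdr <- readBin(con, "integer", n = 3, size = 4, endian = "little")
    px <- readBin(con, "raw", n = hdr[1] * hdr[2])
    frames[[length(frames) + 1L]] <- structure(
      list(width = hdr[1], height = hdr[2], frame_index = hdr[3],
           pixels = matrix(as.integer(px), nrow = hdr[2], ncol = hdr[1],
                           byrow = TRUE)),
      class = "synthetic_frame")
  }
  frames
}
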