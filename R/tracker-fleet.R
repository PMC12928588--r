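# The demonstration fleet: synthetic camera -> background subtraction ->
# tail tracking -> display stub, plus binary/text recorders and an
# experiment-metadata vessel. Exercises the whole framework end-to-end with
# known ground truth.

#' Assemble the fish-tracking demonstration fleet
#'
#' Vessels: `CameraController` (mock driver), `MockCamera` (renders the
#' synthetic movie; link-depends on the controller), `BGSubtractor`
#' (absorbs the first `bg_frames` frames into a median background model,
#' then emits foreground frames), `TailTracker`, `Display` (a counting
#' stub sink for both the camera feed and the tracking results),
#' `ExperimentMetadata` (holds experiment info; its export creates the
#' output folder, writes the metadata file and fixes the recorder paths),
#' and the two recorders `OutputWriter` (text) and `BinaryWriter` (raw
#' frames), which link-depend on `ExperimentMetadata`: they can only build
#' after an export has established where to record. All vessels start
#' inactive; activation is part of the user protocol (see
#' [run_tracker_demo()]).
#'
#' @param scene a [larva_scene()].
#' @param n_frames frames the mock camera produces per activation cycle.
#' @param bg_frames frames absorbed into the background model.
#' @param threshold background-subtraction threshold (8-bit counts).
#' @param camera_rate camera polling rate (Hz).
#' @param out_root directory under which exports create their folders.
#' @param track_config optional [tail_track_config()]; defaults to the
#'   scene's geometry.
#' @return the assembled (not yet launched) fleet.
#' @export
build_tracker_fleet <- function(scene = larva_scene(), n_frames = 500,
                                bg_frames = 50, threshold = 10,
                                camera_rate = 100,
                                out_root = tempfile("tracker_demo_"),
                                track_config = NULL) {
  if (is.null(track_config)) {
    track_config <- tail_track_config(
      head = scene$head, segment_length = scene$segment_length,
      n_segments = scene$n_segments, initial_angle = scene$base_angle)
  }
  fl <- fleet("VirtualFishTracker")

  ctrl <- freight(fl, "CameraController",
                  builder = function() list(scene = scene,
                                            n_frames = n_frames))
  cam <- freight(fl, "MockCamera", depends_on = list(ctrl),
                 builder = function(controller) {
                   e <- new.env(parent = emptyenv())
                   e$scene <- controller$scene
                   e$n_frames <- controller$n_frames
                   e$i <- 0L
                   e
                 },
                 source_rate = camera_rate)
  add_source(cam, output_type = "frame", body = function(comp) {
    if (comp$i >= comp$n_frames) return(list(value = NULL, has_more = FALSE))
    f <- render_frame(comp$scene, comp$i)
    comp$i <- comp$i + 1L
    list(value = f, has_more = FALSE)
  })

  bg <- freight(fl, "BGSubtractor", builder = function() {
    e <- new.env(parent = emptyenv())
    e$buffer <- list()
    e$model <- NULL
    e$bg_frames <- bg_frames
    e$threshold <- threshold
    e
  })
  add_transformer(bg, input_type = "frame", output_type = "fg_frame",
                  body = function(comp, frame, meta) {
    if (is.null(comp$model)) {
      comp$buffer[[length(comp$buffer) + 1L]] <- frame
      if (length(comp$buffer) >= comp$bg_frames) {
        comp$model <- freeze_background(comp$buffer)
        comp$buffer <- list()
      }
      return(NULL)
    }
    subtract_background(comp$model, frame, comp$threshold)
  })

  trk <- freight(fl, "TailTracker", builder = function() track_config)
  add_transformer(trk, input_type = "fg_frame", output_type = "track_result",
                  body = function(cfg, fg, meta) track_tail(fg, cfg))

  disp <- freight(fl, "Display", builder = function() {
    e <- new.env(parent = emptyenv())
    e$frames_rendered <- 0L
    e$tracks_rendered <- 0L
    e
  })
  add_sink(disp, input_type = "frame",
           body = function(comp, value, meta)
             comp$frames_rendered <- comp$frames_rendered + 1L)
  add_sink(disp, input_type = "track_result",
           body = function(comp, value, meta)
             comp$tracks_rendered <- comp$tracks_rendered + 1L)

  meta_v <- freight(fl, "ExperimentMetadata", builder = function() {
    e <- new.env(parent = emptyenv())
    e$out_root <- out_root
    e$experiment <- list(name = "demo", animal_id = "synthetic")
    e$export_count <- 0L
    e$out_dir <- NULL
    e
  })

  writer_builder <- function(kind, filename) {
    force(kind); force(filename)
    function(meta_comp) {
      if (is.null(meta_comp$out_dir))
        stop("no output folder: export the experiment metadata first")
      path <- file.path(meta_comp$out_dir, filename)
      e <- new.env(parent = emptyenv())
      e$path <- path
      e$con <- file(path, open = if (kind == "text") "a" else "ab")
      e$count <- 0L
      e
    }
  }
  txt <- freight(fl, "OutputWriter", depends_on = list(meta_v),
                 builder = writer_builder("text", "tail_metrics.txt"),
                 invalidator = function(meta_comp, comp) close(comp$con))
  add_sink(txt, input_type = "track_result",
           body = function(comp, value, meta) {
             write_text_record(comp$con, value)
             comp$count <- comp$count + 1L
           })
  bin <- freight(fl, "BinaryWriter", depends_on = list(meta_v),
                 builder = writer_builder("binary", "frames.bin"),
                 invalidator = function(meta_comp, comp) close(comp$con))
  add_sink(bin, input_type = "frame",
           body = function(comp, value, meta) {
             write_binary_frame(comp$con, value)
             comp$count <- comp$count + 1L
           })

  for (nm in fl$vessel_names()) fl$vessel(nm)$set_active(FALSE)
  fl
}

#' Export experiment metadata and establish recorder paths
#'
#' Mirrors the export step of the acquisition protocol: creates exactly one
#' new output folder under the metadata vessel's root, writes a
#' human-readable metadata file there (experiment info plus a parameter
#' snapshot of the subtractor and tracker, including the configured segment
#' count and threshold), and fixes the recorder paths so the writer vessels
#' can build.
#'
#' @param fl the tracker fleet.
#' @return the created output folder path, invisibly.
#' @export
export_experiment_metadata <- function(fl) {
  res <- fl$vessel("ExperimentMetadata")$execute_call(function(comp) {
    comp$export_count <- comp$export_count + 1L
    dir <- file.path(comp$out_root, sprintf("export_%03d", comp$export_count))
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    comp$out_dir <- dir
    dir
  })
  if (!call_succeeded(res)) stop(res$error$message, call. = FALSE)
  out_dir <- call_value(res)
  snapshot <- collect_metadata(fl, list(
    BGSubtractor = c("bg_frames", "threshold"),
    TailTracker = c("n_segments", "segment_length", "half_angle",
                    "arc_samples"),
    MockCamera = c("n_frames")))
  write_metadata_report(snapshot, file.path(out_dir, "metadata.txt"))
  fleet_log(fl, "ExperimentMetadata",
            sprintf("exported metadata to %s", out_dir), "notice")
  invisible(out_dir)
}

#' Run the scripted tracking demonstration
#'
#' Executes the full user protocol on the demonstration fleet: launch
#' (recorders fail to build, no output folder exists yet); activate display,
#' camera, tracker and subtractor; run a configuration phase long enough to
#' freeze the background model and verify tracking; export the metadata;
#' reload the camera (restarting the movie while keeping the tracking
#' configuration); bring up and activate the recorders; activate the camera;
#' record the whole movie; shut down. Optionally the tracker vessel is
#' killed mid-recording to demonstrate failure containment: the camera,
#' subtractor and binary recorder keep producing while the text recorder's
#' line count freezes.
#'
#' @param scene a [larva_scene()].
#' @param n_frames movie length in frames.
#' @param bg_frames,threshold,camera_rate,out_root,track_config passed to
#'   [build_tracker_fleet()].
#' @param kill_tracker_at_frame if not `NULL`, the frame index (0-based,
#'   recording phase) at which the tracker vessel is invalidated mid-run.
#' @return a list: `fleet`, `out_dir`, `records` (parsed text records),
#'   `n_binary_frames`, `amplitude_truth`, `amplitude_estimate`,
#'   `angle_mae`, `display_frames`, `display_tracks`, `text_lines`.
#' @export
run_tracker_demo <- function(scene = larva_scene(), n_frames = 500,
                             bg_frames = 50, threshold = 10,
                             camera_rate = 100,
                             out_root = tempfile("tracker_demo_"),
                             track_config = NULL,
                             kill_tracker_at_frame = NULL) {
  fl <- build_tracker_fleet(scene, n_frames = n_frames,
                            bg_frames = bg_frames, threshold = threshold,
                            camera_rate = camera_rate, out_root = out_root,
                            track_config = track_config)
  launch(fl)   # recorders end up offline: no export has happened yet

  # 1. activate the live pipeline and configure on the fly
  for (nm in c("Display", "MockCamera", "TailTracker", "BGSubtractor"))
    set_active(fl$vessel(nm), TRUE)
  config_frames <- bg_frames + 10
  run_for(fl, config_frames / camera_rate + 0.05)
  run_until_idle(fl)   # flush in-flight frames before touching the recorders

  # 2. export metadata; 3. reload the camera (movie restarts at frame 0)
  export_experiment_metadata(fl)
  set_active(fl$vessel("MockCamera"), FALSE)
  reload(fl$vessel("MockCamera"))
  fl$vessel("MockCamera")$execute_call(function(comp) comp$i <- 0L)

  # 4. recorders online + active, then camera back on
  reload(fl$vessel("OutputWriter"))
  reload(fl$vessel("BinaryWriter"))
  set_active(fl$vessel("OutputWriter"), TRUE)
  set_active(fl$vessel("BinaryWriter"), TRUE)
  set_active(fl$vessel("MockCamera"), TRUE)

  if (!is.null(kill_tracker_at_frame)) {
    t_kill <- fl$now() + kill_tracker_at_frame / camera_rate * 1e9
    fl$scheduler$schedule(t_kill, function()
      fl$cascade_invalidate("TailTracker", "local_failure"))
  }
  run_for(fl, n_frames / camera_rate + 0.1)
  run_until_idle(fl)

  meta_comp <- fl$vessel("ExperimentMetadata")$component
  out_dir <- meta_comp$out_dir
  disp <- fl$vessel("Display")$component
  text_path <- file.path(out_dir, "tail_metrics.txt")
  bin_path <- file.path(out_dir, "frames.bin")
  shutdown(fl)   # closes the writer connections

  records <- read_text_records(text_path)
  n_bin <- if (file.exists(bin_path))
    floor(file.size(bin_path) / (16 + scene$width * scene$height)) else 0L

  amp_est <- NA_real_
  mae <- NA_real_
  if (nrow(records) > 0) {
    last_col <- paste0("angle_", scene$n_segments)
    term <- records[[last_col]]
    amp_est <- (max(term, na.rm = TRUE) - min(term, na.rm = TRUE)) / 2
    truth <- t(vapply(records$frame_index,
                      function(t) truth_angles(scene, t),
                      numeric(scene$n_segments)))
    est <- as.matrix(records[, paste0("angle_", seq_len(scene$n_segments)),
                             drop = FALSE])
    mae <- mean(abs(est - truth), na.rm = TRUE)
  }
  list(fleet = fl, out_dir = out_dir, records = records,
       n_binary_frames = n_bin, amplitude_truth = scene$amplitude,
       amplitude_estimate = amp_est, angle_mae = mae,
       display_frames = disp$frames_rendered,
       display_tracks = disp$tracks_rendered,
       text_lines = nrow(records))
}
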