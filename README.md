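# fleetkit

Fault-tolerant orchestration of desk-scale data-acquisition and online
analysis pipelines in R.

Experiment-control software has to run many moving parts at once — cameras,
stages, trackers, recorders — and a single misbehaving device should never
take the whole rig down. fleetkit structures such a system as a **fleet** of
**vessels**, each wrapping one component behind a small state machine
(builder / initializer / invalidator, guarded calls, an online/offline state
and an independent activity flag). Vessels are connected by two graphs with
different failure semantics:

* the **link graph** — a DAG of strong dependencies. Startup proceeds in
  topological rank order; when a vessel fails, exactly its descendants are
  invalidated with it (cascade), and `restore_segment()` revives exactly
  those casualties once the fault is repaired.
* the **data graph** — typed message routes derived automatically from the
  payload types of attached *source* / *transformer* / *sink* operations.
  Messages are stamped with provenance metadata (sender, original source,
  rate, a strictly increasing fleet-global id, timestamp) and multicast to
  every compatible consumer through a bounded FIFO inbox queue, so a slow or
  stalled consumer saturates only its own queue and never delays a producer.

The package is aimed at people who build and maintain acquisition rigs and
near-real-time analysis pipelines and want the orchestration — ordered
startup, failure containment, queueing, logging, settings, metadata capture —
handled by a library rather than ad-hoc glue code. It also ships a
waveform-sequencing model for hardware-control patterns (synthesizers →
pattern blocks → sequenced device arrays with virtual instruction channels),
a self-contained synthetic fish-tracking demonstration fleet with ground
truth, and a framework-overhead benchmark whose estimator is the no-intercept
regression `T_framework = a · T_ref` (slope `a = Σxy/Σx²`, overhead `a − 1`).

## A worked example

A camera provider, a camera that depends on it, and a frame saver connected
only through the data graph:

```r
library(fleetkit)

fl <- fleet("imaging")
provider <- freight(fl, "CameraProvider",
  builder = function() list(cameras = list(list(serial = "SN_Test"))))
camera <- freight(fl, "ImagingCamera", depends_on = list(provider),
  builder = function(p) { e <- new.env(); e$i <- 0L; e },
  invalidator = function(p, cam) cam$i <- -1L)
saver <- freight(fl, "FrameSaver",
  builder = function() { e <- new.env(); e$saved <- 0L; e })

add_source(camera, output_type = "frame", body = function(cam) {
  cam$i <- cam$i + 1L
  list(value = cam$i, has_more = FALSE)
})
add_sink(saver, input_type = "frame",
         body = function(s, frame, meta) s$saved <- s$saved + 1L)

launch(fl)
set_source_rate(fl, camera, 100)   # poll the camera at 100 Hz
run_for(fl, 1)                     # one (virtual) second
status_snapshot(fl)
#>           vessel  state active occupancy_pct queued dropped
#> 1 CameraProvider online   TRUE             0      0       0
#> 2  ImagingCamera online   TRUE             0      0       0
#> 3     FrameSaver online   TRUE             0      0       0
saver$component$saved
#> [1] 100
```

One hundred polls produced one hundred frames delivered through the queue.
Now the provider fails; the camera is its dependent and goes down with it,
but the saver is connected only by data and stays online:

```r
cascade_invalidate(fl, "CameraProvider", "local_failure")
#> [1] "CameraProvider" "ImagingCamera"
status_snapshot(fl)$state
#> [1] "offline" "offline" "online"
restore_segment(fl, "CameraProvider")
#> [1] "CameraProvider" "ImagingCamera"
shutdown(fl)
```

The demonstration fleet runs the full pipeline (synthetic movie → background
subtraction → arc-search tail tracking → display stub + text/binary
recorders) end to end:

```r
res <- run_tracker_demo(n_frames = 500)
res$amplitude_estimate   # ~0.37 rad against a ground truth of 0.35
res$angle_mae            # ~0.04 rad mean absolute segment-angle error
```

A thin command-line front end is included at `inst/cli/fleetkit.R`
(`run-demo`, `bench`, `status`, `graph --dot FILE`).

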