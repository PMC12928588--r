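---
title: "Orchestrating acquisition fleets: models, semantics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Orchestrating acquisition fleets: models, semantics and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fleetkit)
```

fleetkit orchestrates desk-scale data-acquisition and online-analysis
pipelines. This vignette explains the model the package implements, the
semantics it guarantees, the parameters that matter, and the design decisions
taken where the design was genuinely open.

## The two-graph model

A system is described as a **fleet** of **vessels**, each wrapping one
component (a camera driver, a filter, a file writer). Vessels are connected
by two distinct graphs with deliberately different failure semantics:

* the **link graph** records *strong, hierarchical* dependencies: a camera
  can only run while its controller board runs. It must be acyclic. It
  governs startup order (topological, by longest-path rank, alphabetical
  within a rank for determinism) and failure propagation: when a vessel
  fails, every link-graph descendant is invalidated with it, in ascending
  rank order.
* the **data graph** records *weak, messaging* connections: routes are
  derived automatically from declared payload types (a producer of type `T`
  reaches every operation consuming `T`). Failures never propagate along
  data routes; a consumer that disappears is simply skipped.

The separation is the core robustness claim: breakage is contained to the
subtree that genuinely cannot function, while everything connected only by
data keeps operating on whatever input still arrives.

### The vessel state machine

Each vessel carries a builder, an optional initializer and an optional
invalidator. `reload()` runs builder then initializer and moves the vessel
offline → loading → online; `invalidate()` runs the invalidator, drops the
component and returns the vessel offline, recording a cause (`user`,
`local_failure`, `cascade`, `shutdown`). Two flags are deliberately
independent: the state (is the component running?) and the activity flag (is
the vessel participating in messaging?), so an online vessel can be muted
without tearing its component down.

All component code — builders, initializers, invalidators, data-operation
bodies and `execute_call()` actions — runs behind a guard. An error is
caught, produces exactly one error-level log record, is stored as a
structured record on the vessel, and (for actions and operation bodies)
invalidates the vessel. No component error ever propagates to the caller of
a framework function.

Three open points were settled as follows:

* **Initializer failure** tears the partially built component down with the
  invalidator before going offline: the component exists at that point and
  deserves a proper teardown.
* **`reload()` on an online vessel** resets locally (teardown + rebuild)
  without cascading downstream, because a reset is routine — the
  acquisition protocol of the demo fleet reloads its camera mid-session and
  must not take the recorders down. A standalone `invalidate()` does emit
  the downstream cascade.
* **Automatic restoration** (`restore_segment()`) revives only descendants
  whose recorded cause is `cascade`. A vessel a user explicitly stopped
  stays stopped; repairing a fault should not override an operator's
  decision.

## The cooperative scheduler and its clock

The runtime the package models is inherently concurrent: pollers fire on
timers, each vessel processes its inbox independently, producers never wait
for consumers. R is single-threaded, so fleetkit implements this as a
*cooperative event scheduler on a virtual nanosecond clock*. Every timed
activity is an event; events execute atomically and in deterministic order
(time, then scheduling order). Per-vessel parallelism is expressed through
independent *busy windows*: processing one message occupies the consuming
vessel's window — measured real execution time plus an optional configured
virtual cost — while producers' timer events fire on schedule regardless.

This design has two consequences worth understanding:

* **Producer isolation holds by construction** — exactly the property the
  per-vessel inbox queue exists to provide. What remains empirically checked
  (and is checked in the tests) is the bookkeeping around it: a stalled
  consumer's queue saturates, overflow increments its dropped counter, FIFO
  order within the queue is preserved, and nothing deadlocks.
* **Determinism**: given a seed, every run is reproducible, including
  "concurrent" ones. Interleaving tests (e.g. one hundred simultaneous first
  requests for a service) schedule their tasks at the same virtual instant.

What the simulation does not model: preemption (an event body is atomic),
OS scheduling jitter, and true multi-core execution. Wall-clock costs do
enter the virtual clock through the busy windows, which is what makes the
overload behaviour of the benchmark physically meaningful.

## Messaging semantics

Every payload is stamped with metadata: payload type, sender (updated at
each transformer hop), original source (preserved along the whole chain),
the source's polling rate, a fleet-global strictly increasing message id
(one atomic counter starting at 0 — the simplest scheme that gives a total
order usable for downstream resolution), and a virtual-clock timestamp
(wall-clock time appears only in log records).

Operations come in three kinds with fixed body contracts: sources
(`function(component)` returning `list(value =, has_more =)`), transformers
(`function(component, value, metadata)` returning a value or `NULL`) and
sinks (same signature, no return). Routing is by exact type-identifier
match plus explicitly registered widenings — predictability was preferred
over structural convenience. Per-operation source filters restrict
consumption to chosen original sources.

Numerical/policy choices:

* **Inbox capacity** defaults to 64 messages; occupancy is observable as a
  fraction. **Overflow drops the newest** message, logs a warning and
  increments a per-vessel counter: overload is a failure mode that should be
  visible, but it must never block a producer or crash the fleet.
* **The `has_more` drain loop is capped** at `queue_capacity` invocations
  per polling call so a greedy source cannot starve the scheduler.
* **Messages queued at invalidation are retained** and processed after the
  vessel is restored — experimental data should survive a transient repair.
* `direct` dispatch bypasses the queue and processes synchronously in the
  sender's flow; for an uncontended single chain it delivers the identical
  payload sequence, which the tests assert.

## Services, settings, logging

Services are fleet-scoped lazy singletons with serialized access. In the
cooperative runtime a critical section is atomic, so the guard's practical
role is rejecting re-entrant acquisition; the singleton property under
interleaved first requests is exercised by scheduling the requests as
simultaneous events. A failing constructor caches nothing, so the next
request retries.

Settings live in a small XML dialect (nested elements for the path, values
as attributes) loaded read-only at fleet creation; a missing file is an
empty document on which every lookup returns `NULL`. The logger orders
eight levels `trace < debug < info < notice < warning < error < critical <
fatal` (any ordered eight would satisfy the contract; these are
conventional syslog-style names). Vessel state transitions are logged
automatically at `info`; each caught component error produces exactly one
`error` record. Components' standard output can be rerouted into the log
per vessel (`capture_logs`).

## The waveform model

Hardware-control output is built from per-channel waveform synthesizers
(constant, sine, square, ramp, explicit samples), aligned into **pattern
blocks** (equal-length tracks plus virtual software-instruction events at
sample positions), and concatenated by the **sequencer** into full
per-channel arrays with an absolute-index instruction timeline. Convention
choices: sample indices are 0-based; block event ranges are half-open
`[0, length)`; a ramp excludes its endpoint so repeated blocks chain
seamlessly; digital tracks are stored as 0/1 samples for uniformity; a
synthesized track has `round(rate × duration)` samples (at least one).
Virtual events fire in absolute-index order, exactly once each; a failing
handler is recorded and the remaining events still fire. Only a simulated
device exists — hardware adapters are out of scope.

## The synthetic tracking demonstration

The demonstration fleet recreates an online behavioural-tracking pipeline
with mock hardware and known ground truth. The movie generator renders a
head-fixed larva: a static textured background, a bright body drawn as
connected segments from a fixed head point, per-frame Gaussian sensor
noise. Segment `k` (0-based) at frame `t` points at

\[ \theta_k(t) = \theta_0 + A \sin(2\pi f t / r + k\,\varphi), \]

a travelling wave along the tail. Defaults: 120×120 px frames, 7 segments
of 10 px, amplitude `A = 0.35` rad, tail-beat frequency `f = 2` Hz at a
frame rate `r = 100` Hz, phase lag `φ = 0.4` rad per segment, noise
standard deviation 4 (8-bit counts) — magnitudes typical of close-up
larval imaging, with a beat slow enough that a 100 Hz mock camera samples
each cycle densely. Frame `t` renders deterministically from `seed + t`.

What the generator does *not* emulate: occlusions, illumination drift,
body-thickness changes, head movement (the preparation is head-fixed by
construction) and real videography noise statistics. Passing the recovery
tests therefore demonstrates that the pipeline wiring, queueing and
bookkeeping are correct and that the tracker solves the geometry it was
designed for — not that it would track arbitrary real recordings.

The tracker is the classical sequential arc search used for larval posture
estimation: from the current point and heading, candidate directions are
sampled over an arc (defaults: half-angle 0.7 rad, 31 candidates — wide
enough to cover the largest per-segment angle change the generator's
defaults produce, dense enough that discretization error is well below the
accepted tolerance); intensity is sampled by bilinear interpolation at the
half and full segment radius; the intensity-weighted mean direction becomes
the segment angle. A summed arc intensity below a floor (default 5) marks
the frame as failed rather than raising. Background subtraction uses a
per-pixel median over the first 50 frames and an absolute-difference
threshold of 10/255 — with a tail sweeping several times through the
background window, the median converges on the static scene.

The scripted protocol mirrors real acquisition: launch (the recorders fail
to build — no output folder exists), activate and configure the live
pipeline, export the experiment metadata (which creates exactly one output
folder and fixes the recorder paths), reload the camera, bring the
recorders up, record. The text recorder writes one tab-separated line per
frame; the binary recorder writes each frame with a fixed 16-byte header.
Killing the tracker mid-recording demonstrates containment: frames keep
streaming to the binary recorder while the text file freezes.

## The overhead benchmark

A six-stage fleet measures what the framework adds around a pure
computation: request source at a fixed rate (default 50 Hz) → timestamper →
calibrated multiply-add load → second timestamper → difference calculator →
record writer. The two timestampers are separate vessels so the measured
interval crosses real dispatch, queueing and metadata stamping. The load is
pure and deterministic with compute time linear in an integer difficulty;
`calibrate_test_operator()` sizes it per machine.

The overhead estimate pairs each framework timing with the mean reference
timing (direct invocation, warmup discarded) of its difficulty and fits a
no-intercept regression `y = a·x`; the closed form is `a = Σxy / Σx²` and
the overhead fraction is `a − 1`. When the per-item compute time exceeds the
request period the operator's inbox accumulates; this is detected from the
occupancy trace and reported as an overload flag, never an error. Absolute
overhead numbers are machine- and runtime-dependent; the meaningful
invariants are `a ≥ 1`, exactness of the closed form, and the qualitative
overload transition.

Problem sizes in the test suite and the acceptance script are kept modest
by choice — calibration spans ~0.5–4 ms, a handful of difficulties, tens of
samples per difficulty; the exported defaults (difficulties 1–10, 2–20 ms,
500 samples) remain available for real measurements via the CLI.

## Known limitations

* One process, cooperative scheduling: a long-running operation body delays
  every event behind it in *real* time (virtual bookkeeping stays correct).
  True preemption or multi-process isolation is out of scope.
* Type routing is nominal; there is no structural or class-hierarchy
  matching beyond registered widenings.
* The remote-command registry is in-process only; no interprocess
  transport.
* The waveform model stops at a simulated device; no DAQ hardware adapters.
* Log records are kept in memory for the fleet's lifetime (plus an optional
  file sink); there is no rotation.
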