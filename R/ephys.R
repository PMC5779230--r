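# Action-potential detection and passive-property measurement from
# current-clamp traces.
#
# A spike event is accepted when the discrete second derivative of Vm
# ("spike acceleration") first exceeds 20 mV/ms^2 AND the membrane potential
# reaches 0 mV within a short confirmation window. Both criteria are
# required: fast subthreshold deflections fail the 0 mV gate, slow ramps
# that reach 0 mV fail the acceleration gate.

#' Detect action potentials by the acceleration + amplitude criterion
#'
#' Scans a uniformly sampled current-clamp trace for events whose membrane
#' potential acceleration (discrete central second difference of Vm, in
#' mV/ms^2) exceeds `accel_threshold` and that reach `amplitude_gate`
#' within `confirm_ms`. The event threshold is the first acceleration
#' crossing; after a confirmed event, scanning resumes once Vm falls back
#' below that event's threshold voltage, so multi-crossing upstrokes are
#' counted once.
#'
#' @param trace A [voltage_trace()] sampled at >= 10 kHz.
#' @param accel_threshold Acceleration criterion in mV/ms^2.
#' @param amplitude_gate Voltage the spike must reach (mV).
#' @param confirm_ms Confirmation window after a threshold crossing (ms).
#' @param smooth If `TRUE`, apply a 5-point quadratic Savitzky-Golay filter
#'   before differentiating (off by default; the criterion is defined on
#'   the raw trace).
#' @param release_tol_mv Refractory release tolerance (mV): scanning resumes
#'   once Vm falls below `threshold_vm + release_tol_mv`. Non-zero so a
#'   noise-free repolarization that approaches the threshold voltage
#'   asymptotically still releases the guard.
#'
#' @return A tibble of spike events with columns `threshold_time_ms`,
#'   `threshold_vm_mv`, `peak_time_ms`, `peak_vm_mv`.
#' @export
#' @examples
#' sim <- gen_voltage_trace(n_spikes = 2, noise_sd = 0, seed = 4)
#' detect_action_potentials(sim$trace)
detect_action_potentials <- function(trace, accel_threshold = 20,
                                     amplitude_gate = 0, confirm_ms = 10,
                                     smooth = FALSE, release_tol_mv = 0.5) {
  stopifnot(inherits(trace, "voltage_trace"))
  if (trace$sampling_khz < 10) abort("trace must be sampled at >= 10 kHz")
  v <- trace$vm_mv
  n <- length(v)
  empty <- tibble::tibble(threshold_time_ms = numeric(0),
                          threshold_vm_mv = numeric(0),
                          peak_time_ms = numeric(0),
                          peak_vm_mv = numeric(0))
  if (n < 3) return(empty)
  dt <- 1 / trace$sampling_khz
  vs <- v
  if (smooth) {
    if (!requireNamespace("signal", quietly = TRUE)) {
      abort("`smooth = TRUE` requires the signal package")
    }
    vs <- as.numeric(signal::sgolayfilt(v, p = 2, n = 5))
  }
  accel <- c(NA, diff(vs, differences = 2), NA) / dt^2
  cross <- which(accel > accel_threshold)
  if (length(cross) == 0) return(empty)

  # index of the next sample reaching the amplitude gate, computed backwards
  reach <- ifelse(v >= amplitude_gate, seq_len(n), Inf)
  nxt <- rev(cummin(rev(reach)))
  w <- round(confirm_ms / dt)
  confirmed <- cross[nxt[cross] - cross <= w]
  if (length(confirmed) == 0) return(empty)

  events <- list()
  guard <- 0L  # scan resumes past this index
  for (i0 in confirmed) {
    if (i0 <= guard) next
    ipk_start <- nxt[i0]
    # peak = maximum while Vm stays at/above the event threshold voltage
    rel <- which(v[ipk_start:n] < v[i0] + release_tol_mv)
    iend <- if (length(rel) == 0) n else ipk_start + rel[1] - 2L
    seg <- i0:iend
    ipk <- seg[which.max(v[seg])]
    events[[length(events) + 1]] <- tibble::tibble(
      threshold_time_ms = trace$t_ms[i0],
      threshold_vm_mv = v[i0],
      peak_time_ms = trace$t_ms[ipk],
      peak_vm_mv = v[ipk]
    )
    guard <- iend
  }
  dplyr::bind_rows(events)
}

#' Measure spike features on the response step
#'
#' Completes detected events with amplitude and width, and computes the
#' spike frequency of the response step. Amplitude is the difference
#' between the membrane potential at the threshold point and at the spike
#' peak. Width runs from the upstroke's half-maximal-amplitude voltage to
#' the same voltage during repolarization, with linear interpolation
#' between samples. Frequency divides the number of action potentials
#' falling inside the `response_step_pa` step by the current injection
#' time.
#'
#' @param trace A [voltage_trace()] with a protocol containing the
#'   response step.
#' @param events Events from [detect_action_potentials()].
#' @param response_step_pa Amplitude of the response step (pA).
#'
#' @return A list with `events` (tibble gaining `amplitude_mv`, `width_ms`
#'   and logical `width_defined`) and `spike_frequency_hz`.
#' @export
measure_spike_features <- function(trace, events, response_step_pa = 200) {
  stopifnot(inherits(trace, "voltage_trace"))
  if (is.null(trace$protocol)) abort("trace has no protocol")
  step <- trace$protocol[trace$protocol$amplitude_pa == response_step_pa, ]
  if (nrow(step) == 0) {
    abort(sprintf("no %g pA step in the protocol", response_step_pa))
  }
  v <- trace$vm_mv
  t <- trace$t_ms

  half_cross <- function(i_from, i_to, level, rising) {
    # first crossing of `level` between samples, linearly interpolated
    idx <- i_from:(i_to - 1)
    if (rising) {
      hit <- idx[v[idx] < level & v[idx + 1] >= level]
    } else {
      hit <- idx[v[idx] >= level & v[idx + 1] < level]
    }
    if (length(hit) == 0) return(NA_real_)
    i <- hit[1]
    t[i] + (level - v[i]) / (v[i + 1] - v[i]) * (t[i + 1] - t[i])
  }

  n <- length(v)
  amp <- events$peak_vm_mv - events$threshold_vm_mv
  width <- rep(NA_real_, nrow(events))
  defined <- rep(FALSE, nrow(events))
  for (k in seq_len(nrow(events))) {
    i0 <- which.min(abs(t - events$threshold_time_ms[k]))
    ipk <- which.min(abs(t - events$peak_time_ms[k]))
    level <- events$threshold_vm_mv[k] + amp[k] / 2
    iend <- if (k < nrow(events)) {
      which.min(abs(t - events$threshold_time_ms[k + 1]))
    } else n
    up <- half_cross(i0, ipk + 1, level, rising = TRUE)
    down <- half_cross(ipk, iend, level, rising = FALSE)
    if (is.finite(up) && is.finite(down)) {
      width[k] <- down - up
      defined[k] <- TRUE
    }
  }
  events$amplitude_mv <- amp
  events$width_ms <- width
  events$width_defined <- defined

  in_step <- events$threshold_time_ms >= step$onset_ms[1] &
    events$threshold_time_ms < step$onset_ms[1] + step$duration_ms[1]
  list(
    events = events,
    spike_frequency_hz = sum(in_step) / (step$duration_ms[1] / 1000)
  )
}

#' Measure passive membrane properties
#'
#' Resting membrane potential is the mean Vm over the baseline window
#' immediately preceding the first current step (before any current is
#' applied). Input resistance is the steady-state voltage change of a
#' hyperpolarizing step divided by the injected current, using the
#' smallest-magnitude of the first three negative steps (the step most
#' likely to stay in the linear regime); the steady state is read from the
#' final 100 ms of the step. `fires_ap` records whether any action
#' potential was detected during a depolarizing step.
#'
#' @param trace A [voltage_trace()] with a protocol and >= 200 ms baseline.
#' @param baseline_ms Baseline window length (ms).
#' @param ... Passed to [detect_action_potentials()].
#'
#' @return A tibble with `resting_mv`, `input_resistance_mohm` (NA with a
#'   flag when no hyperpolarizing step exists), `fires_ap`, and
#'   `input_resistance_defined`.
#' @export
measure_passive_properties <- function(trace, baseline_ms = 200, ...) {
  stopifnot(inherits(trace, "voltage_trace"))
  if (is.null(trace$protocol)) abort("trace has no protocol")
  p <- trace$protocol
  t <- trace$t_ms
  v <- trace$vm_mv
  first_on <- min(p$onset_ms)
  if (first_on < baseline_ms) abort("baseline before the first step is too short")
  base_idx <- t >= first_on - baseline_ms & t < first_on
  resting <- mean(v[base_idx])

  neg <- p[p$amplitude_pa < 0, ]
  neg <- head(neg[order(neg$onset_ms), ], 3)
  if (nrow(neg) > 0) {
    pick <- neg[which.min(abs(neg$amplitude_pa)), ]
    ss_idx <- t >= pick$onset_ms + pick$duration_ms - 100 &
      t < pick$onset_ms + pick$duration_ms
    dv <- mean(v[ss_idx]) - resting
    # mV / pA = GOhm -> MOhm
    rin <- abs(dv) / abs(pick$amplitude_pa) * 1000
    rin_ok <- TRUE
  } else {
    rin <- NA_real_
    rin_ok <- FALSE
    warn("no hyperpolarizing step: input resistance undefined")
  }

  ev <- detect_action_potentials(trace, ...)
  pos <- p[p$amplitude_pa > 0, ]
  fires <- FALSE
  if (nrow(ev) > 0 && nrow(pos) > 0) {
    for (k in seq_len(nrow(pos))) {
      fires <- fires || any(ev$threshold_time_ms >= pos$onset_ms[k] &
                              ev$threshold_time_ms <
                                pos$onset_ms[k] + pos$duration_ms[k])
    }
  }
  tibble::tibble(
    resting_mv = resting,
    input_resistance_mohm = rin,
    input_resistance_defined = rin_ok,
    fires_ap = fires
  )
}

#' Assess spontaneous activity
#'
#' A neuron is spontaneously active if it produces any action potential
#' within two minutes of recording without current injection.
#'
#' @param trace A zero-current [voltage_trace()] of at least 120 s.
#' @param ... Passed to [detect_action_potentials()].
#'
#' @return `TRUE` if at least one action potential is detected.
#' @export
assess_spontaneous_activity <- function(trace, ...) {
  stopifnot(inherits(trace, "voltage_trace"))
  if (!is.null(trace$protocol)) {
    abort("spontaneous activity requires a zero-current recording")
  }
  if (diff(range(trace$t_ms)) < 120000) {
    abort("recording must cover at least 120 s")
  }
  nrow(detect_action_potentials(trace, ...)) >= 1
}
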