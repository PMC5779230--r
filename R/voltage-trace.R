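#' Current-step stimulation protocol
#'
#' Describes the current-clamp protocol used to probe maturing neurons:
#' 800 ms current steps applied in an alternating negative/positive pattern,
#' with the magnitude growing by 20 pA per same-sign step (-20, +20, -40,
#' +40, ... pA). The largest positive step (200 pA by default) is the
#' response step used for spike-feature measurement.
#'
#' @param max_pa Largest step magnitude in pA.
#' @param increment_pa Magnitude increment per same-sign step (pA).
#' @param step_ms Step duration in ms.
#' @param gap_ms Zero-current gap between steps (ms).
#' @param baseline_ms Zero-current baseline before the first step (ms);
#'   the resting membrane potential is read here.
#'
#' @return A tibble with columns `step`, `onset_ms`, `duration_ms`,
#'   `amplitude_pa`, one row per step.
#' @export
#' @examples
#' current_step_protocol(max_pa = 60)
current_step_protocol <- function(max_pa = 200, increment_pa = 20,
                                  step_ms = 800, gap_ms = 200,
                                  baseline_ms = 200) {
  assert_scalar_num(max_pa, "max_pa", lower = increment_pa)
  levels <- seq(increment_pa, max_pa, by = increment_pa)
  amps <- as.vector(rbind(-levels, levels))
  onsets <- baseline_ms + (seq_along(amps) - 1) * (step_ms + gap_ms)
  tibble::tibble(
    step = seq_along(amps),
    onset_ms = onsets,
    duration_ms = step_ms,
    amplitude_pa = amps
  )
}

#' Construct a membrane-voltage trace
#'
#' Container for a uniformly sampled current-clamp recording, optionally
#' carrying the current-step protocol that produced it. Sampling uniformity
#' is checked on construction.
#'
#' @param t_ms Sample times in ms, uniformly spaced.
#' @param vm_mv Membrane potential in mV, same length as `t_ms`.
#' @param sampling_khz Sampling rate in kHz; must agree with `t_ms`.
#' @param protocol A [current_step_protocol()] tibble, or `NULL` for a
#'   spontaneous (zero-current) recording.
#'
#' @return An object of class `voltage_trace`.
#' @export
voltage_trace <- function(t_ms, vm_mv, sampling_khz, protocol = NULL) {
  if (length(t_ms) == 0) abort("empty trace")
  if (length(t_ms) != length(vm_mv)) {
    abort("`t_ms` and `vm_mv` must have the same length.")
  }
  if (any(!is.finite(vm_mv))) abort("`vm_mv` contains non-finite values.")
  dt <- 1 / sampling_khz
  if (length(t_ms) > 1) {
    dts <- diff(t_ms)
    if (any(abs(dts - dt) > 1e-6 * dt)) {
      abort("trace is not uniformly sampled at the stated rate")
    }
  }
  structure(
    list(t_ms = as.numeric(t_ms), vm_mv = as.numeric(vm_mv),
         sampling_khz = sampling_khz, protocol = protocol),
    class = "voltage_trace"
  )
}

#' @export
print.voltage_trace <- function(x, ...) {
  dur <- diff(range(x$t_ms)) / 1000
  cat(sprintf("<voltage_trace> %.1f s at %g kHz, Vm in [%.1f, %.1f] mV, %s\n",
              dur, x$sampling_khz, min(x$vm_mv), max(x$vm_mv),
              if (is.null(x$protocol)) "spontaneous" else
                sprintf("%d current steps", nrow(x$protocol))))
  invisible(x)
}
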