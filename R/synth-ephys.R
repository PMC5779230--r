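# Synthetic current-clamp traces with planted action potentials.

#' Analytic spike template
#'
#' Difference-of-exponentials waveform used to plant action potentials:
#' `s(t) = A * (exp(-t / decay_tau) - exp(-t / rise_tau))` for `t >= 0`.
#' The decay time constant is solved numerically so the template's
#' half-maximal width equals `half_width_ms`; the amplitude `A` is scaled so
#' the waveform peaks at `peak_mv` above baseline. Because the waveform
#' starts with a slope discontinuity at onset, its discrete second
#' difference at the onset sample is large and controllable, so planted
#' spikes reliably satisfy an acceleration-threshold detection criterion.
#'
#' @param peak_mv Peak of the template above its baseline (mV).
#' @param half_width_ms Full width at half-maximal amplitude (ms).
#' @param rise_tau_ms Rise time constant (ms).
#'
#' @return A list with the waveform function `fun(t_ms)`, the solved
#'   `decay_tau_ms`, peak time `t_peak_ms`, analytic `half_width_ms`, the
#'   onset slope `onset_slope_mv_ms`, and the template support
#'   `support_ms` after which the waveform is below 0.1% of peak.
#' @export
spike_template <- function(peak_mv = 80, half_width_ms = 1.5,
                           rise_tau_ms = 0.25) {
  assert_scalar_num(peak_mv, "peak_mv", lower = 1e-6)
  assert_scalar_num(half_width_ms, "half_width_ms", lower = 1e-3)
  assert_scalar_num(rise_tau_ms, "rise_tau_ms", lower = 1e-4)

  shape <- function(t, tr, td) ifelse(t > 0, exp(-t / td) - exp(-t / tr), 0)
  shape_width <- function(td) {
    tr <- rise_tau_ms
    tp <- log(td / tr) * tr * td / (td - tr)
    pk <- shape(tp, tr, td)
    up <- uniroot(function(t) shape(t, tr, td) - pk / 2,
                  c(1e-9, tp), tol = 1e-12)$root
    dn <- uniroot(function(t) shape(t, tr, td) - pk / 2,
                  c(tp, 60 * td), tol = 1e-12)$root
    dn - up
  }
  td <- uniroot(function(td) shape_width(td) - half_width_ms,
                c(rise_tau_ms * 1.001, 100 * half_width_ms), tol = 1e-10)$root
  tp <- log(td / rise_tau_ms) * rise_tau_ms * td / (td - rise_tau_ms)
  pk <- shape(tp, rise_tau_ms, td)
  amp <- peak_mv / pk
  support <- -td * log(1e-3 * pk)
  list(
    fun = function(t_ms) amp * shape(t_ms, rise_tau_ms, td),
    peak_mv = peak_mv,
    rise_tau_ms = rise_tau_ms,
    decay_tau_ms = td,
    t_peak_ms = tp,
    half_width_ms = half_width_ms,
    onset_slope_mv_ms = amp * (1 / rise_tau_ms - 1 / td),
    support_ms = support
  )
}

# Noise-free membrane response to the protocol: RC charging toward I*R with
# time constant tau, exponential relaxation after each step ends.
rc_response_mv <- function(t_ms, protocol, r_mohm, tau_ms) {
  v <- numeric(length(t_ms))
  if (is.null(protocol)) return(v)
  for (k in seq_len(nrow(protocol))) {
    on <- protocol$onset_ms[k]
    off <- on + protocol$duration_ms[k]
    # pA * MOhm = 1e-6 V; divide by 1000 for mV
    vss <- protocol$amplitude_pa[k] * r_mohm / 1000
    during <- t_ms >= on & t_ms < off
    v[during] <- v[during] + vss * (1 - exp(-(t_ms[during] - on) / tau_ms))
    after <- t_ms >= off
    v_end <- vss * (1 - exp(-(off - on) / tau_ms))
    v[after] <- v[after] + v_end * exp(-(t_ms[after] - off) / tau_ms)
  }
  v
}

#' Generate a synthetic current-clamp trace with planted action potentials
#'
#' Builds a noise-free membrane response to a current-step protocol (RC
#' charging with resistance `r_mohm` and time constant `tau_ms`), plants
#' `n_spikes` spike templates during the largest positive step (the response
#' step), optionally adds subthreshold distractor humps that peak below
#' -10 mV, and adds white noise. The planted ground truth (onset times,
#' threshold voltages, template parameters) is returned alongside so
#' downstream detection can be verified by parameter recovery.
#'
#' @param n_spikes Number of action potentials to plant (>= 0).
#' @param protocol A [current_step_protocol()] tibble, or `NULL` for a
#'   spontaneous zero-current recording of length `duration_ms`.
#' @param resting_mv Resting membrane potential (mV).
#' @param noise_sd Additive white-noise standard deviation (mV).
#' @param sampling_khz Sampling rate (kHz), at least 10.
#' @param seed Integer seed; identical arguments give identical output.
#' @param r_mohm Input resistance (MOhm) of the simulated membrane.
#' @param tau_ms Membrane time constant (ms).
#' @param spike_peak_mv Absolute peak voltage of planted spikes (mV);
#'   must be above 0 mV so planted spikes satisfy the amplitude gate.
#' @param spike_half_width_ms Analytic half-width of planted spikes (ms).
#' @param n_distractors Number of subthreshold distractor humps.
#' @param distractor_peak_mv Absolute peak of distractors (mV), below -10.
#' @param duration_ms Recording length when `protocol` is `NULL`.
#'
#' @return A list with `trace` (a [voltage_trace()]) and `truth`, a list
#'   holding planted spike onset/threshold/peak values and the template
#'   parameters.
#' @export
#' @examples
#' sim <- gen_voltage_trace(n_spikes = 3, seed = 1)
#' sim$truth$spike_onset_ms
gen_voltage_trace <- function(n_spikes,
                              protocol = current_step_protocol(),
                              resting_mv = -60,
                              noise_sd = 0.2,
                              sampling_khz = 20,
                              seed = 1,
                              r_mohm = 150,
                              tau_ms = 20,
                              spike_peak_mv = 20,
                              spike_half_width_ms = 1.5,
                              n_distractors = 0,
                              distractor_peak_mv = -20,
                              duration_ms = 120000) {
  n_spikes <- assert_count(n_spikes, "n_spikes")
  n_distractors <- assert_count(n_distractors, "n_distractors")
  assert_scalar_num(sampling_khz, "sampling_khz", lower = 10)
  assert_scalar_num(noise_sd, "noise_sd", lower = 0)
  if (spike_peak_mv <= 0) abort("planted spikes must peak above 0 mV")
  if (distractor_peak_mv > -10) {
    abort("distractors must peak below -10 mV")
  }
  dt <- 1 / sampling_khz
  if (dt * 6 > spike_half_width_ms) {
    abort("sampling too coarse to resolve the spike template")
  }

  total_ms <- if (is.null(protocol)) {
    duration_ms
  } else {
    max(protocol$onset_ms + protocol$duration_ms) +
      protocol$onset_ms[1]  # trailing baseline mirrors the leading one
  }
  n <- floor(total_ms / dt) + 1
  t_ms <- (seq_len(n) - 1) * dt
  vm0 <- resting_mv + rc_response_mv(t_ms, protocol, r_mohm, tau_ms)

  # spikes go in the response step (largest positive amplitude); margins keep
  # templates inside the step so amplitude ground truth is clean
  if (is.null(protocol)) {
    win <- c(500, total_ms - 500)
  } else {
    resp <- protocol[which.max(protocol$amplitude_pa), ]
    win <- c(resp$onset_ms + 100, resp$onset_ms + resp$duration_ms - 50)
  }

  with_seed(seed, {
    onset_ms <- numeric(0)
    if (n_spikes > 0) {
      slot <- diff(win) / n_spikes
      if (slot < 40) abort("too many spikes for the response step")
      onset_ms <- win[1] + (seq_len(n_spikes) - 1 + runif(n_spikes) * 0.5) * slot
      onset_ms <- round(onset_ms / dt) * dt  # snap to the sample grid
    }
    thr_mv <- numeric(n_spikes)
    tmpl <- NULL
    vm <- vm0
    for (k in seq_len(n_spikes)) {
      i0 <- round(onset_ms[k] / dt) + 1
      thr_mv[k] <- vm0[i0]
      tk <- spike_template(peak_mv = spike_peak_mv - thr_mv[k],
                           half_width_ms = spike_half_width_ms)
      if (is.null(tmpl)) tmpl <- tk
      idx <- i0:min(n, i0 + ceiling(tk$support_ms / dt))
      vm[idx] <- vm[idx] + tk$fun(t_ms[idx] - onset_ms[k])
    }

    distractor_onset_ms <- numeric(0)
    if (n_distractors > 0) {
      # distractors sit on the pre-step baseline, away from planted spikes
      dwin <- c(10, if (is.null(protocol)) 400 else protocol$onset_ms[1] - 30)
      if (diff(dwin) < 20 * n_distractors) {
        abort("baseline too short for the requested distractors")
      }
      slot <- diff(dwin) / n_distractors
      distractor_onset_ms <-
        dwin[1] + (seq_len(n_distractors) - 1 + 0.25) * slot
      distractor_onset_ms <- round(distractor_onset_ms / dt) * dt
      dk <- spike_template(peak_mv = distractor_peak_mv - resting_mv,
                           half_width_ms = spike_half_width_ms)
      for (o in distractor_onset_ms) {
        i0 <- round(o / dt) + 1
        idx <- i0:min(n, i0 + ceiling(dk$support_ms / dt))
        vm[idx] <- vm[idx] + dk$fun(t_ms[idx] - o)
      }
    }

    if (noise_sd > 0) vm <- vm + rnorm(n, 0, noise_sd)

    list(
      trace = voltage_trace(t_ms, vm, sampling_khz, protocol),
      truth = list(
        n_spikes = n_spikes,
        spike_onset_ms = onset_ms,
        spike_threshold_mv = thr_mv,
        spike_peak_mv = rep(spike_peak_mv, n_spikes),
        amplitude_mv = spike_peak_mv - thr_mv,
        half_width_ms = spike_half_width_ms,
        template = tmpl,
        distractor_onset_ms = distractor_onset_ms,
        resting_mv = resting_mv,
        r_mohm = r_mohm,
        tau_ms = tau_ms
      )
    )
  })
}
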