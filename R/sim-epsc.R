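#' Parameters for a synthetic EPSC train
#'
#' Each stimulus evokes a biexponential current
#' `A * g(t)` with `g(t) = (exp(-t/tau_decay) - exp(-t/tau_rise))` normalized
#' to unit peak, shifted by `onset_latency_ms` after the stimulus. Successive
#' pulses are scaled by `depression_ratio^(k-1)` (short-term depression;
#' a ratio near 0 models nearly absolute depression) and sum linearly.
#'
#' @param tau_rise_ms,tau_decay_ms kinetic time constants, ms
#'   (0 < rise < decay).
#' @param amplitude_pA peak amplitude, pA; negative for an inward current.
#' @param onset_latency_ms synaptic latency from stimulus onset, ms.
#' @param depression_ratio amplitude scaling of pulse k+1 relative to pulse
#'   k, in `[0, 1]`.
#' @param noise_sd_pA additive Gaussian noise SD, pA.
#' @param sample_rate_khz sampling rate, kHz.
#' @return an `epsc_params` list.
#' @export
epsc_params <- function(tau_rise_ms = 2, tau_decay_ms = 50,
                        amplitude_pA = -100, onset_latency_ms = 4,
                        depression_ratio = 0.05, noise_sd_pA = 0,
                        sample_rate_khz = 20) {
  if (!(tau_rise_ms > 0 && tau_rise_ms < tau_decay_ms)) {
    stop("need 0 < tau_rise_ms < tau_decay_ms")
  }
  stopifnot(
    depression_ratio >= 0, depression_ratio <= 1,
    noise_sd_pA >= 0, sample_rate_khz > 0
  )
  structure(
    list(
      tau_rise_ms = tau_rise_ms, tau_decay_ms = tau_decay_ms,
      amplitude_pA = amplitude_pA, onset_latency_ms = onset_latency_ms,
      depression_ratio = depression_ratio, noise_sd_pA = noise_sd_pA,
      sample_rate_khz = sample_rate_khz
    ),
    class = "epsc_params"
  )
}

#' Unit-peak biexponential synaptic conductance shape
#'
#' `g(t) = (exp(-t/tau_decay) - exp(-t/tau_rise)) / g(t_peak)` for `t >= 0`,
#' 0 before; peak time is
#' `t* = tau_rise * tau_decay / (tau_decay - tau_rise) * log(tau_decay/tau_rise)`.
#'
#' @param t_ms time since onset, ms (vector).
#' @param tau_rise_ms,tau_decay_ms time constants, ms.
#' @return shape values, peak exactly 1 at `t*`.
#' @export
biexp_shape <- function(t_ms, tau_rise_ms, tau_decay_ms) {
  tp <- biexp_peak_time(tau_rise_ms, tau_decay_ms)
  norm <- exp(-tp / tau_decay_ms) - exp(-tp / tau_rise_ms)
  out <- numeric(length(t_ms))
  pos <- t_ms >= 0
  out[pos] <- (exp(-t_ms[pos] / tau_decay_ms) - exp(-t_ms[pos] / tau_rise_ms)) / norm
  out
}

#' @rdname biexp_shape
#' @export
biexp_peak_time <- function(tau_rise_ms, tau_decay_ms) {
  tau_rise_ms * tau_decay_ms / (tau_decay_ms - tau_rise_ms) *
    log(tau_decay_ms / tau_rise_ms)
}

#' Analytic crossing time of a fraction of peak on the biexponential rise
#'
#' Time after onset at which the unit-peak biexponential first reaches
#' `frac` of its peak, found by bisection on `[0, t_peak]`. Used as the
#' closed-form oracle for latency and rise-time measurements.
#'
#' @param frac fraction of peak in (0, 1).
#' @param tau_rise_ms,tau_decay_ms time constants, ms.
#' @return crossing time, ms.
#' @export
biexp_rise_crossing <- function(frac, tau_rise_ms, tau_decay_ms) {
  stopifnot(frac > 0, frac < 1)
  tp <- biexp_peak_time(tau_rise_ms, tau_decay_ms)
  f <- function(t) biexp_shape(t, tau_rise_ms, tau_decay_ms) - frac
  stats::uniroot(f, c(0, tp), tol = 1e-12)$root
}

#' Generate a synthetic EPSC current trace
#'
#' @param params an [epsc_params()].
#' @param stim_times_ms sorted stimulus onset times, ms (default: 5 pulses at
#'   10 Hz, i.e. 100-ms interstimulus interval).
#' @param duration_ms trace length, ms; default covers the last stimulus plus
#'   300 ms.
#' @param pre_ms baseline recorded before time 0 is not modeled; stimuli
#'   should leave >= `pre_ms` of baseline at the start (default first
#'   stimulus at >= 50 ms).
#' @param seed integer seed (used only if `noise_sd_pA > 0`).
#' @return data.frame of class `epsc_trace` with columns `t_ms`,
#'   `current_pA`, and attributes `stim_times_ms`, `params`.
#' @export
generate_epsc_train <- function(params = epsc_params(),
                                stim_times_ms = 50 + 100 * (0:4),
                                duration_ms = NULL, pre_ms = 50, seed = 1L) {
  p <- params
  if (is.unsorted(stim_times_ms, strictly = TRUE)) {
    stop("stim_times_ms must be strictly increasing")
  }
  if (is.null(duration_ms)) duration_ms <- max(stim_times_ms) + 300
  dt <- 1 / p$sample_rate_khz
  t_ms <- seq(0, duration_ms, by = dt)
  i <- numeric(length(t_ms))
  for (k in seq_along(stim_times_ms)) {
    onset <- stim_times_ms[k] + p$onset_latency_ms
    amp_k <- p$amplitude_pA * p$depression_ratio^(k - 1)
    i <- i + amp_k * biexp_shape(t_ms - onset, p$tau_rise_ms, p$tau_decay_ms)
  }
  if (p$noise_sd_pA > 0) {
    i <- i + with_seed(
      split_seed(seed, 0L),
      stats::rnorm(length(t_ms), 0, p$noise_sd_pA)
    )
  }
  out <- data.frame(t_ms = t_ms, current_pA = i)
  class(out) <- c("epsc_trace", "data.frame")
  attr(out, "stim_times_ms") <- stim_times_ms
  attr(out, "params") <- p
  out
}
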