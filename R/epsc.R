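#' Baseline-correct a current trace
#'
#' Subtracts the mean current over a window ending at the first stimulus,
#' so all downstream metrics are invariant to a constant offset.
#'
#' @param trace `epsc_trace` data.frame (`t_ms`, `current_pA`) with a
#'   `stim_times_ms` attribute, or pass `stim_times_ms` explicitly.
#' @param window_ms baseline window length before the first stimulus, ms.
#' @param stim_times_ms stimulus onsets, ms (default from the trace).
#' @return the trace with corrected `current_pA`, attribute `baseline_sd`
#'   set to the SD over the baseline window.
#' @export
baseline_correct <- function(trace, window_ms = 20, stim_times_ms = NULL) {
  stim <- stim_times_ms %||% attr(trace, "stim_times_ms")
  if (is.null(stim)) stop("stimulus times required")
  t0 <- stim[1]
  sel <- trace$t_ms >= max(t0 - window_ms, min(trace$t_ms)) & trace$t_ms < t0
  if (!any(sel)) stop("empty baseline window")
  mu <- mean(trace$current_pA[sel])
  out <- trace
  out$current_pA <- trace$current_pA - mu
  attr(out, "stim_times_ms") <- stim
  attr(out, "baseline_sd") <- stats::sd(trace$current_pA[sel])
  out
}

# analysis window for pulse k: (stim onset, next stim onset or stim + 250 ms]
pulse_window <- function(trace, stim, k, max_ms = 250) {
  lo <- stim[k]
  hi <- if (k < length(stim)) stim[k + 1L] else stim[k] + max_ms
  which(trace$t_ms > lo & trace$t_ms <= hi)
}

# lightly smooth for robust peak/crossing detection on noisy traces
smoothed_current <- function(trace, smooth_ms = 0) {
  if (smooth_ms <= 0) {
    return(trace$current_pA)
  }
  dt <- trace$t_ms[2] - trace$t_ms[1]
  boxcar_smooth(trace$current_pA, max(1L, round(smooth_ms / dt / 2)))
}

#' Peak amplitude of the response to one stimulus
#'
#' Finds the extremum (most negative for an inward current) in the window
#' from the stimulus onset to the next stimulus (or onset + 250 ms) and
#' reports its magnitude. A response is called absent when the extremum
#' does not exceed `noise_mult` times the baseline SD.
#'
#' @param trace baseline-corrected `epsc_trace`.
#' @param stim_index which stimulus (1-based).
#' @param direction `"inward"` (negative peaks) or `"outward"`.
#' @param noise_mult no-response criterion, multiples of baseline SD.
#' @param smooth_ms boxcar pre-smoothing for detection, ms (0 = none).
#' @return list `amplitude_pA` (magnitude), `peak_time_ms`, `responded`.
#' @export
measure_peak <- function(trace, stim_index = 1L, direction = "inward",
                         noise_mult = 3, smooth_ms = 0) {
  stim <- attr(trace, "stim_times_ms")
  idx <- pulse_window(trace, stim, stim_index)
  sgn <- if (direction == "inward") -1 else 1
  cur <- sgn * smoothed_current(trace, smooth_ms)[idx]
  i_pk <- which.max(cur)
  amp <- cur[i_pk]
  noise_floor <- noise_mult * (attr(trace, "baseline_sd") %||% 0)
  if (!is.finite(amp) || amp <= noise_floor || amp <= 0) {
    return(list(amplitude_pA = NA_real_, peak_time_ms = NA_real_,
      responded = FALSE
    ))
  }
  list(
    amplitude_pA = amp, peak_time_ms = trace$t_ms[idx[i_pk]],
    responded = TRUE
  )
}

# first upward crossing of `level` by `y`, linearly interpolated; with
# sustain_pts > 1 the trace must stay at or above the level for that many
# consecutive samples (counting past the end of `y` as satisfied), which
# rejects transient noise crossings; returns time or NA
first_crossing <- function(t, y, level, sustain_pts = 1L) {
  above <- y >= level
  if (!any(above)) {
    return(NA_real_)
  }
  n <- length(y)
  cand <- which(above)
  if (sustain_pts > 1L) {
    # length of the consecutive run of TRUEs starting at each index
    run <- integer(n)
    run[n] <- as.integer(above[n])
    for (i in (n - 1L):1L) {
      run[i] <- if (above[i]) run[i + 1L] + 1L else 0L
    }
    need <- pmin(sustain_pts, n - cand + 1L)
    cand <- cand[run[cand] >= need]
    if (length(cand) == 0L) {
      return(NA_real_)
    }
  }
  i <- cand[1]
  if (i == 1L) {
    return(t[1])
  }
  t[i - 1L] + (level - y[i - 1L]) / (y[i] - y[i - 1L]) * (t[i] - t[i - 1L])
}

#' Latency from stimulus onset to EPSC onset
#'
#' Time from the stimulus to the first crossing of `criterion_frac` of the
#' peak amplitude (default 5%), linearly interpolated between samples. An
#' alternative absolute criterion of `criterion_sd` baseline SDs is used
#' when `criterion = "sd"`.
#'
#' @param trace baseline-corrected trace.
#' @param stim_index stimulus number.
#' @param criterion `"frac"` (fraction of peak) or `"sd"`.
#' @param criterion_frac fraction of peak for `"frac"`.
#' @param criterion_sd multiples of baseline SD for `"sd"`.
#' @param direction,smooth_ms as in [measure_peak()].
#' @param sustain_ms the trace must stay above the criterion level for this
#'   long for a crossing to count (rejects transient noise crossings).
#' @return latency, ms (`NA` if no response or no crossing).
#' @export
latency_to_onset <- function(trace, stim_index = 1L, criterion = "frac",
                             criterion_frac = 0.05, criterion_sd = 3,
                             direction = "inward", smooth_ms = 0,
                             sustain_ms = 1) {
  stim <- attr(trace, "stim_times_ms")
  pk <- measure_peak(trace, stim_index, direction, smooth_ms = smooth_ms)
  if (!pk$responded) {
    return(NA_real_)
  }
  idx <- pulse_window(trace, stim, stim_index)
  sgn <- if (direction == "inward") -1 else 1
  y <- sgn * smoothed_current(trace, smooth_ms)[idx]
  rise <- idx[trace$t_ms[idx] <= pk$peak_time_ms]
  yr <- y[seq_along(rise)]
  level <- if (criterion == "sd") {
    criterion_sd * (attr(trace, "baseline_sd") %||% 0)
  } else {
    criterion_frac * pk$amplitude_pA
  }
  dt <- trace$t_ms[2] - trace$t_ms[1]
  tc <- first_crossing(trace$t_ms[rise], yr, level,
    sustain_pts = max(1L, round(sustain_ms / dt))
  )
  if (is.na(tc)) {
    return(NA_real_)
  }
  tc - stim[stim_index]
}

#' 20-80% rise time
#'
#' Interpolated time between the first 20% and first 80%-of-peak crossings
#' on the rising phase. Non-monotonic rises use the first crossing of each
#' level.
#'
#' @inheritParams latency_to_onset
#' @return rise time, ms (`NA` if no response).
#' @export
rise_time_20_80 <- function(trace, stim_index = 1L, direction = "inward",
                            smooth_ms = 0) {
  stim <- attr(trace, "stim_times_ms")
  pk <- measure_peak(trace, stim_index, direction, smooth_ms = smooth_ms)
  if (!pk$responded) {
    return(NA_real_)
  }
  idx <- pulse_window(trace, stim, stim_index)
  sgn <- if (direction == "inward") -1 else 1
  y <- sgn * smoothed_current(trace, smooth_ms)[idx]
  rise <- trace$t_ms[idx] <= pk$peak_time_ms
  t20 <- first_crossing(trace$t_ms[idx][rise], y[rise], 0.2 * pk$amplitude_pA)
  t80 <- first_crossing(trace$t_ms[idx][rise], y[rise], 0.8 * pk$amplitude_pA)
  t80 - t20
}

#' Monoexponential decay time constant
#'
#' Least-squares fit of `A * exp(-t / tau)` (Levenberg-Marquardt) to the
#' falling phase, from the point where the response has decayed to
#' `fit_start_frac` of its peak (default 90%, to avoid rise contamination)
#' to the earlier of the next stimulus or `recovery_frac` recovery toward
#' baseline. When the rising phase is slow relative to the decay, the 90%
#' point can still carry rise-component contamination, so the fit
#' additionally starts no earlier than `rise_guard` rise time constants
#' (estimated from the 20-80% rise time) past the peak.
#'
#' @inheritParams latency_to_onset
#' @param fit_start_frac fraction of peak at which the fit starts on the
#'   falling phase.
#' @param recovery_frac fit ends once the response falls below
#'   `1 - recovery_frac` of peak (default 95% recovery).
#' @param rise_guard extra guard past the peak, in estimated rise time
#'   constants (0 disables).
#' @param min_points minimum samples required in the fit window.
#' @return list `tau_ms`, `rms_pA`, `n_points`, plus the fitted amplitude
#'   `a_pA` and its time anchor `t0_ms` (the fit-window start), so the
#'   fitted exponential can be extrapolated as
#'   `a_pA * exp(-(t - t0_ms) / tau_ms)`. `tau_ms = NA` on failure.
#' @export
fit_decay_tau <- function(trace, stim_index = 1L, direction = "inward",
                          fit_start_frac = 0.9, recovery_frac = 0.95,
                          rise_guard = 3, min_points = 10L, smooth_ms = 0) {
  stim <- attr(trace, "stim_times_ms")
  pk <- measure_peak(trace, stim_index, direction, smooth_ms = smooth_ms)
  failed <- list(
    tau_ms = NA_real_, rms_pA = NA_real_, n_points = 0L,
    a_pA = NA_real_, t0_ms = NA_real_
  )
  if (!pk$responded) {
    return(failed)
  }
  idx <- pulse_window(trace, stim, stim_index)
  sgn <- if (direction == "inward") -1 else 1
  tt <- trace$t_ms[idx]
  y <- sgn * trace$current_pA[idx]
  fall <- tt > pk$peak_time_ms
  t_guard <- -Inf
  if (rise_guard > 0) {
    r2080 <- rise_time_20_80(trace, stim_index, direction, smooth_ms)
    if (is.finite(r2080)) {
      t_guard <- pk$peak_time_ms + rise_guard * r2080 / log(4)
    }
  }
  below_start <- fall & y <= fit_start_frac * pk$amplitude_pA & tt >= t_guard
  if (!any(below_start)) {
    return(failed)
  }
  i0 <- which(below_start)[1]
  recovered <- which(fall & y <= (1 - recovery_frac) * pk$amplitude_pA &
    seq_along(y) > i0)
  i1 <- if (length(recovered)) recovered[1] else length(y)
  sel <- i0:i1
  if (length(sel) < min_points) {
    failed$n_points <- length(sel)
    return(failed)
  }
  tf <- tt[sel] - tt[sel][1]
  yf <- y[sel]
  pos <- yf > 0
  tau0 <- if (sum(pos) >= 2) {
    cf <- stats::coef(stats::lm(log(yf[pos]) ~ tf[pos]))
    if (is.finite(cf[2]) && cf[2] < 0) -1 / cf[2] else diff(range(tf)) / 2
  } else {
    diff(range(tf)) / 2
  }
  fit <- tryCatch(
    minpack.lm::nlsLM(
      yf ~ A * exp(-tf / tau),
      start = list(A = yf[1], tau = max(tau0, 1e-3)),
      control = minpack.lm::nls.lm.control(maxiter = 200)
    ),
    error = function(e) NULL
  )
  if (is.null(fit)) {
    failed$n_points <- length(sel)
    return(failed)
  }
  list(
    tau_ms = unname(stats::coef(fit)["tau"]),
    rms_pA = sqrt(mean(stats::residuals(fit)^2)),
    n_points = length(sel),
    a_pA = unname(stats::coef(fit)["A"]),
    t0_ms = tt[sel][1]
  )
}

#' Duration at half maximum
#'
#' Interpolated width between the rising and falling 50%-of-peak crossings.
#' Undefined (with a flag attribute) when the falling crossing is truncated
#' by the next stimulus.
#'
#' @inheritParams latency_to_onset
#' @return half-width, ms (`NA` if undefined).
#' @export
halfwidth <- function(trace, stim_index = 1L, direction = "inward",
                      smooth_ms = 0) {
  stim <- attr(trace, "stim_times_ms")
  pk <- measure_peak(trace, stim_index, direction, smooth_ms = smooth_ms)
  if (!pk$responded) {
    return(NA_real_)
  }
  idx <- pulse_window(trace, stim, stim_index)
  sgn <- if (direction == "inward") -1 else 1
  tt <- trace$t_ms[idx]
  y <- sgn * smoothed_current(trace, smooth_ms)[idx]
  half <- 0.5 * pk$amplitude_pA
  rise <- tt <= pk$peak_time_ms
  t_up <- first_crossing(tt[rise], y[rise], half)
  fall_i <- which(!rise)
  below <- fall_i[y[fall_i] <= half]
  if (length(below) == 0L) {
    out <- NA_real_
    attr(out, "truncated") <- TRUE
    return(out)
  }
  i <- below[1]
  t_dn <- if (i == fall_i[1] || i == 1L) {
    tt[i]
  } else {
    tt[i - 1L] + (half - y[i - 1L]) / (y[i] - y[i - 1L]) * (tt[i] - tt[i - 1L])
  }
  t_dn - t_up
}

#' Paired-pulse ratio
#'
#' `amplitude(pulse 2) / amplitude(pulse 1)`. Because these EPSCs decay
#' slowly relative to the interstimulus interval, the second amplitude is
#' measured after subtracting the extrapolated monoexponential decay of the
#' first response (switch off with `overlap_correct = FALSE` for a simple
#' peak measurement).
#'
#' @param trace baseline-corrected trace with >= 2 stimuli.
#' @param isi_ms expected interstimulus interval, ms (checked).
#' @param direction,smooth_ms as in [measure_peak()].
#' @param overlap_correct subtract the first response's extrapolated decay.
#' @return list `ppr`, `amplitude1_pA`, `amplitude2_pA` (`ppr = NA` if the
#'   first response is absent; 0 if only the second is absent).
#' @export
paired_pulse_ratio <- function(trace, isi_ms = 100, direction = "inward",
                               overlap_correct = TRUE, smooth_ms = 0) {
  stim <- attr(trace, "stim_times_ms")
  if (length(stim) < 2L) stop("need at least two stimuli")
  if (abs(diff(stim[1:2]) - isi_ms) > 1e-6) {
    warning(sprintf(
      "first interstimulus interval is %.3g ms, not %.3g ms",
      diff(stim[1:2]), isi_ms
    ))
  }
  p1 <- measure_peak(trace, 1L, direction, smooth_ms = smooth_ms)
  if (!p1$responded) {
    return(list(ppr = NA_real_, amplitude1_pA = NA_real_,
      amplitude2_pA = NA_real_
    ))
  }
  work <- trace
  if (overlap_correct) {
    fit <- fit_decay_tau(trace, 1L, direction, smooth_ms = smooth_ms)
    if (is.finite(fit$tau_ms)) {
      sgn <- if (direction == "inward") -1 else 1
      after <- trace$t_ms > fit$t0_ms
      pred <- sgn * fit$a_pA *
        exp(-(trace$t_ms[after] - fit$t0_ms) / fit$tau_ms)
      work$current_pA[after] <- work$current_pA[after] - pred
    }
  }
  p2 <- measure_peak(work, 2L, direction, smooth_ms = smooth_ms)
  amp2 <- if (p2$responded) p2$amplitude_pA else 0
  list(
    ppr = amp2 / p1$amplitude_pA,
    amplitude1_pA = p1$amplitude_pA,
    amplitude2_pA = if (p2$responded) p2$amplitude_pA else NA_real_
  )
}

#' All six EPSC metrics for one trace
#'
#' Convenience wrapper returning peak amplitude, onset latency, 20-80% rise
#' time, decay time constant, half-width and paired-pulse ratio for a
#' baseline-corrected trace.
#'
#' @param trace an `epsc_trace` (will be baseline-corrected if not yet).
#' @param isi_ms interstimulus interval for the PPR, ms.
#' @param direction `"inward"` or `"outward"`.
#' @param smooth_ms detection pre-smoothing, ms.
#' @return one-row data.frame: `peak_amplitude_pA`, `latency_ms`,
#'   `rise_20_80_ms`, `tau_decay_ms`, `halfwidth_ms`, `ppr`.
#' @export
epsc_metrics <- function(trace, isi_ms = 100, direction = "inward",
                         smooth_ms = 0) {
  if (is.null(attr(trace, "baseline_sd"))) trace <- baseline_correct(trace)
  pk <- measure_peak(trace, 1L, direction, smooth_ms = smooth_ms)
  ppr <- if (length(attr(trace, "stim_times_ms")) >= 2L) {
    paired_pulse_ratio(trace, isi_ms, direction, smooth_ms = smooth_ms)$ppr
  } else {
    NA_real_
  }
  data.frame(
    peak_amplitude_pA = pk$amplitude_pA,
    latency_ms = latency_to_onset(trace, 1L,
      direction = direction,
      smooth_ms = smooth_ms
    ),
    rise_20_80_ms = rise_time_20_80(trace, 1L, direction, smooth_ms),
    tau_decay_ms = fit_decay_tau(trace, 1L, direction,
      smooth_ms = smooth_ms
    )$tau_ms,
    halfwidth_ms = as.numeric(halfwidth(trace, 1L, direction, smooth_ms)),
    ppr = ppr
  )
}
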