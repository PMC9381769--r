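test_that("generator superposes depressed biexponential pulses", {
  # no depression, no noise: both peaks equal after overlap correction is
  # unnecessary (tau_decay short against the ISI here)
  tr <- biexp_trace(
    tau_rise = 1, tau_decay = 10, depression = 1, noise = 0,
    stim = c(50, 150)
  )
  tr <- baseline_correct(tr)
  p1 <- measure_peak(tr, 1L)
  p2 <- measure_peak(tr, 2L)
  expect_equal(p2$amplitude_pA / p1$amplitude_pA, 1, tolerance = 1e-3)

  # tau_rise -> 0 limit: pure exponential decay at tau_decay
  trq <- generate_epsc_train(
    epsc_params(
      tau_rise_ms = 1e-4, tau_decay_ms = 20, amplitude_pA = -80,
      onset_latency_ms = 0, noise_sd_pA = 0
    ),
    stim_times_ms = 50, duration_ms = 200
  )
  sel <- trq$t_ms >= 51 & trq$t_ms <= 120
  fit <- lm(log(-trq$current_pA[sel]) ~ trq$t_ms[sel])
  expect_equal(unname(-1 / coef(fit)[2]), 20, tolerance = 1e-3)

  # stated depression shows up as the raw second/first peak ratio
  trd <- biexp_trace(
    tau_rise = 1, tau_decay = 10, depression = 0.05,
    noise = 0, stim = c(50, 150)
  )
  trd <- baseline_correct(trd)
  r <- measure_peak(trd, 2L)$amplitude_pA / measure_peak(trd, 1L)$amplitude_pA
  expect_equal(r, 0.05, tolerance = 0.01)

  expect_error(epsc_params(tau_rise_ms = 10, tau_decay_ms = 5), "tau_rise")
})

test_that("baseline correction leaves metrics offset-invariant", {
  tr <- biexp_trace(noise = 0)
  shifted <- tr
  shifted$current_pA <- shifted$current_pA + 50
  m0 <- epsc_metrics(baseline_correct(tr))
  m1 <- epsc_metrics(baseline_correct(shifted))
  expect_equal(m0, m1, tolerance = 1e-9)
  # zero-mean baseline: unchanged
  bc <- baseline_correct(tr)
  expect_equal(bc$current_pA, tr$current_pA, tolerance = 1e-12)
  expect_error(
    baseline_correct(tr, stim_times_ms = 0),
    "empty baseline"
  )
})

test_that("peak measurement flags flat traces as no response", {
  flat <- data.frame(t_ms = seq(0, 300, by = 0.05), current_pA = 0)
  attr(flat, "stim_times_ms") <- 50
  flat <- baseline_correct(flat)
  expect_false(measure_peak(flat, 1L)$responded)
  expect_true(is.na(halfwidth(flat, 1L)))
  tr <- baseline_correct(biexp_trace(noise = 0))
  expect_equal(measure_peak(tr, 1L)$amplitude_pA, 100, tolerance = 1e-3)
})

test_that("onset latency equals the stated delay plus the analytic 5% rise", {
  for (lat in c(0, 4)) {
    tr <- baseline_correct(generate_epsc_train(
      epsc_params(onset_latency_ms = lat, noise_sd_pA = 0),
      stim_times_ms = 50, duration_ms = 400
    ))
    expect_equal(
      latency_to_onset(tr, 1L),
      lat + biexp_rise_crossing(0.05, 2, 50),
      tolerance = 0.05
    )
  }
})

test_that("latency is robust to noise at one-fifth peak SD", {
  lat <- vapply(1:20, function(s) {
    tr <- baseline_correct(generate_epsc_train(
      epsc_params(noise_sd_pA = 20),
      stim_times_ms = 50, duration_ms = 400, seed = s
    ))
    latency_to_onset(tr, 1L, smooth_ms = 0.25)
  }, numeric(1))
  noiseless <- 4 + biexp_rise_crossing(0.05, 2, 50)
  expect_lt(abs(mean(lat, na.rm = TRUE) - noiseless), 1)
})

test_that("20-80% rise time matches tau * log(4) on saturating rises", {
  # saturating-exponential rise fixture built directly
  for (tau in c(1, 0.5)) {
    t <- seq(0, 400, by = 0.05)
    i <- ifelse(t >= 50, -(1 - exp(-(t - 50) / tau)), 0)
    tr <- data.frame(t_ms = t, current_pA = 100 * i)
    attr(tr, "stim_times_ms") <- 50
    tr <- baseline_correct(tr)
    expect_equal(rise_time_20_80(tr, 1L), tau * log(4), tolerance = 0.01)
  }
  # step rise: bounded by two sample intervals
  t <- seq(0, 300, by = 0.05)
  tr_step <- data.frame(t_ms = t, current_pA = ifelse(t >= 60, -100, 0))
  attr(tr_step, "stim_times_ms") <- 50
  tr_step <- baseline_correct(tr_step)
  expect_lte(rise_time_20_80(tr_step, 1L), 2 * 0.05)
})

test_that("decay fitting recovers tau exactly, under noise, and on biexps", {
  # pure exponential: exact
  t <- seq(0, 300, by = 0.05)
  tr <- data.frame(
    t_ms = t,
    current_pA = ifelse(t >= 55, -100 * exp(-(t - 55) / 10), 0)
  )
  attr(tr, "stim_times_ms") <- 50
  tr <- baseline_correct(tr)
  expect_equal(fit_decay_tau(tr, 1L)$tau_ms, 10, tolerance = 1e-6)

  # tau 50 with 5% noise: within 10% over seeds
  taus <- vapply(1:20, function(s) {
    trn <- baseline_correct(generate_epsc_train(
      epsc_params(tau_decay_ms = 50, noise_sd_pA = 5),
      stim_times_ms = 50, duration_ms = 500, seed = s
    ))
    fit_decay_tau(trn, 1L)$tau_ms
  }, numeric(1))
  expect_lt(abs(mean(taus) - 50) / 50, 0.10)

  # biexponential with fast rise: fitted tau within 5% of tau_decay
  trb <- baseline_correct(generate_epsc_train(
    epsc_params(tau_rise_ms = 1, tau_decay_ms = 40, noise_sd_pA = 0),
    stim_times_ms = 50, duration_ms = 500
  ))
  expect_lt(abs(fit_decay_tau(trb, 1L)$tau_ms - 40) / 40, 0.05)
})

test_that("half-width matches closed forms and geometry", {
  # instantaneous rise, exponential decay: width = tau * log(2)
  t <- seq(0, 400, by = 0.05)
  tr <- data.frame(
    t_ms = t,
    current_pA = ifelse(t >= 55, -100 * exp(-(t - 55) / 30), 0)
  )
  attr(tr, "stim_times_ms") <- 50
  tr <- baseline_correct(tr)
  expect_equal(halfwidth(tr, 1L), 30 * log(2), tolerance = 0.01)

  # symmetric triangle of base 10 ms: width 5 ms
  tri <- pmax(0, 1 - abs(t - 100) / 5)
  tr2 <- data.frame(t_ms = t, current_pA = -100 * tri)
  attr(tr2, "stim_times_ms") <- 90
  tr2 <- baseline_correct(tr2)
  expect_equal(halfwidth(tr2, 1L), 5, tolerance = 0.01)
})

test_that("paired-pulse ratio uses overlap correction for slow decays", {
  # identical noiseless responses
  tr1 <- baseline_correct(biexp_trace(
    tau_rise = 1, tau_decay = 10,
    depression = 1, noise = 0, stim = c(50, 150)
  ))
  expect_equal(paired_pulse_ratio(tr1)$ppr, 1, tolerance = 1e-3)

  # slow decay, strong depression: naive second peak rides on the first
  # response's tail; extrapolated-decay subtraction recovers 0.05
  tr2 <- baseline_correct(biexp_trace(
    tau_rise = 2, tau_decay = 50,
    depression = 0.05, noise = 0, stim = c(50, 150)
  ))
  expect_lt(abs(paired_pulse_ratio(tr2)$ppr - 0.05), 0.01)
  naive <- paired_pulse_ratio(tr2, overlap_correct = FALSE)$ppr
  expect_gt(naive, 0.1) # the uncorrected measure is visibly biased

  # full depression: no second response
  tr3 <- baseline_correct(biexp_trace(
    tau_rise = 2, tau_decay = 50,
    depression = 0, noise = 0, stim = c(50, 150)
  ))
  expect_equal(paired_pulse_ratio(tr3)$ppr, 0, tolerance = 0.01)
})

test_that("all metrics hit analytic values within 1% on noiseless fixtures", {
  p <- epsc_params(
    tau_rise_ms = 2, tau_decay_ms = 50, amplitude_pA = -100,
    onset_latency_ms = 4, depression_ratio = 0.5, noise_sd_pA = 0
  )
  tr <- baseline_correct(generate_epsc_train(p, stim_times_ms = c(50, 150)))
  m <- epsc_metrics(tr)
  expect_equal(m$peak_amplitude_pA, 100, tolerance = 0.01 * 100)
  expect_equal(m$latency_ms, 4 + biexp_rise_crossing(0.05, 2, 50),
    tolerance = 0.01 * 4
  )
  rise_true <- biexp_rise_crossing(0.8, 2, 50) - biexp_rise_crossing(0.2, 2, 50)
  expect_equal(m$rise_20_80_ms, rise_true, tolerance = 0.01 * rise_true)
  expect_equal(m$tau_decay_ms, 50, tolerance = 0.05 * 50)
  expect_equal(m$ppr, 0.5, tolerance = 0.01)
})

test_that("kinetics are recovered within 10% at SNR 10 across a 3^3 grid", {
  grid <- expand.grid(
    tau_rise = c(1, 2, 4), tau_decay = c(20, 50, 80),
    amp = c(50, 100, 200)
  )
  n_seeds <- 5
  for (g in seq_len(nrow(grid))) {
    tre <- grid$tau_rise[g]
    tde <- grid$tau_decay[g]
    amp <- grid$amp[g]
    got <- vapply(seq_len(n_seeds), function(s) {
      tr <- baseline_correct(generate_epsc_train(
        epsc_params(tre, tde, -amp, 4, noise_sd_pA = amp / 10),
        stim_times_ms = 50, duration_ms = 600, seed = g * 100 + s
      ))
      c(
        measure_peak(tr, 1L, smooth_ms = 1)$amplitude_pA,
        latency_to_onset(tr, 1L, smooth_ms = 0.25),
        fit_decay_tau(tr, 1L)$tau_ms
      )
    }, numeric(3))
    est <- rowMeans(got)
    lat_true <- 4 + biexp_rise_crossing(0.05, tre, tde)
    expect_lt(abs(est[1] - amp) / amp, 0.10)
    expect_lt(abs(est[2] - lat_true) / lat_true, 0.10)
    expect_lt(abs(est[3] - tde) / tde, 0.10)
  }
})
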