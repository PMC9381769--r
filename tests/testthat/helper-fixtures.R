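# shared fixtures, all built in code

# a tiny deterministic trajectory moving at constant speed along x
constant_speed_trajectory <- function(speed_cmps = 10, duration_s = 1,
                                      dt = 0.025, y = 25,
                                      arena = arena_config()) {
  t <- seq(0, duration_s, by = dt)
  out <- data.frame(t_s = t, x_cm = pmin(speed_cmps * t, arena$side_length_cm),
    y_cm = y
  )
  class(out) <- c("trajectory", "data.frame")
  attr(out, "arena") <- arena
  out
}

# occupancy/rate matrices wrapped for direct SI calls
grid_occ <- function(dwell) {
  list(dwell_s = dwell, visited = dwell > 0, arena = NULL)
}

# brute-force direct-sum Skaggs SI oracle, written independently of
# spatial_information(): plain loop over bins
si_oracle <- function(rate, dwell, mode = "skaggs") {
  tot <- 0
  p_sum <- 0
  lbar <- 0
  nvis <- 0
  for (i in seq_along(rate)) {
    if (!is.na(rate[i]) && dwell[i] > 0) {
      p_sum <- p_sum + dwell[i]
      nvis <- nvis + 1
    }
  }
  if (p_sum == 0) {
    return(NA_real_)
  }
  for (i in seq_along(rate)) {
    if (!is.na(rate[i]) && dwell[i] > 0) {
      lbar <- lbar + if (mode == "skaggs") {
        (dwell[i] / p_sum) * rate[i]
      } else {
        rate[i] / nvis
      }
    }
  }
  if (lbar <= 0) {
    return(NA_real_)
  }
  for (i in seq_along(rate)) {
    if (is.na(rate[i]) || dwell[i] <= 0 || rate[i] == 0) next
    r <- rate[i] / lbar
    w <- if (mode == "skaggs") dwell[i] / p_sum else 1 / nvis
    tot <- tot + w * r * log2(r)
  }
  tot
}

# brute-force renormalized-kernel smoothing oracle
smooth_oracle <- function(rate, visited, sigma) {
  n <- nrow(rate)
  r <- ceiling(3 * sigma)
  out <- matrix(NA_real_, n, n)
  for (i in 1:n) {
    for (j in 1:n) {
      if (!visited[i, j]) next
      num <- 0
      den <- 0
      for (di in -r:r) {
        for (dj in -r:r) {
          ii <- i + di
          jj <- j + dj
          if (ii < 1 || ii > n || jj < 1 || jj > n) next
          if (!visited[ii, jj]) next
          w <- exp(-(di^2 + dj^2) / (2 * sigma^2))
          num <- num + w * rate[ii, jj]
          den <- den + w
        }
      }
      out[i, j] <- num / den
    }
  }
  out
}

# noiseless biexponential trace fixture
biexp_trace <- function(tau_rise = 2, tau_decay = 50, amp = -100,
                        latency = 4, depression = 0.05, noise = 0,
                        rate_khz = 20, stim = 50 + 100 * (0:1), seed = 1) {
  generate_epsc_train(
    epsc_params(tau_rise, tau_decay, amp, latency, depression, noise,
      rate_khz
    ),
    stim_times_ms = stim, seed = seed
  )
}
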