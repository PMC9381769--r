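test_that("speed estimation matches hand-computable motions", {
  # uniform motion: 10 cm over 1 s
  tr <- constant_speed_trajectory(10, duration_s = 1)
  expect_equal(compute_speed(tr), rep(10, nrow(tr)), tolerance = 1e-10)

  # stationary
  tr0 <- constant_speed_trajectory(0)
  expect_true(all(compute_speed(tr0) == 0))

  # 1-D sawtooth of slope +-5 cm/s: speed 5 away from the turning points
  dt <- 0.025
  t <- seq(0, 4, by = dt)
  x <- 5 * abs((t %% 2) - 1) + 20
  tr_saw <- data.frame(t_s = t, x_cm = x, y_cm = 25)
  sp <- compute_speed(tr_saw, smooth_window_s = 0)
  turning <- abs((t %% 2) - 1) > 0.9 | abs((t %% 2) - 1) < 0.1
  expect_equal(sp[!turning], rep(5, sum(!turning)), tolerance = 1e-8)

  expect_error(compute_speed(data.frame(t_s = 0, x_cm = 1, y_cm = 1)),
    "2 trajectory samples"
  )
})

test_that("occupancy accumulates only above the speed filter", {
  arena <- arena_config()
  # parked animal: everything filtered out
  tr0 <- constant_speed_trajectory(0, duration_s = 100)
  occ0 <- compute_occupancy(tr0, arena)
  expect_true(all(occ0$dwell_s == 0))
  expect_false(any(occ0$visited))

  # 10 s in one bin at 5 cm/s: manufacture a speed series to decouple
  # motion from binning
  n <- 401
  tr <- data.frame(t_s = seq(0, 10, length.out = n), x_cm = 1, y_cm = 1)
  occ <- compute_occupancy(tr, arena, speed = rep(5, n))
  expect_equal(occ$dwell_s[1, 1], n * 0.025, tolerance = 1e-9)
  expect_equal(sum(occ$dwell_s > 0), 1L)
})

test_that("positions exactly on an interior edge bin upward", {
  arena <- arena_config(side_length_cm = 50, n_bins_per_side = 5)
  # bin width 10; x = 10 lies on the edge between bins 1 and 2
  idx <- hippotools:::bin_index(c(0, 9.999, 10, 49.999, 50), 50, 5L)
  expect_identical(idx, c(1L, 1L, 2L, 5L, 5L))
})

test_that("rate maps divide filtered spike counts by dwell", {
  arena <- arena_config()
  n <- 401
  tr <- data.frame(t_s = seq(0, 10, length.out = n), x_cm = 1, y_cm = 1)
  class(tr) <- c("trajectory", "data.frame")
  attr(tr, "arena") <- arena
  sp <- rep(5, n)
  occ <- compute_occupancy(tr, arena, speed = sp)
  # 20 spikes in the occupied bin over ~10 s
  spk <- seq(0.25, 9.75, length.out = 20)
  rm1 <- compute_ratemap(spk, tr, occ, speed = sp)
  expect_equal(rm1$rate_hz[1, 1], 20 / occ$dwell_s[1, 1], tolerance = 1e-12)
  expect_true(all(is.na(rm1$rate_hz[-1])))

  # zero spikes: zero rate over visited bins
  rm0 <- compute_ratemap(numeric(0), tr, occ, speed = sp)
  expect_equal(rm0$rate_hz[1, 1], 0)
  expect_equal(rm0$n_spikes_used, 0L)
})

test_that("spike conservation holds on random trajectories", {
  arena <- arena_config()
  for (s in 1:5) {
    traj <- generate_trajectory(arena, 300, seed = s)
    spk <- simulate_spikes(traj, list(place_cell_params(c(25, 25))),
      seed = s
    )
    occ <- compute_occupancy(traj, arena)
    rm1 <- compute_ratemap(spk, traj, occ)
    expect_equal(
      sum(rm1$rate_hz * occ$dwell_s, na.rm = TRUE),
      rm1$n_spikes_used,
      tolerance = 1e-9
    )
  }
})

test_that("smoothing is exact on constants and matches the brute-force oracle", {
  arena <- arena_config(n_bins_per_side = 9)
  dwell <- matrix(1, 9, 9)
  occ <- list(
    dwell_s = dwell, visited = dwell > 0, arena = arena,
    total_s = sum(dwell)
  )
  rmap <- list(
    rate_hz = matrix(2.5, 9, 9), occupancy = occ,
    sigma_bins = NA_real_
  )
  sm <- smooth_ratemap(rmap, 1)
  expect_equal(sm$rate_hz, matrix(2.5, 9, 9), tolerance = 1e-12)

  # single nonzero bin: center keeps the discrete-Gaussian center mass
  rate1 <- matrix(0, 9, 9)
  rate1[5, 5] <- 1
  rmap$rate_hz <- rate1
  sm1 <- smooth_ratemap(rmap, 1)
  k <- exp(-(-3:3)^2 / 2)
  expect_equal(sm1$rate_hz[5, 5], 1 / sum(outer(k, k)), tolerance = 1e-12)

  # random map with an unvisited hole: agree with the oracle
  set.seed(42)
  for (rep in 1:5) {
    rate <- matrix(rexp(81), 9, 9)
    vis <- matrix(runif(81) > 0.2, 9, 9)
    rate[!vis] <- NA
    occ2 <- list(dwell_s = 0 + vis, visited = vis, arena = arena)
    sm2 <- smooth_ratemap(
      list(rate_hz = rate, occupancy = occ2, sigma_bins = NA_real_), 1
    )
    expect_equal(sm2$rate_hz, smooth_oracle(rate, vis, 1), tolerance = 1e-12)
  }
  expect_error(smooth_ratemap(rmap, 0), "sigma_bins")
})

test_that("the fast smoothing operator reproduces smooth_ratemap", {
  set.seed(7)
  vis <- matrix(runif(225) > 0.15, 15, 15)
  rate <- matrix(rexp(225), 15, 15)
  rate[!vis] <- NA
  occ <- list(dwell_s = 0 + vis, visited = vis, arena = arena_config())
  direct <- smooth_ratemap(
    list(rate_hz = rate, occupancy = occ, sigma_bins = NA_real_), 1
  )$rate_hz
  W <- hippotools:::smoothing_operator(vis, 1)
  rvec <- as.vector(rate)
  rvec[is.na(rvec)] <- 0
  viaW <- matrix(W %*% rvec, 15, 15)
  viaW[!vis] <- NA
  expect_equal(viaW, direct, tolerance = 1e-12)
})

test_that("inclusion filter applies rate bounds and stability windows", {
  dur <- 1800
  mk <- function(rate_hz, first = TRUE, last = TRUE) {
    # uniform train, optionally silencing an edge window
    st <- seq(0, dur, by = 1 / rate_hz)
    if (!first) st <- st[st >= 900]
    if (!last) st <- st[st <= dur - 900]
    st
  }
  trains <- rbind(
    data.frame(unit_id = 1, spike_time_s = mk(0.1)), # too slow
    data.frame(unit_id = 2, spike_time_s = mk(2)), # good
    data.frame(unit_id = 3, spike_time_s = mk(6)), # too fast
    data.frame(unit_id = 4, spike_time_s = mk(2, last = FALSE)), # unstable
    data.frame(unit_id = 5, spike_time_s = seq(0.5, dur, by = 5)) # exactly 0.2
  )
  res <- apply_inclusion_filter(trains, 0, dur)
  expect_identical(res$included, c(FALSE, TRUE, FALSE, FALSE, TRUE))
  expect_error(
    apply_inclusion_filter(trains, 0, 100),
    "shorter"
  )
})
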