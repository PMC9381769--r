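#' Running speed from a tracked trajectory
#'
#' Centered finite differences: `speed_i = |r_{i+1} - r_{i-1}| /
#' (t_{i+1} - t_{i-1})` (one-sided at the ends), then boxcar-smoothed over
#' `smooth_window_s`. Returned series has the same length as the input.
#'
#' @param trajectory data.frame with `t_s`, `x_cm`, `y_cm` (>= 2 samples).
#' @param smooth_window_s full smoothing window, s.
#' @return numeric vector of speeds, cm/s.
#' @export
compute_speed <- function(trajectory, smooth_window_s = 0.1) {
  t <- trajectory$t_s
  n <- length(t)
  if (n < 2L) stop("need at least 2 trajectory samples")
  x <- trajectory$x_cm
  y <- trajectory$y_cm
  ip <- c(2:n, n)
  im <- c(1L, 1:(n - 1L))
  dt <- t[ip] - t[im]
  sp <- sqrt((x[ip] - x[im])^2 + (y[ip] - y[im])^2) / dt
  dt_med <- stats::median(diff(t))
  hw <- floor(smooth_window_s / dt_med / 2)
  boxcar_smooth(sp, hw)
}

bin_index <- function(pos, side, n_bins) {
  # half-open [edge_i, edge_{i+1}); a point exactly on an interior edge goes
  # to the higher-index bin; the last bin is closed at the far wall
  i <- floor(pos / (side / n_bins)) + 1L
  i[pos >= side] <- n_bins
  pmax(1L, pmin(as.integer(i), n_bins))
}

#' Speed-filtered occupancy map
#'
#' Dwell time per spatial bin accumulated only over samples whose running
#' speed exceeds `speed_min_cmps` (the running-period filter). Each sample
#' contributes one tracking interval of dwell.
#'
#' @param trajectory a trajectory data.frame (`t_s`, `x_cm`, `y_cm`).
#' @param arena an [arena_config()]; defaults to the trajectory's own.
#' @param speed_min_cmps speed filter threshold, cm/s (strictly greater
#'   than).
#' @param speed optional precomputed speed series (else [compute_speed()]).
#' @return an `occupancy_map`: list with `dwell_s` (n x n matrix, seconds),
#'   `visited` (logical matrix, dwell > 0), `bin_edges_cm`, `arena`,
#'   `total_s`.
#' @export
compute_occupancy <- function(trajectory, arena = NULL, speed_min_cmps = 3,
                              speed = NULL) {
  arena <- arena %||% attr(trajectory, "arena") %||% arena_config()
  n <- arena$n_bins_per_side
  L <- arena$side_length_cm
  if (is.null(speed)) speed <- compute_speed(trajectory)
  dt <- stats::median(diff(trajectory$t_s))
  keep <- speed > speed_min_cmps
  ix <- bin_index(trajectory$x_cm[keep], L, n)
  iy <- bin_index(trajectory$y_cm[keep], L, n)
  dwell <- matrix(
    tabulate((iy - 1L) * n + ix, nbins = n * n) * dt,
    nrow = n, ncol = n
  )
  structure(
    list(
      dwell_s = dwell, visited = dwell > 0,
      bin_edges_cm = seq(0, L, length.out = n + 1L),
      arena = arena, total_s = sum(dwell)
    ),
    class = "occupancy_map"
  )
}

#' Raw firing-rate map
#'
#' Spike positions are linearly interpolated from the tracking at spike
#' times; spikes are speed-filtered with the same threshold as the
#' occupancy, and per-bin counts are divided by dwell time. Bins with zero
#' dwell are undefined (`NA`), never zero-imputed. Spikes outside the
#' trajectory time span, or landing in unvisited bins, are dropped and
#' counted in `n_dropped`.
#'
#' @param spikes numeric vector of spike times (s), or a `spike_train`
#'   data.frame for a single unit.
#' @param trajectory trajectory data.frame.
#' @param occupancy an [compute_occupancy()] result (same trajectory and
#'   filter).
#' @param speed_min_cmps speed filter, cm/s.
#' @param speed optional precomputed speed series.
#' @return a `rate_map`: list with `rate_hz` (matrix, NA = undefined),
#'   `spike_count` (matrix), `n_spikes_used`, `n_dropped`, `occupancy`,
#'   `sigma_bins` (NA for a raw map).
#' @export
compute_ratemap <- function(spikes, trajectory, occupancy,
                            speed_min_cmps = 3, speed = NULL) {
  if (is.data.frame(spikes)) {
    stopifnot(length(unique(spikes$unit_id)) <= 1L)
    spikes <- spikes$spike_time_s
  }
  arena <- occupancy$arena
  n <- arena$n_bins_per_side
  t <- trajectory$t_s
  inside <- spikes >= t[1] & spikes <= t[length(t)]
  n_dropped <- sum(!inside)
  spk <- spikes[inside]
  if (is.null(speed)) speed <- compute_speed(trajectory)
  sx <- stats::approx(t, trajectory$x_cm, xout = spk)$y
  sy <- stats::approx(t, trajectory$y_cm, xout = spk)$y
  sv <- stats::approx(t, speed, xout = spk)$y
  keep <- sv > speed_min_cmps
  ix <- bin_index(sx[keep], arena$side_length_cm, n)
  iy <- bin_index(sy[keep], arena$side_length_cm, n)
  counts <- matrix(
    tabulate((iy - 1L) * n + ix, nbins = n * n),
    nrow = n, ncol = n
  )
  stray <- counts > 0 & !occupancy$visited
  if (any(stray)) {
    n_dropped <- n_dropped + sum(counts[stray])
    counts[stray] <- 0L
  }
  rate <- matrix(NA_real_, n, n)
  rate[occupancy$visited] <-
    counts[occupancy$visited] / occupancy$dwell_s[occupancy$visited]
  structure(
    list(
      rate_hz = rate, spike_count = counts,
      n_spikes_used = sum(counts), n_dropped = n_dropped,
      occupancy = occupancy, sigma_bins = NA_real_
    ),
    class = "rate_map"
  )
}

#' Gaussian-smooth a rate map over visited bins
#'
#' Convolution with a discrete Gaussian kernel (SD `sigma_bins`, truncated
#' at 3 SD), renormalized over visited bins so unvisited bins carry no
#' weight; unvisited bins stay undefined in the output.
#'
#' @param ratemap a [compute_ratemap()] result.
#' @param sigma_bins kernel SD in bins (> 0).
#' @return a `rate_map` with smoothed `rate_hz` and `sigma_bins` set.
#' @export
smooth_ratemap <- function(ratemap, sigma_bins = 1) {
  if (!is.numeric(sigma_bins) || sigma_bins <= 0) {
    stop("sigma_bins must be > 0")
  }
  rate <- ratemap$rate_hz
  visited <- ratemap$occupancy$visited
  n <- nrow(rate)
  r <- ceiling(3 * sigma_bins)
  off <- -r:r
  kern <- exp(-off^2 / (2 * sigma_bins^2))
  k2 <- outer(kern, kern)
  sm <- matrix(NA_real_, n, n)
  for (j in seq_len(n)) {
    for (i in seq_len(n)) {
      if (!visited[i, j]) next
      ii <- pmax(1L, i - r):pmin(n, i + r)
      jj <- pmax(1L, j - r):pmin(n, j + r)
      w <- k2[ii - i + r + 1L, jj - j + r + 1L, drop = FALSE]
      v <- visited[ii, jj, drop = FALSE]
      w[!v] <- 0
      sm[i, j] <- sum(w * rate[ii, jj], na.rm = TRUE) / sum(w)
    }
  }
  out <- ratemap
  out$rate_hz <- sm
  out$sigma_bins <- sigma_bins
  out
}

#' Unit-inclusion filter for putative pyramidal cells
#'
#' Keeps units whose whole-session mean firing rate (spike count / session
#' duration, unfiltered by speed) lies in `[rate_min_hz, rate_max_hz]`
#' (bounds inclusive) and whose mean rate is at least `stability_min_hz` in
#' both the first and the last `window_min` minutes of the session.
#'
#' @param spike_trains a `spike_train` data.frame (columns `unit_id`,
#'   `spike_time_s`) covering one session.
#' @param session_start_s,session_end_s session span, s (duration must be at
#'   least `2 * window_min` minutes).
#' @param rate_min_hz,rate_max_hz whole-session mean-rate bounds, Hz.
#' @param stability_min_hz minimum rate in the edge windows, Hz.
#' @param window_min edge-window length, minutes.
#' @return data.frame per unit: `unit_id`, `mean_rate_hz`, `rate_first_hz`,
#'   `rate_last_hz`, `included`.
#' @export
apply_inclusion_filter <- function(spike_trains, session_start_s,
                                   session_end_s, rate_min_hz = 0.2,
                                   rate_max_hz = 5, stability_min_hz = 0.2,
                                   window_min = 15) {
  dur <- session_end_s - session_start_s
  if (dur < 2 * window_min * 60) {
    stop("session shorter than the two stability windows")
  }
  w <- window_min * 60
  units <- sort(unique(spike_trains$unit_id))
  res <- lapply(units, function(u) {
    st <- spike_trains$spike_time_s[spike_trains$unit_id == u]
    st <- st[st >= session_start_s & st <= session_end_s]
    mean_rate <- length(st) / dur
    r_first <- sum(st < session_start_s + w) / w
    r_last <- sum(st >= session_end_s - w) / w
    data.frame(
      unit_id = u, mean_rate_hz = mean_rate,
      rate_first_hz = r_first, rate_last_hz = r_last,
      included = mean_rate >= rate_min_hz & mean_rate <= rate_max_hz &
        r_first >= stability_min_hz & r_last >= stability_min_hz
    )
  })
  do.call(rbind, res)
}
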