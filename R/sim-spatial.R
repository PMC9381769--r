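#' Arena configuration
#'
#' Square open-field arena discretized into an `n_bins_per_side` x
#' `n_bins_per_side` grid. With the defaults (50-cm side, 15 bins) each bin
#' covers (50/15)^2 ~ 11.1 cm^2.
#'
#' @param side_length_cm arena side, cm.
#' @param n_bins_per_side number of spatial bins per side (>= 2).
#' @param dt_s tracking sample interval, s.
#' @return an object of class `arena_config`.
#' @examples
#' a <- arena_config()
#' bin_area(a) # ~11.1 cm^2
#' @export
arena_config <- function(side_length_cm = 50, n_bins_per_side = 15L, dt_s = 0.025) {
  stopifnot(side_length_cm > 0, n_bins_per_side >= 2, dt_s > 0)
  structure(
    list(
      side_length_cm = side_length_cm,
      n_bins_per_side = as.integer(n_bins_per_side),
      dt_s = dt_s
    ),
    class = "arena_config"
  )
}

#' @rdname arena_config
#' @param arena an `arena_config`.
#' @export
bin_area <- function(arena) {
  (arena$side_length_cm / arena$n_bins_per_side)^2
}

#' @export
print.arena_config <- function(x, ...) {
  cat(sprintf(
    "Square arena: %g cm side, %d x %d bins (%.2f cm^2 each), dt = %g s\n",
    x$side_length_cm, x$n_bins_per_side, x$n_bins_per_side, bin_area(x), x$dt_s
  ))
  invisible(x)
}

#' Simulate an open-field trajectory
#'
#' Ornstein-Uhlenbeck velocity process with reflecting walls. The velocity
#' components relax toward zero with time constant `persistence_s` and are
#' driven so that the stationary speed distribution is Rayleigh with mean
#' `mean_speed_cmps`; this yields realistic exploration including slow
#' (<3 cm/s) epochs that exercise the speed filter. Positions are folded back
#' into the arena (reflection), which leaves speeds unchanged except at wall
#' contacts.
#'
#' @param arena an [arena_config()].
#' @param duration_s recording duration, s (> 0).
#' @param mean_speed_cmps target mean running speed, cm/s (0 gives a
#'   stationary animal).
#' @param persistence_s velocity autocorrelation time, s.
#' @param seed integer seed; identical inputs give identical trajectories.
#' @return a data.frame of class `trajectory` with columns `t_s`, `x_cm`,
#'   `y_cm` and attribute `arena`.
#' @export
generate_trajectory <- function(arena = arena_config(), duration_s,
                                mean_speed_cmps = 8, persistence_s = 1,
                                seed = 1L) {
  if (!is.numeric(duration_s) || duration_s <= 0) {
    stop("duration_s must be positive")
  }
  if (arena$dt_s <= 0) stop("dt_s must be positive")
  dt <- arena$dt_s
  L <- arena$side_length_cm
  n <- floor(duration_s / dt) + 1L
  t_s <- (seq_len(n) - 1L) * dt
  if (mean_speed_cmps == 0) {
    x <- rep(L / 2, n)
    y <- rep(L / 2, n)
  } else {
    # per-component stationary SD for a Rayleigh mean speed
    s_v <- mean_speed_cmps / sqrt(pi / 2)
    a <- exp(-dt / persistence_s)
    b <- s_v * sqrt(1 - a^2)
    xy <- with_seed(split_seed(seed, 0L), {
      vx <- as.numeric(stats::filter(b * stats::rnorm(n), a,
        method = "recursive", init = stats::rnorm(1) * s_v
      ))
      vy <- as.numeric(stats::filter(b * stats::rnorm(n), a,
        method = "recursive", init = stats::rnorm(1) * s_v
      ))
      x0 <- stats::runif(1, 0, L)
      y0 <- stats::runif(1, 0, L)
      list(
        x = x0 + cumsum(c(0, vx[-n])) * dt,
        y = y0 + cumsum(c(0, vy[-n])) * dt
      )
    })
    # fold the free path into [0, L] (reflecting boundaries)
    reflect <- function(p) {
      p <- p %% (2 * L)
      ifelse(p > L, 2 * L - p, p)
    }
    x <- reflect(xy$x)
    y <- reflect(xy$y)
  }
  out <- data.frame(t_s = t_s, x_cm = x, y_cm = y)
  class(out) <- c("trajectory", "data.frame")
  attr(out, "arena") <- arena
  out
}

#' Quadrant index of positions
#'
#' Quadrants are numbered 0-3: 0 = low-x/low-y, 1 = high-x/low-y,
#' 2 = low-x/high-y, 3 = high-x/high-y, split at the arena midlines.
#'
#' @param x,y positions, cm.
#' @param arena an [arena_config()].
#' @return integer vector in 0..3.
#' @export
position_quadrant <- function(x, y, arena) {
  mid <- arena$side_length_cm / 2
  as.integer(x >= mid) + 2L * as.integer(y >= mid)
}

#' Place-cell tuning parameters
#'
#' @param field_center_cm numeric length-2, field center (cm).
#' @param field_width_cm Gaussian field SD (cm).
#' @param peak_rate_hz in-field peak rate (Hz), > baseline.
#' @param baseline_rate_hz out-of-field rate (Hz), >= 0.
#' @return a `place_cell_params` list.
#' @export
place_cell_params <- function(field_center_cm, field_width_cm = 8,
                              peak_rate_hz = 6, baseline_rate_hz = 0.3) {
  stopifnot(
    length(field_center_cm) == 2, field_width_cm > 0,
    baseline_rate_hz >= 0, peak_rate_hz > baseline_rate_hz
  )
  structure(
    list(
      field_center_cm = as.numeric(field_center_cm),
      field_width_cm = field_width_cm,
      peak_rate_hz = peak_rate_hz,
      baseline_rate_hz = baseline_rate_hz
    ),
    class = "place_cell_params"
  )
}

#' Quadrant-confined tuning degradation
#'
#' Models optogenetic inhibition of the spatial input as a flattening of the
#' tuning curve, not a silencing: while the animal is inside the target
#' quadrant during the photoinhibition session (`"S2"`), the instantaneous
#' rate is mixed toward the cell's own session-mean rate,
#' `(1 - d) * lambda(t) + d * lambda_bar`. With `degradation = 1` the cell
#' fires at its spatial mean inside the quadrant (no tuning, unchanged mean
#' rate); with 0 it is untouched.
#'
#' @param target_quadrant quadrant index 0-3 (see [position_quadrant()]).
#' @param degradation mixing weight in `[0, 1]`.
#' @param session_label one of "S1", "S2", "S3"; the effect is applied only
#'   in S2.
#' @return an `inhibition_effect` list.
#' @export
inhibition_effect <- function(target_quadrant, degradation,
                              session_label = "S2") {
  if (!is.numeric(degradation) || degradation < 0 || degradation > 1) {
    stop("degradation must be in [0, 1]")
  }
  stopifnot(target_quadrant %in% 0:3, session_label %in% c("S1", "S2", "S3"))
  structure(
    list(
      target_quadrant = as.integer(target_quadrant),
      degradation = degradation,
      session_label = session_label
    ),
    class = "inhibition_effect"
  )
}

place_cell_rate <- function(cell, x, y) {
  d2 <- (x - cell$field_center_cm[1])^2 + (y - cell$field_center_cm[2])^2
  cell$baseline_rate_hz +
    (cell$peak_rate_hz - cell$baseline_rate_hz) *
      exp(-d2 / (2 * cell$field_width_cm^2))
}

#' Simulate place-field spike trains along a trajectory
#'
#' Inhomogeneous Poisson spiking: the instantaneous rate is
#' `lambda(t) = baseline + (peak - baseline) * exp(-||x(t) - c||^2 / (2 sigma^2))`,
#' evaluated per tracking sample (piecewise constant over `dt`). When an
#' [inhibition_effect()] with `session_label = "S2"` is supplied and the
#' simulated session is S2, samples inside the target quadrant use
#' `(1 - d) * lambda(t) + d * lambda_bar`, where `lambda_bar` is the cell's
#' mean of `lambda(t)` over the whole session. Spike counts per sample are
#' Poisson; spike times are placed uniformly within the sample and are
#' strictly increasing.
#'
#' @param trajectory a [generate_trajectory()] result (or data.frame with
#'   `t_s`, `x_cm`, `y_cm`).
#' @param cells list of [place_cell_params()] (non-empty).
#' @param effect an [inhibition_effect()] or `NULL`.
#' @param session_label session being simulated ("S1", "S2" or "S3").
#' @param seed integer seed.
#' @return data.frame of class `spike_train` with columns `unit_id` (integer)
#'   and `spike_time_s`, sorted within unit.
#' @export
simulate_spikes <- function(trajectory, cells, effect = NULL,
                            session_label = "S1", seed = 1L) {
  if (length(cells) == 0L) stop("cells must be non-empty")
  if (inherits(cells, "place_cell_params")) cells <- list(cells)
  arena <- attr(trajectory, "arena") %||% arena_config()
  t_s <- trajectory$t_s
  n <- length(t_s)
  dt <- if (n > 1) stats::median(diff(t_s)) else arena$dt_s
  in_target <- if (!is.null(effect) && effect$session_label == session_label &&
    session_label == "S2") {
    position_quadrant(trajectory$x_cm, trajectory$y_cm, arena) ==
      effect$target_quadrant
  } else {
    rep(FALSE, n)
  }
  res <- vector("list", length(cells))
  for (k in seq_along(cells)) {
    lam <- place_cell_rate(cells[[k]], trajectory$x_cm, trajectory$y_cm)
    if (any(in_target)) {
      d <- effect$degradation
      lam_bar <- mean(lam)
      lam[in_target] <- (1 - d) * lam[in_target] + d * lam_bar
    }
    st <- with_seed(split_seed(seed, k), {
      counts <- stats::rpois(n, lam * dt)
      idx <- rep.int(seq_len(n), counts)
      if (length(idx) == 0L) {
        numeric(0)
      } else {
        sort(t_s[idx] + stats::runif(length(idx), 0, dt))
      }
    })
    res[[k]] <- data.frame(unit_id = k, spike_time_s = st)
  }
  out <- do.call(rbind, res)
  class(out) <- c("spike_train", "data.frame")
  out
}

#' Simulate the three-session quadrant-inhibition protocol
#'
#' Convenience wrapper: one familiarization session (S1), one session with
#' quadrant-confined inhibition (S2), and one recovery session (S3), each of
#' `session_duration_s`, with the same cell population throughout.
#'
#' By default one exploration path is reused for all three sessions
#' (independent spiking per session). This emulates the reported situation
#' that the manipulation leaves occupancy and running speed unchanged, and
#' guarantees that session-to-session SI changes reflect the manipulation
#' and spiking noise rather than occupancy-sampling differences, to which
#' finite-session SI estimates are sensitive. Set
#' `shared_trajectory = FALSE` for an independent path per session.
#'
#' @param cells list of [place_cell_params()].
#' @param effect an [inhibition_effect()] (applied in S2 only).
#' @param arena an [arena_config()].
#' @param session_duration_s session length, s (default 1800 = 30 min).
#' @param mean_speed_cmps,persistence_s passed to [generate_trajectory()].
#' @param shared_trajectory reuse one path across sessions (default).
#' @param seed integer seed.
#' @return named list `S1`, `S2`, `S3`, each with elements `trajectory` and
#'   `spikes`.
#' @export
simulate_inhibition_experiment <- function(cells, effect,
                                           arena = arena_config(),
                                           session_duration_s = 1800,
                                           mean_speed_cmps = 8,
                                           persistence_s = 1,
                                           shared_trajectory = TRUE,
                                           seed = 1L) {
  sessions <- c("S1", "S2", "S3")
  out <- lapply(seq_along(sessions), function(i) {
    traj <- generate_trajectory(arena, session_duration_s,
      mean_speed_cmps = mean_speed_cmps, persistence_s = persistence_s,
      seed = split_seed(seed, 100L + if (shared_trajectory) 1L else i)
    )
    spk <- simulate_spikes(traj, cells,
      effect = effect,
      session_label = sessions[i], seed = split_seed(seed, 200L + i)
    )
    list(trajectory = traj, spikes = spk)
  })
  names(out) <- sessions
  out
}
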