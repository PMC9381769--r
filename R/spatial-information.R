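#' Spatial information of a rate map
#'
#' Skaggs mode (default) is the standard occupancy-weighted form,
#' \deqn{SI = \sum_x p_x \frac{\lambda_x}{\bar\lambda}
#'   \log_2 \frac{\lambda_x}{\bar\lambda},}
#' with `p_x` the dwell-time proportion of bin x and
#' `lambda_bar = sum p_x lambda_x`; `0 log 0` is taken as 0 and unvisited
#' bins are excluded from every sum. Literal mode is the unweighted per-bin
#' sum `(1 / sum_x P_x) * sum_x (lambda_x/lambda_bar) log2(...)`, with
#' `P_x` the normalized occupancy (so the prefactor is 1) and `lambda_bar`
#' the unweighted mean rate over visited bins, the reading under which the
#' quantity stays non-negative.
#'
#' Undefined (`NA`) when the mean rate is zero or no bin is both visited
#' and defined.
#'
#' @param ratemap a `rate_map` (raw or smoothed), or a numeric matrix of
#'   rates with `NA` for undefined bins.
#' @param occupancy an `occupancy_map`, or a numeric matrix of dwell times.
#' @param mode `"skaggs"` or `"literal"`.
#' @param bins optional logical matrix restricting the computation to a
#'   subset of bins (e.g. one quadrant).
#' @return spatial information in bits/spike, or `NA` if undefined.
#' @export
spatial_information <- function(ratemap, occupancy, mode = c("skaggs", "literal"),
                                bins = NULL) {
  mode <- match.arg(mode)
  rate <- if (is.list(ratemap)) ratemap$rate_hz else ratemap
  dwell <- if (is.list(occupancy)) occupancy$dwell_s else occupancy
  use <- dwell > 0 & !is.na(rate)
  if (!is.null(bins)) use <- use & bins
  if (!any(use)) {
    return(NA_real_)
  }
  lx <- rate[use]
  px <- dwell[use] / sum(dwell[use])
  if (mode == "skaggs") {
    lbar <- sum(px * lx)
    if (lbar <= 0) {
      return(NA_real_)
    }
    ratio <- lx / lbar
    terms <- px * ratio * ifelse(ratio > 0, log2(ratio), 0)
  } else {
    lbar <- mean(lx)
    if (lbar <= 0) {
      return(NA_real_)
    }
    ratio <- lx / lbar
    terms <- ratio * ifelse(ratio > 0, log2(ratio), 0) / length(lx)
  }
  sum(terms)
}

#' Partition the bin grid into four equal quadrants
#'
#' Bins whose centers fall exactly on an arena midline (the middle row and
#' column of an odd grid) are excluded, leaving four quadrants of equal bin
#' count. Quadrant indices follow [position_quadrant()]: 0 = low-x/low-y,
#' 1 = high-x/low-y, 2 = low-x/high-y, 3 = high-x/high-y.
#'
#' @param n_bins bins per side.
#' @return integer matrix n x n; entries 0-3, `NA` for excluded midline
#'   bins. Rows index x, columns y.
#' @export
quadrant_partition <- function(n_bins = 15L) {
  n <- as.integer(n_bins)
  centers <- (seq_len(n) - 0.5) / n # in units of arena side
  half <- ifelse(centers == 0.5, NA_integer_, as.integer(centers > 0.5))
  outer(half, half, function(hx, hy) hx + 2L * hy)
}

#' Per-quadrant spatial information
#'
#' SI computed independently within each quadrant's bins, with occupancy
#' proportions and the mean rate renormalized within the quadrant (default)
#' or, optionally, keeping the whole-map mean rate as the reference.
#' Quadrants with no visited bins or zero mean rate are `NA`.
#'
#' @param ratemap,occupancy,mode as in [spatial_information()].
#' @param partition a [quadrant_partition()] matrix matching the grid.
#' @param local_mean if `FALSE`, `lambda_bar` is the whole-map
#'   occupancy-weighted mean instead of the within-quadrant one.
#' @return numeric length-4 vector, SI (bits/spike) for quadrants 0-3.
#' @export
quadrant_si <- function(ratemap, occupancy, partition = NULL,
                        mode = c("skaggs", "literal"), local_mean = TRUE) {
  mode <- match.arg(mode)
  rate <- if (is.list(ratemap)) ratemap$rate_hz else ratemap
  dwell <- if (is.list(occupancy)) occupancy$dwell_s else occupancy
  if (is.null(partition)) partition <- quadrant_partition(nrow(rate))
  stopifnot(all(dim(partition) == dim(rate)))
  vapply(0:3, function(q) {
    bins <- !is.na(partition) & partition == q
    if (local_mean) {
      spatial_information(rate, dwell, mode = mode, bins = bins)
    } else {
      use <- dwell > 0 & !is.na(rate)
      if (!any(use & bins)) {
        return(NA_real_)
      }
      px_all <- dwell / sum(dwell[use])
      lbar <- sum(px_all[use] * rate[use])
      if (lbar <= 0) {
        return(NA_real_)
      }
      sel <- use & bins
      px <- dwell[sel] / sum(dwell[sel])
      ratio <- rate[sel] / lbar
      sum(px * ratio * ifelse(ratio > 0, log2(ratio), 0))
    }
  }, numeric(1))
}

# Gaussian smoothing over visited bins as a linear operator: row i gives the
# renormalized kernel weights of output bin i over all visited input bins.
# Identical to smooth_ratemap() on any map sharing the visited mask.
smoothing_operator <- function(visited, sigma_bins) {
  n <- nrow(visited)
  r <- ceiling(3 * sigma_bins)
  off <- -r:r
  kern <- exp(-off^2 / (2 * sigma_bins^2))
  k2 <- outer(kern, kern)
  nb <- n * n
  W <- matrix(0, nb, nb)
  vis <- as.vector(visited)
  for (j in seq_len(n)) {
    for (i in seq_len(n)) {
      if (!visited[i, j]) next
      ii <- max(1L, i - r):min(n, i + r)
      jj <- max(1L, j - r):min(n, j + r)
      w <- k2[ii - i + r + 1L, jj - j + r + 1L, drop = FALSE]
      idx <- rep(ii, times = length(jj)) + (rep(jj, each = length(ii)) - 1L) * n
      keep <- vis[idx]
      row <- numeric(nb)
      row[idx[keep]] <- w[keep]
      W[(j - 1L) * n + i, ] <- row / sum(row)
    }
  }
  W
}

#' Full per-unit SI table for one session
#'
#' Convenience pipeline: occupancy, per-unit raw and smoothed rate maps,
#' whole-map and per-quadrant SI. Smoothing is applied through a
#' precomputed linear operator (identical to [smooth_ratemap()] for the
#' session's visited mask), so large unit populations stay fast.
#'
#' @param spike_trains `spike_train` data.frame for the session.
#' @param trajectory the session trajectory.
#' @param arena an [arena_config()].
#' @param session_label label stored in the result.
#' @param speed_min_cmps speed filter, cm/s.
#' @param sigma_bins smoothing SD in bins.
#' @param mode SI mode.
#' @param local_mean per-quadrant SI normalization: within-quadrant mean
#'   rate (`TRUE`) or whole-map mean (`FALSE`); see [quadrant_si()].
#' @return data.frame: `unit_id`, `session_label`, `mean_rate_hz`,
#'   `si_whole`, `si_q0`..`si_q3`.
#' @export
session_si_table <- function(spike_trains, trajectory, arena = NULL,
                             session_label = "S1", speed_min_cmps = 3,
                             sigma_bins = 1, mode = "skaggs",
                             local_mean = TRUE) {
  arena <- arena %||% attr(trajectory, "arena") %||% arena_config()
  n <- arena$n_bins_per_side
  speed <- compute_speed(trajectory)
  occ <- compute_occupancy(trajectory, arena, speed_min_cmps, speed = speed)
  part <- quadrant_partition(n)
  W <- smoothing_operator(occ$visited, sigma_bins)
  t0 <- trajectory$t_s[1]
  t1 <- trajectory$t_s[length(trajectory$t_s)]
  dur <- t1 - t0

  si_of_spikes <- function(st) {
    rm_raw <- compute_ratemap(st, trajectory, occ, speed_min_cmps,
      speed = speed
    )
    rvec <- as.vector(rm_raw$rate_hz)
    rvec[is.na(rvec)] <- 0 # unvisited rows of W carry zero weight
    sm <- matrix(W %*% rvec, n, n)
    sm[!occ$visited] <- NA_real_
    c(
      spatial_information(sm, occ, mode = mode),
      quadrant_si(sm, occ, part, mode = mode, local_mean = local_mean)
    )
  }

  units <- sort(unique(spike_trains$unit_id))
  res <- lapply(units, function(u) {
    st <- spike_trains$spike_time_s[spike_trains$unit_id == u]
    si <- si_of_spikes(st)
    data.frame(
      unit_id = u, session_label = session_label,
      mean_rate_hz = length(st) / dur,
      si_whole = si[1],
      si_q0 = si[2], si_q1 = si[3], si_q2 = si[4], si_q3 = si[5]
    )
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Two-sided Mann-Whitney (Wilcoxon rank-sum) comparison
#'
#' Thin wrapper over [stats::wilcox.test()]: exact null distribution when
#' `n1 * n2 <= 400` and there are no ties, otherwise the normal
#' approximation with continuity and tie correction.
#'
#' @param x,y numeric samples.
#' @param alternative as in `wilcox.test`.
#' @return list `statistic` (U), `p_value`, `exact` (logical).
#' @export
rank_sum_test <- function(x, y, alternative = "two.sided") {
  x <- x[is.finite(x)]
  y <- y[is.finite(y)]
  has_ties <- anyDuplicated(c(x, y)) > 0
  exact <- length(x) * length(y) <= 400 && !has_ties
  if (length(unique(c(x, y))) == 1L) {
    # degenerate: all values identical
    return(list(
      statistic = length(x) * length(y) / 2, p_value = 1,
      exact = FALSE
    ))
  }
  wt <- suppressWarnings(stats::wilcox.test(x, y,
    alternative = alternative,
    exact = exact, correct = TRUE
  ))
  list(
    statistic = unname(wt$statistic), p_value = wt$p.value,
    exact = exact
  )
}

#' Compare per-quadrant SI across the three sessions
#'
#' For every unit present in all three sessions, computes the SI change
#' from S1 inside the target quadrant and outside (mean of the other three
#' quadrants), for S2 - S1 and S3 - S1, then compares inside vs outside
#' deltas with a two-sided Mann-Whitney test per session pair.
#'
#' @param si_s1,si_s2,si_s3 [session_si_table()] results for the three
#'   sessions (same unit set; units missing a session are dropped and
#'   counted).
#'
#'   The rank-sum tests compare the per-unit target-quadrant deltas against
#'   the per-quadrant deltas of the three non-target quadrants (three
#'   values per unit, not their mean): with no manipulation all
#'   per-quadrant deltas are identically distributed, which keeps the test
#'   size nominal, whereas averaging the outside quadrants first shrinks
#'   their dispersion by about sqrt(3) and makes the comparison
#'   anti-conservative. The per-unit mean-of-three outside delta is still
#'   what `deltas` reports.
#' @param target_quadrant quadrant index 0-3 under inhibition in S2.
#' In addition to the inside-versus-outside tests (`p_s2`, `p_s3`), the
#' within-region comparisons of the S2 - S1 deltas against the S3 - S1
#' deltas are reported (`p_inside`, `p_outside`): an acute, reversible
#' effect shows up as a strong within-target difference that vanishes
#' outside.
#'
#' @return list with `deltas` (data.frame: `unit_id`, `inside_s2`,
#'   `outside_s2`, `inside_s3`, `outside_s3`), `p_s2`, `p_s3`,
#'   `p_inside`, `p_outside`, `n_dropped`.
#' @export
compare_sessions <- function(si_s1, si_s2, si_s3, target_quadrant) {
  stopifnot(target_quadrant %in% 0:3)
  common <- Reduce(intersect, list(
    si_s1$unit_id, si_s2$unit_id, si_s3$unit_id
  ))
  n_dropped <- length(unique(c(
    si_s1$unit_id, si_s2$unit_id, si_s3$unit_id
  ))) - length(common)
  qcols <- paste0("si_q", 0:3)
  tq <- qcols[target_quadrant + 1L]
  oq <- setdiff(qcols, tq)
  pick <- function(tab) tab[match(common, tab$unit_id), , drop = FALSE]
  s1 <- pick(si_s1)
  s2 <- pick(si_s2)
  s3 <- pick(si_s3)
  outside_mean <- function(tab) rowMeans(tab[, oq, drop = FALSE], na.rm = TRUE)
  deltas <- data.frame(
    unit_id = common,
    inside_s2 = s2[[tq]] - s1[[tq]],
    outside_s2 = outside_mean(s2) - outside_mean(s1),
    inside_s3 = s3[[tq]] - s1[[tq]],
    outside_s3 = outside_mean(s3) - outside_mean(s1)
  )
  out_q <- function(tab) unlist(tab[, oq], use.names = FALSE)
  out_q_s2 <- out_q(s2) - out_q(s1)
  out_q_s3 <- out_q(s3) - out_q(s1)
  t_s2 <- rank_sum_test(deltas$inside_s2, out_q_s2)
  t_s3 <- rank_sum_test(deltas$inside_s3, out_q_s3)
  t_in <- rank_sum_test(deltas$inside_s2, deltas$inside_s3)
  t_out <- rank_sum_test(out_q_s2, out_q_s3)
  list(
    deltas = deltas, p_s2 = t_s2$p_value, p_s3 = t_s3$p_value,
    p_inside = t_in$p_value, p_outside = t_out$p_value,
    n_dropped = n_dropped
  )
}
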