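#' Quadrant-inhibition recovery experiment, end to end
#'
#' Runs the full generator-plus-analysis pipeline for the three-session
#' protocol over several independent replicates: place-cell populations
#' with uniformly placed fields, a quadrant-confined tuning degradation in
#' S2, per-session SI tables and the session comparisons of
#' [compare_sessions()].
#'
#' @param n_units place cells per replicate.
#' @param degradation S2 tuning degradation in the target quadrant.
#' @param n_seeds number of independent replicates.
#' @param master_seed seed from which all replicate seeds derive.
#' @param target_quadrant quadrant index 0-3.
#' @param session_duration_s session length, s.
#' @param arena an [arena_config()].
#' @return data.frame with one row per replicate: `seed`, `p_s2`, `p_s3`,
#'   `p_inside`, `p_outside`, `median_inside_s2`, `median_outside_s2`.
#' @export
run_inhibition_recovery <- function(n_units = 100, degradation = 0.8,
                                    n_seeds = 20, master_seed = 1L,
                                    target_quadrant = 2L,
                                    session_duration_s = 1800,
                                    arena = arena_config()) {
  res <- lapply(seq_len(n_seeds), function(i) {
    seed <- split_seed(master_seed, 300L + i)
    cells <- with_seed(split_seed(seed, 7L), {
      lapply(seq_len(n_units), function(k) {
        place_cell_params(stats::runif(2, 5, arena$side_length_cm - 5))
      })
    })
    eff <- inhibition_effect(target_quadrant, degradation)
    sim <- simulate_inhibition_experiment(cells, eff, arena,
      session_duration_s = session_duration_s, seed = seed
    )
    tabs <- lapply(names(sim), function(s) {
      session_si_table(sim[[s]]$spikes, sim[[s]]$trajectory, arena, s)
    })
    cmp <- compare_sessions(tabs[[1]], tabs[[2]], tabs[[3]], target_quadrant)
    data.frame(
      seed = seed, p_s2 = cmp$p_s2, p_s3 = cmp$p_s3,
      p_inside = cmp$p_inside, p_outside = cmp$p_outside,
      median_inside_s2 = stats::median(cmp$deltas$inside_s2, na.rm = TRUE),
      median_outside_s2 = stats::median(cmp$deltas$outside_s2, na.rm = TRUE)
    )
  })
  do.call(rbind, res)
}

#' Colocalization recovery sweep
#'
#' Generates punctum image pairs over a grid of ground-truth colocalized
#' fractions and recovers each with the full densitometry pipeline at a
#' fixed threshold, reporting the mean estimated overlap fraction of the
#' reference channel per truth level.
#'
#' @param fractions ground-truth colocalized fractions.
#' @param n_seeds image pairs per fraction.
#' @param master_seed seed from which image seeds derive.
#' @param params base [punctum_field_params()]; `coloc_fraction` is
#'   overridden per level (noise defaults to 0 here).
#' @param threshold mask threshold applied to both channels.
#' @return data.frame: `coloc_fraction`, `mean_estimate`, `sd_estimate`.
#' @export
run_coloc_recovery <- function(fractions = c(0, 0.05, 0.15, 0.5, 1),
                               n_seeds = 5, master_seed = 1L,
                               params = punctum_field_params(noise_sd = 0),
                               threshold = 500) {
  res <- lapply(seq_along(fractions), function(fi) {
    p <- params
    p$coloc_fraction <- fractions[fi]
    est <- vapply(seq_len(n_seeds), function(s) {
      pair <- generate_punctum_image_pair(
        p,
        seed = split_seed(master_seed, fi * 1000L + s)
      )
      coloc_densitometry(pair$image_A, pair$image_B, p$pixel_size_nm,
        threshold_a = threshold, threshold_b = threshold
      )$relative_to_b
    }, numeric(1))
    data.frame(
      coloc_fraction = fractions[fi],
      mean_estimate = mean(est), sd_estimate = stats::sd(est)
    )
  })
  do.call(rbind, res)
}
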