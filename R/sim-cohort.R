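#' Home-cage session schedule
#'
#' The standard protocol: 5 days on the initially assigned port (A), an
#' injection at the start of day 0, three 3-day rotations to novel ports
#' (B, C, D), then 5 days back on the original port (A*). Experimental days
#' are counted from the injection: A covers days -5..-1, B days 0..2,
#' C days 3..5, D days 6..8, A* days 9..13, so day 8 is the last D day and
#' day 9 the first A* day.
#'
#' @param n_ports number of water ports in the cage.
#' @return data.frame with columns `session`, `start_day`, `end_day`
#'   (inclusive), of class `session_schedule`.
#' @export
session_schedule <- function(n_ports = 8L) {
  sched <- data.frame(
    session = c("A", "B", "C", "D", "A*"),
    start_day = c(-5L, 0L, 3L, 6L, 9L),
    end_day = c(-1L, 2L, 5L, 8L, 13L),
    stringsAsFactors = FALSE
  )
  attr(sched, "n_ports") <- as.integer(n_ports)
  class(sched) <- c("session_schedule", "data.frame")
  sched
}

#' Cohort parameters for the home-cage learning simulation
#'
#' Within each session, an animal's probability of poking its assigned port
#' follows a saturating-exponential learning curve
#' `p(t) = p_inf - (p_inf - p0_eff) * exp(-t / tau_eff)` (t = days since
#' session start). The per-animal ablation covariate (fraction of the
#' layer-6b input removed) slows learning in novel sessions
#' (`tau_eff = learn_tau * (1 + ablation_slowing * ablation)`) and acts
#' asymmetrically in the return session A*: animals that cannot forget the
#' old port start A* closer to their previously learned performance
#' (`p0_eff = p0 + (p_end_A - p0) * retention`, with
#' `retention = retention_base + (1 - retention_base) * ablation`), so
#' stronger ablation means better immediate A* performance. Non-assigned
#' pokes are spread uniformly over the other ports.
#'
#' @param n_animals animals per group.
#' @param pokes_per_day mean daily nosepoke count (Poisson).
#' @param p0 initial correct-poke probability (default chance, 1/8).
#' @param p_inf asymptotic correct-poke probability (`p0 <= p_inf <= 1`).
#' @param learn_tau_days learning time constant, days.
#' @param ablation_fractions per-animal ablation covariate in `[0, 1]`
#'   (recycled to `n_animals`); the surviving-terminal density is
#'   `1 - ablation`.
#' @param ablation_slowing multiplier strength of the novel-session slowing.
#' @param retention_base A* retention of the old memory at zero ablation.
#' @return a `cohort_params` list.
#' @export
cohort_params <- function(n_animals = 8L, pokes_per_day = 100,
                          p0 = 1 / 8, p_inf = 0.6, learn_tau_days = 1,
                          ablation_fractions = 0,
                          ablation_slowing = 6, retention_base = 0.2) {
  stopifnot(
    n_animals >= 1, pokes_per_day > 0, p0 >= 0, p0 <= p_inf, p_inf <= 1,
    learn_tau_days > 0, all(ablation_fractions >= 0),
    all(ablation_fractions <= 1), retention_base >= 0, retention_base <= 1
  )
  structure(
    list(
      n_animals = as.integer(n_animals), pokes_per_day = pokes_per_day,
      p0 = p0, p_inf = p_inf, learn_tau_days = learn_tau_days,
      ablation_fractions = rep_len(ablation_fractions, n_animals),
      ablation_slowing = ablation_slowing, retention_base = retention_base
    ),
    class = "cohort_params"
  )
}

#' Simulate a multi-animal nosepoke log over the full session schedule
#'
#' @param params a [cohort_params()].
#' @param schedule a [session_schedule()].
#' @param group group label attached to every animal (e.g. "TMP",
#'   "vehicle").
#' @param seed integer seed.
#' @return list with `log` (data.frame: `animal_id`, `timestamp_s`, `port`,
#'   `assigned_port`, `group`; timestamps sorted within animal) and
#'   `ablation` (data.frame: `animal_id`, `ablation_fraction`,
#'   `surviving_density`). Timestamp 0 is the injection (start of day 0).
#' @export
generate_cohort_log <- function(params = cohort_params(),
                                schedule = session_schedule(),
                                group = "TMP", seed = 1L) {
  p <- params
  n_ports <- attr(schedule, "n_ports")
  day_s <- 86400
  rows <- vector("list", 0L)
  for (a in seq_len(p$n_animals)) {
    abl <- p$ablation_fractions[a]
    ports <- with_seed(
      split_seed(seed, 1000L + a),
      sample.int(n_ports, nrow(schedule) - 1L, replace = FALSE)
    )
    # A* reuses the A port
    assigned <- c(ports, ports[1])
    names(assigned) <- schedule$session
    p_end_A <- NA_real_
    animal_rows <- vector("list", nrow(schedule))
    for (s in seq_len(nrow(schedule))) {
      ses <- schedule$session[s]
      days <- schedule$start_day[s]:schedule$end_day[s]
      novel <- ses %in% c("B", "C", "D")
      after_injection <- schedule$start_day[s] >= 0
      tau_eff <- if (novel && after_injection) {
        p$learn_tau_days * (1 + p$ablation_slowing * abl)
      } else {
        p$learn_tau_days
      }
      p0_eff <- if (ses == "A*") {
        retention <- p$retention_base + (1 - p$retention_base) * abl
        p$p0 + (p_end_A - p$p0) * retention
      } else {
        p$p0
      }
      sim <- with_seed(split_seed(seed, 2000L + a * 50L + s), {
        out <- vector("list", length(days))
        for (di in seq_along(days)) {
          t_in <- di - 0.5 # mid-day, days since session start
          p_correct <- p$p_inf - (p$p_inf - p0_eff) * exp(-t_in / tau_eff)
          n_pokes <- stats::rpois(1, p$pokes_per_day)
          if (n_pokes == 0L) next
          correct <- stats::runif(n_pokes) < p_correct
          port <- integer(n_pokes)
          port[correct] <- assigned[ses]
          n_wrong <- sum(!correct)
          if (n_wrong > 0) {
            others <- setdiff(seq_len(n_ports), assigned[ses])
            port[!correct] <- others[sample.int(length(others), n_wrong,
              replace = TRUE
            )]
          }
          ts <- sort(stats::runif(
            n_pokes, days[di] * day_s, (days[di] + 1) * day_s
          ))
          out[[di]] <- data.frame(
            animal_id = a, timestamp_s = ts, port = port,
            assigned_port = assigned[ses], group = group,
            row.names = NULL
          )
        }
        do.call(rbind, out)
      })
      # realized end-of-A performance seeds the A* retention model
      if (ses == "A") {
        p_end_A <- p$p_inf - (p$p_inf - p$p0) *
          exp(-(length(days) - 0.5) / p$learn_tau_days)
      }
      animal_rows[[s]] <- sim
    }
    rows[[a]] <- do.call(rbind, animal_rows)
  }
  log <- do.call(rbind, rows)
  rownames(log) <- NULL
  ablation <- data.frame(
    animal_id = seq_len(p$n_animals),
    ablation_fraction = p$ablation_fractions,
    surviving_density = 1 - p$ablation_fractions
  )
  list(log = log, ablation = ablation, schedule = schedule, group = group)
}
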