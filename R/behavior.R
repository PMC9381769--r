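#' Label nosepoke events with sessions and experimental days
#'
#' Experimental days are 24-h windows anchored at the injection (timestamp
#' 0 = start of day 0); the day index is `floor(timestamp / 86400)`. Each
#' event is tagged with the schedule session covering its day; events
#' outside the schedule get `NA` session and `in_schedule = FALSE`.
#'
#' @param log nosepoke data.frame (`animal_id`, `timestamp_s`, `port`,
#'   `assigned_port`, optionally `group`).
#' @param schedule a [session_schedule()] (non-overlapping sessions).
#' @return the log with added `day` and `session` columns and
#'   `in_schedule` flags.
#' @export
label_sessions <- function(log, schedule = session_schedule()) {
  days <- unlist(Map(seq, schedule$start_day, schedule$end_day))
  if (anyDuplicated(days)) stop("overlapping sessions in schedule")
  day <- floor(log$timestamp_s / 86400)
  ses <- rep(NA_character_, nrow(log))
  for (s in seq_len(nrow(schedule))) {
    sel <- day >= schedule$start_day[s] & day <= schedule$end_day[s]
    ses[sel] <- schedule$session[s]
  }
  log$day <- as.integer(day)
  log$session <- ses
  log$in_schedule <- !is.na(ses)
  log
}

#' Per-animal daily error rate
#'
#' By default the error rate is the fraction of nosepokes at non-assigned
#' ports per experimental day (the internally consistent reading of the
#' error-rate rule); `definition = "literal"` instead returns assigned /
#' total (the success-rate reading). Days with zero pokes are absent from
#' the result.
#'
#' @param log a [label_sessions()]-labelled log.
#' @param definition `"error"` (non-assigned / total) or `"literal"`
#'   (assigned / total).
#' @return data.frame of class `error_rate_series`: `animal_id`, `day`,
#'   `session`, `n_pokes`, `n_assigned`, `error_rate`, plus `group` if
#'   present in the log.
#' @export
daily_error_rate <- function(log, definition = c("error", "literal")) {
  definition <- match.arg(definition)
  if (is.null(log$day)) stop("log must be labelled with label_sessions()")
  log <- log[log$in_schedule, , drop = FALSE]
  key <- interaction(log$animal_id, log$day, drop = TRUE)
  agg <- do.call(rbind, lapply(split(log, key), function(d) {
    n <- nrow(d)
    n_ok <- sum(d$port == d$assigned_port)
    data.frame(
      animal_id = d$animal_id[1], day = d$day[1], session = d$session[1],
      n_pokes = n, n_assigned = n_ok,
      error_rate = if (definition == "error") (n - n_ok) / n else n_ok / n,
      group = if (!is.null(d$group)) d$group[1] else NA_character_
    )
  }))
  agg <- agg[order(agg$animal_id, agg$day), , drop = FALSE]
  rownames(agg) <- NULL
  class(agg) <- c("error_rate_series", "data.frame")
  agg
}

#' Exclude animals that failed the initial learning criterion
#'
#' Keeps animals whose error rate on the last day of the initial learning
#' session (A; day -1 with the standard schedule) is strictly below
#' `threshold`. Animals with no pokes on that day are excluded and flagged.
#'
#' @param series an [daily_error_rate()] result.
#' @param threshold exclusion threshold on the error rate (strict `<`
#'   keeps).
#' @param last_a_day the last day of session A.
#' @return data.frame: `animal_id`, `error_last_a`, `included`, `reason`.
#' @export
apply_exclusion <- function(series, threshold = 0.7, last_a_day = -1L) {
  animals <- sort(unique(series$animal_id))
  res <- lapply(animals, function(a) {
    row <- series[series$animal_id == a & series$day == last_a_day, ,
      drop = FALSE
    ]
    if (nrow(row) == 0L) {
      data.frame(
        animal_id = a, error_last_a = NA_real_, included = FALSE,
        reason = "no pokes on last initial-learning day"
      )
    } else {
      ok <- row$error_rate[1] < threshold
      data.frame(
        animal_id = a, error_last_a = row$error_rate[1], included = ok,
        reason = if (ok) "" else "error rate at or above threshold"
      )
    }
  })
  do.call(rbind, res)
}

#' Group learning curve (daily mean and SEM)
#'
#' Unweighted animal-level mean error rate per experimental day, with the
#' standard error of the mean across animals.
#'
#' @param series an [daily_error_rate()] result.
#' @param group optional group label to filter on (requires a `group`
#'   column).
#' @return data.frame: `day`, `n_animals`, `mean_error`, `sem_error`.
#' @export
group_learning_curve <- function(series, group = NULL) {
  if (!is.null(group)) {
    series <- series[!is.na(series$group) & series$group == group, ,
      drop = FALSE
    ]
  }
  if (length(unique(series$animal_id)) < 2L) {
    stop("need at least 2 animals for a group curve")
  }
  out <- do.call(rbind, lapply(split(series, series$day), function(d) {
    data.frame(
      day = d$day[1], n_animals = nrow(d),
      mean_error = mean(d$error_rate),
      sem_error = stats::sd(d$error_rate) / sqrt(nrow(d))
    )
  }))
  out <- out[order(out$day), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Ablation-versus-performance rank correlations
#'
#' Correlates each animal's surviving-terminal density with its error rate
#' on a late novel-session day and on the familiar-return day, by one-tailed
#' Spearman correlation ([spearman_rank()]). For the novel day the stated
#' direction is negative (less surviving input, higher error); for the
#' familiar-return day it is positive (less surviving input, better
#' retention of the old port, lower error).
#'
#' @param series an [daily_error_rate()] result for the analyzed group.
#' @param ablation_table data.frame with `animal_id` and
#'   `surviving_density` (e.g. from [generate_cohort_log()] or measured
#'   with [coloc_densitometry()]).
#' @param novel_day,familiar_day experimental days to test (defaults 8 and
#'   9: last day of the final novel session and first day after return).
#' @return list `novel` and `familiar`, each a [spearman_rank()] result
#'   plus `day` and the paired values.
#' @export
ablation_performance_analysis <- function(series, ablation_table,
                                          novel_day = 8L, familiar_day = 9L) {
  one_day <- function(day, alternative) {
    sub <- series[series$day == day, , drop = FALSE]
    m <- merge(sub, ablation_table, by = "animal_id")
    if (nrow(m) < 3L) stop("fewer than 3 animals with data on day ", day)
    res <- spearman_rank(m$surviving_density, m$error_rate,
      alternative = alternative
    )
    c(res, list(
      day = day, surviving_density = m$surviving_density,
      error_rate = m$error_rate
    ))
  }
  list(
    novel = one_day(novel_day, "less"),
    familiar = one_day(familiar_day, "greater")
  )
}
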