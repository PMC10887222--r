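# Simulated operator behavior.
#
# Every response-required event receives a response record. A responded
# event carries an engagement interval (onset + latency, for a
# profile-dependent duration, clipped to the event's allowed response
# window); a missed response-required event is an error. SYSM engagement is
# a short notice plus one click; COMM engagement spans listening and radio
# adjustment; RMAN engagement is a sustained valve-management interval whose
# duration follows the block's duty cycle. TRCK and RMAN additionally
# produce out-of-bounds intervals (tracking circle / tank levels) used by the
# error-rate report.

#' Operator behavior profile
#'
#' Defaults produce the low error rates typical of operators who adapt well
#' to the task across all load levels (per-subtask error rates well below
#' 0.15).
#'
#' @param miss_rate Named miss probabilities per subtask (`SYSM`, `COMM`,
#'   `RMAN`).
#' @param latency_mean,latency_sd,latency_min Response-latency model,
#'   seconds (normal, truncated below).
#' @param comm_duration_mean,comm_duration_sd,comm_duration_min COMM
#'   engagement duration, seconds.
#' @param sysm_click_duration SYSM notice-plus-click duration, seconds.
#' @param rman_duty_cycle Named per-block-type fraction of a block's RMAN
#'   inter-event spacing spent actively managing valves.
#' @param trck_out_of_bounds_rate Fraction of ML+HL time the tracking circle
#'   leaves its boundary.
#' @param rman_out_of_bounds_rate Fraction of non-PW time the tank levels
#'   stray out of bounds.
#' @return A `behavior_profile` list.
#' @export
behavior_profile <- function(miss_rate = c(SYSM = 0.05, COMM = 0.07, RMAN = 0.04),
                             latency_mean = 1.2, latency_sd = 0.4, latency_min = 0.25,
                             comm_duration_mean = 4.5, comm_duration_sd = 1.0,
                             comm_duration_min = 1.5,
                             sysm_click_duration = 0.8,
                             rman_duty_cycle = c(PW = 0, LL = 0.2, ML = 0.35, HL = 0.5),
                             trck_out_of_bounds_rate = 0.03,
                             rman_out_of_bounds_rate = 0.03) {
  stopifnot(all(miss_rate >= 0 & miss_rate <= 1),
            all(c("SYSM", "COMM", "RMAN") %in% names(miss_rate)),
            all(c("PW", "LL", "ML", "HL") %in% names(rman_duty_cycle)),
            trck_out_of_bounds_rate >= 0, trck_out_of_bounds_rate <= 1,
            rman_out_of_bounds_rate >= 0, rman_out_of_bounds_rate <= 1)
  structure(list(miss_rate = miss_rate, latency_mean = latency_mean,
                 latency_sd = latency_sd, latency_min = latency_min,
                 comm_duration_mean = comm_duration_mean,
                 comm_duration_sd = comm_duration_sd,
                 comm_duration_min = comm_duration_min,
                 sysm_click_duration = sysm_click_duration,
                 rman_duty_cycle = rman_duty_cycle,
                 trck_out_of_bounds_rate = trck_out_of_bounds_rate,
                 rman_out_of_bounds_rate = rman_out_of_bounds_rate),
            class = "behavior_profile")
}

.rtruncnorm <- function(n, mean, sd, lower) pmax(rnorm(n, mean, sd), lower)

# Scatter a total out-of-bounds duration across an interval as short
# excursions; returns a tibble of [start, end] intervals.
.scatter_oob <- function(total, start, end, mean_len = 2.5) {
  if (total <= 0 || end <= start) {
    return(tibble::tibble(start = numeric(0), end = numeric(0)))
  }
  n <- max(1L, as.integer(round(total / mean_len)))
  len <- rep(total / n, n)
  s <- sort(runif(n, start, end - len[1]))
  tibble::tibble(start = s, end = pmin(s + len, end))
}

#' Simulate operator responses to a scheduled session
#'
#' @param events An `event_log` from [schedule_events()].
#' @param config The `session_config` the events were scheduled for.
#' @param profile A [behavior_profile()].
#' @param rng_seed Integer seed.
#' @return A `response_log` tibble with one row per response-required event:
#'   `event_id`, `subtask`, `onset`, `responded`, `engage_start`,
#'   `engage_end` (NA when missed), `error`, `block_type`. Out-of-bounds
#'   intervals for TRCK/RMAN are attached as the `oob` attribute (tibble:
#'   `subtask`, `start`, `end`).
#' @export
simulate_behavior <- function(events, config, profile = behavior_profile(),
                              rng_seed = 0L) {
  stopifnot(inherits(profile, "behavior_profile"))
  ev <- events[events$requires_response, ]
  bt <- block_table(config)
  with_rng(rng_seed, {
    n <- nrow(ev)
    responded <- rbinom(n, 1, 1 - unname(profile$miss_rate[ev$subtask])) == 1
    latency <- .rtruncnorm(n, profile$latency_mean, profile$latency_sd,
                           profile$latency_min)
    dur <- numeric(n)
    dur[ev$subtask == "SYSM"] <- profile$sysm_click_duration
    idx_c <- ev$subtask == "COMM"
    dur[idx_c] <- .rtruncnorm(sum(idx_c), profile$comm_duration_mean,
                              profile$comm_duration_sd, profile$comm_duration_min)
    idx_r <- which(ev$subtask == "RMAN")
    if (length(idx_r)) {
      # Sustained management: duty cycle x the block's RMAN event spacing.
      n_rman <- table(ev$block_index[idx_r])
      spacing <- bt$duration[ev$block_index[idx_r]] /
        as.numeric(n_rman[as.character(ev$block_index[idx_r])])
      dur[idx_r] <- profile$rman_duty_cycle[ev$block_type[idx_r]] * spacing
    }
    start <- ev$onset + latency
    end <- pmin(start + dur, ev$onset + ev$nominal_duration)
    # Clip to the response window; a response must start inside it.
    start <- pmin(start, ev$onset + ev$nominal_duration)
    out <- tibble::tibble(
      event_id = ev$event_id, subtask = ev$subtask, onset = ev$onset,
      responded = responded,
      engage_start = ifelse(responded, start, NA_real_),
      engage_end = ifelse(responded, end, NA_real_),
      error = !responded,
      block_index = ev$block_index, block_type = ev$block_type)

    # Out-of-bounds excursions for the time-fraction error definitions.
    mlhl <- bt[bt$block_type %in% c("ML", "HL"), ]
    nonpw <- bt[bt$block_type != "PW", ]
    oob <- list()
    for (i in seq_len(nrow(mlhl))) {
      tot <- profile$trck_out_of_bounds_rate * mlhl$duration[i] *
        runif(1, 0.5, 1.5)
      o <- .scatter_oob(tot, mlhl$start[i], mlhl$end[i])
      if (nrow(o)) oob[[length(oob) + 1]] <- tibble::tibble(subtask = "TRCK", o)
    }
    for (i in seq_len(nrow(nonpw))) {
      tot <- profile$rman_out_of_bounds_rate * nonpw$duration[i] *
        runif(1, 0.5, 1.5)
      o <- .scatter_oob(tot, nonpw$start[i], nonpw$end[i])
      if (nrow(o)) oob[[length(oob) + 1]] <- tibble::tibble(subtask = "RMAN", o)
    }
    oob <- if (length(oob)) do.call(rbind, oob) else
      tibble::tibble(subtask = character(0), start = numeric(0), end = numeric(0))
    attr(out, "oob") <- oob
    attr(out, "session_id") <- config$session_id
    attr(out, "subject_id") <- config$subject_id
    class(out) <- c("response_log", class(out))
    out
  })
}

#' Engagement intervals from a response log
#'
#' @param responses A `response_log`.
#' @param subtask Optional subtask filter.
#' @return Tibble of `subtask`, `start`, `end` for responded events.
#' @export
engagement_intervals <- function(responses, subtask = NULL) {
  r <- responses[responses$responded, ]
  out <- tibble::tibble(subtask = r$subtask, start = r$engage_start,
                        end = r$engage_end, onset = r$onset)
  if (!is.null(subtask)) out <- out[out$subtask %in% subtask, ]
  out
}
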