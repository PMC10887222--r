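# Subtask event scheduling.
#
# Per-block-type demand rates follow the MATB-II study protocol: per 5-minute
# block, SYSM anomalies 10/10/20, response-required COMM calls 6/10/14 and
# RMAN demands 5/10/20 for LL/ML/HL; PW blocks are frozen (no events); TRCK
# is off in PW/LL and active (faster in HL) as a continuous subtask with no
# discrete events. 150 s blocks carry half the 5-minute counts, rounded
# half-up.

#' Per-block-type subtask demand rates
#'
#' Counts are events per 300 s block; 150 s blocks receive half the count,
#' rounded half-up. `trck_speed` is `"off"`, `"normal"` (ML) or `"fast"`
#' (HL); tracking produces no discrete events.
#'
#' @return A `block_rates` object: one row per block type with columns
#'   `sysm_count`, `comm_count`, `rman_count`, `trck_speed`.
#' @export
default_block_rates <- function() {
  x <- tibble::tibble(
    block_type = TL_LEVELS,
    sysm_count = c(0L, 10L, 10L, 20L),
    comm_count = c(0L, 6L, 10L, 14L),
    rman_count = c(0L, 5L, 10L, 20L),
    trck_speed = c("off", "off", "normal", "fast")
  )
  structure(x, class = c("block_rates", class(x)))
}

validate_block_rates <- function(rates) {
  ref <- default_block_rates()
  cols <- c("sysm_count", "comm_count", "rman_count")
  if (!identical(as.data.frame(rates[, c("block_type", cols, "trck_speed")]),
                 as.data.frame(ref[, c("block_type", cols, "trck_speed")]))) {
    stop("block rates must match the protocol table ",
         "(SYSM 10/10/20, COMM 6/10/14, RMAN 5/10/20 for LL/ML/HL; PW empty)")
  }
  invisible(rates)
}

# Half-up rounding for 150 s blocks (2.5 -> 3).
round_half_up <- function(x) floor(x + 0.5)

scale_count <- function(count_300, duration) {
  if (duration == 300) return(as.integer(count_300))
  as.integer(round_half_up(count_300 * duration / 300))
}

# Nominal stimulus durations / allowed response windows, seconds.
EVENT_WINDOWS <- c(SYSM = 10, COMM = 12, RMAN = 15)

# Jittered-uniform placement of n onsets inside [start, end), keeping a
# minimum inter-event gap: each event owns an equal slot and is jittered
# within the slack the gap leaves.
.place_events <- function(n, start, end, min_gap) {
  if (n == 0) return(numeric(0))
  slot <- (end - start) / n
  if (slot < min_gap) {
    stop(sprintf("block of %.0f s too short for %d events at a %.0f s minimum gap",
                 end - start, n, min_gap))
  }
  slack <- (slot - min_gap) / 2
  centers <- start + (seq_len(n) - 0.5) * slot
  sort(centers + runif(n, -slack, slack))
}

#' Schedule subtask events over a session
#'
#' Places SYSM/COMM/RMAN events block by block according to the demand-rate
#' table: exact protocol counts in 300 s blocks, half (rounded half-up) in
#' 150 s blocks, none in PW. Events are placed on a jittered-uniform grid
#' with a minimum inter-event gap per subtask. COMM additionally receives
#' distractor calls (other-callsign audio that must be ignored) at
#' `distractor_ratio` per response-required call; distractors are not part of
#' the protocol counts and have `requires_response = FALSE`.
#'
#' @param config A `session_config`.
#' @param rates A `block_rates` table (must equal [default_block_rates()]).
#' @param rng_seed Integer seed; the schedule is a pure function of it.
#' @param min_gap Minimum spacing between events of one subtask, seconds.
#' @param distractor_ratio Distractor COMM calls per own-callsign call.
#' @return An `event_log` tibble: `subtask`, `onset`, `nominal_duration`,
#'   `requires_response`, `block_index`, `block_type`, plus session metadata
#'   in attributes.
#' @export
schedule_events <- function(config, rates = default_block_rates(), rng_seed = 0L,
                            min_gap = 5, distractor_ratio = 0.5) {
  validate_block_rates(rates)
  bt <- block_table(config)
  with_rng(rng_seed, {
    rows <- list()
    for (i in seq_len(nrow(bt))) {
      ty <- bt$block_type[i]
      if (ty == "PW") next
      r <- rates[rates$block_type == ty, ]
      for (task in c("SYSM", "COMM", "RMAN")) {
        n <- scale_count(r[[paste0(tolower(task), "_count")]], bt$duration[i])
        n_extra <- if (task == "COMM") floor(n * distractor_ratio) else 0L
        onsets <- .place_events(n + n_extra, bt$start[i], bt$end[i], min_gap)
        req <- rep(TRUE, n + n_extra)
        if (n_extra > 0) req[sample.int(n + n_extra, n_extra)] <- FALSE
        if (n + n_extra > 0) {
          rows[[length(rows) + 1]] <- tibble::tibble(
            subtask = task, onset = onsets,
            nominal_duration = unname(EVENT_WINDOWS[task]),
            requires_response = req,
            block_index = bt$block_index[i], block_type = ty)
        }
      }
    }
    ev <- do.call(rbind, rows)
    ev <- ev[order(ev$onset), ]
    ev$event_id <- seq_len(nrow(ev))
    attr(ev, "session_id") <- config$session_id
    attr(ev, "subject_id") <- config$subject_id
    class(ev) <- c("event_log", class(ev))
    ev
  })
}

#' Count response-required events by block type and subtask
#' @param events An `event_log`.
#' @return A tibble of counts.
#' @export
event_counts <- function(events) {
  ev <- events[events$requires_response, ]
  out <- as.data.frame(table(block_type = ev$block_type, subtask = ev$subtask))
  tibble::as_tibble(out)
}
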