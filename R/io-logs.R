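# Text formats for event/response logs (TSV), NASA-TLX tables (CSV) and the
# study manifest (JSON). The TSV schema is a documented stand-in for the
# MATB-II program's own log dialect: one row per scheduled event carrying the
# simulated response alongside it.

LOG_COLUMNS <- c("timestamp_s", "subtask", "event_type", "requires_response",
                 "responded", "engage_start_s", "engage_end_s", "error")

#' Write event + response logs as one TSV
#'
#' One row per scheduled event (stimulus rows joined with their response
#' fields) followed by out-of-bounds interval rows (`event_type = "oob"`).
#' Timestamps are seconds from session start at millisecond precision.
#'
#' @param events An `event_log`.
#' @param responses The matching `response_log`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_logs <- function(events, responses, path) {
  m <- match(events$event_id, responses$event_id)
  df <- data.frame(
    timestamp_s = sprintf("%.3f", events$onset),
    subtask = events$subtask,
    event_type = "stimulus",
    requires_response = events$requires_response,
    responded = ifelse(is.na(m), NA, responses$responded[m]),
    engage_start_s = ifelse(is.na(m) | is.na(responses$engage_start[m]), "",
                            sprintf("%.3f", responses$engage_start[m])),
    engage_end_s = ifelse(is.na(m) | is.na(responses$engage_end[m]), "",
                          sprintf("%.3f", responses$engage_end[m])),
    error = ifelse(is.na(m), NA, responses$error[m]))
  oob <- attr(responses, "oob")
  if (!is.null(oob) && nrow(oob)) {
    df <- rbind(df, data.frame(
      timestamp_s = sprintf("%.3f", oob$start), subtask = oob$subtask,
      event_type = "oob", requires_response = FALSE, responded = NA,
      engage_start_s = sprintf("%.3f", oob$start),
      engage_end_s = sprintf("%.3f", oob$end), error = TRUE))
  }
  df <- df[order(as.numeric(df$timestamp_s)), ]
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a TSV session log
#'
#' Rows with non-monotone timestamps are stably sorted with a warning;
#' unknown subtask tokens are an error naming the offending row.
#'
#' @param path TSV path written by [write_logs()].
#' @return A tibble with the logged columns; numeric timestamps in seconds.
#' @export
read_logs <- function(path) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  if (!all(LOG_COLUMNS %in% names(df))) {
    stop("log file lacks required columns: ",
         paste(setdiff(LOG_COLUMNS, names(df)), collapse = ", "))
  }
  bad <- which(!df$subtask %in% SUBTASKS)
  if (length(bad)) {
    stop(sprintf("unknown subtask '%s' in log row %d", df$subtask[bad[1]], bad[1]))
  }
  df$timestamp_s <- as.numeric(df$timestamp_s)
  df$engage_start_s <- suppressWarnings(as.numeric(df$engage_start_s))
  df$engage_end_s <- suppressWarnings(as.numeric(df$engage_end_s))
  if (is.unsorted(df$timestamp_s)) {
    warning("log timestamps are not monotone; applying a stable sort")
    df <- df[order(df$timestamp_s), ]
  }
  tibble::as_tibble(df)
}

#' Write / read a NASA-TLX table as CSV
#'
#' Reading validates every variable to be an integer in 1-100.
#'
#' @param tlx Tibble from [generate_tlx()] (possibly row-bound over sessions).
#' @param path CSV path.
#' @return `path` invisibly (write); a validated tibble (read).
#' @export
write_tlx <- function(tlx, path) {
  utils::write.csv(tlx, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_tlx
#' @export
read_tlx <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (v in TLX_VARIABLES) {
    if (!v %in% names(df)) stop("TLX table lacks column ", v)
    x <- df[[v]]
    if (any(!is.finite(x)) || any(x != round(x)) || any(x < 1 | x > 100)) {
      stop(sprintf("TLX variable '%s' outside the integer 1-100 scale", v))
    }
    df[[v]] <- as.integer(x)
  }
  tibble::as_tibble(df)
}

#' Write / read the study manifest as JSON
#'
#' @param manifest Manifest tibble from [generate_study()].
#' @param path JSON path.
#' @return `path` invisibly (write); a tibble (read).
#' @export
write_manifest <- function(manifest, path) {
  jsonlite::write_json(manifest, path, dataframe = "rows", auto_unbox = TRUE,
                       pretty = TRUE, na = "null")
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  tibble::as_tibble(jsonlite::fromJSON(path))
}
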