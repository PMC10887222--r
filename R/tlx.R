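# NASA-TLX simulation.
#
# Six variables (mental demand, physical demand, temporal demand,
# performance, effort, frustration) on an integer 1-100 scale, one
# administration per TLX point of a session. Class means for the four
# workload-relevant variables are ordered LL < ML < HL with default gaps of
# about 12 (low vs medium) and 6 (medium vs high) points.

TLX_VARIABLES <- c("mental_demand", "physical_demand", "temporal_demand",
                   "performance", "effort", "frustration")

#' Default per-block-type NASA-TLX means
#'
#' Rows are block types (`LL`, `ML`, `HL`), columns the six TLX variables.
#' Workload-relevant variables rise with the task load (gaps of roughly 12
#' points between low and medium and 6 between medium and high); physical
#' demand and (inverted) performance stay nearly flat, since the task is
#' designed to vary mental rather than physical load.
#'
#' @return A 3 x 6 numeric matrix with dimnames.
#' @export
default_tlx_means <- function() {
  m <- rbind(
    LL = c(mental_demand = 30, physical_demand = 12, temporal_demand = 28,
           performance = 25, effort = 32, frustration = 20),
    ML = c(mental_demand = 42, physical_demand = 14, temporal_demand = 40,
           performance = 28, effort = 44, frustration = 32),
    HL = c(mental_demand = 48, physical_demand = 16, temporal_demand = 46,
           performance = 30, effort = 50, frustration = 38))
  m
}

#' Generate NASA-TLX responses for a session
#'
#' One six-variable response per TLX administration point. Scores are drawn
#' around the block type's class means with Gaussian noise, rounded, and
#' clipped to the integer scale 1-100.
#'
#' @param config A `session_config`.
#' @param class_means Matrix as in [default_tlx_means()]; rows must cover the
#'   block types at the session's TLX points.
#' @param noise_sd Score noise standard deviation (points).
#' @param rng_seed Integer seed.
#' @return A tibble with `subject_id`, `session_id`, `block_index`,
#'   `block_type` and the six variable columns (integers in 1-100).
#' @export
generate_tlx <- function(config, class_means = default_tlx_means(),
                         noise_sd = 10, rng_seed = 0L) {
  if (!all(is.finite(class_means))) stop("class means must be finite")
  bt <- block_table(config)
  pts <- config$tlx_points
  types <- bt$block_type[pts]
  if (!all(types %in% rownames(class_means))) {
    stop("class_means lacks a row for a TLX block type")
  }
  with_rng(rng_seed, {
    scores <- class_means[types, TLX_VARIABLES, drop = FALSE] +
      matrix(rnorm(length(pts) * length(TLX_VARIABLES), 0, noise_sd),
             nrow = length(pts))
    scores <- pmin(pmax(round(scores), 1), 100)
    out <- tibble::tibble(subject_id = config$subject_id,
                          session_id = config$session_id,
                          block_index = as.integer(pts), block_type = types)
    for (j in seq_along(TLX_VARIABLES)) out[[TLX_VARIABLES[j]]] <- as.integer(scores[, j])
    out
  })
}
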