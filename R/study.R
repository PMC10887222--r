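# Whole-study generation: subjects x sessions, arrangement ids cycled over
# the four block orders, with a manifest linking every artifact.

#' Generate a complete synthetic study
#'
#' Produces `n_subjects x sessions_per_subject` sessions. Arrangement ids
#' cycle over the four block orders so consecutive sessions of one subject
#' use different arrangements. EEG synthesis is the expensive part and can
#' be disabled (`make_eeg = FALSE`) when only the protocol, logs and ratings
#' are needed (for example, segment-count arithmetic); recordings can also be
#' written straight to EDF via `out_dir` instead of being kept in memory.
#'
#' @param n_subjects Number of subjects (>= 1).
#' @param sessions_per_subject Sessions per subject (default 2).
#' @param protocol `"full"` (51-minute sessions) or `"mini"` (12-minute
#'   validation-scale sessions).
#' @param eeg_params [eeg_gen_params()] used for every recording.
#' @param profile [behavior_profile()] used for every session. In confusable
#'   mode (`eeg_params$ml_hl_confusable`), the RMAN duty cycle and miss rates
#'   of ML and HL are equalized so the two classes differ only in event
#'   counts.
#' @param tlx_means,tlx_noise_sd Passed to [generate_tlx()].
#' @param make_eeg Synthesize recordings? (`FALSE` keeps the study light.)
#' @param out_dir If given, recordings are written as EDF (and logs/TLX as
#'   TSV/CSV) under this directory and not kept in memory.
#' @param rng_seed Integer master seed; every per-session stream is derived
#'   from it.
#' @return A `study_bundle`: list with `manifest` (tibble), `configs`,
#'   `events`, `responses`, `tlx` (tibble over all sessions) and, when
#'   requested, `recordings`.
#' @export
generate_study <- function(n_subjects, sessions_per_subject = 2,
                           protocol = c("full", "mini"),
                           eeg_params = eeg_gen_params(),
                           profile = behavior_profile(),
                           tlx_means = default_tlx_means(), tlx_noise_sd = 10,
                           make_eeg = FALSE, out_dir = NULL, rng_seed = 0L) {
  if (!is.numeric(n_subjects) || n_subjects < 1) stop("n_subjects must be >= 1")
  protocol <- match.arg(protocol)
  gen_cfg <- switch(protocol, full = generate_session_config,
                    mini = generate_mini_session_config)
  if (isTRUE(eeg_params$ml_hl_confusable)) {
    profile$rman_duty_cycle[c("ML", "HL")] <- mean(profile$rman_duty_cycle[c("ML", "HL")])
  }
  if (!is.null(out_dir)) dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  manifest <- list(); configs <- list(); events <- list()
  responses <- list(); tlx <- list(); recordings <- list()
  k <- 0L
  for (s in seq_len(n_subjects)) {
    subject_id <- sprintf("S%02d", s)
    for (r in seq_len(sessions_per_subject)) {
      k <- k + 1L
      session_id <- sprintf("%s_R%d", subject_id, r)
      config_id <- ((k - 1L) %% 4L) + 1L
      seed_s <- child_seed(rng_seed, k)
      cfg <- gen_cfg(config_id, subject_id, session_id, seed_s)
      ev <- schedule_events(cfg, rng_seed = seed_s)
      rs <- simulate_behavior(ev, cfg, profile, rng_seed = child_seed(seed_s, 1))
      tl <- generate_tlx(cfg, tlx_means, tlx_noise_sd,
                         rng_seed = child_seed(seed_s, 2))
      configs[[session_id]] <- cfg
      events[[session_id]] <- ev
      responses[[session_id]] <- rs
      tlx[[session_id]] <- tl
      edf_path <- NA_character_
      if (make_eeg) {
        rec <- synthesize_eeg(cfg, ev, rs, eeg_params,
                              rng_seed = child_seed(seed_s, 3))
        if (!is.null(out_dir)) {
          edf_path <- file.path(out_dir, paste0(session_id, ".edf"))
          write_edf(rec, edf_path)
        } else {
          recordings[[session_id]] <- rec
        }
      }
      if (!is.null(out_dir)) {
        write_logs(ev, rs, file.path(out_dir, paste0(session_id, "_log.tsv")))
        write_tlx(tl, file.path(out_dir, paste0(session_id, "_tlx.csv")))
      }
      manifest[[k]] <- tibble::tibble(
        subject_id = subject_id, session_id = session_id,
        config_id = config_id, protocol = protocol,
        duration_s = session_duration(cfg), session_seed = seed_s,
        edf_path = edf_path)
    }
  }
  manifest <- do.call(rbind, manifest)
  if (!is.null(out_dir)) {
    write_manifest(manifest, file.path(out_dir, "manifest.json"))
  }
  bundle <- list(manifest = manifest, configs = configs, events = events,
                 responses = responses, tlx = do.call(rbind, tlx))
  if (make_eeg && is.null(out_dir)) bundle$recordings <- recordings
  structure(bundle, class = "study_bundle")
}

#' @export
print.study_bundle <- function(x, ...) {
  cat(sprintf("<study_bundle> %d sessions (%d subjects), protocol '%s'%s\n",
              nrow(x$manifest), length(unique(x$manifest$subject_id)),
              x$manifest$protocol[1],
              if (!is.null(x$recordings)) ", with EEG" else ""))
  invisible(x)
}
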