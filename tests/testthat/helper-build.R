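# In-code fixture builders: canonical rows with sensible defaults.

T0 <- as.POSIXct("2021-03-01 00:00:00", tz = "UTC")

make_epoch <- function(epoch_id = "E1", patient_id = "P1",
                       start = T0, end = T0 + 10 * 86400,
                       enabled_patterns = "A1;A2;B1;B2",
                       daily_therapy_limit = 1000L,
                       long_episode_threshold_s = 30,
                       stimulation_enabled = TRUE) {
  tibble::tibble(epoch_id = epoch_id, patient_id = patient_id,
                 start = start, end = end,
                 enabled_patterns = enabled_patterns,
                 daily_therapy_limit = daily_therapy_limit,
                 long_episode_threshold_s = long_episode_threshold_s,
                 stimulation_enabled = stimulation_enabled)
}

make_recording <- function(recording_id = "R1", epoch_id = "E1",
                           patient_id = "P1",
                           trigger_type = "PATTERN", pattern = "A1",
                           episode_class = "EPISODE",
                           eip_present = TRUE, eip_onset_s = 10,
                           first_detection_s = 12.5,
                           in_progress = FALSE,
                           start_time = T0 + 3600,
                           duration_s = 90) {
  triggered <- trigger_type == "PATTERN"
  tibble::tibble(
    recording_id = recording_id, patient_id = patient_id,
    epoch_id = epoch_id, trigger_type = trigger_type,
    start_time = start_time, duration_s = duration_s,
    has_first_episode = triggered,
    fe_onset_s = if (triggered) eip_onset_s else NA_real_,
    fe_triggering_pattern = if (triggered) pattern else NA_character_,
    fe_episode_class = if (triggered) episode_class else NA_character_,
    fe_in_progress_at_start = if (triggered) in_progress else NA,
    fe_first_detection_s = if (triggered) first_detection_s else NA_real_,
    fe_therapy_times_s = NA_character_,
    eip_present = eip_present,
    eip_onset_s = if (eip_present) eip_onset_s else NA_real_,
    laterality = if (eip_present) "LEFT" else NA_character_
  )
}

make_hist_day <- function(date = as.Date("2021-03-01"), patient_id = "P1",
                          a1 = 0L, a2 = 0L, b1 = 0L, b2 = 0L,
                          episodes = NULL, long_episodes = 0L,
                          therapies = 0L, saturations = 0L, magnets = 0L,
                          missing = FALSE) {
  if (is.null(episodes)) episodes <- a1 + a2 + b1 + b2 - long_episodes
  tibble::tibble(patient_id = patient_id, date = date,
                 a1_count = as.integer(a1), a2_count = as.integer(a2),
                 b1_count = as.integer(b1), b2_count = as.integer(b2),
                 episode_count = as.integer(episodes),
                 long_episode_count = as.integer(long_episodes),
                 therapy_count = as.integer(therapies),
                 saturation_count = as.integer(saturations),
                 magnet_count = as.integer(magnets),
                 histogram_data_missing = missing,
                 diagnostic_data_missing = FALSE)
}

# a batch of recordings realizing given per-stratum TP/FP counts plus pooled
# negatives; returns the recordings tibble
make_confusion_recordings <- function(counts, tn = 0, fn = 0,
                                      epoch_id = "E1", patient_id = "P1") {
  n_pos <- counts$tp + counts$fp
  pattern <- rep(counts$pattern, n_pos)
  class_ <- rep(counts$episode_class, n_pos)
  eip <- unlist(purrr::map2(counts$tp, counts$fp,
                            function(a, b) c(rep(TRUE, a), rep(FALSE, b))))
  eip <- c(eip, rep(FALSE, tn), rep(TRUE, fn))
  n_trig <- length(pattern)
  n <- n_trig + tn + fn
  if (n == 0) return(make_recording()[0, ])
  triggered <- seq_len(n) <= n_trig
  tibble::tibble(
    recording_id = sprintf("R%03d", seq_len(n)),
    patient_id = patient_id, epoch_id = epoch_id,
    trigger_type = ifelse(triggered, "PATTERN", "SCHEDULED"),
    start_time = T0 + 3600 + seq_len(n),
    duration_s = 90,
    has_first_episode = triggered,
    fe_onset_s = ifelse(triggered, 10, NA_real_),
    fe_triggering_pattern = c(pattern, rep(NA_character_, tn + fn)),
    fe_episode_class = c(class_, rep(NA_character_, tn + fn)),
    fe_in_progress_at_start = ifelse(triggered, FALSE, NA),
    fe_first_detection_s = ifelse(triggered, 12.5, NA_real_),
    fe_therapy_times_s = NA_character_,
    eip_present = eip,
    eip_onset_s = ifelse(eip, ifelse(triggered, 10, 5), NA_real_),
    laterality = ifelse(eip, "LEFT", NA_character_)
  )
}

`%||%` <- function(x, y) if (is.null(x) || length(x) == 0 || is.na(x)) y else x

# hand-constructed ground-truth stream for storage-constraint tests
make_truth <- function(cfg, events) {
  ev <- events
  if (is.null(ev[["day"]])) ev$day <- as.integer(floor(ev$time_s / 86400))
  if (is.null(ev[["time_d"]])) ev$time_d <- ev$time_s / 86400
  for (col in c("eip", "in_progress")) if (is.null(ev[[col]])) ev[[col]] <- FALSE
  if (is.null(ev[["latency_s"]])) ev$latency_s <- NA_real_
  if (is.null(ev[["therapies"]])) ev$therapies <- 0L
  if (is.null(ev[["episode_class"]])) ev$episode_class <-
      ifelse(!is.na(ev$pattern), "EPISODE", NA_character_)
  epochs <- rnsmetrics:::build_epochs(cfg)
  ev$epoch_id <- epochs$epoch_id[1]
  structure(list(config = cfg, events = ev, epochs = epochs),
            class = "rns_truth")
}

# brute-force null of the signed-rank statistic: all 2^n sign assignments
enumerate_signed_rank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w_all <- as.vector(signs %*% r)
  min(1, 2 * min(mean(w_all <= w_obs + 1e-9), mean(w_all >= w_obs - 1e-9)))
}

new_dataset_for_validation <- function() {
  rnsmetrics:::new_rns_dataset(list(
    epochs = make_epoch(),
    recordings = make_recording(),
    histogram_daily = make_hist_day(a1 = 3, episodes = 3)
  ))
}

# detection event shorthand for make_truth
det_events <- function(times_s, pattern = "A1", eip = TRUE) {
  tibble::tibble(time_s = times_s, kind = ifelse(eip, "EIP", "INTERICTAL"),
                 eip = eip, pattern = pattern)
}
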