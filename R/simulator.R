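# Closed-loop device simulator.
#
# Generates a ground-truth event stream for one simulated patient (an EIP
# point process with optional multidien modulation, a background interictal
# process carrying per-Pattern false triggers, scheduled and magnet
# recordings, saturations, therapy delivery under a daily limit) and then
# degrades it through the device's documented storage constraints: 4-slot
# ECoG storage with trigger-type slot reservation and oldest-first
# overwriting, ~700-entry Event List truncation per interrogation interval,
# and 255-events/hour histogram saturation. The pre-constraint recording
# stream defines the known true detector performance that the weighted
# method is meant to recover.

#' Simulation configuration
#'
#' Builds and validates the configuration for one simulated patient. All
#' randomness flows from `seed`; identical configurations produce identical
#' datasets.
#'
#' @param seed Integer seed (mandatory).
#' @param duration_days Length of the simulated record, days.
#' @param n_epochs Number of equal-length programming epochs (settings are
#'   held constant; epochs differ only by sampling).
#' @param eip_rate_per_day Mean electrographic-ictal-pattern rate, events/day.
#' @param multidien_period_days,multidien_amplitude Sinusoidal modulation of
#'   the EIP rate (amplitude in `[0, 1)`; 0 disables).
#' @param interictal_rate_per_day Background interictal-activity rate; the
#'   per-Pattern false triggers are thinned from this process, so the
#'   detector false-trigger rates must sum to at most this value.
#' @param detectors Named list (`A1`, `A2`, `B1`, `B2`) of
#'   `list(p_detect_eip =, false_trigger_rate_per_day =)`. Patterns are tried
#'   in configured order; the first that fires triggers the episode.
#' @param long_episode_prob Probability a triggered episode exceeds the
#'   long-episode threshold.
#' @param therapies_per_episode_probs Probabilities that a triggered episode
#'   receives 1, 2, ... therapies (one per configured therapy slot).
#' @param daily_therapy_limit Maximum therapies per calendar day.
#' @param interrogation_interval_hours Mean hours between patient
#'   interrogations (lognormal with a heavy right tail).
#' @param scheduled_recordings_per_day Scheduled ECoG stores per day (evenly
#'   spaced clock times).
#' @param magnet_rate_per_day,saturation_rate_per_day Poisson rates.
#' @param eip_state_window_hours,magnet_state_window_hours Persistence
#'   windows governing how often an undetected EIP is captured by a scheduled
#'   or magnet recording (capture probability `1 - exp(-rate_missed * w)`).
#' @param ecog_slots ECoG storage slots (use `Inf` for unlimited storage).
#' @param slot_reservation Named integer vector reserving slots per trigger
#'   class (`PATTERN_A`, `PATTERN_B`, `PATTERN`, `SCHEDULED`, `MAGNET`);
#'   unreserved slots form a shared pool.
#' @param event_list_capacity Event List entries retained per interrogation
#'   interval (oldest kept, newer lost).
#' @param hourly_histogram_cap Histogram saturation point, events per hour.
#' @param annotation_noise Probability a reviewer annotation is flipped.
#' @param latency_shape,latency_scale,latency_shift_s Detector latency is
#'   `rgamma(shape, scale) - shift` seconds (a small negative mass is legal:
#'   stimulation can precede the annotated onset).
#' @param pre_trigger_s,recording_duration_s ECoG buffer layout, seconds.
#' @param long_episode_threshold_s Episode duration threshold, seconds.
#' @param daily_therapy_limit Programmable therapies per 24 h.
#' @param stimulation_enabled Whether therapy delivery is on.
#' @param bursts Burst-configuration tibble (canonical `bursts` schema minus
#'   `epoch_id`); default is a bilateral two-therapy montage.
#' @param seizure_reporting_rate Probability a true EIP appears in the
#'   patient's monthly seizure report.
#' @param patient_id Identifier; default derived from the seed.
#' @param start First timestamp of the record (UTC).
#' @return An `rns_sim_config` list.
#' @export
simulation_config <- function(seed,
                              duration_days = 90,
                              n_epochs = 3L,
                              eip_rate_per_day = 8,
                              multidien_period_days = 20,
                              multidien_amplitude = 0.3,
                              interictal_rate_per_day = 20,
                              detectors = default_detectors(),
                              long_episode_prob = 0.2,
                              therapies_per_episode_probs = c(0.9, 0.1),
                              daily_therapy_limit = 2000L,
                              interrogation_interval_hours = 30.3,
                              scheduled_recordings_per_day = 2L,
                              magnet_rate_per_day = 0.5,
                              saturation_rate_per_day = 1,
                              eip_state_window_hours = 2,
                              magnet_state_window_hours = 6,
                              ecog_slots = 4,
                              slot_reservation = c(PATTERN_A = 1L, PATTERN_B = 1L,
                                                   SCHEDULED = 1L, MAGNET = 1L),
                              event_list_capacity = 700,
                              hourly_histogram_cap = 255,
                              annotation_noise = 0,
                              latency_shape = 2,
                              latency_scale = 1.25,
                              latency_shift_s = 0.5,
                              pre_trigger_s = 30,
                              recording_duration_s = 90,
                              long_episode_threshold_s = 30,
                              stimulation_enabled = TRUE,
                              bursts = default_bursts(),
                              seizure_reporting_rate = 0.25,
                              patient_id = NULL,
                              start = as.POSIXct("2020-01-01 00:00:00", tz = "UTC")) {
  if (missing(seed) || is.null(seed) || is.na(seed)) abort("seed is mandatory")
  seed <- as.integer(seed)
  cfg <- as.list(environment())
  if (is.null(cfg$patient_id)) cfg$patient_id <- sprintf("SIM%05d", seed %% 100000L)
  stopifnot(duration_days > 0, n_epochs >= 1, eip_rate_per_day > 0,
            interictal_rate_per_day >= 0,
            multidien_amplitude >= 0, multidien_amplitude < 1,
            long_episode_prob >= 0, long_episode_prob <= 1,
            annotation_noise >= 0, annotation_noise <= 1,
            seizure_reporting_rate >= 0, seizure_reporting_rate <= 1)
  if (!all(names(detectors) %in% PATTERN_LEVELS) || length(detectors) < 1) {
    abort("detectors must be named by Pattern (A1, A2, B1, B2)")
  }
  for (d in detectors) {
    if (d$p_detect_eip < 0 || d$p_detect_eip > 1 || d$false_trigger_rate_per_day < 0) {
      abort("detector parameters out of range")
    }
  }
  ft_total <- sum(map_dbl(detectors, "false_trigger_rate_per_day"))
  if (ft_total > interictal_rate_per_day + 1e-9) {
    abort("sum of false_trigger_rate_per_day exceeds interictal_rate_per_day")
  }
  if (is.finite(ecog_slots) && sum(slot_reservation) > ecog_slots) {
    abort("slot_reservation exceeds ecog_slots")
  }
  if (abs(sum(therapies_per_episode_probs) - 1) > 1e-9) {
    cfg$therapies_per_episode_probs <-
      therapies_per_episode_probs / sum(therapies_per_episode_probs)
  }
  structure(cfg, class = "rns_sim_config")
}

#' Default per-Pattern detector parameters (heterogeneous)
#' @return Named list of detector parameter lists.
#' @export
default_detectors <- function() {
  list(
    A1 = list(p_detect_eip = 0.35, false_trigger_rate_per_day = 2),
    A2 = list(p_detect_eip = 0.15, false_trigger_rate_per_day = 1),
    B1 = list(p_detect_eip = 0.25, false_trigger_rate_per_day = 1.5),
    B2 = list(p_detect_eip = 0.10, false_trigger_rate_per_day = 0.5)
  )
}

#' Default bilateral burst configuration
#'
#' Two therapy slots, each with one left- and one right-hemisphere burst
#' (2 mA, 160 us, 125 Hz, 100 ms, 0.8 cm^2).
#' @return Tibble in the canonical `bursts` schema without `epoch_id`.
#' @export
default_bursts <- function() {
  tidyr::expand_grid(therapy_index = 1:2, burst_index = 1:2) |>
    mutate(current_ma = 2, pulse_width_us = 160, frequency_hz = 125,
           duration_ms = 100,
           cathode_electrodes = ifelse(.data$burst_index == 1, "1;2", "5;6"),
           anode_electrodes = ifelse(.data$burst_index == 1, "3;4", "7;8"),
           electrode_area_cm2 = 0.8,
           hemisphere = ifelse(.data$burst_index == 1, "LEFT", "RIGHT"))
}

# inhomogeneous Poisson times (days) by thinning
sample_eip_times <- function(cfg) {
  rate <- cfg$eip_rate_per_day
  amp <- cfg$multidien_amplitude
  lambda_max <- rate * (1 + amp)
  n <- rpois(1, lambda_max * cfg$duration_days)
  if (n == 0) return(numeric())
  t <- sort(runif(n, 0, cfg$duration_days))
  if (amp > 0) {
    accept <- runif(n) <
      (1 + amp * sin(2 * pi * t / cfg$multidien_period_days)) / (1 + amp)
    t <- t[accept]
  }
  t
}

#' Simulate the ground-truth event stream
#'
#' @param cfg An `rns_sim_config`.
#' @return An `rns_truth` object: the complete labelled event stream
#'   (`events`); the pre-constraint recording stream in canonical form
#'   (`recordings_full`) with its per-stratum confusion (`true_performance`)
#'   and pooled per-epoch sample metrics (`true_metrics`, the
#'   complete-review ideal); the detector's performance over all neural
#'   events including unobserved ones (`true_event_performance`,
#'   `true_event_metrics`); and true rates (`true_rates`).
#' @export
simulate_ground_truth <- function(cfg) {
  stopifnot(inherits(cfg, "rns_sim_config"))
  withr::with_seed(cfg$seed, simulate_ground_truth_impl(cfg))
}

simulate_ground_truth_impl <- function(cfg) {
  days <- cfg$duration_days
  patterns <- names(cfg$detectors)
  p_detect <- map_dbl(cfg$detectors, "p_detect_eip")
  ft_rate <- map_dbl(cfg$detectors, "false_trigger_rate_per_day")

  # EIP process and sequential per-Pattern detection
  eip_t <- sample_eip_times(cfg)
  n_eip <- length(eip_t)
  detected_by <- rep(NA_character_, n_eip)
  if (n_eip > 0) {
    u <- matrix(runif(n_eip * length(patterns)), ncol = length(patterns))
    hit <- sweep(u, 2, p_detect, "<")
    first_hit <- apply(hit, 1, function(r) which(r)[1])
    detected_by <- patterns[first_hit]
  }
  eips <- tibble(time_d = eip_t, kind = "EIP", eip = TRUE,
                 pattern = detected_by)

  # background interictal process; per-Pattern false triggers thinned from it
  n_int <- rpois(1, cfg$interictal_rate_per_day * days)
  interictal <- tibble(time_d = sort(runif(n_int, 0, days)), kind = "INTERICTAL",
                       eip = FALSE, pattern = NA_character_)
  if (n_int > 0 && cfg$interictal_rate_per_day > 0) {
    q <- ft_rate / cfg$interictal_rate_per_day
    cat_probs <- c(q, 1 - sum(q))
    draw <- sample.int(length(patterns) + 1, n_int, replace = TRUE,
                       prob = cat_probs)
    interictal$pattern <- c(patterns, NA_character_)[draw]
  }

  sched_k <- max(0L, as.integer(round(cfg$scheduled_recordings_per_day)))
  sched_t <- if (sched_k > 0) {
    as.vector(outer((seq_len(sched_k) - 0.5) / sched_k, seq_len(ceiling(days)) - 1, "+"))
  } else numeric()
  sched_t <- sort(sched_t[sched_t < days])

  n_mag <- rpois(1, cfg$magnet_rate_per_day * days)
  mag_t <- sort(runif(n_mag, 0, days))
  n_sat <- rpois(1, cfg$saturation_rate_per_day * days)
  sat_t <- sort(runif(n_sat, 0, days))

  # undetected-EIP capture probability for detector-independent recordings
  missed_rate <- sum(is.na(detected_by)) / days
  p_sched_eip <- 1 - exp(-missed_rate * cfg$eip_state_window_hours / 24)
  p_mag_eip <- 1 - exp(-missed_rate * cfg$magnet_state_window_hours / 24)

  ev <- bind_rows(
    eips,
    interictal,
    tibble(time_d = sched_t, kind = "SCHEDULED", eip = NA, pattern = NA_character_),
    tibble(time_d = mag_t, kind = "MAGNET", eip = NA, pattern = NA_character_),
    tibble(time_d = sat_t, kind = "SATURATION", eip = FALSE, pattern = NA_character_)
  ) |> arrange(.data$time_d)

  is_sched <- ev$kind == "SCHEDULED"
  ev$eip[is_sched] <- runif(sum(is_sched)) < p_sched_eip
  is_mag <- ev$kind == "MAGNET"
  ev$eip[is_mag] <- runif(sum(is_mag)) < p_mag_eip

  detection <- (ev$kind == "EIP" | ev$kind == "INTERICTAL") & !is.na(ev$pattern)
  ev$episode_class <- NA_character_
  ev$episode_class[detection] <- ifelse(
    runif(sum(detection)) < cfg$long_episode_prob, "LONG_EPISODE", "EPISODE")
  ev$latency_s <- NA_real_
  tp <- detection & ev$eip
  ev$latency_s[tp] <- rgamma(sum(tp), shape = cfg$latency_shape,
                             scale = cfg$latency_scale) - cfg$latency_shift_s
  ev$in_progress <- !is.na(ev$latency_s) & ev$latency_s > cfg$pre_trigger_s

  # therapy delivery per detected episode, subject to the daily limit
  ev$therapies <- 0L
  if (cfg$stimulation_enabled && any(detection)) {
    k <- length(cfg$therapies_per_episode_probs)
    want <- integer(nrow(ev))
    want[detection] <- sample.int(k, sum(detection), replace = TRUE,
                                  prob = cfg$therapies_per_episode_probs)
    day_i <- floor(ev$time_d)
    delivered <- unsplit(lapply(split(want, day_i), function(w) {
      used <- cumsum(w)
      prior <- used - w
      pmax(pmin(w, cfg$daily_therapy_limit - prior), 0L)
    }), day_i)
    ev$therapies <- as.integer(delivered)
  }
  ev$time_s <- ev$time_d * 86400
  ev$day <- as.integer(floor(ev$time_d))

  epochs <- build_epochs(cfg)
  ev$epoch_id <- epochs$epoch_id[
    findInterval(ev$time_s, as.numeric(epochs$start - cfg$start, units = "secs"))]

  rec_full <- events_to_recordings(ev, cfg, noise = 0, id_prefix = "T")
  true_conf <- aggregate_epoch_confusion(rec_full, epochs)
  true_std <- standard_epoch_metrics(true_conf)

  # detector performance over ALL neural events (nothing overwritten,
  # nothing unobserved): every EIP counts whether or not any recording
  # captured it, every interictal event counts as a specificity trial
  neural <- filter(ev, .data$kind %in% c("EIP", "INTERICTAL"))
  true_event_perf <- all_strata() |>
    left_join(
      neural |>
        filter(!is.na(.data$pattern)) |>
        summarise(tp = sum(.data$kind == "EIP"),
                  fp = sum(.data$kind == "INTERICTAL"),
                  .by = c("pattern", "episode_class")),
      by = c("pattern", "episode_class")) |>
    mutate(tp = .data$tp %na% 0L, fp = .data$fp %na% 0L)
  true_event_metrics <- stratum_metrics(tibble(
    tp = sum(true_event_perf$tp),
    fp = sum(true_event_perf$fp),
    fn = sum(neural$kind == "EIP" & is.na(neural$pattern)),
    tn = sum(neural$kind == "INTERICTAL" & is.na(neural$pattern))
  ))
  n_months <- days / DAYS_PER_MONTH
  true_rates <- tibble(
    events_per_hour = (sum(detection) + n_sat + n_mag) / (days * 24),
    eips_per_month = n_eip / n_months,
    detected_eips_per_month = sum(tp) / n_months,
    stimulations_per_episode =
      if (any(detection)) sum(ev$therapies) / sum(detection) else NA_real_,
    therapies_total = sum(ev$therapies)
  )
  structure(
    list(config = cfg, events = ev, epochs = epochs,
         recordings_full = rec_full,
         true_performance = true_conf,
         true_metrics = true_std,
         true_event_performance = true_event_perf,
         true_event_metrics = true_event_metrics,
         true_rates = true_rates),
    class = "rns_truth"
  )
}

build_epochs <- function(cfg) {
  bounds <- cfg$start + seq(0, cfg$duration_days * 86400,
                            length.out = cfg$n_epochs + 1)
  tibble(
    epoch_id = sprintf("%s-E%02d", cfg$patient_id, seq_len(cfg$n_epochs)),
    patient_id = cfg$patient_id,
    start = bounds[-length(bounds)],
    end = bounds[-1],
    enabled_patterns = paste(names(cfg$detectors), collapse = ";"),
    daily_therapy_limit = as.integer(cfg$daily_therapy_limit),
    long_episode_threshold_s = cfg$long_episode_threshold_s,
    stimulation_enabled = cfg$stimulation_enabled
  )
}

# Canonical recordings table from recording-generating events (detections,
# scheduled, magnet). Annotation noise flips eip_present.
events_to_recordings <- function(ev, cfg, noise = 0, id_prefix = "R") {
  detection <- (ev$kind %in% c("EIP", "INTERICTAL")) & !is.na(ev$pattern)
  keep <- detection | ev$kind %in% c("SCHEDULED", "MAGNET")
  r <- ev[keep, ]
  is_det <- (r$kind %in% c("EIP", "INTERICTAL")) & !is.na(r$pattern)
  eip_obs <- r$eip
  if (noise > 0 && nrow(r) > 0) {
    flip <- runif(nrow(r)) < noise
    eip_obs <- xor(eip_obs, flip)
  }
  pre <- cfg$pre_trigger_s
  onset <- ifelse(r$in_progress %na% FALSE, 0, pmax(pre - (r$latency_s %na% 0), 0))
  n <- nrow(r)
  therapy_str <- map_chr(seq_len(n), function(i) {
    k <- r$therapies[[i]]
    if (is.na(k) || k == 0) NA_character_
    else paste(pre + 2 * seq_len(k), collapse = ";")
  })
  lat_lab <- rep(NA_character_, n)
  has_eip <- eip_obs %na% FALSE
  if (any(has_eip)) {
    lat_lab[has_eip] <- sample(c("LEFT", "RIGHT", "BILATERAL"), sum(has_eip),
                               replace = TRUE, prob = c(0.4, 0.4, 0.2))
  }
  tibble(
    recording_id = sprintf("%s%06d", id_prefix, seq_len(n)),
    patient_id = cfg$patient_id,
    epoch_id = r$epoch_id,
    trigger_type = ifelse(is_det, "PATTERN",
                          ifelse(r$kind == "SCHEDULED", "SCHEDULED", "MAGNET")),
    start_time = cfg$start + round(ifelse(is_det, r$time_s - pre, r$time_s)),
    duration_s = cfg$recording_duration_s,
    has_first_episode = is_det,
    fe_onset_s = ifelse(is_det, pre, NA_real_),
    fe_triggering_pattern = ifelse(is_det, r$pattern, NA_character_),
    fe_episode_class = ifelse(is_det, r$episode_class, NA_character_),
    fe_in_progress_at_start = ifelse(is_det, r$in_progress %na% FALSE, NA),
    fe_first_detection_s = ifelse(is_det, pre, NA_real_),
    fe_therapy_times_s = ifelse(is_det, therapy_str, NA_character_),
    eip_present = has_eip,
    eip_onset_s = ifelse(has_eip,
                         ifelse(is_det, onset,
                                runif(n, 0, cfg$recording_duration_s)),
                         NA_real_),
    laterality = lat_lab
  )
}

#' Apply device storage constraints to a ground-truth stream
#'
#' Degrades the complete recording stream through the device's storage
#' model: between consecutive interrogations, recordings fill their
#' reserved trigger-class slots with oldest-first overwriting (plus a shared
#' pool for unreserved slots); the Event List keeps at most its capacity of
#' episodes per interval (newer events lost); hourly histogram counts
#' saturate at the hourly cap, flagging affected days
#' `histogram_data_missing`. The Activity Log is always complete.
#'
#' @param truth An `rns_truth` from [simulate_ground_truth()].
#' @param cfg The same `rns_sim_config` used to simulate.
#' @return An `rns_dataset` of observed (canonical) tables.
#' @export
apply_device_constraints <- function(truth, cfg = truth$config) {
  stopifnot(inherits(truth, "rns_truth"))
  withr::with_seed(cfg$seed + 104729L, apply_device_constraints_impl(truth, cfg))
}

apply_device_constraints_impl <- function(truth, cfg) {
  ev <- truth$events
  epochs <- truth$epochs
  dur_s <- cfg$duration_days * 86400

  # interrogation schedule: lognormal intervals with the configured mean,
  # heavy right tail; a terminal read-out flushes the device
  mu <- log(cfg$interrogation_interval_hours) - 0.683^2 / 2
  gaps <- rlnorm(ceiling(dur_s / 3600 / cfg$interrogation_interval_hours * 3) + 10,
                 meanlog = mu, sdlog = 0.683) * 3600
  intr_s <- round(cumsum(gaps))
  intr_s <- unique(c(intr_s[intr_s < dur_s], dur_s))

  detection <- (ev$kind %in% c("EIP", "INTERICTAL")) & !is.na(ev$pattern)
  is_recording <- detection | ev$kind %in% c("SCHEDULED", "MAGNET")
  countable <- detection | ev$kind %in% c("SATURATION", "MAGNET")

  interval <- findInterval(ev$time_s, intr_s, left.open = TRUE) + 1L

  # --- ECoG slot retention ---------------------------------------------
  res <- cfg$slot_reservation
  storage_class <- rep(NA_character_, nrow(ev))
  fo <- ifelse(detection, first_order_pattern(ev$pattern), NA)
  storage_class[detection] <-
    ifelse(paste0("PATTERN_", fo[detection]) %in% names(res),
           paste0("PATTERN_", fo[detection]),
           ifelse("PATTERN" %in% names(res), "PATTERN", "SHARED"))
  storage_class[ev$kind == "SCHEDULED"] <-
    if ("SCHEDULED" %in% names(res)) "SCHEDULED" else "SHARED"
  storage_class[ev$kind == "MAGNET"] <-
    if ("MAGNET" %in% names(res)) "MAGNET" else "SHARED"

  stored <- logical(nrow(ev))
  if (is.infinite(cfg$ecog_slots)) {
    stored <- is_recording
  } else {
    shared_slots <- cfg$ecog_slots - sum(res)
    idx_rec <- which(is_recording)
    grp <- split(idx_rec, list(interval[idx_rec], storage_class[idx_rec]),
                 drop = TRUE)
    for (g in grp) {
      cls <- storage_class[g[[1]]]
      k <- if (cls == "SHARED") shared_slots else unname(res[[cls]])
      if (k > 0) stored[tail(sort(g), k)] <- TRUE
    }
  }

  # --- hourly histogram saturation --------------------------------------
  hour_i <- floor(ev$time_s / 3600)
  retained <- countable
  idx_cnt <- which(countable)
  if (is.finite(cfg$hourly_histogram_cap)) {
    for (g in split(idx_cnt, hour_i[idx_cnt])) {
      if (length(g) > cfg$hourly_histogram_cap) {
        retained[tail(sort(g), length(g) - cfg$hourly_histogram_cap)] <- FALSE
      }
    }
  }
  capped_hours <- tibble(hour = hour_i[idx_cnt]) |>
    count(.data$hour, name = "true_count") |>
    mutate(event_count = pmin(.data$true_count, cfg$hourly_histogram_cap),
           capped = .data$true_count > cfg$hourly_histogram_cap)

  all_days <- seq_len(ceiling(cfg$duration_days)) - 1L
  capped_days <- unique(floor(capped_hours$hour[capped_hours$capped] / 24))

  rv <- ev[retained, ]
  rv_det <- (rv$kind %in% c("EIP", "INTERICTAL")) & !is.na(rv$pattern)
  daily <- tibble(day = all_days) |>
    left_join(
      tibble(day = rv$day, det = rv_det, pattern = rv$pattern,
             class = rv$episode_class, kind = rv$kind,
             therapies = rv$therapies) |>
        summarise(
          a1_count = sum(.data$det & .data$pattern == "A1", na.rm = TRUE),
          a2_count = sum(.data$det & .data$pattern == "A2", na.rm = TRUE),
          b1_count = sum(.data$det & .data$pattern == "B1", na.rm = TRUE),
          b2_count = sum(.data$det & .data$pattern == "B2", na.rm = TRUE),
          episode_count = sum(.data$det & .data$class == "EPISODE", na.rm = TRUE),
          long_episode_count = sum(.data$det & .data$class == "LONG_EPISODE",
                                   na.rm = TRUE),
          therapy_count = sum(.data$therapies[.data$det]),
          saturation_count = sum(.data$kind == "SATURATION"),
          magnet_count = sum(.data$kind == "MAGNET"),
          .by = "day"),
      by = "day") |>
    mutate(across(-"day", ~ as.integer(.x %na% 0L)),
           patient_id = cfg$patient_id,
           date = as.Date(cfg$start, tz = "UTC") + .data$day,
           histogram_data_missing = .data$day %in% capped_days,
           diagnostic_data_missing = FALSE) |>
    select("patient_id", "date", "a1_count", "a2_count", "b1_count",
           "b2_count", "episode_count", "long_episode_count", "therapy_count",
           "saturation_count", "magnet_count", "histogram_data_missing",
           "diagnostic_data_missing")

  hourly <- capped_hours |>
    mutate(patient_id = cfg$patient_id,
           date = as.Date(cfg$start, tz = "UTC") + floor(.data$hour / 24),
           hour = as.integer(.data$hour %% 24),
           event_count = as.integer(.data$event_count)) |>
    select("patient_id", "date", "hour", "event_count", "capped")

  # --- Activity Log (always complete) -----------------------------------
  al <- tibble(interval = interval[countable],
               pattern = ev$pattern[countable],
               kind = ev$kind[countable],
               det = detection[countable]) |>
    summarise(
      pattern_a_events = sum(.data$det & substr(.data$pattern, 1, 1) == "A",
                             na.rm = TRUE),
      pattern_b_events = sum(.data$det & substr(.data$pattern, 1, 1) == "B",
                             na.rm = TRUE),
      saturations = sum(.data$kind == "SATURATION"),
      magnet_swipes = sum(.data$kind == "MAGNET"),
      .by = "interval")
  activity_log <- tibble(interval = seq_along(intr_s)) |>
    left_join(al, by = "interval") |>
    mutate(across(-"interval", ~ as.integer(.x %na% 0L)),
           patient_id = cfg$patient_id,
           interrogation_time = cfg$start + intr_s[.data$interval]) |>
    select("patient_id", "interrogation_time", "pattern_a_events",
           "pattern_b_events", "saturations", "magnet_swipes")

  # --- Event List truncation --------------------------------------------
  el_idx <- which(detection)
  el_keep <- unlist(lapply(split(el_idx, interval[el_idx]), function(g) {
    head(sort(g), cfg$event_list_capacity)
  }), use.names = FALSE)
  elv <- ev[sort(el_keep), ]
  event_list <- tibble(
    patient_id = cfg$patient_id,
    interrogation_time = cfg$start +
      intr_s[interval[sort(el_keep)]],
    episode_onset = cfg$start + round(elv$time_s),
    triggering_pattern = elv$pattern,
    episode_class = elv$episode_class,
    therapy_count = as.integer(elv$therapies)
  )

  # --- stored recordings -------------------------------------------------
  stored_ev <- ev[stored, ]
  recordings <- events_to_recordings(stored_ev, cfg,
                                     noise = cfg$annotation_noise,
                                     id_prefix = "R")

  # --- monthly seizure reports ------------------------------------------
  eip_ev <- filter(ev, .data$kind == "EIP")
  months <- format(cfg$start + eip_ev$time_s, "%Y-%m", tz = "UTC")
  seizure_reports <- tibble(month = months) |>
    count(.data$month, name = "true_eips") |>
    mutate(patient_id = cfg$patient_id,
           reported_seizures = as.double(
             rbinom(n(), .data$true_eips, cfg$seizure_reporting_rate))) |>
    select("patient_id", "month", "reported_seizures")

  bursts <- if (cfg$stimulation_enabled && nrow(cfg$bursts) > 0) {
    tidyr::expand_grid(epoch_id = epochs$epoch_id, cfg$bursts) |>
      mutate(therapy_index = as.integer(.data$therapy_index),
             burst_index = as.integer(.data$burst_index))
  } else empty_table("bursts")

  new_rns_dataset(
    list(epochs = epochs, bursts = bursts, recordings = recordings,
         event_list = event_list, activity_log = activity_log,
         histogram_daily = daily, histogram_hourly = hourly,
         seizure_reports = seizure_reports),
    device = list(
      ecog_slots = if (is.finite(cfg$ecog_slots)) as.integer(cfg$ecog_slots) else .Machine$integer.max,
      event_list_capacity = if (is.finite(cfg$event_list_capacity)) as.integer(cfg$event_list_capacity) else .Machine$integer.max,
      hourly_histogram_cap = if (is.finite(cfg$hourly_histogram_cap)) as.integer(cfg$hourly_histogram_cap) else .Machine$integer.max
    )
  )
}

#' Simulate a complete observed dataset
#'
#' Convenience wrapper: ground truth plus device constraints.
#'
#' @param cfg An `rns_sim_config`.
#' @return List with `dataset` (the observed `rns_dataset`) and `truth`
#'   (the `rns_truth`).
#' @export
simulate_dataset <- function(cfg) {
  truth <- simulate_ground_truth(cfg)
  list(dataset = apply_device_constraints(truth, cfg), truth = truth)
}

#' Render a dataset (and optionally its ground truth) to disk
#'
#' Writes the canonical dataset files; ground truth, when supplied, goes to a
#' separate `truth/` subdirectory that the evaluation pipeline never reads.
#'
#' @param obs An `rns_dataset`.
#' @param out_path Output directory.
#' @param truth Optional `rns_truth`.
#' @return Tibble manifest of written files.
#' @export
render_dataset <- function(obs, out_path, truth = NULL) {
  manifest <- write_dataset(obs, out_path)
  if (!is.null(truth)) {
    tdir <- file.path(out_path, "truth")
    dir.create(tdir, recursive = TRUE, showWarnings = FALSE)
    readr::write_csv(truth$true_metrics, file.path(tdir, "true_metrics.csv"))
    readr::write_csv(truth$true_event_metrics,
                     file.path(tdir, "true_event_metrics.csv"))
    readr::write_csv(truth$true_rates, file.path(tdir, "true_rates.csv"))
    ev_out <- truth$events |>
      select("time_s", "kind", "eip", "pattern", "episode_class", "latency_s",
             "in_progress", "therapies", "epoch_id")
    readr::write_csv(ev_out, file.path(tdir, "events.csv"))
    manifest <- bind_rows(manifest,
                          tibble(file = file.path(tdir, c("true_metrics.csv",
                                                          "true_event_metrics.csv",
                                                          "true_rates.csv",
                                                          "events.csv"))))
  }
  manifest
}
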