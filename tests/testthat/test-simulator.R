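# device simulator: determinism, statistical structure, storage constraints

test_that("identical configuration and seed give identical output", {
  cfg <- simulation_config(seed = 101, duration_days = 7, n_epochs = 2)
  a <- simulate_dataset(cfg)
  b <- simulate_dataset(cfg)
  expect_identical(a$truth$events, b$truth$events)
  for (nm in c("recordings", "event_list", "activity_log", "histogram_daily")) {
    expect_identical(a$dataset[[nm]], b$dataset[[nm]])
  }
})

test_that("config validation rejects bad detector and storage settings", {
  expect_error(simulation_config(), "seed")
  expect_error(simulation_config(seed = 1, detectors = list(
    A1 = list(p_detect_eip = 1.5, false_trigger_rate_per_day = 0))),
    "out of range")
  expect_error(simulation_config(seed = 1, interictal_rate_per_day = 1,
                                 detectors = list(
    A1 = list(p_detect_eip = 0.5, false_trigger_rate_per_day = 5))),
    "exceeds")
  expect_error(simulation_config(seed = 1, ecog_slots = 2), "slot_reservation")
})

test_that("perfect detectors give true sensitivity 1 and zero false positives", {
  det <- list(A1 = list(p_detect_eip = 1, false_trigger_rate_per_day = 0))
  cfg <- simulation_config(seed = 13, duration_days = 10, n_epochs = 1,
                           detectors = det, interictal_rate_per_day = 5)
  truth <- simulate_ground_truth(cfg)
  expect_equal(truth$true_metrics$sensitivity, 1)
  expect_equal(truth$true_metrics$fp, 0)
  expect_equal(truth$true_event_metrics$sensitivity, 1)
  expect_equal(truth$true_event_metrics$fp, 0)
})

test_that("EIP totals follow the configured Poisson rate", {
  counts <- purrr::map_int(1:20, function(s) {
    cfg <- simulation_config(seed = s, duration_days = 30, n_epochs = 1,
                             eip_rate_per_day = 10, multidien_amplitude = 0)
    sum(simulate_ground_truth(cfg)$events$kind == "EIP")
  })
  lo <- qpois(0.0005, 300)
  hi <- qpois(0.9995, 300)
  expect_true(all(counts >= lo & counts <= hi))
})

test_that("observed data conserve truth: activity log complete, storage bounded", {
  cfg <- simulation_config(seed = 29, duration_days = 14, n_epochs = 1)
  sim <- simulate_dataset(cfg)
  ev <- sim$truth$events
  detection <- ev$kind %in% c("EIP", "INTERICTAL") & !is.na(ev$pattern)
  al <- sim$dataset$activity_log
  expect_equal(sum(al$pattern_a_events + al$pattern_b_events), sum(detection))
  expect_equal(sum(al$saturations), sum(ev$kind == "SATURATION"))
  expect_equal(sum(al$magnet_swipes), sum(ev$kind == "MAGNET"))
  # stored recordings are a subset of the full recording stream
  expect_lte(nrow(sim$dataset$recordings), nrow(sim$truth$recordings_full))
  expect_lte(nrow(sim$dataset$recordings),
             cfg$ecog_slots * nrow(al))
  expect_true(all(sim$dataset$recordings$start_time %in%
                    sim$truth$recordings_full$start_time))
})

test_that("stored recordings cluster toward interrogation times (temporal bias)", {
  ratios <- purrr::map_dbl(c(37, 41, 43), function(s) {
    cfg <- simulation_config(seed = s, duration_days = 21, n_epochs = 1)
    sim <- simulate_dataset(cfg)
    intr <- as.numeric(sim$dataset$activity_log$interrogation_time)
    age <- function(t) {
      nxt <- intr[findInterval(t, intr, left.open = TRUE) + 1]
      nxt - t
    }
    all_t <- as.numeric(sim$truth$recordings_full$start_time)
    sto_t <- as.numeric(sim$dataset$recordings$start_time)
    mean(age(sto_t)) / mean(age(all_t))
  })
  expect_true(all(ratios < 1))
})

test_that("oldest-first overwriting keeps exactly the last k per slot class", {
  cfg <- simulation_config(seed = 1, duration_days = 1, n_epochs = 1,
                           interrogation_interval_hours = 1000,
                           slot_reservation = setNames(integer(0), character(0)),
                           scheduled_recordings_per_day = 0,
                           magnet_rate_per_day = 0, saturation_rate_per_day = 0)
  truth <- make_truth(cfg, det_events(seq(1000, 10000, by = 1000)))
  obs <- apply_device_constraints(truth, cfg)
  expect_equal(nrow(obs$recordings), 4)
  # the 4 newest triggers survive (start_time = trigger - pre-trigger buffer)
  expect_equal(sort(as.numeric(obs$recordings$start_time) - as.numeric(cfg$start)),
               c(7000, 8000, 9000, 10000) - cfg$pre_trigger_s)
})

test_that("slot reservation by trigger class is honoured", {
  cfg <- simulation_config(seed = 1, duration_days = 1, n_epochs = 1,
                           interrogation_interval_hours = 1000,
                           scheduled_recordings_per_day = 0,
                           magnet_rate_per_day = 0, saturation_rate_per_day = 0)
  ev <- dplyr::bind_rows(
    det_events(seq(1000, 5000, by = 1000), pattern = "A1"),
    det_events(seq(1500, 5500, by = 1000), pattern = "B1"),
    tibble::tibble(time_s = c(20000, 30000), kind = "SCHEDULED",
                   eip = FALSE, pattern = NA_character_)
  )
  obs <- apply_device_constraints(make_truth(cfg, ev), cfg)
  # 1 slot each for Pattern A, Pattern B, scheduled; magnet slot unused
  stored <- obs$recordings
  expect_equal(sum(stored$fe_triggering_pattern == "A1", na.rm = TRUE), 1)
  expect_equal(sum(stored$fe_triggering_pattern == "B1", na.rm = TRUE), 1)
  expect_equal(sum(stored$trigger_type == "SCHEDULED"), 1)
  # the retained pattern recordings are the newest of their class
  expect_equal(max(as.numeric(stored$start_time) - as.numeric(cfg$start)),
               30000)
})

test_that("event list truncates at capacity, newest entries lost", {
  cfg <- simulation_config(seed = 1, duration_days = 1, n_epochs = 1,
                           interrogation_interval_hours = 1000,
                           scheduled_recordings_per_day = 0,
                           magnet_rate_per_day = 0, saturation_rate_per_day = 0)
  truth <- make_truth(cfg, det_events(seq_len(1000) * 80))
  obs <- apply_device_constraints(truth, cfg)
  expect_equal(nrow(obs$event_list), 700)
  expect_equal(max(as.numeric(obs$event_list$episode_onset) - as.numeric(cfg$start)),
               700 * 80)
  comp <- completeness(obs$activity_log, obs$event_list, obs$histogram_daily,
                       obs$recordings)
  expect_equal(comp$event_list_pct, 70)
})

test_that("hourly histogram saturates at the cap and flags the day", {
  cfg <- simulation_config(seed = 1, duration_days = 1, n_epochs = 1,
                           interrogation_interval_hours = 1000,
                           scheduled_recordings_per_day = 0,
                           magnet_rate_per_day = 0, saturation_rate_per_day = 0)
  # 300 detections within one hour
  truth <- make_truth(cfg, det_events(3600 + seq_len(300) * 10))
  obs <- apply_device_constraints(truth, cfg)
  hr <- dplyr::filter(obs$histogram_hourly, hour == 1)
  expect_equal(hr$event_count, 255L)
  expect_true(hr$capped)
  expect_true(obs$histogram_daily$histogram_data_missing[
    obs$histogram_daily$date == as.Date(cfg$start)])
})

test_that("unlimited storage and disabled caps preserve everything", {
  cfg <- simulation_config(seed = 53, duration_days = 10, n_epochs = 1,
                           ecog_slots = Inf, event_list_capacity = Inf,
                           hourly_histogram_cap = Inf)
  sim <- simulate_dataset(cfg)
  expect_equal(nrow(sim$dataset$recordings), nrow(sim$truth$recordings_full))
  expect_false(any(sim$dataset$histogram_daily$histogram_data_missing))
  std_obs <- standard_epoch_metrics(
    aggregate_epoch_confusion(sim$dataset$recordings, sim$dataset$epochs))
  expect_equal(std_obs$accuracy, sim$truth$true_metrics$accuracy,
               tolerance = 1e-12)
  expect_equal(std_obs$sensitivity, sim$truth$true_metrics$sensitivity,
               tolerance = 1e-12)
})

test_that("rendered datasets load back and keep truth out of band", {
  cfg <- simulation_config(seed = 61, duration_days = 5, n_epochs = 1)
  sim <- simulate_dataset(cfg)
  dir <- withr::local_tempdir()
  manifest <- render_dataset(sim$dataset, dir, truth = sim$truth)
  expect_true(file.exists(file.path(dir, "truth", "true_metrics.csv")))
  back <- load_dataset(dir)
  expect_equal(sum(validate_dataset(back)$severity == "error"), 0)
  # deleting the truth directory does not affect loading or evaluation
  unlink(file.path(dir, "truth"), recursive = TRUE)
  ev1 <- evaluate_dataset(load_dataset(dir))
  expect_equal(nrow(ev1$epoch_metrics), 1)
})
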