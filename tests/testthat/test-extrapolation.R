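# weight construction and weighted epoch metrics

wt_epoch <- function(days = 10) make_epoch(end = T0 + days * 86400)

test_that("raw weights reproduce the trigger-share x history-share products", {
  # episode stratum: A1 triggered 3 of 4 ECoG episodes; history A1=60 of 100
  recs <- make_confusion_recordings(
    tibble::tibble(pattern = c("A1", "B1"), episode_class = "EPISODE",
                   tp = c(2, 1), fp = c(1, 0)))
  hist <- make_hist_day(a1 = 60, a2 = 20, b1 = 20, b2 = 0)
  conf <- aggregate_epoch_confusion(recs, wt_epoch())
  wt <- compute_weight_table(conf, hist, wt_epoch())
  a1e <- dplyr::filter(wt, pattern == "A1", episode_class == "EPISODE")
  expect_equal(a1e$raw_weight, (3 / 4) * (60 / 100))
  # long-episode stratum: all ECoG long episodes by B1; history LE=10, E=90
  recs2 <- make_confusion_recordings(
    tibble::tibble(pattern = "B1", episode_class = "LONG_EPISODE", tp = 2, fp = 0))
  hist2 <- make_hist_day(b1 = 100, episodes = 90, long_episodes = 10)
  conf2 <- aggregate_epoch_confusion(recs2, wt_epoch())
  wt2 <- compute_weight_table(conf2, hist2, wt_epoch())
  b1le <- dplyr::filter(wt2, pattern == "B1", episode_class == "LONG_EPISODE")
  expect_equal(b1le$raw_weight, 1.0 * (10 / 100))
  # single surviving stratum -> normalized weight 1 regardless of magnitude
  expect_equal(b1le$normalized_weight, 1)
})

test_that("normalized weights sum to one and are scale invariant", {
  withr::with_seed(5, {
    for (rep in 1:10) {
      counts <- tidyr::expand_grid(pattern = c("A1", "A2", "B1", "B2"),
                                   episode_class = c("EPISODE", "LONG_EPISODE")) |>
        dplyr::mutate(tp = rpois(8, 3), fp = rpois(8, 2))
      recs <- make_confusion_recordings(counts, tn = 2, fn = 1)
      hist <- make_hist_day(a1 = rpois(1, 50) + 1, a2 = rpois(1, 30),
                            b1 = rpois(1, 40), b2 = rpois(1, 20),
                            long_episodes = rpois(1, 10))
      conf <- aggregate_epoch_confusion(recs, wt_epoch())
      wt <- compute_weight_table(conf, hist, wt_epoch())
      expect_equal(sum(wt$normalized_weight[!wt$excluded]), 1, tolerance = 1e-12)
      hist10 <- dplyr::mutate(hist, dplyr::across(dplyr::ends_with("_count"), ~ .x * 10L))
      wt10 <- compute_weight_table(conf, hist10, wt_epoch())
      expect_equal(wt$normalized_weight, wt10$normalized_weight, tolerance = 1e-12)
      m <- weighted_epoch_metric(conf, wt, "accuracy")$value
      m10 <- weighted_epoch_metric(conf, wt10, "accuracy")$value
      expect_equal(m, m10, tolerance = 1e-12)
    }
  })
})

test_that("zero-support strata are excluded; no support at all is an error", {
  recs <- make_confusion_recordings(
    tibble::tibble(pattern = "A1", episode_class = "EPISODE", tp = 1, fp = 0))
  hist <- make_hist_day(a1 = 10, b1 = 5)
  conf <- aggregate_epoch_confusion(recs, wt_epoch())
  wt <- compute_weight_table(conf, hist, wt_epoch())
  expect_true(all(wt$excluded[!(wt$pattern == "A1" & wt$episode_class == "EPISODE")]))
  hist0 <- make_hist_day()
  expect_error(compute_weight_table(conf, hist0, wt_epoch()),
               "no weighting support")
})

test_that("weighted metrics are weight-combined stratum values", {
  # two strata, accuracies 1.0 and 0.5, normalized weights 0.6/0.4 -> 0.8
  conf <- aggregate_epoch_confusion(
    make_confusion_recordings(
      tibble::tibble(pattern = c("A1", "B1"), episode_class = "EPISODE",
                     tp = c(3, 2), fp = c(0, 2))),
    wt_epoch())
  strat <- dplyr::filter(conf, scope == "stratum", tp + fp > 0)
  expect_equal(sort(strat$accuracy), c(0.5, 1.0))
  wt <- compute_weight_table(conf, make_hist_day(a1 = 60, b1 = 40), wt_epoch())
  w <- dplyr::filter(wt, !excluded)
  manual <- sum(strat$accuracy[match(paste(w$pattern, w$episode_class),
                                     paste(strat$pattern, strat$episode_class))] *
                  w$normalized_weight)
  got <- weighted_epoch_metric(conf, wt, "accuracy")$value
  expect_equal(got, manual, tolerance = 1e-12)
  # identity: single stratum, weight 1
  conf1 <- aggregate_epoch_confusion(
    make_confusion_recordings(
      tibble::tibble(pattern = "A1", episode_class = "EPISODE", tp = 4, fp = 1)),
    wt_epoch())
  wt1 <- compute_weight_table(conf1, make_hist_day(a1 = 10), wt_epoch())
  expect_equal(weighted_epoch_metric(conf1, wt1, "accuracy")$value, 0.8)
})

test_that("weighted metrics are convex combinations of stratum values", {
  withr::with_seed(7, {
    for (rep in 1:20) {
      counts <- tidyr::expand_grid(pattern = c("A1", "A2", "B1", "B2"),
                                   episode_class = c("EPISODE", "LONG_EPISODE")) |>
        dplyr::mutate(tp = rpois(8, 4), fp = rpois(8, 3))
      recs <- make_confusion_recordings(counts, tn = rpois(1, 3), fn = rpois(1, 2))
      hist <- make_hist_day(a1 = rpois(1, 40) + 1, a2 = rpois(1, 30) + 1,
                            b1 = rpois(1, 20) + 1, b2 = rpois(1, 10) + 1,
                            long_episodes = rpois(1, 15))
      conf <- aggregate_epoch_confusion(recs, wt_epoch())
      wt <- compute_weight_table(conf, hist, wt_epoch())
      joined <- dplyr::inner_join(
        dplyr::filter(conf, scope == "stratum"), tibble::as_tibble(wt),
        by = c("epoch_id", "pattern", "episode_class"))
      for (m in c("accuracy", "sensitivity", "specificity")) {
        vals <- joined[[m]][!joined$excluded]
        if (m == "sensitivity") vals <- joined[[m]][!joined$excluded & joined$tp > 0]
        if (m == "specificity") vals <- joined[[m]][!joined$excluded & joined$fp > 0]
        vals <- vals[!is.na(vals)]
        got <- weighted_epoch_metric(conf, wt, m)$value
        if (length(vals) == 0) {
          expect_true(is.na(got))
        } else {
          expect_gte(got, min(vals) - 1e-12)
          expect_lte(got, max(vals) + 1e-12)
        }
      }
    }
  })
})

test_that("weighted equals standard in the proportional symmetric limit", {
  # equal pattern totals, uniform precision, history proportional to ECoG
  counts <- tidyr::expand_grid(pattern = c("A1", "A2", "B1", "B2"),
                               episode_class = "EPISODE") |>
    dplyr::mutate(tp = 6L, fp = 4L)
  recs <- make_confusion_recordings(counts, tn = 4, fn = 2)
  hist <- make_hist_day(a1 = 30, a2 = 30, b1 = 30, b2 = 30)
  conf <- aggregate_epoch_confusion(recs, wt_epoch())
  wt <- compute_weight_table(conf, hist, wt_epoch())
  std <- standard_epoch_metrics(conf)
  for (m in c("accuracy", "sensitivity", "specificity")) {
    expect_equal(weighted_epoch_metric(conf, wt, m)$value, std[[m]],
                 tolerance = 1e-9)
  }
})

test_that("weighted latency combines stratum means over latency-bearing strata", {
  mk_lat <- function(pattern, lats, start_id) {
    purrr::imap(lats, function(l, i) {
      make_recording(paste0("R", start_id + i), pattern = pattern,
                     eip_present = TRUE, eip_onset_s = 10,
                     first_detection_s = 10 + l)
    }) |> dplyr::bind_rows()
  }
  recs <- mk_lat("A1", c(2, 4), 0)
  conf <- aggregate_epoch_confusion(recs, wt_epoch())
  wt <- compute_weight_table(conf, make_hist_day(a1 = 10), wt_epoch())
  expect_equal(weighted_latency(conf, wt)$latency_s, 3)
  # two strata with mean latencies 1 and -1, equal weights -> 0
  recs2 <- dplyr::bind_rows(mk_lat("A1", c(1, 1), 10), mk_lat("B1", c(-1, -1), 20))
  conf2 <- aggregate_epoch_confusion(recs2, wt_epoch())
  wt2 <- compute_weight_table(conf2, make_hist_day(a1 = 50, b1 = 50), wt_epoch())
  expect_equal(weighted_latency(conf2, wt2)$latency_s, 0, tolerance = 1e-12)
  # in-progress TP contributes no latency; lone in-progress stratum -> NA
  recs3 <- make_recording("R1", eip_present = TRUE, eip_onset_s = 0,
                          first_detection_s = 30, in_progress = TRUE)
  conf3 <- aggregate_epoch_confusion(recs3, wt_epoch())
  wt3 <- compute_weight_table(conf3, make_hist_day(a1 = 10), wt_epoch())
  expect_true(is.na(weighted_latency(conf3, wt3)$latency_s))
})

test_that("event and therapy rates come straight from the logs", {
  ep <- make_epoch(end = T0 + 10 * 3600)  # a 10-hour epoch
  act <- tibble::tibble(patient_id = "P1",
                        interrogation_time = T0 + c(5, 10) * 3600,
                        pattern_a_events = c(100L, 80L),
                        pattern_b_events = c(20L, 20L),
                        saturations = c(10L, 5L), magnet_swipes = c(3L, 2L))
  r <- event_rate_metrics(make_hist_day(), act, ep)
  expect_equal(r$events_per_hour, 240 / 10)
  expect_equal(r$pattern_detections_per_hour, 220 / 10)
  # stimulations per episode and days at the daily limit
  ep10 <- make_epoch(end = T0 + 10 * 86400, daily_therapy_limit = 1000L)
  hist <- purrr::map(0:9, function(d) {
    make_hist_day(date = as.Date("2021-03-01") + d, a1 = 10,
                  therapies = if (d < 3) 1000L else 11L)
  }) |> dplyr::bind_rows()
  hist$episode_count <- 10L
  r2 <- event_rate_metrics(hist, act, ep10)
  expect_equal(r2$stimulations_per_episode, (3 * 1000 + 7 * 11) / 100)
  expect_equal(r2$pct_days_at_limit, 30)
  # missing days are excluded from day-based metrics
  hist$histogram_data_missing[1:2] <- TRUE
  r3 <- event_rate_metrics(hist, act, ep10)
  expect_equal(r3$n_days_valid, 8)
  expect_equal(r3$pct_days_at_limit, 100 * 1 / 8)
})

test_that("therapies=110 over 100 episodes gives 1.1 stimulations/episode", {
  ep <- make_epoch()
  hist <- make_hist_day(a1 = 100, therapies = 110)
  r <- event_rate_metrics(hist, tibble::tibble(
    patient_id = character(), interrogation_time = as.POSIXct(character(), tz = "UTC"),
    pattern_a_events = integer(), pattern_b_events = integer(),
    saturations = integer(), magnet_swipes = integer()), ep)
  expect_equal(r$stimulations_per_episode, 1.1)
})

test_that("EIPs per month scale the weighted EIP fraction by history episodes", {
  ep <- make_epoch(end = T0 + 30.44 * 86400)
  recs <- make_confusion_recordings(
    tibble::tibble(pattern = "A1", episode_class = "EPISODE", tp = 5, fp = 5))
  conf <- aggregate_epoch_confusion(recs, ep)
  hist <- make_hist_day(a1 = 200)
  wt <- compute_weight_table(conf, hist, ep)
  r <- eip_rate(conf, wt, hist, ep)
  expect_equal(r$eip_fraction, 0.5)
  expect_equal(r$eips_per_month, 100)
  # fraction 1 over two months
  ep2 <- make_epoch(end = T0 + 60.88 * 86400)
  recs2 <- make_confusion_recordings(
    tibble::tibble(pattern = "A1", episode_class = "EPISODE", tp = 4, fp = 0))
  conf2 <- aggregate_epoch_confusion(recs2, ep2)
  hist2 <- make_hist_day(a1 = 50)
  wt2 <- compute_weight_table(conf2, hist2, ep2)
  expect_equal(eip_rate(conf2, wt2, hist2, ep2)$eips_per_month, 25)
  # no history episodes -> 0 with a warning
  hist3 <- make_hist_day(a1 = 10, episodes = 0)
  expect_warning(r3 <- eip_rate(conf, wt, hist3, ep), "no history episodes")
  expect_equal(r3$eips_per_month, 0)
})

make_burst <- function(epoch_id = "E1", therapy = 1L, burst = 1L,
                       current = 1, pw = 160, freq = 100, dur = 100,
                       area = 0.08, hemi = "LEFT") {
  tibble::tibble(epoch_id = epoch_id, therapy_index = therapy,
                 burst_index = burst, current_ma = current,
                 pulse_width_us = pw, frequency_hz = freq, duration_ms = dur,
                 cathode_electrodes = "1;2", anode_electrodes = "3;4",
                 electrode_area_cm2 = area, hemisphere = hemi)
}

test_that("charge dose matches an independent per-pulse summation", {
  # 1 mA, 160 us, 0.08 cm^2 -> 2 uC/cm^2 per pulse phase; 100 Hz x 100 ms
  # burst -> 10 pulses; delivered 100 times -> 2000 uC/cm^2
  ep <- make_epoch()
  bursts <- make_burst()
  hist <- make_hist_day(a1 = 100, therapies = 100)
  dose <- charge_dose(hist, ep, bursts)
  oracle <- 0
  for (delivery in seq_len(100)) {
    for (pulse in seq_len(floor(100 * 100 / 1000))) {
      oracle <- oracle + 1 * 160 * 1e-3 / 0.08
    }
  }
  expect_equal(sum(dose$dose_uC_per_cm2), oracle)
  expect_equal(oracle, 2000)
})

test_that("dose is zero without deliveries, splits by hemisphere, adds over days", {
  ep <- make_epoch()
  bursts <- dplyr::bind_rows(make_burst(hemi = "LEFT"),
                             make_burst(burst = 2L, hemi = "RIGHT"))
  expect_equal(sum(charge_dose(make_hist_day(a1 = 5), ep, bursts)$dose_uC_per_cm2), 0)
  hist <- make_hist_day(a1 = 40, therapies = 40)
  dose <- charge_dose(hist, ep, bursts)
  left <- dose$dose_uC_per_cm2[dose$hemisphere == "LEFT"]
  right <- dose$dose_uC_per_cm2[dose$hemisphere == "RIGHT"]
  expect_equal(left, right)
  expect_equal(sum(dose$dose_uC_per_cm2), 2 * left)
  # additivity over disjoint day ranges
  h1 <- make_hist_day(date = as.Date("2021-03-01"), a1 = 10, therapies = 10)
  h2 <- make_hist_day(date = as.Date("2021-03-05"), a1 = 30, therapies = 30)
  d_both <- sum(charge_dose(dplyr::bind_rows(h1, h2), ep, bursts)$dose_uC_per_cm2)
  d_sep <- sum(charge_dose(h1, ep, bursts)$dose_uC_per_cm2) +
    sum(charge_dose(h2, ep, bursts)$dose_uC_per_cm2)
  expect_equal(d_both, d_sep)
  # missing electrode area names the burst
  bad <- make_burst(); bad$electrode_area_cm2 <- NA_real_
  expect_error(charge_dose(hist, ep, bad), "electrode area")
})
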