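# History-weighted extrapolation of reviewed-ECoG metrics.
#
# Stored ECoG snippets are a biased sample of device activity; the daily
# Neurostimulator History histograms count every retained event. Per-stratum
# snippet metrics are therefore recombined with weights built from the
# product of ECoG trigger shares and history count shares:
#
#   w(P, E)  = [ECoG episode count of P / total ECoG episode counts]
#              x [history count of P / total history Pattern counts]
#   w(P, LE) = [ECoG long-episode count of P / total ECoG long-episode counts]
#              x [LE_History / (LE_History + E_History)]
#
# and the weighted epoch metric is the weight-combined sum of the stratum
# metrics (PE_Acc and analogues). Raw weights do not generally sum to one;
# the default normalizes them over surviving strata so the result is a
# proportion, while `literal = TRUE` reproduces the unnormalized sum for
# audit.

hist_in_epoch <- function(histogram_daily, epoch_row, include_missing = FALSE) {
  h <- filter(histogram_daily,
              .data$patient_id == epoch_row$patient_id,
              .data$date >= as.Date(epoch_row$start, tz = "UTC"),
              .data$date <= as.Date(epoch_row$end - 1, tz = "UTC"))
  if (!include_missing) h <- filter(h, !.data$histogram_data_missing)
  h
}

#' Per-stratum extrapolation weights for programming epochs
#'
#' Builds the raw weight table (ECoG trigger shares times daily-history count
#' shares) and its normalization over strata with nonzero support. Histogram
#' days flagged `histogram_data_missing` are excluded from the history shares.
#'
#' @param conf An `rns_confusion` from [aggregate_epoch_confusion()].
#' @param histogram_daily Daily Neurostimulator History table.
#' @param epochs Epochs table (patient, start, end per epoch).
#' @return An `rns_weights` tibble: one row per epoch per stratum with
#'   `ecog_count`, `ecog_share`, `history_share`, `raw_weight`,
#'   `normalized_weight`, and `excluded` (zero ECoG or history support).
#' @export
compute_weight_table <- function(conf, histogram_daily, epochs) {
  strat <- filter(conf, .data$scope == "stratum")
  out <- map(unique(strat$epoch_id), function(eid) {
    ep <- filter(epochs, .data$epoch_id == eid)
    if (nrow(ep) != 1) abort(paste0("epoch not found (or duplicated): ", eid))
    h <- hist_in_epoch(histogram_daily, ep)
    hp <- c(A1 = sum(h$a1_count), A2 = sum(h$a2_count),
            B1 = sum(h$b1_count), B2 = sum(h$b2_count))
    e_hist <- sum(h$episode_count)
    le_hist <- sum(h$long_episode_count)
    sc <- filter(strat, .data$epoch_id == eid) |>
      mutate(ecog_count = .data$tp + .data$fp)
    class_tot <- sc |> summarise(tot = sum(.data$ecog_count), .by = "episode_class")
    sc <- sc |>
      left_join(class_tot, by = "episode_class") |>
      mutate(
        ecog_share = ifelse(.data$tot > 0, .data$ecog_count / .data$tot, 0),
        history_share = ifelse(
          .data$episode_class == "EPISODE",
          if (sum(hp) > 0) hp[.data$pattern] / sum(hp) else 0,
          if (e_hist + le_hist > 0) le_hist / (e_hist + le_hist) else 0
        ),
        raw_weight = .data$ecog_share * .data$history_share,
        excluded = .data$raw_weight <= 0
      )
    tot_raw <- sum(sc$raw_weight[!sc$excluded])
    if (tot_raw <= 0) {
      abort(paste0("no weighting support in epoch ", eid))
    }
    sc$normalized_weight <- ifelse(sc$excluded, 0, sc$raw_weight / tot_raw)
    select(sc, "epoch_id", "pattern", "episode_class", "ecog_count",
           "ecog_share", "history_share", "raw_weight", "normalized_weight",
           "excluded")
  }) |> list_rbind()
  class(out) <- c("rns_weights", class(out))
  out
}

join_conf_weights <- function(conf, wt) {
  conf |>
    filter(.data$scope == "stratum") |>
    inner_join(as_tibble(wt),
               by = c("epoch_id", "pattern", "episode_class"))
}

#' Weighted epoch metric
#'
#' Combines per-stratum metric values with the extrapolation weights:
#' the sum over non-excluded strata of stratum metric times weight. Strata
#' whose metric is undefined are dropped and the remaining normalized weights
#' renormalized (default), so the result is a convex combination of defined
#' stratum values; with `literal = TRUE` the unnormalized raw weights are used
#' as printed, in which case the sum need not lie in \[0, 1\].
#'
#' Strata contribute a metric only where they carry information about it:
#' sensitivity conditions on EIP-bearing recordings, so strata with no true
#' positives are excluded from the sensitivity combination; symmetrically,
#' strata with no false positives are excluded from the specificity
#' combination (their pool-apportioned negatives alone would contribute
#' degenerate 0 or 1 values that reflect the apportionment, not the
#' detector).
#'
#' @param conf An `rns_confusion`.
#' @param wt An `rns_weights` from [compute_weight_table()].
#' @param metric One of `"accuracy"`, `"sensitivity"`, `"specificity"`.
#' @param literal Use unnormalized raw weights (audit mode).
#' @return Tibble with `epoch_id`, `metric`, `value` (NA when no stratum
#'   survives), and `n_strata` contributing.
#' @export
weighted_epoch_metric <- function(conf, wt,
                                  metric = c("accuracy", "sensitivity", "specificity"),
                                  literal = FALSE) {
  metric <- match.arg(metric)
  join_conf_weights(conf, wt) |>
    mutate(m = .data[[metric]],
           m = dplyr::case_when(
             .env$metric == "sensitivity" & .data$tp == 0 ~ NA_real_,
             .env$metric == "specificity" & .data$fp == 0 ~ NA_real_,
             .default = .data$m
           )) |>
    summarise(
      value = {
        ok <- !.data$excluded & !is.na(.data$m)
        if (!any(ok)) NA_real_
        else if (literal) sum(.data$m[ok] * .data$raw_weight[ok])
        else sum(.data$m[ok] * .data$normalized_weight[ok]) /
          sum(.data$normalized_weight[ok])
      },
      n_strata = sum(!.data$excluded & !is.na(.data$m)),
      .by = "epoch_id"
    ) |>
    mutate(metric = .env$metric, .after = "epoch_id")
}

#' Weighted detector latency
#'
#' Combines per-stratum mean TP latencies (first detection minus annotated
#' EIP onset; recordings beginning with an in-progress episode excluded) with
#' the extrapolation weights restricted to latency-bearing strata. Negative
#' results are legal: stimulation preceded the annotated onset.
#'
#' @inheritParams weighted_epoch_metric
#' @return Tibble with `epoch_id`, `latency_s` (NA when no stratum carries an
#'   eligible latency), and `n_strata`.
#' @export
weighted_latency <- function(conf, wt, literal = FALSE) {
  join_conf_weights(conf, wt) |>
    summarise(
      latency_s = {
        ok <- !.data$excluded & .data$n_latency > 0
        if (!any(ok)) NA_real_
        else if (literal) sum(.data$mean_latency_s[ok] * .data$raw_weight[ok])
        else sum(.data$mean_latency_s[ok] * .data$normalized_weight[ok]) /
          sum(.data$normalized_weight[ok])
      },
      n_strata = sum(!.data$excluded & .data$n_latency > 0),
      .by = "epoch_id"
    )
}

#' Weighted epoch metrics, wide form
#'
#' @inheritParams weighted_epoch_metric
#' @return One row per epoch with `weighted_accuracy`, `weighted_sensitivity`,
#'   `weighted_specificity`, `weighted_latency_s`.
#' @export
weighted_epoch_metrics <- function(conf, wt, literal = FALSE) {
  wide <- map(c("accuracy", "sensitivity", "specificity"), function(m) {
    weighted_epoch_metric(conf, wt, m, literal = literal) |>
      select("epoch_id", "metric", "value")
  }) |>
    list_rbind() |>
    tidyr::pivot_wider(names_from = "metric", values_from = "value",
                       names_prefix = "weighted_")
  lat <- weighted_latency(conf, wt, literal = literal) |>
    select("epoch_id", weighted_latency_s = "latency_s")
  left_join(wide, lat, by = "epoch_id")
}

#' Event- and therapy-rate metrics from log data
#'
#' Rate metrics computed directly from log data, no weighting needed. Total
#' events (pattern detections + saturations + magnet swipes) and pattern
#' detections per hour come from the Activity Log (the complete source) over
#' the full epoch duration; stimulations per episode and the percentage of
#' days reaching the daily therapy limit come from daily histogram days with
#' `histogram_data_missing = FALSE`.
#'
#' @param histogram_daily Daily history table.
#' @param activity_log Activity-log table.
#' @param epochs Epochs table.
#' @return One row per epoch: `events_per_hour`, `pattern_detections_per_hour`,
#'   `stimulations_per_episode`, `pct_days_at_limit`, `days_to_stim_enabled`,
#'   `n_days_valid`, `n_days_missing`.
#' @export
event_rate_metrics <- function(histogram_daily, activity_log, epochs) {
  stim_start <- epochs |>
    summarise(first_start = min(.data$start),
              first_stim = if (any(.data$stimulation_enabled))
                min(.data$start[.data$stimulation_enabled]) else
                  as.POSIXct(NA),
              .by = "patient_id") |>
    mutate(days_to_stim_enabled =
             as.numeric(difftime(.data$first_stim, .data$first_start,
                                 units = "days")))
  epochs |>
    rowwise_epochs() |>
    map(function(ep) {
      hours <- as.numeric(difftime(ep$end, ep$start, units = "hours"))
      al <- filter(activity_log,
                   .data$patient_id == ep$patient_id,
                   .data$interrogation_time > ep$start,
                   .data$interrogation_time <= ep$end)
      total_events <- sum(al$pattern_a_events + al$pattern_b_events +
                            al$saturations + al$magnet_swipes)
      detections <- sum(al$pattern_a_events + al$pattern_b_events)
      h <- hist_in_epoch(histogram_daily, ep)
      h_all <- hist_in_epoch(histogram_daily, ep, include_missing = TRUE)
      episodes <- sum(h$episode_count + h$long_episode_count)
      tibble(
        epoch_id = ep$epoch_id,
        patient_id = ep$patient_id,
        events_per_hour = if (hours > 0) total_events / hours else NA_real_,
        pattern_detections_per_hour = if (hours > 0) detections / hours else NA_real_,
        stimulations_per_episode =
          if (episodes > 0) sum(h$therapy_count) / episodes else NA_real_,
        pct_days_at_limit =
          if (nrow(h) > 0)
            100 * mean(h$therapy_count >= ep$daily_therapy_limit) else NA_real_,
        n_days_valid = nrow(h),
        n_days_missing = nrow(h_all) - nrow(h)
      )
    }) |>
    list_rbind() |>
    left_join(select(stim_start, "patient_id", "days_to_stim_enabled"),
              by = "patient_id")
}

rowwise_epochs <- function(epochs) {
  map(seq_len(nrow(epochs)), function(i) epochs[i, ])
}

#' Weighted EIPs per month
#'
#' The weighted EIP fraction (per-stratum TP/(TP+FP) combined with the
#' normalized weights) applied to the total history episode count, scaled to
#' a 30.44-day month.
#'
#' @inheritParams compute_weight_table
#' @param wt An `rns_weights`.
#' @return Tibble with `epoch_id`, `eip_fraction`, `history_episodes`,
#'   `eips_per_month`.
#' @export
eip_rate <- function(conf, wt, histogram_daily, epochs) {
  frac <- join_conf_weights(conf, wt) |>
    mutate(prec = ifelse(.data$tp + .data$fp > 0,
                         .data$tp / (.data$tp + .data$fp), NA_real_)) |>
    summarise(
      eip_fraction = {
        ok <- !.data$excluded & !is.na(.data$prec)
        if (!any(ok)) NA_real_
        else sum(.data$prec[ok] * .data$normalized_weight[ok]) /
          sum(.data$normalized_weight[ok])
      },
      .by = "epoch_id"
    )
  frac |>
    left_join(epochs, by = "epoch_id") |>
    rowwise_epochs() |>
    map(function(ep) {
      h <- hist_in_epoch(histogram_daily, ep)
      n_eps <- sum(h$episode_count + h$long_episode_count)
      days <- as.numeric(difftime(ep$end, ep$start, units = "days"))
      if (n_eps == 0) {
        warn(paste0("no history episodes in epoch ", ep$epoch_id,
                    "; EIPs/month reported as 0"))
      }
      tibble(epoch_id = ep$epoch_id,
             eip_fraction = ep$eip_fraction,
             history_episodes = n_eps,
             eips_per_month =
               if (n_eps == 0) 0
               else (ep$eip_fraction %na% 0) * n_eps / (days / DAYS_PER_MONTH))
    }) |>
    list_rbind()
}

#' Per-phase charge density of one stimulation pulse
#'
#' `current_ma * pulse_width_us * 1e-3 / electrode_area_cm2` microcoulombs
#' per square centimetre: the single-phase charge of a biphasic,
#' charge-balanced pulse divided by the electrode surface area (the device
#' programming convention).
#'
#' @param current_ma Current in milliamps.
#' @param pulse_width_us Pulse width in microseconds.
#' @param electrode_area_cm2 Electrode surface area in cm^2.
#' @return Charge density in uC/cm^2 per pulse phase.
#' @export
pulse_charge_density <- function(current_ma, pulse_width_us, electrode_area_cm2) {
  current_ma * pulse_width_us * 1e-3 / electrode_area_cm2
}

#' Cumulative stimulation charge density at a horizon
#'
#' Accumulates per-hemisphere charge density from delivered therapy counts in
#' the daily history. Each counted therapy delivers all its configured bursts;
#' per burst the dose is `pulses_per_burst x pulse_charge_density`. Delivered
#' counts are apportioned to therapy slots in configured order (every episode
#' receives its first therapy before any receives its second). Days flagged
#' `histogram_data_missing` are excluded.
#'
#' @param histogram_daily Daily history table.
#' @param epochs Epochs table.
#' @param bursts Burst-configuration table (canonical `bursts` schema).
#' @param horizon_days Accumulation horizon in days post-implant (first epoch
#'   start); default 8.5 months of 30.44 days.
#' @return Tibble with one row per epoch per hemisphere:
#'   `dose_uC_per_cm2`, plus `therapies_counted`.
#' @export
charge_dose <- function(histogram_daily, epochs, bursts,
                        horizon_days = 8.5 * DAYS_PER_MONTH) {
  if (nrow(bursts) > 0) {
    bad <- is.na(bursts$electrode_area_cm2) | bursts$electrode_area_cm2 <= 0
    if (any(bad)) {
      abort(paste0("missing or invalid electrode area for burst(s): ",
                   paste(bursts$epoch_id[bad], bursts$therapy_index[bad],
                         bursts$burst_index[bad], sep = "/", collapse = ", ")))
    }
  }
  implant <- epochs |>
    summarise(implant = min(.data$start), .by = "patient_id")
  epochs |>
    rowwise_epochs() |>
    map(function(ep) {
      imp <- implant$implant[implant$patient_id == ep$patient_id]
      h <- hist_in_epoch(histogram_daily, ep) |>
        filter(as.numeric(.data$date - as.Date(imp, tz = "UTC")) < horizon_days)
      bu <- filter(bursts, .data$epoch_id == ep$epoch_id) |>
        mutate(dose_per_delivery =
                 pulses_per_burst(.data$frequency_hz, .data$duration_ms) *
                 pulse_charge_density(.data$current_ma, .data$pulse_width_us,
                                      .data$electrode_area_cm2))
      k <- if (nrow(bu) > 0) max(bu$therapy_index) else 0L
      slot_counts <- rep(0, max(k, 1L))
      for (i in seq_len(nrow(h))) {
        t_d <- h$therapy_count[i]
        ep_d <- h$episode_count[i] + h$long_episode_count[i]
        if (t_d <= 0) next
        if (k == 0L) next
        if (ep_d == 0) {
          slot_counts[1] <- slot_counts[1] + t_d
        } else {
          nj <- pmin(pmax(t_d - (seq_len(k) - 1) * ep_d, 0), ep_d)
          leftover <- t_d - sum(nj)
          if (leftover > 0) nj[k] <- nj[k] + leftover
          slot_counts <- slot_counts + nj
        }
      }
      if (nrow(bu) == 0) {
        return(tibble(epoch_id = ep$epoch_id, patient_id = ep$patient_id,
                      hemisphere = "UNKNOWN", dose_uC_per_cm2 = 0,
                      therapies_counted = sum(h$therapy_count)))
      }
      bu |>
        mutate(delivered = slot_counts[.data$therapy_index],
               dose = .data$delivered * .data$dose_per_delivery) |>
        summarise(dose_uC_per_cm2 = sum(.data$dose), .by = "hemisphere") |>
        mutate(epoch_id = ep$epoch_id, patient_id = ep$patient_id,
               therapies_counted = sum(h$therapy_count), .before = 1)
    }) |>
    list_rbind()
}
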