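# End-to-end evaluation: dataset -> per-epoch metrics -> agreement report.

#' Per-epoch standard and weighted metrics
#'
#' Assembles the full per-epoch metric table: standard (snippet-only pooled)
#' accuracy/sensitivity/specificity/latency, the history-weighted versions
#' (both normalized and literal raw-weight sums), event and therapy rates,
#' weighted EIPs per month, and cumulative charge density at the dose
#' horizon.
#'
#' @param ds An `rns_dataset`.
#' @param negative_attribution Passed to [aggregate_epoch_confusion()].
#' @param dose_horizon_days Passed to [charge_dose()].
#' @return One row per epoch.
#' @export
epoch_metrics <- function(ds,
                          negative_attribution = c("replicate_pooled", "none"),
                          dose_horizon_days = 8.5 * DAYS_PER_MONTH) {
  negative_attribution <- match.arg(negative_attribution)
  conf <- aggregate_epoch_confusion(ds$recordings, ds$epochs,
                                    negative_attribution = negative_attribution)
  std <- standard_epoch_metrics(conf) |>
    rename_with(~ paste0("standard_", .x),
                c("accuracy", "sensitivity", "specificity")) |>
    rename(standard_latency_s = "mean_latency_s")
  wt <- compute_weight_table(conf, ds$histogram_daily, ds$epochs)
  wtd <- weighted_epoch_metrics(conf, wt)
  lit <- weighted_epoch_metrics(conf, wt, literal = TRUE) |>
    rename_with(~ sub("^weighted_", "literal_weighted_", .x), -"epoch_id")
  rates <- event_rate_metrics(ds$histogram_daily, ds$activity_log, ds$epochs)
  eip <- eip_rate(conf, wt, ds$histogram_daily, ds$epochs) |>
    select("epoch_id", "eip_fraction", "eips_per_month")
  dose <- charge_dose(ds$histogram_daily, ds$epochs, ds$bursts,
                      horizon_days = dose_horizon_days) |>
    summarise(dose_total_uC_per_cm2 = sum(.data$dose_uC_per_cm2),
              dose_left_uC_per_cm2 =
                sum(.data$dose_uC_per_cm2[.data$hemisphere == "LEFT"]),
              dose_right_uC_per_cm2 =
                sum(.data$dose_uC_per_cm2[.data$hemisphere == "RIGHT"]),
              .by = "epoch_id")
  ds$epochs |>
    select("epoch_id", "patient_id", "start", "end") |>
    left_join(std, by = "epoch_id") |>
    left_join(wtd, by = "epoch_id") |>
    left_join(lit, by = "epoch_id") |>
    left_join(select(rates, -"patient_id"), by = "epoch_id") |>
    left_join(eip, by = "epoch_id") |>
    left_join(dose, by = "epoch_id")
}

# estimated EIPs per calendar month: each day's history episodes scaled by
# the weighted EIP fraction of the epoch the day falls in
monthly_eip_estimates <- function(ds, eip_fractions) {
  day_epoch <- ds$histogram_daily |>
    filter(!.data$histogram_data_missing) |>
    left_join(ds$epochs |>
                mutate(start_date = as.Date(.data$start, tz = "UTC"),
                       end_date = as.Date(.data$end - 1, tz = "UTC")) |>
                select("epoch_id", "patient_id", "start_date", "end_date"),
              by = "patient_id", relationship = "many-to-many") |>
    filter(.data$date >= .data$start_date, .data$date <= .data$end_date) |>
    left_join(eip_fractions, by = "epoch_id") |>
    mutate(month = format(.data$date, "%Y-%m"),
           est = (.data$episode_count + .data$long_episode_count) *
             (.data$eip_fraction %na% 0))
  day_epoch |>
    summarise(estimated_eips = sum(.data$est), .by = c("patient_id", "month"))
}

#' Evaluate a dataset end-to-end
#'
#' Runs the full pipeline: validation, per-epoch standard and weighted
#' metrics, standard-vs-weighted agreement statistics, logging completeness,
#' cross-epoch heterogeneity, and (when monthly seizure reports are present)
#' the EIP-vs-reported-seizure correlation.
#'
#' @param ds An `rns_dataset` or a path to a canonical dataset directory.
#' @param negative_attribution,dose_horizon_days See [epoch_metrics()].
#' @param loa_multiplier,clinical_threshold See [agreement_table()].
#' @param strict Abort when validation reports errors (default TRUE).
#' @return An `rns_evaluation`: list of tibbles `epoch_metrics`, `weights`,
#'   `agreement`, `completeness`, `heterogeneity`, `patient_summary`,
#'   `correlation`, plus the `validation` report.
#' @export
evaluate_dataset <- function(ds,
                             negative_attribution = c("replicate_pooled", "none"),
                             dose_horizon_days = 8.5 * DAYS_PER_MONTH,
                             loa_multiplier = 1.96,
                             clinical_threshold = 0.05,
                             strict = TRUE) {
  if (is.character(ds)) ds <- load_dataset(ds)
  negative_attribution <- match.arg(negative_attribution)
  val <- validate_dataset(ds)
  if (strict && any(val$severity == "error")) {
    abort(paste0("dataset validation failed:\n",
                 paste(sprintf("  [%s] %s (%s)", val$code, val$message, val$ids)[
                   val$severity == "error"], collapse = "\n")))
  }
  conf <- aggregate_epoch_confusion(ds$recordings, ds$epochs,
                                    negative_attribution = negative_attribution)
  wt <- compute_weight_table(conf, ds$histogram_daily, ds$epochs)
  em <- epoch_metrics(ds, negative_attribution = negative_attribution,
                      dose_horizon_days = dose_horizon_days)
  agree <- if (nrow(em) >= 2) {
    agreement_table(em, loa_multiplier = loa_multiplier,
                    clinical_threshold = clinical_threshold)
  } else NULL
  comp <- completeness(ds$activity_log, ds$event_list, ds$histogram_daily,
                       ds$recordings)
  het <- tryCatch(
    heterogeneity(em, c("weighted_accuracy", "weighted_sensitivity",
                        "weighted_specificity", "weighted_latency_s")),
    error = function(e) NULL)
  patient_summary <- em |>
    summarise(n_epochs = n(),
              across(c("standard_accuracy", "weighted_accuracy",
                       "standard_sensitivity", "weighted_sensitivity",
                       "standard_specificity", "weighted_specificity",
                       "events_per_hour", "stimulations_per_episode",
                       "eips_per_month"),
                     ~ mean(.x, na.rm = TRUE)),
              dose_total_uC_per_cm2 = sum(.data$dose_total_uC_per_cm2, na.rm = TRUE),
              dose_left_uC_per_cm2 = sum(.data$dose_left_uC_per_cm2, na.rm = TRUE),
              dose_right_uC_per_cm2 = sum(.data$dose_right_uC_per_cm2, na.rm = TRUE),
              .by = "patient_id")
  correlation <- NULL
  if (nrow(ds$seizure_reports) > 0) {
    monthly <- monthly_eip_estimates(
      ds, eip_rate(conf, wt, ds$histogram_daily, ds$epochs) |>
        select("epoch_id", "eip_fraction")) |>
      inner_join(ds$seizure_reports, by = c("patient_id", "month"))
    correlation <- tryCatch(
      pearson_corr(monthly, .data$estimated_eips, .data$reported_seizures),
      error = function(e) NULL)
    if (!is.null(correlation)) correlation$n_months <- nrow(monthly)
  }
  structure(
    list(epoch_metrics = em, weights = as_tibble(wt),
         agreement = agree, completeness = comp, heterogeneity = het,
         patient_summary = patient_summary, correlation = correlation,
         validation = val,
         options = list(negative_attribution = negative_attribution,
                        dose_horizon_days = dose_horizon_days,
                        loa_multiplier = loa_multiplier,
                        clinical_threshold = clinical_threshold)),
    class = "rns_evaluation"
  )
}

#' @export
print.rns_evaluation <- function(x, ...) {
  cat("<rns_evaluation>\n")
  cat("  epochs evaluated:", nrow(x$epoch_metrics), "\n")
  if (!is.null(x$agreement)) {
    cat("  agreement (standard - weighted):\n")
    for (i in seq_len(nrow(x$agreement))) {
      r <- x$agreement[i, ]
      cat(sprintf("    %-12s bias %+.4f, LoA [%+.4f, %+.4f], p = %.3g\n",
                  r$metric, r$bias, r$loa_low, r$loa_high, r$p_value))
    }
  }
  invisible(x)
}

#' Run the evaluation workflow and write report tables
#'
#' Loads (or accepts) a dataset, evaluates it, writes the report tables and a
#' machine-readable run manifest to `out_path`.
#'
#' @inheritParams evaluate_dataset
#' @param input Dataset directory or `rns_dataset`.
#' @param out_path Output directory.
#' @return The `rns_evaluation`, invisibly.
#' @export
run_evaluate <- function(input, out_path,
                         negative_attribution = c("replicate_pooled", "none"),
                         dose_horizon_days = 8.5 * DAYS_PER_MONTH,
                         loa_multiplier = 1.96,
                         clinical_threshold = 0.05) {
  negative_attribution <- match.arg(negative_attribution)
  checksums <- NULL
  if (is.character(input)) {
    files <- list.files(input, pattern = "\\.(csv|yaml)$", full.names = TRUE)
    checksums <- as.list(tools::md5sum(files))
    names(checksums) <- basename(files)
  }
  ds <- if (is.character(input)) load_dataset(input) else input
  ev <- evaluate_dataset(ds,
                         negative_attribution = negative_attribution,
                         dose_horizon_days = dose_horizon_days,
                         loa_multiplier = loa_multiplier,
                         clinical_threshold = clinical_threshold)
  write_report_tables(ev, out_path)
  manifest <- list(
    tool = "rnsmetrics",
    version = as.character(utils::packageVersion("rnsmetrics")),
    schema_version = ds$schema_version,
    options = ev$options,
    input_checksums = checksums
  )
  jsonlite::write_json(manifest, file.path(out_path, "run_manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(ev)
}

#' Simulate a dataset and write it to disk
#'
#' @param cfg An `rns_sim_config`, or a path to a YAML file of
#'   [simulation_config()] arguments.
#' @param out_path Output directory for the canonical dataset (ground truth
#'   is written under `truth/`).
#' @return The simulation (list with `dataset` and `truth`), invisibly.
#' @export
run_simulate <- function(cfg, out_path) {
  if (is.character(cfg)) {
    args <- yaml::read_yaml(cfg)
    if (!is.null(args$bursts)) args$bursts <- as_tibble(args$bursts)
    if (!is.null(args$slot_reservation)) {
      args$slot_reservation <- unlist(args$slot_reservation)
    }
    cfg <- do.call(simulation_config, args)
  }
  stopifnot(inherits(cfg, "rns_sim_config"))
  sim <- simulate_dataset(cfg)
  render_dataset(sim$dataset, out_path, truth = sim$truth)
  manifest <- list(
    tool = "rnsmetrics",
    version = as.character(utils::packageVersion("rnsmetrics")),
    seed = cfg$seed,
    duration_days = cfg$duration_days,
    n_epochs = cfg$n_epochs,
    patient_id = cfg$patient_id
  )
  jsonlite::write_json(manifest, file.path(out_path, "run_manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(sim)
}
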