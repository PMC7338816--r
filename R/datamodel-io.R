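# Canonical on-disk schemas and dataset IO.
#
# A dataset is a directory of UTF-8 CSV files (one per logging tier) plus an
# optional dataset.yaml naming file locations and device storage constants.
# All timestamps are ISO-8601 UTC at 1-second resolution; within-recording
# offsets are floating-point seconds relative to recording start.

DEFAULT_FILES <- c(
  epochs           = "epochs.csv",
  bursts           = "bursts.csv",
  recordings       = "recordings.csv",
  event_list       = "event_list.csv",
  activity_log     = "activity_log.csv",
  histogram_daily  = "histogram_daily.csv",
  histogram_hourly = "histogram_hourly.csv",
  seizure_reports  = "seizure_reports.csv"
)

DEFAULT_DEVICE <- list(
  ecog_slots = 4L,
  event_list_capacity = 700L,
  hourly_histogram_cap = 255L
)

# readr column specifications, one per canonical table
dataset_schemas <- function() {
  T_ <- readr::col_datetime()
  list(
    epochs = readr::cols(
      epoch_id = "c", patient_id = "c", start = T_, end = T_,
      enabled_patterns = "c", daily_therapy_limit = "i",
      long_episode_threshold_s = "d", stimulation_enabled = "l"
    ),
    bursts = readr::cols(
      epoch_id = "c", therapy_index = "i", burst_index = "i",
      current_ma = "d", pulse_width_us = "d", frequency_hz = "d",
      duration_ms = "d", cathode_electrodes = "c", anode_electrodes = "c",
      electrode_area_cm2 = "d", hemisphere = "c"
    ),
    recordings = readr::cols(
      recording_id = "c", patient_id = "c", epoch_id = "c",
      trigger_type = "c", start_time = T_, duration_s = "d",
      has_first_episode = "l", fe_onset_s = "d", fe_triggering_pattern = "c",
      fe_episode_class = "c", fe_in_progress_at_start = "l",
      fe_first_detection_s = "d", fe_therapy_times_s = "c",
      eip_present = "l", eip_onset_s = "d", laterality = "c"
    ),
    event_list = readr::cols(
      patient_id = "c", interrogation_time = T_, episode_onset = T_,
      triggering_pattern = "c", episode_class = "c", therapy_count = "i"
    ),
    activity_log = readr::cols(
      patient_id = "c", interrogation_time = T_, pattern_a_events = "i",
      pattern_b_events = "i", saturations = "i", magnet_swipes = "i"
    ),
    histogram_daily = readr::cols(
      patient_id = "c", date = readr::col_date(),
      a1_count = "i", a2_count = "i", b1_count = "i", b2_count = "i",
      episode_count = "i", long_episode_count = "i", therapy_count = "i",
      saturation_count = "i", magnet_count = "i",
      histogram_data_missing = "l", diagnostic_data_missing = "l"
    ),
    histogram_hourly = readr::cols(
      patient_id = "c", date = readr::col_date(), hour = "i",
      event_count = "i", capped = "l"
    ),
    seizure_reports = readr::cols(
      patient_id = "c", month = "c", reported_seizures = "d"
    )
  )
}

empty_table <- function(name) {
  spec <- dataset_schemas()[[name]]
  cls <- vapply(spec$cols, function(x) class(x)[[1]], character(1))
  cols <- lapply(cls, function(cl) {
    switch(cl,
      collector_character = character(),
      collector_integer   = integer(),
      collector_double    = double(),
      collector_logical   = logical(),
      collector_datetime  = as.POSIXct(character(), tz = "UTC"),
      collector_date      = as.Date(character())
    )
  })
  as_tibble(cols)
}

new_rns_dataset <- function(tables, device = DEFAULT_DEVICE,
                            schema_version = SCHEMA_VERSION) {
  for (nm in names(DEFAULT_FILES)) {
    if (is.null(tables[[nm]])) tables[[nm]] <- empty_table(nm)
  }
  structure(
    c(tables[names(DEFAULT_FILES)],
      list(device = device, schema_version = schema_version)),
    class = "rns_dataset"
  )
}

#' @export
print.rns_dataset <- function(x, ...) {
  cat("<rns_dataset> schema", x$schema_version, "\n")
  for (nm in names(DEFAULT_FILES)) {
    cat(sprintf("  %-17s %6d rows\n", nm, nrow(x[[nm]])))
  }
  cat("  device: ", paste(names(x$device), unlist(x$device),
                          sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Load a canonical dataset directory
#'
#' Reads the canonical CSV files (plus an optional `dataset.yaml` naming file
#' locations and device storage constants), validates schemas and referential
#' integrity, and returns a typed dataset.
#'
#' @param path Directory containing the canonical files.
#' @return An `rns_dataset`: a named list of tibbles (`epochs`, `bursts`,
#'   `recordings`, `event_list`, `activity_log`, `histogram_daily`,
#'   `histogram_hourly`, `seizure_reports`) plus `device` constants and the
#'   schema version.
#' @seealso [validate_dataset()], [write_dataset()]
#' @export
load_dataset <- function(path) {
  if (!dir.exists(path)) abort(paste0("dataset directory not found: ", path))
  files <- DEFAULT_FILES
  device <- DEFAULT_DEVICE
  schema_version <- SCHEMA_VERSION
  cfg_path <- file.path(path, "dataset.yaml")
  if (file.exists(cfg_path)) {
    cfg <- yaml::read_yaml(cfg_path)
    if (!is.null(cfg$files)) files[names(cfg$files)] <- unlist(cfg$files)
    if (!is.null(cfg$device)) device <- modifyList(device, cfg$device)
    if (!is.null(cfg$schema_version)) schema_version <- as.character(cfg$schema_version)
  }
  schemas <- dataset_schemas()
  tables <- list()
  for (nm in names(files)) {
    fp <- file.path(path, files[[nm]])
    if (!file.exists(fp)) {
      abort(paste0("missing canonical file: ", files[[nm]], " (", nm, ")"))
    }
    hdr <- names(readr::read_csv(fp, n_max = 0, col_types = readr::cols(),
                                 show_col_types = FALSE))
    expected <- names(schemas[[nm]]$cols)
    missing_cols <- setdiff(expected, hdr)
    if (length(missing_cols) > 0) {
      abort(paste0("schema mismatch in ", files[[nm]], ": missing column(s) ",
                   paste(missing_cols, collapse = ", ")))
    }
    tbl <- readr::read_csv(fp, col_types = schemas[[nm]], show_col_types = FALSE)
    tbl <- tbl[, expected]
    for (cl in which(vapply(tbl, inherits, logical(1), "POSIXct"))) {
      attr(tbl[[cl]], "tzone") <- "UTC"
    }
    tables[[nm]] <- tbl
  }
  ds <- new_rns_dataset(tables, device, schema_version)
  bad_epoch <- setdiff(unique(ds$recordings$epoch_id), ds$epochs$epoch_id)
  if (length(bad_epoch) > 0) {
    abort(paste0("recordings reference unknown epoch_id(s): ",
                 paste(bad_epoch, collapse = ", ")))
  }
  bad_burst <- setdiff(unique(ds$bursts$epoch_id), ds$epochs$epoch_id)
  if (length(bad_burst) > 0) {
    abort(paste0("bursts reference unknown epoch_id(s): ",
                 paste(bad_burst, collapse = ", ")))
  }
  ds
}

#' Write a dataset to a canonical directory
#'
#' Inverse of [load_dataset()]; writes every table plus `dataset.yaml`.
#' Round-tripping preserves all fields at 1-second timestamp resolution.
#'
#' @param ds An `rns_dataset`.
#' @param path Output directory (created if absent).
#' @return Tibble manifest of written files (invisibly).
#' @export
write_dataset <- function(ds, path) {
  stopifnot(inherits(ds, "rns_dataset"))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  written <- character()
  for (nm in names(DEFAULT_FILES)) {
    fp <- file.path(path, DEFAULT_FILES[[nm]])
    readr::write_csv(ds[[nm]], fp)
    written <- c(written, fp)
  }
  yaml::write_yaml(
    list(schema_version = ds$schema_version,
         files = as.list(DEFAULT_FILES),
         device = ds$device),
    file.path(path, "dataset.yaml")
  )
  invisible(tibble(file = c(written, file.path(path, "dataset.yaml"))))
}

validation_row <- function(severity, code, message, ids) {
  tibble(severity = severity, code = code, message = message,
         ids = paste(ids, collapse = ";"))
}

#' Validate a loaded dataset
#'
#' Checks the dataset invariants and returns a report instead of raising:
#' errors for invariant violations (overlapping epochs, negative counts,
#' EIP onset without an EIP, pattern triggers without an episode record),
#' warnings for suspicious-but-legal states (histogram totals differing from
#' activity-log totals, epochs without reviewed recordings).
#'
#' @param ds An `rns_dataset`.
#' @return Tibble with columns `severity` ("error"/"warning"), `code`,
#'   `message`, and the offending record `ids`.
#' @export
validate_dataset <- function(ds) {
  stopifnot(inherits(ds, "rns_dataset"))
  out <- list()
  ep <- ds$epochs
  if (nrow(ep) > 0) {
    bad <- ep$epoch_id[!(ep$start < ep$end)]
    if (length(bad) > 0) {
      out <- c(out, list(validation_row("error", "epoch_order",
        "epoch start must precede end", bad)))
    }
    by_pat <- split(ep[order(ep$start), ], ep$patient_id[order(ep$start)])
    for (pe in by_pat) {
      if (nrow(pe) < 2) next
      overlap <- which(head(pe$end, -1) > tail(pe$start, -1))
      for (i in overlap) {
        out <- c(out, list(validation_row("error", "epoch_overlap",
          paste0("overlapping epochs for patient ", pe$patient_id[[1]]),
          c(pe$epoch_id[i], pe$epoch_id[i + 1]))))
      }
    }
    no_rec <- setdiff(ep$epoch_id, unique(ds$recordings$epoch_id))
    if (length(no_rec) > 0) {
      out <- c(out, list(validation_row("warning", "epoch_no_recordings",
        "epoch has no reviewed ECoG recordings", no_rec)))
    }
  }
  rec <- ds$recordings
  if (nrow(rec) > 0) {
    bad <- rec$recording_id[!rec$eip_present %na% FALSE & !is.na(rec$eip_onset_s)]
    if (length(bad) > 0) {
      out <- c(out, list(validation_row("error", "eip_onset_without_eip",
        "eip_onset_s present but eip_present is FALSE", bad)))
    }
    bad <- rec$recording_id[!is.na(rec$eip_onset_s) &
                            (rec$eip_onset_s < 0 | rec$eip_onset_s > rec$duration_s)]
    if (length(bad) > 0) {
      out <- c(out, list(validation_row("error", "eip_onset_range",
        "eip_onset_s outside [0, duration_s]", bad)))
    }
    bad <- rec$recording_id[rec$trigger_type == "PATTERN" & !(rec$has_first_episode %na% FALSE)]
    if (length(bad) > 0) {
      out <- c(out, list(validation_row("error", "pattern_without_episode",
        "PATTERN-triggered recording lacks first-episode fields", bad)))
    }
    bad <- rec$recording_id[!rec$trigger_type %in% TRIGGER_TYPES]
    if (length(bad) > 0) {
      out <- c(out, list(validation_row("error", "bad_trigger_type",
        "unknown trigger_type", bad)))
    }
  }
  hd <- ds$histogram_daily
  if (nrow(hd) > 0) {
    counts <- hd[c("a1_count", "a2_count", "b1_count", "b2_count",
                   "episode_count", "long_episode_count", "therapy_count",
                   "saturation_count", "magnet_count")]
    bad <- hd$patient_id[rowSums(counts < 0, na.rm = TRUE) > 0]
    if (length(bad) > 0) {
      out <- c(out, list(validation_row("error", "negative_histogram_counts",
        "negative histogram counts", unique(bad))))
    }
    ok <- !hd$histogram_data_missing
    mism <- ok & (hd$episode_count + hd$long_episode_count !=
                    hd$a1_count + hd$a2_count + hd$b1_count + hd$b2_count)
    if (any(mism, na.rm = TRUE)) {
      out <- c(out, list(validation_row("warning", "histogram_totals",
        "episode totals inconsistent with pattern totals on non-missing days",
        paste(hd$patient_id[which(mism)], hd$date[which(mism)], sep = "/"))))
    }
  }
  al <- ds$activity_log
  if (nrow(al) > 0) {
    counts <- al[c("pattern_a_events", "pattern_b_events", "saturations",
                   "magnet_swipes")]
    bad <- al$patient_id[rowSums(counts < 0, na.rm = TRUE) > 0]
    if (length(bad) > 0) {
      out <- c(out, list(validation_row("error", "negative_activity_counts",
        "negative activity-log counts", unique(bad))))
    }
    for (pid in unique(al$patient_id)) {
      tt <- al$interrogation_time[al$patient_id == pid]
      if (is.unsorted(tt, strictly = TRUE)) {
        out <- c(out, list(validation_row("error", "interrogations_unsorted",
          "interrogation times not strictly increasing", pid)))
      }
    }
    # histogram totals vs activity-log totals, per patient (warning only)
    if (nrow(hd) > 0) {
      al_tot <- al |>
        summarise(total = sum(.data$pattern_a_events + .data$pattern_b_events +
                                .data$saturations + .data$magnet_swipes),
                  .by = "patient_id")
      hd_tot <- hd |>
        filter(!.data$histogram_data_missing) |>
        summarise(total = sum(.data$a1_count + .data$a2_count + .data$b1_count +
                                .data$b2_count + .data$saturation_count +
                                .data$magnet_count),
                  .by = "patient_id")
      cmp <- inner_join(al_tot, hd_tot, by = "patient_id",
                        suffix = c("_activity", "_histogram"))
      off <- cmp$patient_id[cmp$total_histogram > cmp$total_activity]
      if (length(off) > 0) {
        out <- c(out, list(validation_row("warning", "histogram_exceeds_activity",
          "histogram totals exceed activity-log totals", off)))
      }
    }
  }
  bu <- ds$bursts
  if (nrow(bu) > 0) {
    cath <- strsplit(bu$cathode_electrodes %na% "", ";")
    ano <- strsplit(bu$anode_electrodes %na% "", ";")
    overlap <- map2(cath, ano, intersect)
    bad <- which(lengths(overlap) > 0 | lengths(cath) == 0 | lengths(ano) == 0)
    if (length(bad) > 0) {
      out <- c(out, list(validation_row("error", "bad_electrode_montage",
        "cathode/anode sets must be disjoint and non-empty",
        paste(bu$epoch_id[bad], bu$therapy_index[bad], bu$burst_index[bad],
              sep = "/"))))
    }
    bad <- which(!is.na(bu$electrode_area_cm2) & bu$electrode_area_cm2 <= 0)
    if (length(bad) > 0) {
      out <- c(out, list(validation_row("error", "bad_electrode_area",
        "electrode_area_cm2 must be > 0",
        paste(bu$epoch_id[bad], bu$therapy_index[bad], sep = "/"))))
    }
  }
  if (length(out) == 0) {
    return(tibble(severity = character(), code = character(),
                  message = character(), ids = character()))
  }
  bind_rows(out)
}

#' Write evaluation report tables
#'
#' Writes the per-epoch metrics table, per-patient summary, and (when present)
#' the agreement-statistics table of an evaluation result to a directory, in
#' the canonical CSV format. Re-loading reproduces values to full precision.
#'
#' @param results An `rns_evaluation` (see [evaluate_dataset()]) or a named
#'   list of data frames to write.
#' @param out_path Output directory.
#' @return Tibble manifest of written file paths.
#' @export
write_report_tables <- function(results, out_path) {
  if (inherits(results, "rns_evaluation")) {
    tables <- results[vapply(results, is.data.frame, logical(1))]
  } else if (is.data.frame(results)) {
    tables <- list(epoch_metrics = results)
  } else {
    tables <- results
  }
  tables <- tables[vapply(tables, function(x) is.data.frame(x) && nrow(x) > 0,
                          logical(1))]
  if (length(tables) == 0) abort("no results to write")
  dir.create(out_path, recursive = TRUE, showWarnings = FALSE)
  paths <- character(length(tables))
  for (i in seq_along(tables)) {
    paths[[i]] <- file.path(out_path, paste0(names(tables)[[i]], ".csv"))
    readr::write_csv(tables[[i]], paths[[i]])
  }
  tibble(table = names(tables), file = paths)
}
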