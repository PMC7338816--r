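# Confusion-matrix classification of reviewed ECoG recordings.
#
# A PATTERN-triggered recording is a detector positive: TP when the reviewer
# marked an electrographic ictal pattern (EIP), FP otherwise, stratified by
# (triggering second-order Pattern x episode class). Scheduled and magnet
# recordings sample brain activity independent of the detector and supply the
# pooled negatives: FN when an EIP is present, TN otherwise. Detector latency
# (first detection - EIP onset, seconds; negative values legal) is recorded
# for TP recordings only, excluding recordings that begin with an in-progress
# episode.

#' Classify reviewed ECoG recordings into confusion outcomes
#'
#' @param recordings Tibble of annotated recordings (canonical `recordings`
#'   schema; see [load_dataset()]).
#' @return The input with columns `label` (TP/FP/TN/FN), `stratum_pattern`,
#'   `stratum_class` (NA for pooled negatives), and `latency_s` (defined for
#'   TP recordings not beginning with an in-progress episode).
#' @export
classify_recordings <- function(recordings) {
  rec <- as_tibble(recordings)
  if (nrow(rec) == 0) {
    return(mutate(rec, label = character(), stratum_pattern = character(),
                  stratum_class = character(), latency_s = double()))
  }
  bad <- rec$trigger_type == "PATTERN" & !(rec$has_first_episode %na% FALSE)
  if (any(bad)) {
    abort(paste0("PATTERN-triggered recording(s) without first-episode data: ",
                 paste(rec$recording_id[bad], collapse = ", ")))
  }
  triggered <- rec$trigger_type == "PATTERN"
  eip <- rec$eip_present %na% FALSE
  rec$label <- ifelse(triggered,
                      ifelse(eip, "TP", "FP"),
                      ifelse(eip, "FN", "TN"))
  rec$stratum_pattern <- ifelse(triggered, rec$fe_triggering_pattern, NA_character_)
  rec$stratum_class <- ifelse(triggered, rec$fe_episode_class, NA_character_)
  lat <- rec$fe_first_detection_s - rec$eip_onset_s
  eligible <- rec$label == "TP" & !(rec$fe_in_progress_at_start %na% FALSE)
  rec$latency_s <- ifelse(eligible, lat, NA_real_)
  rec
}

all_strata <- function() {
  tidyr::expand_grid(pattern = PATTERN_LEVELS, episode_class = EPISODE_CLASSES)
}

#' Aggregate per-epoch confusion counts by stratum
#'
#' Partitions classified recordings into the eight (Pattern x episode-class)
#' strata plus pooled negatives from non-triggered (scheduled/magnet)
#' recordings. Non-triggered recordings carry no triggering Pattern, so their
#' TN/FN counts cannot be placed in a stratum directly; under the default
#' `negative_attribution = "replicate_pooled"` policy each stratum receives a
#' share of the pooled negatives proportional to its share of triggered
#' recordings (preserving pooled totals and keeping every supported stratum's
#' accuracy defined); under `"none"` strata carry TP/FP only.
#'
#' @param recordings Annotated recordings for one or more epochs.
#' @param epochs Epochs table (defines which epochs appear in the output even
#'   when empty). Optional; defaults to the epochs present in `recordings`.
#' @param negative_attribution `"replicate_pooled"` (default) or `"none"`.
#' @return An `rns_confusion` tibble: one row per epoch per stratum
#'   (`scope = "stratum"`) with counts `tp`, `fp`, `tn`, `fn`, latency
#'   summaries, and one `scope = "pooled"` row per epoch holding the pooled
#'   totals.
#' @export
aggregate_epoch_confusion <- function(recordings, epochs = NULL,
                                      negative_attribution = c("replicate_pooled", "none")) {
  negative_attribution <- match.arg(negative_attribution)
  cls <- classify_recordings(recordings)
  epoch_ids <- if (!is.null(epochs)) epochs$epoch_id else unique(cls$epoch_id)
  if (length(epoch_ids) == 0) epoch_ids <- NA_character_
  out <- map(epoch_ids, function(eid) {
    ec <- if (is.na(eid)) cls else filter(cls, .data$epoch_id == eid)
    pos <- filter(ec, .data$label %in% c("TP", "FP"))
    neg <- filter(ec, .data$label %in% c("TN", "FN"))
    tn0 <- sum(neg$label == "TN")
    fn0 <- sum(neg$label == "FN")
    strata <- all_strata() |>
      left_join(
        pos |>
          summarise(tp = sum(.data$label == "TP"),
                    fp = sum(.data$label == "FP"),
                    latencies = list(.data$latency_s[!is.na(.data$latency_s)]),
                    .by = c("stratum_pattern", "stratum_class")),
        by = c(pattern = "stratum_pattern", episode_class = "stratum_class")
      ) |>
      mutate(tp = .data$tp %na% 0L, fp = .data$fp %na% 0L,
             latencies = map(.data$latencies,
                             function(x) if (is.numeric(x)) x else double()))
    n_trig <- sum(strata$tp + strata$fp)
    share <- if (n_trig > 0) (strata$tp + strata$fp) / n_trig else rep(0, nrow(strata))
    if (negative_attribution == "replicate_pooled") {
      strata$tn <- tn0 * share
      strata$fn <- fn0 * share
    } else {
      strata$tn <- 0
      strata$fn <- 0
    }
    strata <- strata |>
      mutate(scope = "stratum",
             n_latency = lengths(.data$latencies),
             mean_latency_s = map_dbl(.data$latencies,
                                      function(x) if (length(x)) mean(x) else NA_real_))
    pooled <- tibble(
      pattern = NA_character_, episode_class = NA_character_,
      scope = "pooled",
      tp = sum(strata$tp), fp = sum(strata$fp), tn = tn0, fn = fn0,
      latencies = list(as.double(sort(unlist(strata$latencies)))),
      n_latency = sum(strata$n_latency),
      mean_latency_s = {
        l <- unlist(strata$latencies)
        if (length(l)) mean(l) else NA_real_
      }
    )
    bind_rows(strata, pooled) |> mutate(epoch_id = eid, .before = 1)
  }) |> list_rbind()
  out <- stratum_metrics(out)
  class(out) <- c("rns_confusion", class(out))
  out
}

#' Accuracy, sensitivity and specificity from confusion counts
#'
#' `accuracy = (tp+tn)/(tp+fp+tn+fn)`, `sensitivity = tp/(tp+fn)`,
#' `specificity = tn/(tn+fp)`; a metric whose denominator is zero is
#' undefined (`NA`), never coerced to 0 or 1.
#'
#' @param counts Data frame with columns `tp`, `fp`, `tn`, `fn` (or a list
#'   with those elements).
#' @return The input with `accuracy`, `sensitivity`, `specificity` columns.
#' @export
stratum_metrics <- function(counts) {
  counts <- as_tibble(counts)
  denom <- counts$tp + counts$fp + counts$tn + counts$fn
  counts$accuracy <- ifelse(denom > 0, (counts$tp + counts$tn) / denom, NA_real_)
  pos <- counts$tp + counts$fn
  counts$sensitivity <- ifelse(pos > 0, counts$tp / pos, NA_real_)
  neg <- counts$tn + counts$fp
  counts$specificity <- ifelse(neg > 0, counts$tn / neg, NA_real_)
  counts
}

#' Standard (snippet-only) epoch metrics
#'
#' The standard method pools the reviewed ECoG confusion counts across all
#' strata together with the pooled negatives, with no history weighting;
#' latency is the unweighted mean of all eligible TP latencies.
#'
#' @param conf An `rns_confusion` from [aggregate_epoch_confusion()].
#' @return One row per epoch: `accuracy`, `sensitivity`, `specificity`,
#'   `mean_latency_s`, and the pooled counts.
#' @export
standard_epoch_metrics <- function(conf) {
  conf |>
    filter(.data$scope == "pooled") |>
    select("epoch_id", "tp", "fp", "tn", "fn",
           "accuracy", "sensitivity", "specificity",
           "mean_latency_s", "n_latency") |>
    as_tibble()
}
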