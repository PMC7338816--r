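# Standard-vs-weighted agreement statistics.
#
# Differences are always taken as standard - weighted. The paired signed-rank
# test uses an exact tie-aware null distribution (convolution of the rank
# generating function) for up to 25 nonzero differences and a normal
# approximation with continuity and tie corrections above that. Clinical
# significance follows the >5% mean-absolute-difference convention.

#' Bland-Altman agreement analysis
#'
#' Computes bias (mean of paired differences, `standard - weighted`), the
#' n-1 standard deviation of differences, and limits of agreement
#' `bias +/- loa_multiplier * sd`. Pairs with either value undefined are
#' dropped and counted.
#'
#' @param data Data frame of paired values.
#' @param standard,weighted Columns holding the two methods' values
#'   (tidy-eval).
#' @param loa_multiplier Limits-of-agreement multiplier (default 1.96).
#' @return An `rns_bland_altman` object; see [tidy()][generics::tidy] for the
#'   (mean, difference) pairs and [glance()][generics::glance] for the
#'   one-row summary.
#' @export
bland_altman <- function(data, standard, weighted, loa_multiplier = 1.96) {
  s <- dplyr::pull(data, {{ standard }})
  w <- dplyr::pull(data, {{ weighted }})
  ok <- !is.na(s) & !is.na(w)
  n_dropped <- sum(!ok)
  s <- s[ok]; w <- w[ok]
  if (length(s) < 2) abort("bland_altman requires >= 2 pairs with both values defined")
  d <- s - w
  bias <- mean(d)
  sd_diff <- sd(d)
  structure(
    list(
      bias = bias, sd_diff = sd_diff,
      loa_low = bias - loa_multiplier * sd_diff,
      loa_high = bias + loa_multiplier * sd_diff,
      loa_multiplier = loa_multiplier,
      n_pairs = length(d), n_dropped = n_dropped,
      pairs = tibble(mean = (s + w) / 2, difference = d)
    ),
    class = "rns_bland_altman"
  )
}

#' @export
print.rns_bland_altman <- function(x, ...) {
  cat(sprintf(
    "Bland-Altman (standard - weighted): bias %.6g, sd %.6g, LoA [%.6g, %.6g], n = %d\n",
    x$bias, x$sd_diff, x$loa_low, x$loa_high, x$n_pairs))
  invisible(x)
}

# Exact null distribution of the positive signed-rank sum with (possibly
# tied, half-integer) ranks, on the doubled-rank integer scale. Returns the
# probability vector over 0..sum(2*ranks).
signed_rank_null <- function(ranks) {
  r2 <- as.integer(round(2 * ranks))
  probs <- c(1, rep(0, sum(r2)))
  for (r in r2) {
    shifted <- c(rep(0, r), probs[seq_len(length(probs) - r)])
    probs <- (probs + shifted) / 2
  }
  probs
}

#' Wilcoxon signed-rank test for paired metric values
#'
#' Two-sided test on paired differences (zero differences dropped). For up to
#' `exact_limit` nonzero differences the p-value is exact, from the tie-aware
#' null distribution of the signed-rank sum; above that a normal
#' approximation with continuity and tie corrections is used. The mean
#' absolute difference across all defined pairs is reported for the >5%
#' clinical-significance comparison.
#'
#' @param data Data frame of paired values, or a numeric vector of
#'   differences.
#' @param standard,weighted Columns holding the two methods' values (ignored
#'   when `data` is a numeric vector of differences).
#' @param exact_limit Largest `n_effective` for which the exact null is used.
#' @return An `rns_signed_rank` object with `statistic` (positive-rank sum),
#'   `p_value`, `n_effective`, `mean_abs_difference`, `method`.
#' @export
wilcoxon_signed_rank <- function(data, standard = NULL, weighted = NULL,
                                 exact_limit = 25L) {
  if (is.numeric(data)) {
    d <- data
  } else {
    s <- dplyr::pull(data, {{ standard }})
    w <- dplyr::pull(data, {{ weighted }})
    ok <- !is.na(s) & !is.na(w)
    d <- s[ok] - w[ok]
  }
  d <- d[!is.na(d)]
  mean_abs <- mean(abs(d))
  nz <- d[d != 0]
  if (length(nz) == 0) abort("degenerate pairs: all differences are zero")
  ranks <- rank(abs(nz))
  stat <- sum(ranks[nz > 0])
  n <- length(nz)
  if (n <= exact_limit) {
    probs <- signed_rank_null(ranks)
    w2 <- as.integer(round(2 * stat))
    p_le <- sum(probs[seq_len(w2 + 1)])
    p_ge <- sum(probs[seq.int(w2 + 1, length(probs))])
    p <- min(1, 2 * min(p_le, p_ge))
    method <- "exact"
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(ranks)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    cc <- 0.5 * sign(stat - mu)
    z <- (stat - mu - cc) / sqrt(sigma2)
    p <- min(1, 2 * pnorm(-abs(z)))
    method <- "normal approximation"
  }
  structure(
    list(statistic = stat, p_value = p, n_pairs = length(d),
         n_effective = n, mean_abs_difference = mean_abs, method = method),
    class = "rns_signed_rank"
  )
}

#' @export
print.rns_signed_rank <- function(x, ...) {
  cat(sprintf(
    "Wilcoxon signed rank (%s): V = %g, p = %.4g, n_eff = %d, mean |diff| = %.4g\n",
    x$method, x$statistic, x$p_value, x$n_effective, x$mean_abs_difference))
  invisible(x)
}

#' Logging completeness relative to the Activity Log
#'
#' The Activity Log is the source of truth: total events are the sum of its
#' pattern detection, saturation, and magnet swipe counts per patient.
#' Completeness of stored ECoG recordings, Event List entries, and histogram
#' counts (non-missing days) is each expressed as a percentage of total
#' events, capped at 100 with a warning when exceeded.
#'
#' @param activity_log,event_list,histogram_daily,recordings Canonical tables.
#' @return One row per patient: `total_events`, `ecog_pct`, `event_list_pct`,
#'   `histogram_pct` (NA with a warning when `total_events` is zero).
#' @export
completeness <- function(activity_log, event_list, histogram_daily, recordings) {
  totals <- activity_log |>
    summarise(total_events = sum(.data$pattern_a_events + .data$pattern_b_events +
                                   .data$saturations + .data$magnet_swipes),
              .by = "patient_id")
  stored <- recordings |>
    filter(.data$trigger_type %in% c("PATTERN", "MAGNET", "SATURATION")) |>
    summarise(n_ecog = n(), .by = "patient_id")
  entries <- event_list |> summarise(n_entries = n(), .by = "patient_id")
  hist_ev <- histogram_daily |>
    filter(!.data$histogram_data_missing) |>
    summarise(n_hist = sum(.data$a1_count + .data$a2_count + .data$b1_count +
                             .data$b2_count + .data$saturation_count +
                             .data$magnet_count),
              .by = "patient_id")
  out <- totals |>
    left_join(stored, by = "patient_id") |>
    left_join(entries, by = "patient_id") |>
    left_join(hist_ev, by = "patient_id") |>
    mutate(across(c("n_ecog", "n_entries", "n_hist"), ~ .x %na% 0L),
           ecog_pct = 100 * .data$n_ecog / .data$total_events,
           event_list_pct = 100 * .data$n_entries / .data$total_events,
           histogram_pct = 100 * .data$n_hist / .data$total_events)
  if (any(out$total_events == 0)) {
    warn("zero total events for some patient(s); completeness undefined")
    out <- out |>
      mutate(across(c("ecog_pct", "event_list_pct", "histogram_pct"),
                    ~ ifelse(.data$total_events == 0, NA_real_, .x)))
  }
  over <- with(out, pmax(ecog_pct, event_list_pct, histogram_pct, na.rm = TRUE)) > 100
  if (any(over, na.rm = TRUE)) {
    warn(paste0("completeness above 100% capped for patient(s): ",
                paste(out$patient_id[which(over)], collapse = ", ")))
    out <- out |>
      mutate(across(c("ecog_pct", "event_list_pct", "histogram_pct"),
                    ~ pmin(.x, 100)))
  }
  select(out, "patient_id", "total_events", "ecog_pct", "event_list_pct",
         "histogram_pct")
}

#' Pearson correlation of device-derived EIPs and reported seizures
#'
#' Sample Pearson r with the two-sided p-value from the t transform
#' (delegated to [stats::cor.test()]).
#'
#' @param data Data frame of monthly pairs.
#' @param eips,seizures Columns holding monthly EIP estimates and reported
#'   seizure counts.
#' @return One-row tibble: `r`, `p_value`, `n`.
#' @export
pearson_corr <- function(data, eips, seizures) {
  x <- dplyr::pull(data, {{ eips }})
  y <- dplyr::pull(data, {{ seizures }})
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) abort("pearson_corr requires >= 3 complete pairs")
  if (sd(x) == 0 || sd(y) == 0) abort("zero variance in one coordinate")
  ct <- cor.test(x, y, method = "pearson")
  tibble(r = unname(ct$estimate), p_value = ct$p.value, n = length(x))
}

#' Cross-epoch heterogeneity summary
#'
#' Mean, median, 25th/75th percentiles (linear-interpolation, type-7
#' quantiles) and range of each metric across epochs or patients.
#'
#' @param data Data frame with one row per epoch/patient.
#' @param cols Tidy-selection of metric columns to summarise.
#' @return One row per metric: `mean`, `median`, `q25`, `q75`, `min`, `max`,
#'   `n`.
#' @export
heterogeneity <- function(data, cols) {
  long <- data |>
    select({{ cols }}) |>
    tidyr::pivot_longer(dplyr::everything(), names_to = "metric") |>
    filter(!is.na(.data$value))
  if (nrow(long) == 0) abort("no defined values to summarise")
  long |>
    summarise(mean = mean(.data$value),
              median = median(.data$value),
              q25 = quantile(.data$value, 0.25, type = 7, names = FALSE),
              q75 = quantile(.data$value, 0.75, type = 7, names = FALSE),
              min = min(.data$value),
              max = max(.data$value),
              n = n(),
              .by = "metric")
}

#' Standard-vs-weighted agreement table
#'
#' One row per metric: Bland-Altman bias and limits of agreement, the
#' signed-rank test, the mean absolute difference, and the clinical
#' significance flag (mean |difference| above `clinical_threshold`; applied to
#' proportion metrics, NA for latency, whose units differ).
#'
#' @param epoch_metrics Per-epoch metrics with `standard_<m>` and
#'   `weighted_<m>` column pairs (see [epoch_metrics()]).
#' @param metrics Metric stems to compare.
#' @param loa_multiplier Limits-of-agreement multiplier.
#' @param clinical_threshold Clinical-significance threshold on the mean
#'   absolute difference (default 0.05, i.e. 5 percentage points on a
#'   proportion).
#' @return Tibble with one row per metric.
#' @export
agreement_table <- function(epoch_metrics,
                            metrics = c("accuracy", "sensitivity",
                                        "specificity", "latency_s"),
                            loa_multiplier = 1.96,
                            clinical_threshold = 0.05) {
  map(metrics, function(m) {
    s_col <- paste0("standard_", m)
    w_col <- paste0("weighted_", m)
    if (!all(c(s_col, w_col) %in% names(epoch_metrics))) return(NULL)
    df <- tibble(s = epoch_metrics[[s_col]], w = epoch_metrics[[w_col]]) |>
      filter(!is.na(.data$s), !is.na(.data$w))
    n_dropped <- nrow(epoch_metrics) - nrow(df)
    if (nrow(df) < 2) {
      return(tibble(metric = m, n_pairs = nrow(df), n_dropped = n_dropped))
    }
    ba <- bland_altman(df, .data$s, .data$w, loa_multiplier = loa_multiplier)
    wr <- tryCatch(wilcoxon_signed_rank(df, .data$s, .data$w),
                   error = function(e) NULL)
    is_prop <- !grepl("latency", m)
    tibble(
      metric = m, n_pairs = ba$n_pairs, n_dropped = n_dropped,
      bias = ba$bias, sd_diff = ba$sd_diff,
      loa_low = ba$loa_low, loa_high = ba$loa_high,
      statistic = if (is.null(wr)) NA_real_ else wr$statistic,
      p_value = if (is.null(wr)) NA_real_ else wr$p_value,
      mean_abs_difference = mean(abs(df$s - df$w)),
      clinically_significant =
        if (is_prop) mean(abs(df$s - df$w)) > clinical_threshold else NA
    )
  }) |> list_rbind()
}
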