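# End-to-end pipelines: raw waveform -> SQI table, and SQI table + ruleset
# -> accept/reject decisions. All stage parameters are configurable through
# a JSON pipeline config; rule thresholds live in a separate ruleset JSON.

SQI_GROUPS <- list(
  perfusion_sqi = "perfusion_sqi",
  kurtosis_sqi = "kurtosis_sqi",
  skewness_sqi = "skewness_sqi",
  entropy_sqi = "entropy_sqi",
  snr_sqi = "snr_sqi",
  relative_power_sqi = "relative_power_sqi",
  zero_crossing_sqi = "zero_crossing_sqi",
  mean_crossing_sqi = "mean_crossing_sqi",
  msq_sqi = "msq_sqi",
  msq_shift_sqi = "msq_shift_sqi",
  ectopic_sqi = "ectopic_sqi",
  qrs_energy_sqi = "qrs_energy_sqi",
  correlogram_sqi = NULL,  # expands by n_peaks
  hrv_time_sqi = c("mean_nni", "sdnn", "sdsd", "rmssd", "cvsd", "cvnni",
                   "pnn_50", "pnn_20", "hr_mean", "hr_std", "hr_min", "hr_max"),
  hrv_freq_sqi = c("lf", "hf", "lf_hf_ratio", "total_power", "vlf"),
  dtw_sqi = c("dtw_mean", "dtw_median", "dtw_std"),
  beat_stats_sqi = c("kurtosis_mean", "kurtosis_median", "kurtosis_std",
                     "skewness_mean", "skewness_median", "skewness_std",
                     "entropy_mean", "entropy_median", "entropy_std"),
  amplitude_ratio_sqi = c("qrs_a_mean", "qrs_a_std"))

#' List the selectable SQI names
#' @return character vector of canonical SQI group names accepted by
#'   [pipeline_config()].
#' @export
list_sqis <- function() names(SQI_GROUPS)

#' Pipeline configuration
#'
#' @param filter a [filter_spec()] or `NULL` for the signal-type default
#'   (Butterworth order 4; 0.5-8 Hz for PPG, 0.5-40 Hz for ECG).
#' @param segment_length_s segment duration, seconds (default 30).
#' @param invalid_tolerance tolerated invalid-sample fraction per segment
#'   (default 0).
#' @param flatline_min_s,zero_run_min_s invalid-marking thresholds, seconds.
#' @param detector_id peak detector 1-7 (default 5).
#' @param detector_params detector parameter overrides.
#' @param sqi_selection character vector of names from [list_sqis()];
#'   `NULL` selects every SQI applicable to the signal type. An empty
#'   selection is a configuration error.
#' @param msq_detectors length-2 detector ids for the two-detector MSQ.
#' @param msq_shift_s forward shift for the shift-consistency MSQ, seconds.
#' @param correlogram_n_peaks correlogram peaks reported per segment.
#' @param beat_target_len resampled beat length, samples.
#' @param ectopic_rule NN-interval ectopic filter for the HRV SQIs.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(filter = NULL, segment_length_s = 30,
                            invalid_tolerance = 0, flatline_min_s = 2,
                            zero_run_min_s = 2, detector_id = 5L,
                            detector_params = list(), sqi_selection = NULL,
                            msq_detectors = c(5L, 6L), msq_shift_s = 1,
                            correlogram_n_peaks = 3L, beat_target_len = 100L,
                            ectopic_rule = "malik") {
  if (segment_length_s <= 0) stop_config("segment_length_s must be > 0")
  if (!is.null(sqi_selection)) {
    if (!length(sqi_selection)) {
      stop_config("sqi_selection must name at least one SQI")
    }
    unknown <- setdiff(sqi_selection, names(SQI_GROUPS))
    if (length(unknown)) {
      stop_config("unknown SQI name(s): %s (see list_sqis())",
                  paste(unknown, collapse = ", "))
    }
  }
  structure(list(filter = filter, segment_length_s = segment_length_s,
                 invalid_tolerance = invalid_tolerance,
                 flatline_min_s = flatline_min_s,
                 zero_run_min_s = zero_run_min_s,
                 detector_id = as.integer(detector_id),
                 detector_params = detector_params,
                 sqi_selection = sqi_selection,
                 msq_detectors = as.integer(msq_detectors),
                 msq_shift_s = msq_shift_s,
                 correlogram_n_peaks = as.integer(correlogram_n_peaks),
                 beat_target_len = as.integer(beat_target_len),
                 ectopic_rule = ectopic_rule),
            class = "pipeline_config")
}

#' Load a pipeline config from JSON
#'
#' Recognized keys mirror the [pipeline_config()] arguments; `filter` is an
#' object with `method`, `low_cut`, `high_cut`, `order`.
#'
#' @param json_text JSON string or file path.
#' @return a `pipeline_config`.
#' @export
load_pipeline_config <- function(json_text) {
  if (length(json_text) == 1L && !grepl("[{]", json_text) &&
      file.exists(json_text)) {
    json_text <- paste(readLines(json_text, warn = FALSE), collapse = "\n")
  }
  obj <- tryCatch(jsonlite::fromJSON(json_text, simplifyVector = TRUE),
                  error = function(e) stop_config("config JSON parse error: %s",
                                                  conditionMessage(e)))
  filt <- if (!is.null(obj$filter)) {
    do.call(filter_spec, obj$filter)
  } else NULL
  args <- obj[setdiff(names(obj), "filter")]
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(args), known)
  if (length(unknown)) stop_config("unknown config key(s): %s",
                                   paste(unknown, collapse = ", "))
  do.call(pipeline_config, c(list(filter = filt), args))
}

default_selection <- function(signal_type) {
  sel <- names(SQI_GROUPS)
  sel <- setdiff(sel, "hrv_freq_sqi")  # needs >= 60 s spans
  if (signal_type != "ecg") sel <- setdiff(sel, "qrs_energy_sqi")
  sel
}

sqi_column_names <- function(selection, config) {
  unlist(lapply(selection, function(g) {
    if (g == "correlogram_sqi") {
      n <- config$correlogram_n_peaks
      c(paste0("corr_lag_", seq_len(n)), paste0("corr_prom_", seq_len(n)))
    } else {
      SQI_GROUPS[[g]]
    }
  }), use.names = FALSE)
}

na_or <- function(expr) {
  tryCatch(expr, error = function(e) NA_real_)
}

compute_segment_sqis <- function(segment, config, selection) {
  rate <- segment$sampling_rate
  y <- segment$filtered_samples
  x <- segment$raw_samples
  cols <- sqi_column_names(selection, config)
  out <- stats::setNames(rep(NA_real_, length(cols)), cols)
  needs_peaks <- any(selection %in% c("msq_shift_sqi", "ectopic_sqi",
                                      "hrv_time_sqi", "hrv_freq_sqi",
                                      "dtw_sqi", "beat_stats_sqi",
                                      "amplitude_ratio_sqi"))
  ann <- NULL
  beats <- list()
  nn <- NULL
  if (needs_peaks) {
    ann <- tryCatch(detect_peaks(segment, config$detector_id,
                                 config$detector_params),
                    error = function(e) NULL)
    if (!is.null(ann)) {
      ann <- detect_troughs(segment, ann)
      beats <- extract_beats(segment, ann, target_len = config$beat_target_len)
      nn <- tryCatch(nn_intervals(ann, rate, config$ectopic_rule),
                     error = function(e) NULL)
    }
  }
  set1 <- function(nm, val) {
    if (nm %in% names(out)) out[nm] <<- as.numeric(val)
  }
  for (g in selection) {
    switch(g,
      perfusion_sqi = set1("perfusion_sqi", na_or(perfusion_sqi(x, y))),
      kurtosis_sqi = set1("kurtosis_sqi", na_or(kurtosis_sqi(y))),
      skewness_sqi = set1("skewness_sqi", na_or(skewness_sqi(y))),
      entropy_sqi = set1("entropy_sqi", na_or(entropy_sqi(y))),
      snr_sqi = set1("snr_sqi", na_or(snr_sqi(y, rate))),
      relative_power_sqi = set1("relative_power_sqi",
                                na_or(relative_power_sqi(y, rate))),
      zero_crossing_sqi = set1("zero_crossing_sqi", na_or(zero_crossing_sqi(y))),
      mean_crossing_sqi = set1("mean_crossing_sqi", na_or(mean_crossing_sqi(y))),
      msq_sqi = set1("msq_sqi",
                     na_or(msq_sqi(segment, config$msq_detectors[1L],
                                   config$msq_detectors[2L],
                                   params = config$detector_params))),
      msq_shift_sqi = set1("msq_shift_sqi",
                           na_or(msq_shift_sqi(segment, config$detector_id,
                                               shift_s = config$msq_shift_s,
                                               params = config$detector_params))),
      qrs_energy_sqi = set1("qrs_energy_sqi", na_or(qrs_energy_sqi(segment))),
      ectopic_sqi = if (!is.null(nn)) set1("ectopic_sqi", ectopic_sqi(nn)),
      correlogram_sqi = {
        cg <- na_or(correlogram_sqi(segment, n_peaks = config$correlogram_n_peaks))
        if (is.list(cg)) {
          for (i in seq_len(config$correlogram_n_peaks)) {
            set1(paste0("corr_lag_", i), cg$lags_s[i])
            set1(paste0("corr_prom_", i), cg$prominences[i])
          }
        }
      },
      hrv_time_sqi = if (!is.null(nn)) {
        ht <- hrv_time_sqi(nn)
        for (nm in names(ht)) set1(nm, ht[[nm]])
      },
      hrv_freq_sqi = if (!is.null(nn)) {
        hf <- hrv_freq_sqi(nn)
        for (nm in names(hf)) set1(nm, hf[[nm]])
      },
      dtw_sqi = if (length(beats)) {
        tpl <- make_template(
          if (segment$signal_type == "ecg") "ecg_pqrst_gaussian_sum"
          else "ppg_double_gaussian",
          config$beat_target_len)
        costs <- vapply(beats, function(b) na_or(dtw_sqi(b, tpl)), numeric(1L))
        costs <- costs[is.finite(costs)]
        if (length(costs)) {
          set1("dtw_mean", mean(costs))
          set1("dtw_median", stats::median(costs))
          set1("dtw_std", if (length(costs) > 1L) stats::sd(costs) else 0)
        }
      },
      beat_stats_sqi = if (length(beats)) {
        agg <- function(fun) {
          v <- vapply(beats, function(b) na_or(fun(b)), numeric(1L))
          v <- v[is.finite(v)]
          if (!length(v)) return(c(NA_real_, NA_real_, NA_real_))
          c(mean(v), stats::median(v), if (length(v) > 1L) stats::sd(v) else 0)
        }
        k <- agg(kurtosis_sqi); s <- agg(skewness_sqi); e <- agg(entropy_sqi)
        set1("kurtosis_mean", k[1L]); set1("kurtosis_median", k[2L])
        set1("kurtosis_std", k[3L])
        set1("skewness_mean", s[1L]); set1("skewness_median", s[2L])
        set1("skewness_std", s[3L])
        set1("entropy_mean", e[1L]); set1("entropy_median", e[2L])
        set1("entropy_std", e[3L])
      },
      amplitude_ratio_sqi = if (length(beats)) {
        ar <- amplitude_ratio_sqi(beats, segment$signal_type)
        set1("qrs_a_mean", ar$mean)
        set1("qrs_a_std", ar$std)
      })
  }
  out
}

#' Extract an SQI table from a raw waveform
#'
#' Runs the full extraction pipeline: bandpass filter, invalid-signal
#' marking (on the raw signal), fixed-duration segmentation, and per-segment
#' SQI computation (per-beat SQIs aggregated as mean/median/sd over the
#' segment's beats). Invalid segments are retained as all-NA rows so row
#' indices always tile the recording.
#'
#' @param record a [waveform_record()].
#' @param config a [pipeline_config()].
#' @return data frame: `segment_id`, `start_s`, `end_s`, `valid`, then one
#'   column per SQI. Zero valid segments yields an empty (0-row) table with
#'   a warning, not an error.
#' @examples
#' rec <- synth_record(synthesis_spec("ppg", duration_s = 90, seed = 3))$record
#' tab <- extract_pipeline(rec, pipeline_config(
#'   sqi_selection = c("kurtosis_sqi", "entropy_sqi")))
#' @export
extract_pipeline <- function(record, config = pipeline_config()) {
  stopifnot(inherits(record, "waveform_record"),
            inherits(config, "pipeline_config"))
  selection <- config$sqi_selection %||% default_selection(record$signal_type)
  marked <- mark_invalid(record, config$flatline_min_s, config$zero_run_min_s)
  filtered <- bandpass_filter(marked, config$filter)
  sqikit_log("extract: %d samples @ %g Hz, %d marked invalid",
             length(record$samples), record$sampling_rate,
             sum(!marked$valid_mask))
  segments <- segment_by_duration(filtered, config$segment_length_s,
                                  config$invalid_tolerance, raw_record = record)
  n_valid <- sum(vapply(segments, `[[`, TRUE, "valid"))
  sqikit_log("extract: %d segment(s) of %g s, %d valid", length(segments),
             config$segment_length_s, n_valid)
  cols <- sqi_column_names(selection, config)
  if (!length(segments) || n_valid == 0L) {
    warning("no valid segments; returning empty SQI table")
    empty <- as.data.frame(stats::setNames(
      rep(list(numeric()), length(cols) + 4L),
      c("segment_id", "start_s", "end_s", "valid", cols)))
    return(empty)
  }
  rows <- lapply(segments, function(seg) {
    vals <- if (seg$valid) compute_segment_sqis(seg, config, selection) else
      stats::setNames(rep(NA_real_, length(cols)), cols)
    c(segment_id = seg$index, start_s = seg$start / seg$sampling_rate,
      end_s = seg$end / seg$sampling_rate, valid = as.numeric(seg$valid), vals)
  })
  tab <- as.data.frame(do.call(rbind, rows))
  tab$segment_id <- as.integer(tab$segment_id)
  tab$valid <- tab$valid == 1
  sqikit_log("extract: SQI table %d x %d", nrow(tab), ncol(tab))
  tab
}

#' Classify an SQI table with a ruleset
#'
#' One decision per row via [apply_ruleset()]; all-NA rows fall through to
#' each rule's `na_decision` (default reject).
#'
#' @param table SQI table from [extract_pipeline()] (or read from CSV).
#' @param ruleset an [sqi_ruleset()] or path/JSON accepted by
#'   [parse_ruleset()].
#' @return data frame: `segment_id`, `label`, `triggered_rule`.
#' @export
classify_pipeline <- function(table, ruleset) {
  if (!inherits(ruleset, "sqi_ruleset")) ruleset <- parse_ruleset(ruleset)
  missing <- setdiff(ruleset$order, names(table))
  if (length(missing)) {
    stop_config("SQI table lacks column(s) required by the ruleset: %s",
                paste(missing, collapse = ", "))
  }
  res <- lapply(seq_len(nrow(table)), function(i) {
    apply_ruleset(ruleset, table[i, , drop = FALSE])
  })
  out <- data.frame(
    segment_id = if ("segment_id" %in% names(table)) table$segment_id else
      seq_len(nrow(table)),
    label = vapply(res, `[[`, "", "label"),
    triggered_rule = vapply(res, `[[`, "", "triggered_rule"),
    stringsAsFactors = FALSE)
  sqikit_log("classify: %d accept / %d reject", sum(out$label == "accept"),
             sum(out$label == "reject"))
  out
}

#' Derive a ruleset from a labelled SQI table
#'
#' Builds one single-boundary rule per requested SQI, with thresholds from
#' either the accept-class percentile or the quantile-grid search.
#'
#' @param sqi_table data frame of SQI values.
#' @param labels `"accept"`/`"reject"` per row.
#' @param sqis column names to derive rules for.
#' @param method `"search"` (balanced-accuracy grid search, default) or
#'   `"percentile"` (95th percentile of the accept class).
#' @param q percentile for the percentile method.
#' @param side tail rejected by the percentile method.
#' @return an [sqi_ruleset()].
#' @export
derive_ruleset <- function(sqi_table, labels, sqis,
                           method = c("search", "percentile"), q = 95,
                           side = "upper") {
  method <- match.arg(method)
  is_acc <- as.character(labels) == "accept"
  rules <- lapply(sqis, function(nm) {
    v <- sqi_table[[nm]]
    if (is.null(v)) stop_config("table is missing column '%s'", nm)
    if (method == "search") {
      rule_from_search(nm, threshold_search(v[is_acc], v[!is_acc]))
    } else {
      tp <- threshold_percentile(v[is_acc], q = q, side = side)
      sqi_rule(nm, list(list(op = tp$op, value = tp$threshold,
                             decision = "reject")), na_decision = "reject")
    }
  })
  sqi_ruleset(rules)
}
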