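# End-to-end orchestration: frame log -> labeled -> demultiplexed ->
# filtered -> windowed features -> calibrated R -> SpO2 + heart rate.

#' Run configuration for the end-to-end pipeline
#'
#' @param filter A [filter_spec].
#' @param window_s Feature window length in seconds (default 10).
#' @param tone_class Fitzpatrick class of the subject, or `NULL` to skip
#'   tone calibration.
#' @param calibration A [calibration_table] (default the packaged one).
#' @param pair Wavelength pair for calibration (`"red_blue"` here; the
#'   screen flashes red and blue).
#' @param model An SpO2 model (`linear_spo2_model` or
#'   `quadratic_spo2_model`); default the packaged linear map. `NULL`
#'   leaves SpO2 unset (R values only).
#' @param mixed_frac Mixed-frame threshold fraction for
#'   [label_illumination()].
#' @param edge_trim_s Filter-settling margin excluded from AC
#'   computation in the first and last window (see [window_features()];
#'   default 2 s).
#' @return Object of class `run_config`.
#' @export
run_config <- function(filter = filter_spec(), window_s = 10,
                       tone_class = NULL,
                       calibration = default_calibration_table(),
                       pair = "red_blue",
                       model = linear_spo2_model(),
                       mixed_frac = 0.4, edge_trim_s = 2) {
  stopifnot(inherits(filter, "filter_spec"), window_s > 0,
            edge_trim_s >= 0)
  if (!is.null(tone_class)) stopifnot(tone_class %in% 1:6)
  structure(list(filter = filter, window_s = window_s,
                 tone_class = tone_class, calibration = calibration,
                 pair = pair, model = model, mixed_frac = mixed_frac,
                 edge_trim_s = edge_trim_s),
            class = "run_config")
}

#' Process a frame log end to end
#'
#' Labels illumination (when not already labeled), demultiplexes into
#' red and blue channel signals, band-pass filters and Savitzky-Golay
#' smooths each, extracts windowed AC/DC features and the ratio of
#' ratios, applies the tone-normalization coefficient when a tone class
#' is configured, and maps calibrated R to SpO2. Deterministic for a
#' given log and configuration.
#'
#' @param log A [frame_log].
#' @param config A [run_config].
#' @return Object of class `run_result`: list with `windows` (data frame
#'   `t_start`, `t_end`, `ac_red`, `dc_red`, `ac_blue`, `dc_blue`,
#'   `r_value`, `r_calibrated`, `spo2`, `heart_rate_bpm`) and `qc`
#'   (frame counts: `frames_in`, `used_red`, `used_blue`, `mixed`,
#'   `unknown`, `undefined_windows`).
#' @export
process_run <- function(log, config = run_config()) {
  stopifnot(inherits(log, "frame_log"))
  if (nrow(log) == 0) {
    ox_stop("empty frame log", "oxitone_insufficient_data")
  }
  if (all(log$illum == "unknown")) {
    log <- label_illumination(log, mixed_frac = config$mixed_frac)
  }
  ch <- demultiplex(log)
  red_f <- savgol_smooth(bandpass(ch$red, config$filter), config$filter)
  blue_f <- savgol_smooth(bandpass(ch$blue, config$filter), config$filter)
  feats <- window_features(ch$red, red_f, ch$blue, blue_f,
                           window_s = config$window_s,
                           hr_band = c(config$filter$band_low,
                                       config$filter$band_high),
                           edge_trim_s = config$edge_trim_s)
  r_cal <- feats$r_value
  if (!is.null(config$tone_class)) {
    r_cal <- apply_calibration(feats$r_value, config$calibration,
                               config$tone_class, config$pair)
  }
  spo2 <- if (!is.null(config$model)) {
    predict(config$model, r_cal)
  } else {
    rep(NA_real_, nrow(feats))
  }
  windows <- data.frame(feats[c("t_start", "t_end", "ac_red", "dc_red",
                                "ac_blue", "dc_blue", "r_value")],
                        r_calibrated = r_cal, spo2 = spo2,
                        heart_rate_bpm = feats$heart_rate_bpm)
  qc <- list(frames_in = nrow(log),
             used_red = unname(ch$dropped["used_red"]),
             used_blue = unname(ch$dropped["used_blue"]),
             mixed = unname(ch$dropped["mixed"]),
             unknown = unname(ch$dropped["unknown"]),
             undefined_windows = sum(!is.finite(windows$r_value)))
  structure(list(windows = windows, qc = qc), class = "run_result")
}

#' @export
print.run_result <- function(x, ...) {
  w <- x$windows
  cat(sprintf("Run result: %d windows", nrow(w)))
  if (any(is.finite(w$spo2))) {
    cat(sprintf(", SpO2 %.1f-%.1f%%", min(w$spo2, na.rm = TRUE),
                max(w$spo2, na.rm = TRUE)))
  }
  if (any(is.finite(w$heart_rate_bpm))) {
    cat(sprintf(", HR median %.0f bpm",
                stats::median(w$heart_rate_bpm, na.rm = TRUE)))
  }
  cat(sprintf("\n  QC: %d frames in = %d red + %d blue + %d mixed + %d unknown\n",
              x$qc$frames_in, x$qc$used_red, x$qc$used_blue, x$qc$mixed,
              x$qc$unknown))
  invisible(x)
}

#' Classify skin tone from a calibration image and fetch coefficients
#'
#' Measures the mean RGB of the six in-image reference patches and of
#' the skin patch, classifies the skin against the measured (not the
#' packaged) strip colors — so ambient lighting common to strip and skin
#' cancels — and returns the tone-normalization coefficients of the
#' detected class from the active calibration table.
#'
#' @param image RGB array (`height x width x 3`) or path to a PPM file.
#' @param regions List with `strip` (list of six rectangles
#'   `c(x0, y0, x1, y1)`, classes 1-6 in order) and `skin` (one
#'   rectangle).
#' @param table A [calibration_table].
#' @param method Classification method, see [classify_tone()].
#' @return List with `result` (a `skin_tone_result`) and `coefficients`
#'   (named pair `red_ir`, `red_blue`).
#' @export
run_skin_tone_calibration <- function(image, regions,
                                      table = default_calibration_table(),
                                      method = "rgb_euclidean") {
  if (is.character(image)) image <- read_ppm(image)
  if (is.null(regions$strip) || length(regions$strip) != 6 ||
      is.null(regions$skin)) {
    ox_stop("regions must list six strip rectangles and one skin rectangle",
            "oxitone_config_error")
  }
  strip <- t(vapply(regions$strip, function(rc) mean_rgb(image, rc),
                    numeric(3)))
  rownames(strip) <- 1:6
  patch <- mean_rgb(image, regions$skin)
  res <- classify_tone(patch, strip, method)
  cls <- res$fitzpatrick_class
  coefs <- c(red_ir = get_coefficient(table, cls, "red_ir"),
             red_blue = get_coefficient(table, cls, "red_blue"))
  list(result = res, coefficients = coefs)
}
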