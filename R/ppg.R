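# Photoplethysmogram processing: band-pass + Savitzky-Golay filtering,
# windowed AC/DC feature extraction, the ratio of ratios, and heart-rate
# estimation.

#' Filter specification for PPG cleaning
#'
#' Defaults follow standard practice for pulse signals: a 0.5-2 Hz pass
#' band (30-120 bpm) and a third-order, 35-sample Savitzky-Golay
#' smoothing stage.
#'
#' @param band_low,band_high Pass-band edges in Hz.
#' @param sg_order Savitzky-Golay polynomial order.
#' @param sg_window Savitzky-Golay window length (odd, > `sg_order`).
#' @return Object of class `filter_spec`.
#' @export
filter_spec <- function(band_low = 0.5, band_high = 2,
                        sg_order = 3, sg_window = 35) {
  if (!(band_low > 0 && band_high > band_low)) {
    ox_stop("need 0 < band_low < band_high", "oxitone_config_error")
  }
  if (sg_window %% 2 != 1 || sg_window <= sg_order) {
    ox_stop("sg_window must be odd and larger than sg_order",
            "oxitone_config_error")
  }
  structure(list(band_low = band_low, band_high = band_high,
                 sg_order = sg_order, sg_window = sg_window),
            class = "filter_spec")
}

#' Band-pass filter a channel signal
#'
#' Fourth-order Butterworth band-pass applied forward and backward
#' (zero phase), preserving length and sampling rate.
#'
#' @param signal A [channel_signal].
#' @param spec A [filter_spec].
#' @return Filtered [channel_signal].
#' @export
bandpass <- function(signal, spec = filter_spec()) {
  stopifnot(inherits(signal, "channel_signal"))
  if (signal$sample_rate <= 2 * spec$band_high) {
    ox_stop(sprintf(
      "sample rate %g Hz too low for a %g Hz upper cutoff (Nyquist)",
      signal$sample_rate, spec$band_high),
      "oxitone_nyquist_error")
  }
  ba <- butter_bandpass(spec$band_low, spec$band_high, signal$sample_rate)
  out <- signal
  out$samples <- filtfilt(ba$b, ba$a, signal$samples)
  out
}

#' Savitzky-Golay smooth a channel signal
#'
#' @inheritParams bandpass
#' @return Smoothed [channel_signal] of the same length.
#' @export
savgol_smooth <- function(signal, spec = filter_spec()) {
  stopifnot(inherits(signal, "channel_signal"))
  if (length(signal$samples) < spec$sg_window) {
    ox_stop(sprintf("signal (%d samples) shorter than the %d-sample window",
                    length(signal$samples), spec$sg_window),
            "oxitone_insufficient_data")
  }
  out <- signal
  out$samples <- savgol(signal$samples, spec$sg_order, spec$sg_window)
  out
}

#' Ratio of ratios
#'
#' The perfusion-normalized two-wavelength ratio mapped to SpO2:
#' `R = (AC_red / DC_red) / (AC_blue / DC_blue)`. Vectorized; windows
#' with a non-positive `dc_red`, `dc_blue` or `ac_blue` yield `NA`
#' (an undefined window, not an error).
#'
#' @param ac_red,dc_red,ac_blue,dc_blue Window features (AC = pulsatile
#'   RMS, DC = baseline mean) of the two channels.
#' @return Numeric R value(s).
#' @export
#' @examples
#' ratio_of_ratios(0.02, 1.0, 0.01, 0.5)  # = 1
ratio_of_ratios <- function(ac_red, dc_red, ac_blue, dc_blue) {
  r <- (ac_red / dc_red) / (ac_blue / dc_blue)
  bad <- !is.finite(r) | dc_red <= 0 | dc_blue <= 0 | ac_blue <= 0
  bad[is.na(bad)] <- TRUE
  r[bad] <- NA_real_
  r
}

#' DC transmission ratio of two wavelength bands
#'
#' Ratio of the longer-wavelength baseline transmission to the shorter:
#' IR/red for a commodity oximeter, red/blue for the screen-based pair.
#'
#' @param longer_band_dc,shorter_band_dc Positive DC intensities.
#' @return Ratio(s).
#' @export
dc_transmission_ratio <- function(longer_band_dc, shorter_band_dc) {
  if (any(longer_band_dc <= 0) || any(shorter_band_dc <= 0)) {
    ox_stop("DC intensities must be positive", "oxitone_domain_error")
  }
  longer_band_dc / shorter_band_dc
}

#' Estimate heart rate from a filtered PPG segment
#'
#' 60 times the dominant frequency of the periodogram, restricted to the
#' pass band. Flat (pulseless) input yields `NA` with a warning.
#'
#' @param filtered A band-limited [channel_signal] of at least 5 s.
#' @param band Search band in Hz (default `c(0.5, 2)`, i.e. 30-120 bpm).
#' @return Heart rate in beats per minute, or `NA_real_`.
#' @export
estimate_heart_rate <- function(filtered, band = c(0.5, 2)) {
  stopifnot(inherits(filtered, "channel_signal"))
  dur <- length(filtered$samples) / filtered$sample_rate
  if (dur < 5) {
    ox_stop(sprintf("need at least 5 s of signal, got %.2f s", dur),
            "oxitone_insufficient_data")
  }
  f <- dominant_frequency(filtered$samples, filtered$sample_rate,
                          band[1], band[2])
  if (is.na(f)) {
    ox_warn("no pulsatile component found", "oxitone_no_pulse")
    return(NA_real_)
  }
  60 * f
}

#' Windowed AC/DC features and the ratio of ratios
#'
#' Cuts the aligned signals into consecutive non-overlapping windows of
#' `window_s` seconds (trailing partial window dropped). Per window, the
#' AC of each channel is the RMS of the filtered signal about its window
#' mean, the DC is the mean of the raw signal, `r_value` is
#' [ratio_of_ratios()], and `heart_rate_bpm` is estimated from the
#' filtered red channel (windows of 5 s or more).
#'
#' @param red_raw,red_filt,blue_raw,blue_filt [channel_signal]s at a
#'   common sampling rate; raw/filtered pairs must be aligned
#'   sample-for-sample, and the two channels must overlap in time (their
#'   sample grids may be offset by up to half a sample period, as
#'   produced by [demultiplex()] of alternating frames).
#' @param window_s Window length in seconds (default 10).
#' @param hr_band Heart-rate search band in Hz.
#' @param edge_trim_s Seconds of the filtered signals' outermost samples
#'   excluded from AC (and heart-rate) computation, where zero-phase
#'   filtering and Savitzky-Golay edge polynomials leave a settling
#'   artifact (default 0; the pipeline uses 2 s). Only windows touching
#'   a signal edge are affected; DC always uses the full raw window.
#' @return Data frame of class `window_features` with columns `t_start`,
#'   `t_end`, `ac_red`, `dc_red`, `ac_blue`, `dc_blue`, `r_value`,
#'   `heart_rate_bpm`.
#' @export
window_features <- function(red_raw, red_filt, blue_raw, blue_filt,
                            window_s = 10, hr_band = c(0.5, 2),
                            edge_trim_s = 0) {
  sigs <- list(red_raw = red_raw, red_filt = red_filt,
               blue_raw = blue_raw, blue_filt = blue_filt)
  for (s in sigs) stopifnot(inherits(s, "channel_signal"))
  rates <- vapply(sigs, function(s) s$sample_rate, numeric(1))
  if (diff(range(rates)) > 1e-9) {
    ox_stop("signals must share one sampling rate", "oxitone_alignment_error")
  }
  fs <- rates[[1]]
  for (pair in list(c("red_raw", "red_filt"), c("blue_raw", "blue_filt"))) {
    a <- sigs[[pair[1]]]; b <- sigs[[pair[2]]]
    if (length(a$samples) != length(b$samples) ||
        abs(a$start_time - b$start_time) > 1e-9) {
      ox_stop(paste0(pair[1], " and ", pair[2], " are not aligned"),
              "oxitone_alignment_error")
    }
  }
  if (abs(red_raw$start_time - blue_raw$start_time) > 0.5 / fs + 1e-9) {
    ox_stop("red and blue channels offset by more than half a sample",
            "oxitone_alignment_error")
  }
  t0 <- max(red_raw$start_time, blue_raw$start_time)
  t_end_all <- min(vapply(sigs, function(s) {
    s$start_time + (length(s$samples) - 1) / s$sample_rate
  }, numeric(1)))
  n_win <- floor((t_end_all - t0 + 1 / fs) / window_s)
  if (n_win < 1) {
    ox_stop("signals shorter than one window", "oxitone_insufficient_data")
  }
  wps <- window_s * fs   # samples per window (may be fractional only if
                         # fs*window_s is; demand integer for exact cuts)
  if (abs(wps - round(wps)) > 1e-9) {
    ox_stop("window_s times sample rate must be an integer",
            "oxitone_config_error")
  }
  wps <- as.integer(round(wps))

  trim <- as.integer(round(edge_trim_s * fs))
  slice <- function(sig, j, trim_edges = FALSE) {
    off <- as.integer(round((t0 - sig$start_time) * fs))
    idx <- (off + (j - 1L) * wps + 1L):(off + j * wps)
    lo <- if (trim_edges) 1L + trim else 1L
    hi <- if (trim_edges) length(sig$samples) - trim else length(sig$samples)
    idx <- idx[idx >= lo & idx <= hi]
    sig$samples[idx]
  }
  rows <- lapply(seq_len(n_win), function(j) {
    rr <- slice(sigs$red_raw, j);  rf <- slice(sigs$red_filt, j, TRUE)
    br <- slice(sigs$blue_raw, j); bf <- slice(sigs$blue_filt, j, TRUE)
    ac_r <- if (length(rf) >= 2) sqrt(mean((rf - mean(rf))^2)) else NA_real_
    ac_b <- if (length(bf) >= 2) sqrt(mean((bf - mean(bf))^2)) else NA_real_
    dc_r <- mean(rr); dc_b <- mean(br)
    hr <- if (window_s >= 5 && length(rf) >= 4) {
      f <- dominant_frequency(rf, fs, hr_band[1], hr_band[2])
      if (is.na(f)) NA_real_ else 60 * f
    } else NA_real_
    data.frame(t_start = t0 + (j - 1) * window_s,
               t_end = t0 + j * window_s,
               ac_red = ac_r, dc_red = dc_r,
               ac_blue = ac_b, dc_blue = dc_b,
               r_value = ratio_of_ratios(ac_r, dc_r, ac_b, dc_b),
               heart_rate_bpm = hr)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("window_features", "data.frame")
  out
}

#' Write window features to CSV
#'
#' Columns: `t_start,t_end,ac_red,dc_red,ac_blue,dc_blue,r_value,heart_rate_bpm`.
#'
#' @param features A `window_features` data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_features <- function(features, path) {
  utils::write.csv(as.data.frame(features), path, row.names = FALSE)
  invisible(path)
}
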