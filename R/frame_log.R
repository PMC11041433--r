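# Frame logs: the raw sensor record of the capture app. Each row is one
# camera frame's mean R, G, B intensity plus a timestamp; illumination
# alternates between the screen's red and blue phases, with occasional
# unusable "mixed" (purple) frames straddling a color transition.

ILLUM_LEVELS <- c("red", "blue", "mixed", "unknown")

#' Construct a frame log
#'
#' A frame log is a data frame with columns `timestamp` (seconds,
#' non-decreasing), `r`, `g`, `b` (per-frame mean channel intensities)
#' and `illum` (one of `"red"`, `"blue"`, `"mixed"`, `"unknown"`), with
#' the nominal camera frame rate and the intensity value range attached
#' as attributes.
#'
#' @param records Data frame with columns `timestamp`, `r`, `g`, `b` and
#'   optionally `illum`.
#' @param frame_rate Nominal camera frame rate in Hz. If `NULL`, inferred
#'   from the median timestamp increment.
#' @param value_range `"0-255"`, `"0-1"`, or `"auto"` (detected from the
#'   maximum channel value: logs whose channels never exceed 1 are taken
#'   as normalized).
#' @return Object of class `frame_log` (a data frame).
#' @export
#' @examples
#' frame_log(data.frame(timestamp = 0:2 / 30, r = c(200, 5, 200),
#'                      g = 2, b = c(5, 180, 5)))
frame_log <- function(records, frame_rate = NULL,
                      value_range = c("auto", "0-255", "0-1")) {
  value_range <- match.arg(value_range)
  req <- c("timestamp", "r", "g", "b")
  missing_cols <- setdiff(req, names(records))
  if (length(missing_cols) > 0) {
    ox_stop(paste0("frame log is missing column(s): ",
                   paste(missing_cols, collapse = ", ")),
            "oxitone_format_error")
  }
  records <- as.data.frame(records)
  for (col in req) {
    v <- records[[col]]
    if (!is.numeric(v)) {
      bad <- which(is.na(suppressWarnings(as.numeric(as.character(v)))) &
                     !is.na(v))
      ox_stop(paste0("non-numeric value in column '", col, "' at row ",
                     if (length(bad)) bad[1] else NA),
              "oxitone_parse_error")
    }
    if (any(!is.finite(v))) {
      ox_stop(paste0("non-finite value in column '", col, "' at row ",
                     which(!is.finite(v))[1]),
              "oxitone_parse_error")
    }
  }
  if (any(records$timestamp < 0)) {
    ox_stop("negative timestamp in frame log", "oxitone_format_error")
  }
  if (is.unsorted(records$timestamp)) {
    records <- records[order(records$timestamp), , drop = FALSE]
  }
  if (is.null(records$illum)) {
    records$illum <- rep("unknown", nrow(records))
  }
  records$illum <- as.character(records$illum)
  if (!all(records$illum %in% ILLUM_LEVELS)) {
    ox_stop("illumination labels must be red/blue/mixed/unknown",
            "oxitone_format_error")
  }
  records <- records[c("timestamp", "r", "g", "b", "illum")]
  rownames(records) <- NULL

  if (value_range == "auto") {
    mx <- suppressWarnings(max(records$r, records$g, records$b, 0))
    value_range <- if (nrow(records) > 0 && mx <= 1) "0-1" else "0-255"
  }
  top <- if (value_range == "0-1") 1 else 255
  chans <- c(records$r, records$g, records$b)
  if (length(chans) && (min(chans) < 0 || max(chans) > top)) {
    ox_stop(sprintf("channel means outside declared range [0, %g]", top),
            "oxitone_format_error")
  }

  if (is.null(frame_rate)) {
    dt <- diff(records$timestamp)
    dt <- dt[dt > 0]
    frame_rate <- if (length(dt) > 0) 1 / stats::median(dt) else NA_real_
  }
  if (!is.na(frame_rate) && frame_rate <= 0) {
    ox_stop("nominal frame rate must be positive", "oxitone_format_error")
  }
  if (nrow(records) > 2 && !is.na(frame_rate)) {
    jit <- abs(diff(records$timestamp) - 1 / frame_rate)
    if (any(jit > 0.5 / frame_rate)) {
      ox_warn(sprintf("%d inter-frame gaps deviate from the nominal period by > 50%%",
                      sum(jit > 0.5 / frame_rate)),
              "oxitone_jitter_warning")
    }
  }
  structure(records, frame_rate = frame_rate, value_range = value_range,
            class = c("frame_log", "data.frame"))
}

#' @export
print.frame_log <- function(x, ...) {
  cat(sprintf("Frame log: %d frames, nominal rate %s Hz, range %s\n",
              nrow(x), format(attr(x, "frame_rate")), attr(x, "value_range")))
  tab <- table(factor(x$illum, ILLUM_LEVELS))
  cat("  illumination:", paste(names(tab), tab, sep = "=", collapse = " "), "\n")
  invisible(x)
}

#' Read a frame log from CSV
#'
#' Expects a header `timestamp,r,g,b` with an optional `illum` column
#' (UTF-8, `.` decimal separator). Records are sorted by timestamp; an
#' empty body yields a zero-record log with a warning.
#'
#' @param path Path to a CSV file.
#' @inheritParams frame_log
#' @return A [frame_log].
#' @export
read_frame_log <- function(path, frame_rate = NULL,
                           value_range = c("auto", "0-255", "0-1")) {
  if (!file.exists(path)) {
    ox_stop(paste0("no such frame log: ", path), "oxitone_io_error")
  }
  raw <- utils::read.csv(path, colClasses = "character",
                         stringsAsFactors = FALSE)
  req <- c("timestamp", "r", "g", "b")
  missing_cols <- setdiff(req, names(raw))
  if (length(missing_cols) > 0) {
    ox_stop(paste0("frame log ", path, " is missing column(s): ",
                   paste(missing_cols, collapse = ", ")),
            "oxitone_format_error")
  }
  if (nrow(raw) == 0) {
    ox_warn(paste0("frame log ", path, " has a header but no records"))
    empty <- data.frame(timestamp = numeric(0), r = numeric(0),
                        g = numeric(0), b = numeric(0),
                        illum = character(0))
    return(frame_log(empty, frame_rate = frame_rate,
                     value_range = if (identical(value_range, "auto")) "0-255"
                                   else match.arg(value_range)))
  }
  for (col in req) {
    num <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(num))
    if (length(bad) > 0) {
      ox_stop(sprintf("cannot parse column '%s' at row %d of %s",
                      col, bad[1], path),
              "oxitone_parse_error")
    }
    raw[[col]] <- num
  }
  frame_log(raw, frame_rate = frame_rate, value_range = value_range)
}

#' Write a frame log to CSV
#'
#' Numeric columns are written with 17 significant digits so that
#' `read_frame_log(write_frame_log(log))` reproduces the records exactly.
#' The `illum` column is written only when at least one frame carries a
#' non-`unknown` label.
#'
#' @param log A [frame_log].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_frame_log <- function(log, path) {
  stopifnot(inherits(log, "frame_log"))
  out <- data.frame(
    timestamp = formatC(log$timestamp, digits = 17, format = "g"),
    r = formatC(log$r, digits = 17, format = "g"),
    g = formatC(log$g, digits = 17, format = "g"),
    b = formatC(log$b, digits = 17, format = "g")
  )
  if (nrow(log) > 0 && any(log$illum != "unknown")) out$illum <- log$illum
  if (nrow(log) == 0) out$illum <- NULL
  ok <- tryCatch({
    utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) ox_stop(paste0("cannot write frame log to ", path),
                   "oxitone_io_error")
  invisible(path)
}

#' Label frame illumination from channel dominance
#'
#' A frame is `"mixed"` when both its red and blue means exceed the mixed
#' threshold (a camera frame that straddled a screen color transition —
#' a purple frame — carries both illuminants and is unusable), `"red"` or
#' `"blue"` when the respective channel dominates, and `"unknown"` when
#' all channels are zero. Existing non-`unknown` labels are kept unless
#' `force = TRUE`.
#'
#' @param log A [frame_log].
#' @param mixed_frac Mixed threshold as a fraction of the log's
#'   per-channel maximum (default 0.4).
#' @param mixed_threshold Optional absolute threshold applied to both
#'   channels; overrides `mixed_frac`.
#' @param force Relabel frames that already carry a label.
#' @return The log with `illum` filled in.
#' @export
label_illumination <- function(log, mixed_frac = 0.4,
                               mixed_threshold = NULL, force = FALSE) {
  stopifnot(inherits(log, "frame_log"))
  if (nrow(log) == 0) {
    ox_stop("cannot label an empty frame log", "oxitone_insufficient_data")
  }
  thr_r <- if (is.null(mixed_threshold)) mixed_frac * max(log$r) else mixed_threshold
  thr_b <- if (is.null(mixed_threshold)) mixed_frac * max(log$b) else mixed_threshold
  lab <- ifelse(log$r > thr_r & log$b > thr_b, "mixed",
                ifelse(log$r >= log$b, "red", "blue"))
  zero <- log$r == 0 & log$g == 0 & log$b == 0
  lab[zero] <- "unknown"
  if (any(zero)) {
    ox_warn(sprintf("%d all-zero frame(s) labeled unknown", sum(zero)))
  }
  keep <- !force & log$illum != "unknown"
  log$illum <- ifelse(keep, log$illum, lab)
  log
}

#' Construct a channel signal
#'
#' A uniformly sampled intensity series for one illumination band, as
#' produced by [demultiplex()].
#'
#' @param band `"red"`, `"blue"`, or `"infrared"`.
#' @param samples Numeric vector of intensities, all finite.
#' @param sample_rate Sampling rate in Hz (> 0).
#' @param start_time Time of the first sample in seconds.
#' @return Object of class `channel_signal`.
#' @export
channel_signal <- function(band = c("red", "blue", "infrared"), samples,
                           sample_rate, start_time = 0) {
  band <- match.arg(band)
  samples <- as.numeric(samples)
  if (any(!is.finite(samples))) {
    ox_stop("channel signal contains non-finite samples",
            "oxitone_format_error")
  }
  if (!is.numeric(sample_rate) || sample_rate <= 0) {
    ox_stop("sample_rate must be positive", "oxitone_format_error")
  }
  structure(list(band = band, samples = samples,
                 sample_rate = sample_rate, start_time = start_time),
            class = "channel_signal")
}

#' @export
print.channel_signal <- function(x, ...) {
  cat(sprintf("Channel signal [%s]: %d samples at %g Hz (%.1f s from t=%.3f)\n",
              x$band, length(x$samples), x$sample_rate,
              length(x$samples) / x$sample_rate, x$start_time))
  invisible(x)
}

# sample times of a channel signal
signal_times <- function(sig) {
  sig$start_time + (seq_along(sig$samples) - 1) / sig$sample_rate
}

#' Split an interleaved frame log into red and blue channel signals
#'
#' Red-labeled frames contribute their `r` mean, blue-labeled frames
#' their `b` mean; mixed and unknown frames are dropped and counted.
#' Each channel is resampled by linear interpolation onto a uniform grid
#' at half the nominal frame rate (each color is lit on alternate
#' frames), anchored at that channel's first retained frame.
#'
#' @param log A labeled [frame_log].
#' @param target_rate Output sampling rate in Hz; default
#'   `frame_rate / 2`.
#' @return List with elements `red` and `blue` ([channel_signal]s) and
#'   `dropped`, a named count of frames per disposition
#'   (`used_red + used_blue + mixed + unknown == nrow(log)`).
#' @export
demultiplex <- function(log, target_rate = NULL) {
  stopifnot(inherits(log, "frame_log"))
  fr <- attr(log, "frame_rate")
  if (is.null(target_rate)) {
    if (is.na(fr)) ox_stop("frame rate unknown; pass target_rate",
                           "oxitone_format_error")
    target_rate <- fr / 2
  }
  if (all(log$illum == "unknown") && nrow(log) > 0) {
    ox_stop("frame log is unlabeled; run label_illumination() first",
            "oxitone_format_error")
  }
  counts <- c(used_red = sum(log$illum == "red"),
              used_blue = sum(log$illum == "blue"),
              mixed = sum(log$illum == "mixed"),
              unknown = sum(log$illum == "unknown"))
  out <- list()
  for (side in c("red", "blue")) {
    sel <- log$illum == side
    if (sum(sel) < 2) {
      ox_stop(sprintf("fewer than 2 %s-labeled frames; cannot demultiplex",
                      side),
              "oxitone_insufficient_data")
    }
    t <- log$timestamp[sel]
    v <- if (side == "red") log$r[sel] else log$b[sel]
    grid <- seq(t[1], t[length(t)], by = 1 / target_rate)
    vi <- stats::approx(t, v, xout = grid, rule = 2, ties = "ordered")$y
    out[[side]] <- channel_signal(side, vi, target_rate, start_time = grid[1])
  }
  list(red = out$red, blue = out$blue, dropped = counts)
}
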