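#' Band specifications for the physiological filter bank
#'
#' Fourth-order Butterworth bandpass definitions used throughout the
#' pipeline. Named presets cover the bands the analysis relies on:
#'
#' * `respiration`: 0.1–0.5 Hz chest-wall breathing motion,
#' * `pulse_wave`: 0.75–3.0 Hz pulse-wave component (45–180 bpm),
#' * `heart_sound_A`: 25–400 Hz, the classic phonocardiogram band,
#' * `heart_sound_B`: 16–80 Hz, the radar-adjusted heart-sound band
#'   (physiological heart sounds live below 80 Hz; radar adds low-frequency
#'   content through its areal integration over the chest),
#' * `ecg`: 0.5–20 Hz ECG conditioning band.
#'
#' @param name Label for the band.
#' @param low,high Passband edges in Hz, `0 < low < high`.
#' @param order Butterworth prototype order (default 4).
#' @return A `band_spec` object (named list).
#' @export
band_spec <- function(name, low, high, order = 4L) {
  assert_scalar_pos(low, "low")
  assert_scalar_pos(high, "high")
  if (low >= high) {
    abort("`low` must be below `high`.", class = "radarheart_invalid_input")
  }
  structure(list(name = as.character(name), low = low, high = high,
                 order = as.integer(order)),
            class = "band_spec")
}

#' @rdname band_spec
#' @param preset One of `"respiration"`, `"pulse_wave"`, `"heart_sound_A"`,
#'   `"heart_sound_B"`, `"ecg"`.
#' @export
band_preset <- function(preset = c("heart_sound_B", "heart_sound_A",
                                   "respiration", "pulse_wave", "ecg")) {
  preset <- match.arg(preset)
  edges <- switch(preset,
    respiration  = c(0.1, 0.5),
    pulse_wave   = c(0.75, 3.0),
    heart_sound_A = c(25, 400),
    heart_sound_B = c(16, 80),
    ecg          = c(0.5, 20.0)
  )
  band_spec(preset, edges[1], edges[2])
}

#' @export
print.band_spec <- function(x, ...) {
  cat(sprintf("<band_spec> %s: %.3g-%.3g Hz, order %d Butterworth\n",
              x$name, x$low, x$high, x$order))
  invisible(x)
}

#' Design a Butterworth bandpass for a given sampling rate
#'
#' @param band A [band_spec()].
#' @param fs Sampling rate in Hz. The upper edge must lie below `fs/2`.
#' @return A list with filter coefficients `b`, `a` (and the design
#'   metadata), as used by [extract_component()].
#' @export
design_bandpass <- function(band, fs) {
  stopifnot(inherits(band, "band_spec"))
  assert_scalar_pos(fs, "fs")
  if (band$high >= fs / 2) {
    abort(sprintf("band '%s' upper edge %.3g Hz violates the Nyquist limit %.3g Hz.",
                  band$name, band$high, fs / 2),
          class = "radarheart_nyquist_violation")
  }
  if (band$low <= 0) {
    abort("band lower edge must be positive.", class = "radarheart_invalid_input")
  }
  flt <- signal::butter(band$order, c(band$low, band$high) / (fs / 2),
                        type = "pass")
  list(b = flt$b, a = flt$a, band = band, fs = fs)
}

# The transfer-function form of a narrow bandpass far below Nyquist is
# ill-conditioned; choose an intermediate rate at which the band is well
# placed: fs_work <= 500*low (conditioning) and fs_work >= 4*high (headroom).
bandpass_work_rate <- function(band, fs) {
  target <- max(4 * band$high, min(fs, 500 * band$low))
  dec <- max(1L, floor(fs / target))
  while (dec > 1L && band$high >= (fs / dec) / 2 / 1.25) dec <- dec - 1L
  dec
}

#' Extract a frequency band from a time series
#'
#' Applies the band's fourth-order Butterworth filter with zero-phase
#' forward-backward filtering (no group delay, so segment onset timings are
#' preserved) and odd-reflection edge padding. Bands lying far below the
#' Nyquist rate are filtered at a reduced intermediate rate (staged
#' anti-aliased decimation) and spline-interpolated back, which keeps the
#' quartic design numerically well conditioned.
#'
#' @param x Numeric time series.
#' @param band A [band_spec()] or preset name (string).
#' @param fs Sampling rate in Hz.
#' @param zero_phase Use forward-backward filtering (default `TRUE`); set
#'   `FALSE` for a causal single pass.
#' @return Filtered series, same length as `x`.
#' @examples
#' fs <- 2000
#' t <- seq(0, 2, by = 1 / fs)
#' x <- sin(2 * pi * 40 * t)
#' y <- extract_component(x, "heart_sound_B", fs)
#' @export
extract_component <- function(x, band, fs, zero_phase = TRUE) {
  if (is.character(band)) band <- band_preset(band)
  assert_scalar_pos(fs, "fs")
  if (band$high >= fs / 2) {
    abort(sprintf("band '%s' upper edge %.3g Hz violates the Nyquist limit %.3g Hz.",
                  band$name, band$high, fs / 2),
          class = "radarheart_nyquist_violation")
  }
  n <- length(x)
  x <- x - mean(x)  # a bandpass excludes DC; removing it first avoids the
                    # long step transient of the quartic filter
  dec <- bandpass_work_rate(band, fs)
  if (dec > 1L) {
    xw <- decimate_staged(x, dec)
    fsw <- fs / dec
  } else {
    xw <- x
    fsw <- fs
  }
  flt <- design_bandpass(band, fsw)
  pad <- min(length(xw) - 1L, max(30L, ceiling(2 * fsw / band$low)))
  if (zero_phase) {
    yw <- filtfilt_pad(flt, xw, pad)
  } else {
    pre <- 2 * xw[1] - xw[min(length(xw), pad + 1L):2L]
    yw <- signal::filter(signal::Arma(b = flt$b, a = flt$a), c(pre, xw))
    yw <- yw[(length(pre) + 1L):(length(pre) + length(xw))]
  }
  if (dec > 1L) {
    tw <- (seq_along(yw) - 1) * dec
    y <- stats::spline(tw, yw, xout = seq_len(n) - 1)$y
  } else {
    y <- as.numeric(yw)
  }
  y
}

#' Add band-filtered channels to a recording
#'
#' Data-frame-first convenience over [extract_component()]: filters one
#' column of a recording through one or more band presets and appends the
#' results as new columns named `<col>_<band>`.
#'
#' @param rec A recording tibble (must contain `col`).
#' @param col Column to filter (string).
#' @param bands Character vector of preset names or list of [band_spec()]s.
#' @param fs Sampling rate; inferred from the recording when missing.
#' @return The recording with the filtered columns appended.
#' @export
filter_bands <- function(rec, col, bands, fs = NULL) {
  fs <- infer_fs(rec, fs)
  if (!col %in% names(rec)) {
    abort(sprintf("column `%s` not found in recording.", col),
          class = "radarheart_missing_channel")
  }
  if (!is.list(bands)) bands <- as.list(bands)
  for (b in bands) {
    bs <- if (is.character(b)) band_preset(b) else b
    rec[[paste0(col, "_", bs$name)]] <- extract_component(rec[[col]], bs, fs)
  }
  rec
}
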