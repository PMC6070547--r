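#' Double integration of an acceleration signal
#'
#' The phonocardiograph measures chest-surface acceleration while the radar
#' measures displacement; to compare morphologies the PCG segment is
#' integrated twice (differentiating the radar instead would overweight its
#' noise). Cumulative trapezoidal integration is applied twice, with a
#' linear detrend after each pass to control integration drift.
#'
#' @param pcg Acceleration series.
#' @param fs Sampling rate, Hz.
#' @return Displacement-domain series, same length.
#' @export
double_integrate <- function(pcg, fs) {
  assert_scalar_pos(fs, "fs")
  v <- detrend_linear(cumtrapz_vec(pcg, 1 / fs))
  detrend_linear(cumtrapz_vec(v, 1 / fs))
}

cumtrapz_vec <- function(x, dx) {
  n <- length(x)
  if (n < 2L) return(rep(0, n))
  c(0, cumsum((x[-1] + x[-n]) / 2 * dx))
}

# Endpoint-anchored linear detrend: removes the line through the first and
# last samples, then the mean. Exact for periodic content spanning whole
# cycles (a least-squares line would tilt a sinusoid), while still removing
# the linear/quadratic drift that repeated integration accumulates.
detrend_linear <- function(x) {
  n <- length(x)
  if (n < 3L) return(x - mean(x))
  slope <- (x[n] - x[1]) / (n - 1)
  y <- x - (x[1] + slope * (seq_len(n) - 1))
  y - mean(y)
}

#' Cross-correlation lag between two series
#'
#' Returns the integer lag `m` maximising the raw cross-correlation
#' `sum_n x1[n] * x2[n + m]` over all lags. Positive lag means the second
#' input trails the first (x2 is a delayed copy of x1).
#'
#' @param x1,x2 Numeric series.
#' @return Integer lag in samples (positive: `x2` delayed w.r.t. `x1`).
#' @export
xcorr_align <- function(x1, x2) {
  n1 <- length(x1); n2 <- length(x2)
  cc <- full_xcorr(x1, x2)
  # lag axis: m = -(n1-1) .. (n2-1); cc[k] corresponds to m = k - n1
  m <- which.max(cc) - n1
  as.integer(m)
}

# Full linear cross-correlation sum_n x1[n] * x2[n+m] via FFT.
full_xcorr <- function(x1, x2) {
  n1 <- length(x1); n2 <- length(x2)
  nf <- stats::nextn(n1 + n2 - 1L, 2)
  X1 <- stats::fft(c(x1, rep(0, nf - n1)))
  X2 <- stats::fft(c(x2, rep(0, nf - n2)))
  cc <- Re(stats::fft(Conj(X1) * X2, inverse = TRUE)) / nf
  # reorder from circular to linear lags -(n1-1)..(n2-1)
  c(cc[(nf - n1 + 2L):nf], cc[1L:n2])
}

#' Pearson similarity of two aligned heart-sound segments
#'
#' Normalised zero-lag cross-correlation after mean removal, i.e. the
#' Pearson correlation coefficient: each signal is normalised so its
#' autocorrelation at zero lag equals one. Inputs must already be aligned
#' and length-equalised.
#'
#' @param x1,x2 Aligned numeric series of equal length.
#' @return Correlation coefficient in `[-1, 1]`.
#' @export
pearson_similarity <- function(x1, x2) {
  if (length(x1) != length(x2)) {
    abort("inputs must have equal length (align and trim first).",
          class = "radarheart_invalid_input")
  }
  x1 <- x1 - mean(x1); x2 <- x2 - mean(x2)
  den <- sqrt(sum(x1^2) * sum(x2^2))
  if (den == 0) return(NA_real_)
  sum(x1 * x2) / den
}

#' Morphology comparison of a radar/PCG heart-sound pair
#'
#' Full morphology procedure: the PCG segment is double-integrated into the
#' displacement domain, the inter-sensor delay is removed by
#' cross-correlation alignment, the non-overlapping ends are trimmed, and
#' the Pearson similarity of the aligned segments is returned.
#'
#' @param radar_segment Radar displacement-domain heart-sound samples.
#' @param pcg_segment PCG acceleration-domain samples.
#' @param fs Sampling rate, Hz.
#' @param integrate_pcg Double-integrate the PCG first (default `TRUE`).
#' @return A tibble with `lag` (samples), `lag_ms` and `similarity`.
#' @export
compare_morphology <- function(radar_segment, pcg_segment, fs,
                               integrate_pcg = TRUE) {
  if (!length(radar_segment) || !length(pcg_segment)) {
    abort("segments must be non-empty.", class = "radarheart_invalid_input")
  }
  p <- if (integrate_pcg) double_integrate(pcg_segment, fs) else pcg_segment
  lag <- xcorr_align(radar_segment, p)
  # positive lag: p trails radar, i.e. radar[i] pairs with p[i + lag];
  # trim both to the overlapping support
  n1 <- length(radar_segment); n2 <- length(p)
  i0 <- max(1L, 1L - lag); i1 <- min(n1, n2 - lag)
  if (i1 <= i0) {
    return(tibble::tibble(lag = lag, lag_ms = 1000 * lag / fs,
                          similarity = NA_real_))
  }
  r <- radar_segment[i0:i1]
  q <- p[(i0 + lag):(i1 + lag)]
  tibble::tibble(lag = lag, lag_ms = 1000 * lag / fs,
                 similarity = pearson_similarity(r, q))
}

segments_of <- function(seg, sound) {
  sound <- match.arg(sound, c("S1", "S2"))
  seg[seg$state == sound, , drop = FALSE]
}

slice_samples <- function(x, fs, start, end) {
  i0 <- max(1L, as.integer(floor(start * fs)) + 1L)
  i1 <- min(length(x), as.integer(ceiling(end * fs)))
  if (i1 < i0) return(numeric(0))
  x[i0:i1]
}

#' Per-beat heart-sound segment SNR
#'
#' The segment SNR is the ratio of the heart-sound segment amplitude to the
#' amplitude of the subsequent quiet segment: S1 is referenced to the
#' following systole, S2 to the following diastole. RMS is used as the
#' amplitude statistic; per-beat values are reported in dB
#' (`20*log10(RMS_sound / RMS_reference)`).
#'
#' @param x Band-limited heart-sound series.
#' @param seg An `rh_segmentation`.
#' @param fs Sampling rate, Hz.
#' @param sound `"S1"` or `"S2"`.
#' @param statistic `"rms"` (default) or `"peak"` (peak-to-peak amplitude).
#' @return Tibble with `beat`, `time`, `snr_db`; mean SNR in attribute
#'   `mean_snr_db`.
#' @export
segment_snr <- function(x, seg, fs, sound = c("S1", "S2"),
                        statistic = c("rms", "peak")) {
  sound <- match.arg(sound)
  statistic <- match.arg(statistic)
  ref_state <- if (sound == "S1") "systole" else "diastole"
  amp <- function(v) {
    if (!length(v)) return(NA_real_)
    if (statistic == "rms") vec_rms(v) else diff(range(v))
  }
  snd <- segments_of(seg, sound)
  out <- purrr::map_dfr(seq_len(nrow(snd)), function(k) {
    refs <- seg[seg$state == ref_state & seg$start >= snd$end[k] - 1e-9, ]
    if (!nrow(refs)) return(NULL)
    a_s <- amp(slice_samples(x, fs, snd$start[k], snd$end[k]))
    a_r <- amp(slice_samples(x, fs, refs$start[1], refs$end[1]))
    if (!is.finite(a_s) || !is.finite(a_r) || a_r == 0) return(NULL)
    tibble::tibble(beat = k, time = snd$start[k],
                   snr_db = 20 * log10(a_s / a_r))
  })
  attr(out, "mean_snr_db") <- if (nrow(out)) mean(out$snr_db) else NA_real_
  out
}

#' Per-beat peak-to-peak envelope (PPE) series
#'
#' For each beat's segment of one sound type, computes the difference
#' between the upper and lower peak envelopes (smoothed analytic-signal
#' envelope of the signal and of its negation). The per-beat PPE series is
#' the carrier of respiratory amplitude modulation of the heart sounds.
#'
#' @param x Band-limited heart-sound series.
#' @param seg An `rh_segmentation` (or ground-truth segments tibble).
#' @param fs Sampling rate, Hz.
#' @param sound `"S1"` or `"S2"`.
#' @param smooth_s Envelope smoothing window, seconds (default 0.01).
#' @return Tibble with `beat`, `time` (segment midpoints) and `ppe`
#'   (upper minus lower peak envelope, `>= 0`).
#' @export
peak_envelope_series <- function(x, seg, fs, sound = c("S1", "S2"),
                                 smooth_s = 0.01) {
  sound <- match.arg(sound)
  snd <- segments_of(seg, sound)
  purrr::map_dfr(seq_len(nrow(snd)), function(k) {
    v <- slice_samples(x, fs, snd$start[k], snd$end[k])
    if (length(v) < 4L) return(NULL)
    env <- hilbert_envelope(v, fs, smooth_s = smooth_s)
    upper <- max(env)
    lower <- -max(hilbert_envelope(-v, fs, smooth_s = smooth_s))
    tibble::tibble(beat = k, time = (snd$start[k] + snd$end[k]) / 2,
                   ppe = max(0, upper - lower))
  })
}

#' Respiratory correlation of a PPE series
#'
#' Band-filters both the per-beat PPE series and the respiration-sensor
#' signal to the respiration band (0.1–0.5 Hz), resamples the PPE onto the
#' respiration timeline, and returns the Pearson coefficient. The sign is
#' preserved: respiratory coupling of the heart-sound envelopes occurs both
#' in phase and inverted.
#'
#' @param ppe Tibble from [peak_envelope_series()] (`time`, `ppe`).
#' @param resp Respiration series (numeric vector sampled at `fs`, or a
#'   tibble with `time` and `resp`).
#' @param fs Sampling rate of `resp`, Hz.
#' @return Pearson correlation coefficient.
#' @export
respiratory_correlation <- function(ppe, resp, fs) {
  if (is.data.frame(resp)) {
    fs <- infer_fs(resp, fs)
    resp <- resp$resp
  }
  assert_scalar_pos(fs, "fs")
  if (nrow(ppe) < 4L) {
    abort("need at least 4 beats of PPE values.",
          class = "radarheart_insufficient_data")
  }
  # resample the irregular per-beat PPE onto a uniform 4 Hz grid
  fr <- 4
  t0 <- min(ppe$time); t1 <- max(ppe$time)
  tg <- seq(t0, t1, by = 1 / fr)
  pg <- stats::approx(ppe$time, ppe$ppe, xout = tg, rule = 2)$y
  pg_f <- extract_component(pg, band_preset("respiration"), fr)
  rs_f <- extract_component(resp, band_preset("respiration"), fs)
  rg <- stats::approx((seq_along(rs_f) - 1) / fs, rs_f, xout = tg, rule = 2)$y
  pearson_similarity(pg_f, rg)
}

#' A2–P2 gap of a split second heart sound
#'
#' Smooths the segment envelope and looks for the two most prominent local
#' maxima separated by a trough; returns the peak-to-peak time in
#' milliseconds, or `NA` when no second peak of sufficient prominence
#' exists (no split). The non-pathological S2 split into aortic (A2) and
#' pulmonary (P2) components occurs during inspiration.
#'
#' @param s2_segment Samples of one S2 segment.
#' @param fs Sampling rate, Hz.
#' @param smooth_s Envelope smoothing window, seconds (default 0.01 —
#'   resolves gaps down to the ~35 ms physiological minimum).
#' @param min_prominence Secondary peak must reach this fraction of the
#'   main peak, and the trough between the peaks must drop below
#'   `1 - min_prominence` of the smaller peak (default 0.3).
#' @return Gap in ms, or `NA_real_` when the segment is not split.
#' @export
s2_split_gap <- function(s2_segment, fs, smooth_s = 0.01,
                         min_prominence = 0.3) {
  if (length(s2_segment) < 8L) return(NA_real_)
  env <- hilbert_envelope(s2_segment, fs, smooth_s = smooth_s)
  n <- length(env)
  loc <- which(diff(sign(diff(env))) < 0) + 1L
  if (length(loc) < 2L) return(NA_real_)
  loc <- loc[order(env[loc], decreasing = TRUE)]
  p1 <- loc[1]
  for (p2 in loc[-1]) {
    small <- min(env[p1], env[p2])
    if (small < min_prominence * max(env[p1], env[p2])) next
    trough <- min(env[min(p1, p2):max(p1, p2)])
    if (trough <= (1 - min_prominence) * small) {
      return(1000 * abs(p2 - p1) / fs)
    }
  }
  NA_real_
}

#' Propagation velocity from a path and time difference
#'
#' Heart sounds propagate as mechanical waves along vessels and tissue;
#' comparing their arrival times at two chest regions of interest separated
#' by a known path difference yields the propagation velocity.
#'
#' @param path_diff_m Path difference in metres.
#' @param time_diff_s Arrival-time difference in seconds (> 0).
#' @return Velocity in m/s.
#' @examples
#' propagation_velocity(0.30, 0.075)  # 4 m/s
#' @export
propagation_velocity <- function(path_diff_m, time_diff_s) {
  if (any(time_diff_s <= 0)) {
    abort("`time_diff_s` must be positive.", class = "radarheart_invalid_input")
  }
  path_diff_m / time_diff_s
}
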