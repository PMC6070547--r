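#' Scene configuration for the synthetic multichannel generator
#'
#' Describes a synthetic monitoring scene: a breathing subject with a
#' beating heart observed by a 24.17 GHz Six-Port radar, a chest-contact
#' phonocardiograph (PCG, acceleration domain), a 3-lead ECG and a
#' respiration sensor, all sampled synchronously at `fs`.
#'
#' The chest-surface displacement is modelled as the superposition of
#' respiration (sinusoid, mm scale), a pulse-wave bump per beat (tens of
#' micrometres) and short S1/S2 heart-sound bursts (Gaussian-windowed
#' cosines, ~10 micrometres, 16–80 Hz content, durations drawn from the
#' empirical duration model: S1 122 +/- 22 ms, S2 92 +/- 22 ms). S1 onset
#' follows the ECG R-peak, S2 onset follows the T-wave end. Burst
#' amplitudes can be modulated by the respiration phase (peak-envelope
#' coupling, either sign), and S2 can be split into aortic/pulmonary
#' sub-bursts during inspiration.
#'
#' @param duration Scene length in seconds (default 30).
#' @param fs Sampling rate in Hz (default 2000, matching a 24-bit medical
#'   ADC front end).
#' @param bpm Mean heart rate in beats per minute (default 72).
#' @param hr_drift_bpm Peak amplitude of a slow sinusoidal heart-rate drift
#'   (default 3 bpm at 0.03 Hz).
#' @param hr_jitter_sd Per-beat white cycle jitter, seconds (default 0.01).
#' @param resp_rate Respiration rate in Hz, within 0.1–0.5 (default 0.25).
#' @param resp_amp Respiration displacement amplitude in metres
#'   (default 1.5e-3: millimetre-scale chest-wall motion).
#' @param pulse_amp Pulse-wave displacement amplitude in metres (default 5e-5).
#' @param s1_amp,s2_amp Heart-sound burst displacement amplitudes in metres
#'   (defaults 1e-5 and 8e-6).
#' @param s1_freq,s2_freq Burst centre frequencies in Hz within the
#'   16–80 Hz heart-sound band (defaults 30 and 45).
#' @param s1_dur_mean,s1_dur_sd,s2_dur_mean,s2_dur_sd Duration model for the
#'   bursts, seconds (defaults 0.122/0.022 and 0.092/0.022; draws truncated
#'   at +/- 3 sd).
#' @param s1_delay S1 onset delay after the R-peak, seconds (default 0.04).
#' @param s2_delay S2 onset delay after the T-wave end, seconds (default 0.01).
#' @param systole_frac Fraction of the cycle from S1 onset to S2 onset
#'   (default 0.3, i.e. systole about one third of the cycle).
#' @param systole_jitter_sd Jitter of the systolic interval, s (default 0.008).
#' @param ppe_coupling Respiratory amplitude-modulation depth of the burst
#'   envelopes in 0..1 (default 0.3).
#' @param ppe_sign +1 for in-phase coupling with respiration, -1 for
#'   inverted (the coupling sign is empirically random across recordings).
#' @param s2_split_ms A2–P2 gap in milliseconds applied to S2 during
#'   inspiratory half-cycles, or `NULL` (default) for no split.
#' @param ellipse_center,ellipse_a,ellipse_b,ellipse_tilt I/Q baseband-error
#'   ellipse: the ideal unit-circle locus is mapped affinely to an offset,
#'   tilted ellipse (equivalently offsets plus gain/phase imbalance).
#' @param common_mode Common-mode voltage added when splitting I/Q into the
#'   four Six-Port channels (only channel differences are contractual).
#' @param radar_noise,pcg_noise,ecg_noise,resp_noise Additive white noise
#'   standard deviations per channel (radar in volts on a unit-radius
#'   locus; PCG in m/s^2; ECG and respiration in arbitrary units).
#' @param tapping Prepend a shoulder-tapping synchronisation pattern
#'   (default `FALSE`).
#' @param tap_offset Inter-sensor offset of the PCG channel in seconds when
#'   tapping is enabled (default 0.5).
#' @param lead_in Length of the tapping lead-in window, seconds (default 5).
#' @param carrier_freq Radar carrier frequency in Hz (default 24.17e9).
#' @param seed Integer seed fixing all randomness of the scene.
#' @return A `scene_config` object (named list).
#' @export
scene_config <- function(duration = 30, fs = 2000, bpm = 72,
                         hr_drift_bpm = 3, hr_jitter_sd = 0.01,
                         resp_rate = 0.25, resp_amp = 1.5e-3,
                         pulse_amp = 5e-5, s1_amp = 1e-5, s2_amp = 8e-6,
                         s1_freq = 30, s2_freq = 45,
                         s1_dur_mean = 0.122, s1_dur_sd = 0.022,
                         s2_dur_mean = 0.092, s2_dur_sd = 0.022,
                         s1_delay = 0.04, s2_delay = 0.01,
                         systole_frac = 0.3, systole_jitter_sd = 0.008,
                         ppe_coupling = 0.3, ppe_sign = 1,
                         s2_split_ms = NULL,
                         ellipse_center = 0.15 + 0.1i, ellipse_a = 1.2,
                         ellipse_b = 0.8, ellipse_tilt = 0.5,
                         common_mode = 1,
                         radar_noise = 5e-4, pcg_noise = 1,
                         ecg_noise = 0.01, resp_noise = 0.02,
                         tapping = FALSE, tap_offset = 0.5, lead_in = 5,
                         carrier_freq = 24.17e9, seed = 1L) {
  cfg <- as.list(environment())
  for (nm in c("duration", "fs", "bpm", "resp_rate", "carrier_freq")) {
    assert_scalar_pos(cfg[[nm]], nm)
  }
  amps <- c("resp_amp", "pulse_amp", "s1_amp", "s2_amp", "radar_noise",
            "pcg_noise", "ecg_noise", "resp_noise")
  for (nm in amps) {
    if (cfg[[nm]] < 0) {
      abort(sprintf("`%s` must be >= 0.", nm), class = "radarheart_invalid_input")
    }
  }
  if (fs <= 2 * max(s1_freq, s2_freq)) {
    abort("fs must exceed twice the highest burst frequency.",
          class = "radarheart_invalid_input")
  }
  if (!ppe_sign %in% c(-1, 1)) {
    abort("`ppe_sign` must be +1 or -1.", class = "radarheart_invalid_input")
  }
  cfg$seed <- as.integer(seed)
  structure(cfg, class = "scene_config")
}

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

rnorm_trunc <- function(n, mean, sd, lim = 3) {
  x <- rnorm(n, mean, sd)
  bad <- abs(x - mean) > lim * sd
  while (any(bad)) {
    x[bad] <- rnorm(sum(bad), mean, sd)
    bad <- abs(x - mean) > lim * sd
  }
  x
}

# Gaussian-windowed cosine burst added in place; support +/- 4 sd.
add_burst <- function(x, t, center, dur, freq, amp, fs) {
  sigma <- dur / 6
  i0 <- max(1L, floor((center - 4 * sigma) * fs) + 1L)
  i1 <- min(length(x), ceiling((center + 4 * sigma) * fs) + 1L)
  if (i0 > i1) return(x)
  tt <- t[i0:i1] - center
  x[i0:i1] <- x[i0:i1] + amp * exp(-tt^2 / (2 * sigma^2)) * cos(2 * pi * freq * tt)
  x
}

#' Generate the true chest-surface displacement and ground truth
#'
#' Builds the displacement waveform `x(t)` = respiration sinusoid +
#' per-beat pulse-wave bumps + S1/S2 heart-sound bursts, together with the
#' ground-truth fiducials (R-peaks, T-wave ends, true S1/S2 segment
#' intervals) implied by the beat schedule.
#'
#' @param config A [scene_config()].
#' @return A list with elements `displacement` (tibble: `time`,
#'   `displacement`, `resp`, `pulse`, `sounds`) and `truth` (list with
#'   `r_peaks`, `t_ends`, `segments` tibble of S1/S2 intervals, `cycle_s`,
#'   and per-beat burst metadata).
#' @export
generate_displacement <- function(config) {
  stopifnot(inherits(config, "scene_config"))
  with_seed(config$seed, generate_displacement_impl(config))
}

generate_displacement_impl <- function(config) {
  fs <- config$fs
  n <- as.integer(round(config$duration * fs))
  t <- (seq_len(n) - 1) / fs
  resp <- config$resp_amp * sin(2 * pi * config$resp_rate * t)

  # beat schedule: slow sinusoidal drift plus white jitter on the cycle
  r_peaks <- numeric(0)
  tcur <- if (config$tapping) config$lead_in + 0.3 else 0.5
  while (tcur < config$duration - 0.6) {
    r_peaks <- c(r_peaks, tcur)
    bpm_t <- config$bpm + config$hr_drift_bpm * sin(2 * pi * 0.03 * tcur)
    cyc <- 60 / bpm_t + rnorm(1, 0, config$hr_jitter_sd)
    tcur <- tcur + max(0.3, cyc)
  }
  nb <- length(r_peaks)
  cycles <- c(diff(r_peaks), 60 / config$bpm)

  d1 <- rnorm_trunc(nb, config$s1_dur_mean, config$s1_dur_sd)
  d2 <- rnorm_trunc(nb, config$s2_dur_mean, config$s2_dur_sd)
  s1_start <- r_peaks + config$s1_delay
  s1_end <- s1_start + d1
  systole <- pmax(0.05, config$systole_frac * cycles - config$s1_dur_mean +
                    rnorm(nb, 0, config$systole_jitter_sd))
  s2_start <- s1_end + systole
  s2_end <- s2_start + d2
  t_ends <- s2_start - config$s2_delay

  # respiratory peak-envelope coupling (sign is a scene parameter)
  resp_phase <- function(tt) sin(2 * pi * config$resp_rate * tt)
  inspiring <- function(tt) cos(2 * pi * config$resp_rate * tt) > 0

  sounds <- numeric(n)
  pulse <- numeric(n)
  split_flag <- logical(nb)
  gain <- function(tt) {
    pmax(0.2, 1 + config$ppe_coupling * config$ppe_sign * resp_phase(tt))
  }
  for (k in seq_len(nb)) {
    c1 <- (s1_start[k] + s1_end[k]) / 2
    sounds <- add_burst(sounds, t, c1, d1[k], config$s1_freq,
                        config$s1_amp * gain(c1), fs)
    c2 <- (s2_start[k] + s2_end[k]) / 2
    if (!is.null(config$s2_split_ms) && inspiring(c2)) {
      split_flag[k] <- TRUE
      gap <- config$s2_split_ms / 1000
      for (cc in c(c2 - gap / 2, c2 + gap / 2)) {
        sounds <- add_burst(sounds, t, cc, d2[k] * 0.55, config$s2_freq,
                            config$s2_amp * gain(c2) * 0.75, fs)
      }
    } else {
      sounds <- add_burst(sounds, t, c2, d2[k], config$s2_freq,
                          config$s2_amp * gain(c2), fs)
    }
    # pulse wave: smooth mechanical bump following each R-peak
    cp <- r_peaks[k] + 0.15
    sigp <- 0.08
    i0 <- max(1L, floor((cp - 4 * sigp) * fs) + 1L)
    i1 <- min(n, ceiling((cp + 4 * sigp) * fs) + 1L)
    tt <- t[i0:i1] - cp
    pulse[i0:i1] <- pulse[i0:i1] + config$pulse_amp * exp(-tt^2 / (2 * sigp^2))
  }

  segments <- tibble::tibble(
    beat = rep(seq_len(nb), 2L),
    state = rep(c("S1", "S2"), each = nb),
    start = c(s1_start, s2_start),
    end = c(s1_end, s2_end)
  )
  segments <- segments[order(segments$start), ]

  disp <- tibble::tibble(time = t, displacement = resp + pulse + sounds,
                         resp = resp, pulse = pulse, sounds = sounds)
  attr(disp, "fs") <- fs
  truth <- list(r_peaks = r_peaks, t_ends = t_ends, segments = segments,
                cycle_s = 60 / config$bpm, s2_split = split_flag,
                s1_dur = d1, s2_dur = d2)
  list(displacement = disp, truth = truth)
}

#' Synthesise Six-Port baseband channels from a displacement waveform
#'
#' The ideal radar return is a unit-circle I/Q locus
#' `Z(t) = exp(i * 2 * pi * x(t) / (lambda/2))`; baseband offset/gain/phase
#' errors map it affinely onto the configured ellipse, per-channel white
#' noise is added, and I/Q are split into the four Six-Port voltages with a
#' common-mode component (`b5 - b6 = I`, `b3 - b4 = Q`).
#'
#' @param displacement Numeric displacement vector in metres, or the tibble
#'   from [generate_displacement()].
#' @param config A [scene_config()] (supplies ellipse, noise, carrier, fs).
#' @return Tibble with columns `time`, `b3`, `b4`, `b5`, `b6`; attributes
#'   `fs`, `carrier_freq` and `ellipse` (true distortion as `rh_ellipse`).
#' @export
generate_baseband <- function(displacement, config) {
  stopifnot(inherits(config, "scene_config"))
  with_seed(config$seed + 1L, generate_baseband_impl(displacement, config))
}

generate_baseband_impl <- function(displacement, config) {
  x <- if (is.data.frame(displacement)) displacement$displacement else displacement
  fs <- config$fs
  lambda <- C_LIGHT / config$carrier_freq
  phi0 <- runif(1, 0, 2 * pi)  # arbitrary absolute range offset
  phi <- 2 * pi * x / (lambda / 2) + phi0
  z <- exp(1i * phi)
  re <- Re(z) * config$ellipse_a
  im <- Im(z) * config$ellipse_b
  ct <- cos(config$ellipse_tilt); st <- sin(config$ellipse_tilt)
  zd <- config$ellipse_center +
    complex(real = re * ct - im * st, imaginary = re * st + im * ct)
  n <- length(zd)
  i_ch <- Re(zd)
  q_ch <- Im(zd)
  cm <- config$common_mode
  out <- tibble::tibble(
    time = (seq_len(n) - 1) / fs,
    b3 = (cm + q_ch) / 2 + rnorm(n, 0, config$radar_noise),
    b4 = (cm - q_ch) / 2 + rnorm(n, 0, config$radar_noise),
    b5 = (cm + i_ch) / 2 + rnorm(n, 0, config$radar_noise),
    b6 = (cm - i_ch) / 2 + rnorm(n, 0, config$radar_noise)
  )
  attr(out, "fs") <- fs
  attr(out, "carrier_freq") <- config$carrier_freq
  attr(out, "ellipse") <- structure(
    list(center = config$ellipse_center, a = config$ellipse_a,
         b = config$ellipse_b, tilt = config$ellipse_tilt),
    class = "rh_ellipse")
  out
}

#' Synthesise PCG, ECG and respiration-sensor companion channels
#'
#' PCG is the second finite difference of the burst-only displacement
#' (acceleration domain — radar and PCG observe the same phenomenon in
#' different domains) plus white noise. ECG is a per-beat sum-of-Gaussians
#' template whose R-peak and T-end placement equal the ground truth, plus
#' 0.1–0.5 Hz baseline wander. The respiration sensor reproduces the
#' respiration waveform in arbitrary units plus noise.
#'
#' @param disp The displacement tibble from [generate_displacement()].
#' @param truth Matching ground-truth list.
#' @param config A [scene_config()].
#' @return Tibble with columns `time`, `pcg`, `ecg`, `resp`.
#' @export
generate_companion_channels <- function(disp, truth, config) {
  stopifnot(inherits(config, "scene_config"))
  with_seed(config$seed + 2L, generate_companion_impl(disp, truth, config))
}

generate_companion_impl <- function(disp, truth, config) {
  fs <- config$fs
  t <- disp$time
  n <- length(t)
  s <- disp$sounds
  acc <- c(0, diff(s, differences = 2) * fs^2, 0)
  pcg <- acc + rnorm(n, 0, config$pcg_noise)

  ecg <- numeric(n)
  bump <- function(x, center, sigma, amp) {
    i0 <- max(1L, floor((center - 4 * sigma) * fs) + 1L)
    i1 <- min(n, ceiling((center + 4 * sigma) * fs) + 1L)
    if (i0 > i1) return(x)
    tt <- t[i0:i1] - center
    x[i0:i1] <- x[i0:i1] + amp * exp(-tt^2 / (2 * sigma^2))
    x
  }
  sig_t <- 0.04
  for (k in seq_along(truth$r_peaks)) {
    r <- truth$r_peaks[k]
    ecg <- bump(ecg, r - 0.17, 0.025, 0.15)        # P wave
    ecg <- bump(ecg, r - 0.025, 0.010, -0.15)      # Q
    ecg <- bump(ecg, r, 0.012, 1.0)                # R
    ecg <- bump(ecg, r + 0.03, 0.012, -0.25)       # S
    ecg <- bump(ecg, truth$t_ends[k] - 2 * sig_t, sig_t, 0.3)  # T, end at +2 sd
  }
  ecg <- ecg + 0.05 * sin(2 * pi * config$resp_rate * t + 0.7) +
    rnorm(n, 0, config$ecg_noise)

  resp <- disp$resp / max(config$resp_amp, .Machine$double.eps) +
    rnorm(n, 0, config$resp_noise)
  tibble::tibble(time = t, pcg = pcg, ecg = ecg, resp = resp)
}

#' Generate a complete synchronised synthetic recording
#'
#' Composes [generate_displacement()], [generate_baseband()] and
#' [generate_companion_channels()] into one multichannel recording. When
#' `tapping` is enabled, a shoulder-tap burst pattern is written into the
#' radar displacement and PCG during the lead-in window and the PCG channel
#' is delayed by `tap_offset` seconds (exercising [sync_by_tapping()]).
#' Deterministic for a fixed `config$seed`.
#'
#' @param config A [scene_config()].
#' @param seed Optional override of `config$seed`.
#' @return A list with `recording` (tibble with columns `time`, `b3..b6`,
#'   `pcg`, `ecg`, `resp`; attributes `fs`, `carrier_freq`, `units`,
#'   `truth`, `config`) and `truth`.
#' @examples
#' rec <- generate_recording(scene_config(duration = 10, seed = 7))
#' names(rec$recording)
#' @export
generate_recording <- function(config, seed = NULL) {
  stopifnot(inherits(config, "scene_config"))
  if (!is.null(seed)) config$seed <- as.integer(seed)
  gd <- generate_displacement(config)
  disp <- gd$displacement
  truth <- gd$truth

  if (config$tapping) {
    tap_times <- seq(1, config$lead_in - 1.5, by = 0.5)
    disp_t <- disp
    for (tt in tap_times) {
      disp_t$sounds <- add_burst(disp_t$sounds, disp_t$time, tt, 0.08, 25,
                                 8 * config$s1_amp, config$fs)
    }
    disp_t$displacement <- disp_t$resp + disp_t$pulse + disp_t$sounds
    disp <- disp_t
    truth$tap_times <- tap_times
  }

  bb <- generate_baseband(disp, config)
  comp <- generate_companion_channels(disp, truth, config)

  if (config$tapping && config$tap_offset != 0) {
    # PCG acquired asynchronously: delay by an integer number of samples
    k <- as.integer(round(config$tap_offset * config$fs))
    pcg <- comp$pcg
    if (k > 0) {
      comp$pcg <- c(rep(0, k), pcg[seq_len(length(pcg) - k)])
    } else if (k < 0) {
      comp$pcg <- c(pcg[(-k + 1):length(pcg)], rep(0, -k))
    }
  }

  rec <- dplyr::bind_cols(bb, comp[c("pcg", "ecg", "resp")])
  attr(rec, "fs") <- config$fs
  attr(rec, "carrier_freq") <- config$carrier_freq
  attr(rec, "units") <- c(b3 = "V", b4 = "V", b5 = "V", b6 = "V",
                          pcg = "m/s2", ecg = "au", resp = "au")
  attr(rec, "truth") <- truth
  attr(rec, "config") <- config
  class(rec) <- c("rh_recording", class(rec))
  list(recording = rec, truth = truth)
}

#' Ground truth attached to a recording
#' @param rec A recording produced by [generate_recording()] or read back
#'   by [read_recording()].
#' @return The ground-truth list, or `NULL` when absent.
#' @export
recording_truth <- function(rec) attr(rec, "truth")
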