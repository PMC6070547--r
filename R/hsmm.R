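HS_STATES <- c("S1", "systole", "S2", "diastole")

#' Segmentation variant configuration
#'
#' Two published parameterisations of the heart-sound segmenter:
#' variant A (classic phonocardiogram settings: 25–400 Hz band,
#' autocorrelation heart-cycle search limits 0.5–2.0 s, i.e. 30–120 bpm)
#' and variant B (radar-adjusted: 16–80 Hz band, cycle limits 0.45–1.45 s,
#' favouring 41–133 bpm).
#'
#' @param variant `"B"` (default, radar-adjusted) or `"A"`.
#' @param feature_rate Envelope feature frame rate in Hz (default 100; a
#'   10 ms frame keeps the decoded S1/S2 segment durations an unbiased
#'   estimate of the underlying duration distributions).
#' @return A `variant_config` list with `band`, `cycle_limits`,
#'   `feature_rate`.
#' @export
variant_config <- function(variant = c("B", "A"), feature_rate = 100) {
  variant <- match.arg(variant)
  assert_scalar_pos(feature_rate, "feature_rate")
  if (variant == "A") {
    structure(list(variant = "A", band = band_preset("heart_sound_A"),
                   cycle_limits = c(0.5, 2.0), feature_rate = feature_rate),
              class = "variant_config")
  } else {
    structure(list(variant = "B", band = band_preset("heart_sound_B"),
                   cycle_limits = c(0.45, 1.45), feature_rate = feature_rate),
              class = "variant_config")
  }
}

#' Heart-sound state duration model
#'
#' Per-state normal duration distributions. S1 and S2 durations are the
#' empirical values for healthy adults (122 +/- 22 ms and 92 +/- 22 ms).
#' Systole-without-S1 and diastole-without-S2 are derived per recording
#' from the estimated heart cycle `c`: mean `max(k * c - mu_S, floor)` with
#' `k = 0.3` (systole) and `k = 0.7` (diastole), sd 25% of the mean — this
#' keeps the four state means summing to the estimated cycle.
#'
#' @param s1_mean,s1_sd,s2_mean,s2_sd S1/S2 duration moments in seconds.
#' @param systole_frac,diastole_frac Cycle fractions `k` (see above).
#' @param rel_sd Relative sd of the derived systole/diastole durations.
#' @param floor_s Lower floor on derived duration means, seconds.
#' @param trunc_sd Duration support truncation, in sd units (default 3).
#' @return A `duration_model` list.
#' @export
duration_model <- function(s1_mean = 0.122, s1_sd = 0.022,
                           s2_mean = 0.092, s2_sd = 0.022,
                           systole_frac = 0.3, diastole_frac = 0.7,
                           rel_sd = 0.25, floor_s = 0.05, trunc_sd = 3) {
  structure(list(s1_mean = s1_mean, s1_sd = s1_sd, s2_mean = s2_mean,
                 s2_sd = s2_sd, systole_frac = systole_frac,
                 diastole_frac = diastole_frac, rel_sd = rel_sd,
                 floor_s = floor_s, trunc_sd = trunc_sd),
            class = "duration_model")
}

# Per-state (mean, sd) in seconds given the estimated heart cycle.
state_durations <- function(dur, cycle_s) {
  sys_mean <- max(dur$floor_s, dur$systole_frac * cycle_s - dur$s1_mean)
  dia_mean <- max(dur$floor_s, dur$diastole_frac * cycle_s - dur$s2_mean)
  list(
    S1 = c(dur$s1_mean, dur$s1_sd),
    systole = c(sys_mean, dur$rel_sd * sys_mean),
    S2 = c(dur$s2_mean, dur$s2_sd),
    diastole = c(dia_mean, dur$rel_sd * dia_mean)
  )
}

#' Estimate the heart-cycle duration by autocorrelation
#'
#' Computes the autocorrelation of the smoothed heart-sound envelope and
#' returns the lag of its maximum within the variant's cycle limits. Limits
#' of 0.45–1.45 s correspond to heart rates of 41–133 bpm (`floor(60/limit)`).
#'
#' @param hs_signal Band-limited heart-sound series.
#' @param fs Sampling rate in Hz.
#' @param limits Two-element numeric `(min_s, max_s)` search window.
#' @return Estimated cycle duration in seconds.
#' @export
estimate_heart_cycle <- function(hs_signal, fs, limits = c(0.45, 1.45)) {
  assert_scalar_pos(fs, "fs")
  if (length(hs_signal) < 2 * limits[2] * fs) {
    abort("signal must be at least twice the maximum cycle limit long.",
          class = "radarheart_insufficient_data")
  }
  env <- hilbert_envelope(hs_signal, fs, smooth_s = 0.02)
  fr <- 50
  env_f <- frame_aggregate(env, fs, fr)
  lag_min <- max(1L, floor(limits[1] * fr))
  lag_max <- min(length(env_f) - 1L, ceiling(limits[2] * fr))
  ac <- stats::acf(env_f, lag.max = lag_max, plot = FALSE, demean = TRUE)$acf[, 1, 1]
  lags <- lag_min:lag_max
  best <- lags[which.max(ac[lags + 1L])]
  min(max(best / fr, limits[1]), limits[2])
}

# Average a sample-rate series into non-overlapping frames at `fr` Hz.
frame_aggregate <- function(x, fs, fr) {
  step <- fs / fr
  nf <- max(1L, floor(length(x) / step))
  idx <- floor((seq_len(nf) - 1) * step)
  w <- max(1L, floor(step))
  out <- numeric(nf)
  for (k in seq_len(nf)) {
    i0 <- idx[k] + 1L
    out[k] <- mean(x[i0:min(length(x), i0 + w - 1L)])
  }
  out
}

#' Envelope features for heart-sound segmentation
#'
#' Computes four per-frame features of a band-limited heart-sound signal at
#' the variant's frame rate: (1) the homomorphic envelope (low-passed log
#' magnitude envelope, exponentiated), (2) the analytic-signal (Hilbert)
#' magnitude envelope, (3) RMS power in the lower half of the variant band,
#' (4) RMS power in the upper half. Each feature is standardised to zero
#' mean and unit variance per recording; a constant feature (e.g. on an
#' all-zero signal) standardises to zeros.
#'
#' @param hs_signal Band-limited heart-sound series.
#' @param fs Sampling rate, Hz.
#' @param config A [variant_config()].
#' @param homo_lp_hz Cut-off of the homomorphic envelope low-pass in Hz
#'   (default 20). Lower values smooth more but smear segment boundaries
#'   outward, biasing decoded durations long.
#' @return Tibble with `time` (frame centres, s) and feature columns
#'   `f_homo`, `f_hilb`, `f_band_lo`, `f_band_hi`; attribute `feature_rate`.
#' @export
hs_features <- function(hs_signal, fs, config = variant_config("B"),
                        homo_lp_hz = 20) {
  assert_scalar_pos(fs, "fs")
  fr <- config$feature_rate
  env <- Mod(analytic_signal(hs_signal))
  eps <- 1e-12
  lp <- signal::butter(2, min(0.99, homo_lp_hz / (fs / 2)), type = "low")
  homo <- exp(filtfilt_pad(list(b = lp$b, a = lp$a), log(env + eps),
                           pad = min(length(env) - 1L, as.integer(fs))))
  mid <- sqrt(config$band$low * config$band$high)
  lo <- extract_component(hs_signal, band_spec("lo", config$band$low, mid), fs)
  hi <- extract_component(hs_signal, band_spec("hi", mid, config$band$high), fs)

  f <- tibble::tibble(
    time = (seq_len(max(1L, floor(length(hs_signal) / (fs / fr)))) - 0.5) / fr,
    f_homo = frame_aggregate(homo, fs, fr),
    f_hilb = frame_aggregate(env, fs, fr),
    f_band_lo = sqrt(frame_aggregate(lo^2, fs, fr)),
    f_band_hi = sqrt(frame_aggregate(hi^2, fs, fr))
  )
  for (nm in setdiff(names(f), "time")) {
    v <- f[[nm]]
    s <- sd(v)
    f[[nm]] <- if (is.finite(s) && s > 0) (v - mean(v)) / s else rep(0, length(v))
  }
  attr(f, "feature_rate") <- fr
  f
}

#' Frame-level reference labels from ground-truth fiducials
#'
#' Assigns each feature frame one of the four cyclic states using true (or
#' ECG-derived) S1/S2 intervals: frames inside an S1 interval are `S1`,
#' inside an S2 interval `S2`, between an S1 end and the following S2 start
#' `systole`, otherwise `diastole`.
#'
#' @param truth Ground-truth list with a `segments` tibble (see
#'   [generate_displacement()]), or a segments tibble directly.
#' @param times Frame-centre times in seconds.
#' @return Factor vector of labels over [HS_STATES].
#' @export
frame_labels <- function(truth, times) {
  seg <- if (is.data.frame(truth)) truth else truth$segments
  lab <- rep("diastole", length(times))
  s1 <- seg[seg$state == "S1", ]
  s2 <- seg[seg$state == "S2", ]
  for (k in seq_len(nrow(s1))) {
    lab[times >= s1$start[k] & times < s1$end[k]] <- "S1"
  }
  for (k in seq_len(nrow(s2))) {
    lab[times >= s2$start[k] & times < s2$end[k]] <- "S2"
  }
  # systole: from each S1 end to the next S2 start
  for (k in seq_len(nrow(s1))) {
    nxt <- s2$start[s2$start >= s1$end[k]]
    if (length(nxt)) {
      lab[times >= s1$end[k] & times < nxt[1]] <- "systole"
    }
  }
  factor(lab, levels = HS_STATES)
}

#' Train one-vs-rest logistic-regression emission models
#'
#' Fits one binomial logistic regression per state against the rest on
#' standardised envelope features; per-frame state posteriors are the
#' normalised one-vs-rest probabilities.
#'
#' @param features Feature tibble from [hs_features()].
#' @param labels Factor/character vector of per-frame reference states
#'   (all four states must be present).
#' @return An `rh_emissions` object. [tidy()] returns the coefficients,
#'   [glance()] the training accuracy and size.
#' @export
train_emissions <- function(features, labels) {
  labels <- as.character(labels)
  missing_states <- setdiff(HS_STATES, unique(labels))
  if (length(missing_states)) {
    abort(paste0("state(s) absent from labels: ",
                 paste(missing_states, collapse = ", ")),
          class = "radarheart_missing_state")
  }
  fcols <- setdiff(names(features), "time")
  X <- as.matrix(features[fcols])
  coefs <- matrix(NA_real_, nrow = length(fcols) + 1L, ncol = 4L,
                  dimnames = list(c("(Intercept)", fcols), HS_STATES))
  for (s in HS_STATES) {
    y <- as.integer(labels == s)
    fit <- suppressWarnings(
      glm.fit(cbind(1, X), y, family = binomial())
    )
    coefs[, s] <- fit$coefficients
  }
  coefs[!is.finite(coefs)] <- 0
  post <- emission_posteriors_matrix(coefs, X)
  acc <- mean(HS_STATES[max.col(post)] == labels)
  priors <- vapply(HS_STATES, function(s) mean(labels == s), numeric(1))
  structure(list(coefficients = coefs, features = fcols,
                 class_priors = priors,
                 train_accuracy = acc, n_frames = nrow(X)),
            class = "rh_emissions")
}

emission_posteriors_matrix <- function(coefs, X) {
  eta <- cbind(1, X) %*% coefs
  p <- 1 / (1 + exp(-eta))
  p <- pmax(p, 1e-12)
  p / rowSums(p)
}

#' Per-frame state posteriors from an emission model
#'
#' With `scale = "posterior"`, returns the normalised one-vs-rest state
#' probabilities. With `scale = "likelihood"` (used by the decoder), the
#' posteriors are divided by the training class priors and renormalised,
#' approximating the emission likelihoods `P(features | state)`: the state
#' frequencies are then contributed solely by the duration model rather
#' than being double-counted, which removes the shrinkage of the rare,
#' short S1/S2 states at segment boundaries.
#'
#' @param emissions An `rh_emissions` model.
#' @param features Feature tibble from [hs_features()].
#' @param scale `"posterior"` (default) or `"likelihood"`.
#' @return Numeric matrix, frames x 4 states, rows summing to one.
#' @export
emission_posteriors <- function(emissions, features,
                                scale = c("posterior", "likelihood")) {
  stopifnot(inherits(emissions, "rh_emissions"))
  scale <- match.arg(scale)
  X <- as.matrix(features[emissions$features])
  p <- emission_posteriors_matrix(emissions$coefficients, X)
  if (scale == "likelihood") {
    pr <- emissions$class_priors %||% rep(0.25, 4)
    p <- sweep(p, 2, pmax(pr, 1e-6), "/")
    p <- p / rowSums(p)
  }
  p
}

#' @export
print.rh_emissions <- function(x, ...) {
  cat(sprintf("<rh_emissions> one-vs-rest logistic regression, %d features, training accuracy %.3f (%d frames)\n",
              length(x$features), x$train_accuracy, x$n_frames))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.rh_emissions <- function(x, ...) {
  co <- x$coefficients
  tibble::tibble(
    state = rep(colnames(co), each = nrow(co)),
    term = rep(rownames(co), times = ncol(co)),
    estimate = as.numeric(co)
  )
}

#' @exportS3Method generics::glance
glance.rh_emissions <- function(x, ...) {
  tibble::tibble(train_accuracy = x$train_accuracy, n_frames = x$n_frames,
                 n_features = length(x$features))
}

# Discretised truncated-normal log-pmf over a duration support (in frames).
duration_log_pmf <- function(mean_s, sd_s, fr, trunc_sd = 3, t_max = Inf) {
  mu <- mean_s * fr
  sg <- max(sd_s * fr, 0.25)
  dmin <- max(1L, as.integer(floor(mu - trunc_sd * sg)))
  dmax <- max(dmin, as.integer(ceiling(mu + trunc_sd * sg)))
  dmax <- min(dmax, max(dmin, as.integer(t_max)))
  d <- dmin:dmax
  w <- dnorm(d, mu, sg)
  if (sum(w) <= 0) w <- rep(1, length(d))
  list(dmin = dmin, dmax = dmax, logp = log(w / sum(w)))
}

#' Duration-dependent Viterbi decoding of heart-sound states
#'
#' Extended (hidden semi-Markov) Viterbi decoding: maximises the sum of
#' per-frame log state posteriors plus per-segment log duration
#' probabilities, subject to the fixed cyclic order
#' S1 -> systole -> S2 -> diastole -> S1. The probability of leaving a
#' state grows with the time already spent in it, as encoded by the
#' truncated-normal duration distributions. Ties are broken toward the
#' earlier state change.
#'
#' @param posteriors Frames x 4 matrix of state posteriors (columns in
#'   [HS_STATES] order), e.g. from [emission_posteriors()].
#' @param durations A [duration_model()].
#' @param cycle_s Estimated heart-cycle duration in seconds.
#' @param feature_rate Frame rate of the posteriors, Hz.
#' @param t0 Time of the first frame centre (s), used for segment times.
#' @return An `rh_segmentation`: tibble of segments (`state`, `start`,
#'   `end`, half-open, seconds) with per-frame `labels` and the decoding
#'   `score` as attributes.
#' @export
decode_states <- function(posteriors, durations = duration_model(), cycle_s,
                          feature_rate = 50, t0 = 0.5 / feature_rate) {
  if (is.data.frame(posteriors)) posteriors <- as.matrix(posteriors)
  Tn <- nrow(posteriors)
  stopifnot(ncol(posteriors) == 4L, Tn >= 1L)
  fr <- feature_rate
  E <- log(pmax(posteriors, 1e-12))
  cumE <- rbind(0, apply(E, 2, cumsum))  # (T+1) x 4

  sd_list <- state_durations(durations, cycle_s)
  pmf <- lapply(HS_STATES, function(s) {
    duration_log_pmf(sd_list[[s]][1], sd_list[[s]][2], fr,
                     trunc_sd = durations$trunc_sd, t_max = Tn)
  })
  prev_state <- c(4L, 1L, 2L, 3L)  # cyclic order

  V <- matrix(-Inf, nrow = Tn + 1L, ncol = 4L)
  V[1L, ] <- 0
  bp_d <- matrix(0L, nrow = Tn + 1L, ncol = 4L)
  for (t in seq_len(Tn)) {
    for (s in 1:4) {
      dmin <- pmf[[s]]$dmin
      if (t < dmin) next
      dmax <- min(pmf[[s]]$dmax, t)
      ds <- dmin:dmax
      idx <- t - ds + 1L  # row index into V / cumE for segment start
      sc <- cumE[t + 1L, s] - cumE[idx, s] + pmf[[s]]$logp[ds - dmin + 1L] +
        V[idx, prev_state[s]]
      m <- max(sc)
      if (m > -Inf) {
        # tie-break toward the earlier state change (largest duration)
        dbest <- ds[max(which(sc == m))]
        V[t + 1L, s] <- m
        bp_d[t + 1L, s] <- dbest
      }
    }
  }
  send <- which.max(V[Tn + 1L, ])
  if (!is.finite(V[Tn + 1L, send])) {
    # pathologically short input: fall back to frame-wise argmax
    lab <- HS_STATES[max.col(E)]
    return(segmentation_from_labels(lab, fr, t0, score = sum(apply(E, 1, max))))
  }
  labels <- character(Tn)
  t <- Tn
  s <- send
  while (t > 0L) {
    d <- bp_d[t + 1L, s]
    labels[(t - d + 1L):t] <- HS_STATES[s]
    t <- t - d
    s <- prev_state[s]
  }
  segmentation_from_labels(labels, fr, t0, score = V[Tn + 1L, send])
}

segmentation_from_labels <- function(labels, fr, t0, score = NA_real_,
                                     gated = FALSE) {
  Tn <- length(labels)
  if (Tn == 0L) {
    seg <- tibble::tibble(state = character(), start = numeric(),
                          end = numeric())
  } else {
    r <- rle(labels)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    # frame k is centred at t0 + (k-1)/fr and spans +/- half a frame
    seg <- tibble::tibble(
      state = r$values,
      start = t0 + (starts - 1L) / fr - 0.5 / fr,
      end = t0 + (ends - 1L) / fr + 0.5 / fr
    )
  }
  structure(seg, class = c("rh_segmentation", class(seg)),
            labels = labels, feature_rate = fr, score = score, gated = gated)
}

#' @export
print.rh_segmentation <- function(x, ...) {
  n1 <- sum(x$state == "S1"); n2 <- sum(x$state == "S2")
  cat(sprintf("<rh_segmentation> %d segments (%d S1, %d S2)%s\n",
              nrow(x), n1, n2,
              if (isTRUE(attr(x, "gated"))) " [low-SNR gated]" else ""))
  NextMethod()
}

# Scale-invariant burst gate: transient heart sounds make the smoothed
# envelope strongly leptokurtic, while silence or featureless noise does
# not. Distinguishes decodable input from low-SNR stretches.
has_heart_sounds <- function(hs_signal, fs, min_kurtosis = 2.5) {
  if (!all(is.finite(hs_signal)) || sd(hs_signal) == 0) return(FALSE)
  env <- hilbert_envelope(hs_signal, fs, smooth_s = 0.05)
  v <- env - mean(env)
  s2 <- mean(v^2)
  if (s2 <= 0) return(FALSE)
  kurt <- mean(v^4) / s2^2 - 3
  is.finite(kurt) && kurt > min_kurtosis
}

#' Segment a heart-sound signal into S1/systole/S2/diastole
#'
#' Full segmentation pipeline: band-limit the input with the variant's
#' Butterworth band, gate out featureless (low-SNR) input, estimate the
#' heart cycle by envelope autocorrelation, extract envelope features,
#' evaluate emission posteriors and run duration-dependent Viterbi
#' decoding. Deterministic given its inputs.
#'
#' @param x Time series (displacement or already band-limited signal).
#' @param fs Sampling rate, Hz.
#' @param emissions Trained `rh_emissions` model.
#' @param variant A [variant_config()] (default variant B).
#' @param durations A [duration_model()].
#' @param prefilter Apply the variant band filter first (default `TRUE`;
#'   set `FALSE` if `x` is already band-limited).
#' @return An `rh_segmentation` tibble (`state`, `start`, `end`). When the
#'   input shows no heart-sound-like burst contrast, an empty segmentation
#'   with attribute `gated = TRUE` is returned rather than a forced cycle.
#' @export
segment_heartsounds <- function(x, fs, emissions,
                                variant = variant_config("B"),
                                durations = duration_model(),
                                prefilter = TRUE) {
  assert_scalar_pos(fs, "fs")
  hs <- if (prefilter) extract_component(x, variant$band, fs) else x
  if (!has_heart_sounds(hs, fs)) {
    return(segmentation_from_labels(character(0), variant$feature_rate, 0,
                                    gated = TRUE))
  }
  cycle <- estimate_heart_cycle(hs, fs, variant$cycle_limits)
  feats <- hs_features(hs, fs, variant)
  post <- emission_posteriors(emissions, feats, scale = "likelihood")
  seg <- decode_states(post, durations, cycle, variant$feature_rate,
                       t0 = feats$time[1])
  attr(seg, "cycle_s") <- cycle
  attr(seg, "variant") <- variant$variant
  seg
}
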