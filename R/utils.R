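# Internal numerical helpers shared across modules.

# Analytic signal via FFT; returns complex vector the same length as x.
analytic_signal <- function(x) {
  n <- length(x)
  if (n == 1L) return(complex(real = x, imaginary = 0))
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2L == 0L) {
    h[1L] <- 1
    h[n / 2L + 1L] <- 1
    h[2L:(n / 2L)] <- 2
  } else {
    h[1L] <- 1
    h[2L:((n + 1L) / 2L)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

# Envelope = magnitude of the analytic signal, optionally smoothed with a
# centred moving average of width win_s seconds.
hilbert_envelope <- function(x, fs, smooth_s = 0) {
  env <- Mod(analytic_signal(x))
  if (smooth_s > 0) env <- moving_average(env, max(1L, round(smooth_s * fs)))
  env
}

# Centred moving average with edge truncation (window shrinks at the ends).
moving_average <- function(x, n) {
  n <- as.integer(n)
  if (n <= 1L) return(x)
  csum <- cumsum(c(0, x))
  half <- n %/% 2L
  len <- length(x)
  lo <- pmax(seq_len(len) - half, 1L)
  hi <- pmin(seq_len(len) + (n - 1L - half), len)
  (csum[hi + 1L] - csum[lo]) / (hi - lo + 1L)
}

# Zero-phase Butterworth application with odd-reflection padding. `flt` is a
# signal::Arma-style list with elements b and a. The pad suppresses the
# forward-backward transients that plain filtfilt leaves at the edges.
filtfilt_pad <- function(flt, x, pad) {
  n <- length(x)
  pad <- as.integer(min(pad, n - 1L))
  if (pad > 0L) {
    pre <- 2 * x[1L] - x[(pad + 1L):2L]
    post <- 2 * x[n] - x[(n - 1L):(n - pad)]
    xp <- c(pre, x, post)
  } else {
    xp <- x
  }
  yp <- signal::filtfilt(signal::Arma(b = flt$b, a = flt$a), xp)
  if (pad > 0L) yp[(pad + 1L):(pad + n)] else yp
}

# Staged low-pass decimation by an integer factor. Each stage decimates by
# at most 10 after a zero-phase order-4 Butterworth anti-alias filter.
decimate_staged <- function(x, factor) {
  factor <- as.integer(factor)
  while (factor > 1L) {
    q <- min(factor, 10L)
    lp <- signal::butter(4, 0.8 / q, type = "low")
    x <- filtfilt_pad(list(b = lp$b, a = lp$a), x, pad = min(length(x) - 1L, 30L * q))
    x <- x[seq(1L, length(x), by = q)]
    factor <- factor %/% q
  }
  x
}

# Wrap angles to [-pi, +pi).
wrap_to_pi <- function(phi) {
  w <- (phi + pi) %% (2 * pi) - pi
  w[w >= pi] <- w[w >= pi] - 2 * pi
  w
}

vec_rms <- function(x) sqrt(mean(x^2))

assert_scalar_pos <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    abort(sprintf("`%s` must be a single positive number.", name),
          class = "radarheart_invalid_input")
  }
  invisible(x)
}

first_col_time <- function(df) {
  if (!is.data.frame(df)) {
    abort("expected a data frame.", class = "radarheart_invalid_input")
  }
  if (!"time" %in% names(df)) {
    abort("data frame must contain a `time` column.",
          class = "radarheart_invalid_input")
  }
  invisible(df)
}

# Infer sampling rate from a recording attribute or a time column.
infer_fs <- function(df, fs = NULL) {
  fs <- fs %||% attr(df, "fs")
  if (is.null(fs)) {
    first_col_time(df)
    dt <- diff(df$time[1:2])
    fs <- 1 / dt
  }
  assert_scalar_pos(fs, "fs")
  fs
}
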