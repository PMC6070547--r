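#' Combine Six-Port baseband channels into a complex I/Q trace
#'
#' A Six-Port interferometer outputs four baseband voltages `b3..b6` whose
#' pairwise differences form the in-phase and quadrature components of the
#' received signal: `Z = (b5 - b6) + i (b3 - b4)`. Common-mode content on
#' the differential pairs cancels exactly.
#'
#' @param frame A data frame with numeric columns `b3`, `b4`, `b5`, `b6`
#'   (equal length) and optionally `time`.
#' @return A tibble with columns `time` (seconds; synthesised from `fs` when
#'   absent), `i`, `q` and `z` (complex). The sampling rate is carried in the
#'   `fs` attribute.
#' @param fs Sampling rate in Hz; taken from `attr(frame, "fs")` or the
#'   `time` column when missing.
#' @examples
#' frame <- tibble::tibble(b3 = 0, b4 = 0, b5 = 1, b6 = 0)
#' combine_baseband(frame, fs = 2000)$z  # 1+0i
#' @export
combine_baseband <- function(frame, fs = NULL) {
  need <- c("b3", "b4", "b5", "b6")
  if (!is.data.frame(frame) || !all(need %in% names(frame))) {
    abort("`frame` must be a data frame with columns b3, b4, b5, b6.",
          class = "radarheart_invalid_input")
  }
  lens <- vapply(frame[need], length, integer(1))
  if (length(unique(lens)) != 1L || lens[1] < 1L) {
    abort("baseband channels must be non-empty and of equal length.",
          class = "radarheart_invalid_input")
  }
  fs <- infer_fs(frame, fs)
  i <- frame$b5 - frame$b6
  q <- frame$b3 - frame$b4
  time <- if ("time" %in% names(frame)) frame$time else (seq_along(i) - 1) / fs
  out <- tibble::tibble(time = time, i = i, q = q,
                        z = complex(real = i, imaginary = q))
  attr(out, "fs") <- fs
  out
}

#' Fit an ellipse to an I/Q point cloud
#'
#' Direct algebraic least-squares conic fit with the ellipse constraint
#' (Fitzgibbon-type, in the numerically stable partitioned form). Baseband
#' offset, gain and phase errors deform the ideal unit-circle I/Q locus into
#' an offset, tilted ellipse; the fitted parameters drive [compensate_iq()].
#' Five coarsely distributed points suffice to determine the ellipse.
#'
#' @param z Complex vector of I/Q samples, or a data frame with columns
#'   `i`/`q` (or a `z` column) as returned by [combine_baseband()].
#' @return An object of class `rh_ellipse`: list with `center` (complex),
#'   `a`, `b` (semi-axes, `a >= b > 0`) and `tilt` (radians in `[-pi/2, pi/2)`).
#' @examples
#' th <- seq(0, 2 * pi, length.out = 9)[-9]
#' fit_ellipse(complex(real = cos(th), imaginary = sin(th)))
#' @export
fit_ellipse <- function(z) {
  z <- as_iq_complex(z)
  z <- z[is.finite(Re(z)) & is.finite(Im(z))]
  z <- z[!duplicated(signif(cbind(Re(z), Im(z)), 12))]
  if (length(z) < 5L) {
    abort("ellipse fitting needs at least 5 distinct I/Q points.",
          class = "radarheart_insufficient_data")
  }
  x <- Re(z); y <- Im(z)
  # normalise for conditioning; uniform scale keeps the tilt unchanged
  mx <- mean(x); my <- mean(y)
  sc <- mean(sqrt((x - mx)^2 + (y - my)^2))
  if (sc <= 0) {
    abort("degenerate I/Q geometry: points coincide.",
          class = "radarheart_degenerate_geometry")
  }
  xn <- (x - mx) / sc; yn <- (y - my) / sc

  D1 <- cbind(xn^2, xn * yn, yn^2)
  D2 <- cbind(xn, yn, 1)
  S1 <- crossprod(D1); S2 <- crossprod(D1, D2); S3 <- crossprod(D2)
  Tm <- tryCatch(-solve(S3, t(S2)), error = function(e) NULL)
  if (is.null(Tm)) {
    abort("degenerate I/Q geometry: collinear or coincident points.",
          class = "radarheart_degenerate_geometry")
  }
  M <- S1 + S2 %*% Tm
  M <- rbind(M[3, ] / 2, -M[2, ], M[1, ] / 2)
  ev <- eigen(M)
  V <- Re(ev$vectors)
  cond <- 4 * V[1, ] * V[3, ] - V[2, ]^2
  ok <- which(cond > 0)
  if (length(ok) == 0L) {
    abort("points do not determine an ellipse (non-elliptic conic).",
          class = "radarheart_degenerate_geometry")
  }
  a1 <- V[, ok[1]]
  coefs <- c(a1, as.numeric(Tm %*% a1))  # A B C D E F in normalised frame

  A <- coefs[1]; B <- coefs[2]; Cc <- coefs[3]
  D <- coefs[4]; E <- coefs[5]; Fc <- coefs[6]
  Q <- matrix(c(A, B / 2, B / 2, Cc), 2)
  ctr <- tryCatch(solve(2 * Q, -c(D, E)), error = function(e) NULL)
  if (is.null(ctr)) {
    abort("degenerate conic: no finite ellipse center.",
          class = "radarheart_degenerate_geometry")
  }
  F0 <- A * ctr[1]^2 + B * ctr[1] * ctr[2] + Cc * ctr[2]^2 +
    D * ctr[1] + E * ctr[2] + Fc
  eq <- eigen(Q, symmetric = TRUE)
  ax2 <- -F0 / eq$values
  if (any(!is.finite(ax2)) || any(ax2 <= 0)) {
    abort("points do not determine an ellipse (non-elliptic conic).",
          class = "radarheart_degenerate_geometry")
  }
  axes <- sqrt(ax2)
  imaj <- which.max(axes)
  tilt <- atan2(eq$vectors[2, imaj], eq$vectors[1, imaj])
  # fold tilt into [-pi/2, pi/2): the axis direction is sign-ambiguous
  tilt <- ((tilt + pi / 2) %% pi) - pi / 2

  structure(
    list(center = complex(real = mx + sc * ctr[1], imaginary = my + sc * ctr[2]),
         a = sc * max(axes), b = sc * min(axes), tilt = tilt),
    class = "rh_ellipse"
  )
}

#' @export
print.rh_ellipse <- function(x, ...) {
  cat(sprintf(
    "<rh_ellipse> center = %.4g%+.4gi, semi-axes a = %.4g, b = %.4g, tilt = %.4g rad\n",
    Re(x$center), Im(x$center), x$a, x$b, x$tilt))
  invisible(x)
}

as_iq_complex <- function(z) {
  if (is.data.frame(z)) {
    if ("z" %in% names(z)) return(as.complex(z$z))
    if (all(c("i", "q") %in% names(z))) {
      return(complex(real = z$i, imaginary = z$q))
    }
    abort("data frame must contain `z` or `i`/`q` columns.",
          class = "radarheart_invalid_input")
  }
  as.complex(z)
}

#' Compensate I/Q baseband errors with a fitted ellipse
#'
#' Applies, in order: subtraction of the ellipse offset, rotation by the
#' negative tilt, and per-axis scaling by the inverse semi-axes. Points on
#' the fitted ellipse land on the unit circle. The trace is deliberately
#' left in the rotated (axis-aligned) frame: the omitted back-rotation is a
#' constant phase offset that cancels in relative phase differences.
#'
#' @param z Complex vector or I/Q data frame (see [fit_ellipse()]).
#' @param ellipse An `rh_ellipse`.
#' @return Complex vector of compensated samples.
#' @export
compensate_iq <- function(z, ellipse) {
  if (!inherits(ellipse, "rh_ellipse")) {
    abort("`ellipse` must be an rh_ellipse.", class = "radarheart_invalid_input")
  }
  z <- as_iq_complex(z)
  z0 <- (z - ellipse$center) * exp(-1i * ellipse$tilt)
  complex(real = Re(z0) / ellipse$a, imaginary = Im(z0) / ellipse$b)
}

#' Arctangent demodulation of a complex trace
#'
#' Wrapped phase as the four-quadrant arctangent of each sample, on the
#' branch `[-pi, +pi)`.
#'
#' @param z Complex vector or I/Q data frame.
#' @param zero_policy What to do at zero-magnitude samples, where phase is
#'   undefined: `"error"` (default) or `"hold"` the previous phase (0 for a
#'   leading zero) — the tolerant choice for noisy real data.
#' @return Numeric vector of wrapped phase values (radians).
#' @export
demodulate_phase <- function(z, zero_policy = c("error", "hold")) {
  zero_policy <- match.arg(zero_policy)
  z <- as_iq_complex(z)
  bad <- Mod(z) == 0
  if (any(bad)) {
    if (zero_policy == "error") {
      abort("zero-magnitude sample: phase undefined (see `zero_policy`).",
            class = "radarheart_undefined_phase")
    }
  }
  phi <- atan2(Im(z), Re(z))
  phi[phi >= pi] <- phi[phi >= pi] - 2 * pi
  if (any(bad)) {
    idx <- which(bad)
    for (k in idx) phi[k] <- if (k == 1L) 0 else phi[k - 1L]
  }
  phi
}

#' Unwrap a wrapped phase series
#'
#' Corrects consecutive-sample jumps with magnitude greater than `pi` by
#' adding or subtracting multiples of `2*pi`; the first sample is unchanged.
#'
#' @param phi Numeric vector of wrapped phase values (radians).
#' @return Numeric vector of unwrapped phase values.
#' @export
unwrap_phase <- function(phi) {
  if (length(phi) < 2L) return(phi)
  d <- diff(phi)
  phi + c(0, cumsum(-2 * pi * round(d / (2 * pi))))
}

#' Convert unwrapped phase to relative displacement
#'
#' For a monostatic interferometer at carrier frequency `f`, a relative
#' phase shift maps to radial displacement as
#' `dx = dsigma / (2*pi) * lambda / 2` with `lambda = c / f`. The output is
#' zero-referenced to the first sample.
#'
#' @param phi Unwrapped phase (radians).
#' @param carrier_freq Carrier frequency in Hz (e.g. `24.17e9`).
#' @return Numeric vector of relative displacement in metres.
#' @examples
#' phase_to_displacement(c(0, 2 * pi), 24.17e9)[2]  # lambda/2 ~ 6.2 mm
#' @export
phase_to_displacement <- function(phi, carrier_freq) {
  assert_scalar_pos(carrier_freq, "carrier_freq")
  lambda <- C_LIGHT / carrier_freq
  (phi - phi[1]) / (2 * pi) * lambda / 2
}

#' Demodulate a Six-Port baseband frame into displacement
#'
#' Full demodulation chain: channel combination, ellipse fit on the frame's
#' own I/Q locus, baseband-error compensation, arctangent demodulation,
#' unwrapping and phase-to-displacement conversion.
#'
#' @param frame Data frame with columns `b3..b6` (and optionally `time`),
#'   e.g. a synthetic recording from [generate_recording()].
#' @param carrier_freq Carrier frequency in Hz; defaults to the frame's
#'   `carrier_freq` attribute, else 24.17 GHz.
#' @param fs Sampling rate (Hz); inferred when missing.
#' @param refit_window Optional window length in seconds. When set, the
#'   ellipse is refitted on consecutive windows (tracking slow drifts of the
#'   baseband errors) and the per-window phase is stitched continuously at
#'   the window boundaries. Default `NULL`: one global fit.
#' @param zero_policy Passed to [demodulate_phase()].
#' @return A tibble with columns `time` and `displacement` (metres,
#'   zero-referenced), attributes `fs`, `carrier_freq` and `ellipse` (the
#'   global fit).
#' @export
demodulate <- function(frame, carrier_freq = NULL, fs = NULL,
                       refit_window = NULL, zero_policy = "error") {
  fs <- infer_fs(frame, fs)
  carrier_freq <- carrier_freq %||% attr(frame, "carrier_freq") %||% 24.17e9
  assert_scalar_pos(carrier_freq, "carrier_freq")
  iq <- combine_baseband(frame, fs)
  # a stationary target collapses the locus to one point: zero displacement
  spread <- max(Mod(iq$z - iq$z[1]))
  if (spread <= 1e-9 * max(1, max(Mod(iq$z)))) {
    out <- tibble::tibble(time = iq$time, displacement = rep(0, nrow(iq)))
    attr(out, "fs") <- fs
    attr(out, "carrier_freq") <- carrier_freq
    return(out)
  }
  ellipse <- fit_ellipse(iq$z)
  if (is.null(refit_window)) {
    phi <- unwrap_phase(demodulate_phase(compensate_iq(iq$z, ellipse),
                                         zero_policy = zero_policy))
  } else {
    assert_scalar_pos(refit_window, "refit_window")
    n <- nrow(iq)
    wlen <- max(5L, as.integer(round(refit_window * fs)))
    starts <- seq(1L, n, by = wlen)
    phi <- numeric(n)
    for (s in starts) {
      e <- min(n, s + wlen - 1L)
      s0 <- max(1L, s - 1L)  # one-sample overlap stitches adjacent windows
      zw <- iq$z[s0:e]
      ew <- tryCatch(fit_ellipse(zw), error = function(err) ellipse)
      pw <- unwrap_phase(demodulate_phase(compensate_iq(zw, ew),
                                          zero_policy = zero_policy))
      if (s0 < s) {
        # per-window tilts differ only by a constant phase offset; remove it
        phi[s:e] <- pw[-1L] + (phi[s0] - pw[1L])
      } else {
        phi[s:e] <- pw
      }
    }
  }
  out <- tibble::tibble(time = iq$time,
                        displacement = phase_to_displacement(phi, carrier_freq))
  attr(out, "fs") <- fs
  attr(out, "carrier_freq") <- carrier_freq
  attr(out, "ellipse") <- ellipse
  out
}
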