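fs <- 2000

test_that("double integration recovers sinusoid displacement from acceleration", {
  t <- seq(0, 5, by = 1 / fs)
  w <- 2 * pi * 2
  acc <- -w^2 * sin(w * t)
  x <- double_integrate(acc, fs)
  expect_gt(stats::cor(x, sin(w * t)), 0.999)
  expect_equal(double_integrate(numeric(1000), fs), numeric(1000))
  # a constant offset integrates to a quadratic that the detrend removes
  y <- double_integrate(rep(1, 4000), fs)
  expect_lt(max(abs(y)), 1e-3)
})

test_that("cross-correlation alignment finds integer lags with a fixed sign", {
  set.seed(4)
  x <- rnorm(500)
  x2 <- c(rep(0, 17), x)[1:500]  # delayed copy
  expect_equal(xcorr_align(x, x2), 17L)
  expect_equal(xcorr_align(x, x), 0L)
  a <- numeric(100); a[10] <- 1
  b <- numeric(100); b[40] <- 1
  expect_equal(abs(xcorr_align(a, b)), 30L)
})

test_that("Pearson similarity equals the covariance formula and is affine invariant", {
  x1 <- c(0.3, -1.2, 0.8, 2.1, -0.5, 0.1, 1.4, -2.2)
  x2 <- c(1.0, -0.7, 0.2, 1.8, -1.1, 0.4, 0.9, -1.6)
  direct <- sum((x1 - mean(x1)) * (x2 - mean(x2))) /
    sqrt(sum((x1 - mean(x1))^2) * sum((x2 - mean(x2))^2))
  expect_equal(pearson_similarity(x1, x2), direct, tolerance = 1e-12)
  expect_equal(pearson_similarity(x1, x2), stats::cor(x1, x2),
               tolerance = 1e-12)
  expect_equal(pearson_similarity(x1, 3 * x1), 1.0)
  expect_equal(pearson_similarity(x1, -x1), -1.0)
  expect_equal(pearson_similarity(x1, 5 - 2 * x2),
               -pearson_similarity(x1, x2), tolerance = 1e-12)
  expect_equal(pearson_similarity(x2, x1), pearson_similarity(x1, x2))
  expect_error(pearson_similarity(x1, x2[1:4]),
               class = "radarheart_invalid_input")
})

make_burst <- function(n, center, sigma, freq, fs, amp = 1) {
  t <- (seq_len(n) - 1) / fs
  amp * exp(-(t - center)^2 / (2 * sigma^2)) * cos(2 * pi * freq * (t - center))
}

test_that("morphology comparison recovers the second-derivative relation", {
  n <- 600
  radar <- make_burst(n, 0.15, 0.02, 30, fs, amp = 1e-5)
  acc <- c(0, diff(radar, differences = 2) * fs^2, 0)
  lagged <- c(rep(0, 25), acc)[1:n]
  cm <- compare_morphology(radar, lagged, fs)
  expect_gt(cm$similarity, 0.99)
  expect_equal(cm$lag, 25L, tolerance = 2)
  cm0 <- compare_morphology(radar, radar, fs, integrate_pcg = FALSE)
  expect_equal(cm0$lag, 0L)
  expect_equal(cm0$similarity, 1.0, tolerance = 1e-12)
})

test_that("independent noise segments show no morphology similarity", {
  set.seed(5)
  hits <- 0
  for (k in 1:50) {
    a <- rnorm(200)
    b <- rnorm(200)
    if (abs(pearson_similarity(a, b)) < 0.2) hits <- hits + 1
  }
  expect_gte(hits, 45)
})

test_that("morphology similarity degrades monotonically with noise", {
  set.seed(6)
  n <- 600
  radar <- make_burst(n, 0.15, 0.02, 30, fs)
  acc <- c(0, diff(radar, differences = 2) * fs^2, 0)
  # noise grid below the saturation floor where alignment-by-maximum
  # dominates the coefficient
  sims <- vapply(c(0, 0.25, 0.5, 1, 2), function(nl) {
    mean(replicate(8, {
      noisy <- acc + rnorm(n, 0, nl * stats::sd(acc))
      compare_morphology(radar, noisy, fs)$similarity
    }))
  }, numeric(1))
  expect_true(all(diff(sims) < 0.03))
  expect_lt(sims[5], sims[1] - 0.5)
})

test_that("segment SNR matches constructed amplitude ratios", {
  seg <- tibble::tibble(
    state = rep(c("S1", "systole", "S2", "diastole"), 3),
    start = seq(0, by = 0.25, length.out = 12),
    end = seq(0.25, by = 0.25, length.out = 12)
  )
  t <- seq(0, 3, by = 1 / fs)[-1]
  x <- sin(2 * pi * 40 * t)
  amp <- rep(1, length(t))
  state_of <- findInterval(t - 1e-9, seg$start)
  amp[seg$state[pmin(12, state_of)] == "systole"] <- 0.1
  amp[seg$state[pmin(12, state_of)] == "diastole"] <- 10^(-7.1 / 20)
  s <- segment_snr(x * amp, seg, fs, "S1")
  expect_equal(mean(s$snr_db), 20, tolerance = 0.5)
  s2 <- segment_snr(x * amp, seg, fs, "S2")
  expect_equal(mean(s2$snr_db), 7.1, tolerance = 1)
  # equal amplitudes give 0 dB
  s0 <- segment_snr(x, seg, fs, "S1")
  expect_equal(mean(s0$snr_db), 0, tolerance = 0.3)
})

test_that("peak envelope series measures per-beat amplitude modulation", {
  dur <- 40
  t <- seq(0, dur, by = 1 / fs)
  n <- length(t)
  centers <- seq(1, dur - 1, by = 1)
  x <- numeric(n)
  segs <- tibble::tibble(state = "S1", start = centers - 0.06,
                         end = centers + 0.06)
  mods <- 1 + 0.5 * sin(2 * pi * 0.25 * centers)
  for (k in seq_along(centers)) {
    x <- x + make_burst(n, centers[k], 0.02, 40, fs, amp = mods[k])
  }
  ppe <- peak_envelope_series(x, segs, fs, "S1")
  expect_equal(nrow(ppe), length(centers))
  expect_true(all(ppe$ppe >= 0))
  # symmetric burst: PPE close to twice the peak amplitude
  expect_equal(ppe$ppe / (2 * mods), rep(1, length(centers)), tolerance = 0.1)
  # the modulation frequency dominates the PPE spectrum
  pg <- stats::spec.pgram(ts(ppe$ppe - mean(ppe$ppe), frequency = 1),
                          plot = FALSE)
  expect_equal(pg$freq[which.max(pg$spec)], 0.25, tolerance = 0.05)
  # constant bursts carry no respiration-band modulation
  x0 <- numeric(n)
  for (k in seq_along(centers)) {
    x0 <- x0 + make_burst(n, centers[k], 0.02, 40, fs)
  }
  ppe0 <- peak_envelope_series(x0, segs, fs, "S1")
  expect_lt(stats::sd(ppe0$ppe), 0.02 * mean(ppe0$ppe))
})

test_that("respiratory coupling of the PPE is detected with its sign", {
  sc_pos <- fixture_scene(seed = 31, duration = 40, ppe_sign = 1,
                          ppe_coupling = 0.4)
  tr <- sc_pos$truth$segments
  ppe <- peak_envelope_series(sc_pos$hs, tr, sc_pos$fs, "S1")
  expect_gt(respiratory_correlation(ppe, sc_pos$recording$resp, sc_pos$fs),
            0.9)
  sc_neg <- fixture_scene(seed = 32, duration = 40, ppe_sign = -1,
                          ppe_coupling = 0.4)
  ppe_n <- peak_envelope_series(sc_neg$hs, sc_neg$truth$segments,
                                sc_neg$fs, "S1")
  expect_lt(respiratory_correlation(ppe_n, sc_neg$recording$resp, sc_neg$fs),
            -0.9)
  # null: no coupling leaves at most incidental correlation (median
  # over independent scenes)
  nulls <- vapply(33:35, function(sd) {
    scn <- fixture_scene(seed = sd, duration = 40, ppe_coupling = 0)
    ppe0 <- peak_envelope_series(scn$hs, scn$truth$segments, scn$fs, "S1")
    abs(respiratory_correlation(ppe0, scn$recording$resp, scn$fs))
  }, numeric(1))
  expect_lt(stats::median(nulls), 0.3)
})

test_that("S2 split gap is recovered across the physiological range", {
  split_seg <- function(gap_ms) {
    n <- round(0.25 * fs)
    make_burst(n, 0.1 - gap_ms / 2000, 0.008, 45, fs) +
      make_burst(n, 0.1 + gap_ms / 2000, 0.008, 45, fs)
  }
  expect_equal(s2_split_gap(split_seg(66), fs), 66, tolerance = 2)
  expect_equal(s2_split_gap(split_seg(35), fs), 35, tolerance = 2)
  for (gap in seq(25, 80, by = 5)) {
    expect_equal(s2_split_gap(split_seg(gap), fs), gap, tolerance = 10)
  }
  # a single burst has no split
  single <- make_burst(round(0.25 * fs), 0.1, 0.012, 45, fs)
  expect_true(is.na(s2_split_gap(single, fs)))
})

test_that("propagation velocity is the path over time ratio", {
  expect_equal(propagation_velocity(0.30, 0.075), 4.0)
  expect_equal(propagation_velocity(0.15, 0.0375), 4.0)
  expect_equal(propagation_velocity(0, 0.05), 0)
  expect_error(propagation_velocity(0.3, 0), class = "radarheart_invalid_input")
})
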