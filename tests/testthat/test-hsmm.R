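fs <- 2000

burst_train <- function(period, duration, fs, freq = 30, dur = 0.1) {
  t <- seq(0, duration, by = 1 / fs)
  x <- numeric(length(t))
  centers <- seq(0.5, duration - 0.5, by = period)
  for (cc in centers) {
    sel <- abs(t - cc) < dur
    x[sel] <- x[sel] + exp(-(t[sel] - cc)^2 / (2 * (dur / 6)^2)) *
      cos(2 * pi * freq * (t[sel] - cc))
  }
  x
}

test_that("autocorrelation cycle estimate finds the burst period", {
  x <- burst_train(1.0, 20, fs)
  expect_equal(estimate_heart_cycle(x, fs, c(0.45, 1.45)), 1.0,
               tolerance = 1 / 50 + 1e-9)
  # a period outside the window is clipped into it
  x2 <- burst_train(0.42, 20, fs)
  est <- estimate_heart_cycle(x2, fs, c(0.45, 1.45))
  expect_gte(est, 0.45)
  expect_lte(est, 1.45)
  expect_error(estimate_heart_cycle(x[1:fs], fs, c(0.45, 1.45)),
               class = "radarheart_insufficient_data")
  # the variant-B window corresponds to 41..133 bpm
  lim <- variant_config("B")$cycle_limits
  expect_equal(floor(60 / lim), c(133, 41))
})

test_that("envelope features localise bursts and are scale invariant", {
  t <- seq(0, 10, by = 1 / fs)
  x <- numeric(length(t))
  sel <- abs(t - 5) < 0.1
  x[sel] <- exp(-(t[sel] - 5)^2 / (2 * 0.02^2)) * cos(2 * pi * 40 * (t[sel] - 5))
  fe <- hs_features(x, fs)
  fr <- attr(fe, "feature_rate")
  for (nm in c("f_homo", "f_hilb", "f_band_lo", "f_band_hi")) {
    expect_lt(abs(fe$time[which.max(fe[[nm]])] - 5), 1.5 / fr)
  }
  fe2 <- hs_features(2 * x, fs)
  expect_equal(fe2$f_hilb, fe$f_hilb, tolerance = 1e-6)
  expect_equal(fe2$f_band_lo, fe$f_band_lo, tolerance = 1e-6)
  # all-zero input yields all-zero standardised features
  fe0 <- hs_features(numeric(length(t)), fs)
  expect_true(all(fe0$f_hilb == 0) && all(fe0$f_band_hi == 0))
})

test_that("emission training separates separable states and guards labels", {
  set.seed(3)
  n <- 400
  lab <- rep(c("S1", "systole", "S2", "diastole"), each = n / 4)
  mu <- c(S1 = 3, systole = -1, S2 = 1.5, diastole = -3)
  fe <- tibble::tibble(
    time = seq_len(n) / 50,
    f_homo = mu[lab] + rnorm(n, 0, 0.05),
    f_hilb = -mu[lab] + rnorm(n, 0, 0.05),
    f_band_lo = rnorm(n, 0, 0.05),
    f_band_hi = as.numeric(lab %in% c("S1", "S2")) + rnorm(n, 0, 0.05)
  )
  em <- train_emissions(fe, lab)
  expect_equal(em$train_accuracy, 1.0)
  post <- emission_posteriors(em, fe)
  expect_equal(rowSums(post), rep(1, n), tolerance = 1e-12)
  expect_error(train_emissions(fe[lab != "S2", ], lab[lab != "S2"]),
               class = "radarheart_missing_state")
  # broom-style accessors
  td <- tidy(em)
  expect_setequal(unique(td$state), c("S1", "systole", "S2", "diastole"))
  expect_equal(glance(em)$n_frames, n)
})

test_that("trained emissions on a synthetic scene are informative", {
  sc <- fixture_scene(seed = 11)
  em <- fixture_emissions()
  fe <- hs_features(sc$hs, sc$fs)
  lab <- as.character(frame_labels(sc$truth, fe$time))
  post <- emission_posteriors(em, fe)
  true_post <- post[cbind(seq_len(nrow(post)),
                          match(lab, c("S1", "systole", "S2", "diastole")))]
  expect_gt(mean(true_post), 0.5)
})

test_that("decoding reproduces a legal one-hot state sequence exactly", {
  fr <- 10
  lab <- rep(rep(c("S1", "systole", "S2", "diastole"), 4),
             times = rep(c(2, 3, 2, 4), 4))
  n <- length(lab)
  post <- matrix(1e-6, nrow = n, ncol = 4)
  post[cbind(seq_len(n), match(lab, c("S1", "systole", "S2", "diastole")))] <- 1
  post <- post / rowSums(post)
  dm <- duration_model(s1_mean = 0.2, s1_sd = 0.05, s2_mean = 0.2,
                       s2_sd = 0.05, systole_frac = 0.5, diastole_frac = 0.6,
                       rel_sd = 0.25, floor_s = 0.1, trunc_sd = 3)
  seg <- decode_states(post, dm, cycle_s = 1.1, feature_rate = fr)
  expect_equal(attr(seg, "labels"), lab)
})

test_that("duration-dependent Viterbi matches exhaustive enumeration", {
  set.seed(99)
  for (k in 1:60) {
    Tn <- sample(8:13, 1)
    inst <- random_decode_instance(Tn)
    seg <- decode_states(inst$post, inst$dm, inst$cycle,
                         feature_rate = inst$fr)
    oracle <- brute_force_decode(inst$post, inst$pmfs)
    expect_equal(attr(seg, "score"), oracle$score, tolerance = 1e-9)
    expect_equal(attr(seg, "labels"), oracle$labels)
  }
})

test_that("decoded segments follow the cyclic state order", {
  sc <- fixture_scene(seed = 11)
  em <- fixture_emissions()
  seg <- segment_heartsounds(sc$hs, sc$fs, em, prefilter = FALSE)
  states <- seg$state
  nxt <- c(S1 = "systole", systole = "S2", S2 = "diastole", diastole = "S1")
  expect_true(all(states[-1] == nxt[states[-length(states)]]))
  expect_true(all(seg$end > seg$start))
  expect_equal(seg$start[-1], seg$end[-nrow(seg)])
})

test_that("segmentation is invariant to uniform amplitude scaling", {
  sc <- fixture_scene(seed = 11)
  em <- fixture_emissions()
  seg1 <- segment_heartsounds(sc$hs, sc$fs, em, prefilter = FALSE)
  seg2 <- segment_heartsounds(sc$hs * 37.5, sc$fs, em, prefilter = FALSE)
  expect_equal(seg1$state, seg2$state)
  expect_equal(seg1$start, seg2$start)
})

test_that("silence and featureless noise are gated, not forced into cycles", {
  em <- fixture_emissions()
  seg <- segment_heartsounds(numeric(fs * 10), fs, em)
  expect_equal(nrow(seg), 0L)
  expect_true(attr(seg, "gated"))
  set.seed(8)
  seg2 <- segment_heartsounds(rnorm(fs * 10), fs, em)
  expect_equal(sum(seg2$state %in% c("S1", "S2")), 0L)
})

test_that("variant A is a configuration swap and also decodes", {
  sc <- fixture_scene(seed = 11)
  vcA <- variant_config("A")
  emA <- fixture_emissions(vcA)
  segA <- segment_heartsounds(sc$disp$displacement, sc$fs, emA, vcA)
  expect_gt(sum(segA$state == "S1"), 10)
  ts <- sc$truth$segments
  m <- match_events(beat_events(segA, "S1"), ts$start[ts$state == "S1"], 0.1)
  expect_gt(f_score(m)$f1, 0.8)
})

test_that("decoded S1/S2 durations track the duration model", {
  em <- fixture_emissions()
  d1 <- c(); d2 <- c()
  for (seed in 21:22) {
    sc <- fixture_scene(seed = seed, duration = 40, bpm = 70)
    seg <- segment_heartsounds(sc$hs, sc$fs, em, prefilter = FALSE)
    d1 <- c(d1, seg$end[seg$state == "S1"] - seg$start[seg$state == "S1"])
    d2 <- c(d2, seg$end[seg$state == "S2"] - seg$start[seg$state == "S2"])
  }
  expect_gt(length(d1), 60)
  expect_lt(abs(mean(d1) - 0.122), 0.01)
  expect_lt(abs(mean(d2) - 0.092), 0.01)
})
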