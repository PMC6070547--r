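# Shared fixtures, memoised so expensive synthetic scenes and emission
# training run once per test session.

.rh_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.rh_cache[[key]])) .rh_cache[[key]] <- force(expr)
  .rh_cache[[key]]
}

# Distort a unit-circle locus with ellipse parameters (forward model).
distort_ellipse <- function(z, center, a, b, tilt) {
  re <- Re(z) * a
  im <- Im(z) * b
  center + complex(real = re * cos(tilt) - im * sin(tilt),
                   imaginary = re * sin(tilt) + im * cos(tilt))
}

# A demodulated scene: recording, truth, displacement and heart-sound band.
fixture_scene <- function(seed = 11, duration = 30, bpm = 72, ...) {
  key <- paste0("scene_", seed, "_", duration, "_", bpm, "_",
                paste(c(...), collapse = "_"))
  cached(key, {
    cfg <- scene_config(duration = duration, seed = seed, bpm = bpm, ...)
    gr <- generate_recording(cfg)
    disp <- demodulate(gr$recording)
    hs <- extract_component(disp$displacement, "heart_sound_B", cfg$fs)
    list(config = cfg, recording = gr$recording, truth = gr$truth,
         disp = disp, hs = hs, fs = cfg$fs)
  })
}

# Emission model trained on two held-out synthetic subjects.
fixture_emissions <- function(variant = variant_config("B")) {
  key <- paste0("emissions_", variant$variant, "_", variant$feature_rate)
  cached(key, {
    feats <- list(); labs <- list()
    for (s in 1:2) {
      sc <- fixture_scene(seed = 100 + s, duration = 30, bpm = 66 + 6 * s)
      hs <- if (variant$variant == "B") sc$hs else
        extract_component(sc$disp$displacement, variant$band, sc$fs)
      fe <- hs_features(hs, sc$fs, variant)
      feats[[s]] <- fe
      labs[[s]] <- as.character(frame_labels(sc$truth, fe$time))
    }
    train_emissions(dplyr::bind_rows(feats), unlist(labs))
  })
}

# Independent brute-force oracle for duration-dependent decoding: full
# enumeration of every legal cyclic segmentation, scored with the same
# objective (sum of per-frame log emissions plus per-segment duration
# log-pmf) but maximised by exhaustive recursion instead of Viterbi.
brute_force_decode <- function(post, pmfs) {
  E <- log(pmax(post, 1e-12))
  Tn <- nrow(E)
  cum <- rbind(0, apply(E, 2, cumsum))
  prev <- c(4L, 1L, 2L, 3L)
  best <- -Inf
  best_lab <- NULL
  rec <- function(t, s, score, labs) {
    dmin <- pmfs[[s]]$dmin
    dmax <- min(pmfs[[s]]$dmax, t)
    if (t < dmin) return(invisible())
    for (d in dmin:dmax) {
      sc <- score + cum[t + 1L, s] - cum[t - d + 1L, s] +
        pmfs[[s]]$logp[d - dmin + 1L]
      nl <- c(rep(s, d), labs)
      if (t - d == 0L) {
        if (sc > best) {
          best <<- sc
          best_lab <<- nl
        }
      } else {
        rec(t - d, prev[s], sc, nl)
      }
    }
  }
  for (s in 1:4) rec(Tn, s, 0, integer(0))
  list(score = best, labels = c("S1", "systole", "S2", "diastole")[best_lab])
}

# Small random decoding instance: random continuous posteriors plus a
# random duration model. The oracle consumes the identical duration pmfs
# (shared objective); only the maximisation differs.
random_decode_instance <- function(Tn, fr = 10) {
  post <- matrix(exp(rnorm(Tn * 4)), nrow = Tn)
  post <- post / rowSums(post)
  cycle <- runif(1, 0.8, 1.2)
  dm <- duration_model(
    s1_mean = runif(1, 0.18, 0.30), s1_sd = runif(1, 0.05, 0.10),
    s2_mean = runif(1, 0.15, 0.25), s2_sd = runif(1, 0.05, 0.10),
    systole_frac = runif(1, 0.45, 0.60), diastole_frac = runif(1, 0.55, 0.75),
    rel_sd = 0.3, floor_s = 0.1, trunc_sd = 2
  )
  sd_list <- radarheart:::state_durations(dm, cycle)
  pmfs <- lapply(c("S1", "systole", "S2", "diastole"), function(s) {
    radarheart:::duration_log_pmf(sd_list[[s]][1], sd_list[[s]][2], fr,
                                  trunc_sd = dm$trunc_sd, t_max = Tn)
  })
  list(post = post, dm = dm, cycle = cycle, pmfs = pmfs, fr = fr)
}
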