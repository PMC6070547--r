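#' Synchronise two sensors by their tapping pattern
#'
#' At the start of a recording the investigator taps on the subject's
#' shoulder; the taps are visible to both the radar and the (asynchronously
#' acquired) PCG, so cross-correlating the initial windows recovers the
#' inter-sensor lag. A confidence guard flags windows without a clear
#' correlation peak (no tapping pattern present).
#'
#' @param radar_hs Radar heart-sound-band series (reference timeline).
#' @param pcg PCG series to be aligned.
#' @param fs Sampling rate, Hz.
#' @param window Length of the initial window to correlate, seconds
#'   (default 10).
#' @param min_peak_ratio Minimum robust z-score (peak against the
#'   median/MAD of the absolute correlation) for a confident estimate
#'   (default 8); windows without a tapping pattern fall well below it.
#' @return A list with `lag_s` (positive: PCG trails the radar), `lag`
#'   (samples) and `confident` (logical).
#' @export
sync_by_tapping <- function(radar_hs, pcg, fs, window = 10,
                            min_peak_ratio = 8) {
  assert_scalar_pos(fs, "fs")
  n <- min(length(radar_hs), length(pcg), as.integer(round(window * fs)))
  # envelopes make the tap pattern comparable across sensing domains
  e1 <- hilbert_envelope(radar_hs[seq_len(n)], fs, smooth_s = 0.01)
  e2 <- hilbert_envelope(pcg[seq_len(n)], fs, smooth_s = 0.01)
  e1 <- e1 - mean(e1); e2 <- e2 - mean(e2)
  cc <- full_xcorr(e1, e2)
  # only consider lags with at least a quarter-window overlap
  m_all <- seq_len(length(cc)) - n
  keep <- abs(m_all) <= 3 * n / 4
  ccs <- cc[keep]
  pk <- which.max(abs(ccs))
  lag <- m_all[keep][pk]
  z <- (abs(ccs[pk]) - median(abs(ccs))) /
    (stats::mad(abs(ccs)) + .Machine$double.eps)
  list(lag_s = lag / fs, lag = as.integer(lag),
       confident = is.finite(z) && z >= min_peak_ratio)
}

#' Interbeat-interval series at 1 Hz
#'
#' At each whole second, the IBI value is the median of the five most
#' recent inter-event intervals ending at or before that second; values are
#' undefined (NA) until six events (five intervals) have occurred.
#'
#' @param events Strictly increasing beat-event times in seconds (ECG
#'   R-peaks for the reference; S1 segment start times for heart-sound
#'   based detection).
#' @param duration_s Recording length in seconds.
#' @return Tibble with `time` (1, 2, ... s) and `ibi` (s, NA during
#'   warm-up).
#' @export
ibi_series <- function(events, duration_s) {
  events <- as.numeric(events)
  if (is.unsorted(events, strictly = TRUE)) {
    abort("`events` must be strictly increasing.",
          class = "radarheart_invalid_input")
  }
  ts <- seq_len(floor(duration_s))
  ivals <- diff(events)
  iend <- events[-1]  # interval k ends at events[k+1]
  ibi <- vapply(ts, function(tt) {
    k <- which(iend <= tt)
    if (length(k) < 5L) return(NA_real_)
    median(ivals[tail(k, 5L)])
  }, numeric(1))
  tibble::tibble(time = as.numeric(ts), ibi = ibi)
}

#' RMSE between two IBI series
#'
#' Root-mean-square error of a measured IBI series against a reference
#' (typically ECG-derived), over the timestamps where both are defined:
#' `sqrt(mean((I_ecg - I)^2))`.
#'
#' @param ibi,ref Tibbles from [ibi_series()] (columns `time`, `ibi`).
#' @return RMSE in seconds.
#' @export
ibi_rmse <- function(ibi, ref) {
  j <- dplyr::inner_join(ibi, ref, by = "time", suffix = c("", "_ref"))
  j <- j[is.finite(j$ibi) & is.finite(j$ibi_ref), ]
  if (!nrow(j)) {
    abort("no common defined timestamps.",
          class = "radarheart_insufficient_data")
  }
  sqrt(mean((j$ibi_ref - j$ibi)^2))
}

#' Match detected beat events to a reference
#'
#' Greedy one-to-one nearest matching within a tolerance window: detected
#' events are considered in order of their distance to the closest unused
#' reference event; each reference matches at most once.
#'
#' @param detected,reference Event-time vectors, seconds.
#' @param tol_s Matching tolerance, seconds (default 0.1).
#' @return A list with counts `tp`, `fp`, `fn` and the matched index pairs.
#' @export
match_events <- function(detected, reference, tol_s = 0.1) {
  nd <- length(detected); nr <- length(reference)
  if (nd == 0L) {
    return(list(tp = 0L, fp = 0L, fn = nr,
                pairs = tibble::tibble(detected = integer(), reference = integer())))
  }
  if (nr == 0L) {
    return(list(tp = 0L, fp = nd, fn = 0L,
                pairs = tibble::tibble(detected = integer(), reference = integer())))
  }
  d <- abs(outer(detected, reference, "-"))
  d[d > tol_s] <- NA_real_
  used_d <- logical(nd); used_r <- logical(nr)
  pairs <- list()
  repeat {
    d[used_d, ] <- NA_real_
    d[, used_r] <- NA_real_
    if (all(is.na(d))) break
    ij <- arrayInd(which.min(d), dim(d))
    used_d[ij[1]] <- TRUE; used_r[ij[2]] <- TRUE
    pairs[[length(pairs) + 1L]] <- c(ij[1], ij[2])
  }
  tp <- length(pairs)
  pairs <- if (tp) {
    m <- do.call(rbind, pairs)
    tibble::tibble(detected = m[, 1], reference = m[, 2])
  } else {
    tibble::tibble(detected = integer(), reference = integer())
  }
  list(tp = tp, fp = nd - tp, fn = nr - tp, pairs = pairs)
}

#' Precision, recall and F1 score
#'
#' `p = TP/(TP+FP)`, `r = TP/(TP+FN)`, `F1 = 2*p*r/(p+r)`; all guarded to 0
#' when the denominator vanishes.
#'
#' @param tp,fp,fn Counts, or a list with those elements (as returned by
#'   [match_events()]).
#' @return Tibble with `precision`, `recall`, `f1`.
#' @export
f_score <- function(tp, fp = NULL, fn = NULL) {
  if (is.list(tp)) { fp <- tp$fp; fn <- tp$fn; tp <- tp$tp }
  p <- if (tp + fp > 0) tp / (tp + fp) else 0
  r <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (p + r > 0) 2 * p * r / (p + r) else 0
  tibble::tibble(precision = p, recall = r, f1 = f1)
}

#' Beat events from a segmentation
#'
#' Heart-sound based beat instants: the start times of the decoded S1 (or
#' S2) segments.
#'
#' @param seg An `rh_segmentation`.
#' @param sound `"S1"` (default) or `"S2"`.
#' @return Numeric vector of event times in seconds.
#' @export
beat_events <- function(seg, sound = "S1") {
  sort(seg$start[seg$state == sound])
}

#' Enumerate train/test subject splits
#'
#' All combinations of `n_train` training subjects out of `n_subjects`
#' (the remaining subjects form the test set). With 11 subjects and 6
#' training subjects this enumerates all `choose(11, 6) = 462` splits.
#'
#' @param n_subjects Total number of subjects.
#' @param n_train Number of training subjects per split.
#' @return List of lists with integer vectors `train` and `test`.
#' @export
subject_splits <- function(n_subjects, n_train) {
  cmb <- combn(n_subjects, n_train)
  lapply(seq_len(ncol(cmb)), function(k) {
    tr <- cmb[, k]
    list(train = tr, test = setdiff(seq_len(n_subjects), tr))
  })
}

#' Cross-validated F-scores over synthetic subjects
#'
#' For each train/test split, trains emission models on the training
#' subjects' pooled features and ground-truth labels, segments each test
#' subject's heart-sound signal, and scores detected S1/S2 onsets against
#' the true onsets within a matching tolerance. Results are aggregated as
#' mean and standard deviation over splits.
#'
#' @param subjects List of per-subject lists, each with elements `hs`
#'   (band-limited heart-sound series), `fs`, and `truth` (ground-truth
#'   list with `segments`).
#' @param n_train Training subjects per split.
#' @param variant A [variant_config()].
#' @param durations A [duration_model()].
#' @param tol_s Event-matching tolerance, seconds (default 0.1).
#' @param max_splits Cap on the number of evaluated splits (deterministic
#'   evenly spaced subsample of the full enumeration); `Inf` evaluates all.
#' @return A list with `splits` (number enumerated), `results` (tibble per
#'   evaluated split: `split`, `f1_s1`, `f1_s2`, `f1_avg`) and `summary`
#'   (tibble with mean and sd per score).
#' @export
cross_validate <- function(subjects, n_train, variant = variant_config("B"),
                           durations = duration_model(), tol_s = 0.1,
                           max_splits = Inf) {
  splits <- subject_splits(length(subjects), n_train)
  eval_idx <- if (is.finite(max_splits) && max_splits < length(splits)) {
    unique(round(seq(1, length(splits), length.out = max_splits)))
  } else {
    seq_along(splits)
  }
  results <- purrr::map_dfr(eval_idx, function(si) {
    sp <- splits[[si]]
    feats <- list(); labs <- list()
    for (i in sp$train) {
      su <- subjects[[i]]
      fe <- hs_features(su$hs, su$fs, variant)
      feats[[length(feats) + 1L]] <- fe
      labs[[length(labs) + 1L]] <- as.character(frame_labels(su$truth, fe$time))
    }
    em <- train_emissions(dplyr::bind_rows(feats), unlist(labs))
    scores <- purrr::map_dfr(sp$test, function(i) {
      su <- subjects[[i]]
      seg <- segment_heartsounds(su$hs, su$fs, em, variant, durations,
                                 prefilter = FALSE)
      truth_seg <- su$truth$segments
      s1 <- f_score(match_events(beat_events(seg, "S1"),
                                 truth_seg$start[truth_seg$state == "S1"], tol_s))
      s2 <- f_score(match_events(beat_events(seg, "S2"),
                                 truth_seg$start[truth_seg$state == "S2"], tol_s))
      tibble::tibble(f1_s1 = s1$f1, f1_s2 = s2$f1)
    })
    tibble::tibble(split = si, f1_s1 = mean(scores$f1_s1),
                   f1_s2 = mean(scores$f1_s2),
                   f1_avg = mean(c(scores$f1_s1, scores$f1_s2)))
  })
  summary <- tibble::tibble(
    score = c("f1_s1", "f1_s2", "f1_avg"),
    mean = vapply(results[c("f1_s1", "f1_s2", "f1_avg")], mean, numeric(1)),
    sd = vapply(results[c("f1_s1", "f1_s2", "f1_avg")], sd, numeric(1))
  )
  list(splits = length(splits), results = results, summary = summary)
}
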