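UNIT_VOCAB <- c("V", "m", "m/s2", "au", "s")

#' Write a multichannel recording to a portable container
#'
#' Plain-text container: one JSON metadata header line (prefixed `#`)
#' carrying the sampling rate, carrier frequency, per-channel unit tags and
#' any ground truth, followed by the channels in CSV. Round-trips
#' losslessly (full double precision).
#'
#' @param rec Recording tibble (e.g. from [generate_recording()]).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path) {
  fs <- infer_fs(rec)
  units <- attr(rec, "units")
  if (!is.null(units) && !all(units %in% UNIT_VOCAB)) {
    abort(sprintf("unknown unit tag(s): %s (allowed: %s)",
                  paste(setdiff(units, UNIT_VOCAB), collapse = ", "),
                  paste(UNIT_VOCAB, collapse = ", ")),
          class = "radarheart_invalid_units")
  }
  truth <- attr(rec, "truth")
  meta <- list(fs = fs,
               carrier_freq = attr(rec, "carrier_freq"),
               units = as.list(units %||% list()),
               scenario = attr(rec, "scenario"))
  if (!is.null(truth)) {
    meta$truth <- list(r_peaks = truth$r_peaks, t_ends = truth$t_ends,
                       segments = truth$segments, cycle_s = truth$cycle_s)
  }
  hdr <- paste0("# ", jsonlite::toJSON(meta, auto_unbox = TRUE, digits = NA,
                                       null = "null"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  df <- as.data.frame(rec)
  writeLines(paste(names(df), collapse = ","), con)
  body <- do.call(paste, c(lapply(df, format_full), list(sep = ",")))
  writeLines(body, con)
  invisible(path)
}

format_full <- function(x) {
  if (is.numeric(x)) sprintf("%.17g", x) else as.character(x)
}

#' Read a recording written by [write_recording()]
#'
#' @param path File path.
#' @param require_channels Channel names that must be present; a named
#'   missing-channel error is raised otherwise.
#' @return Recording tibble with `fs`, `carrier_freq`, `units` and `truth`
#'   attributes restored.
#' @export
read_recording <- function(path, require_channels = NULL) {
  hdr <- readLines(path, n = 1L)
  if (!startsWith(hdr, "# ")) {
    abort("not a recording container: missing metadata header line.",
          class = "radarheart_invalid_input")
  }
  meta <- jsonlite::fromJSON(substring(hdr, 3L))
  rec <- tibble::as_tibble(utils::read.csv(path, skip = 1L))
  units <- unlist(meta$units)
  if (length(units) && !all(units %in% UNIT_VOCAB)) {
    abort(sprintf("unknown unit tag(s) in container: %s",
                  paste(setdiff(units, UNIT_VOCAB), collapse = ", ")),
          class = "radarheart_invalid_units")
  }
  if (!is.null(require_channels)) {
    miss <- setdiff(require_channels, names(rec))
    if (length(miss)) {
      abort(paste0("missing channel(s): ", paste(miss, collapse = ", ")),
            class = "radarheart_missing_channel")
    }
  }
  attr(rec, "fs") <- meta$fs
  attr(rec, "carrier_freq") <- meta$carrier_freq
  attr(rec, "units") <- units
  attr(rec, "scenario") <- meta$scenario
  if (!is.null(meta$truth)) {
    tr <- meta$truth
    tr$segments <- tibble::as_tibble(tr$segments)
    attr(rec, "truth") <- tr
  }
  class(rec) <- c("rh_recording", class(rec))
  rec
}

#' Run the full monitoring pipeline on a recording
#'
#' Executes the complete processing chain: tapping-based PCG
#' synchronisation and lead-in trimming (when a tapping pattern is
#' present), Six-Port demodulation to displacement, heart-sound band
#' extraction, HSMM segmentation, and — when ground truth or a PCG channel
#' is available — beat-timing metrics (F1, IBI RMSE) and per-beat
#' radar/PCG morphology. Fully deterministic given its inputs.
#'
#' @param rec Recording tibble containing at least `b3..b6`.
#' @param emissions Trained `rh_emissions` model.
#' @param variant A [variant_config()].
#' @param durations A [duration_model()].
#' @param tol_s Event-matching tolerance for the F-score, s (default 0.1).
#' @param sync_window Tapping correlation window, s (default 10).
#' @return An `rh_report` list: `segmentation`, `events`, `metrics`
#'   (tibble or `NULL` when no reference is available), `morphology`
#'   (per-beat tibble or `NULL`), `provenance` (variant, tolerance, config
#'   hash, package version, sync lag).
#' @export
run_pipeline <- function(rec, emissions, variant = variant_config("B"),
                         durations = duration_model(), tol_s = 0.1,
                         sync_window = 10) {
  fs <- infer_fs(rec)
  need <- c("b3", "b4", "b5", "b6")
  miss <- setdiff(need, names(rec))
  if (length(miss)) {
    abort(paste0("missing channel(s): ", paste(miss, collapse = ", ")),
          class = "radarheart_missing_channel")
  }
  truth <- attr(rec, "truth")
  cfg <- attr(rec, "config")

  disp <- demodulate(rec, fs = fs)
  hs <- extract_component(disp$displacement, variant$band, fs)

  sync <- NULL
  t_offset <- 0
  if (!is.null(cfg) && isTRUE(cfg$tapping) && "pcg" %in% names(rec)) {
    sync <- sync_by_tapping(hs, rec$pcg, fs, window = sync_window)
    if (sync$confident && sync$lag != 0L) {
      # shift PCG back into the radar timeline
      k <- sync$lag
      pcg <- rec$pcg
      if (k > 0) {
        rec$pcg <- c(pcg[(k + 1):length(pcg)], rep(0, k))
      } else {
        rec$pcg <- c(rep(0, -k), pcg[seq_len(length(pcg) + k)])
      }
    }
    # drop the tapping lead-in from analysis
    t_offset <- cfg$lead_in
    keep <- disp$time >= t_offset
    disp <- disp[keep, ]
    hs <- hs[keep]
    rec <- rec[rec$time >= t_offset, ]
  }

  seg <- segment_heartsounds(hs, fs, emissions, variant, durations,
                             prefilter = FALSE)
  if (nrow(seg)) {
    seg$start <- seg$start + t_offset
    seg$end <- seg$end + t_offset
  }
  events <- beat_events(seg, "S1")
  duration_s <- max(rec$time)

  metrics <- NULL
  if (!is.null(truth)) {
    tseg <- truth$segments
    tseg <- tseg[tseg$start >= t_offset, ]
    s1m <- f_score(match_events(events, tseg$start[tseg$state == "S1"], tol_s))
    s2m <- f_score(match_events(beat_events(seg, "S2"),
                                tseg$start[tseg$state == "S2"], tol_s))
    rp <- truth$r_peaks[truth$r_peaks >= t_offset]
    rmse <- tryCatch(
      ibi_rmse(ibi_series(events, duration_s), ibi_series(rp, duration_s)),
      error = function(e) NA_real_)
    metrics <- tibble::tibble(
      sound = c("S1", "S2"),
      precision = c(s1m$precision, s2m$precision),
      recall = c(s1m$recall, s2m$recall),
      f1 = c(s1m$f1, s2m$f1),
      ibi_rmse_s = c(rmse, NA_real_)
    )
  }

  morphology <- NULL
  if ("pcg" %in% names(rec)) {
    pcg_hs <- extract_component(rec$pcg, variant$band, fs)
    s1seg <- seg[seg$state == "S1", ]
    morphology <- purrr::map_dfr(seq_len(nrow(s1seg)), function(k) {
      r <- slice_samples(hs, fs, s1seg$start[k] - t_offset,
                         s1seg$end[k] - t_offset)
      p <- slice_samples(pcg_hs, fs, s1seg$start[k] - t_offset,
                         s1seg$end[k] - t_offset)
      if (length(r) < 8L || length(p) < 8L) return(NULL)
      cm <- compare_morphology(r, p, fs)
      tibble::tibble(beat = k, time = s1seg$start[k], lag_ms = cm$lag_ms,
                     similarity = cm$similarity)
    })
  }

  structure(list(
    segmentation = seg,
    events = events,
    metrics = metrics,
    morphology = morphology,
    provenance = list(
      variant = variant$variant,
      tol_s = tol_s,
      sync = sync,
      config_hash = rlang::hash(cfg),
      package_version = as.character(utils::packageVersion("radarheart"))
    )
  ), class = "rh_report")
}

#' @export
print.rh_report <- function(x, ...) {
  cat(sprintf("<rh_report> variant %s: %d S1 / %d S2 segments\n",
              x$provenance$variant,
              sum(x$segmentation$state == "S1"),
              sum(x$segmentation$state == "S2")))
  if (!is.null(x$metrics)) {
    cat(sprintf("  S1 F1 = %.3f, S2 F1 = %.3f, IBI RMSE = %.1f ms\n",
                x$metrics$f1[1], x$metrics$f1[2],
                1000 * x$metrics$ibi_rmse_s[1]))
  }
  if (!is.null(x$morphology) && nrow(x$morphology)) {
    cat(sprintf("  morphology: mean similarity %.3f over %d beats\n",
                mean(x$morphology$similarity, na.rm = TRUE),
                nrow(x$morphology)))
  }
  invisible(x)
}

#' Serialise a pipeline report to JSON
#'
#' @param report An `rh_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  out <- list(
    segmentation = as.data.frame(report$segmentation),
    events = report$events,
    metrics = if (is.null(report$metrics)) NULL else as.data.frame(report$metrics),
    morphology = if (is.null(report$morphology)) NULL else as.data.frame(report$morphology),
    provenance = report$provenance[c("variant", "tol_s", "config_hash",
                                     "package_version")]
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Save or load a trained emission model
#'
#' Serialises the one-vs-rest logistic-regression weights, feature names
#' and class priors to JSON so a model trained once can drive the CLI or a
#' later session.
#'
#' @param emissions An `rh_emissions` model.
#' @param path JSON file path.
#' @return `path` (write) or the restored `rh_emissions` (read).
#' @export
write_emissions <- function(emissions, path) {
  stopifnot(inherits(emissions, "rh_emissions"))
  out <- list(coefficients = emissions$coefficients,
              features = emissions$features,
              class_priors = emissions$class_priors,
              train_accuracy = emissions$train_accuracy,
              n_frames = emissions$n_frames)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_emissions
#' @export
read_emissions <- function(path) {
  raw <- jsonlite::fromJSON(path)
  co <- as.matrix(raw$coefficients)
  colnames(co) <- HS_STATES
  rownames(co) <- c("(Intercept)", raw$features)
  structure(list(coefficients = co, features = raw$features,
                 class_priors = setNames(unlist(raw$class_priors), HS_STATES),
                 train_accuracy = raw$train_accuracy,
                 n_frames = raw$n_frames),
            class = "rh_emissions")
}
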