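#' Preprocessing configuration
#'
#' @param max_missing_fraction Maximum tolerated fraction of missing frames
#'   in a recording before it is excluded, in `[0, 1]` (default 0.3;
#'   exclusion is strict: a recording is dropped only when its missingness
#'   exceeds the threshold).
#' @param target_rate Uniform resampling rate in Hz (default 5, the nominal
#'   mean capture rate of webcam landmark recordings).
#' @param interpolation Interpolation method; only `"linear"` is supported.
#' @param trim_policy `"common-overlap"` (trim all recordings of a group to
#'   the intersection of their spans) or `"fixed-duration"` (truncate every
#'   recording to `fixed_duration_seconds` from its own start).
#' @param fixed_duration_seconds Duration for the fixed-duration policy.
#' @param iod_cm Physical inter-ocular distance used to convert pixels to
#'   centimetres (default 6.3 cm, the adult average).
#' @param head_movement_stat Per-second statistic of nose-tip displacement:
#'   `"sum"` (default; path length per second, "nose energy") or `"mean"`
#'   (mean per-frame displacement).
#' @return An object of class `preproc_config`.
#' @export
preproc_config <- function(max_missing_fraction = 0.3, target_rate = 5,
                           interpolation = "linear",
                           trim_policy = c("common-overlap",
                                           "fixed-duration"),
                           fixed_duration_seconds = NULL,
                           iod_cm = 6.3,
                           head_movement_stat = c("sum", "mean")) {
  trim_policy <- match.arg(trim_policy)
  interpolation <- match.arg(interpolation, "linear")
  stopifnot(max_missing_fraction >= 0, max_missing_fraction <= 1,
            target_rate > 0, iod_cm > 0)
  if (trim_policy == "fixed-duration" &&
      (is.null(fixed_duration_seconds) || fixed_duration_seconds <= 0)) {
    abort("fixed-duration trimming needs a positive `fixed_duration_seconds`")
  }
  structure(
    list(max_missing_fraction = max_missing_fraction,
         target_rate = target_rate, interpolation = interpolation,
         trim_policy = trim_policy,
         fixed_duration_seconds = fixed_duration_seconds,
         iod_cm = iod_cm,
         head_movement_stat = match.arg(head_movement_stat)),
    class = "preproc_config"
  )
}

#' Fraction of missing frames in a raw recording
#'
#' `1 - (frames with valid landmarks) / (duration * expected_rate)`, clamped
#' to `[0, 1]`, where duration is the span between the first and last
#' timestamp. Frames whose landmark cell failed to parse count as missing.
#'
#' @param raw A `raw_recording`.
#' @param expected_rate Expected capture rate in Hz.
#' @return A number in `[0, 1]`.
#' @export
missingness_fraction <- function(raw, expected_rate) {
  stopifnot(inherits(raw, "raw_recording"), expected_rate > 0)
  times <- raw$frames$time
  if (length(unique(times)) < 2) {
    abort("recording has a single timestamp: duration undefined")
  }
  duration <- max(times) - min(times)
  valid <- sum(raw$frames$valid)
  min(max(1 - valid / (duration * expected_rate), 0), 1)
}

#' Filter raw recordings by missingness
#'
#' @param raws List of `raw_recording` objects.
#' @param config A [preproc_config()].
#' @param expected_rate Expected capture rate; defaults to
#'   `config$target_rate`.
#' @return A list with `kept` (list of recordings) and `excluded` (tibble
#'   with `participant`, `group`, `fraction`). A recording is excluded iff
#'   its missingness fraction strictly exceeds `max_missing_fraction`.
#' @export
filter_by_missingness <- function(raws, config,
                                  expected_rate = config$target_rate) {
  fr <- vapply(raws, missingness_fraction, numeric(1),
               expected_rate = expected_rate)
  drop <- fr > config$max_missing_fraction
  excluded <- tibble(
    participant = vapply(raws[drop], function(r) r$participant_id,
                         character(1)),
    group = vapply(raws[drop], function(r) group_label(r$group_values),
                   character(1)),
    fraction = fr[drop]
  )
  if (nrow(excluded) > 0) {
    inform(sprintf("excluded %d recording(s) above missingness %.2f",
                   nrow(excluded), config$max_missing_fraction))
  }
  list(kept = raws[!drop], excluded = excluded)
}

# Phase-aligned uniform grid inside [t0, t1]: sample times k / rate.
phase_grid <- function(t0, t1, rate) {
  k0 <- ceiling(t0 * rate - 1e-9)
  k1 <- floor(t1 * rate + 1e-9)
  if (k1 < k0) abort("empty resampling span")
  (k0:k1) / rate
}

#' Resample a raw recording onto a uniform grid
#'
#' Linearly interpolates each of the 136 landmark coordinate channels (and
#' each emotion channel) onto the phase-aligned uniform grid of
#' `target_rate` spanning the valid portion of the recording. No
#' extrapolation is performed: leading/trailing invalid frames shorten the
#' usable span; interior gaps are bridged linearly.
#'
#' @param raw A `raw_recording` with at least 2 valid frames.
#' @param config A [preproc_config()].
#' @return An object of class `recording`: `time` (uniform grid, s),
#'   `landmarks` (T x 68 x 2 array), `emotions` (T x 7 matrix or `NULL`),
#'   `head_movement` (`NULL` until computed), `participant_id`,
#'   `group_values`, `rate`, `settings`.
#' @export
resample_to_grid <- function(raw, config) {
  stopifnot(inherits(raw, "raw_recording"))
  ok <- raw$frames$valid
  if (sum(ok) < 2) abort("fewer than 2 valid frames: cannot resample")
  tv <- raw$frames$time[ok]
  coords <- raw$frames$landmarks[ok]
  grid <- phase_grid(min(tv), max(tv), config$target_rate)
  v <- length(tv)
  flat <- matrix(NA_real_, nrow = v, ncol = 136)
  for (i in seq_len(v)) {
    flat[i, ] <- as.vector(t(coords[[i]]))   # x1 y1 x2 y2 ... per row
  }
  res <- apply(flat, 2, function(ch) {
    stats::approx(tv, ch, xout = grid, method = "linear", ties = mean)$y
  })
  res <- matrix(res, nrow = length(grid))
  lm_arr <- array(NA_real_, dim = c(length(grid), 68, 2))
  lm_arr[, , 1] <- res[, seq(1, 135, by = 2)]
  lm_arr[, , 2] <- res[, seq(2, 136, by = 2)]
  emotions <- NULL
  emo_cols <- intersect(emotion_names(), names(raw$frames))
  if (length(emo_cols) > 0) {
    emotions <- sapply(emo_cols, function(nm) {
      yv <- raw$frames[[nm]]
      use <- !is.na(yv)
      if (sum(use) < 2) return(rep(NA_real_, length(grid)))
      stats::approx(raw$frames$time[use], yv[use], xout = grid,
                    method = "linear", ties = mean, rule = 2)$y
    })
    emotions <- matrix(emotions, nrow = length(grid),
                       dimnames = list(NULL, emo_cols))
  }
  structure(
    list(time = grid, landmarks = lm_arr, emotions = emotions,
         head_movement = NULL, participant_id = raw$participant_id,
         group_values = raw$group_values, rate = config$target_rate,
         settings = unclass(config)),
    class = "recording"
  )
}

#' Align resampled recordings into a set with a shared grid
#'
#' Under `"common-overlap"` every recording is trimmed to
#' `[max of start times, min of end times]` on the shared phase-aligned
#' grid; under `"fixed-duration"` every recording is truncated to the stated
#' duration from its own start (and re-indexed to start at 0 s). Head
#' movement is computed for every recording after trimming. All resulting
#' recordings have identical sample counts, which is asserted.
#'
#' @param recordings List of [resample_to_grid()] outputs at a common rate.
#' @param config A [preproc_config()].
#' @return An object of class `recording_set`: `recordings`, `time`, `rate`,
#'   `settings`.
#' @export
align_group <- function(recordings, config) {
  if (length(recordings) < 2) {
    abort("at least 2 recordings are required for synchrony analyses")
  }
  rates <- vapply(recordings, function(r) r$rate, numeric(1))
  if (length(unique(rates)) != 1) abort("recordings differ in rate")
  rate <- rates[1]
  if (config$trim_policy == "common-overlap") {
    t0 <- max(vapply(recordings, function(r) min(r$time), numeric(1)))
    t1 <- min(vapply(recordings, function(r) max(r$time), numeric(1)))
    if (t1 <= t0) {
      spans <- vapply(recordings, function(r) {
        sprintf("%s: [%.2f, %.2f]", r$participant_id, min(r$time),
                max(r$time))
      }, character(1))
      abort(paste0("recordings share no temporal overlap: ",
                   paste(spans, collapse = "; ")))
    }
    out <- lapply(recordings, function(r) {
      keep <- r$time >= t0 - 1e-9 & r$time <= t1 + 1e-9
      trim_recording(r, keep, r$time[keep])
    })
  } else {
    n_keep <- round(config$fixed_duration_seconds * rate) + 1
    out <- lapply(recordings, function(r) {
      if (length(r$time) < n_keep) {
        abort(sprintf("recording %s shorter than the fixed duration",
                      r$participant_id))
      }
      keep <- seq_len(n_keep)
      trim_recording(r, keep, (keep - 1) / rate)
    })
  }
  lens <- vapply(out, function(r) length(r$time), integer(1))
  stopifnot(length(unique(lens)) == 1)
  out <- lapply(out, function(r) {
    r$head_movement <- head_movement_series(r, config)
    r
  })
  structure(list(recordings = out, time = out[[1]]$time, rate = rate,
                 settings = unclass(config)),
            class = "recording_set")
}

trim_recording <- function(r, keep, new_time) {
  r$landmarks <- r$landmarks[keep, , , drop = FALSE]
  if (!is.null(r$emotions)) r$emotions <- r$emotions[keep, , drop = FALSE]
  r$time <- new_time
  r$head_movement <- NULL
  r
}

eye_centroid_distance <- function(landmarks_t) {
  right <- colMeans(landmarks_t[landmark_index(37:42), , drop = FALSE])
  left <- colMeans(landmarks_t[landmark_index(43:48), , drop = FALSE])
  sqrt(sum((right - left)^2))
}

#' Per-second head movement from nose-tip displacement
#'
#' For each 1-s bin, sums (or averages, per configuration) the
#' frame-to-frame Euclidean displacements of the nose tip (landmark 34),
#' converted from pixels to centimetres by `iod_cm / IOD_pixels`, where
#' `IOD_pixels` is the per-recording median distance between the right-eye
#' (37-42) and left-eye (43-48) landmark centroids. The displacement
#' between frames i and i+1 is credited to the bin containing frame i, so
#' every bin holds `rate` displacements except the last. The measure is
#' invariant to global translation and to uniform spatial scaling of the
#' face.
#'
#' @param recording A resampled `recording` of at least one full second.
#' @param config A [preproc_config()] (supplies `iod_cm` and the per-bin
#'   statistic).
#' @return A tibble with `second` (bin start, seconds from recording start)
#'   and `head_movement` (cm/s, non-negative).
#' @export
head_movement_series <- function(recording, config = preproc_config()) {
  stopifnot(inherits(recording, "recording"))
  f <- recording$rate
  t_n <- length(recording$time)
  if (t_n - 1 < f) abort("recording shorter than one full second")
  iod_px <- median(vapply(seq_len(t_n), function(i) {
    eye_centroid_distance(recording$landmarks[i, , ])
  }, numeric(1)))
  if (!is.finite(iod_px) || iod_px <= 0) {
    abort("degenerate inter-ocular distance: cannot scale to centimetres")
  }
  nose <- recording$landmarks[, nose_tip_landmark(), ]
  disp <- sqrt(rowSums((nose[-1, , drop = FALSE] -
                          nose[-t_n, , drop = FALSE])^2))
  bin <- (seq_len(t_n - 1) - 1) %/% f      # bin of the earlier frame
  stat <- if (config$head_movement_stat == "mean") mean else sum
  vals <- tapply(disp, bin, stat) * (config$iod_cm / iod_px)
  tibble(second = as.numeric(names(vals)), head_movement = as.numeric(vals))
}

#' Summarise head movement at several aggregation levels
#'
#' @param set A `recording_set` whose recordings carry head movement.
#' @param level `"participant"` (mean and SE of per-second values per
#'   recording), `"condition"` (mean of participant means per group label,
#'   SE across participants), `"per-second"` (mean and SE across
#'   participants at each second), or `"whole-recording"` (one row per
#'   recording; the value is the mean of its per-second values).
#' @return A tibble of means and standard errors at the requested level.
#' @export
movement_summary <- function(set, level = c("participant", "condition",
                                            "per-second",
                                            "whole-recording")) {
  stopifnot(inherits(set, "recording_set"))
  level <- match.arg(level)
  long <- purrr::map_dfr(set$recordings, function(r) {
    dplyr::mutate(r$head_movement,
                  participant = r$participant_id,
                  group = group_label(r$group_values))
  })
  se <- function(v) if (length(v) > 1) sd(v) / sqrt(length(v)) else 0
  if (level %in% c("participant", "whole-recording")) {
    return(dplyr::summarise(
      dplyr::group_by(long, .data$participant, .data$group),
      mean = mean(.data$head_movement), se = se(.data$head_movement),
      .groups = "drop"))
  }
  if (level == "condition") {
    per_part <- dplyr::summarise(
      dplyr::group_by(long, .data$participant, .data$group),
      m = mean(.data$head_movement), .groups = "drop")
    return(dplyr::summarise(dplyr::group_by(per_part, .data$group),
                            mean = mean(.data$m), se = se(.data$m),
                            n = dplyr::n(), .groups = "drop"))
  }
  dplyr::summarise(dplyr::group_by(long, .data$second),
                   mean = mean(.data$head_movement),
                   se = se(.data$head_movement), .groups = "drop")
}
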