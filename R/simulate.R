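# Seeded generators for the two built-in validation studies and for raw
# Trace-dialect CSV fixtures.

with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  force(code)
}

#' Specification of the injected head-movement synchrony study
#'
#' Study conditions for the single-channel validation simulation: `n_subjects`
#' independent unit-SD white-noise "head movement" signals sampled at `rate`
#' Hz for `duration` seconds, with a shared sinusoidal template mixed in at
#' weight `alpha` during a synchrony event around `sync_window`.
#'
#' The 0.5 Hz template sampled at 1 Hz sits exactly at the Nyquist frequency,
#' where a zero-phase sine samples to all zeros; the default
#' `template_phase = pi/2` therefore yields the non-degenerate alternating
#' +1/-1 sequence. With `align_events_to_segments = TRUE` (default) the event
#' occupies the whole analysis segments of `segment_seconds` whose closed
#' time span intersects the closed `sync_window`, so the event spans complete
#' segments of the downstream segmented analysis.
#'
#' @param n_subjects Number of simulated participants (default 30).
#' @param duration Recording length in seconds (default 120).
#' @param rate Sampling rate in Hz (default 1).
#' @param sync_window Two-element numeric, start/end of the synchrony event
#'   in seconds (default `c(70, 80)`).
#' @param alpha Mixing weight of the shared template inside the event
#'   (default 0.7); the signal there is
#'   `alpha * template + (1 - alpha) * noise`.
#' @param template_freq Template frequency in Hz (default 0.5).
#' @param template_phase Template phase in radians (default `pi/2`).
#' @param noise_sd SD of the white Gaussian noise (default 1).
#' @param segment_seconds Segment length used to align the event (default 5).
#' @param align_events_to_segments Expand the event to whole segments
#'   intersecting `sync_window` (default `TRUE`).
#' @return An object of class `susy_sim_spec` (a list of the above fields).
#' @export
susy_sim_spec <- function(n_subjects = 30, duration = 120, rate = 1,
                          sync_window = c(70, 80), alpha = 0.7,
                          template_freq = 0.5, template_phase = pi / 2,
                          noise_sd = 1, segment_seconds = 5,
                          align_events_to_segments = TRUE) {
  stopifnot(alpha >= 0, alpha <= 1, rate > 0, duration > 0,
            length(sync_window) == 2)
  if (sync_window[1] < 0 || sync_window[2] > duration ||
      sync_window[1] > sync_window[2]) {
    abort("`sync_window` must be an increasing interval within [0, duration].")
  }
  structure(
    list(n_subjects = n_subjects, duration = duration, rate = rate,
         sync_window = sync_window, alpha = alpha,
         template_freq = template_freq, template_phase = template_phase,
         noise_sd = noise_sd, segment_seconds = segment_seconds,
         align_events_to_segments = align_events_to_segments),
    class = "susy_sim_spec"
  )
}

#' Simulate the injected head-movement synchrony study
#'
#' Generates one single-channel signal per subject: white Gaussian noise
#' everywhere, with a shared sinusoidal template convexly mixed in
#' (`alpha * template + (1 - alpha) * noise`) during the synchrony event.
#' Bit-identical output under a fixed seed.
#'
#' @param spec A [susy_sim_spec()].
#' @param seed Integer seed controlling all randomness.
#' @return A list of class `susy_sim` with elements `signals` (subjects x
#'   samples matrix), `time` (sample times in seconds), `injected` (logical
#'   per sample, `TRUE` inside the event), `spec` and `seed`.
#' @examples
#' sim <- simulate_head_movement_study(susy_sim_spec(), seed = 1)
#' dim(sim$signals)
#' range(sim$time[sim$injected])
#' @export
simulate_head_movement_study <- function(spec = susy_sim_spec(), seed = NULL) {
  stopifnot(inherits(spec, "susy_sim_spec"))
  t_n <- round(spec$duration * spec$rate)
  times <- (seq_len(t_n) - 1) / spec$rate
  injected <- times >= spec$sync_window[1] & times <= spec$sync_window[2]
  if (spec$align_events_to_segments) {
    seg_len <- round(spec$segment_seconds * spec$rate)
    seg_id <- (seq_len(t_n) - 1) %/% seg_len
    touched <- unique(seg_id[injected])
    # drop the trailing partial segment: it never enters the analysis
    touched <- touched[touched < t_n %/% seg_len]
    injected <- seg_id %in% touched
  }
  template <- sin(2 * pi * spec$template_freq * times + spec$template_phase)
  signals <- with_seed(seed, {
    x <- matrix(rnorm(spec$n_subjects * t_n, sd = spec$noise_sd),
                nrow = spec$n_subjects)
    if (any(injected)) {
      mixed <- spec$alpha * matrix(template[injected],
                                   nrow = spec$n_subjects,
                                   ncol = sum(injected), byrow = TRUE) +
        (1 - spec$alpha) * x[, injected, drop = FALSE]
      x[, injected] <- mixed
    }
    x
  })
  rownames(signals) <- sprintf("S%02d", seq_len(spec$n_subjects))
  structure(list(signals = signals, time = times, injected = injected,
                 spec = spec, seed = seed),
            class = "susy_sim")
}

#' @export
as_tibble.susy_sim <- function(x, ...) {
  tibble(
    subject = rep(rownames(x$signals), each = length(x$time)),
    time = rep(x$time, times = nrow(x$signals)),
    value = as.vector(t(x$signals)),
    injected = rep(x$injected, times = nrow(x$signals))
  )
}

region_signals <- function() {
  list(
    mouth     = function(t) sin(t) + 0.5 * sin(2 * t),
    left_eye  = function(t) cos(2 * t) + 0.2 * cos(4 * t),
    right_eye = function(t) sin(1.5 * t) + 0.3 * sin(3 * t),
    jawline   = function(t) 0.5 + 0.5 * sin(0.8 * t),
    nose      = function(t) sin(3 * t) + 0.2 * sin(6 * t)
  )
}

#' Specification of the injected landmark-synchrony study
#'
#' Study conditions for the multivariate validation simulation: per-subject
#' faces built from the canonical template with Gaussian spatial offsets
#' (`offset_sd`, the between-subject variance) and white temporal noise
#' (`noise_sd`), with region-specific oscillatory signals injected for
#' participant subsets during stated windows. Each injected subject receives
#' an integer circular phase shift of up to `phase_jitter_frames` frames and
#' an amplitude factor drawn from `amp_range`.
#'
#' Region signals (t in seconds): mouth `sin(t) + 0.5 sin(2t)`, left eye
#' `cos(2t) + 0.2 cos(4t)`, right eye `sin(1.5t) + 0.3 sin(3t)`, jawline
#' `0.5 + 0.5 sin(0.8t)`, nose `sin(3t) + 0.2 sin(6t)`.
#'
#' @param n_subjects Number of participants (default 30).
#' @param duration Recording length in seconds (default 60).
#' @param rate Sampling rate in Hz (default 5).
#' @param offset_sd SD (px) of per-subject landmark position offsets
#'   (default 5).
#' @param noise_sd SD (px) of white temporal noise per coordinate sample
#'   (default 0.5, keeping the injected region signals - amplitudes of
#'   roughly 1-1.5 px - strongly synchronous relative to tracking noise).
#' @param events List of events, each a list with `region` (a name from
#'   [face_regions()] with a defined signal), `subjects` (integer ids) and
#'   `window` (closed interval, seconds). Defaults to mouth synchrony for
#'   subjects 1-15 at 20-22 s and left-eye synchrony for subjects 16-25 at
#'   30-32 s.
#' @param phase_jitter_frames Maximum absolute per-subject circular shift in
#'   frames (default 2).
#' @param amp_range Range of the per-subject amplitude factor (default
#'   `c(0.8, 1.2)`).
#' @param axes Coordinate axes the signal is added to (default both).
#' @return An object of class `corrca_sim_spec`.
#' @export
corrca_sim_spec <- function(n_subjects = 30, duration = 60, rate = 5,
                            offset_sd = 5, noise_sd = 0.5,
                            events = list(
                              list(region = "mouth", subjects = 1:15,
                                   window = c(20, 22)),
                              list(region = "left_eye", subjects = 16:25,
                                   window = c(30, 32))
                            ),
                            phase_jitter_frames = 2,
                            amp_range = c(0.8, 1.2),
                            axes = c("x", "y")) {
  stopifnot(rate > 0, duration > 0, offset_sd >= 0, noise_sd >= 0)
  axes <- match.arg(axes, c("x", "y"), several.ok = TRUE)
  regions <- vapply(events, function(e) e$region, character(1))
  if (anyDuplicated(regions)) {
    abort("event regions must be disjoint: each region may appear only once")
  }
  for (e in events) {
    if (!e$region %in% names(region_signals())) {
      abort(paste0("no region signal defined for region '", e$region, "'"))
    }
    if (e$window[1] < 0 || e$window[2] > duration) {
      abort("event windows must lie within the recording duration")
    }
    stopifnot(all(e$subjects >= 1), all(e$subjects <= n_subjects))
  }
  structure(
    list(n_subjects = n_subjects, duration = duration, rate = rate,
         offset_sd = offset_sd, noise_sd = noise_sd, events = events,
         phase_jitter_frames = phase_jitter_frames, amp_range = amp_range,
         axes = axes),
    class = "corrca_sim_spec"
  )
}

circular_shift <- function(x, k) {
  n <- length(x)
  if (n == 0) return(x)
  k <- ((k %% n) + n) %% n
  if (k == 0) x else c(x[(n - k + 1):n], x[seq_len(n - k)])
}

#' Simulate the injected landmark-synchrony study
#'
#' Builds a subjects x landmarks x coordinates x samples tensor from the
#' canonical face template plus per-subject spatial offsets and white
#' temporal noise, then adds region-localised oscillations for designated
#' participant subsets within stated time windows (with per-subject circular
#' phase jitter and amplitude scaling). Bit-identical under a fixed seed.
#'
#' @param spec A [corrca_sim_spec()].
#' @param seed Integer seed controlling all randomness.
#' @return A list of class `corrca_sim` with `coords` (N x 68 x 2 x T array),
#'   `time`, `events` (tibble: event, region, window start/end, subjects,
#'   sample indices), `spec`, `seed`.
#' @examples
#' sim <- simulate_landmark_study(corrca_sim_spec(), seed = 1)
#' dim(sim$coords)
#' @export
simulate_landmark_study <- function(spec = corrca_sim_spec(), seed = NULL) {
  stopifnot(inherits(spec, "corrca_sim_spec"))
  n <- spec$n_subjects
  t_n <- round(spec$duration * spec$rate)
  times <- (seq_len(t_n) - 1) / spec$rate
  tpl <- face_template()
  coords <- with_seed(seed, {
    arr <- array(rnorm(n * 68 * 2 * t_n, sd = spec$noise_sd),
                 dim = c(n, 68, 2, t_n))
    offs <- array(rnorm(n * 68 * 2, sd = spec$offset_sd), dim = c(n, 68, 2))
    base_x <- tpl$x
    base_y <- tpl$y
    for (s in seq_len(n)) {
      arr[s, , 1, ] <- arr[s, , 1, ] + base_x + offs[s, , 1]
      arr[s, , 2, ] <- arr[s, , 2, ] + base_y + offs[s, , 2]
    }
    axis_idx <- match(spec$axes, c("x", "y"))
    for (e in spec$events) {
      idx <- which(times >= e$window[1] & times <= e$window[2])
      if (length(idx) == 0) next
      lms <- face_regions()[[e$region]]
      sig <- region_signals()[[e$region]](times[idx])
      for (s in e$subjects) {
        shift <- sample(seq(-spec$phase_jitter_frames,
                            spec$phase_jitter_frames), 1)
        amp <- runif(1, spec$amp_range[1], spec$amp_range[2])
        s_sig <- amp * circular_shift(sig, shift)
        for (ax in axis_idx) {
          arr[s, lms, ax, idx] <- arr[s, lms, ax, idx] +
            matrix(s_sig, nrow = length(lms), ncol = length(idx), byrow = TRUE)
        }
      }
    }
    arr
  })
  dimnames(coords) <- list(sprintf("S%02d", seq_len(n)), NULL,
                           c("x", "y"), NULL)
  events <- purrr::map_dfr(seq_along(spec$events), function(i) {
    e <- spec$events[[i]]
    tibble(event = i, region = e$region,
           window_start = e$window[1], window_end = e$window[2],
           subjects = list(e$subjects),
           samples = list(which(times >= e$window[1] & times <= e$window[2])))
  })
  structure(list(coords = coords, time = times, events = events,
                 spec = spec, seed = seed),
            class = "corrca_sim")
}

#' Write simulated raw Trace-dialect CSV files
#'
#' Emulates the irregular webcam capture that the reader and preprocessing
#' modules must handle: jittered timestamps around a nominal rate, randomly
#' dropped frames, landmark cells encoded as JSON paired vectors,
#' seven emotion-score columns, and (optionally) a grouping column.
#' The underlying clean trajectories are smooth sinusoidal motions of the
#' canonical template; the returned object exposes them as a closure for
#' oracle comparison after preprocessing.
#'
#' @param out_dir Directory to write into (created if needed).
#' @param n_subjects Number of participants (default 4).
#' @param duration Nominal recording length in seconds (default 30).
#' @param mean_rate Nominal mean sampling rate in Hz (default 5).
#' @param drop_fraction Fraction of frames dropped at random, in `[0, 1)`
#'   (default 0.2).
#' @param jitter Uniform timestamp jitter half-width in seconds (default
#'   0.02).
#' @param conditions Optional character vector of condition labels; when
#'   given, every participant is written once per condition under a
#'   `condition` column.
#' @param bad_cell_fraction Fraction of retained rows whose landmark cell is
#'   written as truncated JSON (default 0), for degraded-input testing.
#' @param events Optional list of region synchrony events (as in
#'   [corrca_sim_spec()]): each adds its region signal (no jitter or
#'   amplitude variation) to the designated subjects' clean trajectories
#'   within its window, for end-to-end recovery testing.
#' @param timestamp_unit `"ms"` (default, Trace dialect) or `"s"`.
#' @param seed Integer seed.
#' @return Invisibly, a list with `files`, `manifest` (path of the JSON
#'   ground-truth manifest), `n_rows` (rows written), `n_dropped`,
#'   `expected_rows` (before dropping), and `clean(subject, times)`, a
#'   function returning the noiseless 68 x 2 coordinate array at arbitrary
#'   times.
#' @export
simulate_raw_trace_csv <- function(out_dir, n_subjects = 4, duration = 30,
                                   mean_rate = 5, drop_fraction = 0.2,
                                   jitter = 0.02, conditions = NULL,
                                   bad_cell_fraction = 0, events = NULL,
                                   timestamp_unit = c("ms", "s"),
                                   seed = NULL) {
  stopifnot(mean_rate > 0, drop_fraction >= 0, drop_fraction < 1)
  timestamp_unit <- match.arg(timestamp_unit)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  tpl <- face_template()
  n_frames <- floor(duration * mean_rate) + 1
  cond_levels <- conditions %||% NA_character_

  res <- with_seed(seed, {
    # smooth per-subject motion parameters (define the clean signal)
    phase <- runif(n_subjects, 0, 2 * pi)
    amp <- runif(n_subjects, 1, 3)
    freq <- 0.25
    clean_fun <- function(subject, times) {
      a <- amp[subject]
      p <- phase[subject]
      arr <- array(0, dim = c(68, 2, length(times)))
      arr[, 1, ] <- outer(tpl$x, a * sin(2 * pi * freq * times + p), "+")
      arr[, 2, ] <- outer(tpl$y, a * cos(2 * pi * freq * times + p), "+")
      for (e in events %||% list()) {
        if (!subject %in% e$subjects) next
        idx <- which(times >= e$window[1] & times <= e$window[2])
        if (length(idx) == 0) next
        lms <- face_regions()[[e$region]]
        sig <- region_signals()[[e$region]](times[idx])
        sm <- matrix(sig, nrow = length(lms), ncol = length(idx),
                     byrow = TRUE)
        arr[lms, 1, idx] <- arr[lms, 1, idx] + sm
        arr[lms, 2, idx] <- arr[lms, 2, idx] + sm
      }
      arr
    }
    rows <- list()
    n_dropped <- 0L
    expected_rows <- 0L
    for (cond in cond_levels) {
      for (s in seq_len(n_subjects)) {
        ts <- (seq_len(n_frames) - 1) / mean_rate
        if (jitter > 0) {
          ts <- ts + runif(n_frames, -jitter, jitter)
          ts <- sort(pmax(ts, 0))
        }
        keep <- runif(n_frames) >= drop_fraction
        expected_rows <- expected_rows + n_frames
        n_dropped <- n_dropped + sum(!keep)
        ts <- ts[keep]
        if (length(ts) < 2) ts <- (c(0, n_frames - 1)) / mean_rate
        coords <- clean_fun(s, ts)
        cells <- vapply(seq_along(ts), function(i) {
          pairs <- cbind(round(coords[, 1, i], 2), round(coords[, 2, i], 2))
          jsonlite::toJSON(pairs, digits = NA)
        }, character(1))
        if (bad_cell_fraction > 0) {
          bad <- runif(length(cells)) < bad_cell_fraction
          cells[bad] <- substr(cells[bad], 1, 25)
        }
        emo <- sapply(seq_along(emotion_names()), function(e) {
          pmin(pmax(0.5 + 0.4 * sin(2 * pi * 0.05 * ts + e + phase[s]), 0), 1)
        })
        emo <- matrix(emo, nrow = length(ts))
        colnames(emo) <- paste0(emotion_names(), "Detection")
        df <- tibble(
          participant = sprintf("P%02d", s),
          timestamp = if (timestamp_unit == "ms") round(ts * 1000, 1)
                      else round(ts, 4),
          landmarks = cells
        )
        df <- dplyr::bind_cols(df, as_tibble(emo))
        if (!is.na(cond)) df$condition <- cond
        rows[[length(rows) + 1]] <- df
      }
    }
    list(data = dplyr::bind_rows(rows), clean_fun = clean_fun,
         n_dropped = n_dropped, expected_rows = expected_rows)
  })

  path <- file.path(out_dir, "trace_data.csv")
  readr::write_csv(res$data, path)
  manifest <- list(
    generator = "simulate_raw_trace_csv",
    n_subjects = n_subjects, duration = duration, mean_rate = mean_rate,
    drop_fraction = drop_fraction, jitter = jitter,
    conditions = conditions, seed = seed,
    n_rows = nrow(res$data), expected_rows = res$expected_rows,
    n_dropped = res$n_dropped
  )
  manifest_path <- file.path(out_dir, "truth_manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       null = "null")
  invisible(list(files = path, manifest = manifest_path,
                 n_rows = nrow(res$data), n_dropped = res$n_dropped,
                 expected_rows = res$expected_rows, clean = res$clean_fun))
}
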