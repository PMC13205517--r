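#' Compress landmark X/Y trajectories into scalar feature series
#'
#' Multivariate synchrony analysis needs one scalar series per landmark
#' rather than X/Y pairs (separate horizontal/vertical features would yield
#' anatomically implausible components). Two scalarisations are provided:
#'
#' * `"vector_norm"` (default): `r(t) = sqrt(x'(t)^2 + y'(t)^2)`, the
#'   distance from the landmark's mean-centred position, with the mean taken
#'   over the full recording;
#' * `"motion_amplitude"`: `d(t) = sqrt((x_t - x_(t-1))^2 +
#'   (y_t - y_(t-1))^2)`, the displacement from the previous frame, with
#'   `d(1) = 0`.
#'
#' `vector_norm` is invariant to a constant offset of a landmark's
#' trajectory; `motion_amplitude` is additionally invariant to
#' mean-centring.
#'
#' @param x An aligned [recording_set][align_group()], a
#'   [corrca_sim][simulate_landmark_study()] object, or a subjects x 68 x 2
#'   x samples array.
#' @param mode `"vector_norm"` or `"motion_amplitude"`.
#' @param rate Sampling rate in Hz (taken from `x` when available).
#' @param ... Passed between methods.
#' @return An object of class `feature_matrix`: `data` (subjects x 68 x
#'   samples array), `feature_labels` (landmark ids), `subject_ids`,
#'   `rate`, `mode`, `time`.
#' @examples
#' sim <- simulate_landmark_study(seed = 1)
#' fm <- scalarize(sim)
#' dim(fm$data)
#' @export
scalarize <- function(x, mode = c("vector_norm", "motion_amplitude"), ...) {
  UseMethod("scalarize")
}

scalarize_coords <- function(arr, mode) {
  # arr: N x 68 x 2 x T
  n <- dim(arr)[1]; d <- dim(arr)[2]; t_n <- dim(arr)[4]
  out <- array(NA_real_, dim = c(n, d, t_n))
  for (s in seq_len(n)) {
    xs <- matrix(arr[s, , 1, ], nrow = d)
    ys <- matrix(arr[s, , 2, ], nrow = d)
    if (mode == "vector_norm") {
      xs <- xs - rowMeans(xs)
      ys <- ys - rowMeans(ys)
      out[s, , ] <- sqrt(xs^2 + ys^2)
    } else {
      dx <- xs[, -1, drop = FALSE] - xs[, -t_n, drop = FALSE]
      dy <- ys[, -1, drop = FALSE] - ys[, -t_n, drop = FALSE]
      out[s, , ] <- cbind(rep(0, d), sqrt(dx^2 + dy^2))
    }
  }
  out
}

#' @rdname scalarize
#' @export
scalarize.array <- function(x, mode = c("vector_norm", "motion_amplitude"),
                            rate = NULL, ...) {
  mode <- match.arg(mode)
  if (length(dim(x)) != 4 || dim(x)[3] != 2) {
    abort("expected a subjects x landmarks x 2 x samples array")
  }
  data <- scalarize_coords(x, mode)
  structure(
    list(data = data,
         feature_labels = landmark_index(seq_len(dim(x)[2])),
         subject_ids = dimnames(x)[[1]] %||%
           sprintf("S%02d", seq_len(dim(x)[1])),
         rate = rate, mode = mode,
         time = if (!is.null(rate)) (seq_len(dim(x)[4]) - 1) / rate),
    class = "feature_matrix"
  )
}

#' @rdname scalarize
#' @export
scalarize.corrca_sim <- function(x, mode = c("vector_norm",
                                             "motion_amplitude"), ...) {
  fm <- scalarize.array(x$coords, mode = mode, rate = x$spec$rate)
  fm$time <- x$time
  fm
}

#' @rdname scalarize
#' @export
scalarize.recording_set <- function(x, mode = c("vector_norm",
                                                "motion_amplitude"), ...) {
  mode <- match.arg(mode)
  n <- length(x$recordings)
  t_n <- length(x$time)
  arr <- array(NA_real_, dim = c(n, 68, 2, t_n))
  for (s in seq_len(n)) {
    arr[s, , 1, ] <- t(x$recordings[[s]]$landmarks[, , 1])
    arr[s, , 2, ] <- t(x$recordings[[s]]$landmarks[, , 2])
  }
  fm <- scalarize.array(arr, mode = mode, rate = x$rate)
  fm$subject_ids <- vapply(x$recordings, function(r) r$participant_id,
                           character(1))
  fm$time <- x$time
  fm
}

#' @export
as_tibble.feature_matrix <- function(x, ...) {
  n <- dim(x$data)[1]; d <- dim(x$data)[2]; t_n <- dim(x$data)[3]
  tibble(
    subject = rep(x$subject_ids, each = d * t_n),
    landmark = rep(rep(x$feature_labels, each = t_n), times = n),
    time = rep(x$time %||% seq_len(t_n), times = n * d),
    value = as.vector(aperm(x$data, c(3, 2, 1)))
  )
}
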