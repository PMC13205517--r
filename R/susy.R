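#' Configuration for Surrogate Synchrony (SUSY)
#'
#' @param segment_seconds Segment length in seconds (default 5). Series are
#'   partitioned into consecutive non-overlapping segments of
#'   `round(segment_seconds * rate)` samples; a trailing partial segment is
#'   dropped.
#' @param maxlag_seconds Maximum lag `l` in seconds (default 0). Lags run
#'   over `-L .. +L` samples with `L = round(l * rate)`, giving `2L + 1`
#'   cross-correlation coefficients per segment.
#' @param rate Sampling rate `f` in Hz.
#' @param n_surrogates Number of circular-shuffle surrogate replicates
#'   (default 100).
#' @param aggregate How Fisher-Z values are aggregated across segments and
#'   lags for the effect size: `"signed-mean"` (default) or
#'   `"absolute-mean"`.
#' @param seed Integer seed for the surrogate draws.
#' @return An object of class `susy_config`.
#' @export
susy_config <- function(segment_seconds = 5, maxlag_seconds = 0, rate = 1,
                        n_surrogates = 100,
                        aggregate = c("signed-mean", "absolute-mean"),
                        seed = NULL) {
  aggregate <- match.arg(aggregate)
  stopifnot(segment_seconds > 0, maxlag_seconds >= 0, rate > 0,
            n_surrogates >= 1)
  seg_len <- round(segment_seconds * rate)
  maxlag <- round(maxlag_seconds * rate)
  if (seg_len < 3) {
    abort("segment length must be at least 3 samples at the given rate")
  }
  if (maxlag >= seg_len) {
    abort("maximum lag in samples must be smaller than the segment length")
  }
  structure(
    list(segment_seconds = segment_seconds, maxlag_seconds = maxlag_seconds,
         rate = rate, n_surrogates = n_surrogates, aggregate = aggregate,
         seed = seed, segment_samples = seg_len, maxlag_samples = maxlag),
    class = "susy_config"
  )
}

susy_segments <- function(t_n, config) {
  seg_len <- config$segment_samples
  n_seg <- t_n %/% seg_len
  if (n_seg < 1) abort("series shorter than one segment")
  start <- (seq_len(n_seg) - 1) * seg_len
  tibble(
    segment = seq_len(n_seg),
    t_start = start / config$rate,
    t_end = (start + seg_len - 1) / config$rate,
    t_mid = (start + (seg_len - 1) / 2) / config$rate
  )
}

# Column-wise Pearson correlation of two equally shaped matrices, each
# column mean-centred over its own rows. Zero-variance columns give NA.
col_cor <- function(a, b) {
  ac <- sweep(a, 2, colMeans(a))
  bc <- sweep(b, 2, colMeans(b))
  num <- colSums(ac * bc)
  den <- sqrt(colSums(ac^2) * colSums(bc^2))
  ifelse(den > 0, num / den, NA_real_)
}

clip_r <- function(r) pmin(pmax(r, -1 + 1e-7), 1 - 1e-7)

#' Segmented lagged Fisher-Z cross-correlations for one dyad
#'
#' Partitions both series into consecutive non-overlapping segments and, for
#' every segment and every integer lag in `-L .. +L` samples, computes the
#' Pearson correlation between the overlapping within-segment portions of
#' `a[t]` and `b[t + lag]` (each portion mean-centred over the overlap).
#' Correlations are clipped to `|r| <= 1 - 1e-7` and Fisher-Z transformed
#' (`atanh`). Zero-variance overlaps yield `z = 0` and are counted in the
#' `n_zero_variance` attribute.
#'
#' @param a,b Numeric series of equal length at the same rate.
#' @param config A [susy_config()].
#' @return An object of class `dyad_z`: list with `z` (segments x lags
#'   matrix), `lags` (sample lags), `segments` (tibble of segment spans).
#' @examples
#' cfg <- susy_config(segment_seconds = 5, maxlag_seconds = 3, rate = 5)
#' z <- lagged_segment_z(rnorm(150), rnorm(150), cfg)
#' dim(z$z)    # segments x (2 * round(3 * 5) + 1)
#' @export
lagged_segment_z <- function(a, b, config) {
  if (length(a) != length(b)) {
    abort("`a` and `b` must have the same length")
  }
  seg_len <- config$segment_samples
  segs <- susy_segments(length(a), config)
  n_seg <- nrow(segs)
  used <- n_seg * seg_len
  am <- matrix(a[seq_len(used)], nrow = seg_len)
  bm <- matrix(b[seq_len(used)], nrow = seg_len)
  lags <- seq(-config$maxlag_samples, config$maxlag_samples)
  z <- matrix(NA_real_, nrow = n_seg, ncol = length(lags))
  n_zero <- 0L
  for (j in seq_along(lags)) {
    tau <- lags[j]
    if (tau >= 0) {
      ra <- seq_len(seg_len - tau)
      rb <- ra + tau
    } else {
      rb <- seq_len(seg_len + tau)
      ra <- rb - tau
    }
    if (length(ra) < 2) {
      z[, j] <- 0
      n_zero <- n_zero + n_seg
      next
    }
    r <- col_cor(am[ra, , drop = FALSE], bm[rb, , drop = FALSE])
    bad <- is.na(r)           # zero-variance overlap: z = 0 by convention
    n_zero <- n_zero + sum(bad)
    zz <- atanh(clip_r(ifelse(bad, 0, r)))
    zz[bad] <- 0
    z[, j] <- zz
  }
  structure(list(z = z, lags = lags, segments = segs),
            class = "dyad_z", n_zero_variance = n_zero)
}

rotate_series <- function(x, offset) {
  n <- length(x)
  offset <- ((offset %% n) + n) %% n
  if (offset == 0) x else x[c((offset + 1):n, seq_len(offset))]
}

#' Circular-shuffle surrogate Fisher-Z replicates for one dyad
#'
#' For each replicate, `b` is circularly rotated by a random offset drawn
#' uniformly from `[segment samples, T - segment samples]` and the segmented
#' lagged Fisher-Z analysis is recomputed on `(a, rotated b)`. Rotation
#' preserves `b`'s value multiset exactly (hence its mean and SD) while
#' destroying the temporal alignment, so the replicates form a synchrony
#' null that shares the marginal statistics of the data.
#'
#' @inheritParams lagged_segment_z
#' @param n_surrogates Number of replicates; defaults to `config$n_surrogates`.
#' @param seed Integer seed; defaults to `config$seed`.
#' @return List of class `dyad_surrogates`: `z` (replicates x segments x
#'   lags array), `offsets`, `lags`, `segments`.
#' @export
circular_surrogates <- function(a, b, config,
                                n_surrogates = config$n_surrogates,
                                seed = config$seed) {
  t_n <- length(a)
  lo <- config$segment_samples
  hi <- t_n - config$segment_samples
  if (hi < lo) {
    abort("series too short to admit a legal circular-shuffle offset")
  }
  offsets <- with_seed(seed, sample(lo:hi, n_surrogates, replace = TRUE))
  template <- lagged_segment_z(a, b, config)
  z <- array(NA_real_, dim = c(n_surrogates, nrow(template$z),
                               ncol(template$z)))
  for (r in seq_len(n_surrogates)) {
    z[r, , ] <- lagged_segment_z(a, rotate_series(b, offsets[r]), config)$z
  }
  structure(list(z = z, offsets = offsets, lags = template$lags,
                 segments = template$segments),
            class = "dyad_surrogates")
}

aggregate_z <- function(z, aggregate) {
  if (aggregate == "absolute-mean") mean(abs(z)) else mean(z)
}

#' Surrogate-referenced synchrony effect size
#'
#' Cohen's-d-like effect size
#' `ES = (mu_real - mu_surrogate) / sigma_surrogate`, where `mu_real` is the
#' aggregated real Fisher-Z, and `mu_surrogate`/`sigma_surrogate` are the
#' mean and SD over surrogate replicates of the identically aggregated
#' surrogate Fisher-Z.
#'
#' @param real A `dyad_z` (or its segments x lags matrix).
#' @param surrogate A `dyad_surrogates` (or its replicates x segments x lags
#'   array).
#' @param aggregate `"signed-mean"` (default) or `"absolute-mean"`.
#' @return A single numeric effect size.
#' @examples
#' # mu_real 1.5, mu_surrogate 0, sigma_surrogate 0.5 -> ES = 3
#' @export
effect_size <- function(real, surrogate,
                        aggregate = c("signed-mean", "absolute-mean")) {
  aggregate <- match.arg(aggregate)
  zr <- if (inherits(real, "dyad_z")) real$z else real
  zs <- if (inherits(surrogate, "dyad_surrogates")) surrogate$z else surrogate
  mu_real <- aggregate_z(zr, aggregate)
  reps <- apply(zs, 1, aggregate_z, aggregate = aggregate)
  sigma <- sd(reps)
  if (!is.finite(sigma) || sigma == 0) {
    abort("surrogate SD is zero: effect size undefined")
  }
  (mu_real - mean(reps)) / sigma
}

#' Surrogate Synchrony across all dyads of a group
#'
#' Runs the full SUSY procedure - segmented lagged Fisher-Z
#' cross-correlations, circular-shuffle surrogates and effect sizes - for
#' every unordered pair of subjects on a single channel.
#'
#' @param x A subjects x samples numeric matrix (rownames are subject ids),
#'   a long data frame with columns `subject`, `time`, `value`, a
#'   [recording_set][align_group()] (with `channel`), or a `susy_sim`
#'   object.
#' @param config A [susy_config()]; its `rate` must match the data.
#' @param channel Channel name, used for recording sets (e.g.
#'   `"head_movement"` or an emotion name) and carried into the result.
#' @param ... Passed between methods.
#' @return An object of class `susy_result`: `dyads` (tibble with
#'   `dyad`, `subject_a`, `subject_b`, `es`), `z_real` (list of segments x
#'   lags matrices), `z_surrogate` (list of replicates x segments x lags
#'   arrays), `segments`, `lags`, `config`, `channel`.
#' @examples
#' sim <- simulate_head_movement_study(seed = 1)
#' res <- susy(sim, config = susy_config(rate = 1, n_surrogates = 20,
#'                                       seed = 2))
#' nrow(res$dyads)  # choose(30, 2)
#' @export
susy <- function(x, ...) UseMethod("susy")

# All-pairs Fisher-Z for one (possibly rotated) subject matrix pair:
# entry (s, lag, d) is the correlation of subject pairs_i[d]'s series (rows
# of `xa`) with subject pairs_j[d]'s series (rows of `xb`) at that segment
# and lag. Zero-variance overlaps give z = 0.
all_pairs_z <- function(xa, xb, config, pairs_i, pairs_j) {
  seg_len <- config$segment_samples
  n_seg <- ncol(xa) %/% seg_len
  lags <- seq(-config$maxlag_samples, config$maxlag_samples)
  z <- array(NA_real_, dim = c(n_seg, length(lags), length(pairs_i)))
  idx <- cbind(pairs_i, pairs_j)
  for (li in seq_along(lags)) {
    tau <- lags[li]
    if (tau >= 0) {
      ra <- seq_len(seg_len - tau); rb <- ra + tau
    } else {
      rb <- seq_len(seg_len + tau); ra <- rb - tau
    }
    if (length(ra) < 2) {
      z[, li, ] <- 0
      next
    }
    for (s in seq_len(n_seg)) {
      off <- (s - 1) * seg_len
      a <- t(xa[, off + ra, drop = FALSE])
      b <- t(xb[, off + rb, drop = FALSE])
      a <- sweep(a, 2, colMeans(a))
      b <- sweep(b, 2, colMeans(b))
      a <- sweep(a, 2, sqrt(colSums(a^2)), "/")
      b <- sweep(b, 2, sqrt(colSums(b^2)), "/")
      r <- crossprod(a, b)[idx]
      bad <- !is.finite(r)
      zz <- atanh(clip_r(ifelse(bad, 0, r)))
      zz[bad] <- 0
      z[s, li, ] <- zz
    }
  }
  z
}

#' @rdname susy
#' @export
susy.matrix <- function(x, config, channel = "signal", ...) {
  n <- nrow(x)
  if (n < 2) abort("at least 2 subjects are required for dyadic synchrony")
  t_n <- ncol(x)
  ids <- rownames(x) %||% sprintf("S%02d", seq_len(n))
  pairs <- utils::combn(n, 2)
  n_dyads <- ncol(pairs)
  segs <- susy_segments(t_n, config)
  lags <- seq(-config$maxlag_samples, config$maxlag_samples)
  lo <- config$segment_samples
  hi <- t_n - config$segment_samples
  if (hi < lo) {
    abort("series too short to admit a legal circular-shuffle offset")
  }
  zr <- all_pairs_z(x, x, config, pairs[1, ], pairs[2, ])
  reps <- config$n_surrogates
  # one rotation per subject per replicate, shared across that subject's
  # dyads; pair (i, j) correlates unrotated i with rotated j
  offsets <- with_seed(config$seed,
                       matrix(sample(lo:hi, reps * n, replace = TRUE),
                              nrow = reps))
  zs <- array(NA_real_, dim = c(reps, dim(zr)))
  for (r in seq_len(reps)) {
    xrot <- x
    for (j in seq_len(n)) xrot[j, ] <- rotate_series(x[j, ], offsets[r, j])
    zs[r, , , ] <- all_pairs_z(x, xrot, config, pairs[1, ], pairs[2, ])
  }
  z_real <- lapply(seq_len(n_dyads), function(d) zr[, , d, drop = FALSE][, , 1, drop = TRUE])
  z_real <- lapply(z_real, function(m) matrix(m, nrow = nrow(segs)))
  z_surr <- lapply(seq_len(n_dyads), function(d) {
    array(zs[, , , d], dim = c(reps, nrow(segs), length(lags)))
  })
  es <- vapply(seq_len(n_dyads), function(d) {
    effect_size(z_real[[d]], z_surr[[d]], config$aggregate)
  }, numeric(1))
  dyads <- tibble(
    dyad = seq_len(n_dyads),
    subject_a = ids[pairs[1, ]],
    subject_b = ids[pairs[2, ]],
    es = es
  )
  structure(list(dyads = dyads, z_real = z_real, z_surrogate = z_surr,
                 segments = segs, lags = lags, config = config,
                 channel = channel),
            class = "susy_result")
}

#' @rdname susy
#' @export
susy.data.frame <- function(x, config, channel = "signal", ...) {
  need <- c("subject", "time", "value")
  if (!all(need %in% names(x))) {
    abort("data frame input needs columns `subject`, `time`, `value`")
  }
  wide <- tidyr::pivot_wider(
    dplyr::arrange(x, .data$subject, .data$time),
    id_cols = "subject", names_from = "time", values_from = "value"
  )
  m <- as.matrix(wide[, -1])
  rownames(m) <- as.character(wide$subject)
  if (anyNA(m)) abort("subjects must share an identical time grid")
  susy.matrix(m, config = config, channel = channel)
}

#' @rdname susy
#' @export
susy.susy_sim <- function(x, config = NULL, channel = "head_movement", ...) {
  config <- config %||% susy_config(rate = x$spec$rate)
  susy.matrix(x$signals, config = config, channel = channel)
}

#' @rdname susy
#' @export
susy.recording_set <- function(x, config = NULL, channel = "head_movement",
                               ...) {
  m <- channel_matrix(x, channel)
  rate <- if (identical(channel, "head_movement")) 1 else x$rate
  config <- config %||% susy_config(rate = rate)
  if (!isTRUE(all.equal(config$rate, rate))) {
    abort(sprintf("config rate (%g Hz) does not match channel rate (%g Hz)",
                  config$rate, rate))
  }
  susy.matrix(m, config = config, channel = channel)
}

#' Summarise a SUSY result at a chosen aggregation level
#'
#' @param x A `susy_result`, or - for `level = "condition"` - a named list
#'   of `susy_result` objects (one per condition).
#' @param level `"grand"`, `"dyad"`, `"segment"`, or `"condition"`.
#' @return A tibble of means and standard errors of real and surrogate
#'   Fisher-Z (and, where defined, effect size) at the requested level.
#'   Segment-level rows are indexed by segment midpoint time.
#' @export
susy_summarise <- function(x, level = c("grand", "dyad", "segment",
                                        "condition")) {
  level <- match.arg(level)
  if (level == "condition") {
    if (!is.list(x) || inherits(x, "susy_result")) {
      abort("condition-level summary needs a named list of susy_result objects")
    }
    return(purrr::map_dfr(names(x), function(nm) {
      dplyr::mutate(susy_summarise(x[[nm]], "grand"), condition = nm,
                    .before = 1)
    }))
  }
  stopifnot(inherits(x, "susy_result"))
  se <- function(v) if (length(v) > 1) sd(v) / sqrt(length(v)) else 0
  if (level == "grand") {
    zr <- unlist(x$z_real)
    zs <- unlist(x$z_surrogate)
    return(tibble(
      n_dyads = nrow(x$dyads),
      mean_z_real = mean(zr), se_z_real = se(zr),
      mean_z_surrogate = mean(zs), se_z_surrogate = se(zs),
      mean_es = mean(x$dyads$es), se_es = se(x$dyads$es)
    ))
  }
  if (level == "dyad") {
    return(dplyr::mutate(
      x$dyads,
      mean_z_real = vapply(x$z_real, mean, numeric(1)),
      mean_z_surrogate = vapply(x$z_surrogate, mean, numeric(1))
    ))
  }
  # segment level: pool across dyads and lags within each segment
  purrr::map_dfr(seq_len(nrow(x$segments)), function(s) {
    zr <- unlist(lapply(x$z_real, function(m) m[s, ]))
    zs <- unlist(lapply(x$z_surrogate, function(a) a[, s, ]))
    tibble(segment = s, t_mid = x$segments$t_mid[s],
           mean_z_real = mean(zr), se_z_real = se(zr),
           mean_z_surrogate = mean(zs), se_z_surrogate = se(zs))
  })
}

#' Paired test of real vs surrogate Fisher-Z within a time window
#'
#' Pools (real z, replicate-mean surrogate z) pairs across all dyads, all
#' segments whose closed time span intersects the closed `window`, and all
#' lags, and performs a paired t-test. With 435 dyads, 3 intersecting
#' segments and a single lag this yields df = 1304.
#'
#' @param result A `susy_result`.
#' @param window Two-element numeric time interval in seconds.
#' @return A one-row tibble: `statistic`, `df`, `p_value`, `n_pairs`,
#'   `mean_real`, `mean_surrogate`.
#' @export
real_vs_surrogate_test <- function(result, window) {
  stopifnot(inherits(result, "susy_result"), length(window) == 2)
  segs <- result$segments
  keep <- segs$t_end >= window[1] & segs$t_start <= window[2]
  if (!any(keep)) {
    abort("no segment intersects the requested window")
  }
  idx <- which(keep)
  real <- unlist(lapply(result$z_real, function(m) m[idx, , drop = FALSE]))
  surr <- unlist(lapply(result$z_surrogate, function(a) {
    apply(a[, idx, , drop = FALSE], c(2, 3), mean)
  }))
  diffs <- real - surr
  if (sd(diffs) == 0) {
    # degenerate pairing (real identical to surrogate up to a constant)
    stat <- if (mean(diffs) == 0) 0 else Inf * sign(mean(diffs))
    return(tibble(statistic = stat, df = length(diffs) - 1,
                  p_value = if (stat == 0) 1 else 0,
                  n_pairs = length(real),
                  mean_real = mean(real), mean_surrogate = mean(surr)))
  }
  tt <- t.test(real, surr, paired = TRUE)
  tibble(statistic = unname(tt$statistic), df = unname(tt$parameter),
         p_value = tt$p.value, n_pairs = length(real),
         mean_real = mean(real), mean_surrogate = mean(surr))
}
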