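#' Tidy a SUSY result into a long per-observation tibble
#'
#' One row per dyad x segment x lag, with the real Fisher-Z, the
#' replicate-mean surrogate Fisher-Z and the dyad's effect size.
#'
#' @param x A `susy_result`.
#' @param ... Unused.
#' @return A tibble with columns `dyad`, `subject_a`, `subject_b`,
#'   `segment`, `t_mid`, `lag`, `z_real`, `z_surrogate_mean`, `es`.
#' @method tidy susy_result
#' @export
tidy.susy_result <- function(x, ...) {
  purrr::map_dfr(seq_len(nrow(x$dyads)), function(d) {
    zr <- x$z_real[[d]]
    zs <- apply(x$z_surrogate[[d]], c(2, 3), mean)
    tibble(
      dyad = x$dyads$dyad[d],
      subject_a = x$dyads$subject_a[d],
      subject_b = x$dyads$subject_b[d],
      segment = rep(x$segments$segment, times = length(x$lags)),
      t_mid = rep(x$segments$t_mid, times = length(x$lags)),
      lag = rep(x$lags, each = nrow(zr)),
      z_real = as.vector(zr),
      z_surrogate_mean = as.vector(zs),
      es = x$dyads$es[d]
    )
  })
}

#' One-row summary of a SUSY result
#'
#' @param x A `susy_result`.
#' @param ... Unused.
#' @return A tibble: dyad count, segment count, lag count, mean real and
#'   surrogate Fisher-Z, mean and SD of the dyadic effect sizes.
#' @method glance susy_result
#' @export
glance.susy_result <- function(x, ...) {
  tibble(
    n_dyads = nrow(x$dyads),
    n_segments = nrow(x$segments),
    n_lags = length(x$lags),
    n_surrogates = x$config$n_surrogates,
    mean_z_real = mean(unlist(x$z_real)),
    mean_z_surrogate = mean(unlist(x$z_surrogate)),
    mean_es = mean(x$dyads$es),
    sd_es = sd(x$dyads$es)
  )
}

#' Tidy a CorrCA fit into a per-component tibble
#'
#' @param x A `corrca_result`.
#' @param ... Unused.
#' @return A tibble with `component`, `eigenvalue` and `isc`
#'   (`rho = eigenvalue / (N - 1)`).
#' @method tidy corrca_result
#' @export
tidy.corrca_result <- function(x, ...) {
  tibble(component = seq_along(x$lambda),
         eigenvalue = x$lambda,
         isc = x$rho)
}

#' One-row summary of a CorrCA fit
#'
#' @param x A `corrca_result`.
#' @param ... Unused.
#' @return A tibble: dimensions, shrinkage, leading-component ISC.
#' @method glance corrca_result
#' @export
glance.corrca_result <- function(x, ...) {
  tibble(
    n_subjects = x$n_subjects,
    n_features = x$n_features,
    n_samples = x$n_samples,
    gamma = x$gamma,
    n_components = ncol(x$W),
    isc_1 = x$rho[1]
  )
}

#' @export
print.susy_result <- function(x, ...) {
  cat(sprintf("<susy_result> %d dyads x %d segments x %d lags (channel: %s)\n",
              nrow(x$dyads), nrow(x$segments), length(x$lags), x$channel))
  cat(sprintf("  mean z real %.3f | mean z surrogate %.3f | mean ES %.2f\n",
              mean(unlist(x$z_real)), mean(unlist(x$z_surrogate)),
              mean(x$dyads$es)))
  invisible(x)
}

#' @export
print.corrca_result <- function(x, ...) {
  cat(sprintf("<corrca_result> N=%d subjects, D=%d features, T=%d samples, gamma=%g\n",
              x$n_subjects, x$n_features, x$n_samples, x$gamma))
  k <- min(3, length(x$rho))
  cat(sprintf("  leading ISC: %s\n",
              paste(sprintf("C%d=%.3f", seq_len(k), x$rho[seq_len(k)]),
                    collapse = ", ")))
  invisible(x)
}
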