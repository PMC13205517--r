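#' Configuration for Correlated Component Analysis
#'
#' @param gamma Shrinkage weight in `[0, 1]` (default 0.1). The pooled
#'   within-subject covariance is regularised as
#'   `R_w(gamma) = (1 - gamma) R_w + gamma (trace(R_w)/D) I`, blending the
#'   sample covariance with an isotropic target; `gamma = 1` gives the pure
#'   isotropic endpoint.
#' @param window_seconds Sliding-window length in seconds for the windowed
#'   ISC trace (default 3).
#' @param window_step_seconds Step between window starts in seconds
#'   (default 1).
#' @param n_components Number of components to retain (default all).
#' @param normalize_windowed Scale the windowed ISC by `1/(N - 1)` so it is
#'   comparable with the component ISC `rho` (default `TRUE`); `FALSE`
#'   gives the raw windowed Rayleigh quotient.
#' @param subject_isc_variant `"pooled"` (default): per-subject ISC uses the
#'   pooled shrunk within-subject covariance in the denominator, scaled by
#'   `1/(N - 1)` so the subject mean equals `rho_k` exactly;
#'   `"per-subject"`: each subject's own within-subject covariance is used
#'   instead.
#' @return An object of class `corrca_config`.
#' @export
corrca_config <- function(gamma = 0.1, window_seconds = 3,
                          window_step_seconds = 1, n_components = NULL,
                          normalize_windowed = TRUE,
                          subject_isc_variant = c("pooled", "per-subject")) {
  stopifnot(gamma >= 0, gamma <= 1, window_seconds > 0,
            window_step_seconds > 0)
  structure(
    list(gamma = gamma, window_seconds = window_seconds,
         window_step_seconds = window_step_seconds,
         n_components = n_components,
         normalize_windowed = isTRUE(normalize_windowed),
         subject_isc_variant = match.arg(subject_isc_variant)),
    class = "corrca_config"
  )
}

feature_array <- function(x) {
  if (inherits(x, "feature_matrix")) return(x$data)
  if (is.array(x) && length(dim(x)) == 3) return(x)
  abort("expected a feature_matrix or a subjects x features x samples array")
}

feature_rate <- function(x) {
  if (inherits(x, "feature_matrix")) x$rate else NULL
}

#' Pooled within- and between-subject covariance matrices
#'
#' With each subject's feature series mean-centred over time, the pairwise
#' cross-covariance between subjects i and j is
#' `R_ij = X_i X_j' / (T - 1)`. The per-subject within-covariance is
#' `R_w,i = R_ii`; the per-subject between-covariance is the symmetrised sum
#' of that subject's cross-covariances,
#' `R_b,i = sum_{j != i} (R_ij + R_ij') / 2`. Pooled matrices are the sums
#' over subjects: `R_w = sum_i R_w,i` and `R_b = sum_i R_b,i`.
#'
#' @param x A [feature_matrix][scalarize()] or a subjects x features x
#'   samples numeric array (N >= 2).
#' @param sample_idx Optional integer vector of sample indices; covariances
#'   are then estimated (and mean-centred) within that subset only.
#' @param warn_rank Warn when there are fewer samples than features
#'   (default `TRUE`; sliding-window estimation disables it).
#' @return An object of class `covariance_set`: `R_w`, `R_b` (D x D),
#'   `R_w_i`, `R_b_i` (N x D x D arrays), `n_subjects`, `n_features`,
#'   `n_samples`.
#' @examples
#' X <- array(rnorm(3 * 2 * 50), dim = c(3, 2, 50))
#' cs <- estimate_covariances(X)
#' all.equal(cs$R_w, cs$R_w_i[1, , ] + cs$R_w_i[2, , ] + cs$R_w_i[3, , ])
#' @export
estimate_covariances <- function(x, sample_idx = NULL, warn_rank = TRUE) {
  arr <- feature_array(x)
  n <- dim(arr)[1]; d <- dim(arr)[2]
  if (n < 2) abort("at least 2 subjects are required")
  if (!is.null(sample_idx)) arr <- arr[, , sample_idx, drop = FALSE]
  t_n <- dim(arr)[3]
  if (t_n < 2) abort("at least 2 samples are required")
  if (t_n < d && warn_rank) {
    warn(sprintf(
      "fewer samples (%d) than features (%d): covariance estimates are rank-deficient",
      t_n, d))
  }
  xc <- vector("list", n)
  for (i in seq_len(n)) {
    xi <- matrix(arr[i, , ], nrow = d)
    xc[[i]] <- xi - rowMeans(xi)
  }
  s_tot <- Reduce(`+`, xc)
  denom <- t_n - 1
  r_w_i <- array(NA_real_, dim = c(n, d, d))
  r_b_i <- array(NA_real_, dim = c(n, d, d))
  for (i in seq_len(n)) {
    r_w_i[i, , ] <- tcrossprod(xc[[i]]) / denom
    cross <- tcrossprod(xc[[i]], s_tot - xc[[i]]) / denom
    r_b_i[i, , ] <- (cross + t(cross)) / 2
  }
  r_w <- apply(r_w_i, c(2, 3), sum)
  r_b <- apply(r_b_i, c(2, 3), sum)
  r_w <- (r_w + t(r_w)) / 2
  r_b <- (r_b + t(r_b)) / 2
  structure(list(R_w = r_w, R_b = r_b, R_w_i = r_w_i, R_b_i = r_b_i,
                 n_subjects = n, n_features = d, n_samples = t_n),
            class = "covariance_set")
}

shrink_rw <- function(r_w, gamma) {
  d <- nrow(r_w)
  (1 - gamma) * r_w + gamma * (sum(diag(r_w)) / d) * diag(d)
}

# Generalised eigendecomposition R_b w = lambda R_w(gamma) w via a
# (pivoted-fallback) Cholesky whitening of the shrunk within covariance.
geneig <- function(r_b, r_wg) {
  if (any(!is.finite(r_b)) || any(!is.finite(r_wg))) {
    abort("non-finite covariance entries: cannot eigendecompose")
  }
  u <- tryCatch(chol(r_wg), error = function(e) NULL)
  if (is.null(u)) {
    ev <- eigen(r_wg, symmetric = TRUE)
    tol <- max(ev$values) * 1e-10
    if (any(ev$values <= tol)) {
      abort(paste0("shrunk within-subject covariance is singular; ",
                   "increase gamma or reduce features"))
    }
    u <- diag(sqrt(ev$values)) %*% t(ev$vectors)
  }
  ui <- backsolve(u, diag(nrow(u)))
  c_mat <- t(ui) %*% r_b %*% ui
  c_mat <- (c_mat + t(c_mat)) / 2
  ee <- eigen(c_mat, symmetric = TRUE)
  list(values = ee$values, vectors = ui %*% ee$vectors)
}

#' Component-level intersubject correlation from eigenvalues
#'
#' Normalises generalised eigenvalues to correlation-like component ISC
#' values, `rho_k = lambda_k / (N - 1)`.
#'
#' @param lambda Numeric eigenvalues.
#' @param n_subjects Number of subjects N (>= 2).
#' @return Numeric vector of `rho_k`. Errors if any `|rho_k|` exceeds 1 by
#'   more than 1e-8 (a numeric-integrity violation).
#' @export
component_isc <- function(lambda, n_subjects) {
  stopifnot(n_subjects >= 2)
  rho <- lambda / (n_subjects - 1)
  if (any(abs(rho) > 1 + 1e-8)) {
    abort(sprintf("component ISC bound violated: max |rho| = %.6g", max(abs(rho))))
  }
  rho
}

#' Fit Correlated Component Analysis
#'
#' Estimates pooled within/between-subject covariances, applies isotropic
#' shrinkage to the within-subject covariance, and solves the generalised
#' eigenvalue problem `R_b W = R_w(gamma) W Lambda`. Eigenvectors are
#' ordered by descending eigenvalue, normalised so that
#' `w' R_w(gamma) w = 1`, and sign-fixed so that each component's
#' largest-magnitude forward-model loading is positive (the generalised
#' eigenproblem determines eigenvectors only up to sign).
#'
#' @param x A [feature_matrix][scalarize()] or subjects x features x samples
#'   array.
#' @param config A [corrca_config()].
#' @return An object of class `corrca_result`: `W` (D x K), `lambda`, `rho`
#'   (= `lambda/(N-1)`), `subject_isc` (N x K matrix), `A` (D x K forward
#'   model, computed from the unshrunk `R_w`), `windowed` (tibble
#'   `component`, `time`, `isc`, present when the input carries a sampling
#'   rate), `covariances`, `config`, `gamma`, dimensions `n_subjects`,
#'   `n_features`, `n_samples`, and `feature_labels`/`subject_ids` when
#'   available.
#' @examples
#' X <- array(rnorm(4 * 3 * 200), dim = c(4, 3, 200))
#' fit <- corrca_fit(X, corrca_config(gamma = 0.1))
#' fit$rho
#' @export
corrca_fit <- function(x, config = corrca_config()) {
  covs <- estimate_covariances(x)
  d <- covs$n_features
  k <- config$n_components %||% d
  if (k > d) abort("n_components cannot exceed the number of features")
  r_wg <- shrink_rw(covs$R_w, config$gamma)
  ge <- geneig(covs$R_b, r_wg)
  ord <- order(ge$values, decreasing = TRUE)   # stable sort: ties keep solver order
  w <- ge$vectors[, ord, drop = FALSE][, seq_len(k), drop = FALSE]
  lambda <- ge$values[ord][seq_len(k)]
  # normalise so w' R_w(gamma) w = 1 per component
  nrm <- sqrt(colSums(w * (r_wg %*% w)))
  w <- sweep(w, 2, nrm, "/")
  a <- forward_model(covs, w)
  flip <- vapply(seq_len(k), function(j) {
    v <- a[, j]
    s <- sign(v[which.max(abs(v))])
    if (s == 0) 1 else s
  }, numeric(1))
  w <- sweep(w, 2, flip, "*")
  a <- sweep(a, 2, flip, "*")
  rho <- component_isc(lambda, covs$n_subjects)
  res <- structure(
    list(W = w, lambda = lambda, rho = rho, A = a,
         subject_isc = NULL, windowed = NULL,
         covariances = covs, config = config, gamma = config$gamma,
         n_subjects = covs$n_subjects, n_features = d,
         n_samples = covs$n_samples,
         feature_labels = if (inherits(x, "feature_matrix"))
           x$feature_labels else NULL,
         subject_ids = if (inherits(x, "feature_matrix"))
           x$subject_ids else NULL),
    class = "corrca_result"
  )
  res$subject_isc <- subject_isc(res)
  if (!is.null(feature_rate(x))) {
    res$windowed <- windowed_isc(x, res, config)
  }
  res
}

#' Per-subject intersubject correlation
#'
#' For each subject i and component k, the default (pooled-denominator)
#' definition is
#' `ISC_ik = N (w_k' R_b,i w_k) / ((N - 1) w_k' R_w(gamma) w_k)`:
#' the subject's symmetrised between-subject covariance against the pooled
#' shrunk within-subject covariance, scaled so that the subject mean equals
#' `rho_k` exactly (the pooled denominator is the sum of N per-subject
#' within covariances). The `"per-subject"` variant instead uses subject
#' i's own within-subject covariance,
#' `ISC_ik = (w_k' R_b,i w_k) / ((N - 1) w_k' R_w,i w_k)`.
#' Both give `ISC_ik = 1` for identical subjects at `gamma = 0`.
#'
#' @param result A `corrca_result`.
#' @param covariances A `covariance_set`; defaults to the one stored in
#'   `result`.
#' @param variant `"pooled"` (default) or `"per-subject"`.
#' @return An N x K numeric matrix of per-subject ISC values.
#' @export
subject_isc <- function(result, covariances = result$covariances,
                        variant = result$config$subject_isc_variant) {
  w <- result$W
  n <- covariances$n_subjects
  k <- ncol(w)
  r_wg <- shrink_rw(covariances$R_w, result$gamma)
  denom_pooled <- colSums(w * (r_wg %*% w))
  out <- matrix(NA_real_, nrow = n, ncol = k)
  for (i in seq_len(n)) {
    num <- colSums(w * (covariances$R_b_i[i, , ] %*% w))
    if (variant == "pooled") {
      out[i, ] <- n * num / ((n - 1) * denom_pooled)
    } else {
      den_i <- colSums(w * (covariances$R_w_i[i, , ] %*% w))
      out[i, ] <- num / ((n - 1) * den_i)
    }
  }
  rownames(out) <- result$subject_ids %||% sprintf("S%02d", seq_len(n))
  colnames(out) <- paste0("C", seq_len(k))
  out
}

#' Sliding-window intersubject correlation trace
#'
#' Re-estimates within/between-subject covariances inside each sliding
#' window and projects them through the *global* eigenvectors `W` (never
#' refit per window, so component identity is preserved across time):
#' `ISC_k(t) = (w_k' R_b(t) w_k) / (w_k' R_w(t) w_k)`, scaled by
#' `1/(N - 1)` when `normalize_windowed` is set. Windows lie on a full
#' window grid: starts 0, step, 2 step, ... with start + window <= duration,
#' giving `floor((T_seconds - window) / step) + 1` estimates; data are
#' mean-centred within each window.
#'
#' @param x The [feature_matrix][scalarize()] (or array plus `rate`) the fit
#'   was computed on.
#' @param result A `corrca_result`.
#' @param config A [corrca_config()]; defaults to the one stored in
#'   `result`.
#' @param rate Sampling rate in Hz; taken from `x` when it is a
#'   feature_matrix.
#' @return A tibble with columns `component`, `time` (window centre,
#'   seconds) and `isc`.
#' @export
windowed_isc <- function(x, result, config = result$config,
                         rate = feature_rate(x)) {
  arr <- feature_array(x)
  if (is.null(rate)) abort("a sampling rate is required for windowed ISC")
  t_n <- dim(arr)[3]
  win <- round(config$window_seconds * rate)
  step <- max(1L, round(config$window_step_seconds * rate))
  if (win < 2) abort("window must contain at least 2 samples")
  if (win > t_n) abort("window is longer than the recording")
  starts <- seq(1L, t_n - win + 1L, by = step)
  w <- result$W
  k <- ncol(w)
  scale <- if (config$normalize_windowed) result$n_subjects - 1 else 1
  out <- purrr::map_dfr(starts, function(s0) {
    idx <- s0:(s0 + win - 1L)
    cs <- estimate_covariances(arr, sample_idx = idx, warn_rank = FALSE)
    num <- colSums(w * (cs$R_b %*% w))
    den <- colSums(w * (cs$R_w %*% w))
    tibble(component = seq_len(k),
           time = ((s0 - 1) + (win - 1) / 2) / rate,
           isc = num / (den * scale))
  })
  out
}

#' Forward model of fitted components
#'
#' Maps components back into feature space:
#' `A = R_w W (W' R_w W)^(-1)`, using the *unshrunk* pooled within-subject
#' covariance. Columns of `A` are spatial loading patterns; large absolute
#' loadings mark features (landmarks) contributing strongly to a component.
#' Each column is invariant to rescaling of the corresponding eigenvector.
#'
#' @param covariances A `covariance_set` (or a `corrca_result`, whose stored
#'   covariances are used).
#' @param W D x K eigenvector matrix; defaults to the fitted `W` when a
#'   result is given.
#' @return A D x K numeric matrix.
#' @export
forward_model <- function(covariances, W = NULL) {
  if (inherits(covariances, "corrca_result")) {
    W <- W %||% covariances$W
    covariances <- covariances$covariances
  }
  r_w <- covariances$R_w
  m <- t(W) %*% r_w %*% W
  minv <- tryCatch(solve(m), error = function(e) {
    abort(paste0("W' R_w W is singular; use a larger gamma or fewer ",
                 "components"))
  })
  r_w %*% W %*% minv
}

#' Reconstruct feature contributions of the retained components
#'
#' `X_hat_i = A W' X_i` per subject, on mean-centred data. With all D
#' components retained and full-rank `W`, this reproduces each subject's
#' mean-centred data exactly.
#'
#' @param result A `corrca_result` (supplies `A` and `W`), or a D x K
#'   forward-model matrix `A` with `W` given explicitly.
#' @param x The feature matrix or array to reconstruct.
#' @param W Eigenvector matrix when `result` is a plain matrix.
#' @return A subjects x features x samples array of reconstructed
#'   (mean-centred) data.
#' @export
reconstruct_features <- function(result, x, W = NULL) {
  if (inherits(result, "corrca_result")) {
    a <- result$A
    w <- result$W
  } else {
    a <- result
    w <- W
    if (is.null(w)) abort("`W` is required when `result` is a plain matrix")
  }
  arr <- feature_array(x)
  n <- dim(arr)[1]; d <- dim(arr)[2]; t_n <- dim(arr)[3]
  proj <- a %*% t(w)
  out <- array(NA_real_, dim = dim(arr), dimnames = dimnames(arr))
  for (i in seq_len(n)) {
    xi <- matrix(arr[i, , ], nrow = d)
    xi <- xi - rowMeans(xi)
    out[i, , ] <- proj %*% xi
  }
  out
}

#' Shrinkage sensitivity sweep
#'
#' Refits CorrCA at each value of the shrinkage parameter and reports the
#' leading component's ISC per group, together with the rank order of
#' groups at each gamma and whether that order is stable across the sweep.
#'
#' @param x A [feature_matrix][scalarize()]/array, or a named list of them
#'   (one per group/condition).
#' @param gammas Shrinkage values to sweep (default
#'   `c(0.05, 0.1, 0.2, 0.5, 1)`).
#' @param config Base [corrca_config()]; its `gamma` is overridden.
#' @return A tibble with columns `gamma`, `group`, `rho_1` and a list
#'   column `subject_isc` (leading-component per-subject ISC). The
#'   attribute `"rank_stable"` is `TRUE` when the rank order of groups by
#'   `rho_1` is identical across all gammas.
#' @export
gamma_sweep <- function(x, gammas = c(0.05, 0.1, 0.2, 0.5, 1),
                        config = corrca_config()) {
  groups <- if (is.list(x) && !inherits(x, "feature_matrix") &&
                !is.array(x)) x else list(all = x)
  if (is.null(names(groups))) names(groups) <- paste0("G", seq_along(groups))
  out <- purrr::map_dfr(gammas, function(g) {
    cfg <- config
    cfg$gamma <- g
    purrr::map_dfr(names(groups), function(nm) {
      fit <- corrca_fit(groups[[nm]], cfg)
      tibble(gamma = g, group = nm, rho_1 = fit$rho[1],
             subject_isc = list(fit$subject_isc[, 1]))
    })
  })
  ranks <- lapply(split(out, out$gamma), function(df) {
    df$group[order(-df$rho_1)]
  })
  attr(out, "rank_stable") <- length(unique(ranks)) == 1
  out
}
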