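test_that("pooled covariances match the brute-force definition", {
  set.seed(61)
  arr <- array(rnorm(3 * 2 * 5), dim = c(3, 2, 5))
  cs <- estimate_covariances(arr)
  oracle <- brute_covariances(arr)
  expect_equal(cs$R_w, oracle$R_w)
  expect_equal(cs$R_b, oracle$R_b)
  for (i in 1:3) {
    expect_equal(cs$R_w_i[i, , ], oracle$R_w_i[[i]])
    expect_equal(cs$R_b_i[i, , ], oracle$R_b_i[[i]])
  }
  # pooling identities hold by construction
  expect_equal(cs$R_w, cs$R_w_i[1, , ] + cs$R_w_i[2, , ] + cs$R_w_i[3, , ])
  expect_equal(cs$R_b, cs$R_b_i[1, , ] + cs$R_b_i[2, , ] + cs$R_b_i[3, , ])
  expect_error(estimate_covariances(array(1, dim = c(1, 2, 5))),
               "2 subjects")
})

test_that("identical subjects give R_b = (N-1) R_w and perfect ISC at gamma 0", {
  set.seed(62)
  n <- 5
  base <- matrix(rnorm(3 * 400), nrow = 3)
  arr <- array(NA_real_, dim = c(n, 3, 400))
  for (i in seq_len(n)) arr[i, , ] <- base
  cs <- estimate_covariances(arr)
  expect_equal(cs$R_b, (n - 1) * cs$R_w, tolerance = 1e-10)
  fit <- corrca_fit(arr, corrca_config(gamma = 0))
  expect_equal(fit$rho[1], 1, tolerance = 1e-8)
  expect_equal(fit$lambda[1], n - 1, tolerance = 1e-8)
  expect_equal(unname(fit$subject_isc[, 1]), rep(1, n), tolerance = 1e-8)
})

test_that("independent subjects have vanishing between-subject covariance", {
  set.seed(63)
  arr <- array(rnorm(4 * 4 * 10000), dim = c(4, 4, 10000))
  cs <- estimate_covariances(arr)
  expect_lt(norm(cs$R_b, "F") / norm(cs$R_w, "F"), 0.1)
})

test_that("the leading eigenvalue matches the brute-force Rayleigh maximiser", {
  for (seed in 1:4) {
    set.seed(seed)
    arr <- array(rnorm(6 * 2 * 300), dim = c(6, 2, 300))
    arr[, 1, ] <- arr[, 1, ] +
      matrix(rnorm(300), 6, 300, byrow = TRUE)   # shared component
    for (g in c(0, 0.1, 0.5)) {
      fit <- corrca_fit(arr, corrca_config(gamma = g))
      cs <- fit$covariances
      oracle <- rayleigh_max(cs$R_b, facesync:::shrink_rw(cs$R_w, g))
      expect_equal(fit$lambda[1], oracle, tolerance = 1e-4)
    }
  }
})

test_that("the eigenvalue spectrum is invariant to common invertible mixing at gamma 0", {
  set.seed(64)
  arr <- array(rnorm(4 * 3 * 500), dim = c(4, 3, 500))
  arr[, 2, ] <- arr[, 2, ] + matrix(rnorm(500), 4, 500, byrow = TRUE)
  m <- matrix(c(1, 0.5, 0, -0.3, 2, 0.2, 0.1, 0, 1.5), 3, 3)
  mixed <- arr
  for (i in 1:4) mixed[i, , ] <- m %*% matrix(arr[i, , ], nrow = 3)
  f1 <- corrca_fit(arr, corrca_config(gamma = 0))
  f2 <- corrca_fit(mixed, corrca_config(gamma = 0))
  expect_equal(f1$lambda, f2$lambda, tolerance = 1e-8)
})

test_that("eigenvalues normalise to component ISC by 1/(N-1)", {
  expect_equal(component_isc(14.5, 30), 0.5)
  expect_equal(component_isc(29, 30), 1)
  expect_error(component_isc(40, 30), "bound violated")
  # pure-noise fixture: leading ISC stays small
  set.seed(65)
  arr <- array(rnorm(10 * 5 * 2000), dim = c(10, 5, 2000))
  fit <- corrca_fit(arr, corrca_config(gamma = 0))
  expect_lt(fit$rho[1], 0.2)
})

test_that("the subject mean of per-subject ISC equals rho exactly", {
  set.seed(66)
  for (i in 1:5) {
    n <- sample(3:8, 1)
    arr <- array(rnorm(n * 4 * 200), dim = c(n, 4, 200))
    fit <- corrca_fit(arr, corrca_config(gamma = sample(c(0, 0.1, 0.5), 1)))
    expect_equal(unname(colMeans(fit$subject_isc)), fit$rho,
                 tolerance = 1e-10)
  }
  # per-subject denominator variant still averages near rho
  arr <- array(rnorm(6 * 3 * 400), dim = c(6, 3, 400))
  fit <- corrca_fit(arr, corrca_config(gamma = 0.1,
                                       subject_isc_variant = "per-subject"))
  expect_equal(dim(fit$subject_isc), c(6L, 3L))
})

test_that("windowed ISC is flat at 1 for stationary identical subjects", {
  set.seed(67)
  base <- matrix(rnorm(3 * 200), nrow = 3)
  arr <- array(NA_real_, dim = c(4, 3, 200))
  for (i in 1:4) arr[i, , ] <- base
  fm <- structure(list(data = arr, feature_labels = 1:3,
                       subject_ids = sprintf("S%d", 1:4), rate = 5,
                       mode = "vector_norm", time = (0:199) / 5),
                  class = "feature_matrix")
  fit <- corrca_fit(fm, corrca_config(gamma = 0, window_seconds = 3,
                                      window_step_seconds = 1))
  tr1 <- fit$windowed[fit$windowed$component == 1, ]
  expect_equal(tr1$isc, rep(1, nrow(tr1)), tolerance = 1e-8)
  # trace length = floor((T_seconds - window) / step) + 1
  expect_equal(nrow(tr1), floor((200 / 5 - 3) / 1) + 1)
  expect_error(windowed_isc(fm, fit, corrca_config(window_seconds = 100)),
               "longer than the recording")
})

test_that("the forward model inverts to the data at full rank and gamma 0", {
  set.seed(68)
  arr <- array(rnorm(4 * 3 * 300), dim = c(4, 3, 300))
  fit <- corrca_fit(arr, corrca_config(gamma = 0))
  rec <- reconstruct_features(fit, arr)
  for (i in 1:4) {
    xi <- matrix(arr[i, , ], nrow = 3)
    xi <- xi - rowMeans(xi)
    expect_equal(rec[i, , ], xi, tolerance = 1e-6)
  }
  # the reconstruction operator A W' is invariant to any rescaling of the
  # eigenvectors (A itself scales inversely, by homogeneity)
  a1 <- forward_model(fit$covariances, fit$W)
  w_scaled <- fit$W %*% diag(c(2, -0.5, 7))
  a2 <- forward_model(fit$covariances, w_scaled)
  expect_equal(a2 %*% t(w_scaled), a1 %*% t(fit$W), tolerance = 1e-8)
  expect_equal(a2[, 1], a1[, 1] / 2, tolerance = 1e-8)
})

test_that("component sign is fixed by the largest forward-model loading", {
  set.seed(69)
  arr <- array(rnorm(5 * 4 * 300), dim = c(5, 4, 300))
  fit <- corrca_fit(arr, corrca_config(gamma = 0.1))
  for (k in seq_len(ncol(fit$A))) {
    expect_gt(fit$A[which.max(abs(fit$A[, k])), k], 0)
  }
})

test_that("the shrinkage sweep refits at each gamma and flags rank stability", {
  set.seed(70)
  arr <- array(rnorm(6 * 3 * 300), dim = c(6, 3, 300))
  sw <- gamma_sweep(arr)
  expect_equal(sw$gamma, c(0.05, 0.1, 0.2, 0.5, 1))
  expect_equal(nrow(sw), 5)
  expect_type(attr(sw, "rank_stable"), "logical")
  # gamma = 1: within covariance fully isotropic
  iso <- facesync:::shrink_rw(estimate_covariances(arr)$R_w, 1)
  expect_equal(iso, diag(sum(diag(estimate_covariances(arr)$R_w)) / 3, 3))
  # increasing shrinkage never raises the leading noise ISC
  rho1 <- vapply(c(0.05, 0.1, 0.2, 0.5, 1), function(g) {
    corrca_fit(arr, corrca_config(gamma = g))$rho[1]
  }, numeric(1))
  expect_true(all(diff(rho1) <= 1e-10))
})

test_that("two synthetic groups keep their rank order across the sweep", {
  set.seed(71)
  mk <- function(share) {
    arr <- array(rnorm(30 * 4 * 400), dim = c(30, 4, 400))
    shared <- matrix(rnorm(400), 30, 400, byrow = TRUE)
    arr[, 1, ] <- sqrt(1 - share^2) * arr[, 1, ] + share * shared
    arr
  }
  sw <- gamma_sweep(list(strong = mk(0.8), weak = mk(0.3)))
  expect_true(attr(sw, "rank_stable"))
  top <- dplyr::slice_max(dplyr::group_by(sw, gamma), rho_1, n = 1)
  expect_true(all(top$group == "strong"))
})

test_that("the ISC bound holds across randomized fits", {
  set.seed(72)
  worst <- 0
  for (i in 1:40) {
    n <- sample(2:10, 1); d <- sample(2:6, 1); t_n <- sample(50:300, 1)
    arr <- array(rnorm(n * d * t_n), dim = c(n, d, t_n))
    g <- sample(c(0.05, 0.1, 0.2, 0.5, 1), 1)
    fit <- corrca_fit(arr, corrca_config(gamma = g))
    worst <- max(worst, abs(fit$rho))
  }
  expect_lte(worst, 1 + 1e-8)
})
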