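test_that("the lag axis has 2*round(l*f) + 1 points for any configuration", {
  cases <- list(c(3, 5), c(0, 5), c(1, 1), c(0.5, 5), c(2, 2))
  for (cs in cases) {
    cfg <- susy_config(segment_seconds = 5, maxlag_seconds = cs[1],
                       rate = cs[2])
    z <- lagged_segment_z(rnorm(100), rnorm(100), cfg)
    expect_length(z$lags, 2 * round(cs[1] * cs[2]) + 1)
    expect_equal(ncol(z$z), 2 * round(cs[1] * cs[2]) + 1)
  }
  # the two printed cases: l = 3 s at 5 Hz -> 31; l = 0 -> 1
  expect_length(lagged_segment_z(rnorm(50), rnorm(50),
                                 susy_config(maxlag_seconds = 3,
                                             rate = 5))$lags, 31)
  expect_length(lagged_segment_z(rnorm(50), rnorm(50),
                                 susy_config(maxlag_seconds = 0,
                                             rate = 5))$lags, 1)
})

test_that("identical series give the clipped Fisher-Z ceiling at lag zero", {
  a <- rnorm(60)
  cfg <- susy_config(segment_seconds = 5, rate = 2)
  z <- lagged_segment_z(a, a, cfg)
  expect_true(all(abs(z$z[, 1] - atanh(1 - 1e-7)) < 1e-6))
  # trailing partial segment is dropped
  expect_equal(nrow(z$z), 6)
})

test_that("independent white noise yields near-zero mean Fisher-Z", {
  set.seed(10)
  t_n <- 5000
  cfg <- susy_config(segment_seconds = 5, rate = 2, n_surrogates = 5)
  z <- lagged_segment_z(rnorm(t_n), rnorm(t_n), cfg)
  n_seg <- nrow(z$z)
  expect_lt(abs(mean(z$z)), 3 / sqrt(n_seg * (10 - 3)))
})

test_that("lagged correlations obey the dyad-swap symmetry", {
  set.seed(11)
  a <- rnorm(100); b <- rnorm(100)
  cfg <- susy_config(segment_seconds = 4, maxlag_seconds = 2, rate = 1)
  zab <- lagged_segment_z(a, b, cfg)
  zba <- lagged_segment_z(b, a, cfg)
  expect_equal(zab$z, zba$z[, rev(seq_along(zab$lags))])
})

test_that("zero-variance overlaps yield z = 0 and are logged", {
  a <- rep(1, 20)
  b <- rnorm(20)
  cfg <- susy_config(segment_seconds = 5, rate = 1)
  z <- lagged_segment_z(a, b, cfg)
  expect_true(all(z$z == 0))
  expect_gt(attr(z, "n_zero_variance"), 0)
})

test_that("circular surrogates preserve the value multiset and are seeded", {
  set.seed(12)
  a <- rnorm(60); b <- rnorm(60)
  cfg <- susy_config(segment_seconds = 5, rate = 1, n_surrogates = 8,
                     seed = 99)
  s1 <- circular_surrogates(a, b, cfg)
  s2 <- circular_surrogates(a, b, cfg)
  expect_identical(s1$z, s2$z)                  # same seed, same draws
  for (off in s1$offsets) {
    rb <- facesync:::rotate_series(b, off)
    expect_identical(sort(rb), sort(b))         # exact multiset equality
    expect_equal(mean(rb), mean(b))
    expect_equal(sd(rb), sd(b))
  }
  expect_true(all(s1$offsets >= 5 & s1$offsets <= 55))
  expect_error(circular_surrogates(rnorm(8), rnorm(8),
                                   susy_config(segment_seconds = 5,
                                               rate = 1)),
               "too short")
})

test_that("the effect size is (mu_real - mu_surrogate) / sigma_surrogate", {
  zr <- matrix(1.5, nrow = 4, ncol = 1)
  zs <- array(0, dim = c(3, 4, 1))
  zs[1, , ] <- -0.5; zs[3, , ] <- 0.5
  # replicate aggregates are -0.5, 0, 0.5: mean 0, sd 0.5 -> ES = 3
  expect_equal(effect_size(zr, zs), 3)
  # equality of means -> 0
  zr0 <- matrix(0, nrow = 4, ncol = 1)
  expect_equal(effect_size(zr0, zs), 0)
  zs_const <- array(1, dim = c(3, 4, 1))
  expect_error(effect_size(zr, zs_const), "undefined")
})

test_that("group analysis covers all dyads deterministically", {
  x <- noise_matrix(5, 60, seed = 21)
  cfg <- susy_config(segment_seconds = 5, rate = 1, n_surrogates = 10,
                     seed = 7)
  res <- susy(x, config = cfg)
  expect_equal(nrow(res$dyads), choose(5, 2))
  res2 <- susy(x, config = cfg)
  expect_identical(res$dyads$es, res2$dyads$es)
  expect_identical(res$z_surrogate, res2$z_surrogate)
  # two subjects: a single dyad
  expect_equal(nrow(susy(x[1:2, ], config = cfg)$dyads), 1)
  # per-dyad real z agrees with the single-dyad operation
  d <- lagged_segment_z(x[2, ], x[4, ], cfg)
  expect_equal(unname(res$z_real[[which(res$dyads$subject_a == "S02" &
                                          res$dyads$subject_b == "S04")]]),
               unname(d$z))
})

test_that("long-format and matrix inputs agree", {
  x <- noise_matrix(3, 40, seed = 31)
  df <- tidyr::pivot_longer(
    dplyr::mutate(tibble::as_tibble(t(x)), time = 0:39),
    -time, names_to = "subject", values_to = "value")
  cfg <- susy_config(segment_seconds = 5, rate = 1, n_surrogates = 5,
                     seed = 3)
  expect_equal(susy(df, config = cfg)$z_real,
               susy(x, config = cfg)$z_real)
})

test_that("summaries have the documented shapes at each level", {
  x <- noise_matrix(4, 60, seed = 41)
  cfg <- susy_config(segment_seconds = 5, rate = 1, n_surrogates = 10,
                     seed = 5)
  res <- susy(x, config = cfg)
  expect_equal(nrow(susy_summarise(res, "grand")), 1)
  expect_equal(nrow(susy_summarise(res, "dyad")), choose(4, 2))
  seg <- susy_summarise(res, "segment")
  expect_equal(nrow(seg), nrow(res$segments))
  expect_equal(seg$t_mid, res$segments$t_mid)
  cond <- susy_summarise(list(calm = res, scary = res), "condition")
  expect_equal(nrow(cond), 2)
  expect_setequal(cond$condition, c("calm", "scary"))
  # grand level on a single dyad is that dyad's aggregate
  res1 <- susy(x[1:2, ], config = cfg)
  g <- susy_summarise(res1, "grand")
  expect_equal(g$mean_z_real, mean(res1$z_real[[1]]))
})

test_that("the paired window test counts pairs over closed-interval intersections", {
  x <- noise_matrix(4, 120, seed = 51)
  cfg <- susy_config(segment_seconds = 5, rate = 1, n_surrogates = 5,
                     seed = 2)
  res <- susy(x, config = cfg)
  # closed window [70, 80] touches segments [70,74], [75,79], [80,84]
  tt <- real_vs_surrogate_test(res, c(70, 80))
  expect_equal(tt$n_pairs, choose(4, 2) * 3 * 1)
  expect_equal(tt$df, tt$n_pairs - 1)
  expect_error(real_vs_surrogate_test(res, c(500, 600)), "no segment")
  # identical real and surrogate values give t = 0
  res0 <- res
  res0$z_surrogate <- lapply(res$z_real, function(m) {
    array(rep(m, each = 2), dim = c(2, nrow(m), ncol(m)))
  })
  t0 <- real_vs_surrogate_test(res0, c(70, 80))
  expect_equal(t0$statistic, 0)
})

test_that("null dyads produce calibrated, centred effect sizes", {
  es <- vapply(1:60, function(s) {
    x <- noise_matrix(2, 120, seed = 6000 + s)
    cfg <- susy_config(segment_seconds = 5, rate = 1, n_surrogates = 40,
                       seed = 7000 + s)
    susy(x, config = cfg)$dyads$es
  }, numeric(1))
  expect_lt(abs(mean(es)), 3 * sd(es) / sqrt(length(es)))
})
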