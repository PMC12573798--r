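# Shot averaging, normalization, phase splitting, nonlinear signal fits and
# transport derivation.

test_that("average_shots pools correctly and is order-invariant", {
  tt <- seq(0, 1, by = 0.1)
  tr1 <- heterodyne_trace(tt, sin(tt))
  # single shot: unchanged, zero sd
  av1 <- average_shots(list(tr1))
  expect_equal(av1$values, tr1$values)
  expect_true(all(av1$per_point_sd == 0))
  # symmetric pair cancels
  tr2 <- heterodyne_trace(tt, -sin(tt))
  expect_true(all(average_shots(list(tr1, tr2))$values == 0))
  # permutation invariance
  set.seed(2)
  shots <- lapply(1:5, function(k) heterodyne_trace(tt, stats::rnorm(11)))
  a <- average_shots(shots)
  b <- average_shots(rev(shots))
  expect_identical(a$values, b$values)
  expect_identical(a$per_point_sd, b$per_point_sd)
  # mismatched grids rejected
  expect_error(average_shots(list(tr1, heterodyne_trace(tt + 1, sin(tt)))),
               "identical time grid")
})

test_that("3000-shot averages have the law-of-large-numbers standard error", {
  cfg <- quick_config(noise_sd = 0.05, n_shots = 3000, seed = 3,
                      t_on = 0.02, t_off = 0.01)
  shots <- simulate_shot_set(cfg)
  av <- average_shots(shots)
  expect_equal(mean(av$per_point_sd), 0.05 / sqrt(3000), tolerance = 0.1)
  # noise realism: per-point sd across shots matches the generator sd
  vals <- sapply(shots, function(s) s$values)
  expect_equal(mean(apply(vals, 1, stats::sd)), 0.05, tolerance = 0.05)
})

test_that("normalization is idempotent, scale-invariant and accurate under noise", {
  cfg <- quick_config()
  tr <- simulate_averaged_trace(cfg)
  trn <- normalize_trace(tr)
  expect_lt(max(abs(trn$values - tr$values)), 1e-9)   # already normalized
  # scale invariance
  tr_scaled <- tr
  tr_scaled$values <- 3.7 * tr$values
  trs <- normalize_trace(tr_scaled)
  expect_lt(max(abs(trs$values - trn$values)), 1e-9)
  # noisy plateau estimate within 1%
  cfg_n <- quick_config(noise_sd = 0.01, n_shots = 1, seed = 5)
  trn2 <- normalize_trace(simulate_averaged_trace(cfg_n))
  expect_equal(trn2$meta$normalization_scale, 1, tolerance = 0.01)
  # degenerate: a flat-zero trace has no thermal plateau
  flat <- heterodyne_trace(seq(0, 1, 1e-3), rep(0, 1001))
  expect_error(normalize_trace(flat), "degenerate")
})

test_that("phase splitting conserves samples and re-zeroes the off phase", {
  tt <- seq(0, 1, by = 0.01)
  tr <- heterodyne_trace(tt, seq_along(tt) * 1.0)
  sp <- split_phases(tr, 0.5)
  expect_equal(length(sp$on$times) + length(sp$off$times), length(tt))
  expect_true(all(sp$on$times < 0.5))
  expect_equal(sp$off$times[1], 0)
  # split at the first interior point leaves a one-point prefix
  sp2 <- split_phases(tr, tt[2])
  expect_equal(sp2$on$times, tt[1])
  expect_error(split_phases(tr, 2), "inside the time span")
  expect_error(split_phases(tr, 0), "inside the time span")
})

test_that("noiseless signals are recovered to high precision in both phases", {
  cfg <- quick_config()
  truth <- c(1e-3, 0.03, 0.6)
  tr <- simulate_averaged_trace(cfg)
  sp <- split_phases(tr, cfg$t_on)
  for (phase in c("on", "off")) {
    f <- fit_signal(sp[[phase]], phase)
    expect_true(f$converged)
    expect_rel_equal(coef(f), truth, 1e-4)
    expect_lt(f$residual_rms, 1e-8)
  }
})

test_that("a null concentration mode is not hallucinated", {
  cfg <- quick_config(A0 = 0, noise_sd = 0.01, n_shots = 3000, seed = 9)
  tr <- simulate_averaged_trace(cfg)
  sp <- split_phases(tr, cfg$t_on)
  f <- fit_signal(sp$on, "on")
  expect_lt(abs(coef(f)[["A0"]]), 3 * sqrt(vcov(f)["A0", "A0"]))
  tc <- derive_transport(f, std_geometry(), std_contrast(), std_cw)
  # S_T consistent with zero at the same resolution
  expect_lt(abs(tc$S_T),
            3 * abs(amplitude_to_soret(sqrt(vcov(f)["A0", "A0"]),
                                       std_contrast(), std_cw)))
})

test_that("estimator bias vanishes as the noise level decreases", {
  truth <- c(1e-3, 0.03, 0.6)
  sds <- c(0.05, 0.01, 0.002)
  bias <- matrix(NA_real_, length(sds), 3)
  for (i in seq_along(sds)) {
    est <- matrix(NA_real_, 50, 3)
    for (s in 1:50) {
      cfg <- quick_config(noise_sd = sds[i], n_shots = 50,
                          seed = 1000 * i + s)
      tr <- simulate_averaged_trace(cfg)
      f <- fit_signal(split_phases(tr, cfg$t_on)$on, "on")
      est[s, ] <- coef(f)
    }
    bias[i, ] <- colMeans(est) - truth
  }
  rel_bias <- abs(bias) / matrix(truth, length(sds), 3, byrow = TRUE)
  for (j in 1:3) {
    expect_true(all(diff(rel_bias[, j]) <= 0) ||
                  rel_bias[1, j] > rel_bias[3, j])
    expect_lt(rel_bias[3, j], 0.01)
  }
})

test_that("on- and off-phase Soret estimates agree within joint uncertainty", {
  ok <- 0
  n_rep <- 20
  conv <- function(se_A0) abs(amplitude_to_soret(se_A0, std_contrast(),
                                                 std_cw))
  for (s in 1:n_rep) {
    cfg <- quick_config(noise_sd = 0.01, n_shots = 3000, seed = 400 + s)
    tr <- simulate_averaged_trace(cfg)
    sp <- split_phases(tr, cfg$t_on)
    f_on <- fit_signal(sp$on, "on")
    f_off <- fit_signal(sp$off, "off")
    st_on <- amplitude_to_soret(coef(f_on)[["A0"]], std_contrast(), std_cw)
    st_off <- amplitude_to_soret(coef(f_off)[["A0"]], std_contrast(), std_cw)
    se <- sqrt(conv(sqrt(vcov(f_on)["A0", "A0"]))^2 +
               conv(sqrt(vcov(f_off)["A0", "A0"]))^2)
    if (abs(st_on - st_off) < 2 * se) ok <- ok + 1
  }
  expect_gte(ok, 0.9 * n_rep)
})

test_that("transport coefficients round-trip through simulate and fit", {
  g <- std_geometry(); ctr <- std_contrast()
  cfg <- quick_config()
  truth_D <- 1 / (0.03 * g$q^2)
  truth_Dth <- 1 / (1e-3 * g$q^2)
  truth_ST <- amplitude_to_soret(0.6, ctr, std_cw)
  tr <- simulate_averaged_trace(cfg)
  f <- fit_signal(split_phases(tr, cfg$t_on)$on, "on")
  tc <- derive_transport(f, g, ctr, std_cw)
  expect_rel_equal(c(tc$D, tc$D_th, tc$S_T),
                   c(truth_D, truth_Dth, truth_ST), 1e-3)
  expect_equal(tc$D_T, tc$S_T * tc$D)
})

test_that("fit_signal validates its inputs", {
  tr <- heterodyne_trace(seq(0, 1, length.out = 10), rep(0.5, 10))
  expect_error(fit_signal(tr, "on"), "at least 30 samples")
})

test_that("pooling returns the mean with its standard error", {
  p1 <- pool_estimates(2.5)
  expect_equal(p1$mean, 2.5)
  expect_identical(p1$sem, 0)
  expect_identical(p1$n, 1L)
  p2 <- pool_estimates(c(1, 1, 1, 1))
  expect_equal(p2$mean, 1)
  expect_identical(p2$sem, 0)
  p3 <- pool_estimates(c(1, 2, 3, 4))
  expect_equal(p3$mean, 2.5)
  expect_equal(p3$sem, 0.6454972, tolerance = 1e-6)
})
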