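test_that("cross-correlation peak and lag behave on constructed series", {
  # exact anti-phase
  set.seed(3)
  x <- cumsum(rnorm(400))
  out <- xcorr_peak_lag(-x, x, dt = 0.01)
  expect_equal(out$r_peak, -1)
  expect_equal(out$lag_s, 0)

  # shifted, sign-flipped sinusoid: peak -1 at +0.1 s (hand lags cursor)
  tt <- seq(0, 6, by = 0.01)
  out <- xcorr_peak_lag(-sin(2 * pi * (tt - 0.1)), sin(2 * pi * tt), dt = 0.01)
  expect_equal(out$r_peak, -1, tolerance = 1e-6)
  expect_equal(out$lag_s, 0.1)

  # agrees with the brute-force per-lag Pearson oracle
  for (i in 1:10) {
    h <- cumsum(rnorm(300))
    cu <- cumsum(rnorm(300))
    got <- xcorr_peak_lag(h, cu, dt = 0.01)
    ora <- brute_xcorr(h, cu, dt = 0.01)
    expect_equal(got$r_peak, unname(ora["r"]), tolerance = 1e-9)
    expect_equal(got$lag_s, unname(ora["lag"]), tolerance = 1e-12)
  }

  expect_error(xcorr_peak_lag(rep(1, 100), rnorm(100), dt = 0.01),
               class = "cst_degenerate")
  expect_error(xcorr_peak_lag(rnorm(5), rnorm(6), dt = 0.01),
               class = "cst_bad_input")
})

test_that("white-noise series show no spurious peak correlation", {
  set.seed(11)
  h <- rnorm(600)
  cu <- rnorm(600)
  obs <- abs(xcorr_peak_lag(h, cu, dt = 0.01)$r_peak)
  null <- replicate(200, abs(xcorr_peak_lag(sample(h), cu, dt = 0.01)$r_peak))
  expect_lt(obs, quantile(null, 0.99) * 1.25)
})

test_that("RMS ratio matches its direct formula", {
  tt <- seq(0, 6, 0.01)
  mk <- function(x, p) tibble::tibble(t = tt, x = x, p = p)
  expect_equal(rms_ratio(mk(sin(tt), 2 * sin(tt))), 2)
  expect_equal(rms_ratio(mk(sin(tt), sin(tt))), 1)
  set.seed(4)
  x <- rnorm(length(tt), 1)
  p <- rnorm(length(tt), -2)
  expect_equal(rms_ratio(mk(x, p)), sqrt(mean(p^2)) / sqrt(mean(x^2)))
  expect_error(rms_ratio(mk(rep(0, length(tt)), sin(tt))),
               class = "cst_degenerate")
})

test_that("success binning uses half-open 0.3-wide bins from 1.5", {
  mk <- function(lam, success) tibble::tibble(lam = lam, success = success)
  tb <- bin_success_rate(mk(c(1.6, 1.6, 1.9), c(TRUE, TRUE, TRUE)))
  expect_equal(tb$bin_center, c(1.65, 1.95))
  expect_equal(tb$rate, c(100, 100))
  tb <- bin_success_rate(mk(rep(1.6, 4), c(TRUE, TRUE, TRUE, FALSE)))
  expect_equal(tb$rate, 75)
  expect_equal(tb$n, 4)
  # bin edges: 1.8 belongs to the second bin
  tb <- bin_success_rate(mk(c(1.7, 1.8), c(TRUE, FALSE)))
  expect_equal(tb$bin_center, c(1.65, 1.95))
  expect_error(bin_success_rate(mk(numeric(), logical())),
               class = "cst_bad_input")
})

test_that("psychometric fit recovers noiseless parameters exactly", {
  lam <- seq(1.65, 6.75, by = 0.3)
  rate <- 100 * (1 - pnorm((lam - 4) / 0.5))
  tb <- tibble::tibble(bin_center = lam, rate = rate, n = 200)
  fit <- fit_psychometric(tb)
  expect_equal(fit$lam_c, 4, tolerance = 1e-8)
  expect_equal(fit$sigma, 0.5, tolerance = 1e-8)
  expect_equal(predict(fit, fit$lam_c), 50)
  expect_equal(tidy(fit)$estimate, c(4, 0.5), tolerance = 1e-8)
  expect_equal(glance(fit)$n_bins, length(lam))

  flat <- tibble::tibble(bin_center = lam, rate = 100, n = 200)
  expect_error(fit_psychometric(flat), class = "cst_degenerate")
  zero <- tibble::tibble(bin_center = lam, rate = 0, n = 200)
  expect_error(fit_psychometric(zero), class = "cst_degenerate")
  expect_error(fit_psychometric(tb[1:2, ]), class = "cst_degenerate")
})

test_that("trial summary reproduces closed-form values", {
  tt <- seq(0, 6, by = 0.01)
  d <- tibble::tibble(t = tt, x = rep(2, length(tt)), xdot = 0,
                      p = sin(tt))
  s <- trial_summary(d)
  expect_equal(s$mean_x, 2)
  expect_equal(s$mean_xdot, 0)
  expect_equal(s$rms_x, 2)
  expect_equal(s$rms_xdot, 0)
  expect_true(is.na(s$r_peak))   # constant cursor: correlation undefined

  # sinusoid over whole periods
  tt6 <- seq(0, 6 - 0.01, by = 0.01)
  d2 <- tibble::tibble(t = tt6, x = sin(2 * pi * tt6),
                       xdot = 2 * pi * cos(2 * pi * tt6), p = -sin(2 * pi * tt6))
  s2 <- trial_summary(d2)
  expect_equal(s2$mean_x, 0, tolerance = 1e-10)
  expect_equal(s2$rms_x, 1 / sqrt(2), tolerance = 1e-3)
  expect_equal(s2$rms_ratio, 1, tolerance = 1e-12)
  expect_equal(s2$r_peak, -1, tolerance = 1e-9)
})

test_that("mean-state correlation and RMS slope behave on constructed clouds", {
  f <- tibble::tibble(lam = rep(2, 10), success = TRUE,
                      mean_x = 1:10, mean_xdot = 2 * (1:10) + 3,
                      rms_x = 1:10, rms_xdot = 3 * (1:10))
  expect_equal(meanstate_correlation(f, lam_max = 5)$r, 1)
  sl <- rms_slope(f, lam_max = 5)
  expect_equal(sl$slope, 3)
  expect_equal(sl$intercept, 0, tolerance = 1e-12)
  expect_equal(rms_slope(f, lam_max = 5, through_origin = TRUE)$slope, 3)

  set.seed(8)
  iso <- tibble::tibble(lam = rep(2, 500), success = TRUE,
                        mean_x = rnorm(500), mean_xdot = rnorm(500),
                        rms_x = abs(rnorm(500)), rms_xdot = abs(rnorm(500)))
  expect_lt(abs(meanstate_correlation(iso, lam_max = 5)$r), 0.1)

  expect_error(meanstate_correlation(f[1:2, ], lam_max = 5),
               class = "cst_degenerate")
  degen <- tibble::tibble(lam = rep(2, 5), success = TRUE,
                          mean_x = 1:5, mean_xdot = 1:5,
                          rms_x = rep(1, 5), rms_xdot = 1:5)
  expect_error(rms_slope(degen, lam_max = 5), class = "cst_degenerate")
})

test_that("metrics are pure and invariant to a joint sign flip", {
  set.seed(12)
  tt <- seq(0, 6, 0.01)
  x <- cumsum(rnorm(length(tt), 0, 0.1))
  p <- -x + rnorm(length(tt), 0, 0.05)
  d <- tibble::tibble(t = tt, x = x, xdot = c(diff(x), 0) / 0.01, p = p)
  dflip <- dplyr::mutate(d, x = -x, xdot = -xdot, p = -p)
  s1 <- trial_summary(d)
  s2 <- trial_summary(dflip)
  expect_equal(s2$r_peak, s1$r_peak)
  expect_equal(s2$lag_s, s1$lag_s)
  expect_equal(s2$rms_ratio, s1$rms_ratio)
  expect_equal(s2$rms_x, s1$rms_x)
  expect_identical(trial_summary(d), trial_summary(d))
})

test_that("feature tables carry trial metadata and feed the aggregate curves", {
  set <- default_batch("position", c(2, 4), 20, 31)
  f <- trial_features(set)
  expect_equal(nrow(f), nrow(set))
  expect_true(all(c("trial_id", "lam", "objective", "success", "r_peak",
                    "lag_s", "rms_ratio", "rms_x", "rms_xdot") %in% names(f)))
  expect_true(all(f$rms_x >= abs(f$mean_x) - 1e-12))
  expect_true(all(abs(f$r_peak) <= 1, na.rm = TRUE))
  cur <- metric_curves(f)
  expect_true(all(cur$n > 0))
  expect_true(all(cur$success_pct >= 0 & cur$success_pct <= 100))
})
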