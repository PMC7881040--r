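test_that("linear detrending removes exactly the fitted trend", {
  expect_equal(linear_detrend(2 * (1:10) + 3), rep(0, 10), tolerance = 1e-12)
  x <- c(1, 2, 3, 2, 1)            # symmetric, hence zero OLS slope
  expect_equal(linear_detrend(x + 9), x - mean(x), tolerance = 1e-12)
  set.seed(1)
  r <- linear_detrend(stats::rnorm(40))
  expect_lt(abs(linear_trend(r)), 1e-12)
  expect_lt(abs(mean(r)), 1e-12)
  expect_error(linear_detrend(c(1, 2)), "at least 3")
})

test_that("partial correlation reduces to Pearson without controls and saturates at identity", {
  set.seed(2)
  y <- stats::rnorm(30); x <- stats::rnorm(30)
  pc <- partial_correlation(y, x)
  expect_equal(pc$estimate, cor(y, x), tolerance = 1e-12)
  expect_equal(pc$p_value, cor.test(y, x)$p.value, tolerance = 1e-10)

  z <- stats::rnorm(30)
  expect_equal(partial_correlation(y, y, cbind(z))$estimate, 1)
})

test_that("residual-regression and precision-matrix implementations agree with each other and an oracle", {
  set.seed(3)
  for (k in 0:4) {
    y <- stats::rnorm(50)
    x <- stats::rnorm(50)
    C <- if (k > 0) matrix(stats::rnorm(50 * k), 50) else NULL
    a <- partial_correlation(y, x, C, method = "residual")$estimate
    b <- partial_correlation(y, x, C, method = "precision")$estimate
    expect_equal(a, b, tolerance = 1e-10)
    if (k > 0) expect_equal(a, pcor_matrix_oracle(y, x, C), tolerance = 1e-10)
  }
})

test_that("partial correlation is symmetric in its two arguments", {
  set.seed(4)
  for (i in 1:10) {
    y <- stats::rnorm(25); x <- stats::rnorm(25)
    C <- matrix(stats::rnorm(50), 25)
    expect_equal(partial_correlation(y, x, C)$estimate,
                 partial_correlation(x, y, C)$estimate, tolerance = 1e-12)
  }
})

test_that("degenerate inputs are flagged undefined, not fabricated", {
  y <- stats::rnorm(20)
  pc <- partial_correlation(y, rep(1, 20))
  expect_true(pc$undefined)
  expect_true(is.na(pc$estimate))
  expect_error(partial_correlation(stats::rnorm(5), stats::rnorm(5),
                                   matrix(stats::rnorm(20), 5)),
               "too small")
})

test_that("the seasonal carryover profile recovers a designed EGS-to-PGS link", {
  fld <- simulate_carryover_pair(n_cells = 60, n_years = 35, gamma = 0.6,
                                 noise_sd = 1, seed = 9)
  prof <- seasonal_vgc_profile(fld, "PGS")
  co <- prof[prof$role == "carryover", ]
  expect_gt(mean(co$r_p > 0), 0.95)
  # carryover is the strongest driver in nearly every cell
  by_cell <- split(prof, prof$cell_id)
  strongest <- vapply(by_cell, function(d) {
    d$role[which.max(abs(d$r_p))]
  }, character(1))
  expect_gt(mean(strongest == "carryover"), 0.9)
})

test_that("a driver duplicating the target saturates and leaves the rest undefined", {
  fld <- simulate_carryover_pair(n_cells = 1, n_years = 30, gamma = 0.3,
                                 seed = 10)
  # overwrite PGS temperature with the PGS vegetation series
  y <- fld$value[fld$variable == "NDVI" & fld$season == "PGS"]
  fld$value[fld$variable == "TMP" & fld$season == "PGS"] <- y
  prof <- seasonal_vgc_profile(fld, "PGS")
  expect_equal(prof$r_p[prof$role == "concurrent_tmp"], 1, tolerance = 1e-8)
  expect_true(all(prof$undefined[prof$role != "concurrent_tmp"]))
})

test_that("the EGS profile chains vegetation to the previous LGS and climate to the dormancy season", {
  cfg <- seasonal_system_config(
    n_cells = 60, n_years = 35,
    gamma = c(lgs_egs = 0.6, egs_pgs = 0, pgs_lgs = 0),
    beta_t = 0, beta_p = 0, beta_t_ps = 0, beta_p_ps = 0,
    noise_sd = 1, tmp_trend_decade = 0, seed = 11)
  fld <- simulate_seasonal_system(cfg)
  prof <- seasonal_vgc_profile(fld, "EGS")
  co <- prof[prof$role == "carryover", ]
  expect_gt(mean(co$r_p > 0), 0.95)
  expect_true(all(co$n == 34))   # first year has no preceding LGS
})

test_that("residual analysis recovers an injected previous-year legacy and reports explained variance", {
  set.seed(12)
  n <- 35
  fld <- simulate_carryover_pair(n_cells = 1, n_years = n, gamma = 0,
                                 seed = 12)
  prev_lgs_pre <- fld$value[fld$variable == "PRE" & fld$season == "LGS"]
  eps <- c(NA, prev_lgs_pre[-n]) + stats::rnorm(n, 0, 1)   # legacy + noise
  out <- residual_driver_correlation(eps, years = 1:n, fld, "PGS")
  expect_setequal(out$driver,
                  c("TMP_DS", "PRE_DS", "NDVI_LGS_py", "TMP_LGS_py",
                    "PRE_LGS_py", "NDVI_PGS_py", "TMP_PGS_py", "PRE_PGS_py"))
  expect_equal(out$driver[which.max(abs(out$r_p))], "PRE_LGS_py")
  expect_gt(attr(out, "r_squared"), 0.9)

  # near-deterministic residual: correlation saturates
  eps2 <- c(NA, prev_lgs_pre[-n]) + stats::rnorm(n, 0, 1e-4)
  out2 <- residual_driver_correlation(eps2, 1:n, fld, "PGS")
  expect_gt(out2$r_p[out2$driver == "PRE_LGS_py"], 0.999)
  expect_gt(attr(out2, "r_squared"), 0.999)
})

test_that("lagged partial autocorrelation isolates persistence at the correct lead", {
  # near-unit persistence
  set.seed(13)
  y <- as.vector(simulate_annual_ar(0.97, 60, seed = 13))
  pac <- lagged_pacf(y, max_lead = 1)
  expect_gt(pac$coefficient[1], 0.6)   # finite-sample bias pulls it below phi
  expect_lt(pac$p_value[1], 1e-6)

  # AR(1): lead-1 near phi, higher leads near zero (median over replicates)
  reps <- vapply(1:60, function(i) {
    y <- as.vector(simulate_annual_ar(0.4, 100, seed = 100 + i))
    clim <- matrix(stats::rnorm(200), 100, 2,
                   dimnames = list(NULL, c("TMP", "PRE")))
    lagged_pacf(y, clim, max_lead = 3)$coefficient
  }, numeric(3))
  expect_equal(median(reps[1, ]), 0.4, tolerance = 0.07)
  expect_lt(abs(median(reps[2, ])), 0.07)
  expect_lt(abs(median(reps[3, ])), 0.07)
})

test_that("lagged analysis enforces its sample-size requirements", {
  expect_error(lagged_pacf(stats::rnorm(10)), "at least 15")
  y <- stats::rnorm(16)
  clim <- matrix(stats::rnorm(16 * 6), 16)
  expect_error(lagged_pacf(y, clim, max_lead = 3), "controls")
})

test_that("sign/significance summaries count exactly", {
  res <- data.frame(r_p = c(rep(0.5, 7), rep(-0.2, 3)),
                    p_value = c(rep(0.01, 3), rep(0.5, 7)))
  s <- sign_frequency_summary(res)
  expect_equal(s$pct_positive, 70)
  expect_equal(s$pct_negative, 30)
  expect_equal(s$pct_sig_positive, 30)
  expect_equal(s$pct_sig_negative, 0)

  res$grp <- rep(c("a", "b"), 5)
  s2 <- sign_frequency_summary(res, group = "grp")
  expect_equal(nrow(s2), 2)
  expect_equal(sum(s2$n), 10)

  # undefined entries are excluded from percentages but counted
  res$r_p[1] <- NA
  s3 <- sign_frequency_summary(res)
  expect_equal(s3$n, 9)
  expect_equal(s3$n_undefined, 1)
})
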