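test_that("the linear trend operator matches hand values and simulation", {
  expect_equal(linear_trend(c(1, 2, 3), year = c(1, 2, 3)), 1.0)
  expect_equal(linear_trend(rep(4, 10)), 0.0)
  expect_error(linear_trend(c(1, 2, 3), year = rep(2000, 3)), "constant")

  set.seed(14)
  slopes <- vapply(1:1000, function(i) {
    linear_trend(0.0012 * (1:35) + stats::rnorm(35, 0, 0.02))
  }, numeric(1))
  expect_lt(abs(mean(slopes) - 0.0012), 4 * sd(slopes) / sqrt(1000))
  det <- linear_trend(0.0012 * (1:35) + stats::rnorm(35, 0, 1e-4),
                      details = TRUE)
  expect_equal(det$slope, 0.0012, tolerance = 0.01)
  expect_lt(det$p_value, 1e-10)
})

make_drivers <- function(n, seed = 15) {
  set.seed(seed)
  cbind(Y_ps = stats::rnorm(n), TMP_ps = stats::rnorm(n),
        PRE_ps = stats::rnorm(n), TMP = stats::rnorm(n),
        PRE = stats::rnorm(n))
}

test_that("sensitivities identify a noiseless linear system exactly and flag rank deficiency", {
  X <- make_drivers(20)
  y <- 0.5 * X[, "Y_ps"] + 0.01 * X[, "TMP"] + 2
  fit <- fit_sensitivities(y, X)
  expect_equal(unname(fit$beta),
               c(0.5, 0, 0, 0.01, 0), tolerance = 1e-10)
  expect_equal(fit$intercept, 2, tolerance = 1e-10)

  Xdup <- X
  Xdup[, "PRE"] <- Xdup[, "TMP"]
  expect_false(fit_sensitivities(y, Xdup)$rank_ok)
})

test_that("with orthogonal drivers the joint coefficients equal single-regression slopes", {
  n <- 16
  base <- stats::contr.helmert(n)[, 1:5]    # mutually orthogonal columns
  X <- base
  colnames(X) <- c("Y_ps", "TMP_ps", "PRE_ps", "TMP", "PRE")
  set.seed(16)
  y <- stats::rnorm(n)
  fit <- fit_sensitivities(y, X)
  for (v in colnames(X)) {
    single <- coef(lm(y ~ X[, v]))[2]
    expect_equal(unname(fit$beta[v]), unname(single), tolerance = 1e-10)
  }
})

test_that("trend decomposition reproduces designed contributions and closes exactly", {
  n <- 35
  yr <- seq_len(n)
  set.seed(17)
  # y is exactly TMP; TMP trends at 0.03 per year
  X <- make_drivers(n, seed = 17)
  X[, "TMP"] <- 0.03 * yr + stats::rnorm(n, 0, 0.1)
  y <- X[, "TMP"]
  dec <- decompose_trend(y, X, year = yr)
  expect_equal(unname(dec$delta["TMP"]), linear_trend(X[, "TMP"], yr),
               tolerance = 1e-10)
  expect_equal(unname(dec$delta[c("Y_ps", "TMP_ps", "PRE_ps", "PRE")]),
               rep(0, 4), tolerance = 1e-10)
  expect_equal(dec$residual_trend, 0, tolerance = 1e-10)

  # trending noise with trendless drivers ends up entirely in the residual
  X0 <- make_drivers(n, seed = 18)
  X0 <- apply(X0, 2, linear_detrend)
  colnames(X0) <- colnames(X)
  y2 <- 0.002 * yr + stats::rnorm(n, 0, 0.01)
  dec2 <- decompose_trend(y2, X0, year = yr)
  expect_equal(sum(abs(dec2$delta)), 0, tolerance = 1e-3)
  expect_equal(dec2$residual_trend, dec2$total_trend, tolerance = 1e-3)
})

test_that("contributions equal sensitivity-times-trend products from an independent computation", {
  set.seed(19)
  n <- 35
  X <- make_drivers(n, seed = 19) + outer(1:n, c(0.01, 0.02, 0, -0.01, 0.005))
  y <- 0.4 * X[, "Y_ps"] + 0.3 * X[, "TMP"] - 0.2 * X[, "PRE_ps"] +
    stats::rnorm(n, 0, 0.2)
  dec <- decompose_trend(y, X)
  beta_oracle <- coef(lm(y ~ X))[-1]
  for (i in seq_len(5)) {
    trend_oracle <- unname(coef(lm(X[, i] ~ seq_len(n)))[2])
    expect_equal(unname(dec$delta[i]),
                 unname(beta_oracle[i]) * trend_oracle, tolerance = 1e-10)
  }
  # residual trend computed two ways: closure remainder and OLS-residual trend
  fit <- fit_sensitivities(y, X)
  expect_equal(dec$residual_trend, linear_trend(fit$residuals),
               tolerance = 1e-10)
})

test_that("the decomposition identity holds to machine precision on every synthetic cell", {
  fld <- simulate_seasonal_system(seasonal_system_config(
    n_cells = 40, n_years = 35, seed = 20))
  res <- attribute_seasonal_trends(fld, "PGS")
  expect_equal(nrow(res), 40)
  expect_lt(max(abs(res$closure_error)), 1e-12)
  expect_equal(res$carryover + res$clm_ps + res$clm + res$residual_trend,
               res$total_trend, tolerance = 1e-12)
})

test_that("the decomposition is scale equivariant", {
  set.seed(21)
  n <- 35
  X <- make_drivers(n, seed = 21) + outer(1:n, rep(0.01, 5))
  y <- 0.3 * X[, "Y_ps"] + stats::rnorm(n, 0, 0.1)
  d1 <- decompose_trend(y, X)
  d10 <- decompose_trend(10 * y, X)
  expect_equal(10 * d1$delta["Y_ps"], d10$delta["Y_ps"], tolerance = 1e-10)
  expect_equal(10 * d1$residual_trend, d10$residual_trend, tolerance = 1e-10)
  expect_equal(10 * d1$total_trend, d10$total_trend, tolerance = 1e-10)
})

test_that("hemispheric summaries weight cells and report signed shares", {
  cells <- data.frame(cell_id = c("a", "b"), season = "PGS",
                      carryover = c(0.4, 0.2), clm_ps = c(0.1, -0.1),
                      clm = c(0.5, 0.7), residual_trend = c(0, 0.2),
                      total_trend = c(1.0, 1.0), closure_error = 0, n = 35)
  s_one <- summarize_contributions(cells[1, ])
  expect_equal(unname(s_one$shares["carryover"]), 40)
  s_two <- summarize_contributions(cells)
  expect_equal(unname(s_two$contributions["carryover"]), 0.3)
  w <- data.frame(cell_id = c("a", "b"), weight = c(3, 1))
  s_w <- summarize_contributions(cells, w)
  expect_equal(unname(s_w$contributions["carryover"]), 0.35)

  cells0 <- within(cells, {
    total_trend <- 0; residual_trend <- -(carryover + clm_ps + clm)
  })
  s0 <- summarize_contributions(cells0)
  expect_true(all(is.na(s0$shares)))
  expect_false(anyNA(s0$contributions))
})

test_that("designed hemispheric share is recovered on a synthetic hemisphere", {
  # concurrent temperature built to supply ~75% of the EGS trend
  cfg <- seasonal_system_config(
    n_cells = 150, n_years = 35,
    gamma = c(lgs_egs = 0, egs_pgs = 0, pgs_lgs = 0),
    beta_t = 0.02, beta_p = 0, beta_t_ps = 0, beta_p_ps = 0,
    tmp_sd = 0.8, noise_sd = 0.01, tmp_trend_decade = 0.3, seed = 22)
  fld <- simulate_seasonal_system(cfg)
  # add an independent trend component so temperature is 75% of the total:
  # temperature contributes 0.02 * 0.03 = 6e-4; add 2e-4 via the noise term
  extra <- 2e-4
  sel <- fld$variable == "NDVI" & fld$season == "EGS"
  fld$value[sel] <- fld$value[sel] + extra * fld$year[sel]
  res <- attribute_seasonal_trends(fld, "EGS")
  s <- summarize_contributions(res)
  expect_equal(unname(s$shares["clm"]), 75, tolerance = 8)
})
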