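test_that("the climatological cycle is the per-period multi-year mean", {
  bw2 <- data.frame(cell_id = "c1",
                    year = rep(1:2, each = 24), period = rep(1:24, 2),
                    value = c(sin(1:24), sin(1:24) + 2))
  expect_equal(climatological_cycle(bw2), sin(1:24) + 1)

  sim <- simulate_biweekly_ndvi(pheno_curve_params(anomaly_sd = 0.03),
                                n_years = 35, seed = 8)
  cyc <- climatological_cycle(sim$biweekly)
  oracle <- vapply(1:24, function(p) {
    mean(sim$biweekly$value[sim$biweekly$period == p])
  }, numeric(1))
  expect_equal(cyc, oracle, tolerance = 1e-12)
})

test_that("cycle construction reports unusable composite periods", {
  bw <- data.frame(cell_id = "c1", year = rep(1:3, each = 24),
                   period = rep(1:24, 3), value = 0.3)
  bw$value[bw$period == 7] <- NA
  expect_error(climatological_cycle(bw), "7.*missing in all years")
  bw$value[bw$period == 7 & bw$year == 1] <- 0.2  # only one year left
  expect_error(climatological_cycle(bw), "fewer than 2 years")
})

test_that("SOS/EOS detection recovers the slope extrema of noise-free curves within half a composite", {
  cases <- list(pheno_curve_params(),
                pheno_curve_params(sos_mid = 110, eos_mid = 290,
                                   sos_rate = 0.06, eos_rate = 0.12),
                pheno_curve_params(baseline = 0.05, amplitude = 0.7))
  for (p in cases) {
    sim <- simulate_biweekly_ndvi(p, n_years = 3, seed = 1)
    cyc <- climatological_cycle(sim$biweekly)
    det <- detect_sos_eos(cyc)
    expect_true(det$detectable)
    expect_lt(abs(det$sos_doy - sim$truth$sos_doy), 8)
    expect_lt(abs(det$eos_doy - sim$truth$eos_doy), 8)
  }
})

test_that("SOS/EOS detection is translation invariant, flags flat cycles, and swaps roles under time reversal", {
  p <- pheno_curve_params()
  cyc <- climatological_cycle(
    simulate_biweekly_ndvi(p, n_years = 2, seed = 2)$biweekly)
  d1 <- detect_sos_eos(cyc)
  d2 <- detect_sos_eos(cyc + 0.3)
  expect_identical(d1[c("sos_doy", "eos_doy")], d2[c("sos_doy", "eos_doy")])

  expect_false(detect_sos_eos(rep(0.2, 24))$detectable)

  dr <- detect_sos_eos(rev(cyc))
  # mirrored cycle: fastest green-up maps onto the mirrored senescence day
  expect_lt(abs(dr$sos_doy - (366 - d1$eos_doy)), 16)
  expect_lt(abs(dr$eos_doy - (366 - d1$sos_doy)), 16)
})

test_that("season windows follow the peak-season rules and exclusions", {
  # worked example: SOS in May, EOS in September, best pair July-August
  mcyc <- c(0.05, 0.05, 0.08, 0.15, 0.30, 0.50, 0.65, 0.60, 0.35, 0.15,
            0.08, 0.05)
  w <- define_seasons(sos_doy = 130, eos_doy = 260, mcyc)
  expect_equal(w$months$EGS, 5:6)
  expect_equal(w$months$PGS, 7:8)
  expect_equal(w$months$LGS, 9L)
  expect_setequal(w$months$DS, c(10:12, 1:4))

  # maximum in March -> excluded
  mcyc_mar <- c(0.1, 0.3, 0.6, 0.3, 0.2, 0.15, 0.12, 0.12, 0.1, 0.1, 0.1, 0.1)
  ex <- define_seasons(100, 250, mcyc_mar)
  expect_s3_class(ex, "season_exclusion")
  expect_equal(ex$reason, "peak-outside-apr-oct")

  # non-vegetated cell
  ex2 <- define_seasons(130, 260, rep(0.05, 12))
  expect_equal(ex2$reason, "non-vegetated")

  # growing season of 3 months (Jun-Aug): single-month peak season
  mshort <- c(0.02, 0.02, 0.02, 0.02, 0.02, 0.2, 0.5, 0.25, 0.05, 0.02,
              0.02, 0.02)
  ws <- define_seasons(sos_doy = 160, eos_doy = 235, mshort)
  expect_length(ws$months$PGS, 1)
  expect_equal(ws$months$PGS, 7L)
})

test_that("season windows always partition the twelve months in EGS<PGS<LGS order", {
  set.seed(21)
  for (i in 1:20) {
    p <- pheno_curve_params(sos_mid = stats::runif(1, 100, 150),
                            eos_mid = stats::runif(1, 250, 300),
                            sos_rate = stats::runif(1, 0.05, 0.15),
                            eos_rate = stats::runif(1, 0.05, 0.15))
    sim <- simulate_biweekly_ndvi(p, n_years = 4, seed = i)
    ws <- delineate_seasons(sim$biweekly)[[1]]
    expect_s3_class(ws, "season_windows")      # validity asserts partition
    expect_true(max(ws$months$EGS) < min(ws$months$PGS))
    expect_true(max(ws$months$PGS) < min(ws$months$LGS))
  }
})

test_that("second-derivative phenology matches the logistic closed form", {
  # logistic green-up: maximum curvature at m - ln(2 + sqrt(3)) / r
  r <- 0.1; m <- 120
  d <- 1:365
  gpp <- 10 / (1 + exp(-r * (d - m)))
  det <- detect_sos_eos_gpp(gpp, spar = 0.4)
  expect_lt(abs(det$sos_doy - (m - log(2 + sqrt(3)) / r)), 3)

  expect_false(detect_sos_eos_gpp(rep(5, 365))$detectable)

  gpp_miss <- gpp
  gpp_miss[sample.int(365, 100)] <- NA
  expect_error(detect_sos_eos_gpp(gpp_miss), "excluded")
})

test_that("senescence onset is located on the symmetric double-logistic within tolerance", {
  r1 <- 0.1; r2 <- 0.1; m1 <- 120; m2 <- 260
  d <- 1:365
  gpp <- 8 * (stats::plogis(r1 * (d - m1)) - stats::plogis(r2 * (d - m2)))
  det <- detect_sos_eos_gpp(gpp, spar = 0.4)
  expect_lt(abs(det$sos_doy - (m1 - log(2 + sqrt(3)) / r1)), 3)
  expect_lt(abs(det$eos_doy - (m2 - log(2 + sqrt(3)) / r2)), 3)
  expect_gt(det$eos_doy, det$sos_doy)
})

test_that("seasonal aggregation averages or sums member months and spans the year boundary for dormancy", {
  w <- season_windows(130, 273, egs = 5:6, pgs = 7:8, lgs = 9L,
                      ds = c(10:12, 1:4), cell_id = "c1")
  mo <- expand.grid(month = 1:12, year = 2000:2002)
  monthly <- rbind(
    data.frame(cell_id = "c1", year = mo$year, month = mo$month,
               variable = "NDVI", value = 0.1 * mo$month),
    data.frame(cell_id = "c1", year = mo$year, month = mo$month,
               variable = "PRE", value = 10 * mo$month))
  sf <- aggregate_seasonal(monthly, w)
  expect_equal(sf$value[sf$variable == "NDVI" & sf$season == "EGS" &
                          sf$year == 2001], mean(c(0.5, 0.6)))
  expect_equal(sf$value[sf$variable == "PRE" & sf$season == "PGS" &
                          sf$year == 2001], 70 + 80)
  # dormancy of year t uses Oct-Dec of t-1 and Jan-Apr of t
  expect_equal(sf$value[sf$variable == "PRE" & sf$season == "DS" &
                          sf$year == 2001],
               sum(10 * c(10, 11, 12, 1, 2, 3, 4)))
  # first year's dormancy lacks the previous autumn
  expect_true(is.na(sf$value[sf$variable == "PRE" & sf$season == "DS" &
                               sf$year == 2000]))
})

test_that("seasonal aggregation equals an independent month-set oracle on a synthetic grid", {
  set.seed(31)
  mo <- expand.grid(cell_id = c("a", "b"), month = 1:12, year = 1:4)
  monthly <- data.frame(cell_id = as.character(mo$cell_id), year = mo$year,
                        month = mo$month, variable = "NDVI",
                        value = stats::runif(nrow(mo), 0, 1))
  w <- list(
    a = season_windows(121, 273, egs = 5L, pgs = 6:7, lgs = 8:9,
                       ds = c(10:12, 1:4), cell_id = "a"),
    b = season_windows(100, 300, egs = 4:5, pgs = 6:7, lgs = 8:10,
                       ds = c(11:12, 1:3), cell_id = "b"))
  sf <- aggregate_seasonal(monthly, w, sum_vars = character())
  for (cell in c("a", "b")) {
    for (s in c("EGS", "PGS", "LGS")) {
      mm <- w[[cell]]$months[[s]]
      for (yr in 1:4) {
        oracle <- mean(monthly$value[monthly$cell_id == cell &
                                       monthly$year == yr &
                                       monthly$month %in% mm])
        got <- sf$value[sf$cell_id == cell & sf$season == s & sf$year == yr]
        expect_equal(got, oracle, tolerance = 1e-12)
      }
    }
  }
})

test_that("season-window validity rejects malformed month sets", {
  expect_error(season_windows(100, 280, egs = 4:5, pgs = 6:7, lgs = 8:9,
                              ds = c(11:12, 1:3)), "partition")
  expect_error(season_windows(100, 280, egs = 4:7, pgs = 6:7, lgs = 8:9,
                              ds = c(10:12, 1:3)), "partition|precede")
  expect_error(season_windows(100, 280, egs = 4:5, pgs = 6:8, lgs = 9:10,
                              ds = c(11:12, 1:3)), "1 or 2")
})
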