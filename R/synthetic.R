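# Synthetic inputs with recorded ground truth: biweekly vegetation-index
# curves, season-chained driver systems, annual AR series, raw ring widths.
# Every generator is deterministic given (config, seed) and stores the truth
# needed to score the matching estimator.

#' Parameters of the synthetic seasonal vegetation curve
#'
#' A double-logistic curve of day-of-year: a winter baseline, a logistic
#' green-up centred at `sos_mid`, and a logistic senescence centred at
#' `eos_mid`.  This is the conventional smooth unimodal model of the
#' climatological vegetation cycle; its slope extrema define the true start
#' and end of season.
#'
#' @param baseline winter index value (dimensionless, default 0.15).
#' @param amplitude summer increase above baseline (default 0.55).
#' @param sos_mid,eos_mid midpoints (day of year) of green-up and
#'   senescence; green-up must precede senescence.
#' @param sos_rate,eos_rate logistic steepness (per day) of the two
#'   transitions.
#' @param anomaly_sd standard deviation of the additive per-year anomaly.
#' @param trend additive trend per year applied to the whole curve.
#' @return object of class `pheno_curve_params`.
#' @export
pheno_curve_params <- function(baseline = 0.15, amplitude = 0.55,
                               sos_mid = 130, eos_mid = 280,
                               sos_rate = 0.10, eos_rate = 0.07,
                               anomaly_sd = 0.02, trend = 0) {
  if (amplitude < 0) stop("amplitude must be >= 0", call. = FALSE)
  if (amplitude > 0 && sos_mid >= eos_mid) {
    stop("green-up midpoint must precede senescence midpoint", call. = FALSE)
  }
  structure(list(baseline = baseline, amplitude = amplitude,
                 sos_mid = sos_mid, eos_mid = eos_mid,
                 sos_rate = sos_rate, eos_rate = eos_rate,
                 anomaly_sd = anomaly_sd, trend = trend),
            class = "pheno_curve_params")
}

# noise-free curve and its exact derivative
.pheno_curve <- function(d, p) {
  p$baseline + p$amplitude *
    (stats::plogis((d - p$sos_mid) * p$sos_rate) -
       stats::plogis((d - p$eos_mid) * p$eos_rate))
}

.pheno_slope <- function(d, p) {
  g1 <- stats::plogis((d - p$sos_mid) * p$sos_rate)
  g2 <- stats::plogis((d - p$eos_mid) * p$eos_rate)
  p$amplitude * (p$sos_rate * g1 * (1 - g1) - p$eos_rate * g2 * (1 - g2))
}

#' Simulate biweekly vegetation-index composites
#'
#' Samples the noise-free double-logistic cycle at the 24 composite periods
#' of each year (period `p` observed at day-of-year `(p - 0.5) * 365/24`),
#' adds an independent per-year anomaly and a linear trend, and returns the
#' exactly located slope extrema of the noise-free curve as ground truth.
#'
#' @param params [pheno_curve_params()].
#' @param n_years number of years.
#' @param n_cells number of cells (all share `params`; anomalies differ).
#' @param seed integer RNG seed.
#' @return list with `biweekly` (long data frame `cell_id`, `year`,
#'   `period`, `value`) and `truth` (`sos_doy`, `eos_doy`, `undefined`
#'   flag, `params`).
#' @export
simulate_biweekly_ndvi <- function(params, n_years = 35, n_cells = 1,
                                   seed = NULL) {
  stopifnot(inherits(params, "pheno_curve_params"))
  if (!is.null(seed)) set.seed(seed)
  doy <- (seq_len(24) - 0.5) * 365 / 24
  base <- .pheno_curve(doy, params)
  grid <- expand.grid(period = seq_len(24), year = seq_len(n_years),
                      cell = seq_len(n_cells))
  anom <- matrix(stats::rnorm(n_years * n_cells, 0, params$anomaly_sd),
                 n_years, n_cells)
  val <- base[grid$period] + anom[cbind(grid$year, grid$cell)] +
    params$trend * (grid$year - 1)
  bw <- data.frame(cell_id = sprintf("c%04d", grid$cell),
                   year = grid$year, period = grid$period, value = val,
                   stringsAsFactors = FALSE)
  if (params$amplitude <= 0) {
    truth <- list(sos_doy = NA_real_, eos_doy = NA_real_,
                  undefined = TRUE, params = params)
  } else {
    mid <- (params$sos_mid + params$eos_mid) / 2
    sos <- optimize(.pheno_slope, c(1, mid), p = params,
                    maximum = TRUE, tol = 1e-6)$maximum
    eos <- optimize(.pheno_slope, c(mid, 365), p = params,
                    tol = 1e-6)$minimum
    truth <- list(sos_doy = sos, eos_doy = eos, undefined = FALSE,
                  params = params)
  }
  list(biweekly = bw, truth = truth)
}

#' Configuration of the season-chained driver system
#'
#' The generative counterpart of the seasonal carryover model: within each
#' year seasons are generated in order DS, EGS, PGS, LGS, and the
#' vegetation index of each active season is
#' `gamma * NDVI_prev_season + beta_t * TMP + beta_p * PRE +
#'  beta_t_ps * TMP_prev + beta_p_ps * PRE_prev + noise`,
#' with EGS chained to the previous year's LGS.  Soil moisture carries a
#' state between seasons: `SM = sm_carry * SM_prev - sm_depletion * NDVI +
#' sm_recharge * PRE + noise`.  Anomalies are stationary whenever every
#' `|gamma| < 1`.
#'
#' Defaults describe a 35-year record of 100 cells with moderate
#' carryover (0.3-0.5 per transition), temperature sensitivity
#' 0.02 index/degC, precipitation sensitivity 0.001 index/mm, a warming
#' trend of 0.3 degC per decade, and index-scale noise (SD 0.03).
#'
#' @param n_cells,n_years record dimensions (burn-in years are extra).
#' @param burn_in years discarded before the recorded window (default 10)
#'   so the chained anomalies are stationary.
#' @param gamma named carryover per transition:
#'   `lgs_egs` (previous LGS to EGS), `egs_pgs`, `pgs_lgs`.
#' @param beta_t,beta_p concurrent climate sensitivities (index per degC,
#'   index per mm).
#' @param beta_t_ps,beta_p_ps preceding-season climate sensitivities.
#' @param tmp_sd,pre_sd interannual climate SDs (degC, mm).
#' @param tmp_trend_decade,pre_trend_decade driver trends per decade.
#' @param noise_sd vegetation-index innovation SD.
#' @param sm_carry,sm_depletion,sm_recharge,sm_sd soil-moisture coupling
#'   (carryover per season, depletion per unit greenness, recharge per mm,
#'   innovation SD).
#' @param seed integer RNG seed, recorded in the truth.
#' @return object of class `seasonal_system_config`.
#' @export
seasonal_system_config <- function(n_cells = 100, n_years = 35, burn_in = 10,
                                   gamma = c(lgs_egs = 0.3, egs_pgs = 0.5,
                                             pgs_lgs = 0.4),
                                   beta_t = 0.02, beta_p = 0.001,
                                   beta_t_ps = 0.005, beta_p_ps = 0.0005,
                                   tmp_sd = 1, pre_sd = 20,
                                   tmp_trend_decade = 0.3,
                                   pre_trend_decade = 0,
                                   noise_sd = 0.03,
                                   sm_carry = 0.5, sm_depletion = 0.1,
                                   sm_recharge = 0.002, sm_sd = 0.02,
                                   seed = NULL) {
  gamma <- gamma[c("lgs_egs", "egs_pgs", "pgs_lgs")]
  if (anyNA(gamma)) {
    stop("gamma must name lgs_egs, egs_pgs, pgs_lgs", call. = FALSE)
  }
  if (any(abs(gamma) >= 1)) {
    stop("|gamma| must be < 1 for stationary anomalies", call. = FALSE)
  }
  if (noise_sd < 0 || sm_sd < 0 || tmp_sd < 0 || pre_sd < 0) {
    stop("noise SDs must be >= 0", call. = FALSE)
  }
  structure(list(n_cells = n_cells, n_years = n_years, burn_in = burn_in,
                 gamma = gamma, beta_t = beta_t, beta_p = beta_p,
                 beta_t_ps = beta_t_ps, beta_p_ps = beta_p_ps,
                 tmp_sd = tmp_sd, pre_sd = pre_sd,
                 tmp_trend_decade = tmp_trend_decade,
                 pre_trend_decade = pre_trend_decade,
                 noise_sd = noise_sd,
                 sm_carry = sm_carry, sm_depletion = sm_depletion,
                 sm_recharge = sm_recharge, sm_sd = sm_sd, seed = seed),
            class = "seasonal_system_config")
}

# seasonal baseline levels added to the anomalies (index, degC, mm, m3/m3)
.SYS_BASE <- list(
  NDVI = c(EGS = 0.45, PGS = 0.65, LGS = 0.50),
  TMP  = c(DS = -5, EGS = 8, PGS = 16, LGS = 10),
  PRE  = c(DS = 40, EGS = 60, PGS = 80, LGS = 60),
  SM   = 0.25)

#' Simulate the season-chained vegetation-climate-soil system
#'
#' @param config [seasonal_system_config()].
#' @return long seasonal field (`cell_id`, `year`, `season`, `variable`,
#'   `value`) with variables NDVI (active seasons only; the dormancy season
#'   carries no vegetation signal), TMP, PRE, SM, and an attribute `truth`
#'   holding the generating configuration.
#' @export
simulate_seasonal_system <- function(config) {
  stopifnot(inherits(config, "seasonal_system_config"))
  cf <- config
  if (!is.null(cf$seed)) set.seed(cf$seed)
  nt <- cf$n_years + cf$burn_in
  nc <- cf$n_cells
  rn <- function(sd) matrix(stats::rnorm(nt * nc, 0, sd), nt, nc)
  # climate anomalies per season, independent across seasons and years
  yr_off <- (seq_len(nt) - cf$burn_in - 1)         # 0 at first recorded year
  tmp <- lapply(SEASONS, function(s)
    rn(cf$tmp_sd) + cf$tmp_trend_decade / 10 * yr_off)
  pre <- lapply(SEASONS, function(s)
    rn(cf$pre_sd) + cf$pre_trend_decade / 10 * yr_off)
  names(tmp) <- names(pre) <- SEASONS

  ndvi <- list(EGS = matrix(0, nt, nc), PGS = matrix(0, nt, nc),
               LGS = matrix(0, nt, nc))
  sm <- lapply(SEASONS, function(s) matrix(0, nt, nc))
  names(sm) <- SEASONS
  prev_lgs <- rep(0, nc)
  prev_sm <- rep(0, nc)
  g <- cf$gamma
  for (t in seq_len(nt)) {
    # DS first: climate only, soil moisture carries across the year boundary
    sm$DS[t, ] <- cf$sm_carry * prev_sm + cf$sm_recharge * pre$DS[t, ] +
      stats::rnorm(nc, 0, cf$sm_sd)
    e <- cf$beta_t * tmp$EGS[t, ] + cf$beta_p * pre$EGS[t, ] +
      cf$beta_t_ps * tmp$DS[t, ] + cf$beta_p_ps * pre$DS[t, ]
    ndvi$EGS[t, ] <- g[["lgs_egs"]] * prev_lgs + e +
      stats::rnorm(nc, 0, cf$noise_sd)
    sm$EGS[t, ] <- cf$sm_carry * sm$DS[t, ] -
      cf$sm_depletion * ndvi$EGS[t, ] + cf$sm_recharge * pre$EGS[t, ] +
      stats::rnorm(nc, 0, cf$sm_sd)
    e <- cf$beta_t * tmp$PGS[t, ] + cf$beta_p * pre$PGS[t, ] +
      cf$beta_t_ps * tmp$EGS[t, ] + cf$beta_p_ps * pre$EGS[t, ]
    ndvi$PGS[t, ] <- g[["egs_pgs"]] * ndvi$EGS[t, ] + e +
      stats::rnorm(nc, 0, cf$noise_sd)
    sm$PGS[t, ] <- cf$sm_carry * sm$EGS[t, ] -
      cf$sm_depletion * ndvi$PGS[t, ] + cf$sm_recharge * pre$PGS[t, ] +
      stats::rnorm(nc, 0, cf$sm_sd)
    e <- cf$beta_t * tmp$LGS[t, ] + cf$beta_p * pre$LGS[t, ] +
      cf$beta_t_ps * tmp$PGS[t, ] + cf$beta_p_ps * pre$PGS[t, ]
    ndvi$LGS[t, ] <- g[["pgs_lgs"]] * ndvi$PGS[t, ] + e +
      stats::rnorm(nc, 0, cf$noise_sd)
    sm$LGS[t, ] <- cf$sm_carry * sm$PGS[t, ] -
      cf$sm_depletion * ndvi$LGS[t, ] + cf$sm_recharge * pre$LGS[t, ] +
      stats::rnorm(nc, 0, cf$sm_sd)
    prev_lgs <- ndvi$LGS[t, ]
    prev_sm <- sm$LGS[t, ]
  }
  keep <- (cf$burn_in + 1):nt
  cells <- sprintf("c%05d", seq_len(nc))
  years <- seq_len(cf$n_years)
  long1 <- function(m, season, variable) {
    base <- .SYS_BASE[[variable]]
    b <- if (variable == "SM") base else base[[season]]
    data.frame(cell_id = rep(cells, each = length(years)),
               year = rep(years, nc),
               season = season, variable = variable,
               value = as.vector(m[keep, , drop = FALSE]) + b,
               stringsAsFactors = FALSE)
  }
  parts <- c(
    lapply(ACTIVE_SEASONS, function(s) long1(ndvi[[s]], s, "NDVI")),
    lapply(SEASONS, function(s) long1(tmp[[s]], s, "TMP")),
    lapply(SEASONS, function(s) long1(pre[[s]], s, "PRE")),
    lapply(SEASONS, function(s) long1(sm[[s]], s, "SM")))
  out <- do.call(rbind, parts)
  attr(out, "truth") <- cf
  out
}

#' Simulate annual first-order autoregressive anomalies
#'
#' AR(1) series with known coefficient `phi`, used as ground truth for the
#' interannual persistence estimators.  A 50-year burn-in precedes the
#' recorded window.
#'
#' @param phi AR(1) coefficient, `|phi| < 1`.
#' @param n_years recorded length.
#' @param n_series number of independent series (columns).
#' @param sd innovation standard deviation.
#' @param seed integer RNG seed.
#' @return numeric matrix `n_years x n_series` with attribute `truth`.
#' @export
simulate_annual_ar <- function(phi, n_years, n_series = 1, sd = 1,
                               seed = NULL) {
  if (abs(phi) >= 1) stop("|phi| must be < 1", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  burn <- 50L
  nt <- n_years + burn
  x <- matrix(0, nt, n_series)
  eps <- matrix(stats::rnorm(nt * n_series, 0, sd), nt, n_series)
  x[1L, ] <- eps[1L, ] / sqrt(1 - phi^2)
  for (t in 2:nt) x[t, ] <- phi * x[t - 1L, ] + eps[t, ]
  out <- x[(burn + 1L):nt, , drop = FALSE]
  attr(out, "truth") <- list(phi = phi, sd = sd, seed = seed)
  out
}

#' Configuration of the ring-width simulator
#'
#' Raw widths follow `width_t = age(t) * (1 + signal_t + tree noise)` with a
#' negative-exponential age trend `age(t) = age_amp * exp(-age_rate * t) +
#' age_base` (mm), a common AR(1) stand signal shared by all trees, and
#' independent tree-level noise.  Defaults: 20 trees over 100 years,
#' juvenile width 1.6 mm declining to a 0.6 mm asymptote, common-signal
#' AR(1) coefficient 0.3 with marginal SD 0.2, tree noise SD 0.1.
#'
#' @param n_trees number of trees (>= 2).
#' @param n_years series length in years.
#' @param age_amp,age_rate,age_base negative-exponential parameters
#'   (mm, per year, mm); all must be positive (`age_base` the asymptote).
#' @param ar_phi AR(1) coefficient of the common signal, in (-1, 1).
#' @param signal_sd marginal SD of the common signal (dimensionless).
#' @param tree_sd SD of independent tree-level noise.
#' @param outlier optional `list(tree =, factor =)` scaling one tree's raw
#'   widths by `factor`.
#' @param year_start first calendar year (default 1901).
#' @param seed integer RNG seed.
#' @return object of class `ring_sim_config`.
#' @export
ring_sim_config <- function(n_trees = 20, n_years = 100,
                            age_amp = 1.0, age_rate = 0.02, age_base = 0.6,
                            ar_phi = 0.3, signal_sd = 0.2, tree_sd = 0.1,
                            outlier = NULL, year_start = 1901, seed = NULL) {
  if (n_trees < 2) stop("n_trees must be >= 2", call. = FALSE)
  if (age_amp <= 0 || age_rate <= 0 || age_base <= 0) {
    stop("age-trend parameters must be positive", call. = FALSE)
  }
  if (abs(ar_phi) >= 1) stop("AR coefficient must lie in (-1, 1)", call. = FALSE)
  if (signal_sd < 0 || tree_sd < 0) stop("noise SDs must be >= 0", call. = FALSE)
  structure(list(n_trees = n_trees, n_years = n_years, age_amp = age_amp,
                 age_rate = age_rate, age_base = age_base, ar_phi = ar_phi,
                 signal_sd = signal_sd, tree_sd = tree_sd, outlier = outlier,
                 year_start = year_start, seed = seed),
            class = "ring_sim_config")
}

#' Simulate raw ring-width series
#'
#' @param config [ring_sim_config()].
#' @return list with `rwl` (long data frame `series_id`, `year`,
#'   `width_mm`), `widths` (year-by-tree matrix), and `truth` (common
#'   signal, age trend, per-tree true indices, config).
#' @export
simulate_ring_widths <- function(config) {
  stopifnot(inherits(config, "ring_sim_config"))
  cf <- config
  if (!is.null(cf$seed)) set.seed(cf$seed)
  t <- seq_len(cf$n_years)
  age <- cf$age_amp * exp(-cf$age_rate * t) + cf$age_base
  if (cf$signal_sd > 0) {
    sig <- as.vector(simulate_annual_ar(cf$ar_phi, cf$n_years, 1,
                                        sd = cf$signal_sd *
                                          sqrt(1 - cf$ar_phi^2)))
  } else {
    sig <- rep(0, cf$n_years)
  }
  noise <- matrix(stats::rnorm(cf$n_years * cf$n_trees, 0, cf$tree_sd),
                  cf$n_years, cf$n_trees)
  idx_true <- 1 + sig + noise              # per-tree true index
  w <- age * idx_true
  w[w < 0.01] <- 0.01                      # widths are physically positive
  if (!is.null(cf$outlier)) {
    w[, cf$outlier$tree] <- w[, cf$outlier$tree] * cf$outlier$factor
  }
  ids <- sprintf("SIM%03d", seq_len(cf$n_trees))
  colnames(w) <- ids
  years <- as.integer(cf$year_start) + t - 1L
  rownames(w) <- years
  rwl <- data.frame(series_id = rep(ids, each = cf$n_years),
                    year = rep(years, cf$n_trees),
                    width_mm = as.vector(w), stringsAsFactors = FALSE)
  list(rwl = rwl, widths = w,
       truth = list(signal = sig, age_trend = age, index = idx_true,
                    config = cf))
}
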