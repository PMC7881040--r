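# Partial-correlation machinery: seasonal carryover profiles with mutual
# driver control, residual-vs-previous-year correlations, interannual
# lead-1..3 partial autocorrelation, and sign/significance summaries.

#' Remove the linear trend from a yearly series
#'
#' Ordinary least-squares residuals against the year; the output has zero
#' mean and zero fitted trend.  `NA`s are preserved in place.
#'
#' @param x per-year values (at least 3 non-missing).
#' @param year time axis (defaults to the index).
#' @return anomaly series, same length as `x`.
#' @export
linear_detrend <- function(x, year = seq_along(x)) {
  ok <- !is.na(x)
  if (sum(ok) < 3L) stop("need at least 3 values to detrend", call. = FALSE)
  fit <- lm.fit(cbind(1, year[ok]), x[ok])
  out <- rep(NA_real_, length(x))
  out[ok] <- fit$residuals
  out
}

.residualize <- function(v, controls) {
  lm.fit(cbind(1, controls), v)$residuals
}

#' Partial correlation with covariate control
#'
#' Correlation between `y` and `x` after removing, from both, the part
#' explained linearly by the control variables.  Two implementations are
#' provided and agree to numerical precision: `"residual"` correlates the
#' OLS residuals of `y` and `x` on the controls; `"precision"` reads the
#' coefficient off the inverse correlation matrix of all variables.
#' Significance uses a two-sided t test with `n - 2 - k` degrees of
#' freedom (`k` controls).
#'
#' Rows with any missing value are dropped listwise.  If either variable is
#' (numerically) constant after residualization the coefficient is
#' undefined and flagged rather than fabricated.
#'
#' @param y,x numeric vectors of equal length.
#' @param controls optional numeric matrix / data frame of control
#'   variables (columns), or `NULL` for a plain Pearson correlation.
#' @param method `"residual"` (default) or `"precision"`.
#' @return object of class `partial_corr`: `estimate`, `p_value`, `n`,
#'   `df`, `controls` (names), `undefined` flag.
#' @examples
#' set.seed(1)
#' z <- rnorm(50); y <- z + rnorm(50); x <- z + rnorm(50)
#' partial_correlation(y, x, controls = cbind(z = z))
#' @export
partial_correlation <- function(y, x, controls = NULL,
                                method = c("residual", "precision")) {
  method <- match.arg(method)
  if (length(y) != length(x)) stop("y and x differ in length", call. = FALSE)
  if (!is.null(controls)) {
    controls <- as.matrix(controls)
    if (nrow(controls) != length(y)) {
      stop("controls differ in length from y", call. = FALSE)
    }
  }
  k <- if (is.null(controls)) 0L else ncol(controls)
  cc <- stats::complete.cases(y, x, if (is.null(controls)) rep(TRUE, length(y)) else controls)
  y <- y[cc]; x <- x[cc]
  if (!is.null(controls)) controls <- controls[cc, , drop = FALSE]
  n <- length(y)
  if (n <= k + 2L) {
    stop(sprintf("sample size %d too small for %d controls (need > %d)",
                 n, k, k + 2L), call. = FALSE)
  }
  ctrl_names <- if (k > 0L) {
    colnames(controls) %||% paste0("C", seq_len(k))
  } else character()
  make <- function(est, undefined = FALSE) {
    df <- n - 2L - k
    p <- if (undefined || is.na(est)) {
      NA_real_
    } else if (abs(est) >= 1) {
      0
    } else {
      tt <- est * sqrt(df / (1 - est^2))
      2 * pt(-abs(tt), df)
    }
    structure(list(estimate = est, p_value = p, n = n, df = df,
                   controls = ctrl_names, method = method,
                   undefined = undefined),
              class = "partial_corr")
  }
  tol <- 1e-12
  if (method == "residual") {
    if (k > 0L) {
      ry <- .residualize(y, controls)
      rx <- .residualize(x, controls)
    } else {
      ry <- y - mean(y); rx <- x - mean(x)
    }
    sy <- sqrt(sum(ry^2) / (n - 1)); sx <- sqrt(sum(rx^2) / (n - 1))
    scale <- max(sd(y), sd(x), 1)
    if (sy < tol * scale || sx < tol * scale) {
      return(make(NA_real_, undefined = TRUE))
    }
    est <- sum(ry * rx) / ((n - 1) * sy * sx)
  } else {
    m <- cbind(y = y, x = x, controls)
    if (any(apply(m, 2L, sd) < tol * max(abs(m), 1))) {
      return(make(NA_real_, undefined = TRUE))
    }
    R <- cor(m)
    P <- tryCatch(solve(R), error = function(e) NULL)
    if (is.null(P)) return(make(NA_real_, undefined = TRUE))
    est <- -P[1L, 2L] / sqrt(P[1L, 1L] * P[2L, 2L])
  }
  make(min(1, max(-1, est)))
}

#' @export
print.partial_corr <- function(x, ...) {
  if (x$undefined) {
    cat("Partial correlation: undefined (degenerate input)\n")
  } else {
    cat(sprintf("Partial correlation: r_p = %.4f (p = %.4g, n = %d, df = %d)\n",
                x$estimate, x$p_value, x$n, x$df))
  }
  if (length(x$controls)) {
    cat("  controlling for:", paste(x$controls, collapse = ", "), "\n")
  }
  invisible(x)
}

# --- seasonal driver alignment --------------------------------------------

# within-year season order is DS, EGS, PGS, LGS (DS precedes the EGS it is
# attached to); the preceding season of EGS therefore crosses the year
# boundary for vegetation (previous LGS) but not for climate (same-year DS)
.PS_MAP <- list(
  EGS = list(veg_season = "LGS", veg_shift = -1L,
             clim_season = "DS", clim_shift = 0L),
  PGS = list(veg_season = "EGS", veg_shift = 0L,
             clim_season = "EGS", clim_shift = 0L),
  LGS = list(veg_season = "PGS", veg_shift = 0L,
             clim_season = "PGS", clim_shift = 0L))

.pivot_season_var <- function(seasonal, variable, season, years, cells) {
  d <- seasonal[seasonal$variable == variable & seasonal$season == season, ]
  m <- matrix(NA_real_, length(years), length(cells),
              dimnames = list(years, cells))
  m[cbind(match(d$year, years), match(d$cell_id, cells))] <- d$value
  m
}

.shift_rows <- function(m, shift) {
  if (shift == 0L) return(m)
  out <- m
  out[] <- NA_real_
  nr <- nrow(m)
  out[(1L - shift):nr, ] <- m[seq_len(nr + shift), ]   # shift = -1: lag 1 yr
  out
}

# year-by-cell matrices of the target and its five drivers
.driver_arrays <- function(seasonal, season, target_var = "NDVI") {
  stopifnot(season %in% ACTIVE_SEASONS)
  years <- sort(unique(seasonal$year))
  cells <- sort(unique(seasonal$cell_id))
  ps <- .PS_MAP[[season]]
  list(years = years, cells = cells,
       y = .pivot_season_var(seasonal, target_var, season, years, cells),
       y_ps = .shift_rows(
         .pivot_season_var(seasonal, target_var, ps$veg_season, years, cells),
         ps$veg_shift),
       tmp = .pivot_season_var(seasonal, "TMP", season, years, cells),
       pre = .pivot_season_var(seasonal, "PRE", season, years, cells),
       tmp_ps = .shift_rows(
         .pivot_season_var(seasonal, "TMP", ps$clim_season, years, cells),
         ps$clim_shift),
       pre_ps = .shift_rows(
         .pivot_season_var(seasonal, "PRE", ps$clim_season, years, cells),
         ps$clim_shift))
}

# fast path used per cell: five mutually-controlled partial correlations
# from one 6-column matrix (y, then drivers); rows already complete
.profile_pcors <- function(m) {
  n <- nrow(m)
  k <- 4L
  df <- n - 2L - k
  est <- p <- rep(NA_real_, 5L)
  undef <- rep(FALSE, 5L)
  scale <- max(apply(m, 2L, sd), 1e-300)
  for (i in 2:6) {
    ctrl <- m[, setdiff(2:6, i), drop = FALSE]
    ry <- .residualize(m[, 1L], ctrl)
    rx <- .residualize(m[, i], ctrl)
    sy <- sqrt(sum(ry^2)); sx <- sqrt(sum(rx^2))
    if (sy < 1e-12 * scale || sx < 1e-12 * scale) {
      undef[i - 1L] <- TRUE
      next
    }
    r <- min(1, max(-1, sum(ry * rx) / (sy * sx)))
    est[i - 1L] <- r
    p[i - 1L] <- if (abs(r) >= 1) 0 else {
      tt <- r * sqrt(df / (1 - r^2))
      2 * pt(-abs(tt), df)
    }
  }
  list(est = est, p = p, n = n, undefined = undef)
}

#' Seasonal vegetation-growth-carryover profile
#'
#' For one target season, computes per cell the partial correlation of the
#' seasonal vegetation index with each of five drivers - preceding-season
#' vegetation (the carryover term), concurrent temperature and
#' precipitation, and preceding-season temperature and precipitation -
#' where each driver's coefficient controls for the remaining four.  The
#' preceding season of EGS is the previous year's LGS for vegetation and
#' the dormancy season for climate; for PGS and LGS it is the same-year
#' EGS and PGS respectively.
#'
#' @param seasonal seasonal field (`cell_id`, `year`, `season`,
#'   `variable`, `value`) holding at least the target variable, `TMP`, and
#'   `PRE`.
#' @param season target season, one of `"EGS"`, `"PGS"`, `"LGS"`.
#' @param target_var vegetation variable name (default `"NDVI"`; any
#'   growth proxy such as GPP runs unchanged).
#' @param detrend if `TRUE`, all series are linearly detrended before the
#'   correlations (anomaly variant).
#' @param min_years minimum complete years per cell (default 10); cells
#'   with fewer are skipped.
#' @return tidy data frame: `cell_id`, `season`, `driver`, `role`
#'   (`carryover`, `concurrent_tmp`, `concurrent_pre`, `preceding_tmp`,
#'   `preceding_pre`), `r_p`, `p_value`, `n`, `undefined`.
#' @export
seasonal_vgc_profile <- function(seasonal, season, target_var = "NDVI",
                                 detrend = FALSE, min_years = 10L) {
  .assert_cols(seasonal, c("cell_id", "year", "season", "variable", "value"),
               "seasonal field")
  a <- .driver_arrays(seasonal, season, target_var)
  drivers <- c(paste0(target_var, "_ps"), "TMP", "PRE", "TMP_ps", "PRE_ps")
  roles <- c("carryover", "concurrent_tmp", "concurrent_pre",
             "preceding_tmp", "preceding_pre")
  nc <- length(a$cells)
  out <- vector("list", nc)
  for (j in seq_len(nc)) {
    m <- cbind(a$y[, j], a$y_ps[, j], a$tmp[, j], a$pre[, j],
               a$tmp_ps[, j], a$pre_ps[, j])
    yrs <- a$years
    keep <- stats::complete.cases(m)
    m <- m[keep, , drop = FALSE]
    yrs <- yrs[keep]
    if (nrow(m) < max(min_years, 7L)) next
    if (detrend) m <- apply(m, 2L, function(v) lm.fit(cbind(1, yrs), v)$residuals)
    pc <- .profile_pcors(m)
    out[[j]] <- data.frame(cell_id = a$cells[j], season = season,
                           driver = drivers, role = roles,
                           r_p = pc$est, p_value = pc$p, n = pc$n,
                           undefined = pc$undefined,
                           stringsAsFactors = FALSE)
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (length(out) == 0L) {
    stop("no cell provided at least ", min_years, " complete years",
         call. = FALSE)
  }
  do.call(rbind, out)
}

# factors of the previous year for the residual analysis: the three seasons
# before the immediately preceding one (which Eq.-style regression already
# uses), vegetation omitted for the dormancy season
.previous_year_factors <- function(season, target_var = "NDVI") {
  cycle <- c("DS", "EGS", "PGS", "LGS")          # within-year order
  pos <- match(season, cycle)
  lag_pos <- ((pos - 1L - (2:4)) %% 4L) + 1L     # season lags 2..4
  lag_off <- (pos - 1L - (2:4)) %/% 4L           # year offsets (0 or -1)
  out <- list()
  for (i in seq_along(lag_pos)) {
    s <- cycle[lag_pos[i]]
    off <- lag_off[i]
    vars <- if (s == "DS") c("TMP", "PRE") else c(target_var, "TMP", "PRE")
    for (v in vars) {
      out[[length(out) + 1L]] <- list(variable = v, season = s,
                                      year_offset = off)
    }
  }
  out
}

#' Correlate attribution residuals with previous-year factors
#'
#' The residual of the five-driver trend regression captures variability
#' unexplained by the concurrent and immediately preceding season.  This
#' operation extends the window to the rest of the previous year: the
#' residual series is partially correlated (mutual control) with the
#' vegetation index, temperature, and precipitation of the three seasons
#' before the immediately preceding one (climate only for the dormancy
#' season; e.g. for a PGS target: previous-year PGS and LGS plus dormancy
#' climate), and the collective explained variance is reported.
#'
#' @param residuals per-year residual series (from [decompose_trend()]).
#' @param years calendar years of `residuals`.
#' @param seasonal seasonal field supplying the factors (single cell or
#'   hemispheric series with a constant `cell_id`).
#' @param season target season of the residuals.
#' @param target_var vegetation variable name.
#' @return data frame `driver`, `r_p`, `p_value`, `n` with attribute
#'   `r_squared` (R^2 of the residuals on all factors jointly).
#' @export
residual_driver_correlation <- function(residuals, years, seasonal, season,
                                        target_var = "NDVI") {
  facs <- .previous_year_factors(season, target_var)
  if (length(facs) == 0L) stop("empty factor list", call. = FALSE)
  cells <- unique(seasonal$cell_id)
  if (length(cells) > 1L) {
    stop("residual_driver_correlation expects a single series; aggregate first",
         call. = FALSE)
  }
  yrs_all <- sort(unique(seasonal$year))
  cols <- vapply(facs, function(f) {
    m <- .pivot_season_var(seasonal, f$variable, f$season, yrs_all, cells)
    as.vector(m[match(years + f$year_offset, yrs_all), 1L])
  }, numeric(length(years)))
  labs <- vapply(facs, function(f) {
    paste0(f$variable, "_", f$season, if (f$year_offset < 0L) "_py" else "")
  }, character(1))
  colnames(cols) <- labs
  keep <- stats::complete.cases(residuals, cols)
  eps <- residuals[keep]
  X <- cols[keep, , drop = FALSE]
  res <- lapply(seq_len(ncol(X)), function(i) {
    pc <- partial_correlation(eps, X[, i], X[, -i, drop = FALSE])
    data.frame(driver = labs[i], r_p = pc$estimate, p_value = pc$p_value,
               n = pc$n, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  fit <- lm(eps ~ X)
  attr(out, "r_squared") <- summary(fit)$r.squared
  out
}

#' Lagged partial autocorrelation of annual anomalies
#'
#' The lead-1 coefficient is the partial correlation of the series with
#' itself one year earlier, controlling temperature and precipitation of
#' the present and preceding year.  For lead `j > 1` the series at all
#' smaller leads `1 .. j-1` joins the control set, so each coefficient
#' measures the persistence unique to its lead.  Linear trends are removed
#' first (comparability with standardized tree-ring series).
#'
#' @param y annual series.
#' @param climate optional data frame / matrix of annual covariates
#'   aligned with `y` (typically columns `TMP` and `PRE`); `NULL` for none.
#' @param max_lead largest lead in years (1-3).
#' @param detrend remove linear trends from all series first (default
#'   `TRUE`).
#' @return data frame `lead`, `coefficient`, `p_value`, `n`, `controls`.
#' @export
lagged_pacf <- function(y, climate = NULL, max_lead = 3L, detrend = TRUE) {
  stopifnot(max_lead >= 1L, max_lead <= 3L)
  n_full <- length(y)
  if (n_full < 15L) stop("need at least 15 years", call. = FALSE)
  if (!is.null(climate)) {
    climate <- as.matrix(climate)
    if (nrow(climate) != n_full) stop("climate length mismatch", call. = FALSE)
    if (is.null(colnames(climate))) {
      colnames(climate) <- paste0("clim", seq_len(ncol(climate)))
    }
  }
  if (detrend) {
    y <- linear_detrend(y)
    if (!is.null(climate)) climate <- apply(climate, 2L, linear_detrend)
  }
  out <- vector("list", max_lead)
  for (j in seq_len(max_lead)) {
    t_idx <- (j + 1L):n_full
    yt <- y[t_idx]
    ylag <- y[t_idx - j]
    ctrl <- NULL
    cn <- character()
    if (!is.null(climate)) {
      ctrl <- cbind(climate[t_idx, , drop = FALSE],
                    climate[t_idx - 1L, , drop = FALSE])
      cn <- c(colnames(climate), paste0(colnames(climate), "_prev"))
    }
    if (j > 1L) {
      smaller <- vapply(seq_len(j - 1L), function(l) y[t_idx - l],
                        numeric(length(t_idx)))
      ctrl <- cbind(ctrl, smaller)
      cn <- c(cn, paste0("y_lag", seq_len(j - 1L)))
    }
    if (!is.null(ctrl)) colnames(ctrl) <- cn
    k <- length(cn)
    if (length(t_idx) <= k + 2L) {
      stop(sprintf(
        "lead %d: %d usable years cannot support %d controls (deficit %d)",
        j, length(t_idx), k, k + 3L - length(t_idx)), call. = FALSE)
    }
    pc <- partial_correlation(yt, ylag, ctrl)
    out[[j]] <- data.frame(lead = j, coefficient = pc$estimate,
                           p_value = pc$p_value, n = pc$n,
                           controls = paste(cn, collapse = ";"),
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Sign and significance frequencies of correlation results
#'
#' Summarizes a set of per-cell (or per-series) coefficients into the
#' percentages of positive and negative values and of statistically
#' significant ones, optionally by group.  Undefined (flagged) results are
#' excluded from the percentages but counted.
#'
#' @param results data frame with a coefficient column (`r_p` or
#'   `coefficient`) and `p_value`.
#' @param group optional name of a grouping column in `results`, or a
#'   vector of labels.
#' @param alpha significance level (default 0.05).
#' @return data frame per group: `group`, `n`, `n_undefined`,
#'   `pct_positive`, `pct_negative`, `pct_sig_positive`,
#'   `pct_sig_negative`.
#' @export
sign_frequency_summary <- function(results, group = NULL, alpha = 0.05) {
  cf <- results[["r_p"]] %||% results[["coefficient"]]
  if (is.null(cf)) stop("no coefficient column (r_p or coefficient)",
                        call. = FALSE)
  if (nrow(results) == 0L) stop("empty result set", call. = FALSE)
  p <- results[["p_value"]]
  g <- if (is.null(group)) {
    rep("all", length(cf))
  } else if (is.character(group) && length(group) == 1L &&
             group %in% names(results)) {
    as.character(results[[group]])
  } else {
    as.character(group)
  }
  res <- lapply(split(seq_along(cf), g), function(i) {
    ci <- cf[i]; pi <- p[i]
    und <- is.na(ci)
    ci <- ci[!und]; pi <- pi[!und]
    n <- length(ci)
    data.frame(group = g[i[1L]], n = n, n_undefined = sum(und),
               pct_positive = 100 * mean(ci > 0),
               pct_negative = 100 * mean(ci < 0),
               pct_sig_positive = 100 * mean(ci > 0 & pi < alpha),
               pct_sig_negative = 100 * mean(ci < 0 & pi < alpha),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
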