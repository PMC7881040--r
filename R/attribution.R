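# Linear trend attribution: decompose the multi-year trend of seasonal
# vegetation growth into carryover, lagged-climate, concurrent-climate
# contributions and a residual.  The decomposition is exact by
# construction: each contribution is (regression sensitivity) x (driver
# trend) and the residual trend is the closure remainder, which equals the
# trend of the OLS residuals because both the regression and the trend
# operator are linear.

#' Least-squares linear trend
#'
#' @param x per-year values (>= 3 non-missing).
#' @param year time axis.
#' @param details if `TRUE`, return a list with `slope`, `p_value`, `n`;
#'   otherwise the slope alone.
#' @return slope in units of `x` per year.
#' @export
linear_trend <- function(x, year = seq_along(x), details = FALSE) {
  ok <- stats::complete.cases(x, year)
  x <- x[ok]; year <- year[ok]
  if (length(x) < 3L) stop("need at least 3 values for a trend", call. = FALSE)
  if (sd(year) == 0) stop("year vector is constant", call. = FALSE)
  if (!details) {
    return(sum((year - mean(year)) * (x - mean(x))) /
             sum((year - mean(year))^2))
  }
  fit <- lm(x ~ year)
  sm <- summary(fit)$coefficients
  list(slope = unname(sm["year", "Estimate"]),
       p_value = unname(sm["year", "Pr(>|t|)"]),
       n = length(x))
}

.DRIVER_ORDER <- c("Y_ps", "TMP_ps", "PRE_ps", "TMP", "PRE")

.driver_matrix <- function(drivers) {
  m <- as.matrix(drivers)
  if (is.null(colnames(m)) && ncol(m) == 5L) colnames(m) <- .DRIVER_ORDER
  miss <- setdiff(.DRIVER_ORDER, colnames(m))
  if (length(miss) > 0L) {
    stop("drivers must provide columns ",
         paste(.DRIVER_ORDER, collapse = ", "), call. = FALSE)
  }
  m[, .DRIVER_ORDER, drop = FALSE]
}

#' Fit sensitivities of seasonal growth to its five drivers
#'
#' Multiple linear regression of the seasonal vegetation series on the
#' preceding-season vegetation (`Y_ps`), preceding-season climate
#' (`TMP_ps`, `PRE_ps`), and concurrent climate (`TMP`, `PRE`) jointly.
#' The coefficients are the partial sensitivities used by
#' [decompose_trend()].
#'
#' @param y seasonal vegetation series (per year).
#' @param drivers data frame / matrix with columns `Y_ps`, `TMP_ps`,
#'   `PRE_ps`, `TMP`, `PRE`.
#' @param min_years minimum number of complete years (default 8).
#' @return list: `beta` (named coefficients), `intercept`, `r_squared`,
#'   `n`, `rank_ok` (FALSE flags a rank-deficient design).
#' @export
fit_sensitivities <- function(y, drivers, min_years = 8L) {
  X <- .driver_matrix(drivers)
  keep <- stats::complete.cases(y, X)
  y <- y[keep]; X <- X[keep, , drop = FALSE]
  n <- length(y)
  if (n < min_years) {
    stop(sprintf("only %d complete years (need >= %d)", n, min_years),
         call. = FALSE)
  }
  M <- cbind(`(Intercept)` = 1, X)
  qr_ <- qr(M)
  if (qr_$rank < ncol(M)) {
    return(list(beta = setNames(rep(NA_real_, 5L), .DRIVER_ORDER),
                intercept = NA_real_, r_squared = NA_real_, n = n,
                rank_ok = FALSE))
  }
  fit <- lm.fit(M, y)
  cf <- fit$coefficients
  ss_res <- sum(fit$residuals^2)
  ss_tot <- sum((y - mean(y))^2)
  list(beta = cf[.DRIVER_ORDER], intercept = unname(cf[1L]),
       r_squared = if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_,
       n = n, rank_ok = TRUE, residuals = unname(fit$residuals))
}

#' Decompose a seasonal growth trend into driver contributions
#'
#' Each driver's contribution to the observed trend is its regression
#' sensitivity times its own trend; temperature and precipitation are also
#' combined into lagged-climate and concurrent-climate totals; the residual
#' term is the closure remainder.  The identity
#' `carryover + lagged climate + concurrent climate + residual = observed
#' trend` holds to machine precision.
#'
#' @param y seasonal vegetation series.
#' @param drivers five-driver matrix as in [fit_sensitivities()].
#' @param year time axis (defaults to the index).
#' @return object of class `trend_attribution`: per-driver contributions
#'   (`delta`), combined `clm_ps` and `clm`, `residual_trend`,
#'   `total_trend`, per-driver trends, sensitivities and diagnostics.
#' @export
decompose_trend <- function(y, drivers, year = seq_along(y)) {
  X <- .driver_matrix(drivers)
  keep <- stats::complete.cases(y, X, year)
  y <- y[keep]; X <- X[keep, , drop = FALSE]; year <- year[keep]
  sens <- fit_sensitivities(y, X)
  if (!sens$rank_ok) {
    stop("rank-deficient driver design; cell must be flagged upstream",
         call. = FALSE)
  }
  total <- linear_trend(y, year)
  x_trends <- apply(X, 2L, linear_trend, year = year)
  delta <- sens$beta * x_trends
  resid_trend <- total - sum(delta)
  out <- list(delta = delta,
              clm_ps = unname(delta["TMP_ps"] + delta["PRE_ps"]),
              clm = unname(delta["TMP"] + delta["PRE"]),
              carryover = unname(delta["Y_ps"]),
              residual_trend = resid_trend,
              total_trend = total,
              driver_trends = x_trends,
              beta = sens$beta,
              r_squared = sens$r_squared,
              n = sens$n,
              year = year,
              residuals = sens$residuals)
  class(out) <- "trend_attribution"
  out
}

#' @export
print.trend_attribution <- function(x, ...) {
  cat(sprintf("Trend attribution over %d years (total %.5g / yr):\n",
              x$n, x$total_trend))
  cat(sprintf("  carryover          %.5g\n", x$carryover))
  cat(sprintf("  lagged climate     %.5g\n", x$clm_ps))
  cat(sprintf("  concurrent climate %.5g\n", x$clm))
  cat(sprintf("  residual           %.5g\n", x$residual_trend))
  invisible(x)
}

#' Per-cell trend attribution of a seasonal field
#'
#' Runs [decompose_trend()] for every cell of a seasonal field, aligning
#' the five drivers exactly as [seasonal_vgc_profile()] does.  Cells with
#' rank-deficient designs or too few complete years are skipped and listed
#' in the `skipped` attribute.
#'
#' @inheritParams seasonal_vgc_profile
#' @return data frame with one row per cell: contributions of each term,
#'   total trend, and closure error.
#' @export
attribute_seasonal_trends <- function(seasonal, season, target_var = "NDVI",
                                      min_years = 8L) {
  a <- .driver_arrays(seasonal, season, target_var)
  rows <- vector("list", length(a$cells))
  skipped <- character()
  for (j in seq_along(a$cells)) {
    X <- cbind(Y_ps = a$y_ps[, j], TMP_ps = a$tmp_ps[, j],
               PRE_ps = a$pre_ps[, j], TMP = a$tmp[, j], PRE = a$pre[, j])
    res <- tryCatch(
      decompose_trend(a$y[, j], X, year = a$years),
      error = function(e) NULL)
    if (is.null(res)) {
      skipped <- c(skipped, a$cells[j])
      next
    }
    rows[[j]] <- data.frame(
      cell_id = a$cells[j], season = season,
      carryover = res$carryover, clm_ps = res$clm_ps, clm = res$clm,
      residual_trend = res$residual_trend, total_trend = res$total_trend,
      closure_error = res$total_trend -
        (res$carryover + res$clm_ps + res$clm + res$residual_trend),
      n = res$n, stringsAsFactors = FALSE)
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0L) stop("no cell could be attributed", call. = FALSE)
  out <- do.call(rbind, rows)
  attr(out, "skipped") <- skipped
  out
}

#' Hemispheric summary of per-cell contributions
#'
#' Area-weighted means of each contribution term and their percentage
#' shares of the area-weighted total trend.  Shares are signed and may
#' exceed 100 percent when terms oppose each other; when the total trend is
#' (numerically) zero the shares are undefined while the absolute
#' contributions are still reported.
#'
#' @param cells output of [attribute_seasonal_trends()].
#' @param weights optional `cell_id` / `weight` table (e.g.
#'   [cos_lat_weights()]); `NULL` for equal weights.
#' @param share_basis `"observed"` (default): shares relative to the
#'   observed total trend; `"explained"`: relative to the explained part.
#' @return list with `contributions` (named means), `shares` (percent),
#'   `total_trend`, `n_cells`.
#' @export
summarize_contributions <- function(cells, weights = NULL,
                                    share_basis = c("observed", "explained")) {
  share_basis <- match.arg(share_basis)
  if (nrow(cells) == 0L) stop("no valid cells", call. = FALSE)
  w <- if (is.null(weights)) {
    rep(1, nrow(cells))
  } else {
    weights$weight[match(cells$cell_id, weights$cell_id)]
  }
  if (anyNA(w)) stop("weights do not cover all cells", call. = FALSE)
  wm <- function(v) sum(v * w) / sum(w)
  contr <- c(carryover = wm(cells$carryover),
             clm_ps = wm(cells$clm_ps),
             clm = wm(cells$clm),
             residual = wm(cells$residual_trend))
  total <- wm(cells$total_trend)
  base <- if (share_basis == "observed") total else total - contr["residual"]
  shares <- if (abs(base) < 1e-300) {
    setNames(rep(NA_real_, 4L), names(contr))
  } else {
    100 * contr / base
  }
  list(contributions = contr, shares = shares, total_trend = total,
       n_cells = nrow(cells), share_basis = share_basis)
}
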