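# Season delineation from the climatological vegetation cycle: SOS/EOS from
# slope extrema of the interpolated biweekly cycle, month assignment to
# EGS/PGS/LGS/DS, the site-level second-derivative variant for daily GPP,
# and monthly-to-seasonal aggregation.

# day-of-year of the midpoint of composite period p (365-day calendar)
.period_doy <- function(p) (p - 0.5) * 365 / 24

.MONTH_END <- cumsum(c(31, 28, 31, 30, 31, 30, 31, 31, 30, 31, 30, 31))

.doy_month <- function(doy) findInterval(doy - 0.5, c(0, .MONTH_END))

#' Multi-year mean seasonal cycle at biweekly resolution
#'
#' @param biweekly biweekly series for a single cell (`cell_id`, `year`,
#'   `period`, `value`); multiple cells are rejected.
#' @param years optional subset of years to average over.
#' @return numeric vector of length 24: per-period multi-year means.
#' @export
climatological_cycle <- function(biweekly, years = NULL) {
  validate_biweekly(biweekly)
  if (length(unique(biweekly$cell_id)) > 1L) {
    stop("climatological_cycle expects a single cell; split by cell first",
         call. = FALSE)
  }
  if (!is.null(years)) biweekly <- biweekly[biweekly$year %in% years, ]
  cyc <- rep(NA_real_, 24)
  nyr <- integer(24)
  for (p in 1:24) {
    v <- biweekly$value[biweekly$period == p]
    v <- v[!is.na(v)]
    nyr[p] <- length(v)
    if (length(v) > 0L) cyc[p] <- mean(v)
  }
  if (any(nyr == 0L)) {
    stop("composite period(s) ", paste(which(nyr == 0L), collapse = ", "),
         " missing in all years", call. = FALSE)
  }
  if (any(nyr < 2L)) {
    stop("composite period(s) ", paste(which(nyr < 2L), collapse = ", "),
         " observed in fewer than 2 years", call. = FALSE)
  }
  cyc
}

#' Detect start and end of season from the mean cycle
#'
#' The 24-point climatological cycle is interpolated to daily resolution
#' with a cubic spline (fit over three concatenated annual cycles so the
#' year boundary is smooth), and the start/end of season are the days of
#' the largest/smallest daily first difference, i.e. the fastest green-up
#' and fastest senescence.  Adding a constant to the cycle does not move
#' either date.
#'
#' @param cycle numeric vector of length 24 (one climatological value per
#'   composite period).
#' @param min_amplitude minimum seasonal range (max - min of the cycle)
#'   below which phenology is declared undetectable.
#' @return list with `sos_doy`, `eos_doy`, and logical `detectable`.
#' @export
detect_sos_eos <- function(cycle, min_amplitude = 0.05) {
  stopifnot(length(cycle) == 24)
  if (anyNA(cycle)) stop("cycle contains missing periods", call. = FALSE)
  if (diff(range(cycle)) < min_amplitude) {
    return(list(sos_doy = NA_real_, eos_doy = NA_real_, detectable = FALSE))
  }
  doy <- .period_doy(1:24)
  x3 <- c(doy - 365, doy, doy + 365)
  y3 <- rep(cycle, 3)
  daily <- spline(x3, y3, xout = seq_len(365))$y
  rate <- diff(daily)                       # change over day i -> i+1
  sos <- which.max(rate) + 0.5
  eos <- which.min(rate) + 0.5
  if (!(sos < eos)) {
    return(list(sos_doy = NA_real_, eos_doy = NA_real_, detectable = FALSE))
  }
  list(sos_doy = sos, eos_doy = eos, detectable = TRUE)
}

#' Season windows for one cell
#'
#' Month sets must be disjoint, cover all 12 months, and the active seasons
#' must appear in within-year order EGS before PGS before LGS; PGS has one
#' or two months.
#'
#' @param sos_doy,eos_doy detected phenological dates (day of year).
#' @param egs,pgs,lgs,ds integer month sets.
#' @param cell_id optional identifier carried along.
#' @return object of class `season_windows`.
#' @export
season_windows <- function(sos_doy, eos_doy, egs, pgs, lgs, ds,
                           cell_id = NA_character_) {
  w <- structure(list(cell_id = cell_id, sos_doy = sos_doy,
                      eos_doy = eos_doy,
                      months = list(EGS = as.integer(egs),
                                    PGS = as.integer(pgs),
                                    LGS = as.integer(lgs),
                                    DS = as.integer(ds))),
                 class = "season_windows")
  validate_season_windows(w)
  w
}

#' @rdname season_windows
#' @param w a `season_windows` object.
#' @export
validate_season_windows <- function(w) {
  m <- w$months
  all12 <- sort(unlist(m, use.names = FALSE))
  if (!identical(all12, 1:12)) {
    stop("season month sets must partition months 1..12 (cell ",
         w$cell_id, ")", call. = FALSE)
  }
  if (length(m$PGS) < 1L || length(m$PGS) > 2L) {
    stop("PGS must contain 1 or 2 months (cell ", w$cell_id, ")",
         call. = FALSE)
  }
  if (length(m$EGS) > 0L && max(m$EGS) >= min(m$PGS)) {
    stop("EGS months must precede PGS months (cell ", w$cell_id, ")",
         call. = FALSE)
  }
  if (length(m$LGS) > 0L && min(m$LGS) <= max(m$PGS)) {
    stop("LGS months must follow PGS months (cell ", w$cell_id, ")",
         call. = FALSE)
  }
  invisible(w)
}

#' @export
print.season_windows <- function(x, ...) {
  fm <- function(v) if (length(v)) paste(month.abb[v], collapse = ",") else "-"
  cat(sprintf("Season windows%s: SOS %.0f, EOS %.0f\n",
              if (is.na(x$cell_id)) "" else paste0(" [", x$cell_id, "]"),
              x$sos_doy, x$eos_doy))
  cat(sprintf("  EGS {%s}  PGS {%s}  LGS {%s}  DS {%s}\n",
              fm(x$months$EGS), fm(x$months$PGS), fm(x$months$LGS),
              fm(x$months$DS)))
  invisible(x)
}

#' Assign calendar months to EGS, PGS, LGS and DS
#'
#' The peak growing season (PGS) is the two consecutive months with the
#' largest summed climatological index, restricted to April-October (ties
#' broken toward the earlier pair); when the growing season spans three
#' months or fewer, PGS is the single month with the maximum value.  Cells
#' whose maximum-index month falls before April or after October are
#' excluded, as are cells whose growing-season maximum falls below
#' `min_ndvi` (non-vegetated).  EGS runs from the month containing SOS to
#' the month before PGS; LGS from the month after PGS to the month
#' containing EOS; the remaining months form the dormancy season.
#'
#' @param sos_doy,eos_doy detected dates from [detect_sos_eos()].
#' @param monthly_cycle numeric vector of length 12: climatological monthly
#'   means of the vegetation index.
#' @param min_ndvi non-vegetated threshold on the cycle maximum.
#' @param cell_id optional identifier used in messages.
#' @return a [season_windows()] object, or a `season_exclusion` object
#'   whose `reason` field is one of `"undetectable-phenology"`,
#'   `"non-vegetated"`, `"peak-outside-apr-oct"`.
#' @export
define_seasons <- function(sos_doy, eos_doy, monthly_cycle, min_ndvi = 0.1,
                           cell_id = NA_character_) {
  stopifnot(length(monthly_cycle) == 12)
  excl <- function(reason) {
    structure(list(cell_id = cell_id, reason = reason),
              class = "season_exclusion")
  }
  if (is.na(sos_doy) || is.na(eos_doy)) {
    return(excl("undetectable-phenology"))
  }
  if (max(monthly_cycle, na.rm = TRUE) < min_ndvi) {
    return(excl("non-vegetated"))
  }
  m_max <- which.max(monthly_cycle)
  if (m_max < 4L || m_max > 10L) {
    return(excl("peak-outside-apr-oct"))
  }
  sos_m <- .doy_month(sos_doy)
  eos_m <- .doy_month(eos_doy)
  gs_len <- eos_m - sos_m + 1L
  if (gs_len <= 3L) {
    pgs <- m_max
  } else {
    # best consecutive April-October pair; ties toward the earlier pair
    starts <- 4:9
    sums <- monthly_cycle[starts] + monthly_cycle[starts + 1L]
    s <- starts[which.max(sums)]
    pgs <- c(s, s + 1L)
  }
  if (min(pgs) <= sos_m) {
    stop("PGS would not follow the SOS month (cell ", cell_id, ")",
         call. = FALSE)
  }
  if (max(pgs) >= eos_m) {
    stop("PGS would not precede the EOS month (cell ", cell_id, ")",
         call. = FALSE)
  }
  egs <- seq.int(sos_m, min(pgs) - 1L)
  lgs <- seq.int(max(pgs) + 1L, eos_m)
  ds <- setdiff(1:12, c(egs, pgs, lgs))
  season_windows(sos_doy, eos_doy, egs, pgs, lgs, ds, cell_id = cell_id)
}

#' Delineate seasons for every cell of a biweekly field
#'
#' Convenience pipeline: per cell, builds the climatological biweekly cycle,
#' detects SOS/EOS from its interpolated slope, composites to a monthly
#' climatology, and assigns season windows.
#'
#' @param biweekly multi-cell biweekly series.
#' @param min_ndvi,min_amplitude thresholds passed on to [define_seasons()]
#'   and [detect_sos_eos()].
#' @return named list (by cell) of `season_windows` or `season_exclusion`
#'   objects.
#' @export
delineate_seasons <- function(biweekly, min_ndvi = 0.1,
                              min_amplitude = 0.05) {
  monthly <- composite_monthly_max(biweekly)
  out <- lapply(split(biweekly, biweekly$cell_id), function(bw) {
    cell <- bw$cell_id[1L]
    cyc <- climatological_cycle(bw)
    se <- detect_sos_eos(cyc, min_amplitude = min_amplitude)
    mo <- monthly[monthly$cell_id == cell, ]
    mcyc <- vapply(1:12, function(m) {
      v <- mo$value[mo$month == m]
      mean(v, na.rm = TRUE)
    }, numeric(1))
    define_seasons(se$sos_doy, se$eos_doy, mcyc, min_ndvi = min_ndvi,
                   cell_id = cell)
  })
  out
}

#' Detect SOS/EOS from daily productivity by the second-derivative method
#'
#' The daily series is smoothed with a spline, and the start of season is
#' the day of the maximum second derivative before the seasonal peak (onset
#' of accelerating growth) while the end of season is the day of the
#' minimum second derivative after the peak (onset of decline).  Sites with
#' more than `max_missing` of days missing are excluded.
#'
#' @param gpp daily productivity values.
#' @param doy day of year of each value (defaults to `seq_along(gpp)`).
#' @param spar smoothing parameter handed to [stats::smooth.spline()];
#'   0.6 by default (smooth enough to suppress synoptic noise without
#'   flattening the transitions).
#' @param max_missing maximum tolerated missing fraction.
#' @param min_amplitude minimum seasonal range, as in [detect_sos_eos()].
#' @return list with `sos_doy`, `eos_doy`, `detectable`.
#' @export
detect_sos_eos_gpp <- function(gpp, doy = seq_along(gpp), spar = 0.6,
                               max_missing = 0.2, min_amplitude = NULL) {
  ok <- !is.na(gpp)
  if (mean(!ok) > max_missing) {
    stop(sprintf("site excluded: %.0f%% of days missing (> %.0f%%)",
                 100 * mean(!ok), 100 * max_missing), call. = FALSE)
  }
  y <- gpp[ok]; x <- doy[ok]
  if (is.null(min_amplitude)) min_amplitude <- 0.05 * max(abs(y), 1e-12)
  if (diff(range(y)) < min_amplitude) {
    return(list(sos_doy = NA_real_, eos_doy = NA_real_, detectable = FALSE))
  }
  fit <- smooth.spline(x, y, spar = spar)
  grid <- seq(min(x), max(x), by = 0.25)
  sm <- predict(fit, grid)$y
  d2 <- predict(fit, grid, deriv = 2)$y
  peak <- grid[which.max(sm)]
  pre <- grid <= peak
  post <- grid >= peak
  sos <- grid[pre][which.max(d2[pre])]
  eos <- grid[post][which.min(d2[post])]
  list(sos_doy = sos, eos_doy = eos, detectable = TRUE)
}

#' Aggregate a monthly field to seasonal values
#'
#' Active-season values are computed from the member months of the same
#' calendar year.  The dormancy season spans the year boundary: months
#' after EOS are taken from year `t - 1` and months before SOS from year
#' `t`, and the result is attached to year `t` so that DS immediately
#' precedes the EGS it is paired with.  A season-year with any member month
#' missing is missing.
#'
#' @param monthly monthly field (`cell_id`, `year`, `month`, `variable`,
#'   `value`).
#' @param windows a `season_windows` object (single cell) or named list of
#'   them (multi-cell, names = cell ids; `NULL` entries are skipped).
#' @param sum_vars variables accumulated by summation instead of averaging
#'   (precipitation by default).
#' @return seasonal field (`cell_id`, `year`, `season`, `variable`,
#'   `value`).
#' @export
aggregate_seasonal <- function(monthly, windows, sum_vars = "PRE") {
  .assert_cols(monthly, c("cell_id", "year", "month", "variable", "value"),
               "monthly field")
  if (inherits(windows, "season_windows")) {
    cells <- unique(monthly$cell_id)
    if (length(cells) > 1L) {
      stop("single season_windows given for a multi-cell field", call. = FALSE)
    }
    windows <- setNames(list(windows), cells)
  }
  res <- list()
  for (cell in names(windows)) {
    w <- windows[[cell]]
    if (is.null(w) || !inherits(w, "season_windows")) next
    validate_season_windows(w)
    mo <- monthly[monthly$cell_id == cell, ]
    eos_m <- .doy_month(w$eos_doy)
    for (v in unique(mo$variable)) {
      mv <- mo[mo$variable == v, ]
      agg <- if (v %in% sum_vars) sum else mean
      for (s in SEASONS) {
        mm <- w$months[[s]]
        if (length(mm) == 0L) next
        # source year of each member month (DS wraps the year boundary)
        years <- sort(unique(mv$year))
        for (yr in years) {
          src_year <- rep(yr, length(mm))
          if (s == "DS") src_year[mm > eos_m] <- yr - 1L
          vals <- mv$value[match(paste(src_year, mm),
                                 paste(mv$year, mv$month))]
          val <- if (anyNA(vals)) NA_real_ else agg(vals)
          res[[length(res) + 1L]] <- data.frame(
            cell_id = cell, year = yr, season = s, variable = v,
            value = val, stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (length(res) == 0L) stop("no cell had defined season windows", call. = FALSE)
  out <- do.call(rbind, res)
  out[order(out$cell_id, out$variable, out$season, out$year), , drop = FALSE]
}
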