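# Tree-ring standardization and chronology construction: Tucson/RWL
# reader-writer, cubic-smoothing-spline detrending with a 50% frequency
# cutoff, Tukey biweight chronologies, and the interannual carryover
# analysis over chronology sets.

#' Read ring widths in Tucson (RWL) decadal format
#'
#' Each line carries a series id, the calendar year of the line's first
#' value, and up to ten annual values; a stop marker (999 for 0.01 mm
#' units, -9999 for 0.001 mm) ends a series.  A long CSV with columns
#' `series_id`, `year`, `width_mm` is accepted as a fallback with the same
#' output contract.
#'
#' @param path file path (`.rwl`/`.txt` Tucson or `.csv`).
#' @return long data frame `series_id`, `year`, `width_mm`.
#' @export
read_rwl <- function(path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    df <- read.csv(path, stringsAsFactors = FALSE)
    .assert_cols(df, c("series_id", "year", "width_mm"), "ring-width CSV")
    return(df[order(df$series_id, df$year), , drop = FALSE])
  }
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  recs <- list()
  for (li in seq_along(lines)) {
    tok <- strsplit(trimws(lines[li]), "[[:space:]]+")[[1L]]
    if (length(tok) < 3L) {
      stop(sprintf("RWL parse error at line %d: fewer than 3 fields", li),
           call. = FALSE)
    }
    id <- tok[1L]
    yr0 <- suppressWarnings(as.integer(tok[2L]))
    vals <- suppressWarnings(as.numeric(tok[-(1:2)]))
    if (is.na(yr0) || anyNA(vals)) {
      stop(sprintf("RWL parse error at line %d: non-numeric field", li),
           call. = FALSE)
    }
    recs[[li]] <- list(id = id, yr0 = yr0, vals = vals)
  }
  out <- list()
  for (id in unique(vapply(recs, `[[`, character(1), "id"))) {
    rr <- recs[vapply(recs, function(r) r$id == id, logical(1))]
    years <- integer(); vals <- numeric(); stopped <- FALSE
    last_year <- NA_integer_
    for (r in rr) {
      if (stopped) break
      if (!is.na(last_year) && r$yr0 != last_year + 1L) {
        stop(sprintf(
          "RWL decade misalignment in series %s: line starts at %d, expected %d",
          id, r$yr0, last_year + 1L), call. = FALSE)
      }
      for (i in seq_along(r$vals)) {
        v <- r$vals[i]
        if (v == 999 || v == -9999) {
          stopped <- TRUE
          if (v == -9999) attr(vals, "div") <- 1000
          break
        }
        years <- c(years, r$yr0 + i - 1L)
        vals <- c(vals, v)
      }
      last_year <- r$yr0 + length(r$vals) - 1L
    }
    div <- attr(vals, "div") %||% 100
    out[[id]] <- data.frame(series_id = id, year = years,
                            width_mm = as.numeric(vals) / div,
                            stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Write ring widths in Tucson (RWL) decadal format
#'
#' Values are written in 0.01 mm units with the conventional 999 stop
#' marker, ten values per decade line; [read_rwl()] round-trips the result
#' exactly at that precision.
#'
#' @param rwl long data frame `series_id`, `year`, `width_mm`.
#' @param path output path.
#' @export
write_rwl <- function(rwl, path) {
  .assert_cols(rwl, c("series_id", "year", "width_mm"), "ring-width table")
  con <- file(path, "w")
  on.exit(close(con))
  for (id in unique(rwl$series_id)) {
    d <- rwl[rwl$series_id == id, ]
    d <- d[order(d$year), ]
    vals <- as.integer(round(d$width_mm * 100))
    years <- d$year
    i <- 1L
    while (i <= length(years)) {
      yr <- years[i]
      dec_end <- (yr %/% 10L) * 10L + 9L
      j <- min(which(years > dec_end) - 1L, length(years))
      if (!length(j) || is.infinite(j)) j <- length(years)
      fields <- sprintf("%6d", vals[i:j])
      if (j == length(years)) fields <- c(fields, sprintf("%6d", 999L))
      writeLines(sprintf("%-8s%4d%s", id, yr,
                         paste(fields, collapse = "")), con)
      i <- j + 1L
    }
  }
  invisible(path)
}

# cubic smoothing spline (discrete second-difference penalty) with the
# 50% frequency-response cutoff at wavelength nyrs
.css_fit <- function(y, nyrs) {
  n <- length(y)
  if (nyrs <= 1) stop("nyrs must exceed 1 year", call. = FALSE)
  lam <- 1 / (2 - 2 * cos(2 * pi / nyrs))^2
  D <- diff(diag(n), differences = 2L)
  A <- diag(n) + lam * crossprod(D)
  as.vector(solve(A, y))
}

#' Standardize a ring-width series with a cubic smoothing spline
#'
#' Fits a cubic smoothing spline whose frequency response is 50 percent at
#' the cutoff wavelength (by default two-thirds of the series length, the
#' dendrochronological convention) and returns the ratio index
#' `raw / fitted`.  The spline removes the low-frequency age/size trend
#' while preserving interannual to interdecadal variability; because the
#' index is a ratio, rescaling the raw series leaves it unchanged.
#'
#' @param widths raw widths (mm), ordered by year, no gaps.
#' @param nyrs cutoff wavelength in years; default `stiffness *
#'   length(widths)`.
#' @param stiffness cutoff as a fraction of series length (default 0.67).
#' @return list: `index`, `fitted`, `nyrs`.
#' @export
spline_detrend <- function(widths, nyrs = NULL, stiffness = 0.67) {
  if (anyNA(widths)) stop("widths contain gaps; split or fill first",
                          call. = FALSE)
  n <- length(widths)
  if (n < 10L) stop("series too short to detrend", call. = FALSE)
  if (is.null(nyrs)) nyrs <- stiffness * n
  fitted <- .css_fit(widths, nyrs)
  if (any(fitted <= 0)) {
    stop("spline fit is nonpositive; series must be excluded", call. = FALSE)
  }
  list(index = widths / fitted, fitted = fitted, nyrs = nyrs)
}

#' Standardize every series of a ring-width table
#'
#' Applies [spline_detrend()] per series; series shorter than `min_years`
#' (25 by default, the usual chronology inclusion rule), series with
#' internal year gaps, and series whose spline fit goes nonpositive are
#' excluded and reported.
#'
#' @param rwl long data frame `series_id`, `year`, `width_mm`.
#' @param stiffness,nyrs passed to [spline_detrend()].
#' @param min_years minimum series length.
#' @return long data frame `series_id`, `year`, `index`, with attribute
#'   `excluded` (named character vector of reasons).
#' @export
standardize_rwl <- function(rwl, stiffness = 0.67, nyrs = NULL,
                            min_years = 25L) {
  .assert_cols(rwl, c("series_id", "year", "width_mm"), "ring-width table")
  out <- list()
  excluded <- character()
  for (id in unique(rwl$series_id)) {
    d <- rwl[rwl$series_id == id, ]
    d <- d[order(d$year), ]
    if (nrow(d) < min_years) {
      excluded[id] <- sprintf("shorter than %d years", min_years)
      next
    }
    if (any(diff(d$year) != 1L)) {
      excluded[id] <- "year gaps"
      next
    }
    det <- tryCatch(spline_detrend(d$width_mm, nyrs = nyrs,
                                   stiffness = stiffness),
                    error = function(e) NULL)
    if (is.null(det)) {
      excluded[id] <- "nonpositive spline fit"
      next
    }
    out[[id]] <- data.frame(series_id = id, year = d$year,
                            index = det$index, stringsAsFactors = FALSE)
  }
  if (length(out) == 0L) stop("no series survived standardization",
                              call. = FALSE)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "excluded") <- excluded
  res
}

#' Tukey biweight robust location
#'
#' Iteratively reweighted biweight mean with tuning constant `c` times the
#' median absolute deviation; observations beyond the tuning radius get
#' zero weight, so a single wild value barely moves the estimate.  When
#' the MAD is (numerically) zero the median is returned.
#'
#' @param x numeric values (`NA`s dropped).
#' @param c tuning constant (default 9, the standard choice for
#'   chronology building).
#' @param tol,max_iter convergence controls.
#' @return the biweight location estimate (scalar).
#' @export
biweight_mean <- function(x, c = 9, tol = 1e-8, max_iter = 50L) {
  x <- x[!is.na(x)]
  if (length(x) == 0L) return(NA_real_)
  m <- median(x)
  for (it in seq_len(max_iter)) {
    mad_ <- median(abs(x - m))
    if (mad_ < 1e-12 * max(1, abs(m))) return(median(x))
    u <- (x - m) / (c * mad_)
    w <- ifelse(abs(u) < 1, (1 - u^2)^2, 0)
    if (sum(w) == 0) return(m)
    m_new <- sum(w * x) / sum(w)
    if (abs(m_new - m) < tol) return(m_new)
    m <- m_new
  }
  m
}

#' Build a site chronology from standardized indices
#'
#' Averages tree-level standardized indices per year with the Tukey
#' biweight robust mean and records the sample depth; years with fewer
#' than `min_depth` overlapping series are left missing.
#'
#' @param indices long data frame `series_id`, `year`, `index` (from
#'   [standardize_rwl()]) or a year-by-series matrix with years as row
#'   names.
#' @param min_depth minimum series per retained year (default 2).
#' @param site_id identifier stored with the chronology.
#' @return data frame of class `chronology`: `year`, `index`, `depth`.
#' @export
build_chronology <- function(indices, min_depth = 2L, site_id = "site") {
  if (is.matrix(indices)) {
    years <- as.integer(rownames(indices))
    mat <- indices
  } else {
    .assert_cols(indices, c("series_id", "year", "index"), "index table")
    years <- sort(unique(indices$year))
    sids <- unique(indices$series_id)
    mat <- matrix(NA_real_, length(years), length(sids),
                  dimnames = list(years, sids))
    mat[cbind(match(indices$year, years),
              match(indices$series_id, sids))] <- indices$index
  }
  depth <- rowSums(!is.na(mat))
  idx <- vapply(seq_along(years), function(i) {
    if (depth[i] < min_depth) NA_real_ else biweight_mean(mat[i, ])
  }, numeric(1))
  out <- data.frame(year = years, index = idx, depth = as.integer(depth))
  attr(out, "site_id") <- site_id
  class(out) <- c("chronology", "data.frame")
  out
}

#' Interannual carryover of tree-ring chronologies
#'
#' Runs the lead-1..3 lagged partial autocorrelation (see
#' [lagged_pacf()]) on every chronology, controlling annual climate when
#' supplied, and returns one row per (site, lead) ready for
#' [sign_frequency_summary()].  Chronologies are linearly detrended inside
#' the lagged analysis.
#'
#' @param chronologies long data frame `site_id`, `year`, `index`, or a
#'   named list of [build_chronology()] outputs.
#' @param climate optional data frame `year` plus covariate columns
#'   (e.g. `TMP`, `PRE`: annual or growing-season means), matched to each
#'   site by year.
#' @param groups optional named vector mapping site ids to wood-porosity
#'   (or other) groups; unlabelled sites are reported as `"ungrouped"`.
#' @param max_lead largest lead in years.
#' @param min_years minimum usable years per site.
#' @return data frame `site_id`, `group`, `lead`, `coefficient`,
#'   `p_value`, `n`.
#' @export
chronology_vgc <- function(chronologies, climate = NULL, groups = NULL,
                           max_lead = 3L, min_years = 15L) {
  if (is.list(chronologies) && !is.data.frame(chronologies)) {
    chronologies <- do.call(rbind, lapply(names(chronologies), function(s) {
      d <- chronologies[[s]]
      data.frame(site_id = s, year = d$year, index = d$index,
                 stringsAsFactors = FALSE)
    }))
  }
  .assert_cols(chronologies, c("site_id", "year", "index"),
               "chronology table")
  out <- list()
  for (site in unique(chronologies$site_id)) {
    d <- chronologies[chronologies$site_id == site, ]
    d <- d[order(d$year), ]
    ok <- !is.na(d$index)
    d <- d[ok, ]
    if (nrow(d) < min_years) next
    clim <- NULL
    if (!is.null(climate)) {
      cc <- climate[match(d$year, climate$year), , drop = FALSE]
      clim <- as.matrix(cc[, setdiff(names(cc), "year"), drop = FALSE])
      keep <- stats::complete.cases(clim)
      d <- d[keep, , drop = FALSE]
      clim <- clim[keep, , drop = FALSE]
      if (nrow(d) < min_years) next
    }
    pac <- lagged_pacf(d$index, climate = clim, max_lead = max_lead)
    g <- if (!is.null(groups) && !is.na(groups[site] %||% NA)) {
      unname(groups[site])
    } else {
      "ungrouped"
    }
    out[[site]] <- data.frame(site_id = site, group = g, lead = pac$lead,
                              coefficient = pac$coefficient,
                              p_value = pac$p_value, n = pac$n,
                              stringsAsFactors = FALSE)
  }
  if (length(out) == 0L) stop("no chronology long enough", call. = FALSE)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
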