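# Shared data model, compositing, masking, aggregation and long-CSV I/O.

`%||%` <- function(a, b) if (is.null(a)) b else a

.assert_cols <- function(df, cols, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss) > 0L) {
    stop(sprintf("%s is missing column(s): %s", what,
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  invisible(df)
}

#' Validate a biweekly vegetation-index series
#'
#' A biweekly series holds up to 24 composites per calendar year
#' (periods `2k - 1` and `2k` belong to month `k`).  Missing composites are
#' represented as `NA`, never dropped silently by downstream compositing.
#'
#' @param df data frame with columns `cell_id`, `year`, `period`, `value`.
#' @return `df`, invisibly, after validation.
#' @export
validate_biweekly <- function(df) {
  .assert_cols(df, c("cell_id", "year", "period", "value"), "biweekly series")
  bad <- which(!is.na(df$period) & (df$period < 1L | df$period > 24L |
                                      df$period != floor(df$period)))
  if (length(bad) > 0L) {
    i <- bad[1L]
    stop(sprintf("malformed composite period %s (cell %s, year %s)",
                 df$period[i], df$cell_id[i], df$year[i]), call. = FALSE)
  }
  key <- paste(df$cell_id, df$year, df$period, sep = "\r")
  if (anyDuplicated(key)) {
    stop("duplicate (cell, year, period) records in biweekly series",
         call. = FALSE)
  }
  invisible(df)
}

#' Composite biweekly values to monthly maxima
#'
#' Maximum-value compositing: the monthly value is the largest non-missing
#' composite of that month, the standard way of suppressing cloud and
#' atmospheric contamination in AVHRR-era vegetation indices.  Months whose
#' composites are all missing stay missing.
#'
#' @param biweekly data frame with columns `cell_id`, `year`, `period`
#'   (1-24) and `value`.
#' @param variable name recorded in the `variable` column of the output.
#' @return monthly field: `cell_id`, `year`, `month`, `variable`, `value`.
#' @examples
#' bw <- data.frame(cell_id = "c1", year = 2000, period = 1:2,
#'                  value = c(0.30, 0.45))
#' composite_monthly_max(bw)$value  # 0.45
#' @export
composite_monthly_max <- function(biweekly, variable = "NDVI") {
  validate_biweekly(biweekly)
  month <- (biweekly$period + 1L) %/% 2L
  key <- interaction(biweekly$cell_id, biweekly$year, month, drop = TRUE)
  mx <- tapply(biweekly$value, key, function(v) {
    v <- v[!is.na(v)]
    if (length(v) == 0L) NA_real_ else max(v)
  })
  parts <- do.call(rbind, strsplit(names(mx), ".", fixed = TRUE))
  out <- data.frame(cell_id = parts[, 1L],
                    year = as.integer(parts[, 2L]),
                    month = as.integer(parts[, 3L]),
                    variable = variable,
                    value = as.numeric(mx),
                    stringsAsFactors = FALSE)
  out[order(out$cell_id, out$year, out$month), , drop = FALSE]
}

#' Label cells by dominant vegetation cover
#'
#' A cell is assigned to a vegetation class only when that class covers more
#' than `threshold` of the cell's area; all other cells are excluded, which
#' limits the confounding of mixed land cover and cover change.
#'
#' @param fractions data frame with columns `cell_id`, `class`, `fraction`
#'   (fractions within a cell must be nonnegative and sum to at most 1).
#' @param threshold dominance threshold in (0, 1]; default 0.6, i.e. the
#'   class must occupy more than 60 percent of the cell.
#' @return data frame `cell_id`, `class` (`NA` for excluded cells),
#'   `fraction` of the winning class.
#' @export
dominant_cover_mask <- function(fractions, threshold = 0.6) {
  .assert_cols(fractions, c("cell_id", "class", "fraction"), "cover fractions")
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      threshold <= 0 || threshold > 1) {
    stop("threshold must be a single value in (0, 1]", call. = FALSE)
  }
  if (any(fractions$fraction < 0, na.rm = TRUE)) {
    stop("negative cover fractions", call. = FALSE)
  }
  tot <- tapply(fractions$fraction, fractions$cell_id, sum, na.rm = TRUE)
  if (any(tot > 1 + 1e-8)) {
    stop("cover fractions exceed 1 for cell(s): ",
         paste(names(tot)[tot > 1 + 1e-8], collapse = ", "), call. = FALSE)
  }
  sp <- split(fractions, fractions$cell_id)
  res <- lapply(sp, function(d) {
    i <- which.max(d$fraction)
    win <- d$fraction[i] > threshold
    data.frame(cell_id = d$cell_id[1L],
               class = if (win) d$class[i] else NA_character_,
               fraction = d$fraction[i],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Cosine-latitude area weights
#'
#' On a regular longitude-latitude grid the area of a cell is proportional
#' to the cosine of its latitude; these are the default weights for
#' hemispheric averages.
#'
#' @param cells data frame with columns `cell_id` and `lat` (degrees north).
#' @return data frame `cell_id`, `weight`.
#' @export
cos_lat_weights <- function(cells) {
  .assert_cols(cells, c("cell_id", "lat"), "cell table")
  if (any(abs(cells$lat) > 90, na.rm = TRUE)) {
    stop("latitudes must lie in [-90, 90]", call. = FALSE)
  }
  data.frame(cell_id = cells$cell_id,
             weight = cos(cells$lat * pi / 180),
             stringsAsFactors = FALSE)
}

#' Area-weighted mean of a seasonal field
#'
#' Collapses a per-cell seasonal field to one hemispheric (or regional)
#' series per (year, season, variable).  Cells with missing values are
#' dropped from both numerator and denominator; a (year, season, variable)
#' combination where every cell is missing yields `NA`.
#'
#' @param field seasonal field: `cell_id`, `year`, `season`, `variable`,
#'   `value`.
#' @param weights data frame `cell_id`, `weight` with nonnegative weights,
#'   or `NULL` for an unweighted mean.  Uniform rescaling of the weights
#'   does not change the result.
#' @return data frame `year`, `season`, `variable`, `value`.
#' @export
area_weighted_mean <- function(field, weights = NULL) {
  .assert_cols(field, c("cell_id", "year", "season", "variable", "value"),
               "seasonal field")
  if (is.null(weights)) {
    w <- rep(1, nrow(field))
  } else {
    .assert_cols(weights, c("cell_id", "weight"), "weights")
    if (any(weights$weight < 0, na.rm = TRUE)) {
      stop("weights must be nonnegative", call. = FALSE)
    }
    w <- weights$weight[match(field$cell_id, weights$cell_id)]
    if (anyNA(w[!is.na(field$value)])) {
      stop("weights do not cover all non-missing cells", call. = FALSE)
    }
  }
  key <- interaction(field$year, field$season, field$variable, drop = TRUE)
  ok <- !is.na(field$value) & !is.na(w)
  num <- tapply(ifelse(ok, field$value * w, 0), key, sum)
  den <- tapply(ifelse(ok, w, 0), key, sum)
  if (all(den == 0)) stop("no positive weight in any aggregation", call. = FALSE)
  first <- !duplicated(key)
  out <- data.frame(year = field$year[first],
                    season = field$season[first],
                    variable = field$variable[first],
                    value = as.numeric(num[match(key[first], names(num))] /
                                         ifelse(den[match(key[first], names(den))] == 0,
                                                NA_real_,
                                                den[match(key[first], names(den))])),
                    stringsAsFactors = FALSE)
  out[order(out$variable, out$season, out$year), , drop = FALSE]
}

#' Read / write long-format field tables
#'
#' The package's interchange format is a long CSV table; `read_field_csv`
#' checks the presence of the core key columns for the requested layout.
#'
#' @param path file path.
#' @param layout one of `"monthly"`, `"seasonal"`, `"biweekly"`.
#' @return data frame in the corresponding layout.
#' @export
read_field_csv <- function(path, layout = c("monthly", "seasonal", "biweekly")) {
  layout <- match.arg(layout)
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- switch(layout,
                 monthly  = c("cell_id", "year", "month", "variable", "value"),
                 seasonal = c("cell_id", "year", "season", "variable", "value"),
                 biweekly = c("cell_id", "year", "period", "value"))
  .assert_cols(df, need, sprintf("%s CSV '%s'", layout, path))
  df
}

#' @rdname read_field_csv
#' @param df data frame to write.
#' @export
write_field_csv <- function(df, path) {
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
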