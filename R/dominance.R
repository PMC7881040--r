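# Per-cell classification of the dominant driver of interannual vegetation
# variation (carryover vs concurrent vs preceding-season climate) and
# area-fraction summaries for observation-model comparison.

#' Dominant-driver label vocabulary
#'
#' The three driver families a cell can be assigned to: vegetation growth
#' carryover, concurrent climate, preceding-season climate.
#' @export
DRIVER_LABELS <- c("VGC", "concurrent_climate", "preceding_climate")

#' Classify the dominant driver per cell
#'
#' Scores each cell of a carryover profile on three families: the absolute
#' partial correlation of preceding-season vegetation (carryover), the
#' stronger of the two concurrent climate coefficients, and the stronger of
#' the two preceding-season climate coefficients.  The label is the family
#' with the largest score; exact ties fall to the fixed priority carryover
#' > concurrent > preceding and are flagged.  Cells with any undefined
#' score stay unlabeled.  Rescaling all coefficients by a common factor
#' does not change the labels.
#'
#' @param profile output of [seasonal_vgc_profile()] (per-cell rows with a
#'   `role` column).
#' @param collapse how the two members of each climate family combine:
#'   `"max"` of absolute coefficients (default) or root sum of squares
#'   (`"sumsq"`).
#' @return data frame `cell_id`, `label` (`NA` when unlabeled), `score`,
#'   `tie`.
#' @export
classify_dominant_driver <- function(profile, collapse = c("max", "sumsq")) {
  collapse <- match.arg(collapse)
  .assert_cols(profile, c("cell_id", "role", "r_p"), "carryover profile")
  comb <- if (collapse == "max") {
    function(a, b) pmax(abs(a), abs(b))
  } else {
    function(a, b) sqrt(a^2 + b^2)
  }
  get <- function(role) {
    d <- profile[profile$role == role, ]
    setNames(d$r_p, d$cell_id)
  }
  vgc <- get("carryover")
  cells <- names(vgc)
  scores <- cbind(
    VGC = abs(vgc),
    concurrent_climate = comb(get("concurrent_tmp")[cells],
                              get("concurrent_pre")[cells]),
    preceding_climate = comb(get("preceding_tmp")[cells],
                             get("preceding_pre")[cells]))
  label <- rep(NA_character_, length(cells))
  best <- rep(NA_real_, length(cells))
  tie <- rep(FALSE, length(cells))
  ok <- stats::complete.cases(scores)
  if (any(ok)) {
    s <- scores[ok, , drop = FALSE]
    win <- apply(s, 1L, which.max)         # ties -> first = priority order
    label[ok] <- DRIVER_LABELS[win]
    best[ok] <- s[cbind(seq_len(nrow(s)), win)]
    tie[ok] <- apply(s, 1L, function(v) sum(v == max(v)) > 1L)
  }
  data.frame(cell_id = cells, label = label, score = best, tie = tie,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Area fractions of dominant-driver labels
#'
#' Weighted share of each driver label over the labeled cells; fractions
#' sum to one and are invariant to uniform weight rescaling.  The weight
#' fraction of unlabeled cells is reported separately.
#'
#' @param labels output of [classify_dominant_driver()] (or any data frame
#'   with `cell_id` and `label`).
#' @param weights optional `cell_id` / `weight` table; `NULL` for equal
#'   weights.
#' @return named numeric vector of fractions per label, with attributes
#'   `unlabeled_fraction` and `n_labeled`.
#' @export
area_fractions <- function(labels, weights = NULL) {
  .assert_cols(labels, c("cell_id", "label"), "label map")
  w <- if (is.null(weights)) {
    rep(1, nrow(labels))
  } else {
    weights$weight[match(labels$cell_id, weights$cell_id)]
  }
  lab <- labels$label
  ok <- !is.na(lab)
  if (!any(ok)) stop("all cells are unlabeled", call. = FALSE)
  tot <- sum(w[ok])
  fr <- vapply(DRIVER_LABELS, function(L) sum(w[ok & lab == L]) / tot,
               numeric(1))
  structure(fr,
            unlabeled_fraction = sum(w[!ok]) / sum(w),
            n_labeled = sum(ok))
}

#' Compare observed and modeled driver-dominance fractions
#'
#' For each model, the signed difference from the observed fraction per
#' label; additionally counts how many models fall under/over the observed
#' carryover-dominated fraction and reports the ensemble mean.
#'
#' @param observed named fraction vector (as from [area_fractions()]).
#' @param models named list of fraction vectors with the same labels.
#' @return list: `differences` (model-by-label matrix of model minus
#'   observed), `n_under_vgc`, `n_over_vgc`, `ensemble_mean`.
#' @export
compare_fraction_sets <- function(observed, models) {
  labs <- names(observed)
  if (is.null(labs)) stop("observed fractions must be named", call. = FALSE)
  for (m in names(models)) {
    if (!setequal(names(models[[m]]), labs)) {
      stop("label mismatch in model '", m, "'", call. = FALSE)
    }
  }
  mat <- do.call(rbind, lapply(models, function(v) v[labs]))
  diffs <- sweep(mat, 2L, as.numeric(observed[labs]))
  vgc_obs <- observed[["VGC"]]
  list(differences = diffs,
       n_under_vgc = sum(mat[, "VGC"] < vgc_obs),
       n_over_vgc = sum(mat[, "VGC"] > vgc_obs),
       ensemble_mean = colMeans(mat))
}
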