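# Small in-code fixtures shared across test files.

# long seasonal field from named per-variable matrices (years x cells)
make_seasonal <- function(mats, season, cells = NULL, years = NULL) {
  out <- list()
  for (v in names(mats)) {
    m <- mats[[v]]
    yrs <- years %||% seq_len(nrow(m))
    cls <- cells %||% sprintf("c%03d", seq_len(ncol(m)))
    out[[v]] <- data.frame(cell_id = rep(cls, each = length(yrs)),
                           year = rep(yrs, ncol(m)), season = season,
                           variable = v, value = as.vector(m),
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# independent partial-correlation oracle via the inverse correlation matrix,
# written without reference to the package implementation
pcor_matrix_oracle <- function(y, x, controls) {
  R <- stats::cor(cbind(y, x, controls))
  P <- solve(R)
  -P[1, 2] / sqrt(P[1, 1] * P[2, 2])
}

# seasonal field with only an EGS->PGS carryover link, used by several tests
simulate_carryover_pair <- function(n_cells, n_years, gamma, noise_sd = 1,
                                    seed = 1) {
  cfg <- seasonal_system_config(
    n_cells = n_cells, n_years = n_years,
    gamma = c(lgs_egs = 0, egs_pgs = gamma, pgs_lgs = 0),
    beta_t = 0, beta_p = 0, beta_t_ps = 0, beta_p_ps = 0,
    noise_sd = noise_sd, tmp_trend_decade = 0, seed = seed)
  simulate_seasonal_system(cfg)
}
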