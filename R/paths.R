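# Recursive path analysis of the seasonal vegetation-climate-soil network:
# equation-wise least squares on standardized observed variables, effect
# decomposition by path tracing, and the sign-based rule for orienting the
# soil-moisture / vegetation edge.

#' Declare a recursive path model
#'
#' Nodes are observed variables; directed edges state the hypothesized
#' direction of causation and must form an acyclic graph; covariance pairs
#' among exogenous nodes are allowed (they are left free, as the estimator
#' conditions on the exogenous variables jointly).
#'
#' @param edges data frame with columns `from`, `to`.
#' @param covariances optional data frame `a`, `b` of exogenous covariance
#'   pairs.
#' @param nodes node names; defaults to every name appearing in `edges`.
#' @return object of class `path_model_spec` with a stored topological
#'   order.
#' @export
path_model_spec <- function(edges, covariances = NULL, nodes = NULL) {
  .assert_cols(edges, c("from", "to"), "edge table")
  nodes <- nodes %||% unique(c(edges$from, edges$to))
  bad <- setdiff(c(edges$from, edges$to), nodes)
  if (length(bad)) stop("edge endpoints not declared as nodes: ",
                        paste(bad, collapse = ", "), call. = FALSE)
  # Kahn topological sort; leftovers form a cycle
  indeg <- setNames(integer(length(nodes)), nodes)
  for (v in edges$to) indeg[v] <- indeg[v] + 1L
  order <- character()
  queue <- names(indeg)[indeg == 0L]
  indeg2 <- indeg
  while (length(queue)) {
    v <- queue[1L]; queue <- queue[-1L]
    order <- c(order, v)
    outs <- edges$to[edges$from == v]
    for (u in outs) {
      indeg2[u] <- indeg2[u] - 1L
      if (indeg2[u] == 0L) queue <- c(queue, u)
    }
  }
  if (length(order) < length(nodes)) {
    stop("edges contain a cycle through: ",
         paste(setdiff(nodes, order), collapse = ", "), call. = FALSE)
  }
  structure(list(nodes = nodes, edges = edges, covariances = covariances,
                 order = order),
            class = "path_model_spec")
}

#' Fit a recursive path model by equation-wise least squares
#'
#' All variables are standardized to unit variance; each endogenous node is
#' regressed on its declared parents, so the coefficients are standardized
#' partial regression weights (path coefficients) with per-equation t-test
#' p-values, and each endogenous node reports its explained variance.  For
#' recursive models of observed variables these estimates coincide with the
#' maximum-likelihood point estimates.  As a goodness summary the maximum
#' absolute difference between the observed and the model-implied
#' correlation matrix is reported.
#'
#' @param data data frame whose columns include every node, one row per
#'   observation (grid cell, year, or site-year).
#' @param spec a [path_model_spec()].
#' @return object of class `path_fit`: `edges` (`from`, `to`,
#'   `coefficient`, `p_value`), `r_squared` (named, endogenous nodes),
#'   `max_resid_cor`, `n`, `spec`.
#' @export
fit_recursive_paths <- function(data, spec) {
  stopifnot(inherits(spec, "path_model_spec"))
  miss <- setdiff(spec$nodes, names(data))
  if (length(miss)) stop("data lacks node variable(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  X <- as.matrix(data[, spec$nodes, drop = FALSE])
  X <- X[stats::complete.cases(X), , drop = FALSE]
  n <- nrow(X)
  max_indeg <- max(table(factor(spec$edges$to, levels = spec$nodes)))
  if (n <= max_indeg + 2L) stop("too few observations for the densest node",
                                call. = FALSE)
  Z <- scale(X)
  edges <- spec$edges
  edges$coefficient <- NA_real_
  edges$p_value <- NA_real_
  endo <- unique(edges$to)
  r2 <- setNames(rep(NA_real_, length(endo)), endo)
  for (v in endo) {
    parents <- edges$from[edges$to == v]
    M <- cbind(1, Z[, parents, drop = FALSE])
    fit <- lm.fit(M, Z[, v])
    dof <- n - ncol(M)
    sigma2 <- sum(fit$residuals^2) / dof
    se <- sqrt(diag(sigma2 * solve(crossprod(M))))
    b <- fit$coefficients[-1L]
    tt <- b / se[-1L]
    pp <- 2 * pt(-abs(tt), dof)
    for (k in seq_along(parents)) {
      i <- edges$from == parents[k] & edges$to == v
      edges$coefficient[i] <- b[k]
      edges$p_value[i] <- pp[k]
    }
    r2[v] <- 1 - sum(fit$residuals^2) / sum((Z[, v] - mean(Z[, v]))^2)
  }
  # model-implied correlations in topological order
  obs <- cor(Z)
  imp <- matrix(NA_real_, length(spec$nodes), length(spec$nodes),
                dimnames = list(spec$nodes, spec$nodes))
  exo <- setdiff(spec$nodes, endo)
  imp[exo, exo] <- obs[exo, exo]
  placed <- exo
  for (v in spec$order) {
    if (v %in% exo) next
    parents <- edges$from[edges$to == v]
    b <- edges$coefficient[edges$to == v]
    for (z in placed) {
      imp[v, z] <- imp[z, v] <- sum(b * imp[parents, z])
    }
    imp[v, v] <- 1
    placed <- c(placed, v)
  }
  structure(list(edges = edges, r_squared = r2,
                 max_resid_cor = max(abs(obs - imp), na.rm = TRUE),
                 n = n, spec = spec),
            class = "path_fit")
}

#' @export
print.path_fit <- function(x, ...) {
  cat(sprintf("Recursive path model (n = %d):\n", x$n))
  for (i in seq_len(nrow(x$edges))) {
    e <- x$edges[i, ]
    cat(sprintf("  %s -> %s: %.3f (p = %.3g)\n",
                e$from, e$to, e$coefficient, e$p_value))
  }
  cat("  r-squared:",
      paste(sprintf("%s %.3f", names(x$r_squared), x$r_squared),
            collapse = ", "), "\n")
  cat(sprintf("  max |observed - implied| correlation: %.4g\n",
              x$max_resid_cor))
  invisible(x)
}

# all directed paths from source to target (list of node vectors)
.enumerate_paths <- function(edges, source, target) {
  paths <- list()
  walk <- function(node, trail) {
    if (node == target && length(trail) > 1L) {
      paths[[length(paths) + 1L]] <<- trail
      return(invisible())
    }
    for (nxt in edges$to[edges$from == node]) {
      if (!(nxt %in% trail)) walk(nxt, c(trail, nxt))
    }
  }
  walk(source, source)
  paths
}

#' Direct, indirect and total effects along a fitted path model
#'
#' The indirect effect of `source` on `target` is the sum over all
#' directed paths (excluding the single direct edge) of the products of
#' their path coefficients; the total effect adds the direct edge.  The
#' identity total = direct + indirect holds by construction.
#'
#' @param fit a [fit_recursive_paths()] result.
#' @param source,target node names.
#' @return for `indirect_effect`, the indirect effect (0 with attribute
#'   `note = "no-path"` when no connecting path exists); `direct_effect`
#'   and `total_effect` analogous.
#' @export
indirect_effect <- function(fit, source, target) {
  stopifnot(inherits(fit, "path_fit"))
  e <- fit$edges
  paths <- .enumerate_paths(e, source, target)
  indirect <- paths[vapply(paths, length, integer(1)) > 2L]
  if (length(paths) == 0L) {
    return(structure(0, note = "no-path"))
  }
  if (length(indirect) == 0L) return(0)
  sum(vapply(indirect, function(p) {
    prod(vapply(seq_len(length(p) - 1L), function(i) {
      e$coefficient[e$from == p[i] & e$to == p[i + 1L]]
    }, numeric(1)))
  }, numeric(1)))
}

#' @rdname indirect_effect
#' @export
direct_effect <- function(fit, source, target) {
  e <- fit$edges
  i <- e$from == source & e$to == target
  if (any(i)) e$coefficient[i] else 0
}

#' @rdname indirect_effect
#' @export
total_effect <- function(fit, source, target) {
  direct_effect(fit, source, target) + as.numeric(indirect_effect(fit, source, target))
}

#' Orient the soil-moisture / vegetation edge by correlation sign
#'
#' Positive correlation between soil moisture and greenness is read as
#' soil moisture stimulating growth (moisture drives vegetation); negative
#' correlation as growth depleting the store (vegetation drives soil
#' moisture); correlations smaller in magnitude than `threshold` are left
#' undetermined.
#'
#' @param sm,ndvi aligned series (n >= 10 after missing removal).
#' @param threshold minimum |r| to call a direction (default 0.05).
#' @return list: `direction` (one of
#'   `"soil-moisture-drives-vegetation"`,
#'   `"vegetation-depletes-soil-moisture"`, `"undetermined"`,
#'   `"undefined"` for constant input), `correlation`, `n`.
#' @export
sm_vegetation_causality <- function(sm, ndvi, threshold = 0.05) {
  ok <- stats::complete.cases(sm, ndvi)
  sm <- sm[ok]; ndvi <- ndvi[ok]
  n <- length(sm)
  if (n < 10L) stop("need at least 10 paired values", call. = FALSE)
  if (sd(sm) == 0 || sd(ndvi) == 0) {
    return(list(direction = "undefined", correlation = NA_real_, n = n))
  }
  r <- cor(sm, ndvi)
  dir <- if (abs(r) < threshold) {
    "undetermined"
  } else if (r > 0) {
    "soil-moisture-drives-vegetation"
  } else {
    "vegetation-depletes-soil-moisture"
  }
  list(direction = dir, correlation = r, n = n)
}
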