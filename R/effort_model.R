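# Visit-count model: quasi-Poisson GLM of sampling effort on
# accessibility and attractiveness covariates, with collinearity (VIF)
# and spatial-autocorrelation (Moran's I) diagnostics. A spatially
# correlated random effect is deliberately not fitted; overdispersion
# scaling plus a permutation Moran's I on the residuals stands in as the
# diagnostic, so inference is approximate while point estimates are
# ordinary GLM estimates.

.effort_predictors <- c("log_dist_hub", "dist_road", "protected", "urban",
                        "cultivated", "precip", "t_summer", "t_winter")

#' Build an effort-model design table from a landscape
#'
#' Assembles the response (visits per pentad) and the standard predictor
#' set: log-transformed hub distance (natural log; hub pentads are
#' excluded upstream so the distance is strictly positive), road
#' distance in km, the three cover fractions, and the three climate
#' variables standardized within the design for conditioning
#' (coefficients are then on the per-SD scale).
#'
#' @param covariates a `pentad_covariates` table with distance columns.
#' @param effort data.frame `pentad`, `visits`.
#' @param coords optional data.frame `pentad`, `midpoint_lat`,
#'   `midpoint_lon` for spatial diagnostics.
#' @param group optional named vector: pentad -> group label (province
#'   analogue); stored as column `group`.
#' @return an `effort_design` data.frame.
#' @export
effort_design <- function(covariates, effort, coords = NULL, group = NULL) {
  m <- merge(as.data.frame(covariates), effort[, c("pentad", "visits")],
             by = "pentad")
  if (any(m$dist_hub_km <= 0)) {
    stop("hub pentads (zero hub distance) must not enter the design",
         call. = FALSE)
  }
  z <- function(x) as.numeric(scale(x))
  out <- data.frame(
    pentad = m$pentad, visits = as.integer(m$visits),
    log_dist_hub = log(m$dist_hub_km), dist_road = m$dist_road_km,
    protected = m$protected, urban = m$urban, cultivated = m$cultivated,
    precip = z(m$precip), t_summer = z(m$t_summer), t_winter = z(m$t_winter),
    stringsAsFactors = FALSE
  )
  if (!is.null(group)) out$group <- unname(group[out$pentad])
  if (!is.null(coords)) {
    out <- merge(out, coords[, c("pentad", "midpoint_lat", "midpoint_lon")],
                 by = "pentad")
  }
  stopifnot(all(is.finite(as.matrix(out[, .effort_predictors]))),
            all(out$visits >= 0))
  class(out) <- c("effort_design", "data.frame")
  out
}

#' Fit the quasi-Poisson effort model
#'
#' Log-link Poisson regression of visits on the full predictor set,
#' fitted by iteratively reweighted least squares; standard errors are
#' scaled by the square root of the quasi-Poisson dispersion (Pearson
#' chi-square over residual df), and t-values with two-sided p-values
#' are taken on the residual degrees of freedom.
#'
#' @param design an [effort_design()] table (one group).
#' @return an `effort_fit` list: `coefficients`, `se`, `t_values`,
#'   `p_values`, `dispersion`, `vif`, `df_residual`, `converged`, and
#'   the underlying `glm` object.
#' @export
fit_poisson_glm <- function(design) {
  preds <- intersect(.effort_predictors, names(design))
  form <- if (length(preds)) stats::reformulate(preds, response = "visits")
          else visits ~ 1
  x <- stats::model.matrix(form, data = design)
  if (nrow(x) <= ncol(x)) {
    stop("need more pentads than predictors", call. = FALSE)
  }
  qrx <- qr(x)
  if (qrx$rank < ncol(x)) {
    bad <- colnames(x)[-seq_len(qrx$rank)]
    stop("design matrix is rank deficient; collinear column(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  fit <- stats::glm(form, family = stats::poisson(), data = design,
                    control = stats::glm.control(epsilon = 1e-10, maxit = 100))
  if (!fit$converged) {
    stop("IRLS did not converge in 100 iterations (final deviance ",
         format(fit$deviance), ")", call. = FALSE)
  }
  df_res <- fit$df.residual
  pearson <- stats::residuals(fit, type = "pearson")
  dispersion <- sum(pearson^2) / df_res
  sm <- summary(fit)
  se <- sm$coefficients[, "Std. Error"] * sqrt(dispersion)
  coefs <- stats::coef(fit)
  tv <- coefs / se
  pv <- 2 * stats::pt(-abs(tv), df = df_res)
  structure(list(coefficients = coefs, se = se, t_values = tv, p_values = pv,
                 dispersion = dispersion,
                 vif = if (length(preds)) {
                   variance_inflation(as.matrix(design[, preds, drop = FALSE]))
                 } else stats::setNames(numeric(0), character(0)),
                 df_residual = df_res, converged = fit$converged, glm = fit),
            class = "effort_fit")
}

#' @export
print.effort_fit <- function(x, ...) {
  cat(sprintf("<effort_fit> quasi-Poisson, dispersion = %.3f, df = %d\n",
              x$dispersion, x$df_residual))
  print(round(data.frame(coef = x$coefficients, se = x$se, t = x$t_values,
                         p = x$p_values), 4))
  invisible(x)
}

#' Variance inflation factors
#'
#' VIF of each predictor from the linear regression of that predictor on
#' all the others: `1 / (1 - R^2_j)`. Perfect collinearity yields `Inf`.
#'
#' @param design an [effort_design()] table or a numeric predictor
#'   matrix/data.frame.
#' @return named numeric vector of VIFs.
#' @export
variance_inflation <- function(design) {
  preds <- if (inherits(design, "effort_design")) {
    intersect(.effort_predictors, names(design))
  } else colnames(design)
  x <- as.matrix(as.data.frame(design)[, preds, drop = FALSE])
  vapply(seq_along(preds), function(j) {
    fit <- stats::lm.fit(cbind(1, x[, -j, drop = FALSE]), x[, j])
    r2 <- 1 - sum(fit$residuals^2) / sum((x[, j] - mean(x[, j]))^2)
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1)) |> stats::setNames(preds)
}

#' Moran's I of model residuals with a permutation test
#'
#' Spatial-autocorrelation diagnostic on the Pearson residuals of the
#' effort fit. Weights are inverse haversine distance between pentad
#' midpoints, zero diagonal, row-standardized. The p-value comes from
#' random permutation of residuals over locations (upper tail: positive
#' autocorrelation), with `p = (1 + #{I_perm >= I_obs}) / (n_perm + 1)`.
#'
#' @param residuals numeric vector.
#' @param coords two-column matrix/data.frame of `lat, lon` midpoints.
#' @param n_perm number of permutations, default 999.
#' @param seed RNG seed for the permutations.
#' @return a `morans_i` list: `I`, `expected` (null mean `-1/(n-1)`),
#'   `p_value`, `n_perm`; `I` and `p_value` are `NA` (with `reason`)
#'   when the residuals are constant.
#' @export
morans_i <- function(residuals, coords, n_perm = 999L, seed = 1L) {
  coords <- as.matrix(coords)
  n <- length(residuals)
  stopifnot(nrow(coords) == n)
  if (n < 10L) stop("need at least 10 locations for Moran's I", call. = FALSE)
  if (stats::sd(residuals) == 0) {
    return(structure(list(I = NA_real_, expected = -1 / (n - 1),
                          p_value = NA_real_, n_perm = n_perm,
                          reason = "residuals are constant"),
                     class = "morans_i"))
  }
  d <- matrix(0, n, n)
  for (i in seq_len(n - 1L)) {
    js <- (i + 1L):n
    dij <- haversine_km(matrix(coords[i, ], nrow = length(js), ncol = 2,
                               byrow = TRUE), coords[js, , drop = FALSE])
    d[i, js] <- dij; d[js, i] <- dij
  }
  w <- 1 / d
  diag(w) <- 0
  w[!is.finite(w)] <- max(w[is.finite(w)]) # coincident points: max weight
  diag(w) <- 0
  w <- w / rowSums(w)
  stat <- function(zv) {
    zc <- zv - mean(zv)
    as.numeric(zc %*% (w %*% zc)) / sum(zc^2) * n / sum(w)
  }
  i_obs <- stat(residuals)
  perm <- .with_seed(seed, vapply(seq_len(n_perm),
                                  function(k) stat(sample(residuals)),
                                  numeric(1)))
  structure(list(I = i_obs, expected = -1 / (n - 1),
                 p_value = (1 + sum(perm >= i_obs)) / (n_perm + 1),
                 n_perm = n_perm),
            class = "morans_i")
}

#' @export
print.morans_i <- function(x, ...) {
  if (is.na(x$I)) {
    cat("<morans_i> undefined:", x$reason, "\n")
  } else {
    cat(sprintf("<morans_i> I = %.4f (null mean %.4f), permutation p = %.4g (%d perms)\n",
                x$I, x$expected, x$p_value, x$n_perm))
  }
  invisible(x)
}

#' Fit per-group effort models and tabulate t-values
#'
#' Fits the quasi-Poisson effort model separately within each level of
#' `design$group` (the province analogue) and lays the t-values out as
#' one row per group and one column per predictor, with significance
#' markers at .05/.01/.001/.0001.
#'
#' @param design an [effort_design()] with a `group` column (a single
#'   implicit group is used when absent).
#' @return list `fits` (named list of `effort_fit`) and `table`
#'   (data.frame of formatted t-values).
#' @export
fit_effort_models <- function(design) {
  groups <- if ("group" %in% names(design)) unique(design$group) else "all"
  fits <- lapply(groups, function(g) {
    d <- if ("group" %in% names(design)) {
      design[design$group == g, , drop = FALSE]
    } else design
    fit_poisson_glm(d)
  })
  names(fits) <- groups
  stars <- function(p) {
    ifelse(p < 1e-4, "****", ifelse(p < 1e-3, "***",
      ifelse(p < .01, "**", ifelse(p < .05, "*", " n.s."))))
  }
  tab <- do.call(rbind, lapply(groups, function(g) {
    f <- fits[[g]]
    vals <- f$t_values[.effort_predictors]
    ps <- f$p_values[.effort_predictors]
    as.data.frame(c(list(group = g),
                    stats::setNames(as.list(sprintf("%.2f%s", vals, stars(ps))),
                                    .effort_predictors)))
  }))
  list(fits = fits, table = tab)
}
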