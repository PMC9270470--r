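#' @title Population-level gradients in mean cavity direction
#' @description Linear regression of population mean direction on latitude
#'   and on climate principal components, the permutation partial Mantel
#'   test, and a sunset-azimuth gradient helper. Mean directions are treated
#'   as plain numbers, which is only valid when all values fall inside one
#'   contiguous arc narrower than 180 degrees; the functions enforce this and
#'   raise an error (rather than silently re-centering) when it fails.
#' @name geoclim
NULL

# Width of the smallest arc containing all bearings: 360 minus the largest
# gap between consecutive sorted angles.
circular_span <- function(angles) {
  a <- sort(angles %% 360)
  if (length(a) < 2L) return(0)
  gaps <- diff(c(a, a[1] + 360))
  360 - max(gaps)
}

check_linearizable <- function(mean_dirs) {
  span <- circular_span(mean_dirs)
  if (span >= 180)
    stop(sprintf(paste0("mean directions span %.1f degrees (>= 180): the ",
                        "linear treatment is invalid; re-center the angles ",
                        "onto a contiguous arc first"), span), call. = FALSE)
  invisible(span)
}

ols_result <- function(y, x, predictor = "x") {
  fit <- stats::lm(y ~ x)
  s <- summary(fit)
  structure(list(predictor = predictor,
                 slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 se_slope = s$coefficients[2, 2],
                 t_statistic = s$coefficients[2, 3],
                 df = fit$df.residual,
                 p_value = s$coefficients[2, 4],
                 r_squared = s$r.squared,
                 fit = fit),
            class = "gradient_regression")
}

#' @export
print.gradient_regression <- function(x, ...) {
  cat(sprintf(
    "OLS of mean direction on %s\n  slope = %.4f (SE %.4f), intercept = %.3f\n  t = %.3f, df = %d, p = %.4g, R^2 = %.3f\n",
    x$predictor, x$slope, x$se_slope, x$intercept, x$t_statistic, x$df,
    x$p_value, x$r_squared))
  invisible(x)
}

#' Regress population mean cavity direction on latitude
#'
#' Ordinary least squares of mean direction (degrees, linearised) on latitude
#' across populations, with a two-sided t test on the slope. Requires at
#' least 3 sites and all mean directions inside one arc < 180 degrees wide.
#'
#' @param summaries data frame with columns \code{latitude_deg} and
#'   \code{mean_dir_deg} (one row per population).
#' @return \code{gradient_regression}: slope, intercept, se_slope,
#'   t_statistic, df, p_value, r_squared.
#' @examples
#' latitude_regression(table1_sites())
#' @export
latitude_regression <- function(summaries) {
  if (nrow(summaries) < 3L)
    stop("latitude_regression: need at least 3 sites", call. = FALSE)
  check_linearizable(summaries$mean_dir_deg)
  ols_result(summaries$mean_dir_deg, summaries$latitude_deg, "latitude")
}

#' PCA of standardised climate variables
#'
#' Principal components of the site x variable climate table after centering
#' and scaling to unit standard deviation (equivalently, eigendecomposition
#' of the correlation matrix). Zero-variance variables are dropped with a
#' warning. For determinism, each component's sign is fixed so that its
#' largest-magnitude loading is positive.
#'
#' @param climate_table data frame or matrix, sites x variables (typically
#'   the 19 bioclim columns); row order defines score order.
#' @return \code{climate_pca}: list with \code{loadings} (variables x
#'   components), \code{scores} (sites x components),
#'   \code{variance_proportion}, \code{dropped} (names of zero-variance
#'   variables).
#' @export
climate_pca <- function(climate_table) {
  X <- as.matrix(climate_table)
  if (nrow(X) < 3L) stop("climate_pca: need at least 3 sites", call. = FALSE)
  if (anyNA(X)) stop("climate_pca: missing values not allowed", call. = FALSE)
  sds <- apply(X, 2, stats::sd)
  dropped <- colnames(X)[sds == 0]
  if (length(dropped)) {
    warning("climate_pca: dropping zero-variance variable(s): ",
            paste(dropped, collapse = ", "), call. = FALSE)
    X <- X[, sds > 0, drop = FALSE]
  }
  pc <- stats::prcomp(X, center = TRUE, scale. = TRUE)
  flip <- apply(pc$rotation, 2, function(v) sign(v[which.max(abs(v))]))
  flip[flip == 0] <- 1
  loadings <- sweep(pc$rotation, 2, flip, `*`)
  scores <- sweep(pc$x, 2, flip, `*`)
  structure(list(loadings = loadings, scores = scores,
                 variance_proportion = pc$sdev^2 / sum(pc$sdev^2),
                 dropped = dropped),
            class = "climate_pca")
}

#' Regress mean cavity direction on a climate principal component
#'
#' @param summaries data frame with \code{mean_dir_deg}, one row per site, in
#'   the same row order as the PCA scores.
#' @param pca \code{climate_pca} object (or a numeric score vector).
#' @param component which component to use as predictor (default 1).
#' @return \code{gradient_regression}.
#' @export
pc_regression <- function(summaries, pca, component = 1L) {
  score <- if (inherits(pca, "climate_pca")) pca$scores[, component] else pca
  if (length(score) != nrow(summaries))
    stop("pc_regression: score length does not match number of sites",
         call. = FALSE)
  check_linearizable(summaries$mean_dir_deg)
  ols_result(summaries$mean_dir_deg, score, paste0("PC", component))
}

#' Distance-matrix builders for the Mantel analysis
#'
#' \code{dist_direction}: pairwise absolute differences in mean direction
#' (valid under the same < 180-degree arc condition as the regressions).
#' \code{dist_latitude}: pairwise absolute latitude differences.
#' \code{dist_climate}: pairwise Euclidean distances on the centered and
#' scaled climate variables.
#'
#' @param summaries site summary data frame.
#' @param climate_table sites x variables climate table.
#' @return square symmetric distance matrix with zero diagonal.
#' @name mantel_distances
NULL

#' @rdname mantel_distances
#' @export
dist_direction <- function(summaries) {
  check_linearizable(summaries$mean_dir_deg)
  m <- as.matrix(stats::dist(summaries$mean_dir_deg, method = "manhattan"))
  dimnames(m) <- list(summaries$site, summaries$site)
  m
}

#' @rdname mantel_distances
#' @export
dist_latitude <- function(summaries) {
  m <- as.matrix(stats::dist(summaries$latitude_deg, method = "manhattan"))
  dimnames(m) <- list(summaries$site, summaries$site)
  m
}

#' @rdname mantel_distances
#' @export
dist_climate <- function(climate_table) {
  as.matrix(stats::dist(scale(as.matrix(climate_table))))
}

upper_vec <- function(m) m[upper.tri(m)]

partial_cor <- function(y, x, z) {
  rxy <- stats::cor(x, y); rxz <- stats::cor(x, z); ryz <- stats::cor(y, z)
  den <- sqrt((1 - rxz^2) * (1 - ryz^2))
  if (!is.finite(den) || den < 1e-6)
    stop("partial correlation undefined: covariate perfectly collinear with ",
         "predictor or response distances", call. = FALSE)
  (rxy - rxz * ryz) / den
}

#' Permutation partial Mantel test
#'
#' Partial Pearson correlation between the vectorised upper triangles of a
#' response and a predictor distance matrix, controlling for a covariate
#' distance matrix. Significance comes from jointly permuting the rows and
#' columns of the response matrix \code{n_perm} times and recomputing the
#' partial correlation; two-tailed
#' \eqn{p = (1 + \#\{|r_{perm}| \ge |r_{obs}|\}) / (n_{perm} + 1)}.
#'
#' By default the raw response matrix is permuted; \code{method =
#' "residual"} permutes the residuals of the response distances on the
#' covariate distances instead.
#'
#' @param d_response,d_predictor,d_covariate square symmetric distance
#'   matrices of identical dimension >= 4 with zero diagonal.
#' @param n_perm number of permutations (default 1000).
#' @param seed optional integer seed.
#' @param method permutation scheme, \code{"raw"} (default) or
#'   \code{"residual"}.
#' @return \code{mantel_result}: list with \code{partial_r}, \code{p_value},
#'   \code{n_perm}, \code{seed}, \code{method}.
#' @export
partial_mantel <- function(d_response, d_predictor, d_covariate,
                           n_perm = 1000L, seed = NULL,
                           method = c("raw", "residual")) {
  method <- match.arg(method)
  mats <- list(d_response, d_predictor, d_covariate)
  n <- unique(vapply(mats, nrow, 1L))
  if (length(n) != 1L || n < 4L)
    stop("partial_mantel: matrices must share one dimension >= 4", call. = FALSE)
  for (m in mats) {
    if (!isTRUE(all.equal(m, t(m), tolerance = 1e-8)) ||
        any(abs(diag(m)) > 1e-12))
      stop("partial_mantel: matrices must be symmetric with zero diagonal",
           call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  x <- upper_vec(d_predictor); z <- upper_vec(d_covariate)
  resp <- if (method == "residual") {
    # regress response distances on covariate distances, permute the
    # residual matrix instead of the raw one
    yv <- upper_vec(d_response)
    res <- stats::residuals(stats::lm(yv ~ z))
    m <- matrix(0, n, n); m[upper.tri(m)] <- res
    m + t(m)
  } else d_response
  obs <- partial_cor(upper_vec(resp), x, z)
  perm_r <- vapply(seq_len(n_perm), function(i) {
    ord <- sample.int(n)
    partial_cor(upper_vec(resp[ord, ord]), x, z)
  }, numeric(1))
  p <- (1 + sum(abs(perm_r) >= abs(obs) - 1e-12)) / (n_perm + 1)
  structure(list(partial_r = obs, p_value = p, n_perm = as.integer(n_perm),
                 seed = seed, method = method, perm_r = perm_r),
            class = "mantel_result")
}

#' @export
print.mantel_result <- function(x, ...) {
  cat(sprintf("Partial Mantel test (%s permutation, n_perm = %d)\n  partial r = %.4f, two-tailed p = %.4g\n",
              x$method, x$n_perm, x$partial_r, x$p_value))
  invisible(x)
}

#' Sunset azimuth for a latitude and day of year
#'
#' Uses the sinusoidal approximation to solar declination,
#' \eqn{\delta = 23.44 \sin(2\pi (day - 80) / 365.25)} degrees, and the
#' azimuth of sunset (clockwise from north)
#' \eqn{A = 360 - \arccos(\sin\delta / \cos\phi)}. At the equinox this is
#' exactly 270 (due west). Intended for order-of-magnitude contrasts of the
#' sunset-direction gradient with the fitted orientation gradient, not for
#' sub-degree astronomy.
#'
#' @param latitude_deg latitude in decimal degrees, |latitude| < 66.5.
#' @param day_of_year integer day of the year (1-366).
#' @return sunset azimuth bearing in degrees.
#' @export
sunset_azimuth <- function(latitude_deg, day_of_year) {
  if (any(abs(latitude_deg) >= 66.5))
    stop("sunset_azimuth: latitude in the polar day/night regime", call. = FALSE)
  delta <- 23.44 * sin(2 * pi * (day_of_year - 80) / 365.25)
  ratio <- sin(delta * pi / 180) / cos(latitude_deg * pi / 180)
  if (any(abs(ratio) > 1))
    stop("sunset_azimuth: no sunset at this latitude/date (polar regime)",
         call. = FALSE)
  360 - acos(ratio) * 180 / pi
}

#' Sunset-azimuth gradient per degree of latitude
#'
#' Convenience contrast: the change in sunset azimuth per degree of latitude
#' between two latitudes at a fixed date, for comparison with the fitted
#' orientation-latitude slope.
#'
#' @param lat_south,lat_north latitudes in degrees.
#' @param day_of_year day of year (default 172, summer solstice, near the
#'   post-nesting excavation season).
#' @return degrees of azimuth per degree of latitude.
#' @export
sunset_gradient <- function(lat_south, lat_north, day_of_year = 172L) {
  (sunset_azimuth(lat_north, day_of_year) -
     sunset_azimuth(lat_south, day_of_year)) / (lat_north - lat_south)
}

#' Literature panel of population circular summaries
#'
#' The packaged 11-population panel of red-cockaded woodpecker mean cavity
#' orientations (site label, US state, latitude, longitude, mean direction,
#' mean resultant length r), combining published accounts with monitoring
#' datasets, sorted by latitude. This table is itself an input to the
#' gradient analyses.
#'
#' @return data frame with columns site, state, latitude_deg, longitude_deg,
#'   mean_dir_deg, r.
#' @export
table1_sites <- function() {
  path <- system.file("extdata", "population_panel.csv", package = "cavorient",
                      mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
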