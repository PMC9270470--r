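test_that("latitude regression matches the closed-form OLS oracle", {
  # 3 exactly collinear points
  res <- suppressWarnings(
    latitude_regression(data.frame(latitude_deg = c(30, 32, 34),
                                   mean_dir_deg = c(250, 260, 270))))
  expect_equal(res$r_squared, 1)
  expect_equal(res$slope, 5)

  # closed-form OLS on (0,240), (1,241), (2,243)
  res <- latitude_regression(data.frame(latitude_deg = 0:2,
                                        mean_dir_deg = c(240, 241, 243)))
  expect_equal(res$slope, 1.5)
  expect_equal(res$intercept, 239 + 5 / 6, tolerance = 1e-12)
  expect_equal(res$r_squared, 27 / 28, tolerance = 1e-12)
  expect_equal(res$df, 1)

  expect_error(latitude_regression(data.frame(latitude_deg = c(30, 32),
                                              mean_dir_deg = c(250, 260))),
               "at least 3")
})

test_that("the packaged population panel reproduces the published gradient", {
  res <- latitude_regression(table1_sites())
  expect_equal(res$r_squared, 0.5883363, tolerance = 1e-6)
  expect_equal(res$t_statistic, 3.586434, tolerance = 1e-6)
  expect_equal(res$df, 9)
  expect_lt(res$p_value, 0.006)
})

test_that("wide angular spans are rejected, not silently linearised", {
  expect_error(latitude_regression(data.frame(
    latitude_deg = c(30, 32, 34), mean_dir_deg = c(10, 180, 350))), "180")
  # slope is equivariant to rotating all directions by a constant
  s <- table1_sites()
  res0 <- latitude_regression(s)
  s$mean_dir_deg <- s$mean_dir_deg - 100
  res1 <- latitude_regression(s)
  expect_equal(res1$slope, res0$slope, tolerance = 1e-12)
  expect_equal(res1$r_squared, res0$r_squared, tolerance = 1e-12)
})

test_that("climate PCA honours standardisation and the sign convention", {
  set.seed(31)
  one <- data.frame(bio1 = rnorm(8))
  expect_equal(climate_pca(one)$variance_proportion, 1)

  # two variables with correlation rho: PC1 proportion = (1 + |rho|) / 2
  for (i in 1:5) {
    x <- rnorm(40)
    y <- 0.6 * x + rnorm(40, sd = runif(1, 0.3, 2))
    rho <- cor(x, y)
    pc <- climate_pca(data.frame(a = x, b = y))
    expect_equal(pc$variance_proportion[1], (1 + abs(rho)) / 2,
                 tolerance = 1e-10)
  }

  # duplicated variable: equal loading magnitudes, invariance to rescaling
  X <- data.frame(a = rnorm(10), b = rnorm(10))
  X$c <- X$a
  pc <- climate_pca(X)
  expect_equal(abs(pc$loadings["a", 1]), abs(pc$loadings["c", 1]),
               tolerance = 1e-10)
  pc_scaled <- climate_pca(transform(X, b = 1000 * b))
  expect_equal(pc_scaled$variance_proportion, pc$variance_proportion,
               tolerance = 1e-10)

  # deterministic sign: largest-magnitude loading positive on each component
  for (j in seq_len(ncol(pc$loadings)))
    expect_gte(pc$loadings[which.max(abs(pc$loadings[, j])), j], 0)
  expect_equal(sum(pc$variance_proportion), 1, tolerance = 1e-12)

  Z <- data.frame(a = rnorm(6), b = rep(2, 6))
  expect_warning(climate_pca(Z), "zero-variance")
})

test_that("PC1 regression reduces to latitude regression for affine climate", {
  s <- table1_sites()
  # climate exactly affine in latitude: PC1 score is affine in latitude, so
  # R^2 and |t| equal the latitude regression's
  clim <- as.data.frame(outer(s$latitude_deg, c(-1, 2, 0.5)))
  res_lat <- latitude_regression(s)
  res_pc <- pc_regression(s, climate_pca(clim))
  expect_equal(res_pc$r_squared, res_lat$r_squared, tolerance = 1e-10)
  expect_equal(abs(res_pc$t_statistic), abs(res_lat$t_statistic),
               tolerance = 1e-8)
  # single climate variable equal to latitude: identical t
  res_one <- pc_regression(s, climate_pca(data.frame(bio1 = s$latitude_deg)))
  expect_equal(abs(res_one$t_statistic), abs(res_lat$t_statistic),
               tolerance = 1e-8)
})

test_that("partial correlation agrees with the residual-regression oracle", {
  set.seed(17)
  for (i in 1:10) {
    y <- rnorm(30); x <- rnorm(30); z <- rnorm(30)
    direct <- cavorient:::partial_cor(y, x, z)
    oracle <- cor(residuals(lm(y ~ z)), residuals(lm(x ~ z)))
    expect_equal(direct, oracle, tolerance = 1e-12)
  }
})

test_that("partial Mantel recovers a perfect association", {
  set.seed(23)
  pts <- runif(8)
  dy <- as.matrix(dist(pts))
  dz <- as.matrix(dist(runif(8)))
  res <- partial_mantel(dy, dy, dz, n_perm = 500, seed = 3)
  expect_gt(res$partial_r, 0.99)
  expect_lt(res$p_value, 0.05)
})

test_that("partial Mantel p matches the 4x4 exhaustive permutation oracle", {
  set.seed(29)
  dy <- as.matrix(dist(runif(4)))
  dx <- as.matrix(dist(runif(4)))
  dz <- as.matrix(dist(runif(4)))
  exact <- oracle_mantel_enum_p(dy, dx, dz)
  res <- partial_mantel(dy, dx, dz, n_perm = 5000, seed = 4)
  se <- sqrt(exact * (1 - exact) / 5000)
  expect_lt(abs(res$p_value - exact), 3 * se + 1e-3)
})

test_that("partial Mantel rejects malformed input and collinear covariates", {
  d3 <- as.matrix(dist(runif(3)))
  expect_error(partial_mantel(d3, d3, d3), ">= 4")
  dy <- as.matrix(dist(runif(6)))
  asym <- dy; asym[1, 2] <- asym[1, 2] + 1
  expect_error(partial_mantel(asym, dy, dy), "symmetric")
  dx <- as.matrix(dist(runif(6)))
  expect_error(partial_mantel(dy, dx, dx), "collinear")
})

test_that("mantel permutations are reproducible and both schemes run", {
  set.seed(37)
  dy <- as.matrix(dist(runif(7)))
  dx <- as.matrix(dist(runif(7)))
  dz <- as.matrix(dist(runif(7)))
  r1 <- partial_mantel(dy, dx, dz, n_perm = 300, seed = 5)
  r2 <- partial_mantel(dy, dx, dz, n_perm = 300, seed = 5)
  expect_identical(r1$p_value, r2$p_value)
  rr <- partial_mantel(dy, dx, dz, n_perm = 300, seed = 5,
                       method = "residual")
  expect_true(rr$p_value > 0 && rr$p_value <= 1)
})

test_that("distance builders produce valid Mantel inputs", {
  s <- table1_sites()
  clim <- data.frame(bio1 = -s$latitude_deg + rnorm(11, sd = 0.1),
                     bio2 = s$latitude_deg * 2)
  for (m in list(dist_direction(s), dist_latitude(s), dist_climate(clim))) {
    expect_true(isSymmetric(unname(m)))
    expect_true(all(diag(m) == 0))
  }
  expect_equal(dist_direction(s)[1, 2], abs(255 - 242))
})

test_that("sunset azimuth follows the declination model", {
  expect_equal(sunset_azimuth(35, 80), 270)     # equinox: due west
  expect_equal(sunset_azimuth(-20, 80), 270)
  # summer solstice at 35N: hand evaluation of the formula
  delta <- 23.44 * sin(2 * pi * (172 - 80) / 365.25)
  expected <- 360 - acos(sin(delta * pi / 180) / cos(35 * pi / 180)) * 180 / pi
  expect_equal(sunset_azimuth(35, 172), expected, tolerance = 1e-10)
  expect_equal(sunset_azimuth(35, 172), 299.05, tolerance = 0.01)
  expect_error(sunset_azimuth(70, 172), "polar")
})

test_that("sunset gradient is an order of magnitude below the fitted slope", {
  fitted_slope <- latitude_regression(table1_sites())$slope
  # mid-May (day 135), within the nesting season, across the panel's span
  sg <- sunset_gradient(28, 35, day_of_year = 135)
  expect_gt(fitted_slope / sg, 5)
  expect_lt(sg, 1)
})
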