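test_that("harmonic design columns hit exact trigonometric values", {
  X <- build_harmonic_design(0, cycles = 2)
  expect_equal(unname(X[1, "sin2"]), 0)
  expect_equal(unname(X[1, "cos2"]), 1)
  X <- build_harmonic_design(45, cycles = 2)
  expect_equal(unname(X[1, "sin2"]), 1)
  expect_equal(unname(X[1, "cos2"]), 0, tolerance = 1e-15)
  # periodicity: theta and theta + 360 give identical rows
  th <- runif(20, 0, 360)
  X0 <- build_harmonic_design(th, 1:4, adults = rep(3, 20),
                              interactions = c(2, 4))
  X1 <- build_harmonic_design(th + 360, 1:4, adults = rep(3, 20),
                              interactions = c(2, 4))
  expect_equal(X0, X1, tolerance = 1e-12)
  # deterministic column order
  expect_equal(colnames(X0),
               c("sin1", "cos1", "sin2", "cos2", "sin3", "cos3", "sin4",
                 "cos4", "adults", "adults:sin2", "adults:cos2",
                 "adults:sin4", "adults:cos4"))
  expect_error(build_harmonic_design(10, integer(0), adults = 2,
                                     interactions = 1), "empty cycles")
})

test_that("harmonic_spec enforces term-pairing invariants", {
  expect_error(harmonic_spec("poisson_count", "fledglings", cycles = 5),
               "1:4")
  expect_error(harmonic_spec("poisson_count", "fledglings", cycles = 1,
                             include_adults = TRUE, interactions = 2),
               "main-effect")
  expect_error(harmonic_spec("poisson_count", "hatch"), "fledglings")
  s <- harmonic_spec("binomial_rate", "hatch", cycles = c(2, 1),
                     include_adults = TRUE, interactions = 2)
  expect_equal(s$cycles, c(1L, 2L))
})

make_sim_nests <- function(seed, n = 300, tau00 = 0.15) {
  cfg <- sim_config(n_nest_records = n, n_clusters = 40L,
                    tau00_true = tau00)
  gen_nesting(cfg, seed = seed)
}

test_that("intercept-only Poisson reproduces the closed-form MLE", {
  nests <- make_sim_nests(1)$nests
  # constant response: intercept = log(c) exactly
  const <- transform(nests, fledglings = 2L, hatchlings = 3L, eggs = 4L)
  spec <- harmonic_spec("poisson_count", "fledglings",
                        random_intercept = FALSE)
  fit <- fit_fecundity(const, spec)
  expect_equal(fit$coefficients$estimate, log(2), tolerance = 1e-10)
  # general counts: intercept = log(mean)
  fit <- fit_fecundity(nests, spec)
  expect_equal(fit$coefficients$estimate, log(mean(nests$fledglings)),
               tolerance = 1e-8)
})

test_that("link-scale and ratio-scale estimates are mutually consistent", {
  nests <- make_sim_nests(2)$nests
  spec <- harmonic_spec("binomial_rate", "hatch", cycles = 2,
                        include_adults = TRUE, interactions = 2)
  fit <- fit_rate_glmm(nests, spec)
  expect_equal(log(fit$coefficients$ratio), fit$coefficients$estimate,
               tolerance = 1e-10)
  expect_equal(log(fit$coefficients$ratio_low), fit$coefficients$ci_low,
               tolerance = 1e-10)
  expect_equal(fit$sigma2_latent, pi^2 / 3)
  expect_equal(fit$icc, fit$tau00 / (fit$tau00 + pi^2 / 3))
})

test_that("ICC arithmetic matches the latent-logistic convention", {
  expect_equal(round(pi^2 / 3, 2), 3.29)
  expect_equal(round(icc_logit(0.06), 2), 0.02)
  expect_equal(round(icc_logit(0.17), 2), 0.05)
  expect_equal(icc_logit(0), 0)
  expect_error(icc_logit(-0.1), ">= 0")
})

test_that("pseudo_r2 follows the Cox-Snell / Nagelkerke formulas", {
  f1 <- list(ll = -140, n = 100)
  f0 <- list(ll = -150, n = 100)
  r2 <- pseudo_r2(f1, f0)
  expect_equal(r2$cox_snell, 1 - exp(-0.2), tolerance = 1e-12)
  expect_equal(r2$nagelkerke, (1 - exp(-0.2)) / (1 - exp(-3)),
               tolerance = 1e-12)
  expect_equal(pseudo_r2(f0, f0), list(cox_snell = 0, nagelkerke = 0))
  expect_gte(r2$nagelkerke, r2$cox_snell)
  expect_error(pseudo_r2(f0, f1), "nested")
})

test_that("zero cluster variance triggers the singular GLM fallback", {
  g <- make_sim_nests(3, n = 400, tau00 = 0)
  spec <- harmonic_spec("poisson_count", "fledglings", cycles = 2,
                        include_adults = TRUE, interactions = 2,
                        random_intercept = TRUE)
  fit <- suppressMessages(fit_fecundity(g$nests, spec))
  expect_true(fit$singular)
  expect_equal(fit$tau00, 0)
  glm_spec <- spec; glm_spec$random_intercept <- FALSE
  glm_fit <- fit_fecundity(g$nests, glm_spec)
  expect_equal(fit$coefficients$estimate, glm_fit$coefficients$estimate,
               tolerance = 1e-6)
  expect_equal(fit$loglik, glm_fit$loglik, tolerance = 1e-8)
})

test_that("fits are invariant to rotating directions by 360 degrees", {
  nests <- make_sim_nests(4)$nests
  spec <- harmonic_spec("binomial_rate", "fledge", cycles = 2,
                        include_adults = TRUE, random_intercept = FALSE)
  f0 <- suppressMessages(fit_rate_glmm(nests, spec))
  rot <- transform(nests, direction_deg = (direction_deg + 360) %% 720)
  f1 <- suppressMessages(fit_rate_glmm(rot, spec))
  expect_equal(f0$coefficients$estimate, f1$coefficients$estimate,
               tolerance = 1e-10)
})

test_that("rate models exclude zero-denominator rows with a notice", {
  g <- make_sim_nests(5, n = 200)
  nests <- g$nests
  nests$hatchlings[1:5] <- 0L
  nests$fledglings[1:5] <- 0L
  spec <- harmonic_spec("binomial_rate", "fledge", random_intercept = FALSE)
  expect_message(fit <- fit_rate_glmm(nests, spec), "zero hatchlings")
  expect_equal(fit$n_obs, sum(nests$hatchlings >= 1))
})

test_that("predictions are periodic, flat when unstructured, and bounded", {
  nests <- make_sim_nests(6)$nests
  spec2 <- harmonic_spec("binomial_rate", "hatch", cycles = 2,
                         include_adults = TRUE, interactions = 2,
                         random_intercept = FALSE)
  fit <- fit_rate_glmm(nests, spec2)
  pr <- predict_success(fit, direction_grid = seq(0, 359, by = 1),
                        adults_levels = c(2, 6))
  # two-cycle model: exact 180-degree periodicity
  half <- pr$direction_deg < 180
  expect_equal(pr$fit[half], pr$fit[!half], tolerance = 1e-12)
  expect_true(all(pr$lwr <= pr$fit & pr$fit <= pr$upr))

  spec0 <- harmonic_spec("poisson_count", "fledglings",
                         random_intercept = FALSE)
  flat <- predict_success(fit_fecundity(nests, spec0), 0:359, 4)
  expect_equal(diff(range(flat$fit)), 0, tolerance = 1e-12)
  expect_equal(flat$fit[1], mean(nests$fledglings), tolerance = 1e-8)
  expect_error(predict_success(fit, numeric(0)), "empty")
})

test_that("predicted optima sit near the generating optima", {
  g <- make_sim_nests(8, n = 500, tau00 = 0.05)
  spec <- harmonic_spec("binomial_rate", "hatch", cycles = 2,
                        include_adults = TRUE, interactions = 2,
                        random_intercept = FALSE)
  fit <- fit_rate_glmm(g$nests, spec)
  b <- g$truth$beta_hatch
  for (A in c(3, 6)) {
    s <- b[["sin2"]] + b[["adults_sin2"]] * A
    cc <- b[["cos2"]] + b[["adults_cos2"]] * A
    true_opt <- (atan2(s, cc) * 180 / pi / 2) %% 180
    pr <- predict_success(fit, seq(0, 179.5, by = 0.5), A)
    got_opt <- pr$direction_deg[which.max(pr$fit)] %% 180
    dev <- min(abs(got_opt - true_opt), 180 - abs(got_opt - true_opt))
    expect_lt(dev, 15)
  }
})

test_that("top-down selection keeps the generating block and prunes noise", {
  g <- gen_nesting(sim_config(tau00_true = 0.2), seed = 9)
  sel <- suppressWarnings(select_model(g$nests, "binomial_rate", "hatch"))
  terms <- sel$fit$coefficients$term
  expect_true(all(c("adults", "sin2", "cos2", "adults:sin2", "adults:cos2")
                  %in% terms))
  # trace bookkeeping: every decision recorded, final nested in initial
  expect_true(all(sel$trace$decision %in% c("drop", "keep")))
  expect_true(all(sel$trace$lr_statistic >= 0))
  expect_gte(sel$pseudo_r2$nagelkerke, sel$pseudo_r2$cox_snell)
})

test_that("selection on direction-free data retains no direction terms", {
  cfg <- sim_config(n_nest_records = 400L, n_clusters = 40L,
                    kappa_nest_dir = 0, tau00_true = 0.1,
                    beta_hatch = c(intercept = 0.3, adults = 0.15, sin2 = 0,
                                   cos2 = 0, adults_sin2 = 0,
                                   adults_cos2 = 0))
  g <- gen_nesting(cfg, seed = 10)
  sel <- suppressWarnings(select_model(g$nests, "binomial_rate", "hatch"))
  expect_false(any(grepl("sin|cos", sel$fit$coefficients$term)))
})
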