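#' @title Harmonic regression of reproductive success on nest direction
#' @description Nest-cavity entrance direction enters generalized linear
#'   (mixed) models through paired sine and cosine terms, sin(k*theta) and
#'   cos(k*theta) for k cycles per revolution, so that the periodic nature of
#'   bearings is respected (1 degree is close to 360 degrees). Total
#'   fecundity (fledgling count) uses a Poisson log link; hatch rate
#'   (hatchlings out of eggs) and fledge rate (fledglings out of hatchlings)
#'   use binomial logit links with a territory-cluster random intercept.
#'   Group size (number of adults) enters as a main effect and through
#'   interactions with the trigonometric terms. Model reduction follows a
#'   top-down protocol dropping the least-supported term block by
#'   likelihood-ratio test.
#' @name nestmodels
NULL

#' Specify a harmonic success model
#'
#' @param family \code{"poisson_count"} (fledgling counts) or
#'   \code{"binomial_rate"} (hatch or fledge proportions).
#' @param response one of \code{"fledglings"}, \code{"hatch"},
#'   \code{"fledge"}.
#' @param cycles integer subset of 1:4; sine and cosine of each cycle enter
#'   and leave together.
#' @param include_adults include the group-size main effect.
#' @param interactions integer subset of \code{cycles} whose trigonometric
#'   pairs interact with adults; requires the main-effect cycle present.
#' @param random_intercept include a cluster random intercept.
#' @return object of class \code{harmonic_spec}.
#' @export
harmonic_spec <- function(family = c("poisson_count", "binomial_rate"),
                          response = c("fledglings", "hatch", "fledge"),
                          cycles = integer(0), include_adults = FALSE,
                          interactions = integer(0), random_intercept = TRUE) {
  family <- match.arg(family)
  response <- match.arg(response)
  cycles <- sort(unique(as.integer(cycles)))
  interactions <- sort(unique(as.integer(interactions)))
  if (!all(cycles %in% 1:4)) stop("cycles must be a subset of 1:4", call. = FALSE)
  if (length(interactions) && !length(cycles))
    stop("interactions requested with no cycle terms", call. = FALSE)
  if (!all(interactions %in% cycles))
    stop("an interaction requires its main-effect cycle present", call. = FALSE)
  if (length(interactions) && !include_adults)
    stop("adults-by-direction interactions require the adults main effect",
         call. = FALSE)
  if (family == "poisson_count" && response != "fledglings")
    stop("poisson_count models the fledglings count", call. = FALSE)
  if (family == "binomial_rate" && response == "fledglings")
    stop("binomial_rate models hatch or fledge proportions", call. = FALSE)
  structure(list(family = family, response = response, cycles = cycles,
                 include_adults = include_adults, interactions = interactions,
                 random_intercept = random_intercept),
            class = "harmonic_spec")
}

#' Harmonic design matrix for direction and group size
#'
#' Builds the fixed-effect design columns: sin(k*theta) and cos(k*theta) for
#' each requested cycle k (theta = direction in radians), then adults, then
#' adults-by-trigonometric interaction columns. Column order is cycles in
#' increasing k (sine before cosine), adults, interactions in increasing k.
#'
#' @param direction_deg bearings in degrees.
#' @param cycles integer subset of 1:4.
#' @param adults optional vector of adult counts (adds the adults column).
#' @param interactions integer subset of \code{cycles}; requires
#'   \code{adults}.
#' @return numeric matrix (no intercept column).
#' @export
build_harmonic_design <- function(direction_deg, cycles, adults = NULL,
                                  interactions = integer(0)) {
  if (length(interactions) && !length(cycles))
    stop("build_harmonic_design: interactions requested with empty cycles",
         call. = FALSE)
  if (length(interactions) && is.null(adults))
    stop("build_harmonic_design: interactions require adults", call. = FALSE)
  theta <- (direction_deg %% 360) * pi / 180
  cols <- list()
  for (k in sort(unique(as.integer(cycles)))) {
    cols[[paste0("sin", k)]] <- sin(k * theta)
    cols[[paste0("cos", k)]] <- cos(k * theta)
  }
  if (!is.null(adults)) cols[["adults"]] <- as.numeric(adults)
  for (k in sort(unique(as.integer(interactions)))) {
    cols[[paste0("adults:sin", k)]] <- as.numeric(adults) * sin(k * theta)
    cols[[paste0("adults:cos", k)]] <- as.numeric(adults) * cos(k * theta)
  }
  do.call(cbind, cols)
}

# Assemble the model frame for a response: trig columns for all cycles 1:4
# are precomputed; zero-denominator rows are excluded for rate models.
prepare_nest_frame <- function(records, response) {
  theta <- (records$direction_deg %% 360) * pi / 180
  d <- data.frame(cluster = factor(records$cluster_id),
                  adults = as.numeric(records$adults))
  for (k in 1:4) {
    d[[paste0("sin", k)]] <- sin(k * theta)
    d[[paste0("cos", k)]] <- cos(k * theta)
  }
  if (response == "fledglings") {
    y <- records$fledglings
    if (any(y < 0) || any(y != round(y)))
      stop("fledglings must be non-negative integers", call. = FALSE)
    d$y <- y
  } else if (response == "hatch") {
    keep <- records$eggs >= 1
    if (any(!keep))
      message("excluding ", sum(!keep), " nest(s) with zero eggs from the ",
              "hatch-rate model")
    d <- d[keep, , drop = FALSE]
    d$succ <- records$hatchlings[keep]
    d$fail <- records$eggs[keep] - records$hatchlings[keep]
  } else {
    keep <- records$hatchlings >= 1
    if (any(!keep))
      message("excluding ", sum(!keep), " nest(s) with zero hatchlings from ",
              "the fledge-rate model")
    d <- d[keep, , drop = FALSE]
    d$succ <- records$fledglings[keep]
    d$fail <- records$hatchlings[keep] - records$fledglings[keep]
  }
  d
}

spec_rhs <- function(spec) {
  terms <- character(0)
  if (spec$include_adults) terms <- c(terms, "adults")
  for (k in spec$cycles) terms <- c(terms, paste0("sin", k), paste0("cos", k))
  for (k in spec$interactions)
    terms <- c(terms, paste0("adults:sin", k), paste0("adults:cos", k))
  if (!length(terms)) "1" else paste(terms, collapse = " + ")
}

spec_formula <- function(spec, random = spec$random_intercept) {
  lhs <- if (spec$family == "poisson_count") "y" else "cbind(succ, fail)"
  rhs <- spec_rhs(spec)
  if (random) rhs <- paste(rhs, "+ (1 | cluster)")
  stats::as.formula(paste(lhs, "~", rhs))
}

glm_family <- function(spec) {
  if (spec$family == "poisson_count") stats::poisson(link = "log")
  else stats::binomial(link = "logit")
}

#' Fit a harmonic success model
#'
#' Fits the model described by a \code{\link{harmonic_spec}} to nest
#' records. Mixed models are estimated by Laplace-approximate maximum
#' likelihood (\code{lme4::glmer}); when the cluster variance estimate falls
#' below \code{singular_tol} the model is refit without the random intercept
#' and flagged \code{singular} (the fixed-effects-only fit is reported).
#'
#' @param records validated nest-record data frame
#'   (\code{\link{read_nests}}).
#' @param spec \code{harmonic_spec}.
#' @param conf confidence level for Wald intervals (default 0.95).
#' @param singular_tol variance-scale tolerance triggering the fixed-effects
#'   fallback (default 1e-6).
#' @param nAGQ integration setting passed to \code{lme4::glmer}: 1 (default)
#'   is the Laplace approximation; 0 uses the faster penalised-least-squares
#'   approximation (used internally for model-selection scans).
#' @return object of class \code{harmonic_fit}: coefficient table with
#'   link-scale estimates, standard errors, Wald CIs and exponentiated
#'   ratio-scale estimates (incidence-rate ratios for Poisson, odds ratios
#'   for binomial), \code{tau00}, \code{sigma2_latent} (\eqn{\pi^2/3} for
#'   binomial-logit, NA for Poisson), \code{icc}, \code{loglik},
#'   \code{n_obs}, \code{singular}, and the underlying model object.
#' @export
fit_harmonic <- function(records, spec, conf = 0.95, singular_tol = 1e-6,
                         nAGQ = 1L) {
  stopifnot(inherits(spec, "harmonic_spec"))
  d <- prepare_nest_frame(records, spec$response)
  n_par <- 1L + spec$include_adults + 2L * length(spec$cycles) +
    2L * length(spec$interactions)
  if (nrow(d) <= n_par)
    stop("fit_harmonic: more parameters than observations", call. = FALSE)
  fam <- glm_family(spec)
  singular <- FALSE
  tau00 <- 0
  if (spec$random_intercept) {
    fit <- lme4::glmer(spec_formula(spec), data = d, family = fam,
                       nAGQ = nAGQ)
    tau00 <- as.numeric(lme4::VarCorr(fit)$cluster[1, 1])
    if (tau00 < singular_tol) {
      singular <- TRUE
      fit <- stats::glm(spec_formula(spec, random = FALSE), data = d,
                        family = fam)
      tau00 <- 0
    }
  } else {
    fit <- stats::glm(spec_formula(spec, random = FALSE), data = d,
                      family = fam)
  }
  mixed <- inherits(fit, "merMod")
  if (!mixed && !fit$converged)
    stop("fit_harmonic: IRLS did not converge (possible separation); ",
         "deviance = ", format(stats::deviance(fit)), call. = FALSE)
  beta <- if (mixed) lme4::fixef(fit) else stats::coef(fit)
  vc <- as.matrix(stats::vcov(fit))
  se <- sqrt(diag(vc))
  zq <- stats::qnorm(1 - (1 - conf) / 2)
  coefs <- data.frame(term = names(beta), estimate = unname(beta),
                      se = unname(se),
                      ci_low = unname(beta - zq * se),
                      ci_high = unname(beta + zq * se),
                      z = unname(beta / se),
                      p_value = 2 * stats::pnorm(-abs(unname(beta / se))),
                      stringsAsFactors = FALSE)
  coefs$ratio <- exp(coefs$estimate)
  coefs$ratio_low <- exp(coefs$ci_low)
  coefs$ratio_high <- exp(coefs$ci_high)
  sigma2_latent <- if (spec$family == "binomial_rate") pi^2 / 3 else NA_real_
  icc <- if (is.na(sigma2_latent)) NA_real_ else tau00 / (tau00 + sigma2_latent)
  structure(list(spec = spec, coefficients = coefs, tau00 = tau00,
                 sigma2_latent = sigma2_latent, icc = icc,
                 loglik = as.numeric(stats::logLik(fit)),
                 n_obs = nrow(d), singular = singular, conf = conf,
                 model = fit, data = d),
            class = "harmonic_fit")
}

#' @export
print.harmonic_fit <- function(x, digits = 3, ...) {
  ratio_lab <- if (x$spec$family == "poisson_count") "IRR" else "OR"
  cat(sprintf("Harmonic %s model for %s (%s)\n",
              if (x$spec$random_intercept && !x$singular) "mixed" else "fixed-effects",
              x$spec$response, x$spec$family))
  tab <- x$coefficients
  out <- data.frame(term = tab$term,
                    ratio = round(tab$ratio, digits),
                    ci = sprintf("%.*f-%.*f", digits - 1, tab$ratio_low,
                                 digits - 1, tab$ratio_high),
                    p = signif(tab$p_value, 2))
  names(out)[2] <- ratio_lab
  print(out, row.names = FALSE)
  cat(sprintf("n = %d, logLik = %.2f", x$n_obs, x$loglik))
  if (!is.na(x$icc))
    cat(sprintf(", tau00 = %.3f, sigma2 = %.2f, ICC = %.2f",
                x$tau00, x$sigma2_latent, x$icc))
  if (x$singular) cat("  [singular fit: fixed-effects refit reported]")
  cat("\n")
  invisible(x)
}

#' Poisson model of total nest fecundity
#'
#' @inheritParams fit_harmonic
#' @param spec \code{harmonic_spec} with \code{family = "poisson_count"}.
#' @return \code{harmonic_fit}.
#' @export
fit_fecundity <- function(records, spec, conf = 0.95, singular_tol = 1e-6) {
  if (spec$family != "poisson_count")
    stop("fit_fecundity expects a poisson_count spec", call. = FALSE)
  fit_harmonic(records, spec, conf = conf, singular_tol = singular_tol)
}

#' Binomial mixed model of hatch or fledge rate
#'
#' Successes and failures are aggregated per nest: hatchlings out of eggs
#' (hatch rate) or fledglings out of hatchlings (fledge rate); nests with a
#' zero denominator are excluded with a notice. Reports the latent-scale
#' intraclass correlation ICC = tau00 / (tau00 + pi^2/3).
#'
#' @inheritParams fit_harmonic
#' @param spec \code{harmonic_spec} with \code{family = "binomial_rate"}.
#' @return \code{harmonic_fit}.
#' @export
fit_rate_glmm <- function(records, spec, conf = 0.95, singular_tol = 1e-6) {
  if (spec$family != "binomial_rate")
    stop("fit_rate_glmm expects a binomial_rate spec", call. = FALSE)
  fit_harmonic(records, spec, conf = conf, singular_tol = singular_tol)
}

#' Latent-scale intraclass correlation for a logit mixed model
#'
#' @param tau00 cluster random-intercept variance (>= 0).
#' @param sigma2_latent latent residual variance; defaults to \eqn{\pi^2/3},
#'   the variance of the standard logistic distribution.
#' @return ICC in \[0, 1\].
#' @export
icc_logit <- function(tau00, sigma2_latent = pi^2 / 3) {
  if (any(tau00 < 0)) stop("tau00 must be >= 0", call. = FALSE)
  tau00 / (tau00 + sigma2_latent)
}

#' Cox-Snell and Nagelkerke pseudo-R-squared
#'
#' @param fit fitted \code{harmonic_fit}.
#' @param null_fit the intercept(+random)-only \code{harmonic_fit} on the
#'   same data.
#' @return list with \code{cox_snell} and \code{nagelkerke}.
#' @export
pseudo_r2 <- function(fit, null_fit) {
  ll1 <- if (inherits(fit, "harmonic_fit")) fit$loglik else fit$ll
  ll0 <- if (inherits(null_fit, "harmonic_fit")) null_fit$loglik else null_fit$ll
  n <- if (inherits(fit, "harmonic_fit")) fit$n_obs else fit$n
  if (inherits(fit, "harmonic_fit") && inherits(null_fit, "harmonic_fit") &&
      fit$n_obs != null_fit$n_obs)
    stop("pseudo_r2: fits are not on identical data", call. = FALSE)
  if (ll1 < ll0 - 1e-4)
    stop("pseudo_r2: null log-likelihood exceeds model log-likelihood ",
         "(models are not nested on the same data)", call. = FALSE)
  ll1 <- max(ll1, ll0)   # clamp optimizer noise when the fits coincide
  cs <- 1 - exp((2 / n) * (ll0 - ll1))
  list(cox_snell = cs, nagelkerke = cs / (1 - exp(2 * ll0 / n)))
}

# Refit helpers used by select_model ----------------------------------------

drop_block <- function(spec, block) {
  s <- spec
  if (block$type == "interaction") {
    s$interactions <- setdiff(s$interactions, block$k)
  } else if (block$type == "cycle") {
    s$cycles <- setdiff(s$cycles, block$k)
  } else {
    s$include_adults <- FALSE
  }
  s
}

candidate_blocks <- function(spec) {
  out <- list()
  for (k in spec$interactions)
    out[[length(out) + 1L]] <- list(type = "interaction", k = k, df = 2L,
                                    label = sprintf("adults:(sin%d,cos%d)", k, k))
  for (k in setdiff(spec$cycles, spec$interactions))
    out[[length(out) + 1L]] <- list(type = "cycle", k = k, df = 2L,
                                    label = sprintf("(sin%d,cos%d)", k, k))
  if (spec$include_adults && !length(spec$interactions))
    out[[length(out) + 1L]] <- list(type = "adults", k = NA, df = 1L,
                                    label = "adults")
  out
}

#' Top-down selection of a harmonic success model
#'
#' Starts from the full model (cycles 1-4, adults, all adults-by-direction
#' interactions, cluster random intercept) and repeatedly removes the
#' least-supported term block: interaction pairs before their main-effect
#' cycles, sine and cosine always together, adults only once no interaction
#' remains. At each step every droppable block is refit and the block with
#' the largest likelihood-ratio p-value is removed if p > \code{alpha}
#' (with \code{criterion = "AIC"}, the block whose removal lowers AIC most
#' is removed while any removal lowers it). Random-intercept singularity in
#' the full model switches the whole selection to fixed-effects fits.
#'
#' @param records validated nest-record data frame.
#' @param family,response as in \code{\link{harmonic_spec}}.
#' @param alpha retention threshold for the LRT criterion (default 0.05).
#' @param criterion \code{"LRT"} (default) or \code{"AIC"}.
#' @param conf confidence level for the final fit's intervals.
#' @return list with \code{fit} (final \code{harmonic_fit}), \code{trace}
#'   (data frame: step, dropped block, log-likelihoods, test statistic,
#'   p-value or delta-AIC, decision), and \code{pseudo_r2} of the final
#'   model against its intercept(+random)-only null.
#' @export
select_model <- function(records, family = c("poisson_count", "binomial_rate"),
                         response = c("fledglings", "hatch", "fledge"),
                         alpha = 0.05, criterion = c("LRT", "AIC"),
                         conf = 0.95) {
  family <- match.arg(family)
  response <- match.arg(response)
  criterion <- match.arg(criterion)
  if (nrow(records) < 50L)
    stop("select_model: need at least 50 records", call. = FALSE)
  if (length(unique(records$cluster_id)) < 2L)
    stop("select_model: need records from at least 2 clusters", call. = FALSE)
  full <- harmonic_spec(family, response, cycles = 1:4, include_adults = TRUE,
                        interactions = 1:4, random_intercept = TRUE)
  # Selection scans use the fast PIRLS approximation (nAGQ = 0); the final
  # and null models are refit with the Laplace approximation.
  scan_fit <- function(spec) suppressWarnings(suppressMessages(
    fit_harmonic(records, spec, conf = conf, nAGQ = 0L)))
  current <- tryCatch(
    scan_fit(full),
    error = function(e) {
      warning("full model failed (", conditionMessage(e),
              "); restarting from cycles {1,2}", call. = FALSE)
      scan_fit(harmonic_spec(family, response, cycles = 1:2,
                             include_adults = TRUE, interactions = 1:2,
                             random_intercept = TRUE))
    })
  # A singular full model pins the whole selection path to fixed effects so
  # that all likelihoods in the LRTs are comparable.
  use_random <- current$spec$random_intercept && !current$singular
  if (!use_random && current$spec$random_intercept) {
    s <- current$spec; s$random_intercept <- FALSE
    current <- scan_fit(s)
  }
  trace <- list()
  step <- 0L
  repeat {
    cands <- candidate_blocks(current$spec)
    if (!length(cands)) break
    fits <- lapply(cands, function(b) {
      s <- drop_block(current$spec, b)
      s$random_intercept <- use_random
      scan_fit(s)
    })
    stat <- vapply(seq_along(cands), function(i)
      2 * (current$loglik - fits[[i]]$loglik), numeric(1))
    stat <- pmax(stat, 0)
    pval <- vapply(seq_along(cands), function(i)
      stats::pchisq(stat[i], df = cands[[i]]$df, lower.tail = FALSE),
      numeric(1))
    daic <- vapply(seq_along(cands), function(i)
      stat[i] - 2 * cands[[i]]$df, numeric(1))  # AIC(reduced) - AIC(current)
    pick <- if (criterion == "LRT") which.max(pval) else which.min(daic)
    ok <- if (criterion == "LRT") pval[pick] > alpha else daic[pick] < 0
    step <- step + 1L
    trace[[step]] <- data.frame(
      step = step, block = cands[[pick]]$label, df = cands[[pick]]$df,
      loglik_current = current$loglik, loglik_reduced = fits[[pick]]$loglik,
      lr_statistic = stat[pick], p_value = pval[pick], delta_aic = daic[pick],
      decision = if (ok) "drop" else "keep", stringsAsFactors = FALSE)
    if (!ok) break
    current <- fits[[pick]]
  }
  final_spec <- current$spec
  final_spec$random_intercept <- use_random
  final <- suppressWarnings(suppressMessages(
    fit_harmonic(records, final_spec, conf = conf)))
  null_spec <- harmonic_spec(family, response, cycles = integer(0),
                             include_adults = FALSE,
                             random_intercept = use_random)
  null_fit <- suppressWarnings(suppressMessages(
    fit_harmonic(records, null_spec, conf = conf)))
  list(fit = final,
       trace = if (length(trace)) do.call(rbind, trace) else
         data.frame(step = integer(0), block = character(0)),
       pseudo_r2 = pseudo_r2(final, null_fit))
}

#' Response-scale predictions over a direction grid
#'
#' Predicted success (fixed effects only; random intercept at zero) over a
#' grid of nest directions, one curve per group size, with delta-method
#' (Wald-on-link-scale) confidence bands. A final model containing only
#' 2-cycle terms yields curves with period 180 degrees.
#'
#' @param fit \code{harmonic_fit}.
#' @param direction_grid bearings in degrees (default 0..359).
#' @param adults_levels group sizes to predict for.
#' @param conf confidence level.
#' @return data frame with direction_deg, adults, fit, lwr, upr on the
#'   response scale.
#' @export
predict_success <- function(fit, direction_grid = 0:359, adults_levels = 2:6,
                            conf = 0.95) {
  stopifnot(inherits(fit, "harmonic_fit"))
  if (!length(direction_grid)) stop("predict_success: empty grid", call. = FALSE)
  spec <- fit$spec
  grid <- expand.grid(direction_deg = direction_grid, adults = adults_levels)
  X <- cbind("(Intercept)" = 1,
             build_harmonic_design(grid$direction_deg, spec$cycles,
                                   adults = grid$adults,
                                   interactions = spec$interactions))
  terms <- fit$coefficients$term
  X <- X[, terms, drop = FALSE]
  beta <- fit$coefficients$estimate
  vc <- as.matrix(stats::vcov(fit$model))
  eta <- drop(X %*% beta)
  se <- sqrt(rowSums((X %*% vc) * X))
  zq <- stats::qnorm(1 - (1 - conf) / 2)
  linkinv <- glm_family(spec)$linkinv
  data.frame(direction_deg = grid$direction_deg, adults = grid$adults,
             fit = linkinv(eta), lwr = linkinv(eta - zq * se),
             upr = linkinv(eta + zq * se))
}
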