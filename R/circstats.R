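# %% 360 can return exactly 360 for tiny negative inputs (floating point);
# enforce the half-open [0, 360) convention.
wrap360 <- function(x) {
  y <- x %% 360
  y[y >= 360] <- 0
  y
}

#' Circular mean direction and mean resultant length by vector addition
#'
#' Each bearing is treated as a unit vector; the vector sum is normalised by
#' the number of observations. The norm of the normalised sum is the mean
#' resultant length \eqn{r \in [0, 1]} (0 = uniform spread, 1 = perfect
#' concentration) and its direction is the mean bearing.
#'
#' @param angles numeric vector of bearings in degrees clockwise from north.
#'   Values are normalised into \[0, 360) internally.
#' @return list with components \code{mean_deg} (bearing in \[0, 360), or
#'   \code{NA} when \code{r} falls below \code{tol}), \code{r}, and \code{n}.
#' @param tol tolerance below which \code{r} is treated as zero and the mean
#'   direction is undefined (default \code{1e-12}).
#' @examples
#' circ_mean(c(350, 10))   # mean 0, r = cos(10 deg)
#' circ_mean(c(0, 180))    # r = 0, mean undefined
#' @export
circ_mean <- function(angles, tol = 1e-12) {
  if (length(angles) == 0L) stop("circ_mean: empty input", call. = FALSE)
  if (anyNA(angles)) stop("circ_mean: NA bearings not allowed", call. = FALSE)
  th <- (angles %% 360) * pi / 180
  C <- sum(cos(th)) / length(th)
  S <- sum(sin(th)) / length(th)
  r <- sqrt(C^2 + S^2)
  mean_deg <- if (r < tol) NA_real_ else wrap360(atan2(S, C) * 180 / pi)
  list(mean_deg = mean_deg, r = min(r, 1), n = length(th))
}

#' Rayleigh test of circular uniformity
#'
#' Tests a sample of bearings for a unimodal departure from uniformity using
#' the statistic \eqn{z = n r^2} and the standard second-order series
#' approximation to the p-value,
#' \deqn{p = e^{-z}\left[1 + \frac{2z - z^2}{4n}
#'       - \frac{24z - 132z^2 + 76z^3 - 9z^4}{288 n^2}\right],}
#' clamped into \[0, 1\].
#'
#' @inheritParams circ_mean
#' @return list with \code{z}, \code{p}, \code{r}, \code{n}.
#' @export
rayleigh_test <- function(angles) {
  n <- length(angles)
  if (n < 3L) stop("rayleigh_test: need at least 3 bearings", call. = FALSE)
  if (n < 10L)
    warning("rayleigh_test: n < 10, p-value approximation is crude", call. = FALSE)
  r <- circ_mean(angles)$r
  z <- n * r^2
  p <- exp(-z) * (1 + (2 * z - z^2) / (4 * n) -
                    (24 * z - 132 * z^2 + 76 * z^3 - 9 * z^4) / (288 * n^2))
  list(z = z, p = min(max(p, 0), 1), r = r, n = n)
}

#' Bootstrap percentile confidence interval for the circular mean
#'
#' Resamples the bearings with replacement, computes each replicate's circular
#' mean, and forms a percentile interval on the angular deviations of the
#' replicate means from the observed mean (so the interval behaves correctly
#' across the 0/360 wraparound). Replicates whose resultant length is zero
#' (mean undefined) are redrawn.
#'
#' @inheritParams circ_mean
#' @param n_boot number of bootstrap replicates (>= 200).
#' @param conf confidence level, default 0.95.
#' @param seed optional integer seed for reproducibility.
#' @return list with \code{ci_low_deg}, \code{ci_high_deg} (bearings),
#'   \code{mean_deg}, \code{n_boot}, and \code{n_redrawn}.
#' @export
bootstrap_mean_ci <- function(angles, n_boot = 1000L, conf = 0.95, seed = NULL) {
  n <- length(angles)
  if (n < 10L) stop("bootstrap_mean_ci: need at least 10 bearings", call. = FALSE)
  if (n_boot < 200L) stop("bootstrap_mean_ci: n_boot must be >= 200", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  obs <- circ_mean(angles)
  if (is.na(obs$mean_deg))
    stop("bootstrap_mean_ci: observed mean direction undefined (r = 0)", call. = FALSE)
  th <- (angles %% 360) * pi / 180
  cs <- cos(th); sn <- sin(th)
  draw_means <- function(b) {
    idx <- matrix(sample.int(n, b * n, replace = TRUE), nrow = b)
    C <- rowSums(matrix(cs[idx], nrow = b))
    S <- rowSums(matrix(sn[idx], nrow = b))
    list(mean = (atan2(S, C) * 180 / pi) %% 360, r = sqrt(C^2 + S^2) / n)
  }
  bm <- draw_means(n_boot)
  n_redrawn <- 0L
  while (any(bad <- bm$r < 1e-12)) {   # redraw degenerate replicates
    n_redrawn <- n_redrawn + sum(bad)
    rep2 <- draw_means(sum(bad))
    bm$mean[bad] <- rep2$mean; bm$r[bad] <- rep2$r
  }
  if (n_redrawn > 0L)
    message("bootstrap_mean_ci: redrew ", n_redrawn, " replicate(s) with r = 0")
  dev <- ((bm$mean - obs$mean_deg + 180) %% 360) - 180
  alpha <- (1 - conf) / 2
  q <- stats::quantile(dev, c(alpha, 1 - alpha), names = FALSE, type = 7)
  list(ci_low_deg = wrap360(obs$mean_deg + q[1]),
       ci_high_deg = wrap360(obs$mean_deg + q[2]),
       mean_deg = obs$mean_deg, n_boot = n_boot, n_redrawn = n_redrawn)
}

#' Per-site, per-stage circular summaries of cavity records
#'
#' Summarises entrance orientations for each site and each pool in
#' \code{{start, complete, nest, all}} ("all" pools starts and completes;
#' nests are a marked subset of completes, so they are never double counted).
#'
#' @param cavities data frame of cavity records as returned by
#'   \code{\link{read_cavities}}.
#' @param ci logical; add bootstrap confidence bounds where n >= 10.
#' @param n_boot,conf,seed passed to \code{\link{bootstrap_mean_ci}}.
#' @return data frame with columns site, stage, n, mean_dir_deg, r,
#'   rayleigh_p, ci_low_deg, ci_high_deg.
#' @export
circ_summary <- function(cavities, ci = FALSE, n_boot = 1000L, conf = 0.95,
                         seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  pools <- list(
    start    = function(d) d$orientation_deg[d$stage == "start"],
    complete = function(d) d$orientation_deg[d$stage == "complete"],
    nest     = function(d) d$orientation_deg[d$is_nest],
    all      = function(d) d$orientation_deg
  )
  out <- list()
  for (site in unique(cavities$site)) {
    d <- cavities[cavities$site == site, , drop = FALSE]
    for (stage in names(pools)) {
      a <- pools[[stage]](d)
      if (length(a) == 0L) next
      m <- circ_mean(a)
      p <- if (length(a) >= 3L) suppressWarnings(rayleigh_test(a)$p) else NA_real_
      lo <- hi <- NA_real_
      if (ci && length(a) >= 10L && !is.na(m$mean_deg)) {
        b <- bootstrap_mean_ci(a, n_boot = n_boot, conf = conf)
        lo <- b$ci_low_deg; hi <- b$ci_high_deg
      }
      out[[length(out) + 1L]] <- data.frame(
        site = site, stage = stage, n = m$n, mean_dir_deg = m$mean_deg,
        r = m$r, rayleigh_p = p, ci_low_deg = lo, ci_high_deg = hi,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
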