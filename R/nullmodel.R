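#' Resampling null-model test of directional clustering
#'
#' Tests whether a focal subset of excavation bearings is more (or less)
#' directionally clustered than random subsets of a reference pool. Each
#' iteration draws \code{length(subset)} bearings from \code{pool} with
#' replacement and records the mean resultant length r; the one-tailed
#' p-value is \eqn{(1 + b) / (n_{iter} + 1)} where b counts null values at
#' least as extreme as the observed r (ties count as extreme).
#'
#' @param subset bearings (degrees) of the focal stage, e.g. completed
#'   cavities at one site.
#' @param pool bearings of the reference pool, e.g. all excavations at the
#'   same site. The caller is responsible for the subset and pool coming from
#'   the same site.
#' @param n_iter number of resampling iterations (default 1000).
#' @param tail \code{"greater"} tests for stronger clustering than the pool,
#'   \code{"less"} for weaker.
#' @param seed optional integer seed.
#' @return object of class \code{null_test}: list with \code{observed_r},
#'   \code{null_r} (length \code{n_iter}), \code{n_subset}, \code{n_pool},
#'   \code{n_iter}, \code{tail}, \code{p}, \code{seed}.
#' @export
clustering_null_test <- function(subset, pool, n_iter = 1000L,
                                 tail = c("greater", "less"), seed = NULL) {
  tail <- match.arg(tail)
  if (length(subset) == 0L) stop("clustering_null_test: empty subset", call. = FALSE)
  if (length(pool) == 0L) stop("clustering_null_test: empty pool", call. = FALSE)
  if (n_iter < 100L)
    warning("clustering_null_test: n_iter < 100 gives a very coarse p-value",
            call. = FALSE)
  if (length(subset) > length(pool))
    message("clustering_null_test: subset larger than pool (resampling with ",
            "replacement, permitted)")
  if (!is.null(seed)) set.seed(seed)
  n_sub <- length(subset)
  observed_r <- circ_mean(subset)$r
  th <- (pool %% 360) * pi / 180
  cs <- cos(th); sn <- sin(th)
  idx <- matrix(sample.int(length(pool), n_iter * n_sub, replace = TRUE),
                nrow = n_iter)
  C <- rowSums(matrix(cs[idx], nrow = n_iter))
  S <- rowSums(matrix(sn[idx], nrow = n_iter))
  null_r <- pmin(sqrt(C^2 + S^2) / n_sub, 1)
  eps <- 1e-12    # ties must count as extreme despite rounding noise
  b <- if (tail == "greater") sum(null_r >= observed_r - eps)
       else sum(null_r <= observed_r + eps)
  structure(list(observed_r = observed_r, null_r = null_r, n_subset = n_sub,
                 n_pool = length(pool), n_iter = as.integer(n_iter),
                 tail = tail, p = (1 + b) / (n_iter + 1), seed = seed),
            class = "null_test")
}

#' @export
print.null_test <- function(x, ...) {
  cat(sprintf(
    "Clustering null test (tail = %s)\n  observed r = %.4f  null mean r = %.4f\n  n_subset = %d, n_pool = %d, iterations = %d\n  p = %.4g\n",
    x$tail, x$observed_r, mean(x$null_r), x$n_subset, x$n_pool, x$n_iter, x$p))
  invisible(x)
}

#' Stage-wise clustering tests for one site
#'
#' Runs the three null-model comparisons for a single site's cavity records:
#' completed cavities vs the pool of all excavations (tail = greater), cavity
#' starts vs all excavations (tail = less), and nests vs completed cavities
#' (tail = greater). Nests are completed cavities and are included in the
#' "all" and "complete" pools; set \code{exclude_nests_from_pool = TRUE} to
#' remove them from the completed-cavity pool in the nest test.
#'
#' A test whose focal subset is empty is skipped with a notice.
#'
#' @param cavities data frame of cavity records for ONE site.
#' @param n_iter iterations per test.
#' @param seed optional integer seed (applied once; tests run in a fixed order).
#' @param exclude_nests_from_pool see Description.
#' @return named list of \code{null_test} objects (subset of
#'   \code{complete_vs_all}, \code{start_vs_all}, \code{nest_vs_complete}).
#' @export
stagewise_tests <- function(cavities, n_iter = 1000L, seed = NULL,
                            exclude_nests_from_pool = FALSE) {
  if (length(unique(cavities$site)) > 1L)
    stop("stagewise_tests: records from more than one site supplied", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  all_a <- cavities$orientation_deg
  comp  <- cavities$orientation_deg[cavities$stage == "complete"]
  start <- cavities$orientation_deg[cavities$stage == "start"]
  nest  <- cavities$orientation_deg[cavities$is_nest]
  nest_pool <- if (exclude_nests_from_pool)
    cavities$orientation_deg[cavities$stage == "complete" & !cavities$is_nest]
  else comp
  out <- list()
  run <- function(name, sub, pool, tail) {
    if (length(sub) == 0L || length(pool) == 0L) {
      message("stagewise_tests: skipping ", name, " (empty subset or pool)")
      return(invisible(NULL))
    }
    out[[name]] <<- clustering_null_test(sub, pool, n_iter = n_iter, tail = tail)
  }
  run("complete_vs_all", comp, all_a, "greater")
  run("start_vs_all", start, all_a, "less")
  run("nest_vs_complete", nest, nest_pool, "greater")
  out
}

#' Tabulate null-test results across sites
#'
#' @param results named list of site -> list of \code{null_test} (as from
#'   \code{\link{stagewise_tests}} per site).
#' @return data frame with one row per site x test.
#' @export
nulltest_table <- function(results) {
  rows <- list()
  for (site in names(results)) for (test in names(results[[site]])) {
    x <- results[[site]][[test]]
    rows[[length(rows) + 1L]] <- data.frame(
      site = site, test_name = test, n_subset = x$n_subset, n_pool = x$n_pool,
      observed_r = x$observed_r, null_mean_r = mean(x$null_r), p = x$p,
      n_iter = x$n_iter, tail = x$tail, stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}
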