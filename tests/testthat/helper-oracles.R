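# Independent oracles and fixture builders used across the suite.

# Brute-force circular mean: unit vectors as complex numbers, summed after
# sorting by angle (independent of the implementation's code path).
oracle_circ_mean <- function(angles) {
  th <- sort((angles %% 360) * pi / 180)
  z <- sum(complex(modulus = 1, argument = th)) / length(th)
  list(mean_deg = (Arg(z) * 180 / pi) %% 360, r = Mod(z))
}

# Exact null-test p by full enumeration of all |pool|^n_subset equiprobable
# resamples with replacement (tiny cases only).
oracle_enum_null_p <- function(subset, pool, tail = "greater") {
  n <- length(subset)
  obs <- oracle_circ_mean(subset)$r
  grids <- do.call(expand.grid, rep(list(seq_along(pool)), n))
  r <- apply(grids, 1, function(idx) oracle_circ_mean(pool[idx])$r)
  eps <- 1e-12
  if (tail == "greater") mean(r >= obs - eps) else mean(r <= obs + eps)
}

# Partial Mantel p by exhausting all n! row/column permutations.
oracle_mantel_enum_p <- function(dy, dx, dz) {
  n <- nrow(dy)
  perms <- function(v) {
    if (length(v) <= 1L) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (rest in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], rest)
    out
  }
  pc <- function(y, x, z) {
    rxy <- cor(x, y); rxz <- cor(x, z); ryz <- cor(y, z)
    (rxy - rxz * ryz) / sqrt((1 - rxz^2) * (1 - ryz^2))
  }
  ut <- function(m) m[upper.tri(m)]
  x <- ut(dx); z <- ut(dz)
  obs <- pc(ut(dy), x, z)
  r <- vapply(perms(seq_len(n)), function(ord)
    pc(ut(dy[ord, ord]), x, z), numeric(1))
  mean(abs(r) >= abs(obs) - 1e-12)
}

write_temp_csv <- function(df) {
  path <- tempfile(fileext = ".csv")
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}

make_cavity_df <- function(site = "A", starts = numeric(0),
                           completes = numeric(0), nests = numeric(0)) {
  k <- length(starts) + length(completes) + length(nests)
  data.frame(
    site = site,
    cavity_id = paste0(site, "_c", seq_len(k)),
    stage = rep(c("start", "complete", "complete"),
                c(length(starts), length(completes), length(nests))),
    is_nest = rep(c(FALSE, FALSE, TRUE),
                  c(length(starts), length(completes), length(nests))),
    orientation_deg = c(starts, completes, nests),
    stringsAsFactors = FALSE)
}

# Bearing membership in a (possibly wrapped) circular interval [lo, hi].
in_circ_interval <- function(x, lo, hi) {
  ((x - lo) %% 360) <= ((hi - lo) %% 360) + 1e-9
}
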