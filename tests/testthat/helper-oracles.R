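# Independent oracles used to validate the package's own implementations.
# Each is a deliberately naive brute-force route: numerical quadrature for the
# convolution, full enumeration for the exact tests.

# Trapezoidal quadrature of the compartment convolution on a fine grid, with
# the plasma curve linearly interpolated. eval times must be multiples of dt.
quadrature_tofts <- function(ktrans, dv, cp, eval_times, dt = 0.1) {
  kt <- ktrans / 100 / 60
  a <- kt / (dv / 100)
  vapply(eval_times, function(te) {
    if (te <= 0) return(0)
    grid <- seq(0, te, by = dt)
    cpg <- approx(cp$times, cp$values, xout = grid, rule = 2)$y
    w <- rep(dt, length(grid)); w[c(1, length(grid))] <- dt / 2
    kt * sum(w * cpg * exp(-a * (te - grid)))
  }, numeric(1))
}

# Two-sided Mann-Whitney p by explicit enumeration of all group assignments.
mw_enum_p <- function(x, y) {
  m <- length(x); n <- length(y); mn <- m * n
  pool <- c(x, y)
  r <- rank(pool)
  combs <- combn(m + n, m)
  us <- apply(combs, 2, function(idx) sum(r[idx]) - m * (m + 1) / 2)
  ux <- sum(r[seq_len(m)]) - m * (m + 1) / 2
  umin <- min(ux, mn - ux)
  if (2 * umin == mn) return(1)
  mean(us <= umin + 1e-9) + mean(us >= mn - umin - 1e-9)
}

# Friedman exact p by explicit enumeration of all (k!)^n within-row rank
# permutations (feasible for a handful of rows).
friedman_enum_p <- function(values) {
  values <- as.matrix(values)
  n <- nrow(values); k <- ncol(values)
  R <- t(apply(values, 1, rank))
  A <- sum(R^2)
  C <- n * k * (k + 1)^2 / 4
  stat_fun <- function(colsums) {
    if (A - C <= 1e-12) return(0)
    (k - 1) * sum((colsums - n * (k + 1) / 2)^2) / (A - C)
  }
  obs <- stat_fun(colSums(R))
  perms <- function(v) {
    if (length(v) == 1L) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (p in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
    out
  }
  row_perms <- lapply(seq_len(n), function(i) perms(R[i, ]))
  idx <- do.call(expand.grid, lapply(row_perms, seq_along))
  stats <- apply(idx, 1, function(sel) {
    cs <- Reduce(`+`, Map(function(rp, j) rp[[j]], row_perms, sel))
    stat_fun(cs)
  })
  mean(stats >= obs - 1e-9)
}

# Spearman exact two-sided p by explicit permutation of y.
spearman_enum_p <- function(x, y) {
  n <- length(x)
  rx <- rank(x); ry <- rank(y)
  obs <- abs(cor(rx, ry))
  perms <- function(v) {
    if (length(v) == 1L) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (p in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
    out
  }
  ps <- perms(seq_len(n))
  rs <- vapply(ps, function(p) cor(rx, ry[p]), numeric(1))
  mean(abs(rs) >= obs - 1e-9)
}

# Compact cohort used by several suites: small but complete.
tiny_cohort <- function(seed = 42, noise_snr = 40) {
  generate_cohort(cohort_spec(n_patients = 6L, max_lesions = 11L,
                              noise_snr = noise_snr, seed = seed))
}
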