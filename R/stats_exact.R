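#' Statistical test result
#'
#' @param statistic test statistic.
#' @param p_value p-value in `[0, 1]` (`NA` if undefined).
#' @param method label.
#' @param exact logical: was the p-value obtained by exact enumeration (TRUE)
#'   or an asymptotic approximation (FALSE)?
#' @param estimate optional effect estimate (e.g. a correlation).
#' @return An object of class `stat_result`.
#' @export
stat_result <- function(statistic, p_value, method, exact, estimate = NULL) {
  if (!is.na(p_value) && (p_value < 0 || p_value > 1))
    dce_validation_error("p_value must lie in [0, 1]")
  structure(list(statistic = statistic, p_value = p_value, method = method,
                 exact = exact, estimate = estimate),
            class = "stat_result")
}

#' @export
print.stat_result <- function(x, ...) {
  cat("<stat_result> ", x$method, ": statistic = ", signif(x$statistic, 5),
      ", p = ", signif(x$p_value, 4),
      if (isTRUE(x$exact)) " (exact)" else " (asymptotic)", "\n", sep = "")
  invisible(x)
}

## all permutations of 1..n as a matrix (n! rows); n small
.perms <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- .perms(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    rest <- seq_len(n)[-i]
    cbind(i, matrix(rest[sub], nrow(sub), n - 1L))
  }))
}

## mid-ranks
.midrank <- function(x) rank(x, ties.method = "average")

## ---- Friedman -------------------------------------------------------------

## Tie-robust Friedman statistic (Conover form) from column rank sums.
## A = sum of all squared within-row ranks (invariant under within-row
## permutation), n rows, k columns. Reduces to the classic chi-square form
## 12/(nk(k+1)) * sum Rj^2 - 3n(k+1) when there are no ties.
.friedman_stat <- function(colsums, n, k, A) {
  C <- n * k * (k + 1)^2 / 4
  if (A - C <= 1e-12) return(0)   # all rows constant
  (k - 1) * sum((colsums - n * (k + 1) / 2)^2) / (A - C)
}

## Exact null distribution of the column-rank-sum vector by dynamic
## programming over rows: each row's rank vector is permuted uniformly over
## its k! arrangements; states are the first (k-1) doubled rank sums.
.friedman_exact_p <- function(R, stat_obs) {
  n <- nrow(R); k <- ncol(R)
  A <- sum(R^2)
  P <- .perms(k)
  states <- new.env(hash = TRUE, parent = emptyenv())
  assign(paste(integer(k - 1L), collapse = ","), 1, envir = states)
  for (i in seq_len(n)) {
    r2 <- as.integer(round(2 * R[i, ]))  # doubled mid-ranks are integers
    # uniform over k! permutations: weight each distinct arrangement by its
    # multiplicity among the k! permutations
    all_arr <- matrix(r2[P], nrow(P), k)
    keys_arr <- apply(all_arr[, -k, drop = FALSE], 1, paste, collapse = ",")
    wt <- table(keys_arr) / nrow(P)
    arr_sums <- do.call(rbind, strsplit(names(wt), ","))
    arr_sums <- matrix(as.integer(arr_sums), nrow = length(wt))
    nxt <- new.env(hash = TRUE, parent = emptyenv())
    for (key in ls(states)) {
      s <- as.integer(strsplit(key, ",")[[1]])
      w0 <- get(key, envir = states)
      for (j in seq_along(wt)) {
        ns <- s + arr_sums[j, ]
        nk <- paste(ns, collapse = ",")
        prev <- if (exists(nk, envir = nxt, inherits = FALSE))
          get(nk, envir = nxt) else 0
        assign(nk, prev + w0 * as.numeric(wt[j]), envir = nxt)
      }
    }
    states <- nxt
  }
  rowtot <- sum(R[1, ])  # identical for every row (ranks of k values)
  total_all <- n * rowtot
  p <- 0
  for (key in ls(states)) {
    s2 <- as.integer(strsplit(key, ",")[[1]]) / 2  # back to mid-rank units
    colsums <- c(s2, n * rowtot - sum(s2))
    q <- .friedman_stat(colsums, n, k, A)
    if (q >= stat_obs - 1e-9) p <- p + get(key, envir = states)
  }
  min(p, 1)
}

#' Friedman test for repeated measures across timepoints
#'
#' Nonparametric test for a location shift across k >= 3 related samples
#' (e.g. a kinetic parameter at three timepoints for the same lesions).
#' Within-row mid-ranks are used for ties; the tie-robust (Conover-form)
#' chi-square statistic is computed. For small samples
#' (`n <= exact_limit` rows) the p-value is exact, obtained by enumerating
#' the null distribution over all (k!)^n within-row rank arrangements via
#' dynamic programming; otherwise the chi-square approximation with k-1
#' degrees of freedom is used.
#'
#' @param values numeric matrix, rows = subjects/lesions, columns =
#'   conditions/timepoints (k >= 3, no missing cells).
#' @param exact_limit maximum number of rows for exact enumeration
#'   (default 8).
#' @return A [stat_result()] (constant data give statistic 0, p = 1).
#' @export
friedman_exact <- function(values, exact_limit = 8L) {
  values <- as.matrix(values)
  if (anyNA(values)) dce_validation_error("missing cells are not allowed")
  n <- nrow(values); k <- ncol(values)
  if (n < 2L || k < 3L)
    dce_validation_error("need >= 2 rows and >= 3 columns")
  R <- t(apply(values, 1, .midrank))
  A <- sum(R^2)
  stat <- .friedman_stat(colSums(R), n, k, A)
  C <- n * k * (k + 1)^2 / 4
  if (A - C <= 1e-12)
    return(stat_result(0, 1, "Friedman (degenerate: constant rows)", TRUE))
  if (n <= exact_limit) {
    p <- .friedman_exact_p(R, stat)
    stat_result(stat, p, "Friedman (exact permutation)", TRUE)
  } else {
    p <- stats::pchisq(stat, df = k - 1, lower.tail = FALSE)
    stat_result(stat, p, "Friedman (chi-square approximation)", FALSE)
  }
}

## ---- Mann-Whitney ---------------------------------------------------------

## exact null counts of U = 0..mn for group sizes m, n (no ties), cached
.mw_cache <- new.env(parent = emptyenv())
.mw_counts <- function(m, n) {
  key <- paste(m, n, sep = "_")
  if (!is.null(.mw_cache[[key]])) return(.mw_cache[[key]])
  mn <- m * n
  # dp[i+1, u+1]: ways to assign the smallest k ranks with i of them in
  # group x and pair-beat count u; placing rank k as x beats the k-i y's
  # already placed... (k - 1 - (i - 1)) = k - i.
  dp <- matrix(0, m + 1L, mn + 1L)
  dp[1L, 1L] <- 1
  N <- m + n
  for (k in seq_len(N)) {
    new <- matrix(0, m + 1L, mn + 1L)
    for (i in 0:min(k, m)) {
      row <- dp[i + 1L, ]
      if (!any(row > 0)) next
      # as y: allowed if y count so far (k-1-i) < n
      if (k - 1L - i < n) new[i + 1L, ] <- new[i + 1L, ] + row
      # as x: allowed if i < m; U increases by (k-1-i)
      if (i < m) {
        shift <- k - 1L - i
        new[i + 2L, (1L + shift):(mn + 1L)] <-
          new[i + 2L, (1L + shift):(mn + 1L)] + row[1:(mn + 1L - shift)]
      }
    }
    dp <- new
  }
  counts <- dp[m + 1L, ]
  .mw_cache[[key]] <- counts
  counts
}

#' Mann-Whitney U test for two independent groups
#'
#' Reports the smaller of the two U statistics. For combined sample sizes up
#' to `exact_limit` with no ties the two-sided p-value is exact, computed
#' from the full enumeration (dynamic-programming count) of the null U
#' distribution: p = P(U <= min(u, mn-u)) + P(U >= max(u, mn-u)). With ties
#' or larger samples, the tie-corrected normal approximation (no continuity
#' correction) is used; identical groups then give p = 1 by the symmetry of
#' the statistic.
#'
#' @param x,y numeric vectors (both nonempty).
#' @param exact_limit maximum `length(x) + length(y)` for exact enumeration
#'   (default 25).
#' @return A [stat_result()] with `statistic` = min(U).
#' @export
mann_whitney_u <- function(x, y, exact_limit = 25L) {
  if (!length(x) || !length(y))
    dce_validation_error("both groups must be nonempty")
  m <- length(x); n <- length(y); mn <- m * n
  r <- .midrank(c(x, y))
  ux <- sum(r[seq_len(m)]) - m * (m + 1) / 2
  uy <- mn - ux
  u <- min(ux, uy)
  ties <- anyDuplicated(c(x, y)) > 0L
  if (!ties && m + n <= exact_limit) {
    counts <- .mw_counts(m, n)
    tot <- sum(counts)
    lo <- sum(counts[seq_len(u + 1L)])                 # P(U <= u)
    hi <- sum(counts[(mn - u + 1L):(mn + 1L)])         # P(U >= mn - u)
    p <- if (2 * u == mn) 1 else min(1, (lo + hi) / tot)
    return(stat_result(u, p, "Mann-Whitney U (exact enumeration)", TRUE))
  }
  tie_tab <- table(r)
  N <- m + n
  sigma2 <- m * n / 12 * ((N + 1) - sum(tie_tab^3 - tie_tab) / (N * (N - 1)))
  if (sigma2 <= 0) return(stat_result(u, 1, "Mann-Whitney U (degenerate)", FALSE))
  z <- (ux - mn / 2) / sqrt(sigma2)
  p <- min(1, 2 * stats::pnorm(-abs(z)))
  stat_result(u, p, "Mann-Whitney U (normal approximation, tie-corrected)", FALSE)
}

## ---- Spearman -------------------------------------------------------------

#' Spearman rank correlation
#'
#' Rank correlation with mid-ranks for ties (Pearson correlation of the rank
#' vectors). For `n <= exact_limit` the two-sided p-value is exact by full
#' permutation enumeration, P(|rho_perm| >= |rho_obs|); otherwise the
#' t-approximation with n-2 degrees of freedom is used. Zero variance in
#' either variable leaves the correlation undefined (statistic `NA`,
#' p `NA`).
#'
#' @param x,y paired numeric vectors, n >= 3.
#' @param exact_limit maximum n for exact permutation (default 9).
#' @return A [stat_result()] with `estimate` = rho.
#' @export
spearman_rank <- function(x, y, exact_limit = 9L) {
  n <- length(x)
  if (n != length(y) || n < 3L)
    dce_validation_error("need n >= 3 complete pairs")
  rx <- .midrank(x); ry <- .midrank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0)
    return(stat_result(NA_real_, NA_real_,
                       "Spearman rank correlation (undefined: zero variance)",
                       FALSE, estimate = NA_real_))
  rho <- stats::cor(rx, ry)
  if (n <= exact_limit) {
    P <- .perms(n)
    # correlation for every permutation of y-ranks against fixed x-ranks
    ryp <- matrix(ry[P], nrow(P), n)
    num <- ryp %*% rx - n * mean(rx) * mean(ry)
    rall <- num / (n * stats::sd(rx) * stats::sd(ry) * (n - 1) / n)
    p <- mean(abs(rall) >= abs(rho) - 1e-12)
    return(stat_result(rho, p, "Spearman rank correlation (exact permutation)",
                       TRUE, estimate = rho))
  }
  tstat <- rho * sqrt((n - 2) / (1 - rho^2))
  p <- min(1, 2 * stats::pt(-abs(tstat), df = n - 2))
  stat_result(rho, p, "Spearman rank correlation (t approximation)", FALSE,
              estimate = rho)
}
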