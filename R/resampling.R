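#' Permutation test for two independent samples
#'
#' Tests the difference of group means by permuting group labels. When the
#' number of distinct label assignments is at most `exact_limit` the full
#' null distribution is enumerated and the p-value is the exact proportion
#' of assignments with `|statistic| >= |observed|`; otherwise `n_perm`
#' Monte-Carlo permutations are drawn and the add-one estimator
#' `p = (1 + n_extreme) / (n_perm + 1)` is used, so the p-value is never
#' zero. Two-sided throughout; missing values are removed per group.
#'
#' @param x,y Numeric vectors (each needs at least two non-missing values).
#' @param n_perm Number of Monte-Carlo permutations.
#' @param seed Optional integer seed for the Monte-Carlo path.
#' @param exact_limit Enumerate exhaustively when the number of assignments
#'   is at most this.
#' @return Object of class `perm_test`: `statistic` (mean(x) - mean(y)),
#'   `p_value`, `n_perm` (a count, or `"exact"`), `seed`, `strata`.
#' @export
perm_test <- function(x, y, n_perm = 100000L, seed = NULL,
                      exact_limit = 200000L) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) < 2L || length(y) < 2L)
    stopf("both groups need at least two non-missing values")
  perm_engine(values = c(x, y), is_x = rep(c(TRUE, FALSE), c(length(x), length(y))),
              strata = rep(1L, length(x) + length(y)),
              n_perm = n_perm, seed = seed, exact_limit = exact_limit)
}

#' Stratified permutation test for two independent samples
#'
#' As [perm_test()], but group labels are permuted only within strata (e.g.
#' pre/postnatal stage), preserving each stratum's group counts, which
#' conditions the test on the stratum margins. Strata containing only one
#' group are dropped with a warning. With a single stratum the test reduces
#' exactly to [perm_test()] (same seed, same p-value).
#'
#' @param x,y Numeric vectors.
#' @param strata Stratum labels aligned to `c(x, y)`.
#' @inheritParams perm_test
#' @return A `perm_test` object with the stratum labels recorded.
#' @export
stratified_perm_test <- function(x, y, strata, n_perm = 100000L, seed = NULL,
                                 exact_limit = 200000L) {
  if (length(strata) != length(x) + length(y))
    stopf("`strata` must align with c(x, y)")
  values <- c(x, y)
  is_x <- rep(c(TRUE, FALSE), c(length(x), length(y)))
  ok <- !is.na(values)
  values <- values[ok]; is_x <- is_x[ok]; strata <- strata[ok]
  if (sum(is_x) < 2L || sum(!is_x) < 2L)
    stopf("both groups need at least two non-missing values")
  degenerate <- vapply(split(is_x, strata),
                       function(s) all(s) || !any(s), TRUE)
  if (all(degenerate)) stopf("every stratum contains only one group")
  if (any(degenerate)) {
    drop <- names(degenerate)[degenerate]
    warnf("stratum/strata with a single group dropped: %s",
          paste(drop, collapse = ", "))
    keep <- !(strata %in% drop)
    values <- values[keep]; is_x <- is_x[keep]; strata <- strata[keep]
  }
  res <- perm_engine(values, is_x, strata, n_perm, seed, exact_limit)
  res$strata <- sort(unique(as.character(strata)))
  res
}

# shared engine: exact enumeration over per-stratum label assignments when
# feasible, Monte-Carlo within-stratum shuffling otherwise
perm_engine <- function(values, is_x, strata, n_perm, seed, exact_limit) {
  idx_by_s <- split(seq_along(values), strata)
  nx_s <- vapply(idx_by_s, function(i) sum(is_x[i]), 0L)
  n_s <- lengths(idx_by_s)
  nx <- sum(is_x); ny <- sum(!is_x)
  obs <- mean(values[is_x]) - mean(values[!is_x])
  total_assignments <- prod(choose(n_s, nx_s))
  tol <- 1e-8 * (max(abs(values)) + 1)
  to_stat <- function(sum_x) {
    tot <- sum(values)
    sum_x / nx - (tot - sum_x) / ny
  }
  if (total_assignments <= exact_limit) {
    # per stratum, the possible sums of the x-labelled values; combine by
    # outer addition across strata (each assignment appears exactly once)
    sums_s <- lapply(seq_along(idx_by_s), function(s) {
      v <- values[idx_by_s[[s]]]
      k <- nx_s[s]
      if (k == 0L) return(0)
      if (k == n_s[s]) return(sum(v))
      colSums(matrix(v[utils::combn(n_s[s], k)], nrow = k))
    })
    sum_x <- Reduce(function(a, b) as.vector(outer(a, b, `+`)), sums_s)
    stats_all <- to_stat(sum_x)
    p <- mean(abs(stats_all) >= abs(obs) - tol)
    out <- list(statistic = obs, p_value = p, n_perm = "exact",
                n_assignments = length(stats_all), seed = seed, strata = NULL)
  } else {
    if (!is.null(seed)) set.seed(seed)
    count <- 0L
    for (b in seq_len(n_perm)) {
      sum_x <- 0
      for (s in seq_along(idx_by_s)) {
        v <- values[idx_by_s[[s]]]
        pick <- sample.int(n_s[s], nx_s[s])
        sum_x <- sum_x + sum(v[pick])
      }
      if (abs(to_stat(sum_x)) >= abs(obs) - tol) count <- count + 1L
    }
    p <- (1 + count) / (n_perm + 1)
    out <- list(statistic = obs, p_value = p, n_perm = n_perm,
                seed = seed, strata = NULL)
  }
  structure(out, class = "perm_test")
}

#' @export
print.perm_test <- function(x, ...) {
  cat(sprintf("two-sample permutation test%s\n",
              if (!is.null(x$strata)) " (stratified)" else ""))
  cat(sprintf("  statistic (mean difference): %.6g\n", x$statistic))
  cat(sprintf("  p-value: %.6g  [%s]\n", x$p_value,
              if (identical(x$n_perm, "exact"))
                sprintf("exact, %d assignments", x$n_assignments)
              else sprintf("Monte-Carlo, %d permutations", x$n_perm)))
  invisible(x)
}

#' Spearman rank correlation with t-approximation p-value
#'
#' Pearson correlation of average-tie ranks after pairwise deletion of
#' missing values, with a two-sided p-value from the t-approximation on
#' n - 2 degrees of freedom.
#'
#' @param x,y Numeric vectors of equal length.
#' @return List with `r`, `p` and `n` (complete pairs). A constant vector
#'   gives `r = NA` with a warning.
#' @export
spearman_corr <- function(x, y) {
  if (length(x) != length(y)) stopf("`x` and `y` must have equal length")
  ok <- stats::complete.cases(x, y)
  n <- sum(ok)
  if (n < 3L) stopf("fewer than 3 complete pairs")
  x <- x[ok]; y <- y[ok]
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warnf("constant input; correlation undefined")
    return(list(r = NA_real_, p = NA_real_, n = n))
  }
  r <- stats::cor(rank(x), rank(y))
  if (abs(r) >= 1) return(list(r = r, p = 0, n = n))
  tstat <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p = 2 * stats::pt(-abs(tstat), df = n - 2), n = n)
}

#' Per-animal mean and coefficient of variation of morphometric measurements
#'
#' Summarizes repeated histomorphometric measurements (e.g. nuclear area over
#' at least 200 nuclei per animal) as the per-animal mean and coefficient of
#' variation (sample standard deviation over mean), the latter a measure of
#' cell heterogeneity such as anisocytosis. The CV is undefined (`NA`) when
#' the mean is not strictly positive.
#'
#' @param measurements Long-format data frame with columns `animal_id`,
#'   `parameter`, `value`.
#' @return Data frame `animal_id`, `parameter`, `n`, `mean`, `cv`.
#' @export
summarize_morphometry <- function(measurements) {
  need <- c("animal_id", "parameter", "value")
  if (!all(need %in% names(measurements)))
    stopf("`measurements` needs columns %s", paste(need, collapse = ", "))
  parts <- split(measurements,
                 list(measurements$animal_id, measurements$parameter),
                 drop = TRUE)
  rows <- lapply(parts, function(d) {
    v <- d$value[!is.na(d$value)]
    if (length(v) < 2L)
      stopf("animal %s, parameter %s: need at least two measurements",
            d$animal_id[1], d$parameter[1])
    mu <- mean(v)
    data.frame(animal_id = d$animal_id[1], parameter = d$parameter[1],
               n = length(v), mean = mu,
               cv = if (mu > 0) stats::sd(v) / mu else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$animal_id, out$parameter), , drop = FALSE]
}
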