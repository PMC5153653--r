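#' Merge rare score categories before correspondence analysis
#'
#' Poorly represented categories distort correspondence-analysis dimensions,
#' so any observed category with fewer than `min_count` individuals is merged
#' with its adjacent observed severity category and the rule is iterated
#' until every observed category reaches `min_count` (or a variable is left
#' with a single category and is dropped with a warning). Merging prefers the
#' next-higher severity neighbour and falls back to the next-lower one, so a
#' rare pathological grade joins the adjacent pathological grade rather than
#' the "absent" baseline whenever possible. Merged labels concatenate their
#' constituent codes in severity order (e.g. `S1` + `S2` becomes `S1S2`).
#' Unobserved categories never contribute.
#'
#' @param table Data frame of categorical scores (rows = animals). Columns
#'   may be factors whose level order encodes severity; character columns
#'   use code sort order.
#' @param min_count Minimum number of individuals per observed category.
#' @return Data frame of character columns with merged category labels.
#' @export
merge_rare_categories <- function(table, min_count = 4L) {
  min_count <- assert_count(min_count, "min_count", lower = 1L)
  out <- as.data.frame(table, stringsAsFactors = FALSE)
  for (v in names(out)) {
    x <- out[[v]]
    sev <- if (is.factor(x)) levels(x) else sort(unique(as.character(x)))
    x <- as.character(x)
    # groups of constituent codes, kept in severity order
    grps <- as.list(intersect(sev, unique(x)))
    label <- function(g) paste(g, collapse = "")
    repeat {
      counts <- vapply(grps, function(g) sum(x %in% g), 0L)
      rare <- which(counts < min_count)
      if (!length(rare) || length(grps) == 1L) break
      i <- rare[[1]]
      j <- if (i < length(grps)) i + 1L else i - 1L
      grps[[min(i, j)]] <- c(grps[[min(i, j)]], grps[[max(i, j)]])
      grps[[max(i, j)]] <- NULL
    }
    if (length(grps) == 1L) {
      warnf("variable %s collapsed to a single category; dropped", v)
      out[[v]] <- NULL
      next
    }
    for (g in grps) x[x %in% g] <- label(g)
    out[[v]] <- x
  }
  out
}

#' Multiple correspondence analysis of categorical scores
#'
#' Correspondence analysis of the complete disjunctive (indicator) coding of
#' `Q` categorical variables: eigenvalues sum to `J/Q - 1` for `J` observed
#' categories; variance percentages are raw eigenvalue shares (no adjusted
#' inertia). Row (individual) and column (category) coordinates are in
#' principal normalization. Each axis is oriented so that its
#' largest-magnitude category coordinate is positive.
#'
#' @param table Data frame of categorical variables with no missing cells,
#'   at least two variables and two observed categories each.
#' @return An object of class `ordination`: `eig` (data frame `eigenvalue`,
#'   `pct_variance`, `cum_pct`), `row_coords`, `col_coords`,
#'   `contributions` (category x dim, in percent), `cos2`, `total_inertia`,
#'   `method = "mca"`.
#' @export
mca <- function(table) {
  table <- as.data.frame(table, stringsAsFactors = FALSE)
  if (ncol(table) < 2L) stopf("MCA needs at least two variables")
  if (anyNA(table))
    stopf("MCA input has missing cells; remove incomplete rows first")
  q <- ncol(table)
  ind <- lapply(names(table), function(v) {
    f <- factor(table[[v]])
    if (nlevels(f) < 2L) stopf("variable %s has fewer than two observed categories", v)
    m <- stats::model.matrix(~ f - 1)
    colnames(m) <- paste(v, levels(f), sep = ".")
    m
  })
  Z <- do.call(cbind, ind)
  res <- ca_core(Z)
  res$total_inertia <- ncol(Z) / q - 1
  res$method <- "mca"
  rownames(res$row_coords) <- rownames(table) %||% as.character(seq_len(nrow(table)))
  res
}

# correspondence analysis of a nonnegative matrix (indicator coding here);
# returns principal coordinates with deterministic axis orientation
ca_core <- function(Z, tol = 1e-12) {
  P <- Z / sum(Z)
  r <- rowSums(P)
  cmass <- colSums(P)
  S <- (P - tcrossprod(r, cmass)) / sqrt(tcrossprod(r, cmass))
  dec <- svd(S)
  keep <- which(dec$d^2 > tol * max(1, dec$d[1]^2))
  d <- dec$d[keep]
  lam <- d^2
  row_coords <- sweep(dec$u[, keep, drop = FALSE] %*% diag(d, length(d)), 1,
                      sqrt(r), "/")
  col_coords <- sweep(dec$v[, keep, drop = FALSE] %*% diag(d, length(d)), 1,
                      sqrt(cmass), "/")
  # orient each axis so the largest-magnitude category coordinate is positive
  for (s in seq_along(lam)) {
    k <- which.max(abs(col_coords[, s]))
    if (col_coords[k, s] < 0) {
      col_coords[, s] <- -col_coords[, s]
      row_coords[, s] <- -row_coords[, s]
    }
  }
  dn <- paste0("Dim", seq_along(lam))
  dimnames(row_coords) <- list(rownames(Z), dn)
  dimnames(col_coords) <- list(colnames(Z), dn)
  contrib <- sweep(col_coords^2 * cmass, 2, lam, "/") * 100
  cos2 <- col_coords^2 / rowSums(col_coords^2)
  pct <- lam / sum(lam) * 100
  structure(list(eig = data.frame(eigenvalue = lam, pct_variance = pct,
                                  cum_pct = cumsum(pct), row.names = dn),
                 row_coords = row_coords, col_coords = col_coords,
                 contributions = contrib, cos2 = cos2),
            class = "ordination")
}

#' Principal component analysis of rank-converted variables
#'
#' Replaces each variable by its average-tie ranks (homogenizing skewed
#' percentage distributions), then performs PCA on the correlation matrix.
#' Rows with any missing value are excluded; zero-variance columns are
#' excluded with a warning. The result is invariant under strictly monotone
#' transforms of any input column. Axes are oriented so the
#' largest-magnitude loading is positive.
#'
#' @param table Data frame or matrix of quantitative variables (rows =
#'   individuals).
#' @param drop Optional character vector of variable names to remove before
#'   the analysis.
#' @return An `ordination` object; `col_coords` holds variable loadings
#'   scaled to correlations with the components.
#' @export
rank_pca <- function(table, drop = NULL) {
  x <- as.data.frame(table)
  if (!is.null(drop)) {
    unknown <- setdiff(drop, names(x))
    if (length(unknown)) stopf("cannot drop unknown variables: %s",
                               paste(unknown, collapse = ", "))
    x <- x[, setdiff(names(x), drop), drop = FALSE]
  }
  cc <- stats::complete.cases(x)
  if (!all(cc)) message(sum(!cc), " row(s) with missing values excluded")
  x <- x[cc, , drop = FALSE]
  ranks <- as.data.frame(lapply(x, rank), col.names = names(x))
  v <- vapply(ranks, stats::var, 0)
  if (any(v == 0)) {
    warnf("zero-variance variable(s) excluded: %s",
          paste(names(ranks)[v == 0], collapse = ", "))
    ranks <- ranks[, v > 0, drop = FALSE]
  }
  if (ncol(ranks) < 2L) stopf("fewer than two variables with nonzero variance")
  pca_core(scale(as.matrix(ranks)), rownames(x) %||% which(cc), method = "rank_pca")
}

# PCA of a centred/scaled matrix via SVD; eigenvalues on the sample-variance
# scale, row scores in principal coordinates, loadings as correlations
pca_core <- function(Zs, row_names, method, col_weights = NULL, tol = 1e-12) {
  n <- nrow(Zs)
  dec <- svd(Zs / sqrt(n - 1))
  keep <- which(dec$d^2 > tol * max(1, dec$d[1]^2))
  d <- dec$d[keep]
  lam <- d^2
  scores <- dec$u[, keep, drop = FALSE] %*% diag(d * sqrt(n - 1), length(d))
  load <- dec$v[, keep, drop = FALSE]
  # variable correlation with each component
  corr <- vapply(seq_along(lam), function(s)
    suppressWarnings(stats::cor(Zs, scores[, s]))[, 1], numeric(ncol(Zs)))
  corr <- matrix(corr, ncol = length(lam))
  for (s in seq_along(lam)) {
    k <- which.max(abs(load[, s]))
    if (load[k, s] < 0) {
      load[, s] <- -load[, s]
      scores[, s] <- -scores[, s]
      corr[, s] <- -corr[, s]
    }
  }
  dn <- paste0("Dim", seq_along(lam))
  dimnames(scores) <- list(row_names, dn)
  dimnames(load) <- list(colnames(Zs), dn)
  dimnames(corr) <- list(colnames(Zs), dn)
  pct <- lam / sum(lam) * 100
  structure(list(eig = data.frame(eigenvalue = lam, pct_variance = pct,
                                  cum_pct = cumsum(pct), row.names = dn),
                 row_coords = scores, col_coords = corr, loadings = load,
                 method = method),
            class = "ordination")
}

#' Multiple factor analysis across variable sets
#'
#' Balances several sets of quantitative variables measured on the same
#' individuals and analyses them jointly: every variable is centred and
#' unit-scaled, each set is weighted by the inverse of the first eigenvalue
#' of its separate PCA (so no set can dominate the first global axis), and a
#' global PCA of the concatenated weighted matrix yields the common
#' dimensions. Each active set's coordinate on dimension s is its weighted
#' sum of squared variable correlations with that dimension (these sum to
#' the dimension's eigenvalue across sets and are bounded by 1). A
#' categorical illustrative variable is projected as the squared correlation
#' ratio (eta-squared) of each dimension against its categories.
#'
#' @param sets Named list of data frames sharing row names (individuals).
#'   Rows with a missing value in any set are excluded with a message.
#' @param illustrative Optional factor/character vector of group labels,
#'   either named by individual or aligned to the common rows.
#' @return An object of class `mfa` (inheriting `ordination`) with
#'   additional elements `set_weights` (1/lambda1 per set), `group_coords`
#'   (sets x dims), `illustrative_coords` (eta-squared per dim), and
#'   `var_correlations`.
#' @export
mfa <- function(sets, illustrative = NULL) {
  if (!is.list(sets) || is.null(names(sets)) || length(sets) < 2L)
    stopf("`sets` must be a named list of at least two variable sets")
  sets <- lapply(sets, as.data.frame)
  ids <- rownames(sets[[1]])
  if (is.null(ids)) stopf("set rows must be named by individual")
  for (s in sets) if (!identical(rownames(s), ids))
    stopf("all sets must share the same individuals in the same order")
  complete <- Reduce(`&`, lapply(sets, stats::complete.cases))
  if (!all(complete))
    message(sum(!complete), " individual(s) with missing data excluded")
  sets <- lapply(sets, function(s) s[complete, , drop = FALSE])
  ids <- ids[complete]
  if (length(ids) < 3L) stopf("fewer than three complete individuals")

  scaled <- lapply(names(sets), function(nm) {
    m <- as.matrix(sets[[nm]])
    if (!is.numeric(m)) stopf("set %s is not numeric", nm)
    sds <- apply(m, 2, stats::sd)
    if (any(sds == 0)) stopf("set %s contains a constant variable", nm)
    colnames(m) <- paste(nm, colnames(m), sep = ".")
    scale(m)
  })
  lambda1 <- vapply(scaled, function(z) eigen(stats::cor(z), symmetric = TRUE,
                                              only.values = TRUE)$values[1], 0)
  names(lambda1) <- names(sets)
  weights <- 1 / lambda1
  weighted <- Map(function(z, w) z * sqrt(w), scaled, weights)
  Zw <- do.call(cbind, weighted)

  res <- pca_core(Zw, ids, method = "mfa")
  ndim <- nrow(res$eig)

  # correlations of the original (unweighted) variables with each dimension;
  # scaling does not change correlations, so reuse the weighted columns
  corr <- res$col_coords
  set_of <- rep(names(sets), vapply(scaled, ncol, 0L))
  gc <- vapply(names(sets), function(nm) {
    cols <- set_of == nm
    colSums(corr[cols, , drop = FALSE]^2) * weights[nm]
  }, numeric(ndim))
  group_coords <- t(matrix(gc, nrow = ndim,
                           dimnames = list(rownames(res$eig), names(sets))))

  ill <- NULL
  if (!is.null(illustrative)) {
    g <- illustrative
    if (!is.null(names(g))) g <- g[ids]
    if (length(g) != length(ids))
      stopf("`illustrative` must align with the complete-case individuals")
    ill <- vapply(seq_len(ndim), function(s) eta_squared(res$row_coords[, s], g), 0)
    names(ill) <- rownames(res$eig)
  }

  res$set_weights <- weights
  res$set_lambda1 <- lambda1
  res$group_coords <- group_coords
  res$illustrative_coords <- ill
  res$var_correlations <- corr
  class(res) <- c("mfa", "ordination")
  res
}

# squared correlation ratio of a quantitative score against a grouping
eta_squared <- function(x, g) {
  g <- as.factor(g)
  mu <- mean(x)
  ss_tot <- sum((x - mu)^2)
  if (ss_tot == 0) return(NA_real_)
  mg <- tapply(x, g, mean)
  ng <- tapply(x, g, length)
  sum(ng * (mg - mu)^2) / ss_tot
}

#' Correlation of variables with an ordination dimension
#'
#' Pearson correlation of each quantitative variable with the row scores of
#' one dimension, with a two-sided t-test p-value; no multiplicity
#' correction is applied. Variables with fewer than three complete pairs are
#' skipped with a warning.
#'
#' @param result An `ordination` (or `mfa`) object.
#' @param variables Data frame of quantitative variables whose rows match
#'   the ordination rows (by rowname when available, else by position).
#' @param dim Dimension index.
#' @param alpha Significance level for the `significant` flag.
#' @return Data frame `variable`, `r`, `p`, `significant`.
#' @export
dim_correlations <- function(result, variables, dim = 1L, alpha = 0.05) {
  scores <- result$row_coords[, dim]
  variables <- as.data.frame(variables)
  if (!is.null(rownames(variables)) &&
      all(rownames(result$row_coords) %in% rownames(variables)))
    variables <- variables[rownames(result$row_coords), , drop = FALSE]
  else if (nrow(variables) != length(scores))
    stopf("`variables` rows do not match the ordination rows")
  rows <- lapply(names(variables), function(v) {
    x <- variables[[v]]
    ok <- stats::complete.cases(x, scores)
    if (sum(ok) < 3L) {
      warnf("variable %s has fewer than 3 complete pairs; skipped", v)
      return(NULL)
    }
    if (stats::sd(x[ok]) == 0) {
      warnf("variable %s is constant; skipped", v)
      return(NULL)
    }
    ct <- stats::cor.test(x[ok], scores[ok])
    data.frame(variable = v, r = unname(ct$estimate), p = ct$p.value,
               significant = ct$p.value < alpha, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows) %||%
    data.frame(variable = character(), r = numeric(), p = numeric(),
               significant = logical())
}

#' Confidence ellipses of group means in an ordination plane
#'
#' For each group, the 95 percent (by default) confidence ellipse of the
#' group mean in a two-dimensional ordination plane: centred on the group
#' centroid, with dispersion equal to the sample covariance divided by the
#' group size, scaled by the chi-square quantile with 2 degrees of freedom.
#' Groups with fewer than three members, or with degenerate (zero)
#' dispersion, are skipped with a warning.
#'
#' @param row_coords Numeric matrix of row scores (at least two columns).
#' @param groups Group label per row.
#' @param level Confidence level.
#' @param dims Length-2 integer vector of dimensions to use.
#' @return Data frame with one row per retained group: `group`, `n`,
#'   centre (`cx`, `cy`), dispersion entries (`v11`, `v12`, `v22`) and
#'   `scale` (the chi-square quantile).
#' @export
group_ellipses <- function(row_coords, groups, level = 0.95, dims = c(1L, 2L)) {
  assert_number(level, "level", 0, 1)
  xy <- row_coords[, dims, drop = FALSE]
  rows <- lapply(unique(groups), function(g) {
    m <- xy[groups == g, , drop = FALSE]
    if (nrow(m) < 3L) {
      warnf("group %s has fewer than 3 members; skipped", g)
      return(NULL)
    }
    v <- stats::cov(m) / nrow(m)
    if (det(v) <= 0 && all(abs(v) < 1e-12)) {
      warnf("group %s has degenerate dispersion; skipped", g)
      return(NULL)
    }
    data.frame(group = g, n = nrow(m), cx = mean(m[, 1]), cy = mean(m[, 2]),
               v11 = v[1, 1], v12 = v[1, 2], v22 = v[2, 2],
               scale = stats::qchisq(level, df = 2), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows) %||%
    data.frame(group = character(), n = integer(), cx = numeric(),
               cy = numeric(), v11 = numeric(), v12 = numeric(),
               v22 = numeric(), scale = numeric())
}

#' @export
print.ordination <- function(x, ...) {
  cat(sprintf("%s ordination: %d dimensions\n", x$method, nrow(x$eig)))
  print(round(utils::head(x$eig, 5), 3))
  invisible(x)
}

#' @export
print.mfa <- function(x, ...) {
  cat(sprintf("MFA over %d sets, %d dimensions\n",
              nrow(x$group_coords), nrow(x$eig)))
  print(round(utils::head(x$eig, 5), 3))
  cat("set coordinates (first two dimensions):\n")
  print(round(x$group_coords[, seq_len(min(2, ncol(x$group_coords))), drop = FALSE], 3))
  invisible(x)
}
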