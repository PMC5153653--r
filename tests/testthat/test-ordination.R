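# brute-force CA/PCA oracle: eigen-decomposition of the explicitly
# constructed small matrices, independent of the package's SVD route
ca_eigen_oracle <- function(Z) {
  P <- Z / sum(Z)
  r <- rowSums(P); cmass <- colSums(P)
  S <- (P - outer(r, cmass)) / sqrt(outer(r, cmass))
  ev <- eigen(t(S) %*% S, symmetric = TRUE, only.values = TRUE)$values
  sort(ev[ev > 1e-10], decreasing = TRUE)
}

indicator <- function(df) {
  do.call(cbind, lapply(names(df), function(v) {
    f <- factor(df[[v]])
    m <- stats::model.matrix(~ f - 1)
    colnames(m) <- paste(v, levels(f), sep = ".")
    m
  }))
}

test_that("rare-category merging follows the severity-adjacency rule", {
  fx <- load_lesion_fixture()
  sc <- fx$scores[complete.cases(fx$scores), -1]
  merged <- merge_rare_categories(sc)
  expect_setequal(unique(merged$S), c("S0", "S1S2"))
  expect_equal(sum(merged$S == "S1S2"), 5)
  expect_setequal(unique(merged$A), c("A0", "A1", "A2A3"))
  expect_setequal(unique(merged$C), c("C0", "C1C2"))
  expect_setequal(unique(merged$I), c("I0", "I1I2"))
  expect_setequal(unique(merged$R), c("R0", "R1", "R2"))  # all counts >= 4

  # identity when every category is already frequent
  common <- data.frame(X = rep(c("X0", "X1"), each = 5),
                       Y = rep(c("Y0", "Y1"), 5))
  expect_identical(merge_rare_categories(common), common)

  # a variable that collapses to one category is dropped
  skewed <- data.frame(X = rep(c("X0", "X1"), each = 5),
                       Z = c(rep("Z0", 9), "Z1"))
  expect_warning(out <- merge_rare_categories(skewed, min_count = 4), "dropped")
  expect_named(out, "X")
})

test_that("MCA closed forms: perfect association and independence", {
  # two perfectly associated binary variables, balanced n = 8
  assoc <- data.frame(X = rep(c("X0", "X1"), each = 4),
                      Y = rep(c("Y0", "Y1"), each = 4))
  res <- mca(assoc)
  expect_equal(res$eig$eigenvalue[1], 1)
  expect_equal(res$eig$pct_variance[1], 100)
  expect_equal(sum(res$eig$eigenvalue), 4 / 2 - 1)

  # two independent balanced binary variables, crossed design
  indep <- data.frame(X = rep(c("X0", "X1"), each = 4),
                      Y = rep(c("Y0", "Y1"), 4))
  res2 <- mca(indep)
  expect_equal(res2$eig$eigenvalue, c(0.5, 0.5))
  expect_equal(res2$eig$pct_variance[1], 50)
})

test_that("MCA inertia, eigenvalue range, orthogonality and oracle agreement", {
  fx <- load_lesion_fixture()
  sc <- fx$scores[complete.cases(fx$scores), -1]
  merged <- merge_rare_categories(sc)
  res <- mca(merged)
  j <- length(unique(unlist(lapply(merged, unique))))
  q <- ncol(merged)
  expect_equal(sum(res$eig$eigenvalue), j / q - 1, tolerance = 1e-10)
  expect_equal(res$total_inertia, j / q - 1)
  expect_true(all(res$eig$eigenvalue >= 0 & res$eig$eigenvalue <= 1 + 1e-10))
  expect_equal(sum(res$eig$pct_variance), 100, tolerance = 1e-6)
  # row scores of distinct dimensions are uncorrelated
  cc <- crossprod(scale(res$row_coords, scale = FALSE))
  expect_lt(max(abs(cc[upper.tri(cc)])) / max(diag(cc)), 1e-8)
  # eigenvalues agree with a direct eigen-decomposition oracle
  expect_equal(res$eig$eigenvalue, ca_eigen_oracle(indicator(merged)),
               tolerance = 1e-8)
  expect_error(mca(fx$scores[, -1]), "missing")
})

test_that("rank PCA is monotone-invariant and handles co-monotone pairs", {
  set.seed(21)
  x <- rnorm(15)
  co <- data.frame(a = x, b = exp(x))           # strictly co-monotone
  res <- rank_pca(co)
  expect_equal(res$eig$pct_variance[1], 100)
  anti <- data.frame(a = x, b = -x^3)           # strictly anti-monotone
  expect_equal(rank_pca(anti)$eig$pct_variance[1], 100)

  dat <- data.frame(a = rnorm(15), b = rnorm(15), c = rnorm(15))
  res1 <- rank_pca(dat)
  warped <- data.frame(a = qexp(pnorm(scale(dat$a))), b = dat$b^3 + dat$b,
                       c = atan(dat$c))
  res2 <- rank_pca(warped)
  expect_equal(res2$eig$eigenvalue, res1$eig$eigenvalue, tolerance = 1e-10)
  expect_equal(abs(res2$row_coords), abs(res1$row_coords), tolerance = 1e-8)

  # eigenvalues match a direct eigen-decomposition of the rank correlation
  oracle <- sort(eigen(cor(apply(dat, 2, rank)), symmetric = TRUE,
                       only.values = TRUE)$values, decreasing = TRUE)
  expect_equal(res1$eig$eigenvalue, oracle, tolerance = 1e-10)

  const <- cbind(dat, d = 1)
  expect_warning(res3 <- rank_pca(const), "zero-variance")
  expect_equal(nrow(res3$eig), nrow(res1$eig))
})

test_that("MFA closed forms and balancing invariants hold", {
  set.seed(5)
  v <- rnorm(10)
  ids <- paste0("i", 1:10)
  s1 <- data.frame(a = v, row.names = ids)
  s2 <- data.frame(b = v, row.names = ids)
  res <- mfa(list(A = s1, B = s2))
  expect_equal(res$eig$eigenvalue[1], 2)
  expect_equal(unname(res$group_coords[, 1]), c(1, 1))

  # orthogonal one-variable sets load on separate dimensions
  x1 <- rnorm(12); x2 <- residuals(lm(rnorm(12) ~ x1))
  ids <- paste0("i", 1:12)
  res2 <- mfa(list(A = data.frame(a = x1, row.names = ids),
                   B = data.frame(b = x2, row.names = ids)))
  expect_equal(unname(res2$group_coords[, 1]), c(1, 0), tolerance = 1e-8)
  expect_equal(unname(res2$group_coords[, 2]), c(0, 1), tolerance = 1e-8)

  # multi-variable sets: weighting makes each set's first eigenvalue 1 and
  # group coordinates sum to the global eigenvalues
  set.seed(6)
  m1 <- data.frame(matrix(rnorm(20 * 4), 20), row.names = paste0("i", 1:20))
  m2 <- data.frame(matrix(rnorm(20 * 3), 20), row.names = paste0("i", 1:20))
  names(m1) <- paste0("u", 1:4); names(m2) <- paste0("v", 1:3)
  res3 <- mfa(list(S1 = m1, S2 = m2))
  for (nm in c("S1", "S2")) {
    z <- scale(as.matrix(if (nm == "S1") m1 else m2)) * sqrt(res3$set_weights[nm])
    lam1 <- eigen(cov(z), symmetric = TRUE, only.values = TRUE)$values[1]
    expect_equal(lam1, 1, tolerance = 1e-10)
  }
  expect_equal(unname(colSums(res3$group_coords)), res3$eig$eigenvalue,
               tolerance = 1e-8)
  expect_true(all(res3$group_coords <= 1 + 1e-8))
  # eigenvalues agree with a direct eigen-decomposition of the weighted
  # concatenated correlation structure
  zw <- cbind(scale(as.matrix(m1)) * sqrt(res3$set_weights["S1"]),
              scale(as.matrix(m2)) * sqrt(res3$set_weights["S2"]))
  oracle <- sort(eigen(cov(zw), symmetric = TRUE, only.values = TRUE)$values,
                 decreasing = TRUE)
  expect_equal(res3$eig$eigenvalue, oracle[seq_len(nrow(res3$eig))],
               tolerance = 1e-10)
})

test_that("the illustrative group coordinate is eta-squared of the scores", {
  set.seed(7)
  ids <- paste0("i", 1:20)
  grp <- rep(c("g1", "g2"), each = 10)
  shift <- ifelse(grp == "g1", -5, 5)
  s1 <- data.frame(a = shift + rnorm(20, sd = 0.1),
                   b = shift + rnorm(20, sd = 0.1), row.names = ids)
  s2 <- data.frame(c = shift + rnorm(20, sd = 0.1), row.names = ids)
  res <- mfa(list(A = s1, B = s2), illustrative = grp)
  expect_gte(res$illustrative_coords[1], 0.99)
  expect_true(all(res$illustrative_coords <= 1 + 1e-8))
})

test_that("MFA excludes incomplete individuals and rejects bad input", {
  ids <- paste0("i", 1:10)
  s1 <- data.frame(a = rnorm(10), row.names = ids)
  s2 <- data.frame(b = rnorm(10), row.names = ids)
  s1$a[3] <- NA
  expect_message(res <- mfa(list(A = s1, B = s2)), "excluded")
  expect_equal(nrow(res$row_coords), 9)
  s_const <- data.frame(b = rep(1, 10), row.names = ids)
  expect_error(mfa(list(A = s2, B = s_const)), "constant")
  rownames(s2) <- rev(ids)
  expect_error(mfa(list(A = s1, B = s2)), "same individuals")
})

test_that("dimension correlations flag real signal and respect alpha", {
  set.seed(8)
  n <- 40
  x <- data.frame(matrix(rnorm(n * 3), n), row.names = paste0("i", 1:n))
  names(x) <- c("a", "b", "c")
  res <- rank_pca(x)
  vars <- data.frame(hit = res$row_coords[, 1],
                     row.names = rownames(res$row_coords))
  dc <- dim_correlations(res, vars, dim = 1)
  expect_equal(dc$r[dc$variable == "hit"], 1, tolerance = 1e-8)
  expect_true(dc$significant[dc$variable == "hit"])

  # type-I rate of the significance flag for pure noise ~ alpha
  set.seed(9)
  flags <- replicate(400, {
    noise <- data.frame(v = rnorm(17), row.names = rownames(res$row_coords)[1:17])
    sub <- res
    sub$row_coords <- res$row_coords[1:17, , drop = FALSE]
    dim_correlations(sub, noise, dim = 1)$significant
  })
  rate <- mean(flags)
  expect_lt(abs(rate - 0.05), 2.576 * sqrt(0.05 * 0.95 / 400) + 0.005)

  skinny <- data.frame(v = c(1, 2, rep(NA, nrow(x) - 2)),
                       row.names = rownames(x))
  expect_warning(out <- dim_correlations(res, skinny), "complete pairs")
  expect_equal(nrow(out), 0)
})

test_that("group ellipses match the closed form and translate with the mean", {
  set.seed(10)
  n <- 4000
  xy <- cbind(rnorm(n, sd = 2), rnorm(n, sd = 2))
  ell <- group_ellipses(xy, rep("g", n))
  expect_equal(ell$scale, qchisq(0.95, 2))
  expect_equal(ell$v11, 4 / n, tolerance = 0.1)
  expect_equal(ell$v22, 4 / n, tolerance = 0.1)
  expect_lt(abs(ell$v12), 4 / n)

  shifted <- sweep(xy, 2, c(10, -3), "+")
  both <- group_ellipses(rbind(xy, shifted), rep(c("a", "b"), each = n))
  expect_equal(both$cx[2] - both$cx[1], 10, tolerance = 0.2)
  expect_equal(both[1, c("v11", "v12", "v22")],
               both[2, c("v11", "v12", "v22")], ignore_attr = TRUE)

  degen <- matrix(1, nrow = 5, ncol = 2)
  expect_warning(out <- group_ellipses(degen, rep("g", 5)), "degenerate")
  expect_equal(nrow(out), 0)
  expect_warning(group_ellipses(xy[1:2, ], rep("g", 2)), "fewer than 3")
})
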