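test_that("exact permutation p-values match exhaustive enumeration", {
  pt <- perm_test(c(1, 2, 3), c(4, 5, 6))
  expect_identical(pt$n_perm, "exact")
  expect_equal(pt$n_assignments, choose(6, 3))
  expect_equal(pt$p_value, 2 / 20)   # only the two extreme splits qualify
  expect_equal(pt$statistic, -3)

  same <- perm_test(c(2, 2, 2), c(2, 2, 2))
  expect_equal(same$p_value, 1)

  expect_error(perm_test(1, c(1, 2)), "two non-missing")
  expect_error(perm_test(c(1, NA), c(1, 2)), "two non-missing")
})

test_that("Monte-Carlo p-values converge to the exact value", {
  exact <- perm_test(c(1, 2, 3), c(4, 5, 6))$p_value
  mc <- perm_test(c(1, 2, 3), c(4, 5, 6), n_perm = 100000, seed = 3,
                  exact_limit = 0)
  expect_lt(abs(mc$p_value - exact),
            3 * sqrt(exact * (1 - exact) / 100000) + 1e-4)
  expect_lt(abs(mc$p_value - exact), 0.01)
  # same seed reproduces the same Monte-Carlo p
  mc2 <- perm_test(c(1, 2, 3), c(4, 5, 6), n_perm = 100000, seed = 3,
                   exact_limit = 0)
  expect_equal(mc2$p_value, mc$p_value)
})

test_that("permutation p is invariant to group exchange and location shift", {
  set.seed(14)
  x <- rnorm(5); y <- rnorm(6) + 1
  a <- perm_test(x, y)
  b <- perm_test(y, x)
  expect_equal(b$p_value, a$p_value)
  expect_equal(b$statistic, -a$statistic)
  shifted <- perm_test(x + 100, y + 100)
  expect_equal(shifted$p_value, a$p_value)
})

test_that("stratified test reduces to the plain test for one stratum", {
  set.seed(15)
  x <- rnorm(4); y <- rnorm(5)
  plain <- perm_test(x, y, n_perm = 2000, seed = 77, exact_limit = 0)
  strat <- stratified_perm_test(x, y, strata = rep("only", 9),
                                n_perm = 2000, seed = 77, exact_limit = 0)
  expect_equal(strat$p_value, plain$p_value)
  expect_equal(strat$statistic, plain$statistic)

  plain_ex <- perm_test(x, y)
  strat_ex <- stratified_perm_test(x, y, strata = rep("only", 9))
  expect_equal(strat_ex$p_value, plain_ex$p_value)
})

test_that("stratification guards against a stage-confounded effect", {
  # two strata with opposite group effects: pooled labels look different,
  # within-stratum exchange shows no consistent effect
  x <- c(10, 11, 20, 21)           # group A: stratum 1 low, stratum 2 high
  y <- c(20, 21, 10, 11)           # group B: mirrored
  strata <- c(1, 1, 2, 2, 1, 1, 2, 2)
  strat <- stratified_perm_test(x, y, strata)
  expect_identical(strat$n_perm, "exact")
  expect_equal(strat$statistic, 0)
  expect_equal(strat$p_value, 1)

  # confounded design: group membership correlated with stratum; pooling
  # exaggerates the contrast while within-stratum exchange does not.
  # p = 12/16 frozen from hand enumeration of the 4 x 4 assignments
  xc <- c(0, 1, 2, 21); yc <- c(1, 20, 22, 19)
  sc <- c(1, 1, 1, 2, 1, 2, 2, 2)
  strat_conf <- stratified_perm_test(xc, yc, sc)
  naive_conf <- perm_test(xc, yc)
  expect_equal(strat_conf$p_value, 12 / 16)
  expect_lt(naive_conf$p_value, strat_conf$p_value)

  # strata of size 2 (one observation per group): only identity/swap per
  # stratum, 2^S assignments in total
  x2 <- c(1, 2, 3); y2 <- c(5, 7, 9)
  strat2 <- stratified_perm_test(x2, y2, strata = c(1, 2, 3, 1, 2, 3))
  expect_identical(strat2$n_perm, "exact")
  expect_equal(strat2$n_assignments, 2^3)
  # enumeration oracle over the 8 sign patterns of the per-stratum swaps
  diffs <- c(1 - 5, 2 - 7, 3 - 9)
  stats <- apply(expand.grid(c(1, -1), c(1, -1), c(1, -1)), 1,
                 function(s) mean(s * diffs))
  p_oracle <- mean(abs(stats) >= abs(mean(diffs)) - 1e-8)
  expect_equal(strat2$p_value, p_oracle)

  expect_warning(
    stratified_perm_test(c(1, 2, 5), c(3, 4, 6),
                         strata = c(1, 1, 2, 1, 1, 1)),
    "dropped")
  expect_error(stratified_perm_test(c(1, 2), c(3, 4),
                                    strata = c(1, 1, 2, 2)), "one group")
})

test_that("type-I error of the permutation test is calibrated at the null", {
  set.seed(16)
  n_sim <- 500
  rejections <- vapply(seq_len(n_sim), function(i) {
    x <- rnorm(6); y <- rnorm(6)
    perm_test(x, y)$p_value <= 0.05
  }, TRUE)
  rate <- mean(rejections)
  expect_lt(abs(rate - 0.05), 2.576 * sqrt(0.05 * 0.95 / n_sim) + 0.005)
})

test_that("Spearman correlation handles ties like the rank-formula oracle", {
  expect_equal(spearman_corr(1:5, c(2, 4, 6, 8, 10))$r, 1)
  expect_equal(spearman_corr(1:5, 5:1)$r, -1)
  expect_equal(spearman_corr(1:5, 5:1)$p, 0)

  x <- c(1, 2, 2, 4); y <- c(1, 3, 2, 4)
  out <- spearman_corr(x, y)
  rx <- c(1, 2.5, 2.5, 4); ry <- c(1, 3, 2, 4)      # hand-averaged ranks
  r_oracle <- sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  expect_equal(out$r, r_oracle)
  expect_equal(out$r, suppressWarnings(
    cor.test(x, y, method = "spearman", exact = FALSE)$estimate[[1]]))

  # pairwise deletion of missing values
  out2 <- spearman_corr(c(1, 2, NA, 4, 5), c(2, 3, 9, 5, NA))
  expect_equal(out2$n, 3)
  expect_error(spearman_corr(c(1, 2), c(3, 4)), "3 complete")
  expect_warning(flat <- spearman_corr(c(1, 1, 1), c(1, 2, 3)), "constant")
  expect_true(is.na(flat$r))
})

test_that("morphometry summaries compute mean and CV per animal", {
  d <- data.frame(animal_id = rep(c("a1", "a2", "a3"), each = 3),
                  parameter = "area",
                  value = c(2, 2, 2, 1, 3, NA, -2, -1, -3))
  out <- summarize_morphometry(d)
  a1 <- out[out$animal_id == "a1", ]
  expect_equal(a1$mean, 2)
  expect_equal(a1$cv, 0)
  a2 <- out[out$animal_id == "a2", ]
  expect_equal(a2$mean, 2)
  expect_equal(a2$cv, sqrt(2) / 2)
  a3 <- out[out$animal_id == "a3", ]        # negative mean: CV undefined
  expect_true(is.na(a3$cv))
  expect_error(summarize_morphometry(
    data.frame(animal_id = "a", parameter = "x", value = 1)), "two measurements")
})

test_that("fatty-acid features derive families and ratios from the names", {
  tab <- data.frame(`C22:6w3` = 2, `C20:4w6` = 4, `C16:0` = 50,
                    `C18:1w9` = 44, check.names = FALSE)
  f <- fa_features(tab)
  expect_equal(f$`C22:6w3_C20:4w6`, 0.5)
  expect_equal(f$SFA, 50)
  expect_equal(f$MUFA, 44)
  expect_equal(f$PUFA, 6)
  expect_equal(f$w3, 2)
  expect_equal(f$w6, 4)
  expect_equal(f$w3_w6, 0.5)
  expect_equal(f$SFA + f$MUFA + f$PUFA, sum(tab))  # conservation

  sat_only <- data.frame(`C16:0` = 60, `C18:0` = 40, check.names = FALSE)
  g <- fa_features(sat_only)
  expect_equal(g$PUFA, 0)
  expect_true(is.na(g$w3_w6))
  expect_equal(g$PUFA_SFA, 0)      # SFA denominator is positive
  expect_true(is.na(g$`C22:6w3_C20:4w6`))

  expect_error(fa_features(data.frame(nonsense = 1)), "nonsense")
})

test_that("the PCA and MFA fatty-acid variable sets have 22 and 48 variables", {
  set.seed(17)
  base <- matrix(runif(5 * 13, 1, 10), nrow = 5)
  pl <- as.data.frame(base); nl <- as.data.frame(base * 1.1)
  fas <- c("C14:0", "C16:0", "C16:1w7", "C18:0", "C18:1w9", "C18:2w6",
           "C18:3w3", "C20:3w6", "C20:4w6", "C20:5w3", "C22:4w6",
           "C22:5w3", "C22:6w3")
  names(pl) <- names(nl) <- fas
  pca_set <- fa_pca_variables(pl, nl)
  expect_equal(ncol(pca_set), 22)
  expect_false(any(c("PL_C18:1w9", "NL_C20:3w6", "PL_C22:4w6", "NL_C20:5w3")
                   %in% names(pca_set)))
  mfa_set <- fa_mfa_variables(pl, nl)
  expect_equal(ncol(mfa_set), 48)
  expect_equal(sum(startsWith(names(mfa_set), "PL_")), 24)
  expect_error(fa_pca_variables(pl[, -1], nl), "lacks")
})
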