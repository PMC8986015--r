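test_that("shape PCA matches an independent eigen-decomposition", {
  set.seed(101)
  m <- matrix(rnorm(60), 10, 6)
  p <- shape_pca(m)
  eo <- eigen(cov(m), symmetric = TRUE)
  expect_equal(p$eigenvalues, eo$values[1:6], tolerance = 1e-10)
  expect_equal(sum(p$percent), 100, tolerance = 1e-6)
  # scores reproduce the centred data through the loadings
  rec <- p$scores %*% p$loadings
  expect_lt(max(abs(rec - scale(m, scale = FALSE))), 1e-8)
  # score covariance is diagonal
  cc <- cov(p$scores)
  expect_lt(max(abs(cc[upper.tri(cc)])), 1e-8)
})

test_that("variance along a single direction loads entirely on PC1", {
  set.seed(102)
  v <- rnorm(8); v <- v / sqrt(sum(v^2))
  m <- outer(rnorm(12), v)
  p <- shape_pca(m)
  expect_equal(p$percent[1], 100, tolerance = 1e-8)
  expect_error(shape_pca(m[1, , drop = FALSE]), "at least 2")
})

test_that("variance-explained regression has the exact algebraic limits", {
  set.seed(103)
  x <- rnorm(30)
  b <- matrix(rnorm(10), 1, 10)
  y_exact <- cbind(x) %*% b          # shape an exact linear function of x
  expect_equal(variance_explained_regression(y_exact, x)$percent, 100,
               tolerance = 1e-9)
  # predictor orthogonal to every column
  y <- matrix(rnorm(300), 30, 10)
  y_orth <- qr.resid(qr(cbind(1, x)), y)
  expect_lt(variance_explained_regression(y_orth, x)$percent, 1e-9)
  expect_error(variance_explained_regression(y, rep(1, 30)), "constant")
})

test_that("regression percentages match a normal-equations oracle", {
  set.seed(104)
  x <- rnorm(12)
  y <- matrix(rnorm(48), 12, 4)
  got <- variance_explained_regression(y, x)$percent
  # hand linear algebra: beta = (X'X)^-1 X'y per column, SS from fits
  X <- cbind(1, x)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  fits <- X %*% beta
  ssm <- sum((sweep(fits, 2, colMeans(y)))^2)
  sst <- sum((sweep(y, 2, colMeans(y)))^2)
  expect_equal(got, 100 * ssm / sst, tolerance = 1e-10)
})

test_that("percentages for orthogonal predictors are additive", {
  n <- 40
  x1 <- rep(c(-1, 1), n / 2)
  x2 <- rep(c(-1, -1, 1, 1), n / 4)     # orthogonal to x1 by construction
  expect_equal(sum(x1 * x2), 0)
  set.seed(105)
  y <- outer(x1, rnorm(6)) + outer(x2, rnorm(6)) + matrix(rnorm(n * 6), n, 6)
  p1 <- variance_explained_regression(y, x1)$percent
  p2 <- variance_explained_regression(y, x2)$percent
  p12 <- variance_explained_regression(y, data.frame(a = x1, b = x2))$percent
  expect_equal(p1 + p2, p12, tolerance = 1e-9)
})

test_that("allometry correction removes pure size effects", {
  set.seed(106)
  n <- 100
  lncs <- rnorm(n)
  sex <- rep(c("F", "M"), n / 2)
  allo <- matrix(rnorm(8), 1, 8)
  y_size_only <- cbind(lncs) %*% allo + matrix(rnorm(n * 8, 0, 0.05), n, 8)
  r <- allometry_corrected_sex_effect(y_size_only, lncs, sex)
  expect_lt(r$percent_of_residual, 1)
  expect_gt(r$allometry_percent, 95)
  expect_error(allometry_corrected_sex_effect(y_size_only, lncs,
                                              rep("F", n)), "both sexes")
})

test_that("allometry-corrected sex share recovers a constructed decomposition", {
  set.seed(107)
  n <- 200
  lncs <- rnorm(n)
  sex <- rep(c("F", "M"), n / 2)
  sgn <- ifelse(sex == "F", -0.5, 0.5)
  va <- rnorm(12); va <- va / sqrt(sum(va^2))
  vs <- rnorm(12); vs <- vs - sum(vs * va) * va; vs <- vs / sqrt(sum(vs^2))
  y <- outer(lncs, va) + outer(2 * sgn, vs) + matrix(rnorm(n * 12, 0, 0.7), n, 12)
  r <- allometry_corrected_sex_effect(y, lncs, sex)
  # expected share of the residual variance once the size axis is removed
  ss_sex <- sum((2 * sgn - mean(2 * sgn))^2)
  ss_noise <- n * 12 * 0.7^2
  expected <- 100 * ss_sex / (ss_sex + ss_noise)
  expect_equal(r$percent_of_residual, expected, tolerance = 0.35)
})

test_that("correcting for allometry shrinks a size-aligned sex effect", {
  set.seed(108)
  n <- 120
  sex <- rep(c("F", "M"), n / 2)
  sgn <- ifelse(sex == "F", -0.5, 0.5)
  lncs <- 0.8 * sgn + rnorm(n, 0, 0.3)  # sexes separated in size
  v <- rnorm(10); v <- v / sqrt(sum(v^2))
  y <- outer(lncs, v) + matrix(rnorm(n * 10, 0, 0.3), n, 10)
  uncorrected <- variance_explained_regression(y, factor(sex))$percent
  corrected <- allometry_corrected_sex_effect(y, lncs, sex)$percent_of_residual
  expect_lt(corrected, uncorrected)
})

test_that("an enormous mean offset gives the minimal permutation p", {
  set.seed(109)
  y <- matrix(rnorm(40), 20, 2)
  y[1:10, ] <- y[1:10, ] + 100
  labels <- rep(c("a", "b"), each = 10)
  r <- permutation_mean_difference(y, labels, n_perm = 99, seed = 1)
  expect_equal(r$p_value, 1 / 100)
})

test_that("the exact permutation p matches a full manual enumeration", {
  set.seed(110)
  y <- matrix(rnorm(18), 6, 3)
  labels <- rep(c("a", "b"), each = 3)
  r <- permutation_mean_difference(y, labels, exact = TRUE)
  expect_equal(r$n_perm, choose(6, 3))
  # independent enumeration
  obs <- sqrt(sum((colMeans(y[1:3, ]) - colMeans(y[4:6, ]))^2))
  ds <- apply(combn(6, 3), 2, function(idx)
    sqrt(sum((colMeans(y[idx, , drop = FALSE]) -
              colMeans(y[-idx, , drop = FALSE]))^2)))
  expect_equal(r$p_value, mean(ds >= obs - 1e-12))
  expect_error(permutation_mean_difference(y, rep(c("a", "b", "c"), 2)),
               "two groups")
})

test_that("permutation p-values are seed-reproducible and in (0, 1]", {
  set.seed(111)
  y <- matrix(rnorm(60), 20, 3)
  labels <- rep(c("a", "b"), each = 10)
  r1 <- permutation_mean_difference(y, labels, n_perm = 199, seed = 7)
  r2 <- permutation_mean_difference(y, labels, n_perm = 199, seed = 7)
  expect_identical(r1$p_value, r2$p_value)
  expect_gt(r1$p_value, 0)
  expect_lte(r1$p_value, 1)
})

test_that("a single-factor Procrustes ANOVA equals the plain regression", {
  set.seed(112)
  n <- 24
  sex <- factor(rep(c("F", "M"), n / 2))
  y <- outer(as.numeric(sex) - 1.5, rnorm(5)) + matrix(rnorm(n * 5), n, 5)
  a <- procrustes_anova(y, data.frame(sex = sex), "sex", n_perm = 0)
  r <- variance_explained_regression(y, sex)
  expect_equal(a$SS[1], r$ss$ss_model, tolerance = 1e-10)
  expect_equal(a$percent[1], r$percent, tolerance = 1e-10)
  expect_equal(a$SS[3], r$ss$ss_tot, tolerance = 1e-10)
})

test_that("a null factor added second explains nothing and its p is diffuse", {
  set.seed(113)
  n <- 60
  a <- factor(rep(c("x", "y"), n / 2))
  b <- factor(rep(c("p", "q", "r"), n / 3))
  y <- outer(as.numeric(a), rnorm(4)) + matrix(rnorm(n * 4), n, 4)
  tab <- procrustes_anova(y, data.frame(a = a, b = b), c("a", "b"),
                          n_perm = 199, seed = 5)
  expect_lt(tab$percent[2], 7)
  expect_gt(tab$p[2], 0.01)
  expect_lt(tab$p[1], 0.05)
})

test_that("rank-deficient designs are refused with the aliased term named", {
  n <- 20
  a <- factor(rep(c("x", "y"), n / 2))
  dup <- a
  y <- matrix(rnorm(n * 3), n, 3)
  expect_error(procrustes_anova(y, data.frame(a = a, dup = dup),
                                c("a", "dup"), n_perm = 0), "dup")
})

test_that("interaction terms are included on request", {
  set.seed(114)
  n <- 48
  a <- factor(rep(c("x", "y"), n / 2))
  b <- factor(rep(c("p", "p", "q", "q"), n / 4))
  y <- matrix(rnorm(n * 4), n, 4)
  tab <- procrustes_anova(y, data.frame(a = a, b = b), c("a", "b"),
                          include_interaction = TRUE, n_perm = 49, seed = 2)
  expect_true("a:b" %in% tab$term)
  expect_equal(nrow(tab), 5L)  # a, b, a:b, Residuals, Total
})

test_that("t statistics match a hand computation on six values", {
  v <- c(1.0, 2.0, 3.0, 7.0, 8.0, 12.0)
  sex <- c("F", "F", "F", "M", "M", "M")
  u <- ttest_and_effect(v, sex)
  # textbook pooled-variance computation, written out
  mf <- 2; mm <- 9
  sf2 <- ((1 - 2)^2 + (2 - 2)^2 + (3 - 2)^2) / 2       # 1
  sm2 <- ((7 - 9)^2 + (8 - 9)^2 + (12 - 9)^2) / 2      # 7
  sp2 <- (2 * sf2 + 2 * sm2) / 4
  t_hand <- (mm - mf) / sqrt(sp2 * (1 / 3 + 1 / 3))
  p_hand <- 2 * pt(-abs(t_hand), df = 4)
  expect_equal(u$t_statistic, t_hand, tolerance = 1e-12)
  expect_equal(u$p_value, p_hand, tolerance = 1e-12)
  expect_equal(u$average_difference, 7)
  expect_error(ttest_and_effect(v, rep("F", 6)), "two sexes")
})

test_that("raw-data effect sizes equal the summary-statistics reconstruction", {
  set.seed(115)
  v <- c(rnorm(14, 10, 2), rnorm(19, 13, 2.5))
  sex <- rep(c("F", "M"), c(14, 19))
  u <- ttest_and_effect(v, sex)
  s <- summary_from_groups(14, mean(v[1:14]), sd(v[1:14]),
                           19, mean(v[15:33]), sd(v[15:33]))
  expect_equal(u$cohens_d_total, s$cohens_d_total, tolerance = 1e-12)
  expect_equal(u$cohens_d_pooled, s$cohens_d_pooled, tolerance = 1e-12)
  expect_equal(u$average_difference, s$average_difference, tolerance = 1e-12)
  expect_equal(u$t_statistic, s$t_statistic, tolerance = 1e-9)
})

test_that("degenerate group summaries behave as closed forms dictate", {
  s0 <- summary_from_groups(5, 10, 2, 7, 10, 2)
  expect_equal(s0$average_difference, 0)
  expect_equal(s0$cohens_d_total, 0)
  # zero within-group SD: total SD reduces to the between-group SD
  s1 <- summary_from_groups(4, 10, 0, 4, 14, 0)
  grand <- 12
  between <- sqrt((4 * (10 - grand)^2 + 4 * (14 - grand)^2) / 8)
  expect_equal(s1$total_sd, between, tolerance = 1e-12)
  expect_error(summary_from_groups(1, 10, 1, 4, 12, 1), "n >= 2")
  expect_error(summary_from_groups(4, 10, -1, 4, 12, 1), "non-negative")
})
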