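test_that("iterative standardization reaches both margins or fails loudly", {
  set.seed(1)
  M <- matrix(exp(rnorm(20 * 15, 0, 1)), 20, 15)
  S <- iterative_standardize(M)
  expect_lte(attr(S, "iterations"), 50)
  expect_lt(max(abs(rowMeans(S))), 1e-6)
  expect_lt(max(abs(colMeans(S))), 1e-6)
  pop_var <- function(v) mean((v - mean(v))^2)
  expect_lt(max(abs(apply(S, 1, pop_var) - 1)), 1e-5)
  expect_lt(max(abs(apply(S, 2, pop_var) - 1)), 1e-5)
  # a matrix already at the fixed point is returned unchanged
  S2 <- iterative_standardize(S)
  expect_equal(unclass(S2), unclass(S), ignore_attr = TRUE)
  expect_equal(attr(S2, "iterations"), 0)
  expect_error(iterative_standardize(matrix(1, 4, 4)), "constant")
  M2 <- M; M2[2, ] <- 3
  expect_error(iterative_standardize(M2), "constant")
})

test_that("rank inverse normal transform maps ranks to normal quantiles", {
  out <- rank_inverse_normal(c(3, 1, 2))
  expect_equal(out, qnorm((c(3, 1, 2) - 0.5) / 3))
  expect_equal(out[3], 0)
  set.seed(2)
  y <- rexp(40)
  expect_equal(cor(y, rank_inverse_normal(y), method = "spearman"), 1)
  tied <- rank_inverse_normal(c(5, 1, 1, 7))
  expect_equal(tied[2], tied[3])
  y2 <- c(2, 1, NA, 3)
  expect_true(is.na(rank_inverse_normal(y2)[3]))
  expect_error(rank_inverse_normal(c(1, 1, 1)), "identical")
})

test_that("sample kinship has unit diagonal and detects duplicate samples", {
  set.seed(3)
  K <- random_kinship(12, 120)
  expect_equal(unname(diag(K$K)), rep(1, 12), tolerance = 1e-4)
  expect_true(min(K$values) >= 0)
  # duplicated sample column gives an off-diagonal near 1
  M <- matrix(rnorm(600), 60, 10)
  M[, 10] <- M[, 9]
  S <- iterative_standardize(M)
  K2 <- sample_kinship(S)
  expect_gt(K2$K[9, 10], 0.95)
  # orthogonal unit-variance columns give the identity
  n <- 8
  H <- qr.Q(qr(matrix(rnorm(64), n, n)))
  Ko <- sample_kinship(sqrt(n) * t(H))
  expect_equal(unname(Ko$K), diag(n), tolerance = 1e-8)
  expect_error(sample_kinship(matrix(1, 1, 5)), "2 genes")
})

test_that("identity-kinship fits reduce exactly to ordinary regression", {
  set.seed(4)
  for (i in 1:10) {
    n <- sample(30:80, 1)
    x <- rnorm(n)
    y <- 0.3 * scale(x)[, 1] + rnorm(n)
    fit <- lmm_fit_one(y, x, diag(n))
    oracle <- ols_oracle(y, x)
    expect_equal(fit$beta, oracle$beta, tolerance = 1e-8)
    expect_equal(fit$se, oracle$se, tolerance = 1e-8)
    expect_lt(abs(fit$p - oracle$p), 1e-6)
  }
  # x = y exactly: slope is sd(y) on the standardized scale, p ~ 0
  y <- rnorm(50)
  fit <- lmm_fit_one(y, y, diag(50), standardize_x = FALSE)
  expect_equal(fit$beta, 1, tolerance = 1e-8)
  expect_lt(fit$p, 1e-200)
})

test_that("p-values are invariant to positive rescaling of the kinship", {
  # block-structured samples give an interior variance-ratio optimum
  set.seed(5)
  n <- 50; blocks <- rep(1:5, each = 10)
  M <- t(vapply(1:120, function(g) rnorm(5)[blocks] + rnorm(n, 0, 0.7),
                numeric(n)))
  colnames(M) <- sprintf("S%02d", 1:n)
  K <- sample_kinship(iterative_standardize(M))
  Lk <- kinship_factor(K$K)
  x <- rnorm(n)
  y <- draw_mixed(scale(x)[, 1], 0.4, Lk, 0.6, 0.4)
  f1 <- lmm_fit_one(y, x, K)
  f2 <- lmm_fit_one(y, x, 7.3 * K$K)
  expect_false(f1$at_bound)
  expect_equal(f1$p, f2$p, tolerance = 1e-8)
  expect_equal(f1$beta, f2$beta, tolerance = 1e-8)
  # the variance ratio re-absorbs the scale factor
  expect_equal(f2$delta / f1$delta, 7.3, tolerance = 1e-3)
})

test_that("the profiled likelihood beats a 41-point grid at the optimum", {
  set.seed(6)
  K <- random_kinship(35, 150)
  x <- rnorm(35)
  y <- draw_mixed(scale(x)[, 1], 0.2, kinship_factor(K$K), 0.6, 0.4)
  fit <- lmm_fit_one(y, x, K)
  U <- K$vectors
  yt <- drop(crossprod(U, y))
  Wt <- crossprod(U, cbind(1, scale(x)[, 1]))
  grid_ll <- vapply(seq(-10, 10, length.out = 41), function(g)
    mmaomics:::reml_profile(exp(g), yt, Wt, K$values)$ll, numeric(1))
  expect_gte(fit$loglik, max(grid_ll) - 1e-8)
})

test_that("scan reuses one rotation, is deterministic, and finds planted genes", {
  set.seed(7)
  n <- 150; p <- 120
  X <- matrix(rnorm(p * n), p, n,
              dimnames = list(sprintf("G%03d", 1:p), sprintf("S%03d", 1:n)))
  K <- sample_kinship(iterative_standardize(X))
  planted <- sprintf("G%03d", 1:10)
  factor_z <- rnorm(n)
  for (g in planted) X[g, ] <- factor_z + rnorm(n, 0, 0.5)
  y <- factor_z + rnorm(n, 0, 0.5)
  names(y) <- colnames(X)
  K <- sample_kinship(iterative_standardize(X))
  s1 <- lmm_scan(y, X, K)
  s2 <- lmm_scan(y, X, K)
  expect_identical(s1, s2)
  expect_true(all(planted %in% s1$gene[1:20]))
  # mismatched sample names are refused
  y2 <- y; names(y2)[1] <- "nope"
  expect_error(lmm_scan(y2, X, K), "identifiers")
})

test_that("mito filter subsets fits by gene set and preserves order", {
  fits <- data.frame(gene = c("MMUT", "OGDH", "ACO1"), p = c(1e-5, 1e-3, 0.2))
  expect_equal(mito_filter(fits, fits$gene), fits, ignore_attr = TRUE)
  expect_equal(mito_filter(fits, c("OGDH", "MMUT"))$gene, c("MMUT", "OGDH"))
  expect_warning(out <- mito_filter(fits, "ZZZ"), "no scan gene")
  expect_equal(nrow(out), 0)
  expect_error(mito_filter(fits, character(0)), "non-empty")
})

test_that("blup prediction has the right degenerate limits and recovers signal", {
  set.seed(8)
  n <- 60
  X <- cbind(rnorm(n), rnorm(n))
  y <- 0.8 * X[, 1] - 0.5 * X[, 2] + rnorm(n)
  K <- random_kinship(n, 300)
  # no random effect: identical to ordinary least squares
  pb <- predict_blup(y, X, K, delta_override = Inf)
  ols <- lm(y ~ X)
  expect_equal(unname(pb$prediction), unname(fitted(ols)), tolerance = 1e-8)
  # K = I, intercept only: ridge-style shrinkage toward the mean by
  # sigma_g2 / (sigma_g2 + sigma_e2)
  pb2 <- predict_blup(y, fixed = NULL, K = diag(n), delta_override = 1.5)
  lambda <- 1 / (1 + 1.5)          # = sigma_g2 / (sigma_g2 + sigma_e2)
  expect_equal(unname(pb2$prediction),
               mean(y) + lambda * (y - mean(y)), tolerance = 1e-8)
  expect_error(predict_blup(y, cbind(1, X[, 1]), K), "singular")
  # recovery: predicted response tracks the true expected response
  set.seed(9)
  n <- 150
  K2 <- random_kinship(n, 450)
  Lk <- kinship_factor(K2$K)
  Xf <- cbind(rnorm(n), rnorm(n))
  expected <- 0.9 * Xf[, 1] - 0.7 * Xf[, 2]
  y2 <- expected + sqrt(0.4) * drop(Lk %*% rnorm(n)) + rnorm(n, 0, sqrt(0.4))
  pb3 <- predict_blup(y2, Xf, K2)
  expect_gt(cor(pb3$prediction, expected, method = "spearman"), 0.8)
})
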