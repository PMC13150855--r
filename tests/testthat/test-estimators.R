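test_that("the registry holds 15 estimators in the three categories", {
  reg <- estimator_registry()
  expect_length(reg, 15L)
  cats <- vapply(reg, `[[`, "", "category")
  expect_equal(sum(cats == "parametric"), 10L)
  expect_equal(sum(cats == "semiparametric"), 2L)
  expect_equal(sum(cats == "nonparametric"), 3L)
  expect_error(estimator_spec("DeepNet"), "unknown estimator")
  expect_error(estimator_spec("RR", trees = 5), "unknown hyperparameter")
})

test_that("fixed-lambda ridge reproduces the direct linear-solve oracle", {
  X <- matrix(c(1, 0, 1, 0, 1, 1), 3, 2)
  y <- c(1, 1, 2)
  f <- gp_fit(estimator_spec("RR", lambda = 1), y, X = X, intercept = FALSE)
  u_oracle <- solve(crossprod(X) + diag(2), crossprod(X, y))
  expect_equal(f$u, drop(u_oracle), tolerance = 1e-12)
  expect_equal(f$u, c(0.75, 0.75), tolerance = 1e-12)
})

test_that("vanishing ridge penalty recovers noiseless marker effects", {
  set.seed(5)
  n <- 40; p <- 15
  X <- matrix(rnorm(n * p), n, p)
  u_true <- rnorm(p)
  y <- drop(X %*% u_true)
  f <- gp_fit(estimator_spec("RR", lambda = 1e-8), y, X = X,
              intercept = FALSE)
  expect_lt(max(abs(f$u - u_true)), 1e-6)
})

test_that("null responses give null effect estimates for linear estimators", {
  X <- matrix(rbinom(60, 2, 0.4), 20, 3)
  y <- rep(0, 20)
  for (nm in c("RR", "rrBLUP", "GBLUP")) {
    sp <- if (nm == "RR") estimator_spec("RR", lambda = 1) else nm
    f <- gp_fit(sp, y, X = X)
    pr <- predict(f, X_new = X)
    expect_equal(pr, rep(0, 20), tolerance = 1e-8,
                 label = paste(nm, "predictions"))
  }
})

test_that("rrBLUP marker form and GBLUP kinship form are equivalent BLUPs", {
  # the standard equivalence: K = XX' and matched REML components
  worst <- 0
  for (s in 1:5) {
    set.seed(100 + s)
    n <- 30; p <- 50
    X <- matrix(rnorm(n * p), n, p)
    y <- drop(X %*% rnorm(p, 0, 0.2)) + rnorm(n)
    Xn <- matrix(rnorm(10 * p), 10, p)
    f1 <- gp_fit("rrBLUP", y, X = X)
    f2 <- gp_fit("GBLUP", y, K = tcrossprod(X))
    p1 <- predict(f1, X_new = Xn)
    p2 <- predict(f2, K_cross = Xn %*% t(X))
    worst <- max(worst, max(abs(p1 - p2)))
  }
  expect_lt(worst, 1e-8)
})

test_that("predict is consistent on training data and symmetric on duplicates", {
  set.seed(9)
  X <- matrix(rnorm(80), 20, 4)
  y <- drop(X %*% c(1, -1, 0.5, 0)) + rnorm(20, 0, 0.1)
  f <- gp_fit("rrBLUP", y, X = X)
  fitted <- predict(f, X_new = X)
  expect_equal(predict(f, X_new = X), fitted)
  dup <- X[c(3, 3), , drop = FALSE]
  pd <- predict(f, X_new = dup)
  expect_equal(pd[1], pd[2])
  expect_error(predict(f, X_new = X[, 1:2]), "columns")
  fk <- gp_fit("GBLUP", y, K = tcrossprod(X))
  expect_error(predict(fk, K_cross = matrix(0, 2, 5)), "columns")
})

test_that("Gibbs samplers with pinned unit variances match the analytic ridge posterior mean", {
  X <- matrix(c(1, 0, 1, 0, 1, 1), 3, 2)
  y <- c(1, 1, 2)
  ridge <- c(0.75, 0.75)
  for (nm in c("BRR", "BayesC")) {
    sp <- estimator_spec(nm)
    sp$hyperparams[c("niter", "burnin", "thin")] <- list(20000L, 2000L, 1L)
    sp$hyperparams$var_u <- 1
    sp$hyperparams$var_e <- 1
    if (nm == "BayesC") sp$hyperparams$pi <- 0  # all markers in the model
    f <- gp_fit(sp, y, X = X, intercept = FALSE)
    expect_equal(f$u, ridge, tolerance = 0.02, label = paste(nm, "effects"))
  }
})

test_that("BayesB with pi = 0 and pinned variances collapses to the ridge limit", {
  sp <- estimator_spec("BayesB", pi = 0)
  sp$hyperparams[c("niter", "burnin", "thin")] <- list(20000L, 2000L, 1L)
  sp$hyperparams$var_u <- 1
  sp$hyperparams$var_e <- 1
  X <- matrix(c(1, 0, 1, 0, 1, 1), 3, 2)
  f <- gp_fit(sp, c(1, 1, 2), X = X, intercept = FALSE)
  expect_equal(f$u, c(0.75, 0.75), tolerance = 0.02)
})

test_that("every estimator is deterministic under a fixed seed", {
  set.seed(77)
  n <- 40; p <- 25
  X <- matrix(rbinom(n * p, 2, 0.3), n, p)
  y <- drop(X %*% rnorm(p, 0, 0.2)) + rnorm(n, 0, 0.5)
  Xn <- matrix(rbinom(10 * p, 2, 0.3), 10, p)
  for (nm in names(estimator_registry())) {
    sp <- if (nm %in% c("BRR", "BayesA", "BayesB", "BayesC", "BL"))
      quick_gibbs(nm) else estimator_spec(nm)
    p1 <- predict(gp_fit(sp, y, X = X), X_new = Xn)
    p2 <- predict(gp_fit(sp, y, X = X), X_new = Xn)
    expect_identical(p1, p2, label = paste(nm, "reproducibility"))
    expect_true(all(is.finite(p1)), label = paste(nm, "finite predictions"))
  }
})

test_that("Gibbs chains are stable across half-chains (split-mean check)", {
  set.seed(31)
  n <- 60; p <- 10
  X <- matrix(rbinom(n * p, 2, 0.4), n, p)
  y <- drop(X %*% rnorm(p, 0, 0.5)) + rnorm(n, 0, 0.7)
  sp <- estimator_spec("BRR")
  sp$hyperparams[c("niter", "burnin", "thin")] <- list(6000L, 1000L, 1L)
  sp$hyperparams$keep_chain <- TRUE
  f <- gp_fit(sp, y, X = X)
  ch <- f$diagnostics$chain[, seq_len(p), drop = FALSE]
  # thin to near-independence before the split-mean comparison
  ch <- ch[seq(1, nrow(ch), by = 10), , drop = FALSE]
  half <- nrow(ch) %/% 2
  a <- ch[seq_len(half), , drop = FALSE]
  b <- ch[(half + 1):nrow(ch), , drop = FALSE]
  # Geweke-style: difference of half-chain means within 3 MC s.e.
  se <- sqrt(apply(a, 2, var) / half + apply(b, 2, var) / half)
  z <- abs(colMeans(a) - colMeans(b)) / se
  expect_lt(mean(z > 3), 0.2)
  expect_lt(max(abs(colMeans(a) - colMeans(b))), 0.15)
})

test_that("RKHS kernel fits interpolate smooth signals and MKRKHS weights sum to 1", {
  set.seed(13)
  n <- 50
  X <- matrix(runif(n * 3), n, 3)
  y <- sin(2 * pi * X[, 1]) + X[, 2]^2 + rnorm(n, 0, 0.05)
  f1 <- gp_fit("RKHS", y, X = X)
  expect_gt(cor(predict(f1, X_new = X), y), 0.95)
  f2 <- gp_fit("MKRKHS", y, X = X)
  expect_equal(sum(f2$diagnostics$kernel_weights), 1, tolerance = 1e-12)
  expect_gt(cor(predict(f2, X_new = X), y), 0.95)
})
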