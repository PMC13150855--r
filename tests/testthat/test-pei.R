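pei_index <- function(x, envs = paste0("E", seq_along(x))) {
  env_index("F1", c(1, 5), stats::setNames(x, envs), centre = 0)
}

test_that("interaction blocks scale dosages by the index value", {
  M <- matrix(c(1, 2, 0, 1), 2, 2)
  expect_equal(build_interaction_block(M, 2), matrix(c(2, 4, 0, 2), 2, 2))
  expect_equal(build_interaction_block(M, 0), matrix(0, 2, 2))
  expect_equal(build_interaction_block(M, 1), M)
  expect_error(build_interaction_block(M, NaN), "finite")
})

test_that("the stacked design has shared main and interaction columns", {
  geno <- random_geno(3, 4, seed = 2)
  M <- unclass(geno)
  idx <- pei_index(c(0, 1))
  d <- build_design(geno, idx)
  expect_equal(dim(d$X_all), c(6L, 8L))  # 2p columns
  expect_equal(d$X_all[1:3, 5:8], unname(M * 0), ignore_attr = TRUE)
  expect_equal(d$X_all[4:6, 5:8], unname(M), ignore_attr = TRUE)
  expect_equal(d$X_all[4:6, 1:4], unname(M), ignore_attr = TRUE)
  expect_equal(unname(d$env_cov), rep(c(0, 1), each = 3))
  expect_error(build_design(geno, idx, environments = "E9"), "E9")
})

test_that("kinship blocks equal (1 + x_j x_j') G and match the explicit product", {
  geno <- random_geno(20, 40, seed = 4)
  x <- c(-0.8, 0.1, 0.7)
  idx <- pei_index(x)
  K <- build_kinship(geno, idx, grm = "crossprod")
  d <- build_design(geno, idx)
  expect_lt(max(abs(K - tcrossprod(d$X_all))), 1e-9)
  # block structure against G
  G <- tcrossprod(unclass(geno))
  expect_equal(K[1:20, 21:40], (1 + x[1] * x[2]) * G, ignore_attr = TRUE)
  # x = 0 limit: every block is G
  K0 <- build_kinship(geno, pei_index(c(0, 0, 0)), grm = "crossprod")
  expect_equal(K0, kronecker(matrix(1, 3, 3), G), ignore_attr = TRUE)
  # single environment: (1 + x^2) G
  K1 <- build_kinship(geno, pei_index(0.5, "E1"), environments = "E1",
                      grm = "crossprod")
  expect_equal(K1, 1.25 * G, ignore_attr = TRUE)
})

test_that("the PEI kinship is positive semi-definite", {
  geno <- random_geno(15, 30, seed = 6)
  for (grm in c("vanraden", "crossprod")) {
    K <- build_kinship(geno, pei_index(c(-1.2, 0.3, 0.9)), grm = grm)
    ev <- eigen(K, symmetric = TRUE, only.values = TRUE)$values
    expect_gte(min(ev), -1e-8 * sum(diag(K)) / nrow(K))
  }
})

noiseless_pei <- function(n = 200, p = 100, m = 4, seed = 19) {
  geno <- random_geno(n, p, seed = seed)
  M <- unclass(geno)
  set.seed(seed + 1)
  a <- rnorm(p, 0, 0.2); b <- rnorm(p, 0, 0.2)
  x <- seq(-1.5, 1.5, length.out = m)
  envs <- paste0("E", seq_len(m))
  vals <- 3 + outer(drop(M %*% a), rep(1, m)) +
    outer(drop(M %*% b), x) + matrix(0.5 * x, n, m, byrow = TRUE)
  dimnames(vals) <- list(rownames(M), envs)
  list(geno = geno, idx = pei_index(x, envs), ph = pheno_from_matrix(vals),
       vals = vals)
}

test_that("noiseless generative data are recovered for held-out genotypes", {
  d <- noiseless_pei()
  test_ids <- rownames(d$geno)[161:200]
  tc <- expand.grid(genotype = test_ids,
                    environment = names(d$idx$centred_index),
                    stringsAsFactors = FALSE)
  pr <- fit_predict_pei(d$ph, d$geno, d$idx, "rrBLUP", tc)
  obs <- merge(pr, d$ph, by = c("genotype", "environment"))
  rel <- max(abs(obs$predicted - obs$value)) / diff(range(obs$value))
  expect_lt(rel, 1e-3)
})

test_that("marker-form and kinship-form PEI predictions are equivalent", {
  worst <- 0
  for (s in 1:3) {
    d <- noiseless_pei(n = 40, p = 30, m = 3, seed = 40 + s)
    ph <- d$ph
    set.seed(s)
    ph$value <- ph$value + rnorm(nrow(ph), 0, 0.3)
    test_ids <- rownames(d$geno)[31:40]
    tc <- expand.grid(genotype = test_ids,
                      environment = names(d$idx$centred_index),
                      stringsAsFactors = FALSE)
    p1 <- fit_predict_pei(ph, d$geno, d$idx, "rrBLUP", tc)
    p2 <- fit_predict_pei(ph, d$geno, d$idx, "GBLUP", tc, grm = "crossprod")
    worst <- max(worst, max(abs(p1$predicted - p2$predicted)))
  }
  expect_lt(worst, 1e-8)
})

test_that("constant phenotypes predict the constant", {
  d <- noiseless_pei(n = 30, p = 20, m = 3, seed = 50)
  ph <- d$ph; ph$value <- 4.2
  tc <- data.frame(genotype = rownames(d$geno)[25:30], environment = "E2")
  pr <- fit_predict_pei(ph, d$geno, d$idx, "rrBLUP", tc)
  expect_equal(pr$predicted, rep(4.2, 6), tolerance = 1e-6)
})

test_that("predictions are invariant to environment block ordering", {
  d <- noiseless_pei(n = 40, p = 30, m = 4, seed = 60)
  ph <- d$ph
  set.seed(60); ph$value <- ph$value + rnorm(nrow(ph), 0, 0.2)
  tc <- expand.grid(genotype = rownames(d$geno)[35:40],
                    environment = paste0("E", 1:4),
                    stringsAsFactors = FALSE)
  shuf <- ph[order(rev(ph$environment), ph$genotype), ]
  # exact with a closed-form variance structure
  p1 <- fit_predict_pei(ph, d$geno, d$idx, "rrBLUP", tc,
                        variance = "common")
  p2 <- fit_predict_pei(shuf, d$geno, d$idx, "rrBLUP", tc,
                        variance = "common")
  expect_equal(p1$predicted, p2$predicted, tolerance = 1e-9)
  # default mode: invariant up to the mix-weight optimizer's tolerance
  q1 <- fit_predict_pei(ph, d$geno, d$idx, "rrBLUP", tc)
  q2 <- fit_predict_pei(shuf, d$geno, d$idx, "rrBLUP", tc)
  expect_equal(q1$predicted, q2$predicted, tolerance = 1e-4)
})

test_that("unknown test genotypes and missing environment indices error", {
  d <- noiseless_pei(n = 20, p = 10, m = 3, seed = 70)
  expect_error(
    fit_predict_pei(d$ph, d$geno, d$idx, "rrBLUP",
                    data.frame(genotype = "ghost", environment = "E1")),
    "absent from genotype matrix")
  expect_error(
    fit_predict_pei(d$ph, d$geno, d$idx, "rrBLUP",
                    data.frame(genotype = rownames(d$geno)[1],
                               environment = "E99")),
    "without an index")
})

test_that("polygenic interaction improves held-out prediction when present, not when absent", {
  wins_b <- wins_0 <- logical(0)
  for (s in 1:50) {
    for (has_inter in c(TRUE, FALSE)) {
      cfg <- sim_config(n = 100, p = 60, m = 4, days = 30,
                        causal_window = c(8, 22),
                        n_qtl_main = 15,
                        n_qtl_inter = if (has_inter) 10 else 0,
                        sd_inter = 0.5, Ve = 1.5, seed = 900 + s)
      sim <- sim_met(cfg)
      idx <- env_index(cfg$causal_factor, cfg$causal_window,
                       sim$truth$raw_index)
      test_ids <- rownames(sim$geno)[81:100]
      tc <- expand.grid(genotype = test_ids,
                        environment = names(idx$centred_index),
                        stringsAsFactors = FALSE)
      obs <- sim$pheno[sim$pheno$genotype %in% test_ids, ]
      acc <- function(interaction) {
        pr <- fit_predict_pei(sim$pheno, sim$geno, idx, "rrBLUP", tc,
                              interaction = interaction)
        m <- merge(pr, obs[, c("genotype", "environment", "value")],
                   by = c("genotype", "environment"))
        accuracy(m$predicted, m$value)
      }
      win <- acc(TRUE) > acc(FALSE)
      if (has_inter) wins_b <- c(wins_b, win) else wins_0 <- c(wins_0, win)
    }
  }
  expect_gte(mean(wins_b), 0.9)
  # no interaction simulated: paired sign test should not reject
  pv <- binom.test(sum(wins_0), length(wins_0))$p.value
  expect_gt(pv, 0.05)
})
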