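test_that("accuracy is Pearson correlation with sane degenerate handling", {
  obs <- c(1, 3, 2, 5, 4)
  expect_equal(accuracy(obs, obs), 1)
  expect_equal(accuracy(-obs, obs), -1)
  expect_equal(accuracy(obs + 10, obs), 1)   # location invariance
  expect_warning(a <- accuracy(rep(1, 5), obs), "zero variance")
  expect_true(is.na(a))
  expect_warning(a2 <- accuracy(c(1, 2), c(1, 2)), "fewer than 3")
  expect_true(is.na(a2))
})

test_that("heritability follows the entry-mean formula and its monotonicities", {
  expect_equal(heritability(variance_components(1, 0, 0, 3, 2)), 1)
  expect_equal(heritability(variance_components(1, 1, 1, 2, 2)),
               1 / (1 + 0.5 + 0.25))
  expect_equal(heritability(variance_components(0, 1, 1, 2, 2)), 0)
  expect_error(heritability(variance_components(0, 0, 0, 2, 2)), "undefined")
  # property: increasing Vg raises H; increasing Vge or Ve lowers it
  set.seed(8)
  for (i in 1:20) {
    v <- runif(3, 0.1, 3); L <- sample(2:6, 1); R <- sample(1:3, 1)
    H0 <- heritability(variance_components(v[1], v[2], v[3], L, R))
    expect_gt(heritability(variance_components(v[1] * 2, v[2], v[3], L, R)), H0)
    expect_lt(heritability(variance_components(v[1], v[2] * 2, v[3], L, R)), H0)
    expect_lt(heritability(variance_components(v[1], v[2], v[3] * 2, L, R)), H0)
  }
})

test_that("variance components are recovered from a balanced generative design", {
  set.seed(42)
  n <- 500; L <- 4; R <- 2
  g <- rnorm(n, 0, sqrt(2))
  ge <- matrix(rnorm(n * L, 0, 1), n, L)
  recs <- expand.grid(genotype = sprintf("g%03d", 1:n),
                      environment = paste0("E", 1:L), rep = 1:R,
                      stringsAsFactors = FALSE)
  gi <- match(recs$genotype, sprintf("g%03d", 1:n))
  ei <- match(recs$environment, paste0("E", 1:L))
  recs$trait <- "T"
  recs$value <- 10 + g[gi] + ge[cbind(gi, ei)] + rnorm(nrow(recs), 0, 1)
  vc <- estimate_components(pheno_table(recs))
  expect_equal(vc$Vg, 2, tolerance = 0.15 * 2)
  expect_equal(vc$Vge, 1, tolerance = 0.15)
  expect_equal(vc$Ve, 1, tolerance = 0.15)
  expect_equal(vc$L, 4L)
  expect_equal(vc$R, 2L)
})

test_that("pure genotype signal and pure noise decompose as expected", {
  n <- 200; L <- 3; R <- 2
  g <- rnorm(n, 0, 1)
  recs <- expand.grid(genotype = sprintf("g%03d", 1:n),
                      environment = paste0("E", 1:L), rep = 1:R,
                      stringsAsFactors = FALSE)
  gi <- match(recs$genotype, sprintf("g%03d", 1:n))
  recs$trait <- "T"
  recs$value <- g[gi]
  vc <- suppressWarnings(estimate_components(pheno_table(recs)))
  expect_equal(vc$Vge, 0, tolerance = 1e-10)
  expect_equal(vc$Ve, 0, tolerance = 1e-10)
  expect_equal(vc$Vg, var(g), tolerance = 1e-8)
  # pure noise at 500 genotypes
  set.seed(77)
  n <- 500
  recs <- expand.grid(genotype = sprintf("g%03d", 1:n),
                      environment = paste0("E", 1:L), rep = 1:R,
                      stringsAsFactors = FALSE)
  recs$trait <- "T"
  recs$value <- rnorm(nrow(recs))
  vc <- suppressWarnings(estimate_components(pheno_table(recs)))
  expect_lt(vc$Vg, 0.05)
  expect_lt(vc$Vge, 0.05)
})

test_that("unbalanced designs are refused", {
  recs <- data.frame(genotype = c("a", "a", "b"),
                     environment = c("E1", "E2", "E1"),
                     trait = "T", value = 1:3)
  expect_error(estimate_components(pheno_table(recs)), "unbalanced")
})

test_that("problem dimension is the base-10 order of magnitude", {
  expect_identical(gp_dimension(100, 10000), 6L)
  expect_identical(gp_dimension(1, 10), 1L)
  expect_identical(gp_dimension(10, 10), 2L)
  expect_warning(gp_dimension(1e4, 1e4), "dimension 8")
})

cv_fixture <- function(h2 = NULL, Ve = NULL, seed = 5) {
  cfg <- sim_config(n = 60, p = 40, m = 4, days = 30,
                    causal_window = c(8, 22), n_qtl_main = 12,
                    n_qtl_inter = 8, sd_inter = 0.4,
                    h2 = if (is.null(h2)) 0.5 else h2, Ve = Ve, seed = seed)
  sim_met(cfg)
}

test_that("genotype-fold CV on noiseless generative data is near-perfect and deterministic", {
  sim <- cv_fixture(Ve = 0)
  res <- cv_untested_genotypes(sim$geno, sim$pheno, sim$series, "PEI",
                               "rrBLUP", k = 10, reps = 2, seed = 4,
                               min_width = 7, step = 3)
  expect_gt(res$overall, 0.99)
  # partitions: every genotype appears exactly once per replicate
  expect_equal(sum(res$folds$n_test[res$folds$environment == "E01"]),
               2 * 60)
  res2 <- cv_untested_genotypes(sim$geno, sim$pheno, sim$series, "PEI",
                                "rrBLUP", k = 10, reps = 2, seed = 4,
                                min_width = 7, step = 3)
  expect_identical(res$folds, res2$folds)
  expect_identical(res$overall, res2$overall)
  # overall is the unweighted mean over environments
  expect_equal(res$overall, mean(res$by_environment$mean_accuracy))
})

test_that("half-split CV of pure-noise phenotypes has accuracy near zero", {
  cfg <- sim_config(n = 60, p = 40, m = 4, days = 30,
                    causal_window = c(8, 22), n_qtl_main = 2,
                    n_qtl_inter = 0, sd_main = 1e-6, Ve = 1, seed = 9)
  sim <- sim_met(cfg)
  res <- cv_untested_genotypes(sim$geno, sim$pheno, sim$series, "PEI",
                               "rrBLUP", k = 2, reps = 3, seed = 2,
                               min_width = 7, step = 3)
  # null band ~ 2/sqrt(n_test) with n_test = 30 per fold
  expect_lt(abs(res$overall), 2 / sqrt(30))
})

test_that("RN cross-validation demands at least three environments", {
  sim <- cv_fixture(Ve = 1, seed = 11)
  ph2 <- sim$pheno[sim$pheno$environment %in% c("E01", "E02"), ]
  expect_error(
    cv_untested_genotypes(sim$geno, ph2, sim$series, "RN", "rrBLUP",
                          k = 5, reps = 1, seed = 1),
    "three", ignore.case = TRUE)
  expect_error(
    cv_novel_environment(sim$geno, ph2, sim$series, "RN", "rrBLUP"),
    "three", ignore.case = TRUE)
})

test_that("leave-one-environment-out recovers noiseless PEI data in every environment", {
  # noiseless in both senses: no residual variance and no daily weather
  # noise, so the index extrapolates exactly to the held-out environment
  cfg <- sim_config(n = 50, p = 40, m = 5, days = 30,
                    causal_window = c(8, 22), n_qtl_main = 12,
                    n_qtl_inter = 8, sd_inter = 0.4, Ve = 0, seed = 13,
                    factors = list(
                      DHT = list(base = 28, amplitude = 4, period = 60,
                                 env_sd = 2.5, noise_sd = 0),
                      DLT = list(base = 16, amplitude = 3, period = 60,
                                 env_sd = 1.5, noise_sd = 0)))
  sim <- sim_met(cfg)
  res <- cv_novel_environment(sim$geno, sim$pheno, sim$series, "PEI",
                              "rrBLUP", min_width = 7, step = 3)
  expect_true(all(res$folds$accuracy > 0.99))
})

test_that("a held-out environment sharing a training x_j reproduces fitted values", {
  d_geno <- random_geno(30, 20, seed = 17)
  x <- c(-1, 0, 1, 0)  # E4 duplicates E2's index value
  envs <- paste0("E", 1:4)
  idx <- env_index("F1", c(1, 5), stats::setNames(x, envs), centre = 0)
  M <- unclass(d_geno)
  set.seed(17)
  vals <- outer(drop(M %*% rnorm(20, 0, 0.3)), rep(1, 4)) +
    outer(drop(M %*% rnorm(20, 0, 0.3)), x) +
    matrix(rnorm(120, 0, 0.2), 30, 4)
  dimnames(vals) <- list(rownames(M), envs)
  ph_no4 <- pheno_from_matrix(vals[, 1:3])
  tc4 <- data.frame(genotype = rownames(M), environment = "E4")
  pr4 <- fit_predict_pei(ph_no4, d_geno, idx, "rrBLUP", tc4,
                         scale_index = FALSE, variance = "common")
  # oracle: the same stacked-design fit, evaluated in-sample at E2 (x = 0):
  # because x_E4 = x_E2, the novel-environment rows coincide with E2's
  # training design rows, so predictions must equal E2's fitted values
  tr <- ph_no4
  x_tr <- idx$centred_index[tr$environment]
  Mi <- M[match(tr$genotype, rownames(M)), ]
  f <- gp_fit("rrBLUP", tr$value, X = cbind(Mi, Mi * x_tr),
              covariates = cbind(x = as.numeric(x_tr)))
  fitted_e2 <- predict(f, X_new = cbind(M, M * 0),
                       covariates_new = cbind(x = rep(0, nrow(M))))
  expect_equal(pr4$predicted, fitted_e2, tolerance = 1e-9)
})
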