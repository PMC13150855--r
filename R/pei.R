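## Polygenic-environment-interaction (PEI) framework.
## Every marker carries a main effect a_k and an index-interaction effect
## b_k; in environment j with centred index x_j the genetic value of
## individual i is sum_k m_ik (a_k + b_k x_j). Stacking environments gives
## the marker-form design [M | x_j M] per environment block with a SINGLE
## shared length-2p effect vector, and the equivalent kinship with blocks
## K_(j,j') = (1 + x_j x_j') G. Shared effects are what lets information
## flow to an environment with no training records (novel-environment
## prediction); a literal per-environment block-diagonal parameterization
## is retained behind effects = "by_env" for comparison.

#' Marker-by-index interaction block for one environment
#'
#' @param M dosage matrix (n x p).
#' @param x_j scalar centred index value of the environment.
#' @return n x p matrix `x_j * M`.
#' @export
build_interaction_block <- function(M, x_j) {
  if (!is.finite(x_j)) stop("index value must be finite", call. = FALSE)
  unclass(as.matrix(M)) * x_j
}

#' Stacked PEI design across environments
#'
#' Rows are ordered environment-block by environment-block, genotypes in
#' `rownames(geno)` order within each block. Columns are the p main-effect
#' dosages followed by the p interaction columns; the bare index enters
#' separately as a fixed covariate (`env_cov`), not as a penalized column.
#'
#' @param geno genotype matrix.
#' @param index [env_index()] with values for every requested environment.
#' @param environments ordered environments to stack (default: all in the
#'   index).
#' @return list of class `"pei_design"`: `X_all` ((n*m) x 2p), `env_cov`
#'   (length n*m), `rows` (data.frame genotype/environment per row),
#'   `environments`, `x` (named centred indices).
#' @export
build_design <- function(geno, index, environments = NULL) {
  if (is.null(environments)) environments <- names(index$centred_index)
  miss <- setdiff(environments, names(index$centred_index))
  if (length(miss))
    stop("unknown environment(s) in index: ", paste(miss, collapse = ", "),
         call. = FALSE)
  M <- unclass(as.matrix(geno))
  x <- as.numeric(index$centred_index[environments])
  names(x) <- environments
  blocks <- lapply(environments, function(e)
    cbind(M, build_interaction_block(M, x[[e]])))
  X_all <- do.call(rbind, blocks)
  colnames(X_all) <- c(colnames(M), paste0(colnames(M), ":x"))
  rows <- data.frame(
    genotype = rep(rownames(M), times = length(environments)),
    environment = rep(environments, each = nrow(M)),
    stringsAsFactors = FALSE)
  structure(list(X_all = X_all, env_cov = x[rows$environment],
                 rows = rows, environments = environments, x = x),
            class = "pei_design")
}

#' Multi-environment kinship induced by shared main + interaction effects
#'
#' Block (j, j') equals (1 + x_j x_j') * G. With `grm = "crossprod"`
#' (G = M M') this is exactly the cross-product of the stacked marker
#' columns [M | x_j M]; `grm = "vanraden"` (default) uses the
#' allele-frequency-scaled relationship matrix instead.
#'
#' @param geno genotype matrix.
#' @param index [env_index()].
#' @param environments ordered environments (default: all in the index).
#' @param grm `"vanraden"` or `"crossprod"`.
#' @return (n*m) x (n*m) kinship with a `rows` attribute mapping rows to
#'   (genotype, environment).
#' @export
build_kinship <- function(geno, index, environments = NULL,
                          grm = c("vanraden", "crossprod")) {
  grm <- match.arg(grm)
  if (is.null(environments)) environments <- names(index$centred_index)
  x <- as.numeric(index$centred_index[environments])
  if (anyNA(x) || any(!is.finite(x)))
    stop("non-finite index value among requested environments", call. = FALSE)
  M <- unclass(as.matrix(geno))
  G <- if (grm == "vanraden") vanraden_grm(M) else tcrossprod(M)
  Cm <- 1 + outer(x, x)
  K <- kronecker(Cm, G)
  rows <- data.frame(
    genotype = rep(rownames(M), times = length(environments)),
    environment = rep(environments, each = nrow(M)),
    stringsAsFactors = FALSE)
  attr(K, "rows") <- rows
  K
}

## kinship entries for arbitrary cell lists (avoids materializing the full
## (n*m)^2 matrix when only train/test blocks are needed)
pei_kinship_cells <- function(G, geno_ids, x, cells_a, cells_b,
                              shared = TRUE,
                              component = c("both", "main", "inter")) {
  component <- match.arg(component)
  ia <- match(cells_a$genotype, geno_ids)
  ib <- match(cells_b$genotype, geno_ids)
  xa <- as.numeric(x[cells_a$environment])
  xb <- as.numeric(x[cells_b$environment])
  base <- G[ia, ib, drop = FALSE]
  coef <- switch(component,
                 both = 1 + outer(xa, xb),
                 main = matrix(1, length(xa), length(xb)),
                 inter = outer(xa, xb))
  out <- coef * base
  if (!shared) {
    same <- outer(cells_a$environment, cells_b$environment, "==")
    out <- out * same
  }
  out
}

## REML choice of the relative weight of the interaction kernel
pei_block_weight <- function(y, K_main, K_inter, W) {
  obj <- function(w) reml_kernel(y, (1 - w) * K_main + w * K_inter, W)$loglik
  stats::optimize(obj, c(1e-4, 1 - 1e-4), maximum = TRUE, tol = 1e-3)$maximum
}

#' Fit the PEI model and predict phenotypes for chosen cells
#'
#' Training cells are the observed (non-missing) phenotype records minus
#' `test_cells`. The fixed part is an intercept plus a regression on the
#' centred index (so environments wholly absent from training remain
#' predictable from their own x_j). The estimator determines the route:
#' marker-form linear estimators fit the stacked [M | x_j M] design;
#' GBLUP fits the induced kinship; kernel and tree learners consume
#' per-record features `[dosages, x_j]` (or the augmented
#' `[dosages, x_j * dosages, x_j]` with `features = "augment"`).
#'
#' @param pheno phenotype table.
#' @param geno genotype matrix.
#' @param index [env_index()] covering all training and test environments
#'   (extend novel environments with [index_environment()]).
#' @param spec an [estimator_spec()] or estimator name.
#' @param test_cells data.frame with columns `genotype`, `environment`:
#'   the cells to predict (they are removed from training even if observed).
#' @param trait trait name (default: single trait present).
#' @param grm relationship matrix for the kinship route.
#' @param effects `"shared"` (one effect vector across environments;
#'   default) or `"by_env"` (literal block-diagonal per-environment
#'   effects; kinship-route estimators only — carries no information into
#'   an unobserved environment).
#' @param features feature layout for kernel/tree estimators.
#' @param interaction include the marker-by-index interaction columns
#'   (default TRUE). FALSE drops them, leaving a main-effects-only model
#'   with the same fixed part — the natural null for quantifying what the
#'   polygenic interaction adds (linear and kinship routes only).
#' @param variance for the GBLUP/rrBLUP routes: `"per_block"` (default)
#'   gives the main and interaction blocks separate variance components
#'   (their relative weight is chosen by REML, so an absent interaction is
#'   shrunk away); `"common"` is the literal single-component model in
#'   which one variance covers all 2p effects.
#' @param scale_index divide the centred index by its standard deviation
#'   across the index's environments before building interaction terms
#'   (default TRUE). Because main and interaction effects share a single
#'   shrinkage parameter, the measurement units of the index otherwise set
#'   the implicit prior weight of the interaction block arbitrarily;
#'   standardizing makes the model unit-invariant. Disable to work on the
#'   raw centred scale.
#' @return `test_cells` with a `predicted` column appended.
#' @export
fit_predict_pei <- function(pheno, geno, index, spec, test_cells,
                            trait = NULL, grm = c("vanraden", "crossprod"),
                            effects = c("shared", "by_env"),
                            features = c("plain", "augment"),
                            interaction = TRUE, scale_index = TRUE,
                            variance = c("per_block", "common")) {
  grm <- match.arg(grm); effects <- match.arg(effects)
  features <- match.arg(features); variance <- match.arg(variance)
  if (is.character(spec)) spec <- estimator_spec(spec)
  pheno <- pheno_table(pheno)
  if (is.null(trait)) {
    tr <- unique(pheno$trait)
    if (length(tr) != 1L) stop("multiple traits; specify `trait`", call. = FALSE)
    trait <- tr
  }
  x <- index$centred_index
  if (scale_index) {
    sx <- stats::sd(x)
    if (is.finite(sx) && sx > 0) x <- x / sx
  }
  miss_g <- setdiff(unique(test_cells$genotype), rownames(geno))
  if (length(miss_g))
    stop("test genotype(s) absent from genotype matrix: ",
         paste(utils::head(miss_g, 5), collapse = ", "), call. = FALSE)
  miss_e <- setdiff(unique(c(pheno$environment[!is.na(pheno$value)],
                             test_cells$environment)), names(x))
  if (length(miss_e))
    stop("environment(s) without an index value: ",
         paste(miss_e, collapse = ", "), call. = FALSE)

  obs <- pheno[pheno$trait == trait & !is.na(pheno$value) &
                 pheno$genotype %in% rownames(geno), , drop = FALSE]
  key <- function(d) paste(d$genotype, d$environment, sep = "\r")
  train <- obs[!(key(obs) %in% key(test_cells)), , drop = FALSE]
  if (!nrow(train)) stop("no training cells remain", call. = FALSE)
  y <- train$value
  tr_cells <- train[, c("genotype", "environment")]
  te_cells <- test_cells[, c("genotype", "environment")]
  x_tr <- as.numeric(x[tr_cells$environment])
  x_te <- as.numeric(x[te_cells$environment])
  M <- unclass(as.matrix(geno))
  name <- spec$name

  pred <- if (name == "GBLUP" || effects == "by_env") {
    if (effects == "by_env" && !name %in% c("GBLUP", "RKHS", "MKRKHS"))
      stop("effects = \"by_env\" is only defined for kinship-route ",
           "estimators", call. = FALSE)
    if (effects == "by_env" && name %in% c("RKHS", "MKRKHS"))
      stop("by_env kernels are not defined for RKHS estimators", call. = FALSE)
    G <- if (grm == "vanraden") vanraden_grm(M) else tcrossprod(M)
    shared <- effects == "shared"
    cells_K <- function(a, b, component)
      pei_kinship_cells(G, rownames(M), x, a, b, shared, component)
    if (!interaction) {
      K_tr <- cells_K(tr_cells, tr_cells, "main")
      K_te <- cells_K(te_cells, tr_cells, "main")
    } else if (variance == "per_block") {
      W <- cbind(1, x_tr)
      w <- pei_block_weight(y, cells_K(tr_cells, tr_cells, "main"),
                            cells_K(tr_cells, tr_cells, "inter"), W)
      K_tr <- (1 - w) * cells_K(tr_cells, tr_cells, "main") +
        w * cells_K(tr_cells, tr_cells, "inter")
      K_te <- (1 - w) * cells_K(te_cells, tr_cells, "main") +
        w * cells_K(te_cells, tr_cells, "inter")
    } else {
      K_tr <- cells_K(tr_cells, tr_cells, "both")
      K_te <- cells_K(te_cells, tr_cells, "both")
    }
    fit <- gp_fit(spec, y, K = K_tr, covariates = cbind(x = x_tr))
    predict(fit, K_cross = K_te, covariates_new = cbind(x = x_te))
  } else if (name %in% c("RKHS", "MKRKHS", "SVM", "RF", "GBM")) {
    feat <- function(cells, xs) {
      Mi <- M[match(cells$genotype, rownames(M)), , drop = FALSE]
      if (features == "augment") cbind(Mi, Mi * xs, x = xs)
      else cbind(Mi, x = xs)
    }
    F_tr <- feat(tr_cells, x_tr); F_te <- feat(te_cells, x_te)
    fit <- gp_fit(spec, y, X = F_tr)
    predict(fit, X_new = F_te)
  } else {
    # marker-form linear estimators on the stacked [M | x_j M] design.
    # rrBLUP honours variance = "per_block" through block rescaling by
    # (sqrt(1-w), sqrt(w)) — equivalent to separate variance components;
    # the other penalized/Bayesian estimators carry their own per-marker
    # shrinkage and use the design as-is.
    wts <- c(1, 1)
    if (interaction && variance == "per_block" && name == "rrBLUP") {
      # derive the mix weight from the same cell-kinship arithmetic the
      # kinship route uses, so the two routes stay numerically equivalent
      Gc <- tcrossprod(M)
      base <- pei_kinship_cells(Gc, rownames(M), x, tr_cells, tr_cells,
                                shared = TRUE, component = "main")
      inter <- pei_kinship_cells(Gc, rownames(M), x, tr_cells, tr_cells,
                                 shared = TRUE, component = "inter")
      w <- pei_block_weight(y, base, inter, cbind(1, x_tr))
      wts <- c(sqrt(1 - w), sqrt(w))
    }
    design <- function(cells, xs) {
      Mi <- M[match(cells$genotype, rownames(M)), , drop = FALSE]
      if (interaction) cbind(wts[1] * Mi, wts[2] * (Mi * xs)) else Mi
    }
    X_tr <- design(tr_cells, x_tr); X_te <- design(te_cells, x_te)
    fit <- gp_fit(spec, y, X = X_tr, covariates = cbind(x = x_tr))
    predict(fit, X_new = X_te, covariates_new = cbind(x = x_te))
  }
  out <- te_cells
  out$predicted <- as.numeric(pred)
  out
}
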