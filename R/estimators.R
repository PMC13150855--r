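## Unified fit/predict contract over the 15-estimator ensemble.
## Three routes share one interface:
##   marker form     y = W b + X u + e          (ridge family, Bayesian alphabet)
##   kinship form    y = W b + g + e, V(g) = s2 K   (GBLUP, RKHS kernels)
##   delegated form  y ~ f(features)            (SVM / RF / GBM)

.ESTIMATORS <- list(
  GBLUP  = list(category = "parametric"),
  BayesA = list(category = "parametric"),
  BayesB = list(category = "parametric"),
  BayesC = list(category = "parametric"),
  BRR    = list(category = "parametric"),
  BL     = list(category = "parametric"),
  LASSO  = list(category = "parametric"),
  RR     = list(category = "parametric"),
  rrBLUP = list(category = "parametric"),
  EN     = list(category = "parametric"),
  RKHS   = list(category = "semiparametric"),
  MKRKHS = list(category = "semiparametric"),
  SVM    = list(category = "nonparametric"),
  RF     = list(category = "nonparametric"),
  GBM    = list(category = "nonparametric")
)

.default_hyper <- function(name) {
  gibbs <- list(niter = 6000L, burnin = 1000L, thin = 5L, df0 = 5,
                R2 = 0.5, seed = 1L)
  switch(name,
    GBLUP  = list(ratio = NULL, seed = 1L),   # fixed sigma_u^2/sigma_e^2
    rrBLUP = list(ratio = NULL, seed = 1L),   # NULL -> REML
    RR     = list(lambda = NULL, seed = 1L),          # NULL -> CV grid
    LASSO  = list(lambda = NULL, nfolds = 5L, seed = 1L),
    EN     = list(lambda = NULL, alpha = 0.5, nfolds = 5L, seed = 1L),
    BRR    = gibbs,
    BayesA = gibbs,
    BayesB = c(gibbs, list(pi = 0.95)),
    BayesC = c(gibbs, list(pi = 0.95)),
    BL     = gibbs,
    RKHS   = list(h = 1, seed = 1L),
    MKRKHS = list(h_grid = c(0.1, 0.5, 1, 2.5, 5), seed = 1L),
    SVM    = list(kernel = "radial", seed = 1L),
    RF     = list(ntree = 500L, seed = 1L),
    GBM    = list(nrounds = 500L, max_depth = 3L, eta = 0.05, seed = 1L),
    stop("unknown estimator: ", name, call. = FALSE))
}

#' Build an estimator specification
#'
#' @param name one of the 15 registered estimators (see
#'   [estimator_registry()]).
#' @param ... hyperparameter overrides (e.g. `lambda`, `niter`, `pi`, `h`,
#'   `ntree`, `seed`). Unknown names are rejected.
#' @return list of class `"estimator_spec"` with `name`, `category`,
#'   `hyperparams`.
#' @export
estimator_spec <- function(name, ...) {
  if (!name %in% names(.ESTIMATORS))
    stop("unknown estimator: ", name, "; registry has: ",
         paste(names(.ESTIMATORS), collapse = ", "), call. = FALSE)
  hp <- .default_hyper(name)
  dots <- list(...)
  bad <- setdiff(names(dots), names(hp))
  if (length(bad))
    stop("unknown hyperparameter(s) for ", name, ": ",
         paste(bad, collapse = ", "), call. = FALSE)
  hp[names(dots)] <- dots
  structure(list(name = name, category = .ESTIMATORS[[name]]$category,
                 hyperparams = hp),
            class = "estimator_spec")
}

#' The 15-estimator registry
#'
#' Ten parametric (GBLUP, BayesA/B/C, BRR, Bayesian LASSO, LASSO, ridge
#' regression, rr-BLUP, elastic net), two semi-parametric (RKHS, multi-kernel
#' RKHS), three non-parametric (SVM, random forest, gradient boosting).
#' RR and rr-BLUP differ in how the ridge penalty is chosen: RR uses a fixed
#' or cross-validated lambda, rr-BLUP estimates it by REML.
#'
#' @return named list of 15 default [estimator_spec()] objects.
#' @export
estimator_registry <- function() {
  out <- lapply(names(.ESTIMATORS), estimator_spec)
  names(out) <- names(.ESTIMATORS)
  out
}

## run code under a local, restored RNG state
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (has_old) get(".Random.seed", envir = globalenv())
    on.exit({
      if (has_old) assign(".Random.seed", old, envir = globalenv())
      else suppressWarnings(rm(".Random.seed", envir = globalenv()))
    }, add = TRUE)
    set.seed(seed)
  }
  force(code)
}

#' VanRaden genomic relationship matrix
#'
#' G = Z Z' / c with Z the dosage matrix centred by twice the allele
#' frequency per marker and c = 2 * sum(pbar * (1 - pbar)). Monomorphic
#' markers contribute nothing to the numerator or the scale.
#'
#' @param M dosage matrix (0/1/2), individuals in rows.
#' @return n x n relationship matrix.
#' @export
vanraden_grm <- function(M) {
  M <- unclass(as.matrix(M))
  pbar <- colMeans(M) / 2
  Z <- sweep(M, 2L, 2 * pbar)
  c0 <- 2 * sum(pbar * (1 - pbar))
  if (c0 <= 0) stop("all markers monomorphic; GRM undefined", call. = FALSE)
  tcrossprod(Z) / c0
}

## ---- spectral REML for y = W b + g + e, V(g) = sigma_u^2 K ----------------

check_psd <- function(K, tol = 1e-8) {
  if (!isSymmetric(unname(K), tol = 1e-6))
    stop("kinship matrix is not symmetric", call. = FALSE)
  K
}

reml_kernel <- function(y, K, W, bounds = c(-14, 14), fixed_ratio = NULL) {
  n <- length(y)
  K <- check_psd(K)
  eig <- eigen(K, symmetric = TRUE)
  d <- eig$values
  if (min(d) < -1e-8 * max(abs(d), 1) * n)
    stop("kinship matrix has substantially negative eigenvalues (not PSD)",
         call. = FALSE)
  d <- pmax(d, 0)
  U <- eig$vectors
  yt <- drop(crossprod(U, y))
  Wt <- crossprod(U, W)
  q <- ncol(W)
  profile <- function(logphi) {
    phi <- exp(logphi)
    w <- 1 / (phi * d + 1)
    WtWw <- crossprod(Wt, Wt * w)
    beta <- solve(WtWw, crossprod(Wt, yt * w))
    r <- yt - drop(Wt %*% beta)
    s2 <- sum(w * r^2) / (n - q)
    ll <- -0.5 * ((n - q) * log(max(s2, 1e-300)) + sum(log(phi * d + 1)) +
                    as.numeric(determinant(WtWw)$modulus))
    list(ll = ll, beta = beta, r = r, w = w, s2 = s2, phi = phi)
  }
  lp_hat <- if (!is.null(fixed_ratio)) log(fixed_ratio) else
    stats::optimize(function(lp) -profile(lp)$ll,
                    interval = bounds, tol = 1e-10)$minimum
  fit <- profile(lp_hat)
  vstar <- U %*% (fit$w * fit$r)    # = (phi K + I)^-1 (y - W beta)
  list(beta = drop(fit$beta), phi = fit$phi,
       sigma_e2 = fit$s2, sigma_u2 = fit$phi * fit$s2,
       vstar = drop(vstar), loglik = fit$ll)
}

## ---- exact ridge with unpenalized fixed part ------------------------------

ridge_solve <- function(X, y, lambda, W = NULL) {
  p <- ncol(X)
  if (is.null(W) || ncol(W) == 0L) {
    u <- solve(crossprod(X) + diag(lambda, p), crossprod(X, y))
    return(list(beta = numeric(0), u = drop(u)))
  }
  q <- ncol(W)
  A <- rbind(cbind(crossprod(W), crossprod(W, X)),
             cbind(crossprod(X, W), crossprod(X) + diag(lambda, p)))
  b <- c(crossprod(W, y), crossprod(X, y))
  th <- solve(A, b)
  list(beta = th[seq_len(q)], u = th[-seq_len(q)])
}

## ---- Gaussian kernels ------------------------------------------------------

sq_dist <- function(A, B = A) {
  an <- rowSums(A^2); bn <- rowSums(B^2)
  D <- outer(an, bn, "+") - 2 * tcrossprod(A, B)
  pmax(D, 0)
}

gauss_kernel <- function(A, B, h, scale) exp(-h * sq_dist(A, B) / scale)

## ---- main contract ---------------------------------------------------------

#' Fit an estimator under the unified contract
#'
#' @param spec an [estimator_spec()] (or estimator name, taken with default
#'   hyperparameters).
#' @param y numeric response of length N, no missing values (mask upstream).
#' @param X N x q design/feature matrix (marker form or delegated learners).
#' @param K N x N kinship/kernel matrix (kinship form: GBLUP; also accepted
#'   by RKHS in place of features).
#' @param covariates optional N x c matrix of fixed covariates (unpenalized
#'   in linear estimators, appended to features in delegated learners).
#' @param intercept fit an intercept (default TRUE). Disable only for
#'   textbook oracles.
#' @return object of class `"gp_fit"` with elements `beta` (fixed effects,
#'   intercept first), `u` (marker effects, marker form), `g` (individual
#'   effects, kinship form), variance components where defined, and
#'   `diagnostics`.
#' @export
gp_fit <- function(spec, y, X = NULL, K = NULL, covariates = NULL,
                   intercept = TRUE) {
  if (is.character(spec)) spec <- estimator_spec(spec)
  stopifnot(inherits(spec, "estimator_spec"))
  y <- as.numeric(y)
  n <- length(y)
  if (n < 2L) stop("need at least 2 observations", call. = FALSE)
  if (anyNA(y)) stop("missing responses; mask them upstream", call. = FALSE)
  if (!is.null(covariates)) covariates <- as.matrix(covariates)
  W <- cbind(if (intercept) matrix(1, n, 1), covariates)
  if (!is.null(W) && ncol(W) == 0L) W <- NULL
  hp <- spec$hyperparams
  name <- spec$name

  fit <- switch(name,
    GBLUP  = fit_gblup(y, X, K, W, hp),
    rrBLUP = fit_rrblup(y, X, W, hp),
    RR     = fit_rr(y, X, W, hp),
    LASSO  = fit_glmnet(y, X, W, covariates, intercept, alpha = 1, hp),
    EN     = fit_glmnet(y, X, W, covariates, intercept,
                        alpha = hp$alpha, hp),
    BRR    = ,
    BayesA = ,
    BayesB = ,
    BayesC = ,
    BL     = fit_bayes(name, y, X, W, hp),
    RKHS   = fit_rkhs(y, X, K, W, hp),
    MKRKHS = fit_mkrkhs(y, X, K, W, hp),
    SVM    = fit_svm(y, X, covariates, hp),
    RF     = fit_rf(y, X, covariates, hp),
    GBM    = fit_gbm(y, X, covariates, hp))

  fit$spec <- spec
  fit$intercept <- intercept
  fit$n_covariates <- if (is.null(covariates)) 0L else ncol(covariates)
  fit$n_train <- n
  class(fit) <- "gp_fit"
  fit
}

fit_gblup <- function(y, X, K, W, hp = list()) {
  if (is.null(K)) {
    if (is.null(X)) stop("GBLUP needs K or X", call. = FALSE)
    K <- tcrossprod(unclass(as.matrix(X)))
    X_train <- unclass(as.matrix(X))
  } else X_train <- NULL
  if (is.null(W)) W <- matrix(0, length(y), 0)  # degenerate; guard below
  if (ncol(W) == 0L)
    stop("GBLUP requires an intercept or covariates in the fixed part",
         call. = FALSE)
  rm <- reml_kernel(y, K, W, fixed_ratio = hp$ratio)
  g <- rm$phi * drop(K %*% rm$vstar)
  list(route = "kinship", beta = rm$beta, g = g, K_train = K,
       X_train = X_train, phi = rm$phi, vstar = rm$vstar,
       sigma_g2 = rm$sigma_u2, sigma_e2 = rm$sigma_e2,
       diagnostics = list(loglik = rm$loglik, converged = TRUE))
}

fit_rrblup <- function(y, X, W, hp = list()) {
  if (is.null(X)) stop("rrBLUP needs a marker matrix X", call. = FALSE)
  X <- unclass(as.matrix(X))
  if (is.null(W)) {
    # no fixed part: REML needs >= 1 fixed df; use a zero-weight pseudo
    # column is not meaningful -- require an intercept instead
    stop("rrBLUP requires an intercept or covariates", call. = FALSE)
  }
  K <- tcrossprod(X)
  rm <- reml_kernel(y, K, W, fixed_ratio = hp$ratio)
  u <- rm$phi * drop(crossprod(X, rm$vstar))
  list(route = "marker", beta = rm$beta, u = u,
       sigma_u2 = rm$sigma_u2, sigma_e2 = rm$sigma_e2,
       diagnostics = list(loglik = rm$loglik, converged = TRUE))
}

fit_rr <- function(y, X, W, hp) {
  if (is.null(X)) stop("RR needs a marker matrix X", call. = FALSE)
  X <- unclass(as.matrix(X))
  lambda <- hp$lambda
  if (is.null(lambda)) {
    # ridge path by cross-validation (glmnet, alpha = 0), on the same
    # (1/2n) * RSS + lambda/2 * ||u||^2 scale; convert to the exact-solve
    # penalty scale lambda_exact = n * lambda_glmnet / sd adjustments are
    # avoided by standardize = FALSE
    cv <- with_seed(hp$seed,
      glmnet::cv.glmnet(X, y, alpha = 0, standardize = FALSE,
                        nfolds = min(5L, length(y))))
    lambda <- cv$lambda.min * length(y)
  }
  sol <- ridge_solve(X, y, lambda, W)
  list(route = "marker", beta = sol$beta, u = sol$u, lambda = lambda,
       diagnostics = list(converged = TRUE))
}

fit_glmnet <- function(y, X, W, covariates, intercept, alpha, hp) {
  if (is.null(X)) stop("penalized regression needs X", call. = FALSE)
  X <- unclass(as.matrix(X))
  Xf <- cbind(X, covariates)
  pf <- c(rep(1, ncol(X)),
          rep(0, if (is.null(covariates)) 0 else ncol(covariates)))
  lam <- hp$lambda
  fit <- with_seed(hp$seed, {
    if (is.null(lam)) {
      cv <- glmnet::cv.glmnet(Xf, y, alpha = alpha, penalty.factor = pf,
                              intercept = intercept,
                              nfolds = min(hp$nfolds, length(y)))
      lam <- cv$lambda.min
      cv$glmnet.fit
    } else {
      glmnet::glmnet(Xf, y, alpha = alpha, penalty.factor = pf,
                     intercept = intercept)
    }
  })
  co <- as.numeric(stats::coef(fit, s = lam))
  nc <- if (is.null(covariates)) 0L else ncol(covariates)
  u <- co[1L + seq_len(ncol(X))]
  beta <- c(if (intercept) co[1L], if (nc) co[1L + ncol(X) + seq_len(nc)])
  list(route = "marker", beta = beta, u = u, lambda = lam,
       diagnostics = list(converged = TRUE))
}

fit_rkhs <- function(y, X, K, W, hp) {
  if (is.null(W) || ncol(W) == 0L)
    stop("RKHS requires an intercept or covariates", call. = FALSE)
  if (is.null(K)) {
    if (is.null(X)) stop("RKHS needs X or K", call. = FALSE)
    X <- unclass(as.matrix(X))
    D <- sq_dist(X)
    scale <- stats::median(D[upper.tri(D)])
    if (!is.finite(scale) || scale <= 0) scale <- 1
    K <- gauss_kernel(X, X, hp$h, scale)
    kern <- list(X_train = X, scale = scale, h = hp$h)
  } else kern <- NULL
  rm <- reml_kernel(y, K, W)
  g <- rm$phi * drop(K %*% rm$vstar)
  list(route = "kinship", beta = rm$beta, g = g, K_train = K, kern = kern,
       phi = rm$phi, vstar = rm$vstar,
       sigma_g2 = rm$sigma_u2, sigma_e2 = rm$sigma_e2,
       diagnostics = list(loglik = rm$loglik, converged = TRUE))
}

fit_mkrkhs <- function(y, X, K, W, hp) {
  if (is.null(X) && is.null(K))
    stop("MKRKHS needs X (features) or K", call. = FALSE)
  if (is.null(X)) {
    # single supplied kernel: degenerate to RKHS
    return(fit_rkhs(y, NULL, K, W, list(h = 1)))
  }
  X <- unclass(as.matrix(X))
  D <- sq_dist(X)
  scale <- stats::median(D[upper.tri(D)])
  if (!is.finite(scale) || scale <= 0) scale <- 1
  hs <- hp$h_grid
  lls <- numeric(length(hs))
  Ks <- vector("list", length(hs))
  for (i in seq_along(hs)) {
    Ks[[i]] <- exp(-hs[i] * D / scale)
    lls[i] <- reml_kernel(y, Ks[[i]], W)$loglik
  }
  # kernel averaging: weights from the per-bandwidth REML evidence
  wts <- exp(lls - max(lls)); wts <- wts / sum(wts)
  Kbar <- Reduce(`+`, Map(`*`, Ks, wts))
  rm <- reml_kernel(y, Kbar, W)
  g <- rm$phi * drop(Kbar %*% rm$vstar)
  list(route = "kinship", beta = rm$beta, g = g, K_train = Kbar,
       kern = list(X_train = X, scale = scale, h = hs, weights = wts),
       phi = rm$phi, vstar = rm$vstar,
       sigma_g2 = rm$sigma_u2, sigma_e2 = rm$sigma_e2,
       diagnostics = list(loglik = rm$loglik, converged = TRUE,
                          kernel_weights = wts))
}

fit_svm <- function(y, X, covariates, hp) {
  Xf <- cbind(unclass(as.matrix(X)), covariates)
  mod <- with_seed(hp$seed,
    e1071::svm(x = Xf, y = y, type = "eps-regression", kernel = hp$kernel))
  list(route = "ml", beta = numeric(0), model = mod,
       diagnostics = list(converged = TRUE))
}

fit_rf <- function(y, X, covariates, hp) {
  Xf <- cbind(unclass(as.matrix(X)), covariates)
  colnames(Xf) <- paste0("f", seq_len(ncol(Xf)))
  mod <- with_seed(hp$seed,
    randomForest::randomForest(x = Xf, y = y, ntree = hp$ntree))
  list(route = "ml", beta = numeric(0), model = mod, feat_names = colnames(Xf),
       diagnostics = list(converged = TRUE))
}

fit_gbm <- function(y, X, covariates, hp) {
  Xf <- cbind(unclass(as.matrix(X)), covariates)
  mod <- with_seed(hp$seed,
    xgboost::xgboost(x = Xf, y = y, nrounds = hp$nrounds,
                     max_depth = hp$max_depth, learning_rate = hp$eta,
                     objective = "reg:squarederror", nthreads = 1L,
                     verbosity = 0, seed = hp$seed))
  list(route = "ml", beta = numeric(0), model = mod,
       diagnostics = list(converged = TRUE))
}

#' @export
print.gp_fit <- function(x, ...) {
  cat(sprintf("<gp_fit> %s (%s route), N = %d\n",
              x$spec$name, x$route, x$n_train))
  invisible(x)
}

#' Predict from a fitted estimator
#'
#' Marker-form fits take `X_new` (same columns as training X); kinship-form
#' fits take `K_cross` (N' x N against training individuals) or, when the
#' kernel was built from features, `X_new`; delegated learners take `X_new`.
#'
#' @param object a [gp_fit()] result.
#' @param X_new new design/feature matrix.
#' @param K_cross cross-kinship against training rows.
#' @param covariates_new covariates for the new rows (required if the fit
#'   used covariates).
#' @param ... unused.
#' @return numeric vector of predictions.
#' @export
predict.gp_fit <- function(object, X_new = NULL, K_cross = NULL,
                           covariates_new = NULL, ...) {
  f <- object
  if (f$n_covariates > 0L) {
    if (is.null(covariates_new))
      stop("fit used ", f$n_covariates,
           " covariate(s); supply covariates_new", call. = FALSE)
    covariates_new <- as.matrix(covariates_new)
    if (ncol(covariates_new) != f$n_covariates)
      stop("expected ", f$n_covariates, " covariate column(s), got ",
           ncol(covariates_new), call. = FALSE)
  }
  if (f$route == "ml") {
    Xf <- cbind(unclass(as.matrix(X_new)), covariates_new)
    if (!is.null(f$feat_names)) colnames(Xf) <- f$feat_names
    return(as.numeric(stats::predict(f$model, Xf)))
  }
  if (f$route == "marker") {
    if (is.null(X_new)) stop("marker-form fit needs X_new", call. = FALSE)
    X_new <- unclass(as.matrix(X_new))
    if (ncol(X_new) != length(f$u))
      stop("X_new has ", ncol(X_new), " columns; training had ",
           length(f$u), call. = FALSE)
    nprime <- nrow(X_new)
    W_new <- cbind(if (f$intercept) matrix(1, nprime, 1), covariates_new)
    fixed <- if (length(f$beta)) drop(W_new %*% f$beta) else 0
    return(as.numeric(fixed + X_new %*% f$u))
  }
  # kinship route
  if (is.null(K_cross)) {
    if (!is.null(f$kern) && !is.null(X_new)) {
      X_new <- unclass(as.matrix(X_new))
      if (length(f$kern$h) > 1L) {
        Ks <- lapply(f$kern$h, function(h)
          gauss_kernel(X_new, f$kern$X_train, h, f$kern$scale))
        K_cross <- Reduce(`+`, Map(`*`, Ks, f$kern$weights))
      } else {
        K_cross <- gauss_kernel(X_new, f$kern$X_train, f$kern$h, f$kern$scale)
      }
    } else if (!is.null(f$X_train) && !is.null(X_new)) {
      K_cross <- unclass(as.matrix(X_new)) %*% t(f$X_train)
    } else {
      stop("kinship-form fit needs K_cross (or X_new when fitted from features)",
           call. = FALSE)
    }
  }
  K_cross <- as.matrix(K_cross)
  if (ncol(K_cross) != f$n_train)
    stop("K_cross has ", ncol(K_cross), " columns; training N is ",
         f$n_train, call. = FALSE)
  nprime <- nrow(K_cross)
  W_new <- cbind(if (f$intercept) matrix(1, nprime, 1), covariates_new)
  fixed <- if (length(f$beta)) drop(W_new %*% f$beta) else 0
  as.numeric(fixed + f$phi * (K_cross %*% f$vstar))
}
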