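## Single-site Gibbs samplers for the Bayesian whole-genome regressions.
## Shared state: y = W b + X u + e with flat prior on b, scaled-inverse-
## chi-square prior on sigma_e^2, and marker-effect priors per estimator:
##   BRR    u_k ~ N(0, s_u^2), common s_u^2 ~ scaled-inv-chi2
##   BayesA u_k ~ N(0, s_k^2), per-marker s_k^2 ~ scaled-inv-chi2
##   BayesB u_k = 0 with prob pi, else N(0, s_k^2) (per-marker variance)
##   BayesC u_k = 0 with prob pi, else N(0, s_u^2) (common variance)
##   BL     u_k ~ N(0, s_e^2 tau_k^2), 1/tau_k^2 ~ inverse-Gaussian,
##          lambda^2 ~ Gamma (Park-Casella hierarchy)
## Hyper-scales follow the usual R2-based elicitation: the prior mode of the
## marker-effect variance accounts for a fraction R2 of var(y) spread over
## the realized marker sum of squares.

rscinvchisq <- function(df, scale) df * scale / stats::rchisq(1L, df)

rinvgauss1 <- function(mu, lambda) {
  # Michael, Schucany & Haas
  nu <- stats::rnorm(1L)
  z2 <- nu * nu
  x <- mu + (mu * mu * z2) / (2 * lambda) -
    (mu / (2 * lambda)) * sqrt(4 * mu * lambda * z2 + mu * mu * z2 * z2)
  if (x <= 0) return(mu * mu / max(x, .Machine$double.xmin))
  if (stats::runif(1L) <= mu / (mu + x)) x else mu * mu / x
}

fit_bayes <- function(prior, y, X, W, hp) {
  if (is.null(X)) stop(prior, " needs a marker matrix X", call. = FALSE)
  X <- unclass(as.matrix(X))
  n <- length(y); p <- ncol(X)
  if (is.null(W)) W <- matrix(0, n, 0)
  q <- ncol(W)
  niter <- as.integer(hp$niter); burnin <- as.integer(hp$burnin)
  thin <- as.integer(hp$thin)
  df0 <- hp$df0; R2 <- hp$R2
  pi0 <- if (!is.null(hp$pi)) hp$pi else 0
  fixed_vu <- hp$var_u; fixed_ve <- hp$var_e   # NULL unless pinned
  keep_chain <- isTRUE(hp$keep_chain)

  vy <- stats::var(y); if (!is.finite(vy) || vy <= 0) vy <- 1e-8
  msx <- sum(apply(X, 2L, stats::var))
  if (msx <= 0) msx <- sum(colMeans(X^2)) + 1e-8
  S0e <- vy * (1 - R2) * (df0 + 2)
  incl_frac <- if (prior %in% c("BayesB", "BayesC")) max(1 - pi0, 1e-3) else 1
  S0u <- vy * R2 / (msx * incl_frac) * (df0 + 2)

  xtx <- colSums(X^2)
  wtw <- if (q) colSums(W^2) else numeric(0)

  with_seed(hp$seed, {
    b <- if (q) drop(stats::lm.fit(W, y)$coefficients) else numeric(0)
    b[is.na(b)] <- 0
    u <- numeric(p)
    delta <- rep(TRUE, p)                       # inclusion (BayesB/C)
    s_e <- if (!is.null(fixed_ve)) fixed_ve else max(vy * (1 - R2), 1e-8)
    s_u <- if (!is.null(fixed_vu)) fixed_vu else S0u / (df0 + 2)
    s_k <- rep(s_u, p)                          # per-marker variances
    tau2 <- rep(1, p); lam2 <- 2 * p / max(sum(1 / s_k), 1e-8)  # BL
    e <- y - (if (q) drop(W %*% b) else 0)

    nsamp <- 0L
    u_sum <- numeric(p); b_sum <- numeric(max(q, 1L))
    se_sum <- su_sum <- 0
    chain <- if (keep_chain)
      matrix(NA_real_, (niter - burnin) %/% thin + 1L, p + 2L) else NULL
    crow <- 0L

    for (it in seq_len(niter)) {
      # fixed effects, flat prior, coordinate-wise
      for (j in seq_len(q)) {
        e <- e + W[, j] * b[j]
        rhs <- sum(W[, j] * e)
        b[j] <- stats::rnorm(1L, rhs / wtw[j], sqrt(s_e / wtw[j]))
        e <- e - W[, j] * b[j]
      }
      # marker effects
      if (prior %in% c("BRR", "BayesA", "BL")) {
        for (k in seq_len(p)) {
          vk <- switch(prior, BRR = s_u, BayesA = s_k[k], BL = tau2[k] * s_e)
          e <- e + X[, k] * u[k]
          rhs <- sum(X[, k] * e)
          Ck <- xtx[k] + s_e / vk
          u[k] <- stats::rnorm(1L, rhs / Ck, sqrt(s_e / Ck))
          e <- e - X[, k] * u[k]
        }
      } else {  # BayesB / BayesC spike-and-slab
        for (k in seq_len(p)) {
          vk <- if (prior == "BayesB") s_k[k] else s_u
          e <- e + X[, k] * u[k]
          z <- sum(X[, k] * e)
          v0 <- s_e * xtx[k]
          v1 <- v0 + xtx[k]^2 * vk
          logodds <- log(1 - pi0) - log(pi0) +
            0.5 * (log(v0) - log(v1)) + 0.5 * z * z * (1 / v0 - 1 / v1)
          pin <- if (pi0 <= 0) 1 else 1 / (1 + exp(-logodds))
          if (stats::runif(1L) < pin) {
            delta[k] <- TRUE
            Ck <- xtx[k] + s_e / vk
            u[k] <- stats::rnorm(1L, z / Ck, sqrt(s_e / Ck))
          } else {
            delta[k] <- FALSE
            u[k] <- 0
          }
          e <- e - X[, k] * u[k]
        }
      }
      if (!all(is.finite(u)) || !all(is.finite(e)))
        stop("sampler diverged (non-finite state) at iteration ", it,
             call. = FALSE)
      # variance updates (skipped when pinned)
      if (is.null(fixed_vu)) {
        if (prior == "BRR") {
          s_u <- rscinvchisq(df0 + p, (sum(u^2) + S0u) / (df0 + p))
        } else if (prior %in% c("BayesA", "BayesB")) {
          for (k in seq_len(p))
            s_k[k] <- rscinvchisq(df0 + 1, (u[k]^2 + S0u) / (df0 + 1))
        } else if (prior == "BayesC") {
          m <- sum(delta)
          s_u <- rscinvchisq(df0 + m, (sum(u[delta]^2) + S0u) / (df0 + m))
        } else if (prior == "BL") {
          for (k in seq_len(p)) {
            if (abs(u[k]) < 1e-10) {
              tau2[k] <- stats::rexp(1L, lam2 / 2)
            } else {
              itau <- rinvgauss1(sqrt(lam2 * s_e / u[k]^2), lam2)
              tau2[k] <- 1 / itau
            }
          }
          lam2 <- stats::rgamma(1L, shape = p + 1,
                                rate = 1e-4 + sum(tau2) / 2)
        }
      }
      if (is.null(fixed_ve)) {
        ss <- if (prior == "BL") sum(u^2 / pmax(tau2, 1e-12)) else 0
        s_e <- rscinvchisq(df0 + n + (if (prior == "BL") p else 0),
                           (sum(e^2) + ss + S0e) / (df0 + n +
                              (if (prior == "BL") p else 0)))
      }
      if (it > burnin && (it - burnin) %% thin == 0L) {
        nsamp <- nsamp + 1L
        u_sum <- u_sum + u
        if (q) b_sum[seq_len(q)] <- b_sum[seq_len(q)] + b
        se_sum <- se_sum + s_e
        su_sum <- su_sum + (if (prior %in% c("BayesA", "BayesB"))
          mean(s_k) else if (prior == "BL") s_e * mean(tau2) else s_u)
        if (keep_chain) {
          crow <- crow + 1L
          chain[crow, ] <- c(u, s_e,
                             if (prior %in% c("BayesA", "BayesB"))
                               mean(s_k) else s_u)
        }
      }
    }
    if (nsamp == 0L) stop("no posterior samples retained; increase niter",
                          call. = FALSE)
    list(route = "marker",
         beta = if (q) b_sum[seq_len(q)] / nsamp else numeric(0),
         u = u_sum / nsamp,
         sigma_u2 = su_sum / nsamp, sigma_e2 = se_sum / nsamp,
         diagnostics = list(converged = TRUE, n_samples = nsamp,
                            chain = if (keep_chain)
                              chain[seq_len(crow), , drop = FALSE]))
  })
}
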