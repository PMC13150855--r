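## Seeded synthetic multi-environment trial generator. The phenotype model
## mirrors the PEI generative structure:
##   y_ijr = mu + beta x_j + sum_k m_ik (a_k + b_k x_j) + eps_ijr
## with x_j the centred window-mean of one "causal" weather factor, sparse
## main (a) and interaction (b) marker effects, and residual noise
## calibrated so that the entry-mean heritability
## H = Vg / (Vg + Vge/L + Ve/(R L)) hits a target. The generated weather
## series are smooth seasonal curves with environment-level offsets
## (guaranteeing between-environment index variance) plus daily noise.

#' Simulation configuration
#'
#' @param n genotypes.
#' @param p markers.
#' @param m environments.
#' @param days monitored days per environment.
#' @param maf_range uniform range for per-marker allele frequencies
#'   (must exclude 0 and 1).
#' @param factors named list of factor settings; each a list with `base`,
#'   `amplitude`, `period`, `env_sd` (sd of environment offsets) and
#'   `noise_sd` (daily noise). Defaults emulate daily max/min temperature.
#' @param causal_factor factor driving the phenotype.
#' @param causal_window inclusive (start, end) day window of the true index.
#' @param n_qtl_main,n_qtl_inter numbers of markers with non-zero main /
#'   interaction effects.
#' @param sd_main,sd_inter effect-size standard deviations for a_k, b_k.
#' @param mu grand mean; `beta` fixed index coefficient.
#' @param h2 target entry-mean heritability (ignored if `Ve` is given).
#' @param Ve residual variance override; `Ve = 0` gives noiseless data.
#' @param R replicates per genotype x environment cell.
#' @param seed integer seed.
#' @return list of class `"sim_config"`.
#' @export
sim_config <- function(n = 200L, p = 100L, m = 4L, days = 60L,
                       maf_range = c(0.1, 0.5),
                       factors = list(
                         DHT = list(base = 28, amplitude = 4, period = 60,
                                    env_sd = 2.5, noise_sd = 0.8),
                         DLT = list(base = 16, amplitude = 3, period = 60,
                                    env_sd = 1.5, noise_sd = 0.8)),
                       causal_factor = "DHT",
                       causal_window = c(21L, 35L),
                       n_qtl_main = 20L, n_qtl_inter = 10L,
                       sd_main = 0.3, sd_inter = 0.1,
                       mu = 10, beta = 0.5, h2 = 0.5, Ve = NULL,
                       R = 1L, seed = 1L) {
  if (maf_range[1] <= 0 || maf_range[2] >= 1 || maf_range[1] > maf_range[2])
    stop("maf_range must satisfy 0 < low <= high < 1", call. = FALSE)
  if (causal_window[1] < 1L || causal_window[2] > days ||
      causal_window[1] > causal_window[2])
    stop("causal_window must lie within 1..days", call. = FALSE)
  if (!causal_factor %in% names(factors))
    stop("causal_factor not among factors", call. = FALSE)
  if (is.null(Ve) && (h2 <= 0 || h2 > 1))
    stop("h2 must be in (0, 1]", call. = FALSE)
  structure(list(n = as.integer(n), p = as.integer(p), m = as.integer(m),
                 days = as.integer(days), maf_range = maf_range,
                 factors = factors, causal_factor = causal_factor,
                 causal_window = as.integer(causal_window),
                 n_qtl_main = as.integer(n_qtl_main),
                 n_qtl_inter = as.integer(n_qtl_inter),
                 sd_main = sd_main, sd_inter = sd_inter,
                 mu = mu, beta = beta, h2 = h2, Ve = Ve,
                 R = as.integer(R), seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate biallelic genotype dosages
#'
#' Dosages are Binomial(2, p_k) draws, independent across markers, with
#' allele frequencies uniform in `maf_range`.
#'
#' @param cfg a [sim_config()].
#' @return a [geno_matrix()].
#' @export
sim_genotypes <- function(cfg) {
  with_seed(sub_seed(cfg$seed, 11L), {
    freq <- stats::runif(cfg$p, cfg$maf_range[1], cfg$maf_range[2])
    M <- vapply(freq, function(f) stats::rbinom(cfg$n, 2L, f),
                numeric(cfg$n))
    geno_matrix(M, sample_ids = sprintf("G%04d", seq_len(cfg$n)),
                marker_ids = sprintf("M%04d", seq_len(cfg$p)))
  })
}

#' Simulate daily environmental series
#'
#' Per environment and factor: base + seasonal sinusoid + environment
#' offset (N(0, env_sd)) + daily noise (N(0, noise_sd)). Non-zero offsets
#' guarantee between-environment variance of any window mean.
#'
#' @param cfg a [sim_config()].
#' @return harmonized env series data.frame.
#' @export
sim_environments <- function(cfg) {
  with_seed(sub_seed(cfg$seed, 13L), {
    envs <- sprintf("E%02d", seq_len(cfg$m))
    day <- seq_len(cfg$days)
    rows <- list()
    for (f in names(cfg$factors)) {
      fc <- cfg$factors[[f]]
      # random offset directions, rescaled so the between-environment sd
      # is exactly env_sd: the index spread is a controlled condition of
      # the simulated trial, not a lottery over seeds
      offs <- stats::rnorm(cfg$m)
      if (cfg$m > 1L && stats::sd(offs) > 0 && fc$env_sd > 0) {
        offs <- (offs - mean(offs)) / stats::sd(offs) * fc$env_sd
      } else {
        offs <- rep(0, cfg$m)
      }
      for (j in seq_len(cfg$m)) {
        v <- fc$base + fc$amplitude * sin(2 * pi * day / fc$period) +
          offs[j] + stats::rnorm(cfg$days, 0, fc$noise_sd)
        rows[[length(rows) + 1L]] <- data.frame(
          environment = envs[j], day = day, factor = f, value = v,
          stringsAsFactors = FALSE)
      }
    }
    env_series(do.call(rbind, rows))
  })
}

#' Simulate multi-environment phenotypes with known ground truth
#'
#' Computes the true index (window mean of the causal factor, centred),
#' draws sparse main and interaction marker effects, builds the genetic
#' surface, and calibrates the residual variance so the realized
#' entry-mean heritability matches `cfg$h2` (unless `cfg$Ve` pins it).
#' Calibration is empirical — Vg and Vge are taken from the realized
#' genetic values, since sparse-effect variances depend on realized dosage
#' frequencies.
#'
#' @param geno genotype matrix from [sim_genotypes()].
#' @param series env series from [sim_environments()].
#' @param cfg a [sim_config()].
#' @return list: `pheno` (phenotype table; a `rep` column when R > 1) and
#'   `truth` (effects `a`, `b`, index, x, variance components, and the
#'   noiseless genetic surface).
#' @export
sim_phenotypes <- function(geno, series, cfg) {
  M <- unclass(as.matrix(geno))
  envs <- sort(unique(series$environment))
  e_raw <- window_mean(series, cfg$causal_factor, cfg$causal_window)[envs]
  x <- e_raw - mean(e_raw)
  with_seed(sub_seed(cfg$seed, 17L), {
    a <- numeric(cfg$p); b <- numeric(cfg$p)
    qa <- sample.int(cfg$p, cfg$n_qtl_main)
    a[qa] <- stats::rnorm(cfg$n_qtl_main, 0, cfg$sd_main)
    if (cfg$n_qtl_inter > 0L) {
      qb <- sample.int(cfg$p, cfg$n_qtl_inter)
      b[qb] <- stats::rnorm(cfg$n_qtl_inter, 0, cfg$sd_inter)
    }
    # scale the drawn effects so the realized genetic variances equal
    # their nominal values (n_qtl * sd^2 * mean marker variance): the
    # draws set which markers matter and in which direction, while the
    # variance budget of the trial stays an exact design condition
    vbar <- mean(apply(M, 2L, stats::var))
    rescale <- function(eff, target) {
      gv <- stats::var(drop(M %*% eff))
      if (gv > 0 && target > 0) eff * sqrt(target / gv) else eff
    }
    a <- rescale(a, cfg$n_qtl_main * cfg$sd_main^2 * vbar)
    if (cfg$n_qtl_inter > 0L)
      b <- rescale(b, cfg$n_qtl_inter * cfg$sd_inter^2 * vbar)
    ga <- drop(M %*% a)          # genotype main values
    gb <- drop(M %*% b)          # genotype index sensitivities
    surf <- outer(ga, rep(1, cfg$m)) + outer(gb, as.numeric(x))
    colnames(surf) <- envs; rownames(surf) <- rownames(M)
    ra <- rowMeans(surf); ca <- colMeans(surf); gm <- mean(surf)
    Vg <- stats::var(ra)
    # double-centred interaction deviations, on the ANOVA mean-square scale
    dev <- surf - outer(ra, rep(1, cfg$m)) -
      outer(rep(1, cfg$n), ca) + gm
    Vge <- sum(dev^2) / ((cfg$n - 1L) * (cfg$m - 1L))
    if (!is.null(cfg$Ve)) {
      Ve <- cfg$Ve
    } else {
      if (Vg <= 0)
        stop("no genetic variance realized; cannot calibrate h2", call. = FALSE)
      Ve <- cfg$R * cfg$m * Vg * (1 - cfg$h2) / cfg$h2 - cfg$R * Vge
      if (Ve < 0)
        stop("target h2 = ", cfg$h2, " unattainable: interaction variance ",
             "alone exceeds the implied non-genetic budget; lower h2 or ",
             "n_qtl_inter", call. = FALSE)
    }
    reps <- seq_len(cfg$R)
    grid <- expand.grid(genotype = rownames(M), environment = envs,
                        rep = reps, stringsAsFactors = FALSE)
    gi <- match(grid$genotype, rownames(M))
    ej <- match(grid$environment, envs)
    noise <- if (Ve > 0) stats::rnorm(nrow(grid), 0, sqrt(Ve)) else 0
    grid$trait <- "trait"
    grid$value <- cfg$mu + cfg$beta * as.numeric(x)[ej] +
      surf[cbind(gi, ej)] + noise
    pheno <- grid[, c("genotype", "environment", "trait",
                      if (cfg$R > 1L) "rep", "value")]
    truth <- list(a = a, b = b, raw_index = e_raw, x = x,
                  mu = cfg$mu, beta = cfg$beta,
                  Vg = Vg, Vge = Vge, Ve = Ve,
                  surface = surf, residuals = as.numeric(noise) * rep(1, nrow(grid)),
                  causal_factor = cfg$causal_factor,
                  causal_window = cfg$causal_window)
    list(pheno = pheno_table(pheno), truth = truth)
  })
}

#' Simulate a complete MET dataset
#'
#' @param cfg a [sim_config()].
#' @return list with `geno`, `series`, `pheno`, `truth`, `cfg`.
#' @export
sim_met <- function(cfg = sim_config()) {
  geno <- sim_genotypes(cfg)
  series <- sim_environments(cfg)
  ph <- sim_phenotypes(geno, series, cfg)
  list(geno = geno, series = series, pheno = ph$pheno, truth = ph$truth,
       cfg = cfg)
}
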