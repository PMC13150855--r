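#' Prediction accuracy (Pearson correlation)
#'
#' Sample Pearson correlation over complete (predicted, observed) pairs.
#' Returns NA with a warning when fewer than 3 pairs remain or either side
#' has zero variance (the correlation is undefined there, not zero).
#'
#' @param pred,obs numeric vectors of equal length.
#' @return scalar correlation in [-1, 1], or NA.
#' @export
accuracy <- function(pred, obs) {
  ok <- is.finite(pred) & is.finite(obs)
  if (sum(ok) < 3L) {
    warning("fewer than 3 complete pairs; accuracy undefined", call. = FALSE)
    return(NA_real_)
  }
  if (stats::sd(pred[ok]) < 1e-12 || stats::sd(obs[ok]) < 1e-12) {
    warning("zero variance in predictions or observations; accuracy undefined",
            call. = FALSE)
    return(NA_real_)
  }
  stats::cor(pred[ok], obs[ok])
}

## deterministic sub-seed per (replicate, fold); exact in doubles and
## kept below 2^31 so set.seed() accepts it
sub_seed <- function(seed, a, b = 0L) {
  as.integer((as.numeric(seed) * 7919 + as.numeric(a) * 104729 +
                as.numeric(b) * 1299709) %% 2147483647)
}

#' Cross-validation scenario (i): untested genotypes in tested environments
#'
#' Per replicate, genotypes are partitioned into k folds (k = 2 is the
#' half-split variant). Per fold the environmental index is re-searched on
#' the training genotypes only (their environment means), the framework is
#' fitted on training genotypes, and held-out genotypes are predicted in
#' every environment. Accuracy is the per-environment Pearson correlation;
#' per-environment means average over replicates and folds, and the overall
#' figure is the unweighted mean over environments.
#'
#' @param geno genotype matrix.
#' @param pheno phenotype table.
#' @param series harmonized env series.
#' @param framework `"RN"` or `"PEI"`.
#' @param spec estimator spec or name.
#' @param trait trait name (default: single trait present).
#' @param k folds per replicate (default 10).
#' @param reps replicates (default 5).
#' @param seed integer seed; all fold randomness derives from it.
#' @param min_width,step index-search grid (see [search_index()]).
#' @param ... passed to the framework fit ([fit_predict_pei()] extras).
#' @return object of class `"cv_result"`: `folds` (one row per
#'   environment/replicate/fold), `by_environment` (mean and pooled
#'   accuracy), `overall` (mean over environments), `scheme` metadata.
#' @export
cv_untested_genotypes <- function(geno, pheno, series,
                                  framework = c("PEI", "RN"), spec,
                                  trait = NULL, k = 10L, reps = 5L,
                                  seed = 1L, min_width = 7L, step = 1L,
                                  ...) {
  framework <- match.arg(framework)
  if (is.character(spec)) spec <- estimator_spec(spec)
  pheno <- pheno_table(pheno)
  if (is.null(trait)) {
    tr <- unique(pheno$trait)
    if (length(tr) != 1L) stop("multiple traits; specify `trait`", call. = FALSE)
    trait <- tr
  }
  genos <- intersect(rownames(geno), unique(pheno$genotype))
  if (length(genos) < 2L * k)
    stop("too few genotypes (", length(genos), ") for k = ", k, call. = FALSE)
  envs <- sort(unique(pheno$environment[pheno$trait == trait &
                                          !is.na(pheno$value)]))
  if (framework == "RN" && length(envs) < 3L)
    stop("the reaction-norm framework requires a minimum of three ",
         "environments", call. = FALSE)
  rows <- list()
  pool <- list()
  for (r in seq_len(reps)) {
    fold_id <- with_seed(sub_seed(seed, r), {
      sample(rep_len(seq_len(k), length(genos)))
    })
    for (f in seq_len(k)) {
      test_ids <- genos[fold_id == f]
      train_ids <- genos[fold_id != f]
      em <- env_means(pheno, trait, genotype_subset = train_ids,
                      environments = envs)
      idx <- search_index(series, em, min_width = min_width,
                          step = step)$best
      pr <- run_framework(framework, geno, pheno, idx, spec, trait,
                          train_ids, test_ids, envs, ...)
      obs <- pheno[pheno$trait == trait & pheno$genotype %in% test_ids &
                     !is.na(pheno$value), , drop = FALSE]
      m <- merge(pr, obs[, c("genotype", "environment", "value")],
                 by = c("genotype", "environment"))
      for (e in envs) {
        me <- m[m$environment == e, , drop = FALSE]
        acc <- if (nrow(me) < 2L) NA_real_ else
          suppressWarnings(accuracy(me$predicted, me$value))
        rows[[length(rows) + 1L]] <- data.frame(
          environment = e, replicate = r, fold = f, accuracy = acc,
          n_test = nrow(me), stringsAsFactors = FALSE)
      }
      pool[[length(pool) + 1L]] <- m
    }
  }
  finish_cv(do.call(rbind, rows), do.call(rbind, pool), envs,
            list(scheme = "untested_genotypes", framework = framework,
                 estimator = spec$name, k = k, reps = reps, seed = seed))
}

run_framework <- function(framework, geno, pheno, idx, spec, trait,
                          train_ids, test_ids, envs, ...) {
  if (framework == "RN") {
    tr_ph <- pheno[pheno$genotype %in% train_ids, , drop = FALSE]
    params <- suppressWarnings(fit_rn(tr_ph, idx, trait))
    usable <- intersect(train_ids, params$genotype)
    rp <- predict_rn_traits(params, geno, usable, test_ids, spec)
    out <- reconstruct_rn(rp, idx, envs, trait)
    out$predicted <- out$value
    out[, c("genotype", "environment", "predicted")]
  } else {
    tc <- expand.grid(genotype = test_ids, environment = envs,
                      stringsAsFactors = FALSE)
    fit_predict_pei(pheno, geno, idx, spec, tc, trait = trait, ...)
  }
}

finish_cv <- function(folds, pooled, envs, scheme) {
  by_env <- do.call(rbind, lapply(envs, function(e) {
    fe <- folds[folds$environment == e, , drop = FALSE]
    pe <- pooled[pooled$environment == e, , drop = FALSE]
    data.frame(environment = e,
               mean_accuracy = mean(fe$accuracy, na.rm = TRUE),
               pooled_accuracy = if (nrow(pe) >= 3L)
                 suppressWarnings(accuracy(pe$predicted, pe$value))
               else NA_real_,
               n_folds = sum(!is.na(fe$accuracy)),
               stringsAsFactors = FALSE)
  }))
  structure(list(folds = folds, by_environment = by_env,
                 overall = mean(by_env$mean_accuracy, na.rm = TRUE),
                 scheme = scheme),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  s <- x$scheme
  cat(sprintf("<cv_result> %s | %s + %s | overall accuracy %.4f\n",
              s$scheme, s$framework, s$estimator, x$overall))
  print(x$by_environment, row.names = FALSE)
  invisible(x)
}

#' Cross-validation scenario (ii): novel environments
#'
#' Leave-one-environment-out: each environment is masked in turn, the index
#' is re-searched on the remaining environments, the framework is fitted
#' without the held-out environment, and all its genotypes are predicted
#' using the held-out environment's own index value (computed from its
#' weather series and centred with the training centre). For the RN
#' framework the per-genotype lines fitted on the training environments are
#' extrapolated directly; it needs at least three training environments per
#' genotype.
#'
#' @inheritParams cv_untested_genotypes
#' @return a `"cv_result"` with one fold per held-out environment.
#' @export
cv_novel_environment <- function(geno, pheno, series,
                                 framework = c("PEI", "RN"), spec,
                                 trait = NULL, seed = 1L, min_width = 7L,
                                 step = 1L, ...) {
  framework <- match.arg(framework)
  if (is.character(spec)) spec <- estimator_spec(spec)
  pheno <- pheno_table(pheno)
  if (is.null(trait)) {
    tr <- unique(pheno$trait)
    if (length(tr) != 1L) stop("multiple traits; specify `trait`", call. = FALSE)
    trait <- tr
  }
  envs <- sort(unique(pheno$environment[pheno$trait == trait &
                                          !is.na(pheno$value)]))
  m <- length(envs)
  if (framework == "RN" && m < 3L)
    stop("the reaction-norm framework requires a minimum of three ",
         "environments", call. = FALSE)
  if (framework == "PEI" && m < 2L)
    stop("need at least 2 environments", call. = FALSE)
  rows <- list(); pool <- list()
  for (h in envs) {
    train_envs <- setdiff(envs, h)
    em <- env_means(pheno, trait, environments = train_envs)
    idx <- search_index(series[series$environment %in% train_envs, ,
                               drop = FALSE],
                        em, min_width = min_width, step = step)$best
    idx <- index_environment(idx, series, h)
    obs_h <- pheno[pheno$trait == trait & pheno$environment == h &
                     !is.na(pheno$value), , drop = FALSE]
    if (framework == "RN") {
      tr_ph <- pheno[pheno$environment %in% train_envs, , drop = FALSE]
      params <- suppressWarnings(fit_rn(tr_ph, idx, trait))
      rp <- params[, c("genotype", "slope", "intercept")]
      pr <- reconstruct_rn(rp, idx, h, trait)
      pr$predicted <- pr$value
      pr <- pr[, c("genotype", "environment", "predicted")]
    } else {
      tc <- obs_h[, c("genotype", "environment")]
      masked <- pheno
      pr <- fit_predict_pei(masked, geno, idx, spec, tc, trait = trait, ...)
    }
    mg <- merge(pr, obs_h[, c("genotype", "environment", "value")],
                by = c("genotype", "environment"))
    acc <- if (nrow(mg) < 3L) NA_real_ else
      suppressWarnings(accuracy(mg$predicted, mg$value))
    rows[[length(rows) + 1L]] <- data.frame(
      environment = h, replicate = 1L, fold = match(h, envs),
      accuracy = acc, n_test = nrow(mg), stringsAsFactors = FALSE)
    pool[[length(pool) + 1L]] <- mg
  }
  finish_cv(do.call(rbind, rows), do.call(rbind, pool), envs,
            list(scheme = "novel_environment", framework = framework,
                 estimator = spec$name, k = m, reps = 1L, seed = seed))
}

#' Variance components of a balanced two-way MET design
#'
#' Expected-mean-squares method of moments on the genotype x environment
#' table with R replicates per cell: Vg = (MS_G - MS_GxE) / (R L),
#' Vge = (MS_GxE - MS_error) / R, Ve = MS_error. With a single replicate
#' the interaction and residual variances are confounded; the interaction
#' mean square is then reported as Ve with Vge = 0 and a warning. Negative
#' moment estimates are truncated at zero.
#'
#' @param pheno phenotype table with a `rep` column (or R = 1 without).
#' @param trait trait name (default: single trait present).
#' @return a [variance_components()] object.
#' @export
estimate_components <- function(pheno, trait = NULL) {
  pheno <- pheno_table(pheno)
  if (is.null(trait)) {
    tr <- unique(pheno$trait)
    if (length(tr) != 1L) stop("multiple traits; specify `trait`", call. = FALSE)
    trait <- tr
  }
  d <- pheno[pheno$trait == trait & !is.na(pheno$value), , drop = FALSE]
  tab <- table(d$genotype, d$environment)
  if (length(unique(as.vector(tab))) != 1L || any(tab == 0L))
    stop("unbalanced design: every genotype x environment cell must have ",
         "the same number of replicates; balance the data or supply ",
         "externally estimated components", call. = FALSE)
  R <- as.integer(tab[1L]); L <- ncol(tab); n_g <- nrow(tab)
  if (n_g < 2L || L < 2L)
    stop("need >= 2 genotypes and >= 2 environments", call. = FALSE)
  G <- factor(d$genotype); E <- factor(d$environment)
  if (R >= 2L) {
    a <- stats::anova(stats::lm(d$value ~ G * E))
    ms <- a$`Mean Sq`; names(ms) <- rownames(a)
    MSg <- ms[["G"]]; MSge <- ms[["G:E"]]; MSe <- ms[["Residuals"]]
    Ve <- MSe
    Vge <- (MSge - MSe) / R
    Vg <- (MSg - MSge) / (R * L)
  } else {
    a <- stats::anova(stats::lm(d$value ~ G + E))
    ms <- a$`Mean Sq`; names(ms) <- rownames(a)
    MSg <- ms[["G"]]; MSres <- ms[["Residuals"]]
    warning("single replicate: interaction and residual variances are ",
            "confounded; reporting the interaction mean square as Ve with ",
            "Vge = 0", call. = FALSE)
    Ve <- MSres; Vge <- 0
    Vg <- (MSg - MSres) / L
  }
  clamp <- function(v, lab) {
    if (v < 0) {
      warning(lab, " moment estimate negative (", format(v, digits = 3),
              "); truncated at 0", call. = FALSE)
      0
    } else v
  }
  variance_components(clamp(Vg, "Vg"), clamp(Vge, "Vge"), clamp(Ve, "Ve"),
                      L = L, R = R)
}

#' Broad-sense heritability on an entry-mean basis
#'
#' H = Vg / (Vg + Vge / L + Ve / (R L)) for a trial with L environments and
#' R replicates per environment.
#'
#' @param vc a [variance_components()] object.
#' @return scalar H in [0, 1].
#' @export
heritability <- function(vc) {
  stopifnot(inherits(vc, "variance_components"))
  den <- vc$Vg + vc$Vge / vc$L + vc$Ve / (vc$R * vc$L)
  if (den <= 0)
    stop("all variance components are zero; heritability undefined",
         call. = FALSE)
  vc$Vg / den
}

#' Problem "dimension" for resource guidance
#'
#' The order of magnitude (base 10) of population size times marker count:
#' floor(log10(n_lines * n_markers)). At dimension 8 and above the
#' whole-genome samplers and kernel methods become expensive for little
#' accuracy gain, so a guidance warning suggests considering lighter
#' estimators.
#'
#' @param n_lines number of individuals (>= 1).
#' @param n_markers number of markers (>= 1).
#' @param warn emit the guidance warning at dimension >= 8 (default TRUE).
#' @return integer dimension.
#' @export
gp_dimension <- function(n_lines, n_markers, warn = TRUE) {
  stopifnot(n_lines >= 1, n_markers >= 1)
  d <- as.integer(floor(log10(as.numeric(n_lines) * as.numeric(n_markers))))
  if (warn && d >= 8L)
    warning("problem dimension ", d, " (>= 8): consider lighter estimators ",
            "(e.g. GBM, SVM) or marker pruning", call. = FALSE)
  d
}
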