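#' Fit per-genotype reaction norms on an environmental index
#'
#' For each genotype i observed in at least three environments, ordinary
#' least squares of its phenotypes on the centred environmental index x_j:
#' y_ij = k_i x_j + b_i + e_ij. The intercept b_i is the expected phenotype
#' at the across-environment index mean (x = 0); the slope k_i is the
#' sensitivity to the index. Genotypes seen in fewer than three environments
#' cannot anchor a line and are excluded with a warning.
#'
#' @param pheno phenotype table.
#' @param index an [env_index()] covering the phenotyped environments.
#' @param trait trait name (default: the single trait present).
#' @return data.frame of class `"rn_params"` with columns `genotype`,
#'   `slope`, `intercept`, `sigma2` (residual variance), `n_envs`; excluded
#'   genotypes in `attr(, "excluded")`.
#' @export
fit_rn <- function(pheno, index, trait = NULL) {
  pheno <- pheno_table(pheno)
  if (is.null(trait)) {
    tr <- unique(pheno$trait)
    if (length(tr) != 1L) stop("multiple traits; specify `trait`", call. = FALSE)
    trait <- tr
  }
  x_map <- index$centred_index
  d <- pheno[pheno$trait == trait & !is.na(pheno$value) &
               pheno$environment %in% names(x_map), , drop = FALSE]
  if (!nrow(d)) stop("no usable phenotype records", call. = FALSE)
  if (stats::sd(x_map[unique(d$environment)]) < 1e-12)
    stop("environmental index is constant across the phenotyped environments;",
         " reaction norms are unidentifiable", call. = FALSE)
  d$x <- as.numeric(x_map[d$environment])
  split_y <- split(d, d$genotype)
  rows <- lapply(split_y, function(g) {
    if (nrow(g) < 3L) return(NULL)
    if (stats::sd(g$x) < 1e-12) return(NULL)  # all obs at one index value
    xb <- mean(g$x); yb <- mean(g$value)
    k <- sum((g$x - xb) * (g$value - yb)) / sum((g$x - xb)^2)
    b <- yb - k * xb
    res <- g$value - (b + k * g$x)
    data.frame(genotype = g$genotype[1L], slope = k, intercept = b,
               sigma2 = if (nrow(g) > 2L) sum(res^2) / (nrow(g) - 2L) else 0,
               n_envs = nrow(g), stringsAsFactors = FALSE)
  })
  keep <- !vapply(rows, is.null, logical(1))
  excluded <- names(split_y)[!keep]
  if (!any(keep))
    stop("every genotype is observed in fewer than 3 environments; ",
         "the reaction-norm framework requires at least three", call. = FALSE)
  if (length(excluded))
    warning(length(excluded), " genotype(s) observed in < 3 environments ",
            "excluded from reaction-norm fitting", call. = FALSE)
  out <- do.call(rbind, rows[keep])
  rownames(out) <- NULL
  attr(out, "excluded") <- excluded
  attr(out, "trait") <- trait
  class(out) <- c("rn_params", class(out))
  out
}

#' Genomic prediction of reaction-norm intercept and slope
#'
#' Treats the fitted intercepts and slopes as two derived traits and runs
#' two independent genomic predictions (same estimator) from training to
#' test genotypes.
#'
#' @param params [fit_rn()] output.
#' @param geno genotype matrix covering train and test genotypes.
#' @param train_ids training genotype IDs (must have fitted params).
#' @param test_ids genotype IDs to predict (disjoint from training).
#' @param spec an [estimator_spec()].
#' @return data.frame `genotype`, `slope`, `intercept` for `test_ids`.
#' @export
predict_rn_traits <- function(params, geno, train_ids, test_ids, spec) {
  if (is.character(spec)) spec <- estimator_spec(spec)
  miss <- setdiff(train_ids, params$genotype)
  if (length(miss))
    stop("training genotype(s) without fitted reaction norms: ",
         paste(utils::head(miss, 5), collapse = ", "), call. = FALSE)
  miss_g <- setdiff(c(train_ids, test_ids), rownames(geno))
  if (length(miss_g))
    stop("genotype(s) absent from the genotype matrix: ",
         paste(utils::head(miss_g, 5), collapse = ", "), call. = FALSE)
  X_tr <- unclass(geno)[train_ids, , drop = FALSE]
  X_te <- unclass(geno)[test_ids, , drop = FALSE]
  pr <- lapply(c(slope = "slope", intercept = "intercept"), function(tr) {
    yv <- params[[tr]][match(train_ids, params$genotype)]
    fit <- tryCatch(gp_fit(spec, yv, X = X_tr),
                    error = function(e)
                      stop("estimator failed for derived trait '", tr, "': ",
                           conditionMessage(e), call. = FALSE))
    predict(fit, X_new = X_te)
  })
  data.frame(genotype = test_ids, slope = pr$slope, intercept = pr$intercept,
             stringsAsFactors = FALSE)
}

#' Reconstruct phenotypes from predicted reaction norms
#'
#' y_hat_ij = intercept_i + slope_i * x_j, with x_j centred against the
#' TRAINING centre carried by `index` — a novel environment whose raw index
#' equals the training centre therefore predicts the intercepts themselves.
#'
#' @param rn_pred data.frame with `genotype`, `slope`, `intercept`.
#' @param index an [env_index()] providing x_j for every requested
#'   environment (extend novel environments with [index_environment()]).
#' @param environments environments to reconstruct.
#' @param trait trait label for the output table.
#' @return phenotype-table-shaped data.frame of predictions.
#' @export
reconstruct_rn <- function(rn_pred, index, environments,
                           trait = "predicted") {
  miss <- setdiff(environments, names(index$centred_index))
  if (length(miss))
    stop("no index value for environment(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  out <- expand.grid(genotype = rn_pred$genotype, environment = environments,
                     stringsAsFactors = FALSE)
  i <- match(out$genotype, rn_pred$genotype)
  out$trait <- trait
  out$value <- rn_pred$intercept[i] +
    rn_pred$slope[i] * as.numeric(index$centred_index[out$environment])
  out
}
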