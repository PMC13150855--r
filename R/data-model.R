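#' Construct and validate an additive genotype matrix
#'
#' Wraps an n x p numeric matrix of additive allele dosages (0, 1, 2) with
#' sample IDs as row names and marker IDs as column names. Missing dosages
#' (NA) are permitted only when `allow_missing = TRUE`; they are expected to
#' be imputed before model fitting.
#'
#' @param dosages numeric matrix, individuals in rows, markers in columns.
#' @param sample_ids character vector of unique sample identifiers. Defaults
#'   to existing row names.
#' @param marker_ids character vector of unique marker identifiers. Defaults
#'   to existing column names.
#' @param allow_missing logical; tolerate NA entries (pre-imputation state).
#' @return the validated matrix with class `"geno_matrix"` prepended.
#' @export
geno_matrix <- function(dosages, sample_ids = rownames(dosages),
                        marker_ids = colnames(dosages),
                        allow_missing = FALSE) {
  dosages <- as.matrix(dosages)
  storage.mode(dosages) <- "double"
  if (is.null(sample_ids)) sample_ids <- paste0("S", seq_len(nrow(dosages)))
  if (is.null(marker_ids)) marker_ids <- paste0("M", seq_len(ncol(dosages)))
  if (length(sample_ids) != nrow(dosages))
    stop("length(sample_ids) != number of rows", call. = FALSE)
  if (length(marker_ids) != ncol(dosages))
    stop("length(marker_ids) != number of columns", call. = FALSE)
  if (anyDuplicated(sample_ids))
    stop("duplicate sample IDs: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(marker_ids))
    stop("duplicate marker IDs: ",
         paste(unique(marker_ids[duplicated(marker_ids)]), collapse = ", "),
         call. = FALSE)
  if (anyNA(dosages) && !allow_missing)
    stop("genotype matrix contains missing dosages; impute or pass allow_missing = TRUE",
         call. = FALSE)
  bad <- which(!is.na(dosages) & !(dosages %in% c(0, 1, 2)))
  if (length(bad)) {
    rc <- arrayInd(bad[1L], dim(dosages))
    stop(sprintf("invalid dosage %s at row %d (%s), column %d (%s): must be 0, 1 or 2",
                 format(dosages[bad[1L]]), rc[1], sample_ids[rc[1]],
                 rc[2], marker_ids[rc[2]]), call. = FALSE)
  }
  dimnames(dosages) <- list(sample_ids, marker_ids)
  class(dosages) <- c("geno_matrix", class(dosages))
  dosages
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat(sprintf("<geno_matrix> %d samples x %d markers", nrow(x), ncol(x)))
  nmiss <- sum(is.na(x))
  if (nmiss) cat(sprintf(" (%d missing)", nmiss))
  cat("\n")
  invisible(x)
}

#' Validate a long-format phenotype table
#'
#' A phenotype table holds one record per (genotype, environment, trait)
#' cell of a multi-environment trial; `value` may be NA to mask an untested
#' cell without dropping the record. An optional `rep` column carries
#' within-environment replicate labels for variance-component estimation.
#'
#' @param x data.frame with columns `genotype`, `environment`, `trait`,
#'   `value` (and optionally `rep`).
#' @return the validated data.frame (character keys, numeric value).
#' @export
pheno_table <- function(x) {
  need <- c("genotype", "environment", "trait", "value")
  miss <- setdiff(need, names(x))
  if (length(miss))
    stop("phenotype table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  x$genotype    <- as.character(x$genotype)
  x$environment <- as.character(x$environment)
  x$trait       <- as.character(x$trait)
  x$value       <- as.numeric(x$value)
  keycols <- c("genotype", "environment", "trait")
  if ("rep" %in% names(x)) keycols <- c(keycols, "rep")
  key <- do.call(paste, c(x[keycols], sep = "\r"))
  if (anyDuplicated(key)) {
    d <- key[duplicated(key)][1L]
    stop("duplicate phenotype record for (",
         gsub("\r", ", ", d, fixed = TRUE), ")", call. = FALSE)
  }
  rownames(x) <- NULL
  x
}

#' Validate a daily environmental-factor series
#'
#' Long-format daily records, one row per (environment, day, factor). Days
#' are 1-based integers over a shared monitored period; harmonization to the
#' common day range and factor set across environments happens in
#' [read_env_series()] / [harmonize_env_series()].
#'
#' @param x data.frame with columns `environment`, `day`, `factor`, `value`.
#' @return validated data.frame.
#' @export
env_series <- function(x) {
  need <- c("environment", "day", "factor", "value")
  miss <- setdiff(need, names(x))
  if (length(miss))
    stop("environment series lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  x$environment <- as.character(x$environment)
  x$day         <- as.integer(x$day)
  x$factor      <- as.character(x$factor)
  x$value       <- as.numeric(x$value)
  if (any(x$day < 1L)) stop("day indices must be >= 1 (1-based)", call. = FALSE)
  key <- paste(x$environment, x$day, x$factor, sep = "\r")
  if (anyDuplicated(key)) {
    d <- strsplit(key[duplicated(key)][1L], "\r", fixed = TRUE)[[1L]]
    stop(sprintf("duplicate series record for environment %s, day %s, factor %s",
                 d[1], d[2], d[3]), call. = FALSE)
  }
  rownames(x) <- NULL
  x
}

#' Restrict an environmental series to days and factors shared by all environments
#'
#' Keeps the intersection of per-environment day ranges and the factors
#' recorded in every environment, so window means are comparable across
#' environments.
#'
#' @param x validated env series data.frame.
#' @return harmonized data.frame; errors if the day ranges do not overlap.
#' @export
harmonize_env_series <- function(x) {
  x <- env_series(x)
  envs <- unique(x$environment)
  lo <- max(vapply(envs, function(e) min(x$day[x$environment == e]), 1L))
  hi <- min(vapply(envs, function(e) max(x$day[x$environment == e]), 1L))
  if (lo > hi)
    stop("environments share no overlapping day range", call. = FALSE)
  fac_by_env <- lapply(envs, function(e) unique(x$factor[x$environment == e]))
  shared <- Reduce(intersect, fac_by_env)
  if (!length(shared))
    stop("environments share no common environmental factor", call. = FALSE)
  dropped <- setdiff(unique(x$factor), shared)
  if (length(dropped))
    warning("dropping factor(s) absent from some environments: ",
            paste(dropped, collapse = ", "), call. = FALSE)
  out <- x[x$day >= lo & x$day <= hi & x$factor %in% shared, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Environmental index object
#'
#' A scalar index per environment: the mean of one environmental factor over
#' one day window, plus its centred form (centred by the across-environment
#' mean, so the centred values sum to zero).
#'
#' @param factor_name factor the index is computed from.
#' @param window integer length-2, inclusive (start_day, end_day).
#' @param raw_index named numeric vector, environment -> window mean.
#' @param r2 coefficient of determination of environment-mean phenotype on
#'   the index (NA if not derived from a search).
#' @param r signed Pearson correlation matching `r2` (NA if unknown).
#' @param centre centring constant; defaults to `mean(raw_index)`. Pass the
#'   training centre when indexing a novel environment.
#' @return an object of class `"env_index"`.
#' @export
env_index <- function(factor_name, window, raw_index, r2 = NA_real_,
                      r = NA_real_, centre = mean(raw_index)) {
  window <- as.integer(window)
  if (length(window) != 2L || window[1] > window[2])
    stop("window must be (start_day, end_day) with start <= end", call. = FALSE)
  if (is.null(names(raw_index)))
    stop("raw_index must be named by environment", call. = FALSE)
  if (!is.na(r2) && (r2 < -1e-12 || r2 > 1 + 1e-12))
    stop("r2 outside [0, 1]", call. = FALSE)
  structure(list(factor_name = factor_name, window = window,
                 raw_index = raw_index, centre = centre,
                 centred_index = raw_index - centre,
                 r2 = r2, r = r),
            class = "env_index")
}

#' @export
print.env_index <- function(x, ...) {
  cat(sprintf("<env_index> factor %s, days %d-%d, %d environments",
              x$factor_name, x$window[1], x$window[2], length(x$raw_index)))
  if (!is.na(x$r2)) cat(sprintf(", R2 = %.4f", x$r2))
  cat("\n")
  invisible(x)
}

#' Variance components of a balanced multi-environment trial
#'
#' @param Vg genetic (genotype main-effect) variance.
#' @param Vge genotype-by-environment interaction variance.
#' @param Ve residual (plot) variance.
#' @param L number of environments.
#' @param R number of replicates per environment.
#' @return list of class `"variance_components"`.
#' @export
variance_components <- function(Vg, Vge, Ve, L, R) {
  if (any(c(Vg, Vge, Ve) < 0)) stop("variances must be >= 0", call. = FALSE)
  if (L < 1 || R < 1) stop("L and R must be >= 1", call. = FALSE)
  structure(list(Vg = Vg, Vge = Vge, Ve = Ve, L = as.integer(L),
                 R = as.integer(R)),
            class = "variance_components")
}
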