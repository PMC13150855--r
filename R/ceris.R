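#' Environment-mean phenotypes
#'
#' Arithmetic mean of non-missing phenotype values per environment,
#' optionally restricted to a genotype subset. During cross-validation the
#' subset is the training genotypes, so the index search never sees
#' held-out phenotypes.
#'
#' @param pheno phenotype table (see [pheno_table()]).
#' @param trait trait name; defaults to the single trait present.
#' @param genotype_subset character vector of genotype IDs, or NULL for all.
#' @param environments restrict to these environments (default: all present).
#' @return named numeric vector, environment -> mean phenotype.
#' @export
env_means <- function(pheno, trait = NULL, genotype_subset = NULL,
                      environments = NULL) {
  pheno <- pheno_table(pheno)
  if (is.null(trait)) {
    tr <- unique(pheno$trait)
    if (length(tr) != 1L)
      stop("multiple traits present; specify `trait`", call. = FALSE)
    trait <- tr
  }
  d <- pheno[pheno$trait == trait, , drop = FALSE]
  # fix the environment set BEFORE subsetting genotypes, so a subset that
  # empties an environment is an error rather than a silent drop
  if (is.null(environments)) environments <- unique(d$environment)
  if (!is.null(genotype_subset))
    d <- d[d$genotype %in% genotype_subset, , drop = FALSE]
  d <- d[d$environment %in% environments & !is.na(d$value), , drop = FALSE]
  out <- vapply(environments, function(e) {
    v <- d$value[d$environment == e]
    if (!length(v))
      stop("no usable phenotype records in environment ", e,
           " (trait ", trait, ")", call. = FALSE)
    mean(v)
  }, numeric(1))
  names(out) <- environments
  out
}

#' Per-environment window mean of an environmental factor
#'
#' @param series harmonized env series.
#' @param factor_name factor to average.
#' @param window inclusive (start_day, end_day).
#' @return named numeric vector, environment -> mean over the window.
#' @export
window_mean <- function(series, factor_name, window) {
  window <- as.integer(window)
  d <- series[series$factor == factor_name, , drop = FALSE]
  if (!nrow(d)) stop("unknown factor: ", factor_name, call. = FALSE)
  rng <- range(d$day)
  if (window[1] < rng[1] || window[2] > rng[2] || window[1] > window[2])
    stop(sprintf("window (%d, %d) outside harmonized day range (%d, %d)",
                 window[1], window[2], rng[1], rng[2]), call. = FALSE)
  keep <- d$day >= window[1] & d$day <= window[2]
  out <- tapply(d$value[keep], d$environment[keep], mean)
  out <- out[unique(d$environment)]
  stats::setNames(as.numeric(out), names(out))
}

#' Exhaustive environmental-index search (CERIS)
#'
#' For every environmental factor and every day window (start, end) on the
#' step grid with width >= `min_width`, computes the per-environment window
#' mean e_j and regresses the environment-mean phenotype on e_j by simple
#' OLS across environments. The candidate with the highest R-squared is the
#' selected index; exact ties are broken by earlier start, then shorter
#' window, then factor name. A window whose e_j is constant across
#' environments carries no information and scores R-squared 0.
#'
#' With only two environments any non-degenerate factor fits perfectly, so
#' fewer than three environments is refused.
#'
#' @param series harmonized env series.
#' @param env_pheno_means named vector from [env_means()].
#' @param min_width minimum window width in days (default 7).
#' @param step grid step in days for window starts and ends (default 1).
#' @param factors subset of factors to search (default: all in the series).
#' @return object of class `"ceris_search"`: `best` (an [env_index()]) and
#'   `table` (one row per candidate: factor, start, end, r, r2).
#' @export
search_index <- function(series, env_pheno_means, min_width = 7L, step = 1L,
                         factors = NULL) {
  envs <- names(env_pheno_means)
  if (length(envs) < 3L)
    stop("environmental-index search needs >= 3 environments; with 2 any ",
         "non-degenerate factor fits perfectly", call. = FALSE)
  series <- series[series$environment %in% envs, , drop = FALSE]
  if (is.null(factors)) factors <- sort(unique(series$factor))
  y <- as.numeric(env_pheno_means)
  sy <- stats::sd(y)

  tabs <- lapply(factors, function(f) {
    d <- series[series$factor == f, , drop = FALSE]
    days <- sort(unique(d$day))
    d1 <- days[1L]; dD <- days[length(days)]
    # cumulative sums per environment for O(1) window means
    cums <- vapply(envs, function(e) {
      v <- d$value[d$environment == e][order(d$day[d$environment == e])]
      cumsum(v)
    }, numeric(length(days)))
    starts <- seq(d1, dD, by = step)
    grid <- do.call(rbind, lapply(starts, function(s) {
      e0 <- s + min_width - 1L
      if (e0 > dD) return(NULL)
      cbind(start = s, end = seq(e0, dD, by = step))
    }))
    if (is.null(grid)) return(NULL)
    si <- match(grid[, "start"], days)
    ei <- match(grid[, "end"], days)
    n_r2 <- n_r <- numeric(nrow(grid))
    for (i in seq_len(nrow(grid))) {
      lo <- si[i]; hi <- ei[i]
      tot <- cums[hi, ] - (if (lo > 1L) cums[lo - 1L, ] else 0)
      e_j <- tot / (hi - lo + 1L)
      if (stats::sd(e_j) < 1e-12 || sy < 1e-12) {
        n_r[i] <- 0; n_r2[i] <- 0
      } else {
        rr <- stats::cor(y, e_j)
        n_r[i] <- rr; n_r2[i] <- rr * rr
      }
    }
    data.frame(factor = f, start = grid[, "start"], end = grid[, "end"],
               r = n_r, r2 = n_r2, stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, tabs)
  if (is.null(tab) || !nrow(tab))
    stop("no candidate window satisfies min_width on the harmonized range",
         call. = FALSE)
  # deterministic tie-break: max r2, earlier start, shorter window, factor name
  ord <- order(-tab$r2, tab$start, tab$end - tab$start, tab$factor)
  tab <- tab[ord, , drop = FALSE]
  rownames(tab) <- NULL
  b <- tab[1L, ]
  if (b$r2 <= 0)
    warning("all candidate windows are uninformative (R2 = 0); ",
            "returning first candidate by tie-break", call. = FALSE)
  e_best <- window_mean(series, b$factor, c(b$start, b$end))[envs]
  best <- env_index(b$factor, c(b$start, b$end), e_best,
                    r2 = b$r2, r = b$r)
  structure(list(best = best, table = tab), class = "ceris_search")
}

#' @export
print.ceris_search <- function(x, ...) {
  cat(sprintf("<ceris_search> %d candidates over %d factor(s)\n",
              nrow(x$table), length(unique(x$table$factor))))
  print(x$best)
  invisible(x)
}

#' Index a (possibly novel) environment with an existing env_index
#'
#' Computes the window mean of the selected factor over the selected days
#' for additional environments and centres it with the TRAINING centre, so
#' predictions extrapolate consistently to environments unseen at search
#' time.
#'
#' @param index an [env_index()].
#' @param series harmonized env series containing the new environment(s).
#' @param environments environments to index.
#' @return updated `env_index` whose raw/centred maps include the new
#'   environments (centre unchanged).
#' @export
index_environment <- function(index, series, environments) {
  e_new <- window_mean(series[series$environment %in% environments, ,
                              drop = FALSE],
                       index$factor_name, index$window)
  if (anyNA(e_new))
    stop("cannot compute index for environment(s): ",
         paste(environments[is.na(e_new[environments])], collapse = ", "),
         call. = FALSE)
  raw <- c(index$raw_index, e_new[setdiff(names(e_new), names(index$raw_index))])
  env_index(index$factor_name, index$window, raw,
            r2 = index$r2, r = index$r, centre = index$centre)
}
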