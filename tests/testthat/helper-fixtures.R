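# Small programmatic fixtures shared across test files.

# deterministic daily series: m environments, two factors, linear-in-day
# values with environment offsets so window means always vary across envs.
# F2's offsets are non-collinear with F1's so the two factors carry
# distinguishable environment signals.
tiny_series <- function(m = 4, days = 30, offsets = seq_len(m),
                        offsets2 = offsets^2 - offsets) {
  do.call(rbind, lapply(seq_len(m), function(j) {
    rbind(
      data.frame(environment = paste0("E", j), day = seq_len(days),
                 factor = "F1", value = 10 + 0.2 * seq_len(days) + offsets[j]),
      data.frame(environment = paste0("E", j), day = seq_len(days),
                 factor = "F2", value = 5 - 0.1 * seq_len(days) + offsets2[j]))
  }))
}

# phenotype table from a genotype x environment matrix of values
pheno_from_matrix <- function(vals, trait = "trait") {
  df <- expand.grid(genotype = rownames(vals), environment = colnames(vals),
                    stringsAsFactors = FALSE)
  df$trait <- trait
  df$value <- vals[cbind(df$genotype, df$environment)]
  pheno_table(df)
}

# fast Gibbs settings for unit tests
quick_gibbs <- function(name, ...) {
  sp <- estimator_spec(name, ...)
  sp$hyperparams$niter <- 800L
  sp$hyperparams$burnin <- 200L
  sp$hyperparams$thin <- 2L
  sp
}

random_geno <- function(n, p, seed = 1, maf = 0.3) {
  set.seed(seed)
  geno_matrix(matrix(rbinom(n * p, 2, maf), n, p),
              sample_ids = sprintf("G%03d", seq_len(n)),
              marker_ids = sprintf("M%03d", seq_len(p)))
}
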