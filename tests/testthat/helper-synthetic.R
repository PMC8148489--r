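# Shared fixture builders. Everything is generated in code; no stored data.

# Fresh scratch directory under the session tempdir.
local_tempdir <- function() {
  d <- tempfile("svrsig-test-")
  dir.create(d)
  d
}

# Small planted-signal cohort via the package generator.
tiny_sim <- function(n = 60, d = 50, k = 5, noise_sd = 0.2,
                     nonlinear_fraction = 0, censor_fraction = 0,
                     seed = 11, ...) {
  simulate_cohort(simulation_config(
    n_samples = n, n_features = d, signal_features = k,
    noise_sd = noise_sd, nonlinear_fraction = nonlinear_fraction,
    censor_fraction = censor_fraction, seed = seed, ...))
}

# Hand-built survival dataset with y an exact linear function of the
# first k z-scored features (no generator involved).
linear_dataset <- function(n = 40, d = 8, k = 3, noise_sd = 0, seed = 5) {
  set.seed(seed)
  X <- matrix(rexp(n * d, rate = 0.1), n, d)
  Z <- scale(X[, seq_len(k), drop = FALSE])
  beta <- seq(1, 0.5, length.out = k)
  y <- 4 + Z %*% beta + rnorm(n, 0, noise_sd)
  cohort <- expression_cohort(X, sprintf("P%03d", seq_len(n)),
                              sprintf("feat-%02d", seq_len(d)))
  structure(list(cohort = cohort, survival_years = as.numeric(y)),
            class = "survival_dataset")
}

default_svr <- function() svr_config(gamma = 0.1, cost = 8, nu = 0.5)

# Write a small expression + clinical table pair, returning the paths.
write_tiny_tables <- function(dir, expr_values, ids, feats, clinical) {
  expr_path <- file.path(dir, "expr.tsv")
  tab <- data.frame(sample_id = ids, expr_values, check.names = FALSE)
  colnames(tab) <- c("sample_id", feats)
  write.table(tab, expr_path, sep = "\t", quote = FALSE, row.names = FALSE)
  clin_path <- file.path(dir, "clin.tsv")
  write.table(clinical, clin_path, sep = "\t", quote = FALSE,
              row.names = FALSE, na = "")
  list(expr = expr_path, clin = clin_path)
}

# A fake deterministic fitness function over chromosomes, for cheap GA
# operator tests: fitness depends only on which genes are set.
toy_eval_fn <- function(weights) {
  force(weights)
  function(chrom) {
    cc <- sum(weights[chrom$features == 1L]) +
      0.001 * sum(chrom$params)
    list(cc = cc, mae_years = -cc)
  }
}
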