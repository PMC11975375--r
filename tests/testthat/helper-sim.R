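# Scaled-down configurations used throughout the suite; the full study-scale
# defaults are exercised in the acceptance tests.

small_pool_config <- function(seed = 1L, ...) {
  sim_config(n_droplets_per_pool = 4000L, n_snps = 100L, seed = seed, ...)
}

small_atlas_config <- function(seed = 1L, ...) {
  sim_config(n_genes = 300L, n_clusters = 8L, cells_per_sample = 200L,
             seed = seed, ...)
}

no_effect <- function() data.frame(cluster = character(),
                                   covariate = character(),
                                   fold = numeric())

no_expr_effect <- function() data.frame(gene = character(),
                                        cluster = character(),
                                        covariate = character(),
                                        fold = numeric())

# Independent negative-binomial matrix for GLM-level tests (bypasses the
# atlas generator so count_glm is tested on its own terms).
nb_matrix <- function(n_features, n_samples, mu = 50, phi = 0.1,
                      seed = 1L, fold = 1, group = NULL) {
  withr::with_seed(seed, {
    m <- matrix(rnbinom(n_features * n_samples, mu = mu,
                        size = if (phi > 0) 1 / phi else Inf),
                nrow = n_features)
    if (!is.null(group) && fold != 1) {
      idx <- which(group == levels(factor(group))[2])
      m[, idx] <- matrix(rnbinom(n_features * length(idx), mu = mu * fold,
                                 size = if (phi > 0) 1 / phi else Inf),
                         nrow = n_features)
    }
    rownames(m) <- sprintf("f%04d", seq_len(n_features))
    colnames(m) <- sprintf("s%02d", seq_len(n_samples))
    m
  })
}

study_design <- function(n_samples = 24L) {
  n_rep <- n_samples / 4L
  data.frame(
    sample = sprintf("s%02d", seq_len(n_samples)),
    replicate = rep(paste0("r", seq_len(n_rep)), each = 4),
    species = rep(c("A", "B"), n_samples / 2),
    sex = rep(rep(c("F", "M"), each = 2), n_rep),
    row.names = sprintf("s%02d", seq_len(n_samples))
  )
}
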