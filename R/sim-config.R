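#' Simulation configuration
#'
#' Builds a validated configuration for the synthetic-data generator. The
#' defaults emulate the structure of a cross-species pooled preoptic-area
#' snRNA-seq experiment: 6 replicate 10x pools, each containing 4 samples
#' (2 species \code{A}/\code{B} x 2 sexes \code{F}/\code{M}), roughly 20,000
#' droplets per pool with a 9\% detectable multiplet rate, and a
#' cluster-structured neuronal count matrix over ~50 clusters with planted
#' abundance fold changes (1.6x and 3.4x on the species covariate) and
#' species/sex expression effects.
#'
#' @param n_replicates Number of replicate pools (default 6).
#' @param samples_per_pool Samples pooled per run; must be 4 (2 species x
#'   2 sexes), the pooling design this generator emulates.
#' @param n_droplets_per_pool Droplets per pool after background filtering.
#' @param multiplet_rate Fraction of droplets containing two nuclei.
#' @param mismap_rate Fraction of a nucleus' reads that map to the wrong
#'   species' genome (cross-mapping leakage).
#' @param read_depth_law Named list \code{list(meanlog=, sdlog=)} of the
#'   per-droplet total-read log-normal distribution.
#' @param n_snps Number of genotyped SNPs available for sample assignment.
#' @param maf Minor-allele frequency used when simulating genotypes.
#' @param snp_read_rate Expected fraction of a droplet's reads that cover a
#'   genotyped SNP (Poisson thinning of total depth).
#' @param snp_error Sequencing error rate for allele observations.
#' @param n_genes Number of genes in the atlas count matrix (synthetic
#'   marker genes \code{Gad1}, \code{Gad2}, \code{Slc17a6}, \code{Xist} are
#'   appended in addition).
#' @param n_clusters Number of neuronal clusters.
#' @param cells_per_sample Nuclei retained per sample in the atlas matrix.
#' @param abundance_effects Data frame with columns \code{cluster},
#'   \code{covariate} (\code{"species"} or \code{"sex"}), \code{fold}:
#'   multiplicative abundance change for the second covariate level
#'   (species \code{B}, sex \code{M}).
#' @param expression_effects Data frame with columns \code{gene},
#'   \code{cluster}, \code{covariate} (\code{"species"}, \code{"sex"},
#'   \code{"sex:A"} or \code{"sex:B"} for sex effects restricted to one
#'   species), \code{fold}.
#' @param category_map Data frame with columns \code{gene}, \code{category}
#'   assigning genes to functional categories for enrichment testing, or
#'   \code{NULL} for the built-in default (a category enriched among the
#'   planted species-DE genes plus a null category).
#' @param dispersion Negative-binomial dispersion of per-cell gene counts
#'   (0 gives Poisson counts).
#' @param seed Root seed; every stage derives named child streams from it.
#'
#' @return A list of class \code{"sim_config"}.
#' @export
sim_config <- function(n_replicates = 6L,
                       samples_per_pool = 4L,
                       n_droplets_per_pool = 20000L,
                       multiplet_rate = 0.09,
                       mismap_rate = 0.01,
                       read_depth_law = list(meanlog = log(8000), sdlog = 0.6),
                       n_snps = 200L,
                       maf = 0.3,
                       snp_read_rate = 0.02,
                       snp_error = 0.01,
                       n_genes = 2000L,
                       n_clusters = 50L,
                       cells_per_sample = 500L,
                       abundance_effects = data.frame(
                         cluster = c("c01", "c02"),
                         covariate = c("species", "species"),
                         fold = c(1.6, 3.4)
                       ),
                       expression_effects = NULL,
                       category_map = NULL,
                       dispersion = 0.1,
                       seed = 1L) {
  n_replicates <- check_count(n_replicates, "n_replicates", min = 1)
  samples_per_pool <- check_count(samples_per_pool, "samples_per_pool", min = 2)
  if (samples_per_pool != 4L) {
    stop2("samples_per_pool must be 4 (2 species x 2 sexes)")
  }
  n_droplets_per_pool <- check_count(n_droplets_per_pool,
                                     "n_droplets_per_pool", min = 1)
  check_fraction(multiplet_rate, "multiplet_rate")
  check_fraction(mismap_rate, "mismap_rate", max = 0.5)
  check_fraction(snp_read_rate, "snp_read_rate")
  check_fraction(snp_error, "snp_error", max = 0.5)
  if (!is.list(read_depth_law) ||
      !all(c("meanlog", "sdlog") %in% names(read_depth_law)) ||
      read_depth_law$sdlog < 0) {
    stop2("read_depth_law must be list(meanlog=, sdlog>=0)")
  }
  n_snps <- check_count(n_snps, "n_snps", min = 1)
  if (!is.numeric(maf) || maf <= 0 || maf > 0.5) {
    stop2("maf must be in (0, 0.5]")
  }
  n_genes <- check_count(n_genes, "n_genes", min = 1)
  n_clusters <- check_count(n_clusters, "n_clusters", min = 1)
  cells_per_sample <- check_count(cells_per_sample, "cells_per_sample", min = 1)
  if (!is.numeric(dispersion) || dispersion < 0) {
    stop2("dispersion must be >= 0")
  }
  abundance_effects <- validate_effects(abundance_effects,
                                        c("cluster", "covariate", "fold"),
                                        c("species", "sex"))
  expression_effects <- validate_effects(
    expression_effects, c("gene", "cluster", "covariate", "fold"),
    c("species", "sex", "sex:A", "sex:B")
  )
  if (is.null(expression_effects)) {
    expression_effects <- default_expression_effects(n_genes, n_clusters)
  }
  cfg <- list(
    n_replicates = n_replicates,
    samples_per_pool = samples_per_pool,
    n_droplets_per_pool = n_droplets_per_pool,
    multiplet_rate = multiplet_rate,
    mismap_rate = mismap_rate,
    read_depth_law = read_depth_law,
    n_snps = n_snps,
    maf = maf,
    snp_read_rate = snp_read_rate,
    snp_error = snp_error,
    n_genes = n_genes,
    n_clusters = n_clusters,
    cells_per_sample = cells_per_sample,
    abundance_effects = abundance_effects,
    expression_effects = expression_effects,
    category_map = category_map,
    dispersion = dispersion,
    seed = check_count(seed, "seed", min = 0)
  )
  class(cfg) <- "sim_config"
  cfg
}

validate_effects <- function(x, cols, covariates) {
  if (is.null(x) || (is.data.frame(x) && nrow(x) == 0L)) return(x)
  if (!is.data.frame(x) || !all(cols %in% names(x))) {
    stop2("effects must be a data frame with columns ",
          paste(cols, collapse = ", "))
  }
  if (!all(x$covariate %in% covariates)) {
    stop2("effect covariate must be one of: ",
          paste(covariates, collapse = ", "))
  }
  if (any(x$fold <= 0)) stop2("fold changes must be > 0")
  x
}

# Default planted expression truth: 20 genes with a 2x species effect in
# cluster c01, 10 genes with a 2x sex effect (both species) in c02, and 5
# genes with a species-A-only sex effect in c03.
default_expression_effects <- function(n_genes, n_clusters) {
  gene_id <- function(i) sprintf("g%04d", i)
  eff <- data.frame(
    gene = gene_id(1:20), cluster = "c01",
    covariate = "species", fold = 2
  )
  if (n_clusters >= 2L && n_genes >= 30L) {
    eff <- rbind(eff, data.frame(
      gene = gene_id(21:30), cluster = "c02",
      covariate = "sex", fold = 2
    ))
  }
  if (n_clusters >= 3L && n_genes >= 35L) {
    eff <- rbind(eff, data.frame(
      gene = gene_id(31:35), cluster = "c03",
      covariate = "sex:A", fold = 2
    ))
  }
  eff[eff$gene %in% gene_id(seq_len(n_genes)) &
        eff$cluster %in% cluster_ids(n_clusters), , drop = FALSE]
}

cluster_ids <- function(n) sprintf("c%02d", seq_len(n))

gene_names <- function(cfg) {
  c(sprintf("g%04d", seq_len(cfg$n_genes)),
    "Gad1", "Gad2", "Slc17a6", "Xist")
}

# Sample naming: pool r, species A/B, sex F/M -> "r1_A_F" etc. Each pooled
# animal is a distinct sample.
sample_ids <- function(replicate) {
  as.vector(outer(c("A", "B"), c("F", "M"),
                  function(sp, sx) paste(paste0("r", replicate), sp, sx,
                                         sep = "_")))
}

#' Per-sample metadata table for a simulated experiment
#'
#' @param config A [sim_config()].
#' @return Data frame with columns \code{sample}, \code{replicate},
#'   \code{species}, \code{sex}; one row per pooled animal.
#' @export
sample_metadata <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  meta <- do.call(rbind, lapply(seq_len(config$n_replicates), function(r) {
    data.frame(
      sample = sample_ids(r),
      replicate = paste0("r", r),
      species = rep(c("A", "B"), 2),
      sex = rep(c("F", "M"), each = 2)
    )
  }))
  rownames(meta) <- meta$sample
  meta
}

#' @export
print.sim_config <- function(x, ...) {
  cat("sim_config:",
      x$n_replicates, "pools x", x$samples_per_pool, "samples,",
      x$n_droplets_per_pool, "droplets/pool,",
      sprintf("multiplet rate %.2f,", x$multiplet_rate),
      x$n_clusters, "clusters,", x$n_genes, "genes\n")
  invisible(x)
}
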