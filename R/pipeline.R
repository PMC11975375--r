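#' Pipeline run configuration
#'
#' Assembles stage toggles, thresholds and the root seed for
#' [run_pipeline()]. Defaults are the analysis constants of the study
#' design this package models: 500-read demux bins, homology threshold
#' 0.15, abundance FDR 0.3, DE FDR 0.05, 5000 enrichment resamples. Any
#' override is echoed into the run report.
#'
#' @param sim A [sim_config()]; defaults to \code{sim_config(seed = seed)}.
#' @param stages Character vector of stages to run, in dependency order.
#' @param bin_width Demux primary-read bin width.
#' @param min_prop Homology-mapping proportion threshold.
#' @param abundance_fdr Candidate FDR cutoff for differential abundance.
#' @param de_fdr FDR cutoff for differential expression.
#' @param enrichment_B Background resamples for the enrichment test.
#' @param inputs Optional named list of external demux input paths
#'   (\code{reads}, \code{alleles}, \code{vcf}, \code{samples}); when
#'   given, the demux stage reads these instead of simulating a pool.
#' @param seed Root seed; stages derive named child streams.
#' @return List of class \code{"run_config"}.
#' @export
run_config <- function(sim = NULL,
                       stages = c("simulate", "demux", "abundance", "de",
                                  "annotate", "enrich"),
                       bin_width = 500,
                       min_prop = 0.15,
                       abundance_fdr = 0.3,
                       de_fdr = 0.05,
                       enrichment_B = 5000L,
                       inputs = NULL,
                       seed = 1L) {
  seed <- check_count(seed, "seed", min = 0)
  if (is.null(sim)) sim <- sim_config(seed = seed)
  stopifnot(inherits(sim, "sim_config"))
  defaults <- list(bin_width = 500, min_prop = 0.15, abundance_fdr = 0.3,
                   de_fdr = 0.05, enrichment_B = 5000L)
  cfg <- list(sim = sim, stages = stages, bin_width = bin_width,
              min_prop = min_prop, abundance_fdr = abundance_fdr,
              de_fdr = de_fdr, enrichment_B = enrichment_B,
              inputs = inputs, seed = seed)
  cfg$overrides <- names(defaults)[vapply(
    names(defaults), function(k) !identical(as.numeric(cfg[[k]]),
                                            as.numeric(defaults[[k]])),
    logical(1))]
  class(cfg) <- "run_config"
  cfg
}

#' Load a run configuration from YAML
#'
#' Top-level keys map to [run_config()] arguments; the \code{sim} key maps
#' to [sim_config()] arguments.
#'
#' @param path YAML file.
#' @return A \code{"run_config"}.
#' @export
run_config_from_yaml <- function(path) {
  if (!file.exists(path)) stop2("config file not found: ", path)
  y <- yaml::read_yaml(path)
  sim_args <- y$sim
  y$sim <- NULL
  if (!is.null(sim_args)) {
    if (!is.null(sim_args$read_depth_law)) {
      sim_args$read_depth_law <- as.list(sim_args$read_depth_law)
    }
    y$sim <- do.call(sim_config, sim_args)
  }
  do.call(run_config, y)
}

#' Run the full synthetic-to-results pipeline
#'
#' Orchestrates simulate -> demux -> abundance -> DE -> annotation ->
#' enrichment with a single root seed, writing per-stage TSV/JSON outputs
#' and a structured run report. Stage outputs are pure functions of their
#' inputs and the configuration, so a rerun with the same config is
#' byte-identical. When external demux inputs are configured, their
#' existence is checked before any stage runs.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory.
#' @return The run report (invisibly), also written to
#'   \code{report.json}.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "run_config"))
  if (!is.null(config$inputs)) {
    for (f in unlist(config$inputs)) {
      if (!file.exists(f)) stop2("missing input file: ", f)
    }
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "run.log")
  cat("", file = log_path)
  logf <- function(...) {
    cat(paste0("[", paste(...), "]\n"), file = log_path, append = TRUE)
  }
  report <- list(parameters = list(
    bin_width = config$bin_width, min_prop = config$min_prop,
    abundance_fdr = config$abundance_fdr, de_fdr = config$de_fdr,
    enrichment_B = config$enrichment_B, seed = config$seed,
    overridden = config$overrides
  ))
  st <- config$stages

  pool <- NULL
  if (!is.null(config$inputs)) {
    pool <- do.call(read_droplet_pool, config$inputs)
    logf("demux-input", "external files")
  } else if ("simulate" %in% st) {
    logf("simulate", "pool 1")
    pool <- simulate_pooled_run(config$sim, replicate = 1L)
    write_droplet_pool(pool, file.path(out_dir, "pool1"))
  }

  if ("demux" %in% st && !is.null(pool)) {
    logf("demux", paste("bin_width", config$bin_width))
    dmx <- demux_pool(pool, bin_width = config$bin_width)
    write_tsv(dmx$calls, file.path(out_dir, "demux_calls.tsv"))
    jsonlite::write_json(
      list(line = unclass(dmx$threshold$line),
           bins = lapply(dmx$threshold$fits, unclass)),
      file.path(out_dir, "demux_model.json"),
      auto_unbox = TRUE, digits = NA)
    s <- dmx$summary
    report$demux <- list(
      n_droplets = s$n_droplets, n_singlets = s$n_singlets,
      n_removed_multiplets = s$n_species_multiplets + s$n_sample_multiplets,
      n_species_multiplets = s$n_species_multiplets,
      n_sample_multiplets = s$n_sample_multiplets,
      n_ambiguous = s$n_ambiguous
    )
  }

  atlas <- NULL
  if (any(c("abundance", "de", "annotate", "enrich") %in% st)) {
    logf("simulate", "atlas counts")
    atlas <- simulate_atlas_counts(config$sim)
  }

  if ("abundance" %in% st) {
    logf("abundance", paste("fdr", config$abundance_fdr))
    ab <- build_abundance_matrix(atlas$cell_metadata,
                                 samples = atlas$sample_metadata$sample)
    da <- differential_abundance(ab, atlas$sample_metadata,
                                 fdr_threshold = config$abundance_fdr)
    write_tsv(da, file.path(out_dir, "differential_abundance.tsv"))
    report$abundance <- list(
      n_clusters = nrow(ab),
      n_candidates_species = sum(da$candidate[da$contrast == "species"]),
      n_candidates_sex = sum(da$candidate[da$contrast == "sex"])
    )
  }

  de_sp <- NULL
  pb <- NULL
  if (any(c("de", "enrich") %in% st)) {
    logf("de", paste("fdr", config$de_fdr))
    pb <- pseudobulk(atlas$counts, atlas$cell_metadata$cluster,
                     atlas$cell_metadata$sample)
    de_sp <- de_species(pb, atlas$sample_metadata, fdr = config$de_fdr)
    de_sex_a <- de_sex_within_species(pb, atlas$sample_metadata, "A",
                                      fdr = config$de_fdr)
    de_sex_b <- de_sex_within_species(pb, atlas$sample_metadata, "B",
                                      fdr = config$de_fdr)
    write_tsv(de_sp, file.path(out_dir, "de_species.tsv"))
    write_tsv(de_sex_a, file.path(out_dir, "de_sex_speciesA.tsv"))
    write_tsv(de_sex_b, file.path(out_dir, "de_sex_speciesB.tsv"))
    cl_sizes <- table(atlas$cell_metadata$cluster)
    sum_sp <- de_summary(de_sp, abundance = cl_sizes)
    sum_sex <- de_summary(de_sex_a, de_sex_b, abundance = cl_sizes)
    report$de <- list(
      n_species_de = sum_sp$n_de,
      n_species_de_genes = sum_sp$n_unique_genes,
      sex_partition = as.list(sum_sex$partition)
    )
  }

  if ("annotate" %in% st) {
    logf("annotate", paste("min_prop", config$min_prop))
    cm <- cluster_mean_cpm(atlas$counts, atlas$cell_metadata$cluster)
    classes <- classify_neuron_class(cm)
    props <- label_proportion_matrix(atlas$cell_metadata$transferred_label,
                                     atlas$cell_metadata$cluster)
    hom <- assign_homology(props, excluded_labels = character(0),
                           min_prop = config$min_prop)
    hom$class <- classes[hom$cluster]
    write_tsv(hom, file.path(out_dir, "homology.tsv"))
    report$annotation <- list(
      n_inhibitory = sum(classes == "inhibitory"),
      n_excitatory = sum(classes == "excitatory"),
      n_mapped = length(unique(hom$cluster[!is.na(hom$label)])),
      n_unmapped = sum(is.na(hom$label))
    )
  }

  if ("enrich" %in% st) {
    logf("enrich", paste("B", config$enrichment_B))
    fg_tab <- de_sp[de_sp$significant, , drop = FALSE]
    if (nrow(fg_tab)) {
      gene_cpm <- cpm(rowSums(pb$counts))
      cl_cpm <- cluster_cpm_matrix(pb)
      bins <- bin_genes_by_expression(gene_cpm)
      fg_expr <- foreground_expression(cl_cpm, fg_tab)
      fg <- names(fg_expr)
      fg_bins <- clamp_bins(bin_genes_by_expression(fg_expr)$bin, bins)
      enr <- enrichment_test(fg, atlas$truth$category_map, bins,
                             B = config$enrichment_B,
                             seed = child_seed(config$seed, "enrich"),
                             foreground_bins = fg_bins)
      write_tsv(as.data.frame(enr), file.path(out_dir, "enrichment.tsv"))
      report$enrichment <- lapply(
        split(as.data.frame(enr), enr$category), function(r) {
          list(n_foreground = r$n_foreground,
               enrichment_score = r$enrichment_score,
               empirical_p = r$empirical_p, fdr = r$fdr)
        })
    } else {
      report$enrichment <- list()
    }
  }

  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  invisible(report)
}

#' Per-cluster mean CPM matrix
#'
#' Library-size-normalized (CPM) expression averaged over each cluster's
#' cells; used for inhibitory/excitatory classing.
#'
#' @param counts Genes x cells matrix.
#' @param clusters Per-cell cluster labels.
#' @return Genes x clusters matrix.
#' @export
cluster_mean_cpm <- function(counts, clusters) {
  norm <- Matrix::t(Matrix::t(counts) / Matrix::colSums(counts)) * 1e6
  cl <- factor(clusters)
  ind <- Matrix::fac2sparse(cl)
  m <- as.matrix(Matrix::tcrossprod(norm, ind))
  sweep(m, 2L, as.vector(table(cl)), `/`)
}

# Foreground bins are computed on per-cluster CPM, which can exceed any
# whole-dataset CPM; map such bins to the nearest populated universe bin.
clamp_bins <- function(fg_bins, bins) {
  have <- names(bins$members)
  have_num <- suppressWarnings(as.numeric(have))
  vapply(fg_bins, function(b) {
    if (b %in% have) return(b)
    x <- suppressWarnings(as.numeric(b))
    cand <- have[!is.na(have_num)]
    if (is.na(x) || !length(cand)) return(have[1])
    cand[which.min(abs(have_num[!is.na(have_num)] - x))]
  }, character(1), USE.NAMES = FALSE)
}

# CPM per gene within each cluster's pseudobulk (summed over samples).
cluster_cpm_matrix <- function(pb) {
  ind <- Matrix::fac2sparse(factor(pb$groups$cluster))
  tot <- as.matrix(Matrix::tcrossprod(pb$counts, ind))
  cpm(tot)
}
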