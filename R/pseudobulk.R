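#' Pseudobulk a single-cell count matrix
#'
#' Sums gene counts across all cells belonging to the same (cluster,
#' sample) group. Summation is exact integer arithmetic: for every cluster,
#' each gene's total equals the sum of that gene over the cluster's cells.
#'
#' @param counts Genes x cells count matrix (sparse or dense).
#' @param clusters Character/factor vector: per-cell cluster label.
#' @param samples Character/factor vector: per-cell sample label.
#' @return List of class \code{"pseudobulk"}: \code{counts} (genes x
#'   groups), \code{groups} (data frame \code{cluster}, \code{sample} per
#'   column), \code{clusters}, \code{samples} (level sets).
#' @export
pseudobulk <- function(counts, clusters, samples) {
  if (length(clusters) != ncol(counts) || length(samples) != ncol(counts)) {
    stop2("clusters and samples must have one entry per cell")
  }
  if (anyNA(clusters) || anyNA(samples)) {
    stop2("every cell must have a cluster and a sample label")
  }
  cl <- factor(clusters)
  sa <- factor(samples)
  grp <- factor(paste(cl, sa, sep = "\r"),
                levels = as.vector(outer(levels(cl), levels(sa),
                                         paste, sep = "\r")))
  ind <- Matrix::fac2sparse(grp, drop.unused.levels = FALSE)  # groups x cells
  pb <- as.matrix(Matrix::tcrossprod(counts, ind))
  parts <- do.call(rbind, strsplit(levels(grp), "\r", fixed = TRUE))
  groups <- data.frame(cluster = parts[, 1], sample = parts[, 2])
  colnames(pb) <- paste(groups$cluster, groups$sample, sep = ".")
  structure(list(counts = pb, groups = groups,
                 clusters = levels(cl), samples = levels(sa)),
            class = "pseudobulk")
}

#' @export
print.pseudobulk <- function(x, ...) {
  cat("pseudobulk:", nrow(x$counts), "genes x", length(x$clusters),
      "clusters x", length(x$samples), "samples\n")
  invisible(x)
}

pb_cluster_counts <- function(pb, cluster) {
  sel <- pb$groups$cluster == cluster
  m <- pb$counts[, sel, drop = FALSE]
  colnames(m) <- pb$groups$sample[sel]
  m
}

#' Per-cluster differential expression across species
#'
#' For each cluster, fits a per-gene negative-binomial GLM on the cluster's
#' pseudobulk counts with replicate, sex and species covariates, tests the
#' species coefficient, and applies BH FDR within the cluster's gene family
#' (genes with all-zero or near-zero counts in the cluster are dropped from
#' the family first).
#'
#' @param pb A \code{"pseudobulk"}.
#' @param sample_metadata Per-sample data frame (\code{replicate},
#'   \code{species}, \code{sex}).
#' @param fdr Significance threshold recorded in the \code{significant}
#'   column (default 0.05).
#' @param min_total Minimum cluster-wide count for a gene to be tested.
#' @return Data frame: \code{cluster}, \code{gene}, \code{log2_fold_change}
#'   (positive = higher in species B), \code{p_value}, \code{fdr},
#'   \code{significant}, \code{direction} (\code{"B"}/\code{"A"} bias).
#' @export
de_species <- function(pb, sample_metadata, fdr = 0.05, min_total = 10) {
  stopifnot(inherits(pb, "pseudobulk"))
  per_cluster_de(pb, sample_metadata, fdr, min_total,
                 formula = ~ replicate + sex + species,
                 coef_prefix = "species", dir_levels = c("A", "B"))
}

#' Per-cluster differential expression across sex within one species
#'
#' Restricts the pseudobulk table to one species' samples and tests the sex
#' coefficient per gene per cluster under a replicate + sex design.
#'
#' @param pb A \code{"pseudobulk"}.
#' @param sample_metadata Per-sample data frame.
#' @param species Which species' samples to analyze.
#' @param fdr,min_total As in [de_species()].
#' @return Data frame as in [de_species()] with \code{direction}
#'   \code{"M"}/\code{"F"} (male-/female-biased).
#' @export
de_sex_within_species <- function(pb, sample_metadata, species,
                                  fdr = 0.05, min_total = 10) {
  stopifnot(inherits(pb, "pseudobulk"))
  meta <- normalize_sample_meta(sample_metadata, pb$samples)
  keep_samples <- rownames(meta)[meta$species == species]
  if (length(keep_samples) == 0L) stop2("no samples of species ", species)
  sub <- restrict_pseudobulk(pb, keep_samples)
  per_cluster_de(sub, meta[keep_samples, ], fdr, min_total,
                 formula = ~ replicate + sex,
                 coef_prefix = "sex", dir_levels = c("F", "M"))
}

restrict_pseudobulk <- function(pb, keep_samples) {
  sel <- pb$groups$sample %in% keep_samples
  structure(list(counts = pb$counts[, sel, drop = FALSE],
                 groups = pb$groups[sel, , drop = FALSE],
                 clusters = pb$clusters, samples = keep_samples),
            class = "pseudobulk")
}

per_cluster_de <- function(pb, sample_metadata, fdr, min_total,
                           formula, coef_prefix, dir_levels) {
  meta <- normalize_sample_meta(sample_metadata, pb$samples)
  out <- lapply(pb$clusters, function(cl) {
    m <- pb_cluster_counts(pb, cl)[, rownames(meta), drop = FALSE]
    # samples contributing no cells to this cluster cannot be normalized;
    # drop them, and skip the cluster if the design collapses without them
    keep <- colSums(m) > 0
    if (sum(keep) < 4L) return(NULL)
    m <- m[, keep, drop = FALSE]
    meta_cl <- droplevels(meta[keep, , drop = FALSE])
    design <- tryCatch(model.matrix(formula, data = meta_cl),
                       error = function(e) NULL)
    if (is.null(design) || qr(design)$rank < ncol(design) ||
        nrow(design) <= ncol(design)) {  # no residual df
      return(NULL)
    }
    coef <- grep(paste0("^", coef_prefix), colnames(design), value = TRUE)
    if (length(coef) != 1L) return(NULL)
    tab <- glm_test_table(m, design, coefs = coef, min_total = min_total)
    if (!nrow(tab)) return(NULL)
    data.frame(cluster = cl, gene = tab$feature,
               log2_fold_change = tab$log2_fold_change,
               p_value = tab$p_value, fdr = tab$fdr,
               significant = !is.na(tab$fdr) & tab$fdr < fdr,
               direction = ifelse(tab$log2_fold_change > 0,
                                  dir_levels[2], dir_levels[1]),
               row.names = NULL)
  })
  res <- do.call(rbind, out)
  if (is.null(res)) {
    res <- data.frame(cluster = character(), gene = character(),
                      log2_fold_change = numeric(), p_value = numeric(),
                      fdr = numeric(), significant = logical(),
                      direction = character())
  }
  attr(res, "fdr_threshold") <- fdr
  res
}

#' Summarize differential-expression tables
#'
#' Per-cluster DE counts split by bias direction, unique-gene union counts,
#' and (when two per-species sex tables are given) the species-specific /
#' shared partition of sex-biased genes. A sex bias is shared when the same
#' gene is significant in the same cluster with the same direction in both
#' species.
#'
#' @param de_table DE table from [de_species()] or
#'   [de_sex_within_species()].
#' @param de_table2 Optional second species' sex DE table.
#' @param abundance Optional named vector of per-cluster cell totals, added
#'   to the per-cluster summary for abundance-vs-#DE scatter data.
#' @return List with \code{per_cluster} (counts by direction),
#'   \code{n_unique_genes}, and, given two tables, \code{shared} (gene,
#'   cluster, direction) plus \code{partition} counts (only-1 / only-2 /
#'   shared).
#' @export
de_summary <- function(de_table, de_table2 = NULL, abundance = NULL) {
  sig <- de_table[de_table$significant, , drop = FALSE]
  dirs <- sort(unique(de_table$direction))
  if (!length(dirs)) dirs <- character()
  per_cluster <- as.data.frame.matrix(
    table(factor(sig$cluster, levels = unique(de_table$cluster)),
          factor(sig$direction, levels = dirs)))
  per_cluster$total <- rowSums(per_cluster)
  per_cluster <- cbind(cluster = rownames(per_cluster), per_cluster)
  rownames(per_cluster) <- NULL
  if (!is.null(abundance)) {
    per_cluster$n_cells <- as.vector(abundance[per_cluster$cluster])
  }
  out <- list(per_cluster = per_cluster,
              n_unique_genes = length(unique(sig$gene)),
              n_de = nrow(sig))
  if (!is.null(de_table2)) {
    sig2 <- de_table2[de_table2$significant, , drop = FALSE]
    key <- function(d) paste(d$gene, d$cluster, d$direction, sep = "|")
    shared_keys <- intersect(key(sig), key(sig2))
    out$shared <- sig[key(sig) %in% shared_keys,
                      c("gene", "cluster", "direction")]
    # gene-level partition of the union (the strict same-cluster,
    # same-direction shared list is reported separately above)
    u1 <- unique(sig$gene); u2 <- unique(sig2$gene)
    out$partition <- c(
      only_1 = length(setdiff(u1, u2)),
      only_2 = length(setdiff(u2, u1)),
      shared = length(intersect(u1, u2))
    )
  }
  out
}
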