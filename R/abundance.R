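#' Cluster x sample cell-count matrix
#'
#' Exact cross-tabulation of assigned nuclei: entry (c, s) is the number of
#' cells of sample s in cluster c; unobserved pairs are zero.
#'
#' @param cell_metadata Data frame with columns \code{cluster},
#'   \code{sample} (one row per cell).
#' @param samples Optional character vector fixing the column set and
#'   order; metadata samples outside this set raise an error.
#' @return Integer matrix clusters x samples.
#' @export
build_abundance_matrix <- function(cell_metadata, samples = NULL) {
  stopifnot(all(c("cluster", "sample") %in% names(cell_metadata)))
  if (anyNA(cell_metadata$cluster) || anyNA(cell_metadata$sample)) {
    stop2("every cell must have a cluster and a sample")
  }
  if (is.null(samples)) {
    samples <- sort(unique(cell_metadata$sample))
  } else if (!all(cell_metadata$sample %in% samples)) {
    stop2("unknown sample(s) in metadata: ",
          paste(setdiff(cell_metadata$sample, samples), collapse = ", "))
  }
  tab <- table(factor(cell_metadata$cluster),
               factor(cell_metadata$sample, levels = samples))
  m <- matrix(as.integer(tab), nrow = nrow(tab), dimnames = dimnames(tab))
  names(dimnames(m)) <- NULL
  m
}

#' Differential cell-type abundance across species and sex
#'
#' Treats per-cluster cell counts as count data: TMM factors on the
#' cluster x sample matrix absorb differences in total neurons profiled per
#' sample, and a negative-binomial GLM with replicate, sex and species
#' covariates is fit per cluster. Both the species and the sex coefficient
#' are tested from the single joint fit, with BH FDR within each contrast.
#' A lenient default FDR threshold (0.3) flags candidate clusters intended
#' for downstream experimental validation. Clusters with fewer than
#' \code{min_cells} total cells are reported but flagged low-confidence.
#'
#' @param abundance_matrix Cluster x sample count matrix (columns named by
#'   sample).
#' @param sample_metadata Data frame with rownames (or column
#'   \code{sample}) matching the matrix columns, and columns
#'   \code{replicate}, \code{species}, \code{sex}.
#' @param fdr_threshold Candidate FDR cutoff (default 0.3).
#' @param min_cells Low-confidence flag threshold (default 20).
#' @return Data frame: \code{cluster}, \code{contrast} (\code{"species"} /
#'   \code{"sex"}), \code{log2_fold_change}, \code{p_value}, \code{fdr},
#'   \code{candidate}, \code{low_confidence}.
#' @export
differential_abundance <- function(abundance_matrix, sample_metadata,
                                   fdr_threshold = 0.3, min_cells = 20L) {
  m <- as.matrix(abundance_matrix)
  meta <- normalize_sample_meta(sample_metadata, colnames(m))
  for (v in c("species", "sex")) {
    if (length(unique(meta[[v]])) < 2L ||
        min(table(meta[[v]])) < 2L) {
      stop2("need >= 2 samples per ", v, " level")
    }
  }
  design <- model.matrix(~ replicate + sex + species, data = meta)
  sp_coef <- grep("^species", colnames(design), value = TRUE)
  sx_coef <- grep("^sex", colnames(design), value = TRUE)
  if (length(sp_coef) != 1L || length(sx_coef) != 1L) {
    stop2("species and sex must each have exactly two levels")
  }
  tab <- glm_test_table(m, design, coefs = c(sp_coef, sx_coef),
                        min_total = 0)
  tab$contrast <- ifelse(tab$coef == sp_coef, "species", "sex")
  tab$cluster <- tab$feature
  tab$candidate <- !is.na(tab$fdr) & tab$fdr < fdr_threshold
  tab$low_confidence <- rowSums(m)[tab$cluster] < min_cells
  tab[c("cluster", "contrast", "log2_fold_change", "p_value", "fdr",
        "candidate", "low_confidence")]
}

# Accepts metadata keyed by rownames or a `sample` column; reorders to the
# given sample set and fixes factor codings (A/F as reference levels).
normalize_sample_meta <- function(sample_metadata, samples) {
  meta <- as.data.frame(sample_metadata)
  if (!is.null(meta$sample)) rownames(meta) <- meta$sample
  if (!all(samples %in% rownames(meta))) {
    stop2("sample metadata missing sample(s): ",
          paste(setdiff(samples, rownames(meta)), collapse = ", "))
  }
  meta <- meta[samples, , drop = FALSE]
  need <- c("replicate", "species", "sex")
  if (!all(need %in% names(meta))) {
    stop2("sample metadata needs columns: ", paste(need, collapse = ", "))
  }
  meta$replicate <- factor(meta$replicate)
  meta$species <- factor(meta$species)
  meta$sex <- factor(meta$sex)
  meta
}
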