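#' Bin genes by expression level
#'
#' Assigns every gene to a half-open expression bin of width 0.5 in
#' log10(CPM): bin id \code{floor(log10(CPM) / 0.5)}. Genes with zero CPM
#' are set aside in a dedicated \code{"zero"} bin that participates in
#' background matching like any other bin.
#'
#' @param cpm Named numeric vector of counts-per-million per gene.
#' @return Object of class \code{"expression_bins"}: \code{bin} (named
#'   character vector of bin ids) and \code{members} (genes per bin).
#' @export
bin_genes_by_expression <- function(cpm) {
  if (is.null(names(cpm))) stop2("cpm must be named by gene")
  if (any(cpm < 0)) stop2("negative CPM")
  bin <- ifelse(cpm == 0, "zero",
                as.character(floor(log10(cpm) / 0.5)))
  names(bin) <- names(cpm)
  structure(list(bin = bin, members = split(names(cpm), bin)),
            class = "expression_bins")
}

#' @export
print.expression_bins <- function(x, ...) {
  cat("expression_bins:", length(x$bin), "genes in", length(x$members),
      "bins of 0.5 log10(CPM)\n")
  invisible(x)
}

#' Expression level used to match a multi-cluster DE gene
#'
#' A gene differentially expressed in several cell types is matched at the
#' highest of its expression levels over the clusters where it is DE.
#'
#' @param gene Gene id.
#' @param per_cluster_expression Named numeric vector (or one row of a CPM
#'   matrix): the gene's CPM per cluster.
#' @param de_clusters Clusters in which the gene is DE.
#' @return The CPM value to use for expression matching.
#' @export
resolve_foreground_expression <- function(gene, per_cluster_expression,
                                          de_clusters) {
  if (length(de_clusters) == 0L) {
    stop2("gene ", gene, " is not DE in any cluster")
  }
  missing <- setdiff(de_clusters, names(per_cluster_expression))
  if (length(missing)) {
    stop2("no expression value for cluster(s): ",
          paste(missing, collapse = ", "))
  }
  max(per_cluster_expression[de_clusters])
}

#' Matched CPM for every foreground gene
#'
#' Vectorized wrapper over [resolve_foreground_expression()]: from a gene x
#' cluster CPM matrix and a (gene, cluster) DE table, the per-gene maximum
#' CPM over the clusters where the gene is DE.
#'
#' @param cpm_matrix Genes x clusters CPM matrix.
#' @param de_table Data frame with columns \code{gene}, \code{cluster}.
#' @return Named numeric vector, one matched CPM per unique DE gene.
#' @export
foreground_expression <- function(cpm_matrix, de_table) {
  stopifnot(all(c("gene", "cluster") %in% names(de_table)))
  genes <- unique(de_table$gene)
  setNames(vapply(genes, function(g) {
    resolve_foreground_expression(
      g, cpm_matrix[g, ], de_table$cluster[de_table$gene == g])
  }, numeric(1)), genes)
}

#' Draw one expression-matched background list
#'
#' For each foreground gene, draws one gene uniformly from the same
#' expression bin of the entire dataset. Draws are independent across
#' foreground genes (repeats are possible) and foreground genes are not
#' excluded from their own bins.
#'
#' @param foreground_bins Character vector: bin id per foreground gene.
#' @param bins An \code{"expression_bins"}.
#' @return Character vector of background genes, aligned with the
#'   foreground.
#' @export
sample_matched_background <- function(foreground_bins, bins) {
  stopifnot(inherits(bins, "expression_bins"))
  vapply(foreground_bins, function(b) {
    members <- bins$members[[b]]
    if (is.null(members) || length(members) == 0L) {
      stop2("empty expression bin '", b, "'")
    }
    members[sample.int(length(members), 1L)]
  }, character(1), USE.NAMES = FALSE)
}

#' Expression-matched permutation test for gene-category enrichment
#'
#' Compares the number of foreground (e.g. differentially expressed) genes
#' in each category with the counts in \code{B} random background lists
#' matched to the foreground's expression-bin profile. The empirical
#' p-value is \code{k/B}, where \code{k} is the number of background lists
#' containing an equal or higher category count; when \code{k = 0} the
#' resolution bound \code{1/B} is reported (flagged in \code{p_is_bound}).
#' The enrichment score is the foreground count divided by the mean
#' background count (\code{Inf} when the category is never sampled). BH FDR
#' is applied across the tested categories.
#'
#' @param foreground Character vector of foreground genes (each must be in
#'   the binned universe).
#' @param categories Named list of gene vectors, or a data frame with
#'   columns \code{gene}, \code{category}.
#' @param bins An \code{"expression_bins"} over the whole dataset.
#' @param B Number of background resamples (default 5000).
#' @param seed Integer seed for the resampling stream.
#' @param foreground_bins Optional per-foreground-gene bin ids overriding
#'   the universe assignment (used to match a multi-cluster DE gene at its
#'   highest DE-cluster expression, cf.
#'   [resolve_foreground_expression()]).
#' @return Data frame of class \code{"enrichment_result"}: \code{category},
#'   \code{n_foreground}, \code{mean_background}, \code{enrichment_score},
#'   \code{empirical_p}, \code{p_is_bound}, \code{fdr}, \code{B},
#'   \code{in_universe}.
#' @export
enrichment_test <- function(foreground, categories, bins, B = 5000L,
                            seed = 1L, foreground_bins = NULL) {
  stopifnot(inherits(bins, "expression_bins"))
  B <- check_count(B, "B", min = 1)
  if (length(foreground) == 0L) stop2("empty foreground")
  if (is.data.frame(categories)) {
    categories <- split(categories$gene, categories$category)
  }
  universe <- names(bins$bin)
  if (!all(foreground %in% universe)) {
    stop2("foreground gene(s) not in the binned universe: ",
          paste(head(setdiff(foreground, universe), 5), collapse = ", "))
  }
  fg_bins <- if (is.null(foreground_bins)) bins$bin[foreground] else {
    stopifnot(length(foreground_bins) == length(foreground))
    foreground_bins
  }
  for (b in unique(fg_bins)) {
    if (length(bins$members[[b]]) == 0L) stop2("empty expression bin '", b, "'")
  }

  cat_names <- names(categories)
  in_universe <- vapply(categories,
                        function(g) any(g %in% universe), logical(1))
  membership <- vapply(categories, function(g) universe %in% g,
                       logical(length(universe)))  # universe x categories
  rownames(membership) <- universe
  fg_count <- colSums(membership[foreground, , drop = FALSE])

  bg_counts <- with_seed(seed, {
    acc <- matrix(0L, nrow = B, ncol = length(categories))
    for (b in unique(fg_bins)) {
      members <- bins$members[[b]]
      n_here <- sum(fg_bins == b)
      draws <- matrix(sample.int(length(members), B * n_here,
                                 replace = TRUE), nrow = B)
      memb_b <- membership[members, , drop = FALSE]
      for (j in seq_along(categories)) {
        acc[, j] <- acc[, j] +
          as.integer(rowSums(matrix(memb_b[, j][draws], nrow = B)))
      }
    }
    acc
  })

  k <- vapply(seq_along(categories),
              function(j) sum(bg_counts[, j] >= fg_count[j]), integer(1))
  mean_bg <- colMeans(bg_counts)
  p <- ifelse(k == 0, 1 / B, k / B)
  score <- ifelse(mean_bg > 0, fg_count / mean_bg,
                  ifelse(fg_count > 0, Inf, NaN))
  res <- data.frame(
    category = cat_names,
    n_foreground = as.integer(fg_count),
    mean_background = mean_bg,
    enrichment_score = score,
    empirical_p = p,
    p_is_bound = k == 0,
    fdr = bh_fdr(p),
    B = B,
    in_universe = in_universe,
    row.names = NULL
  )
  class(res) <- c("enrichment_result", "data.frame")
  res
}

#' Counts-per-million
#'
#' @param counts Count matrix (features x samples) or vector.
#' @return CPM on the same shape.
#' @export
cpm <- function(counts) {
  if (is.null(dim(counts))) return(counts / sum(counts) * 1e6)
  m <- as.matrix(counts)
  sweep(m, 2L, colSums(m), `/`) * 1e6
}
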