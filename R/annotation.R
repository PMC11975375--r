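# Reference cell-type labels that map indiscriminately onto many clusters
# and lack distinctive markers; removed before homology thresholding.
DEFAULT_EXCLUDED_LABELS <- c("e1:Glut", "i1:Gaba", "i7:Gaba", "i9:Gaba",
                             "i11:Gaba", "i13:Gaba", "i12:Gaba", "i15:Gaba",
                             "i39:Gaba")

#' Classify clusters as inhibitory or excitatory
#'
#' A cluster is inhibitory when its mean expression of the GABAergic
#' markers \code{Gad1} and \code{Gad2} exceeds that of the glutamatergic
#' marker \code{Slc17a6}, excitatory when strictly lower, and unassigned on
#' an exact tie (including the all-zero case). The two inhibitory markers
#' are aggregated by their mean by default (\code{aggregate = "max"} uses
#' the larger of the two instead).
#'
#' @param cluster_means Matrix of normalized mean expression, clusters x
#'   genes (must contain columns \code{Gad1}, \code{Gad2},
#'   \code{Slc17a6}), or a genes x clusters matrix with those rows.
#' @param aggregate \code{"mean"} or \code{"max"} over the two inhibitory
#'   markers.
#' @return Named character vector: \code{"inhibitory"},
#'   \code{"excitatory"} or \code{"unassigned"} per cluster.
#' @export
classify_neuron_class <- function(cluster_means,
                                  aggregate = c("mean", "max")) {
  aggregate <- match.arg(aggregate)
  markers <- c("Gad1", "Gad2", "Slc17a6")
  m <- as.matrix(cluster_means)
  if (all(markers %in% rownames(m))) m <- t(m)
  if (!all(markers %in% colnames(m))) {
    stop2("marker gene(s) missing from matrix: ",
          paste(setdiff(markers, colnames(m)), collapse = ", "))
  }
  inhib <- if (aggregate == "mean") (m[, "Gad1"] + m[, "Gad2"]) / 2
           else pmax(m[, "Gad1"], m[, "Gad2"])
  excit <- m[, "Slc17a6"]
  out <- ifelse(inhib > excit, "inhibitory",
                ifelse(inhib < excit, "excitatory", "unassigned"))
  setNames(out, rownames(m))
}

#' Per-cluster transferred-label proportions
#'
#' Row-normalized cross-tabulation: the fraction of each cluster's cells
#' carrying each transferred reference label.
#'
#' @param labels Character vector: per-cell transferred reference label.
#' @param clusters Character vector: per-cell cluster id.
#' @return Matrix clusters x labels with rows summing to 1.
#' @export
label_proportion_matrix <- function(labels, clusters) {
  if (length(labels) != length(clusters)) {
    stop2("labels and clusters must be aligned per cell")
  }
  if (length(labels) == 0L) stop2("empty cluster set")
  tab <- table(factor(clusters), factor(labels))
  if (any(rowSums(tab) == 0)) stop2("empty cluster encountered")
  m <- sweep(matrix(as.numeric(tab), nrow = nrow(tab),
                    dimnames = dimnames(tab)), 1L, rowSums(tab), `/`)
  names(dimnames(m)) <- NULL
  m
}

#' Map clusters onto reference cell-type labels
#'
#' Applies the proportion-threshold homology rule: indiscriminate reference
#' labels are removed first, then every remaining label covering at least
#' \code{min_prop} of a cluster's cells is accepted (a cluster may map to
#' several labels, and a label to several clusters); clusters with no
#' accepted label are unmapped.
#'
#' @param proportions Cluster x label proportion matrix from
#'   [label_proportion_matrix()].
#' @param excluded_labels Labels removed before thresholding; defaults to
#'   the built-in indiscriminate-label list.
#' @param min_prop Acceptance threshold (default 0.15).
#' @return Data frame of accepted pairs: \code{cluster}, \code{label},
#'   \code{proportion}; unmapped clusters appear with \code{label = NA}.
#'   The full post-exclusion proportion matrix is attached as attribute
#'   \code{"proportions"}.
#' @export
assign_homology <- function(proportions,
                            excluded_labels = DEFAULT_EXCLUDED_LABELS,
                            min_prop = 0.15) {
  check_fraction(min_prop, "min_prop")
  m <- as.matrix(proportions)
  m <- m[, !colnames(m) %in% excluded_labels, drop = FALSE]
  out <- do.call(rbind, lapply(rownames(m), function(cl) {
    hits <- which(m[cl, ] >= min_prop)
    if (length(hits) == 0L) {
      data.frame(cluster = cl, label = NA_character_,
                 proportion = NA_real_)
    } else {
      data.frame(cluster = cl, label = colnames(m)[hits],
                 proportion = unname(m[cl, hits]))
    }
  }))
  rownames(out) <- NULL
  attr(out, "proportions") <- m
  out
}

#' Validate class-consistency of transferred labels
#'
#' Checks that inhibitory reference labels were transferred only onto cells
#' of inhibitory clusters and excitatory labels only onto excitatory
#' clusters (the transfer is run separately per class, so a violation
#' indicates mislabeled input).
#'
#' @param labels,clusters Per-cell transferred label and cluster id.
#' @param cluster_class Named vector from [classify_neuron_class()].
#' @param label_class Function mapping a label to \code{"inhibitory"} /
#'   \code{"excitatory"}; the default reads the conventional \code{i} /
#'   \code{e} prefix.
#' @return Invisibly \code{TRUE}; errors on violation.
#' @export
check_label_classes <- function(labels, clusters, cluster_class,
                                label_class = prefix_label_class) {
  lc <- vapply(labels, label_class, character(1))
  cc <- cluster_class[clusters]
  bad <- !is.na(cc) & cc != "unassigned" & lc != cc
  if (any(bad)) {
    stop2(sum(bad), " cell(s) carry a transferred label whose class ",
          "conflicts with their cluster's class (e.g. label '",
          labels[bad][1], "' on a ", cc[bad][1], " cluster)")
  }
  invisible(TRUE)
}

prefix_label_class <- function(label) {
  switch(substr(label, 1, 1),
         i = "inhibitory", e = "excitatory",
         stop2("cannot infer class of label '", label, "'"))
}
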