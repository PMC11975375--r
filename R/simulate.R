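#' Simulate a genotype table for pooled samples
#'
#' Draws biallelic genotypes (0/1/2 alternate-allele copies) for each sample
#' under Hardy-Weinberg proportions at the requested minor-allele frequency,
#' resampling until every pair of samples is discriminated by at least one
#' SNP (so that genotype-based demultiplexing is well posed).
#'
#' @param n_samples Number of samples (>= 2).
#' @param n_snps Number of SNPs (>= 1).
#' @param maf Minor-allele frequency in (0, 0.5].
#' @param seed Integer seed.
#' @param max_tries Resampling budget for the discrimination requirement.
#' @return Integer matrix \code{n_samples x n_snps} with values in
#'   \{0, 1, 2\}; rownames are sample ids, colnames SNP ids.
#' @export
simulate_genotypes <- function(n_samples, n_snps, maf, seed = 1L,
                               max_tries = 100L) {
  n_samples <- check_count(n_samples, "n_samples", min = 2)
  n_snps <- check_count(n_snps, "n_snps", min = 1)
  if (!is.numeric(maf) || maf <= 0 || maf > 0.5) {
    stop2("maf must be in (0, 0.5]")
  }
  with_seed(seed, {
    for (try in seq_len(max_tries)) {
      g <- matrix(rbinom(n_samples * n_snps, 2L, maf),
                  nrow = n_samples, ncol = n_snps)
      if (all_pairs_discriminated(g)) {
        dimnames(g) <- list(paste0("s", seq_len(n_samples)),
                            sprintf("snp%04d", seq_len(n_snps)))
        return(g)
      }
    }
    stop2("could not discriminate all sample pairs with ", n_snps,
          " SNP(s) at maf ", maf, " within ", max_tries, " attempts")
  })
}

all_pairs_discriminated <- function(g) {
  n <- nrow(g)
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      if (all(g[i, ] == g[j, ])) return(FALSE)
    }
  }
  TRUE
}

#' Simulate one pooled-droplet 10x run
#'
#' Generates per-droplet read counts mapped to each of the two species'
#' genomes plus sparse per-SNP allele counts, with known truth labels.
#' Singlets carry one sample's nucleus; multiplets (pairs only) carry two
#' distinct samples whose reads are split Binomial(total, 1/2). A fraction
#' \code{mismap_rate} of each nucleus' reads leaks onto the other species'
#' genome; a droplet pooling two species therefore shows substantial reads
#' on both genomes, reproducing the two-cluster geometry that the
#' species-multiplet threshold exploits. SNP-covering reads are Poisson
#' thinned from total depth and draw alleles from the contributing sample's
#' genotype with error \code{snp_error}.
#'
#' @param config A [sim_config()].
#' @param replicate Which pool to generate (1-based).
#' @return A list of class \code{"droplet_pool"} with elements:
#'   \describe{
#'     \item{profiles}{data frame \code{barcode}, \code{reads_a},
#'       \code{reads_b}.}
#'     \item{ref, alt}{sparse droplet x SNP matrices of reference and
#'       alternate allele read counts.}
#'     \item{genotypes}{the pool's sample x SNP genotype matrix.}
#'     \item{samples}{per-sample metadata for the pool.}
#'     \item{truth}{data frame with true \code{sample1}, \code{sample2}
#'       (\code{NA} for singlets), \code{species} (\code{"A"}, \code{"B"},
#'       or \code{"AB"}), \code{multiplet}, \code{total_reads}.}
#'   }
#' @export
simulate_pooled_run <- function(config, replicate = 1L) {
  stopifnot(inherits(config, "sim_config"))
  replicate <- check_count(replicate, "replicate", min = 1)
  ids <- sample_ids(replicate)
  species_of <- setNames(rep(c("A", "B"), 2), ids)
  genotypes <- simulate_genotypes(
    length(ids), config$n_snps, config$maf,
    seed = child_seed(config$seed, paste0("genotypes", replicate))
  )
  rownames(genotypes) <- ids

  with_seed(child_seed(config$seed, paste0("pool", replicate)), {
    n <- config$n_droplets_per_pool
    total <- pmax(1L, as.integer(round(rlnorm(
      n, config$read_depth_law$meanlog, config$read_depth_law$sdlog
    ))))
    mult <- runif(n) < config$multiplet_rate
    i1 <- sample.int(4L, n, replace = TRUE)
    # second nucleus: uniform over the three other samples
    i2 <- (i1 - 1L + sample.int(3L, n, replace = TRUE)) %% 4L + 1L
    i2[!mult] <- NA_integer_
    r1 <- ifelse(mult, rbinom(n, total, 0.5), total)
    r2 <- total - r1

    leak1 <- rbinom(n, r1, config$mismap_rate)
    leak2 <- rbinom(n, r2, config$mismap_rate)
    sp1 <- species_of[ids[i1]]
    sp2 <- ifelse(mult, species_of[ids[i2]], NA)
    to_a <- ifelse(sp1 == "A", r1 - leak1, leak1) +
      ifelse(mult & !is.na(sp2), ifelse(sp2 == "A", r2 - leak2, leak2), 0L)
    reads_a <- as.integer(to_a)
    reads_b <- total - reads_a

    barcodes <- sprintf("r%d-bc%05d", replicate, seq_len(n))
    alleles <- simulate_allele_reads(total, r1, ids[i1], ids[i2], genotypes,
                                     config$snp_read_rate, config$snp_error,
                                     n, config$n_snps)

    truth_species <- ifelse(mult & sp1 != sp2, "AB", sp1)
    pool <- list(
      profiles = data.frame(barcode = barcodes, reads_a = reads_a,
                            reads_b = reads_b),
      ref = alleles$ref, alt = alleles$alt,
      genotypes = genotypes,
      samples = data.frame(sample = ids, species = rep(c("A", "B"), 2),
                           sex = rep(c("F", "M"), each = 2),
                           row.names = ids),
      truth = data.frame(
        barcode = barcodes,
        sample1 = ids[i1],
        sample2 = ifelse(mult, ids[i2], NA_character_),
        species = unname(truth_species),
        multiplet = mult,
        total_reads = total
      ),
      replicate = paste0("r", replicate)
    )
    rownames(pool$ref) <- rownames(pool$alt) <- barcodes
    class(pool) <- "droplet_pool"
    pool
  })
}

# Read-level simulation of SNP allele observations, aggregated to sparse
# droplet x SNP ref/alt count matrices.
simulate_allele_reads <- function(total, r1, s1, s2, genotypes,
                                  rate, error, n_droplets, n_snps) {
  k <- rpois(n_droplets, total * rate)
  m <- sum(k)
  dims <- c(n_droplets, n_snps)
  dn <- list(NULL, colnames(genotypes))
  if (m == 0L) {
    z <- Matrix::sparseMatrix(i = integer(), j = integer(), x = numeric(),
                              dims = dims, dimnames = dn)
    return(list(ref = z, alt = z))
  }
  drop_idx <- rep.int(seq_len(n_droplets), k)
  # source nucleus of each read, proportional to its read share
  from1 <- runif(m) < rep.int(r1 / total, k)
  src <- ifelse(from1, s1[drop_idx], s2[drop_idx])
  src[is.na(src)] <- s1[drop_idx][is.na(src)]  # singlets: all reads from s1
  snp <- sample.int(n_snps, m, replace = TRUE)
  g <- genotypes[cbind(match(src, rownames(genotypes)), snp)]
  p_alt <- c(error, 0.5, 1 - error)[g + 1L]
  is_alt <- runif(m) < p_alt
  agg <- function(keep) {
    Matrix::sparseMatrix(i = drop_idx[keep], j = snp[keep],
                         x = rep(1, sum(keep)), dims = dims, dimnames = dn)
  }
  list(ref = agg(!is_alt), alt = agg(is_alt))
}

#' @export
print.droplet_pool <- function(x, ...) {
  cat("droplet_pool:", nrow(x$profiles), "droplets,",
      ncol(x$ref), "SNPs,", nrow(x$genotypes), "samples,",
      sum(x$truth$multiplet), "true multiplets\n")
  invisible(x)
}

#' Simulate a cluster-structured single-nucleus count matrix
#'
#' Generates a sparse genes x cells count matrix over all samples of the
#' experiment with known differential-abundance and differential-expression
#' truth. Cells are assigned to clusters by a per-sample multinomial whose
#' baseline proportions follow a decreasing power-law-like profile; planted
#' abundance effects multiply a cluster's probability for species B (or
#' males). Gene counts are negative binomial with log-normal baseline means,
#' mild cluster-specific profiles, and planted expression fold changes.
#' Four synthetic marker genes are appended: \code{Gad1}/\code{Gad2} (high
#' in inhibitory clusters), \code{Slc17a6} (high in excitatory clusters) and
#' \code{Xist}, expressed only in female cells.
#'
#' @param config A [sim_config()].
#' @return A list of class \code{"atlas_sim"} with \code{counts} (sparse
#'   genes x cells), \code{cell_metadata} (\code{cell}, \code{sample},
#'   \code{replicate}, \code{species}, \code{sex}, \code{cluster},
#'   \code{transferred_label}), \code{sample_metadata}, and \code{truth}
#'   (planted abundance and expression effects, per-cluster baseline
#'   proportions, cluster classes, cluster-to-reference-label map).
#' @export
simulate_atlas_counts <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  genes <- gene_names(config)
  clusters <- cluster_ids(config$n_clusters)
  check_effect_refs(config, genes, clusters)
  meta <- sample_metadata(config)

  with_seed(child_seed(config$seed, "atlas"), {
    n_cl <- config$n_clusters
    base_prop <- sort(rgamma(n_cl, shape = 1), decreasing = TRUE)
    base_prop <- base_prop / sum(base_prop)
    names(base_prop) <- clusters

    cl_class <- setNames(rep(c("inhibitory", "excitatory"), length.out = n_cl),
                         clusters)
    # reference labels for the label-transfer emulation, one per cluster,
    # drawn from a smaller label pool so several clusters can share a label
    pool_i <- sprintf("iL%02d", seq_len(max(2L, ceiling(n_cl / 3))))
    pool_e <- sprintf("eL%02d", seq_len(max(2L, ceiling(n_cl / 3))))
    cl_label <- ifelse(cl_class == "inhibitory",
                       sample(pool_i, n_cl, replace = TRUE),
                       sample(pool_e, n_cl, replace = TRUE))
    names(cl_label) <- clusters

    lambda <- rlnorm(config$n_genes, meanlog = log(0.2), sdlog = 1)
    names(lambda) <- genes[seq_len(config$n_genes)]
    # mild cluster-specific expression profile, shared by all samples
    cl_profile <- matrix(rlnorm(config$n_genes * n_cl, 0, 0.3),
                         nrow = config$n_genes,
                         dimnames = list(names(lambda), clusters))

    cells <- list()
    counts <- list()
    for (s in meta$sample) {
      sp <- meta[s, "species"]; sx <- meta[s, "sex"]
      prob <- base_prop
      ae <- config$abundance_effects
      if (!is.null(ae) && nrow(ae)) {
        for (k in seq_len(nrow(ae))) {
          hit <- (ae$covariate[k] == "species" && sp == "B") ||
            (ae$covariate[k] == "sex" && sx == "M")
          if (hit) prob[ae$cluster[k]] <- prob[ae$cluster[k]] * ae$fold[k]
        }
        prob <- prob / sum(prob)
      }
      n_cells <- config$cells_per_sample
      cl <- sample(clusters, n_cells, replace = TRUE, prob = prob)
      cell_ids <- paste(s, sprintf("cell%04d", seq_len(n_cells)), sep = ".")
      size <- rlnorm(n_cells, 0, 0.3)
      mu <- lambda * cl_profile[, cl, drop = FALSE]  # genes x cells
      mu <- sweep(mu, 2L, size, `*`)
      mu <- apply_expression_effects(mu, cl, sp, sx,
                                     config$expression_effects)
      y <- draw_nb(mu, config$dispersion)
      y <- rbind(y, marker_rows(cl, cl_class, sx, size, config$dispersion))
      rownames(y) <- genes
      colnames(y) <- cell_ids
      counts[[s]] <- methods::as(Matrix::Matrix(y, sparse = TRUE),
                                 "CsparseMatrix")
      lab <- ifelse(runif(n_cells) < 0.8, cl_label[cl],
                    ifelse(cl_class[cl] == "inhibitory",
                           sample(pool_i, n_cells, replace = TRUE),
                           sample(pool_e, n_cells, replace = TRUE)))
      cells[[s]] <- data.frame(
        cell = cell_ids, sample = s, replicate = meta[s, "replicate"],
        species = sp, sex = sx, cluster = cl,
        transferred_label = unname(lab)
      )
    }
    cell_metadata <- do.call(rbind, cells)
    rownames(cell_metadata) <- cell_metadata$cell
    out <- list(
      counts = do.call(cbind, counts),
      cell_metadata = cell_metadata,
      sample_metadata = meta,
      truth = list(
        abundance_effects = config$abundance_effects,
        expression_effects = config$expression_effects,
        base_proportions = base_prop,
        cluster_class = cl_class,
        cluster_label = cl_label,
        category_map = category_map_for(config)
      )
    )
    class(out) <- "atlas_sim"
    out
  })
}

check_effect_refs <- function(config, genes, clusters) {
  ae <- config$abundance_effects
  if (!is.null(ae) && nrow(ae) && !all(ae$cluster %in% clusters)) {
    stop2("abundance_effects references unknown cluster(s): ",
          paste(setdiff(ae$cluster, clusters), collapse = ", "))
  }
  ee <- config$expression_effects
  if (!is.null(ee) && nrow(ee)) {
    if (!all(ee$cluster %in% clusters)) {
      stop2("expression_effects references unknown cluster(s): ",
            paste(setdiff(ee$cluster, clusters), collapse = ", "))
    }
    if (!all(ee$gene %in% genes)) {
      stop2("expression_effects references unknown gene(s): ",
            paste(setdiff(ee$gene, genes), collapse = ", "))
    }
  }
  invisible(TRUE)
}

apply_expression_effects <- function(mu, cl, species, sex, effects) {
  if (is.null(effects) || !nrow(effects)) return(mu)
  for (k in seq_len(nrow(effects))) {
    cov <- effects$covariate[k]
    hit <- switch(cov,
      "species" = species == "B",
      "sex" = sex == "M",
      "sex:A" = species == "A" && sex == "M",
      "sex:B" = species == "B" && sex == "M"
    )
    if (hit) {
      cols <- cl == effects$cluster[k]
      if (any(cols) && effects$gene[k] %in% rownames(mu)) {
        mu[effects$gene[k], cols] <- mu[effects$gene[k], cols] *
          effects$fold[k]
      }
    }
  }
  mu
}

draw_nb <- function(mu, dispersion) {
  y <- if (dispersion > 0) {
    rnbinom(length(mu), size = 1 / dispersion, mu = as.vector(mu))
  } else {
    rpois(length(mu), as.vector(mu))
  }
  matrix(y, nrow = nrow(mu))
}

# Gad1/Gad2 high in inhibitory clusters, Slc17a6 in excitatory; Xist is
# strictly female-only by construction.
marker_rows <- function(cl, cl_class, sex, size, dispersion) {
  inhib <- cl_class[cl] == "inhibitory"
  mu_gad <- ifelse(inhib, 3, 0.05) * size
  mu_slc <- ifelse(inhib, 0.05, 3) * size
  mu_xist <- if (sex == "F") 2 * size else rep(0, length(size))
  rbind(
    Gad1 = draw_nb(matrix(mu_gad, 1), dispersion),
    Gad2 = draw_nb(matrix(mu_gad, 1), dispersion),
    Slc17a6 = draw_nb(matrix(mu_slc, 1), dispersion),
    Xist = draw_nb(matrix(mu_xist, 1), dispersion)
  )
}

category_map_for <- function(config) {
  if (!is.null(config$category_map)) return(config$category_map)
  ee <- config$expression_effects
  de_genes <- if (!is.null(ee)) unique(ee$gene[ee$covariate == "species"])
              else character()
  extra <- setdiff(sprintf("g%04d", seq_len(min(200L, config$n_genes))),
                   de_genes)
  rbind(
    data.frame(gene = c(de_genes, head(extra, 10)), category = "catA"),
    data.frame(gene = head(rev(extra), 50), category = "catB")
  )
}

#' @export
print.atlas_sim <- function(x, ...) {
  cat("atlas_sim:", nrow(x$counts), "genes x", ncol(x$counts), "cells,",
      length(unique(x$cell_metadata$cluster)), "clusters,",
      nrow(x$sample_metadata), "samples\n")
  invisible(x)
}
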