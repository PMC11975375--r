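#' Write a count matrix as a 10x-style Matrix Market directory
#'
#' Writes \code{matrix.mtx} (triplet format), \code{features.tsv} and
#' \code{barcodes.tsv}, uncompressed.
#'
#' @param counts Genes x cells matrix (sparse or dense) with dimnames.
#' @param dir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_10x <- function(counts, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  m <- methods::as(Matrix::Matrix(counts, sparse = TRUE), "CsparseMatrix")
  Matrix::writeMM(m, file.path(dir, "matrix.mtx"))
  writeLines(rownames(m), file.path(dir, "features.tsv"))
  writeLines(colnames(m), file.path(dir, "barcodes.tsv"))
  invisible(dir)
}

#' Read a 10x-style Matrix Market directory
#'
#' @param dir Directory containing \code{matrix.mtx}, \code{features.tsv},
#'   \code{barcodes.tsv}.
#' @return Sparse genes x cells matrix with dimnames.
#' @export
read_10x <- function(dir) {
  mtx <- file.path(dir, "matrix.mtx")
  if (!file.exists(mtx)) stop2("no matrix.mtx in ", dir)
  m <- methods::as(Matrix::readMM(mtx), "CsparseMatrix")
  dimnames(m) <- list(readLines(file.path(dir, "features.tsv")),
                      readLines(file.path(dir, "barcodes.tsv")))
  m
}

#' Write genotypes as a minimal GT-only VCF
#'
#' Emits a VCFv4.2 file with one biallelic record per SNP and a single
#' \code{GT} FORMAT field (0/0, 0/1, 1/1 for 0, 1, 2 alternate-allele
#' copies).
#'
#' @param genotypes Sample x SNP matrix of 0/1/2 with dimnames.
#' @param path Output file.
#' @return \code{path}, invisibly.
#' @export
write_genotypes_vcf <- function(genotypes, path) {
  stopifnot(!is.null(rownames(genotypes)), !is.null(colnames(genotypes)))
  gt_code <- c("0/0", "0/1", "1/1")
  header <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", rownames(genotypes)), collapse = "\t")
  )
  rows <- vapply(seq_len(ncol(genotypes)), function(j) {
    paste(c("1", j, colnames(genotypes)[j], "A", "T", ".", ".", ".", "GT",
            gt_code[genotypes[, j] + 1L]), collapse = "\t")
  }, character(1))
  writeLines(c(header, rows), path)
  invisible(path)
}

#' Read a GT-only VCF into a genotype matrix
#'
#' Parses only the GT field (the first colon-separated entry of each
#' sample column); phased separators are accepted.
#'
#' @param path VCF file.
#' @return Sample x SNP integer matrix of alternate-allele copies
#'   (\code{NA} for missing genotypes).
#' @export
read_genotypes_vcf <- function(path) {
  if (!file.exists(path)) stop2("VCF not found: ", path)
  lines <- readLines(path)
  hdr <- grep("^#CHROM", lines)
  if (length(hdr) != 1L) stop2("malformed VCF: no #CHROM header")
  cols <- strsplit(lines[hdr], "\t")[[1]]
  samples <- cols[-(1:9)]
  body <- lines[-seq_len(hdr)]
  body <- body[nzchar(body)]
  g <- matrix(NA_integer_, nrow = length(samples), ncol = length(body),
              dimnames = list(samples, NULL))
  ids <- character(length(body))
  for (k in seq_along(body)) {
    f <- strsplit(body[k], "\t")[[1]]
    ids[k] <- f[3]
    gt <- sub(":.*", "", f[-(1:9)])
    alleles <- strsplit(gt, "[/|]")
    g[, k] <- vapply(alleles, function(a) {
      if (any(a == ".")) NA_integer_ else sum(as.integer(a))
    }, integer(1))
  }
  colnames(g) <- ids
  g
}

#' Write a droplet pool to plain-text files
#'
#' Writes \code{reads.tsv} (barcode, reads_a, reads_b),
#' \code{alleles.tsv} (barcode, snp, ref, alt; nonzero entries only),
#' \code{genotypes.vcf}, \code{samples.tsv}, and \code{truth.tsv} when
#' truth labels are present.
#'
#' @param pool A \code{"droplet_pool"}.
#' @param dir Output directory.
#' @return \code{dir}, invisibly.
#' @export
write_droplet_pool <- function(pool, dir) {
  stopifnot(inherits(pool, "droplet_pool"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_tsv(pool$profiles, file.path(dir, "reads.tsv"))
  tri_r <- Matrix::summary(pool$ref)
  tri_a <- Matrix::summary(pool$alt)
  key_r <- paste(tri_r$i, tri_r$j)
  key_a <- paste(tri_a$i, tri_a$j)
  keys <- union(key_r, key_a)
  ij <- do.call(rbind, strsplit(keys, " "))
  i <- as.integer(ij[, 1]); j <- as.integer(ij[, 2])
  alleles <- data.frame(
    barcode = pool$profiles$barcode[i],
    snp = colnames(pool$ref)[j],
    ref = as.vector(pool$ref[cbind(i, j)]),
    alt = as.vector(pool$alt[cbind(i, j)])
  )
  alleles <- alleles[order(i, j), ]
  write_tsv(alleles, file.path(dir, "alleles.tsv"))
  write_genotypes_vcf(pool$genotypes, file.path(dir, "genotypes.vcf"))
  write_tsv(pool$samples, file.path(dir, "samples.tsv"))
  if (!is.null(pool$truth)) write_tsv(pool$truth, file.path(dir, "truth.tsv"))
  invisible(dir)
}

#' Read a droplet pool from plain-text files
#'
#' Inverse of [write_droplet_pool()]; \code{reads}, \code{alleles} and
#' \code{vcf} may also be given as explicit paths.
#'
#' @param dir Directory written by [write_droplet_pool()], or \code{NULL}
#'   when all three paths are supplied.
#' @param reads,alleles,vcf,samples Optional explicit file paths.
#' @return A \code{"droplet_pool"}.
#' @export
read_droplet_pool <- function(dir = NULL, reads = NULL, alleles = NULL,
                              vcf = NULL, samples = NULL) {
  pick <- function(p, f) if (!is.null(p)) p else file.path(dir, f)
  reads <- pick(reads, "reads.tsv")
  alleles <- pick(alleles, "alleles.tsv")
  vcf <- pick(vcf, "genotypes.vcf")
  samples <- pick(samples, "samples.tsv")
  for (f in c(reads, alleles, vcf, samples)) {
    if (!file.exists(f)) stop2("input file not found: ", f)
  }
  profiles <- read_tsv(reads)
  genotypes <- read_genotypes_vcf(vcf)
  al <- read_tsv(alleles)
  i <- match(al$barcode, profiles$barcode)
  j <- match(al$snp, colnames(genotypes))
  if (anyNA(i) || anyNA(j)) {
    stop2("alleles.tsv references unknown barcode(s) or SNP(s)")
  }
  dims <- c(nrow(profiles), ncol(genotypes))
  dn <- list(profiles$barcode, colnames(genotypes))
  pool <- list(
    profiles = profiles,
    ref = Matrix::sparseMatrix(i = i, j = j, x = al$ref, dims = dims,
                               dimnames = dn),
    alt = Matrix::sparseMatrix(i = i, j = j, x = al$alt, dims = dims,
                               dimnames = dn),
    genotypes = genotypes,
    samples = read_tsv(samples)
  )
  truth_path <- file.path(if (is.null(dir)) dirname(reads) else dir,
                          "truth.tsv")
  if (file.exists(truth_path)) pool$truth <- read_tsv(truth_path)
  class(pool) <- "droplet_pool"
  pool
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path) {
  read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
             check.names = FALSE)
}
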