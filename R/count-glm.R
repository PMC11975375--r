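#' TMM normalization factors
#'
#' Trimmed-mean-of-M-values factors (computed via edgeR's
#' \code{calcNormFactors}): for each sample, the precision-weighted mean of
#' log2 count ratios against a reference sample, after trimming the most
#' extreme \code{trim_m} of M-values and \code{trim_a} of A-values, is
#' exponentiated; factors are rescaled to have geometric mean 1.
#'
#' @param counts Non-negative count matrix (features x samples).
#' @param trim_m M-value trim fraction (default 0.30).
#' @param trim_a A-value trim fraction (default 0.05).
#' @return Numeric vector of per-sample normalization factors.
#' @export
tmm_factors <- function(counts, trim_m = 0.30, trim_a = 0.05) {
  counts <- as.matrix(counts)
  if (ncol(counts) < 2L) stop2("need >= 2 samples")
  if (any(counts < 0)) stop2("counts must be non-negative")
  zero <- colSums(counts) == 0
  if (any(zero)) {
    stop2("sample(s) with all-zero counts: ",
          paste(colnames(counts)[zero], collapse = ", "))
  }
  unname(edgeR::calcNormFactors(counts, method = "TMM",
                                logratioTrim = trim_m, sumTrim = trim_a))
}

#' Library-size offsets with TMM correction
#'
#' @param counts Count matrix (features x samples).
#' @param norm_factors Optional per-sample factors; computed by
#'   [tmm_factors()] if omitted.
#' @return Per-sample offsets \code{log(library size x factor)}.
#' @export
tmm_offsets <- function(counts, norm_factors = NULL) {
  if (is.null(norm_factors)) norm_factors <- tmm_factors(counts)
  log(colSums(as.matrix(counts)) * norm_factors)
}

#' Estimate negative-binomial dispersions
#'
#' Per-feature tagwise dispersions with empirical-Bayes shrinkage toward a
#' common/trended value (edgeR's \code{estimateDisp} with default
#' parameters). Features with all-zero counts are returned as \code{NA}.
#'
#' @param counts Count matrix (features x samples).
#' @param design Full-rank design matrix.
#' @return Numeric vector of per-feature dispersions (NA for all-zero
#'   features).
#' @export
estimate_dispersion <- function(counts, design) {
  counts <- as.matrix(counts)
  if (qr(design)$rank < ncol(design)) stop2("design matrix is rank-deficient")
  disp <- edgeR::estimateDisp(counts, design)$tagwise.dispersion
  disp <- rep_len(disp, nrow(counts))
  disp[rowSums(counts) == 0] <- NA_real_
  disp
}

#' Fit negative-binomial log-linear models
#'
#' Fits \code{log mu = X beta + offset} per feature under NB(mu, phi)
#' (edgeR's \code{glmFit}; Fisher-scoring IRLS). Features whose estimated
#' coefficients are extreme (complete separation: a design group entirely
#' zero) are flagged; their estimates are the capped values the fitter
#' returns and their tests are reported as \code{NA}.
#'
#' @param counts Count matrix (features x samples).
#' @param design Design matrix (samples x coefficients).
#' @param offsets Per-sample offsets, typically [tmm_offsets()].
#' @param dispersion Scalar or per-feature NB dispersion (0 = Poisson).
#' @param cap Natural-log magnitude beyond which a non-intercept
#'   coefficient is reported as capped (complete separation: one design
#'   group entirely zero). Capped features keep valid likelihood-ratio
#'   tests; only features carrying no information at all (all counts zero)
#'   are flagged \code{separated} and get \code{NA} tests.
#' @return List of class \code{"nb_fit"}: the edgeR fit plus
#'   \code{separated} and \code{capped} (logical per feature).
#' @export
fit_nb_glm <- function(counts, design, offsets, dispersion, cap = 15) {
  counts <- as.matrix(counts)
  if (qr(design)$rank < ncol(design)) stop2("design matrix is rank-deficient")
  disp <- ifelse(is.na(dispersion), 0, dispersion)
  fit <- edgeR::glmFit(counts, design = design, offset = offsets,
                       dispersion = disp, prior.count = 0)
  co <- fit$coefficients
  capped <- apply(abs(co[, -1, drop = FALSE]) > cap, 1L, any)
  separated <- rowSums(counts) == 0
  structure(list(fit = fit, separated = unname(separated),
                 capped = unname(capped) & !unname(separated),
                 design = design), class = "nb_fit")
}

#' Likelihood-ratio test for one coefficient
#'
#' Nested-model comparison dropping the named coefficient, with a chi-square
#' (1 df) reference (edgeR's \code{glmLRT}). Separation-flagged features get
#' \code{NA} p-values.
#'
#' @param nb_fit An \code{"nb_fit"} from [fit_nb_glm()].
#' @param coef Coefficient name (must be a design column).
#' @return Data frame with \code{log2_fold_change}, \code{p_value} per
#'   feature.
#' @export
test_coefficient <- function(nb_fit, coef) {
  stopifnot(inherits(nb_fit, "nb_fit"))
  if (!coef %in% colnames(nb_fit$design)) {
    stop2("coefficient '", coef, "' not in design: ",
          paste(colnames(nb_fit$design), collapse = ", "))
  }
  lrt <- edgeR::glmLRT(nb_fit$fit, coef = coef)
  p <- lrt$table$PValue
  p[nb_fit$separated] <- NA_real_
  data.frame(log2_fold_change = lrt$table$logFC, p_value = p,
             row.names = rownames(nb_fit$fit$coefficients))
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted q-values; \code{NA} p-values are excluded from the
#' family size m and returned as \code{NA}.
#'
#' @param p_values Numeric vector of p-values in \[0, 1\] (NAs allowed).
#' @return Numeric vector of q-values, same length and order.
#' @export
bh_fdr <- function(p_values) {
  ok <- !is.na(p_values)
  if (any(p_values[ok] < 0 | p_values[ok] > 1)) {
    stop2("p-values must lie in [0, 1]")
  }
  q <- rep(NA_real_, length(p_values))
  q[ok] <- p.adjust(p_values[ok], method = "BH")
  q
}

#' Full per-feature GLM test table
#'
#' Convenience wrapper running [tmm_factors()], [estimate_dispersion()],
#' [fit_nb_glm()] and [test_coefficient()] for one or more coefficients,
#' with BH FDR within each coefficient's family. Features with total count
#' below \code{min_total} are dropped before testing.
#'
#' @param counts Count matrix (features x samples).
#' @param design Design matrix.
#' @param coefs Character vector of design columns to test.
#' @param min_total Minimum total count for a feature to enter testing.
#' @param norm_factors Optional precomputed TMM factors.
#' @return Data frame: \code{feature}, \code{coef}, \code{log2_fold_change},
#'   \code{p_value}, \code{fdr}, \code{dispersion}.
#' @export
glm_test_table <- function(counts, design, coefs, min_total = 10,
                           norm_factors = NULL) {
  counts <- as.matrix(counts)
  keep <- rowSums(counts) >= min_total
  if (!any(keep)) {
    return(data.frame(feature = character(), coef = character(),
                      log2_fold_change = numeric(), p_value = numeric(),
                      fdr = numeric(), dispersion = numeric()))
  }
  offsets <- tmm_offsets(counts, norm_factors)
  kept <- counts[keep, , drop = FALSE]
  disp <- estimate_dispersion(kept, design)
  fit <- fit_nb_glm(kept, design, offsets, disp)
  do.call(rbind, lapply(coefs, function(cf) {
    tab <- test_coefficient(fit, cf)
    data.frame(feature = rownames(kept), coef = cf,
               log2_fold_change = tab$log2_fold_change,
               p_value = tab$p_value, fdr = bh_fdr(tab$p_value),
               dispersion = disp, row.names = NULL)
  }))
}
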