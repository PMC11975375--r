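#' Assign each droplet's primary species by majority read count
#'
#' The species receiving the majority of a droplet's reads is called the
#' primary species; the other is secondary. Exact ties are assigned to
#' species A with a warning (ties are measure-zero in practice and such
#' droplets are typically flagged as multiplets downstream).
#'
#' @param profiles Data frame with columns \code{barcode}, \code{reads_a},
#'   \code{reads_b} (non-negative integers).
#' @return Data frame with \code{barcode}, \code{species} (\code{"A"} or
#'   \code{"B"}), \code{primary_reads}, \code{secondary_reads}.
#' @export
assign_primary_species <- function(profiles) {
  stopifnot(all(c("barcode", "reads_a", "reads_b") %in% names(profiles)))
  a <- profiles$reads_a; b <- profiles$reads_b
  if (any(a < 0 | b < 0)) stop2("read counts must be non-negative")
  if (any(a + b == 0)) {
    stop2("droplet(s) with zero total reads: ",
          paste(head(profiles$barcode[a + b == 0], 5), collapse = ", "))
  }
  ties <- a == b
  if (any(ties)) {
    warning(sum(ties), " droplet(s) with tied read counts assigned to ",
            "species A", call. = FALSE)
  }
  is_a <- a >= b
  data.frame(
    barcode = profiles$barcode,
    species = ifelse(is_a, "A", "B"),
    primary_reads = pmax(a, b),
    secondary_reads = pmin(a, b)
  )
}

#' Bin droplets by primary-genome read count
#'
#' Half-open bins \code{[k*width, (k+1)*width)} indexed from 0.
#'
#' @param primary_reads Numeric vector of primary-genome read counts.
#' @param width Bin width in reads (default 500).
#' @return Integer vector of bin indices.
#' @export
bin_by_primary_reads <- function(primary_reads, width = 500) {
  if (!is.numeric(width) || length(width) != 1L || width <= 0) {
    stop2("width must be a single positive number")
  }
  as.integer(floor(primary_reads / width))
}

#' Fit a two-component univariate Gaussian mixture by EM
#'
#' Expectation-maximization for a two-Gaussian mixture on secondary-genome
#' read counts within one primary-read bin. Initialization is deterministic
#' (component means at the 25th and 75th percentiles, pooled SD, equal
#' weights), so repeated fits on the same data agree exactly. Components are
#' reported in canonical order (mu1 < mu2). Standard deviations are floored
#' at \code{1e-6} of the data range to prevent collapse onto a single point.
#'
#' @param values Numeric vector (one bin's secondary read counts).
#' @param tol Relative log-likelihood convergence tolerance.
#' @param max_iter Maximum EM iterations.
#' @param min_values Minimum number of values required for a stable fit.
#' @param bin_index,bin_center Optional bookkeeping recorded in the result.
#' @return Object of class \code{"mixture_fit"}: \code{weights},
#'   \code{means}, \code{sds}, \code{loglik_trace}, \code{converged},
#'   \code{n}, \code{bin_index}, \code{bin_center}.
#' @export
fit_two_gaussian_mixture <- function(values, tol = 1e-6, max_iter = 500L,
                                     min_values = 50L,
                                     bin_index = NA_integer_,
                                     bin_center = NA_real_) {
  x <- as.numeric(values)
  if (anyNA(x)) stop2("values must not contain NA")
  if (length(x) < min_values) {
    stop2("need at least ", min_values, " values for a mixture fit, got ",
          length(x))
  }
  rng <- diff(range(x))
  if (rng == 0) stop2("degenerate bin: all values identical")
  sd_floor <- 1e-6 * rng

  mu <- unname(quantile(x, c(0.25, 0.75)))
  if (mu[1] == mu[2]) mu <- mu + c(-0.25, 0.25) * rng
  sig <- rep(max(sd(x), sd_floor), 2)
  w <- c(0.5, 0.5)

  trace <- numeric(0)
  ll_old <- -Inf
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    d1 <- w[1] * dnorm(x, mu[1], sig[1])
    d2 <- w[2] * dnorm(x, mu[2], sig[2])
    tot <- d1 + d2
    tot[tot == 0] <- .Machine$double.xmin
    ll <- sum(log(tot))
    trace <- c(trace, ll)
    if (is.finite(ll_old) &&
        abs(ll - ll_old) <= tol * (abs(ll_old) + .Machine$double.eps)) {
      converged <- TRUE
      break
    }
    ll_old <- ll
    r2 <- d2 / tot
    r1 <- 1 - r2
    n1 <- sum(r1); n2 <- sum(r2)
    w <- c(n1, n2) / length(x)
    mu <- c(sum(r1 * x) / n1, sum(r2 * x) / n2)
    sig <- pmax(c(sqrt(sum(r1 * (x - mu[1])^2) / n1),
                  sqrt(sum(r2 * (x - mu[2])^2) / n2)), sd_floor)
  }
  ord <- order(mu)
  fit <- list(
    weights = w[ord], means = mu[ord], sds = sig[ord],
    loglik_trace = trace, converged = converged, n = length(x),
    bin_index = bin_index, bin_center = bin_center
  )
  class(fit) <- "mixture_fit"
  fit
}

#' @export
print.mixture_fit <- function(x, ...) {
  cat(sprintf(
    "mixture_fit (n=%d%s): w=(%.3f, %.3f), mu=(%.1f, %.1f), sd=(%.1f, %.1f), %s\n",
    x$n,
    if (is.na(x$bin_index)) "" else paste0(", bin ", x$bin_index),
    x$weights[1], x$weights[2], x$means[1], x$means[2],
    x$sds[1], x$sds[2],
    if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

#' Crossing point of two weighted Gaussian densities
#'
#' Solves \eqn{w_1 \phi(x; \mu_1, \sigma_1) = w_2 \phi(x; \mu_2, \sigma_2)}
#' for the unique root strictly between the two component means (the
#' quadratic in the log-density difference has up to two roots; only the
#' interior one separates the components).
#'
#' @param fit A \code{"mixture_fit"}, or any list with \code{weights},
#'   \code{means}, \code{sds}.
#' @return The crossing point (scalar).
#' @export
gaussian_crossing <- function(fit) {
  w <- fit$weights; mu <- fit$means; sig <- fit$sds
  if (mu[1] >= mu[2]) stop2("no interior crossing: means not separated")
  A <- 1 / (2 * sig[2]^2) - 1 / (2 * sig[1]^2)
  B <- mu[1] / sig[1]^2 - mu[2] / sig[2]^2
  C <- mu[2]^2 / (2 * sig[2]^2) - mu[1]^2 / (2 * sig[1]^2) +
    log(w[1] * sig[2]) - log(w[2] * sig[1])
  roots <- if (abs(A) < 1e-14 * (1 / sig[1]^2 + 1 / sig[2]^2)) {
    if (B == 0) numeric() else -C / B
  } else {
    disc <- B^2 - 4 * A * C
    if (disc < 0) numeric()
    else (-B + c(-1, 1) * sqrt(disc)) / (2 * A)
  }
  inside <- roots[roots > mu[1] & roots < mu[2]]
  if (length(inside) == 0L) {
    stop2("no interior crossing between component means")
  }
  inside[1]
}

#' Fit the singlet/multiplet threshold line
#'
#' Ordinary least-squares fit of per-bin mixture crossing points on bin
#' centers; the fitted line is the decision boundary between singlets and
#' cross-species multiplets in the (primary reads, secondary reads) plane.
#'
#' @param points Data frame with columns \code{bin_center},
#'   \code{crossing}.
#' @return Object of class \code{"threshold_line"} with \code{slope},
#'   \code{intercept}, \code{n_points}.
#' @export
fit_threshold_line <- function(points) {
  stopifnot(all(c("bin_center", "crossing") %in% names(points)))
  pts <- points[stats::complete.cases(points[c("bin_center", "crossing")]), ]
  if (nrow(pts) < 2L) stop2("insufficient bins: need >= 2 crossing points")
  if (length(unique(pts$bin_center)) < 2L) {
    stop2("insufficient bins: bin centers must differ")
  }
  co <- coef(lm(crossing ~ bin_center, data = pts))
  structure(list(slope = unname(co[2]), intercept = unname(co[1]),
                 n_points = nrow(pts)),
            class = "threshold_line")
}

#' @export
print.threshold_line <- function(x, ...) {
  cat(sprintf("threshold_line: secondary = %.4f * primary + %.1f (%d bins)\n",
              x$slope, x$intercept, x$n_points))
  invisible(x)
}

#' Classify droplets as singlets or cross-species multiplets
#'
#' A droplet is a species multiplet iff its secondary-genome reads exceed
#' the threshold line evaluated at its primary-genome reads.
#'
#' @param primary Data frame from [assign_primary_species()].
#' @param line A \code{"threshold_line"}.
#' @return Character vector (\code{"singlet"} / \code{"species_multiplet"}),
#'   aligned with \code{primary}.
#' @export
classify_species_multiplets <- function(primary, line) {
  stopifnot(inherits(line, "threshold_line"))
  ifelse(primary$secondary_reads >
           line$slope * primary$primary_reads + line$intercept,
         "species_multiplet", "singlet")
}

#' Fit the binned mixture threshold for one pool
#'
#' Runs the full species-multiplet thresholding procedure: bin droplets by
#' primary-genome reads, fit a two-Gaussian mixture to each sufficiently
#' populated bin's secondary-read distribution, take each fit's interior
#' crossing point, and fit the least-squares threshold line through all
#' (bin center, crossing) points. Bins with fewer than \code{min_bin_droplets}
#' droplets, degenerate bins, and bins whose mixture has no interior
#' crossing are skipped.
#'
#' In addition, a bin's crossing point is used only when the fitted
#' components are genuinely distinct populations: the means must be
#' separated by at least \code{min_separation} times the sum of the
#' component SDs, and each component must carry at least
#' \code{min_component} droplets of effective weight. Sparse bins
#' otherwise contribute spurious crossings (the mixture splits the singlet
#' cloud, or chases a couple of outliers) that corrupt the least-squares
#' line.
#'
#' @param primary Data frame from [assign_primary_species()].
#' @param bin_width Primary-read bin width (default 500).
#' @param min_bin_droplets Minimum droplets per usable bin (default 50).
#' @param min_separation Required component separation in pooled-SD units.
#' @param min_component Minimum effective droplets per component.
#' @param tol,max_iter EM settings, see [fit_two_gaussian_mixture()].
#' @return List with \code{fits} (per-bin \code{"mixture_fit"}s),
#'   \code{points} (bin centers and crossings), \code{line}
#'   (\code{"threshold_line"}).
#' @export
fit_species_threshold <- function(primary, bin_width = 500,
                                  min_bin_droplets = 50L,
                                  min_separation = 2,
                                  min_component = 5,
                                  tol = 1e-6, max_iter = 500L) {
  bins <- bin_by_primary_reads(primary$primary_reads, bin_width)
  fits <- list()
  centers <- crossings <- numeric(0)
  for (b in sort(unique(bins))) {
    v <- primary$secondary_reads[bins == b]
    if (length(v) < min_bin_droplets) next
    center <- (b + 0.5) * bin_width
    fit <- tryCatch(
      fit_two_gaussian_mixture(v, tol = tol, max_iter = max_iter,
                               min_values = min_bin_droplets,
                               bin_index = b, bin_center = center),
      error = function(e) NULL
    )
    if (is.null(fit)) next
    if (diff(fit$means) < min_separation * sum(fit$sds)) next
    if (min(fit$weights) * fit$n < min_component) next
    cp <- tryCatch(gaussian_crossing(fit), error = function(e) NULL)
    if (is.null(cp)) next
    fits[[as.character(b)]] <- fit
    centers <- c(centers, center)
    crossings <- c(crossings, cp)
  }
  points <- data.frame(bin_center = centers, crossing = crossings)
  list(fits = fits, points = points, line = fit_threshold_line(points))
}

# Per-genotype alternate-read probability under the simple binomial read
# model: hom-ref reads are alt only through error, hets are 50/50, hom-alt
# reads are alt unless erroneous.
geno_alt_prob <- function(genotypes, epsilon) {
  p <- c(epsilon, 0.5, 1 - epsilon)[genotypes + 1L]
  matrix(p, nrow = nrow(genotypes), dimnames = dimnames(genotypes))
}

#' Assign pooled samples to droplets by genotype likelihood
#'
#' A count-level stand-in for genotype-based demultiplexing: each candidate
#' sample's log-likelihood of a droplet's per-SNP allele counts is computed
#' under binomial reads whose alternate-allele probability is determined by
#' the candidate's genotype (0 -> \code{epsilon}, 1 -> 0.5, 2 ->
#' 1-\code{epsilon}). The best single sample is compared against the best
#' 50/50 two-sample mixture: the droplet is a \code{sample_multiplet} when
#' the mixture beats every singleton by at least \code{delta} log units,
#' \code{ambiguous} when the top two singletons are within \code{delta} (or
#' no informative SNP reads were observed), and a \code{singlet} otherwise.
#' Candidates are restricted to samples of the droplet's called species.
#'
#' @param ref,alt Droplet x SNP matrices of reference/alternate allele read
#'   counts (dense or sparse).
#' @param genotypes Sample x SNP genotype matrix (0/1/2).
#' @param species Character vector: each droplet's called species.
#' @param sample_species Named character vector mapping sample id ->
#'   species.
#' @param epsilon Allele-observation error rate in (0, 0.5).
#' @param delta Log-likelihood decision margin (natural-log units).
#' @return Data frame with \code{sample} (id or \code{"UNASSIGNED"}),
#'   \code{status}, \code{best_pair}, and per-droplet log-likelihood
#'   summaries \code{ll_best}, \code{ll_second}, \code{ll_pair}.
#' @export
assign_sample_by_genotype <- function(ref, alt, genotypes, species,
                                      sample_species,
                                      epsilon = 0.01, delta = 2) {
  if (epsilon <= 0 || epsilon >= 0.5) stop2("epsilon must be in (0, 0.5)")
  ref <- methods::as(ref, "matrix") * 1
  alt <- methods::as(alt, "matrix") * 1
  samples <- rownames(genotypes)
  if (is.null(samples)) stop2("genotypes must have sample rownames")
  if (!all(samples %in% names(sample_species))) {
    stop2("sample_species must name every genotyped sample")
  }
  p <- geno_alt_prob(genotypes, epsilon)              # samples x SNPs
  ll_single <- alt %*% t(log(p)) + ref %*% t(log1p(-p))  # droplets x samples

  pairs <- utils::combn(seq_along(samples), 2)
  same_sp <- sample_species[samples[pairs[1, ]]] ==
    sample_species[samples[pairs[2, ]]]
  pair_p <- (p[pairs[1, ], , drop = FALSE] + p[pairs[2, ], , drop = FALSE]) / 2
  ll_pair <- alt %*% t(log(pair_p)) + ref %*% t(log1p(-pair_p))
  pair_sp <- ifelse(same_sp, sample_species[samples[pairs[1, ]]], NA)

  n <- nrow(ref)
  out <- data.frame(
    sample = rep("UNASSIGNED", n), status = rep("ambiguous", n),
    best_pair = rep(NA_character_, n),
    ll_best = rep(NA_real_, n), ll_second = rep(NA_real_, n),
    ll_pair = rep(NA_real_, n), stringsAsFactors = FALSE
  )
  informative <- Matrix::rowSums(ref + alt) > 0
  for (i in which(informative)) {
    cand <- which(sample_species[samples] == species[i])
    if (length(cand) == 0L) next
    lls <- ll_single[i, cand]
    ordc <- order(lls, decreasing = TRUE)
    best <- lls[ordc[1]]
    second <- if (length(lls) > 1L) lls[ordc[2]] else -Inf
    pc <- which(!is.na(pair_sp) & pair_sp == species[i])
    bestp <- if (length(pc)) max(ll_pair[i, pc]) else -Inf
    out$ll_best[i] <- best; out$ll_second[i] <- second
    out$ll_pair[i] <- bestp
    if (is.finite(bestp) && bestp > best + delta) {
      j <- pc[which.max(ll_pair[i, pc])]
      out$status[i] <- "sample_multiplet"
      out$best_pair[i] <- paste(samples[pairs[, j]], collapse = "+")
    } else if (best - second < delta) {
      out$status[i] <- "ambiguous"
    } else {
      out$status[i] <- "singlet"
      out$sample[i] <- samples[cand[ordc[1]]]
    }
  }
  out
}

#' Demultiplex one pooled-droplet run
#'
#' Two-stage demultiplexing of a pooled two-species run: (1) primary-species
#' assignment and cross-species multiplet flagging via the binned
#' two-Gaussian mixture threshold; (2) genotype-likelihood sample assignment
#' within the called species for droplets passing stage 1. Droplets flagged
#' at either stage are excluded from downstream analyses.
#'
#' @param pool A \code{"droplet_pool"} (from [simulate_pooled_run()] or
#'   [read_droplet_pool()]).
#' @param bin_width,min_bin_droplets Threshold-fitting settings, see
#'   [fit_species_threshold()].
#' @param epsilon,delta Genotype-assignment settings, see
#'   [assign_sample_by_genotype()].
#' @return List of class \code{"demux_result"} with \code{calls} (per
#'   droplet: \code{barcode}, \code{species}, \code{sample},
#'   \code{status}), \code{threshold} (fits + line), and \code{summary}
#'   (droplet bookkeeping).
#' @export
demux_pool <- function(pool, bin_width = 500, min_bin_droplets = 50L,
                       epsilon = 0.01, delta = 2) {
  stopifnot(inherits(pool, "droplet_pool"))
  primary <- assign_primary_species(pool$profiles)
  thr <- fit_species_threshold(primary, bin_width = bin_width,
                               min_bin_droplets = min_bin_droplets)
  stage1 <- classify_species_multiplets(primary, thr$line)

  sample_species <- setNames(pool$samples$species, pool$samples$sample)
  geno <- assign_sample_by_genotype(pool$ref, pool$alt, pool$genotypes,
                                    primary$species, sample_species,
                                    epsilon = epsilon, delta = delta)

  status <- ifelse(stage1 == "species_multiplet", "species_multiplet",
                   geno$status)
  sample <- ifelse(status == "singlet", geno$sample, "UNASSIGNED")
  calls <- data.frame(
    barcode = primary$barcode,
    species = primary$species,
    sample = sample,
    status = status
  )
  res <- list(
    calls = calls,
    threshold = thr,
    summary = list(
      n_droplets = nrow(calls),
      n_singlets = sum(status == "singlet"),
      n_species_multiplets = sum(status == "species_multiplet"),
      n_sample_multiplets = sum(status == "sample_multiplet"),
      n_ambiguous = sum(status == "ambiguous")
    )
  )
  class(res) <- "demux_result"
  res
}

#' @export
print.demux_result <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    "demux_result: %d droplets -> %d singlets, %d species multiplets, %d sample multiplets, %d ambiguous\n",
    s$n_droplets, s$n_singlets, s$n_species_multiplets,
    s$n_sample_multiplets, s$n_ambiguous))
  invisible(x)
}
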