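test_that("primary species follows the majority rule with tie warning", {
  p <- data.frame(barcode = c("b1", "b2"), reads_a = c(900, 100),
                  reads_b = c(100, 900))
  out <- assign_primary_species(p)
  expect_equal(out$species, c("A", "B"))
  expect_equal(out$primary_reads, c(900, 900))
  expect_equal(out$secondary_reads, c(100, 100))

  tie <- data.frame(barcode = "b3", reads_a = 500, reads_b = 500)
  expect_warning(res <- assign_primary_species(tie), "tie")
  expect_equal(res$species, "A")

  expect_error(assign_primary_species(
    data.frame(barcode = "b0", reads_a = 0, reads_b = 0)), "zero total")
})

test_that("primary-read bins are half-open intervals of the given width", {
  expect_identical(bin_by_primary_reads(250), 0L)
  expect_identical(bin_by_primary_reads(500), 1L)
  expect_identical(bin_by_primary_reads(1249), 2L)
  expect_identical(bin_by_primary_reads(c(0, 499, 999, 1000), width = 500),
                   c(0L, 0L, 1L, 2L))
  expect_error(bin_by_primary_reads(10, width = 0), "positive")
})

test_that("EM recovers two-component parameters across seeds", {
  for (s in 1:10) {
    x <- withr::with_seed(s, c(rnorm(1000, 50, 5), rnorm(1000, 400, 30)))
    fit <- fit_two_gaussian_mixture(x)
    expect_true(fit$converged)
    expect_lt(abs(fit$means[1] - 50), 5)
    expect_lt(abs(fit$means[2] - 400), 5)
    # log-likelihood trace is non-decreasing on every fit
    expect_true(all(diff(fit$loglik_trace) >= -1e-8))
    expect_lt(abs(sum(fit$weights) - 1), 1e-9)
    expect_lt(fit$means[1], fit$means[2])
  }
})

test_that("EM weights are symmetric for a mirror-symmetric sample", {
  half <- withr::with_seed(11L, rnorm(1500, 4, 1))
  x <- c(half, -half)  # exactly symmetric around 0, two equal components
  fit <- fit_two_gaussian_mixture(x)
  expect_lt(abs(fit$weights[1] - 0.5), 0.05)
  expect_lt(abs(fit$weights[2] - 0.5), 0.05)
})

test_that("EM agrees with an independent mixture fitter", {
  skip_if_not_installed("mclust")
  withr::local_package("mclust")
  x <- withr::with_seed(21L, c(rnorm(800, 30, 4), rnorm(400, 200, 25)))
  fit <- fit_two_gaussian_mixture(x)
  mc <- Mclust(x, G = 2, modelNames = "V", verbose = FALSE)
  expect_lt(max(abs(sort(fit$means) - sort(mc$parameters$mean))), 2)
})

test_that("degenerate bins are rejected", {
  expect_error(fit_two_gaussian_mixture(rep(5, 100)), "degenerate")
  expect_error(fit_two_gaussian_mixture(1:10), "at least")
})

test_that("gaussian crossing matches symmetry and a grid-search oracle", {
  sym <- list(weights = c(0.5, 0.5), means = c(0, 4), sds = c(1, 1))
  expect_equal(gaussian_crossing(sym), 2, tolerance = 1e-12)

  fit <- list(weights = c(0.5, 0.5), means = c(0, 3), sds = c(1, 2))
  grid <- seq(0, 3, by = 1e-6)
  d1 <- fit$weights[1] * dnorm(grid, fit$means[1], fit$sds[1])
  d2 <- fit$weights[2] * dnorm(grid, fit$means[2], fit$sds[2])
  oracle <- grid[which.min(abs(d1 - d2))]
  expect_equal(gaussian_crossing(fit), oracle, tolerance = 1e-4)

  expect_error(gaussian_crossing(list(weights = c(.5, .5), means = c(1, 1),
                                      sds = c(1, 1))), "crossing")
  # extreme weight imbalance: no root between the means
  expect_error(gaussian_crossing(list(weights = c(1e-12, 1 - 1e-12),
                                      means = c(0, 1), sds = c(1, 1))),
               "no interior crossing")
})

test_that("crossing and classification ignore component order", {
  # canonicalization: the EM reports mu1 < mu2 regardless of data order,
  # so downstream crossings are order-invariant
  x <- withr::with_seed(31L, c(rnorm(500, 20, 3), rnorm(500, 80, 6)))
  f1 <- fit_two_gaussian_mixture(x)
  f2 <- fit_two_gaussian_mixture(rev(x))
  expect_equal(f1$means, f2$means, tolerance = 1e-8)
  expect_equal(gaussian_crossing(f1), gaussian_crossing(f2),
               tolerance = 1e-8)
})

test_that("threshold line equals the least-squares closed form", {
  exact <- fit_threshold_line(data.frame(bin_center = 0:2, crossing = 0:2))
  expect_equal(exact$slope, 1)
  expect_equal(exact$intercept, 0)

  two <- fit_threshold_line(data.frame(bin_center = c(1, 3),
                                       crossing = c(5, 1)))
  expect_equal(two$slope * 1 + two$intercept, 5)
  expect_equal(two$slope * 3 + two$intercept, 1)

  pts <- withr::with_seed(41L, data.frame(
    bin_center = seq(500, 5000, length.out = 10),
    crossing = 0.3 * seq(500, 5000, length.out = 10) + rnorm(10, 0, 20)))
  line <- fit_threshold_line(pts)
  X <- cbind(1, pts$bin_center)
  beta <- solve(t(X) %*% X, t(X) %*% pts$crossing)  # normal equations
  expect_equal(line$intercept, beta[1], tolerance = 1e-10)
  expect_equal(line$slope, beta[2], tolerance = 1e-10)

  expect_error(fit_threshold_line(data.frame(bin_center = 1, crossing = 1)),
               "insufficient")
})

test_that("droplets are classified against the line by definition", {
  line <- structure(list(slope = 0.1, intercept = 50, n_points = 5),
                    class = "threshold_line")
  prim <- data.frame(primary_reads = c(1000, 1000),
                     secondary_reads = c(10, 500))
  expect_equal(classify_species_multiplets(prim, line),
               c("singlet", "species_multiplet"))
})

test_that("genotype assignment follows the likelihood arithmetic", {
  eps <- 0.01
  # two samples, 10 SNPs where s1 is hom-alt and s2 hom-ref
  g <- rbind(s1 = rep(2L, 10), s2 = rep(0L, 10))
  colnames(g) <- sprintf("snp%02d", 1:10)
  alt <- matrix(1, 1, 10); ref <- matrix(0, 1, 10)
  sp <- c(s1 = "A", s2 = "A")
  call <- assign_sample_by_genotype(ref, alt, g, species = "A",
                                    sample_species = sp, epsilon = eps)
  expect_equal(call$status, "singlet")
  expect_equal(call$sample, "s1")
  # margin over s2 is 10 * log((1-eps)/eps)
  expect_equal(call$ll_best - call$ll_second, 10 * log((1 - eps) / eps),
               tolerance = 1e-9)

  none <- assign_sample_by_genotype(matrix(0, 1, 10), matrix(0, 1, 10),
                                    g, "A", sp)
  expect_equal(none$status, "ambiguous")
  expect_equal(none$sample, "UNASSIGNED")

  # 50/50 support from two samples' discriminating alleles -> multiplet
  alt2 <- matrix(c(rep(1, 5), rep(0, 5)), 1)   # alt reads at s1's alt SNPs
  ref2 <- matrix(c(rep(0, 5), rep(1, 5)), 1)   # ref reads where s1 is alt
  g2 <- rbind(s1 = rep(2L, 10), s2 = rep(0L, 10))
  colnames(g2) <- colnames(g)
  mix <- assign_sample_by_genotype(ref2, alt2, g2, "A", sp)
  expect_equal(mix$status, "sample_multiplet")
  expect_equal(mix$best_pair, "s1+s2")
})

test_that("scaling all read counts rescales the fitted geometry only", {
  cfg <- small_pool_config(seed = 51L)
  pool <- simulate_pooled_run(cfg)
  prim <- suppressWarnings(assign_primary_species(pool$profiles))
  thr1 <- fit_species_threshold(prim, bin_width = 500)
  prim2 <- prim
  prim2$primary_reads <- prim$primary_reads * 10
  prim2$secondary_reads <- prim$secondary_reads * 10
  thr2 <- fit_species_threshold(prim2, bin_width = 5000)
  expect_equal(thr2$line$slope, thr1$line$slope, tolerance = 1e-4)
  expect_equal(thr2$line$intercept, 10 * thr1$line$intercept,
               tolerance = 1e-4)
  f1 <- thr1$fits[[1]]; f2 <- thr2$fits[[1]]
  expect_equal(f2$means, 10 * f1$means, tolerance = 1e-4)
  expect_equal(f2$sds, 10 * f1$sds, tolerance = 1e-3)
  expect_identical(classify_species_multiplets(prim, thr1$line),
                   classify_species_multiplets(prim2, thr2$line))
})

test_that("end-to-end demultiplexing recovers truth on a synthetic pool", {
  cfg <- small_pool_config(seed = 61L)
  pool <- simulate_pooled_run(cfg)
  res <- suppressWarnings(demux_pool(pool))
  tr <- pool$truth
  called <- res$calls$status == "species_multiplet"
  truem <- tr$species == "AB"
  recall <- sum(called & truem) / sum(truem)
  precision <- sum(called & truem) / sum(called)
  expect_gte(recall, 0.90)
  expect_gte(precision, 0.90)
  sing <- !tr$multiplet
  expect_gte(mean(res$calls$species[sing] == tr$species[sing]), 0.99)
  ok <- sing & res$calls$status == "singlet"
  expect_gte(mean(res$calls$sample[ok] == tr$sample1[ok]), 0.98)
  # bookkeeping identity
  s <- res$summary
  expect_identical(s$n_droplets,
                   s$n_singlets + s$n_species_multiplets +
                     s$n_sample_multiplets + s$n_ambiguous)
})
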