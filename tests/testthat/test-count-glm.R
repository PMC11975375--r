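# Independent TMM oracle: trimmed, precision-weighted mean of M-values
# against a reference column, as in the published normalization method.
tmm_oracle <- function(counts, ref = 1, trim_m = 0.30, trim_a = 0.05) {
  lib <- colSums(counts)
  f <- vapply(seq_len(ncol(counts)), function(j) {
    if (j == ref) return(1)
    ok <- counts[, j] > 0 & counts[, ref] > 0
    y <- counts[ok, j] / lib[j]
    r <- counts[ok, ref] / lib[ref]
    M <- log2(y / r)
    A <- (log2(y) + log2(r)) / 2
    w <- 1 / ((lib[j] - counts[ok, j]) / (lib[j] * counts[ok, j]) +
                (lib[ref] - counts[ok, ref]) / (lib[ref] * counts[ok, ref]))
    n <- length(M)
    loM <- floor(n * trim_m) + 1; hiM <- n + 1 - loM
    loA <- floor(n * trim_a) + 1; hiA <- n + 1 - loA
    keep <- rank(M) >= loM & rank(M) <= hiM &
      rank(A) >= loA & rank(A) <= hiA
    2^(sum(w[keep] * M[keep]) / sum(w[keep]))
  }, numeric(1))
  f / exp(mean(log(f)))
}

test_that("TMM factors satisfy the trimmed-mean contract", {
  m <- nb_matrix(50, 3, mu = 100, phi = 0, seed = 1L)
  same <- cbind(m[, 1], m[, 1], m[, 1])
  expect_equal(tmm_factors(same), rep(1, 3))

  # pure library-size scaling carries no composition change
  scaled <- cbind(a = m[, 1], b = 2L * m[, 1])
  expect_equal(tmm_factors(scaled), c(1, 1))

  # 20-gene toy with a single 100x outlier gene: the outlier is trimmed,
  # so the factor equals the common M-value of the 19 unaffected genes
  # (the composition correction), hand-computed here
  a <- rep(50L, 20)
  b <- a; b[1] <- 5000L
  m_common <- log2((50 / sum(b)) / (50 / sum(a)))  # M of b against ref a
  expected <- c(2^(-m_common / 2), 2^(m_common / 2))  # geometric mean 1
  expect_equal(tmm_factors(cbind(a, b)), expected, tolerance = 1e-10)

  expect_error(tmm_factors(cbind(a = rep(0L, 5), b = rep(1L, 5))),
               "all-zero")
})

test_that("TMM factors match an independent trimmed-mean computation", {
  m <- nb_matrix(200, 2, mu = 80, phi = 0.2, seed = 7L)
  m[1:10, 2] <- m[1:10, 2] * 6L  # composition effect to be trimmed
  got <- tmm_factors(m)
  oracle <- list(tmm_oracle(m, ref = 1), tmm_oracle(m, ref = 2))
  err <- min(vapply(oracle, function(o) max(abs(got - o)), numeric(1)))
  expect_lt(err, 1e-8)
})

test_that("dispersion estimation flags all-zero features and bad designs", {
  m <- nb_matrix(100, 8, mu = 40, phi = 0.2, seed = 2L)
  m[5, ] <- 0L
  design <- model.matrix(~ gl(2, 4))
  d <- estimate_dispersion(m, design)
  expect_true(is.na(d[5]))
  expect_true(all(d[-5] >= 0))
  bad <- cbind(design, design[, 2])
  expect_error(estimate_dispersion(m, bad), "rank")
})

test_that("NB fit reproduces closed forms", {
  # intercept-only with equal offsets o: beta0 = log(mean(y)) - o
  y <- matrix(c(3, 7, 5, 9, 4, 8), nrow = 1)
  o <- rep(2.5, 6)
  fit <- fit_nb_glm(y, matrix(1, 6, 1), o, dispersion = 0.1)
  expect_equal(unname(fit$fit$coefficients[1, 1]), log(mean(y)) - 2.5,
               tolerance = 1e-6)

  # two-group Poisson: group coefficient = log ratio of group means
  g <- gl(2, 6)
  y2 <- matrix(c(10, 12, 8, 11, 9, 10, 20, 22, 18, 21, 19, 20), nrow = 1)
  design <- model.matrix(~ g)
  fit2 <- fit_nb_glm(y2, design, rep(0, 12), dispersion = 0)
  m1 <- mean(y2[1:6]); m2 <- mean(y2[7:12])
  expect_equal(unname(fit2$fit$coefficients[1, 2]), log(m2 / m1),
               tolerance = 1e-6)

  # all-zero feature -> no-information flag and NA test
  y3 <- rbind(y2, 0)
  fit3 <- fit_nb_glm(y3, design, rep(0, 12), dispersion = 0)
  expect_identical(fit3$separated, c(FALSE, TRUE))
  tab <- test_coefficient(fit3, "g2")
  expect_true(is.na(tab$p_value[2]))
  expect_false(is.na(tab$p_value[1]))

  # one group entirely zero: capped estimate, test still valid and small
  y4 <- matrix(c(rep(30, 6), rep(0, 6)), nrow = 1)
  fit4 <- fit_nb_glm(y4, design, rep(0, 12), dispersion = 0.05)
  expect_true(fit4$capped[1])
  expect_lt(test_coefficient(fit4, "g2")$p_value[1], 1e-3)

  expect_error(test_coefficient(fit2, "nope"), "not in design")
})

test_that("NB fit converges to the Poisson GLM as dispersion vanishes", {
  meta <- study_design(12L)
  m <- nb_matrix(5, 12, mu = 60, phi = 0, seed = 3L)
  design <- model.matrix(~ species + sex, data = meta)
  off <- log(colSums(m))
  fit <- fit_nb_glm(m, design, off, dispersion = 1e-8)
  for (i in 1:5) {
    pois <- glm(m[i, ] ~ design - 1 + offset(off), family = poisson())
    expect_lt(max(abs(fit$fit$coefficients[i, ] - coef(pois))), 1e-4)
  }
})

test_that("offsets absorb library-size differences", {
  meta <- study_design(12L)
  m <- nb_matrix(20, 12, mu = 50, phi = 0, seed = 4L)
  design <- model.matrix(~ species + sex, data = meta)
  off <- log(colSums(m))
  fit1 <- fit_nb_glm(m, design, off, dispersion = 0)
  # a global offset shift moves only the intercept, exactly
  fit2 <- fit_nb_glm(m, design, off + 3, dispersion = 0)
  expect_lt(max(abs(fit1$fit$coefficients[, -1] -
                      fit2$fit$coefficients[, -1])), 1e-8)
  expect_lt(max(abs(fit1$fit$coefficients[, 1] -
                      fit2$fit$coefficients[, 1] - 3)), 1e-8)
  # doubling one sample's counts together with its offset leaves the
  # fold-change estimates stable (it only re-weights that sample)
  m2 <- m; m2[, 3] <- m[, 3] * 2L
  off2 <- off; off2[3] <- off[3] + log(2)
  fit3 <- fit_nb_glm(m2, design, off2, dispersion = 0)
  expect_lt(max(abs(fit1$fit$coefficients[, -1] -
                      fit3$fit$coefficients[, -1])), 0.1)
})

test_that("BH adjustment reproduces step-up arithmetic and its invariants", {
  expect_equal(bh_fdr(0.04), 0.04)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))

  p <- withr::with_seed(5L, runif(100)^2)
  q <- bh_fdr(p)
  perm <- withr::with_seed(6L, sample(100))
  expect_equal(bh_fdr(p[perm]), q[perm])       # order invariance
  expect_true(all(q >= p - 1e-12))             # q >= p below the cap
  expect_true(all(q <= 1))
  # monotone in p-rank
  expect_true(all(diff(q[order(p)]) >= -1e-12))

  # NAs excluded from the family size
  p_na <- c(0.01, NA, 0.02, 0.03)
  expect_equal(bh_fdr(p_na), c(0.03, NA, 0.03, 0.03))
  expect_error(bh_fdr(c(0.5, 1.2)), "0, 1")
})

test_that("planted fold changes are recovered without systematic bias", {
  # 1.6x planted on the species covariate at the study's 24-sample design
  meta <- study_design(24L)
  design <- model.matrix(~ replicate + sex + species, data = meta)
  biases <- vapply(1:25, function(s) {
    m <- nb_matrix(2, 24, mu = 200, phi = 0.05, seed = 100 + s,
                   fold = 1.6, group = meta$species)
    # equal expected sequencing depth across samples: constant offsets
    fit <- fit_nb_glm(m, design, rep(0, 24), dispersion = 0.05)
    mean(fit$fit$coefficients[, "speciesB"] / log(2)) - log2(1.6)
  }, numeric(1))
  expect_lt(abs(mean(biases)), 0.1)
})
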