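test_that("expression bins are half-open intervals of 0.5 log10(CPM)", {
  cpm <- c(a = 1, b = 10, c = 10^1.5, d = 10^1.49, e = 0, f = 0.9)
  bins <- bin_genes_by_expression(cpm)
  expect_equal(unname(bins$bin["a"]), "0")    # [0, 0.5)
  expect_equal(unname(bins$bin["b"]), "2")    # [1.0, 1.5)
  expect_equal(unname(bins$bin["c"]), "3")    # [1.5, 2.0): boundary up
  expect_equal(unname(bins$bin["d"]), "2")
  expect_equal(unname(bins$bin["e"]), "zero")
  expect_equal(unname(bins$bin["f"]), "-1")
  expect_error(bin_genes_by_expression(c(g = -1)), "negative")
})

test_that("multi-cluster DE genes are matched at their highest expression", {
  expr <- c(cl1 = 2, cl2 = 8, cl3 = 5)
  expect_equal(resolve_foreground_expression("g", expr, c("cl1", "cl2")), 8)
  expect_equal(resolve_foreground_expression("g", expr, "cl3"), 5)
  expect_equal(resolve_foreground_expression("g", c(cl1 = 4, cl2 = 4),
                                             c("cl1", "cl2")), 4)
  expect_error(resolve_foreground_expression("g", expr, character()),
               "not DE")

  m <- rbind(g1 = c(cl1 = 2, cl2 = 8), g2 = c(cl1 = 7, cl2 = 1))
  de <- data.frame(gene = c("g1", "g1", "g2"),
                   cluster = c("cl1", "cl2", "cl1"))
  expect_equal(foreground_expression(m, de), c(g1 = 8, g2 = 7))
})

test_that("background sampling is bin-matched, independent, and seeded", {
  cpm <- c(g1 = 1, g2 = 1.1, g3 = 1.2, g4 = 1.3, solo = 100)
  bins <- bin_genes_by_expression(cpm)
  # a singleton bin forces the draw
  expect_equal(withr::with_seed(1L, sample_matched_background("4", bins)),
               "solo")
  # per-draw category probability 0.5 -> mean category count near 1.0
  fg_bins <- c("0", "0")
  counts <- withr::with_seed(2L, vapply(1:5000, function(i) {
    sum(sample_matched_background(fg_bins, bins) %in% c("g1", "g2"))
  }, numeric(1)))
  se <- sqrt(2 * 0.5 * 0.5 / 5000)
  expect_lt(abs(mean(counts) - 1.0), 3 * se)
  # seeded determinism
  b1 <- withr::with_seed(3L, sample_matched_background(fg_bins, bins))
  b2 <- withr::with_seed(3L, sample_matched_background(fg_bins, bins))
  expect_identical(b1, b2)
  expect_error(sample_matched_background("9", bins), "empty expression bin")
})

test_that("enrichment test matches the closed-form toy", {
  # one bin of 4 genes, category {g1, g2}, foreground {g1, g2}:
  # background count ~ Binomial(2, 1/2); p = P(X >= 2) = 1/4, E[X] = 1
  cpm <- c(g1 = 1, g2 = 1.1, g3 = 1.2, g4 = 1.3)
  bins <- bin_genes_by_expression(cpm)
  res <- enrichment_test(c("g1", "g2"), list(C = c("g1", "g2")), bins,
                         B = 5000, seed = 42L)
  expect_equal(res$n_foreground, 2L)
  expect_lt(abs(res$empirical_p - 0.25), 3 * sqrt(0.25 * 0.75 / 5000))
  expect_lt(abs(res$mean_background - 1.0), 3 * sqrt(0.5 / 5000))
  expect_lt(abs(res$enrichment_score - 2.0), 0.1)
  expect_false(res$p_is_bound)
  # determinism under the same seed
  res2 <- enrichment_test(c("g1", "g2"), list(C = c("g1", "g2")), bins,
                          B = 5000, seed = 42L)
  expect_identical(res$empirical_p, res2$empirical_p)
})

test_that("a foreground disjoint from a sampled category scores zero", {
  cpm <- c(g1 = 1, g2 = 1.1, g3 = 1.2, g4 = 1.3)
  bins <- bin_genes_by_expression(cpm)
  res <- enrichment_test(c("g3", "g4"), list(C = c("g1", "g2")), bins,
                         B = 500, seed = 7L)
  expect_equal(res$n_foreground, 0L)
  expect_equal(res$enrichment_score, 0)
  expect_equal(res$empirical_p, 1)  # every list has >= 0 category genes
})

test_that("empirical p converges to the enumerated p on tiny universes", {
  # universe of 6 genes in two bins; foreground 3 genes; exhaustive
  # enumeration of the background distribution
  cpm <- c(a = 1, b = 1.2, c = 1.4, d = 10, e = 11, f = 12)
  bins <- bin_genes_by_expression(cpm)
  cat_genes <- c("a", "b", "d")
  fg <- c("a", "c", "d")
  # bins: {a,b,c} (two draws: fg a and c), {d,e,f} (one draw: fg d)
  # exact p = P(X1 + X2 + X3 >= fg count) with X1,X2~Bern(2/3), X3~Bern(1/3)
  fg_count <- sum(fg %in% cat_genes)  # 2
  probs <- c(2 / 3, 2 / 3, 1 / 3)
  states <- expand.grid(0:1, 0:1, 0:1)
  pr <- apply(states, 1, function(s) {
    prod(ifelse(s == 1, probs, 1 - probs))
  })
  p_exact <- sum(pr[rowSums(states) >= fg_count])
  ok <- 0L
  for (s in 1:10) {
    res <- enrichment_test(fg, list(C = cat_genes), bins, B = 2000,
                           seed = 1000L + s)
    tol <- 3 * sqrt(p_exact * (1 - p_exact) / 2000)
    ok <- ok + as.integer(abs(res$empirical_p - p_exact) <= tol)
  }
  expect_gte(ok, 9L)
})

test_that("scores are invariant to relabeling genes within bins", {
  cpm <- c(g1 = 1, g2 = 1.1, g3 = 1.2, g4 = 1.3)
  bins <- bin_genes_by_expression(cpm)
  r1 <- enrichment_test(c("g1", "g2"), list(C = c("g1", "g2")), bins,
                        B = 3000, seed = 5L)
  # swap the roles of (g1,g2) and (g3,g4) everywhere
  r2 <- enrichment_test(c("g3", "g4"), list(C = c("g3", "g4")), bins,
                        B = 3000, seed = 5L)
  expect_identical(r1$n_foreground, r2$n_foreground)
  expect_lt(abs(r1$empirical_p - r2$empirical_p), 0.03)
})

test_that("the minimum reportable p bound at B resamples is 1/B", {
  # category fully contained in the foreground; the second category gene is
  # matched (highest-expression rule) into a bin with no category genes, so
  # no background list can reach the foreground count
  cpm <- c(g1 = 100, g2 = 0.5, x1 = 0.55, x2 = 0.6, x3 = 398, x4 = 400)
  bins <- bin_genes_by_expression(cpm)
  res <- enrichment_test(
    c("g1", "g2"), list(C = c("g1", "g2")), bins, B = 5000, seed = 9L,
    foreground_bins = c(bins$bin[["g1"]], bins$bin[["x3"]]))
  expect_true(res$p_is_bound)
  expect_equal(res$empirical_p, 1 / 5000)
  expect_equal(res$empirical_p, 2e-4)

  expect_error(enrichment_test(character(), list(C = "g1"), bins), "empty")
  # a category absent from the universe is flagged
  res2 <- enrichment_test("g1", list(C = "g1", D = "nope"), bins,
                          B = 100, seed = 1L)
  expect_false(res2$in_universe[res2$category == "D"])
})
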