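test_that("quantile normalization applies the rank-mean algorithm", {
  m <- cbind(s1 = c(1, 2, 3), s2 = c(2, 4, 6))
  out <- quantile_normalize(m)
  expect_equal(unname(out[, 1]), c(1.5, 3.0, 4.5))
  expect_equal(unname(out[, 2]), c(1.5, 3.0, 4.5))

  same <- cbind(a = c(5, 1, 9), b = c(5, 1, 9))
  expect_equal(quantile_normalize(same), same)

  # a constant column maps every feature to the mean over all rank means
  cm <- cbind(a = c(2, 2, 2), b = c(1, 5, 9))
  out2 <- quantile_normalize(cm)
  mu <- rowMeans(cbind(sort(cm[, 1]), sort(cm[, 2])))
  expect_equal(unname(out2[, 1]), rep(mean(mu), 3))
  expect_equal(unname(out2[, 2]), mu[rank(cm[, 2])])
})

test_that("quantile normalization equalizes column distributions", {
  set.seed(21)
  m <- matrix(rpois(400, 30) * runif(400, 0.5, 2), ncol = 4)
  colnames(m) <- paste0("s", 1:4)
  out <- quantile_normalize(m)
  ref <- sort(out[, 1])
  for (j in 2:4) expect_equal(sort(out[, j]), ref)
  expect_equal(mean(out), mean(m), tolerance = 1e-12)
  # agreement with the reference implementation in limma
  skip_if_not_installed("limma")
  expect_equal(unname(out),
               unname(limma::normalizeQuantiles(m, ties = TRUE)),
               tolerance = 1e-10)
})

test_that("single-sample normalization warns and returns the input", {
  tab <- count_table("f1", "miRNA", data.frame(s1 = 5))
  expect_warning(out <- quantile_normalize(tab), "single sample")
  expect_equal(out, tab)
})

test_that("Fisher test handles degenerate and symmetric tables", {
  expect_equal(fisher_test(0, 0, 100, 100), 1)
  expect_equal(fisher_test(5, 5, 100, 100), 1)
  expect_error(fisher_test(5, 5, 0, 10), "positive")
  expect_error(fisher_test(11, 5, 10, 10), "invalid margins")
  # two-sided symmetry under swapping the samples
  expect_equal(fisher_test(10, 3, 500, 700), fisher_test(3, 10, 700, 500))
})

test_that("Fisher p matches hypergeometric enumeration and fisher.test", {
  set.seed(33)
  for (i in 1:50) {
    nt <- sample(20:2000, 1)
    nc <- sample(20:2000, 1)
    a <- sample(0:min(40, nt), 1)
    b <- sample(0:min(40, nc), 1)
    got <- fisher_test(a, b, nt, nc)
    expect_equal(got, fisher_oracle(a, b, nt, nc), tolerance = 1e-12)
    ft <- stats::fisher.test(matrix(c(a, nt - a, b, nc - b), nrow = 2,
                                    byrow = TRUE))$p.value
    expect_equal(got, min(ft, 1), tolerance = 1e-7)
  }
})

test_that("BH adjustment follows the step-up rule", {
  expect_equal(adjust_pvalues(0.02), 0.02)
  expect_equal(adjust_pvalues(rep(0.03, 5)), rep(0.03, 5))
  expect_equal(adjust_pvalues(c(0.01, 0.02, 0.04)), c(0.03, 0.03, 0.04))
  p <- runif(20)
  expect_true(all(adjust_pvalues(p) >= p))
  expect_true(all(adjust_pvalues(p) <= 1))
})

test_that("identical columns produce no differential calls", {
  tab <- count_table(sprintf("f%d", 1:10), "miRNA",
                     data.frame(a = c(5, 50, 500, 3, 80, 9, 120, 7, 60, 33),
                                b = c(5, 50, 500, 3, 80, 9, 120, 7, 60, 33)))
  de <- differential_expression(tab, "a", "b")
  expect_true(all(de$call == "unchanged"))
  expect_true(all(de$signed_fc == 1))
  expect_equal(de$p_value, rep(1, nrow(de)), tolerance = 1e-12)
  expect_true(all(de$adj_p >= de$p_value))
  smry <- summary(de)
  expect_equal(smry$pct_unchanged, 100)
})

test_that("zero-count features are unchanged with a positive correction", {
  tab <- count_table(c("f1", "f2"), "miRNA",
                     data.frame(a = c(0, 100), b = c(0, 100)))
  de <- differential_expression(tab, "a", "b",
                                de_params(correction = 10))
  expect_equal(de$signed_fc, c(1, 1))
  expect_equal(de$call, c("unchanged", "unchanged"))
})

test_that("DE calls are invariant to feature input order", {
  set.seed(44)
  n <- 40
  tab <- count_table(sprintf("f%02d", 1:n), "miRNA",
                     data.frame(a = rpois(n, 60) * sample(c(1, 4), n, TRUE,
                                                          c(0.8, 0.2)),
                                b = rpois(n, 60)))
  de1 <- differential_expression(tab, "a", "b")
  perm <- sample(n)
  de2 <- differential_expression(tab[perm, ], "a", "b")
  de2 <- de2[match(de1$feature_id, de2$feature_id), ]
  expect_equal(de1$p_value, de2$p_value)
  expect_equal(de1$signed_fc, de2$signed_fc)
  expect_equal(de1$call, de2$call)
})

test_that("unknown sample names are an error", {
  tab <- count_table("f1", "miRNA", data.frame(a = 1, b = 2))
  expect_error(differential_expression(tab, "a", "zz"), "unknown sample")
})

test_that("clustering merges identical samples at distance zero", {
  set.seed(5)
  x <- rpois(30, 50)
  tab <- count_table(sprintf("f%d", 1:30), "miRNA",
                     data.frame(a = x, b = x, c = rev(x) + rpois(30, 10)))
  cl <- hierarchical_cluster(tab)
  expect_equal(cl$hclust$height[1], 0, tolerance = 1e-12)
  first <- sort(cl$hclust$labels[-cl$hclust$merge[1, ]])
  expect_equal(first, c("a", "b"))
  expect_match(cl$newick, "^\\(")
})

test_that("anticorrelated profiles sit at distance two", {
  x <- c(1, 2, 3, 4, 5)
  tab <- count_table(sprintf("f%d", 1:5), "miRNA",
                     data.frame(a = x, b = 6 - x))
  cl <- hierarchical_cluster(tab)
  expect_equal(max(cl$hclust$height), 2, tolerance = 1e-12)
})

test_that("clustering recovers two simulated sample groups", {
  set.seed(17)
  base1 <- rpois(100, 100)
  base2 <- rpois(100, 100)
  noisy <- function(b) pmax(0, b + rpois(100, 5) - 5)
  tab <- count_table(sprintf("f%03d", 1:100), "miRNA",
                     data.frame(a1 = noisy(base1), a2 = noisy(base1),
                                b1 = noisy(base2), b2 = noisy(base2)))
  cl <- hierarchical_cluster(tab)
  merges <- cl$hclust$merge
  # the first two merges join leaves within the same group
  for (r in 1:2) {
    pair <- sort(cl$hclust$labels[-merges[r, ]])
    expect_true(identical(pair, c("a1", "a2")) ||
                  identical(pair, c("b1", "b2")))
  }
})

test_that("PCA separates simulated groups and handles degenerate input", {
  const <- count_table(sprintf("f%d", 1:10), "miRNA",
                       data.frame(a = rep(3, 10), b = rep(3, 10),
                                  c = rep(3, 10)))
  pc <- pca_samples(const)
  expect_true(all(pc$variance_fraction == 0))

  two <- count_table(sprintf("f%d", 1:10), "miRNA",
                     data.frame(a = 1:10, b = c(2:10, 1)))
  pc2 <- pca_samples(two)
  expect_equal(pc2$variance_fraction[1], 1)

  set.seed(9)
  g1 <- rpois(50, 200); g2 <- g1 + sample(c(-60, 60), 50, replace = TRUE)
  tab <- count_table(sprintf("f%d", 1:50), "miRNA",
                     data.frame(a1 = g1 + rpois(50, 3), a2 = g1 + rpois(50, 3),
                                b1 = g2 + rpois(50, 3), b2 = g2 + rpois(50, 3)))
  pc3 <- pca_samples(tab)
  pc1 <- pc3$coordinates$PC1
  names(pc1) <- pc3$coordinates$sample
  expect_true(sign(pc1[["a1"]]) == sign(pc1[["a2"]]) &&
                sign(pc1[["b1"]]) == sign(pc1[["b2"]]) &&
                sign(pc1[["a1"]]) != sign(pc1[["b1"]]))
  expect_lte(sum(pc3$variance_fraction), 1 + 1e-12)
})
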