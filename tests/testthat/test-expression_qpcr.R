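test_that("scale_rows implements unit_max and zscore with NA handling", {
  m <- rbind(g1 = c(1, 2, 3), g2 = c(5, 5, 5), g3 = c(2, NA, 4))
  um <- scale_rows(m, "unit_max")
  expect_equal(unname(um["g1", ]), c(1 / 3, 2 / 3, 1))
  z <- scale_rows(m, "zscore")
  expect_equal(unname(z["g2", ]), c(0, 0, 0))        # sd = 0 rule
  expect_equal(mean(z["g1", ]), 0)
  expect_equal(stats::sd(z["g1", ]), 1)
  expect_true(is.na(z["g3", 2]))
  expect_equal(mean(z["g3", ], na.rm = TRUE), 0)
  expect_error(scale_rows(rbind(m, g4 = c(NA, NA, NA)), "zscore"), "all-NA")
  expect_equal(scale_rows(m, "none"), m)
})

test_that("pearson distances behave at the extremes", {
  m <- rbind(a = c(1, 2, 3, 4), b = c(2, 4, 6, 8), c = c(4, 3, 2, 1))
  hc <- hierarchical_cluster(m, "rows", "pearson", "average")
  # identical (up to scale) rows merge first at height 0
  expect_equal(hc$height[1], 0, tolerance = 1e-12)
  expect_equal(sort(hclust_merge_members(hc)[[1]]), c(1, 2))
  # perfect anti-correlation gives distance 2 = 1 - (-1)
  expect_equal(hc$height[2], 2, tolerance = 1e-12)
})

test_that("merge order equals the exhaustive-agglomeration oracle", {
  set.seed(51)
  for (rep in 1:5) {
    m <- matrix(rnorm(36), 6, 6,
                dimnames = list(paste0("g", 1:6), paste0("t", 1:6)))
    for (link in c("average", "complete", "single")) {
      hc <- hierarchical_cluster(m, "rows", "euclidean", link)
      d <- as.matrix(stats::dist(m))
      orc <- oracle_agglomerate(d, link)
      expect_equal(hclust_merge_members(hc), orc$merges)
      expect_equal(hc$height, orc$heights, tolerance = 1e-12)
    }
    hc <- hierarchical_cluster(m, "rows", "pearson", "average")
    n <- nrow(m)
    dp <- matrix(0, n, n)
    for (i in 1:n) for (j in 1:n) dp[i, j] <- 1 - stats::cor(m[i, ], m[j, ])
    diag(dp) <- 0
    orc <- oracle_agglomerate(dp, "average")
    expect_equal(hclust_merge_members(hc), orc$merges)
  }
})

test_that("clustering matches stats::hclust on complete tie-free data", {
  set.seed(52)
  m <- matrix(rnorm(80), 10, 8, dimnames = list(paste0("g", 1:10), NULL))
  for (link in c("average", "complete", "single")) {
    h1 <- hierarchical_cluster(m, "rows", "euclidean", link)
    h2 <- stats::hclust(stats::dist(m), link)
    expect_equal(h1$height, h2$height, tolerance = 1e-12)
    expect_equal(stats::cutree(h1, 4)[h2$labels],
                 stats::cutree(h2, 4))
  }
})

test_that("dendrogram heights are monotone and row order is irrelevant", {
  set.seed(53)
  m <- matrix(rnorm(70), 10, 7, dimnames = list(paste0("g", 1:10), NULL))
  hc <- hierarchical_cluster(m, "rows", "pearson", "average")
  expect_true(all(diff(hc$height) >= -1e-12))
  expect_true(all(hc$height >= 0 & hc$height <= 2 + 1e-12))
  perm <- sample(1:10)
  hp <- hierarchical_cluster(m[perm, ], "rows", "pearson", "average")
  k3 <- stats::cutree(hc, 3)
  kp <- stats::cutree(hp, 3)[names(k3)]
  expect_equal(unname(table(k3, kp) > 0) %*% rep(1, 3), cbind(rep(1, 3)))
})

test_that("sparse genes are excluded and short overlaps error", {
  m <- rbind(g1 = c(1, 2, 3, 4), g2 = c(2, 1, 4, 3),
             g3 = c(NA, NA, NA, 1), g4 = c(4, 3, 2, 1))
  expect_warning(hc <- hierarchical_cluster(m, "rows", "euclidean"), "g3")
  expect_equal(sort(hc$labels), c("g1", "g2", "g4"))
  m2 <- rbind(g1 = c(1, 2, NA, NA), g2 = c(NA, NA, 1, 2),
              g3 = c(1, 2, 3, 4))
  expect_error(hierarchical_cluster(m2, "rows", "pearson", min_obs_frac = 0),
               "shared")
})

test_that("planted expression clusters are recovered with high ARI", {
  skip_if_not_installed("mclust")
  ex <- default_expression()
  hc <- hierarchical_cluster(ex$expression, "rows")
  truth <- ex$expression_clusters[hc$labels]
  k <- length(unique(truth))
  cl <- stats::cutree(hc, k = k)
  expect_gte(mclust::adjustedRandIndex(cl, truth), 0.9)
})

test_that("duplicate-pair expression similarity reproduces the 9/11 split", {
  fam <- default_family()
  ex <- default_expression()
  sim <- pair_expression_similarity(ex$expression, fam$truth$duplicate_pairs)
  expect_equal(sum(sim$call == "similar"), 9L)
  expect_equal(round(mean(sim$call == "similar") * 100, 2), 81.82)

  m <- rbind(a = c(1, 2, 3, 4), b = c(1, 2, 3, 4), c = c(10, 7, 5, 1),
             d = c(1, NA, NA, NA))
  ps <- pair_expression_similarity(m, data.frame(gene_a = c("a", "a", "a"),
                                                 gene_b = c("b", "c", "d")))
  expect_equal(ps$call, c("similar", "divergent", "undeterminable"))
  expect_equal(ps$r[1], 1)
  expect_lt(ps$r[2], -0.8)
})

test_that("ddct reproduces closed-form comparative-Ct values", {
  df <- data.frame(sample = rep(c("s", "cal"), each = 2),
                   gene = rep(c("tgt", "ref"), 2),
                   replicate = 1L, ct = c(24, 20, 22, 20))
  qt <- qpcr_table(df, "ref", "cal")
  r <- ddct(qt, "tgt", "s")
  expect_equal(r$ddct, 2)
  expect_equal(r$relative_expression, 0.25)
  expect_equal(ddct(qt, "tgt", "cal")$relative_expression, 1.0)

  # replicates averaged before dCT
  df2 <- rbind(df, data.frame(sample = "s", gene = "tgt",
                              replicate = 2:3, ct = c(24.2, 23.8)))
  qt2 <- qpcr_table(df2, "ref", "cal")
  expect_equal(ddct(qt2, "tgt", "s")$ddct, 2)
  expect_length(ddct(qt2, "tgt", "s")$per_replicate, 3L)

  # reciprocity: rel(s|cal) * rel(cal|s) = 1
  expect_equal(ddct(qt, "tgt", "s")$relative_expression *
                 ddct(qt, "tgt", "cal", calibrator = "s")$relative_expression,
               1.0)

  expect_error(qpcr_table(df[df$gene != "ref" | df$sample != "s", ], "ref"),
               "reference")
  expect_error(qpcr_table(transform(df, ct = c(-1, 20, 22, 20)), "ref"),
               "positive")
})

test_that("ddct recovers the generator's planted expression fold", {
  ex <- default_expression()
  pf <- ex$planted_fold
  r <- ddct(ex$ct, pf$gene, pf$tissue)
  # Ct noise sd 0.15 over 4 averaged triplicates: sd(ddCt) ~ 0.17; a 5-sigma
  # bound on the log2 scale is ~0.9
  expect_lt(abs(log2(r$relative_expression / pf$fold)), 0.9)
})
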