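test_that("welch t-test matches the independent reference implementation", {
  set.seed(10)
  m <- matrix(rnorm(6 * 10, 20), 6, 10)
  m[3, 4] <- m[5, 8] <- NA
  ds <- make_ds(m, group = rep(c("A", "B"), each = 3))
  for (ev in c(FALSE, TRUE)) {
    de <- de_ttest(ds, "group", "A", "B", equal_var = ev)
    for (p in seq_len(10)) {
      x1 <- m[1:3, p]; x2 <- m[4:6, p]
      ref <- t.test(x1[!is.na(x1)], x2[!is.na(x2)], var.equal = ev)
      expect_equal(de$statistic[p], unname(ref$statistic), tolerance = 1e-12)
      expect_equal(de$p[p], ref$p.value, tolerance = 1e-12)
      expect_equal(de$log2_fc[p],
                   mean(x1, na.rm = TRUE) - mean(x2, na.rm = TRUE))
    }
  }
})

test_that("t-test handles degenerate proteins per the skip rules", {
  # identical group values with nonzero variance -> t = 0, p = 1
  m <- cbind(c(10, 12, 10, 12), c(1, 2, 3, 4))
  ds <- make_ds(m, group = c("A", "A", "B", "B"))
  de <- de_ttest(ds, "group", "A", "B")
  expect_equal(de$statistic[1], 0)
  expect_equal(de$p[1], 1)
  expect_equal(de$log2_fc[1], 0)

  # zero variance in both groups: undefined, skipped (no epsilon fudge)
  m2 <- cbind(c(1, 1, 2, 2), c(1, 2, 3, 4))
  de2 <- de_ttest(make_ds(m2, group = c("A", "A", "B", "B")),
                  "group", "A", "B")
  expect_equal(de2$status[1], "skipped_low_n")
  expect_true(is.na(de2$p[1]))
  # but the effect estimate is still reported
  expect_equal(de2$log2_fc[1], -1)

  # min_obs gate
  m3 <- cbind(c(1, NA, 3, 4), c(1, 2, 3, 4))
  de3 <- de_ttest(make_ds(m3, group = c("A", "A", "B", "B")),
                  "group", "A", "B", min_obs = 2)
  expect_equal(de3$status, c("skipped_low_n", "ok"))
  # q computed over tested proteins only
  expect_true(is.na(de3$q[1]))

  expect_error(de_ttest(ds, "group", "A", "Z"), "Z")
})

test_that("anova equals t^2 on two groups and the sum-of-squares oracle on three", {
  set.seed(11)
  m <- matrix(rnorm(6 * 8, 20), 6, 8)
  ds <- make_ds(m, group = rep(c("A", "B"), each = 3))
  de_t <- de_ttest(ds, "group", "A", "B", equal_var = TRUE)
  de_f <- de_anova(ds, "group")
  expect_equal(de_f$statistic, de_t$statistic^2, tolerance = 1e-9)
  expect_equal(de_f$p, de_t$p, tolerance = 1e-9)

  # 3-group toy against a direct SS decomposition
  g3 <- rep(c("A", "B", "C"), each = 3)
  m3 <- matrix(rnorm(9 * 5, 20), 9, 5)
  m3[1:3, 1] <- m3[1:3, 1] + 2
  ds3 <- make_ds(m3, group = g3)
  de3 <- de_anova(ds3, "group")
  for (p in seq_len(5)) {
    y <- m3[, p]
    gm <- mean(y)
    means <- tapply(y, g3, mean)
    ssb <- sum(3 * (means - gm)^2)
    ssw <- sum((y - means[g3])^2)
    f <- (ssb / 2) / (ssw / 6)
    expect_equal(de3$statistic[p], f, tolerance = 1e-9)
    expect_equal(de3$p[p], pf(f, 2, 6, lower.tail = FALSE), tolerance = 1e-9)
  }

  # constant matrix: every protein skipped
  cds <- make_ds(matrix(5, 6, 3), group = rep(c("A", "B"), each = 3))
  expect_warning(dec <- de_anova(cds, "group"), "skipped")
  expect_true(all(dec$status == "skipped_low_n"))
})

test_that("ancova partial F matches a nested least-squares oracle", {
  set.seed(12)
  n <- 12
  g <- rep(c("A", "B", "C"), each = 4)
  age <- rnorm(n, 50, 8)
  m <- matrix(rnorm(n * 6, 20), n, 6)
  m[, 1] <- m[, 1] + 0.1 * age          # covariate effect only
  m[g == "B", 2] <- m[g == "B", 2] + 3  # group effect only
  ds <- make_ds(m, group = g, age = age)
  de <- de_ancova(ds, "group", "age")

  # independent oracle: explicit projection residual sums of squares
  for (p in seq_len(6)) {
    y <- m[, p]
    X0 <- cbind(1, age)
    X1 <- cbind(1, g == "B", g == "C", age)
    rss <- function(X) {
      b <- solve(crossprod(X), crossprod(X, y))
      sum((y - X %*% b)^2)
    }
    f <- ((rss(X0) - rss(X1)) / 2) / (rss(X1) / (n - 4))
    expect_equal(de$statistic[p], f, tolerance = 1e-8)
    expect_equal(de$p[p], pf(f, 2, n - 4, lower.tail = FALSE),
                 tolerance = 1e-8)
  }

  # zero-effect covariate: with a covariate constructed exactly orthogonal
  # to the intensities and the group indicators, the partial F equals the
  # plain anova F up to the residual-df ratio (n-4 vs n-3)
  y <- m[, 3]
  G <- cbind(1, g == "B", g == "C")
  raw_cov <- rnorm(n)
  orth <- raw_cov - cbind(G, y) %*%
    solve(crossprod(cbind(G, y)), crossprod(cbind(G, y), raw_cov))
  ds2 <- make_ds(matrix(y, n, 1), group = g, age = as.numeric(orth))
  de2 <- de_ancova(ds2, "group", "age")
  dea <- de_anova(ds2, "group")
  expect_equal(de2$statistic[1] * (n - 3) / (n - 4), dea$statistic[1],
               tolerance = 1e-8)
  expect_equal(de2$p[1], pf(dea$statistic[1] * (n - 4) / (n - 3), 2, n - 4,
                            lower.tail = FALSE), tolerance = 1e-8)

  # constructed confound: intensity driven by the covariate, which differs
  # by group; anova is fooled, ancova is not
  age_conf <- c(rnorm(4, 30, 1), rnorm(4, 50, 1), rnorm(4, 70, 1))
  m3 <- matrix(2 * age_conf + rnorm(n, 0, 0.5), n, 1)
  ds3 <- make_ds(m3, group = g, age = age_conf)
  expect_lt(de_anova(ds3, "group")$p[1], 1e-6)
  expect_gt(de_ancova(ds3, "group", "age")$p[1], 0.001)

  # collinear duplicate covariates -> rank-deficient -> skipped
  ds4 <- make_ds(m, group = g, age = age, age2 = age)
  de4 <- de_ancova(ds4, "group", c("age", "age2"))
  expect_true(all(de4$status == "skipped_low_n"))

  expect_error(de_ancova(ds, "group", "bmi"), "covariate column missing")
})

test_that("BH adjustment equals the brute-force step-up on random vectors", {
  expect_equal(adjust_bh(c(0.01, 0.02, 0.04)), c(0.03, 0.03, 0.04))
  expect_equal(adjust_bh(rep(0.2, 5)), rep(0.2, 5))
  expect_equal(adjust_bh(0.7), 0.7)
  expect_error(adjust_bh(c(0.5, 1.2)), "0, 1")

  set.seed(13)
  for (rep in 1:20) {
    p <- runif(sample(3:40, 1))^sample(1:3, 1)
    expect_equal(adjust_bh(p), bh_brute(p), tolerance = 1e-12)
    # monotone non-decreasing after sorting by p
    q <- adjust_bh(p)[order(p)]
    expect_true(all(diff(q) >= -1e-12))
  }
  # NAs pass through and do not affect m
  p <- c(0.01, NA, 0.02, 0.04)
  expect_equal(adjust_bh(p), c(0.03, NA, 0.03, 0.04))
})

test_that("ORA matches exhaustive hypergeometric enumeration on a 10-protein toy", {
  background <- paste0("P", 1:10)
  term <- list(T1 = paste0("P", 1:5), Ttiny = "P1")
  significant <- paste0("P", c(1, 2, 3, 4))
  res <- ora(significant, background, term, min_term_size = 2)
  expect_equal(nrow(res), 1) # Ttiny filtered out
  expect_equal(res$n_term_hits, 4)

  # exhaustive enumeration of all 4-subsets of the background
  subsets <- combn(10, 4)
  overlaps <- apply(subsets, 2, function(s) sum(s <= 5))
  p_exact <- mean(overlaps >= 4)
  expect_equal(res$p, p_exact, tolerance = 1e-12)
  expect_equal(res$p, choose(5, 4) * choose(5, 0) / choose(10, 4) +
                 choose(5, 5) * 0, tolerance = 1e-12)

  # zero overlap with a small term: p ~ 1
  res0 <- ora("P10", background, list(T1 = c("P1", "P2")), min_term_size = 2)
  expect_gt(res0$p, 0.75)

  # invariant: hits <= min(n_sig, term size)
  expect_true(all(res$n_term_hits <= pmin(res$n_sig, res$n_term_background)))
  expect_error(ora(c("P1", "ZZ"), background, term), "subset")

  # data-frame annotation input and GAF-style reading
  ann_df <- data.frame(term = c("T1", "T1", "T2"),
                       protein = c("P1", "P2", "P3"))
  res_df <- ora(c("P1", "P2"), background, ann_df, min_term_size = 2)
  expect_equal(res_df$term_id, "T1")
  f <- withr::local_tempfile()
  writeLines(c("term\tprotein", "T1\tP1", "T1\tP2"), f)
  ann <- read_annotation(f)
  expect_equal(nrow(ann), 2)
  expect_equal(ann$term_id, c("T1", "T1"))
})

test_that("PCA matches an eigendecomposition and reconstructs at full rank", {
  set.seed(14)
  m <- matrix(rnorm(3 * 2), 3, 2)
  ds <- make_ds(m)
  pc <- pca_analysis(ds, 2)
  ev <- eigen(cov(m))$values
  expect_equal(pc$explained_variance_ratio, ev / sum(ev), tolerance = 1e-9)

  # full-rank reconstruction
  m2 <- matrix(rnorm(6 * 4), 6, 4)
  ds2 <- make_ds(m2)
  pc2 <- pca_analysis(ds2, 4)
  centered <- scale(m2, center = TRUE, scale = FALSE)
  recon <- pc2$scores %*% t(pc2$loadings)
  expect_lt(max(abs(recon - centered)), 1e-8)
  # orthonormal loadings
  expect_lt(max(abs(crossprod(pc2$loadings) - diag(4))), 1e-8)
  # sign convention: largest-magnitude loading positive
  for (j in 1:4) {
    expect_gt(pc2$loadings[which.max(abs(pc2$loadings[, j])), j], 0)
  }
  # ratios non-increasing, in (0,1], summing <= 1
  expect_true(all(diff(pc2$explained_variance_ratio) <= 1e-12))
  expect_lte(sum(pc2$explained_variance_ratio), 1 + 1e-12)

  # collinear samples: first component explains everything
  base <- rnorm(5)
  m3 <- outer(c(0, 1, 2, 3), base) + 10
  pc3 <- pca_analysis(make_ds(m3), 1)
  expect_equal(pc3$explained_variance_ratio[1], 1, tolerance = 1e-9)

  dsna <- make_ds(rbind(c(1, NA), c(2, 3), c(0, 1)))
  expect_error(pca_analysis(dsna, 1), "impute")
  expect_error(pca_analysis(ds2, 10), "n_components")
})

test_that("hierarchical clustering matches brute force on three points", {
  m <- matrix(c(0, 1, 4), ncol = 1)
  rownames(m) <- c("a", "b", "c")
  hc <- hcluster(cbind(m, 0), "samples", "euclidean", "single")
  expect_equal(hc$merge_tree$height, c(1, 3))
  expect_setequal(hc$merge_tree[1, c("left", "right")] |> unlist() |> unname(),
                  c(-1L, -2L))
  # leaf order is a permutation
  expect_setequal(hc$leaf_order, 1:3)

  # duplicates merge first at height 0
  m2 <- rbind(c(1, 2), c(1, 2), c(9, 9))
  hc2 <- hcluster(m2, "samples", "euclidean", "average")
  expect_equal(hc2$merge_tree$height[1], 0)
  expect_setequal(unlist(hc2$merge_tree[1, c("left", "right")]) |> unname(),
                  c(-1L, -2L))

  # heights non-decreasing for all three linkages; order always a permutation
  set.seed(15)
  for (link in c("single", "complete", "average")) {
    mm <- matrix(rnorm(8 * 4), 8, 4)
    h <- hcluster(mm, "samples", "euclidean", link)
    expect_true(all(diff(h$merge_tree$height) >= -1e-12))
    expect_setequal(h$leaf_order, 1:8)
    hp <- hcluster(mm, "proteins", "correlation", link)
    expect_setequal(hp$leaf_order, 1:4)
  }

  expect_error(hcluster(rbind(c(1, 1, 1), c(1, 2, 3)), "samples",
                        "correlation"), "constant")
})
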