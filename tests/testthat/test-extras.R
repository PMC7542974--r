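test_that("all seven distances are non-negative, symmetric, zero on identity", {
  set.seed(3)
  mat <- matrix(rnorm(8 * 6), 8, 6,
                dimnames = list(paste0("i", 1:8), paste0("f", 1:6)))
  metrics <- c("euclidean", "correlation", "minkowski", "canberra",
               "binary", "manhattan", "maximum")
  for (m in metrics) {
    D <- as.matrix(featureDistance(abs(mat), m))
    expect_true(all(D >= -1e-12), info = m)
    expect_equal(D, t(D), tolerance = 1e-12, info = m)
    expect_equal(unname(diag(D)), rep(0, 8), tolerance = 1e-12, info = m)
  }
  # triangle inequality for the metric ones on sampled triples
  for (m in c("euclidean", "manhattan", "maximum", "minkowski", "canberra")) {
    D <- as.matrix(featureDistance(abs(mat), m))
    for (r in 1:20) {
      ijk <- sample(8, 3)
      expect_lte(D[ijk[1], ijk[3]],
                 D[ijk[1], ijk[2]] + D[ijk[2], ijk[3]] + 1e-10, )
    }
  }
  expect_error(featureDistance(rbind(const = rep(1, 4), mat[1:2, 1:4]),
                               "correlation"), "const")
})

test_that("clustering separates two Gaussian blobs exactly", {
  set.seed(27)
  n <- 20
  blob <- rbind(matrix(rnorm(n * 3, 0, 0.3), n, 3),
                matrix(rnorm(n * 3, 5, 0.3), n, 3))
  blob <- exp(blob * 0.1 + 5)
  rownames(blob) <- sprintf("s%02d", 1:(2 * n))
  colnames(blob) <- paste0("v", 1:3)
  truth <- rep(1:2, each = n)
  ps <- make_peakset(blob, group = rep(c("A", "B"), each = n))
  hc <- hclusterPeaks(ps, "samples", "euclidean", "complete", k = 2)
  tab <- table(hc$assignments, truth)
  expect_equal(min(sum(diag(tab)), sum(tab) - sum(diag(tab))) , 0)
})

test_that("single linkage merges the closest collinear pair first", {
  mat <- matrix(c(0, 1, 5), 3, 1, dimnames = list(c("A", "B", "C"), "x"))
  ps <- suppressWarnings(PeakSet(mat))
  hc <- hclusterPeaks(ps, "samples", "euclidean", "single")
  first <- hc$tree$merge[1, ]
  expect_setequal(abs(first), c(1, 2))  # A and B (|AB| = 1 < |BC| = 4)
})

test_that("sub-cluster analysis adds per-group cluster profiles", {
  ps <- two_group_peakset(6, 8, shift = 2, seed = 33, informative = 4)
  hc <- hclusterPeaks(ps, "variables", "correlation", "average", k = 2)
  expect_s3_class(hc$cluster_profiles, "data.frame")
  expect_setequal(unique(hc$cluster_profiles$cluster), 1:2)
  expect_setequal(unique(hc$cluster_profiles$group), c("A", "B"))
})

test_that("ROC analysis matches concordant-pair counting and handles ties", {
  expect_equal(rocAnalysis(c(1, 2, 3, 4), c(0, 0, 1, 1))$auc, 1.0)
  expect_equal(rocAnalysis(c(1, 2, 3, 4), c(0, 1, 0, 1))$auc, 0.75)
  expect_equal(rocAnalysis(rep(2, 6), c(0, 1, 0, 1, 0, 1))$auc, 0.5)
  set.seed(47)
  for (r in 1:10) {
    n <- sample(10:200, 1)
    scores <- sample(seq(0, 5, by = 0.5), n, replace = TRUE)  # many ties
    labels <- rbinom(n, 1, 0.4)
    if (length(unique(labels)) < 2) next
    expect_equal(rocAnalysis(scores, labels)$auc,
                 oracle_auc(scores, labels), tolerance = 1e-12)
  }
  expect_error(rocAnalysis(1:4, c(1, 1, 1, 1)), "both classes")
})

test_that("the Youden cutoff maximizes TPR - FPR", {
  scores <- c(0.1, 0.2, 0.35, 0.4, 0.6, 0.8, 0.9)
  labels <- c(0, 0, 0, 1, 1, 1, 1)
  roc <- rocAnalysis(scores, labels)
  expect_equal(roc$auc, 1.0)
  expect_equal(roc$youden$J, 1.0)
  expect_equal(roc$youden$tpr, 1.0)
  expect_equal(roc$youden$fpr, 0.0)
})

test_that("power analysis solves either direction consistently", {
  res <- powerAnalysis("two_sample_t", effect_size = 1, power = 0.8)
  expect_equal(res$n, 17)  # classical d = 1 answer
  back <- powerAnalysis("two_sample_t", effect_size = 1, n = res$n)
  expect_gte(back$power, 0.8)
  expect_lt(powerAnalysis("two_sample_t", effect_size = 1,
                          n = res$n - 1)$power, 0.8)
  for (kind in c("paired_t", "one_way_anova", "two_proportions")) {
    r <- powerAnalysis(kind, effect_size = 0.5, power = 0.8)
    b <- powerAnalysis(kind, effect_size = 0.5, n = r$n)
    expect_gte(b$power, 0.8)
  }
  expect_error(powerAnalysis("two_sample_t", effect_size = 0, n = 10),
               "positive")
  expect_error(powerAnalysis("two_sample_t", effect_size = 1), "exactly one")
})

test_that("power tends to alpha as the effect vanishes and grows with n and d", {
  near_null <- powerAnalysis("two_sample_t", effect_size = 1e-8, n = 20,
                             alpha = 0.05)
  expect_equal(near_null$power, 0.05, tolerance = 1e-4)
  grid_n <- vapply(c(5, 10, 20, 40),
                   function(n) powerAnalysis("two_sample_t", 0.8,
                                             n = n)$power, numeric(1))
  expect_true(all(diff(grid_n) > 0))
  grid_d <- vapply(c(0.2, 0.5, 0.8, 1.2),
                   function(d) powerAnalysis("one_way_anova", d,
                                             n = 15)$power, numeric(1))
  expect_true(all(diff(grid_d) > 0))
})

test_that("computed t-test sample size delivers the simulated power", {
  res <- powerAnalysis("two_sample_t", effect_size = 1, alpha = 0.05,
                       power = 0.8)
  set.seed(53)
  n <- res$n
  reject <- mean(replicate(20000, {
    t.test(rnorm(n), rnorm(n, mean = 1))$p.value < 0.05
  }))
  expect_lt(abs(reject - res$power), 0.02)
})

test_that("venn regions enumerate memberships and sum to the union", {
  v <- vennCounts(list(a = "x", b = "y"))
  expect_equal(v$regions$count, c(1, 1, 0))
  same <- vennCounts(list(a = c("p", "q"), b = c("q", "p")))
  expect_equal(sum(same$regions$count), 2)
  expect_equal(same$regions$count[same$regions$a & same$regions$b], 2)
  set.seed(59)
  sets <- lapply(1:4, function(i) sample(letters, sample(5:15, 1)))
  names(sets) <- paste0("S", 1:4)
  v4 <- vennCounts(sets)
  expect_equal(sum(v4$regions$count), length(unique(unlist(sets))))
  # brute-force bitmask oracle
  uni <- sort(unique(unlist(sets)))
  mask <- sapply(sets, function(s) uni %in% s)
  for (i in seq_len(nrow(v4$regions))) {
    pat <- unlist(v4$regions[i, 1:4])
    expect_equal(v4$regions$count[i],
                 sum(apply(mask, 1, function(r) all(r == pat))))
  }
  expect_error(vennCounts(list(1:2)), "between 2 and 6")
  expect_error(vennCounts(rep(list(1:2), 7)), "between 2 and 6")
})

test_that("linear regression recovers exact fits and flags collinearity", {
  x <- 1:10
  lr <- suppressWarnings(linearRegression(3 * x, x))
  expect_equal(lr$coefficients$estimate[2], 3, tolerance = 1e-10)
  expect_equal(lr$r_squared, 1, tolerance = 1e-10)
  X <- cbind(a = x, b = 2 * x)
  expect_error(linearRegression(rnorm(10), X), "collinear")
  expect_error(linearRegression(1:3, cbind(1:3, 3:1)), "n > p")
})

test_that("null regression slope p-values are roughly uniform", {
  set.seed(67)
  pvals <- replicate(400, {
    linearRegression(rnorm(20), rnorm(20))$coefficients$p[2]
  })
  frac <- mean(pvals < 0.05)
  expect_lt(abs(frac - 0.05), 0.04)
  expect_gt(ks.test(pvals, "punif")$p.value, 0.001)
})
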