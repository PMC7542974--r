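test_that("classical correlations honour their defining properties", {
  x <- c(1, 2, 3, 4, 5, 6)
  mat <- cbind(a = x, b = 2 * x + 1, c = c(2, 1, 4, 3, 6, 5))
  rownames(mat) <- paste0("s", 1:6)
  res <- correlateFeatures(mat, method = "pearson")
  ab <- res[res$feature_a == "a" & res$feature_b == "b", ]
  expect_equal(ab$r, 1.0, tolerance = 1e-12)
  expect_lt(ab$p, 0.05)
  # Spearman is invariant under monotone transforms of either margin
  sp1 <- correlateFeatures(mat, method = "spearman")
  mat2 <- mat; mat2[, "a"] <- exp(mat2[, "a"]); mat2[, "c"] <- mat2[, "c"]^3
  sp2 <- correlateFeatures(mat2, method = "spearman")
  expect_equal(sp1$r, sp2$r, tolerance = 1e-12)
  expect_error(correlateFeatures(mat[1:3, ]), "at least 4")
})

test_that("cross-table correlation is symmetric in the table arguments", {
  set.seed(19)
  a <- matrix(rnorm(40), 10, 4, dimnames = list(paste0("s", 1:10),
                                                paste0("a", 1:4)))
  b <- matrix(rnorm(30), 10, 3, dimnames = list(paste0("s", 1:10),
                                                paste0("b", 1:3)))
  ab <- correlateFeatures(a, b, method = "kendall")
  ba <- correlateFeatures(b, a, method = "kendall")
  key_ab <- paste(ab$feature_a, ab$feature_b)
  key_ba <- paste(ba$feature_b, ba$feature_a)
  expect_equal(ab$r, ba$r[match(key_ab, key_ba)], tolerance = 1e-12)
  expect_equal(ab$p, ba$p[match(key_ab, key_ba)], tolerance = 1e-12)
})

test_that("partial Spearman removes a shared confounder", {
  set.seed(29)
  n <- 80
  z <- rnorm(n)
  conf_driven <- cbind(a = 2 * z + rnorm(n, sd = 0.3),
                       b = -1.5 * z + rnorm(n, sd = 0.3))
  rownames(conf_driven) <- paste0("s", 1:n)
  Z <- matrix(z, dimnames = list(rownames(conf_driven), "z"))
  naive <- correlateFeatures(conf_driven, method = "spearman")
  partial <- correlateFeatures(conf_driven, method = "partial_spearman",
                               confounders = Z)
  expect_lt(naive$p, 0.01)          # naive sees the spurious association
  expect_gt(partial$p, 0.05)        # adjusted does not
  expect_error(correlateFeatures(conf_driven, method = "partial_spearman"),
               "confounders")
})

test_that("null-pair p-values are calibrated", {
  set.seed(37)
  n <- 100; p <- 40
  mat <- matrix(rnorm(n * p), n, p,
                dimnames = list(paste0("s", 1:n), paste0("v", 1:p)))
  res <- correlateFeatures(mat, method = "pearson")
  frac <- mean(res$p < 0.05)
  m <- nrow(res)
  bound <- 3 * sqrt(0.05 * 0.95 / m)
  expect_lt(abs(frac - 0.05), bound + 0.02)
})

test_that("distance correlation matches the explicit double-centering oracle", {
  set.seed(43)
  for (r in 1:5) {
    n <- sample(10:50, 1)
    x <- rnorm(n); y <- x^2 + rnorm(n, sd = 0.2)
    expect_equal(distanceCorrelation(x, y), oracle_dcor(x, y),
                 tolerance = 1e-10)
  }
  # independence gives a small value, strong dependence a large one
  x <- rnorm(40)
  expect_gt(distanceCorrelation(x, x^2), 0.3)
})

test_that("CLR transform centers log-ratios per sample and handles zeros", {
  mat <- matrix(c(1, 2, 0, 4, 2, 2), 2, 3,
                dimnames = list(c("s1", "s2"), c("t1", "t2", "t3")))
  clr <- clrTransform(mat)
  expect_equal(unname(rowSums(clr)), c(0, 0), tolerance = 1e-12)
  expect_true(all(is.finite(clr)))
  expect_error(clrTransform(-mat), "non-negative")
})

test_that("GRaMM labels planted linear and quadratic couplings correctly", {
  d <- simDesign(n_per_group = 30, n_variables = 8, n_informative = 0,
                 seed = 71)
  sim <- simulatePeakTable(d)
  cm <- simulateCoupledMicrobiome(sim$table, n_taxa = 12, n_linear = 2,
                                  n_nonlinear = 2, n_confounded = 1,
                                  seed = 71)
  conf <- sampleMeta(cm$metab)[, "confounder", drop = FALSE]
  gr <- gramm(cm$metab, cm$microbe, confounders = conf,
              n_permutations = 99, seed = 5)
  key <- function(df) paste(df$metabolite, df$taxon)
  gr_t <- gr[match(key(cm$truth), key(gr)), ]
  expect_equal(gr_t$type[cm$truth$type == "linear"], c("linear", "linear"))
  expect_true(all(gr_t$q[cm$truth$type == "linear"] < 0.05))
  expect_equal(gr_t$type[cm$truth$type == "nonlinear"],
               c("nonlinear", "nonlinear"))
  # confounder-driven pair is not called significant after adjustment
  expect_gt(gr_t$q[cm$truth$type == "confounded"], 0.05)
})

test_that("GRaMM without confounders reduces to the centered two-channel pipeline", {
  set.seed(83)
  n <- 30
  metab <- matrix(rlnorm(n * 2, 8, 0.5), n, 2,
                  dimnames = list(paste0("s", 1:n), c("m1", "m2")))
  microbe <- matrix(rexp(n * 2), n, 2,
                    dimnames = list(paste0("s", 1:n), c("t1", "t2")))
  a <- gramm(metab, microbe, n_permutations = 49, seed = 2)
  zero_conf <- matrix(nrow = n, ncol = 0,
                      dimnames = list(paste0("s", 1:n), NULL))
  b <- gramm(metab, microbe, confounders = zero_conf, n_permutations = 49,
             seed = 2)
  expect_equal(a$r, b$r, tolerance = 1e-10)
  expect_equal(a$p, b$p, tolerance = 1e-10)
})

test_that("pair retrieval applies the criterion, drops self-pairs, sorts by |r|", {
  res <- data.frame(
    feature_a = c("a", "b", "c", "d", "e"),
    feature_b = c("b", "c", "c", "e", "f"),
    r = c(0.9, -0.7, 0.99, 0.3, 0.65),
    q = c(0.001, 0.01, 0.2, 0.001, 0.04))
  res$feature_b[3] <- "c"  # self pair
  edges <- retrievePairs(res, min_abs_r = 0.6, max_q = 0.05)
  expect_equal(edges$source, c("a", "b", "e"))
  expect_equal(edges$interaction, c("positive", "negative", "positive"))
  none <- retrievePairs(res, min_abs_r = 0.999)
  expect_equal(nrow(none), 0L)
  expect_named(none, c("source", "interaction", "target", "r", "q"))
})
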