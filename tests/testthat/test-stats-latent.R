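test_that("PCA equals the SVD of the centered/scaled matrix", {
  set.seed(17)
  for (r in 1:3) {
    mat <- matrix(rlnorm(20 * 50, 8, 0.6), 20, 50,
                  dimnames = list(sprintf("s%02d", 1:20),
                                  sprintf("v%02d", 1:50)))
    ps <- PeakSet(mat)
    m <- fitPCA(ps, n_components = 5, scaling = "unit_variance")
    X <- scale(mat)
    sv <- svd(X)
    for (a in 1:5) {
      ref_load <- sv$v[, a]
      s <- sign(ref_load[which.max(abs(ref_load))])
      expect_equal(unname(m@loadings[, a]), s * ref_load, tolerance = 1e-8)
      expect_equal(unname(m@scores[, a]), s * sv$u[, a] * sv$d[a],
                   tolerance = 1e-8)
    }
    expect_equal(m@explained_variance, (sv$d[1:5]^2) / sum(sv$d^2),
                 tolerance = 1e-10)
  }
})

test_that("PCA handles rank-1 data, full rank, duplicates and preconditions", {
  # points on a line in 2-D: one component explains everything
  t_par <- seq(-2, 2, length.out = 8)
  mat <- cbind(V1 = 10 + 3 * t_par, V2 = 7 - 2 * t_par)
  rownames(mat) <- paste0("s", 1:8)
  m <- fitPCA(PeakSet(mat), 1, scaling = "none")
  expect_equal(m@explained_variance, 1.0, tolerance = 1e-12)
  # full decomposition sums to 1
  ps <- two_group_peakset(5, 4, seed = 2)
  full <- fitPCA(ps, n_components = min(9, 4))
  expect_equal(sum(full@explained_variance), 1.0, tolerance = 1e-10)
  # duplicated samples give duplicated score rows
  mm <- intensities(ps); mm <- rbind(mm, dup = mm[1, ])
  rownames(mm)[nrow(mm)] <- "dup"
  md <- fitPCA(PeakSet(mm), 2)
  expect_equal(unname(md@scores["dup", ]), unname(md@scores[1, ]),
               tolerance = 1e-10)
  # missing values are a directed error
  m2 <- intensities(ps); m2[1, 1] <- NA
  expect_error(fitPCA(PeakSet(m2), 2), "imputeMissing")
  expect_error(fitPCA(ps, 50), "n_components")
})

test_that("VIP is maximal for the separating variable and mean(VIP^2) = 1", {
  ps <- two_group_peakset(10, 8, shift = 3, seed = 4, informative = 1)
  m <- fitPLSDA(ps, n_components = 2, seed = 1)
  expect_equal(mean(m@vip^2), 1, tolerance = 1e-10)
  expect_equal(names(which.max(m@vip)), "V01")
  # scores separate the groups with no overlap
  g <- groups(ps)
  t1 <- m@scores[, 1]
  expect_true(max(t1[g == "A"]) < min(t1[g == "B"]) ||
              min(t1[g == "A"]) > max(t1[g == "B"]))
  # single-variable model: VIP forced to 1
  one <- fitPLSDA(retrieveRows(ps, "V01", "variables"), 1, seed = 1)
  expect_equal(unname(one@vip), 1, tolerance = 1e-10)
})

test_that("the first PLS1 weight is the normalised covariance direction X'y", {
  ps <- two_group_peakset(8, 10, shift = 1.5, seed = 6)
  pls <- fitPLSDA(ps, n_components = 1, orthogonal = 0, seed = 1)
  g <- groups(ps)
  y <- as.numeric(g == unique(g)[2]); y <- y - mean(y)
  w_ref <- unname(crossprod(scale(intensities(ps)), y)[, 1])
  w_ref <- w_ref / sqrt(sum(w_ref^2))
  expect_equal(unname(pls@weights[, 1]), w_ref, tolerance = 1e-10)
  # scores follow as X w
  expect_equal(unname(pls@scores[, 1]),
               unname(scale(intensities(ps)) %*% w_ref)[, 1],
               tolerance = 1e-10)
  opls <- fitPLSDA(ps, n_components = 1, orthogonal = 1, seed = 1)
  expect_equal(dim(opls@orthogonal_scores), c(16L, 1L))
  # orthogonal score is uncorrelated with the predictive score
  expect_lt(abs(cor(opls@scores[, 1], opls@orthogonal_scores[, 1])), 1e-8)
})

test_that("orthogonal filtering concentrates class information in the predictive score", {
  set.seed(23)
  n <- 30; p <- 40
  g <- rep(c(0, 1), each = n / 2)
  ortho <- rnorm(n, sd = 3)                    # strong class-orthogonal trend
  base <- matrix(rnorm(n * p, sd = 1), n, p)
  load_o <- runif(p, 0.5, 1.5)
  load_g <- c(rep(1.2, 5), rep(0, p - 5))      # class signal on 5 variables
  mat <- exp(8 + base * 0.2 + outer(ortho, load_o) * 0.2 +
               outer(g, load_g) * 0.4)
  dimnames(mat) <- list(sprintf("s%02d", 1:n), sprintf("v%02d", 1:p))
  ps <- make_peakset(mat, group = ifelse(g == 1, "B", "A"))
  pls <- fitPLSDA(ps, n_components = 1, orthogonal = 0, seed = 1)
  opls <- fitPLSDA(ps, n_components = 1, orthogonal = 1, seed = 1)
  cor_pls <- abs(cor(pls@scores[, 1], g))
  cor_opls <- abs(cor(opls@scores[, 1], g))
  expect_gt(cor_opls, cor_pls)
})

test_that("permutation p is near-uniform under the null and small under signal", {
  ps <- two_group_peakset(10, 15, shift = 2.5, seed = 9, informative = 3)
  m <- fitPLSDA(ps, orthogonal = 1, n_permutations = 39, seed = 2)
  expect_lt(m@permutation_p, 0.1)
  # shuffled labels: permutation p rarely small
  set.seed(31)
  high <- 0
  for (r in 1:10) {
    g <- sample(groups(ps))
    names(g) <- sampleIds(ps)
    psn <- PeakSet(intensities(ps),
                   sampleData = data.frame(group = g,
                                           row.names = sampleIds(ps)))
    mn <- fitPLSDA(psn, orthogonal = 1, n_permutations = 19, seed = r)
    if (mn@permutation_p > 0.05) high <- high + 1
  }
  expect_gte(high, 8)
})

test_that("fits are reproducible for a fixed seed", {
  ps <- two_group_peakset(8, 12, shift = 1, seed = 10)
  a <- fitPLSDA(ps, orthogonal = 1, n_permutations = 10, seed = 7)
  b <- fitPLSDA(ps, orthogonal = 1, n_permutations = 10, seed = 7)
  expect_identical(a@q2, b@q2)
  expect_identical(a@permutation_q2, b@permutation_q2)
  expect_identical(a@scores, b@scores)
})

test_that("NIPALS scores and VIP agree with an independent PLS implementation", {
  ps <- two_group_peakset(10, 10, shift = 0.7, seed = 44, informative = 2)
  m <- fitPLSDA(ps, n_components = 2, seed = 1)
  mx <- mixOmics::plsda(scale(intensities(ps)), factor(groups(ps)),
                        ncomp = 2, scale = FALSE)
  for (a in 1:2)
    expect_gt(abs(cor(m@scores[, a], mx$variates$X[, a])), 1 - 1e-10)
  expect_equal(unname(m@vip), unname(mixOmics::vip(mx)[, 2]),
               tolerance = 1e-8)
})

test_that("latent model export writes readable coordinate tables", {
  ps <- two_group_peakset(6, 5, shift = 2, seed = 11)
  m <- fitPLSDA(ps, seed = 1)
  prefix <- file.path(withr::local_tempdir(), "pls")
  exportLatentModel(m, prefix)
  vip_back <- readResultTable(paste0(prefix, "_vip.txt"))
  expect_equal(vip_back$vip, unname(m@vip), tolerance = 1e-12)
  scores_back <- readResultTable(paste0(prefix, "_scores.txt"))
  expect_equal(scores_back$t1, unname(m@scores[, 1]), tolerance = 1e-12)
})
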