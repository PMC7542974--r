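test_that("outlier rule replaces |x - mean| > 3 SD points by the max of the rest", {
  v <- c(1, 2, 3, 2, 1, 2, 3, 2, 1, 2, 1000)
  # independent check that 1000 really is the only 3-SD outlier
  mu <- mean(v); s <- sd(v)
  expect_true(abs(1000 - mu) > 3 * s)
  expect_true(all(abs(v[-11] - mu) <= 3 * s))
  mat <- cbind(V1 = v, V2 = rep(5, 11))
  rownames(mat) <- sprintf("S%02d", 1:11)
  out <- replaceOutliers(PeakSet(mat))
  expect_equal(unname(intensities(out$table)[11, "V1"]), 3)  # max of the rest
  expect_equal(out$report$n_outliers_replaced, c(1L, 0L))
  # constant variable: SD 0, nothing replaced
  expect_equal(unname(intensities(out$table)[, "V2"]), rep(5, 11))
})

test_that("outlier replacement skips short variables and is bounded on re-run", {
  mat <- cbind(V1 = c(1, 2, NA, NA, NA), V2 = c(5, 5, 5, 5, 100))
  rownames(mat) <- paste0("S", 1:5)
  expect_warning(out <- replaceOutliers(PeakSet(mat)), "V1")
  expect_equal(unname(intensities(out$table)[, "V1"]), unname(mat[, "V1"]))
  second <- suppressWarnings(replaceOutliers(out$table))
  expect_lte(sum(second$report$n_outliers_replaced),
             sum(out$report$n_outliers_replaced))
})

test_that("imputation honours each strategy's contract", {
  mat <- cbind(V1 = c(2, NA, 6), V2 = c(1, 2, 3))
  rownames(mat) <- paste0("S", 1:3)
  ps <- PeakSet(mat)
  expect_equal(unname(intensities(imputeMissing(ps, "minimum"))[2, "V1"]), 2)
  # knn with k >= n - 1: mean of the other samples' values
  expect_equal(unname(intensities(imputeMissing(ps, "knn", k = 10))[2, "V1"]),
               mean(c(2, 6)))
  # complete table: unchanged under all methods
  full <- two_group_peakset(4, 3, seed = 5)
  for (m in c("minimum", "knn", "qrilc"))
    expect_equal(intensities(imputeMissing(full, m, seed = 1)),
                 intensities(full))
})

test_that("qrilc is seed-reproducible and draws into the left tail", {
  set.seed(11)
  n <- 60
  x <- rlnorm(n, 8, 0.5)
  x[x < quantile(x, 0.25)] <- NA
  mat <- cbind(V1 = x, V2 = rlnorm(n, 8, 0.5))
  rownames(mat) <- sprintf("S%02d", 1:n)
  ps <- PeakSet(mat)
  a <- intensities(imputeMissing(ps, "qrilc", seed = 9))
  b <- intensities(imputeMissing(ps, "qrilc", seed = 9))
  expect_identical(a, b)
  imputed <- a[is.na(mat[, 1]), "V1"]
  observed <- mat[!is.na(mat[, 1]), 1]
  expect_true(all(imputed <= min(observed)))
  expect_lt(median(imputed), median(observed))
  expect_true(all(imputed >= 0))
  expect_equal(sum(is.na(a)), 0L)
})

test_that("all-missing variables are dropped with a warning", {
  mat <- cbind(V1 = c(NA_real_, NA, NA), V2 = c(1, 2, 3))
  rownames(mat) <- paste0("S", 1:3)
  expect_warning(out <- imputeMissing(PeakSet(mat), "minimum"), "V1")
  expect_equal(variableIds(out), "V2")
})

test_that("total-intensity normalization equalises row sums and keeps profiles scale-free", {
  ps <- two_group_peakset(6, 8, seed = 13)
  nr <- normalizeIntensities(ps, "total_intensity")
  sums <- rowSums(intensities(nr$table))
  expect_equal(max(sums) - min(sums), 0, tolerance = 1e-8 * mean(sums))
  expect_true(all(nr$report$divisor > 0))
  # scaling the sample with the largest total by c > 1 leaves the median
  # total, and hence every normalized row, unchanged
  mat <- intensities(ps)
  big <- which.max(rowSums(mat))
  mat2 <- mat; mat2[big, ] <- mat2[big, ] * 7
  nr2 <- normalizeIntensities(PeakSet(mat2, sampleData = sampleMeta(ps)),
                              "total_intensity")
  expect_equal(intensities(nr2$table), intensities(nr$table),
               tolerance = 1e-12)
})

test_that("internal-standard normalization divides by the IS variable", {
  mat <- cbind(IS = c(1, 2, 4), V = c(10, 20, 40))
  rownames(mat) <- paste0("S", 1:3)
  out <- normalizeIntensities(PeakSet(mat), "internal_standard",
                              is_variable = "IS")
  expect_equal(unname(intensities(out$table)[, "V"]), c(10, 10, 10))
  # IS identically 1: identity
  mat1 <- cbind(IS = c(1, 1, 1), V = c(3, 4, 5))
  rownames(mat1) <- paste0("S", 1:3)
  out1 <- normalizeIntensities(PeakSet(mat1), "internal_standard",
                               is_variable = "IS")
  expect_equal(intensities(out1$table), mat1)
  expect_error(normalizeIntensities(PeakSet(mat), "internal_standard",
                                    is_variable = "missing"), "missing")
})

test_that("qc-rlsc shrinks QC variation under a synthetic linear drift", {
  d <- simDesign(n_per_group = 20, n_variables = 15, n_informative = 0,
                 drift_slope = 0.05, qc_every = 4, seed = 31)
  sim <- simulatePeakTable(d)
  tab <- sim$table
  qc <- isQC(tab)
  cv <- function(m) apply(m, 2, function(v) sd(v) / mean(v))
  pre_cv <- cv(intensities(tab)[qc, , drop = FALSE])
  out <- normalizeIntensities(tab, "qc_rlsc")
  post_cv <- cv(intensities(out$table)[qc, , drop = FALSE])
  expect_lt(median(post_cv), median(pre_cv))
  expect_error(normalizeIntensities(two_group_peakset(5, 3), "qc_rlsc"),
               "injection_order")
})

test_that("transforms implement their closed forms and degenerate rules", {
  mat <- cbind(V1 = c(1, exp(1), exp(2)), V2 = c(2, 4, 6), V3 = c(5, 5, 5))
  rownames(mat) <- paste0("S", 1:3)
  lg <- transformIntensities(PeakSet(mat), "log")
  expect_equal(unname(intensities(lg)[, "V1"]), c(0, 1, 2))
  expect_warning(zs <- transformIntensities(PeakSet(mat), "zscore"), "V3")
  z <- intensities(zs)
  expect_equal(unname(colMeans(z[, 1:2])), c(0, 0), tolerance = 1e-12)
  expect_equal(unname(apply(z[, 1:2], 2, sd)), c(1, 1), tolerance = 1e-12)
  expect_equal(unname(z[, "V3"]), c(0, 0, 0))
  neg <- matrix(c(-1, 1), 1, 2, dimnames = list("S1", c("A", "B")))
  ps_neg <- suppressWarnings(PeakSet(abs(neg)))
  m <- intensities(ps_neg); m[1, 1] <- 0
  intensitiesOk <- PeakSet(m)
  expect_silent(transformIntensities(intensitiesOk, "log"))
})

test_that("basic statistics report closed-form summaries overall and per group", {
  mat <- cbind(V1 = c(1, 2, 3, 10, 10, 10))
  rownames(mat) <- paste0("S", 1:6)
  ps <- make_peakset(mat, group = rep(c("A", "B"), each = 3))
  bs <- basicStatistics(ps)
  ov <- bs[bs$stratum == "overall", ]
  a <- bs[bs$stratum == "A", ]
  b <- bs[bs$stratum == "B", ]
  expect_equal(a$mean, 2); expect_equal(a$sd, 1); expect_equal(a$median, 2)
  expect_equal(b$cv_percent, 0)
  expect_equal(ov$n, 6); expect_equal(ov$n_missing, 0)
  # all-missing variable: dropped statistics, n = 0
  mat2 <- cbind(V1 = c(NA_real_, NA), V2 = c(1, 2))
  rownames(mat2) <- paste0("S", 1:2)
  bs2 <- basicStatistics(PeakSet(mat2))
  expect_equal(bs2$n[bs2$variable_id == "V1"], 0)
  expect_true(is.na(bs2$mean[bs2$variable_id == "V1"]))
})
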