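#' @include AllClasses.R AllGenerics.R
NULL

#' Pairwise distances between samples or variables
#'
#' Seven metrics: `euclidean`, `correlation` (1 - Pearson r), `minkowski`
#' (default exponent 3), `canberra`, `binary` (Jaccard on the nonzero
#' pattern), `manhattan`, `maximum`.
#'
#' @param mat items x features numeric matrix.
#' @param distance metric name.
#' @param minkowski_p Minkowski exponent (default 3).
#' @return a `dist` object.
#' @export
featureDistance <- function(mat, distance = c("euclidean", "correlation",
                            "minkowski", "canberra", "binary", "manhattan",
                            "maximum"), minkowski_p = 3) {
  distance <- match.arg(distance)
  if (distance == "correlation") {
    sds <- apply(mat, 1, stats::sd)
    bad <- rownames(mat)[is.na(sds) | sds == 0]
    if (length(bad))
      stop("correlation distance undefined for constant item(s): ",
           paste(bad, collapse = ", "))
    return(stats::as.dist(1 - stats::cor(t(mat))))
  }
  stats::dist(mat, method = distance, p = minkowski_p)
}

#' Hierarchical clustering and sub-cluster analysis
#'
#' Agglomerative clustering of samples or variables under seven distance
#' metrics and seven linkages (`ward` = ward.D2, `mcquitty` = WPGMA,
#' `median` = WPGMC, `centroid` = UPGMC). With `k` the tree is cut into `k`
#' clusters; in variable mode with group labels present, per-cluster mean
#' intensity profiles per sample group are added (sub-cluster analysis).
#'
#' @param x a [PeakSet-class] with no missing values.
#' @param axis cluster `"samples"` or `"variables"`.
#' @param distance see [featureDistance()].
#' @param linkage one of ward, single, complete, average, mcquitty, median,
#'   centroid.
#' @param k optional number of clusters to cut.
#' @param minkowski_p Minkowski exponent.
#' @return list with `tree` (hclust), `assignments` (named cluster ids, when
#'   `k` given) and `cluster_profiles` (sub-cluster group means, variable
#'   mode with groups and `k`).
#' @export
hclusterPeaks <- function(x, axis = c("samples", "variables"),
                          distance = "euclidean",
                          linkage = c("ward", "single", "complete", "average",
                                      "mcquitty", "median", "centroid"),
                          k = NULL, minkowski_p = 3) {
  axis <- match.arg(axis); linkage <- match.arg(linkage)
  mat <- .latent_matrix(x)
  items <- if (axis == "samples") mat else t(mat)
  if (!is.null(k) && k > nrow(items))
    stop("k exceeds the number of items (", nrow(items), ")")
  d <- featureDistance(items, distance, minkowski_p)
  method <- if (linkage == "ward") "ward.D2" else linkage
  tree <- stats::hclust(d, method = method)
  out <- list(tree = tree, assignments = NULL, cluster_profiles = NULL)
  if (!is.null(k)) {
    out$assignments <- stats::cutree(tree, k = k)
    g <- groups(x)
    if (axis == "variables" && !is.null(g)) {
      profiles <- list()
      for (cl in sort(unique(out$assignments))) {
        vars <- names(out$assignments)[out$assignments == cl]
        sub <- mat[, vars, drop = FALSE]
        for (lev in unique(g)) {
          profiles[[length(profiles) + 1L]] <- data.frame(
            cluster = cl, group = lev, n_variables = length(vars),
            mean_intensity = mean(sub[g == lev, , drop = FALSE]),
            sd_intensity = stats::sd(as.numeric(sub[g == lev, , drop = FALSE])))
        }
      }
      out$cluster_profiles <- do.call(rbind, profiles)
    }
  }
  out
}

#' ROC analysis
#'
#' AUC by the rank (Mann-Whitney) formulation with midrank tie correction;
#' the full (FPR, TPR) curve at every threshold; and the cutoff maximizing
#' the Youden index J = TPR - FPR. Higher scores are taken to indicate the
#' positive class.
#'
#' @param scores per-sample numeric scores.
#' @param labels binary labels (logical, 0/1, or a 2-level factor whose
#'   second level is positive).
#' @return list: `auc`, `curve` (data.frame threshold/fpr/tpr), `youden`
#'   (best threshold, its J, TPR, FPR).
#' @export
rocAnalysis <- function(scores, labels) {
  if (is.factor(labels)) labels <- as.integer(labels) - 1L
  labels <- as.integer(as.logical(labels))
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  r <- rank(scores)  # midranks handle ties
  auc <- (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  curve <- data.frame(threshold = thr,
    tpr = vapply(thr, function(t) mean(scores[labels == 1] >= t), numeric(1)),
    fpr = vapply(thr, function(t) mean(scores[labels == 0] >= t), numeric(1)))
  j <- curve$tpr - curve$fpr
  best <- which.max(j)
  list(auc = auc, curve = curve,
       youden = list(threshold = curve$threshold[best], J = j[best],
                     tpr = curve$tpr[best], fpr = curve$fpr[best]))
}

#' Power and sample-size analysis
#'
#' Solves for the missing one of \{power, n\} given a standardized effect
#' size and significance level, using the exact noncentral distribution of
#' the test (both rejection tails are counted, so power tends to `alpha` as
#' the effect vanishes). Effect sizes: Cohen's d (`two_sample_t`,
#' `paired_t`), Cohen's f (`one_way_anova`), Cohen's h (`two_proportions`).
#' `n` is per group (pairs for `paired_t`) and is rounded up when solved
#' for.
#'
#' @param kind test type.
#' @param effect_size standardized effect, > 0.
#' @param alpha two-sided significance level (default 0.05).
#' @param power target power (give exactly one of `power`, `n`).
#' @param n per-group sample size.
#' @param n_groups groups for `one_way_anova` (default 3).
#' @return list with `kind`, `effect_size`, `alpha`, `power`, `n` (the
#'   missing quantity filled in).
#' @export
powerAnalysis <- function(kind = c("two_sample_t", "paired_t",
                          "one_way_anova", "two_proportions"),
                          effect_size, alpha = 0.05, power = NULL, n = NULL,
                          n_groups = 3) {
  kind <- match.arg(kind)
  if (effect_size <= 0) stop("effect_size must be positive")
  if (is.null(power) == is.null(n))
    stop("give exactly one of power, n")
  pw <- function(nn) {
    switch(kind,
      two_sample_t = {
        df <- 2 * nn - 2; ncp <- effect_size * sqrt(nn / 2)
        q <- stats::qt(1 - alpha / 2, df)
        stats::pt(-q, df, ncp) + 1 - stats::pt(q, df, ncp)
      },
      paired_t = {
        df <- nn - 1; ncp <- effect_size * sqrt(nn)
        q <- stats::qt(1 - alpha / 2, df)
        stats::pt(-q, df, ncp) + 1 - stats::pt(q, df, ncp)
      },
      one_way_anova = {
        df1 <- n_groups - 1; df2 <- n_groups * (nn - 1)
        lambda <- n_groups * nn * effect_size^2
        1 - stats::pf(stats::qf(1 - alpha, df1, df2), df1, df2, ncp = lambda)
      },
      two_proportions = {
        z <- stats::qnorm(1 - alpha / 2); delta <- effect_size * sqrt(nn / 2)
        stats::pnorm(-z - delta) + stats::pnorm(delta - z)
      })
  }
  if (is.null(power)) {
    list(kind = kind, effect_size = effect_size, alpha = alpha,
         power = pw(n), n = n)
  } else {
    if (power <= alpha || power >= 1)
      stop("target power must lie in (alpha, 1)")
    lo <- 2; hi <- 2
    while (pw(hi) < power && hi < 1e7) hi <- hi * 2
    if (pw(hi) < power) stop("required n exceeds 1e7")
    n_cont <- if (pw(lo) >= power) lo else
      stats::uniroot(function(nn) pw(nn) - power, c(lo, hi))$root
    n_int <- ceiling(n_cont - 1e-9)
    while (pw(n_int) < power) n_int <- n_int + 1
    list(kind = kind, effect_size = effect_size, alpha = alpha,
         power = pw(n_int), n = n_int)
  }
}

#' Venn region counts for up to six sets
#'
#' @param sets named list of 2 to 6 id vectors.
#' @return list with `regions` (data.frame: one row per non-empty membership
#'   pattern with per-set indicator columns and `count`) and `membership`
#'   (per-element set membership table). Region counts sum to the size of
#'   the union.
#' @export
vennCounts <- function(sets) {
  m <- length(sets)
  if (m < 2 || m > 6) stop("between 2 and 6 sets are supported")
  if (is.null(names(sets)) || any(!nzchar(names(sets))))
    names(sets) <- paste0("set", seq_len(m))
  sets <- lapply(sets, unique)
  universe <- sort(unique(unlist(sets)))
  member <- vapply(sets, function(s) universe %in% s, logical(length(universe)))
  if (length(universe) == 1) member <- matrix(member, nrow = 1,
                                              dimnames = list(NULL, names(sets)))
  patterns <- expand.grid(rep(list(c(FALSE, TRUE)), m))[-1, , drop = FALSE]
  names(patterns) <- names(sets)
  counts <- apply(patterns, 1, function(pat)
    sum(apply(member, 1, function(row) all(row == pat))))
  regions <- cbind(patterns, count = counts)
  rownames(regions) <- NULL
  membership <- data.frame(id = universe, member, row.names = NULL,
                           check.names = FALSE)
  list(regions = regions, membership = membership)
}

#' Ordinary least-squares regression with diagnostics
#'
#' Fits `y ~ X` with an intercept. Collinear predictors are a hard error
#' naming the offending columns.
#'
#' @param y numeric response.
#' @param X numeric vector, matrix or data.frame of predictors.
#' @return list: `coefficients` (data.frame: term, estimate, std_error,
#'   statistic, p), `r_squared`, `adj_r_squared`, `sigma`, `fitted`,
#'   `residuals`.
#' @export
linearRegression <- function(y, X) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  if (length(y) <= ncol(X) + 1)
    stop("need n > p + 1 observations")
  design <- cbind(`(Intercept)` = 1, X)
  qrd <- qr(design)
  if (qrd$rank < ncol(design)) {
    dropped <- colnames(design)[qrd$pivot[seq(qrd$rank + 1, ncol(design))]]
    stop("rank-deficient design; collinear column(s): ",
         paste(dropped, collapse = ", "))
  }
  fit <- stats::lm(y ~ X)
  sm <- summary(fit)
  co <- sm$coefficients
  list(coefficients = data.frame(term = c("(Intercept)", colnames(X)),
                                 estimate = co[, 1], std_error = co[, 2],
                                 statistic = co[, 3], p = co[, 4],
                                 row.names = NULL),
       r_squared = sm$r.squared, adj_r_squared = sm$adj.r.squared,
       sigma = sm$sigma, fitted = stats::fitted(fit),
       residuals = stats::resid(fit))
}
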