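#' @include AllClasses.R AllGenerics.R
NULL

#' Replace extreme intensity values
#'
#' Per variable, data points deviating more than 3 sample standard deviations
#' from the variable mean (both computed once over the non-missing values,
#' n-1 divisor) are replaced by the maximum of the remaining, non-flagged
#' values. Missing entries are untouched. Variables with fewer than three
#' non-missing values are skipped with a warning. With `side = "high"` only
#' upward outliers are replaced.
#'
#' The rule is deliberately single-pass: a second run on its own output can
#' flag additional points (the SD shrinks), so the operation is not
#' idempotent.
#'
#' @param x a [PeakSet-class].
#' @param n_sd threshold in standard deviations (default 3).
#' @param side replace both-sided (default) or only high outliers.
#' @return list with elements `table` (the corrected [PeakSet-class]) and
#'   `report` (data.frame: variable_id, n_outliers_replaced, replacement).
#' @export
replaceOutliers <- function(x, n_sd = 3, side = c("both", "high")) {
  side <- match.arg(side)
  mat <- intensities(x)
  rep_count <- integer(ncol(mat)); rep_value <- rep(NA_real_, ncol(mat))
  skipped <- character()
  for (j in seq_len(ncol(mat))) {
    v <- mat[, j]
    obs <- which(!is.na(v))
    if (length(obs) < 3) { skipped <- c(skipped, colnames(mat)[j]); next }
    mu <- mean(v[obs]); s <- stats::sd(v[obs])
    if (is.na(s) || s == 0) next
    dev <- v[obs] - mu
    flag <- if (side == "both") abs(dev) > n_sd * s else dev > n_sd * s
    if (!any(flag) || all(flag)) next
    repl <- max(v[obs][!flag])
    mat[obs[flag], j] <- repl
    rep_count[j] <- sum(flag); rep_value[j] <- repl
  }
  if (length(skipped))
    warning("variables with < 3 observed values skipped: ",
            paste(skipped, collapse = ", "))
  intensities(x) <- mat
  x@provenance$outliers_replaced <- list(n_sd = n_sd, side = side)
  list(table = x,
       report = data.frame(variable_id = colnames(mat),
                           n_outliers_replaced = rep_count,
                           replacement = rep_value))
}

#' Impute missing intensities
#'
#' Three strategies:
#' \describe{
#'   \item{minimum}{each missing cell takes the variable's observed minimum.}
#'   \item{knn}{each missing cell takes the unweighted mean of the `k`
#'     nearest samples' values for that variable. Sample distances are
#'     Euclidean over the variables observed in both samples (z-scored
#'     first), rescaled by the number of shared variables; `k` is capped at
#'     the number of usable donors.}
#'   \item{qrilc}{quantile-regression imputation of left-censored data: per
#'     variable, a normal distribution is estimated by regressing the
#'     observed order-statistic quantiles on standard-normal quantiles over
#'     the upper 75 percent of the observed distribution (where censoring has
#'     the least bite), and missing cells are drawn from that normal
#'     truncated above at the variable's observed minimum. Reproducible for
#'     a given `seed`.}
#' }
#' Variables with no observed value cannot be imputed and are dropped with a
#' warning.
#'
#' @param x a [PeakSet-class].
#' @param method `"minimum"`, `"knn"`, or `"qrilc"`.
#' @param k neighbours for `knn` (default 10).
#' @param seed integer seed used by `qrilc`.
#' @return imputed [PeakSet-class] with no missing values.
#' @export
imputeMissing <- function(x, method = c("minimum", "knn", "qrilc"), k = 10,
                          seed = 1L) {
  method <- match.arg(method)
  mat <- intensities(x)
  all_missing <- colSums(!is.na(mat)) == 0
  if (any(all_missing)) {
    warning("variables with no observed value dropped: ",
            paste(colnames(mat)[all_missing], collapse = ", "))
    x <- x[!all_missing, ]
    mat <- mat[, !all_missing, drop = FALSE]
  }
  out <- switch(method,
    minimum = .impute_minimum(mat),
    knn = .impute_knn(mat, k),
    qrilc = .impute_qrilc(mat, seed))
  intensities(x) <- out
  x@provenance$imputed <- list(method = method, k = k, seed = seed)
  x
}

.impute_minimum <- function(mat) {
  for (j in seq_len(ncol(mat))) {
    miss <- is.na(mat[, j])
    if (any(miss)) mat[miss, j] <- min(mat[, j], na.rm = TRUE)
  }
  mat
}

.impute_knn <- function(mat, k) {
  n <- nrow(mat)
  # z-score per variable for the distance computation only
  z <- scale(mat)
  z[, attr(z, "scaled:scale") == 0 | is.na(attr(z, "scaled:scale"))] <- 0
  out <- mat
  for (i in seq_len(n)) {
    miss_j <- which(is.na(mat[i, ]))
    if (!length(miss_j)) next
    d <- rep(NA_real_, n)
    for (i2 in seq_len(n)) {
      if (i2 == i) next
      shared <- which(!is.na(z[i, ]) & !is.na(z[i2, ]))
      if (!length(shared)) next
      d[i2] <- sqrt(sum((z[i, shared] - z[i2, shared])^2) / length(shared))
    }
    for (j in miss_j) {
      donors <- which(!is.na(mat[, j]) & !is.na(d))
      if (!length(donors)) next
      ord <- donors[order(d[donors])]
      use <- ord[seq_len(min(k, length(ord)))]
      out[i, j] <- mean(mat[use, j])
    }
  }
  out
}

.impute_qrilc <- function(mat, seed, fit_fraction = 0.75) {
  set.seed(seed)
  out <- mat
  for (j in seq_len(ncol(mat))) {
    miss <- is.na(mat[, j])
    if (!any(miss)) next
    obs <- sort(mat[!miss, j])
    n_obs <- length(obs)
    if (n_obs == 1) { out[miss, j] <- obs; next }
    # probability points of the observed order statistics, shifted up by the
    # (unknown) censored fraction: observed values are the upper part of the
    # full distribution
    p_missing <- sum(miss) / nrow(mat)
    pr <- p_missing + (1 - p_missing) * (seq_len(n_obs) - 0.5) / n_obs
    zq <- stats::qnorm(pr)
    upper <- pr >= stats::quantile(pr, 1 - fit_fraction)
    if (sum(upper) < 2) upper <- rep(TRUE, n_obs)
    fit <- stats::lm(obs[upper] ~ zq[upper])
    mu <- unname(stats::coef(fit)[1]); sig <- max(unname(stats::coef(fit)[2]), 1e-8)
    # draw from N(mu, sig) truncated to (0, observed minimum]: intensities
    # are non-negative, censoring acts from the left
    hi <- stats::pnorm(min(obs), mu, sig)
    lo <- stats::pnorm(0, mu, sig)
    if (hi <= lo) { out[miss, j] <- min(obs); next }
    u <- stats::runif(sum(miss), lo, hi)
    out[miss, j] <- stats::qnorm(u, mu, sig)
  }
  out
}

#' Normalize a peak table across samples
#'
#' \describe{
#'   \item{total_intensity}{each sample is divided by its total signal and
#'     rescaled by the median sample total, so all samples share a common
#'     total intensity.}
#'   \item{internal_standard}{each sample is divided by the intensity of the
#'     named internal-standard variable.}
#'   \item{qc_rlsc}{quality-control based robust LOESS signal correction:
#'     per variable, a LOESS curve (degree 1, span `loess_span`) is fitted to
#'     the QC-sample intensities against injection order and every sample is
#'     divided by the curve value interpolated at its own injection order
#'     (times the variable's QC median, so the intensity scale is kept).}
#' }
#'
#' @param x a [PeakSet-class]; `qc_rlsc` needs `injection_order` and at least
#'   5 QC samples in the sample metadata.
#' @param method normalization method.
#' @param is_variable internal-standard variable id (for
#'   `internal_standard`).
#' @param loess_span LOESS span for `qc_rlsc` (default 0.75).
#' @return list with `table` (normalized [PeakSet-class]) and `report`
#'   (data.frame of per-sample divisors, or per-variable curves summary for
#'   `qc_rlsc`).
#' @export
normalizeIntensities <- function(x, method = c("total_intensity",
                                 "internal_standard", "qc_rlsc"),
                                 is_variable = NULL, loess_span = 0.75) {
  method <- match.arg(method)
  mat <- intensities(x)
  if (method == "total_intensity") {
    totals <- rowSums(mat, na.rm = TRUE)
    bad <- names(totals)[totals <= 0]
    if (length(bad)) stop("non-positive total intensity for sample(s): ",
                          paste(bad, collapse = ", "))
    target <- stats::median(totals)
    factors <- totals / target
    mat <- sweep(mat, 1, factors, "/")
    report <- data.frame(sample_id = rownames(mat), divisor = factors)
  } else if (method == "internal_standard") {
    if (is.null(is_variable) || !is_variable %in% colnames(mat))
      stop("internal-standard variable not found: ", is_variable)
    isv <- mat[, is_variable]
    bad <- rownames(mat)[is.na(isv) | isv <= 0]
    if (length(bad)) stop("internal standard missing or non-positive in sample(s): ",
                          paste(bad, collapse = ", "))
    mat <- sweep(mat, 1, isv, "/")
    report <- data.frame(sample_id = rownames(mat), divisor = isv)
  } else {
    ord <- injectionOrder(x); qc <- isQC(x)
    if (is.null(ord) || any(is.na(ord)))
      stop("qc_rlsc requires a complete injection_order in the sample metadata")
    if (sum(qc) < 5)
      stop("qc_rlsc requires at least 5 QC samples (found ", sum(qc), ")")
    for (j in seq_len(ncol(mat))) {
      y_qc <- mat[qc, j]; o_qc <- ord[qc]
      keep <- !is.na(y_qc)
      if (sum(keep) < 5) next
      fit <- stats::loess(y_qc[keep] ~ o_qc[keep], span = loess_span,
                          degree = 1,
                          control = stats::loess.control(surface = "direct"))
      curve <- stats::predict(fit, newdata = ord)
      # clamp extrapolation beyond the QC range to the edge values
      curve[ord < min(o_qc)] <- stats::predict(fit, newdata = min(o_qc))
      curve[ord > max(o_qc)] <- stats::predict(fit, newdata = max(o_qc))
      ok <- !is.na(curve) & curve > 0
      med <- stats::median(y_qc[keep])
      mat[ok, j] <- mat[ok, j] / curve[ok] * med
    }
    report <- data.frame(sample_id = rownames(mat),
                         injection_order = ord, is_qc = qc)
  }
  intensities(x) <- mat
  x@provenance$normalized <- list(method = method, is_variable = is_variable,
                                  loess_span = loess_span)
  list(table = x, report = report)
}

#' Log or z-score transform
#'
#' `log`: natural log; zeros are shifted by half the smallest positive value
#' of their variable before taking the log (negative values are an error).
#' `zscore`: per-variable centering and unit-variance scaling; constant
#' variables map to all zeros with a warning.
#'
#' @param x a [PeakSet-class].
#' @param method `"log"` or `"zscore"`.
#' @return transformed [PeakSet-class].
#' @export
transformIntensities <- function(x, method = c("log", "zscore")) {
  method <- match.arg(method)
  mat <- intensities(x)
  if (method == "log") {
    if (any(mat < 0, na.rm = TRUE))
      stop("log transform requires non-negative intensities")
    for (j in seq_len(ncol(mat))) {
      v <- mat[, j]
      zero <- !is.na(v) & v == 0
      if (any(zero)) {
        pos <- v[!is.na(v) & v > 0]
        pseudo <- if (length(pos)) min(pos) / 2 else 1
        v[zero] <- pseudo
      }
      mat[, j] <- log(v)
    }
    x@provenance$log_transformed <- TRUE
  } else {
    const <- character()
    for (j in seq_len(ncol(mat))) {
      v <- mat[, j]
      s <- stats::sd(v, na.rm = TRUE)
      if (is.na(s) || s == 0) {
        mat[, j] <- ifelse(is.na(v), NA_real_, 0)
        const <- c(const, colnames(mat)[j])
      } else {
        mat[, j] <- (v - mean(v, na.rm = TRUE)) / s
      }
    }
    if (length(const))
      warning("constant variables mapped to zero: ", paste(const, collapse = ", "))
    x@provenance$zscore_transformed <- TRUE
  }
  md <- metadata(x); md$transformed <- TRUE; metadata(x) <- md
  intensities(x) <- mat
  x
}

#' Per-variable summary statistics
#'
#' For each variable (overall and, when a `group` column is present, per
#' group): number of observed values, mean, SD, median, min, max, coefficient
#' of variation in percent, and missing count.
#'
#' @param x a [PeakSet-class].
#' @return data.frame with one row per variable x stratum.
#' @export
basicStatistics <- function(x) {
  mat <- intensities(x)
  g <- groups(x)
  strata <- list(overall = rep(TRUE, nrow(mat)))
  if (!is.null(g))
    for (lev in unique(g)) strata[[lev]] <- g == lev
  rows <- list()
  for (s in names(strata)) {
    sub <- mat[strata[[s]], , drop = FALSE]
    for (j in seq_len(ncol(sub))) {
      v <- sub[, j]; obs <- v[!is.na(v)]
      n <- length(obs)
      rows[[length(rows) + 1L]] <- data.frame(
        variable_id = colnames(sub)[j], stratum = s, n = n,
        mean = if (n) mean(obs) else NA_real_,
        sd = if (n > 1) stats::sd(obs) else NA_real_,
        median = if (n) stats::median(obs) else NA_real_,
        min = if (n) min(obs) else NA_real_,
        max = if (n) max(obs) else NA_real_,
        cv_percent = if (n > 1 && mean(obs) != 0)
          100 * stats::sd(obs) / mean(obs) else if (n > 1) NA_real_ else NA_real_,
        n_missing = sum(is.na(v)))
    }
  }
  do.call(rbind, rows)
}
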