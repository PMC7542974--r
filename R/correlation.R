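#' @include AllClasses.R AllGenerics.R
NULL

.feature_matrix <- function(x) {
  if (is(x, "PeakSet")) intensities(x) else as.matrix(x)
}

.rank_residualize <- function(v, Z) {
  # partial Spearman: residualize the ranks on the rank-transformed
  # confounders
  r <- rank(v)
  if (is.null(Z) || ncol(Z) == 0) return(r - mean(r))
  Zr <- apply(Z, 2, rank)
  stats::resid(stats::lm(r ~ Zr))
}

#' Pairwise feature correlation
#'
#' All pairwise correlations within one table or across two tables, by
#' Pearson, Spearman, Kendall, or partial Spearman (Spearman on the
#' residuals of rank-transformed features regressed on the confounders).
#' p-values are corrected across all reported pairs.
#'
#' @param a samples x features matrix or [PeakSet-class].
#' @param b optional second table sharing samples with `a`; when given,
#'   correlations are computed across tables only.
#' @param method correlation method.
#' @param confounders numeric matrix/data.frame of per-sample confounders
#'   (required for `partial_spearman`).
#' @param correction method for [adjustPvalues()] (default `"fdr"`).
#' @return data.frame: feature_a, feature_b, method, r, p, q.
#' @export
correlateFeatures <- function(a, b = NULL,
                              method = c("pearson", "spearman", "kendall",
                                         "partial_spearman"),
                              confounders = NULL,
                              correction = c("fdr", "bonferroni", "holm")) {
  method <- match.arg(method); correction <- match.arg(correction)
  ma <- .feature_matrix(a)
  mb <- if (is.null(b)) NULL else .feature_matrix(b)
  if (!is.null(mb)) {
    shared <- intersect(rownames(ma), rownames(mb))
    if (length(shared) < 4) stop("need at least 4 shared samples (found ",
                                 length(shared), ")")
    ma <- ma[shared, , drop = FALSE]; mb <- mb[shared, , drop = FALSE]
  } else if (nrow(ma) < 4) stop("need at least 4 samples")
  Z <- NULL
  if (method == "partial_spearman") {
    if (is.null(confounders)) stop("partial_spearman requires confounders")
    Z <- as.matrix(confounders)
    Z <- Z[rownames(ma), , drop = FALSE]
  }
  corr_one <- function(u, v) {
    if (method == "partial_spearman") {
      ru <- .rank_residualize(u, Z); rv <- .rank_residualize(v, Z)
      ct <- stats::cor.test(ru, rv, method = "pearson")
    } else {
      ct <- suppressWarnings(stats::cor.test(u, v, method = method,
                                             exact = FALSE))
    }
    c(r = unname(ct$estimate), p = ct$p.value)
  }
  rows <- list()
  if (is.null(mb)) {
    ids <- colnames(ma)
    for (i in seq_len(ncol(ma) - 1)) for (j in seq((i + 1), ncol(ma))) {
      rp <- corr_one(ma[, i], ma[, j])
      rows[[length(rows) + 1L]] <- data.frame(
        feature_a = ids[i], feature_b = ids[j], method = method,
        r = rp["r"], p = rp["p"], stringsAsFactors = FALSE)
    }
  } else {
    for (i in seq_len(ncol(ma))) for (j in seq_len(ncol(mb))) {
      rp <- corr_one(ma[, i], mb[, j])
      rows[[length(rows) + 1L]] <- data.frame(
        feature_a = colnames(ma)[i], feature_b = colnames(mb)[j],
        method = method, r = rp["r"], p = rp["p"], stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$q <- adjustPvalues(out$p, correction)
  rownames(out) <- NULL
  out
}

#' Distance correlation
#'
#' Sample distance correlation (double-centered Euclidean distance matrices)
#' between two numeric vectors: a value in [0, 1] that is zero (in
#' population) exactly under independence, sensitive to nonlinear
#' association.
#'
#' @param x,y numeric vectors of equal length.
#' @return distance correlation in [0, 1].
#' @export
distanceCorrelation <- function(x, y) {
  n <- length(x)
  stopifnot(length(y) == n, n >= 3)
  A <- .dcenter(abs(outer(x, x, "-")))
  B <- .dcenter(abs(outer(y, y, "-")))
  dcov2 <- mean(A * B)
  dvx <- mean(A * A); dvy <- mean(B * B)
  if (dvx <= 0 || dvy <= 0) return(0)
  sqrt(max(dcov2, 0) / sqrt(dvx * dvy))
}

.dcenter <- function(D) {
  sweep(sweep(D, 1, rowMeans(D)), 2, colMeans(D)) + mean(D)
}

#' Centered log-ratio transform of a composition table
#'
#' Zeros are replaced by half the smallest positive value of the whole
#' table before the per-sample geometric-mean log-ratio.
#'
#' @param mat samples x taxa non-negative matrix.
#' @return CLR-transformed matrix.
#' @export
clrTransform <- function(mat) {
  mat <- as.matrix(mat)
  if (any(mat < 0, na.rm = TRUE)) stop("abundances must be non-negative")
  pos_min <- suppressWarnings(min(mat[mat > 0], na.rm = TRUE))
  if (!is.finite(pos_min)) stop("abundance table is all zero")
  mat[mat == 0] <- pos_min / 2
  lg <- log(mat)
  sweep(lg, 1, rowMeans(lg))
}

#' Generalized metabolome-microbiome correlation (GRaMM-style)
#'
#' For every metabolite-taxon pair: (1) taxa are CLR-transformed; (2) both
#' features are residualized on the confounders by linear regression;
#' (3) a linear channel computes Pearson correlation on the residuals and a
#' nonlinear channel computes the distance correlation with a seeded
#' permutation p-value; (4) the pair is labelled `linear` when the linear
#' channel's p-value is at most the nonlinear one's, else `nonlinear`; the
#' winning channel supplies the reported r and p. q is FDR across all pairs.
#'
#' The two-channel arbitration and CLR preprocessing are this package's
#' concrete design for the generalized-correlation contract; the linear
#' channel's r is signed, the nonlinear channel's r is a [0, 1] strength.
#'
#' @param metab samples x metabolites matrix or [PeakSet-class].
#' @param microbe samples x taxa non-negative matrix.
#' @param confounders optional per-sample numeric matrix/data.frame.
#' @param n_permutations permutations for the distance-correlation p
#'   (default 199).
#' @param log_metabolites natural-log the metabolite intensities first
#'   (default TRUE, the usual scale for concentration data; zeros get half
#'   the variable's smallest positive value).
#' @param seed integer seed.
#' @return data.frame: metabolite, taxon, type, r, p, q plus both channels'
#'   statistics (r_linear, p_linear, r_nonlinear, p_nonlinear).
#' @export
gramm <- function(metab, microbe, confounders = NULL, n_permutations = 199,
                  log_metabolites = TRUE, seed = 1L) {
  mm <- .feature_matrix(metab)
  if (log_metabolites) {
    if (any(mm < 0, na.rm = TRUE))
      stop("metabolite intensities must be non-negative for the log scale")
    for (j in seq_len(ncol(mm))) {
      v <- mm[, j]; zero <- !is.na(v) & v == 0
      if (any(zero)) {
        pos <- v[v > 0 & !is.na(v)]
        v[zero] <- if (length(pos)) min(pos) / 2 else 1
      }
      mm[, j] <- log(v)
    }
  }
  tb <- as.matrix(microbe)
  shared <- intersect(rownames(mm), rownames(tb))
  if (!length(shared)) stop("no shared samples between tables")
  if (length(shared) < 20)
    warning("fewer than 20 shared samples; nonlinear detection is weak")
  mm <- mm[shared, , drop = FALSE]
  tb <- clrTransform(tb[shared, , drop = FALSE])
  Z <- NULL
  if (!is.null(confounders)) {
    Z <- as.matrix(confounders)[shared, , drop = FALSE]
  }
  residualize <- function(v) {
    if (is.null(Z) || ncol(Z) == 0) return(v - mean(v))
    stats::resid(stats::lm(v ~ Z))
  }
  set.seed(seed)
  res_m <- apply(mm, 2, residualize)
  res_t <- apply(tb, 2, residualize)
  rows <- list()
  n <- length(shared)
  for (i in seq_len(ncol(res_m))) for (j in seq_len(ncol(res_t))) {
    u <- res_m[, i]; v <- res_t[, j]
    lin <- suppressWarnings(stats::cor.test(u, v, method = "pearson"))
    dc <- distanceCorrelation(u, v)
    perm_ge <- 0L
    for (b in seq_len(n_permutations)) {
      if (distanceCorrelation(u, v[sample(n)]) >= dc) perm_ge <- perm_ge + 1L
    }
    p_nl <- (1 + perm_ge) / (1 + n_permutations)
    is_linear <- lin$p.value <= p_nl
    rows[[length(rows) + 1L]] <- data.frame(
      metabolite = colnames(res_m)[i], taxon = colnames(res_t)[j],
      type = if (is_linear) "linear" else "nonlinear",
      r = if (is_linear) unname(lin$estimate) else dc,
      p = if (is_linear) lin$p.value else p_nl,
      r_linear = unname(lin$estimate), p_linear = lin$p.value,
      r_nonlinear = dc, p_nonlinear = p_nl, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out$q <- adjustPvalues(out$p, "fdr")
  rownames(out) <- NULL
  out
}

#' Retrieve correlation pairs passing a criterion as a network edge list
#'
#' Filters a correlation result (from [correlateFeatures()] or [gramm()]) by
#' minimum absolute r and maximum q, drops self-pairs, and returns a
#' SIF-style edge list (source, interaction = sign of r, target, r, q)
#' sorted by |r| descending, loadable by network tools such as Cytoscape.
#'
#' @param results correlation result data.frame.
#' @param min_abs_r minimum |r| (inclusive, default 0.6).
#' @param max_q maximum q (exclusive, default 0.05).
#' @return edge-list data.frame.
#' @export
retrievePairs <- function(results, min_abs_r = 0.6, max_q = 0.05) {
  acol <- if ("feature_a" %in% names(results)) "feature_a" else "metabolite"
  bcol <- if ("feature_b" %in% names(results)) "feature_b" else "taxon"
  keep <- !is.na(results$r) & abs(results$r) >= min_abs_r &
    !is.na(results$q) & results$q < max_q &
    results[[acol]] != results[[bcol]]
  sub <- results[keep, , drop = FALSE]
  sub <- sub[order(-abs(sub$r), sub[[acol]], sub[[bcol]]), , drop = FALSE]
  data.frame(source = sub[[acol]],
             interaction = ifelse(sub$r >= 0, "positive", "negative"),
             target = sub[[bcol]], r = sub$r, q = sub$q,
             row.names = NULL, stringsAsFactors = FALSE)
}
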