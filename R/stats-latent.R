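#' @include AllClasses.R AllGenerics.R
NULL

.latent_matrix <- function(x) {
  mat <- intensities(x)
  if (anyNA(mat))
    stop("matrix contains missing values; run imputeMissing() first")
  mat
}

.center_scale <- function(mat, scaling) {
  ctr <- colMeans(mat)
  scl <- if (scaling == "unit_variance") apply(mat, 2, stats::sd) else
    rep(1, ncol(mat))
  scl[scl == 0 | is.na(scl)] <- 1
  list(x = sweep(sweep(mat, 2, ctr), 2, scl, "/"), center = ctr, scale = scl)
}

#' Principal component analysis
#'
#' Centered (optionally unit-variance scaled, the metabolomics default)
#' singular value decomposition. The sign convention makes the
#' largest-magnitude loading of each component positive, so output is
#' deterministic.
#'
#' @param x a [PeakSet-class] with no missing values.
#' @param n_components number of components, at most `min(n - 1, p)`.
#' @param scaling `"unit_variance"` (default) or `"none"`.
#' @return a [LatentModel-class]; `explained_variance` holds the fraction of
#'   (scaled) variance per component.
#' @export
fitPCA <- function(x, n_components = 2,
                   scaling = c("unit_variance", "none")) {
  scaling <- match.arg(scaling)
  mat <- .latent_matrix(x)
  n <- nrow(mat); p <- ncol(mat)
  kmax <- min(n - 1, p)
  if (n_components > kmax)
    stop("n_components must be <= min(n - 1, p) = ", kmax)
  cs <- .center_scale(mat, scaling)
  sv <- svd(cs$x)
  k <- seq_len(n_components)
  loadings <- sv$v[, k, drop = FALSE]
  scores <- sv$u[, k, drop = FALSE] %*% diag(sv$d[k], n_components)
  # sign convention: largest |loading| positive per component
  for (a in k) {
    s <- sign(loadings[which.max(abs(loadings[, a])), a])
    if (s < 0) { loadings[, a] <- -loadings[, a]; scores[, a] <- -scores[, a] }
  }
  dimnames(scores) <- list(rownames(mat), paste0("PC", k))
  dimnames(loadings) <- list(colnames(mat), paste0("PC", k))
  ev <- sv$d[k]^2 / sum(sv$d^2)
  new("LatentModel", method = "pca", scores = scores, loadings = loadings,
      weights = matrix(0, 0, 0), explained_variance = ev, vip = numeric(),
      n_orthogonal = 0, orthogonal_scores = matrix(0, 0, 0),
      r2y = NA_real_, q2 = NA_real_, permutation_p = NA_real_,
      permutation_q2 = numeric(),
      details = list(center = cs$center, scale = cs$scale,
                     singular_values = sv$d))
}

# ---- NIPALS machinery ----------------------------------------------------

.nipals_pls <- function(X, Y, ncomp, tol = 1e-10, maxit = 500) {
  n <- nrow(X); p <- ncol(X); q <- ncol(Y)
  W <- matrix(0, p, ncomp); P <- matrix(0, p, ncomp)
  Tm <- matrix(0, n, ncomp); C <- matrix(0, q, ncomp)
  ssx0 <- sum(X^2); ssy0 <- sum(Y^2)
  r2x <- numeric(ncomp); ssy_expl <- numeric(ncomp)
  for (a in seq_len(ncomp)) {
    u <- Y[, which.max(colSums(Y^2))]
    t_old <- rep(Inf, n)
    for (it in seq_len(maxit)) {
      w <- crossprod(X, u)[, 1]
      w <- w / sqrt(sum(w^2))
      tt <- X %*% w
      cc <- crossprod(Y, tt)[, 1] / sum(tt^2)
      u <- (Y %*% cc) / sum(cc^2)
      if (sum((tt - t_old)^2) / max(sum(tt^2), 1e-300) < tol^2) break
      t_old <- tt
    }
    pp <- crossprod(X, tt)[, 1] / sum(tt^2)
    ssy_expl[a] <- sum(cc^2) * sum(tt^2)
    r2x[a] <- sum(tt^2) * sum(pp^2) / ssx0
    X <- X - tt %*% t(pp)
    Y <- Y - tt %*% t(cc)
    W[, a] <- w; P[, a] <- pp; Tm[, a] <- tt; C[, a] <- cc
  }
  list(W = W, P = P, T = Tm, C = C, r2x = r2x, ssy_expl = ssy_expl,
       ssy0 = ssy0, r2y = cumsum(ssy_expl) / ssy0)
}

.vip_from_pls <- function(W, ssy_expl) {
  p <- nrow(W)
  denom <- sum(ssy_expl)
  if (denom <= 0) return(rep(NA_real_, p))
  sqrt(p * colSums(t(W^2) * ssy_expl) / denom)
}

.opls_filter <- function(X, y, n_orth) {
  # y: centered numeric vector; returns filtered X and orthogonal components
  w <- crossprod(X, y)[, 1]
  w <- w / sqrt(sum(w^2))
  To <- matrix(0, nrow(X), n_orth); Po <- matrix(0, ncol(X), n_orth)
  Wo <- matrix(0, ncol(X), n_orth)
  if (n_orth > 0) for (a in seq_len(n_orth)) {
    tt <- X %*% w
    pp <- crossprod(X, tt)[, 1] / sum(tt^2)
    wo <- pp - sum(w * pp) * w
    nwo <- sqrt(sum(wo^2))
    if (nwo < 1e-12) { To <- To[, seq_len(a - 1), drop = FALSE]
                       Po <- Po[, seq_len(a - 1), drop = FALSE]
                       Wo <- Wo[, seq_len(a - 1), drop = FALSE]; break }
    wo <- wo / nwo
    to <- X %*% wo
    po <- crossprod(X, to)[, 1] / sum(to^2)
    X <- X - to %*% t(po)
    To[, a] <- to; Po[, a] <- po; Wo[, a] <- wo
  }
  list(X = X, w = w, T_orth = To, P_orth = Po, W_orth = Wo)
}

.make_dummy <- function(g, levs) {
  if (length(levs) == 2) {
    y <- matrix(as.numeric(g == levs[2]), ncol = 1,
                dimnames = list(names(g), levs[2]))
  } else {
    y <- vapply(levs, function(l) as.numeric(g == l), numeric(length(g)))
    dimnames(y) <- list(names(g), levs)
  }
  y
}

.stratified_folds <- function(g, k) {
  fold <- integer(length(g))
  for (lev in unique(g)) {
    i <- which(g == lev)
    fold[i] <- rep_len(sample(k), length(i))[sample(length(i))]
  }
  fold
}

.q2_cv <- function(mat, g, levs, n_components, n_orth, scaling, cv_folds) {
  # cross-validated Q2 of the (O)PLS-DA model; folds stratified by group
  y_full <- .make_dummy(g, levs)
  fold <- .stratified_folds(g, cv_folds)
  press <- 0; tss <- 0
  for (f in sort(unique(fold))) {
    tr <- fold != f; te <- !tr
    if (sum(tr) < 3 || length(unique(g[tr])) < length(levs)) next
    cs <- .center_scale(mat[tr, , drop = FALSE], scaling)
    Xtr <- cs$x
    Xte <- sweep(sweep(mat[te, , drop = FALSE], 2, cs$center), 2, cs$scale, "/")
    Ytr <- y_full[tr, , drop = FALSE]
    ymean <- colMeans(Ytr)
    Ytrc <- sweep(Ytr, 2, ymean)
    if (n_orth > 0 && ncol(Ytrc) == 1) {
      of <- .opls_filter(Xtr, Ytrc[, 1], n_orth)
      Xtr <- of$X
      if (ncol(of$T_orth) > 0) for (a in seq_len(ncol(of$T_orth))) {
        to <- Xte %*% of$W_orth[, a]
        Xte <- Xte - to %*% t(of$P_orth[, a])
      }
    }
    fit <- .nipals_pls(Xtr, Ytrc, n_components)
    # regression prediction: Y_hat = Xte B, B from NIPALS factors
    R <- fit$W %*% solve(t(fit$P) %*% fit$W)
    B <- R %*% t(fit$C)
    Yhat <- sweep(Xte %*% B, 2, ymean, "+")
    Yte <- y_full[te, , drop = FALSE]
    press <- press + sum((Yte - Yhat)^2)
    tss <- tss + sum(sweep(Yte, 2, ymean)^2)
  }
  if (tss == 0) return(NA_real_)
  1 - press / tss
}

#' Fit a PLS-DA or OPLS-DA model
#'
#' NIPALS partial least squares discriminant analysis on the unit-variance
#' scaled (by default) peak matrix against a dummy-coded group response.
#' With `orthogonal > 0` (two groups only) the stated number of
#' class-orthogonal components is removed first and a single predictive
#' component is fitted on the filtered matrix (OPLS-DA). Per-variable VIP
#' scores are computed from the predictive weights and the response variance
#' explained per component, normalised so `mean(vip^2) = 1` for a single
#' response.
#'
#' Model validation: Q2 by `cv_folds`-fold cross-validation stratified by
#' group, and an optional label-permutation test. The permutation p-value
#' uses the add-one estimator `(1 + #\{Q2_perm >= Q2\}) / (1 + n_permutations)`
#' so it is never exactly zero. All randomness is governed by `seed`.
#'
#' @param x a [PeakSet-class], no missing values.
#' @param n_components predictive components (default 2; forced to 1 when
#'   `orthogonal > 0`).
#' @param orthogonal number of orthogonal components (0 = plain PLS-DA).
#' @param n_permutations label permutations for the validation test
#'   (default 0 = skip).
#' @param cv_folds folds for Q2 (default 7).
#' @param scaling `"unit_variance"` or `"none"`.
#' @param seed integer seed.
#' @return a [LatentModel-class].
#' @export
fitPLSDA <- function(x, n_components = 2, orthogonal = 0,
                     n_permutations = 0, cv_folds = 7,
                     scaling = c("unit_variance", "none"), seed = 1L) {
  scaling <- match.arg(scaling)
  mat <- .latent_matrix(x)
  g <- groups(x)
  if (is.null(g)) stop("sample metadata has no 'group' column")
  levs <- unique(g)
  if (length(levs) < 2) stop("PLS-DA needs at least 2 groups")
  if (orthogonal > 0 && length(levs) != 2)
    stop("OPLS-DA requires exactly 2 groups")
  if (orthogonal > 0) n_components <- 1
  n_components <- min(n_components, nrow(mat) - 1, ncol(mat))

  cs <- .center_scale(mat, scaling)
  X <- cs$x
  Y <- .make_dummy(g, levs)
  Yc <- sweep(Y, 2, colMeans(Y))

  orth_scores <- matrix(0, 0, 0); n_orth_used <- 0
  if (orthogonal > 0) {
    of <- .opls_filter(X, Yc[, 1], orthogonal)
    X <- of$X
    orth_scores <- of$T_orth
    n_orth_used <- ncol(of$T_orth)
    if (nrow(orth_scores)) rownames(orth_scores) <- rownames(mat)
  }
  fit <- .nipals_pls(X, Yc, n_components)
  vip <- .vip_from_pls(fit$W, fit$ssy_expl)
  names(vip) <- colnames(mat)
  scores <- fit$T
  dimnames(scores) <- list(rownames(mat),
                           paste0("t", seq_len(ncol(scores))))
  loadings <- fit$P; weights <- fit$W
  dimnames(loadings) <- dimnames(weights) <-
    list(colnames(mat), paste0("comp", seq_len(ncol(loadings))))

  set.seed(seed)
  q2 <- .q2_cv(mat, g, levs, n_components, orthogonal, scaling, cv_folds)
  perm_q2 <- numeric(0); perm_p <- NA_real_
  if (n_permutations > 0) {
    perm_q2 <- vapply(seq_len(n_permutations), function(b) {
      gp <- stats::setNames(sample(g), names(g))
      .q2_cv(mat, gp, levs, n_components, orthogonal, scaling, cv_folds)
    }, numeric(1))
    perm_p <- (1 + sum(perm_q2 >= q2, na.rm = TRUE)) / (1 + n_permutations)
  }

  new("LatentModel",
      method = if (orthogonal > 0) "oplsda" else "plsda",
      scores = scores, loadings = loadings, weights = weights,
      explained_variance = fit$r2x, vip = vip,
      n_orthogonal = n_orth_used, orthogonal_scores = orth_scores,
      r2y = fit$r2y[length(fit$r2y)], q2 = q2,
      permutation_p = perm_p, permutation_q2 = perm_q2,
      details = list(levels = levs, center = cs$center, scale = cs$scale,
                     seed = seed, cv_folds = cv_folds,
                     scaling = scaling))
}

#' VIP scores of a fitted discriminant model
#' @param model a [LatentModel-class] from [fitPLSDA()].
#' @return named numeric vector of VIP values.
#' @export
vipScores <- function(model) {
  if (!length(model@vip)) stop("model carries no VIP scores (PCA?)")
  model@vip
}

#' Export scores/loadings/VIP as plain-text coordinate tables
#'
#' Writes `<prefix>_scores.txt`, `<prefix>_loadings.txt` and, for
#' discriminant models, `<prefix>_vip.txt`.
#'
#' @param model a [LatentModel-class].
#' @param prefix output path prefix.
#' @return character vector of written paths, invisibly.
#' @export
exportLatentModel <- function(model, prefix) {
  paths <- character()
  sc <- data.frame(sample_id = rownames(model@scores), model@scores,
                   check.names = FALSE)
  writeResultTable(sc, paste0(prefix, "_scores.txt"))
  paths <- c(paths, paste0(prefix, "_scores.txt"))
  ld <- data.frame(variable_id = rownames(model@loadings), model@loadings,
                   check.names = FALSE)
  writeResultTable(ld, paste0(prefix, "_loadings.txt"))
  paths <- c(paths, paste0(prefix, "_loadings.txt"))
  if (length(model@vip)) {
    vip <- data.frame(variable_id = names(model@vip), vip = model@vip)
    writeResultTable(vip, paste0(prefix, "_vip.txt"))
    paths <- c(paths, paste0(prefix, "_vip.txt"))
  }
  invisible(paths)
}
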