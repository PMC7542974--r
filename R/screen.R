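#' @include AllClasses.R AllGenerics.R stats-latent.R
NULL

.group_factor <- function(x) {
  g <- groups(x)
  if (is.null(g)) stop("sample metadata has no 'group' column")
  factor(g)
}

#' Random-forest variable importance
#'
#' Seeded random forest on the group labels; importance is the permutation
#' (mean decrease in accuracy) measure, ranked descending. The out-of-bag
#' error rate is reported alongside.
#'
#' @param x a [PeakSet-class], no missing values, 2+ groups.
#' @param n_trees forest size (default 500).
#' @param seed integer seed.
#' @return list with `result` (data.frame: variable_id, importance, rank)
#'   and `oob_error` (overall out-of-bag error rate).
#' @export
rfImportance <- function(x, n_trees = 500, seed = 1L) {
  mat <- .latent_matrix(x)
  g <- .group_factor(x)
  if (nlevels(g) < 2) stop("need at least 2 groups")
  set.seed(seed)
  rf <- randomForest::randomForest(x = mat, y = g, ntree = n_trees,
                                   importance = TRUE)
  imp <- randomForest::importance(rf, type = 1)[, 1]
  ord <- order(-imp, names(imp))
  res <- data.frame(variable_id = names(imp), importance = unname(imp))
  res$rank <- NA_integer_; res$rank[ord] <- seq_along(ord)
  list(result = res[order(res$rank), , drop = FALSE],
       oob_error = unname(rf$err.rate[n_trees, "OOB"]))
}

.cv_folds_index <- function(g, k) {
  fold <- integer(length(g))
  for (lev in levels(g)) {
    i <- which(g == lev)
    fold[i] <- rep_len(sample(k), length(i))[sample(length(i))]
  }
  fold
}

.svm_cv_perm_importance <- function(X, g, kernel, folds = 5) {
  # permutation importance on held-out folds: mean accuracy drop per feature
  fold <- .cv_folds_index(g, folds)
  drop_sum <- numeric(ncol(X)); base_acc <- 0; nfold <- 0
  for (f in sort(unique(fold))) {
    tr <- fold != f
    if (length(unique(g[tr])) < 2 || sum(!tr) == 0) next
    fit <- e1071::svm(x = X[tr, , drop = FALSE], y = g[tr], kernel = kernel,
                      scale = TRUE, cost = 1, gamma = 1 / ncol(X))
    Xte <- X[!tr, , drop = FALSE]
    acc0 <- mean(stats::predict(fit, Xte) == g[!tr])
    base_acc <- base_acc + acc0; nfold <- nfold + 1
    for (j in seq_len(ncol(X))) {
      Xp <- Xte
      Xp[, j] <- Xp[sample(nrow(Xp)), j]
      drop_sum[j] <- drop_sum[j] + acc0 - mean(stats::predict(fit, Xp) == g[!tr])
    }
  }
  list(importance = drop_sum / max(nfold, 1), cv_accuracy = base_acc / max(nfold, 1))
}

#' SVM variable ranking
#'
#' Two-group support vector machine ranking. With the linear kernel,
#' variables are ranked by the absolute primal weight `|w_j|` of the fitted
#' maximum-margin hyperplane. With the nonlinear kernels (polynomial,
#' radial, sigmoid), recursive feature elimination is used: per round, the
#' cross-validated permutation-importance of each surviving variable is
#' measured and the least important fifth is eliminated; rank is the reverse
#' elimination order. Fixed sensible defaults: cost 1, gamma `1/p`.
#'
#' @param x a [PeakSet-class], exactly 2 groups, no missing values.
#' @param kernel `"linear"`, `"polynomial"`, `"radial"`, or `"sigmoid"`.
#' @param folds cross-validation folds for the nonlinear ranking (default 5).
#' @param seed integer seed.
#' @return list with `result` (variable_id, importance, rank) and
#'   `cv_accuracy` (linear: in-sample CV accuracy of the full model).
#' @export
svmRank <- function(x, kernel = c("linear", "polynomial", "radial", "sigmoid"),
                    folds = 5, seed = 1L) {
  kernel <- match.arg(kernel)
  mat <- .latent_matrix(x)
  g <- .group_factor(x)
  if (nlevels(g) != 2) stop("svmRank supports exactly 2 groups")
  set.seed(seed)
  if (kernel == "linear") {
    fit <- e1071::svm(x = mat, y = g, kernel = "linear", scale = TRUE,
                      cost = 1, cross = min(folds, min(table(g))))
    w <- t(fit$coefs) %*% fit$SV
    imp <- abs(as.numeric(w))
    names(imp) <- colnames(mat)
    cv_acc <- if (!is.null(fit$tot.accuracy)) fit$tot.accuracy / 100 else NA_real_
  } else {
    surviving <- colnames(mat)
    elim_order <- character()
    cv_acc <- NA_real_
    while (length(surviving) > 1) {
      pi <- .svm_cv_perm_importance(mat[, surviving, drop = FALSE], g, kernel,
                                    folds)
      if (is.na(cv_acc)) cv_acc <- pi$cv_accuracy
      k_drop <- max(1L, floor(length(surviving) / 5))
      drop_idx <- order(pi$importance, surviving)[seq_len(k_drop)]
      elim_order <- c(elim_order, surviving[drop_idx])
      surviving <- surviving[-drop_idx]
    }
    ranking <- rev(c(elim_order, surviving))
    imp <- stats::setNames(rev(seq_along(ranking)) / length(ranking), ranking)
    imp <- imp[colnames(mat)]
  }
  ord <- order(-imp, names(imp))
  res <- data.frame(variable_id = names(imp), importance = unname(imp))
  res$rank <- NA_integer_; res$rank[ord] <- seq_along(ord)
  list(result = res[order(res$rank), , drop = FALSE], cv_accuracy = cv_acc)
}

#' Boruta-style shadow-feature confirmation
#'
#' All-relevant marker confirmation: per iteration every candidate variable
#' gets a "shadow" copy with its rows independently permuted; a random
#' forest is fitted on candidates plus shadows and a candidate scores a hit
#' when its permutation importance exceeds the maximum shadow importance.
#' After each iteration a two-sided binomial test (hits out of iterations,
#' null probability 0.5, Bonferroni-corrected across candidates) promotes
#' candidates to `confirmed` or demotes them to `rejected`; undecided
#' candidates at `max_iter` stay `tentative`.
#'
#' @param x a [PeakSet-class], no missing values.
#' @param candidates variable ids to test (non-empty, subset of the table).
#' @param max_iter maximum iterations (default 100).
#' @param alpha significance level of the binomial decision (default 0.01).
#' @param n_trees trees per inner forest (default 300).
#' @param seed integer seed.
#' @return data.frame: variable_id, hits, iterations, decision.
#' @export
borutaConfirm <- function(x, candidates, max_iter = 100, alpha = 0.01,
                          n_trees = 300, seed = 1L) {
  if (!length(candidates)) stop("candidates is empty")
  unknown <- setdiff(candidates, variableIds(x))
  if (length(unknown)) stop("unknown candidate variable(s): ",
                            paste(unknown, collapse = ", "))
  mat <- .latent_matrix(x)[, candidates, drop = FALSE]
  g <- .group_factor(x)
  set.seed(seed)
  m <- length(candidates)
  hits <- stats::setNames(integer(m), candidates)
  tested <- stats::setNames(integer(m), candidates)
  decision <- stats::setNames(rep("tentative", m), candidates)
  active <- candidates
  for (iter in seq_len(max_iter)) {
    if (!length(active)) break
    keep <- candidates[decision[candidates] != "rejected"]
    Xr <- mat[, keep, drop = FALSE]
    shadow <- apply(Xr, 2, sample)
    colnames(shadow) <- paste0(".shadow_", colnames(Xr))
    rf <- randomForest::randomForest(x = cbind(Xr, shadow), y = g,
                                     ntree = n_trees, importance = TRUE)
    imp <- randomForest::importance(rf, type = 1)[, 1]
    shadow_max <- max(imp[startsWith(names(imp), ".shadow_")])
    hit_now <- imp[active] > shadow_max
    hits[active] <- hits[active] + as.integer(hit_now)
    tested[active] <- tested[active] + 1L
    thr <- alpha / m
    for (v in active) {
      p_conf <- stats::pbinom(hits[v] - 1, tested[v], 0.5, lower.tail = FALSE)
      p_rej <- stats::pbinom(hits[v], tested[v], 0.5)
      if (p_conf < thr) decision[v] <- "confirmed"
      else if (p_rej < thr) decision[v] <- "rejected"
    }
    active <- names(decision)[decision == "tentative"]
  }
  data.frame(variable_id = candidates, hits = hits[candidates],
             iterations = tested[candidates],
             decision = decision[candidates], row.names = NULL)
}

# ---- joint (collaborative) screen ---------------------------------------

.fit_pls_classifier <- function(X, g) {
  cs <- .center_scale(X, "unit_variance")
  y <- as.numeric(g == levels(g)[2])
  yc <- y - mean(y)
  w <- crossprod(cs$x, yc)[, 1]
  nw <- sqrt(sum(w^2)); if (nw == 0) nw <- 1
  w <- w / nw
  t_scores <- cs$x %*% w
  fit <- stats::coef(stats::lm(y ~ t_scores))
  list(center = cs$center, scale = cs$scale, w = w, coef = fit,
       levels = levels(g))
}

.predict_pls_classifier <- function(model, X) {
  Xs <- sweep(sweep(X, 2, model$center), 2, model$scale, "/")
  t_scores <- Xs %*% model$w
  yhat <- model$coef[1] + model$coef[2] * t_scores
  factor(model$levels[1 + (yhat >= 0.5)], levels = model$levels)
}

#' Collaborative marker screen across PLS-DA, random forest and SVM
#'
#' Bootstrap-based joint screening in the spirit of tiered molecular
#' signature discovery: for each of `bootstraps` stratified bootstrap
#' resamples and each of the three classifiers (one-component PLS-DA,
#' random forest, linear SVM), the out-of-bag accuracy is compared with the
#' accuracy after permuting one variable at a time; a variable scores a
#' success when the permutation lowers accuracy. Per classifier, a one-sided
#' binomial test (null probability 0.5, level `alpha`) across bootstraps
#' assigns tier `"A"` (significant) or `"rejected"`. The final set is every
#' variable reaching tier A in at least one classifier.
#'
#' @param x a [PeakSet-class], exactly 2 groups, at least 10 samples, no
#'   missing values.
#' @param bootstraps number of bootstrap resamples (default 50, must be > 0).
#' @param alpha binomial significance level (default 0.05).
#' @param n_trees forest size per bootstrap (default 100).
#' @param seed integer seed.
#' @return list with `result` (data.frame: variable_id, per-classifier
#'   success counts and tiers, `selected`) and `final` (character vector of
#'   selected variable ids).
#' @export
jointScreen <- function(x, bootstraps = 50, alpha = 0.05, n_trees = 100,
                        seed = 1L) {
  if (bootstraps <= 0) stop("bootstraps must be positive")
  mat <- .latent_matrix(x)
  g <- .group_factor(x)
  if (nlevels(g) != 2) stop("jointScreen supports exactly 2 groups")
  if (nrow(mat) < 10) stop("need at least 10 samples for stable resampling")
  set.seed(seed)
  p <- ncol(mat)
  classifiers <- c("plsda", "rf", "svm")
  succ <- matrix(0L, p, length(classifiers),
                 dimnames = list(colnames(mat), classifiers))
  used <- stats::setNames(integer(length(classifiers)), classifiers)
  for (b in seq_len(bootstraps)) {
    idx <- unlist(lapply(levels(g), function(l) {
      i <- which(g == l); sample(i, length(i), replace = TRUE)
    }))
    oob <- setdiff(seq_len(nrow(mat)), unique(idx))
    if (length(oob) < 2 || length(unique(g[idx])) < 2) next
    Xtr <- mat[idx, , drop = FALSE]; gtr <- droplevels(g[idx])
    Xte <- mat[oob, , drop = FALSE]; gte <- g[oob]
    models <- list(
      plsda = .fit_pls_classifier(Xtr, gtr),
      rf = randomForest::randomForest(x = Xtr, y = gtr, ntree = n_trees),
      svm = e1071::svm(x = Xtr, y = gtr, kernel = "linear", scale = TRUE,
                       cost = 1))
    predict_fun <- list(
      plsda = function(m, X) .predict_pls_classifier(m, X),
      rf = function(m, X) stats::predict(m, X),
      svm = function(m, X) stats::predict(m, X))
    for (cl in classifiers) {
      acc0 <- mean(predict_fun[[cl]](models[[cl]], Xte) == gte)
      used[cl] <- used[cl] + 1L
      perm <- sample(nrow(Xte))
      for (j in seq_len(p)) {
        Xp <- Xte; Xp[, j] <- Xp[perm, j]
        accj <- mean(predict_fun[[cl]](models[[cl]], Xp) == gte)
        if (accj < acc0) succ[j, cl] <- succ[j, cl] + 1L
      }
    }
  }
  tiers <- matrix("rejected", p, length(classifiers),
                  dimnames = dimnames(succ))
  for (cl in classifiers) {
    if (used[cl] == 0) next
    pv <- stats::pbinom(succ[, cl] - 1, used[cl], 0.5, lower.tail = FALSE)
    tiers[pv < alpha, cl] <- "A"
  }
  selected <- rowSums(tiers == "A") > 0
  res <- data.frame(variable_id = colnames(mat),
                    succ_plsda = succ[, "plsda"], succ_rf = succ[, "rf"],
                    succ_svm = succ[, "svm"],
                    tier_plsda = tiers[, "plsda"], tier_rf = tiers[, "rf"],
                    tier_svm = tiers[, "svm"],
                    selected = selected, row.names = NULL)
  list(result = res, final = colnames(mat)[selected])
}
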