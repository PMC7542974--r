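#' @include AllClasses.R AllGenerics.R
NULL

#' Multiple-testing correction
#'
#' Bonferroni, Holm step-down, or Benjamini-Hochberg FDR (the package
#' default, the common choice in metabolomics where several metabolites are
#' expected to pass). Output order matches input order.
#'
#' @param p numeric vector of p-values in [0, 1].
#' @param method `"fdr"` (default), `"bonferroni"`, or `"holm"`.
#' @return adjusted p-values.
#' @export
adjustPvalues <- function(p, method = c("fdr", "bonferroni", "holm")) {
  method <- match.arg(method)
  if (any(p < 0 | p > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = switch(method, fdr = "BH", method))
}

#' Univariate differential testing
#'
#' Per variable: group means, fold change (second group over first, on the
#' raw scale: when the table carries a log-transform provenance flag the
#' means are exponentiated back before the ratio), test statistic, raw p,
#' and p adjusted across all tested variables.
#'
#' Tests: `welch_t` (the default unpaired two-group test), `t_test` (pooled
#' variance), `mann_whitney`, `paired_t`, `wilcoxon_signed` (two groups);
#' `anova`, `kruskal_wallis` (two or more groups). Variables with fewer than
#' 2 observations in any group are skipped with a warning.
#'
#' @param x a [PeakSet-class] whose sample metadata has a `group` column.
#' @param test test name (see above).
#' @param correction multiplicity correction for [adjustPvalues()].
#' @param groups_use optional character vector choosing/ordering the group
#'   levels (first = reference for fold change).
#' @return data.frame: variable_id, per-group means, fold_change, statistic,
#'   p, p_adjusted.
#' @export
runUnivariate <- function(x, test = c("welch_t", "t_test", "mann_whitney",
                          "anova", "kruskal_wallis", "paired_t",
                          "wilcoxon_signed"),
                          correction = c("fdr", "bonferroni", "holm"),
                          groups_use = NULL) {
  test <- match.arg(test); correction <- match.arg(correction)
  g <- groups(x)
  if (is.null(g)) stop("sample metadata has no 'group' column")
  if (!is.null(groups_use)) {
    unknown <- setdiff(groups_use, g)
    if (length(unknown)) stop("unknown group label(s): ",
                              paste(unknown, collapse = ", "))
    keep <- g %in% groups_use
    x <- x[, keep]; g <- g[keep]
    levs <- groups_use
  } else levs <- unique(g)
  two_group_tests <- c("welch_t", "t_test", "mann_whitney", "paired_t",
                       "wilcoxon_signed")
  if (test %in% two_group_tests && length(levs) != 2)
    stop(test, " requires exactly 2 groups (found ", length(levs), ")")
  if (length(levs) < 2) stop("need at least 2 groups")
  mat <- intensities(x)
  logged <- isTRUE(provenance(x)$log_transformed)
  idx <- lapply(levs, function(l) which(g == l))
  rows <- vector("list", ncol(mat)); skipped <- character()
  for (j in seq_len(ncol(mat))) {
    vals <- lapply(idx, function(i) { v <- mat[i, j]; v[!is.na(v)] })
    if (any(vapply(vals, length, integer(1)) < 2)) {
      skipped <- c(skipped, colnames(mat)[j]); next
    }
    means <- vapply(vals, mean, numeric(1))
    raw_means <- if (logged) exp(means) else means
    fc <- raw_means[2] / raw_means[1]
    res <- tryCatch(switch(test,
      welch_t = stats::t.test(vals[[2]], vals[[1]], var.equal = FALSE),
      t_test = stats::t.test(vals[[2]], vals[[1]], var.equal = TRUE),
      mann_whitney = stats::wilcox.test(vals[[2]], vals[[1]], exact = FALSE,
                                        correct = TRUE),
      paired_t = stats::t.test(vals[[2]], vals[[1]], paired = TRUE),
      wilcoxon_signed = stats::wilcox.test(vals[[2]], vals[[1]], paired = TRUE,
                                           exact = FALSE, correct = TRUE),
      anova = {
        y <- unlist(vals); f <- factor(rep(levs, lengths(vals)))
        a <- stats::anova(stats::lm(y ~ f))
        list(statistic = a$`F value`[1], p.value = a$`Pr(>F)`[1])
      },
      kruskal_wallis = {
        y <- unlist(vals); f <- factor(rep(levs, lengths(vals)))
        stats::kruskal.test(y, f)
      }), error = function(e) NULL)
    if (is.null(res)) { skipped <- c(skipped, colnames(mat)[j]); next }
    row <- data.frame(variable_id = colnames(mat)[j], stringsAsFactors = FALSE)
    for (k in seq_along(levs)) row[[paste0("mean_", levs[k])]] <- means[k]
    row$fold_change <- unname(fc)
    row$statistic <- unname(res$statistic[[1]])
    row$p <- res$p.value
    rows[[j]] <- row
  }
  if (length(skipped))
    warning("variables skipped (too few observations per group): ",
            paste(skipped, collapse = ", "))
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) stop("no variable could be tested")
  out <- do.call(rbind, rows)
  out$p_adjusted <- adjustPvalues(out$p, correction)
  rownames(out) <- NULL
  out
}

#' Select differential variables by combined p-value and VIP rule
#'
#' The conventional metabolomics screen: a variable is differential when its
#' univariate p-value falls strictly below `p_threshold` and its (O)PLS-DA
#' VIP rises strictly above `vip_threshold`.
#'
#' @param uni univariate result (data.frame with `variable_id` and `p`).
#' @param vip named numeric vector of VIP scores (as in
#'   `LatentModel@vip`), or a data.frame with `variable_id` and `vip`.
#' @param p_threshold default 0.05 (strict `<`).
#' @param vip_threshold default 1.0 (strict `>`).
#' @param use_adjusted gate on `p_adjusted` instead of raw `p`.
#' @return character vector of selected variable ids.
#' @export
selectDifferential <- function(uni, vip, p_threshold = 0.05,
                               vip_threshold = 1.0, use_adjusted = FALSE) {
  if (is.data.frame(vip)) {
    if (!all(c("variable_id", "vip") %in% names(vip)))
      stop("vip data.frame needs columns variable_id and vip")
    v <- stats::setNames(vip$vip, vip$variable_id)
  } else {
    if (is.null(names(vip))) stop("vip vector must be named by variable id")
    v <- vip
  }
  pcol <- if (use_adjusted) "p_adjusted" else "p"
  missing_vip <- setdiff(uni$variable_id, names(v))
  if (length(missing_vip))
    stop("VIP missing for variable(s): ",
         paste(utils::head(missing_vip, 5), collapse = ", "))
  sel <- uni$variable_id[uni[[pcol]] < p_threshold &
                           v[uni$variable_id] > vip_threshold]
  sel[!is.na(sel)]
}
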