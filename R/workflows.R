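#' @include AllClasses.R AllGenerics.R tables-io.R preprocess.R ratios.R
#'   stats-univariate.R stats-latent.R screen.R
NULL

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("workflow stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

.write_config <- function(config, path) {
  lines <- vapply(names(config), function(k)
    paste0(k, " = ", paste(format(config[[k]]), collapse = ",")),
    character(1))
  writeLines(lines, path)
}

#' Output files of the statistics workflow
#' @return character vector of file names [workflowStatistics()] writes.
#' @export
statisticsWorkflowManifest <- function() c(
  "config.txt", "preprocessed_table.txt", "preprocess_report.txt",
  "univariate.txt", "pca_scores.txt", "pca_loadings.txt",
  "oplsda_scores.txt", "oplsda_loadings.txt", "oplsda_vip.txt",
  "rf_importance.txt", "svm_importance.txt", "boruta.txt",
  "joint_screen.txt", "selected_markers.txt")

#' End-to-end statistical analysis workflow
#'
#' Runs the standard two-group pipeline with the package defaults:
#' outlier replacement, imputation, normalization, optional ratio expansion
#' against a reaction-pair database, log transform, univariate testing
#' (Welch t, FDR), PCA, OPLS-DA with VIP, RF and linear-SVM ranking, Boruta
#' confirmation of the top candidates, and the joint screen. Every stage
#' writes a tab-delimited result file into `output_dir` (see
#' [statisticsWorkflowManifest()]); `config.txt` records every parameter
#' and the seed, so a rerun from the same config is bit-reproducible.
#' Any stage error aborts with the stage name.
#'
#' @param x a [PeakSet-class] with `group` metadata (2 groups).
#' @param output_dir results directory (created if absent).
#' @param reaction_db optional [ReactionPairDB-class] for ratio expansion.
#' @param annotation_map optional named map variable -> compound id (needed
#'   for ratio expansion).
#' @param impute_method,normalize_method,transform_method preprocessing
#'   choices (defaults: minimum, total_intensity, log).
#' @param test,correction univariate test and correction.
#' @param orthogonal orthogonal components of the OPLS-DA (default 1).
#' @param n_permutations OPLS-DA permutations (default 100).
#' @param rf_trees random-forest size (default 500).
#' @param boruta_top candidates fed to Boruta: union of the top-`boruta_top`
#'   RF and SVM variables (default 10 each).
#' @param bootstraps joint-screen bootstraps (default 50).
#' @param p_threshold,vip_threshold differential selection rule (default
#'   p < 0.05 and VIP > 1).
#' @param seed integer seed driving every stochastic stage.
#' @return list: `selected` (differential variable ids), `boruta`
#'   (confirmation table), `joint` (joint-screen result), `vip`, `univariate`,
#'   `output_dir`.
#' @export
workflowStatistics <- function(x, output_dir, reaction_db = NULL,
                               annotation_map = NULL,
                               impute_method = "minimum",
                               normalize_method = "total_intensity",
                               transform_method = "log",
                               test = "welch_t", correction = "fdr",
                               orthogonal = 1, n_permutations = 100,
                               rf_trees = 500, boruta_top = 10,
                               bootstraps = 50, p_threshold = 0.05,
                               vip_threshold = 1.0, seed = 1L) {
  if (is.null(groups(x)))
    stop("sample metadata with a 'group' column is required", call. = FALSE)
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  config <- list(impute_method = impute_method,
                 normalize_method = normalize_method,
                 transform_method = transform_method, test = test,
                 correction = correction, orthogonal = orthogonal,
                 n_permutations = n_permutations, rf_trees = rf_trees,
                 boruta_top = boruta_top, bootstraps = bootstraps,
                 p_threshold = p_threshold, vip_threshold = vip_threshold,
                 seed = seed)
  .write_config(config, file.path(output_dir, "config.txt"))

  out <- .stage("outlier replacement", replaceOutliers(x))
  writeResultTable(out$report, file.path(output_dir, "preprocess_report.txt"))
  tab <- .stage("imputation",
                imputeMissing(out$table, impute_method, seed = seed))
  tab <- .stage("normalization",
                normalizeIntensities(tab, normalize_method))$table
  if (!is.null(reaction_db)) {
    if (is.null(annotation_map))
      stop("workflow stage 'ratio expansion' failed: annotation_map required",
           call. = FALSE)
    tab <- .stage("ratio expansion",
                  expandRatios(tab, reaction_db, annotation_map))$table
  }
  tab <- .stage("transformation", transformIntensities(tab, transform_method))
  # drop QC samples from the statistics
  if (any(isQC(tab))) tab <- tab[, !isQC(tab)]
  writePeakTable(tab, file.path(output_dir, "preprocessed_table.txt"))

  uni <- .stage("univariate testing", runUnivariate(tab, test, correction))
  writeResultTable(uni, file.path(output_dir, "univariate.txt"))

  pca <- .stage("PCA", fitPCA(tab, n_components = 2))
  exportLatentModel(pca, file.path(output_dir, "pca"))
  opls <- .stage("OPLS-DA",
                 fitPLSDA(tab, orthogonal = orthogonal,
                          n_permutations = n_permutations, seed = seed))
  exportLatentModel(opls, file.path(output_dir, "oplsda"))

  rf <- .stage("random forest", rfImportance(tab, n_trees = rf_trees,
                                             seed = seed))
  writeResultTable(rf$result, file.path(output_dir, "rf_importance.txt"))
  sv <- .stage("SVM", svmRank(tab, kernel = "linear", seed = seed))
  writeResultTable(sv$result, file.path(output_dir, "svm_importance.txt"))

  candidates <- union(utils::head(rf$result$variable_id, boruta_top),
                      utils::head(sv$result$variable_id, boruta_top))
  bor <- .stage("Boruta", borutaConfirm(tab, candidates, seed = seed))
  writeResultTable(bor, file.path(output_dir, "boruta.txt"))
  joint <- .stage("joint screen",
                  jointScreen(retrieveRows(tab, candidates, "variables"),
                              bootstraps = bootstraps, seed = seed))
  writeResultTable(joint$result, file.path(output_dir, "joint_screen.txt"))

  selected <- .stage("differential selection",
                     selectDifferential(uni, vipScores(opls),
                                        p_threshold, vip_threshold))
  sel_df <- if (length(selected))
    data.frame(variable_id = selected) else
    data.frame(variable_id = "(none)")
  writeResultTable(sel_df, file.path(output_dir, "selected_markers.txt"))

  list(selected = selected, boruta = bor, joint = joint,
       vip = vipScores(opls), univariate = uni, oplsda = opls,
       output_dir = output_dir)
}

#' Pathway and enrichment workflow
#'
#' From compound hits to pathway results: loads the species library from a
#' directory of `<species>.txt` files (format of [readPathwayLibrary()]),
#' runs [pathwayAnalysis()] under the configured centrality algorithm, and
#' writes the bubble table sorted by enrichment p.
#'
#' @param hits character vector of significant compound ids (non-empty).
#' @param library_dir directory of per-species pathway files, or a
#'   [PathwayLibrary-class] directly.
#' @param species species tag (ignored when a library object is given).
#' @param output_dir results directory.
#' @param algorithm centrality algorithm (default `"eigenvector"`).
#' @return the [pathwayAnalysis()] table, invisibly written to
#'   `pathway_results.txt`.
#' @export
workflowPathway <- function(hits, library_dir, species = NULL, output_dir,
                            algorithm = "eigenvector") {
  if (!length(hits)) stop("hit set is empty", call. = FALSE)
  lib <- if (is(library_dir, "PathwayLibrary")) library_dir else {
    files <- list.files(library_dir, pattern = "\\.txt$")
    available <- sub("\\.txt$", "", files)
    if (is.null(species) || !species %in% available)
      stop("unknown species '", species, "'; available: ",
           paste(available, collapse = ", "), call. = FALSE)
    readPathwayLibrary(file.path(library_dir, paste0(species, ".txt")),
                       species)
  }
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  res <- .stage("pathway analysis", pathwayAnalysis(hits, lib, algorithm))
  writeResultTable(res, file.path(output_dir, "pathway_results.txt"))
  .write_config(list(algorithm = algorithm, species = lib@species,
                     n_hits = length(hits)),
                file.path(output_dir, "config.txt"))
  res
}
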