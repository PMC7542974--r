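#' @import methods
#' @importFrom S4Vectors DataFrame SimpleList metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays
#'   assays<- rowData colData rowData<- colData<-
NULL

#' PeakSet: a metabolomics peak table with sample and variable annotation
#'
#' `PeakSet` is the central container of the package. It extends
#' \linkS4class{SummarizedExperiment}: variables (peaks, metabolites, ratio
#' variables) are rows, samples are columns, and the single assay
#' `"intensity"` holds non-negative (or missing) ion intensities. Per-sample
#' annotation (group label, injection order, QC flag, confounders) lives in
#' `colData`; per-variable annotation (m/z, retention time, annotation string,
#' ratio-variable flag) lives in `rowData`.
#'
#' The peak-table file convention in metabolomics is samples in rows and
#' variables in columns; the `intensities()` accessor therefore returns the
#' matrix in that orientation while the object itself follows the Bioconductor
#' features-by-samples layout.
#'
#' @slot provenance list recording processing steps already applied
#'   (e.g. whether a log transform was taken, used to report fold changes on
#'   the raw scale).
#'
#' @seealso [PeakSet()] for construction, [intensities()], [sampleIds()],
#'   [variableIds()], [groups()].
#' @export
setClass("PeakSet",
  contains = "SummarizedExperiment",
  representation(provenance = "list"),
  prototype(provenance = list())
)

setValidity("PeakSet", function(object) {
  msg <- character()
  if (!"intensity" %in% names(assays(object)))
    msg <- c(msg, "assay 'intensity' is required")
  if (anyDuplicated(rownames(object)))
    msg <- c(msg, paste0("duplicate variable ids: ",
      paste(unique(rownames(object)[duplicated(rownames(object))]), collapse = ", ")))
  if (anyDuplicated(colnames(object)))
    msg <- c(msg, paste0("duplicate sample ids: ",
      paste(unique(colnames(object)[duplicated(colnames(object))]), collapse = ", ")))
  if ("intensity" %in% names(assays(object))) {
    x <- assay(object, "intensity")
    if (!is.numeric(x))
      msg <- c(msg, "intensities must be numeric")
    else if (!isTRUE(metadata(object)$transformed) && any(x < 0, na.rm = TRUE))
      msg <- c(msg, "intensities must be non-negative (or missing)")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a PeakSet
#'
#' @param intensities numeric matrix, samples in rows and variables in columns
#'   (the peak-table file convention). Row and column names are required and
#'   become the sample and variable identifiers.
#' @param sampleData optional `data.frame`/`DataFrame` of per-sample metadata,
#'   one row per sample. Recognised columns: `group` (factor/character),
#'   `injection_order` (positive integer), `is_qc` (logical); any other
#'   numeric columns are available as confounders. Row names (or a
#'   `sample_id` column) must cover the samples of `intensities`.
#' @param variableData optional per-variable metadata with columns such as
#'   `mz` (Dalton), `rt` (seconds), `annotation`, `spectrum`.
#' @param provenance list of processing flags carried through the pipeline.
#'
#' @return A [PeakSet-class] object.
#' @examples
#' m <- matrix(abs(rnorm(12)) + 1, 3, 4,
#'   dimnames = list(paste0("S", 1:3), paste0("V", 1:4)))
#' ps <- PeakSet(m, sampleData = data.frame(group = c("A", "A", "B"),
#'   row.names = rownames(m)))
#' ps
#' @export
PeakSet <- function(intensities, sampleData = NULL, variableData = NULL,
                    provenance = list()) {
  intensities <- as.matrix(intensities)
  if (is.null(rownames(intensities)))
    rownames(intensities) <- paste0("sample_", seq_len(nrow(intensities)))
  if (is.null(colnames(intensities)))
    colnames(intensities) <- paste0("variable_", seq_len(ncol(intensities)))
  storage.mode(intensities) <- "double"

  cd <- .as_sample_dataframe(sampleData, rownames(intensities))
  rd <- .as_variable_dataframe(variableData, colnames(intensities))

  se <- SummarizedExperiment(
    assays = SimpleList(intensity = t(intensities)),
    rowData = rd, colData = cd
  )
  if (isTRUE(provenance$log_transformed) || isTRUE(provenance$zscore_transformed))
    metadata(se)$transformed <- TRUE
  new("PeakSet", se, provenance = provenance)
}

.as_sample_dataframe <- function(sampleData, sample_ids) {
  if (is.null(sampleData))
    return(DataFrame(row.names = sample_ids))
  sampleData <- as.data.frame(sampleData)
  if ("sample_id" %in% names(sampleData)) {
    rownames(sampleData) <- as.character(sampleData$sample_id)
    sampleData$sample_id <- NULL
  }
  missing <- setdiff(sample_ids, rownames(sampleData))
  if (length(missing))
    stop("sample metadata is missing samples: ", paste(missing, collapse = ", "))
  DataFrame(sampleData[sample_ids, , drop = FALSE])
}

.as_variable_dataframe <- function(variableData, variable_ids) {
  if (is.null(variableData))
    return(DataFrame(row.names = variable_ids))
  variableData <- as.data.frame(variableData)
  if ("variable_id" %in% names(variableData)) {
    rownames(variableData) <- as.character(variableData$variable_id)
    variableData$variable_id <- NULL
  }
  missing <- setdiff(variable_ids, rownames(variableData))
  if (length(missing))
    stop("variable metadata is missing variables: ", paste(missing, collapse = ", "))
  DataFrame(variableData[variable_ids, , drop = FALSE])
}

setMethod("show", "PeakSet", function(object) {
  cat("PeakSet with", ncol(object), "samples and", nrow(object), "variables\n")
  x <- assay(object, "intensity")
  cat("  missing values:", sum(is.na(x)), "\n")
  if ("group" %in% names(colData(object))) {
    tab <- table(colData(object)$group)
    cat("  groups:", paste(sprintf("%s (%d)", names(tab), tab), collapse = ", "), "\n")
  }
  if (length(object@provenance))
    cat("  provenance:", paste(names(object@provenance), collapse = " -> "), "\n")
  invisible(object)
})

#' CompoundLibrary: reference compounds for annotation
#'
#' Holds library entries used by [matchByMass()] and [matchBySpectrum()]:
#' compound identifier, name, monoisotopic mass (Da), optional retention time
#' and optional centroided spectrum (list of two-column matrices `mz`,
#' `relative_intensity` on a 0-999 scale).
#'
#' @export
setClass("CompoundLibrary", representation(entries = "data.frame"))

setValidity("CompoundLibrary", function(object) {
  e <- object@entries
  req <- c("compound_id", "name", "monoisotopic_mass")
  msg <- character()
  if (!all(req %in% names(e)))
    msg <- c(msg, paste("missing columns:", paste(setdiff(req, names(e)), collapse = ", ")))
  else {
    if (anyDuplicated(e$compound_id))
      msg <- c(msg, "compound_id values must be unique")
    if (any(e$monoisotopic_mass <= 0, na.rm = TRUE))
      msg <- c(msg, "monoisotopic masses must be positive")
  }
  if (length(msg)) msg else TRUE
})

#' @param entries data.frame with columns `compound_id`, `name`,
#'   `monoisotopic_mass` and optionally `rt`, `spectrum` (list column).
#' @rdname CompoundLibrary-class
#' @export
CompoundLibrary <- function(entries) {
  entries <- as.data.frame(entries)
  if (!"rt" %in% names(entries)) entries$rt <- NA_real_
  if (!"spectrum" %in% names(entries)) entries$spectrum <- vector("list", nrow(entries))
  new("CompoundLibrary", entries = entries)
}

setMethod("show", "CompoundLibrary", function(object) {
  e <- object@entries
  cat("CompoundLibrary with", nrow(e), "compounds;",
      sum(!is.na(e$rt)), "with RT,",
      sum(!vapply(e$spectrum, is.null, logical(1))), "with spectra\n")
  invisible(object)
})

#' ReactionPairDB: substrate/product reaction pairs
#'
#' A validated table of substrate -> product compound pairs with reaction and
#' enzyme identifiers, used by [expandRatios()] to append product/substrate
#' ratio variables to a peak table.
#'
#' @export
setClass("ReactionPairDB", representation(pairs = "data.frame"))

setValidity("ReactionPairDB", function(object) {
  p <- object@pairs
  req <- c("substrate", "product", "reaction")
  msg <- character()
  if (!all(req %in% names(p)))
    msg <- c(msg, paste("missing columns:", paste(setdiff(req, names(p)), collapse = ", ")))
  else {
    bad <- which(p$substrate == p$product)
    if (length(bad))
      msg <- c(msg, paste0("substrate equals product in row(s): ",
        paste(bad, collapse = ", ")))
    if (anyDuplicated(p[req]))
      msg <- c(msg, "(substrate, product, reaction) triples must be unique")
  }
  if (length(msg)) msg else TRUE
})

#' @param pairs data.frame with columns `substrate`, `product`, `reaction`,
#'   optionally `enzyme` and `reversible`.
#' @rdname ReactionPairDB-class
#' @export
ReactionPairDB <- function(pairs) {
  pairs <- as.data.frame(pairs)
  if (!"enzyme" %in% names(pairs)) pairs$enzyme <- NA_character_
  if (!"reversible" %in% names(pairs)) pairs$reversible <- FALSE
  pairs$reversible <- as.logical(pairs$reversible)
  new("ReactionPairDB", pairs = pairs)
}

setMethod("show", "ReactionPairDB", function(object) {
  cat("ReactionPairDB with", nrow(object@pairs), "reaction pairs (",
      sum(object@pairs$reversible), "reversible )\n")
  invisible(object)
})

#' PathwayGraph: one metabolic pathway as a directed compound graph
#'
#' Nodes are compound identifiers; edges are substrate -> product reactions.
#' Reversible reactions are stored once with `reversible = TRUE` and expanded
#' to both directions before any directed centrality is computed.
#'
#' @export
setClass("PathwayGraph", representation(
  pathway_id = "character", name = "character", species = "character",
  nodes = "character", edges = "data.frame"
))

setValidity("PathwayGraph", function(object) {
  msg <- character()
  e <- object@edges
  if (nrow(e) && !all(c("from", "to", "reversible") %in% names(e)))
    msg <- c(msg, "edges need columns from, to, reversible")
  else if (nrow(e)) {
    unknown <- setdiff(unique(c(e$from, e$to)), object@nodes)
    if (length(unknown))
      msg <- c(msg, paste0("edges reference undeclared nodes: ",
        paste(unknown, collapse = ", ")))
  }
  if (anyDuplicated(object@nodes))
    msg <- c(msg, "node ids must be unique")
  if (length(msg)) msg else TRUE
})

#' @param pathway_id,name,species identifiers of the pathway.
#' @param nodes character vector of compound ids.
#' @param edges data.frame with columns `from`, `to`, `reversible`.
#' @rdname PathwayGraph-class
#' @export
PathwayGraph <- function(pathway_id, nodes, edges = NULL, name = pathway_id,
                         species = "unknown") {
  if (is.null(edges) || !nrow(edges))
    edges <- data.frame(from = character(), to = character(),
                        reversible = logical())
  edges <- as.data.frame(edges)
  if (!"reversible" %in% names(edges)) edges$reversible <- FALSE
  new("PathwayGraph", pathway_id = pathway_id, name = name, species = species,
      nodes = as.character(nodes), edges = edges)
}

setMethod("show", "PathwayGraph", function(object) {
  cat(sprintf("PathwayGraph '%s' (%s): %d compounds, %d reactions (%d reversible)\n",
    object@pathway_id, object@name, length(object@nodes), nrow(object@edges),
    sum(object@edges$reversible)))
  invisible(object)
})

#' PathwayLibrary: all pathways of one species
#'
#' @export
setClass("PathwayLibrary", representation(
  species = "character", pathways = "list"
))

setValidity("PathwayLibrary", function(object) {
  ids <- vapply(object@pathways, function(p) p@pathway_id, character(1))
  msg <- character()
  if (anyDuplicated(ids)) msg <- c(msg, "pathway ids must be unique")
  ok <- vapply(object@pathways, is, logical(1), "PathwayGraph")
  if (!all(ok)) msg <- c(msg, "all elements must be PathwayGraph objects")
  if (length(msg)) msg else TRUE
})

#' @param species species tag.
#' @param pathways list of [PathwayGraph-class] objects.
#' @rdname PathwayLibrary-class
#' @export
PathwayLibrary <- function(species, pathways) {
  pl <- new("PathwayLibrary", species = species, pathways = pathways)
  names(pl@pathways) <- vapply(pathways, function(p) p@pathway_id, character(1))
  pl
}

#' All compound ids appearing in a pathway library
#' @param library a [PathwayLibrary-class].
#' @return character vector (the enrichment universe).
#' @export
pathwayUniverse <- function(library) {
  sort(unique(unlist(lapply(library@pathways, function(p) p@nodes))))
}

setMethod("show", "PathwayLibrary", function(object) {
  cat(sprintf("PathwayLibrary for species '%s': %d pathways, %d compounds\n",
    object@species, length(object@pathways), length(pathwayUniverse(object))))
  invisible(object)
})

#' LatentModel: fitted PCA / PLS-DA / OPLS-DA decomposition
#'
#' Scores are samples x components, loadings and weights variables x
#' components. For discriminant models the per-variable VIP (variable
#' importance in projection, normalised so that mean(VIP^2) = 1 for a single
#' response) and, when requested, the label-permutation p-value and
#' cross-validated Q2 are filled in.
#'
#' @export
setClass("LatentModel", representation(
  method = "character", scores = "matrix", loadings = "matrix",
  weights = "matrix", explained_variance = "numeric", vip = "numeric",
  n_orthogonal = "numeric", orthogonal_scores = "matrix",
  r2y = "numeric", q2 = "numeric", permutation_p = "numeric",
  permutation_q2 = "numeric", details = "list"
))

setMethod("show", "LatentModel", function(object) {
  cat(sprintf("LatentModel (%s): %d samples, %d components",
    object@method, nrow(object@scores), ncol(object@scores)))
  if (length(object@n_orthogonal) && object@n_orthogonal > 0)
    cat(sprintf(" + %d orthogonal", object@n_orthogonal))
  cat("\n")
  if (length(object@explained_variance))
    cat("  explained variance:",
        paste(sprintf("%.1f%%", 100 * object@explained_variance), collapse = ", "), "\n")
  if (length(object@q2) && !is.na(object@q2[1]))
    cat(sprintf("  Q2 = %.3f", object@q2[1]),
        if (length(object@permutation_p) && !is.na(object@permutation_p[1]))
          sprintf(" (permutation p = %.4g)", object@permutation_p[1]) else "", "\n")
  invisible(object)
})
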