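#' @include AllClasses.R
NULL

#' Accessors for PeakSet
#'
#' `intensities()` returns the intensity matrix in the peak-table convention
#' (samples in rows, variables in columns). `sampleIds()`, `variableIds()`,
#' `groups()`, `injectionOrder()` and `isQC()` expose the identifier and
#' metadata columns; `variableMeta()` returns the per-variable annotation as a
#' data.frame.
#'
#' @param x a [PeakSet-class].
#' @name PeakSet-accessors
NULL

#' @rdname PeakSet-accessors
#' @export
setGeneric("intensities", function(x) standardGeneric("intensities"))

#' @rdname PeakSet-accessors
#' @export
setMethod("intensities", "PeakSet", function(x) t(assay(x, "intensity")))

#' @rdname PeakSet-accessors
#' @export
setGeneric("intensities<-", function(x, value) standardGeneric("intensities<-"))

#' @rdname PeakSet-accessors
#' @param value samples x variables numeric matrix.
#' @export
setMethod("intensities<-", "PeakSet", function(x, value) {
  assays(x)[["intensity"]] <- t(value)
  validObject(x)
  x
})

#' @rdname PeakSet-accessors
#' @export
sampleIds <- function(x) colnames(x)

#' @rdname PeakSet-accessors
#' @export
variableIds <- function(x) rownames(x)

#' @rdname PeakSet-accessors
#' @export
groups <- function(x) {
  cd <- colData(x)
  if (!"group" %in% names(cd)) return(NULL)
  g <- as.character(cd$group)
  names(g) <- rownames(cd)
  g
}

#' @rdname PeakSet-accessors
#' @export
injectionOrder <- function(x) {
  cd <- colData(x)
  if (!"injection_order" %in% names(cd)) return(NULL)
  o <- as.integer(cd$injection_order)
  names(o) <- rownames(cd)
  o
}

#' @rdname PeakSet-accessors
#' @export
isQC <- function(x) {
  cd <- colData(x)
  if (!"is_qc" %in% names(cd)) return(rep(FALSE, ncol(x)))
  q <- as.logical(cd$is_qc)
  q[is.na(q)] <- FALSE
  names(q) <- rownames(cd)
  q
}

#' @rdname PeakSet-accessors
#' @export
variableMeta <- function(x) as.data.frame(rowData(x))

#' @rdname PeakSet-accessors
#' @export
sampleMeta <- function(x) as.data.frame(colData(x))

#' Provenance flags of a PeakSet
#'
#' Processing steps already applied (e.g. `log_transformed`), used downstream
#' to decide on which scale fold changes are reported.
#' @param x a [PeakSet-class].
#' @export
provenance <- function(x) x@provenance
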