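#' @include AllClasses.R AllGenerics.R
NULL

.MISSING_TOKENS <- c("", "na", "nan")

.parse_numeric_cells <- function(df, path) {
  # df: character data.frame, rownames set. Empty / NA / NaN (any case) -> NA.
  m <- as.matrix(df)
  flat <- trimws(as.character(m))
  is_missing <- tolower(flat) %in% .MISSING_TOKENS | is.na(flat)
  num <- suppressWarnings(as.numeric(flat))
  bad <- which(!is_missing & is.na(num))
  if (length(bad)) {
    i <- ((bad[1] - 1) %% nrow(m)) + 1
    j <- ((bad[1] - 1) %/% nrow(m)) + 1
    stop(sprintf("non-numeric cell '%s' at row '%s', column '%s' in %s",
                 flat[bad[1]], rownames(df)[i], colnames(df)[j], path))
  }
  num[is_missing] <- NA_real_
  matrix(num, nrow(m), ncol(m), dimnames = dimnames(m))
}

.check_unique <- function(ids, what, path) {
  if (anyDuplicated(ids)) {
    dups <- unique(ids[duplicated(ids)])
    stop(sprintf("duplicate %s identifiers in %s: %s", what, path,
                 paste(dups, collapse = ", ")))
  }
}

#' Read a tab-delimited peak table
#'
#' Reads a tab-delimited text file with a header row and identifiers in the
#' first column. Empty cells and the tokens `NA`/`NaN` (case-insensitive)
#' become missing values. Whatever the file orientation, the returned
#' [PeakSet-class] is in the canonical layout (query it with [intensities()],
#' samples x variables).
#'
#' @param path file path.
#' @param orientation `"samples_in_rows"` (default, the common peak-table
#'   convention) or `"variables_in_rows"`.
#' @param sampleData optional per-sample metadata (see [PeakSet()]).
#' @param variableData optional per-variable metadata.
#' @return A [PeakSet-class].
#' @export
readPeakTable <- function(path,
                          orientation = c("samples_in_rows", "variables_in_rows"),
                          sampleData = NULL, variableData = NULL) {
  orientation <- match.arg(orientation)
  df <- utils::read.delim(path, header = TRUE, sep = "\t", row.names = NULL,
                          colClasses = "character", check.names = FALSE,
                          na.strings = NULL, quote = "")
  if (ncol(df) < 2) stop("peak table needs an id column plus at least one data column: ", path)
  ids <- as.character(df[[1]])
  .check_unique(ids, "row", path)
  .check_unique(colnames(df)[-1], "column", path)
  rownames(df) <- ids
  mat <- .parse_numeric_cells(df[, -1, drop = FALSE], path)
  if (orientation == "variables_in_rows") mat <- t(mat)
  PeakSet(mat, sampleData = sampleData, variableData = variableData)
}

#' Write a peak table to tab-delimited text
#'
#' @param x a [PeakSet-class].
#' @param path output file.
#' @param orientation file orientation (see [readPeakTable()]).
#' @param id_column header of the identifier column.
#' @return `path`, invisibly.
#' @export
writePeakTable <- function(x, path, orientation = c("samples_in_rows",
                           "variables_in_rows"), id_column = "sample_id") {
  orientation <- match.arg(orientation)
  mat <- intensities(x)
  if (orientation == "variables_in_rows") {
    mat <- t(mat)
    if (identical(id_column, "sample_id")) id_column <- "variable_id"
  }
  .write_matrix_txt(mat, path, id_column)
  invisible(path)
}

.format_number <- function(v) {
  vapply(v, function(x) {
    if (is.na(x)) return("")
    trimws(formatC(x, digits = 15, format = "g"))
  }, character(1))
}

.write_matrix_txt <- function(mat, path, id_column) {
  txt <- apply(mat, 2, .format_number)
  if (is.null(dim(txt))) txt <- matrix(txt, nrow = nrow(mat))
  out <- cbind(rownames(mat), txt)
  colnames(out) <- c(id_column, colnames(mat))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = TRUE)
}

#' Write a result table to tab-delimited text
#'
#' Result tables (per-variable, per-pair or per-pathway statistics) are plain
#' data.frames with an identifier column. Numeric columns are serialised with
#' 15 significant digits and plain decimal notation for magnitudes down to
#' 1e-4, so a read-back reproduces the values.
#'
#' @param result data.frame, non-empty.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeResultTable <- function(result, path) {
  if (!is.data.frame(result) || nrow(result) == 0)
    stop("result table is empty; nothing to write")
  out <- result
  for (j in seq_along(out)) {
    if (is.numeric(out[[j]])) out[[j]] <- .format_number(out[[j]])
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = TRUE)
  invisible(path)
}

#' Read a result table written by [writeResultTable()]
#' @param path file path.
#' @return data.frame with numeric columns restored.
#' @export
readResultTable <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character", check.names = FALSE,
                          na.strings = NULL, quote = "")
  for (j in seq_along(df)) {
    v <- trimws(df[[j]])
    miss <- tolower(v) %in% .MISSING_TOKENS
    num <- suppressWarnings(as.numeric(v))
    if (all(miss | !is.na(num))) {
      num[miss] <- NA_real_
      df[[j]] <- num
    }
  }
  df
}

#' Read a sample metadata table
#'
#' Tab-delimited with a `sample_id` first column and columns such as `group`,
#' `injection_order`, `is_qc` plus numeric confounders.
#' @param path file path.
#' @return data.frame keyed by sample id.
#' @export
readSampleMetadata <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                          quote = "")
  names(df)[1] <- "sample_id"
  .check_unique(df$sample_id, "sample", path)
  rownames(df) <- df$sample_id
  if ("is_qc" %in% names(df)) {
    v <- df$is_qc
    df$is_qc <- if (is.logical(v)) v else
      tolower(trimws(as.character(v))) %in% c("1", "true", "yes", "qc")
  }
  df
}

#' Concatenate two peak tables along samples or variables
#'
#' The shared axis is aligned by identifier (order taken from `a`); ids on the
#' grown axis that collide are deterministically suffixed `_2`, `_3`, ... on
#' the second table.
#'
#' @param a,b [PeakSet-class] objects.
#' @param axis `"variables"` to add the variables of `b` (tables must share
#'   samples), `"samples"` to add its samples (must share variables).
#' @return merged [PeakSet-class].
#' @export
mergeTables <- function(a, b, axis = c("variables", "samples")) {
  axis <- match.arg(axis)
  ma <- intensities(a); mb <- intensities(b)
  if (axis == "variables") {
    if (ncol(mb) == 0) return(a)
    shared <- intersect(rownames(ma), rownames(mb))
    if (length(shared) == 0) stop("tables share no samples; cannot merge variables")
    if (!setequal(rownames(ma), rownames(mb)))
      stop("sample sets differ: ",
           paste(c(setdiff(rownames(ma), rownames(mb)),
                   setdiff(rownames(mb), rownames(ma))), collapse = ", "))
    mb <- mb[rownames(ma), , drop = FALSE]
    colnames(mb) <- .dedup_ids(colnames(ma), colnames(mb))
    merged <- cbind(ma, mb)
    vm <- .rbind_meta(variableMeta(a), variableMeta(b), colnames(merged))
    PeakSet(merged, sampleData = sampleMeta(a), variableData = vm,
            provenance = provenance(a))
  } else {
    if (nrow(mb) == 0) return(a)
    if (!setequal(colnames(ma), colnames(mb)))
      stop("variable sets differ: ",
           paste(c(setdiff(colnames(ma), colnames(mb)),
                   setdiff(colnames(mb), colnames(ma))), collapse = ", "))
    mb <- mb[, colnames(ma), drop = FALSE]
    rownames(mb) <- .dedup_ids(rownames(ma), rownames(mb))
    merged <- rbind(ma, mb)
    sm <- .rbind_meta(sampleMeta(a), sampleMeta(b), rownames(merged))
    PeakSet(merged, sampleData = sm, variableData = variableMeta(a),
            provenance = provenance(a))
  }
}

.dedup_ids <- function(existing, incoming) {
  out <- incoming
  for (i in seq_along(out)) {
    id <- out[i]; k <- 2
    taken <- c(existing, out[-i])
    while (out[i] %in% taken) {
      out[i] <- paste0(id, "_", k)
      k <- k + 1
    }
  }
  out
}

.rbind_meta <- function(a, b, ids) {
  cols <- union(names(a), names(b))
  fill <- function(df, n) {
    for (cc in setdiff(cols, names(df))) df[[cc]] <- rep(NA, nrow(df))
    df[, cols, drop = FALSE]
  }
  if (!length(cols)) return(data.frame(row.names = ids))
  out <- rbind(fill(a), fill(b))
  rownames(out) <- ids
  out
}

#' Retrieve target samples or variables by identifier
#'
#' Subsets a peak table preserving the order of `ids`; unknown identifiers
#' raise a warning listing them and are dropped from the result.
#'
#' @param x a [PeakSet-class].
#' @param ids identifiers to keep, in the desired output order.
#' @param axis `"samples"` or `"variables"`.
#' @return subset [PeakSet-class].
#' @export
retrieveRows <- function(x, ids, axis = c("samples", "variables")) {
  axis <- match.arg(axis)
  have <- if (axis == "samples") sampleIds(x) else variableIds(x)
  unknown <- setdiff(ids, have)
  if (length(unknown))
    warning("unknown ", axis, " ids dropped: ", paste(unknown, collapse = ", "))
  keep <- ids[ids %in% have]
  if (axis == "samples") x[, keep] else x[keep, ]
}
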