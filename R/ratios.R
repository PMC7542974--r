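#' @include AllClasses.R AllGenerics.R
NULL

#' Load a reaction-pair database from tab-delimited text
#'
#' Required columns: `substrate`, `product`, `reaction`; optional `enzyme`
#' and `reversible` (logical or 0/1). Duplicate (substrate, product,
#' reaction) triples are collapsed with a warning; a row whose substrate
#' equals its product is an error.
#'
#' @param path file path.
#' @return a [ReactionPairDB-class].
#' @export
readReactionPairs <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                          quote = "")
  req <- c("substrate", "product", "reaction")
  missing <- setdiff(req, names(df))
  if (length(missing))
    stop("reaction-pair file lacks required column(s): ",
         paste(missing, collapse = ", "))
  same <- which(df$substrate == df$product)
  if (length(same))
    stop("substrate equals product in row(s): ", paste(same, collapse = ", "))
  dup <- duplicated(df[req])
  if (any(dup)) {
    warning(sum(dup), " duplicate reaction pair(s) collapsed")
    df <- df[!dup, , drop = FALSE]
  }
  if ("reversible" %in% names(df)) {
    v <- df$reversible
    df$reversible <- if (is.logical(v)) v else
      tolower(trimws(as.character(v))) %in% c("1", "true", "yes")
  }
  ReactionPairDB(df)
}

#' Expand a peak table with product/substrate ratio variables
#'
#' For every reaction pair whose substrate and product both map to measured
#' variables (via `annotation_map`), a new variable named
#' `"product_id/substrate_id"` is appended whose value per sample is the
#' product intensity divided by the substrate intensity. A zero or missing
#' substrate intensity yields a missing ratio in that sample. Original
#' variables are untouched; ratio variables are flagged `is_ratio` in the
#' variable metadata. A reversible pair contributes one ratio as listed
#' unless `both_directions = TRUE`.
#'
#' When several variables map to the same compound, the variable with the
#' highest median intensity represents it (recorded in the provenance table).
#'
#' @param x a [PeakSet-class] (typically imputed and normalized).
#' @param db a [ReactionPairDB-class].
#' @param annotation_map named character vector: names are variable ids,
#'   values are compound ids.
#' @param both_directions also append substrate/product ratios for
#'   reversible pairs (default FALSE).
#' @return list with `table` (the expanded [PeakSet-class]) and `provenance`
#'   (data.frame: ratio_id, reaction, enzyme, product/substrate variable ids).
#' @export
expandRatios <- function(x, db, annotation_map, both_directions = FALSE) {
  if (!length(annotation_map)) stop("annotation_map is empty")
  mat <- intensities(x)
  annotation_map <- annotation_map[names(annotation_map) %in% colnames(mat)]
  # one representative variable per compound: highest median intensity
  rep_var <- vapply(split(names(annotation_map), unname(annotation_map)),
    function(vars) {
      if (length(vars) == 1) return(vars)
      meds <- apply(mat[, vars, drop = FALSE], 2, stats::median, na.rm = TRUE)
      vars[which.max(meds)]
    }, character(1))

  pairs <- db@pairs
  if (both_directions && any(pairs$reversible)) {
    rev <- pairs[pairs$reversible, , drop = FALSE]
    tmp <- rev$substrate; rev$substrate <- rev$product; rev$product <- tmp
    pairs <- rbind(pairs, rev)
  }
  keep <- pairs$substrate %in% names(rep_var) & pairs$product %in% names(rep_var)
  pairs <- pairs[keep, , drop = FALSE]

  prov <- list(); newcols <- list(); newids <- character()
  for (i in seq_len(nrow(pairs))) {
    pv <- rep_var[[pairs$product[i]]]; sv <- rep_var[[pairs$substrate[i]]]
    rid <- paste0(pairs$product[i], "/", pairs$substrate[i])
    if (rid %in% c(colnames(mat), newids)) next  # one ratio per compound pair
    s <- mat[, sv]; p <- mat[, pv]
    ratio <- ifelse(is.na(s) | s == 0 | is.na(p), NA_real_, p / s)
    newcols[[rid]] <- ratio; newids <- c(newids, rid)
    prov[[length(prov) + 1L]] <- data.frame(
      ratio_id = rid, reaction = pairs$reaction[i],
      enzyme = if ("enzyme" %in% names(pairs)) pairs$enzyme[i] else NA_character_,
      product_variable = pv, substrate_variable = sv,
      stringsAsFactors = FALSE)
  }
  prov <- if (length(prov)) do.call(rbind, prov) else
    data.frame(ratio_id = character(), reaction = character(),
               enzyme = character(), product_variable = character(),
               substrate_variable = character())
  if (!length(newcols))
    return(list(table = x, provenance = prov))

  newmat <- do.call(cbind, newcols)
  colnames(newmat) <- newids
  vm <- variableMeta(x)
  if (!"is_ratio" %in% names(vm))
    vm$is_ratio <- rep(FALSE, nrow(vm))
  vm_new <- vm[rep(NA_integer_, length(newids)), , drop = FALSE]
  rownames(vm_new) <- newids
  vm_new$is_ratio <- TRUE
  merged <- cbind(mat, newmat)
  out <- PeakSet(merged, sampleData = sampleMeta(x),
                 variableData = rbind(vm, vm_new),
                 provenance = provenance(x))
  out@provenance$ratios_expanded <- list(n = length(newids),
                                         both_directions = both_directions)
  list(table = out, provenance = prov)
}
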