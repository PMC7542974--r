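#' @include AllClasses.R AllGenerics.R
NULL

#' Read a compound library from tab-delimited text
#'
#' Columns: `compound_id`, `name`, `monoisotopic_mass` (Da), optional `rt`
#' (seconds) and optional `spectrum` encoded as `"mz:int,mz:int,..."`
#' (relative intensities 0-999).
#'
#' @param path file path.
#' @return a [CompoundLibrary-class].
#' @export
readCompoundLibrary <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                          quote = "")
  if ("spectrum" %in% names(df)) {
    df$spectrum <- lapply(as.character(df$spectrum), .parse_spectrum)
  }
  CompoundLibrary(df)
}

.parse_spectrum <- function(s) {
  if (is.na(s) || !nzchar(trimws(s))) return(NULL)
  parts <- strsplit(trimws(s), ",", fixed = TRUE)[[1]]
  mzint <- do.call(rbind, lapply(parts, function(p) {
    kv <- as.numeric(strsplit(p, ":", fixed = TRUE)[[1]])
    if (length(kv) != 2 || any(is.na(kv))) stop("malformed spectrum token: ", p)
    kv
  }))
  colnames(mzint) <- c("mz", "relative_intensity")
  mzint
}

.encode_spectrum <- function(sp) {
  if (is.null(sp)) return("")
  paste(sprintf("%g:%g", sp[, 1], sp[, 2]), collapse = ",")
}

#' ppm mass error, (observed - reference) / reference * 1e6
#' @param observed,reference masses in Dalton.
#' @return signed error in parts per million.
#' @export
ppmError <- function(observed, reference) (observed - reference) / reference * 1e6

#' Annotate peaks by exact mass
#'
#' For every variable carrying an `mz` value, library compounds are matched
#' within a ppm (or Dalton) window, optionally after applying adduct mass
#' shifts, and optionally gated by retention time. Candidates are ranked by
#' absolute ppm error (ties by absolute RT error, then compound id); rank 1
#' is the best hit. Mass tolerance comparisons are inclusive (<=); the RT
#' gate is strict (<).
#'
#' @param x a [PeakSet-class] whose `variableMeta()` has an `mz` column (and
#'   optionally `rt`, in seconds).
#' @param lib a [CompoundLibrary-class].
#' @param tol_ppm ppm tolerance (default 10).
#' @param tol_da optional Dalton tolerance; when given it replaces the ppm
#'   criterion.
#' @param rt_tol_s optional retention-time gate in seconds, applied when both
#'   the variable and the library entry have an RT.
#' @param top_n candidates reported per variable (default 5).
#' @param adducts named numeric vector of mass shifts added to the neutral
#'   library mass before comparison (e.g. `c("[M+H]+" = 1.007276)`); default
#'   none (neutral-mass matching).
#' @return data.frame of hits: variable_id, compound_id, name, adduct,
#'   mz_error_ppm, mz_error_da, rt_error_s, rank. Unmatched variables appear
#'   once with `compound_id = NA`.
#' @export
matchByMass <- function(x, lib, tol_ppm = 10, tol_da = NULL, rt_tol_s = NULL,
                        top_n = 5, adducts = c(none = 0)) {
  vm <- variableMeta(x)
  if (!"mz" %in% names(vm)) stop("variable metadata has no 'mz' column; cannot match by mass")
  e <- lib@entries
  if (!nrow(e)) stop("compound library is empty")
  has_rt <- "rt" %in% names(vm)
  out <- list()
  for (i in seq_len(nrow(vm))) {
    vid <- rownames(vm)[i]
    mz <- vm$mz[i]
    if (is.na(mz)) next
    cand <- list()
    for (a in seq_along(adducts)) {
      ref <- e$monoisotopic_mass + adducts[a]
      d_da <- mz - ref
      d_ppm <- d_da / ref * 1e6
      pass <- if (!is.null(tol_da)) abs(d_da) <= tol_da else abs(d_ppm) <= tol_ppm
      rt_err <- rep(NA_real_, nrow(e))
      if (!is.null(rt_tol_s) && has_rt && !is.na(vm$rt[i])) {
        rt_err <- vm$rt[i] - e$rt
        pass <- pass & (is.na(rt_err) | abs(rt_err) < rt_tol_s)
      }
      k <- which(pass)
      if (length(k))
        cand[[length(cand) + 1L]] <- data.frame(
          variable_id = vid, compound_id = e$compound_id[k], name = e$name[k],
          adduct = names(adducts)[a], mz_error_ppm = d_ppm[k],
          mz_error_da = d_da[k], rt_error_s = rt_err[k],
          stringsAsFactors = FALSE)
    }
    if (!length(cand)) {
      out[[length(out) + 1L]] <- data.frame(
        variable_id = vid, compound_id = NA_character_, name = NA_character_,
        adduct = NA_character_, mz_error_ppm = NA_real_, mz_error_da = NA_real_,
        rt_error_s = NA_real_, rank = NA_integer_, stringsAsFactors = FALSE)
      next
    }
    cand <- do.call(rbind, cand)
    ord <- order(abs(cand$mz_error_ppm),
                 ifelse(is.na(cand$rt_error_s), Inf, abs(cand$rt_error_s)),
                 cand$compound_id)
    cand <- cand[ord, , drop = FALSE]
    cand <- cand[seq_len(min(top_n, nrow(cand))), , drop = FALSE]
    cand$rank <- seq_len(nrow(cand))
    out[[length(out) + 1L]] <- cand
  }
  if (!length(out))
    return(data.frame(variable_id = character(), compound_id = character(),
                      name = character(), adduct = character(),
                      mz_error_ppm = numeric(), mz_error_da = numeric(),
                      rt_error_s = numeric(), rank = integer()))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Spectral similarity of two centroided spectra
#'
#' Cosine similarity of square-root-intensity-weighted vectors after binning
#' both spectra to unit-Dalton bins (`round(mz / bin_width)`), the GC-MS
#' unit-mass convention.
#'
#' @param a,b two-column matrices (`mz`, `relative_intensity`).
#' @param bin_width bin width in Dalton (default 1).
#' @return similarity in [0, 1].
#' @export
spectralSimilarity <- function(a, b, bin_width = 1.0) {
  bin <- function(sp) {
    key <- round(sp[, 1] / bin_width)
    tapply(sqrt(pmax(sp[, 2], 0)), key, sum)
  }
  va <- bin(a); vb <- bin(b)
  keys <- union(names(va), names(vb))
  xa <- ifelse(keys %in% names(va), va[keys], 0)
  xb <- ifelse(keys %in% names(vb), vb[keys], 0)
  na <- sqrt(sum(xa^2)); nb <- sqrt(sum(xb^2))
  if (na == 0 || nb == 0) return(0)
  sum(xa * xb) / (na * nb)
}

#' Annotate peaks by spectral similarity
#'
#' GC-MS style matching: each variable's centroided spectrum is compared to
#' every library spectrum by [spectralSimilarity()]; candidates require
#' similarity strictly greater than `min_similarity` and, when both sides
#' carry an RT, an RT difference strictly below `rt_tol` (minutes).
#' Candidates are ranked by similarity, descending (ties by compound id).
#'
#' @param x a [PeakSet-class] whose `variableMeta()` has a `spectrum` list
#'   column (and optionally `rt`, minutes).
#' @param lib a [CompoundLibrary-class] with spectra (RT in minutes).
#' @param min_similarity minimum cosine similarity, exclusive (default 0.7).
#' @param rt_tol retention-time tolerance in minutes, exclusive (default 0.3).
#' @param bin_width spectral bin width in Dalton (default 1).
#' @param top_n candidates per variable (default 5).
#' @return data.frame of hits as in [matchByMass()], with a
#'   `spectral_similarity` column.
#' @export
matchBySpectrum <- function(x, lib, min_similarity = 0.7, rt_tol = 0.3,
                            bin_width = 1.0, top_n = 5) {
  vm <- variableMeta(x)
  if (!"spectrum" %in% names(vm))
    stop("variable metadata has no 'spectrum' column; cannot match by spectrum")
  e <- lib@entries
  has_lib_spec <- !vapply(e$spectrum, is.null, logical(1))
  if (!any(has_lib_spec)) stop("compound library has no spectra")
  has_rt <- "rt" %in% names(vm)
  out <- list()
  for (i in seq_len(nrow(vm))) {
    vid <- rownames(vm)[i]
    sp <- vm$spectrum[[i]]
    if (is.null(sp)) next
    sims <- rep(NA_real_, nrow(e)); rt_err <- rep(NA_real_, nrow(e))
    for (k in which(has_lib_spec)) {
      sims[k] <- spectralSimilarity(sp, e$spectrum[[k]], bin_width)
      if (has_rt && !is.na(vm$rt[i]) && !is.na(e$rt[k]))
        rt_err[k] <- vm$rt[i] - e$rt[k]
    }
    pass <- !is.na(sims) & sims > min_similarity &
      (is.na(rt_err) | abs(rt_err) < rt_tol)
    k <- which(pass)
    if (!length(k)) {
      out[[length(out) + 1L]] <- data.frame(
        variable_id = vid, compound_id = NA_character_, name = NA_character_,
        spectral_similarity = NA_real_, rt_error_min = NA_real_,
        rank = NA_integer_, stringsAsFactors = FALSE)
      next
    }
    k <- k[order(-sims[k], e$compound_id[k])]
    k <- k[seq_len(min(top_n, length(k)))]
    out[[length(out) + 1L]] <- data.frame(
      variable_id = vid, compound_id = e$compound_id[k], name = e$name[k],
      spectral_similarity = sims[k], rt_error_min = rt_err[k],
      rank = seq_along(k), stringsAsFactors = FALSE)
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(variable_id = character(), compound_id = character(),
               name = character(), spectral_similarity = numeric(),
               rt_error_min = numeric(), rank = integer())
  rownames(res) <- NULL
  res
}

#' Best-hit table from an annotation result
#'
#' @param hits output of [matchByMass()] or [matchBySpectrum()].
#' @return the rank-1 rows (one per annotated variable).
#' @export
bestHits <- function(hits) hits[!is.na(hits$rank) & hits$rank == 1, , drop = FALSE]
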