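#' @include AllClasses.R AllGenerics.R
NULL

#' Simulation design for synthetic peak tables
#'
#' Bundles and validates the knobs of [simulatePeakTable()]: group sizes,
#' number of variables and planted markers, effect size (in units of the
#' per-variable biological SD on the log scale), missingness rate and
#' whether it is left-censored, multiplicative injection-order drift, QC
#' spacing, confounder strength and seed.
#'
#' @param n_per_group biological samples per group (two groups).
#' @param n_variables total variables.
#' @param n_informative planted group-shifted variables (first
#'   `n_informative` ids).
#' @param effect_size group shift in SD units (log scale).
#' @param missing_rate fraction of intensities set missing.
#' @param censor_left concentrate missingness in low intensities (the
#'   assumption behind QRILC).
#' @param drift_slope per-injection multiplicative drift fraction.
#' @param qc_every insert a pooled-QC sample every this many injections
#'   (0 = none).
#' @param confounder_strength SD of the shared confounder effect used by
#'   [simulateCoupledMicrobiome()].
#' @param seed integer seed.
#' @return validated list of class `sim_design`.
#' @export
simDesign <- function(n_per_group = 30, n_variables = 200, n_informative = 10,
                      effect_size = 1.5, missing_rate = 0, censor_left = TRUE,
                      drift_slope = 0, qc_every = 0, confounder_strength = 1,
                      seed = 1L) {
  stopifnot(n_per_group >= 2, n_variables >= 1,
            n_informative >= 0, n_informative <= n_variables,
            missing_rate >= 0, missing_rate < 1, qc_every >= 0)
  structure(list(n_per_group = n_per_group, n_variables = n_variables,
                 n_informative = n_informative, effect_size = effect_size,
                 missing_rate = missing_rate, censor_left = censor_left,
                 drift_slope = drift_slope, qc_every = qc_every,
                 confounder_strength = confounder_strength,
                 seed = as.integer(seed)),
            class = "sim_design")
}

#' Simulate a two-group metabolomics peak table
#'
#' Log-normal baseline intensities (per-variable mean log intensity uniform
#' on log(1e4)..log(1e6), biological SD uniform on 0.2..0.6 log units) with:
#' planted group shifts of `effect_size` SD units (alternating sign) on the
#' first `n_informative` variables; multiplicative injection-order drift;
#' pooled QC samples every `qc_every` injections; and missingness that is
#' either left-censored (the lowest intensities of each variable go missing)
#' or completely at random. A per-sample standard-normal confounder is
#' stored in the metadata.
#'
#' @param design a [simDesign()] object.
#' @return list: `table` (a [PeakSet-class] with group, injection_order,
#'   is_qc, confounder metadata), `truth` (data.frame: variable_id,
#'   informative, effect).
#' @export
simulatePeakTable <- function(design) {
  stopifnot(inherits(design, "sim_design"))
  set.seed(design$seed)
  n_bio <- 2L * design$n_per_group
  p <- design$n_variables
  vid <- sprintf("V%03d", seq_len(p))
  g_bio <- rep(c("G1", "G2"), each = design$n_per_group)
  # interleave groups over the injection sequence (avoids confounding group
  # with drift), then insert QCs
  ord_bio <- sample(n_bio)
  mu <- stats::runif(p, log(1e4), log(1e6))
  sigma <- stats::runif(p, 0.2, 0.6)
  effect <- numeric(p)
  if (design$n_informative > 0) {
    k <- seq_len(design$n_informative)
    effect[k] <- design$effect_size * sigma[k] * rep_len(c(1, -1),
                                                         design$n_informative)
  }
  logx <- matrix(stats::rnorm(n_bio * p), n_bio, p)
  logx <- sweep(logx, 2, sigma, "*")
  logx <- sweep(logx, 2, mu, "+")
  shift <- outer(as.numeric(g_bio == "G2"), effect)
  logx <- logx + shift

  samples <- data.frame(sample_id = sprintf("S%03d", seq_len(n_bio)),
                        group = g_bio, is_qc = FALSE,
                        stringsAsFactors = FALSE)
  x <- exp(logx)
  if (design$qc_every > 0) {
    pooled_mu <- colMeans(logx)
    n_qc <- floor(n_bio / design$qc_every)
    qc_log <- matrix(stats::rnorm(n_qc * p, sd = 0.05), n_qc, p)
    qc_log <- sweep(qc_log, 2, pooled_mu, "+")
    x <- rbind(x, exp(qc_log))
    samples <- rbind(samples,
      data.frame(sample_id = sprintf("QC%02d", seq_len(n_qc)), group = "QC",
                 is_qc = TRUE, stringsAsFactors = FALSE))
  }
  n_tot <- nrow(x)
  # injection order: biological samples in shuffled order, QCs evenly spread
  ord <- integer(n_tot)
  if (design$qc_every > 0) {
    n_qc <- n_tot - n_bio
    qc_slots <- round(seq(1, n_tot, length.out = n_qc + 2))[1 + seq_len(n_qc)]
    bio_slots <- setdiff(seq_len(n_tot), qc_slots)
    ord[seq_len(n_bio)] <- bio_slots[ord_bio]
    ord[n_bio + seq_len(n_qc)] <- qc_slots
  } else {
    ord[seq_len(n_bio)] <- ord_bio
  }
  samples$injection_order <- ord
  if (design$drift_slope != 0)
    x <- x * (1 + design$drift_slope * ord)

  if (design$missing_rate > 0) {
    if (design$censor_left) {
      for (j in seq_len(p)) {
        thr <- stats::quantile(x[, j], design$missing_rate)
        x[x[, j] < thr, j] <- NA_real_
      }
    } else {
      miss <- matrix(stats::runif(n_tot * p) < design$missing_rate, n_tot, p)
      x[miss] <- NA_real_
    }
  }
  samples$confounder <- stats::rnorm(n_tot)
  rownames(x) <- samples$sample_id
  colnames(x) <- vid
  table <- PeakSet(x, sampleData = samples)
  truth <- data.frame(variable_id = vid,
                      informative = seq_len(p) <= design$n_informative,
                      effect = effect)
  list(table = table, truth = truth)
}

#' Simulate a microbiome table coupled to a metabolome
#'
#' Generates a compositional taxa abundance table over the samples of
#' `metab` with planted couplings: `n_linear` taxa track the log intensity
#' of one metabolite each (slope 1 on the z scale plus noise SD 0.5),
#' `n_nonlinear` taxa follow a centred quadratic of a metabolite's log
#' z-score (Pearson-silent, distance-correlation-visible), and
#' `n_confounded` metabolite/taxon pairs are both driven by the stored
#' per-sample confounder (strength `confounder_strength`) with no direct
#' link. The returned metabolite table carries the confounder effect added
#' to the confounded metabolite columns.
#'
#' @param metab a [PeakSet-class] with at least 20 samples and a
#'   `confounder` metadata column (as produced by [simulatePeakTable()]).
#' @param n_taxa total taxa (default 30).
#' @param n_linear,n_nonlinear,n_confounded planted pair counts.
#' @param confounder_strength effect of the confounder on both members of a
#'   confounded pair (log-scale SD units).
#' @param seed integer seed.
#' @return list: `metab` (possibly modified [PeakSet-class]), `microbe`
#'   (samples x taxa relative-abundance matrix), `truth` (data.frame:
#'   metabolite, taxon, type).
#' @export
simulateCoupledMicrobiome <- function(metab, n_taxa = 30, n_linear = 3,
                                      n_nonlinear = 3, n_confounded = 2,
                                      confounder_strength = 1, seed = 1L) {
  if (ncol(intensities(metab)) < n_linear + n_nonlinear + n_confounded)
    stop("not enough metabolite variables for the requested couplings")
  mat <- intensities(metab)
  if (nrow(mat) < 20) stop("need at least 20 samples")
  if (anyNA(mat)) stop("impute the metabolite table first")
  set.seed(seed)
  n <- nrow(mat)
  conf <- sampleMeta(metab)$confounder
  if (is.null(conf)) conf <- stats::rnorm(n)
  logm <- log(mat)
  zscore <- function(v) (v - mean(v)) / stats::sd(v)

  taxa_log <- matrix(stats::rnorm(n * n_taxa, sd = 1), n, n_taxa)
  taxa_log <- sweep(taxa_log, 2, stats::runif(n_taxa, 0, 3), "+")
  tid <- sprintf("T%03d", seq_len(n_taxa))
  colnames(taxa_log) <- tid

  needed <- n_linear + n_nonlinear + n_confounded
  met_idx <- sample(ncol(mat), needed)
  tax_idx <- sample(n_taxa, needed)
  truth <- list(); k <- 0
  for (i in seq_len(n_linear)) {
    k <- k + 1
    z <- zscore(logm[, met_idx[k]])
    taxa_log[, tax_idx[k]] <- z + stats::rnorm(n, sd = 0.5)
    truth[[k]] <- data.frame(metabolite = colnames(mat)[met_idx[k]],
                             taxon = tid[tax_idx[k]], type = "linear")
  }
  for (i in seq_len(n_nonlinear)) {
    k <- k + 1
    z <- zscore(logm[, met_idx[k]])
    q <- z^2 - mean(z^2)
    taxa_log[, tax_idx[k]] <- q / stats::sd(q) + stats::rnorm(n, sd = 0.3)
    truth[[k]] <- data.frame(metabolite = colnames(mat)[met_idx[k]],
                             taxon = tid[tax_idx[k]], type = "nonlinear")
  }
  if (n_confounded > 0) {
    for (i in seq_len(n_confounded)) {
      k <- k + 1
      j <- met_idx[k]
      logm[, j] <- logm[, j] + confounder_strength * conf
      taxa_log[, tax_idx[k]] <- confounder_strength * conf +
        stats::rnorm(n, sd = 0.5)
      truth[[k]] <- data.frame(metabolite = colnames(mat)[j],
                               taxon = tid[tax_idx[k]], type = "confounded")
    }
    mat <- exp(logm)
    rownames(mat) <- rownames(intensities(metab))
    metab <- PeakSet(mat, sampleData = sampleMeta(metab),
                     variableData = variableMeta(metab),
                     provenance = provenance(metab))
  }
  rel <- exp(taxa_log)
  rel <- rel / rowSums(rel)
  rownames(rel) <- rownames(mat)
  list(metab = metab, microbe = rel,
       truth = do.call(rbind, truth))
}

#' Simulate a species pathway library with a matching reaction-pair DB
#'
#' Random connected pathway graphs (a random spanning tree plus extra
#' edges, random edge directions, reversible flags drawn at rate 0.3) over
#' a shared compound pool, so pathways overlap as real KEGG maps do. The
#' returned reaction-pair database contains exactly the library's edges,
#' giving ratio expansion and pathway analysis one common ground truth.
#'
#' @param n_pathways number of pathways (default 10).
#' @param nodes_per_pathway integer range, default `c(5, 15)`.
#' @param seed integer seed.
#' @param species species tag.
#' @return list: `library` (a [PathwayLibrary-class]), `reaction_db`
#'   (a [ReactionPairDB-class]).
#' @export
simulatePathwayLibrary <- function(n_pathways = 10,
                                   nodes_per_pathway = c(5, 15), seed = 1L,
                                   species = "synthetic") {
  set.seed(seed)
  pool_size <- max(20, round(n_pathways * mean(nodes_per_pathway) * 0.7))
  pool <- sprintf("C%05d", seq_len(pool_size))
  pathways <- list(); all_edges <- list()
  for (i in seq_len(n_pathways)) {
    nn <- sample(seq(nodes_per_pathway[1], nodes_per_pathway[2]), 1)
    nodes <- sample(pool, nn)
    # spanning tree for connectivity
    edges <- list()
    for (v in seq(2, nn)) {
      u <- sample(v - 1, 1)
      edges[[length(edges) + 1L]] <- c(nodes[u], nodes[v])
    }
    n_extra <- stats::rbinom(1, nn, 0.2)
    for (e in seq_len(n_extra)) {
      uv <- sample(nn, 2)
      edges[[length(edges) + 1L]] <- c(nodes[uv[1]], nodes[uv[2]])
    }
    ed <- unique(do.call(rbind, edges))
    flip <- stats::runif(nrow(ed)) < 0.5
    ed_df <- data.frame(from = ifelse(flip, ed[, 2], ed[, 1]),
                        to = ifelse(flip, ed[, 1], ed[, 2]),
                        reversible = stats::runif(nrow(ed)) < 0.3,
                        stringsAsFactors = FALSE)
    ed_df <- ed_df[ed_df$from != ed_df$to, , drop = FALSE]
    pid <- sprintf("P%04d", i)
    pathways[[i]] <- PathwayGraph(pid, nodes = nodes, edges = ed_df,
                                  name = paste("Synthetic pathway", i),
                                  species = species)
    ed_df$pathway <- pid
    all_edges[[i]] <- ed_df
  }
  lib <- PathwayLibrary(species, pathways)
  ed_all <- do.call(rbind, all_edges)
  pairs <- data.frame(substrate = ed_all$from, product = ed_all$to,
                      reaction = sprintf("R%05d", seq_len(nrow(ed_all))),
                      enzyme = sprintf("EC%d.%d.%d.%d",
                                       sample(6, nrow(ed_all), TRUE),
                                       sample(9, nrow(ed_all), TRUE),
                                       sample(9, nrow(ed_all), TRUE),
                                       sample(99, nrow(ed_all), TRUE)),
                      reversible = ed_all$reversible,
                      stringsAsFactors = FALSE)
  list(library = lib, reaction_db = ReactionPairDB(pairs))
}
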