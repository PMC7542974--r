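#' @include AllClasses.R AllGenerics.R
NULL

.expand_edges <- function(graph) {
  e <- graph@edges
  if (!nrow(e)) return(e[, c("from", "to"), drop = FALSE])
  rev <- e[e$reversible, c("to", "from"), drop = FALSE]
  names(rev) <- c("from", "to")
  out <- rbind(e[, c("from", "to")], rev)
  out[!duplicated(out), , drop = FALSE]
}

.pathway_igraph <- function(graph, directed = TRUE) {
  ed <- .expand_edges(graph)
  g <- igraph::graph_from_data_frame(ed, directed = directed,
                                     vertices = data.frame(name = graph@nodes))
  # a reversible reaction is one undirected connection, not a parallel edge
  if (!directed) g <- igraph::simplify(g)
  g
}

#' Node centrality of a pathway graph
#'
#' Seven algorithms. Degree and closeness respect edge direction (reversible
#' reactions are expanded to both directions first); betweenness and
#' eigenvector are computed on the undirected expansion, the convention that
#' keeps them well-defined on reaction graphs that are not strongly
#' connected.
#'
#' \describe{
#'   \item{in_degree / out_degree / total_degree}{connection counts directed
#'     to / from a node, and their sum.}
#'   \item{relative_betweenness}{number of shortest paths through a node,
#'     normalised by `(n-1)(n-2)/2`.}
#'   \item{in_closeness / out_closeness / total_closeness}{reciprocal of the
#'     summed distances to the node's reachable companions (0 for isolated
#'     nodes).}
#'   \item{eigenvector}{principal-eigenvector importance (power iteration,
#'     tolerance 1e-10), scaled to maximum 1.}
#' }
#'
#' @param graph a [PathwayGraph-class], non-empty.
#' @param algorithm one of the names above.
#' @return named numeric vector of non-negative scores, one per node.
#' @export
nodeCentrality <- function(graph,
                           algorithm = c("eigenvector", "out_degree",
                                         "in_degree", "total_degree",
                                         "relative_betweenness",
                                         "out_closeness", "in_closeness",
                                         "total_closeness")) {
  algorithm <- match.arg(algorithm)
  if (!length(graph@nodes)) stop("pathway graph has no nodes")
  nodes <- graph@nodes
  n <- length(nodes)
  if (algorithm %in% c("out_degree", "in_degree", "total_degree")) {
    g <- .pathway_igraph(graph, directed = TRUE)
    mode <- switch(algorithm, out_degree = "out", in_degree = "in",
                   total_degree = "all")
    sc <- igraph::degree(g, mode = mode, loops = FALSE)
    return(sc[nodes])
  }
  if (algorithm == "relative_betweenness") {
    g <- .pathway_igraph(graph, directed = FALSE)
    b <- igraph::betweenness(g, directed = FALSE)
    norm <- if (n > 2) (n - 1) * (n - 2) / 2 else 1
    return((b / norm)[nodes])
  }
  if (algorithm %in% c("out_closeness", "in_closeness", "total_closeness")) {
    g <- .pathway_igraph(graph, directed = TRUE)
    mode <- switch(algorithm, out_closeness = "out", in_closeness = "in",
                   total_closeness = "all")
    d <- igraph::distances(g, mode = mode)
    sc <- apply(d, 1, function(row) {
      reach <- row[is.finite(row) & row > 0]
      if (!length(reach)) 0 else 1 / sum(reach)
    })
    return(sc[nodes])
  }
  # eigenvector: power iteration on the undirected adjacency
  ed <- .expand_edges(graph)
  A <- matrix(0, n, n, dimnames = list(nodes, nodes))
  if (nrow(ed)) {
    A[cbind(ed$from, ed$to)] <- 1
    A <- pmax(A, t(A))
  }
  diag(A) <- 0
  if (all(A == 0)) return(stats::setNames(rep(0, n), nodes))
  # power iteration on A + I: same principal eigenvector, but convergent on
  # bipartite graphs (no +/- lambda oscillation)
  v <- rep(1, n)
  for (it in seq_len(100000)) {
    v2 <- as.numeric(A %*% v) + v
    m <- max(abs(v2))
    if (m == 0) return(stats::setNames(rep(0, n), nodes))
    v2 <- v2 / m
    if (max(abs(v2 - v)) < 1e-13) { v <- v2; break }
    v <- v2
  }
  v <- abs(v) / max(abs(v))
  stats::setNames(v, nodes)
}

#' Hypergeometric metabolite-set enrichment
#'
#' Per pathway, the one-sided upper-tail hypergeometric probability of
#' observing at least the seen overlap between the hit compounds and the
#' pathway, drawing from the library universe (all compounds of the
#' species' pathways; switch to the measured set with
#' `universe = "measured"` and `measured_ids`). q is FDR across pathways.
#'
#' @param hits character vector of significant compound ids.
#' @param library a [PathwayLibrary-class].
#' @param correction method for [adjustPvalues()].
#' @param universe `"library"` (default) or `"measured"`.
#' @param measured_ids measured compound ids (required for
#'   `universe = "measured"`).
#' @return data.frame: pathway_id, name, hits, total, universe, draws,
#'   enrichment_p, enrichment_q.
#' @export
enrichPathways <- function(hits, library,
                           correction = c("fdr", "bonferroni", "holm"),
                           universe = c("library", "measured"),
                           measured_ids = NULL) {
  correction <- match.arg(correction); universe <- match.arg(universe)
  uni <- pathwayUniverse(library)
  if (universe == "measured") {
    if (is.null(measured_ids)) stop("universe = 'measured' needs measured_ids")
    uni <- intersect(uni, measured_ids)
  }
  hits_u <- unique(intersect(hits, uni))
  if (!length(hits_u))
    stop("none of the hits map into the pathway universe")
  N <- length(uni); n_draw <- length(hits_u)
  rows <- lapply(library@pathways, function(p) {
    pw_nodes <- intersect(p@nodes, uni)
    K <- length(pw_nodes)
    k <- length(intersect(hits_u, pw_nodes))
    pval <- if (k == 0) 1.0 else
      stats::phyper(k - 1, K, N - K, n_draw, lower.tail = FALSE)
    data.frame(pathway_id = p@pathway_id, name = p@name, hits = k,
               total = K, universe = N, draws = n_draw,
               enrichment_p = pval, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$enrichment_q <- adjustPvalues(out$enrichment_p, correction)
  rownames(out) <- NULL
  out
}

#' Pathway impact from topological centrality
#'
#' The sum of the centralities of the hit nodes divided by the total
#' centrality of all nodes of the pathway: 0 with no hits, 1 when the hits
#' carry all the centrality. When the graph has no edges (all centralities
#' zero) the fraction of hit nodes is returned with a warning.
#'
#' @param hits character vector of compound ids.
#' @param graph a [PathwayGraph-class].
#' @param algorithm centrality algorithm (default `"eigenvector"`, the
#'   package default for topology analysis).
#' @return impact in [0, 1].
#' @export
pathwayImpact <- function(hits, graph, algorithm = "eigenvector") {
  cent <- nodeCentrality(graph, algorithm)
  total <- sum(cent)
  hit_nodes <- intersect(hits, graph@nodes)
  if (total == 0) {
    warning("graph '", graph@pathway_id,
            "' has zero total centrality; using hit fraction")
    return(length(hit_nodes) / length(graph@nodes))
  }
  sum(cent[hit_nodes]) / total
}

#' Combined pathway enrichment and topology analysis
#'
#' Joins [enrichPathways()] (which depends only on set overlaps, never on
#' the topology algorithm) and [pathwayImpact()] per pathway, yielding the
#' bubble-plot table: pathway, -log(p), impact, hits, total. Rows are sorted
#' by enrichment p.
#'
#' @inheritParams enrichPathways
#' @param algorithm centrality algorithm for the impact scores.
#' @return data.frame with columns pathway_id, name, hits, total,
#'   enrichment_p, enrichment_q, neg_log10_p, impact, algorithm.
#' @export
pathwayAnalysis <- function(hits, library, algorithm = "eigenvector",
                            correction = "fdr", universe = "library",
                            measured_ids = NULL) {
  if (!length(hits)) stop("hit set is empty")
  enr <- enrichPathways(hits, library, correction, universe, measured_ids)
  enr$neg_log10_p <- -log10(enr$enrichment_p)
  enr$impact <- vapply(enr$pathway_id, function(pid)
    suppressWarnings(pathwayImpact(hits, library@pathways[[pid]], algorithm)),
    numeric(1))
  enr$algorithm <- algorithm
  enr[order(enr$enrichment_p, enr$pathway_id), , drop = FALSE]
}

# ---- pathway library text format ----------------------------------------

#' Read a species pathway library from text
#'
#' Line-based format, one file per species:
#' \preformatted{
#' pathway<TAB>P0001<TAB>Glycolysis
#' node<TAB>C00031
#' edge<TAB>C00031 -> C00668 [reversible]
#' edge<TAB>C00668 -> C05345
#' }
#' Each `pathway` line starts a new pathway; `node` and `edge` lines belong
#' to the most recent one. The `[reversible]` suffix marks reversible
#' reactions.
#'
#' @param path file path.
#' @param species species tag (default: file name without extension).
#' @return a [PathwayLibrary-class].
#' @export
readPathwayLibrary <- function(path, species = NULL) {
  if (is.null(species))
    species <- sub("\\.[^.]*$", "", basename(path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  pathways <- list()
  cur <- NULL
  flush <- function(cur, pathways) {
    if (is.null(cur)) return(pathways)
    edges <- if (length(cur$edges)) do.call(rbind, cur$edges) else NULL
    pw <- PathwayGraph(cur$id, nodes = cur$nodes, edges = edges,
                       name = cur$name, species = species)
    c(pathways, stats::setNames(list(pw), cur$id))
  }
  for (ln in lines) {
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    key <- parts[1]
    if (key == "pathway") {
      pathways <- flush(cur, pathways)
      cur <- list(id = parts[2],
                  name = if (length(parts) >= 3) parts[3] else parts[2],
                  nodes = character(), edges = list())
    } else if (key == "node") {
      cur$nodes <- c(cur$nodes, parts[2])
    } else if (key == "edge") {
      spec <- trimws(parts[2])
      reversible <- grepl("\\[reversible\\]", spec)
      spec <- trimws(sub("\\[reversible\\]", "", spec))
      ft <- trimws(strsplit(spec, "->", fixed = TRUE)[[1]])
      if (length(ft) != 2) stop("malformed edge line: ", ln)
      cur$edges[[length(cur$edges) + 1L]] <-
        data.frame(from = ft[1], to = ft[2], reversible = reversible,
                   stringsAsFactors = FALSE)
    } else stop("unknown line type '", key, "' in ", path)
  }
  pathways <- flush(cur, pathways)
  PathwayLibrary(species, unname(pathways))
}

#' Write a pathway library in the text format of [readPathwayLibrary()]
#' @param library a [PathwayLibrary-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writePathwayLibrary <- function(library, path) {
  con <- file(path, "w"); on.exit(close(con))
  for (p in library@pathways) {
    writeLines(paste("pathway", p@pathway_id, p@name, sep = "\t"), con)
    for (nd in p@nodes) writeLines(paste("node", nd, sep = "\t"), con)
    e <- p@edges
    for (i in seq_len(nrow(e))) {
      suffix <- if (e$reversible[i]) " [reversible]" else ""
      writeLines(paste0("edge\t", e$from[i], " -> ", e$to[i], suffix), con)
    }
  }
  invisible(path)
}
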