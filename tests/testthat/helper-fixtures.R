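# Small in-code fixtures and independent oracles used across the suite.

make_peakset <- function(mat, group = NULL, ...) {
  sd <- NULL
  if (!is.null(group))
    sd <- data.frame(group = group, row.names = rownames(mat), ...)
  PeakSet(mat, sampleData = sd)
}

two_group_peakset <- function(n_per_group = 10, p = 6, shift = 0, seed = 1,
                              informative = 1) {
  set.seed(seed)
  n <- 2 * n_per_group
  mat <- matrix(exp(rnorm(n * p, mean = 8, sd = 0.4)), n, p,
                dimnames = list(sprintf("S%02d", 1:n), sprintf("V%02d", 1:p)))
  g <- rep(c("A", "B"), each = n_per_group)
  if (shift != 0)
    mat[g == "B", seq_len(informative)] <-
      mat[g == "B", seq_len(informative)] * exp(shift)
  make_peakset(mat, group = g)
}

# ---- textbook multiple-testing oracles ----------------------------------

oracle_bonferroni <- function(p) pmin(1, length(p) * p)

oracle_holm <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  run <- 0
  for (i in seq_len(m)) {
    run <- max(run, (m - i + 1) * p[o[i]])
    adj[o[i]] <- min(1, run)
  }
  adj
}

oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  run <- Inf
  for (i in rev(seq_len(m))) {
    run <- min(run, m / i * p[o[i]])
    adj[o[i]] <- min(1, run)
  }
  adj
}

# ---- AUC by concordant-pair counting ------------------------------------

oracle_auc <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  total <- 0
  for (a in pos) for (b in neg)
    total <- total + (a > b) + 0.5 * (a == b)
  total / (length(pos) * length(neg))
}

# ---- distance correlation by explicit loops -----------------------------

oracle_dcor <- function(x, y) {
  n <- length(x)
  a <- outer(x, x, function(u, v) abs(u - v))
  b <- outer(y, y, function(u, v) abs(u - v))
  A <- matrix(0, n, n); B <- matrix(0, n, n)
  for (i in 1:n) for (j in 1:n) {
    A[i, j] <- a[i, j] - mean(a[i, ]) - mean(a[, j]) + mean(a)
    B[i, j] <- b[i, j] - mean(b[i, ]) - mean(b[, j]) + mean(b)
  }
  dcov2 <- sum(A * B) / n^2
  dvx <- sum(A * A) / n^2; dvy <- sum(B * B) / n^2
  if (dvx <= 0 || dvy <= 0) return(0)
  sqrt(max(dcov2, 0) / sqrt(dvx * dvy))
}

# ---- exact hypergeometric upper tail ------------------------------------

oracle_hyper_upper <- function(k, K, N, n) {
  # P(X >= k), X ~ Hypergeometric(N total, K successes, n draws)
  ks <- k:min(K, n)
  sum(choose(K, ks) * choose(N - K, n - ks)) / choose(N, n)
}

# ---- brute-force centralities on a PathwayGraph -------------------------

graph_adjacency <- function(graph, directed = TRUE) {
  nodes <- graph@nodes
  n <- length(nodes)
  A <- matrix(0, n, n, dimnames = list(nodes, nodes))
  e <- graph@edges
  for (i in seq_len(nrow(e))) {
    A[e$from[i], e$to[i]] <- 1
    if (e$reversible[i] || !directed) A[e$to[i], e$from[i]] <- 1
  }
  if (!directed) A <- pmax(A, t(A))
  diag(A) <- 0
  A
}

oracle_distances <- function(A) {
  # Floyd-Warshall on unit weights
  n <- nrow(A)
  D <- ifelse(A > 0, 1, Inf); diag(D) <- 0
  for (k in 1:n) for (i in 1:n) for (j in 1:n)
    if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
  D
}

oracle_degree <- function(graph, mode) {
  A <- graph_adjacency(graph, directed = TRUE)
  switch(mode, out = rowSums(A), `in` = colSums(A),
         all = rowSums(A) + colSums(A))
}

oracle_closeness <- function(graph, mode) {
  A <- graph_adjacency(graph, directed = TRUE)
  if (mode == "all") A <- pmax(A, t(A))
  D <- oracle_distances(if (mode == "in") t(A) else A)
  apply(D, 1, function(row) {
    reach <- row[is.finite(row) & row > 0]
    if (!length(reach)) 0 else 1 / sum(reach)
  })
}

oracle_betweenness_relative <- function(graph) {
  A <- graph_adjacency(graph, directed = FALSE)
  nodes <- rownames(A); n <- length(nodes)
  D <- oracle_distances(A)
  # count shortest paths per source by DP in order of distance
  sigma <- matrix(0, n, n, dimnames = dimnames(A))  # sigma[s, v]
  for (s in 1:n) {
    sigma[s, s] <- 1
    ds <- D[s, ]
    for (dist in sort(unique(ds[is.finite(ds) & ds > 0]))) {
      for (v in which(ds == dist)) {
        preds <- which(A[, v] > 0 & ds == dist - 1)
        sigma[s, v] <- sum(sigma[s, preds])
      }
    }
  }
  btw <- numeric(n)
  for (v in 1:n) {
    tot <- 0
    for (s in 1:n) for (t in 1:n) {
      if (s >= t || s == v || t == v) next
      if (!is.finite(D[s, t])) next
      if (D[s, v] + D[v, t] == D[s, t])
        tot <- tot + sigma[s, v] * sigma[v, t] / sigma[s, t]
    }
    btw[v] <- tot
  }
  norm <- if (n > 2) (n - 1) * (n - 2) / 2 else 1
  stats::setNames(btw / norm, nodes)
}

oracle_eigenvector <- function(graph) {
  A <- graph_adjacency(graph, directed = FALSE)
  if (all(A == 0)) return(stats::setNames(rep(0, nrow(A)), rownames(A)))
  ev <- eigen(A, symmetric = TRUE)
  v <- abs(ev$vectors[, 1])
  stats::setNames(v / max(v), rownames(A))
}

# battery of small graphs for oracle-equivalence checks
centrality_battery <- function() {
  graphs <- list()
  mk <- function(id, nodes, from, to, reversible = FALSE) {
    PathwayGraph(id, nodes = nodes,
                 edges = data.frame(from = from, to = to,
                                    reversible = reversible))
  }
  for (n in 2:7) {
    v <- paste0("N", 1:n)
    graphs[[paste0("chain", n)]] <-
      mk(paste0("chain", n), v, v[-n], v[-1])
  }
  for (n in 3:7) {
    v <- paste0("N", 1:n)
    graphs[[paste0("cycle", n)]] <-
      mk(paste0("cycle", n), v, v, c(v[-1], v[1]))
  }
  for (n in 3:7) {
    v <- paste0("N", 1:n)
    graphs[[paste0("star", n)]] <-
      mk(paste0("star", n), v, rep(v[1], n - 1), v[-1])
  }
  for (n in 2:5) {
    v <- paste0("N", 1:n)
    pairs <- t(combn(n, 2))
    graphs[[paste0("complete", n)]] <-
      mk(paste0("complete", n), v, v[pairs[, 1]], v[pairs[, 2]],
         reversible = TRUE)
  }
  set.seed(404)
  for (r in 1:6) {
    n <- sample(4:7, 1)
    v <- paste0("N", 1:n)
    from <- integer(0); to <- integer(0)
    for (j in 2:n) { from <- c(from, sample(j - 1, 1)); to <- c(to, j) }
    extra <- sample(0:2, 1)
    for (e in seq_len(extra)) {
      uv <- sample(n, 2)
      from <- c(from, min(uv)); to <- c(to, max(uv))
    }
    keep <- !duplicated(paste(from, to))
    graphs[[paste0("random", r)]] <-
      mk(paste0("random", r), v, v[from[keep]], v[to[keep]],
         reversible = runif(sum(keep)) < 0.4)
  }
  graphs
}
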