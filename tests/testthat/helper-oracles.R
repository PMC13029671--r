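# Independent brute-force oracles, deliberately written without touching
# the package's internals: exhaustive permutation enumeration, Floyd-
# Warshall shortest paths, shortest-path enumeration for betweenness,
# triple counting for transitivity, and direct evaluation of modularity Q.

oraclePerms <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (p in oraclePerms(n - 1L)) {
    for (pos in 0:(n - 1L)) {
      out[[length(out) + 1L]] <- append(p, n, after = pos)
    }
  }
  out
}

# Spearman rho by the classic d^2 formula (valid without ties)
oracleSpearmanRho <- function(x, y) {
  n <- length(x)
  d <- rank(x) - rank(y)
  1 - 6 * sum(d^2) / (n * (n^2 - 1))
}

oracleSpearmanExactP <- function(x, y, two_sided = TRUE) {
  n <- length(x)
  obs <- oracleSpearmanRho(x, y)
  ry <- rank(y)
  hits <- 0; tot <- 0
  for (p in oraclePerms(n)) {
    r <- oracleSpearmanRho(rank(x), ry[p])
    tot <- tot + 1
    stat <- if (two_sided) abs(r) else r
    ref <- if (two_sided) abs(obs) else obs
    if (stat >= ref - 1e-12) hits <- hits + 1
  }
  hits / tot
}

# --- graph oracles -------------------------------------------------------
# Graphs are given as a vertex count plus an edge data.frame with integer
# endpoints v1 < v2 and a distance weight per edge.

oracleAdjacency <- function(nv, edges) {
  A <- matrix(FALSE, nv, nv)
  for (i in seq_len(nrow(edges))) {
    A[edges$v1[i], edges$v2[i]] <- TRUE
    A[edges$v2[i], edges$v1[i]] <- TRUE
  }
  A
}

oracleFloydWarshall <- function(nv, edges, weights = NULL) {
  D <- matrix(Inf, nv, nv)
  diag(D) <- 0
  w <- if (is.null(weights)) rep(1, nrow(edges)) else weights
  for (i in seq_len(nrow(edges))) {
    D[edges$v1[i], edges$v2[i]] <- min(D[edges$v1[i], edges$v2[i]], w[i])
    D[edges$v2[i], edges$v1[i]] <- D[edges$v1[i], edges$v2[i]]
  }
  for (k in seq_len(nv)) for (i in seq_len(nv)) for (j in seq_len(nv))
    if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
  D
}

oracleDensity <- function(nv, edges) 2 * nrow(edges) / (nv * (nv - 1))

oracleTransitivity <- function(nv, edges) {
  A <- oracleAdjacency(nv, edges)
  closed <- 0; triples <- 0
  for (i in seq_len(nv)) for (j in seq_len(nv)) for (k in seq_len(nv)) {
    if (i == j || j == k || i == k) next
    if (A[i, j] && A[j, k]) {
      triples <- triples + 1
      if (A[i, k]) closed <- closed + 1
    }
  }
  if (triples == 0) NaN else closed / triples
}

# all shortest s -> t paths under unit weights, by recursive descent
# along the BFS distance field
oracleShortestPathList <- function(A, D, s, t) {
  if (s == t) return(list(s))
  out <- list()
  for (nb in which(A[s, ])) {
    if (is.finite(D[s, t]) && D[nb, t] == D[s, t] - 1) {
      for (sub in oracleShortestPathList(A, D, nb, t))
        out[[length(out) + 1L]] <- c(s, sub)
    }
  }
  out
}

oracleBetweenness <- function(nv, edges) {
  A <- oracleAdjacency(nv, edges)
  D <- oracleFloydWarshall(nv, edges)
  b <- numeric(nv)
  for (s in seq_len(nv - 1)) for (t in (s + 1):nv) {
    if (!is.finite(D[s, t])) next
    paths <- oracleShortestPathList(A, D, s, t)
    for (p in paths) {
      inner <- setdiff(p, c(s, t))
      b[inner] <- b[inner] + 1 / length(paths)
    }
  }
  b
}

oracleCentralization <- function(nv, edges) {
  b <- oracleBetweenness(nv, edges)
  sum(max(b) - b) / ((nv - 1)^2 * (nv - 2) / 2)
}

oracleModularityQ <- function(nv, edges, membership) {
  m <- nrow(edges)
  deg <- numeric(nv)
  for (i in seq_len(m)) {
    deg[edges$v1[i]] <- deg[edges$v1[i]] + 1
    deg[edges$v2[i]] <- deg[edges$v2[i]] + 1
  }
  q <- 0
  for (c in unique(membership)) {
    inside <- sum(membership[edges$v1] == c & membership[edges$v2] == c)
    dc <- sum(deg[membership == c])
    q <- q + inside / m - (dc / (2 * m))^2
  }
  q
}

# random CorrelationNetwork over nv nodes with edge probability p;
# attributes drawn to satisfy the class thresholds
randomNetwork <- function(nv, p_edge, seed) {
  set.seed(seed)
  ids <- sprintf("n%02d", seq_len(nv))
  pairs <- t(combn(nv, 2))
  keep <- runif(nrow(pairs)) < p_edge
  pairs <- pairs[keep, , drop = FALSE]
  rho <- runif(nrow(pairs), 0.905, 0.999) * sample(c(-1, 1), nrow(pairs),
                                                   replace = TRUE)
  edges <- data.frame(source = ids[pairs[, 1]], target = ids[pairs[, 2]],
                      rho = rho, sign = ifelse(rho > 0, 1, -1),
                      p = rep(1e-4, nrow(pairs)), stringsAsFactors = FALSE)
  nodes <- data.frame(otu_id = ids,
                      kingdom = sample(c("bacteria", "fungi"), nv, TRUE),
                      phylum = "unclassified", stringsAsFactors = FALSE)
  list(net = correlationNetwork(nodes, edges,
                                params = list(rho_threshold = 0.9,
                                              p_threshold = 0.01,
                                              weight_scheme =
                                                "one_minus_abs_rho")),
       nv = nv,
       edges_int = data.frame(v1 = pairs[, 1], v2 = pairs[, 2]),
       dist_w = 1 - abs(rho))
}

# exhaustive Mantel p over all relabelings
oracleMantelExact <- function(d1, d2, method = "spearman") {
  n <- nrow(d1)
  lt <- lower.tri(d1)
  v1 <- d1[lt]
  obs <- cor(v1, d2[lt], method = method)
  hits <- 0; tot <- 0
  for (p in oraclePerms(n)) {
    d2p <- d2[p, p]
    r <- cor(v1, d2p[lt], method = method)
    tot <- tot + 1
    if (r >= obs - 1e-12) hits <- hits + 1
  }
  hits / tot
}

# direct evaluation of the ACE formula from the frequency counts
oracleAce <- function(counts, thr = 10) {
  counts <- counts[counts > 0]
  sab <- sum(counts > thr)
  rare <- counts[counts <= thr]
  srare <- length(rare)
  if (srare == 0) return(sab)
  nrare <- sum(rare)
  f1 <- sum(rare == 1)
  cace <- 1 - f1 / nrare
  num <- 0
  for (i in 1:thr) num <- num + i * (i - 1) * sum(rare == i)
  g2 <- max(srare / cace * num / (nrare * (nrare - 1)) - 1, 0)
  sab + srare / cace + f1 / cace * g2
}
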