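# Independent oracles used across the suite:
#  - exhaustive enumeration of graph isomorphism classes (incremental
#    vertex extension + BLISS canonical forms), cached per session
#  - Floyd-Warshall / path-counting centrality oracle
#  - brute-force k-core and MCODE vertex-weight oracles over all vertex
#    subsets
#  - hypergeometric tail by exhaustive draw enumeration
#  - Benjamini-Hochberg step-up formula evaluated directly

.oracle_cache <- new.env(parent = emptyenv())

canon_key <- function(g) {
  p <- igraph::canonical_permutation(g)$labeling
  gg <- igraph::permute(g, p)
  e <- igraph::as_edgelist(gg, names = FALSE)
  if (nrow(e) == 0L) return(paste0("n", igraph::vcount(gg)))
  a <- pmin(e[, 1], e[, 2]); b <- pmax(e[, 1], e[, 2])
  o <- order(a, b)
  paste0("n", igraph::vcount(gg), ":",
         paste(a[o], b[o], sep = "-", collapse = ","))
}

# All isomorphism classes of simple graphs on 1..max_n vertices, built by
# attaching one new vertex (every neighborhood subset) to every class on
# n-1 vertices. Sequence of class counts: 1, 2, 4, 11, 34, 156, 1044.
graph_classes <- function(max_n) {
  cur <- get0("classes", envir = .oracle_cache)
  if (is.null(cur)) {
    cur <- list(list(igraph::make_empty_graph(1, directed = FALSE)))
  }
  if (length(cur) < max_n) {
    for (n in (length(cur) + 1L):max_n) {
      seen <- new.env(parent = emptyenv())
      out <- vector("list", 0L)
      for (parent in cur[[n - 1L]]) {
        for (mask in 0:(2^(n - 1L) - 1L)) {
          nb <- which(bitwAnd(mask, bitwShiftL(1L, 0:(n - 2L))) != 0L)
          g <- igraph::add_vertices(parent, 1)
          if (length(nb) > 0L) {
            g <- igraph::add_edges(g, as.vector(rbind(nb, n)))
          }
          key <- canon_key(g)
          if (is.null(get0(key, envir = seen))) {
            assign(key, TRUE, envir = seen)
            out[[length(out) + 1L]] <- g
          }
        }
      }
      cur[[n]] <- out
    }
    assign("classes", cur, envir = .oracle_cache)
  }
  cur[seq_len(max_n)]
}

connected_graph_classes <- function(max_n) {
  lapply(graph_classes(max_n), function(gs) {
    Filter(function(g) igraph::is_connected(g), gs)
  })
}

# Floyd-Warshall distances, path counts by DP over increasing distance,
# betweenness from the pair-dependency definition, closeness per
# component. Normalization matches the package conventions.
oracle_metrics <- function(g) {
  n <- igraph::vcount(g)
  A <- as.matrix(igraph::as_adjacency_matrix(g))
  D <- matrix(Inf, n, n); diag(D) <- 0; D[A == 1] <- 1
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n)) {
    if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
  }
  S <- matrix(0, n, n); diag(S) <- 1
  for (s in seq_len(n)) {
    for (t in order(D[s, ])) {
      if (t == s || !is.finite(D[s, t])) next
      nbrs <- which(A[, t] == 1 & D[s, ] == D[s, t] - 1)
      S[s, t] <- sum(S[s, nbrs])
    }
  }
  btw <- numeric(n)
  for (v in seq_len(n)) {
    tot <- 0
    for (s in seq_len(n - 1L)) for (t in (s + 1L):n) {
      if (s == v || t == v || !is.finite(D[s, t])) next
      if (D[s, v] + D[v, t] == D[s, t]) tot <- tot + S[s, v] * S[v, t] / S[s, t]
    }
    btw[v] <- tot
  }
  if (n >= 3) btw <- btw / ((n - 1) * (n - 2) / 2)
  cls <- numeric(n)
  for (v in seq_len(n)) {
    comp <- which(is.finite(D[v, ]))
    cls[v] <- if (length(comp) <= 1L) 0 else
      (length(comp) - 1) / sum(D[v, comp])
  }
  list(betweenness = btw, closeness = cls)
}

# Literal simple-path enumeration betweenness (small n only): counts all
# shortest paths between every pair by DFS over simple paths.
path_enum_betweenness <- function(g) {
  n <- igraph::vcount(g)
  A <- as.matrix(igraph::as_adjacency_matrix(g))
  paths_between <- function(s, t) {
    found <- list()
    walk <- function(path) {
      v <- path[length(path)]
      if (v == t) { found[[length(found) + 1L]] <<- path; return() }
      for (u in which(A[v, ] == 1)) if (!(u %in% path)) walk(c(path, u))
    }
    walk(s)
    found
  }
  btw <- numeric(n)
  for (s in seq_len(n - 1L)) for (t in (s + 1L):n) {
    ps <- paths_between(s, t)
    if (length(ps) == 0L) next
    lens <- vapply(ps, length, integer(1))
    shortest <- ps[lens == min(lens)]
    for (p in shortest) {
      interior <- setdiff(p, c(s, t))
      btw[interior] <- btw[interior] + 1 / length(shortest)
    }
  }
  if (n >= 3) btw <- btw / ((n - 1) * (n - 2) / 2)
  btw
}

# k-core as the union of all vertex subsets whose induced subgraph has
# minimum degree >= k.
brute_k_core_vertices <- function(g, k) {
  n <- igraph::vcount(g)
  A <- as.matrix(igraph::as_adjacency_matrix(g))
  core <- integer(0)
  for (mask in seq_len(2^n - 1L)) {
    vs <- which(bitwAnd(mask, bitwShiftL(1L, 0:(n - 1L))) != 0L)
    if (length(vs) < k + 1L) next
    if (min(rowSums(A[vs, vs, drop = FALSE])) >= k) core <- union(core, vs)
  }
  sort(core)
}

# MCODE vertex weight by subset enumeration over the closed neighborhood.
brute_vertex_weight <- function(g, v, degree_cutoff = 2) {
  A <- as.matrix(igraph::as_adjacency_matrix(g))
  if (sum(A[v, ]) < degree_cutoff) return(0)
  closed <- sort(c(v, which(A[v, ] == 1)))
  B <- A[closed, closed, drop = FALSE]
  m <- length(closed)
  k_max <- 0L
  for (mask in seq_len(2^m - 1L)) {
    vs <- which(bitwAnd(mask, bitwShiftL(1L, 0:(m - 1L))) != 0L)
    if (length(vs) < 2L) next
    k_max <- max(k_max, min(rowSums(B[vs, vs, drop = FALSE])))
  }
  if (k_max == 0L) return(0)
  core <- integer(0)
  for (mask in seq_len(2^m - 1L)) {
    vs <- which(bitwAnd(mask, bitwShiftL(1L, 0:(m - 1L))) != 0L)
    if (length(vs) < 2L) next
    if (min(rowSums(B[vs, vs, drop = FALSE])) >= k_max) core <- union(core, vs)
  }
  e <- sum(B[core, core]) / 2
  nc <- length(core)
  k_max * 2 * e / (nc * (nc - 1))
}

# Upper-tail hypergeometric probability by enumerating every draw of n
# elements from 1..N, with 1..K as the marked set.
enum_hyper_tail <- function(N, K, n, k) {
  draws <- utils::combn(N, n)
  mean(colSums(draws <= K) >= k)
}

# Benjamini-Hochberg step-up formula evaluated directly:
# adj_(i) = min_{j >= i} p_(j) * m / j, mapped back to input order.
bh_formula <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  adj <- vapply(seq_len(m), function(i) {
    min(pmin(ps[i:m] * m / (i:m), 1))
  }, numeric(1))
  out <- numeric(m)
  out[o] <- adj
  out
}

jaccard <- function(a, b) length(intersect(a, b)) / length(union(a, b))

# A descriptor row that passes every rule system (neutral, Lipinski ok).
good_descriptor <- function(compound_id = "C1", ...) {
  d <- data.frame(
    compound_id = compound_id, name = compound_id,
    mw = 350, mlogp = 2, wlogp = 2, xlogp = 2, hbd = 2, hba = 4,
    tpsa = 80, rotatable_bonds = 5, molar_refractivity = 80,
    heavy_atoms = 30, rings = 3, carbons = 20, heteroatoms = 4,
    ionization_class = "neutral", stringsAsFactors = FALSE
  )
  override <- list(...)
  for (nm in names(override)) d[[nm]] <- override[[nm]]
  d
}
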