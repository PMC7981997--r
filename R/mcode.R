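#' @title MCODE molecular-complex detection
#'
#' @description
#' The three-stage molecular complex detection algorithm of Bader and
#' Hogue, as used to extract densely connected modules from
#' protein-protein interaction networks:
#'
#' 1. *Vertex weighting*: each vertex is scored by the highest k-core of
#'    its closed neighborhood times that core's density; vertices below
#'    the degree cutoff are zero-weighted (they cannot seed a complex but
#'    may still be absorbed into one).
#' 2. *Complex prediction*: complexes are grown outward from the
#'    highest-weight unvisited seed, including unvisited neighbors whose
#'    weight is within `node_score_cutoff` of the seed weight.
#' 3. *Post-processing*: each complex is replaced by the 2-core of its
#'    induced subgraph (the "haircut"); complexes without a 2-core are
#'    discarded. Optional "fluff" adds boundary neighbors with dense
#'    neighborhoods.
#'
#' A complex is scored as its density times its node count, the quality
#' measure reported by the Cytoscape plug-in.
#'
#' @name mcode
NULL

#' Maximal k-core of a graph
#'
#' The maximal subgraph in which every vertex has degree >= k, obtained
#' from the coreness decomposition; an empty graph when no such subgraph
#' exists. Idempotent.
#'
#' @param g igraph object (simple, undirected).
#' @param k minimum degree (default 2).
#' @return igraph object (possibly with zero vertices).
#' @export
k_core <- function(g, k = 2) {
  core <- igraph::coreness(g)
  igraph::induced_subgraph(g, which(core >= k))
}

.density_simple <- function(n, e) {
  if (n < 2) return(0)
  2 * e / (n * (n - 1))
}

#' MCODE vertex weights
#'
#' For each vertex v with degree >= `degree_cutoff`, the induced subgraph
#' on the closed neighborhood of v is decomposed into cores; the weight
#' is k_max times the density of the k_max-core. Vertices below the
#' cutoff get weight 0.
#'
#' @param g igraph object.
#' @param degree_cutoff minimum degree to receive a non-zero weight
#'   (default 2).
#' @return data frame: `id`, `k_max`, `weight`.
#' @export
vertex_weights <- function(g, degree_cutoff = 2) {
  n <- igraph::vcount(g)
  ids <- igraph::V(g)$name
  if (is.null(ids)) ids <- as.character(seq_len(n))
  deg <- igraph::degree(g)
  k_max <- integer(n)
  weight <- numeric(n)
  adj <- igraph::adjacent_vertices(g, igraph::V(g))
  for (i in seq_len(n)) {
    if (deg[i] < degree_cutoff) next
    nb <- c(i, as.integer(adj[[i]]))
    sub <- igraph::induced_subgraph(g, nb)
    core <- igraph::coreness(sub)
    km <- max(core)
    core_nodes <- which(core >= km)
    core_sub <- igraph::induced_subgraph(sub, core_nodes)
    k_max[i] <- km
    weight[i] <- km * .density_simple(length(core_nodes), igraph::ecount(core_sub))
  }
  data.frame(id = ids, k_max = k_max, weight = weight, stringsAsFactors = FALSE)
}

.cluster_record <- function(g, members, seed) {
  sub <- igraph::induced_subgraph(g, members)
  n <- igraph::vcount(sub)
  e <- igraph::ecount(sub)
  dens <- .density_simple(n, e)
  list(
    members = sort(igraph::V(sub)$name),
    seed = seed,
    n = n,
    e = e,
    density = dens,
    score = dens * n
  )
}

#' Predict complexes from vertex weights
#'
#' Seeds are taken in descending weight order (ties by id) among
#' unvisited positive-weight vertices; each complex grows by
#' breadth-first inclusion of unvisited neighbors u with
#' weight(u) >= (1 - node_score_cutoff) * weight(seed). Complexes are
#' pairwise disjoint.
#'
#' @param g igraph object.
#' @param weights data frame from [vertex_weights()] (recomputed when
#'   NULL).
#' @param node_score_cutoff growth tolerance in [0, 1) (default 0.2).
#' @param degree_cutoff passed to [vertex_weights()] when recomputing.
#' @return list of clusters; each has `members`, `seed`, `n`, `e`,
#'   `density`, `score`.
#' @export
predict_complexes <- function(g, weights = NULL, node_score_cutoff = 0.2,
                              degree_cutoff = 2) {
  if (is.null(weights)) weights <- vertex_weights(g, degree_cutoff)
  ids <- igraph::V(g)$name
  if (is.null(ids)) {
    ids <- as.character(seq_len(igraph::vcount(g)))
    igraph::V(g)$name <- ids
  }
  w <- weights$weight[match(ids, weights$id)]
  visited <- logical(length(ids))
  adj <- igraph::adjacent_vertices(g, igraph::V(g))
  clusters <- list()
  repeat {
    open <- which(!visited & w > 0)
    if (length(open) == 0L) break
    seed <- open[order(-w[open], ids[open])][1L]
    threshold <- (1 - node_score_cutoff) * w[seed]
    members <- seed
    visited[seed] <- TRUE
    frontier <- seed
    while (length(frontier) > 0L) {
      nb <- unique(unlist(lapply(frontier, function(v) as.integer(adj[[v]]))))
      nb <- nb[!visited[nb] & w[nb] >= threshold]
      if (length(nb) == 0L) break
      visited[nb] <- TRUE
      members <- c(members, nb)
      frontier <- nb
    }
    clusters[[length(clusters) + 1L]] <-
      .cluster_record(g, members, seed = ids[seed])
  }
  clusters
}

#' Post-process predicted complexes
#'
#' Haircut: each complex is replaced by the `require_core`-core of its
#' induced subgraph (iterative pruning of low-degree members); complexes
#' whose core is empty are discarded. Fluff (off by default) then adds
#' boundary neighbors whose closed-neighborhood density exceeds
#' `fluff_density`; fluffed members do not trigger further expansion.
#'
#' @param clusters list from [predict_complexes()].
#' @param g the graph the clusters came from.
#' @param require_core core order used for the haircut (default 2).
#' @param haircut apply the core filter (default TRUE).
#' @param fluff add dense boundary neighbors (default FALSE).
#' @param fluff_density density threshold for fluff (default 0.5).
#' @return list of clusters with updated membership and scores.
#' @export
postprocess_clusters <- function(clusters, g, require_core = 2,
                                 haircut = TRUE, fluff = FALSE,
                                 fluff_density = 0.5) {
  out <- list()
  for (cl in clusters) {
    members <- cl$members
    if (haircut || require_core > 0) {
      sub <- igraph::induced_subgraph(g, members)
      core <- k_core(sub, require_core)
      members <- igraph::V(core)$name
      if (length(members) == 0L) next
    }
    if (fluff) {
      idx <- match(members, igraph::V(g)$name)
      nb <- setdiff(
        unique(unlist(igraph::adjacent_vertices(g, idx))),
        idx
      )
      add <- character(0)
      for (v in nb) {
        closed <- c(v, as.integer(igraph::adjacent_vertices(g, v)[[1L]]))
        nsub <- igraph::induced_subgraph(g, closed)
        if (.density_simple(igraph::vcount(nsub), igraph::ecount(nsub)) >
            fluff_density) {
          add <- c(add, igraph::V(g)$name[v])
        }
      }
      members <- union(members, add)
    }
    out[[length(out) + 1L]] <- .cluster_record(g, members, seed = cl$seed)
  }
  out
}

#' MCODE cluster score
#'
#' Density times node count, the quality measure of a detected complex:
#' `n * 2e / (n (n - 1))`. Equals n exactly when the complex is a clique.
#'
#' @param n number of nodes (>= 2).
#' @param e number of internal edges, in [0, n(n-1)/2].
#' @return numeric score in (0, n].
#' @export
cluster_score <- function(n, e) {
  if (any(n < 2)) stop("cluster score requires n >= 2")
  if (any(e < 0) || any(e > n * (n - 1) / 2)) {
    stop("edge count outside [0, n(n-1)/2]")
  }
  n * 2 * e / (n * (n - 1))
}

#' Rank clusters
#'
#' Descending score; ties by descending node count, then by seed id.
#'
#' @param clusters list of clusters.
#' @return the same clusters, ordered.
#' @export
rank_clusters <- function(clusters) {
  if (length(clusters) == 0L) return(clusters)
  score <- vapply(clusters, `[[`, numeric(1), "score")
  n <- vapply(clusters, `[[`, numeric(1), "n")
  seed <- vapply(clusters, `[[`, character(1), "seed")
  clusters[order(-score, -n, seed)]
}

#' Run the full MCODE procedure
#'
#' Vertex weighting, complex prediction, post-processing and ranking
#' with the standard parameter set (node score cutoff 0.2, k-core 2,
#' degree cutoff 2, haircut on, fluff off).
#'
#' @param g igraph object.
#' @param node_score_cutoff growth tolerance (default 0.2).
#' @param k_core core order required of a final complex (default 2).
#' @param degree_cutoff minimum degree for a positive vertex weight
#'   (default 2).
#' @param haircut,fluff post-processing switches.
#' @return ranked list of clusters.
#' @export
mcode <- function(g, node_score_cutoff = 0.2, k_core = 2, degree_cutoff = 2,
                  haircut = TRUE, fluff = FALSE) {
  w <- vertex_weights(g, degree_cutoff)
  cl <- predict_complexes(g, w, node_score_cutoff)
  cl <- postprocess_clusters(cl, g, require_core = k_core,
                             haircut = haircut, fluff = fluff)
  rank_clusters(cl)
}

#' Tabulate clusters in report form
#'
#' @param clusters ranked list of clusters.
#' @return data frame: rank, score, n, e, seed, members (comma-joined).
#' @export
cluster_table <- function(clusters) {
  if (length(clusters) == 0L) {
    return(data.frame(
      rank = integer(0), score = numeric(0), n = integer(0),
      e = integer(0), seed = character(0), members = character(0),
      stringsAsFactors = FALSE
    ))
  }
  data.frame(
    rank = seq_along(clusters),
    score = round(vapply(clusters, `[[`, numeric(1), "score"), 3),
    n = vapply(clusters, function(x) as.integer(x$n), integer(1)),
    e = vapply(clusters, function(x) as.integer(x$e), integer(1)),
    seed = vapply(clusters, `[[`, character(1), "seed"),
    members = vapply(clusters, function(x) paste(x$members, collapse = ","),
                     character(1)),
    stringsAsFactors = FALSE
  )
}
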