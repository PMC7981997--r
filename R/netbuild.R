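#' @title Typed network assembly and topology
#'
#' @description
#' Builds undirected networks whose nodes carry a class label (compound,
#' target, pathway or protein), computes the three topological
#' coefficients used to rank nodes (degree, normalized betweenness,
#' within-component normalized closeness), filters confidence-weighted
#' protein-protein interaction edges, and selects top-k hubs.
#'
#' Networks are plain igraph objects with a vertex attribute `class` and,
#' where applicable, an edge attribute `confidence`.
#'
#' @name netbuild
NULL

#' Construct a typed undirected network
#'
#' @param nodes data frame with columns `id` and `class`
#'   (compound | target | pathway | protein).
#' @param edges data frame with columns `from`, `to` and optionally
#'   `confidence` in [0, 1].
#' @return igraph object.
#' @export
typed_network <- function(nodes, edges) {
  stopifnot(is.data.frame(nodes), is.data.frame(edges))
  ids <- as.character(nodes$id)
  if (anyDuplicated(ids)) stop("duplicate node ids")
  if (nrow(edges) > 0L) {
    from <- as.character(edges$from)
    to <- as.character(edges$to)
    if (any(from == to)) stop("self-loops are not allowed")
    missing <- setdiff(c(from, to), ids)
    if (length(missing) > 0L) {
      stop("edge endpoint(s) absent from node table: ",
           paste(utils::head(missing, 5), collapse = ", "))
    }
    key <- paste(pmin(from, to), pmax(from, to))
    if (anyDuplicated(key)) stop("duplicate edges")
  }
  g <- igraph::graph_from_data_frame(edges, directed = FALSE, vertices = nodes)
  g
}

#' Build a compound-target bipartite network
#'
#' One edge per (compound, gene) pair of `mapping`. By default the
#' compound layer consists of the mapping's compounds (all of which have
#' at least one target); passing `compounds` retains a fixed compound
#' layer instead, so that screened compounds that lost all their targets
#' still appear as isolated nodes, as published compound-target networks
#' commonly draw them.
#'
#' @param mapping named list: compound id -> character vector of target
#'   genes.
#' @param compounds optional character vector fixing the compound layer.
#' @return igraph object with vertex classes "compound" and "target".
#' @export
build_bipartite <- function(mapping, compounds = NULL) {
  if (length(mapping) == 0L && is.null(compounds)) {
    stop("empty mapping")
  }
  mapping <- mapping[lengths(mapping) > 0L]
  if (is.null(compounds)) {
    compounds <- names(mapping)
  } else {
    compounds <- as.character(compounds)
    extra <- setdiff(names(mapping), compounds)
    if (length(extra) > 0L) {
      stop("mapping contains compounds outside the supplied layer: ",
           paste(utils::head(extra, 5), collapse = ", "))
    }
  }
  genes <- sort(unique(unlist(mapping, use.names = FALSE)))
  clash <- intersect(compounds, genes)
  if (length(clash) > 0L) {
    stop("compound id(s) collide with gene symbol(s): ",
         paste(utils::head(clash, 5), collapse = ", "),
         "; namespace the compound ids")
  }
  nodes <- data.frame(
    id = c(compounds, genes),
    class = c(rep("compound", length(compounds)), rep("target", length(genes))),
    stringsAsFactors = FALSE
  )
  edges <- data.frame(
    from = rep(names(mapping), lengths(mapping)),
    to = unlist(mapping, use.names = FALSE),
    stringsAsFactors = FALSE
  )
  typed_network(nodes, edges)
}

#' Build a compound-target-pathway tripartite network
#'
#' Union of compound-target edges and target-pathway membership edges.
#' Pathway members absent from the target layer are dropped with a
#' warning.
#'
#' @param mapping named list: compound id -> target genes.
#' @param pathway_membership named list: pathway id -> member genes.
#' @return igraph object with vertex classes "compound", "target",
#'   "pathway".
#' @export
build_tripartite <- function(mapping, pathway_membership) {
  mapping <- mapping[lengths(mapping) > 0L]
  compounds <- names(mapping)
  targets <- sort(unique(unlist(mapping, use.names = FALSE)))

  pw_edges <- NULL
  pathways <- character(0)
  if (length(pathway_membership) > 0L) {
    members <- lapply(pathway_membership, function(g) {
      g <- unique(as.character(g))
      lost <- setdiff(g, targets)
      if (length(lost) > 0L) {
        warning("pathway member(s) absent from the target layer dropped: ",
                paste(utils::head(lost, 5), collapse = ", "))
      }
      intersect(g, targets)
    })
    members <- members[lengths(members) > 0L]
    pathways <- names(members)
    if (length(pathways) > 0L) {
      pw_edges <- data.frame(
        from = unlist(members, use.names = FALSE),
        to = rep(pathways, lengths(members)),
        stringsAsFactors = FALSE
      )
    }
  }
  nodes <- data.frame(
    id = c(compounds, targets, pathways),
    class = c(
      rep("compound", length(compounds)),
      rep("target", length(targets)),
      rep("pathway", length(pathways))
    ),
    stringsAsFactors = FALSE
  )
  ct_edges <- data.frame(
    from = rep(compounds, lengths(mapping)),
    to = unlist(mapping, use.names = FALSE),
    stringsAsFactors = FALSE
  )
  typed_network(nodes, rbind(ct_edges, pw_edges))
}

#' Per-node topological coefficients
#'
#' Degree; betweenness normalized by (n-1)(n-2)/2 (undirected pair
#' count, n = graph order); closeness computed within each connected
#' component as (n_c - 1) / sum of shortest-path distances, 0 for
#' isolated nodes. With `normalized = FALSE` the raw Brandes
#' accumulation and the literal reciprocal distance sum 1/sum(d) are
#' returned instead.
#'
#' @param net igraph object.
#' @param normalized logical (default TRUE).
#' @return data frame: `id`, `class` (NA when absent), `degree`,
#'   `betweenness`, `closeness`.
#' @export
node_metrics <- function(net, normalized = TRUE) {
  n <- igraph::vcount(net)
  deg <- igraph::degree(net)
  if (n < 3L) {
    btw <- rep(0, n)
  } else {
    btw <- igraph::betweenness(net, directed = FALSE, normalized = normalized)
  }
  cls <- suppressWarnings(igraph::closeness(net, normalized = normalized))
  cls[!is.finite(cls)] <- 0
  classes <- if ("class" %in% igraph::vertex_attr_names(net)) {
    igraph::V(net)$class
  } else {
    rep(NA_character_, n)
  }
  data.frame(
    id = igraph::V(net)$name,
    class = classes,
    degree = as.integer(deg),
    betweenness = unname(btw),
    closeness = unname(cls),
    stringsAsFactors = FALSE
  )
}

#' Mean topological coefficients over a node subset
#'
#' @param net igraph object.
#' @param ids character vector of node ids.
#' @return named numeric vector: mean_degree, mean_betweenness,
#'   mean_closeness.
#' @export
mean_metrics <- function(net, ids) {
  m <- node_metrics(net)
  ids <- as.character(ids)
  missing <- setdiff(ids, m$id)
  if (length(missing) > 0L) {
    stop("node id(s) not in network: ", paste(utils::head(missing, 5), collapse = ", "))
  }
  sub <- m[match(ids, m$id), ]
  c(
    mean_degree = mean(sub$degree),
    mean_betweenness = mean(sub$betweenness),
    mean_closeness = mean(sub$closeness)
  )
}

#' Filter a protein-protein interaction edge table by confidence
#'
#' Keeps edges with combined confidence strictly greater than
#' `threshold`; nodes left without any surviving edge are dropped.
#'
#' @param edges data frame with columns `from`, `to`, `confidence`.
#' @param threshold confidence cutoff (default 0.7, strict).
#' @return igraph object, vertex class "protein", edge attribute
#'   `confidence`.
#' @export
filter_ppi <- function(edges, threshold = 0.7) {
  stopifnot(is.data.frame(edges))
  conf <- as.numeric(edges$confidence)
  if (any(!is.finite(conf) | conf < 0 | conf > 1)) {
    stop("confidence values must lie in [0, 1]")
  }
  keep <- edges[conf > threshold, , drop = FALSE]
  ids <- sort(unique(c(as.character(keep$from), as.character(keep$to))))
  nodes <- data.frame(id = ids, class = rep("protein", length(ids)),
                      stringsAsFactors = FALSE)
  typed_network(nodes, keep[, c("from", "to", "confidence")])
}

#' Top-k hub nodes by degree
#'
#' Descending degree, ties broken by descending betweenness, then by id.
#'
#' @param net igraph object.
#' @param k number of hubs (default 20); `min(k, n)` nodes are returned.
#' @return character vector of node ids, ranked.
#' @export
top_k_by_degree <- function(net, k = 20) {
  m <- node_metrics(net)
  ord <- order(-m$degree, -m$betweenness, m$id)
  m$id[ord][seq_len(min(k, nrow(m)))]
}

#' Export a network as SIF
#'
#' One `node<TAB>relation<TAB>node` line per edge; isolated nodes are
#' written as bare node lines.
#'
#' @param net igraph object.
#' @param path output file.
#' @param relation relation label (default "interacts").
#' @export
write_sif <- function(net, path, relation = "interacts") {
  e <- igraph::as_edgelist(net)
  lines <- if (nrow(e) > 0L) paste(e[, 1], relation, e[, 2], sep = "\t") else character(0)
  isolated <- igraph::V(net)$name[igraph::degree(net) == 0]
  writeLines(c(lines, isolated), path)
  invisible(path)
}

#' Export a network as GraphML
#'
#' Vertex `class` and edge `confidence` attributes are carried along.
#'
#' @param net igraph object.
#' @param path output file.
#' @export
write_graphml <- function(net, path) {
  igraph::write_graph(net, path, format = "graphml")
  invisible(path)
}
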