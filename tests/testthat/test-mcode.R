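# k-cores, vertex weighting, complex growth, scores and ranking.

make_graph_named <- function(edges, n = max(edges)) {
  g <- igraph::make_empty_graph(n, directed = FALSE)
  g <- igraph::add_edges(g, as.vector(t(edges)))
  igraph::V(g)$name <- paste0("v", seq_len(n))
  g
}

test_that("k-core handles cliques, paths and idempotence", {
  tri <- make_graph_named(cbind(c(1, 2, 3), c(2, 3, 1)))
  expect_equal(igraph::vcount(k_core(tri, 2)), 3)

  p4 <- make_graph_named(cbind(1:3, 2:4))
  expect_equal(igraph::vcount(k_core(p4, 2)), 0)

  set.seed(31)
  for (i in 1:10) {
    g <- igraph::sample_gnp(8, 0.4)
    igraph::V(g)$name <- paste0("v", 1:8)
    once <- k_core(g, 2)
    twice <- k_core(once, 2)
    expect_setequal(igraph::V(twice)$name, igraph::V(once)$name)
  }
})

test_that("k-core equals brute-force subset search on random graphs up to 8 nodes", {
  set.seed(17)
  for (i in 1:30) {
    n <- sample(4:8, 1)
    g <- igraph::sample_gnp(n, runif(1, 0.2, 0.7))
    igraph::V(g)$name <- paste0("v", seq_len(n))
    for (k in 2:3) {
      got <- sort(match(igraph::V(k_core(g, k))$name, igraph::V(g)$name))
      expect_equal(got, brute_k_core_vertices(g, k))
    }
  }
})

test_that("vertex weights follow the clique closed form and the degree cutoff", {
  k5 <- make_graph_named(t(utils::combn(5, 2)))
  w <- vertex_weights(k5)
  expect_equal(w$weight, rep(4, 5))
  expect_equal(w$k_max, rep(4L, 5))

  # pendant vertex (degree 1) is zero-weighted under cutoff 2
  k5p <- igraph::add_vertices(k5, 1)
  igraph::V(k5p)$name <- paste0("v", 1:6)
  k5p <- igraph::add_edges(k5p, c(1, 6))
  wp <- vertex_weights(k5p)
  expect_equal(wp$weight[wp$id == "v6"], 0)
})

test_that("vertex weights match the subset-enumeration oracle on random graphs", {
  set.seed(23)
  for (i in 1:15) {
    n <- sample(5:8, 1)
    g <- igraph::sample_gnp(n, runif(1, 0.3, 0.7))
    igraph::V(g)$name <- paste0("v", seq_len(n))
    w <- vertex_weights(g)
    for (v in seq_len(n)) {
      expect_equal(w$weight[v], brute_vertex_weight(g, v), tolerance = 1e-12)
    }
  }
})

test_that("complex prediction recovers disjoint cliques and ignores edgeless graphs", {
  # K4 on v1..v4, K3 on v5..v7
  edges <- rbind(t(utils::combn(1:4, 2)), t(utils::combn(5:7, 2)))
  g <- make_graph_named(edges, n = 7)
  cl <- rank_clusters(predict_complexes(g))
  expect_length(cl, 2)
  expect_setequal(cl[[1]]$members, paste0("v", 1:4))
  expect_setequal(cl[[2]]$members, paste0("v", 5:7))
  expect_equal(cl[[1]]$score, 4)
  expect_equal(cl[[2]]$score, 3)

  empty <- igraph::make_empty_graph(5, directed = FALSE)
  igraph::V(empty)$name <- paste0("v", 1:5)
  expect_length(predict_complexes(empty), 0)
})

test_that("post-processing discards coreless clusters and trims pendants", {
  star <- make_graph_named(cbind(1, 2:6), n = 6)
  cl_star <- list(list(members = paste0("v", 1:6), seed = "v1"))
  expect_length(postprocess_clusters(cl_star, star), 0)

  tri_pend <- make_graph_named(rbind(c(1, 2), c(2, 3), c(3, 1), c(3, 4)))
  cl <- postprocess_clusters(list(list(members = paste0("v", 1:4), seed = "v1")),
                             tri_pend)
  expect_length(cl, 1)
  expect_setequal(cl[[1]]$members, paste0("v", 1:3))
  expect_equal(cl[[1]]$score, 3)
})

test_that("cluster scores reproduce the published worked examples", {
  expect_equal(round(cluster_score(13, 58), 3), 9.667)
  expect_equal(cluster_score(5, 10), 5)
  expect_equal(cluster_score(5, 8), 4)
  expect_equal(cluster_score(6, 8), 3.2)
  expect_equal(cluster_score(3, 3), 3)
  expect_equal(round(cluster_score(8, 10), 3), 2.857)
  expect_equal(cluster_score(2, 1), 2)
})

test_that("cluster score validates its inputs and peaks at cliques", {
  expect_error(cluster_score(1, 0), "n >= 2")
  expect_error(cluster_score(4, 7), "edge count")
  expect_error(cluster_score(4, -1), "edge count")
  for (n in 2:8) {
    expect_equal(cluster_score(n, n * (n - 1) / 2), n)
    expect_lt(cluster_score(n, n * (n - 1) / 2 - 1), n)
  }
})

test_that("cluster ranking is by score, then size, then seed", {
  mk <- function(score, n, seed) list(score = score, n = n, seed = seed,
                                      members = character(0), e = 0)
  ranked <- rank_clusters(list(mk(3, 3, "b"), mk(3, 6, "a"), mk(5, 5, "c")))
  expect_equal(vapply(ranked, `[[`, numeric(1), "score"), c(5, 3, 3))
  expect_equal(vapply(ranked, `[[`, numeric(1), "n"), c(5, 6, 3))

  septet <- list(c(13, 58), c(5, 10), c(5, 8), c(6, 8), c(3, 3), c(3, 3), c(8, 10))
  scores <- vapply(septet, function(x) cluster_score(x[1], x[2]), numeric(1))
  expect_equal(order(-scores), c(1, 2, 3, 4, 5, 6, 7))
})

test_that("full MCODE run is deterministic and clusters are disjoint, connected 2-cores", {
  set.seed(41)
  g <- igraph::sample_gnp(60, 0.08)
  igraph::V(g)$name <- sprintf("v%02d", 1:60)
  r1 <- mcode(g)
  r2 <- mcode(g)
  expect_identical(r1, r2)
  members <- unlist(lapply(r1, `[[`, "members"))
  expect_equal(anyDuplicated(members), 0L)
  for (cl in r1) {
    sub <- igraph::induced_subgraph(g, cl$members)
    expect_true(igraph::is_connected(sub))
    expect_gte(min(igraph::degree(sub)), 2)
  }
})

test_that("a planted clique in a sparse background is recovered", {
  set.seed(53)
  g <- igraph::sample_gnp(80, 0.04)
  igraph::V(g)$name <- sprintf("v%02d", 1:80)
  clique <- sample(igraph::V(g)$name, 8)
  idx <- match(clique, igraph::V(g)$name)
  pairs <- utils::combn(idx, 2)
  existing <- igraph::get_edge_ids(g, as.vector(pairs))
  g <- igraph::add_edges(g, as.vector(pairs[, existing == 0]))
  top <- mcode(g)[[1]]
  expect_gte(jaccard(top$members, clique), 0.9)
})

test_that("cluster tables mirror the report columns", {
  edges <- rbind(t(utils::combn(1:4, 2)))
  g <- make_graph_named(edges, n = 4)
  tab <- cluster_table(mcode(g))
  expect_equal(names(tab), c("rank", "score", "n", "e", "seed", "members"))
  expect_equal(tab$score, 4)
  expect_equal(tab$n, 4L)
  expect_equal(tab$e, 6L)
  expect_equal(cluster_table(list())$rank, integer(0))
})
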