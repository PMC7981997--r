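# Typed network assembly, topological coefficients, PPI filter, hubs.

test_that("bipartite construction counts nodes and edges", {
  net <- build_bipartite(list(c1 = c("G1", "G2"), c2 = "G2"))
  expect_equal(igraph::vcount(net), 4)
  expect_equal(igraph::ecount(net), 3)
  expect_setequal(igraph::V(net)$class, c("compound", "target"))

  single <- build_bipartite(list(c9 = "G9"))
  expect_equal(igraph::vcount(single), 2)
  expect_equal(igraph::ecount(single), 1)
})

test_that("a fixed compound layer keeps targetless compounds as isolated nodes", {
  net <- build_bipartite(list(c1 = "G1"), compounds = c("c1", "c2", "c3"))
  expect_equal(igraph::vcount(net), 4)
  expect_equal(igraph::ecount(net), 1)
  expect_equal(sum(igraph::degree(net) == 0), 2)
})

test_that("compound/gene namespace collisions are rejected", {
  expect_error(build_bipartite(list(G1 = c("G1", "G2"))), "collide")
})

test_that("the planted mapping reproduces the (785, 3747) network shape", {
  compounds <- sprintf("CMP%03d", 1:56)
  preds <- gen_predictions(compounds, seed = 13)
  fp <- filter_predictions(preds$predictions)
  net <- build_bipartite(fp$per_compound, compounds = compounds)
  expect_equal(igraph::vcount(net), 785)
  expect_equal(igraph::ecount(net), 3747)
  deg <- igraph::degree(net)
  expect_equal(sum(deg), 2 * igraph::ecount(net))
})

test_that("tripartite assembly chains the two edge layers", {
  net <- build_tripartite(list(c1 = "G1"), list(P1 = "G1"))
  expect_equal(igraph::vcount(net), 3)
  expect_equal(igraph::ecount(net), 2)
  expect_equal(sort(unique(igraph::V(net)$class)),
               c("compound", "pathway", "target"))

  bip <- build_tripartite(list(c1 = c("G1", "G2")), list())
  expect_equal(igraph::vcount(bip), 3)
  expect_equal(igraph::ecount(bip), 2)
})

test_that("pathway members missing from the target layer are dropped with a warning", {
  expect_warning(
    net <- build_tripartite(list(c1 = "G1"), list(P1 = c("G1", "G9"))),
    "absent"
  )
  expect_equal(igraph::ecount(net), 2)
  expect_false("G9" %in% igraph::V(net)$name)
})

test_that("degree, betweenness and closeness match closed-form small cases", {
  star <- typed_network(
    data.frame(id = c("h", paste0("l", 1:5)), class = "protein"),
    data.frame(from = "h", to = paste0("l", 1:5))
  )
  m <- node_metrics(star)
  expect_equal(m$degree[m$id == "h"], 5L)
  expect_equal(m$closeness[m$id == "h"], 1)

  p3 <- typed_network(
    data.frame(id = c("a", "b", "c"), class = "protein"),
    data.frame(from = c("a", "b"), to = c("b", "c"))
  )
  m3 <- node_metrics(p3)
  expect_equal(m3$betweenness[m3$id == "b"], 1)
  expect_equal(m3$closeness[m3$id == "a"], 2 / 3)

  k4 <- typed_network(
    data.frame(id = letters[1:4], class = "protein"),
    data.frame(from = c("a", "a", "a", "b", "b", "c"),
               to = c("b", "c", "d", "c", "d", "d"))
  )
  expect_equal(mean_metrics(k4, letters[1:4]),
               c(mean_degree = 3, mean_betweenness = 0, mean_closeness = 1))

  iso <- typed_network(data.frame(id = c("a", "b", "x"), class = "protein"),
                       data.frame(from = "a", to = "b"))
  mi <- node_metrics(iso)
  expect_equal(mi$degree[mi$id == "x"], 0L)
  expect_equal(mi$closeness[mi$id == "x"], 0)
  expect_equal(mi$betweenness, c(0, 0, 0))
})

test_that("mean metrics over a subset equal direct recomputation", {
  preds <- gen_predictions(sprintf("c%02d", 1:12), universe_size = 80,
                           n_targetless = 0, edge_total = 300, seed = 5)
  net <- build_bipartite(filter_predictions(preds$predictions)$per_compound)
  top5 <- top_k_by_degree(net, 5)
  metrics <- node_metrics(net)
  sub <- metrics[match(top5, metrics$id), ]
  expect_equal(
    mean_metrics(net, top5),
    c(mean_degree = mean(sub$degree),
      mean_betweenness = mean(sub$betweenness),
      mean_closeness = mean(sub$closeness))
  )
  expect_equal(mean_metrics(net, top5[1])[["mean_degree"]], sub$degree[1])
})

test_that("PPI confidence filter is strict and idempotent", {
  edges <- data.frame(
    from = c("A", "B", "C", "D"),
    to = c("B", "C", "D", "E"),
    confidence = c(0.70, 0.71, 0.90, 0.30)
  )
  net <- filter_ppi(edges, 0.7)
  expect_equal(igraph::ecount(net), 2)
  expect_setequal(igraph::V(net)$name, c("B", "C", "D"))  # A, E dropped

  refiltered <- filter_ppi(igraph::as_data_frame(net, "edges"), 0.7)
  expect_equal(igraph::ecount(refiltered), igraph::ecount(net))
  expect_setequal(igraph::V(refiltered)$name, igraph::V(net)$name)
})

test_that("planted confident edges survive the PPI filter exactly", {
  genes <- sprintf("P%03d", 1:60)
  ppi <- gen_ppi(genes, modules = list(c(8, 12), c(5, 10)),
                 background_p = 0, seed = 8)
  net <- filter_ppi(ppi$edges, 0.7)
  expect_equal(igraph::ecount(net), 22)
  expect_setequal(igraph::V(net)$name, unlist(ppi$manifest$modules))
})

test_that("hub ranking breaks ties by betweenness then id", {
  # path a-b-c-d plus edge c-e: c and b have degrees 3 and 2
  net <- typed_network(
    data.frame(id = letters[1:5], class = "protein"),
    data.frame(from = c("a", "b", "c", "c"), to = c("b", "c", "d", "e"))
  )
  expect_equal(top_k_by_degree(net, 2), c("c", "b"))
  expect_equal(top_k_by_degree(net, 99), c("c", "b", "a", "d", "e"))

  triangle <- typed_network(
    data.frame(id = c("z", "m", "a"), class = "protein"),
    data.frame(from = c("z", "m", "a"), to = c("m", "a", "z"))
  )
  expect_equal(top_k_by_degree(triangle, 3), c("a", "m", "z"))
})

test_that("network exports are readable back", {
  net <- build_bipartite(list(c1 = c("G1", "G2")), compounds = c("c1", "c2"))
  sif <- withr::local_tempfile(fileext = ".sif")
  write_sif(net, sif)
  lines <- readLines(sif)
  expect_length(lines, 3)  # 2 edges + 1 isolated node
  gml <- withr::local_tempfile(fileext = ".graphml")
  write_graphml(net, gml)
  back <- igraph::read_graph(gml, format = "graphml")
  expect_equal(igraph::vcount(back), 4)
  expect_setequal(igraph::V(back)$class, c("compound", "target"))
})

test_that("centralities agree with shortest-path oracles on graph classes up to 6 nodes", {
  classes <- connected_graph_classes(6)
  count <- 0
  for (gs in classes) for (g in gs) {
    igraph::V(g)$name <- paste0("v", seq_len(igraph::vcount(g)))
    m <- node_metrics(g)
    o <- oracle_metrics(g)
    expect_equal(m$betweenness, o$betweenness, tolerance = 1e-10)
    expect_equal(m$closeness, o$closeness, tolerance = 1e-10)
    expect_equal(sum(m$degree), 2 * igraph::ecount(g))
    count <- count + 1
  }
  expect_equal(count, 1 + 1 + 2 + 6 + 21 + 112)
})

test_that("betweenness matches literal path enumeration up to 5 nodes", {
  for (gs in connected_graph_classes(5)) for (g in gs) {
    igraph::V(g)$name <- paste0("v", seq_len(igraph::vcount(g)))
    expect_equal(node_metrics(g)$betweenness, path_enum_betweenness(g),
                 tolerance = 1e-10)
  }
})
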