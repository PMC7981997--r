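# Prediction filtering, disease-gene selection, DE deciles and Venn steps.

test_that("prediction filter keeps the boundary, collapses duplicates, drops sub-threshold", {
  preds <- data.frame(
    compound_id = c("c1", "c1", "c1"),
    gene = c("G1", "G1", "G2"),
    probability = c(0.10, 0.50, 0.09)
  )
  res <- filter_predictions(preds)
  expect_equal(res$per_compound, list(c1 = "G1"))
  expect_equal(res$union, "G1")
})

test_that("prediction filter handles empty input and flags bad probabilities", {
  res <- filter_predictions(data.frame(compound_id = character(0),
                                       gene = character(0),
                                       probability = numeric(0)))
  expect_length(res$per_compound, 0)
  expect_length(res$union, 0)
  bad <- data.frame(compound_id = "c1", gene = "G1", probability = 1.5)
  expect_error(filter_predictions(bad), "row")
})

test_that("raising the probability threshold never enlarges the union", {
  preds <- gen_predictions(sprintf("c%02d", 1:10), universe_size = 60,
                           n_targetless = 2, edge_total = 150, seed = 3)$predictions
  sizes <- vapply(c(0.05, 0.1, 0.3, 0.6),
                  function(p) length(filter_predictions(preds, p)$union),
                  numeric(1))
  expect_true(all(diff(sizes) <= 0))
})

test_that("targetless compounds are dropped in order", {
  mapping <- list(a = c("G1"), b = character(0), d = c("G2", "G3"))
  expect_equal(drop_targetless_compounds(c("a", "b", "c", "d"), mapping),
               c("a", "d"))
  expect_equal(drop_targetless_compounds(character(0), mapping), character(0))
  expect_equal(drop_targetless_compounds(c("b", "c"), mapping), character(0))
  expect_equal(drop_targetless_compounds(c("d", "a"), mapping), c("d", "a"))
})

test_that("planted targetless compounds reproduce the 56 -> 53 drop", {
  compounds <- sprintf("CMP%03d", 1:56)
  preds <- gen_predictions(compounds, universe_size = 729, n_targetless = 3,
                           edge_total = 3747, seed = 21)
  fp <- filter_predictions(preds$predictions)
  retained <- drop_targetless_compounds(compounds, fp$per_compound)
  expect_length(retained, 53)
  expect_setequal(setdiff(compounds, retained), preds$manifest$targetless)
  expect_length(fp$union, 729)
})

test_that("disease-gene filter is inclusive at the threshold", {
  recs <- data.frame(gene = c("A", "B"), relevance_score = c(10.0, 9.99))
  expect_equal(filter_disease_genes(recs), "A")
  expect_equal(filter_disease_genes(data.frame(gene = character(0),
                                               relevance_score = numeric(0))),
               character(0))
  expect_error(
    filter_disease_genes(data.frame(gene = "A", relevance_score = -1)),
    "negative"
  )
})

test_that("decile selection sizes follow the ceiling and stay disjoint", {
  set.seed(1)
  expr <- matrix(rexp(10 * 6), 10, 6,
                 dimnames = list(paste0("g", 1:10), paste0("s", 1:6)))
  labels <- c(rep("tumor", 3), rep("normal", 3))
  de <- select_top_decile_de(expr, labels, fraction = 0.10)
  expect_length(de$over, 1)
  expect_length(de$under, 1)
  expect_length(intersect(de$over, de$under), 0)

  expr25 <- matrix(rexp(25 * 6), 25, 6,
                   dimnames = list(sprintf("g%02d", 1:25), paste0("s", 1:6)))
  de25 <- select_top_decile_de(expr25, labels, fraction = 0.10)
  expect_length(de25$over, 3)
})

test_that("all-tied expression stays disjoint via lexicographic tie-breaks", {
  expr <- matrix(5, 10, 4,
                 dimnames = list(LETTERS[1:10], paste0("s", 1:4)))
  labels <- c("tumor", "tumor", "normal", "normal")
  de <- select_top_decile_de(expr, labels, fraction = 0.10)
  expect_equal(de$over, "A")
  expect_equal(de$under, "J")
})

test_that("reversing tumor/normal labels swaps over and under", {
  set.seed(7)
  expr <- matrix(rexp(50 * 8, rate = 0.1), 50, 8,
                 dimnames = list(sprintf("g%02d", 1:50), paste0("s", 1:8)))
  labels <- c(rep("tumor", 5), rep("normal", 3))
  de <- select_top_decile_de(expr, labels)
  de_rev <- select_top_decile_de(expr, ifelse(labels == "tumor", "normal", "tumor"))
  expect_equal(de_rev$over, de$under)
  expect_equal(de_rev$under, de$over)
})

test_that("invalid selection fractions are rejected", {
  expr <- matrix(1:8, 4, 2, dimnames = list(letters[1:4], c("s1", "s2")))
  labels <- c("tumor", "normal")
  expect_error(select_top_decile_de(expr, labels, fraction = 0), "fraction")
  expect_error(select_top_decile_de(expr, labels, fraction = 0.51), "fraction")
  expect_error(select_top_decile_de(expr, labels, fraction = 1.01), "fraction")
})

test_that("noiseless planted expression is recovered exactly", {
  ex <- gen_expression(G = 100, planted_over = sprintf("UP%02d", 1:10),
                       planted_under = sprintf("DN%02d", 1:10),
                       noise_sd = 0, seed = 4)
  de <- select_top_decile_de(ex$expr, ex$labels, fraction = 0.10)
  expect_setequal(de$over, ex$manifest$planted_over)
  expect_setequal(de$under, ex$manifest$planted_under)
})

test_that("set intersection emits the Venn summary", {
  r <- intersect_gene_sets(c("A", "B", "C"), c("B", "C", "D"))
  expect_equal(as.character(r), c("B", "C"))
  expect_equal(attr(r, "venn"), c(n_a = 3L, n_b = 3L, n_common = 2L))
  empty <- intersect_gene_sets(c("X", "Y"), character(0))
  expect_length(empty, 0)
})

test_that("intersection sizes obey set algebra on generated sets", {
  set.seed(11)
  for (i in 1:20) {
    a <- sample(sprintf("G%03d", 1:200), sample(5:100, 1))
    b <- sample(sprintf("G%03d", 1:200), sample(5:100, 1))
    common <- intersect_gene_sets(a, b)
    expect_lte(length(common), min(length(a), length(b)))
    expect_equal(length(common) + length(setdiff(a, b)), length(unique(a)))
  }
})

test_that("symbol normalization is idempotent and applied on ingest", {
  x <- c("  tp53 ", "EGFR", "egfr")
  once <- normalize_symbols(x)
  expect_equal(normalize_symbols(once), once)
  r <- intersect_gene_sets(c("tp53", "EGFR"), c("TP53  ", "kras"))
  expect_equal(as.character(r), "TP53")
})
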