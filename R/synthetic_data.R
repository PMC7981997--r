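#' @title Seeded synthetic-data generators with planted ground truth
#'
#' @description
#' Generators for all six input tables the pipeline consumes, each with
#' configurable planted structure so that every stage has a known
#' expected outcome. The defaults reproduce the funnel shape of the
#' herbal-compound screen the package re-implements: 97 compounds of
#' which 56 pass the drug-likeness gate and 53 retain targets; 729
#' predicted target genes, 1893 disease genes, 272 shared candidates and
#' 136 expression-validated targets; a compound-target network of 785
#' nodes and 3747 edges; and two dense interaction modules shaped
#' (13 nodes, 58 edges) and (5 nodes, 10 edges).
#'
#' A single integer seed drives everything; each generator draws from
#' its own deterministic substream, so adding a generator never perturbs
#' the tables of another. Re-running with the same seed reproduces
#' byte-identical tables.
#'
#' @name synthetic_data
NULL

# Deterministic per-generator substream. Offsets are fixed per table.
.with_substream <- function(seed, offset, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed((as.integer(seed) %% 1000003L) * 1013L + offset)
  expr
}

#' Generate a compound descriptor table with a planted pass count
#'
#' Exactly `n_pass` rows are drawn inside the intersection of all five
#' drug-likeness rule boxes (neutral ionization, Lipinski-compliant, so
#' bioavailability score 0.55); the remaining rows violate every rule
#' system and fail Lipinski (bioavailability score 0.17), so the
#' candidate gate rejects them on both grounds.
#'
#' @param n total number of compounds (default 97).
#' @param n_pass number of compounds planted to pass the gate
#'   (default 56).
#' @param seed integer seed.
#' @return list with `descriptors` (data frame) and `manifest`
#'   (planted ids).
#' @export
gen_compounds <- function(n = 97, n_pass = 56, seed = 1) {
  stopifnot(n_pass >= 0, n_pass <= n)
  .with_substream(seed, 101L, {
    ids <- sprintf("CMP%03d", seq_len(n))
    pass_idx <- sort(sample.int(n, n_pass))
    is_pass <- seq_len(n) %in% pass_idx

    r <- function(lo, hi) stats::runif(n, lo, hi)
    ri <- function(lo, hi) sample(seq(lo, hi), n, replace = TRUE)
    # interior of every rule box
    d_pass <- data.frame(
      mw = r(210, 470), mlogp = r(0, 4.1), wlogp = r(0.5, 5),
      xlogp = r(0, 4.9), hbd = ri(0, 5), hba = ri(2, 8),
      tpsa = r(20, 130), rotatable_bonds = ri(0, 10),
      molar_refractivity = r(50, 120), heavy_atoms = ri(20, 34),
      rings = ri(1, 5), carbons = ri(15, 25), heteroatoms = ri(2, 8)
    )
    # violates every rule system and >=2 Lipinski criteria
    d_fail <- data.frame(
      mw = r(700, 1200), mlogp = r(5, 9), wlogp = r(7, 10),
      xlogp = r(6, 9), hbd = ri(6, 12), hba = ri(11, 20),
      tpsa = r(160, 250), rotatable_bonds = ri(16, 25),
      molar_refractivity = r(140, 200), heavy_atoms = ri(80, 120),
      rings = ri(8, 12), carbons = ri(30, 45), heteroatoms = ri(12, 20)
    )
    d <- d_pass
    d[!is_pass, ] <- d_fail[!is_pass, ]
    descriptors <- data.frame(
      compound_id = ids,
      name = paste0("compound-", seq_len(n)),
      d,
      ionization_class = "neutral",
      stringsAsFactors = FALSE
    )
    list(
      descriptors = descriptors,
      manifest = list(n = n, n_pass = n_pass, planted_pass = ids[is_pass])
    )
  })
}

#' Generate a compound-target prediction table with planted structure
#'
#' Among the `compounds`, `n_targetless` random ones receive only
#' sub-threshold probabilities (< 0.1); the rest share `edge_total`
#' distinct probability-passing (compound, gene) pairs whose gene union
#' has exactly `universe_size` members, every compound getting at least
#' one. Decoy sub-threshold rows are mixed in throughout.
#'
#' @param compounds character vector of compound ids (e.g. the gate's
#'   selected set).
#' @param universe_size number of distinct passing target genes
#'   (default 729).
#' @param n_targetless compounds planted without any passing prediction
#'   (default 3).
#' @param edge_total number of passing (compound, gene) pairs
#'   (default 3747).
#' @param n_decoy number of additional sub-threshold rows (default 200).
#' @param seed integer seed.
#' @return list with `predictions` (data frame compound_id, gene,
#'   probability) and `manifest`.
#' @export
gen_predictions <- function(compounds, universe_size = 729, n_targetless = 3,
                            edge_total = 3747, n_decoy = 200, seed = 1) {
  compounds <- as.character(compounds)
  n <- length(compounds)
  stopifnot(n_targetless >= 0, n_targetless < n || (n_targetless == n))
  n_with <- n - n_targetless
  if (n_with > 0) {
    if (edge_total < universe_size || edge_total < n_with) {
      stop("edge_total must cover every gene and every compound at least once")
    }
    if (edge_total > n_with * universe_size) {
      stop("edge_total exceeds the number of available (compound, gene) pairs")
    }
  }
  .with_substream(seed, 211L, {
    genes <- sprintf("G%04d", seq_len(universe_size))
    targetless <- if (n_targetless > 0) sort(sample(compounds, n_targetless)) else character(0)
    with_targets <- setdiff(compounds, targetless)

    pairs <- NULL
    if (length(with_targets) > 0) {
      # round-robin coverage of every gene (hence every compound, since
      # universe_size >= n_with is implied by edge_total bounds)
      base_c <- with_targets[(seq_len(universe_size) - 1L) %% length(with_targets) + 1L]
      base <- cbind(base_c, genes)
      all_idx <- seq_len(length(with_targets) * universe_size)
      base_idx <- (match(base_c, with_targets) - 1L) * universe_size +
        seq_len(universe_size)
      extra_n <- edge_total - universe_size
      extra_idx <- sample(setdiff(all_idx, base_idx), extra_n)
      extra <- cbind(
        with_targets[(extra_idx - 1L) %/% universe_size + 1L],
        genes[(extra_idx - 1L) %% universe_size + 1L]
      )
      pairs <- rbind(base, extra)
    }
    passing <- if (is.null(pairs)) NULL else data.frame(
      compound_id = pairs[, 1], gene = pairs[, 2],
      probability = stats::runif(nrow(pairs), 0.1, 1),
      stringsAsFactors = FALSE
    )
    decoys <- data.frame(
      compound_id = sample(compounds, n_decoy, replace = TRUE),
      gene = sample(genes, n_decoy, replace = TRUE),
      probability = stats::runif(n_decoy, 0, 0.0999),
      stringsAsFactors = FALSE
    )
    if (n_targetless > 0) {
      decoys <- rbind(decoys, data.frame(
        compound_id = rep(targetless, each = 5L),
        gene = sample(genes, 5L * n_targetless, replace = TRUE),
        probability = stats::runif(5L * n_targetless, 0, 0.0999),
        stringsAsFactors = FALSE
      ))
    }
    predictions <- rbind(passing, decoys)
    predictions <- predictions[sample.int(nrow(predictions)), , drop = FALSE]
    rownames(predictions) <- NULL
    list(
      predictions = predictions,
      manifest = list(
        universe = genes, targetless = targetless,
        edge_total = edge_total
      )
    )
  })
}

#' Generate a disease-gene relevance table with a planted overlap
#'
#' Exactly `n_pass` genes carry a relevance score >= 10, of which
#' `overlap_with_targets` are drawn from `target_universe`; a pool of
#' sub-threshold records is mixed in.
#'
#' @param target_universe character vector of predicted target genes.
#' @param n_pass genes passing the score filter (default 1893).
#' @param overlap_with_targets passing genes shared with the target
#'   universe (default 272).
#' @param n_below sub-threshold records (default 300).
#' @param seed integer seed.
#' @return list with `disease` (data frame gene, relevance_score) and
#'   `manifest`.
#' @export
gen_disease_table <- function(target_universe, n_pass = 1893,
                              overlap_with_targets = 272, n_below = 300,
                              seed = 1) {
  stopifnot(overlap_with_targets <= n_pass,
            overlap_with_targets <= length(target_universe))
  .with_substream(seed, 307L, {
    shared <- sort(sample(target_universe, overlap_with_targets))
    only_disease <- sprintf("DIS%05d", seq_len(n_pass - overlap_with_targets))
    passing <- c(shared, only_disease)
    below_pool <- c(
      setdiff(target_universe, shared),
      sprintf("DIS%05d", n_pass - overlap_with_targets + seq_len(n_below))
    )
    below <- sample(below_pool, min(n_below, length(below_pool)))
    disease <- data.frame(
      gene = c(passing, below),
      relevance_score = c(
        stats::runif(length(passing), 10, 100),
        stats::runif(length(below), 0, 9.99)
      ),
      stringsAsFactors = FALSE
    )
    disease <- disease[sample.int(nrow(disease)), , drop = FALSE]
    rownames(disease) <- NULL
    list(
      disease = disease,
      manifest = list(n_pass = n_pass, shared = shared)
    )
  })
}

#' Generate a tumor/normal expression matrix with planted DE genes
#'
#' Baseline log2 expression per gene is N(`baseline_mean`,
#' `baseline_sd`); planted genes are shifted by +/- `log2fc` in tumor
#' samples; every observation gets independent N(0, `noise_sd`) noise in
#' log2 space and is returned on the raw (non-negative) scale.
#'
#' @param G number of genes (default 2000).
#' @param tumor,normal sample counts (defaults 30 and 10).
#' @param planted_over,planted_under character vectors of planted gene
#'   symbols.
#' @param genes optional full gene-name vector of length G containing
#'   the planted genes; filler names are auto-generated when NULL.
#' @param log2fc planted effect size (default 2).
#' @param noise_sd observation noise in log2 space (default 0.5).
#' @param baseline_mean,baseline_sd baseline log2 expression
#'   distribution (defaults 6 and 1).
#' @param seed integer seed.
#' @return list with `expr` (matrix), `labels` and `manifest`.
#' @export
gen_expression <- function(G = 2000, tumor = 30, normal = 10,
                           planted_over = character(0),
                           planted_under = character(0),
                           genes = NULL, log2fc = 2, noise_sd = 0.5,
                           baseline_mean = 6, baseline_sd = 1, seed = 1) {
  planted_over <- as.character(planted_over)
  planted_under <- as.character(planted_under)
  if (length(intersect(planted_over, planted_under)) > 0L) {
    stop("planted over and under sets must be disjoint")
  }
  if (is.null(genes)) {
    n_fill <- G - length(planted_over) - length(planted_under)
    stopifnot(n_fill >= 0)
    genes <- c(planted_over, planted_under, sprintf("EXP%05d", seq_len(n_fill)))
  }
  stopifnot(length(genes) == G, !anyDuplicated(genes),
            all(planted_over %in% genes), all(planted_under %in% genes))
  .with_substream(seed, 401L, {
    n_s <- tumor + normal
    labels <- c(rep("tumor", tumor), rep("normal", normal))
    baseline <- stats::rnorm(G, baseline_mean, baseline_sd)
    shift <- numeric(G)
    shift[genes %in% planted_over] <- log2fc
    shift[genes %in% planted_under] <- -log2fc
    logx <- matrix(baseline, G, n_s) +
      outer(shift, as.numeric(labels == "tumor")) +
      matrix(stats::rnorm(G * n_s, 0, noise_sd), G, n_s)
    expr <- 2^logx
    rownames(expr) <- genes
    colnames(expr) <- sprintf("S%03d", seq_len(n_s))
    list(
      expr = expr, labels = labels,
      manifest = list(planted_over = sort(planted_over),
                      planted_under = sort(planted_under))
    )
  })
}

#' Generate a PPI edge table with planted dense modules
#'
#' Each module spec (n, e) is wired as a spanning cycle plus uniformly
#' random extra edges up to e, all with confidence above the filter
#' threshold; background edges between nodes of different modules (or
#' unassigned nodes) appear with probability `background_p` and carry
#' confidences straddling the threshold.
#'
#' @param genes character vector of node names.
#' @param modules list of c(n, e) module shapes (default the two
#'   top-scoring shapes (13, 58) and (5, 10)).
#' @param background_p background edge probability (default 0.02).
#' @param conf_planted confidence range of module edges
#'   (default c(0.75, 0.99)).
#' @param conf_background confidence range of background edges
#'   (default c(0.40, 0.95)).
#' @param seed integer seed.
#' @return list with `edges` (data frame from, to, confidence) and
#'   `manifest` (module memberships).
#' @export
gen_ppi <- function(genes, modules = list(c(13, 58), c(5, 10)),
                    background_p = 0.02, conf_planted = c(0.75, 0.99),
                    conf_background = c(0.40, 0.95), seed = 1) {
  genes <- as.character(genes)
  need <- sum(vapply(modules, `[[`, numeric(1), 1))
  stopifnot(need <= length(genes))
  .with_substream(seed, 503L, {
    pool <- sample(genes)
    offset <- 0L
    module_members <- list()
    edge_from <- character(0); edge_to <- character(0)
    for (m in modules) {
      n_m <- m[1]; e_m <- m[2]
      if (e_m < n_m || e_m > n_m * (n_m - 1) / 2) {
        stop("module edge count must lie in [n, n(n-1)/2]")
      }
      members <- pool[offset + seq_len(n_m)]
      offset <- offset + n_m
      # spanning cycle guarantees a 2-core
      cyc_from <- members
      cyc_to <- members[c(seq_len(n_m)[-1], 1L)]
      all_pairs <- utils::combn(members, 2)
      key <- paste(pmin(all_pairs[1, ], all_pairs[2, ]),
                   pmax(all_pairs[1, ], all_pairs[2, ]))
      cyc_key <- paste(pmin(cyc_from, cyc_to), pmax(cyc_from, cyc_to))
      rest <- which(!(key %in% cyc_key))
      extra <- sample(rest, e_m - n_m)
      edge_from <- c(edge_from, cyc_from, all_pairs[1, extra])
      edge_to <- c(edge_to, cyc_to, all_pairs[2, extra])
      module_members[[length(module_members) + 1L]] <- sort(members)
    }
    n_planted <- length(edge_from)
    conf <- stats::runif(n_planted, conf_planted[1], conf_planted[2])

    if (background_p > 0 && length(genes) > 1) {
      module_of <- rep(NA_integer_, length(genes))
      names(module_of) <- genes
      for (i in seq_along(module_members)) {
        module_of[module_members[[i]]] <- i
      }
      pairs <- utils::combn(genes, 2)
      same_module <- !is.na(module_of[pairs[1, ]]) &
        module_of[pairs[1, ]] == module_of[pairs[2, ]]
      eligible <- which(!same_module)
      hit <- eligible[stats::runif(length(eligible)) < background_p]
      edge_from <- c(edge_from, pairs[1, hit])
      edge_to <- c(edge_to, pairs[2, hit])
      conf <- c(conf, stats::runif(length(hit), conf_background[1],
                                   conf_background[2]))
    }
    edges <- data.frame(
      from = edge_from, to = edge_to, confidence = conf,
      stringsAsFactors = FALSE
    )
    edges <- edges[sample.int(nrow(edges)), , drop = FALSE]
    rownames(edges) <- NULL
    list(
      edges = edges,
      manifest = list(modules = module_members,
                      shapes = modules)
    )
  })
}

#' Generate annotation terms with one planted enriched term
#'
#' The planted term contains `planted_overlap` genes from the query plus
#' filler from the rest of the universe; decoy terms are drawn uniformly
#' from the universe with sizes uniform over `size_range`. Categories
#' are assigned round-robin over BP/CC/MF/KEGG with the planted term in
#' KEGG.
#'
#' @param universe character vector of background genes.
#' @param query character vector the enrichment will be run with.
#' @param planted_overlap planted term's overlap with the query
#'   (default 30).
#' @param planted_size planted term's size (default 40).
#' @param n_terms total number of terms including the planted one
#'   (default 100).
#' @param size_range decoy size range (default c(20, 200)).
#' @param seed integer seed.
#' @return list with `terms` (annotation data frame) and `manifest`.
#' @export
gen_annotations <- function(universe, query, planted_overlap = 30,
                            planted_size = 40, n_terms = 100,
                            size_range = c(20, 200), seed = 1) {
  universe <- unique(as.character(universe))
  query <- unique(as.character(query))
  stopifnot(all(query %in% universe),
            planted_overlap <= min(planted_size, length(query)),
            planted_size - planted_overlap <= length(universe) - length(query))
  .with_substream(seed, 607L, {
    planted <- c(
      sample(query, planted_overlap),
      sample(setdiff(universe, query), planted_size - planted_overlap)
    )
    cats <- c("BP", "CC", "MF", "KEGG")
    n_decoy <- n_terms - 1L
    sizes <- sample(seq(size_range[1], size_range[2]), n_decoy, replace = TRUE)
    decoys <- lapply(sizes, function(s) sort(sample(universe, s)))
    terms <- data.frame(
      term_id = c("T0001", sprintf("T%04d", 1L + seq_len(n_decoy))),
      term_name = c("planted-module", sprintf("decoy-term-%d", seq_len(n_decoy))),
      category = c("KEGG", cats[(seq_len(n_decoy) - 1L) %% 4L + 1L]),
      members = I(c(list(sort(planted)), decoys)),
      stringsAsFactors = FALSE
    )
    list(
      terms = terms,
      manifest = list(planted_term = "T0001", planted_members = sort(planted))
    )
  })
}

#' Generate the full six-table synthetic study
#'
#' Chains the individual generators so their planted structures compose
#' into the default funnel: 97 -> 56 -> 53 compounds, 729 -> 272 -> 136
#' genes, a (785, 3747) compound-target network, two planted interaction
#' modules and one planted enriched term. The returned manifest records
#' every planted identity.
#'
#' @param seed integer seed driving all substreams.
#' @param G expression matrix size (default 2000).
#' @param de_fraction decile fraction the expression stage will use
#'   (default 0.10); the planted over/under sets fill the deciles
#'   exactly, with half of the 272 candidate genes (136) planted.
#' @param noise_sd expression noise (default 0.5).
#' @return list: `descriptors`, `predictions`, `disease`, `expression`
#'   (list expr/labels), `ppi_edges`, `annotations`, `manifest`.
#' @export
gen_all <- function(seed = 1, G = 2000, de_fraction = 0.10, noise_sd = 0.5) {
  comp <- gen_compounds(seed = seed)
  verdicts <- select_candidates(comp$descriptors)
  selected <- verdicts$compound_id[verdicts$selected]

  preds <- gen_predictions(selected, seed = seed)
  fp <- filter_predictions(preds$predictions)
  retained <- drop_targetless_compounds(selected, fp$per_compound)
  target_union <- sort(unique(unlist(fp$per_compound[retained],
                                     use.names = FALSE)))

  dis <- gen_disease_table(target_union, seed = seed)
  candidates <- intersect_gene_sets(
    target_union,
    filter_disease_genes(dis$disease)
  )

  m <- ceiling(de_fraction * G)
  n_cand_planted <- length(candidates) %/% 2L   # 136 of the 272 by default
  half <- n_cand_planted %/% 2L
  over_cand <- candidates[seq_len(half)]
  under_cand <- candidates[half + seq_len(n_cand_planted - half)]
  fill_over <- sprintf("FOV%04d", seq_len(m - length(over_cand)))
  fill_under <- sprintf("FUN%04d", seq_len(m - length(under_cand)))
  planted_over <- c(over_cand, fill_over)
  planted_under <- c(under_cand, fill_under)
  filler <- sprintf("EXP%05d",
                    seq_len(G - 2L * m - (length(candidates) - n_cand_planted)))
  genes_expr <- c(planted_over, planted_under,
                  setdiff(candidates, c(over_cand, under_cand)), filler)
  ex <- gen_expression(
    G = G, planted_over = planted_over, planted_under = planted_under,
    genes = genes_expr, noise_sd = noise_sd, seed = seed
  )
  validated <- sort(c(over_cand, under_cand))

  ppi <- gen_ppi(validated, seed = seed)
  ann_universe <- c(validated, sprintf("BG%04d", seq_len(2000 - length(validated))))
  ann <- gen_annotations(ann_universe, validated, seed = seed)

  list(
    descriptors = comp$descriptors,
    predictions = preds$predictions,
    disease = dis$disease,
    expression = list(expr = ex$expr, labels = ex$labels),
    ppi_edges = ppi$edges,
    annotations = ann$terms,
    manifest = list(
      seed = seed,
      compounds = comp$manifest,
      predictions = preds$manifest["targetless"],
      target_union = target_union,
      candidates = as.character(candidates),
      planted_over = ex$manifest$planted_over,
      planted_under = ex$manifest$planted_under,
      validated = validated,
      ppi_modules = ppi$manifest,
      planted_term = ann$manifest
    )
  )
}

#' Write the six synthetic tables and their manifest to a directory
#'
#' @param data list from [gen_all()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_fixtures <- function(data, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_tsv(data$descriptors, file.path(dir, "compounds.tsv"))
  write_tsv(data$predictions, file.path(dir, "predictions.tsv"))
  write_tsv(data$disease, file.path(dir, "disease_genes.tsv"))
  write_expression(data$expression$expr, data$expression$labels,
                   file.path(dir, "expression.tsv"))
  write_tsv(data$ppi_edges, file.path(dir, "ppi_edges.tsv"))
  write_gmt(data$annotations, file.path(dir, "annotations.gmt"))
  write_tsv(
    data$annotations[, c("term_id", "category")],
    file.path(dir, "annotations.categories.tsv")
  )
  jsonlite::write_json(
    data$manifest, file.path(dir, "manifest.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(dir)
}
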