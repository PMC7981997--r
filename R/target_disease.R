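#' @title Target mapping, disease-gene selection and the Venn funnel
#'
#' @description
#' Filters predicted compound-target interactions by probability, drops
#' compounds left without any target, selects disease genes by relevance
#' score and by top-decile differential expression, and intersects gene
#' sets to produce the candidate-target funnel.
#'
#' @name target_disease
NULL

#' Normalize gene symbols
#'
#' Uppercases and strips surrounding whitespace. Idempotent; no alias
#' mapping is attempted.
#'
#' @param x character vector of gene symbols.
#' @return normalized character vector.
#' @export
normalize_symbols <- function(x) {
  toupper(trimws(as.character(x)))
}

#' Filter compound-target predictions by probability
#'
#' Keeps predictions with probability >= `p_min` (inclusive), collapses
#' duplicate (compound, gene) pairs, and returns the per-compound target
#' sets together with their union.
#'
#' @param preds data frame with columns `compound_id`, `gene`,
#'   `probability`.
#' @param p_min minimum prediction probability (default 0.1).
#' @return list with `per_compound` (named list of sorted gene vectors,
#'   only compounds with at least one passing prediction) and `union`
#'   (sorted union of all passing genes).
#' @export
filter_predictions <- function(preds, p_min = 0.1) {
  stopifnot(is.data.frame(preds))
  if (nrow(preds) == 0L) {
    return(list(per_compound = structure(list(), names = character(0)),
                union = character(0)))
  }
  p <- as.numeric(preds$probability)
  bad <- which(!is.finite(p) | p < 0 | p > 1)
  if (length(bad) > 0L) {
    stop("probability outside [0, 1] in row(s) ", paste(bad, collapse = ", "))
  }
  keep <- preds[p >= p_min, , drop = FALSE]
  if (nrow(keep) == 0L) {
    return(list(per_compound = structure(list(), names = character(0)),
                union = character(0)))
  }
  genes <- normalize_symbols(keep$gene)
  per_compound <- lapply(
    split(genes, as.character(keep$compound_id)),
    function(g) sort(unique(g))
  )
  list(
    per_compound = per_compound,
    union = sort(unique(genes))
  )
}

#' Drop compounds without any predicted target
#'
#' @param compound_ids character vector of selected compounds, in screening
#'   order.
#' @param mapping per-compound target sets, as returned by
#'   [filter_predictions()]`$per_compound`.
#' @return the compounds whose target set is non-empty, original order
#'   preserved.
#' @export
drop_targetless_compounds <- function(compound_ids, mapping) {
  compound_ids <- as.character(compound_ids)
  has_targets <- vapply(
    compound_ids,
    function(id) !is.null(mapping[[id]]) && length(mapping[[id]]) > 0L,
    logical(1)
  )
  compound_ids[has_targets]
}

#' Select disease genes by relevance score
#'
#' @param records data frame with columns `gene` and `relevance_score`.
#' @param score_min minimum relevance score, inclusive (default 10).
#' @return sorted character vector of unique passing gene symbols.
#' @export
filter_disease_genes <- function(records, score_min = 10) {
  stopifnot(is.data.frame(records))
  if (nrow(records) == 0L) return(character(0))
  s <- as.numeric(records$relevance_score)
  bad <- which(!is.finite(s) | s < 0)
  if (length(bad) > 0L) {
    stop("negative or non-finite relevance score in row(s) ",
         paste(bad, collapse = ", "))
  }
  sort(unique(normalize_symbols(records$gene[s >= score_min])))
}

#' Top-decile over/under-expressed gene selection
#'
#' Ranks genes by the log2 fold change of tumor versus normal group means
#' (pseudo-count `pseudo` added to both means) and returns the top
#' `ceiling(fraction * G)` genes as `over` and the bottom as `under`.
#' Ties are broken by gene symbol: lexicographically ascending on the
#' over side and descending on the under side, which keeps the two sets
#' disjoint even on fully degenerate (all-tied) input.
#'
#' @param expr numeric matrix, genes in rows (rownames = symbols), samples
#'   in columns; non-negative expression values.
#' @param labels character vector per sample, values "tumor" or "normal".
#' @param fraction fraction of genes to select on each side, in (0, 0.5]
#'   (default 0.10); `2 * ceiling(fraction * G)` must not exceed G.
#' @param pseudo pseudo-count added to each group mean (default 1).
#' @return list with sorted character vectors `over` and `under` and the
#'   numeric vector `effect` (named per gene).
#' @export
select_top_decile_de <- function(expr, labels, fraction = 0.10, pseudo = 1) {
  stopifnot(is.matrix(expr), length(labels) == ncol(expr))
  if (!is.numeric(fraction) || length(fraction) != 1L ||
      fraction <= 0 || fraction > 0.5) {
    stop("fraction must lie in (0, 0.5]")
  }
  labels <- as.character(labels)
  if (!all(labels %in% c("tumor", "normal"))) {
    stop("labels must be 'tumor' or 'normal'")
  }
  if (sum(labels == "tumor") < 1L || sum(labels == "normal") < 1L) {
    stop("need at least one tumor and one normal sample")
  }
  genes <- normalize_symbols(rownames(expr))
  if (anyDuplicated(genes)) stop("duplicate gene symbols in expression matrix")
  g_n <- nrow(expr)
  m <- ceiling(fraction * g_n)
  if (2L * m > g_n) {
    stop("selection fraction too large: over and under sets would overlap")
  }
  mu_t <- rowMeans(expr[, labels == "tumor", drop = FALSE])
  mu_n <- rowMeans(expr[, labels == "normal", drop = FALSE])
  effect <- log2((mu_t + pseudo) / (mu_n + pseudo))
  names(effect) <- genes

  over_order <- order(-effect, genes)
  under_order <- order(effect, genes, decreasing = c(FALSE, TRUE), method = "radix")
  list(
    over = sort(genes[over_order[seq_len(m)]]),
    under = sort(genes[under_order[seq_len(m)]]),
    effect = effect
  )
}

#' Intersect two gene sets (a Venn step)
#'
#' @param a,b character vectors of gene symbols.
#' @return sorted intersection, with a `venn` attribute
#'   `c(n_a, n_b, n_common)`.
#' @export
intersect_gene_sets <- function(a, b) {
  a <- sort(unique(normalize_symbols(a)))
  b <- sort(unique(normalize_symbols(b)))
  common <- intersect(a, b)
  structure(
    common,
    venn = c(n_a = length(a), n_b = length(b), n_common = length(common))
  )
}
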