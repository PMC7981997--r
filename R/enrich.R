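#' @title Gene-set over-representation analysis
#'
#' @description
#' Hypergeometric (or EASE-corrected) over-representation of a query
#' gene list against GO/KEGG-style annotation terms, with
#' Benjamini-Hochberg false-discovery-rate control applied within each
#' annotation category and a configurable FDR significance gate
#' (default FDR < 0.01). The rich factor of a term is the fraction of
#' its genes hit by the query, k/K.
#'
#' @name enrich
NULL

#' Upper-tail hypergeometric probability
#'
#' P(X >= k) for X ~ Hypergeometric(N, K, n): the chance that a uniform
#' draw of n genes from a universe of N containing K term genes hits the
#' term at least k times.
#'
#' @param N universe size.
#' @param K term size within the universe.
#' @param n query size within the universe.
#' @param k observed overlap.
#' @return probability in (0, 1].
#' @export
hypergeom_upper_tail <- function(N, K, n, k) {
  if (any(K > N)) stop("bound violated: K <= N")
  if (any(n > N)) stop("bound violated: n <= N")
  if (any(k < 0)) stop("bound violated: k >= 0")
  if (any(k > pmin(K, n))) stop("bound violated: k <= min(K, n)")
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' EASE-corrected enrichment probability
#'
#' The conservative variant used by DAVID: the hypergeometric upper tail
#' evaluated at k - 1 (so a single-gene overlap is never significant).
#'
#' @inheritParams hypergeom_upper_tail
#' @return probability in (0, 1]; always >= the plain upper tail.
#' @export
ease_p <- function(N, K, n, k) {
  if (any(k > pmin(K, n))) stop("bound violated: k <= min(K, n)")
  hypergeom_upper_tail(N, K, n, pmax(k - 1, 0))
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param p numeric vector of p-values in (0, 1].
#' @return adjusted values, same order as the input, clipped to (0, 1].
#' @export
bh_fdr <- function(p) {
  p <- as.numeric(p)
  if (any(!is.finite(p) | p <= 0 | p > 1)) {
    stop("p-values must lie in (0, 1]")
  }
  stats::p.adjust(p, method = "BH")
}

#' Read a GMT annotation file
#'
#' Each line: term id, description, then member genes, tab-separated.
#'
#' @param path GMT file.
#' @param category annotation category recorded for every term in the
#'   file (e.g. "BP", "KEGG"); default NA.
#' @return data frame with columns `term_id`, `term_name`, `category`
#'   and list-column `members` (deduplicated, uppercased).
#' @export
read_gmt <- function(path, category = NA_character_) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 3L)
  if (length(bad) > 0L) {
    stop("malformed GMT line(s) (need id, description, >=1 gene): ",
         paste(bad, collapse = ", "))
  }
  data.frame(
    term_id = vapply(parts, `[[`, character(1), 1L),
    term_name = vapply(parts, `[[`, character(1), 2L),
    category = category,
    members = I(lapply(parts, function(x) sort(unique(normalize_symbols(x[-(1:2)]))))),
    stringsAsFactors = FALSE
  )
}

#' Write annotation terms as GMT
#'
#' @param terms data frame as returned by [read_gmt()].
#' @param path output file.
#' @export
write_gmt <- function(terms, path) {
  lines <- vapply(seq_len(nrow(terms)), function(i) {
    paste(c(terms$term_id[i], terms$term_name[i], terms$members[[i]]),
          collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Over-representation analysis of a query gene list
#'
#' Each term is intersected with the universe; terms left empty are
#' dropped. Query genes outside the universe are dropped with a warning.
#' BH adjustment runs within each category separately. Rows are ordered
#' by FDR ascending, then rich factor descending, then term id.
#'
#' @param query character vector of gene symbols.
#' @param terms annotation data frame (`term_id`, `term_name`,
#'   `category`, list-column `members`).
#' @param universe background gene set; default is the union of all term
#'   members.
#' @param method "hypergeometric" (default) or "ease".
#' @param fdr_gate FDR significance threshold (default 0.01).
#' @return data frame: term_id, term_name, category, k, K, n, N,
#'   rich_factor, p_value, fdr, significant.
#' @export
enrich <- function(query, terms, universe = NULL,
                   method = c("hypergeometric", "ease"), fdr_gate = 0.01) {
  method <- match.arg(method)
  stopifnot(is.data.frame(terms), nrow(terms) > 0L)
  if (is.null(universe)) {
    universe <- unique(unlist(terms$members, use.names = FALSE))
  }
  universe <- unique(normalize_symbols(universe))
  if (length(universe) == 0L) stop("empty universe")
  query <- unique(normalize_symbols(query))
  if (length(query) == 0L) stop("empty query")
  outside <- setdiff(query, universe)
  if (length(outside) > 0L) {
    warning(length(outside), " query gene(s) outside the universe dropped")
    query <- intersect(query, universe)
    if (length(query) == 0L) stop("no query genes left inside the universe")
  }
  members <- lapply(terms$members, intersect, universe)
  keep <- lengths(members) >= 1L
  terms <- terms[keep, , drop = FALSE]
  members <- members[keep]

  N <- length(universe)
  n <- length(query)
  K <- lengths(members)
  k <- vapply(members, function(m) length(intersect(m, query)), integer(1))
  p_fun <- if (method == "ease") ease_p else hypergeom_upper_tail
  p <- p_fun(N, K, n, k)
  p <- pmin(pmax(p, .Machine$double.xmin), 1)

  res <- data.frame(
    term_id = terms$term_id,
    term_name = terms$term_name,
    category = terms$category,
    k = k, K = as.integer(K), n = n, N = N,
    rich_factor = k / K,
    p_value = p,
    stringsAsFactors = FALSE
  )
  grp <- ifelse(is.na(res$category), "uncategorized", res$category)
  res$fdr <- stats::ave(res$p_value, grp, FUN = bh_fdr)
  res$significant <- res$fdr < fdr_gate
  res[order(res$fdr, -res$rich_factor, res$term_id), , drop = FALSE]
}

#' Bubble-chart table of an enrichment result
#'
#' The compact table behind a rich-factor bubble chart: term, rich
#' factor, overlap count and FDR for the significant rows.
#'
#' @param result data frame from [enrich()].
#' @param only_significant keep only significant rows (default TRUE).
#' @return data frame: term_id, term_name, category, rich_factor, k, fdr.
#' @export
bubble_table <- function(result, only_significant = TRUE) {
  if (only_significant) result <- result[result$significant, , drop = FALSE]
  result[, c("term_id", "term_name", "category", "rich_factor", "k", "fdr")]
}
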