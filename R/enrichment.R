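# Category (GO-style) over-representation analysis: one-sided Fisher exact
# (hypergeometric tail) with Benjamini-Hochberg correction over a
# user-supplied gene-to-category map.

#' One-sided Fisher exact over-representation p-value
#'
#' Upper hypergeometric tail `P(X >= k)` for drawing `k` category genes in a
#' list of size `n` from a universe of `N` genes of which `K` belong to the
#' category.
#'
#' @param k Hits in the list. @param K Category size. @param n List size.
#' @param N Universe size.
#' @return The one-sided p-value.
#' @export
fisher_overrepresentation <- function(k, K, n, N) {
  ok <- length(k) == length(K) && length(K) == length(n) && length(n) == length(N)
  if (!ok) stop("k, K, n, N must have equal length", call. = FALSE)
  bad <- k < 0 | K < 0 | n < 0 | N < 1 | K > N | n > N | k > pmin(n, K)
  if (any(bad)) stop("inconsistent counts: need 0 <= k <= min(n, K), K <= N, n <= N",
                     call. = FALSE)
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Benjamini-Hochberg adjusted q-values
#'
#' Standard step-up adjustment (via [stats::p.adjust()]); order-preserving
#' with enforced monotonicity in p rank.
#'
#' @param p_values Numeric vector of p-values in (0, 1\].
#' @return q-values of the same length and order.
#' @export
bh_adjust <- function(p_values) {
  if (length(p_values) == 0L) return(numeric())
  if (any(!is.finite(p_values)) || any(p_values <= 0 | p_values > 1)) {
    stop("p-values must lie in (0, 1]", call. = FALSE)
  }
  stats::p.adjust(p_values, method = "BH")
}

normalize_categories <- function(categories) {
  if (is.data.frame(categories)) {
    assert_columns(categories, c("category_id", "gene_symbol"),
                   "category map")
    categories <- split(categories$gene_symbol, categories$category_id)
  }
  if (!is.list(categories) || is.null(names(categories)) ||
      any(!nzchar(names(categories)))) {
    stop("categories must be a named list or a (category_id, gene_symbol) table",
         call. = FALSE)
  }
  lapply(categories, unique)
}

#' Category over-representation analysis of a gene list
#'
#' One Fisher exact test per category against the universe, BH-corrected
#' across the categories with at least one hit. Genes in the list but not in
#' the universe are dropped with a warning; category genes outside the
#' universe are trimmed. Fold enrichment is `(k/n) / (K/N)`. (An annotation-
#' clustering "enrichment score" in the DAVID sense is deliberately not
#' computed; it depends on proprietary clustering of terms.)
#'
#' @param gene_list Character vector of gene symbols.
#' @param categories Named list of gene vectors, or a two-column data frame
#'   (`category_id`, `gene_symbol`).
#' @param universe Character vector of all eligible genes (typically every
#'   gene on the annotation).
#' @return Data frame sorted by p-value, one row per category with
#'   `k >= 1`: `category_id`, `k`, `K`, `n`, `N`, `fold_enrichment`,
#'   `p_value`, `q_value`.
#' @export
enrich <- function(gene_list, categories, universe) {
  categories <- normalize_categories(categories)
  universe <- unique(universe)
  if (length(universe) == 0L) stop("universe is empty", call. = FALSE)
  gene_list <- unique(gene_list)
  outside <- setdiff(gene_list, universe)
  if (length(outside)) {
    warning(sprintf("dropping %d gene(s) not in the universe",
                    length(outside)), call. = FALSE)
    gene_list <- intersect(gene_list, universe)
  }
  categories <- lapply(categories, intersect, universe)
  categories <- categories[lengths(categories) > 0L]
  N <- length(universe)
  n <- length(gene_list)
  rows <- lapply(names(categories), function(id) {
    K <- length(categories[[id]])
    k <- length(intersect(gene_list, categories[[id]]))
    if (k == 0L) return(NULL)
    data.frame(
      category_id = id, k = k, K = K, n = n, N = N,
      fold_enrichment = (k / n) / (K / N),
      p_value = fisher_overrepresentation(k, K, n, N),
      stringsAsFactors = FALSE
    )
  })
  rows <- do.call(rbind, rows)
  if (is.null(rows)) {
    return(data.frame(category_id = character(), k = integer(),
                      K = integer(), n = integer(), N = integer(),
                      fold_enrichment = numeric(), p_value = numeric(),
                      q_value = numeric(), stringsAsFactors = FALSE))
  }
  rows$q_value <- bh_adjust(rows$p_value)
  rows <- rows[order(rows$p_value, rows$category_id), , drop = FALSE]
  rownames(rows) <- NULL
  rows
}

#' Read a two-column category map
#'
#' TSV with columns `category_id` and `gene_symbol`, one gene-category pair
#' per row.
#'
#' @param path Path to the TSV.
#' @return Named list of gene vectors.
#' @export
read_category_map <- function(path) {
  normalize_categories(read_tsv_plain(path))
}
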