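#' Hypergeometric enrichment of a CpG subset in a category
#'
#' Tests whether a subset of CpGs (e.g. the senescence-associated set) is
#' over- or under-represented in a category (e.g. H3K27me3 targets) within
#' a universe of CpGs. With `N` universe members, `K` of them in the
#' category and a subset of size `n` overlapping the category in `k` sites,
#' `p_over = P(X >= k)` and `p_under = P(X <= k)` for
#' `X ~ Hypergeometric(N, K, n)`; both tails are always reported, along
#' with the fold enrichment `(k/n) / (K/N)`.
#'
#' @param subset Character vector of CpG ids (must lie inside `universe`).
#' @param membership Membership tibble (`cpg_id`, `category`), or a
#'   character vector of category-member CpG ids for a single unnamed
#'   category.
#' @param universe Character vector of CpG ids defining the universe.
#' @return Tibble, one row per category: `category`, `N`, `K`, `n`, `k`,
#'   `fold`, `p_over`, `p_under`.
#' @examples
#' hypergeom_enrichment(c("a", "b"), tibble::tibble(
#'   cpg_id = c("a", "b", "c"), category = "mark"),
#'   universe = letters[1:10])
#' @export
hypergeom_enrichment <- function(subset, membership, universe) {
  universe <- unique(universe)
  stray <- setdiff(subset, universe)
  if (length(stray)) {
    abort(paste0("subset CpGs outside the universe: ",
                 paste(head(stray, 5), collapse = ", "),
                 if (length(stray) > 5) sprintf(" (+%d more)", length(stray) - 5)))
  }
  if (!is.data.frame(membership)) {
    membership <- tibble(cpg_id = membership, category = "category")
  }
  subset <- unique(subset)
  N <- length(universe); n <- length(subset)
  purrr::map_dfr(unique(membership$category), function(cat) {
    members <- intersect(unique(membership$cpg_id[membership$category == cat]),
                         universe)
    K <- length(members)
    k <- length(intersect(subset, members))
    tibble(category = cat, N = N, K = K, n = n, k = k,
           fold = if (n > 0 && K > 0) (k / n) / (K / N) else NA_real_,
           p_over = phyper(k - 1, K, N - K, n, lower.tail = FALSE),
           p_under = phyper(k, K, N - K, n))
  })
}

#' Fisher exact enrichment of gene sets in a query list
#'
#' Generic set over-representation: for each term, the 2x2 table of
#' query/non-query by in-term/out-of-term genes is tested with Fisher's
#' exact test. Both the two-sided p-value and the one-sided
#' over-representation p-value (which equals the hypergeometric upper
#' tail) are reported, with Benjamini-Hochberg adjusted values across
#' terms.
#'
#' @param term_map Named list of character vectors (term -> gene set), or a
#'   tibble with columns `term` and `gene`.
#' @param query Character vector of genes of interest (subset of
#'   `universe`).
#' @param universe Character vector of background genes (nonempty).
#' @return Tibble per term: `term`, `N`, `K`, `n`, `k`, `fold`, `p_over`,
#'   `p_two_sided`, `p_over_adj`, `p_two_sided_adj`.
#' @export
fisher_set_enrichment <- function(term_map, query, universe) {
  universe <- unique(universe)
  if (!length(universe)) abort("universe must be nonempty.")
  stray <- setdiff(query, universe)
  if (length(stray)) {
    abort(paste0("query genes outside the universe: ",
                 paste(head(stray, 5), collapse = ", ")))
  }
  if (is.data.frame(term_map)) {
    term_map <- split(term_map$gene, term_map$term)
  }
  query <- unique(query)
  N <- length(universe); n <- length(query)
  out <- purrr::imap_dfr(term_map, function(genes, term) {
    members <- intersect(unique(genes), universe)
    K <- length(members)
    k <- length(intersect(query, members))
    tab <- matrix(c(k, n - k, K - k, N - K - n + k), 2)
    tibble(term = term, N = N, K = K, n = n, k = k,
           fold = if (n > 0 && K > 0) (k / n) / (K / N) else NA_real_,
           p_over = fisher.test(tab, alternative = "greater")$p.value,
           p_two_sided = fisher.test(tab)$p.value)
  })
  out %>% mutate(p_over_adj = p.adjust(.data$p_over, "BH"),
                 p_two_sided_adj = p.adjust(.data$p_two_sided, "BH"))
}
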