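# Over-representation analysis: observed vs expected category counts with a
# hypergeometric upper-tail p-value, screened over a gene-set collection.

#' Hypergeometric over-representation test for one category
#'
#' Given a selected gene list drawn from a universe, tests whether a
#' category is over-represented: with `N = |universe|`,
#' `K = |category intersect universe|`, `n = |selected|` and
#' `k = |selected intersect category|`, the expected count is `n K / N` and
#' the p-value is the upper tail `P(X >= k)` for `X` hypergeometric.
#' Duplicate symbols collapse to one gene before counting; the category is
#' intersected with the universe before testing. The test is one-sided
#' (enrichment only).
#'
#' @param selected Character vector of selected gene symbols; must be a
#'   subset of `universe`.
#' @param category Character vector of category members.
#' @param universe Character vector: the analysis universe (all annotated
#'   genes on the platform, not the genome).
#' @param name Optional category name carried into the result.
#' @return One-row `data.frame`: `category`, `observed`, `expected`,
#'   `p_value`.
#' @export
ora_test <- function(selected, category, universe, name = NA_character_) {
  universe <- unique(as.character(universe))
  if (!length(universe)) stop("empty universe")
  selected <- unique(as.character(selected))
  outside <- setdiff(selected, universe)
  if (length(outside)) {
    stop("selected gene(s) outside the universe: ",
         paste(utils::head(outside, 5), collapse = ", "))
  }
  category <- intersect(unique(as.character(category)), universe)
  N <- length(universe)
  K <- length(category)
  n <- length(selected)
  k <- length(intersect(selected, category))
  p <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  data.frame(category = name, observed = k,
             expected = n * K / N, p_value = p,
             stringsAsFactors = FALSE)
}

#' Screen a gene-set collection for over-represented categories
#'
#' Runs [ora_test()] for every category of the collection with at least
#' `min_category` members after intersection with the universe, and returns
#' results sorted by p-value (stable order for ties) with a BH-adjusted
#' column.
#'
#' @inheritParams ora_test
#' @param collection A [gene_set_collection()].
#' @param min_category Minimum post-intersection category size (default 3).
#' @return `data.frame` sorted by `p_value`: `category`, `set_size`,
#'   `observed`, `expected`, `p_value`, `padj`.
#' @export
enrich_all <- function(selected, collection, universe, min_category = 3) {
  stopifnot(inherits(collection, "gene_set_collection"))
  universe <- unique(as.character(universe))
  sizes <- vapply(collection, function(s) length(intersect(unique(s), universe)), 1L)
  keep <- names(collection)[sizes >= min_category]
  rows <- lapply(keep, function(nm) {
    r <- ora_test(selected, collection[[nm]], universe, name = nm)
    r$set_size <- length(intersect(unique(collection[[nm]]), universe))
    r
  })
  if (!length(rows)) {
    return(data.frame(category = character(), set_size = integer(),
                      observed = integer(), expected = numeric(),
                      p_value = numeric(), padj = numeric(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out$padj <- bh_adjust(out$p_value)
  out <- out[order(out$p_value), c("category", "set_size", "observed",
                                   "expected", "p_value", "padj")]
  rownames(out) <- NULL
  out
}
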