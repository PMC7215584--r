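# Hypergeometric over-representation of a query target set against a
# gene-set collection, with Benjamini-Hochberg FDR control across all sets
# of the collection. The universe is always the collection's explicit
# target universe (standard over-representation analysis).

#' Upper-tail hypergeometric probability
#'
#' Probability of drawing `k0` or more members of a set of size `K` when
#' sampling `m` targets without replacement from a universe of size
#' `M_universe`:
#' \deqn{P = \sum_{k = k_0}^{\min(K, m)}
#'   \binom{K}{k}\binom{M-K}{m-k} / \binom{M}{m}}
#' Evaluated in log space (via [stats::phyper()]) for numerical stability.
#' Returns 1 when `k0 <= 0` and 0 when `k0 > min(K, m)`.
#'
#' @param k0 Observed overlap (hits).
#' @param K Set size within the universe.
#' @param m Query size.
#' @param M_universe Universe size.
#' @return The upper-tail probability.
#' @examples
#' hypergeom_upper_tail(3, K = 4, m = 5, M_universe = 10) # 66/252
#' @export
hypergeom_upper_tail <- function(k0, K, m, M_universe) {
  if (K < 0 || K > M_universe || m < 0 || m > M_universe || k0 < 0 ||
      M_universe < 0) {
    stop("hypergeometric parameters out of bounds", call. = FALSE)
  }
  if (k0 <= 0) return(1)
  if (k0 > min(K, m)) return(0)
  stats::phyper(k0 - 1, K, M_universe - K, m, lower.tail = FALSE)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Standard BH step-up: with p-values sorted ascending,
#' `p*_(i) = min_{k >= i} min(p_(k) * n / k, 1)`, mapped back to the input
#' order. Controls the false discovery rate across the tested sets.
#'
#' @param pvalues Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values in input order.
#' @export
bh_adjust <- function(pvalues) {
  if (length(pvalues) == 0L) return(numeric(0))
  if (anyNA(pvalues) || any(pvalues < 0 | pvalues > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(pvalues, method = "BH")
}

#' Over-representation of a query target set in a gene-set collection
#'
#' For each set in the collection, counts the overlap with the query and
#' computes the upper-tail hypergeometric p-value against the collection's
#' universe, then adjusts across all sets with [bh_adjust()]. Query members
#' outside the universe are dropped with a message.
#'
#' @param query Character vector of target ids.
#' @param collection A `gene_set_collection`.
#' @return An `enrichment_result` data frame sorted by ascending `p` (ties
#'   broken by `set_id`): columns `set_id`, `k0` (hits), `K` (set size),
#'   `m` (query size), `M_universe`, `p`, `p_adj`, `rank`.
#' @export
enrich <- function(query, collection) {
  stopifnot(inherits(collection, "gene_set_collection"))
  query <- unique(as.character(query))
  outside <- setdiff(query, collection$universe)
  if (length(outside) > 0L) {
    message("enrich: dropped ", length(outside),
            " query target(s) outside the universe")
    query <- setdiff(query, outside)
  }
  if (length(query) == 0L) {
    stop("empty query after intersection with the universe", call. = FALSE)
  }
  m <- length(query)
  M <- length(collection$universe)
  set_ids <- names(collection$sets)
  K <- vapply(collection$sets, function(s) length(s$members), integer(1))
  k0 <- vapply(collection$sets,
               function(s) length(intersect(s$members, query)), integer(1))
  p <- vapply(seq_along(set_ids),
              function(i) hypergeom_upper_tail(k0[i], K[i], m, M),
              numeric(1))
  res <- data.frame(set_id = set_ids, k0 = k0, K = K, m = m,
                    M_universe = M, p = p, p_adj = bh_adjust(p),
                    stringsAsFactors = FALSE)
  res <- res[order(res$p, res$set_id), , drop = FALSE]
  res$rank <- seq_len(nrow(res))
  rownames(res) <- NULL
  structure(res, class = c("enrichment_result", "data.frame"))
}

#' Category-stratified over-representation
#'
#' Runs [enrich()] once per modulator category, with the query of category
#' `c` defined as the union of the targets of all drugs in that category
#' (known edges, plus predicted edges when `include_predicted = TRUE`), and
#' once pooled over all categories.
#'
#' @param catalog A `drug_catalog`.
#' @param interactions An `interaction_set` (may contain predicted edges).
#' @param collection A `gene_set_collection`.
#' @param include_predicted Include `provenance == "predicted"` edges in the
#'   queries.
#' @return Named list of `enrichment_result` tables: `activator`,
#'   `inhibitor`, `dual`, `pooled`. A category with no targets yields an
#'   empty table with a warning.
#' @export
enrich_by_category <- function(catalog, interactions, collection,
                               include_predicted = FALSE) {
  edges <- interactions
  if (!include_predicted) {
    edges <- edges[edges$provenance == "known", , drop = FALSE]
  }
  queries <- lapply(MODULATOR_CATEGORIES, function(ct) {
    ids <- catalog$drug_id[catalog$category == ct]
    unique(edges$target_id[edges$drug_id %in% ids])
  })
  names(queries) <- MODULATOR_CATEGORIES
  out <- lapply(MODULATOR_CATEGORIES, function(ct) {
    q <- intersect(queries[[ct]], collection$universe)
    if (length(q) == 0L) {
      warning("category '", ct, "' has no targets in the universe",
              call. = FALSE)
      return(structure(
        data.frame(set_id = character(), k0 = integer(), K = integer(),
                   m = integer(), M_universe = integer(), p = numeric(),
                   p_adj = numeric(), rank = integer(),
                   stringsAsFactors = FALSE),
        class = c("enrichment_result", "data.frame")))
    }
    enrich(q, collection)
  })
  names(out) <- MODULATOR_CATEGORIES
  out$pooled <- enrich(unique(unlist(queries, use.names = FALSE)), collection)
  out
}

#' Filter an enrichment table at a significance cutoff
#'
#' Two reporting conventions are supported: the raw-p filter
#' (`adjusted = FALSE`, the convention behind "p < 0.05" pathway lists) and
#' the FDR filter on BH-adjusted p-values.
#'
#' @param result An `enrichment_result`.
#' @param alpha Significance cutoff.
#' @param adjusted Filter on `p_adj` instead of raw `p`.
#' @return The filtered rows, order preserved.
#' @export
significant_sets <- function(result, alpha = 0.05, adjusted = FALSE) {
  col <- if (adjusted) "p_adj" else "p"
  result[result[[col]] < alpha, , drop = FALSE]
}
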