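# Bipartite drug-target network summaries: per-drug degree (promiscuity),
# degree histograms per modulator category, frequently targeted proteins,
# and the 7-region overlap partition of the three category target sets.

#' Per-drug degree table
#'
#' The degree of a modulator is the number of targets connected to it in
#' the bipartite drug-target network; the higher the degree, the more
#' promiscuous the modulator. Known and predicted edges are counted
#' separately.
#'
#' @param interactions An `interaction_set`.
#' @param catalog A `drug_catalog`.
#' @return A `degree_table` data frame with one row per catalog drug:
#'   `drug_id`, `category`, `known_degree`, `predicted_degree`,
#'   `total_degree`.
#' @export
modulator_degrees <- function(interactions, catalog) {
  count_layer <- function(prov) {
    e <- interactions[interactions$provenance == prov, , drop = FALSE]
    tab <- table(factor(e$drug_id, levels = catalog$drug_id))
    as.integer(tab)
  }
  known <- count_layer("known")
  predicted <- count_layer("predicted")
  structure(data.frame(drug_id = catalog$drug_id,
                       category = catalog$category,
                       known_degree = known,
                       predicted_degree = predicted,
                       total_degree = known + predicted,
                       stringsAsFactors = FALSE),
            class = c("degree_table", "data.frame"))
}

#' Per-category promiscuity histogram
#'
#' Bins the per-drug degrees into the breakpoints used for promiscuity
#' reporting — by default \{1, 2-4, 5-9, >=10\}, separating single-target
#' drugs from highly promiscuous ones (>= 10 targets).
#'
#' @param degrees A `degree_table` from [modulator_degrees()].
#' @param breaks Increasing integer lower bin edges; the last bin is
#'   open-ended. Degree-0 drugs fall in a separate `"0"` bin when present.
#' @param layer Which degree to bin: `"known"` (default) or `"total"`.
#' @return Data frame with `category`, `bin`, `count`, `pct`; percentages
#'   sum to 100 within each non-empty category.
#' @export
promiscuity_histogram <- function(degrees, breaks = c(1, 2, 5, 10),
                                  layer = c("known", "total")) {
  layer <- match.arg(layer)
  stopifnot(all(diff(breaks) > 0), all(breaks >= 1))
  deg <- degrees[[paste0(layer, "_degree")]]
  edges <- c(-Inf, breaks, Inf)
  labels <- c("0", vapply(seq_along(breaks), function(i) {
    lo <- breaks[i]
    hi <- if (i < length(breaks)) breaks[i + 1] - 1 else Inf
    if (is.infinite(hi)) paste0(">=", lo)
    else if (hi == lo) as.character(lo)
    else paste0(lo, "-", hi)
  }, character(1)))
  bin <- cut(deg, edges, labels = labels, right = FALSE)
  out <- do.call(rbind, lapply(MODULATOR_CATEGORIES, function(ct) {
    counts <- table(bin[degrees$category == ct])
    n <- sum(counts)
    data.frame(category = ct, bin = names(counts),
               count = as.integer(counts),
               pct = if (n > 0) 100 * as.integer(counts) / n else 0,
               stringsAsFactors = FALSE)
  }))
  zero <- out$bin == "0" & out$count == 0L
  out <- out[!zero, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Frequently targeted proteins
#'
#' Targets interacting with at least `min_modulators` known modulators,
#' annotated with per-category known-modulator counts and the number of
#' additional predicted interactions.
#'
#' @param interactions An `interaction_set`.
#' @param catalog A `drug_catalog`.
#' @param min_modulators Known-modulator threshold (default 5).
#' @return Data frame sorted by descending `n_known` (ties by target id):
#'   `target_id`, `n_known`, `n_activator`, `n_inhibitor`, `n_dual`,
#'   `n_predicted`.
#' @export
frequent_targets <- function(interactions, catalog, min_modulators = 5) {
  known <- interactions[interactions$provenance == "known", , drop = FALSE]
  pred <- interactions[interactions$provenance == "predicted", , drop = FALSE]
  cat_of <- stats::setNames(catalog$category, catalog$drug_id)
  targets <- sort(unique(known$target_id))
  counts <- lapply(targets, function(t) {
    drugs <- known$drug_id[known$target_id == t]
    cats <- cat_of[drugs]
    c(n_known = length(drugs),
      n_activator = sum(cats == "activator", na.rm = TRUE),
      n_inhibitor = sum(cats == "inhibitor", na.rm = TRUE),
      n_dual = sum(cats == "dual", na.rm = TRUE),
      n_predicted = sum(pred$target_id == t))
  })
  out <- cbind(data.frame(target_id = targets, stringsAsFactors = FALSE),
               as.data.frame(do.call(rbind, counts)))
  out <- out[out$n_known >= min_modulators, , drop = FALSE]
  out <- out[order(-out$n_known, out$target_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Overlap partition of the category target sets
#'
#' Partitions the distinct targets into the seven disjoint regions of the
#' Venn diagram of the activator / inhibitor / dual target sets (targets of
#' exactly one category, of each pair, and of all three).
#'
#' @param interactions An `interaction_set`.
#' @param catalog A `drug_catalog`.
#' @param include_predicted Count predicted edges too.
#' @return An `overlap_partition` list: `regions` (named integer vector
#'   `activator_only`, `inhibitor_only`, `dual_only`,
#'   `activator_inhibitor`, `activator_dual`, `inhibitor_dual`,
#'   `all_three`) and `union_size`.
#' @export
category_overlap <- function(interactions, catalog,
                             include_predicted = FALSE) {
  edges <- interactions
  if (!include_predicted) {
    edges <- edges[edges$provenance == "known", , drop = FALSE]
  }
  sets <- lapply(MODULATOR_CATEGORIES, function(ct) {
    ids <- catalog$drug_id[catalog$category == ct]
    unique(edges$target_id[edges$drug_id %in% ids])
  })
  names(sets) <- MODULATOR_CATEGORIES
  all_targets <- unique(edges$target_id)
  inA <- all_targets %in% sets$activator
  inI <- all_targets %in% sets$inhibitor
  inD <- all_targets %in% sets$dual
  regions <- c(activator_only = sum(inA & !inI & !inD),
               inhibitor_only = sum(!inA & inI & !inD),
               dual_only = sum(!inA & !inI & inD),
               activator_inhibitor = sum(inA & inI & !inD),
               activator_dual = sum(inA & !inI & inD),
               inhibitor_dual = sum(!inA & inI & inD),
               all_three = sum(inA & inI & inD))
  structure(list(regions = regions, union_size = length(all_targets)),
            class = "overlap_partition")
}

#' @export
print.overlap_partition <- function(x, ...) {
  cat("overlap_partition over", x$union_size, "targets:\n")
  print(x$regions)
  invisible(x)
}
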