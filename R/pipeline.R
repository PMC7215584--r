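# One-call orchestration: load inputs, fit the PMF predictor, compute
# similarities, enrichment (known-only and known+predicted) and network
# summaries, and write every result table plus a plain-text run manifest.

#' Run the full modulator-target analysis pipeline
#'
#' Executes load -> PMF fit -> prediction selection -> similarity ->
#' enrichment (known-only and, when predictions are enabled, known +
#' predicted) -> network summaries, writing TSV outputs and a run manifest
#' under `out_dir`. With a fixed seed the output bundle is byte-identical
#' across runs.
#'
#' @param drugs A `drug_catalog` or path to a catalog TSV.
#' @param interactions An `interaction_set` or path to an edge-list TSV.
#' @param gene_sets A `gene_set_collection`, path to a GMT file, or `NULL`
#'   to skip enrichment.
#' @param out_dir Output directory (created if needed).
#' @param predict Fit the PMF model and emit predictions (`--no-predict`
#'   equivalent: `FALSE`).
#' @param D,epochs,learning_rate,neg_ratio PMF hyperparameters, see
#'   [fit_pmf()].
#' @param threshold,top_k Prediction selection cutoffs, see
#'   [select_predictions()].
#' @param min_modulators Frequent-target threshold, see
#'   [frequent_targets()].
#' @param alpha Significance cutoff recorded for enrichment reporting.
#' @param seed Integer seed for the PMF fit.
#' @return Invisibly, a list with all in-memory results (`catalog`,
#'   `interactions`, `model`, `predictions`, `similarity`, `enrichment`,
#'   `degrees`, `frequent_targets`, `overlap`, `paths`).
#' @export
run_pipeline <- function(drugs, interactions, gene_sets = NULL, out_dir,
                         predict = TRUE, D = 50, epochs = 200,
                         learning_rate = 0.01, neg_ratio = 1,
                         threshold = 0.6, top_k = 40, min_modulators = 5,
                         alpha = 0.05, seed = 1L) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  emit <- function(df, name) {
    path <- file.path(out_dir, paste0(name, ".tsv"))
    utils::write.table(as.data.frame(df), path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
    paths[[name]] <<- path
    path
  }

  catalog <- stage("load", {
    if (is.character(drugs)) load_drug_catalog(drugs) else drugs
  })
  known <- stage("load", {
    if (is.character(interactions)) load_interactions(interactions, catalog)
    else interactions
  })
  collection <- stage("load", {
    if (is.character(gene_sets)) load_gene_sets(gene_sets) else gene_sets
  })

  model <- NULL
  predictions <- NULL
  if (predict) {
    model <- stage("fit_pmf", {
      bm <- build_matrix(known, catalog)
      fit_pmf(bm, D = D, epochs = epochs, learning_rate = learning_rate,
              neg_ratio = neg_ratio, seed = seed)
    })
    predictions <- stage("select_predictions", {
      select_predictions(score_pairs(model), known,
                         threshold = threshold, top_k = top_k)
    })
    emit(predictions, "predictions")
  }
  all_edges <- combine_interactions(known, predictions)

  similarity <- stage("similarity", {
    out <- list()
    if (any(!is.na(catalog$fingerprint))) {
      out$structural <- similarity_matrix(catalog, kind = "structural_tanimoto")
    }
    out$functional <- similarity_matrix(catalog, known,
                                        kind = "functional_cosine")
    out
  })
  for (nm in names(similarity)) {
    sim <- similarity[[nm]]
    df <- data.frame(drug_id = rownames(sim),
                     as.data.frame(unclass(sim), check.names = FALSE),
                     check.names = FALSE, stringsAsFactors = FALSE)
    emit(df, paste0("similarity_", nm))
  }

  enrichment <- NULL
  if (!is.null(collection)) {
    enrichment <- stage("enrichment", {
      out <- list(known = enrich_by_category(catalog, known, collection,
                                             include_predicted = FALSE))
      if (predict) {
        out$with_predicted <- enrich_by_category(catalog, all_edges,
                                                 collection,
                                                 include_predicted = TRUE)
      }
      out
    })
    for (layer in names(enrichment)) {
      for (ct in names(enrichment[[layer]])) {
        emit(enrichment[[layer]][[ct]],
             paste0("enrichment_", layer, "_", ct))
      }
    }
  }

  degrees <- stage("summaries", modulator_degrees(all_edges, catalog))
  emit(degrees, "degrees")
  emit(promiscuity_histogram(degrees), "promiscuity_histogram")
  fts <- stage("summaries",
               frequent_targets(all_edges, catalog,
                                min_modulators = min_modulators))
  emit(fts, "frequent_targets")
  overlap <- stage("summaries", category_overlap(all_edges, catalog))
  emit(data.frame(region = c(names(overlap$regions), "union"),
                  n_targets = c(unname(overlap$regions),
                                overlap$union_size),
                  stringsAsFactors = FALSE),
       "category_overlap")

  manifest <- c(
    "autoqsp run manifest",
    paste0("drugs: ", nrow(catalog)),
    paste0("known_edges: ", sum(known$provenance == "known")),
    paste0("gene_sets: ", if (is.null(collection)) 0L
           else length(collection$sets)),
    paste0("predict: ", predict),
    paste0("D: ", D),
    paste0("epochs: ", epochs),
    paste0("learning_rate: ", learning_rate),
    paste0("neg_ratio: ", neg_ratio),
    paste0("confidence_threshold: ", threshold),
    paste0("top_k: ", top_k),
    paste0("frequent_target_min_modulators: ", min_modulators),
    paste0("alpha: ", alpha),
    paste0("seed: ", seed),
    paste0("outputs: ", paste(sort(names(paths)), collapse = ", ")))
  writeLines(manifest, file.path(out_dir, "manifest.txt"))
  paths[["manifest"]] <- file.path(out_dir, "manifest.txt")

  invisible(list(catalog = catalog, interactions = all_edges, model = model,
                 predictions = predictions, similarity = similarity,
                 enrichment = enrichment, degrees = degrees,
                 frequent_targets = fts, overlap = overlap, paths = paths))
}
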