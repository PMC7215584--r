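# Shared fixture builders; everything is generated in code at test time.

write_catalog_file <- function(lines, path = tempfile(fileext = ".tsv")) {
  writeLines(c("drug_id\tname\tcategory", lines), path)
  path
}

write_edges_file <- function(lines, path = tempfile(fileext = ".tsv")) {
  writeLines(c("drug_id\ttarget_id", lines), path)
  path
}

# tiny catalog + edge list with known degree structure
tiny_catalog <- function() {
  new_tiny <- data.frame(
    drug_id = c("a1", "a2", "i1", "d1"),
    name = paste("drug", 1:4),
    category = c("activator", "activator", "inhibitor", "dual"),
    smiles = NA_character_,
    fingerprint = c("1100", "1010", "0110", "0011"),
    stringsAsFactors = FALSE)
  autoqsp:::new_drug_catalog(new_tiny)
}

tiny_interactions <- function() {
  autoqsp:::new_interaction_set(
    drug_id = c("a1", "a1", "a2", "i1", "i1", "d1"),
    target_id = c("t1", "t2", "t1", "t2", "t3", "t1"),
    provenance = rep("known", 6),
    confidence = rep(1, 6))
}

# a binary matrix whose thresholded outer product is exactly rank 1
rank1_matrix <- function() {
  u <- c(0.1, 0.1, 0.1, 2, 2, 2)
  v <- c(0.1, 0.1, 0.1, 0.1, 2, 2, 2, 2)
  R <- (outer(u, v) > stats::median(outer(u, v))) * 1
  dimnames(R) <- list(paste0("d", 1:6), paste0("t", 1:8))
  R
}

matrix_to_inputs <- function(R) {
  edges <- which(R == 1, arr.ind = TRUE)
  ints <- autoqsp:::new_interaction_set(
    rownames(R)[edges[, 1]], colnames(R)[edges[, 2]],
    rep("known", nrow(edges)), rep(1, nrow(edges)))
  negs <- which(R == 0, arr.ind = TRUE)
  negdf <- data.frame(drug_id = rownames(R)[negs[, 1]],
                      target_id = colnames(R)[negs[, 2]],
                      stringsAsFactors = FALSE)
  list(interactions = ints, negatives = negdf)
}

# hand-built latent model producing prescribed raw scores for one target
score_model <- function(scores) {
  ids <- sprintf("d%02d", seq_along(scores))
  structure(list(U = matrix(scores, nrow = 1, dimnames = list(NULL, ids)),
                 V = matrix(1, nrow = 1, dimnames = list(NULL, "t1")),
                 D = 1L, lambda_u = 0, lambda_v = 0,
                 row_index = ids, col_index = "t1",
                 known_mask = matrix(FALSE, length(scores), 1),
                 training_log = 0, seed = 1L),
            class = "latent_model")
}

# small standard synthetic world used across tests
small_world <- function(seed = 5, planted = list()) {
  generate_world(world_config(
    n_drugs = 80, n_targets = 160, latent_dim = 4, density = 0.02,
    n_pathways = 25, fingerprint_length = 64, planted = planted,
    seed = seed))
}

# the study-condition world for enrichment-recovery experiments
enrichment_world_config <- function(seed, planted = list()) {
  world_config(n_drugs = 300, n_targets = 800, latent_dim = 5,
               density = 0.02, n_pathways = 50,
               pathway_prob_range = c(0.08, 0.12),
               planted = planted, fingerprint_length = 32, seed = seed)
}
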