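# catalog + edge list matching the published count arithmetic for a curated
# modulator set: 174/31/20 drugs with 1339/389/103 known interactions,
# 31/3/3 drugs at degree >= 10, one 303-degree outlier inhibitor
count_matched_inputs <- function() {
  degs <- c(
    stats::setNames(c(145, 124, 78, 48, rep(12, 27), rep(5, 48), rep(4, 95)),
                    sprintf("act%03d", 1:174)),
    stats::setNames(c(303, 11, 10, rep(3, 9), rep(2, 19)),
                    sprintf("inh%03d", 1:31)),
    stats::setNames(c(12, 10, 10, rep(5, 3), rep(4, 14)),
                    sprintf("dua%03d", 1:20)))
  catalog <- autoqsp:::new_drug_catalog(data.frame(
    drug_id = names(degs),
    name = names(degs),
    category = rep(c("activator", "inhibitor", "dual"), c(174, 31, 20)),
    smiles = NA_character_, fingerprint = NA_character_,
    stringsAsFactors = FALSE))
  drug <- rep(names(degs), degs)
  target <- unlist(lapply(degs, function(d) sprintf("T%03d", seq_len(d))),
                   use.names = FALSE)
  ints <- autoqsp:::new_interaction_set(drug, target,
                                        rep("known", length(drug)),
                                        rep(1, length(drug)))
  list(catalog = catalog, interactions = ints)
}

test_that("degree table reproduces the curated-catalog count arithmetic", {
  inp <- count_matched_inputs()
  deg <- modulator_degrees(inp$interactions, inp$catalog)
  expect_equal(sum(deg$known_degree), 1831)
  act <- deg[deg$category == "activator", ]
  inh <- deg[deg$category == "inhibitor", ]
  expect_equal(sum(act$known_degree), 1339)
  expect_equal(sum(inh$known_degree), 389)
  expect_equal(round(mean(act$known_degree), 1), 7.7)
  # inhibitor mean excluding the single most promiscuous outlier
  inh_sorted <- sort(inh$known_degree, decreasing = TRUE)
  expect_equal(round(mean(inh_sorted[-1]), 1), 2.9)
})

test_that("degree sums are conserved on both sides of the bipartite graph", {
  w <- small_world(seed = 61)
  deg <- modulator_degrees(w$interactions, w$catalog)
  expect_equal(sum(deg$known_degree), nrow(w$interactions))
  target_side <- table(w$interactions$target_id)
  expect_equal(sum(target_side), nrow(w$interactions))
  # drugs without edges have degree zero
  lonely <- setdiff(w$catalog$drug_id, w$interactions$drug_id)
  expect_true(all(deg$known_degree[deg$drug_id %in% lonely] == 0))
})

test_that("promiscuity histogram reports the published top-bin shares", {
  inp <- count_matched_inputs()
  deg <- modulator_degrees(inp$interactions, inp$catalog)
  hist <- promiscuity_histogram(deg)
  top <- hist[hist$bin == ">=10", ]
  expect_equal(round(top$pct[top$category == "activator"], 1), 17.8)
  expect_equal(round(top$pct[top$category == "inhibitor"], 1), 9.7)
  expect_equal(round(top$pct[top$category == "dual"], 1), 15.0)
  for (ct in MODULATOR_CATEGORIES) {
    expect_equal(sum(hist$pct[hist$category == ct]), 100, tolerance = 1e-9)
  }

  # degenerate case: every drug has exactly one target
  ctl <- tiny_catalog()
  one <- autoqsp:::new_interaction_set(ctl$drug_id, paste0("t", 1:4),
                                       rep("known", 4), rep(1, 4))
  h1 <- promiscuity_histogram(modulator_degrees(one, ctl))
  expect_true(all(h1$pct[h1$bin == "1"] == 100))
})

test_that("frequent-target detection applies the known-modulator threshold", {
  ctl <- autoqsp:::new_drug_catalog(data.frame(
    drug_id = sprintf("d%02d", 1:9), name = "x",
    category = rep(c("activator", "inhibitor", "dual"), each = 3),
    smiles = NA_character_, fingerprint = NA_character_,
    stringsAsFactors = FALSE))
  # tA: 5 known modulators; tB: 4; tC: 6
  edges <- rbind(
    data.frame(drug_id = sprintf("d%02d", 1:5), target_id = "tA"),
    data.frame(drug_id = sprintf("d%02d", 1:4), target_id = "tB"),
    data.frame(drug_id = sprintf("d%02d", c(1:4, 7, 8)), target_id = "tC"))
  ints <- autoqsp:::new_interaction_set(edges$drug_id, edges$target_id,
                                        rep("known", nrow(edges)),
                                        rep(1, nrow(edges)))
  ft <- frequent_targets(ints, ctl, min_modulators = 5)
  expect_equal(ft$target_id, c("tC", "tA"))
  expect_equal(ft$n_known, c(6, 5))
  expect_equal(ft$n_activator[ft$target_id == "tC"], 3)
  expect_equal(ft$n_inhibitor[ft$target_id == "tC"], 1)
  expect_equal(ft$n_dual[ft$target_id == "tC"], 2)
  # threshold 1 returns every targeted protein
  expect_equal(nrow(frequent_targets(ints, ctl, min_modulators = 1)), 3)
  # predicted edges counted separately, not towards the threshold
  with_pred <- combine_interactions(
    ints, data.frame(drug_id = "d09", target_id = "tB", confidence = 0.9))
  ft2 <- frequent_targets(with_pred, ctl, min_modulators = 5)
  expect_false("tB" %in% ft2$target_id)
  expect_equal(ft2$n_predicted, c(0, 0))
})

test_that("category overlap partition agrees with set arithmetic", {
  ctl <- tiny_catalog()
  ints <- tiny_interactions()
  ov <- category_overlap(ints, ctl)
  # t1: activators + dual; t2: activators + inhibitor; t3: inhibitor only
  expect_equal(unname(ov$regions["activator_dual"]), 1)
  expect_equal(unname(ov$regions["activator_inhibitor"]), 1)
  expect_equal(unname(ov$regions["inhibitor_only"]), 1)
  expect_equal(sum(ov$regions), ov$union_size)

  # random world against an independent brute-force set computation
  w <- small_world(seed = 71)
  ov2 <- category_overlap(w$interactions, w$catalog)
  sets <- lapply(MODULATOR_CATEGORIES, function(ct) {
    ids <- w$catalog$drug_id[w$catalog$category == ct]
    unique(w$interactions$target_id[w$interactions$drug_id %in% ids])
  })
  names(sets) <- MODULATOR_CATEGORIES
  A <- sets$activator; I <- sets$inhibitor; D <- sets$dual
  expect_equal(unname(ov2$regions["all_three"]),
               length(intersect(intersect(A, I), D)))
  expect_equal(unname(ov2$regions["activator_only"]),
               length(setdiff(setdiff(A, I), D)))
  expect_equal(unname(ov2$regions["inhibitor_dual"]),
               length(setdiff(intersect(I, D), A)))
  expect_equal(sum(ov2$regions), length(union(union(A, I), D)))
  expect_equal(ov2$union_size, length(unique(w$interactions$target_id)))

  # disjoint categories leave all intersection regions empty
  disj <- autoqsp:::new_interaction_set(
    c("a1", "i1", "d1"), c("t1", "t2", "t3"),
    rep("known", 3), rep(1, 3))
  ov3 <- category_overlap(disj, ctl)
  expect_true(all(ov3$regions[c("activator_inhibitor", "activator_dual",
                                "inhibitor_dual", "all_three")] == 0))
})
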