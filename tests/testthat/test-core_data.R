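test_that("drug catalog parsing validates categories and ids", {
  path <- write_catalog_file(c("d1\tdrug one\tactivator",
                               "d2\tdrug two\tinhibitor",
                               "d3\tdrug three\tdual"))
  cat3 <- load_drug_catalog(path)
  expect_s3_class(cat3, "drug_catalog")
  expect_equal(cat3$drug_id, c("d1", "d2", "d3"))
  expect_equal(cat3$category, c("activator", "inhibitor", "dual"))

  bad <- write_catalog_file(c("d1\tdrug one\tactivator",
                              "d2\tdrug two\tenhancer"))
  expect_error(load_drug_catalog(bad), "row 2")
  dup <- write_catalog_file(c("d1\ta\tactivator", "d1\tb\tdual"))
  expect_error(load_drug_catalog(dup), "duplicate drug_id")

  # comment lines and optional columns
  path2 <- tempfile(fileext = ".tsv")
  writeLines(c("# a comment", "drug_id\tname\tcategory\tfingerprint",
               "d1\tx\tactivator\t1010", "d2\ty\tdual\t0110"), path2)
  cat2 <- load_drug_catalog(path2)
  expect_identical(attr(cat2, "fingerprint_length"), 4L)
})

test_that("a catalog with the curated category split reports 225 drugs", {
  lines <- c(sprintf("act%03d\ta\tactivator", 1:174),
             sprintf("inh%03d\ti\tinhibitor", 1:31),
             sprintf("dua%03d\td\tdual", 1:20))
  ctl <- load_drug_catalog(write_catalog_file(lines))
  expect_equal(nrow(ctl), 225)
  expect_equal(as.vector(table(ctl$category)[MODULATOR_CATEGORIES]),
               c(174, 31, 20))
})

test_that("interaction loading deduplicates and resolves ids", {
  ctl <- tiny_catalog()
  path <- write_edges_file(c("a1\tt1", "a1\tt2", "a1\tt1", "i1\tt3"))
  expect_message(ints <- load_interactions(path, ctl), "1 duplicate")
  expect_equal(nrow(ints), 3)
  expect_true(all(ints$provenance == "known"))
  expect_true(all(ints$confidence == 1))

  empty <- write_edges_file(character(0))
  expect_equal(nrow(load_interactions(empty, ctl)), 0)

  bad <- write_edges_file(c("zz\tt1"))
  expect_error(load_interactions(bad, ctl), "zz")
  badt <- write_edges_file(c("a1\tt9"))
  expect_error(load_interactions(badt, ctl, targets = c("t1", "t2")), "t9")
})

test_that("per-category edge totals sum to the catalog-wide edge count", {
  # mirrors the bookkeeping 1339 + 389 + 103 = 1831 on a generated world
  w <- small_world(seed = 7)
  per_cat <- vapply(MODULATOR_CATEGORIES, function(ct) {
    ids <- w$catalog$drug_id[w$catalog$category == ct]
    sum(w$interactions$drug_id %in% ids)
  }, numeric(1))
  expect_equal(sum(per_cat), nrow(w$interactions))
})

test_that("GMT parsing builds a validated collection", {
  path <- tempfile(fileext = ".gmt")
  writeLines(c("s1\tfirst set\tt1\tt2\tt3",
               "s2\tsecond set\tt2\tt4"), path)
  gs <- load_gene_sets(path)
  expect_s3_class(gs, "gene_set_collection")
  expect_equal(length(gs$sets), 2)
  expect_equal(gs$universe, c("t1", "t2", "t3", "t4"))

  expect_message(
    gs2 <- load_gene_sets(path, universe = c("t1", "t2", "t3")),
    "dropped 1 member")
  expect_equal(gs2$sets$s2$members, "t2")

  bad <- tempfile(fileext = ".gmt")
  writeLines(c("s1\tdesc\tt1", "just_one_field"), bad)
  expect_error(load_gene_sets(bad), "line 2")
})

test_that("build_matrix places exactly the known edges", {
  ints <- autoqsp:::new_interaction_set(
    c("d1", "d2"), c("t1", "t3"), rep("known", 2), rep(1, 2))
  bm <- build_matrix(ints, c("d1", "d2"), c("t1", "t2", "t3"))
  expect_equal(sum(bm$values), 2)
  expect_equal(bm$values["d1", "t1"], 1)
  expect_equal(bm$values["d2", "t3"], 1)
  expect_equal(unname(rowSums(bm$values)), c(1, 1))

  # row sums equal per-drug degrees on a larger world
  w <- small_world(seed = 9)
  bmw <- build_matrix(w$interactions, w$catalog, w$targets$target_id)
  expect_equal(sum(bmw$values), nrow(w$interactions))
  deg <- modulator_degrees(w$interactions, w$catalog)
  expect_equal(unname(rowSums(bmw$values)), deg$known_degree)

  empty <- autoqsp:::new_interaction_set(character(0), character(0),
                                         character(0), numeric(0))
  expect_error(build_matrix(empty, "d1"), "nothing to factorize")
})

test_that("catalog, edge list and GMT files round-trip exactly", {
  w <- small_world(seed = 11)
  dir <- tempfile()
  paths <- write_world(w, dir)

  cat2 <- load_drug_catalog(paths[["catalog"]])
  expect_equal(as.data.frame(cat2), as.data.frame(w$catalog))
  ints2 <- load_interactions(paths[["edges"]], cat2)
  expect_equal(ints2$drug_id, w$interactions$drug_id)
  expect_equal(ints2$target_id, w$interactions$target_id)
  gs2 <- load_gene_sets(paths[["pathways"]],
                        universe = readLines(paths[["universe"]]))
  expect_equal(names(gs2$sets), names(w$pathways$sets))
  for (id in names(gs2$sets)) {
    expect_equal(gs2$sets[[id]]$members, w$pathways$sets[[id]]$members)
  }
  expect_equal(gs2$universe, w$pathways$universe)
})
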