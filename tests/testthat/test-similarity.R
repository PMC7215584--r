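# set-enumeration oracles, written independently of the vectorised ops
oracle_tanimoto <- function(a, b) {
  A <- which(a == 1); B <- which(b == 1)
  length(intersect(A, B)) / length(union(A, B))
}
oracle_cosine_dist <- function(a, b) {
  A <- which(a == 1); B <- which(b == 1)
  1 - length(intersect(A, B)) / sqrt(length(A) * length(B))
}

test_that("scalar Tanimoto matches hand counts and the set oracle", {
  expect_equal(tanimoto_similarity(c(1, 1, 0, 0), c(1, 0, 1, 0)), 1 / 3)
  expect_equal(tanimoto_similarity("1100", "1010"), 1 / 3)
  expect_equal(tanimoto_similarity(c(1, 0, 1), c(1, 0, 1)), 1)
  expect_equal(tanimoto_similarity(c(1, 1, 0, 0), c(0, 0, 1, 1)), 0)
  expect_error(tanimoto_similarity(c(0, 0), c(1, 0)), "all-zero")
  expect_error(tanimoto_similarity(c(1, 0), c(1, 0, 1)), "equal length")

  set.seed(42)
  for (i in 1:1000) {
    len <- sample(3:10, 1)
    a <- stats::rbinom(len, 1, 0.5); b <- stats::rbinom(len, 1, 0.5)
    if (!any(a) || !any(b)) next
    expect_equal(tanimoto_similarity(a, b), oracle_tanimoto(a, b))
  }
})

test_that("scalar cosine distance matches the formula and the set oracle", {
  expect_equal(interaction_cosine_distance(c(1, 1, 0), c(1, 0, 1)), 0.5)
  expect_equal(interaction_cosine_distance(c(1, 0, 1), c(1, 0, 1)), 0)
  expect_equal(interaction_cosine_distance(c(1, 0), c(0, 1)), 1)
  expect_error(interaction_cosine_distance(c(0, 0), c(1, 0)), "no targets")

  set.seed(43)
  for (i in 1:1000) {
    len <- sample(3:10, 1)
    a <- stats::rbinom(len, 1, 0.5); b <- stats::rbinom(len, 1, 0.5)
    if (!any(a) || !any(b)) next
    expect_equal(interaction_cosine_distance(a, b),
                 oracle_cosine_dist(a, b))
  }
})

test_that("similarity matrices compose the scalar ops symmetrically", {
  ctl <- tiny_catalog()
  sim <- similarity_matrix(ctl, kind = "structural_tanimoto")
  expect_equal(dim(sim), c(4, 4))
  for (i in 1:4) for (j in 1:4) {
    expect_equal(sim[i, j],
                 tanimoto_similarity(ctl$fingerprint[i], ctl$fingerprint[j]))
  }
  expect_equal(unclass(sim), t(unclass(sim)), ignore_attr = TRUE)
  expect_equal(unname(diag(sim)), rep(1, 4))
  expect_true(all(sim >= 0 & sim <= 1))

  ints <- tiny_interactions()
  fsim <- similarity_matrix(ctl, ints, kind = "functional_cosine")
  # functional similarity = 1 - cosine distance of 0/1 target profiles
  prof <- function(d) as.integer(c("t1", "t2", "t3") %in%
                                   ints$target_id[ints$drug_id == d])
  expect_equal(fsim["a1", "i1"],
               1 - interaction_cosine_distance(prof("a1"), prof("i1")))
  expect_equal(unname(diag(fsim)), rep(1, 4))
})

test_that("row order permutation permutes the matrix consistently", {
  ctl <- tiny_catalog()
  sim <- similarity_matrix(ctl, kind = "structural_tanimoto")
  perm <- c(3, 1, 4, 2)
  ctl_perm <- autoqsp:::new_drug_catalog(as.data.frame(ctl)[perm, ])
  sim_perm <- similarity_matrix(ctl_perm, kind = "structural_tanimoto")
  expect_equal(unclass(sim_perm),
               unclass(sim)[perm, perm], ignore_attr = TRUE)
})

test_that("drugs sharing a latent class are more similar than others", {
  w <- small_world(seed = 41)
  sim <- similarity_matrix(w$catalog, kind = "structural_tanimoto")
  # recover each drug's latent class from the ground-truth factors
  U <- w$U_true
  cl <- stats::cutree(stats::hclust(stats::dist(t(U))),
                      k = w$config$n_drug_classes)
  same <- outer(cl, cl, "==") & upper.tri(sim)
  diff <- (!outer(cl, cl, "==")) & upper.tri(sim)
  expect_gt(mean(sim[same]), mean(sim[diff]))
})

test_that("heatmap order keeps well-separated blocks contiguous", {
  ids <- c(paste0("x", 1:4), paste0("y", 1:4))
  vals <- matrix(0.05, 8, 8, dimnames = list(ids, ids))
  vals[1:4, 1:4] <- 0.9
  vals[5:8, 5:8] <- 0.9
  diag(vals) <- 1
  sim <- structure(vals, kind = "structural_tanimoto",
                   class = c("similarity_matrix", "matrix"))
  ord <- heatmap_order(sim)
  grp <- substr(ord, 1, 1)
  expect_equal(length(rle(grp)$lengths), 2) # each block contiguous
  expect_identical(ord, heatmap_order(sim)) # deterministic
  # singleton input
  single <- structure(matrix(1, 1, 1, dimnames = list("only", "only")),
                      class = c("similarity_matrix", "matrix"))
  expect_equal(heatmap_order(single), "only")
})

test_that("SMILES-derived fingerprints feed the Tanimoto pipeline", {
  skip_if_not_installed("ChemmineOB")
  fps <- fingerprint_from_smiles(c("c1ccccc1C(=O)O", "c1ccccc1C(=O)OC",
                                   "CCCCCCCC"))
  expect_true(all(nchar(fps) == 1024))
  expect_true(all(grepl("^[01]+$", fps)))
  # aromatic acid vs its ester share far more substructure than vs octane
  expect_gt(tanimoto_similarity(fps[1], fps[2]),
            tanimoto_similarity(fps[1], fps[3]))
})
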