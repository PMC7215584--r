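# Synthetic DrugBank-like worlds with known ground truth. Drugs and targets
# carry low-rank latent factors drawn around class/family prototypes (drug
# catalogs cluster into chemotype/mechanism classes and targets into protein
# families; interaction profiles inherit that block structure); observed
# interactions follow a temperature-scaled logistic link on the latent inner
# products, with an intercept calibrated to the requested density;
# fingerprints are random logistic projections of the drug factors so
# structurally similar drugs share interaction profiles; pathway sets can
# carry planted enrichment for the targets of one modulator category.

derive_seeds <- function(seed, n = 5L) {
  # one documented sub-stream per stage so stages can be re-sampled
  # independently of each other
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  sample.int(.Machine$integer.max - 1L, n)
}

#' Configuration of a synthetic drug-target world
#'
#' Bundles and validates the parameters of [generate_world()]. Defaults
#' emulate a curated modulator catalog of 225 drugs in the proportions
#' 174 activators : 31 inhibitors : 20 dual-modulators with 993 candidate
#' targets, an interaction density of about 0.8% (the density of a curated
#' modulator-target subnetwork; full-database worlds are closer to 0.1% and
#' can be requested explicitly), and 294 pathway-like gene sets.
#'
#' @param n_drugs,n_targets World dimensions.
#' @param latent_dim True latent dimension of the generative factors.
#' @param density Expected fraction of drug-target pairs observed as known
#'   positives; must lie in (0, 0.5).
#' @param category_proportions Length-3 numeric vector of activator /
#'   inhibitor / dual proportions, summing to 1.
#' @param n_pathways Number of gene sets in the synthetic collection.
#' @param pathway_prob_range Range of per-set base membership probabilities;
#'   each set draws its own base probability uniformly from this range.
#' @param planted List of enrichment plants, each a
#'   `list(pathway = <index>, category = <modulator category>,
#'   odds = <multiplier> )`: members of the planted set are sampled with the
#'   base probability multiplied by `odds` for targets interacting with
#'   drugs of that category.
#' @param fingerprint_length Number of fingerprint bits per drug.
#' @param noise_sd Standard deviation of the Gaussian noise added to latent
#'   scores before the logistic observation link.
#' @param n_drug_classes,n_target_families Number of latent prototype
#'   vectors for drugs and targets. Drug factors are drawn around class
#'   prototypes and target factors around family prototypes, giving the
#'   interaction propensities the block structure of real chemogenomics
#'   matrices (chemotype classes x protein families); factors remain
#'   zero-mean with unit scale marginally.
#' @param class_sd Within-class latent spread relative to the prototype
#'   scale (before normalisation to unit marginal scale).
#' @param link_scale Temperature of the logistic observation link: the pair
#'   inclusion probability is `sigmoid((score + noise) / link_scale + b)`
#'   with `b` calibrated to the density. Smaller values sharpen the
#'   affinity threshold separating detected from undetected interactions.
#' @param seed Integer seed; every artifact of the world is a pure function
#'   of the configuration including this seed.
#' @return A validated `world_config` list.
#' @export
world_config <- function(n_drugs = 225, n_targets = 993, latent_dim = 5,
                         density = 0.008,
                         category_proportions = c(174, 31, 20) / 225,
                         n_pathways = 294,
                         pathway_prob_range = c(0.03, 0.08),
                         planted = list(),
                         fingerprint_length = 2048,
                         noise_sd = 0.1,
                         n_drug_classes = 6, n_target_families = 8,
                         class_sd = 0.1, link_scale = 0.25, seed = 1L) {
  stopifnot(n_drugs >= 2, n_targets >= 2, latent_dim >= 1,
            length(category_proportions) == 3L,
            all(category_proportions >= 0),
            n_pathways >= 0, fingerprint_length >= 1, noise_sd >= 0,
            n_drug_classes >= 1, n_target_families >= 1,
            class_sd >= 0, link_scale > 0,
            length(pathway_prob_range) == 2L,
            pathway_prob_range[1] > 0, pathway_prob_range[2] < 1,
            pathway_prob_range[1] <= pathway_prob_range[2])
  if (!(density > 0 && density < 0.5)) {
    stop("density must lie in (0, 0.5)", call. = FALSE)
  }
  if (abs(sum(category_proportions) - 1) > 1e-9) {
    stop("category_proportions must sum to 1", call. = FALSE)
  }
  for (p in planted) {
    if (!all(c("pathway", "category", "odds") %in% names(p))) {
      stop("each plant needs fields pathway, category, odds", call. = FALSE)
    }
    if (!p$category %in% MODULATOR_CATEGORIES) {
      stop("unknown plant category: ", p$category, call. = FALSE)
    }
    if (p$pathway < 1 || p$pathway > n_pathways) {
      stop("plant pathway index out of range: ", p$pathway, call. = FALSE)
    }
    if (p$odds < 1) stop("plant odds multiplier must be >= 1", call. = FALSE)
  }
  structure(list(n_drugs = as.integer(n_drugs),
                 n_targets = as.integer(n_targets),
                 latent_dim = as.integer(latent_dim),
                 density = density,
                 category_proportions = category_proportions,
                 n_pathways = as.integer(n_pathways),
                 pathway_prob_range = pathway_prob_range,
                 planted = planted,
                 fingerprint_length = as.integer(fingerprint_length),
                 noise_sd = noise_sd,
                 n_drug_classes = as.integer(n_drug_classes),
                 n_target_families = as.integer(n_target_families),
                 class_sd = class_sd, link_scale = link_scale,
                 seed = as.integer(seed)),
            class = "world_config")
}

true_scores <- function(U, V) {
  crossprod(U, V)
}

#' Generate a synthetic drug-target world with known ground truth
#'
#' Draws per-world class/family prototype vectors and then i.i.d. latent
#' factors around them (zero-mean, unit scale marginally) for drugs and
#' targets, assigns modulator categories by the configured proportions,
#' samples a known-interaction edge set through the density-calibrated
#' logistic link on the latent inner products, generates binary
#' fingerprints whose bits are logistic projections of the drug factors, and
#' builds a pathway-like gene-set collection over the targets, optionally
#' with planted over-representation for the targets of one category.
#'
#' @param config A [world_config()].
#' @return A `ground_truth` list: `config`, `U_true` (D x N), `V_true`
#'   (D x M), `catalog` (a `drug_catalog` with fingerprints), `targets`
#'   (target catalog data frame), `interactions` (the world's known edges),
#'   `pathways` (a `gene_set_collection`) and `planted_sets` (data frame
#'   recording which sets were enriched for which category).
#' @export
generate_world <- function(config) {
  stopifnot(inherits(config, "world_config"))
  seeds <- derive_seeds(config$seed, 5L)
  N <- config$n_drugs; M <- config$n_targets; D <- config$latent_dim

  set.seed(seeds[1L])
  draw_factors <- function(n, k) {
    prototypes <- matrix(stats::rnorm(D * k), D, k)
    members <- sample.int(k, n, replace = TRUE)
    noise <- matrix(stats::rnorm(D * n, 0, config$class_sd), D, n)
    (prototypes[, members, drop = FALSE] + noise) /
      sqrt(1 + config$class_sd^2)
  }
  U <- draw_factors(N, config$n_drug_classes)
  V <- draw_factors(M, config$n_target_families)

  set.seed(seeds[2L])
  categories <- sample(MODULATOR_CATEGORIES, N, replace = TRUE,
                       prob = config$category_proportions)
  drug_ids <- sprintf("D%04d", seq_len(N))
  target_ids <- sprintf("T%04d", seq_len(M))
  colnames(U) <- drug_ids
  colnames(V) <- target_ids

  truth <- list(config = config, U_true = U, V_true = V,
                drug_ids = drug_ids, target_ids = target_ids)
  interactions <- sample_observed_interactions(truth, config$density,
                                               seed = seeds[3L])

  set.seed(seeds[4L])
  W <- matrix(stats::rnorm(config$fingerprint_length * D), ncol = D)
  bit_prob <- stats::plogis((W %*% U) / sqrt(D))
  bits <- matrix(stats::rbinom(length(bit_prob), 1L, bit_prob),
                 nrow = config$fingerprint_length)
  fingerprints <- apply(bits, 2L, paste, collapse = "")

  catalog <- new_drug_catalog(data.frame(
    drug_id = drug_ids,
    name = paste("synthetic drug", seq_len(N)),
    category = categories,
    smiles = NA_character_,
    fingerprint = fingerprints,
    stringsAsFactors = FALSE))
  targets <- data.frame(target_id = target_ids, family = NA_character_,
                        stringsAsFactors = FALSE)

  set.seed(seeds[5L])
  pathways <- NULL
  planted_sets <- data.frame(set_id = character(), category = character(),
                             odds = numeric(), stringsAsFactors = FALSE)
  if (config$n_pathways > 0L) {
    set_ids <- sprintf("PW%03d", seq_len(config$n_pathways))
    base_prob <- stats::runif(config$n_pathways,
                              config$pathway_prob_range[1],
                              config$pathway_prob_range[2])
    # targets reached by each category in this world's known edge set
    cat_targets <- lapply(MODULATOR_CATEGORIES, function(ct) {
      ids <- drug_ids[categories == ct]
      unique(interactions$target_id[interactions$drug_id %in% ids])
    })
    names(cat_targets) <- MODULATOR_CATEGORIES
    plant_by_set <- vector("list", config$n_pathways)
    for (p in config$planted) {
      if (base_prob[p$pathway] * p$odds > 1) {
        stop("infeasible plant: odds multiplier ", p$odds,
             " pushes membership probability above 1 for pathway ",
             p$pathway, call. = FALSE)
      }
      plant_by_set[[p$pathway]] <- p
      planted_sets <- rbind(planted_sets, data.frame(
        set_id = set_ids[p$pathway], category = p$category, odds = p$odds,
        stringsAsFactors = FALSE))
    }
    sets <- vector("list", config$n_pathways)
    for (s in seq_len(config$n_pathways)) {
      prob <- rep(base_prob[s], M)
      p <- plant_by_set[[s]]
      if (!is.null(p)) {
        hit <- target_ids %in% cat_targets[[p$category]]
        prob[hit] <- prob[hit] * p$odds
      }
      members <- target_ids[stats::runif(M) < prob]
      sets[[s]] <- list(description = if (is.null(p)) "background set"
                        else paste0("planted:", p$category),
                        members = members)
    }
    names(sets) <- set_ids
    keep <- vapply(sets, function(s) length(s$members) > 0L, logical(1))
    pathways <- new_gene_set_collection(sets[keep], universe = target_ids)
  }

  structure(list(config = config, U_true = U, V_true = V,
                 drug_ids = drug_ids, target_ids = target_ids,
                 catalog = catalog, targets = targets,
                 interactions = interactions,
                 pathways = pathways, planted_sets = planted_sets),
            class = "ground_truth")
}

#' @export
print.ground_truth <- function(x, ...) {
  cat("ground_truth world:", x$config$n_drugs, "drugs x",
      x$config$n_targets, "targets, latent dim", x$config$latent_dim, "\n")
  cat("  known edges:", nrow(x$interactions), "; pathways:",
      if (is.null(x$pathways)) 0L else length(x$pathways$sets),
      "; plants:", nrow(x$planted_sets), "\n")
  invisible(x)
}

#' Sample an observed known-interaction edge set from a world
#'
#' Pair `(i, j)` is included as a known positive with probability
#' `sigmoid((U_i . V_j + noise) / link_scale + b)`, where the intercept `b`
#' is calibrated (by root finding) so that the expected edge count equals
#' `density * N * M`. Calibrating the link in its natural-parameter space,
#' rather than rescaling the probabilities multiplicatively, keeps the
#' inclusion probability exponentially tilted towards high-scoring pairs —
#' a multiplicative rescale would flatten all pairs past the sigmoid's
#' saturation point onto one rate and erase the rank signal the world is
#' meant to carry. Deterministic given the seed.
#'
#' @param truth A `ground_truth` (or the latent slots of one).
#' @param density Expected fraction of observed pairs.
#' @param seed Integer seed for this draw.
#' @return An `interaction_set` of known edges.
#' @export
sample_observed_interactions <- function(truth, density, seed) {
  U <- truth$U_true; V <- truth$V_true
  N <- ncol(U); M <- ncol(V)
  expected <- density * N * M
  if (!(density > 0) || expected < 10) {
    stop("degenerate world: expected edge count ", round(expected, 2),
         " below 10 (is density > 0?)", call. = FALSE)
  }
  set.seed(as.integer(seed))
  s <- true_scores(U, V)
  noise_sd <- if (is.null(truth$config)) 0 else truth$config$noise_sd
  link_scale <- if (is.null(truth$config)) 1 else truth$config$link_scale
  if (noise_sd > 0) s <- s + matrix(stats::rnorm(N * M, 0, noise_sd), N, M)
  s <- s / link_scale
  b <- stats::uniroot(function(b) sum(stats::plogis(s + b)) - expected,
                      lower = -100, upper = 100, extendInt = "yes",
                      tol = 1e-8)$root
  p <- stats::plogis(s + b)
  hit <- which(matrix(stats::runif(N * M), N, M) < p, arr.ind = TRUE)
  if (nrow(hit) == 0L) stop("no edges sampled; increase density", call. = FALSE)
  new_interaction_set(truth$drug_ids[hit[, 1L]],
                      truth$target_ids[hit[, 2L]],
                      provenance = rep("known", nrow(hit)),
                      confidence = rep(1, nrow(hit)))
}

#' Write a synthetic world to the package's standard file formats
#'
#' Emits `catalog.tsv`, `targets.tsv`, `edges.tsv`, `pathways.gmt` and
#' `universe.txt` under `dir`, so a generated world is indistinguishable
#' from real input at the file-format level.
#'
#' @param truth A `ground_truth`.
#' @param dir Output directory (created if needed).
#' @return Named character vector of the written paths, invisibly.
#' @export
write_world <- function(truth, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(catalog = file.path(dir, "catalog.tsv"),
             targets = file.path(dir, "targets.tsv"),
             edges = file.path(dir, "edges.tsv"),
             pathways = file.path(dir, "pathways.gmt"),
             universe = file.path(dir, "universe.txt"))
  write_drug_catalog(truth$catalog, paths[["catalog"]])
  utils::write.table(truth$targets, paths[["targets"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_interactions(truth$interactions, paths[["edges"]])
  if (!is.null(truth$pathways)) {
    write_gene_sets(truth$pathways, paths[["pathways"]])
    writeLines(truth$pathways$universe, paths[["universe"]])
  }
  invisible(paths)
}
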