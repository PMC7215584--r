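# Drug-drug similarity: structural similarity from binary 2D-structure
# fingerprints (Tanimoto) and functional similarity from binary
# interaction-pattern vectors (cosine).

#' Tanimoto similarity between two binary fingerprints
#'
#' `|a AND b| / |a OR b|` for equal-length binary vectors; the companion
#' Tanimoto distance is `1 - similarity`.
#'
#' @param fp_a,fp_b Binary vectors (0/1, logical, or "0101..." bitstrings)
#'   of equal length, each with at least one set bit.
#' @return Similarity in `[0, 1]`.
#' @examples
#' tanimoto_similarity(c(1, 1, 0, 0), c(1, 0, 1, 0)) # 1/3
#' @export
tanimoto_similarity <- function(fp_a, fp_b) {
  a <- as_bits(fp_a); b <- as_bits(fp_b)
  if (length(a) != length(b)) {
    stop("fingerprints must have equal length", call. = FALSE)
  }
  if (!any(a) || !any(b)) {
    stop("Tanimoto similarity undefined for an all-zero fingerprint",
         call. = FALSE)
  }
  sum(a & b) / sum(a | b)
}

as_bits <- function(x) {
  if (is.character(x) && length(x) == 1L) {
    x <- as.integer(strsplit(x, "", fixed = TRUE)[[1L]])
  }
  if (anyNA(x) || !all(x %in% c(0, 1))) {
    stop("fingerprint must be binary", call. = FALSE)
  }
  as.logical(x)
}

#' Cosine distance between two binary interaction vectors
#'
#' `1 - (d_i . d_j) / (|d_i| |d_j|)` for the 0/1 target-membership vectors
#' of two drugs; for binary vectors the value lies in `[0, 1]`. The
#' functional similarity used elsewhere is `1 -` this distance.
#'
#' @param d_i,d_j Numeric 0/1 vectors of equal length, both nonzero.
#' @return Cosine distance.
#' @examples
#' interaction_cosine_distance(c(1, 1, 0), c(1, 0, 1)) # 0.5
#' @export
interaction_cosine_distance <- function(d_i, d_j) {
  if (length(d_i) != length(d_j)) {
    stop("interaction vectors must have equal length", call. = FALSE)
  }
  ni <- sqrt(sum(d_i^2)); nj <- sqrt(sum(d_j^2))
  if (ni == 0 || nj == 0) {
    stop("cosine distance undefined for a drug with no targets",
         call. = FALSE)
  }
  1 - sum(d_i * d_j) / (ni * nj)
}

#' Pairwise drug-drug similarity matrix
#'
#' `kind = "structural_tanimoto"` compares binary fingerprints from the
#' catalog (drugs without a usable fingerprint are excluded, with a
#' message); `kind = "functional_cosine"` compares binary interaction
#' profiles over the known targets and reports `1 - cosine distance`
#' (drugs with no known targets are excluded, with a message).
#'
#' @param catalog A `drug_catalog`.
#' @param interactions An `interaction_set` (required for the functional
#'   kind).
#' @param kind `"structural_tanimoto"` or `"functional_cosine"`.
#' @return A `similarity_matrix`: symmetric numeric matrix in `[0, 1]` with
#'   unit diagonal, drug-id dimnames and a `kind` attribute.
#' @export
similarity_matrix <- function(catalog, interactions = NULL,
                              kind = c("structural_tanimoto",
                                       "functional_cosine")) {
  kind <- match.arg(kind)
  if (kind == "structural_tanimoto") {
    has_fp <- !is.na(catalog$fingerprint)
    profiles <- lapply(catalog$fingerprint[has_fp], as_bits)
    nonzero <- vapply(profiles, any, logical(1))
    if (sum(has_fp) - sum(nonzero) > 0) {
      message("similarity_matrix: excluded ", sum(has_fp) - sum(nonzero),
              " drug(s) with all-zero fingerprints")
    }
    if (sum(!has_fp) > 0) {
      message("similarity_matrix: excluded ", sum(!has_fp),
              " drug(s) without fingerprints")
    }
    ids <- catalog$drug_id[has_fp][nonzero]
    X <- do.call(rbind, profiles[nonzero]) * 1
  } else {
    if (is.null(interactions)) {
      stop("functional similarity needs an interaction set", call. = FALSE)
    }
    known <- interactions[interactions$provenance == "known", , drop = FALSE]
    targets <- sort(unique(known$target_id))
    ids <- catalog$drug_id[catalog$drug_id %in% known$drug_id]
    excluded <- nrow(catalog) - length(ids)
    if (excluded > 0) {
      message("similarity_matrix: excluded ", excluded,
              " drug(s) with no known targets")
    }
    X <- matrix(0, length(ids), length(targets),
                dimnames = list(ids, targets))
    X[cbind(match(known$drug_id, ids), match(known$target_id, targets))] <- 1
    X <- X[rownames(X) %in% ids, , drop = FALSE]
  }
  if (length(ids) < 2L) {
    stop("fewer than 2 eligible drugs for ", kind, call. = FALSE)
  }
  if (kind == "structural_tanimoto") {
    inter <- tcrossprod(X)
    row_sums <- rowSums(X)
    union <- outer(row_sums, row_sums, "+") - inter
    values <- inter / union
  } else {
    norms <- sqrt(rowSums(X^2))
    values <- tcrossprod(X) / outer(norms, norms)
  }
  values <- (values + t(values)) / 2   # remove float asymmetry
  diag(values) <- 1
  dimnames(values) <- list(ids, ids)
  structure(values, kind = kind, class = c("similarity_matrix", "matrix"))
}

#' Hierarchical-clustering leaf order for heatmap display
#'
#' Average-linkage hierarchical clustering on `1 - similarity`; the leaf
#' order groups similar drugs next to each other, reproducing the row/column
#' arrangement of a clustered similarity heatmap. Deterministic given the
#' input.
#'
#' @param matrix A `similarity_matrix`.
#' @return Character vector: drug ids in leaf order.
#' @export
heatmap_order <- function(matrix) {
  ids <- rownames(matrix)
  if (length(ids) <= 2L) return(ids)
  hc <- stats::hclust(stats::as.dist(1 - unclass(matrix)),
                      method = "average")
  ids[hc$order]
}

#' Compute a 2D-structure fingerprint from SMILES
#'
#' Uses the OpenBabel FP2 path-based 2D fingerprint (1024 bits) through the
#' ChemmineOB package when available. Precomputed fingerprints in a catalog
#' always take precedence over SMILES-derived ones.
#'
#' @param smiles Character vector of SMILES strings.
#' @return Character vector of 0/1 bitstrings (length 1024).
#' @export
fingerprint_from_smiles <- function(smiles) {
  if (!requireNamespace("ChemmineOB", quietly = TRUE)) {
    stop("fingerprint computation from SMILES requires the ChemmineOB package",
         call. = FALSE)
  }
  vapply(smiles, function(s) {
    fp <- ChemmineOB::fingerprint_OB(
      ChemmineOB::forEachMol("SMILES", s, identity), "FP2")
    paste(as.integer(fp > 0), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}
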