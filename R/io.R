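# Readers and writers for the package's plain-text interfaces: TSV drug
# catalogs, TSV interaction edge lists and GMT gene-set collections.
# Identifiers are opaque, case-sensitive strings; no symbol normalisation.

read_tsv_table <- function(path, required, optional = character()) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                          comment.char = "#", stringsAsFactors = FALSE,
                          colClasses = "character", check.names = FALSE)
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L) {
    stop("missing required column(s) in ", path, ": ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  df[, c(required, intersect(optional, names(df))), drop = FALSE]
}

#' Load a drug catalog from a TSV file
#'
#' Reads a tab-separated drug catalog with header columns `drug_id`, `name`,
#' `category` and optional `smiles` and `fingerprint` columns. Comment lines
#' starting with `#` are ignored. The `category` column must contain one of
#' `r paste(MODULATOR_CATEGORIES, collapse = ", ")`. Fingerprints are 0/1
#' bitstrings; all fingerprints in a catalog must share one length.
#'
#' @param path Path to the TSV file.
#' @return A `drug_catalog`: a data frame with columns `drug_id`, `name`,
#'   `category`, `smiles`, `fingerprint` (the latter two `NA` when absent),
#'   input row order preserved, with attribute `fingerprint_length`.
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("drug_id\tname\tcategory",
#'              "d1\tdrug one\tactivator",
#'              "d2\tdrug two\tinhibitor"), tf)
#' load_drug_catalog(tf)
#' @export
load_drug_catalog <- function(path) {
  df <- read_tsv_table(path, required = c("drug_id", "name", "category"),
                       optional = c("smiles", "fingerprint"))
  if (anyDuplicated(df$drug_id)) {
    dup <- unique(df$drug_id[duplicated(df$drug_id)])
    stop("duplicate drug_id in catalog: ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  bad <- which(!df$category %in% MODULATOR_CATEGORIES)
  if (length(bad) > 0L) {
    stop("unknown category '", df$category[bad[1L]], "' in row ", bad[1L],
         " (drug_id ", df$drug_id[bad[1L]], "); expected one of ",
         paste(MODULATOR_CATEGORIES, collapse = ", "), call. = FALSE)
  }
  if (is.null(df$smiles)) df$smiles <- NA_character_
  if (is.null(df$fingerprint)) df$fingerprint <- NA_character_
  df$smiles[!nzchar(df$smiles) | is.na(df$smiles)] <- NA_character_
  df$fingerprint[!nzchar(df$fingerprint) | is.na(df$fingerprint)] <- NA_character_
  new_drug_catalog(df)
}

new_drug_catalog <- function(df) {
  fps <- df$fingerprint[!is.na(df$fingerprint)]
  fplen <- NA_integer_
  if (length(fps) > 0L) {
    if (any(grepl("[^01]", fps))) {
      stop("fingerprints must be 0/1 bitstrings", call. = FALSE)
    }
    lens <- unique(nchar(fps))
    if (length(lens) > 1L) {
      stop("fingerprints have inconsistent lengths: ",
           paste(lens, collapse = ", "), call. = FALSE)
    }
    fplen <- as.integer(lens)
  }
  rownames(df) <- NULL
  structure(df, fingerprint_length = fplen,
            class = c("drug_catalog", "data.frame"))
}

#' @export
print.drug_catalog <- function(x, ...) {
  cat("drug_catalog:", nrow(x), "drugs (",
      paste(vapply(MODULATOR_CATEGORIES, function(ct) {
        sprintf("%d %s", sum(x$category == ct), ct)
      }, character(1)), collapse = ", "), ")\n")
  fl <- attr(x, "fingerprint_length")
  if (!is.na(fl)) cat("fingerprints:", fl, "bits\n")
  invisible(x)
}

#' Write a drug catalog to TSV
#'
#' Inverse of [load_drug_catalog()]: writing then reading reproduces the
#' catalog exactly.
#'
#' @param catalog A `drug_catalog`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_drug_catalog <- function(catalog, path) {
  df <- as.data.frame(catalog)
  df$smiles[is.na(df$smiles)] <- ""
  df$fingerprint[is.na(df$fingerprint)] <- ""
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Load a target catalog from a TSV file
#'
#' Reads a table with header column `target_id` and optional `family`
#' annotation (pass-through metadata, e.g. kinase / GPCR / ion channel).
#'
#' @param path Path to the TSV file.
#' @return A data frame with columns `target_id` and `family`.
#' @export
load_target_catalog <- function(path) {
  df <- read_tsv_table(path, required = "target_id", optional = "family")
  if (anyDuplicated(df$target_id)) {
    dup <- unique(df$target_id[duplicated(df$target_id)])
    stop("duplicate target_id in catalog: ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  if (is.null(df$family)) df$family <- NA_character_
  rownames(df) <- NULL
  df
}

resolve_ids <- function(x, what) {
  if (is.data.frame(x)) {
    col <- intersect(c("drug_id", "target_id"), names(x))[1L]
    if (is.na(col)) stop("cannot extract ", what, " ids", call. = FALSE)
    as.character(x[[col]])
  } else {
    as.character(x)
  }
}

#' Load a drug-target interaction edge list
#'
#' Reads a two-column TSV (`drug_id`, `target_id`) of known interactions,
#' validates every identifier against the supplied catalogs, and removes
#' duplicate pairs (the number dropped is reported via [message()]).
#'
#' @param path Path to the TSV edge list.
#' @param drugs A `drug_catalog` or character vector of valid drug ids.
#' @param targets Optional target catalog or character vector of valid target
#'   ids; if `NULL`, any target id is accepted.
#' @return An `interaction_set`: a data frame with columns `drug_id`,
#'   `target_id`, `provenance` (`"known"`) and `confidence` (1 for known
#'   edges).
#' @export
load_interactions <- function(path, drugs, targets = NULL) {
  df <- read_tsv_table(path, required = c("drug_id", "target_id"))
  drug_ids <- resolve_ids(drugs, "drug")
  bad_d <- setdiff(unique(df$drug_id), drug_ids)
  if (length(bad_d) > 0L) {
    stop("unresolvable drug id(s) in edge list: ",
         paste(bad_d, collapse = ", "), call. = FALSE)
  }
  if (!is.null(targets)) {
    target_ids <- resolve_ids(targets, "target")
    bad_t <- setdiff(unique(df$target_id), target_ids)
    if (length(bad_t) > 0L) {
      stop("unresolvable target id(s) in edge list: ",
           paste(bad_t, collapse = ", "), call. = FALSE)
    }
  }
  dup <- duplicated(df[, c("drug_id", "target_id")])
  if (any(dup)) {
    message("load_interactions: dropped ", sum(dup), " duplicate edge(s)")
    df <- df[!dup, , drop = FALSE]
  }
  new_interaction_set(df$drug_id, df$target_id,
                      provenance = rep("known", nrow(df)),
                      confidence = rep(1, nrow(df)))
}

new_interaction_set <- function(drug_id, target_id, provenance, confidence) {
  stopifnot(all(provenance %in% c("known", "predicted")),
            all(confidence >= 0 & confidence <= 1))
  df <- data.frame(drug_id = as.character(drug_id),
                   target_id = as.character(target_id),
                   provenance = provenance,
                   confidence = confidence,
                   stringsAsFactors = FALSE)
  if (anyDuplicated(df[, c("drug_id", "target_id")])) {
    stop("duplicate (drug_id, target_id) pair in interaction set",
         call. = FALSE)
  }
  rownames(df) <- NULL
  structure(df, class = c("interaction_set", "data.frame"))
}

#' @export
print.interaction_set <- function(x, ...) {
  cat("interaction_set:", nrow(x), "edges (",
      sum(x$provenance == "known"), "known,",
      sum(x$provenance == "predicted"), "predicted ) over",
      length(unique(x$drug_id)), "drugs and",
      length(unique(x$target_id)), "targets\n")
  invisible(x)
}

#' Write an interaction edge list to TSV
#'
#' Known edges are written as a two-column edge list readable by
#' [load_interactions()]; predicted edges (if present) carry their
#' confidence in a third column.
#'
#' @param interactions An `interaction_set`.
#' @param path Output file path.
#' @param known_only If `TRUE` (default) write only known edges in the
#'   two-column round-trip format.
#' @return `path`, invisibly.
#' @export
write_interactions <- function(interactions, path, known_only = TRUE) {
  df <- as.data.frame(interactions)
  if (known_only) {
    df <- df[df$provenance == "known", c("drug_id", "target_id")]
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Combine known and predicted edges into one interaction set
#'
#' @param known An `interaction_set` of known edges.
#' @param predictions A prediction table with columns `drug_id`, `target_id`,
#'   `confidence` (e.g. from [select_predictions()]); may be empty.
#' @return An `interaction_set` holding both layers.
#' @export
combine_interactions <- function(known, predictions) {
  if (is.null(predictions) || nrow(predictions) == 0L) return(known)
  new_interaction_set(
    c(known$drug_id, predictions$drug_id),
    c(known$target_id, predictions$target_id),
    provenance = c(known$provenance, rep("predicted", nrow(predictions))),
    confidence = c(known$confidence, predictions$confidence))
}

#' Load a gene-set collection from a GMT file
#'
#' Standard GMT dialect: one set per line, tab-separated fields
#' `set_id <TAB> description <TAB> member...`. Members outside the declared
#' universe are dropped (count reported via [message()]); when no universe is
#' given the universe is the union of all members.
#'
#' @param path Path to the GMT file.
#' @param universe Optional character vector of valid target ids.
#' @return A `gene_set_collection`: list with elements `sets` (named list of
#'   `list(description, members)`) and `universe`.
#' @export
load_gene_sets <- function(path, universe = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  sets <- vector("list", length(lines))
  ids <- character(length(lines))
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(fields) < 2L) {
      stop("malformed GMT line ", i, ": fewer than 2 fields", call. = FALSE)
    }
    ids[i] <- fields[1L]
    members <- unique(fields[-(1:2)])
    members <- members[nzchar(members)]
    sets[[i]] <- list(description = fields[2L], members = members)
  }
  if (anyDuplicated(ids)) {
    stop("duplicate set_id in GMT: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  names(sets) <- ids
  new_gene_set_collection(sets, universe)
}

new_gene_set_collection <- function(sets, universe = NULL) {
  all_members <- unique(unlist(lapply(sets, `[[`, "members"), use.names = FALSE))
  if (is.null(universe)) {
    universe <- sort(all_members)
  } else {
    universe <- unique(as.character(universe))
    n_out <- 0L
    for (i in seq_along(sets)) {
      keep <- sets[[i]]$members %in% universe
      n_out <- n_out + sum(!keep)
      sets[[i]]$members <- sets[[i]]$members[keep]
    }
    if (n_out > 0L) {
      message("gene sets: dropped ", n_out, " member(s) outside the universe")
    }
  }
  if (length(universe) == 0L) stop("gene-set universe is empty", call. = FALSE)
  empty <- vapply(sets, function(s) length(s$members) == 0L, logical(1))
  if (any(empty)) {
    message("gene sets: removed ", sum(empty), " empty set(s)")
    sets <- sets[!empty]
  }
  structure(list(sets = sets, universe = universe),
            class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  sizes <- vapply(x$sets, function(s) length(s$members), integer(1))
  cat("gene_set_collection:", length(x$sets), "sets over a universe of",
      length(x$universe), "targets; set sizes",
      if (length(sizes)) paste0("[", min(sizes), ", ", max(sizes), "]") else "[]",
      "\n")
  invisible(x)
}

#' Write a gene-set collection to GMT
#'
#' @param collection A `gene_set_collection`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_gene_sets <- function(collection, path) {
  lines <- vapply(names(collection$sets), function(id) {
    s <- collection$sets[[id]]
    paste(c(id, s$description, s$members), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Build the binary drug-target interaction matrix
#'
#' Arranges the known edges of an interaction set into the sparse binary
#' matrix `R` factorised by [fit_pmf()]: entry `(i, j)` is 1 iff drug `i` is
#' known to interact with target `j`. The observation mask marks the cells
#' treated as observed during fitting; by default only the known positives
#' are observed (implicit-feedback setting) and any explicitly supplied
#' negative pairs are added as observed zeros.
#'
#' @param interactions An `interaction_set`; only `provenance == "known"`
#'   edges are used.
#' @param drugs A `drug_catalog` or character vector of drug ids (row order).
#' @param targets Optional target catalog or character vector of target ids
#'   (column order); defaults to the sorted distinct targets of the edges.
#' @param negatives Optional data frame of (`drug_id`, `target_id`) pairs
#'   known to be non-interacting, recorded as observed zeros.
#' @return A `binary_matrix`: list with `values` (0/1 matrix), `mask`
#'   (logical matrix of observed cells), `row_index` and `col_index`.
#' @export
build_matrix <- function(interactions, drugs, targets = NULL, negatives = NULL) {
  known <- interactions[interactions$provenance == "known", , drop = FALSE]
  if (nrow(known) == 0L) {
    stop("no known interactions: nothing to factorize", call. = FALSE)
  }
  row_index <- resolve_ids(drugs, "drug")
  col_index <- if (is.null(targets)) sort(unique(known$target_id))
               else resolve_ids(targets, "target")
  bad_d <- setdiff(known$drug_id, row_index)
  bad_t <- setdiff(known$target_id, col_index)
  if (length(bad_d) || length(bad_t)) {
    stop("edge ids missing from the catalogs: ",
         paste(c(bad_d, bad_t), collapse = ", "), call. = FALSE)
  }
  values <- matrix(0, length(row_index), length(col_index),
                   dimnames = list(row_index, col_index))
  idx <- cbind(match(known$drug_id, row_index),
               match(known$target_id, col_index))
  values[idx] <- 1
  mask <- values == 1
  if (!is.null(negatives) && nrow(negatives) > 0L) {
    nidx <- cbind(match(as.character(negatives$drug_id), row_index),
                  match(as.character(negatives$target_id), col_index))
    if (anyNA(nidx)) stop("negative pair ids missing from the catalogs",
                          call. = FALSE)
    mask[nidx] <- TRUE
  }
  structure(list(values = values, mask = mask,
                 row_index = row_index, col_index = col_index),
            class = "binary_matrix")
}

#' @export
print.binary_matrix <- function(x, ...) {
  cat("binary_matrix:", length(x$row_index), "drugs x",
      length(x$col_index), "targets;", sum(x$values), "positives;",
      sum(x$mask), "observed cells\n")
  invisible(x)
}
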