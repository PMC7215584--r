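# Probabilistic matrix factorization of the sparse binary drug-target
# matrix R ~ U'V, trained by stochastic gradient descent on the observed
# cells plus per-epoch resampled implicit negatives. Reconstructed values,
# clamped to [0, 1], are the confidence scores for unobserved pairs.

#' Fit a probabilistic matrix factorization model
#'
#' Decomposes the binary interaction matrix `R` (N drugs x M targets) into
#' drug factors `U` (D x N) and target factors `V` (D x M) minimising
#' \deqn{\sum_{(i,j) \in obs} (R_{ij} - U_i \cdot V_j)^2
#'   + \lambda_u \|U\|^2 + \lambda_v \|V\|^2}
#' by per-sample stochastic gradient descent. The observed set consists of
#' the matrix's masked cells (known positives, plus any explicit zeros)
#' together with `neg_ratio` x (number of positives) unobserved cells
#' resampled each epoch as soft negatives with value 0 — positive-only data
#' carries no explicit negatives, and resampling avoids committing to any
#' fixed false-negative set.
#'
#' Training stops early once the relative change of the epoch objective
#' stays below `tol` over `tol_window` consecutive epochs.
#'
#' @param matrix A `binary_matrix` from [build_matrix()] with at least one
#'   positive.
#' @param D Latent dimension (>= 1). The default 50 suits database-scale
#'   matrices; match the expected latent complexity, or select by held-out
#'   AUC via [evaluate_holdout()].
#' @param lambda_u,lambda_v L2 regularisation weights for `U` and `V`.
#' @param epochs Maximum number of passes over the observed cells.
#' @param learning_rate SGD step size.
#' @param neg_ratio Number of implicit negatives sampled per positive per
#'   epoch (0 disables negative sampling, e.g. for fully observed matrices).
#' @param seed Integer seed; fitting is deterministic given
#'   (matrix, hyperparameters, seed).
#' @param init_sd Standard deviation of the Gaussian factor initialisation.
#' @param tol,tol_window Early-stopping tolerance on the relative objective
#'   change and the number of epochs it must persist.
#' @return A `latent_model`: list with `U`, `V`, `D`, `lambda_u`,
#'   `lambda_v`, `row_index`, `col_index`, `known_mask`, `training_log`
#'   (per-epoch objective) and `seed`.
#' @export
fit_pmf <- function(matrix, D = 50, lambda_u = 0.05, lambda_v = 0.05,
                    epochs = 200, learning_rate = 0.05, neg_ratio = 1,
                    seed = 1L, init_sd = 0.1, tol = 1e-5, tol_window = 10L) {
  stopifnot(inherits(matrix, "binary_matrix"))
  if (D < 1) stop("latent dimension D must be >= 1", call. = FALSE)
  stopifnot(epochs >= 1, learning_rate > 0, neg_ratio >= 0)
  R <- matrix$values
  mask <- matrix$mask
  N <- nrow(R); M <- ncol(R)
  obs <- which(mask)
  n_pos <- sum(R[obs] == 1)
  if (n_pos < 1) stop("matrix has no positives", call. = FALSE)
  unobs <- which(!mask)
  n_neg <- if (neg_ratio > 0) min(round(neg_ratio * n_pos), length(unobs)) else 0L

  set.seed(as.integer(seed))
  U <- matrix(stats::rnorm(D * N, 0, init_sd), D, N)
  V <- matrix(stats::rnorm(D * M, 0, init_sd), D, M)
  obs_i <- ((obs - 1L) %% N) + 1L
  obs_j <- ((obs - 1L) %/% N) + 1L
  obs_r <- R[obs]

  training_log <- numeric(0)
  for (epoch in seq_len(epochs)) {
    if (n_neg > 0L) {
      neg <- sample(unobs, n_neg)
      i_ep <- c(obs_i, ((neg - 1L) %% N) + 1L)
      j_ep <- c(obs_j, ((neg - 1L) %/% N) + 1L)
      r_ep <- c(obs_r, numeric(n_neg))
    } else {
      i_ep <- obs_i; j_ep <- obs_j; r_ep <- obs_r
    }
    n_ep <- length(r_ep)
    for (s in sample.int(n_ep)) {
      ii <- i_ep[s]; jj <- j_ep[s]
      ui <- U[, ii]; vj <- V[, jj]
      err <- r_ep[s] - sum(ui * vj)
      U[, ii] <- ui + learning_rate * (err * vj - lambda_u * ui)
      V[, jj] <- vj + learning_rate * (err * ui - lambda_v * vj)
    }
    pred <- colSums(U[, i_ep, drop = FALSE] * V[, j_ep, drop = FALSE])
    objective <- sum((r_ep - pred)^2) +
      lambda_u * sum(U^2) + lambda_v * sum(V^2)
    if (!is.finite(objective)) {
      stop("PMF objective diverged (non-finite); try a smaller learning_rate",
           call. = FALSE)
    }
    training_log <- c(training_log, objective)
    if (epoch > tol_window) {
      window <- training_log[(epoch - tol_window):epoch]
      rel <- abs(diff(window)) / pmax(abs(window[-length(window)]), 1e-12)
      if (all(rel < tol)) break
    }
  }
  structure(list(U = U, V = V, D = as.integer(D),
                 lambda_u = lambda_u, lambda_v = lambda_v,
                 row_index = matrix$row_index, col_index = matrix$col_index,
                 known_mask = matrix$values == 1,
                 training_log = training_log, seed = as.integer(seed)),
            class = "latent_model")
}

#' @export
print.latent_model <- function(x, ...) {
  cat("latent_model: D =", x$D, "over", length(x$row_index), "drugs x",
      length(x$col_index), "targets;", length(x$training_log),
      "epochs, final objective",
      format(utils::tail(x$training_log, 1), digits = 6), "\n")
  invisible(x)
}

#' Confidence scores for all drug-target pairs
#'
#' The reconstruction `U'V` assigns each cell a raw score; confidences are
#' the raw scores clamped to `[0, 1]`. Known pairs keep their flag (the
#' `"known"` attribute) and are never re-emitted as predictions by
#' [select_predictions()].
#'
#' @param model A fitted `latent_model`.
#' @param raw If `TRUE` return unclamped scores.
#' @return An N x M matrix of confidences with drug/target dimnames and a
#'   logical attribute `known` marking the training positives.
#' @export
score_pairs <- function(model, raw = FALSE) {
  stopifnot(inherits(model, "latent_model"))
  scores <- crossprod(model$U, model$V)
  dimnames(scores) <- list(model$row_index, model$col_index)
  if (!raw) scores <- pmin(pmax(scores, 0), 1)
  attr(scores, "known") <- model$known_mask
  scores
}

#' Select thresholded top-k predictions per drug
#'
#' For each drug, the unknown pairs are ranked by confidence (descending,
#' ties broken by target id); pairs are kept when their rank is at most
#' `top_k` *and* their confidence is strictly greater than `threshold`.
#' The defaults (0.6, 40) follow common practice for balancing sensitivity
#' against specificity in database-scale interaction prediction.
#'
#' @param confidences Confidence matrix from [score_pairs()].
#' @param known An `interaction_set` of known edges (excluded from output),
#'   or `NULL` to use the matrix's `known` attribute.
#' @param threshold Strict lower confidence bound in `[0, 1]`.
#' @param top_k Maximum predictions per drug (>= 1).
#' @return A `prediction_list` data frame: `drug_id`, `target_id`,
#'   `confidence`, `rank` (contiguous 1..k within each drug).
#' @export
select_predictions <- function(confidences, known = NULL,
                               threshold = 0.6, top_k = 40) {
  stopifnot(threshold >= 0, threshold <= 1, top_k >= 1)
  known_mask <- attr(confidences, "known")
  if (!is.null(known)) {
    known_mask <- matrix(FALSE, nrow(confidences), ncol(confidences))
    kn <- known[known$provenance == "known", , drop = FALSE]
    ri <- match(kn$drug_id, rownames(confidences))
    ci <- match(kn$target_id, colnames(confidences))
    ok <- !is.na(ri) & !is.na(ci)
    known_mask[cbind(ri[ok], ci[ok])] <- TRUE
  }
  if (is.null(known_mask)) {
    known_mask <- matrix(FALSE, nrow(confidences), ncol(confidences))
  }
  out <- vector("list", nrow(confidences))
  target_ids <- colnames(confidences)
  for (i in seq_len(nrow(confidences))) {
    cand <- which(!known_mask[i, ])
    if (length(cand) == 0L) next
    conf <- confidences[i, cand]
    ord <- cand[order(-conf, target_ids[cand])]
    ord <- ord[seq_len(min(top_k, length(ord)))]
    keep <- ord[confidences[i, ord] > threshold]
    if (length(keep) == 0L) next
    out[[i]] <- data.frame(drug_id = rownames(confidences)[i],
                           target_id = target_ids[keep],
                           confidence = confidences[i, keep],
                           rank = seq_along(keep),
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  if (is.null(res)) {
    res <- data.frame(drug_id = character(), target_id = character(),
                      confidence = numeric(), rank = integer(),
                      stringsAsFactors = FALSE)
  }
  rownames(res) <- NULL
  structure(res, class = c("prediction_list", "data.frame"))
}

#' Hold out a fraction of known positives from a binary matrix
#'
#' Removes a random fraction of the positive cells from the matrix (value
#' and mask) for held-out evaluation of a model fitted on the remainder.
#'
#' @param matrix A `binary_matrix`.
#' @param fraction Fraction of positives to hold out, in (0, 1).
#' @param seed Integer seed.
#' @return List with `train` (the reduced `binary_matrix`) and `held_out`
#'   (data frame of held-out `drug_id`, `target_id` pairs).
#' @export
holdout_split <- function(matrix, fraction = 0.1, seed = 1L) {
  stopifnot(inherits(matrix, "binary_matrix"), fraction > 0, fraction < 1)
  pos <- which(matrix$values == 1)
  n_out <- max(1L, round(fraction * length(pos)))
  set.seed(as.integer(seed))
  out <- sample(pos, n_out)
  train <- matrix
  train$values[out] <- 0
  train$mask[out] <- FALSE
  N <- nrow(matrix$values)
  held <- data.frame(drug_id = matrix$row_index[((out - 1L) %% N) + 1L],
                     target_id = matrix$col_index[((out - 1L) %/% N) + 1L],
                     stringsAsFactors = FALSE)
  list(train = train, held_out = held)
}

#' Rank-based AUC of a model on held-out pairs
#'
#' Computes the probability that a random held-out positive receives a
#' higher confidence than a random negative pair (the area under the ROC
#' curve of the confidence ranking), with ties counted 0.5.
#'
#' @param model A fitted `latent_model`.
#' @param held_out_positives,sampled_negatives Data frames of (`drug_id`,
#'   `target_id`) pairs; each must be non-empty and the positives disjoint
#'   from the training positives.
#' @return AUC in `[0, 1]`.
#' @export
evaluate_holdout <- function(model, held_out_positives, sampled_negatives) {
  stopifnot(inherits(model, "latent_model"))
  if (nrow(held_out_positives) == 0L || nrow(sampled_negatives) == 0L) {
    stop("both the positive and the negative class must be non-empty",
         call. = FALSE)
  }
  scores <- score_pairs(model)
  pick <- function(pairs) {
    ri <- match(as.character(pairs$drug_id), rownames(scores))
    ci <- match(as.character(pairs$target_id), colnames(scores))
    if (anyNA(ri) || anyNA(ci)) {
      stop("held-out pair ids missing from the model", call. = FALSE)
    }
    scores[cbind(ri, ci)]
  }
  rank_auc(pick(held_out_positives), pick(sampled_negatives))
}

rank_auc <- function(pos_scores, neg_scores) {
  np <- length(pos_scores); nn <- length(neg_scores)
  r <- rank(c(pos_scores, neg_scores), ties.method = "average")
  (sum(r[seq_len(np)]) - np * (np + 1) / 2) / (np * nn)
}
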