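#' One-hot cluster indicator matrix
#'
#' @param labels integer vector of 0-based cluster labels.
#' @param n_clusters number of clusters; labels must lie in
#'   `[0, n_clusters)`.
#' @return binary cells x `n_clusters` matrix with one 1 per row.
#' @export
binarize_labels <- function(labels, n_clusters = max(labels) + 1L) {
  if (any(labels < 0 | labels >= n_clusters))
    stopf("labels out of range [0, %d)", n_clusters)
  out <- matrix(0, length(labels), n_clusters)
  out[cbind(seq_along(labels), labels + 1L)] <- 1
  out
}

#' Retrain feature factors against frozen cluster indicators
#'
#' Re-runs the tri-factorization optimization with the cell factors replaced
#' by frozen binary cluster indicators (used as-is, no softmax), so the
#' latent dimension equals the number of clusters and each feature-factor
#' column aligns with one cluster. Feature factors and association matrices
#' are initialized fresh; biases and scales are re-learned. Additional
#' matrices (e.g. motif deviation scores) can be attached to existing
#' batches as extra modalities and receive feature factors too.
#'
#' @param data a `mosaic_dataset` (pseudo slots filled).
#' @param labels integer 0-based cluster labels for all cells, ordered as the
#'   concatenation of the dataset's batches, or a named list of per-batch
#'   label vectors.
#' @param n_clusters number of clusters (defaults to `max(labels) + 1`).
#' @param extra optional list of extra matrices, each a list with elements
#'   `batch`, `modality`, `matrix` (cells x features, cells matching the
#'   batch); passed through unnormalized.
#' @param lambda_reg,n_iters,batch_frac,learning_rate,checkpoint_every,seed
#'   optimization settings as in [tri_factor()].
#' @param normalize apply per-modality default normalization to the dataset's
#'   own matrices (extras are never normalized).
#' @return object of class `tri_factor` (also `mosaic_retrain`), with
#'   `cell_factors` bitwise equal to the supplied indicators.
#' @export
retrain_factors <- function(data, labels, n_clusters = NULL, extra = NULL,
                            lambda_reg = 0.001, n_iters = 2000,
                            batch_frac = 0.1, learning_rate = 0.01,
                            checkpoint_every = 100, seed = 0,
                            normalize = TRUE) {
  stopifnot(inherits(data, "mosaic_dataset"))
  if (normalize) data <- normalize_mosaic(data)
  sizes <- vapply(data$cell_ids, length, integer(1))
  if (is.list(labels)) {
    stopifnot(identical(sort(names(labels)), sort(data$batch_ids)))
    lab_list <- labels[data$batch_ids]
  } else {
    stopifnot(length(labels) == sum(sizes))
    lab_list <- split(labels, factor(rep(data$batch_ids, sizes[data$batch_ids]),
                                     levels = data$batch_ids))
  }
  all_lab <- unlist(lab_list, use.names = FALSE)
  if (is.null(n_clusters)) n_clusters <- max(all_lab) + 1L
  fixed <- lapply(lab_list, binarize_labels, n_clusters = n_clusters)

  slots <- mosaic_slots(data)
  mats <- list()
  for (i in seq_len(nrow(slots)))
    mats[[slot_key(slots$batch[i], slots$modality[i])]] <-
      as_dense(mosaic_matrix(data, slots$batch[i], slots$modality[i]))
  feature_names <- data$feature_names
  if (!is.null(extra)) for (ex in extra) {
    stopifnot(all(c("batch", "modality", "matrix") %in% names(ex)))
    x <- as_dense(ex$matrix)
    if (nrow(x) != sizes[[ex$batch]])
      stopf("extra matrix for batch '%s' has %d cells, expected %d",
            ex$batch, nrow(x), sizes[[ex$batch]])
    if (is.null(colnames(x)))
      colnames(x) <- paste0(ex$modality, "_feat", seq_len(ncol(x)))
    slots <- rbind(slots, data.frame(batch = ex$batch, modality = ex$modality,
                                     provenance = "observed"))
    mats[[slot_key(ex$batch, ex$modality)]] <- x
    feature_names[[ex$modality]] <- colnames(x)
  }

  res <- tf_engine(slots, mats, d = n_clusters, lambda_reg = lambda_reg,
                   n_iters = n_iters, batch_frac = batch_frac,
                   learning_rate = learning_rate,
                   checkpoint_every = checkpoint_every, seed = seed,
                   fixed_cells = fixed)
  structure(c(res, list(
    d = n_clusters, lambda_reg = lambda_reg, seed = seed,
    n_iters = n_iters, batch_frac = batch_frac,
    learning_rate = learning_rate, slots = slots, data = data,
    feature_names = feature_names, labels = lab_list,
    call = match.call())),
    class = c("mosaic_retrain", "tri_factor"))
}

#' Feature scoring matrix of one modality
#'
#' Multiplies a retrained feature factor by the transpose of the shared
#' association matrix, `M = C_feat %*% t(Sigma)`; column `c` holds the
#' importance of every feature for cluster `c`, and the within-column ranking
#' is the marker ranking.
#'
#' @param C_feat features x d feature factor (or a `mosaic_retrain` model,
#'   in which case `modality` selects the factor and Sigma is taken from the
#'   model).
#' @param sigma d x d association matrix.
#' @param modality modality id when `C_feat` is a model.
#' @return object of class `feature_scores`: the features x clusters score
#'   matrix with feature names as rownames.
#' @export
feature_scores <- function(C_feat, sigma = NULL, modality = NULL) {
  if (inherits(C_feat, "tri_factor")) {
    model <- C_feat
    modality <- modality %||% names(model$feature_factors)[1]
    C_feat <- model$feature_factors[[modality]]
    fn <- model$feature_names[[modality]] %||% model$data$feature_names[[modality]]
    if (!is.null(fn)) rownames(C_feat) <- fn
    sigma <- sigma %||% model$sigma_shared
  }
  if (ncol(C_feat) != ncol(sigma) || nrow(sigma) != ncol(sigma))
    stopf("shape mismatch: C_feat is %dx%d, sigma %dx%d",
          nrow(C_feat), ncol(C_feat), nrow(sigma), ncol(sigma))
  M <- C_feat %*% t(sigma)
  colnames(M) <- paste0("cluster", seq_len(ncol(M)) - 1L)
  structure(M, class = c("feature_scores", class(M)), modality = modality)
}

#' Top-scoring features of one cluster
#'
#' @param M a `feature_scores` matrix (features x clusters).
#' @param cluster 0-based cluster index.
#' @param n number of features (default 20); if `n` exceeds the feature
#'   count, all features are returned with a warning.
#' @return character vector of feature names (or indices when unnamed), by
#'   descending score; ties broken by ascending feature index.
#' @export
top_features <- function(M, cluster, n = 20) {
  if (cluster < 0 || cluster >= ncol(M)) stopf("invalid cluster %s", cluster)
  if (n > nrow(M)) {
    warnf("n = %d exceeds feature count %d; returning all", n, nrow(M))
    n <- nrow(M)
  }
  if (n == 0) return(character(0))
  col <- M[, cluster + 1L]
  ord <- order(-col, seq_along(col))[seq_len(n)]
  if (!is.null(rownames(M))) rownames(M)[ord] else as.character(ord)
}
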