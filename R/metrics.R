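#' Graph connectivity of an embedding
#'
#' Builds a kNN graph over all cells from the embedding and, for every cell
#' type, computes the fraction of its cells lying in the largest connected
#' component of the type's induced subgraph; the score is the mean over
#' types. 1 means every type forms a single connected community across
#' batches (well-mixed batches); types with a single cell contribute 1 with
#' a warning.
#'
#' @param embedding cells x dim matrix.
#' @param type_labels per-cell type labels.
#' @param k_metric neighbors for the metric's kNN graph (default 15).
#' @return scalar in [0, 1].
#' @export
graph_connectivity <- function(embedding, type_labels, k_metric = 15) {
  stopifnot(nrow(embedding) == length(type_labels))
  nn <- knn_indices(embedding, min(k_metric, nrow(embedding) - 1L))
  types <- unique(type_labels)
  per_type <- vapply(types, function(tt) {
    members <- which(type_labels == tt)
    if (length(members) == 1L) {
      warnf("type '%s' has a single cell; contributes 1.0", tt)
      return(1)
    }
    sub <- matrix(FALSE, length(members), length(members))
    pos <- match(seq_len(nrow(embedding)), members)
    for (ii in seq_along(members)) {
      nb <- pos[nn[members[ii], ]]
      nb <- nb[!is.na(nb)]
      sub[ii, nb] <- TRUE; sub[nb, ii] <- TRUE
    }
    g <- igraph::graph_from_adjacency_matrix(sub, mode = "undirected")
    max(igraph::components(g)$csize) / length(members)
  }, numeric(1))
  mean(per_type)
}

# row-wise k nearest neighbors (excluding self), Euclidean
knn_indices <- function(x, k) {
  D <- as.matrix(stats::dist(x))
  diag(D) <- Inf
  matrix(t(apply(D, 1, function(row) order(row)[seq_len(k)])),
         nrow = nrow(D), ncol = k, byrow = (k == 1))
}

#' Adjusted Rand index between two partitions
#' @param a,b label vectors of equal length.
#' @return scalar in [-1, 1]; 1 iff the partitions coincide up to label
#'   permutation. NA (with a warning) when either partition is a single
#'   cluster and so chance-adjustment is undefined alongside a single-cluster
#'   comparison.
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  n <- length(a)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) {
    warnf("ARI undefined (degenerate partitions); returning NA")
    return(NA_real_)
  }
  (sum_ij - expected) / (max_index - expected)
}

#' Normalized mutual information between two partitions
#'
#' Mutual information normalized by the arithmetic mean of the two label
#' entropies, in [0, 1].
#' @param a,b label vectors of equal length.
#' @return scalar in [0, 1].
#' @export
normalized_mutual_info <- function(a, b) {
  stopifnot(length(a) == length(b))
  n <- length(a)
  tab <- table(a, b) / n
  pa <- rowSums(tab); pb <- colSums(tab)
  mi <- 0
  for (i in seq_along(pa)) for (j in seq_along(pb))
    if (tab[i, j] > 0)
      mi <- mi + tab[i, j] * log(tab[i, j] / (pa[i] * pb[j]))
  ha <- -sum(pa[pa > 0] * log(pa[pa > 0]))
  hb <- -sum(pb[pb > 0] * log(pb[pb > 0]))
  if (ha + hb == 0) return(1)
  as.numeric(mi / ((ha + hb) / 2))
}

#' Resolution-swept clustering scores against ground truth
#'
#' Runs Leiden clustering at every resolution of the sweep (0.1 to 10 in
#' steps of 0.5 by default) and reports the best ARI and the best NMI over
#' the sweep, each maximized independently.
#'
#' @param graph a normalized `neighbor_graph` (or any object accepted by
#'   [cluster_cells()]).
#' @param truth_labels per-cell ground-truth labels covering all cells.
#' @param resolutions numeric vector of resolutions.
#' @param seed RNG seed for clustering.
#' @return list with `ari`, `nmi`, `best_resolution_ari`,
#'   `best_resolution_nmi`, and `sweep` (per-resolution table with the
#'   labels of the best-ARI resolution retained as attribute `"labels"`).
#' @export
clustering_scores <- function(graph, truth_labels,
                              resolutions = seq(0.1, 10, by = 0.5),
                              seed = 0) {
  stopifnot(length(truth_labels) == length(graph$batch))
  if (length(unique(truth_labels)) < 2L)
    warnf("single-cluster truth; ARI will be NA at degenerate resolutions")
  rows <- lapply(resolutions, function(res) {
    lab <- cluster_cells(graph, resolution = res, seed = seed)
    data.frame(resolution = res,
               n_clusters = length(unique(lab)),
               ari = suppressWarnings(adjusted_rand_index(lab, truth_labels)),
               nmi = normalized_mutual_info(lab, truth_labels),
               labels = I(list(lab)))
  })
  sweep <- do.call(rbind, rows)
  bi_ari <- which.max(sweep$ari)
  bi_nmi <- which.max(sweep$nmi)
  best_labels <- sweep$labels[[bi_ari]]
  out_sweep <- sweep[, c("resolution", "n_clusters", "ari", "nmi")]
  list(ari = sweep$ari[bi_ari], nmi = sweep$nmi[bi_nmi],
       best_resolution_ari = sweep$resolution[bi_ari],
       best_resolution_nmi = sweep$resolution[bi_nmi],
       labels = best_labels, sweep = out_sweep)
}

#' kNN agreement of a label set with one pre-integration matrix
#'
#' Reduces the matrix (PCA to 30 components for expression/protein, LSI for
#' accessibility), builds the per-cell k nearest neighborhoods, and averages
#' over cells the fraction of neighbors sharing the cell's label. High
#' scores mean the labels respect the cell-cell variation of the raw matrix.
#'
#' @param x one cell x feature data matrix.
#' @param labels per-cell labels.
#' @param k neighbors per cell.
#' @param modality `"atac"` selects LSI, anything else PCA.
#' @param n_components dimensionality of the reduction (default 30, capped
#'   below `min(dim(x))`).
#' @return scalar in [0, 1].
#' @export
knn_agreement <- function(x, labels, k = 15, modality = "rna",
                          n_components = 30) {
  x <- as_dense(x)
  stopifnot(nrow(x) == length(labels))
  if (k >= nrow(x)) stopf("k must be < number of cells")
  nc <- min(n_components, min(dim(x)) - 1L)
  red <- if (identical(modality, "atac")) {
    lsi_embed(x, nc)
  } else {
    stats::prcomp(x, center = TRUE, scale. = FALSE)$x[, seq_len(nc), drop = FALSE]
  }
  nn <- knn_indices(red, k)
  mean(vapply(seq_len(nrow(x)), function(i)
    mean(labels[nn[i, ]] == labels[i]), numeric(1)))
}

#' Dataset-level kNN agreement over all matrices of a mosaic
#'
#' Averages [knn_agreement()] over every input matrix of the dataset (each
#' scored with its batch's labels and its modality's reduction).
#'
#' @param data a `mosaic_dataset`.
#' @param labels named list of per-batch label vectors, or one vector over
#'   the concatenated batches.
#' @param k neighbors per cell.
#' @return scalar in [0, 1].
#' @export
knn_agreement_mosaic <- function(data, labels, k = 15) {
  sizes <- vapply(data$cell_ids, length, integer(1))
  if (!is.list(labels)) {
    stopifnot(length(labels) == sum(sizes))
    labels <- split(labels, factor(rep(data$batch_ids, sizes[data$batch_ids]),
                                   levels = data$batch_ids))
  }
  slots <- mosaic_slots(data)
  mean(vapply(seq_len(nrow(slots)), function(i) {
    b <- slots$batch[i]; m <- slots$modality[i]
    knn_agreement(mosaic_matrix(data, b, m), labels[[b]], k = k,
                  modality = m)
  }, numeric(1)))
}

#' Rare-type detection F1
#'
#' The predicted rare cluster is the cluster with the largest overlap with
#' the true rare-type cell set; the score is the harmonic mean of that
#' cluster's precision and recall against the mask.
#'
#' @param pred_labels per-cell predicted cluster labels.
#' @param rare_truth_mask logical per-cell mask of the true rare type.
#' @return scalar in [0, 1].
#' @export
f1_rare <- function(pred_labels, rare_truth_mask) {
  stopifnot(length(pred_labels) == length(rare_truth_mask))
  if (!any(rare_truth_mask)) stopf("no true rare cells")
  if (!length(pred_labels)) stopf("no clusters")
  overlap <- tapply(rare_truth_mask, pred_labels, sum)
  best <- names(overlap)[which.max(overlap)]
  sel <- pred_labels == best
  precision <- sum(sel & rare_truth_mask) / sum(sel)
  recall <- sum(sel & rare_truth_mask) / sum(rare_truth_mask)
  if (precision + recall == 0) return(0)
  2 * precision * recall / (precision + recall)
}

#' Kendall rank correlation between two rankings
#'
#' Tie-corrected (tau-b) Kendall correlation between two orderings of the
#' same item set.
#'
#' @param ranking_a,ranking_b vectors of items, best-ranked first; must
#'   contain the same items.
#' @return tau in [-1, 1].
#' @export
kendall_tau <- function(ranking_a, ranking_b) {
  if (!setequal(ranking_a, ranking_b) ||
      length(ranking_a) != length(ranking_b))
    stopf("rankings must cover the same item set")
  items <- ranking_a
  ra <- seq_along(items)
  rb <- match(items, ranking_b)
  stats::cor(ra, rb, method = "kendall")
}

#' Bundle the benchmark metrics into one report
#'
#' @param embedding cells x d embedding.
#' @param graph a normalized `neighbor_graph` over the same cells.
#' @param truth_labels per-cell ground-truth type labels.
#' @param rare_truth_mask optional logical mask of the rare type.
#' @param k_metric kNN size for graph connectivity.
#' @param resolutions resolution sweep.
#' @param seed RNG seed.
#' @return list of class `metric_report` with gc, ari, nmi, best
#'   resolutions, optional f1_rare, and the sweep table.
#' @export
metric_report <- function(embedding, graph, truth_labels,
                          rare_truth_mask = NULL, k_metric = 15,
                          resolutions = seq(0.1, 10, by = 0.5), seed = 0) {
  gc_score <- graph_connectivity(embedding, truth_labels, k_metric)
  cs <- clustering_scores(graph, truth_labels, resolutions, seed)
  rep <- list(gc = gc_score, ari = cs$ari, nmi = cs$nmi,
              best_resolution_ari = cs$best_resolution_ari,
              best_resolution_nmi = cs$best_resolution_nmi,
              labels = cs$labels, sweep = cs$sweep)
  if (!is.null(rare_truth_mask))
    rep$f1_rare <- f1_rare(cs$labels, rare_truth_mask)
  structure(rep, class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf("GC = %.3f | ARI = %.3f (res %.1f) | NMI = %.3f (res %.1f)",
              x$gc, x$ari, x$best_resolution_ari, x$nmi,
              x$best_resolution_nmi))
  if (!is.null(x$f1_rare)) cat(sprintf(" | rare-type F1 = %.3f", x$f1_rare))
  cat("\n")
  invisible(x)
}
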