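#' Per-batch neighbor quotas
#'
#' Splits a total neighbor budget `k` across batches proportionally to batch
#' size, `k_i = (N_i / N_total) * k`, rounded by floor plus largest
#' remainder (ties to the lower batch index) so that the quotas sum to `k`
#' exactly and every batch receives at least one neighbor.
#'
#' @param batch_sizes integer vector of cells per batch (named or not).
#' @param k total number of neighbors per cell.
#' @return integer vector of quotas, same length/names as `batch_sizes`.
#' @export
neighbor_quotas <- function(batch_sizes, k) {
  nb <- length(batch_sizes)
  if (k < nb) stopf("k = %d cannot give each of %d batches >= 1 neighbor", k, nb)
  exact <- batch_sizes / sum(batch_sizes) * k
  q <- floor(exact)
  rem <- k - sum(q)
  if (rem > 0) {
    frac <- exact - q
    give <- order(-frac, seq_len(nb))[seq_len(rem)]
    q[give] <- q[give] + 1
  }
  # enforce the >= 1 floor, taking from the largest quotas
  while (any(q == 0)) {
    i <- which(q == 0)[1]
    j <- which.max(q)
    q[i] <- 1; q[j] <- q[j] - 1
  }
  stats::setNames(as.integer(q), names(batch_sizes))
}

#' Cross-batch nearest-neighbor graph over cell factors
#'
#' Builds the directed kNN graph used for visualization and clustering:
#' Euclidean distances between cell-factor rows; each cell draws its
#' [neighbor_quotas()] share of nearest neighbors from every batch
#' (including its own, excluding itself); then, per ordered batch pair, only
#' the fraction `r` of shortest cross-batch edges is kept (`r = 1` skips
#' pruning; within-batch edges are never pruned).
#'
#' @param cell_factors either a `tri_factor` model, or a named list of
#'   per-batch cells x d factor matrices.
#' @param k total neighbors per cell.
#' @param r pruning radius, fraction in (0, 1] of cross-batch edges kept.
#' @return object of class `neighbor_graph`: an edge list with per-cell
#'   batch labels.
#' @export
neighbor_graph <- function(cell_factors, k = 30, r = 1) {
  if (inherits(cell_factors, "tri_factor")) {
    emb <- cell_embedding(cell_factors)
    batch <- attr(emb, "batch")
  } else {
    emb <- do.call(rbind, cell_factors)
    batch <- rep(names(cell_factors), vapply(cell_factors, nrow, integer(1)))
    if (is.null(rownames(emb))) rownames(emb) <- paste0("cell", seq_len(nrow(emb)))
  }
  stopifnot(r > 0, r <= 1)
  batch_ids <- unique(batch)
  sizes <- table(factor(batch, levels = batch_ids))
  quota <- neighbor_quotas(as.integer(sizes), k)
  names(quota) <- batch_ids

  D <- as.matrix(stats::dist(emb))
  n <- nrow(D)
  src <- dst <- integer(0); dd <- numeric(0)
  for (bi in batch_ids) {
    members <- which(batch == bi)
    ki <- quota[bi]
    own <- ki > 0
    for (m in seq_len(n)) {
      cand <- members
      if (batch[m] == bi) cand <- setdiff(cand, m)
      kk <- min(ki, length(cand))
      if (kk < ki)
        warnf("quota %d exceeds population of batch %s; capped at %d", ki, bi, kk)
      if (kk == 0) next
      ord <- cand[order(D[m, cand], cand)][seq_len(kk)]
      src <- c(src, rep(m, kk)); dst <- c(dst, ord)
      dd <- c(dd, D[m, ord])
    }
  }
  edges <- data.frame(src = src, dst = dst, dist = dd,
                      src_batch = batch[src], dst_batch = batch[dst],
                      stringsAsFactors = FALSE)

  if (r < 1) {
    keep <- rep(TRUE, nrow(edges))
    cross <- edges$src_batch != edges$dst_batch
    for (bi in batch_ids) for (bj in setdiff(batch_ids, bi)) {
      sel <- which(cross & edges$src_batch == bi & edges$dst_batch == bj)
      if (!length(sel)) next
      n_keep <- ceiling(r * length(sel))
      drop <- sel[order(edges$dist[sel])][-seq_len(n_keep)]
      keep[drop] <- FALSE
    }
    edges <- edges[keep, , drop = FALSE]
  }

  structure(list(edges = edges, batch = batch, cell_ids = rownames(emb),
                 k = k, r = r, quotas = quota, normalized = FALSE),
            class = "neighbor_graph")
}

#' Normalize cross-batch distances of a neighbor graph
#'
#' For every cell, rescales the distances to its neighbors in each other
#' batch by the ratio of its mean within-batch neighbor distance to its mean
#' cross-batch neighbor distance in that batch, so that after normalization
#' both means coincide. Within-batch edges are unchanged; the operation is
#' idempotent.
#'
#' @param graph a `neighbor_graph` from [neighbor_graph()].
#' @return the graph with a `ndist` edge column and `normalized = TRUE`.
#' @export
normalize_distances <- function(graph) {
  e <- graph$edges
  e$ndist <- e$dist
  within_mean <- tapply(e$dist[e$src_batch == e$dst_batch],
                        e$src[e$src_batch == e$dst_batch], mean)
  cross <- which(e$src_batch != e$dst_batch)
  if (length(cross)) {
    grp <- paste(e$src[cross], e$dst_batch[cross], sep = "\r")
    cross_mean <- tapply(e$dist[cross], grp, mean)
    dii <- within_mean[as.character(e$src[cross])]
    dij <- cross_mean[grp]
    ratio <- ifelse(is.na(dii), 1, ifelse(dij > 0, dii / dij,
                                          ifelse(dii > 0, 0, 1)))
    if (any(dij == 0 & !is.na(dii) & dii > 0))
      warnf("some cells have zero mean cross-batch distance; edges left at 0")
    e$ndist[cross] <- e$dist[cross] * ratio
  }
  graph$edges <- e
  graph$normalized <- TRUE
  graph
}

#' @export
print.neighbor_graph <- function(x, ...) {
  cat(sprintf("neighbor_graph: %d cells, %d directed edges (k = %d, r = %g)%s\n",
              length(x$batch), nrow(x$edges), x$k, x$r,
              if (x$normalized) ", normalized" else ""))
  cat("quotas:", paste(sprintf("%s=%d", names(x$quotas), x$quotas),
                       collapse = ", "), "\n")
  invisible(x)
}

# shared-neighbor (Jaccard) affinity graph for community detection; neighbor
# sets include the cell itself so duplicated cells get affinity 1
snn_igraph <- function(graph) {
  e <- graph$edges
  n <- length(graph$batch)
  nbrs <- split(e$dst, factor(e$src, levels = seq_len(n)))
  nbrs <- lapply(seq_len(n), function(i) unique(c(i, nbrs[[i]])))
  und <- unique(data.frame(a = pmin(e$src, e$dst), b = pmax(e$src, e$dst)))
  w <- vapply(seq_len(nrow(und)), function(i) {
    na <- nbrs[[und$a[i]]]; nb <- nbrs[[und$b[i]]]
    length(intersect(na, nb)) / length(union(na, nb))
  }, numeric(1))
  keep <- w > 0
  igraph::graph_from_data_frame(
    cbind(und[keep, , drop = FALSE], weight = w[keep]),
    directed = FALSE,
    vertices = data.frame(name = seq_len(n)))
}

#' Leiden clustering of a normalized neighbor graph
#'
#' Converts the graph to shared-neighbor (Jaccard) affinities and partitions
#' it with the Leiden algorithm (modularity objective). Deterministic for a
#' fixed seed.
#'
#' @param graph a normalized `neighbor_graph`.
#' @param resolution Leiden resolution parameter.
#' @param seed RNG seed.
#' @return integer vector of 0-based cluster labels, one per cell.
#' @export
cluster_cells <- function(graph, resolution = 1, seed = 0) {
  stopifnot(inherits(graph, "neighbor_graph"))
  if (nrow(graph$edges) == 0L) stopf("empty graph")
  g <- snn_igraph(graph)
  set.seed(seed)
  cl <- igraph::cluster_leiden(g, objective_function = "modularity",
                               resolution = resolution, n_iterations = 3)
  m <- igraph::membership(cl)
  as.integer(m[as.character(seq_along(graph$batch))]) - 1L
}

#' Export a neighbor graph as an edge-list table
#'
#' @param graph a `neighbor_graph`.
#' @param path optional TSV path; when NULL the data.frame is returned.
#' @return data.frame with src, dst (cell ids), batches, distance and
#'   normalized distance.
#' @export
graph_edge_table <- function(graph, path = NULL) {
  e <- graph$edges
  out <- data.frame(src = graph$cell_ids[e$src], dst = graph$cell_ids[e$dst],
                    src_batch = e$src_batch, dst_batch = e$dst_batch,
                    distance = e$dist,
                    normalized_distance = e$ndist %||% e$dist)
  if (!is.null(path)) {
    utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(out))
  }
  out
}
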