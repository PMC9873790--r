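#' Assemble a mosaic dataset
#'
#' A mosaic dataset is a grid of cell-by-feature matrices indexed by
#' (batch, modality); any subset of the grid may be observed. All matrices of
#' one batch must share the same cells (rows) in the same order, and all
#' matrices of one modality the same features (columns). The grid, viewed as
#' a bipartite graph whose nodes are batches and modalities and whose edges
#' are matrices, must be connected before the model can be fitted; missing
#' slots can be declared for pseudo-count filling.
#'
#' @param matrices nested list: `matrices[[batch]][[modality]]` is a numeric
#'   cell x feature matrix (dense or `Matrix` sparse). Row/column names, when
#'   present, seed `cell_ids` / `feature_names`.
#' @param cell_ids optional named list of per-batch cell identifier vectors.
#' @param feature_names optional named list of per-modality feature names.
#' @param provenance optional named character vector keyed by
#'   `"batch:modality"`, values `"observed"` or `"pseudo"`; defaults to
#'   `"observed"` everywhere.
#' @param pseudo_slots optional data.frame with columns `batch`, `modality`
#'   declaring missing slots that will later be filled with pseudo-counts
#'   (they count towards connectivity checks).
#' @return an object of class `mosaic_dataset`.
#' @export
mosaic_dataset <- function(matrices, cell_ids = NULL, feature_names = NULL,
                           provenance = NULL, pseudo_slots = NULL) {
  if (length(matrices) == 0L) stopf("no matrices supplied")
  batch_ids <- names(matrices)
  if (is.null(batch_ids) || anyNA(batch_ids) || any(batch_ids == ""))
    stopf("matrices must be a named list (one element per batch)")
  for (b in batch_ids) {
    if (length(matrices[[b]]) == 0L)
      stopf("batch '%s' has zero matrices", b)
    if (is.null(names(matrices[[b]])))
      stopf("matrices[['%s']] must be named by modality", b)
  }
  modality_ids <- unique(unlist(lapply(matrices, names)))

  # resolve per-batch cell ids and per-modality feature names, checking
  # alignment across the grid
  resolved_cells <- list()
  resolved_feats <- list()
  for (b in batch_ids) {
    for (m in names(matrices[[b]])) {
      x <- matrices[[b]][[m]]
      if (any(dim(x) == 0L)) stopf("empty matrix for (%s, %s)", b, m)
      if (!inherits(x, "Matrix") && !is.double(x)) {
        storage.mode(x) <- "double"
        matrices[[b]][[m]] <- x
      }
      cid <- rownames(x) %||% cell_ids[[b]] %||%
        paste0(b, "_cell", seq_len(nrow(x)))
      fid <- colnames(x) %||% feature_names[[m]] %||%
        paste0(m, "_feat", seq_len(ncol(x)))
      if (length(cid) != nrow(x))
        stopf("cell id length mismatch for (%s, %s)", b, m)
      if (length(fid) != ncol(x))
        stopf("feature name length mismatch for (%s, %s)", b, m)
      if (is.null(resolved_cells[[b]])) {
        resolved_cells[[b]] <- cid
      } else if (!identical(resolved_cells[[b]], cid)) {
        stopf("cell ids of batch '%s' differ between its matrices", b)
      }
      if (is.null(resolved_feats[[m]])) {
        resolved_feats[[m]] <- fid
      } else if (!identical(resolved_feats[[m]], fid)) {
        stopf("feature names of modality '%s' differ between matrices", m)
      }
      dimnames(matrices[[b]][[m]]) <- list(cid, fid)
    }
  }

  if (!is.null(pseudo_slots)) {
    pseudo_slots <- as.data.frame(pseudo_slots, stringsAsFactors = FALSE)
    stopifnot(all(c("batch", "modality") %in% names(pseudo_slots)))
    modality_ids <- union(modality_ids, pseudo_slots$modality)
  }

  presence <- matrix(FALSE, length(batch_ids), length(modality_ids),
                     dimnames = list(batch_ids, modality_ids))
  prov <- character()
  for (b in batch_ids) for (m in names(matrices[[b]])) {
    presence[b, m] <- TRUE
    key <- paste(b, m, sep = ":")
    prov[key] <- provenance[key] %||% "observed"
  }
  stopifnot(all(prov %in% c("observed", "pseudo")))

  obj <- structure(list(
    matrices = matrices,
    batch_ids = batch_ids,
    modality_ids = modality_ids,
    presence = presence,
    cell_ids = resolved_cells,
    feature_names = resolved_feats,
    provenance = prov,
    pseudo_slots = pseudo_slots
  ), class = "mosaic_dataset")
  obj
}

#' Grid slots present in a mosaic dataset
#'
#' @param data a `mosaic_dataset`.
#' @return data.frame with columns `batch`, `modality`, `provenance`.
#' @export
mosaic_slots <- function(data) {
  out <- do.call(rbind, lapply(data$batch_ids, function(b) {
    ms <- names(data$matrices[[b]])
    data.frame(batch = rep(b, length(ms)), modality = ms,
               stringsAsFactors = FALSE)
  }))
  out$provenance <- data$provenance[paste(out$batch, out$modality, sep = ":")]
  out
}

#' Extract one matrix of the grid
#' @param data a `mosaic_dataset`.
#' @param batch,modality slot identifiers.
#' @return the cell x feature matrix.
#' @export
mosaic_matrix <- function(data, batch, modality) {
  x <- data$matrices[[batch]][[modality]]
  if (is.null(x)) stopf("no matrix at (%s, %s)", batch, modality)
  x
}

#' Batch index sets per modality
#'
#' For every modality, the set of batches carrying a matrix of it (the index
#' sets over which the joint loss sums run).
#' @param data a `mosaic_dataset`.
#' @return named list of character vectors.
#' @export
batch_index_sets <- function(data) {
  sets <- lapply(data$modality_ids, function(m)
    data$batch_ids[data$presence[, m]])
  names(sets) <- data$modality_ids
  sets
}

# union-find over the entity graph (batches + modalities); matrices and
# declared pseudo slots are the edges
entity_components <- function(data, include_pseudo_slots = TRUE) {
  nodes <- c(paste0("batch:", data$batch_ids),
             paste0("modality:", data$modality_ids))
  parent <- seq_along(nodes)
  names(parent) <- nodes
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  unite <- function(a, b) {
    ra <- find(match(a, nodes)); rb <- find(match(b, nodes))
    if (ra != rb) parent[rb] <<- ra
  }
  for (b in data$batch_ids) for (m in names(data$matrices[[b]]))
    unite(paste0("batch:", b), paste0("modality:", m))
  if (include_pseudo_slots && !is.null(data$pseudo_slots))
    for (i in seq_len(nrow(data$pseudo_slots)))
      unite(paste0("batch:", data$pseudo_slots$batch[i]),
            paste0("modality:", data$pseudo_slots$modality[i]))
  roots <- vapply(seq_along(nodes), function(i) nodes[find(i)], character(1))
  split(nodes, roots)
}

#' Is the entity graph of a mosaic dataset connected?
#'
#' Batches and modalities are graph nodes; every matrix (and, optionally,
#' every declared pseudo slot) is an edge. Integration is only identifiable
#' when this graph has a single connected component.
#'
#' @param data a `mosaic_dataset`.
#' @param include_pseudo_slots count declared-but-unfilled pseudo slots as
#'   edges (default TRUE).
#' @return logical scalar; attribute `"components"` lists the components.
#' @export
entity_connected <- function(data, include_pseudo_slots = TRUE) {
  comp <- entity_components(data, include_pseudo_slots)
  structure(length(comp) == 1L, components = unname(comp))
}

check_connected <- function(data) {
  ok <- entity_connected(data)
  if (!ok) {
    comp <- attr(ok, "components")
    desc <- paste(vapply(comp, function(x) paste0("{", paste(x, collapse = ", "), "}"),
                         character(1)), collapse = " | ")
    stopf(paste0("entity graph is disconnected and no pseudo slots bridge it; ",
                 "components: %s"), desc)
  }
  invisible(TRUE)
}

#' @export
print.mosaic_dataset <- function(x, ...) {
  cat(sprintf("mosaic_dataset: %d batch(es) x %d modality(ies)\n",
              length(x$batch_ids), length(x$modality_ids)))
  grid <- matrix(".", nrow(x$presence), ncol(x$presence),
                 dimnames = dimnames(x$presence))
  for (b in x$batch_ids) for (m in names(x$matrices[[b]]))
    grid[b, m] <- if (x$provenance[paste(b, m, sep = ":")] == "pseudo") "p" else "X"
  print(grid, quote = FALSE)
  n_cells <- vapply(x$cell_ids, length, integer(1))
  cat("cells per batch:", paste(sprintf("%s=%d", names(n_cells), n_cells),
                                collapse = ", "), "\n")
  cat("connected:", isTRUE(entity_connected(x)), "\n")
  invisible(x)
}

#' @export
summary.mosaic_dataset <- function(object, ...) {
  print(object)
  cat("features per modality:",
      paste(sprintf("%s=%d", names(object$feature_names),
                    vapply(object$feature_names, length, integer(1))),
            collapse = ", "), "\n")
  invisible(object)
}

read_id_file <- function(path) {
  if (!file.exists(path)) stopf("id file not found: %s", path)
  readLines(path)
}

read_matrix_file <- function(path) {
  if (!file.exists(path)) stopf("matrix file not found: %s", path)
  x <- if (grepl("\\.mtx$", path)) {
    as_dense(Matrix::readMM(path))
  } else {
    as.matrix(utils::read.table(path, sep = "\t", header = FALSE))
  }
  storage.mode(x) <- "double"
  dimnames(x) <- NULL
  x
}

#' Load a mosaic dataset from a run-configuration file
#'
#' The configuration is a JSON file listing, for every present
#' (batch, modality) slot, a matrix file (Matrix Market `.mtx` or dense TSV)
#' plus sidecar files of cell ids (one per row) and feature names (one per
#' column). Paths are resolved relative to the configuration file. Optional
#' `pseudo_slots` declare missing slots to be filled by pseudo-counts.
#'
#' @param config_path path to the JSON configuration.
#' @return a validated, connected `mosaic_dataset`.
#' @export
read_mosaic <- function(config_path) {
  if (!file.exists(config_path)) stopf("config not found: %s", config_path)
  cfg <- jsonlite::read_json(config_path, simplifyVector = TRUE)
  base <- dirname(config_path)
  if (is.null(cfg$matrices) || nrow(cfg$matrices) == 0L)
    stopf("config declares no matrices")
  entries <- cfg$matrices
  mats <- list()
  prov <- character()
  for (i in seq_len(nrow(entries))) {
    e <- entries[i, ]
    x <- read_matrix_file(file.path(base, e$file))
    rownames(x) <- read_id_file(file.path(base, e$cells))
    colnames(x) <- read_id_file(file.path(base, e$features))
    if (is.null(mats[[e$batch]])) mats[[e$batch]] <- list()
    mats[[e$batch]][[e$modality]] <- x
    prov[paste(e$batch, e$modality, sep = ":")] <-
      if (!is.null(e$provenance) && !is.na(e$provenance)) e$provenance else "observed"
  }
  data <- mosaic_dataset(mats, provenance = prov,
                         pseudo_slots = cfg$pseudo_slots)
  check_connected(data)
  data
}

#' Write a mosaic dataset to disk
#'
#' Writes one Matrix Market file per grid slot plus sidecar cell-id and
#' feature-name TSVs and a JSON configuration, in the layout `read_mosaic()`
#' consumes; `read_mosaic(write_mosaic(data, dir))` round-trips exactly.
#'
#' @param data a `mosaic_dataset`.
#' @param dir output directory (created if absent).
#' @return path of the written configuration file, invisibly.
#' @export
write_mosaic <- function(data, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  entries <- NULL
  for (b in data$batch_ids) {
    writeLines(data$cell_ids[[b]], file.path(dir, paste0(b, "_cells.tsv")))
    for (m in names(data$matrices[[b]])) {
      fn <- sprintf("%s_%s.mtx", b, m)
      Matrix::writeMM(methods::as(methods::as(
        Matrix::Matrix(as_dense(mosaic_matrix(data, b, m)), sparse = TRUE),
        "generalMatrix"), "CsparseMatrix"), file.path(dir, fn))
      entries <- rbind(entries, data.frame(
        batch = b, modality = m, file = fn,
        cells = paste0(b, "_cells.tsv"),
        features = paste0(m, "_features.tsv"),
        provenance = data$provenance[paste(b, m, sep = ":")],
        stringsAsFactors = FALSE))
    }
  }
  for (m in names(data$feature_names))
    writeLines(data$feature_names[[m]],
               file.path(dir, paste0(m, "_features.tsv")))
  cfg <- list(matrices = entries)
  if (!is.null(data$pseudo_slots)) cfg$pseudo_slots <- data$pseudo_slots
  cfg_path <- file.path(dir, "mosaic.json")
  jsonlite::write_json(cfg, cfg_path, auto_unbox = TRUE, digits = NA)
  invisible(cfg_path)
}

#' Run configuration defaults
#'
#' Bundles the tunable parameters of an integration run. Defaults follow the
#' method's recommended settings: latent dimension `d = 30`, association
#' regularization `lambda = 0.001`, `k = 30` graph neighbors, pruning radius
#' `r = 1` (no pruning), 10\% mini-batches.
#'
#' @param d latent dimension (>= 2).
#' @param lambda_reg weight on matrix-specific association matrices.
#' @param k_neighbors total neighbors per cell in post-processing.
#' @param radius_r fraction of cross-batch edges kept per batch pair, (0, 1].
#' @param n_iters training iterations.
#' @param batch_frac fraction of rows/columns sampled per iteration, (0, 1].
#' @param learning_rate step size of the adaptive gradient updates.
#' @param checkpoint_every full-data loss evaluation interval (iterations).
#' @param seed integer RNG seed.
#' @return a list of class `run_config`.
#' @export
run_config <- function(d = 30, lambda_reg = 0.001, k_neighbors = 30,
                       radius_r = 1, n_iters = 4000, batch_frac = 0.1,
                       learning_rate = 0.01, checkpoint_every = 100,
                       seed = 0) {
  stopifnot(d >= 2, radius_r > 0, radius_r <= 1,
            batch_frac > 0, batch_frac <= 1, n_iters >= 1,
            learning_rate > 0)
  structure(list(d = as.integer(d), lambda_reg = lambda_reg,
                 k_neighbors = as.integer(k_neighbors), radius_r = radius_r,
                 n_iters = as.integer(n_iters), batch_frac = batch_frac,
                 learning_rate = learning_rate,
                 checkpoint_every = as.integer(checkpoint_every),
                 seed = as.integer(seed)),
            class = "run_config")
}
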