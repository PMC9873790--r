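#' Simulation parameters
#'
#' The generator emulates the structures the integration model exploits:
#' shared cluster (cell-type) structure across batches, a linear region-gene
#' coupling (marker genes drive their private regions' accessibility, and
#' gene means are proportional to summed region activity), a one-to-one
#' protein-gene coupling, additive per-batch feature offsets on the latent
#' (logit / log-mean) scale, and one designated rare cell type.
#'
#' @param n_batches number of batches (default 6).
#' @param n_types number of cell types shared across batches (default 16).
#' @param cells_per_type cells per non-rare type per batch (default 50).
#' @param n_genes number of genes (default 100).
#' @param markers_per_type disjoint marker genes per type (default 5;
#'   `n_types * markers_per_type <= n_genes`).
#' @param max_regions_per_gene each gene receives 1 to this many private
#'   regions (default 5).
#' @param n_background_regions regions mapped to no gene (default 20).
#' @param n_proteins proteins, each mapped 1-1 to a marker gene (default 20).
#' @param marker_strength logit-scale accessibility boost of a type's marker
#'   regions (default 2.5, a strong separation).
#' @param atac_type_sd sd of the type-specific logit offsets of every region
#'   (default 1; cell types differ in accessibility genome-wide, not only at
#'   marker regions).
#' @param logit_base baseline region accessibility logit (default -2).
#' @param rna_depth scale of gene expression means (default 5).
#' @param type_effect_sd sd of type-specific log-scale gene effects
#'   (default 0.2).
#' @param batch_effect_sd sd of per-batch per-feature latent offsets
#'   (default 0.3, mild).
#' @param nb_size negative-binomial size (inverse overdispersion) of RNA
#'   counts (default 10).
#' @param protein_noise_sd sd of log-normal protein noise (default 0.3).
#' @param rare_type_frac rare-type size as a fraction of a normal type
#'   (default 0.15); the last type is the rare one.
#' @param seed RNG seed.
#' @return a list of class `sim_params`.
#' @export
sim_params <- function(n_batches = 6, n_types = 16, cells_per_type = 50,
                       n_genes = 100, markers_per_type = 5,
                       max_regions_per_gene = 5, n_background_regions = 20,
                       n_proteins = 20, marker_strength = 2.5,
                       atac_type_sd = 1,
                       logit_base = -2, rna_depth = 5, type_effect_sd = 0.2,
                       batch_effect_sd = 0.3, nb_size = 10,
                       protein_noise_sd = 0.3, rare_type_frac = 0.15,
                       seed = 0) {
  p <- as.list(environment())
  with(p, {
    if (any(c(n_batches, n_types, cells_per_type, n_genes, n_proteins) < 1))
      stopf("all counts must be positive")
    if (rare_type_frac <= 0 || rare_type_frac >= 1)
      stopf("rare_type_frac must be in (0, 1)")
    if (n_types * markers_per_type > n_genes)
      stopf("infeasible sizes: need n_genes >= n_types * markers_per_type")
    if (n_proteins > n_types * markers_per_type)
      stopf("infeasible sizes: n_proteins exceeds marker gene pool")
  })
  structure(p, class = "sim_params")
}

#' Simulate a multi-batch tri-modal mosaic dataset with ground truth
#'
#' Generates paired gene expression, chromatin accessibility and protein
#' abundance matrices for every batch. Per type, region accessibility
#' probabilities are logistic in a baseline plus a marker boost (markers of a
#' type activate that type's private regions); gene means are proportional
#' to the summed activity of the gene's regions times a log-normal
#' type-specific effect; accessibility is Bernoulli with per-batch logit
#' shifts; expression is negative binomial with per-batch log-mean shifts;
#' protein is log-normal noise around `1 + mean` of the cognate gene. The
#' designated rare type has `rare_type_frac * cells_per_type` cells per
#' batch. Output is deterministic for a fixed seed.
#'
#' @param params a [sim_params()] object.
#' @return list with elements `data` (a `mosaic_dataset` with modalities
#'   rna/atac/protein per batch) and `truth` (class `sim_truth`: per-batch
#'   type labels, the rare type id, the region-gene association, the
#'   protein-gene map, noiseless per-type gene means and per-type
#'   ground-truth marker rankings).
#' @export
simulate_mosaic <- function(params = sim_params()) {
  p <- params
  set.seed(p$seed)
  gene_names <- sprintf("gene%03d", seq_len(p$n_genes))

  # region-gene association: 1-5 private regions per gene + background pool
  k_g <- sample.int(p$max_regions_per_gene, p$n_genes, replace = TRUE)
  owner <- rep(seq_len(p$n_genes), k_g)
  n_regions <- length(owner) + p$n_background_regions
  region_names <- sprintf("region%04d", seq_len(n_regions))
  assoc <- Matrix::sparseMatrix(i = seq_along(owner), j = owner, x = 1,
                                dims = c(n_regions, p$n_genes),
                                dimnames = list(region_names, gene_names))

  # marker blocks: disjoint genes per type
  marker_of <- matrix(0, p$n_types, p$n_genes)
  for (t in seq_len(p$n_types))
    marker_of[t, ((t - 1) * p$markers_per_type + 1):(t * p$markers_per_type)] <- 1

  region_offset <- stats::rnorm(n_regions, 0, 0.2)
  # per-type region logits: private regions inherit their gene's marker boost
  gene_boost <- p$marker_strength * marker_of          # types x genes
  region_logit <- matrix(p$logit_base, p$n_types, n_regions)
  region_logit[, seq_along(owner)] <- p$logit_base +
    gene_boost[, owner, drop = FALSE]
  region_logit <- sweep(region_logit, 2, region_offset, `+`) +
    matrix(stats::rnorm(p$n_types * n_regions, 0, p$atac_type_sd),
           p$n_types, n_regions)
  region_prob <- stats::plogis(region_logit)           # types x regions

  type_effect <- matrix(stats::rnorm(p$n_types * p$n_genes, 0, p$type_effect_sd),
                        p$n_types, p$n_genes)
  activity <- as_dense(region_prob %*% assoc)          # types x genes
  activity <- sweep(activity, 2, k_g, `/`)
  type_means <- p$rna_depth * activity * exp(type_effect)
  dimnames(type_means) <- list(paste0("type", seq_len(p$n_types)), gene_names)

  marker_pool <- which(colSums(marker_of) > 0)
  prot_genes <- sort(sample(marker_pool, p$n_proteins))
  protein_names <- sprintf("prot_%s", gene_names[prot_genes])
  pg_map <- stats::setNames(gene_names[prot_genes], protein_names)

  batch_gene_shift <- matrix(stats::rnorm(p$n_batches * p$n_genes, 0,
                                          p$batch_effect_sd),
                             p$n_batches, p$n_genes)
  batch_region_shift <- matrix(stats::rnorm(p$n_batches * n_regions, 0,
                                            p$batch_effect_sd),
                               p$n_batches, n_regions)
  batch_prot_shift <- matrix(stats::rnorm(p$n_batches * p$n_proteins, 0,
                                          p$batch_effect_sd),
                             p$n_batches, p$n_proteins)

  rare_type <- p$n_types
  n_per_type <- rep(p$cells_per_type, p$n_types)
  n_per_type[rare_type] <- max(1L, round(p$rare_type_frac * p$cells_per_type))

  matrices <- list(); labels <- list()
  for (b in seq_len(p$n_batches)) {
    lab <- rep(seq_len(p$n_types), n_per_type)
    n_cells <- length(lab)
    mu_rna <- type_means[lab, , drop = FALSE] *
      matrix(exp(batch_gene_shift[b, ]), n_cells, p$n_genes, byrow = TRUE)
    rna <- matrix(stats::rnbinom(n_cells * p$n_genes, mu = mu_rna,
                                 size = p$nb_size), n_cells, p$n_genes)
    pr_atac <- stats::plogis(region_logit[lab, , drop = FALSE] +
                               matrix(batch_region_shift[b, ], n_cells,
                                      n_regions, byrow = TRUE))
    atac <- matrix(stats::rbinom(n_cells * n_regions, 1, pr_atac),
                   n_cells, n_regions)
    mu_prot <- 1 + type_means[lab, prot_genes, drop = FALSE]
    prot <- mu_prot * exp(matrix(batch_prot_shift[b, ], n_cells,
                                 p$n_proteins, byrow = TRUE) +
                            matrix(stats::rnorm(n_cells * p$n_proteins, 0,
                                                p$protein_noise_sd),
                                   n_cells, p$n_proteins))
    bid <- paste0("batch", b)
    cid <- sprintf("%s_c%04d", bid, seq_len(n_cells))
    dimnames(rna) <- list(cid, gene_names)
    dimnames(atac) <- list(cid, region_names)
    dimnames(prot) <- list(cid, protein_names)
    matrices[[bid]] <- list(rna = rna, atac = atac, protein = prot)
    labels[[bid]] <- lab
  }

  data <- mosaic_dataset(matrices)
  rest_mean <- vapply(seq_len(p$n_types), function(t)
    colMeans(type_means[-t, , drop = FALSE]), numeric(p$n_genes))
  lfc <- log2(type_means) - log2(t(rest_mean))       # types x genes
  rankings <- lapply(seq_len(p$n_types), function(t)
    order(-lfc[t, ], seq_len(p$n_genes)))
  truth <- structure(list(
    labels = labels,
    batch = rep(names(labels), vapply(labels, length, integer(1))),
    rare_type = rare_type,
    region_gene_assoc = assoc,
    protein_gene_map = pg_map,
    type_means = type_means,
    lfc = lfc,
    marker_rankings = rankings,
    params = p), class = "sim_truth")
  list(data = data, truth = truth)
}

#' @export
print.sim_truth <- function(x, ...) {
  cat(sprintf("sim_truth: %d batches, %d types (rare type: %d), %d genes\n",
              length(x$labels), nrow(x$type_means), x$rare_type,
              ncol(x$type_means)))
  invisible(x)
}

#' Ground-truth marker ranking of one cell type
#'
#' Genes ordered by the log2 fold change of the noiseless type means (type
#' versus the mean of all other types); ties broken by ascending gene index.
#' The default `direction = "up"` ranks by signed fold change (most
#' over-expressed first), matching the biomarker notion a non-negative
#' factor score can recover; `direction = "absolute"` ranks by magnitude
#' regardless of sign (symmetric differential expression).
#'
#' @param truth a `sim_truth`.
#' @param type_id 1-based type index.
#' @param direction `"up"` (signed, default) or `"absolute"`.
#' @return character vector of gene names, strongest marker first.
#' @export
ground_truth_ranking <- function(truth, type_id,
                                 direction = c("up", "absolute")) {
  direction <- match.arg(direction)
  if (type_id < 1 || type_id > nrow(truth$type_means))
    stopf("type %s absent from the simulation", type_id)
  lfc <- truth$lfc[type_id, ]
  key <- if (direction == "up") -lfc else -abs(lfc)
  colnames(truth$type_means)[order(key, seq_along(lfc))]
}

# subset one batch of a dataset (and its labels) to the given cell indices
subset_batch <- function(data, truth, batch, idx) {
  for (m in names(data$matrices[[batch]]))
    data$matrices[[batch]][[m]] <-
      data$matrices[[batch]][[m]][idx, , drop = FALSE]
  data$cell_ids[[batch]] <- data$cell_ids[[batch]][idx]
  truth$labels[[batch]] <- truth$labels[[batch]][idx]
  list(data = data, truth = truth)
}

#' Derive a benchmark scenario from a simulated dataset
#'
#' Scenario constructors reshape a fully paired simulation into the layouts
#' used for benchmarking:
#' \describe{
#'   \item{unequal_composition}{remove all cells of 4 randomly chosen types
#'     from every batch (each batch retains 12 of 16 types).}
#'   \item{imbalanced_sizes}{subsample batches 1, 4 and 6 to one tenth of the
#'     size of each remaining batch.}
#'   \item{diagonal}{keep only accessibility for the first half of the
#'     batches and only gene expression for the second half; the missing
#'     expression slots are declared for pseudo-count filling.}
#'   \item{bimodal_bridge}{as `diagonal`, but the first batch of the second
#'     half keeps both modalities.}
#'   \item{triple_modal}{first third accessibility only, middle third protein
#'     only, last third expression only; pseudo-expression is declared for
#'     the accessibility batches and pseudo-protein for the accessibility and
#'     expression batches.}
#' }
#' Truth labels are filtered consistently.
#'
#' @param data a simulated `mosaic_dataset` (paired rna/atac/protein).
#' @param truth the matching `sim_truth`.
#' @param scenario scenario name.
#' @param n_drop types removed per batch for `unequal_composition`
#'   (default 4).
#' @param seed RNG seed for the random removals/subsamples.
#' @return list with reshaped `data` and `truth`.
#' @export
apply_scenario <- function(data, truth,
                           scenario = c("unequal_composition",
                                        "imbalanced_sizes", "diagonal",
                                        "bimodal_bridge", "triple_modal"),
                           n_drop = 4, seed = 0) {
  scenario <- match.arg(scenario)
  set.seed(seed)
  nb <- length(data$batch_ids)
  n_types <- nrow(truth$type_means)

  if (scenario == "unequal_composition") {
    for (b in data$batch_ids) {
      drop <- sample.int(n_types, n_drop)
      keep <- which(!(truth$labels[[b]] %in% drop))
      res <- subset_batch(data, truth, b, keep)
      data <- res$data; truth <- res$truth
    }
  } else if (scenario == "imbalanced_sizes") {
    small <- intersect(c(1, 4, 6), seq_len(nb))
    big <- setdiff(seq_len(nb), small)
    target <- max(1L, round(mean(vapply(data$cell_ids[big], length,
                                        integer(1))) / 10))
    for (bi in small) {
      b <- data$batch_ids[bi]
      keep <- sort(sample.int(length(data$cell_ids[[b]]), target))
      res <- subset_batch(data, truth, b, keep)
      data <- res$data; truth <- res$truth
    }
  } else if (scenario %in% c("diagonal", "bimodal_bridge")) {
    if (nb < 2) stopf("scenario needs at least 2 batches")
    half <- nb %/% 2
    pseudo <- NULL
    for (bi in seq_len(nb)) {
      b <- data$batch_ids[bi]
      keep_m <- if (bi <= half) "atac" else "rna"
      if (scenario == "bimodal_bridge" && bi == half + 1)
        keep_m <- c("atac", "rna")
      data$matrices[[b]] <- data$matrices[[b]][keep_m]
      if (identical(keep_m, "atac"))
        pseudo <- rbind(pseudo, data.frame(batch = b, modality = "rna"))
    }
    data <- rebuild_dataset(data, pseudo)
  } else if (scenario == "triple_modal") {
    if (nb < 3) stopf("scenario needs at least 3 batches")
    third <- ceiling(nb / 3)
    pseudo <- NULL
    for (bi in seq_len(nb)) {
      b <- data$batch_ids[bi]
      keep_m <- if (bi <= third) "atac"
        else if (bi <= 2 * third) "protein" else "rna"
      data$matrices[[b]] <- data$matrices[[b]][keep_m]
      if (keep_m == "atac")
        pseudo <- rbind(pseudo,
                        data.frame(batch = b, modality = c("rna", "protein")))
      if (keep_m == "rna")
        pseudo <- rbind(pseudo, data.frame(batch = b, modality = "protein"))
    }
    data <- rebuild_dataset(data, pseudo)
  }
  if (scenario %in% c("unequal_composition", "imbalanced_sizes"))
    data <- rebuild_dataset(data, data$pseudo_slots)
  truth$batch <- rep(names(truth$labels),
                     vapply(truth$labels, length, integer(1)))
  list(data = data, truth = truth)
}

# re-validate a dataset after in-place surgery on its matrices
rebuild_dataset <- function(data, pseudo_slots = NULL) {
  mosaic_dataset(data$matrices, provenance = data$provenance,
                 pseudo_slots = pseudo_slots)
}
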