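#' Gene-activity pseudo-counts from chromatin accessibility
#'
#' For every gene, sums the region counts of all regions associated with the
#' gene (upstream window or gene body) and binarizes the sum; the binary
#' matrix serves as a pseudo-gene-expression matrix bridging accessibility
#' batches to the gene modality.
#'
#' @param R cell x region matrix of accessibility counts.
#' @param assoc region x gene binary association matrix
#'   (see [map_regions_to_genes()]).
#' @return binary cell x gene matrix.
#' @export
pseudo_rna_from_atac <- function(R, assoc) {
  if (ncol(R) != nrow(assoc))
    stopf("region dimension mismatch: %d regions vs %d assoc rows",
          ncol(R), nrow(assoc))
  G <- as_dense(as_dense(R) %*% as_dense(assoc))
  out <- (G > 0) + 0
  rownames(out) <- rownames(R)
  colnames(out) <- colnames(assoc)
  out
}

#' Pseudo-protein counts from gene expression
#'
#' Each protein has a one-to-one cognate gene; its pseudo-count is a copy of
#' that gene's expression column.
#'
#' @param G cell x gene matrix.
#' @param pg_map named character vector mapping protein name -> gene name;
#'   every gene must be a column of `G`.
#' @return cell x protein matrix.
#' @export
pseudo_protein_from_rna <- function(G, pg_map) {
  G <- as_dense(G)
  missing <- setdiff(unname(pg_map), colnames(G))
  if (length(missing))
    stopf("proteins map to genes absent from the matrix: %s",
          paste(names(pg_map)[pg_map %in% missing], collapse = ", "))
  P <- G[, unname(pg_map), drop = FALSE]
  colnames(P) <- names(pg_map)
  P
}

#' Pseudo-protein counts from chromatin accessibility
#'
#' Composition of [pseudo_rna_from_atac()] and [pseudo_protein_from_rna()]:
#' binarized gene activity is computed first, then the cognate-gene columns
#' are copied, so values are in `{0, 1}`.
#'
#' @inheritParams pseudo_rna_from_atac
#' @inheritParams pseudo_protein_from_rna
#' @return binary cell x protein matrix.
#' @export
pseudo_protein_from_atac <- function(R, assoc, pg_map) {
  pseudo_protein_from_rna(pseudo_rna_from_atac(R, assoc), pg_map)
}

#' Fill missing grid slots with pseudo-count matrices
#'
#' Fills the declared pseudo slots of a mosaic dataset (or, with
#' `only_required = FALSE`, every fillable missing slot) from the observed
#' matrices of the same batch: missing gene expression is derived from
#' accessibility via `assoc`; missing protein from gene expression (observed
#' preferred over pseudo) or, failing that, from accessibility. Filled
#' matrices are marked with provenance `"pseudo"`.
#'
#' @param data a `mosaic_dataset` with `pseudo_slots` declared (or any
#'   dataset when `only_required = FALSE`).
#' @param assoc region x gene association matrix (needed for gene slots).
#' @param pg_map protein -> gene map (needed for protein slots).
#' @param only_required fill only declared `pseudo_slots` (default) rather
#'   than every missing slot that can be bridged.
#' @return the dataset with pseudo matrices inserted.
#' @export
fill_pseudo <- function(data, assoc = NULL, pg_map = NULL,
                        only_required = TRUE) {
  slots <- if (only_required) {
    data$pseudo_slots
  } else {
    expand.grid(batch = data$batch_ids, modality = intersect(
      c("rna", "protein"), data$modality_ids), stringsAsFactors = FALSE)
  }
  if (is.null(slots) || nrow(slots) == 0L) return(data)
  for (i in seq_len(nrow(slots))) {
    b <- slots$batch[i]; m <- slots$modality[i]
    if (isTRUE(data$presence[b, m])) next
    have <- names(data$matrices[[b]])
    x <- NULL
    if (m == "rna" && "atac" %in% have) {
      if (is.null(assoc)) stopf("assoc required to fill (%s, rna)", b)
      x <- pseudo_rna_from_atac(mosaic_matrix(data, b, "atac"), assoc)
    } else if (m == "protein") {
      if (is.null(pg_map)) stopf("pg_map required to fill (%s, protein)", b)
      if ("rna" %in% have) {
        x <- pseudo_protein_from_rna(mosaic_matrix(data, b, "rna"), pg_map)
      } else if ("atac" %in% have) {
        if (is.null(assoc)) stopf("assoc required to fill (%s, protein)", b)
        x <- pseudo_protein_from_atac(mosaic_matrix(data, b, "atac"),
                                      assoc, pg_map)
      }
    }
    if (is.null(x))
      stopf("cannot fill slot (%s, %s): no usable source modality", b, m)
    rownames(x) <- data$cell_ids[[b]]
    data$matrices[[b]][[m]] <- x
    data$presence[b, m] <- TRUE
    data$provenance[paste(b, m, sep = ":")] <- "pseudo"
    if (is.null(data$feature_names[[m]])) data$feature_names[[m]] <- colnames(x)
  }
  # consume declared slots that are now filled
  if (!is.null(data$pseudo_slots)) {
    done <- data$presence[cbind(data$pseudo_slots$batch,
                                data$pseudo_slots$modality)]
    data$pseudo_slots <- data$pseudo_slots[!done, , drop = FALSE]
    if (nrow(data$pseudo_slots) == 0L) data$pseudo_slots <- NULL
  }
  data
}
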