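#' @keywords internal
"_PACKAGE"

# Key used to address one (batch, modality) slot of the grid.
matrix_key <- function(batch, modality) paste(batch, modality, sep = "\r")

split_key <- function(key) strsplit(key, "\r", fixed = TRUE)[[1L]]

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

as_dense <- function(x) {
  if (inherits(x, "Matrix")) as.matrix(x) else x
}

#' Cell-type composition of a label vector
#'
#' Returns the percentage of cells carrying each label, the standard
#' "composition barplot" quantity used when comparing batches with unequal
#' cell-type make-up.
#'
#' @param labels vector of per-cell type labels.
#' @return named numeric vector of percentages summing to 100.
#' @export
type_composition <- function(labels) {
  if (length(labels) == 0L) stopf("empty label vector")
  tab <- table(labels)
  pct <- 100 * as.vector(tab) / length(labels)
  names(pct) <- names(tab)
  pct
}

#' Composition shift when one cell type is subsampled
#'
#' Given a batch of `n_total` cells of which `n_type` belong to one cell
#' type, compute the percentage of that type before and after subsampling it
#' down to `n_keep` cells (all other cells retained). Used to construct
#' batches with disproportionate cell-type composition, e.g. downsampling the
#' dominant B-cell population of a spleen batch.
#'
#' @param n_total total cells in the batch.
#' @param n_type cells of the focal type before subsampling.
#' @param n_keep cells of the focal type kept.
#' @return named numeric vector `c(before =, after =)`, in percent.
#' @export
#' @examples
#' subsample_composition(4382, 2621, 100)
subsample_composition <- function(n_total, n_type, n_keep) {
  if (n_type > n_total) stopf("n_type exceeds n_total")
  if (n_keep > n_type) stopf("n_keep exceeds n_type")
  before <- 100 * n_type / n_total
  after <- 100 * n_keep / (n_total - n_type + n_keep)
  c(before = before, after = after)
}

#' Subsample one cell type within a label vector
#'
#' @param labels per-cell labels.
#' @param type label value (or values) to subsample jointly.
#' @param n_keep number of cells of `type` to keep.
#' @return integer indices of the retained cells, in original order.
#' @export
subsample_type <- function(labels, type, n_keep) {
  idx <- which(labels %in% type)
  if (n_keep > length(idx)) stopf("n_keep exceeds population of type")
  keep <- sort(sample(idx, n_keep))
  sort(c(setdiff(seq_along(labels), idx), keep))
}
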