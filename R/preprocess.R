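#' Normalize one count matrix
#'
#' Per-modality normalization applied before factorization. `quantile` forces
#' every cell (row) onto the mean empirical distribution over the rows of the
#' same matrix (gene expression); `quantile_log` applies `log(1 + x)` first
#' (protein abundance); `binarize` thresholds at zero (chromatin
#' accessibility and pseudo-gene-activity matrices). Ties in ranks receive
#' the mean of the tied reference values, so within-row rank order is
#' preserved and all row sums agree.
#'
#' @param x non-negative cell x feature matrix.
#' @param scheme one of `"quantile"`, `"quantile_log"`, `"binarize"`.
#' @return normalized matrix of the same shape and dimnames.
#' @export
normalize_counts <- function(x, scheme = c("quantile", "quantile_log", "binarize")) {
  scheme <- match.arg(scheme)
  x <- as_dense(x)
  if (any(x < 0)) stopf("negative entries; normalization expects counts")
  out <- switch(scheme,
    binarize = (x > 0) + 0,
    quantile = quantile_rows(x),
    quantile_log = quantile_rows(log1p(x)))
  dimnames(out) <- dimnames(x)
  out
}

# quantile-normalize rows against the mean sorted profile of the matrix;
# tied entries receive the mean of the tied reference values, so row sums
# are identical across rows and within-row rank order is preserved
quantile_rows <- function(x) {
  ref <- colMeans(t(apply(x, 1, sort)))
  out <- x
  for (r in seq_len(nrow(x))) {
    v <- numeric(ncol(x))
    v[order(x[r, ])] <- ref
    out[r, ] <- stats::ave(v, x[r, ], FUN = mean)
  }
  out
}

# default normalization scheme per modality id; unknown modalities (e.g.
# motif deviations, which are signed) pass through untouched
modality_scheme <- function(modality, provenance = "observed") {
  if (modality == "rna" && provenance == "pseudo") return("binarize")
  switch(modality,
         rna = "quantile",
         atac = "binarize",
         protein = "quantile_log",
         NA_character_)
}

normalize_mosaic <- function(data) {
  for (b in data$batch_ids) for (m in names(data$matrices[[b]])) {
    sch <- modality_scheme(m, data$provenance[paste(b, m, sep = ":")])
    if (!is.na(sch))
      data$matrices[[b]][[m]] <- normalize_counts(mosaic_matrix(data, b, m), sch)
  }
  data
}

#' Select highly variable genes
#'
#' Ranks genes by the variance-to-mean dispersion of `log(1 + x)` and returns
#' the indices of the top `n`; ties are broken by ascending gene index, so
#' the selection is deterministic.
#'
#' @param x cell x gene count matrix.
#' @param n number of genes to keep (`n <=` gene count).
#' @return integer vector of `n` gene column indices, most dispersed first.
#' @export
select_hvg <- function(x, n) {
  x <- as_dense(x)
  if (n > ncol(x)) stopf("n exceeds number of genes")
  lx <- log1p(x)
  mu <- colMeans(lx)
  v <- apply(lx, 2, stats::var)
  disp <- ifelse(mu > 0, v / mu, 0)
  order(-disp, seq_along(disp))[seq_len(n)]
}

#' Read a BED file of regions
#'
#' BED 3+ with 0-based half-open coordinates; converted to `GRanges`
#' (1-based closed).
#'
#' @param path BED file path.
#' @return `GRanges` of the regions, named `chrom:start-end` in BED
#'   coordinates.
#' @export
read_regions_bed <- function(path) {
  bed <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE)
  if (any(bed[[2]] >= bed[[3]])) stopf("malformed interval: start >= end")
  gr <- GenomicRanges::GRanges(bed[[1]],
                               IRanges::IRanges(bed[[2]] + 1L, bed[[3]]))
  names(gr) <- sprintf("%s:%d-%d", bed[[1]], bed[[2]], bed[[3]])
  gr
}

#' Read a gene annotation table
#'
#' TSV with columns chrom, start, end, strand, name; coordinates 0-based
#' half-open (BED convention).
#'
#' @param path file path.
#' @return data.frame with those columns.
#' @export
read_gene_annotation <- function(path) {
  g <- utils::read.table(path, sep = "\t", header = FALSE,
                         stringsAsFactors = FALSE,
                         col.names = c("chrom", "start", "end", "strand", "name"))
  if (any(g$start >= g$end)) stopf("malformed gene interval: start >= end")
  g
}

#' Map chromatin regions to genes
#'
#' A region is associated with a gene when it overlaps (by any base pair) the
#' gene body or the strand-adjusted upstream promoter window
#' `[TSS - window_bp, TSS)`. All coordinates are 0-based half-open.
#'
#' @param regions `GRanges` from [read_regions_bed()], or a data.frame with
#'   columns chrom, start, end (0-based half-open).
#' @param genes data.frame with columns chrom, start, end, strand, name
#'   (0-based half-open; TSS = start on `+`, end on `-`).
#' @param window_bp upstream window size, default 2000.
#' @return sparse binary `dgCMatrix`, regions x genes.
#' @export
map_regions_to_genes <- function(regions, genes, window_bp = 2000) {
  if (is.data.frame(regions)) {
    if (any(regions$start >= regions$end)) stopf("malformed interval: start >= end")
    rn <- regions$name %||% sprintf("%s:%d-%d", regions$chrom,
                                    regions$start, regions$end)
    regions <- GenomicRanges::GRanges(
      regions$chrom, IRanges::IRanges(regions$start + 1L, regions$end))
    names(regions) <- rn
  }
  stopifnot(is.data.frame(genes))
  # gene body plus upstream window, in 0-based half-open coordinates:
  # + strand: [start - w, end); - strand: [start, end + w)
  ext_start <- ifelse(genes$strand == "+", pmax(genes$start - window_bp, 0),
                      genes$start)
  ext_end <- ifelse(genes$strand == "+", genes$end, genes$end + window_bp)
  gene_gr <- GenomicRanges::GRanges(
    genes$chrom, IRanges::IRanges(ext_start + 1L, ext_end))
  hits <- GenomicRanges::findOverlaps(regions, gene_gr)
  assoc <- Matrix::sparseMatrix(
    i = S4Vectors::queryHits(hits), j = S4Vectors::subjectHits(hits), x = 1,
    dims = c(length(regions), nrow(genes)),
    dimnames = list(names(regions), genes$name))
  assoc@x[] <- 1  # collapse duplicated hits to binary
  methods::as(assoc, "CsparseMatrix")
}

#' Read a two-column protein-to-gene map
#'
#' @param path TSV with columns protein, gene (no header).
#' @return named character vector, `names` = proteins, values = genes.
#' @export
read_protein_gene_map <- function(path) {
  pg <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE)
  stats::setNames(pg[[2]], pg[[1]])
}

#' Latent semantic indexing of a binary accessibility matrix
#'
#' TF-IDF transform followed by truncated SVD; the embedding is the
#' `n_components` leading left singular vectors scaled by their singular
#' values. Used to reduce accessibility matrices before the kNN-agreement
#' metric.
#'
#' @param x binary cell x region matrix.
#' @param n_components number of components, `< min(dim(x))`.
#' @return cell x `n_components` embedding matrix.
#' @export
lsi_embed <- function(x, n_components = 30) {
  x <- as_dense(x)
  if (n_components >= min(dim(x))) stopf("n_components must be < min(dim)")
  tf <- x / pmax(rowSums(x), 1)
  idf <- log1p(nrow(x) / pmax(colSums(x > 0), 1))
  ti <- sweep(tf, 2, idf, `*`)
  sv <- svd(ti, nu = n_components, nv = 0)
  emb <- sv$u %*% diag(sv$d[seq_len(n_components)], n_components)
  rownames(emb) <- rownames(x)
  emb
}

# TF-IDF matrix alone (exposed for tests of the low-rank property)
tfidf_matrix <- function(x) {
  x <- as_dense(x)
  tf <- x / pmax(rowSums(x), 1)
  idf <- log1p(nrow(x) / pmax(colSums(x > 0), 1))
  sweep(tf, 2, idf, `*`)
}
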