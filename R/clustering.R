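# Ward hierarchical clustering of cell lines on the signature genes, tree
# cutting, and clustered-image-map (heat map + dendrograms) export.
#
# Convention: Ward linkage is computed by the Lance-Williams "ward.D" update
# on *squared* Euclidean distances of per-gene z-scored values. With that
# convention a merge height equals the Ward merge cost
# 2 * |A||B| / (|A|+|B|) * ||mean_A - mean_B||^2, i.e. twice the increase in
# within-cluster sum of squares, and heights are non-decreasing.

#' Subset an expression matrix to the signature genes and z-score each gene
#'
#' Each signature gene row is centered and scaled to unit variance across
#' cell lines, the standard preprocessing for clustered-image-map displays.
#' Zero-variance rows become all-zero with a warning.
#'
#' @param expr An [expression_matrix()].
#' @param sig A [select_signature()] result (or a character vector of genes).
#' @return An [expression_matrix()] restricted to the signature genes.
#' @export
standardize_signature_matrix <- function(expr, sig) {
  genes <- if (inherits(sig, "signature")) signature_genes(sig)
           else as.character(sig)
  missing <- setdiff(genes, rownames(expr))
  if (length(missing))
    stop("signature gene(s) absent from expression matrix: ",
         paste(missing, collapse = ", "))
  m <- unclass(expr)[genes, , drop = FALSE]
  mu <- rowMeans(m, na.rm = TRUE)
  sd_ <- apply(m, 1, stats::sd, na.rm = TRUE)
  flat <- !is.finite(sd_) | sd_ == 0
  if (any(flat)) {
    warning("zero-variance signature gene(s) set to all-zero rows: ",
            paste(genes[flat], collapse = ", "))
    sd_[flat] <- 1
    mu[flat] <- m[flat, 1]
  }
  z <- (m - mu) / sd_
  z[flat & is.na(rowSums(z)), ] <- 0
  z[flat, ] <- 0
  expression_matrix(z, genes, colnames(expr))
}

#' Ward hierarchical clustering along one axis of an expression matrix
#'
#' Agglomerative Ward linkage on Euclidean geometry (see the convention note
#' above). Deterministic given the input; ties in merge cost resolve to the
#' smallest object index, as in [stats::hclust()].
#'
#' @param matrix An [expression_matrix()] (or plain numeric matrix),
#'   genes x cell lines.
#' @param axis `"lines"` (cluster cell lines, the columns; default) or
#'   `"genes"` (cluster the rows).
#' @return An object of class `c("ward_dendrogram", "hclust")`.
#' @export
ward_cluster <- function(matrix, axis = c("lines", "genes")) {
  axis <- match.arg(axis)
  m <- unclass(matrix)
  if (axis == "lines") m <- t(m)
  if (nrow(m) < 2) stop("need at least 2 objects to cluster on axis ", axis)
  d <- stats::dist(m)
  hc <- stats::hclust(d^2, method = "ward.D")
  hc$axis <- axis
  class(hc) <- c("ward_dendrogram", "hclust")
  hc
}

#' Cut a Ward dendrogram into k clusters
#'
#' Labels are assigned 1..k by first appearance in the dendrogram leaf
#' order, so cluster 1 is always the leftmost cluster of the tree.
#'
#' @param dend A [ward_cluster()] result.
#' @param k Number of clusters, between 1 and the number of leaves.
#' @return A named integer vector (object id -> cluster label) of class
#'   `"cluster_assignment"`, with attribute `k`.
#' @export
cut_tree <- function(dend, k) {
  n <- length(dend$labels)
  if (k < 1 || k > n) stop("k must be between 1 and ", n)
  raw <- stats::cutree(stats::as.hclust(dend), k = k)
  # relabel by first appearance in leaf order
  leaf_labels <- raw[dend$order]
  mapping <- stats::setNames(seq_along(unique(leaf_labels)),
                             unique(leaf_labels))
  out <- as.integer(mapping[as.character(raw)])
  names(out) <- names(raw)
  attr(out, "k") <- as.integer(k)
  class(out) <- "cluster_assignment"
  out
}

#' Export a dendrogram in newick format
#'
#' @param dend A [ward_cluster()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_dendrogram_newick <- function(dend, path) {
  ape::write.tree(ape::as.phylo(stats::as.hclust(dend)), file = path)
  invisible(path)
}

#' Render a clustered image map (heat map with dendrograms)
#'
#' Presentational only: the matrix values, both dendrograms, and an optional
#' per-cell-line sensitivity annotation bar are drawn; nothing is recomputed.
#'
#' @param matrix The (typically z-scored) genes x lines matrix.
#' @param row_dend [ward_cluster()] result for the genes (rows).
#' @param col_dend [ward_cluster()] result for the cell lines (columns).
#' @param annotations Optional named vector/factor of per-cell-line labels
#'   (e.g. sensitive/resistant) drawn as a column annotation bar.
#' @param path Output file; extension selects the device (png or svg... any
#'   extension pheatmap supports).
#' @return `path`, invisibly.
#' @export
render_cim <- function(matrix, row_dend, col_dend, annotations = NULL,
                       path) {
  m <- unclass(matrix)
  if (!identical(sort(row_dend$labels), sort(rownames(m))))
    stop("row dendrogram labels do not match matrix rows")
  if (!identical(sort(col_dend$labels), sort(colnames(m))))
    stop("column dendrogram labels do not match matrix columns")
  ann <- NA
  if (!is.null(annotations)) {
    ann <- data.frame(sensitivity = factor(annotations[colnames(m)]),
                      row.names = colnames(m))
  }
  pheatmap::pheatmap(m,
                     cluster_rows = stats::as.hclust(row_dend),
                     cluster_cols = stats::as.hclust(col_dend),
                     annotation_col = if (is.data.frame(ann)) ann else NA,
                     silent = TRUE, filename = path,
                     fontsize_row = 6, fontsize_col = 6)
  invisible(path)
}
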