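# COMPARE-style correlation ranking: every gene's expression profile is
# correlated with the per-cell-line log10(IC50) response profile, genes are
# sorted by the correlation coefficient R, and a top-k positive ("standard",
# resistance-associated) plus top-k negative ("reverse",
# sensitivity-associated) signature is selected.

#' Correlate every gene with the drug-response profile
#'
#' For each gene with at least 3 pairwise-complete observations across the
#' shared cell lines, computes the Pearson (or, optionally, Spearman)
#' correlation with the response and a two-sided p-value from the
#' t-distribution with `n_used - 2` degrees of freedom. Zero-variance genes
#' are excluded with a warning. Results are sorted by `r` descending with
#' ties broken by gene id, and ranked 1..n.
#'
#' @param expr An [expression_matrix()].
#' @param resp A [response_vector()].
#' @param method `"pearson"` (default) or `"spearman"`.
#' @param fdr If `TRUE`, append a Benjamini-Hochberg adjusted p-value column
#'   (`p_bh`); an extension over the plain R-ordered list, for downstream
#'   filtering.
#' @return A data frame of class `"compare_result"` with columns `gene_id`,
#'   `r`, `p`, `n_used`, `rank` (and `p_bh` when `fdr = TRUE`).
#' @export
compare_correlate <- function(expr, resp, method = c("pearson", "spearman"),
                              fdr = FALSE) {
  method <- match.arg(method)
  if (!nrow(expr) || !ncol(expr)) stop("empty expression matrix")
  shared <- intersect(colnames(expr), names(resp))
  if (length(shared) < 3)
    stop("need >= 3 shared cell lines between expression matrix and ",
         "response; found ", length(shared))
  x <- t(unclass(expr)[, shared, drop = FALSE])  # lines x genes
  y <- as.numeric(unclass(resp)[shared])

  n_used <- colSums(!is.na(x) & !is.na(y))
  r <- suppressWarnings(as.vector(
    stats::cor(x, y, use = "pairwise.complete.obs", method = method)))

  usable <- n_used >= 3
  degenerate <- usable & !is.finite(r)  # zero variance over the used lines
  if (any(degenerate))
    warning("excluding ", sum(degenerate),
            " zero-variance gene(s): ",
            paste(utils::head(colnames(x)[degenerate], 5), collapse = ", "),
            if (sum(degenerate) > 5) ", ...")
  if (any(!usable))
    warning("excluding ", sum(!usable),
            " gene(s) with fewer than 3 pairwise-complete values")
  keep <- usable & is.finite(r)
  res <- data.frame(gene_id = colnames(x)[keep], r = r[keep],
                    n_used = n_used[keep], stringsAsFactors = FALSE)
  tstat <- res$r * sqrt(res$n_used - 2) / sqrt(pmax(1 - res$r^2, 0))
  res$p <- 2 * stats::pt(-abs(tstat), df = res$n_used - 2)
  res$p[res$r^2 >= 1] <- 0
  if (fdr) res$p_bh <- stats::p.adjust(res$p, method = "BH")
  ord <- order(-res$r, res$gene_id)
  res <- res[ord, c("gene_id", "r", "p", "n_used",
                    if (fdr) "p_bh")]
  res$rank <- seq_len(nrow(res))
  rownames(res) <- NULL
  class(res) <- c("compare_result", "data.frame")
  res
}

#' Select a top-k positive / top-k negative gene signature
#'
#' Standard COMPARE semantics: the top `k_pos` genes with `r > 0` are
#' resistance-associated (greater expression, greater IC50); the top `k_neg`
#' genes with `r < 0` are sensitivity-associated ("reverse" COMPARE). If
#' fewer genes qualify on either side, the shorter list is returned with a
#' warning. Ties in `r` at the k-th slot resolve to the lexicographically
#' smaller gene id.
#'
#' @param results A [compare_correlate()] result.
#' @param k_pos,k_neg Number of genes to select on each side (default 20).
#' @return A list of class `"signature"` with fields `positive` (gene ids,
#'   `r` descending), `negative` (gene ids, `r` ascending), `k_pos`, `k_neg`.
#' @export
select_signature <- function(results, k_pos = 20, k_neg = 20) {
  if (!nrow(results)) stop("empty COMPARE result")
  if (k_pos <= 0 || k_neg <= 0) stop("k_pos and k_neg must be positive")
  pos <- results[results$r > 0, ]
  pos <- pos[order(-pos$r, pos$gene_id), ]
  neg <- results[results$r < 0, ]
  neg <- neg[order(neg$r, neg$gene_id), ]
  if (nrow(pos) < k_pos)
    warning("only ", nrow(pos), " positively correlated gene(s) available ",
            "(requested ", k_pos, ")")
  if (nrow(neg) < k_neg)
    warning("only ", nrow(neg), " negatively correlated gene(s) available ",
            "(requested ", k_neg, ")")
  structure(list(positive = utils::head(pos$gene_id, k_pos),
                 negative = utils::head(neg$gene_id, k_neg),
                 k_pos = as.integer(k_pos), k_neg = as.integer(k_neg)),
            class = "signature")
}

#' Gene ids in a signature
#' @param x A `"signature"` object.
#' @return Character vector: positive then negative gene ids.
#' @export
signature_genes <- function(x) c(x$positive, x$negative)

#' @export
print.signature <- function(x, ...) {
  cat("Signature:", length(x$positive), "resistance-associated (r > 0) +",
      length(x$negative), "sensitivity-associated (r < 0) genes\n")
  cat("  positive:", paste(utils::head(x$positive, 8), collapse = ", "),
      if (length(x$positive) > 8) "...", "\n")
  cat("  negative:", paste(utils::head(x$negative, 8), collapse = ", "),
      if (length(x$negative) > 8) "...", "\n")
  invisible(x)
}
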