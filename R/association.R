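# Sensitive/resistant partition of the cell-line panel by a log10(IC50)
# threshold, cluster-by-sensitivity contingency tables, and the Pearson
# chi-square association test (no continuity correction).

#' Partition cell lines into sensitive and resistant
#'
#' Lines with log10(IC50) strictly below the threshold are sensitive; lines
#' at or above it are resistant (a value exactly equal to the threshold is
#' resistant -- the documented tie rule). `"median"` resolves the threshold
#' to the sample median of the response.
#'
#' @param resp A [response_vector()].
#' @param threshold Numeric threshold in log10 molar, or `"median"`
#'   (default).
#' @return A named factor (levels `sensitive`, `resistant`) of class
#'   `"sensitivity_labels"`, with attribute `threshold`.
#' @export
partition_by_threshold <- function(resp, threshold = "median") {
  if (!length(resp)) stop("empty response vector")
  y <- unclass(resp)
  thr <- if (identical(threshold, "median")) stats::median(y)
         else as.numeric(threshold)
  lab <- factor(ifelse(y < thr, "sensitive", "resistant"),
                levels = c("sensitive", "resistant"))
  names(lab) <- names(y)
  attr(lab, "threshold") <- thr
  class(lab) <- c("sensitivity_labels", "factor")
  lab
}

#' Build a cluster x sensitivity contingency table
#'
#' @param clusters A [cut_tree()] assignment.
#' @param labels A [partition_by_threshold()] labeling over the same cell
#'   lines.
#' @return An integer matrix (clusters x `c("sensitive", "resistant")`) of
#'   class `"contingency_table"`.
#' @export
build_contingency <- function(clusters, labels) {
  ids_c <- names(clusters)
  ids_l <- names(labels)
  if (!setequal(ids_c, ids_l))
    stop("cluster and label id sets differ; only in clusters: ",
         paste(setdiff(ids_c, ids_l), collapse = ", "),
         "; only in labels: ", paste(setdiff(ids_l, ids_c), collapse = ", "))
  lab <- factor(as.character(labels)[match(ids_c, ids_l)],
                levels = c("sensitive", "resistant"))
  k <- max(clusters)
  tab <- table(factor(paste0("Cluster ", unclass(clusters)),
                      levels = paste0("Cluster ", seq_len(k))), lab)
  counts <- matrix(as.integer(tab), nrow = k,
                   dimnames = list(rownames(tab), colnames(tab)))
  class(counts) <- c("contingency_table", class(counts))
  counts
}

#' Pearson chi-square test of a contingency table
#'
#' The classic Pearson statistic without continuity correction, with
#' `df = (rows - 1) * (cols - 1)` and an upper-tail chi-square p-value.
#' Expected counts below 5 trigger a warning (not an error), and an optional
#' Monte-Carlo p-value can be computed alongside (never replacing) the
#' asymptotic one.
#'
#' @param table A [build_contingency()] table (or plain count matrix) with
#'   at least 2 rows and 2 columns and no all-zero row or column.
#' @param monte_carlo_B If > 0, also compute a Monte-Carlo p-value from this
#'   many simulated tables with fixed margins (uses the current RNG state).
#' @return A list of class `"chisq_assoc"` with `statistic`, `df`, `p.value`,
#'   `expected`, `small_expected` (logical), and optionally `p.monte_carlo`.
#' @export
chi_square_test <- function(table, monte_carlo_B = 0) {
  counts <- unclass(table)
  if (nrow(counts) < 2 || ncol(counts) < 2)
    stop("need at least a 2 x 2 table")
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0))
    stop("zero row or column marginal; drop empty categories first")
  res <- suppressWarnings(stats::chisq.test(counts, correct = FALSE))
  small <- any(res$expected < 5)
  if (small)
    warning("expected count(s) below 5; the asymptotic chi-square p-value ",
            "may be inaccurate (consider monte_carlo_B > 0)")
  out <- list(statistic = unname(res$statistic),
              df = unname(res$parameter),
              p.value = res$p.value,
              expected = res$expected,
              small_expected = small)
  if (monte_carlo_B > 0) {
    mc <- suppressWarnings(stats::chisq.test(counts, correct = FALSE,
                                             simulate.p.value = TRUE,
                                             B = monte_carlo_B))
    out$p.monte_carlo <- mc$p.value
  }
  class(out) <- "chisq_assoc"
  out
}

#' @export
print.chisq_assoc <- function(x, ...) {
  cat(sprintf("Pearson chi-square = %.4f, df = %d, p = %.3g\n",
              x$statistic, x$df, x$p.value))
  if (!is.null(x$p.monte_carlo))
    cat(sprintf("Monte-Carlo p = %.3g\n", x$p.monte_carlo))
  invisible(x)
}
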