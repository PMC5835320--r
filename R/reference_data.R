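# Loaders for the small curated reference tables shipped with the package:
# published arsenic trioxide cytotoxicity values for paired
# sensitive/resistant cell lines, and the published cluster-by-sensitivity
# counts for the 58-line panel.

#' Published arsenic trioxide IC50 values for paired cell lines
#'
#' Mean IC50 (uM) and sd for three sensitive/resistant cell-line pairs
#' (CCRF-CEM vs CEM/ADR5000 leukemia, U87.MG vs U87.MG dEGFR glioblastoma,
#' HCT116 p53+/+ vs p53-/- colon carcinoma), as reported for the resazurin
#' viability assay.
#'
#' @return A data frame with columns `cellline`, `ic50_uM`, `sd_uM`, `pair`,
#'   `role` (`parental`/`resistant`).
#' @export
as2o3_ic50_table <- function() {
  path <- system.file("extdata", "as2o3_cellline_ic50.csv",
                      package = "comparetox", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Published cluster-by-sensitivity counts for the 58-line panel
#'
#' The 4 x 2 contingency table of Ward cluster membership against the
#' sensitive/resistant partition of the panel at log10(IC50) = -5.45 M, as
#' reported for arsenic trioxide.
#'
#' @return An integer matrix of class `"contingency_table"`
#'   (4 clusters x sensitive/resistant).
#' @export
as2o3_cluster_counts <- function() {
  path <- system.file("extdata", "as2o3_cluster_counts.tsv",
                      package = "comparetox", mustWork = TRUE)
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  counts <- as.matrix(df[, c("sensitive", "resistant")])
  storage.mode(counts) <- "integer"
  dimnames(counts) <- list(df$cluster, c("sensitive", "resistant"))
  class(counts) <- c("contingency_table", class(counts))
  counts
}
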