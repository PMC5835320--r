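# End-to-end orchestration: compare -> signature -> cluster -> associate,
# with optional motif-enrichment and over-representation stages, per-stage
# TSV outputs, and a deterministic JSON run manifest (config echo, seed,
# package version, per-output checksums; no timestamps, so identical inputs
# give byte-identical manifests).

#' Pipeline configuration with the workflow's standard defaults
#'
#' Defaults mirror the published workflow where it states them: a 20 + 20
#' gene signature, 4 cell-line clusters, a median log10(IC50) partition
#' threshold (a fixed threshold such as -5.45 can be supplied instead), a
#' 50 kb promoter window, 100 shuffle rounds, and a 1.3 -log10(p) ORA
#' cutoff.
#'
#' @param expr_path Path to the expression matrix TSV (header of cell-line
#'   ids, first column gene ids).
#' @param response_path Path to the response CSV/TSV (`cellline`,
#'   `log10_ic50`).
#' @param out_dir Output directory (created if absent).
#' @param k_pos,k_neg Signature sizes (default 20/20).
#' @param cluster_k Number of cell-line clusters (default 4).
#' @param threshold `"median"` or a numeric log10 molar threshold.
#' @param annotation_path,genome_path,pwm_path Optional motif-stage inputs
#'   (gene annotation TSV, genome FASTA, JASPAR PFM file); the stage is
#'   skipped when any is `NULL`.
#' @param window_bp,n_shuffles Motif-stage window (default 50000) and
#'   shuffle count (default 100).
#' @param gmt_path Optional gene-set GMT; the ORA stage is skipped when
#'   `NULL`.
#' @param edges_path Optional curated edge TSV for network assembly.
#' @param ora_cutoff `-log10(p)` cutoff for ORA (default 1.3).
#' @param seed Integer seed for the stochastic stages.
#' @return A list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(expr_path, response_path, out_dir,
                            k_pos = 20, k_neg = 20, cluster_k = 4,
                            threshold = "median",
                            annotation_path = NULL, genome_path = NULL,
                            pwm_path = NULL, window_bp = 50000,
                            n_shuffles = 100, gmt_path = NULL,
                            edges_path = NULL, ora_cutoff = 1.3, seed = 1) {
  structure(list(expr_path = expr_path, response_path = response_path,
                 out_dir = out_dir, k_pos = k_pos, k_neg = k_neg,
                 cluster_k = cluster_k, threshold = threshold,
                 annotation_path = annotation_path,
                 genome_path = genome_path, pwm_path = pwm_path,
                 window_bp = window_bp, n_shuffles = n_shuffles,
                 gmt_path = gmt_path, edges_path = edges_path,
                 ora_cutoff = ora_cutoff, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full drug-sensitivity pharmacogenomics pipeline
#'
#' Executes correlation ranking, signature selection, Ward clustering of
#' cell lines on the z-scored signature matrix, the sensitivity partition
#' and chi-square association, and (when their inputs are configured)
#' promoter motif enrichment and gene-set over-representation with network
#' assembly. Every stage writes a TSV next to the manifest; any stage
#' failure aborts with an error naming the stage.
#'
#' @param config A [pipeline_config()].
#' @return The run manifest (list), invisibly; also written as
#'   `manifest.json` in `out_dir`.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "pipeline_config"))
    stop("config must be a pipeline_config")
  required <- c("expr_path", "response_path")
  optional <- c("annotation_path", "genome_path", "pwm_path", "gmt_path",
                "edges_path")
  for (f in c(required, optional)) {
    p <- config[[f]]
    if (f %in% required && is.null(p)) stop("missing required input: ", f)
    if (!is.null(p) && !file.exists(p))
      stop("input path does not exist (", f, "): ", p)
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  stages <- list()
  outputs <- character(0)
  run_stage <- function(name, fun) {
    tryCatch(fun(), error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  out_file <- function(name) file.path(config$out_dir, name)

  expr <- run_stage("read_inputs",
                    function() read_expression_matrix(config$expr_path))
  resp <- run_stage("read_inputs", function() read_response(config$response_path))

  # -- compare ----------------------------------------------------------------
  cmp <- run_stage("compare", function() compare_correlate(expr, resp))
  utils::write.table(cmp, out_file("compare.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  outputs <- c(outputs, "compare.tsv")
  stages$compare <- list(status = "ok", n_genes = nrow(cmp))

  # -- signature --------------------------------------------------------------
  sig <- run_stage("signature",
                   function() select_signature(cmp, config$k_pos, config$k_neg))
  sig_df <- data.frame(gene_id = signature_genes(sig),
                       side = rep(c("positive", "negative"),
                                  c(length(sig$positive),
                                    length(sig$negative))))
  utils::write.table(sig_df, out_file("signature.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  outputs <- c(outputs, "signature.tsv")
  stages$signature <- list(status = "ok", size = nrow(sig_df))

  # -- cluster ----------------------------------------------------------------
  clu <- run_stage("cluster", function() {
    z <- standardize_signature_matrix(expr, sig)
    line_dend <- ward_cluster(z, axis = "lines")
    gene_dend <- ward_cluster(z, axis = "genes")
    assign <- cut_tree(line_dend, config$cluster_k)
    list(z = z, line_dend = line_dend, gene_dend = gene_dend,
         assign = assign)
  })
  utils::write.table(
    data.frame(cellline = names(clu$assign),
               cluster = as.integer(clu$assign)),
    out_file("clusters.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  write_dendrogram_newick(clu$line_dend, out_file("lines_dendrogram.nwk"))
  outputs <- c(outputs, "clusters.tsv", "lines_dendrogram.nwk")
  stages$cluster <- list(status = "ok", k = config$cluster_k)

  # -- associate --------------------------------------------------------------
  assoc <- run_stage("associate", function() {
    labels <- partition_by_threshold(resp, config$threshold)
    tab <- build_contingency(clu$assign, labels)
    test <- suppressWarnings(chi_square_test(tab))
    list(labels = labels, table = tab, test = test)
  })
  utils::write.table(
    data.frame(cluster = rownames(assoc$table),
               sensitive = assoc$table[, "sensitive"],
               resistant = assoc$table[, "resistant"]),
    out_file("contingency.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  jsonlite::write_json(
    list(statistic = assoc$test$statistic, df = assoc$test$df,
         p = assoc$test$p.value,
         threshold = attr(assoc$labels, "threshold"),
         threshold_rule = if (identical(config$threshold, "median"))
           "sample median" else "fixed",
         tie_rule = "value equal to threshold labeled resistant",
         small_expected = assoc$test$small_expected),
    out_file("association.json"), auto_unbox = TRUE, digits = NA)
  outputs <- c(outputs, "contingency.tsv", "association.json")
  stages$associate <- list(status = "ok", p = assoc$test$p.value)

  # -- motifs (optional) ------------------------------------------------------
  if (!is.null(config$annotation_path) && !is.null(config$genome_path) &&
      !is.null(config$pwm_path)) {
    motifs <- run_stage("motifs", function() {
      proms <- extract_promoters(signature_genes(sig),
                                 config$annotation_path, config$genome_path,
                                 config$window_bp)
      write_bed(proms$intervals, out_file("promoters.bed"))
      enrich_motifs(proms, parse_jaspar(config$pwm_path),
                    n_shuffles = config$n_shuffles, seed = config$seed)
    })
    utils::write.table(motifs, out_file("motifs.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    outputs <- c(outputs, "promoters.bed", "motifs.tsv")
    stages$motifs <- list(status = "ok", n_motifs = nrow(motifs))
  } else {
    stages$motifs <- list(status = "skipped",
                          reason = "annotation/genome/PWM input not configured")
  }

  # -- enrichment + network (optional) ---------------------------------------
  if (!is.null(config$gmt_path)) {
    ora <- run_stage("enrich", function() {
      ora_fisher(signature_genes(sig), read_gmt(config$gmt_path),
                 universe = rownames(expr),
                 cutoff_neg_log10_p = config$ora_cutoff)
    })
    utils::write.table(ora, out_file("ora.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    net <- run_stage("enrich", function() {
      assemble_network(signature_genes(sig), edges = config$edges_path)
    })
    write_network(net, out_file("network.graphml"), format = "graphml")
    outputs <- c(outputs, "ora.tsv", "network.graphml")
    stages$enrich <- list(status = "ok",
                          n_significant = sum(ora$passes_cutoff))
  } else {
    stages$enrich <- list(status = "skipped",
                          reason = "gene-set GMT input not configured")
  }

  checksums <- as.list(tools::md5sum(file.path(config$out_dir,
                                               sort(outputs))))
  names(checksums) <- sort(outputs)
  manifest <- list(
    package = "comparetox",
    version = as.character(utils::packageVersion("comparetox")),
    seed = config$seed,
    config = unclass(config),
    stages = stages,
    checksums = checksums)
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  invisible(manifest)
}
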