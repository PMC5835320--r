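# Functional-group classification from a curated determinant table, gene-set
# over-representation by Fisher's right-tailed exact test with a 1.3
# -log10(p) cutoff, and curated interaction-network assembly/export. This is
# an open substitute for proprietary pathway software: enrichment runs
# against user-supplied GMT collections, and the network comes from a
# curated edge table, not from a closed interaction database.

#' Curated functional groups of arsenic trioxide response determinants
#'
#' The packaged table of genes/proteins reported as determinants of cancer
#' cell responsiveness to arsenic trioxide, each assigned one primary
#' functional group (oxidative stress response, drug transport, DNA repair,
#' cell cycle/proliferation, tumor suppressors/oncogenes, signal
#' transduction, metabolic pathways, cytoskeleton, apoptosis). The `label`
#' column preserves the published designation verbatim (including composite
#' and non-HGNC labels); `symbol` is the normalized token used for matching.
#'
#' @return A data frame with columns `label`, `symbol`, `group`, `source`.
#' @export
functional_group_table <- function() {
  path <- system.file("extdata", "as2o3_functional_groups.tsv",
                      package = "comparetox", mustWork = TRUE)
  utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                    stringsAsFactors = FALSE)
}

#' Classify genes into curated functional groups
#'
#' Case-insensitive match of query ids against the `symbol` column of the
#' functional-group table; unmatched ids map to `"unclassified"`.
#'
#' @param genes Character vector of gene ids.
#' @param table A functional-group table (default:
#'   [functional_group_table()]).
#' @return A named character vector gene -> group.
#' @export
classify_functional_groups <- function(genes, table = functional_group_table()) {
  idx <- match(toupper(genes), toupper(table$symbol))
  out <- ifelse(is.na(idx), "unclassified", table$group[idx])
  names(out) <- genes
  out
}

#' Gene-set over-representation by Fisher's right-tailed exact test
#'
#' For every gene set, tests whether the overlap with the query list is
#' larger than expected by chance among the universe, using the right tail
#' of the hypergeometric distribution (equivalently, the one-sided Fisher
#' exact test on the 2x2 in-set/out-set x in-query/out-query table). Sets
#' are intersected with the universe before testing.
#'
#' @param query Character vector of query gene ids; must be drawn from the
#'   universe (ids outside it are dropped with a warning).
#' @param sets A [gene_set_collection()].
#' @param universe Character vector of background gene ids.
#' @param cutoff_neg_log10_p Significance cutoff on `-log10(p)`
#'   (default 1.3, i.e. p <= 0.05); `passes_cutoff` uses `>=`.
#' @return A data frame of class `"ora_result"`, sorted by p ascending, with
#'   columns `set_name`, `overlap`, `set_size`, `query_size`,
#'   `universe_size`, `p`, `p_bh` (Benjamini-Hochberg, reported alongside
#'   the raw p that the cutoff applies to), `neg_log10_p`, `passes_cutoff`.
#' @export
ora_fisher <- function(query, sets, universe, cutoff_neg_log10_p = 1.3) {
  universe <- unique(as.character(universe))
  query <- unique(as.character(query))
  if (!length(universe)) stop("empty universe")
  if (!length(query)) stop("empty query")
  outside <- setdiff(query, universe)
  if (length(outside)) {
    warning("dropping ", length(outside),
            " query gene(s) outside the universe: ",
            paste(utils::head(outside, 5), collapse = ", "))
    query <- intersect(query, universe)
    if (!length(query)) stop("no query genes left inside the universe")
  }
  N <- length(universe)
  n <- length(query)
  rows <- lapply(names(sets), function(nm) {
    members <- intersect(sets[[nm]]$genes, universe)
    K <- length(members)
    k <- length(intersect(members, query))
    p <- if (K == 0) 1 else
      stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(set_name = nm, overlap = k, set_size = K, query_size = n,
               universe_size = N, p = p, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res$p_bh <- stats::p.adjust(res$p, method = "BH")
  res$neg_log10_p <- -log10(res$p)
  res$passes_cutoff <- res$neg_log10_p >= cutoff_neg_log10_p - 1e-12
  res <- res[order(res$p, res$set_name), ]
  rownames(res) <- NULL
  class(res) <- c("ora_result", "data.frame")
  res
}

#' Assemble a functional-group-labeled gene interaction network
#'
#' Builds a graph over the supplied genes with curated direct/indirect
#' edges. Edges touching genes outside the node list, and self-loops, are
#' dropped with a warning.
#'
#' @param genes Character vector of node gene ids.
#' @param groups A functional-group table (default
#'   [functional_group_table()]); used to label nodes.
#' @param edges Data frame (or TSV path) with columns `a`, `b`, `type`
#'   (`direct`/`indirect`), `provenance`. May be empty for a node-only
#'   network.
#' @return A list of class `"gene_network"` with `graph` (igraph), `nodes`
#'   (data frame id/group), `edges` (the retained edge table).
#' @export
assemble_network <- function(genes, groups = functional_group_table(),
                             edges = NULL) {
  genes <- unique(as.character(genes))
  if (is.character(edges) && length(edges) == 1) {
    edges <- utils::read.table(edges, header = TRUE, sep = "\t", quote = "",
                               stringsAsFactors = FALSE)
  }
  if (is.null(edges) || !nrow(edges)) {
    edges <- data.frame(a = character(0), b = character(0),
                        type = character(0), provenance = character(0),
                        stringsAsFactors = FALSE)
  }
  need <- c("a", "b", "type", "provenance")
  if (!all(need %in% names(edges)))
    stop("edge table must have columns: ", paste(need, collapse = ", "))
  bad_type <- !edges$type %in% c("direct", "indirect")
  if (any(bad_type))
    stop("edge line ", which(bad_type)[1],
         ": interaction type must be 'direct' or 'indirect'")
  loops <- edges$a == edges$b
  if (any(loops)) {
    warning("dropping ", sum(loops), " self-loop edge(s)")
    edges <- edges[!loops, ]
  }
  outside <- !(edges$a %in% genes & edges$b %in% genes)
  if (any(outside)) {
    warning("dropping ", sum(outside),
            " edge(s) with endpoint(s) outside the gene list")
    edges <- edges[!outside, ]
  }
  nodes <- data.frame(id = genes,
                      group = unname(classify_functional_groups(genes, groups)),
                      stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = nodes)
  structure(list(graph = g, nodes = nodes, edges = edges),
            class = "gene_network")
}

#' Export a gene network
#'
#' @param net An [assemble_network()] result.
#' @param path Output path.
#' @param format `"tsv"` (edge list) or `"graphml"`.
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path, format = c("tsv", "graphml")) {
  format <- match.arg(format)
  if (format == "tsv") {
    utils::write.table(net$edges, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    igraph::write_graph(net$graph, path, format = "graphml")
  }
  invisible(path)
}
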