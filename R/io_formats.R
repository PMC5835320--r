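# Readers/writers and validated containers for every external format the
# pipeline touches. All readers reject malformed input with an error naming
# the offending line; writers round-trip exactly with their readers.
#
# Coordinate convention: genomic intervals are 0-based, half-open [start, end)
# everywhere inside the package (the BED convention); 1-based coordinates
# appear only in messages, labeled as such.

# ---- ExpressionMatrix --------------------------------------------------------

#' Construct a validated expression matrix
#'
#' A genes x cell-lines matrix of log2-scale expression values with unique
#' row (gene) and column (cell line) identifiers. Missing values are allowed
#' but every cell line must retain at least 3 observed values so that
#' pairwise-complete correlations downstream are defined.
#'
#' @param values Numeric matrix, genes in rows, cell lines in columns.
#' @param gene_ids Character vector of unique gene identifiers
#'   (default: `rownames(values)`).
#' @param cellline_ids Character vector of unique cell-line identifiers
#'   (default: `colnames(values)`).
#' @return A numeric matrix of class `"expression_matrix"` with dimnames set.
#' @export
expression_matrix <- function(values, gene_ids = rownames(values),
                              cellline_ids = colnames(values)) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(gene_ids) || is.null(cellline_ids))
    stop("gene and cell-line identifiers are required")
  gene_ids <- as.character(gene_ids)
  cellline_ids <- as.character(cellline_ids)
  if (length(gene_ids) != nrow(values))
    stop("length of gene_ids (", length(gene_ids), ") does not match row count (",
         nrow(values), ")")
  if (length(cellline_ids) != ncol(values))
    stop("length of cellline_ids (", length(cellline_ids),
         ") does not match column count (", ncol(values), ")")
  if (anyDuplicated(gene_ids))
    stop("duplicated gene ids: ",
         paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ", "))
  if (anyDuplicated(cellline_ids))
    stop("duplicated cell-line ids: ",
         paste(unique(cellline_ids[duplicated(cellline_ids)]), collapse = ", "))
  n_obs <- colSums(!is.na(values))
  min_obs <- min(3L, nrow(values))  # small matrices can't reach 3
  if (any(n_obs < min_obs))
    stop("cell line(s) with fewer than ", min_obs, " non-missing values: ",
         paste(cellline_ids[n_obs < min_obs], collapse = ", "))
  dimnames(values) <- list(gene_ids, cellline_ids)
  class(values) <- c("expression_matrix", class(values))
  values
}

#' Read a genes x cell-lines expression matrix
#'
#' Supports a plain TSV dialect (header row of cell-line ids, first column of
#' gene ids) and the GCT dialect (two preamble lines, then Name/Description
#' columns). Duplicate gene-id rows are collapsed to their per-cell mean with
#' a warning, mirroring probe-to-gene summarization.
#'
#' @param path Path to the file.
#' @param dialect `"tsv"` or `"gct"`.
#' @param missing_token String representing a missing value (default `"NA"`).
#' @return An [expression_matrix()].
#' @export
read_expression_matrix <- function(path, dialect = c("tsv", "gct"),
                                   missing_token = "NA") {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file does not exist: ", path)
  lines <- readLines(path, warn = FALSE)
  if (dialect == "gct") {
    if (length(lines) < 3) stop("empty or truncated GCT file: ", path)
    lines <- lines[-(1:2)]
  }
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2) stop("empty expression file: ", path)
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  id_cols <- if (dialect == "gct") 2L else 1L
  cellline_ids <- header[-seq_len(id_cols)]
  body <- strsplit(lines[-1], "\t", fixed = TRUE)
  n_fields <- id_cols + length(cellline_ids)
  gene_ids <- character(length(body))
  values <- matrix(NA_real_, nrow = length(body), ncol = length(cellline_ids))
  for (i in seq_along(body)) {
    f <- body[[i]]
    if (length(f) != n_fields)
      stop("line ", i + 1L, ": expected ", n_fields, " fields, found ", length(f))
    gene_ids[i] <- f[1]
    cells <- f[-seq_len(id_cols)]
    miss <- cells == missing_token | cells == ""
    num <- suppressWarnings(as.numeric(cells))
    bad <- which(is.na(num) & !miss)
    if (length(bad))
      stop("non-numeric value ", dQuote(cells[bad[1]]), " at row ", gene_ids[i],
           ", column ", cellline_ids[bad[1]])
    num[miss] <- NA_real_
    values[i, ] <- num
  }
  if (anyDuplicated(gene_ids)) {
    dups <- unique(gene_ids[duplicated(gene_ids)])
    warning("collapsing ", length(dups), " duplicated gene id(s) by mean: ",
            paste(utils::head(dups, 5), collapse = ", "),
            if (length(dups) > 5) ", ...")
    values <- rowsum(values, gene_ids, na.rm = TRUE) /
      rowsum((!is.na(values)) + 0, gene_ids)
    values[!is.finite(values)] <- NA_real_
    gene_ids <- rownames(values)
  }
  expression_matrix(values, gene_ids, cellline_ids)
}

#' Write an expression matrix as TSV
#'
#' @param expr An [expression_matrix()] (or plain matrix with dimnames).
#' @param path Output path.
#' @param missing_token Token used for missing values.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(expr, path, missing_token = "NA") {
  df <- data.frame(gene_id = rownames(expr), as.data.frame(unclass(expr)),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = missing_token)
  invisible(path)
}

# ---- ResponseVector ----------------------------------------------------------

#' Construct a per-cell-line drug-response vector
#'
#' Holds log10(IC50) in molar units per cell line; this is the target profile
#' that COMPARE-style correlation ranks genes against.
#'
#' @param log10_ic50 Numeric vector of finite log10 molar IC50 values.
#' @param cellline_ids Unique cell-line identifiers
#'   (default: `names(log10_ic50)`).
#' @return A named numeric vector of class `"response_vector"`.
#' @export
response_vector <- function(log10_ic50, cellline_ids = names(log10_ic50)) {
  log10_ic50 <- as.numeric(log10_ic50)
  if (is.null(cellline_ids)) stop("cell-line ids are required")
  cellline_ids <- as.character(cellline_ids)
  if (length(cellline_ids) != length(log10_ic50))
    stop("id and value lengths differ")
  if (anyDuplicated(cellline_ids))
    stop("duplicated cell-line ids: ",
         paste(unique(cellline_ids[duplicated(cellline_ids)]), collapse = ", "))
  if (any(!is.finite(log10_ic50)))
    stop("non-finite log10(IC50) for: ",
         paste(cellline_ids[!is.finite(log10_ic50)], collapse = ", "))
  names(log10_ic50) <- cellline_ids
  class(log10_ic50) <- "response_vector"
  log10_ic50
}

#' Read a per-cell-line response table
#'
#' Expects a CSV/TSV with columns `cellline` and `log10_ic50` (header
#' required; separator sniffed from the extension).
#'
#' @param path Path to the table.
#' @return A [response_vector()].
#' @export
read_response <- function(path) {
  if (!file.exists(path)) stop("file does not exist: ", path)
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  need <- c("cellline", "log10_ic50")
  if (!all(need %in% names(df)))
    stop("response table must have columns: ", paste(need, collapse = ", "))
  response_vector(df$log10_ic50, df$cellline)
}

# ---- GenomicInterval / BED ---------------------------------------------------

#' Construct a set of genomic intervals (0-based, half-open)
#'
#' @param chrom Character chromosome names.
#' @param start Integer 0-based start positions (inclusive).
#' @param end Integer end positions (exclusive), strictly greater than start.
#' @param name Interval names (default `"."`).
#' @param strand `"+"` or `"-"` per interval (default `"+"`).
#' @return A data frame of class `"genomic_intervals"` with columns
#'   chrom/start/end/name/strand.
#' @export
genomic_intervals <- function(chrom, start, end, name = ".", strand = "+") {
  n <- length(chrom)
  df <- data.frame(chrom = as.character(chrom),
                   start = as.integer(start), end = as.integer(end),
                   name = rep_len(as.character(name), n),
                   strand = rep_len(as.character(strand), n),
                   stringsAsFactors = FALSE)
  bad <- which(df$start < 0L)
  if (length(bad)) stop("negative start at interval ", bad[1])
  bad <- which(df$start >= df$end)
  if (length(bad))
    stop("start >= end at interval ", bad[1], " (", df$chrom[bad[1]], ":",
         df$start[bad[1]], "-", df$end[bad[1]], ")")
  if (!all(df$strand %in% c("+", "-")))
    stop("strand must be '+' or '-'")
  class(df) <- c("genomic_intervals", "data.frame")
  df
}

#' Read a BED file of promoter (or other) intervals
#'
#' Accepts BED3 to BED6; 0-based half-open coordinates are preserved
#' unchanged. Missing name/strand columns default to `"."` / `"+"`.
#'
#' @param path Path to the BED file.
#' @return A [genomic_intervals()] data frame.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("file does not exist: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#") &
                   !startsWith(lines, "track")]
  if (!length(lines)) stop("empty BED file: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  out <- vector("list", length(fields))
  for (i in seq_along(fields)) {
    f <- fields[[i]]
    if (length(f) < 3) stop("line ", i, ": BED requires >= 3 fields")
    start <- suppressWarnings(as.integer(f[2]))
    end <- suppressWarnings(as.integer(f[3]))
    if (is.na(start) || is.na(end))
      stop("line ", i, ": non-integer coordinates")
    if (start < 0) stop("line ", i, ": negative start")
    if (start >= end) stop("line ", i, ": start >= end")
    out[[i]] <- data.frame(
      chrom = f[1], start = start, end = end,
      name = if (length(f) >= 4) f[4] else ".",
      strand = if (length(f) >= 6) f[6] else "+",
      stringsAsFactors = FALSE)
  }
  df <- do.call(rbind, out)
  genomic_intervals(df$chrom, df$start, df$end, df$name, df$strand)
}

#' Write intervals to a BED6 file
#'
#' @param intervals A [genomic_intervals()] data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(intervals, path) {
  df <- data.frame(intervals$chrom, intervals$start, intervals$end,
                   intervals$name, 0L, intervals$strand)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# ---- PWM / JASPAR ------------------------------------------------------------

#' Construct a position probability matrix
#'
#' @param motif_id Motif identifier.
#' @param matrix 4 x L numeric matrix of per-column probabilities,
#'   rows in A, C, G, T order. Columns must each sum to 1 (tolerance 1e-9).
#' @param background Length-4 background nucleotide distribution
#'   (default uniform), summing to 1.
#' @param pseudocount Pseudocount recorded from parsing (default 0.01).
#' @return A list of class `"pwm"`.
#' @export
pwm <- function(motif_id, matrix, background = rep(0.25, 4),
                pseudocount = 0.01) {
  matrix <- as.matrix(matrix)
  if (nrow(matrix) != 4) stop("PWM must have 4 rows (A, C, G, T)")
  if (ncol(matrix) < 1) stop("PWM must have at least one column")
  if (pseudocount <= 0) stop("pseudocount must be positive")
  sums <- colSums(matrix)
  if (any(abs(sums - 1) > 1e-9))
    stop("PWM columns must sum to 1; column ", which(abs(sums - 1) > 1e-9)[1],
         " sums to ", sums[which(abs(sums - 1) > 1e-9)[1]])
  if (abs(sum(background) - 1) > 1e-9) stop("background must sum to 1")
  rownames(matrix) <- c("A", "C", "G", "T")
  structure(list(motif_id = as.character(motif_id), matrix = matrix,
                 background = background, pseudocount = pseudocount),
            class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat("PWM", x$motif_id, "(", ncol(x$matrix), "bp )\n")
  print(round(x$matrix, 3))
  invisible(x)
}

#' Parse JASPAR-format position frequency matrices
#'
#' Reads the JASPAR PFM text dialect: a `>` header line per motif followed by
#' four rows of counts for A, C, G and T (either bare numbers or the
#' bracketed `A [ 1 2 3 ]` form). Counts plus a pseudocount are normalized
#' per column to probabilities.
#'
#' @param path Path to a JASPAR PFM file.
#' @param pseudocount Pseudocount added to every count before normalization.
#' @return A list of [pwm()] objects.
#' @export
parse_jaspar <- function(path, pseudocount = 0.01) {
  if (!file.exists(path)) stop("file does not exist: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  heads <- which(startsWith(lines, ">"))
  if (!length(heads)) stop("no '>' motif headers found in ", path)
  bounds <- c(heads, length(lines) + 1L)
  out <- vector("list", length(heads))
  for (m in seq_along(heads)) {
    block <- lines[(bounds[m] + 1L):(bounds[m + 1L] - 1L)]
    id <- sub("^>\\s*", "", lines[heads[m]])
    id <- strsplit(id, "\\s+")[[1]][1]
    if (length(block) != 4)
      stop("motif ", id, ": expected 4 nucleotide rows, found ", length(block))
    counts <- lapply(block, function(row) {
      row <- gsub("^[ACGTacgt]\\s*", "", row)
      row <- gsub("[][]", " ", row)
      vals <- suppressWarnings(as.numeric(strsplit(trimws(row), "\\s+")[[1]]))
      if (anyNA(vals)) stop("motif ", id, ": non-numeric count row")
      vals
    })
    lens <- lengths(counts)
    if (length(unique(lens)) != 1)
      stop("motif ", id, ": unequal row lengths (",
           paste(lens, collapse = ", "), ")")
    mat <- do.call(rbind, counts) + pseudocount
    mat <- sweep(mat, 2, colSums(mat), "/")
    out[[m]] <- pwm(id, mat, pseudocount = pseudocount)
  }
  out
}

# ---- GeneSetCollection / GMT -------------------------------------------------

#' Construct a gene-set collection
#'
#' @param sets Named list; each element is a list with `description` (string)
#'   and `genes` (non-empty character vector).
#' @return A list of class `"gene_set_collection"`.
#' @export
gene_set_collection <- function(sets) {
  if (!length(sets)) stop("empty gene-set collection")
  if (is.null(names(sets)) || any(!nzchar(names(sets))))
    stop("every gene set must be named")
  if (anyDuplicated(names(sets)))
    stop("duplicated set name: ",
         paste(unique(names(sets)[duplicated(names(sets))]), collapse = ", "))
  for (nm in names(sets)) {
    if (!length(sets[[nm]]$genes))
      stop("gene set ", nm, " has no members")
    sets[[nm]]$genes <- as.character(sets[[nm]]$genes)
  }
  structure(sets, class = "gene_set_collection")
}

#' Read a GMT gene-set file
#'
#' Tab-separated lines: set name, description, then one or more member genes.
#'
#' @param path Path to the GMT file.
#' @return A [gene_set_collection()].
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("file does not exist: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("empty GMT file: ", path)
  sets <- list()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3)
      stop("line ", i, ": GMT requires >= 3 tab-separated fields")
    if (f[1] %in% names(sets)) stop("line ", i, ": duplicated set name ", f[1])
    sets[[f[1]]] <- list(description = f[2], genes = f[-(1:2)])
  }
  gene_set_collection(sets)
}

#' Write a gene-set collection as GMT
#'
#' @param sets A [gene_set_collection()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, sets[[nm]]$description, sets[[nm]]$genes), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
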