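# Promoter window extraction, log-odds PWM scanning, and motif enrichment
# against a dinucleotide-shuffle null.
#
# The enrichment statistic: T = mean over promoters of the best log-odds hit
# score. The null is built by dinucleotide-shuffling every promoter
# independently n_shuffles times and recomputing T, giving mu0 and sigma0;
# z = (mu0 - T) / sigma0 so that *negative z means enriched*, and
# p = Phi(z) is the one-sided normal tail. This statistic is an open
# stand-in for database motif screens whose internals are proprietary or
# unpublished; it shares their sign convention but not their exact values.

.NTS <- c("A", "C", "G", "T")

# encode a sequence string as integers 1..4 (A,C,G,T), 5 for anything else
encode_seq <- function(seq) {
  codes <- match(strsplit(toupper(seq), "")[[1]], .NTS)
  codes[is.na(codes)] <- 5L
  codes
}

decode_seq <- function(codes) paste(c(.NTS, "N")[codes], collapse = "")

# complement in code space: A<->T, C<->G, N->N
revcomp_codes <- function(codes) rev(c(4L, 3L, 2L, 1L, 5L)[codes])

# log2-odds score matrix with a 5th all-zero row: ambiguous bases (N)
# contribute the background expectation, score 0
pwm_score_matrix <- function(pwm) {
  s <- log2(pmax(pwm$matrix, 1e-12) / pwm$background)
  rbind(s, 0)
}

scan_codes <- function(codes, S5) {
  L <- ncol(S5)
  n_pos <- length(codes) - L + 1L
  sc <- numeric(n_pos)
  for (j in seq_len(L)) sc <- sc + unname(S5[codes[j:(j + n_pos - 1L)], j])
  sc
}

#' Best log-odds PWM hit in a sequence
#'
#' Scores `sum(log2(P_pwm / P_background))` per column at every offset on
#' both strands and returns the maximum. Ambiguous bases (N) score 0, the
#' background expectation.
#'
#' @param seq A nucleotide string (or `DNAString`).
#' @param pwm A [pwm()].
#' @return A list with `score` (best log2-odds), `start` (1-based offset of
#'   the best window on the input sequence), `strand` (`"+"` or `"-"`).
#' @export
scan_best_score <- function(seq, pwm) {
  codes <- encode_seq(as.character(seq))
  L <- ncol(pwm$matrix)
  if (length(codes) < L)
    stop("sequence (", length(codes), " bp) shorter than motif (", L, " bp)")
  S5 <- pwm_score_matrix(pwm)
  fwd <- scan_codes(codes, S5)
  rev_ <- scan_codes(revcomp_codes(codes), S5)
  n_pos <- length(fwd)
  if (max(fwd) >= max(rev_)) {
    i <- which.max(fwd)
    list(score = fwd[i], start = i, strand = "+")
  } else {
    i <- which.max(rev_)
    # window i on the reverse strand starts at n - (i + L - 1) + 1 forward
    list(score = rev_[i], start = n_pos - i + 1L, strand = "-")
  }
}

# best score only, over both strands, given precomputed codes + rc codes
best_score_only <- function(codes, rc, S5) {
  max(max(scan_codes(codes, S5)), max(scan_codes(rc, S5)))
}

#' Dinucleotide-preserving sequence shuffle
#'
#' Altschul-Erickson doublet shuffle: a uniformly random Eulerian-walk
#' rearrangement that exactly preserves the dinucleotide (and hence
#' mononucleotide) composition, the standard null for motif statistics.
#' Uses the current RNG state.
#'
#' @param seq Nucleotide string.
#' @return A shuffled string with identical dinucleotide counts.
#' @export
dinucleotide_shuffle <- function(seq) {
  codes <- encode_seq(as.character(seq))
  decode_seq(shuffle_codes(codes))
}

shuffle_codes <- function(codes) {
  n <- length(codes)
  if (n < 3) return(codes)
  verts <- sort(unique(codes))
  k <- length(verts)
  a <- match(codes, verts)
  last_v <- a[n]
  targets <- vector("list", k)
  for (v in seq_len(k)) targets[[v]] <- a[which(a[-n] == v) + 1L]
  # reserve a random "last edge" per vertex (except the terminal one) such
  # that following last edges from any vertex reaches the terminal vertex
  for (attempt in seq_len(1000)) {
    last_edge <- rep(NA_integer_, k)
    for (v in seq_len(k)) {
      if (v != last_v && length(targets[[v]]))
        last_edge[v] <- targets[[v]][sample.int(length(targets[[v]]), 1)]
    }
    ok <- TRUE
    for (v in seq_len(k)) {
      if (v == last_v || !length(targets[[v]])) next
      cur <- v
      for (step in seq_len(k)) {
        cur <- last_edge[cur]
        if (is.na(cur) || cur == last_v) break
      }
      if (is.na(cur) || cur != last_v) { ok <- FALSE; break }
    }
    if (ok) break
  }
  if (!ok) return(codes)  # degenerate composition; give up gracefully
  out <- integer(n)
  ptr <- vector("list", k)
  for (v in seq_len(k)) {
    rest <- targets[[v]]
    if (!is.na(last_edge[v])) {
      drop_i <- match(last_edge[v], rest)
      rest <- rest[-drop_i]
    }
    if (length(rest) > 1) rest <- rest[sample.int(length(rest))]
    ptr[[v]] <- c(rest, if (!is.na(last_edge[v])) last_edge[v])
  }
  pos <- rep(1L, k)
  cur <- a[1]
  out[1] <- cur
  for (i in 2:n) {
    nxt <- ptr[[cur]][pos[cur]]
    pos[cur] <- pos[cur] + 1L
    out[i] <- nxt
    cur <- nxt
  }
  verts[out]
}

#' Extract strand-aware promoter windows
#'
#' For a plus-strand gene the window is `[max(0, TSS - window_bp), TSS)`;
#' for a minus-strand gene it is `(TSS, TSS + window_bp]` and the sequence
#' is reverse-complemented, so every returned sequence reads 5' to 3' toward
#' its TSS. Windows are truncated at contig boundaries with a warning.
#' Coordinates are 0-based half-open throughout.
#'
#' @param genes Character vector of gene ids to extract.
#' @param annotation Data frame (or TSV path) with columns `gene`, `chrom`,
#'   `tss` (0-based), `strand`.
#' @param genome A named `DNAStringSet` or FASTA path covering every
#'   chromosome used.
#' @param window_bp Window size upstream of the TSS, at most 50000 bp
#'   (default 50000, the full regulatory window the workflow targets).
#' @return A list of class `"promoter_set"` with `gene_ids`, `intervals`
#'   ([genomic_intervals()]), `sequences` (named `DNAStringSet`), and
#'   `window_bp`.
#' @export
extract_promoters <- function(genes, annotation, genome, window_bp = 50000) {
  if (window_bp < 1 || window_bp > 50000)
    stop("window_bp must be between 1 and 50000")
  if (is.character(annotation) && length(annotation) == 1)
    annotation <- utils::read.table(annotation, header = TRUE, sep = "\t",
                                    stringsAsFactors = FALSE)
  need <- c("gene", "chrom", "tss", "strand")
  if (!all(need %in% names(annotation)))
    stop("annotation must have columns: ", paste(need, collapse = ", "))
  if (is.character(genome) && length(genome) == 1)
    genome <- Biostrings::readDNAStringSet(genome)
  names(genome) <- sub("\\s.*$", "", names(genome))
  missing <- setdiff(genes, annotation$gene)
  if (length(missing))
    stop("gene(s) absent from annotation: ", paste(missing, collapse = ", "))
  ann <- annotation[match(genes, annotation$gene), ]
  bad_chrom <- setdiff(unique(ann$chrom), names(genome))
  if (length(bad_chrom))
    stop("chromosome(s) absent from genome: ",
         paste(bad_chrom, collapse = ", "))

  starts <- ends <- integer(length(genes))
  seqs <- character(length(genes))
  truncated <- character(0)
  for (i in seq_along(genes)) {
    chrom_len <- Biostrings::width(genome[ann$chrom[i]])
    tss <- as.integer(ann$tss[i])
    if (ann$strand[i] == "+") {
      s <- max(0L, tss - as.integer(window_bp)); e <- tss
    } else {
      s <- tss + 1L; e <- min(chrom_len, tss + 1L + as.integer(window_bp))
    }
    if (e - s < window_bp) truncated <- c(truncated, genes[i])
    if (s >= e)
      stop("empty promoter window for gene ", genes[i],
           " (TSS at contig edge)")
    starts[i] <- s; ends[i] <- e
    sq <- Biostrings::subseq(genome[[ann$chrom[i]]], start = s + 1L, end = e)
    if (ann$strand[i] == "-") sq <- Biostrings::reverseComplement(sq)
    seqs[i] <- as.character(sq)
  }
  if (length(truncated))
    warning("promoter window(s) truncated at contig boundary: ",
            paste(truncated, collapse = ", "))
  dss <- Biostrings::DNAStringSet(seqs)
  names(dss) <- genes
  structure(list(gene_ids = genes,
                 intervals = genomic_intervals(ann$chrom, starts, ends,
                                               genes, ann$strand),
                 sequences = dss, window_bp = as.integer(window_bp)),
            class = "promoter_set")
}

#' Rank motifs by enrichment in a promoter set
#'
#' For each PWM, the observed statistic is the mean best-hit log-odds score
#' over promoters; the null distribution of that mean comes from
#' `n_shuffles` dinucleotide shuffles of every promoter. The enrichment
#' z-score is `(mu0 - T) / sigma0` (negative when enriched) and the p-value
#' is the one-sided normal tail. Results are sorted by `-log10(p)`
#' descending, ties broken by motif id.
#'
#' @param proms A [extract_promoters()] result, a named `DNAStringSet`, or a
#'   character vector of sequences.
#' @param pwms A list of [pwm()] objects.
#' @param n_shuffles Number of shuffle rounds for the null; at least 20
#'   (fewer gives an unstable null sd). Default 100.
#' @param seed Integer seed for the shuffle RNG.
#' @return A data frame of class `"motif_enrichment"` with columns
#'   `motif_id`, `z`, `p`, `neg_log10_p`, `minus10_log10_p`
#'   (`10 * neg_log10_p`, the x10 display scale some screens print), `rank`.
#' @export
enrich_motifs <- function(proms, pwms, n_shuffles = 100, seed = 1) {
  seqs <- if (inherits(proms, "promoter_set")) proms$sequences else proms
  seqs <- as.character(seqs)
  if (!length(seqs)) stop("no promoter sequences")
  if (!length(pwms)) stop("no PWMs")
  if (inherits(pwms, "pwm")) pwms <- list(pwms)
  if (n_shuffles < 20)
    stop("n_shuffles must be >= 20 for a stable null (got ", n_shuffles, ")")
  set.seed(substream_seed(seed, 4L))

  S5s <- lapply(pwms, pwm_score_matrix)
  ids <- vapply(pwms, function(p) p$motif_id, character(1))
  codes <- lapply(seqs, encode_seq)
  rcs <- lapply(codes, revcomp_codes)
  n_prom <- length(codes)
  n_pwm <- length(pwms)

  obs <- matrix(0, n_prom, n_pwm)
  for (i in seq_len(n_prom))
    for (m in seq_len(n_pwm))
      obs[i, m] <- best_score_only(codes[[i]], rcs[[i]], S5s[[m]])
  T_obs <- colMeans(obs)

  T_null <- matrix(0, n_shuffles, n_pwm)
  for (b in seq_len(n_shuffles)) {
    acc <- numeric(n_pwm)
    for (i in seq_len(n_prom)) {
      sh <- shuffle_codes(codes[[i]])
      rc <- revcomp_codes(sh)
      for (m in seq_len(n_pwm))
        acc[m] <- acc[m] + best_score_only(sh, rc, S5s[[m]])
    }
    T_null[b, ] <- acc / n_prom
  }
  mu0 <- colMeans(T_null)
  sd0 <- apply(T_null, 2, stats::sd)
  degenerate <- sd0 == 0 | !is.finite(sd0)
  if (any(degenerate)) {
    warning("degenerate shuffle null (sd = 0) for motif(s): ",
            paste(ids[degenerate], collapse = ", "))
    sd0[degenerate] <- 1
  }
  z <- (mu0 - T_obs) / sd0
  z[degenerate] <- 0
  p <- stats::pnorm(z)
  res <- data.frame(motif_id = ids, z = z, p = p,
                    neg_log10_p = -log10(p),
                    minus10_log10_p = -10 * log10(p),
                    stringsAsFactors = FALSE)
  res <- res[order(-res$neg_log10_p, res$motif_id), ]
  res$rank <- seq_len(nrow(res))
  rownames(res) <- NULL
  class(res) <- c("motif_enrichment", "data.frame")
  res
}
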