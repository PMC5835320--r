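make_toy_genome <- function() {
  set.seed(99)
  chr1 <- paste(sample(c("A", "C", "G", "T"), 3000, TRUE), collapse = "")
  g <- Biostrings::DNAStringSet(c(chr1 = chr1))
  g
}

test_that("promoter windows respect strand and coordinates", {
  genome <- make_toy_genome()
  ann <- data.frame(gene = c("PLUS", "MINUS"), chrom = "chr1",
                    tss = c(1000L, 1000L), strand = c("+", "-"))
  ps <- extract_promoters(c("PLUS", "MINUS"), ann, genome, window_bp = 200)
  expect_equal(ps$intervals$start, c(800L, 1001L))
  expect_equal(ps$intervals$end, c(1000L, 1201L))
  expect_equal(unname(Biostrings::width(ps$sequences)), c(200L, 200L))
  # plus strand: the window immediately upstream of the TSS, forward
  expect_equal(as.character(ps$sequences[["PLUS"]]),
               as.character(Biostrings::subseq(genome[[1]], 801, 1000)))
  # minus strand: downstream coordinates, reverse-complemented
  expect_equal(as.character(ps$sequences[["MINUS"]]),
               as.character(Biostrings::reverseComplement(
                 Biostrings::subseq(genome[[1]], 1002, 1201))))
})

test_that("promoter windows truncate at contig boundaries with a warning", {
  genome <- make_toy_genome()
  ann <- data.frame(gene = "EDGE", chrom = "chr1", tss = 100L, strand = "+")
  expect_warning(ps <- extract_promoters("EDGE", ann, genome, 500),
                 "truncated")
  expect_equal(ps$intervals$start, 0L)
  expect_equal(ps$intervals$end, 100L)
  expect_equal(unname(Biostrings::width(ps$sequences)), 100L)

  expect_error(extract_promoters("NOPE", ann, genome, 100), "NOPE")
  ann2 <- data.frame(gene = "G", chrom = "chrX", tss = 10L, strand = "+")
  expect_error(extract_promoters("G", ann2, genome, 5), "chrX")
})

test_that("consensus sequences score the column-max sum and background scores zero", {
  mot <- make_consensus_pwm(c(1, 3, 2, 4), major = 0.9)
  consensus <- "AGCT"
  hit <- scan_best_score(consensus, mot)
  expect_equal(hit$score, sum(log2(apply(mot$matrix, 2, max) / 0.25)),
               tolerance = 1e-12)
  expect_equal(hit$start, 1L)

  uniform <- pwm("U", matrix(0.25, 4, 5))
  s <- scan_best_score("ACGTACGTACG", uniform)
  expect_equal(s$score, 0)
  expect_error(scan_best_score("ACG", mot), "shorter than motif")
})

test_that("scanning equals exhaustive enumeration over all placements", {
  set.seed(14)
  mot <- make_random_pwm("R", L = 4, seed = 14)
  seq <- "TTGACGTCAAGG"
  best <- scan_best_score(seq, mot)
  # brute force: all 9 offsets on both strands, summing per-column log-odds
  score_at <- function(s, p) {
    chars <- strsplit(s, "")[[1]]
    sum(vapply(seq_along(chars), function(j) {
      log2(p$matrix[chars[j], j] / 0.25)
    }, numeric(1)))
  }
  rc <- function(s) as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(s)))
  windows <- substring(seq, 1:9, 4:12)
  all_scores <- c(vapply(windows, score_at, numeric(1), p = mot),
                  vapply(vapply(windows, rc, ""), score_at, numeric(1),
                         p = mot))
  expect_equal(best$score, max(all_scores), tolerance = 1e-12)
})

test_that("best scores are strand-symmetric", {
  set.seed(25)
  mot <- make_random_pwm("S", L = 6, seed = 25)
  seqs <- vapply(1:20, function(i)
    paste(sample(c("A", "C", "G", "T"), 50, TRUE), collapse = ""),
    character(1))
  for (s in seqs) {
    rc <- as.character(
      Biostrings::reverseComplement(Biostrings::DNAString(s)))
    expect_equal(scan_best_score(s, mot)$score,
                 scan_best_score(rc, mot)$score, tolerance = 1e-12)
  }
})

test_that("ambiguous bases contribute the background expectation", {
  mot <- make_consensus_pwm(c(1, 1, 1, 1), major = 0.9)
  all_n <- scan_best_score("NNNNNNNN", mot)
  expect_equal(all_n$score, 0)
})

test_that("dinucleotide shuffling preserves doublet composition", {
  count_dinuc <- function(x)
    sort(table(substring(x, 1:(nchar(x) - 1), 2:nchar(x))))
  set.seed(50)
  for (i in 1:10) {
    s <- paste(sample(c("A", "C", "G", "T"), 60, TRUE,
                      prob = c(0.4, 0.1, 0.2, 0.3)), collapse = "")
    sh <- dinucleotide_shuffle(s)
    expect_equal(nchar(sh), nchar(s))
    expect_identical(count_dinuc(sh), count_dinuc(s))
    expect_equal(substr(sh, 1, 1), substr(s, 1, 1))
    expect_equal(substr(sh, 60, 60), substr(s, 60, 60))
  }
})

test_that("a planted motif ranks first among decoys", {
  mot <- make_consensus_pwm(c(1, 3, 2, 4, 1, 2, 3), id = "PLANTED")
  decoys <- lapply(1:10, function(i)
    make_random_pwm(sprintf("DECOY%02d", i), L = 8, seed = 100 + i))
  gp <- gen_promoters(60, 120, mot, plant_rate = 0.8, seed = 5)
  enr <- enrich_motifs(gp$sequences, c(list(mot), decoys),
                       n_shuffles = 40, seed = 5)
  expect_equal(enr$motif_id[1], "PLANTED")
  expect_lt(enr$z[1], 0)                       # enriched = negative z
  expect_true(all(diff(enr$neg_log10_p) <= 1e-12))
  expect_equal(enr$rank, seq_len(nrow(enr)))
})

test_that("enrichment is deterministic under a fixed seed and guards the null size", {
  mot <- make_consensus_pwm(c(2, 4, 1, 3, 2), id = "M")
  gp <- gen_promoters(15, 60, mot, plant_rate = 0.5, seed = 3)
  e1 <- enrich_motifs(gp$sequences, list(mot), n_shuffles = 25, seed = 9)
  e2 <- enrich_motifs(gp$sequences, list(mot), n_shuffles = 25, seed = 9)
  expect_identical(e1, e2)
  expect_error(enrich_motifs(gp$sequences, list(mot), n_shuffles = 19),
               "n_shuffles")
})

test_that("unplanted promoter sets give null-scale z-scores", {
  mot <- make_consensus_pwm(c(1, 3, 2, 4, 1, 2, 3), id = "M")
  decoy <- make_random_pwm("D", L = 7, seed = 9)
  zs <- unlist(lapply(1:10, function(s) {
    gp <- gen_promoters(30, 100, mot, plant_rate = 0, seed = s)
    enrich_motifs(gp$sequences, list(mot, decoy),
                  n_shuffles = 40, seed = s)$z
  }))
  expect_gte(mean(abs(zs) < 3), 0.95)
})
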