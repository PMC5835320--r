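# Shared fixture builders: small in-code matrices, PWMs and files.

make_expr <- function(values, genes = sprintf("G%d", seq_len(nrow(values))),
                      lines = sprintf("L%d", seq_len(ncol(values)))) {
  expression_matrix(values, genes, lines)
}

# a near-deterministic PWM spelling out `consensus` (indices into A,C,G,T)
make_consensus_pwm <- function(consensus_idx, id = "CONS", major = 0.97) {
  L <- length(consensus_idx)
  m <- matrix((1 - major) / 3, 4, L)
  for (j in seq_len(L)) m[consensus_idx[j], j] <- major
  m <- sweep(m, 2, colSums(m), "/")
  pwm(id, m)
}

make_random_pwm <- function(id, L = 8, seed = 1) {
  set.seed(seed)
  m <- matrix(stats::rgamma(4 * L, 0.5) + 0.01, 4, L)
  m <- sweep(m, 2, colSums(m), "/")
  pwm(id, m)
}

write_tmp <- function(lines, ext = ".txt") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

# direct-formula Pearson correlation, element-by-element (test oracle;
# deliberately avoids cor())
pearson_oracle <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  mx <- sum(x) / n; my <- sum(y) / n
  num <- 0; dx2 <- 0; dy2 <- 0
  for (i in seq_len(n)) {
    num <- num + (x[i] - mx) * (y[i] - my)
    dx2 <- dx2 + (x[i] - mx)^2
    dy2 <- dy2 + (y[i] - my)^2
  }
  num / sqrt(dx2 * dy2)
}

# greedy minimal-Ward-cost agglomeration from the sum-of-squares definition
# (test oracle; no hclust). Returns the list of partitions after each merge
# and the merge costs 2 * |A||B|/(|A|+|B|) * ||mean_A - mean_B||^2.
ward_oracle <- function(x) {
  n <- nrow(x)
  clusters <- lapply(seq_len(n), identity)
  partitions <- list()
  costs <- numeric(0)
  while (length(clusters) > 1) {
    best <- c(NA, NA); best_cost <- Inf
    for (i in seq_len(length(clusters) - 1)) {
      for (j in (i + 1):length(clusters)) {
        a <- clusters[[i]]; b <- clusters[[j]]
        ma <- colMeans(x[a, , drop = FALSE])
        mb <- colMeans(x[b, , drop = FALSE])
        cost <- 2 * length(a) * length(b) / (length(a) + length(b)) *
          sum((ma - mb)^2)
        if (cost < best_cost - 1e-12) {
          best_cost <- cost; best <- c(i, j)
        }
      }
    }
    merged <- sort(c(clusters[[best[1]]], clusters[[best[2]]]))
    clusters <- clusters[-best]
    clusters[[length(clusters) + 1]] <- merged
    costs <- c(costs, best_cost)
    partitions[[length(partitions) + 1]] <- clusters
  }
  list(partitions = partitions, costs = costs)
}

# canonical form of a partition for label-free comparison
partition_key <- function(labels) {
  groups <- split(names(labels), unclass(labels))
  paste(sort(vapply(groups, function(g) paste(sort(g), collapse = ","),
                    character(1))), collapse = "|")
}

# right-tail hypergeometric probability by explicit summation over choose()
# ratios (test oracle; no phyper)
hyper_tail_oracle <- function(k, K, N, n) {
  kk <- k:min(K, n)
  sum(choose(K, kk) * choose(N - K, n - kk)) / choose(N, n)
}
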