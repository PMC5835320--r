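# Synthetic-data generators. Each generator plants the statistical structure
# a downstream stage assumes (response-correlated genes, promoter motif
# instances, 4PL dose-response curves) and records the ground truth so that
# recovery can be scored. All generators are fully reproducible given a seed.

# Derive a per-component substream seed from a global seed, so individual
# stages can be regenerated independently. Kept below 2^31 - 1.
substream_seed <- function(seed, component) {
  (as.integer(seed) %% 1000003L) * 2011L + as.integer(component) %% 2011L
}

#' Configuration for the expression/response simulator
#'
#' @param n_genes Total number of genes.
#' @param n_lines Number of cell lines (default 58, the panel size the
#'   COMPARE workflow is built around).
#' @param n_planted_pos,n_planted_neg Number of genes planted with positive /
#'   negative correlation to the response.
#' @param rho Target absolute Pearson correlation of planted genes, in (0, 1).
#' @param noise_sd Standard deviation of the per-gene expression noise
#'   (log2 units; default 1).
#' @param seed Integer random seed.
#' @return A list of class `"simulation_config"`.
#' @export
simulation_config <- function(n_genes, n_lines = 58, n_planted_pos = 20,
                              n_planted_neg = 20, rho = 0.6, noise_sd = 1,
                              seed = 1) {
  if (n_genes < 1 || n_lines < 3) stop("need n_genes >= 1 and n_lines >= 3")
  if (n_planted_pos < 0 || n_planted_neg < 0)
    stop("planted counts must be non-negative")
  if (n_planted_pos + n_planted_neg > n_genes)
    stop("n_planted_pos + n_planted_neg exceeds n_genes")
  if (!(rho > 0 && rho < 1) && !(rho == 0 && n_planted_pos + n_planted_neg == 0))
    stop("rho must lie in (0, 1)")
  if (noise_sd <= 0) stop("noise_sd must be positive")
  structure(list(n_genes = as.integer(n_genes), n_lines = as.integer(n_lines),
                 n_planted_pos = as.integer(n_planted_pos),
                 n_planted_neg = as.integer(n_planted_neg),
                 rho = rho, noise_sd = noise_sd, seed = as.integer(seed)),
            class = "simulation_config")
}

#' Simulate an expression matrix with response-correlated planted genes
#'
#' The response is drawn per cell line from a normal law centered at -5.45
#' log10 molar with sd 0.8 (the scale on which the sensitive/resistant
#' partition threshold of the workflow lives). A planted gene is
#' `a * response + noise`, with `a` signed and scaled so that the expected
#' Pearson correlation satisfies
#' `rho = a * sd(response) / sqrt(a^2 var(response) + noise_sd^2)`;
#' non-planted genes are independent noise around gene-specific baselines.
#'
#' @param config A [simulation_config()].
#' @return A list with elements `expr` ([expression_matrix()]),
#'   `response` ([response_vector()]), and `truth` (list with
#'   `planted_pos_ids`, `planted_neg_ids`, `true_ic50s`).
#' @export
gen_expression_response <- function(config) {
  if (!inherits(config, "simulation_config")) config <- do.call(simulation_config, config)
  set.seed(substream_seed(config$seed, 1L))
  resp_mu <- -5.45
  resp_sd <- 0.8
  lines <- sprintf("LINE%02d", seq_len(config$n_lines))
  genes <- sprintf("GENE%04d", seq_len(config$n_genes))
  y <- stats::rnorm(config$n_lines, resp_mu, resp_sd)
  names(y) <- lines

  n_planted <- config$n_planted_pos + config$n_planted_neg
  planted_idx <- seq_len(n_planted)  # ids are arbitrary labels; first block
  pos_ids <- genes[seq_len(config$n_planted_pos)]
  neg_ids <- genes[config$n_planted_pos + seq_len(config$n_planted_neg)]

  baseline <- stats::rnorm(config$n_genes, mean = 7, sd = 1.5)
  values <- matrix(stats::rnorm(config$n_genes * config$n_lines,
                                sd = config$noise_sd),
                   nrow = config$n_genes)
  values <- values + baseline
  if (n_planted > 0) {
    # slope giving expected |r| = rho against the population response sd
    a <- config$rho * config$noise_sd / (resp_sd * sqrt(1 - config$rho^2))
    sign_vec <- rep(c(1, -1), c(config$n_planted_pos, config$n_planted_neg))
    yc <- y - resp_mu
    values[planted_idx, ] <- values[planted_idx, ] +
      (sign_vec * a) %o% yc
  }
  list(expr = expression_matrix(values, genes, lines),
       response = response_vector(y, lines),
       truth = list(planted_pos_ids = pos_ids, planted_neg_ids = neg_ids,
                    true_ic50s = y))
}

#' Simulate promoter sequences with a planted motif
#'
#' Background sequences are i.i.d. draws from `background`; in
#' `ceiling(plant_rate * n_seqs)` of them a single motif instance, sampled
#' column-wise from the PWM, replaces the sequence at a random offset.
#'
#' @param n_seqs Number of promoter sequences.
#' @param length Sequence length in bp; must exceed the motif length.
#' @param motif A [pwm()] to plant.
#' @param plant_rate Fraction of sequences receiving one instance, in `[0, 1]`.
#' @param seed Integer random seed.
#' @param background Length-4 background nucleotide distribution (A, C, G, T).
#' @return A list with `sequences` (named `DNAStringSet`) and `truth`
#'   (list with `planted_ids`, `positions` (1-based insert starts), and
#'   `planted_motif_id`).
#' @export
gen_promoters <- function(n_seqs, length, motif, plant_rate, seed = 1,
                          background = rep(0.25, 4)) {
  if (!inherits(motif, "pwm")) stop("motif must be a pwm object")
  L <- ncol(motif$matrix)
  if (length <= L) stop("sequence length must exceed motif length (", L, ")")
  if (plant_rate < 0 || plant_rate > 1) stop("plant_rate must be in [0, 1]")
  set.seed(substream_seed(seed, 2L))
  nts <- c("A", "C", "G", "T")
  seqs <- vapply(seq_len(n_seqs), function(i) {
    paste(sample(nts, length, replace = TRUE, prob = background),
          collapse = "")
  }, character(1))
  ids <- sprintf("PROM%04d", seq_len(n_seqs))
  n_plant <- ceiling(plant_rate * n_seqs)
  planted <- if (n_plant > 0) sort(sample.int(n_seqs, n_plant)) else integer(0)
  positions <- integer(0)
  for (i in planted) {
    inst <- paste(vapply(seq_len(L), function(j) {
      sample(nts, 1, prob = motif$matrix[, j])
    }, character(1)), collapse = "")
    pos <- sample.int(length - L + 1L, 1)
    substr(seqs[i], pos, pos + L - 1L) <- inst
    positions <- c(positions, pos)
  }
  dss <- Biostrings::DNAStringSet(seqs)
  names(dss) <- ids
  list(sequences = dss,
       truth = list(planted_ids = ids[planted], positions = positions,
                    planted_motif_id = motif$motif_id))
}

#' Simulate a replicated viability table from a 4PL dose-response model
#'
#' Viability follows `1 / (1 + (c / ic50)^hill)` with multiplicative
#' log-normal noise (`exp(N(0, noise_sd))`), clipped to `[0, 1.2]` as plate
#' readings normalized to untreated controls can slightly exceed 1.
#'
#' @param ic50 True IC50 in uM (positive).
#' @param hill Hill slope (default 1).
#' @param conc_grid Ascending positive concentrations in uM (default: 10
#'   log-spaced points from 0.003 to 500 uM).
#' @param noise_sd Log-scale noise sd (fractional noise; default 0.05).
#' @param seed Integer random seed.
#' @param n_replicates Replicates per concentration (default 6).
#' @return A data frame with columns `concentration_uM`, `replicate`,
#'   `viability`.
#' @export
gen_dose_response <- function(ic50, hill = 1,
                              conc_grid = 10^seq(log10(0.003), log10(500),
                                                 length.out = 10),
                              noise_sd = 0.05, seed = 1, n_replicates = 6) {
  if (ic50 <= 0) stop("ic50 must be positive")
  if (any(conc_grid <= 0) || is.unsorted(conc_grid))
    stop("conc_grid must be positive and ascending")
  set.seed(substream_seed(seed, 3L))
  conc <- rep(conc_grid, each = n_replicates)
  mu <- 1 / (1 + (conc / ic50)^hill)
  noise <- if (noise_sd > 0) exp(stats::rnorm(length(conc), 0, noise_sd)) else 1
  v <- pmin(pmax(mu * noise, 0), 1.2)
  data.frame(concentration_uM = conc,
             replicate = rep(seq_len(n_replicates), times = length(conc_grid)),
             viability = v)
}
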