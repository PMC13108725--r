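# shared fixture builders; all randomness behind explicit seeds

# balanced one-way grouped data with optional unit fixed effects
make_grouped_data <- function(n_groups, n_units, sd_group, sd_resid,
                              seed, standardize_group = TRUE,
                              unit_sd = 0.3) {
  set.seed(seed)
  dat <- expand.grid(donor = paste0("D", seq_len(n_groups)),
                     unit = paste0("U", seq_len(n_units)),
                     stringsAsFactors = FALSE)
  g <- rnorm(n_groups)
  if (standardize_group && sd_group > 0 && n_groups > 1) {
    g <- (g - mean(g)) / sd(g) * sd_group
  } else {
    g <- g * sd_group
  }
  u <- rnorm(n_units, 0, unit_sd)
  dat$y <- g[match(dat$donor, paste0("D", seq_len(n_groups)))] +
    u[match(dat$unit, paste0("U", seq_len(n_units)))] +
    rnorm(nrow(dat), 0, sd_resid)
  dat
}

# NB count matrix with the first `n_planted` genes shifted by `lfc` log2
# units in the second half of samples
make_de_counts <- function(n_genes = 2000, n_per_group = 6, n_planted = 20,
                           lfc = 3, dispersion = 0.05, seed = 1) {
  set.seed(seed)
  S <- 2 * n_per_group
  x <- rep(c(0, 1), each = n_per_group)
  b0 <- rnorm(n_genes, 5, 2)
  # planted genes sit in the well-expressed range so the planted fold
  # change, not count sparsity, drives their behaviour
  if (n_planted > 0) b0[seq_len(n_planted)] <- rnorm(n_planted, 6, 1)
  shift <- c(rep(lfc, n_planted), rep(0, n_genes - n_planted))
  mu <- 2^(matrix(b0, n_genes, S) + outer(shift, x))
  cnt <- matrix(rnbinom(n_genes * S, mu = mu, size = 1 / dispersion),
                n_genes,
                dimnames = list(sprintf("g%04d", seq_len(n_genes)),
                                paste0("s", seq_len(S))))
  list(counts = cnt,
       groups = factor(rep(c("lo", "hi"), each = n_per_group),
                       levels = c("lo", "hi")),
       planted = sprintf("g%04d", seq_len(n_planted)))
}

# area under the ROC of score-ranks for a binary truth vector
auroc <- function(score, is_positive) {
  r <- rank(score)
  n1 <- sum(is_positive)
  n0 <- sum(!is_positive)
  (sum(r[is_positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# tiny measurement table fixture written to a temp CSV
write_measurement_csv <- function(df, path = tempfile(fileext = ".csv")) {
  utils::write.csv(df, path, row.names = FALSE)
  path
}
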