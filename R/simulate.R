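#' Default simulation scenario
#'
#' Builds the scenario the package uses as its reference study design:
#' 3 macrophage donors, 25 tumor cell lines plus one untreated control well,
#' and 10 secreted analytes of which 7 are quantifiable and 3 are designed to
#' fall below their assay LLoQ in well over 40% of observations (so the
#' censoring filter retains exactly 7). Donor intraclass correlations span
#' ~0.1-0.75 across analytes, the range reported for donor-to-donor
#' variability in multiplexed secretome panels. The linked expression matrix
#' has 2000 genes with 5 planted genes per analyte whose log2 expression
#' tracks that analyte's latent polarization score.
#'
#' Concentrations are log10-normal: positive, right-skewed, and decidedly
#' non-normal on the raw scale, which is why the scoring stage uses robust
#' modified z-scores. The latent per-cell-line score enters linearly on the
#' log scale with per-analyte loading `loading`.
#'
#' @param seed integer master seed stored in the scenario.
#' @return a `sim_scenario` list: `analytes` tibble (name,
#'   `baseline_log10_mean`, `donor_sd`, `residual_sd`, `loading`, `lloq`,
#'   `latent_group`, `target_icc`), plus `n_donors`, `n_cell_lines`,
#'   `n_genes`, `n_planted_per_analyte`, `planted_effect`, `nb_dispersion`,
#'   `library_size_range`, `seed`.
#' @export
make_default_scenario <- function(seed = 1L) {
  icc <- c(VEGF = 0.614, TNFa = 0.182, IL10 = 0.115, CCL2 = 0.754,
           IL8 = 0.209, TGFb = 0.628, KC_like = 0.096,
           IL2 = 0.2, IL6 = 0.2, IFNg = 0.2)
  total_sd <- 0.35 # log10 units
  analytes <- tibble::tibble(
    name = names(icc),
    baseline_log10_mean = c(2.5, 1.9, 1.8, 3.0, 2.8, 2.0, 2.2,
                            0.8, 0.6, 0.7),
    target_icc = unname(icc),
    donor_sd = total_sd * sqrt(unname(icc)),
    residual_sd = total_sd * sqrt(1 - unname(icc)),
    loading = c(0.6, 0.4, 0.4, 0.3, 0.35, 0.3, 0.35, 0.2, 0.2, 0.2),
    latent_group = names(icc),
    detectable = c(rep(TRUE, 7), rep(FALSE, 3))
  )
  # LLoQ: detectable analytes censored only in the far-left tail; the three
  # designed failures have the LLoQ 0.8 total-SD above their mean level
  tot <- sqrt(analytes$donor_sd^2 + analytes$residual_sd^2 +
                analytes$loading^2)
  analytes$lloq <- ifelse(
    analytes$detectable,
    10^(analytes$baseline_log10_mean - 1.5),
    10^(analytes$baseline_log10_mean + 0.8 * tot)
  )
  structure(
    list(analytes = analytes, n_donors = 3L, n_cell_lines = 25L,
         n_genes = 2000L, n_planted_per_analyte = 5L,
         planted_effect = 1.5, nb_dispersion = 0.05,
         library_size_range = c(5e5, 1.5e6), seed = as.integer(seed)),
    class = "sim_scenario"
  )
}

#' @export
print.sim_scenario <- function(x, ...) {
  cat("<sim_scenario> ", x$n_donors, " donors x ", x$n_cell_lines,
      " cell lines x ", nrow(x$analytes), " analytes; ", x$n_genes,
      " genes (", x$n_planted_per_analyte, " planted/analyte); seed ",
      x$seed, "\n", sep = "")
  invisible(x)
}

#' Simulate a donor-structured secretome experiment
#'
#' Generates the long measurement table of a tumor-conditioned-media
#' experiment. For donor d, cell line c and analyte a the concentration is
#' `10^(mu_a + delta_{d,a} + loading_a * s_{c,a} + eps)` with
#' `eps ~ N(0, residual_sd_a^2)` and `s_{c,a} ~ N(0, 1)` the latent
#' polarization score (shared across analytes in the same `latent_group`).
#' Donor intercepts `delta` are drawn Normal and then standardized to sample
#' mean 0 and sample sd `donor_sd_a`, so each dataset realizes its target
#' ICC `donor_sd^2 / (donor_sd^2 + residual_sd^2)` exactly in the generating
#' effects — with as few as 3-5 donors, unstandardized draws would make the
#' realized donor variance (and hence any recovery assessment) essentially
#' arbitrary. An untreated control well (`CTRL`) with latent score 0 is
#' included for every donor.
#'
#' @param scenario a `sim_scenario`, e.g. [make_default_scenario()].
#' @return list with `table` (tibble: donor, unit, analyte, concentration,
#'   below_lloq), `lloq_map`, and `truth` (list: `latent_scores` cell line x
#'   analyte matrix, `donor_effects`, `target_icc`, `variance_components`,
#'   `scenario`).
#' @export
simulate_cytokine_experiment <- function(scenario) {
  an <- scenario$analytes
  if (any(an$donor_sd < 0) || any(an$residual_sd < 0)) {
    abort("Scenario standard deviations must be non-negative.")
  }
  if (any(an$target_icc > 0 & an$donor_sd <= 0)) {
    abort("A positive target ICC requires a positive donor_sd.")
  }
  set.seed(scenario$seed)
  donors <- paste0("D", seq_len(scenario$n_donors))
  lines <- sprintf("L%02d", seq_len(scenario$n_cell_lines))
  units <- c(lines, "CTRL")

  groups <- unique(an$latent_group)
  latent_by_group <- matrix(rnorm(scenario$n_cell_lines * length(groups)),
                            nrow = scenario$n_cell_lines,
                            dimnames = list(lines, groups))
  latent <- latent_by_group[, an$latent_group, drop = FALSE]
  colnames(latent) <- an$name

  donor_effects <- sapply(seq_len(nrow(an)), function(i) {
    d <- rnorm(scenario$n_donors)
    if (an$donor_sd[i] == 0 || scenario$n_donors < 2) {
      return(rep(0, scenario$n_donors))
    }
    (d - mean(d)) / sd(d) * an$donor_sd[i]
  })
  dimnames(donor_effects) <- list(donors, an$name)

  grid <- tidyr::expand_grid(donor = donors, unit = units, analyte = an$name)
  ai <- match(grid$analyte, an$name)
  s <- ifelse(grid$unit == "CTRL", 0,
              latent[cbind(match(grid$unit, lines), ai)])
  log10_conc <- an$baseline_log10_mean[ai] +
    donor_effects[cbind(match(grid$donor, donors), ai)] +
    an$loading[ai] * s +
    rnorm(nrow(grid), 0, an$residual_sd[ai])
  lloq_map <- setNames(an$lloq, an$name)
  table <- grid |>
    dplyr::mutate(concentration = 10^log10_conc,
                  below_lloq = .data$concentration <
                    unname(lloq_map[.data$analyte]))
  truth <- list(
    latent_scores = latent,
    donor_effects = donor_effects,
    target_icc = setNames(an$target_icc, an$name),
    variance_components = tibble::tibble(
      analyte = an$name, donor_sd = an$donor_sd,
      residual_sd = an$residual_sd, loading = an$loading
    ),
    scenario = scenario
  )
  list(table = table, lloq_map = lloq_map, truth = truth)
}

#' Simulate a linked RNA-seq count matrix with planted genes
#'
#' Generates a gene x cell-line negative-binomial count matrix in which, for
#' each analyte, `n_planted_per_analyte` genes have log2 mean expression
#' `b0_g + b1 * s_{c,a}` tracking that analyte's latent polarization score
#' (`b1 = planted_effect`); all other genes are flat. Per-gene baselines
#' `b0_g ~ N(5, 2)` on the log2 scale give realistic right-skewed abundance.
#' Expected counts are rescaled per sample to a library size drawn uniformly
#' from `library_size_range`, then counts are drawn NB with dispersion
#' `nb_dispersion`. The normalized matrix is TPM computed with unit gene
#' lengths (counts proportional), since length bias plays no role in a
#' per-gene rank screen.
#'
#' @param scenario a `sim_scenario`.
#' @param truth truth list from [simulate_cytokine_experiment()] (provides
#'   the latent scores; updated with planted-gene ids on return).
#' @return list with `bundle` (an `expression_bundle`) and the updated
#'   `truth` (gains `planted_genes`: tibble gene/analyte/b1).
#' @export
simulate_expression_bundle <- function(scenario, truth) {
  an <- scenario$analytes
  n_planted_total <- scenario$n_planted_per_analyte * nrow(an)
  if (scenario$n_genes < n_planted_total) {
    abort("n_genes is smaller than the total number of planted genes.")
  }
  set.seed(scenario$seed + 1L)
  lines <- rownames(truth$latent_scores)
  genes <- sprintf("g%04d", seq_len(scenario$n_genes))
  planted <- tibble::tibble(
    gene = genes[seq_len(n_planted_total)],
    analyte = rep(an$name, each = scenario$n_planted_per_analyte),
    b1 = scenario$planted_effect
  )
  b0 <- rnorm(scenario$n_genes, mean = 5, sd = 2)
  log2_mu <- matrix(b0, nrow = scenario$n_genes, ncol = length(lines),
                    dimnames = list(genes, lines))
  s_planted <- t(truth$latent_scores[, planted$analyte, drop = FALSE])
  log2_mu[seq_len(n_planted_total), ] <-
    log2_mu[seq_len(n_planted_total), ] + planted$b1 * s_planted
  mu <- 2^log2_mu
  lib <- runif(length(lines), scenario$library_size_range[1],
               scenario$library_size_range[2])
  mu <- sweep(mu, 2, lib / colSums(mu), `*`)
  counts <- matrix(
    rnbinom(length(mu), mu = mu, size = 1 / scenario$nb_dispersion),
    nrow = nrow(mu), dimnames = dimnames(mu)
  )
  tpm <- sweep(counts, 2, colSums(counts), `/`) * 1e6
  truth$planted_genes <- planted
  list(bundle = new_expression_bundle(counts, tpm), truth = truth)
}

#' Simulate an exosome-fractionation experiment
#'
#' Balanced design: every donor's macrophages are treated with every
#' fraction of every cell line's conditioned media, and the secreted analyte
#' (pg/mL) is `baseline + effect_condition + u_donor + eps`. The default
#' effects encode an exosome-only fraction that raises secretion by
#' 1000 pg/mL over whole and exosome-depleted media, which do not differ.
#'
#' @param n_donors number of donors (default 3).
#' @param n_lines number of cell lines (default 7).
#' @param condition_effects named numeric vector of condition effects in
#'   pg/mL (needs >= 2 conditions).
#' @param baseline grand mean, pg/mL.
#' @param donor_sd,residual_sd random-intercept and residual SDs, pg/mL.
#' @param seed integer seed.
#' @return tibble `donor`, `line`, `condition`, `response` with the true
#'   effects attached as attribute `truth`; if `n_donors == 1` the table
#'   carries attribute `random_effect_unidentifiable = TRUE` and a warning
#'   is raised.
#' @export
simulate_fractionation <- function(n_donors = 3, n_lines = 7,
                                   condition_effects = c(whole = 0,
                                                         depleted = 0,
                                                         exosome_only = 1000),
                                   baseline = 1500, donor_sd = 300,
                                   residual_sd = 350, seed = 1L) {
  if (length(condition_effects) < 2) {
    abort("Need at least 2 conditions to simulate a fractionation contrast.")
  }
  set.seed(as.integer(seed))
  donors <- paste0("D", seq_len(n_donors))
  u <- rnorm(n_donors, 0, donor_sd)
  grid <- tidyr::expand_grid(donor = donors,
                             line = sprintf("CL%d", seq_len(n_lines)),
                             condition = names(condition_effects))
  tab <- grid |>
    dplyr::mutate(response = baseline +
                    unname(condition_effects[.data$condition]) +
                    u[match(.data$donor, donors)] +
                    rnorm(nrow(grid), 0, residual_sd))
  attr(tab, "truth") <- list(condition_effects = condition_effects,
                             baseline = baseline, donor_sd = donor_sd,
                             residual_sd = residual_sd, seed = seed)
  if (n_donors < 2) {
    warn("Single donor: random effect unidentifiable in downstream models.")
    attr(tab, "random_effect_unidentifiable") <- TRUE
  }
  tab
}

#' Simulate a chemokine dose-response experiment
#'
#' Generates per-donor dose-response data on the inverse scale:
#' `1/y = a + b * dose + u_donor + eps`, with responses kept positive by
#' redrawing `eps` for any observation whose inverse would be non-positive.
#' Defaults place the predicted mean response at 7.42 pg/mL for dose 0 and
#' 23.02 pg/mL at 5 ng/mL (`a = 1/7.42`, `b = (1/23.02 - 1/7.42)/5`).
#'
#' @param n_donors number of donors (default 4).
#' @param doses numeric dose levels, ng/mL (default 0, 1.25, 2.5, 5).
#' @param inverse_intercept `a`, 1/(pg/mL).
#' @param inverse_slope `b`, 1/(pg/mL) per ng/mL.
#' @param donor_sd,residual_sd SDs on the inverse scale.
#' @param seed integer seed.
#' @return tibble `donor`, `dose`, `response` with attribute `truth`
#'   recording the inverse-scale coefficients.
#' @export
simulate_dose_response <- function(n_donors = 4,
                                   doses = c(0, 1.25, 2.5, 5),
                                   inverse_intercept = 1 / 7.42,
                                   inverse_slope = (1 / 23.02 - 1 / 7.42) / 5,
                                   donor_sd = 0.003, residual_sd = 0.003,
                                   seed = 1L) {
  if (length(unique(doses)) < 2) {
    abort("dose effect unidentifiable: need at least 2 distinct dose levels.")
  }
  mean_inv <- inverse_intercept + inverse_slope * doses
  if (any(mean_inv <= 0)) {
    abort("Parameters imply a non-positive mean inverse response at some dose.")
  }
  set.seed(as.integer(seed))
  donors <- paste0("D", seq_len(n_donors))
  u <- rnorm(n_donors, 0, donor_sd)
  grid <- tidyr::expand_grid(donor = donors, dose = doses)
  base <- inverse_intercept + inverse_slope * grid$dose +
    u[match(grid$donor, donors)]
  inv <- base + rnorm(nrow(grid), 0, residual_sd)
  for (i in which(inv <= 0)) {
    while (inv[i] <= 0) inv[i] <- base[i] + rnorm(1, 0, residual_sd)
  }
  tab <- dplyr::mutate(grid, response = 1 / inv)
  attr(tab, "truth") <- list(inverse_intercept = inverse_intercept,
                             inverse_slope = inverse_slope,
                             donor_sd = donor_sd,
                             residual_sd = residual_sd, seed = seed)
  tab
}
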