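#' Pipeline configuration
#'
#' Validated bundle of the tunable parameters of the full pipeline, with the
#' defaults used throughout the package.
#'
#' @param lloq_exclusion_fraction analyte censoring threshold in `[0, 1]`.
#' @param censored_imputation `"half_lloq"`, `"lloq"` or `"drop"`.
#' @param score_pooling `"pooled"` or `"per_donor"`.
#' @param de_lfc_min,de_alpha DE significance thresholds.
#' @param gsea_weight,gsea_permutations,gsea_min_size,gsea_max_size GSEA
#'   parameters.
#' @param perm_cell_line,perm_tumor_type permutation counts for the
#'   overrepresentation families.
#' @param fdr_method `"storey"` or `"bh"` for the gene screen q-values.
#' @param seed master seed; every stochastic stage derives its stream from
#'   it.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(lloq_exclusion_fraction = 0.4,
                            censored_imputation = "half_lloq",
                            score_pooling = "pooled",
                            de_lfc_min = 1, de_alpha = 0.05,
                            gsea_weight = 1, gsea_permutations = 1000,
                            gsea_min_size = 10, gsea_max_size = 500,
                            perm_cell_line = 20000, perm_tumor_type = 5000,
                            fdr_method = "storey", seed = 1L) {
  if (lloq_exclusion_fraction < 0 || lloq_exclusion_fraction > 1) {
    abort("lloq_exclusion_fraction must lie in [0, 1].")
  }
  if (de_alpha <= 0 || de_alpha > 1) abort("de_alpha must lie in (0, 1].")
  if (gsea_permutations < 1 || perm_cell_line < 1 || perm_tumor_type < 1) {
    abort("Permutation counts must be >= 1.")
  }
  censored_imputation <- match.arg(censored_imputation,
                                   c("half_lloq", "lloq", "drop"))
  score_pooling <- match.arg(score_pooling, c("pooled", "per_donor"))
  fdr_method <- match.arg(fdr_method, c("storey", "bh"))
  structure(
    list(lloq_exclusion_fraction = lloq_exclusion_fraction,
         censored_imputation = censored_imputation,
         score_pooling = score_pooling,
         de_lfc_min = de_lfc_min, de_alpha = de_alpha,
         gsea_weight = gsea_weight, gsea_permutations = gsea_permutations,
         gsea_min_size = gsea_min_size, gsea_max_size = gsea_max_size,
         perm_cell_line = perm_cell_line, perm_tumor_type = perm_tumor_type,
         fdr_method = fdr_method, seed = as.integer(seed)),
    class = "pipeline_config"
  )
}

#' Run the full simulated-study pipeline
#'
#' End-to-end driver: simulates the default study (secretome table, linked
#' expression bundle, fractionation and dose-response experiments), scores
#' polarization capacity, runs the cytokine correlation matrix, the
#' genome-wide screen and quartile DE for the first retained analyte,
#' preranked enrichment against a collection (optional), the
#' overrepresentation permutation test, and the downstream mixed models.
#' Every artifact is written under `out_dir` together with a JSON run
#' manifest recording inputs, configuration and seed.
#'
#' @param out_dir output directory (created if missing).
#' @param config a [pipeline_config()].
#' @param scenario simulation scenario (default
#'   `make_default_scenario(config$seed)`).
#' @param collection optional gene-set collection (named list) for the
#'   enrichment stage.
#' @return invisibly, a list with every stage's in-memory result.
#' @export
run_pipeline <- function(out_dir, config = pipeline_config(),
                         scenario = NULL, collection = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed
  scenario <- scenario %||% make_default_scenario(seed)

  log_stage <- function(stage, ...) {
    message(format(Sys.time(), "%H:%M:%OS2"), " [", stage, "] ", ...)
  }

  sim <- simulate_cytokine_experiment(scenario)
  log_stage("simulate", nrow(sim$table), " measurements, ",
            nrow(scenario$analytes), " analytes")
  expr <- simulate_expression_bundle(scenario, sim$truth)
  log_stage("simulate", "expression ", nrow(expr$bundle$counts), " x ",
            ncol(expr$bundle$counts))

  scores <- score_polarization(
    sim$table, sim$lloq_map,
    max_censored_fraction = config$lloq_exclusion_fraction,
    imputation = config$censored_imputation,
    pooling = config$score_pooling, control_units = "CTRL"
  )
  log_stage("score", length(scores$retained_analytes), " analytes retained")

  cyto_cor <- pairwise_cytokine_correlations(scores)
  lead_analyte <- scores$retained_analytes[
    which.max(scenario$analytes$loading[
      match(scores$retained_analytes, scenario$analytes$name)])]
  screen <- gene_score_screen(expr$bundle, scores, lead_analyte,
                              fdr_method = config$fdr_method)
  log_stage("screen", nrow(screen), " genes vs ", lead_analyte)

  de <- quartile_de(expr$bundle, scores$quartiles, lead_analyte,
                    alpha = config$de_alpha, lfc_min = config$de_lfc_min)
  log_stage("de", sum(de$significant), " significant genes")

  enr <- NULL
  if (!is.null(collection)) {
    set.seed(seed + 2L)
    enr <- preranked_gsea(
      tibble::tibble(gene = de$gene, score = de$lfc_shrunken), collection,
      weight_exponent = config$gsea_weight,
      n_permutations = config$gsea_permutations,
      min_size = config$gsea_min_size, max_size = config$gsea_max_size
    )
    log_stage("gsea", nrow(enr), " sets scored")
  }

  overrep <- overrepresentation_test(
    scores$quartiles, n_perm_lines = config$perm_cell_line, seed = seed + 3L
  )
  log_stage("permtest", nrow(overrep), " unit x direction tests")

  frac <- simulate_fractionation(seed = seed + 4L)
  frac_fit <- fit_random_intercept(frac, response ~ condition,
                                   group = "donor")
  frac_contrasts <- pairwise_contrasts(frac_fit, "condition")
  dose <- simulate_dose_response(seed = seed + 5L)
  dose_fit <- dose_response_fit(dose)
  log_stage("models", "fractionation + dose-response fitted")

  write_results_table(sim$table, file.path(out_dir, "measurements.csv"),
                      seed, config)
  write_results_table(scores$per_unit, file.path(out_dir, "scores.csv"),
                      seed, config)
  write_results_table(scores$quartiles, file.path(out_dir, "quartiles.csv"),
                      seed, config)
  write_results_table(cyto_cor, file.path(out_dir, "cytokine_cor.csv"),
                      seed, config)
  write_results_table(screen, file.path(out_dir, "gene_screen.csv"),
                      seed, config)
  write_results_table(de, file.path(out_dir, "quartile_de.csv"),
                      seed, config)
  if (!is.null(enr)) {
    write_results_table(enr, file.path(out_dir, "enrichment.csv"),
                        seed, config)
  }
  write_results_table(overrep, file.path(out_dir, "overrepresentation.csv"),
                      seed, config)
  write_results_table(frac_contrasts,
                      file.path(out_dir, "fractionation_contrasts.csv"),
                      seed, config)
  write_results_table(dose_fit$predicted,
                      file.path(out_dir, "dose_predicted.csv"),
                      seed, config)
  jsonlite::write_json(
    list(seed = seed, config = unclass(config),
         scenario = list(n_donors = scenario$n_donors,
                         n_cell_lines = scenario$n_cell_lines,
                         n_genes = scenario$n_genes,
                         analytes = scenario$analytes$name),
         truth = list(target_icc = as.list(sim$truth$target_icc)),
         r_version = as.character(getRversion()),
         outputs = list.files(out_dir)),
    file.path(out_dir, "manifest.json"), auto_unbox = TRUE, digits = NA
  )
  log_stage("done", "artifacts in ", out_dir)
  invisible(list(scenario = scenario, truth = expr$truth,
                 measurements = sim$table, bundle = expr$bundle,
                 scores = scores, cytokine_correlations = cyto_cor,
                 screen = screen, de = de, enrichment = enr,
                 overrepresentation = overrep, fractionation_fit = frac_fit,
                 fractionation_contrasts = frac_contrasts,
                 dose_fit = dose_fit))
}
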