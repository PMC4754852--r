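# End-to-end orchestration: simulate (or load) two platforms, aggregate,
# scan with bootstrap summaries, SAM on both platforms, cross-platform
# predictor validation, methylation-expression correlation, and a
# manifest of checksums and seeds. Every stage seed derives from the
# master seed by stage name, and outputs carry no timestamps, so a rerun
# with the same config is byte-identical.

#' Build and validate a pipeline configuration
#'
#' Each platform is either simulated (`training_sim` / `validation_sim`
#' parameter lists) or loaded from files (`training_paths` /
#' `validation_paths` with elements beta, annotation, samples, and for
#' validation also expression); exactly one of the two must be given per
#' platform.
#'
#' @param out_dir output directory (created if needed).
#' @param seed master integer seed.
#' @param training_sim,validation_sim simulation parameter lists; see
#'   Details.
#' @param training_paths,validation_paths input file path lists.
#' @param p_thresholds p-value cuts for the direction summaries.
#' @param delta_training,delta_validation SAM delta per platform.
#' @param alpha t-test confirmation level for validation.
#' @param n_bootstrap bootstrap replicates for direction CIs.
#' @param n_permutations SAM permutations.
#' @param knn_k imputation neighbours.
#' @param n_predictors how many top training SAM genes to carry into
#'   validation.
#'
#' @details Simulation lists accept `n_samples`, `prevalence_positive`,
#' `n_genes`, `race_weights`, plus effect parameters
#' (`frac_hyper_in_positive`, `frac_hypo_in_positive`,
#' `effect_size_logit`, `frac_inverse_expression`, `noise_sd_logit`,
#' `expression_noise_sd`). Defaults emulate the two study designs: a
#' 75-sample, 807-gene panel at 71 % ER/PR-positive prevalence and a
#' 306-sample, 2000-gene platform at 78 %; training genes are a subset of
#' validation genes so predictors transfer across platforms.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(out_dir, seed, training_sim = list(),
                            validation_sim = list(),
                            training_paths = NULL, validation_paths = NULL,
                            p_thresholds = c(1, 0.2, 0.05),
                            delta_training = 0.7, delta_validation = 3,
                            alpha = 0.05, n_bootstrap = 1000,
                            n_permutations = 1000, knn_k = 10,
                            n_predictors = 25) {
  if (missing(seed)) stop("a master seed is required")
  for (side in c("training", "validation")) {
    paths <- get(paste0(side, "_paths"))
    sim <- get(paste0(side, "_sim"))
    if (!is.null(paths) && length(sim) > 0)
      stop("give either ", side, "_paths or ", side,
           "_sim parameters, not both")
    if (!is.null(paths)) {
      need <- c("beta", "annotation", "samples")
      if (side == "validation") need <- c(need, "expression")
      missing_el <- setdiff(need, names(paths))
      if (length(missing_el) > 0)
        stop(side, "_paths lacks element(s): ",
             paste(missing_el, collapse = ", "))
    }
  }
  structure(list(out_dir = out_dir, seed = seed,
                 training_sim = training_sim,
                 validation_sim = validation_sim,
                 training_paths = training_paths,
                 validation_paths = validation_paths,
                 p_thresholds = p_thresholds,
                 delta_training = delta_training,
                 delta_validation = delta_validation, alpha = alpha,
                 n_bootstrap = n_bootstrap,
                 n_permutations = n_permutations, knn_k = knn_k,
                 n_predictors = n_predictors),
            class = "pipeline_config")
}

sim_defaults <- function(sim, side) {
  base <- if (side == "training")
    list(n_samples = 75, prevalence_positive = 0.71, n_genes = 807,
         race_weights = c(nH_White = 21, nH_Black = 31, Hispanic = 23) / 75)
  else
    list(n_samples = 306, prevalence_positive = 0.78, n_genes = 2000,
         race_weights = c(nH_White = 182, nH_Black = 22, Hispanic = 1,
                          Asian = 21, Unknown = 80) / 306)
  eff <- list(frac_hyper_in_positive = 0.05, frac_hypo_in_positive = 0.01,
              effect_size_logit = 1, frac_inverse_expression = 0.85,
              expression_slope_magnitude = 5, noise_sd_logit = 0.5,
              expression_noise_sd = 1)
  utils::modifyList(c(base, eff), sim)
}

load_or_simulate <- function(config, side, effects_val) {
  paths <- config[[paste0(side, "_paths")]]
  if (!is.null(paths)) {
    beta <- read_beta_matrix(paths$beta, platform_id = side)
    ann <- read_probe_annotation(paths$annotation, platform_id = side)
    samples <- read_sample_table(paths$samples)
    gm <- aggregate_to_genes(beta, ann)
    expr <- if (!is.null(paths$expression)) {
      em <- read_beta_matrix2_expr(paths$expression)
      em
    } else NULL
    return(list(samples = samples, beta = beta, annotation = ann,
                gene_meth = gm, expression = expr, truth = NULL))
  }
  sim <- sim_defaults(config[[paste0(side, "_sim")]], side)
  effects <- if (side == "training")
    effects_val[seq_len(min(sim$n_genes, nrow(effects_val))), ]
  else effects_val
  platform <- if (side == "training") platform_goldengate()
              else platform_hm27()
  simulate_platform_cohort(
    sim$n_samples, sim$prevalence_positive, effects, platform,
    seed = derive_seed(config$seed, side),
    race_weights = sim$race_weights,
    expression = (side == "validation"))
}

# expression matrices share the beta-matrix text layout but are not range
# restricted
read_beta_matrix2_expr <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE,
                          data.table = FALSE, check.names = FALSE)
  vals <- as.matrix(dt[, -1, drop = FALSE])
  rownames(vals) <- dt[[1]]
  structure(vals, class = c("expression_matrix", "matrix", "array"))
}

#' Run the full two-platform analysis pipeline
#'
#' Stages: simulate/load both platforms -> aggregate probes to genes ->
#' per-gene logistic scan with bootstrapped direction summaries at each
#' p threshold -> SAM (gene level on training, probe level on
#' validation) -> cross-platform validation of the top training
#' predictors -> methylation-expression correlation on the validation
#' platform -> manifest. All outputs are tab-separated text under
#' `config$out_dir`; the manifest records md5 checksums, stage seeds and
#' package version. Reruns with an identical config are byte-identical.
#'
#' @param config a [pipeline_config].
#' @return (invisibly) a list with every stage result and output paths.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(config$out_dir, f)
  log_lines <- character(0)
  say <- function(...) {
    msg <- sprintf(...)
    message("[methscan] ", msg)
    log_lines <<- c(log_lines, msg)
  }

  # --- stage: data -------------------------------------------------------
  n_genes_val <- sim_defaults(config$validation_sim, "validation")$n_genes
  eff_par <- sim_defaults(config$validation_sim, "validation")
  effects_val <- make_gene_effects(
    n_genes = n_genes_val,
    frac_hyper_in_positive = eff_par$frac_hyper_in_positive,
    frac_hypo_in_positive = eff_par$frac_hypo_in_positive,
    effect_size_logit = eff_par$effect_size_logit,
    frac_inverse_expression = eff_par$frac_inverse_expression,
    expression_slope_magnitude = eff_par$expression_slope_magnitude,
    noise_sd_logit = eff_par$noise_sd_logit,
    expression_noise_sd = eff_par$expression_noise_sd,
    seed = derive_seed(config$seed, "effects"))
  training <- load_or_simulate(config, "training", effects_val)
  validation <- load_or_simulate(config, "validation", effects_val)
  say("training: %d probes x %d samples, %d genes",
      nrow(training$beta), ncol(training$beta), nrow(training$gene_meth))
  say("validation: %d probes x %d samples, %d genes",
      nrow(validation$beta), ncol(validation$beta),
      nrow(validation$gene_meth))
  write_beta_matrix(training$beta, out("training_beta.tsv"))
  write_table(training$annotation, out("training_annotation.tsv"))
  write_table(training$samples, out("training_samples.tsv"))
  write_beta_matrix(validation$beta, out("validation_beta.tsv"))
  write_table(validation$annotation, out("validation_annotation.tsv"))
  write_table(validation$samples, out("validation_samples.tsv"))
  if (!is.null(validation$expression))
    write_beta_matrix(validation$expression, out("validation_expression.tsv"),
                      id_column = "gene_symbol")
  if (!is.null(training$truth))
    write_table(training$truth, out("truth.tsv"))
  write_beta_matrix(training$gene_meth, out("training_gene_meth.tsv"),
                    id_column = "gene_symbol")
  write_beta_matrix(validation$gene_meth, out("validation_gene_meth.tsv"),
                    id_column = "gene_symbol")

  # --- stage: scan -------------------------------------------------------
  scan <- scan_all_genes(training$gene_meth, training$samples)
  write_table(scan, out("training_associations.tsv"))
  say("scan: %d genes fitted, %d excluded", sum(scan$converged),
      sum(!scan$converged))
  summaries <- lapply(config$p_thresholds, function(p)
    bootstrap_direction_ci(training$gene_meth, training$samples,
                           p_threshold = p,
                           n_bootstrap = config$n_bootstrap,
                           seed = derive_seed(config$seed, "bootstrap")))
  summary_df <- do.call(rbind, lapply(summaries, as.data.frame))
  write_table(summary_df, out("direction_summary.tsv"))

  # --- stage: sam --------------------------------------------------------
  sam_train <- run_sam(training$gene_meth, training$samples,
                       sam_config(delta = config$delta_training,
                                  n_permutations = config$n_permutations,
                                  knn_k = config$knn_k,
                                  seed = derive_seed(config$seed,
                                                     "sam_training")))
  write_table(as.data.frame(sam_train), out("sam_training.tsv"))
  say("sam training: s0 = %.4g, %d called positive, %d negative",
      sam_train$s0, length(sam_train$significant_positive),
      length(sam_train$significant_negative))
  sam_val <- run_sam(validation$beta, validation$samples,
                     sam_config(delta = config$delta_validation,
                                n_permutations = config$n_permutations,
                                knn_k = config$knn_k,
                                seed = derive_seed(config$seed,
                                                   "sam_validation")),
                     annotation = validation$annotation)
  write_table(as.data.frame(sam_val), out("sam_validation_probes.tsv"))
  write_table(sam_val$gene_view, out("sam_validation_genes.tsv"))

  # --- stage: validate ---------------------------------------------------
  d_called <- sam_train$d_scores[sam_train$significant_positive]
  top <- names(sort(d_called, decreasing = TRUE))
  top <- head(top, config$n_predictors)
  predictors <- data.frame(gene_symbol = top,
                           training_direction = rep("positive",
                                                    length(top)),
                           training_d = unname(sam_train$d_scores[top]),
                           stringsAsFactors = FALSE)
  val <- validate_predictors(predictors, validation$beta,
                             validation$annotation, validation$samples,
                             sam_val, alpha = config$alpha)
  write_table(val$records, out("predictor_validation.tsv"))
  write_table(as.data.frame(val$summary), out("concordance_summary.tsv"))
  say("validation: %d/%d concordant, %d t-test confirmed",
      val$summary$n_direction_concordant, val$summary$n_predictors,
      val$summary$n_ttest_confirmed)

  # --- stage: correlate --------------------------------------------------
  correlations <- NULL
  if (!is.null(validation$expression)) {
    correlations <- correlate_methylation_expression(
      validation$gene_meth, validation$expression, validation$samples,
      stratum = "each")
    write_table(correlations, out("correlations.tsv"))
    counts <- count_significant_correlations(correlations,
                                             alpha = config$alpha)
    write_table(counts, out("correlation_counts.tsv"))
    say("correlation: %d genes x %d strata",
        length(unique(correlations$gene_symbol)),
        length(unique(correlations$stratum)))
  }

  # --- manifest ----------------------------------------------------------
  files <- sort(setdiff(list.files(config$out_dir),
                        c("manifest.tsv", "run_log.txt")))
  manifest <- data.frame(
    file = files,
    md5 = unname(tools::md5sum(file.path(config$out_dir, files))),
    stringsAsFactors = FALSE)
  info <- data.frame(
    file = c("#master_seed", "#package_version",
             paste0("#seed_", c("effects", "training", "validation",
                                "bootstrap", "sam_training",
                                "sam_validation"))),
    md5 = c(as.character(config$seed),
            as.character(utils::packageVersion("methscan")),
            vapply(c("effects", "training", "validation", "bootstrap",
                     "sam_training", "sam_validation"),
                   function(s) as.character(derive_seed(config$seed, s)),
                   character(1))),
    stringsAsFactors = FALSE)
  write_table(rbind(info, manifest), out("manifest.tsv"))
  writeLines(log_lines, out("run_log.txt"))

  invisible(list(training = training, validation = validation,
                 scan = scan, summaries = summaries,
                 sam_training = sam_train, sam_validation = sam_val,
                 validation_result = val, correlations = correlations,
                 out_dir = config$out_dir))
}
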