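# Seeded synthetic-cohort generator.
#
# Emulates two methylation array designs with planted, recorded
# ground-truth effects: group shifts are planted on the logit scale of
# beta (so values stay inside [0,1]) and expression is linearly coupled to
# gene mean beta. Every stochastic function takes an explicit seed and is
# byte-deterministic under it.

#' Platform design specification
#'
#' @param platform_id label.
#' @param probes_per_gene_weights length-3 probability vector for a gene
#'   carrying 1, 2, or 3+ probes ("3+" is drawn uniformly from 3..5,
#'   matching designs with up to five promoter CpG sites per gene).
#' @param probe_offset_sd_logit SD of the fixed probe-specific shift on
#'   the logit-beta scale (probes of one gene share the gene baseline but
#'   differ in their own offset).
#' @param missing_rate fraction of cells set missing at random.
#' @return a `platform_spec` list.
#' @export
platform_spec <- function(platform_id,
                          probes_per_gene_weights = c(0.286, 0.573, 0.141),
                          probe_offset_sd_logit = 0.5,
                          missing_rate = 0.02) {
  w <- probes_per_gene_weights
  if (length(w) != 3 || any(w < 0) || abs(sum(w) - 1) > 1e-8)
    stop("probes_per_gene_weights must be 3 non-negative weights summing to 1")
  if (probe_offset_sd_logit <= 0) stop("probe_offset_sd_logit must be > 0")
  if (missing_rate < 0 || missing_rate >= 1)
    stop("missing_rate must be in [0, 1)")
  structure(list(platform_id = platform_id,
                 probes_per_gene_weights = w,
                 probe_offset_sd_logit = probe_offset_sd_logit,
                 missing_rate = missing_rate),
            class = "platform_spec")
}

#' Built-in platform presets
#'
#' `platform_goldengate()` emulates a 1505-probe cancer panel covering 807
#' genes with 28.6/57.3/14.1 % of genes carrying 1/2/3+ probes;
#' `platform_hm27()` emulates a larger promoter array where nearly every
#' gene has about two probes.
#'
#' @return a [platform_spec].
#' @export
platform_goldengate <- function() {
  platform_spec("goldengate_like",
                probes_per_gene_weights = c(0.286, 0.573, 0.141),
                probe_offset_sd_logit = 0.5, missing_rate = 0.02)
}

#' @rdname platform_goldengate
#' @export
platform_hm27 <- function() {
  platform_spec("hm27_like",
                probes_per_gene_weights = c(0.35, 0.45, 0.20),
                probe_offset_sd_logit = 0.5, missing_rate = 0.01)
}

#' Simulate a sample phenotype table
#'
#' Exactly `round(n_samples * prevalence_positive)` samples are made
#' ER/PR-positive (assigned ER and/or PR positive at random); the rest are
#' negative for both receptors. Ages are uniform over `age_range`, race
#' drawn from `race_weights`.
#'
#' @param n_samples number of samples (>= 4, so both groups can hold two).
#' @param prevalence_positive fraction ER/PR-positive, strictly in (0,1).
#' @param race_weights named probability vector over the race/ethnicity
#'   levels; defaults to the training-cohort composition (21 nH White, 31
#'   nH Black, 23 Hispanic of 75).
#' @param age_range length-2 numeric, ages drawn uniformly inside it.
#' @param seed integer seed; identical seeds give identical tables.
#' @return a [sample_table].
#' @export
simulate_cohort <- function(n_samples, prevalence_positive = 0.71,
                            race_weights = c(nH_White = 21, nH_Black = 31,
                                             Hispanic = 23) / 75,
                            age_range = c(30, 80), seed) {
  if (n_samples < 4) stop("n_samples must be >= 4")
  if (prevalence_positive <= 0 || prevalence_positive >= 1)
    stop("prevalence_positive must be strictly inside (0, 1)")
  if (abs(sum(race_weights) - 1) > 1e-8)
    stop("race_weights must sum to 1")
  if (!all(names(race_weights) %in% RACE_LEVELS))
    stop("race_weights names must be among: ",
         paste(RACE_LEVELS, collapse = ", "))
  n_pos <- round(n_samples * prevalence_positive)
  with_seed(seed, {
    ids <- sprintf("S%04d", seq_len(n_samples))
    pos <- sample(n_samples, n_pos)
    er <- pr <- rep("negative", n_samples)
    # among positives: both receptors positive most often, then ER-only,
    # then PR-only
    combo <- sample(c("both", "er_only", "pr_only"), n_pos, replace = TRUE,
                    prob = c(0.65, 0.20, 0.15))
    er[pos] <- ifelse(combo %in% c("both", "er_only"), "positive",
                      "negative")
    pr[pos] <- ifelse(combo %in% c("both", "pr_only"), "positive",
                      "negative")
    age <- round(runif(n_samples, age_range[1], age_range[2]), 1)
    race <- sample(names(race_weights), n_samples, replace = TRUE,
                   prob = race_weights)
    sample_table(ids, er, pr, age, race)
  })
}

#' Plant per-gene ground-truth effects
#'
#' `round(n_genes * frac_hyper_in_positive)` genes receive a positive
#' logit-scale methylation shift in ER/PR-positive samples (hypermethylated
#' in receptor-positive disease), `round(n_genes * frac_hypo_in_positive)`
#' the negative shift, the remainder no shift. Expression coupling slopes
#' are negative (inverse, the typical promoter-methylation effect) for
#' `round(n_genes * frac_inverse_expression)` genes and positive for the
#' rest. Baseline beta values are drawn from a symmetric Beta(2,2) on
#' (0,1).
#'
#' @param n_genes number of genes.
#' @param frac_hyper_in_positive,frac_hypo_in_positive effect fractions;
#'   their sum must not exceed 1.
#' @param effect_size_logit positive logit-scale shift magnitude.
#' @param frac_inverse_expression fraction of genes with inverse
#'   methylation-expression coupling.
#' @param expression_slope_magnitude absolute coupling slope (expression
#'   units per unit mean beta).
#' @param noise_sd_logit per-cell methylation noise SD (logit scale).
#' @param expression_noise_sd per-cell expression noise SD.
#' @param seed integer seed.
#' @return a `gene_effects` data.frame with one row per gene: gene_symbol,
#'   baseline_beta, effect_logit, expression_slope, noise_sd_logit,
#'   expression_noise_sd.
#' @export
make_gene_effects <- function(n_genes = 807, frac_hyper_in_positive = 0.05,
                              frac_hypo_in_positive = 0.01,
                              effect_size_logit = 1,
                              frac_inverse_expression = 0.85,
                              expression_slope_magnitude = 5,
                              noise_sd_logit = 0.5,
                              expression_noise_sd = 1, seed) {
  fracs <- c(frac_hyper_in_positive, frac_hypo_in_positive,
             frac_inverse_expression)
  if (any(fracs < 0 | fracs > 1)) stop("fractions must lie in [0, 1]")
  if (frac_hyper_in_positive + frac_hypo_in_positive > 1)
    stop("frac_hyper_in_positive + frac_hypo_in_positive must be <= 1")
  if (effect_size_logit < 0) stop("effect_size_logit must be >= 0")
  if (noise_sd_logit <= 0 || expression_noise_sd <= 0)
    stop("noise standard deviations must be > 0")
  n_hyper <- round(n_genes * frac_hyper_in_positive)
  n_hypo <- round(n_genes * frac_hypo_in_positive)
  n_inv <- round(n_genes * frac_inverse_expression)
  with_seed(seed, {
    effect <- numeric(n_genes)
    pick <- sample(n_genes, n_hyper + n_hypo)
    effect[pick[seq_len(n_hyper)]] <- effect_size_logit
    if (n_hypo > 0)
      effect[pick[n_hyper + seq_len(n_hypo)]] <- -effect_size_logit
    slope <- rep(expression_slope_magnitude, n_genes)
    slope[sample(n_genes, n_inv)] <- -expression_slope_magnitude
    baseline <- pmin(pmax(rbeta(n_genes, 2, 2), 1e-3), 1 - 1e-3)
    structure(data.frame(gene_symbol = sprintf("GENE%05d", seq_len(n_genes)),
                         baseline_beta = baseline, effect_logit = effect,
                         expression_slope = slope,
                         noise_sd_logit = noise_sd_logit,
                         expression_noise_sd = expression_noise_sd,
                         stringsAsFactors = FALSE),
              class = c("gene_effects", "data.frame"))
  })
}

#' Simulate probe-level methylation for a cohort
#'
#' Each gene receives a probe count drawn from the platform's weights; a
#' probe value is `plogis(qlogis(baseline) + probe_offset + effect *
#' is_positive + noise)`, clamped to \[1e-6, 1-1e-6\], then a
#' `missing_rate` fraction of cells is blanked at random (never a whole
#' probe row).
#'
#' @param samples a [sample_table].
#' @param effects a `gene_effects` table from [make_gene_effects()].
#' @param platform a [platform_spec].
#' @param seed integer seed.
#' @return list with elements `beta` (a [beta_matrix]) and `annotation`
#'   (a [probe_annotation]).
#' @export
simulate_methylation <- function(samples, effects, platform, seed) {
  stopifnot(inherits(platform, "platform_spec"))
  if (nrow(effects) == 0) stop("'effects' must be non-empty")
  n <- nrow(samples)
  pos <- as.numeric(samples$erpr_group == "positive")
  with_seed(seed, {
    k_class <- sample(3L, nrow(effects), replace = TRUE,
                      prob = platform$probes_per_gene_weights)
    k <- ifelse(k_class == 3L, sample(3:5, nrow(effects), replace = TRUE),
                k_class)
    gene_of_probe <- rep(seq_len(nrow(effects)), k)
    n_probes <- length(gene_of_probe)
    probe_ids <- sprintf("cg%06d", seq_len(n_probes))
    offset <- rnorm(n_probes, 0, platform$probe_offset_sd_logit)
    eta <- qlogis(effects$baseline_beta[gene_of_probe]) + offset
    m <- matrix(eta, n_probes, n) +
      outer(effects$effect_logit[gene_of_probe], pos) +
      matrix(rnorm(n_probes * n, 0,
                   rep(effects$noise_sd_logit[gene_of_probe], n)),
             n_probes, n)
    vals <- pmin(pmax(plogis(m), 1e-6), 1 - 1e-6)
    if (platform$missing_rate > 0) {
      vals[runif(length(vals)) < platform$missing_rate] <- NA_real_
      gone <- which(rowSums(!is.na(vals)) == 0)
      for (i in gone)  # keep every probe observed at least once
        vals[i, sample(n, 1)] <- pmin(pmax(plogis(
          eta[i] + rnorm(1, 0, effects$noise_sd_logit[gene_of_probe[i]])),
          1e-6), 1 - 1e-6)
    }
    dimnames(vals) <- list(probe_ids, samples$sample_id)
    list(beta = beta_matrix(vals, platform_id = platform$platform_id),
         annotation = probe_annotation(
           probe_ids, effects$gene_symbol[gene_of_probe],
           platform_id = platform$platform_id))
  })
}

#' Simulate expression coupled to gene methylation
#'
#' `expression(g, s) = intercept + slope_g * mean_beta(g, s) + noise`;
#' a negative slope models the usual repressive effect of promoter
#' methylation on transcription.
#'
#' @param gene_meth gene x sample mean-beta matrix
#'   (from [aggregate_to_genes()]).
#' @param effects `gene_effects` table covering all genes of `gene_meth`.
#' @param seed integer seed.
#' @param intercept common expression baseline (log-scale units).
#' @return an `expression_matrix` (genes x samples).
#' @export
simulate_expression <- function(gene_meth, effects, seed, intercept = 8) {
  idx <- match(rownames(gene_meth), effects$gene_symbol)
  if (anyNA(idx))
    stop("genes missing from effects: ",
         paste(head(rownames(gene_meth)[is.na(idx)]), collapse = ", "))
  with_seed(seed, {
    slope <- effects$expression_slope[idx]
    noise <- matrix(rnorm(length(gene_meth), 0,
                          rep(effects$expression_noise_sd[idx],
                              ncol(gene_meth))),
                    nrow(gene_meth), ncol(gene_meth))
    expr <- intercept + gene_meth * slope + noise
    dimnames(expr) <- dimnames(gene_meth)
    structure(unclass(expr), class = c("expression_matrix", "matrix",
                                       "array"))
  })
}

#' Simulate a full cohort on one platform
#'
#' Convenience wrapper bundling phenotype, methylation, annotation,
#' expression and the ground truth into one object. Sub-stage seeds are
#' derived from `seed` by stage name, so the methylation draw does not
#' depend on whether expression is requested.
#'
#' @param n_samples,prevalence_positive,race_weights,age_range passed to
#'   [simulate_cohort()].
#' @param effects `gene_effects` table (the planted truth).
#' @param platform a [platform_spec].
#' @param seed integer master seed for this cohort.
#' @param expression if `TRUE` (default) also simulate coupled expression.
#' @return a `synthetic_cohort` list: samples, beta, annotation,
#'   gene_meth, expression, truth.
#' @export
simulate_platform_cohort <- function(n_samples, prevalence_positive,
                                     effects, platform, seed,
                                     race_weights = c(nH_White = 21,
                                                      nH_Black = 31,
                                                      Hispanic = 23) / 75,
                                     age_range = c(30, 80),
                                     expression = TRUE) {
  samples <- simulate_cohort(n_samples, prevalence_positive, race_weights,
                             age_range, seed = derive_seed(seed, "samples"))
  meth <- simulate_methylation(samples, effects, platform,
                               seed = derive_seed(seed, "methylation"))
  gm <- aggregate_to_genes(meth$beta, meth$annotation)
  expr <- if (expression)
    simulate_expression(gm, effects, seed = derive_seed(seed, "expression"))
  else NULL
  structure(list(samples = samples, beta = meth$beta,
                 annotation = meth$annotation, gene_meth = gm,
                 expression = expr, truth = effects),
            class = "synthetic_cohort")
}
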