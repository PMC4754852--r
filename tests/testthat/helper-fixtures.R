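# Small in-code fixtures shared across test files.

# deterministic toy beta matrix
toy_beta <- function(nr = 3, nc = 2, platform = "toy") {
  vals <- matrix(seq(0.1, 0.9, length.out = nr * nc), nr, nc,
                 dimnames = list(sprintf("cg%03d", seq_len(nr)),
                                 sprintf("S%02d", seq_len(nc))))
  beta_matrix(vals, platform_id = platform)
}

# balanced two-group phenotype table; first n_pos samples ER/PR-positive
toy_samples <- function(n_pos, n_neg, age = NULL) {
  n <- n_pos + n_neg
  sample_table(sprintf("S%02d", seq_len(n)),
               er_status = rep(c("positive", "negative"),
                               c(n_pos, n_neg)),
               pr_status = rep("negative", n),
               age_years = age %||% seq(40, 70, length.out = n),
               race_ethnicity = rep(c("nH_White", "nH_Black", "Hispanic"),
                                    length.out = n))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# null cohort (no planted effects) on the compact panel design
null_cohort <- function(n_genes, n_samples, seed, noise_sd = 0.5,
                        missing_rate = 0) {
  eff <- make_gene_effects(n_genes, frac_hyper_in_positive = 0,
                           frac_hypo_in_positive = 0,
                           noise_sd_logit = noise_sd, seed = seed)
  plat <- platform_spec("toy_panel", missing_rate = missing_rate)
  simulate_platform_cohort(n_samples, 0.71, eff, plat, seed = seed,
                           expression = FALSE)
}

# longhand SAM statistic for a single feature (independent of sam_d_scores)
longhand_d <- function(x1, x2, s0 = 0) {
  n1 <- length(x1); n2 <- length(x2)
  ss <- sum((x1 - mean(x1))^2) + sum((x2 - mean(x2))^2)
  s <- sqrt((1 / n1 + 1 / n2) * ss / (n1 + n2 - 2))
  list(d = (mean(x1) - mean(x2)) / (s + s0), s = s)
}
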