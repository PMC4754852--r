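# Gene-level association scan.
#
# Probe beta values are averaged per gene; each gene's mean beta then
# predicts ER/PR-positive status in its own logistic model, adjusted for
# age and race/ethnicity. Coefficient signs are dichotomized into positive
# vs inverse associations and summarized as a positive fraction and a
# positive:inverse ratio with bias-corrected percentile bootstrap CIs.

#' Average probe beta values to gene level
#'
#' All probes annotated to the same gene are averaged per sample over
#' their non-missing values; a gene-sample cell is missing only when every
#' contributing probe is missing there.
#'
#' @param beta a [beta_matrix].
#' @param annotation a [probe_annotation] covering every probe of `beta`.
#' @return a `gene_methylation` matrix (genes x samples, rownames = gene
#'   symbols, genes in first-appearance order of the annotation).
#' @export
aggregate_to_genes <- function(beta, annotation) {
  missing_probes <- setdiff(rownames(beta), annotation$probe_id)
  if (length(missing_probes) > 0)
    stop("probes without annotation: ",
         paste(head(missing_probes, 10), collapse = ", "))
  ann <- annotation[match(rownames(beta), annotation$probe_id), ]
  genes <- unique(ann$gene_symbol)
  g <- factor(ann$gene_symbol, levels = genes)
  obs <- !is.na(beta)
  x <- beta
  x[!obs] <- 0
  sums <- rowsum(unclass(x), g)
  counts <- rowsum(obs + 0, g)
  out <- sums / counts                      # 0/0 -> NaN where all missing
  out[counts == 0] <- NA_real_
  structure(unclass(out), platform_id = attr(beta, "platform_id"),
            class = c("gene_methylation", "matrix", "array"))
}

# covariate design shared by all genes: numeric age + race dummies with
# nH White as the referent
build_covariates <- function(samples) {
  race <- samples$race_ethnicity
  levs <- setdiff(intersect(RACE_LEVELS, unique(race)), "nH_White")
  cov <- cbind(age_years = samples$age_years)
  for (lv in levs) cov <- cbind(cov, as.numeric(race == lv))
  colnames(cov) <- c("age_years", paste0("race_", levs))
  cov
}

as_association_df <- function(fit, gene_symbols) {
  direction <- rep("excluded", length(gene_symbols))
  direction[fit$converged & !is.na(fit$coefficient) &
              fit$coefficient > 0] <- "positive"
  direction[fit$converged & !is.na(fit$coefficient) &
              fit$coefficient < 0] <- "inverse"
  structure(data.frame(gene_symbol = gene_symbols,
                       coefficient = fit$coefficient,
                       std_error = fit$std_error, p_value = fit$p_value,
                       direction = direction, converged = fit$converged,
                       n_used = fit$n_used, stringsAsFactors = FALSE),
            class = c("association_result", "data.frame"))
}

#' Fit one gene's adjusted logistic model
#'
#' Maximum-likelihood logistic regression of ER/PR-positive status on a
#' gene's mean beta plus optional covariates, by iteratively reweighted
#' least squares. Samples with a missing gene value are dropped
#' (`n_used`). Non-convergence, separation, a constant predictor or a
#' rank-deficient design yield an excluded (non-converged) result rather
#' than an error; Wald two-sided p-values.
#'
#' @param gene_values per-sample mean beta (NA allowed).
#' @param outcome per-sample 0/1, 1 = ER/PR-positive.
#' @param covariates optional numeric matrix (samples x covariates).
#' @param gene_symbol label for the result row.
#' @return a one-row `association_result` data.frame.
#' @export
fit_gene_logistic <- function(gene_values, outcome, covariates = NULL,
                              gene_symbol = "gene") {
  if (!all(outcome %in% c(0, 1))) stop("outcome must be binary 0/1")
  if (is.null(covariates))
    covariates <- matrix(numeric(0), nrow = 0, ncol = 0)
  covariates <- as.matrix(covariates)
  fit <- .logistic_scan_cpp(matrix(gene_values, nrow = 1),
                            as.numeric(outcome), covariates)
  as_association_df(fit, gene_symbol)
}

#' Scan every gene's association with ER/PR status
#'
#' Runs [fit_gene_logistic()] for each gene one at a time, adjusting for
#' age (continuous) and race/ethnicity (dummies against the nH White
#' referent). Samples with unknown ER/PR group are dropped up front.
#'
#' @param gene_meth gene x sample matrix from [aggregate_to_genes()].
#' @param samples a [sample_table] covering the matrix columns.
#' @return an `association_result` data.frame, one row per gene in matrix
#'   order.
#' @export
scan_all_genes <- function(gene_meth, samples) {
  idx <- match(colnames(gene_meth), samples$sample_id)
  if (anyNA(idx))
    stop("samples missing from sample table: ",
         paste(head(colnames(gene_meth)[is.na(idx)]), collapse = ", "))
  samples <- samples[idx, ]
  keep <- samples$erpr_group != "unknown"
  samples <- samples[keep, ]
  y <- as.numeric(samples$erpr_group == "positive")
  if (sum(y == 0) == 0) stop("cohort has no ER/PR-negative samples")
  if (sum(y == 1) == 0) stop("cohort has no ER/PR-positive samples")
  fit <- .logistic_scan_cpp(unclass(gene_meth)[, keep, drop = FALSE], y,
                            build_covariates(samples))
  as_association_df(fit, rownames(gene_meth))
}

#' Summarize association directions at a p-value threshold
#'
#' Counts converged genes with `p_value <= p_threshold` by coefficient
#' sign and forms the positive fraction and the positive:inverse ratio.
#' Values are kept at full precision; [format()] rounds for presentation
#' (proportion to 2 decimals, ratio to 1, percentage to integer).
#'
#' @param results an `association_result` data.frame.
#' @param p_threshold raw p-value cut (1 keeps every converged gene).
#' @return a `direction_summary` list: p_threshold, n_total, n_positive,
#'   n_inverse, prop_positive, ratio_pos_inverse, ci fields (NULL until
#'   bootstrapped), n_bootstrap, defined flag.
#' @export
summarize_directions <- function(results, p_threshold = 1) {
  if (p_threshold <= 0 || p_threshold > 1)
    stop("p_threshold must be in (0, 1]")
  sel <- results$converged & !is.na(results$p_value) &
    results$p_value <= p_threshold & results$direction != "excluded"
  n_pos <- sum(results$direction[sel] == "positive")
  n_inv <- sum(results$direction[sel] == "inverse")
  n_tot <- n_pos + n_inv
  structure(list(p_threshold = p_threshold, n_total = n_tot,
                 n_positive = n_pos, n_inverse = n_inv,
                 prop_positive = if (n_tot > 0) n_pos / n_tot else NA_real_,
                 ratio_pos_inverse = if (n_tot == 0) NA_real_
                                     else if (n_inv == 0) Inf
                                     else n_pos / n_inv,
                 ci_prop = NULL, ci_ratio = NULL, n_bootstrap = 0L,
                 defined = n_tot > 0),
            class = "direction_summary")
}

# bias-corrected percentile interval (no acceleration): z0 from the
# fraction of bootstrap statistics strictly below the observed value with
# ties counted half
bc_interval <- function(boot, observed, conf_level = 0.95) {
  boot <- boot[is.finite(boot)]
  if (length(boot) == 0) return(c(NA_real_, NA_real_))
  z0 <- qnorm((sum(boot < observed) + 0.5 * sum(boot == observed)) /
                length(boot))
  za <- qnorm(1 - (1 - conf_level) / 2)
  probs <- pnorm(c(2 * z0 - za, 2 * z0 + za))
  quantile(boot, probs, names = FALSE, type = 7)
}

#' Bootstrap bias-corrected CIs for the direction summary
#'
#' Resamples patients with replacement (unstratified), reruns the full
#' per-gene scan and direction summary on each replicate, and attaches
#' bias-corrected percentile intervals for the positive fraction and the
#' positive:inverse ratio. Replicates where the ratio is undefined or
#' infinite (no inverse associations) are excluded from the ratio CI and
#' counted in `n_degenerate_ratio`; bootstrap medians of both statistics
#' are reported alongside.
#'
#' @param gene_meth gene x sample matrix.
#' @param samples a [sample_table].
#' @param p_threshold p-value cut passed to [summarize_directions()].
#' @param n_bootstrap number of replicates (>= 1; 1000 in routine use).
#' @param seed integer seed; replicate b draws its resample from seed + b,
#'   so partial reruns reproduce individual replicates.
#' @param conf_level nominal CI coverage.
#' @return a `direction_summary` with `ci_prop`, `ci_ratio`,
#'   `boot_median_prop`, `boot_median_ratio`, `n_degenerate_ratio`,
#'   `n_degenerate_prop` filled in.
#' @export
bootstrap_direction_ci <- function(gene_meth, samples, p_threshold = 0.05,
                                   n_bootstrap = 1000, seed,
                                   conf_level = 0.95) {
  if (n_bootstrap < 1) stop("n_bootstrap must be >= 1")
  obs <- summarize_directions(scan_all_genes(gene_meth, samples),
                              p_threshold)
  idx0 <- match(colnames(gene_meth), samples$sample_id)
  samples <- samples[idx0, ]
  keep <- samples$erpr_group != "unknown"
  samples <- samples[keep, ]
  gm0 <- unclass(gene_meth)[, keep, drop = FALSE]
  y0 <- as.numeric(samples$erpr_group == "positive")
  cov0 <- build_covariates(samples)
  n <- length(y0)
  prop_b <- ratio_b <- rep(NA_real_, n_bootstrap)
  for (b in seq_len(n_bootstrap)) {
    take <- with_seed((as.numeric(seed) + b) %% 2147483647,
                      sample(n, n, replace = TRUE))
    # same per-gene fits as scan_all_genes on the resampled cohort
    # (constant covariate columns from absent levels drop inside the fit)
    fit <- .logistic_scan_cpp(gm0[, take, drop = FALSE], y0[take],
                              cov0[take, , drop = FALSE])
    sel <- fit$converged & !is.na(fit$p_value) &
      fit$p_value <= p_threshold & fit$coefficient != 0
    n_pos <- sum(fit$coefficient[sel] > 0)
    n_inv <- sum(fit$coefficient[sel] < 0)
    if (n_pos + n_inv > 0) {
      prop_b[b] <- n_pos / (n_pos + n_inv)
      ratio_b[b] <- if (n_inv == 0) Inf else n_pos / n_inv
    }
  }
  obs$n_bootstrap <- as.integer(n_bootstrap)
  obs$n_degenerate_prop <- sum(!is.finite(prop_b))
  obs$n_degenerate_ratio <- sum(!is.finite(ratio_b))
  obs$ci_prop <- if (obs$defined)
    bc_interval(prop_b, obs$prop_positive, conf_level) else c(NA, NA)
  obs$ci_ratio <- if (obs$defined && is.finite(obs$ratio_pos_inverse))
    bc_interval(ratio_b, obs$ratio_pos_inverse, conf_level) else c(NA, NA)
  obs$boot_median_prop <- median(prop_b[is.finite(prop_b)])
  obs$boot_median_ratio <- median(ratio_b[is.finite(ratio_b)])
  obs
}

#' Per-gene two-group distribution tests
#'
#' For each gene: Welch two-sided t-test, Wilcoxon rank-sum (normal
#' approximation with tie correction) and two-sample Kolmogorov-Smirnov
#' test of ER/PR-positive vs ER/PR-negative beta values, with group means.
#' Genes with fewer than two non-missing values in either group are
#' flagged (`ok = FALSE`, NA statistics); groups with identical constant
#' values give t = 0 and maximal p.
#'
#' @param gene_meth gene x sample matrix.
#' @param samples a [sample_table].
#' @return a `group_test_result` data.frame, one row per gene.
#' @export
group_difference_tests <- function(gene_meth, samples) {
  idx <- match(colnames(gene_meth), samples$sample_id)
  grp <- samples$erpr_group[idx]
  res <- lapply(seq_len(nrow(gene_meth)), function(i) {
    xp <- gene_meth[i, grp == "positive"]
    xn <- gene_meth[i, grp == "negative"]
    xp <- xp[!is.na(xp)]; xn <- xn[!is.na(xn)]
    if (length(xp) < 2 || length(xn) < 2)
      return(data.frame(t_stat = NA_real_, t_p = NA_real_,
                        wilcoxon_p = NA_real_, ks_p = NA_real_,
                        mean_beta_positive = mean(xp),
                        mean_beta_negative = mean(xn), ok = FALSE))
    if (sd(xp) == 0 && sd(xn) == 0) {
      eq <- mean(xp) == mean(xn)
      return(data.frame(t_stat = if (eq) 0 else Inf * sign(mean(xp) - mean(xn)),
                        t_p = if (eq) 1 else .Machine$double.xmin,
                        wilcoxon_p = if (eq) 1 else
                          suppressWarnings(wilcox.test(xp, xn,
                                                       exact = FALSE)$p.value),
                        ks_p = if (eq) 1 else
                          suppressWarnings(ks.test(xp, xn)$p.value),
                        mean_beta_positive = mean(xp),
                        mean_beta_negative = mean(xn), ok = TRUE))
    }
    tt <- t.test(xp, xn, var.equal = FALSE)
    wt <- suppressWarnings(wilcox.test(xp, xn, exact = FALSE))
    kt <- suppressWarnings(ks.test(xp, xn))
    data.frame(t_stat = unname(tt$statistic), t_p = tt$p.value,
               wilcoxon_p = wt$p.value, ks_p = kt$p.value,
               mean_beta_positive = mean(xp), mean_beta_negative = mean(xn),
               ok = TRUE)
  })
  out <- do.call(rbind, res)
  out <- cbind(gene_symbol = rownames(gene_meth), out)
  rownames(out) <- NULL
  structure(out, class = c("group_test_result", "data.frame"))
}

#' Pearson chi-square test of a contingency table
#'
#' Pearson chi-square without continuity correction,
#' df = (rows-1)(cols-1); used for cohort-description tables of
#' clinicopathological features against ER/PR status.
#'
#' @param counts matrix of non-negative integer counts with all row and
#'   column sums positive.
#' @return list with `statistic`, `p_value`, `df`.
#' @export
chi_square_table <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be non-negative")
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0))
    stop("zero marginal row/column sum in contingency table")
  ct <- suppressWarnings(chisq.test(counts, correct = FALSE))
  list(statistic = unname(ct$statistic), p_value = ct$p.value,
       df = unname(ct$parameter))
}

#' @export
format.direction_summary <- function(x, ...) {
  pct <- if (is.na(x$prop_positive)) NA else round(100 * x$prop_positive)
  c(sprintf("direction summary at P <= %g: %d coefficients (%d positive, %d inverse)",
            x$p_threshold, x$n_total, x$n_positive, x$n_inverse),
    sprintf("  proportion positive %s (%s%%)%s",
            format(round(x$prop_positive, 2), nsmall = 2), pct,
            if (!is.null(x$ci_prop))
              sprintf("  95%% CI (%.2f, %.2f)", x$ci_prop[1], x$ci_prop[2])
            else ""),
    sprintf("  positive:inverse ratio %s%s",
            format(round(x$ratio_pos_inverse, 1), nsmall = 1),
            if (!is.null(x$ci_ratio))
              sprintf("  95%% CI (%.1f, %.1f)", x$ci_ratio[1],
                      x$ci_ratio[2]) else ""))
}

#' @export
print.direction_summary <- function(x, ...) {
  cat(format(x), sep = "\n")
  invisible(x)
}

#' @export
as.data.frame.direction_summary <- function(x, ...) {
  data.frame(p_threshold = x$p_threshold, n_total = x$n_total,
             n_positive = x$n_positive, n_inverse = x$n_inverse,
             prop_positive = x$prop_positive,
             ratio_pos_inverse = x$ratio_pos_inverse,
             ci_prop_low = (x$ci_prop %||% c(NA, NA))[1],
             ci_prop_high = (x$ci_prop %||% c(NA, NA))[2],
             ci_ratio_low = (x$ci_ratio %||% c(NA, NA))[1],
             ci_ratio_high = (x$ci_ratio %||% c(NA, NA))[2],
             n_bootstrap = x$n_bootstrap)
}
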