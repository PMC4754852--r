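# Methylation-expression correlation.
#
# Per-gene Pearson correlation between gene mean beta and expression,
# overall or within an ER/PR stratum, with p-values from the t transform
# of rho (df = n_pairs - 2) and pairwise-complete deletion of missing
# cells.

pearson_with_p <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  n <- sum(ok)
  if (n < 3 || sd(x[ok]) == 0 || sd(y[ok]) == 0)
    return(list(rho = NA_real_, p = NA_real_, n = n))
  r <- cor(x[ok], y[ok])
  r <- max(min(r, 1), -1)
  p <- if (abs(r) >= 1) .Machine$double.xmin else {
    tt <- r * sqrt((n - 2) / (1 - r^2))
    max(2 * pt(-abs(tt), df = n - 2), .Machine$double.xmin)
  }
  list(rho = r, p = p, n = n)
}

stratum_samples <- function(samples, stratum) {
  switch(stratum,
         all = samples$sample_id[samples$erpr_group != "unknown"],
         erpr_positive = samples$sample_id[samples$erpr_group == "positive"],
         erpr_negative = samples$sample_id[samples$erpr_group == "negative"],
         stop("unknown stratum: ", stratum))
}

#' Correlate gene methylation with expression
#'
#' For each gene present on both matrices, computes the pairwise-complete
#' Pearson correlation between mean beta and expression across the
#' samples of the chosen stratum. Genes absent from the expression matrix
#' are dropped; correlations with fewer than 3 pairs or a constant
#' variable are undefined (NA, flagged by `n_pairs`).
#'
#' @param gene_meth gene x sample mean-beta matrix.
#' @param expression gene x sample expression matrix.
#' @param samples a [sample_table].
#' @param stratum one of "all", "erpr_positive", "erpr_negative", or
#'   "each" (all three stacked).
#' @return a `correlation_result` data.frame: gene_symbol, stratum, rho,
#'   p_value, n_pairs.
#' @export
correlate_methylation_expression <- function(gene_meth, expression,
                                             samples,
                                             stratum = c("all",
                                                         "erpr_positive",
                                                         "erpr_negative",
                                                         "each")) {
  stratum <- match.arg(stratum)
  strata <- if (stratum == "each")
    c("all", "erpr_positive", "erpr_negative") else stratum
  genes <- intersect(rownames(gene_meth), rownames(expression))
  shared <- intersect(colnames(gene_meth), colnames(expression))
  if (length(genes) == 0 || length(shared) == 0)
    stop("no shared genes/samples between methylation and expression")
  out <- lapply(strata, function(st) {
    ids <- intersect(shared, stratum_samples(samples, st))
    if (length(ids) == 0) stop("stratum '", st, "' has no samples")
    m <- gene_meth[genes, ids, drop = FALSE]
    e <- expression[genes, ids, drop = FALSE]
    res <- lapply(seq_along(genes), function(i)
      pearson_with_p(m[i, ], e[i, ]))
    data.frame(gene_symbol = genes, stratum = st,
               rho = vapply(res, `[[`, numeric(1), "rho"),
               p_value = vapply(res, `[[`, numeric(1), "p"),
               n_pairs = vapply(res, `[[`, numeric(1), "n"),
               stringsAsFactors = FALSE)
  })
  structure(do.call(rbind, out),
            class = c("correlation_result", "data.frame"))
}

#' Count significant correlations by stratum and sign
#'
#' @param results a `correlation_result` data.frame.
#' @param alpha significance level (correlations with `p <= alpha`
#'   count).
#' @return data.frame per stratum: n_genes, n_inverse_significant
#'   (rho < 0), n_positive_significant (rho > 0), n_undefined.
#' @export
count_significant_correlations <- function(results, alpha = 0.05) {
  do.call(rbind, lapply(split(results, results$stratum), function(r) {
    sig <- !is.na(r$p_value) & r$p_value <= alpha
    data.frame(stratum = r$stratum[1], n_genes = nrow(r),
               n_inverse_significant = sum(sig & r$rho < 0),
               n_positive_significant = sum(sig & r$rho > 0),
               n_undefined = sum(is.na(r$rho)), row.names = NULL,
               stringsAsFactors = FALSE)
  }))
}

#' Correlations over random sample subsets
#'
#' Re-estimates each gene's methylation-expression Pearson rho on
#' `n_repeats` random subsets of `subset_size` samples drawn without
#' replacement, emulating repeated small-cohort analyses on a large
#' cohort.
#'
#' @param gene_meth,expression,samples as in
#'   [correlate_methylation_expression()].
#' @param subset_size samples per subset (>= 3, <= cohort size).
#' @param n_repeats number of subsets.
#' @param seed integer seed.
#' @return numeric matrix genes x repeats of per-subset rho (NA where
#'   undefined).
#' @export
subsample_correlations <- function(gene_meth, expression, samples,
                                   subset_size, n_repeats = 100, seed) {
  genes <- intersect(rownames(gene_meth), rownames(expression))
  shared <- intersect(colnames(gene_meth), colnames(expression))
  shared <- intersect(shared, samples$sample_id)
  if (subset_size < 3) stop("subset_size must be >= 3")
  if (subset_size > length(shared))
    stop("subset_size exceeds the number of shared samples")
  m <- gene_meth[genes, shared, drop = FALSE]
  e <- expression[genes, shared, drop = FALSE]
  with_seed(seed, {
    out <- matrix(NA_real_, length(genes), n_repeats,
                  dimnames = list(genes, NULL))
    for (r in seq_len(n_repeats)) {
      take <- sample(length(shared), subset_size)
      for (i in seq_along(genes)) {
        pw <- pearson_with_p(m[i, take], e[i, take])
        out[i, r] <- pw$rho
      }
    }
    out
  })
}
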