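# Cross-platform validation of training-set predictor genes.
#
# Platforms with disjoint probe designs are matched at the gene-symbol
# level; each predictor's direction is re-assessed on the validation
# cohort (Welch t-test on the gene mean beta, SAM d of the highest-|d|
# probe) and concordance with the training direction is tallied.

#' Match predictor genes to a validation platform
#'
#' Exact, case-sensitive symbol matching after whitespace trimming; no
#' synonym resolution is attempted.
#'
#' @param predictors character vector of unique gene symbols.
#' @param validation_annotation [probe_annotation] of the validation
#'   platform.
#' @return list with `probes` (named list gene -> probe ids) and
#'   `absent` (symbols with no probe on the platform).
#' @export
match_genes <- function(predictors, validation_annotation) {
  predictors <- trimws(predictors)
  if (anyDuplicated(predictors)) stop("predictor symbols must be unique")
  probes <- lapply(predictors, function(g)
    validation_annotation$probe_id[validation_annotation$gene_symbol == g])
  names(probes) <- predictors
  absent <- predictors[lengths(probes) == 0]
  list(probes = probes[lengths(probes) > 0], absent = absent)
}

#' Validate training predictors on an independent platform
#'
#' Per predictor: its validation-platform probes are averaged to a gene
#' mean-beta row and compared between ER/PR groups with a Welch two-sided
#' t-test; the reported validation d is the highest-|d| probe's SAM d
#' score. Status: `absent` when no probe matches; `not_associated` when
#' that d is 0; otherwise `positive`/`inverse` by the sign of the group
#' mean difference, downgraded to `non_significant` when the reported
#' probe is outside SAM's called set. A predictor is direction-concordant
#' when its (non-downgraded) status equals its training direction, and
#' t-test-confirmed when additionally `t_p <= alpha`.
#'
#' @param predictors data.frame with columns `gene_symbol`,
#'   `training_direction` ("positive"/"inverse") and optionally
#'   `training_d`.
#' @param validation_beta [beta_matrix] of the validation platform.
#' @param validation_annotation its [probe_annotation].
#' @param validation_samples its [sample_table].
#' @param sam_result a `sam_result` from a probe-level [run_sam()] on the
#'   validation platform (must carry a `gene_view`).
#' @param alpha significance level for t-test confirmation.
#' @return list with `records` (a `predictor_record` data.frame) and
#'   `summary` (a `concordance_summary` list).
#' @export
validate_predictors <- function(predictors, validation_beta,
                                validation_annotation, validation_samples,
                                sam_result, alpha = 0.05) {
  stopifnot(is.data.frame(predictors),
            all(c("gene_symbol", "training_direction") %in%
                  colnames(predictors)))
  if (is.null(sam_result$gene_view))
    stop("sam_result must come from a probe-level run (gene_view missing)")
  idx <- match(colnames(validation_beta), validation_samples$sample_id)
  grp <- validation_samples$erpr_group[idx]
  if (sum(grp == "positive") < 2 || sum(grp == "negative") < 2)
    stop("validation cohort needs >= 2 samples in each ER/PR group")
  matched <- match_genes(predictors$gene_symbol, validation_annotation)
  gv <- sam_result$gene_view

  empty_record <- data.frame(
    gene_symbol = character(0), training_direction = character(0),
    training_d = numeric(0), validation_status = character(0),
    validation_d = numeric(0), validation_t_p = numeric(0),
    mean_beta_positive = numeric(0), mean_beta_negative = numeric(0),
    stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(predictors)), function(i) {
    g <- trimws(predictors$gene_symbol[i])
    rec <- data.frame(gene_symbol = g,
                      training_direction = predictors$training_direction[i],
                      training_d = predictors$training_d[i] %||% NA_real_,
                      validation_status = "absent",
                      validation_d = NA_real_, validation_t_p = NA_real_,
                      mean_beta_positive = NA_real_,
                      mean_beta_negative = NA_real_,
                      stringsAsFactors = FALSE)
    probes <- matched$probes[[g]]
    if (is.null(probes)) return(rec)
    sub <- validation_beta[probes, , drop = FALSE]
    gene_row <- colMeans(unclass(sub), na.rm = TRUE)
    gene_row[colSums(!is.na(sub)) == 0] <- NA_real_
    xp <- gene_row[grp == "positive"]
    xn <- gene_row[grp == "negative"]
    xp <- xp[!is.na(xp)]; xn <- xn[!is.na(xn)]
    rec$mean_beta_positive <- mean(xp)
    rec$mean_beta_negative <- mean(xn)
    if (length(xp) >= 2 && length(xn) >= 2 && (sd(xp) > 0 || sd(xn) > 0))
      rec$validation_t_p <- t.test(xp, xn, var.equal = FALSE)$p.value
    gvi <- gv[gv$gene_symbol == g, , drop = FALSE]
    d <- if (nrow(gvi) == 1) gvi$d else NA_real_
    rec$validation_d <- d
    rec$validation_status <-
      if (is.na(d)) "absent"
      else if (d == 0) "not_associated"
      else if (!isTRUE(gvi$called)) "non_significant"
      else if (mean(xp) - mean(xn) > 0) "positive" else "inverse"
    rec
  })
  records <- structure(do.call(rbind, c(list(empty_record), rows)),
                       class = c("predictor_record", "data.frame"))
  concordant <- records$validation_status %in% c("positive", "inverse") &
    records$validation_status == records$training_direction
  confirmed <- concordant & !is.na(records$validation_t_p) &
    records$validation_t_p <= alpha
  summary <- structure(
    list(n_predictors = nrow(records),
         n_with_validation_data = sum(records$validation_status != "absent"),
         n_direction_concordant = sum(concordant),
         n_ttest_confirmed = sum(confirmed), alpha = alpha),
    class = "concordance_summary")
  list(records = records, summary = summary)
}

#' @export
print.concordance_summary <- function(x, ...) {
  cat(sprintf(
    "concordance: %d/%d predictors with validation data, %d direction-concordant, %d confirmed by t-test (alpha = %g)\n",
    x$n_with_validation_data, x$n_predictors, x$n_direction_concordant,
    x$n_ttest_confirmed, x$alpha))
  invisible(x)
}

#' @export
as.data.frame.concordance_summary <- function(x, ...) {
  data.frame(n_predictors = x$n_predictors,
             n_with_validation_data = x$n_with_validation_data,
             n_direction_concordant = x$n_direction_concordant,
             n_ttest_confirmed = x$n_ttest_confirmed, alpha = x$alpha)
}
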