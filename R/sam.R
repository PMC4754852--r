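# Two-class significance analysis of microarrays (SAM), from scratch.
#
# The moderated statistic d_i = (mean1_i - mean2_i) / (s_i + s0) compares
# ER/PR-positive (group 1) against ER/PR-negative samples per feature;
# the fudge factor s0 damps the inflation of d at low-scatter features
# and is selected by minimizing the coefficient of variation of d's
# median absolute deviation across scatter quantiles (the Tusher
# procedure). Significance is judged against permutation expected order
# statistics with asymmetric delta cutoffs, and FDR is the median count
# of permuted-data exceedances over the number of calls.

#' SAM run configuration
#'
#' @param delta non-negative distance from the expected order-statistic
#'   line beyond which features are called.
#' @param n_permutations label permutations (all distinct relabelings are
#'   enumerated instead when there are no more of them than this).
#' @param knn_k neighbors for missing-value imputation (default 10).
#' @param seed integer seed for the permutation draw.
#' @param s0_method "tusher" (select by the CV criterion) or "fixed".
#' @param s0_fixed the fixed fudge factor when `s0_method = "fixed"`.
#' @param fdr_quantile quantile of the per-permutation false-call counts
#'   summarising the FDR (0.5 = median).
#' @return a `sam_config` list.
#' @export
sam_config <- function(delta = 0.7, n_permutations = 1000, knn_k = 10,
                       seed, s0_method = c("tusher", "fixed"),
                       s0_fixed = NULL, fdr_quantile = 0.5) {
  s0_method <- match.arg(s0_method)
  if (delta < 0) stop("delta must be >= 0")
  if (n_permutations < 1) stop("n_permutations must be >= 1")
  if (knn_k < 1) stop("knn_k must be >= 1")
  if (s0_method == "fixed" && (is.null(s0_fixed) || s0_fixed < 0))
    stop("s0_fixed must be a non-negative number when s0_method = 'fixed'")
  structure(list(delta = delta, n_permutations = as.integer(n_permutations),
                 knn_k = as.integer(knn_k), seed = seed,
                 s0_method = s0_method, s0_fixed = s0_fixed,
                 fdr_quantile = fdr_quantile),
            class = "sam_config")
}

#' K-nearest-neighbour imputation of missing values
#'
#' For each missing cell (f, s), candidate neighbour features are ranked
#' by Euclidean distance to f computed over the samples where both
#' features are observed and scaled by the number of shared observed
#' samples; the imputed value is the mean of the `k` nearest neighbours
#' observed at sample s (nearer neighbours missing at s are skipped in
#' favour of the next nearest). Fully observed features are untouched.
#'
#' @param x feature x sample numeric matrix with missing values.
#' @param k number of neighbours (default 10; must leave k other
#'   features).
#' @return the matrix with no missing values.
#' @export
knn_impute <- function(x, k = 10) {
  x <- as.matrix(x)
  nf <- nrow(x)
  if (k > nf - 1) stop("k must be <= number of features - 1")
  all_missing <- rowSums(!is.na(x)) == 0
  if (any(all_missing))
    stop("feature(s) entirely missing: ",
         paste(head(rownames(x)[all_missing] %||%
                      which(all_missing)), collapse = ", "))
  miss <- which(is.na(x), arr.ind = TRUE)
  if (nrow(miss) == 0) return(x)
  # pairwise NA-aware squared distances via masked cross-products
  m <- (!is.na(x)) + 0
  z <- x
  z[is.na(z)] <- 0
  z2 <- z * z
  shared <- m %*% t(m)
  d2 <- (z2 %*% t(m)) + (m %*% t(z2)) - 2 * (z %*% t(z))
  d <- sqrt(pmax(d2, 0) / pmax(shared, 1))
  d[shared == 0] <- Inf                   # no overlap: never a neighbour
  diag(d) <- Inf
  out <- x
  for (f in unique(miss[, 1])) {
    ord <- order(d[f, ])
    cols <- miss[miss[, 1] == f, 2]
    for (s in cols) {
      avail <- ord[!is.na(x[ord, s]) & is.finite(d[f, ord])]
      nb <- head(avail, k)
      out[f, s] <- if (length(nb) > 0) mean(x[nb, s])
                   else mean(x[f, ], na.rm = TRUE)   # no usable neighbour
    }
  }
  out
}

# per-feature group means and pooled scatter; g1 logical, group 1 =
# ER/PR-positive by convention (d > 0 <=> higher beta in positives)
sam_moments <- function(x, g1) {
  n1 <- sum(g1)
  n2 <- sum(!g1)
  if (n1 < 2 || n2 < 2) stop("each group needs >= 2 samples")
  m1 <- rowMeans(x[, g1, drop = FALSE])
  m2 <- rowMeans(x[, !g1, drop = FALSE])
  ss1 <- rowSums((x[, g1, drop = FALSE] - m1)^2)
  ss2 <- rowSums((x[, !g1, drop = FALSE] - m2)^2)
  s <- sqrt((1 / n1 + 1 / n2) * (ss1 + ss2) / (n1 + n2 - 2))
  list(diff = m1 - m2, s = s)
}

#' SAM d scores
#'
#' `d_i = (mean1_i - mean2_i) / (s_i + s0)` with
#' `s_i = sqrt((1/n1 + 1/n2) * (SS1_i + SS2_i) / (n1 + n2 - 2))`, where SS
#' is the within-group sum of squared deviations. Group 1 is the
#' ER/PR-positive group, so positive d means higher methylation in
#' receptor-positive disease.
#'
#' @param x feature x sample matrix without missing values.
#' @param labels per-sample group labels; `group1` is defined by
#'   `group1_label`.
#' @param s0 non-negative fudge factor.
#' @param group1_label the label treated as group 1.
#' @return list with `d` and `s` (per-feature).
#' @export
sam_d_scores <- function(x, labels, s0 = 0, group1_label = "positive") {
  if (anyNA(x)) stop("matrix must not contain missing values (impute first)")
  if (s0 < 0) stop("s0 must be >= 0")
  mom <- sam_moments(as.matrix(x), labels == group1_label)
  list(d = mom$diff / (mom$s + s0), s = mom$s)
}

#' Select the SAM fudge factor s0 (Tusher procedure)
#'
#' Candidates are 0 plus the 5th..95th percentiles (step 5) of the
#' per-feature scatter s. For each candidate the features are split into
#' scatter-quantile bins (100 bins on large matrices; the bin count drops
#' to `max(5, n/5)` so each bin keeps several members), the median
#' absolute deviation of d is computed per bin, and the candidate
#' minimizing the coefficient of variation of these MADs across bins
#' wins; ties go to the smallest candidate.
#'
#' @inheritParams sam_d_scores
#' @return the selected `s0` (always an element of the candidate set).
#' @export
select_s0 <- function(x, labels, group1_label = "positive") {
  x <- as.matrix(x)
  mom <- sam_moments(x, labels == group1_label)
  nf <- nrow(x)
  n_bins <- min(100, max(5, floor(nf / 5)))
  candidates <- c(0, unname(quantile(mom$s, seq(0.05, 0.95, by = 0.05),
                                     type = 7)))
  bin <- ceiling(rank(mom$s, ties.method = "first") * n_bins / nf)
  cv <- vapply(candidates, function(a) {
    d <- mom$diff / (mom$s + a)
    mads <- vapply(split(d, bin), mad, numeric(1))
    sd(mads) / mean(mads)
  }, numeric(1))
  cv[!is.finite(cv)] <- Inf
  if (all(is.infinite(cv))) return(0)  # flat/degenerate criterion
  best <- min(cv)
  candidates[which(cv <= best * (1 + 1e-9))[1]]
}

#' Permutation expected order statistics for SAM
#'
#' Draws label permutations uniformly over balanced relabelings (all
#' `choose(n, n1)` distinct relabelings are enumerated exactly when there
#' are no more of them than `n_permutations`), computes d scores under
#' each, and averages the sorted d's rank by rank into the expected order
#' statistics.
#'
#' @inheritParams sam_d_scores
#' @param n_permutations permutations to draw.
#' @param seed integer seed.
#' @return list with `expected_d` (ascending, per rank), `permuted_d`
#'   (feature x permutation matrix of unsorted d scores),
#'   `n_permutations` actually used and `exhaustive` flag.
#' @export
sam_permutation <- function(x, labels, s0, n_permutations = 1000, seed,
                            group1_label = "positive") {
  x <- as.matrix(x)
  g1 <- labels == group1_label
  n <- ncol(x)
  n1 <- sum(g1)
  n2 <- n - n1
  if (n1 < 2 || n2 < 2) stop("each group needs >= 2 samples")
  n_all <- choose(n, n1)
  exhaustive <- is.finite(n_all) && n_all <= n_permutations
  picks <- if (exhaustive) {
    asplit(utils::combn(n, n1), 2)
  } else {
    with_seed(seed, lapply(seq_len(n_permutations),
                           function(i) sample(n, n1)))
  }
  p <- length(picks)
  w <- matrix(0, n, p)
  for (j in seq_len(p)) w[picks[[j]], j] <- 1
  # group sums across all permutations in two matrix products
  x2 <- x * x
  s1 <- x %*% w
  q1 <- x2 %*% w
  rs <- rowSums(x)
  rq <- rowSums(x2)
  m1 <- s1 / n1
  m2 <- (rs - s1) / n2
  ss1 <- q1 - s1^2 / n1
  ss2 <- (rq - q1) - (rs - s1)^2 / n2
  s <- sqrt(pmax((1 / n1 + 1 / n2) * (ss1 + ss2) / (n - 2), 0))
  d <- (m1 - m2) / (s + s0)
  sorted <- apply(d, 2, sort)
  list(expected_d = rowMeans(sorted), permuted_d = d,
       n_permutations = p, exhaustive = exhaustive)
}

#' Call significant features at a delta threshold
#'
#' Observed d's are paired with the expected order statistics by rank.
#' The upper cut is the smallest observed d among ranks exceeding the
#' expected value by more than delta; the lower cut is the largest
#' observed d falling more than delta below it (asymmetric, side-specific
#' cuts). FDR is the `fdr_quantile` (default median) across permutations
#' of the count of permuted d values beyond the cuts, divided by the
#' number of features called; undefined (NA) when nothing is called.
#'
#' @param d observed per-feature d scores (named by feature).
#' @param expected_d expected order statistics from [sam_permutation()].
#' @param permuted_d feature x permutation d matrix.
#' @param delta non-negative threshold.
#' @param s per-feature scatter values (carried into the result).
#' @param s0 fudge factor used (carried into the result).
#' @param fdr_quantile quantile of false-call counts (0.5 = median).
#' @return a `sam_result` list: feature_ids, d_scores, s_values, s0,
#'   expected_d, delta, cut_up, cut_low, significant_positive,
#'   significant_negative, fdr_estimate, n_permutations.
#' @export
call_significant <- function(d, expected_d, permuted_d, delta, s = NULL,
                             s0 = NA_real_, fdr_quantile = 0.5) {
  if (length(d) != length(expected_d))
    stop("d and expected_d lengths differ")
  ids <- names(d) %||% as.character(seq_along(d))
  ds <- sort(d)
  gap <- ds - expected_d
  up <- which(gap > delta)
  lo <- which(-gap > delta)
  cut_up <- if (length(up) > 0) min(ds[up]) else Inf
  cut_low <- if (length(lo) > 0) max(ds[lo]) else -Inf
  sig_pos <- ids[d >= cut_up]
  sig_neg <- ids[d <= cut_low]
  n_called <- length(sig_pos) + length(sig_neg)
  fdr <- if (n_called == 0) NA_real_ else {
    false_counts <- colSums(permuted_d >= cut_up | permuted_d <= cut_low)
    unname(quantile(false_counts, fdr_quantile, type = 7)) / n_called
  }
  structure(list(feature_ids = ids, d_scores = d, s_values = s, s0 = s0,
                 expected_d = expected_d, delta = delta, cut_up = cut_up,
                 cut_low = cut_low, significant_positive = sig_pos,
                 significant_negative = sig_neg, fdr_estimate = fdr,
                 n_permutations = ncol(permuted_d)),
            class = "sam_result")
}

#' Run the full SAM pipeline on a feature matrix
#'
#' Pipeline: KNN imputation (when missing values are present) -> s0
#' selection (or fixed override) -> observed d scores -> permutation
#' expected order statistics -> delta-threshold calls with FDR. When the
#' features are probes and an annotation is supplied, a per-gene view is
#' added reporting, for each gene, the probe with the highest absolute d.
#'
#' @param x feature x sample matrix (genes for a gene-level run, probes
#'   for a probe-level run); missing values allowed.
#' @param samples a [sample_table] covering the columns; samples with
#'   unknown ER/PR group are dropped.
#' @param config a [sam_config].
#' @param annotation optional [probe_annotation] when rows are probes.
#' @return a `sam_result`; with annotation, also a `gene_view` data.frame
#'   (gene_symbol, probe_id, d, called, call side).
#' @export
run_sam <- function(x, samples, config, annotation = NULL) {
  stopifnot(inherits(config, "sam_config"))
  x <- as.matrix(x)
  idx <- match(colnames(x), samples$sample_id)
  if (anyNA(idx))
    stop("samples missing from sample table: ",
         paste(head(colnames(x)[is.na(idx)]), collapse = ", "))
  grp <- samples$erpr_group[idx]
  keep <- grp != "unknown"
  x <- x[, keep, drop = FALSE]
  labels <- grp[keep]
  if (anyNA(x)) x <- knn_impute(x, k = config$knn_k)
  s0 <- if (config$s0_method == "fixed") config$s0_fixed
        else select_s0(x, labels)
  dsc <- sam_d_scores(x, labels, s0 = s0)
  names(dsc$d) <- rownames(x)
  perm <- sam_permutation(x, labels, s0 = s0,
                          n_permutations = config$n_permutations,
                          seed = config$seed)
  res <- call_significant(dsc$d, perm$expected_d, perm$permuted_d,
                          delta = config$delta, s = dsc$s, s0 = s0,
                          fdr_quantile = config$fdr_quantile)
  res$exhaustive <- perm$exhaustive
  if (!is.null(annotation)) {
    ann <- annotation[match(rownames(x), annotation$probe_id), ]
    if (anyNA(ann$probe_id))
      stop("probes without annotation in SAM input")
    best <- tapply(seq_len(nrow(x)), ann$gene_symbol,
                   function(ii) ii[which.max(abs(res$d_scores[ii]))])
    best <- unlist(best)
    called_side <- rep("none", nrow(x))
    called_side[res$feature_ids %in% res$significant_positive] <- "positive"
    called_side[res$feature_ids %in% res$significant_negative] <- "negative"
    res$gene_view <- data.frame(
      gene_symbol = names(best), probe_id = rownames(x)[best],
      d = unname(res$d_scores[best]),
      called = called_side[best] != "none",
      side = called_side[best], stringsAsFactors = FALSE, row.names = NULL)
  }
  res
}

#' @export
print.sam_result <- function(x, ...) {
  cat(sprintf(
    "SAM: %d features, s0 = %.4g, delta = %g, %d permutations%s\n",
    length(x$feature_ids), x$s0, x$delta, x$n_permutations,
    if (isTRUE(x$exhaustive)) " (exhaustive)" else ""))
  cat(sprintf("  called: %d positive, %d negative; FDR estimate %s\n",
              length(x$significant_positive),
              length(x$significant_negative),
              ifelse(is.na(x$fdr_estimate), "undefined",
                     sprintf("%.3g", x$fdr_estimate))))
  invisible(x)
}

#' @export
as.data.frame.sam_result <- function(x, ...) {
  side <- rep("none", length(x$feature_ids))
  side[x$feature_ids %in% x$significant_positive] <- "positive"
  side[x$feature_ids %in% x$significant_negative] <- "negative"
  data.frame(feature_id = x$feature_ids, d = unname(x$d_scores),
             s = if (is.null(x$s_values)) NA_real_ else unname(x$s_values),
             called = side != "none", side = side,
             stringsAsFactors = FALSE)
}
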