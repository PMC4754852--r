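test_that("KNN imputation fills cells from the nearest features", {
  x <- matrix(runif(24), 6, 4)
  expect_identical(knn_impute(x, k = 2), x)   # nothing missing: identity
  # identical rows: imputed value equals the common value at that sample
  xi <- matrix(rep(c(0.2, 0.4, 0.6, 0.8), each = 5), 5, 4)
  xi[3, 2] <- NA
  expect_equal(knn_impute(xi, k = 2)[3, 2], 0.4)
  # 6x4 toy, k = 2: mean of the 2 nearest rows at that column, nearest
  # found by exhaustive pairwise search
  set.seed(51)
  x <- matrix(runif(24), 6, 4)
  x[2, 3] <- NA
  dist_to_2 <- vapply(seq_len(6), function(j) {
    if (j == 2) return(Inf)
    shared <- !is.na(x[2, ]) & !is.na(x[j, ])
    sqrt(sum((x[2, shared] - x[j, shared])^2) / sum(shared))
  }, numeric(1))
  nearest <- order(dist_to_2)[1:2]
  expect_equal(knn_impute(x, k = 2)[2, 3], mean(x[nearest, 3]))
  # neighbours missing at the target column are skipped for the next ones
  x2 <- x
  x2[nearest[1], 3] <- NA
  dist2 <- vapply(seq_len(6), function(j) {
    if (j == 2) return(Inf)
    shared <- !is.na(x2[2, ]) & !is.na(x2[j, ])
    sqrt(sum((x2[2, shared] - x2[j, shared])^2) / sum(shared))
  }, numeric(1))
  usable <- order(dist2)[!is.na(x2[order(dist2), 3])][1:2]
  expect_equal(knn_impute(x2, k = 2)[2, 3], mean(x2[usable, 3]))
  xall <- x
  xall[4, ] <- NA
  expect_error(knn_impute(xall, k = 2), "entirely missing")
  expect_error(knn_impute(x, k = 6), "k must be")
})

test_that("d scores match longhand arithmetic and are scale/label symmetric", {
  x <- rbind(f1 = c(0.70, 0.80, 0.75, 0.30, 0.35, 0.25),
             f2 = c(0.50, 0.52, 0.48, 0.51, 0.49, 0.50))
  colnames(x) <- sprintf("S%02d", 1:6)
  labels <- rep(c("positive", "negative"), each = 3)
  got <- sam_d_scores(x, labels, s0 = 0.1)
  for (i in 1:2) {
    hand <- longhand_d(x[i, 1:3], x[i, 4:6], s0 = 0.1)
    expect_equal(unname(got$d[i]), hand$d, tolerance = 1e-9)
    expect_equal(unname(got$s[i]), hand$s, tolerance = 1e-9)
  }
  # equal group means -> d = 0 whatever s0
  xeq <- rbind(f1 = c(0.3, 0.5, 0.7, 0.3, 0.5, 0.7))
  colnames(xeq) <- colnames(x)
  expect_equal(unname(sam_d_scores(xeq, labels, s0 = 0)$d), 0)
  expect_equal(unname(sam_d_scores(xeq, labels, s0 = 5)$d), 0)
  # scale invariance at s0 = 0
  expect_equal(sam_d_scores(3.7 * x, labels, s0 = 0)$d,
               sam_d_scores(x, labels, s0 = 0)$d, tolerance = 1e-12)
  # antisymmetry under label swap
  swapped <- rep(c("negative", "positive"), each = 3)
  expect_equal(sam_d_scores(x, swapped, s0 = 0.1)$d, -got$d,
               tolerance = 1e-12)
  expect_error(sam_d_scores(x, c("positive", rep("negative", 5)), 0),
               ">= 2")
})

test_that("s0 selection is closed over its candidates and matches exhaustive evaluation", {
  set.seed(61)
  n <- 500
  labels <- rep(c("positive", "negative"), each = 8)
  # heteroscedastic: scatter grows across features
  x <- t(vapply(seq_len(n), function(i)
    rnorm(16, mean = 0.5, sd = 0.02 + 0.3 * i / n), numeric(16)))
  rownames(x) <- sprintf("f%03d", seq_len(n))
  s0 <- select_s0(x, labels)
  # independent exhaustive evaluation of the CV criterion
  mom <- lapply(seq_len(n), function(i) longhand_d(x[i, 1:8], x[i, 9:16]))
  s <- vapply(mom, `[[`, numeric(1), "s")
  diffs <- vapply(seq_len(n), function(i)
    mean(x[i, 1:8]) - mean(x[i, 9:16]), numeric(1))
  candidates <- c(0, unname(quantile(s, seq(0.05, 0.95, 0.05), type = 7)))
  nb <- 100
  bin <- ceiling(rank(s, ties.method = "first") * nb / n)
  cv <- sapply(candidates, function(a) {
    mads <- tapply(diffs / (s + a), bin, mad)
    sd(mads) / mean(mads)
  })
  expect_true(s0 %in% candidates)
  expect_equal(s0, candidates[which.min(cv)])
  # homoscedastic scatter (identical s_i, varying mean shifts): the CV
  # criterion is flat across candidates and the tie rule returns 0
  set.seed(62)
  base1 <- rnorm(8, 0.5, 0.1)
  base2 <- rnorm(8, 0.5, 0.1)
  xh <- t(sapply(seq(-0.2, 0.2, length.out = 50),
                 function(dl) c(base1 + dl, base2)))
  expect_equal(select_s0(xh, labels), 0)
})

test_that("permutation order statistics match exhaustive enumeration on 2v2 and 3v3 toys", {
  for (npg in c(2, 3)) {
    set.seed(70 + npg)
    n <- 2 * npg
    x <- matrix(rnorm(7 * n, mean = 0.5, sd = 0.1), 7, n)
    rownames(x) <- sprintf("f%d", 1:7)
    labels <- rep(c("positive", "negative"), each = npg)
    s0 <- 0.05
    perm <- sam_permutation(x, labels, s0 = s0, n_permutations = 1000,
                            seed = 1)
    expect_true(perm$exhaustive)
    expect_equal(perm$n_permutations, choose(n, npg))
    # oracle: enumerate every relabeling and average sorted d by rank
    combos <- combn(n, npg)
    sorted_all <- sapply(seq_len(ncol(combos)), function(j) {
      g1 <- combos[, j]
      d <- vapply(seq_len(7), function(i)
        longhand_d(x[i, g1], x[i, -g1], s0 = s0)$d, numeric(1))
      sort(d)
    })
    expect_equal(perm$expected_d, rowMeans(sorted_all), tolerance = 1e-12)
    # permuted d columns match the longhand d for each relabeling
    d1 <- vapply(seq_len(7), function(i)
      longhand_d(x[i, combos[, 1]], x[i, -combos[, 1]], s0 = s0)$d,
      numeric(1))
    expect_equal(unname(perm$permuted_d[, 1]), d1, tolerance = 1e-12)
  }
})

test_that("delta cuts call exactly the features the rule dictates", {
  set.seed(81)
  x <- matrix(rnorm(100 * 10, 0.5, 0.1), 100, 10)
  x[1:5, 1:5] <- x[1:5, 1:5] + 0.3         # planted positive shift
  rownames(x) <- sprintf("f%03d", 1:100)
  labels <- rep(c("positive", "negative"), each = 5)
  d <- sam_d_scores(x, labels, s0 = 0.05)$d
  names(d) <- rownames(x)
  perm <- sam_permutation(x, labels, s0 = 0.05, n_permutations = 100,
                          seed = 2)
  delta <- 1
  res <- call_significant(d, perm$expected_d, perm$permuted_d, delta)
  # brute-force application of the cutoff rule
  ds <- sort(d)
  gap <- ds - perm$expected_d
  cut_up <- if (any(gap > delta)) min(ds[gap > delta]) else Inf
  cut_low <- if (any(-gap > delta)) max(ds[-gap > delta]) else -Inf
  expect_equal(sort(res$significant_positive),
               sort(names(d)[d >= cut_up]))
  expect_equal(sort(res$significant_negative),
               sort(names(d)[d <= cut_low]))
  counts <- apply(perm$permuted_d, 2,
                  function(col) sum(col >= cut_up | col <= cut_low))
  expect_equal(res$fdr_estimate,
               unname(quantile(counts, 0.5, type = 7)) /
                 (length(res$significant_positive) +
                    length(res$significant_negative)))
  # delta -> Inf: nothing called, FDR undefined
  res_inf <- call_significant(d, perm$expected_d, perm$permuted_d, 1e9)
  expect_equal(length(res_inf$significant_positive), 0L)
  expect_true(is.na(res_inf$fdr_estimate))
  # delta = 0: every feature off the expected line is called on its side
  res0 <- call_significant(d, perm$expected_d, perm$permuted_d, 0)
  called0 <- length(res0$significant_positive) +
    length(res0$significant_negative)
  expect_gte(called0, sum(abs(gap) > 0) - 2)  # cuts sweep in whole tails
  # monotonicity: larger delta never enlarges the called set
  sizes <- vapply(c(0, 0.5, 1, 2, 4), function(dl) {
    r <- call_significant(d, perm$expected_d, perm$permuted_d, dl)
    length(r$significant_positive) + length(r$significant_negative)
  }, numeric(1))
  expect_true(all(diff(sizes) <= 0))
})

test_that("run_sam is deterministic, recovers planted genes and rolls probes up per gene", {
  eff <- make_gene_effects(120, frac_hyper_in_positive = 1 / 3,
                           frac_hypo_in_positive = 0,
                           effect_size_logit = 1.5, noise_sd_logit = 0.4,
                           seed = 91)
  co <- simulate_platform_cohort(60, 0.5, eff, platform_goldengate(),
                                 seed = 91, expression = FALSE)
  cfg <- sam_config(delta = 0.7, n_permutations = 150, seed = 5)
  r1 <- run_sam(co$gene_meth, co$samples, cfg)
  r2 <- run_sam(co$gene_meth, co$samples, cfg)
  expect_identical(r1[setdiff(names(r1), "s_values")],
                   r2[setdiff(names(r2), "s_values")])
  planted <- eff$gene_symbol[eff$effect_logit > 0]
  hits <- intersect(r1$significant_positive, planted)
  expect_gte(length(hits) / length(r1$significant_positive), 0.9)
  # probe-level run yields one row per gene, reporting the max-|d| probe
  rp <- run_sam(co$beta, co$samples, cfg, annotation = co$annotation)
  expect_equal(sort(rp$gene_view$gene_symbol), sort(eff$gene_symbol))
  i <- which(rp$gene_view$gene_symbol == planted[1])
  probes <- co$annotation$probe_id[co$annotation$gene_symbol == planted[1]]
  expect_equal(abs(rp$gene_view$d[i]), max(abs(rp$d_scores[probes])))
})

test_that("under the global null few features are called and FDR bounds the false fraction", {
  called_frac <- fdr_est <- numeric(20)
  for (s in seq_len(20)) {
    co <- null_cohort(100, 40, seed = 100 + s)
    r <- run_sam(co$gene_meth, co$samples,
                 sam_config(delta = 1.2, n_permutations = 100,
                            seed = 100 + s))
    n_called <- length(r$significant_positive) +
      length(r$significant_negative)
    called_frac[s] <- n_called / 100
    fdr_est[s] <- ifelse(is.na(r$fdr_estimate), 1, r$fdr_estimate)
  }
  expect_lt(mean(called_frac), 0.10)
  # every null call is a false call; the estimate should not undershoot
  # the observed false fraction grossly on average
  expect_gte(mean(fdr_est) + 0.1, mean(called_frac))
})
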