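test_that("probe-to-gene aggregation averages non-missing probe values", {
  vals <- rbind(cg1 = c(0.2, 0.2, NA),
                cg2 = c(0.4, NA,  NA),
                cg3 = c(0.7, 0.7, 0.6))
  colnames(vals) <- c("S1", "S2", "S3")
  b <- beta_matrix(vals)
  ann <- probe_annotation(c("cg1", "cg2", "cg3"), c("GA", "GA", "GB"))
  gm <- aggregate_to_genes(b, ann)
  expect_equal(gm["GA", "S1"], 0.3)          # mean of 0.2 and 0.4
  expect_equal(gm["GA", "S2"], 0.2)          # missing probe skipped
  expect_equal(gm["GA", "S3"], NA_real_)     # all contributing missing
  expect_equal(unname(gm["GB", ]), unname(vals["cg3", ]))  # 1-probe gene
  # {0.2, missing, 0.7} -> 0.45
  vals2 <- matrix(c(0.2, NA, 0.7), 3, 1,
                  dimnames = list(c("p1", "p2", "p3"), "S1"))
  gm2 <- aggregate_to_genes(beta_matrix(vals2),
                            probe_annotation(c("p1", "p2", "p3"),
                                             rep("G", 3)))
  expect_equal(unname(gm2["G", "S1"]), 0.45)
  expect_error(aggregate_to_genes(b, probe_annotation("cg1", "GA")),
               "without annotation")
})

test_that("per-gene logistic fit agrees with glm and with a likelihood grid search", {
  set.seed(11)
  n <- 40
  g <- runif(n, 0.1, 0.9)
  y <- rbinom(n, 1, plogis(-1 + 3 * g))
  cov <- cbind(age = rnorm(n, 55, 8))
  fit <- fit_gene_logistic(g, y, cov)
  gl <- glm(y ~ g + cov, family = binomial)
  expect_true(fit$converged)
  expect_equal(fit$coefficient, unname(coef(gl)["g"]), tolerance = 1e-6)
  expect_equal(fit$std_error,
               unname(summary(gl)$coefficients["g", "Std. Error"]),
               tolerance = 1e-6)
  expect_equal(fit$p_value,
               unname(summary(gl)$coefficients["g", "Pr(>|z|)"]),
               tolerance = 1e-5)

  # independent oracle: iterated grid search over (b0, b1), no covariates
  set.seed(12)
  g2 <- runif(20, 0.1, 0.9)
  y2 <- rbinom(20, 1, plogis(-0.5 + 2 * g2))
  loglik <- function(b0, b1) {
    eta <- b0 + b1 * g2
    sum(y2 * eta - log1p(exp(eta)))
  }
  centre <- c(0, 0); width <- 16
  for (step in 1:24) {
    b0s <- seq(centre[1] - width, centre[1] + width, length.out = 21)
    b1s <- seq(centre[2] - width, centre[2] + width, length.out = 21)
    ll <- outer(b0s, b1s, Vectorize(loglik))
    ix <- which(ll == max(ll), arr.ind = TRUE)[1, ]
    centre <- c(b0s[ix[1]], b1s[ix[2]])
    width <- width / 4
  }
  fit2 <- fit_gene_logistic(g2, y2)
  expect_equal(fit2$coefficient, centre[2], tolerance = 1e-3)
})

test_that("degenerate fits are excluded and label swaps negate the coefficient", {
  y <- rep(c(1, 0), each = 10)
  const <- fit_gene_logistic(rep(0.5, 20), y)
  expect_false(const$converged)
  expect_equal(const$direction, "excluded")
  set.seed(13)
  g <- runif(20, 0.2, 0.8)
  a <- fit_gene_logistic(g, y)
  b <- fit_gene_logistic(g, 1 - y)
  expect_equal(a$coefficient, -b$coefficient, tolerance = 1e-6)
  expect_equal(a$p_value, b$p_value, tolerance = 1e-6)
  # perfectly separated data are flagged, not returned as a fit
  sep <- fit_gene_logistic(c(runif(10, 0.1, 0.4), runif(10, 0.6, 0.9)), y)
  expect_false(sep$converged)
  expect_error(fit_gene_logistic(g, y * 2), "binary")
})

test_that("the scan equals independent per-gene fits and handles excluded genes", {
  co <- null_cohort(20, 30, seed = 21)
  scan <- scan_all_genes(co$gene_meth, co$samples)
  expect_equal(nrow(scan), 20)
  expect_true(all(scan$converged))
  cov <- methscan:::build_covariates(co$samples)
  y <- as.numeric(co$samples$erpr_group == "positive")
  for (i in c(1, 7, 20)) {
    single <- fit_gene_logistic(co$gene_meth[i, ], y, cov)
    expect_equal(scan$coefficient[i], single$coefficient)
    expect_equal(scan$p_value[i], single$p_value)
  }
  gm <- co$gene_meth
  gm[3, ] <- 0.4
  scan2 <- scan_all_genes(gm, co$samples)
  expect_equal(scan2$direction[3], "excluded")
  expect_true(all(scan2$converged[-3]))
})

test_that("direction summaries reproduce ratio arithmetic and nest across thresholds", {
  mk <- function(n, dir, p) data.frame(
    gene_symbol = sprintf("g%d", seq_len(n)), coefficient = ifelse(dir ==
      "positive", 1, -1), std_error = 1, p_value = p, direction = dir,
    converged = TRUE, n_used = 75)
  res <- rbind(mk(10, "positive", 0.01), mk(2, "inverse", 0.01),
               mk(5, "positive", 0.1), mk(4, "inverse", 0.1),
               mk(3, "positive", 0.5), mk(6, "inverse", 0.5))
  s05 <- summarize_directions(res, 0.05)
  expect_equal(s05$n_total, 12)
  expect_equal(s05$prop_positive, 10 / 12)
  expect_equal(s05$ratio_pos_inverse, 5)
  s20 <- summarize_directions(res, 0.20)
  s1 <- summarize_directions(res, 1)
  expect_lte(s05$n_total, s20$n_total)
  expect_lte(s20$n_total, s1$n_total)
  expect_equal(s1$n_total, 30)
  expect_equal(s1$n_positive + s1$n_inverse, s1$n_total)
  # equal counts give prop 0.5 and ratio 1; no inverse gives Inf
  even <- rbind(mk(4, "positive", 0.01), mk(4, "inverse", 0.01))
  se <- summarize_directions(even, 0.05)
  expect_equal(se$prop_positive, 0.5)
  expect_equal(se$ratio_pos_inverse, 1)
  onesided <- summarize_directions(mk(4, "positive", 0.01), 0.05)
  expect_equal(onesided$ratio_pos_inverse, Inf)
  empty <- summarize_directions(mk(4, "positive", 0.5), 0.05)
  expect_false(empty$defined)
})

test_that("bias-corrected interval collapses and reduces correctly", {
  bc <- methscan:::bc_interval
  # degenerate bootstrap distribution equal to the observed value
  expect_equal(bc(rep(0.7, 100), 0.7), c(0.7, 0.7))
  # zero bias (median = observed) reduces to the plain percentile interval
  set.seed(31)
  boot <- rnorm(2001)
  obs <- median(boot)
  expect_equal(bc(boot, obs),
               unname(quantile(boot, c(0.025, 0.975), type = 7)),
               tolerance = 1e-10)
  # endpoints monotone in nominal coverage, observed inside when z0 = 0
  ci90 <- bc(boot, obs, conf_level = 0.90)
  ci99 <- bc(boot, obs, conf_level = 0.99)
  expect_lte(ci99[1], ci90[1])
  expect_gte(ci99[2], ci90[2])
  expect_true(obs >= ci90[1] && obs <= ci90[2])
})

test_that("bootstrap summary carries CIs that contain the point estimate", {
  co <- null_cohort(40, 40, seed = 41)
  bs <- bootstrap_direction_ci(co$gene_meth, co$samples, p_threshold = 1,
                               n_bootstrap = 100, seed = 42)
  expect_equal(bs$n_bootstrap, 100L)
  expect_true(bs$ci_prop[1] <= bs$ci_prop[2])
  expect_true(bs$prop_positive >= 0 && bs$prop_positive <= 1)
  expect_equal(bs$n_positive + bs$n_inverse, bs$n_total)
  # same seed, same interval
  bs2 <- bootstrap_direction_ci(co$gene_meth, co$samples, p_threshold = 1,
                                n_bootstrap = 100, seed = 42)
  expect_identical(bs$ci_prop, bs2$ci_prop)
})

test_that("two-group tests match the longhand Welch formula and are symmetric", {
  xp <- c(0.42, 0.55, 0.61, 0.38)
  xn <- c(0.30, 0.25, 0.33, 0.41)
  gm <- structure(rbind(G1 = c(xp, xn)), class = c("gene_methylation",
                                                   "matrix", "array"))
  colnames(gm) <- sprintf("S%02d", 1:8)
  s <- toy_samples(4, 4)
  res <- group_difference_tests(gm, s)
  # longhand Welch arithmetic
  se2 <- var(xp) / 4 + var(xn) / 4
  t_hand <- (mean(xp) - mean(xn)) / sqrt(se2)
  df_hand <- se2^2 / ((var(xp) / 4)^2 / 3 + (var(xn) / 4)^2 / 3)
  p_hand <- 2 * pt(-abs(t_hand), df_hand)
  expect_equal(res$t_stat, t_hand, tolerance = 1e-6)
  expect_equal(res$t_p, p_hand, tolerance = 1e-6)
  expect_equal(res$mean_beta_positive, mean(xp))
  # swapping groups negates t, keeps p
  s_sw <- toy_samples(4, 4)
  s_sw$er_status <- rev(s_sw$er_status)
  s_sw$erpr_group <- rev(s_sw$erpr_group)
  res_sw <- group_difference_tests(gm, s_sw)
  expect_equal(res_sw$t_stat, -res$t_stat, tolerance = 1e-10)
  expect_equal(res_sw$t_p, res$t_p, tolerance = 1e-10)
  expect_equal(res_sw$wilcoxon_p, res$wilcoxon_p, tolerance = 1e-10)
  # identical groups: zero statistic, maximal p
  gm0 <- structure(rbind(G1 = rep(0.5, 8)),
                   class = c("gene_methylation", "matrix", "array"))
  colnames(gm0) <- sprintf("S%02d", 1:8)
  res0 <- group_difference_tests(gm0, s)
  expect_equal(res0$t_stat, 0)
  expect_equal(res0$t_p, 1)
  expect_equal(res0$ks_p, 1)
})

test_that("chi-square test matches the direct formula and its degenerate cases", {
  expect_equal(chi_square_table(matrix(c(10, 10, 10, 10), 2))$statistic, 0)
  same_prop <- matrix(c(20, 10, 40, 20), 2)   # identical row proportions
  ct <- chi_square_table(same_prop)
  expect_equal(ct$statistic, 0, tolerance = 1e-12)
  expect_equal(ct$p_value, 1)
  tab <- matrix(c(20, 5, 5, 20), 2)
  e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  expect_equal(chi_square_table(tab)$statistic, sum((tab - e)^2 / e),
               tolerance = 1e-9)
  expect_equal(chi_square_table(tab)$df, 1)
  expect_error(chi_square_table(matrix(c(0, 0, 5, 5), 2)), "marginal")
})
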