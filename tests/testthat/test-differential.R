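test_that("a pure treatment shift loads only on the treatment effect", {
  d <- toy_design(G = 4)
  y <- ifelse(d$treatment == "stressed", 1, 0) # zero-noise constructed signal
  fit <- fit_gene_anova(y, d)
  expect_lt(fit$p_raw[fit$effect == "treatment"], 1e-12)
  expect_equal(fit$F[fit$effect == "genotype"], 0)
  expect_equal(fit$F[fit$effect == "gxt"], 0)
})

test_that("a constant gene yields F = 0 and p = 1 everywhere", {
  d <- toy_design()
  fit <- fit_gene_anova(rep(3.14, nrow(d)), d)
  expect_equal(fit$F, rep(0, 4))
  expect_equal(fit$p_raw, rep(1, 4))
})

test_that("F statistics match an independent Type-II linear-model oracle", {
  skip_if_not_installed("car")
  set.seed(21)
  d <- toy_design(G = 8)
  check_gene <- function(y, des) {
    mine <- fit_gene_anova(y, des)
    dd <- data.frame(y = y, block = factor(des$block),
                     genotype = factor(des$genotype),
                     treatment = factor(des$treatment))
    a <- car::Anova(stats::lm(y ~ block + genotype + treatment +
                                genotype:treatment, dd), type = 2)
    ref <- a[c("block", "genotype", "treatment", "genotype:treatment"),
             "F value"]
    expect_equal(mine$F, unname(ref), tolerance = 1e-8)
  }
  for (r in 1:3) check_gene(rnorm(nrow(d)), d)
  # unbalanced design (one chip missing) exercises the Type-II path
  d2 <- d[-7, ]
  for (r in 1:3) check_gene(rnorm(nrow(d2)), d2)
})

test_that("balanced-design F is invariant to sample order and constant shifts", {
  set.seed(22)
  d <- toy_design(G = 4)
  y <- rnorm(nrow(d))
  f0 <- fit_gene_anova(y, d)
  perm <- sample(nrow(d))
  f1 <- fit_gene_anova(y[perm], d[perm, ])
  expect_equal(f0$F, f1$F, tolerance = 1e-10)
  f2 <- fit_gene_anova(y + 100, d)
  expect_equal(f0$F, f2$F, tolerance = 1e-8)
})

test_that("Bonferroni adjustment uses the explicit family size", {
  expect_equal(adjust_bonferroni(0.001, 32423), 1)
  expect_equal(adjust_bonferroni(1e-6, 32423), 0.032423)
  expect_equal(adjust_bonferroni(0, 5000), 0)
  expect_error(adjust_bonferroni(0.1, 0), "family size")
})

test_that("Bartlett pooling keeps homoscedastic genes and trims an outlier", {
  # identical variances: statistic 0, p 1, everything pooled
  eq <- pool_residual_variance(rep(2, 50), rep(32, 50))
  expect_true(all(eq$pooled))
  expect_equal(eq$pooled_variance, 2)
  expect_equal(eq$pooled_df, 50 * 32)
  expect_equal(eq$bartlett_p, 1)

  # a 100x-variance gene is rejected by Bartlett and trimmed
  set.seed(23)
  s2 <- stats::rchisq(200, 32) / 32
  s2[17] <- 100
  pr <- pool_residual_variance(s2, rep(32, 200))
  expect_false(pr$pooled[17])
  expect_gte(pr$bartlett_p, 0.05)
  expect_lt(pr$n_trimmed / 200, 0.25)

  expect_warning(p1 <- pool_residual_variance(2, 32), "fewer than 2")
  expect_false(any(p1$pooled))
})

test_that("the closed-form Bartlett statistic equals stats::bartlett.test", {
  set.seed(24)
  groups <- lapply(1:6, function(i) rnorm(9, sd = sqrt(i)))
  ref <- stats::bartlett.test(groups)
  s2 <- vapply(groups, stats::var, 1)
  mine <- droughtnet:::bartlett_from_variances(s2, rep(8, 6))
  expect_equal(mine$statistic, unname(ref$statistic), tolerance = 1e-10)
  expect_equal(mine$p, ref$p.value, tolerance = 1e-10)
})

test_that("pooled F statistics follow the nominal F distribution under homoscedasticity", {
  set.seed(25)
  d <- toy_design(G = 8)
  expr <- matrix(rnorm(1000 * nrow(d)), 1000, nrow(d),
                 dimnames = list(sprintf("g%04d", 1:1000), d$plant_id))
  fit <- fit_anova(expr, d, pool = TRUE)
  expect_true(mean(fit$pooled) > 0.7) # most genes share the common variance
  f_t <- fit$table$F[fit$table$effect == "treatment" &
                       fit$table$gene %in% names(fit$pooled)[fit$pooled]]
  ks <- stats::ks.test(f_t, stats::pf, 1, fit$pooled_df)
  expect_gt(ks$p.value, 0.01)
})

test_that("significance patterns map deterministically onto the eight classes", {
  combos <- expand.grid(genotype = c(FALSE, TRUE), treatment = c(FALSE, TRUE),
                        gxt = c(FALSE, TRUE))
  flags <- as.matrix(combos)
  rownames(flags) <- sprintf("g%d", seq_len(nrow(flags)))
  got <- as.character(classify_effects(flags))
  want <- c("none", "g_o", "t_o", "g_t", "g*t_o", "g*t_g", "g*t_t", "All")
  expect_equal(got, want)
  # pure function of the flags: permuting genes permutes labels identically
  perm <- sample(nrow(flags))
  expect_equal(as.character(classify_effects(flags[perm, ])), want[perm])
})

test_that("scenario cross-tabulation satisfies its roll-up identities", {
  genes <- sprintf("g%03d", 1:200)
  all_none <- factor(stats::setNames(rep("none", 200), genes),
                     levels = droughtnet:::effect_class_levels)
  ct0 <- cross_tabulate_scenarios(all_none, all_none)
  expect_equal(ct0$core["none", "none"], 200)
  expect_equal(sum(ct0$core), 200)

  set.seed(26)
  lv <- droughtnet:::effect_class_levels
  c1 <- factor(stats::setNames(sample(lv, 200, replace = TRUE), genes), levels = lv)
  c2 <- factor(stats::setNames(sample(lv, 200, replace = TRUE), genes), levels = lv)
  ct <- cross_tabulate_scenarios(c1, c2)
  # "at least treatment" roll-up = t_o + g_t + g*t_t + All, on both margins
  t_cls <- c("t_o", "g_t", "g*t_t", "All")
  expect_equal(ct$full["t", "t"], sum(ct$core[t_cls, t_cls]))
  expect_equal(ct$full["Eff", "Eff"],
               sum(ct$core[setdiff(lv, "none"), setdiff(lv, "none")]))
  expect_equal(sum(ct$core), 200)
  expect_error(cross_tabulate_scenarios(c1, c2[1:100]), "different gene sets")
})

test_that("Tukey HSD flags exactly the genotype carrying the planted contrast", {
  set.seed(27)
  d <- toy_design(G = 4)
  y <- rnorm(nrow(d), sd = 0.2)
  shift <- d$genotype == "GT2" & d$treatment == "stressed"
  y[shift] <- y[shift] + 8
  fit <- fit_gene_anova(y, d)
  mse_fit <- fit_anova(matrix(y, 1, dimnames = list("g", d$plant_id)), d,
                       pool = FALSE)
  hsd <- tukey_hsd_by_genotype(y, d, mse = mse_fit$resid_var[["g"]],
                               df_err = mse_fit$df_resid)
  expect_true(hsd$significant[hsd$genotype == "GT2"])
  expect_false(any(hsd$significant[hsd$genotype != "GT2"]))
  expect_equal(hsd$diff[hsd$genotype == "GT2"], 8, tolerance = 0.5)
})

test_that("Tukey HSD agrees with the reference studentized-range implementation", {
  set.seed(28)
  d <- toy_design(G = 3)
  y <- rnorm(nrow(d)) + ifelse(d$treatment == "stressed", 1.2, 0)
  cell <- interaction(factor(d$genotype), factor(d$treatment))
  fm <- stats::aov(y ~ cell)
  ref <- stats::TukeyHSD(fm)$cell
  mse <- sum(stats::residuals(fm)^2) / stats::df.residual(fm)
  hsd <- tukey_hsd_by_genotype(y, d, mse = mse, df_err = stats::df.residual(fm))
  for (g in unique(d$genotype)) {
    rn <- paste0(g, ".stressed-", g, ".control")
    expect_equal(hsd$p[hsd$genotype == g], unname(ref[rn, "p adj"]),
                 tolerance = 1e-8)
  }
})

test_that("Tukey HSD edge cases: equal cells and zero MSE", {
  d <- toy_design(G = 2)
  y <- rep(c(1, 1, 1), length.out = nrow(d))
  expect_warning(hsd <- tukey_hsd_by_genotype(y, d, mse = 0, df_err = 10),
                 "zero MSE")
  expect_equal(hsd$q, rep(0, 2))
  expect_false(any(hsd$significant))
})

test_that("null simulation keeps the HSD family-wise false-positive rate in check", {
  set.seed(29)
  d <- toy_design(G = 8)
  fp <- vapply(1:500, function(i) {
    y <- rnorm(nrow(d))
    fit <- fit_anova(matrix(y, 1, dimnames = list("g", d$plant_id)), d,
                     pool = FALSE)
    hsd <- tukey_hsd_by_genotype(y, d, mse = fit$resid_var[["g"]],
                                 df_err = fit$df_resid)
    any(hsd$significant)
  }, TRUE)
  expect_lte(mean(fp), 0.07)
})

test_that("double hierarchical classification separates planted sample groups", {
  set.seed(30)
  # two sample groups with opposite signatures over two gene groups
  grp <- rep(c(0, 1), each = 6)
  expr <- rbind(
    matrix(rnorm(5 * 12, mean = rep(grp * 4, each = 5)), 5, 12),
    matrix(rnorm(5 * 12, mean = rep((1 - grp) * 4, each = 5)), 5, 12)
  )
  dimnames(expr) <- list(paste0("g", 1:10), paste0("s", 1:12))
  bc <- hierarchical_bicluster(expr)
  ord_grp <- grp[bc$sample_order]
  expect_equal(sum(diff(ord_grp) != 0), 1) # one boundary: groups contiguous
  expect_match(bc$sample_newick, "^\\(")

  # identical samples merge at distance 0
  e2 <- cbind(expr, s13 = expr[, 1])
  bc2 <- hierarchical_bicluster(e2)
  expect_equal(min(bc2$sample_hclust$height), 0)

  # single gene: trivial one-leaf tree (sample correlations over one gene
  # are undefined, so the distance fallback warns)
  suppressWarnings(bc3 <- hierarchical_bicluster(expr[1, , drop = FALSE]))
  expect_null(bc3$gene_hclust)
  expect_equal(bc3$gene_order, 1L)

  # constant gene row: distance falls back with a warning
  e4 <- expr; e4[1, ] <- 7
  expect_warning(hierarchical_bicluster(e4), "constant")
})

test_that("ANOVA tables serialize with class labels", {
  ds <- simulate_dataset(small_config(seed = 31))
  j <- ds$samples$scenario == "FDS"
  fit <- fit_anova(ds$expr[, j], ds$samples[j, ], pool = FALSE)
  f <- tempfile(fileext = ".tsv")
  write_anova_tsv(fit, f)
  back <- utils::read.delim(f)
  expect_equal(nrow(back), 4 * nrow(ds$expr))
  expect_true(all(back$class %in% droughtnet:::effect_class_levels))
  unlink(f)
})
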