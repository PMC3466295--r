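# Per-gene two-way ANOVA machinery. The per-effect sums of squares are
# Type II (each effect adjusted for the others at its marginality level),
# computed for all genes at once from reduced-model residual sums of
# squares; on a balanced design this reduces to the classical
# decomposition.

effect_levels <- c("block", "genotype", "treatment", "gxt")

anova_design <- function(samples) {
  block <- factor(samples$block)
  genotype <- factor(samples$genotype)
  treatment <- factor(samples$treatment)
  if (nlevels(genotype) < 2 || nlevels(treatment) != 2 || nlevels(block) < 1) {
    stop("design needs >= 2 genotypes, exactly 2 treatments and >= 1 block")
  }
  cells <- table(genotype, treatment)
  if (any(cells == 0)) {
    stop("empty genotype x treatment cell: design untestable")
  }
  list(block = block, genotype = genotype, treatment = treatment)
}

# thin QR wrapper: residual-maker applied to Y (samples x genes)
rss_under <- function(formula_terms, data, Y) {
  X <- stats::model.matrix(formula_terms, data = data)
  qr_x <- qr(X)
  Q <- qr.Q(qr_x)[, seq_len(qr_x$rank), drop = FALSE]
  res <- Y - Q %*% crossprod(Q, Y)
  list(rss = colSums(res * res), rank = qr_x$rank)
}

#' Per-gene ANOVA for one drought scenario
#'
#' Fits, for every gene, the fixed-effects model
#' block + genotype + treatment + genotype:treatment on the scenario's
#' samples and returns per-effect F statistics and p-values (Type II sums
#' of squares; classical decomposition when the design is balanced).
#' Optionally pools residual variances across genes judged homoscedastic
#' by Bartlett's test (see \code{\link{pool_residual_variance}}), recomputing
#' the pooled genes' F denominators with the common variance and summed
#' residual degrees of freedom. Raw p-values are Bonferroni-adjusted per
#' effect with m = number of genes tested.
#'
#' @param expr genes x samples matrix (the scenario's samples).
#' @param samples matching sample sheet (block, genotype, treatment).
#' @param pool apply Bartlett-gated residual-variance pooling? Default TRUE.
#' @param alpha significance level on adjusted p-values (default 0.05).
#' @param alpha_bartlett Bartlett gate for the pooled set (default 0.05).
#' @return an object of class \code{anova_fit}: \code{table} (long
#'   data.frame gene, effect, F, p_raw, p_bonf, significant), \code{flags}
#'   (genes x 4 logical), \code{classes} (per-gene effect-class label),
#'   \code{resid_var}, \code{df_resid}, \code{pooled} (per-gene flag),
#'   \code{pooled_variance}, \code{pooled_df}, \code{m}.
#' @export
fit_anova <- function(expr, samples, pool = TRUE, alpha = 0.05,
                      alpha_bartlett = 0.05) {
  stopifnot(identical(colnames(expr), samples$plant_id))
  des <- anova_design(samples)
  dat <- data.frame(block = des$block, genotype = des$genotype,
                    treatment = des$treatment)
  Y <- t(expr)
  n <- nrow(Y)

  full <- rss_under(~ block + genotype + treatment + genotype:treatment, dat, Y)
  add  <- rss_under(~ block + genotype + treatment, dat, Y)
  no_g <- rss_under(~ block + treatment, dat, Y)
  no_t <- rss_under(~ block + genotype, dat, Y)
  no_b <- rss_under(~ genotype + treatment + genotype:treatment, dat, Y)

  df_g <- nlevels(des$genotype) - 1L
  df_t <- 1L
  df_b <- nlevels(des$block) - 1L
  df_gt <- df_g * df_t
  df_resid <- n - full$rank
  if (df_resid <= 0) stop("no residual degrees of freedom")

  ss <- cbind(block = no_b$rss - full$rss,
              genotype = no_g$rss - add$rss,
              treatment = no_t$rss - add$rss,
              gxt = add$rss - full$rss)
  dfs <- c(block = df_b, genotype = df_g, treatment = df_t, gxt = df_gt)
  # flush QR round-off to exact zero, relative to each gene's total SS,
  # so noise-free constructed signals give F = 0 on absent effects
  tot <- colSums(sweep(Y, 2, colMeans(Y))^2)
  eps <- 1e-9 * pmax(tot, .Machine$double.eps)
  ss[ss < eps] <- 0
  rss_full <- full$rss
  rss_full[rss_full < eps] <- 0
  s2 <- rss_full / df_resid

  pooling <- list(pooled = rep(FALSE, ncol(Y)), pooled_variance = NA_real_,
                  pooled_df = NA_real_, bartlett_p = NA_real_)
  if (pool) {
    pooling <- pool_residual_variance(s2, rep(df_resid, ncol(Y)),
                                      alpha_bartlett = alpha_bartlett)
  }
  den <- ifelse(pooling$pooled, pooling$pooled_variance, s2)
  den_df <- ifelse(pooling$pooled, pooling$pooled_df, df_resid)

  genes <- colnames(Y)
  m <- ncol(Y)
  tab <- do.call(rbind, lapply(effect_levels, function(e) {
    ms <- ss[, e] / dfs[[e]]
    f <- ifelse(ms == 0, 0, ms / den)
    f[ms > 0 & den == 0] <- Inf
    p <- ifelse(ms == 0 & den == 0, 1,
                stats::pf(f, dfs[[e]], den_df, lower.tail = FALSE))
    data.frame(gene = genes, effect = e, F = f, p_raw = p,
               p_bonf = adjust_bonferroni(p, m),
               stringsAsFactors = FALSE)
  }))
  tab$significant <- tab$p_bonf < alpha
  flags <- matrix(tab$significant, ncol = 4,
                  dimnames = list(genes, effect_levels))

  structure(list(table = tab, flags = flags,
                 classes = classify_effects(flags),
                 resid_var = stats::setNames(s2, genes),
                 df_resid = df_resid,
                 pooled = stats::setNames(pooling$pooled, genes),
                 pooled_variance = pooling$pooled_variance,
                 pooled_df = pooling$pooled_df,
                 bartlett_p = pooling$bartlett_p,
                 m = m, alpha = alpha,
                 design = dat, samples = samples$plant_id),
            class = "anova_fit")
}

#' Single-gene ANOVA (convenience wrapper)
#'
#' @param expr_row named numeric vector, one gene's expression.
#' @param samples sample sheet for those samples.
#' @return data.frame effect, F, p_raw.
#' @export
fit_gene_anova <- function(expr_row, samples) {
  expr <- matrix(expr_row, nrow = 1,
                 dimnames = list("gene", samples$plant_id))
  fit <- fit_anova(expr, samples, pool = FALSE)
  fit$table[, c("effect", "F", "p_raw")]
}

#' Bonferroni family-wise adjustment with explicit family size
#'
#' @param p raw p-values.
#' @param m family size (number of genes tested per scenario per effect).
#' @return adjusted p-values, min(1, p * m).
#' @export
adjust_bonferroni <- function(p, m) {
  if (m < 1) stop("family size m must be >= 1")
  pmin(1, p * m)
}

# Bartlett's homogeneity statistic over per-group variances with known
# degrees of freedom (closed form; equivalent to stats::bartlett.test on
# the raw residuals).
bartlett_from_variances <- function(s2, df) {
  k <- length(s2)
  if (k < 2) return(list(statistic = NA_real_, p = NA_real_))
  vtot <- sum(df)
  sp2 <- sum(df * s2) / vtot
  # guard logs of zero variances
  if (sp2 <= 0 || any(s2 <= 0)) return(list(statistic = Inf, p = 0))
  stat <- (vtot * log(sp2) - sum(df * log(s2))) /
    (1 + (sum(1 / df) - 1 / vtot) / (3 * (k - 1)))
  list(statistic = stat,
       p = stats::pchisq(stat, k - 1, lower.tail = FALSE))
}

#' Bartlett-gated pooling of per-gene residual variances
#'
#' Tests homogeneity of the per-gene residual variances with Bartlett's
#' test; while the test rejects at \code{alpha_bartlett}, the
#' largest-variance gene is trimmed from the candidate set (up to
#' \code{max_trim} of the genes). The surviving set shares the mean common
#' residual variance with summed residual degrees of freedom; trimmed
#' genes keep their own variance. If the cap is reached without
#' homogeneity no gene is pooled.
#'
#' @param s2 per-gene residual variances.
#' @param df per-gene residual degrees of freedom.
#' @param alpha_bartlett homogeneity gate (default 0.05).
#' @param max_trim maximum fraction of genes trimmed (default 0.25).
#' @return list: \code{pooled} (logical per gene), \code{pooled_variance},
#'   \code{pooled_df}, \code{bartlett_p} (final), \code{n_trimmed}.
#' @export
pool_residual_variance <- function(s2, df, alpha_bartlett = 0.05,
                                   max_trim = 0.25) {
  k <- length(s2)
  if (k < 2) {
    warning("fewer than 2 genes: no variance pooling")
    return(list(pooled = rep(FALSE, k), pooled_variance = NA_real_,
                pooled_df = NA_real_, bartlett_p = NA_real_, n_trimmed = 0L))
  }
  ord <- order(s2, decreasing = TRUE) # trim candidates, largest first
  max_out <- floor(max_trim * k)
  n_out <- 0L
  repeat {
    keep <- if (n_out > 0) setdiff(seq_len(k), ord[seq_len(n_out)]) else seq_len(k)
    bt <- bartlett_from_variances(s2[keep], df[keep])
    if (is.na(bt$p) || bt$p >= alpha_bartlett) break
    if (n_out >= max_out) {
      return(list(pooled = rep(FALSE, k), pooled_variance = NA_real_,
                  pooled_df = NA_real_, bartlett_p = bt$p,
                  n_trimmed = n_out))
    }
    n_out <- n_out + 1L
  }
  pooled <- rep(FALSE, k)
  pooled[keep] <- TRUE
  list(pooled = pooled,
       pooled_variance = sum(df[keep] * s2[keep]) / sum(df[keep]),
       pooled_df = sum(df[keep]),
       bartlett_p = bt$p, n_trimmed = n_out)
}

# The eight effect-class labels of the significance cross-tabulation.
effect_class_levels <- c("All", "g_o", "g_t", "g*t_g", "g*t_o", "g*t_t",
                         "t_o", "none")

#' Map per-gene significance flags to effect-class labels
#'
#' Deterministic mapping from the (genotype, treatment, g*t) significance
#' pattern to the eight class labels: none, t_o, g_o, g*t_o, g_t, g*t_g,
#' g*t_t, All. Block significance does not enter the classes.
#'
#' @param flags genes x effects logical matrix with columns genotype,
#'   treatment, gxt (a block column is ignored), or a data.frame alike.
#' @return factor of class labels, one per gene.
#' @export
classify_effects <- function(flags) {
  flags <- as.matrix(flags)
  g <- flags[, "genotype"]
  t <- flags[, "treatment"]
  gt <- flags[, "gxt"]
  lab <- rep("none", length(g))
  lab[g & !t & !gt] <- "g_o"
  lab[!g & t & !gt] <- "t_o"
  lab[!g & !t & gt] <- "g*t_o"
  lab[g & t & !gt] <- "g_t"
  lab[g & !t & gt] <- "g*t_g"
  lab[!g & t & gt] <- "g*t_t"
  lab[g & t & gt] <- "All"
  factor(stats::setNames(lab, rownames(flags)), levels = effect_class_levels)
}

# roll-up definitions over exclusive classes
effect_rollups <- list(
  Eff = setdiff(effect_class_levels, "none"),
  t = c("t_o", "g_t", "g*t_t", "All"),
  g = c("g_o", "g_t", "g*t_g", "All"),
  `g*t` = c("g*t_o", "g*t_g", "g*t_t", "All")
)

#' Cross-tabulate effect classes between the two scenarios
#'
#' Counts genes per (FIS class, FDS class) cell and appends the roll-up
#' rows/columns (Eff = at least one effect, t / g / g*t = at least that
#' effect), each the sum of its constituent exclusive cells.
#'
#' @param classes_fds,classes_fis per-gene class labels
#'   (named, same gene universe).
#' @return list: \code{core} 8 x 8 count matrix (FIS rows, FDS columns),
#'   \code{full} the same with roll-up rows/columns appended.
#' @export
cross_tabulate_scenarios <- function(classes_fds, classes_fis) {
  if (!setequal(names(classes_fds), names(classes_fis))) {
    stop("scenario class vectors cover different gene sets")
  }
  classes_fis <- classes_fis[names(classes_fds)]
  core <- table(
    FIS = factor(classes_fis, levels = effect_class_levels),
    FDS = factor(classes_fds, levels = effect_class_levels)
  )
  core <- unclass(core)
  groups <- c(stats::setNames(as.list(effect_class_levels),
                              effect_class_levels),
              effect_rollups)
  full <- vapply(groups, function(cls_col) {
    vapply(groups, function(cls_row) sum(core[cls_row, cls_col]),
           numeric(1))
  }, numeric(length(groups)))
  list(core = core, full = full)
}

#' Tukey HSD treated-vs-control contrasts within genotypes
#'
#' Compares all genotype x treatment cell means of one gene with the
#' studentized range (family = all cell pairs), using the model's (pooled)
#' mean squared error, and reports the treated-vs-control contrast within
#' each genotype.
#'
#' @param expr_row named numeric vector, one gene's expression (log2).
#' @param samples matching sample sheet.
#' @param mse mean squared error from the ANOVA (pooled or gene-specific).
#' @param df_err its degrees of freedom.
#' @param alpha family-wise level (default 0.05).
#' @return data.frame genotype, diff (stressed - control, log2),
#'   fold_change (2^diff), q, p, significant.
#' @export
tukey_hsd_by_genotype <- function(expr_row, samples, mse, df_err,
                                  alpha = 0.05) {
  if (mse < 0 || !is.finite(mse)) stop("invalid MSE")
  des <- anova_design(samples)
  cell <- interaction(des$genotype, des$treatment, drop = FALSE)
  means <- tapply(expr_row, cell, mean)
  ns <- tapply(expr_row, cell, length)
  nmeans <- length(means)
  genos <- levels(des$genotype)
  out <- data.frame(genotype = genos, diff = NA_real_, fold_change = NA_real_,
                    q = NA_real_, p = NA_real_, significant = NA,
                    stringsAsFactors = FALSE)
  degenerate <- mse == 0
  if (degenerate) warning("zero MSE: HSD degenerate for this gene")
  for (i in seq_along(genos)) {
    a <- paste0(genos[i], ".stressed")
    b <- paste0(genos[i], ".control")
    dm <- means[[a]] - means[[b]]
    se <- sqrt(mse / 2 * (1 / ns[[a]] + 1 / ns[[b]]))
    q <- if (se == 0) ifelse(dm == 0, 0, Inf) else abs(dm) / se
    p <- if (q == 0) 1 else
      stats::ptukey(q, nmeans = nmeans, df = df_err, lower.tail = FALSE)
    out$diff[i] <- dm
    out$fold_change[i] <- 2^dm
    out$q[i] <- q
    out$p[i] <- p
    out$significant[i] <- !degenerate && p < alpha && dm != 0
  }
  out
}

#' Double hierarchical classification of genes and samples
#'
#' Agglomerative clustering of the genes and of the samples of an
#' expression submatrix (typically the significant genes), with distance
#' 1 - Pearson correlation and average linkage by default. Constant rows
#' or columns (undefined correlation) are placed at distance 1 with a
#' warning. A single gene or sample yields a trivial one-leaf tree.
#'
#' @param expr genes x samples matrix.
#' @param linkage linkage method passed to \code{hclust}.
#' @param distance "pearson" (1 - correlation) or any \code{dist} method.
#' @return list: \code{gene_hclust}, \code{sample_hclust} (NULL for single
#'   leaves), \code{gene_order}, \code{sample_order} (leaf orders),
#'   \code{gene_newick}, \code{sample_newick}.
#' @export
hierarchical_bicluster <- function(expr, linkage = "average",
                                   distance = "pearson") {
  cluster_one <- function(mat, labels) {
    if (nrow(mat) == 1) {
      return(list(hclust = NULL, order = 1L,
                  newick = paste0(labels, ";")))
    }
    if (distance == "pearson") {
      cc <- suppressWarnings(stats::cor(t(mat)))
      if (anyNA(cc)) {
        warning("constant profile: undefined correlation set to distance 1")
        cc[is.na(cc)] <- 0
      }
      dd <- stats::as.dist(1 - cc)
    } else {
      dd <- stats::dist(mat, method = distance)
    }
    hc <- stats::hclust(dd, method = linkage)
    hc$labels <- labels
    list(hclust = hc, order = hc$order,
         newick = ape::write.tree(ape::as.phylo(hc)))
  }
  g <- cluster_one(expr, rownames(expr))
  s <- cluster_one(t(expr), colnames(expr))
  list(gene_hclust = g$hclust, sample_hclust = s$hclust,
       gene_order = g$order, sample_order = s$order,
       gene_newick = g$newick, sample_newick = s$newick)
}

#' Write a long-format ANOVA table as TSV
#'
#' Columns: gene, effect, F, p_raw, p_bonf, significant, class.
#'
#' @param fit an \code{\link{fit_anova}} result.
#' @param path output TSV.
#' @export
write_anova_tsv <- function(fit, path) {
  tab <- fit$table
  tab$class <- as.character(fit$classes[tab$gene])
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
}
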