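#' Run the full gene-phenotype network pipeline on a dataset
#'
#' Executes the analysis end to end: normalization (block centering +
#' quantile normalization), per-scenario two-way ANOVA with Bonferroni
#' control and variance pooling, per-scenario sPLS of phenotypes on
#' expression, association-score networks at the threshold, merge across
#' scenarios, ANOVA-effect node annotation, and (when a field gene list
#' is given) the per-trait trait-link enrichment tests plus the induced
#' field subnetwork.
#'
#' @param expr genes x samples log2 expression matrix.
#' @param samples sample sheet (plant_id, scenario, block, genotype,
#'   treatment) matching \code{colnames(expr)}.
#' @param phenotypes per-plant phenotype table with plant_id and the nine
#'   trait columns ITW, E, OP, RWC, LMA, CID, PHe, CoD, TLA.
#' @param field_genes optional character vector of independent gene IDs.
#' @param threshold association-score threshold (default 0.65).
#' @param n_components sPLS components (default 3).
#' @param keepX genes kept per component (default 50).
#' @param alpha ANOVA significance level on Bonferroni-adjusted p-values.
#' @param pool_variance apply Bartlett-gated residual-variance pooling?
#' @return list of class \code{droughtnet_run}: \code{normalized},
#'   \code{anova} (per scenario), \code{spls} (per scenario),
#'   \code{scores} (per scenario), \code{networks} (per scenario),
#'   \code{merged}, \code{crosstab}, \code{trait_tests},
#'   \code{field_net}, \code{manifest}.
#' @export
run_pipeline <- function(expr, samples, phenotypes, field_genes = NULL,
                         threshold = 0.65, n_components = 3, keepX = 50,
                         alpha = 0.05, pool_variance = TRUE) {
  stopifnot(identical(colnames(expr), samples$plant_id))
  trait_cols <- c("ITW", "E", "OP", "RWC", "LMA", "CID", "PHe", "CoD", "TLA")
  miss <- setdiff(trait_cols, names(phenotypes))
  if (length(miss)) stop("phenotype table lacks: ", paste(miss, collapse = ", "))

  norm <- normalize_expression(expr, samples)

  scenarios <- sort(unique(samples$scenario))
  anova_fits <- list(); spls_fits <- list()
  score_sets <- list(); nets <- list()
  for (sc in scenarios) {
    j <- which(samples$scenario == sc)
    sub_expr <- norm[, j, drop = FALSE]
    sub_samples <- samples[j, , drop = FALSE]
    anova_fits[[sc]] <- fit_anova(sub_expr, sub_samples,
                                  pool = pool_variance, alpha = alpha)
    Y <- as.matrix(phenotypes[match(sub_samples$plant_id,
                                    phenotypes$plant_id), trait_cols])
    rownames(Y) <- sub_samples$plant_id
    spls_fits[[sc]] <- fit_spls(t(sub_expr), Y,
                                n_components = n_components, keepX = keepX)
    score_sets[[sc]] <- association_scores(spls_fits[[sc]])
    nets[[sc]] <- build_network(score_sets[[sc]]$scores,
                                threshold = threshold, scenario = sc)
  }

  merged <- NULL; crosstab <- NULL
  trait_tests <- NULL; field_net <- NULL
  if (all(c("FDS", "FIS") %in% scenarios)) {
    merged <- merge_networks(nets[["FDS"]], nets[["FIS"]])
    merged <- annotate_nodes(merged, anova_fits[["FDS"]], anova_fits[["FIS"]])
    crosstab <- cross_tabulate_scenarios(anova_fits[["FDS"]]$classes,
                                         anova_fits[["FIS"]]$classes)
    if (!is.null(field_genes) && length(field_genes) &&
        nrow(merged$genes) > 0 &&
        length(intersect(field_genes, merged$genes$gene)) > 0) {
      tested <- unique(merged$edges$phenotype)
      trait_tests <- do.call(rbind, lapply(tested, function(tr) {
        trait_link_enrichment(field_genes, merged, tr)
      }))
      field_net <- field_subnetwork(field_genes, merged)
    }
  }

  manifest <- list(
    n_genes = nrow(expr), n_samples = ncol(expr),
    scenarios = scenarios, threshold = threshold,
    n_components = n_components, keepX = keepX, alpha = alpha,
    pool_variance = pool_variance,
    edges = vapply(nets, function(n) nrow(n$edges), integer(1)),
    merged_genes = if (is.null(merged)) NA_integer_ else nrow(merged$genes),
    merged_edges = if (is.null(merged)) NA_integer_ else nrow(merged$edges)
  )
  structure(list(normalized = norm, anova = anova_fits, spls = spls_fits,
                 scores = score_sets, networks = nets, merged = merged,
                 crosstab = crosstab, trait_tests = trait_tests,
                 field_net = field_net, manifest = manifest),
            class = "droughtnet_run")
}

#' @export
print.droughtnet_run <- function(x, ...) {
  m <- x$manifest
  cat("drought gene-phenotype pipeline run:\n")
  cat("  ", m$n_genes, "genes x", m$n_samples, "samples;",
      "scenarios:", paste(m$scenarios, collapse = ", "), "\n")
  cat("  edges per scenario:",
      paste(sprintf("%s=%d", names(m$edges), m$edges), collapse = ", "), "\n")
  if (!is.na(m$merged_genes)) {
    cat("  merged network:", m$merged_genes, "genes,",
        m$merged_edges, "edges\n")
  }
  invisible(x)
}

#' Compare a merged network against the planted truth
#'
#' Precision and recall of the recovered gene-phenotype edges against the
#' planted association list of a synthetic dataset (matched on the
#' (gene, phenotype) pair; \code{signs_match} additionally requires the
#' recovered edge sign to equal the planted sign).
#'
#' @param merged a merged \code{assoc_network}.
#' @param truth a \code{sim_truth} record.
#' @return one-row data.frame: n_edges, n_planted, true_positives,
#'   precision, recall, sign_agreement.
#' @export
edge_recovery <- function(merged, truth) {
  planted <- truth$associations
  pkey <- paste(planted$gene, planted$phenotype)
  ekey <- paste(merged$edges$gene, merged$edges$phenotype)
  tp_idx <- ekey %in% pkey
  tp <- sum(tp_idx)
  sign_ok <- if (tp > 0) {
    planted_sign <- planted$sign[match(ekey[tp_idx], pkey)]
    mean(sign(merged$edges$score[tp_idx]) == planted_sign)
  } else NA_real_
  data.frame(n_edges = length(ekey), n_planted = length(pkey),
             true_positives = tp,
             precision = if (length(ekey)) tp / length(ekey) else NA_real_,
             recall = tp / length(pkey),
             sign_agreement = sign_ok)
}
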