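# Bipartite gene-phenotype relevance network built from sPLS latent
# variates: the association score of a (gene, phenotype) pair accumulates
# the products of their correlations with the X-variates over components,
# and edges keep pairs whose absolute score clears the threshold.

#' Pairwise gene-phenotype association scores from a fitted sPLS model
#'
#' score(i, j) = sum over components h of cor(x_i, t_h) * cor(y_j, t_h),
#' computed on the centred/scaled training data with the model's
#' X-variates. Scores are computed for all genes; genes with zero loading
#' on every component are reported with a \code{selected = FALSE} flag
#' alongside.
#'
#' @param model a fitted \code{\link{fit_spls}} model.
#' @return list: \code{scores} (genes x phenotypes signed matrix),
#'   \code{selected} (per-gene logical, nonzero loading on any component).
#' @export
association_scores <- function(model) {
  gene_cor <- suppressWarnings(stats::cor(model$X_scaled, model$variates_x))
  phen_cor <- suppressWarnings(stats::cor(model$Y_scaled, model$variates_x))
  if (anyNA(gene_cor) || anyNA(phen_cor)) {
    warning("constant column(s): association score set to 0")
    gene_cor[is.na(gene_cor)] <- 0
    phen_cor[is.na(phen_cor)] <- 0
  }
  scores <- tcrossprod(gene_cor, phen_cor)
  dimnames(scores) <- list(rownames(model$u), rownames(model$v))
  list(scores = scores,
       selected = rowSums(abs(model$u)) > 0)
}

#' Threshold association scores into a bipartite network
#'
#' Keeps edges with |score| strictly above the threshold; isolated genes
#' are dropped. Edge sign is the score sign. Scores are not clipped; a
#' magnitude above 1 (possible with several components) is flagged.
#'
#' @param scores genes x phenotypes signed score matrix.
#' @param threshold absolute-score threshold (default 0.65, strict).
#' @param scenario scenario label recorded on every edge ("FDS" or "FIS").
#' @return object of class \code{assoc_network}: \code{edges} (gene,
#'   phenotype, score, sign, scenario), \code{genes} (gene, membership),
#'   \code{phenotypes}, \code{threshold}.
#' @export
build_network <- function(scores, threshold = 0.65, scenario = "FDS") {
  if (threshold <= 0 || threshold > 1) stop("threshold must be in (0, 1]")
  hit <- which(abs(scores) > threshold, arr.ind = TRUE)
  edges <- data.frame(
    gene = rownames(scores)[hit[, 1]],
    phenotype = colnames(scores)[hit[, 2]],
    score = scores[hit],
    stringsAsFactors = FALSE
  )
  edges <- edges[order(edges$gene, edges$phenotype), , drop = FALSE]
  rownames(edges) <- NULL
  edges$sign <- ifelse(edges$score >= 0, "pos", "neg")
  edges$scenario <- rep(scenario, nrow(edges))
  if (any(abs(edges$score) > 1)) {
    warning("association score magnitude above 1 (multi-component sum)")
  }
  gene_ids <- sort(unique(edges$gene))
  genes <- data.frame(gene = gene_ids,
                      membership = rep(scenario, length(gene_ids)),
                      stringsAsFactors = FALSE)
  structure(list(edges = edges, genes = genes,
                 phenotypes = colnames(scores), threshold = threshold),
            class = "assoc_network")
}

#' @export
print.assoc_network <- function(x, ...) {
  cat("gene-phenotype network:", nrow(x$genes), "genes,",
      nrow(x$edges), "edges (|score| >", x$threshold, ")\n")
  if (nrow(x$genes)) {
    print(table(membership = x$genes$membership))
  }
  invisible(x)
}

#' Merge the two scenario networks into one
#'
#' Union of edges; an edge present (same gene, same phenotype) in both
#' scenarios is tagged "both". Gene membership records whether the gene
#' has any edge in only one source network or in both.
#'
#' @param fds,fis \code{assoc_network} objects with identical phenotype
#'   name spaces.
#' @return merged \code{assoc_network} with membership levels
#'   "FDS-only" / "shared" / "FIS-only".
#' @export
merge_networks <- function(fds, fis) {
  if (!setequal(fds$phenotypes, fis$phenotypes)) {
    stop("phenotype name spaces differ between networks")
  }
  key <- function(e) paste(e$gene, e$phenotype, sep = "\r")
  e1 <- fds$edges; e2 <- fis$edges
  in_both <- intersect(key(e1), key(e2))
  e1$scenario[key(e1) %in% in_both] <- "both"
  e2 <- e2[!(key(e2) %in% in_both), , drop = FALSE]
  edges <- rbind(e1, e2)
  edges <- edges[order(edges$gene, edges$phenotype), , drop = FALSE]
  rownames(edges) <- NULL
  g1 <- unique(fds$edges$gene); g2 <- unique(fis$edges$gene)
  genes <- sort(union(g1, g2))
  membership <- ifelse(genes %in% g1 & genes %in% g2, "shared",
                       ifelse(genes %in% g1, "FDS-only", "FIS-only"))
  structure(list(edges = edges,
                 genes = data.frame(gene = genes, membership = membership,
                                    stringsAsFactors = FALSE),
                 phenotypes = fds$phenotypes,
                 threshold = fds$threshold),
            class = "assoc_network")
}

#' Annotate network genes with their ANOVA effect flags
#'
#' Adds to each gene node the three boolean flags displayed on the
#' integrated network: treatment effect under FDS (moderate-stress
#' responsive), treatment effect under FIS (severe-stress responsive) and
#' g*t effect under FIS (genotype-dependent response), plus the full
#' effect-class labels as secondary attributes. Genes absent from an
#' ANOVA table get NA flags with a warning. Idempotent.
#'
#' @param net an \code{assoc_network}.
#' @param fds_anova,fis_anova \code{\link{fit_anova}} results.
#' @return the network with flag columns added to \code{genes}.
#' @export
annotate_nodes <- function(net, fds_anova, fis_anova) {
  g <- net$genes$gene
  pick <- function(fit, effect) {
    v <- fit$flags[match(g, rownames(fit$flags)), effect]
    as.logical(v)
  }
  missing_any <- !(g %in% rownames(fds_anova$flags)) |
    !(g %in% rownames(fis_anova$flags))
  if (any(missing_any)) {
    warning(sum(missing_any), " network gene(s) absent from an ANOVA table")
  }
  net$genes$treatment_fds <- pick(fds_anova, "treatment")
  net$genes$treatment_fis <- pick(fis_anova, "treatment")
  net$genes$gxt_fis <- pick(fis_anova, "gxt")
  net$genes$class_fds <-
    as.character(fds_anova$classes[match(g, names(fds_anova$classes))])
  net$genes$class_fis <-
    as.character(fis_anova$classes[match(g, names(fis_anova$classes))])
  net
}

#' Convert a network to an igraph bipartite graph
#'
#' @param net an \code{assoc_network}.
#' @return an igraph object with node attribute \code{type} ("gene" /
#'   "phenotype") and all recorded node and edge attributes.
#' @export
network_to_igraph <- function(net) {
  nodes <- data.frame(
    name = c(net$genes$gene, net$phenotypes),
    type = c(rep("gene", nrow(net$genes)),
             rep("phenotype", length(net$phenotypes))),
    stringsAsFactors = FALSE
  )
  extra <- setdiff(names(net$genes), "gene")
  for (cl in extra) {
    v <- net$genes[[cl]]
    if (is.logical(v)) v <- as.character(v) # GraphML-safe
    nodes[[cl]] <- c(v, rep(NA_character_, length(net$phenotypes)))
  }
  igraph::graph_from_data_frame(net$edges, directed = FALSE,
                                vertices = nodes)
}

#' Export a network to SIF, GraphML and flat-edge TSV
#'
#' SIF lines read \code{gene assoc_pos|assoc_neg phenotype}; GraphML
#' carries all node and edge attributes; the TSV mirrors the edge table.
#'
#' @param net an \code{assoc_network}.
#' @param path_prefix output prefix; writes \code{<prefix>.sif},
#'   \code{<prefix>.graphml} and \code{<prefix>_edges.tsv}.
#' @param formats subset of c("sif", "graphml", "tsv").
#' @return invisibly, the files written.
#' @export
export_network <- function(net, path_prefix,
                           formats = c("sif", "graphml", "tsv")) {
  bad <- setdiff(formats, c("sif", "graphml", "tsv"))
  if (length(bad)) stop("unknown format(s): ", paste(bad, collapse = ", "))
  written <- character(0)
  if ("sif" %in% formats) {
    f <- paste0(path_prefix, ".sif")
    lines <- if (nrow(net$edges)) {
      paste(net$edges$gene, paste0("assoc_", net$edges$sign),
            net$edges$phenotype)
    } else character(0)
    writeLines(lines, f)
    written <- c(written, f)
  }
  if ("graphml" %in% formats) {
    f <- paste0(path_prefix, ".graphml")
    igraph::write_graph(network_to_igraph(net), f, format = "graphml")
    written <- c(written, f)
  }
  if ("tsv" %in% formats) {
    f <- paste0(path_prefix, "_edges.tsv")
    utils::write.table(net$edges, f, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    written <- c(written, f)
  }
  invisible(written)
}
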