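# Hypergeometric enrichment machinery. Conventions: an urn of N genes of
# which K are "successes"; n genes drawn without replacement; k successes
# observed. The field-transfer test reports both the point probability
# (the statistic the study prints) and the upper-tail p-value.

check_hyper_args <- function(k, N, K, n) {
  if (any(c(k, N, K, n) < 0) || K > N || n > N) {
    stop("invalid hypergeometric parameters: need 0 <= K, n <= N and k >= 0")
  }
  if (k > min(K, n)) stop("k cannot exceed min(K, n)")
}

#' Hypergeometric point probability
#'
#' P(X = k) for X ~ Hypergeometric(N, K, n): the probability of exactly k
#' annotated genes in a draw of n from an urn of N containing K annotated
#' genes. Evaluated in log space.
#'
#' @param k observed successes.
#' @param N urn (universe) size.
#' @param K successes in the urn.
#' @param n draw size.
#' @return P(X = k).
#' @export
hypergeom_pmf <- function(k, N, K, n) {
  check_hyper_args(k, N, K, n)
  exp(stats::dhyper(k, K, N - K, n, log = TRUE))
}

#' Hypergeometric upper-tail probability
#'
#' P(X >= k), the standard one-sided enrichment p-value.
#'
#' @inheritParams hypergeom_pmf
#' @return P(X >= k).
#' @export
hypergeom_upper_tail <- function(k, N, K, n) {
  check_hyper_args(k, N, K, n)
  if (k == 0) return(1)
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Term enrichment of a query gene set against a reference universe
#'
#' One row per annotation term with at least one query hit (and at least
#' \code{min_reference} annotated genes in the universe): raw p is the
#' hypergeometric upper tail, adjusted across tested terms with
#' Benjamini-Yekutieli FDR (valid under arbitrary dependence among
#' terms); the point probability at the observed count is reported
#' alongside.
#'
#' @param query character vector of query gene IDs (subset of universe).
#' @param universe character vector, the reference gene universe.
#' @param annotations data.frame gene_id, term_id (genes outside the
#'   universe are ignored).
#' @param term_names optional data.frame term_id, name.
#' @param min_reference minimum annotated universe genes per tested term
#'   (default 2).
#' @return data.frame term_id, name, query_hits, query_total,
#'   reference_hits, reference_total, pmf, p_raw, p_fdr; ordered by p_raw.
#' @export
term_enrichment <- function(query, universe, annotations,
                            term_names = NULL, min_reference = 2) {
  if (length(query) == 0) {
    warning("empty query set")
    return(data.frame(term_id = character(0), name = character(0),
                      query_hits = integer(0), query_total = integer(0),
                      reference_hits = integer(0), reference_total = integer(0),
                      pmf = numeric(0), p_raw = numeric(0),
                      p_fdr = numeric(0), stringsAsFactors = FALSE))
  }
  if (!all(query %in% universe)) stop("query must be a subset of the universe")
  ann <- annotations[annotations$gene_id %in% universe, , drop = FALSE]
  ann <- unique(ann[, c("gene_id", "term_id")])
  N <- length(unique(universe))
  n <- length(unique(query))
  ref_hits <- table(ann$term_id)
  qry_hits <- table(ann$term_id[ann$gene_id %in% query])
  terms <- names(qry_hits)[qry_hits >= 1]
  terms <- terms[ref_hits[terms] >= min_reference]
  rows <- lapply(terms, function(tm) {
    K <- as.integer(ref_hits[[tm]])
    k <- as.integer(qry_hits[[tm]])
    data.frame(term_id = tm,
               query_hits = k, query_total = n,
               reference_hits = K, reference_total = N,
               pmf = hypergeom_pmf(k, N, K, n),
               p_raw = hypergeom_upper_tail(k, N, K, n),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(term_id = character(0), query_hits = integer(0),
                      query_total = integer(0), reference_hits = integer(0),
                      reference_total = integer(0), pmf = numeric(0),
                      p_raw = numeric(0), stringsAsFactors = FALSE)
  }
  out$p_fdr <- stats::p.adjust(out$p_raw, method = "BY")
  out$name <- if (!is.null(term_names)) {
    term_names$name[match(out$term_id, term_names$term_id)]
  } else NA_character_
  out <- out[order(out$p_raw, out$term_id), c(
    "term_id", "name", "query_hits", "query_total", "reference_hits",
    "reference_total", "pmf", "p_raw", "p_fdr")]
  rownames(out) <- NULL
  out
}

#' Trait-link enrichment of an independent gene list in the network
#'
#' Tests whether an independently derived (e.g. field) gene list is
#' enriched in network genes linked to one phenotypic trait. The universe
#' N is the merged network's gene set, K the genes with at least one edge
#' to the trait, n the field genes present in the network and k their
#' overlap with the trait-linked genes. Reports the hypergeometric point
#' probability (the study's printed statistic) and the upper-tail
#' p-value.
#'
#' @param field_genes character vector of independent gene IDs.
#' @param net a merged \code{assoc_network}.
#' @param trait phenotype name (must be one of the network's phenotypes).
#' @return one-row data.frame trait, N, K, n, k, pmf, p_upper.
#' @export
trait_link_enrichment <- function(field_genes, net, trait) {
  if (!trait %in% net$phenotypes) stop("unknown trait: ", trait)
  network_genes <- net$genes$gene
  N <- length(network_genes)
  linked <- unique(net$edges$gene[net$edges$phenotype == trait])
  K <- length(linked)
  in_net <- intersect(unique(field_genes), network_genes)
  n <- length(in_net)
  if (n == 0) stop("no field gene maps into the network: test undefined")
  k <- length(intersect(in_net, linked))
  data.frame(trait = trait, N = N, K = K, n = n, k = k,
             pmf = hypergeom_pmf(k, N, K, n),
             p_upper = hypergeom_upper_tail(k, N, K, n),
             stringsAsFactors = FALSE)
}

#' Induced subnetwork on an independent gene list
#'
#' Restricts a network to the genes of an external list (e.g. the field
#' drought-regulated genes), keeping all node and edge attributes and
#' scenario tags.
#'
#' @param field_genes character vector of gene IDs.
#' @param net an \code{assoc_network}.
#' @return an \code{assoc_network} on the intersection.
#' @export
field_subnetwork <- function(field_genes, net) {
  keep <- net$genes$gene %in% field_genes
  if (!any(keep)) warning("field list does not intersect the network")
  out <- net
  out$genes <- net$genes[keep, , drop = FALSE]
  out$edges <- net$edges[net$edges$gene %in% net$genes$gene[keep], ,
                         drop = FALSE]
  rownames(out$genes) <- rownames(out$edges) <- NULL
  out
}
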