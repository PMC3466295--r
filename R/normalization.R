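#' Block-centre an expression matrix
#'
#' For every gene, subtracts the mean intensity within each experimental
#' block and adds back the gene's global mean across all samples, removing
#' block shifts while preserving each gene's global mean exactly. A block
#' with a single sample is allowed (its value maps to the gene's global
#' mean).
#'
#' @param expr genes x samples matrix (log2 intensities).
#' @param block character/factor vector, one block label per sample.
#' @return matrix of the same shape.
#' @export
block_center <- function(expr, block) {
  if (length(block) != ncol(expr)) {
    stop("need one block label per sample")
  }
  if (anyNA(block)) stop("unknown (missing) block label")
  block <- as.character(block)
  global <- rowMeans(expr)
  out <- expr
  for (b in unique(block)) {
    j <- which(block == b)
    out[, j] <- expr[, j, drop = FALSE] -
      rowMeans(expr[, j, drop = FALSE]) + global
  }
  out
}

#' Quantile-normalize an expression matrix
#'
#' Forces every sample onto the common reference distribution (the
#' row-wise mean of the sorted columns); tied values within a sample
#' receive the mean of the reference values at their tied ranks. Delegates
#' to \code{limma::normalizeQuantiles}.
#'
#' @param expr genes x samples matrix.
#' @return matrix of the same shape.
#' @export
quantile_normalize <- function(expr) {
  if (ncol(expr) < 2) stop("quantile normalization needs at least 2 samples")
  out <- limma::normalizeQuantiles(expr, ties = TRUE)
  dimnames(out) <- dimnames(expr)
  out
}

#' Run the post-summarization normalization used by the pipeline
#'
#' Block centering (per gene, with global-mean restoration) followed by
#' quantile normalization, optionally per scenario.
#'
#' @param expr genes x samples matrix.
#' @param samples sample sheet with columns plant_id, block, scenario
#'   matching \code{colnames(expr)}.
#' @param per_scenario normalize each scenario separately? Default FALSE
#'   (joint across all samples).
#' @return normalized matrix, same shape and dimnames.
#' @export
normalize_expression <- function(expr, samples, per_scenario = FALSE) {
  stopifnot(identical(colnames(expr), samples$plant_id))
  if (!per_scenario) {
    return(quantile_normalize(block_center(expr, samples$block)))
  }
  out <- expr
  for (sc in unique(samples$scenario)) {
    j <- which(samples$scenario == sc)
    out[, j] <- quantile_normalize(
      block_center(expr[, j, drop = FALSE], samples$block[j])
    )
  }
  out
}
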