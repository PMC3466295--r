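#' Write an expression matrix as TSV
#'
#' First column \code{gene_id}, remaining columns one per sample.
#'
#' @param expr genes x samples numeric matrix with dimnames.
#' @param path output file.
#' @export
write_expression_tsv <- function(expr, path) {
  df <- data.frame(gene_id = rownames(expr), expr, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Read an expression matrix from TSV
#'
#' @param path TSV with first column gene IDs, header = sample IDs.
#' @return genes x samples numeric matrix.
#' @export
read_expression_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  ids <- df[[1]]
  if (anyDuplicated(ids)) stop("duplicate gene IDs in expression file")
  m <- as.matrix(df[, -1, drop = FALSE])
  if (anyNA(m)) stop("missing values in expression matrix")
  rownames(m) <- ids
  m
}

#' Read a sample sheet
#'
#' @param path CSV with columns plant_id (or sample), genotype, treatment,
#'   block, scenario.
#' @return data.frame with a \code{plant_id} column.
#' @export
read_sample_sheet <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"plant_id" %in% names(df) && "sample" %in% names(df)) {
    names(df)[names(df) == "sample"] <- "plant_id"
  }
  need <- c("plant_id", "genotype", "treatment", "block", "scenario")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("sample sheet lacks columns: ", paste(miss, collapse = ", "))
  df
}

#' Read a gene list (one ID per line)
#' @param path text file.
#' @return character vector.
#' @export
read_gene_list <- function(path) {
  x <- readLines(path)
  x[nzchar(trimws(x))]
}

#' Read a gene-to-term annotation table
#' @param path two-column TSV (gene_id, term_id), no header required; a
#'   header line named gene_id/term_id is tolerated.
#' @return data.frame gene_id, term_id.
#' @export
read_annotations <- function(path) {
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (identical(tolower(as.character(df[1, 1])), "gene_id")) {
    df <- df[-1, , drop = FALSE]
  }
  stats::setNames(df[, 1:2], c("gene_id", "term_id"))
}
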