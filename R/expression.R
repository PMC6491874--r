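#' Validate a genes-by-samples expression matrix
#'
#' Expression data are represented throughout the package as a plain numeric
#' matrix with genes in rows (`rownames` = gene identifiers) and samples in
#' columns (`colnames` = sample identifiers). This helper enforces the
#' container invariants: both dimension names present and free of duplicates.
#'
#' @param x A numeric matrix or an object coercible to one.
#' @return The validated matrix.
#' @export
as_expression_matrix <- function(x) {
  x <- as.matrix(x)
  if (!is.numeric(x)) stop("expression values must be numeric")
  if (is.null(rownames(x)) || is.null(colnames(x)))
    stop("expression matrix requires gene rownames and sample colnames")
  if (anyDuplicated(rownames(x)) > 0) stop("duplicate gene identifiers")
  if (anyDuplicated(colnames(x)) > 0) stop("duplicate sample identifiers")
  x
}

#' Read a tab-separated expression matrix
#'
#' Expects the TCGA level-3 style layout: first column gene identifiers,
#' header row of sample identifiers, tab-separated numeric values.
#'
#' @param path Path to the tab-separated file.
#' @return A genes-by-samples numeric matrix.
#' @export
read_expression <- function(path) {
  df <- utils::read.delim(path, row.names = 1, check.names = FALSE)
  as_expression_matrix(as.matrix(df))
}

#' Write an expression matrix as tab-separated text
#'
#' @param mat A genes-by-samples matrix.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_expression <- function(mat, path) {
  mat <- as_expression_matrix(mat)
  df <- data.frame(gene_id = rownames(mat), mat, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a clinical table
#'
#' Tab-separated file with columns `sample_id`, `time_days` and `event`
#' (1 = death observed, 0 = censored).
#'
#' @param path Path to the tab-separated file.
#' @return A data frame with one row per sample.
#' @export
read_clinical <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  validate_clinical(df)
}

#' Validate a clinical table
#'
#' @param clinical Data frame with columns `sample_id`, `time_days`, `event`.
#' @return The validated data frame.
#' @export
validate_clinical <- function(clinical) {
  need <- c("sample_id", "time_days", "event")
  if (!all(need %in% names(clinical)))
    stop("clinical table requires columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(clinical$sample_id) > 0)
    stop("duplicate sample identifiers in clinical table")
  if (any(!is.finite(clinical$time_days)) || any(clinical$time_days < 0))
    stop("survival times must be finite and non-negative")
  if (!all(clinical$event %in% c(0, 1)))
    stop("event indicator must be 0 (censored) or 1 (death)")
  clinical
}

#' Intersect an expression matrix with a clinical table
#'
#' Samples present in only one of the two inputs are dropped with a warning.
#'
#' @param mat Genes-by-samples matrix.
#' @param clinical Clinical data frame.
#' @return A list with elements `expression` and `clinical`, restricted to the
#'   shared samples (expression column order).
#' @export
align_samples <- function(mat, clinical) {
  mat <- as_expression_matrix(mat)
  clinical <- validate_clinical(clinical)
  shared <- intersect(colnames(mat), clinical$sample_id)
  if (length(shared) == 0) stop("no shared samples between expression and clinical data")
  dropped <- setdiff(union(colnames(mat), clinical$sample_id), shared)
  if (length(dropped) > 0)
    warning(length(dropped), " sample(s) present in only one input were dropped")
  list(
    expression = mat[, shared, drop = FALSE],
    clinical = clinical[match(shared, clinical$sample_id), , drop = FALSE]
  )
}
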