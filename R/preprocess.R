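#' Resolve missing values in a raw expression matrix
#'
#' Genes with more than `max_missing` missing entries are dropped; remaining
#' missing entries are imputed with the gene's mean across samples. Run this
#' before [quantile_normalize()], which requires finite values.
#'
#' @param mat Genes-by-samples matrix, possibly containing `NA`.
#' @param max_missing Maximum tolerated fraction of missing entries per gene
#'   (default 0.2).
#' @return A matrix with finite values only.
#' @export
resolve_missing <- function(mat, max_missing = 0.2) {
  mat <- as_expression_matrix(mat)
  miss <- rowMeans(!is.finite(mat))
  dropped <- miss > max_missing
  if (any(dropped)) {
    warning(sum(dropped), " gene(s) dropped (> ", 100 * max_missing, "% missing)")
    mat <- mat[!dropped, , drop = FALSE]
  }
  bad <- !is.finite(mat)
  if (any(bad)) {
    means <- rowMeans(mat, na.rm = TRUE)
    mat[bad] <- means[row(mat)[bad]]
  }
  mat
}

#' Quantile normalization
#'
#' Forces every sample column to share one value distribution: the mean
#' quantile profile across columns (Bolstad's procedure, with tied values
#' receiving the mean of the row means at their tied ranks). Delegates to
#' [limma::normalizeQuantiles()].
#'
#' @param mat Genes-by-samples matrix with finite values.
#' @return Normalized matrix with the same dimension names.
#' @export
quantile_normalize <- function(mat) {
  mat <- as_expression_matrix(mat)
  if (any(!is.finite(mat)))
    stop("non-finite values: run resolve_missing() first")
  if (ncol(mat) < 2) {
    warning("single-sample matrix: quantile normalization is a no-op")
    return(mat)
  }
  out <- limma::normalizeQuantiles(mat, ties = TRUE)
  dimnames(out) <- dimnames(mat)
  out
}

#' Discretize prognosis at a survival horizon
#'
#' Patients who died within the horizon are labelled high-risk; patients with
#' total survival beyond the horizon (regardless of event status) low-risk;
#' patients censored within the horizon carry no usable label and are
#' excluded.
#'
#' @param clinical Clinical data frame (`sample_id`, `time_days`, `event`).
#' @param horizon_days Prognosis horizon in days; default three years
#'   (365.25 x 3 = 1095.75).
#' @return An object of class `prognosis_labels`: list with `labels` (named
#'   character vector, values `"high_risk"`/`"low_risk"`), `excluded`
#'   (character vector of sample ids) and `horizon_days`.
#' @export
discretize_prognosis <- function(clinical, horizon_days = 365.25 * 3) {
  if (!is.numeric(horizon_days) || horizon_days <= 0)
    stop("horizon_days must be a positive number")
  clinical <- validate_clinical(clinical)
  high <- clinical$event == 1 & clinical$time_days <= horizon_days
  low <- clinical$time_days > horizon_days
  excluded <- clinical$event == 0 & clinical$time_days <= horizon_days
  labels <- ifelse(high, "high_risk", "low_risk")
  names(labels) <- clinical$sample_id
  structure(
    list(
      labels = labels[high | low],
      excluded = clinical$sample_id[excluded],
      horizon_days = horizon_days
    ),
    class = "prognosis_labels"
  )
}

#' @export
print.prognosis_labels <- function(x, ...) {
  cat("Prognosis labels at horizon", x$horizon_days, "days:\n")
  cat("  high_risk:", sum(x$labels == "high_risk"),
      " low_risk:", sum(x$labels == "low_risk"),
      " excluded:", length(x$excluded), "\n")
  invisible(x)
}
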