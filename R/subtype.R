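#' Select high-variance feature genes
#'
#' Returns the genes with the largest sample variance, ordered by decreasing
#' variance. By default the top 15% are taken, the usual choice for
#' clustering features on expression arrays.
#'
#' @param mat Genes-by-samples matrix.
#' @param fraction Fraction of genes to keep, in (0, 1]. `ceiling(fraction *
#'   G)` genes are returned.
#' @return Character vector of gene identifiers, decreasing variance order.
#' @export
select_variance_features <- function(mat, fraction = 0.15) {
  mat <- as_expression_matrix(mat)
  if (!is.numeric(fraction) || fraction <= 0 || fraction > 1)
    stop("fraction must be in (0, 1]")
  if (ncol(mat) < 2) stop("variance requires >= 2 samples")
  v <- rowSums((mat - rowMeans(mat))^2) / (ncol(mat) - 1)
  ord <- order(-v, rownames(mat))
  rownames(mat)[ord][seq_len(ceiling(fraction * nrow(mat)))]
}

#' Dunn index of a clustering
#'
#' Ratio of the minimal between-cluster separation to the maximal
#' within-cluster spread: the minimum over cluster pairs of the Euclidean
#' distance between cluster centroids, divided by the maximum over clusters
#' of the mean pairwise distance among that cluster's samples. Higher values
#' indicate compact, well-separated clusters.
#'
#' @param points Samples-by-features numeric matrix.
#' @param labels Cluster assignment, one per row of `points`.
#' @return The Dunn index (a positive real).
#' @export
dunn_index <- function(points, labels) {
  points <- as.matrix(points)
  labels <- as.factor(labels)
  if (nrow(points) != length(labels)) stop("one label per point required")
  sizes <- table(labels)
  if (length(sizes) < 2) stop("need >= 2 clusters")
  if (any(sizes == 0)) stop("empty cluster")
  lev <- levels(labels)
  cent <- vapply(lev, function(l) {
    colMeans(points[labels == l, , drop = FALSE])
  }, numeric(ncol(points)))
  centroids <- if (is.matrix(cent)) t(cent) else matrix(cent, ncol = 1)
  # mean pairwise distance within each cluster (0 for singletons)
  spread <- vapply(lev, function(l) {
    p <- points[labels == l, , drop = FALSE]
    if (nrow(p) < 2) return(0)
    mean(stats::dist(p))
  }, numeric(1))
  if (max(spread) == 0)
    stop("all clusters are singletons: Dunn index undefined")
  separation <- min(stats::dist(centroids))
  separation / max(spread)
}

#' Discover expression subtypes by K-means with Dunn-index model selection
#'
#' Clusters samples in the space of high-variance feature genes with K-means
#' (Euclidean distance, best of `restarts` random initializations per K) for
#' each K in `k_min:k_max`, scores each clustering with the Dunn index, and
#' keeps the K with the highest index (ties broken toward the smaller K).
#'
#' @param mat Genes-by-samples matrix (typically quantile-normalized).
#' @param fraction Fraction of genes kept as clustering features
#'   (see [select_variance_features()]); default 0.15.
#' @param k_min,k_max Range of cluster counts to evaluate (defaults 2 and 6).
#' @param restarts Random initializations per K (default 25).
#' @param seed Optional integer seed for reproducibility.
#' @return An object of class `subtype_model`: list with `feature_genes`,
#'   `k`, `centroids` (k x features matrix), `assignments` (named integer
#'   vector over training samples), `dunn_by_k` and `withinss_by_k`.
#' @export
fit_subtypes <- function(mat, fraction = 0.15, k_min = 2, k_max = 6,
                         restarts = 25, seed = NULL) {
  mat <- as_expression_matrix(mat)
  if (k_min < 2 || k_max < k_min) stop("require 2 <= k_min <= k_max")
  if (k_max >= ncol(mat)) stop("k_max must be smaller than the sample count")
  features <- select_variance_features(mat, fraction)
  x <- t(mat[features, , drop = FALSE])
  if (!is.null(seed)) set.seed(seed)
  ks <- k_min:k_max
  dunn <- numeric(length(ks))
  withinss <- numeric(length(ks))
  fits <- vector("list", length(ks))
  for (i in seq_along(ks)) {
    fit <- NULL
    for (attempt in 1:5) {
      fit <- tryCatch(
        stats::kmeans(x, centers = ks[i], nstart = restarts, iter.max = 100),
        error = function(e) NULL
      )
      if (!is.null(fit) && length(unique(fit$cluster)) == ks[i]) break
      fit <- NULL
    }
    if (is.null(fit)) stop("K-means degenerate for K = ", ks[i])
    fits[[i]] <- fit
    dunn[i] <- dunn_index(x, fit$cluster)
    withinss[i] <- fit$tot.withinss
  }
  names(dunn) <- names(withinss) <- as.character(ks)
  best <- which.max(dunn)
  fit <- fits[[best]]
  assignments <- fit$cluster
  names(assignments) <- colnames(mat)
  centroids <- fit$centers
  colnames(centroids) <- features
  structure(
    list(
      feature_genes = features,
      k = ks[best],
      centroids = centroids,
      assignments = assignments,
      dunn_by_k = dunn,
      withinss_by_k = withinss
    ),
    class = "subtype_model"
  )
}

#' @export
print.subtype_model <- function(x, ...) {
  cat("Subtype model:", x$k, "subtypes over", length(x$feature_genes),
      "feature genes\n")
  cat("Dunn index by K:\n")
  print(round(x$dunn_by_k, 4))
  cat("Subtype sizes:", paste(table(x$assignments), collapse = ", "), "\n")
  invisible(x)
}

#' Assign a sample to its nearest subtype centroid
#'
#' Feature genes absent from the sample vector (or `NA`) are dropped from
#' both the vector and the centroids for that sample's distance computation.
#' Ties go to the lowest subtype index.
#'
#' @param model A `subtype_model`.
#' @param sample_vector Named numeric vector of expression values (names are
#'   gene identifiers) or an unnamed vector already ordered like
#'   `model$feature_genes`.
#' @return Integer subtype index in `1:model$k`.
#' @export
assign_subtype <- function(model, sample_vector) {
  if (is.null(names(sample_vector))) {
    if (length(sample_vector) != length(model$feature_genes))
      stop("unnamed sample vector must match the feature gene count")
    v <- sample_vector
  } else {
    v <- sample_vector[model$feature_genes]
  }
  keep <- is.finite(v)
  if (!any(keep)) stop("no feature genes present in the sample")
  d <- sqrt(colSums((t(model$centroids[, keep, drop = FALSE]) - v[keep])^2))
  as.integer(which.min(d))
}

#' Assign every column of a matrix to a subtype
#'
#' @param model A `subtype_model`.
#' @param mat Genes-by-samples matrix.
#' @return Named integer vector of subtype indices.
#' @export
assign_subtypes <- function(model, mat) {
  mat <- as_expression_matrix(mat)
  vapply(colnames(mat), function(s) assign_subtype(model, mat[, s]), integer(1))
}
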