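#' Pearson correlation between two expression profiles
#'
#' Sample correlation (n - 1 denominator). Constant vectors have no defined
#' correlation; such pairs are flagged with `NA` and never become network
#' edges.
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @return Correlation in `[-1, 1]`, or `NA` (with a warning) if either
#'   vector is constant.
#' @export
pearson <- function(x, y) {
  if (length(x) != length(y)) stop("vectors must have equal length")
  if (length(x) < 3) stop("need >= 3 paired observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("constant vector: correlation undefined")
    return(NA_real_)
  }
  stats::cor(x, y)
}

#' Build a rank-based gene co-expression network
#'
#' Pearson correlations are computed among all gene pairs; each gene selects
#' its `n_neighbors` most related genes, and the union of all selections
#' forms an undirected graph (an edge exists if either endpoint selected the
#' other). "Most related" defaults to largest absolute correlation, so strong
#' negative co-expression also links genes; `rank_by = "signed"` ranks by the
#' signed coefficient instead. Selection ties are broken by gene identifier
#' order. Genes with zero variance are excluded (their correlation is
#' undefined).
#'
#' @param mat Genes-by-samples matrix (the samples of one subtype).
#' @param n_neighbors Neighbors selected per gene (default 4).
#' @param rank_by `"absolute"` (default) or `"signed"`.
#' @return An object of class `coexpression_network`: list with `graph`
#'   (an [igraph][igraph::graph_from_data_frame] with edge attribute
#'   `weight` = Pearson r), `selections` (per-gene neighbor lists),
#'   `n_neighbors`, `rank_by`, `n_edges` (deduplicated) and
#'   `raw_selection_count` (genes x n_neighbors, before deduplication).
#' @export
build_rank_network <- function(mat, n_neighbors = 4,
                               rank_by = c("absolute", "signed")) {
  rank_by <- match.arg(rank_by)
  mat <- as_expression_matrix(mat)
  if (n_neighbors < 1) stop("n_neighbors must be >= 1")
  v <- rowSums((mat - rowMeans(mat))^2)
  if (any(v == 0)) {
    warning(sum(v == 0), " zero-variance gene(s) excluded from the network")
    mat <- mat[v > 0, , drop = FALSE]
  }
  genes <- rownames(mat)
  g_count <- length(genes)
  if (g_count < n_neighbors + 1)
    stop("need at least n_neighbors + 1 genes with nonzero variance")
  cmat <- stats::cor(t(mat))
  key <- if (rank_by == "absolute") abs(cmat) else cmat
  diag(key) <- -Inf
  selections <- lapply(seq_len(g_count), function(i) {
    ord <- order(-key[i, ], genes)
    genes[ord][seq_len(n_neighbors)]
  })
  names(selections) <- genes
  from <- rep(genes, each = n_neighbors)
  to <- unlist(selections, use.names = FALSE)
  a <- pmin(from, to)
  b <- pmax(from, to)
  keep <- !duplicated(paste(a, b, sep = "\r"))
  edges <- data.frame(a = a[keep], b = b[keep],
                      weight = cmat[cbind(a[keep], b[keep])],
                      stringsAsFactors = FALSE)
  graph <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                         vertices = genes)
  structure(
    list(
      graph = graph,
      selections = selections,
      n_neighbors = n_neighbors,
      rank_by = rank_by,
      n_edges = nrow(edges),
      raw_selection_count = g_count * n_neighbors
    ),
    class = "coexpression_network"
  )
}

#' @export
print.coexpression_network <- function(x, ...) {
  cat("Co-expression network:", igraph::vcount(x$graph), "genes,",
      x$n_edges, "edges (", x$raw_selection_count, "raw selections),",
      "top-", x$n_neighbors, " by ", x$rank_by, " correlation\n", sep = "")
  invisible(x)
}

#' Write a network edge list as tab-separated text
#'
#' @param network A `coexpression_network`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_edge_list <- function(network, path) {
  el <- igraph::as_data_frame(network$graph, what = "edges")
  names(el) <- c("gene_a", "gene_b", "r")
  utils::write.table(el, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.as_igraph <- function(network) {
  g <- if (inherits(network, "coexpression_network")) network$graph else network
  if (!igraph::is_igraph(g)) stop("expected a coexpression_network or igraph")
  if (is.null(igraph::V(g)$name))
    igraph::V(g)$name <- as.character(seq_len(igraph::vcount(g)))
  igraph::simplify(g, edge.attr.comb = "first")
}

#' Power-law fit of a network degree distribution
#'
#' Least-squares line fit of log10 P(k) against log10 k over the observed
#' degrees with nonzero frequency (zero-degree nodes excluded). Used to check
#' the scale-free character of the co-expression networks.
#'
#' @param network A `coexpression_network` or igraph object with >= 2
#'   distinct positive degrees.
#' @return List with `correlation` (absolute Pearson correlation of the
#'   log-log points), `r_square` of the fit, and the fitted `slope` and
#'   `intercept`.
#' @export
power_law_fit <- function(network) {
  g <- .as_igraph(network)
  deg <- igraph::degree(g)
  deg <- deg[deg > 0]
  tab <- table(deg)
  if (length(tab) < 2) stop("need >= 2 distinct degrees")
  k <- as.numeric(names(tab))
  p <- as.numeric(tab) / sum(tab)
  lk <- log10(k)
  lp <- log10(p)
  fit <- stats::lm(lp ~ lk)
  # R^2 computed directly: summary.lm warns on exact fits, which are a
  # legitimate input here (e.g. frequencies exactly on a power law)
  r2 <- 1 - sum(stats::residuals(fit)^2) / sum((lp - mean(lp))^2)
  list(
    correlation = abs(stats::cor(lk, lp)),
    r_square = r2,
    slope = unname(stats::coef(fit)[2]),
    intercept = unname(stats::coef(fit)[1])
  )
}
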