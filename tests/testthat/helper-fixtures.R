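# Shared fixtures and independent oracles, built in code.

# small genes-by-samples matrix with names
toy_matrix <- function(values, genes = NULL, samples = NULL) {
  m <- as.matrix(values)
  rownames(m) <- genes %||% sprintf("g%02d", seq_len(nrow(m)))
  colnames(m) <- samples %||% sprintf("s%02d", seq_len(ncol(m)))
  m
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# brute-force Pearson per the n-1 / standardized-product formula
pearson_bruteforce <- function(x, y) {
  n <- length(x)
  sum(((x - mean(x)) / sd(x)) * ((y - mean(y)) / sd(y))) / (n - 1)
}

# exhaustive concordant-pair AUC (ties count one half)
auc_bruteforce <- function(labels, scores) {
  pos <- which(labels == "high_risk")
  neg <- which(labels == "low_risk")
  total <- 0
  for (i in pos) for (j in neg) {
    total <- total + (scores[i] > scores[j]) + 0.5 * (scores[i] == scores[j])
  }
  total / (length(pos) * length(neg))
}

# hypergeometric upper tail by direct term-by-term enumeration
hyper_enum <- function(N, M, n, m) {
  i <- m:min(M, n)
  sum(choose(M, i) * choose(N - M, n - i)) / choose(N, n)
}

# two-group log-rank by the observed-minus-expected sums over event times
logrank_oracle <- function(times, events, group) {
  group <- as.integer(as.factor(group))
  o_minus_e <- 0
  v <- 0
  for (t in sort(unique(times[events == 1]))) {
    at_risk <- times >= t
    n_tot <- sum(at_risk)
    n1 <- sum(at_risk & group == 1)
    d_tot <- sum(times == t & events == 1)
    d1 <- sum(times == t & events == 1 & group == 1)
    e1 <- d_tot * n1 / n_tot
    o_minus_e <- o_minus_e + d1 - e1
    if (n_tot > 1)
      v <- v + d_tot * (n1 / n_tot) * (1 - n1 / n_tot) *
        (n_tot - d_tot) / (n_tot - 1)
  }
  o_minus_e^2 / v
}

# planted-clique graph: ER background with a clique over `clique_size` nodes
planted_clique_graph <- function(n_nodes = 100, p = 0.03, clique_size = 8) {
  g <- igraph::sample_gnp(n_nodes, p)
  igraph::V(g)$name <- sprintf("v%03d", seq_len(n_nodes))
  members <- sample(seq_len(n_nodes), clique_size)
  pairs <- t(combn(members, 2))
  g <- igraph::add_edges(g, t(pairs))
  g <- igraph::simplify(g)
  list(graph = g, clique = igraph::V(g)$name[members])
}

# three well-separated Gaussian blobs in `d` dimensions
blob_matrix <- function(n_per = 20, d = 5, sep = 10) {
  centers <- diag(sep, 3, d)
  x <- do.call(rbind, lapply(1:3, function(i)
    matrix(rnorm(n_per * d, mean = rep(centers[i, ], each = n_per)),
           nrow = n_per)))
  truth <- rep(1:3, each = n_per)
  list(points = x, truth = truth)
}

# labels helper
make_labels <- function(samples, labels) stats::setNames(labels, samples)
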