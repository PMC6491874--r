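# MCODE dense-cluster mining (Bader & Hogue style), reimplemented on igraph
# primitives: k-core-based vertex weighting, seeded greedy expansion,
# 2-core post-filter, haircut (remove singly-connected vertices), optional
# fluff. Communities are vertex-disjoint.

#' MCODE vertex weights
#'
#' The weight of a vertex is `k_max * density` of the highest k-core of its
#' closed neighborhood (the vertex plus its direct neighbors), where density
#' of a subgraph with n' vertices and E' edges is `2 E' / (n' (n' - 1))`.
#' Isolated vertices weigh 0.
#'
#' @param network A `coexpression_network` or igraph object.
#' @return Named numeric vector of weights, one per vertex.
#' @export
mcode_vertex_weights <- function(network) {
  g <- .as_igraph(network)
  if (igraph::vcount(g) == 0) return(stats::setNames(numeric(0), character(0)))
  egos <- igraph::make_ego_graph(g, order = 1)
  w <- vapply(egos, function(h) {
    n <- igraph::vcount(h)
    if (n < 2) return(0)
    core <- igraph::coreness(h)
    kmax <- max(core)
    if (kmax == 0) return(0)
    sub <- igraph::induced_subgraph(h, which(core == kmax))
    ns <- igraph::vcount(sub)
    if (ns < 2) return(0)
    kmax * 2 * igraph::ecount(sub) / (ns * (ns - 1))
  }, numeric(1))
  stats::setNames(w, igraph::V(g)$name)
}

#' Mine dense communities with the MCODE procedure
#'
#' Stages: (1) vertex weighting via [mcode_vertex_weights()]; (2) greedy
#' seeded expansion from the highest-weight unassigned vertex, breadth-first,
#' including unassigned neighbors whose weight exceeds
#' `seed_weight * (1 - node_score_cutoff)`; (3) post-processing: complexes
#' lacking a `k_core`-core are discarded, the haircut removes
#' singly-connected vertices, and the optional fluff step adds unassigned
#' boundary vertices whose closed-neighborhood density exceeds
#' `fluff_density`. Communities are ranked by score = density x size
#' (ties by member identifier order) and are vertex-disjoint.
#'
#' @param network A `coexpression_network` or igraph object.
#' @param node_score_cutoff Expansion tolerance in `[0, 1)` (default 0.2).
#' @param k_core Minimum core a complex must contain (default 2).
#' @param haircut Remove singly-connected vertices (default `TRUE`).
#' @param fluff Add dense boundary vertices (default `FALSE`).
#' @param fluff_density Density threshold for fluff (default 0.2).
#' @param max_depth Maximum breadth-first expansion depth (default 100).
#' @return List of `community` objects, each a list with `members` (sorted
#'   gene identifiers), `score`, `density` and `rank`.
#' @export
mcode_find_communities <- function(network, node_score_cutoff = 0.2,
                                   k_core = 2, haircut = TRUE, fluff = FALSE,
                                   fluff_density = 0.2, max_depth = 100) {
  if (node_score_cutoff < 0 || node_score_cutoff >= 1)
    stop("node_score_cutoff must be in [0, 1)")
  g <- .as_igraph(network)
  nv <- igraph::vcount(g)
  if (nv == 0) return(list())
  w <- mcode_vertex_weights(g)
  names_v <- igraph::V(g)$name
  adj <- igraph::as_adj_list(g)
  adj <- lapply(adj, as.integer)
  seed_order <- order(-w, names_v)
  assigned <- logical(nv)
  complexes <- list()
  for (seed in seed_order) {
    if (assigned[seed]) next
    threshold <- w[seed] * (1 - node_score_cutoff)
    in_complex <- logical(nv)
    examined <- logical(nv)
    in_complex[seed] <- examined[seed] <- TRUE
    frontier <- seed
    depth <- 0
    while (length(frontier) > 0 && depth < max_depth) {
      nbr <- unique(unlist(adj[frontier], use.names = FALSE))
      nbr <- nbr[!examined[nbr] & !assigned[nbr]]
      examined[nbr] <- TRUE
      keep <- nbr[w[nbr] > threshold]
      in_complex[keep] <- TRUE
      frontier <- keep
      depth <- depth + 1
    }
    members <- which(in_complex)
    if (length(members) < 2) next
    sub <- igraph::induced_subgraph(g, members)
    core <- igraph::coreness(sub)
    if (max(core) < k_core) next
    if (haircut) {
      keep <- core >= 2
      if (sum(keep) < 2) next
      sub <- igraph::induced_subgraph(sub, which(keep))
    }
    if (fluff) {
      member_ids <- match(igraph::V(sub)$name, names_v)
      boundary <- unique(unlist(adj[member_ids], use.names = FALSE))
      boundary <- boundary[!assigned[boundary] &
                             !(boundary %in% member_ids)]
      if (length(boundary) > 0) {
        dens <- vapply(boundary, function(v) {
          nb <- c(v, adj[[v]])
          h <- igraph::induced_subgraph(g, nb)
          ns <- igraph::vcount(h)
          if (ns < 2) 0 else 2 * igraph::ecount(h) / (ns * (ns - 1))
        }, numeric(1))
        add <- boundary[dens > fluff_density]
        if (length(add) > 0)
          sub <- igraph::induced_subgraph(g, c(member_ids, add))
      }
    }
    final <- match(igraph::V(sub)$name, names_v)
    assigned[final] <- TRUE
    ns <- igraph::vcount(sub)
    density <- 2 * igraph::ecount(sub) / (ns * (ns - 1))
    complexes[[length(complexes) + 1]] <- list(
      members = sort(igraph::V(sub)$name),
      score = density * ns,
      density = density
    )
  }
  if (length(complexes) == 0) return(list())
  first_member <- vapply(complexes, function(cx) cx$members[1], character(1))
  scores <- vapply(complexes, function(cx) cx$score, numeric(1))
  ord <- order(-scores, first_member)
  complexes <- complexes[ord]
  for (i in seq_along(complexes)) {
    complexes[[i]]$rank <- i
    class(complexes[[i]]) <- "community"
  }
  complexes
}

#' @export
print.community <- function(x, ...) {
  cat("Community rank ", x$rank, ": ", length(x$members),
      " genes, score ", round(x$score, 3), "\n", sep = "")
  invisible(x)
}

#' Write communities as tab-separated text
#'
#' One community per line: rank, score, size, comma-separated members.
#'
#' @param communities List of `community` objects.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_communities <- function(communities, path) {
  df <- data.frame(
    rank = vapply(communities, function(cx) cx$rank, integer(1)),
    score = vapply(communities, function(cx) cx$score, numeric(1)),
    size = vapply(communities, function(cx) length(cx$members), integer(1)),
    members = vapply(communities, function(cx)
      paste(cx$members, collapse = ","), character(1))
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read communities written by [write_communities()]
#'
#' @param path Path to the tab-separated community file.
#' @return List of `community` objects.
#' @export
read_communities <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  lapply(seq_len(nrow(df)), function(i) {
    structure(list(
      members = strsplit(df$members[i], ",", fixed = TRUE)[[1]],
      score = df$score[i],
      density = NA_real_,
      rank = df$rank[i]
    ), class = "community")
  })
}
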