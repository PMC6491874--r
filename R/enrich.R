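# Hypergeometric drug-target screening against community gene sets, and
# enrichment of disease-indicated drugs among the screened drugs.

#' Hypergeometric upper-tail p-value
#'
#' Probability of observing at least `m` successes when drawing `n` items
#' without replacement from a universe of `N` items containing `M`
#' successes.
#'
#' @param N Universe size.
#' @param M Successes in the universe.
#' @param n Draws.
#' @param m Observed successes among the draws.
#' @return `P(X >= m)`, in `(0, 1]`.
#' @export
hypergeom_pvalue <- function(N, M, n, m) {
  vals <- c(N, M, n, m)
  if (any(vals != round(vals)) || any(vals < 0))
    stop("counts must be non-negative integers")
  if (M > N || n > N || m > min(M, n))
    stop("inconsistent counts: require 0 <= m <= min(M, n) <= N")
  stats::phyper(m - 1, M, N - M, n, lower.tail = FALSE)
}

#' Read a GMT-like drug-target file
#'
#' Each line: drug name, description, then tab-separated target genes. Drug
#' names are case-folded; repeated drugs have their target sets unioned
#' (the merging rule for combining several databases).
#'
#' @param path Path to the GMT file.
#' @return Named list of character vectors (drug -> target genes).
#' @export
read_drug_targets <- function(path) {
  sets <- fgsea::gmtPathways(path)
  names(sets) <- tolower(names(sets))
  out <- list()
  for (i in seq_along(sets)) {
    d <- names(sets)[i]
    out[[d]] <- union(out[[d]], sets[[i]])
  }
  out
}

#' Read a two-column drug-indication file
#'
#' Tab-separated with columns `drug` and `disease`; drug names are
#' case-folded.
#'
#' @param path Path to the file.
#' @return Named list of character vectors (drug -> indicated diseases).
#' @export
read_drug_indications <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("drug", "disease") %in% names(df)))
    stop("indication file requires columns drug, disease")
  split(df$disease, tolower(df$drug))
}

#' Assemble a drug-target map
#'
#' @param targets Named list of target gene sets (e.g. the union of several
#'   databases via [read_drug_targets()]).
#' @param indications Optional named list of indicated diseases per drug.
#' @return Object of class `drug_target_map`.
#' @export
drug_target_map <- function(targets, indications = NULL) {
  if (any(lengths(targets) == 0)) stop("empty target set")
  names(targets) <- tolower(names(targets))
  if (!is.null(indications)) names(indications) <- tolower(names(indications))
  structure(list(targets = targets, indications = indications),
            class = "drug_target_map")
}

#' Screen drugs whose targets are enriched in a community
#'
#' For each drug, the overlap between the community's genes and the drug's
#' targets (both restricted to the expression universe) is tested with the
#' hypergeometric upper tail. Drugs with at least one overlapping target and
#' p below `alpha` are returned, ascending by p.
#'
#' @param community A `community` object or character vector of gene ids.
#' @param targets A `drug_target_map`.
#' @param universe Character vector of all genes in the training expression
#'   data (the hypergeometric universe).
#' @param alpha Screening threshold (default 0.05).
#' @param adjust Apply Benjamini-Hochberg correction before thresholding
#'   (default `FALSE`, matching the plain per-drug test).
#' @return Data frame with `drug`, `overlap`, `targets_in_universe`,
#'   `p_value` (and `p_adjusted` when `adjust`).
#' @export
screen_drugs <- function(community, targets, universe, alpha = 0.05,
                         adjust = FALSE) {
  members <- if (inherits(community, "community")) community$members
             else as.character(community)
  members <- intersect(members, universe)
  if (length(members) == 0) stop("community has no genes in the universe")
  N <- length(universe)
  rows <- lapply(names(targets$targets), function(d) {
    tg <- intersect(targets$targets[[d]], universe)
    if (length(tg) == 0) {
      warning("drug '", d, "' has no targets in the universe; skipped")
      return(NULL)
    }
    m <- length(intersect(members, tg))
    data.frame(drug = d, overlap = m, targets_in_universe = length(tg),
               p_value = hypergeom_pvalue(N, length(members), length(tg), m))
  })
  df <- do.call(rbind, rows)
  if (is.null(df)) return(data.frame(drug = character(0), overlap = integer(0),
                                     targets_in_universe = integer(0),
                                     p_value = numeric(0)))
  if (adjust) {
    df$p_adjusted <- stats::p.adjust(df$p_value, method = "BH")
    crit <- df$p_adjusted
  } else {
    crit <- df$p_value
  }
  df <- df[df$overlap >= 1 & crit < alpha, , drop = FALSE]
  df <- df[order(df$p_value, df$drug), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Enrichment of disease-indicated drugs among screened drugs
#'
#' Tests whether the screened drug list contains more drugs indicated for
#' `disease` than expected from the whole drug map: hypergeometric upper tail
#' with N = all drugs, M = drugs indicated for the disease, n = screened
#' drugs, m = screened drugs indicated for the disease.
#'
#' @param screened Character vector of screened drug names.
#' @param targets A `drug_target_map` with indications.
#' @param disease Disease name (matched exactly within each drug's
#'   indication set).
#' @return List with `p_value`, `n_screened`, `n_indicated_screened`,
#'   `n_indicated_total`, `n_drugs`.
#' @export
disease_drug_enrichment <- function(screened, targets, disease) {
  if (is.null(targets$indications)) stop("drug map carries no indications")
  screened <- tolower(as.character(screened))
  all_drugs <- names(targets$targets)
  indicated <- all_drugs[vapply(all_drugs, function(d)
    disease %in% targets$indications[[d]], logical(1))]
  if (length(screened) == 0) {
    warning("empty screened list: p = 1")
    return(list(p_value = 1, n_screened = 0, n_indicated_screened = 0,
                n_indicated_total = length(indicated),
                n_drugs = length(all_drugs)))
  }
  screened <- intersect(screened, all_drugs)
  m <- length(intersect(screened, indicated))
  list(
    p_value = hypergeom_pvalue(length(all_drugs), length(indicated),
                               length(screened), m),
    n_screened = length(screened),
    n_indicated_screened = m,
    n_indicated_total = length(indicated),
    n_drugs = length(all_drugs)
  )
}
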