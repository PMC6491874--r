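# End-to-end orchestration: preprocess -> subtype -> per-subtype network ->
# communities -> accuracy-filtered ensemble, with JSON/TSV intermediates
# cached under a config-hash directory.

#' Pipeline configuration
#'
#' All tunables of the pipeline in one validated list. Unknown keys are
#' rejected.
#'
#' @param horizon_days Prognosis horizon (default 3 years = 1095.75 days).
#' @param variance_fraction Feature fraction for subtype clustering
#'   (default 0.15).
#' @param k_min,k_max Cluster-count range (defaults 2 and 6).
#' @param restarts K-means restarts (default 25).
#' @param n_neighbors Neighbors per gene in the co-expression network
#'   (default 4).
#' @param rank_by Neighbor ranking, `"absolute"` or `"signed"`.
#' @param node_score_cutoff,k_core,haircut,fluff MCODE parameters (defaults
#'   0.2, 2, `TRUE`, `FALSE`).
#' @param acc_threshold Sub-classifier accuracy threshold (default 0.56).
#' @param threshold_grid Optional grid scanned for the report (default
#'   `seq(0.55, 0.60, 0.01)`; `NULL` to skip).
#' @param quantile_normalize Apply quantile normalization (default `TRUE`).
#' @param max_missing Missingness tolerance per gene (default 0.2).
#' @param seed Integer seed for the stochastic stages (default 1).
#' @return Object of class `pipeline_config` (a named list).
#' @export
pipeline_config <- function(horizon_days = 365.25 * 3,
                            variance_fraction = 0.15,
                            k_min = 2, k_max = 6, restarts = 25,
                            n_neighbors = 4, rank_by = "absolute",
                            node_score_cutoff = 0.2, k_core = 2,
                            haircut = TRUE, fluff = FALSE,
                            acc_threshold = 0.56,
                            threshold_grid = seq(0.55, 0.60, by = 0.01),
                            quantile_normalize = TRUE,
                            max_missing = 0.2, seed = 1) {
  cfg <- as.list(environment())
  structure(cfg, class = "pipeline_config")
}

#' Read a flat key-value configuration file
#'
#' One `key = value` (or `key: value`) pair per line; keys must be known
#' [pipeline_config()] arguments.
#'
#' @param path Path to the file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- strsplit(lines, "[=:]", perl = TRUE)
  keys <- trimws(vapply(kv, `[`, character(1), 1))
  vals <- trimws(vapply(kv, function(x) paste(x[-1], collapse = ":"),
                        character(1)))
  known <- names(formals(pipeline_config))
  unknown <- setdiff(keys, known)
  if (length(unknown) > 0)
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  args <- lapply(seq_along(keys), function(i) {
    v <- vals[i]
    if (keys[i] == "rank_by") return(v)
    if (v %in% c("TRUE", "FALSE", "true", "false"))
      return(as.logical(toupper(v)))
    parsed <- suppressWarnings(as.numeric(strsplit(v, ",")[[1]]))
    if (any(is.na(parsed))) v else parsed
  })
  names(args) <- keys
  do.call(pipeline_config, args)
}

.config_hash <- function(cfg) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(unclass(cfg), tmp, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}

.cache_path <- function(cache_dir, cfg, name) {
  if (is.null(cache_dir)) return(NULL)
  d <- file.path(cache_dir, .config_hash(cfg))
  if (!dir.exists(d)) dir.create(d, recursive = TRUE)
  file.path(d, name)
}

#' Serialize a subtype model to JSON
#'
#' @param model A `subtype_model`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_subtype_model <- function(model, path) {
  obj <- list(
    feature_genes = model$feature_genes,
    k = model$k,
    centroids = apply(model$centroids, 1, identity, simplify = FALSE),
    assignments = as.list(model$assignments),
    dunn_by_k = as.list(model$dunn_by_k),
    withinss_by_k = as.list(model$withinss_by_k)
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a subtype model written by [write_subtype_model()]
#'
#' @param path Path to the JSON file.
#' @return A `subtype_model`.
#' @export
read_subtype_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  centroids <- do.call(rbind, obj$centroids)
  colnames(centroids) <- obj$feature_genes
  structure(
    list(
      feature_genes = obj$feature_genes,
      k = as.integer(obj$k),
      centroids = centroids,
      assignments = unlist(obj$assignments),
      dunn_by_k = unlist(obj$dunn_by_k),
      withinss_by_k = unlist(obj$withinss_by_k)
    ),
    class = "subtype_model"
  )
}

#' Run the full prognostic-model pipeline
#'
#' Preprocess (missing-value resolution, optional quantile normalization,
#' prognosis discretization), discover subtypes, build one rank-based
#' co-expression network and its MCODE communities per subtype, and assemble
#' the accuracy-filtered majority-voting ensemble. Expensive stage outputs
#' (subtype model, edge lists, communities) are cached as plain text under
#' `cache_dir/<config hash>/` and reused byte-identically on rerun.
#'
#' @param expr Genes-by-samples matrix (raw; normalization handled here).
#' @param clinical Clinical data frame (`sample_id`, `time_days`, `event`).
#' @param config A [pipeline_config()].
#' @param cache_dir Optional cache directory.
#' @return Object of class `pipeline_result`: list with `model` (the
#'   `ensemble_model`), `subtype_model`, `networks`, `communities`,
#'   `labels`, `normalized` (matrix), `subtype_data` and `report`.
#' @export
run_pipeline <- function(expr, clinical, config = pipeline_config(),
                         cache_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  aligned <- align_samples(expr, clinical)
  mat <- resolve_missing(aligned$expression, config$max_missing)
  if (isTRUE(config$quantile_normalize)) mat <- quantile_normalize(mat)
  labels <- discretize_prognosis(aligned$clinical, config$horizon_days)

  st_path <- .cache_path(cache_dir, config, "subtype_model.json")
  if (!is.null(st_path) && file.exists(st_path)) {
    subtype_model <- read_subtype_model(st_path)
  } else {
    subtype_model <- fit_subtypes(mat, fraction = config$variance_fraction,
                                  k_min = config$k_min, k_max = config$k_max,
                                  restarts = config$restarts,
                                  seed = config$seed)
    if (!is.null(st_path)) write_subtype_model(subtype_model, st_path)
  }

  networks <- list()
  communities <- list()
  subtype_data <- list()
  for (s in seq_len(subtype_model$k)) {
    key <- as.character(s)
    in_sub <- names(subtype_model$assignments)[subtype_model$assignments == s]
    submat <- mat[, in_sub, drop = FALSE]
    net <- build_rank_network(submat, n_neighbors = config$n_neighbors,
                              rank_by = config$rank_by)
    networks[[key]] <- net
    cm_path <- .cache_path(cache_dir, config,
                           paste0("communities_subtype", s, ".tsv"))
    if (!is.null(cm_path) && file.exists(cm_path)) {
      communities[[key]] <- read_communities(cm_path)
    } else {
      communities[[key]] <- mcode_find_communities(
        net, node_score_cutoff = config$node_score_cutoff,
        k_core = config$k_core, haircut = config$haircut,
        fluff = config$fluff
      )
      if (!is.null(cm_path)) write_communities(communities[[key]], cm_path)
    }
    if (!is.null(cache_dir))
      write_edge_list(net, .cache_path(cache_dir, config,
                                       paste0("network_subtype", s, ".tsv")))
    labelled <- intersect(in_sub, names(labels$labels))
    subtype_data[[key]] <- list(matrix = mat[, labelled, drop = FALSE],
                                labels = labels$labels[labelled])
  }

  model <- build_ensemble(subtype_data, communities,
                          acc_threshold = config$acc_threshold,
                          subtype_model = subtype_model)
  training <- ensemble_training_metrics(model, subtype_data)
  power_law <- lapply(networks, function(net)
    tryCatch(power_law_fit(net), error = function(e) NULL))
  scan <- NULL
  if (!is.null(config$threshold_grid))
    scan <- scan_acc_threshold(subtype_data, communities,
                               grid = config$threshold_grid,
                               subtype_model = subtype_model)

  report <- list(
    config = unclass(config),
    n_samples = ncol(mat),
    n_genes = nrow(mat),
    n_labelled = length(labels$labels),
    n_excluded = length(labels$excluded),
    chosen_k = subtype_model$k,
    dunn_by_k = subtype_model$dunn_by_k,
    communities_per_subtype = vapply(communities, length, integer(1)),
    sub_classifiers_per_subtype = vapply(model$subtype_models, length,
                                         integer(1)),
    training_metrics = training$metrics,
    power_law = power_law,
    threshold_scan = scan
  )
  structure(
    list(model = model, subtype_model = subtype_model, networks = networks,
         communities = communities, labels = labels, normalized = mat,
         subtype_data = subtype_data, report = report),
    class = "pipeline_result"
  )
}

#' @export
print.pipeline_result <- function(x, ...) {
  r <- x$report
  cat("Pipeline result: ", r$n_genes, " genes x ", r$n_samples, " samples (",
      r$n_labelled, " labelled, ", r$n_excluded, " excluded)\n", sep = "")
  cat("Chosen K = ", r$chosen_k, "; communities per subtype: ",
      paste(r$communities_per_subtype, collapse = ", "), "\n", sep = "")
  cat("Sub-classifiers per subtype: ",
      paste(r$sub_classifiers_per_subtype, collapse = ", "), "\n", sep = "")
  m <- r$training_metrics
  cat(sprintf("Training (LOOCV votes): AUC %.4f  MCC %.4f  ACC %.4f\n",
              m$auc, m$mcc, m$acc))
  invisible(x)
}
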