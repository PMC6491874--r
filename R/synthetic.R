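#' Generate a synthetic expression cohort with planted structure
#'
#' Emulates a continuous, microarray-like (log-scale) expression cohort with
#' the three features the pipeline exploits: (i) subtype structure - marker
#' genes carry a mean shift in exactly one subtype; (ii) co-expressed gene
#' modules - each module's genes load on a shared latent factor so that any
#' two module genes have (population) Pearson correlation
#' `within_module_corr`; (iii) module-driven survival - each module belongs
#' to one subtype and its latent factor enters that subtype's log-hazard with
#' coefficient `hazard_effects`, under an exponential survival model with
#' uniform-within-follow-up censoring.
#'
#' Defaults define the package's reference study conditions: 3 subtypes of
#' 50 samples, 1000 genes, 2 modules of 10 genes per subtype at r = 0.8,
#' a 2-SD marker shift on 10% of genes, module hazard coefficient 1, a
#' baseline hazard placing 40% of deaths within 3 years, and 25% censoring.
#'
#' @param n_subtypes Number of planted subtypes (default 3).
#' @param samples_per_subtype Samples per subtype (default 50).
#' @param n_genes Total genes (default 1000).
#' @param n_modules_per_subtype Correlated modules planted per subtype
#'   (default 2).
#' @param module_size Genes per module (default 10).
#' @param within_module_corr Pairwise correlation within a module, in
#'   `[0, 1)` (default 0.8).
#' @param subtype_shift Marker mean shift in within-subtype SD units
#'   (default 2).
#' @param marker_fraction Fraction of genes acting as subtype markers
#'   (default 0.10), split evenly across subtypes.
#' @param hazard_effects Log-hazard coefficient(s) per module factor,
#'   recycled over modules (default 1).
#' @param censor_rate Expected fraction of censored samples (default 0.25).
#' @param death_within_horizon Baseline probability of death within
#'   `horizon_days` at zero log-hazard (default 0.4).
#' @param horizon_days Calibration horizon in days (default 1095.75).
#' @param baseline_mean,baseline_sd Per-gene baseline intensity distribution
#'   (defaults 7 and 1, a typical log2 microarray scale).
#' @param seed Optional integer seed; identical seeds give bit-identical
#'   outputs.
#' @return Object of class `synthetic_dataset`: list with `expression`
#'   (genes x samples matrix), `clinical` (`sample_id`, `time_days`,
#'   `event`) and `truth` (subtype assignments, module memberships and
#'   factors, marker genes, hazard effects, linear predictor).
#' @export
generate_dataset <- function(n_subtypes = 3, samples_per_subtype = 50,
                             n_genes = 1000, n_modules_per_subtype = 2,
                             module_size = 10, within_module_corr = 0.8,
                             subtype_shift = 2, marker_fraction = 0.10,
                             hazard_effects = 1, censor_rate = 0.25,
                             death_within_horizon = 0.4,
                             horizon_days = 365.25 * 3,
                             baseline_mean = 7, baseline_sd = 1,
                             seed = NULL) {
  if (within_module_corr < 0 || within_module_corr >= 1)
    stop("within_module_corr must be in [0, 1)")
  if (censor_rate < 0 || censor_rate >= 1)
    stop("censor_rate must be in [0, 1)")
  n_modules <- n_subtypes * n_modules_per_subtype
  n_marker <- ceiling(marker_fraction * n_genes)
  n_marker <- n_marker - n_marker %% n_subtypes  # split evenly
  if (n_modules * module_size + n_marker > n_genes)
    stop("module and marker genes exceed n_genes")
  if (!is.null(seed)) set.seed(seed)

  n <- n_subtypes * samples_per_subtype
  genes <- sprintf("g%04d", seq_len(n_genes))
  samples <- sprintf("s%04d", seq_len(n))
  subtype_of <- rep(seq_len(n_subtypes), each = samples_per_subtype)
  names(subtype_of) <- samples

  # disjoint gene roles: modules first, then markers, rest background
  module_members <- list()
  module_subtype <- integer(n_modules)
  idx <- 1
  for (s in seq_len(n_subtypes)) {
    for (j in seq_len(n_modules_per_subtype)) {
      mid <- length(module_members) + 1
      module_members[[sprintf("module_%02d", mid)]] <-
        genes[idx:(idx + module_size - 1)]
      module_subtype[mid] <- s
      idx <- idx + module_size
    }
  }
  marker_genes <- if (n_marker > 0) genes[idx:(idx + n_marker - 1)]
                  else character(0)
  marker_subtype <- rep(seq_len(n_subtypes), each = n_marker / n_subtypes)

  expr <- matrix(stats::rnorm(n_genes * n), nrow = n_genes,
                 dimnames = list(genes, samples))

  # latent-factor modules: unit-variance genes with pairwise corr rho
  loading <- sqrt(within_module_corr)
  noise_sd <- sqrt(1 - within_module_corr)
  factors <- matrix(stats::rnorm(n_modules * n), nrow = n_modules,
                    dimnames = list(names(module_members), samples))
  for (mid in seq_len(n_modules)) {
    rows <- module_members[[mid]]
    expr[rows, ] <- loading * matrix(factors[mid, ], nrow = module_size,
                                     ncol = n, byrow = TRUE) +
      noise_sd * expr[rows, ]
  }

  # subtype marker shifts
  if (n_marker > 0) {
    for (i in seq_along(marker_genes)) {
      in_sub <- subtype_of == marker_subtype[i]
      expr[marker_genes[i], in_sub] <- expr[marker_genes[i], in_sub] +
        subtype_shift
    }
  }

  baseline <- stats::rnorm(n_genes, baseline_mean, baseline_sd)
  expr <- expr + baseline

  # survival: exponential with log-hazard from own-subtype module factors
  effects <- rep_len(hazard_effects, n_modules)
  lp <- numeric(n)
  for (mid in seq_len(n_modules)) {
    in_sub <- subtype_of == module_subtype[mid]
    lp[in_sub] <- lp[in_sub] + effects[mid] * factors[mid, in_sub]
  }
  lambda0 <- -log(1 - death_within_horizon) / horizon_days
  t_event <- stats::rexp(n, rate = lambda0 * exp(lp))
  censored <- stats::runif(n) < censor_rate
  time <- ifelse(censored, stats::runif(n) * t_event, t_event)
  clinical <- data.frame(
    sample_id = samples,
    time_days = time,
    event = as.integer(!censored)
  )

  structure(
    list(
      expression = expr,
      clinical = clinical,
      truth = list(
        subtype_of = subtype_of,
        module_members = module_members,
        module_subtype = stats::setNames(module_subtype,
                                         names(module_members)),
        module_effects = stats::setNames(effects, names(module_members)),
        module_factors = factors,
        marker_genes = marker_genes,
        linear_predictor = stats::setNames(lp, samples)
      )
    ),
    class = "synthetic_dataset"
  )
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  tr <- x$truth
  cat("Synthetic cohort:", nrow(x$expression), "genes x",
      ncol(x$expression), "samples;",
      length(unique(tr$subtype_of)), "subtypes,",
      length(tr$module_members), "planted modules,",
      length(tr$marker_genes), "marker genes\n")
  invisible(x)
}

#' Write a synthetic dataset in the pipeline's input formats
#'
#' Writes `expression.tsv`, `clinical.tsv` and `truth.json` under `dir`.
#'
#' @param dataset A `synthetic_dataset`.
#' @param dir Output directory (created if missing).
#' @return Invisibly, `dir`.
#' @export
write_synthetic_dataset <- function(dataset, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_expression(dataset$expression, file.path(dir, "expression.tsv"))
  utils::write.table(dataset$clinical, file.path(dir, "clinical.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  truth <- dataset$truth
  truth$module_factors <- NULL
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
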