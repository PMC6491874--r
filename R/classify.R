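# Nearest-centroid classification on standardized expression, leave-one-out
# evaluation, feature ranking for the control classifiers, and the
# per-subtype majority-voting ensemble.

.check_labels <- function(labels) {
  if (inherits(labels, "prognosis_labels")) labels <- labels$labels
  if (is.null(names(labels))) stop("labels must be named by sample identifier")
  bad <- !labels %in% c("high_risk", "low_risk")
  if (any(bad)) stop("labels must be 'high_risk' or 'low_risk'")
  labels
}

#' Welch two-sample t statistic
#'
#' `t = (mean(x) - mean(y)) / sqrt(var(x)/n + var(y)/m)` with a two-sided
#' p-value from the t distribution at the Welch-Satterthwaite degrees of
#' freedom.
#'
#' @param x,y Numeric vectors, each of length >= 2.
#' @return List with `statistic`, `p_value` and `df`.
#' @export
t_statistic <- function(x, y) {
  n <- length(x)
  m <- length(y)
  if (n < 2 || m < 2) stop("each group needs >= 2 observations")
  vx <- stats::var(x)
  vy <- stats::var(y)
  se2 <- vx / n + vy / m
  if (se2 == 0) return(list(statistic = 0, p_value = 1, df = n + m - 2))
  t <- (mean(x) - mean(y)) / sqrt(se2)
  df <- se2^2 / ((vx / n)^2 / (n - 1) + (vy / m)^2 / (m - 1))
  list(statistic = t, p_value = 2 * stats::pt(-abs(t), df), df = df)
}

#' Rank genes by differential-expression or survival association
#'
#' `method = "ttest"` ranks genes by the two-sided Welch t-test p-value
#' between the high- and low-risk classes; `method = "cox"` by the Wald
#' p-value of a univariate Cox proportional-hazards fit on survival time and
#' event status. Constant genes get p = 1 and rank last.
#'
#' @param mat Genes-by-samples matrix.
#' @param labels Named prognosis labels (required for `"ttest"`).
#' @param method `"ttest"` or `"cox"`.
#' @param clinical Clinical data frame (required for `"cox"`).
#' @return Data frame (`gene`, `statistic`, `p_value`) ordered by ascending
#'   p-value, ties broken by gene identifier.
#' @export
rank_genes <- function(mat, labels = NULL, method = c("ttest", "cox"),
                       clinical = NULL) {
  method <- match.arg(method)
  mat <- as_expression_matrix(mat)
  if (method == "ttest") {
    labels <- .check_labels(labels)
    samples <- intersect(colnames(mat), names(labels))
    lab <- labels[samples]
    if (length(unique(lab)) < 2) stop("both classes must be present")
    xh <- mat[, samples[lab == "high_risk"], drop = FALSE]
    xl <- mat[, samples[lab == "low_risk"], drop = FALSE]
    n <- ncol(xh)
    m <- ncol(xl)
    if (n < 2 || m < 2) stop("each class needs >= 2 samples")
    mh <- rowMeans(xh)
    ml <- rowMeans(xl)
    vh <- rowSums((xh - mh)^2) / (n - 1)
    vl <- rowSums((xl - ml)^2) / (m - 1)
    se2 <- vh / n + vl / m
    t <- ifelse(se2 == 0, 0, (mh - ml) / sqrt(se2))
    df <- ifelse(se2 == 0, n + m - 2,
                 se2^2 / ((vh / n)^2 / (n - 1) + (vl / m)^2 / (m - 1)))
    p <- ifelse(se2 == 0, 1, 2 * stats::pt(-abs(t), df))
    out <- data.frame(gene = rownames(mat), statistic = t, p_value = p)
  } else {
    clinical <- validate_clinical(clinical)
    samples <- intersect(colnames(mat), clinical$sample_id)
    ci <- clinical[match(samples, clinical$sample_id), ]
    stats_p <- t(vapply(rownames(mat), function(g) {
      x <- mat[g, samples]
      if (stats::sd(x) == 0) return(c(0, 1))
      fit <- tryCatch(
        cox_univariate(x, ci$time_days, ci$event),
        error = function(e) NULL
      )
      if (is.null(fit)) c(0, 1) else c(fit$beta, fit$p_value)
    }, numeric(2)))
    out <- data.frame(gene = rownames(mat), statistic = stats_p[, 1],
                      p_value = stats_p[, 2])
  }
  out <- out[order(out$p_value, out$gene), ]
  rownames(out) <- NULL
  out
}

#' Train a nearest-centroid classifier
#'
#' Per-feature standardization (mean/SD) is fit on all training samples; the
#' class centroids are the mean standardized vectors of the high- and
#' low-risk samples. Zero-SD features get SD 1 (they then contribute nothing
#' to distances).
#'
#' @param mat Genes-by-samples matrix.
#' @param labels Named prognosis labels covering (a subset of) the columns.
#' @param features Gene identifiers to use.
#' @return Object of class `centroid_classifier`: list with `features`,
#'   `center`, `scale`, `centroid_high`, `centroid_low`.
#' @export
train_centroid <- function(mat, labels, features) {
  mat <- as_expression_matrix(mat)
  labels <- .check_labels(labels)
  if (!all(features %in% rownames(mat))) stop("features missing from matrix")
  samples <- intersect(colnames(mat), names(labels))
  lab <- labels[samples]
  if (!all(c("high_risk", "low_risk") %in% lab))
    stop("both classes required for training")
  x <- t(mat[features, samples, drop = FALSE])
  center <- colMeans(x)
  xc <- sweep(x, 2, center)
  scl <- if (nrow(x) > 1) sqrt(colSums(xc^2) / (nrow(x) - 1))
         else stats::setNames(rep(0, ncol(x)), colnames(x))
  scl[scl == 0] <- 1
  z <- sweep(xc, 2, scl, "/")
  structure(
    list(
      features = features,
      center = center,
      scale = scl,
      centroid_high = colMeans(z[lab == "high_risk", , drop = FALSE]),
      centroid_low = colMeans(z[lab == "low_risk", , drop = FALSE])
    ),
    class = "centroid_classifier"
  )
}

#' Predict with a nearest-centroid classifier
#'
#' The continuous score is `d(sample, centroid_low) - d(sample,
#' centroid_high)` in standardized Euclidean space: positive scores favor
#' high risk. Exact ties go to low risk.
#'
#' @param clf A `centroid_classifier`.
#' @param sample_vector Named numeric vector (or unnamed, ordered like
#'   `clf$features`). Features absent or `NA` are dropped from the distance.
#' @return List with `label` (`"high_risk"`/`"low_risk"`) and `score`.
#' @export
predict_centroid <- function(clf, sample_vector) {
  if (is.null(names(sample_vector))) {
    if (length(sample_vector) != length(clf$features))
      stop("unnamed sample vector must match the feature count")
    v <- sample_vector
  } else {
    v <- sample_vector[clf$features]
  }
  keep <- is.finite(v)
  if (!any(keep)) stop("no classifier features present in the sample")
  z <- (v[keep] - clf$center[keep]) / clf$scale[keep]
  d_high <- sqrt(sum((z - clf$centroid_high[keep])^2))
  d_low <- sqrt(sum((z - clf$centroid_low[keep])^2))
  score <- d_low - d_high
  list(label = if (score > 0) "high_risk" else "low_risk", score = score)
}

#' Leave-one-out evaluation of a centroid classifier
#'
#' For each sample the classifier (standardization and centroids) is refit on
#' the remaining samples with the feature set fixed, and the held-out sample
#' is predicted. If a fold's training set loses a class entirely, the fold
#' predicts the training majority class. Metrics are computed over the pooled
#' held-out predictions and scores.
#'
#' @param mat Genes-by-samples matrix.
#' @param labels Named prognosis labels.
#' @param features Gene identifiers to use.
#' @return List with `acc`, `auc`, `mcc`, and per-sample `predictions` and
#'   `scores` (named vectors).
#' @export
loocv_metrics <- function(mat, labels, features) {
  mat <- as_expression_matrix(mat)
  labels <- .check_labels(labels)
  samples <- intersect(colnames(mat), names(labels))
  lab <- labels[samples]
  if (sum(lab == "high_risk") < 2 || sum(lab == "low_risk") < 2)
    stop("LOOCV requires >= 2 samples per class")
  preds <- character(length(samples))
  scores <- numeric(length(samples))
  for (i in seq_along(samples)) {
    train <- samples[-i]
    tl <- lab[-i]
    if (length(unique(tl)) < 2) {
      maj <- names(which.max(table(tl)))
      preds[i] <- maj
      scores[i] <- if (maj == "high_risk") Inf else -Inf
      next
    }
    clf <- train_centroid(mat[, train, drop = FALSE], tl, features)
    pr <- predict_centroid(clf, mat[, samples[i]])
    preds[i] <- pr$label
    scores[i] <- pr$score
  }
  names(preds) <- names(scores) <- samples
  m <- classification_metrics(lab, preds, scores)
  list(acc = m$acc, auc = m$auc, mcc = m$mcc,
       predictions = preds, scores = scores)
}

#' Build candidate sub-classifiers from communities
#'
#' One candidate per community with >= 2 usable genes: the community's
#' nearest-centroid classifier trained on the subtype's labelled samples,
#' together with its leave-one-out accuracy and per-sample leave-one-out
#' predictions.
#'
#' @param mat Genes-by-samples matrix of one subtype.
#' @param labels Named prognosis labels for the subtype's samples.
#' @param communities List of `community` objects from the subtype network.
#' @return List of `sub_classifier` objects (`community`, `classifier`,
#'   `loocv_acc`, `loocv_predictions`, `loocv_scores`).
#' @export
build_sub_classifiers <- function(mat, labels, communities) {
  mat <- as_expression_matrix(mat)
  labels <- .check_labels(labels)
  out <- list()
  for (cx in communities) {
    features <- intersect(cx$members, rownames(mat))
    if (length(features) < 2) next
    cv <- loocv_metrics(mat, labels, features)
    clf <- train_centroid(mat, labels, features)
    out[[length(out) + 1]] <- structure(
      list(community = cx, classifier = clf, loocv_acc = cv$acc,
           loocv_predictions = cv$predictions, loocv_scores = cv$scores),
      class = "sub_classifier"
    )
  }
  out
}

#' Assemble the per-subtype majority-voting ensemble
#'
#' Keeps, within each subtype, the community sub-classifiers whose
#' leave-one-out accuracy is at least `acc_threshold` ("no less than" the
#' threshold), and routes prediction through subtype assignment followed by a
#' majority vote of the retained sub-classifiers.
#'
#' @param subtype_data Named list, one element per subtype index, each a list
#'   with `matrix` (genes x samples) and `labels` (named prognosis labels).
#' @param communities Named list of community lists, parallel to
#'   `subtype_data`.
#' @param acc_threshold Minimum leave-one-out accuracy (default 0.56).
#' @param subtype_model The `subtype_model` used to route new samples.
#' @return Object of class `ensemble_model`: list with `subtype_models`
#'   (list of accepted `sub_classifier`s per subtype), `acc_threshold`,
#'   `subtype_assigner`.
#' @export
build_ensemble <- function(subtype_data, communities, acc_threshold = 0.56,
                           subtype_model = NULL) {
  if (!identical(names(subtype_data), names(communities)))
    stop("subtype_data and communities must share names")
  subtype_models <- list()
  for (s in names(subtype_data)) {
    cands <- build_sub_classifiers(subtype_data[[s]]$matrix,
                                   subtype_data[[s]]$labels,
                                   communities[[s]])
    keep <- Filter(function(sc) sc$loocv_acc >= acc_threshold, cands)
    if (length(keep) == 0)
      stop("subtype ", s, ": no sub-classifier reached accuracy ",
           acc_threshold, "; relax acc_threshold")
    subtype_models[[s]] <- keep
  }
  structure(
    list(subtype_models = subtype_models, acc_threshold = acc_threshold,
         subtype_assigner = subtype_model),
    class = "ensemble_model"
  )
}

#' @export
print.ensemble_model <- function(x, ...) {
  cat("Ensemble model (ACC threshold ", x$acc_threshold, "):\n", sep = "")
  for (s in names(x$subtype_models))
    cat("  subtype ", s, ": ", length(x$subtype_models[[s]]),
        " sub-classifier(s)\n", sep = "")
  invisible(x)
}

#' Predict prognosis with the ensemble
#'
#' The sample is routed to a subtype by centroid distance, then every
#' retained sub-classifier of that subtype votes. The vote fraction (share of
#' high-risk votes) is the continuous score; the label is high-risk when the
#' fraction is at least 0.5 (an even split counts as high-risk).
#'
#' @param model An `ensemble_model`.
#' @param sample_vector Named expression vector.
#' @param subtype Optional pre-computed subtype index (skips routing).
#' @return List with `label`, `vote_fraction` and `subtype`.
#' @export
ensemble_predict <- function(model, sample_vector, subtype = NULL) {
  if (is.null(subtype)) {
    if (is.null(model$subtype_assigner))
      stop("model has no subtype assigner; pass `subtype` explicitly")
    subtype <- assign_subtype(model$subtype_assigner, sample_vector)
  }
  subs <- model$subtype_models[[as.character(subtype)]]
  if (is.null(subs) || length(subs) == 0)
    stop("no sub-classifiers available for subtype ", subtype)
  votes <- vapply(subs, function(sc)
    predict_centroid(sc$classifier, sample_vector)$label, character(1))
  frac <- mean(votes == "high_risk")
  list(label = if (frac >= 0.5) "high_risk" else "low_risk",
       vote_fraction = frac, subtype = as.integer(subtype))
}

#' Evaluate an ensemble on a labelled expression matrix
#'
#' @param model An `ensemble_model`.
#' @param mat Genes-by-samples matrix.
#' @param labels Named prognosis labels (samples without labels are skipped).
#' @param subtypes Optional named subtype assignments (skips routing).
#' @return List with `metrics` (auc/mcc/acc), per-sample `predictions`,
#'   `vote_fractions` and `subtypes`.
#' @export
evaluate_ensemble <- function(model, mat, labels, subtypes = NULL) {
  mat <- as_expression_matrix(mat)
  labels <- .check_labels(labels)
  samples <- intersect(colnames(mat), names(labels))
  preds <- character(length(samples))
  frac <- numeric(length(samples))
  sub <- integer(length(samples))
  for (i in seq_along(samples)) {
    pr <- ensemble_predict(model, mat[, samples[i]],
                           subtype = subtypes[[samples[i]]])
    preds[i] <- pr$label
    frac[i] <- pr$vote_fraction
    sub[i] <- pr$subtype
  }
  names(preds) <- names(frac) <- names(sub) <- samples
  list(metrics = classification_metrics(labels[samples], preds, frac),
       predictions = preds, vote_fractions = frac, subtypes = sub)
}

#' Training (leave-one-out) metrics of an ensemble
#'
#' Each training sample's vote fraction is recomputed from the retained
#' sub-classifiers' leave-one-out predictions for that sample, so the
#' training score never sees the sample's own contribution to any centroid.
#' Metrics are pooled across subtypes.
#'
#' @param model An `ensemble_model`.
#' @param subtype_data The `subtype_data` used to build the model.
#' @return List with `metrics`, `predictions` and `vote_fractions`.
#' @export
ensemble_training_metrics <- function(model, subtype_data) {
  preds <- character(0)
  frac <- numeric(0)
  truth <- character(0)
  for (s in names(model$subtype_models)) {
    subs <- model$subtype_models[[s]]
    labels <- .check_labels(subtype_data[[s]]$labels)
    samples <- names(subs[[1]]$loocv_predictions)
    vote_mat <- vapply(subs, function(sc)
      sc$loocv_predictions[samples] == "high_risk", logical(length(samples)))
    vote_mat <- matrix(vote_mat, nrow = length(samples))
    f <- rowMeans(vote_mat)
    p <- ifelse(f >= 0.5, "high_risk", "low_risk")
    names(f) <- names(p) <- samples
    preds <- c(preds, p)
    frac <- c(frac, f)
    truth <- c(truth, labels[samples])
  }
  list(metrics = classification_metrics(truth, preds, frac),
       predictions = preds, vote_fractions = frac)
}

#' Scan the sub-classifier accuracy threshold
#'
#' Rebuilds the ensemble over a grid of accuracy thresholds (candidate
#' sub-classifiers are computed once) and reports pooled training
#' (leave-one-out) metrics per threshold. Thresholds at which some subtype
#' retains no sub-classifier are reported with `NA` metrics.
#'
#' @param subtype_data As in [build_ensemble()].
#' @param communities As in [build_ensemble()].
#' @param grid Numeric vector of thresholds (default `seq(0.55, 0.60, 0.01)`).
#' @param subtype_model Optional router stored in each scanned model.
#' @return Data frame with columns `threshold`, `n_sub_classifiers`, `auc`,
#'   `mcc`, `acc`.
#' @export
scan_acc_threshold <- function(subtype_data, communities,
                               grid = seq(0.55, 0.60, by = 0.01),
                               subtype_model = NULL) {
  cands <- lapply(names(subtype_data), function(s)
    build_sub_classifiers(subtype_data[[s]]$matrix,
                          subtype_data[[s]]$labels, communities[[s]]))
  names(cands) <- names(subtype_data)
  rows <- lapply(grid, function(thr) {
    kept <- lapply(cands, function(cs)
      Filter(function(sc) sc$loocv_acc >= thr, cs))
    n_kept <- sum(vapply(kept, length, integer(1)))
    if (any(vapply(kept, length, integer(1)) == 0))
      return(data.frame(threshold = thr, n_sub_classifiers = n_kept,
                        auc = NA_real_, mcc = NA_real_, acc = NA_real_))
    model <- structure(
      list(subtype_models = kept, acc_threshold = thr,
           subtype_assigner = subtype_model),
      class = "ensemble_model"
    )
    m <- ensemble_training_metrics(model, subtype_data)$metrics
    data.frame(threshold = thr, n_sub_classifiers = n_kept,
               auc = m$auc, mcc = m$mcc, acc = m$acc)
  })
  do.call(rbind, rows)
}

#' Build a control centroid classifier on top-ranked genes
#'
#' The paper-style control: rank all genes once on the full training set
#' (t-test between risk classes, or univariate Cox), then for each n in
#' `1:n_max` train a centroid classifier on the top-n genes, evaluate it by
#' leave-one-out accuracy, and keep the best n (ties toward the smaller n).
#' With `per_subtype = TRUE` the same procedure is run independently within
#' each subtype.
#'
#' @param mat Genes-by-samples matrix.
#' @param labels Named prognosis labels.
#' @param n_max Largest feature-set size scanned (default 100, capped at the
#'   gene count with a warning).
#' @param per_subtype Build one classifier per subtype (default `FALSE`).
#' @param subtypes Named subtype assignments (required when `per_subtype`).
#' @param method Feature-ranking method, `"ttest"` or `"cox"`.
#' @param clinical Clinical table (required for `method = "cox"`).
#' @param metric Model-selection metric, `"acc"` (default) or `"auc"`.
#' @return For the global control, an object of class `control_classifier`
#'   (`classifier`, `best_n`, `scan`, `loocv`, `ranking`); for
#'   `per_subtype`, a named list of such objects.
#' @export
build_control_classifier <- function(mat, labels, n_max = 100,
                                     per_subtype = FALSE, subtypes = NULL,
                                     method = c("ttest", "cox"),
                                     clinical = NULL,
                                     metric = c("acc", "auc")) {
  method <- match.arg(method)
  metric <- match.arg(metric)
  mat <- as_expression_matrix(mat)
  labels <- .check_labels(labels)
  if (per_subtype) {
    if (is.null(subtypes)) stop("per_subtype requires subtype assignments")
    out <- lapply(sort(unique(subtypes)), function(s) {
      keep <- names(subtypes)[subtypes == s]
      keep <- intersect(keep, intersect(colnames(mat), names(labels)))
      build_control_classifier(mat[, keep, drop = FALSE], labels[keep],
                               n_max = n_max, method = method,
                               clinical = clinical, metric = metric)
    })
    names(out) <- as.character(sort(unique(subtypes)))
    return(out)
  }
  ranking <- rank_genes(mat, labels, method = method, clinical = clinical)
  n_max_eff <- min(n_max, nrow(ranking))
  if (n_max_eff < n_max)
    warning("n_max capped at the gene count (", n_max_eff, ")")
  scan <- data.frame(n = seq_len(n_max_eff), acc = NA_real_, auc = NA_real_)
  cvs <- vector("list", n_max_eff)
  for (n in seq_len(n_max_eff)) {
    cv <- loocv_metrics(mat, labels, ranking$gene[seq_len(n)])
    cvs[[n]] <- cv
    scan$acc[n] <- cv$acc
    scan$auc[n] <- cv$auc
  }
  crit <- scan[[metric]]
  best_n <- scan$n[which.max(crit)]
  structure(
    list(
      classifier = train_centroid(mat, labels, ranking$gene[seq_len(best_n)]),
      best_n = best_n,
      scan = scan,
      loocv = cvs[[best_n]],
      ranking = ranking,
      method = method,
      metric = metric
    ),
    class = "control_classifier"
  )
}

#' @export
print.control_classifier <- function(x, ...) {
  cat("Control centroid classifier: top-", x$best_n, " genes by ", x$method,
      " (LOOCV acc ", round(x$loocv$acc, 3), ")\n", sep = "")
  invisible(x)
}
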