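# Survival machinery (Kaplan-Meier, log-rank, univariate Cox via the
# survival package) plus the Cox-sign risk score, median split, and the
# AUC/MCC/ACC metric set.

#' Kaplan-Meier survival curve
#'
#' Product-limit estimate: right-continuous, non-increasing, starting at 1.
#'
#' @param times Non-negative survival times.
#' @param events Event indicators (1 = death, 0 = censored).
#' @return Object of class `km_curve`: list with `time`, `surv`, `n_risk`,
#'   `n_event` and `surv_at` (a step function t -> S(t)).
#' @export
km_curve <- function(times, events) {
  if (length(times) == 0) stop("empty input")
  if (any(times < 0)) stop("negative survival times")
  fit <- survival::survfit(survival::Surv(times, events) ~ 1)
  step <- stats::stepfun(fit$time, c(1, fit$surv), right = FALSE)
  structure(
    list(time = fit$time, surv = fit$surv, n_risk = fit$n.risk,
         n_event = fit$n.event, surv_at = step),
    class = "km_curve"
  )
}

#' @export
print.km_curve <- function(x, ...) {
  cat("Kaplan-Meier curve over", length(x$time), "time point(s); final S =",
      round(x$surv[length(x$surv)], 4), "\n")
  invisible(x)
}

#' k-sample log-rank test
#'
#' @param times Non-negative survival times.
#' @param events Event indicators.
#' @param groups Group labels with k >= 2 non-empty levels.
#' @return List with `chi_square`, `df` (k - 1) and `p_value`.
#' @export
logrank_test <- function(times, events, groups) {
  groups <- as.factor(as.character(groups))
  if (nlevels(groups) < 2) stop("need >= 2 groups")
  if (any(table(groups) == 0)) stop("empty group")
  fit <- survival::survdiff(survival::Surv(times, events) ~ groups)
  df <- nlevels(groups) - 1
  list(chi_square = fit$chisq, df = df,
       p_value = stats::pchisq(fit$chisq, df, lower.tail = FALSE))
}

#' Univariate Cox proportional-hazards fit
#'
#' One-covariate partial-likelihood maximum (Breslow tie handling) with the
#' Wald p-value.
#'
#' @param expr Numeric covariate (e.g. one gene's expression).
#' @param times Survival times.
#' @param events Event indicators.
#' @return List with `beta`, `se` and `p_value`.
#' @export
cox_univariate <- function(expr, times, events) {
  if (sum(events) == 0) stop("no events observed")
  if (stats::sd(expr) == 0) stop("constant covariate")
  fit <- survival::coxph(survival::Surv(times, events) ~ expr,
                         ties = "breslow")
  beta <- unname(stats::coef(fit))
  se <- sqrt(unname(fit$var[1, 1]))
  list(beta = beta, se = se,
       p_value = 2 * stats::pnorm(-abs(beta / se)))
}

#' Fit a Cox-sign risk model over a gene signature
#'
#' Each signature gene is fit univariately against survival; the model keeps
#' only the sign of each fitted coefficient. Genes absent from the matrix or
#' failing to fit are dropped with a warning.
#'
#' @param mat Genes-by-samples matrix.
#' @param clinical Clinical table covering the matrix samples.
#' @param genes Signature gene identifiers.
#' @return Object of class `risk_model`: list with `gene_signs` (named +1/-1
#'   vector) and `source_genes`.
#' @export
fit_risk_model <- function(mat, clinical, genes) {
  mat <- as_expression_matrix(mat)
  clinical <- validate_clinical(clinical)
  samples <- intersect(colnames(mat), clinical$sample_id)
  ci <- clinical[match(samples, clinical$sample_id), ]
  present <- intersect(genes, rownames(mat))
  if (length(present) < length(genes))
    warning(length(genes) - length(present), " signature gene(s) absent")
  if (length(present) == 0) stop("no signature genes present")
  signs <- numeric(0)
  for (g in present) {
    fit <- tryCatch(
      cox_univariate(mat[g, samples], ci$time_days, ci$event),
      error = function(e) NULL
    )
    if (is.null(fit) || fit$beta == 0) next
    signs[g] <- sign(fit$beta)
  }
  if (length(signs) == 0) stop("no gene obtained a nonzero Cox coefficient")
  structure(list(gene_signs = signs, source_genes = genes),
            class = "risk_model")
}

#' Risk score from Cox coefficient signs
#'
#' Per sample: the sum of expression of positive-sign genes minus the sum of
#' expression of negative-sign genes (GGI-style score on the normalized
#' expression scale).
#'
#' @param mat Genes-by-samples matrix.
#' @param risk_model A `risk_model` (or list with `gene_signs`).
#' @return Named numeric vector of scores, one per sample.
#' @export
risk_score <- function(mat, risk_model) {
  mat <- as_expression_matrix(mat)
  signs <- risk_model$gene_signs
  present <- intersect(names(signs), rownames(mat))
  if (length(present) == 0) stop("no signature genes present in the matrix")
  if (length(present) < length(signs))
    warning(length(signs) - length(present), " signature gene(s) missing")
  signs <- signs[present]
  pos <- present[signs > 0]
  neg <- present[signs < 0]
  score <- rep(0, ncol(mat))
  if (length(pos) > 0) score <- score + colSums(mat[pos, , drop = FALSE])
  if (length(neg) > 0) score <- score - colSums(mat[neg, , drop = FALSE])
  stats::setNames(score, colnames(mat))
}

#' Split samples into high/low risk at the median score
#'
#' Scores strictly above the median go to `high_risk`; scores at or below it
#' to `low_risk`. Ties at the median make the groups unequal and trigger a
#' warning.
#'
#' @param scores Named numeric vector of risk scores (>= 2 samples).
#' @return Named character vector with values `"high_risk"`/`"low_risk"`.
#' @export
median_split <- function(scores) {
  if (length(scores) < 2) stop("need >= 2 samples")
  med <- stats::median(scores)
  if (all(scores == med)) stop("all scores identical: no split possible")
  if (sum(scores == med) > 0 && length(scores) %% 2 == 0)
    warning("ties at the median: groups are unequal")
  out <- ifelse(scores > med, "high_risk", "low_risk")
  stats::setNames(out, names(scores))
}

#' Classification metric set: AUC, MCC, ACC
#'
#' AUC via the rank statistic (midranks for tied scores), MCC from the
#' confusion matrix (defined as 0 when a denominator factor vanishes), ACC as
#' the fraction correct. `"high_risk"` is the positive class; larger scores
#' mean more likely high-risk.
#'
#' @param labels True labels (`"high_risk"`/`"low_risk"`).
#' @param predictions Predicted labels.
#' @param scores Continuous scores for AUC (optional; `NA` AUC if missing).
#' @return List with `auc`, `mcc`, `acc`.
#' @export
classification_metrics <- function(labels, predictions, scores = NULL) {
  labels <- as.character(labels)
  predictions <- as.character(predictions)
  if (length(labels) != length(predictions)) stop("length mismatch")
  acc <- mean(predictions == labels)
  pos <- labels == "high_risk"
  n_pos <- sum(pos)
  n_neg <- sum(!pos)
  auc <- NA_real_
  if (!is.null(scores) && n_pos > 0 && n_neg > 0) {
    r <- rank(scores)
    auc <- (sum(r[pos]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  } else if (n_pos == 0 || n_neg == 0) {
    warning("one-class truth: AUC undefined")
  }
  tp <- sum(predictions == "high_risk" & pos)
  tn <- sum(predictions == "low_risk" & !pos)
  fp <- sum(predictions == "high_risk" & !pos)
  fn <- sum(predictions == "low_risk" & pos)
  den <- sqrt(as.numeric(tp + fp) * (tp + fn) * (tn + fp) * (tn + fn))
  mcc <- if (den == 0) 0 else (as.numeric(tp) * tn - as.numeric(fp) * fn) / den
  list(auc = auc, mcc = mcc, acc = acc)
}
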