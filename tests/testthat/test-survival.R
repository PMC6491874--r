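test_that("Kaplan-Meier curve matches the product-limit hand case", {
  km <- km_curve(c(1, 2), c(1, 1))
  expect_equal(km$surv_at(0), 1)
  expect_equal(km$surv_at(1), 0.5)
  expect_equal(km$surv_at(2), 0)
  expect_equal(km$surv_at(1.5), 0.5)  # right-continuous step

  # all censored: constant 1
  km2 <- km_curve(c(3, 5, 8), c(0, 0, 0))
  expect_true(all(km2$surv == 1))

  # censoring after the last event does not change the curve
  km3 <- km_curve(c(1, 2, 10), c(1, 1, 0))
  expect_equal(km3$surv_at(1), 2 / 3)
  expect_equal(km3$surv_at(2), 1 / 3)
  expect_equal(km3$surv_at(5), 1 / 3)

  expect_error(km_curve(numeric(0), numeric(0)), "empty")
})

test_that("log-rank test matches the O-E oracle and handles k groups", {
  # identical groups: statistic 0, p 1
  t0 <- c(1, 2, 3, 1, 2, 3)
  e0 <- c(1, 1, 0, 1, 1, 0)
  g0 <- rep(c("a", "b"), each = 3)
  lr0 <- logrank_test(t0, e0, g0)
  expect_equal(lr0$chi_square, 0, tolerance = 1e-12)
  expect_equal(lr0$p_value, 1)

  # hand-worked 6-subject two-group example vs the exhaustive oracle
  times <- c(1, 3, 4, 2, 5, 7)
  events <- c(1, 1, 0, 1, 1, 1)
  grp <- rep(c("x", "y"), each = 3)
  lr <- logrank_test(times, events, grp)
  expect_equal(lr$chi_square, logrank_oracle(times, events, grp),
               tolerance = 1e-9)
  expect_equal(lr$df, 1)

  # k = 3 groups: df = 2
  set.seed(6)
  lr3 <- logrank_test(rexp(30), rbinom(30, 1, 0.8), rep(1:3, each = 10))
  expect_equal(lr3$df, 2)

  expect_error(logrank_test(c(1, 2), c(1, 1), c("a", "a")), "2 groups")
})

test_that("univariate Cox estimates behave correctly", {
  set.seed(31)
  n <- 150
  x <- rnorm(n)
  times <- rexp(n, rate = exp(x))
  events <- rep(1, n)
  fit <- cox_univariate(x, times, events)
  expect_gt(fit$beta, 0.6)
  expect_lt(fit$p_value, 1e-6)
  # negating the covariate negates beta
  fit_neg <- cox_univariate(-x, times, events)
  expect_equal(fit_neg$beta, -fit$beta, tolerance = 1e-8)

  expect_error(cox_univariate(x, times, rep(0, n)), "no events")
  expect_error(cox_univariate(rep(1, n), times, events), "constant")
})

test_that("risk score sums positive-sign genes minus negative-sign genes", {
  m <- toy_matrix(rbind(c(5, 1), c(3, 2), c(4, 4)),
                  genes = c("A", "B", "C"), samples = c("p1", "p2"))
  rm1 <- structure(list(gene_signs = c(A = 1, B = -1)), class = "risk_model")
  expect_equal(unname(risk_score(m, rm1)["p1"]), 2)

  rm2 <- structure(list(gene_signs = c(A = -1, B = -1, C = -1)),
                   class = "risk_model")
  expect_equal(unname(risk_score(m, rm2)), unname(-colSums(m)))

  rm3 <- structure(list(gene_signs = c(A = 1, B = 1, C = -1)),
                   class = "risk_model")
  expect_equal(unname(risk_score(m, rm3)["p2"]), -1)  # (1 + 2) - 4

  rm4 <- structure(list(gene_signs = c(A = 1, Z = -1)), class = "risk_model")
  expect_warning(risk_score(m, rm4), "missing")
  rm5 <- structure(list(gene_signs = c(Z = 1)), class = "risk_model")
  expect_error(risk_score(m, rm5), "no signature genes")
})

test_that("Cox-sign model recovers planted effect directions", {
  set.seed(17)
  n <- 200
  m <- toy_matrix(matrix(rnorm(4 * n), 4, n),
                  genes = c("up", "down", "n1", "n2"))
  lp <- m["up", ] - m["down", ]
  clinical <- data.frame(sample_id = colnames(m),
                         time_days = rexp(n, exp(lp)), event = 1)
  rm_ <- fit_risk_model(m, clinical, c("up", "down"))
  expect_equal(unname(rm_$gene_signs["up"]), 1)
  expect_equal(unname(rm_$gene_signs["down"]), -1)
})

test_that("median split sends scores above the median to high risk", {
  s <- make_labels(c("a", "b", "c", "d"), c(1, 2, 3, 4))
  sp <- median_split(s)
  expect_equal(unname(sp[c("c", "d")]), rep("high_risk", 2))
  expect_equal(unname(sp[c("a", "b")]), rep("low_risk", 2))

  # odd n: the median sample goes low
  s3 <- make_labels(c("a", "b", "c"), c(1, 2, 3))
  expect_equal(unname(median_split(s3)["b"]), "low_risk")

  s_tie <- make_labels(letters[1:4], c(1, 2, 2, 4))
  expect_warning(sp_tie <- median_split(s_tie), "unequal")
  expect_equal(sum(sp_tie == "high_risk"), 1)

  expect_error(median_split(c(2, 2, 2)), "identical")
})

test_that("metric set matches hand-worked AUC and MCC values", {
  lab <- c("low_risk", "low_risk", "high_risk", "high_risk")
  scores <- c(0.1, 0.4, 0.35, 0.8)
  m <- classification_metrics(lab, ifelse(scores > 0.37, "high_risk",
                                          "low_risk"), scores)
  expect_equal(m$auc, 0.75)

  # confusion TP=3 TN=4 FP=1 FN=2 -> MCC = 10 / sqrt(600)
  truth <- c(rep("high_risk", 5), rep("low_risk", 5))
  pred <- c(rep("high_risk", 3), rep("low_risk", 2),
            "high_risk", rep("low_risk", 4))
  m2 <- classification_metrics(truth, pred)
  expect_equal(m2$mcc, 10 / sqrt(600))
  expect_equal(m2$acc, 0.7)

  perfect <- classification_metrics(truth, truth,
                                    ifelse(truth == "high_risk", 1, 0))
  expect_equal(perfect$auc, 1)
  expect_equal(perfect$mcc, 1)
  expect_equal(perfect$acc, 1)

  expect_warning(
    one <- classification_metrics(rep("high_risk", 3), rep("high_risk", 3),
                                  1:3),
    "one-class"
  )
  expect_true(is.na(one$auc))
  expect_equal(one$acc, 1)
})

test_that("AUC equals exhaustive concordant-pair enumeration", {
  set.seed(40)
  for (i in 1:25) {
    n <- sample(4:30, 1)
    lab <- sample(c("high_risk", "low_risk"), n, replace = TRUE)
    if (length(unique(lab)) < 2) next
    scores <- sample(seq(0, 1, 0.1), n, replace = TRUE)  # forces ties
    m <- classification_metrics(lab, lab, scores)
    expect_equal(m$auc, auc_bruteforce(lab, scores), tolerance = 1e-12)
  }
})
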