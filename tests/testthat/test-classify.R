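test_that("Welch t statistic matches hand-worked cases", {
  r <- t_statistic(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$statistic, -3 / sqrt(2 / 3), tolerance = 1e-12)
  # equal means
  expect_equal(t_statistic(c(1, 2, 3), c(0, 2, 4))$statistic, 0)
  # antisymmetry
  set.seed(1)
  x <- rnorm(8); y <- rnorm(12, 1)
  expect_equal(t_statistic(x, y)$statistic, -t_statistic(y, x)$statistic)
  # agrees with the standard Welch test
  ref <- t.test(x, y)
  r2 <- t_statistic(x, y)
  expect_equal(r2$statistic, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(r2$p_value, ref$p.value, tolerance = 1e-12)
  expect_error(t_statistic(1, c(1, 2)), ">= 2")
})

test_that("gene ranking orders by p-value with degenerate genes last", {
  set.seed(10)
  n <- 30
  lab <- make_labels(sprintf("s%02d", 1:n),
                     rep(c("high_risk", "low_risk"), each = n / 2))
  m <- toy_matrix(matrix(rnorm(5 * n), 5, n),
                  samples = names(lab))
  m["g01", ] <- ifelse(lab == "high_risk", 10, 0) + rnorm(n, sd = 0.01)
  m["g02", ] <- 3  # constant
  rk <- rank_genes(m, lab, method = "ttest")
  expect_equal(rk$gene[1], "g01")
  expect_equal(rk$gene[nrow(rk)], "g02")
  expect_equal(rk$p_value[nrow(rk)], 1)
})

test_that("planted differential genes rank inside the top ten", {
  hits <- 0
  for (s in 1:20) {
    set.seed(300 + s)
    n <- 60
    lab <- make_labels(sprintf("s%02d", 1:n),
                       rep(c("high_risk", "low_risk"), each = n / 2))
    m <- toy_matrix(matrix(rnorm(100 * n), 100, n), samples = names(lab))
    for (g in 1:5)
      m[g, lab == "high_risk"] <- m[g, lab == "high_risk"] + 2
    rk <- rank_genes(m, lab, method = "ttest")
    if (all(sprintf("g%02d", 1:5) %in% rk$gene[1:10])) hits <- hits + 1
  }
  expect_gte(hits, 19)
})

test_that("centroid training standardizes and averages per class", {
  lab <- make_labels(c("a", "b", "c", "d"),
                     c("high_risk", "high_risk", "low_risk", "low_risk"))
  m <- toy_matrix(t(rbind(c(0, 0), c(2, 2), c(4, 4), c(6, 6))),
                  genes = c("f1", "f2"), samples = names(lab))
  clf <- train_centroid(m, lab, c("f1", "f2"))
  # feature means 3, sd sqrt(20/3); class means at standardized (1,1), (5,5)
  sdv <- sd(c(0, 2, 4, 6))
  expect_equal(unname(clf$centroid_high), rep((1 - 3) / sdv, 2))
  expect_equal(unname(clf$centroid_low), rep((5 - 3) / sdv, 2))

  # duplicating every training sample leaves the raw-space class centroids
  # unchanged (the sample SD shrinks, so compare after de-standardizing)
  m2 <- cbind(m, m)
  colnames(m2) <- c(names(lab), paste0(names(lab), "x"))
  lab2 <- make_labels(colnames(m2), rep(lab, 2))
  clf2 <- train_centroid(m2, lab2, c("f1", "f2"))
  raw_centroid <- function(cc, which_c) cc$center + cc$scale * cc[[which_c]]
  expect_equal(raw_centroid(clf2, "centroid_high"),
               raw_centroid(clf, "centroid_high"))
  expect_equal(raw_centroid(clf2, "centroid_low"),
               raw_centroid(clf, "centroid_low"))

  expect_error(train_centroid(m, lab[1:2], c("f1", "f2")), "both classes")
})

test_that("centroid prediction uses the distance-difference score", {
  lab <- make_labels(c("a", "b", "c", "d"),
                     c("high_risk", "high_risk", "low_risk", "low_risk"))
  m <- toy_matrix(t(rbind(c(0, 0), c(2, 2), c(4, 4), c(6, 6))),
                  genes = c("f1", "f2"), samples = names(lab))
  clf <- train_centroid(m, lab, c("f1", "f2"))
  at_high <- predict_centroid(clf, c(f1 = 1, f2 = 1))
  expect_equal(at_high$label, "high_risk")
  expect_gt(at_high$score, 0)
  at_low <- predict_centroid(clf, c(f1 = 5, f2 = 5))
  expect_equal(at_low$label, "low_risk")
  tie <- predict_centroid(clf, c(f1 = 3, f2 = 3))
  expect_equal(tie$score, 0)
  expect_equal(tie$label, "low_risk")  # tie rule
  expect_error(predict_centroid(clf, c(zz = 1)), "no classifier features")
})

test_that("LOOCV matches a fold-by-fold oracle and never leaks", {
  set.seed(77)
  n <- 12
  lab <- make_labels(sprintf("s%02d", 1:n),
                     rep(c("high_risk", "low_risk"), each = n / 2))
  m <- toy_matrix(matrix(rnorm(4 * n), 4, n), samples = names(lab))
  cv <- loocv_metrics(m, lab, rownames(m))
  # independent fold-by-fold oracle
  for (i in seq_len(n)) {
    clf <- train_centroid(m[, -i, drop = FALSE], lab[-i], rownames(m))
    pr <- predict_centroid(clf, m[, i])
    expect_equal(unname(cv$predictions[i]), pr$label)
    expect_equal(unname(cv$scores[i]), pr$score)
  }
  # leakage: a fold's model never sees its held-out sample, so perturbing
  # sample 3 leaves fold 3's model identical to one fit without sample 3
  m2 <- m
  m2[, 3] <- m2[, 3] + 100
  cv2 <- loocv_metrics(m2, lab, rownames(m))
  clf3 <- train_centroid(m[, -3, drop = FALSE], lab[-3], rownames(m))
  expect_equal(unname(cv2$scores[3]), predict_centroid(clf3, m2[, 3])$score)

  # perfectly separated classes reach ACC 1
  m3 <- m
  m3[1, ] <- ifelse(lab == "high_risk", 50, -50) + rnorm(n, sd = 0.1)
  expect_equal(loocv_metrics(m3, lab, "g01")$acc, 1)

  # label-independent features stay near chance for n = 40 balanced
  set.seed(123)
  n4 <- 40
  lab4 <- make_labels(sprintf("t%02d", 1:n4),
                      rep(c("high_risk", "low_risk"), each = n4 / 2))
  m4 <- toy_matrix(matrix(rnorm(6 * n4), 6, n4), samples = names(lab4))
  acc4 <- loocv_metrics(m4, lab4, rownames(m4))$acc
  expect_gte(acc4, 0.3)
  expect_lte(acc4, 0.7)
})

test_that("ensemble assembly filters sub-classifiers by LOOCV accuracy", {
  set.seed(99)
  n <- 40
  lab <- make_labels(sprintf("s%02d", 1:n),
                     rep(c("high_risk", "low_risk"), each = n / 2))
  m <- toy_matrix(matrix(rnorm(12 * n), 12, n), samples = names(lab))
  # genes 1-4 strongly predictive; 5-8 weakly; 9-12 noise
  for (g in 1:4) m[g, ] <- ifelse(lab == "high_risk", 3, 0) + rnorm(n, sd = .5)
  comms <- list(
    structure(list(members = sprintf("g%02d", 1:4), score = 3, rank = 1L),
              class = "community"),
    structure(list(members = sprintf("g%02d", 9:12), score = 2, rank = 2L),
              class = "community"),
    structure(list(members = "g05", score = 1, rank = 3L),
              class = "community")  # < 2 usable genes: skipped
  )
  cands <- build_sub_classifiers(m, lab, comms)
  expect_length(cands, 2)
  expect_gt(cands[[1]]$loocv_acc, 0.9)

  model0 <- build_ensemble(list(`1` = list(matrix = m, labels = lab)),
                           list(`1` = comms), acc_threshold = 0)
  expect_length(model0$subtype_models[["1"]], 2)  # threshold 0 keeps all
  expect_error(
    build_ensemble(list(`1` = list(matrix = m, labels = lab)),
                   list(`1` = comms), acc_threshold = 1.01),
    "relax"
  )
  model <- build_ensemble(list(`1` = list(matrix = m, labels = lab)),
                          list(`1` = comms), acc_threshold = 0.9)
  expect_length(model$subtype_models[["1"]], 1)
})

test_that("ensemble voting follows the majority rule with high-risk ties", {
  mk_sub <- function(label) {
    # classifier that always votes `label`: centroids placed asymmetrically
    clf <- structure(list(
      features = "gX",
      center = c(gX = 0), scale = c(gX = 1),
      centroid_high = c(gX = if (label == "high_risk") 0 else 100),
      centroid_low = c(gX = if (label == "high_risk") 100 else 0)
    ), class = "centroid_classifier")
    structure(list(community = NULL, classifier = clf, loocv_acc = 1),
              class = "sub_classifier")
  }
  model <- structure(list(
    subtype_models = list(`1` = list(mk_sub("high_risk"), mk_sub("high_risk"),
                                     mk_sub("low_risk"))),
    acc_threshold = 0, subtype_assigner = NULL
  ), class = "ensemble_model")
  pr <- ensemble_predict(model, c(gX = 0), subtype = 1)
  expect_equal(pr$label, "high_risk")
  expect_equal(pr$vote_fraction, 2 / 3)

  model$subtype_models[["1"]] <- list(mk_sub("low_risk"), mk_sub("low_risk"))
  pr2 <- ensemble_predict(model, c(gX = 0), subtype = 1)
  expect_equal(pr2$label, "low_risk")
  expect_equal(pr2$vote_fraction, 0)

  model$subtype_models[["1"]] <- list(mk_sub("high_risk"), mk_sub("low_risk"))
  pr3 <- ensemble_predict(model, c(gX = 0), subtype = 1)
  expect_equal(pr3$vote_fraction, 0.5)
  expect_equal(pr3$label, "high_risk")  # even split counts as high-risk

  expect_error(ensemble_predict(model, c(gX = 0), subtype = 9),
               "no sub-classifiers")
})

test_that("control classifier scans top-n feature sets", {
  set.seed(55)
  n <- 30
  lab <- make_labels(sprintf("s%02d", 1:n),
                     rep(c("high_risk", "low_risk"), each = n / 2))
  m <- toy_matrix(matrix(rnorm(15 * n), 15, n), samples = names(lab))
  m[1, ] <- ifelse(lab == "high_risk", 4, 0) + rnorm(n, sd = 0.5)
  ctrl1 <- build_control_classifier(m, lab, n_max = 1)
  expect_equal(ctrl1$best_n, 1)
  expect_equal(ctrl1$classifier$features, ctrl1$ranking$gene[1])
  expect_warning(
    ctrl <- build_control_classifier(m, lab, n_max = 50),
    "capped"
  )
  expect_equal(nrow(ctrl$scan), 15)
  expect_gte(ctrl$loocv$acc, max(ctrl$scan$acc) - 1e-12)
})

test_that("noise features beyond the signal do not inflate LOOCV accuracy", {
  gains <- numeric(20)
  for (s in 1:20) {
    set.seed(400 + s)
    n <- 40
    lab <- make_labels(sprintf("s%02d", 1:n),
                       rep(c("high_risk", "low_risk"), each = n / 2))
    m <- toy_matrix(matrix(rnorm(30 * n), 30, n), samples = names(lab))
    for (g in 1:3)
      m[g, lab == "high_risk"] <- m[g, lab == "high_risk"] + 2
    rk <- rank_genes(m, lab)
    acc_signal <- loocv_metrics(m, lab, rk$gene[1:3])$acc
    acc_padded <- loocv_metrics(m, lab, rk$gene[1:20])$acc
    gains[s] <- acc_padded - acc_signal
  }
  expect_lte(mean(gains), 0.05)
})
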