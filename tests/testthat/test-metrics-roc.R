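test_that("Cohen's kappa matches its closed form and edge conventions", {
  expect_equal(cohen_kappa(list(tp = 10, fn = 0, fp = 0, tn = 15)), 1)
  # constant prediction: agreement is pure chance
  expect_equal(cohen_kappa(list(tp = 7, fn = 0, fp = 26, tn = 0)), 0)
  k <- cohen_kappa(list(tp = 6, fn = 1, fp = 2, tn = 24))
  expect_equal(k, (30 / 33 - 706 / 1089) / (1 - 706 / 1089))
  expect_equal(round(k, 4), 0.7415)
})

test_that("kappa equals the brute-force agreement statistic on all small tables", {
  # independent oracle: expand each table to label/prediction vectors and use
  # e1071's agreement computation
  for (n in 2:12) {
    tabs <- expand.grid(tp = 0:n, fn = 0:n, fp = 0:n)
    tabs$tn <- n - tabs$tp - tabs$fn - tabs$fp
    tabs <- tabs[tabs$tn >= 0, ]
    for (i in seq_len(nrow(tabs))) {
      cm <- as.list(tabs[i, ])
      truth <- rep(c("m", "m", "w", "w"),
                   c(cm$tp, cm$fn, cm$fp, cm$tn))
      call <- rep(c("m", "w", "m", "w"),
                  c(cm$tp, cm$fn, cm$fp, cm$tn))
      tab <- table(factor(truth, c("m", "w")), factor(call, c("m", "w")))
      oracle <- e1071::classAgreement(tab)$kappa
      ours <- cohen_kappa(cm)
      if (is.nan(oracle)) {
        expect_equal(ours, 0)  # our degenerate-table convention
      } else {
        expect_equal(ours, oracle, tolerance = 1e-12)
      }
    }
  }
})

test_that("confusion metrics obey their definitions and symmetries", {
  m <- metrics_from_confusion(list(tp = 6, fn = 1, fp = 2, tn = 24))
  expect_equal(m$sensitivity, 100 * 6 / 7)
  expect_equal(m$specificity, 100 * 24 / 26)
  expect_equal(m$balanced_accuracy, (m$sensitivity + m$specificity) / 2)

  sym <- metrics_from_confusion(list(tp = 5, fn = 3, fp = 3, tn = 5))
  expect_equal(sym$sensitivity, sym$specificity)

  # with 7 positives in the test set one flipped call moves sensitivity by
  # 100/7 ~ 14.3 points
  a <- metrics_from_confusion(list(tp = 6, fn = 1, fp = 2, tn = 24))
  b <- metrics_from_confusion(list(tp = 5, fn = 2, fp = 2, tn = 24))
  expect_equal(a$sensitivity - b$sensitivity, 100 / 7)

  expect_error(metrics_from_confusion(list(tp = 0, fn = 0, fp = 2, tn = 4)),
               "absent")
})

test_that("presentation rounding is half-up at one decimal", {
  expect_equal(round_half_up((82.4 + 83.4) / 2), 82.9)
  expect_equal(round_half_up((75.5 + 62.6) / 2), 69.1)  # 69.05 rounds up
  expect_equal(round_half_up(0.25, 1), 0.3)
})

test_that("kappa-optimal threshold matches an exhaustive sweep", {
  # clean separation: kappa = 1 on a plateau, tie broken toward 0.5
  out <- select_threshold_kappa(c(0.1, 0.2, 0.8, 0.9),
                                c("wildtype", "wildtype", "mutated",
                                  "mutated"))
  expect_equal(out$threshold, 0.5)
  expect_equal(out$kappa, 1)

  one_each <- select_threshold_kappa(c(0.3, 0.7), c("wildtype", "mutated"))
  expect_equal(one_each$kappa, 1)
  expect_gt(one_each$threshold, 0.3)
  expect_lt(one_each$threshold, 0.7)

  # label-independent scores: compare against a brute-force sweep oracle
  set.seed(14)
  scores <- runif(400)
  labels <- sample(rep(c("mutated", "wildtype"), 200))
  ours <- select_threshold_kappa(scores, labels)
  u <- sort(unique(scores))
  cands <- unique(c(0, (u[-1] + u[-length(u)]) / 2, 1))
  brute <- vapply(cands, function(p) {
    tab <- table(factor(labels, c("mutated", "wildtype")),
                 factor(ifelse(scores >= p, "mutated", "wildtype"),
                        c("mutated", "wildtype")))
    e1071::classAgreement(tab)$kappa
  }, numeric(1))
  expect_equal(ours$kappa, max(brute), tolerance = 1e-12)
  expect_lt(abs(ours$kappa), 0.25)  # near-chance by construction

  expect_error(select_threshold_kappa(rep(0.4, 6),
                                      rep(c("mutated", "wildtype"), 3)),
               "constant")
})

test_that("ROC endpoints, AUC and annotations behave as specified", {
  sep <- roc_curve(c(0.9, 0.8, 0.2, 0.1),
                   c("mutated", "mutated", "wildtype", "wildtype"))
  expect_equal(sep$auc, 1)

  flat <- roc_curve(rep(0.5, 10), rep(c("mutated", "wildtype"), 5))
  expect_equal(flat$auc, 0.5)

  set.seed(16)
  scores <- runif(1000)
  labels <- sample(rep(c("mutated", "wildtype"), 500))
  rnd <- roc_curve(scores, labels)
  expect_lt(abs(rnd$auc - 0.5), 0.05)

  # AUC is invariant under strictly monotone transforms of the scores
  warped <- roc_curve(plogis(5 * scores - 2), labels)
  expect_equal(rnd$auc, warped$auc, tolerance = 1e-12)

  # independent oracle on a smaller sweep
  if (requireNamespace("pROC", quietly = TRUE)) {
    s2 <- c(0.1, 0.3, 0.35, 0.4, 0.6, 0.65, 0.8, 0.9)
    l2 <- c("wildtype", "wildtype", "mutated", "wildtype", "mutated",
            "wildtype", "mutated", "mutated")
    ours <- roc_curve(s2, l2)$auc
    oracle <- as.numeric(pROC::auc(pROC::roc(
      response = l2, predictor = s2, levels = c("wildtype", "mutated"),
      direction = "<", quiet = TRUE)))
    expect_equal(ours, oracle, tolerance = 1e-12)
  }

  # annotations: A maximises sensitivity, B specificity, C the balance,
  # all within the 70% target region when attainable
  set.seed(17)
  good <- c(rnorm(60, 0.7, 0.12), rnorm(60, 0.3, 0.12))
  glab <- rep(c("mutated", "wildtype"), each = 60)
  rc <- roc_curve(good, glab)
  ann <- rc$annotations
  expect_true(all(ann$sensitivity >= 70 & ann$specificity >= 70,
                  na.rm = TRUE))
  expect_gte(ann$sensitivity[ann$point == "A"],
             ann$sensitivity[ann$point == "B"])
  expect_gte(ann$specificity[ann$point == "B"],
             ann$specificity[ann$point == "A"])

  expect_error(roc_curve(c(0.2, 0.4), c("mutated", "mutated")),
               "both classes")
})

test_that("vertical ROC averaging is idempotent and unbiased", {
  set.seed(18)
  scores <- c(rnorm(40, 0.65, 0.15), rnorm(40, 0.35, 0.15))
  labels <- rep(c("mutated", "wildtype"), each = 40)
  rc <- roc_curve(scores, labels)

  same <- mean_roc(list(rc, rc, rc))
  one <- mean_roc(list(rc))
  expect_equal(same$points$sensitivity, one$points$sensitivity)
  # single curve survives interpolation to within 0.005 AUC
  expect_lt(abs(one$auc - rc$auc), 0.005)

  # negated scores reflect the curve through the centre (AUC a vs 1 - a);
  # their vertical average is the chance diagonal
  rc_mirror <- roc_curve(1 - scores, labels)
  m <- mean_roc(list(rc, rc_mirror))
  expect_lt(abs(m$auc - 0.5), 0.02)
})
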