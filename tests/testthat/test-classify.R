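split_meta <- function(n_mut, n_wt) {
  tibble::tibble(
    spectrum_id = paste0("s", seq_len(n_mut + n_wt)),
    group_id = paste0("g", seq_len(n_mut + n_wt)),
    class_label = rep(c("mutated", "wildtype"), c(n_mut, n_wt))
  )
}

test_that("grouped splits are stratified, disjoint and deterministic", {
  plan <- grouped_split(split_meta(5, 5), 0.7, seed = 3)
  expect_length(plan$train_groups, 7L)
  expect_length(plan$test_groups, 3L)
  expect_length(intersect(plan$train_groups, plan$test_groups), 0L)
  expect_identical(grouped_split(split_meta(5, 5), 0.7, seed = 3), plan)

  # 33 mutated + 66 wildtype at 70:30 -> test side 10 + 20
  big <- grouped_split(split_meta(33, 66), 0.7, seed = 1)
  cls <- rep(c("mutated", "wildtype"), c(33, 66))
  names(cls) <- paste0("g", 1:99)
  expect_equal(sum(cls[big$test_groups] == "mutated"), 10L)
  expect_equal(sum(cls[big$test_groups] == "wildtype"), 20L)

  expect_error(grouped_split(split_meta(1, 5)), ">= 2 groups")
})

test_that("no group ever appears on both sides across many resamples", {
  meta <- split_meta(8, 12)
  for (s in 1:25) {
    plan <- grouped_split(meta, 0.7, seed = s)
    expect_length(intersect(plan$train_groups, plan$test_groups), 0L)
    cls <- setNames(meta$class_label, meta$group_id)
    expect_setequal(unique(cls[plan$train_groups]),
                    c("mutated", "wildtype"))
    expect_setequal(unique(cls[plan$test_groups]),
                    c("mutated", "wildtype"))
  }
})

test_that("sampling balances classes exactly as specified", {
  set.seed(2)
  x <- matrix(rnorm(40 * 6), 40, 6)
  labels <- rep(c("wildtype", "mutated"), c(30, 10))

  up <- apply_sampling(x, labels, "up", seed = 1)
  expect_equal(unname(table(up$labels)), c(30L, 30L), ignore_attr = TRUE)
  new_rows <- up$x[41:nrow(up$x), , drop = FALSE]
  orig_min <- x[labels == "mutated", ]
  expect_true(all(apply(new_rows, 1, function(r) {
    any(apply(orig_min, 1, function(o) isTRUE(all.equal(r, o))))
  })))

  down <- apply_sampling(x, labels, "down", seed = 1)
  expect_equal(unname(table(down$labels)), c(10L, 10L), ignore_attr = TRUE)
  kept_maj <- down$x[down$labels == "wildtype", ]
  expect_true(all(kept_maj %in% x[labels == "wildtype", ]))

  sm <- apply_sampling(x, labels, "smote", seed = 1)
  expect_equal(unname(table(sm$labels)), c(30L, 30L), ignore_attr = TRUE)
  synth <- sm$x[41:nrow(sm$x), , drop = FALSE]
  # every synthetic point lies on a segment between two minority rows:
  # residual after projecting onto the best segment is ~0
  seg_resid <- apply(synth, 1, function(p) {
    min(apply(utils::combn(nrow(orig_min), 2), 2, function(ij) {
      a <- orig_min[ij[1], ]; b <- orig_min[ij[2], ]
      v <- b - a
      t_ <- sum((p - a) * v) / sum(v^2)
      if (!is.finite(t_)) return(Inf)
      sqrt(sum((a + max(0, min(1, t_)) * v - p)^2))
    }))
  })
  expect_lt(max(seg_resid), 1e-9)

  expect_error(apply_sampling(x[c(1, 31), ], labels[c(1, 31)], "smote"),
               "minority")
})

test_that("all four families separate well-separated clouds perfectly", {
  set.seed(4)
  n <- 30
  x <- rbind(matrix(rnorm(n * 8, 0), n, 8), matrix(rnorm(n * 8, 6), n, 8))
  labels <- rep(c("wildtype", "mutated"), each = n)
  for (fam in c("lda", "plsda", "rf", "svm")) {
    model <- train_classifier(x, labels, classifier_spec(fam), seed = 1)
    prob <- predict(model, x)
    expect_true(all(prob >= 0 & prob <= 1))
    acc <- mean((prob > 0.5) == (labels == "mutated"))
    expect_gte(acc, 0.99)
  }
})

test_that("shrinkage LDA tolerates duplicated features without changing calls", {
  set.seed(6)
  x <- rbind(matrix(rnorm(25 * 5, 0), 25, 5), matrix(rnorm(25 * 5, 2), 25, 5))
  labels <- rep(c("wildtype", "mutated"), each = 25)
  xdup <- cbind(x, x)  # singular pooled covariance without shrinkage
  m1 <- train_classifier(x, labels, classifier_spec("lda"))
  m2 <- train_classifier(xdup, labels, classifier_spec("lda"))
  p1 <- predict(m1, x)
  p2 <- predict(m2, xdup)
  # the automatic shrinkage intensity differs between the two designs, so
  # probabilities agree up to that regularisation, not bitwise
  expect_gt(cor(p1, p2), 0.95)
  expect_gte(mean((p1 > 0.5) == (p2 > 0.5)), 0.9)
})

test_that("permuted labels give chance-level out-of-sample accuracy", {
  set.seed(8)
  x <- matrix(rnorm(200 * 100), 200, 100)
  labels <- sample(rep(c("mutated", "wildtype"), each = 100))
  model <- train_classifier(x[1:140, ], labels[1:140],
                            classifier_spec("lda"))
  prob <- predict(model, x[141:200, ])
  call <- ifelse(prob >= 0.5, "mutated", "wildtype")
  cm <- confusion_matrix(labels[141:200], call)
  ba <- metrics_from_confusion(cm)$balanced_accuracy
  expect_gt(ba, 30)
  expect_lt(ba, 70)
})

test_that("group aggregation votes, scores and breaks ties as documented", {
  meta9 <- tibble::tibble(spectrum_id = paste0("s", 1:9),
                          group_id = "patientA", class_label = "mutated")
  probs <- c(0.8, 0.7, 0.9, 0.6, 0.75, 0.2, 0.1, 0.3, 0.4)  # 5 of 9 above p
  g <- aggregate_group(probs, meta9, mode = "majority_vote", threshold = 0.5)
  expect_equal(g$call, "mutated")
  expect_equal(g$n_member_spectra, 9L)
  expect_equal(g$vote_fraction, 5 / 9)
  expect_equal(g$score, mean(probs))

  # all probabilities exactly at p: tie resolved by mean_prob >= p
  tie <- aggregate_group(rep(0.5, 4), meta9[1:4, ], mode = "majority_vote",
                         threshold = 0.5)
  expect_equal(tie$call, "mutated")

  single <- aggregate_group(0.3, meta9[1, ], mode = "majority_vote",
                            threshold = 0.5)
  expect_equal(single$call, "wildtype")

  two <- tibble::tibble(spectrum_id = c("a", "b"), group_id = c("g1", "g2"),
                        class_label = c("mutated", "wildtype"))
  m <- aggregate_group(c(0.9, 0.2), two, mode = "mean_prob",
                       threshold = 0.5)
  expect_equal(m$call[m$group_id == "g1"], "mutated")
  expect_equal(m$call[m$group_id == "g2"], "wildtype")

  expect_error(aggregate_group(numeric(0), meta9[0, ]), "empty")
  expect_error(aggregate_group(c(0.5), meta9[1:2, ]), "group assignment")
})

test_that("Gini importance ranks an informative feature first", {
  set.seed(10)
  n <- 120
  labels <- rep(c("mutated", "wildtype"), each = n / 2)
  x <- matrix(rnorm(n * 12), n, 12)
  x[, 7] <- x[, 7] + ifelse(labels == "mutated", 2.5, 0)
  grid <- seq(1744, 1700, by = -4)
  model <- train_classifier(x, labels, classifier_spec("rf", ntree = 300),
                            seed = 2)
  imp <- gini_importance(model, grid, top_k = 12)
  expect_equal(imp$wavenumber[1], grid[7])
  expect_equal(imp$rank, seq_len(12))
  expect_true(all(diff(imp$sum_gini) <= 0))
  # nearest-assignment annotation: 1744 is within 12 cm-1 of the 1740.5 row
  expect_match(imp$assignment[imp$wavenumber == 1744], "Lipids")

  lda <- train_classifier(x, labels, classifier_spec("lda"))
  expect_error(gini_importance(lda, grid), "random forest")
})

test_that("all-noise forests spread importance without a dominant feature", {
  set.seed(12)
  x <- matrix(rnorm(150 * 10), 150, 10)
  labels <- sample(rep(c("mutated", "wildtype"), 75))
  model <- train_classifier(x, labels, classifier_spec("rf", ntree = 300),
                            seed = 3)
  imp <- gini_importance(model, seq(1736, 1700, by = -4), top_k = 10)
  expect_lt(max(imp$sum_gini), 3 * mean(imp$sum_gini))
})
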