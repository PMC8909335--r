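test_that("subset plans are balanced, seeded and exhaustive over the minority", {
  set.seed(1)
  labels <- factor(rep(c("recurrence", "nonrecurrence"), c(28, 55)))
  plan <- make_subset_plan(labels, seed = 5L)
  expect_length(plan, 7L)
  for (s in plan) {
    expect_length(s, 56L)
    expect_equal(sum(labels[s] == "recurrence"), 28L)
    expect_equal(sum(labels[s] == "nonrecurrence"), 28L)
    expect_false(anyDuplicated(s) > 0)
  }
  expect_identical(plan, make_subset_plan(labels, seed = 5L))
  expect_false(identical(plan[[1]], make_subset_plan(labels, seed = 6L)[[1]]))
  ## already balanced: each subset is the full cohort
  bal <- factor(rep(c("recurrence", "nonrecurrence"), c(10, 10)))
  expect_true(all(vapply(make_subset_plan(bal, seed = 1L), length, 1L) == 20L))
  expect_error(make_subset_plan(factor(rep("a", 5))), "two non-empty")
})

test_that("LOPO ensemble predicts a separable feature perfectly, never ties", {
  rows <- simulate_feature_cohort(12, 18, seed = 3L)
  set.seed(99)
  rows[["ACE_W0"]] <- ifelse(rows$label == "recurrence", 5, -5) +
    rnorm(30, 0, 0.1)
  for (cl in c("knn", "svm")) {
    preds <- lopo_predict(rows, "ACE_W0",
                          classifier_config(classifier = cl), seed = 2L)
    expect_true(all(preds$pred == preds$label))
    cv <- evaluate_predictions(preds, n_boot = 200L)
    expect_equal(cv$metrics[["auc"]], 1)
    expect_equal(cv$metrics[["accuracy"]], 100)
    ## 7 voters: vote fractions never 0.5
    expect_false(any(preds$score == 0.5))
  }
  expect_error(lopo_predict(rows, "NOPE"), "not present")
})

test_that("permuted labels drive LOPO AUC to chance", {
  rows <- simulate_feature_cohort(10, 20, seed = 8L)
  aucs <- sapply(1:20, function(i) {
    set.seed(100 + i)
    perm <- rows
    perm$label <- sample(perm$label)
    preds <- lopo_predict(perm, c("ACE_W0", "dMBF"), seed = i)
    evaluate_predictions(preds, n_boot = 2L)$metrics[["auc"]]
  })
  expect_gt(mean(aucs), 0.38)
  expect_lt(mean(aucs), 0.62)
})

test_that("metrics arithmetic, AUC oracle and label-flip symmetry", {
  ## TP 3, FN 1, TN 4, FP 2 -> Sn 75, Sp 66.7, Acc 70
  lab <- factor(rep(c("recurrence", "nonrecurrence"), c(4, 6)))
  pred <- factor(c("recurrence", "recurrence", "recurrence", "nonrecurrence",
                   "recurrence", "recurrence", rep("nonrecurrence", 4)),
                 levels = levels(lab))
  set.seed(2)
  score <- c(runif(4, 0.5, 1), runif(6, 0, 0.6))
  preds <- data.frame(label = lab, pred = pred, score = score)
  cv <- evaluate_predictions(preds, n_boot = 100L)
  expect_equal(cv$metrics[["sensitivity"]], 75)
  expect_equal(cv$metrics[["specificity"]], 100 * 4 / 6)
  expect_equal(cv$metrics[["accuracy"]], 70)
  expect_equal(unname(cv$confusion), c(3, 2, 1, 4))
  ## AUC equals the all-pairs oracle, including ties
  score2 <- c(0.9, 0.7, 0.7, 0.2, 0.7, 0.4, 0.4, 0.1, 0.2, 0.3)
  preds2 <- data.frame(label = lab, pred = pred, score = score2)
  cv2 <- evaluate_predictions(preds2, n_boot = 2L)
  expect_equal(cv2$metrics[["auc"]], oracle_auc(score2, lab == "recurrence"))
  ## label flip: Sn <-> Sp, AUC -> 1 - AUC
  flip <- function(f) factor(ifelse(f == "recurrence", "nonrecurrence",
                                    "recurrence"), levels = levels(lab))
  cv3 <- evaluate_predictions(
    data.frame(label = flip(lab), pred = flip(pred), score = score2),
    n_boot = 2L)
  expect_equal(cv3$metrics[["sensitivity"]], cv2$metrics[["specificity"]])
  expect_equal(cv3$metrics[["specificity"]], cv2$metrics[["sensitivity"]])
  expect_equal(cv3$metrics[["auc"]], 1 - cv2$metrics[["auc"]])
  ## CI bounds bracket the point estimates
  expect_true(all(cv$ci[, "lower"] <= cv$ci[, "upper"]))
  expect_error(evaluate_predictions(
    data.frame(label = factor(rep("recurrence", 4), levels(lab)),
               pred = pred[1:4], score = score[1:4])), "single class")
})

test_that("forward selection finds injected signal and matches exhaustive search", {
  rows <- simulate_feature_cohort(12, 20, effect = c("ACE_W0" = 3), seed = 5L)
  fit <- qus_model(rows, candidates = c("ACE_W0", "dMBF", "dSS", "SI_W0"),
                   seed = 4L)
  expect_equal(fit$selected[1], "ACE_W0")
  expect_lte(length(fit$selected), 3L)
  expect_s3_class(fit$cv, "qus_cv")

  ## max_features = 1 equals brute-force single-feature search
  cands <- c("dMBF", "ACE_W0")
  fit1 <- qus_model(rows, classifier_config(max_features = 1L),
                    candidates = cands, seed = 9L)
  plan <- make_subset_plan(rows$label, seed = 9L)
  bacc <- sapply(cands, function(f) {
    p <- lopo_predict(rows, f, plan = plan)
    pos <- p$label == "recurrence"
    (mean(p$pred[pos] == "recurrence") + mean(p$pred[!pos] == "nonrecurrence")) / 2
  })
  expect_equal(fit1$selected, names(which.max(bacc)))

  ## determinism of the whole CV result
  fit2 <- qus_model(rows, candidates = c("ACE_W0", "dMBF", "dSS", "SI_W0"),
                    seed = 4L)
  expect_identical(fit$preds, fit2$preds)
  expect_identical(fit$cv$metrics, fit2$cv$metrics)
})

test_that("fitted ensemble predicts new patients consistently", {
  rows <- simulate_feature_cohort(12, 20, effect = c("ACE_W0" = 4), seed = 6L)
  fit <- qus_model(rows, candidates = c("ACE_W0", "dMBF"), seed = 2L)
  new <- simulate_feature_cohort(5, 5, effect = c("ACE_W0" = 4), seed = 7L)
  pred <- predict(fit, new)
  score <- predict(fit, new, type = "score")
  expect_length(pred, 10L)
  expect_true(all(score >= 0 & score <= 1))
  expect_gt(mean(pred == new$label), 0.7)
  expect_error(predict(fit, new[, 1:4]), "lacks")
})

test_that("tier comparison reports one row per tier and classifier", {
  rows <- simulate_feature_cohort(10, 14, effect = c("ACE_W0" = 3), seed = 3L)
  cmp <- compare_feature_sets(rows, tiers = c("qus_tex1", "all"),
                              classifiers = "knn", seed = 2L)
  expect_equal(nrow(cmp), 2L)
  expect_s3_class(cmp, "data.frame")
  expect_true(all(c("sensitivity", "specificity", "accuracy", "auc") %in%
                    names(cmp)))
  expect_length(attr(cmp, "models"), 2L)
})

test_that("univariate screening switches tests on normality and finds shifts", {
  set.seed(10)
  n <- 30
  rows <- data.frame(
    label = factor(rep(c("recurrence", "nonrecurrence"), each = n)),
    shifted = c(rnorm(n, 2), rnorm(n, 0)),       # d = 2: strong signal
    skewed = c(rexp(n), rexp(n)),                # non-normal -> Mann-Whitney
    same = rep(rnorm(n), 2),                     # identical values -> p = 1
    flat = rep(1, 2 * n))                        # zero variance -> sentinel
  sc <- univariate_screen(rows)
  expect_equal(sc$p_value[sc$feature == "same"], 1)
  expect_lt(sc$p_value[sc$feature == "shifted"], 0.05)
  expect_equal(sc$test[sc$feature == "skewed"], "mann-whitney")
  expect_equal(sc$test[sc$feature == "flat"], "degenerate")
  expect_equal(sc$p_value[sc$feature == "flat"], 1)

  ## hand-computed pooled-variance t statistic on a 3+3 toy
  a <- c(1, 2, 3); b <- c(4, 6, 8)
  sp2 <- (2 * var(a) + 2 * var(b)) / 4
  t_hand <- (mean(a) - mean(b)) / sqrt(sp2 * (2 / 3))
  p_hand <- 2 * pt(abs(t_hand), df = 4, lower.tail = FALSE)
  toy <- data.frame(label = factor(rep(c("recurrence", "nonrecurrence"),
                                       each = 3)),
                    x = c(a, b))
  expect_equal(univariate_screen(toy)$p_value, p_hand, tolerance = 1e-12)
})
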