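## Class-imbalance-aware classification protocol: seven class-balanced
## training subsets with majority voting (k-NN or RBF-SVM base learners),
## greedy forward feature selection capped at three features, and
## leave-one-patient-out cross-validation.  The vote fraction (votes for the
## positive class / number of subsets) is the ROC score.

model_meta_cols <- c("patient_id", "label", "time", "event")

split_rows <- function(rows) {
  stopifnot(is.data.frame(rows), "label" %in% names(rows))
  feats <- setdiff(names(rows), model_meta_cols)
  X <- as.matrix(rows[, feats, drop = FALSE])
  storage.mode(X) <- "double"
  y <- factor(rows$label)
  list(X = X, y = y, features = feats)
}

positive_class <- function(y) {
  if ("recurrence" %in% levels(y)) "recurrence" else levels(y)[nlevels(y)]
}

#' Balanced training-subset plan
#'
#' Builds `n_subsets` class-balanced index sets: each contains every
#' minority-class patient plus an equal-size draw (without replacement,
#' independent across subsets) from the majority class.
#'
#' @param labels Factor of class labels.
#' @param n_subsets Number of subsets (odd, so majority votes cannot tie).
#' @param seed Integer seed.
#' @return List of `n_subsets` integer index vectors; attribute `seed`.
#' @export
make_subset_plan <- function(labels, n_subsets = 7L, seed = 1L) {
  labels <- factor(labels)
  tab <- table(labels)
  if (any(tab == 0) || nlevels(labels) != 2L)
    stop("need two non-empty classes", call. = FALSE)
  minority <- names(tab)[which.min(tab)]
  idx_min <- which(labels == minority)
  idx_maj <- which(labels != minority)
  old <- .Random.seed_exists()
  set.seed(derive_seed(seed, 41L))
  on.exit(.Random.seed_restore(old), add = TRUE)
  plan <- lapply(seq_len(n_subsets), function(s)
    sort(c(idx_min, sample(idx_maj, length(idx_min)))))
  attr(plan, "seed") <- seed
  plan
}

## deterministic k-NN vote: ties in distance broken by lowest training index
knn_vote <- function(Ztr, ytr_pos, z, k) {
  d2 <- (Ztr[, 1] - z[1])^2
  if (length(z) > 1) for (j in 2:length(z)) d2 <- d2 + (Ztr[, j] - z[j])^2
  nn <- order(d2)[seq_len(min(k, length(d2)))]
  mean(ytr_pos[nn]) > 0.5
}

fold_standardize <- function(X, i, col_sums, col_sq) {
  n <- nrow(X)
  mu <- (col_sums - X[i, ]) / (n - 1)
  v <- (col_sq - X[i, ]^2 - (n - 1) * mu^2) / (n - 2)
  sd <- sqrt(pmax(v, 0))
  sd[sd < 1e-12] <- 1
  list(mu = mu, sd = sd)
}

## Leave-one-patient-out ensemble votes for a fixed feature set.
lopo_votes <- function(X, y, plan, config) {
  n <- nrow(X)
  pos <- positive_class(y)
  y_pos <- y == pos
  k <- config$k
  col_sums <- colSums(X)
  col_sq <- colSums(X^2)
  votes <- integer(n)
  n_sub <- length(plan)
  for (i in seq_len(n)) {
    st <- fold_standardize(X, i, col_sums, col_sq)
    Z <- sweep(sweep(X, 2, st$mu), 2, st$sd, `/`)
    zi <- Z[i, ]
    v <- 0L
    for (s in seq_len(n_sub)) {
      tr <- plan[[s]]
      tr <- tr[tr != i]
      if (config$classifier == "knn") {
        if (knn_vote(Z[tr, , drop = FALSE], y_pos[tr], zi, k)) v <- v + 1L
      } else {
        fit <- e1071::svm(Z[tr, , drop = FALSE], factor(y_pos[tr], c(FALSE, TRUE)),
                          kernel = "radial", cost = config$cost,
                          gamma = config$gamma %||% (1 / ncol(X)),
                          scale = FALSE)
        if (as.logical(as.character(stats::predict(
          fit, matrix(zi, 1))))) v <- v + 1L
      }
    }
    votes[i] <- v
  }
  list(votes = votes, n_subsets = n_sub, positive = pos,
       score = votes / n_sub, pred = votes / n_sub > 0.5)
}

#' Leave-one-patient-out prediction with the balanced-subset ensemble
#'
#' For each held-out patient, feature standardisation statistics are
#' computed on the remaining patients only, the ensemble's balanced subsets
#' (with the held-out patient removed) each train one classifier, and the
#' predicted label is the majority of their votes; the vote fraction is the
#' continuous score.
#'
#' @param rows Data frame of model rows: a `label` column plus feature
#'   columns (and optionally `patient_id`, `time`, `event`).
#' @param features Character vector of feature names to use.
#' @param config A [classifier_config()].
#' @param plan Subset plan from [make_subset_plan()]; built from `seed` if
#'   missing.
#' @param seed Seed for the subset plan.
#' @return Data frame with `patient_id`, `label`, `votes`, `score`
#'   (vote fraction) and `pred` (factor).
#' @export
lopo_predict <- function(rows, features, config = classifier_config(),
                         plan = NULL, seed = 1L) {
  sp <- split_rows(rows)
  missing_f <- setdiff(features, sp$features)
  if (length(missing_f))
    stop("feature(s) not present in rows: ",
         paste(missing_f, collapse = ", "), call. = FALSE)
  if (min(table(sp$y)) < 2)
    stop("need at least 2 patients per class", call. = FALSE)
  if (is.null(plan)) plan <- make_subset_plan(sp$y, config$n_subsets, seed)
  lv <- lopo_votes(sp$X[, features, drop = FALSE], sp$y, plan, config)
  pred <- factor(ifelse(lv$pred, lv$positive,
                        setdiff(levels(sp$y), lv$positive)),
                 levels = levels(sp$y))
  data.frame(patient_id = rows$patient_id %||% seq_len(nrow(rows)),
             label = sp$y, votes = lv$votes, score = lv$score, pred = pred)
}

auc_rank <- function(scores, is_pos) {
  n1 <- sum(is_pos); n0 <- sum(!is_pos)
  if (n1 == 0 || n0 == 0) stop("AUC needs both classes", call. = FALSE)
  r <- rank(scores, ties.method = "average")
  (sum(r[is_pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

metrics_from <- function(pred_pos, is_pos, scores) {
  tp <- sum(pred_pos & is_pos); fn <- sum(!pred_pos & is_pos)
  tn <- sum(!pred_pos & !is_pos); fp <- sum(pred_pos & !is_pos)
  c(sensitivity = 100 * tp / (tp + fn),
    specificity = 100 * tn / (tn + fp),
    accuracy = 100 * (tp + tn) / length(is_pos),
    auc = auc_rank(scores, is_pos))
}

#' Classification metrics with bootstrap confidence intervals
#'
#' Sensitivity, specificity and accuracy (percent) from the confusion
#' counts, AUC from the mid-rank statistic over the vote-fraction scores,
#' and percentile confidence intervals from a patient-level bootstrap.
#'
#' @param preds Data frame from [lopo_predict()] (columns `label`, `pred`,
#'   `score`), or vectors via `labels`/`scores`.
#' @param n_boot Bootstrap resamples.
#' @param conf_level Confidence level.
#' @param seed Bootstrap seed.
#' @return An object of class `qus_cv`: `metrics` (named vector), `ci`
#'   (matrix with `lower`/`upper`), confusion counts, `n`.
#' @export
evaluate_predictions <- function(preds, n_boot = 2000L, conf_level = 0.95,
                                 seed = 1L) {
  y <- factor(preds$label)
  if (nlevels(droplevels(y)) < 2)
    stop("labels contain a single class", call. = FALSE)
  pos <- positive_class(y)
  is_pos <- y == pos
  pred_pos <- preds$pred == pos
  m <- metrics_from(pred_pos, is_pos, preds$score)

  old <- .Random.seed_exists()
  set.seed(derive_seed(seed, 59L))
  on.exit(.Random.seed_restore(old), add = TRUE)
  n <- length(is_pos)
  boot <- matrix(NA_real_, n_boot, 4)
  for (b in seq_len(n_boot)) {
    idx <- sample.int(n, n, replace = TRUE)
    if (length(unique(is_pos[idx])) < 2) next
    boot[b, ] <- metrics_from(pred_pos[idx], is_pos[idx], preds$score[idx])
  }
  alpha <- (1 - conf_level) / 2
  ci <- t(apply(boot, 2, stats::quantile, probs = c(alpha, 1 - alpha),
                na.rm = TRUE))
  dimnames(ci) <- list(names(m), c("lower", "upper"))
  structure(list(metrics = m, ci = ci, n = n,
                 confusion = c(TP = sum(pred_pos & is_pos),
                               FP = sum(pred_pos & !is_pos),
                               FN = sum(!pred_pos & is_pos),
                               TN = sum(!pred_pos & !is_pos)),
                 positive = pos, conf_level = conf_level),
            class = "qus_cv")
}

#' @export
print.qus_cv <- function(x, ...) {
  cat(sprintf("LOPO-CV metrics (n = %d, positive = '%s'):\n", x$n, x$positive))
  for (nm in names(x$metrics)) {
    unit <- if (nm == "auc") "" else "%"
    cat(sprintf("  %-12s %6.2f%s  (%d%% CI %.2f-%.2f)\n", nm,
                x$metrics[[nm]], unit, round(100 * x$conf_level),
                x$ci[nm, 1], x$ci[nm, 2]))
  }
  invisible(x)
}

balanced_accuracy <- function(pred_pos, is_pos) {
  (sum(pred_pos & is_pos) / sum(is_pos) +
     sum(!pred_pos & !is_pos) / sum(!is_pos)) / 2
}

select_greedy <- function(X, y, candidates, config, plan, max_features) {
  selected <- character(0)
  best_score <- -Inf
  candidates <- sort(candidates)
  repeat {
    if (length(selected) >= max_features) break
    round_best <- NULL; round_score <- -Inf
    pos <- positive_class(y)
    for (cand in setdiff(candidates, selected)) {
      lv <- lopo_votes(X[, c(selected, cand), drop = FALSE], y, plan, config)
      sc <- balanced_accuracy(lv$pred, y == pos)
      if (sc > round_score + 1e-12) {  # ties keep the first (name-sorted) one
        round_score <- sc; round_best <- cand
      }
    }
    if (is.null(round_best) || round_score <= best_score + 1e-12) break
    selected <- c(selected, round_best)
    best_score <- round_score
  }
  list(selected = selected, score = best_score)
}

#' Forward feature selection with the ensemble protocol
#'
#' Greedy forward selection: each round adds the candidate feature that
#' maximises balanced accuracy of the leave-one-patient-out ensemble
#' predictions, stopping at `max_features` (default 3) or when no candidate
#' improves the criterion; ties are broken by name order.  By default the
#' selection wraps the LOPO loop once on the full cohort (reported metrics
#' then carry the usual selection optimism); `nested = TRUE` re-runs the
#' selection inside every fold, the unbiased but much slower variant.
#'
#' The returned model also carries an ensemble fitted on the full cohort so
#' it can predict new patients.
#'
#' @param rows Model-row data frame (see [lopo_predict()]).
#' @param config A [classifier_config()].
#' @param candidates Candidate feature names (default: all feature columns).
#' @param seed Seed for the subset plan and bootstrap.
#' @param nested Re-select features inside every LOPO fold.
#' @return An object of class `qus_model` with elements `selected`,
#'   `preds`, `cv` (a `qus_cv`), `config`, and the fitted full-data
#'   ensemble; supports `print()`, `summary()`, `predict()`.
#' @export
#' @examples
#' rows <- simulate_feature_cohort(10, 14, effect = c("ACE_W0" = 2.5), seed = 2)
#' fit <- qus_model(rows, candidates = c("ACE_W0", "MBF_W0", "dSS"))
#' fit$selected
qus_model <- function(rows, config = classifier_config(), candidates = NULL,
                      seed = 1L, nested = FALSE) {
  sp <- split_rows(rows)
  candidates <- candidates %||% sp$features
  missing_f <- setdiff(candidates, sp$features)
  if (length(missing_f))
    stop("unknown candidate feature(s): ", paste(missing_f, collapse = ", "),
         call. = FALSE)
  plan <- make_subset_plan(sp$y, config$n_subsets, seed)
  pos <- positive_class(sp$y)

  if (!nested) {
    sel <- select_greedy(sp$X[, candidates, drop = FALSE], sp$y, candidates,
                         config, plan, config$max_features)
    selected <- sel$selected
    lv <- lopo_votes(sp$X[, selected, drop = FALSE], sp$y, plan, config)
    votes <- lv$votes
  } else {
    n <- nrow(sp$X)
    votes <- integer(n)
    selected_by_fold <- vector("list", n)
    for (i in seq_len(n)) {
      Xtr <- sp$X[-i, candidates, drop = FALSE]
      ytr <- droplevels(sp$y[-i])
      plan_i <- make_subset_plan(ytr, config$n_subsets, derive_seed(seed, i))
      sel_i <- select_greedy(Xtr, ytr, candidates, config, plan_i,
                             config$max_features)
      selected_by_fold[[i]] <- sel_i$selected
      ## predict patient i from the fold's own ensemble
      mu <- colMeans(Xtr[, sel_i$selected, drop = FALSE])
      sd <- apply(Xtr[, sel_i$selected, drop = FALSE], 2, stats::sd)
      sd[sd < 1e-12] <- 1
      Ztr <- sweep(sweep(Xtr[, sel_i$selected, drop = FALSE], 2, mu), 2, sd, `/`)
      zi <- (sp$X[i, sel_i$selected] - mu) / sd
      v <- 0L
      for (s in seq_along(plan_i)) {
        tr <- plan_i[[s]]
        if (config$classifier == "knn") {
          if (knn_vote(Ztr[tr, , drop = FALSE], ytr[tr] == pos, zi, config$k))
            v <- v + 1L
        } else {
          fit <- e1071::svm(Ztr[tr, , drop = FALSE],
                            factor(ytr[tr] == pos, c(FALSE, TRUE)),
                            kernel = "radial", cost = config$cost,
                            gamma = config$gamma %||% (1 / length(zi)),
                            scale = FALSE)
          if (as.logical(as.character(stats::predict(fit, matrix(zi, 1)))))
            v <- v + 1L
        }
      }
      votes[i] <- v
    }
    selected <- sort(unique(unlist(selected_by_fold)))
  }

  n_sub <- length(plan)
  preds <- data.frame(
    patient_id = rows$patient_id %||% seq_len(nrow(sp$X)),
    label = sp$y, votes = votes, score = votes / n_sub,
    pred = factor(ifelse(votes / n_sub > 0.5, pos,
                         setdiff(levels(sp$y), pos)), levels = levels(sp$y)))
  cv <- evaluate_predictions(preds, seed = seed)

  ## final ensemble on the full cohort (for predicting new patients)
  fit_feats <- if (nested) selected else selected
  mu <- colMeans(sp$X[, fit_feats, drop = FALSE])
  sd <- apply(sp$X[, fit_feats, drop = FALSE], 2, stats::sd)
  sd[sd < 1e-12] <- 1
  Z <- sweep(sweep(sp$X[, fit_feats, drop = FALSE], 2, mu), 2, sd, `/`)
  subset_models <- lapply(plan, function(tr) {
    if (config$classifier == "knn")
      list(Z = Z[tr, , drop = FALSE], y_pos = sp$y[tr] == pos)
    else
      e1071::svm(Z[tr, , drop = FALSE], factor(sp$y[tr] == pos, c(FALSE, TRUE)),
                 kernel = "radial", cost = config$cost,
                 gamma = config$gamma %||% (1 / length(fit_feats)),
                 scale = FALSE)
  })
  structure(list(selected = selected, preds = preds, cv = cv, config = config,
                 plan = plan, nested = nested, positive = pos,
                 levels = levels(sp$y), center = mu, scale = sd,
                 subset_models = subset_models,
                 selected_by_fold = if (nested) selected_by_fold else NULL),
            class = "qus_model")
}

#' @rdname qus_model
#' @param ... Passed to [qus_model()].
#' @export
forward_select <- function(rows, ...) qus_model(rows, ...)

#' @export
print.qus_model <- function(x, ...) {
  cat(sprintf("Balanced-subset %s ensemble (%d subsets, %s selection)\n",
              toupper(x$config$classifier), length(x$plan),
              if (x$nested) "nested" else "cohort-level"))
  cat("Selected features:", paste(x$selected, collapse = ", "), "\n")
  print(x$cv)
  invisible(x)
}

#' @export
summary.qus_model <- function(object, ...) {
  print(object)
  cat("\nConfusion counts:\n")
  print(object$cv$confusion)
  invisible(object)
}

#' @export
predict.qus_model <- function(object, newdata, type = c("class", "score"), ...) {
  type <- match.arg(type)
  feats <- names(object$center)
  missing_f <- setdiff(feats, names(newdata))
  if (length(missing_f))
    stop("newdata lacks feature(s): ", paste(missing_f, collapse = ", "),
         call. = FALSE)
  Xn <- as.matrix(newdata[, feats, drop = FALSE])
  Zn <- sweep(sweep(Xn, 2, object$center), 2, object$scale, `/`)
  votes <- integer(nrow(Zn))
  for (m in object$subset_models) {
    if (object$config$classifier == "knn") {
      for (i in seq_len(nrow(Zn)))
        if (knn_vote(m$Z, m$y_pos, Zn[i, ], object$config$k))
          votes[i] <- votes[i] + 1L
    } else {
      p <- as.logical(as.character(stats::predict(m, Zn)))
      votes <- votes + as.integer(p)
    }
  }
  score <- votes / length(object$subset_models)
  if (type == "score") return(score)
  factor(ifelse(score > 0.5, object$positive,
                setdiff(object$levels, object$positive)),
         levels = object$levels)
}

#' Model-feature tiers
#'
#' @param tier `"qus_tex1"` (mean QUS + first-order texture, both time
#'   representations: 62 features) or `"all"` (adds the texture
#'   derivatives: 190 features).
#' @return Character vector of model feature names.
#' @export
feature_tier <- function(tier = c("all", "qus_tex1")) {
  tier <- match.arg(tier)
  tp <- switch(tier,
               qus_tex1 = c(qus_feature_names("qus"), qus_feature_names("tex1")),
               all = qus_feature_names("timepoint"))
  c(paste0(tp, "_W0"), paste0("d", tp))
}

#' Compare feature tiers and classifiers
#'
#' Runs the full protocol (forward selection + LOPO-CV) for each requested
#' feature tier and classifier and tabulates sensitivity, specificity,
#' accuracy, AUC with confidence intervals, and the selected features --
#' the incremental-value comparison of texture derivatives over
#' QUS + first-order texture alone.
#'
#' @param rows Model-row data frame.
#' @param tiers Character vector of tiers (see [feature_tier()]).
#' @param classifiers Character vector among `"knn"`, `"svm"`.
#' @param seed Seed passed to each model fit.
#' @param ... Further arguments to [classifier_config()].
#' @return Data frame (class `qus_tier_comparison`) with one row per
#'   tier x classifier; attribute `models` holds the fitted `qus_model`s.
#' @export
compare_feature_sets <- function(rows, tiers = c("qus_tex1", "all"),
                                 classifiers = c("knn", "svm"), seed = 1L,
                                 ...) {
  out <- list(); models <- list()
  for (cl in classifiers) for (tier in tiers) {
    cand <- intersect(feature_tier(tier), names(rows))
    fit <- qus_model(rows, classifier_config(classifier = cl, ...),
                     candidates = cand, seed = seed)
    key <- paste(cl, tier, sep = ".")
    models[[key]] <- fit
    out[[key]] <- data.frame(
      classifier = cl, tier = tier,
      sensitivity = fit$cv$metrics[["sensitivity"]],
      specificity = fit$cv$metrics[["specificity"]],
      accuracy = fit$cv$metrics[["accuracy"]],
      auc = fit$cv$metrics[["auc"]],
      auc_lower = fit$cv$ci["auc", "lower"],
      auc_upper = fit$cv$ci["auc", "upper"],
      features = paste(fit$selected, collapse = " + "))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "models") <- models
  class(res) <- c("qus_tier_comparison", "data.frame")
  res
}

#' Univariate feature screening
#'
#' Per feature: Shapiro--Wilk normality within each outcome group at
#' alpha = 0.05; when both groups are consistent with normality a two-sided
#' unpaired (pooled-variance) t-test is used, otherwise a two-sided
#' Mann--Whitney U test.  Significance at p < 0.05 without multiplicity
#' correction.  Zero-variance features get the sentinel p = 1.
#'
#' @param rows Model-row data frame.
#' @param features Features to screen (default: all feature columns).
#' @return Data frame with `feature`, `test`, `p_value`, `significant`.
#' @export
univariate_screen <- function(rows, features = NULL) {
  sp <- split_rows(rows)
  features <- features %||% sp$features
  g <- split(seq_along(sp$y), sp$y)
  if (any(lengths(g) < 3)) stop("need >= 3 patients per group", call. = FALSE)
  res <- lapply(features, function(f) {
    a <- sp$X[g[[1]], f]; b <- sp$X[g[[2]], f]
    if (stats::sd(a) < 1e-12 || stats::sd(b) < 1e-12)
      return(data.frame(feature = f, test = "degenerate", p_value = 1))
    normal <- stats::shapiro.test(a)$p.value > 0.05 &&
      stats::shapiro.test(b)$p.value > 0.05
    if (normal) {
      p <- stats::t.test(a, b, var.equal = TRUE)$p.value
      data.frame(feature = f, test = "t", p_value = p)
    } else {
      p <- stats::wilcox.test(a, b, exact = FALSE)$p.value
      data.frame(feature = f, test = "mann-whitney", p_value = p)
    }
  })
  out <- do.call(rbind, res)
  out$significant <- out$p_value < 0.05
  out
}
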