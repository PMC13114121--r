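#' Stratified cross-validation folds
#'
#' Partitions samples into `n_folds` folds preserving the class ratio:
#' within each class, samples are shuffled (seeded) and dealt round-robin,
#' so per-fold class counts differ by at most one sample.
#'
#' @param labels Label tibble (`sample_id`, `response`).
#' @param n_folds Number of folds (default 5).
#' @param seed Seed for the shuffle (default 42, the study's split seed).
#' @return Tibble `sample_id`, `response`, `fold` (0-based fold index),
#'   with attribute `seed`.
#' @export
make_folds <- function(labels, n_folds = 5, seed = 42) {
  validate_labels(labels)
  n <- nrow(labels)
  if (n < n_folds) abort("need at least one sample per fold")
  if (length(unique(labels$response)) < 2) abort("both classes must be present")
  cnt <- table(labels$response)
  if (any(cnt < n_folds)) {
    warn(sprintf("class with %d member(s) cannot appear in every one of %d folds",
                 min(cnt), n_folds))
  }
  set.seed(as.integer(seed))
  fold <- integer(n)
  offset <- 0L
  for (cls in sort(unique(labels$response))) {
    idx <- which(labels$response == cls)
    idx <- idx[sample.int(length(idx))]
    # continue the deal across classes so fold sizes stay balanced overall
    fold[idx] <- (offset + seq_along(idx) - 1L) %% n_folds
    offset <- offset + length(idx)
  }
  out <- tibble::tibble(sample_id = labels$sample_id,
                        response = labels$response, fold = fold)
  attr(out, "seed") <- as.integer(seed)
  out
}

# ---- metrics -------------------------------------------------------------

# AUC by trapezoidal ROC integration; the rank form handles score ties as
# the trapezoid over the tied block (equivalently, ties count 1/2).
auc_trapezoid <- function(scores, truth) {
  np <- sum(truth == 1)
  nn <- sum(truth == 0)
  if (np == 0 || nn == 0) return(NA_real_)
  r <- rank(scores, ties.method = "average")
  (sum(r[truth == 1]) - np * (np + 1) / 2) / (np * nn)
}

# AUPR by step-wise precision-recall integration (no interpolation):
# thresholds sweep the distinct scores in descending order and each recall
# increment contributes the precision at that threshold.
aupr_step <- function(scores, truth) {
  np <- sum(truth == 1)
  if (np == 0 || sum(truth == 0) == 0) return(NA_real_)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; t <- truth[ord]
  tp <- cumsum(t == 1); fp <- cumsum(t == 0)
  last <- !duplicated(s, fromLast = TRUE)  # end of each tied block
  tp <- tp[last]; fp <- fp[last]
  prec <- tp / (tp + fp)
  rec <- tp / np
  sum(diff(c(0, rec)) * prec)
}

#' Accuracy, AUC and AUPR of scored predictions
#'
#' Accuracy thresholds probabilities at 0.5; AUC is trapezoidal ROC
#' integration; AUPR is step-wise precision-recall integration. With a
#' single-class truth vector AUC/AUPR are `NA` with a warning while
#' accuracy is still computed.
#'
#' @param data Tibble with columns `truth` (0/1) and `prob`.
#' @return One-row tibble `accuracy`, `auc`, `aupr`, `n`.
#' @export
evaluate_predictions <- function(data) {
  stopifnot(all(c("truth", "prob") %in% names(data)))
  truth <- data$truth
  prob <- data$prob
  acc <- mean((prob >= 0.5) == (truth == 1))
  if (length(unique(truth)) < 2) {
    warn("single-class truth: AUC and AUPR are undefined")
    return(tibble::tibble(accuracy = acc, auc = NA_real_, aupr = NA_real_,
                          n = length(truth)))
  }
  tibble::tibble(accuracy = acc,
                 auc = auc_trapezoid(prob, truth),
                 aupr = aupr_step(prob, truth),
                 n = length(truth))
}

# ROC curve points (FPR, TPR) for plotting; trapezoid over these equals
# auc_trapezoid.
roc_points <- function(scores, truth) {
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; t <- truth[ord]
  tp <- cumsum(t == 1); fp <- cumsum(t == 0)
  last <- !duplicated(s, fromLast = TRUE)
  tibble::tibble(fpr = c(0, fp[last] / max(sum(truth == 0), 1)),
                 tpr = c(0, tp[last] / max(sum(truth == 1), 1)))
}

# ---- cross-validated training -------------------------------------------

#' Five-fold cross-validated training and evaluation
#'
#' For each fold: (optionally) scores features by mutual information on the
#' training split and keeps the top `select_k`; fits the z-score scaler
#' (training split only by default, to avoid leakage); trains the model;
#' scores the held-out validation split. Reported metrics are per-fold
#' accuracy, AUC and AUPR with their mean and SD across folds.
#'
#' @param ab Raw (unstandardized) abundance tibble.
#' @param labels Label tibble.
#' @param prior Prior tibble or P x E matrix.
#' @param config A [pvae_config()] (or `NULL` for defaults).
#' @param settings A [pvae_train_settings()].
#' @param select_k Optional mutual-information screening size.
#' @param n_folds Number of folds (default 5).
#' @param folds Optional precomputed [make_folds()] table.
#' @param mi_scope,scaling_scope `"fold"` (default; fitted on the training
#'   split of each fold) or `"global"` (fitted once on all samples, the
#'   study-level variant).
#' @param keep_models Keep per-fold models for attribution (default TRUE).
#' @return An object of class `pvae_cv`: per-fold `metrics`, pooled
#'   validation `predictions` (each sample appears exactly once), and —
#'   when `keep_models` — the per-fold models, scalers and selected
#'   features needed by [attribute_cv()].
#' @export
run_cv <- function(ab, labels, prior, config = NULL,
                   settings = pvae_train_settings(), select_k = NULL,
                   n_folds = 5, folds = NULL,
                   mi_scope = c("fold", "global"),
                   scaling_scope = c("fold", "global"),
                   keep_models = TRUE) {
  mi_scope <- match.arg(mi_scope)
  scaling_scope <- match.arg(scaling_scope)
  j <- join_cohort(ab, labels)
  ab <- j$abundance; labels <- j$labels
  if (is.null(folds)) folds <- make_folds(labels, n_folds, seed = settings$seed)
  fold_of <- folds$fold[match(labels$sample_id, folds$sample_id)]
  global_sel <- if (!is.null(select_k) && mi_scope == "global") {
    select_top_k(mi_scores(ab, labels, seed = settings$seed), select_k)
  }
  global_scaler <- if (scaling_scope == "global") fit_scaler(ab)
  fold_ids <- sort(unique(folds$fold))
  fits <- vector("list", length(fold_ids))
  preds <- vector("list", length(fold_ids))
  for (i in seq_along(fold_ids)) {
    f <- fold_ids[i]
    tr <- which(fold_of != f)
    va <- which(fold_of == f)
    ab_tr <- ab[tr, , drop = FALSE]
    lab_tr <- labels[tr, , drop = FALSE]
    sel <- if (is.null(select_k)) NULL
      else if (mi_scope == "global") global_sel
      else select_top_k(mi_scores(ab_tr, lab_tr, seed = settings$seed + f), select_k)
    if (!is.null(sel)) ab_tr <- ab_tr[, c("sample_id", sel), drop = FALSE]
    scaler <- if (scaling_scope == "global") {
      if (is.null(sel)) global_scaler else fit_scaler(ab[, c("sample_id", sel)])
    } else fit_scaler(ab_tr)
    ab_tr_std <- apply_scaler(ab_tr, scaler)
    fold_settings <- settings
    fold_settings$seed <- settings$seed + f
    fold_cfg <- config
    if (is.null(fold_cfg)) fold_cfg <- pvae_config(input_dim = ncol(ab_tr_std) - 1)
    fold_cfg$input_dim <- ncol(ab_tr_std) - 1
    fold_cfg$seed <- settings$seed + f
    model <- pvae_train(ab_tr_std, lab_tr, prior, fold_cfg, fold_settings)
    ab_va <- ab[va, , drop = FALSE]
    if (!is.null(sel)) ab_va <- ab_va[, c("sample_id", sel), drop = FALSE]
    ab_va_std <- apply_scaler(ab_va, scaler)
    pr <- predict(model, ab_va_std, type = "prob")
    preds[[i]] <- tibble::tibble(sample_id = pr$sample_id, fold = f,
                                 truth = labels$response[va], prob = pr$.pred)
    fits[[i]] <- list(fold = f, model = if (keep_models) model,
                      scaler = if (keep_models) scaler, selected = sel)
  }
  predictions <- dplyr::bind_rows(preds)
  metrics <- predictions %>%
    dplyr::group_by(fold = .data$fold) %>%
    dplyr::group_modify(~ evaluate_predictions(.x)) %>%
    dplyr::ungroup()
  structure(list(folds = folds, fits = fits, predictions = predictions,
                 metrics = metrics, settings = settings, select_k = select_k,
                 mi_scope = mi_scope, scaling_scope = scaling_scope),
            class = "pvae_cv")
}

#' @export
print.pvae_cv <- function(x, ...) {
  g <- glance(x)
  cat(sprintf("<pvae_cv> %d folds | accuracy %.3f +/- %.3f | AUC %.3f +/- %.3f | AUPR %.3f +/- %.3f\n",
              nrow(x$metrics), g$mean_accuracy, g$sd_accuracy,
              g$mean_auc, g$sd_auc, g$mean_aupr, g$sd_aupr))
  invisible(x)
}

#' Tidy per-fold metrics of a cross-validation run
#'
#' @param x A `pvae_cv` object.
#' @param ... Unused.
#' @return Tibble with one row per fold (`fold`, `accuracy`, `auc`,
#'   `aupr`, `n`).
#' @export
tidy.pvae_cv <- function(x, ...) x$metrics

#' One-row summary of a cross-validation run
#'
#' @param x A `pvae_cv` object.
#' @param ... Unused.
#' @return One-row tibble with mean and SD of accuracy, AUC and AUPR
#'   across folds.
#' @export
glance.pvae_cv <- function(x, ...) {
  m <- x$metrics
  tibble::tibble(n_folds = nrow(m),
                 mean_accuracy = mean(m$accuracy), sd_accuracy = stats::sd(m$accuracy),
                 mean_auc = mean(m$auc), sd_auc = stats::sd(m$auc),
                 mean_aupr = mean(m$aupr), sd_aupr = stats::sd(m$aupr))
}

# ---- bootstrap and AUC comparison ---------------------------------------

#' Percentile bootstrap confidence interval for a ranking metric
#'
#' Sample-level resampling with replacement; replicates that draw a single
#' class are skipped and counted. The interval is the percentile
#' (2.5, 97.5) range for `conf = 0.95`.
#'
#' @param data Tibble with `truth` and `prob`.
#' @param metric `"auc"`, `"aupr"` or `"accuracy"`.
#' @param n_rep Number of bootstrap replicates (default 1000).
#' @param seed Seed for resampling.
#' @param conf Confidence level (default 0.95).
#' @return One-row tibble `metric`, `estimate`, `low`, `high`, `n_rep`,
#'   `n_skipped`.
#' @export
bootstrap_ci <- function(data, metric = c("auc", "aupr", "accuracy"),
                         n_rep = 1000, seed = 42, conf = 0.95) {
  metric <- match.arg(metric)
  stopifnot(nrow(data) >= 10)
  fn <- switch(metric,
               auc = function(t, p) auc_trapezoid(p, t),
               aupr = function(t, p) aupr_step(p, t),
               accuracy = function(t, p) mean((p >= 0.5) == (t == 1)))
  n <- nrow(data)
  set.seed(as.integer(seed))
  reps <- rep(NA_real_, n_rep)
  for (r in seq_len(n_rep)) {
    idx <- sample.int(n, n, replace = TRUE)
    t <- data$truth[idx]
    if (metric != "accuracy" && length(unique(t)) < 2) next
    reps[r] <- fn(t, data$prob[idx])
  }
  skipped <- sum(is.na(reps))
  if (skipped > 0) inform(sprintf("bootstrap_ci: skipped %d single-class replicate(s)", skipped))
  qs <- quantile(reps, probs = c((1 - conf) / 2, 1 - (1 - conf) / 2), na.rm = TRUE)
  tibble::tibble(metric = metric, estimate = fn(data$truth, data$prob),
                 low = qs[[1]], high = qs[[2]],
                 n_rep = n_rep, n_skipped = skipped)
}

#' Paired bootstrap test for an AUC difference
#'
#' Two score vectors on the same samples are compared by resampling
#' samples (keeping the pairing) and recomputing the AUC difference; the
#' two-sided p-value is twice the smaller tail fraction of the bootstrap
#' distribution around zero (with the +1 continuity correction), capped
#' at 1.
#'
#' @param scores_a,scores_b Scores of the two classifiers on the same
#'   samples.
#' @param truth 0/1 labels.
#' @param n_rep Bootstrap replicates (default 2000).
#' @param seed Seed.
#' @return One-row tibble `auc_a`, `auc_b`, `delta`, `p_value`.
#' @export
auc_difference_test <- function(scores_a, scores_b, truth,
                                n_rep = 2000, seed = 42) {
  if (length(scores_a) != length(scores_b) || length(scores_a) != length(truth)) {
    abort("scores_a, scores_b and truth must have equal length")
  }
  n <- length(truth)
  set.seed(as.integer(seed))
  deltas <- rep(NA_real_, n_rep)
  for (r in seq_len(n_rep)) {
    idx <- sample.int(n, n, replace = TRUE)
    t <- truth[idx]
    if (length(unique(t)) < 2) next
    deltas[r] <- auc_trapezoid(scores_a[idx], t) - auc_trapezoid(scores_b[idx], t)
  }
  deltas <- deltas[!is.na(deltas)]
  lo <- (sum(deltas <= 0) + 1) / (length(deltas) + 1)
  hi <- (sum(deltas >= 0) + 1) / (length(deltas) + 1)
  tibble::tibble(auc_a = auc_trapezoid(scores_a, truth),
                 auc_b = auc_trapezoid(scores_b, truth),
                 delta = auc_trapezoid(scores_a, truth) - auc_trapezoid(scores_b, truth),
                 p_value = min(1, 2 * min(lo, hi)))
}

# ---- baseline ------------------------------------------------------------

#' L1-penalized logistic regression baseline
#'
#' Fits a LASSO logistic classifier with the penalty chosen by inner
#' cross-validation on each training fold (glmnet), using the same fold
#' assignment and metrics as [run_cv()]. Zero-variance features in a
#' training fold are dropped with a warning.
#'
#' @param ab Raw abundance tibble.
#' @param labels Label tibble.
#' @param folds A [make_folds()] table (share it with [run_cv()] for a
#'   paired comparison).
#' @param seed Seed for the inner cross-validation.
#' @return An object of class `pvae_cv` (per-fold metrics + pooled
#'   predictions); per-fold fits hold the glmnet objects.
#' @export
lasso_baseline <- function(ab, labels, folds, seed = 42) {
  j <- join_cohort(ab, labels)
  ab <- j$abundance; labels <- j$labels
  fold_of <- folds$fold[match(labels$sample_id, folds$sample_id)]
  fold_ids <- sort(unique(folds$fold))
  preds <- vector("list", length(fold_ids))
  fits <- vector("list", length(fold_ids))
  for (i in seq_along(fold_ids)) {
    f <- fold_ids[i]
    tr <- which(fold_of != f); va <- which(fold_of == f)
    scaler <- fit_scaler(ab[tr, , drop = FALSE])
    xtr <- abundance_matrix(apply_scaler(ab[tr, , drop = FALSE], scaler))
    keep <- apply(xtr, 2, function(v) any(v != 0))
    if (!all(keep)) warn(sprintf("dropping %d all-zero feature(s) in fold %d", sum(!keep), f))
    xtr <- xtr[, keep, drop = FALSE]
    set.seed(as.integer(seed) + f)
    cvfit <- glmnet::cv.glmnet(xtr, j$labels$response[tr], family = "binomial",
                               alpha = 1, nfolds = 5)
    xva <- abundance_matrix(apply_scaler(ab[va, , drop = FALSE], scaler))[, keep, drop = FALSE]
    p <- as.numeric(predict(cvfit, newx = xva, s = "lambda.min", type = "response"))
    preds[[i]] <- tibble::tibble(sample_id = ab$sample_id[va], fold = f,
                                 truth = labels$response[va], prob = p)
    fits[[i]] <- list(fold = f, model = cvfit, scaler = scaler, selected = colnames(xtr))
  }
  predictions <- dplyr::bind_rows(preds)
  metrics <- predictions %>%
    dplyr::group_by(fold = .data$fold) %>%
    dplyr::group_modify(~ evaluate_predictions(.x)) %>%
    dplyr::ungroup()
  structure(list(folds = folds, fits = fits, predictions = predictions,
                 metrics = metrics, settings = NULL, select_k = NULL),
            class = "pvae_cv")
}

# ---- cross-cohort transfer ----------------------------------------------

#' Train-on-one / test-on-others cross-cohort evaluation
#'
#' Each cohort in turn is the training set: it is aligned to the reference
#' feature set, standardized by its own scaler, and a model is trained on
#' all of its samples. Every cohort (including the training one, giving
#' the resubstitution diagonal) is then aligned, standardized with the
#' *training* cohort's scaler, and scored.
#'
#' @param cohorts Named list; each element a list with `abundance` and
#'   `labels`.
#' @param reference_feature_ids Shared feature space for alignment.
#' @param prior Prior tibble or matrix.
#' @param config,settings As in [run_cv()].
#' @param select_k Optional per-training-cohort MI screening size.
#' @return Tibble `train`, `test`, `auc`, `n_test` (long form of the
#'   transfer AUC matrix); single-class test cohorts yield `NA` AUC with a
#'   warning.
#' @export
cross_cohort_eval <- function(cohorts, reference_feature_ids, prior,
                              config = NULL, settings = pvae_train_settings(),
                              select_k = NULL) {
  stopifnot(length(cohorts) >= 2, !is.null(names(cohorts)))
  aligned <- lapply(cohorts, function(co) {
    suppressMessages(align_to_reference(co$abundance, reference_feature_ids))
  })
  out <- list()
  for (tr_name in names(cohorts)) {
    ab_tr <- aligned[[tr_name]]
    lab_tr <- cohorts[[tr_name]]$labels
    sel <- if (!is.null(select_k)) {
      select_top_k(mi_scores(ab_tr, lab_tr, seed = settings$seed), select_k)
    } else reference_feature_ids
    ab_tr <- ab_tr[, c("sample_id", sel), drop = FALSE]
    scaler <- fit_scaler(ab_tr)
    cfg <- config
    if (is.null(cfg)) cfg <- pvae_config(input_dim = length(sel))
    cfg$input_dim <- length(sel)
    model <- pvae_train(apply_scaler(ab_tr, scaler), lab_tr, prior, cfg, settings)
    for (te_name in names(cohorts)) {
      ab_te <- aligned[[te_name]][, c("sample_id", sel), drop = FALSE]
      lab_te <- cohorts[[te_name]]$labels
      pr <- predict(model, apply_scaler(ab_te, scaler), type = "prob")
      truth <- lab_te$response[match(pr$sample_id, lab_te$sample_id)]
      auc <- if (length(unique(truth)) < 2) {
        warn(sprintf("test cohort %s has a single class; AUC undefined", te_name))
        NA_real_
      } else auc_trapezoid(pr$.pred, truth)
      out[[length(out) + 1]] <- tibble::tibble(train = tr_name, test = te_name,
                                               auc = auc, n_test = length(truth))
    }
  }
  dplyr::bind_rows(out)
}
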