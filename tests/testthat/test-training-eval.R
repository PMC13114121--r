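test_that("stratified folds partition samples and balance classes", {
  lab <- tibble::tibble(sample_id = paste0("s", 1:10),
                        response = rep(c(0L, 1L), 5))
  f <- make_folds(lab, 5, seed = 42)
  expect_setequal(f$sample_id, lab$sample_id)
  counts <- table(f$fold, f$response)
  expect_true(all(counts == 1))  # 5+5 over 5 folds: one of each class per fold
  expect_identical(make_folds(lab, 5, seed = 42), f)
  expect_false(identical(make_folds(lab, 5, seed = 1)$fold, f$fold))
  expect_warning(make_folds(tibble::tibble(sample_id = paste0("s", 1:8),
                                           response = c(1L, rep(0L, 7))), 5),
                 "cannot appear")
})

test_that("ranking metrics match enumeration and no-skill baselines", {
  # enumerate positive-negative pairs: 3 concordant of 4 -> AUC 0.75
  truth <- c(1, 0, 1, 0)
  scores <- c(0.9, 0.8, 0.3, 0.1)
  ev <- evaluate_predictions(tibble::tibble(truth = truth, prob = scores))
  expect_equal(ev$auc, 0.75)

  # perfect ranking
  perf <- evaluate_predictions(tibble::tibble(truth = c(1, 1, 0, 0),
                                              prob = c(0.9, 0.8, 0.2, 0.1)))
  expect_equal(perf$auc, 1.0)
  expect_equal(perf$aupr, 1.0)

  # constant scorer: AUC 1/2, AUPR equals prevalence
  const <- evaluate_predictions(tibble::tibble(truth = c(1, 0, 0, 0),
                                               prob = rep(0.5, 4)))
  expect_equal(const$auc, 0.5)
  expect_equal(const$aupr, 0.25)

  expect_warning(ev1 <- evaluate_predictions(tibble::tibble(truth = c(1, 1),
                                                            prob = c(0.9, 0.2))),
                 "single-class")
  expect_true(is.na(ev1$auc))
  expect_equal(ev1$accuracy, 0.5)
})

test_that("AUC and AUPR agree with an independent implementation", {
  skip_if_not_installed("pROC")
  set.seed(11)
  truth <- rbinom(80, 1, 0.4)
  prob <- plogis(rnorm(80) + truth)
  ours <- evaluate_predictions(tibble::tibble(truth = truth, prob = prob))
  ref <- as.numeric(pROC::auc(pROC::roc(truth, prob, quiet = TRUE)))
  expect_equal(ours$auc, ref, tolerance = 1e-12)
})

test_that("training reduces the loss and is reproducible; zero epochs is a no-op", {
  b <- small_cv_bundle()
  sc <- fit_scaler(b$cohort$abundance)
  ab <- apply_scaler(b$cohort$abundance, sc)

  m <- small_trained_model()$model
  expect_lt(tail(m$history$total, 1), m$history$total[1])

  m1 <- pvae_train(ab, b$cohort$labels, b$prior, b$config,
                   pvae_train_settings(epochs = 3, seed = 5))
  m2 <- pvae_train(ab, b$cohort$labels, b$prior, b$config,
                   pvae_train_settings(epochs = 3, seed = 5))
  expect_identical(m1$params, m2$params)

  m0 <- pvae_train(ab, b$cohort$labels, b$prior, b$config,
                   pvae_train_settings(epochs = 0, seed = 5))
  init <- pvae_model(local({ cfg <- b$config; cfg$input_dim <- ncol(ab) - 1; cfg }),
                     b$prior)
  expect_identical(m0$params, init$params)
  expect_null(m0$history)
})

test_that("cross-validated training recovers a planted signal", {
  b <- small_cv_bundle()
  cv <- b$cv
  expect_equal(nrow(cv$metrics), 5)
  # each sample is scored exactly once across folds
  expect_setequal(cv$predictions$sample_id, b$cohort$abundance$sample_id)
  expect_equal(anyDuplicated(cv$predictions$sample_id), 0L)
  expect_gte(glance(cv)$mean_auc, 0.8)
  # glance/tidy arithmetic is re-derivable
  expect_equal(glance(cv)$mean_auc, mean(tidy(cv)$auc))
  expect_equal(glance(cv)$sd_auc, sd(tidy(cv)$auc))
})

test_that("an ablated model (no prior path, no VAE terms) is a strong MLP", {
  # linearly separable regime: no zero-inflation, 2-SD log-scale shift
  spec <- synthetic_spec(n = 200, m = 100, k_inf = 20, delta = 2, pi0 = 0,
                         p_prior = 8, e_dim = 16, seed = 31)
  co <- generate_cohort(spec)
  prior <- generate_prior(spec)
  cfg <- pvae_config(latent_dim = 64, hidden_dim = 96, prior_dim = 16,
                     n_heads = 4, classifier_dims = c(32, 16),
                     lambda_fuse = 1, lambda_rec = 0, lambda_kl = 0)
  cv <- suppressMessages(run_cv(co$abundance, co$labels, prior, config = cfg,
                                settings = pvae_train_settings(epochs = 40, seed = 42),
                                keep_models = FALSE))
  expect_gte(glance(cv)$mean_auc, 0.95)
})

test_that("bootstrap intervals behave at the edges and are ordered", {
  perfect <- tibble::tibble(truth = rep(c(1, 0), each = 10),
                            prob = rep(c(0.9, 0.1), each = 10))
  ci <- bootstrap_ci(perfect, "auc", n_rep = 100, seed = 1)
  expect_equal(ci$low, 1.0)
  expect_equal(ci$high, 1.0)
  set.seed(2)
  noisy <- tibble::tibble(truth = rbinom(40, 1, 0.5), prob = runif(40))
  ci2 <- bootstrap_ci(noisy, "auc", n_rep = 200, seed = 3)
  expect_lte(ci2$low, ci2$high)
  expect_identical(bootstrap_ci(noisy, "auc", n_rep = 200, seed = 3), ci2)
})

test_that("the paired bootstrap AUC test separates identical from distinct scorers", {
  set.seed(12)
  truth <- rep(c(1, 0), each = 100)
  perfect <- truth + rnorm(200, 0, 0.01)
  random <- runif(200)
  same <- auc_difference_test(random, random, truth, n_rep = 200, seed = 1)
  expect_gte(same$p_value, 0.9)
  diff <- auc_difference_test(perfect, random, truth, n_rep = 500, seed = 1)
  expect_lt(diff$p_value, 0.01)
  expect_true(diff$p_value >= 0 && diff$p_value <= 1)
  expect_error(auc_difference_test(1:3, 1:4, c(0, 1, 0)), "equal length")
})

test_that("the LASSO baseline separates the planted signal on shared folds", {
  b <- small_cv_bundle()
  folds <- b$cv$folds
  las <- suppressWarnings(lasso_baseline(b$cohort$abundance, b$cohort$labels,
                                         folds, seed = 42))
  expect_gte(glance(las)$mean_auc, 0.9)
  expect_identical(las$folds, folds)
  # sparsity: active set never exceeds the feature count
  nz <- vapply(las$fits, function(f) {
    sum(as.matrix(glmnet::coef.glmnet(f$model, s = "lambda.min"))[-1, ] != 0)
  }, numeric(1))
  expect_true(all(nz <= ncol(b$cohort$abundance) - 1))
})
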