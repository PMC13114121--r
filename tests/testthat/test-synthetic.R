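test_that("cohort generation matches its declared statistical construction", {
  spec <- synthetic_spec(n = 200, m = 100, k_inf = 10, delta = 2, pi0 = 0.6,
                         seed = 17)
  co <- generate_cohort(spec)
  x <- abundance_matrix(co$abundance)
  y <- co$labels$response

  # zero fraction concentrates around pi0 for n*M >= 1e4
  expect_lt(abs(mean(x == 0) - spec$pi0), 0.03)

  # every planted feature has a higher responder mean on the log scale
  for (f in co$planted) {
    v <- x[, f]
    lr <- mean(log(v[y == 1 & v > 0]))
    ln_ <- mean(log(v[y == 0 & v > 0]))
    expect_gt(lr, ln_)
  }

  # determinism from the seed
  co2 <- generate_cohort(spec)
  expect_identical(co2$abundance, co$abundance)
  expect_identical(co2$labels, co$labels)

  # balanced responder fraction is realized exactly
  expect_equal(sum(y), 100)
})

test_that("a null effect plants no detectable difference", {
  spec <- synthetic_spec(n = 200, m = 50, k_inf = 10, delta = 0, pi0 = 0.3,
                         seed = 19)
  co <- generate_cohort(spec)
  x <- abundance_matrix(co$abundance)
  y <- co$labels$response
  tstats <- vapply(co$planted, function(f) {
    unname(t.test(log1p(x[y == 1, f]), log1p(x[y == 0, f]))$statistic)
  }, numeric(1))
  expect_lt(max(abs(tstats)), 4)
})

test_that("the synthetic prior is a seeded standard-normal matrix", {
  spec <- synthetic_spec(p_prior = 40, e_dim = 320)
  pr <- generate_prior(spec)
  m <- prior_matrix(pr)
  expect_equal(dim(m), c(40, 320))
  expect_lt(abs(mean(m)), 0.05)
  expect_lt(abs(var(as.vector(m)) - 1), 0.05)
  expect_identical(prior_matrix(generate_prior(spec)), m)
})

test_that("multi-cohort generation controls signal sharing and shift", {
  spec <- synthetic_spec(n = 60, m = 80, k_inf = 8, delta = 1, pi0 = 0.4,
                         shift_scale = 0.5, seed = 23)
  shared <- generate_multi_cohort(spec, 3, shared_signal = TRUE)
  expect_identical(shared[[1]]$planted, shared[[2]]$planted)
  expect_identical(shared[[2]]$planted, shared[[3]]$planted)

  disjoint <- generate_multi_cohort(spec, 3, shared_signal = FALSE)
  expect_length(intersect(disjoint[[1]]$planted, disjoint[[2]]$planted), 0)
  expect_length(intersect(disjoint[[1]]$planted, disjoint[[3]]$planted), 0)

  # cohort-level shift moves marginal feature means
  m1 <- colMeans(abundance_matrix(shared[[1]]$abundance))
  m2 <- colMeans(abundance_matrix(shared[[2]]$abundance))
  expect_gt(stats::sd(log(m1 / m2)), 0.1)

  expect_error(generate_multi_cohort(synthetic_spec(m = 10, k_inf = 6), 2,
                                     shared_signal = FALSE),
               "disjoint")
})

test_that("cohort TSV export round-trips through the readers", {
  spec <- synthetic_spec(n = 12, m = 8, k_inf = 2, p_prior = 4, e_dim = 6,
                         seed = 29)
  co <- generate_cohort(spec)
  pr <- generate_prior(spec)
  dir <- withr::local_tempdir()
  write_cohort_tsv(co, pr, dir)
  expect_equal(read_abundance_tsv(file.path(dir, "abundance.tsv")), co$abundance)
  expect_equal(read_labels_tsv(file.path(dir, "labels.tsv")), co$labels)
  expect_equal(read_annotations_tsv(file.path(dir, "annotations.tsv")),
               co$annotations)
})

test_that("discrimination improves monotonically with the planted effect size", {
  aucs <- vapply(c(0, 1, 2), function(delta) {
    spec <- synthetic_spec(n = 120, m = 60, k_inf = 10, delta = delta,
                           pi0 = 0.5, p_prior = 8, e_dim = 16, seed = 37)
    co <- generate_cohort(spec)
    prior <- generate_prior(spec)
    cfg <- pvae_config(latent_dim = 32, hidden_dim = 48, prior_dim = 16,
                       n_heads = 4, classifier_dims = c(16, 8))
    cv <- suppressMessages(run_cv(co$abundance, co$labels, prior, config = cfg,
                                  settings = pvae_train_settings(epochs = 30, seed = 42),
                                  keep_models = FALSE))
    glance(cv)$mean_auc
  }, numeric(1))
  expect_lt(aucs[1], aucs[2])
  expect_lt(aucs[2], aucs[3])
})
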