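test_that("integrated gradients recover a linear scorer exactly", {
  set.seed(15)
  w <- rnorm(6)
  lin <- list(value = function(x) sum(w * x), gradient = function(x) w)
  x <- rnorm(6)
  ig <- integrated_gradients(lin, x, steps = 10)
  expect_equal(ig, w * x, tolerance = 1e-12)
  # zero path: x equal to the baseline gives all-zero attributions
  expect_equal(integrated_gradients(lin, rep(0, 6), steps = 10), rep(0, 6))
})

test_that("integrated gradients satisfy completeness on a trained model", {
  sm <- small_trained_model()
  model <- sm$model
  ns <- asNamespace("priorvae")
  x <- abundance_matrix(sm$ab_std)[3, ]
  ig <- integrated_gradients(model, x, steps = 200)
  f_x <- ns$pvae_prob(model, matrix(x, 1))
  f_0 <- ns$pvae_prob(model, matrix(0, 1, length(x)))
  expect_lt(abs(sum(ig) - (f_x - f_0)) / max(abs(f_x - f_0), 1e-8), 0.01)
  # x at the baseline attributes nothing
  expect_equal(unname(integrated_gradients(model, numeric(length(x)), steps = 10)),
               numeric(length(x)))
})

test_that("cross-validated attribution pools only correctly predicted samples", {
  b <- small_cv_bundle()
  at <- suppressMessages(attribute_cv(b$cv, b$cohort$abundance, steps = 20))
  expect_equal(at$feature_id, names(b$cohort$abundance)[-1])
  correct <- with(b$cv$predictions, (prob >= 0.5) == (truth == 1))
  expect_equal(at$n_responder[1], sum(b$cv$predictions$truth == 1 & correct))
  expect_equal(at$n_nonresponder[1], sum(b$cv$predictions$truth == 0 & correct))
  expect_true(all(is.finite(at$mean_ig_responder)))

  # pooled mean equals the count-weighted mean of per-fold means: recompute
  # fold sums directly for one feature
  ns <- asNamespace("priorvae")
  total <- 0; nresp <- 0
  for (fit in b$cv$fits) {
    pred_f <- b$cv$predictions[b$cv$predictions$fold == fit$fold, ]
    ok <- pred_f[(pred_f$prob >= 0.5) == (pred_f$truth == 1) & pred_f$truth == 1, ]
    if (nrow(ok) == 0) next
    ab_f <- b$cohort$abundance[match(ok$sample_id, b$cohort$abundance$sample_id), ]
    xs <- abundance_matrix(apply_scaler(ab_f, fit$scaler))
    for (i in seq_len(nrow(xs))) {
      total <- total + unname(integrated_gradients(fit$model, xs[i, ], steps = 20)[1])
      nresp <- nresp + 1
    }
  }
  expect_equal(at$mean_ig_responder[1], total / nresp, tolerance = 1e-12)
})

test_that("planted features dominate the top attributions", {
  b <- small_cv_bundle()
  at <- suppressMessages(attribute_cv(b$cv, b$cohort$abundance, steps = 20))
  top <- top_k_by_attribution(at, "responder", k = 2 * length(b$cohort$planted))
  hits <- length(intersect(top$feature_id, b$cohort$planted))
  expect_gte(hits, 0.5 * length(b$cohort$planted))
})

test_that("top-k attribution ranks by absolute value with deterministic ties", {
  at <- tibble::tibble(feature_id = c("a", "b", "c"),
                       mean_ig_responder = c(0.5, -0.7, 0.1),
                       n_responder = 3L,
                       mean_ig_nonresponder = c(0, 0, 0),
                       n_nonresponder = 2L)
  class(at) <- c("pvae_attribution", class(at))
  top <- top_k_by_attribution(at, "responder", 2)
  expect_equal(top$feature_id, c("b", "a"))
  expect_equal(top$mean_ig, c(-0.7, 0.5))  # signed values reported
  zero <- top_k_by_attribution(at, "nonresponder", 3)
  expect_equal(zero$feature_id, c("a", "b", "c"))  # id-ascending tie rule
})

test_that("feature labels render family/genus with confidences and nulls", {
  ann <- tibble::tibble(
    feature_id = c("f1", "f2", "f3"),
    family = c("Rikenellaceae", "FamilyX", NA),
    family_conf = c(1, 0.93, NA),
    genus = c("Alistipes", NA, NA),
    genus_conf = c(1, NA, NA))
  expect_equal(format_feature_label("f1", ann), "Rikenellaceae-1.00 > Alistipes-1.00")
  expect_equal(format_feature_label("f2", ann), "FamilyX-0.93 > null")
  expect_equal(format_feature_label("f3", ann), "null > null")
  expect_equal(format_feature_label("missing", ann), "null > null")
})

test_that("taxon aggregation sums member scores and conserves the total", {
  ann <- tibble::tibble(feature_id = c("f1", "f2", "f3"),
                        family = c("FamA", "FamA", NA),
                        family_conf = c(1, 1, NA),
                        genus = c("G", "G", NA),
                        genus_conf = c(1, 1, NA))
  at <- tibble::tibble(feature_id = c("f1", "f2", "f3"),
                       mean_ig_responder = c(0.3, -0.1, 0.2),
                       n_responder = 1L,
                       mean_ig_nonresponder = c(0.05, 0.05, -0.2),
                       n_nonresponder = 1L)
  class(at) <- c("pvae_attribution", class(at))
  agg <- aggregate_by_taxon(at, ann, "genus", "responder")
  expect_equal(agg$cumulative_ig[agg$taxon == "G"], 0.2)
  expect_equal(agg$cumulative_ig[agg$taxon == "null"], 0.2)
  expect_equal(sum(agg$cumulative_ig), sum(at$mean_ig_responder))
  fam <- aggregate_by_taxon(at, ann, "family", "nonresponder")
  expect_equal(sum(fam$cumulative_ig), sum(at$mean_ig_nonresponder))
})
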