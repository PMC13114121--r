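test_that("loss terms match their closed forms", {
  # KL of unit-variance posterior: half the squared latent mean, batch mean
  expect_equal(kl_loss(matrix(0, 3, 4)), 0)
  expect_equal(kl_loss(matrix(c(1, 1), 1, 2)), 1.0)
  expect_equal(kl_loss(rbind(c(1, 1), c(3, 0))), (1 + 4.5) / 2)
  expect_equal(kl_loss(rbind(c(1, 1), c(3, 0)), reduction = "sum"), 5.5)

  # reconstruction: batch mean of squared residual norms (no 1/M)
  x <- rbind(c(1, 1), c(3, 0))
  expect_equal(reconstruction_loss(x, x), 0)
  expect_equal(reconstruction_loss(matrix(c(1, 1), 1, 2), matrix(0, 1, 2)), 2.0)
  expect_equal(reconstruction_loss(x, matrix(0, 2, 2)), (2 + 9) / 2)
  expect_error(reconstruction_loss(x, matrix(0, 1, 2)), "shape")

  # binary cross-entropy
  expect_equal(classification_loss(0.5, 1), log(2))
  expect_lt(classification_loss(1 - 1e-9, 1), 1e-6)
  expect_equal(classification_loss(c(0.5, 0.5), c(1, 0)), log(2))

  # composite identity
  tl <- total_loss(2, 2.75, log(2), lambda_rec = 0.1, lambda_kl = 0.2)
  expect_equal(tl$total, 0.1 * 2 + 0.2 * 2.75 + log(2))
  expect_equal(total_loss(0, 0, 0)$total, 0)
  expect_equal(total_loss(5, 7, 1.3, lambda_rec = 0, lambda_kl = 0)$total, 1.3)
})

test_that("forward operations honor their shape and range contracts", {
  m <- tiny_model()
  set.seed(1)
  x <- matrix(rnorm(4 * 7), 4, 7)
  mu <- pvae_encode(m, x)
  expect_equal(dim(mu), c(4, 8))
  # duplicate rows map identically in inference mode, and calls are bitwise equal
  x2 <- x[c(1, 1, 2, 3), ]
  mu2 <- pvae_encode(m, x2)
  expect_identical(mu2[1, ], mu2[2, ])
  expect_identical(pvae_encode(m, x), mu)
  expect_error(pvae_encode(m, x[, 1:3]), "features")

  rp <- pvae_project_prior(m)
  expect_equal(dim(rp), c(3, 8))

  a <- pvae_attend(m, mu)
  expect_equal(dim(a$a), c(4, 8))
  for (w in a$weights) expect_equal(rowSums(w), rep(1, 4), tolerance = 1e-6)

  zt <- pvae_fuse(mu, a$a, 0.7)
  expect_equal(zt, 0.7 * mu + 0.3 * a$a)
  expect_equal(pvae_fuse(mu, a$a, 1), mu)
  expect_equal(pvae_fuse(mu, mu, 0.3), mu)
  z1 <- c(1, rep(0, 7)); a1 <- c(0, 1, rep(0, 6))
  expect_equal(drop(pvae_fuse(rbind(z1), rbind(a1), 0.7)),
               c(0.7, 0.3, rep(0, 6)))

  xr <- pvae_decode(m, zt)
  expect_equal(dim(xr), c(4, 7))
  expect_true(all(xr > 0 & xr < 1))

  p <- pvae_classify(m, mu)
  expect_true(all(p > 0 & p < 1))
  expect_identical(pvae_classify(m, mu2)[1], pvae_classify(m, mu2)[2])
  # zeroed final layer gives sigmoid(0) = 0.5
  m0 <- m
  m0$params$cls_W3[] <- 0; m0$params$cls_b3[] <- 0
  expect_equal(pvae_classify(m0, mu), rep(0.5, 4))
})

test_that("reparameterization draws unit-variance noise around mu", {
  mu <- matrix(0.5, 100, 100)
  r0 <- pvae_reparameterize(mu, sample = FALSE)
  expect_identical(r0$z, mu)
  set.seed(4); r1 <- pvae_reparameterize(mu)
  set.seed(4); r2 <- pvae_reparameterize(mu)
  expect_identical(r1$z, r2$z)
  eps <- r1$z - mu
  expect_lt(abs(mean(eps)), 0.05)
  expect_lt(abs(var(as.vector(eps)) - 1), 0.05)
  expect_equal(r1$z, mu + r1$epsilon)
})

test_that("attention at P = 1 collapses to the direct matrix arithmetic", {
  cfg <- tiny_config()
  m <- tiny_model(cfg, p_rows = 1)
  set.seed(6)
  mu <- matrix(rnorm(3 * 8), 3, 8)
  got <- pvae_attend(m, mu)
  # single key: softmax weight is exactly 1, every sample receives the same
  # value row -> hand-compute R' Wv blocks through Wo and layer norm
  rp <- pvae_project_prior(m)
  v <- rp %*% m$params$att_Wv          # 1 x d, heads are column blocks
  u <- v %*% m$params$att_Wo + matrix(m$params$att_bo, 1)
  xh <- (u - rowMeans(u)) / sqrt(mean(u^2) - mean(u)^2 + 1e-5)
  expected_row <- drop(xh * m$params$ln_g + m$params$ln_b)
  for (i in 1:3) expect_equal(unname(got$a[i, ]), unname(expected_row), tolerance = 1e-12)
  for (w in got$weights) expect_equal(unname(w), matrix(1, 3, 1))
})

test_that("attention is invariant to permuting prior rows", {
  cfg <- tiny_config()
  m <- tiny_model(cfg, p_rows = 4)
  set.seed(7)
  mu <- matrix(rnorm(2 * 8), 2, 8)
  a1 <- pvae_attend(m, mu)$a
  m2 <- m
  m2$prior <- m$prior[c(3, 1, 4, 2), ]
  expect_equal(pvae_attend(m2, mu)$a, a1, tolerance = 1e-12)
})

test_that("analytic gradients match finite differences on a tiny network", {
  ns <- asNamespace("priorvae")
  cfg <- tiny_config()
  model <- tiny_model(cfg)
  set.seed(13)
  b <- 4
  x <- matrix(rnorm(b * 7), b, 7)
  y <- c(1, 0, 1, 0)
  eps_mat <- matrix(rnorm(b * 8), b, 8)

  forward_frozen <- function(model) {
    p <- model$params
    enc <- ns$forward_encoder(model, x, TRUE)
    rp <- ns$nn_linear_fwd(model$prior, p$pri_W, p$pri_b)
    att <- ns$nn_attention_fwd(enc$mu, rp, p, cfg$n_heads)
    z <- enc$mu + eps_mat
    zt <- cfg$lambda_fuse * z + (1 - cfg$lambda_fuse) * att$out
    dec <- ns$forward_decoder(model, zt, TRUE)
    cls <- ns$forward_classifier(model, enc$mu, TRUE)
    list(enc = enc, rp = rp, att = att, zt = zt, dec = dec, cls = cls,
         rep = list(z = z, epsilon = eps_mat), x_target = x, y = y,
         loss = cfg$lambda_rec * reconstruction_loss(dec$xr, x) +
           cfg$lambda_kl * kl_loss(enc$mu) +
           ns$classification_loss_logits(drop(cls$logit), y, "mean"))
  }

  fw <- forward_frozen(model)
  grads <- ns$pvae_backward(model, fw)
  h <- 1e-5
  set.seed(14)
  for (nm in names(grads)) {
    idx <- sample(length(grads[[nm]]), min(4, length(grads[[nm]])))
    for (i in idx) {
      m2 <- model
      m2$params[[nm]][i] <- m2$params[[nm]][i] + h
      lp <- forward_frozen(m2)$loss
      m2$params[[nm]][i] <- m2$params[[nm]][i] - 2 * h
      lm <- forward_frozen(m2)$loss
      num <- (lp - lm) / (2 * h)
      expect_lt(abs(num - grads[[nm]][i]) / max(1e-6, abs(num) + abs(grads[[nm]][i])),
                1e-4)
    }
  }
})

test_that("the prior matrix is bit-identical after training steps", {
  b <- small_cv_bundle()
  sc <- fit_scaler(b$cohort$abundance)
  ab <- apply_scaler(b$cohort$abundance, sc)
  before <- prior_matrix(b$prior)
  m <- pvae_train(ab, b$cohort$labels, b$prior, b$config,
                  pvae_train_settings(epochs = 2, seed = 3))
  expect_identical(m$prior, before)
  expect_identical(prior_matrix(b$prior), before)
})

test_that("the loss breakdown identity holds along the training history", {
  sm <- small_trained_model()
  h <- sm$model$history
  expect_true(all(abs(h$total - (0.1 * h$reconstruction + 0.2 * h$kl +
                                   h$classification)) < 1e-6))
})
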