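#' Network configuration for the prior-conditioned VAE
#'
#' The model encodes a standardized RPKM profile `x` (width `input_dim`)
#' into a latent mean `mu` (width `latent_dim`), draws `z = mu + eps` with
#' unit-variance reparameterization, attends from `mu` over the projected
#' protein-embedding prior to obtain a biology-aware embedding `a`, fuses
#' `z_tilde = lambda * z + (1 - lambda) * a`, decodes back to the input
#' width through a sigmoid, and classifies the response from `mu`. The
#' composite loss is
#' `lambda_rec * L_rec + lambda_kl * L_KL + L_cls`.
#'
#' @param input_dim Number of input features M (set automatically by
#'   [pvae_train()] when `NULL`).
#' @param latent_dim Latent width d (default 256); must be divisible by
#'   `n_heads`.
#' @param hidden_dim Encoder/decoder hidden width (default 512).
#' @param prior_dim Embedding width E of the prior matrix (default 320).
#' @param n_heads Attention heads H (default 4).
#' @param lambda_fuse Fusion weight lambda on the sampled latent `z`
#'   (default 0.7; the prior pathway gets `1 - lambda`).
#' @param classifier_dims Hidden widths of the classifier head
#'   (default `c(128, 64)`).
#' @param lambda_rec,lambda_kl Loss weights (defaults 0.1 and 0.2).
#' @param reconstruction_target `"zscore"` (reconstruct the standardized
#'   input directly, the literal reading of the model) or `"minmax"`
#'   (additionally rescale the target per feature into \[0, 1\] to match
#'   the sigmoid output range).
#' @param loss_reduction `"mean"` (default; KL and classification terms are
#'   batch means, so loss magnitudes are batch-size invariant) or `"sum"`
#'   (sum over the batch, the literal printed formulas).
#' @param seed Seed for weight initialization.
#' @return An object of class `pvae_config`.
#' @export
pvae_config <- function(input_dim = NULL, latent_dim = 256, hidden_dim = 512,
                        prior_dim = 320, n_heads = 4, lambda_fuse = 0.7,
                        classifier_dims = c(128, 64),
                        lambda_rec = 0.1, lambda_kl = 0.2,
                        reconstruction_target = c("zscore", "minmax"),
                        loss_reduction = c("mean", "sum"), seed = 42) {
  reconstruction_target <- match.arg(reconstruction_target)
  loss_reduction <- match.arg(loss_reduction)
  if (latent_dim %% n_heads != 0) abort("latent_dim must be divisible by n_heads")
  stopifnot(lambda_fuse >= 0, lambda_fuse <= 1,
            lambda_rec >= 0, lambda_rec <= 1, lambda_kl >= 0, lambda_kl <= 1,
            latent_dim > 0, hidden_dim > 0, prior_dim > 0,
            all(classifier_dims > 0))
  structure(list(input_dim = input_dim, latent_dim = latent_dim,
                 hidden_dim = hidden_dim, prior_dim = prior_dim,
                 n_heads = n_heads, lambda_fuse = lambda_fuse,
                 classifier_dims = classifier_dims,
                 lambda_rec = lambda_rec, lambda_kl = lambda_kl,
                 reconstruction_target = reconstruction_target,
                 loss_reduction = loss_reduction, seed = as.integer(seed)),
            class = "pvae_config")
}

#' Initialize a prior-conditioned VAE
#'
#' Builds the network weights (seeded fan-in uniform initialization) and
#' stores the fixed prior matrix. The prior is never updated by training.
#'
#' @param config A [pvae_config()]; `input_dim` must be set.
#' @param prior Prior tibble (`protein_id` + embedding columns) or a
#'   numeric P x E matrix.
#' @return An object of class `pvae_model`.
#' @export
pvae_model <- function(config, prior) {
  stopifnot(inherits(config, "pvae_config"))
  if (is.null(config$input_dim)) abort("config$input_dim must be set")
  rmat <- if (is.matrix(prior)) prior else prior_matrix(prior)
  if (ncol(rmat) != config$prior_dim) {
    abort(sprintf("prior width %d does not match config prior_dim %d",
                  ncol(rmat), config$prior_dim))
  }
  if (nrow(rmat) < 1) abort("prior must have at least one row")
  m <- config$input_dim
  d <- config$latent_dim
  hd <- config$hidden_dim
  c1 <- config$classifier_dims[1]
  c2 <- config$classifier_dims[2]
  set.seed(config$seed)
  p <- list()
  li <- init_linear(m, hd);  p$enc_W1 <- li$W; p$enc_b1 <- li$b
  p$enc_g1 <- rep(1, hd); p$enc_be1 <- rep(0, hd)
  li <- init_linear(hd, d);  p$enc_W2 <- li$W; p$enc_b2 <- li$b
  li <- init_linear(config$prior_dim, d); p$pri_W <- li$W; p$pri_b <- li$b
  li <- init_linear(d, d); p$att_Wq <- li$W
  li <- init_linear(d, d); p$att_Wk <- li$W
  li <- init_linear(d, d); p$att_Wv <- li$W
  li <- init_linear(d, d); p$att_Wo <- li$W; p$att_bo <- li$b
  p$ln_g <- rep(1, d); p$ln_b <- rep(0, d)
  li <- init_linear(d, hd); p$dec_W1 <- li$W; p$dec_b1 <- li$b
  p$dec_g1 <- rep(1, hd); p$dec_be1 <- rep(0, hd)
  li <- init_linear(hd, m); p$dec_W2 <- li$W; p$dec_b2 <- li$b
  p$dec_g2 <- rep(1, m); p$dec_be2 <- rep(0, m)
  li <- init_linear(d, c1); p$cls_W1 <- li$W; p$cls_b1 <- li$b
  p$cls_g1 <- rep(1, c1); p$cls_be1 <- rep(0, c1)
  li <- init_linear(c1, c2); p$cls_W2 <- li$W; p$cls_b2 <- li$b
  p$cls_g2 <- rep(1, c2); p$cls_be2 <- rep(0, c2)
  li <- init_linear(c2, 1); p$cls_W3 <- li$W; p$cls_b3 <- li$b
  bn0 <- function(width) list(mean = rep(0, width), var = rep(1, width))
  structure(list(config = config, prior = rmat, params = p,
                 bn = list(enc1 = bn0(hd), dec1 = bn0(hd), dec2 = bn0(m),
                           cls1 = bn0(c1), cls2 = bn0(c2)),
                 feature_ids = NULL, history = NULL, trained_epochs = 0L),
            class = "pvae_model")
}

#' @export
print.pvae_model <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(paste0("<pvae_model> M=%d -> d=%d (hidden %d), %d-head attention over ",
                     "%d prior rows (E=%d), trained %d epoch(s)\n"),
              cfg$input_dim, cfg$latent_dim, cfg$hidden_dim, cfg$n_heads,
              nrow(x$prior), cfg$prior_dim, x$trained_epochs))
  invisible(x)
}

# ---- spec-surface forward operations -------------------------------------

#' Encode standardized profiles to latent means
#'
#' @param model A `pvae_model`.
#' @param x Numeric B x M matrix of standardized features (or an abundance
#'   tibble, whose feature columns are used).
#' @param training Use batch statistics (`TRUE`, needs B >= 2) or the
#'   running batch-norm statistics (`FALSE`, deterministic).
#' @return B x d matrix of latent means `mu`.
#' @export
pvae_encode <- function(model, x, training = FALSE) {
  x <- coerce_input_matrix(model, x)
  f <- forward_encoder(model, x, training)
  f$mu
}

#' Reparameterized latent sample
#'
#' `z = mu + eps` with `eps ~ N(0, I)` during training; in evaluation mode
#' `eps = 0` so `z = mu` and inference is deterministic.
#'
#' @param mu B x d latent mean matrix.
#' @param sample Draw noise (`TRUE`) or return `mu` (`FALSE`).
#' @return List with `z`, `mu` and `epsilon`.
#' @export
pvae_reparameterize <- function(mu, sample = TRUE) {
  eps <- if (sample) matrix(rnorm(length(mu)), nrow(mu), ncol(mu)) else mu * 0
  list(z = mu + eps, mu = mu, epsilon = eps)
}

#' Project the fixed prior into latent space
#'
#' @param model A `pvae_model`.
#' @return P x d matrix `R'`, recomputed from the current projection
#'   weights; the stored prior itself is never modified.
#' @export
pvae_project_prior <- function(model) {
  nn_linear_fwd(model$prior, model$params$pri_W, model$params$pri_b)
}

#' Attend from latent means over the projected prior
#'
#' Multi-head scaled dot-product attention with `mu` as query and the
#' projected prior rows as keys and values, followed by an output map and
#' layer normalization.
#'
#' @param model A `pvae_model`.
#' @param mu B x d latent mean matrix.
#' @return List with `a` (B x d biology-aware embedding) and `weights`
#'   (per-head list of B x P attention weight matrices; rows sum to 1).
#' @export
pvae_attend <- function(model, mu) {
  rp <- pvae_project_prior(model)
  att <- nn_attention_fwd(mu, rp, model$params, model$config$n_heads)
  list(a = att$out, weights = att$weights)
}

#' Fuse sampled latent and prior embedding
#'
#' @param z,a B x d matrices.
#' @param lambda Convex weight on `z` (default 0.7).
#' @return `lambda * z + (1 - lambda) * a`.
#' @export
pvae_fuse <- function(z, a, lambda = 0.7) {
  stopifnot(identical(dim(z), dim(a)), lambda >= 0, lambda <= 1)
  lambda * z + (1 - lambda) * a
}

#' Decode a fused latent to reconstructed features
#'
#' @param model A `pvae_model`.
#' @param z_tilde B x d fused latent matrix.
#' @inheritParams pvae_encode
#' @return B x M matrix with entries in (0, 1) (sigmoid output).
#' @export
pvae_decode <- function(model, z_tilde, training = FALSE) {
  forward_decoder(model, z_tilde, training)$xr
}

#' Classify response probability from latent means
#'
#' The classifier consumes `mu` (not the sampled `z`), so evaluation-mode
#' predictions are deterministic.
#'
#' @param model A `pvae_model`.
#' @param mu B x d latent mean matrix.
#' @inheritParams pvae_encode
#' @return Numeric vector of B probabilities in (0, 1).
#' @export
pvae_classify <- function(model, mu, training = FALSE) {
  drop(forward_classifier(model, mu, training)$yhat)
}

# ---- loss terms ----------------------------------------------------------

#' Loss terms of the composite objective
#'
#' `reconstruction_loss()` is the batch mean of the squared Euclidean
#' residual norm (no division by the feature count). `kl_loss()` is the KL
#' divergence of a unit-variance Gaussian posterior against the standard
#' normal prior, `0.5 * sum(mu^2)` per sample. `classification_loss()` is
#' binary cross-entropy with a 1e-7 clamp on the probabilities.
#' `reduction = "mean"` averages over the batch; `"sum"` follows the
#' summed form.
#'
#' @param x_recon,x_target B x M matrices.
#' @param reduction `"mean"` or `"sum"` over the batch.
#' @return A single non-negative number.
#' @export
reconstruction_loss <- function(x_recon, x_target) {
  if (!identical(dim(x_recon), dim(x_target))) abort("shape mismatch in reconstruction_loss")
  sum((x_recon - x_target)^2) / nrow(x_recon)
}

#' @rdname reconstruction_loss
#' @param mu B x d latent mean matrix.
#' @export
kl_loss <- function(mu, reduction = c("mean", "sum")) {
  reduction <- match.arg(reduction)
  per_sample <- 0.5 * rowSums(mu^2)
  if (reduction == "mean") mean(per_sample) else sum(per_sample)
}

#' @rdname reconstruction_loss
#' @param y_hat Predicted probabilities in (0, 1).
#' @param y Truth labels in \{0, 1\}.
#' @export
classification_loss <- function(y_hat, y, reduction = c("mean", "sum")) {
  reduction <- match.arg(reduction)
  if (length(y_hat) != length(y)) abort("y_hat and y must have equal length")
  if (any(y_hat <= 0) || any(y_hat >= 1)) {
    inform("classification_loss: probabilities clamped to [1e-7, 1 - 1e-7]")
  }
  p <- pmin(pmax(y_hat, 1e-7), 1 - 1e-7)
  per_sample <- -(y * log(p) + (1 - y) * log(1 - p))
  if (reduction == "mean") mean(per_sample) else sum(per_sample)
}

#' Composite loss breakdown
#'
#' @param reconstruction,kl,classification The three loss terms.
#' @param lambda_rec,lambda_kl Weights on reconstruction and KL.
#' @return Tibble with columns `total`, `reconstruction`, `kl`,
#'   `classification`; `total = lambda_rec * reconstruction +
#'   lambda_kl * kl + classification`.
#' @export
total_loss <- function(reconstruction, kl, classification,
                       lambda_rec = 0.1, lambda_kl = 0.2) {
  stopifnot(is.finite(reconstruction), is.finite(kl), is.finite(classification))
  tibble::tibble(total = lambda_rec * reconstruction + lambda_kl * kl + classification,
                 reconstruction = reconstruction, kl = kl,
                 classification = classification)
}

# ---- internal forward passes ---------------------------------------------

coerce_input_matrix <- function(model, x) {
  if (is.data.frame(x)) x <- abundance_matrix(x)
  if (ncol(x) != model$config$input_dim) {
    abort(sprintf("input has %d features, model expects %d",
                  ncol(x), model$config$input_dim))
  }
  x
}

forward_encoder <- function(model, x, training) {
  p <- model$params
  l1 <- nn_linear_fwd(x, p$enc_W1, p$enc_b1)
  bn1 <- nn_bn_fwd(l1, p$enc_g1, p$enc_be1, model$bn$enc1, training)
  r1 <- nn_relu_fwd(bn1$out)
  mu <- nn_linear_fwd(r1, p$enc_W2, p$enc_b2)
  list(mu = mu, x = x, l1 = l1, bn1 = bn1, r1 = r1)
}

forward_decoder <- function(model, zt, training) {
  p <- model$params
  l1 <- nn_linear_fwd(zt, p$dec_W1, p$dec_b1)
  bn1 <- nn_bn_fwd(l1, p$dec_g1, p$dec_be1, model$bn$dec1, training)
  r1 <- nn_relu_fwd(bn1$out)
  l2 <- nn_linear_fwd(r1, p$dec_W2, p$dec_b2)
  bn2 <- nn_bn_fwd(l2, p$dec_g2, p$dec_be2, model$bn$dec2, training)
  xr <- sigmoid(bn2$out)
  list(xr = xr, zt = zt, bn1 = bn1, r1 = r1, bn2 = bn2)
}

forward_classifier <- function(model, mu, training) {
  p <- model$params
  l1 <- nn_linear_fwd(mu, p$cls_W1, p$cls_b1)
  bn1 <- nn_bn_fwd(l1, p$cls_g1, p$cls_be1, model$bn$cls1, training)
  r1 <- nn_relu_fwd(bn1$out)
  l2 <- nn_linear_fwd(r1, p$cls_W2, p$cls_b2)
  bn2 <- nn_bn_fwd(l2, p$cls_g2, p$cls_be2, model$bn$cls2, training)
  r2 <- nn_relu_fwd(bn2$out)
  logit <- nn_linear_fwd(r2, p$cls_W3, p$cls_b3)
  list(yhat = sigmoid(logit), logit = logit, mu = mu,
       bn1 = bn1, r1 = r1, bn2 = bn2, r2 = r2)
}

# Full training-mode forward pass with caches, plus the loss breakdown.
pvae_forward <- function(model, x, y, x_target = x, training = TRUE,
                         sample_eps = training) {
  p <- model$params
  cfg <- model$config
  enc <- forward_encoder(model, x, training)
  rep_ <- pvae_reparameterize(enc$mu, sample = sample_eps)
  rp <- nn_linear_fwd(model$prior, p$pri_W, p$pri_b)
  att <- nn_attention_fwd(enc$mu, rp, p, cfg$n_heads)
  zt <- cfg$lambda_fuse * rep_$z + (1 - cfg$lambda_fuse) * att$out
  dec <- forward_decoder(model, zt, training)
  cls <- forward_classifier(model, enc$mu, training)
  rec <- reconstruction_loss(dec$xr, x_target)
  kl <- kl_loss(enc$mu, reduction = cfg$loss_reduction)
  clsl <- classification_loss_logits(drop(cls$logit), y, cfg$loss_reduction)
  loss <- total_loss(rec, kl, clsl, cfg$lambda_rec, cfg$lambda_kl)
  list(loss = loss, enc = enc, rep = rep_, rp = rp, att = att, zt = zt,
       dec = dec, cls = cls, x_target = x_target, y = y)
}

# Numerically stable BCE from logits (value matches classification_loss up
# to the probability clamp).
classification_loss_logits <- function(logit, y, reduction) {
  per_sample <- ifelse(logit > 0,
                       logit - y * logit + log1p(exp(-logit)),
                       -y * logit + log1p(exp(logit)))
  if (reduction == "mean") mean(per_sample) else sum(per_sample)
}

# Backward pass: gradients for every parameter. The prior matrix receives
# no gradient by construction.
pvae_backward <- function(model, fw) {
  p <- model$params
  cfg <- model$config
  b <- nrow(fw$enc$x)
  g <- list()

  # classification head
  yhat <- drop(fw$cls$yhat)
  dlogit <- matrix(yhat - fw$y, b, 1)
  if (cfg$loss_reduction == "mean") dlogit <- dlogit / b
  lb <- nn_linear_bwd(dlogit, fw$cls$r2, p$cls_W3)
  g$cls_W3 <- lb$dW; g$cls_b3 <- lb$db
  dr2 <- lb$dx * (fw$cls$bn2$out > 0)
  bb <- nn_bn_bwd(dr2, fw$cls$bn2$cache)
  g$cls_g2 <- bb$dgamma; g$cls_be2 <- bb$dbeta
  lb <- nn_linear_bwd(bb$dx, fw$cls$r1, p$cls_W2)
  g$cls_W2 <- lb$dW; g$cls_b2 <- lb$db
  dr1 <- lb$dx * (fw$cls$bn1$out > 0)
  bb <- nn_bn_bwd(dr1, fw$cls$bn1$cache)
  g$cls_g1 <- bb$dgamma; g$cls_be1 <- bb$dbeta
  lb <- nn_linear_bwd(bb$dx, fw$enc$mu, p$cls_W1)
  g$cls_W1 <- lb$dW; g$cls_b1 <- lb$db
  dmu <- lb$dx

  # decoder / reconstruction
  dxr <- cfg$lambda_rec * 2 * (fw$dec$xr - fw$x_target) / b
  do2 <- dxr * fw$dec$xr * (1 - fw$dec$xr)
  bb <- nn_bn_bwd(do2, fw$dec$bn2$cache)
  g$dec_g2 <- bb$dgamma; g$dec_be2 <- bb$dbeta
  lb <- nn_linear_bwd(bb$dx, fw$dec$r1, p$dec_W2)
  g$dec_W2 <- lb$dW; g$dec_b2 <- lb$db
  dr1 <- lb$dx * (fw$dec$bn1$out > 0)
  bb <- nn_bn_bwd(dr1, fw$dec$bn1$cache)
  g$dec_g1 <- bb$dgamma; g$dec_be1 <- bb$dbeta
  lb <- nn_linear_bwd(bb$dx, fw$zt, p$dec_W1)
  g$dec_W1 <- lb$dW; g$dec_b1 <- lb$db
  dzt <- lb$dx

  # fusion: z path feeds mu directly (z = mu + eps); a path feeds attention
  dmu <- dmu + cfg$lambda_fuse * dzt
  da <- (1 - cfg$lambda_fuse) * dzt
  ab <- nn_attention_bwd(da, fw$att$cache, p)
  g$att_Wq <- ab$dWq; g$att_Wk <- ab$dWk; g$att_Wv <- ab$dWv
  g$att_Wo <- ab$dWo; g$att_bo <- ab$dbo
  g$ln_g <- ab$dln_g; g$ln_b <- ab$dln_b
  dmu <- dmu + ab$dmu
  g$pri_W <- crossprod(model$prior, ab$drp)
  g$pri_b <- colSums(ab$drp)

  # KL term
  dkl <- cfg$lambda_kl * fw$enc$mu
  if (cfg$loss_reduction == "mean") dkl <- dkl / b
  dmu <- dmu + dkl

  # encoder
  lb <- nn_linear_bwd(dmu, fw$enc$r1, p$enc_W2)
  g$enc_W2 <- lb$dW; g$enc_b2 <- lb$db
  dr1 <- lb$dx * (fw$enc$bn1$out > 0)
  bb <- nn_bn_bwd(dr1, fw$enc$bn1$cache)
  g$enc_g1 <- bb$dgamma; g$enc_be1 <- bb$dbeta
  lb <- nn_linear_bwd(bb$dx, fw$enc$x, p$enc_W1)
  g$enc_W1 <- lb$dW; g$enc_b1 <- lb$db
  g
}

# Gradient of the positive-class probability w.r.t. the input, in
# evaluation mode (affine batch norm from running statistics). Only the
# encoder -> classifier path contributes; used by integrated gradients.
pvae_input_gradient <- function(model, x) {
  x <- coerce_input_matrix(model, x)
  enc <- forward_encoder(model, x, training = FALSE)
  cls <- forward_classifier(model, enc$mu, training = FALSE)
  p <- model$params
  yhat <- drop(cls$yhat)
  dlogit <- matrix(yhat * (1 - yhat), nrow(x), 1)
  dr2 <- tcrossprod(dlogit, p$cls_W3) * (cls$bn2$out > 0)
  d2 <- nn_bn_bwd(dr2, cls$bn2$cache)$dx
  dr1 <- tcrossprod(d2, p$cls_W2) * (cls$bn1$out > 0)
  d1 <- nn_bn_bwd(dr1, cls$bn1$cache)$dx
  dmu <- tcrossprod(d1, p$cls_W1)
  de <- tcrossprod(dmu, p$enc_W2) * (enc$bn1$out > 0)
  de <- nn_bn_bwd(de, enc$bn1$cache)$dx
  tcrossprod(de, p$enc_W1)
}
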