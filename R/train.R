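#' Training settings
#'
#' Defaults mirror the study protocol: 500 epochs, batch size 8, Adam with
#' learning rate 1e-3, seed 42. No early stopping and no learning-rate
#' schedule. Trailing batches of size 1 are dropped (batch normalization
#' needs batch statistics) and reported once.
#'
#' @param epochs Number of passes over the training data.
#' @param batch_size Mini-batch size.
#' @param learning_rate Adam learning rate.
#' @param seed Seed driving shuffling and reparameterization noise.
#' @return An object of class `pvae_train_settings`.
#' @export
pvae_train_settings <- function(epochs = 500, batch_size = 8,
                                learning_rate = 1e-3, seed = 42) {
  stopifnot(epochs >= 0, batch_size >= 2, learning_rate > 0)
  structure(list(epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, seed = as.integer(seed)),
            class = "pvae_train_settings")
}

#' Train the prior-conditioned VAE
#'
#' Runs mini-batch Adam on the composite loss for exactly
#' `settings$epochs` epochs (`epochs = 0` returns the initialized model
#' unchanged). Inputs are expected standardized (see [fit_scaler()]);
#' samples are joined to labels on `sample_id`.
#'
#' @param ab Standardized abundance tibble.
#' @param labels Label tibble (`sample_id`, `response`).
#' @param prior Prior tibble or P x E matrix (fixed; never updated).
#' @param config A [pvae_config()]; `input_dim` is filled from the data
#'   when `NULL`.
#' @param settings A [pvae_train_settings()].
#' @return A trained `pvae_model`; `$history` holds the per-epoch loss
#'   breakdown (`epoch`, `total`, `reconstruction`, `kl`,
#'   `classification`).
#' @export
pvae_train <- function(ab, labels, prior, config = NULL,
                       settings = pvae_train_settings()) {
  j <- join_cohort(ab, labels)
  x <- abundance_matrix(j$abundance)
  y <- j$labels$response
  if (is.null(config)) config <- pvae_config(input_dim = ncol(x))
  if (is.null(config$input_dim)) config$input_dim <- ncol(x)
  rmat <- if (is.matrix(prior)) prior else prior_matrix(prior)
  model <- pvae_model(config, rmat)
  model$feature_ids <- colnames(x)
  x_target <- make_reconstruction_target(x, config$reconstruction_target)
  model <- pvae_fit(model, x, y, x_target, settings)
  model
}

make_reconstruction_target <- function(x, mode) {
  if (mode == "zscore") return(x)
  lo <- apply(x, 2, min)
  hi <- apply(x, 2, max)
  rng <- hi - lo
  rng[rng == 0] <- 1
  sweep(sweep(x, 2, lo, "-"), 2, rng, "/")
}

# Core optimization loop over an already-initialized model.
pvae_fit <- function(model, x, y, x_target, settings) {
  n <- nrow(x)
  if (n < 2) abort("training needs at least 2 samples")
  adam <- adam_init(model$params)
  set.seed(settings$seed)
  hist <- vector("list", settings$epochs)
  warned_drop <- FALSE
  for (ep in seq_len(settings$epochs)) {
    perm <- sample.int(n)
    starts <- seq(1, n, by = settings$batch_size)
    ep_loss <- c(total = 0, reconstruction = 0, kl = 0, classification = 0)
    ep_n <- 0L
    for (s in starts) {
      idx <- perm[s:min(s + settings$batch_size - 1L, n)]
      if (length(idx) < 2) {
        if (!warned_drop) {
          inform("dropping trailing batch of size 1 (batch normalization)")
          warned_drop <- TRUE
        }
        next
      }
      fw <- pvae_forward(model, x[idx, , drop = FALSE], y[idx],
                         x_target[idx, , drop = FALSE], training = TRUE)
      check_finite_loss(fw$loss)
      model$bn$enc1 <- fw$enc$bn1$state
      model$bn$dec1 <- fw$dec$bn1$state
      model$bn$dec2 <- fw$dec$bn2$state
      model$bn$cls1 <- fw$cls$bn1$state
      model$bn$cls2 <- fw$cls$bn2$state
      g <- pvae_backward(model, fw)
      st <- adam_step(model$params, g, adam, lr = settings$learning_rate)
      model$params <- st$params
      adam <- st$state
      w <- length(idx)
      ep_loss <- ep_loss + w * unlist(fw$loss[1, c("total", "reconstruction",
                                                   "kl", "classification")])
      ep_n <- ep_n + w
    }
    hist[[ep]] <- ep_loss / ep_n
  }
  if (settings$epochs > 0) {
    h <- do.call(rbind, hist)
    model$history <- tibble::tibble(epoch = seq_len(settings$epochs),
                                    total = h[, "total"],
                                    reconstruction = h[, "reconstruction"],
                                    kl = h[, "kl"],
                                    classification = h[, "classification"])
  }
  model$trained_epochs <- model$trained_epochs + settings$epochs
  model
}

check_finite_loss <- function(loss) {
  for (term in c("reconstruction", "kl", "classification", "total")) {
    if (!is.finite(loss[[term]])) {
      abort(sprintf("non-finite %s loss during training", term))
    }
  }
}

#' Predict from a trained model
#'
#' Evaluation-mode forward pass (deterministic: `eps = 0`, running
#' batch-norm statistics).
#'
#' @param object A trained `pvae_model`.
#' @param new_data Standardized abundance tibble (or matrix) with the
#'   model's feature columns.
#' @param type `"prob"` (response probability), `"class"` (thresholded at
#'   0.5) or `"latent"` (the latent mean matrix).
#' @param ... Unused.
#' @return For `"prob"`/`"class"`, a tibble `sample_id`, `.pred`; for
#'   `"latent"`, a B x d matrix.
#' @export
predict.pvae_model <- function(object, new_data,
                               type = c("prob", "class", "latent"), ...) {
  type <- match.arg(type)
  sid <- if (is.data.frame(new_data)) new_data$sample_id else rownames(new_data)
  x <- coerce_input_matrix(object, new_data)
  mu <- pvae_encode(object, x, training = FALSE)
  if (type == "latent") return(mu)
  prob <- pvae_classify(object, mu, training = FALSE)
  if (is.null(sid)) sid <- paste0("s", seq_along(prob))
  if (type == "class") {
    tibble::tibble(sample_id = sid, .pred = as.integer(prob >= 0.5))
  } else {
    tibble::tibble(sample_id = sid, .pred = prob)
  }
}
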