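# Internal layer primitives for the prior-conditioned VAE.
#
# Everything is plain matrix algebra on BLAS: linear maps, batch
# normalization (running statistics, momentum 0.1), layer normalization,
# ReLU, scaled dot-product multi-head attention, and an Adam optimizer.
# Each *_fwd returns its output together with the cache its *_bwd needs;
# analytic gradients are verified against central finite differences in the
# test suite.

# column-broadcast helpers: column-major recycling avoids sweep()'s aperm
addcol <- function(x, v) x + rep(v, each = nrow(x))
mulcol <- function(x, v) x * rep(v, each = nrow(x))

nn_linear_fwd <- function(x, W, b) {
  addcol(x %*% W, b)
}

# dout -> list(dx, dW, db)
nn_linear_bwd <- function(dout, x, W) {
  list(dx = tcrossprod(dout, W), dW = crossprod(x, dout), db = colSums(dout))
}

nn_relu_fwd <- function(x) {
  x * (x > 0)
}

BN_EPS <- 1e-5
BN_MOMENTUM <- 0.1

# Batch normalization. `state` holds running mean/var (initialized 0/1);
# training mode normalizes by batch statistics (population variance) and
# updates the running statistics with the unbiased batch variance.
nn_bn_fwd <- function(x, gamma, beta, state, training) {
  if (training) {
    if (nrow(x) < 2) stop("batch normalization needs batch size >= 2 in training mode")
    bm <- colMeans(x)
    bv <- colMeans(x^2) - bm^2
    bv[bv < 0] <- 0
    inv <- 1 / sqrt(bv + BN_EPS)
    xhat <- mulcol(addcol(x, -bm), inv)
    b <- nrow(x)
    unb <- bv * b / (b - 1)
    state$mean <- (1 - BN_MOMENTUM) * state$mean + BN_MOMENTUM * bm
    state$var <- (1 - BN_MOMENTUM) * state$var + BN_MOMENTUM * unb
  } else {
    inv <- 1 / sqrt(state$var + BN_EPS)
    xhat <- mulcol(addcol(x, -state$mean), inv)
  }
  out <- addcol(mulcol(xhat, gamma), beta)
  list(out = out, state = state,
       cache = list(xhat = xhat, inv = inv, gamma = gamma, training = training))
}

nn_bn_bwd <- function(dout, cache) {
  xhat <- cache$xhat
  dgamma <- colSums(dout * xhat)
  dbeta <- colSums(dout)
  dxhat <- mulcol(dout, cache$gamma)
  if (cache$training) {
    b <- nrow(dout)
    m1 <- rep(colMeans(dxhat), each = b)
    m2 <- rep(colMeans(dxhat * xhat), each = b)
    dx <- mulcol(dxhat - m1 - xhat * m2, cache$inv)
  } else {
    dx <- mulcol(dxhat, cache$inv)
  }
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

LN_EPS <- 1e-5

# Layer normalization across features, per sample, with learnable scale/shift.
nn_ln_fwd <- function(x, gamma, beta) {
  mu <- rowMeans(x)
  va <- rowMeans(x^2) - mu^2
  va[va < 0] <- 0
  inv <- 1 / sqrt(va + LN_EPS)
  xhat <- (x - mu) * inv
  out <- addcol(mulcol(xhat, gamma), beta)
  list(out = out, cache = list(xhat = xhat, inv = inv, gamma = gamma))
}

nn_ln_bwd <- function(dout, cache) {
  xhat <- cache$xhat
  dgamma <- colSums(dout * xhat)
  dbeta <- colSums(dout)
  dxhat <- mulcol(dout, cache$gamma)
  dx <- (dxhat - rowMeans(dxhat) - xhat * rowMeans(dxhat * xhat)) * cache$inv
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

row_softmax <- function(s) {
  s <- s - s[cbind(seq_len(nrow(s)), max.col(s, ties.method = "first"))]
  e <- exp(s)
  e / rowSums(e)
}

# Multi-head scaled dot-product attention with the sample latent mean as
# query and the projected prior rows as keys and values. Wq/Wk/Wv are d x d
# with head h occupying the h-th block of dh columns; Wo is d x d.
nn_attention_fwd <- function(mu, rp, p, n_heads) {
  d <- ncol(mu)
  dh <- d %/% n_heads
  q <- mu %*% p$att_Wq
  k <- rp %*% p$att_Wk
  v <- rp %*% p$att_Wv
  o <- matrix(0, nrow(mu), d)
  aw <- vector("list", n_heads)
  for (h in seq_len(n_heads)) {
    cols <- ((h - 1) * dh + 1):(h * dh)
    s <- tcrossprod(q[, cols, drop = FALSE], k[, cols, drop = FALSE]) / sqrt(dh)
    if (any(!is.finite(s))) stop("non-finite attention logits")
    a <- row_softmax(s)
    aw[[h]] <- a
    o[, cols] <- a %*% v[, cols, drop = FALSE]
  }
  u <- addcol(o %*% p$att_Wo, p$att_bo)
  ln <- nn_ln_fwd(u, p$ln_g, p$ln_b)
  list(out = ln$out, weights = aw,
       cache = list(q = q, k = k, v = v, o = o, mu = mu, rp = rp,
                    aw = aw, dh = dh, n_heads = n_heads, ln = ln$cache))
}

nn_attention_bwd <- function(dout, cache, p) {
  lnb <- nn_ln_bwd(dout, cache$ln)
  du <- lnb$dx
  dWo <- crossprod(cache$o, du)
  dbo <- colSums(du)
  do_ <- tcrossprod(du, p$att_Wo)
  d <- ncol(do_)
  dh <- cache$dh
  dq <- matrix(0, nrow(do_), d)
  dk <- matrix(0, nrow(cache$rp), d)
  dv <- matrix(0, nrow(cache$rp), d)
  for (h in seq_len(cache$n_heads)) {
    cols <- ((h - 1) * dh + 1):(h * dh)
    a <- cache$aw[[h]]
    doh <- do_[, cols, drop = FALSE]
    da <- tcrossprod(doh, cache$v[, cols, drop = FALSE])
    dv[, cols] <- crossprod(a, doh)
    ds <- a * (da - rowSums(da * a))
    dq[, cols] <- (ds %*% cache$k[, cols, drop = FALSE]) / sqrt(dh)
    dk[, cols] <- (crossprod(ds, cache$q[, cols, drop = FALSE])) / sqrt(dh)
  }
  list(dmu = tcrossprod(dq, p$att_Wq),
       drp = tcrossprod(dk, p$att_Wk) + tcrossprod(dv, p$att_Wv),
       dWq = crossprod(cache$mu, dq),
       dWk = crossprod(cache$rp, dk),
       dWv = crossprod(cache$rp, dv),
       dWo = dWo, dbo = dbo,
       dln_g = lnb$dgamma, dln_b = lnb$dbeta)
}

sigmoid <- function(x) 1 / (1 + exp(-x))

# Fan-in uniform initialization (U(-1/sqrt(fan_in), 1/sqrt(fan_in)) for both
# weights and biases), drawn from the current RNG stream.
init_linear <- function(fan_in, fan_out) {
  a <- 1 / sqrt(fan_in)
  list(W = matrix(runif(fan_in * fan_out, -a, a), fan_in, fan_out),
       b = runif(fan_out, -a, a))
}

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

# One Adam step; updates params and the moment estimates in place through
# the compiled kernel (the training loop owns all three exclusively).
adam_step <- function(params, grads, state, lr = 1e-3,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  for (nm in names(grads)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    adam_update_inplace(params[[nm]], g, state$m[[nm]], state$v[[nm]],
                        lr, beta1, beta2, eps, state$t)
  }
  list(params = params, state = state)
}
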