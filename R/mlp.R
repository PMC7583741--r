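# Minimal dense networks with hand-written backpropagation and Adam.
# The policy and Q-functions are small multilayer perceptrons over the
# flattened board; all heavy lifting is BLAS matrix products, which keeps a
# gradient step cheap enough for CPU-only training loops in R.

# He-initialized fully connected net: sizes = c(in, hidden..., out),
# ReLU on hidden layers, linear output.
mlp_init <- function(sizes, rng) {
  n_layers <- length(sizes) - 1
  w <- vector("list", n_layers)
  b <- vector("list", n_layers)
  for (l in seq_len(n_layers)) {
    sd <- sqrt(2 / sizes[l])
    w[[l]] <- matrix(rng_rnorm(rng, sizes[l] * sizes[l + 1], sd = sd),
                     sizes[l], sizes[l + 1])
    b[[l]] <- numeric(sizes[l + 1])
  }
  list(w = w, b = b, sizes = sizes)
}

# X: batch x in. Returns output and the per-layer activations needed by
# mlp_backward.
mlp_forward <- function(net, x) {
  n_layers <- length(net$w)
  acts <- vector("list", n_layers + 1)
  acts[[1]] <- x
  for (l in seq_len(n_layers)) {
    z <- x %*% net$w[[l]]
    z <- z + rep(net$b[[l]], each = nrow(z))
    if (l < n_layers) z[z < 0] <- 0   # ReLU, in place
    acts[[l + 1]] <- z
    x <- z
  }
  list(out = acts[[n_layers + 1]], acts = acts)
}

# d_out: gradient of the scalar loss w.r.t. the network output.
mlp_backward <- function(net, fwd, d_out) {
  n_layers <- length(net$w)
  gw <- vector("list", n_layers)
  gb <- vector("list", n_layers)
  delta <- d_out
  for (l in n_layers:1) {
    gw[[l]] <- crossprod(fwd$acts[[l]], delta)
    gb[[l]] <- colSums(delta)
    if (l > 1) {
      delta <- tcrossprod(delta, net$w[[l]])
      delta <- delta * (fwd$acts[[l]] > 0)   # ReLU mask (acts are post-ReLU)
    }
  }
  list(w = gw, b = gb)
}

adam_init <- function(net) {
  zeros_like <- function(p) lapply(p, function(m) m * 0)
  list(mw = zeros_like(net$w), vw = zeros_like(net$w),
       mb = zeros_like(net$b), vb = zeros_like(net$b),
       t = 0L, beta1 = 0.9, beta2 = 0.999, eps = 1e-8)
}

# One Adam step; returns list(net, opt).
adam_step <- function(net, grads, opt, lr) {
  opt$t <- opt$t + 1L
  c1 <- 1 - opt$beta1^opt$t
  c2 <- 1 - opt$beta2^opt$t
  for (l in seq_along(net$w)) {
    opt$mw[[l]] <- opt$beta1 * opt$mw[[l]] + (1 - opt$beta1) * grads$w[[l]]
    opt$vw[[l]] <- opt$beta2 * opt$vw[[l]] + (1 - opt$beta2) * grads$w[[l]]^2
    net$w[[l]] <- net$w[[l]] -
      lr * (opt$mw[[l]] / c1) / (sqrt(opt$vw[[l]] / c2) + opt$eps)
    opt$mb[[l]] <- opt$beta1 * opt$mb[[l]] + (1 - opt$beta1) * grads$b[[l]]
    opt$vb[[l]] <- opt$beta2 * opt$vb[[l]] + (1 - opt$beta2) * grads$b[[l]]^2
    net$b[[l]] <- net$b[[l]] -
      lr * (opt$mb[[l]] / c1) / (sqrt(opt$vb[[l]] / c2) + opt$eps)
  }
  list(net = net, opt = opt)
}

softmax_rows <- function(z) {
  m <- z[cbind(seq_len(nrow(z)), max.col(z, ties.method = "first"))]
  e <- exp(z - m)
  e / rowSums(e)
}
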