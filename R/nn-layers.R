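# Neural-network primitives: 1-D convolution, batch normalization, leaky
# ReLU, tanh, average pooling, fully connected layers and (partitioned)
# multi-head self-attention, each with a hand-written backward pass on BLAS
# matrix operations.
#
# Conventions
#   * feature maps are arrays of dim (channels, time, batch)
#   * fully connected activations are matrices of dim (features, batch)
#   * all parameters of a model live in one environment `P`, keyed by a
#     unique name; gradients accumulate in a parallel environment `G`
#   * a layer is a plain list describing its type, parameter names and
#     hyper-parameters; `layer_fwd()` returns list(out, cache) and
#     `layer_bwd()` returns the input gradient, adding parameter gradients
#     into `G` (skipped when `G` is NULL, used when only input gradients are
#     needed, e.g. generator updates through a frozen discriminator)

new_registry <- function() {
  reg <- new.env(parent = emptyenv())
  reg$P <- new.env(parent = emptyenv())
  reg$trainable <- character()
  reg$stats <- character()
  reg
}

reg_param <- function(reg, name, value, trainable = TRUE) {
  if (!is.null(reg$P[[name]])) stop("duplicate parameter name: ", name)
  reg$P[[name]] <- value
  if (trainable) reg$trainable <- c(reg$trainable, name)
  else reg$stats <- c(reg$stats, name)
  name
}

# He-style fan-in scaled init
w_init <- function(n_out, n_in_eff) {
  matrix(rnorm(n_out * n_in_eff, 0, sqrt(2 / n_in_eff)), n_out, n_in_eff)
}

nn_conv1d <- function(reg, prefix, c_in, c_out, k = 3, stride = 1, pad = (k - 1) %/% 2) {
  list(type = "conv", k = k, stride = stride, pad = pad, c_in = c_in, c_out = c_out,
       W = reg_param(reg, paste0(prefix, ".W"), w_init(c_out, c_in * k)),
       b = reg_param(reg, paste0(prefix, ".b"), numeric(c_out)))
}

nn_bn <- function(reg, prefix, c_ch, momentum = 0.1, eps = 1e-5) {
  list(type = "bn", c_ch = c_ch, momentum = momentum, eps = eps,
       gamma = reg_param(reg, paste0(prefix, ".gamma"), rep(1, c_ch)),
       beta = reg_param(reg, paste0(prefix, ".beta"), numeric(c_ch)),
       rm = reg_param(reg, paste0(prefix, ".rm"), numeric(c_ch), trainable = FALSE),
       rv = reg_param(reg, paste0(prefix, ".rv"), rep(1, c_ch), trainable = FALSE))
}

nn_lrelu <- function(slope = 0.2) list(type = "lrelu", slope = slope)
nn_tanh <- function() list(type = "tanh")
nn_pool2 <- function() list(type = "pool2")
nn_flatten <- function() list(type = "flatten")

nn_linear <- function(reg, prefix, f_in, f_out) {
  list(type = "linear", f_in = f_in, f_out = f_out,
       W = reg_param(reg, paste0(prefix, ".W"), w_init(f_out, f_in)),
       b = reg_param(reg, paste0(prefix, ".b"), numeric(f_out)))
}

# partitioned multi-head self-attention with a residual connection;
# partitions = 1 gives global attention over the full token sequence.
# `buf` holds the layer's softmax-cache buffer, reused across training steps;
# one training-mode forward must be consumed by its backward before the next.
nn_mha <- function(reg, prefix, c_ch, heads, partitions = 1) {
  stopifnot(c_ch %% heads == 0)
  xav <- function() matrix(rnorm(c_ch * c_ch, 0, sqrt(1 / c_ch)), c_ch, c_ch)
  list(type = "mha", c_ch = c_ch, heads = heads, partitions = partitions,
       buf = new.env(parent = emptyenv()),
       Wq = reg_param(reg, paste0(prefix, ".Wq"), xav()),
       Wk = reg_param(reg, paste0(prefix, ".Wk"), xav()),
       Wv = reg_param(reg, paste0(prefix, ".Wv"), xav()),
       Wo = reg_param(reg, paste0(prefix, ".Wo"), xav()),
       bq = reg_param(reg, paste0(prefix, ".bq"), numeric(c_ch)),
       bk = reg_param(reg, paste0(prefix, ".bk"), numeric(c_ch)),
       bv = reg_param(reg, paste0(prefix, ".bv"), numeric(c_ch)),
       bo = reg_param(reg, paste0(prefix, ".bo"), numeric(c_ch)))
}

# token-wise two-layer feedforward with a residual connection
nn_ff <- function(reg, prefix, c_ch, hidden = 2 * c_ch, slope = 0.2) {
  list(type = "ff", c_ch = c_ch, hidden = hidden, slope = slope,
       W1 = reg_param(reg, paste0(prefix, ".W1"), w_init(hidden, c_ch)),
       b1 = reg_param(reg, paste0(prefix, ".b1"), numeric(hidden)),
       W2 = reg_param(reg, paste0(prefix, ".W2"), w_init(c_ch, hidden)),
       b2 = reg_param(reg, paste0(prefix, ".b2"), numeric(c_ch)))
}

g_acc <- function(G, name, d) {
  if (!is.null(G)) {
    cur <- G[[name]]
    G[[name]] <- if (is.null(cur)) d else cur + d
  }
}

conv_out_len <- function(T_in, k, stride, pad) (T_in + 2 * pad - k) %/% stride + 1L

conv_fwd <- function(ly, P, x) {
  d <- dim(x); C <- d[1]; T_in <- d[2]; B <- d[3]
  k <- ly$k; s <- ly$stride; p <- ly$pad
  To <- conv_out_len(T_in, k, s, p)
  if (To < 1) stop("conv output length < 1")
  if (p > 0) {
    xp <- array(0, c(C, T_in + 2 * p, B))
    xp[, (p + 1):(p + T_in), ] <- x
  } else xp <- x
  Xc <- im2col_cpp(xp, k, s, To)
  Y <- P[[ly$W]] %*% Xc + P[[ly$b]]
  dim(Y) <- c(ly$c_out, To, B)
  list(out = Y, cache = list(Xc = Xc, T_in = T_in, To = To, B = B, C = C))
}

conv_bwd <- function(ly, P, G, cache, dy) {
  C <- cache$C; To <- cache$To; B <- cache$B; T_in <- cache$T_in
  k <- ly$k; s <- ly$stride; p <- ly$pad
  dYm <- matrix(dy, ly$c_out, To * B)
  g_acc(G, ly$W, tcrossprod(dYm, cache$Xc))
  g_acc(G, ly$b, rowSums(dYm))
  dXc <- crossprod(P[[ly$W]], dYm)
  dxp <- col2im_cpp(dXc, C, T_in + 2 * p, B, k, s, To)
  if (p > 0) dxp[, (p + 1):(p + T_in), , drop = FALSE] else dxp
}

bn_fwd <- function(ly, P, x, training) {
  d <- dim(x); C <- d[1]
  M <- matrix(x, C)
  if (training) {
    st <- bn_stats_cpp(M)
    mu <- as.vector(st$mu)
    v <- as.vector(st$v)
    P[[ly$rm]] <- (1 - ly$momentum) * P[[ly$rm]] + ly$momentum * mu
    P[[ly$rv]] <- (1 - ly$momentum) * P[[ly$rv]] + ly$momentum * v
  } else {
    mu <- P[[ly$rm]]
    v <- P[[ly$rv]]
  }
  inv_std <- 1 / sqrt(v + ly$eps)
  ap <- bn_apply_cpp(M, mu, inv_std, P[[ly$gamma]], P[[ly$beta]])
  y <- ap$y
  dim(y) <- d
  list(out = y,
       cache = list(xhat = ap$xhat, inv_std = inv_std, d = d, training = training))
}

bn_bwd <- function(ly, P, G, cache, dy) {
  d <- cache$d; C <- d[1]
  dY <- matrix(dy, C)
  if (cache$training) {
    r <- bn_bwd_cpp(dY, cache$xhat, cache$inv_std, P[[ly$gamma]])
    g_acc(G, ly$gamma, as.vector(r$dgamma))
    g_acc(G, ly$beta, as.vector(r$dbeta))
    dx <- r$dx
  } else {
    g_acc(G, ly$gamma, rowSums(dY * cache$xhat))
    g_acc(G, ly$beta, rowSums(dY))
    dx <- dY * (P[[ly$gamma]] * cache$inv_std)
  }
  dim(dx) <- d
  dx
}

lrelu_fwd <- function(ly, x) {
  y <- lrelu_fwd_flat(x, ly$slope)
  dim(y) <- dim(x)
  list(out = y, cache = y) # sign of the output recovers the mask
}

lrelu_bwd <- function(ly, cache, dy) {
  dx <- lrelu_bwd_flat(cache, dy, ly$slope)
  dim(dx) <- dim(dy)
  dx
}

tanh_fwd <- function(x) {
  y <- tanh(x)
  list(out = y, cache = y)
}
tanh_bwd <- function(cache, dy) dy * (1 - cache^2)

pool2_fwd <- function(x) {
  d <- dim(x)
  stopifnot(d[2] %% 2 == 0)
  list(out = pool2_fwd_cpp(x), cache = d)
}

pool2_bwd <- function(cache, dy) pool2_bwd_cpp(dy)

flatten_fwd <- function(x) {
  d <- dim(x)
  list(out = matrix(x, d[1] * d[2], d[3]), cache = d)
}
flatten_bwd <- function(cache, dy) array(dy, cache)

linear_fwd <- function(ly, P, x) {
  list(out = P[[ly$W]] %*% x + P[[ly$b]], cache = x)
}

linear_bwd <- function(ly, P, G, cache, dy) {
  g_acc(G, ly$W, dy %*% t(cache))
  g_acc(G, ly$b, rowSums(dy))
  crossprod(P[[ly$W]], dy)
}

mha_fwd <- function(ly, P, x, training = FALSE) {
  d <- dim(x); C <- d[1]; T_tok <- d[2]; B <- d[3]
  np <- ly$partitions
  if (T_tok %% np != 0) {
    abort(sprintf("token count %d not divisible by %d partitions.", T_tok, np),
          class = "eeggan_config_error")
  }
  X2 <- matrix(x, C)
  Q <- P[[ly$Wq]] %*% X2 + P[[ly$bq]]; dim(Q) <- d
  K <- P[[ly$Wk]] %*% X2 + P[[ly$bk]]; dim(K) <- d
  V <- P[[ly$Wv]] %*% X2 + P[[ly$bv]]; dim(V) <- d
  r <- attn_fwd_cpp(Q, K, V, ly$heads, np, keep_cache = training,
                    pool = ly$buf$cache)
  if (training) ly$buf$cache <- r$cache
  O <- r$O
  Y <- P[[ly$Wo]] %*% matrix(O, C) + P[[ly$bo]]; dim(Y) <- d
  list(out = x + Y,
       cache = list(X2 = X2, Q = Q, K = K, V = V, O = O, d = d,
                    attn = r$cache))
}

mha_bwd <- function(ly, P, G, cache, dy) {
  d <- cache$d; C <- d[1]
  dY2 <- matrix(dy, C)
  g_acc(G, ly$Wo, tcrossprod(dY2, matrix(cache$O, C)))
  g_acc(G, ly$bo, rowSums(dY2))
  dO <- crossprod(P[[ly$Wo]], dY2); dim(dO) <- d
  gr <- attn_bwd_cpp(cache$Q, cache$K, cache$V, dO, ly$heads, ly$partitions,
                     cache$attn)
  dQ2 <- matrix(gr$dQ, C); dK2 <- matrix(gr$dK, C); dV2 <- matrix(gr$dV, C)
  g_acc(G, ly$Wq, tcrossprod(dQ2, cache$X2)); g_acc(G, ly$bq, rowSums(dQ2))
  g_acc(G, ly$Wk, tcrossprod(dK2, cache$X2)); g_acc(G, ly$bk, rowSums(dK2))
  g_acc(G, ly$Wv, tcrossprod(dV2, cache$X2)); g_acc(G, ly$bv, rowSums(dV2))
  dX2 <- crossprod(P[[ly$Wq]], dQ2) + crossprod(P[[ly$Wk]], dK2) +
    crossprod(P[[ly$Wv]], dV2)
  dy + array(dX2, d)
}

ff_fwd <- function(ly, P, x) {
  d <- dim(x); C <- d[1]
  X2 <- matrix(x, C)
  A <- P[[ly$W1]] %*% X2 + P[[ly$b1]]
  Z <- lrelu_fwd_flat(A, ly$slope)
  dim(Z) <- dim(A)
  Y <- P[[ly$W2]] %*% Z + P[[ly$b2]]
  dim(Y) <- d
  list(out = x + Y, cache = list(X2 = X2, Z = Z, d = d))
}

ff_bwd <- function(ly, P, G, cache, dy) {
  d <- cache$d; C <- d[1]
  dY2 <- matrix(dy, C)
  g_acc(G, ly$W2, tcrossprod(dY2, cache$Z))
  g_acc(G, ly$b2, rowSums(dY2))
  dZ <- crossprod(P[[ly$W2]], dY2)
  dA <- lrelu_bwd_flat(cache$Z, dZ, ly$slope)
  dim(dA) <- dim(dZ)
  g_acc(G, ly$W1, tcrossprod(dA, cache$X2))
  g_acc(G, ly$b1, rowSums(dA))
  dX <- crossprod(P[[ly$W1]], dA)
  dim(dX) <- d
  dy + dX
}

layer_fwd <- function(ly, P, x, training = FALSE) {
  switch(ly$type,
    conv = conv_fwd(ly, P, x),
    bn = bn_fwd(ly, P, x, training),
    lrelu = lrelu_fwd(ly, x),
    tanh = tanh_fwd(x),
    pool2 = pool2_fwd(x),
    flatten = flatten_fwd(x),
    linear = linear_fwd(ly, P, x),
    mha = mha_fwd(ly, P, x, training),
    ff = ff_fwd(ly, P, x),
    stop("unknown layer type: ", ly$type)
  )
}

layer_bwd <- function(ly, P, G, cache, dy) {
  switch(ly$type,
    conv = conv_bwd(ly, P, G, cache, dy),
    bn = bn_bwd(ly, P, G, cache, dy),
    lrelu = lrelu_bwd(ly, cache, dy),
    tanh = tanh_bwd(cache, dy),
    pool2 = pool2_bwd(cache, dy),
    flatten = flatten_bwd(cache, dy),
    linear = linear_bwd(ly, P, G, cache, dy),
    mha = mha_bwd(ly, P, G, cache, dy),
    ff = ff_bwd(ly, P, G, cache, dy),
    stop("unknown layer type: ", ly$type)
  )
}

seq_fwd <- function(layers, P, x, training = FALSE) {
  caches <- vector("list", length(layers))
  for (i in seq_along(layers)) {
    r <- layer_fwd(layers[[i]], P, x, training)
    x <- r$out
    caches[[i]] <- r$cache
  }
  list(out = x, caches = caches)
}

seq_bwd <- function(layers, P, G, caches, dy) {
  for (i in rev(seq_along(layers))) {
    dy <- layer_bwd(layers[[i]], P, G, caches[[i]], dy)
  }
  dy
}

# Adam optimizer over the named trainable parameters of a model
adam_new <- function(P, names) {
  opt <- new.env(parent = emptyenv())
  opt$t <- 0L
  opt$m <- new.env(parent = emptyenv())
  opt$v <- new.env(parent = emptyenv())
  for (nm in names) {
    opt$m[[nm]] <- P[[nm]] * 0
    opt$v[[nm]] <- P[[nm]] * 0
  }
  opt
}

adam_step <- function(P, G, opt, names, lr, beta1, beta2, eps = 1e-8) {
  opt$t <- opt$t + 1L
  b1t <- 1 - beta1^opt$t
  b2t <- 1 - beta2^opt$t
  for (nm in names) {
    g <- G[[nm]]
    if (is.null(g)) next
    opt$m[[nm]] <- beta1 * opt$m[[nm]] + (1 - beta1) * g
    opt$v[[nm]] <- beta2 * opt$v[[nm]] + (1 - beta2) * g^2
    P[[nm]] <- P[[nm]] - lr * (opt$m[[nm]] / b1t) / (sqrt(opt$v[[nm]] / b2t) + eps)
  }
  invisible(NULL)
}

g_reset <- function(G) {
  rm(list = ls(G), envir = G)
  invisible(G)
}

model_n_params <- function(model) {
  sum(vapply(model$trainable, function(nm) length(model$P[[nm]]), 0))
}

model_state <- function(model) {
  s <- as.list(model$P)
  s[order(names(s))]
}

model_restore <- function(model, state) {
  for (nm in names(state)) model$P[[nm]] <- state[[nm]]
  invisible(model)
}
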