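#' Generator configuration
#'
#' The generator has two structurally identical branches — one learns the
#' clean-EEG distribution, the other the noise distribution — plus two
#' tanh-gating networks that fuse the branch outputs. Each branch is:
#' preprocessing (two 1-D convolutions to `pre_dim` channels and a k=2/s=2
#' average pooling, halving the token count), five encoding blocks run as
#' two parallel streams (a CNN stream of conv/BN/LReLU pairs and a
#' local-global Transformer stream whose blocks compute partition-local
#' self-attention, a feedforward, global self-attention, a second
#' feedforward, then a conv/BN/LReLU tail), a fusion layer (channel
#' concatenation, 1x1 convolution, BN), and a decoder (two convolutions and
#' one fully connected layer back to `input_len` samples). Channel widths
#' follow `encoder_dims` and every encoding block halves the token count.
#'
#' @param input_len segment length in samples.
#' @param pre_dim channel count after preprocessing.
#' @param encoder_dims channel widths of the five encoding blocks.
#' @param local_partitions number of contiguous chunks for local attention;
#'   must divide the token count at every block.
#' @param conv_kernel kernel size of the convolutional layers.
#' @param lrelu_slope negative slope of the leaky ReLU activations.
#' @param width_scale uniform divisor applied to all channel widths for
#'   desk-scale runs (1 = the full-size network).
#' @param gate_hidden hidden width of the two gating networks.
#' @param n_heads attention heads per attention stage.
#' @param seed integer seed for weight initialization.
#' @param branch_mode `"dual"` (default), `"clean_only"` or `"noise_only"`
#'   (ablation switches: single-branch variants skip the gated fusion).
#' @param transformer `"lgtb"` (default local-global blocks), `"plain"`
#'   (single global self-attention stage per block) or `"none"` (CNN stream
#'   only).
#' @return A `generator_config` list.
#' @export
generator_config <- function(input_len = 1024, pre_dim = 32,
                             encoder_dims = c(64, 128, 256, 512, 1024),
                             local_partitions = 8, conv_kernel = 3,
                             lrelu_slope = 0.2, width_scale = 1,
                             gate_hidden = 512, n_heads = 4, seed = 1,
                             branch_mode = c("dual", "clean_only", "noise_only"),
                             transformer = c("lgtb", "plain", "none")) {
  branch_mode <- match.arg(branch_mode)
  transformer <- match.arg(transformer)
  ws <- width_scale
  if (ws <= 0) abort("`width_scale` must be positive.", class = "eeggan_config_error")
  sdim <- function(v) {
    out <- as.integer(round(v / ws))
    if (any(out < 1)) abort("width_scale reduces a channel width below 1.",
                            class = "eeggan_config_error")
    out
  }
  cfg <- list(input_len = as.integer(input_len), pre_dim = sdim(pre_dim),
              encoder_dims = sdim(encoder_dims),
              n_blocks = length(encoder_dims),
              local_partitions = as.integer(local_partitions),
              conv_kernel = as.integer(conv_kernel),
              lrelu_slope = lrelu_slope, width_scale = ws,
              gate_hidden = sdim(gate_hidden), n_heads = as.integer(n_heads),
              seed = as.integer(seed), branch_mode = branch_mode,
              transformer = transformer)
  # token schedule: input_len/2 after preprocessing, then halved per block
  tok <- cfg$input_len %/% 2L
  for (i in seq_len(cfg$n_blocks)) {
    if (cfg$transformer != "none" && tok %% cfg$local_partitions != 0) {
      abort(sprintf("local_partitions (%d) must divide the token count (%d) at block %d.",
                    cfg$local_partitions, tok, i), class = "eeggan_config_error")
    }
    tok <- tok %/% 2L
  }
  cfg$latent_tokens <- as.integer(cfg$input_len / 2 / 2^cfg$n_blocks)
  if (cfg$latent_tokens < 1) abort("input too short for the encoder depth.",
                                   class = "eeggan_config_error")
  if (any(c(cfg$pre_dim, cfg$encoder_dims) %% cfg$n_heads != 0) &&
      cfg$transformer != "none") {
    abort("`n_heads` must divide pre_dim and every encoder width.",
          class = "eeggan_config_error")
  }
  class(cfg) <- "generator_config"
  cfg
}

build_branch <- function(reg, prefix, cfg) {
  k <- cfg$conv_kernel
  sl <- cfg$lrelu_slope
  pre <- list(
    nn_conv1d(reg, paste0(prefix, ".pre1"), 1, cfg$pre_dim, k),
    nn_lrelu(sl),
    nn_conv1d(reg, paste0(prefix, ".pre2"), cfg$pre_dim, cfg$pre_dim, k),
    nn_lrelu(sl),
    nn_pool2()
  )
  cnn <- list()
  lgtb <- list()
  c_in <- cfg$pre_dim
  for (i in seq_len(cfg$n_blocks)) {
    c_out <- cfg$encoder_dims[i]
    cnn <- c(cnn, list(
      nn_conv1d(reg, sprintf("%s.cnn%d.c1", prefix, i), c_in, c_out, k, stride = 2, pad = 1),
      nn_bn(reg, sprintf("%s.cnn%d.bn1", prefix, i), c_out),
      nn_lrelu(sl),
      nn_conv1d(reg, sprintf("%s.cnn%d.c2", prefix, i), c_out, c_out, k),
      nn_bn(reg, sprintf("%s.cnn%d.bn2", prefix, i), c_out),
      nn_lrelu(sl)
    ))
    if (cfg$transformer == "lgtb") {
      lgtb <- c(lgtb, list(
        nn_mha(reg, sprintf("%s.lg%d.lsa", prefix, i), c_in, cfg$n_heads,
               partitions = cfg$local_partitions),
        nn_ff(reg, sprintf("%s.lg%d.ff1", prefix, i), c_in, slope = sl),
        nn_mha(reg, sprintf("%s.lg%d.gsa", prefix, i), c_in, cfg$n_heads, partitions = 1),
        nn_ff(reg, sprintf("%s.lg%d.ff2", prefix, i), c_in, slope = sl),
        nn_conv1d(reg, sprintf("%s.lg%d.tail", prefix, i), c_in, c_out, k, stride = 2, pad = 1),
        nn_bn(reg, sprintf("%s.lg%d.bn", prefix, i), c_out),
        nn_lrelu(sl)
      ))
    } else if (cfg$transformer == "plain") {
      lgtb <- c(lgtb, list(
        nn_mha(reg, sprintf("%s.lg%d.sa", prefix, i), c_in, cfg$n_heads, partitions = 1),
        nn_ff(reg, sprintf("%s.lg%d.ff", prefix, i), c_in, slope = sl),
        nn_conv1d(reg, sprintf("%s.lg%d.tail", prefix, i), c_in, c_out, k, stride = 2, pad = 1),
        nn_bn(reg, sprintf("%s.lg%d.bn", prefix, i), c_out),
        nn_lrelu(sl)
      ))
    }
    c_in <- c_out
  }
  c5 <- cfg$encoder_dims[cfg$n_blocks]
  fusion <- if (cfg$transformer == "none") {
    list(nn_conv1d(reg, paste0(prefix, ".fuse"), c5, c5, 1, pad = 0),
         nn_bn(reg, paste0(prefix, ".fusebn"), c5))
  } else {
    list(nn_conv1d(reg, paste0(prefix, ".fuse"), 2 * c5, c5, 1, pad = 0),
         nn_bn(reg, paste0(prefix, ".fusebn"), c5))
  }
  dec_mid <- max(1L, c5 %/% 4L)
  dec_ch <- max(1L, as.integer(round(32 / cfg$width_scale)))
  decoder <- list(
    nn_conv1d(reg, paste0(prefix, ".dec1"), c5, dec_mid, k),
    nn_lrelu(sl),
    nn_conv1d(reg, paste0(prefix, ".dec2"), dec_mid, dec_ch, k),
    nn_lrelu(sl),
    nn_flatten(),
    nn_linear(reg, paste0(prefix, ".decfc"), dec_ch * cfg$latent_tokens, cfg$input_len)
  )
  list(pre = pre, cnn = cnn, lgtb = lgtb, fusion = fusion, decoder = decoder)
}

#' Build a generator with freshly initialized weights
#'
#' @param cfg a [generator_config()].
#' @return An object of class `eeggan_generator` holding the architecture,
#'   the parameter environment and the trainable-parameter names.
#' @export
new_generator <- function(cfg = generator_config()) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(cfg$seed)
  reg <- new_registry()
  branches <- list(b1 = build_branch(reg, "b1", cfg),
                   b2 = build_branch(reg, "b2", cfg))
  gh <- cfg$gate_hidden
  gate <- function(prefix) {
    layers <- list(
      nn_linear(reg, paste0(prefix, ".fc1"), cfg$input_len, gh),
      nn_lrelu(cfg$lrelu_slope),
      nn_linear(reg, paste0(prefix, ".fc2"), gh, cfg$input_len),
      nn_tanh()
    )
    # warm start: small input-dependent term around a half-open gate, so the
    # initial fused output is close to half the raw input instead of noise
    fc2 <- layers[[3]]
    reg$P[[fc2$W]] <- reg$P[[fc2$W]] * 0.01
    reg$P[[fc2$b]] <- rep(atanh(0.5), cfg$input_len)
    layers
  }
  gates <- list(g1 = gate("g1"), g2 = gate("g2"))
  structure(list(cfg = cfg, branches = branches, gates = gates,
                 P = reg$P, trainable = sort(reg$trainable),
                 stats = sort(reg$stats)),
            class = "eeggan_generator")
}

#' @export
print.eeggan_generator <- function(x, ...) {
  cat(sprintf("<eeggan_generator> input_len=%d dims=[%s] width_scale=%g params=%s\n",
              x$cfg$input_len, paste(x$cfg$encoder_dims, collapse = ","),
              x$cfg$width_scale, format(model_n_params(x), big.mark = ",")))
  invisible(x)
}

# raw (B x T) signal matrix -> (1, T, B) feature-map array
as_feature_map <- function(xraw) {
  array(t(xraw), c(1L, ncol(xraw), nrow(xraw)))
}

branch_fwd <- function(br, P, xraw, training) {
  x <- as_feature_map(xraw)
  pre <- seq_fwd(br$pre, P, x, training)
  cnn <- seq_fwd(br$cnn, P, pre$out, training)
  if (length(br$lgtb) > 0) {
    lg <- seq_fwd(br$lgtb, P, pre$out, training)
    fused_in <- abind_ch(cnn$out, lg$out)
  } else {
    lg <- NULL
    fused_in <- cnn$out
  }
  fus <- seq_fwd(br$fusion, P, fused_in, training)
  dec <- seq_fwd(br$decoder, P, fus$out, training)
  list(out = t(dec$out), # back to (B x T)
       cache = list(pre = pre$caches, cnn = cnn$caches,
                    lg = if (is.null(lg)) NULL else lg$caches,
                    fus = fus$caches, dec = dec$caches,
                    c_cnn = dim(cnn$out)[1]))
}

branch_bwd <- function(br, P, G, cache, dout) {
  dy <- t(dout) # (T x B) matrix feeding the decoder's final linear layer
  dfus_out <- seq_bwd(br$decoder, P, G, cache$dec, dy)
  dfused_in <- seq_bwd(br$fusion, P, G, cache$fus, dfus_out)
  if (!is.null(cache$lg)) {
    c_cnn <- cache$c_cnn
    d_cnn <- dfused_in[seq_len(c_cnn), , , drop = FALSE]
    d_lg <- dfused_in[(c_cnn + 1):dim(dfused_in)[1], , , drop = FALSE]
    dpre1 <- seq_bwd(br$cnn, P, G, cache$cnn, d_cnn)
    dpre2 <- seq_bwd(br$lgtb, P, G, cache$lg, d_lg)
    dpre <- dpre1 + dpre2
  } else {
    dpre <- seq_bwd(br$cnn, P, G, cache$cnn, dfused_in)
  }
  dx <- seq_bwd(br$pre, P, G, cache$pre, dpre)
  t(matrix(dx, dim(dx)[2], dim(dx)[3])) # (B x T), rarely needed
}

# concatenate two (C, T, B) maps on the channel axis
abind_ch <- function(a, b) {
  da <- dim(a); db <- dim(b)
  stopifnot(da[2] == db[2], da[3] == db[3])
  out <- array(0, c(da[1] + db[1], da[2], da[3]))
  out[seq_len(da[1]), , ] <- a
  out[(da[1] + 1):(da[1] + db[1]), , ] <- b
  out
}

gate_fwd <- function(gl, P, xraw, training) {
  r <- seq_fwd(gl, P, t(xraw), training)
  list(out = t(r$out), cache = r$caches)
}

gate_bwd <- function(gl, P, G, cache, dout) {
  dx <- seq_bwd(gl, P, G, cache, t(dout))
  t(dx)
}

#' Gated fusion of the two branch outputs
#'
#' `ypre = mask1 * y1 + mask2 * (xraw - y2)`: the first branch's clean
#' estimate and the residual after subtracting the second branch's noise
#' estimate, blended elementwise by the tanh gating masks.
#'
#' @param xraw raw input segments (batch x samples matrix).
#' @param y1 branch-1 clean estimate, same shape.
#' @param y2 branch-2 noise estimate, same shape.
#' @param mask1,mask2 gating masks in (-1, 1), same shape.
#' @return The fused clean estimate, same shape.
#' @export
fuse <- function(xraw, y1, y2, mask1, mask2) {
  dims <- lapply(list(xraw, y1, y2, mask1, mask2), dim)
  if (length(unique(dims)) != 1L) {
    abort("all five inputs must share the same shape.", class = "eeggan_invalid_input")
  }
  mask1 * y1 + mask2 * (xraw - y2)
}

#' Run the generator forward
#'
#' @param gen an [new_generator()] model.
#' @param xraw batch of raw segments (batch x samples matrix; a vector is
#'   treated as one segment).
#' @param training logical; `TRUE` uses batch statistics in the BN layers
#'   and keeps the caches needed for a backward pass.
#' @return List with `y1` (branch-1 clean estimate), `y2` (branch-2 noise
#'   estimate), `mask1`, `mask2` (gating masks in (-1, 1)) and `ypre` (the
#'   fused clean estimate), all batch x samples; plus `cache` when
#'   `training = TRUE`.
#' @export
generator_forward <- function(gen, xraw, training = FALSE) {
  if (is.vector(xraw)) xraw <- matrix(xraw, nrow = 1)
  if (ncol(xraw) != gen$cfg$input_len) {
    abort(sprintf("input length %d != configured input_len %d.",
                  ncol(xraw), gen$cfg$input_len), class = "eeggan_shape_error")
  }
  P <- gen$P
  b1 <- branch_fwd(gen$branches$b1, P, xraw, training)
  b2 <- branch_fwd(gen$branches$b2, P, xraw, training)
  g1 <- gate_fwd(gen$gates$g1, P, xraw, training)
  g2 <- gate_fwd(gen$gates$g2, P, xraw, training)
  y1 <- b1$out; y2 <- b2$out
  mask1 <- g1$out; mask2 <- g2$out
  ypre <- switch(gen$cfg$branch_mode,
    dual = fuse(xraw, y1, y2, mask1, mask2),
    clean_only = y1,
    noise_only = xraw - y2
  )
  out <- list(y1 = y1, y2 = y2, mask1 = mask1, mask2 = mask2, ypre = ypre)
  if (training) {
    out$cache <- list(b1 = b1$cache, b2 = b2$cache, g1 = g1$cache, g2 = g2$cache,
                      xraw = xraw, y1 = y1, y2 = y2, mask1 = mask1, mask2 = mask2)
  }
  out
}

# backward through fusion, gates and both branches; d_* are (B x T) gradients
# of the loss w.r.t. y1, y2 and ypre
generator_backward <- function(gen, cache, d_y1, d_y2, d_ypre, G) {
  P <- gen$P
  mode <- gen$cfg$branch_mode
  if (mode == "dual") {
    dy1 <- d_y1 + d_ypre * cache$mask1
    dy2 <- d_y2 - d_ypre * cache$mask2
    dm1 <- d_ypre * cache$y1
    dm2 <- d_ypre * (cache$xraw - cache$y2)
    gate_bwd(gen$gates$g1, P, G, cache$g1, dm1)
    gate_bwd(gen$gates$g2, P, G, cache$g2, dm2)
  } else if (mode == "clean_only") {
    dy1 <- d_y1 + d_ypre
    dy2 <- d_y2
  } else {
    dy1 <- d_y1
    dy2 <- d_y2 - d_ypre
  }
  branch_bwd(gen$branches$b1, P, G, cache$b1, dy1)
  branch_bwd(gen$branches$b2, P, G, cache$b2, dy2)
  invisible(NULL)
}
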