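#' Discriminator configuration
#'
#' Three structurally identical discriminators guide training: D1 scores
#' branch-1 clean estimates against real clean EEG, D2 scores branch-2 noise
#' estimates against the true noise component, D3 scores the fused output
#' against real clean EEG. Each is a stack of `n_layers` 1-D convolutions
#' (kernel 3, stride 2, padding 1, so the temporal length halves at every
#' stage: 1024 -> 4 after eight stages), each followed by batch
#' normalization and a leaky ReLU, then a single fully connected layer to a
#' scalar realism score. No sigmoid is applied by default (least-squares GAN
#' convention); the post-activation feature maps of all stages are exposed
#' for the feature loss.
#'
#' @param channels output channels of the convolutional stages.
#' @param kernel,stride,padding convolution hyper-parameters.
#' @param lrelu_slope negative slope of the leaky ReLU.
#' @param width_scale uniform channel-width divisor for desk-scale runs.
#' @param input_len segment length; must survive `n_layers` halvings.
#' @param use_sigmoid apply a sigmoid to the final score (ablation switch).
#' @param seed integer seed for weight initialization.
#' @return A `discriminator_config` list.
#' @export
discriminator_config <- function(channels = c(64, 64, 128, 128, 256, 256, 512, 512),
                                 kernel = 3, stride = 2, padding = 1,
                                 lrelu_slope = 0.2, width_scale = 1,
                                 input_len = 1024, use_sigmoid = FALSE, seed = 1) {
  ws <- width_scale
  ch <- as.integer(round(channels / ws))
  if (any(ch < 1)) abort("width_scale reduces a channel width below 1.",
                         class = "eeggan_config_error")
  n_layers <- length(channels)
  if (input_len %% 2^n_layers != 0) {
    abort(sprintf("input_len %d does not survive %d stride-2 halvings.",
                  input_len, n_layers), class = "eeggan_config_error")
  }
  structure(list(channels = ch, kernel = as.integer(kernel),
                 stride = as.integer(stride), padding = as.integer(padding),
                 n_layers = n_layers, lrelu_slope = lrelu_slope,
                 width_scale = ws, input_len = as.integer(input_len),
                 use_sigmoid = use_sigmoid, seed = as.integer(seed)),
            class = "discriminator_config")
}

#' Build a discriminator with freshly initialized weights
#'
#' @param cfg a [discriminator_config()].
#' @return An object of class `eeggan_discriminator`.
#' @export
new_discriminator <- function(cfg = discriminator_config()) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(cfg$seed)
  reg <- new_registry()
  stages <- vector("list", cfg$n_layers)
  c_in <- 1L
  for (i in seq_len(cfg$n_layers)) {
    c_out <- cfg$channels[i]
    stages[[i]] <- list(
      nn_conv1d(reg, sprintf("d.s%d.conv", i), c_in, c_out, cfg$kernel,
                stride = cfg$stride, pad = cfg$padding),
      nn_bn(reg, sprintf("d.s%d.bn", i), c_out),
      nn_lrelu(cfg$lrelu_slope)
    )
    c_in <- c_out
  }
  final_len <- cfg$input_len %/% 2^cfg$n_layers
  head_fc <- nn_linear(reg, "d.head", c_in * final_len, 1L)
  structure(list(cfg = cfg, stages = stages, head = head_fc,
                 P = reg$P, trainable = sort(reg$trainable),
                 stats = sort(reg$stats)),
            class = "eeggan_discriminator")
}

#' @export
print.eeggan_discriminator <- function(x, ...) {
  cat(sprintf("<eeggan_discriminator> channels=[%s] params=%s\n",
              paste(x$cfg$channels, collapse = ","),
              format(model_n_params(x), big.mark = ",")))
  invisible(x)
}

#' Run a discriminator forward
#'
#' @param disc an [new_discriminator()] model.
#' @param s batch of segment-shaped inputs (batch x samples matrix).
#' @param training logical; `TRUE` uses batch statistics in BN layers and
#'   keeps caches for a backward pass.
#' @return List with `score` (numeric vector, one realism score per batch
#'   item), `features` (ordered list of the post-activation feature maps of
#'   every stage) and `cache` when `training = TRUE`.
#' @export
discriminator_forward <- function(disc, s, training = FALSE) {
  if (is.vector(s)) s <- matrix(s, nrow = 1)
  if (ncol(s) != disc$cfg$input_len) {
    abort(sprintf("input length %d != configured input_len %d.",
                  ncol(s), disc$cfg$input_len), class = "eeggan_shape_error")
  }
  P <- disc$P
  x <- as_feature_map(s)
  features <- vector("list", disc$cfg$n_layers)
  caches <- vector("list", disc$cfg$n_layers)
  for (i in seq_along(disc$stages)) {
    r <- seq_fwd(disc$stages[[i]], P, x, training)
    x <- r$out
    features[[i]] <- x
    caches[[i]] <- r$caches
  }
  fl <- flatten_fwd(x)
  hd <- linear_fwd(disc$head, P, fl$out)
  score <- as.vector(hd$out)
  if (disc$cfg$use_sigmoid) score <- 1 / (1 + exp(-score))
  out <- list(score = score, features = features)
  if (training) out$cache <- list(stages = caches, flat = fl$cache,
                                  head = hd$cache, raw_score = as.vector(hd$out))
  out
}

# backward through the discriminator; dscore is d(loss)/d(score) per item,
# dfeatures an optional list of per-stage gradient injections (feature loss).
# G = NULL backpropagates to the input without touching parameter gradients
# (generator updates through a frozen discriminator).
discriminator_backward <- function(disc, cache, dscore, dfeatures = NULL, G = NULL) {
  P <- disc$P
  if (disc$cfg$use_sigmoid) {
    sig <- 1 / (1 + exp(-cache$raw_score))
    dscore <- dscore * sig * (1 - sig)
  }
  dflat <- linear_bwd(disc$head, P, G, cache$head, matrix(dscore, nrow = 1))
  dx <- flatten_bwd(cache$flat, dflat)
  for (i in rev(seq_along(disc$stages))) {
    if (!is.null(dfeatures) && !is.null(dfeatures[[i]])) {
      dx <- dx + dfeatures[[i]]
    }
    dx <- seq_bwd(disc$stages[[i]], P, G, cache$stages[[i]], dx)
  }
  # back to (B x T)
  t(matrix(dx, dim(dx)[2], dim(dx)[3]))
}
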