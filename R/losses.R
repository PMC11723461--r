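#' Loss system
#'
#' The generator is trained on three branch losses, each combining a mean
#' squared error term against its regression target, a feature-matching term
#' (MSE between discriminator intermediate features of prediction and
#' target, averaged over all stages) and a least-squares adversarial term
#' `mean((D(pred) - 1)^2)`:
#'
#' * branch 1: clean estimate `y1` vs the clean EEG `x`, scored by D1;
#' * branch 2: noise estimate `y2` vs the scaled noise component
#'   `lambda * n` (the quantity the fusion subtracts from the input), scored
#'   by D2;
#' * fused output `ypre` vs `x`, scored by D3.
#'
#' The total generator loss is their sum. Each discriminator is trained on
#' `mean(0.5 * D(fake)^2 + 0.5 * (D(real) - 1)^2)`.
#'
#' @name losses
NULL

#' Feature- and adversarial-loss weights
#'
#' @param lambda1 weight of the feature loss.
#' @param lambda2 weight of the adversarial loss.
#' @return A `loss_weights` list.
#' @export
loss_weights <- function(lambda1 = 0.01, lambda2 = 0.01) {
  if (lambda1 < 0 || lambda2 < 0) abort("loss weights must be >= 0.",
                                        class = "eeggan_invalid_input")
  list(lambda1 = lambda1, lambda2 = lambda2)
}

#' @rdname losses
#' @param pred,target equal-shaped numeric arrays (batch x samples).
#' @return `mse_loss()`: the mean squared error over all elements (per-sample
#'   MSE averaged over the batch).
#' @export
mse_loss <- function(pred, target) {
  if (!identical(dim(pred), dim(target)) && length(pred) != length(target)) {
    abort("`pred` and `target` must have equal shapes.", class = "eeggan_invalid_input")
  }
  mean((pred - target)^2)
}

disc_apply <- function(disc, s, training = FALSE) {
  if (is.function(disc)) {
    list(score = disc(s), features = NULL)
  } else {
    discriminator_forward(disc, s, training = training)
  }
}

#' @rdname losses
#' @param disc an `eeggan_discriminator` (or, for score-only losses, any
#'   function mapping a batch matrix to a score vector).
#' @param training use batch statistics in the discriminator's BN layers.
#' @return `feature_loss()`: mean over discriminator stages of the MSE
#'   between the stage's features for `pred` and for `target`.
#' @export
feature_loss <- function(pred, target, disc, training = FALSE) {
  fp <- discriminator_forward(disc, pred, training = training)$features
  ft <- discriminator_forward(disc, target, training = training)$features
  mean(vapply(seq_along(fp), function(m) mean((fp[[m]] - ft[[m]])^2), 0))
}

#' @rdname losses
#' @return `adversarial_loss()`: `mean((D(pred) - 1)^2)`.
#' @export
adversarial_loss <- function(pred, disc, training = FALSE) {
  s <- disc_apply(disc, pred, training)$score
  mean((s - 1)^2)
}

#' @rdname losses
#' @param real,fake batches of real and generated segments.
#' @return `discriminator_loss()`:
#'   `mean(0.5 * D(fake)^2 + 0.5 * (D(real) - 1)^2)`.
#' @export
discriminator_loss <- function(real, fake, disc, training = FALSE) {
  sr <- disc_apply(disc, real, training)$score
  sf <- disc_apply(disc, fake, training)$score
  mean(0.5 * sf^2 + 0.5 * (sr - 1)^2)
}

#' @rdname losses
#' @param outputs a [generator_forward()] result.
#' @param x clean EEG batch (ground truth).
#' @param noise_target the scaled noise component `lambda * n` of each
#'   segment (batch x samples).
#' @param discs list of the three discriminators `list(d1, d2, d3)`.
#' @param w a [loss_weights()].
#' @return `branch_losses()`: a `loss_report` — tibble with one row per
#'   branch (`mse`, `feat`, `adv`, `total`) plus attributes `ltotal`.
#' @export
branch_losses <- function(outputs, x, noise_target, discs, w = loss_weights(),
                          training = FALSE) {
  if (length(discs) != 3 || any(vapply(discs, is.null, TRUE))) {
    abort("three discriminators are required.", class = "eeggan_config_error")
  }
  preds <- list(outputs$y1, outputs$y2, outputs$ypre)
  targets <- list(x, noise_target, x)
  rows <- purrr::map_dfr(1:3, function(k) {
    m <- mse_loss(preds[[k]], targets[[k]])
    f <- if (w$lambda1 > 0) feature_loss(preds[[k]], targets[[k]], discs[[k]], training) else 0
    a <- if (w$lambda2 > 0) adversarial_loss(preds[[k]], discs[[k]], training) else 0
    tibble(branch = k, mse = m, feat = f, adv = a,
           total = m + w$lambda1 * f + w$lambda2 * a)
  })
  attr(rows, "ltotal") <- sum(rows$total)
  class(rows) <- c("loss_report", class(rows))
  rows
}
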