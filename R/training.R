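#' Training configuration
#'
#' Alternating adversarial training: in every iteration the three
#' discriminators are each updated on their own least-squares loss with the
#' generator frozen, then the generator is updated on the total branch loss
#' with the discriminators frozen. Validation MSE of the fused output is
#' computed after every epoch; training stops early once it has worsened
#' more than `early_stop_C` consecutive epochs, and the best-validation
#' checkpoint (not the last) is returned.
#'
#' @param batch_size minibatch size.
#' @param max_epochs epoch cap.
#' @param lr_gen,lr_disc Adam learning rates (the generator default follows
#'   the conservative of the two published settings; `1e-3` is the other).
#' @param gen_adam,disc_adam Adam `(beta1, beta2)` for generator and
#'   discriminators.
#' @param early_stop_C early-stopping patience (consecutive worsenings).
#' @param inner_K discriminator/generator update pairs per outer iteration.
#' @param lambda1,lambda2 feature- and adversarial-loss weights.
#' @param seed integer seed controlling shuffling (and, via derived seeds,
#'   model initialization in [fit_denoiser()]).
#' @return A `train_config` list.
#' @export
train_config <- function(batch_size = 40, max_epochs = 1000,
                         lr_gen = 1e-4, lr_disc = 1e-4,
                         gen_adam = c(0.5, 0.9), disc_adam = c(0.9, 0.999),
                         early_stop_C = 5, inner_K = 1,
                         lambda1 = 0.01, lambda2 = 0.01, seed = 1) {
  if (batch_size < 1) abort("`batch_size` must be >= 1.", class = "eeggan_config_error")
  if (any(c(gen_adam, disc_adam) <= 0) || any(c(gen_adam, disc_adam) >= 1)) {
    abort("Adam betas must lie in (0, 1).", class = "eeggan_config_error")
  }
  list(batch_size = as.integer(batch_size), max_epochs = as.integer(max_epochs),
       lr_gen = lr_gen, lr_disc = lr_disc,
       gen_adam = gen_adam, disc_adam = disc_adam,
       early_stop_C = as.integer(early_stop_C), inner_K = as.integer(inner_K),
       weights = loss_weights(lambda1, lambda2), seed = as.integer(seed))
}

# standardize a pair_set: every mixture by its own sd, the same factor
# applied to the clean target and the noise component
standardize_pairs <- function(ps) {
  scales <- apply(ps$Y, 1, sd)
  if (any(scales <= 0)) abort("zero-variance mixture segment.",
                              class = "eeggan_degenerate_input")
  list(Y = ps$Y / scales, X = ps$X / scales,
       NL = sweep(ps$N, 1, ps$lam, `*`) / scales,
       scales = scales, snr_db = ps$snr_db, fs = ps$fs,
       artifact_type = ps$artifact_type)
}

# one alternating update on a standardized batch; returns the loss report
train_step_impl <- function(gen, discs, opts, batch, tcfg) {
  w <- tcfg$weights
  B <- nrow(batch$Y)
  out <- generator_forward(gen, batch$Y, training = TRUE)
  preds <- list(out$y1, out$y2, out$ypre)
  targets <- list(batch$X, batch$NL, batch$X)

  ld <- numeric(3)
  for (k in 1:3) {
    # discriminator update, generator frozen (fakes are plain values)
    fr <- discriminator_forward(discs[[k]], targets[[k]], training = TRUE)
    ff <- discriminator_forward(discs[[k]], preds[[k]], training = TRUE)
    sr <- fr$score; sf <- ff$score
    ld[k] <- mean(0.5 * sf^2 + 0.5 * (sr - 1)^2)
    G <- new.env(parent = emptyenv())
    discriminator_backward(discs[[k]], fr$cache, (sr - 1) / B, G = G)
    discriminator_backward(discs[[k]], ff$cache, sf / B, G = G)
    adam_step(discs[[k]]$P, G, opts$disc[[k]], discs[[k]]$trainable,
              tcfg$lr_disc, tcfg$disc_adam[1], tcfg$disc_adam[2])
  }

  # generator update, discriminators frozen
  l_mse <- l_feat <- l_adv <- numeric(3)
  dpred <- vector("list", 3)
  for (k in 1:3) {
    p <- preds[[k]]; tg <- targets[[k]]
    l_mse[k] <- mean((p - tg)^2)
    d_mse <- 2 * (p - tg) / length(p)
    fp <- discriminator_forward(discs[[k]], p, training = TRUE)
    ft <- discriminator_forward(discs[[k]], tg, training = TRUE)
    per_stage <- vapply(seq_along(fp$features),
                        function(m) mean((fp$features[[m]] - ft$features[[m]])^2), 0)
    l_feat[k] <- mean(per_stage)
    l_adv[k] <- mean((fp$score - 1)^2)
    M <- length(fp$features)
    dfeat <- lapply(seq_len(M), function(m) {
      w$lambda1 * 2 * (fp$features[[m]] - ft$features[[m]]) /
        (length(fp$features[[m]]) * M)
    })
    dscore <- w$lambda2 * 2 * (fp$score - 1) / B
    dpred[[k]] <- d_mse +
      discriminator_backward(discs[[k]], fp$cache, dscore, dfeatures = dfeat, G = NULL)
  }
  G <- new.env(parent = emptyenv())
  generator_backward(gen, out$cache, dpred[[1]], dpred[[2]], dpred[[3]], G)
  adam_step(gen$P, G, opts$gen, gen$trainable,
            tcfg$lr_gen, tcfg$gen_adam[1], tcfg$gen_adam[2])

  total <- l_mse + w$lambda1 * l_feat + w$lambda2 * l_adv
  report <- tibble(branch = 1:3, mse = l_mse, feat = l_feat, adv = l_adv,
                   total = total)
  ltotal <- sum(total)
  if (!is.finite(ltotal) || any(!is.finite(ld))) {
    abort("training diverged (non-finite loss).", class = "eeggan_divergence")
  }
  list(report = report, ltotal = ltotal, ld = ld)
}

#' One alternating adversarial training step
#'
#' Updates the three discriminators on their own losses (generator frozen),
#' then the generator on the total branch loss (discriminators frozen).
#' Mainly useful for inspection; [fit_denoiser()] drives whole runs.
#'
#' @param models list with `gen` (generator), `discs` (list of three
#'   discriminators) and `opts` (optimizer states as built by
#'   [fit_denoiser()]; pass the list returned by a previous call to keep
#'   state).
#' @param batch list with standardized matrices `Y` (mixtures), `X` (clean),
#'   `NL` (scaled noise), each batch x samples.
#' @param tcfg a [train_config()].
#' @return List with `models` (updated in place), `report` (per-branch loss
#'   tibble), `ltotal` and `ld` (discriminator losses).
#' @export
train_step <- function(models, batch, tcfg = train_config()) {
  if (is.null(models$opts)) {
    models$opts <- list(
      gen = adam_new(models$gen$P, models$gen$trainable),
      disc = lapply(models$discs, function(d) adam_new(d$P, d$trainable))
    )
  }
  res <- train_step_impl(models$gen, models$discs, models$opts, batch, tcfg)
  c(list(models = models), res)
}

validation_mse <- function(gen, val_std, chunk = 64L) {
  n <- nrow(val_std$Y)
  total <- 0
  i <- 1L
  while (i <= n) {
    j <- min(i + chunk - 1L, n)
    out <- generator_forward(gen, val_std$Y[i:j, , drop = FALSE], training = FALSE)
    total <- total + sum((out$ypre - val_std$X[i:j, , drop = FALSE])^2)
    i <- j + 1L
  }
  total / length(val_std$Y)
}

#' Train the dual-branch adversarial denoiser
#'
#' @param train,val `pair_set`s of contaminated training and validation
#'   pairs (built by [build_splits()] or [pair_set()]); each pair is
#'   standardized by the standard deviation of its mixture before entering
#'   the network.
#' @param gen_cfg a [generator_config()].
#' @param disc_cfg a [discriminator_config()]; the three discriminators
#'   share the architecture but are initialized and trained independently.
#' @param tcfg a [train_config()].
#' @param val_metric_fn optional override of the per-epoch validation
#'   metric: `function(gen, val_std, epoch) -> numeric` (lower is better).
#'   The default computes the MSE of the fused output on the validation
#'   set. Mainly a hook for testing the early-stopping schedule.
#' @param verbose print per-epoch progress.
#' @return An `eeggan_fit`: list with the trained `generator` (weights of
#'   the best-validation epoch), `discriminators`, `log` (per-epoch tibble),
#'   `best_epoch`, `best_val_mse`, `epochs_run` and the three configs.
#' @export
fit_denoiser <- function(train, val, gen_cfg = generator_config(),
                         disc_cfg = discriminator_config(),
                         tcfg = train_config(),
                         val_metric_fn = NULL, verbose = FALSE) {
  if (n_pairs(train) == 0 || n_pairs(val) == 0) {
    abort("empty train or validation set.", class = "eeggan_config_error")
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(tcfg$seed)
  # derive distinct init seeds from the run seed (kept below 2^31)
  gen_cfg$seed <- (tcfg$seed * 7L + 1L) %% 2147483647L
  gen <- new_generator(gen_cfg)
  discs <- lapply(1:3, function(k) {
    dcfg <- disc_cfg
    dcfg$seed <- (tcfg$seed * 11L + k) %% 2147483647L
    new_discriminator(dcfg)
  })
  opts <- list(gen = adam_new(gen$P, gen$trainable),
               disc = lapply(discs, function(d) adam_new(d$P, d$trainable)))

  tr <- standardize_pairs(train)
  vl <- standardize_pairs(val)
  n <- nrow(tr$Y)
  bs <- min(tcfg$batch_size, n)

  log_rows <- list()
  best_val <- Inf
  best_epoch <- 0L
  best_state <- NULL
  worsen <- 0L
  prev_val <- Inf
  epoch <- 0L

  while (epoch < tcfg$max_epochs) {
    epoch <- epoch + 1L
    ord <- sample.int(n)
    starts <- seq.int(1L, n, by = bs)
    ep_loss <- 0; ep_ld <- c(0, 0, 0); nb <- 0L
    for (s0 in starts) {
      sel <- ord[s0:min(s0 + bs - 1L, n)]
      batch <- list(Y = tr$Y[sel, , drop = FALSE], X = tr$X[sel, , drop = FALSE],
                    NL = tr$NL[sel, , drop = FALSE])
      for (k_in in seq_len(tcfg$inner_K)) {
        res <- train_step_impl(gen, discs, opts, batch, tcfg)
      }
      ep_loss <- ep_loss + res$ltotal
      ep_ld <- ep_ld + res$ld
      nb <- nb + 1L
    }
    val_mse <- if (is.null(val_metric_fn)) validation_mse(gen, vl)
               else val_metric_fn(gen, vl, epoch)
    log_rows[[epoch]] <- tibble(
      epoch = epoch, ltotal = ep_loss / nb,
      ld1 = ep_ld[1] / nb, ld2 = ep_ld[2] / nb, ld3 = ep_ld[3] / nb,
      val_mse = val_mse
    )
    if (verbose) {
      message(sprintf("epoch %3d  ltotal=%.5f  val_mse=%.5f", epoch,
                      ep_loss / nb, val_mse))
    }
    if (val_mse < best_val) {
      best_val <- val_mse
      best_epoch <- epoch
      best_state <- model_state(gen)
    }
    worsen <- if (val_mse > prev_val) worsen + 1L else 0L
    prev_val <- val_mse
    if (worsen > tcfg$early_stop_C) break
  }
  if (!is.null(best_state)) model_restore(gen, best_state)

  structure(list(generator = gen, discriminators = discs,
                 log = dplyr::bind_rows(log_rows),
                 best_epoch = best_epoch, best_val_mse = best_val,
                 epochs_run = epoch,
                 gen_cfg = gen_cfg, disc_cfg = disc_cfg, train_cfg = tcfg),
            class = "eeggan_fit")
}

#' @export
print.eeggan_fit <- function(x, ...) {
  cat(sprintf("<eeggan_fit> %d epochs (best %d, val MSE %.5f), %s generator params\n",
              x$epochs_run, x$best_epoch, x$best_val_mse,
              format(model_n_params(x$generator), big.mark = ",")))
  invisible(x)
}

#' @export
tidy.eeggan_fit <- function(x, ...) x$log

#' @export
glance.eeggan_fit <- function(x, ...) {
  tibble(epochs_run = x$epochs_run, best_epoch = x$best_epoch,
         best_val_mse = x$best_val_mse,
         n_params_gen = model_n_params(x$generator),
         n_params_disc = model_n_params(x$discriminators[[1]]))
}

#' @export
autoplot.eeggan_fit <- function(object, ...) {
  d <- tidyr::pivot_longer(object$log, -"epoch",
                           names_to = "series", values_to = "value")
  ggplot2::ggplot(d, ggplot2::aes(.data$epoch, .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~series, scales = "free_y") +
    ggplot2::labs(x = "epoch", y = NULL, title = "Training losses")
}

#' Denoise a store of contaminated segments
#'
#' Each segment is standardized by its own standard deviation, passed
#' through the generator (the fused output is the denoised estimate) and
#' rescaled back.
#'
#' @param object an `eeggan_fit` or `eeggan_generator`.
#' @param store a [segment_store] (or a plain batch x samples matrix) of
#'   contaminated segments.
#' @param chunk forward-pass batch size.
#' @return A [segment_store] labelled `"DENOISED"` (or a matrix when a
#'   matrix was supplied).
#' @export
denoise <- function(object, store, chunk = 64L) {
  gen <- if (inherits(object, "eeggan_fit")) object$generator else object
  stopifnot(inherits(gen, "eeggan_generator"))
  as_matrix_in <- is.matrix(store)
  Y <- if (as_matrix_in) store else store$data
  scales <- apply(Y, 1, sd)
  if (any(scales <= 0)) abort("zero-variance segment.", class = "eeggan_degenerate_input")
  out <- matrix(0, nrow(Y), ncol(Y))
  i <- 1L
  while (i <= nrow(Y)) {
    j <- min(i + chunk - 1L, nrow(Y))
    res <- generator_forward(gen, Y[i:j, , drop = FALSE] / scales[i:j],
                             training = FALSE)
    out[i:j, ] <- res$ypre * scales[i:j]
    i <- j + 1L
  }
  if (as_matrix_in) return(out)
  segment_store(out, store$fs, "DENOISED", meta = store$meta)
}

#' Evaluate a denoiser on contaminated pairs
#'
#' Runs the denoiser on every mixture, scores all six metrics per pair, and
#' aggregates per SNR level plus a grand mean.
#'
#' @param pairs a `pair_set` of test pairs.
#' @param object an `eeggan_fit` / `eeggan_generator` (ignored when
#'   `denoiser` is given).
#' @param denoiser optional function `(batch x samples matrix) -> matrix`
#'   replacing the model, e.g. `identity` for the no-op baseline.
#' @param mi_bins histogram bins for the mutual-information estimator.
#' @return List of class `eeggan_eval` with `records` (per-pair tibble,
#'   columns `snr_db`, `artifact_type`, `rrmse_t`, `rrmse_f`, `cc`, `cc_p`,
#'   `eta`, `ssim`, `mi`) and `report` (a `metric_report`).
#' @export
evaluate_pairs <- function(pairs, object = NULL, denoiser = NULL, mi_bins = 8) {
  stopifnot(inherits(pairs, "pair_set"))
  FY <- if (!is.null(denoiser)) denoiser(pairs$Y) else denoise(object, pairs$Y)
  records <- purrr::map_dfr(seq_len(nrow(FY)), function(i) {
    segment_metrics(FY[i, ], pairs$Y[i, ], pairs$X[i, ], fs = pairs$fs,
                    snr_db = pairs$snr_db[i], artifact_type = pairs$artifact_type,
                    mi_bins = mi_bins)
  })
  structure(list(records = records, report = aggregate_metrics(records)),
            class = "eeggan_eval")
}

#' @export
print.eeggan_eval <- function(x, ...) {
  cat("<eeggan_eval>\n")
  print(x$report)
  invisible(x)
}

#' Save / load a trained model checkpoint
#'
#' The checkpoint stores every parameter (including BN running statistics),
#' the three configurations and the training log, and is self-describing:
#' loading rebuilds the generator from its stored configuration and
#' restores the weights, so evaluation after a round trip is bit-identical.
#'
#' @param fit an `eeggan_fit`.
#' @param path file path (.rds).
#' @export
save_checkpoint <- function(fit, path) {
  stopifnot(inherits(fit, "eeggan_fit"))
  saveRDS(list(gen_state = model_state(fit$generator),
               disc_states = lapply(fit$discriminators, model_state),
               gen_cfg = fit$gen_cfg, disc_cfg = fit$disc_cfg,
               train_cfg = fit$train_cfg, log = fit$log,
               best_epoch = fit$best_epoch, best_val_mse = fit$best_val_mse,
               epochs_run = fit$epochs_run),
          path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  gen <- new_generator(ck$gen_cfg)
  model_restore(gen, ck$gen_state)
  discs <- lapply(seq_along(ck$disc_states), function(k) {
    dcfg <- ck$disc_cfg
    d <- new_discriminator(dcfg)
    model_restore(d, ck$disc_states[[k]])
    d
  })
  structure(list(generator = gen, discriminators = discs, log = ck$log,
                 best_epoch = ck$best_epoch, best_val_mse = ck$best_val_mse,
                 epochs_run = ck$epochs_run, gen_cfg = ck$gen_cfg,
                 disc_cfg = ck$disc_cfg, train_cfg = ck$train_cfg),
            class = "eeggan_fit")
}

#' Write per-pair metric records to CSV
#'
#' @param records tibble of per-pair metric rows (see [evaluate_pairs()]).
#' @param path output file.
#' @export
write_metrics_csv <- function(records, path) {
  cols <- c("snr_db", "artifact_type", "rrmse_t", "rrmse_f", "cc", "cc_p",
            "eta", "ssim", "mi")
  write.csv(records[, cols], path, row.names = FALSE)
  invisible(path)
}
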