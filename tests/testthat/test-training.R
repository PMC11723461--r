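make_models <- function(seed = 1) {
  list(gen = new_generator(tiny_gen_cfg(seed = seed)),
       discs = lapply(1:3, function(k) new_discriminator(tiny_disc_cfg(seed = seed + k))))
}

small_batch <- function(n = 8, seed = 5) {
  ps <- make_pairs(n, snr_db = 0, seed = seed, fs = 128, duration_s = 2)
  std <- eeggan:::standardize_pairs(ps)
  list(Y = std$Y, X = std$X, NL = std$NL)
}

small_tcfg <- function(...) {
  train_config(batch_size = 8, max_epochs = 3, lr_gen = 1e-3, lr_disc = 1e-3,
               seed = 1, ...)
}

test_that("a zero learning rate leaves every weight bitwise unchanged", {
  m <- make_models()
  before_g <- eeggan:::model_state(m$gen)
  before_d <- eeggan:::model_state(m$discs[[1]])
  batch <- small_batch()
  tcfg <- train_config(batch_size = 8, lr_gen = 0, lr_disc = 0, seed = 1)
  invisible(train_step(m, batch, tcfg))
  after_g <- eeggan:::model_state(m$gen)
  # trainable weights identical (BN running stats do update in training mode)
  tr <- m$gen$trainable
  expect_identical(before_g[tr], after_g[tr])
  expect_identical(before_d[m$discs[[1]]$trainable],
                   eeggan:::model_state(m$discs[[1]])[m$discs[[1]]$trainable])
})

test_that("repeated steps on one batch drive the generator loss down", {
  m <- make_models(seed = 3)
  batch <- small_batch(seed = 7)
  tcfg <- small_tcfg()
  m1 <- train_step(m, batch, tcfg)
  l_first <- m1$ltotal
  for (i in 1:5) m1 <- train_step(m1$models, batch, tcfg)
  expect_lt(m1$ltotal, l_first)
  expect_equal(nrow(m1$report), 3)
  expect_equal(m1$report$total,
               m1$report$mse + 0.01 * m1$report$feat + 0.01 * m1$report$adv,
               tolerance = 1e-10)
})

test_that("training runs are bitwise reproducible under a fixed seed", {
  ps <- make_pairs(16, snr_db = c(-7, 0), seed = 11, fs = 128)
  vl <- make_pairs(4, snr_db = 0, seed = 12, fs = 128)
  gcfg <- generator_config(input_len = 256, pre_dim = 4, encoder_dims = c(4, 8, 8, 8, 8),
                           gate_hidden = 16)
  dcfg <- tiny_disc_cfg()
  tcfg <- train_config(batch_size = 8, max_epochs = 2, lr_gen = 1e-3,
                       lr_disc = 1e-3, seed = 4)
  f1 <- fit_denoiser(ps, vl, gcfg, dcfg, tcfg)
  f2 <- fit_denoiser(ps, vl, gcfg, dcfg, tcfg)
  expect_identical(f1$log, f2$log)
  expect_identical(eeggan:::model_state(f1$generator),
                   eeggan:::model_state(f2$generator))
})

test_that("early stopping halts after C consecutive worsenings and keeps the best epoch", {
  ps <- make_pairs(8, snr_db = 0, seed = 21, fs = 128)
  vl <- make_pairs(2, snr_db = 0, seed = 22, fs = 128)
  schedule <- c(1.0, 1.1, 1.2, 1.3, 1.4)
  snaps <- list()
  hook <- function(gen, val, epoch) {
    snaps[[epoch]] <<- eeggan:::model_state(gen)
    schedule[epoch]
  }
  fit <- fit_denoiser(ps, vl, tiny_gen_cfg(), tiny_disc_cfg(),
                      train_config(batch_size = 8, max_epochs = 10,
                                   early_stop_C = 1, seed = 2),
                      val_metric_fn = hook)
  expect_equal(fit$epochs_run, 3) # worsened at epochs 2 and 3 -> stop
  expect_equal(fit$best_epoch, 1)
  expect_equal(fit$best_val_mse, 1.0)
  expect_identical(eeggan:::model_state(fit$generator), snaps[[1]])
  expect_equal(nrow(fit$log), 3) # one log row per epoch run
})

test_that("a recovering validation curve resets the worsening counter", {
  ps <- make_pairs(8, snr_db = 0, seed = 23, fs = 128)
  vl <- make_pairs(2, snr_db = 0, seed = 24, fs = 128)
  schedule <- c(1.0, 1.1, 0.9, 1.0, 1.1, 1.2)
  fit <- fit_denoiser(ps, vl, tiny_gen_cfg(), tiny_disc_cfg(),
                      train_config(batch_size = 8, max_epochs = 6,
                                   early_stop_C = 1, seed = 2),
                      val_metric_fn = function(gen, val, epoch) schedule[epoch])
  # the worsening at epoch 2 is forgiven by the recovery at epoch 3; the
  # rises at epochs 4 and 5 then exceed the patience of 1
  expect_equal(fit$epochs_run, 5)
  expect_equal(fit$best_epoch, 3)
})

test_that("checkpoint round trip reproduces validation MSE bitwise", {
  ps <- make_pairs(8, snr_db = 0, seed = 31, fs = 128)
  vl <- make_pairs(3, snr_db = 0, seed = 32, fs = 128)
  fit <- fit_denoiser(ps, vl, tiny_gen_cfg(), tiny_disc_cfg(),
                      train_config(batch_size = 8, max_epochs = 2, seed = 3))
  vstd <- eeggan:::standardize_pairs(vl)
  v0 <- eeggan:::validation_mse(fit$generator, vstd)
  p <- tempfile(fileext = ".rds")
  save_checkpoint(fit, p)
  back <- load_checkpoint(p)
  expect_identical(eeggan:::validation_mse(back$generator, vstd), v0)
  expect_identical(back$log, fit$log)
  unlink(p)
})

test_that("denoising inverts its own standardization and preserves shapes", {
  gen <- new_generator(tiny_gen_cfg())
  ps <- make_pairs(5, snr_db = 0, seed = 41, fs = 128)
  store <- segment_store(ps$Y, fs = 128, label = "MIXED")
  den <- denoise(gen, store)
  expect_s3_class(den, "segment_store")
  expect_equal(dim(den$data), dim(store$data))
  expect_equal(den$label, "DENOISED")
  # manual pipeline oracle: standardize -> forward -> rescale
  i <- 2
  sc <- sd(ps$Y[i, ])
  manual <- generator_forward(gen, matrix(ps$Y[i, ] / sc, 1))$ypre * sc
  expect_equal(den$data[i, ], as.vector(manual), tolerance = 1e-10)
})

test_that("evaluation aggregates per level and supports plug-in denoisers", {
  ps <- make_pairs(20, snr_db = rep(-7:2, 2), seed = 51, fs = 128)
  ev <- evaluate_pairs(ps, denoiser = identity)
  expect_equal(nrow(ev$report), 11)
  expect_equal(sort(stats::na.omit(ev$report$snr_db)), -7:2)
  # oracle denoiser returning the clean signal
  oracle <- evaluate_pairs(ps, denoiser = function(Y) ps$X)
  ov <- oracle$report[is.na(oracle$report$snr_db), ]
  expect_equal(ov$rrmse_t, 0)
  expect_equal(ov$cc, 1)
  expect_equal(ov$eta, 100)
  expect_gt(ov$ssim, 1 - 1e-6)
})

test_that("tidiers and accessors summarize a fit", {
  ps <- make_pairs(8, snr_db = 0, seed = 61, fs = 128)
  vl <- make_pairs(2, snr_db = 0, seed = 62, fs = 128)
  fit <- fit_denoiser(ps, vl, tiny_gen_cfg(), tiny_disc_cfg(),
                      train_config(batch_size = 8, max_epochs = 2, seed = 5))
  td <- tidy(fit)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), fit$epochs_run)
  gl <- glance(fit)
  expect_equal(nrow(gl), 1)
  expect_gt(gl$n_params_gen, 0)
})
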