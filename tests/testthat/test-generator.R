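# one small generator shared across blocks (weights fixed by seed)
gen <- new_generator(tiny_gen_cfg())
Xb <- {
  set.seed(100)
  matrix(rnorm(3 * 256), 3)
}

test_that("generator outputs share the input shape and satisfy the fusion identity", {
  out <- generator_forward(gen, Xb)
  for (nm in c("y1", "y2", "mask1", "mask2", "ypre")) {
    expect_equal(dim(out[[nm]]), c(3L, 256L))
  }
  expect_lt(max(abs(out$ypre - fuse(Xb, out$y1, out$y2, out$mask1, out$mask2))), 1e-6)
  expect_true(all(abs(out$mask1) < 1) && all(abs(out$mask2) < 1))
  expect_true(all(is.finite(out$ypre)))
})

test_that("fusion matches an elementwise scalar-loop oracle and its identities", {
  set.seed(8)
  xr <- matrix(rnorm(2 * 16), 2)
  y1 <- matrix(rnorm(2 * 16), 2); y2 <- matrix(rnorm(2 * 16), 2)
  m1 <- matrix(tanh(rnorm(2 * 16)), 2); m2 <- matrix(tanh(rnorm(2 * 16)), 2)
  got <- fuse(xr, y1, y2, m1, m2)
  want <- xr * 0
  for (i in 1:2) for (j in 1:16) {
    want[i, j] <- m1[i, j] * y1[i, j] + m2[i, j] * (xr[i, j] - y2[i, j])
  }
  expect_lt(max(abs(got - want)), 1e-6)
  ones <- matrix(1, 2, 16); zeros <- matrix(0, 2, 16)
  expect_equal(fuse(xr, y1, y2, ones, zeros), y1)
  expect_equal(fuse(xr, y1, zeros, zeros, ones), xr)
  expect_error(fuse(xr, y1[, 1:8], y2, m1, m2), class = "eeggan_invalid_input")
})

test_that("forward passes are deterministic and input-dependent", {
  o1 <- generator_forward(gen, Xb)
  o2 <- generator_forward(gen, Xb)
  expect_identical(o1$ypre, o2$ypre) # eval-mode bitwise determinism
  o3 <- generator_forward(gen, 2 * Xb)
  expect_gt(abs(sum(o3$y1^2) - sum(o1$y1^2)), 1e-8) # no constant map
  expect_false(identical(o1$mask1, o3$mask1)) # gates depend on the input
  z <- generator_forward(gen, matrix(0, 2, 256))
  expect_true(all(is.finite(z$ypre)))
})

test_that("same seed rebuilds identical weights; seeds change weights, not counts", {
  g2 <- new_generator(tiny_gen_cfg())
  expect_identical(eeggan:::model_state(gen), eeggan:::model_state(g2))
  g3 <- new_generator(tiny_gen_cfg(seed = 8))
  expect_equal(eeggan:::model_n_params(gen), eeggan:::model_n_params(g3))
  expect_false(identical(gen$P[["b1.pre1.W"]], g3$P[["b1.pre1.W"]]))
})

test_that("preprocessing yields the documented 32-channel half-length feature map", {
  full <- new_generator(generator_config(seed = 2))
  x <- matrix(rnorm(4 * 1024), 4)
  h <- eeggan:::seq_fwd(full$branches$b1$pre, full$P, eeggan:::as_feature_map(x))
  expect_equal(dim(h$out), c(32L, 512L, 4L))
})

test_that("attention matches a double-precision reference, local and global", {
  set.seed(12)
  d <- c(8, 64, 2)
  Q <- array(rnorm(prod(d)), d); K <- array(rnorm(prod(d)), d); V <- array(rnorm(prod(d)), d)
  for (parts in c(1L, 8L)) {
    got <- eeggan:::attn_fwd_cpp(Q, K, V, 4L, parts)$O
    want <- ref_attention(Q, K, V, 4, parts)
    expect_lt(max(abs(got - want)), 1e-4) # single-precision kernel
  }
  # partitions = 1 collapses local attention onto global attention
  expect_identical(eeggan:::attn_fwd_cpp(Q, K, V, 4L, 1L)$O,
                   eeggan:::attn_fwd_cpp(Q, K, V, 4L, 1L)$O)
})

test_that("attention blocks reduce to the identity under zeroed projections", {
  reg <- eeggan:::new_registry()
  set.seed(3)
  lsa <- eeggan:::nn_mha(reg, "t.lsa", 8, 2, partitions = 4)
  ffl <- eeggan:::nn_ff(reg, "t.ff", 8)
  reg$P[[lsa$Wo]][] <- 0
  reg$P[[lsa$bo]][] <- 0
  reg$P[[ffl$W2]][] <- 0
  reg$P[[ffl$b2]][] <- 0
  x <- array(rnorm(8 * 32 * 2), c(8, 32, 2))
  a <- eeggan:::layer_fwd(lsa, reg$P, x)
  expect_equal(a$out, x) # residual path carries the input through
  b <- eeggan:::layer_fwd(ffl, reg$P, a$out)
  expect_equal(b$out, x)
})

test_that("token counts indivisible by the partition count are rejected", {
  expect_error(generator_config(input_len = 320), class = "eeggan_config_error")
  reg <- eeggan:::new_registry()
  ly <- eeggan:::nn_mha(reg, "t", 4, 2, partitions = 8)
  x <- array(rnorm(4 * 30 * 1), c(4, 30, 1))
  expect_error(eeggan:::layer_fwd(ly, reg$P, x), class = "eeggan_config_error")
})

test_that("generator gradients agree with finite differences", {
  g <- new_generator(tiny_gen_cfg(seed = 21))
  set.seed(22)
  X <- matrix(rnorm(2 * 256), 2)
  tgt <- matrix(rnorm(2 * 256), 2)
  loss_fn <- function() {
    o <- generator_forward(g, X, training = TRUE)
    mean((o$y1 - tgt)^2) + mean((o$y2 + tgt)^2) + mean((o$ypre - 2 * tgt)^2)
  }
  o <- generator_forward(g, X, training = TRUE)
  G <- new.env(parent = emptyenv())
  eeggan:::generator_backward(g, o$cache,
                              2 * (o$y1 - tgt) / length(tgt),
                              2 * (o$y2 + tgt) / length(tgt),
                              2 * (o$ypre - 2 * tgt) / length(tgt), G)
  check <- c("b1.cnn3.c1.W", "b1.lg2.lsa.Wq", "b1.lg4.gsa.Wo", "b2.lg1.ff1.W1",
             "b1.decfc.W", "g1.fc1.W", "b2.fuse.W", "b1.cnn1.bn1.gamma")
  # eps must stay small: the softmax nonlinearity makes the curvature error
  # of coarser central differences visible well before float noise matters
  eps <- 1e-4
  for (nm in check) {
    th <- g$P[[nm]]
    for (i in sample(length(th), 2)) {
      v0 <- th[i]
      g$P[[nm]][i] <- v0 + eps; lp <- loss_fn()
      g$P[[nm]][i] <- v0 - eps; lm <- loss_fn()
      g$P[[nm]][i] <- v0
      fd <- (lp - lm) / (2 * eps)
      an <- G[[nm]][i]
      if (abs(fd) + abs(an) > 5e-3) {
        expect_lt(abs(fd - an) / (abs(fd) + abs(an)), 2e-2)
      } else {
        expect_lt(abs(fd - an), 1e-3)
      }
    }
  }
})

test_that("ablation switches change the fusion rule as documented", {
  co <- new_generator(generator_config(input_len = 256, pre_dim = 4,
                                       encoder_dims = c(4, 8, 8, 8, 8),
                                       gate_hidden = 16, seed = 7,
                                       branch_mode = "clean_only"))
  oc <- generator_forward(co, Xb)
  expect_identical(oc$ypre, oc$y1)
  no <- new_generator(generator_config(input_len = 256, pre_dim = 4,
                                       encoder_dims = c(4, 8, 8, 8, 8),
                                       gate_hidden = 16, seed = 7,
                                       branch_mode = "noise_only"))
  on <- generator_forward(no, Xb)
  expect_identical(on$ypre, Xb - on$y2)
  nt <- new_generator(generator_config(input_len = 256, pre_dim = 4,
                                       encoder_dims = c(4, 8, 8, 8, 8),
                                       gate_hidden = 16, seed = 7,
                                       transformer = "none"))
  ot <- generator_forward(nt, Xb)
  expect_equal(dim(ot$ypre), c(3L, 256L))
})
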