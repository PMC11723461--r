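test_that("rms matches closed forms and a loop-based oracle", {
  expect_equal(rms(rep(2.5, 10)), 2.5)
  expect_equal(rms(rep(-3, 7)), 3)
  expect_equal(rms(c(3, 4)), sqrt(12.5))
  set.seed(42)
  g <- rnorm(1024)
  ss <- 0
  for (v in g) ss <- ss + v * v # brute-force sum of squares
  expect_lt(abs(rms(g) - sqrt(ss / 1024)) / sqrt(ss / 1024), 1e-12)
  expect_error(rms(numeric(0)), class = "eeggan_invalid_input")
  expect_error(rms(c(1, NA)), class = "eeggan_invalid_input")
})

test_that("rms is absolutely homogeneous", {
  set.seed(7)
  g <- rnorm(256)
  for (a in c(-3.2, -1, 0.5, 2, 10)) {
    expect_equal(rms(a * g), abs(a) * rms(g), tolerance = 1e-12)
  }
})

test_that("periodogram concentrates a sinusoid and zeroes a zero segment", {
  fs <- 512
  t <- (0:1023) / fs
  p <- periodogram_psd(sin(2 * pi * 10 * t), fs)
  expect_equal(p$freq[which.max(p$psd)], 10)
  expect_equal(nrow(p), 513)
  expect_equal(p$freq[2] - p$freq[1], fs / 1024)
  expect_true(all(periodogram_psd(rep(0, 1024), fs)$psd == 0))
})

test_that("periodogram satisfies Parseval on random segments", {
  set.seed(11)
  for (i in 1:100) {
    g <- rnorm(1024)
    p <- periodogram_psd(g, 512)
    expect_lt(abs(sum(p$psd) * 512 / 1024 - mean(g^2)) / mean(g^2), 1e-6)
  }
})

test_that("periodogram agrees with spec.pgram up to its scaling convention", {
  set.seed(3)
  g <- rnorm(1024)
  fs <- 512
  mine <- periodogram_psd(g, fs)
  ref <- stats::spec.pgram(stats::ts(g, frequency = fs), taper = 0, detrend = FALSE,
                           demean = FALSE, fast = FALSE, plot = FALSE)
  # spec.pgram drops the DC bin and halves nothing; density scaling differs
  # by the one-sided doubling factor
  expect_rel_equal(mine$psd[2:512], 2 * ref$spec[1:511], 1e-10)
})

test_that("standardize is invertible and scale-consistent", {
  set.seed(5)
  y <- rnorm(512, sd = 2)
  r <- standardize(y)
  expect_equal(sd(r$samples), 1, tolerance = 1e-12)
  expect_equal(r$scale, sd(y))
  expect_lt(max(abs(r$samples * r$scale - y)), 1e-12)
  r2 <- standardize(y, reference_scale = 4)
  expect_equal(r2$samples, y / 4)
  # standardizing a pair by the mixture's sd preserves RMS ratios
  x <- rnorm(512)
  s <- sd(y)
  expect_equal(rms(x / s) / rms(y / s), rms(x) / rms(y), tolerance = 1e-12)
  expect_error(standardize(rep(1, 100)), class = "eeggan_degenerate_input")
})

test_that("store round trip is bit-exact and validates its sidecar", {
  s <- gen_eeg(10, seed = 3)
  path <- tempfile()
  write_store(s, path)
  s2 <- read_store(path)
  expect_identical(s$data, s2$data)
  expect_equal(s2$fs, 512)
  expect_equal(s2$label, "EEG")
  expect_equal(s2$meta$seed, 3)
  # corrupt the sidecar length claim
  sc <- jsonlite::read_json(paste0(path, ".json"))
  sc$n_samples <- 999
  jsonlite::write_json(sc, paste0(path, ".json"), auto_unbox = TRUE)
  expect_error(read_store(path), class = "eeggan_format_error")
  expect_error(read_store(tempfile()), class = "eeggan_format_error")
})

test_that("store round trip is lossless on many random stores", {
  set.seed(21)
  for (i in 1:100) {
    n <- sample(1:5, 1)
    len <- sample(c(64, 128), 1)
    st <- segment_store(matrix(rnorm(n * len), n), fs = 256, label = "EMG")
    p <- tempfile()
    write_store(st, p)
    back <- read_store(p)
    expect_identical(back$data, st$data)
    unlink(c(p, paste0(p, ".json")))
  }
})

test_that("a 3400-segment store reads back with the full count", {
  big <- segment_store(matrix(rnorm(3400 * 64), 3400), fs = 512, label = "EOG")
  p <- tempfile()
  write_store(big, p)
  expect_equal(n_segments(read_store(p)), 3400)
  unlink(c(p, paste0(p, ".json")))
})

test_that("segment stores validate their inputs", {
  expect_error(segment_store(matrix(c(1, Inf), 1), fs = 512), class = "eeggan_invalid_input")
  expect_error(segment_store(matrix(1, 1), fs = -1), class = "eeggan_invalid_input")
  s <- segment_store(matrix(rnorm(2 * 8), 2), fs = 4)
  tb <- tibble::as_tibble(s)
  expect_equal(nrow(tb), 16)
  expect_equal(max(tb$time_s), 7 / 4)
})
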