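test_that("all six metrics match independent brute-force oracles", {
  set.seed(10)
  for (i in 1:100) {
    x <- rnorm(256)
    fy <- 0.7 * x + 0.5 * rnorm(256)
    y <- x + rnorm(256)
    expect_lt(abs(rrmse_t(fy, x) - oracle_rrmse_t(fy, x)), 1e-8)
    expect_lt(abs(rrmse_f(fy, x, 512) - oracle_rrmse_f(fy, x, 512)), 1e-8)
    expect_lt(abs(cc(fy, x)$estimate - sum(scale(fy) * scale(x)) / 255), 1e-8)
    ccb <- cor(y, x)
    expect_lt(abs(eta(fy, y, x) -
                    (1 - (1 - cor(fy, x)) / (1 - ccb)) * 100), 1e-8)
    expect_lt(abs(ssim(fy, x) - oracle_ssim(fy, x)), 1e-8)
    expect_identical(mi(fy, x), oracle_mi(fy, x)) # same binning, bit-identical
  }
})

test_that("correlation handles exact, inverted and affine-shifted inputs", {
  set.seed(1)
  x <- rnorm(1024)
  expect_equal(cc(x, x)$estimate, 1)
  expect_equal(cc(-x, x)$estimate, -1)
  expect_equal(cc(x, x)$p.value, 0)
  fy <- 0.8 * x + rnorm(1024)
  r0 <- cc(fy, x)
  r1 <- cc(3.2 * fy + 5, x)
  expect_equal(r0$estimate, r1$estimate, tolerance = 1e-12)
  ref <- cor.test(fy, x)
  expect_equal(r0$estimate, unname(ref$estimate), tolerance = 1e-12)
  expect_equal(r0$p.value, ref$p.value, tolerance = 1e-10)
})

test_that("artifact-reduction percentage hits its anchors and closed form", {
  set.seed(2)
  x <- rnorm(1024)
  n <- rnorm(1024)
  y <- x + n
  expect_equal(eta(x, y, x), 100)
  expect_equal(eta(y, y, x), 0, tolerance = 1e-9)
  # reported EMG-removal benchmark scores are mutually consistent under this
  # reading: CC = 0.9201 with eta = 82.35% implies CCb = 0.5473, a plausible
  # contaminated-baseline correlation
  expect_equal((1 - (1 - 0.9201) / (1 - 0.5473)) * 100, 82.35, tolerance = 0.005)
  expect_error(eta(x, x, x), class = "eeggan_degenerate_input")
})

test_that("SSIM is symmetric, bounded by 1 at equality", {
  set.seed(3)
  x <- rnorm(512)
  fy <- x + 0.3 * rnorm(512)
  expect_equal(ssim(fy, x), ssim(x, fy), tolerance = 1e-12)
  expect_equal(ssim(x, x), 1, tolerance = 1e-6)
  expect_lt(ssim(fy, x), 1)
})

test_that("mutual information is symmetric, maximal at identity, near zero under independence", {
  set.seed(4)
  x <- rnorm(1024)
  fy <- 0.5 * x + rnorm(1024)
  expect_equal(mi(fy, x), mi(x, fy), tolerance = 1e-12)
  # identity: MI equals the binned marginal entropy
  bi <- table(eeggan:::bin_index(x, 8)) / 1024
  expect_equal(mi(x, x), -sum(bi * log(bi)), tolerance = 1e-12)
  nulls <- vapply(1:100, function(i) {
    set.seed(1000 + i)
    mi(rnorm(1024), rnorm(1024))
  }, 0)
  expect_lt(mean(nulls), 0.1)
})

test_that("spectral RRMSE ignores a common circular time shift of a sinusoid", {
  fs <- 512
  t <- (0:1023) / fs
  x <- sin(2 * pi * 12 * t)
  xs <- sin(2 * pi * 12 * t + 1.1) # phase-shifted copy
  fy <- x + 0.1 * sin(2 * pi * 40 * t)
  fys <- xs + 0.1 * sin(2 * pi * 40 * t + 0.7)
  expect_equal(rrmse_f(fy, x, fs), rrmse_f(fys, xs, fs), tolerance = 1e-6)
})

test_that("fidelity is monotone along the clean-contaminated interpolation", {
  set.seed(5)
  for (rep in 1:10) {
    x <- rnorm(512)
    y <- x + 1.5 * rnorm(512)
    alphas <- seq(0, 1, 0.1)
    ccs <- vapply(alphas, function(a) cor(a * x + (1 - a) * y, x), 0)
    rr <- vapply(alphas, function(a) rrmse_t(a * x + (1 - a) * y, x), 0)
    expect_true(all(diff(ccs) >= -1e-12))
    expect_true(all(diff(rr) <= 1e-12))
  }
})

test_that("aggregation averages per SNR level plus a grand mean", {
  set.seed(6)
  recs <- purrr::map_dfr(rep(-7:2, each = 3), function(s) {
    x <- rnorm(128); fy <- x + 0.1 * rnorm(128); y <- x + rnorm(128)
    segment_metrics(fy, y, x, fs = 512, snr_db = s, artifact_type = "EOG")
  })
  rep1 <- aggregate_metrics(recs)
  expect_equal(nrow(rep1), 11) # 10 levels + grand mean
  expect_equal(sum(is.na(rep1$snr_db)), 1)
  expect_equal(rep1$rrmse_t[is.na(rep1$snr_db)], mean(recs$rrmse_t))
  # permutation invariance
  rep2 <- aggregate_metrics(recs[sample(nrow(recs)), ])
  expect_equal(rep1, rep2, ignore_attr = TRUE)
  single <- aggregate_metrics(recs[1, ])
  expect_equal(single$cc[1], recs$cc[1])
})

test_that("metric CSV export uses the documented column set", {
  set.seed(7)
  x <- rnorm(128); fy <- x + 0.1 * rnorm(128); y <- x + rnorm(128)
  rec <- segment_metrics(fy, y, x, 512, snr_db = 0, artifact_type = "EOG")
  p <- tempfile(fileext = ".csv")
  write_metrics_csv(rec, p)
  back <- utils::read.csv(p)
  expect_equal(names(back), c("snr_db", "artifact_type", "rrmse_t", "rrmse_f",
                              "cc", "cc_p", "eta", "ssim", "mi"))
  unlink(p)
})
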