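#' Denoising quality metrics
#'
#' Six per-segment scores comparing a denoised segment `fy` against the clean
#' ground truth `x` (and, for the artifact-reduction percentage, the
#' contaminated input `y`):
#'
#' * `rrmse_t`: time-domain relative RMSE, `rms(fy - x) / rms(x)`; lower is
#'   better, 0 at perfect recovery.
#' * `rrmse_f`: the same ratio computed on full-segment periodogram PSDs.
#' * `cc`: Pearson correlation between `fy` and `x`, with a p-value from the
#'   t distribution on N - 2 degrees of freedom.
#' * `eta`: percentage artifact reduction,
#'   `(1 - (1 - CC) / (1 - CCb)) * 100`, where `CCb` is the correlation of
#'   the *contaminated* segment with the clean one; 100 at perfect recovery,
#'   0 when the output is no better than the input.
#' * `ssim`: 1-D structural similarity computed globally over the segment
#'   (whole-signal means, variances and covariance; stabilizing constants
#'   `C1 = C2 = 1e-4`).
#' * `mi`: mutual information in nats, estimated by an equal-width 2-D
#'   histogram plug-in estimator over each signal's observed range.
#'
#' Metrics are computed in double precision.
#'
#' @name metrics
NULL

#' @rdname metrics
#' @param fy denoised segment (numeric vector).
#' @param x clean ground-truth segment.
#' @export
rrmse_t <- function(fy, x) rms(fy - x) / rms(x)

#' @rdname metrics
#' @param fs sampling rate in Hz.
#' @export
rrmse_f <- function(fy, x, fs) {
  p1 <- periodogram_psd(fy, fs)$psd
  p0 <- periodogram_psd(x, fs)$psd
  rms(p1 - p0) / rms(p0)
}

#' @rdname metrics
#' @return `cc()` returns a list with `estimate` and `p.value`.
#' @export
cc <- function(fy, x) {
  r <- cor(fy, x)
  n <- length(x)
  p <- if (abs(r) >= 1) 0 else {
    tstat <- r * sqrt((n - 2) / (1 - r^2))
    2 * pt(-abs(tstat), df = n - 2)
  }
  list(estimate = r, p.value = p)
}

#' @rdname metrics
#' @param y contaminated segment (input to the denoiser).
#' @export
eta <- function(fy, y, x) {
  ccb <- cor(y, x)
  if (ccb >= 1 - 1e-12) {
    abort("uncontaminated input: CCb == 1, artifact reduction undefined.",
          class = "eeggan_degenerate_input")
  }
  (1 - (1 - cor(fy, x)) / (1 - ccb)) * 100
}

#' @rdname metrics
#' @param C1,C2 stabilizing constants of the structural-similarity formula.
#' @export
ssim <- function(fy, x, C1 = 1e-4, C2 = 1e-4) {
  mx <- mean(x); mf <- mean(fy)
  vx <- var(x); vf <- var(fy); cv <- cov(fy, x)
  ((2 * mx * mf + C1) * (2 * cv + C2)) /
    ((mx^2 + mf^2 + C1) * (vx + vf + C2))
}

#' @rdname metrics
#' @param bins number of equal-width histogram bins per axis. The default (8)
#'   keeps the plug-in bias of the estimator, bounded by
#'   `(bins - 1)^2 / (2 * N)` nats, well below 0.1 for 1024-sample segments,
#'   so independent signals score near zero.
#' @export
mi <- function(fy, x, bins = 8) {
  n <- length(x)
  stopifnot(length(fy) == n, n > 1)
  bx <- bin_index(x, bins)
  bf <- bin_index(fy, bins)
  joint <- matrix(0, bins, bins)
  for (i in seq_len(n)) joint[bf[i], bx[i]] <- joint[bf[i], bx[i]] + 1
  joint <- joint / n
  pf <- rowSums(joint)
  px <- colSums(joint)
  s <- 0
  for (a in seq_len(bins)) {
    for (b in seq_len(bins)) {
      pj <- joint[a, b]
      if (pj > 0) s <- s + pj * log(pj / (pf[a] * px[b]))
    }
  }
  s
}

# equal-width bin assignment over the observed range; the max lands in the
# top bin
bin_index <- function(v, bins) {
  lo <- min(v); hi <- max(v)
  if (hi == lo) return(rep(1L, length(v)))
  idx <- floor((v - lo) / (hi - lo) * bins) + 1L
  pmin(idx, bins)
}

#' Compute all six metrics for one denoised segment
#'
#' @param fy denoised segment.
#' @param y contaminated segment.
#' @param x clean ground-truth segment.
#' @param fs sampling rate (Hz).
#' @param snr_db,artifact_type carried into the output row.
#' @param mi_bins histogram bins for the mutual-information estimator.
#' @return One-row tibble with columns `snr_db`, `artifact_type`, `rrmse_t`,
#'   `rrmse_f`, `cc`, `cc_p`, `eta`, `ssim`, `mi`.
#' @export
segment_metrics <- function(fy, y, x, fs, snr_db = NA_real_,
                            artifact_type = NA_character_, mi_bins = 8) {
  ccr <- cc(fy, x)
  tibble(
    snr_db = snr_db, artifact_type = artifact_type,
    rrmse_t = rrmse_t(fy, x),
    rrmse_f = rrmse_f(fy, x, fs),
    cc = ccr$estimate, cc_p = ccr$p.value,
    eta = eta(fy, y, x),
    ssim = ssim(fy, x),
    mi = mi(fy, x, bins = mi_bins)
  )
}

#' Aggregate per-segment metric records
#'
#' Arithmetic means per SNR level plus a grand-mean row (`snr_db = NA`).
#'
#' @param records tibble of per-segment rows as produced by
#'   [segment_metrics()].
#' @return A `metric_report` tibble: one row per SNR level and one overall
#'   row, columns `snr_db`, `n` and the mean of every metric.
#' @export
aggregate_metrics <- function(records) {
  metric_cols <- c("rrmse_t", "rrmse_f", "cc", "cc_p", "eta", "ssim", "mi")
  per_level <- records |>
    dplyr::group_by(.data$snr_db) |>
    dplyr::summarise(n = dplyr::n(),
                     dplyr::across(dplyr::all_of(metric_cols), mean),
                     .groups = "drop") |>
    dplyr::arrange(.data$snr_db)
  overall <- records |>
    dplyr::summarise(snr_db = NA_real_, n = dplyr::n(),
                     dplyr::across(dplyr::all_of(metric_cols), mean))
  out <- dplyr::bind_rows(per_level, overall)
  class(out) <- c("metric_report", class(out))
  out
}

#' @export
autoplot.metric_report <- function(object, ...) {
  d <- object |>
    dplyr::filter(!is.na(.data$snr_db)) |>
    tidyr::pivot_longer(dplyr::all_of(c("rrmse_t", "rrmse_f", "cc", "eta", "ssim", "mi")),
                        names_to = "metric", values_to = "value")
  ggplot2::ggplot(d, ggplot2::aes(.data$snr_db, .data$value)) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 1) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "SNR (dB)", y = NULL, title = "Denoising metrics by SNR level")
}
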