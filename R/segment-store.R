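#' Segment containers and signal primitives
#'
#' A *segment* is a single-channel real-valued series of fixed duration
#' (default 2 s at 512 Hz, i.e. 1024 samples); a [segment_store] is a batch of
#' segments sharing sampling rate and length, the unit all generators, mixers
#' and models operate on.
#'
#' @name segment-store
NULL

SEGMENT_LABELS <- c("EEG", "EMG", "EOG", "ECG", "MIXED", "DENOISED")

#' Create a store of equal-length single-channel segments
#'
#' @param data numeric matrix, one segment per row.
#' @param fs sampling rate in Hz (positive scalar).
#' @param label one of `"EEG"`, `"EMG"`, `"EOG"`, `"ECG"`, `"MIXED"`,
#'   `"DENOISED"`.
#' @param meta named list of free-form metadata (source tag, seed, ...).
#' @return An object of class `segment_store`: a list with elements `data`
#'   (segments x samples matrix), `fs`, `label`, `meta`.
#' @examples
#' s <- segment_store(matrix(rnorm(4 * 1024), 4), fs = 512, label = "EEG")
#' n_segments(s)
#' @export
segment_store <- function(data, fs, label = "EEG", meta = list()) {
  if (is.vector(data)) data <- matrix(data, nrow = 1)
  if (!is.matrix(data) || !is.numeric(data)) {
    abort("`data` must be a numeric matrix (segments x samples).", class = "eeggan_invalid_input")
  }
  if (!all(is.finite(data))) {
    abort("segment samples must all be finite.", class = "eeggan_invalid_input")
  }
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0) {
    abort("`fs` must be a positive finite scalar (Hz).", class = "eeggan_invalid_input")
  }
  label <- match.arg(label, SEGMENT_LABELS)
  structure(list(data = unname(data), fs = fs, label = label, meta = meta),
            class = "segment_store")
}

#' @rdname segment_store
#' @param x a `segment_store`.
#' @export
n_segments <- function(x) nrow(x$data)

#' @rdname segment_store
#' @export
n_samples <- function(x) ncol(x$data)

#' @export
print.segment_store <- function(x, ...) {
  cat(sprintf("<segment_store> %d x %d samples @ %g Hz, label=%s\n",
              n_segments(x), n_samples(x), x$fs, x$label))
  invisible(x)
}

#' @export
as_tibble.segment_store <- function(x, ...) {
  tibble(
    segment = rep(seq_len(n_segments(x)), each = n_samples(x)),
    time_s  = rep((seq_len(n_samples(x)) - 1) / x$fs, n_segments(x)),
    value   = as.vector(t(x$data)),
    label   = x$label
  )
}

#' Root-mean-square amplitude of a segment
#'
#' `rms(g) = sqrt(mean(g^2))`; the scale on which SNR and the time-domain
#' relative RMSE are defined.
#'
#' @param g numeric vector (one segment).
#' @return Non-negative scalar; zero iff all samples are zero.
#' @examples
#' rms(c(3, 4)) # sqrt(12.5)
#' @export
rms <- function(g) {
  if (length(g) == 0L) abort("empty segment.", class = "eeggan_invalid_input")
  if (!all(is.finite(g))) abort("non-finite samples.", class = "eeggan_invalid_input")
  sqrt(mean(g^2))
}

#' One-sided periodogram power spectral density
#'
#' Full-segment periodogram: rectangular window, no averaging or overlap,
#' density scaling (power per Hz), frequency resolution `fs / N`. One-sided:
#' all bins except DC (and Nyquist for even N) are doubled so that
#' `sum(psd) * fs / N == mean(g^2)` (Parseval).
#'
#' @param g numeric vector (one segment).
#' @param fs sampling rate in Hz.
#' @return Tibble with columns `freq` (Hz) and `psd` (power / Hz).
#' @examples
#' p <- periodogram_psd(sin(2 * pi * 10 * (0:1023) / 512), fs = 512)
#' p$freq[which.max(p$psd)] # 10
#' @export
periodogram_psd <- function(g, fs) {
  if (length(g) == 0L) abort("empty segment.", class = "eeggan_invalid_input")
  n <- length(g)
  xf <- fft(g)
  full <- (Mod(xf)^2) / (fs * n)
  n_keep <- floor(n / 2) + 1L
  psd <- full[seq_len(n_keep)]
  dbl <- rep(2, n_keep)
  dbl[1L] <- 1
  if (n %% 2L == 0L) dbl[n_keep] <- 1
  psd <- psd * dbl
  tibble(freq = (seq_len(n_keep) - 1) * fs / n, psd = psd)
}

#' Standardize a segment to unit scale, invertibly
#'
#' Divides samples by `reference_scale` if given, otherwise by the segment's
#' own standard deviation, and returns the scale so the transform can be
#' undone exactly. Used to bring contaminated segments to bounded amplitude
#' before they enter the network; the same factor is applied to the clean
#' target and the noise component of a pair so that SNR and RMS ratios are
#' unchanged.
#'
#' @param y numeric vector.
#' @param reference_scale optional positive scalar overriding the own-sd scale.
#' @return List with `samples` (scaled vector) and `scale`.
#' @export
standardize <- function(y, reference_scale = NULL) {
  if (!all(is.finite(y))) abort("non-finite samples.", class = "eeggan_invalid_input")
  if (is.null(reference_scale)) {
    s <- sd(y)
    if (!is.finite(s) || s <= 0) {
      abort("zero-variance segment cannot be standardized by its own sd.",
            class = "eeggan_degenerate_input")
    }
  } else {
    if (!is.numeric(reference_scale) || length(reference_scale) != 1L || reference_scale <= 0) {
      abort("`reference_scale` must be a positive scalar.", class = "eeggan_invalid_input")
    }
    s <- reference_scale
  }
  list(samples = y / s, scale = s)
}

#' Read and write segment stores
#'
#' A store is persisted as a flat little-endian float64 binary file of the
#' segments x samples matrix (row-major) plus a JSON sidecar `<path>.json`
#' holding `n_segments`, `n_samples`, `fs`, `label` and free metadata. The
#' round trip is bit-exact on samples.
#'
#' @param store a [segment_store].
#' @param path file path for the binary array (sidecar gets `.json` appended).
#' @return `write_store` returns `path` invisibly; `read_store` returns a
#'   [segment_store].
#' @export
write_store <- function(store, path) {
  stopifnot(inherits(store, "segment_store"))
  sidecar <- paste0(path, ".json")
  con <- file(path, "wb")
  on.exit(close(con))
  # row-major so one segment is contiguous on disk
  writeBin(as.vector(t(store$data)), con, size = 8, endian = "little")
  meta <- list(
    n_segments = n_segments(store), n_samples = n_samples(store),
    fs = store$fs, label = store$label, dtype = "float64", order = "row-major",
    meta = store$meta
  )
  jsonlite::write_json(meta, sidecar, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_store
#' @export
read_store <- function(path) {
  sidecar <- paste0(path, ".json")
  if (!file.exists(sidecar)) {
    abort(sprintf("missing sidecar metadata file '%s'.", sidecar),
          class = "eeggan_format_error")
  }
  if (!file.exists(path)) {
    abort(sprintf("missing array file '%s'.", path), class = "eeggan_format_error")
  }
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  for (f in c("n_segments", "n_samples", "fs", "label")) {
    if (is.null(meta[[f]])) {
      abort(sprintf("sidecar is missing required field '%s'.", f),
            class = "eeggan_format_error")
    }
  }
  n_expect <- meta$n_segments * meta$n_samples
  n_bytes <- file.info(path)$size
  if (n_bytes != 8 * n_expect) {
    abort(sprintf(
      "array file length (%d bytes) does not match sidecar n_segments x n_samples (%d x %d).",
      n_bytes, meta$n_segments, meta$n_samples), class = "eeggan_format_error")
  }
  con <- file(path, "rb")
  on.exit(close(con))
  v <- readBin(con, "double", n = n_expect, size = 8, endian = "little")
  data <- matrix(v, nrow = meta$n_segments, byrow = TRUE)
  extra <- meta$meta
  if (is.null(extra)) extra <- list()
  segment_store(data, fs = meta$fs, label = meta$label, meta = as.list(extra))
}

#' @export
autoplot.segment_store <- function(object, max_segments = 6, ...) {
  d <- as_tibble(object)
  keep <- unique(d$segment)[seq_len(min(max_segments, n_segments(object)))]
  d <- dplyr::filter(d, .data$segment %in% keep)
  ggplot2::ggplot(d, ggplot2::aes(.data$time_s, .data$value)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~segment, scales = "free_y") +
    ggplot2::labs(x = "time (s)", y = "amplitude",
                  title = sprintf("%s segments @ %g Hz", object$label, object$fs))
}
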