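#' Seeded generators of EEG-like and artifact-like segments
#'
#' These generators emulate the spectral signatures of the signal classes the
#' denoiser is trained on, so the whole pipeline is exercisable without any
#' recorded data: EEG as 1/f-type background plus theta/alpha band activity;
#' EMG as broadband noise with an approximately flat spectrum; EOG as slow
#' blink-like deflections band-limited to 0.5-5 Hz; ECG as a quasi-periodic
#' QRS-like spike train whose power sits almost entirely below 20 Hz.
#' All generators emit zero-mean, unit-variance segments (amplitude is
#' irrelevant downstream: the mixing scale absorbs it) and are deterministic
#' under `seed`. Band limiting is done by frequency-domain masking with a
#' smooth raised-cosine rolloff rather than IIR filtering, for exact
#' reproducibility.
#'
#' @param n_segments number of segments to generate.
#' @param fs sampling rate in Hz.
#' @param duration_s segment duration in seconds; `fs * duration_s` must be
#'   a whole number of samples.
#' @param seed integer seed; same seed, same store.
#' @return A [segment_store] of `n_segments` x `fs * duration_s` samples.
#' @name synthetic-signals
NULL

check_gen_spec <- function(n_segments, fs, duration_s, seed) {
  if (!is.numeric(n_segments) || n_segments < 1) {
    abort("`n_segments` must be >= 1.", class = "eeggan_invalid_input")
  }
  n <- fs * duration_s
  if (abs(n - round(n)) > 1e-9) {
    abort("`fs * duration_s` must be integral.", class = "eeggan_invalid_input")
  }
  if (!is.numeric(seed) || length(seed) != 1L) {
    abort("`seed` must be a single integer.", class = "eeggan_invalid_input")
  }
  as.integer(round(n))
}

# zero-mean, unit-variance (population sd) normalization
unitize <- function(x) {
  x <- x - mean(x)
  s <- sqrt(mean(x^2))
  if (s == 0) x else x / s
}

# smooth one-sided spectral mask: 1 inside [f_lo, f_hi], raised-cosine rolloff
# of width `roll` Hz on both edges, 0 outside
spectral_mask <- function(freqs, f_lo, f_hi, roll = 0.25) {
  m <- numeric(length(freqs))
  for (i in seq_along(freqs)) {
    f <- freqs[i]
    if (f >= f_lo && f <= f_hi) {
      m[i] <- 1
    } else if (f > f_lo - roll && f < f_lo) {
      m[i] <- 0.5 * (1 + cos(pi * (f_lo - f) / roll))
    } else if (f > f_hi && f < f_hi + roll) {
      m[i] <- 0.5 * (1 + cos(pi * (f - f_hi) / roll))
    }
  }
  m
}

# synthesize a real signal from a one-sided amplitude profile with random phases
colored_noise <- function(n, fs, amp_profile) {
  n_keep <- floor(n / 2) + 1L
  amp <- amp_profile
  stopifnot(length(amp) == n_keep)
  ph <- runif(n_keep, 0, 2 * pi)
  half <- amp * exp(1i * ph)
  half[1L] <- 0 # zero mean
  if (n %% 2L == 0L) half[n_keep] <- Re(half[n_keep])
  full <- c(half, Conj(rev(half[2:(n_keep - 1L)])))
  Re(fft(full, inverse = TRUE)) / n
}

one_sided_freqs <- function(n, fs) (seq_len(floor(n / 2) + 1L) - 1) * fs / n

#' @rdname synthetic-signals
#' @param alpha_range range of the 1/f^alpha spectral exponent.
#' @export
gen_eeg <- function(n_segments, fs = 512, duration_s = 2, seed = 1,
                    alpha_range = c(1, 2)) {
  n <- check_gen_spec(n_segments, fs, duration_s, seed)
  freqs <- one_sided_freqs(n, fs)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  data <- matrix(0, n_segments, n)
  for (i in seq_len(n_segments)) {
    a <- runif(1, alpha_range[1], alpha_range[2])
    amp <- ifelse(freqs > 0, freqs^(-a / 2), 0)
    amp <- amp * spectral_mask(freqs, 0.5, 45, roll = 0.5)
    bg <- colored_noise(n, fs, amp * rnorm(length(amp), 1, 0.2))
    t <- (seq_len(n) - 1) / fs
    # theta (4-8 Hz) and alpha (8-13 Hz) oscillations, random freq/phase/amplitude
    th <- runif(1, 0.3, 0.8) * sin(2 * pi * runif(1, 4, 8) * t + runif(1, 0, 2 * pi))
    al <- runif(1, 0.5, 1.2) * sin(2 * pi * runif(1, 8, 13) * t + runif(1, 0, 2 * pi))
    data[i, ] <- unitize(unitize(bg) + th + al)
  }
  segment_store(data, fs, "EEG", meta = list(seed = seed, source = "synthetic"))
}

#' @rdname synthetic-signals
#' @export
gen_emg <- function(n_segments, fs = 512, duration_s = 2, seed = 1) {
  n <- check_gen_spec(n_segments, fs, duration_s, seed)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  data <- matrix(0, n_segments, n)
  for (i in seq_len(n_segments)) {
    # broadband: white noise with a very gentle high-pass (muscle activity has
    # little energy at DC) -> approximately flat PSD up to Nyquist
    x <- rnorm(n)
    xf <- fft(x)
    freqs_full <- c(one_sided_freqs(n, fs), rev(one_sided_freqs(n, fs)[2:(floor(n / 2))]))
    mask <- ifelse(freqs_full < 2, freqs_full / 2, 1)
    x <- Re(fft(xf * mask, inverse = TRUE)) / n
    data[i, ] <- unitize(x)
  }
  segment_store(data, fs, "EMG", meta = list(seed = seed, source = "synthetic"))
}

#' @rdname synthetic-signals
#' @param blink_rate_hz expected blink rate (events per second). At most
#'   three blinks land in a segment, keeping them sparse so the blink peaks
#'   dominate the background spread.
#' @export
gen_eog <- function(n_segments, fs = 512, duration_s = 2, seed = 1,
                    blink_rate_hz = 0.5) {
  n <- check_gen_spec(n_segments, fs, duration_s, seed)
  freqs <- one_sided_freqs(n, fs)
  mask <- spectral_mask(freqs, 0.5, 5, roll = 0.5)
  mask_full <- c(mask, rev(mask[2:(floor(n / 2))]))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  t <- (seq_len(n) - 1) / fs
  data <- matrix(0, n_segments, n)
  for (i in seq_len(n_segments)) {
    # one dominant blink keeps the segment sparse (peak well above the
    # background spread); occasional weaker secondaries add variety
    n_blinks <- min(3L, max(1L, stats::rpois(1, blink_rate_hz * duration_s)))
    x <- numeric(n)
    for (b in seq_len(n_blinks)) {
      c0 <- runif(1, 0.1, duration_s - 0.1)
      w <- runif(1, 0.04, 0.1) # blink half-width, s
      amp <- if (b == 1) runif(1, 6, 9) else runif(1, 0.8, 1.8)
      x <- x + amp * exp(-((t - c0)^2) / (2 * w^2))
    }
    # slow baseline drift
    x <- x + 0.3 * sin(2 * pi * runif(1, 0.5, 1) * t + runif(1, 0, 2 * pi))
    # enforce the 0.5-5 Hz band limit in the frequency domain
    xf <- fft(x)
    x <- Re(fft(xf * mask_full, inverse = TRUE)) / n
    data[i, ] <- unitize(x)
  }
  segment_store(data, fs, "EOG", meta = list(seed = seed, source = "synthetic"))
}

#' @rdname synthetic-signals
#' @param bpm_range heart-rate range in beats per minute.
#' @export
gen_ecg <- function(n_segments, fs = 512, duration_s = 2, seed = 1,
                    bpm_range = c(50, 90)) {
  n <- check_gen_spec(n_segments, fs, duration_s, seed)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  t <- (seq_len(n) - 1) / fs
  data <- matrix(0, n_segments, n)
  for (i in seq_len(n_segments)) {
    bpm <- runif(1, bpm_range[1], bpm_range[2])
    period <- 60 / bpm
    x <- numeric(n)
    beat_t <- runif(1, 0, period)
    while (beat_t < duration_s + period) {
      # QRS-like biphasic spike (Gaussian second derivative, sigma ~ 18 ms)
      # plus a broad T-wave bump
      s_qrs <- 0.018
      u <- (t - beat_t) / s_qrs
      x <- x + (1 - u^2) * exp(-u^2 / 2)
      x <- x + 0.25 * exp(-((t - beat_t - 0.22)^2) / (2 * 0.05^2))
      # jitter kept small so the inter-beat interval CV stays < 0.2
      beat_t <- beat_t + period * (1 + rnorm(1, 0, 0.05))
    }
    data[i, ] <- unitize(x)
  }
  segment_store(data, fs, "ECG", meta = list(seed = seed, source = "synthetic"))
}

# save/restore the global RNG state so generators do not clobber the caller's
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}
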