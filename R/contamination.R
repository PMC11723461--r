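#' Semi-simulated contamination of clean EEG with artifact segments
#'
#' A contaminated segment is built by linear mixing, `y = x + lambda * n`,
#' where `x` is the clean EEG ground truth, `n` a pure artifact segment and
#' `lambda` a scale chosen so the mixture hits a target signal-to-noise
#' ratio `SNR = 10 * log10(rms(x) / rms(lambda * n))` in dB. Note the SNR is
#' defined on the RMS ratio itself (not its square), so an identity
#' "denoiser" at 0 dB has time-domain relative RMSE exactly 1.
#'
#' @name contamination
NULL

#' Solve the mixing scale for a target SNR
#'
#' @param x clean EEG segment (numeric vector).
#' @param n artifact segment (numeric vector), same length.
#' @param snr_db target SNR in dB.
#' @return `lambda > 0` such that `10*log10(rms(x)/rms(lambda*n)) == snr_db`.
#' @examples
#' x <- sin(2 * pi * 10 * (0:1023) / 512)
#' n <- rnorm(1024)
#' lam <- solve_lambda(x, n, snr_db = -7)
#' 10 * log10(rms(x) / rms(lam * n)) # -7
#' @export
solve_lambda <- function(x, n, snr_db) {
  rx <- rms(x); rn <- rms(n)
  if (rx == 0 || rn == 0) {
    abort("zero-RMS segment: cannot set an SNR.", class = "eeggan_degenerate_input")
  }
  rx / (rn * 10^(snr_db / 10))
}

#' Mix a clean segment with a scaled artifact
#'
#' @param x clean EEG segment.
#' @param n artifact segment, same length.
#' @param lam positive mixing scale.
#' @param fs sampling rate in Hz.
#' @param artifact_type one of `"EMG"`, `"EOG"`, `"ECG"`, `"MIXED"`.
#' @return A `contaminated_pair`: list with `x`, `n`, `lam`, `y = x + lam*n`,
#'   `snr_db` (realized SNR recomputed from the components), `artifact_type`,
#'   `fs`.
#' @export
mix_segments <- function(x, n, lam, fs = 512, artifact_type = "EOG") {
  if (length(x) != length(n)) {
    abort("`x` and `n` must have the same length.", class = "eeggan_invalid_input")
  }
  if (lam < 0) abort("`lam` must be >= 0.", class = "eeggan_invalid_input")
  artifact_type <- match.arg(artifact_type, c("EMG", "EOG", "ECG", "MIXED"))
  y <- x + lam * n
  snr_db <- if (lam > 0) 10 * log10(rms(x) / rms(lam * n)) else Inf
  structure(list(x = x, n = n, lam = lam, y = y, snr_db = snr_db,
                 artifact_type = artifact_type, fs = fs),
            class = "contaminated_pair")
}

#' Split-protocol specification
#'
#' 80/10/10 train/validation/test partition; training pairs are mixed at one
#' SNR per pair drawn from the -7..2 dB range, while every validation and
#' test artifact segment is mixed once at each of the ten integer levels
#' (-7, -6, ..., 1, 2 dB), so those partitions have 10x as many examples as
#' pairs.
#'
#' @param train_frac,val_frac,test_frac partition fractions, must sum to 1.
#' @param train_snr_range_db SNR range used for training mixes.
#' @param eval_snr_levels_db the SNR grid used for validation/test mixes.
#' @param seed integer seed controlling pairing, partition and SNR draws.
#' @param snr_sampling `"integer-grid"` draws training SNRs uniformly from
#'   the ten integer dB levels; `"continuous-uniform"` draws from the
#'   continuous range.
#' @return A `split_spec` list.
#' @export
split_spec <- function(train_frac = 0.8, val_frac = 0.1, test_frac = 0.1,
                       train_snr_range_db = c(-7, 2),
                       eval_snr_levels_db = -7:2,
                       seed = 1,
                       snr_sampling = c("integer-grid", "continuous-uniform")) {
  if (abs(train_frac + val_frac + test_frac - 1) > 1e-9) {
    abort("partition fractions must sum to 1.", class = "eeggan_config_error")
  }
  list(train_frac = train_frac, val_frac = val_frac, test_frac = test_frac,
       train_snr_range_db = train_snr_range_db,
       eval_snr_levels_db = eval_snr_levels_db,
       seed = as.integer(seed),
       snr_sampling = match.arg(snr_sampling))
}

#' Batch of contaminated pairs
#'
#' Matrix-backed collection of `(x, n, lambda, y, snr)` records: `X`, `N`,
#' `Y` are pairs x samples matrices, `lam` and `snr_db` vectors.
#'
#' @param X,N matrices of clean and artifact segments (rows are pairs).
#' @param lam per-pair mixing scales.
#' @param snr_db per-pair nominal SNRs (dB).
#' @param artifact_type artifact label.
#' @param fs sampling rate (Hz).
#' @return A `pair_set` with `Y = X + lam * N` built row-wise.
#' @export
pair_set <- function(X, N, lam, snr_db, artifact_type = "EOG", fs = 512) {
  stopifnot(nrow(X) == nrow(N), nrow(X) == length(lam), length(lam) == length(snr_db))
  Y <- X + sweep(N, 1, lam, `*`)
  structure(list(X = X, N = N, Y = Y, lam = lam, snr_db = snr_db,
                 artifact_type = artifact_type, fs = fs),
            class = "pair_set")
}

#' @export
print.pair_set <- function(x, ...) {
  cat(sprintf("<pair_set> %d pairs x %d samples, artifact=%s, SNR %s dB\n",
              nrow(x$X), ncol(x$X), x$artifact_type,
              paste(range(x$snr_db), collapse = "..")))
  invisible(x)
}

#' @export
as_tibble.pair_set <- function(x, ...) {
  tibble(pair = seq_along(x$lam), lam = x$lam, snr_db = x$snr_db,
         artifact_type = x$artifact_type)
}

n_pairs <- function(ps) nrow(ps$X)

#' Build train/validation/test splits of contaminated pairs
#'
#' Clean and artifact segments are randomly paired without replacement, the
#' pairs are partitioned 80/10/10 by seed, and mixtures are generated:
#' training pairs at one SNR each drawn from the training range, validation
#' and test pairs once at every level of the evaluation grid. Segment
#' indices are disjoint across partitions.
#'
#' @param eeg_pool clean-EEG [segment_store].
#' @param artifact_pool artifact [segment_store] (sum EOG and EMG stores
#'   sample-wise first to build MIXED artifacts; the sum is rescaled by a
#'   single lambda).
#' @param spec a [split_spec].
#' @return List with `train`, `val`, `test` (`pair_set`s) and `manifest`
#'   (tibble of partition, pair indices, lambda, snr).
#' @export
build_splits <- function(eeg_pool, artifact_pool, spec = split_spec()) {
  stopifnot(inherits(eeg_pool, "segment_store"), inherits(artifact_pool, "segment_store"))
  if (eeg_pool$fs != artifact_pool$fs || n_samples(eeg_pool) != n_samples(artifact_pool)) {
    abort("pools must share fs and segment length.", class = "eeggan_invalid_input")
  }
  np <- min(n_segments(eeg_pool), n_segments(artifact_pool))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(spec$seed)
  eeg_idx <- sample.int(n_segments(eeg_pool), np)
  art_idx <- sample.int(n_segments(artifact_pool), np)
  n_train <- round(spec$train_frac * np)
  n_val <- round(spec$val_frac * np)
  n_test <- np - n_train - n_val
  if (n_train < 1 || n_val < 1 || n_test < 1) {
    abort("partition fractions leave an empty partition.", class = "eeggan_config_error")
  }
  part <- rep(c("train", "val", "test"), c(n_train, n_val, n_test))
  fs <- eeg_pool$fs
  atype <- if (artifact_pool$label %in% c("EMG", "EOG", "ECG", "MIXED")) artifact_pool$label else "MIXED"

  take <- function(which_part) {
    sel <- which(part == which_part)
    list(X = eeg_pool$data[eeg_idx[sel], , drop = FALSE],
         N = artifact_pool$data[art_idx[sel], , drop = FALSE],
         eeg_idx = eeg_idx[sel], art_idx = art_idx[sel])
  }

  tr <- take("train")
  snr_tr <- if (spec$snr_sampling == "integer-grid") {
    sample(spec$eval_snr_levels_db, nrow(tr$X), replace = TRUE)
  } else {
    runif(nrow(tr$X), spec$train_snr_range_db[1], spec$train_snr_range_db[2])
  }
  lam_tr <- vapply(seq_len(nrow(tr$X)),
                   function(i) solve_lambda(tr$X[i, ], tr$N[i, ], snr_tr[i]), 0)
  train <- pair_set(tr$X, tr$N, lam_tr, snr_tr, atype, fs)

  expand_eval <- function(p) {
    levels <- spec$eval_snr_levels_db
    nb <- nrow(p$X)
    X <- p$X[rep(seq_len(nb), each = length(levels)), , drop = FALSE]
    N <- p$N[rep(seq_len(nb), each = length(levels)), , drop = FALSE]
    snr <- rep(levels, nb)
    lam <- vapply(seq_len(nrow(X)), function(i) solve_lambda(X[i, ], N[i, ], snr[i]), 0)
    pair_set(X, N, lam, snr, atype, fs)
  }
  val <- expand_eval(take("val"))
  test <- expand_eval(take("test"))

  manifest <- dplyr::bind_rows(
    tibble(partition = "train", eeg_idx = tr$eeg_idx, art_idx = tr$art_idx,
           snr_db = snr_tr, lam = lam_tr),
    tibble(partition = "val", eeg_idx = rep(take("val")$eeg_idx, each = length(spec$eval_snr_levels_db)),
           art_idx = rep(take("val")$art_idx, each = length(spec$eval_snr_levels_db)),
           snr_db = val$snr_db, lam = val$lam),
    tibble(partition = "test", eeg_idx = rep(take("test")$eeg_idx, each = length(spec$eval_snr_levels_db)),
           art_idx = rep(take("test")$art_idx, each = length(spec$eval_snr_levels_db)),
           snr_db = test$snr_db, lam = test$lam)
  )
  list(train = train, val = val, test = test, manifest = manifest)
}

#' Sum two artifact stores into a MIXED artifact store
#'
#' EOG and EMG segments are summed sample-wise with equal unit weights; the
#' downstream mixing scale rescales the sum as a whole.
#'
#' @param a,b two [segment_store]s of equal shape.
#' @return A [segment_store] labelled `"MIXED"`.
#' @export
mix_artifact_pools <- function(a, b) {
  stopifnot(inherits(a, "segment_store"), inherits(b, "segment_store"))
  if (a$fs != b$fs || n_samples(a) != n_samples(b)) {
    abort("stores must share fs and segment length.", class = "eeggan_invalid_input")
  }
  np <- min(n_segments(a), n_segments(b))
  segment_store(a$data[seq_len(np), , drop = FALSE] + b$data[seq_len(np), , drop = FALSE],
                a$fs, "MIXED", meta = list(sources = c(a$label, b$label)))
}
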