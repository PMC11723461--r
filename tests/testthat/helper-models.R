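# small model configurations and data builders shared across test files

tiny_gen_cfg <- function(seed = 7) {
  generator_config(input_len = 256, pre_dim = 4, encoder_dims = c(4, 8, 8, 8, 8),
                   gate_hidden = 16, seed = seed)
}

tiny_disc_cfg <- function(seed = 3) {
  discriminator_config(channels = c(4, 4, 8, 8, 8, 8, 8, 8), input_len = 256,
                       seed = seed)
}

# n contaminated EEG+EOG pairs at the given SNR levels (recycled)
make_pairs <- function(n, snr_db = 0, seed = 1, fs = 512, duration_s = 2) {
  eeg <- gen_eeg(n, fs = fs, duration_s = duration_s, seed = seed)
  eog <- gen_eog(n, fs = fs, duration_s = duration_s, seed = seed + 1000)
  snr <- rep_len(snr_db, n)
  lam <- vapply(seq_len(n), function(i) solve_lambda(eeg$data[i, ], eog$data[i, ], snr[i]), 0)
  pair_set(eeg$data, eog$data, lam, snr, "EOG", fs)
}

# reference double-precision attention (partition-local softmax over keys),
# independent of the compiled kernel
ref_attention <- function(Q, K, V, heads, partitions) {
  d <- dim(Q)
  C <- d[1]; T_tok <- d[2]; B <- d[3]
  dh <- C %/% heads
  Tp <- T_tok %/% partitions
  O <- array(0, d)
  for (b in seq_len(B)) {
    for (h in seq_len(heads)) {
      hr <- ((h - 1) * dh + 1):(h * dh)
      for (p in seq_len(partitions)) {
        pc <- ((p - 1) * Tp + 1):(p * Tp)
        Qh <- matrix(Q[hr, pc, b], dh)
        Kh <- matrix(K[hr, pc, b], dh)
        Vh <- matrix(V[hr, pc, b], dh)
        S <- crossprod(Qh, Kh) / sqrt(dh)
        P <- exp(S - apply(S, 1, max))
        P <- P / rowSums(P)
        O[hr, pc, b] <- Vh %*% t(P)
      }
    }
  }
  O
}

expect_rel_equal <- function(x, y, tol) {
  expect_lt(max(abs(x - y)) / max(1e-12, max(abs(y))), tol)
}
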