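# independent brute-force implementations of each metric, written with
# explicit loops/formulas so they share no code with the package versions

oracle_rrmse_t <- function(fy, x) {
  num <- sqrt(sum((fy - x)^2) / length(x))
  den <- sqrt(sum(x^2) / length(x))
  num / den
}

oracle_psd <- function(g, fs) {
  n <- length(g)
  xf <- fft(g)
  keep <- floor(n / 2) + 1
  out <- numeric(keep)
  for (k in seq_len(keep)) {
    v <- Mod(xf[k])^2 / (fs * n)
    if (k > 1 && !(n %% 2 == 0 && k == keep)) v <- 2 * v
    out[k] <- v
  }
  out
}

oracle_rrmse_f <- function(fy, x, fs) {
  p1 <- oracle_psd(fy, fs); p0 <- oracle_psd(x, fs)
  sqrt(mean((p1 - p0)^2)) / sqrt(mean(p0^2))
}

oracle_ssim <- function(fy, x, C1 = 1e-4, C2 = 1e-4) {
  mx <- sum(x) / length(x); mf <- sum(fy) / length(fy)
  vx <- sum((x - mx)^2) / (length(x) - 1)
  vf <- sum((fy - mf)^2) / (length(fy) - 1)
  cv <- sum((x - mx) * (fy - mf)) / (length(x) - 1)
  (2 * mx * mf + C1) * (2 * cv + C2) / ((mx^2 + mf^2 + C1) * (vx + vf + C2))
}

oracle_mi <- function(fy, x, bins = 8) {
  cut_idx <- function(v) {
    lo <- min(v); hi <- max(v)
    i <- floor((v - lo) / (hi - lo) * bins) + 1
    i[i > bins] <- bins
    i
  }
  bx <- cut_idx(x); bf <- cut_idx(fy)
  n <- length(x)
  s <- 0
  for (a in 1:bins) for (b in 1:bins) {
    pj <- sum(bf == a & bx == b) / n
    if (pj > 0) {
      s <- s + pj * log(pj / ((sum(bf == a) / n) * (sum(bx == b) / n)))
    }
  }
  s
}

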