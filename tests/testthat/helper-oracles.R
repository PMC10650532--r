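# Independent brute-force oracles, deliberately written with plain nested
# loops so they share no code path with the package's vectorized
# implementations.

oracle_conv2d <- function(x, w, stride = 1L) {
  # x: (H, W, C); w: (k, k, C, F); valid padding, cross-correlation
  dx <- dim(x); k <- dim(w)[1]; nf <- dim(w)[4]
  h2 <- (dx[1] - k) %/% stride + 1L
  w2 <- (dx[2] - k) %/% stride + 1L
  out <- array(0, c(h2, w2, nf))
  for (f in seq_len(nf)) {
    for (p in seq_len(h2)) {
      for (q in seq_len(w2)) {
        acc <- 0
        for (cc in seq_len(dx[3])) {
          for (ki in seq_len(k)) {
            for (kj in seq_len(k)) {
              acc <- acc + x[(p - 1L) * stride + ki,
                             (q - 1L) * stride + kj, cc] * w[ki, kj, cc, f]
            }
          }
        }
        out[p, q, f] <- acc
      }
    }
  }
  out
}

oracle_max_pool <- function(x, window, stride = window) {
  dx <- dim(x)
  h2 <- (dx[1] - window) %/% stride + 1L
  w2 <- (dx[2] - window) %/% stride + 1L
  out <- array(-Inf, c(h2, w2, dx[3]))
  for (cc in seq_len(dx[3])) {
    for (p in seq_len(h2)) {
      for (q in seq_len(w2)) {
        m <- -Inf
        for (ki in seq_len(window)) {
          for (kj in seq_len(window)) {
            v <- x[(p - 1L) * stride + ki, (q - 1L) * stride + kj, cc]
            if (v > m) m <- v
          }
        }
        out[p, q, cc] <- m
      }
    }
  }
  out
}

# Kruskal-Wallis H from first principles: rank sums with tie correction.
oracle_kruskal_h <- function(groups) {
  x <- unlist(groups)
  n <- length(x)
  r <- rank(x)
  sizes <- vapply(groups, length, integer(1))
  idx <- split(seq_len(n), rep(seq_along(groups), sizes))
  h <- 12 / (n * (n + 1)) *
    sum(vapply(idx, function(i) sum(r[i])^2 / length(i), numeric(1))) -
    3 * (n + 1)
  ties <- table(x)
  correction <- 1 - sum(ties^3 - ties) / (n^3 - n)
  h / correction
}

# Mean periodogram power of one channel in a frequency band.
band_power <- function(segment, channel = 1L, f_lo, f_hi) {
  x <- segment$samples[channel, ]
  n <- length(x)
  fs <- segment$sampling_rate
  sp <- Mod(stats::fft(x))^2 / n
  freq <- (seq_len(n) - 1L) * fs / n
  sel <- freq >= f_lo & freq <= f_hi
  mean(sp[sel])
}

random_image <- function(side, seed) {
  px <- withr::with_seed(seed, matrix(sample(0:255, side * side, TRUE),
                                      side, side))
  structure(list(pixels = px, freq = NULL, time = NULL, side = side,
                 source_channel = 1L, label = "synthetic"),
            class = "spectrogram_image")
}

# All baker partitions of N into parts dividing N (first `limit` found).
baker_partitions <- function(N, limit = 5L) {
  divisors <- rev(Filter(function(d) N %% d == 0L, seq_len(N)))
  found <- list()
  recurse <- function(remaining, acc) {
    if (length(found) >= limit) return()
    if (remaining == 0L) {
      found[[length(found) + 1L]] <<- acc
      return()
    }
    for (d in divisors) {
      if (d <= remaining) recurse(remaining - d, c(acc, d))
    }
  }
  recurse(N, integer(0))
  found
}
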