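## Independent oracles used across the suite. These deliberately avoid the
## package's own code paths: brute-force enumeration and direct formula
## evaluation only.

## Direct evaluation of persistent entropy from interval endpoints.
oracle_entropy <- function(birth, death, max_filter) {
  death[is.infinite(death)] <- max_filter + 1
  len <- death - birth
  len <- len[len > 0]
  L <- sum(len)
  p <- len / L
  H <- -sum(p * log(p))
  list(H = H, H_norm = H / log(max(len)))
}

## O(N^2) Sample Entropy by direct template-pair enumeration.
oracle_sampen <- function(x, m, r) {
  n <- length(x)
  count <- function(mm) {
    tot <- 0L
    for (i in seq_len(n - m - 1L)) {
      for (j in (i + 1L):(n - m)) {
        if (max(abs(x[i:(i + mm - 1L)] - x[j:(j + mm - 1L)])) <= r)
          tot <- tot + 1L
      }
    }
    tot
  }
  A <- count(m + 1L); B <- count(m)
  if (A == 0L || B == 0L) return(Inf)
  -log(A / B)
}

## AUC by concordant-pair counting with half credit for ties.
oracle_auc <- function(scores, is_pos) {
  pos <- scores[is_pos]; neg <- scores[!is_pos]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

## Strict local minima of a sampled signal (endpoints count when locally
## minimal); brute force.
oracle_local_minima <- function(y) {
  n <- length(y)
  if (n == 1L) return(1L)
  cnt <- 0L
  for (k in seq_len(n)) {
    left <- if (k > 1L) y[k - 1L] > y[k] else TRUE
    right <- if (k < n) y[k + 1L] > y[k] else TRUE
    if (left && right) cnt <- cnt + 1L
  }
  cnt
}

## Amplitude of the sinusoid component at frequency f in x (least squares
## on a sin/cos basis), used as a frequency-response probe.
fitted_amplitude <- function(x, f, fs) {
  t <- (seq_along(x) - 1) / fs
  fit <- stats::lm(x ~ sin(2 * pi * f * t) + cos(2 * pi * f * t))
  sqrt(sum(stats::coef(fit)[2:3]^2))
}

## Multiset comparison of barcode intervals in one dimension.
intervals_sorted <- function(bc, d = 0L) {
  iv <- bc$intervals[bc$intervals$dim == d, c("birth", "death")]
  iv[order(iv$birth, iv$death), , drop = FALSE]
}

## Random piecewise-complex test signal.
random_signal <- function(n, amp = 10) stats::runif(n, -amp, amp)

make_recording <- function(mat, fs = 256, label = "unknown") {
  recording(lapply(seq_len(ncol(mat)), function(i)
    channel_signal(mat[, i], fs = fs, sensor_id = i,
                   sensor_label = paste0("CH", i))), label = label)
}
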