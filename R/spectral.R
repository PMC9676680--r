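# Shared time->frequency helpers.
#
# One-sided generalized DFT of a uniformly sampled periodic signal at
# arbitrary positive bin frequencies. Amplitudes are peak (not RMS):
# a pure tone cos(2 pi f t) of amplitude A returns |A_f| = A with a boxcar
# window, up to leakage for off-grid bins.

dft_window <- function(m, window = c("hann", "boxcar")) {
  window <- match.arg(window)
  if (window == "hann") 0.5 - 0.5 * cos(2 * pi * seq_len(m) / m) else rep(1, m)
}

# Weight matrix W (m x nbins) such that A = (2/sum(w)) * t(X %*% W) gives
# one-sided complex amplitudes for signals in the rows of X (n x m).
dft_weights <- function(times, freqs, window = "hann") {
  w <- dft_window(length(times), window)
  ph <- outer(times, freqs, function(t, f) -2 * pi * f * t)
  list(cos = w * cos(ph), sin = w * sin(ph), wsum = sum(w))
}

# Apply: X (n x m) real -> complex amplitude matrix (n x nbins)
dft_apply <- function(X, wts) {
  re <- X %*% wts$cos
  im <- X %*% wts$sin
  (2 / wts$wsum) * (re + 1i * im)
}

# One-sided spectrum of a single periodic cycle x at bins j/T, j = 1..K.
# Returns list(freq, amp) with complex peak amplitudes; DC is dropped.
dft_onesided <- function(x, period, window = "hann", f_max = NULL) {
  m <- length(x)
  if (is.null(f_max)) f_max <- (m %/% 2) / period
  k <- seq_len(floor(f_max * period + 1e-9))
  k <- k[k <= m %/% 2]
  freqs <- k / period
  t <- (seq_len(m) - 1) * period / m
  wts <- dft_weights(t, freqs, window)
  amp <- drop(dft_apply(matrix(x, 1), wts))
  list(freq = freqs, amp = amp)
}
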