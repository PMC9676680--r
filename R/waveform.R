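#' Synthesize a pulsatile venous inlet waveform
#'
#' Builds one period of a pulse-synchronous, Doppler-like inlet velocity
#' waveform: a raised-cosine systolic pulse truncated to `n_harmonics`
#' Fourier harmonics and affinely rescaled so the time-average and maximum
#' hit `mean_v` and `peak_v` exactly (well within the 1% contract). All
#' samples are non-negative: venous inlet flow does not reverse in this
#' model.
#'
#' @param heart_rate_bpm heart rate in beats/min, in `[30, 200]`.
#' @param mean_v target time-average velocity, m/s (> 0).
#' @param peak_v target maximum velocity, m/s (>= `mean_v`).
#' @param n_harmonics number of Fourier harmonics retained (>= 1).
#' @param n_samples samples per period (power of two recommended).
#' @param jitter relative amplitude of seeded per-harmonic perturbation
#'   (realism knob; 0 gives the deterministic canonical shape).
#' @param seed integer seed for the harmonic jitter.
#' @return object of class `inlet_waveform`: `period` (s), `samples` (m/s,
#'   spanning exactly one period), `sample_rate` (Hz), `mean_velocity`,
#'   `peak_velocity`.
#' @export
#' @examples
#' wf <- synthesize_waveform(70, mean_v = 0.198, peak_v = 0.745)
#' wf$period            # 60/70 s
#' mean(wf$samples)     # ~0.198
synthesize_waveform <- function(heart_rate_bpm, mean_v, peak_v,
                                n_harmonics = 8, n_samples = 1024,
                                jitter = 0.02, seed = 1L) {
  if (!is.finite(heart_rate_bpm) || heart_rate_bpm < 30 || heart_rate_bpm > 200) {
    stop("synthesize_waveform: 'heart_rate_bpm' must lie in [30, 200]", call. = FALSE)
  }
  if (!is.finite(mean_v) || mean_v <= 0) {
    stop("synthesize_waveform: 'mean_v' must be > 0", call. = FALSE)
  }
  if (!is.finite(peak_v) || peak_v < mean_v) {
    stop("synthesize_waveform: 'peak_v' must be >= 'mean_v'", call. = FALSE)
  }
  stopifnot(n_harmonics >= 1, n_samples >= 16)
  period <- 60 / heart_rate_bpm

  if (peak_v == mean_v) {
    samples <- rep(mean_v, n_samples)
  } else {
    tau <- seq(0, 1, length.out = n_samples + 1)[-(n_samples + 1)]
    # pulse duty cycle chosen so the affine map below stays non-negative
    m <- mean_v / (peak_v - mean_v)
    duty <- min(0.3, 0.8 * m / (1 + m))
    s <- ifelse(abs(tau - 0.25) < duty / 2,
                cos(pi * (tau - 0.25) / duty)^2, 0)
    # truncate to n_harmonics (low-pass in the Fourier domain)
    S <- fft(s)
    keep <- c(1, 1 + seq_len(min(n_harmonics, n_samples %/% 2 - 1)))
    mask <- rep(0, n_samples)
    mask[keep] <- 1
    mask[n_samples + 2 - keep[-1]] <- 1
    if (jitter > 0) {
      old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
      set.seed(as.integer(seed))
      g <- 1 + jitter * rnorm(length(keep) - 1)
      on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
      S[keep[-1]] <- S[keep[-1]] * g
      S[n_samples + 2 - keep[-1]] <- S[n_samples + 2 - keep[-1]] * g
    }
    s <- Re(fft(S * mask, inverse = TRUE)) / n_samples
    s <- s - min(s)                       # non-negative shape, min = 0
    b <- (peak_v - mean_v) / (max(s) - mean(s))
    a <- mean_v - b * mean(s)
    samples <- pmax(a + b * s, 0)
  }
  structure(
    list(period = period, samples = samples,
         sample_rate = n_samples / period,
         mean_velocity = mean(samples), peak_velocity = max(samples)),
    class = "inlet_waveform"
  )
}

#' @export
print.inlet_waveform <- function(x, ...) {
  cat(sprintf("<inlet_waveform> period %.3f s (%d samples), mean %.3f m/s, peak %.3f m/s\n",
              x$period, length(x$samples), x$mean_velocity, x$peak_velocity))
  invisible(x)
}

#' Sample an inlet waveform at arbitrary times
#'
#' Periodic extension with piecewise-linear interpolation between the stored
#' samples.
#'
#' @param waveform an [synthesize_waveform()] result.
#' @param t time(s) in s, non-negative (vectorized).
#' @return velocity in m/s.
#' @export
sample_at <- function(waveform, t) {
  stopifnot(inherits(waveform, "inlet_waveform"))
  if (any(t < 0)) stop("sample_at: 't' must be non-negative", call. = FALSE)
  n <- length(waveform$samples)
  tau <- (t %% waveform$period) / waveform$period * n   # in [0, n)
  i0 <- floor(tau)
  w <- tau - i0
  v0 <- waveform$samples[(i0 %% n) + 1]
  v1 <- waveform$samples[((i0 + 1) %% n) + 1]
  (1 - w) * v0 + w * v1
}

#' Write / read an inlet waveform as two-column CSV (time s, velocity m/s)
#'
#' @param waveform an inlet waveform.
#' @param path CSV path.
#' @return `path` (write) or an `inlet_waveform` (read).
#' @export
write_waveform_csv <- function(waveform, path) {
  stopifnot(inherits(waveform, "inlet_waveform"))
  n <- length(waveform$samples)
  df <- data.frame(time_s = (0:(n - 1)) * waveform$period / n,
                   velocity_m_s = waveform$samples)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_waveform_csv
#' @export
read_waveform_csv <- function(path) {
  df <- read.csv(path)
  n <- nrow(df)
  dt <- df$time_s[2] - df$time_s[1]
  period <- dt * n
  structure(
    list(period = period, samples = df$velocity_m_s, sample_rate = n / period,
         mean_velocity = mean(df$velocity_m_s), peak_velocity = max(df$velocity_m_s)),
    class = "inlet_waveform"
  )
}
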