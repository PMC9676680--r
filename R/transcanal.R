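#' Short-time Fourier transform of an audio clip
#'
#' Hann-windowed magnitude spectrogram in relative dB (recordings are
#' uncalibrated, so 0 dB is full scale of a unit-amplitude sinusoid;
#' silence maps to the `floor_db` sentinel).
#'
#' @param clip an [audio_clip()].
#' @param window_length window length in s (default 0.25 s; must hold at
#'   least 16 samples).
#' @param overlap fractional overlap in `[0, 0.95]` (default 0.5).
#' @param floor_db dB sentinel for empty bins.
#' @return object of class `spectro_temporal`: `times` (frame centers, s),
#'   `frequencies` (Hz, up to Nyquist), `magnitude_db` (freq x time matrix).
#' @export
stft <- function(clip, window_length = 0.25, overlap = 0.5, floor_db = -120) {
  stopifnot(inherits(clip, "audio_clip"))
  fs <- clip$sample_rate
  nwin <- round(window_length * fs)
  if (nwin < 16) stop("stft: window must hold at least 16 samples", call. = FALSE)
  if (overlap < 0 || overlap > 0.95) {
    stop("stft: 'overlap' must lie in [0, 0.95]", call. = FALSE)
  }
  x <- clip$samples
  if (length(x) < nwin) stop("stft: clip shorter than one window", call. = FALSE)
  hop <- max(1L, round(nwin * (1 - overlap)))
  starts <- seq(1L, length(x) - nwin + 1L, by = hop)
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(nwin) / (nwin + 1))
  nfreq <- nwin %/% 2 + 1L
  mag <- matrix(floor_db, nfreq, length(starts))
  scale <- 2 / sum(w)            # unit-amplitude sinusoid -> 0 dB
  for (k in seq_along(starts)) {
    seg <- x[starts[k] + seq_len(nwin) - 1L] * w
    a <- Mod(fft(seg))[seq_len(nfreq)] * scale
    mag[, k] <- ifelse(a > 0, pmax(20 * log10(a), floor_db), floor_db)
  }
  structure(
    list(times = (starts - 1 + nwin / 2) / fs,
         frequencies = (seq_len(nfreq) - 1) * fs / nwin,
         magnitude_db = mag),
    class = "spectro_temporal"
  )
}

#' @export
print.spectro_temporal <- function(x, ...) {
  cat(sprintf("<spectro_temporal> %d freqs x %d frames, up to %.0f Hz\n",
              length(x$frequencies), length(x$times), max(x$frequencies)))
  invisible(x)
}

# Welch-averaged one-sided amplitude spectrum (relative units): Hann window,
# 50% overlap by default. Returns list(freq, amp_db).
welch_spectrum <- function(samples, fs, window_length = 1, overlap = 0.5,
                           floor_db = -200) {
  nwin <- round(window_length * fs)
  hop <- max(1L, round(nwin * (1 - overlap)))
  starts <- seq(1L, length(samples) - nwin + 1L, by = hop)
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(nwin) / (nwin + 1))
  nfreq <- nwin %/% 2 + 1L
  pow <- numeric(nfreq)
  scale <- 2 / sum(w)
  for (k in seq_along(starts)) {
    seg <- samples[starts[k] + seq_len(nwin) - 1L] * w
    pow <- pow + (Mod(fft(seg))[seq_len(nfreq)] * scale)^2
  }
  pow <- pow / length(starts)
  amp <- sqrt(pow)
  list(freq = (seq_len(nfreq) - 1) * fs / nwin, amp = amp,
       amp_db = ifelse(amp > 0, pmax(20 * log10(amp), floor_db), floor_db))
}

#' Band-limited level difference between paired recordings
#'
#' Compares the somatosound-present clip (PT) against the suppressed clip
#' (NO_PT, recorded during ipsilateral jugular compression): Welch-averaged
#' amplitude spectra of both clips are restricted to the sensing band and
#' the peak and RMS levels are differenced in dB (the RMS delta compares the
#' in-band RMS amplitudes, i.e. an energy measure). All levels are relative
#' (uncalibrated microphone).
#'
#' @param pt_clip,nopt_clip [audio_clip()]s at the same sample rate, each at
#'   least 5 s long.
#' @param band sensing band in Hz (default 65-1000 Hz).
#' @param window_length,overlap Welch parameters (defaults 1 s, 50%).
#' @return object of class `delta_report`: `band`, `peak_delta` (dB),
#'   `rms_delta` (dB), `freq_at_peak_pt` (Hz).
#' @export
band_delta <- function(pt_clip, nopt_clip, band = c(65, 1000),
                       window_length = 1, overlap = 0.5) {
  stopifnot(inherits(pt_clip, "audio_clip"), inherits(nopt_clip, "audio_clip"))
  if (pt_clip$sample_rate != nopt_clip$sample_rate) {
    stop("band_delta: sample rates differ between the clips", call. = FALSE)
  }
  fs <- pt_clip$sample_rate
  if (length(pt_clip$samples) < 5 * fs || length(nopt_clip$samples) < 5 * fs) {
    stop("band_delta: both clips must be at least 5 s long", call. = FALSE)
  }
  sp_pt <- welch_spectrum(pt_clip$samples, fs, window_length, overlap)
  sp_no <- welch_spectrum(nopt_clip$samples, fs, window_length, overlap)
  sel <- sp_pt$freq >= band[1] & sp_pt$freq <= band[2]
  if (!any(sel)) stop("band_delta: no spectral bins inside the band", call. = FALSE)
  pt_db <- sp_pt$amp_db[sel]; no_db <- sp_no$amp_db[sel]
  f <- sp_pt$freq[sel]
  structure(
    list(band = band,
         peak_delta = max(pt_db) - max(no_db),
         rms_delta = 20 * log10(sqrt(mean(sp_pt$amp[sel]^2)) /
                                  sqrt(mean(sp_no$amp[sel]^2))),
         freq_at_peak_pt = f[which.max(pt_db)]),
    class = "delta_report"
  )
}

#' @export
print.delta_report <- function(x, ...) {
  cat(sprintf("<delta_report> band [%g, %g] Hz: peak delta %.1f dB, rms delta %.1f dB, PT peak at %.1f Hz\n",
              x$band[1], x$band[2], x$peak_delta, x$rms_delta, x$freq_at_peak_pt))
  invisible(x)
}

#' Synthesize a paired somatosound recording (PT present vs suppressed)
#'
#' Generates the stand-in for a transcanal recording session with jugular
#' compression: `NO_PT` is stationary broadband background noise; `PT` adds
#' a pulse-train-modulated narrow-band noise centered at `pt_center_freq`
#' whose band-limited excess over the background equals `pt_excess_db`. The
#' excess is defined against the same Welch band spectrum that [band_delta()]
#' measures (peak level in the sensing band), so the generator calibrates
#' the injected component with that estimator. More than 90% of the injected
#' component's power lies below 1 kHz; generation is deterministic per seed.
#'
#' @param heart_rate_bpm pulse rate of the modulation, beats/min.
#' @param pt_excess_db injected band-limited excess in dB (>= 0).
#' @param pt_center_freq center of the narrow-band component, Hz (<= 1000).
#' @param background_level background noise level in dBFS (negative).
#' @param duration clip duration in s (>= 5).
#' @param sample_rate audio rate in Hz.
#' @param seed integer seed (bit-reproducible clips).
#' @param band sensing band used for the calibration, Hz.
#' @return list with elements `pt` and `nopt`, both [audio_clip()]s.
#' @export
synth_somatosound <- function(heart_rate_bpm = 70, pt_excess_db = 10.3,
                              pt_center_freq = 225.5, background_level = -40,
                              duration = 10, sample_rate = 8000, seed = 1L,
                              band = c(65, 1000)) {
  if (duration < 5) stop("synth_somatosound: duration must be >= 5 s", call. = FALSE)
  if (pt_center_freq > 1000) {
    stop("synth_somatosound: pt_center_freq must be <= 1000 Hz", call. = FALSE)
  }
  if (pt_excess_db < 0) stop("synth_somatosound: negative excess", call. = FALSE)
  stopifnot(heart_rate_bpm >= 30, heart_rate_bpm <= 200, sample_rate >= 2000)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  n <- round(duration * sample_rate)
  t <- (seq_len(n) - 1) / sample_rate
  bg_amp <- 10^(background_level / 20)
  background <- rnorm(n) * bg_amp
  nopt <- background
  # narrow-band hum: pulse-modulated carrier at the center frequency plus
  # weaker band-passed noise, so the spectral peak sits at the carrier bin
  bw <- 30   # Hz, half-width of the noise skirt
  z <- fft(rnorm(n))
  f_axis <- (seq_len(n) - 1) * sample_rate / n
  f_fold <- pmin(f_axis, sample_rate - f_axis)
  mask <- exp(-0.5 * ((f_fold - pt_center_freq) / bw)^2)
  skirt <- Re(fft(z * mask, inverse = TRUE)) / n
  skirt <- skirt / stats::sd(skirt)
  nb <- cos(2 * pi * pt_center_freq * (seq_len(n) - 1) / sample_rate +
              runif(1, 0, 2 * pi)) + 0.25 * skirt
  # raised-cosine pulse train at the heart period (systolic bursts)
  Tp <- 60 / heart_rate_bpm
  phase <- (t %% Tp) / Tp
  env <- ifelse(abs(phase - 0.25) < 0.175, cos(pi * (phase - 0.25) / 0.35)^2, 0)
  pt_comp <- nb * env
  # calibrate the injected amplitude so the measured in-band peak excess of
  # (background + component) over background equals pt_excess_db
  if (pt_excess_db > 0) {
    wl <- min(1, duration / 5)
    sp_no <- welch_spectrum(nopt, sample_rate, window_length = wl)
    sel <- sp_no$freq >= band[1] & sp_no$freq <= band[2]
    target <- max(sp_no$amp_db[sel]) + pt_excess_db
    level_at <- function(a) {
      sp <- welch_spectrum(nopt + a * pt_comp, sample_rate, window_length = wl)
      max(sp$amp_db[sel]) - target
    }
    a_hi <- bg_amp / max(abs(pt_comp))
    while (level_at(a_hi) < 0) a_hi <- a_hi * 2
    a <- stats::uniroot(level_at, c(0, a_hi), tol = a_hi * 1e-4)$root
    pt <- nopt + a * pt_comp
  } else {
    pt <- nopt
  }
  pk <- max(abs(c(pt, nopt)), 1)
  list(pt = audio_clip(pt / pk, sample_rate, "PT"),
       nopt = audio_clip(nopt / pk, sample_rate, "NO_PT"))
}

#' Pulse period of a somatosound clip from its band envelope
#'
#' Extracts the band-limited analytic envelope of the clip and estimates its
#' repetition period by harmonic summing over the envelope spectrum (the
#' envelope of a pulse-synchronous somatosound carries spectral lines at
#' every multiple of the heart rate; summing the first few harmonics pins
#' the fundamental far more sharply than a single autocorrelation peak).
#'
#' @param clip an [audio_clip()].
#' @param band analysis band in Hz.
#' @param rate_range candidate pulse-rate range in Hz (default 0.5-3.4 Hz,
#'   i.e. 30-204 bpm).
#' @param n_harmonics harmonics summed.
#' @return estimated pulse period in s.
#' @export
pulse_period_estimate <- function(clip, band = c(65, 1000),
                                  rate_range = c(0.5, 3.4), n_harmonics = 6) {
  stopifnot(inherits(clip, "audio_clip"))
  fs <- clip$sample_rate
  x <- clip$samples
  n <- length(x)
  X <- fft(x)
  f_axis <- (seq_len(n) - 1) * fs / n
  f_fold <- pmin(f_axis, fs - f_axis)
  X[f_fold < band[1] | f_fold > band[2]] <- 0
  xb <- Re(fft(X, inverse = TRUE)) / n
  # analytic envelope via the Hilbert transform (frequency-domain)
  H <- fft(xb)
  pos <- f_axis > 0 & f_axis < fs / 2
  H[pos] <- 2 * H[pos]
  H[f_axis >= fs / 2] <- 0
  env <- Mod(fft(H, inverse = TRUE)) / n
  env <- env - mean(env)
  # zero-padded envelope spectrum, then harmonic summing over candidate rates
  np <- 2^ceiling(log2(4 * n))
  E <- Mod(fft(c(env * dft_window(n, "hann"), rep(0, np - n))))[seq_len(np %/% 2)]
  f_res <- fs / np
  fgrid <- seq(rate_range[1], rate_range[2], by = 0.002)
  score <- vapply(fgrid, function(f0) {
    fh <- f0 * seq_len(n_harmonics)
    sum(E[pmin(length(E), round(fh / f_res) + 1)])
  }, numeric(1))
  1 / fgrid[which.max(score)]
}
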