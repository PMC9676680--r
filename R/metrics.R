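#' Sound pressure level re 20 uPa
#'
#' Converts an RMS acoustic pressure to sound pressure level on the standard
#' 20 uPa hearing reference.
#'
#' @param p_rms RMS pressure in Pa, non-negative (vectorized).
#' @return SPL in dB re 20 uPa; `-Inf` for zero pressure.
#' @seealso [pressure_from_spl()] for the inverse.
#' @export
#' @examples
#' spl_from_pressure(2e-5)  # 0 dB
#' spl_from_pressure(0.2)   # 80 dB
spl_from_pressure <- function(p_rms) {
  if (any(!is.finite(p_rms) | p_rms < 0)) {
    stop("spl_from_pressure: 'p_rms' must be finite and non-negative", call. = FALSE)
  }
  ifelse(p_rms > 0, 20 * log10(p_rms / P_REF), -Inf)
}

#' Inverse of [spl_from_pressure()]
#'
#' @param spl SPL in dB re 20 uPa (vectorized); `-Inf` maps to 0 Pa.
#' @return RMS pressure in Pa.
#' @export
pressure_from_spl <- function(spl) {
  ifelse(is.finite(spl), P_REF * 10^(spl / 20), 0)
}

# 20 uPa hearing reference
P_REF <- 2e-5

#' A-weighting offset at a frequency
#'
#' Closed-form IEC 61672 A-weighting curve, normalized so the offset is
#' exactly 0 dB at 1000 Hz. Adding the offset to an SPL in dB gives the
#' A-weighted level in dBA.
#'
#' @param f frequency in Hz, strictly positive (vectorized).
#' @return weighting offset in dB (negative below ~1 kHz).
#' @export
#' @examples
#' a_weight_offset(1000)  # 0
#' a_weight_offset(20.2)  # about -50.1
a_weight_offset <- function(f) {
  if (any(!is.finite(f) | f <= 0)) {
    stop("a_weight_offset: 'f' must be finite and > 0", call. = FALSE)
  }
  ra <- function(f) {
    f2 <- f^2
    (12194^2 * f2^2) /
      ((f2 + 20.6^2) * sqrt((f2 + 107.7^2) * (f2 + 737.9^2)) * (f2 + 12194^2))
  }
  20 * log10(ra(f)) - 20 * log10(ra(1000))
}

#' Relative error in percent
#'
#' The grid-independence metric: `|value - reference| / |reference| * 100`,
#' as used when tabulating a mesh-refinement ladder against its finest level.
#'
#' @param value observed value.
#' @param reference reference (finest-grid) value, non-zero.
#' @return relative error in percent.
#' @export
#' @examples
#' relative_error(1.5761e-01, 1.5800e-01)  # ~0.247 %
relative_error <- function(value, reference) {
  if (any(!is.finite(reference)) || any(reference == 0)) {
    stop("relative_error: 'reference' must be finite and non-zero", call. = FALSE)
  }
  abs(value - reference) / abs(reference) * 100
}

#' Amplitude gradient between two band reports
#'
#' Difference of band RMS levels between an upstream and a downstream probe,
#' as an absolute dB drop and as a percentage of the upstream level.
#'
#' @param report_a upstream [band_stats()] report (or a bare dB value).
#' @param report_b downstream report (or a bare dB value).
#' @return list with `db_difference` (rms_a - rms_b, dB) and
#'   `percent_decrease` (difference / rms_a * 100).
#' @export
#' @examples
#' amplitude_gradient(82.0, 48.6)  # 33.4 dB, ~40.7 %
amplitude_gradient <- function(report_a, report_b) {
  rms_a <- if (inherits(report_a, "band_report")) report_a$rms_db else report_a
  rms_b <- if (inherits(report_b, "band_report")) report_b$rms_db else report_b
  if (inherits(report_a, "band_report") && inherits(report_b, "band_report") &&
      !isTRUE(all.equal(report_a$band, report_b$band))) {
    stop("amplitude_gradient: reports use different bands", call. = FALSE)
  }
  diff_db <- rms_a - rms_b
  list(db_difference = diff_db, percent_decrease = diff_db / rms_a * 100)
}

#' Pressure spectrum at a probe
#'
#' Container for a one-sided complex pressure spectrum at a virtual
#' microphone, with SPL derived per bin. `amplitude` holds peak (not RMS)
#' complex amplitudes per bin; RMS is `|amplitude|/sqrt(2)` except at DC.
#'
#' @param frequencies bin frequencies in Hz, non-negative increasing.
#' @param amplitude complex (or numeric) peak amplitude per bin, Pa.
#' @param mic probe name.
#' @return object of class `pressure_spectrum` with fields `mic`,
#'   `frequencies`, `amplitude`, `p_rms`, `spl`.
#' @export
pressure_spectrum <- function(frequencies, amplitude, mic = "mic") {
  stopifnot(length(frequencies) == length(amplitude))
  if (is.unsorted(frequencies, strictly = TRUE)) {
    stop("pressure_spectrum: frequencies must be strictly increasing", call. = FALSE)
  }
  if (any(frequencies < 0)) stop("pressure_spectrum: negative frequency", call. = FALSE)
  amplitude <- as.complex(amplitude)
  p_rms <- Mod(amplitude) / ifelse(frequencies == 0, 1, sqrt(2))
  structure(
    list(mic = mic, frequencies = frequencies, amplitude = amplitude,
         p_rms = p_rms, spl = spl_from_pressure(p_rms)),
    class = "pressure_spectrum"
  )
}

#' @export
print.pressure_spectrum <- function(x, ...) {
  cat("<pressure_spectrum> mic:", x$mic, "|", length(x$frequencies), "bins",
      sprintf("[%.2f, %.2f] Hz\n", min(x$frequencies), max(x$frequencies)))
  fin <- is.finite(x$spl)
  if (any(fin)) {
    i <- which.max(x$spl)
    cat(sprintf("  peak %.1f dB at %.1f Hz\n", x$spl[i], x$frequencies[i]))
  }
  invisible(x)
}

#' Band-limited acoustic statistics
#'
#' Peak and RMS levels of a pressure spectrum restricted to a frequency band
#' (default 20-1000 Hz), in dB and dBA, with the frequency at which each peak
#' occurs.
#'
#' The RMS is, by default, the root mean square of the per-bin SPL *values in
#' dB* across the band (`rms_convention = "db"`), i.e. many quiet bins pull
#' the band RMS far below the peak even when one bin dominates the energy.
#' The energy convention (`"energy"`: total in-band RMS pressure re-expressed
#' in dB) is also available. Bins with zero pressure (`-Inf` dB) are excluded
#' from both statistics.
#'
#' @param spectrum a [pressure_spectrum()].
#' @param band length-2 numeric, band edges in Hz (closed interval).
#' @param rms_convention `"db"` (default) or `"energy"`.
#' @return object of class `band_report`: `band`, `peak_db`, `peak_dba`,
#'   `freq_at_peak_db`, `freq_at_peak_dba`, `rms_db`, `rms_dba`.
#' @export
band_stats <- function(spectrum, band = c(20, 1000), rms_convention = c("db", "energy")) {
  stopifnot(inherits(spectrum, "pressure_spectrum"))
  rms_convention <- match.arg(rms_convention)
  if (length(band) != 2 || band[1] >= band[2]) {
    stop("band_stats: 'band' must be (lo, hi) with lo < hi", call. = FALSE)
  }
  sel <- spectrum$frequencies >= band[1] & spectrum$frequencies <= band[2]
  if (!any(sel)) stop("band_stats: no spectrum bins inside the band", call. = FALSE)
  f <- spectrum$frequencies[sel]
  spl <- spectrum$spl[sel]
  prms <- spectrum$p_rms[sel]
  live <- is.finite(spl)
  if (!any(live)) stop("band_stats: all in-band bins are silent", call. = FALSE)
  f <- f[live]; spl <- spl[live]; prms <- prms[live]
  spla <- spl + a_weight_offset(f)

  rms_of <- function(levels, p) {
    if (rms_convention == "db") sqrt(mean(levels^2))
    else spl_from_pressure(sqrt(sum(p^2)))
  }
  ipk <- which.max(spl)
  ipka <- which.max(spla)
  structure(
    list(band = band,
         peak_db = spl[ipk], freq_at_peak_db = f[ipk],
         peak_dba = spla[ipka], freq_at_peak_dba = f[ipka],
         rms_db = rms_of(spl, prms),
         rms_dba = rms_of(spla, prms * 10^(a_weight_offset(f) / 20)),
         rms_convention = rms_convention),
    class = "band_report"
  )
}

#' @export
print.band_report <- function(x, ...) {
  cat(sprintf("<band_report> [%g, %g] Hz\n", x$band[1], x$band[2]))
  cat(sprintf("  peak %.1f dB @ %.1f Hz | %.1f dBA @ %.1f Hz\n",
              x$peak_db, x$freq_at_peak_db, x$peak_dba, x$freq_at_peak_dba))
  cat(sprintf("  rms  %.1f dB | %.1f dBA  (%s convention)\n",
              x$rms_db, x$rms_dba, x$rms_convention))
  invisible(x)
}

#' Sonify a one-cycle signal to audio
#'
#' Renders one pulsatory cycle of a computed pressure or displacement trace
#' as repeated audio, the way simulated somatosounds are played back for
#' subjective rating (nine cycles by default). The cycle is resampled to the
#' audio rate by band-limited (FFT) interpolation, tiled, and peak-normalized
#' to -1 dBFS.
#'
#' @param samples numeric vector: one full cycle, uniformly sampled.
#' @param period cycle duration in s.
#' @param n_cycles number of cycles to render (>= 1).
#' @param sample_rate output audio rate in Hz (>= 8000).
#' @return an [audio_clip()] of duration `n_cycles * period` (+/- 1 sample).
#' @export
sonify <- function(samples, period, n_cycles = 9, sample_rate = 44100) {
  if (length(samples) < 2 || !all(is.finite(samples))) {
    stop("sonify: 'samples' must be a finite vector of length >= 2", call. = FALSE)
  }
  stopifnot(period > 0, n_cycles >= 1, sample_rate >= 8000)
  m <- round(period * sample_rate)          # output samples per cycle
  cyc <- resample_fft(samples, m)
  out <- rep(cyc, n_cycles)
  pk <- max(abs(out))
  if (pk > 0) out <- out * (10^(-1 / 20) / pk)  # -1 dBFS
  audio_clip(out, sample_rate, label = "SONIFIED")
}

# Band-limited periodic resampling of one cycle from length n to length m
# via zero-padded / truncated FFT. Real input, real output.
resample_fft <- function(x, m) {
  n <- length(x)
  if (m == n) return(x)
  X <- fft(x) / n
  Y <- complex(length.out = m)
  half <- min(n, m) %/% 2
  Y[1] <- X[1]
  if (half >= 1) {
    k <- seq_len(half)
    Y[1 + k] <- X[1 + k]
    Y[m + 1 - k] <- X[n + 1 - k]
    # split a shared Nyquist bin when downsampling to even length
    if (m < n && m %% 2 == 0) Y[m / 2 + 1] <- Re(Y[m / 2 + 1])
  }
  Re(fft(Y, inverse = TRUE))
}
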