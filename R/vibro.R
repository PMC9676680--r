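#' Build a locally reacting wall oscillator from a layer stack
#'
#' Each compliant wall patch is modeled as a per-unit-area mass-spring-damper
#' `m x'' + c x' + k x = p(t)`. The areal mass is `sum(rho_i h_i)`. The
#' effective stiffness comes from the fundamental bending mode of a composite
#' strip of the patch span: classical lamination gives the flexural rigidity
#' `D` about the stack's neutral axis (`E_i' = E_i / (1 - nu_i^2)`), and
#' `k = D (beta / a)^4` with `beta = pi` for simply supported edges (soft
#' tissue spanning the dehiscence, unclamped medial wall) or `beta = 4.730`
#' for clamped edges (the bony plate fused to the surrounding mastoid).
#' Adding a stiff outer layer always increases `D`, hence `k`.
#'
#' When `curvature_radius` is given, the hoop-membrane stiffness of the
#' curved conduit wall, `sum(E_i' h_i) / R^2`, is added: for thin soft
#' shells under pressure this membrane action, not flat-plate bending, is
#' the leading restoring force, and omitting it lets an unsupported vessel
#' wall move by unphysical amounts.
#'
#' @param layers ordered list of [material_layer()], outermost first; may be
#'   empty only when `rigid = TRUE`.
#' @param patch_span bending span of the patch in m (> 0).
#' @param damping_ratio dimensionless damping ratio (default 0.05).
#' @param edge `"simply_supported"` (default) or `"clamped"`.
#' @param rigid if `TRUE` the patch never moves (infinite stiffness).
#' @param curvature_radius transverse radius of the conduit wall in m
#'   (`NULL` for a flat strip: bending only).
#' @return object of class `wall_oscillator`: `areal_mass` (kg/m^2),
#'   `effective_stiffness` (Pa/m; `Inf` when rigid), `damping_ratio`,
#'   `flexural_rigidity` (Pa m^3), `resonance_hz`, `edge`, `rigid`.
#' @export
build_oscillator <- function(layers, patch_span, damping_ratio = 0.05,
                             edge = c("simply_supported", "clamped"),
                             rigid = FALSE, curvature_radius = NULL) {
  edge <- match.arg(edge)
  if (rigid) {
    return(structure(list(areal_mass = Inf, effective_stiffness = Inf,
                          damping_ratio = damping_ratio, flexural_rigidity = Inf,
                          resonance_hz = Inf, edge = edge, rigid = TRUE,
                          patch_span = patch_span),
                     class = "wall_oscillator"))
  }
  if (length(layers) < 1) {
    stop("build_oscillator: a non-rigid patch needs at least one layer", call. = FALSE)
  }
  if (!all(vapply(layers, inherits, logical(1), "material_layer"))) {
    stop("build_oscillator: 'layers' must be material_layer objects", call. = FALSE)
  }
  if (!is.finite(patch_span) || patch_span <= 0) {
    stop("build_oscillator: 'patch_span' must be > 0", call. = FALSE)
  }
  h <- vapply(layers, `[[`, numeric(1), "thickness") * 1e-3        # m
  rho <- vapply(layers, `[[`, numeric(1), "density")
  nu <- vapply(layers, `[[`, numeric(1), "poisson_ratio")
  E <- vapply(layers, `[[`, numeric(1), "youngs_modulus") * 1e6    # Pa
  Ep <- E / (1 - nu^2)
  m_areal <- sum(rho * h)
  ztop <- cumsum(c(0, h))
  zc <- (ztop[-length(ztop)] + ztop[-1]) / 2                       # layer centers
  zbar <- sum(Ep * h * zc) / sum(Ep * h)                           # neutral axis
  D <- sum(Ep * (h^3 / 12 + h * (zc - zbar)^2))
  beta <- if (edge == "clamped") 4.730040744862704 else pi
  k <- D * (beta / patch_span)^4
  if (!is.null(curvature_radius)) {
    if (!is.finite(curvature_radius) || curvature_radius <= 0) {
      stop("build_oscillator: 'curvature_radius' must be > 0", call. = FALSE)
    }
    k <- k + sum(Ep * h) / curvature_radius^2
  }
  structure(list(areal_mass = m_areal, effective_stiffness = k,
                 damping_ratio = damping_ratio, flexural_rigidity = D,
                 resonance_hz = sqrt(k / m_areal) / (2 * pi),
                 edge = edge, rigid = FALSE, patch_span = patch_span),
            class = "wall_oscillator")
}

#' @export
print.wall_oscillator <- function(x, ...) {
  if (x$rigid) {
    cat("<wall_oscillator> rigid (infinite stiffness)\n")
  } else {
    cat(sprintf("<wall_oscillator> m = %.4g kg/m^2, k = %.4g Pa/m (%s, span %.1f mm), f0 = %.0f Hz, zeta = %.2g\n",
                x$areal_mass, x$effective_stiffness, x$edge, 1000 * x$patch_span,
                x$resonance_hz, x$damping_ratio))
  }
  invisible(x)
}

#' Flow-forced displacement of a wall patch
#'
#' Steady-periodic response of the patch oscillator to a wall-pressure trace
#' spanning one pulsatory cycle: the trace is moved to the frequency domain,
#' multiplied by the receptance `H(w) = 1 / (k - m w^2 + i c w)` (with
#' `c = 2 zeta sqrt(k m)`), and transformed back. A static pressure therefore
#' maps to `p / k`, and a tone at the resonance to approximately
#' `p / (2 zeta k)`.
#'
#' @param oscillator a [build_oscillator()] result.
#' @param pressure_trace wall-normal forcing pressure in Pa, uniformly
#'   sampled over exactly one cycle.
#' @param period cycle duration in s.
#' @param name patch/probe label carried on the trace.
#' @param spectrum_window window used for the reported displacement spectrum
#'   (same convention as the acoustic bins).
#' @return object of class `displacement_trace`: `name`, `times` (s),
#'   `displacement` (m, signed wall-normal), `period`, `spectrum`
#'   (list `freq`, `amp`: one-sided complex amplitude per bin, m).
#' @export
forced_response <- function(oscillator, pressure_trace, period,
                            name = "patch", spectrum_window = "hann") {
  stopifnot(inherits(oscillator, "wall_oscillator"))
  if (!all(is.finite(pressure_trace))) {
    stop("forced_response: non-finite pressure trace", call. = FALSE)
  }
  m <- length(pressure_trace)
  if (m < 4) stop("forced_response: trace too short", call. = FALSE)
  times <- (seq_len(m) - 1) * period / m
  if (oscillator$rigid || !is.finite(oscillator$effective_stiffness)) {
    x <- rep(0, m)
  } else {
    P <- fft(pressure_trace) / m
    j <- 0:(m - 1)
    f_signed <- ifelse(j <= m / 2, j, j - m) / period
    w <- 2 * pi * f_signed
    k <- oscillator$effective_stiffness
    ma <- oscillator$areal_mass
    cc <- 2 * oscillator$damping_ratio * sqrt(k * ma)
    H <- 1 / (k - ma * w^2 + 1i * cc * w)
    x <- Re(fft(P * H, inverse = TRUE))
  }
  spec <- dft_onesided(x, period, window = spectrum_window)
  structure(list(name = name, times = times, displacement = x, period = period,
                 spectrum = spec),
            class = "displacement_trace")
}

#' @export
print.displacement_trace <- function(x, ...) {
  cat(sprintf("<displacement_trace> %s: %d samples over %.3f s, max |x| = %.3g m\n",
              x$name, length(x$displacement), x$period, max(abs(x$displacement))))
  invisible(x)
}

#' Displacement statistics over a cycle
#'
#' Median, signed cycle extrema (the "low/high" spread), RMS and maximum
#' absolute displacement of a trace.
#'
#' @param trace a [forced_response()] result.
#' @return object of class `displacement_stats`: `median`, `spread_low`,
#'   `spread_high`, `rms`, `max_abs` (m).
#' @export
displacement_stats <- function(trace) {
  stopifnot(inherits(trace, "displacement_trace"))
  x <- trace$displacement
  if (!length(x)) stop("displacement_stats: empty trace", call. = FALSE)
  structure(
    list(median = stats::median(x), spread_low = min(x), spread_high = max(x),
         rms = sqrt(mean(x^2)), max_abs = max(abs(x))),
    class = "displacement_stats"
  )
}

#' @export
print.displacement_stats <- function(x, ...) {
  cat(sprintf("<displacement_stats> median %.3g (%.3g/%.3g) m, rms %.3g m, max |x| %.3g m\n",
              x$median, x$spread_low, x$spread_high, x$rms, x$max_abs))
  invisible(x)
}

#' Vibroacoustic field radiated by vibrating wall patches
#'
#' Per-bin Helmholtz solves with vibrating-wall boundary data: each patch
#' imposes the normal-gradient condition `dp/dn = rho0 w^2 xi_hat` over its
#' boundary faces (piston motion of the patch, displacement positive
#' outward), rigid elsewhere per the problem's boundary set. The field is
#' linear in the displacement amplitudes.
#'
#' @param displacements named list of [forced_response()] traces, one per
#'   vibrating patch; names must match rows of `patch_table`.
#' @param patch_table data frame with `wall` (`"lateral"`/`"medial"`),
#'   `s_start`, `s_end` (m) per vibrating patch (e.g. the non-rigid rows of
#'   [assign_wall_composition()]).
#' @param problem an [acoustic_problem()] whose bins are a subset of the
#'   displacement spectrum bins.
#' @param mics optional microphone table (see [virtual_mics()]).
#' @return list with `fields` (an `acoustic_fields` object) and `spectra`
#'   (named list of [pressure_spectrum()], when `mics` is given).
#' @export
vibro_field <- function(displacements, patch_table, problem, mics = NULL) {
  stopifnot(inherits(problem, "acoustic_problem"))
  if (length(displacements) != nrow(patch_table)) {
    stop("vibro_field: one displacement trace per patch row is required", call. = FALSE)
  }
  mesh <- problem$mesh
  bins <- problem$freq_bins
  n <- length(problem$cell_area)
  rhs <- matrix(0 + 0i, n, length(bins))
  for (r in seq_len(nrow(patch_table))) {
    tr <- displacements[[r]]
    stopifnot(inherits(tr, "displacement_trace"))
    bin_ix <- match_bins(bins, tr$spectrum$freq)
    if (anyNA(bin_ix)) {
      stop("vibro_field: acoustic bins do not match the displacement spectrum bins",
           call. = FALSE)
    }
    xi <- tr$spectrum$amp[bin_ix]
    tag <- if (patch_table$wall[r] == "lateral") "lateral_wall" else "medial_wall"
    fl <- problem$face_len[[tag]]
    on_patch <- mesh$s_centers >= patch_table$s_start[r] &
      mesh$s_centers < patch_table$s_end[r]
    if (!any(on_patch)) next
    cells <- fl$cells[on_patch]
    len <- fl$len[on_patch]
    w2 <- (2 * pi * bins)^2
    # known boundary flux moves to the right-hand side with a minus sign
    rhs[cells, ] <- rhs[cells, ] -
      outer(len, problem$rho0 * w2) * matrix(xi, length(cells), length(bins),
                                             byrow = TRUE)
  }
  p_hat <- solve_helmholtz_bins(problem, rhs)
  fields <- structure(list(freq_bins = bins, p_hat = p_hat, problem = problem),
                      class = "acoustic_fields")
  out <- list(fields = fields, spectra = NULL)
  if (!is.null(mics)) out$spectra <- sample_microphones(fields, mics)
  out
}

# Match requested bins against available spectrum bins (relative tolerance).
match_bins <- function(wanted, have, rtol = 1e-6) {
  vapply(wanted, function(f) {
    d <- abs(have - f)
    i <- which.min(d)
    if (d[i] <= rtol * max(f, 1)) i else NA_integer_
  }, integer(1))
}

#' Oscillators for every patch of a wall composition
#'
#' Convenience wrapper: one [build_oscillator()] per row of the composition's
#' patch table, using the class layer stacks, the patch span, and clamped
#' edges for plate-backed stacks (bone fused to the surrounding mastoid)
#' versus simply supported edges for soft stacks.
#'
#' @param composition an [assign_wall_composition()] result.
#' @param damping_ratio damping ratio applied to all patches.
#' @param curvature_radius conduit wall curvature radius in m (typically the
#'   conduit half-width), adding hoop-membrane stiffness; `NULL` for flat
#'   strips.
#' @return list of `wall_oscillator`, one per patch row.
#' @export
composition_oscillators <- function(composition, damping_ratio = 0.05,
                                    curvature_radius = NULL) {
  stopifnot(inherits(composition, "wall_composition"))
  lapply(seq_len(nrow(composition$patches)), function(r) {
    cls <- composition$patches$class[r]
    if (cls == "RIGID") {
      build_oscillator(list(), composition$patches$span[r], damping_ratio,
                       rigid = TRUE)
    } else {
      build_oscillator(composition$layers[[cls]], composition$patches$span[r],
                       damping_ratio,
                       edge = if (cls == "PLATE_DURA_VESSEL") "clamped"
                              else "simply_supported",
                       curvature_radius = curvature_radius)
    }
  })
}
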