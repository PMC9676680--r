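#' Lighthill tensor of a velocity snapshot
#'
#' The incompressible low-Mach reduction of the Lighthill stress: `Tij = rho
#' ui uj`. The entropy term `(p - p0) - c^2 (rho - rho0)` vanishes for an
#' incompressible solve and the viscous quadrupole is negligible at venous
#' Reynolds numbers; its omission is recorded in the returned metadata.
#'
#' @param ux,uy Cartesian velocity components (equal-shape numeric arrays,
#'   m/s).
#' @param props a [fluid_props()].
#' @return list of class `lighthill_tensor`: `Txx`, `Txy`, `Tyy` (Pa, same
#'   shape as the inputs) and `viscous_term` = `"omitted"`.
#' @export
lighthill_tensor <- function(ux, uy, props = fluid_props()) {
  if (!all(is.finite(ux)) || !all(is.finite(uy))) {
    stop("lighthill_tensor: velocity field contains non-finite values", call. = FALSE)
  }
  if (!identical(dim(ux), dim(uy)) || length(ux) != length(uy)) {
    stop("lighthill_tensor: 'ux' and 'uy' must have identical shape", call. = FALSE)
  }
  rho <- props$density
  structure(list(Txx = rho * ux * ux, Txy = rho * ux * uy, Tyy = rho * uy * uy,
                 viscous_term = "omitted"),
            class = "lighthill_tensor")
}

#' Virtual microphones at the anatomical landmarks
#'
#' One probe per landmark (TS, TSJ, SSLO, JB, IJV), each at the center of
#' the vascular lumen (the conduit centerline).
#'
#' @param geometry a [build_geometry()] result.
#' @return data frame with `name`, `s` (arc length, m), `n` (= 0, m).
#' @export
virtual_mics <- function(geometry) {
  stopifnot(inherits(geometry, "vessel_geometry"))
  data.frame(name = names(geometry$landmarks), s = unname(geometry$landmarks),
             n = 0)
}

#' Define a frequency-domain acoustic problem on a mesh
#'
#' Finite-volume Helmholtz discretization on the structured centerline-fitted
#' mesh (typically coarser than the flow mesh). Boundary conditions per tag:
#' `"rigid"` (zero normal velocity; the natural boundary integral vanishes)
#' or `"nonreflecting"` (first-order impedance-matched closure `dp/dn = -i k
#' p`, used at the inlet/outlet so the truncated conduit does not ring with
#' spurious duct resonances). Vibrating-wall data enters per solve via
#' [vibro_field()].
#'
#' @param mesh a [generate_mesh()] result (the acoustic mesh).
#' @param freq_bins strictly increasing positive bin frequencies in Hz
#'   (default: multiples of `1/period` up to 1 kHz need a period, so here
#'   every integer Hz 1..1000; pipelines pass cycle-locked bins).
#' @param c0 reference sound speed in m/s (default 1540, soft tissue/blood).
#' @param rho0 reference density, kg/m^3.
#' @param bc named list of boundary conditions for tags `inlet`, `outlet`,
#'   `lateral_wall`, `medial_wall`.
#' @return object of class `acoustic_problem`.
#' @export
acoustic_problem <- function(mesh, freq_bins = 1:1000, c0 = 1540, rho0 = 1050,
                             bc = list(inlet = "nonreflecting",
                                       outlet = "nonreflecting",
                                       lateral_wall = "rigid",
                                       medial_wall = "rigid")) {
  stopifnot(inherits(mesh, "vessel_mesh"))
  if (any(freq_bins <= 0) || is.unsorted(freq_bins, strictly = TRUE)) {
    stop("acoustic_problem: freq_bins must be positive and strictly increasing",
         call. = FALSE)
  }
  tags <- c("inlet", "outlet", "lateral_wall", "medial_wall")
  for (tg in tags) {
    if (is.null(bc[[tg]]) || !bc[[tg]] %in% c("rigid", "nonreflecting")) {
      stop(sprintf("acoustic_problem: boundary '%s' needs exactly one condition ('rigid' or 'nonreflecting')", tg),
           call. = FALSE)
    }
  }
  ns <- mesh$ns; nn <- mesh$nn; ds <- mesh$ds; dn <- mesh$dn
  met <- flow_metrics(mesh)
  idx <- function(i, j) (j - 1L) * ns + i
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  dg <- numeric(ns * nn)
  if (ns > 1) {
    i <- rep(2:ns, nn); j <- rep(seq_len(nn), each = ns - 1)
    a <- dn / (met$h_u[cbind(i, j)] * ds)
    p1 <- idx(i - 1L, j); p2 <- idx(i, j)
    ii <- c(ii, p1, p2); jj <- c(jj, p2, p1); xx <- c(xx, a, a)
    add <- tapply(c(a, a), c(p1, p2), sum)
    dg[as.integer(names(add))] <- dg[as.integer(names(add))] - add
  }
  if (nn > 1) {
    i <- rep(seq_len(ns), nn - 1); j <- rep(2:nn, each = ns)
    a <- met$h_v[cbind(i, j)] * ds / dn
    p1 <- idx(i, j - 1L); p2 <- idx(i, j)
    ii <- c(ii, p1, p2); jj <- c(jj, p2, p1); xx <- c(xx, a, a)
    add <- tapply(c(a, a), c(p1, p2), sum)
    dg[as.integer(names(add))] <- dg[as.integer(names(add))] - add
  }
  L <- Matrix::sparseMatrix(i = c(ii, seq_len(ns * nn)), j = c(jj, seq_len(ns * nn)),
                            x = c(xx, dg), dims = c(ns * nn, ns * nn))
  area <- as.vector(met$h_c) * ds * dn
  # impedance accumulator: per cell, total nonreflecting face length
  imp <- numeric(ns * nn)
  face_len <- list(
    inlet = list(cells = idx(rep(1L, nn), seq_len(nn)), len = rep(dn, nn)),
    outlet = list(cells = idx(rep(ns, nn), seq_len(nn)), len = rep(dn, nn)),
    lateral_wall = list(cells = idx(seq_len(ns), rep(nn, ns)),
                        len = met$h_v[, nn + 1] * ds),
    medial_wall = list(cells = idx(seq_len(ns), rep(1L, ns)),
                       len = met$h_v[, 1] * ds)
  )
  for (tg in tags) {
    if (bc[[tg]] == "nonreflecting") {
      imp[face_len[[tg]]$cells] <- imp[face_len[[tg]]$cells] + face_len[[tg]]$len
    }
  }
  structure(
    list(mesh = mesh, freq_bins = freq_bins, c0 = c0, rho0 = rho0, bc = bc,
         laplacian = L, cell_area = area, impedance_len = imp,
         face_len = face_len),
    class = "acoustic_problem"
  )
}

#' @export
print.acoustic_problem <- function(x, ...) {
  cat(sprintf("<acoustic_problem> %d cells, %d bins [%.2f, %.2f] Hz, c0 = %g m/s\n",
              length(x$cell_area), length(x$freq_bins), min(x$freq_bins),
              max(x$freq_bins), x$c0))
  invisible(x)
}

# Bilinear interpolation from cell-centered values on one structured mesh to
# arbitrary (s, n) points. 'values' is ns x nn (or a vector); returns vector.
interp_cells <- function(mesh, values, s, n) {
  v <- matrix(values, mesh$ns, mesh$nn)
  sx <- pmin(pmax((s - mesh$s_centers[1]) / mesh$ds, 0), mesh$ns - 1)
  nx <- pmin(pmax((n - mesh$n_centers[1]) / mesh$dn, 0), mesh$nn - 1)
  i0 <- pmin(floor(sx), mesh$ns - 2); j0 <- pmin(floor(nx), mesh$nn - 2)
  fs <- sx - i0; fn <- nx - j0
  i0 <- i0 + 1L; j0 <- j0 + 1L
  (1 - fs) * (1 - fn) * v[cbind(i0, j0)] +
    fs * (1 - fn) * v[cbind(i0 + 1L, j0)] +
    (1 - fs) * fn * v[cbind(i0, j0 + 1L)] +
    fs * fn * v[cbind(i0 + 1L, j0 + 1L)]
}

# Conservative FV divergence of a cell-centered vector given in (s, n)
# components: interior face values by averaging, boundary fluxes zero.
# Returns the integrated divergence per cell (units of field x length).
flux_divergence <- function(mesh, met, g_s, g_n) {
  ns <- mesh$ns; nn <- mesh$nn
  Fs <- matrix(0, ns + 1, nn)                     # flux across s-faces
  if (ns > 1) Fs[2:ns, ] <- 0.5 * (g_s[1:(ns - 1), ] + g_s[2:ns, ]) * mesh$dn
  Fn <- matrix(0, ns, nn + 1)                     # flux across n-faces
  if (nn > 1) {
    Fn[, 2:nn] <- 0.5 * (g_n[, 1:(nn - 1)] + g_n[, 2:nn]) *
      met$h_v[, 2:nn] * mesh$ds
  }
  (Fs[2:(ns + 1), ] - Fs[1:ns, ]) + (Fn[, 2:(nn + 1)] - Fn[, 1:nn])
}

# Cartesian gradient of a cell-centered scalar on the curvilinear grid via
# chain rule: grad = T (1/h) d/ds + N d/dn. Central differences inside,
# one-sided at edges. 'phi_t' is the tangent angle per s station.
cart_grad <- function(mesh, f, met, phi_t) {
  ns <- mesh$ns; nn <- mesh$nn
  f <- matrix(f, ns, nn)
  dfs <- f
  if (ns >= 3) {
    dfs[2:(ns - 1), ] <- (f[3:ns, ] - f[1:(ns - 2), ]) / (2 * mesh$ds)
    dfs[1, ] <- (f[2, ] - f[1, ]) / mesh$ds
    dfs[ns, ] <- (f[ns, ] - f[ns - 1, ]) / mesh$ds
  } else dfs[] <- 0
  dfn <- f
  if (nn >= 3) {
    dfn[, 2:(nn - 1)] <- (f[, 3:nn] - f[, 1:(nn - 2)]) / (2 * mesh$dn)
    dfn[, 1] <- (f[, 2] - f[, 1]) / mesh$dn
    dfn[, nn] <- (f[, nn] - f[, nn - 1]) / mesh$dn
  } else dfn[] <- 0
  dfs_h <- dfs / met$h_c
  cosp <- matrix(cos(phi_t), ns, nn)
  sinp <- matrix(sin(phi_t), ns, nn)
  list(x = cosp * dfs_h - sinp * dfn,
       y = sinp * dfs_h + cosp * dfn)
}

#' Assemble per-frequency hydroacoustic source vectors
#'
#' Implements the volume term of the variational Lighthill analogy for an
#' incompressible flow: the double divergence of `Tij = rho ui uj` is
#' evaluated per acoustic cell at every stored time of the selected cycle
#' (velocities are projected from the flow mesh onto the acoustic mesh), and
#' the time series is mapped to the problem's frequency bins by a windowed
#' discrete Fourier transform (Hann by default; bin spacing is the inverse
#' cycle duration, about 1.17 Hz at 70 bpm).
#'
#' @param flow a [solve_transient()] result with full-rate storage covering
#'   `cycle_index` at >= twice the highest bin frequency.
#' @param problem an [acoustic_problem()].
#' @param cycle_index pulsatory cycle used (default 2).
#' @param window DFT window, `"hann"` or `"boxcar"`.
#' @return object of class `acoustic_sources`: `freq_bins`, `q_hat`
#'   (acoustic cells x bins, complex amplitude of the quadrupole source
#'   density, Pa/m^2), `problem`, `cycle_index`, `window`.
#' @export
assemble_sources <- function(flow, problem, cycle_index = 2, window = "hann") {
  stopifnot(inherits(flow, "flow_series"), inherits(problem, "acoustic_problem"))
  sel <- cycle_index_set(flow, cycle_index, full_only = TRUE)
  if (length(sel) < 8) {
    stop("assemble_sources: selected cycle has too few full-rate samples", call. = FALSE)
  }
  if (flow$store_rate < 2 * max(problem$freq_bins)) {
    stop(sprintf(
      "assemble_sources: flow storage rate %.0f Hz is below the Nyquist rate %.0f Hz for the requested bins",
      flow$store_rate, 2 * max(problem$freq_bins)), call. = FALSE)
  }
  amesh <- problem$mesh
  fmesh <- flow$mesh
  met <- flow_metrics(amesh)
  phi_a <- centerline_frame(amesh$geometry$segments, amesh$s_centers)$phi
  phi_f <- centerline_frame(fmesh$geometry$segments, fmesh$s_centers)$phi
  # acoustic cell centers in (s, n)
  sc <- rep(amesh$s_centers, amesh$nn)
  nc <- rep(amesh$n_centers, each = amesh$ns)
  m <- length(sel)
  Q <- matrix(0, length(problem$cell_area), m)
  cosf <- matrix(cos(phi_f), fmesh$ns, fmesh$nn)
  sinf <- matrix(sin(phi_f), fmesh$ns, fmesh$nn)
  for (kk in seq_len(m)) {
    tix <- sel[kk]
    us <- flow$u_s[, , tix]; un <- flow$u_n[, , tix]
    ux_f <- cosf * us - sinf * un
    uy_f <- sinf * us + cosf * un
    ux <- interp_cells(fmesh, ux_f, sc, nc)
    uy <- interp_cells(fmesh, uy_f, sc, nc)
    TT <- lighthill_tensor(matrix(ux, amesh$ns, amesh$nn),
                           matrix(uy, amesh$ns, amesh$nn), flow$props)
    gxx <- cart_grad(amesh, TT$Txx, met, phi_a)
    gxy <- cart_grad(amesh, TT$Txy, met, phi_a)
    gyy <- cart_grad(amesh, TT$Tyy, met, phi_a)
    g1 <- gxx$x + gxy$y     # div of row 1
    g2 <- gxy$x + gyy$y     # div of row 2
    # outer divergence in conservative flux form so the quadrupole source
    # integrates to exactly zero: boundary fluxes are dropped (for rigid
    # walls the surface term of the variational form vanishes; inlet/outlet
    # faces are non-physical truncation boundaries)
    cosm <- matrix(cos(phi_a), amesh$ns, amesh$nn)
    sinm <- matrix(sin(phi_a), amesh$ns, amesh$nn)
    g_s <- cosm * g1 + sinm * g2
    g_n <- -sinm * g1 + cosm * g2
    Q[, kk] <- as.vector(flux_divergence(amesh, met, g_s, g_n)) /
      matrix(problem$cell_area, amesh$ns, amesh$nn)
  }
  tloc <- flow$times[sel] - flow$times[sel][1]
  wts <- dft_weights(tloc, problem$freq_bins, window)
  q_hat <- dft_apply(Q, wts)
  structure(list(freq_bins = problem$freq_bins, q_hat = q_hat,
                 cycle_index = cycle_index, window = window,
                 viscous_term = "omitted"),
            class = "acoustic_sources")
}

#' @export
print.acoustic_sources <- function(x, ...) {
  cat(sprintf("<acoustic_sources> %d cells x %d bins (cycle %d, %s window)\n",
              nrow(x$q_hat), length(x$freq_bins), x$cycle_index, x$window))
  invisible(x)
}

# Per-bin Helmholtz solve. rhs_mat: cells x bins complex right-hand side of
# the FV-integrated system sum_f T_f (p_nb - p_c) + k^2 A_c p_c +
# i k |impedance faces| p_c = rhs. Returns cells x bins complex fields.
solve_helmholtz_bins <- function(problem, rhs_mat, freq_bins = problem$freq_bins) {
  L <- problem$laplacian
  A <- problem$cell_area
  Cimp <- problem$impedance_len
  n <- length(A)
  out <- matrix(NA_complex_, n, length(freq_bins))
  for (b in seq_along(freq_bins)) {
    k <- 2 * pi * freq_bins[b] / problem$c0
    Are <- L + Matrix::Diagonal(n, k^2 * A)
    # complex A = Are + i k Cimp -> real block system
    Aim <- Matrix::Diagonal(n, -k * Cimp)
    big <- rbind(cbind(Are, -Aim), cbind(Aim, Are))
    rhs <- c(Re(rhs_mat[, b]), Im(rhs_mat[, b]))
    sol <- tryCatch(Matrix::solve(big, rhs),
                    error = function(e) NULL)
    if (is.null(sol)) {
      warning(sprintf("solve_acoustic: singular system at bin %.2f Hz; bin skipped",
                      freq_bins[b]))
      next
    }
    sol <- as.vector(sol)
    out[, b] <- sol[seq_len(n)] + 1i * sol[n + seq_len(n)]
  }
  out
}

#' Solve the per-frequency acoustic field from hydroacoustic sources
#'
#' Per-bin Helmholtz solves of the variational Lighthill problem: `lap(p) +
#' k^2 p = -q_hat`, with rigid patches imposing a vanishing normal
#' derivative and nonreflecting patches the first-order impedance closure.
#' The solution is linear in the sources.
#'
#' @param problem an [acoustic_problem()].
#' @param sources an [assemble_sources()] result, or a complex matrix
#'   (cells x bins) of source densities `q_hat`.
#' @return object of class `acoustic_fields`: `freq_bins`, `p_hat`
#'   (cells x bins complex pressure amplitude, Pa), `problem`.
#' @export
solve_acoustic <- function(problem, sources) {
  stopifnot(inherits(problem, "acoustic_problem"))
  q_hat <- if (inherits(sources, "acoustic_sources")) sources$q_hat else sources
  if (nrow(q_hat) != length(problem$cell_area) ||
      ncol(q_hat) != length(problem$freq_bins)) {
    stop("solve_acoustic: source matrix does not match the problem's cells/bins",
         call. = FALSE)
  }
  rhs <- -q_hat * problem$cell_area
  p_hat <- solve_helmholtz_bins(problem, rhs)
  structure(list(freq_bins = problem$freq_bins, p_hat = p_hat, problem = problem),
            class = "acoustic_fields")
}

#' @export
print.acoustic_fields <- function(x, ...) {
  cat(sprintf("<acoustic_fields> %d cells x %d bins\n", nrow(x$p_hat),
              length(x$freq_bins)))
  invisible(x)
}

#' Sample acoustic fields at virtual microphones
#'
#' Bilinear interpolation of the per-bin complex pressure at each microphone
#' location, returning one [pressure_spectrum()] per microphone (SPL re 20
#' uPa).
#'
#' @param fields a [solve_acoustic()] / [vibro_field()] result.
#' @param mics data frame with `name`, `s`, `n` (see [virtual_mics()]).
#' @return named list of [pressure_spectrum()].
#' @export
sample_microphones <- function(fields, mics) {
  stopifnot(inherits(fields, "acoustic_fields"))
  mesh <- fields$problem$mesh
  L <- mesh$geometry$total_length
  w <- mesh$width
  if (any(mics$s < 0 | mics$s > L | abs(mics$n) > w / 2)) {
    stop("sample_microphones: microphone outside the flow domain", call. = FALSE)
  }
  out <- lapply(seq_len(nrow(mics)), function(r) {
    re <- vapply(seq_along(fields$freq_bins), function(b)
      interp_cells(mesh, Re(fields$p_hat[, b]), mics$s[r], mics$n[r]), numeric(1))
    im <- vapply(seq_along(fields$freq_bins), function(b)
      interp_cells(mesh, Im(fields$p_hat[, b]), mics$s[r], mics$n[r]), numeric(1))
    pressure_spectrum(fields$freq_bins, complex(real = re, imaginary = im),
                      mic = mics$name[r])
  })
  names(out) <- mics$name
  out
}
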