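#' Fluid properties
#'
#' @param density blood density in kg/m^3 (default 1050).
#' @param viscosity dynamic viscosity in Pa s (default 0.00345).
#' @return object of class `fluid_props`.
#' @export
fluid_props <- function(density = 1050, viscosity = 0.00345) {
  if (!is.finite(density) || density <= 0) {
    stop("fluid_props: density must be > 0", call. = FALSE)
  }
  if (!is.finite(viscosity) || viscosity <= 0) {
    stop("fluid_props: viscosity must be > 0", call. = FALSE)
  }
  structure(list(density = density, viscosity = viscosity), class = "fluid_props")
}

# Inlet velocity table for the Womersley profile: rows are the time steps of
# one cycle, columns the wall-normal stations. Each waveform harmonic k gets
# the exact oscillatory plane-channel shape 1 - cosh(g n)/cosh(g a) with
# g = sqrt(i w_k / nu), normalized to unit discrete cross-average; the DC
# harmonic is the parabola.
womersley_inlet_table <- function(inlet, n_c, width, nu, nsteps_cycle, dt) {
  m <- length(inlet$samples)
  ck <- fft(inlet$samples) / m
  Tp <- inlet$period
  a <- width / 2
  K <- min(m %/% 2 - 1L, 64L)
  t <- seq_len(nsteps_cycle) * dt
  par <- 1.5 * (1 - (n_c / a)^2)
  tab <- matrix(Re(ck[1]) * par / mean(par), nsteps_cycle, length(n_c),
                byrow = TRUE)
  for (k in seq_len(K)) {
    if (Mod(ck[k + 1]) < 1e-14 * max(Mod(ck))) next
    w <- 2 * pi * k / Tp
    g <- sqrt(complex(imaginary = w) / nu)
    phi <- if (Mod(g * a) > 200) rep(1 + 0i, length(n_c)) else
      1 - cosh(g * n_c) / cosh(g * a)
    phi <- phi / mean(phi)
    tab <- tab + 2 * Re(outer(exp(complex(imaginary = w * t)), ck[k + 1] * phi))
  }
  tab
}

# Metric arrays for the centerline-fitted staggered grid. h = 1 - kappa * n.
flow_metrics <- function(mesh) {
  ns <- mesh$ns; nn <- mesh$nn
  n_c <- mesh$n_centers
  n_nd <- seq(-mesh$width / 2, mesh$width / 2, length.out = nn + 1)
  list(
    h_u  = 1 - outer(mesh$kappa_nodes, n_c),        # (ns+1) x nn, u faces
    h_c  = 1 - outer(mesh$kappa_s, n_c),            # ns x nn, cell centers
    h_v  = 1 - outer(mesh$kappa_s, n_nd),           # ns x (nn+1), v faces
    h_un = 1 - outer(mesh$kappa_nodes, n_nd),       # (ns+1) x (nn+1), corners
    n_nodes = n_nd
  )
}

# Sparse pressure-Poisson operator (SPD, outlet Dirichlet) for the staggered
# curvilinear grid. Returns the Cholesky factor and the face coefficients.
build_poisson <- function(mesh, met) {
  ns <- mesh$ns; nn <- mesh$nn
  ds <- mesh$ds; dn <- mesh$dn
  idx <- function(i, j) (j - 1L) * ns + i
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  dg <- numeric(ns * nn)
  # s-direction interior faces (between (i-1,j) and (i,j), i = 2..ns)
  if (ns > 1) {
    i <- rep(2:ns, nn); j <- rep(seq_len(nn), each = ns - 1)
    a <- dn / (met$h_u[cbind(i, j)] * ds)
    p1 <- idx(i - 1L, j); p2 <- idx(i, j)
    ii <- c(ii, p1, p2); jj <- c(jj, p2, p1); xx <- c(xx, -a, -a)
    add <- tapply(c(a, a), c(p1, p2), sum)
    dg[as.integer(names(add))] <- dg[as.integer(names(add))] + add
  }
  # n-direction interior faces (between (i,j-1) and (i,j), j = 2..nn)
  if (nn > 1) {
    i <- rep(seq_len(ns), nn - 1); j <- rep(2:nn, each = ns)
    a <- met$h_v[cbind(i, j)] * ds / dn
    p1 <- idx(i, j - 1L); p2 <- idx(i, j)
    ii <- c(ii, p1, p2); jj <- c(jj, p2, p1); xx <- c(xx, -a, -a)
    add <- tapply(c(a, a), c(p1, p2), sum)
    dg[as.integer(names(add))] <- dg[as.integer(names(add))] + add
  }
  # outlet Dirichlet p = 0 on the s = L face (half-cell gradient)
  j <- seq_len(nn)
  a_out <- 2 * dn / (met$h_u[cbind(rep(ns + 1L, nn), j)] * ds)
  pout <- idx(rep(ns, nn), j)
  dg[pout] <- dg[pout] + a_out
  A <- Matrix::sparseMatrix(i = c(ii, seq_len(ns * nn)), j = c(jj, seq_len(ns * nn)),
                            x = c(xx, dg), dims = c(ns * nn, ns * nn))
  list(chol = Matrix::Cholesky(Matrix::forceSymmetric(A), LDL = FALSE, perm = TRUE),
       a_out = a_out)
}

#' Solve transient incompressible laminar flow
#'
#' Integrates the incompressible Navier-Stokes equations (conservation of
#' mass and momentum for a Newtonian fluid) on the structured
#' centerline-fitted mesh with a staggered-grid Chorin projection scheme:
#' explicit first-order upwind advection and explicit central diffusion,
#' followed by an exact discrete pressure projection (sparse Cholesky).
#' Boundary conditions: prescribed pulsatile velocity at the inlet (flat or
#' parabolic profile scaled by the waveform), zero pressure at the outlet,
#' no-slip rigid walls. Metric (curvature) terms of the bent conduit are
#' retained in continuity, advection and pressure; the viscous operator uses
#' the scalar Laplacian of each velocity component (exact for straight
#' channels).
#'
#' The time step is snapped to divide the waveform period exactly. Three
#' cycles are computed by default and the second is the conventional
#' presentation cycle (the first carries the start-up transient).
#'
#' @param mesh a [generate_mesh()] result.
#' @param inlet an [synthesize_waveform()] result.
#' @param props a [fluid_props()].
#' @param dt requested time step in s; must satisfy the advective CFL bound.
#' @param n_cycles number of pulsatory cycles (default 3).
#' @param profile inlet velocity profile: `"womersley"` (default; the exact
#'   oscillatory plane-channel profile per waveform harmonic, so the inlet
#'   carries no artificial adjustment region), `"parabolic"` or `"flat"`.
#' @param store_rate full-rate field storage in Hz for `store_cycles`
#'   (default 2000 Hz so the 0-1 kHz band is observable).
#' @param store_cycles integer cycle indices stored at full rate (default 2);
#'   `NULL` stores every cycle at full rate (memory heavy).
#' @param coarse_rate storage rate for all remaining times, Hz.
#' @param cfl_max maximum advective CFL number allowed for `dt`.
#' @param div_tol relative divergence tolerance for the projected field.
#' @return object of class `flow_series`: `mesh`, `times` (s), `cycle`
#'   (index per stored time), `full` (logical: stored at full rate), `dt`,
#'   `n_cycles`, cell-centered fields `u_s`, `u_n` (m/s) and `p` (Pa) as
#'   `ns x nn x n_times` arrays, `props`, `inlet`, `profile`,
#'   `store_rate`, `max_divergence`, and `cycle_l2` (relative L2 velocity
#'   difference between consecutive cycles).
#' @export
solve_transient <- function(mesh, inlet, props = fluid_props(), dt = 2.5e-4,
                            n_cycles = 3,
                            profile = c("womersley", "parabolic", "flat"),
                            store_rate = 2000, store_cycles = 2L,
                            coarse_rate = 200, cfl_max = 0.9, div_tol = 1e-8) {
  stopifnot(inherits(mesh, "vessel_mesh"), inherits(inlet, "inlet_waveform"),
            inherits(props, "fluid_props"))
  profile <- match.arg(profile)
  if (n_cycles < 1) stop("solve_transient: n_cycles must be >= 1", call. = FALSE)
  ns <- mesh$ns; nn <- mesh$nn; ds <- mesh$ds; dn <- mesh$dn
  rho <- props$density; mu <- props$viscosity; nu <- mu / rho

  # CFL precondition on the requested dt (parabolic profiles peak at 1.5x)
  u_ref <- inlet$peak_velocity * (if (profile == "parabolic") 1.5 else 1.0)
  u_ref <- max(u_ref, 1e-12)
  dt_cfl <- cfl_max * min(ds, dn) / u_ref
  if (dt > dt_cfl) {
    stop(sprintf(
      "solve_transient: dt = %.3g s violates the advective CFL bound; need dt <= %.3g s for this mesh and peak velocity",
      dt, dt_cfl), call. = FALSE)
  }
  dt_diff <- 1 / (4 * nu * (1 / ds^2 + 1 / dn^2))   # explicit 2-D bound w/ margin
  if (dt > dt_diff) {
    stop(sprintf(
      "solve_transient: dt = %.3g s violates the explicit diffusion bound %.3g s",
      dt, dt_diff), call. = FALSE)
  }
  period <- inlet$period
  nsteps_cycle <- max(2L, as.integer(round(period / dt)))
  dt <- period / nsteps_cycle            # snap dt to divide the period
  nsteps <- nsteps_cycle * n_cycles

  met <- flow_metrics(mesh)
  pois <- build_poisson(mesh, met)
  n_c <- mesh$n_centers
  if (profile == "womersley") {
    # exact oscillatory plane-channel profile per waveform harmonic; each
    # harmonic is normalized to unit discrete cross-average so the inlet
    # flux reproduces the waveform exactly
    inlet_table <- womersley_inlet_table(inlet, n_c, mesh$width, nu,
                                         nsteps_cycle, dt)
  } else {
    prof <- if (profile == "parabolic") 1.5 * (1 - (2 * n_c / mesh$width)^2)
            else rep(1, nn)
    prof <- prof / mean(prof)            # discrete mean exactly 1
  }

  dec_full <- max(1L, as.integer(round(1 / (store_rate * dt))))
  dec_coarse <- max(1L, as.integer(round(1 / (coarse_rate * dt))))
  if (is.null(store_cycles)) store_cycles <- seq_len(n_cycles)
  step_cycle <- rep(seq_len(n_cycles), each = nsteps_cycle)
  keep_full <- (seq_len(nsteps) %% dec_full == 0L) & (step_cycle %in% store_cycles)
  keep_coarse <- (seq_len(nsteps) %% dec_coarse == 0L) & !keep_full
  keep <- keep_full | keep_coarse
  nt <- sum(keep)
  u_s <- array(0, c(ns, nn, nt)); u_n <- array(0, c(ns, nn, nt))
  p_arr <- array(0, c(ns, nn, nt))
  times <- numeric(nt); cyc <- integer(nt); full <- logical(nt)

  u <- matrix(0, ns + 1, nn)   # streamwise velocity at s-faces
  v <- matrix(0, ns, nn + 1)   # normal velocity at n-faces
  p <- matrix(0, ns, nn)
  h_u <- met$h_u; h_c <- met$h_c; h_v <- met$h_v; h_un <- met$h_un
  kap_u <- matrix(mesh$kappa_nodes, ns + 1, nn)
  kap_v <- matrix(mesh$kappa_s, ns, nn + 1)
  inv_h_c <- 1 / h_c
  max_div <- 0
  cycle_end_u <- vector("list", n_cycles)
  ks <- 0L

  for (step in seq_len(nsteps)) {
    t_new <- step * dt
    u_in <- if (profile == "womersley") {
      inlet_table[(step - 1L) %% nsteps_cycle + 1L, ]
    } else {
      prof * sample_at(inlet, t_new)
    }

    ## --- advection + diffusion for u at interior s-faces (i = 2..ns) ---
    # padded u in n with no-slip ghosts: mirror for advection, quadratic
    # (second-order at the wall face) for diffusion
    up <- cbind(-u[, 1], u, -u[, nn])                       # (ns+1) x (nn+2)
    upv <- cbind(-2 * u[, 1] + u[, 2] / 3, u, -2 * u[, nn] + u[, nn - 1] / 3)
    iu <- 2:ns
    # v averaged to u-faces
    v_u <- 0.25 * (v[iu - 1, 1:nn] + v[iu - 1, 2:(nn + 1)] +
                   v[iu, 1:nn] + v[iu, 2:(nn + 1)])
    ucc <- u[iu, , drop = FALSE]
    dus_b <- (u[iu, ] - u[iu - 1, ]) / ds
    dus_f <- (u[iu + 1, ] - u[iu, ]) / ds
    dus <- ifelse(ucc > 0, dus_b, dus_f)
    dun_b <- (up[iu, 2:(nn + 1)] - up[iu, 1:nn]) / dn
    dun_f <- (up[iu, 3:(nn + 2)] - up[iu, 2:(nn + 1)]) / dn
    dun <- ifelse(v_u > 0, dun_b, dun_f)
    adv_u <- ucc / h_u[iu, ] * dus + v_u * dun - kap_u[iu, ] / h_u[iu, ] * ucc * v_u
    # scalar Laplacian in the metric
    lap_u <- (1 / h_u[iu, ]) * (
      (inv_h_c[iu, ] * (u[iu + 1, ] - u[iu, ]) -
         inv_h_c[iu - 1, ] * (u[iu, ] - u[iu - 1, ])) / ds^2 +
      (h_un[iu, 2:(nn + 1)] * (upv[iu, 3:(nn + 2)] - upv[iu, 2:(nn + 1)]) -
         h_un[iu, 1:nn] * (upv[iu, 2:(nn + 1)] - upv[iu, 1:nn])) / dn^2)
    u_star <- u
    u_star[iu, ] <- u[iu, ] + dt * (-adv_u + nu * lap_u)
    u_star[1, ] <- u_in
    u_star[ns + 1, ] <- u_star[ns, ]      # convective outflow, corrected below

    ## --- advection + diffusion for v at interior n-faces (j = 2..nn) ---
    jv <- 2:nn
    vp <- rbind(0, v, v[ns, ])             # inlet ghost v = 0, outlet replicate
    u_v <- 0.25 * (u[1:ns, jv - 1] + u[2:(ns + 1), jv - 1] +
                   u[1:ns, jv] + u[2:(ns + 1), jv])
    vcc <- v[, jv, drop = FALSE]
    dvs_b <- (vp[2:(ns + 1), jv] - vp[1:ns, jv]) / ds
    dvs_f <- (vp[3:(ns + 2), jv] - vp[2:(ns + 1), jv]) / ds
    dvs <- ifelse(u_v > 0, dvs_b, dvs_f)
    dvn_b <- (v[, jv] - v[, jv - 1]) / dn
    dvn_f <- (v[, jv + 1] - v[, jv]) / dn
    dvn <- ifelse(vcc > 0, dvn_b, dvn_f)
    adv_v <- u_v / h_v[, jv] * dvs + vcc * dvn + kap_v[, jv] / h_v[, jv] * u_v^2
    lap_v <- (1 / h_v[, jv]) * (
      ((vp[3:(ns + 2), jv] - vp[2:(ns + 1), jv]) / h_un[2:(ns + 1), jv] -
         (vp[2:(ns + 1), jv] - vp[1:ns, jv]) / h_un[1:ns, jv]) / ds^2 +
      (h_c[, jv] * (v[, jv + 1] - v[, jv]) -
         h_c[, jv - 1] * (v[, jv] - v[, jv - 1])) / dn^2)
    v_star <- v
    v_star[, jv] <- v[, jv] + dt * (-adv_v + nu * lap_v)
    v_star[, 1] <- 0; v_star[, nn + 1] <- 0

    ## --- pressure projection ---
    div_int <- (u_star[2:(ns + 1), ] - u_star[1:ns, ]) * dn +
      (h_v[, 2:(nn + 1)] * v_star[, 2:(nn + 1)] - h_v[, 1:nn] * v_star[, 1:nn]) * ds
    rhs <- -(rho / dt) * as.vector(div_int)
    p <- matrix(as.vector(Matrix::solve(pois$chol, rhs)), ns, nn)
    u <- u_star
    u[iu, ] <- u[iu, ] - (dt / rho) * (p[iu, ] - p[iu - 1, ]) / (h_u[iu, ] * ds)
    u[ns + 1, ] <- u[ns + 1, ] - (dt / rho) * (0 - p[ns, ]) * pois$a_out / dn
    v <- v_star
    v[, jv] <- v[, jv] - (dt / rho) * (p[, jv] - p[, jv - 1]) / dn

    if (!all(is.finite(u)) || !all(is.finite(v))) {
      stop("solve_transient: solver diverged (non-finite fields); reduce dt",
           call. = FALSE)
    }

    if (keep[step]) {
      ks <- ks + 1L
      u_s[, , ks] <- 0.5 * (u[1:ns, ] + u[2:(ns + 1), ])
      u_n[, , ks] <- 0.5 * (v[, 1:nn] + v[, 2:(nn + 1)])
      p_arr[, , ks] <- p
      times[ks] <- t_new
      cyc[ks] <- step_cycle[step]
      full[ks] <- keep_full[step]
      div_new <- (u[2:(ns + 1), ] - u[1:ns, ]) * dn +
        (h_v[, 2:(nn + 1)] * v[, 2:(nn + 1)] - h_v[, 1:nn] * v[, 1:nn]) * ds
      rel_div <- max(abs(div_new)) / max(u_ref * dn, 1e-30)
      max_div <- max(max_div, rel_div)
      if (rel_div > div_tol) {
        stop(sprintf("solve_transient: divergence residual %.3g above tolerance %.3g after projection",
                     rel_div, div_tol), call. = FALSE)
      }
    }
    if (step %% nsteps_cycle == 0L) {
      cycle_end_u[[step %/% nsteps_cycle]] <- list(u = u, v = v)
    }
  }

  cycle_l2 <- rep(NA_real_, max(0, n_cycles - 1))
  for (k in seq_len(max(0, n_cycles - 1))) {
    a <- cycle_end_u[[k]]; b <- cycle_end_u[[k + 1]]
    num <- sqrt(sum((b$u - a$u)^2) + sum((b$v - a$v)^2))
    den <- sqrt(sum(b$u^2) + sum(b$v^2))
    cycle_l2[k] <- if (den > 0) num / den else 0
  }

  structure(
    list(mesh = mesh, times = times[seq_len(ks)], cycle = cyc[seq_len(ks)],
         full = full[seq_len(ks)], dt = dt, n_cycles = n_cycles,
         u_s = u_s[, , seq_len(ks), drop = FALSE],
         u_n = u_n[, , seq_len(ks), drop = FALSE],
         p = p_arr[, , seq_len(ks), drop = FALSE],
         props = props, inlet = inlet, profile = profile,
         store_rate = 1 / (dec_full * dt),
         max_divergence = max_div, cycle_l2 = cycle_l2),
    class = "flow_series"
  )
}

#' @export
print.flow_series <- function(x, ...) {
  cat(sprintf("<flow_series> %d cycles, dt = %.3g s, %d stored times (%d full-rate @ %.0f Hz)\n",
              x$n_cycles, x$dt, length(x$times), sum(x$full), x$store_rate))
  cat(sprintf("  max |div| (rel): %.2g; cycle-to-cycle L2: %s\n", x$max_divergence,
              paste(sprintf("%.3g", x$cycle_l2), collapse = ", ")))
  invisible(x)
}

# Stored-time selector for one cycle (full-rate samples only by default).
cycle_index_set <- function(flow, cycle_index, full_only = TRUE) {
  sel <- flow$cycle == cycle_index
  if (full_only) sel <- sel & flow$full
  which(sel)
}

#' Hemodynamic summary over one pulsatory cycle
#'
#' @param flow a [solve_transient()] result.
#' @param cycle_index cycle to summarize (default 2, the presentation cycle).
#' @return object of class `hemodynamic_summary`: `avg_velocity` (space-time
#'   mean of |u| over the cycle, area weighted, m/s), `peak_velocity` (max
#'   over space and time), `wall_pressure_min` / `wall_pressure_max` (Pa, on
#'   both walls over the cycle), `avg_pressure_gradient` ((cycle-mean inlet
#'   pressure - outlet pressure) / centerline length, Pa/m).
#' @export
summarize_hemodynamics <- function(flow, cycle_index = 2) {
  stopifnot(inherits(flow, "flow_series"))
  sel <- cycle_index_set(flow, cycle_index, full_only = FALSE)
  if (!length(sel)) stop("summarize_hemodynamics: no stored times in that cycle",
                         call. = FALSE)
  mesh <- flow$mesh
  met <- flow_metrics(mesh)
  wgt <- met$h_c / mean(met$h_c)
  nn <- mesh$nn
  spd <- sqrt(flow$u_s[, , sel, drop = FALSE]^2 + flow$u_n[, , sel, drop = FALSE]^2)
  avg_v <- mean(apply(spd, 3, function(m) mean(m * wgt)))
  peak_v <- max(spd)
  pw <- flow$p[, c(1, nn), sel, drop = FALSE]   # wall-adjacent pressure
  # inlet-face pressure by linear extrapolation from the first two columns
  p_in <- 1.5 * flow$p[1, , sel, drop = FALSE] - 0.5 * flow$p[2, , sel, drop = FALSE]
  grad <- mean(p_in) / mesh$geometry$total_length
  structure(
    list(avg_velocity = avg_v, peak_velocity = peak_v,
         wall_pressure_min = min(pw), wall_pressure_max = max(pw),
         avg_pressure_gradient = grad, cycle_index = cycle_index),
    class = "hemodynamic_summary"
  )
}

#' @export
print.hemodynamic_summary <- function(x, ...) {
  cat(sprintf("<hemodynamic_summary> cycle %d\n", x$cycle_index))
  cat(sprintf("  avg velocity  %.4g m/s, peak %.4g m/s\n", x$avg_velocity, x$peak_velocity))
  cat(sprintf("  wall pressure [%.4g, %.4g] Pa\n", x$wall_pressure_min, x$wall_pressure_max))
  cat(sprintf("  avg pressure gradient %.4g Pa/m\n", x$avg_pressure_gradient))
  invisible(x)
}

#' Wall traction traces on a tagged boundary
#'
#' Extracts the fluid traction sigma_ij n_j (outward normal) along a tagged
#' boundary at every stored time: the normal component (-p + 2 mu du_n/dn)
#' and the tangential (shear) component (mu du_t/dn at walls). Wall-normal
#' gradients use one-sided quadratic differences honoring no-slip, so the
#' plane-Poiseuille shear is recovered exactly.
#'
#' @param flow a [solve_transient()] result.
#' @param boundary_tag one of `"lateral_wall"`, `"medial_wall"`, `"inlet"`,
#'   `"outlet"`.
#' @return list with `s` (arc-length stations, m; or `n` stations for
#'   inlet/outlet), `times` (s), `normal` and `shear` (stations x times
#'   matrices, Pa).
#' @export
boundary_stress <- function(flow, boundary_tag) {
  stopifnot(inherits(flow, "flow_series"))
  tags <- c("lateral_wall", "medial_wall", "inlet", "outlet")
  if (!boundary_tag %in% tags) {
    stop(sprintf("boundary_stress: unknown boundary tag '%s' (expected one of %s)",
                 boundary_tag, paste(tags, collapse = ", ")), call. = FALSE)
  }
  mesh <- flow$mesh
  mu <- flow$props$viscosity
  ns <- mesh$ns; nn <- mesh$nn; dn <- mesh$dn; ds <- mesh$ds
  nt <- length(flow$times)
  if (boundary_tag %in% c("lateral_wall", "medial_wall")) {
    j1 <- if (boundary_tag == "lateral_wall") nn else 1L
    j2 <- if (boundary_tag == "lateral_wall") nn - 1L else 2L
    ut1 <- flow$u_s[, j1, , drop = FALSE]; ut2 <- flow$u_s[, j2, , drop = FALSE]
    un1 <- flow$u_n[, j1, , drop = FALSE]; un2 <- flow$u_n[, j2, , drop = FALSE]
    p1 <- flow$p[, j1, , drop = FALSE]; p2 <- flow$p[, j2, , drop = FALSE]
    # one-sided quadratic derivatives at the wall from values at dn/2 and
    # 3dn/2 into the fluid (zeta = distance from the wall, no-slip at 0)
    dut_dz <- (9 * ut1 - ut2) / (3 * dn)
    dun_dz <- (9 * un1 - un2) / (3 * dn)
    pw <- 1.5 * p1 - 0.5 * p2
    # outward-normal derivative of the outward-normal velocity component:
    # +d(u_n)/dzeta on the medial wall, -d(u_n)/dzeta on the lateral wall
    sgn <- if (boundary_tag == "lateral_wall") -1 else 1
    normal <- matrix(-pw + 2 * mu * sgn * dun_dz, ns, nt)
    shear <- matrix(mu * dut_dz, ns, nt)   # magnitude = wall shear stress
    list(s = mesh$s_centers, times = flow$times, normal = normal, shear = shear)
  } else {
    i1 <- if (boundary_tag == "inlet") 1L else ns
    i2 <- if (boundary_tag == "inlet") 2L else ns - 1L
    us1 <- flow$u_s[i1, , , drop = FALSE]; us2 <- flow$u_s[i2, , , drop = FALSE]
    p1 <- flow$p[i1, , , drop = FALSE]; p2 <- flow$p[i2, , , drop = FALSE]
    pw <- 1.5 * p1 - 0.5 * p2
    duds <- (us1 - us2) / ds * (if (boundary_tag == "inlet") -1 else 1)
    normal <- matrix(-pw + 2 * mu * duds, nn, nt)
    un1 <- flow$u_n[i1, , , drop = FALSE]; un2 <- flow$u_n[i2, , , drop = FALSE]
    shear <- matrix(mu * (un1 - un2) / ds * (if (boundary_tag == "inlet") -1 else 1),
                    nn, nt)
    list(s = mesh$n_centers, times = flow$times, normal = normal, shear = shear)
  }
}

#' Inlet and outlet volumetric flux per stored time
#'
#' Per unit out-of-plane depth (2-D), m^2/s. With rigid walls and an
#' incompressible fluid the two balance at every stored instant.
#'
#' @param flow a [solve_transient()] result.
#' @return data frame with `time`, `inlet_flux`, `outlet_flux`.
#' @export
flow_flux_balance <- function(flow) {
  stopifnot(inherits(flow, "flow_series"))
  mesh <- flow$mesh
  dn <- mesh$dn
  nt <- length(flow$times)
  # reconstruct face fluxes from cell-centered storage is lossy; use the
  # divergence-free property instead: integrate u_s across the first and
  # last cell columns.
  q_in <- apply(flow$u_s[1, , , drop = FALSE], 3, sum) * dn
  q_out <- apply(flow$u_s[mesh$ns, , , drop = FALSE], 3, sum) * dn
  data.frame(time = flow$times, inlet_flux = q_in, outlet_flux = q_out)
}
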