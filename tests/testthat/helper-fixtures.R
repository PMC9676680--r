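# Shared fixtures. Expensive solves are computed once per test run and
# cached; everything is generated in code at test time.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, .fixture_cache)) assign(key, force(expr), .fixture_cache)
  get(key, .fixture_cache)
}

# A (numerically) straight channel: vanishingly small bends, no dehiscence.
straight_channel_geometry <- function(length = 0.02, width = 0.002) {
  build_geometry(list(
    total_length = length, width = width,
    l_ts = 0.4 * length, l_mid = 0.2 * length,
    bend_angle_1 = 1, bend_angle_2 = 1,
    bend_radius_1 = 10 * length, bend_radius_2 = 10 * length,
    dehiscence_length = 0
  ))
}

# An exactly straight channel (single zero-curvature segment), for fixtures
# where frame rotation must vanish identically (e.g. uniform-flow sources).
exact_straight_geometry <- function(length = 0.12, width = 0.007) {
  g <- straight_channel_geometry(length, width)
  g$segments <- list(list(type = "straight", len = length, kappa = 0,
                          s0 = 0, x0 = c(0, 0), phi0 = 0))
  fr <- venacoustics:::centerline_frame(g$segments, g$s)
  g$centerline <- fr$point
  g$kappa <- fr$kappa
  g
}

# Steady plane-Poiseuille reference solve (constant inlet, run to steady
# state), reused by flow oracles.
poiseuille_flow <- function() {
  cached("poiseuille", {
    g <- straight_channel_geometry(0.02, 0.002)
    m <- generate_mesh(g, 0.000125)
    wf <- synthesize_waveform(60, 0.02, 0.02)   # constant inlet
    list(geometry = g, mesh = m, waveform = wf,
         flow = solve_transient(m, wf, fluid_props(), dt = 5e-4, n_cycles = 2,
                                profile = "parabolic", store_rate = 50,
                                store_cycles = 2L, coarse_rate = 10))
  })
}

# Full default pipeline (the study conditions), reused by the qualitative
# invariants and the acceptance property suite.
default_pipeline <- function() {
  cached("pipeline", run_pt_pipeline(quiet = TRUE))
}

# Monopole Helmholtz solve in a large absorbing box vs the free-space 2-D
# Green's function.
monopole_case <- function() {
  cached("monopole", {
    g <- build_geometry(list(total_length = 2, width = 1, l_ts = 0.9,
                             l_mid = 0.2, bend_angle_1 = 1, bend_angle_2 = 1,
                             bend_radius_1 = 20, bend_radius_2 = 20,
                             dehiscence_length = 0))
    m <- generate_mesh(g, 0.01)
    f0 <- 500; c0 <- 340
    pr <- acoustic_problem(m, freq_bins = f0, c0 = c0,
                           bc = list(inlet = "nonreflecting",
                                     outlet = "nonreflecting",
                                     lateral_wall = "nonreflecting",
                                     medial_wall = "nonreflecting"))
    i0 <- which.min(abs(m$s_centers - 1.0))
    j0 <- which.min(abs(m$n_centers))
    q <- matrix(0 + 0i, length(pr$cell_area), 1)
    cellid <- (j0 - 1) * m$ns + i0
    q[cellid, 1] <- -1 / pr$cell_area[cellid]
    list(mesh = m, problem = pr, k = 2 * pi * f0 / c0,
         fields = solve_acoustic(pr, q))
  })
}

# A fabricated flow series on an exactly straight channel whose streamwise
# velocity oscillates at a single tone: u_s(s, n, t) = U(s, n) cos(2 pi f0 t).
# The period is chosen so 5 Hz bins are exact DFT harmonics (no leakage).
single_tone_flow <- function(f0 = 35, amp = 1) {
  g <- exact_straight_geometry(0.12, 0.007)
  m <- generate_mesh(g, 0.002)
  period <- 0.2
  rate <- 2000
  nt <- period * rate
  times <- seq_len(nt) / rate
  us <- array(0, c(m$ns, m$nn, nt))
  U <- amp * outer(sin(pi * m$s_centers / 0.12), rep(1, m$nn))
  for (k in seq_len(nt)) us[, , k] <- U * cos(2 * pi * f0 * times[k])
  structure(
    list(mesh = m, times = times, cycle = rep(1L, nt), full = rep(TRUE, nt),
         dt = 1 / rate, n_cycles = 1L, u_s = us,
         u_n = array(0, c(m$ns, m$nn, nt)), p = array(0, c(m$ns, m$nn, nt)),
         props = fluid_props(), inlet = NULL, profile = "fabricated",
         store_rate = rate, max_divergence = 0, cycle_l2 = numeric(0)),
    class = "flow_series")
}

# Hydrostatic rest state: zero velocity, uniform pressure P.
hydrostatic_flow <- function(P = 40) {
  g <- straight_channel_geometry(0.02, 0.002)
  m <- generate_mesh(g, 0.00025)
  nt <- 3L
  structure(
    list(mesh = m, times = (1:nt) / 100, cycle = rep(1L, nt),
         full = rep(TRUE, nt), dt = 0.01, n_cycles = 1L,
         u_s = array(0, c(m$ns, m$nn, nt)), u_n = array(0, c(m$ns, m$nn, nt)),
         p = array(P, c(m$ns, m$nn, nt)),
         props = fluid_props(), inlet = NULL, profile = "fabricated",
         store_rate = 100, max_divergence = 0, cycle_l2 = numeric(0)),
    class = "flow_series")
}
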