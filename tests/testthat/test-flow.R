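test_that("steady channel flow reproduces the plane-Poiseuille solution", {
  pf <- poiseuille_flow()
  m <- pf$mesh; fl <- pf$flow
  U <- 0.02; w <- 0.002; mu <- fl$props$viscosity
  nt <- length(fl$times)
  i_probe <- round(m$ns * 0.75)
  prof <- fl$u_s[i_probe, , nt]
  exact <- 1.5 * U * (1 - (2 * m$n_centers / w)^2)
  expect_lt(sqrt(sum((prof - exact)^2) / sum(exact^2)), 0.02)   # velocity profile
  s <- summarize_hemodynamics(fl, 2)
  expect_lt(abs(s$avg_pressure_gradient - 12 * mu * U / w^2) /
              (12 * mu * U / w^2), 0.02)                        # pressure gradient
  for (wall in c("medial_wall", "lateral_wall")) {
    bs <- boundary_stress(fl, wall)
    tau <- abs(bs$shear[i_probe, nt])
    expect_lt(abs(tau - 6 * mu * U / w) / (6 * mu * U / w), 0.03)  # wall shear
  }
})

test_that("inlet and outlet volumetric flux balance at every stored time", {
  pf <- poiseuille_flow()
  fb <- flow_flux_balance(pf$flow)
  expect_lt(max(abs(fb$inlet_flux - fb$outlet_flux) / abs(fb$inlet_flux)), 0.005)
  expect_lt(pf$flow$max_divergence, 1e-10)
})

test_that("zero inflow leaves the fields identically zero", {
  g <- straight_channel_geometry(0.01, 0.002)
  m <- generate_mesh(g, 0.00025)
  wf0 <- structure(list(period = 1, samples = rep(0, 64), sample_rate = 64,
                        mean_velocity = 0, peak_velocity = 0),
                   class = "inlet_waveform")
  fl <- solve_transient(m, wf0, fluid_props(), dt = 2e-3, n_cycles = 1,
                        store_rate = 20, store_cycles = 1L, coarse_rate = 10)
  expect_equal(max(abs(fl$u_s)), 0)
  expect_equal(max(abs(fl$u_n)), 0)
  expect_equal(max(abs(fl$p)), 0)
})

test_that("hydrostatic state returns pure normal traction -P", {
  P <- 40
  fl <- hydrostatic_flow(P)
  for (tag in c("medial_wall", "lateral_wall", "inlet", "outlet")) {
    bs <- boundary_stress(fl, tag)
    expect_equal(max(abs(bs$normal + P)), 0, tolerance = 1e-12)
    expect_equal(max(abs(bs$shear)), 0, tolerance = 1e-12)
  }
  expect_error(boundary_stress(fl, "roof"), "unknown boundary tag")
})

test_that("creeping-flow response is linear in the driving and the viscosity", {
  g <- straight_channel_geometry(0.01, 0.002)
  m <- generate_mesh(g, 0.0003)
  run <- function(U, visc) {
    wf <- synthesize_waveform(60, U, U)
    fl <- solve_transient(m, wf, fluid_props(viscosity = visc), dt = 1e-3,
                          n_cycles = 2, profile = "parabolic", store_rate = 20,
                          store_cycles = 2L, coarse_rate = 10)
    list(grad = summarize_hemodynamics(fl, 2)$avg_pressure_gradient,
         traction = boundary_stress(fl, "medial_wall"))
  }
  base <- run(0.002, 0.00345)
  dbl_u <- run(0.004, 0.00345)
  dbl_mu <- run(0.002, 0.0069)
  # scaling the state by 2 scales the traction by 2 (Stokes linearity)
  nt <- ncol(base$traction$shear)
  i_probe <- round(m$ns * 0.7)
  expect_lt(abs(dbl_u$traction$shear[i_probe, nt] /
                  base$traction$shear[i_probe, nt] - 2), 0.03 * 2)
  # doubling mu doubles the pressure gradient in the Stokes regime
  expect_lt(abs(dbl_mu$grad / base$grad - 2) / 2, 0.03)
})

test_that("time steps violating stability bounds are refused with the limit", {
  g <- straight_channel_geometry(0.02, 0.002)
  m <- generate_mesh(g, 0.000125)
  wf <- synthesize_waveform(60, 0.2, 0.6)
  expect_error(solve_transient(m, wf, fluid_props(), dt = 5e-3),
               "CFL bound")
  err <- tryCatch(solve_transient(m, wf, fluid_props(), dt = 5e-3),
                  error = function(e) conditionMessage(e))
  expect_match(err, "dt <= [0-9.e-]+")
  wf_slow <- synthesize_waveform(60, 0.001, 0.001)
  expect_error(solve_transient(m, wf_slow, fluid_props(), dt = 5e-2),
               "diffusion bound")
})

test_that("pulsatile flow settles to a quasi-periodic cycle by cycle three", {
  g <- straight_channel_geometry(0.02, 0.002)
  m <- generate_mesh(g, 0.00025)
  wf <- synthesize_waveform(70, 0.05, 0.15)
  fl <- solve_transient(m, wf, fluid_props(), dt = 1e-3, n_cycles = 3,
                        store_rate = 100, store_cycles = 2L, coarse_rate = 20)
  expect_lt(fl$cycle_l2[2], 0.02)   # cycle 3 vs cycle 2 below 2 %
})

test_that("an element-size ladder tabulates monotone relative errors", {
  g <- straight_channel_geometry(0.02, 0.002)
  sizes <- c(0.4e-3, 0.3e-3, 0.2e-3)
  wf <- synthesize_waveform(60, 0.02, 0.02)
  obs <- numeric(0); ncl <- numeric(0)
  for (es in sizes) {
    m <- generate_mesh(g, es)
    fl <- solve_transient(m, wf, fluid_props(), dt = 1e-3, n_cycles = 2,
                          profile = "parabolic", store_rate = 20,
                          store_cycles = 2L, coarse_rate = 10)
    # a discretization-sensitive observable for the independence protocol
    obs <- c(obs, summarize_hemodynamics(fl, 2)$avg_pressure_gradient)
    ncl <- c(ncl, nrow(m$cells))
  }
  tab <- grid_independence_table(sizes, ncl, obs)
  expect_true(all(diff(tab$n_cells) > 0))
  re <- tab$relative_error_pct[!is.na(tab$relative_error_pct)]
  expect_true(all(diff(re) < 0))        # refinement shrinks the error
  expect_true(all(re < 5))              # all levels within the 5 % criterion
})
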