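test_that("the Lighthill tensor reduces to rho u_i u_j", {
  rho <- fluid_props()$density
  # zero velocity -> zero tensor
  z <- matrix(0, 4, 3)
  T0 <- lighthill_tensor(z, z)
  expect_true(all(T0$Txx == 0) && all(T0$Txy == 0) && all(T0$Tyy == 0))
  # uniform u = (U, 0): constant Txx = rho U^2, all else zero
  U <- 0.4
  Tu <- lighthill_tensor(matrix(U, 5, 5), matrix(0, 5, 5))
  expect_equal(max(abs(Tu$Txx - rho * U^2)), 0, tolerance = 1e-12)
  expect_true(all(Tu$Txy == 0) && all(Tu$Tyy == 0))
  # shear field u = (y, 0): Txx = rho y^2, Txy = 0 at the sampled points
  y <- matrix(seq(-0.5, 0.5, length.out = 11), 1)
  Ts <- lighthill_tensor(y, 0 * y)
  expect_equal(Ts$Txx, rho * y^2)
  expect_true(all(Ts$Txy == 0))
  expect_equal(Ts$viscous_term, "omitted")
  expect_error(lighthill_tensor(matrix(NaN, 2, 2), matrix(0, 2, 2)),
               "non-finite")
})

test_that("spatially uniform flow produces no quadrupole source at any bin", {
  fl <- single_tone_flow(f0 = 35)
  fl$u_s[] <- 0.3                      # overwrite with a uniform field
  pr <- acoustic_problem(fl$mesh, freq_bins = seq(5, 100, by = 5))
  src <- assemble_sources(fl, pr, cycle_index = 1)
  expect_lt(max(Mod(src$q_hat)), 1e-8)
})

test_that("a single-tone flow sources only the doubled frequency", {
  f0 <- 35
  fl <- single_tone_flow(f0 = f0, amp = 1)
  bins <- seq(5, 200, by = 5)          # includes f0 and 2 f0
  pr <- acoustic_problem(fl$mesh, freq_bins = bins)
  src <- assemble_sources(fl, pr, cycle_index = 1, window = "boxcar")
  energy <- colSums(Mod(src$q_hat)^2)
  e2f <- energy[bins == 2 * f0]
  expect_gt(e2f / sum(energy), 0.999)  # rho u u is quadratic: DC + 2 f0 only
  # doubling the velocity quadruples the 2 f0 source amplitude
  fl4 <- single_tone_flow(f0 = f0, amp = 2)
  src4 <- assemble_sources(fl4, pr, cycle_index = 1, window = "boxcar")
  ratio <- Mod(src4$q_hat[, bins == 2 * f0]) / Mod(src$q_hat[, bins == 2 * f0])
  ratio <- ratio[is.finite(ratio)]
  expect_equal(median(ratio), 4, tolerance = 1e-6)
})

test_that("source assembly enforces the Nyquist precondition", {
  fl <- single_tone_flow()
  pr <- acoustic_problem(fl$mesh, freq_bins = c(100, 1500))
  expect_error(assemble_sources(fl, pr, cycle_index = 1), "Nyquist")
})

test_that("the Helmholtz solve is linear and vanishes without sources", {
  g <- straight_channel_geometry(0.12, 0.007)
  m <- generate_mesh(g, 0.002)
  pr <- acoustic_problem(m, freq_bins = c(50, 250))
  n <- length(pr$cell_area)
  z <- matrix(0 + 0i, n, 2)
  expect_equal(max(Mod(solve_acoustic(pr, z)$p_hat)), 0)
  set.seed(11)
  q1 <- matrix(complex(real = rnorm(2 * n), imaginary = rnorm(2 * n)), n, 2)
  q2 <- matrix(complex(real = rnorm(2 * n), imaginary = rnorm(2 * n)), n, 2)
  f1 <- solve_acoustic(pr, q1)$p_hat
  f2 <- solve_acoustic(pr, q2)$p_hat
  f12 <- solve_acoustic(pr, q1 + q2)$p_hat
  expect_equal(f12, f1 + f2, tolerance = 1e-9)
})

test_that("a point monopole reproduces the free-space Green's function decay", {
  mc <- monopole_case()
  r <- seq(0.08, 0.3, by = 0.02)
  p_num <- vapply(r, function(rr)
    venacoustics:::interp_cells(mc$mesh, Mod(mc$fields$p_hat[, 1]), 1 + rr, 0),
    numeric(1))
  p_an <- Mod(besselJ(mc$k * r, 0) - 1i * besselY(mc$k * r, 0)) / 4
  decay_err <- abs((p_num / p_num[1]) / (p_an / p_an[1]) - 1)
  expect_lt(max(decay_err), 0.05)
})

test_that("microphone sampling interpolates the field and validates locations", {
  g <- straight_channel_geometry(0.12, 0.007)
  m <- generate_mesh(g, 0.002)
  pr <- acoustic_problem(m, freq_bins = c(100))
  fields <- structure(list(freq_bins = pr$freq_bins,
                           p_hat = matrix(2e-5 * sqrt(2) + 0i,
                                          length(pr$cell_area), 1),
                           problem = pr),
                      class = "acoustic_fields")
  # uniform field of 2e-5 Pa rms -> 0 dB at the bin
  sp <- sample_microphones(fields, data.frame(name = "M", s = 0.05, n = 0))
  expect_equal(sp$M$spl, 0, tolerance = 1e-9)
  # a microphone exactly at a cell center returns the nodal value
  i0 <- 11; j0 <- 2
  vals <- matrix(seq_along(pr$cell_area) + 0i, m$ns, m$nn)
  fields$p_hat <- matrix(as.vector(vals), ncol = 1)
  sp2 <- sample_microphones(fields, data.frame(name = "M", s = m$s_centers[i0],
                                               n = m$n_centers[j0]))
  expect_equal(Mod(sp2$M$amplitude), Mod(vals[i0, j0]))
  expect_error(sample_microphones(fields, data.frame(name = "X", s = 1, n = 0)),
               "outside")
})

test_that("windowed spectra keep Parseval consistency for periodic signals", {
  Tp <- 0.8
  m <- 512
  t <- (seq_len(m) - 1) * Tp / m
  x <- 0.3 + 0.5 * cos(2 * pi * 3 * t / Tp) + 0.2 * sin(2 * pi * 7 * t / Tp)
  sp <- venacoustics:::dft_onesided(x, Tp, window = "boxcar")
  expect_equal(Mod(sp$amp[sp$freq == 3 / Tp]), 0.5, tolerance = 1e-10)
  expect_equal(Mod(sp$amp[sp$freq == 7 / Tp]), 0.2, tolerance = 1e-10)
  # mean square = DC^2 + sum of one-sided amplitude^2 / 2
  expect_equal(mean(x^2), 0.3^2 + sum(Mod(sp$amp)^2) / 2, tolerance = 1e-10)
})

test_that("landmark microphones mirror the elbow/straight amplitude contrast", {
  pp <- default_pipeline()
  rms <- vapply(pp$hydro$reports, `[[`, numeric(1), "rms_db")
  # the junction and bulb elbows (and the transverse sinus) ride above the
  # segments without sharp turns
  expect_gte(min(rms[c("TS", "TSJ", "JB")]), max(rms[c("SSLO", "IJV")]))
})
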