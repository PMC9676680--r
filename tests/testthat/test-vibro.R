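test_that("oscillator mass and stiffness follow the layer stack", {
  ly <- sigmoid_wall_layers()
  full <- build_oscillator(list(ly$plate, ly$dura, ly$vessel), 0.007)
  # areal mass is sum(rho_i h_i): 1868*1e-4 + 1174*7e-4 + 1050*3e-4
  expect_equal(full$areal_mass, 1.3236, tolerance = 1e-12)
  dv <- build_oscillator(list(ly$dura, ly$vessel), 0.007)
  expect_lt(dv$effective_stiffness, full$effective_stiffness)
  # adding a stiff outer layer never decreases the stiffness
  expect_gt(build_oscillator(list(ly$plate, ly$vessel), 0.007)$effective_stiffness,
            build_oscillator(list(ly$vessel), 0.007)$effective_stiffness)
  # hoop-membrane option adds sum(E' h)/R^2
  vr <- build_oscillator(list(ly$vessel), 0.007, curvature_radius = 0.0035)
  vf <- build_oscillator(list(ly$vessel), 0.007)
  Eh <- 1.26e6 / (1 - 0.3^2) * 3e-4
  expect_equal(vr$effective_stiffness - vf$effective_stiffness, Eh / 0.0035^2,
               tolerance = 1e-9)
  expect_error(build_oscillator(list(), 0.007), "at least one layer")
  expect_true(is.infinite(build_oscillator(list(), 0.007, rigid = TRUE)$effective_stiffness))
})

test_that("forced response matches the closed-form receptance", {
  ly <- sigmoid_wall_layers()
  osc <- build_oscillator(list(ly$dura, ly$vessel), 0.007, damping_ratio = 0.05)
  per <- 1; m <- 4096
  t <- (seq_len(m) - 1) * per / m
  k <- osc$effective_stiffness; ma <- osc$areal_mass
  # static load -> P / k
  tr <- forced_response(osc, rep(10, m), per)
  expect_equal(max(abs(tr$displacement)), 10 / k, tolerance = 1e-9)
  # tone far below resonance -> P / k within 2 %
  tr10 <- forced_response(osc, 5 * cos(2 * pi * 10 * t), per)
  expect_lt(abs(max(abs(tr10$displacement)) - 5 / k) / (5 / k), 0.02)
  # tone at resonance -> P / (2 zeta k) within 2 %
  f0 <- round(osc$resonance_hz)
  trr <- forced_response(osc, 5 * cos(2 * pi * f0 * t), per)
  expect_lt(abs(max(abs(trr$displacement)) - 5 / (2 * 0.05 * k)) /
              (5 / (2 * 0.05 * k)), 0.02)
  # rigid patches never move
  rig <- build_oscillator(list(), 0.007, rigid = TRUE)
  expect_equal(max(abs(forced_response(rig, 5 * cos(2 * pi * 10 * t),
                                       per)$displacement)), 0)
  expect_error(forced_response(osc, c(1, NA, 3, 4), per), "non-finite")
})

test_that("displacement statistics match closed forms", {
  per <- 1; m <- 1024
  t <- (seq_len(m) - 1) * per / m
  mk_trace <- function(x) structure(
    list(name = "t", times = t, displacement = x, period = per,
         spectrum = venacoustics:::dft_onesided(x, per)),
    class = "displacement_trace")
  st_c <- displacement_stats(mk_trace(rep(3e-9, m)))
  expect_equal(st_c$median, 3e-9)
  expect_equal(st_c$rms, 3e-9)
  expect_equal(c(st_c$spread_low, st_c$spread_high), c(3e-9, 3e-9))
  A <- 2e-8
  st_s <- displacement_stats(mk_trace(A * sin(2 * pi * 5 * t)))
  expect_equal(st_s$rms, A / sqrt(2), tolerance = 1e-3)
  expect_equal(st_s$max_abs, A, tolerance = 1e-6)
  expect_lte(st_s$spread_low, st_s$median)
  expect_lte(st_s$median, st_s$spread_high)
  # the reported displacement maxima ratio arithmetic
  expect_equal(round(7.0e-9 / 7.3e-10, 1), 9.6)
})

test_that("a duct wall piston radiates the plane-wave closed-form pressure", {
  g <- build_geometry(list(total_length = 1, width = 0.05, l_ts = 0.2,
                           l_mid = 0.1, bend_angle_1 = 1, bend_angle_2 = 1,
                           bend_radius_1 = 5, bend_radius_2 = 5,
                           dehiscence_length = 0))
  m <- generate_mesh(g, 0.005)
  f0 <- 500; c0 <- 340; rho0 <- 1.2; xi0 <- 1e-6
  pr <- acoustic_problem(m, freq_bins = f0, c0 = c0, rho0 = rho0)
  per <- 1 / f0; ms <- 64
  t <- (seq_len(ms) - 1) * per / ms
  x <- xi0 * cos(2 * pi * f0 * t)
  tr <- structure(list(name = "piston", times = t, displacement = x,
                       period = per,
                       spectrum = venacoustics:::dft_onesided(x, per,
                                                             window = "boxcar")),
                  class = "displacement_trace")
  patch <- data.frame(wall = "lateral", s_start = 0.45, s_end = 0.55)
  res <- vibro_field(list(tr), patch, pr,
                     mics = data.frame(name = "M", s = 0.8, n = 0))
  # compact piston of span a in a duct of width w with absorbing ends:
  # |p| = rho0 c0 w xi a / (2 w_duct)
  p_an <- rho0 * c0 * 2 * pi * f0 * xi0 * 0.1 / (2 * 0.05)
  expect_lt(abs(Mod(res$spectra$M$amplitude) / p_an - 1), 0.05)
  # doubling every displacement raises the level by 20 log10(2) dB
  tr2 <- tr; tr2$displacement <- 2 * x; tr2$spectrum$amp <- 2 * tr$spectrum$amp
  res2 <- vibro_field(list(tr2), patch, pr,
                      mics = data.frame(name = "M", s = 0.8, n = 0))
  expect_equal(res2$spectra$M$spl - res$spectra$M$spl, 20 * log10(2),
               tolerance = 1e-6)
  # zero displacement -> zero field
  tr0 <- tr; tr0$displacement <- 0 * x; tr0$spectrum$amp <- 0 * tr$spectrum$amp
  expect_equal(max(Mod(vibro_field(list(tr0), patch, pr)$fields$p_hat)), 0)
  # mismatched bins are refused
  pr2 <- acoustic_problem(m, freq_bins = 777)
  expect_error(vibro_field(list(tr), patch, pr2), "bins")
})

test_that("wall classes separate displacement by at least an order of magnitude", {
  pp <- default_pipeline()
  cm <- pp$vibro$class_max
  expect_gte(cm[["VESSEL_ONLY"]] / cm[["DURA_VESSEL"]], 10)
  expect_gte(cm[["DURA_VESSEL"]] / cm[["PLATE_DURA_VESSEL"]], 10)
})

test_that("vibroacoustic level and wall forcing decline from proximal to distal", {
  pp <- default_pipeline()
  rms <- vapply(pp$vibro$reports, `[[`, numeric(1), "rms_db")
  expect_gte(rms[["TS"]], rms[["IJV"]])
  # the medial wall patches themselves lose amplitude downstream
  med <- pp$vibro$vib_rows[pp$vibro$composition$patches$class[pp$vibro$vib_rows] ==
                             "VESSEL_ONLY"]
  mx <- vapply(med, function(r) max(abs(pp$vibro$traces[[r]]$displacement)),
               numeric(1))
  expect_true(all(diff(mx) < 0))
})

test_that("dehiscence displacement spectra are dominated by the lowest band", {
  pp <- default_pipeline()
  r_deh <- pp$vibro$vib_rows[pp$vibro$composition$patches$class[pp$vibro$vib_rows] ==
                               "DURA_VESSEL"]
  sp <- pp$vibro$traces[[r_deh]]$spectrum
  low <- max(Mod(sp$amp[sp$freq <= 20]))
  high <- max(Mod(sp$amp[sp$freq > 20]))
  expect_gt(low, high)
})
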