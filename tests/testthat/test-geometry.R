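test_that("default geometry carries five ordered landmarks and is deterministic", {
  g1 <- build_geometry()
  g2 <- build_geometry()
  expect_named(g1$landmarks, c("TS", "TSJ", "SSLO", "JB", "IJV"))
  expect_true(all(diff(g1$landmarks) > 0))
  expect_true(all(g1$landmarks > 0 & g1$landmarks < g1$total_length))
  expect_identical(g1$centerline, g2$centerline)
  expect_true(all(g1$radius_profile > 0))
  # the two elbows live at the TSJ and JB landmarks
  fr <- venacoustics:::centerline_frame(g1$segments,
                                        g1$landmarks[c("TSJ", "JB")])
  expect_true(all(abs(fr$kappa) > 0))
  fr2 <- venacoustics:::centerline_frame(g1$segments,
                                         g1$landmarks[c("TS", "SSLO", "IJV")])
  expect_true(all(fr2$kappa == 0))
})

test_that("degenerate and invalid geometry parameters are handled", {
  g0 <- build_geometry(list(dehiscence_length = 0))
  expect_length(g0$dehiscence_patch, 0)
  expect_error(build_geometry(list(width = -1)), "width")
  expect_error(build_geometry(list(bend_angle_1 = 190)), "bend_angle_1")
  expect_error(build_geometry(list(total_length = 0.01)), "total_length")
})

test_that("mesh refinement quadruples the cell count when halving element size", {
  g <- straight_channel_geometry(0.02, 0.004)
  m1 <- generate_mesh(g, 0.0005)
  m2 <- generate_mesh(g, 0.00025)
  ratio <- nrow(m2$cells) / nrow(m1$cells)
  expect_gte(ratio, 3.5)
  expect_lte(ratio, 4.5)
})

test_that("mesh area matches the analytic channel area and cells are sound", {
  g <- straight_channel_geometry(0.03, 0.003)
  m <- generate_mesh(g, 0.0003)
  expect_lt(abs(sum(mesh_cell_areas(m)) - 0.03 * 0.003) / (0.03 * 0.003), 0.01)
  expect_true(all(mesh_cell_areas(m) > 0))
  # boundary tags partition the boundary: every boundary edge tagged once
  bt <- m$boundary_tags
  expect_equal(nrow(bt), 2 * m$ns + 2 * m$nn)
  expect_equal(anyDuplicated(bt[, c("node1", "node2")]), 0L)
  expect_setequal(unique(bt$tag),
                  c("inlet", "outlet", "lateral_wall", "medial_wall"))
})

test_that("bent default mesh keeps cell quality above the angle floor", {
  m <- generate_mesh(build_geometry(), 0.0007)
  expect_gt(mesh_min_angle(m), 60)
})

test_that("mesh generation refuses impossible element sizes", {
  g <- straight_channel_geometry()
  expect_error(generate_mesh(g, 0.002), "half-width")
  expect_error(generate_mesh(g, -1), "element_size")
})

test_that("wall composition tiles the wall and honors the dehiscence", {
  g <- build_geometry()
  m <- generate_mesh(g, 0.0007)
  wc <- assign_wall_composition(m, g)
  p <- wc$patches
  for (side in c("lateral", "medial")) {
    rows <- p[p$wall == side, ]
    expect_equal(rows$s_start[1], 0)
    expect_equal(rows$s_end[nrow(rows)], g$total_length)
    expect_equal(rows$s_start[-1], rows$s_end[-nrow(rows)])  # no gaps/overlap
    expect_equal(sum(rows$span), g$total_length)
  }
  deh <- p[p$class == "DURA_VESSEL", ]
  expect_equal(nrow(deh), 1L)
  expect_equal(c(deh$s_start, deh$s_end), g$dehiscence_patch)
  expect_true(all(p$class[p$wall == "medial"] == "VESSEL_ONLY"))
  # layer stacks: outermost-first thicknesses 0.1 / 0.7 / 0.3 mm
  expect_equal(vapply(wc$layers$PLATE_DURA_VESSEL, `[[`, numeric(1), "thickness"),
               c(0.1, 0.7, 0.3))
})

test_that("zero-length dehiscence yields no DURA_VESSEL patch", {
  g <- build_geometry(list(dehiscence_length = 0))
  m <- generate_mesh(g, 0.0007)
  wc <- assign_wall_composition(m, g)
  expect_false("DURA_VESSEL" %in% wc$patches$class)
})

test_that("missing layer definitions are a configuration error", {
  g <- build_geometry()
  m <- generate_mesh(g, 0.0007)
  expect_error(assign_wall_composition(m, g, table2 = list(plate = NULL)),
               "missing layer")
})

test_that("material layers validate their physical ranges", {
  expect_error(material_layer("x", -1, 1000, 0.3, 10), "thickness")
  expect_error(material_layer("x", 1, 1000, 0.5, 10), "poisson")
  expect_s3_class(material_layer("x", 1, 1000, 0.3, 10), "material_layer")
})

test_that("meshes round-trip to legacy VTK text", {
  g <- straight_channel_geometry()
  m <- generate_mesh(g, 0.0005)
  path <- withr::local_tempfile(fileext = ".vtk")
  write_mesh_vtk(m, path, metadata = list(case = "channel"))
  txt <- readLines(path)
  expect_equal(txt[1], "# vtk DataFile Version 3.0")
  expect_true(any(grepl(sprintf("^POINTS %d double", nrow(m$nodes)), txt)))
  expect_equal(sum(txt == "9"), nrow(m$cells))
})
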