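#' Material layer description
#'
#' One layer of the wall composite (sigmoid plate, dura mater, or vascular
#' wall). Units follow the boundary-condition table convention: thickness in
#' mm, Young's modulus in MPa.
#'
#' @param name layer name.
#' @param thickness_mm layer thickness in mm (> 0).
#' @param density_kg_m3 density in kg/m^3 (> 0).
#' @param poisson_ratio Poisson's ratio in `[0, 0.5)`.
#' @param youngs_modulus_mpa Young's modulus in MPa (> 0).
#' @return object of class `material_layer`.
#' @export
material_layer <- function(name, thickness_mm, density_kg_m3, poisson_ratio,
                           youngs_modulus_mpa) {
  if (thickness_mm <= 0) stop("material_layer: thickness must be > 0", call. = FALSE)
  if (density_kg_m3 <= 0) stop("material_layer: density must be > 0", call. = FALSE)
  if (poisson_ratio < 0 || poisson_ratio >= 0.5) {
    stop("material_layer: poisson_ratio must lie in [0, 0.5)", call. = FALSE)
  }
  if (youngs_modulus_mpa <= 0) stop("material_layer: modulus must be > 0", call. = FALSE)
  structure(list(name = name, thickness = thickness_mm, density = density_kg_m3,
                 poisson_ratio = poisson_ratio, youngs_modulus = youngs_modulus_mpa),
            class = "material_layer")
}

#' Default wall-layer properties
#'
#' The layered boundary-condition set used throughout: a thin stiff sigmoid
#' (bony) plate, a thick compliant dura mater, and the vascular wall
#' (thickness mm / density kg/m^3 / Poisson / modulus MPa:
#' 0.1/1868/0.3/12000, 0.7/1174/0.45/70, 0.3/1050/0.3/1.26).
#'
#' @return named list of [material_layer()]: `plate`, `dura`, `vessel`.
#' @export
sigmoid_wall_layers <- function() {
  list(
    plate  = material_layer("sigmoid_plate", 0.1, 1868, 0.30, 12000),
    dura   = material_layer("dura_mater",    0.7, 1174, 0.45, 70.0),
    vessel = material_layer("vascular_wall", 0.3, 1050, 0.30, 1.26)
  )
}

#' Default geometry parameters
#'
#' Desk-scale stand-in for a transverse-sigmoid sinus: a 7 mm wide planar
#' conduit, 120 mm of centerline, with two 90-degree elbows (at the
#' transverse-sigmoid junction and the jugular bulb) and a 7 mm dehiscence
#' patch on the lateral wall just distal to the first elbow.
#'
#' @return named list of scalar parameters accepted by [build_geometry()].
#' @export
default_geometry_params <- function() {
  list(
    total_length = 0.120,      # m, centerline
    width = 0.007,             # m, conduit width (2 x half-width)
    l_ts = 0.040,              # m, straight transverse-sinus segment
    l_mid = 0.025,             # m, straight segment between the elbows
    bend_angle_1 = 90,         # deg, elbow at TSJ
    bend_angle_2 = 90,         # deg, elbow at JB
    bend_radius_1 = 0.012,     # m
    bend_radius_2 = 0.012,     # m
    dehiscence_length = 0.007, # m, arc-length extent of the dehiscence
    dehiscence_offset = 0.002, # m, gap between first elbow end and dehiscence
    seed = 1L
  )
}

#' Build the synthetic vessel geometry
#'
#' Constructs a parametric 2-D planar curved conduit standing in for the
#' patient-specific transverse-sigmoid sinus: straight segment (transverse
#' sinus, TS) - elbow (transverse-sigmoid junction, TSJ) - straight segment
#' (lower sigmoid curve, SSLO) - elbow (jugular bulb, JB) - straight outflow
#' (internal jugular vein, IJV). The two elbows turn in opposite directions
#' (an S shape). Arc length is measured from the inlet; intervals are
#' half-open `[start, end)`. Construction is deterministic: the same
#' parameters (and seed) always give the same centerline.
#'
#' @param params named list as in [default_geometry_params()]; missing
#'   entries take defaults.
#' @return object of class `vessel_geometry` with fields `centerline`
#'   (n x 2 matrix, m), `s` (arc length per point), `radius_profile`
#'   (half-width per point, m), `kappa` (signed centerline curvature per
#'   point, 1/m), `landmarks` (named vector TS/TSJ/SSLO/JB/IJV, m),
#'   `dehiscence_patch` (length-2, m, half-open), `total_length`,
#'   `width`, `segments`, `params`.
#' @export
build_geometry <- function(params = list()) {
  p <- utils::modifyList(default_geometry_params(), params)
  for (nm in c("total_length", "width", "l_ts", "l_mid",
               "bend_radius_1", "bend_radius_2", "dehiscence_length")) {
    if (!is.finite(p[[nm]]) || p[[nm]] < 0 ||
        (p[[nm]] == 0 && nm != "dehiscence_length")) {
      stop(sprintf("build_geometry: parameter '%s' must be positive", nm), call. = FALSE)
    }
  }
  for (nm in c("bend_angle_1", "bend_angle_2")) {
    if (!is.finite(p[[nm]]) || p[[nm]] <= 0 || p[[nm]] >= 180) {
      stop(sprintf("build_geometry: '%s' must lie in (0, 180) degrees", nm), call. = FALSE)
    }
  }
  for (nm in c("bend_radius_1", "bend_radius_2")) {
    if (p[[nm]] <= p$width / 2) {
      stop(sprintf("build_geometry: '%s' must exceed the conduit half-width", nm),
           call. = FALSE)
    }
  }
  arc1 <- p$bend_radius_1 * p$bend_angle_1 * pi / 180
  arc2 <- p$bend_radius_2 * p$bend_angle_2 * pi / 180
  l_ijv <- p$total_length - p$l_ts - arc1 - p$l_mid - arc2
  if (l_ijv <= 0) {
    stop("build_geometry: 'total_length' too short for the requested segments",
         call. = FALSE)
  }
  # segment table: straight / arc pieces with signed curvature
  segs <- list(
    list(type = "straight", len = p$l_ts, kappa = 0),
    list(type = "arc", len = arc1, kappa = +1 / p$bend_radius_1),
    list(type = "straight", len = p$l_mid, kappa = 0),
    list(type = "arc", len = arc2, kappa = -1 / p$bend_radius_2),
    list(type = "straight", len = l_ijv, kappa = 0)
  )
  s0 <- 0; x <- c(0, 0); phi <- 0
  for (i in seq_along(segs)) {
    segs[[i]]$s0 <- s0
    segs[[i]]$x0 <- x
    segs[[i]]$phi0 <- phi
    s0 <- s0 + segs[[i]]$len
    if (segs[[i]]$type == "straight") {
      x <- x + segs[[i]]$len * c(cos(phi), sin(phi))
    } else {
      k <- segs[[i]]$kappa
      dphi <- k * segs[[i]]$len
      # rotate about the arc center
      cen <- segs[[i]]$x0 + (1 / k) * c(-sin(phi), cos(phi))
      phi <- phi + dphi
      x <- cen - (1 / k) * c(-sin(phi), cos(phi))
    }
  }
  L <- p$total_length
  ends <- cumsum(vapply(segs, `[[`, numeric(1), "len"))
  landmarks <- c(
    TS   = p$l_ts / 2,
    TSJ  = p$l_ts + arc1 / 2,
    SSLO = ends[2] + p$l_mid / 2,
    JB   = ends[3] + arc2 / 2,
    IJV  = ends[4] + l_ijv / 2
  )
  d0 <- ends[2] + p$dehiscence_offset
  dehiscence <- if (p$dehiscence_length > 0) c(d0, d0 + p$dehiscence_length) else numeric(0)
  if (length(dehiscence) && dehiscence[2] > L) {
    stop("build_geometry: dehiscence patch extends beyond the conduit", call. = FALSE)
  }
  s_pts <- seq(0, L, length.out = 481)
  frames <- centerline_frame(segs, s_pts)
  structure(
    list(centerline = frames$point, s = s_pts,
         radius_profile = rep(p$width / 2, length(s_pts)),
         kappa = frames$kappa,
         landmarks = landmarks, dehiscence_patch = dehiscence,
         total_length = L, width = p$width, segments = segs, params = p),
    class = "vessel_geometry"
  )
}

#' @export
print.vessel_geometry <- function(x, ...) {
  cat(sprintf("<vessel_geometry> length %.1f mm, width %.1f mm\n",
              1000 * x$total_length, 1000 * x$width))
  cat("  landmarks (mm):",
      paste(sprintf("%s=%.1f", names(x$landmarks), 1000 * x$landmarks), collapse = ", "),
      "\n")
  if (length(x$dehiscence_patch)) {
    cat(sprintf("  dehiscence: [%.1f, %.1f) mm on the lateral wall\n",
                1000 * x$dehiscence_patch[1], 1000 * x$dehiscence_patch[2]))
  } else cat("  dehiscence: none\n")
  invisible(x)
}

# Evaluate centerline point, tangent angle and curvature at arc lengths s.
centerline_frame <- function(segs, s) {
  n <- length(s)
  pts <- matrix(0, n, 2)
  phi <- numeric(n)
  kap <- numeric(n)
  s0s <- vapply(segs, `[[`, numeric(1), "s0")
  lens <- vapply(segs, `[[`, numeric(1), "len")
  idx <- findInterval(pmin(pmax(s, 0), sum(lens) - 1e-12), s0s)
  for (i in seq_len(n)) {
    sg <- segs[[idx[i]]]
    ds <- s[i] - sg$s0
    if (sg$type == "straight") {
      pts[i, ] <- sg$x0 + ds * c(cos(sg$phi0), sin(sg$phi0))
      phi[i] <- sg$phi0
      kap[i] <- 0
    } else {
      k <- sg$kappa
      cen <- sg$x0 + (1 / k) * c(-sin(sg$phi0), cos(sg$phi0))
      a <- sg$phi0 + k * ds
      pts[i, ] <- cen - (1 / k) * c(-sin(a), cos(a))
      phi[i] <- a
      kap[i] <- k
    }
  }
  list(point = pts, phi = phi, kappa = kap)
}

# Physical location of (s, n) in centerline-fitted coordinates.
map_sn <- function(geometry, s, n) {
  fr <- centerline_frame(geometry$segments, s)
  nx <- -sin(fr$phi); ny <- cos(fr$phi)
  cbind(fr$point[, 1] + n * nx, fr$point[, 2] + n * ny)
}

#' Generate a structured quadrilateral mesh on a vessel geometry
#'
#' Maps a structured grid along the centerline: `ns x nn` quadrilateral cells
#' in centerline-fitted coordinates (arc length s, wall-normal n). Boundary
#' edges are tagged `inlet` (s = 0), `outlet` (s = L), `lateral_wall`
#' (n = +w/2, the temporal-bone side carrying the dehiscence) and
#' `medial_wall` (n = -w/2, the brain side).
#'
#' @param geometry a [build_geometry()] result (constant radius profile).
#' @param element_size target cell edge in m; must be positive and smaller
#'   than the minimum conduit half-width.
#' @return object of class `vessel_mesh`: `nodes` ((ns+1)(nn+1) x 2 m),
#'   `cells` (ns*nn x 4 node indices, counter-clockwise), `boundary_tags`
#'   (data frame: node1, node2, tag), `element_size`, plus the structured
#'   metadata the solvers use (`ns`, `nn`, `ds`, `dn`, `s_centers`,
#'   `n_centers`, `kappa_s` at cell-center stations, `width`, `geometry`).
#' @export
generate_mesh <- function(geometry, element_size) {
  stopifnot(inherits(geometry, "vessel_geometry"))
  rmin <- min(geometry$radius_profile)
  if (!is.finite(element_size) || element_size <= 0) {
    stop("generate_mesh: 'element_size' must be > 0", call. = FALSE)
  }
  if (element_size >= rmin) {
    stop(sprintf(
      "generate_mesh: element_size (%.3g m) must be smaller than the minimum conduit half-width (%.3g m)",
      element_size, rmin), call. = FALSE)
  }
  if (diff(range(geometry$radius_profile)) > 1e-9 * rmin) {
    stop("generate_mesh: only constant-radius conduits are meshed", call. = FALSE)
  }
  L <- geometry$total_length
  w <- geometry$width
  ns <- max(4L, as.integer(round(L / element_size)))
  nn <- max(4L, as.integer(round(w / element_size)))
  ds <- L / ns
  dn <- w / nn
  s_nodes <- seq(0, L, length.out = ns + 1)
  n_nodes <- seq(-w / 2, w / 2, length.out = nn + 1)
  nodes <- matrix(0, (ns + 1) * (nn + 1), 2)
  for (j in seq_len(nn + 1)) {
    rows <- (j - 1) * (ns + 1) + seq_len(ns + 1)
    nodes[rows, ] <- map_sn(geometry, s_nodes, n_nodes[j])
  }
  nid <- function(i, j) (j - 1L) * (ns + 1L) + i   # i along s, j along n
  ii <- rep(seq_len(ns), nn)
  jj <- rep(seq_len(nn), each = ns)
  cells <- cbind(nid(ii, jj), nid(ii + 1L, jj), nid(ii + 1L, jj + 1L), nid(ii, jj + 1L))
  bt <- rbind(
    data.frame(node1 = nid(1L, seq_len(nn)), node2 = nid(1L, seq_len(nn) + 1L),
               tag = "inlet"),
    data.frame(node1 = nid(ns + 1L, seq_len(nn)), node2 = nid(ns + 1L, seq_len(nn) + 1L),
               tag = "outlet"),
    data.frame(node1 = nid(seq_len(ns), nn + 1L), node2 = nid(seq_len(ns) + 1L, nn + 1L),
               tag = "lateral_wall"),
    data.frame(node1 = nid(seq_len(ns), 1L), node2 = nid(seq_len(ns) + 1L, 1L),
               tag = "medial_wall")
  )
  s_centers <- (seq_len(ns) - 0.5) * ds
  kf <- centerline_frame(geometry$segments, s_centers)
  kfn <- centerline_frame(geometry$segments, s_nodes)
  structure(
    list(nodes = nodes, cells = cells, boundary_tags = bt,
         element_size = element_size,
         ns = ns, nn = nn, ds = ds, dn = dn,
         s_centers = s_centers,
         n_centers = (seq_len(nn) - 0.5) * dn - w / 2,
         kappa_s = kf$kappa, kappa_nodes = kfn$kappa,
         width = w, geometry = geometry),
    class = "vessel_mesh"
  )
}

#' @export
print.vessel_mesh <- function(x, ...) {
  cat(sprintf("<vessel_mesh> %d x %d cells (%d), element size %.2f mm\n",
              x$ns, x$nn, nrow(x$cells), 1000 * x$element_size))
  invisible(x)
}

#' Cell areas of a mesh (shoelace formula)
#'
#' @param mesh a [generate_mesh()] result.
#' @return numeric vector of cell areas in m^2.
#' @export
mesh_cell_areas <- function(mesh) {
  v <- mesh$nodes
  c4 <- mesh$cells
  x <- matrix(v[c4, 1], ncol = 4)
  y <- matrix(v[c4, 2], ncol = 4)
  0.5 * abs(
    x[, 1] * y[, 2] - x[, 2] * y[, 1] +
    x[, 2] * y[, 3] - x[, 3] * y[, 2] +
    x[, 3] * y[, 4] - x[, 4] * y[, 3] +
    x[, 4] * y[, 1] - x[, 1] * y[, 4]
  )
}

#' Minimum interior angle across mesh cells
#'
#' Mesh-quality measure; structured bent conduits keep this well above 30
#' degrees at the default bend radii.
#'
#' @param mesh a [generate_mesh()] result.
#' @return smallest interior angle in degrees.
#' @export
mesh_min_angle <- function(mesh) {
  v <- mesh$nodes
  c4 <- mesh$cells
  amin <- 180
  for (k in 1:4) {
    a <- c4[, k]
    b <- c4[, (k %% 4) + 1]
    d <- c4[, ((k + 2) %% 4) + 1]
    u1 <- v[b, , drop = FALSE] - v[a, , drop = FALSE]
    u2 <- v[d, , drop = FALSE] - v[a, , drop = FALSE]
    ct <- rowSums(u1 * u2) / (sqrt(rowSums(u1^2)) * sqrt(rowSums(u2^2)))
    amin <- min(amin, acos(pmin(pmax(ct, -1), 1)) * 180 / pi)
  }
  amin
}

#' Assign the layered wall composition
#'
#' Partitions the full wall boundary (lateral + medial) into patch classes:
#' the dehiscence interval gets `DURA_VESSEL` (plate absent), the flanking
#' lateral wall gets `PLATE_DURA_VESSEL` windows of `flank_length` on each
#' side (or `RIGID` if `flank_class = "RIGID"`), the rest of the lateral wall
#' is `RIGID` (vascular wall leaning against temporal bone), and the medial
#' (brain-side) wall is `VESSEL_ONLY`, split into `n_medial_patches` equal
#' spans so each carries its own oscillator.
#'
#' @param mesh a [generate_mesh()] result.
#' @param geometry the matching [build_geometry()] result.
#' @param table2 named list with [material_layer()] entries `plate`, `dura`,
#'   `vessel` (see [sigmoid_wall_layers()]).
#' @param flank_length lateral compliant window on each side of the
#'   dehiscence, m.
#' @param flank_class `"PLATE_DURA_VESSEL"` (default) or `"RIGID"`.
#' @param n_medial_patches number of equal medial patches.
#' @return object of class `wall_composition`: `patches` (data frame: wall,
#'   s_start, s_end [half-open, m], class, span) and `layers` (per class,
#'   ordered outermost first).
#' @export
assign_wall_composition <- function(mesh, geometry, table2 = sigmoid_wall_layers(),
                                    flank_length = 0.007,
                                    flank_class = c("PLATE_DURA_VESSEL", "RIGID"),
                                    n_medial_patches = 8) {
  stopifnot(inherits(mesh, "vessel_mesh"), inherits(geometry, "vessel_geometry"))
  flank_class <- match.arg(flank_class)
  for (nm in c("plate", "dura", "vessel")) {
    if (is.null(table2[[nm]]) || !inherits(table2[[nm]], "material_layer")) {
      stop(sprintf("assign_wall_composition: 'table2' is missing layer '%s'", nm),
           call. = FALSE)
    }
  }
  L <- geometry$total_length
  deh <- geometry$dehiscence_patch
  lat <- if (length(deh)) {
    f0 <- max(0, deh[1] - flank_length)
    f1 <- min(L, deh[2] + flank_length)
    brk <- unique(c(0, f0, deh[1], deh[2], f1, L))
    cls <- character(length(brk) - 1)
    for (i in seq_along(cls)) {
      mid <- (brk[i] + brk[i + 1]) / 2
      cls[i] <- if (mid >= deh[1] && mid < deh[2]) "DURA_VESSEL"
      else if (mid >= f0 && mid < f1) flank_class
      else "RIGID"
    }
    data.frame(wall = "lateral", s_start = brk[-length(brk)], s_end = brk[-1],
               class = cls)
  } else {
    data.frame(wall = "lateral", s_start = 0, s_end = L, class = "RIGID")
  }
  mb <- seq(0, L, length.out = n_medial_patches + 1)
  med <- data.frame(wall = "medial", s_start = mb[-length(mb)], s_end = mb[-1],
                    class = "VESSEL_ONLY")
  patches <- rbind(lat, med)
  patches <- patches[patches$s_end > patches$s_start, ]
  patches$span <- patches$s_end - patches$s_start
  rownames(patches) <- NULL
  layers <- list(
    RIGID = list(),
    PLATE_DURA_VESSEL = list(table2$plate, table2$dura, table2$vessel),
    DURA_VESSEL = list(table2$dura, table2$vessel),
    VESSEL_ONLY = list(table2$vessel)
  )
  structure(list(patches = patches, layers = layers),
            class = "wall_composition")
}

#' @export
print.wall_composition <- function(x, ...) {
  cat("<wall_composition>\n")
  print(x$patches)
  invisible(x)
}

#' Write a mesh as legacy ASCII VTK (unstructured quads)
#'
#' @param mesh a [generate_mesh()] result.
#' @param path output `.vtk` path.
#' @param metadata optional named list echoed as a JSON comment in the header.
#' @return `path`, invisibly.
#' @export
write_mesh_vtk <- function(mesh, path, metadata = NULL) {
  stopifnot(inherits(mesh, "vessel_mesh"))
  np <- nrow(mesh$nodes)
  nc <- nrow(mesh$cells)
  hdr_note <- if (is.null(metadata)) "venacoustics mesh" else
    substr(jsonlite::toJSON(metadata, auto_unbox = TRUE), 1, 255)
  lines <- c(
    "# vtk DataFile Version 3.0",
    hdr_note,
    "ASCII",
    "DATASET UNSTRUCTURED_GRID",
    sprintf("POINTS %d double", np),
    sprintf("%.9g %.9g 0", mesh$nodes[, 1], mesh$nodes[, 2]),
    sprintf("CELLS %d %d", nc, nc * 5),
    sprintf("4 %d %d %d %d", mesh$cells[, 1] - 1L, mesh$cells[, 2] - 1L,
            mesh$cells[, 3] - 1L, mesh$cells[, 4] - 1L),
    sprintf("CELL_TYPES %d", nc),
    rep("9", nc)   # VTK_QUAD
  )
  writeLines(lines, path)
  invisible(path)
}
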