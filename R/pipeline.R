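#' Default pipeline configuration
#'
#' Study conditions of the desk-scale run: the default synthetic geometry,
#' a 70 bpm inlet calibrated to the reported field-average mean/peak
#' velocities (0.198 / 0.745 m/s), blood at 1050 kg/m^3 and 3.45 mPa s,
#' 0.35 mm flow cells (~7k) with a 0.7 mm acoustic mesh, dt = 0.25 ms for
#' three cycles with the second analyzed, frequency bins at the inverse
#' cycle duration up to 1 kHz, and the 20-1000 Hz reporting band.
#'
#' @return named list of configuration entries for [run_pt_pipeline()].
#' @export
default_pipeline_config <- function() {
  list(
    geometry = default_geometry_params(),
    element_size_flow = 0.35e-3,
    element_size_acoustic = 0.7e-3,
    heart_rate_bpm = 70,
    mean_velocity = 0.198,
    peak_velocity = 0.745,
    density = 1050,
    viscosity = 0.00345,
    dt = 2.5e-4,
    n_cycles = 3,
    cycle_index = 2,
    f_max = 1000,
    c0 = 1540,
    rho0 = 1050,
    damping_ratio = 0.05,
    band = c(20, 1000),
    waveform_seed = 1L
  )
}

#' Run the full pulsatile-tinnitus simulation pipeline
#'
#' One call for the whole desk-scale study: synthetic geometry and mesh,
#' pulsatile inlet, transient incompressible flow, hydroacoustic (Lighthill)
#' sources and per-frequency fields, layered-wall forced vibration and the
#' radiated vibroacoustic field, with band-limited dB/dBA reports at the
#' five landmark microphones and displacement statistics per wall patch.
#'
#' @param config named list overriding entries of
#'   [default_pipeline_config()].
#' @param out_dir optional directory: writes the mesh (VTK), waveform (CSV),
#'   microphone spectra (CSV), and a JSON results summary.
#' @param quiet suppress progress messages.
#' @return list of class `pt_pipeline` with components `config`, `geometry`,
#'   `mesh`, `waveform`, `flow`, `hemodynamics`, `hydro` (problem, sources,
#'   fields, spectra, reports), `vibro` (composition, oscillators, traces,
#'   stats, class_max, spectra, reports), and `summary` (headline numbers).
#' @export
run_pt_pipeline <- function(config = list(), out_dir = NULL, quiet = FALSE) {
  cfg <- utils::modifyList(default_pipeline_config(), config)
  say <- function(...) if (!quiet) message(...)

  say("building geometry and meshes ...")
  geometry <- build_geometry(cfg$geometry)
  mesh <- generate_mesh(geometry, cfg$element_size_flow)
  amesh <- generate_mesh(geometry, cfg$element_size_acoustic)

  say("synthesizing inlet waveform ...")
  waveform <- synthesize_waveform(cfg$heart_rate_bpm, cfg$mean_velocity,
                                  cfg$peak_velocity, seed = cfg$waveform_seed)
  props <- fluid_props(cfg$density, cfg$viscosity)

  say("solving transient flow (", cfg$n_cycles, " cycles) ...")
  flow <- solve_transient(mesh, waveform, props, dt = cfg$dt,
                          n_cycles = cfg$n_cycles,
                          store_cycles = cfg$cycle_index)
  hemo <- summarize_hemodynamics(flow, cfg$cycle_index)

  say("hydroacoustics: sources and per-frequency fields ...")
  bins <- seq_len(floor(cfg$f_max * waveform$period)) / waveform$period
  problem <- acoustic_problem(amesh, freq_bins = bins, c0 = cfg$c0,
                              rho0 = cfg$rho0)
  sources <- assemble_sources(flow, problem, cycle_index = cfg$cycle_index)
  hfields <- solve_acoustic(problem, sources)
  mics <- virtual_mics(geometry)
  hspec <- sample_microphones(hfields, mics)
  hreports <- lapply(hspec, band_stats, band = cfg$band)

  say("vibroacoustics: wall response and radiated field ...")
  comp <- assign_wall_composition(mesh, geometry)
  oscs <- composition_oscillators(comp, damping_ratio = cfg$damping_ratio,
                                  curvature_radius = geometry$width / 2)
  sel <- cycle_index_set(flow, cfg$cycle_index, full_only = TRUE)
  bs <- list(lateral = boundary_stress(flow, "lateral_wall"),
             medial = boundary_stress(flow, "medial_wall"))
  traces <- vector("list", nrow(comp$patches))
  vib_rows <- integer(0)
  for (r in seq_len(nrow(comp$patches))) {
    row <- comp$patches[r, ]
    if (row$class == "RIGID") next
    tr_bs <- bs[[row$wall]]
    on <- mesh$s_centers >= row$s_start & mesh$s_centers < row$s_end
    forcing <- -colMeans(tr_bs$normal[on, sel, drop = FALSE])
    traces[[r]] <- forced_response(oscs[[r]], forcing, waveform$period,
                                   name = sprintf("%s_%s_%02d", row$wall,
                                                  row$class, r))
    vib_rows <- c(vib_rows, r)
  }
  dstats <- lapply(vib_rows, function(r) displacement_stats(traces[[r]]))
  names(dstats) <- vapply(vib_rows, function(r) traces[[r]]$name, character(1))
  max_abs <- vapply(dstats, `[[`, numeric(1), "max_abs")
  class_max <- tapply(max_abs, comp$patches$class[vib_rows], max)
  vres <- vibro_field(traces[vib_rows], comp$patches[vib_rows, ], problem,
                      mics = mics)
  vreports <- lapply(vres$spectra, band_stats, band = cfg$band)

  hydro_peak <- max(vapply(hreports, `[[`, numeric(1), "peak_db"))
  vibro_peak <- max(vapply(vreports, `[[`, numeric(1), "peak_db"))
  grad_ts_ijv <- amplitude_gradient(vreports$TS, vreports$IJV)
  summary <- list(
    avg_velocity = hemo$avg_velocity,
    peak_velocity = hemo$peak_velocity,
    avg_pressure_gradient = hemo$avg_pressure_gradient,
    wall_pressure_min = hemo$wall_pressure_min,
    wall_pressure_max = hemo$wall_pressure_max,
    hydro_peak_db = hydro_peak,
    vibro_peak_db = vibro_peak,
    vibro_over_hydro_peak = vibro_peak / hydro_peak,
    vibro_ts_ijv_gradient_db = grad_ts_ijv$db_difference,
    vibro_ts_ijv_percent = grad_ts_ijv$percent_decrease,
    displacement_class_max = as.list(class_max),
    displacement_ratio_vessel_dura =
      unname(class_max["VESSEL_ONLY"] / class_max["DURA_VESSEL"]),
    displacement_ratio_dura_plate =
      unname(class_max["DURA_VESSEL"] / class_max["PLATE_DURA_VESSEL"])
  )

  out <- structure(
    list(config = cfg, geometry = geometry, mesh = mesh, waveform = waveform,
         flow = flow, hemodynamics = hemo,
         hydro = list(problem = problem, sources = sources, fields = hfields,
                      spectra = hspec, reports = hreports),
         vibro = list(composition = comp, oscillators = oscs, traces = traces,
                      vib_rows = vib_rows, stats = dstats,
                      class_max = class_max, fields = vres$fields,
                      spectra = vres$spectra, reports = vreports),
         summary = summary),
    class = "pt_pipeline")

  if (!is.null(out_dir)) write_pipeline_outputs(out, out_dir)
  out
}

#' @export
print.pt_pipeline <- function(x, ...) {
  s <- x$summary
  cat("<pt_pipeline>\n")
  cat(sprintf("  flow: avg %.3f m/s, peak %.3f m/s, gradient %.3g Pa/m\n",
              s$avg_velocity, s$peak_velocity, s$avg_pressure_gradient))
  cat(sprintf("  hydro peak %.1f dB, vibro peak %.1f dB (ratio %.2f)\n",
              s$hydro_peak_db, s$vibro_peak_db, s$vibro_over_hydro_peak))
  cat(sprintf("  displacement max per class: V %.3g m | DV %.3g m | PDV %.3g m\n",
              s$displacement_class_max$VESSEL_ONLY,
              s$displacement_class_max$DURA_VESSEL,
              s$displacement_class_max$PLATE_DURA_VESSEL))
  invisible(x)
}

#' Write the main pipeline artifacts to a directory
#'
#' Mesh as legacy VTK, inlet waveform as CSV, per-microphone hydro and vibro
#' spectra as CSV (frequency, |p|, SPL dB, SPL dBA), the flow series as an
#' RDS array container, and the summary as JSON (with the configuration
#' echoed).
#'
#' @param pipeline a [run_pt_pipeline()] result.
#' @param out_dir output directory (created if missing).
#' @return `out_dir`, invisibly.
#' @export
write_pipeline_outputs <- function(pipeline, out_dir) {
  stopifnot(inherits(pipeline, "pt_pipeline"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_mesh_vtk(pipeline$mesh, file.path(out_dir, "mesh.vtk"),
                 metadata = pipeline$config$geometry)
  write_waveform_csv(pipeline$waveform, file.path(out_dir, "inlet_waveform.csv"))
  for (kind in c("hydro", "vibro")) {
    for (nm in names(pipeline[[kind]]$spectra)) {
      write_spectrum_csv(pipeline[[kind]]$spectra[[nm]],
                         file.path(out_dir, sprintf("%s_%s.csv", kind, nm)))
    }
  }
  saveRDS(pipeline$flow, file.path(out_dir, "flow_series.rds"))
  jsonlite::write_json(
    list(config = pipeline$config[setdiff(names(pipeline$config), "geometry")],
         geometry = pipeline$config$geometry,
         summary = pipeline$summary,
         hydro_reports = lapply(pipeline$hydro$reports, unclass),
         vibro_reports = lapply(pipeline$vibro$reports, unclass),
         displacement_stats = lapply(pipeline$vibro$stats, unclass)),
    file.path(out_dir, "summary.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  invisible(out_dir)
}

#' Write a pressure spectrum as CSV
#'
#' Columns: frequency (Hz), |p| (Pa, peak amplitude), SPL (dB re 20 uPa),
#' SPL A-weighted (dBA).
#'
#' @param spectrum a [pressure_spectrum()].
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_spectrum_csv <- function(spectrum, path) {
  stopifnot(inherits(spectrum, "pressure_spectrum"))
  df <- data.frame(
    frequency_hz = spectrum$frequencies,
    amplitude_pa = Mod(spectrum$amplitude),
    spl_db = spectrum$spl,
    spl_dba = spectrum$spl + a_weight_offset(spectrum$frequencies)
  )
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Tabulate a grid-independence ladder
#'
#' Formats an element-size refinement study the way mesh-independence tables
#' are reported: one row per mesh with the observable and its relative error
#' against the finest level (blank for the finest).
#'
#' @param element_sizes element sizes in m, any order.
#' @param n_cells cell counts.
#' @param observable the monitored scalar per mesh (e.g. average outflow
#'   velocity).
#' @return data frame sorted coarse to fine with a `relative_error_pct`
#'   column (NA for the reference row).
#' @export
grid_independence_table <- function(element_sizes, n_cells, observable) {
  stopifnot(length(element_sizes) == length(n_cells),
            length(n_cells) == length(observable))
  o <- order(element_sizes, decreasing = TRUE)
  es <- element_sizes[o]; nc <- n_cells[o]; ob <- observable[o]
  ref <- ob[length(ob)]
  re <- c(relative_error(ob[-length(ob)], ref), NA_real_)
  data.frame(n_cells = nc, element_size_m = es, observable = ob,
             relative_error_pct = re)
}
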