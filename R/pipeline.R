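#' Pipeline run configuration
#'
#' A single serializable object that fully determines a pipeline run:
#' geometry, meshing, blood properties, solver controls, orientation
#' convention and image-grid spacing. Defaults describe a curved
#' middle-cerebral-artery-like segment at a desk-scale mesh resolution.
#'
#' @param seed RNG seed driving the synthetic measurement panel.
#' @param shape centerline shape (`"curved"`, `"straight"`, `"s_curve"`).
#' @param length vessel arclength, m.
#' @param curve_radius curve radius, m.
#' @param base_radius lumen radius, m.
#' @param plaque optional [plaque_spec()].
#' @param target_edge mesh edge target, m.
#' @param near_wall_factor wall-normal refinement factor.
#' @param reynolds target Reynolds number (sets the mean inflow velocity
#'   when no panel velocity is used); NULL uses the panel measurement.
#' @param props a [blood_properties()].
#' @param solver a [solver_config()].
#' @param axes an [anatomical_axes()] convention.
#' @param grid_spacing image spacing, mm.
#' @return object of class `run_config`.
#' @export
run_config <- function(seed = 1L, shape = "curved", length = 0.024,
                       curve_radius = 0.012, base_radius = 0.002,
                       plaque = NULL, target_edge = 7e-4,
                       near_wall_factor = 0.5, reynolds = 121,
                       props = blood_properties(),
                       solver = solver_config(),
                       axes = anatomical_axes(),
                       grid_spacing = c(0.4, 0.4, 0.8)) {
  structure(list(seed = as.integer(seed), shape = shape, length = length,
                 curve_radius = curve_radius, base_radius = base_radius,
                 plaque = plaque, target_edge = target_edge,
                 near_wall_factor = near_wall_factor, reynolds = reynolds,
                 props = props, solver = solver, axes = axes,
                 grid_spacing = grid_spacing),
            class = "run_config")
}

#' Run the full hemodynamics pipeline
#'
#' Orchestrates synthetic geometry -> mesh -> flow solve -> wall shear
#' extraction -> anatomical labeling -> image registration -> WSS ratios as
#' one reproducible run. All artifacts (surface STL, mesh and solution VTU,
#' WSS and label surfaces, projected NIfTI volumes, regional CSV, summary
#' and manifest JSON) are written under `out_dir` when given.
#'
#' A zero-inflow configuration completes with an all-zero WSS field; the
#' summary flags the degenerate result and the ratio entries are NA.
#'
#' @param cfg a [run_config()].
#' @param out_dir output directory (created if missing); NULL skips all
#'   file output.
#' @return the summary list, invisibly when writing files: measured flow
#'   and pressure, regional means, `rwss_vi_ds`, `rwss_inner_outer`,
#'   Reynolds number, mass-conservation residual, convergence and
#'   degeneracy flags, and the config hash.
#' @export
run_pipeline <- function(cfg = run_config(), out_dir = NULL) {
  stopifnot(inherits(cfg, "run_config"))
  emit <- !is.null(out_dir)
  if (emit) dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  # synth ------------------------------------------------------------------
  cl <- make_centerline(cfg$shape, length = cfg$length,
                        curve_radius = cfg$curve_radius, seed = cfg$seed)
  vessel <- make_vessel_surface(cl, cfg$base_radius, plaque = cfg$plaque)
  panel <- make_ultrasound_panel(4L, seed = cfg$seed)
  phantom <- make_image_phantom(vessel, spacing = cfg$grid_spacing)

  # mesh -------------------------------------------------------------------
  mesh <- tetrahedralize(vessel, cfg$target_edge, cfg$near_wall_factor)
  quality <- mesh_quality(mesh)

  # boundary conditions ----------------------------------------------------
  outlet_area <- sum(mesh$face_area[mesh$face_label == "outlet_1"])
  if (!is.null(cfg$reynolds)) {
    v_in <- cfg$reynolds * cfg$props$mu /
      (cfg$props$rho * 2 * cfg$base_radius)
    q_in <- v_in * pi * cfg$base_radius^2
    degenerate <- cfg$reynolds == 0
    res <- if (degenerate) list(R_total = NA_real_, R_out = 1)
           else total_and_outlet_resistance(panel$pressure_pa, q_in,
                                            outlet_area)
    bcs <- boundary_conditions(q_in = q_in, v_in = v_in,
                               r_out = res$R_out, p_brachial = panel$pressure_pa,
                               allow_zero = TRUE)
  } else {
    bcs <- bc_from_panel(panel, 1L, outlet_area)
    degenerate <- FALSE
  }

  # solve + wss ------------------------------------------------------------
  sol <- solve_flow(mesh, bcs, cfg$props, cfg$solver)
  field <- compute_wss(sol, mesh)
  labels <- wall_labels(mesh, cfg$axes)
  mass_residual <- check_mass_conservation(sol, mesh)
  degenerate <- degenerate || max(field$wss_magnitude) == 0

  ratio_or_na <- function(f) if (degenerate) NA_real_ else
    tryCatch(f, error = function(e) NA_real_)
  r_vi_ds <- ratio_or_na(rwss_vi_ds(field, labels, segment = "middle"))
  r_io <- ratio_or_na(rwss_inner_outer(field, labels, segment = "middle"))

  # register ---------------------------------------------------------------
  tr <- grid_transform(spacing = cfg$grid_spacing,
                       origin = phantom$origin)
  proj <- project_wss_to_image(field, tr, dim(phantom$values))

  table <- regional_wss_table(field, labels)
  scales <- characteristic_scales(props = cfg$props)

  summary <- list(
    config_hash = config_hash(cfg),
    seed = cfg$seed,
    n_cells = quality$n_cells,
    min_cell_volume_m3 = quality$min_volume,
    reynolds_characteristic = scales$Re,
    q_in_m3_s = sol$q_in,
    q_out_m3_s = sum(sol$q_out),
    p_out_pa = unname(sol$p_out),
    r_total_pa_s_m3 = bcs$r_total,
    mass_conservation_residual = mass_residual,
    mean_wss_pa = if (max(field$wss_magnitude) > 0)
      regional_mean_wss(field, seq_along(field$face_ids)) else 0,
    rwss_vi_ds_middle = r_vi_ds,
    rwss_inner_outer_middle = r_io,
    converged = sol$converged,
    degenerate = degenerate)

  if (emit) {
    pth <- function(f) file.path(out_dir, f)
    write_surface_stl(vessel, pth("vessel.stl"))
    write_surface_ply(vessel, pth("vessel.ply"))
    write_panel_csv(panel, pth("ultrasound_panel.csv"))
    write_voxel_nifti(phantom, pth("phantom.nii.gz"))
    write_mesh_vtu(mesh, pth("mesh.vtu"))
    write_mesh_vtu(mesh, pth("boundary.vtu"), boundary_ids = TRUE)
    write_solution_vtu(sol, mesh, pth("solution.vtu"))
    write_wss_vtu(field, mesh, pth("wss.vtu"))
    write_labels_vtu(labels, mesh, pth("labels.vtu"))
    write_voxel_nifti(proj$wss, pth("wss_projected.nii.gz"))
    write_voxel_nifti(proj$valid, pth("wss_valid_mask.nii.gz"))
    write_transform_json(tr, pth("grid_transform.json"))
    utils::write.csv(table, pth("regional_wss.csv"), row.names = FALSE)
    jsonlite::write_json(summary, pth("summary.json"), auto_unbox = TRUE,
                         digits = NA)
    jsonlite::write_json(list(config = .serializable_config(cfg),
                              hash = summary$config_hash),
                         pth("manifest.json"), auto_unbox = TRUE,
                         digits = NA)
    return(invisible(summary))
  }
  summary
}

# config as plain (class-free) nested lists for JSON
.serializable_config <- function(cfg) {
  strip <- function(x) if (is.list(x)) lapply(unclass(x), strip) else x
  strip(cfg)
}

#' Hash of a run configuration
#'
#' MD5 of the canonical JSON serialization of the config; identical configs
#' hash identically across sessions, making run manifests comparable.
#'
#' @param cfg a [run_config()].
#' @return hex string.
#' @export
config_hash <- function(cfg) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(.serializable_config(cfg), tmp, auto_unbox = TRUE,
                       digits = NA)
  unname(tools::md5sum(tmp))
}
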