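#' Assemble a pipeline run configuration
#'
#' Bundles the stage parameters of a full phantom-to-postprocessing run:
#' phantom geometry, rendering gray index, thresholds (derived from the
#' gray index unless given), electrode placement and the controlled DC/AC
#' protocol pair (shared geometry, shared 10 mA amplitude, AC at 1 kHz,
#' material table evaluated at 1 kHz for both modes).
#'
#' @param phantom a [phantom_spec].
#' @param gray a [gray_index].
#' @param thresholds optional [threshold_spec]; derived from `gray` if NULL.
#' @param amplitude_a injected current, ampere.
#' @param frequency_hz AC frequency.
#' @param f_material_hz material-evaluation frequency for both modes.
#' @param electrode_edge_mm electrode patch edge length.
#' @param skin_min_thickness_mm thin-layer compensation target.
#' @param seed global seed, fanned out per stage.
#' @return Object of class `run_config`.
#' @export
run_config <- function(phantom = phantom_spec(), gray = gray_index(),
                       thresholds = NULL, amplitude_a = 0.01,
                       frequency_hz = 1e3, f_material_hz = 1e3,
                       electrode_edge_mm = 20, skin_min_thickness_mm = 1,
                       seed = 1L) {
  structure(list(phantom = phantom, gray = gray,
                 thresholds = thresholds %||%
                   threshold_spec_from_gray_index(gray),
                 amplitude_a = amplitude_a, frequency_hz = frequency_hz,
                 f_material_hz = f_material_hz,
                 electrode_edge_mm = electrode_edge_mm,
                 skin_min_thickness_mm = skin_min_thickness_mm,
                 seed = as.integer(seed)),
            class = "run_config")
}

# electrode pair on the +/- x flanks at mid-height of a label volume
default_electrode_pair <- function(vol, edge_mm = 20) {
  d <- dim(vol$labels)
  ctr <- vol$origin + d * vol$spacing / 2
  body <- vol$labels > 0L
  mid_k <- round(d[3] / 2)
  xs_occ <- which(apply(body[, , mid_k], 1, any))
  x_hi <- vol$origin[1] + max(xs_occ) * vol$spacing[1]
  x_lo <- vol$origin[1] + (min(xs_occ) - 1) * vol$spacing[1]
  list(
    electrode_spec(c(x_hi, ctr[2], ctr[3]), "+x", rep(edge_mm, 2), +1L),
    electrode_spec(c(x_lo, ctr[2], ctr[3]), "-x", rep(edge_mm, 2), -1L))
}

#' Run the phantom-to-postprocessing pipeline
#'
#' Executes the requested stages in order (`phantom`, `segment`,
#' `reconstruct`, `mesh`, `solve`, `post`), each stage consuming the
#' previous stage's output, and writes per-stage artifacts plus a JSON run
#' manifest (config hash, seed, versions, outputs, key metrics) under
#' `out_dir`.
#'
#' @param config a [run_config].
#' @param stages subset of stage names (contiguous from "phantom").
#' @param out_dir output directory.
#' @param quiet suppress progress messages.
#' @return The manifest, invisibly (list).
#' @export
run_pipeline <- function(config, stages = c("phantom", "segment",
                                            "reconstruct", "mesh", "solve",
                                            "post"),
                         out_dir = tempfile("armstim_run_"),
                         quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  all_stages <- c("phantom", "segment", "reconstruct", "mesh", "solve",
                  "post")
  stages <- match.arg(stages, all_stages, several.ok = TRUE)
  stages <- all_stages[all_stages %in% stages]
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message(sprintf(...))
  cfg_json <- jsonlite::toJSON(
    list(phantom = unclass(config$phantom), gray = unclass(config$gray),
         amplitude_a = config$amplitude_a,
         frequency_hz = config$frequency_hz,
         f_material_hz = config$f_material_hz,
         electrode_edge_mm = config$electrode_edge_mm,
         skin_min_thickness_mm = config$skin_min_thickness_mm,
         seed = config$seed),
    auto_unbox = TRUE, digits = NA)
  manifest <- list(config_hash = poly_hash(as.character(cfg_json)),
                   seed = config$seed,
                   package_version =
                     as.character(utils::packageVersion("armstim")),
                   stages = stages, outputs = list(), metrics = list())
  env <- new.env(parent = emptyenv())

  need <- function(what, stage) {
    if (!exists(what, envir = env))
      stop_arm("missing upstream artifact '%s': rerun stage '%s'",
               what, stage)
    get(what, envir = env)
  }

  for (st in stages) {
    say("stage: %s", st)
    if (st == "phantom") {
      vol <- build_phantom(config$phantom)
      stack <- render_slices(vol, config$gray,
                             seed = stage_seed(config$seed, 1L))
      write_label_volume(vol, file.path(out_dir, "ground_truth.json"))
      write_slice_stack(stack, file.path(out_dir, "stack"))
      assign("truth", vol, env); assign("stack", stack, env)
      manifest$outputs$phantom <- c("ground_truth.json", "stack/")
    } else if (st == "segment") {
      stack <- need("stack", "phantom")
      seg <- threshold_segment(stack, config$thresholds)
      write_label_volume(seg, file.path(out_dir, "segmented.json"))
      assign("segmented", seg, env)
      manifest$outputs$segment <- "segmented.json"
    } else if (st == "reconstruct") {
      seg <- need("segmented", "segment")
      # cumulative (filled-hull) clouds outer->inner, then innermost wins
      order_out_in <- c("skin", "fat", "muscle", "bone", "marrow")
      present <- order_out_in[order_out_in %in%
                                tissue_name(sort(unique(
                                  as.vector(seg$labels))))]
      surfaces <- list()
      for (t in present) {
        # filled hull of tissue t: t plus everything anatomically inside
        code <- tissue_codes()[[t]]
        hull_mask <- seg$labels > 0L & seg$labels <= code
        hull <- label_volume(array(as.integer(hull_mask) * code,
                                   dim(seg$labels)),
                             seg$spacing, seg$origin)
        pc <- extract_point_cloud(hull, t)
        # occupancy voxel must cover the coarsest source spacing or the
        # re-voxelized shell is not closed
        surfaces[[t]] <- reconstruct_surface(pc, voxel = max(seg$spacing))
      }
      recon <- solidify(surfaces, seg)
      recon <- compensate_thin_layers(recon, "skin",
                                      config$skin_min_thickness_mm)
      for (t in names(surfaces))
        write_surface_stl(surfaces[[t]],
                          file.path(out_dir, sprintf("surface_%s.stl", t)))
      write_label_volume(recon, file.path(out_dir, "reconstructed.json"))
      assign("recon", recon, env)
      manifest$outputs$reconstruct <-
        c("reconstructed.json", sprintf("surface_%s.stl", names(surfaces)))
    } else if (st == "mesh") {
      vol <- need("recon", "reconstruct")
      mesh <- voxel_to_tet(vol)
      q <- mesh_quality(mesh)
      assign("mesh", mesh, env)
      manifest$metrics$mesh <- list(
        nodes = q$n_nodes, tets = q$n_tets,
        min_dihedral_deg = q$min_dihedral_deg)
      write_vtk_mesh(mesh, file.path(out_dir, "mesh.vtk"))
      manifest$outputs$mesh <- "mesh.vtk"
    } else if (st == "solve") {
      mesh <- need("mesh", "mesh")
      sys <- assemble(mesh, tissue_properties(),
                      f_eval = config$f_material_hz)
      electrodes <- default_electrode_pair(
        label_volume(mesh_labels(mesh), mesh$spacing, mesh$origin),
        config$electrode_edge_mm)
      load <- electrode_load(sys, electrodes, config$amplitude_a)
      dc <- solve_phasor(sys, load, f = 0)
      ac <- solve_phasor(sys, load, f = config$frequency_hz)
      assign("sys", sys, env); assign("load", load, env)
      assign("dc", dc, env); assign("ac", ac, env)
      manifest$metrics$solve <- list(
        realized_j_a_m2 = load$electrodes[[1]]$j_realized,
        dc_residual = dc$residual, ac_residual = ac$residual)
      manifest$outputs$solve <- character(0)
    } else if (st == "post") {
      sys <- need("sys", "solve"); load <- need("load", "solve")
      dc <- need("dc", "solve"); ac <- need("ac", "solve")
      cn <- vapply(load$electrodes, function(e) e$contact_node, integer(1))
      prof_dc <- line_profile(dc, sys, load)
      prof_ac <- line_profile(ac, sys, load)
      utils::write.csv(prof_dc, file.path(out_dir, "profile_dc.csv"),
                       row.names = FALSE)
      utils::write.csv(prof_ac, file.path(out_dir, "profile_ac.csv"),
                       row.names = FALSE)
      metrics <- list(
        dc_contact_potential_v = max(abs(Re(dc$phi[cn]))),
        ac_contact_amplitude_v = max(Mod(ac$phi[cn])),
        dc_effective_depth_mm = effective_depth(prof_dc),
        ac_effective_depth_mm = effective_depth(prof_ac),
        ac_vs_dc_contact_excess_pct =
          percent_excess(prof_ac$j_mag[1], prof_dc$j_mag[1]))
      manifest$metrics$post <- metrics
      manifest$outputs$post <- c("profile_dc.csv", "profile_ac.csv")
    }
  }
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

# label grid reconstructed from a tet mesh's source voxels
mesh_labels <- function(mesh) {
  lab <- array(0L, dim = mesh$grid_dim)
  lab[mesh$voxel_linear] <- mesh$tissue[seq(1L, nrow(mesh$tets), by = 6L)]
  lab
}
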