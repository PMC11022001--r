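#' Pipeline run configuration
#'
#' Bundles the phantom, waveform, stimulus, sweep and scan settings of an
#' end-to-end synthetic identification run.
#'
#' @param phantom A \code{\link{phantom_spec}}.
#' @param waveform A \code{\link{waveform_spec}}.
#' @param flow_rates Stimulus plateau flow rates, ml/min.
#' @param stimulus_onset,stimulus_duration Pulse timing, s.
#' @param grid_n,grid_layout Parameter-sweep size and layout.
#' @param dt_grid Acquisition-offset scan grid, s.
#' @param delta_t_true Ground-truth offset used to synthesize the
#'   experimental volume change, s.
#' @param mode Identification mode ("joint" or "per-load").
#' @param dv_source "forward" (volume changes synthesized by the forward
#'   model at the phantom's ground-truth constants; sub-voxel deformations
#'   resolved exactly) or "mask" (image-domain voxel volumetry of the
#'   phantom masks; subject to voxel quantization).
#' @param seed Integer seed recorded in every output artifact.
#' @return A \code{run_config} list.
#' @export
run_config <- function(phantom = phantom_spec(),
                       waveform = waveform_spec(),
                       flow_rates = c(150, 170, 190),
                       stimulus_onset = 1,
                       stimulus_duration = 3,
                       grid_n = 51,
                       grid_layout = "grid",
                       dt_grid = seq(0.01, 0.07, by = 0.01),
                       delta_t_true = 0.04,
                       mode = "joint",
                       dv_source = c("forward", "mask"),
                       seed = 1L) {
  dv_source <- match.arg(dv_source)
  structure(list(phantom = phantom, waveform = waveform,
                 flow_rates = flow_rates,
                 stimulus_onset = stimulus_onset,
                 stimulus_duration = stimulus_duration,
                 grid_n = grid_n, grid_layout = grid_layout,
                 dt_grid = dt_grid, delta_t_true = delta_t_true,
                 mode = mode, dv_source = dv_source,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Run the full synthetic identification pipeline
#'
#' Executes phantom synthesis, volumetry, inverse identification and
#' stress-state reporting, writing every artifact (masks, volume report,
#' scan table, identification result, stress summary and a checksummed
#' manifest) into \code{out_dir}. Reruns with the same configuration are
#' bit-identical.
#'
#' @param config A \code{\link{run_config}}.
#' @param out_dir Output directory (created if needed).
#' @return The identification summary list, invisibly; artifacts on disk.
#' @export
run_pipeline <- function(config = run_config(), out_dir = tempfile("aneufit_run_")) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  wf <- config$waveform
  loads <- lapply(config$flow_rates, function(q)
    load_program(wf, stimulus_spec(flow_rate = q,
                                   duration = config$stimulus_duration,
                                   onset_time = config$stimulus_onset)))
  geom <- sac_geometry(config$phantom$sac_radius, config$phantom$wall_thickness)
  runner <- forward_runner(geom, loads)
  mat_true <- config$phantom$material_truth

  # --- synthesis: C1 once, one C2 per flow rate -------------------------
  acq_phase <- wf$systole_fraction * wf$period  # end-systole, as in forward_runner
  t2 <- vapply(loads, function(ld)
    floor((ld$stimulus$onset_time + 2) / wf$period) * wf$period + acq_phase,
    numeric(1))
  t1 <- ((t2[1] %% wf$period) - config$delta_t_true) %% wf$period
  pairs <- lapply(seq_along(loads), function(k) {
    spec_k <- config$phantom
    spec_k$seed <- config$phantom$seed + k
    generate_phantom_pair(spec_k, loads[[k]], t1 = t1, t2 = t2[k])
  })
  write_mask_nifti(pairs[[1]]$c1, file.path(out_dir, "c1.nii.gz"),
                   sidecar = c(pairs[[1]]$ground_truth, seed = config$seed))
  for (k in seq_along(pairs))
    write_mask_nifti(pairs[[k]]$c2,
                     file.path(out_dir, sprintf("c2_d%d.nii.gz", k)),
                     sidecar = c(pairs[[k]]$ground_truth, seed = config$seed))

  # --- volumetry: overlay, delimit, measure -----------------------------
  plane <- region_delimitation(
    point = c(0, 0, config$phantom$parent_vessel_radius + config$phantom$voxel_size),
    normal = c(0, 0, 1), side = 1)
  write_region(plane, file.path(out_dir, "plane.json"))
  dv_mask <- vapply(seq_along(pairs), function(k) {
    tr <- register_overlay(pairs[[k]]$c1, pairs[[k]]$c2, exclude = plane,
                           subsample = 5000, maxit = 200)
    write_transform(tr, file.path(out_dir, sprintf("overlay_d%d.json", k)))
    c2r <- transform_mask(pairs[[k]]$c2, tr)
    luminal_volume(c2r, plane) - luminal_volume(pairs[[k]]$c1, plane)
  }, numeric(1))
  v_c1 <- luminal_volume(pairs[[1]]$c1, plane)
  dv_true <- vapply(pairs, function(p) p$ground_truth$delta_v_true, numeric(1))
  dv_exp <- if (config$dv_source == "forward") dv_true else dv_mask
  vol_tab <- data.frame(flow_mlmin = config$flow_rates,
                        v_c1_mm3 = v_c1,
                        dv_mask_mm3 = dv_mask,
                        dv_true_mm3 = dv_true,
                        dv_exp_mm3 = dv_exp)
  utils::write.csv(vol_tab, file.path(out_dir, "volume_report.csv"),
                   row.names = FALSE)

  # --- inverse identification -------------------------------------------
  grid <- design_grid(n = config$grid_n, layout = config$grid_layout,
                      seed = config$seed)
  id <- if (config$mode == "joint") {
    scan_delta_t(dv_exp, runner, grid, config$dt_grid, mode = "joint")
  } else {
    scan_delta_t(dv_exp[1], function(a, b, dt) runner(a, b, dt)[1],
                 grid, config$dt_grid, mode = "per-load")
  }
  utils::write.csv(id$scan, file.path(out_dir, "dt_scan.csv"), row.names = FALSE)
  jsonlite::write_json(list(a_hat = id$a_hat, b_hat = id$b_hat,
                            delta_t = id$delta_t, fc_min = id$fc_min,
                            delta_v_num_mat = id$delta_v_num_mat,
                            e_pct = id$e_pct, mode = id$mode,
                            a_true = mat_true$a, b_true = mat_true$b,
                            delta_t_true = config$delta_t_true,
                            seed = config$seed),
                       file.path(out_dir, "identification.json"),
                       auto_unbox = TRUE, digits = NA)

  # --- stress state at the systole peak ---------------------------------
  mat_hat <- fung_material(id$a_hat, id$b_hat)
  p_sys <- waveform_pressure(wf, systole_peak_time(wf))
  s_c1 <- inflate_membrane(geom$R0, geom$wall_thickness, mat_hat, p_sys,
                           warn_thick = FALSE)
  stress <- do.call(rbind, lapply(seq_along(loads), function(k) {
    t_sys_c2 <- floor((loads[[k]]$stimulus$onset_time + 2) / wf$period) *
      wf$period + systole_peak_time(wf)
    p_c2 <- transmural_pressure(loads[[k]], t = t_sys_c2)
    s_c2 <- inflate_membrane(geom$R0, geom$wall_thickness, mat_hat, p_c2,
                             warn_thick = FALSE)
    m <- stress_metrics(s_c1, s_c2)
    data.frame(flow_mlmin = config$flow_rates[k],
               p_c2_kpa = m$p_c2, sigma1_c2_kpa = m$sigma1_c2,
               dp_pct = m$d_p_pct, dsigma1_pct = m$d_sigma1_pct,
               criterion_ratio_provisional =
                 criterion_ratio(m$sigma1_c2, m$p_c2))
  }))
  utils::write.csv(stress, file.path(out_dir, "stress_state.csv"),
                   row.names = FALSE)

  # --- manifest ----------------------------------------------------------
  files <- setdiff(list.files(out_dir), "manifest.json")
  manifest <- list(seed = config$seed,
                   mode = config$mode,
                   dv_source = config$dv_source,
                   flow_rates = config$flow_rates,
                   delta_t_true = config$delta_t_true,
                   checksums = as.list(tools::md5sum(file.path(out_dir, files))))
  names(manifest$checksums) <- files
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(out_dir = out_dir, volumes = vol_tab, identification = id,
                 stress = stress))
}
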