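# shared study configuration for the analysis scripts
# (sourced by 01..04; edit here to change the synthetic study conditions)

library(aneufit)

study_config <- function(seed = 1L) {
  run_config(
    phantom = phantom_spec(parent_vessel_radius = 1.5,
                           parent_vessel_length = 12,
                           sac_radius = 2,
                           sac_neck_radius = 1.2,
                           voxel_size = 0.25,
                           wall_thickness = 430,
                           material_truth = fung_material(300, 16.2),
                           noise_level = 0.02,
                           seed = seed),
    waveform = waveform_spec(),               # 240 bpm, 0.35 m/s systole peak
    flow_rates = c(150, 170, 190),            # protocol levels D1..D3
    stimulus_onset = 1, stimulus_duration = 3,
    grid_n = 51, grid_layout = "grid",
    dt_grid = seq(0.01, 0.07, by = 0.01),
    delta_t_true = 0.04,
    mode = "joint",
    dv_source = "forward",
    seed = seed)
}

results_dir <- function(...) {
  d <- file.path("results", ...)
  dir.create(d, showWarnings = FALSE, recursive = TRUE)
  d
}
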