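# shared small fixtures; everything is generated in code

default_loads <- function(flows = c(150, 170, 190), onset = 1,
                          wf = waveform_spec()) {
  lapply(flows, function(q)
    load_program(wf, stimulus_spec(flow_rate = q, onset_time = onset)))
}

default_runner <- function(geom = sac_geometry(2, 430), loads = default_loads()) {
  forward_runner(geom, loads)
}

# brute-force membrane oracle: dense stretch grid minimizing the Laplace
# residual, independent of the root-bracketing solver
oracle_inflate <- function(R0, H, material, P, lam_max = 1.6, n = 400001) {
  lam <- seq(1, lam_max, length.out = n)
  I1 <- 2 * lam^2 + lam^-4
  sig <- 2 * (material$a / 2) * exp(material$b / 2 * (I1 - 3)) *
    (lam^2 - lam^-4)
  p_model <- 2 * sig * (H / 1000) * lam^-3 / R0  # kPa
  i <- which.min(abs(p_model - P / 1000))
  list(stretch = lam[i], sigma1 = sig[i])
}

# small phantom that keeps voxel grids and registration cheap
small_phantom <- function(...) {
  phantom_spec(parent_vessel_radius = 1.2, parent_vessel_length = 8,
               sac_radius = 1.6, sac_neck_radius = 1.0, ...)
}

neck_plane <- function(spec) {
  region_delimitation(c(0, 0, spec$parent_vessel_radius + spec$voxel_size),
                      c(0, 0, 1), side = 1)
}
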