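#' Binary segmentation mask
#'
#' Container for a 3D binary lumen-occupancy grid with isotropic or
#' anisotropic voxel spacing and an identity-orientation world affine
#' (world coordinates in mm, axis order x, y, z; voxel indices 0-based in
#' the affine convention).
#'
#' @param occupancy 3D array with values in \{0, 1\}.
#' @param voxel_size Voxel edge lengths, mm (length 1 or 3).
#' @param origin World coordinates (mm) of the center of voxel (1,1,1).
#' @param label Acquisition tag, e.g. "C1", "C2-D1".
#' @return An object of class \code{segmentation_mask}.
#' @export
segmentation_mask <- function(occupancy, voxel_size, origin = c(0, 0, 0),
                              label = "") {
  if (length(dim(occupancy)) != 3) stop("occupancy must be a 3D array")
  if (!all(occupancy %in% c(0, 1))) stop("occupancy values must be 0 or 1")
  voxel_size <- rep(voxel_size, length.out = 3)
  if (any(voxel_size <= 0)) stop("voxel_size must be > 0 on all axes")
  structure(list(occupancy = array(as.integer(occupancy), dim(occupancy)),
                 voxel_size = voxel_size,
                 origin = as.numeric(origin),
                 label = label),
            class = "segmentation_mask")
}

#' @export
print.segmentation_mask <- function(x, ...) {
  cat(sprintf("segmentation mask [%s]: %s voxels @ %s mm, %d lumen voxels (%.2f mm^3)\n",
              x$label, paste(dim(x$occupancy), collapse = "x"),
              paste(signif(x$voxel_size, 3), collapse = "x"),
              sum(x$occupancy), mask_volume(x)))
  invisible(x)
}

#' Voxel-count volume of a mask (mm^3)
#' @param mask A \code{\link{segmentation_mask}}.
#' @return Lumen volume in mm^3 (occupied voxels times voxel volume).
#' @export
mask_volume <- function(mask) {
  stopifnot(inherits(mask, "segmentation_mask"))
  sum(mask$occupancy) * prod(mask$voxel_size)
}

#' World coordinates of all voxel centers
#' @param mask A \code{\link{segmentation_mask}}.
#' @return List of arrays \code{x}, \code{y}, \code{z} matching the grid.
#' @keywords internal
voxel_centers <- function(mask) {
  d <- dim(mask$occupancy)
  xs <- mask$origin[1] + (seq_len(d[1]) - 1) * mask$voxel_size[1]
  ys <- mask$origin[2] + (seq_len(d[2]) - 1) * mask$voxel_size[2]
  zs <- mask$origin[3] + (seq_len(d[3]) - 1) * mask$voxel_size[3]
  list(x = array(rep(xs, times = d[2] * d[3]), d),
       y = array(rep(rep(ys, each = d[1]), times = d[3]), d),
       z = array(rep(zs, each = d[1] * d[2]), d))
}

#' Voxelize an analytic solid
#'
#' Center-sampling rule: a voxel belongs to the lumen iff its center lies
#' inside the analytic surface (half-open, deterministic).
#'
#' @param inside A function of three equal-shaped coordinate arrays (x, y,
#'   z in world mm) returning a logical array.
#' @param lower,upper World-space bounding box corners, mm.
#' @param voxel_size Voxel edge length(s), mm.
#' @param label Mask label.
#' @param margin Extra margin, in voxels, added around the bounding box.
#' @return A \code{\link{segmentation_mask}}.
#' @export
voxelize <- function(inside, lower, upper, voxel_size = 0.25, label = "",
                     margin = 2) {
  voxel_size <- rep(voxel_size, length.out = 3)
  lower <- lower - margin * voxel_size
  upper <- upper + margin * voxel_size
  n <- pmax(1L, as.integer(ceiling((upper - lower) / voxel_size)) + 1L)
  origin <- lower
  d <- n
  xs <- origin[1] + (seq_len(d[1]) - 1) * voxel_size[1]
  ys <- origin[2] + (seq_len(d[2]) - 1) * voxel_size[2]
  zs <- origin[3] + (seq_len(d[3]) - 1) * voxel_size[3]
  X <- array(rep(xs, times = d[2] * d[3]), d)
  Y <- array(rep(rep(ys, each = d[1]), times = d[3]), d)
  Z <- array(rep(zs, each = d[1] * d[2]), d)
  occ <- inside(X, Y, Z)
  if (!is.logical(occ) || !identical(dim(occ), d))
    stop("inside() must return a logical array of the grid shape")
  segmentation_mask(array(as.integer(occ), d), voxel_size, origin, label)
}

#' Phantom specification
#'
#' Idealized imaging phantom: a straight parent vessel (cylinder along x)
#' carrying a saccular bulge (sphere tangent to the vessel through a neck),
#' voxelized at photon-counting-CT-like resolution. The sac radius is the
#' diastolic reference \eqn{R_0} of the forward model; its inflated states
#' are produced by \code{\link{inflate_membrane}} at the acquisition-time
#' transmural pressures.
#'
#' @param parent_vessel_radius,parent_vessel_length Vessel radius and
#'   length, mm.
#' @param sac_radius Reference sac radius, mm.
#' @param sac_neck_radius Neck radius, mm (must be < sac_radius).
#' @param voxel_size Voxel edge, mm (imaging default 0.25).
#' @param wall_thickness Uniform wall thickness, micrometres.
#' @param material_truth Ground-truth \code{\link{fung_material}}.
#' @param noise_level Fraction of boundary voxels randomly flipped, in
#'   [0, 0.1).
#' @param seed Integer seed for the noise model.
#' @return An object of class \code{phantom_spec}.
#' @export
phantom_spec <- function(parent_vessel_radius = 1.5,
                         parent_vessel_length = 12,
                         sac_radius = 2,
                         sac_neck_radius = 1.2,
                         voxel_size = 0.25,
                         wall_thickness = 430,
                         material_truth = fung_material(353.6, 16.7),
                         noise_level = 0,
                         seed = 1L) {
  if (any(c(parent_vessel_radius, parent_vessel_length, sac_radius,
            sac_neck_radius, voxel_size, wall_thickness) <= 0))
    stop("all phantom lengths must be > 0")
  if (sac_neck_radius >= sac_radius)
    stop("sac_neck_radius must be < sac_radius")
  if (noise_level < 0 || noise_level >= 0.1)
    stop("noise_level must lie in [0, 0.1)")
  stopifnot(inherits(material_truth, "fung_material"))
  structure(list(parent_vessel_radius = parent_vessel_radius,
                 parent_vessel_length = parent_vessel_length,
                 sac_radius = sac_radius,
                 sac_neck_radius = sac_neck_radius,
                 voxel_size = voxel_size,
                 wall_thickness = wall_thickness,
                 material_truth = material_truth,
                 noise_level = noise_level,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

# sac center height above the vessel axis (z): sphere meets the vessel
# surface in a circle of the requested neck radius
.sac_center_z <- function(spec, sac_radius = spec$sac_radius) {
  spec$parent_vessel_radius + sqrt(max(sac_radius^2 - spec$sac_neck_radius^2, 0))
}

#' Voxelize one phantom state
#'
#' @param spec A \code{\link{phantom_spec}}.
#' @param sac_radius Sac radius of this state, mm (default: reference).
#' @param label Mask label.
#' @return A \code{\link{segmentation_mask}} of vessel lumen plus sac.
#' @export
phantom_mask <- function(spec, sac_radius = spec$sac_radius, label = "") {
  stopifnot(inherits(spec, "phantom_spec"))
  if (spec$sac_radius < 3 * spec$voxel_size)
    stop("voxel grid too coarse to resolve the sac (sac_radius < 3 voxels)")
  rp <- spec$parent_vessel_radius
  L <- spec$parent_vessel_length
  zc <- .sac_center_z(spec)
  rs <- sac_radius
  lower <- c(min(-L / 2, -rs), min(-rp, -rs), -rp)
  upper <- c(max(L / 2, rs), max(rp, rs), zc + rs)
  mask <- voxelize(function(x, y, z) {
    in_vessel <- (y^2 + z^2 < rp^2) & (abs(x) <= L / 2)
    in_sac <- x^2 + y^2 + (z - zc)^2 < rs^2
    in_vessel | in_sac
  }, lower, upper, spec$voxel_size, label)
  mask
}

# flip a random subset of boundary voxels (voxels whose 6-neighbourhood
# mixes lumen and background); seeded, touches only the boundary shell
.apply_boundary_noise <- function(mask, noise_level, seed) {
  if (noise_level <= 0) return(mask)
  occ <- mask$occupancy
  d <- dim(occ)
  pad <- array(0L, d + 2L)
  pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- occ
  nb <- pad[1:d[1], 2:(d[2] + 1), 2:(d[3] + 1)] +
        pad[3:(d[1] + 2), 2:(d[2] + 1), 2:(d[3] + 1)] +
        pad[2:(d[1] + 1), 1:d[2], 2:(d[3] + 1)] +
        pad[2:(d[1] + 1), 3:(d[2] + 2), 2:(d[3] + 1)] +
        pad[2:(d[1] + 1), 2:(d[2] + 1), 1:d[3]] +
        pad[2:(d[1] + 1), 2:(d[2] + 1), 3:(d[3] + 2)]
  boundary <- which((occ == 1L & nb < 6L) | (occ == 0L & nb > 0L))
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  set.seed(seed)
  flip <- boundary[stats::runif(length(boundary)) < noise_level]
  occ[flip] <- 1L - occ[flip]
  segmentation_mask(occ, mask$voxel_size, mask$origin, mask$label)
}

#' Generate a baseline/stimulated phantom mask pair
#'
#' Produces the C1 (baseline) and C2 (stimulated) segmentation masks of the
#' phantom, with the sac inflated by the package's own forward model at the
#' two acquisition instants, plus a ground-truth record.
#'
#' @param spec A \code{\link{phantom_spec}}.
#' @param load_c2 \code{\link{load_program}} with the stimulus pulse.
#' @param t1 Baseline acquisition instant, s (stimulus off; default: the
#'   first systole peak).
#' @param t2 Stimulated acquisition instant, s (default: the systole peak
#'   of the cycle 2 s after stimulus onset).
#' @param fluid A \code{\link{fluid_properties}}.
#' @return List with \code{c1}, \code{c2} (\code{segmentation_mask}s) and
#'   \code{ground_truth} (material constants, true sac volumes and
#'   \code{delta_v_true} mm^3 in the forward model's full-sphere
#'   convention, acquisition times, stretches).
#' @export
generate_phantom_pair <- function(spec, load_c2, t1 = NULL, t2 = NULL,
                                  fluid = fluid_properties()) {
  stopifnot(inherits(spec, "phantom_spec"), inherits(load_c2, "load_program"))
  wf <- load_c2$waveform
  if (is.null(t2)) {
    onset <- if (is.null(load_c2$stimulus)) 0 else load_c2$stimulus$onset_time
    cyc <- floor((onset + 2) / wf$period)
    t2 <- systole_peak_time(wf, cyc)
  }
  if (is.null(t1)) t1 <- systole_peak_time(wf, 0) %% wf$period
  p1 <- waveform_pressure(wf, t1)
  p2 <- transmural_pressure(load_c2, fluid, t2)
  mat <- spec$material_truth
  s1 <- inflate_membrane(spec$sac_radius, spec$wall_thickness, mat, p1,
                         warn_thick = FALSE)
  s2 <- inflate_membrane(spec$sac_radius, spec$wall_thickness, mat, p2,
                         warn_thick = FALSE)
  c1 <- phantom_mask(spec, sac_radius = s1$radius, label = "C1")
  c2 <- phantom_mask(spec, sac_radius = s2$radius, label = "C2")
  c1 <- .apply_boundary_noise(c1, spec$noise_level, spec$seed)
  c2 <- .apply_boundary_noise(c2, spec$noise_level, spec$seed + 1L)
  list(c1 = c1, c2 = c2,
       ground_truth = list(a = mat$a, b = mat$b,
                           t1 = t1, t2 = t2,
                           p1_pa = p1, p2_pa = p2,
                           stretch_c1 = s1$stretch, stretch_c2 = s2$stretch,
                           v_sac_c1 = s1$volume, v_sac_c2 = s2$volume,
                           delta_v_true = s2$volume - s1$volume))
}

#' Write a segmentation mask as NIfTI
#'
#' uint8 occupancy with voxel spacing in the header; an optional JSON
#' sidecar carries ground truth or provenance.
#'
#' @param mask A \code{\link{segmentation_mask}}.
#' @param path Output path (\code{.nii} or \code{.nii.gz}).
#' @param sidecar Optional list serialized as JSON next to the image.
#' @return \code{path}, invisibly.
#' @export
write_mask_nifti <- function(mask, path, sidecar = NULL) {
  stopifnot(inherits(mask, "segmentation_mask"))
  img <- RNifti::asNifti(mask$occupancy)
  RNifti::pixdim(img) <- mask$voxel_size
  RNifti::writeNifti(img, path, datatype = "uint8")
  if (!is.null(sidecar)) {
    jpath <- sub("\\.nii(\\.gz)?$", ".json", path)
    jsonlite::write_json(sidecar, jpath, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Read a segmentation mask from NIfTI
#'
#' @param path NIfTI path.
#' @param label Mask label to attach.
#' @param origin World origin (mm) of voxel (1,1,1); default zeros.
#' @return A \code{\link{segmentation_mask}}.
#' @export
read_mask_nifti <- function(path, label = "", origin = c(0, 0, 0)) {
  img <- RNifti::readNifti(path)
  occ <- array(as.integer(as.array(img) != 0), dim(img))
  segmentation_mask(occ, RNifti::pixdim(img)[1:3], origin, label)
}
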