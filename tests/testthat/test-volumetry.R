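test_that("mask surface mesh is watertight-consistent with the voxel volume", {
  sphm <- voxelize(function(x, y, z) x^2 + y^2 + z^2 < 4,
                   c(-2, -2, -2), c(2, 2, 2), 0.25)
  msh <- mesh_from_mask(sphm)
  expect_equal(mesh_volume(msh), mask_volume(sphm), tolerance = 1e-10)
  expect_lt(abs(mesh_volume(msh) - 4 / 3 * pi * 8) / (4 / 3 * pi * 8), 0.03)
  # determinism
  msh2 <- mesh_from_mask(sphm)
  expect_identical(msh$vertices, msh2$vertices)
  expect_identical(msh$faces, msh2$faces)
  # degenerate inputs
  empty <- segmentation_mask(array(0L, c(4, 4, 4)), 0.25)
  expect_error(mesh_from_mask(empty), "empty mask")
  single <- array(0L, c(4, 4, 4)); single[2, 2, 2] <- 1L
  m1 <- mesh_from_mask(segmentation_mask(single, 0.25))
  expect_equal(mesh_volume(m1), 0.25^3)
  # disconnected component triggers the largest-component rule with warning
  two <- single; two[4, 4, 4] <- 1L; two[2, 3, 2] <- 1L
  expect_warning(mbig <- mesh_from_mask(segmentation_mask(two, 0.25)),
                 "largest component")
  expect_equal(mesh_volume(mbig), 2 * 0.25^3)
})

test_that("wall offset reproduces radial thickness and shell volume", {
  cyl <- mesh_cylinder(1.5, 10)
  w <- build_wall(cyl, 430)
  rr <- sqrt(rowSums(w$outer$vertices[, 2:3]^2))
  lateral <- abs(w$outer$vertices[, 1]) < 4 & rr > 1
  expect_equal(unique(round(rr[lateral], 6)), 1.93)
  # thin-shell volume control on a sphere
  sph <- mesh_sphere(2, subdivisions = 3)
  ws <- build_wall(sph, 430)
  expect_lt(abs(ws$wall_volume - 4 * pi * 2.215^2 * 0.43) /
            (4 * pi * 2.215^2 * 0.43), 0.10)
  # wall volume ~ midsurface area x thickness (thin-shell estimate; at
  # t/r = 0.29 the inner-surface area underestimates by ~t/r)
  long_cyl <- mesh_cylinder(1.5, 30)
  w_long <- build_wall(long_cyl, 430)
  r_mid <- 1.5 + 0.43 / 2
  a_mid <- 2 * pi * r_mid * (30 + 0.43) + 2 * pi * r_mid^2
  expect_lt(abs(w_long$wall_volume - a_mid * 0.43) / (a_mid * 0.43), 0.10)
  expect_error(build_wall(cyl, 0), "thickness")
  # concave waist with curvature radius below the offset: the hourglass
  # surface of revolution r(x) = 0.5 + 0.8 x^2 has an axial curvature
  # radius ~0.63 mm at the waist, so a 0.9 mm wall must self-intersect
  revolve <- function(rfun, xs, n_theta = 32) {
    th <- seq(0, 2 * pi, length.out = n_theta + 1)[-(n_theta + 1)]
    v <- do.call(rbind, lapply(xs, function(x)
      cbind(x, rfun(x) * cos(th), rfun(x) * sin(th))))
    ring <- function(i) (i - 1) * n_theta + seq_len(n_theta)
    f <- list(); nx1 <- c(seq_len(n_theta)[-1], 1)
    for (i in seq_len(length(xs) - 1)) {
      r1 <- ring(i); r2 <- ring(i + 1)
      f[[i]] <- rbind(cbind(r1, r2[nx1], r2), cbind(r1, r1[nx1], r2[nx1]))
    }
    nv <- nrow(v)
    v <- rbind(v, c(xs[1], 0, 0), c(xs[length(xs)], 0, 0))
    f[["cl"]] <- cbind(nv + 1L, ring(1)[nx1], ring(1))
    f[["cr"]] <- cbind(nv + 2L, ring(length(xs)), ring(length(xs))[nx1])
    tri_mesh(v, do.call(rbind, f))
  }
  hour <- revolve(function(x) 0.5 + 0.8 * x^2, seq(-1.5, 1.5, length.out = 41))
  expect_s3_class(build_wall(hour, 430), "wall_geometry")
  expect_error(build_wall(hour, 900), "self-intersection")
})

test_that("overlay registration recovers known rigid transforms", {
  m <- phantom_mask(small_phantom())
  # translation, applied exactly through the world origin
  t_true <- c(1.0, 0, 0)
  m2 <- transform_mask(m, rigid_transform(diag(3), t_true))
  tr <- register_overlay(m, m2, subsample = 8000)
  expect_lt(max(abs(tr$translation + t_true)), 0.1)
  expect_lt(rotation_angle(tr), 0.5)
  # identity
  tr0 <- register_overlay(m, m, subsample = 8000)
  expect_lt(max(abs(tr0$translation)), 0.05)
  expect_lt(rotation_angle(tr0), 0.5)
  expect_gt(attr(tr0, "dice"), 0.99)
  # rotation about z (resampled mask)
  rz <- 5 * pi / 180
  m3 <- transform_mask(m, rigid_transform(euler_rotation(rz = rz)))
  tr3 <- register_overlay(m, m3, subsample = 8000)
  rec <- atan2(tr3$rotation[2, 1], tr3$rotation[1, 1]) * 180 / pi
  expect_lt(abs(rec + 5), 0.5)
})

test_that("re-registration after alignment is the identity within tolerance", {
  m <- phantom_mask(small_phantom())
  m2 <- transform_mask(m, rigid_transform(diag(3), c(0.6, -0.4, 0.3)))
  tr <- register_overlay(m, m2, subsample = 6000)
  m2r <- transform_mask(m2, tr)
  tr2 <- register_overlay(m, m2r, subsample = 6000)
  expect_lt(max(abs(tr2$translation)), 0.05)
  expect_lt(rotation_angle(tr2), 0.5)
})

test_that("plane delimitation labels faces and areas consistently", {
  sph <- mesh_sphere(2, center = c(0, 0, 2), subdivisions = 4)
  eq <- region_delimitation(c(0, 0, 2), c(0, 0, 1), side = 1)
  lab <- delimit_aneurysm(sph, eq)
  # hemisphere area above the equator
  fc_area <- function(mesh, keep) {
    p1 <- mesh$vertices[mesh$faces[keep, 1], , drop = FALSE]
    p2 <- mesh$vertices[mesh$faces[keep, 2], , drop = FALSE]
    p3 <- mesh$vertices[mesh$faces[keep, 3], , drop = FALSE]
    cr <- cbind((p2 - p1)[, 2] * (p3 - p1)[, 3] - (p2 - p1)[, 3] * (p3 - p1)[, 2],
                (p2 - p1)[, 3] * (p3 - p1)[, 1] - (p2 - p1)[, 1] * (p3 - p1)[, 3],
                (p2 - p1)[, 1] * (p3 - p1)[, 2] - (p2 - p1)[, 2] * (p3 - p1)[, 1])
    sum(sqrt(rowSums(cr^2))) / 2
  }
  area_up <- fc_area(sph, lab == "aneurysm")
  # accuracy limited by the equatorial band of straddling faces
  expect_lt(abs(area_up - 2 * pi * 4) / (2 * pi * 4), 0.03)
  # flipping the side complements the labels away from the cut itself
  lab_fl <- delimit_aneurysm(sph, region_delimitation(c(0, 0, 2), c(0, 0, 1),
                                                      side = -1))
  ctr_sd <- (sph$vertices[sph$faces[, 1], 3] + sph$vertices[sph$faces[, 2], 3] +
             sph$vertices[sph$faces[, 3], 3]) / 3 - 2
  off_cut <- abs(ctr_sd) > 1e-9
  expect_identical((lab == "aneurysm")[off_cut], (lab_fl == "artery")[off_cut])
  # plane outside the geometry
  expect_error(delimit_aneurysm(sph, region_delimitation(c(0, 0, 40), c(0, 0, 1))),
               "does not intersect")
})

test_that("voxel and mesh volume estimators agree with analytic values", {
  ctr <- c(0.11, 0.07, 0.13)  # posed off the voxel lattice
  off <- c(0.06, 0.09, 0.12)  # and the grid origin off the geometry
  sphm <- voxelize(function(x, y, z)
    (x - ctr[1])^2 + (y - ctr[2])^2 + (z - ctr[3])^2 < 4,
    ctr - 2 - off, ctr + 2, 0.25)
  v_sph <- 4 / 3 * pi * 8
  expect_lt(abs(luminal_volume(sphm) - v_sph) / v_sph, 0.02)
  # hemisphere by plane at the equator, both estimators
  eq <- region_delimitation(ctr, c(0, 0, 1), side = 1)
  v_hemi <- v_sph / 2
  expect_lt(abs(luminal_volume(sphm, eq) - v_hemi) / v_hemi, 0.03)
  sph_mesh <- mesh_sphere(2, center = ctr, subdivisions = 3)
  expect_lt(abs(luminal_volume(sph_mesh, eq) - v_hemi) / v_hemi, 0.03)
  expect_lt(abs(luminal_volume(sph_mesh) - v_sph) / v_sph, 0.03)
  # estimators agree with each other
  expect_lt(abs(luminal_volume(sphm, eq) - luminal_volume(mesh_from_mask(sphm), eq)) /
            v_hemi, 0.03)
  # empty region
  far <- region_delimitation(c(0, 0, 10), c(0, 0, 1), side = 1)
  expect_error(luminal_volume(sphm, far), "no lumen voxels")
})

test_that("region volumes are additive across the cut plane", {
  m <- phantom_mask(small_phantom())
  plane <- neck_plane(small_phantom())
  v_total <- luminal_volume(m)
  v_aneurysm <- luminal_volume(m, plane)
  flip <- region_delimitation(plane$point, plane$normal, side = -1)
  v_artery <- luminal_volume(m, flip)
  expect_equal(v_aneurysm + v_artery, v_total, tolerance = 1e-12)
  # mesh estimator within 1%
  msh <- mesh_from_mask(m)
  expect_lt(abs(luminal_volume(msh, plane) + luminal_volume(msh, flip) -
                mesh_volume(msh)) / mesh_volume(msh), 0.01)
})

test_that("volume report reproduces the published variations", {
  r1 <- volume_report(12.98, 13.10)
  expect_equal(r1$delta_v, 0.12)
  expect_equal(round(r1$delta_v_pct, 2), 0.92)
  r2 <- volume_report(9.81, 10.84)
  expect_equal(r2$delta_v, 1.03)
  expect_equal(round(r2$delta_v_pct, 1), 10.5)
  r0 <- volume_report(5, 5)
  expect_equal(r0$delta_v, 0)
  expect_equal(r0$delta_v_pct, 0)
  # round trip: v_c2 recoverable exactly
  expect_equal(r1$v_c1 + r1$delta_v, r1$v_c2)
  expect_error(volume_report(0, 1), "v_c1")
})

test_that("volume change is invariant to which mask is moved before overlay", {
  spec <- small_phantom()
  loads <- default_loads(flows = 190)
  pair <- generate_phantom_pair(spec, loads[[1]])
  plane <- neck_plane(spec)
  t_shift <- rigid_transform(diag(3), c(0.8, 0.5, 0))
  # register (c1, T c2) vs (T^-1 c1, c2): identical volume change
  c2_m <- transform_mask(pair$c2, t_shift)
  tr_a <- register_overlay(pair$c1, c2_m, exclude = plane, subsample = 6000)
  dv_a <- luminal_volume(transform_mask(c2_m, tr_a), plane) -
          luminal_volume(pair$c1, plane)
  c1_m <- transform_mask(pair$c1, invert_transform(t_shift))
  plane_m <- region_delimitation(plane$point - t_shift$translation,
                                 plane$normal, plane$side)
  tr_b <- register_overlay(c1_m, pair$c2, exclude = plane_m, subsample = 6000)
  dv_b <- luminal_volume(transform_mask(pair$c2, tr_b), plane_m) -
          luminal_volume(c1_m, plane_m)
  expect_lt(abs(dv_a - dv_b), 0.01 * abs(luminal_volume(pair$c1, plane)))
})

test_that("delimitation planes and transforms serialize losslessly", {
  plane <- region_delimitation(c(0.5, -1, 2), c(1, 2, 2), side = -1)
  path <- tempfile(fileext = ".json")
  write_region(plane, path)
  back <- read_region(path)
  expect_equal(back$point, plane$point)
  expect_equal(back$normal, plane$normal)
  expect_equal(back$side, plane$side)
  tr <- rigid_transform(euler_rotation(rz = 0.1), c(1, 2, 3))
  tpath <- tempfile(fileext = ".json")
  write_transform(tr, tpath)
  m <- matrix(jsonlite::read_json(tpath, simplifyVector = TRUE)$matrix_rowmajor,
              4, 4, byrow = TRUE)
  expect_equal(m, transform_matrix(tr))
  unlink(c(path, tpath))
})
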