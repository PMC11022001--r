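#' Rigid transform (rotation + translation)
#'
#' Maps world points as \code{x' = R x + t} (mm).
#'
#' @param rotation 3 x 3 rotation matrix.
#' @param translation Length-3 translation, mm.
#' @return An object of class \code{rigid_transform}.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  stopifnot(all(dim(rotation) == c(3, 3)))
  structure(list(rotation = rotation, translation = as.numeric(translation)),
            class = "rigid_transform")
}

#' Apply a rigid transform to points
#' @param transform A \code{\link{rigid_transform}}.
#' @param pts n x 3 matrix, mm.
#' @return Transformed n x 3 matrix.
#' @export
apply_transform <- function(transform, pts) {
  pts <- matrix(pts, ncol = 3)
  sweep(pts %*% t(transform$rotation), 2, transform$translation, "+")
}

#' Invert a rigid transform
#' @param transform A \code{\link{rigid_transform}}.
#' @return The inverse \code{\link{rigid_transform}}.
#' @export
invert_transform <- function(transform) {
  Rt <- t(transform$rotation)
  rigid_transform(Rt, -as.vector(Rt %*% transform$translation))
}

#' Rotation matrix from Euler angles (radians, Rz Ry Rx convention)
#' @param rx,ry,rz Rotations about x, y, z, radians.
#' @return 3 x 3 rotation matrix.
#' @export
euler_rotation <- function(rx = 0, ry = 0, rz = 0) {
  Rx <- rbind(c(1, 0, 0), c(0, cos(rx), -sin(rx)), c(0, sin(rx), cos(rx)))
  Ry <- rbind(c(cos(ry), 0, sin(ry)), c(0, 1, 0), c(-sin(ry), 0, cos(ry)))
  Rz <- rbind(c(cos(rz), -sin(rz), 0), c(sin(rz), cos(rz), 0), c(0, 0, 1))
  Rz %*% Ry %*% Rx
}

#' Total rotation angle of a transform (degrees)
#' @param transform A \code{\link{rigid_transform}}.
#' @return Angle in degrees of the axis-angle decomposition.
#' @export
rotation_angle <- function(transform) {
  tr <- sum(diag(transform$rotation))
  acos(pmin(pmax((tr - 1) / 2, -1), 1)) * 180 / pi
}

#' 4 x 4 homogeneous matrix of a transform
#' @param transform A \code{\link{rigid_transform}}.
#' @return 4 x 4 matrix (row-major semantics when serialized).
#' @export
transform_matrix <- function(transform) {
  m <- diag(4)
  m[1:3, 1:3] <- transform$rotation
  m[1:3, 4] <- transform$translation
  m
}

#' Serialize a rigid transform as JSON (4 x 4 row-major)
#' @param transform A \code{\link{rigid_transform}}.
#' @param path JSON path.
#' @return \code{path}, invisibly.
#' @export
write_transform <- function(transform, path) {
  m <- transform_matrix(transform)
  jsonlite::write_json(list(matrix_rowmajor = as.vector(t(m))), path,
                       auto_unbox = FALSE, digits = NA)
  invisible(path)
}

# trilinear interpolation of a mask's occupancy at world points (0 outside)
.trilinear <- function(mask, pts) {
  d <- dim(mask$occupancy)
  u <- sweep(sweep(pts, 2, mask$origin, "-"), 2, mask$voxel_size, "/") + 1
  i0 <- floor(u)
  f <- u - i0
  val <- numeric(nrow(pts))
  occ_at <- function(i, j, k) {
    ok <- i >= 1 & i <= d[1] & j >= 1 & j <= d[2] & k >= 1 & k <= d[3]
    out <- numeric(length(i))
    idx <- i[ok] + (j[ok] - 1) * d[1] + (k[ok] - 1) * d[1] * d[2]
    out[ok] <- mask$occupancy[idx]
    out
  }
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    w <- (if (dx) f[, 1] else 1 - f[, 1]) *
         (if (dy) f[, 2] else 1 - f[, 2]) *
         (if (dz) f[, 3] else 1 - f[, 3])
    val <- val + w * occ_at(i0[, 1] + dx, i0[, 2] + dy, i0[, 3] + dz)
  }
  val
}

# world coordinates of lumen voxel centers
.lumen_points <- function(mask) {
  ctr <- voxel_centers(mask)
  idx <- which(mask$occupancy == 1L)
  cbind(ctr$x[idx], ctr$y[idx], ctr$z[idx])
}

#' Rigid overlay registration of two segmentation masks
#'
#' Estimates the rigid transform aligning the stimulated mask (\code{c2})
#' onto the baseline mask (\code{c1}) by maximizing the overlap of the
#' masks restricted to the parent-artery region: voxels on the aneurysm
#' side of \code{exclude} are removed from the metric so the sac's
#' deformation does not bias the alignment. Initialization is by artery
#' centroids; refinement is derivative-free (Nelder-Mead) on the mean
#' trilinearly interpolated \code{c1} occupancy at the transformed
#' \code{c2} lumen points.
#'
#' @param c1,c2 \code{\link{segmentation_mask}}s covering the parent
#'   vessel.
#' @param exclude Optional \code{\link{region_delimitation}} whose positive
#'   side (the aneurysm) is excluded from the registration metric.
#' @param subsample Maximum number of \code{c2} points used (deterministic
#'   stride).
#' @param maxit Nelder-Mead iteration cap.
#' @return A \code{\link{rigid_transform}} mapping \code{c2} world
#'   coordinates into the \code{c1} frame, with attributes \code{dice}
#'   (post-registration artery Dice) and \code{objective}.
#' @export
register_overlay <- function(c1, c2, exclude = NULL, subsample = 20000,
                             maxit = 500) {
  stopifnot(inherits(c1, "segmentation_mask"), inherits(c2, "segmentation_mask"))
  p2 <- .lumen_points(c2)
  p1 <- .lumen_points(c1)
  if (!is.null(exclude)) {
    p2 <- p2[signed_distance(exclude, p2) <= 0, , drop = FALSE]
    p1 <- p1[signed_distance(exclude, p1) <= 0, , drop = FALSE]
  }
  if (nrow(p2) == 0 || nrow(p1) == 0)
    stop("no artery-region lumen voxels available for registration")
  n2_full <- nrow(p2)
  if (nrow(p2) > subsample)
    p2 <- p2[seq(1, nrow(p2), length.out = subsample), , drop = FALSE]
  t0 <- colMeans(p1) - colMeans(p2)
  c2m <- colMeans(p2)
  obj <- function(par) {
    R <- euler_rotation(par[1], par[2], par[3])
    # rotate about the moving centroid, then translate
    q <- sweep(sweep(p2, 2, c2m, "-") %*% t(R), 2, c2m + par[4:6], "+")
    -mean(.trilinear(c1, q))
  }
  fit <- stats::optim(c(0, 0, 0, t0), obj, method = "Nelder-Mead",
                      control = list(maxit = maxit, reltol = 1e-10))
  R <- euler_rotation(fit$par[1], fit$par[2], fit$par[3])
  # convert centroid-pivot parameterization to x' = R x + t
  t_full <- c2m + fit$par[4:6] - as.vector(R %*% c2m)
  tr <- rigid_transform(R, t_full)
  # binary Dice on the artery region after alignment
  q <- apply_transform(tr, p2)
  u <- round(sweep(sweep(q, 2, c1$origin, "-"), 2, c1$voxel_size, "/")) + 1
  d <- dim(c1$occupancy)
  ok <- u[, 1] >= 1 & u[, 1] <= d[1] & u[, 2] >= 1 & u[, 2] <= d[2] &
        u[, 3] >= 1 & u[, 3] <= d[3]
  hits <- sum(c1$occupancy[u[ok, 1] + (u[ok, 2] - 1) * d[1] +
                           (u[ok, 3] - 1) * d[1] * d[2]])
  overlap <- hits / nrow(p2) * n2_full
  dice <- 2 * overlap / (n2_full + nrow(p1))
  if (dice < 0.5)
    stop(sprintf("registration failure: artery Dice %.2f < 0.5 after alignment", dice))
  attr(tr, "dice") <- dice
  attr(tr, "objective") <- -fit$value
  tr
}

#' Rigidly transform a segmentation mask
#'
#' Pure translations are applied exactly by shifting the world origin;
#' general rigid motions resample the occupancy (nearest neighbour) onto a
#' grid of the same spacing covering the transformed lumen.
#'
#' @param mask A \code{\link{segmentation_mask}}.
#' @param transform A \code{\link{rigid_transform}}.
#' @return A transformed \code{\link{segmentation_mask}}.
#' @export
transform_mask <- function(mask, transform) {
  stopifnot(inherits(mask, "segmentation_mask"))
  if (isTRUE(all.equal(transform$rotation, diag(3), tolerance = 1e-12))) {
    out <- mask
    out$origin <- mask$origin + transform$translation
    return(out)
  }
  pts <- .lumen_points(mask)
  q <- apply_transform(transform, pts)
  lo <- apply(q, 2, min) - 2 * mask$voxel_size
  hi <- apply(q, 2, max) + 2 * mask$voxel_size
  n <- as.integer(ceiling((hi - lo) / mask$voxel_size)) + 1L
  occ <- array(0L, n)
  inv <- invert_transform(transform)
  ctr <- list(
    x = lo[1] + (seq_len(n[1]) - 1) * mask$voxel_size[1],
    y = lo[2] + (seq_len(n[2]) - 1) * mask$voxel_size[2],
    z = lo[3] + (seq_len(n[3]) - 1) * mask$voxel_size[3])
  X <- array(rep(ctr$x, times = n[2] * n[3]), n)
  Y <- array(rep(rep(ctr$y, each = n[1]), times = n[3]), n)
  Z <- array(rep(ctr$z, each = n[1] * n[2]), n)
  src <- apply_transform(inv, cbind(as.vector(X), as.vector(Y), as.vector(Z)))
  u <- round(sweep(sweep(src, 2, mask$origin, "-"), 2, mask$voxel_size, "/")) + 1
  d <- dim(mask$occupancy)
  ok <- u[, 1] >= 1 & u[, 1] <= d[1] & u[, 2] >= 1 & u[, 2] <= d[2] &
        u[, 3] >= 1 & u[, 3] <= d[3]
  vals <- integer(nrow(u))
  vals[ok] <- mask$occupancy[u[ok, 1] + (u[ok, 2] - 1) * d[1] +
                             (u[ok, 3] - 1) * d[1] * d[2]]
  occ[] <- vals
  segmentation_mask(occ, mask$voxel_size, lo, mask$label)
}
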