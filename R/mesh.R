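#' Triangulated surface mesh
#'
#' @param vertices n x 3 numeric matrix, world mm.
#' @param faces m x 3 integer matrix of vertex indices (1-based),
#'   consistently oriented with outward normals.
#' @return An object of class \code{tri_mesh}.
#' @export
tri_mesh <- function(vertices, faces) {
  vertices <- as.matrix(vertices)
  faces <- matrix(as.integer(as.matrix(faces)), ncol = 3)
  if (ncol(vertices) != 3) stop("vertices must be n x 3")
  if (max(faces) > nrow(vertices) || min(faces) < 1) stop("face index out of range")
  structure(list(vertices = vertices, faces = faces), class = "tri_mesh")
}

#' @export
print.tri_mesh <- function(x, ...) {
  cat(sprintf("triangulated mesh: %d vertices, %d faces, volume %.3f mm^3, area %.3f mm^2\n",
              nrow(x$vertices), nrow(x$faces), mesh_volume(x), mesh_area(x)))
  invisible(x)
}

# per-face vertex coordinate triplets
.face_coords <- function(mesh) {
  list(p1 = mesh$vertices[mesh$faces[, 1], , drop = FALSE],
       p2 = mesh$vertices[mesh$faces[, 2], , drop = FALSE],
       p3 = mesh$vertices[mesh$faces[, 3], , drop = FALSE])
}

.cross3 <- function(u, v) {
  cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
        u[, 3] * v[, 1] - u[, 1] * v[, 3],
        u[, 1] * v[, 2] - u[, 2] * v[, 1])
}

#' Enclosed volume of a closed mesh (mm^3)
#'
#' Divergence-theorem signed volume; positive for outward-oriented closed
#' surfaces.
#' @param mesh A \code{\link{tri_mesh}}.
#' @return Volume, mm^3.
#' @export
mesh_volume <- function(mesh) {
  fc <- .face_coords(mesh)
  abs(sum(rowSums(fc$p1 * .cross3(fc$p2, fc$p3)))) / 6
}

#' Surface area of a mesh (mm^2)
#' @param mesh A \code{\link{tri_mesh}}.
#' @return Area, mm^2.
#' @export
mesh_area <- function(mesh) {
  fc <- .face_coords(mesh)
  n <- .cross3(fc$p2 - fc$p1, fc$p3 - fc$p1)
  sum(sqrt(rowSums(n^2))) / 2
}

# face centroids and (unnormalized) outward normals
.face_centroids <- function(mesh) {
  fc <- .face_coords(mesh)
  (fc$p1 + fc$p2 + fc$p3) / 3
}
.face_normals <- function(mesh) {
  fc <- .face_coords(mesh)
  .cross3(fc$p2 - fc$p1, fc$p3 - fc$p1)
}

#' Surface mesh of a segmentation mask
#'
#' Extracts the exact voxel-boundary surface of the (largest connected
#' component of the) lumen as a watertight triangle mesh: every voxel face
#' separating lumen from background contributes two consistently oriented
#' triangles. The enclosed mesh volume equals the voxel-count volume by
#' construction.
#'
#' @param mask A \code{\link{segmentation_mask}} (non-empty).
#' @return A \code{\link{tri_mesh}} in world mm.
#' @export
mesh_from_mask <- function(mask) {
  stopifnot(inherits(mask, "segmentation_mask"))
  if (sum(mask$occupancy) == 0) stop("empty mask: no lumen voxels")
  occ <- .largest_component(mask)
  if (sum(occ) < sum(mask$occupancy))
    warning(sprintf("mask has %d disconnected lumen voxels; using the largest component",
                    sum(mask$occupancy) - sum(occ)), call. = FALSE)
  d <- dim(occ)
  h <- mask$voxel_size / 2
  # exposed faces per axis/sign via padded shifts
  pad <- array(0L, d + 2L)
  pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- occ
  core <- function(i, j, k) pad[i:(i + d[1] - 1), j:(j + d[2] - 1), k:(k + d[3] - 1)]
  shifts <- list(`+1` = core(3, 2, 2), `-1` = core(1, 2, 2),
                 `+2` = core(2, 3, 2), `-2` = core(2, 1, 2),
                 `+3` = core(2, 2, 3), `-3` = core(2, 2, 1))
  verts <- list(); faces <- list(); nv <- 0L
  axis_uv <- list(c(2, 3), c(3, 1), c(1, 2))
  for (nm in names(shifts)) {
    sgn <- if (substr(nm, 1, 1) == "+") 1 else -1
    ax <- as.integer(substr(nm, 2, 2))
    idx <- which(occ == 1L & shifts[[nm]] == 0L)
    if (length(idx) == 0) next
    ijk <- arrayInd(idx, d)
    ctr <- sweep(sweep(ijk - 1, 2, mask$voxel_size, "*"), 2, mask$origin, "+")
    uv <- axis_uv[[ax]]
    # quad corners in the (u, v) plane of the face, ordered for outward normal
    off_u <- c(-1, 1, 1, -1)
    off_v <- if (sgn > 0) c(-1, -1, 1, 1) else c(-1, 1, 1, -1)
    if (sgn < 0) off_u <- c(-1, -1, 1, 1)
    quad <- vector("list", 4)
    for (q in 1:4) {
      p <- ctr
      p[, ax] <- p[, ax] + sgn * h[ax]
      p[, uv[1]] <- p[, uv[1]] + off_u[q] * h[uv[1]]
      p[, uv[2]] <- p[, uv[2]] + off_v[q] * h[uv[2]]
      quad[[q]] <- p
    }
    n <- nrow(ctr)
    vmat <- rbind(quad[[1]], quad[[2]], quad[[3]], quad[[4]])
    i1 <- nv + seq_len(n); i2 <- i1 + n; i3 <- i2 + n; i4 <- i3 + n
    verts[[nm]] <- vmat
    faces[[nm]] <- rbind(cbind(i1, i2, i3), cbind(i1, i3, i4))
    nv <- nv + 4L * n
  }
  v <- do.call(rbind, verts)
  f <- do.call(rbind, faces)
  # merge duplicated corner vertices
  key <- paste(round(v[, 1], 9), round(v[, 2], 9), round(v[, 3], 9))
  uk <- !duplicated(key)
  remap <- match(key, key[uk])
  tri_mesh(v[uk, , drop = FALSE], matrix(remap[f], ncol = 3))
}

# largest 6-connected component of the lumen, as an integer array
.largest_component <- function(mask) {
  occ <- mask$occupancy
  d <- dim(occ)
  lab <- array(0L, d)
  comp <- 0L
  remaining <- which(occ == 1L & lab == 0L)
  sizes <- integer(0)
  while (length(remaining) > 0) {
    comp <- comp + 1L
    frontier <- remaining[1]
    lab[frontier] <- comp
    size <- 1L
    while (length(frontier) > 0) {
      ijk <- arrayInd(frontier, d)
      nbrs <- rbind(
        cbind(ijk[, 1] + 1L, ijk[, 2], ijk[, 3]),
        cbind(ijk[, 1] - 1L, ijk[, 2], ijk[, 3]),
        cbind(ijk[, 1], ijk[, 2] + 1L, ijk[, 3]),
        cbind(ijk[, 1], ijk[, 2] - 1L, ijk[, 3]),
        cbind(ijk[, 1], ijk[, 2], ijk[, 3] + 1L),
        cbind(ijk[, 1], ijk[, 2], ijk[, 3] - 1L))
      ok <- nbrs[, 1] >= 1 & nbrs[, 1] <= d[1] &
            nbrs[, 2] >= 1 & nbrs[, 2] <= d[2] &
            nbrs[, 3] >= 1 & nbrs[, 3] <= d[3]
      nidx <- unique(nbrs[ok, 1] + (nbrs[ok, 2] - 1L) * d[1] +
                     (nbrs[ok, 3] - 1L) * d[1] * d[2])
      nidx <- nidx[occ[nidx] == 1L & lab[nidx] == 0L]
      lab[nidx] <- comp
      size <- size + length(nidx)
      frontier <- nidx
    }
    sizes[comp] <- size
    remaining <- which(occ == 1L & lab == 0L)
  }
  best <- which.max(sizes)
  array(as.integer(lab == best), d)
}

#' Icosphere mesh
#'
#' Subdivided icosahedron projected to a sphere; a smooth watertight
#' surface for wall-offset and area computations.
#'
#' @param radius Sphere radius, mm.
#' @param center Center, mm.
#' @param subdivisions Number of 4-fold subdivisions (3 gives 1280 faces).
#' @return A \code{\link{tri_mesh}}.
#' @export
mesh_sphere <- function(radius, center = c(0, 0, 0), subdivisions = 3) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
             c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
             c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
             c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
             c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
             c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (s in seq_len(subdivisions)) {
    edges <- new.env(hash = TRUE)
    nv <- nrow(v)
    midpoint <- function(i, j) {
      key <- paste(min(i, j), max(i, j))
      id <- edges[[key]]
      if (is.null(id)) {
        m <- v[i, ] + v[j, ]
        m <- m / sqrt(sum(m^2))
        v <<- rbind(v, m)
        id <- nrow(v)
        edges[[key]] <- id
      }
      id
    }
    nf <- matrix(0L, nrow(f) * 4, 3)
    for (k in seq_len(nrow(f))) {
      a <- f[k, 1]; b <- f[k, 2]; c <- f[k, 3]
      ab <- midpoint(a, b); bc <- midpoint(b, c); ca <- midpoint(c, a)
      nf[(k - 1) * 4 + 1:4, ] <- rbind(c(a, ab, ca), c(b, bc, ab),
                                       c(c, ca, bc), c(ab, bc, ca))
    }
    f <- nf
  }
  tri_mesh(sweep(v * radius, 2, center, "+"), f)
}

#' Capped cylinder mesh
#'
#' Closed cylinder along the x axis, centered at the origin.
#'
#' @param radius Cylinder radius, mm.
#' @param length Cylinder length, mm.
#' @param n_theta Circumferential resolution.
#' @param n_x Axial ring count.
#' @return A \code{\link{tri_mesh}}.
#' @export
mesh_cylinder <- function(radius, length, n_theta = 64, n_x = 24) {
  xs <- seq(-length / 2, length / 2, length.out = n_x)
  th <- seq(0, 2 * pi, length.out = n_theta + 1)[-(n_theta + 1)]
  v <- do.call(rbind, lapply(xs, function(x)
    cbind(x, radius * cos(th), radius * sin(th))))
  ring <- function(i) (i - 1) * n_theta + seq_len(n_theta)
  f <- list()
  for (i in seq_len(n_x - 1)) {
    r1 <- ring(i); r2 <- ring(i + 1)
    nx1 <- c(seq_len(n_theta)[-1], 1)
    f[[i]] <- rbind(cbind(r1, r2[nx1], r2), cbind(r1, r1[nx1], r2[nx1]))
  }
  nv <- nrow(v)
  v <- rbind(v, c(-length / 2, 0, 0), c(length / 2, 0, 0))
  cl <- nv + 1L; cr <- nv + 2L
  r1 <- ring(1); rn <- ring(n_x)
  nx1 <- c(seq_len(n_theta)[-1], 1)
  f[["capL"]] <- cbind(cl, r1[nx1], r1)
  f[["capR"]] <- cbind(cr, rn, rn[nx1])
  m <- tri_mesh(v, do.call(rbind, f))
  # ensure outward orientation overall (positive signed volume)
  fcds <- .face_coords(m)
  vol <- sum(rowSums(fcds$p1 * .cross3(fcds$p2, fcds$p3))) / 6
  if (vol < 0) m$faces <- m$faces[, c(1, 3, 2)]
  m
}

#' Offset wall geometry from an inner surface
#'
#' Builds the outer wall surface by offsetting every vertex of the inner
#' (luminal) surface along its area-weighted outward vertex normal by the
#' wall thickness. Self-intersection of the offset (thickness large
#' relative to the local curvature radius) is detected via face-normal
#' flips and reported as an error.
#'
#' @param inner A closed \code{\link{tri_mesh}} (outward-oriented).
#' @param thickness Wall thickness, micrometres.
#' @return A \code{wall_geometry} list: \code{inner}, \code{outer}
#'   (\code{tri_mesh}es), \code{thickness} (um), \code{wall_volume} (mm^3),
#'   \code{region_labels} (per-face, defaults to "artery").
#' @export
build_wall <- function(inner, thickness = 430) {
  stopifnot(inherits(inner, "tri_mesh"))
  if (thickness <= 0) stop("wall thickness must be > 0 um")
  t_mm <- thickness / 1000
  fn <- .face_normals(inner)
  vn <- matrix(0, nrow(inner$vertices), 3)
  for (j in 1:3) {
    for (c in 1:3) {
      s <- rowsum(fn[, c], inner$faces[, j])
      vn[as.integer(rownames(s)), c] <- vn[as.integer(rownames(s)), c] + s
    }
  }
  nrm <- sqrt(rowSums(vn^2))
  nrm[nrm == 0] <- 1
  vn <- vn / nrm
  outer <- tri_mesh(inner$vertices + t_mm * vn, inner$faces)
  fo <- .face_normals(outer)
  if (any(rowSums(fo * fn) <= 0))
    stop("wall offset self-intersection: face normals flipped; thickness too large for local curvature")
  wall_volume <- mesh_volume(outer) - mesh_volume(inner)
  if (wall_volume <= 0) stop("wall offset self-intersection: non-positive wall volume")
  structure(list(inner = inner, outer = outer, thickness = thickness,
                 wall_volume = wall_volume,
                 region_labels = rep("artery", nrow(inner$faces))),
            class = "wall_geometry")
}

#' Write a mesh as ASCII STL
#'
#' @param mesh A \code{\link{tri_mesh}}.
#' @param path Output path.
#' @param name Solid name in the STL header.
#' @return \code{path}, invisibly.
#' @export
write_stl <- function(mesh, path, name = "surface") {
  fc <- .face_coords(mesh)
  n <- .cross3(fc$p2 - fc$p1, fc$p3 - fc$p1)
  len <- sqrt(rowSums(n^2)); len[len == 0] <- 1
  n <- n / len
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("solid %s", name), con)
  fmt <- paste0(" facet normal %.9g %.9g %.9g\n  outer loop\n",
                "   vertex %.9g %.9g %.9g\n   vertex %.9g %.9g %.9g\n",
                "   vertex %.9g %.9g %.9g\n  endloop\n endfacet")
  writeLines(sprintf(fmt, n[, 1], n[, 2], n[, 3],
                     fc$p1[, 1], fc$p1[, 2], fc$p1[, 3],
                     fc$p2[, 1], fc$p2[, 2], fc$p2[, 3],
                     fc$p3[, 1], fc$p3[, 2], fc$p3[, 3]), con)
  writeLines(sprintf("endsolid %s", name), con)
  invisible(path)
}
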