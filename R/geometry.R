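#' Voxel grid geometry
#'
#' A grid is a matrix size plus a 4x4 affine mapping 0-based voxel indices
#' (i, j, k) to scanner millimetres, the NIfTI convention. Slice gaps are
#' carried in the slice-direction spacing (thickness + gap), so two stacks
#' prescribed with a shared centre and orientation line up in world space.
#'
#' @param dim Integer vector of length 3 (matrix size).
#' @param spacing Voxel spacing in mm, length 3; the slice entry is
#'   thickness + gap.
#' @param affine Optional full 4x4 affine; overrides `spacing`/`center`.
#' @param center World coordinates (mm) of the grid centre; default origin.
#' @return An object of class `"grid_geometry"` with fields `dim`, `affine`.
#' @examples
#' g <- grid_geometry(c(64, 84, 8), c(39.2/64, 51.2/84, 2.4))
#' voxel_to_world(g, c(0, 0, 0))
#' @export
grid_geometry <- function(dim, spacing = NULL, affine = NULL, center = c(0, 0, 0)) {
  dim <- as.integer(dim)
  stopifnot(length(dim) == 3L, all(dim >= 1L))
  if (is.null(affine)) {
    stopifnot(length(spacing) == 3L, all(spacing > 0))
    affine <- diag(c(spacing, 1))
    affine[1:3, 4] <- center - spacing * (dim - 1L) / 2
  } else {
    affine <- unclass(affine)
    stopifnot(is.matrix(affine), all(dim(affine) == c(4L, 4L)))
    if (abs(det(affine[1:3, 1:3])) < 1e-12)
      stop("grid_geometry: singular affine")
  }
  attributes(affine) <- list(dim = c(4L, 4L))
  structure(list(dim = dim, affine = affine), class = "grid_geometry")
}

#' @export
print.grid_geometry <- function(x, ...) {
  cat("grid_geometry:", paste(x$dim, collapse = " x "), "voxels\n")
  cat("  affine (voxel -> mm):\n")
  print(round(x$affine, 5))
  invisible(x)
}

#' Default acquisition geometry
#'
#' Anatomical (1H) and fluorine (19F) grids sharing a 39.2 x 51.2 mm
#' field of view and the stack centre: 1H 196 x 256 in plane, 20 slices of
#' 1 mm with 0.2 mm gap; 19F 64 x 84, 8 slices of 2 mm with 0.4 mm gap.
#'
#' @return List with elements `anat` and `f19`, each a [grid_geometry()].
#' @export
default_geometry <- function() {
  list(anat = grid_geometry(c(196L, 256L, 20L), c(39.2 / 196, 51.2 / 256, 1.2)),
       f19  = grid_geometry(c(64L, 84L, 8L),   c(39.2 / 64,  51.2 / 84,  2.4)))
}

#' Map voxel indices to world coordinates
#'
#' @param geom A [grid_geometry()].
#' @param ijk 0-based voxel indices: length-3 vector or n x 3 matrix.
#' @return World coordinates in mm (same shape).
#' @export
voxel_to_world <- function(geom, ijk) {
  stopifnot(inherits(geom, "grid_geometry"))
  ijk <- rbind_coords(ijk)
  xyz <- ijk %*% t(geom$affine[1:3, 1:3]) +
    matrix(geom$affine[1:3, 4], nrow(ijk), 3, byrow = TRUE)
  drop_coords(xyz, ijk)
}

#' Map world coordinates to (continuous, 0-based) voxel indices
#'
#' @inheritParams voxel_to_world
#' @param xyz World coordinates in mm: length-3 vector or n x 3 matrix.
#' @export
world_to_voxel <- function(geom, xyz) {
  stopifnot(inherits(geom, "grid_geometry"))
  xyz <- rbind_coords(xyz)
  inv <- solve(geom$affine)
  ijk <- xyz %*% t(inv[1:3, 1:3]) +
    matrix(inv[1:3, 4], nrow(xyz), 3, byrow = TRUE)
  drop_coords(ijk, xyz)
}

rbind_coords <- function(x) {
  if (is.matrix(x)) {
    stopifnot(ncol(x) == 3L)
    x
  } else {
    stopifnot(length(x) == 3L)
    structure(matrix(x, 1L, 3L), was_vector = TRUE)
  }
}

drop_coords <- function(out, ref) {
  if (isTRUE(attr(ref, "was_vector"))) drop(out) else out
}

#' World coordinates of every voxel centre
#'
#' @inheritParams voxel_to_world
#' @return n_voxel x 3 matrix, column-major voxel order.
#' @export
grid_world_coords <- function(geom) {
  d <- geom$dim
  ijk <- cbind(rep.int(seq_len(d[1]) - 1L, d[2] * d[3]),
               rep.int(rep(seq_len(d[2]) - 1L, each = d[1]), d[3]),
               rep(seq_len(d[3]) - 1L, each = d[1] * d[2]))
  voxel_to_world(geom, ijk)
}

## Catmull-Rom kernel (a = -0.5), the bicubic convolution ImageJ uses.
cubic_weights <- function(t) {
  a <- -0.5
  w0 <- a * ((t + 1)^3) - 5 * a * ((t + 1)^2) + 8 * a * (t + 1) - 4 * a
  w1 <- (a + 2) * t^3 - (a + 3) * t^2 + 1
  w2 <- (a + 2) * (1 - t)^3 - (a + 3) * (1 - t)^2 + 1
  w3 <- a * ((2 - t)^3) - 5 * a * ((2 - t)^2) + 8 * a * (2 - t) - 4 * a
  list(w0, w1, w2, w3)
}

#' Resample a volume between voxel grids
#'
#' Pulls values from `source_geom` onto every voxel centre of `target_geom`
#' through world space (target voxel -> mm -> continuous source voxel).
#' Interpolation order 0 is nearest neighbour (mask transport), 1 is
#' trilinear, and 3 is separable tricubic convolution with the Catmull-Rom
#' kernel (the "bicubic" of common image tools, applied in all three axes).
#' Source indices are clamped at the edges; target voxels whose centre falls
#' more than half a voxel outside the source extent receive `fill`.
#'
#' @param vol 3-D numeric array on `source_geom`.
#' @param source_geom,target_geom [grid_geometry()] objects.
#' @param order Interpolation order: 0, 1 or 3.
#' @param fill Value for voxels outside the source field of view.
#' @return 3-D array with `target_geom$dim`.
#' @export
resample_between_grids <- function(vol, source_geom, target_geom,
                                   order = 1L, fill = 0) {
  stopifnot(inherits(source_geom, "grid_geometry"),
            inherits(target_geom, "grid_geometry"),
            all(dim(vol) == source_geom$dim))
  order <- as.integer(order)
  if (!order %in% c(0L, 1L, 3L))
    stop("resample_between_grids: order must be 0, 1 or 3")
  M <- solve(source_geom$affine) %*% target_geom$affine  # target vox -> source vox
  d <- target_geom$dim
  sd <- source_geom$dim
  off_diag <- M[1:3, 1:3]; diag(off_diag) <- 0
  if (max(abs(off_diag)) < 1e-10)  # axis-aligned: separable per-axis passes
    return(resample_separable(vol, M, d, order, fill))
  n <- prod(d)
  i <- rep.int(seq_len(d[1]) - 1L, d[2] * d[3])
  j <- rep.int(rep(seq_len(d[2]) - 1L, each = d[1]), d[3])
  k <- rep(seq_len(d[3]) - 1L, each = d[1] * d[2])
  sx <- M[1, 1] * i + M[1, 2] * j + M[1, 3] * k + M[1, 4]
  sy <- M[2, 1] * i + M[2, 2] * j + M[2, 3] * k + M[2, 4]
  sz <- M[3, 1] * i + M[3, 2] * j + M[3, 3] * k + M[3, 4]
  inside <- sx > -0.5 & sx < sd[1] - 0.5 &
            sy > -0.5 & sy < sd[2] - 0.5 &
            sz > -0.5 & sz < sd[3] - 0.5
  clamp <- function(v, hi) pmin.int(pmax.int(v, 0L), hi)
  out <- numeric(n)
  if (order == 0L) {
    ix <- clamp(as.integer(round(sx)), sd[1] - 1L)
    iy <- clamp(as.integer(round(sy)), sd[2] - 1L)
    iz <- clamp(as.integer(round(sz)), sd[3] - 1L)
    out <- vol[1L + ix + sd[1] * (iy + sd[2] * iz)]
  } else if (order == 1L) {
    x0 <- floor(sx); y0 <- floor(sy); z0 <- floor(sz)
    fx <- sx - x0; fy <- sy - y0; fz <- sz - z0
    for (dz in 0:1) for (dy in 0:1) for (dx in 0:1) {
      w <- (if (dx) fx else 1 - fx) * (if (dy) fy else 1 - fy) *
           (if (dz) fz else 1 - fz)
      ix <- clamp(as.integer(x0) + dx, sd[1] - 1L)
      iy <- clamp(as.integer(y0) + dy, sd[2] - 1L)
      iz <- clamp(as.integer(z0) + dz, sd[3] - 1L)
      out <- out + w * vol[1L + ix + sd[1] * (iy + sd[2] * iz)]
    }
  } else {
    x0 <- floor(sx); y0 <- floor(sy); z0 <- floor(sz)
    wx <- cubic_weights(sx - x0)
    wy <- cubic_weights(sy - y0)
    wz <- cubic_weights(sz - z0)
    ix <- lapply(0:3, function(dx) clamp(as.integer(x0) + dx - 1L, sd[1] - 1L))
    iy <- lapply(0:3, function(dy) clamp(as.integer(y0) + dy - 1L, sd[2] - 1L))
    iz <- lapply(0:3, function(dz) clamp(as.integer(z0) + dz - 1L, sd[3] - 1L))
    for (dz in 1:4) {
      izoff <- sd[1] * sd[2] * iz[[dz]]
      for (dy in 1:4) {
        iyz <- 1L + sd[1] * iy[[dy]] + izoff
        wyz <- wy[[dy]] * wz[[dz]]
        for (dx in 1:4) {
          out <- out + (wx[[dx]] * wyz) * vol[ix[[dx]] + iyz]
        }
      }
    }
  }
  out[!inside] <- fill
  array(out, dim = d)
}

## Separable resampling for axis-aligned voxel maps: one 1-D interpolation
## pass per axis (4 taps each for cubic instead of 64), identical result to
## the generic path.
resample_separable <- function(vol, M, tdim, order, fill) {
  src_dim <- dim(vol)
  outside <- vector("list", 3L)
  out <- vol
  for (ax in 1:3) {
    coord <- M[ax, ax] * (seq_len(tdim[ax]) - 1) + M[ax, 4]
    outside[[ax]] <- coord <= -0.5 | coord >= src_dim[ax] - 0.5
    out <- interp_axis(out, ax, coord, order)
  }
  if (any(outside[[1]])) out[outside[[1]], , ] <- fill
  if (any(outside[[2]])) out[, outside[[2]], ] <- fill
  if (any(outside[[3]])) out[, , outside[[3]]] <- fill
  out
}

interp_axis <- function(vol, ax, coord, order) {
  n_src <- dim(vol)[ax]
  clamp1 <- function(v) pmin.int(pmax.int(v, 1L), n_src)
  x0 <- as.integer(floor(coord))
  if (order == 0L) {
    taps <- list(list(idx = clamp1(as.integer(round(coord)) + 1L),
                      w = rep(1, length(coord))))
  } else if (order == 1L) {
    f <- coord - x0
    taps <- list(list(idx = clamp1(x0 + 1L), w = 1 - f),
                 list(idx = clamp1(x0 + 2L), w = f))
  } else {
    w <- cubic_weights(coord - x0)
    taps <- lapply(1:4, function(t) list(idx = clamp1(x0 + t - 1L), w = w[[t]]))
  }
  newdim <- dim(vol); newdim[ax] <- length(coord)
  acc <- array(0, newdim)
  for (tp in taps) {
    sl <- switch(ax,
                 vol[tp$idx, , , drop = FALSE],
                 vol[, tp$idx, , drop = FALSE],
                 vol[, , tp$idx, drop = FALSE])
    w_rep <- switch(ax,
                    tp$w,
                    rep(tp$w, each = newdim[1L]),
                    rep(tp$w, each = newdim[1L] * newdim[2L]))
    acc <- acc + sl * w_rep
  }
  acc
}

#' Transport an integer label volume to another grid
#'
#' Nearest-neighbour resampling for masks and label maps (used for noise-ROI
#' transport and QC overlays; quantitative SNR maps travel the other way,
#' interpolated up to the anatomical grid).
#'
#' @param labels Integer 3-D array.
#' @inheritParams resample_between_grids
#' @return Integer array on the target grid; outside voxels get 0.
#' @export
resample_labels <- function(labels, source_geom, target_geom) {
  out <- resample_between_grids(labels, source_geom, target_geom,
                                order = 0L, fill = 0)
  storage.mode(out) <- "integer"
  out
}
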