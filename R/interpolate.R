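# Voxel-map -> mesh sampling at element centroids (the single integration
# point of each linear tetrahedron).

# world (mm) -> continuous 0-based voxel index
.worldToIndex <- function(affine, pts) {
  inv <- solve(affine)
  t(inv %*% rbind(t(pts), 1))[, 1:3, drop = FALSE]
}

#' Sample a voxel map onto mesh elements
#'
#' Evaluates the map at each element centroid, either by trilinear
#' interpolation (default; exact for fields that are affine in space) or by
#' nearest neighbour (for binary masks such as lesion segmentations).
#'
#' @param map a [VoxelMap-class].
#' @param mesh a [TetMesh-class]; all element centroids must fall inside the
#'   voxel grid after the affine transform.
#' @param method "trilinear" or "nearest".
#' @return numeric vector, one value per element.
#' @export
interpolateToMesh <- function(map, mesh, method = c("trilinear", "nearest")) {
  method <- match.arg(method)
  idx <- .worldToIndex(map@affine, elementCentroids(mesh))
  d <- dim(map@data)
  if (method == "nearest") {
    ijk <- round(idx)
    bad <- which(ijk[, 1] < 0 | ijk[, 1] > d[1] - 1 |
                 ijk[, 2] < 0 | ijk[, 2] > d[2] - 1 |
                 ijk[, 3] < 0 | ijk[, 3] > d[3] - 1)
    if (length(bad))
      stop(sprintf("element %d centroid falls outside the voxel grid", bad[1]))
    return(map@data[cbind(ijk[, 1] + 1L, ijk[, 2] + 1L, ijk[, 3] + 1L)])
  }
  bad <- which(idx[, 1] < 0 | idx[, 1] > d[1] - 1 |
               idx[, 2] < 0 | idx[, 2] > d[2] - 1 |
               idx[, 3] < 0 | idx[, 3] > d[3] - 1)
  if (length(bad))
    stop(sprintf("element %d centroid falls outside the voxel grid", bad[1]))
  i0 <- floor(idx)
  for (c in 1:3) i0[, c] <- pmax(pmin(i0[, c], d[c] - 2), 0)
  f <- idx - i0
  val <- numeric(nrow(idx))
  for (di in 0:1) for (dj in 0:1) for (dk in 0:1) {
    w <- (if (di) f[, 1] else 1 - f[, 1]) *
         (if (dj) f[, 2] else 1 - f[, 2]) *
         (if (dk) f[, 3] else 1 - f[, 3])
    val <- val + w * map@data[cbind(i0[, 1] + di + 1L, i0[, 2] + dj + 1L,
                                    i0[, 3] + dk + 1L)]
  }
  val
}
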