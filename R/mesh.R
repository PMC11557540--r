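# Tetrahedral mesh utilities: construction, volumes, centroids, surface
# extraction, region summaries. All coordinates in mm, volumes in mm^3.

# signed volumes of linear tets (positive for correctly oriented elements)
.tetVolumes <- function(nodes, tets) {
  a <- nodes[tets[, 1], , drop = FALSE]
  u <- nodes[tets[, 2], , drop = FALSE] - a
  v <- nodes[tets[, 3], , drop = FALSE] - a
  w <- nodes[tets[, 4], , drop = FALSE] - a
  (u[, 1] * (v[, 2] * w[, 3] - v[, 3] * w[, 2]) -
   u[, 2] * (v[, 1] * w[, 3] - v[, 3] * w[, 1]) +
   u[, 3] * (v[, 1] * w[, 2] - v[, 2] * w[, 1])) / 6
}

# the four faces of each tet, outward-oriented for a positive tet
.tetFaces <- function(tets) {
  rbind(tets[, c(2L, 3L, 4L)], tets[, c(1L, 4L, 3L)],
        tets[, c(1L, 2L, 4L)], tets[, c(1L, 3L, 2L)])
}

.extractSurface <- function(tets, nNodes) {
  faces <- .tetFaces(tets)
  lo <- pmin(faces[, 1], faces[, 2], faces[, 3])
  hi <- pmax(faces[, 1], faces[, 2], faces[, 3])
  mid <- faces[, 1] + faces[, 2] + faces[, 3] - lo - hi
  key <- ((lo - 1) * nNodes + (mid - 1)) * nNodes + hi
  r <- rle(sort(key))
  if (any(r$lengths > 2L)) stop("non-manifold mesh: a facet is shared by >2 tetrahedra")
  faces[key %in% r$values[r$lengths == 1L], , drop = FALSE]
}

#' Construct a tetrahedral mesh
#'
#' Validates connectivity and element volumes and extracts the outward-oriented
#' boundary triangles. Elements must be positively oriented; a zero or negative
#' signed volume is a validation error (degenerate or inverted element).
#'
#' @param nodes numeric matrix (n x 3) of coordinates in mm.
#' @param tets integer matrix (ne x 4) of 1-based connectivity.
#' @return a [TetMesh-class].
#' @examples
#' m <- tetMesh(rbind(c(0,0,0), c(1,0,0), c(0,1,0), c(0,0,1)),
#'              matrix(1:4, 1))
#' totalVolume(m)
#' @export
tetMesh <- function(nodes, tets) {
  nodes <- as.matrix(nodes)
  storage.mode(nodes) <- "double"
  tets <- as.matrix(tets)
  storage.mode(tets) <- "integer"
  surf <- .extractSurface(tets, nrow(nodes))
  new("TetMesh", nodes = nodes, tets = tets, surfaceFacets = surf)
}

#' @rdname tetMesh
#' @param mesh,object a [TetMesh-class].
#' @export
nElements <- function(mesh) nrow(mesh@tets)

#' @rdname tetMesh
#' @export
nNodes <- function(mesh) nrow(mesh@nodes)

#' @rdname tetMesh
#' @export
elementVolumes <- function(mesh) .tetVolumes(mesh@nodes, mesh@tets)

#' @rdname tetMesh
#' @export
totalVolume <- function(mesh) sum(elementVolumes(mesh))

#' @rdname tetMesh
#' @export
elementCentroids <- function(mesh) {
  (mesh@nodes[mesh@tets[, 1], , drop = FALSE] +
   mesh@nodes[mesh@tets[, 2], , drop = FALSE] +
   mesh@nodes[mesh@tets[, 3], , drop = FALSE] +
   mesh@nodes[mesh@tets[, 4], , drop = FALSE]) / 4
}

# outward unit normals and areas of the boundary triangles
.facetNormals <- function(nodes, facets) {
  a <- nodes[facets[, 1], , drop = FALSE]
  b <- nodes[facets[, 2], , drop = FALSE]
  c <- nodes[facets[, 3], , drop = FALSE]
  e1 <- b - a
  e2 <- c - a
  nvec <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
                e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
                e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  len <- sqrt(rowSums(nvec^2))
  list(normals = nvec / len, areas = len / 2)
}

setMethod("show", "TetMesh", function(object) {
  v <- elementVolumes(object)
  cat("TetMesh:", nrow(object@nodes), "nodes,", nrow(object@tets),
      "linear tetrahedra,", nrow(object@surfaceFacets), "boundary facets\n")
  cat(sprintf("  total volume %.2f cm^3, element volume %.3g-%.3g mm^3\n",
              sum(v) / 1e3, min(v), max(v)))
})

#' Volume and volume-weighted mean of a field over a masked region
#'
#' The observables compared against follow-up MRI (prostate volume, tumour
#' volume, mean cellularities) are all of this form: the region volume is the
#' sum of element volumes over the mask and the mean is volume-weighted, using
#' the single centroid integration point per element.
#'
#' @param mesh a [TetMesh-class].
#' @param field numeric, one value per element.
#' @param mask logical (or 0/1) per element; defaults to the whole mesh.
#' @return list with `volume` (mm^3) and `mean`.
#' @examples
#' m <- tetMesh(rbind(c(0,0,0), c(1,0,0), c(0,1,0), c(0,0,1)), matrix(1:4, 1))
#' regionSummary(m, 0.5)
#' @export
regionSummary <- function(mesh, field, mask = NULL) {
  ne <- nElements(mesh)
  if (length(field) != ne) stop("field must have one value per element")
  if (is.null(mask)) mask <- rep(TRUE, ne)
  if (is.numeric(mask)) {
    if (!all(mask %in% c(0, 1))) stop("mask must be binary")
    mask <- mask > 0
  }
  if (!any(mask)) stop("empty mask: no elements selected")
  v <- elementVolumes(mesh)[mask]
  list(volume = sum(v), mean = sum(v * field[mask]) / sum(v))
}
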