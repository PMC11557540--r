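# Mesh and voxel-map I/O: legacy ASCII VTK unstructured grids (tetrahedra
# only, optional per-element scalar arrays) and NIfTI-1 voxel maps via RNifti.

#' Write a tetrahedral mesh to a legacy ASCII VTK file
#'
#' Coordinates are written with 17 significant digits so that a
#' write/read round trip reproduces them bit-exactly.
#'
#' @param mesh a [TetMesh-class].
#' @param path output file (.vtk).
#' @param fields optional named list of per-element scalar fields.
#' @export
writeVTKMesh <- function(mesh, path, fields = list()) {
  n <- nrow(mesh@nodes)
  ne <- nrow(mesh@tets)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
               "prostasim tetrahedral mesh", "ASCII",
               "DATASET UNSTRUCTURED_GRID",
               sprintf("POINTS %d double", n)), con)
  writeLines(sprintf("%.17g %.17g %.17g",
                     mesh@nodes[, 1], mesh@nodes[, 2], mesh@nodes[, 3]), con)
  writeLines(sprintf("CELLS %d %d", ne, 5L * ne), con)
  writeLines(sprintf("4 %d %d %d %d", mesh@tets[, 1] - 1L, mesh@tets[, 2] - 1L,
                     mesh@tets[, 3] - 1L, mesh@tets[, 4] - 1L), con)
  writeLines(sprintf("CELL_TYPES %d", ne), con)
  writeLines(rep("10", ne), con)
  if (length(fields)) {
    if (is.null(names(fields)) || any(names(fields) == ""))
      stop("fields must be a named list")
    writeLines(sprintf("CELL_DATA %d", ne), con)
    for (nm in names(fields)) {
      f <- fields[[nm]]
      if (length(f) != ne) stop("field '", nm, "' must have one value per element")
      writeLines(c(sprintf("SCALARS %s double 1", nm), "LOOKUP_TABLE default"), con)
      writeLines(sprintf("%.17g", f), con)
    }
  }
  invisible(path)
}

#' Read a tetrahedral mesh from a legacy ASCII VTK file
#'
#' Only unstructured grids made exclusively of linear tetrahedra (VTK cell
#' type 10) are supported; any other cell type is an error.
#'
#' @param path a .vtk file written in the legacy ASCII format.
#' @return list with `mesh` (a [TetMesh-class]) and `fields` (named list of
#'   per-element scalars, possibly empty).
#' @export
readVTKMesh <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!any(grepl("^DATASET\\s+UNSTRUCTURED_GRID", lines, ignore.case = TRUE)))
    stop("not a VTK unstructured grid")
  toks <- function(l) strsplit(trimws(l), "\\s+")[[1]]
  ip <- grep("^POINTS", lines)[1]
  n <- as.integer(toks(lines[ip])[2])
  coords <- as.numeric(unlist(strsplit(trimws(lines[(ip + 1):(ip + n)]), "\\s+")))
  nodes <- matrix(coords, ncol = 3, byrow = TRUE)
  ic <- grep("^CELLS", lines)[1]
  ne <- as.integer(toks(lines[ic])[2])
  cells <- as.integer(unlist(strsplit(trimws(lines[(ic + 1):(ic + ne)]), "\\s+")))
  if (length(cells) != 5L * ne || any(cells[seq(1, length(cells), by = 5)] != 4L))
    stop("unsupported element: only 4-node tetrahedra are supported")
  cells <- matrix(cells, ncol = 5, byrow = TRUE)
  it <- grep("^CELL_TYPES", lines)[1]
  types <- as.integer(lines[(it + 1):(it + ne)])
  if (any(types != 10L))
    stop("unsupported element: VTK cell type ", types[which(types != 10L)[1]],
         " (only linear tetrahedra, type 10)")
  fields <- list()
  id <- grep("^CELL_DATA", lines)
  if (length(id)) {
    pos <- id[1] + 1L
    while (pos <= length(lines) && grepl("^SCALARS", lines[pos])) {
      nm <- toks(lines[pos])[2]
      pos <- pos + 2L  # skip LOOKUP_TABLE
      fields[[nm]] <- as.numeric(lines[pos:(pos + ne - 1L)])
      pos <- pos + ne
    }
  }
  list(mesh = tetMesh(nodes, cells[, 2:5] + 1L), fields = fields)
}

#' Voxel map construction and NIfTI I/O
#'
#' `voxelMap` wraps a 3D array with its voxel-to-world affine (NIfTI
#' convention, 0-based indices) and a unit tag. `readNIfTIMap` /
#' `writeNIfTIMap` convert between files and [VoxelMap-class] objects.
#'
#' @param data 3D numeric array.
#' @param affine 4x4 matrix mapping 0-based voxel indices to mm.
#' @param units unit tag, e.g. "mm^2/s" for ADC or "1/min" for KTrans.
#' @return a [VoxelMap-class].
#' @export
voxelMap <- function(data, affine = diag(4), units = "") {
  new("VoxelMap", data = data, affine = unname(as.matrix(affine)), units = units)
}

#' @rdname voxelMap
#' @param path a .nii or .nii.gz file.
#' @export
readNIfTIMap <- function(path, units = "") {
  img <- RNifti::readNifti(path)
  aff <- unname(matrix(as.numeric(RNifti::xform(img)), 4, 4))
  if (length(dim(img)) != 3L) stop("expected a 3D volume")
  arr <- array(as.numeric(img), dim = dim(img))
  voxelMap(arr, aff, units)
}

#' @rdname voxelMap
#' @param map a [VoxelMap-class].
#' @export
writeNIfTIMap <- function(map, path) {
  img <- RNifti::asNifti(map@data)
  img <- RNifti::`sform<-`(img, structure(map@affine, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

setMethod("show", "VoxelMap", function(object) {
  d <- dim(object@data)
  cat(sprintf("VoxelMap: %d x %d x %d voxels [%s], range %.4g..%.4g\n",
              d[1], d[2], d[3],
              if (nzchar(object@units)) object@units else "unitless",
              min(object@data), max(object@data)))
})
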