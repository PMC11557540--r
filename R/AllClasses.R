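#' @import methods
#' @importFrom Matrix sparseMatrix Diagonal
NULL

setClassUnion("numericOrNULL", c("numeric", "NULL"))

#' Tetrahedral mesh of the prostate
#'
#' A linear-tetrahedron mesh in millimetres. Element fields are evaluated at
#' one integration point per element, located at the centroid. The boundary
#' triangles (each belonging to exactly one tetrahedron) are extracted at
#' construction time and oriented outward.
#'
#' @slot nodes numeric matrix (n x 3), node coordinates in mm.
#' @slot tets integer matrix (ne x 4), 1-based connectivity, positively
#'   oriented (all signed volumes > 0).
#' @slot surfaceFacets integer matrix (nf x 3), boundary triangles, outward
#'   oriented.
#'
#' @export
setClass("TetMesh",
  representation(nodes = "matrix", tets = "matrix", surfaceFacets = "matrix"))

setValidity("TetMesh", function(object) {
  msg <- character(0)
  if (ncol(object@nodes) != 3L) msg <- c(msg, "nodes must be an n x 3 matrix")
  if (ncol(object@tets) != 4L) msg <- c(msg, "tets must be an ne x 4 matrix")
  if (any(object@tets < 1L) || any(object@tets > nrow(object@nodes)))
    msg <- c(msg, "connectivity indices out of range")
  if (!all(is.finite(object@nodes))) msg <- c(msg, "non-finite node coordinates")
  if (!length(msg)) {
    v <- .tetVolumes(object@nodes, object@tets)
    if (any(v <= 0))
      msg <- c(msg, sprintf("degenerate or inverted tetrahedra (min volume %.3g); first: element %d",
                            min(v), which.min(v)))
  }
  if (length(msg)) msg else TRUE
})

#' Scalar voxel map (NIfTI-like)
#'
#' A 3D scalar array with a voxel-index-to-mm affine. Indices are 0-based in
#' the affine convention (NIfTI): world = affine %*% c(i, j, k, 1).
#'
#' @slot data 3D numeric array.
#' @slot affine 4x4 numeric matrix mapping 0-based voxel indices to mm.
#' @slot units character unit tag (e.g. "mm^2/s", "1/min").
#'
#' @export
setClass("VoxelMap",
  representation(data = "array", affine = "matrix", units = "character"))

setValidity("VoxelMap", function(object) {
  msg <- character(0)
  if (length(dim(object@data)) != 3L) msg <- c(msg, "data must be a 3D array")
  if (!all(dim(object@affine) == c(4L, 4L))) msg <- c(msg, "affine must be 4x4")
  if (abs(det(object@affine)) < 1e-12) msg <- c(msg, "affine is singular")
  if (!all(is.finite(object@data))) msg <- c(msg, "non-finite voxel data")
  if (length(msg)) msg else TRUE
})

#' Carrying capacities of the tissue constituents
#'
#' Maximal constituent density in a fully saturated element. Tumour tissue is
#' assumed to pack more cells than the glandular healthy tissue.
#'
#' @slot rhoCT tumour-cell capacity (cells/mm^3).
#' @slot rhoCH healthy-cell capacity (cells/mm^3).
#' @slot rhoCS stroma capacity (g/mm^3).
#'
#' @export
setClass("CarryingCapacities",
  representation(rhoCT = "numeric", rhoCH = "numeric", rhoCS = "numeric"))

setValidity("CarryingCapacities", function(object) {
  msg <- character(0)
  if (any(c(object@rhoCT, object@rhoCH, object@rhoCS) <= 0))
    msg <- c(msg, "capacities must be > 0")
  if (object@rhoCT <= object@rhoCH)
    msg <- c(msg, "tumour capacity must exceed healthy capacity")
  if (length(msg)) msg else TRUE
})

#' Growth (population-dynamics) parameters
#'
#' @slot kg proliferation rate (1/day), shared by all constituents.
#' @slot k corrected carrying capacity (dimensionless, in (0, 1]); caps each
#'   constituent at k * rho_ci to reserve stromal space.
#' @slot kd hypoxic death rate (1/day).
#' @slot beta named numeric (t, h, s); proliferation damping 1/(1+beta_i).
#' @slot thetaP named numeric (t, h, s); oxygen proliferation thresholds (pmol).
#' @slot thetaD named numeric (t, h, s); oxygen death thresholds (pmol).
#'
#' @export
setClass("GrowthParams",
  representation(kg = "numeric", k = "numeric", kd = "numeric",
                 beta = "numeric", thetaP = "numeric", thetaD = "numeric"))

setValidity("GrowthParams", function(object) {
  msg <- character(0)
  need <- c("t", "h", "s")
  for (s in c("beta", "thetaP", "thetaD"))
    if (!all(need %in% names(slot(object, s))))
      msg <- c(msg, sprintf("%s must be named with t, h, s", s))
  if (!length(msg)) {
    if (any(object@thetaD[need] >= object@thetaP[need]))
      msg <- c(msg, "thetaD must be < thetaP for each constituent")
  }
  if (object@kg <= 0 || object@kd <= 0) msg <- c(msg, "kg and kd must be > 0")
  if (object@k <= 0 || object@k > 1) msg <- c(msg, "k must be in (0, 1]")
  if (length(msg)) msg else TRUE
})

#' Oxygen transport parameters
#'
#' @slot rhoBO blood oxygen concentration (pmol).
#' @slot Ao named numeric (t, h); maximal consumption rates (pmol/day).
#' @slot ko named numeric (t, h); half-consumption concentrations (pmol).
#' @slot dtd fast-timescale substep for the time-marching mode (day).
#' @slot tol relative-change convergence tolerance of the marching mode.
#'
#' @export
setClass("OxygenParams",
  representation(rhoBO = "numeric", Ao = "numeric", ko = "numeric",
                 dtd = "numeric", tol = "numeric"))

setValidity("OxygenParams", function(object) {
  msg <- character(0)
  if (object@rhoBO <= 0) msg <- c(msg, "rhoBO must be > 0")
  if (!all(c("t", "h") %in% names(object@Ao)) ||
      !all(c("t", "h") %in% names(object@ko)))
    msg <- c(msg, "Ao and ko must be named with t, h")
  else if (any(object@Ao[c("t", "h")] < 0) || any(object@ko[c("t", "h")] <= 0))
    msg <- c(msg, "Ao must be >= 0 and ko > 0")
  if (object@dtd <= 0 || object@tol <= 0) msg <- c(msg, "dtd and tol must be > 0")
  if (length(msg)) msg else TRUE
})

#' PSA kinetics parameters
#'
#' @slot alphaT PSA production rate of tumour cells (ng/mL/day).
#' @slot alphaH PSA production rate of healthy cells (ng/mL/day).
#' @slot gamma tissue PSA decay rate (1/day).
#' @slot gammaS serum PSA decay rate (1/day).
#'
#' @export
setClass("PSAParams",
  representation(alphaT = "numeric", alphaH = "numeric",
                 gamma = "numeric", gammaS = "numeric"))

setValidity("PSAParams", function(object) {
  msg <- character(0)
  if (object@alphaH < 0 || object@alphaT <= object@alphaH)
    msg <- c(msg, "require alphaT > alphaH >= 0")
  if (object@gamma < 0 || object@gammaS < 0)
    msg <- c(msg, "decay rates must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Mechanics and growth-law parameters
#'
#' @slot Et,Eh,Es Young's moduli of tumour cells, healthy cells and stroma (kPa).
#' @slot nu Poisson ratio.
#' @slot Kstiffness elastic-foundation stiffness of the prostate surroundings,
#'   normal traction per unit normal displacement (kPa/mm).
#' @slot Ktangential tangential foundation stiffness (kPa/mm); a small value
#'   removes the rigid modes the normal springs leave free.
#' @slot kv1,kv2 growth-branch constants of the growth stretch law.
#' @slot kd1 shrinking rate of the resorption branch.
#' @slot alpha thermal-analogy expansion ratio (1).
#' @slot Emin floor on the mixture modulus (kPa).
#'
#' @export
setClass("MechanicsParams",
  representation(Et = "numeric", Eh = "numeric", Es = "numeric",
                 nu = "numeric", Kstiffness = "numeric", Ktangential = "numeric",
                 kv1 = "numeric", kv2 = "numeric", kd1 = "numeric",
                 alpha = "numeric", Emin = "numeric"))

setValidity("MechanicsParams", function(object) {
  msg <- character(0)
  if (any(c(object@Et, object@Eh, object@Es) <= 0))
    msg <- c(msg, "moduli must be > 0")
  if (object@nu <= 0 || object@nu >= 0.5) msg <- c(msg, "nu must be in (0, 0.5)")
  if (object@Kstiffness < 0 || object@Ktangential < 0)
    msg <- c(msg, "foundation stiffness must be >= 0")
  if (object@kv1 + object@kv2 > 1.05 + 1e-9)
    msg <- c(msg, "kv1 + kv2 must not exceed 1.05")
  if (object@kd1 < 0) msg <- c(msg, "kd1 must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Full model parameter record
#'
#' @slot growth a [GrowthParams-class].
#' @slot oxygen an [OxygenParams-class].
#' @slot psa a [PSAParams-class].
#' @slot mechanics a [MechanicsParams-class].
#' @slot capacities a [CarryingCapacities-class].
#'
#' @export
setClass("ModelParams",
  representation(growth = "GrowthParams", oxygen = "OxygenParams",
                 psa = "PSAParams", mechanics = "MechanicsParams",
                 capacities = "CarryingCapacities"))

#' Per-element tissue state
#'
#' Constituent densities, oxygen and tissue PSA per element, plus the scalar
#' serum PSA.
#'
#' @slot rhoT tumour-cell density (cells/mm^3) per element.
#' @slot rhoH healthy-cell density (cells/mm^3) per element.
#' @slot rhoS stroma density (g/mm^3) per element.
#' @slot rhoO oxygen concentration (pmol) per element.
#' @slot P tissue PSA (ng/mL) per element.
#' @slot Ps serum PSA (ng/mL), scalar.
#'
#' @export
setClass("TissueState",
  representation(rhoT = "numeric", rhoH = "numeric", rhoS = "numeric",
                 rhoO = "numeric", P = "numeric", Ps = "numeric"))

setValidity("TissueState", function(object) {
  n <- length(object@rhoT)
  if (length(object@rhoH) != n || length(object@rhoS) != n)
    return("density fields must have equal length")
  if (any(c(object@rhoT, object@rhoH, object@rhoS) < 0))
    return("densities must be >= 0")
  TRUE
})

#' One patient's geometry, biomarkers and clinical series
#'
#' @slot mesh a [TetMesh-class] of the prostate at the diagnostic MRI.
#' @slot tumourMask logical per element; TRUE inside the lesion.
#' @slot cellularity per-element cellularity in [0, 1] (from ADC).
#' @slot ktrans per-element extravasation rate (1/day).
#' @slot pt biopsy tumour burden fraction in [0, 1].
#' @slot psaDates,psaValues serum PSA series (days since diagnostic MRI; ng/mL).
#' @slot followUp data.frame with columns date, prostateVolume (cm^3),
#'   tumourVolume (mm^3), prostateCellularity, tumourCellularity.
#' @slot seed integer seed used to generate the case (NA for clinical data).
#'
#' @export
setClass("PatientCase",
  representation(mesh = "TetMesh", tumourMask = "logical",
                 cellularity = "numeric", ktrans = "numeric", pt = "numeric",
                 psaDates = "numeric", psaValues = "numeric",
                 followUp = "data.frame", seed = "numeric"))

setValidity("PatientCase", function(object) {
  msg <- character(0)
  ne <- nrow(object@mesh@tets)
  for (s in c("tumourMask", "cellularity", "ktrans"))
    if (length(slot(object, s)) != ne)
      msg <- c(msg, sprintf("%s must have one value per element", s))
  if (!any(!object@tumourMask)) msg <- c(msg, "mask must leave a healthy region")
  if (any(object@cellularity < 0 | object@cellularity > 1))
    msg <- c(msg, "cellularity must lie in [0, 1]")
  if (any(object@ktrans < 0)) msg <- c(msg, "ktrans must be >= 0")
  if (object@pt < 0 || object@pt > 1) msg <- c(msg, "pt must lie in [0, 1]")
  if (length(object@psaDates) != length(object@psaValues))
    msg <- c(msg, "PSA dates and values must match")
  if (is.unsorted(object@psaDates, strictly = TRUE))
    msg <- c(msg, "PSA dates must be strictly increasing")
  if (any(object@psaValues < 0)) msg <- c(msg, "PSA values must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Simulated trajectory of observables
#'
#' @slot times step times (day), strictly increasing, starting at 0.
#' @slot observables data.frame with one row per time: prostateVolume (cm^3),
#'   tumourVolume (mm^3), prostateCellularity, tumourCellularity, serumPSA
#'   (ng/mL).
#' @slot snapshots named list of [TissueState-class] at requested times.
#' @slot finalState the [TissueState-class] at the final time.
#' @slot finalMesh the deformed [TetMesh-class] at the final time.
#'
#' @export
setClass("Trajectory",
  representation(times = "numeric", observables = "data.frame",
                 snapshots = "list", finalState = "TissueState",
                 finalMesh = "TetMesh"))

setValidity("Trajectory", function(object) {
  if (is.unsorted(object@times, strictly = TRUE))
    return("times must be strictly increasing")
  if (nrow(object@observables) != length(object@times))
    return("observables must have one row per time")
  TRUE
})
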