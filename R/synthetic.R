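# Synthetic patients with the statistical structure the model assumes: an
# ellipsoidal prostate with a single spherical lesion, smooth cellularity
# around 0.5 (elevated to ~0.6 in the tumour), heterogeneous positive KTrans,
# an exponentially trending serum PSA series, and forward-simulated follow-up
# observables for parameter-recovery experiments.

#' Ellipsoidal tetrahedral prostate mesh
#'
#' A structured cube lattice is triangulated into six tetrahedra per cell
#' (Freudenthal split) and mapped onto the ellipsoid with the standard
#' cube-to-ball map, so boundary nodes lie exactly on the ellipsoid surface
#' and the mesh volume converges quadratically in the element size. The
#' construction is deterministic: identical arguments give identical meshes.
#'
#' @param semiAxes positive semi-axes (a, b, c) in mm.
#' @param elementSize target lattice pitch in mm (the source meshes average
#'   2.5 mm).
#' @param center ellipsoid centre (mm).
#' @return a [TetMesh-class].
#' @examples
#' m <- makeProstateMesh(c(12, 10, 11), elementSize = 5)
#' totalVolume(m) / (4 / 3 * pi * prod(c(12, 10, 11)))  # close to 1
#' @export
makeProstateMesh <- function(semiAxes = c(24, 19, 22), elementSize = 2.5,
                             center = c(0, 0, 0)) {
  if (length(semiAxes) != 3 || any(semiAxes <= 0))
    stop("semiAxes must be three positive lengths")
  if (elementSize <= 0) stop("elementSize must be > 0")
  n <- max(4L, as.integer(round(2 * mean(semiAxes) / elementSize)))
  g <- seq(-1, 1, length.out = n + 1)
  grid <- expand.grid(i = 0:n, j = 0:n, k = 0:n)
  P <- cbind(g[grid$i + 1], g[grid$j + 1], g[grid$k + 1])
  # smooth analytic cube-to-ball map: boundary nodes land on the unit sphere
  # and interior elements keep far better aspect ratios than a radial
  # sup-norm projection (no slivers along the cube diagonals)
  x <- P[, 1]; y <- P[, 2]; z <- P[, 3]
  Q <- cbind(x * sqrt(pmax(1 - y^2 / 2 - z^2 / 2 + y^2 * z^2 / 3, 0)),
             y * sqrt(pmax(1 - z^2 / 2 - x^2 / 2 + z^2 * x^2 / 3, 0)),
             z * sqrt(pmax(1 - x^2 / 2 - y^2 / 2 + x^2 * y^2 / 3, 0)))
  nodes <- sweep(sweep(Q, 2, semiAxes, `*`), 2, center, `+`)
  idx <- function(i, j, k) (k * (n + 1L) + j) * (n + 1L) + i + 1L
  split6 <- rbind(c(0, 1, 3, 7), c(0, 3, 2, 7), c(0, 2, 6, 7),
                  c(0, 6, 4, 7), c(0, 4, 5, 7), c(0, 5, 1, 7))
  corners <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(1, 1, 0),
                   c(0, 0, 1), c(1, 0, 1), c(0, 1, 1), c(1, 1, 1))
  cells <- expand.grid(i = 0:(n - 1L), j = 0:(n - 1L), k = 0:(n - 1L))
  nc <- nrow(cells)
  tets <- matrix(0L, 6L * nc, 4L)
  for (t in 1:6) for (v in 1:4) {
    cc <- corners[split6[t, v] + 1L, ]
    tets[(t - 1L) * nc + seq_len(nc), v] <-
      idx(cells$i + cc[1], cells$j + cc[2], cells$k + cc[3])
  }
  tetMesh(nodes, tets)
}

# Gaussian random field at element centroids: white noise on an auxiliary
# lattice, smoothed by a separable Gaussian kernel with the given correlation
# length, trilinearly sampled at the centroids and standardized to unit sd.
.gaussianField <- function(centroids, correlationLength) {
  if (correlationLength <= 0) return(stats::rnorm(nrow(centroids)))
  pitch <- correlationLength / 2
  lo <- apply(centroids, 2, min) - 2 * correlationLength
  hi <- apply(centroids, 2, max) + 2 * correlationLength
  dims <- pmax(ceiling((hi - lo) / pitch) + 1L, 4L)
  arr <- array(stats::rnorm(prod(dims)), dims)
  r <- ceiling(3 * correlationLength / pitch)
  kern <- stats::dnorm(seq(-r, r) * pitch, sd = correlationLength)
  kern <- kern / sum(kern)
  smooth1 <- function(v) {
    n <- length(v)
    vp <- c(rep(v[1], r), v, rep(v[n], r))
    as.numeric(stats::filter(vp, kern, sides = 2))[(r + 1):(r + n)]
  }
  for (m in 1:3) {
    other <- setdiff(1:3, m)
    arr <- aperm(apply(arr, other, smooth1), order(c(m, other)))
  }
  # trilinear sample at centroids
  idx <- sweep(centroids, 2, lo) / pitch
  i0 <- pmin(pmax(floor(idx), 0), matrix(rep(dims - 2, each = nrow(idx)),
                                         ncol = 3))
  f <- idx - i0
  val <- numeric(nrow(idx))
  for (di in 0:1) for (dj in 0:1) for (dk in 0:1) {
    w <- (if (di) f[, 1] else 1 - f[, 1]) *
         (if (dj) f[, 2] else 1 - f[, 2]) *
         (if (dk) f[, 3] else 1 - f[, 3])
    val <- val + w * arr[cbind(i0[, 1] + di + 1, i0[, 2] + dj + 1,
                               i0[, 3] + dk + 1)]
  }
  s <- stats::sd(val)
  if (s > 0) (val - mean(val)) / s else val * 0
}

#' Synthetic biomarker fields and tumour mask
#'
#' The lesion is a single sphere; elements whose centroid falls inside it are
#' masked. Cellularity is a smooth correlated field around `baseCellularity`
#' (raised to `tumourCellularity` in the lesion); KTrans is lognormal around
#' `ktransMean` with the same spatial correlation.
#'
#' @param mesh a [TetMesh-class].
#' @param tumourCentre lesion centre (mm).
#' @param tumourRadius lesion radius (mm).
#' @param baseCellularity,tumourCellularity mean cellularity outside/inside
#'   the lesion.
#' @param ktransMean mean extravasation rate (1/day). The default matches the
#'   scale of the oxygen consumption parameters so that well-perfused tissue
#'   sits near the proliferation thresholds (see the package vignette).
#' @param cellularityNoise sd of the cellularity field (0 = piecewise
#'   constant).
#' @param ktransLogSD log-scale sd of the KTrans field.
#' @param correlationLength spatial correlation length (mm).
#' @param seed integer seed.
#' @return list with `cellularity`, `ktrans` (1/day) and `mask` (logical).
#' @export
makeBiomarkerFields <- function(mesh, tumourCentre, tumourRadius,
                                baseCellularity = 0.5, tumourCellularity = 0.6,
                                ktransMean = 15000, cellularityNoise = 0.05,
                                ktransLogSD = 0.25, correlationLength = 5,
                                seed = 1L) {
  set.seed(seed)
  cen <- elementCentroids(mesh)
  mask <- sqrt(colSums((t(cen) - tumourCentre)^2)) < tumourRadius
  if (!any(mask)) stop("no element centroid inside the lesion sphere")
  if (all(mask)) stop("lesion covers the whole mesh")
  g1 <- .gaussianField(cen, correlationLength)
  g2 <- .gaussianField(cen, correlationLength)
  cellularity <- ifelse(mask, tumourCellularity, baseCellularity) +
    cellularityNoise * g1
  cellularity <- pmin(pmax(cellularity, 0.01), 0.99)
  ktrans <- ktransMean * exp(ktransLogSD * g2 - ktransLogSD^2 / 2)
  list(cellularity = cellularity, ktrans = ktrans, mask = mask)
}

#' Assemble a complete synthetic patient
#'
#' Builds the mesh, biomarker fields and a pre-diagnosis serum PSA series
#' following an exponential trend with lognormal noise. The biopsy burden
#' `pt` defaults to a draw from the 2-13.6% range reported across the study
#' patients. Follow-up observations are attached by [makeObservations].
#'
#' @param seed integer seed (drives every random choice).
#' @param semiAxes,elementSize,center mesh geometry, see [makeProstateMesh].
#' @param tumourCentre,tumourRadius lesion sphere; the default centre offsets
#'   the lesion into the posterior half.
#' @param pt biopsy tumour burden fraction; NULL draws from U(0.02, 0.136).
#' @param psaA,psaB exponential PSA trend Ps(t) = psaA exp(psaB t) (ng/mL,
#'   1/day).
#' @param psaNoiseSD lognormal noise sd on the PSA measurements.
#' @param psaDates measurement days (<= 0: before/at the diagnostic MRI).
#' @param ... further arguments for [makeBiomarkerFields].
#' @return a [PatientCase-class] with an empty follow-up table.
#' @export
makeSyntheticPatient <- function(seed = 1L, semiAxes = c(24, 19, 22),
                                 elementSize = 2.5, center = c(0, 0, 0),
                                 tumourCentre = NULL, tumourRadius = 7,
                                 pt = NULL, psaA = 4, psaB = 8e-4,
                                 psaNoiseSD = 0.1,
                                 psaDates = seq(-360, 0, by = 90), ...) {
  mesh <- makeProstateMesh(semiAxes, elementSize, center)
  if (is.null(tumourCentre))
    tumourCentre <- center + c(0, -semiAxes[2] / 2, 0)
  fields <- makeBiomarkerFields(mesh, tumourCentre, tumourRadius,
                                seed = seed, ...)
  set.seed(seed + 1000L)
  if (is.null(pt)) pt <- stats::runif(1, 0.02, 0.136)
  psaValues <- psaA * exp(psaB * psaDates) *
    exp(stats::rnorm(length(psaDates), 0, psaNoiseSD))
  new("PatientCase", mesh = mesh, tumourMask = fields$mask,
      cellularity = fields$cellularity, ktrans = fields$ktrans, pt = pt,
      psaDates = psaDates, psaValues = psaValues,
      followUp = data.frame(date = numeric(0), prostateVolume = numeric(0),
                            tumourVolume = numeric(0),
                            prostateCellularity = numeric(0),
                            tumourCellularity = numeric(0)),
      seed = as.numeric(seed))
}

#' Forward-simulated follow-up observations (ground truth for recovery)
#'
#' Runs the simulator with `trueParams`, samples the observables at the
#' follow-up dates with multiplicative lognormal noise (volumes,
#' cellularities), and appends simulated serum PSA measurements with additive
#' Gaussian noise (floored at zero) to the patient's PSA series.
#'
#' @param patient a [PatientCase-class].
#' @param trueParams the generating [ModelParams-class].
#' @param followUpDates observation days (> 0).
#' @param volumeNoise,cellularityNoise lognormal sd for volumes/cellularities.
#' @param psaNoise additive sd (ng/mL) for the appended PSA measurements.
#' @param psaObsDates serum PSA measurement days (> 0); defaults to the
#'   follow-up dates and their midpoints.
#' @param seed integer seed for the observation noise.
#' @param config a [SimConfig-class]; `tFinal` is raised to cover the dates.
#' @return list with `patient` (observations attached) and `trajectory` (the
#'   noiseless forward run).
#' @export
makeObservations <- function(patient, trueParams = modelParams(),
                             followUpDates = c(350, 700), volumeNoise = 0,
                             cellularityNoise = 0, psaNoise = 0,
                             psaObsDates = NULL, seed = 1L,
                             config = simConfig()) {
  if (any(followUpDates <= 0)) stop("follow-up dates must be > 0")
  if (is.null(psaObsDates))
    psaObsDates <- sort(unique(c(followUpDates, followUpDates -
                                 diff(c(0, followUpDates)) / 2)))
  cfg <- config
  cfg@tFinal <- .roundUp(max(c(followUpDates, psaObsDates)), config@dt)
  traj <- simulateGrowth(patient, trueParams, cfg)
  obs <- summarizeAt(traj, followUpDates)
  set.seed(seed + 2000L)
  mnoise <- function(x, sd) x * exp(stats::rnorm(length(x), 0, sd))
  fu <- data.frame(date = followUpDates,
                   prostateVolume = mnoise(obs$prostateVolume, volumeNoise),
                   tumourVolume = mnoise(obs$tumourVolume, volumeNoise),
                   prostateCellularity = mnoise(obs$prostateCellularity,
                                                cellularityNoise),
                   tumourCellularity = mnoise(obs$tumourCellularity,
                                              cellularityNoise))
  psaSim <- summarizeAt(traj, psaObsDates)$serumPSA
  psaObs <- pmax(psaSim + stats::rnorm(length(psaSim), 0, psaNoise), 0)
  patient@followUp <- fu
  keep <- patient@psaDates <= 0
  patient@psaDates <- c(patient@psaDates[keep], psaObsDates)
  patient@psaValues <- c(patient@psaValues[keep], psaObs)
  validObject(patient)
  list(patient = patient, trajectory = traj)
}
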